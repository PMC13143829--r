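#' Synthetic speckle movie advected by a known flow
#'
#' Renders a band-limited random speckle texture (low-pass-filtered white
#' noise with a feature size comparable to a cell, ~50 px) and advects it
#' frame by frame with the flow described by a [flow_spec()].  Uniform flows
#' are advected by exact Fourier shifting; spatially varying flows by
#' periodic bilinear warping, so displacements are subpixel-accurate.  The
#' true per-frame-pair velocity fields are stored alongside the frames, which
#' is what makes the movie usable as a PIV accuracy benchmark.
#'
#' @param flow a [flow_spec()].
#' @param shape `c(nrow, ncol)` in px; each dimension must be at least 160 so
#'   a default 80x80 interrogation window fits with 50% overlap.
#' @param n_frames number of frames T (>= 2).
#' @param pixel_size_um physical pixel size, micrometres per pixel.
#' @param frame_interval_min time between frames, minutes.
#' @param feature_px approximate speckle feature size in px.
#' @param bit_noise standard deviation of per-frame additive sensor noise,
#'   as a fraction of the texture's dynamic range.
#' @return an object of class `synthetic_movie`: list with `frames`
#'   (H x W x T array, intensities in \[0, 1\]), `true_fields` (list of T-1
#'   `list(vx, vy)` px/frame), `flow`, `pixel_size_um`, `frame_interval_min`.
#' @export
make_speckle_movie <- function(flow, shape = c(480L, 480L), n_frames = 21L,
                               pixel_size_um = 0.65, frame_interval_min = 10,
                               feature_px = 50, bit_noise = 0.0) {
  stopifnot(inherits(flow, "flow_spec"))
  if (any(shape < 160)) {
    stop_input("movie shape must be at least 160x160 px so one 80x80 interrogation window fits with overlap",
               "collmot_sizing_error")
  }
  if (n_frames < 2) stop_input("need at least 2 frames", "collmot_parameter_error")
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  n_frames <- as.integer(n_frames)

  out <- with_seed(flow$seed + 1L, {
    base <- speckle_texture(nr, nc, feature_px)
    frames <- array(0, dim = c(nr, nc, n_frames))
    true_fields <- vector("list", n_frames - 1L)

    uniform <- flow$kind %in% c("uniform", "decaying-uniform")
    cur <- base
    shift_acc <- c(0, 0)
    frames[, , 1] <- cur
    for (t in seq_len(n_frames - 1L)) {
      tf <- flow_true_field(flow, c(nr, nc), t)
      true_fields[[t]] <- tf
      if (uniform) {
        # accumulate the exact subpixel shift and apply it to the pristine
        # texture, so no interpolation error ever accumulates
        shift_acc <- shift_acc + c(tf$vx[1, 1], tf$vy[1, 1])
        cur <- if (all(shift_acc == 0)) base else {
          fourier_shift(base, shift_acc[1], shift_acc[2])
        }
      } else if (any(tf$vx != 0) || any(tf$vy != 0)) {
        cur <- warp_bilinear(cur, tf$vx, tf$vy)
      }
      frames[, , t + 1L] <- cur
    }
    if (bit_noise > 0) {
      frames <- frames + array(stats::rnorm(length(frames), sd = bit_noise),
                               dim = dim(frames))
    }
    list(frames = frames, true_fields = true_fields)
  })

  structure(
    list(frames = out$frames, true_fields = out$true_fields, flow = flow,
         pixel_size_um = pixel_size_um, frame_interval_min = frame_interval_min),
    class = "synthetic_movie"
  )
}

# low-pass-filtered white noise, rescaled to [0, 1]
speckle_texture <- function(nr, nc, feature_px) {
  sigma <- feature_px / 6
  ky <- 2 * pi * fft_freq(nr)
  kx <- 2 * pi * fft_freq(nc)
  k2 <- outer(ky^2, kx^2, `+`)
  g <- exp(-k2 * sigma^2 / 2)
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  tex <- ifft2_real(stats::fft(w) * g)
  rng <- range(tex)
  (tex - rng[1]) / (rng[2] - rng[1])
}

# exact periodic subpixel translation: img(x - sx, y - sy)
fourier_shift <- function(img, sx, sy) {
  nr <- nrow(img); nc <- ncol(img)
  fy <- fft_freq(nr); fx <- fft_freq(nc)
  phase <- exp(-2i * pi * (outer(fy * sy, fx * sx, `+`)))
  ifft2_real(stats::fft(img) * phase)
}

# backward bilinear warp with periodic boundary: out(x) = img(x - v(x))
warp_bilinear <- function(img, vx, vy) {
  nr <- nrow(img); nc <- ncol(img)
  yy <- matrix(seq_len(nr), nr, nc) - vy
  xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - vx
  y0 <- floor(yy); x0 <- floor(xx)
  wy <- yy - y0; wx <- xx - x0
  iy0 <- ((y0 - 1) %% nr) + 1
  iy1 <- (y0 %% nr) + 1
  ix0 <- ((x0 - 1) %% nc) + 1
  ix1 <- (x0 %% nc) + 1
  idx <- function(iy, ix) img[cbind(as.vector(iy), as.vector(ix))]
  out <- (1 - wy) * (1 - wx) * idx(iy0, ix0) +
         (1 - wy) * wx       * idx(iy0, ix1) +
         wy       * (1 - wx) * idx(iy1, ix0) +
         wy       * wx       * idx(iy1, ix1)
  matrix(out, nr, nc)
}

#' @export
print.synthetic_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("synthetic_movie: %d frames of %dx%d px (%s flow)\n",
              d[3], d[1], d[2], x$flow$kind))
  cat(sprintf("  pixel size %.3g um, frame interval %.3g min\n",
              x$pixel_size_um, x$frame_interval_min))
  invisible(x)
}

#' Write a synthetic movie as multi-page TIFF with a YAML sidecar
#'
#' The sidecar records pixel size, frame interval and the flow ground truth
#' so a movie on disk remains a self-describing benchmark.
#'
#' @param movie a `synthetic_movie`.
#' @param path output TIFF path; the sidecar is written as `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "synthetic_movie"))
  frames <- movie$frames
  frames[frames < 0] <- 0; frames[frames > 1] <- 1
  pages <- lapply(seq_len(dim(frames)[3]), function(t) frames[, , t])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(
    pixel_size_um = movie$pixel_size_um,
    frame_interval_min = movie$frame_interval_min,
    flow = list(kind = movie$flow$kind, drift = movie$flow$drift,
                vrms = movie$flow$vrms, xi_true = movie$flow$xi_true,
                half_life = movie$flow$half_life, seed = movie$flow$seed)
  )
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a movie written by [write_movie_tiff()]
#'
#' @param path TIFF path with a `<path>.yaml` sidecar.
#' @return a `synthetic_movie`-like object (without true fields if the movie
#'   did not come from the generator).
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (t in seq_along(pages)) {
    p <- pages[[t]]
    if (length(dim(p)) == 3L) p <- p[, , 1]
    frames[, , t] <- p
  }
  meta_path <- paste0(path, ".yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  structure(
    list(frames = frames, true_fields = NULL, flow = meta$flow,
         pixel_size_um = meta$pixel_size_um %||% 1,
         frame_interval_min = meta$frame_interval_min %||% 1),
    class = "synthetic_movie"
  )
}
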