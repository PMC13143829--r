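#' PIV configuration
#'
#' Parameters of the windowed cross-correlation velocimetry: 80x80 px
#' interrogation windows (slightly larger than a typical cell of ~50 px) with
#' 50% spatial overlap, per-pair velocities at a 1-frame lag, and temporal
#' averaging of the per-pair fields over 20-frame chunks (200 min at the
#' default 10-min frame interval) advancing with 50% overlap.
#'
#' @param window_size_px interrogation-window side, px (>= 16).
#' @param overlap spatial overlap fraction between windows, in \[0, 1).
#' @param frame_lag lag between the two frames of a pair, frames (>= 1).
#' @param chunk_length frames per temporal-averaging chunk (>= 1).
#' @param chunk_overlap temporal overlap fraction between chunks, in \[0, 1).
#' @param subpixel subpixel peak interpolation: `"gaussian"` (3-point, per
#'   axis) or `"parabolic"`.
#' @param outlier_policy `"median"` applies a normalized-median test against
#'   the 8-neighbour vectors and replaces outliers with the local median;
#'   `"none"` keeps raw vectors.
#' @param pixel_size_um pixel size, micrometres (used for unit conversion).
#' @param frame_interval_min frame interval, minutes.
#' @param min_valid_fraction a chunk-averaged node is kept only if at least
#'   this fraction of the chunk is valid there.
#' @return object of class `piv_config`.
#' @export
piv_config <- function(window_size_px = 80L, overlap = 0.5, frame_lag = 1L,
                       chunk_length = 20L, chunk_overlap = 0.5,
                       subpixel = c("gaussian", "parabolic"),
                       outlier_policy = c("median", "none"),
                       pixel_size_um = 0.65, frame_interval_min = 10,
                       min_valid_fraction = 0.5) {
  subpixel <- match.arg(subpixel)
  outlier_policy <- match.arg(outlier_policy)
  if (window_size_px < 16) stop_input("window_size_px must be >= 16", "collmot_parameter_error")
  if (overlap < 0 || overlap >= 1) stop_input("overlap must be in [0, 1)", "collmot_parameter_error")
  if (chunk_overlap < 0 || chunk_overlap >= 1) stop_input("chunk_overlap must be in [0, 1)", "collmot_parameter_error")
  if (chunk_length < 1) stop_input("chunk_length must be >= 1", "collmot_parameter_error")
  if (frame_lag < 1) stop_input("frame_lag must be >= 1", "collmot_parameter_error")
  structure(
    list(window_size_px = as.integer(window_size_px), overlap = overlap,
         frame_lag = as.integer(frame_lag), chunk_length = as.integer(chunk_length),
         chunk_overlap = chunk_overlap, subpixel = subpixel,
         outlier_policy = outlier_policy, pixel_size_um = pixel_size_um,
         frame_interval_min = frame_interval_min,
         min_valid_fraction = min_valid_fraction),
    class = "piv_config"
  )
}

#' Displacement between two interrogation windows by cross-correlation
#'
#' Computes the zero-normalized cross-correlation of the two ROIs over all
#' integer lags via zero-padded FFTs: at each lag the correlation coefficient
#' of the overlapping parts of the two windows (each locally mean-subtracted
#' and variance-normalized), so the estimate carries no bias from the finite
#' window support.  The integer peak — searched within half the window size,
#' with at least 25% window overlap — is refined by 3-point Gaussian (or
#' parabolic) interpolation in each axis.  The returned displacement is the
#' shift of `roi_b` relative to `roi_a`: if `roi_b(x) = roi_a(x - d)` the
#' estimate is `d`.
#'
#' A constant (zero-variance) ROI cannot be correlated; the estimate is then
#' flagged invalid rather than raising an error, so one dead window does not
#' abort a whole movie.
#'
#' @param roi_a,roi_b numeric matrices of identical shape, >= 16x16.
#' @param subpixel `"gaussian"` or `"parabolic"`.
#' @param max_disp largest displacement searched, px; defaults to half the
#'   window size.
#' @return list with `dr` (c(dx, dy), px), `peak` (correlation coefficient at
#'   the peak), `snr` (peak over the highest non-adjacent secondary peak),
#'   `valid`.
#' @export
cross_correlate_window <- function(roi_a, roi_b,
                                   subpixel = c("gaussian", "parabolic"),
                                   max_disp = NULL) {
  subpixel <- match.arg(subpixel)
  stopifnot(is.matrix(roi_a), is.matrix(roi_b))
  if (!all(dim(roi_a) == dim(roi_b))) {
    stop_input("ROIs must have identical shape", "collmot_input_error")
  }
  if (any(dim(roi_a) < 16)) stop_input("ROIs must be at least 16x16", "collmot_input_error")
  if (stats::sd(roi_a) == 0 || stats::sd(roi_b) == 0) {
    return(list(dr = c(NA_real_, NA_real_), peak = NA_real_,
                snr = NA_real_, valid = FALSE))
  }
  nr <- nrow(roi_a); nc <- ncol(roi_a)
  if (is.null(max_disp)) max_disp <- floor(min(nr, nc) / 2)

  cc <- zncc_map(roi_a, roi_b, max_disp)

  pk <- which(cc$value == max(cc$value, na.rm = TRUE), arr.ind = TRUE)[1, ]
  iy <- pk[1]; ix <- pk[2]
  dy <- cc$lag_y[iy]; dx <- cc$lag_x[ix]

  cget <- function(di, dj) {
    i <- iy + di; j <- ix + dj
    if (i < 1 || i > nrow(cc$value) || j < 1 || j > ncol(cc$value)) return(NA_real_)
    cc$value[i, j]
  }
  refine <- function(cm, c0, cp) {
    if (!is.finite(cm) || !is.finite(cp)) return(0)
    if (subpixel == "gaussian" && cm > 0 && c0 > 0 && cp > 0) {
      den <- 2 * (log(cm) - 2 * log(c0) + log(cp))
      if (den < 0) return((log(cm) - log(cp)) / den)
    }
    den <- 2 * (cm - 2 * c0 + cp)
    if (den < 0) (cm - cp) / den else 0
  }
  c0 <- cget(0, 0)
  dy <- dy + refine(cget(-1, 0), c0, cget(1, 0))
  dx <- dx + refine(cget(0, -1), c0, cget(0, 1))

  # secondary peak outside the 3x3 neighbourhood of the primary
  mask <- is.finite(cc$value)
  for (di in -1:1) for (dj in -1:1) {
    i <- iy + di; j <- ix + dj
    if (i >= 1 && i <= nrow(mask) && j >= 1 && j <= ncol(mask)) mask[i, j] <- FALSE
  }
  second <- if (any(mask)) max(cc$value[mask]) else NA_real_
  snr <- if (is.finite(second) && second > 0) c0 / second else Inf

  list(dr = c(dx, dy), peak = c0, snr = snr, valid = TRUE)
}

# zero-normalized cross-correlation of b against a over integer lags
# |lag| <= max_disp, computed with zero-padded FFTs; lags with less than 25%
# window overlap are NA.  c(s) is the correlation coefficient of the
# overlapping parts of a(x) and b(x + s).
zncc_map <- function(a, b, max_disp) {
  nr <- nrow(a); nc <- ncol(a)
  mr <- nr + max_disp; mc <- nc + max_disp
  pad <- function(m) { p <- matrix(0, mr, mc); p[1:nr, 1:nc] <- m; p }
  xcorr <- function(f, g) {
    # C(f, g)(s) = sum_x f(x) g(x + s), s in [-(max_disp), +max_disp]
    Re(stats::fft(Conj(stats::fft(pad(f))) * stats::fft(pad(g)), inverse = TRUE)) /
      (mr * mc)
  }
  o <- matrix(1, nr, nc)
  n_ov <- xcorr(o, o)
  s_a  <- xcorr(a, o)
  s_b  <- xcorr(o, b)
  s_aa <- xcorr(a^2, o)
  s_bb <- xcorr(o, b^2)
  s_ab <- xcorr(a, b)

  # circular index set for lags -max_disp..max_disp along each axis
  idx_y <- c((mr - max_disp + 1):mr, 1:(max_disp + 1))
  idx_x <- c((mc - max_disp + 1):mc, 1:(max_disp + 1))
  lag_y <- c(-(max_disp:1), 0:max_disp)
  lag_x <- lag_y

  take <- function(m) m[idx_y, idx_x, drop = FALSE]
  n_ov <- take(n_ov); s_a <- take(s_a); s_b <- take(s_b)
  s_aa <- take(s_aa); s_bb <- take(s_bb); s_ab <- take(s_ab)

  n_ov <- round(n_ov)
  var_a <- s_aa - s_a^2 / n_ov
  var_b <- s_bb - s_b^2 / n_ov
  num <- s_ab - s_a * s_b / n_ov
  den <- sqrt(pmax(var_a, 0) * pmax(var_b, 0))
  val <- num / den
  val[den <= 1e-12] <- NA_real_
  val[n_ov < 0.25 * nr * nc] <- NA_real_
  val[!is.finite(val)] <- NA_real_
  val <- pmin(pmax(val, -1), 1)
  list(value = val, lag_y = lag_y, lag_x = lag_x)
}

# window start indices (1-based) along one dimension; partial far-edge
# windows are discarded
window_starts <- function(extent, ws, overlap) {
  step <- max(1L, as.integer(round(ws * (1 - overlap))))
  starts <- seq.int(1L, extent - ws + 1L, by = step)
  starts
}

#' Per-pair velocity fields of a movie by windowed cross-correlation
#'
#' Divides each frame into interrogation windows, estimates the displacement
#' of every window between frames `t` and `t + frame_lag`, and converts it to
#' a velocity `v = dr / lag` in px/frame.  Vectors failing the correlation
#' (constant windows) are masked; with the `"median"` outlier policy, vectors
#' failing a normalized-median test against their 8 neighbours are replaced
#' by the local median.
#'
#' @param movie a `synthetic_movie`, or a numeric H x W x T array.
#' @param config a [piv_config()]; its pixel size and frame interval are
#'   overridden by the movie's own metadata when present.
#' @return list of `velocity_field`s, one per frame pair.
#' @export
compute_velocity_fields <- function(movie, config = piv_config()) {
  stopifnot(inherits(config, "piv_config"))
  frames <- if (inherits(movie, "synthetic_movie")) movie$frames else movie
  stopifnot(length(dim(frames)) == 3L)
  if (inherits(movie, "synthetic_movie")) {
    config$pixel_size_um <- movie$pixel_size_um
    config$frame_interval_min <- movie$frame_interval_min
  }
  nT <- dim(frames)[3]
  lag <- config$frame_lag
  if (nT < lag + 1) stop_input("movie must have at least frame_lag + 1 frames", "collmot_input_error")
  ws <- config$window_size_px
  ys <- window_starts(dim(frames)[1], ws, config$overlap)
  xs <- window_starts(dim(frames)[2], ws, config$overlap)
  if (length(ys) < 2 || length(xs) < 2) {
    stop_input("movie dimensions admit fewer than 2x2 interrogation windows",
               "collmot_sizing_error")
  }
  # 0-based window-centre coordinates
  xc <- (xs - 1) + (ws - 1) / 2
  yc <- (ys - 1) + (ws - 1) / 2

  lapply(seq_len(nT - lag), function(t) {
    fa <- frames[, , t]; fb <- frames[, , t + lag]
    vx <- matrix(NA_real_, length(ys), length(xs))
    vy <- vx
    valid <- matrix(FALSE, length(ys), length(xs))
    for (i in seq_along(ys)) {
      for (j in seq_along(xs)) {
        ry <- ys[i]:(ys[i] + ws - 1); rx <- xs[j]:(xs[j] + ws - 1)
        est <- cross_correlate_window(fa[ry, rx], fb[ry, rx],
                                      subpixel = config$subpixel)
        if (est$valid) {
          vx[i, j] <- est$dr[1] / lag
          vy[i, j] <- est$dr[2] / lag
          valid[i, j] <- TRUE
        }
      }
    }
    if (config$outlier_policy == "median") {
      filt <- median_filter_vectors(vx, vy, valid)
      vx <- filt$vx; vy <- filt$vy
    }
    velocity_field(vx, vy, xc, yc, valid,
                   pixel_size_um = config$pixel_size_um,
                   frame_interval_min = config$frame_interval_min,
                   t_min = (t - 1 + lag / 2) * config$frame_interval_min)
  })
}

# normalized-median vector validation (threshold 2, noise floor 0.1 px),
# replacing detected outliers with the local median of their 8 neighbours
median_filter_vectors <- function(vx, vy, valid, threshold = 2, eps = 0.1) {
  nr <- nrow(vx); nc <- ncol(vx)
  out_vx <- vx; out_vy <- vy
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!valid[i, j]) next
      ni <- max(1, i - 1):min(nr, i + 1)
      nj <- max(1, j - 1):min(nc, j + 1)
      sel <- valid[ni, nj]
      sel[which(ni == i), which(nj == j)] <- FALSE
      if (sum(sel) < 3) next
      nvx <- vx[ni, nj][sel]; nvy <- vy[ni, nj][sel]
      mx <- stats::median(nvx); my <- stats::median(nvy)
      rmx <- stats::median(abs(nvx - mx)); rmy <- stats::median(abs(nvy - my))
      r0 <- sqrt(((vx[i, j] - mx) / (rmx + eps))^2 +
                 ((vy[i, j] - my) / (rmy + eps))^2)
      if (r0 > threshold) {
        out_vx[i, j] <- mx
        out_vy[i, j] <- my
      }
    }
  }
  list(vx = out_vx, vy = out_vy)
}

#' Temporal average of per-pair velocity fields over chunks
#'
#' Averages the per-pair fields over chunks of `chunk_length` fields whose
#' starts advance by `chunk_length * (1 - chunk_overlap)`; only complete
#' chunks are emitted.  A grid node of a chunk is valid only if at least
#' `min_valid_fraction` of the chunk's fields are valid there; its vector is
#' the mean of the valid vectors.
#'
#' @param fields list of `velocity_field`s (per frame pair).
#' @param chunk_length frames per chunk.
#' @param chunk_overlap overlap fraction between consecutive chunks.
#' @param min_valid_fraction per-node validity threshold.
#' @return list of chunk-averaged `velocity_field`s, timestamped at the chunk
#'   centre.
#' @export
temporal_average <- function(fields, chunk_length = 20L, chunk_overlap = 0.5,
                             min_valid_fraction = 0.5) {
  n <- length(fields)
  if (n < chunk_length) {
    stop_input("fewer per-pair fields than one chunk", "collmot_input_error")
  }
  step <- max(1L, as.integer(round(chunk_length * (1 - chunk_overlap))))
  starts <- seq.int(1L, n - chunk_length + 1L, by = step)
  lapply(starts, function(s) {
    chunk <- fields[s:(s + chunk_length - 1L)]
    f1 <- chunk[[1]]
    acc_x <- matrix(0, length(f1$y), length(f1$x))
    acc_y <- acc_x
    cnt <- acc_x
    for (f in chunk) {
      ok <- f$valid
      acc_x[ok] <- acc_x[ok] + f$vx[ok]
      acc_y[ok] <- acc_y[ok] + f$vy[ok]
      cnt[ok] <- cnt[ok] + 1
    }
    valid <- cnt >= min_valid_fraction * chunk_length & cnt > 0
    vx <- ifelse(valid, acc_x / pmax(cnt, 1), NA_real_)
    vy <- ifelse(valid, acc_y / pmax(cnt, 1), NA_real_)
    velocity_field(vx, vy, f1$x, f1$y, valid,
                   pixel_size_um = f1$pixel_size_um,
                   frame_interval_min = f1$frame_interval_min,
                   t_min = mean(vapply(chunk, `[[`, numeric(1), "t_min")))
  })
}
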