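#' Spectrally synthesized velocity field with exponential spatial correlation
#'
#' Generates a zero-mean, two-component Gaussian random vector field whose
#' isotropic spatial autocorrelation decays approximately as
#' \eqn{\exp(-\delta x/\xi)}.  The synthesis filters white noise in Fourier
#' space with the square root of the 2-D power spectrum of an exponential
#' correlation, \eqn{P(k) \propto (1 + (k\xi)^2)^{-3/2}}, whose inverse
#' transform is \eqn{\exp(-r/\xi)} in the continuum.  Each component is then
#' recentred to exactly zero mean and the pair rescaled so the combined
#' root-mean-square speed equals `vrms` exactly.
#'
#' Used as the ground-truth flow for correlated-motion speckle movies, so the
#' full PIV + correlation-fit pipeline can be checked against a known
#' correlation length.
#'
#' @param shape integer vector `c(nrow, ncol)` in pixels.
#' @param xi_true correlation length in pixels; must be positive.
#' @param vrms target root-mean-square speed, px/frame.
#' @param seed integer seed; identical arguments reproduce the field exactly.
#' @return list with matrices `vx`, `vy` (px/frame; rows index y, columns x).
#' @examples
#' f <- make_correlated_field(c(64, 64), xi_true = 10, vrms = 1, seed = 1)
#' sqrt(mean(f$vx^2 + f$vy^2))  # exactly 1
#' @export
make_correlated_field <- function(shape, xi_true, vrms, seed) {
  stopifnot(length(shape) == 2L, all(shape >= 4))
  if (!is.numeric(xi_true) || length(xi_true) != 1L || xi_true <= 0) {
    stop_input("'xi_true' must be a positive scalar", "collmot_parameter_error")
  }
  if (vrms < 0) {
    stop_input("'vrms' must be non-negative", "collmot_parameter_error")
  }
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])

  ky <- 2 * pi * fft_freq(nr)
  kx <- 2 * pi * fft_freq(nc)
  k2 <- outer(ky^2, kx^2, `+`)
  amp <- (1 + k2 * xi_true^2)^(-0.75)

  with_seed(seed, {
    comp <- lapply(1:2, function(i) {
      w <- matrix(stats::rnorm(nr * nc), nr, nc)
      v <- ifft2_real(stats::fft(w) * amp)
      v - mean(v)
    })
    vx <- comp[[1]]; vy <- comp[[2]]
    rms <- sqrt(mean(vx^2 + vy^2))
    if (rms > 0 && vrms > 0) {
      s <- vrms / rms
      vx <- vx * s; vy <- vy * s
    } else {
      vx[] <- 0; vy[] <- 0
    }
    list(vx = vx, vy = vy)
  })
}

#' Flow specification for synthetic movies
#'
#' Describes the imposed (not emergent) flow advecting a synthetic speckle
#' movie: a uniform drift, a spatially correlated random flow of known
#' correlation length, a drift whose amplitude decays in time (jamming
#' emulation), or a rigid vortex.  An optional temporal half-life applies a
#' \eqn{2^{-t/h}} amplitude decay to any kind.
#'
#' @param kind one of `"uniform"`, `"correlated"`, `"decaying-uniform"`,
#'   `"vortex"`.
#' @param drift length-2 drift vector `(vx, vy)` in px/frame (uniform kinds).
#' @param vrms target r.m.s. speed in px/frame (correlated and vortex kinds).
#' @param xi_true spatial correlation length in px (correlated kind).
#' @param half_life temporal decay half-life in frames; `Inf` for steady flow.
#' @param seed integer seed controlling all randomness of the movie.
#' @return an object of class `flow_spec`.
#' @export
flow_spec <- function(kind = c("uniform", "correlated", "decaying-uniform", "vortex"),
                      drift = c(0, 0), vrms = 0, xi_true = NULL,
                      half_life = Inf, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "correlated") {
    if (is.null(xi_true) || xi_true <= 0) {
      stop_input("correlated flow requires xi_true > 0", "collmot_parameter_error")
    }
    if (vrms < 0) stop_input("vrms must be >= 0", "collmot_parameter_error")
  }
  if (kind == "decaying-uniform" && !is.finite(half_life)) {
    stop_input("decaying-uniform flow requires a finite half_life",
               "collmot_parameter_error")
  }
  stopifnot(length(drift) == 2L, is.numeric(drift))
  structure(
    list(kind = kind, drift = as.numeric(drift), vrms = vrms,
         xi_true = xi_true, half_life = half_life, seed = as.integer(seed)),
    class = "flow_spec"
  )
}

# amplitude multiplier for the flow at frame-pair index t (1-based)
flow_decay <- function(spec, t) {
  if (!is.finite(spec$half_life)) return(1)
  2^(-(t - 1) / spec$half_life)
}

# instantaneous true velocity field (px/frame) for pair t -> t+1
flow_true_field <- function(spec, shape, t) {
  nr <- shape[1]; nc <- shape[2]
  g <- flow_decay(spec, t)
  switch(spec$kind,
    "uniform" = ,
    "decaying-uniform" = list(
      vx = matrix(spec$drift[1] * g, nr, nc),
      vy = matrix(spec$drift[2] * g, nr, nc)
    ),
    "correlated" = {
      base <- make_correlated_field(shape, spec$xi_true, spec$vrms, spec$seed)
      list(vx = base$vx * g, vy = base$vy * g)
    },
    "vortex" = {
      cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
      y <- matrix(seq_len(nr) - cy, nr, nc)
      x <- matrix(seq_len(nc) - cx, nr, nc, byrow = TRUE)
      vx <- -y; vy <- x
      rms <- sqrt(mean(vx^2 + vy^2))
      s <- if (rms > 0) spec$vrms / rms else 0
      list(vx = vx * s * g, vy = vy * s * g)
    }
  )
}
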