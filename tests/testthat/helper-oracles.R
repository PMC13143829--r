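# Independent oracles used to cross-check production code paths.

# Direct pair-enumeration radial velocity-velocity correlation: an explicit
# double loop over valid nodes, written independently of the vectorized
# production implementation.
cvv_enumerate <- function(field, bin_width_px) {
  ok <- which(field$valid, arr.ind = TRUE)
  n <- nrow(ok)
  denom <- 0
  sums <- list(); cnts <- list()
  for (p in seq_len(n)) {
    i <- ok[p, 1]; j <- ok[p, 2]
    denom <- denom + field$vx[i, j]^2 + field$vy[i, j]^2
  }
  denom <- denom / n
  acc <- new.env()
  for (p in seq_len(n)) {
    for (q in seq_len(n)) {
      i1 <- ok[p, 1]; j1 <- ok[p, 2]
      i2 <- ok[q, 1]; j2 <- ok[q, 2]
      d <- sqrt((field$x[j1] - field$x[j2])^2 + (field$y[i1] - field$y[i2])^2)
      b <- as.character(floor(d / bin_width_px + 0.5))
      dot <- field$vx[i1, j1] * field$vx[i2, j2] +
             field$vy[i1, j1] * field$vy[i2, j2]
      cur <- get0(b, envir = acc, ifnotfound = c(0, 0))
      assign(b, cur + c(dot, 1), envir = acc)
    }
  }
  bins <- sort(as.numeric(ls(acc)))
  data.frame(
    r_px = bins * bin_width_px,
    cvv = vapply(as.character(bins), function(b) {
      v <- get(b, envir = acc); v[1] / v[2] / denom
    }, numeric(1)),
    n_pairs = vapply(as.character(bins), function(b) get(b, envir = acc)[2],
                     numeric(1))
  )
}

# Radial autocorrelation of a raw vector field via Wiener-Khinchin, fitted
# log-linearly with a tail-offset correction.  Independent of the PIV path:
# it sees the generated field directly, before any velocimetry.
oracle_field_xi <- function(vx, vy, xi_guess) {
  ac <- function(m) {
    F <- stats::fft(m)
    Re(stats::fft(Conj(F) * F, inverse = TRUE)) / length(m)
  }
  a <- ac(vx) + ac(vy)
  a <- a / a[1, 1]
  nr <- nrow(vx); nc <- ncol(vx)
  yy <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  xx <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  dist <- sqrt(outer(yy^2, xx^2, `+`))
  tail_sel <- dist > 4 * xi_guess & dist < 6 * xi_guess
  m <- if (any(tail_sel)) mean(a[tail_sel]) else 0
  sel <- dist > 0 & dist <= 2 * xi_guess & (a - m) > 0
  fit <- stats::lm(log(a[sel] - m) ~ 0 + I(-dist[sel]))
  unname(1 / stats::coef(fit)[1])
}

# hand-rolled product-limit computation used to freeze KM expectations
km_by_hand <- function(time, event) {
  ut <- sort(unique(time))
  s <- 1
  out <- numeric(0)
  for (t in ut) {
    n_at_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    if (d > 0) s <- s * (1 - d / n_at_risk)
    out <- c(out, s)
  }
  data.frame(time = ut, survival = out)
}

make_test_field <- function(vx, vy, spacing = 40, pixel_size_um = 1,
                            frame_interval_min = 60) {
  stopifnot(all(dim(vx) == dim(vy)))
  x <- (seq_len(ncol(vx)) - 1) * spacing
  y <- (seq_len(nrow(vx)) - 1) * spacing
  velocity_field(vx, vy, x, y, pixel_size_um = pixel_size_um,
                 frame_interval_min = frame_interval_min)
}
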