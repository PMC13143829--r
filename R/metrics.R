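#' Total root-mean-square velocity of a field
#'
#' \eqn{v_{RMS} = \sqrt{\langle |v_t(x)|^2 \rangle_x}} over valid grid nodes.
#' Applied to raw fields it is the total r.m.s. velocity; applied after
#' [drift_correct()] it is the drift-corrected r.m.s. velocity.
#'
#' @param field a `velocity_field`.
#' @param units `"um_h"` (default) or `"px_frame"`.
#' @return scalar; `NA` (with a warning) when the field has no valid vectors.
#' @export
rms_velocity <- function(field, units = c("um_h", "px_frame")) {
  units <- match.arg(units)
  v2 <- field$vx[field$valid]^2 + field$vy[field$valid]^2
  if (length(v2) == 0) {
    warning("no valid vectors; r.m.s. velocity undefined")
    return(NA_real_)
  }
  out <- sqrt(mean(v2))
  if (units == "um_h") out * umh_factor(field) else out
}

#' Spatial mean (drift) vector of a field
#'
#' @param field a `velocity_field`.
#' @param units `"um_h"` or `"px_frame"`.
#' @return length-2 numeric `(vx, vy)`.
#' @export
drift_velocity <- function(field, units = c("um_h", "px_frame")) {
  units <- match.arg(units)
  if (!any(field$valid)) return(c(NA_real_, NA_real_))
  d <- c(mean(field$vx[field$valid]), mean(field$vy[field$valid]))
  if (units == "um_h") d * umh_factor(field) else d
}

#' Remove the spatial mean velocity (drift) from a field
#'
#' \eqn{v^{d.c.}_t(x) = v_t(x) - \langle v_t(x) \rangle_x}; the output field
#' has zero mean over its valid nodes to numerical precision.
#'
#' @param field a `velocity_field` with at least one valid vector.
#' @return the drift-corrected `velocity_field`.
#' @export
drift_correct <- function(field) {
  if (!any(field$valid)) stop_input("field has no valid vectors", "collmot_input_error")
  d <- drift_velocity(field, units = "px_frame")
  out <- field
  out$vx[out$valid] <- out$vx[out$valid] - d[1]
  out$vy[out$valid] <- out$vy[out$valid] - d[2]
  out
}

#' Radial velocity-velocity correlation function
#'
#' For every pair of valid grid nodes, accumulates the dot product of their
#' (drift-corrected) vectors into radial bins of pair separation, and
#' normalizes by the spatial mean squared magnitude:
#' \deqn{C_{vv}(\delta x) = \langle v^{d.c.}(x + \delta x) \cdot v^{d.c.}(x)
#'   \rangle_x / \langle |v^{d.c.}(x)|^2 \rangle_x .}
#' Self-pairs populate the first bin, which therefore equals 1 exactly.
#'
#' The input must already be drift-corrected: a residual mean inflates the
#' long-range plateau of the curve.  Pass the output of [drift_correct()].
#'
#' @param field a drift-corrected `velocity_field`.
#' @param bin_width_px radial bin width, px; defaults to the grid spacing.
#' @return object of class `correlation_curve`: data.frame with `r_px`,
#'   `r_um`, `cvv`, `n_pairs`, plus attributes `pixel_size_um` and
#'   `denominator`.
#' @export
velocity_correlation <- function(field, bin_width_px = NULL) {
  ok <- field$valid
  if (sum(ok) < 2) stop_input("need at least 2 valid nodes", "collmot_input_error")
  vx <- field$vx[ok]; vy <- field$vy[ok]
  xs <- rep(field$x, each = length(field$y))[as.vector(ok)]
  ys <- rep(field$y, times = length(field$x))[as.vector(ok)]
  denom <- mean(vx^2 + vy^2)
  if (denom <= .Machine$double.eps) {
    stop_input("degenerate field: zero velocity variance after drift correction; correlation undefined",
               "collmot_degenerate_field")
  }
  if (is.null(bin_width_px)) {
    sp <- c(diff(sort(unique(field$x))), diff(sort(unique(field$y))))
    bin_width_px <- if (length(sp)) min(sp) else 1
  }
  # all ordered pairs including self-pairs, via outer products
  dx <- outer(xs, xs, `-`)
  dy <- outer(ys, ys, `-`)
  dist <- sqrt(dx^2 + dy^2)
  dots <- outer(vx, vx) + outer(vy, vy)
  bin <- floor(dist / bin_width_px + 0.5)  # bin 0 centred on zero separation
  sums <- tapply(as.vector(dots), as.vector(bin), sum)
  cnts <- tapply(rep(1, length(bin)), as.vector(bin), sum)
  dsum <- tapply(as.vector(dist), as.vector(bin), sum)
  b <- as.integer(names(sums))
  curve <- data.frame(
    r_px = b * bin_width_px,
    r_um = b * bin_width_px * field$pixel_size_um,
    r_mean_px = as.numeric(dsum) / as.numeric(cnts),
    cvv = as.numeric(sums) / as.numeric(cnts) / denom,
    n_pairs = as.integer(cnts)
  )
  curve <- curve[order(curve$r_px), ]
  rownames(curve) <- NULL
  structure(curve, class = c("correlation_curve", "data.frame"),
            pixel_size_um = field$pixel_size_um, denominator = denom)
}

#' Fit an exponential decay to a correlation curve
#'
#' Least-squares fit of \eqn{C_{vv}(\delta x) = \exp(-\delta x / \xi)} on the
#' curve directly (not log-transformed, so near-zero bins are not discarded),
#' returning the spatial correlation length \eqn{\xi} in micrometres.  The
#' default fit range runs from the first off-origin bin to the first bin
#' where \eqn{C_{vv} \le 0.05} (or the last bin).  When the curve stays near
#' 1 across the whole range — the flocking limit — the fit pegs at the upper
#' bound and is flagged, with \eqn{\xi} reported as at least the field size.
#'
#' @param curve a `correlation_curve` (or data.frame with `r_um` and `cvv`).
#' @param fit_range optional `c(min_r_um, max_r_um)` overriding the default.
#' @return list with `xi_um`, `fit_ok`, `pegged`, `residual_norm`, `n_bins`,
#'   `fit_range_um`.
#' @export
fit_correlation_length <- function(curve, fit_range = NULL) {
  r <- curve$r_um; cv <- curve$cvv
  off <- which(r > 0)
  if (is.null(fit_range)) {
    if (length(off) == 0) {
      return(list(xi_um = NA_real_, fit_ok = FALSE, pegged = FALSE,
                  residual_norm = NA_real_, n_bins = 0L,
                  fit_range_um = c(NA_real_, NA_real_)))
    }
    lo <- min(r[off])
    below <- off[cv[off] <= 0.05]
    hi <- if (length(below)) r[min(below)] else max(r)
    fit_range <- c(lo, hi)
  }
  sel <- r >= fit_range[1] & r <= fit_range[2]
  rr <- r[sel]; cc <- cv[sel]
  if (sum(cc > 0) < 3) {
    return(list(xi_um = NA_real_, fit_ok = FALSE, pegged = FALSE,
                residual_norm = NA_real_, n_bins = sum(sel),
                fit_range_um = fit_range))
  }
  rmax <- max(rr)
  sse <- function(log_xi) sum((cc - exp(-rr / exp(log_xi)))^2)
  opt <- stats::optimize(sse, interval = log(c(rmax * 1e-3, rmax * 1e3)))
  xi <- exp(opt$minimum)
  pegged <- xi >= rmax * 0.999e3 || all(cc > 0.7)
  if (pegged) xi <- max(xi, rmax)
  list(xi_um = xi, fit_ok = TRUE, pegged = pegged,
       residual_norm = sqrt(opt$objective), n_bins = length(rr),
       fit_range_um = fit_range)
}

#' Alignment index map of a velocity field
#'
#' Per grid node, the cosine of the angle between the field's mean velocity
#' vector and the local velocity vector: values near 1 throughout indicate
#' flocking (long-range coordinated motion).  Nodes with zero-magnitude
#' vectors are masked; a zero mean vector leaves the whole map masked with a
#' warning flag.
#'
#' @param field a `velocity_field`.
#' @return matrix of alignment values in \[-1, 1\] (`NA` where masked), with
#'   attribute `degenerate = TRUE` when the mean vector was zero.
#' @export
alignment_index <- function(field) {
  d <- drift_velocity(field, units = "px_frame")
  a <- matrix(NA_real_, length(field$y), length(field$x))
  dn <- sqrt(sum(d^2))
  if (!is.finite(dn) || dn == 0) {
    warning("zero mean velocity: alignment index undefined everywhere")
    attr(a, "degenerate") <- TRUE
    return(a)
  }
  mag <- sqrt(field$vx^2 + field$vy^2)
  ok <- field$valid & mag > 0
  a[ok] <- (field$vx[ok] * d[1] + field$vy[ok] * d[2]) / (mag[ok] * dn)
  a[ok] <- pmin(1, pmax(-1, a[ok]))
  attr(a, "degenerate") <- FALSE
  a
}

#' Motility metrics time series from chunk-averaged fields
#'
#' For each chunk-averaged field: total r.m.s. velocity, drift vector,
#' drift-corrected r.m.s. velocity, fitted correlation length and the mean
#' alignment index — the quantities used to place a monolayer relative to
#' the jamming transition and to detect flocking.
#'
#' @param chunks list of chunk-averaged `velocity_field`s
#'   (see [temporal_average()]).
#' @param bin_width_px correlation bin width, px; default grid spacing.
#' @param fit_range optional fixed fit range in micrometres.
#' @return data.frame with one row per chunk: `t_min`, `vrms_tot_umh`,
#'   `drift_x_umh`, `drift_y_umh`, `vrms_dc_umh`, `xi_um`, `fit_ok`,
#'   `pegged`, `mean_alignment`.
#' @export
motility_metrics <- function(chunks, bin_width_px = NULL, fit_range = NULL) {
  rows <- lapply(chunks, function(f) {
    tot <- rms_velocity(f)
    d <- drift_velocity(f)
    dc <- drift_correct(f)
    vdc <- rms_velocity(dc)
    xi <- NA_real_; fit_ok <- FALSE; pegged <- FALSE
    fit <- tryCatch({
      cur <- velocity_correlation(dc, bin_width_px = bin_width_px)
      fit_correlation_length(cur, fit_range = fit_range)
    }, collmot_degenerate_field = function(e) NULL,
       collmot_input_error = function(e) NULL)
    if (!is.null(fit)) {
      xi <- fit$xi_um; fit_ok <- fit$fit_ok; pegged <- fit$pegged
    }
    amap <- suppressWarnings(alignment_index(f))
    data.frame(t_min = f$t_min, vrms_tot_umh = tot,
               drift_x_umh = d[1], drift_y_umh = d[2],
               vrms_dc_umh = vdc, xi_um = xi, fit_ok = fit_ok,
               pegged = pegged,
               mean_alignment = mean(amap, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Jamming-phase trajectory: correlation length versus drift-corrected speed
#'
#' Pairs each chunk's drift-corrected r.m.s. velocity with its fitted
#' correlation length, time-ordered — the trajectory used to visualize a
#' monolayer approaching (or escaping) the jammed state.
#'
#' @param metrics output of [motility_metrics()].
#' @return data.frame with `t_min`, `vrms_dc_umh`, `xi_um`.
#' @export
phase_trajectory <- function(metrics) {
  if (is.null(metrics) || nrow(metrics) == 0) {
    return(data.frame(t_min = numeric(0), vrms_dc_umh = numeric(0),
                      xi_um = numeric(0)))
  }
  out <- metrics[order(metrics$t_min), c("t_min", "vrms_dc_umh", "xi_um")]
  rownames(out) <- NULL
  out
}
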