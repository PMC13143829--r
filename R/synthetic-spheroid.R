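#' Synthetic expanding-disk spheroid mask series
#'
#' Rasterizes a disk of radius \eqn{r(t) = r_0 + v t} at each requested time,
#' emulating the footprint of a spheroid wetting a substrate at a constant
#' radial front speed.  The known speed makes the series a ground-truth
#' fixture for the wetting quantification.
#'
#' @param r0_um initial radius, micrometres (> 0).
#' @param radial_speed_um_per_h front speed, micrometres per hour (may be
#'   negative for a receding front as long as the radius stays positive).
#' @param times_h strictly increasing acquisition times, hours.
#' @param pixel_size_um pixel size of the rasterization, micrometres.
#' @param shape optional `c(nrow, ncol)` canvas; defaults to a square that
#'   fits the largest disk with a small margin.
#' @return object of class `spheroid_series`: list of logical `masks`,
#'   `times_h`, `pixel_size_um`.
#' @export
make_spheroid_series <- function(r0_um, radial_speed_um_per_h, times_h,
                                 pixel_size_um = 2, shape = NULL) {
  if (r0_um <= 0) stop_input("r0_um must be positive", "collmot_parameter_error")
  if (length(times_h) < 1 || any(diff(times_h) <= 0)) {
    stop_input("times_h must be strictly increasing", "collmot_parameter_error")
  }
  radii <- r0_um + radial_speed_um_per_h * times_h
  if (any(radii < 0)) {
    stop_input("radius becomes negative within the requested time range",
               "collmot_parameter_error")
  }
  if (is.null(shape)) {
    half <- ceiling(max(radii) / pixel_size_um) + 4L
    shape <- c(2L * half + 1L, 2L * half + 1L)
  }
  nr <- shape[1]; nc <- shape[2]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  y2 <- (seq_len(nr) - cy)^2
  x2 <- (seq_len(nc) - cx)^2
  d2 <- outer(y2, x2, `+`) * pixel_size_um^2
  masks <- lapply(radii, function(r) d2 <= r^2)
  structure(
    list(masks = masks, times_h = as.numeric(times_h),
         pixel_size_um = pixel_size_um),
    class = "spheroid_series"
  )
}

#' Construct a spheroid mask series from user-provided masks
#'
#' @param masks list of logical matrices, one per time point.
#' @param times_h strictly increasing times, hours.
#' @param pixel_size_um pixel size, micrometres.
#' @return object of class `spheroid_series`.
#' @export
spheroid_series <- function(masks, times_h, pixel_size_um) {
  if (length(masks) < 2) stop_input("need at least 2 time points", "collmot_input_error")
  if (length(masks) != length(times_h)) {
    stop_input("masks and times_h must have the same length", "collmot_input_error")
  }
  if (any(diff(times_h) <= 0)) {
    stop_input("times_h must be strictly increasing", "collmot_input_error")
  }
  structure(
    list(masks = lapply(masks, function(m) m > 0),
         times_h = as.numeric(times_h), pixel_size_um = pixel_size_um),
    class = "spheroid_series"
  )
}
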