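#' Spreading area of a spheroid mask series, normalized to t = 0
#'
#' Area is the mask pixel count times the pixel area; the normalized series
#' divides by the t = 0 area, so its first value is exactly 1.  The
#' equivalent-circle radius \eqn{r(t) = \sqrt{A(t)/\pi}} is reported
#' alongside in micrometres.
#'
#' @param series a `spheroid_series`.
#' @return data.frame with `t_h`, `area_um2`, `norm_area`, `radius_um`.
#' @export
normalized_area <- function(series) {
  stopifnot(inherits(series, "spheroid_series"))
  px_area <- series$pixel_size_um^2
  area <- vapply(series$masks, sum, numeric(1)) * px_area
  if (area[1] <= 0) {
    stop_input("mask at t = 0 is empty; normalization undefined", "collmot_input_error")
  }
  data.frame(
    t_h = series$times_h,
    area_um2 = area,
    norm_area = area / area[1],
    radius_um = sqrt(area / pi)
  )
}

#' Average wetting speed of a spreading spheroid
#'
#' The slope of the least-squares line of the equivalent-circle radius
#' \eqn{r(t) = \sqrt{A(t)/\pi}} versus time, in micrometres per hour.  It is
#' area-based (matching the measured quantity) and robust to irregular
#' fronts; a receding front gives a negative speed.  The `"endpoint"` method
#' instead returns \eqn{(r(T) - r(0)) / T}.
#'
#' @param series a `spheroid_series` with at least 3 time points.
#' @param method `"ls"` (least-squares slope, default) or `"endpoint"`.
#' @return scalar speed, micrometres per hour.
#' @export
average_wetting_speed <- function(series, method = c("ls", "endpoint")) {
  method <- match.arg(method)
  df <- normalized_area(series)
  if (nrow(df) < 3) stop_input("need at least 3 time points", "collmot_input_error")
  if (stats::sd(df$t_h) == 0) stop_input("degenerate time axis", "collmot_input_error")
  if (method == "ls") {
    unname(stats::coef(stats::lm(radius_um ~ t_h, data = df))[2])
  } else {
    nlast <- nrow(df)
    (df$radius_um[nlast] - df$radius_um[1]) / (df$t_h[nlast] - df$t_h[1])
  }
}

#' Full wetting quantification of one mask series
#'
#' @param series a `spheroid_series`.
#' @param method speed estimator, see [average_wetting_speed()].
#' @return list with `areas` (the [normalized_area()] table) and
#'   `speed_um_per_h`.
#' @export
wetting_analysis <- function(series, method = "ls") {
  list(areas = normalized_area(series),
       speed_um_per_h = average_wetting_speed(series, method = method))
}
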