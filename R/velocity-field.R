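#' Gridded velocity field for one time point or chunk
#'
#' The container every motility statistic consumes: velocity vectors on the
#' rectangular grid of interrogation-window centres, in px/frame, together
#' with the calibration needed to express them in micrometres per hour.
#' Coordinates are 0-based pixel indices with the origin at the top-left and
#' y increasing downward; vectors are stored as `(vx, vy)`.
#'
#' @param vx,vy numeric matrices of velocity components, px/frame; rows index
#'   the y grid, columns the x grid.
#' @param x,y numeric vectors of window-centre coordinates, px (0-based).
#' @param valid logical matrix marking usable vectors.
#' @param pixel_size_um pixel size, micrometres.
#' @param frame_interval_min frame interval, minutes.
#' @param t_min time of the field (pair or chunk centre), minutes.
#' @return object of class `velocity_field`.
#' @export
velocity_field <- function(vx, vy, x, y, valid = NULL,
                           pixel_size_um = 1, frame_interval_min = 1,
                           t_min = 0) {
  stopifnot(is.matrix(vx), is.matrix(vy), all(dim(vx) == dim(vy)))
  stopifnot(length(x) == ncol(vx), length(y) == nrow(vx))
  if (is.null(valid)) valid <- matrix(TRUE, nrow(vx), ncol(vx))
  stopifnot(all(dim(valid) == dim(vx)))
  valid <- valid & is.finite(vx) & is.finite(vy)
  structure(
    list(vx = vx, vy = vy, x = as.numeric(x), y = as.numeric(y),
         valid = valid, pixel_size_um = pixel_size_um,
         frame_interval_min = frame_interval_min, t_min = t_min),
    class = "velocity_field"
  )
}

#' Conversion factor from px/frame to micrometres per hour
#'
#' Exactly `pixel_size_um * 60 / frame_interval_min`.
#'
#' @param field a `velocity_field`.
#' @return scalar multiplier.
#' @export
umh_factor <- function(field) {
  field$pixel_size_um * 60 / field$frame_interval_min
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("velocity_field: %dx%d grid, %d/%d valid, t = %.1f min\n",
              length(x$y), length(x$x), sum(x$valid), length(x$valid), x$t_min))
  invisible(x)
}

#' Flatten a velocity field to a tidy data frame
#'
#' @param x a `velocity_field`.
#' @param row.names,optional,... ignored; present for the generic.
#' @return data.frame with t_min, x_px, y_px, vx_px_frame, vy_px_frame,
#'   vx_umh, vy_umh, valid.
#' @export
as.data.frame.velocity_field <- function(x, row.names = NULL, optional = FALSE, ...) {
  f <- umh_factor(x)
  data.frame(
    t_min = x$t_min,
    x_px = rep(x$x, each = length(x$y)),
    y_px = rep(x$y, times = length(x$x)),
    vx_px_frame = as.vector(x$vx),
    vy_px_frame = as.vector(x$vy),
    vx_umh = as.vector(x$vx) * f,
    vy_umh = as.vector(x$vy) * f,
    valid = as.vector(x$valid)
  )
}

#' Write a sequence of velocity fields as one tidy CSV
#'
#' @param fields list of `velocity_field`s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fields_csv <- function(fields, path) {
  df <- do.call(rbind, lapply(fields, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
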