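#' Fixed wavelength analysis grid
#'
#' The analysis grid onto which all calibrated spectra are resampled.
#' The default covers 450--1000 nm with 1922 equally spaced points
#' (endpoints inclusive), i.e. a spacing of 550/1921 ~= 0.286 nm.
#'
#' @param start,stop Grid endpoints in nm, `start < stop`.
#' @param n_points Number of equally spaced points, at least 2.
#' @return An object of class `wavelength_grid`.
#' @export
#' @examples
#' g <- wavelength_grid()
#' length(grid_points(g))  # 1922
wavelength_grid <- function(start = 450, stop = 1000, n_points = 1922L) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(n_points))
  n_points <- as.integer(n_points)
  if (!(start < stop)) abort("grid start must be < stop", class = "drspec_argument_error")
  if (n_points < 2L) abort("grid needs at least 2 points", class = "drspec_argument_error")
  structure(
    list(start = as.numeric(start), stop = as.numeric(stop), n_points = n_points),
    class = "wavelength_grid"
  )
}

#' @describeIn wavelength_grid The grid's wavelength vector.
#' @param grid A `wavelength_grid`.
#' @export
grid_points <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  seq(grid$start, grid$stop, length.out = grid$n_points)
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf(
    "<wavelength_grid> %g-%g nm, %d points (spacing %.5f nm)\n",
    x$start, x$stop, x$n_points, (x$stop - x$start) / (x$n_points - 1)
  ))
  invisible(x)
}
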