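#' Graduated probability colourmap
#'
#' Maps a tumour probability to a colour on the graduated green-to-pink
#' scale used for on-screen feedback: fully normal tissue (p = 0) is pure
#' green `(0, 255, 0)`, fully tumour tissue (p = 1) is pink
#' `(255, 105, 180)`, with linear per-channel interpolation in between and
#' round-half-up to integers.
#'
#' @param p Tumour probability in \[0, 1\] (vectorised).
#' @return Integer matrix with columns `r`, `g`, `b` (one row per
#'   probability).
#' @export
#' @examples
#' probability_to_color(c(0, 0.5, 1))
probability_to_color <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("probability must lie in [0, 1]", class = "drspec_argument_error")
  }
  green <- c(0, 255, 0)
  pink <- c(255, 105, 180)
  out <- outer(p, pink - green) + matrix(green, length(p), 3, byrow = TRUE)
  out <- floor(out + 0.5)  # round half up
  storage.mode(out) <- "integer"
  colnames(out) <- c("r", "g", "b")
  out
}

#' Render classification sites onto a frame
#'
#' Draws each site as a filled disk of its probability colour,
#' alpha-blended over the frame; later sites paint over earlier ones. The
#' input frame is not modified.
#'
#' @param frame RGB array `height x width x 3` in \[0, 1\].
#' @param sites Tibble with `x`, `y`, `tumour_probability` and optional
#'   `radius` (default 8 px).
#' @param alpha Blend weight of the site colour (default 0.6; 1 paints the
#'   pure colour).
#' @return A new RGB array.
#' @export
render_overlay <- function(frame, sites, alpha = 0.6) {
  stopifnot(length(dim(frame)) == 3)
  h <- dim(frame)[1]; w <- dim(frame)[2]
  out <- frame
  if (is.null(sites) || nrow(sites) == 0) return(out)
  sites <- as_tibble(sites)
  if (!("radius" %in% names(sites))) sites$radius <- 8
  oob <- sites$x < 1 | sites$x > w | sites$y < 1 | sites$y > h
  if (any(oob)) {
    abort(sprintf("site(s) outside frame bounds: %s",
                  paste(which(oob), collapse = ", ")),
          class = "drspec_argument_error")
  }
  px <- matrix(rep(seq_len(w), each = h), h, w)
  py <- matrix(rep(seq_len(h), times = w), h, w)
  cols <- probability_to_color(sites$tumour_probability) / 255
  for (i in seq_len(nrow(sites))) {
    mask <- (px - sites$x[i])^2 + (py - sites$y[i])^2 <= sites$radius[i]^2
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[mask] <- (1 - alpha) * plane[mask] + alpha * cols[i, ch]
      out[, , ch] <- plane
    }
  }
  out
}
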