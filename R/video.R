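#' Synthetic marker-scene specification
#'
#' Describes a video of a coloured disk (the probe-tip marker) moving over
#' a plain background along a known trajectory, the ground truth for
#' tracking tests.
#'
#' @param frame_width,frame_height Frame size in pixels.
#' @param n_frames Number of frames, >= 1.
#' @param trajectory `"linear"`, `"circular"` or `"random_walk"`.
#' @param start Start position `c(x, y)` (linear, random_walk).
#' @param velocity Per-frame displacement `c(vx, vy)` (linear).
#' @param center,radius,angular_speed Circle parameters (circular);
#'   `angular_speed` in radians/frame.
#' @param step_sd Per-frame step standard deviation (random_walk).
#' @param marker_radius Disk radius in pixels.
#' @param marker_hue Marker hue in degrees (default 120, green).
#' @param background_color RGB triple in \[0, 1\].
#' @param seed Integer seed (random_walk and pixel noise).
#' @return A `marker_scene_spec`.
#' @export
marker_scene_spec <- function(frame_width = 320, frame_height = 240,
                              n_frames = 30, trajectory = "linear",
                              start = c(60, 60), velocity = c(3, 2),
                              center = c(160, 120), radius = 70,
                              angular_speed = 0.1, step_sd = 2,
                              marker_radius = 9, marker_hue = 120,
                              background_color = c(0.55, 0.35, 0.30),
                              seed = 1L) {
  if (n_frames < 1) abort("n_frames must be >= 1", class = "drspec_argument_error")
  if (marker_radius >= min(frame_width, frame_height) / 2) {
    abort("marker_radius must be smaller than half the frame",
          class = "drspec_argument_error")
  }
  trajectory <- match.arg(trajectory, c("linear", "circular", "random_walk"))
  structure(
    list(frame_width = frame_width, frame_height = frame_height,
         n_frames = as.integer(n_frames), trajectory = trajectory,
         start = start, velocity = velocity, center = center, radius = radius,
         angular_speed = angular_speed, step_sd = step_sd,
         marker_radius = marker_radius, marker_hue = marker_hue,
         background_color = background_color, seed = as.integer(seed)),
    class = "marker_scene_spec"
  )
}

marker_trajectory <- function(spec) {
  n <- spec$n_frames
  t <- seq_len(n) - 1
  xy <- switch(spec$trajectory,
    linear = cbind(spec$start[1] + spec$velocity[1] * t,
                   spec$start[2] + spec$velocity[2] * t),
    circular = cbind(spec$center[1] + spec$radius * cos(spec$angular_speed * t),
                     spec$center[2] + spec$radius * sin(spec$angular_speed * t)),
    random_walk = {
      steps <- matrix(rnorm(2 * n, 0, spec$step_sd), n, 2)
      steps[1, ] <- 0
      sweep(apply(steps, 2, cumsum), 2, spec$start, `+`)
    }
  )
  # keep the disk fully inside the frame
  r <- spec$marker_radius + 1
  xy[, 1] <- pmin(pmax(xy[, 1], r), spec$frame_width - r)
  xy[, 2] <- pmin(pmax(xy[, 2], r), spec$frame_height - r)
  colnames(xy) <- c("x", "y")
  xy
}

#' Render synthetic marker frames
#'
#' Each frame is a `height x width x 3` RGB array in \[0, 1\]: a plain
#' tissue-toned background with a filled disk of the marker colour at the
#' ground-truth position. `occlude_frames` lists frame indices rendered
#' without the marker (simulated occlusion).
#'
#' @param spec A [marker_scene_spec()].
#' @param occlude_frames Integer frame indices whose marker is hidden.
#' @return List with `frames` (list of RGB arrays) and `trajectory`
#'   (tibble `frame`, `x`, `y`, `occluded`).
#' @export
generate_marker_frames <- function(spec, occlude_frames = integer(0)) {
  stopifnot(inherits(spec, "marker_scene_spec"))
  set.seed(spec$seed)
  xy <- marker_trajectory(spec)
  marker_rgb <- grDevices::hsv(spec$marker_hue / 360, 0.85, 0.85)
  marker_rgb <- as.numeric(grDevices::col2rgb(marker_rgb)) / 255
  w <- spec$frame_width; h <- spec$frame_height
  px <- matrix(rep(seq_len(w), each = h), h, w)
  py <- matrix(rep(seq_len(h), times = w), h, w)
  frames <- vector("list", spec$n_frames)
  for (i in seq_len(spec$n_frames)) {
    fr <- array(rep(spec$background_color, each = h * w), c(h, w, 3))
    if (!(i %in% occlude_frames)) {
      mask <- (px - xy[i, 1])^2 + (py - xy[i, 2])^2 <= spec$marker_radius^2
      for (ch in 1:3) {
        plane <- fr[, , ch]
        plane[mask] <- marker_rgb[ch]
        fr[, , ch] <- plane
      }
    }
    frames[[i]] <- fr
  }
  list(
    frames = frames,
    trajectory = tibble(
      frame = seq_len(spec$n_frames), x = xy[, 1], y = xy[, 2],
      occluded = seq_len(spec$n_frames) %in% occlude_frames
    )
  )
}

#' Write / read frame sequences as numbered PNG files
#'
#' @param frames List of RGB arrays in \[0, 1\].
#' @param dir Directory (created if missing).
#' @return `write_frames` returns the file paths invisibly; `read_frames`
#'   the list of arrays (sorted by file name).
#' @export
write_frames <- function(frames, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("frame_%04d.png", seq_along(frames)))
  for (i in seq_along(frames)) png::writePNG(frames[[i]], paths[i])
  invisible(paths)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(paths) == 0) abort("no PNG frames found", class = "drspec_argument_error")
  lapply(paths, function(p) {
    a <- png::readPNG(p)
    if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
    a[, , 1:3, drop = FALSE][, , 1:3]
  })
}
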