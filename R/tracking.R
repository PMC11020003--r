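#' HSV colour range for marker segmentation
#'
#' Hue in degrees of 360 with wraparound support (`hue_min > hue_max`
#' means the range crosses 0), saturation/value as fractions. Defaults
#' select a green marker.
#'
#' @param hue_min,hue_max Hue band in degrees.
#' @param sat_min,sat_max Saturation band.
#' @param val_min,val_max Value band.
#' @param min_blob_area Minimum connected-component area in pixels^2.
#' @return An `hsv_range`.
#' @export
hsv_range <- function(hue_min = 100, hue_max = 140, sat_min = 0.4,
                      sat_max = 1, val_min = 0.3, val_max = 1,
                      min_blob_area = 50) {
  if (sat_min > sat_max || val_min > val_max) {
    abort("saturation/value min must be <= max", class = "drspec_argument_error")
  }
  structure(
    list(hue_min = hue_min, hue_max = hue_max, sat_min = sat_min,
         sat_max = sat_max, val_min = val_min, val_max = val_max,
         min_blob_area = min_blob_area),
    class = "hsv_range"
  )
}

#' Segment the marker in one frame
#'
#' Converts the frame to HSV, thresholds on the configured range
#' (dual-interval masking when the hue band wraps through 0), labels
#' connected components and returns the centroid of the largest component
#' whose area reaches `min_blob_area`. When nothing qualifies the
#' detection is invalid -- the no-marker signal.
#'
#' @param frame RGB array `height x width x 3` in \[0, 1\].
#' @param range An [hsv_range()].
#' @return A tibble row: `x`, `y` (pixel centroid, NA when invalid),
#'   `area`, `valid`.
#' @export
segment_marker <- function(frame, range = hsv_range()) {
  stopifnot(length(dim(frame)) == 3, dim(frame)[3] >= 3)
  h <- dim(frame)[1]; w <- dim(frame)[2]
  rgb <- rbind(as.vector(frame[, , 1]), as.vector(frame[, , 2]),
               as.vector(frame[, , 3]))
  hsv <- rgb2hsv(rgb, maxColorValue = 1)
  hue <- hsv[1, ] * 360
  if (range$hue_min <= range$hue_max) {
    hue_ok <- hue >= range$hue_min & hue <= range$hue_max
  } else {
    hue_ok <- hue >= range$hue_min | hue <= range$hue_max
  }
  mask <- hue_ok & hsv[2, ] >= range$sat_min & hsv[2, ] <= range$sat_max &
    hsv[3, ] >= range$val_min & hsv[3, ] <= range$val_max
  mask_m <- matrix(mask, h, w)
  invalid <- tibble(x = NA_real_, y = NA_real_, area = 0, valid = FALSE)
  if (!any(mask_m)) return(invalid)
  lab <- EBImage::bwlabel(mask_m * 1)
  sizes <- tabulate(lab[lab > 0])
  best <- which.max(sizes)
  if (sizes[best] < range$min_blob_area) return(invalid)
  idx <- which(lab == best, arr.ind = TRUE)
  tibble(x = mean(idx[, 2]), y = mean(idx[, 1]),
         area = sizes[best], valid = TRUE)
}

#' Constant-velocity Kalman track state
#'
#' State vector `(x, y, vx, vy)` in pixels and pixels/frame with a 4x4
#' covariance. [track_init()] initialises from a first detection with zero
#' velocity and a large position/velocity uncertainty diagonal.
#'
#' @param detection One-row detection tibble from [segment_marker()].
#' @param pos_var Initial position variance (px^2).
#' @param vel_var Initial velocity variance ((px/frame)^2).
#' @return A `track_state`.
#' @export
track_init <- function(detection, pos_var = 100, vel_var = 100) {
  stopifnot(isTRUE(detection$valid))
  structure(
    list(
      mean = c(detection$x, detection$y, 0, 0),
      cov = diag(c(pos_var, pos_var, vel_var, vel_var)),
      frames_since_detection = 0L,
      initialized = TRUE
    ),
    class = "track_state"
  )
}

#' One Kalman predict/update step
#'
#' Predicts with the constant-velocity transition over a unit frame step
#' (process noise `q` on each state component, scaled white acceleration
#' on the velocity terms), then, when the detection is valid, applies the
#' standard linear measurement update on the observed `(x, y)` with
#' measurement noise `r`. A missing/invalid detection leaves the
#' prediction as the new state and increments `frames_since_detection`.
#'
#' @param state A `track_state`.
#' @param detection Detection row (or `NULL` for a missed frame).
#' @param q Process noise intensity (px^2/frame^2).
#' @param r Measurement noise variance (px^2).
#' @return Updated `track_state`.
#' @export
kalman_step <- function(state, detection = NULL, q = 1, r = 2) {
  stopifnot(inherits(state, "track_state"))
  ev <- eigen(state$cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    abort("track covariance is not positive-definite", class = "drspec_numeric_error")
  }
  F_ <- rbind(c(1, 0, 1, 0), c(0, 1, 0, 1), c(0, 0, 1, 0), c(0, 0, 0, 1))
  # discretised white-acceleration process noise, dt = 1
  Q <- q * rbind(c(1 / 4, 0, 1 / 2, 0),
                 c(0, 1 / 4, 0, 1 / 2),
                 c(1 / 2, 0, 1, 0),
                 c(0, 1 / 2, 0, 1))
  m <- as.numeric(F_ %*% state$mean)
  P <- F_ %*% state$cov %*% t(F_) + Q
  if (is.null(detection) || !isTRUE(detection$valid)) {
    return(structure(
      list(mean = m, cov = (P + t(P)) / 2,
           frames_since_detection = state$frames_since_detection + 1L,
           initialized = TRUE),
      class = "track_state"
    ))
  }
  H <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  z <- c(detection$x, detection$y)
  S <- H %*% P %*% t(H) + diag(r, 2)
  K <- P %*% t(H) %*% solve(S)
  m_new <- m + as.numeric(K %*% (z - H %*% m))
  # Joseph form keeps the covariance symmetric positive-definite
  IKH <- diag(4) - K %*% H
  P_new <- IKH %*% P %*% t(IKH) + K %*% diag(r, 2) %*% t(K)
  structure(
    list(mean = m_new, cov = (P_new + t(P_new)) / 2,
         frames_since_detection = 0L, initialized = TRUE),
    class = "track_state"
  )
}

#' Track the marker through a frame sequence
#'
#' Runs segmentation on every frame and a constant-velocity Kalman filter
#' over the detections. The track initialises on the first valid
#' detection, coasts through missed detections, is declared lost after
#' `max_misses` consecutive misses and re-initialises on the next valid
#' detection.
#'
#' @param frames List of RGB arrays.
#' @param range An [hsv_range()].
#' @param q,r Kalman noise settings, see [kalman_step()].
#' @param max_misses Consecutive misses before the track is dropped.
#' @return Tibble, one row per frame: `frame`, `x`, `y`, `vx`, `vy`,
#'   `detected`, `tracked`.
#' @export
track_sequence <- function(frames, range = hsv_range(), q = 1, r = 2,
                           max_misses = 15) {
  if (length(frames) < 1) abort("need at least one frame", class = "drspec_argument_error")
  state <- NULL
  rows <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    det <- segment_marker(frames[[i]], range)
    if (is.null(state)) {
      if (det$valid) state <- track_init(det)
    } else {
      state <- kalman_step(state, det, q = q, r = r)
      if (state$frames_since_detection > max_misses) state <- NULL
      if (is.null(state) && det$valid) state <- track_init(det)
    }
    rows[[i]] <- tibble(
      frame = i,
      x = if (is.null(state)) NA_real_ else state$mean[1],
      y = if (is.null(state)) NA_real_ else state$mean[2],
      vx = if (is.null(state)) NA_real_ else state$mean[3],
      vy = if (is.null(state)) NA_real_ else state$mean[4],
      detected = det$valid,
      tracked = !is.null(state)
    )
  }
  out <- bind_rows(rows)
  class(out) <- c("drs_trajectory", class(out))
  out
}

#' Trajectory plot
#' @param object A trajectory tibble from [track_sequence()].
#' @param truth Optional ground-truth tibble with `x`, `y`.
#' @param ... Unused.
#' @export
autoplot.drs_trajectory <- function(object, truth = NULL, ...) {
  p <- ggplot(object, aes(x = .data$x, y = .data$y)) +
    geom_path(colour = "#1B7837") +
    geom_point(aes(shape = .data$detected), size = 1.5) +
    labs(x = "x (px)", y = "y (px)") +
    theme_minimal()
  if (!is.null(truth)) {
    p <- p + geom_path(data = truth, aes(x = .data$x, y = .data$y),
                       colour = "grey50", linetype = 2)
  }
  p
}
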