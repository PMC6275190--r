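#' Retina timing configuration
#'
#' Visual input reaches the network as spikes.  In `regular` mode frames are
#' delivered exactly every `frame_interval` ms; in `jittered` mode the
#' inter-delivery interval is uniform over `jitter_range`.  After a frame is
#' consumed by the planner, input ceases for `processing_gap` ms while the
#' picture is analysed.  Regular mode is the degenerate jittered mode with a
#' zero-width range.
#'
#' @param mode `"regular"` or `"jittered"`.
#' @param frame_interval nominal frame interval, ms (default 30).
#' @param jitter_range two-element range for the jittered interval, ms
#'   (default `c(20, 40)`, which contains the nominal interval).
#' @param processing_gap input silence after a consumed frame, ms
#'   (default 100, >= the interval).
#' @param intensity_threshold channel level above which a pixel's input
#'   neuron is driven (default 128 of 255).
#' @return a `retina_config` list.
#' @export
retina_config <- function(mode = c("regular", "jittered"),
                          frame_interval = 30, jitter_range = c(20, 40),
                          processing_gap = 100, intensity_threshold = 128) {
  mode <- match.arg(mode)
  stopifnot(length(jitter_range) == 2, jitter_range[1] <= jitter_range[2])
  if (frame_interval < jitter_range[1] || frame_interval > jitter_range[2])
    stop("configuration error: jitter range must contain the nominal interval")
  if (processing_gap < frame_interval)
    stop("configuration error: processing gap must be >= the frame interval")
  structure(list(mode = mode, frame_interval = frame_interval,
                 jitter_range = jitter_range, processing_gap = processing_gap,
                 intensity_threshold = intensity_threshold),
            class = "retina_config")
}

#' Sample the next inter-frame interval
#'
#' Regular mode returns the nominal interval; jittered mode draws a uniform
#' integer from the jitter range (using the current RNG state).
#'
#' @param config a [retina_config()].
#' @return interval in ms.
#' @export
sample_frame_interval <- function(config) {
  if (config$mode == "regular") return(config$frame_interval)
  ivals <- seq(config$jitter_range[1], config$jitter_range[2])
  ivals[sample.int(length(ivals), 1)]
}

#' Encode a frame as an injection schedule
#'
#' One input neuron per (pixel, channel), indexed row-major.  Pixels whose
#' channel exceeds the intensity threshold inject a supra-threshold pulse at
#' the frame's delivery time.  The delivery time is `t` plus a draw from the
#' mode's interval distribution; during a processing gap no injections are
#' scheduled (callers simply do not call this while the gap runs).
#'
#' @param pixels a 20x20x3 frame.
#' @param config a [retina_config()].
#' @param t step at which the previous frame was delivered (delivery is at
#'   `t + interval`).
#' @return a data frame with columns `step`, `population`
#'   (`retina_r`/`retina_g`/`retina_b`), `neuron`, `value`, plus attribute
#'   `delivery` giving the delivery step.
#' @export
encode_frame <- function(pixels, config, t = 0L) {
  delivery <- t + sample_frame_interval(config)
  chans <- c("retina_r", "retina_g", "retina_b")
  rows <- lapply(1:3, function(ch) {
    hot <- which(pixels[, , ch] > config$intensity_threshold)  # column-major
    if (!length(hot)) return(NULL)
    data.frame(step = delivery, population = chans[ch], neuron = hot,
               value = 1.3, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out))
    out <- data.frame(step = integer(0), population = character(0),
                      neuron = integer(0), value = numeric(0))
  attr(out, "delivery") <- delivery
  out
}

#' Center-surround response map
#'
#' Slides a `size` x `size` window over a single-channel image (stride 1).
#' The response at each position is mean(center block) - mean(surround),
#' negated for `off_on` polarity, thresholded at zero.  The center block is
#' the inner `size/3` square, so granularities 3, 6 and 9 have 1x1, 2x2 and
#' 3x3 centers.
#'
#' @param image numeric matrix (e.g. one channel of a frame).
#' @param size kernel size: 3, 6 or 9.
#' @param polarity `"on_off"` or `"off_on"`.
#' @return a (nr-size+1) x (nc-size+1) response matrix.
#' @export
center_surround <- function(image, size = 3, polarity = c("on_off", "off_on")) {
  polarity <- match.arg(polarity)
  if (!size %in% c(3, 6, 9))
    stop("configuration error: center-surround size must be 3, 6 or 9")
  cs <- size / 3
  lo <- (size - cs) %/% 2 + 1
  ctr <- lo:(lo + cs - 1)
  nr <- nrow(image) - size + 1; nc <- ncol(image) - size + 1
  if (nr < 1 || nc < 1)
    stop("configuration error: kernel larger than image")
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    block <- image[i:(i + size - 1), j:(j + size - 1)]
    cmean <- mean(block[ctr, ctr])
    smean <- (sum(block) - sum(block[ctr, ctr])) / (size^2 - cs^2)
    out[i, j] <- cmean - smean
  }
  if (polarity == "off_on") out <- -out
  pmax(out, 0)
}

#' Compute the feature maps of a frame
#'
#' On-off and off-on center-surround maps at granularities 3, 6 and 9 on the
#' luminance image; horizontal/vertical edge maps and their diagonal (angle)
#' combinations; and per-colour presence masks at the intensity threshold.
#'
#' @param frame a 20x20x3 frame.
#' @param config a [retina_config()] (for the intensity threshold).
#' @return a `feature_maps` list.
#' @export
feature_maps <- function(frame, config = retina_config()) {
  thr <- config$intensity_threshold
  lum <- (frame[, , 1] + frame[, , 2] + frame[, , 3]) / 3
  cs <- list()
  for (s in c(3, 6, 9))
    for (pol in c("on_off", "off_on"))
      cs[[paste0(pol, "_", s)]] <- center_surround(lum, s, pol)
  gx <- lum[, -1] - lum[, -ncol(lum)]
  gy <- lum[-1, ] - lum[-nrow(lum), ]
  n <- min(nrow(gx), nrow(gy)); m <- min(ncol(gx), ncol(gy))
  red <- frame[, , 1] > thr & frame[, , 3] <= thr & frame[, , 2] <= thr
  blue <- frame[, , 3] > thr & frame[, , 1] <= thr & frame[, , 2] <= thr
  green <- frame[, , 2] > thr & frame[, , 1] <= thr & frame[, , 3] <= thr
  wall <- frame[, , 1] == COLORS$wall[1] & frame[, , 2] == COLORS$wall[2] &
    frame[, , 3] == COLORS$wall[3]
  structure(list(
    cs = cs,
    edges = list(h = abs(gy), v = abs(gx)),
    angles = list(ne = abs(gx[seq_len(n), seq_len(m)] + gy[seq_len(n), seq_len(m)]),
                  nw = abs(gx[seq_len(n), seq_len(m)] - gy[seq_len(n), seq_len(m)])),
    color = list(red = red, blue = blue, green = green),
    wall = wall), class = "feature_maps")
}

MIN_DISCRIMINABLE <- 6L   # below this many shape pixels, kind is unknown

#' Extract a symbolic percept from feature maps
#'
#' Colour is the dominant channel among above-threshold shape pixels;
#' position is the horizontal third containing the shape centroid; kind is
#' read from apex orientation (the widest row at the bottom means pyramid,
#' at the top stalactite) and is `"unknown"` when the shape spans fewer than
#' the minimum discriminable number of pixels.  Corridor-opening visibility
#' and its position come from the green mask; a wall directly ahead is a
#' large grey fill.
#'
#' @param maps a [feature_maps()] object.
#' @return a `visual_percept` list with fields `object_present`, `kind`,
#'   `color`, `position`, `apparent_size`, `corridor_present`,
#'   `corridor_position`, `wall_ahead`.
#' @export
extract_percept <- function(maps) {
  red <- maps$color$red; blue <- maps$color$blue
  mask <- red | blue
  size <- sum(mask)
  pos_of <- function(m) {
    ccol <- mean(which(m, arr.ind = TRUE)[, 2])
    if (ccol < 7.5) "left" else if (ccol > 13.5) "right" else "center"
  }
  percept <- list(object_present = size > 0, kind = "unknown",
                  color = "unknown", position = NA_character_,
                  apparent_size = size,
                  corridor_present = FALSE,
                  corridor_position = NA_character_,
                  wall_ahead = sum(maps$wall) >= 250)
  if (size > 0) {
    percept$color <- if (sum(red) >= sum(blue)) "red" else "blue"
    percept$position <- pos_of(mask)
    rows <- which(rowSums(mask) > 0)
    if (size >= MIN_DISCRIMINABLE && length(rows) >= 2) {
      wt <- sum(mask[min(rows), ]); wb <- sum(mask[max(rows), ])
      if (wb > wt) percept$kind <- "pyramid"
      else if (wt > wb) percept$kind <- "stalactite"
    }
  }
  if (sum(maps$color$green) > 0) {
    percept$corridor_present <- TRUE
    percept$corridor_position <- pos_of(maps$color$green)
  }
  class(percept) <- "visual_percept"
  percept
}

# one-call percept for the agent loop: builds only the masks the percept
# reader uses (the full center-surround / edge maps are available through
# feature_maps() but are not needed every cycle)
frame_percept <- function(frame, config = retina_config()) {
  thr <- config$intensity_threshold
  maps <- list(color = list(
    red = frame[, , 1] > thr & frame[, , 3] <= thr & frame[, , 2] <= thr,
    blue = frame[, , 3] > thr & frame[, , 1] <= thr & frame[, , 2] <= thr,
    green = frame[, , 2] > thr & frame[, , 1] <= thr & frame[, , 3] <= thr),
    wall = frame[, , 1] == COLORS$wall[1] & frame[, , 2] == COLORS$wall[2] &
      frame[, , 3] == COLORS$wall[3])
  extract_percept(maps)
}
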