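# Schematic flat-shaded forward view: a 20x20 RGB raster of what the agent's
# camera sees from a pose.  Shapes project to triangles (pyramid apex up,
# stalactite apex down) whose apparent width shrinks with distance; corridor
# openings project to green rectangles; a wall directly ahead fills the lower
# frame in grey.  Rendering is deterministic per (world, pose); camera noise
# belongs to capture_frame().

FRAME_W <- 20L
FRAME_H <- 20L
VIEW_RANGE <- 12L

COLORS <- list(red = c(255L, 0L, 0L), blue = c(0L, 0L, 255L),
               green = c(0L, 220L, 0L), wall = c(100L, 100L, 100L),
               bg = c(15L, 15L, 15L))

# right-hand unit vector for a heading (x right, y down => right of N is E)
right_of <- function(heading) {
  h <- HEADINGS[[heading]]
  c(-h[2], h[1])
}

# (depth, lateral) coordinates of a cell relative to a pose; NULL if behind
view_coords <- function(pose, x, y) {
  h <- HEADINGS[[pose$heading]]; r <- right_of(pose$heading)
  dx <- x - pose$x; dy <- y - pose$y
  d <- dx * h[1] + dy * h[2]
  l <- dx * r[1] + dy * r[2]
  c(d = d, l = l)
}

in_frustum <- function(dl) dl["d"] >= 1 && dl["d"] <= VIEW_RANGE &&
  abs(dl["l"]) <= dl["d"]

# line of sight along the straight segment of cells between pose and target
line_clear <- function(world, pose, x, y) {
  n <- max(abs(x - pose$x), abs(y - pose$y))
  if (n <= 1) return(TRUE)
  for (i in seq_len(n - 1)) {
    cx <- round(pose$x + (x - pose$x) * i / n)
    cy <- round(pose$y + (y - pose$y) * i / n)
    if (is_wall(world, cx, cy)) return(FALSE)
  }
  TRUE
}

# screen column (1-based) of a lateral offset at a given depth
screen_col <- function(d, l) round(10.5 + 9 * l / max(d, 1))

# apparent base width of one cell at depth d
apparent_width <- function(d) max(1L, as.integer(round(16 / (d + 1))))

paint <- function(frame, rows, cols, rgb) {
  rows <- rows[rows >= 1 & rows <= FRAME_H]
  cols <- cols[cols >= 1 & cols <= FRAME_W]
  for (ch in 1:3) frame[rows, cols, ch] <- rgb[ch]
  frame
}

draw_triangle <- function(frame, kind, color, d, l) {
  w <- apparent_width(d)
  h <- max(1L, as.integer(ceiling(0.75 * w)))
  cx <- screen_col(d, l)
  rgb <- COLORS[[color]]
  for (i in 0:(h - 1)) {                  # i = 0 at the base row
    wi <- max(1L, as.integer(round(w * (h - i) / h)))
    half <- (wi - 1) %/% 2
    cols <- (cx - half):(cx - half + wi - 1)
    row <- if (kind == "pyramid") 13L - i else 7L + i
    frame <- paint(frame, row, cols, rgb)
  }
  frame
}

draw_opening <- function(frame, d, l) {
  w <- max(1L, as.integer(round(24 / (d + 1))))
  h <- max(1L, as.integer(round(w / 3)))
  cx <- screen_col(d, l)
  half <- (w - 1) %/% 2
  paint(frame, 10:(10 + h - 1), (cx - half):(cx - half + w - 1),
        COLORS$green)
}

# entrance cell pairs of every corridor: for each of its two rooms, the two
# corridor cells adjacent to that room
corridor_entrances <- function(world) {
  out <- list()
  for (co in names(world$corridors)) {
    cr <- world$corridors[[co]]
    cells <- rect_cells(cr)
    for (rn in names(world$rooms)) {
      rm <- world$rooms[[rn]]
      near <- cells[
        (cells$x >= rm["x0"] - 1 & cells$x <= rm["x1"] + 1 &
         cells$y >= rm["y0"] - 1 & cells$y <= rm["y1"] + 1), , drop = FALSE]
      if (nrow(near))
        out[[length(out) + 1]] <- list(corridor = co, room = rn,
                                       x = mean(near$x), y = mean(near$y))
    }
  }
  out
}

# corridors whose entrance is currently in view with a clear line of sight
visible_corridors <- function(world, pose) {
  out <- character(0)
  for (e in corridor_entrances(world)) {
    x <- round(e$x); y <- round(e$y)
    dl <- view_coords(pose, x, y)
    if (in_frustum(dl) && line_clear(world, pose, x, y))
      out <- c(out, e$corridor)
  }
  unique(out)
}

#' Render the agent's 20x20 camera view
#'
#' @param world a `cabot_world`.
#' @param pose an [agent_pose()].
#' @return a 20x20x3 integer array (rows, cols, RGB), values in 0..255.
#' @export
render_frame <- function(world, pose) {
  frame <- array(0L, dim = c(FRAME_H, FRAME_W, 3L))
  for (ch in 1:3) frame[, , ch] <- COLORS$bg[ch]

  # wall directly ahead fills the lower frame
  h <- HEADINGS[[pose$heading]]
  if (is_wall(world, pose$x + h[1], pose$y + h[2])) {
    frame <- paint(frame, 6:FRAME_H, 1:FRAME_W, COLORS$wall)
    return(frame)
  }
  if (is_wall(world, pose$x + 2 * h[1], pose$y + 2 * h[2]))
    frame <- paint(frame, 9:FRAME_H, 4:17, COLORS$wall)

  # corridor openings (painter's order: far first)
  ent <- corridor_entrances(world)
  if (length(ent)) {
    dls <- lapply(ent, function(e)
      view_coords(pose, round(e$x), round(e$y)))
    ord <- order(-vapply(dls, `[`, numeric(1), "d"))
    for (i in ord) {
      dl <- dls[[i]]; e <- ent[[i]]
      if (in_frustum(dl) && line_clear(world, pose, round(e$x), round(e$y)))
        frame <- draw_opening(frame, dl["d"], dl["l"])
    }
  }
  # shapes
  sh <- world$shapes
  dls <- lapply(seq_len(nrow(sh)), function(i)
    view_coords(pose, sh$x[i], sh$y[i]))
  ord <- order(-vapply(dls, `[`, numeric(1), "d"))
  for (i in ord) {
    dl <- dls[[i]]
    if (in_frustum(dl) && line_clear(world, pose, sh$x[i], sh$y[i]))
      frame <- draw_triangle(frame, sh$kind[i], sh$color[i], dl["d"], dl["l"])
  }
  frame
}

#' Simulate the camera-to-pixel transfer
#'
#' The rendered scene is deterministic; the capture stage is not.  Each lit
#' pixel (any channel above the intensity threshold) drops out with
#' probability `p_drop`, emulating the variance of the camera-to-pixel
#' mechanism.  Draws come from the supplied RNG state, so captures are
#' reproducible under a seed.
#'
#' @param frame a rendered frame from [render_frame()].
#' @param p_drop per-pixel dropout probability (0 disables noise).
#' @return the noisy frame.
#' @export
capture_frame <- function(frame, p_drop = 0.08) {
  if (p_drop <= 0) return(frame)
  lit <- frame[, , 1] > 128 | frame[, , 2] > 128 | frame[, , 3] > 128
  drop <- lit & (matrix(runif(FRAME_H * FRAME_W), FRAME_H, FRAME_W) < p_drop)
  for (ch in 1:3) {
    plane <- frame[, , ch]
    plane[drop] <- COLORS$bg[ch]
    frame[, , ch] <- plane
  }
  frame
}

#' Write a frame as a plain-text PPM image
#'
#' @param frame a 20x20x3 frame.
#' @param path output path (`.ppm`).
#' @export
write_ppm <- function(frame, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(FRAME_W, FRAME_H), "255"), con)
  for (r in seq_len(FRAME_H))
    writeLines(paste(as.vector(t(frame[r, , ])), collapse = " "), con)
  invisible(path)
}
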