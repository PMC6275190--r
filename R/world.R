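#' Reference four-room world specification
#'
#' Four 9x9 rooms at the corners of a 24x24 grid, joined in a single cycle
#' by four 2-cell-wide corridors.  Each room holds one of the four distinct
#' (kind, colour) shapes: a pyramid or a stalactite, red or blue.  Corridors
#' are green.  Coordinates are 0-based, x rightward, y downward; headings
#' are N = (0,-1), E = (+1,0), S = (0,+1), W = (-1,0).
#'
#' @param seed optional integer; when given, the assignment of the four
#'   shapes to the four rooms is a seeded permutation of the canonical one.
#' @return a world specification list (see [build_world()]).
#' @export
world_spec <- function(seed = NULL) {
  rooms <- list(
    NW = c(x0 = 1, y0 = 1, x1 = 9, y1 = 9),
    NE = c(x0 = 14, y0 = 1, x1 = 22, y1 = 9),
    SE = c(x0 = 14, y0 = 14, x1 = 22, y1 = 22),
    SW = c(x0 = 1, y0 = 14, x1 = 9, y1 = 22))
  corridors <- list(
    N = c(x0 = 10, y0 = 4, x1 = 13, y1 = 5),
    E = c(x0 = 18, y0 = 10, x1 = 19, y1 = 13),
    S = c(x0 = 10, y0 = 18, x1 = 13, y1 = 19),
    W = c(x0 = 4, y0 = 10, x1 = 5, y1 = 13))
  shapes <- data.frame(
    kind = c("pyramid", "pyramid", "stalactite", "stalactite"),
    color = c("red", "blue", "red", "blue"),
    room = c("NW", "NE", "SE", "SW"), stringsAsFactors = FALSE)
  if (!is.null(seed)) {
    op <- options(warn = -1); on.exit(options(op))
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(derive_seed(seed, "world"))
    shapes$room <- sample(shapes$room)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  centers <- list(NW = c(5, 5), NE = c(18, 5), SE = c(18, 18), SW = c(5, 18))
  shapes$x <- vapply(shapes$room, function(r) centers[[r]][1], numeric(1))
  shapes$y <- vapply(shapes$room, function(r) centers[[r]][2], numeric(1))
  list(width = 24, height = 24, rooms = rooms, corridors = corridors,
       shapes = shapes, corridor_color = "green",
       start = list(x = 2, y = 7, heading = "N"))
}

rect_cells <- function(r) {
  g <- expand.grid(x = r["x0"]:r["x1"], y = r["y0"]:r["y1"])
  g
}

rect_overlap <- function(a, b)
  a["x0"] <= b["x1"] && b["x0"] <= a["x1"] && a["y0"] <= b["y1"] && b["y0"] <= a["y1"]

rect_adjacent <- function(a, b) {   # share an edge (touching, not overlapping)
  xtouch <- (a["x1"] + 1 == b["x0"] || b["x1"] + 1 == a["x0"]) &&
    a["y0"] <= b["y1"] && b["y0"] <= a["y1"]
  ytouch <- (a["y1"] + 1 == b["y0"] || b["y1"] + 1 == a["y0"]) &&
    a["x0"] <= b["x1"] && b["x0"] <= a["x1"]
  xtouch || ytouch
}

#' Build a four-room world
#'
#' Validates the specification (room disjointness, a single four-cycle of
#' corridors over the rooms, one shape per room, four distinct
#' (kind, colour) pairs) and precomputes the occupancy grid.
#'
#' @param spec a specification from [world_spec()], possibly modified, or an
#'   integer seed which selects the reference layout with a seeded shape
#'   placement.
#' @return an object of class `cabot_world`.
#' @export
build_world <- function(spec = world_spec()) {
  if (is.numeric(spec)) spec <- world_spec(seed = spec)
  rooms <- spec$rooms; corridors <- spec$corridors
  for (i in seq_along(rooms)) for (j in seq_along(rooms))
    if (i < j && rect_overlap(rooms[[i]], rooms[[j]]))
      stop("configuration error: rooms must be pairwise disjoint (",
           names(rooms)[i], " overlaps ", names(rooms)[j], ")")
  # corridor graph over rooms must be a single 4-cycle
  edges <- lapply(corridors, function(co) {
    names(rooms)[vapply(rooms, function(rm) rect_adjacent(co, rm), logical(1))]
  })
  if (any(lengths(edges) != 2))
    stop("configuration error: each corridor must join exactly two rooms")
  deg <- table(unlist(edges))
  if (length(deg) != length(rooms) || any(deg != 2))
    stop("configuration error: corridors must form a single cycle over the rooms",
         " (every room needs degree 2)")
  # connectivity of the room graph
  adj <- lapply(names(rooms), function(r)
    unique(unlist(lapply(edges, function(e) if (r %in% e) setdiff(e, r)))))
  names(adj) <- names(rooms)
  seen <- names(rooms)[1]; frontier <- seen
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier])), seen)
    seen <- c(seen, nxt); frontier <- nxt
  }
  if (length(seen) != length(rooms))
    stop("configuration error: corridors must form a single cycle over the rooms",
         " (room graph is disconnected)")
  sh <- spec$shapes
  if (anyDuplicated(sh$room) || !setequal(sh$room, names(rooms)))
    stop("configuration error: exactly one shape per room is required")
  if (anyDuplicated(paste(sh$kind, sh$color)))
    stop("configuration error: the four (kind, color) pairs must be distinct")

  wall <- matrix(TRUE, nrow = spec$width, ncol = spec$height)  # [x+1, y+1]
  carve <- function(r) {
    cs <- rect_cells(r)
    wall[cbind(cs$x + 1, cs$y + 1)] <<- FALSE
  }
  for (r in rooms) carve(r)
  for (co in corridors) carve(co)

  # one traversal order of the room cycle, starting from the first room
  cyc <- names(rooms)[1]
  repeat {
    cur <- cyc[length(cyc)]
    nxt <- setdiff(adj[[cur]], cyc)
    if (!length(nxt)) break
    cyc <- c(cyc, nxt[1])
  }
  structure(list(spec = spec, width = spec$width, height = spec$height,
                 wall = wall, rooms = rooms, corridors = corridors,
                 shapes = sh, cycle = cyc,
                 start = spec$start), class = "cabot_world")
}

#' @export
print.cabot_world <- function(x, ...) {
  cat(sprintf("<cabot_world> %dx%d grid, rooms: %s (cycle %s)\n",
              x$width, x$height, paste(names(x$rooms), collapse = " "),
              paste(x$cycle, collapse = "->")))
  print(x$shapes[, c("room", "color", "kind")])
  invisible(x)
}

HEADINGS <- list(N = c(0L, -1L), E = c(1L, 0L), S = c(0L, 1L),
                 W = c(-1L, 0L))
HEADING_ORDER <- c("N", "E", "S", "W")  # turn_right moves forward in this list

is_wall <- function(world, x, y) {
  if (x < 0 || y < 0 || x >= world$width || y >= world$height) return(TRUE)
  world$wall[x + 1, y + 1]
}

# shapes block movement but are not walls
is_walkable <- function(world, x, y) {
  if (is_wall(world, x, y)) return(FALSE)
  !any(world$shapes$x == x & world$shapes$y == y)
}

room_at <- function(world, x, y) {
  for (r in names(world$rooms)) {
    rm <- world$rooms[[r]]
    if (x >= rm["x0"] && x <= rm["x1"] && y >= rm["y0"] && y <= rm["y1"])
      return(r)
  }
  NA_character_
}

corridor_at <- function(world, x, y) {
  for (co in names(world$corridors)) {
    c0 <- world$corridors[[co]]
    if (x >= c0["x0"] && x <= c0["x1"] && y >= c0["y0"] && y <= c0["y1"])
      return(co)
  }
  NA_character_
}

#' Agent pose
#'
#' @param x,y 0-based cell coordinates (must be walkable).
#' @param heading one of `"N"`, `"E"`, `"S"`, `"W"`.
#' @return a pose list.
#' @export
agent_pose <- function(x, y, heading = "N") {
  stopifnot(heading %in% HEADING_ORDER)
  list(x = as.integer(x), y = as.integer(y), heading = heading)
}

#' Apply a primitive action to a pose
#'
#' Turns rotate the heading by 90 degrees; moves translate one cell along or
#' against the heading.  A blocked move (into a wall or a shape) leaves the
#' pose unchanged; `stop` is the identity.  The environment changes only
#' through this operation.
#'
#' @param world a `cabot_world`.
#' @param pose an [agent_pose()].
#' @param action one of `"turn_left"`, `"turn_right"`, `"move_forward"`,
#'   `"move_backward"`, `"stop"`.
#' @return the new pose.
#' @export
apply_action <- function(world, pose, action) {
  h <- match(pose$heading, HEADING_ORDER)
  switch(action,
    turn_left = { pose$heading <- HEADING_ORDER[(h - 2) %% 4 + 1]; pose },
    turn_right = { pose$heading <- HEADING_ORDER[h %% 4 + 1]; pose },
    move_forward = ,
    move_backward = {
      dv <- HEADINGS[[pose$heading]]
      if (action == "move_backward") dv <- -dv
      nx <- pose$x + dv[1]; ny <- pose$y + dv[2]
      if (is_walkable(world, nx, ny)) { pose$x <- nx; pose$y <- ny }
      pose
    },
    stop = pose,
    stop("input error: unknown action '", action, "'"))
}

#' Write a move trace as TSV
#'
#' Columns `t`, `x`, `y`, `heading`, `action`.
#'
#' @param trace a trace data frame from an episode.
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(trace, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render a move trace as an ASCII map
#'
#' Walls are `#`, visited cells dots, the start `S` and the point at which
#' the move command was issued `M`.
#'
#' @param world a `cabot_world`.
#' @param trace a trace data frame with columns `x`, `y` and optionally a
#'   `mark` column containing `"S"`/`"M"` flags.
#' @return a character vector, one row per line.
#' @export
format_trace <- function(world, trace) {
  g <- matrix(" ", world$width, world$height)
  g[world$wall] <- "#"
  for (i in seq_len(nrow(world$shapes)))
    g[world$shapes$x[i] + 1, world$shapes$y[i] + 1] <-
      toupper(substr(world$shapes$kind[i], 1, 1))
  if (nrow(trace)) g[cbind(trace$x + 1, trace$y + 1)] <- "."
  if (!is.null(trace$mark)) {
    for (m in c("S", "M")) {
      i <- which(trace$mark == m)
      if (length(i)) g[trace$x[i[1]] + 1, trace$y[i[1]] + 1] <- m
    }
  } else if (nrow(trace)) {
    g[trace$x[1] + 1, trace$y[1] + 1] <- "S"
  }
  apply(g, 2, paste, collapse = "")
}
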