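test_that("the reference world validates and a broken spec does not", {
  w <- build_world()
  expect_s3_class(w, "cabot_world")
  expect_length(w$rooms, 4)
  expect_length(w$cycle, 4)

  two_shapes <- world_spec()
  two_shapes$shapes$room[2] <- two_shapes$shapes$room[1]
  expect_error(build_world(two_shapes), "one shape per room")

  dup_pair <- world_spec()
  dup_pair$shapes$kind[2] <- dup_pair$shapes$kind[1]
  dup_pair$shapes$color[2] <- dup_pair$shapes$color[1]
  expect_error(build_world(dup_pair), "one shape per room|distinct")

  # removing a corridor leaves a path, not a cycle
  path_only <- world_spec()
  path_only$corridors$W <- NULL
  expect_error(build_world(path_only), "cycle")

  overlapping <- world_spec()
  overlapping$rooms$NE <- c(x0 = 5, y0 = 1, x1 = 12, y1 = 9)
  expect_error(build_world(overlapping), "disjoint")
})

test_that("turns compose to identity and blocked moves are no-ops", {
  w <- build_world()
  p <- agent_pose(2, 7, "N")
  q <- p
  for (i in 1:4) q <- apply_action(w, q, "turn_left")
  expect_identical(q, p)
  for (i in 1:4) q <- apply_action(w, q, "turn_right")
  expect_identical(q, p)
  expect_identical(apply_action(w, p, "stop"), p)
  # pose facing the west wall: forward is blocked
  pw <- agent_pose(1, 5, "W")
  expect_identical(apply_action(w, pw, "move_forward"), pw)
  # shapes block movement
  ps <- agent_pose(5, 6, "N")    # NW shape at (5,5)
  expect_identical(apply_action(w, ps, "move_forward"), ps)
})

test_that("forward then backward restores the cell when both are unblocked", {
  w <- build_world()
  set.seed(5)
  free <- which(!w$wall, arr.ind = TRUE) - 1L
  for (i in sample(nrow(free), 25)) {
    for (h in c("N", "E", "S", "W")) {
      p <- agent_pose(free[i, 1], free[i, 2], h)
      dv <- cabot:::HEADINGS[[h]]
      if (!cabot:::is_walkable(w, p$x + dv[1], p$y + dv[2])) next
      q <- apply_action(w, p, "move_forward")
      r <- apply_action(w, q, "move_backward")
      expect_identical(r[c("x", "y")], p[c("x", "y")])
    }
  }
})

test_that("an action sequence through a corridor matches grid-path arithmetic", {
  w <- build_world()
  # from the N corridor's west mouth, walk east into the NE room
  p <- agent_pose(9, 4, "E")
  for (i in 1:6) p <- apply_action(w, p, "move_forward")
  expect_identical(c(p$x, p$y), c(15L, 4L))
  expect_equal(cabot:::room_at(w, p$x, p$y), "NE")
})

test_that("rendering is deterministic and shapes shrink with distance", {
  w <- build_world()
  p <- agent_pose(18, 20, "N")
  f1 <- render_frame(w, p); f2 <- render_frame(w, p)
  expect_identical(f1, f2)

  near <- frame_percept(render_frame(w, agent_pose(18, 20, "N")))
  far <- frame_percept(render_frame(w, agent_pose(18, 22, "N")))
  expect_gt(near$apparent_size, far$apparent_size)

  # facing a wall at distance 1: no shape pixels at all
  fw <- render_frame(w, agent_pose(2, 1, "N"))
  expect_equal(frame_percept(fw)$apparent_size, 0)
})

test_that("a close red stalactite fills the central third as a downward triangle", {
  w <- build_world()   # red stalactite in SE at (18, 18)
  f <- render_frame(w, agent_pose(18, 20, "N"))
  red <- f[, , 1] > 128 & f[, , 3] <= 128
  cols <- which(red, arr.ind = TRUE)[, 2]
  expect_true(all(cols >= 8 & cols <= 13))
  rows <- which(rowSums(red) > 0)
  expect_gt(sum(red[min(rows), ]), sum(red[max(rows), ]))   # apex down
  pc <- frame_percept(f)
  expect_equal(pc$kind, "stalactite")
  expect_equal(pc$color, "red")
  expect_equal(pc$position, "center")
})

test_that("close-range percepts recover kind and colour exactly, far ones may not", {
  w <- build_world()
  checked <- 0
  for (i in 1:4) {
    for (d in 1:3) for (h in names(cabot:::HEADINGS)) {
      v <- cabot:::HEADINGS[[h]]
      px <- w$shapes$x[i] - d * v[1]; py <- w$shapes$y[i] - d * v[2]
      if (!cabot:::is_walkable(w, px, py)) next
      pc <- frame_percept(render_frame(w, agent_pose(px, py, h)))
      expect_equal(pc$kind, w$shapes$kind[i],
                   info = sprintf("shape %d d %d %s", i, d, h))
      expect_equal(pc$color, w$shapes$color[i])
      checked <- checked + 1
    }
  }
  expect_gt(checked, 30)
  # at long range the raster is too small to discriminate kind
  pc8 <- frame_percept(render_frame(w, agent_pose(18, 10, "S")))  # d = 8
  expect_true(pc8$object_present)
  expect_lt(pc8$apparent_size, 6)
  expect_equal(pc8$kind, "unknown")
})

test_that("world seeds shuffle shape placement but keep the layout valid", {
  w1 <- build_world(1); w2 <- build_world(7)
  expect_setequal(paste(w1$shapes$color, w1$shapes$kind),
                  paste(w2$shapes$color, w2$shapes$kind))
  expect_identical(w1$rooms, w2$rooms)
  expect_identical(build_world(3)$shapes, build_world(3)$shapes)
})

test_that("traces render with start and command marks and round-trip TSV", {
  w <- build_world()
  trace <- data.frame(t = 1:3, x = c(2, 2, 3), y = c(7, 6, 6),
                      heading = c("N", "N", "E"),
                      action = c("move_forward", "turn_right", "move_forward"),
                      mark = c("S", "", "M"))
  lines <- format_trace(w, trace)
  expect_length(lines, 24)
  expect_true(any(grepl("S", lines)))
  expect_true(any(grepl("M", lines)))
  path <- tempfile(fileext = ".tsv")
  write_trace(trace, path)
  expect_equal(nrow(utils::read.table(path, header = TRUE, sep = "\t")), 3)
})

test_that("ppm frames are plain text with the right geometry", {
  w <- build_world()
  path <- tempfile(fileext = ".ppm")
  write_ppm(render_frame(w, agent_pose(18, 20, "N")), path)
  head <- readLines(path, n = 3)
  expect_equal(head[1], "P3")
  expect_equal(head[2], "20 20")
})
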