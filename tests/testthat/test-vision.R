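test_that("retina configuration enforces its timing invariants", {
  expect_s3_class(retina_config("jittered"), "retina_config")
  expect_error(retina_config(frame_interval = 50), "jitter range")
  expect_error(retina_config(processing_gap = 10), "processing gap")
})

test_that("frame encoding drives one neuron per hot pixel at the delivery time", {
  w <- build_world()
  frame <- render_frame(w, agent_pose(18, 20, "N"))
  cfg <- retina_config("regular")
  sched <- encode_frame(frame, cfg, t = 0)
  expect_true(all(sched$step == 30))            # regular: exactly 30 ms later
  expect_equal(sum(sched$population == "retina_r"),
               sum(frame[, , 1] > cfg$intensity_threshold))
  # all-black frame: empty schedule
  black <- array(0L, dim = c(20, 20, 3))
  expect_equal(nrow(encode_frame(black, cfg)), 0)
})

test_that("jittered intervals cover and stay within the configured range", {
  cfg <- retina_config("jittered")
  set.seed(99)
  draws <- replicate(1000, sample_frame_interval(cfg))
  expect_true(all(draws >= 20 & draws <= 40))
  expect_gt(length(unique(draws)), 10)
  # regular mode is the degenerate jittered mode with a zero-width range
  expect_true(all(replicate(10, sample_frame_interval(retina_config())) == 30))
  degen <- retina_config("jittered", jitter_range = c(30, 30))
  expect_true(all(replicate(10, sample_frame_interval(degen)) == 30))
})

test_that("center-surround maps respond as a direct convolution oracle", {
  img <- matrix(0, 20, 20)
  expect_true(all(center_surround(img, 3) == 0))       # uniform: silent
  img[10, 10] <- 200
  for (s in c(3, 6, 9)) {
    m <- center_surround(img, s, "on_off")
    # oracle: recompute the response at the argmax by hand
    idx <- which(m == max(m), arr.ind = TRUE)[1, ]
    cs <- s / 3; lo <- (s - cs) %/% 2 + 1
    block <- img[idx[1]:(idx[1] + s - 1), idx[2]:(idx[2] + s - 1)]
    ctr <- mean(block[lo:(lo + cs - 1), lo:(lo + cs - 1)])
    sur <- (sum(block) - sum(block[lo:(lo + cs - 1), lo:(lo + cs - 1)])) /
      (s^2 - cs^2)
    expect_equal(max(m), ctr - sur)
    # the bright pixel sits inside the winning kernel's center
    expect_true(idx[1] + lo - 1 <= 10 && 10 <= idx[1] + lo + cs - 2)
  }
  expect_error(center_surround(img, 4), "3, 6 or 9")
})

test_that("inverting an image swaps on-off and off-on responses", {
  set.seed(3)
  img <- matrix(runif(400, 0, 255), 20, 20)
  inv <- 255 - img
  for (s in c(3, 6)) {
    expect_equal(center_surround(img, s, "on_off"),
                 center_surround(inv, s, "off_on"))
    expect_equal(center_surround(img, s, "off_on"),
                 center_surround(inv, s, "on_off"))
  }
})

test_that("feature responses translate with the stimulus", {
  img <- matrix(0, 20, 20); img[8, 8] <- 255
  shifted <- matrix(0, 20, 20); shifted[8, 11] <- 255
  m1 <- center_surround(img, 3); m2 <- center_surround(shifted, 3)
  i1 <- which(m1 == max(m1), arr.ind = TRUE)[1, ]
  i2 <- which(m2 == max(m2), arr.ind = TRUE)[1, ]
  expect_equal(unname(i2 - i1), c(0, 3))
})

test_that("percepts read colour, position and apex orientation from the maps", {
  w <- build_world()
  # red stalactite dead ahead
  maps <- feature_maps(render_frame(w, agent_pose(18, 20, "N")))
  pc <- extract_percept(maps)
  expect_true(pc$object_present)
  expect_equal(pc$kind, "stalactite")
  expect_equal(pc$color, "red")
  expect_equal(pc$position, "center")
  # empty scene
  empty <- extract_percept(feature_maps(array(0L, dim = c(20, 20, 3))))
  expect_false(empty$object_present)
  expect_equal(empty$kind, "unknown")
  expect_equal(empty$color, "unknown")
  # a 3-pixel distant blob is below the discriminable size
  blob <- array(0L, dim = c(20, 20, 3))
  blob[10, 10:11, 1] <- 255L; blob[11, 10, 1] <- 255L
  pb <- extract_percept(feature_maps(blob))
  expect_true(pb$object_present)
  expect_equal(pb$kind, "unknown")
})

test_that("camera dropout only darkens lit pixels and is seed-reproducible", {
  w <- build_world()
  frame <- render_frame(w, agent_pose(18, 20, "N"))
  set.seed(8); c1 <- capture_frame(frame, 0.3)
  set.seed(8); c2 <- capture_frame(frame, 0.3)
  expect_identical(c1, c2)
  expect_identical(capture_frame(frame, 0), frame)
  lit <- frame[, , 1] > 128 | frame[, , 2] > 128 | frame[, , 3] > 128
  changed <- c1 != frame
  expect_true(all(which(apply(changed, c(1, 2), any)) %in% which(lit)))
})
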