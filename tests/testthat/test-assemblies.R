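test_that("cell assemblies ignite, persist, and can be extinguished", {
  net <- network()
  ca <- make_ca(net, 5)
  rec <- spike_record(net, cabot:::run_raw(net, 20))
  expect_equal(ca_state(ca, rec), "off")      # unstimulated: stays off
  ca_ignite(ca)
  rec <- spike_record(net, cabot:::run_raw(net, 500))
  expect_equal(ca_state(ca, rec), "ignited")
  ca_extinguish(ca)
  rec <- spike_record(net, cabot:::run_raw(net, 50))
  expect_equal(ca_state(ca, rec), "off")
  # total function: empty record is off
  empty <- structure(data.frame(step = integer(0), population = character(0),
                                neuron = integer(0)), t_end = 0)
  expect_equal(ca_state(ca, empty), "off")
})

test_that("assemblies without a persistent state are calibration errors", {
  net <- network()
  expect_error(make_ca(net, 1), "calibration error")
  expect_error(make_ca(net, 5, intra_weight = 0), "calibration error")
  expect_error(make_ca(net, 3, intra_weight = 0.3), "calibration error")
})

test_that("inhibition extinguishes an ignited assembly", {
  net <- network()
  ca <- make_ca(net, 5)
  add_population(net, "inh", 5, neuron_params(membrane_decay = 0.05))
  add_projection(net, "ic", "inh", ca$pop, rep(1:5, each = 5), rep(1:5, 5),
                 -2)
  ca_ignite(ca)
  inj <- data.frame(step = 1:5, population = "inh",
                    neuron = rep(1:5, each = 5)[1:5], value = 1.3)
  inj <- expand.grid(step = 1:5, neuron = 1:5)
  inj$population <- "inh"; inj$value <- 1.3
  run_network(net, 10, inj)
  rec <- spike_record(net, cabot:::run_raw(net, 30))
  expect_equal(ca_state(ca, rec), "off")
})

test_that("a two-state FSA toggles and a single state persists", {
  net <- network()
  tr <- data.frame(state = c("A", "B"), symbol = "x",
                   next_state = c("B", "A"), stringsAsFactors = FALSE)
  fsa <- make_fsa(net, c("A", "B"), "x", tr, "A")
  fsa_start(fsa)
  rec <- fsa_present(fsa, "x")
  expect_equal(fsa_state(fsa, rec), "B")
  rec <- fsa_present(fsa, "x")
  expect_equal(fsa_state(fsa, rec), "A")

  net2 <- network()
  one <- make_fsa(net2, "S", character(0),
                  data.frame(state = character(0), symbol = character(0),
                             next_state = character(0)), "S")
  fsa_start(one)
  rec <- spike_record(net2, cabot:::run_raw(net2, 2000))
  expect_equal(fsa_state(one, rec), "S")
})

test_that("FSA construction validates its transition table", {
  net <- network()
  expect_error(make_fsa(net, c("A"), "x",
                        data.frame(state = "A", symbol = "x",
                                   next_state = "Z"), "A"),
               "configuration error")
  expect_error(make_fsa(net, c("A"), "x",
                        data.frame(state = "A", symbol = "y",
                                   next_state = "A"), "A"),
               "configuration error")
})

test_that("random FSAs match the symbolic oracle and stay one-hot", {
  set.seed(202)
  for (trial in 1:12) {
    spec <- random_fsa(sample(2:6, 1), sample(2:4, 1))
    input <- sample(spec$symbols, sample(5:15, 1), replace = TRUE)
    res <- run_neural_fsa(spec, input)
    expect_equal(res$final, fsa_oracle(spec$transition, spec$start, input))
    expect_true(all(lengths(res$checkpoints) == 1))   # one-hot at checkpoints
  }
})

test_that("timers emit taps on schedule and only when started", {
  net <- network()
  tm <- make_timer(net, 50, 10, taps = c(0, 2, 4))
  rec <- spike_record(net, cabot:::run_raw(net, 100))
  expect_equal(sum(rec$population == tm$pop), 0)   # not started: silent
  rec <- timer_start(tm)
  w <- timer_tap_windows(tm, rec)
  t0 <- min(rec$step[rec$population == tm$pop])
  expect_equal(w$from - t0, c(0, 20, 40))
  expect_equal(w$to - w$from, c(9, 9, 9))
  expect_true(all(diff(w$from) > 0))               # monotone tap order
  # no output after the duration
  rec2 <- spike_record(net, cabot:::run_raw(net, 500))
  expect_equal(sum(rec2$population == tm$pop), 0)
})

test_that("timer construction validates duration and taps", {
  net <- network()
  expect_error(make_timer(net, 55, 10), "multiple")
  expect_error(make_timer(net, 50, 10, taps = 5), "tap positions")
})
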