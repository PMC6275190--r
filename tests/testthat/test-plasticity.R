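test_that("the STDP kernel potentiates pre-before-post and depresses the reverse", {
  p <- stdp_params(a_plus = 0.02, a_minus = 0.01, tau_plus = 10,
                   tau_minus = 10)
  expect_equal(stdp_kernel(1, p), 0.02 * exp(-1 / 10))
  expect_equal(stdp_kernel(-3, p), -0.01 * exp(-3 / 10))
  expect_equal(stdp_kernel(0, p), 0)
  expect_equal(stdp_kernel(1000, p), 0)        # beyond the cutoff
  # magnitude decays with lag
  lags <- 1:20
  expect_true(all(diff(stdp_kernel(lags, p)) < 0))
})

two_pop_plastic <- function(w0 = 0.05, w_max = 0.12) {
  net <- network()
  add_population(net, "pre", 1, neuron_params())
  add_population(net, "post", 1, neuron_params())
  add_projection(net, "pp", "pre", "post", 1, 1, w0, 1, "stdp_hebbian", w_max)
  net
}

spikes_at <- function(net, pop, steps) {
  df <- data.frame(step = steps, population = pop, neuron = 1)
  structure(df, t_end = max(steps))
}

test_that("single pairings change the weight by the kernel value at the lag", {
  for (lag in c(1, 2, 5)) {
    net <- two_pop_plastic()
    pre <- spikes_at(net, "pre", 10)
    post <- spikes_at(net, "post", 10 + lag)
    w <- apply_plasticity(net, "pp", pre, post)
    expect_equal(w, 0.05 + stdp_kernel(lag), tolerance = 1e-12)
  }
  # post before pre: depression
  net <- two_pop_plastic()
  w <- apply_plasticity(net, "pp", spikes_at(net, "pre", 12),
                        spikes_at(net, "post", 10))
  expect_equal(w, 0.05 + stdp_kernel(-2))
})

test_that("no spikes leave weights unchanged; saturation clips at the bound", {
  net <- two_pop_plastic()
  empty <- structure(data.frame(step = integer(0), population = character(0),
                                neuron = integer(0)), t_end = 0)
  w <- apply_plasticity(net, "pp", empty, empty)
  expect_equal(w, 0.05)
  # massive repeated pre-before-post pairing saturates exactly at w_max
  pre <- spikes_at(net, "pre", seq(1, 400, by = 2))
  post <- spikes_at(net, "post", seq(2, 400, by = 2))
  w <- apply_plasticity(net, "pp", pre, post)
  expect_equal(w, 0.12)
  w <- apply_plasticity(net, "pp", pre, post)   # still bounded
  expect_equal(w, 0.12)
  # and depression never crosses zero magnitude
  net2 <- two_pop_plastic(w0 = 0.01)
  w2 <- apply_plasticity(net2, "pp", spikes_at(net2, "pre", seq(2, 400, 2)),
                         spikes_at(net2, "post", seq(1, 400, 2)))
  expect_gte(w2, 0)
})

test_that("plasticity on a static projection is a usage error", {
  net <- network()
  add_population(net, "a", 1, neuron_params())
  add_population(net, "b", 1, neuron_params())
  add_projection(net, "ab", "a", "b", 1, 1, 0.5)
  expect_error(apply_plasticity(net, "ab", NULL, NULL), "static")
})

test_that("inhibitory synapses keep their sign through plasticity", {
  net <- network()
  add_population(net, "pre", 1, neuron_params())
  add_population(net, "post", 1, neuron_params())
  add_projection(net, "pp", "pre", "post", 1, 1, -0.05, 1, "stdp_hebbian", 0.12)
  w <- apply_plasticity(net, "pp", spikes_at(net, "pre", seq(1, 100, 2)),
                        spikes_at(net, "post", seq(2, 100, 2)))
  expect_lte(w, 0)
  expect_gte(abs(w), 0.05)
})
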