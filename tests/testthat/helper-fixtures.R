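# Small builders shared across tests.  Everything is generated in code; no
# stored fixtures.

single_neuron_net <- function(decay = 0.8, threshold = 1, refractory = 0L,
                              adapt_increment = 0, adapt_decay = 0.9,
                              model = "lif_adapt", ...) {
  net <- network()
  add_population(net, "n", 1,
                 neuron_params(membrane_decay = decay, threshold = threshold,
                               refractory = refractory,
                               adapt_increment = adapt_increment,
                               adapt_decay = adapt_decay, ...),
                 model = model)
  net
}

constant_drive <- function(steps, value, pop = "n", neuron = 1) {
  data.frame(step = seq_len(steps), population = pop, neuron = neuron,
             value = value)
}

# closed-form LIF inter-spike interval: after a reset the potential under
# constant drive I is I * (1 - lambda^k) / (1 - lambda); the neuron fires at
# the first k where this reaches threshold, but no sooner than the
# refractory period allows
lif_isi_closed_form <- function(I, lambda, threshold, refractory) {
  v <- I * (1 - lambda^(1:1000)) / (1 - lambda)
  k <- which(v >= threshold - 1e-9)[1]
  max(k, refractory + 1L)
}

random_fsa <- function(n_states, n_symbols) {
  states <- paste0("q", seq_len(n_states))
  symbols <- paste0("a", seq_len(n_symbols))
  tr <- expand.grid(state = states, symbol = symbols,
                    stringsAsFactors = FALSE)
  tr$next_state <- sample(states, nrow(tr), replace = TRUE)
  list(states = states, symbols = symbols, transition = tr, start = states[1])
}

run_neural_fsa <- function(spec, input) {
  net <- network()
  fsa <- make_fsa(net, spec$states, spec$symbols, spec$transition, spec$start)
  fsa_start(fsa)
  rec <- NULL
  states_seen <- list()
  for (a in input) {
    rec <- fsa_present(fsa, a)
    states_seen[[length(states_seen) + 1L]] <- fsa_state(fsa, rec)
  }
  list(final = fsa_state(fsa, rec), checkpoints = states_seen)
}
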