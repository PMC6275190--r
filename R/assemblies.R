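# Reference parameters for binary cell assemblies and the glue neurons
# (conjunction/coincidence detectors, inhibitory interneurons) used by the
# FSA and timer classes.  CA members are plain LIF units: after a spike the
# potential resets, and the recurrent input (size-1) * intra_weight >= 1
# re-fires every member each step, which is what makes ignition persistent.
ca_params <- function() neuron_params(membrane_decay = 0.2, threshold = 1,
                                      resting = 0, reset = 0, refractory = 0L)
# coincidence detectors: near-memoryless so a single sub-threshold source
# can never integrate to threshold
conj_params <- function() neuron_params(membrane_decay = 0.05, threshold = 1)

CA_INTRA_W <- 0.3
CA_IGNITE <- 1.3          # one-step injection that fires every member
CA_EXTINGUISH <- -5       # per-step inhibitory injection
CA_EXTINGUISH_STEPS <- 3L

# injection schedule block: rows (step, global index, value)
sched_block <- function(net, pop, neurons, steps, val) {
  gidx <- neuron_index(net, pop, neurons)
  cbind(step = rep(as.integer(steps), each = length(gidx)),
        idx = rep(gidx, times = length(steps)),
        val = val)
}

rbind_sched <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (!length(parts)) NULL else do.call(rbind, parts)
}

#' Create a binary cell assembly
#'
#' Adds a fully connected excitatory population to the network: each of the
#' `size` members synapses onto all the others with weight `intra_weight`
#' and delay 1.  Once every member has fired in the same step, the recurrent
#' input re-fires all of them every following step ("ignition"); with no
#' external interference an ignited assembly stays ignited indefinitely, and
#' an unstimulated one stays silent.
#'
#' @param net a [network()].
#' @param size number of member neurons (>= 2; default 5).
#' @param intra_weight internal excitatory weight.
#' @param id population id (auto-generated when `NULL`).
#' @return an object of class `cabot_ca`.
#' @export
make_ca <- function(net, size = 5, intra_weight = CA_INTRA_W, id = NULL) {
  if (size < 2)
    stop("calibration error: a cell assembly needs >= 2 members for mutual support")
  pars <- ca_params()
  if ((size - 1) * intra_weight < pars$threshold)
    stop("calibration error: (size-1)*intra_weight = ",
         (size - 1) * intra_weight, " < threshold ", pars$threshold,
         "; no persistent state exists under delay >= 1")
  if (is.null(id)) id <- sprintf("ca%03d", length(net$pops) + 1L)
  add_population(net, id, size, pars)
  pre <- rep(seq_len(size), each = size - 1)
  post <- unlist(lapply(seq_len(size), function(i) setdiff(seq_len(size), i)))
  add_projection(net, paste0(id, ".intra"), id, id, pre, post,
                 intra_weight, 1L)
  structure(list(net = net, pop = id, size = as.integer(size),
                 intra_weight = intra_weight), class = "cabot_ca")
}

# schedule fragments used by drivers that merge many injections into one run
sched_ignite <- function(ca, step = 1L)
  sched_block(ca$net, ca$pop, seq_len(ca$size), step, CA_IGNITE)
sched_extinguish <- function(ca, step = 1L)
  sched_block(ca$net, ca$pop, seq_len(ca$size),
              step + seq_len(CA_EXTINGUISH_STEPS) - 1L, CA_EXTINGUISH)

#' Ignite or extinguish a cell assembly
#'
#' `ca_ignite()` injects a one-step supra-threshold pulse into every member
#' and runs the network for `settle` steps; `ca_extinguish()` injects strong
#' inhibition for a few steps, which breaks the recurrent firing.
#'
#' @param ca a `cabot_ca`.
#' @param settle steps to run after the injection.
#' @return the spike record of the settling run.
#' @export
ca_ignite <- function(ca, settle = 5L) {
  sched <- sched_ignite(ca)
  spike_record(ca$net, run_raw(ca$net, settle, sched))
}

#' @rdname ca_ignite
#' @export
ca_extinguish <- function(ca, settle = 10L) {
  sched <- sched_extinguish(ca)
  spike_record(ca$net, run_raw(ca$net, settle, sched))
}

#' Read the binary state of a cell assembly from a spike record
#'
#' The assembly is `"ignited"` iff every member fired within the last
#' `window` steps of the record's horizon, and `"off"` otherwise.  The
#' horizon is the record's `t_end` attribute (set by [run_network()]), or
#' the latest spike when absent.  A total function: an empty record gives
#' `"off"`.
#'
#' @param ca a `cabot_ca`.
#' @param record a spike record.
#' @param window steps to look back (>= one intra-assembly cycle).
#' @return `"ignited"` or `"off"`.
#' @export
ca_state <- function(ca, record, window = 10L) {
  if (pop_ignited(record, ca$pop, ca$size, window)) "ignited" else "off"
}

# shared ignition test on a population's members
pop_ignited <- function(record, pop, size, window = 10L,
                        members = seq_len(size)) {
  if (!nrow(record)) return(FALSE)
  t_end <- attr(record, "t_end") %||% max(record$step)
  sel <- record$population == pop & record$step > t_end - window
  all(members %in% record$neuron[sel])
}

#' Build a finite-state automaton from cell assemblies
#'
#' Each state is a binary cell assembly; symbols are transient input lines.
#' Presenting symbol `a` while state `s` is ignited drives, via a
#' conjunction (coincidence-detector) population, a three-stage inhibitory
#' cascade that extinguishes the state layer, followed by a delayed
#' excitatory volley that ignites the successor state `delta(s, a)`.  After
#' each settle window exactly one state assembly is ignited.  Transitions
#' not listed default to self-loops (the state simply persists, which the
#' wiring realizes by doing nothing).
#'
#' @param net a [network()].
#' @param states character vector of state labels.
#' @param symbols character vector of symbol labels.
#' @param transition data frame with columns `state`, `symbol`, `next_state`.
#' @param start start state label.
#' @param settle_window steps allowed for a transition to complete
#'   (default 20); symbols must be presented at least one settle window
#'   apart.
#' @param id prefix for the populations created (auto when `NULL`).
#' @return an object of class `cabot_fsa`.
#' @export
make_fsa <- function(net, states, symbols, transition, start,
                     settle_window = 20L, id = NULL) {
  if (!start %in% states) stop("configuration error: unknown start state")
  bad <- !transition$state %in% states | !transition$next_state %in% states |
    !transition$symbol %in% symbols
  if (any(bad))
    stop("configuration error: transition references unknown state or symbol")
  if (anyDuplicated(transition[c("state", "symbol")]))
    stop("configuration error: duplicate transition for a (state, symbol) pair")
  if (is.null(id)) id <- sprintf("fsa%02d", length(net$pops) + 1L)

  cas <- lapply(states, function(s)
    make_ca(net, 5, id = paste0(id, ".s.", s)))
  names(cas) <- states

  nsym <- length(symbols)
  if (nsym > 0)
    add_population(net, paste0(id, ".sym"), 5L * nsym, conj_params())

  tr <- transition[transition$state != transition$next_state, , drop = FALSE]
  ntr <- nrow(tr)
  if (ntr > 0) {
    add_population(net, paste0(id, ".conj"), 2L * ntr, conj_params())
    for (stage in 1:3)
      add_population(net, paste0(id, ".inh", stage), 1L, conj_params())

    conj_of <- function(k) c(2L * k - 1L, 2L * k)
    sym_block <- function(s) 5L * (match(s, symbols) - 1L) + 1:5

    pre_s <- integer(0); post_s <- integer(0)    # state CA -> conj
    pre_y <- integer(0); post_y <- integer(0)    # symbol  -> conj
    for (k in seq_len(ntr)) {
      post_s <- c(post_s, rep(conj_of(k), each = 5))
      pre_y <- c(pre_y, rep(sym_block(tr$symbol[k]), times = 2))
      post_y <- c(post_y, rep(conj_of(k), each = 5))
    }
    # state -> conj wired per state population
    for (s in unique(tr$state)) {
      ks <- which(tr$state == s)
      post_k <- unlist(lapply(ks, conj_of))
      add_projection(net, sprintf("%s.sc.%s", id, s), paste0(id, ".s.", s),
                     paste0(id, ".conj"),
                     pre = rep(1:5, times = length(post_k)),
                     post = rep(post_k, each = 5), weight = 0.13)
    }
    add_projection(net, paste0(id, ".yc"), paste0(id, ".sym"),
                   paste0(id, ".conj"), pre_y, post_y, 0.13)
    # conjunction -> inhibitory cascade -> all states
    add_projection(net, paste0(id, ".ci"), paste0(id, ".conj"),
                   paste0(id, ".inh1"), seq_len(2L * ntr), 1L, 0.6)
    add_projection(net, paste0(id, ".i12"), paste0(id, ".inh1"),
                   paste0(id, ".inh2"), 1L, 1L, 1.2)
    add_projection(net, paste0(id, ".i23"), paste0(id, ".inh2"),
                   paste0(id, ".inh3"), 1L, 1L, 1.2)
    for (stage in 1:3) for (s in states)
      add_projection(net, sprintf("%s.i%d.%s", id, stage, s),
                     paste0(id, ".inh", stage), paste0(id, ".s.", s),
                     1L, 1:5, -2.5)
    # delayed excitatory volley ignites the successor
    for (k in seq_len(ntr))
      add_projection(net, sprintf("%s.ct.%d", id, k), paste0(id, ".conj"),
                     paste0(id, ".s.", tr$next_state[k]),
                     pre = rep(conj_of(k), each = 5), post = rep(1:5, 2),
                     weight = 0.8, delay = 8L)
  }

  structure(list(net = net, id = id, states = states, symbols = symbols,
                 transition = transition, start = start, cas = cas,
                 settle_window = as.integer(settle_window)),
            class = "cabot_fsa")
}

# symbol injection schedule: a 3-step pulse on the symbol's input block
sched_symbol <- function(fsa, symbol, step = 1L) {
  j <- match(symbol, fsa$symbols)
  if (is.na(j)) stop("input error: unknown symbol '", symbol, "'")
  sched_block(fsa$net, paste0(fsa$id, ".sym"), 5L * (j - 1L) + 1:5,
              step + 0:2, CA_IGNITE)
}

#' Drive a cell-assembly FSA
#'
#' `fsa_start()` ignites the start state; `fsa_present()` injects one symbol
#' and runs a settle window; `fsa_state()` reads the ignited state(s) from a
#' spike record; `fsa_reset()` extinguishes all states and re-ignites the
#' start state.
#'
#' @param fsa a `cabot_fsa`.
#' @param symbol a symbol label.
#' @param record a spike record.
#' @param window look-back window for the state readout.
#' @return `fsa_present()` and `fsa_start()` return the settle-window spike
#'   record; `fsa_state()` returns the labels of ignited state assemblies
#'   (length 1 when the one-hot invariant holds).
#' @export
fsa_start <- function(fsa) {
  sched <- sched_ignite(fsa$cas[[fsa$start]])
  spike_record(fsa$net, run_raw(fsa$net, fsa$settle_window, sched))
}

#' @rdname fsa_start
#' @export
fsa_present <- function(fsa, symbol) {
  sched <- sched_symbol(fsa, symbol)
  spike_record(fsa$net, run_raw(fsa$net, fsa$settle_window, sched))
}

#' @rdname fsa_start
#' @export
fsa_state <- function(fsa, record, window = 5L) {
  on <- vapply(fsa$states, function(s)
    pop_ignited(record, paste0(fsa$id, ".s.", s), 5L, window), logical(1))
  fsa$states[on]
}

#' @rdname fsa_start
#' @export
fsa_reset <- function(fsa) {
  sched <- do.call(rbind, lapply(fsa$states, function(s)
    sched_extinguish(fsa$cas[[s]])))
  run_raw(fsa$net, CA_EXTINGUISH_STEPS + 5L, sched)
  fsa_start(fsa)
}

#' Symbolic FSA oracle
#'
#' Runs the abstract automaton (no neurons) over an input string: the
#' independent reference against which the neural FSA is checked.  Missing
#' transitions are self-loops, as in [make_fsa()].
#'
#' @param transition data frame with columns `state`, `symbol`, `next_state`.
#' @param start start state label.
#' @param input character vector of symbols.
#' @return the final state label.
#' @export
fsa_oracle <- function(transition, start, input) {
  s <- start
  key <- paste(transition$state, transition$symbol)
  for (a in input) {
    hit <- match(paste(s, a), key)
    if (!is.na(hit)) s <- transition$next_state[hit]
  }
  s
}

#' Create a synfire-chain timer
#'
#' A feed-forward chain of `duration` neurons, one per step: starting the
#' timer fires the first neuron, and activity travels down the chain one
#' neuron per step, ending after `duration` steps unless restarted.  The
#' chain is divided into `duration / interval` groups; taps are designated
#' groups whose neurons emit output during their window, used to gate other
#' assemblies by wiring projections from the tap neurons.
#'
#' @param net a [network()].
#' @param duration total steps; must be an integer multiple of `interval`.
#' @param interval steps each group stays active.
#' @param taps 0-based group positions emitting output.
#' @param id population id prefix (auto when `NULL`).
#' @return an object of class `cabot_timer`.
#' @export
make_timer <- function(net, duration, interval, taps = 0L, id = NULL) {
  k <- duration / interval
  if (k != round(k) || k < 1)
    stop("configuration error: duration must be a positive multiple of interval")
  if (any(taps < 0 | taps >= k))
    stop("configuration error: tap positions must lie in [0, ", k, ")")
  if (is.null(id)) id <- sprintf("timer%02d", length(net$pops) + 1L)
  add_population(net, id, as.integer(duration), conj_params())
  if (duration > 1)
    add_projection(net, paste0(id, ".chain"), id, id,
                   pre = seq_len(duration - 1), post = 2:duration,
                   weight = 1.2, delay = 1L)
  structure(list(net = net, pop = id, duration = as.integer(duration),
                 interval = as.integer(interval), k = as.integer(k),
                 taps = as.integer(taps)), class = "cabot_timer")
}

# neurons belonging to tap group p (0-based)
timer_tap_neurons <- function(timer, p)
  p * timer$interval + seq_len(timer$interval)

sched_timer_start <- function(timer, step = 1L)
  sched_block(timer$net, timer$pop, 1L, step, CA_IGNITE)

#' Start a timer and observe its tap windows
#'
#' `timer_start()` injects the head of the chain and runs the network for
#' the timer's full duration (plus slack); `timer_tap_windows()` extracts,
#' from a spike record, the first and last firing step of each tap group.
#'
#' @param timer a `cabot_timer`.
#' @param slack extra steps to run beyond the nominal duration.
#' @param record a spike record.
#' @return `timer_start()` returns the spike record; `timer_tap_windows()` a
#'   data frame with columns `tap`, `from`, `to` (NA when a tap never fired).
#' @export
timer_start <- function(timer, slack = 5L) {
  sched <- sched_timer_start(timer)
  spike_record(timer$net, run_raw(timer$net, timer$duration + slack, sched))
}

#' @rdname timer_start
#' @export
timer_tap_windows <- function(timer, record) {
  rows <- lapply(timer$taps, function(p) {
    sel <- record$population == timer$pop &
      record$neuron %in% timer_tap_neurons(timer, p)
    st <- record$step[sel]
    data.frame(tap = p, from = if (length(st)) min(st) else NA_integer_,
               to = if (length(st)) max(st) else NA_integer_)
  })
  do.call(rbind, rows)
}
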