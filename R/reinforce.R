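# Reward-gated rule selection: antecedent assemblies (the a subnet) project
# plastically to consequent assemblies (the c subnet).  An Explore subnet
# fires at an elevated rate whenever an antecedent is present and drives
# consequents with seeded noise, so that an untrained network tries
# consequents at random.  A correct consequent triggers external activation
# of the Value subnet, which suppresses Explore, and the active pair is
# potentiated while the antecedent's other consequents are depressed; a
# wrong consequent gets a small transient Hebbian increase, no Value, and
# Explore keeps driving until another consequent is selected.  The only
# attractor states are the pairings the reward rule defines.

RL_W0 <- 0.02          # initial a->c weight (low: no direct selection)
RL_WMAX <- 0.30        # 5*w_max drives a consequent by itself
RL_LTP_REWARD <- 0.06  # potentiation of the rewarded pair, per synapse
RL_LTD_REWARD <- 0.04  # depression of the antecedent's other pairs
RL_LTP_WRONG <- 0.01   # transient Hebbian increase on an unrewarded pair
RL_NOISE_RANGE <- c(0.35, 0.75)  # per-window Explore drive to each consequent
RL_WINDOW <- 40L       # steps per selection attempt
RL_REWARD_WINDOW <- 30L

#' Build a reinforcement rule-selection network
#'
#' @param n_antecedents,n_consequents numbers of antecedent / consequent
#'   assemblies (>= 1).
#' @param w0 initial a-to-c weight ("the weights were initially low"); pass
#'   a matrix (`n_antecedents` x `n_consequents`) to preset learned weights.
#' @return an object of class `cabot_rulenet`.
#' @export
build_rulenet <- function(n_antecedents, n_consequents, w0 = RL_W0) {
  stopifnot(n_antecedents >= 1, n_consequents >= 1)
  net <- network()
  blk <- function(i) (i - 1L) * 5L + 1:5
  add_population(net, "a", 5L * n_antecedents, ca_params())
  add_population(net, "c", 5L * n_consequents, ca_params())
  add_population(net, "explore", 10L, neuron_params(membrane_decay = 0.5))
  add_population(net, "value", 10L, neuron_params(membrane_decay = 0.5))
  for (pop in c("a", "c")) {
    nb <- if (pop == "a") n_antecedents else n_consequents
    pre <- integer(0); post <- integer(0)
    for (b in seq_len(nb)) for (i in blk(b)) for (j in setdiff(blk(b), i)) {
      pre <- c(pre, i); post <- c(post, j)
    }
    add_projection(net, paste0(pop, ".intra"), pop, pop, pre, post, CA_INTRA_W)
  }
  g <- expand.grid(pre = seq_len(5L * n_antecedents),
                   post = seq_len(5L * n_consequents))
  wmat <- if (is.matrix(w0)) w0 else
    matrix(w0, n_antecedents, n_consequents)
  wvec <- wmat[cbind((g$pre - 1L) %/% 5L + 1L, (g$post - 1L) %/% 5L + 1L)]
  add_projection(net, "ac", "a", "c", g$pre, g$post, wvec, 1L,
                 "stdp_hebbian", RL_WMAX)
  # any antecedent drives Explore to an elevated rate
  ga <- expand.grid(pre = seq_len(5L * n_antecedents), post = 1:10)
  add_projection(net, "a_explore", "a", "explore", ga$pre, ga$post, 0.15)
  # Explore keeps a small presence on every consequent; the selective part
  # of its drive is the per-window noise injection
  ge <- expand.grid(pre = 1:10, post = seq_len(5L * n_consequents))
  add_projection(net, "explore_c", "explore", "c", ge$pre, ge$post, 0.02)
  # reward suppresses exploration
  add_projection(net, "value_explore", "value", "explore",
                 rep(1:10, each = 10), rep(1:10, 10), -0.3)
  # winner-take-all among consequents
  if (n_consequents > 1) {
    pre <- integer(0); post <- integer(0)
    for (b1 in seq_len(n_consequents)) for (b2 in seq_len(n_consequents))
      if (b1 != b2) {
        pre <- c(pre, rep(blk(b1), each = 5)); post <- c(post, rep(blk(b2), 5))
      }
    add_projection(net, "c.wta", "c", "c", pre, post, -0.4)
  }
  structure(list(net = net, n_a = n_antecedents, n_c = n_consequents),
            class = "cabot_rulenet")
}

rl_blk <- function(i) (i - 1L) * 5L + 1:5

# mean weight matrix of the plastic a->c projection
rulenet_weights <- function(rn) {
  outer(seq_len(rn$n_a), seq_len(rn$n_c), Vectorize(function(a, cc)
    projection_weight(rn$net, "ac", pre = rl_blk(a), post = rl_blk(cc))))
}

set_pair_weight <- function(rn, a, cc, delta) {
  net <- rn$net
  pr <- net$projections[["ac"]]
  pre <- net$syn_pre[pr$idx] + 1L          # pops a, c start at offset 0 / 5n_a
  sel <- ((net$syn_pre[pr$idx] - net$pops[["a"]]$offset) %/% 5L + 1L) == a &
    ((net$syn_post[pr$idx] - net$pops[["c"]]$offset) %/% 5L + 1L) == cc
  w <- net$syn_w[pr$idx][sel] + delta
  net$syn_w[pr$idx][sel] <- pmin(pmax(w, 0), pr$w_max)
  touch_weights(net)
  invisible(rn)
}

rl_extinguish <- function(rn) {
  sched <- rbind(
    sched_block(rn$net, "a", seq_len(5L * rn$n_a), 1:3, CA_EXTINGUISH),
    sched_block(rn$net, "c", seq_len(5L * rn$n_c), 1:3, CA_EXTINGUISH))
  run_raw(rn$net, 8L, sched)
  invisible(rn)
}

ignited_c <- function(rn, rec, window = 6L) {
  which(vapply(seq_len(rn$n_c), function(b)
    pop_ignited(rec, "c", 5L * rn$n_c, window, members = rl_blk(b)),
    logical(1)))
}

# mean firing rate of a population over the record's final `window` steps
pop_rate <- function(rec, pop, size, window) {
  t_end <- attr(rec, "t_end") %||% if (nrow(rec)) max(rec$step) else 0
  sum(rec$population == pop & rec$step > t_end - window) / (size * window)
}

#' Run one reinforcement trial
#'
#' Stimulates one antecedent and lets the network select a consequent: a
#' trained pairing ignites its consequent directly; otherwise Explore's
#' seeded noise drive makes one cross threshold.  A correct selection (per
#' the reward rule) externally activates Value, suppressing Explore, and
#' applies the reward-gated updates (LTP on the active pair, LTD from the
#' antecedent to the other consequents).  A wrong selection gets a small
#' transient potentiation, is then held down for the rest of the trial, and
#' another consequent is tried within the same trial.
#'
#' @param rn a [build_rulenet()] network.
#' @param antecedent antecedent index.
#' @param reward_rule integer vector: `reward_rule[a]` is the correct
#'   consequent for antecedent `a` (must be total).
#' @param max_tries selection attempts per trial.
#' @param keep_record return the full spike record of the trial.
#' @return a list (`trial_outcome`): `antecedent`, `consequent` (the final
#'   selection, NA if none), `rewarded`, `tries`, `weights` (post-trial mean
#'   weight matrix), and optionally `record`, plus `explore_rate` /
#'   `value_rate` over the settled part of each phase.
#' @export
run_trial <- function(rn, antecedent, reward_rule, max_tries = 6L,
                      keep_record = FALSE) {
  if (length(reward_rule) < rn$n_a || any(is.na(reward_rule[seq_len(rn$n_a)])))
    stop("configuration error: reward_rule must be total on the antecedents")
  net <- rn$net
  rl_extinguish(rn)
  run_raw(net, 2L, sched_block(net, "a", rl_blk(antecedent), 1L, CA_IGNITE))
  recs <- list()
  blocked <- integer(0)
  selected <- NA_integer_; rewarded <- FALSE; tries <- 0L
  explore_rates <- numeric(0)
  for (try in seq_len(max_tries)) {
    tries <- try
    noise <- runif(rn$n_c, RL_NOISE_RANGE[1], RL_NOISE_RANGE[2])
    sched <- NULL
    for (cc in seq_len(rn$n_c)) {
      if (cc %in% blocked)
        # must dominate recurrent (1.2) + trained drive (1.5) so a rejected
        # consequent cannot re-ignite within the trial
        sched <- rbind_sched(sched, sched_block(net, "c", rl_blk(cc),
                                                seq_len(RL_WINDOW), -3.5))
      else
        sched <- rbind_sched(sched, sched_block(net, "c", rl_blk(cc),
                                                5:RL_WINDOW, noise[cc]))
    }
    rec <- spike_record(net, run_raw(net, RL_WINDOW, sched))
    recs[[length(recs) + 1L]] <- rec
    explore_rates <- c(explore_rates, pop_rate(rec, "explore", 10L, 20L))
    sel <- setdiff(ignited_c(rn, rec), blocked)
    if (length(sel) != 1) next
    selected <- sel
    if (sel == reward_rule[antecedent]) {
      # reward: Value on, Explore suppressed, reward-gated plasticity
      vsched <- sched_block(net, "value", 1:10, seq_len(RL_REWARD_WINDOW), 1.3)
      vrec <- spike_record(net, run_raw(net, RL_REWARD_WINDOW, vsched))
      recs[[length(recs) + 1L]] <- vrec
      set_pair_weight(rn, antecedent, sel, RL_LTP_REWARD)
      for (cc in setdiff(seq_len(rn$n_c), sel))
        set_pair_weight(rn, antecedent, cc, -RL_LTD_REWARD)
      rewarded <- TRUE
      attr(rewarded, "value_rate") <- pop_rate(vrec, "value", 10L, 20L)
      attr(rewarded, "explore_rate_reward") <- pop_rate(vrec, "explore", 10L, 20L)
      break
    }
    # wrong: transient Hebbian increase, no Value, try again
    set_pair_weight(rn, antecedent, sel, RL_LTP_WRONG)
    run_raw(net, 8L, sched_block(net, "c", rl_blk(sel), 1:3, CA_EXTINGUISH))
    blocked <- c(blocked, sel)
    if (length(blocked) >= rn$n_c) blocked <- integer(0)  # all tried: reopen
  }
  rl_extinguish(rn)
  out <- list(antecedent = antecedent, consequent = selected,
              rewarded = as.logical(rewarded), tries = tries,
              explore_rate = mean(explore_rates),
              value_rate = attr(rewarded, "value_rate") %||% 0,
              explore_rate_during_reward =
                attr(rewarded, "explore_rate_reward") %||% NA_real_,
              weights = rulenet_weights(rn))
  if (keep_record) out$record <- do.call(rbind, recs)
  class(out) <- "trial_outcome"
  out
}

#' Train a rule network on a fixed reward rule
#'
#' Runs `trials` trials with antecedents presented round-robin.
#'
#' @param rn a rule network.
#' @param reward_rule as in [run_trial()].
#' @param trials number of trials.
#' @return `rn`, invisibly.
#' @export
train_rulenet <- function(rn, reward_rule, trials = 20L) {
  for (i in seq_len(trials))
    run_trial(rn, (i - 1L) %% rn$n_a + 1L, reward_rule)
  invisible(rn)
}

#' Read out the learned policy
#'
#' Deterministic argmax-weight readout of the plastic projection; ties are
#' reported per antecedent.
#'
#' @param rn a rule network.
#' @return list with `choice` (integer vector, the argmax consequent per
#'   antecedent) and `tie` (logical vector).
#' @export
policy <- function(rn) {
  w <- rulenet_weights(rn)
  list(choice = apply(w, 1, which.max),
       tie = apply(w, 1, function(x) sum(abs(x - max(x)) < 1e-9) > 1))
}
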