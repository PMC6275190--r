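#' Neuron parameter set
#'
#' Parameters of the discrete-time point-neuron models.  Two model kinds are
#' supported: `"lif_adapt"`, a leaky integrate-and-fire neuron with spike-rate
#' adaptation, and `"flif"`, a fatiguing LIF whose firing propensity drops
#' with recent activity and recovers with rest.  Activation is dimensionless;
#' by default the resting level is 0 and the threshold 1.
#'
#' `membrane_decay` and `adapt_decay` are *retention* fractions per step in
#' (0, 1]: a value of 1 retains the full quantity (no leak), small values
#' leak quickly.  The membrane relaxes toward `resting`; adaptation and
#' fatigue are subtracted from the membrane potential when the threshold is
#' tested, so a fired neuron needs more drive to fire again.
#'
#' @param membrane_decay fraction of the (potential - resting) difference
#'   retained per step, in (0, 1].
#' @param threshold firing threshold (must exceed `resting`).
#' @param resting resting activation level.
#' @param reset potential immediately after a spike.
#' @param refractory number of steps after a spike during which the neuron
#'   cannot fire (>= 0).
#' @param adapt_increment adaptation added at each spike (>= 0).
#' @param adapt_decay fraction of adaptation retained per step, in (0, 1].
#' @param fatigue_increment fatigue added at each spike (FLIF mode, >= 0).
#' @param fatigue_recovery fatigue removed per silent step (FLIF mode, >= 0).
#' @return an object of class `neuron_params`.
#' @examples
#' p <- neuron_params(membrane_decay = 0.5, threshold = 1)
#' @export
neuron_params <- function(membrane_decay = 0.5, threshold = 1, resting = 0,
                          reset = 0, refractory = 0L,
                          adapt_increment = 0, adapt_decay = 0.9,
                          fatigue_increment = 0, fatigue_recovery = 0) {
  stopifnot(membrane_decay > 0, membrane_decay <= 1,
            adapt_decay > 0, adapt_decay <= 1,
            refractory >= 0, adapt_increment >= 0,
            fatigue_increment >= 0, fatigue_recovery >= 0)
  if (threshold <= resting)
    stop("invalid neuron parameters: threshold must exceed resting level")
  structure(list(membrane_decay = membrane_decay, threshold = threshold,
                 resting = resting, reset = reset,
                 refractory = as.integer(refractory),
                 adapt_increment = adapt_increment, adapt_decay = adapt_decay,
                 fatigue_increment = fatigue_increment,
                 fatigue_recovery = fatigue_recovery),
            class = "neuron_params")
}

#' Create an empty spiking network
#'
#' A network holds populations of point neurons and projections (bundles of
#' synapses) between them, together with mutable simulation state (membrane
#' potentials, adaptation, fatigue, refractory counters, spikes in flight,
#' and the global step counter).  The object is an environment: populations
#' and projections added with [add_population()] and [add_projection()]
#' accumulate in place, in the style of a simulator handle.
#'
#' @param step_ms duration of one simulated step in milliseconds (default 1;
#'   a 10 ms mode is used for FLIF-style runs).
#' @return an object of class `cabot_network`.
#' @seealso [add_population()], [add_projection()], [run_network()]
#' @export
network <- function(step_ms = 1) {
  net <- new.env(parent = emptyenv())
  net$step_ms <- step_ms
  net$pops <- list()          # id -> list(size, offset, params, model)
  net$n <- 0L
  net$syn_pre <- integer(0)   # 0-based global indices
  net$syn_post <- integer(0)
  net$syn_w <- numeric(0)
  net$syn_d <- integer(0)
  net$syn_sign <- integer(0)  # +1 excitatory / -1 inhibitory, fixed for life
  net$projections <- list()   # name -> list(src, tgt, plasticity, w_max, idx)
  net$state <- NULL
  net$compiled <- NULL
  class(net) <- "cabot_network"
  reset_network(net)
  net
}

#' @export
print.cabot_network <- function(x, ...) {
  cat(sprintf("<cabot_network> %d populations, %d neurons, %d synapses, t = %d (step %g ms)\n",
              length(x$pops), x$n, length(x$syn_w), x$state$t, x$step_ms))
  invisible(x)
}

#' Add a population of neurons to a network
#'
#' @param net a [network()].
#' @param id unique population identifier.
#' @param size number of neurons (>= 1); indices are 1-based and dense.
#' @param params a [neuron_params()] object.
#' @param model `"lif_adapt"` or `"flif"`.
#' @return `net`, invisibly.
#' @export
add_population <- function(net, id, size, params = neuron_params(),
                           model = c("lif_adapt", "flif")) {
  model <- match.arg(model)
  if (!is.numeric(size) || size < 1)
    stop("configuration error: population size must be a positive count")
  if (id %in% names(net$pops))
    stop("configuration error: duplicate population id '", id, "'")
  if (model == "lif_adapt" &&
      (params$fatigue_increment > 0 || params$fatigue_recovery > 0))
    params$fatigue_increment <- params$fatigue_recovery <- 0
  net$pops[[id]] <- list(size = as.integer(size), offset = net$n,
                         params = params, model = model)
  net$n <- net$n + as.integer(size)
  net$compiled <- NULL
  reset_network(net)
  invisible(net)
}

#' Add a projection (bundle of synapses) between two populations
#'
#' Each synapse is a (pre, post, weight, delay) tuple.  Delays are in steps
#' and must be >= 1: a spike emitted at step t influences its targets no
#' earlier than t + delay.  The sign of each synapse is fixed for its
#' lifetime; plasticity (see [apply_plasticity()]) changes only the
#' magnitude, clipped to `[0, w_max]`.
#'
#' @param net a [network()].
#' @param name unique projection name.
#' @param src,tgt source and target population ids.
#' @param pre,post 1-based neuron indices within `src` / `tgt` (recycled).
#' @param weight signed synaptic weights (recycled).
#' @param delay conduction delays in steps, all >= 1 (recycled).
#' @param plasticity `"static"` or `"stdp_hebbian"`.
#' @param w_max bound on weight magnitude for plastic synapses.
#' @return `net`, invisibly.
#' @export
add_projection <- function(net, name, src, tgt, pre, post, weight, delay = 1L,
                           plasticity = c("static", "stdp_hebbian"),
                           w_max = Inf) {
  plasticity <- match.arg(plasticity)
  for (p in c(src, tgt)) if (!p %in% names(net$pops))
    stop("configuration error: projection endpoint '", p, "' does not exist")
  if (name %in% names(net$projections))
    stop("configuration error: duplicate projection name '", name, "'")
  m <- max(length(pre), length(post), length(weight), length(delay))
  pre <- rep_len(as.integer(pre), m); post <- rep_len(as.integer(post), m)
  weight <- rep_len(weight, m); delay <- rep_len(as.integer(delay), m)
  if (any(delay < 1)) stop("configuration error: synapse delay must be >= 1 step")
  if (any(pre < 1 | pre > net$pops[[src]]$size) ||
      any(post < 1 | post > net$pops[[tgt]]$size))
    stop("configuration error: synapse index outside population")
  idx <- length(net$syn_w) + seq_len(m)
  net$syn_pre <- c(net$syn_pre, net$pops[[src]]$offset + pre - 1L)
  net$syn_post <- c(net$syn_post, net$pops[[tgt]]$offset + post - 1L)
  net$syn_w <- c(net$syn_w, weight)
  net$syn_d <- c(net$syn_d, delay)
  net$syn_sign <- c(net$syn_sign, ifelse(weight < 0, -1L, 1L))
  net$projections[[name]] <- list(src = src, tgt = tgt,
                                  plasticity = plasticity,
                                  w_max = w_max, idx = idx)
  net$compiled <- NULL
  invisible(net)
}

#' Build a network from a structured description
#'
#' The description is a key-value tree (as read from a YAML or JSON
#' configuration file): `step_ms`, a `populations` list of
#' `(id, size, model, params)` entries, and a `projections` list of
#' `(name, src, tgt, pre, post, weight, delay, plasticity, w_max)` entries.
#' Returns a network with zeroed state: all potentials at resting, no spikes
#' in flight.
#'
#' @param spec a list as described above (for instance from
#'   [yaml::read_yaml()]).
#' @return a `cabot_network`.
#' @export
build_network <- function(spec) {
  net <- network(step_ms = spec$step_ms %||% 1)
  for (p in spec$populations) {
    pars <- if (is.null(p$params)) neuron_params() else do.call(neuron_params, p$params)
    add_population(net, p$id, p$size, pars, model = p$model %||% "lif_adapt")
  }
  for (pr in spec$projections) {
    add_projection(net, pr$name, pr$src, pr$tgt, pr$pre, pr$post, pr$weight,
                   pr$delay %||% 1L, pr$plasticity %||% "static",
                   pr$w_max %||% Inf)
  }
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reset network state
#'
#' Returns all membrane potentials to resting, clears adaptation, fatigue,
#' refractory counters and spikes in flight, and rewinds the global step
#' counter to 0.  Synaptic weights are kept.
#'
#' @param net a `cabot_network`.
#' @return `net`, invisibly.
#' @export
reset_network <- function(net) {
  par_vec <- function(field) {
    if (net$n == 0L) return(numeric(0))
    unlist(lapply(net$pops, function(p) rep(p$params[[field]], p$size)),
           use.names = FALSE)
  }
  net$state <- list(
    v = par_vec("resting"), a = rep(0, net$n), f = rep(0, net$n),
    r = rep(0L, net$n), t = 0L,
    pending = matrix(numeric(0), ncol = 3))
  invisible(net)
}

# Per-neuron parameter vectors and the CSR synapse layout, cached until the
# topology changes.  Weights are copied out of net$syn_w on every run so that
# plasticity updates take effect without recompiling.
compile_network <- function(net) {
  if (!is.null(net$compiled)) return(net$compiled)
  pv <- function(field) unlist(lapply(net$pops, function(p)
    rep(p$params[[field]], p$size)), use.names = FALSE)
  ord <- order(net$syn_pre)
  counts <- tabulate(net$syn_pre + 1L, nbins = max(net$n, 1L))
  sizes <- vapply(net$pops, `[[`, integer(1), "size")
  net$compiled <- list(
    decay = pv("membrane_decay"), thr = pv("threshold"),
    resting = pv("resting"), reset = pv("reset"),
    refrac = as.integer(pv("refractory")),
    adapt_inc = pv("adapt_increment"), adapt_dec = pv("adapt_decay"),
    fat_inc = pv("fatigue_increment"), fat_rec = pv("fatigue_recovery"),
    ord = ord,
    syn_ptr = c(0L, cumsum(counts)),
    syn_post = net$syn_post[ord],
    syn_d = net$syn_d[ord],
    max_delay = max(1L, net$syn_d, 1L),
    pop_of = rep(names(net$pops), sizes),        # per-neuron lookup tables
    loc_of = unlist(lapply(sizes, seq_len), use.names = FALSE),
    w_ord = net$syn_w[ord], w_dirty = FALSE)
  net$compiled
}

# plasticity and direct weight edits invalidate the ordered-weight cache
touch_weights <- function(net) {
  if (!is.null(net$compiled)) net$compiled$w_dirty <- TRUE
  invisible(net)
}

# global 0-based neuron index for (population, 1-based local index)
neuron_index <- function(net, pop, idx) {
  p <- net$pops[[pop]]
  if (is.null(p)) stop("input error: unknown population '", pop, "'")
  if (any(idx < 1 | idx > p$size))
    stop("input error: neuron index outside population '", pop, "'")
  p$offset + as.integer(idx) - 1L
}

# population id for a vector of global 0-based indices
population_of <- function(net, gidx) {
  offs <- vapply(net$pops, `[[`, integer(1), "offset")
  sizes <- vapply(net$pops, `[[`, integer(1), "size")
  ids <- names(net$pops)
  out <- character(length(gidx))
  for (k in seq_along(ids))
    out[gidx >= offs[k] & gidx < offs[k] + sizes[k]] <- ids[k]
  out
}

#' Run a network for a number of steps
#'
#' Advances the network `steps` steps from its current state.  The run is
#' deterministic given the network state and the injection schedule; any
#' seeded randomness elsewhere in the package is folded into the schedule
#' before this function is called.  Spikes emitted at step t reach their
#' targets no earlier than t + delay, refractory neurons cannot fire, and
#' adaptation/fatigue accumulate on firing and decay/recover otherwise.
#'
#' @param net a `cabot_network`.
#' @param steps number of steps to simulate (>= 1).
#' @param inputs `NULL`, or a data frame with columns `step` (1..steps,
#'   relative to this call), `population`, `neuron` (1-based) and `value`
#'   (activation injected at that step).
#' @param seed optional integer; recorded for provenance.  The core update
#'   itself contains no randomness.
#' @return a spike record: data frame with columns `step` (global step
#'   index), `population` and `neuron`, ordered by step, with attribute
#'   `t_end` giving the global step at the end of the run.
#' @export
run_network <- function(net, steps, inputs = NULL, seed = NULL) {
  if (steps < 1) stop("input error: steps must be >= 1")
  sched <- NULL
  if (!is.null(inputs) && nrow(inputs)) {
    if (any(inputs$step < 1 | inputs$step > steps))
      stop("input error: schedule step outside 1..steps")
    gidx <- integer(nrow(inputs))
    for (pop in unique(inputs$population)) {
      sel <- inputs$population == pop
      gidx[sel] <- neuron_index(net, pop, inputs$neuron[sel])
    }
    sched <- cbind(step = as.integer(inputs$step), idx = gidx,
                   val = inputs$value)
  }
  rec <- run_raw(net, steps, sched)
  spike_record(net, rec)
}

# Low-level run: schedule as a matrix with columns (step, idx [0-based
# global], val).  Returns list(step, idx) with global steps; updates state.
run_raw <- function(net, steps, sched = NULL) {
  cmp <- compile_network(net)
  st <- net$state
  if (is.null(sched) || nrow(sched) == 0) {
    in_step <- integer(0); in_idx <- integer(0); in_val <- numeric(0)
  } else {
    o <- order(sched[, 1])
    in_step <- as.integer(sched[o, 1]); in_idx <- as.integer(sched[o, 2])
    in_val <- as.numeric(sched[o, 3])
  }
  if (cmp$w_dirty) {
    cmp$w_ord <- net$syn_w[cmp$ord]
    cmp$w_dirty <- FALSE
    net$compiled <- cmp
  }
  res <- run_core(as.integer(steps),
                  cmp$decay, cmp$thr, cmp$resting, cmp$reset, cmp$refrac,
                  cmp$adapt_inc, cmp$adapt_dec, cmp$fat_inc, cmp$fat_rec,
                  cmp$syn_ptr, cmp$syn_post, cmp$w_ord,
                  cmp$syn_d, st$v, st$a, st$f, st$r, st$pending,
                  in_step, in_idx, in_val, st$t, cmp$max_delay)
  net$state <- list(v = res$v, a = res$a, f = res$f, r = res$r,
                    t = st$t + as.integer(steps), pending = res$pending)
  list(step = res$spike_step, idx = res$spike_idx, t_end = net$state$t)
}

# Format a raw spike list as the public spike record data frame.
spike_record <- function(net, rec) {
  cmp <- compile_network(net)
  out <- data.frame(step = rec$step, population = cmp$pop_of[rec$idx + 1L],
                    neuron = cmp$loc_of[rec$idx + 1L],
                    stringsAsFactors = FALSE)
  attr(out, "t_end") <- rec$t_end
  out
}

#' Write / read a spike record as TSV
#'
#' The on-disk format is tab-separated with a `step<TAB>population<TAB>neuron`
#' header.
#'
#' @param record a spike record from [run_network()].
#' @param path file path.
#' @return `write_spikes` returns `path` invisibly; `read_spikes` returns the
#'   record.
#' @export
write_spikes <- function(record, path) {
  utils::write.table(record[, c("step", "population", "neuron")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Derive a module seed from a base seed
#'
#' Every source of randomness in the package draws from a stream seeded by
#' the run's base seed combined with a stable name, so that sub-modules get
#' independent but reproducible streams.  The derivation is a polynomial
#' string hash folded into the positive 32-bit integer range.
#'
#' @param base integer base seed.
#' @param name character scalar naming the stream.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(base, name) {
  h <- as.double(base %% 2147483647)
  for (c in utf8ToInt(name)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}
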