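#' STDP parameters
#'
#' Exponential spike-timing-dependent plasticity kernel with additive
#' updates.  A presynaptic spike followed by a postsynaptic spike at lag
#' `dt > 0` steps potentiates by `a_plus * exp(-dt / tau_plus)`; the reverse
#' order depresses by `a_minus * exp(-dt / tau_minus)`.  Simultaneous spikes
#' contribute nothing.  The asymmetry `a_plus > a_minus` makes sustained
#' co-firing (pairings at both signs of lag) net potentiating, which is what
#' binds co-ignited assemblies.
#'
#' @param a_plus,a_minus potentiation / depression amplitudes per pairing.
#' @param tau_plus,tau_minus kernel time constants in steps.
#' @param cutoff pairings with |lag| beyond this are ignored.
#' @return a list of class `stdp_params`.
#' @export
stdp_params <- function(a_plus = 0.02, a_minus = 0.01,
                        tau_plus = 10, tau_minus = 10,
                        cutoff = 50) {
  structure(list(a_plus = a_plus, a_minus = a_minus, tau_plus = tau_plus,
                 tau_minus = tau_minus, cutoff = cutoff),
            class = "stdp_params")
}

#' STDP kernel function
#'
#' Weight change contributed by a single pre/post pairing at lag
#' `dt = t_post - t_pre` (steps).
#'
#' @param dt lag(s) in steps, positive when the presynaptic spike leads.
#' @param params an [stdp_params()] object.
#' @return weight change(s), same length as `dt`.
#' @export
stdp_kernel <- function(dt, params = stdp_params()) {
  out <- numeric(length(dt))
  pos <- dt > 0 & dt <= params$cutoff
  neg <- dt < 0 & -dt <= params$cutoff
  out[pos] <- params$a_plus * exp(-dt[pos] / params$tau_plus)
  out[neg] <- -params$a_minus * exp(dt[neg] / params$tau_minus)
  out
}

#' Apply spike-timing-dependent plasticity to a projection
#'
#' Updates the weights of a plastic projection from the spike records of its
#' source and target populations, using the all-pairs exponential kernel of
#' [stdp_kernel()].  Weight magnitudes are clipped to `[0, w_max]` and the
#' sign of every synapse is preserved.
#'
#' @param net a `cabot_network`.
#' @param projection name of a projection with `plasticity = "stdp_hebbian"`.
#' @param pre_spikes,post_spikes spike records (see [run_network()]) holding
#'   the source / target population activity to pair.  Only rows belonging
#'   to the projection's endpoint populations are used.
#' @param params an [stdp_params()] object.
#' @return invisibly, the updated weight vector of the projection.
#' @export
apply_plasticity <- function(net, projection, pre_spikes, post_spikes,
                             params = stdp_params()) {
  pr <- net$projections[[projection]]
  if (is.null(pr)) stop("unknown projection '", projection, "'")
  if (pr$plasticity != "stdp_hebbian")
    stop("usage error: apply_plasticity called on a static projection")
  pre_t <- split(pre_spikes$step[pre_spikes$population == pr$src],
                 pre_spikes$neuron[pre_spikes$population == pr$src])
  post_t <- split(post_spikes$step[post_spikes$population == pr$tgt],
                  post_spikes$neuron[post_spikes$population == pr$tgt])
  off_src <- net$pops[[pr$src]]$offset
  off_tgt <- net$pops[[pr$tgt]]$offset
  idx <- pr$idx
  w <- net$syn_w[idx]
  sgn <- net$syn_sign[idx]
  pre_loc <- as.character(net$syn_pre[idx] - off_src + 1L)
  post_loc <- as.character(net$syn_post[idx] - off_tgt + 1L)
  for (k in seq_along(idx)) {
    tp <- pre_t[[pre_loc[k]]]
    tq <- post_t[[post_loc[k]]]
    if (is.null(tp) || is.null(tq)) next
    dt <- outer(tq, tp, `-`)             # t_post - t_pre
    dw <- sum(stdp_kernel(as.vector(dt), params))
    mag <- abs(w[k]) + dw
    mag <- min(max(mag, 0), pr$w_max)
    w[k] <- sgn[k] * mag
  }
  net$syn_w[idx] <- w
  touch_weights(net)
  invisible(w)
}

#' Mean learned weight between two assemblies
#'
#' Convenience readout: the mean absolute weight of the synapses of a
#' projection restricted to given pre/post neuron index sets (1-based within
#' the endpoint populations).  Used for recall-threshold checks on the
#' cognitive map and for rule-network policy readout.
#'
#' @param net a `cabot_network`.
#' @param projection projection name.
#' @param pre,post optional index sets; `NULL` means all.
#' @return mean |weight| over the selected synapses.
#' @export
projection_weight <- function(net, projection, pre = NULL, post = NULL) {
  pr <- net$projections[[projection]]
  if (is.null(pr)) stop("unknown projection '", projection, "'")
  idx <- pr$idx
  keep <- rep(TRUE, length(idx))
  if (!is.null(pre))
    keep <- keep & (net$syn_pre[idx] - net$pops[[pr$src]]$offset + 1L) %in% pre
  if (!is.null(post))
    keep <- keep & (net$syn_post[idx] - net$pops[[pr$tgt]]$offset + 1L) %in% post
  mean(abs(net$syn_w[idx][keep]))
}
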