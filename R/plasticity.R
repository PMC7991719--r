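#' STDP parameters
#'
#' Constants of the exponential spike-timing-dependent plasticity window:
#' a causal pair (pre before post) potentiates by `a_plus * exp(dt/tau_plus)`
#' and an anti-causal pair depresses by `a_minus * exp(-dt/tau_minus)`, where
#' `dt = t_pre - t_post` (negative for causal order). Plastic weights are
#' clipped to `[w_min, w_max]`.
#'
#' @param a_plus,a_minus Potentiation / depression amplitudes (> 0).
#' @param tau_plus,tau_minus Time constants in ms (> 0).
#' @param w_min,w_max Weight bounds, `w_min <= w_max`.
#' @return An object of class `stdp_params`.
#' @export
stdp_params <- function(a_plus = 0.1, a_minus = 0.12,
                        tau_plus = 20, tau_minus = 20,
                        w_min = 0, w_max = 10) {
  stopifnot(a_plus > 0, a_minus > 0, tau_plus > 0, tau_minus > 0,
            w_min <= w_max)
  structure(list(a_plus = a_plus, a_minus = a_minus, tau_plus = tau_plus,
                 tau_minus = tau_minus, w_min = w_min, w_max = w_max),
            class = "stdp_params")
}

stdp_params_from_config <- function(cfg) {
  stdp_params(cfg$a_plus, cfg$a_minus, cfg$tau_plus, cfg$tau_minus,
              w_min = 0, w_max = cfg$w_max)
}

#' STDP weight change for a single spike-time difference
#'
#' @param delta_t `t_pre - t_post` in ms; vectorized. Negative values (pre
#'   before post) potentiate, positive values depress, and exactly zero maps
#'   to zero by convention.
#' @param params An [stdp_params()] object.
#' @return Weight change(s), same length as `delta_t`.
#' @examples
#' stdp_delta(-10, stdp_params())  #  0.1 * exp(-0.5)
#' stdp_delta(10, stdp_params())   # -0.12 * exp(-0.5)
#' @export
stdp_delta <- function(delta_t, params = stdp_params()) {
  out <- numeric(length(delta_t))
  neg <- delta_t < 0
  pos <- delta_t > 0
  out[neg] <- params$a_plus * exp(delta_t[neg] / params$tau_plus)
  out[pos] <- -params$a_minus * exp(-delta_t[pos] / params$tau_minus)
  out
}

# nearest-neighbour pairing: each post spike pairs with its nearest pre
# spike and vice versa; the dendritic delay shifts post spike times so that
# coincident somatic firing is causal at the synapse
stdp_pair_sum <- function(pre_times, post_times, params, dendritic_delay = 0) {
  if (!length(pre_times) || !length(post_times)) return(0)
  nearest <- function(x, ref) ref[vapply(x, function(t)
    which.min(abs(ref - t)), integer(1))]
  post_shift <- post_times + dendritic_delay
  d1 <- nearest(post_times, pre_times) - post_shift          # per post spike
  d2 <- pre_times - (nearest(pre_times, post_times) + dendritic_delay)
  sum(stdp_delta(c(d1, d2), params))
}

#' Create an empty synapse store
#'
#' A mutable sparse registry of weighted, delayed, signed connections
#' between neuron addresses, held as a keyed [data.table::data.table] inside
#' an environment (so that learning functions can update it in place). At
#' most one synapse exists per ordered `(pre, post)` pair. Excitatory
#' synapses are plastic with weights in `[w_min, w_max]` and integer slot
#' delays; inhibitory synapses carry a fixed weight and zero delay.
#'
#' @return An object of class `synapse_store`.
#' @export
synapse_store <- function() {
  e <- new.env(parent = emptyenv())
  e$tab <- data.table::data.table(
    pre = character(0), post = character(0), weight = numeric(0),
    delay_slots = integer(0), sign = character(0), plastic = logical(0))
  data.table::setkeyv(e$tab, c("pre", "post"))
  class(e) <- "synapse_store"
  e
}

#' @export
print.synapse_store <- function(x, ...) {
  tab <- x$tab
  cat(sprintf("<synapse_store> %d synapses (%d excitatory, %d inhibitory)\n",
              nrow(tab), sum(tab$sign == "exc"), sum(tab$sign == "inh")))
  invisible(x)
}

#' Extract the synapse table
#'
#' @param store A [synapse_store()].
#' @return A `data.frame` with columns `pre`, `post`, `weight`,
#'   `delay_slots`, `sign`, `plastic`, ordered by `(pre, post)`.
#' @export
synapse_table <- function(store) {
  as.data.frame(data.table::copy(store$tab))
}

#' Ensure a synapse exists
#'
#' Idempotent creation: a missing excitatory synapse is created at weight
#' zero (excitatory weights start from nothing and are built up by STDP);
#' a missing inhibitory synapse is created at the supplied fixed weight and
#' marked non-plastic. An existing synapse is left untouched.
#'
#' @param store A [synapse_store()]; modified in place.
#' @param pre,post Neuron addresses (must differ).
#' @param sign `"exc"` or `"inh"`.
#' @param delay_slots Transmission delay in note-slot units (inhibitory
#'   synapses must have zero delay).
#' @param weight Initial weight; only used for inhibitory synapses
#'   (excitatory synapses always start at 0).
#' @return The store, invisibly.
#' @export
ensure_synapse <- function(store, pre, post, sign = c("exc", "inh"),
                           delay_slots = 0L, weight = 0) {
  sign <- match.arg(sign)
  if (identical(pre, post)) stop("self-loop synapse requested", call. = FALSE)
  if (sign == "inh" && delay_slots != 0) {
    stop("inhibitory synapses have no transmission delay", call. = FALSE)
  }
  if (delay_slots < 0) stop("negative delay", call. = FALSE)
  tab <- store$tab
  if (!any(tab$pre == pre & tab$post == post)) {
    new <- data.table::data.table(
      pre = pre, post = post,
      weight = if (sign == "exc") 0 else weight,
      delay_slots = as.integer(delay_slots), sign = sign,
      plastic = sign == "exc")
    store$tab <- data.table::rbindlist(list(tab, new))
    data.table::setkeyv(store$tab, c("pre", "post"))
  }
  invisible(store)
}

# non-plastic synapse at a fixed weight (interneuron wiring); idempotent
fixed_synapse <- function(store, pre, post, sign, weight) {
  if (identical(pre, post)) stop("self-loop synapse requested", call. = FALSE)
  tab <- store$tab
  if (!any(tab$pre == pre & tab$post == post)) {
    new <- data.table::data.table(
      pre = pre, post = post, weight = weight, delay_slots = 0L,
      sign = sign, plastic = FALSE)
    store$tab <- data.table::rbindlist(list(tab, new))
    data.table::setkeyv(store$tab, c("pre", "post"))
  }
  invisible(store)
}

#' Apply STDP updates to plastic synapses
#'
#' For every plastic synapse whose presynaptic and postsynaptic neurons both
#' appear in the supplied rasters, spike pairs are formed by nearest
#' neighbours (each post spike with its nearest pre spike and vice versa),
#' the exponential window [stdp_delta()] is summed over the pairs, and the
#' weight is clipped to `[w_min, w_max]`. Postsynaptic spike times are
#' shifted by the small dendritic delay before the comparison, so that
#' exactly coincident pre/post firing reads as causal at the synapse.
#'
#' @param store A [synapse_store()]; modified in place.
#' @param pre_spikes,post_spikes `sm_raster` objects (or bare named lists of
#'   spike-time vectors) covering the same window.
#' @param params An [stdp_params()] object.
#' @param dendritic_delay Dendritic latency in ms (>= 0).
#' @return The store, invisibly.
#' @export
apply_stdp <- function(store, pre_spikes, post_spikes,
                       params = stdp_params(), dendritic_delay = 2) {
  pre_t <- if (inherits(pre_spikes, "sm_raster")) pre_spikes$times else pre_spikes
  post_t <- if (inherits(post_spikes, "sm_raster")) post_spikes$times else post_spikes
  tab <- store$tab
  idx <- which(tab$plastic & tab$pre %in% names(pre_t) &
                 tab$post %in% names(post_t))
  for (i in idx) {
    dw <- stdp_pair_sum(pre_t[[tab$pre[i]]], post_t[[tab$post[i]]],
                        params, dendritic_delay)
    if (dw != 0) {
      w <- min(max(tab$weight[i] + dw, params$w_min), params$w_max)
      data.table::set(store$tab, i, "weight", w)
    }
  }
  invisible(store)
}

#' Slot-resolved synaptic input to one neuron
#'
#' Sums `weight * spike-indicator` over the incoming synapses of `post`.
#' An excitatory synapse with delay `d` reads the presynaptic activity
#' registered `d` slots ago (slot-valued transmission delay); inhibitory
#' synapses act within the current slot and contribute negatively. Slots
#' before the start of history contribute nothing, so delivery is causal.
#'
#' @param store A [synapse_store()].
#' @param post Postsynaptic neuron address.
#' @param slot_history List indexed by slot; each element is a character
#'   vector of addresses that fired in that slot.
#' @param current_slot Index of the slot being evaluated (>= 1).
#' @return Total delivered drive (scalar; positive drives excite).
#' @export
delivered_input <- function(store, post, slot_history, current_slot) {
  stopifnot(current_slot >= 1)
  tab <- store$tab
  inc <- as.data.frame(tab)[tab$post == post, , drop = FALSE]
  if (nrow(inc) == 0) return(0)
  total <- 0
  for (i in seq_len(nrow(inc))) {
    if (inc$sign[i] == "exc") {
      slot <- current_slot - inc$delay_slots[i]
      if (slot >= 1 && slot <= length(slot_history) &&
          inc$pre[i] %in% slot_history[[slot]]) {
        total <- total + inc$weight[i]
      }
    } else {
      if (current_slot <= length(slot_history) &&
          inc$pre[i] %in% slot_history[[current_slot]]) {
        total <- total - inc$weight[i]
      }
    }
  }
  total
}
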