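#' Simulation configuration
#'
#' @param dt Time step, ms.
#' @param duration Total simulated time, ms.
#' @param method `"backward_euler"` (default) or `"crank_nicolson"`.
#' @param v_init Initial voltage, mV.
#' @param spike_threshold Upward-crossing threshold for spike detection, mV.
#' @param refractory Minimum separation between detected spikes, ms.
#' @param seed Optional integer seed recorded with the config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(dt = 0.025, duration = 500,
                       method = c("backward_euler", "crank_nicolson"),
                       v_init = -85, spike_threshold = -10, refractory = 2,
                       seed = NULL) {
  method <- match.arg(method)
  if (dt <= 0) abort("dt must be > 0")
  if (duration < dt) abort("duration must be >= dt")
  structure(list(dt = dt, duration = duration, method = method,
                 v_init = v_init, spike_threshold = spike_threshold,
                 refractory = refractory, seed = seed), class = "sim_config")
}

#' Uniformly sampled trace
#'
#' @param values Numeric samples.
#' @param dt Sample interval, ms.
#' @param t0 Time of the first sample, ms.
#' @param unit `"mV"`, `"pA"` or `"uS"`.
#' @return A tibble of class `msn_trace` with columns `t` and `value`.
#' @export
trace <- function(values, dt, t0 = 0, unit = c("mV", "pA", "uS")) {
  unit <- match.arg(unit)
  if (any(!is.finite(values))) abort("trace values must be finite")
  new_tibble(tibble(t = t0 + dt * (seq_along(values) - 1), value = as.numeric(values)),
             dt = dt, unit = unit, class = "msn_trace")
}

#' @method autoplot msn_trace
#' @export
autoplot.msn_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)",
                  y = paste0("value (", attr(object, "unit") %||% "", ")")) +
    ggplot2::theme_minimal()
}

# frustum lateral area in cm^2 from um inputs
frustum_area_cm2 <- function(len_um, r0_um, r1_um) {
  pi * (r0_um + r1_um) * sqrt(len_um^2 + (r0_um - r1_um)^2) * 1e-8
}

#' Discretize a morphology into a branched cable model
#'
#' Splits every inter-node segment into compartments no longer than
#' `max_seg_length_um`, computes frustum membrane areas (the soma is treated
#' as an equivalent-area cylinder of length and diameter `2 r`), attaches
#' leak, capacitance and voltage-gated channels per the spec's placement
#' rules, and computes axial coupling conductances from the axial
#' resistivity. If sodium channels are requested and the morphology has no
#' axon, the standard 50 um x 0.5 um axon initial segment is appended to the
#' soma (with a message).
#'
#' @param m A morphology.
#' @param spec A model spec as returned by [default_model_spec()].
#' @param max_seg_length_um Maximum compartment length, um.
#' @return A list of class `cable_model` with elements `comps` (tibble),
#'   `channels`, `synapses` (initially empty), `passive`, and `spec`.
#' @export
discretize <- function(m, spec = default_model_spec(), max_seg_length_um = 20) {
  validate_morphology(m)
  pas <- spec$passive
  needs_axon <- any(vapply(spec$channels, function(ch)
    ch$region == "axon_initial_segment" && ch$gbar > 0, logical(1)))
  if (needs_axon && !any(m$node_kind == "axon")) {
    message("appending 50 um x 0.5 um axon initial segment to the soma")
    soma_id <- m$id[m$parent_id == -1L][1]
    s <- m[m$id == soma_id, ]
    n_ais <- 5L
    ais <- tibble(
      id = max(m$id) + seq_len(n_ais),
      parent_id = c(soma_id, max(m$id) + seq_len(n_ais - 1L)),
      node_kind = "axon",
      x = s$x - 10 * seq_len(n_ais),
      y = s$y, z = s$z, radius = 0.25)
    m <- morphology(dplyr::bind_rows(as_tibble(m), ais),
                    label = attr(m, "label") %||% "",
                    provenance = attr(m, "provenance") %||% "synthetic")
  }

  root <- which(m$parent_id == -1L)
  root_r <- m$radius[root]
  # compartment accumulators
  comp_parent <- integer(0); comp_len <- numeric(0); comp_diam <- numeric(0)
  comp_area <- numeric(0); comp_kind <- character(0)
  add_comp <- function(parent, len, diam, area, kind) {
    comp_parent[[length(comp_parent) + 1]] <<- parent
    comp_len[[length(comp_len) + 1]] <<- len
    comp_diam[[length(comp_diam) + 1]] <<- diam
    comp_area[[length(comp_area) + 1]] <<- area
    comp_kind[[length(comp_kind) + 1]] <<- kind
    length(comp_parent)
  }
  # soma compartment: sphere area 4 pi r^2 == cylinder of L = d = 2r
  add_comp(0L, 2 * root_r, 2 * root_r, 4 * pi * root_r^2 * 1e-8, "soma")
  node_comp <- setNames(rep(1L, nrow(m)), m$id)  # node id -> containing comp

  non_root <- which(m$parent_id != -1L)
  for (i in non_root) {
    kind <- m$node_kind[i]
    pid <- m$parent_id[i]
    p <- match(pid, m$id)
    if (kind == "soma") { node_comp[as.character(m$id[i])] <- 1L; next }
    len <- sqrt((m$x[i] - m$x[p])^2 + (m$y[i] - m$y[p])^2 + (m$z[i] - m$z[p])^2)
    if (len <= 0) { node_comp[as.character(m$id[i])] <- node_comp[as.character(pid)]; next }
    k <- max(1L, ceiling(len / max_seg_length_um))
    sub_len <- len / k
    r_from <- if (m$node_kind[p] == "soma") m$radius[i] else m$radius[p]
    r_to <- m$radius[i]
    parent_comp <- node_comp[[as.character(pid)]]
    for (s in seq_len(k)) {
      ra <- r_from + (r_to - r_from) * (s - 1) / k
      rb <- r_from + (r_to - r_from) * s / k
      parent_comp <- add_comp(parent_comp, sub_len, ra + rb,
                              frustum_area_cm2(sub_len, ra, rb), kind)
    }
    node_comp[as.character(m$id[i])] <- parent_comp
  }

  n <- length(comp_parent)
  # axial coupling conductance (uS) between each comp and its parent:
  # series half-cylinder resistances, Ra in Ohm cm, lengths/radii in um
  g_ax <- numeric(n)
  for (i in seq_len(n)[-1]) {
    p <- comp_parent[i]
    half_r <- function(idx) {
      r_um <- comp_diam[idx] / 2
      pas$axial_resistivity * (comp_len[idx] * 1e-4 / 2) / (pi * (r_um * 1e-4)^2)
    }
    g_ax[i] <- 1 / (half_r(i) + half_r(p)) * 1e6
  }

  comps <- tibble(
    parent = comp_parent, kind = comp_kind, length = comp_len,
    diam = comp_diam, area_cm2 = comp_area,
    cap_nF = pas$membrane_capacitance * comp_area * 1e3,
    g_leak_uS = pas$leak_conductance * comp_area * 1e6,
    e_leak = pas$leak_reversal, g_axial_uS = g_ax
  )
  channels <- lapply(spec$channels, function(ch) {
    in_region <- if (ch$region == "axon_initial_segment") comps$kind == "axon"
                 else comps$kind %in% c("soma", "dendrite")
    list(name = ch$name, e_rev = ch$reversal,
         gbar_uS = ifelse(in_region, ch$gbar * comps$area_cm2 * 1e6, 0),
         gates = lapply(ch$gates, function(g) unlist(g[c(
           "exponent", "vhalf", "k", "tau_min", "tau_amp",
           "tau_vhalf", "tau_k1", "tau_k2")], use.names = FALSE)))
  })
  structure(list(comps = comps, channels = channels, synapses = list(),
                 passive = pas, spec = spec),
            class = "cable_model")
}

#' @export
print.cable_model <- function(x, ...) {
  cat(sprintf("<cable_model> %d compartments (%d soma, %d dendrite, %d axon), %d synapses\n",
              nrow(x$comps), sum(x$comps$kind == "soma"),
              sum(x$comps$kind == "dendrite"), sum(x$comps$kind == "axon"),
              length(x$synapses)))
  invisible(x)
}

#' Draw random synapse locations on the dendrites
#'
#' Locations are drawn uniformly per unit dendritic length (compartments are
#' sampled with probability proportional to their length), deterministically
#' for a given seed.
#'
#' @param model A `cable_model`.
#' @param n Number of synapses.
#' @param rng_seed Integer seed.
#' @return Integer vector of compartment indices (1-based), length `n`.
#' @export
place_synapses <- function(model, n, rng_seed = 1) {
  if (n < 0) abort("n must be >= 0")
  dend <- which(model$comps$kind == "dendrite")
  if (length(dend) == 0 || sum(model$comps$length[dend]) <= 0) {
    abort("model has no dendritic cable to place synapses on")
  }
  if (n == 0) return(integer(0))
  with_preserved_seed({
    set.seed(as.integer(rng_seed))
    sample(dend, n, replace = TRUE, prob = model$comps$length[dend])
  })
}

#' Attach synapses with event times to a cable model
#'
#' @param model A `cable_model`.
#' @param spec A `synapse_spec`.
#' @param comp Integer compartment indices (1-based), one per synapse.
#' @param events A list of numeric event-time vectors (ms), one per synapse,
#'   or a single numeric vector recycled to all synapses.
#' @return The model with the synapses appended.
#' @export
attach_synapses <- function(model, spec, comp, events) {
  stopifnot(inherits(spec, "synapse_spec"))
  if (!is.list(events)) events <- rep(list(events), length(comp))
  if (length(events) != length(comp)) abort("need one event vector per synapse")
  add <- map2(comp, events, function(cm, ev) {
    if (cm < 1 || cm > nrow(model$comps)) abort("synapse compartment out of range")
    list(comp = as.integer(cm), spec = spec, events = as.numeric(ev))
  })
  model$synapses <- c(model$synapses, add)
  model
}

#' Integrate a cable model
#'
#' Advances the membrane equations with an implicit theta-method (backward
#' Euler, or Crank-Nicolson when the config requests it), solving the
#' branched system by ordered elimination on the tree at every step. Gating
#' variables advance by exponential (Rush-Larsen) updates between voltage
#' solves. Identical inputs produce bitwise-identical traces.
#'
#' @param model A `cable_model` (synapses already attached, if any).
#' @param config A `sim_config`.
#' @param stimuli Optional data frame of current steps with columns `site`
#'   (compartment index), `amplitude_pA`, `onset_ms`, `duration_ms`.
#' @param record Compartment indices to record, or `"soma"` (compartment 1).
#' @param clamp If `TRUE`, hold the somatic voltage at `v_hold` and record
#'   the clamp current.
#' @param v_hold Holding potential for the clamp, mV.
#' @param check_residual If `TRUE`, also return the maximum absolute residual
#'   of the per-step linear systems (axial current conservation check).
#' @return A list with one voltage `trace` per recorded site (named
#'   `site_<i>`, the soma first), plus `clamp_current` (a pA trace) when
#'   clamping, and `max_residual` when requested.
#' @export
integrate_model <- function(model, config, stimuli = NULL, record = "soma",
                            clamp = FALSE, v_hold = -70,
                            check_residual = FALSE) {
  stopifnot(inherits(model, "cable_model"), inherits(config, "sim_config"))
  if (identical(record, "soma")) record <- 1L
  record <- as.integer(record)
  n_comp <- nrow(model$comps)
  if (any(record < 1 | record > n_comp)) abort("record sites out of range")

  if (is.null(stimuli) || nrow(stimuli) == 0) {
    stim_mat <- matrix(numeric(0), ncol = 4)
  } else {
    stim_mat <- cbind(as.integer(stimuli$site) - 1L,
                      stimuli$amplitude_pA / 1000,  # pA -> nA
                      stimuli$onset_ms, stimuli$duration_ms)
  }
  if (length(model$synapses) > 0) {
    syn_mat <- t(vapply(model$synapses, function(s) c(
      s$comp - 1L, s$spec$reversal, s$spec$gpeak, s$spec$tau_rise,
      s$spec$tau_decay, as.numeric(isTRUE(s$spec$mg_block)),
      s$spec$mg_concentration), numeric(7)))
    syn_events <- lapply(model$synapses, `[[`, "events")
  } else {
    syn_mat <- matrix(numeric(0), ncol = 7)
    syn_events <- list()
  }
  theta <- if (config$method == "crank_nicolson") 0.5 else 1.0
  res <- .run_cable_cpp(
    parent = model$comps$parent - 1L, cap_nF = model$comps$cap_nF,
    g_leak_uS = model$comps$g_leak_uS, e_leak = model$comps$e_leak,
    g_axial_uS = model$comps$g_axial_uS, channels = unname(model$channels),
    synapses = syn_mat, syn_events = syn_events, stimuli = stim_mat,
    dt = config$dt, duration = config$duration, v_init = config$v_init,
    record = record - 1L, clamp = clamp, v_hold = v_hold,
    record_current = clamp, check_residual = check_residual,
    theta = theta)
  out <- setNames(
    lapply(seq_along(record), function(j)
      trace(res$voltages[, j], dt = config$dt, unit = "mV")),
    paste0("site_", record))
  if (clamp) {
    out$clamp_current <- trace(res$clamp_current * 1000, dt = config$dt,
                               unit = "pA")  # nA -> pA
  }
  if (check_residual) out$max_residual <- res$max_residual
  out
}

#' Detect spikes in a voltage trace
#'
#' Upward crossings of the threshold, separated by at least the refractory
#' interval.
#'
#' @param voltage_trace An `msn_trace` in mV (or a data frame with `t` and
#'   `value`).
#' @param threshold_mV Crossing threshold, mV.
#' @param refractory_ms Minimum inter-spike separation, ms.
#' @return Numeric vector of spike times, ms.
#' @export
detect_spikes <- function(voltage_trace, threshold_mV = -10, refractory_ms = 2) {
  v <- voltage_trace$value
  up <- which(v[-1] >= threshold_mV & v[-length(v)] < threshold_mV) + 1L
  if (length(up) == 0) return(numeric(0))
  times <- voltage_trace$t[up]
  keep <- times[1]
  for (tt in times[-1]) {
    if (tt - keep[length(keep)] >= refractory_ms) keep <- c(keep, tt)
  }
  keep
}

#' Spike recording site of a model
#'
#' Spikes initiate in the axon initial segment, whose action-potential
#' amplitude does not depend on the somatodendritic synaptic load; when the
#' model has an axon, its distal compartment is therefore the natural site
#' for spike counting. Falls back to the soma for axonless models.
#'
#' @param model A `cable_model`.
#' @return A compartment index.
#' @export
spike_record_site <- function(model) {
  ax <- which(model$comps$kind == "axon")
  if (length(ax) > 0) max(ax) else 1L
}

#' Firing rate of a voltage trace
#'
#' Spike count divided by trace duration, in Hz.
#'
#' @inheritParams detect_spikes
#' @return Firing rate, Hz.
#' @export
firing_rate <- function(voltage_trace, threshold_mV = -10, refractory_ms = 2) {
  dur_s <- (max(voltage_trace$t) - min(voltage_trace$t)) / 1000
  if (dur_s <= 0) return(0)
  length(detect_spikes(voltage_trace, threshold_mV, refractory_ms)) / dur_s
}
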