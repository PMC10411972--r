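#' Statistical model of a cell's miniature-PSC events
#'
#' Describes the event statistics used by the synthetic trace and dataset
#' generators: amplitude distribution (right-skewed lognormal by default),
#' event frequency, kinetic template, and recording noise.
#'
#' @param amplitude_mean,amplitude_sd Event amplitude mean and SD, pA.
#' @param family `"lognormal"` or `"normal"` (truncated at 0).
#' @param frequency_hz Event rate, Hz.
#' @param kinetics A `synapse_spec` providing the dual-exponential template.
#' @param noise_sd Additive Gaussian noise SD, pA.
#' @param genotype Free-text genotype tag.
#' @return A list of class `event_stat_model`.
#' @export
event_stat_model <- function(amplitude_mean = 20, amplitude_sd = 5,
                             family = c("lognormal", "normal"),
                             frequency_hz = 2,
                             kinetics = default_model_spec()$synapses$AMPA,
                             noise_sd = 1, genotype = "") {
  family <- match.arg(family)
  if (amplitude_mean <= 0) abort("amplitude_mean must be > 0")
  if (frequency_hz < 0 || noise_sd < 0) abort("frequency and noise_sd must be >= 0")
  structure(list(amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
                 family = family, frequency_hz = frequency_hz,
                 kinetics = kinetics, noise_sd = noise_sd,
                 genotype = genotype), class = "event_stat_model")
}

draw_amplitudes <- function(model, n) {
  if (n == 0) return(numeric(0))
  if (model$family == "lognormal") {
    # moment-match mu/sigma of the lognormal to the requested mean/sd
    cv2 <- (model$amplitude_sd / model$amplitude_mean)^2
    sdlog <- sqrt(log(1 + cv2))
    meanlog <- log(model$amplitude_mean) - sdlog^2 / 2
    rlnorm(n, meanlog, sdlog)
  } else {
    pmax(0.1, rnorm(n, model$amplitude_mean, model$amplitude_sd))
  }
}

#' Generate a continuous miniature-PSC trace with ground truth
#'
#' Poisson event times at the model frequency; each event is the model's
#' dual-exponential template scaled to a drawn amplitude (events sum
#' linearly); additive Gaussian noise. The generating event times and
#' amplitudes are returned alongside the trace, so downstream fitting can be
#' validated as parameter recovery.
#'
#' @param model An `event_stat_model`.
#' @param duration_ms,dt_ms Trace duration and sampling interval, ms.
#' @param seed Integer seed (deterministic output).
#' @return A list with `trace` (an `msn_trace`, pA) and `truth` (tibble of
#'   `time`, `amplitude`).
#' @export
generate_event_trace <- function(model, duration_ms = 10000, dt_ms = 0.1,
                                 seed = 1) {
  stopifnot(inherits(model, "event_stat_model"))
  with_preserved_seed({
    set.seed(as.integer(seed))
    n_ev <- rpois(1, model$frequency_hz * duration_ms / 1000)
    times <- sort(runif(n_ev, 0, duration_ms))
    amps <- draw_amplitudes(model, n_ev)
    tt <- seq(0, duration_ms, by = dt_ms)
    v <- numeric(length(tt))
    spec1 <- model$kinetics
    spec1$gpeak <- 1  # unit template; scaled per event below
    for (k in seq_len(n_ev)) {
      idx <- which(tt >= times[k])
      v[idx] <- v[idx] +
        amps[k] * synaptic_conductance_waveform(spec1, tt[idx] - times[k])
    }
    if (model$noise_sd > 0) v <- v + rnorm(length(v), 0, model$noise_sd)
    list(trace = trace(v, dt = dt_ms, unit = "pA"),
         truth = tibble(time = times, amplitude = amps))
  })
}

#' Generate a per-cell genotype dataset of event statistics
#'
#' Draws per-cell summaries (mean amplitude, event frequency, rise time,
#' 50% decay time) with between-cell lognormal variability around each
#' genotype's model, emulating the structure of per-cell miniature-PSC
#' summary tables.
#'
#' @param wt_model,ko_model `event_stat_model`s for the two groups.
#' @param n_cells_per_group Cells per genotype (>= 2).
#' @param seed Integer seed.
#' @param cell_cv Between-cell coefficient of variation (default 0.2).
#' @return A tibble with `genotype`, `cell`, `mean_amplitude`, `frequency`,
#'   `rise`, `t50`.
#' @export
generate_genotype_dataset <- function(wt_model, ko_model,
                                      n_cells_per_group = 15, seed = 1,
                                      cell_cv = 0.2) {
  if (n_cells_per_group < 2) abort("need at least 2 cells per group")
  with_preserved_seed({
    set.seed(as.integer(seed))
    one_group <- function(model, tag) {
      kin <- model$kinetics
      tpl_rise <- 0.6 * log((0.8 / 0.2) *
        (1 - 0.2 * kin$tau_rise / kin$tau_decay)) * kin$tau_rise  # rough 20-80%
      jitter <- function(mu, n) mu * exp(rnorm(n, 0, sqrt(log(1 + cell_cv^2))))
      tibble(
        genotype = tag, cell = seq_len(n_cells_per_group),
        mean_amplitude = jitter(model$amplitude_mean, n_cells_per_group),
        frequency = jitter(max(model$frequency_hz, 1e-6), n_cells_per_group),
        rise = jitter(max(tpl_rise, 0.1), n_cells_per_group),
        t50 = jitter(kin$tau_decay * log(2), n_cells_per_group))
    }
    dplyr::bind_rows(one_group(wt_model, "wt"), one_group(ko_model, "ko"))
  })
}

#' Canonical fixture morphologies
#'
#' Small deterministic morphologies with analytically known properties,
#' shared across tests and examples: a bare soma sphere, a 100 um straight
#' dendrite, a Y-shaped tree, a 4-armed star, and the two genotype presets
#' of the synthetic generator.
#'
#' @param seed Seed used for the two synthesized presets.
#' @return A named list of morphologies.
#' @export
fixture_morphologies <- function(seed = 42) {
  soma <- tibble(id = 1L, parent_id = -1L, node_kind = "soma",
                 x = 0, y = 0, z = 0, radius = 7)
  stick_nodes <- tibble(
    id = 1:11, parent_id = c(-1L, 1:10),
    node_kind = c("soma", rep("dendrite", 10)),
    x = c(0, seq(10, 100, 10)), y = 0, z = 0,
    radius = c(7, rep(0.5, 10)))
  y_nodes <- tibble(
    id = 1:16, parent_id = c(-1L, 1L, 2:5, 6L, 7:10, 6L, 12:15),
    node_kind = c("soma", rep("dendrite", 15)),
    x = c(0, seq(10, 50, 10),                       # stem along +x
          50 + seq(10, 50, 10) / sqrt(2),           # daughter 1 (+x+y)
          50 + seq(10, 50, 10) / sqrt(2)),          # daughter 2 (+x-y)
    y = c(0, rep(0, 5),
          seq(10, 50, 10) / sqrt(2),
          -seq(10, 50, 10) / sqrt(2)),
    z = 0, radius = c(7, rep(0.5, 15)))
  star_arm <- function(dx, dy, first_id) tibble(
    id = first_id + 0:7, parent_id = c(1L, first_id + 0:6),
    node_kind = "dendrite",
    x = dx * seq(10, 80, 10), y = dy * seq(10, 80, 10), z = 0, radius = 0.5)
  star_nodes <- dplyr::bind_rows(
    soma, star_arm(1, 0, 2L), star_arm(-1, 0, 10L),
    star_arm(0, 1, 18L), star_arm(0, -1, 26L))
  list(
    sphere = morphology(soma, label = "sphere"),
    stick100 = morphology(stick_nodes, label = "stick100"),
    y_tree = morphology(y_nodes, label = "y_tree"),
    star4 = morphology(star_nodes, label = "star4"),
    wt_preset = synthesize_morphology(morph_preset("wt"), seed = seed,
                                      label = "wt_preset"),
    ko_preset = synthesize_morphology(morph_preset("ko"), seed = seed,
                                      label = "ko_preset")
  )
}
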