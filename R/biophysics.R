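#' Passive membrane specification
#'
#' @param membrane_capacitance Specific capacitance, uF/cm^2.
#' @param axial_resistivity Cytoplasmic resistivity, Ohm cm.
#' @param leak_conductance Leak conductance density, S/cm^2.
#' @param leak_reversal Leak reversal potential, mV.
#' @return A list of class `passive_spec`.
#' @export
passive_spec <- function(membrane_capacitance = 1, axial_resistivity = 150,
                         leak_conductance = 6e-6, leak_reversal = -80) {
  if (membrane_capacitance <= 0 || axial_resistivity <= 0 || leak_conductance <= 0) {
    abort("capacitance, axial resistivity and leak conductance must be > 0")
  }
  structure(list(membrane_capacitance = membrane_capacitance,
                 axial_resistivity = axial_resistivity,
                 leak_conductance = leak_conductance,
                 leak_reversal = leak_reversal), class = "passive_spec")
}

#' Hodgkin-Huxley gate description
#'
#' Steady state is a Boltzmann function `1/(1 + exp(-(V - vhalf)/k))`; a
#' negative `k` yields an inactivation gate. The voltage-dependent time
#' constant is the bell
#' `tau_min + tau_amp / (exp((V - tau_vhalf)/tau_k1) + exp(-(V - tau_vhalf)/tau_k2))`,
#' which degrades to the constant `tau_min` when `tau_amp = 0`.
#'
#' @param exponent Integer power of the gate in the conductance product.
#' @param vhalf,k Boltzmann half-voltage (mV) and slope (mV).
#' @param tau_min,tau_amp,tau_vhalf,tau_k1,tau_k2 Time-constant parameters
#'   (ms, ms, mV, mV, mV).
#' @return A list of class `gate_spec`.
#' @export
gate_spec <- function(exponent, vhalf, k, tau_min, tau_amp = 0,
                      tau_vhalf = 0, tau_k1 = 10, tau_k2 = 10) {
  if (tau_min <= 0) abort("tau_min must be > 0")
  if (exponent < 0 || exponent != round(exponent)) abort("exponent must be a non-negative integer")
  structure(list(exponent = as.integer(exponent), vhalf = vhalf, k = k,
                 tau_min = tau_min, tau_amp = tau_amp, tau_vhalf = tau_vhalf,
                 tau_k1 = tau_k1, tau_k2 = tau_k2), class = "gate_spec")
}

#' Gate steady state and time constant
#'
#' @param gate A `gate_spec`.
#' @param v Voltage(s), mV.
#' @return `gate_inf`: open fraction in `[0, 1]`; `gate_tau`: ms, > 0.
#' @export
gate_inf <- function(gate, v) 1 / (1 + exp(-(v - gate$vhalf) / gate$k))

#' @rdname gate_inf
#' @export
gate_tau <- function(gate, v) {
  gate$tau_min + gate$tau_amp /
    (exp((v - gate$tau_vhalf) / gate$tau_k1) + exp(-(v - gate$tau_vhalf) / gate$tau_k2))
}

#' Voltage-gated channel specification
#'
#' @param name One of `"Na"`, `"CaV12"`, `"CaV13"`, `"KAS"`, `"KDR"`,
#'   `"KIR"`, `"KRP"`.
#' @param gbar Maximal conductance density, S/cm^2.
#' @param reversal Reversal potential, mV.
#' @param region `"axon_initial_segment"` or `"soma_and_dendrites"`.
#' @param gates List of `gate_spec`s (at most one activation and one
#'   inactivation gate are used by the solver).
#' @return A list of class `channel_spec`.
#' @export
channel_spec <- function(name, gbar, reversal, region, gates) {
  name <- match.arg(name, c("Na", "CaV12", "CaV13", "KAS", "KDR", "KIR", "KRP"))
  region <- match.arg(region, c("axon_initial_segment", "soma_and_dendrites"))
  if (gbar < 0) abort("gbar must be >= 0")
  if (name == "Na" && region != "axon_initial_segment") {
    abort("Na channels are restricted to the axon initial segment")
  }
  if (name != "Na" && region != "soma_and_dendrites") {
    abort(paste0(name, " channels are restricted to soma and dendrites"))
  }
  structure(list(name = name, gbar = gbar, reversal = reversal,
                 region = region, gates = gates), class = "channel_spec")
}

#' Synapse specification
#'
#' Dual-exponential conductance synapse. The miniature-PSC decay is
#' mono-exponential with time constant `tau_decay`; `tau_rise` gives the
#' physically required finite rise.
#'
#' @param kind `"AMPA"`, `"NMDA"` or `"GABA_A"`.
#' @param gpeak Peak conductance, uS.
#' @param tau_rise,tau_decay Rise/decay time constants, ms
#'   (`tau_decay > tau_rise > 0`).
#' @param reversal Reversal potential, mV.
#' @param mg_block Apply the voltage-dependent magnesium block (NMDA only).
#' @param mg_concentration External Mg concentration, mM.
#' @return A list of class `synapse_spec`.
#' @export
synapse_spec <- function(kind, gpeak, tau_rise, tau_decay, reversal,
                         mg_block = FALSE, mg_concentration = 1) {
  kind <- match.arg(kind, c("AMPA", "NMDA", "GABA_A"))
  if (gpeak < 0) abort("gpeak must be >= 0")
  if (!(tau_decay > tau_rise && tau_rise > 0)) {
    abort("need tau_decay > tau_rise > 0")
  }
  if (mg_block && kind != "NMDA") abort("mg_block applies to NMDA synapses only")
  structure(list(kind = kind, gpeak = gpeak, tau_rise = tau_rise,
                 tau_decay = tau_decay, reversal = reversal,
                 mg_block = mg_block, mg_concentration = mg_concentration),
            class = "synapse_spec")
}

#' Dual-exponential synaptic conductance waveform
#'
#' `g(t) = gpeak * N * (exp(-t/tau_decay) - exp(-t/tau_rise))` with the
#' normalization `N` chosen so that the maximum equals `gpeak`, reached at
#' `t* = log(tau_decay/tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)`.
#'
#' @param spec A `synapse_spec`.
#' @param t_since_onset Time(s) since synaptic onset, ms (>= 0).
#' @return Conductance in uS.
#' @export
synaptic_conductance_waveform <- function(spec, t_since_onset) {
  if (any(t_since_onset < 0)) abort("t_since_onset must be >= 0")
  tr <- spec$tau_rise; td <- spec$tau_decay
  tpeak <- log(td / tr) * tr * td / (td - tr)
  norm <- 1 / (exp(-tpeak / td) - exp(-tpeak / tr))
  spec$gpeak * norm * (exp(-t_since_onset / td) - exp(-t_since_onset / tr))
}

#' Voltage-dependent magnesium block of NMDA receptors
#'
#' Standard sigmoidal block fraction
#' `1 / (1 + mg/3.57 * exp(-0.062 V))`; 1 everywhere when `mg = 0`
#' (magnesium-free condition).
#'
#' @param voltage_mV Membrane voltage(s), mV.
#' @param mg_mM External magnesium concentration, mM (>= 0).
#' @return Unblocked fraction in `[0, 1]`.
#' @export
nmda_mg_factor <- function(voltage_mV, mg_mM) {
  if (mg_mM < 0) abort("mg_mM must be >= 0")
  1 / (1 + (mg_mM / 3.57) * exp(-0.062 * voltage_mV))
}

# Default gating parameters. The source model names the channel types and
# densities but not their rate equations; these Boltzmann/bell parameterized
# gates are stand-ins tuned so that the assembled cell shows MSN-like
# behaviour: strongly hyperpolarized rest (inward rectifier dominated),
# delayed spike onset, and a 10-80 pA operating range for sustained somatic
# current injections. They are data, not code: pass custom `channels` to
# `build_cable_model()` to replace them.
default_gates <- function(name) {
  switch(name,
    Na = list(
      gate_spec(3, vhalf = -33, k = 6, tau_min = 0.03, tau_amp = 0.12,
                tau_vhalf = -38, tau_k1 = 12, tau_k2 = 12),
      gate_spec(1, vhalf = -57, k = -4, tau_min = 1.0, tau_amp = 5,
                tau_vhalf = -55, tau_k1 = 12, tau_k2 = 12)
    ),
    KDR = list(
      gate_spec(2, vhalf = -22, k = 8, tau_min = 1.8, tau_amp = 8,
                tau_vhalf = -30, tau_k1 = 20, tau_k2 = 20)
    ),
    KIR = list(
      gate_spec(1, vhalf = -88, k = -10, tau_min = 1)
    ),
    KAS = list(
      gate_spec(2, vhalf = -27, k = 16, tau_min = 2, tau_amp = 15,
                tau_vhalf = -40, tau_k1 = 20, tau_k2 = 20),
      gate_spec(1, vhalf = -60, k = -16, tau_min = 250)
    ),
    KRP = list(
      gate_spec(1, vhalf = -45, k = 5, tau_min = 15)
    ),
    CaV12 = list(
      gate_spec(2, vhalf = -9, k = 6.7, tau_min = 1)
    ),
    CaV13 = list(
      gate_spec(1, vhalf = -33, k = 6.7, tau_min = 1),
      gate_spec(1, vhalf = -50, k = -7, tau_min = 60)
    ),
    abort(paste0("no default gates for channel ", name))
  )
}

#' Default D1-MSN model specification
#'
#' Returns the passive spec, the seven voltage-gated channel populations at
#' their model densities (Na 2.4; CaV1.2 6.7e-6; CaV1.3 1.0e-4; KAS 4.0e-5;
#' KDR 5.0e-3; KIR 1.0e-4; KRP 2.0e-4, all S/cm^2; sodium restricted to the
#' axon initial segment, the rest on soma and dendrites), and the default
#' synaptic conductances (AMPA 7.2e-4 uS, GABA_A 3.6e-4 uS, NMDA 6.8e-5 uS).
#' A single channel set is used for both genotypes: the genotype selects the
#' morphology preset and the miniature-PSC calibration targets
#' (see [genotype_targets()]), not the channel densities.
#'
#' @param genotype `"wt"` or `"ko"`.
#' @return A list with elements `passive`, `channels` (named list of
#'   `channel_spec`s), `synapses` (named list of `synapse_spec`s), and
#'   `genotype`.
#' @export
default_model_spec <- function(genotype = c("wt", "ko")) {
  genotype <- match.arg(genotype)
  densities <- c(Na = 2.4, CaV12 = 6.7e-6, CaV13 = 1.0e-4, KAS = 4.0e-5,
                 KDR = 5.0e-3, KIR = 1.0e-4, KRP = 2.0e-4)
  reversals <- c(Na = 50, CaV12 = 120, CaV13 = 120, KAS = -90, KDR = -90,
                 KIR = -90, KRP = -90)
  channels <- lapply(names(densities), function(nm) {
    channel_spec(nm, gbar = unname(densities[nm]), reversal = unname(reversals[nm]),
                 region = if (nm == "Na") "axon_initial_segment" else "soma_and_dendrites",
                 gates = default_gates(nm))
  })
  names(channels) <- names(densities)
  synapses <- list(
    AMPA = synapse_spec("AMPA", gpeak = 7.2e-4, tau_rise = 0.5,
                        tau_decay = 4, reversal = 0),
    NMDA = synapse_spec("NMDA", gpeak = 6.8e-5, tau_rise = 3,
                        tau_decay = 50, reversal = 0, mg_block = FALSE,
                        mg_concentration = 0),
    GABA_A = synapse_spec("GABA_A", gpeak = 3.6e-4, tau_rise = 0.8,
                          tau_decay = 11, reversal = -70)
  )
  list(passive = passive_spec(), channels = channels, synapses = synapses,
       genotype = genotype)
}
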