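test_that("mono-exponential fitting recovers noiseless parameters exactly", {
  tt <- seq(0, 100, 0.1)
  tr <- trace(20 * exp(-tt / 10), dt = 0.1, unit = "pA")
  fit <- fit_monoexponential(tr)
  expect_equal(fit$A1, 20, tolerance = 1e-6)
  expect_equal(fit$tau1, 10, tolerance = 1e-6)
  expect_equal(fit$baseline, 0, tolerance = 1e-6)
  expect_error(fit_monoexponential(trace(rep(0, 500), dt = 0.1)), "flat")
})

test_that("mono-exponential recovery stays within 5% median under noise", {
  tt <- seq(0, 100, 0.1)
  clean <- 20 * exp(-tt / 10)
  errs <- sapply(1:100, function(s) {
    set.seed(s)
    tr <- trace(clean + rnorm(length(tt), 0, 1), dt = 0.1, unit = "pA")
    fit <- fit_monoexponential(tr, polarity = "positive")
    c(abs(fit$A1 / 20 - 1), abs(fit$tau1 / 10 - 1))
  })
  expect_lt(median(errs[1, ]), 0.05)
  expect_lt(median(errs[2, ]), 0.05)
})

test_that("tidy and glance expose exponential fit coefficients", {
  tt <- seq(0, 60, 0.1)
  fit <- fit_monoexponential(trace(8 * exp(-tt / 5) + 2, dt = 0.1))
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "tau1"], 5, tolerance = 1e-4)
  expect_named(glance(fit), c("A1", "tau1", "baseline", "rmse",
                              "window_start", "window_end"))
})

test_that("PSC shape metrics match analytic cases", {
  tt <- seq(0, 80, 0.01)
  # pure exponential decay: t50 = tau ln 2
  dec <- trace(-15 * exp(-tt / 8), dt = 0.01, unit = "pA")
  m <- psc_metrics(dec, polarity = "negative")
  expect_equal(m$amplitude, 15, tolerance = 1e-3)
  expect_equal(m$t50, 8 * log(2), tolerance = 0.01 * 8 * log(2))
  # linear ramp 0 -> A over 10 ms: 20-80% rise = 6 ms
  ramp <- trace(c(seq(0, 10, length.out = 1001), rep(10, 200)), dt = 0.01,
                unit = "pA")
  r <- psc_metrics(ramp, polarity = "positive")
  expect_equal(r$rise_time, 6, tolerance = 0.01)
  # template event: metrics agree with a brute-force sample scan
  sp <- synapse_spec("GABA_A", gpeak = 1, tau_rise = 1, tau_decay = 9,
                     reversal = -70)
  ev <- 30 * synaptic_conductance_waveform(sp, tt)
  met <- psc_metrics(trace(ev, dt = 0.01, unit = "pA"), polarity = "positive")
  expect_equal(met$amplitude, max(ev), tolerance = 1e-6)
  pk <- which.max(ev)
  i50 <- pk + which(ev[pk:length(ev)] <= max(ev) / 2)[1] - 1
  expect_equal(met$t50, tt[i50] - tt[pk], tolerance = 0.02)
  expect_error(psc_metrics(trace(rep(1, 100), dt = 1), "positive"), "peak")
})

test_that("metrics are invariant to baseline shifts and 2x resampling", {
  tt <- seq(0, 80, 0.02)
  sp <- synapse_spec("AMPA", gpeak = 1, tau_rise = 0.8, tau_decay = 6,
                     reversal = 0)
  ev <- -25 * synaptic_conductance_waveform(sp, tt)
  m0 <- psc_metrics(trace(ev, dt = 0.02, unit = "pA"), "negative")
  m_shift <- psc_metrics(trace(ev - 40, dt = 0.02, unit = "pA"), "negative")
  expect_equal(m_shift$amplitude, m0$amplitude, tolerance = 1e-6)
  expect_equal(m_shift$t50, m0$t50, tolerance = 1e-6)
  m_half <- psc_metrics(trace(ev[seq(1, length(ev), 2)], dt = 0.04,
                              unit = "pA"), "negative")
  expect_equal(m_half$amplitude, m0$amplitude, tolerance = 0.01)
  expect_equal(m_half$t50, m0$t50, tolerance = 0.01)
})

test_that("paired-pulse ratio and percent reduction are plain ratios", {
  expect_equal(ppr(100, 80), 0.8)
  expect_equal(ppr(7, 7), 1)
  expect_equal(ppr(3 * 10, 3 * 8), ppr(10, 8))
  expect_error(ppr(0, 1), "amp1")
  expect_equal(percent_reduction(100, 37), 63)
  expect_equal(percent_reduction(42, 42), 0)
  expect_equal(percent_reduction(100, 0), 100)
  expect_error(percent_reduction(0, 1), "before")
})

test_that("NMDA amplitude estimate reproduces the published products", {
  expect_equal(round(estimate_nmda_amplitude(15.0, 0.68, 40, 70), 1), 5.8)
  expect_equal(round(estimate_nmda_amplitude(19.3, 0.57, 40, 70), 1), 6.3)
  expect_equal(estimate_nmda_amplitude(12, 1, 55, 55), 12)
  expect_error(estimate_nmda_amplitude(10, 0.5, 40, 0), "driving force")
})

test_that("passive measurements agree with closed-form sphere values", {
  mod <- passive_sphere_model(g_leak = 5e-5, e_leak = -80)
  got <- measure_passive(mod, sim_config(duration = 300, v_init = -80))
  area <- 4 * pi * 7e-4^2
  expect_equal(got$v_rest, -80, tolerance = 1e-6)
  expect_equal(got$input_resistance, 1 / (5e-5 * area) / 1e6, tolerance = 0.01)
  expect_equal(got$tau_m, 1e-6 / 5e-5 * 1e3, tolerance = 0.02)
})

test_that("the default cell rests hyperpolarized and fires monotonically", {
  mod <- spiking_test_model()
  pas <- measure_passive(mod, sim_config(duration = 700))
  expect_lt(pas$v_rest, -80)
  expect_gt(pas$v_rest, -95)
  fi <- fi_curve(mod, amplitudes_pA = seq(10, 80, 10))
  expect_equal(nrow(fi), 8)
  expect_true(all(diff(fi$rate_hz) >= 0))
  expect_equal(fi$rate_hz[1], 0)   # 10 pA is subthreshold
  expect_gt(fi$rate_hz[8], 0)      # 80 pA drives repetitive firing
  # passive cell never fires
  fi0 <- fi_curve(passive_sphere_model(g_leak = 5e-4), amplitudes_pA = c(20, 80))
  expect_true(all(fi0$rate_hz == 0))
})

test_that("clamped somatic synapse reproduces the ideal-clamp current limit", {
  mod <- passive_sphere_model(g_leak = 1e-5, e_leak = -70)
  sp <- synapse_spec("AMPA", gpeak = 5e-4, tau_rise = 0.7, tau_decay = 4,
                     reversal = 0)
  mi <- attach_synapses(mod, sp, 1, list(20))
  out <- integrate_model(mi, sim_config(duration = 60, v_init = -70),
                         clamp = TRUE, v_hold = -70)
  cur <- out$clamp_current
  base <- median(cur$value[cur$t < 19])
  peak <- min(cur$value) - base
  expect_equal(peak, 5e-4 * (-70 - 0) * 1000, tolerance = 0.05)
})

test_that("simulated mean mPSCs are deterministic and monotone in gpeak", {
  mod <- spiking_test_model()
  sp <- default_model_spec()$synapses$AMPA
  a <- simulate_mpsc(mod, sp, n_iterations = 5, rng_seed = 2)
  b <- simulate_mpsc(mod, sp, n_iterations = 5, rng_seed = 2)
  expect_identical(a$mean_trace$value, b$mean_trace$value)
  amps <- sapply(c(0.5, 1, 2), function(f) {
    spf <- sp; spf$gpeak <- sp$gpeak * f
    simulate_mpsc(mod, spf, n_iterations = 5, rng_seed = 2)$metrics$amplitude
  })
  expect_true(all(diff(amps) > 0))
})

test_that("match_psc recovers forward-generated synaptic parameters", {
  mod <- spiking_test_model()
  base <- default_model_spec()$synapses$GABA_A
  set.seed(31)
  for (i in 1:3) {
    g_true <- base$gpeak * runif(1, 0.6, 1.6)
    tau_true <- runif(1, 6, 14)
    sp <- synapse_spec("GABA_A", gpeak = g_true, tau_rise = base$tau_rise,
                       tau_decay = tau_true, reversal = base$reversal)
    fwd <- simulate_mpsc(mod, sp, n_iterations = 8, rng_seed = 7)
    fit <- match_psc(mod, "GABA_A", fwd$metrics$amplitude, fwd$metrics$t50,
                     n_iterations = 8, rng_seed = 7)
    expect_equal(fit$spec$gpeak, g_true, tolerance = 0.02)
    expect_equal(fit$spec$tau_decay, tau_true, tolerance = 0.02)
  }
})

test_that("match_psc flags the zero-amplitude boundary and scales with targets", {
  mod <- spiking_test_model()
  expect_warning(z <- match_psc(mod, "AMPA", 0, 3), "boundary")
  expect_lt(z$spec$gpeak, 1e-9)
  lo <- match_psc(mod, "AMPA", 10, 4, n_iterations = 6, rng_seed = 3)
  hi <- match_psc(mod, "AMPA", 20, 4, n_iterations = 6, rng_seed = 3)
  expect_gt(hi$spec$gpeak, lo$spec$gpeak)
})

test_that("genotype targets encode printed amplitudes and effect directions", {
  wt <- genotype_targets("wt"); ko <- genotype_targets("ko")
  expect_equal(wt$amplitude_pA[wt$kind == "AMPA"], 15.0)
  expect_equal(ko$amplitude_pA[ko$kind == "AMPA"], 19.3)
  expect_equal(round(wt$amplitude_pA[wt$kind == "NMDA"], 1), 5.8)
  expect_equal(round(ko$amplitude_pA[ko$kind == "NMDA"], 1), 6.3)
  # knockout inhibition smaller and faster
  expect_lt(ko$amplitude_pA[ko$kind == "GABA_A"],
            wt$amplitude_pA[wt$kind == "GABA_A"])
  expect_lt(ko$t50_ms[ko$kind == "GABA_A"], wt$t50_ms[wt$kind == "GABA_A"])
})
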