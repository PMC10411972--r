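test_that("discretization respects segment caps and conserves membrane area", {
  fx <- fixture_morphologies(seed = 42)
  spec <- default_model_spec()
  spec$channels <- list()
  # sphere -> single somatic compartment (no axon without Na)
  expect_equal(nrow(discretize(fx$sphere, spec)$comps), 1)
  # 100 um dendrite at 10 um cap -> 10 dendritic compartments
  mod <- discretize(fx$stick100, spec, max_seg_length_um = 10)
  expect_equal(sum(mod$comps$kind == "dendrite"), 10)
  expect_true(all(mod$comps$length[mod$comps$kind != "soma"] <= 10 + 1e-12))
  # area conservation vs frusta on random trees
  for (seed in 1:5) {
    m <- random_test_tree(seed)
    mod <- discretize(m, spec, max_seg_length_um = 7)
    seg <- raw_dend_segments(m)
    child <- m[m$parent_id != -1L & m$node_kind == "dendrite", ]
    pidx <- match(child$parent_id, m$id)
    r0 <- ifelse(m$node_kind[pidx] == "soma", child$radius, m$radius[pidx])
    len <- sqrt(rowSums((seg$b - seg$a)^2))
    frusta <- sum(pi * (r0 + child$radius) *
                    sqrt(len^2 + (r0 - child$radius)^2)) * 1e-8
    soma_r <- m$radius[m$parent_id == -1L]
    expect_equal(sum(mod$comps$area_cm2),
                 frusta + 4 * pi * soma_r^2 * 1e-8, tolerance = 0.01)
  }
})

test_that("the axon initial segment is auto-appended when Na is requested", {
  fx <- fixture_morphologies(seed = 42)
  expect_message(mod <- discretize(fx$stick100, default_model_spec()),
                 "axon initial segment")
  ax <- mod$comps[mod$comps$kind == "axon", ]
  expect_equal(sum(ax$length), 50)
  expect_equal(unique(ax$diam), 0.5)
  expect_true(all(mod$channels$Na$gbar_uS[mod$comps$kind != "axon"] == 0))
  expect_true(all(mod$channels$Na$gbar_uS[mod$comps$kind == "axon"] > 0))
})

test_that("passive single compartment reproduces the analytic RC response", {
  mod <- passive_sphere_model(g_leak = 5e-5, e_leak = -80)
  area <- 4 * pi * 7e-4^2
  R <- 1 / (5e-5 * area)            # Ohm
  tau <- 1e-6 * area * R * 1e3      # ms
  cfg <- sim_config(dt = 0.025, duration = 200, v_init = -80)
  stim <- data.frame(site = 1, amplitude_pA = 20, onset_ms = 0,
                     duration_ms = 200)
  v <- integrate_model(mod, cfg, stimuli = stim)$site_1
  analytic <- -80 + 20e-12 * R * 1e3 * (1 - exp(-v$t / tau))
  expect_lt(max(abs(v$value - analytic)), 0.1)
  # steady state within 1% of I*R
  expect_equal(v$value[nrow(v)] - (-80), 20e-12 * R * 1e3, tolerance = 0.01)
  # no stimulus -> flat at leak reversal
  flat <- integrate_model(mod, cfg)$site_1
  expect_true(all(abs(flat$value + 80) < 1e-9))
})

test_that("halving dt changes the RC endpoint by less than 0.05 mV", {
  mod <- passive_sphere_model()
  stim <- data.frame(site = 1, amplitude_pA = 20, onset_ms = 0,
                     duration_ms = 100)
  ends <- vapply(c(0.05, 0.025, 0.0125), function(dt) {
    v <- integrate_model(mod, sim_config(dt = dt, duration = 100, v_init = -80),
                         stimuli = stim)$site_1
    v$value[nrow(v)]
  }, numeric(1))
  expect_lt(abs(ends[2] - ends[1]), 0.05)
  # first-order convergence: error shrinks by ~2 per halving
  expect_lt(abs(ends[3] - ends[2]), abs(ends[2] - ends[1]))
})

test_that("two-compartment passive model matches the eigen-decomposition oracle", {
  mod <- passive_two_comp_model()
  cfg <- sim_config(dt = 0.01, duration = 100, v_init = -80)
  stim <- data.frame(site = 1, amplitude_pA = 30, onset_ms = 0,
                     duration_ms = 100)
  got <- integrate_model(mod, cfg, stimuli = stim)
  # oracle: C dV/dt = -G (V - E) + I solved by eigen decomposition
  cp <- mod$comps
  C <- cp$cap_nF
  gl <- cp$g_leak_uS
  ga <- cp$g_axial_uS[2]
  A <- matrix(c(-(gl[1] + ga) / C[1], ga / C[1],
                ga / C[2], -(gl[2] + ga) / C[2]), 2, 2, byrow = TRUE)
  b <- c((gl[1] * -80 + 0.03) / C[1], (gl[2] * -80) / C[2])
  vss <- solve(-A, b)
  eg <- eigen(A)
  tt <- got$site_1$t
  coefs <- solve(eg$vectors, c(-80, -80) - vss)
  Vt <- sapply(tt, function(t1)
    Re(vss + eg$vectors %*% (coefs * exp(eg$values * t1))))
  expect_lt(max(abs(got$site_1$value - Vt[1, ])), 0.05)
  err_rel <- max(abs(got$site_1$value - Vt[1, ])) / abs(vss[1] + 80)
  expect_lt(err_rel, 0.01)
})

test_that("axial current conservation holds at solver residual level", {
  for (seed in 1:2) {
    m <- random_test_tree(seed)
    spec <- default_model_spec()
    spec$channels <- list()
    mod <- discretize(m, spec, 10)
    stim <- data.frame(site = 1, amplitude_pA = 50, onset_ms = 5,
                       duration_ms = 50)
    out <- integrate_model(mod, sim_config(duration = 80, v_init = -80),
                           stimuli = stim, check_residual = TRUE)
    expect_lt(out$max_residual, 1e-8)
  }
})

test_that("Crank-Nicolson agrees with backward Euler on smooth problems", {
  mod <- passive_sphere_model()
  stim <- data.frame(site = 1, amplitude_pA = 20, onset_ms = 0,
                     duration_ms = 100)
  be <- integrate_model(mod, sim_config(dt = 0.025, duration = 100,
                                        v_init = -80), stimuli = stim)$site_1
  cn <- integrate_model(mod, sim_config(dt = 0.025, duration = 100,
                                        v_init = -80,
                                        method = "crank_nicolson"),
                        stimuli = stim)$site_1
  expect_lt(max(abs(be$value - cn$value)), 0.05)
})

test_that("synapse placement is uniform per length, counted, and deterministic", {
  fx <- fixture_morphologies(seed = 42)
  spec <- default_model_spec(); spec$channels <- list()
  mod <- discretize(fx$y_tree, spec, max_seg_length_um = 10)
  expect_length(place_synapses(mod, 100, rng_seed = 5), 100)
  expect_identical(place_synapses(mod, 50, rng_seed = 5),
                   place_synapses(mod, 50, rng_seed = 5))
  expect_length(place_synapses(mod, 0, rng_seed = 5), 0)
  sphere <- passive_sphere_model()
  expect_error(place_synapses(sphere, 1), "no dendritic cable")
  # two equal daughters receive statistically equal shares
  comp <- place_synapses(mod, 1e4, rng_seed = 9)
  daughters <- split(seq_len(nrow(mod$comps)), mod$comps$kind)$dendrite
  # daughter branches start after the 50 um stem (5 comps); compare the two
  dend <- mod$comps[mod$comps$kind == "dendrite", ]
  stem_n <- 5
  lab <- findInterval(match(comp, daughters), c(stem_n + 1, stem_n + 6))
  n1 <- sum(lab == 1); n2 <- sum(lab == 2)
  # var(n1 - n2) = n * 2/3 for two equal multinomial shares of 1/3 each
  expect_lt(abs(n1 - n2), 4 * sqrt(1e4 * 2 / 3))
})

test_that("spike detection counts upward crossings with refractoriness", {
  flat <- trace(rep(-70, 1000), dt = 1)
  expect_length(detect_spikes(flat, -10), 0)
  v <- rep(-70, 1000)
  for (k in 0:4) v[100 + k * 200 + 0:3] <- 20
  pulses <- trace(v, dt = 1)
  expect_length(detect_spikes(pulses, -10), 5)
  # sinusoid crossing threshold k times upward
  tt <- seq(0, 999, 1)
  sine <- trace(-40 + 35 * sin(2 * pi * tt / 100), dt = 1)
  expect_length(detect_spikes(sine, -10, refractory_ms = 2), 10)
  expect_equal(firing_rate(pulses, -10), 5 / 0.999, tolerance = 1e-6)
})

test_that("integration is bitwise deterministic for identical inputs", {
  mod <- spiking_test_model()
  syn <- default_model_spec()$synapses$AMPA
  comp <- place_synapses(mod, 20, rng_seed = 3)
  ev <- generate_input_trains(20, 10, 2, 300, rng_seed = 4)
  mi <- attach_synapses(mod, syn, comp, ev)
  cfg <- sim_config(duration = 300)
  a <- integrate_model(mi, cfg)
  b <- integrate_model(mi, cfg)
  expect_identical(a$site_1$value, b$site_1$value)
})

test_that("numerical failure is reported with the time of failure", {
  mod <- passive_sphere_model()
  stim <- data.frame(site = 1, amplitude_pA = 1e308, onset_ms = 1,
                     duration_ms = 19)
  expect_error(
    integrate_model(mod, sim_config(duration = 20, v_init = -80),
                    stimuli = stim),
    "numerical failure")
})
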