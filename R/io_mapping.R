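#' Stochastic input-ensemble specification
#'
#' The model cell receives `n_exc` excitatory and `n_inh` inhibitory inputs
#' randomly distributed along the dendrites. In each iteration every input's
#' activation frequency is an independent draw from a normal distribution
#' (truncated at zero) around the condition's nominal rate, emulating the
#' per-iteration dispersion of input activation frequencies.
#'
#' @param n_exc,n_inh Number of excitatory / inhibitory inputs (default 100
#'   each).
#' @param rate_mean Nominal activation rate, Hz.
#' @param rate_sd Between-input rate dispersion, Hz (default 20% of mean).
#' @param train_kind `"poisson"` or `"regular_jittered"`.
#' @param duration Trial duration, ms.
#' @param seed Integer seed.
#' @return A list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_exc = 100, n_inh = 100, rate_mean = 10,
                          rate_sd = 0.2 * rate_mean,
                          train_kind = c("poisson", "regular_jittered"),
                          duration = 2000, seed = 1) {
  train_kind <- match.arg(train_kind)
  if (n_exc < 0 || n_inh < 0) abort("input counts must be >= 0")
  if (rate_sd < 0) abort("rate_sd must be >= 0")
  if (duration <= 0) abort("duration must be > 0")
  structure(list(n_exc = n_exc, n_inh = n_inh, rate_mean = rate_mean,
                 rate_sd = rate_sd, train_kind = train_kind,
                 duration = duration, seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Generate per-input spike trains
#'
#' Each of `n` inputs gets a rate drawn from `Normal(rate_mean, rate_sd)`
#' truncated at 0, then an event train of that rate over `duration`
#' (homogeneous Poisson, or regular with 10% interval jitter).
#'
#' @param n Number of inputs.
#' @param rate_mean,rate_sd Rate distribution, Hz.
#' @param duration Duration, ms.
#' @param train_kind `"poisson"` or `"regular_jittered"`.
#' @param rng_seed Integer seed (deterministic output).
#' @return A list of `n` sorted numeric vectors of event times (ms).
#' @export
generate_input_trains <- function(n, rate_mean, rate_sd = 0.2 * rate_mean,
                                  duration = 2000,
                                  train_kind = c("poisson", "regular_jittered"),
                                  rng_seed = 1) {
  train_kind <- match.arg(train_kind)
  if (n == 0) return(list())
  with_preserved_seed({
    set.seed(as.integer(rng_seed))
    rates <- pmax(0, rnorm(n, rate_mean, rate_sd))
    lapply(rates, function(r) {
      if (r <= 0) return(numeric(0))
      if (train_kind == "poisson") {
        k <- rpois(1, r * duration / 1000)
        sort(runif(k, 0, duration))
      } else {
        isi <- 1000 / r
        t0 <- runif(1, 0, isi)
        tt <- seq(t0, duration, by = isi)
        sort(pmin(pmax(tt + rnorm(length(tt), 0, 0.1 * isi), 0), duration))
      }
    })
  })
}

#' Assemble a genotype-calibrated model cell
#'
#' Synthesizes the genotype's morphology preset, discretizes it with the
#' default channel set, and (optionally) calibrates the AMPA, NMDA and
#' GABA_A peak conductances and decay constants against the genotype's
#' miniature-PSC targets via [match_psc()].
#'
#' @param genotype `"wt"` or `"ko"`.
#' @param seed Seed for the morphology draw and the calibration simulations.
#' @param calibrate If `FALSE`, keep the default synaptic conductances.
#' @param n_iterations Randomized placements per calibration evaluation.
#' @param tol Calibration tolerance passed to [match_psc()].
#' @param max_seg_length_um Spatial discretization.
#' @return A list with `model` (a `cable_model`), `synapses` (named list of
#'   `synapse_spec`s), `genotype`, `n_exc`/`n_inh` (recommended input counts:
#'   excitatory contacts scale with total dendritic length, reflecting the
#'   higher miniature-EPSC frequency and synapse number of the knockout,
#'   while inhibitory counts stay fixed), and `calibration` (achieved
#'   values, or `NULL`).
#' @export
build_genotype_model <- function(genotype = c("wt", "ko"), seed = 1,
                                 calibrate = TRUE, n_iterations = 20,
                                 tol = 0.02, max_seg_length_um = 20) {
  genotype <- match.arg(genotype)
  m <- synthesize_morphology(morph_preset(genotype), seed = seed,
                             label = genotype)
  spec <- default_model_spec(genotype)
  model <- suppressMessages(discretize(m, spec, max_seg_length_um))
  synapses <- spec$synapses
  calib <- NULL
  if (calibrate) {
    targets <- genotype_targets(genotype)
    fits <- lapply(seq_len(nrow(targets)), function(i) {
      match_psc(model, targets$kind[i], targets$amplitude_pA[i],
                targets$t50_ms[i], n_iterations = n_iterations,
                rng_seed = seed, tol = tol)
    })
    names(fits) <- targets$kind
    synapses <- lapply(fits, `[[`, "spec")
    calib <- lapply(fits, function(f)
      c(f$achieved, n_evals = f$n_evals))
  }
  ref_length <- morph_preset("wt")$target_length
  list(model = model, synapses = synapses, genotype = genotype,
       n_exc = round(100 * total_dendritic_length(m) / ref_length),
       n_inh = 100, calibration = calib)
}

#' Run the excitation x inhibition firing-rate grid
#'
#' For every combination of excitatory and inhibitory nominal rates, runs
#' `n_iterations` independent trials. Each trial draws fresh synapse
#' placements and input trains (seeds derived deterministically from
#' `base_seed`), attaches co-localized AMPA+NMDA conductances for each
#' excitatory input and GABA_A for each inhibitory input, integrates the
#' cell in current clamp, and records the somatic firing rate. Cell values
#' are iteration means.
#'
#' @param cell A list as returned by [build_genotype_model()] (elements
#'   `model` and `synapses`), or a bare `cable_model` (then the default
#'   synapses are used).
#' @param exc_rates,inh_rates Nominal rates, Hz.
#' @param n_exc,n_inh Inputs per class (default 100 each).
#' @param n_iterations Trials per grid cell (default 100; use ~10 for
#'   scaled-down runs).
#' @param duration Trial duration, ms.
#' @param rate_sd_frac Rate dispersion as a fraction of the nominal rate.
#' @param train_kind Input train statistics.
#' @param base_seed Master seed; the whole grid is seed-deterministic.
#' @param dt Integration step, ms.
#' @param nmda_mg_mM Magnesium concentration applied to NMDA inputs during
#'   ensemble trials (default 1 mM, physiological; the clamp calibration is
#'   magnesium-free, matching the recording solutions).
#' @return A tibble of class `msn_iogrid`, long format: `f_exc`, `f_inh`,
#'   `mean_rate`, `sd_rate`, `n_iterations`.
#' @export
run_io_grid <- function(cell, exc_rates, inh_rates, n_exc = 100, n_inh = 100,
                        n_iterations = 100, duration = 2000,
                        rate_sd_frac = 0.2,
                        train_kind = c("poisson", "regular_jittered"),
                        base_seed = 1, dt = 0.025, nmda_mg_mM = 1) {
  train_kind <- match.arg(train_kind)
  if (length(exc_rates) == 0 || length(inh_rates) == 0) {
    abort("rate lists must be non-empty")
  }
  if (inherits(cell, "cable_model")) {
    cell <- list(model = cell, synapses = default_model_spec()$synapses)
  }
  if (missing(n_exc) && !is.null(cell$n_exc)) n_exc <- cell$n_exc
  if (missing(n_inh) && !is.null(cell$n_inh)) n_inh <- cell$n_inh
  model <- cell$model
  syn <- cell$synapses
  if (!is.null(syn$NMDA) && nmda_mg_mM > 0) {
    syn$NMDA$mg_block <- TRUE
    syn$NMDA$mg_concentration <- nmda_mg_mM
  }
  cfg <- sim_config(dt = dt, duration = duration, v_init = -85)
  grid <- tidyr::expand_grid(f_inh = inh_rates, f_exc = exc_rates)
  res <- pmap(grid, function(f_inh, f_exc) {
    cell_idx <- which(grid$f_inh == f_inh & grid$f_exc == f_exc)[1]
    rates <- vapply(seq_len(n_iterations), function(it) {
      s <- (as.integer(base_seed) * 10007L + cell_idx * 211L + it * 17L) %% 2147483629L
      run_ensemble_trial(model, syn, f_exc, f_inh, n_exc, n_inh,
                         rate_sd_frac, train_kind, duration, cfg, s)
    }, numeric(1))
    tibble(f_exc = f_exc, f_inh = f_inh, mean_rate = mean(rates),
           sd_rate = if (n_iterations > 1) sd(rates) else 0,
           n_iterations = n_iterations)
  })
  new_tibble(dplyr::bind_rows(res), base_seed = base_seed,
             duration = duration, class = "msn_iogrid")
}

# one ensemble trial -> somatic firing rate (Hz)
run_ensemble_trial <- function(model, syn, f_exc, f_inh, n_exc, n_inh,
                               rate_sd_frac, train_kind, duration, cfg, seed) {
  mi <- model
  if (n_exc > 0 && f_exc > 0) {
    comp_e <- place_synapses(model, n_exc, rng_seed = seed)
    trains_e <- generate_input_trains(n_exc, f_exc, rate_sd_frac * f_exc,
                                      duration, train_kind, rng_seed = seed + 1L)
    mi <- attach_synapses(mi, syn$AMPA, comp_e, trains_e)
    if (!is.null(syn$NMDA)) mi <- attach_synapses(mi, syn$NMDA, comp_e, trains_e)
  }
  if (n_inh > 0 && f_inh > 0) {
    comp_i <- place_synapses(model, n_inh, rng_seed = seed + 2L)
    trains_i <- generate_input_trains(n_inh, f_inh, rate_sd_frac * f_inh,
                                      duration, train_kind, rng_seed = seed + 3L)
    mi <- attach_synapses(mi, syn$GABA_A, comp_i, trains_i)
  }
  site <- spike_record_site(model)
  v <- integrate_model(mi, cfg, record = site)[[1]]
  sp <- detect_spikes(v, cfg$spike_threshold, cfg$refractory)
  length(sp) / (duration / 1000)
}

#' Iso-firing contours of an input-output grid
#'
#' Marching-squares isolines (with linear interpolation between grid points)
#' of the mean firing-rate surface in the excitation x inhibition plane.
#'
#' @param grid An `msn_iogrid`.
#' @param levels_hz Contour levels, Hz (default 1, 5, 10).
#' @return A tibble with columns `level`, `piece`, `f_exc`, `f_inh`; empty
#'   (zero rows) for levels the surface never attains.
#' @export
extract_contours <- function(grid, levels_hz = c(1, 5, 10)) {
  ex <- sort(unique(grid$f_exc)); ih <- sort(unique(grid$f_inh))
  z <- matrix(NA_real_, length(ex), length(ih))
  for (r in seq_len(nrow(grid))) {
    z[match(grid$f_exc[r], ex), match(grid$f_inh[r], ih)] <- grid$mean_rate[r]
  }
  if (anyNA(z)) abort("grid is not complete over exc x inh combinations")
  # contourLines() nudges levels that coincide with grid values; snap each
  # returned point back to the exact linear interpolation along its cell edge
  snap <- function(xs, ys, lv) {
    for (k in seq_along(xs)) {
      i <- which(abs(ex - xs[k]) < 1e-9)
      if (length(i) == 1) {
        j <- findInterval(ys[k], ih, all.inside = TRUE)
        dz <- z[i, j + 1] - z[i, j]
        if (abs(dz) > 1e-12) ys[k] <- ih[j] + (lv - z[i, j]) / dz * (ih[j + 1] - ih[j])
      } else {
        j <- which(abs(ih - ys[k]) < 1e-9)
        if (length(j) == 1) {
          i2 <- findInterval(xs[k], ex, all.inside = TRUE)
          dz <- z[i2 + 1, j] - z[i2, j]
          if (abs(dz) > 1e-12) xs[k] <- ex[i2] + (lv - z[i2, j]) / dz * (ex[i2 + 1] - ex[i2])
        }
      }
    }
    list(x = xs, y = ys)
  }
  out <- list()
  for (lv in levels_hz) {
    cl <- suppressWarnings(grDevices::contourLines(ex, ih, z, levels = lv))
    for (k in seq_along(cl)) {
      pt <- snap(cl[[k]]$x, cl[[k]]$y, lv)
      out[[length(out) + 1]] <- tibble(level = lv, piece = k,
                                       f_exc = pt$x, f_inh = pt$y)
    }
  }
  if (length(out) == 0) {
    return(tibble(level = numeric(0), piece = integer(0),
                  f_exc = numeric(0), f_inh = numeric(0)))
  }
  dplyr::bind_rows(out)
}

#' Fit a gain/offset model to an input-output curve
#'
#' Threshold-linear form: `r = gain * max(0, f - offset)` by least squares
#' (closed-form slope at each candidate threshold, threshold by 1D
#' minimization). Sigmoid form: 4-parameter logistic, with gain = maximum
#' slope and offset = half-activation abscissa.
#'
#' @param exc_rates Input rates, Hz.
#' @param output_rates Output firing rates, Hz.
#' @param fit_form `"threshold_linear"` or `"sigmoid"`.
#' @return A list of class `io_fit` with `offset`, `gain`, `fit_form`,
#'   `rmse`. Supports [tidy()] and [glance()].
#' @export
fit_io_curve <- function(exc_rates, output_rates,
                         fit_form = c("threshold_linear", "sigmoid")) {
  fit_form <- match.arg(fit_form)
  if (length(exc_rates) < 4) abort("need at least 4 points")
  if (all(output_rates <= 0)) abort("degenerate fit: all output rates are zero")
  ord <- order(exc_rates)
  f <- exc_rates[ord]; r <- output_rates[ord]
  if (fit_form == "threshold_linear") {
    sse <- function(o) {
      x <- pmax(0, f - o)
      if (sum(x^2) == 0) return(sum(r^2))
      g <- sum(r * x) / sum(x^2)
      sum((r - g * x)^2)
    }
    # coarse grid then local refinement (the SSE is piecewise smooth in o)
    cand <- seq(min(f), max(f), length.out = 201)
    o0 <- cand[which.min(vapply(cand, sse, numeric(1)))]
    span <- diff(range(f)) / 100
    opt <- optimize(sse, c(max(min(f), o0 - span), min(max(f), o0 + span)),
                    tol = 1e-10)
    offset <- opt$minimum
    x <- pmax(0, f - offset)
    gain <- if (sum(x^2) > 0) sum(r * x) / sum(x^2) else 0
    rmse <- sqrt(sse(offset) / length(r))
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(r ~ d + (a - d) / (1 + exp(-(f - x0) / s)),
                        data = data.frame(f = f, r = r),
                        start = list(a = max(r), d = min(r),
                                     x0 = f[which.min(abs(r - (max(r) + min(r)) / 2))],
                                     s = diff(range(f)) / 8),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) abort("sigmoid fit did not converge"))
    cf <- coef(fit)
    offset <- unname(cf[["x0"]])
    gain <- unname((cf[["a"]] - cf[["d"]]) / (4 * cf[["s"]]))
    rmse <- sqrt(mean(stats::residuals(fit)^2))
  }
  structure(list(offset = offset, gain = gain, fit_form = fit_form,
                 rmse = rmse), class = "io_fit")
}

#' @export
print.io_fit <- function(x, ...) {
  cat(sprintf("<io_fit %s> offset = %.3g Hz, gain = %.3g (rmse %.3g)\n",
              x$fit_form, x$offset, x$gain, x$rmse))
  invisible(x)
}

#' @method tidy io_fit
#' @export
tidy.io_fit <- function(x, ...) {
  tibble(term = c("offset", "gain"), estimate = c(x$offset, x$gain))
}

#' @method glance io_fit
#' @export
glance.io_fit <- function(x, ...) {
  tibble(offset = x$offset, gain = x$gain, fit_form = x$fit_form,
         rmse = x$rmse)
}

#' Compare two input-output fits
#'
#' Classifies the change from `reference` to `test` as additive/subtractive
#' (offset decrease/increase), multiplicative/divisive (gain
#' increase/decrease), `mixed`, or `none`, against stated tolerances.
#'
#' @param reference,test `io_fit` objects of the same form.
#' @param tol_offset_hz Offset changes smaller than this are ignored.
#' @param tol_gain_frac Relative gain changes smaller than this are ignored.
#' @return A tibble with `delta_offset`, `delta_gain`, `classification`.
#' @export
compare_io <- function(reference, test, tol_offset_hz = 0.5,
                       tol_gain_frac = 0.05) {
  stopifnot(inherits(reference, "io_fit"), inherits(test, "io_fit"))
  if (reference$fit_form != test$fit_form) {
    abort("cannot compare fits of different forms")
  }
  d_off <- test$offset - reference$offset
  d_gain <- test$gain - reference$gain
  off_change <- if (abs(d_off) <= tol_offset_hz) "none"
                else if (d_off > 0) "subtractive" else "additive"
  gain_change <- if (abs(d_gain) <= tol_gain_frac * abs(reference$gain)) "none"
                 else if (d_gain > 0) "multiplicative" else "divisive"
  cls <- if (off_change == "none" && gain_change == "none") "none"
         else if (off_change == "none") gain_change
         else if (gain_change == "none") off_change
         else "mixed"
  tibble(delta_offset = d_off, delta_gain = d_gain, classification = cls)
}

#' Plot an input-output grid as a firing-rate heat map
#'
#' @param object An `msn_iogrid`.
#' @param contours Contour levels to overlay, Hz (NULL for none).
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot msn_iogrid
#' @export
autoplot.msn_iogrid <- function(object, contours = c(1, 5, 10), ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$f_exc, y = .data$f_inh,
                                            fill = .data$mean_rate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "rate (Hz)") +
    ggplot2::labs(x = "excitatory rate (Hz)", y = "inhibitory rate (Hz)") +
    ggplot2::theme_minimal()
  if (!is.null(contours)) {
    cl <- extract_contours(object, contours)
    if (nrow(cl) > 0) {
      p <- p + ggplot2::geom_path(
        data = cl, inherit.aes = FALSE,
        ggplot2::aes(x = .data$f_exc, y = .data$f_inh,
                     group = interaction(.data$level, .data$piece)),
        colour = "white")
    }
  }
  p
}
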