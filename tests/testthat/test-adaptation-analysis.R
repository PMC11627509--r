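test_that("PSTH windows tile the stimulus-onset asynchrony and track adaptation", {
  sim <- fx_sim_cohort()
  ps <- psth_windows(sim, roles = "bias")
  expect_equal(dim(ps)[2], 3)
  expect_equal(dimnames(ps)$window, c("onset", "sustained", "offset"))
  # 3 x 50 ms windows tile the 150 ms SOA: every stimulus bin is claimed
  bi <- sim$bin_info
  expect_true(all(!is.na(bi$window[!is.na(bi$event)])))
  # dynamic-model cells adapt: onset rate decreases over early positions
  onset <- rowMeans(ps[, "onset", ])
  expect_lt(onset[5], onset[1])
  # a constant-rate cell yields identical rates across windows and positions
  cfgc <- model_config(n_cortical = 4L, F_A = 0)
  popc <- make_population(cfgc, rate_gain = 0)   # baseline only
  simc <- simulate_experiment(fx_pair()[1:4], popc,
                              noise_config(mode = "rate", n_reps = 1,
                                           keep_trials = FALSE), seed = 2)
  psc <- psth_windows(simc, roles = "bias")
  expect_lt(diff(range(psc[, , 1], na.rm = TRUE)), 1e-9)
})

test_that("response-type classification fits exponentials and labels directions", {
  # synthetic decay with the reported population time course: tau 3.9
  # positions, plateau 13% below initial, Poisson noise over a large cohort
  k <- 1:10
  r_true <- 87 + 13 * exp(-(k - 1) / 3.9)   # starts at 100, plateaus 13% down
  set.seed(6)
  n_cells <- 662
  obs <- colMeans(matrix(rpois(n_cells * 10, rep(r_true, each = n_cells)),
                         n_cells))
  rt <- classify_response_type(obs)
  expect_equal(rt$label, "adapting")
  expect_lt(abs(rt$tau_stimuli / 3.9 - 1), 0.15)
  depth <- (rt$initial_rate - rt$asymptote_rate) / rt$initial_rate
  expect_lt(abs(depth - 0.13), 0.03)   # within 3 points of 13%
  # strictly increasing ramp: facilitating
  expect_equal(classify_response_type(seq(5, 20, length.out = 8))$label,
               "facilitating")
  # constant series: flat flag, not adapting
  ct <- classify_response_type(rep(7, 8))
  expect_true(ct$flat)
  expect_false(ct$label == "adapting")
  expect_error(classify_response_type(c(1, 2, 3)))
})

test_that("recovery fitting returns the configured recovery time constant", {
  # closed-form check: the model's adaptation state decays at F_R per frame
  cfg <- model_config()
  tau_theory <- -1 / (cfg$sample_rate * log(1 - cfg$F_R))
  expect_equal(tau_theory, 1.2, tolerance = 0.02)
  # parameter recovery from the simulated cohort's spontaneous rates
  rec <- recovery_trace(fx_sim_cohort())
  rf <- recovery_fit(rec$t, rec$rate)
  expect_false(rf$degenerate)
  expect_lt(abs(rf$tau_seconds / 1.2 - 1), 0.15)
  # without adaptation there is nothing to recover
  pop0 <- make_population(model_config(F_A = 0))
  sim0 <- simulate_experiment(fx_pair()[1:4], pop0,
                              noise_config(mode = "rate", n_reps = 1,
                                           keep_trials = FALSE),
                              seed = 3, pad_s = 3)
  rec0 <- recovery_trace(sim0)
  expect_true(recovery_fit(rec0$t, rec0$rate)$degenerate)
})

test_that("faster recovery rates shorten the fitted recovery time constant", {
  taus <- vapply(c(1, 2), function(mult) {
    cfg <- model_config()
    cfg$F_R <- cfg$F_R * mult
    pop <- make_population(cfg)
    sim <- simulate_experiment(fx_pair()[c(3, 11, 19, 27)], pop,
                               noise_config(mode = "rate", n_reps = 1,
                                            keep_trials = FALSE),
                               seed = 3, pad_s = 4)
    rec <- recovery_trace(sim)
    recovery_fit(rec$t, rec$rate)$tau_seconds
  }, numeric(1))
  expect_equal(taus[1] / taus[2], 2, tolerance = 0.25)
})

test_that("biased tuning curves dip locally inside the bias region", {
  tc <- biased_tuning(fx_sim_tuning())
  expect_gt(tc$inside_reduction, 2 * tc$outside_reduction)
  expect_lt(tc$inside_ratio_high, 0.9)    # clear high-rate reduction
  # re-centred difference profiles agree across the four regions (rotation
  # invariance of the model): pairwise correlations positive and strong
  mats <- lapply(names(tc$adapted), function(ct) {
    rel <- circular_step(as.numeric(ct), tc$grid)
    prof <- rowMeans(tc$unadapted - tc$adapted[[ct]], na.rm = TRUE)
    prof[order(rel)]
  })
  cc <- combn(4, 2, function(ix) cor(mats[[ix[1]]], mats[[ix[2]]]))
  expect_true(all(cc > 0.8))
  # without adaptation the difference profile is flat around zero
  pop0 <- make_population(model_config(F_A = 0, n_cortical = 48L))
  tun0 <- generate_biased_tuning_set(stimulus_config(), seed = 3)[c(1, 6, 11, 16)]
  sim0 <- simulate_experiment(tun0, pop0,
                              noise_config(mode = "rate", n_reps = 1,
                                           keep_trials = FALSE), seed = 4)
  tc0 <- biased_tuning(sim0)
  expect_lt(max(abs(tc0$difference), na.rm = TRUE), 0.3)
})

test_that("tuning halfwidth walks from the minimum to half-height crossings", {
  # closed-form oracle: von Mises whose analytic half-height width is 2.5 st
  grid <- seq(0, 11.95, by = 0.05)
  sig <- shepadapt:::halfwidth_to_sigma(2.5)
  curve <- vm_peak1(grid, 6, sig)
  expect_equal(as.numeric(tuning_halfwidth(curve, grid)), 2.5,
               tolerance = 0.06)
  # flat curve: degenerate, full octave
  hw_flat <- tuning_halfwidth(rep(3, 48))
  expect_equal(as.numeric(hw_flat), 12)
  expect_true(attr(hw_flat, "degenerate"))
  # exact invariance under affine rate transforms
  set.seed(8)
  curve2 <- curve + 0.2 * sin(2 * pi * grid / 12)
  expect_identical(as.numeric(tuning_halfwidth(curve2, grid)),
                   as.numeric(tuning_halfwidth(5 * curve2 + 2, grid)))
  # weak modulation on a broad curve yields a conservatively large halfwidth
  broad <- vm_peak1(grid, 6, 6)
  expect_gt(tuning_halfwidth(broad, grid), 4)
})

test_that("the synthetic cohort's median tuning halfwidth lies in the narrow range", {
  sim <- fx_sim_cohort()
  resp <- event_responses(sim)
  ev <- sim$events
  tr <- ev$role == "bias"
  pcb <- floor(pitch_class(ev$pitch_class[tr]))
  tun <- rowsum(resp[tr, , drop = FALSE], pcb) / as.vector(table(pcb))
  hw <- apply(tun, 2, function(v) as.numeric(tuning_halfwidth(v)))
  expect_gt(median(hw), 2)
  expect_lt(median(hw), 4.5)
})
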