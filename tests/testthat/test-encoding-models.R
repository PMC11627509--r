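test_that("von Mises tuning is periodic, peaked at the best pitch class, and normalizable", {
  tu <- von_mises_tuning(4, 1.5, normalization = "area_one")
  grid <- seq(0, 12, by = 0.001)[-12001]
  v <- von_mises_response(tu, grid)
  expect_equal(grid[which.max(v)], 4, tolerance = 0.01)
  expect_equal(sum(v) * 0.001, 1, tolerance = 1e-6)       # unit area
  expect_equal(von_mises_response(tu, 1), von_mises_response(tu, 13))
  expect_equal(von_mises_response(tu, 4 + 1.3), von_mises_response(tu, 4 - 1.3))
  expect_equal(grid[which.min(v)], 10, tolerance = 0.01)  # antipode minimum
  tp <- von_mises_tuning(4, 1.5, normalization = "peak_one")
  expect_equal(von_mises_response(tp, 4), 1)
  expect_error(von_mises_tuning(4, 0), "width")
})

test_that("purely local adaptation rescales responses without moving the decoded pitch", {
  pop <- vm_population(100, width = 1.5)
  bp <- bias_profile(3, 5)
  m <- adapt_local(pop, bp, A0 = 0.8)
  test_pcs <- c(0.5, 2, 5.5)
  r <- m$rates(test_pcs); r0 <- m$rates0(test_pcs)
  # uniform per-stimulus scaling by (1 - A0 * S_Bias(S))
  expect_equal(r, (1 - 0.8 * bp(test_pcs)) * r0)
  expect_true(all(rowSums(r)[bp(test_pcs) == 1] < rowSums(r0)[bp(test_pcs) == 1]))
  # population-vector decode unchanged to numerical precision
  grid <- seq(0, 11.9, by = 0.1)
  mx <- apply(m$rates(grid), 2, max)
  d <- population_vector_decode(r, pop$best_pcs, mx, bf_prior = rep(1, 100))
  d0 <- population_vector_decode(r0, pop$best_pcs, mx, bf_prior = rep(1, 100))
  expect_equal(d, d0, tolerance = 1e-9)
  expect_error(adapt_local(pop, bp, A0 = 1.2), "A0")
  # uniform bias profile scales everything identically
  mu <- adapt_local(pop, function(pc) rep(0.5, length(pc)), A0 = 0.8)
  expect_equal(mu$rates(grid), 0.6 * mu$rates0(grid))
})

test_that("global adaptation scales whole tuning curves by bias overlap and repels decodes", {
  pop <- vm_population(100, width = 1.5)
  bp <- bias_profile(3, 5)
  m <- adapt_global(pop, bp, A0 = 0.8)
  # overlap oracle: direct integral of S_Bias against each tuning curve
  grid <- seq(0.005, 11.995, by = 0.01)
  A_oracle <- 0.8 * vapply(pop$tunings, function(tu) {
    w <- von_mises_response(tu, grid)
    sum(w * bp(grid)) / sum(w)
  }, numeric(1))
  expect_equal(m$A, A_oracle, tolerance = 1e-3)
  expect_equal(pop$best_pcs[which.max(m$A)], 3, tolerance = 0.15)
  # a narrowly tuned cell with (numerically) zero bias overlap keeps its tuning
  popn <- vm_population(100, width = 0.5)
  mn <- adapt_global(popn, bp, A0 = 0.8)
  far <- which.min(circular_distance(popn$best_pcs, 9))
  expect_lt(mn$A[far], 1e-3)
  expect_equal(mn$rates(9)[1, far], mn$rates0(9)[1, far],
               tolerance = 1e-3)
  # decode of test tones adjacent to the bias shifts away from the bias
  for (pc in c(0, 6)) {
    d <- popvec_symmetric(m, pc)
    away <- sign(circular_step(3, pc))
    expect_gt(sign(circular_step(pc, d)) * away, 0)
  }
})

test_that("spread adaptation both dips tuning locally and repels decodes", {
  pop <- vm_population(100, width = 1.5)
  mid <- vm_population(48, width = 1.0)
  bp <- bias_profile(3, 5)
  m <- adapt_spread(pop, mid, bp, A0 = 0.8)
  # zero bias profile leaves the model untouched
  m0 <- adapt_spread(pop, mid, function(pc) rep(0, length(pc)), A0 = 0.8)
  grid <- seq(0, 11.9, by = 0.1)
  expect_equal(m0$rates(grid), m0$rates0(grid))
  # single-cell tuning reduced locally: reduction at bias centre at least
  # 3x the reduction at the antipode, for the cell tuned to the centre
  cell <- which.min(circular_distance(pop$best_pcs, 3))
  red <- m$rates0(grid)[, cell] - m$rates(grid)[, cell]
  at <- function(pc) red[which.min(circular_distance(grid, pc))]
  expect_gt(at(3), 3 * max(at(9), 1e-12))
  # the dip extends somewhat beyond the bias support (input spread)
  expect_gt(at(6.2), 0)
  # decode shifts away from the bias for tones at both bias edges
  for (pc in c(0, 6)) {
    d <- popvec_symmetric(m, pc)
    away <- sign(circular_step(3, pc))
    expect_gt(sign(circular_step(pc, d)) * away, 0)
  }
})

test_that("repulsive shift sign is correct in all 8 bias conditions for global and spread", {
  pop <- vm_population(96, width = 1.5)
  mid <- vm_population(48, width = 1.0)
  for (kind in c("global", "spread")) {
    for (base in c(0, 3, 6, 9)) for (dir in c(1, -1)) {
      ctr <- pitch_class(base + dir * 3)
      bp <- bias_profile(ctr, 5)
      m <- if (kind == "global") adapt_global(pop, bp) else
        adapt_spread(pop, mid, bp)
      for (pc in c(base, pitch_class(base + 6))) {
        d <- popvec_symmetric(m, pc)
        away <- sign(circular_step(ctr, pc))
        expect_gt(sign(circular_step(pc, d)) * away, 0,
                  label = sprintf("%s base %g dir %d pc %g", kind, base, dir, pc))
      }
    }
  }
})

test_that("mid-level activity is a normalized tuning-weighted frame average", {
  mid <- vm_population(48, width = 1.0)
  bin_pcs <- (0:23) / 2
  frame <- rep(0, 24); frame[13] <- 1     # impulse at pitch class 6
  T <- midlevel_activity(mid, frame, bin_pcs)
  expect_equal(mid$best_pcs[which.max(T)], 6, tolerance = 0.13)
  expect_equal(midlevel_activity(mid, rep(0, 24), bin_pcs), rep(0, 48))
  f2 <- rep(0, 24); f2[3] <- 2
  expect_equal(midlevel_activity(mid, frame + f2, bin_pcs),
               T + midlevel_activity(mid, f2, bin_pcs))   # linearity
  expect_error(midlevel_activity(mid, rep(0, 10), bin_pcs), "length")
})

test_that("dynamic adaptation state recovers exponentially and reaches its fixed point", {
  cfg <- model_config(n_cortical = 4L, n_midlevel = 8L)
  pop <- make_population(cfg)
  pop$w_max <- apply(pop$W, 1, max)
  J <- cfg$n_midlevel
  A <- matrix(0.5, 4, J)
  # zero drive for k steps: pure exponential recovery, exact
  Tz <- matrix(0, cfg$n_lags, J)
  Ak <- A
  for (k in 1:7) Ak <- step_dynamic_model(Ak, pop, Tz)$A
  expect_equal(Ak, A * (1 - cfg$F_R)^7, tolerance = 1e-12)
  # F_A = 0: rates equal the pure linear filter output
  cfg0 <- model_config(n_cortical = 4L, n_midlevel = 8L, F_A = 0)
  pop0 <- make_population(cfg0)
  Tr <- matrix(abs(sin(seq_len(cfg$n_lags * J))), cfg$n_lags, J)
  st <- step_dynamic_model(matrix(0, 4, J), pop0, Tr)
  lin <- sapply(1:4, function(i) sum(pop0$W[i, , ] * Tr) / J)
  expect_equal(st$rates, lin)
  expect_equal(st$A, matrix(0, 4, J))
  # constant drive: iterated state matches the algebraic fixed point
  Tc <- matrix(0.02, cfg$n_lags, J)
  Ai <- matrix(0, 4, J)
  for (k in 1:10000) Ai <- step_dynamic_model(Ai, pop, Tc)$A
  d <- sapply(1:4, function(i) colSums(pop$W[i, , ] * Tc) / pop$w_max[i] *
                cfg$n_bins)
  # A* = (A* + F_A d (1 - A*))(1 - F_R), solved per synapse
  FA <- cfg$F_A; FR <- cfg$F_R
  Astar <- t(sapply(1:4, function(i) {
    di <- d[, i]
    (FA * di * (1 - FR)) / (FR + FA * di * (1 - FR))
  }))
  expect_equal(Ai, Astar, tolerance = 1e-8)
})

test_that("directional SSTRFs carry an offset late lobe scaled to a quarter of the peak", {
  cfg <- model_config(n_midlevel = 96L)
  up <- build_directional_sstrf(5, "up", cfg)
  down <- build_directional_sstrf(5, "down", cfg)
  none <- build_directional_sstrf(5, "none", cfg)
  lag_t <- (seq_len(cfg$n_lags) - 1) / cfg$sample_rate
  late <- lag_t >= 0.15 & lag_t <= 0.25
  expect_equal(sum(none[late, ]), 0)
  mid_pcs <- (0:95) / 8
  # down cell: late lobe centred above the best pitch class
  expect_equal(mid_pcs[which.max(down[which(late)[1], ])], 8, tolerance = 0.1)
  expect_equal(mid_pcs[which.max(up[which(late)[1], ])], 2, tolerance = 0.1)
  expect_equal(max(up[late, ]) / max(up[1, ]), 0.25, tolerance = 1e-9)
  # early lags carry the cell's own tuning, peak 1
  expect_equal(mid_pcs[which.max(up[1, ])], 5, tolerance = 0.1)
  expect_equal(max(up[1, ]), 1)
})

test_that("population construction spaces best pitch classes and balances direction classes", {
  pop <- make_population(model_config())
  expect_equal(nrow(pop$meta), 100)
  expect_equal(pop$meta$best_pc, (0:99) * 0.12, tolerance = 1e-12)
  expect_true(all(pop$meta$direction == "none"))
  dirpop <- fx_pop_dir()
  counts <- table(dirpop$meta$direction)
  expect_lte(diff(range(counts)), 1)
  # metadata class matches the constructed late-lobe side for every cell
  tdi <- population_directionality(dirpop)
  expect_true(all(tdi$DI[tdi$direction == "up"] > 0))
  expect_true(all(tdi$DI[tdi$direction == "down"] < 0))
  expect_true(all(abs(tdi$DI[tdi$direction == "none"]) < 1e-9))
})

test_that("model responses are equivariant under rotation of the pitch circle", {
  delta <- 3
  cfg <- model_config(n_cortical = 48L)
  pop <- make_population(cfg)
  pop_rot <- make_population(cfg, best_pcs = pitch_class(pop$meta$best_pc + delta))
  sq <- generate_biased_pair_set(stimulus_config(base_pcs = 0, lengths = 5L,
                                                 n_rand = 1L, directions = "up"),
                                 seed = 11)[[1]]
  sq_rot <- sq
  sq_rot$events$pitch_class <- pitch_class(sq$events$pitch_class + delta)
  r1 <- run_dynamic_model(pop, to_spectrogram(sq, 20, 24))
  r2 <- run_dynamic_model(pop_rot, to_spectrogram(sq_rot, 20, 24))
  # rotating stimulus and population together leaves every rate unchanged
  expect_equal(r2$rates, r1$rates, tolerance = 1e-9)
})
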