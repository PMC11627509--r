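# Shared fixtures, built once per test run and memoized. All synthetic
# data is generated in code under fixed seeds; the heavier dynamic-model
# simulations are shared across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures))
    assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# canonical biased-pair stimulus set (32 sequences, 240 bias tones)
fx_pair <- function() fixture("pair", function()
  generate_biased_pair_set(stimulus_config(), seed = 2))

# gap-crossed pair set for the shift-decay analyses (96 sequences)
fx_pair_gaps <- function() fixture("pair_gaps", function()
  generate_biased_pair_set(stimulus_config(expand_gaps = TRUE), seed = 2))

# pair set with the ablation pause (0.3 s)
fx_pair_abl <- function() fixture("pair_abl", function()
  generate_biased_pair_set(stimulus_config(gaps = 0.3), seed = 2))

# non-directional dynamic population at study defaults (N = 100)
fx_pop100 <- function() fixture("pop100", function()
  make_population(model_config()))

# directional thirds population (N = 500)
fx_pop_dir <- function() fixture("pop_dir", function()
  make_population(model_config(n_cortical = 500L,
                               direction_mix = c(none = 1, up = 1, down = 1))))

# noisy simulated experiment: gap-crossed pairs on the N = 100 population
fx_sim_shift <- function() fixture("sim_shift", function()
  simulate_experiment(fx_pair_gaps(), fx_pop100(), noise_config(n_reps = 10),
                      seed = 4, pad_s = 1))

# noisy simulated experiment: ablation-pause pairs on the directional population
fx_sim_dir <- function() fixture("sim_dir", function()
  simulate_experiment(fx_pair_abl(), fx_pop_dir(), noise_config(n_reps = 10),
                      seed = 4, pad_s = 1))

# SSTRF fit + directionality table for the directional simulation
fx_di_dir <- function() fixture("di_dir", function()
  directionality_index(estimate_sstrf(fx_sim_dir())))

# heterogeneous non-directional cohort (calibration-matched conditions)
fx_cohort <- function() fixture("cohort", function()
  emulate_recorded_cohort(
    cohort_config(n = 300L, direction_mix = c(none = 1, up = 0, down = 0)),
    model_config(), seed = 5))

fx_sim_cohort <- function() fixture("sim_cohort", function()
  simulate_experiment(fx_pair(), fx_cohort(), noise_config(n_reps = 10),
                      seed = 6, pad_s = 4))

# biased-tuning simulation on the cohort
fx_sim_tuning <- function() fixture("sim_tuning", function()
  simulate_experiment(generate_biased_tuning_set(stimulus_config(), seed = 3),
                      fx_cohort(),
                      noise_config(n_reps = 6, keep_trials = FALSE),
                      seed = 7, pad_s = 0.5))

# population-vector decode of noiseless non-dynamic model responses with a
# uniform preference prior (symmetric-population oracle conditions). The
# per-cell rate normalization uses the unadapted maximum: in the
# data-driven pipeline the empirical maximum over the many training tones
# approximates it, while normalizing by the adapted curve's own maximum
# would re-inflate adapted cells and cancel the effect under test.
popvec_symmetric <- function(model, test_pcs, grid_step = 0.1) {
  grid <- seq(0, 12 - grid_step, by = grid_step)
  mx <- apply(model$rates0(grid), 2, max)
  population_vector_decode(model$rates(test_pcs), model$pop$best_pcs, mx,
                           bf_prior = rep(1, model$pop$n))
}
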