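# End-to-end orchestration: run configuration, calibration of the
# adaptation constants against the reported time courses, the full
# generate -> simulate -> select -> decode -> directional -> adaptation
# pipeline, and report/CSV output.

#' Assemble a full run configuration
#'
#' Bundles the stimulus, model, cohort and noise configurations with the
#' master seed and output directory. A run is reproducible from this
#' object alone.
#'
#' @param stimulus a [stimulus_config()].
#' @param model a [model_config()].
#' @param cohort a [cohort_config()].
#' @param noise a [noise_config()].
#' @param seed master seed; stage seeds are derived from it.
#' @param out_dir output directory (`NULL` = no files written).
#' @param run_tuning include the biased-tuning paradigm stage.
#' @param run_ablations include the no-adaptation / no-directional-cells
#'   ablation models in the differential-map stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(stimulus = stimulus_config(), model = model_config(),
                       cohort = cohort_config(), noise = noise_config(),
                       seed = 1L, out_dir = NULL, run_tuning = TRUE,
                       run_ablations = TRUE) {
  structure(list(stimulus = stimulus, model = model, cohort = cohort,
                 noise = noise, seed = as.integer(seed), out_dir = out_dir,
                 run_tuning = run_tuning, run_ablations = run_ablations),
            class = "run_config")
}

#' Save / load a run configuration as YAML
#'
#' @param cfg a [run_config()].
#' @param path YAML file path.
#' @return `save_config` returns `path` invisibly; `load_config` returns
#'   the reconstructed `run_config`.
#' @export
save_config <- function(cfg, path) {
  plain <- lapply(unclass(cfg), function(x)
    if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  fix <- function(x, ctor) do.call(ctor, lapply(x, function(v)
    if (is.list(v)) unlist(v) else v))
  run_config(stimulus = fix(raw$stimulus, stimulus_config),
             model = fix(raw$model, model_config),
             cohort = fix(raw$cohort, cohort_config),
             noise = fix(raw$noise, noise_config),
             seed = raw$seed, out_dir = raw$out_dir,
             run_tuning = raw$run_tuning, run_ablations = raw$run_ablations)
}

# derive a stage seed below 2^31 from the master seed
stage_seed <- function(seed, k) (as.integer(seed) * 101L + k * 9973L) %% 2100000000L

#' Calibrate the adaptation constants to the reported time courses
#'
#' Sets `F_R` from the closed form `1 - exp(-1/(sr * tau_rec))` to match
#' the target recovery time constant, then searches `F_A` so that the
#' population onset response over a 10-tone bias train decays with the
#' target build-up time constant to the target plateau depth (squared
#' log-error objective).
#'
#' With first-order depression kinetics the three reported time-course
#' values are not jointly attainable: once recovery is pinned at 1.2 s,
#' a build-up time constant of 3.9 stimuli mathematically implies a
#' synapse-level plateau near 54% (build-up rate = adaptation rate +
#' recovery rate), which dilutes to roughly 30% at the population PSTH
#' level -- well above 13%. The default targets therefore calibrate the
#' two kinetic constants (build-up and recovery); a `plateau_frac`
#' target may be added, in which case the search minimises the joint
#' squared log-error and lands on a compromise.
#'
#' @param cfg a [model_config()] to update.
#' @param targets list with any of `buildup_tau_stimuli` (default 3.9),
#'   `recovery_tau_s` (default 1.2), `plateau_frac` (no default);
#'   supplying none is an error.
#' @param seed seed for the calibration stimuli.
#' @param gain,baseline_hz rate conversion used for the PSTH-like
#'   measure (defaults from [noise_config()]).
#' @return the updated `model_config`, with a `calibration` attribute
#'   recording targets, achieved values and the search diagnostics.
#' @export
calibrate <- function(cfg = model_config(),
                      targets = list(buildup_tau_stimuli = 3.9,
                                     recovery_tau_s = 1.2),
                      seed = 1L, gain = 3500, baseline_hz = 2) {
  if (length(targets) == 0) stop("no calibration targets supplied (ill-posed)")
  if (!is.null(targets$recovery_tau_s))
    cfg$F_R <- 1 - exp(-1 / (cfg$sample_rate * targets$recovery_tau_s))
  if (is.null(targets$buildup_tau_stimuli) && is.null(targets$plateau_frac))
    return(cfg)
  scfg <- stimulus_config(lengths = 10L, n_rand = 1L, gaps = 0.5)
  seqs <- generate_biased_pair_set(scfg, seed = seed)
  measure <- function(F_A) {
    m <- cfg; m$F_A <- F_A
    pop <- make_population(m)
    onset <- vapply(seqs, function(sq) {
      spect <- to_spectrogram(sq, m$sample_rate, m$n_bins)
      run <- run_dynamic_model(pop, spect)
      ali <- run$alignment
      first_fr <- vapply(which(sq$events$role == "bias"), function(k)
        ali$frame[ali$event == k][1], 0L)
      lam <- gain * (run$rates + run$spont) + baseline_hz
      rowMeans(lam)[first_fr]
    }, numeric(sum(seqs[[1]]$events$role == "bias")))
    y <- rowMeans(onset)
    f <- fit_exp_series(y)
    if (is.null(f)) return(NULL)
    r1 <- f$a + f$b * exp(-1 / f$tau)
    list(tau = f$tau, depth = (r1 - f$a) / r1)
  }
  loss <- function(F_A) {
    m <- measure(F_A)
    if (is.null(m) || !is.finite(m$tau) || m$depth <= 0) return(1e6)
    l <- 0
    if (!is.null(targets$buildup_tau_stimuli))
      l <- l + log(m$tau / targets$buildup_tau_stimuli)^2
    if (!is.null(targets$plateau_frac))
      l <- l + log(m$depth / targets$plateau_frac)^2
    l
  }
  opt <- stats::optimize(loss, c(0.02, 0.95), tol = 5e-3)
  cfg$F_A <- opt$minimum
  ach <- measure(cfg$F_A)
  attr(cfg, "calibration") <- list(targets = targets, F_A = cfg$F_A,
                                   F_R = cfg$F_R, achieved = ach,
                                   loss = opt$objective)
  if (opt$objective > 0.5)
    warning("calibration search did not reach the targets closely; best found returned")
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes generate -> simulate -> select -> decode (PCA and population
#' vector) -> directional analyses -> adaptation analyses on the
#' synthetic cohort, and assembles the headline metrics into a report.
#' With an `out_dir`, stage outputs are written as CSV and the report as
#' JSON.
#'
#' @param cfg a [run_config()].
#' @return list of class `run_report` with elements `shift` (PCA-decoded
#'   shift result), `shift_popvec`, `decode_quality` (circular
#'   correlation on the training set), `selection`, `directional`
#'   (per-tone predictions and accuracy table), `near_tone` (p-values
#'   for the full model and any ablations), `adaptation` (adapting
#'   fraction, build-up tau/plateau, recovery tau), `tuning`
#'   (biased-tuning summary, if run), `config`, `files`.
#' @export
run_all <- function(cfg = run_config()) {
  t0 <- Sys.time()
  stages <- list()
  # --- stimuli ---
  pair_cfg <- cfg$stimulus; pair_cfg$expand_gaps <- TRUE
  pair <- generate_biased_pair_set(pair_cfg, seed = stage_seed(cfg$seed, 1L))
  # --- cohort + simulation ---
  pop <- emulate_recorded_cohort(cfg$cohort, cfg$model,
                                 seed = stage_seed(cfg$seed, 2L))
  sim <- simulate_experiment(pair, pop, cfg$noise,
                             seed = stage_seed(cfg$seed, 3L), pad_s = 1)
  # --- unit selection ---
  keep <- select_units(sim)
  stages$selection <- list(n_total = nrow(pop$meta), n_selected = length(keep))
  # --- decoding ---
  dec_pca <- decode_experiment(sim, "pca", cells = keep)
  dec_pv <- decode_experiment(sim, "popvec", cells = keep)
  shift <- measure_bias_shift(dec_pca)
  shift_pv <- measure_bias_shift(dec_pv)
  emb <- attr(dec_pca, "decoder")
  train_dec <- decode_pitch(emb, event_responses(sim)[
    sim$events$role %in% c("bias", "lead_in"), keep, drop = FALSE])
  train_pc <- sim$events$pitch_class[sim$events$role %in%
                                       c("bias", "lead_in")]
  dq <- list(
    circular_cor = circular_cor_pc(train_dec, train_pc),
    pearson_r = stats::cor(train_pc,
                           train_pc + circular_step(train_pc, train_dec)))
  # --- directional analyses ---
  fit <- estimate_sstrf(sim, cells = keep)
  di <- directionality_index(fit)
  dd <- directional_decode_experiment(sim, di)
  acc <- aggregate(correct ~ role + length, data = dd, FUN = mean)
  map <- differential_response_map(sim, di)
  near <- list(full = near_tone_test(map)$p_value)
  if (isTRUE(cfg$run_ablations)) {
    near <- c(near, run_ablation_maps(pair, cfg, seed = cfg$seed))
  }
  # --- adaptation analyses ---
  psth10 <- psth_windows(sim, roles = "bias")
  labels <- vapply(keep, function(i) {
    rt <- classify_response_type(psth10[, , i], soa = cfg$stimulus$soa)
    rt$label
  }, "")
  pop_fit <- classify_response_type(rowMeans(psth10[, , keep, drop = FALSE],
                                             dims = 2),
                                    soa = cfg$stimulus$soa)
  # dedicated recovery simulation: long post-bias silence
  rec_stim <- cfg$stimulus; rec_stim$lengths <- 10L; rec_stim$n_rand <- 1L
  rec_stim$gaps <- 0.5
  rec_seqs <- generate_biased_pair_set(rec_stim,
                                       seed = stage_seed(cfg$seed, 6L))
  rec_sim <- simulate_experiment(rec_seqs, pop, cfg$noise,
                                 seed = stage_seed(cfg$seed, 7L), pad_s = 5)
  rec <- recovery_trace(rec_sim, cells = keep)
  recf <- recovery_fit(rec$t, rec$rate)
  stages$adaptation <- list(
    adapting_fraction = mean(labels == "adapting"),
    buildup_tau_stimuli = pop_fit$tau_stimuli,
    plateau_frac = (pop_fit$initial_rate - pop_fit$asymptote_rate) /
      pop_fit$initial_rate,
    recovery_tau_s = recf$tau_seconds)
  # --- biased tuning (optional, heavier) ---
  tuning <- NULL
  if (isTRUE(cfg$run_tuning)) {
    tun_seqs <- generate_biased_tuning_set(cfg$stimulus,
                                           seed = stage_seed(cfg$seed, 4L))
    tnoise <- cfg$noise; tnoise$keep_trials <- FALSE
    tnoise$n_reps <- cfg$stimulus$repeats
    tsim <- simulate_experiment(tun_seqs, pop, tnoise,
                                seed = stage_seed(cfg$seed, 5L), pad_s = 0.5)
    tc <- biased_tuning(tsim, cells = keep)
    tuning <- list(inside_reduction = tc$inside_reduction,
                   outside_reduction = tc$outside_reduction,
                   inside_ratio = tc$inside_ratio,
                   comparison = tc)
  }
  report <- structure(list(
    shift = shift, shift_popvec = shift_pv, decode_quality = dq,
    selection = stages$selection, directional = list(predictions = dd,
                                                     accuracy = acc),
    near_tone = near, adaptation = stages$adaptation, tuning = tuning,
    di = di, config = cfg,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "run_report")
  if (!is.null(cfg$out_dir)) report$files <- write_report(report, cfg$out_dir)
  report
}

# differential maps for the ablation models (no adaptation; no
# directional cells) on a homogeneous 500-cell population; uses its own
# stimulus set with a 0.3 s bias-to-pair pause -- the shortest pause at
# which the SSTRF's 150-250 ms lags cannot read the bias frames directly,
# so any up/down difference must pass through the adaptation state
run_ablation_maps <- function(pair, cfg, seed = 1L) {
  abl_stim <- cfg$stimulus
  abl_stim$gaps <- 0.3
  abl_stim$expand_gaps <- FALSE
  pair <- generate_biased_pair_set(abl_stim, seed = stage_seed(seed, 9L))
  base <- cfg$model
  base$n_cortical <- 500L
  base$direction_mix <- c(none = 1, up = 1, down = 1)
  variants <- list(
    full_model = base,
    no_adaptation = {
      m <- base; m$F_A <- 0; m
    },
    no_directional = {
      m <- base; m$direction_mix <- c(none = 1, up = 0, down = 0); m
    })
  out <- list()
  breaks <- NULL   # DI axis of the full model, shared across ablations
  for (nm in names(variants)) {
    pop <- make_population(variants[[nm]])
    sim <- simulate_experiment(pair, pop, cfg$noise,
                               seed = stage_seed(seed, 10L + match(nm, names(variants))),
                               pad_s = 1)
    fit <- estimate_sstrf(sim)
    di <- directionality_index(fit)
    map <- differential_response_map(sim, di, di_breaks = breaks)
    if (nm == "full_model") breaks <- map$di_breaks
    out[[nm]] <- near_tone_test(map)$p_value
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("== Shepard-tone adaptation pipeline report ==\n")
  cat(sprintf("Units selected: %d / %d\n", x$selection$n_selected,
              x$selection$n_total))
  cat(sprintf("Training-set decode: circular correlation %.3f, aligned Pearson r %.3f\n",
              x$decode_quality$circular_cor, x$decode_quality$pearson_r))
  print(x$shift)
  cat(sprintf("Adapting fraction: %.2f; build-up tau %.2f stimuli; plateau %.1f%%; recovery tau %.2f s\n",
              x$adaptation$adapting_fraction, x$adaptation$buildup_tau_stimuli,
              100 * x$adaptation$plateau_frac, x$adaptation$recovery_tau_s))
  cat("Directional prediction accuracy (fraction of conditions):\n")
  print(x$directional$accuracy)
  cat("Near-tone ANOVA p-values:\n")
  str(x$near_tone)
  invisible(x)
}

# write the report's tables as CSV and headline metrics as JSON
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  wr(report$shift$per_tone, "decoded_shifts_pca.csv")
  wr(report$shift_popvec$per_tone, "decoded_shifts_popvec.csv")
  wr(report$directional$predictions, "directional_predictions.csv")
  wr(report$di, "directionality_indices.csv")
  headline <- list(
    decode_circular_cor = report$decode_quality,
    mean_shift_st = mean(report$shift$per_tone$shift_away, na.rm = TRUE),
    adapting_fraction = report$adaptation$adapting_fraction,
    buildup_tau_stimuli = report$adaptation$buildup_tau_stimuli,
    plateau_frac = report$adaptation$plateau_frac,
    recovery_tau_s = report$adaptation$recovery_tau_s,
    near_tone_p = report$near_tone,
    n_selected = report$selection$n_selected)
  p <- file.path(out_dir, "report.json")
  jsonlite::write_json(headline, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(files, p)
}
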