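# Synthetic population responses: turn noiseless dynamic-model rates into
# trial-resolved Poisson spike counts in 50 ms bins (the stand-in for the
# recorded dataset), apply the unit-selection rule, and draw heterogeneous
# recorded-like cohorts.

#' Noise configuration for the response simulator
#'
#' @param gain model-rate to Hz conversion factor.
#' @param baseline_hz unadapting spontaneous floor added to every bin, Hz.
#' @param n_reps repetitions per stimulus sequence (default 10, as in the
#'   recording paradigm).
#' @param mode `"spikes"` (Poisson counts) or `"rate"` (noiseless; counts
#'   equal expected values).
#' @param keep_trials keep the per-trial count array (set `FALSE` for
#'   large runs; trial means are always kept).
#' @return named list of class `noise_config`.
#' @export
noise_config <- function(gain = 3500, baseline_hz = 2, n_reps = 10L,
                         mode = c("spikes", "rate"), keep_trials = TRUE) {
  if (gain < 0 || baseline_hz < 0) stop("gain and baseline must be nonnegative")
  structure(list(gain = gain, baseline_hz = baseline_hz,
                 n_reps = as.integer(n_reps), mode = match.arg(mode),
                 keep_trials = keep_trials),
            class = "noise_config")
}

# windows tiling one SOA: onset 0-50, sustained 50-100, offset 100-150 ms
window_names <- c("onset", "sustained", "offset")

#' Simulate a recorded experiment on the dynamic model
#'
#' Runs the dynamic model over every sequence and draws per-trial spike
#' counts in 50 ms bins: `counts ~ Poisson((gain * rate_i(t) *
#' rate_gain_i + baseline) * 0.05)`, with the model's adapting
#' spontaneous rate included in `rate_i(t)`. Each sequence is simulated
#' from a fully recovered state (trials were separated by ~5 s pauses).
#'
#' @param sequences list of `tone_sequence` objects.
#' @param pop a [make_population()] / [emulate_recorded_cohort()] population.
#' @param noise a [noise_config()].
#' @param seed integer seed; same seed reproduces counts exactly.
#' @param pad_s silence appended after each sequence (seconds); provides
#'   baseline bins for unit selection and recovery fitting.
#' @return object of class `sim_experiment`: list with
#'   \describe{
#'   \item{mean_counts}{bins x cells matrix of trial-averaged counts}
#'   \item{counts}{bins x cells x reps array (if `keep_trials`)}
#'   \item{lambda}{bins x cells expected Hz (noiseless)}
#'   \item{bin_info}{data.frame per bin: sequence index, time, event index
#'     within sequence (NA for silence), window label}
#'   \item{events}{schedule with global event ids and bias metadata}
#'   \item{meta}{per-neuron metadata}
#'   }
#' @export
simulate_experiment <- function(sequences, pop, noise = noise_config(),
                                seed = 1L, pad_s = 1) {
  cfg <- pop$cfg
  stopifnot(length(sequences) >= 1)
  bin_dur <- 1 / cfg$sample_rate
  lam_l <- list(); info_l <- list(); ev_l <- list()
  for (si in seq_along(sequences)) {
    sq <- sequences[[si]]
    spect <- to_spectrogram(sq, cfg$sample_rate, cfg$n_bins, pad_s = pad_s)
    run <- run_dynamic_model(pop, spect)
    lam <- noise$gain * (run$rates + run$spont) *
      rep(pop$meta$rate_gain, each = nrow(run$rates)) + noise$baseline_hz
    n_fr <- nrow(lam)
    ev <- sq$events
    event_of <- rep(NA_integer_, n_fr); win <- rep(NA_character_, n_fr)
    frames_per_soa <- length(window_names)
    for (k in seq_len(nrow(ev))) {
      f0 <- which(attr(spect, "alignment")$event == k)
      f0 <- attr(spect, "alignment")$frame[f0][1]   # first on-frame
      idx <- f0 + seq_len(frames_per_soa) - 1L
      idx <- idx[idx <= n_fr & is.na(event_of[idx])]
      event_of[idx] <- k
      win[idx] <- window_names[seq_along(idx)]
    }
    lam_l[[si]] <- lam
    info_l[[si]] <- data.frame(seq = si, t = (seq_len(n_fr) - 0.5) * bin_dur,
                               event = event_of, window = win)
    ev$seq <- si
    ev_l[[si]] <- ev
  }
  lambda <- do.call(rbind, lam_l)
  bin_info <- do.call(rbind, info_l)
  events <- do.call(rbind, ev_l)
  events$sequence_id <- rep(vapply(sequences, `[[`, "", "id"),
                            vapply(ev_l, nrow, 0L))
  events$event_index <- unlist(lapply(ev_l, function(e) seq_len(nrow(e))))
  events$global_event <- seq_len(nrow(events))
  nb <- nrow(lambda); nc <- ncol(lambda)
  mu <- lambda * bin_dur
  if (noise$mode == "rate") {
    counts <- if (noise$keep_trials)
      array(mu, dim = c(nb, nc, noise$n_reps)) else NULL
    mean_counts <- mu
  } else {
    with_seed(seed, {
      if (noise$keep_trials) {
        counts <- array(stats::rpois(nb * nc * noise$n_reps, rep(mu, noise$n_reps)),
                        dim = c(nb, nc, noise$n_reps))
        mean_counts <- apply(counts, c(1, 2), mean)
      } else {
        counts <- NULL
        mean_counts <- matrix(stats::rpois(nb * nc, noise$n_reps * mu),
                              nb, nc) / noise$n_reps
      }
    })
  }
  structure(list(mean_counts = mean_counts, counts = counts, lambda = lambda,
                 bin_info = bin_info, events = events, meta = pop$meta,
                 bin_dur = bin_dur, n_reps = noise$n_reps,
                 sequences = sequences, noise = noise),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("Simulated experiment: %d sequences, %d cells, %d x 50 ms bins, %d reps (%s)\n",
              length(x$sequences), ncol(x$mean_counts), nrow(x$mean_counts),
              x$n_reps, x$noise$mode))
  invisible(x)
}

#' Per-event response table
#'
#' Trial-averaged response rate (Hz) of every cell to every tone, by
#' response window.
#'
#' @param sim a [simulate_experiment()] result.
#' @param windows subset of `c("onset", "sustained", "offset")` to
#'   average over (default all three).
#' @return events x cells matrix of rates (Hz); rownames are global event
#'   ids, aligned with `sim$events`.
#' @export
event_responses <- function(sim, windows = window_names) {
  stopifnot(all(windows %in% window_names))
  sel <- !is.na(sim$bin_info$event) & sim$bin_info$window %in% windows
  key <- interaction(sim$bin_info$seq[sel], sim$bin_info$event[sel],
                     drop = TRUE)
  out <- rowsum(sim$mean_counts[sel, , drop = FALSE], key) /
    as.vector(table(key)) / sim$bin_dur
  # rowsum orders by factor level; map back to global event order
  lev <- levels(key)
  seq_ev <- do.call(rbind, strsplit(lev, ".", fixed = TRUE))
  ord <- order(as.integer(seq_ev[, 1]), as.integer(seq_ev[, 2]))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- sim$events$global_event
  out
}

#' Select responsive, Shepard-tuned units
#'
#' Reproduces the recording study's unit-selection rule on simulated
#' data: keep cells that (i) are significantly driven (one-sided
#' Wilcoxon signed-rank of per-trial driven rate vs per-trial baseline
#' rate) and (ii) respond differentially across Shepard pitch classes
#' (Kruskal-Wallis over per-trial tone responses grouped into pitch-class
#' bins). Thresholds are deliberately not critical.
#'
#' @param sim a [simulate_experiment()] result with per-trial counts.
#' @param alpha significance level for the tuning (Kruskal-Wallis) test.
#' @param driven_alpha significance level for the driven-rate test.
#' @param pc_bins number of pitch-class bins for the tuning test.
#' @return integer vector of selected cell indices, with attributes
#'   `driven_p` and `tuning_p`.
#' @export
select_units <- function(sim, alpha = 0.05, driven_alpha = 0.05,
                         pc_bins = 12L) {
  if (is.null(sim$counts)) stop("select_units needs per-trial counts (keep_trials = TRUE)")
  if (sim$n_reps < 2) stop("need at least 2 repetitions")
  on_bins <- !is.na(sim$bin_info$event) &
    sim$bin_info$window %in% c("onset", "sustained")
  base_bins <- is.na(sim$bin_info$event)
  if (!any(base_bins)) stop("no baseline bins; simulate with pad_s > 0")
  nc <- dim(sim$counts)[2]
  ev_bins <- !is.na(sim$bin_info$event) & sim$bin_info$window == "onset"
  key <- interaction(sim$bin_info$seq[ev_bins], sim$bin_info$event[ev_bins],
                     drop = TRUE)
  pcs <- sim$events$pitch_class
  names(pcs) <- paste(sim$events$seq, sim$events$event_index, sep = ".")
  pc_bin <- factor((floor(pitch_class(pcs[as.character(key)]) *
                            pc_bins / 12) %% pc_bins))
  driven_p <- tuning_p <- rep(NA_real_, nc)
  for (i in seq_len(nc)) {
    drv <- colMeans(sim$counts[on_bins, i, ])
    bas <- colMeans(sim$counts[base_bins, i, ])
    driven_p[i] <- tryCatch(
      stats::wilcox.test(drv, bas, paired = TRUE, alternative = "greater",
                         exact = FALSE)$p.value,
      error = function(e) 1)
    resp <- rowMeans(sim$counts[ev_bins, i, , drop = FALSE])
    tuning_p[i] <- tryCatch(
      stats::kruskal.test(resp, pc_bin)$p.value, error = function(e) 1)
  }
  keep <- which(driven_p < driven_alpha & tuning_p < alpha)
  attr(keep, "driven_p") <- driven_p
  attr(keep, "tuning_p") <- tuning_p
  keep
}

#' Cohort configuration for the recorded-like synthetic population
#'
#' Defaults emulate the selected recorded population: 662 units, tuning
#' halfwidths concentrated in the 2--3 st range (lognormal), 91%
#' adapting, direction classes mixed in thirds, lognormal rate gains,
#' best pitch classes drawn uniformly (hence unevenly sampled, which the
#' population-vector decoder's preference prior compensates).
#'
#' @param ... named overrides.
#' @return named list of class `cohort_config`.
#' @export
cohort_config <- function(...) {
  cfg <- list(n = 662L, halfwidth_meanlog = log(2.5), halfwidth_sdlog = 0.2,
              halfwidth_min = 1.8, halfwidth_max = 8,
              adapting_fraction = 0.91,
              direction_mix = c(none = 1 / 3, up = 1 / 3, down = 1 / 3),
              rate_gain_sdlog = 0.4)
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  class(cfg) <- "cohort_config"
  cfg
}

# invert the von Mises half-height full width (semitones) to sigma
halfwidth_to_sigma <- function(hw) {
  th <- hw * pi / 12
  kap <- log(2) / (1 - cos(th))
  1 / ((2 * pi / 12) * sqrt(kap))
}

#' Draw a heterogeneous, recorded-like model population
#'
#' Samples per-cell best pitch classes, tuning widths (set so the
#' realized cortical tuning, after mid-level spread, has the configured
#' halfwidth), direction classes, adapting flags and rate gains, and
#' builds the corresponding dynamic-model population.
#'
#' @param cohort a [cohort_config()].
#' @param model_cfg a [model_config()] (its `n_cortical` is overridden
#'   by the cohort size).
#' @param seed integer seed.
#' @return a `model_population` whose `meta` additionally carries
#'   `halfwidth_target` and `adapting`.
#' @export
emulate_recorded_cohort <- function(cohort = cohort_config(),
                                    model_cfg = model_config(),
                                    seed = 1L) {
  with_seed(seed, {
    n <- cohort$n
    best <- stats::runif(n, 0, 12)
    hw <- pmin(pmax(stats::rlnorm(n, cohort$halfwidth_meanlog,
                                  cohort$halfwidth_sdlog),
                    cohort$halfwidth_min), cohort$halfwidth_max)
    # realized tuning ~ convolution of cortical and mid-level von Mises:
    # sigma_eff^2 ~ sigma_c^2 + sigma_m^2
    sig_t <- halfwidth_to_sigma(hw)
    sig_c <- sqrt(pmax(sig_t^2 - model_cfg$width_midlevel^2, 0.05^2))
    dirs <- sample(names(cohort$direction_mix), n, replace = TRUE,
                   prob = cohort$direction_mix)
    adapting <- stats::runif(n) < cohort$adapting_fraction
    rg <- stats::rlnorm(n, 0, cohort$rate_gain_sdlog)
    pop <- make_population(model_cfg, best_pcs = best, widths = sig_c,
                           dirs = dirs, adapt_gain = as.numeric(adapting),
                           rate_gain = rg)
    pop$meta$halfwidth_target <- hw
    pop$meta$adapting <- adapting
    pop
  })
}
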