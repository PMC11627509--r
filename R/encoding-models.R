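# Encoding models: von Mises Shepard tuning, the three non-dynamic
# adaptation variants (local / global / local-with-spread), and the
# dynamic SSTRF + synaptic-depression population model with optional
# direction-selective cells.

# kappa of the period-12 von Mises for a width sigma in semitones
vm_kappa <- function(sigma) 1 / ((2 * pi / 12) * sigma)^2

# peak-normalized period-12 von Mises curve (peak 1 at mu)
vm_peak1 <- function(pc, mu, sigma) {
  exp(vm_kappa(sigma) * (cos(2 * pi / 12 * (pc - mu)) - 1))
}

#' Von Mises Shepard tuning curve
#'
#' Each model neuron's tuning over the circular pitch-class space is a
#' period-12 von Mises curve
#' `M(S) = exp(cos(2*pi/12*(S - phi)) / ((2*pi/12)*sigma)^2) / M_total`,
#' with best pitch class `phi` and width `sigma`, both in semitones.
#' `M_total` normalizes either the area over one octave to 1
#' (`"area_one"`) or the peak to 1 (`"peak_one"`).
#'
#' @param best_pc best pitch class `phi` in semitones.
#' @param width tuning width `sigma` in semitones (> 0).
#' @param peak_rate multiplicative rate scale applied after normalization.
#' @param normalization `"area_one"` or `"peak_one"`.
#' @return object of class `von_mises_tuning`.
#' @export
von_mises_tuning <- function(best_pc, width, peak_rate = 1,
                             normalization = c("area_one", "peak_one")) {
  if (width <= 0) stop("tuning width must be > 0")
  structure(list(best_pc = pitch_class(best_pc), width = width,
                 peak_rate = peak_rate,
                 normalization = match.arg(normalization)),
            class = "von_mises_tuning")
}

#' Evaluate a von Mises tuning curve
#'
#' @param tuning a [von_mises_tuning()].
#' @param pc pitch class(es) in semitones at which to evaluate.
#' @return nonnegative rate(s); vectorised over `pc`.
#' @export
von_mises_response <- function(tuning, pc) {
  stopifnot(inherits(tuning, "von_mises_tuning"))
  k <- vm_kappa(tuning$width)
  f <- vm_peak1(pc, tuning$best_pc, tuning$width)
  if (tuning$normalization == "area_one") {
    # area over [0,12) of exp(k*(cos(theta)-1)) is 12 * I0(k) * exp(-k)
    f <- f / (12 * besselI(k, 0, expon.scaled = TRUE))
  }
  tuning$peak_rate * f
}

#' Boxcar bias profile over the pitch circle
#'
#' Idealised continuous bias occupancy `S_Bias(phi)`: 1 inside the
#' circular interval `center +/- range/2`, 0 outside.
#'
#' @param center bias centre pitch class in semitones.
#' @param range bias width in semitones (< 12).
#' @return function of pitch class returning values in \{0, 1\}.
#' @export
bias_profile <- function(center, range = 5) {
  stopifnot(range > 0, range < 12)
  function(pc) as.numeric(circular_distance(pc, center) <= range / 2 + 1e-12)
}

#' Population of von Mises-tuned neurons (non-dynamic models)
#'
#' `N` neurons with best pitch classes equally spaced over `[0, 12)`.
#'
#' @param n number of cortical neurons (default 100).
#' @param width tuning width sigma in semitones.
#' @param normalization passed to [von_mises_tuning()].
#' @return object of class `vm_population` with fields `best_pcs`,
#'   `width`, `tunings`.
#' @export
vm_population <- function(n = 100, width = 1.5,
                          normalization = "area_one") {
  best_pcs <- (seq_len(n) - 1) * 12 / n
  structure(list(best_pcs = best_pcs, width = width, n = n,
                 normalization = normalization,
                 tunings = lapply(best_pcs, von_mises_tuning, width = width,
                                  normalization = normalization)),
            class = "vm_population")
}

# stimuli x neurons matrix of unadapted responses
population_rates <- function(pop, pcs) {
  matrix(vapply(pop$tunings, von_mises_response, numeric(length(pcs)),
                pc = pcs),
         nrow = length(pcs))
}

#' Non-dynamic adaptation models (local, global, local-with-spread)
#'
#' Three idealised accounts of how a bias sequence reshapes the
#' population response to a subsequent test tone:
#' \describe{
#' \item{`adapt_local()`}{purely stimulus-specific adaptation
#'   `R_i(S) = (1 - A0 * S_Bias(S)) * M_i(S)`: responses to previously
#'   presented stimuli are scaled down with no transfer, which rescales
#'   the whole population response to a given test tone and therefore
#'   leaves its decoded pitch unchanged.}
#' \item{`adapt_global()`}{whole-tuning-curve fatigue
#'   `R_i(S) = (1 - A_i) * M_i(S)` with
#'   `A_i = A0 * <S_Bias>_{M_i}` (the M_i-weighted average bias
#'   occupancy): neurons tuned near the bias adapt most, repelling the
#'   decoded pitch of nearby test tones.}
#' \item{`adapt_spread()`}{local adaptation on the connections from a
#'   distributed mid-level representation:
#'   `R_i(S) = 1/J * sum_j M_i(j) (1 - A(j)) T_j(S)` with
#'   `A(j) = A0 * <S_Bias>_{M_j}`: reproduces both the local tuning-curve
#'   dip and the repulsive decoded shift.}
#' }
#'
#' @param pop a [vm_population()].
#' @param bias_prof function over `[0, 12)` with values in `[0, 1]`
#'   (e.g. [bias_profile()]).
#' @param A0 maximal adaptation fraction in `[0, 1]` (default 0.8).
#' @param midlevel a [vm_population()] for the mid-level layer
#'   (`adapt_spread` only).
#' @param grid_n integration grid size over the octave.
#' @return object of class `nd_model`: a list with `rates(pcs)` (stimuli
#'   x neurons response matrix), the per-cell/per-channel adaptation, and
#'   the unadapted `rates0(pcs)`.
#' @name nondynamic_models
NULL

check_A0 <- function(A0) {
  if (A0 < 0 || A0 > 1) stop("A0 must lie in [0, 1]")
  A0
}

new_nd_model <- function(kind, rates, rates0, A, pop) {
  structure(list(kind = kind, rates = rates, rates0 = rates0, A = A,
                 pop = pop), class = "nd_model")
}

#' @rdname nondynamic_models
#' @export
adapt_local <- function(pop, bias_prof, A0 = 0.8) {
  check_A0(A0)
  rates0 <- function(pcs) population_rates(pop, pcs)
  rates <- function(pcs) (1 - A0 * bias_prof(pcs)) * rates0(pcs)
  new_nd_model("local", rates, rates0, NULL, pop)
}

# M-weighted average of the bias profile: overlap integral normalized so
# full coverage gives 1 (bounds A within [0, A0])
overlap_frac <- function(best_pcs, width, bias_prof, grid_n = 1200) {
  grid <- (seq_len(grid_n) - 0.5) * 12 / grid_n
  b <- bias_prof(grid)
  vapply(best_pcs, function(mu) {
    m <- vm_peak1(grid, mu, width)
    sum(m * b) / sum(m)
  }, numeric(1))
}

#' @rdname nondynamic_models
#' @export
adapt_global <- function(pop, bias_prof, A0 = 0.8, grid_n = 1200) {
  check_A0(A0)
  A <- A0 * overlap_frac(pop$best_pcs, pop$width, bias_prof, grid_n)
  rates0 <- function(pcs) population_rates(pop, pcs)
  rates <- function(pcs) sweep(rates0(pcs), 2, 1 - A, "*")
  new_nd_model("global", rates, rates0, A, pop)
}

#' @rdname nondynamic_models
#' @export
adapt_spread <- function(pop, midlevel, bias_prof, A0 = 0.8, grid_n = 1200) {
  check_A0(A0)
  stopifnot(inherits(midlevel, "vm_population"))
  A_j <- A0 * overlap_frac(midlevel$best_pcs, midlevel$width, bias_prof, grid_n)
  J <- midlevel$n
  # connection strengths: cortical tuning evaluated at mid-level BFs (peak 1)
  Mi_j <- vapply(pop$best_pcs, function(mu)
    vm_peak1(midlevel$best_pcs, mu, pop$width), numeric(J))  # J x N
  midT <- function(pcs) matrix(
    vapply(midlevel$best_pcs, function(mu)
      vm_peak1(pcs, mu, midlevel$width), numeric(length(pcs))),
    nrow = length(pcs))  # stim x J
  rates0 <- function(pcs) midT(pcs) %*% Mi_j / J
  rates <- function(pcs) (midT(pcs) * rep(1 - A_j, each = length(pcs))) %*%
    Mi_j / J
  new_nd_model("spread", rates, rates0, A_j, pop)
}

#' Mid-level activity driven by one spectrogram frame
#'
#' `T_j = 1/n_bins * sum_phi M_j(phi) * S(phi)`: each mid-level unit's
#' response is the tuning-weighted average of the frame, with the
#' printed 1/12 normalization generalized to 1/n_bins.
#'
#' @param midlevel a [vm_population()] (peak-1 tuning is used).
#' @param frame numeric vector, one spectrogram column per pitch bin.
#' @param bin_pcs pitch classes of the frame's bins.
#' @return numeric vector of `J` mid-level activities.
#' @export
midlevel_activity <- function(midlevel, frame, bin_pcs) {
  if (length(frame) != length(bin_pcs))
    stop("frame length must equal the number of pitch bins")
  Mw <- vapply(midlevel$best_pcs, function(mu)
    vm_peak1(bin_pcs, mu, midlevel$width), numeric(length(bin_pcs)))
  as.numeric(crossprod(Mw, frame)) / length(frame)
}

#' Dynamic model configuration
#'
#' Parameters of the dynamic SSTRF + synaptic-depression model. Defaults
#' are the study conditions: 20 Hz model sampling rate (50 ms frames),
#' `F_R` set by the closed form `1 - exp(-1/(sr * 1.2 s))` so the
#' adaptation state recovers with a 1.2 s time constant, and `F_A`
#' calibrated once (via [calibrate()]) so the population onset response
#' over a bias train decays with a time constant near 3.9 stimuli to a
#' plateau near 13% below the initial response. Direction-selective
#' cells carry an extra von Mises lobe (peak 0.25 of the main lobe) at
#' lags 150--250 ms, offset 3 st above the best pitch class for
#' down-preferring cells and below for up-preferring cells.
#'
#' @param ... named overrides of any default.
#' @return list of class `model_config`.
#' @export
model_config <- function(...) {
  cfg <- list(
    n_cortical = 100L, n_midlevel = 48L,
    width_cortical = 0.8, width_midlevel = 0.8,
    sample_rate = 20, n_bins = 24L,
    F_A = 0.181, F_R = 1 - exp(-1 / (20 * 1.2)),
    adapt_max = 1,
    direction_mix = c(none = 1, up = 0, down = 0),
    directional_peak = 0.25, directional_offset = 3,
    directional_lag_window = c(0.15, 0.25),
    n_lags = 6L, lag1_scale = 1,
    spont_drive = 0.004,
    update_rule = c("accumulate", "printed"),
    seed = 1L)
  cfg$update_rule <- cfg$update_rule[1]
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  class(cfg) <- "model_config"
  cfg
}

#' Build one cell's Shepard spectrotemporal receptive field (SSTRF)
#'
#' Lags 0 and 1 (the current stimulus frames) carry the cell's own von
#' Mises tuning over the mid-level best pitch classes with peak 1 (lag 1
#' scaled by `lag1_scale`). For directional cells, lags whose time falls
#' in the directional lag window (default 150--250 ms) carry a second
#' von Mises lobe with peak `directional_peak` (default 0.25), centred
#' `directional_offset` st above the best pitch class for
#' down-preferring cells and below it for up-preferring cells, wrapping
#' circularly.
#'
#' @param best_pc the cell's best pitch class in semitones.
#' @param direction `"up"`, `"down"` or `"none"`.
#' @param cfg a [model_config()].
#' @param midlevel_pcs best pitch classes of the mid-level units.
#' @param width optional per-cell tuning width override (semitones).
#' @return `n_lags` x `J` matrix of class `sstrf` (lag 1 = current frame).
#' @export
build_directional_sstrf <- function(best_pc, direction, cfg,
                                    midlevel_pcs = NULL, width = NULL) {
  if (is.null(midlevel_pcs))
    midlevel_pcs <- (seq_len(cfg$n_midlevel) - 1) * 12 / cfg$n_midlevel
  width <- width %||% cfg$width_cortical
  L <- cfg$n_lags
  W <- matrix(0, L, length(midlevel_pcs))
  main <- vm_peak1(midlevel_pcs, best_pc, width)
  W[1, ] <- main
  if (L >= 2) W[2, ] <- cfg$lag1_scale * main
  if (direction != "none") {
    lag_t <- (seq_len(L) - 1) / cfg$sample_rate
    late <- which(lag_t >= cfg$directional_lag_window[1] - 1e-9 &
                    lag_t <= cfg$directional_lag_window[2] + 1e-9)
    off <- if (direction == "down") cfg$directional_offset else
      -cfg$directional_offset
    lobe <- cfg$directional_peak *
      vm_peak1(midlevel_pcs, pitch_class(best_pc + off), width)
    for (l in late) W[l, ] <- W[l, ] + lobe
  }
  structure(W, class = c("sstrf", "matrix"), lag_bin = 1 / cfg$sample_rate,
            best_pc = pitch_class(best_pc), direction = direction)
}

#' Construct the dynamic-model cortical population
#'
#' Best pitch classes equally spaced over `[0, 12)`; direction classes
#' assigned cyclically according to `direction_mix` so each class is
#' itself evenly distributed around the circle (with the default
#' one-third mix the three classes differ in count by at most 1).
#'
#' @param cfg a [model_config()].
#' @param best_pcs,widths,dirs,adapt_gain,rate_gain optional per-cell
#'   overrides (used by [emulate_recorded_cohort()] to draw heterogeneous
#'   populations); defaults give the homogeneous equally spaced
#'   population.
#' @return object of class `model_population`: list with `W` (cell x lag
#'   x mid-level unit array), `meta` (data.frame: id, best_pc, direction,
#'   width, adapt_gain, rate_gain), `midlevel_pcs`, and `cfg`.
#' @export
make_population <- function(cfg = model_config(), best_pcs = NULL,
                            widths = NULL, dirs = NULL, adapt_gain = NULL,
                            rate_gain = NULL) {
  n <- if (!is.null(best_pcs)) length(best_pcs) else cfg$n_cortical
  best_pcs <- best_pcs %||% ((seq_len(n) - 1) * 12 / n)
  mix <- cfg$direction_mix / sum(cfg$direction_mix)
  classes <- c("none", "up", "down")[mix > 0]
  # cyclic assignment: balanced counts, each class evenly spread over BFs
  dirs <- dirs %||% rep_len(classes, n)
  widths <- rep_len(widths %||% cfg$width_cortical, n)
  adapt_gain <- rep_len(adapt_gain %||% 1, n)
  rate_gain <- rep_len(rate_gain %||% 1, n)
  midlevel_pcs <- (seq_len(cfg$n_midlevel) - 1) * 12 / cfg$n_midlevel
  W <- array(0, dim = c(n, cfg$n_lags, cfg$n_midlevel))
  for (i in seq_len(n))
    W[i, , ] <- build_directional_sstrf(best_pcs[i], dirs[i], cfg,
                                        midlevel_pcs, width = widths[i])
  structure(list(
    W = W,
    meta = data.frame(id = seq_len(n), best_pc = pitch_class(best_pcs),
                      direction = dirs, width = widths,
                      adapt_gain = adapt_gain, rate_gain = rate_gain),
    midlevel_pcs = midlevel_pcs, cfg = cfg),
    class = "model_population")
}

#' @export
print.model_population <- function(x, ...) {
  cat(sprintf("Dynamic model population: %d cells (%s), %d mid-level units, %d lags\n",
              nrow(x$meta),
              paste(names(table(x$meta$direction)),
                    table(x$meta$direction), sep = ":", collapse = " "),
              length(x$midlevel_pcs), dim(x$W)[2]))
  invisible(x)
}

#' One step of the dynamic synaptic-depression model
#'
#' Computes the instantaneous cortical rates
#' `R_i = 1/J * sum_j sum_tau SSTRF_i(tau, j) (1 - A_ij) T_j(t - tau)`
#' with the current adaptation state, then updates each synapse's state.
#' The default update accumulates depression with the drive and recovers
#' exponentially: `A <- clip((A + F_A * g_i * d_ij * (1 - A)) * (1 - F_R))`,
#' where `d_ij = sum_tau (SSTRF_i(tau,j)/max SSTRF_i) * T_j(t - tau)` and
#' `g_i` is the cell's adapt gain. `update_rule = "printed"` applies the
#' pure product form `A * (1 - F_A * d) * (1 - F_R)` instead (kept for
#' comparison; it cannot grow from `A = 0`).
#'
#' @param A current cell x mid-level adaptation matrix in `[0, 1]`.
#' @param pop a [make_population()] result.
#' @param T_hist `n_lags` x `J` matrix of mid-level activity, row 1 the
#'   current frame, row `l` the frame `l - 1` steps back.
#' @return list `rates` (length-N vector, clipped at 0) and `A` (updated).
#' @export
step_dynamic_model <- function(A, pop, T_hist) {
  cfg <- pop$cfg
  n <- dim(pop$W)[1]; L <- dim(pop$W)[2]; J <- dim(pop$W)[3]
  stopifnot(nrow(T_hist) >= L, ncol(T_hist) == J)
  C <- matrix(0, n, J)
  for (l in seq_len(L))
    C <- C + pop$W[, l, ] * rep(T_hist[l, ], each = n)
  rates <- pmax(rowSums((1 - A) * C) / J, 0)
  wmax <- pop$w_max %||% apply(pop$W, 1, max)
  # drive on a normalized scale: SSTRF max-normalized per cell, mid-level
  # activity normalized to its single-tone maximum (1/n_bins), so d is
  # O(1) and F_A is independent of the spectrogram bin count
  d <- C / wmax * cfg$n_bins
  g <- cfg$F_A * pop$meta$adapt_gain
  A_new <- if (cfg$update_rule == "printed")
    A * (1 - g * d) * (1 - cfg$F_R)
  else
    (A + g * d * (1 - A)) * (1 - cfg$F_R)
  A_new <- pmin(pmax(A_new, 0), cfg$adapt_max)
  list(rates = rates, A = A_new)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the dynamic model over a stimulus spectrogram
#'
#' Iterates [step_dynamic_model()] over the frames of a pitch-class
#' spectrogram, starting from the given adaptation state. Also returns
#' the model's spontaneous rate, computed by passing a constant
#' mid-level background drive (`spont_drive`) through the same
#' depressing synapses -- so spontaneous firing is suppressed by
#' adaptation and recovers with `F_R`.
#'
#' @param pop a [make_population()] result.
#' @param spect a [to_spectrogram()] result (must use the model's
#'   `n_bins`).
#' @param A0 initial adaptation matrix (default all zero).
#' @return list of class `model_run`: `rates` (frames x cells), `spont`
#'   (frames x cells), `A` (final state), `mean_A` (per-frame mean
#'   adaptation), `alignment` and `sample_rate` carried from `spect`.
#' @export
run_dynamic_model <- function(pop, spect, A0 = NULL) {
  cfg <- pop$cfg
  stopifnot(ncol(spect) == cfg$n_bins,
            abs(attr(spect, "sample_rate") - cfg$sample_rate) < 1e-9)
  bin_pcs <- attr(spect, "bin_pcs")
  n <- dim(pop$W)[1]; L <- dim(pop$W)[2]; J <- dim(pop$W)[3]
  # precompute mid-level tuning over spectrogram bins: J x n_bins
  Mw <- t(vapply(pop$midlevel_pcs, function(mu)
    vm_peak1(bin_pcs, mu, pop$cfg$width_midlevel), numeric(cfg$n_bins)))
  pop$w_max <- apply(pop$W, 1, max)
  A <- A0 %||% matrix(0, n, J)
  n_fr <- nrow(spect)
  Tmat <- spect %*% t(Mw) / cfg$n_bins          # frames x J
  # spontaneous filter weight per cell: b0/J * sum_{tau,j} W[i,tau,j]
  w_spont <- cfg$spont_drive * apply(pop$W, 1, sum) / J
  w_spont_A <- cfg$spont_drive / J              # per-synapse background
  rates <- matrix(0, n_fr, n)
  spont <- matrix(0, n_fr, n)
  T_hist <- matrix(0, L, J)
  Wsum_lj <- apply(pop$W, c(1, 3), sum)          # N x J, for spont with A
  for (t in seq_len(n_fr)) {
    T_hist <- rbind(Tmat[t, ], T_hist[-L, , drop = FALSE])
    st <- step_dynamic_model(A, pop, T_hist)
    rates[t, ] <- st$rates
    spont[t, ] <- w_spont_A * rowSums((1 - A) * Wsum_lj)
    A <- st$A
  }
  structure(list(rates = rates, spont = spont, A = A,
                 mean_A = NULL,
                 alignment = attr(spect, "alignment"),
                 sample_rate = cfg$sample_rate, meta = pop$meta),
            class = "model_run")
}
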