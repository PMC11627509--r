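# Adaptation time-course and tuning analyses: PSTH windows over the bias
# sequence, adapting/facilitating classification with exponential fits,
# recovery of spontaneous rate, biased tuning curves, and tuning halfwidth.

#' Windowed PSTH by position in the bias sequence
#'
#' Averages the trial-mean response of every cell into onset (0--50 ms),
#' sustained (50--100 ms) and offset (100--150 ms) windows relative to
#' each tone's onset, by position of the tone in its sequence, averaged
#' across sequences.
#'
#' @param sim a [simulate_experiment()] result.
#' @param roles event roles included (default the bias tones).
#' @param positions which positions to keep (default all available).
#' @return array positions x windows x cells of rates (Hz), with
#'   dimnames.
#' @export
psth_windows <- function(sim, roles = c("bias", "lead_in"),
                         positions = NULL) {
  ev <- sim$events
  soa_frames <- length(window_names) * sim$bin_dur
  for (si in unique(ev$seq)) {
    on <- ev$onset[ev$seq == si]
    if (any(diff(on) < soa_frames - 1e-9))
      stop("response windows extend past the next tone onset")
  }
  use <- ev$role %in% roles
  pos_of <- stats::ave(seq_len(nrow(ev)), ev$seq,
                       FUN = function(ix) cumsum(ev$role[ix] %in% roles))
  ev$position <- ifelse(use, pos_of, NA)
  maxp <- max(ev$position, na.rm = TRUE)
  if (is.null(positions)) positions <- seq_len(maxp)
  nc <- ncol(sim$mean_counts)
  out <- array(NA_real_, dim = c(length(positions), 3, nc),
               dimnames = list(position = positions, window = window_names,
                               cell = NULL))
  bi <- sim$bin_info
  for (pi in seq_along(positions)) for (wi in 1:3) {
    keep_ev <- which(!is.na(ev$position) & ev$position == positions[pi])
    sel <- !is.na(bi$event) & bi$window == window_names[wi] &
      paste(bi$seq, bi$event) %in% paste(ev$seq[keep_ev],
                                         ev$event_index[keep_ev])
    if (any(sel))
      out[pi, wi, ] <- colMeans(sim$mean_counts[sel, , drop = FALSE]) /
        sim$bin_dur
  }
  out
}

# least-squares exponential fit r(k) = a + b * exp(-k / tau); endpoint
# initialisation, bounded tau > 0; returns NULL on failure
fit_exp_series <- function(y, x = seq_along(y)) {
  y <- unname(y); x <- unname(x)
  a0 <- y[length(y)]
  b0 <- y[which.max(abs(y - a0))] - a0   # robust to non-extreme first point
  t0 <- max(diff(range(x)) / 3, 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a + b * exp(-x / tau),
                      start = list(a = a0, b = b0, tau = t0),
                      lower = c(-Inf, -Inf, 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  list(a = cf[["a"]], b = cf[["b"]], tau = cf[["tau"]],
       fitted = cf[["a"]] + cf[["b"]] * exp(-x / cf[["tau"]]))
}

#' Classify a cell's response type over the bias sequence
#'
#' Fits `r(k) = a + b * exp(-k/tau)` to the sequence of window rates by
#' stimulus position and labels the cell adapting if the asymptotic rate
#' falls below the initial rate, facilitating if it exceeds it. The
#' windows are fitted separately and averaged into a single label.
#' Near-flat series (|asymptote - initial| < 2% of initial) are flagged
#' flat and not counted as adapting.
#'
#' @param rates positions x windows matrix (or vector for one window) of
#'   rates by position, e.g. one cell's slice of [psth_windows()].
#' @param soa stimulus-onset asynchrony in seconds (converts tau to
#'   seconds).
#' @param flat_tol relative tolerance for the flat tie-break.
#' @return object of class `response_type`: `label`
#'   (`"adapting"`/`"facilitating"`), `tau_stimuli`, `tau_seconds`,
#'   `initial_rate`, `asymptote_rate`, `flat`, `reliable`.
#' @export
classify_response_type <- function(rates, soa = 0.15, flat_tol = 0.02) {
  if (is.null(dim(rates))) rates <- matrix(rates, ncol = 1)
  stopifnot(nrow(rates) >= 4)
  res <- apply(rates, 2, function(y) {
    y <- unname(y)
    f <- fit_exp_series(y)
    if (is.null(f))
      c(init = y[1], asym = y[length(y)], tau = NA, ok = 0)
    else
      c(init = f$a + f$b * exp(-1 / f$tau), asym = f$a, tau = f$tau, ok = 1)
  })
  init <- mean(res["init", ]); asym <- mean(res["asym", ])
  taus <- res["tau", res["ok", ] == 1 & is.finite(res["tau", ])]
  tau <- if (length(taus)) mean(taus) else NA_real_
  flat <- abs(asym - init) < flat_tol * max(abs(init), 1e-12)
  structure(list(label = if (!flat && asym < init) "adapting" else "facilitating",
                 tau_stimuli = tau, tau_seconds = tau * soa,
                 initial_rate = init, asymptote_rate = asym, flat = flat,
                 reliable = all(res["ok", ] == 1)),
            class = "response_type")
}

#' @export
print.response_type <- function(x, ...) {
  cat(sprintf("%s%s: initial %.2f -> asymptote %.2f Hz, tau = %.2f stimuli (%.2f s)\n",
              x$label, if (x$flat) " (flat)" else "", x$initial_rate,
              x$asymptote_rate, x$tau_stimuli, x$tau_seconds))
  invisible(x)
}

#' Fit the recovery of spontaneous rate after the bias
#'
#' Exponential approach of the (population-mean) spontaneous rate back
#' to its pre-bias baseline, `r(t) = a - b * exp(-t/tau)`, over time
#' since the end of the bias sequence.
#'
#' @param times seconds since bias end (>= 5 points).
#' @param rates spontaneous rates at those times.
#' @return list `tau_seconds`, `asymptote`, `fitted`, `degenerate`
#'   (TRUE when there is nothing to recover, e.g. without adaptation).
#' @export
recovery_fit <- function(times, rates) {
  stopifnot(length(times) == length(rates), length(times) >= 5)
  rng <- diff(range(rates))
  if (rng < 1e-6 * max(abs(rates), 1e-12))
    return(list(tau_seconds = NA_real_, asymptote = mean(rates),
                fitted = rep(mean(rates), length(rates)), degenerate = TRUE))
  f <- fit_exp_series(rates, x = times)
  if (is.null(f))
    return(list(tau_seconds = NA_real_, asymptote = rates[length(rates)],
                fitted = rates, degenerate = TRUE))
  list(tau_seconds = f$tau, asymptote = f$a, fitted = f$fitted,
       degenerate = FALSE)
}

#' Spontaneous-rate recovery trace from a simulated experiment
#'
#' Extracts the population-mean spontaneous rate in the silent bins
#' following the last tone of each sequence (beyond the offset window).
#'
#' @param sim a [simulate_experiment()] result (simulate with a long
#'   `pad_s` to give the fit room).
#' @param cells optional cell subset.
#' @param skip_s initial seconds after the last tone excluded (offset
#'   responses and the SSTRF's late lags still read the tone there).
#' @return data.frame `t` (s since bias end) and `rate` (Hz, expected
#'   spontaneous rate from the model, noiseless).
#' @export
recovery_trace <- function(sim, cells = NULL, skip_s = 0.3) {
  if (is.null(cells)) cells <- seq_len(ncol(sim$lambda))
  bi <- sim$bin_info
  ev <- sim$events
  out <- list()
  for (si in unique(bi$seq)) {
    last_off <- max(ev$onset[ev$seq == si] + ev$duration[ev$seq == si]) +
      skip_s
    sel <- bi$seq == si & is.na(bi$event) & bi$t > last_off
    if (!any(sel)) next
    out[[length(out) + 1]] <- data.frame(
      t = bi$t[sel] - last_off,
      rate = rowMeans(sim$lambda[sel, cells, drop = FALSE]))
  }
  out <- do.call(rbind, out)
  agg <- aggregate(rate ~ t, data = out, FUN = mean)
  agg[order(agg$t), ]
}

#' Biased tuning-curve comparison
#'
#' From a biased-tuning simulation, builds each bias region's adapted
#' tuning curve from the probe tones (0.5 st grid) and the unadapted
#' baseline from the first 5 lead-in stimuli of every sequence, pooled
#' across conditions (1 st grid, circularly interpolated to 0.5 st).
#' Difference (unadapted - adapted) and ratio (adapted / unadapted)
#' profiles are circularly re-centred on each region's bias centre
#' before averaging.
#'
#' @param sim a [simulate_experiment()] result for a biased-tuning set.
#' @param cells optional cell subset.
#' @param windows response windows used.
#' @param n_baseline number of initial lead-in stimuli per sequence used
#'   for the unadapted estimate (default 5).
#' @return object of class `tuning_comparison`: `rel_grid` (offsets from
#'   bias centre), `difference` and `ratio` (population-mean profiles),
#'   per-region adapted curves, the unadapted curve, and the
#'   inside/outside summary (`inside_reduction`, `outside_reduction`,
#'   `inside_ratio`, and `inside_ratio_high` -- the adapted/unadapted
#'   rate ratio over top-quartile-rate points inside the bias, the
#'   high-rate reduction measure).
#' @export
biased_tuning <- function(sim, cells = NULL, windows = c("onset", "sustained"),
                          n_baseline = 5L) {
  resp <- event_responses(sim, windows)
  if (is.null(cells)) cells <- seq_len(ncol(resp))
  resp <- resp[, cells, drop = FALSE]
  ev <- sim$events
  regions <- vapply(sim$sequences, function(s) s$bias_meta$center, 0)
  region_of <- regions[ev$seq]
  grid <- sort(unique(round(ev$pitch_class[ev$role == "probe"] * 2) / 2))
  # unadapted baseline: first n_baseline lead-in tones per sequence, pooled
  first5 <- unlist(lapply(unique(ev$seq), function(si) {
    ix <- which(ev$seq == si & ev$role == "lead_in")
    ix[seq_len(min(n_baseline, length(ix)))]
  }))
  b_pc <- floor(pitch_class(ev$pitch_class[first5]))
  unad_1st <- rowsum(resp[first5, , drop = FALSE], b_pc) /
    as.vector(table(b_pc))
  pcs1 <- as.numeric(rownames(unad_1st))
  # circular linear interpolation from the 1 st grid to the 0.5 st grid
  interp_circ <- function(xout, x, y) {
    xx <- c(x, x[1] + 12); yy <- rbind(y, y[1, , drop = FALSE])
    xo <- ifelse(xout < min(x), xout + 12, xout)
    apply(yy, 2, function(col) stats::approx(xx, col, xout = xo, rule = 2)$y)
  }
  unadapted <- interp_circ(grid, pcs1, unad_1st)
  centers <- sort(unique(regions))
  adapted <- list(); diffs <- list(); ratios <- list()
  rel_grid <- circular_step(0, grid)  # placeholder ordering
  for (ct in centers) {
    pix <- which(ev$role == "probe" & region_of == ct)
    g <- factor(round(ev$pitch_class[pix] * 2) / 2, levels = grid)
    ad <- matrix(NA_real_, length(grid), ncol(resp))
    rs <- rowsum(resp[pix, , drop = FALSE], g)   # empty levels are dropped
    cnt <- table(g)[rownames(rs)]
    ad[match(rownames(rs), as.character(grid)), ] <- rs / as.vector(cnt)
    rel <- circular_step(ct, grid)
    ord <- order(rel)
    diffs[[as.character(ct)]] <- (unadapted - ad)[ord, , drop = FALSE]
    ratios[[as.character(ct)]] <- (ad / pmax(unadapted, 1e-9))[ord, , drop = FALSE]
    adapted[[as.character(ct)]] <- ad
    rel_grid <- rel[ord]
  }
  diff_prof <- rowMeans(vapply(diffs, function(d) rowMeans(d, na.rm = TRUE),
                               numeric(length(grid))), na.rm = TRUE)
  ratio_prof <- rowMeans(vapply(ratios, function(d) rowMeans(d, na.rm = TRUE),
                                numeric(length(grid))), na.rm = TRUE)
  half_range <- sim$sequences[[1]]$bias_meta$range / 2
  inside <- abs(rel_grid) <= half_range
  outside <- abs(rel_grid) > half_range + 0.5
  # rate reduction at high firing rates: pool per-(cell, probe) points
  # inside the bias whose unadapted rate is in the top quartile, and take
  # the ratio of summed adapted to summed unadapted rate (avoids
  # degenerate divisions by small rates)
  ad_in <- un_in <- numeric(0)
  for (ct in names(adapted)) {
    rel <- circular_step(as.numeric(ct), grid)
    m <- abs(rel) <= half_range
    ad_in <- c(ad_in, as.vector(adapted[[ct]][m, , drop = FALSE]))
    un_in <- c(un_in, as.vector(unadapted[m, , drop = FALSE]))
  }
  ok <- !is.na(ad_in) & un_in >= stats::quantile(un_in, 0.75, na.rm = TRUE)
  structure(list(rel_grid = rel_grid, difference = diff_prof,
                 ratio = ratio_prof, adapted = adapted,
                 unadapted = unadapted, grid = grid,
                 inside_reduction = mean(diff_prof[inside]),
                 outside_reduction = mean(diff_prof[outside]),
                 inside_ratio = mean(ratio_prof[inside]),
                 inside_ratio_high = sum(ad_in[ok]) / sum(un_in[ok])),
            class = "tuning_comparison")
}

#' @export
print.tuning_comparison <- function(x, ...) {
  cat(sprintf("Biased tuning: mean reduction inside bias %.3f Hz vs outside %.3f Hz; inside rate ratio %.2f\n",
              x$inside_reduction, x$outside_reduction, x$inside_ratio))
  invisible(x)
}

#' Tuning halfwidth of a circular tuning curve
#'
#' Range of pitch classes over which the rate exceeds the half-height
#' threshold `f_min + (f_max - f_min)/2`, measured conservatively: walk
#' circularly from the minimum in both directions to the nearest
#' threshold crossings (linearly interpolated) and subtract the
#' below-threshold arc from the octave. Weakly modulated cells thus
#' receive large halfwidths. `literal = TRUE` applies the threshold
#' `(f_max - f_min)/2` without the minimum offset instead.
#'
#' @param curve rates on a circular pitch grid.
#' @param grid_pcs the grid's pitch classes (default equally spaced).
#' @param literal use the literal threshold variant.
#' @param flat_tol relative range below which the curve counts as flat.
#' @return halfwidth in semitones; 12 with attribute `degenerate = TRUE`
#'   for flat curves. Invariant under affine rate transforms.
#' @export
tuning_halfwidth <- function(curve, grid_pcs = NULL, literal = FALSE,
                             flat_tol = 1e-9) {
  n <- length(curve)
  if (is.null(grid_pcs)) grid_pcs <- (seq_len(n) - 1) * 12 / n
  fmin <- min(curve); fmax <- max(curve)
  if (fmax - fmin <= flat_tol * max(abs(fmax), 1)) {
    out <- 12
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  thr <- if (literal) (fmax - fmin) / 2 else fmin + (fmax - fmin) / 2
  if (all(curve >= thr)) {
    out <- 12; attr(out, "degenerate") <- TRUE
    return(out)
  }
  im <- which.min(curve)
  # walk from the minimum to the nearest up-crossing in each direction
  cross <- function(step) {
    i <- im; trav <- 0
    for (s in seq_len(n)) {
      j <- ((i - 1 + step) %% n) + 1
      seg <- circular_distance(grid_pcs[i], grid_pcs[j])
      if (curve[j] >= thr) {
        f <- (thr - curve[i]) / (curve[j] - curve[i])
        return(trav + f * seg)
      }
      trav <- trav + seg; i <- j
    }
    NA_real_
  }
  arc_below <- cross(+1L) + cross(-1L)
  out <- 12 - arc_below
  attr(out, "degenerate") <- FALSE
  out
}
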