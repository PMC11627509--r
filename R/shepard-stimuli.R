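# Shepard-tone stimulus construction: single tones, the biased-pair and
# biased-tuning paradigms, audio synthesis, and the model-facing
# pitch-class spectrogram.

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards. Keeps stimulus generation reproducible
# without clobbering user RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Construct a Shepard tone
#'
#' A Shepard tone is a complex of equal-amplitude, octave-spaced pure
#' tones, characterised by its pitch class (position within the octave,
#' relative to the 440 Hz anchor assigned pitch class 0).
#'
#' @param pitch_class pitch class in semitones (wrapped into `[0, 12)`).
#' @param duration tone duration in seconds (> 0).
#' @param level presentation level in dB SPL (see [synthesize_waveform()]).
#' @param ramp_ms sinusoidal on/off ramp duration in milliseconds.
#' @param phase_seed integer seed for per-trial randomised component phases.
#' @return an object of class `shepard_tone`.
#' @export
shepard_tone <- function(pitch_class, duration = 0.1, level = 70,
                         ramp_ms = 5, phase_seed = 1L) {
  stopifnot(duration > 0, ramp_ms >= 0, 2 * ramp_ms / 1000 <= duration)
  structure(
    list(pitch_class = pitch_class(pitch_class), duration = duration,
         level = level, ramp_ms = ramp_ms, phase_seed = as.integer(phase_seed)),
    class = "shepard_tone")
}

#' @export
print.shepard_tone <- function(x, ...) {
  cat(sprintf("Shepard tone: pitch class %.2f st, %.0f ms, %.0f dB SPL\n",
              x$pitch_class, 1000 * x$duration, x$level))
  invisible(x)
}

#' Octave-spaced component frequencies of a Shepard tone
#'
#' Returns every frequency `440 * 2^(pc/12) * 2^k` (integer `k`) inside
#' the given band, ascending. Pitch classes differing by an octave give
#' identical component sets.
#'
#' @param pc pitch class in semitones.
#' @param band numeric length-2 vector `(low, high)` in Hz, both positive.
#' @return ascending vector of component frequencies in Hz.
#' @examples
#' component_frequencies(0, c(400, 900))   # contains 440
#' @export
component_frequencies <- function(pc, band = c(30, 16000)) {
  stopifnot(length(band) == 2, all(band > 0))
  if (band[1] >= band[2]) stop("empty frequency band")
  f0 <- 440 * 2^(pitch_class(pc) / 12)
  klo <- ceiling(log2(band[1] / f0) - 1e-12)
  khi <- floor(log2(band[2] / f0) + 1e-12)
  if (khi < klo) return(numeric(0))
  f0 * 2^(klo:khi)
}

#' Synthesize the audio waveform of a Shepard tone
#'
#' Sum of equal-amplitude sinusoids at the octave-spaced component
#' frequencies, with phases drawn reproducibly from the tone's
#' `phase_seed`, gated by sinusoidal (raised-cosine) on/off ramps,
#' peak-normalized and scaled to the tone's level (0 dB FS = 100 dB SPL).
#'
#' @param tone a [shepard_tone()].
#' @param audio_rate sampling rate in Hz; must exceed twice the band top.
#' @param band audible band `(low, high)` in Hz for the components.
#' @return numeric sample vector.
#' @export
synthesize_waveform <- function(tone, audio_rate = 48000, band = c(30, 16000)) {
  stopifnot(inherits(tone, "shepard_tone"))
  if (audio_rate <= 2 * band[2])
    stop("audio_rate must exceed twice the band top (Nyquist)")
  freqs <- component_frequencies(tone$pitch_class, band)
  n <- round(tone$duration * audio_rate)
  t <- (seq_len(n) - 1) / audio_rate
  phases <- with_seed(tone$phase_seed, stats::runif(length(freqs), 0, 2 * pi))
  x <- rowSums(vapply(seq_along(freqs),
                      function(i) sin(2 * pi * freqs[i] * t + phases[i]),
                      numeric(n)))
  nr <- round(tone$ramp_ms / 1000 * audio_rate)
  if (nr > 0) {
    ramp <- (1 - cos(pi * (seq_len(nr) - 1) / nr)) / 2
    x[seq_len(nr)] <- x[seq_len(nr)] * ramp
    x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(ramp)
  }
  pk <- max(abs(x))
  if (pk > 0) x <- x / pk
  x * 10^((tone$level - 100) / 20)
}

#' Write a mono waveform to a 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer for auditioning generated stimuli.
#'
#' @param samples numeric samples in `[-1, 1]` (clipped otherwise).
#' @param rate sampling rate in Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path) {
  s <- pmin(pmax(samples, -1), 1)
  pcm <- as.integer(round(s * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nbytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(nbytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Default stimulus configuration
#'
#' Defaults follow the ferret recording paradigm: 0.1 s tones at a 0.15 s
#' stimulus-onset asynchrony; biased-pair sequences with 5-semitone bias
#' ranges around base pitch classes \{0,3,6,9\}, bias lengths \{5,10\},
#' up/down directions, 2 randomisations (32 sequences, 240 bias tones)
#' and bias-to-pair gaps \{0.05, 0.2, 0.5\} s; biased-tuning sequences of
#' 154 tones (15-tone lead-in, 5 bias : 1 probe interleaving, probes on a
#' 24-step / 0.5 st grid, 5 sequences per bias region).
#'
#' @param ... named overrides of any default.
#' @return a named list of class `stimulus_config`.
#' @export
stimulus_config <- function(...) {
  cfg <- list(
    # biased Shepard pair paradigm
    base_pcs = c(0, 3, 6, 9), lengths = c(5L, 10L),
    directions = c("up", "down"), n_rand = 2L,
    bias_range = 5, pair_step = 6,
    gaps = c(0.05, 0.2, 0.5), expand_gaps = FALSE,
    # biased Shepard tuning paradigm
    tuning_length = 154L, lead_in = 15L,
    region_los = c(0, 3, 6, 9), region_width = 5,
    probe_steps = 24L, seqs_per_region = 5L, repeats = 6L,
    # tone and timing parameters (ferret paradigm)
    tone_dur = 0.1, soa = 0.15, level = 70, ramp_ms = 5,
    # MEG probe variant timing
    meg_tone_dur = 0.125, meg_soa = 0.25, meg_probe_dur = 0.03,
    meg_pauses = c(0.5, 1, 2))
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  class(cfg) <- "stimulus_config"
  cfg
}

new_tone_sequence <- function(events, paradigm, bias_meta, id) {
  stopifnot(all(diff(events$onset) > 0))
  structure(list(events = events, paradigm = paradigm,
                 bias_meta = bias_meta, id = id),
            class = "tone_sequence")
}

#' @export
print.tone_sequence <- function(x, ...) {
  cat(sprintf("Tone sequence '%s' (%s): %d events, %.2f s\n", x$id,
              x$paradigm, nrow(x$events),
              max(x$events$onset + x$events$duration)))
  if (!is.null(x$bias_meta))
    cat(sprintf("  bias: center %.2f st, %s, length %d, gap %.2f s\n",
                x$bias_meta$center, x$bias_meta$direction,
                x$bias_meta$length, x$bias_meta$gap))
  invisible(x)
}

#' Generate the biased Shepard pair stimulus set
#'
#' Full factorial over base pitch class, bias direction, bias length and
#' randomisation: 32 sequences containing 240 distinct bias tones in
#' total. Each sequence is a bias of 5 or 10 Shepard tones with pitch
#' classes drawn uniformly and continuously from a 5-semitone range
#' centred 3 st above (up) or below (down) the first test tone, followed
#' after a gap by the ambiguous pair (6 st separation). Gaps cycle over
#' \{0.05, 0.2, 0.5\} s across sequences; set `expand_gaps = TRUE` in the
#' config to cross gaps factorially instead (96 sequences), as used by
#' the gap-decay analysis.
#'
#' @param cfg a [stimulus_config()].
#' @param seed integer master seed; bias draws and per-event phase seeds
#'   derive from it.
#' @param paradigm `"biased_pair"` (ferret timing: 0.1 s tones, 0.15 s
#'   SOA, gaps from `cfg$gaps`) or `"meg_probe"` (MEG timing: 0.125 s
#'   tones at 4 Hz; after the bias and a pause from `cfg$meg_pauses`, a
#'   2 s train of 30 ms probe tones 3 st above or below the first test
#'   tone precedes the pair; no downstream signal analysis consumes this
#'   variant).
#' @return list of `tone_sequence` objects.
#' @export
generate_biased_pair_set <- function(cfg = stimulus_config(), seed = 1L,
                                     paradigm = c("biased_pair",
                                                  "meg_probe")) {
  paradigm <- match.arg(paradigm)
  if (cfg$bias_range >= 12) stop("bias range must be < 12 st (would wrap onto itself)")
  grid <- expand.grid(rand = seq_len(cfg$n_rand), length = cfg$lengths,
                      direction = cfg$directions, base = cfg$base_pcs,
                      stringsAsFactors = FALSE)
  gaps <- if (paradigm == "meg_probe") cfg$meg_pauses else cfg$gaps
  if (isTRUE(cfg$expand_gaps)) {
    grid <- merge(grid, data.frame(gap = gaps))
  } else {
    grid$gap <- rep_len(gaps, nrow(grid))
  }
  tone_dur <- if (paradigm == "meg_probe") cfg$meg_tone_dur else cfg$tone_dur
  soa <- if (paradigm == "meg_probe") cfg$meg_soa else cfg$soa
  with_seed(seed, {
    lapply(seq_len(nrow(grid)), function(k) {
      g <- grid[k, ]
      # up: center = base + 3 -> tones in (base+0.5, base+5.5); down: mirror
      center <- pitch_class(g$base + ifelse(g$direction == "up", 3, -3))
      bias_pcs <- pitch_class(center + stats::runif(g$length,
                                                    -cfg$bias_range / 2,
                                                    cfg$bias_range / 2))
      pcs <- c(bias_pcs)
      roles <- rep("bias", g$length)
      onsets <- (seq_len(g$length) - 1) * soa
      durs <- rep(tone_dur, g$length)
      t <- (g$length - 1) * soa + tone_dur + g$gap
      if (paradigm == "meg_probe") {
        # 2 s probe train: brief tones 3 st to the bias side of test1
        n_pr <- floor(2 / cfg$meg_soa)
        pr_pc <- pitch_class(g$base + ifelse(g$direction == "up", 3, -3))
        pcs <- c(pcs, rep(pr_pc, n_pr))
        roles <- c(roles, rep("probe", n_pr))
        onsets <- c(onsets, t + (seq_len(n_pr) - 1) * cfg$meg_soa)
        durs <- c(durs, rep(cfg$meg_probe_dur, n_pr))
        t <- t + 2
      }
      pcs <- c(pcs, g$base, pitch_class(g$base + cfg$pair_step))
      roles <- c(roles, "test1", "test2")
      onsets <- c(onsets, t, t + soa)
      durs <- c(durs, tone_dur, tone_dur)
      ev <- data.frame(onset = onsets, duration = durs,
                       pitch_class = pcs, role = roles,
                       phase_seed = sample.int(.Machine$integer.max - 1,
                                               length(pcs)))
      new_tone_sequence(
        ev, paradigm,
        list(center = center, range = cfg$bias_range,
             direction = g$direction, length = g$length, gap = g$gap),
        sprintf("%s_b%g_%s_L%d_g%g_r%d", paradigm, g$base, g$direction,
                g$length, g$gap, g$rand))
    })
  })
}

#' Generate the biased Shepard tuning stimulus set
#'
#' Long sequences (default 154 tones) probing each neuron's Shepard
#' tuning under a sustained bias: after a lead-in of bias-range tones,
#' every 6th tone is a probe drawn from the whole octave discretised to
#' 24 steps (0.5 st), while the other 5/6 of tones are drawn continuously
#' from one of the four bias regions ([0-5], [3-8], [6-11], [9-2] st).
#' Probe-grid coverage is balanced across each region's sequences.
#'
#' @inheritParams generate_biased_pair_set
#' @return list of `tone_sequence` objects (regions x sequences).
#' @export
generate_biased_tuning_set <- function(cfg = stimulus_config(), seed = 1L) {
  probe_grid <- (seq_len(cfg$probe_steps) - 1) * 12 / cfg$probe_steps
  n_groups <- (cfg$tuning_length - cfg$lead_in) %/% 6L
  with_seed(seed, {
    out <- list()
    for (lo in cfg$region_los) {
      center <- pitch_class(lo + cfg$region_width / 2)
      # balanced probe pool across this region's sequences
      pool <- sample(rep_len(probe_grid, n_groups * cfg$seqs_per_region))
      for (s in seq_len(cfg$seqs_per_region)) {
        probes <- pool[(s - 1) * n_groups + seq_len(n_groups)]
        draw_bias <- function(n) pitch_class(lo + stats::runif(n, 0, cfg$region_width))
        pcs <- draw_bias(cfg$lead_in)
        roles <- rep("lead_in", cfg$lead_in)
        for (gp in seq_len(n_groups)) {
          pcs <- c(pcs, draw_bias(5L), probes[gp])
          roles <- c(roles, rep("bias", 5L), "probe")
        }
        extra <- cfg$tuning_length - length(pcs)
        if (extra > 0) {
          pcs <- c(pcs, draw_bias(extra))
          roles <- c(roles, rep("bias", extra))
        } else if (extra < 0) {
          pcs <- pcs[seq_len(cfg$tuning_length)]
          roles <- roles[seq_len(cfg$tuning_length)]
        }
        ev <- data.frame(onset = (seq_along(pcs) - 1) * cfg$soa,
                         duration = cfg$tone_dur, pitch_class = pcs,
                         role = roles,
                         phase_seed = sample.int(.Machine$integer.max - 1,
                                                 length(pcs)))
        out[[length(out) + 1]] <- new_tone_sequence(
          ev, "biased_tuning",
          list(center = center, range = cfg$region_width, direction = "none",
               length = cfg$tuning_length, gap = cfg$soa - cfg$tone_dur),
          sprintf("tuning_lo%g_s%d", lo, s))
      }
    }
    out
  })
}

#' Pitch-class spectrogram of a tone sequence
#'
#' The model-facing stimulus representation `S(t, phi)`: a time x
#' circular-pitch-bin matrix at the model sampling rate. Each tone
#' contributes amplitude 1 in its (nearest, circularly wrapped) pitch bin
#' for every frame whose centre falls within the tone's on-time; frames
#' in pauses are zero.
#'
#' @param seq a `tone_sequence`.
#' @param sample_rate model sampling rate in Hz (default 20).
#' @param n_bins circular pitch bins per octave (default 24).
#' @param pad_s trailing silence appended after the last tone, seconds.
#' @return matrix of class `pitch_class_spectrogram` with attributes
#'   `sample_rate`, `bin_pcs` (bin centre pitch classes), and `alignment`
#'   (data.frame mapping on-frames to event indices).
#' @export
to_spectrogram <- function(seq, sample_rate = 20, n_bins = 24, pad_s = 0) {
  stopifnot(inherits(seq, "tone_sequence"), sample_rate > 0, n_bins >= 2)
  ev <- seq$events
  total <- max(ev$onset + ev$duration) + pad_s
  n_fr <- ceiling(total * sample_rate - 1e-9)
  centers <- (seq_len(n_fr) - 0.5) / sample_rate
  S <- matrix(0, n_fr, n_bins)
  ali_fr <- integer(0); ali_ev <- integer(0)
  for (i in seq_len(nrow(ev))) {
    on <- which(centers >= ev$onset[i] - 1e-9 &
                  centers < ev$onset[i] + ev$duration[i] - 1e-9)
    bin <- (round(ev$pitch_class[i] * n_bins / 12) %% n_bins) + 1L
    S[on, bin] <- S[on, bin] + 1
    ali_fr <- c(ali_fr, on); ali_ev <- c(ali_ev, rep(i, length(on)))
  }
  structure(S, class = c("pitch_class_spectrogram", "matrix"),
            sample_rate = sample_rate,
            bin_pcs = (seq_len(n_bins) - 1) * 12 / n_bins,
            alignment = data.frame(frame = ali_fr, event = ali_ev))
}

#' Tabulate the event schedule of generated sequences
#'
#' @param seqs list of `tone_sequence` objects.
#' @return data.frame with one row per event (columns: sequence_id,
#'   event_index, onset_s, duration_s, pitch_class, role, bias_center,
#'   bias_direction, bias_length, gap_s), suitable for CSV export.
#' @export
sequence_schedule <- function(seqs) {
  do.call(rbind, lapply(seqs, function(s) {
    data.frame(sequence_id = s$id, event_index = seq_len(nrow(s$events)),
               onset_s = s$events$onset, duration_s = s$events$duration,
               pitch_class = s$events$pitch_class, role = s$events$role,
               bias_center = s$bias_meta$center,
               bias_direction = s$bias_meta$direction,
               bias_length = s$bias_meta$length, gap_s = s$bias_meta$gap)
  }))
}
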