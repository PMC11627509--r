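test_that("component frequencies are octave-spaced around the 440 Hz anchor", {
  f <- component_frequencies(0, c(400, 900))
  expect_true(any(abs(f - 440) < 1e-9))
  expect_equal(component_frequencies(12, c(20, 20000)),
               component_frequencies(0, c(20, 20000)))
  expect_equal(component_frequencies(6, c(600, 700)), 440 * 2^(6 / 12),
               tolerance = 1e-12)
  full <- component_frequencies(3, c(30, 16000))
  expect_true(all(diff(full) > 0))
  expect_equal(unique(round(diff(log2(full)), 9)), 1)  # octave spacing
  expect_error(component_frequencies(0, c(900, 400)), "empty")
})

test_that("waveform synthesis is seeded, band-limited, and half-cosine ramped", {
  # pitch class 0 puts every component on an integer frequency, so a 1 s
  # FFT resolves them without leakage
  tone <- shepard_tone(0, duration = 1, phase_seed = 7)
  fs <- 48000
  x1 <- synthesize_waveform(tone, fs)
  x2 <- synthesize_waveform(tone, fs)
  expect_identical(x1, x2)
  x3 <- synthesize_waveform(shepard_tone(0, duration = 1, phase_seed = 8), fs)
  expect_false(identical(x1, x3))
  # FFT oracle: spectral peaks only at octave-spaced component frequencies
  spec <- Mod(stats::fft(x1))[1:(fs / 2)]
  freqs <- component_frequencies(0, c(30, 16000))
  bins <- round(freqs) + 1    # 1 s synthesis: 1 Hz resolution
  near <- unique(as.vector(outer(bins, -5:5, "+")))
  expect_gt(min(spec[bins]), 50 * max(spec[-near]))
  # first 5 ms follows a half-cosine (raised-cosine) ramp envelope
  nr <- round(0.005 * fs)
  ramp <- (1 - cos(pi * (seq_len(nr) - 1) / nr)) / 2
  xu <- synthesize_waveform(shepard_tone(0, duration = 1, ramp_ms = 0,
                                         phase_seed = 7), fs)
  expect_equal(x1[1:nr] / max(abs(x1)), (xu[1:nr] / max(abs(xu))) * ramp,
               tolerance = 1e-6)
  expect_error(synthesize_waveform(tone, 8000), "Nyquist")
})

test_that("biased pair set matches the paradigm design counts and geometry", {
  seqs <- fx_pair()
  expect_length(seqs, 32)
  sch <- sequence_schedule(seqs)
  expect_equal(sum(sch$role == "bias"), 240)
  expect_equal(sum(sch$role == "test1"), 32)
  # bias tones drawn from center +/- 2.5 st, continuously
  up3 <- sch[sch$bias_center == 3 & sch$role == "bias", ]
  expect_true(all(up3$pitch_class >= 0.5 & up3$pitch_class <= 5.5))
  expect_gt(length(unique(up3$pitch_class)), nrow(up3) - 2)
  # every up-bias tone lies strictly within (test1, test1 + 6) circularly
  for (s in seqs) {
    b <- s$events$pitch_class[s$events$role == "bias"]
    t1 <- s$events$pitch_class[s$events$role == "test1"]
    rel <- circular_step(t1, b)
    if (s$bias_meta$direction == "up") expect_true(all(rel > 0 & rel < 6))
    else expect_true(all(rel < 0 & rel > -6))
    # test pair separated by the configured step
    t2 <- s$events$pitch_class[s$events$role == "test2"]
    expect_equal(circular_step(t1, t2), 6)
    expect_true(all(diff(s$events$onset) > 0))
  }
  # factorial cardinality and seeded reproducibility
  expect_length(generate_biased_pair_set(
    stimulus_config(base_pcs = c(0, 6), lengths = 5L, n_rand = 3L), seed = 9), 12)
  expect_identical(sequence_schedule(generate_biased_pair_set(seed = 2)),
                   sequence_schedule(fx_pair()))
  expect_error(generate_biased_pair_set(stimulus_config(bias_range = 12)))
})

test_that("biased tuning set interleaves probes on the 0.5 st grid over four regions", {
  seqs <- generate_biased_tuning_set(stimulus_config(), seed = 3)
  expect_length(seqs, 20)   # 4 regions x 5 sequences
  sch <- sequence_schedule(seqs)
  expect_equal(unique(table(sch$sequence_id)), 154L)
  probes <- sch$pitch_class[sch$role == "probe"]
  expect_true(all(abs(probes * 2 - round(probes * 2)) < 1e-9))  # 0.5 st grid
  expect_setequal(unique(sch$bias_center), c(2.5, 5.5, 8.5, 11.5))
  # bias tones confined to their region
  for (s in seqs) {
    b <- s$events$pitch_class[s$events$role %in% c("bias", "lead_in")]
    expect_true(all(circular_distance(b, s$bias_meta$center) <= 2.5 + 1e-9))
  }
  # 1 in 6 tones after the lead-in is a probe (within one tone)
  frac <- mean(sch$role[sch$role != "lead_in"] == "probe")
  expect_lt(abs(frac - 1 / 6), 1 / 139)
  # probe coverage balanced across a region's sequences
  p1 <- probes[sch$bias_center[sch$role == "probe"] == 2.5]
  expect_lte(diff(range(table(factor(p1, levels = (0:23) / 2)))), 1)
})

test_that("spectrogram places unit mass in circular pitch bins over tone frames", {
  seqs <- fx_pair()
  sp <- to_spectrogram(seqs[[1]], 20, 24)
  n_tones <- nrow(seqs[[1]]$events)
  # 0.1 s tones at 20 Hz: exactly 2 frames per tone; total energy exact
  expect_equal(sum(sp), n_tones * 2)
  expect_lte(sum(colSums(sp) > 0), n_tones)
  ali <- attr(sp, "alignment")
  expect_equal(nrow(ali), n_tones * 2)
  # frames outside tone presentations are silent
  expect_equal(sum(sp[setdiff(seq_len(nrow(sp)), ali$frame), ]), 0)
  # circular wrap: a 11.9 st tone lands in the bin nearest 0
  sq <- generate_biased_pair_set(stimulus_config(base_pcs = 11.9,
                                                 lengths = 5L, n_rand = 1L,
                                                 directions = "up"), seed = 1)[[1]]
  sp2 <- to_spectrogram(sq, 20, 24)
  t1_fr <- attr(sp2, "alignment")$frame[attr(sp2, "alignment")$event ==
                                          which(sq$events$role == "test1")][1]
  expect_equal(which(sp2[t1_fr, ] > 0), 1L)  # bin centred at 0
})

test_that("the MEG probe variant uses its own timing and probe train", {
  cfg <- stimulus_config(base_pcs = 0, lengths = 10L, n_rand = 1L)
  sq <- generate_biased_pair_set(cfg, seed = 4, paradigm = "meg_probe")[[1]]
  ev <- sq$events
  expect_equal(unique(ev$duration[ev$role == "bias"]), 0.125)
  expect_equal(unique(diff(ev$onset[ev$role == "bias"])), 0.25)  # 4 Hz
  pr <- ev[ev$role == "probe", ]
  expect_equal(nrow(pr), 8)                      # 2 s at 250 ms SOA
  expect_equal(unique(pr$duration), 0.03)
  # probes sit 3 st to the bias side of the first test tone
  t1 <- ev$pitch_class[ev$role == "test1"]
  side <- if (sq$bias_meta$direction == "up") 3 else -3
  expect_equal(unique(pr$pitch_class), pitch_class(t1 + side))
  expect_true(all(ev$onset[ev$role %in% c("test1", "test2")] >
                    max(pr$onset)))
})

test_that("WAV export writes a readable 16-bit PCM file", {
  p <- tempfile(fileext = ".wav")
  x <- synthesize_waveform(shepard_tone(0, duration = 0.05), 16000, c(100, 7000))
  write_wav(x, 16000, p)
  raw <- readBin(p, "raw", 100)
  expect_identical(rawToChar(raw[1:4]), "RIFF")
  expect_identical(rawToChar(raw[9:12]), "WAVE")
  expect_equal(file.size(p), 44 + 2 * length(x))
  unlink(p)
})
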