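# local helper: write a minimal PCM16 mono WAV
write_wav16 <- function(samples, sr, path) {
  x <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_len <- 2L * length(x)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_len, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")        # PCM
  writeBin(1L, con, size = 2, endian = "little")        # mono
  writeBin(as.integer(sr), con, size = 4, endian = "little")
  writeBin(as.integer(sr * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_len, con, size = 4, endian = "little")
  writeBin(x, con, size = 2, endian = "little")
}

test_that("silence yields near-floor Mel energies and tones hit the right band", {
  cfg <- mel_config()
  sil <- mel_frame_features(numeric(16000), sr = 16000, cfg = cfg)
  expect_true(all(abs(sil - log(cfg$floor)) < 1e-6))
  expect_equal(ncol(sil), cfg$n_mels)
  expect_false(is.null(attr(sil, "times")))

  t <- seq(0, 1, length.out = 16000)
  tone <- 0.5 * sin(2 * pi * 1000 * t)
  M <- mel_frame_features(tone, sr = 16000, cfg = cfg)
  band <- apply(M, 1, which.max)
  expect_equal(length(unique(band)), 1)     # constant argmax band
  # the winning band's center frequency brackets 1 kHz (filterbank oracle)
  mel_pts <- 2595 * log10(1 + seq(0, 8000, length.out = cfg$n_mels + 2) / 700)
  # oracle: nearest Mel center to 1 kHz on the package's stated Mel scale
  centers <- 700 * (10^(seq(2595 * log10(1 + 0 / 700),
                            2595 * log10(1 + 8000 / 700),
                            length.out = cfg$n_mels + 2)[2:(cfg$n_mels + 1)] / 2595) - 1)
  expect_equal(unique(band), which.min(abs(centers - 1000)))
})

test_that("doubling amplitude shifts every log energy by log 2", {
  set.seed(2)
  x <- rnorm(8000) * 0.1
  a <- mel_frame_features(x, sr = 16000)
  b <- mel_frame_features(2 * x, sr = 16000)
  expect_equal(b, a + log(2), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("degenerate audio inputs error", {
  expect_error(mel_frame_features(numeric(0), sr = 16000), "empty")
  expect_error(mel_frame_features(c(0, 2, 0), sr = 16000), "clipped")
})

test_that("PCM WAV files round-trip through read_wav into the Mel path", {
  f <- tempfile(fileext = ".wav")
  t <- seq(0, 0.5, length.out = 8000)
  x <- 0.4 * sin(2 * pi * 440 * t)
  write_wav16(x, 16000, f)
  got <- read_wav(f)
  expect_equal(got$sr, 16000)
  expect_equal(got$samples, x, tolerance = 1e-3)
  M <- mel_frame_features(got)
  expect_equal(ncol(M), 40)
})

test_that("phone mean spectra average the frames inside the interval", {
  frames <- rbind(c(1, 2), c(3, 4), c(5, 6))
  attr(frames, "times") <- c(0.05, 0.15, 0.25)
  expect_equal(as.numeric(phone_mean_spectrum(frames, 0.1, 0.3)), c(4, 5))
  expect_equal(as.numeric(phone_mean_spectrum(frames, 0, 0.06)), c(1, 2))
  expect_null(phone_mean_spectrum(frames, 0.3, 0.4))

  # brute-force masking oracle on random alignments
  set.seed(5)
  F2 <- matrix(rnorm(200), ncol = 4)
  attr(F2, "times") <- sort(runif(50))
  for (rep in 1:10) {
    a <- runif(1, 0, 0.8); b <- a + runif(1, 0.05, 0.2)
    mask <- attr(F2, "times") >= a & attr(F2, "times") < b
    if (!any(mask)) next
    expect_equal(as.numeric(phone_mean_spectrum(F2, a, b)),
                 colMeans(F2[mask, , drop = FALSE]))
  }
})

test_that("spectral distance is the Euclidean metric", {
  expect_equal(spectral_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(spectral_distance(c(0, 3, 4), c(0, 0, 0)), 5)
  expect_error(spectral_distance(1:3, 1:4), "length")
  set.seed(8)
  for (rep in 1:50) {
    a <- rnorm(10); b <- rnorm(10); c <- rnorm(10)
    expect_gte(spectral_distance(a, b), 0)
    expect_equal(spectral_distance(a, b), spectral_distance(b, a))
    expect_lte(spectral_distance(a, c),
               spectral_distance(a, b) + spectral_distance(b, c) + 1e-12)
  }
})

test_that("pair eligibility applies the stop, /h/, stress, content and flag filters", {
  lx <- cds_lexicon(data.frame(
    orthography = c("cat", "sat", "hat", "the"),
    pronunciation = c("K AE1 T", "S AE1 T", "HH AE1 T", "DH AH0"),
    log10_frequency = 1, is_function_word = c(0, 0, 0, 1)))

  s <- make_session(c("cat", "sat", "hat", "the", "sat"),
                    list(c("K", "AE1", "T"), c("S", "AE1", "T"),
                         c("HH", "AE1", "T"), c("DH", "AH0"),
                         c("S", "AE0", "T")))
  el <- eligible_pairs(s, lexicon = lx)
  led <- el$ledger
  # "cat": (K, AE1) stop-vowel excluded; (AE1, T) VC with a stop is eligible
  expect_equal(unname(led["stop_vowel"]), 1)
  # "hat": (HH, AE1) excluded
  expect_equal(unname(led["h_vowel"]), 1)
  # "the": function word, both its pairs excluded
  expect_equal(unname(led["function_word"]), 1)
  # final "sat" with AE0: unstressed pairs excluded
  expect_equal(unname(led["unstressed"]), 2)
  # eligible: sat (S,AE1) + (AE1,T), cat (AE1,T), hat (AE1,T)
  expect_equal(unname(led["eligible"]), 4)
  expect_setequal(el$pairs$order[el$pairs$word_index == 2], c("CV", "VC"))

  # flags dominate every other exclusion reason
  ph <- make_phones(list(c("S", "AE1", "T")))
  ph$whispered <- TRUE
  sf <- cds_session("d", "24", make_tokens("sat"), ph)
  elf <- eligible_pairs(sf, lexicon = lx)
  expect_equal(unname(elf$ledger["flagged"]), 2)
  expect_equal(nrow(elf$pairs), 0)
})

test_that("every enumerated pair lands in exactly one ledger category", {
  cfg <- generator_config(seed = 31, targets = simulation_targets())
  lex <- gen_lexicon(cfg)
  s <- gen_session(2, "7", cfg, lex)
  el <- eligible_pairs(s, lexicon = lex)
  # re-enumerate candidate CV/VC adjacent same-word pairs independently
  ph <- s$phones
  n <- nrow(ph)
  adj <- abs(ph$end[-n] - ph$start[-1]) <= 0.001
  vw <- is_vowel(ph$label)
  cand <- sum(adj & ph$word_index[-n] == ph$word_index[-1] & xor(vw[-n], vw[-1]))
  expect_equal(sum(el$ledger), cand)
})

test_that("Lobanov normalization yields zero-mean unit-sd formants per session", {
  set.seed(12)
  fm <- data.frame(F1_hz = rnorm(30, 600, 80), F2_hz = rnorm(30, 1800, 150))
  z <- lobanov_normalize(fm)
  expect_equal(mean(z$F1_z), 0, tolerance = 1e-12)
  expect_equal(sd(z$F2_z), 1, tolerance = 1e-12)

  # invariance to affine rescaling of the Hz values
  fm2 <- data.frame(F1_hz = 2 * fm$F1_hz + 100, F2_hz = 2 * fm$F2_hz + 100)
  z2 <- lobanov_normalize(fm2)
  expect_equal(z2$F1_z, z$F1_z, tolerance = 1e-10)

  # fewer than two tokens: normalization null, raw retained
  one <- lobanov_normalize(data.frame(F1_hz = 500, F2_hz = 1500))
  expect_true(is.na(one$F1_z))
  expect_equal(one$F1_hz, 500)

  expect_error(lobanov_normalize(data.frame(F1_hz = c(500, 1600),
                                            F2_hz = c(1500, 1500))),
               "F2_hz > F1_hz")
})

test_that("vowel space area matches the shoelace geometry", {
  fm <- data.frame(corner = c("i", "a", "u"),
                   F1_hz = c(300, 301, 300) + c(0, 0, 1),
                   F2_hz = c(2000, 2000, 2001),
                   F1_z = c(0, 0, 1), F2_z = c(0, 1, 0))
  got <- vowel_space_area(fm)
  expect_equal(got$area_z, 0.5)   # unit right triangle

  # collinear category means give zero area
  fm$F1_z <- c(0, 1, 2); fm$F2_z <- c(0, 1, 2)
  expect_equal(vowel_space_area(fm)$area_z, 0)

  # missing category -> NA
  expect_true(is.na(vowel_space_area(fm[fm$corner != "u", ])$area_z))

  # random triangles vs the half-|cross product| oracle
  set.seed(19)
  for (rep in 1:50) {
    f1 <- rnorm(3); f2 <- rnorm(3)
    fmr <- data.frame(corner = c("i", "a", "u"),
                      F1_hz = 300 + 1:3, F2_hz = 2000 + 1:3,
                      F1_z = f1, F2_z = f2)
    v1 <- c(f2[2] - f2[1], f1[2] - f1[1])
    v2 <- c(f2[3] - f2[1], f1[3] - f1[1])
    oracle <- abs(v1[1] * v2[2] - v1[2] * v2[1]) / 2
    expect_equal(vowel_space_area(fmr)$area_z, oracle, tolerance = 1e-12)
  }
})

test_that("area depends on tokens only through the category means", {
  set.seed(29)
  fm <- data.frame(corner = rep(c("i", "a", "u"), each = 5),
                   F1_hz = rep(c(300, 800, 350), each = 5) + rnorm(15, 0, 10),
                   F2_hz = rep(c(2500, 1300, 1000), each = 5) + rnorm(15, 0, 20))
  fm <- lobanov_normalize(fm)
  base <- vowel_space_area(fm)$area_z
  perm <- do.call(rbind, lapply(split(fm, fm$corner), function(g) g[sample(nrow(g)), ]))
  expect_equal(vowel_space_area(perm)$area_z, base)
})

test_that("dispersion measures distance from the session median, per word type", {
  fm <- data.frame(F1_z = c(0, 3, 0), F2_z = c(0, 4, 0),
                   orthography = c("a", "b", "a"))
  # medians are 0,0: token at the median has dispersion 0, (3,4) has 5
  got <- vowel_dispersion(fm)
  expect_equal(got$per_token$dispersion, c(0, 5, 0))
  expect_equal(got$per_type$dispersion[got$per_type$orthography == "b"], 5)

  # type averaging equals a group-by-mean oracle
  set.seed(37)
  fmr <- data.frame(F1_z = rnorm(40), F2_z = rnorm(40),
                    orthography = sample(c("w1", "w2", "w3"), 40, TRUE))
  gotr <- vowel_dispersion(fmr)
  d <- sqrt((fmr$F1_z - median(fmr$F1_z))^2 + (fmr$F2_z - median(fmr$F2_z))^2)
  oracle <- tapply(d, fmr$orthography, mean)
  expect_equal(gotr$per_type$dispersion,
               as.numeric(oracle[gotr$per_type$orthography]))
})

test_that("phone durations are reported in ms with flagged phones removed", {
  ph <- make_phones(list(c("K", "AE1", "T")), dur = 0.15)
  s <- cds_session("d", "24", make_tokens("cat"), ph)
  got <- duration_summary(s)
  expect_equal(got$durations_ms, rep(150, 3))
  expect_equal(got$median_duration_ms, 150)

  ph$whispered <- TRUE
  s2 <- cds_session("d", "24", make_tokens("cat"), ph)
  expect_true(is.na(duration_summary(s2)$median_duration_ms))
})
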