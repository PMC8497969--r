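# Hyperarticulation measures: Lobanov-normalized vowel space area and vowel
# dispersion from midpoint F1/F2, phone duration, and consonant-vowel
# coarticulation as the Euclidean distance between time-averaged Mel
# log-magnitude spectra of adjacent phones (larger distance = less
# coarticulation). Formants are consumed as input; no tracker is included.

#' Default Mel analysis configuration
#'
#' Standard speech-analysis settings: 25 ms Hann window, 10 ms hop, 40 Mel
#' bands spanning 0-8 kHz at a 16 kHz sample rate, log floor 1e-10. Spectral
#' distances are only comparable between analyses run under one
#' configuration.
#'
#' @param frame_ms,hop_ms analysis window and hop in milliseconds.
#' @param n_mels number of Mel filterbank bands.
#' @param fmin_hz,fmax_hz filterbank frequency range.
#' @param sr target sample rate in Hz (input audio is resampled to this).
#' @param floor additive constant inside the log.
#' @return a named list.
#' @export
mel_config <- function(frame_ms = 25, hop_ms = 10, n_mels = 40,
                       fmin_hz = 0, fmax_hz = 8000, sr = 16000,
                       floor = 1e-10) {
  list(frame_ms = frame_ms, hop_ms = hop_ms, n_mels = n_mels,
       fmin_hz = fmin_hz, fmax_hz = fmax_hz, sr = sr, floor = floor)
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# triangular Mel filterbank: n_mels x (n_fft/2 + 1)
mel_filterbank <- function(n_mels, n_fft, sr, fmin, fmax) {
  mel_pts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2)
  hz_pts <- mel_to_hz(mel_pts)
  bin_freqs <- seq(0, sr / 2, length.out = n_fft %/% 2 + 1)
  fb <- matrix(0, nrow = n_mels, ncol = length(bin_freqs))
  for (m in seq_len(n_mels)) {
    lo <- hz_pts[m]; ce <- hz_pts[m + 1]; hi <- hz_pts[m + 2]
    up <- (bin_freqs - lo) / (ce - lo)
    dn <- (hi - bin_freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed 8/16/32-bit integer PCM, mono.
#'
#' @param path file path.
#' @return list with `samples` (numeric in \[-1, 1\]) and `sr` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (rawToChar(readBin(con, "raw", 4)) != "RIFF") stop("not a RIFF file", call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (rawToChar(readBin(con, "raw", 4)) != "WAVE") stop("not a WAVE file", call. = FALSE)
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readBin(con, "raw", 4)
    if (length(id) < 4) break
    id <- rawToChar(id)
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = sum(as.integer(body[1:2]) * c(1, 256)),
        n_channels = sum(as.integer(body[3:4]) * c(1, 256)),
        sr = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits = sum(as.integer(body[15:16]) * c(1, 256)))
    } else if (id == "data") {
      if (is.null(fmt)) stop("malformed WAV: data before fmt chunk", call. = FALSE)
      if (fmt$audio_format != 1) stop("only uncompressed PCM WAV is supported", call. = FALSE)
      if (fmt$n_channels != 1) stop("only mono WAV is supported", call. = FALSE)
      if (fmt$bits == 16) {
        x <- readBin(con, "integer", sz / 2, size = 2, signed = TRUE, endian = "little")
        samples <- x / 32768
      } else if (fmt$bits == 8) {
        x <- readBin(con, "integer", sz, size = 1, signed = FALSE)
        samples <- (x - 128) / 128
      } else if (fmt$bits == 32) {
        x <- readBin(con, "integer", sz / 4, size = 4, endian = "little")
        samples <- x / 2147483648
      } else stop("unsupported PCM bit depth: ", fmt$bits, call. = FALSE)
    } else {
      readBin(con, "raw", sz + sz %% 2)
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found in WAV", call. = FALSE)
  list(samples = samples, sr = fmt$sr)
}

#' Frame-level Mel log-magnitude features
#'
#' Short-time analysis of a mono waveform: Hann-windowed STFT magnitude,
#' Mel filterbank, then `log(x + floor)`. Audio at a sample rate other than
#' the configured one is resampled first.
#'
#' @param wav numeric waveform in \[-1, 1\], or a list with `samples` and
#'   `sr` as returned by [read_wav()].
#' @param sr sample rate of `wav` (ignored when `wav` carries its own).
#' @param cfg a [mel_config()].
#' @return numeric matrix (frames x n_mels) with attribute `"times"` giving
#'   each frame's center time in seconds.
#' @export
mel_frame_features <- function(wav, sr = NULL, cfg = mel_config()) {
  if (is.list(wav)) { sr <- wav$sr; wav <- wav$samples }
  if (is.null(sr)) stop("sample rate required", call. = FALSE)
  if (length(wav) == 0) stop("empty audio", call. = FALSE)
  if (any(abs(wav) > 1 + 1e-6)) stop("clipped audio: samples outside [-1, 1]", call. = FALSE)
  if (sr != cfg$sr) {
    wav <- signal::resample(wav, p = cfg$sr, q = sr)
    sr <- cfg$sr
  }
  frame_len <- round(cfg$frame_ms / 1000 * sr)
  hop <- round(cfg$hop_ms / 1000 * sr)
  if (length(wav) < frame_len) stop("audio shorter than one analysis frame", call. = FALSE)
  starts <- seq(1, length(wav) - frame_len + 1, by = hop)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, frame_len - 1) / (frame_len - 1))
  n_fft <- 2^ceiling(log2(frame_len))
  fb <- mel_filterbank(cfg$n_mels, n_fft, sr, cfg$fmin_hz, cfg$fmax_hz)
  frames <- vapply(starts, function(s) {
    seg <- wav[s:(s + frame_len - 1)] * win
    spec <- Mod(stats::fft(c(seg, numeric(n_fft - frame_len))))[1:(n_fft %/% 2 + 1)]
    as.numeric(log(fb %*% spec + cfg$floor))
  }, numeric(cfg$n_mels))
  out <- t(frames)
  attr(out, "times") <- (starts - 1 + frame_len / 2) / sr
  out
}

#' Time-averaged Mel spectrum of one phone
#'
#' Arithmetic mean of the frame vectors whose centers fall inside the phone
#' interval \[start, end).
#'
#' @param frames matrix from [mel_frame_features()] (or any frames x bands
#'   matrix with a `"times"` attribute).
#' @param start,end phone interval in seconds.
#' @return numeric vector of length `ncol(frames)` with attribute
#'   `"n_frames"`, or `NULL` when no frame center falls inside the phone
#'   (the observation is dropped by callers and counted).
#' @export
phone_mean_spectrum <- function(frames, start, end) {
  times <- attr(frames, "times")
  if (is.null(times)) stop("frames matrix lacks a 'times' attribute", call. = FALSE)
  sel <- times >= start & times < end
  if (!any(sel)) return(NULL)
  out <- colMeans(frames[sel, , drop = FALSE])
  attr(out, "n_frames") <- sum(sel)
  out
}

#' Euclidean distance between two averaged spectra
#'
#' The coarticulation statistic: l2 norm of the difference between the
#' time-averaged Mel log-magnitude spectra of neighboring phones. A larger
#' distance means less coarticulation.
#'
#' @param s1,s2 equal-length numeric vectors.
#' @return non-negative scalar.
#' @export
#' @examples
#' spectral_distance(c(0, 3, 4), c(0, 0, 0))  # 5
spectral_distance <- function(s1, s2) {
  if (length(s1) != length(s2)) {
    stop("spectra differ in length", call. = FALSE)
  }
  sqrt(sum((as.numeric(s1) - as.numeric(s2))^2))
}

# ---------------------------------------------------------------------------
# Eligibility

#' Eligible consonant-vowel coarticulation pairs of a session
#'
#' Enumerates adjacent within-word phone pairs that are consonant-vowel (CV)
#' or vowel-consonant (VC) and applies the eligibility filters: the pair is
#' excluded when the consonant is an oral stop preceding the vowel
#' (utterance-initial closures cannot be delimited; VC order with a stop is
#' eligible), the consonant is the voiceless glottal fricative /h/ preceding
#' the vowel, the vowel is unstressed, the word is a function word (content
#' words only), or either phone carries a whispered/yelled/overlap flag.
#' Each excluded pair lands in exactly one ledger category, applied in that
#' priority order.
#'
#' Content-word status is taken from the token's `is_content` flag when set,
#' else from the lexicon's function-word flag when a lexicon is supplied;
#' tokens with unknown status are treated as content words.
#'
#' @param session a [cds_session()].
#' @param lexicon optional [cds_lexicon()] used to resolve function words.
#' @param tol adjacency tolerance in seconds.
#' @return list with `pairs` (data frame of eligible pairs: `c_index`,
#'   `v_index`, `word_index`, `order` in `c("CV", "VC")`) and `ledger`
#'   (named integer exclusion counts plus `eligible`).
#' @export
eligible_pairs <- function(session, lexicon = NULL, tol = 0.001) {
  ph <- session$phones
  tok <- session$tokens
  n <- nrow(ph)
  ledger <- c(eligible = 0L, flagged = 0L, function_word = 0L,
              unstressed = 0L, stop_vowel = 0L, h_vowel = 0L)
  empty <- data.frame(c_index = integer(0), v_index = integer(0),
                      word_index = integer(0), order = character(0))
  if (n < 2) return(list(pairs = empty, ledger = ledger))
  adj <- adjacent_phones(ph, tol = tol)
  is_content <- resolve_is_content(tok, lexicon)
  vow <- is_vowel(ph$label)
  stressed <- is_stressed(ph$label)
  flagged <- ph$whispered | ph$yelled | ph$overlap
  inv <- arpabet_inventory()
  base <- strip_stress(ph$label)
  i <- seq_len(n - 1L)
  j <- i + 1L
  same_word <- adj & !is.na(ph$word_index[i]) & !is.na(ph$word_index[j]) &
    ph$word_index[i] == ph$word_index[j]
  same_word[is.na(same_word)] <- FALSE
  cv <- same_word & !vow[i] & vow[j]
  vc <- same_word & vow[i] & !vow[j]
  cand <- which(cv | vc)
  if (length(cand) == 0) return(list(pairs = empty, ledger = ledger))
  ci <- ifelse(cv[cand], cand, cand + 1L)
  vi <- ifelse(cv[cand], cand + 1L, cand)
  reason <- rep("eligible", length(cand))
  reason[cv[cand] & base[ci] == inv$glottal] <- "h_vowel"
  reason[cv[cand] & base[ci] %in% inv$stops] <- "stop_vowel"
  reason[!stressed[vi]] <- "unstressed"
  reason[!is_content[ph$word_index[cand]]] <- "function_word"
  reason[flagged[cand] | flagged[cand + 1L]] <- "flagged"
  tab <- table(factor(reason, levels = names(ledger)))
  ledger[names(tab)] <- as.integer(tab)
  keep <- reason == "eligible"
  pairs <- data.frame(c_index = ci[keep], v_index = vi[keep],
                      word_index = ph$word_index[cand[keep]],
                      order = ifelse(cv[cand[keep]], "CV", "VC"),
                      stringsAsFactors = FALSE)
  list(pairs = pairs, ledger = ledger)
}

#' Coarticulation observations of a session
#'
#' Combines [eligible_pairs()] with the session's per-phone averaged Mel
#' spectra and computes the spectral distance of each eligible pair.
#'
#' @param session a [cds_session()] whose `spectra` matrix is set (one row
#'   per phone; rows of phones without spectral coverage may be `NA`).
#' @param lexicon optional [cds_lexicon()] for function-word resolution.
#' @param tol adjacency tolerance in seconds.
#' @return list with `observations` (the eligible-pair data frame plus a
#'   `distance` column), `ledger` (exclusions, incl. `no_spectrum`), and
#'   `median_distance`.
#' @export
coarticulation_observations <- function(session, lexicon = NULL, tol = 0.001) {
  if (is.null(session$spectra)) {
    stop("session carries no phone spectra", call. = FALSE)
  }
  el <- eligible_pairs(session, lexicon = lexicon, tol = tol)
  pr <- el$pairs
  S1 <- session$spectra[pr$c_index, , drop = FALSE]
  S2 <- session$spectra[pr$v_index, , drop = FALSE]
  ok <- !(rowSums(is.na(S1)) > 0 | rowSums(is.na(S2)) > 0)
  dist <- rep(NA_real_, nrow(pr))
  dist[ok] <- sqrt(rowSums((S1[ok, , drop = FALSE] - S2[ok, , drop = FALSE])^2))
  ledger <- el$ledger
  ledger["no_spectrum"] <- sum(!ok)
  ledger["eligible"] <- sum(ok)
  pr$distance <- dist
  obs <- pr[ok, , drop = FALSE]
  list(observations = obs, ledger = ledger,
       median_distance = if (nrow(obs) > 0) stats::median(obs$distance) else NA_real_)
}

# ---------------------------------------------------------------------------
# Vowel space

#' Lobanov normalization of formant measurements
#'
#' Per speaker-session and per formant, z-scores the midpoint formant
#' values over all measured vowel tokens of that session, removing
#' speaker-specific anatomical differences. With fewer than two tokens the
#' normalized values are `NA` and the raw Hz values are retained.
#'
#' @param formants data frame with columns `F1_hz`, `F2_hz` (one row per
#'   measured vowel token of a single speaker-session).
#' @return the input with `F1_z`, `F2_z` columns added.
#' @export
lobanov_normalize <- function(formants) {
  formants <- as.data.frame(formants)
  if (nrow(formants) > 0 &&
      any(formants$F1_hz <= 0 | formants$F2_hz <= formants$F1_hz)) {
    stop("formants must satisfy F2_hz > F1_hz > 0", call. = FALSE)
  }
  if (nrow(formants) < 2) {
    formants$F1_z <- rep(NA_real_, nrow(formants))
    formants$F2_z <- rep(NA_real_, nrow(formants))
    return(formants)
  }
  formants$F1_z <- as.numeric(scale(formants$F1_hz))
  formants$F2_z <- as.numeric(scale(formants$F2_hz))
  formants
}

triangle_area <- function(x, y) {
  # shoelace formula for a triangle
  abs(x[1] * (y[2] - y[3]) + x[2] * (y[3] - y[1]) + x[3] * (y[1] - y[2])) / 2
}

#' Vowel space area from peripheral-vowel formants
#'
#' Area of the triangle whose vertices are the per-category mean (F2, F1)
#' positions of the peripheral vowels /i/, /a/ and /u/, computed both in
#' Lobanov-normalized space and in raw Hz. A missing category yields `NA`
#' for the affected space.
#'
#' @param formants data frame with columns `corner` (`"i"`, `"a"`, `"u"`),
#'   `F1_hz`, `F2_hz` and (optionally, from [lobanov_normalize()]) `F1_z`,
#'   `F2_z`.
#' @return list with `area_z`, `area_hz` and `n_tokens` per category.
#' @export
vowel_space_area <- function(formants) {
  formants <- as.data.frame(formants)
  corners <- c("i", "a", "u")
  n_tokens <- vapply(corners, function(cc) sum(formants$corner == cc, na.rm = TRUE),
                     integer(1))
  area_in <- function(f1col, f2col) {
    if (any(n_tokens == 0)) return(NA_real_)
    if (!all(c(f1col, f2col) %in% names(formants))) return(NA_real_)
    m1 <- vapply(corners, function(cc) mean(formants[[f1col]][formants$corner == cc]),
                 numeric(1))
    m2 <- vapply(corners, function(cc) mean(formants[[f2col]][formants$corner == cc]),
                 numeric(1))
    if (anyNA(m1) || anyNA(m2)) return(NA_real_)
    unname(triangle_area(m2, m1))
  }
  list(area_z = area_in("F1_z", "F2_z"),
       area_hz = area_in("F1_hz", "F2_hz"),
       n_tokens = n_tokens)
}

#' Vowel dispersion of a speaker-session
#'
#' Euclidean distance of each vowel token from the speaker-session median
#' (F1, F2) position in Lobanov space, then averaged within word type so
#' each type contributes one observation (avoiding skew from high-frequency
#' words). Per-token distances are also returned.
#'
#' @param formants data frame with columns `F1_z`, `F2_z` and `orthography`
#'   (owning word type of each token).
#' @return list with `per_token` (input plus `dispersion`), `per_type`
#'   (data frame `orthography`, `dispersion`), and `median_dispersion` (the
#'   median of the per-type values).
#' @export
vowel_dispersion <- function(formants) {
  formants <- as.data.frame(formants)
  if (nrow(formants) == 0 || all(is.na(formants$F1_z))) {
    return(list(per_token = formants, per_type = NULL,
                median_dispersion = NA_real_))
  }
  med1 <- stats::median(formants$F1_z, na.rm = TRUE)
  med2 <- stats::median(formants$F2_z, na.rm = TRUE)
  formants$dispersion <- sqrt((formants$F1_z - med1)^2 + (formants$F2_z - med2)^2)
  per_type <- stats::aggregate(dispersion ~ orthography, data = formants,
                               FUN = mean)
  list(per_token = formants, per_type = per_type,
       median_dispersion = stats::median(per_type$dispersion, na.rm = TRUE))
}

# content-word status: token flag when set, else lexicon function-word
# lookup, else content by default
resolve_is_content <- function(tok, lexicon = NULL) {
  is_content <- tok$is_content
  if (!is.null(lexicon)) {
    fw <- attr(lexicon, "fun_by_orth")
    if (is.null(fw)) fw <- tapply(lexicon$is_function_word, lexicon$orthography, any)
    lex_fun <- unname(fw[tok$orthography])
    is_content <- ifelse(is.na(is_content), !lex_fun, is_content)
  }
  is_content[is.na(is_content)] <- TRUE
  is_content
}

#' Phone duration summary of a session
#'
#' Durations in milliseconds of all phones passing the
#' whispered/yelled/overlap filter, with the session median.
#'
#' @param session a [cds_session()].
#' @return list with `durations_ms` (per kept phone) and
#'   `median_duration_ms` (`NA` when no phone survives the filter).
#' @export
duration_summary <- function(session) {
  ph <- session$phones
  keep <- !(ph$whispered | ph$yelled | ph$overlap)
  dur <- (ph$end[keep] - ph$start[keep]) * 1000
  list(durations_ms = dur,
       median_duration_ms = if (length(dur) > 0) stats::median(dur) else NA_real_)
}
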