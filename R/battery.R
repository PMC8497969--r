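# End-to-end feature extraction: one FeatureRow per (dyad, timepoint),
# combining the lexical and acoustic batteries, plus the corpus-level
# pooled-median counts (long words, low-frequency words).

#' Compute the full feature row of one session
#'
#' Runs transcript cleaning, type/token statistics, MATTR, the per-type
#' lexical profile, and — where the session carries formants and phone
#' spectra — the acoustic battery (Lobanov vowel space area, vowel
#' dispersion, phone duration, coarticulation spectral distance). Formant
#' tokens are restricted to stressed peripheral vowels in content words
#' whose phones are not flagged whispered/yelled/overlap. Missing acoustic
#' measures are `NA`, never 0. The pooled-median counts (`n_long_words`,
#' `n_low_freq_words`) need cross-caregiver medians and are `NA` here; they
#' are filled by [battery()].
#'
#' @param session a [cds_session()].
#' @param lexicon a [cds_lexicon()].
#' @param type_stats optional precomputed [lexicon_type_stats()].
#' @param mattr_window MATTR window in tokens.
#' @param tol adjacency tolerance in seconds.
#' @return list with `row` (one-row data frame of `FEATURE_COLUMNS`),
#'   `profiles` (per-type lexical profile) and `ledgers`.
#' @export
session_features <- function(session, lexicon,
                             type_stats = lexicon_type_stats(lexicon),
                             mattr_window = 10, tol = 0.001) {
  lex <- lexical_profile(session, lexicon, type_stats = type_stats)
  toks <- lex$cleaning$tokens
  if (nrow(toks) == 0) stop("session has no tokens after cleaning", call. = FALSE)
  tts <- type_token_stats(toks)
  mt <- mattr(toks, window = mattr_window)
  dur <- duration_summary(session)

  coart_med <- NA_real_
  n_pairs <- 0L
  coart_ledger <- NULL
  if (!is.null(session$spectra)) {
    co <- coarticulation_observations(session, lexicon = lexicon, tol = tol)
    coart_med <- co$median_distance
    n_pairs <- nrow(co$observations)
    coart_ledger <- co$ledger
  }

  area_z <- area_hz <- disp_med <- NA_real_
  n_formant <- 0L
  if (!is.null(session$formants) && nrow(session$formants) > 0) {
    fm <- prepare_formants(session, lexicon)
    n_formant <- nrow(fm)
    if (n_formant > 0) {
      fm <- lobanov_normalize(fm)
      vsa <- vowel_space_area(fm)
      area_z <- vsa$area_z
      area_hz <- vsa$area_hz
      disp_med <- vowel_dispersion(fm)$median_dispersion
    }
  }

  row <- data.frame(
    dyad_id = session$dyad_id, timepoint = session$timepoint,
    n_types = tts$n_types, n_tokens = tts$n_tokens, ttr = tts$ttr,
    mattr = mt$mattr, mattr_fallback = mt$fallback,
    mean_word_length = lex$summaries$mean_word_length,
    median_log_frequency = lex$summaries$median_log_frequency,
    median_neighborhood_density = lex$summaries$median_neighborhood_density,
    mean_phonprob_z = lex$summaries$mean_phonprob_z,
    n_long_words = NA_integer_, n_low_freq_words = NA_integer_,
    vowel_space_area_z = area_z, vowel_space_area_hz = area_hz,
    median_dispersion = disp_med,
    median_phone_duration_ms = dur$median_duration_ms,
    median_coarticulation_distance = coart_med,
    n_profiled_types = lex$summaries$n_profiled_types,
    n_formant_tokens = n_formant,
    n_duration_phones = length(dur$durations_ms),
    n_coarticulation_pairs = n_pairs,
    stringsAsFactors = FALSE)
  list(row = row, profiles = lex$profiles,
       ledgers = list(cleaning = lex$cleaning$ledger,
                      coarticulation = coart_ledger))
}

# filter a session's formant table to measurable vowel tokens: stressed
# peripheral vowels, content words, unflagged phones; attach corner and
# owning orthography
prepare_formants <- function(session, lexicon = NULL) {
  fm <- as.data.frame(session$formants)
  ph <- session$phones
  tok <- session$tokens
  idx <- fm$phone_index
  lab <- ph$label[idx]
  keep <- !is.na(vowel_corner(lab)) & is_stressed(lab) &
    !(ph$whispered[idx] | ph$yelled[idx] | ph$overlap[idx]) &
    !is.na(ph$word_index[idx])
  is_content <- resolve_is_content(tok, lexicon)
  keep <- keep & is_content[ph$word_index[idx]]
  keep[is.na(keep)] <- FALSE
  fm <- fm[keep, , drop = FALSE]
  fm$corner <- vowel_corner(ph$label[fm$phone_index])
  fm$orthography <- tok$orthography[ph$word_index[fm$phone_index]]
  rownames(fm) <- NULL
  fm
}

#' Run the battery over a whole corpus
#'
#' Computes [session_features()] for every session, then fills the pooled
#' median-split counts: per timepoint, the median word length and median
#' log frequency are pooled over all caregivers' profiled types (one
#' observation per caregiver-type, no deduplication across caregivers), and
#' each caregiver's `n_long_words` (length at or above the pooled median)
#' and `n_low_freq_words` (log frequency strictly below the pooled median)
#' are counted.
#'
#' @param sessions list of [cds_session()] objects.
#' @param lexicon a [cds_lexicon()].
#' @param type_stats optional precomputed [lexicon_type_stats()].
#' @param ... passed to [session_features()].
#' @return list with `features` (data frame, one row per session),
#'   `profiles` (named list of per-type profiles, names `dyad@timepoint`)
#'   and `pooled_medians` (data frame per timepoint).
#' @export
battery <- function(sessions, lexicon,
                    type_stats = lexicon_type_stats(lexicon), ...) {
  res <- lapply(sessions, session_features, lexicon = lexicon,
                type_stats = type_stats, ...)
  features <- do.call(rbind, lapply(res, function(r) r$row))
  profiles <- lapply(res, function(r) r$profiles)
  names(profiles) <- paste0(features$dyad_id, "@", features$timepoint)
  pooled <- list()
  for (tp in unique(features$timepoint)) {
    sel <- which(features$timepoint == tp)
    lens <- lapply(profiles[sel], function(p) p$length_phonemes)
    freqs <- lapply(profiles[sel], function(p) p$log10_frequency)
    med_len <- pooled_type_median(lens)
    med_freq <- pooled_type_median(freqs)
    features$n_long_words[sel] <-
      vapply(lens, long_word_count, numeric(1), med_len)
    features$n_low_freq_words[sel] <-
      vapply(freqs, low_freq_count, numeric(1), med_freq)
    pooled[[tp]] <- data.frame(timepoint = tp,
                               pooled_median_length = med_len,
                               pooled_median_log_frequency = med_freq,
                               stringsAsFactors = FALSE)
  }
  list(features = features,
       profiles = profiles,
       pooled_medians = do.call(rbind, pooled))
}
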