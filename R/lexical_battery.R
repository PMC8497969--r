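# Phono-lexical measures of child-directed speech: transcript cleaning,
# type/token diversity (TTR, MATTR), and per-type lexical statistics against
# a pronouncing lexicon (positional biphone phonotactic probability,
# phonological neighborhood density, word length, word frequency), plus the
# median-split counts used to unnest per-type measures.

#' Clean a session's word inventory
#'
#' Applies the transcript cleaning rules: onomatopoeia, exclamations and
#' proper names are excluded everywhere (place names common to the sample
#' are expected to arrive untagged and are therefore retained); contractions
#' are retained for token/type/TTR counting but excluded from phono-lexical
#' lookups, since pronouncing dictionaries do not carry them.
#'
#' @param session a [cds_session()].
#' @return a list:
#'   \describe{
#'     \item{tokens}{token data frame kept for counting (TTR/MATTR/types/tokens).}
#'     \item{types}{character vector of distinct kept orthographies.}
#'     \item{types_pholex}{types additionally eligible for phono-lexical
#'       lookups (contractions removed).}
#'     \item{ledger}{named integer vector of exclusion counts by reason plus
#'       `kept`; sums to the input token count.}
#'   }
#' @export
clean_word_inventory <- function(session) {
  tok <- session$tokens
  reason <- rep(NA_character_, nrow(tok))
  reason[tok$proper_name] <- "proper_name"
  reason[tok$exclamation] <- "exclamation"
  reason[tok$onomatopoeia] <- "onomatopoeia"
  keep <- is.na(reason)
  kept <- tok[keep, , drop = FALSE]
  ledger <- c(kept = sum(keep),
              onomatopoeia = sum(reason == "onomatopoeia", na.rm = TRUE),
              exclamation = sum(reason == "exclamation", na.rm = TRUE),
              proper_name = sum(reason == "proper_name", na.rm = TRUE))
  types <- unique(kept$orthography)
  contraction_types <- unique(kept$orthography[kept$contraction])
  list(tokens = kept,
       types = types,
       types_pholex = setdiff(types, contraction_types),
       ledger = ledger)
}

#' Type and token counts with type-token ratio
#'
#' @param tokens character vector of word tokens (orthographies), or a token
#'   data frame with an `orthography` column.
#' @return list with `n_types`, `n_tokens` and `ttr = n_types / n_tokens`.
#' @export
#' @examples
#' type_token_stats(c("a", "a", "b", "c"))
type_token_stats <- function(tokens) {
  tokens <- as_token_chr(tokens)
  if (length(tokens) == 0) {
    stop("type/token statistics are undefined for an empty token list",
         call. = FALSE)
  }
  n_types <- length(unique(tokens))
  n_tokens <- length(tokens)
  list(n_types = n_types, n_tokens = n_tokens, ttr = n_types / n_tokens)
}

as_token_chr <- function(tokens) {
  if (is.data.frame(tokens)) tokens <- tokens$orthography
  as.character(tokens)
}

#' Moving-average type-token ratio (MATTR)
#'
#' Mean of the TTR over every contiguous window of exactly `window` tokens,
#' advancing one token at a time over the whole session token stream
#' (windows do not reset at utterance boundaries). If the session is shorter
#' than the window, the plain TTR is returned and flagged.
#'
#' @inheritParams type_token_stats
#' @param window window length in tokens (default 10).
#' @return list with `mattr` in (0, 1], `n_windows`, and logical `fallback`
#'   (TRUE when the plain TTR was substituted).
#' @export
#' @examples
#' mattr(rep("the", 20))$mattr   # 0.1: each 10-token window has one type
mattr <- function(tokens, window = 10) {
  tokens <- as_token_chr(tokens)
  if (length(tokens) == 0) {
    stop("MATTR is undefined for an empty token list", call. = FALSE)
  }
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  n <- length(tokens)
  if (n < window) {
    return(list(mattr = type_token_stats(tokens)$ttr, n_windows = 0L,
                fallback = TRUE))
  }
  ids <- as.integer(factor(tokens))
  n_win <- n - window + 1L
  # sliding distinct count via last-occurrence positions: token i starts a
  # new type within its window iff its previous occurrence is left of the
  # window start
  prev <- integer(n)
  last_seen <- integer(max(ids))
  for (i in seq_len(n)) {
    prev[i] <- last_seen[ids[i]]
    last_seen[ids[i]] <- i
  }
  types_in_window <- vapply(seq_len(n_win), function(s) {
    idx <- s:(s + window - 1L)
    sum(prev[idx] < s)
  }, numeric(1))
  list(mattr = mean(types_in_window) / window, n_windows = n_win,
       fallback = FALSE)
}

# ---------------------------------------------------------------------------
# Biphone tables and phonotactic probability

#' Build positional biphone tables from a lexicon
#'
#' Counts, for every 0-based segment position i and ordered symbol pair
#' (p, q), how many lexicon pronunciation variants contain that pair
#' starting at position i. Counting is type-based and unweighted: each
#' deduplicated pronunciation variant counts once, and stress digits are
#' stripped first. The positional total at i is the number of pronunciations
#' long enough to host a biphone there (length > i + 1), so each position is
#' a proper probability denominator. A frequency-weighted variant (weights =
#' `10^log10_frequency`) is available behind `weighted = TRUE`.
#'
#' @param lexicon a [cds_lexicon()].
#' @param weighted weight pronunciations by corpus frequency instead of
#'   counting each once.
#' @return object of class `biphone_tables`: list with `counts` (named
#'   numeric vector, names `"<i>:<p>+<q>"`) and `totals` (numeric vector,
#'   totals[i + 1] = total at position i).
#' @export
build_biphone_tables <- function(lexicon, weighted = FALSE) {
  prons <- lapply(pron_phones(lexicon$pronunciation), strip_stress)
  w <- if (weighted) 10^lexicon$log10_frequency else rep(1, length(prons))
  lens <- lengths(prons)
  max_pos <- max(c(0L, lens - 1L))
  counts <- new.env(hash = TRUE, parent = emptyenv())
  totals <- numeric(max(0L, max_pos))
  for (k in seq_along(prons)) {
    p <- prons[[k]]
    if (length(p) < 2) next
    for (i in seq_len(length(p) - 1L)) {
      totals[i] <- totals[i] + w[k]
      key <- paste0(i - 1L, ":", p[i], "+", p[i + 1L])
      counts[[key]] <- (if (is.null(counts[[key]])) 0 else counts[[key]]) + w[k]
    }
  }
  cvec <- unlist(as.list(counts))
  if (is.null(cvec)) cvec <- numeric(0)
  structure(list(counts = cvec, totals = totals), class = "biphone_tables")
}

#' Positional biphone phonotactic probability of a pronunciation
#'
#' Mean over biphone positions i of count(i, (p_i, p_{i+1})) / total(i) in
#' the reference tables. Stress digits are stripped. A biphone at a position
#' with zero total contributes probability 0. Pronunciations shorter than
#' two segments have no biphones and return `NA`.
#'
#' @param pron character vector of ARPAbet symbols, or a space-separated
#'   string.
#' @param tables a [build_biphone_tables()] result.
#' @return raw probability in \[0, 1\], or `NA` for a 1-segment pronunciation.
#' @export
phonotactic_probability <- function(pron, tables) {
  p <- as_pron(pron)
  if (length(p) < 2) return(NA_real_)
  probs <- vapply(seq_len(length(p) - 1L), function(i) {
    tot <- if (i <= length(tables$totals)) tables$totals[i] else 0
    if (tot == 0) return(0)
    key <- paste0(i - 1L, ":", p[i], "+", p[i + 1L])
    cnt <- tables$counts[key]
    if (is.na(cnt)) cnt <- 0
    cnt / tot
  }, numeric(1))
  mean(probs)
}

as_pron <- function(pron) {
  if (length(pron) == 1 && grepl("\\s", pron)) pron <- strsplit(pron, "\\s+")[[1]]
  strip_stress(pron)
}

#' Length-stratified z-scores for phonotactic probability
#'
#' Raw positional biphone probabilities confound word length (longer words
#' average over more, typically lower, biphone probabilities), so the raw
#' value is z-scored within its segment-length stratum. The reference
#' distribution for stratum L is the raw probability of every lexicon
#' pronunciation variant of length L. Strata with fewer than two members or
#' zero standard deviation yield `NA` with a warning.
#'
#' @param raw numeric vector of raw probabilities to normalize.
#' @param lengths integer vector of segment lengths (stress-stripped)
#'   matching `raw`.
#' @param lexicon a [cds_lexicon()].
#' @param tables optional precomputed [build_biphone_tables()]; built from
#'   `lexicon` if missing.
#' @return numeric vector of z-scores (sd uses the n-1 denominator).
#' @export
zscore_phonprob <- function(raw, lengths, lexicon,
                            tables = build_biphone_tables(lexicon)) {
  ref <- phonprob_reference(lexicon, tables)
  z <- rep(NA_real_, length(raw))
  degenerate <- character(0)
  for (L in unique(lengths[!is.na(raw)])) {
    stratum <- ref$raw[ref$length == L]
    sel <- which(lengths == L & !is.na(raw))
    if (length(stratum) < 2 || stats::sd(stratum) == 0) {
      degenerate <- c(degenerate, as.character(L))
      next
    }
    z[sel] <- (raw[sel] - mean(stratum)) / stats::sd(stratum)
  }
  if (length(degenerate) > 0) {
    warning("degenerate length stratum/strata (sd = 0 or < 2 members): ",
            paste(sort(unique(degenerate)), collapse = ", "), call. = FALSE)
  }
  z
}

# raw probability of every lexicon pronunciation, with segment lengths
phonprob_reference <- function(lexicon, tables = build_biphone_tables(lexicon)) {
  prons <- pron_phones(lexicon$pronunciation)
  data.frame(length = lengths(prons),
             raw = vapply(prons, phonotactic_probability, numeric(1),
                          tables = tables))
}

# ---------------------------------------------------------------------------
# Neighborhood density

#' Phonological neighborhood density
#'
#' Number of distinct lexicon orthographies (other than the query word
#' itself) with some pronunciation variant at phoneme edit distance exactly
#' one from the query pronunciation — one substitution, one deletion, or one
#' insertion. Stress digits are ignored; homophones count as distinct
#' orthographies, not distinct pronunciations.
#'
#' @param pron query pronunciation (character vector or space-separated
#'   string of ARPAbet symbols).
#' @param lexicon a [cds_lexicon()].
#' @param self_orthography orthography of the query word, excluded from the
#'   neighbor count (optional).
#' @return integer count >= 0.
#' @export
neighborhood_density <- function(pron, lexicon, self_orthography = NULL) {
  q <- as_pron(pron)
  prons <- lapply(pron_phones(lexicon$pronunciation), strip_stress)
  is_nb <- vapply(prons, is_one_edit, logical(1), q = q)
  orth <- unique(lexicon$orthography[is_nb])
  if (!is.null(self_orthography)) orth <- setdiff(orth, tolower(self_orthography))
  length(orth)
}

# exactly one substitution, deletion or insertion between q and p
is_one_edit <- function(p, q) {
  lq <- length(q); lp <- length(p)
  d <- lp - lq
  if (abs(d) > 1) return(FALSE)
  if (d == 0) {
    return(sum(p != q) == 1)
  }
  long <- if (d == 1) p else q
  short <- if (d == 1) q else p
  # deleting one symbol from `long` must yield `short`
  i <- 1L
  n <- length(short)
  while (i <= n && long[i] == short[i]) i <- i + 1L
  all(long[seq.int(i + 1L, length.out = n - i + 1L)] ==
        short[seq.int(i, length.out = n - i + 1L)])
}

#' Select a word's pronunciation variant by phonotactic probability
#'
#' Among an orthography's pronunciation variants, returns the one with the
#' highest positional biphone probability; exact ties (and all-length-1
#' variant sets, whose probability is undefined) fall back to the
#' first-listed variant, with a message.
#'
#' @param variants character vector of space-separated pronunciation
#'   variants (first-listed first).
#' @param tables a [build_biphone_tables()] result.
#' @return list with `pronunciation` (the selected variant string), `raw`
#'   (its probability, `NA` if undefined) and `tie` (logical).
#' @export
select_variant <- function(variants, tables) {
  if (length(variants) == 0) stop("no pronunciation variants", call. = FALSE)
  raw <- vapply(variants, phonotactic_probability, numeric(1), tables = tables,
                USE.NAMES = FALSE)
  if (all(is.na(raw))) {
    return(list(pronunciation = variants[1], raw = NA_real_, tie = FALSE))
  }
  best <- max(raw, na.rm = TRUE)
  hits <- which(!is.na(raw) & raw == best)
  tie <- length(hits) > 1
  if (tie) message("phonotactic-probability tie among variants; keeping first listed")
  list(pronunciation = variants[hits[1]], raw = raw[hits[1]], tie = tie)
}

# ---------------------------------------------------------------------------
# Per-type profiles and summaries

#' Precompute per-orthography lexical statistics for a whole lexicon
#'
#' Per-session profiling only ever looks up lexicon words, so the selected
#' variant, word length, neighborhood density and (z-scored) phonotactic
#' probability of every orthography can be computed once per lexicon and
#' reused across sessions. Neighbor search is restricted to pronunciations
#' whose lengths differ by at most one segment.
#'
#' @param lexicon a [cds_lexicon()].
#' @param tables optional precomputed [build_biphone_tables()].
#' @return data frame, one row per orthography: `orthography`,
#'   `pronunciation`, `length_phonemes`, `log10_frequency`,
#'   `neighborhood_density`, `phonprob_raw`, `phonprob_z`.
#' @export
lexicon_type_stats <- function(lexicon, tables = build_biphone_tables(lexicon)) {
  prons <- lapply(pron_phones(lexicon$pronunciation), strip_stress)
  lens <- lengths(prons)
  orths <- unique(lexicon$orthography)
  n <- length(orths)
  # neighbor sets over variants, then collapsed to distinct orthographies
  nb_orth <- vector("list", nrow(lexicon))
  by_len <- split(seq_len(nrow(lexicon)), lens)
  for (i in seq_len(nrow(lexicon))) {
    cand <- unlist(by_len[as.character(lens[i] + c(-1L, 0L, 1L))], use.names = FALSE)
    cand <- cand[cand != i]
    hit <- cand[vapply(cand, function(j) is_one_edit(prons[[j]], prons[[i]]),
                       logical(1))]
    nb_orth[[i]] <- lexicon$orthography[hit]
  }
  out <- data.frame(orthography = orths,
                    pronunciation = NA_character_,
                    length_phonemes = NA_integer_,
                    log10_frequency = NA_real_,
                    neighborhood_density = NA_integer_,
                    phonprob_raw = NA_real_,
                    phonprob_z = NA_real_,
                    stringsAsFactors = FALSE)
  rows_by_orth <- split(seq_len(nrow(lexicon)), lexicon$orthography)
  for (k in seq_len(n)) {
    rows <- rows_by_orth[[orths[k]]]
    sel <- suppressMessages(select_variant(lexicon$pronunciation[rows], tables))
    out$pronunciation[k] <- sel$pronunciation
    out$length_phonemes[k] <- length(as_pron(sel$pronunciation))
    out$log10_frequency[k] <- lexicon$log10_frequency[rows[1]]
    out$neighborhood_density[k] <-
      length(setdiff(unique(unlist(nb_orth[rows])), orths[k]))
    out$phonprob_raw[k] <- sel$raw
  }
  out$phonprob_z <- suppressWarnings(
    zscore_phonprob(out$phonprob_raw, out$length_phonemes, lexicon,
                    tables = tables))
  out
}

#' Per-type lexical profile of a session
#'
#' For every phono-lexically eligible word type of the cleaned inventory
#' (see [clean_word_inventory()]), looks the type up in the lexicon, selects
#' the pronunciation variant with the highest phonotactic probability, and
#' computes: length in phonemes (stress stripped), log10 corpus frequency,
#' phonological neighborhood density, and raw plus length-normalized (z)
#' phonotactic probability. Types absent from the lexicon are null-profiled
#' and counted. Lexical statistics are computed over word types, not tokens.
#'
#' Session-level summaries follow the battery's aggregators: median log
#' frequency, median neighborhood density, mean word length, mean
#' phonotactic-probability z-score.
#'
#' @param session a [cds_session()].
#' @param lexicon a [cds_lexicon()].
#' @param type_stats optional precomputed [lexicon_type_stats()]; pass it
#'   when profiling many sessions against one lexicon.
#' @return list with `profiles` (data frame, one row per type: `orthography`,
#'   `in_lexicon`, `pronunciation`, `length_phonemes`, `log10_frequency`,
#'   `neighborhood_density`, `phonprob_raw`, `phonprob_z`), `summaries`
#'   (named list), `cleaning` (the [clean_word_inventory()] result) and
#'   `n_missing` (types absent from the lexicon).
#' @export
lexical_profile <- function(session, lexicon,
                            type_stats = lexicon_type_stats(lexicon)) {
  cleaning <- clean_word_inventory(session)
  types <- cleaning$types_pholex
  n <- length(types)
  hit <- match(types, type_stats$orthography)
  prof <- data.frame(orthography = types,
                     in_lexicon = !is.na(hit),
                     pronunciation = type_stats$pronunciation[hit],
                     length_phonemes = type_stats$length_phonemes[hit],
                     log10_frequency = type_stats$log10_frequency[hit],
                     neighborhood_density = type_stats$neighborhood_density[hit],
                     phonprob_raw = type_stats$phonprob_raw[hit],
                     phonprob_z = type_stats$phonprob_z[hit],
                     stringsAsFactors = FALSE)
  med_or_na <- function(x) if (all(is.na(x))) NA_real_ else stats::median(x, na.rm = TRUE)
  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  summaries <- list(
    median_log_frequency = med_or_na(prof$log10_frequency),
    median_neighborhood_density = med_or_na(as.numeric(prof$neighborhood_density)),
    mean_word_length = mean_or_na(as.numeric(prof$length_phonemes)),
    mean_phonprob_z = mean_or_na(prof$phonprob_z),
    n_profiled_types = sum(prof$in_lexicon))
  list(profiles = prof, summaries = summaries, cleaning = cleaning,
       n_missing = sum(!prof$in_lexicon))
}

#' Count word types at or above a pooled median length
#'
#' The median-split unnesting of per-type word length: given the pooled
#' median word length (computed over the union of all caregivers' word types
#' at a timepoint, one observation per caregiver-type), counts how many of
#' this caregiver's types are equal to or longer than the median (inclusive
#' boundary).
#'
#' @param lengths integer vector of per-type word lengths (phonemes) for one
#'   caregiver; `NA`s are dropped.
#' @param pooled_median_length the pooled median length (phonemes).
#' @return integer count.
#' @export
long_word_count <- function(lengths, pooled_median_length) {
  sum(lengths >= pooled_median_length, na.rm = TRUE)
}

#' Count word types strictly below a pooled median frequency
#'
#' Companion of [long_word_count()] for word frequency: counts this
#' caregiver's types with log frequency strictly below the pooled median.
#'
#' @param log_frequencies numeric vector of per-type log frequencies for one
#'   caregiver; `NA`s are dropped.
#' @param pooled_median_freq the pooled median log frequency.
#' @return integer count.
#' @export
low_freq_count <- function(log_frequencies, pooled_median_freq) {
  sum(log_frequencies < pooled_median_freq, na.rm = TRUE)
}

#' Pooled median of a per-type statistic across caregivers
#'
#' One observation per caregiver-type (types shared across caregivers are
#' not deduplicated), pooled over all caregivers at a timepoint.
#'
#' @param per_caregiver_values list of numeric vectors, one per caregiver.
#' @return the pooled median.
#' @export
pooled_type_median <- function(per_caregiver_values) {
  stats::median(unlist(per_caregiver_values), na.rm = TRUE)
}
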