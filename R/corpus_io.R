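# Session containers and on-disk formats: Praat TextGrids (long format),
# token-table TSVs, pronouncing-lexicon TSVs and the per-session feature CSV.
# Times are seconds, intervals half-open [start, end).

ALLOWED_TAGS <- c("onomatopoeia", "exclamation", "proper_name", "contraction")
TIMEPOINT_LEVELS <- c("7", "10-11", "18", "24")

#' Construct a caregiver-child session transcript
#'
#' Bundles the word tokens, phone intervals and (optionally) formant
#' measurements and phone spectra of one caregiver-child play session, and
#' validates the structural invariants: phone intervals must have positive
#' duration, be time-sorted and non-overlapping, every `word_index` must
#' resolve to a token row, and `timepoint` must come from the study's closed
#' label set (7, 10-11, 18 or 24 months).
#'
#' @param dyad_id opaque identifier of the caregiver-child dyad.
#' @param timepoint one of `"7"`, `"10-11"`, `"18"`, `"24"` (months).
#' @param tokens data frame with columns `utterance_index`, `token_index`,
#'   `orthography`, logical tag columns `onomatopoeia`, `exclamation`,
#'   `proper_name`, `contraction`, and logical `is_content` (may be `NA`).
#' @param phones data frame with columns `label`, `start`, `end`,
#'   `word_index` (row index into `tokens` or `NA`) and logical flags
#'   `whispered`, `yelled`, `overlap`.
#' @param formants optional data frame of midpoint formant measurements with
#'   columns `phone_index`, `F1_hz`, `F2_hz` (see [lobanov_normalize()]).
#' @param spectra optional numeric matrix, one row per phone, of
#'   time-averaged log-magnitude Mel spectra (see [phone_mean_spectrum()]).
#' @return an object of class `cds_session`.
#' @export
cds_session <- function(dyad_id, timepoint, tokens, phones,
                        formants = NULL, spectra = NULL) {
  timepoint <- as.character(timepoint)
  if (!timepoint %in% TIMEPOINT_LEVELS) {
    stop(sprintf("timepoint must be one of {%s}, got '%s'",
                 paste(TIMEPOINT_LEVELS, collapse = ", "), timepoint),
         call. = FALSE)
  }
  tokens <- validate_tokens(tokens)
  phones <- validate_phones(phones)
  bad <- !is.na(phones$word_index) &
    (phones$word_index < 1L | phones$word_index > nrow(tokens))
  if (any(bad)) {
    stop("phone word_index does not resolve to an existing token", call. = FALSE)
  }
  if (!is.null(spectra)) {
    spectra <- as.matrix(spectra)
    if (nrow(spectra) != nrow(phones)) {
      stop("spectra must have one row per phone", call. = FALSE)
    }
  }
  structure(list(dyad_id = dyad_id, timepoint = timepoint,
                 tokens = tokens, phones = phones,
                 formants = formants, spectra = spectra),
            class = "cds_session")
}

#' @export
print.cds_session <- function(x, ...) {
  cat(sprintf("<cds_session> dyad %s, %s months: %d tokens, %d phones%s\n",
              x$dyad_id, x$timepoint, nrow(x$tokens), nrow(x$phones),
              if (is.null(x$formants)) "" else
                sprintf(", %d formant measurements", nrow(x$formants))))
  invisible(x)
}

validate_tokens <- function(tokens) {
  tokens <- as.data.frame(tokens)
  need <- c("utterance_index", "token_index", "orthography")
  miss <- setdiff(need, names(tokens))
  if (length(miss) > 0) {
    stop("token table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (tag in ALLOWED_TAGS) {
    if (!tag %in% names(tokens)) tokens[[tag]] <- logical(nrow(tokens))
  }
  if (!"is_content" %in% names(tokens)) {
    tokens$is_content <- rep(NA, nrow(tokens))
  }
  if (nrow(tokens) > 0) {
    if (any(!nzchar(tokens$orthography))) {
      stop("token orthography must be non-empty", call. = FALSE)
    }
    if (any(diff(tokens$token_index) <= 0)) {
      stop("token_index must be strictly increasing", call. = FALSE)
    }
  }
  tokens$orthography <- tolower(tokens$orthography)
  rownames(tokens) <- NULL
  tokens
}

validate_phones <- function(phones) {
  phones <- as.data.frame(phones)
  need <- c("label", "start", "end")
  miss <- setdiff(need, names(phones))
  if (length(miss) > 0) {
    stop("phone table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"word_index" %in% names(phones)) phones$word_index <- NA_integer_
  for (fl in c("whispered", "yelled", "overlap")) {
    if (!fl %in% names(phones)) phones[[fl]] <- FALSE
  }
  if (nrow(phones) > 0) {
    if (any(phones$start < 0)) stop("phone start times must be >= 0", call. = FALSE)
    if (any(phones$end <= phones$start)) {
      stop("phone intervals must satisfy end > start", call. = FALSE)
    }
    check_tier_sorted(phones, "phone")
  }
  rownames(phones) <- NULL
  phones
}

check_tier_sorted <- function(df, what) {
  if (nrow(df) < 2) return(invisible(TRUE))
  if (any(diff(df$start) < 0)) {
    stop(sprintf("%s intervals are not time-sorted", what), call. = FALSE)
  }
  if (any(df$start[-1] < df$end[-nrow(df)] - 1e-12)) {
    stop(sprintf("%s intervals overlap", what), call. = FALSE)
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# TextGrid (Praat long format)

read_text_lines <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  enc <- "UTF-8"
  if (length(raw) >= 2) {
    if (raw[1] == as.raw(0xFE) && raw[2] == as.raw(0xFF)) enc <- "UTF-16BE"
    if (raw[1] == as.raw(0xFF) && raw[2] == as.raw(0xFE)) enc <- "UTF-16LE"
  }
  txt <- if (enc == "UTF-8") {
    if (length(raw) >= 3 && identical(raw[1:3], as.raw(c(0xEF, 0xBB, 0xBF)))) {
      raw <- raw[-(1:3)]
    }
    rawToChar(raw)
  } else {
    iconv(list(raw), from = enc, to = "UTF-8")[[1]]
  }
  strsplit(txt, "\r\n|\n|\r")[[1]]
}

tg_num <- function(line) as.numeric(sub(".*=\\s*", "", line))
tg_str <- function(line) {
  m <- regmatches(line, regexpr('"(?:[^"]|"")*"', line))
  if (length(m) == 0) return("")
  gsub('""', '"', substr(m, 2, nchar(m) - 1))
}

parse_flag_suffixes <- function(labels) {
  whispered <- yelled <- overlap <- logical(length(labels))
  out <- labels
  repeat {
    hit <- grepl("@[wyo]$", out)
    if (!any(hit)) break
    suf <- substr(out[hit], nchar(out[hit]), nchar(out[hit]))
    whispered[hit] <- whispered[hit] | suf == "w"
    yelled[hit]    <- yelled[hit]    | suf == "y"
    overlap[hit]   <- overlap[hit]   | suf == "o"
    out[hit] <- substr(out[hit], 1, nchar(out[hit]) - 2)
  }
  data.frame(label = out, whispered = whispered, yelled = yelled,
             overlap = overlap, stringsAsFactors = FALSE)
}

#' Read a Praat long-format TextGrid
#'
#' Parses the phone and word interval tiers of a long-format TextGrid.
#' Empty-label intervals (alignment padding) are dropped. Phone labels may
#' carry the annotation suffixes `@w` (whispered), `@y` (yelled) and `@o`
#' (overlapping speech), which are parsed into logical flag columns. The
#' short TextGrid format is rejected.
#'
#' @param path file path; UTF-8 or UTF-16 (with BOM) encoded.
#' @param phone_tier_name,word_tier_name names of the interval tiers holding
#'   phone and word alignments.
#' @return a list with data frames `phones` (`label`, `start`, `end`,
#'   `whispered`, `yelled`, `overlap`) and `words` (`label`, `start`, `end`).
#' @export
read_textgrid <- function(path, phone_tier_name = "phones",
                          word_tier_name = "words") {
  lines <- read_text_lines(path)
  if (length(lines) < 2 || !grepl("ooTextFile", lines[1]) ||
      !grepl("TextGrid", lines[2])) {
    stop(sprintf("not a Praat TextGrid: bad header at line 1-2 of %s", path),
         call. = FALSE)
  }
  if (!any(grepl("item\\s*\\[", lines))) {
    stop("short-format TextGrid detected; only the long format is supported",
         call. = FALSE)
  }
  item_starts <- grep("^\\s*item\\s*\\[[0-9]+\\]:", lines)
  if (length(item_starts) == 0) {
    stop(sprintf("malformed TextGrid: no tier items found in %s", path),
         call. = FALSE)
  }
  item_ends <- c(item_starts[-1] - 1L, length(lines))
  tiers <- list()
  for (k in seq_along(item_starts)) {
    block <- lines[item_starts[k]:item_ends[k]]
    name_line <- grep("^\\s*name\\s*=", block, value = TRUE)[1]
    class_line <- grep("^\\s*class\\s*=", block, value = TRUE)[1]
    if (is.na(name_line) || is.na(class_line)) {
      stop(sprintf("malformed TextGrid tier block starting at line %d",
                   item_starts[k]), call. = FALSE)
    }
    if (tg_str(class_line) != "IntervalTier") next
    xmin_idx <- grep("^\\s*xmin\\s*=", block)
    xmax_idx <- grep("^\\s*xmax\\s*=", block)
    text_idx <- grep("^\\s*text\\s*=", block)
    # first xmin/xmax pair describes the tier itself
    n_int <- length(text_idx)
    if (n_int > 0) {
      starts <- vapply(block[xmin_idx[-1]], tg_num, numeric(1), USE.NAMES = FALSE)
      ends <- vapply(block[xmax_idx[-1]], tg_num, numeric(1), USE.NAMES = FALSE)
      texts <- vapply(block[text_idx], tg_str, character(1), USE.NAMES = FALSE)
      if (length(starts) != n_int || length(ends) != n_int ||
          any(is.na(starts)) || any(is.na(ends))) {
        stop(sprintf("malformed interval block in tier '%s' (near line %d)",
                     tg_str(name_line), item_starts[k]), call. = FALSE)
      }
    } else {
      starts <- ends <- numeric(0)
      texts <- character(0)
    }
    tiers[[tg_str(name_line)]] <-
      data.frame(label = texts, start = starts, end = ends,
                 stringsAsFactors = FALSE)
  }
  get_tier <- function(nm) {
    if (!nm %in% names(tiers)) {
      stop(sprintf("tier '%s' not found (tiers present: %s)", nm,
                   paste(names(tiers), collapse = ", ")), call. = FALSE)
    }
    tier <- tiers[[nm]]
    tier <- tier[nzchar(trimws(tier$label)), , drop = FALSE]
    tier <- tier[order(tier$start), , drop = FALSE]
    check_tier_sorted(tier, nm)
    rownames(tier) <- NULL
    tier
  }
  phones_tier <- get_tier(phone_tier_name)
  words <- get_tier(word_tier_name)
  if (nrow(phones_tier) == 0) {
    warning("TextGrid contains no non-empty phone intervals", call. = FALSE)
  }
  flags <- parse_flag_suffixes(phones_tier$label)
  phones <- cbind(flags[, "label", drop = FALSE],
                  phones_tier[, c("start", "end")],
                  flags[, c("whispered", "yelled", "overlap")])
  rownames(phones) <- NULL
  list(phones = phones, words = words)
}

#' Write a Praat long-format TextGrid
#'
#' Inverse of [read_textgrid()]: writes a phone tier (flag columns re-encoded
#' as `@w`/`@y`/`@o` label suffixes) and a word tier, padding gaps with
#' empty-label intervals as Praat expects.
#'
#' @param phones,words data frames as returned by [read_textgrid()].
#' @param path output file path.
#' @param phone_tier_name,word_tier_name tier names to write.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(phones, words, path,
                           phone_tier_name = "phones",
                           word_tier_name = "words") {
  xmax <- max(c(phones$end, words$end, 1))
  labels <- phones$label
  if (!is.null(phones$whispered)) labels <- paste0(labels, ifelse(phones$whispered, "@w", ""))
  if (!is.null(phones$yelled)) labels <- paste0(labels, ifelse(phones$yelled, "@y", ""))
  if (!is.null(phones$overlap)) labels <- paste0(labels, ifelse(phones$overlap, "@o", ""))
  pad <- function(df) {
    # fill tier gaps with empty intervals so the tier tiles [0, xmax]
    out <- data.frame(label = character(0), start = numeric(0), end = numeric(0))
    cur <- 0
    for (i in seq_len(nrow(df))) {
      if (df$start[i] > cur + 1e-9) {
        out <- rbind(out, data.frame(label = "", start = cur, end = df$start[i]))
      }
      out <- rbind(out, df[i, c("label", "start", "end")])
      cur <- df$end[i]
    }
    if (cur < xmax - 1e-9) {
      out <- rbind(out, data.frame(label = "", start = cur, end = xmax))
    }
    out
  }
  tier_lines <- function(df, nm, idx) {
    c(sprintf("    item [%d]:", idx),
      '        class = "IntervalTier"',
      sprintf('        name = "%s"', nm),
      "        xmin = 0",
      sprintf("        xmax = %.17g", xmax),
      sprintf("        intervals: size = %d", nrow(df)),
      unlist(lapply(seq_len(nrow(df)), function(i) {
        c(sprintf("        intervals [%d]:", i),
          sprintf("            xmin = %.17g", df$start[i]),
          sprintf("            xmax = %.17g", df$end[i]),
          sprintf('            text = "%s"', gsub('"', '""', df$label[i])))
      })))
  }
  pt <- pad(data.frame(label = labels, start = phones$start, end = phones$end,
                       stringsAsFactors = FALSE))
  wt <- pad(words[, c("label", "start", "end")])
  out <- c('File type = "ooTextFile"',
           'Object class = "TextGrid"',
           "",
           "xmin = 0",
           sprintf("xmax = %.17g", xmax),
           "tiers? <exists>",
           "size = 2",
           "item []:",
           tier_lines(pt, phone_tier_name, 1),
           tier_lines(wt, word_tier_name, 2))
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Token tables

#' Read a word-token table (TSV)
#'
#' Expects a tab-separated file with header columns `utterance_index`,
#' `token_index`, `orthography`, `tags` (comma-joined, possibly empty).
#' Orthographies are lowercased; allowed tags are `onomatopoeia`,
#' `exclamation`, `proper_name` and `contraction`.
#'
#' @param path file path.
#' @return a token data frame (see [cds_session()]).
#' @export
read_token_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  need <- c("utterance_index", "token_index", "orthography", "tags")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("token table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning("empty token table: ", path, call. = FALSE)
    return(validate_tokens(data.frame(utterance_index = integer(0),
                                      token_index = integer(0),
                                      orthography = character(0))))
  }
  tok_idx <- as.integer(df$token_index)
  if (anyDuplicated(tok_idx)) {
    stop("duplicate token_index values in ", path, call. = FALSE)
  }
  tag_lists <- lapply(strsplit(df$tags, ","), function(x) trimws(x[nzchar(trimws(x))]))
  bad <- setdiff(unique(unlist(tag_lists)), ALLOWED_TAGS)
  if (length(bad) > 0) {
    stop(sprintf("unknown tag(s) %s; allowed tags: %s",
                 paste(bad, collapse = ", "),
                 paste(ALLOWED_TAGS, collapse = ", ")), call. = FALSE)
  }
  tokens <- data.frame(utterance_index = as.integer(df$utterance_index),
                       token_index = tok_idx,
                       orthography = tolower(df$orthography),
                       stringsAsFactors = FALSE)
  for (tag in ALLOWED_TAGS) {
    tokens[[tag]] <- vapply(tag_lists, function(x) tag %in% x, logical(1))
  }
  tokens <- tokens[order(tokens$token_index), , drop = FALSE]
  validate_tokens(tokens)
}

#' Write a word-token table (TSV)
#'
#' @param tokens token data frame (see [cds_session()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_token_table <- function(tokens, path) {
  tags <- apply(as.matrix(tokens[, ALLOWED_TAGS]), 1, function(x) {
    paste(ALLOWED_TAGS[as.logical(x)], collapse = ",")
  })
  if (nrow(tokens) == 0) tags <- character(0)
  out <- data.frame(utterance_index = tokens$utterance_index,
                    token_index = tokens$token_index,
                    orthography = tokens$orthography,
                    tags = tags, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import a minimal CHAT main tier as a token table
#'
#' Convenience converter for CHAT transcripts: keeps only main-tier lines of
#' the requested speaker (default `*MOT:`), splits tokens on whitespace,
#' strips CHAT punctuation and event codes (bracketed material, `&=` events,
#' `xxx`/`yyy` unintelligibles, utterance terminators) and lowercases. No
#' tags are inferred. Everything richer should route through the TSV token
#' table.
#'
#' @param path CHAT (.cha) file path.
#' @param speaker main-tier speaker code, e.g. `"MOT"`.
#' @return a token data frame (see [cds_session()]).
#' @export
read_chat_tokens <- function(path, speaker = "MOT") {
  lines <- read_text_lines(path)
  pat <- paste0("^\\*", speaker, ":")
  main <- grep(pat, lines, value = TRUE)
  utts <- sub(pat, "", main)
  rows <- list()
  tok_i <- 0L
  for (u in seq_along(utts)) {
    s <- utts[u]
    s <- gsub("\\[[^]]*\\]", " ", s)       # bracketed codes
    s <- gsub("&=?\\S+", " ", s)            # events / fillers
    s <- gsub("\\b(xxx|yyy|www)\\b", " ", s)
    s <- gsub("[<>()+/\"^!?.,:;~]", " ", s)
    words <- strsplit(trimws(s), "\\s+")[[1]]
    words <- words[nzchar(words)]
    for (w in words) {
      tok_i <- tok_i + 1L
      rows[[tok_i]] <- data.frame(utterance_index = u - 1L, token_index = tok_i - 1L,
                                  orthography = tolower(w), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    warning("no tokens found for speaker *", speaker, " in ", path, call. = FALSE)
    return(validate_tokens(data.frame(utterance_index = integer(0),
                                      token_index = integer(0),
                                      orthography = character(0))))
  }
  validate_tokens(do.call(rbind, rows))
}

# ---------------------------------------------------------------------------
# Session assembly

#' Attach phone intervals to word tokens
#'
#' Assigns each phone to the word interval containing its midpoint and links
#' it to the corresponding token (word intervals and tokens must be equal in
#' count and order). Phones whose midpoint falls inside no word interval are
#' kept with `word_index = NA` and counted.
#'
#' @param phones phone data frame from [read_textgrid()].
#' @param word_intervals word data frame from [read_textgrid()].
#' @param tokens token data frame from [read_token_table()].
#' @param dyad_id,timepoint session identifiers (see [cds_session()]).
#' @param tol adjacency tolerance in seconds (default 1 ms): phones i and
#'   i+1 count as adjacent when `|end_i - start_{i+1}| <= tol`.
#' @return a [cds_session()], with the number of unassigned phones reported
#'   via `message()` and stored in attribute `"n_unassigned"` of the phone
#'   table.
#' @export
attach_phones_to_words <- function(phones, word_intervals, tokens,
                                   dyad_id = "dyad", timepoint = "24",
                                   tol = 0.001) {
  if (nrow(word_intervals) != nrow(tokens)) {
    stop(sprintf("word intervals (%d) and tokens (%d) differ in count",
                 nrow(word_intervals), nrow(tokens)), call. = FALSE)
  }
  mid <- (phones$start + phones$end) / 2
  word_index <- rep(NA_integer_, nrow(phones))
  for (j in seq_len(nrow(word_intervals))) {
    inside <- mid >= word_intervals$start[j] & mid < word_intervals$end[j]
    word_index[inside] <- j
  }
  n_un <- sum(is.na(word_index))
  if (n_un > 0) {
    message(sprintf("%d phone(s) with midpoint inside no word interval left unassigned",
                    n_un))
  }
  phones$word_index <- word_index
  attr(phones, "n_unassigned") <- n_un
  attr(phones, "adjacency_tol") <- tol
  cds_session(dyad_id, timepoint, tokens, phones)
}

#' Adjacent-phone indicator
#'
#' @param phones phone data frame of a session.
#' @param tol adjacency tolerance in seconds.
#' @return logical vector of length `nrow(phones) - 1`: is phone i adjacent
#'   to phone i+1?
#' @export
adjacent_phones <- function(phones, tol = 0.001) {
  n <- nrow(phones)
  if (n < 2) return(logical(0))
  abs(phones$end[-n] - phones$start[-1]) <= tol
}

# ---------------------------------------------------------------------------
# Lexicon

#' Construct a pronouncing lexicon
#'
#' A lexicon maps orthographies to one or more ARPAbet pronunciation
#' variants (stress digits on vowels), a base-10 log corpus frequency on a
#' SUBTLEX-like scale, and a function-word flag. Entries are deduplicated by
#' (orthography, variant); every symbol must come from the declared phoneme
#' inventory.
#'
#' @param df data frame with columns `orthography`, `pronunciation`
#'   (space-separated ARPAbet), `log10_frequency`, `is_function_word`.
#' @param inventory declared phoneme inventory (stress-free symbols).
#' @return an object of class `cds_lexicon`: a data frame with one row per
#'   pronunciation variant and attribute `"inventory"`.
#' @export
cds_lexicon <- function(df, inventory = arpabet_inventory()$all) {
  df <- as.data.frame(df)
  need <- c("orthography", "pronunciation", "log10_frequency", "is_function_word")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("lexicon missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) stop("lexicon is empty", call. = FALSE)
  if (any(is.na(df$log10_frequency) | !nzchar(as.character(df$log10_frequency)))) {
    stop("log10_frequency is required for every lexicon entry", call. = FALSE)
  }
  fw <- df$is_function_word
  if (!is.logical(fw)) fw <- suppressWarnings(as.numeric(fw)) > 0
  if (any(is.na(fw))) stop("is_function_word must be 0/1 or logical", call. = FALSE)
  out <- data.frame(orthography = tolower(df$orthography),
                    pronunciation = trimws(df$pronunciation),
                    log10_frequency = as.numeric(df$log10_frequency),
                    is_function_word = fw,
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$pronunciation))) {
    stop("every lexicon pronunciation variant must be non-empty", call. = FALSE)
  }
  for (i in seq_len(nrow(out))) {
    check_inventory(strsplit(out$pronunciation[i], "\\s+")[[1]], inventory,
                    context = sprintf("word '%s'", out$orthography[i]))
  }
  out <- out[!duplicated(out[, c("orthography", "pronunciation")]), , drop = FALSE]
  rownames(out) <- NULL
  fun_by_orth <- tapply(out$is_function_word, out$orthography, any)
  structure(out, inventory = inventory, fun_by_orth = fun_by_orth,
            class = c("cds_lexicon", "data.frame"))
}

#' @export
print.cds_lexicon <- function(x, ...) {
  cat(sprintf("<cds_lexicon> %d orthographies, %d pronunciation variants\n",
              length(unique(x$orthography)), nrow(x)))
  invisible(x)
}

#' Read a pronouncing lexicon from TSV
#'
#' TSV columns: `orthography`, `pronunciation` (space-separated ARPAbet with
#' stress digits on vowels), `log10_frequency`, `is_function_word` (0/1).
#' Repeated orthography rows are pronunciation variants.
#'
#' @param path file path.
#' @param inventory declared phoneme inventory.
#' @return a [cds_lexicon()].
#' @export
read_lexicon <- function(path, inventory = arpabet_inventory()$all) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  cds_lexicon(df, inventory = inventory)
}

#' Write a pronouncing lexicon to TSV
#'
#' @param lexicon a [cds_lexicon()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  out <- as.data.frame(lexicon)
  out$is_function_word <- as.integer(out$is_function_word)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# split lexicon pronunciations into phone vectors (internal)
pron_phones <- function(pronunciations) strsplit(pronunciations, "\\s+")

# ---------------------------------------------------------------------------
# Feature table

FEATURE_COLUMNS <- c("dyad_id", "timepoint", "n_types", "n_tokens", "ttr",
                     "mattr", "mattr_fallback", "mean_word_length",
                     "median_log_frequency", "median_neighborhood_density",
                     "mean_phonprob_z", "n_long_words", "n_low_freq_words",
                     "vowel_space_area_z", "vowel_space_area_hz",
                     "median_dispersion", "median_phone_duration_ms",
                     "median_coarticulation_distance",
                     "n_profiled_types", "n_formant_tokens",
                     "n_duration_phones", "n_coarticulation_pairs")

#' Write a per-session feature table (CSV)
#'
#' One row per (dyad, timepoint), stable column order, missing acoustic
#' fields written as empty cells (never 0).
#'
#' @param rows data frame of feature rows (see [session_features()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  for (cn in setdiff(FEATURE_COLUMNS, names(rows))) {
    rows[[cn]] <- rep(NA, nrow(rows))
  }
  rows <- rows[, FEATURE_COLUMNS, drop = FALSE]
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path file path.
#' @return data frame with the stable feature-column order.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(dyad_id = "character",
                                       timepoint = "character"))
  df$mattr_fallback <- as.logical(df$mattr_fallback)
  df
}
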