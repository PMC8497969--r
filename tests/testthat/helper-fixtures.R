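# In-code fixtures shared across test files.

# token data frame from orthographies, with optional tag assignments
make_tokens <- function(orths, tags = list(), is_content = NA) {
  df <- data.frame(utterance_index = 0L,
                   token_index = seq_along(orths) - 1L,
                   orthography = orths,
                   stringsAsFactors = FALSE)
  for (tag in c("onomatopoeia", "exclamation", "proper_name", "contraction")) {
    df[[tag]] <- seq_along(orths) %in% (tags[[tag]] %||% integer(0))
  }
  df$is_content <- is_content
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# contiguous phone layout for a list of per-word phone vectors
make_phones <- function(word_phones, dur = 0.1) {
  labels <- unlist(word_phones)
  n <- length(labels)
  starts <- (seq_len(n) - 1) * dur
  data.frame(label = labels, start = starts, end = starts + dur,
             word_index = rep(seq_along(word_phones), lengths(word_phones)),
             whispered = FALSE, yelled = FALSE, overlap = FALSE,
             stringsAsFactors = FALSE)
}

make_session <- function(orths, word_phones, tags = list(), is_content = NA,
                         timepoint = "24", ...) {
  cds_session("dtest", timepoint, make_tokens(orths, tags, is_content),
              make_phones(word_phones), ...)
}

# small hand lexicon used throughout the lexical tests
toy_lexicon <- function() {
  cds_lexicon(data.frame(
    orthography = c("cat", "sat", "kit", "cats", "maryland", "the"),
    pronunciation = c("K AE1 T", "S AE1 T", "K IH1 T", "K AE1 T S",
                      "M EH1 R IY0 L AH0 N D", "DH AH0"),
    log10_frequency = c(4.2, 3.9, 3.5, 3.3, 2.0, 6.5),
    is_function_word = c(0, 0, 0, 0, 0, 1)))
}

# random lexicon over a small inventory (for property tests)
random_lexicon <- function(n_words, consonants = c("K", "S", "T", "M", "P"),
                           vowels = c("AE", "IH", "UW")) {
  orths <- paste0("w", seq_len(n_words))
  prons <- vapply(seq_len(n_words), function(i) {
    L <- sample(1:4, 1)
    ph <- character(L)
    for (k in seq_len(L)) {
      ph[k] <- if (k %% 2 == 1) sample(consonants, 1)
        else paste0(sample(vowels, 1), sample(0:2, 1))
    }
    paste(ph, collapse = " ")
  }, character(1))
  cds_lexicon(data.frame(orthography = orths, pronunciation = prons,
                         log10_frequency = runif(n_words, 1, 7),
                         is_function_word = 0))
}

# independent brute-force oracles ------------------------------------------

# MATTR by the direct definition: loop all windows, count unique types
mattr_bruteforce <- function(tokens, window) {
  n <- length(tokens)
  if (n < window) return(length(unique(tokens)) / n)
  vals <- vapply(seq_len(n - window + 1), function(s) {
    length(unique(tokens[s:(s + window - 1)])) / window
  }, numeric(1))
  mean(vals)
}

# neighborhood density by generate-all-edits-and-intersect
density_bruteforce <- function(pron, lexicon) {
  q <- strsplit(gsub("[0-2]", "", pron), "\\s+")[[1]]
  inv <- unique(gsub("[0-2]", "", unlist(strsplit(lexicon$pronunciation, "\\s+"))))
  edits <- list()
  for (i in seq_along(q)) {
    for (s in inv) {
      sub <- q; sub[i] <- s
      edits[[length(edits) + 1]] <- sub            # substitution
    }
    edits[[length(edits) + 1]] <- q[-i]            # deletion
  }
  for (i in 0:length(q)) {
    for (s in inv) {
      edits[[length(edits) + 1]] <- append(q, s, after = i)  # insertion
    }
  }
  keys <- unique(vapply(edits, paste, character(1), collapse = " "))
  keys <- setdiff(keys, paste(q, collapse = " "))  # distance must be exactly 1
  lex_keys <- vapply(strsplit(gsub("[0-2]", "", lexicon$pronunciation), "\\s+"),
                     paste, character(1), collapse = " ")
  length(unique(lexicon$orthography[lex_keys %in% keys]))
}
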