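test_that("a single labeled interval round-trips with its duration", {
  tg <- tempfile(fileext = ".TextGrid")
  phones <- data.frame(label = "AE1", start = 0.10, end = 0.25,
                       whispered = FALSE, yelled = FALSE, overlap = FALSE)
  words <- data.frame(label = "at", start = 0.10, end = 0.25)
  write_textgrid(phones, words, tg)
  got <- read_textgrid(tg)
  expect_equal(nrow(got$phones), 1)
  expect_equal(got$phones$label, "AE1")
  expect_equal(got$phones$end - got$phones$start, 0.15)
})

test_that("a TextGrid with only empty intervals yields an empty tier with a warning", {
  tg <- tempfile(fileext = ".TextGrid")
  writeLines(c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
               "xmin = 0", "xmax = 1", "tiers? <exists>", "size = 2",
               "item []:",
               "    item [1]:",
               '        class = "IntervalTier"', '        name = "phones"',
               "        xmin = 0", "        xmax = 1",
               "        intervals: size = 1",
               "        intervals [1]:",
               "            xmin = 0", "            xmax = 1",
               '            text = ""',
               "    item [2]:",
               '        class = "IntervalTier"', '        name = "words"',
               "        xmin = 0", "        xmax = 1",
               "        intervals: size = 1",
               "        intervals [1]:",
               "            xmin = 0", "            xmax = 1",
               '            text = ""'), tg)
  expect_warning(got <- read_textgrid(tg), "no non-empty phone intervals")
  expect_equal(nrow(got$phones), 0)
})

test_that("a randomized 50-interval grid round-trips identically, including flags", {
  set.seed(11)
  n <- 50
  durs <- runif(n, 0.03, 0.2)
  starts <- cumsum(c(0, durs[-n] + sample(c(0, 0.05), n - 1, replace = TRUE)))
  phones <- data.frame(label = sample(c("K", "AE1", "S", "IY0", "T"), n, TRUE),
                       start = starts, end = starts + durs,
                       whispered = runif(n) < 0.1,
                       yelled = runif(n) < 0.1,
                       overlap = runif(n) < 0.1)
  words <- data.frame(label = paste0("w", 1:10),
                      start = seq(0, by = 1.2, length.out = 10),
                      end = seq(0, by = 1.2, length.out = 10) + 1.1)
  tg <- tempfile(fileext = ".TextGrid")
  write_textgrid(phones, words, tg)
  got <- read_textgrid(tg)
  expect_equal(got$phones$label, phones$label)
  expect_equal(got$phones$start, phones$start, tolerance = 1e-12)
  expect_equal(got$phones$end, phones$end, tolerance = 1e-12)
  expect_equal(got$phones$whispered, phones$whispered)
  expect_equal(got$phones$yelled, phones$yelled)
  expect_equal(got$phones$overlap, phones$overlap)
  expect_equal(got$words$label, words$label)
})

test_that("short-format and malformed TextGrids are rejected with clear errors", {
  f <- tempfile()
  writeLines(c('File type = "ooTextFile"', '"TextGrid"', "0", "1", "<exists>"), f)
  expect_error(read_textgrid(f), "short-format")
  writeLines(c("not a grid", "at all"), f)
  expect_error(read_textgrid(f), "header")
})

test_that("overlapping intervals on a tier fail validation", {
  tg <- tempfile(fileext = ".TextGrid")
  phones <- data.frame(label = c("K", "AE1"), start = c(0, 0.05),
                       end = c(0.1, 0.15),
                       whispered = FALSE, yelled = FALSE, overlap = FALSE)
  words <- data.frame(label = "ka", start = 0, end = 0.15)
  # write manually: write_textgrid would pad around them
  lines <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
             "xmin = 0", "xmax = 1", "tiers? <exists>", "size = 2", "item []:",
             "    item [1]:", '        class = "IntervalTier"',
             '        name = "phones"', "        xmin = 0", "        xmax = 1",
             "        intervals: size = 2",
             "        intervals [1]:", "            xmin = 0",
             "            xmax = 0.1", '            text = "K"',
             "        intervals [2]:", "            xmin = 0.05",
             "            xmax = 0.15", '            text = "AE1"',
             "    item [2]:", '        class = "IntervalTier"',
             '        name = "words"', "        xmin = 0", "        xmax = 1",
             "        intervals: size = 1",
             "        intervals [1]:", "            xmin = 0",
             "            xmax = 1", '            text = "ka"')
  writeLines(lines, tg)
  expect_error(read_textgrid(tg), "overlap")
})

test_that("UTF-16 TextGrids are readable", {
  tg <- tempfile(fileext = ".TextGrid")
  phones <- data.frame(label = "IY1", start = 0, end = 0.2,
                       whispered = FALSE, yelled = FALSE, overlap = FALSE)
  words <- data.frame(label = "e", start = 0, end = 0.2)
  write_textgrid(phones, words, tg)
  txt <- readLines(tg)
  con <- file(tg, open = "wb")
  writeBin(as.raw(c(0xFF, 0xFE)), con)
  writeBin(iconv(paste(txt, collapse = "\n"), "UTF-8", "UTF-16LE", toRaw = TRUE)[[1]], con)
  close(con)
  got <- read_textgrid(tg)
  expect_equal(got$phones$label, "IY1")
})

test_that("token tables parse tags, keep place names, and reject bad input", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("utterance_index\ttoken_index\torthography\ttags",
               "0\t0\tMaryland\t",
               "0\t1\tdon't\tcontraction",
               "1\t2\tick\texclamation"), f)
  tok <- read_token_table(f)
  expect_equal(tok$orthography, c("maryland", "don't", "ick"))
  expect_false(tok$proper_name[1])      # common place names arrive untagged
  expect_true(tok$contraction[2])
  expect_true(tok$exclamation[3])

  writeLines(c("utterance_index\ttoken_index\torthography\ttags",
               "0\t0\tcat\t", "0\t0\tsat\t"), f)
  expect_error(read_token_table(f), "duplicate token_index")
  writeLines(c("utterance_index\ttoken_index\torthography\ttags",
               "0\t0\tcat\tshout"), f)
  expect_error(read_token_table(f), "allowed tags")
  writeLines("utterance_index\ttoken_index\torthography\ttags", f)
  expect_warning(tok <- read_token_table(f), "empty")
  expect_equal(nrow(tok), 0)
})

test_that("token tables round-trip through write_token_table", {
  tok <- make_tokens(c("cat", "don't", "boom"),
                     tags = list(contraction = 2, onomatopoeia = 3))
  f <- tempfile(fileext = ".tsv")
  write_token_table(tok, f)
  got <- read_token_table(f)
  expect_equal(got$orthography, tok$orthography)
  expect_equal(got$contraction, tok$contraction)
  expect_equal(got$onomatopoeia, tok$onomatopoeia)
})

test_that("phones attach to the word interval containing their midpoint", {
  phones <- data.frame(label = c("K", "AE1"), start = c(0.10, 0.2),
                       end = c(0.2, 0.28),
                       whispered = FALSE, yelled = FALSE, overlap = FALSE)
  words <- data.frame(label = "cat", start = 0.05, end = 0.30)
  tok <- make_tokens("cat")
  sess <- attach_phones_to_words(phones, words, tok)
  expect_equal(sess$phones$word_index, c(1L, 1L))

  # midpoint outside every word -> unassigned, counted
  phones2 <- rbind(phones, data.frame(label = "S", start = 0.9, end = 1.0,
                                      whispered = FALSE, yelled = FALSE,
                                      overlap = FALSE))
  expect_message(sess2 <- attach_phones_to_words(phones2, words, tok),
                 "1 phone")
  expect_true(is.na(sess2$phones$word_index[3]))
  expect_error(attach_phones_to_words(phones, words, make_tokens(c("a", "b"))),
               "differ in count")
})

test_that("adjacency respects the 1 ms tolerance", {
  ph <- data.frame(label = c("A", "B"), start = c(0, 0.1), end = c(0.1, 0.2))
  expect_true(adjacent_phones(ph, tol = 0.001))
  ph2 <- data.frame(label = c("A", "B"), start = c(0, 0.15), end = c(0.1, 0.2))
  expect_false(adjacent_phones(ph2, tol = 0.001))
})

test_that("lexicons merge variants, require frequency, and round-trip", {
  lx <- cds_lexicon(data.frame(orthography = c("cat", "cat"),
                               pronunciation = c("K AE1 T", "K AE2 T"),
                               log10_frequency = c(4.2, 4.2),
                               is_function_word = c(0, 0)))
  expect_equal(sum(lx$orthography == "cat"), 2)   # one entry, two variants
  expect_equal(length(unique(lx$orthography)), 1)

  expect_error(cds_lexicon(data.frame(orthography = "cat",
                                      pronunciation = "K AE1 T",
                                      log10_frequency = NA,
                                      is_function_word = 0)),
               "frequency")
  expect_error(cds_lexicon(data.frame(orthography = "xx",
                                      pronunciation = "Q X1",
                                      log10_frequency = 1,
                                      is_function_word = 0)),
               "unknown phoneme")

  f <- tempfile(fileext = ".tsv")
  lx5 <- toy_lexicon()
  write_lexicon(lx5, f)
  got <- read_lexicon(f)
  expect_equal(as.data.frame(got), as.data.frame(lx5))
})

test_that("feature tables round-trip with empty cells for missing acoustics", {
  f <- tempfile(fileext = ".csv")
  write_feature_table(data.frame(), f)
  expect_equal(length(readLines(f)), 1)  # header only

  rows <- data.frame(dyad_id = c("d1", "d2"), timepoint = c("7", "24"),
                     n_types = c(10L, 12L), n_tokens = c(30L, 40L),
                     ttr = c(1 / 3, 0.3), mattr = c(0.9, 0.8),
                     mattr_fallback = c(FALSE, TRUE),
                     mean_word_length = c(3.5, NA),
                     median_log_frequency = c(4.4, 4.2),
                     median_neighborhood_density = c(2, 3),
                     mean_phonprob_z = c(0.1, -0.2),
                     n_long_words = c(4L, 5L), n_low_freq_words = c(2L, 1L),
                     vowel_space_area_z = c(NA, 2.5),
                     vowel_space_area_hz = c(NA, 310000),
                     median_dispersion = c(NA, 1.2),
                     median_phone_duration_ms = c(88, 85),
                     median_coarticulation_distance = c(NA, 5.5),
                     n_profiled_types = c(9L, 11L), n_formant_tokens = c(0L, 20L),
                     n_duration_phones = c(90L, 120L),
                     n_coarticulation_pairs = c(0L, 15L),
                     stringsAsFactors = FALSE)
  write_feature_table(rows, f)
  txt <- readLines(f)
  expect_equal(length(txt), 3)
  expect_match(txt[2], ",,", fixed = TRUE)  # NA written as empty cell
  got <- read_feature_table(f)
  expect_equal(got$vowel_space_area_z, rows$vowel_space_area_z)
  expect_equal(got$n_types, rows$n_types)
  expect_equal(got$ttr, rows$ttr)
})

test_that("session validation rejects invariant-violating fixtures", {
  tok <- make_tokens(c("cat", "dog"))
  ph <- make_phones(list(c("K", "AE1", "T"), c("D", "AO1", "G")))
  expect_s3_class(cds_session("d", "24", tok, ph), "cds_session")

  bad_tp <- "12"
  expect_error(cds_session("d", bad_tp, tok, ph), "timepoint")
  ph_bad <- ph; ph_bad$end[1] <- ph_bad$start[1]
  expect_error(cds_session("d", "24", tok, ph_bad), "end > start")
  ph_bad2 <- ph; ph_bad2$word_index[1] <- 9L
  expect_error(cds_session("d", "24", tok, ph_bad2), "resolve")
  tok_bad <- tok; tok_bad$token_index <- c(1L, 1L)
  expect_error(cds_session("d", "24", tok_bad, ph), "strictly increasing")
  tok_bad2 <- tok; tok_bad2$orthography[1] <- ""
  expect_error(cds_session("d", "24", tok_bad2, ph), "non-empty")
})

test_that("randomly mutated generated sessions are rejected by validation", {
  cfg <- generator_config(seed = 5, targets = simulation_targets())
  lex <- gen_lexicon(cfg)
  s <- gen_session(1, "7", cfg, lex)
  for (k in 1:20) {
    set.seed(k)
    tok <- s$tokens; ph <- s$phones
    mutation <- sample(c("overlap", "neg_dur", "bad_link", "dup_index"), 1)
    if (mutation == "overlap") {
      i <- sample(2:nrow(ph), 1); ph$start[i] <- ph$start[i - 1] - 0.01
      ph <- ph[order(ph$start), ]
    } else if (mutation == "neg_dur") {
      i <- sample(nrow(ph), 1); ph$end[i] <- ph$start[i] - 0.01
    } else if (mutation == "bad_link") {
      i <- sample(nrow(ph), 1); ph$word_index[i] <- nrow(tok) + 5L
    } else {
      i <- sample(2:nrow(tok), 1); tok$token_index[i] <- tok$token_index[i - 1]
    }
    expect_error(cds_session(s$dyad_id, s$timepoint, tok, ph))
  }
})

test_that("CHAT main tiers import as cleaned lowercase tokens", {
  f <- tempfile(fileext = ".cha")
  writeLines(c("@Begin", "*MOT:\tlook at the Doggie !",
               "%com:\tpoints", "*CHI:\tba .",
               "*MOT:\twhat [* xxx] is that ?", "@End"), f)
  tok <- read_chat_tokens(f, "MOT")
  expect_equal(tok$orthography, c("look", "at", "the", "doggie",
                                  "what", "is", "that"))
  expect_equal(unique(tok$utterance_index[1:4]), 0L)
})
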