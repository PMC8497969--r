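# Synthetic caregiver-child corpora with known ground truth: a Zipfian
# pronouncing lexicon, phone-aligned play sessions whose token counts,
# lexical diversity, phone durations and coarticulation are controlled by
# per-timepoint targets, and child outcomes generated from declared linear
# models. Every other module is testable against this generator.

# run code under a temporary RNG state (restored afterwards)
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# stable per-(dyad, timepoint) seed below 2^31
session_seed <- function(master, dyad_index, tp_index) {
  (as.numeric(master) * 7919 + dyad_index * 104729 + tp_index * 1299709) %%
    2147483647
}

#' Per-timepoint generator targets
#'
#' The default session-level targets of the generator, one row per
#' timepoint (months): mean/SD of the session token count, the MATTR the
#' token sampling is calibrated to, the median phone duration in ms, and
#' the coarticulation blending coefficient kappa in \[0, 1\] (larger kappa =
#' more blending of each phone's spectrum into its neighbor = more
#' coarticulation = smaller spectral distances). Type-count targets are
#' carried for reference; type counts are an emergent property of Zipfian
#' token sampling rather than directly controlled.
#'
#' Token counts, type counts and MATTR default to the study's reported
#' per-timepoint descriptives (e.g. 873.38 (313.16) tokens and MATTR 0.88
#' at 7 months rising to 1,247.22 (346.29) and 0.91 at 24 months); phone
#' duration medians fall from 90.21 ms to 83.45 ms (the unmeasured 18-month
#' value is interpolated); kappa falls with age so that spectral distance
#' rises, matching the reported hyperarticulation at 24 months.
#'
#' @return data frame with one row per timepoint.
#' @export
default_targets <- function() {
  data.frame(
    timepoint = TIMEPOINT_LEVELS,
    tokens_mean = c(873.38, 864.88, 1012.91, 1247.22),
    tokens_sd = c(313.16, 277.02, 302.73, 346.29),
    types_mean = c(246.63, 237.76, 261.28, 292.68),
    types_sd = c(67.22, 53.56, 59.54, 54.73),
    mattr = c(0.88, 0.87, 0.89, 0.91),
    duration_median_ms = c(90.21, 90.02, 87.0, 83.45),
    kappa = c(0.50, 0.50, 0.47, 0.42),
    stringsAsFactors = FALSE)
}

#' Generator configuration
#'
#' @param seed master seed (mandatory); every session derives its own RNG
#'   stream from it, so corpora are partially regenerable.
#' @param n_dyads number of caregiver-child dyads.
#' @param timepoints timepoint labels to generate (subset of the study's
#'   closed set).
#' @param targets per-timepoint target table, see [default_targets()].
#' @param lexicon_size number of orthographies in the generated lexicon.
#' @param zipf_exponent rank-frequency slope of the lexicon's corpus
#'   frequencies.
#' @param n_mels dimensionality of the per-phone prototype spectra.
#' @param spectrum_noise_sd SD of the Gaussian noise added to realized
#'   spectra.
#' @param vowel_targets per-corner formant means/SDs in Hz (adult female
#'   ranges for /i/, /a/, /u/).
#' @param p_tags probabilities of the token tags
#'   (onomatopoeia/exclamation/proper_name/contraction).
#' @param p_flags per-word probability of whispered/yelled/overlap marking.
#' @param utterance_mean_len mean utterance length in tokens.
#' @param mattr_window MATTR window used for calibration.
#' @return a `cds_generator_config` list.
#' @export
generator_config <- function(seed,
                             n_dyads = 84,
                             timepoints = TIMEPOINT_LEVELS,
                             targets = default_targets(),
                             lexicon_size = 400,
                             zipf_exponent = 1.0,
                             n_mels = 40,
                             spectrum_noise_sd = 0.3,
                             vowel_targets = data.frame(
                               corner = c("i", "a", "u"),
                               F1_mean = c(400, 850, 420),
                               F2_mean = c(2600, 1300, 1050),
                               F1_sd = c(60, 80, 60),
                               F2_sd = c(120, 100, 100)),
                             p_tags = c(onomatopoeia = 0.004,
                                        exclamation = 0.004,
                                        proper_name = 0.004,
                                        contraction = 0.03),
                             p_flags = 0.01,
                             utterance_mean_len = 4,
                             mattr_window = 10) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(all(targets$kappa >= 0 & targets$kappa <= 1),
            all(targets$tokens_sd > 0))
  structure(list(seed = as.integer(seed), n_dyads = n_dyads,
                 timepoints = timepoints, targets = targets,
                 lexicon_size = lexicon_size, zipf_exponent = zipf_exponent,
                 n_mels = n_mels, spectrum_noise_sd = spectrum_noise_sd,
                 vowel_targets = vowel_targets, p_tags = p_tags,
                 p_flags = p_flags, utterance_mean_len = utterance_mean_len,
                 mattr_window = mattr_window),
            class = "cds_generator_config")
}

#' Expected MATTR of Zipfian token sampling (closed form)
#'
#' Under independent token draws with probabilities `probs`, the expected
#' number of distinct types in a window of `window` tokens is
#' `sum(1 - (1 - p)^window)`, so the expected window TTR — and hence the
#' expected MATTR — is that sum divided by `window`. Used to calibrate the
#' sampling exponent to a target MATTR, and as the independent oracle for
#' recovery tests.
#'
#' @param probs token sampling probabilities (sum to 1).
#' @param window MATTR window length.
#' @return expected MATTR in (0, 1\].
#' @export
expected_mattr <- function(probs, window = 10) {
  sum(1 - (1 - probs)^window) / window
}

#' Calibrate a Zipf sampling exponent to a target MATTR
#'
#' Solves for the exponent s such that sampling tokens with probabilities
#' proportional to rank^-s over `n_words` ranks yields the target expected
#' MATTR (see [expected_mattr()]); expected MATTR is strictly decreasing in
#' s, so the root is unique.
#'
#' @param target_mattr target expected MATTR.
#' @param n_words number of word ranks.
#' @param window MATTR window length.
#' @return the calibrated exponent.
#' @export
calibrate_sampling_exponent <- function(target_mattr, n_words, window = 10) {
  f <- function(s) {
    w <- (1:n_words)^(-s)
    expected_mattr(w / sum(w), window) - target_mattr
  }
  if (f(0) < 0) stop("target MATTR unreachable: too high for this lexicon size",
                     call. = FALSE)
  stats::uniroot(f, c(0, 4), tol = 1e-8)$root
}

# ---------------------------------------------------------------------------
# Lexicon generation

# deterministic letter rendering of a pronunciation, for orthographies
orth_from_pron <- function(phones) {
  map <- c(AA = "a", AE = "a", AH = "u", AO = "o", AW = "aw", AY = "ay",
           EH = "e", ER = "er", EY = "ei", IH = "i", IY = "ee", OW = "o",
           OY = "oy", UH = "oo", UW = "u", B = "b", CH = "ch", D = "d",
           DH = "th", F = "f", G = "g", HH = "h", JH = "j", K = "k",
           L = "l", M = "m", N = "n", NG = "ng", P = "p", R = "r", S = "s",
           SH = "sh", T = "t", TH = "th", V = "v", W = "w", Y = "y",
           Z = "z", ZH = "zh")
  paste(map[strip_stress(phones)], collapse = "")
}

#' Generate a Zipfian pronouncing lexicon
#'
#' Word lengths are 1 + Poisson(2.5) segments (capped at 9) alternating
#' consonant and vowel slots, so every word is pronounceable and contains a
#' vowel; the first vowel carries primary stress, later vowels are
#' unstressed. Pronunciations are drawn over a reduced phoneme set (ten
#' consonants spanning the stop/fricative/nasal manners plus the three
#' peripheral corner vowels /i, a, u/ and two non-corner vowels) so that,
#' as in a natural lexicon, words have phonological neighbors; the full
#' ARPAbet space would leave the neighborhood graph almost empty at this
#' lexicon size. Homophones are allowed. log10 corpus frequencies follow a
#' Zipf rank-frequency law with the configured exponent; the top 8% of
#' ranks are flagged function words; roughly 10% of entries receive a
#' second pronunciation variant (one substituted segment).
#'
#' @param config a [generator_config()].
#' @return a [cds_lexicon()].
#' @export
gen_lexicon <- function(config) {
  inv <- list(consonants = c("B", "D", "G", "K", "P", "T", "S", "F", "M", "N"),
              vowels = c("IY", "AA", "UW", "AE", "OW"))
  with_seed(config$seed, {
    n <- config$lexicon_size
    lens <- 1L + stats::rpois(n, 2.5)
    lens[lens > 9] <- 9L
    orths <- character(n)
    prons <- character(n)
    for (i in seq_len(n)) {
      L <- lens[i]
      # alternate consonant/vowel slots starting from a random slot type;
      # homophones are allowed (orthographies are made unique below)
      start_c <- stats::runif(1) < 0.7
      slots <- rep(c(start_c, !start_c), length.out = L)
      ph <- character(L)
      ph[slots] <- sample(setdiff(inv$consonants, "R"), sum(slots), replace = TRUE)
      ph[!slots] <- sample(inv$vowels, sum(!slots), replace = TRUE)
      if (!any(!slots)) { # no vowel slot: force last segment to a vowel
        ph[L] <- sample(inv$vowels, 1)
        slots[L] <- FALSE
      }
      vpos <- which(!slots)
      stress <- rep("0", length(vpos))
      stress[1] <- "1"
      ph[vpos] <- paste0(ph[vpos], stress)
      prons[i] <- paste(ph, collapse = " ")
      o <- orth_from_pron(ph)
      k <- 1L
      oo <- o
      while (oo %in% orths[seq_len(i - 1)]) { k <- k + 1L; oo <- paste0(o, k) }
      orths[i] <- oo
    }
    rank <- seq_len(n)
    log10_freq <- 7 - config$zipf_exponent * log10(rank) +
      stats::rnorm(n, 0, 0.15)
    is_fun <- rank <= ceiling(0.08 * n)
    df <- data.frame(orthography = orths, pronunciation = prons,
                     log10_frequency = log10_freq,
                     is_function_word = is_fun, stringsAsFactors = FALSE)
    # second pronunciation variants for ~10% of entries
    extra <- which(stats::runif(n) < 0.10 & lens >= 2)
    for (i in extra) {
      ph <- strsplit(prons[i], " ")[[1]]
      j <- sample(length(ph), 1)
      pool <- if (is_vowel(ph[j])) paste0(sample(inv$vowels, 1), "1")
        else sample(setdiff(inv$consonants, "R"), 1)
      ph[j] <- pool
      df <- rbind(df, data.frame(orthography = orths[i],
                                 pronunciation = paste(ph, collapse = " "),
                                 log10_frequency = log10_freq[i],
                                 is_function_word = is_fun[i],
                                 stringsAsFactors = FALSE))
    }
    cds_lexicon(df)
  })
}

# per-symbol prototype spectra, deterministic in the master seed
gen_phone_prototypes <- function(config) {
  inv <- arpabet_inventory()$all
  with_seed(config$seed + 1L, {
    proto <- matrix(stats::rnorm(length(inv) * config$n_mels), nrow = length(inv))
    rownames(proto) <- inv
    proto
  })
}

# ---------------------------------------------------------------------------
# Session generation

#' Generate one caregiver-child session
#'
#' Draws the session token count from the timepoint's Normal target
#' (truncated at the MATTR window), samples tokens independently from the
#' lexicon with rank probabilities calibrated so the expected MATTR matches
#' the timepoint target, lays out phone intervals with log-normal durations
#' matched to the target median, and attaches per-phone Mel spectra under a
#' recursive blended-prototype coarticulation model: the realized spectrum
#' of phone i is `r_i = (1 - kappa) * prototype_i + kappa * r_{i-1}` plus
#' Gaussian noise, with `r_1` the first phone's own prototype. Carrying
#' over the preceding *realized* spectrum (articulator inertia) makes the
#' adjacent spectral distance strictly decreasing in kappa — the
#' stationary per-band distance variance is proportional to
#' `(1 - kappa)^2 / (1 + kappa)` — and at kappa = 1 with zero noise all
#' spectra collapse, so repeated-phone distances are exactly 0.
#' Midpoint F1/F2 formants are drawn per vowel corner from the configured
#' Gaussians for stressed peripheral vowels.
#'
#' @param dyad_index integer dyad index (1-based).
#' @param timepoint timepoint label.
#' @param config a [generator_config()].
#' @param lexicon a [cds_lexicon()], typically [gen_lexicon()]`(config)`.
#' @param prototypes optional prototype matrix (computed from `config` when
#'   missing); pass it when generating many sessions.
#' @param kappa optional override of the timepoint's blending coefficient.
#' @return a [cds_session()] with `formants` and `spectra` attached, plus
#'   attribute `"truth"` (list of the generating values: kappa, duration
#'   median, expected MATTR, sampling exponent).
#' @export
gen_session <- function(dyad_index, timepoint, config, lexicon,
                        prototypes = gen_phone_prototypes(config),
                        kappa = NULL) {
  tp_index <- match(timepoint, TIMEPOINT_LEVELS)
  if (is.na(tp_index)) stop("unknown timepoint: ", timepoint, call. = FALSE)
  tgt <- config$targets[config$targets$timepoint == timepoint, ]
  if (nrow(tgt) != 1) stop("no target row for timepoint ", timepoint, call. = FALSE)
  if (is.null(kappa)) kappa <- tgt$kappa
  orths <- unique(lexicon$orthography)
  first_var <- lexicon[!duplicated(lexicon$orthography), ]
  s_exp <- tryCatch(
    calibrate_sampling_exponent(tgt$mattr, length(orths),
                                window = config$mattr_window),
    error = function(e) {
      message("MATTR target unreachable for this lexicon size; sampling uniformly")
      0
    })
  w <- (seq_along(orths))^(-s_exp)
  probs <- w / sum(w)
  with_seed(session_seed(config$seed, dyad_index, tp_index), {
    n_tok <- max(config$mattr_window,
                 round(stats::rnorm(1, tgt$tokens_mean, tgt$tokens_sd)))
    pick <- sample(seq_along(orths), n_tok, replace = TRUE, prob = probs)
    orth <- orths[pick]
    # utterance boundaries: geometric segments with the configured mean
    new_utt <- c(TRUE, stats::runif(n_tok - 1) < 1 / config$utterance_mean_len)
    tokens <- data.frame(utterance_index = cumsum(new_utt) - 1L,
                         token_index = seq_len(n_tok) - 1L,
                         orthography = orth, stringsAsFactors = FALSE)
    for (tag in names(config$p_tags)) {
      tokens[[tag]] <- stats::runif(n_tok) < config$p_tags[[tag]]
    }
    tokens$is_content <- !first_var$is_function_word[pick]
    # phone layout
    prons <- pron_phones(first_var$pronunciation)[pick]
    n_ph_per <- lengths(prons)
    labels <- unlist(prons)
    word_index <- rep(seq_len(n_tok), n_ph_per)
    n_ph <- length(labels)
    durs <- stats::rlnorm(n_ph, meanlog = log(tgt$duration_median_ms / 1000),
                          sdlog = 0.5)
    # gaps: 50 ms between words, 200 ms extra between utterances
    gap <- c(0, ifelse(diff(word_index) > 0, 0.05, 0))
    utt_of_phone <- tokens$utterance_index[word_index]
    gap <- gap + c(0, ifelse(diff(utt_of_phone) > 0, 0.2, 0))
    starts <- cumsum(c(0, durs[-n_ph])) + cumsum(gap)
    word_flag <- stats::runif(n_tok) < config$p_flags
    which_flag <- sample(c("whispered", "yelled", "overlap"), n_tok, replace = TRUE)
    phones <- data.frame(label = labels, start = starts, end = starts + durs,
                         word_index = word_index,
                         whispered = word_flag[word_index] & which_flag[word_index] == "whispered",
                         yelled = word_flag[word_index] & which_flag[word_index] == "yelled",
                         overlap = word_flag[word_index] & which_flag[word_index] == "overlap",
                         stringsAsFactors = FALSE)
    # recursively blended prototype spectra (carryover of the realized
    # spectrum, so distances shrink monotonically in kappa)
    base <- strip_stress(labels)
    P <- prototypes[base, , drop = FALSE]
    if (kappa >= 1) {
      smoothed <- matrix(P[1, ], nrow = n_ph, ncol = config$n_mels, byrow = TRUE)
    } else {
      smoothed <- (1 - kappa) * P
      smoothed[1, ] <- P[1, ]
      if (n_ph > 1) {
        for (i in 2:n_ph) {
          smoothed[i, ] <- smoothed[i, ] + kappa * smoothed[i - 1, ]
        }
      }
    }
    spectra <- smoothed +
      matrix(stats::rnorm(n_ph * config$n_mels, 0, config$spectrum_noise_sd),
             nrow = n_ph)
    # formants for stressed peripheral vowels
    corner <- vowel_corner(labels)
    fidx <- which(!is.na(corner) & is_stressed(labels))
    formants <- NULL
    if (length(fidx) > 0) {
      vt <- config$vowel_targets
      m <- match(corner[fidx], vt$corner)
      F1 <- stats::rnorm(length(fidx), vt$F1_mean[m], vt$F1_sd[m])
      F2 <- stats::rnorm(length(fidx), vt$F2_mean[m], vt$F2_sd[m])
      F1 <- pmax(F1, 150)
      F2 <- pmax(F2, F1 + 200)
      formants <- data.frame(phone_index = fidx, F1_hz = F1, F2_hz = F2)
    }
    sess <- cds_session(sprintf("d%03d", dyad_index), timepoint, tokens,
                        phones, formants = formants, spectra = spectra)
    attr(sess, "truth") <- list(kappa = kappa,
                                duration_median_ms = tgt$duration_median_ms,
                                expected_mattr = expected_mattr(probs, config$mattr_window),
                                sampling_exponent = s_exp)
    sess
  })
}

#' Generate a whole corpus
#'
#' @param config a [generator_config()].
#' @param lexicon optional pre-generated lexicon.
#' @return list with `lexicon`, `sessions` (list, dyads nested in
#'   timepoints) and `config`.
#' @export
gen_corpus <- function(config, lexicon = gen_lexicon(config)) {
  prototypes <- gen_phone_prototypes(config)
  sessions <- list()
  for (tp in config$timepoints) {
    for (d in seq_len(config$n_dyads)) {
      sessions[[length(sessions) + 1L]] <-
        gen_session(d, tp, config, lexicon, prototypes = prototypes)
    }
  }
  list(lexicon = lexicon, sessions = sessions, config = config)
}

# ---------------------------------------------------------------------------
# Outcomes

#' Outcome model configuration
#'
#' Declares the linear models that generate child outcomes from
#' (standardized) battery features: nonword-repetition accuracy on the
#' \[0, 1\] proportion scale (population mean 0.65, SD 0.16) and expressive
#' vocabulary on the MB-CDI 24-month scale (mean 355.94, SD 150.32).
#' Coefficient names refer to feature-table columns or the generated
#' covariates `maternal_ed`, `gender_male` and `vocab_18`.
#'
#' @param nwr_coefs named coefficient vector for NWR accuracy (per SD of
#'   each predictor, on the proportion scale).
#' @param nwr_base,nwr_noise_sd intercept and residual SD of the NWR model.
#' @param vocab_coefs named coefficient vector for expressive vocabulary.
#' @param vocab_base,vocab_noise_sd intercept and residual SD (MB-CDI
#'   units).
#' @return a `cds_outcome_config` list.
#' @export
outcome_config <- function(nwr_coefs = c(median_coarticulation_distance = -0.06,
                                         median_phone_duration_ms = -0.02,
                                         mean_word_length = 0.05,
                                         n_types = 0.04,
                                         vocab_18 = 0.02,
                                         maternal_ed = 0.03),
                           nwr_base = 0.65, nwr_noise_sd = 0.12,
                           vocab_coefs = c(n_types = 60,
                                           median_log_frequency = -30,
                                           median_coarticulation_distance = 25,
                                           median_phone_duration_ms = 30,
                                           maternal_ed = 25,
                                           gender_male = -55),
                           vocab_base = 355.94, vocab_noise_sd = 110) {
  stopifnot(nwr_noise_sd > 0, vocab_noise_sd > 0)
  structure(list(nwr_coefs = nwr_coefs, nwr_base = nwr_base,
                 nwr_noise_sd = nwr_noise_sd, vocab_coefs = vocab_coefs,
                 vocab_base = vocab_base, vocab_noise_sd = vocab_noise_sd),
            class = "cds_outcome_config")
}

zscore_cols <- function(df, cols) {
  for (cn in cols) {
    x <- df[[cn]]
    s <- stats::sd(x, na.rm = TRUE)
    df[[cn]] <- if (is.na(s) || s == 0) x * 0 else (x - mean(x, na.rm = TRUE)) / s
  }
  df
}

#' Generate child outcomes from feature rows
#'
#' Builds the demographic covariates (maternal education in years, child
#' gender, 18-month expressive vocabulary), standardizes every feature
#' named in the outcome coefficients, applies the declared linear
#' predictors plus Gaussian noise, and clips NWR accuracy to \[0, 1\]
#' (warning when more than 10% of children are clipped, which indicates
#' effect sizes inconsistent with the scale).
#'
#' @param features feature data frame, one row per dyad (the predictor
#'   timepoint's battery output).
#' @param config an [outcome_config()].
#' @param seed RNG seed.
#' @return data frame with `dyad_id`, `nwr_accuracy`, `vocab_24`,
#'   `vocab_18`, `maternal_ed`, `gender_male`, and attribute
#'   `"clipping_rate"`.
#' @export
gen_outcomes <- function(features, config = outcome_config(), seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  n <- nrow(features)
  with_seed(seed, {
    out <- data.frame(dyad_id = features$dyad_id,
                      maternal_ed = stats::rnorm(n, 16, 1.5),
                      gender_male = stats::rbinom(n, 1, 35 / 84),
                      vocab_18 = pmax(0, stats::rnorm(n, 112.03, 108.6)),
                      stringsAsFactors = FALSE)
    design <- cbind(features, out[, c("maternal_ed", "gender_male", "vocab_18")])
    lin_pred <- function(coefs) {
      need <- names(coefs)
      miss <- setdiff(need, names(design))
      if (length(miss) > 0) {
        stop("outcome coefficients reference missing column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
      }
      z <- zscore_cols(design[, need, drop = FALSE], need)
      as.numeric(as.matrix(z) %*% coefs)
    }
    nwr_raw <- config$nwr_base + lin_pred(config$nwr_coefs) +
      stats::rnorm(n, 0, config$nwr_noise_sd)
    clipped <- nwr_raw < 0 | nwr_raw > 1
    out$nwr_accuracy <- pmin(1, pmax(0, nwr_raw))
    out$vocab_24 <- config$vocab_base + lin_pred(config$vocab_coefs) +
      stats::rnorm(n, 0, config$vocab_noise_sd)
    rate <- mean(clipped)
    if (rate > 0.10) {
      warning(sprintf("NWR clipping rate %.1f%% exceeds 10%%: effect sizes inconsistent with the [0, 1] scale",
                      100 * rate), call. = FALSE)
    }
    attr(out, "clipping_rate") <- rate
    out
  })
}

# ---------------------------------------------------------------------------
# Recovery experiments

#' Small-session generator targets for simulation studies
#'
#' The default Table-2-scale sessions (around a thousand tokens each) are
#' what single-corpus analyses use; repeated-simulation studies use
#' shorter sessions (120-token target) so hundreds of corpora stay cheap,
#' while keeping the MATTR, duration and kappa structure.
#'
#' @return a target data frame like [default_targets()].
#' @export
simulation_targets <- function() {
  t <- default_targets()
  t$tokens_mean <- rep(120, nrow(t))
  t$tokens_sd <- rep(20, nrow(t))
  t
}

#' End-to-end coefficient recovery experiment
#'
#' The pipeline's acceptance harness: for each replicate, generate a corpus
#' at one predictor timepoint, run the battery, generate outcomes from the
#' declared truth, refit the outcome model on the standardized measured
#' features, and record each coefficient's estimate, 95% CI coverage of the
#' truth, and sign agreement.
#'
#' @param config a [generator_config()] (simulation-scale targets
#'   recommended, see [simulation_targets()]).
#' @param n_reps number of replicates.
#' @param seed master seed for the experiment.
#' @param out_cfg an [outcome_config()] declaring the truth.
#' @param timepoint predictor timepoint to generate.
#' @return list with `estimates` (data frame rep x coefficient) and
#'   `summary` (per coefficient: truth, mean estimate, bias, RMSE,
#'   coverage, sign agreement rate).
#' @export
recovery_experiment <- function(config, n_reps = 200, seed = 1,
                                out_cfg = outcome_config(),
                                timepoint = "10-11") {
  lexicon <- gen_lexicon(config)
  type_stats <- lexicon_type_stats(lexicon)
  prototypes <- gen_phone_prototypes(config)
  coef_names <- names(out_cfg$nwr_coefs)
  rows <- list()
  for (r in seq_len(n_reps)) {
    cfg_r <- config
    cfg_r$seed <- as.integer((config$seed + 7717 * r) %% 2147483647)
    sessions <- lapply(seq_len(config$n_dyads), gen_session,
                       timepoint = timepoint, config = cfg_r,
                       lexicon = lexicon, prototypes = prototypes)
    feats <- do.call(rbind, lapply(sessions, function(s) {
      session_features(s, lexicon, type_stats = type_stats)$row
    }))
    outc <- gen_outcomes(feats, out_cfg, seed = cfg_r$seed + 1)
    d <- cbind(zscore_cols(feats[, intersect(coef_names, names(feats)), drop = FALSE],
                           intersect(coef_names, names(feats))),
               zscore_cols(outc[, intersect(coef_names, names(outc)), drop = FALSE],
                           intersect(coef_names, names(outc))))
    d$.y <- outc$nwr_accuracy
    fit <- fit_ols(stats::as.formula(paste(".y ~", paste(coef_names, collapse = " + "))), d)
    for (cn in coef_names) {
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, coefficient = cn,
        estimate = unname(fit$coefficients[cn]),
        lower = unname(fit$ci[cn, "lower"]),
        upper = unname(fit$ci[cn, "upper"]),
        stringsAsFactors = FALSE)
    }
  }
  est <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(coef_names, function(cn) {
    e <- est[est$coefficient == cn, ]
    truth <- unname(out_cfg$nwr_coefs[cn])
    data.frame(coefficient = cn, truth = truth,
               mean_estimate = mean(e$estimate),
               bias = mean(e$estimate) - truth,
               rmse = sqrt(mean((e$estimate - truth)^2)),
               coverage = mean(e$lower <= truth & truth <= e$upper),
               sign_rate = mean(sign(e$estimate) == sign(truth)),
               stringsAsFactors = FALSE)
  }))
  list(estimates = est, summary = summ)
}

#' Disentangle-classification simulation
#'
#' Draws a correlated predictor pair from a bivariate normal with
#' correlation `rho`, generates `y = beta1 * x1 + beta2 * x2 + noise`, runs
#' [disentangle()] and tallies the classifications; also returns the rate
#' at which each residual test rejects, which under an all-null truth is
#' the test's type-I error.
#'
#' @param n observations per replicate.
#' @param n_reps number of replicates.
#' @param rho predictor correlation.
#' @param beta1,beta2 true coefficients.
#' @param noise_sd residual SD.
#' @param alpha significance threshold.
#' @param seed master seed.
#' @return list with `rates` (named classification proportions),
#'   `reject_x1`, `reject_x2` (residual-test rejection rates) and
#'   `classifications`.
#' @export
disentangle_simulation <- function(n = 84, n_reps = 200, rho = 0.7,
                                   beta1 = 1, beta2 = 0, noise_sd = 1,
                                   alpha = 0.05, seed = 1) {
  cls <- character(n_reps)
  rej1 <- logical(n_reps)
  rej2 <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    d <- with_seed((seed + 7919 * r) %% 2147483647, {
      x1 <- stats::rnorm(n)
      x2 <- rho * x1 + sqrt(1 - rho^2) * stats::rnorm(n)
      y <- beta1 * x1 + beta2 * x2 + stats::rnorm(n, 0, noise_sd)
      data.frame(x1 = x1, x2 = x2, y = y)
    })
    dis <- suppressWarnings(disentangle(d, "x1", "x2", "y", alpha = alpha))
    cls[r] <- dis$classification
    rej1[r] <- !is.na(dis$p_resid_x1) && dis$p_resid_x1 < alpha
    rej2[r] <- !is.na(dis$p_resid_x2) && dis$p_resid_x2 < alpha
  }
  tab <- table(factor(cls, levels = c("x1_direct", "x2_direct", "both", "neither")))
  list(rates = stats::setNames(as.numeric(tab) / n_reps, names(tab)),
       reject_x1 = mean(rej1), reject_x2 = mean(rej2),
       classifications = cls)
}

# ---------------------------------------------------------------------------
# Corpus export

#' Write a corpus to disk
#'
#' Writes each session's TextGrid, token TSV and (when present) formant
#' TSV and spectra CSV under `dir`, plus the lexicon TSV.
#'
#' @param corpus a [gen_corpus()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_lexicon(corpus$lexicon, file.path(dir, "lexicon.tsv"))
  for (s in corpus$sessions) {
    stem <- file.path(dir, sprintf("%s_%s", s$dyad_id, s$timepoint))
    wi <- sort(unique(s$phones$word_index))
    words <- data.frame(label = s$tokens$orthography[wi],
                        start = as.numeric(tapply(s$phones$start, s$phones$word_index, min)),
                        end = as.numeric(tapply(s$phones$end, s$phones$word_index, max)))
    write_textgrid(s$phones, words, paste0(stem, ".TextGrid"))
    write_token_table(s$tokens, paste0(stem, "_tokens.tsv"))
    if (!is.null(s$formants)) {
      utils::write.table(s$formants, paste0(stem, "_formants.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(s$spectra)) {
      utils::write.csv(as.data.frame(s$spectra), paste0(stem, "_spectra.csv"),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}
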