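# Nonword-repetition (NWR) scoring with a real-word articulatory control:
# a phoneme produced incorrectly in both the nonword and the matched
# real-word condition is attributed to articulatory limitation and is not
# marked incorrect in the nonword condition. Items a child fails to repeat
# after two experimenter prompts are scored fully incorrect.

#' Adjudicate a single phoneme target
#'
#' Compares the child's nonword production with the matched real-word
#' production of the same target phoneme. Comparison is exact symbol match
#' after stress stripping (binary scoring, no feature-distance partial
#' credit). A missing or `NA` production counts as incorrect for that
#' condition; a missing real-word response for the pair scores the nonword
#' at face value with a warning.
#'
#' @param nw_produced,nw_target produced and target phoneme in the nonword
#'   condition (ARPAbet symbols).
#' @param rw_produced,rw_target same for the paired real-word condition;
#'   `rw_target = NA` marks an absent real-word response record.
#' @return one of `"correct"`, `"incorrect"`, `"articulatory_control"`.
#' @export
#' @examples
#' score_target("D", "T", "D", "T")  # wrong in both -> articulatory_control
#' score_target("D", "T", "T", "T")  # wrong only in the nonword -> incorrect
score_target <- function(nw_produced, nw_target, rw_produced, rw_target) {
  nw_ok <- phoneme_match(nw_produced, nw_target)
  if (nw_ok) return("correct")
  if (is.na(rw_target)) {
    warning("missing real-word response; scoring nonword target at face value",
            call. = FALSE)
    return("incorrect")
  }
  rw_ok <- phoneme_match(rw_produced, rw_target)
  if (!rw_ok) "articulatory_control" else "incorrect"
}

phoneme_match <- function(produced, target) {
  if (is.na(produced) || is.na(target)) return(FALSE)
  identical(strip_stress(produced), strip_stress(target))
}

#' Adjudicate all targets of one nonword/real-word item pair
#'
#' Applies [score_target()] position by position. A nonword the child
#' refused (failed to repeat after the two allowed experimenter prompts) is
#' scored incorrect on every target; the articulatory control does not apply
#' to refusals.
#'
#' @param nw_produced,rw_produced character vectors of produced phonemes per
#'   target position (`NA` for omissions); `rw_produced = NULL` marks an
#'   absent real-word record.
#' @param targets character vector of target phonemes (shared by the
#'   matched pair by design).
#' @param prompts_given number of experimenter prompts, at most 2.
#' @param refused did the child fail to repeat the nonword at all?
#' @return character vector of adjudications, one per target.
#' @export
score_item <- function(nw_produced, rw_produced, targets,
                       prompts_given = 1, refused = FALSE) {
  if (prompts_given > 2) {
    stop("prompts_given exceeds the two-prompt maximum", call. = FALSE)
  }
  n <- length(targets)
  if (refused) return(rep("incorrect", n))
  if (length(nw_produced) != n) {
    stop("nonword production length does not match target count", call. = FALSE)
  }
  no_rw <- is.null(rw_produced)
  vapply(seq_len(n), function(i) {
    score_target(nw_produced[i], targets[i],
                 if (no_rw) NA_character_ else rw_produced[i],
                 if (no_rw) NA_character_ else targets[i])
  }, character(1))
}

#' Session-level NWR accuracy
#'
#' Scores every stimulus item of a child's session and aggregates the
#' adjudications into an accuracy in \[0, 1\]. In the default
#' `denominator = "keep"` mode, targets forgiven by the articulatory
#' control are scored correct, keeping the full target count in the
#' denominator: accuracy = (correct + articulatory_control) / n_targets.
#' The alternative `"exclude"` mode drops them from the denominator:
#' accuracy = correct / (correct + incorrect).
#'
#' @param responses data frame with one row per (item, condition): columns
#'   `item_id`, `condition` (`"nonword"` or `"realword"`), `produced`
#'   (space-separated produced phonemes, `.` for an omitted position),
#'   `prompts_given`, `refused`.
#' @param stimuli stimulus table as from [nwr_stimuli_synthetic()]: columns
#'   `item_id`, `syllables`, `targets` (space-separated target phonemes).
#' @param denominator `"keep"` (default) or `"exclude"`.
#' @return list with `n_targets`, `n_correct`, `n_incorrect`,
#'   `n_articulatory_control`, `accuracy`, and `adjudications` (data frame
#'   `item_id`, `position`, `target`, `adjudication`).
#' @export
session_accuracy <- function(responses, stimuli, denominator = c("keep", "exclude")) {
  denominator <- match.arg(denominator)
  nw <- responses[responses$condition == "nonword", , drop = FALSE]
  rw <- responses[responses$condition == "realword", , drop = FALSE]
  if (anyDuplicated(nw$item_id) || anyDuplicated(rw$item_id)) {
    stop("duplicate item responses", call. = FALSE)
  }
  missing_items <- setdiff(stimuli$item_id, nw$item_id)
  if (length(missing_items) > 0) {
    stop("no nonword response for item(s): ",
         paste(missing_items, collapse = ", "), call. = FALSE)
  }
  adj <- list()
  for (k in seq_len(nrow(stimuli))) {
    id <- stimuli$item_id[k]
    targets <- strsplit(stimuli$targets[k], "\\s+")[[1]]
    nw_row <- nw[nw$item_id == id, ]
    rw_row <- rw[rw$item_id == id, , drop = FALSE]
    parse_prod <- function(row) {
      if (nrow(row) == 0) return(NULL)
      p <- strsplit(row$produced, "\\s+")[[1]]
      p[p == "."] <- NA_character_
      p
    }
    a <- score_item(parse_prod(nw_row), parse_prod(rw_row), targets,
                    prompts_given = nw_row$prompts_given,
                    refused = isTRUE(nw_row$refused))
    adj[[k]] <- data.frame(item_id = id, position = seq_along(targets),
                           target = targets, adjudication = a,
                           stringsAsFactors = FALSE)
  }
  adj <- do.call(rbind, adj)
  n_cor <- sum(adj$adjudication == "correct")
  n_inc <- sum(adj$adjudication == "incorrect")
  n_art <- sum(adj$adjudication == "articulatory_control")
  acc <- if (denominator == "keep") {
    (n_cor + n_art) / nrow(adj)
  } else {
    if (n_cor + n_inc == 0) NA_real_ else n_cor / (n_cor + n_inc)
  }
  list(n_targets = nrow(adj), n_correct = n_cor, n_incorrect = n_inc,
       n_articulatory_control = n_art, accuracy = acc, adjudications = adj)
}

#' Synthetic NWR stimulus design
#'
#' A placeholder stimulus inventory with the study design's shape — 11
#' nonword/real-word item pairs (4 one-syllable, 4 two-syllable, 3
#' three-syllable) totalling 33 scoreable phoneme targets, three per item —
#' but made-up phoneme strings: the original stimulus items are not
#' reproduced here. One-syllable items score all three CVC positions;
#' longer items score three designated positions. Late-emerging consonants
#' (e.g. /r/) are avoided, mirroring the design's articulatory constraint.
#'
#' @return data frame with columns `item_id`, `syllables`, `targets`
#'   (space-separated ARPAbet, the scored positions), `realword_item_id`.
#' @export
nwr_stimuli_synthetic <- function() {
  items <- data.frame(
    item_id = sprintf("nw%02d", 1:11),
    syllables = c(1, 1, 1, 1, 2, 2, 2, 2, 3, 3, 3),
    targets = c("M AA1 P",
                "T IY1 F",
                "N UW1 S",
                "P EH1 D",
                "B AE1 K",
                "D IH1 M",
                "K AH1 N",
                "F OW1 T",
                "M EY1 D",
                "S AA1 B",
                "P UW1 K"),
    realword_item_id = sprintf("rw%02d", 1:11),
    stringsAsFactors = FALSE)
  stopifnot(sum(lengths(strsplit(items$targets, " "))) == 33)
  items
}

#' Read an NWR stimulus table (TSV)
#'
#' TSV columns: `item_id`, `syllables`, `targets` (space-separated ARPAbet),
#' `realword_item_id`.
#'
#' @param path file path.
#' @return stimulus data frame.
#' @export
read_nwr_stimuli <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read an NWR response table (TSV)
#'
#' TSV columns: `child_id`, `item_id`, `condition`, `produced`
#' (space-separated, `.` for omissions), `prompts_given`, `refused` (0/1).
#'
#' @param path file path.
#' @return response data frame with logical `refused`.
#' @export
read_nwr_responses <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$refused <- as.logical(df$refused) | df$refused == 1
  df
}
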