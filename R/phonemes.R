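#' ARPAbet phoneme inventory
#'
#' The standard 39-symbol ARPAbet inventory for American English, split into
#' vowels and consonants. Vowels may carry a trailing stress digit (0 =
#' unstressed, 1 = primary, 2 = secondary) on transcribed symbols; the
#' inventory itself is stress-free. Consonants never carry stress digits.
#'
#' @return A list with character vectors `vowels`, `consonants`, `stops`
#'   (oral plosives), `glottal` (the voiceless glottal fricative) and `all`.
#' @export
#' @examples
#' inv <- arpabet_inventory()
#' "AE" %in% inv$vowels
arpabet_inventory <- function() {
  vowels <- c("AA", "AE", "AH", "AO", "AW", "AY", "EH", "ER", "EY",
              "IH", "IY", "OW", "OY", "UH", "UW")
  consonants <- c("B", "CH", "D", "DH", "F", "G", "HH", "JH", "K", "L",
                  "M", "N", "NG", "P", "R", "S", "SH", "T", "TH", "V",
                  "W", "Y", "Z", "ZH")
  list(vowels = vowels,
       consonants = consonants,
       stops = c("P", "B", "T", "D", "K", "G"),
       glottal = "HH",
       all = c(vowels, consonants))
}

#' Strip stress digits from ARPAbet symbols
#'
#' @param phones character vector of ARPAbet symbols, possibly with trailing
#'   stress digits on vowels (e.g. `"AE1"`).
#' @return the symbols without stress digits.
#' @export
#' @examples
#' strip_stress(c("K", "AE1", "T"))
strip_stress <- function(phones) {
  sub("[0-2]$", "", phones)
}

#' Extract the stress digit of ARPAbet symbols
#'
#' @inheritParams strip_stress
#' @return integer vector: 0/1/2 for vowels carrying a digit, `NA` otherwise.
#' @export
stress_digit <- function(phones) {
  d <- regmatches(phones, regexpr("[0-2]$", phones))
  out <- rep(NA_integer_, length(phones))
  out[grepl("[0-2]$", phones)] <- as.integer(d)
  out
}

#' Is a symbol a vowel?
#'
#' @inheritParams strip_stress
#' @return logical vector.
#' @export
is_vowel <- function(phones) {
  strip_stress(phones) %in% arpabet_inventory()$vowels
}

#' Is a vowel symbol stressed (primary or secondary)?
#'
#' @inheritParams strip_stress
#' @return logical vector; `FALSE` for consonants and digit-less vowels.
#' @export
is_stressed <- function(phones) {
  d <- stress_digit(phones)
  !is.na(d) & d > 0L
}

#' Map peripheral vowels to corner categories
#'
#' The three peripheral vowels used for vowel-space measurement: /i/ (IY),
#' /a/ (AA) and /u/ (UW). Other symbols map to `NA`.
#'
#' @inheritParams strip_stress
#' @return character vector in `c("i", "a", "u", NA)`.
#' @export
vowel_corner <- function(phones) {
  base <- strip_stress(phones)
  out <- rep(NA_character_, length(phones))
  out[base == "IY"] <- "i"
  out[base == "AA"] <- "a"
  out[base == "UW"] <- "u"
  out
}

# internal: validate that all symbols (stress stripped) are in an inventory
check_inventory <- function(phones, inventory, context = "pronunciation") {
  bad <- setdiff(unique(strip_stress(phones)), inventory)
  if (length(bad) > 0) {
    stop(sprintf("unknown phoneme symbol(s) in %s: %s",
                 context, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
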