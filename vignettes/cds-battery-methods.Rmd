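---
title: "Measuring child-directed speech: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring child-directed speech: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdsbattery)
```

This vignette is the package's own account of its methods: the measures it
computes, the modeling machinery, the assumptions baked into each step, the
tunable parameters and their defaults, and the design choices that were
genuinely open. Nothing stated here as an empirical result goes beyond what
the package's tests and acceptance script themselves compute.

## The measurement problem

Caregiver speech to infants and toddlers changes along two coupled axes.
Lexically, older children hear more word types and tokens, longer and less
frequent words, and words from sparser phonological neighborhoods.
Acoustically, caregivers vary their vowel-space size, segment durations and
degree of coarticulation. These axes are not independent: speakers
phonetically reduce high-frequency, short, dense-neighborhood words, so an
"acoustic" difference between sessions may be a lexical difference in
disguise. A battery that measures both sides on the same phone-aligned
sessions, plus machinery to disentangle collinear predictors of child
outcomes, is therefore needed as one coherent pipeline.

## Input representation

A session is a validated container (`cds_session`) of word tokens,
phone intervals and optional formant measurements and per-phone spectra.
Times are seconds; intervals are half-open `[start, end)`; two phones are
adjacent when `|end_i - start_{i+1}|` is at most the adjacency tolerance
(default 1 ms). Phone alignments are consumed, not produced: the package
reads Praat long-format TextGrids (the short format is rejected so the
parser stays small and fully testable). Whispered, yelled and overlapping
speech must be excluded from acoustic measurement; since annotation
conventions for these vary, the package declares one — label suffixes
`@w`, `@y`, `@o` on the phone tier — as the least invasive encoding.
Formants arrive as a per-phone table (`F1_hz`, `F2_hz` at vowel midpoint);
no formant tracker is included, deliberately: tracking quality dominates
vowel measures and belongs to dedicated tools.

## Lexical battery

**Cleaning** (`clean_word_inventory`). Onomatopoeia, exclamations and
proper names are excluded from all counting (place names common to a
sample are expected to arrive untagged and so are retained). Contractions
are kept for token/type/TTR counts but dropped from phono-lexical lookups,
because pronouncing dictionaries do not list them. The cleaning ledger is
conserving: kept + excluded equals the input token count, and tests assert
it.

**Diversity.** TTR is types/tokens. MATTR averages the TTR of every
contiguous 10-token window, advancing one token at a time over the whole
session stream — windows do not reset at utterance boundaries, matching
how moving-average diversity is conventionally computed over transcripts.
Sessions shorter than the window fall back to plain TTR and carry a flag.
Whether TTR should be computed over raw or cleaned token streams is not
fixed by convention; the package computes it over cleaned tokens (the same
stream as the type count), and the raw stream remains available to anyone
who disagrees.

**Phonotactic probability.** Biphone tables are built from the lexicon:
for 0-based position *i*, the count of pronunciations containing an
ordered pair starting at *i*, divided by the number of pronunciations long
enough to host a biphone there. That denominator choice keeps each
position a proper probability. Counting is type-based and unweighted by
default — each deduplicated pronunciation variant counts once — with a
frequency-weighted switch, since reference dictionaries offer both and the
unweighted table is the simpler reproducible default. A word's raw
probability is the mean of its positional biphone probabilities; because
longer words mechanically average over more (usually rarer) biphones, the
raw value is z-scored within its word-length stratum against the whole
lexicon. Strata with fewer than two members or zero variance yield `NA`
rather than a fabricated zero.

**Neighborhood density** counts distinct orthographies (not
pronunciations — homophones collapse) with some variant exactly one
phoneme edit away (substitution, deletion, insertion), stress ignored,
the query's own orthography excluded. A brute-force
generate-all-edits-and-intersect oracle checks the implementation on
random lexicons.

**Variant selection.** Words with several pronunciation variants use the
variant with the highest phonotactic probability; exact ties keep the
first-listed variant and say so.

**Unnesting.** Per-type measures are nested (many observations per
session). To compare them with unnested measures such as the number of
word types, the battery counts, per caregiver, the types at or above the
pooled median word length ("number of long words", inclusive boundary) and
strictly below the pooled median log frequency ("number of low-frequency
words"). The pooled median takes one observation per caregiver-type
without deduplicating types shared across caregivers — the convention is
not forced by anything deeper, so the simpler one was chosen and is stated
here.

## Acoustic battery

**Spectra.** Audio (mono PCM WAV) is resampled to 16 kHz and analyzed with
a 25 ms Hann window, 10 ms hop, 40 Mel bands over 0–8 kHz, log floor
1e-10. These are standard speech-analysis defaults; all are configurable,
and spectral distances are only comparable within one configuration — the
package's absolute distances are not comparable to values produced by
other toolchains with unknown settings. Each phone's spectrum is the
arithmetic mean of the frame vectors whose centers fall inside the phone.

**Coarticulation** is the Euclidean distance between the averaged spectra
of adjacent phones; *larger distance means less coarticulation*.
Eligibility mirrors the phonetic rationale: pairs must be CV or VC within
a content word with a stressed vowel; prevocalic oral stops are excluded
(utterance-initial closures cannot be delimited) while vowel-before-stop
pairs remain eligible — the exclusion's rationale concerns the closure
before the release, which only affects the C-before-V order, and this
interpretive choice is flagged here; prevocalic /h/ is excluded for its
weak spectral signature; flagged (whispered/yelled/overlap) phones are
excluded. Every excluded pair lands in exactly one ledger category, in a
declared priority order (flags, function word, stress, stop, /h/).

**Vowel measures.** Formants are Lobanov-normalized per speaker-session
(z-score of F1 and F2 over all measured vowel tokens; with fewer than two
tokens normalization is `NA` and raw Hz is retained). Normalizing per
session rather than pooling a speaker's timepoints keeps sessions
independently processable and matches per-timepoint reporting. Vowel-space
area is the shoelace area of the triangle of per-category mean (F2, F1)
positions of /i/, /a/, /u/, computed in both normalized and raw Hz space.
Dispersion is each token's Euclidean distance from the session median
(F1, F2) in normalized space, then averaged within word type so
high-frequency words cannot skew the summary (the per-token values are
also returned, since "computed from word types" admits either reading).
Phone duration is reported in ms with the session median as the summary,
as a speaking-rate proxy.

## Nonword repetition scoring

Two-year-olds make articulatory substitutions that say nothing about
phonological processing. The scoring rule therefore compares each nonword
target with the same target in a matched real word: wrong in both →
`articulatory_control`; wrong only in the nonword → `incorrect`; correct
nonword → `correct`. Items refused after the two allowed prompts are fully
incorrect, and the control does not apply to refusals. "Not marked
incorrect" is read as *scored correct* — keeping all 33 targets in the
denominator, consistent with observed accuracies reaching 1.0 — and an
exclude-from-denominator mode is provided because the wording admits that
reading too. Comparison is exact symbol match after stress stripping; no
feature-distance partial credit. The shipped stimulus table
(`nwr_stimuli_synthetic()`, also under `inst/extdata/`) reproduces only
the design's *shape* — 11 items, 4/4/3 syllable split, 33 targets, no
late-emerging consonants — with made-up phoneme strings, because the
original item strings are not reproduced here; it is labeled synthetic
everywhere.

## Statistical machinery

`fit_ols()` and `fit_random_intercept()` return one fit container
(coefficients, SE, t, p, 95% CI, residuals, log-likelihood, `k`, AIC =
2k − 2ℓ). Random intercepts (dyad) are REML fits via `lme4`; p-values use
a residual-df t approximation, chosen over Satterthwaite machinery —
contrasts are approximate and flagged as such by that choice. Pairwise
timepoint contrasts default to Holm adjustment: the original contrast
tooling's default (likely Tukey) is not reproducible from the reporting,
and Holm is exact and distribution-free; `"none"` is available.

Models mixing nested per-type rows with broadcast session-level covariates
have artificially deflated standard errors on the broadcast terms; such
fits suppress SE/p for those terms and carry an `inflated_alpha` flag
rather than printing numbers that should not be trusted.

**Disentangling collinear predictors** is the three-step residualization:
regress x1 on x2, keep the residuals; model the outcome on the residuals
plus raw x2 (and covariates); ask whether the residuals predict beyond the
ambiguous term; repeat in the other direction; classify (`x1_direct`,
`x2_direct`, `both`, `neither`) at α = 0.05. Its backbone is the
Frisch–Waugh–Lovell identity — the coefficient on resid(x1|x2) next to x2
equals the coefficient on x1 in the joint model — asserted to 1e-8 in the
tests. Calibration is simulated: under an all-null truth the residual test
rejects at the nominal 5% rate (tested within [0.03, 0.07] over 1,000
replicates), and a planted direct/indirect structure is classified
correctly in ≥ 90% of replicates.

## Synthetic corpus generator

The generator exists so every stage has known ground truth. Its defaults
are the study-scale conditions: per-timepoint token-count means/SDs
(873.38 (313.16) at 7 months rising to 1,247.22 (346.29) at 24 months),
MATTR targets (0.88 → 0.91), median phone durations (90.21 → 83.45 ms;
the unmeasured 18-month value interpolated), and a blending coefficient κ
that falls with age so spectral distance rises. Type-count targets are
carried for reference but type counts *emerge* from Zipfian token
sampling rather than being forced.

Two modeling choices deserve explanation:

- **MATTR is controlled analytically.** Tokens are sampled independently
  with rank-probabilities ∝ rank^(−s). Under such sampling the expected
  window TTR has the closed form Σ(1 − (1 − p)^w)/w, which is strictly
  decreasing in s, so `calibrate_sampling_exponent()` solves for the s
  that hits the timepoint's MATTR target exactly in expectation. Recovery
  tests then compare the measured battery MATTR against this closed form —
  an oracle independent of the implementation.
- **Coarticulation is a recursive carryover.** The realized spectrum of
  phone *i* is r_i = (1 − κ)·prototype_i + κ·r_{i−1} + noise. Blending
  with the preceding *realized* spectrum (articulator inertia), rather
  than the preceding prototype, was a deliberate correction: with
  independent prototypes, one-step prototype blending makes the distance
  between consecutive realized spectra non-monotone in κ (its per-band
  variance is κ² + (1 − 2κ)² + (1 − κ)², minimized at κ = 0.5), which
  would break the generator's defining property. The recursive form gives
  stationary distance variance ∝ (1 − κ)²/(1 + κ): strictly decreasing,
  and at κ = 1 with zero noise all spectra collapse, so repeated-phone
  distances are exactly 0.

The generated lexicon draws pronunciations over a reduced phoneme set (ten
consonants, five vowels including the three corners) so that words have
phonological neighbors at realistic rates; at a few hundred words, the
full 39-symbol space leaves the neighborhood graph nearly empty. Word
lengths are 1 + Poisson(2.5) segments (mean 3.5). Each (dyad, timepoint)
session derives its own RNG stream from the master seed, so corpora are
partially regenerable and byte-identical under a fixed seed.

Outcomes follow declared linear models on standardized features: NWR
accuracy on the [0, 1] proportion scale (baseline 0.65, residual SD 0.12,
values clipped with a warning if clipping exceeds 10%) and expressive
vocabulary on the MB-CDI-like scale (baseline 355.94, residual SD 110),
with maternal education, child gender and earlier vocabulary as generated
covariates. Default effect directions mirror the structure the battery is
meant to detect (negative coarticulation-distance effect on NWR; positive
type-count effect on vocabulary).

### What the generator does and does not emulate

It emulates the statistical skeleton the analysis assumes: session-level
summary scales, Zipfian lexical statistics, controllable coarticulation
and duration, and outcome models with known coefficients. It does not
emulate English phonotactics beyond the sampled lexicon, conversational
structure, child speech, or the acoustic detail of real vowel systems
(formant targets are fixed Gaussians per corner vowel). Passing recovery
tests therefore demonstrates that the pipeline measures what the generator
encodes — not that any real-corpus value would be reproduced, and the
normalized vowel-space areas of synthetic sessions are not calibrated to
any reported scale.

## Problem sizes and numerical choices

Simulation studies use shorter sessions (120-token target,
`simulation_targets()`) so hundreds of replicate corpora remain cheap,
while single-corpus analyses use the full study-scale defaults; the
acceptance script runs 84 dyads × 4 timepoints at full scale. Calibration
suites use 1,000 null replicates (type-I error), 500 replicates of 84 × 4
mixed models (variance recovery), and 200 end-to-end replicates
(coefficient sign and coverage). Degenerate inputs resolve explicitly:
empty token lists raise errors; missing acoustic measures are `NA`, never
0; zero-total biphone positions contribute probability 0; singleton
z-score strata are `NA` with a warning; sub-window sessions flag their
MATTR fallback; a MATTR target unreachable for a tiny lexicon falls back
to uniform sampling with a message.

## Known limitations

Mixed-model p-values use residual df (anti-conservative for small group
counts); spectral distances are configuration-relative; the CHAT importer
handles main tiers only; the synthetic stimulus table is a placeholder
with the right shape, not the original items; and the disentangling
classification inherits the usual caveats of sequential significance
testing at a fixed α.
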