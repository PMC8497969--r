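# cdsbattery

Acoustic-lexical profiling of child-directed speech (CDS) for research on
early language development.

When caregivers talk to infants and toddlers, both *what* they say (word
diversity, word length, word frequency, phonological neighborhood
structure) and *how* they say it (vowel-space expansion, segment duration,
coarticulation) change with the child's age — and these properties are
strongly collinear, so their individual contributions to child outcomes
such as phonological processing are hard to separate. `cdsbattery`
implements, as tested reusable R functions:

- **A lexical battery** over phone-aligned play-session transcripts:
  type/token counts, TTR, moving-average TTR over a 10-token window
  (MATTR), and per-word-type statistics against a pronouncing lexicon —
  word length in phonemes, log10 corpus frequency, phonological
  neighborhood density (number of words one phoneme edit away, per
  Vitevitch-and-Luce-style substitution/deletion/addition), and positional
  biphone phonotactic probability with length-stratified z-normalization.
  Transcript cleaning removes onomatopoeia, exclamations and proper names
  everywhere and contractions from the phono-lexical measures only.
- **An acoustic battery** of hyperarticulation measures: Lobanov-normalized
  vowel space area (shoelace area of the /i, a, u/ mean-formant triangle),
  per-type vowel dispersion from the speaker's median F1/F2, phone
  duration, and coarticulation as the Euclidean distance between
  time-averaged Mel log-magnitude spectra of adjacent phones (larger
  distance = less coarticulation), with eligibility filters (content
  words, stressed vowels, no prevocalic stops or /h/, no
  whispered/yelled/overlapping speech).
- **Nonword-repetition (NWR) scoring with an articulatory control**: a
  phoneme wrong in both the nonword and its matched real word is
  attributed to articulatory immaturity and not scored against the child;
  items refused after two prompts are fully incorrect.
- **Modeling tools**: OLS and dyad-random-intercept fits in a common
  container, pairwise timepoint contrasts with Holm adjustment, AIC /
  likelihood-ratio model comparison, median-split unnesting of per-type
  predictors, and a three-step residualization procedure (`disentangle()`)
  that classifies which member of a collinear predictor pair carries the
  direct effect on an outcome — backed by the Frisch-Waugh-Lovell identity.
- **A synthetic corpus generator** with known ground truth (Zipfian
  lexicons, phone-aligned sessions, blended-prototype spectra, declared
  outcome models), so the whole pipeline is testable without any corpus
  download.

File formats: Praat long-format TextGrids, TSV token tables and
pronouncing lexicons (IPhOD-like schema), TSV formant and NWR tables, CSV
feature tables, mono PCM WAV or precomputed Mel frames.

## Worked example

```r
library(cdsbattery)

cfg    <- generator_config(seed = 42, n_dyads = 4, timepoints = c("10-11", "24"))
corpus <- gen_corpus(cfg)
res    <- battery(corpus$sessions, corpus$lexicon)
subset(res$features, timepoint == "24",
       c(dyad_id, n_types, n_tokens, mattr, median_phone_duration_ms,
         median_coarticulation_distance))
```

```
  dyad_id n_types n_tokens     mattr median_phone_duration_ms median_coarticulation_distance
5    d001     319     1676 0.9215957                 82.59869                       5.061378
6    d002     350     2096 0.9053186                 83.44354                       5.082294
7    d003     306     1451 0.9030513                 83.95227                       5.049163
8    d004     297     1258 0.9285028                 82.81432                       5.070321
```

Each row is one caregiver session: 1,200–2,100 word tokens and ~300
distinct types in a 24-month play session, MATTR ≈ 0.91, a median phone
duration near 83 ms, and the session's median adjacent-phone spectral
distance. The disentangling procedure separates a collinear predictor
pair's contributions; on a planted direct/indirect structure
(`y` depends on `x1` only, `cor(x1, x2) = 0.7`, n = 500):

```r
sim <- disentangle_simulation(n = 500, n_reps = 50, rho = 0.7,
                              beta1 = 1, beta2 = 0, seed = 43)
sim$rates
```

```
x1_direct x2_direct      both   neither
     0.94      0.00      0.06      0.00
```

Nearly every replicate is classified `x1_direct`: the residuals of `x1`
given `x2` predict the outcome beyond `x2`, while the reverse residuals do
not (a few replicates land on `both` through chance significance of the
reverse test at the 5% level).

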