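---
title: "Methods: search-query lexical metrics as cognitive markers"
author: "searchlex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: search-query lexical metrics as cognitive markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(searchlex)
```

## The scientific question

Language production degrades early in the course of Alzheimer disease and
related dementias: vocabulary shrinks, word retrieval slows, and generative
(verbal) fluency declines before a clinical diagnosis is possible. Everyday
Internet search queries are a continuously available, ecologically valid
sample of language production in older adults. searchlex implements a
pipeline that turns raw search-engine query logs into three per-subject
lexical metrics and relates them to a composite neuropsychological z-score
with covariate-adjusted directional linear models:

* **unique terms per search** — the subject's distinct cleaned vocabulary
  divided by their number of searches, a naturalistic analogue of
  psychometric verbal fluency;
* **mean word length** — total letters over total cleaned tokens;
* **mean term obscurity** — the mean, over the subject's token instances,
  of the inverse of each term's occurrence count across *all* subjects'
  cleaned searches (a term searched once scores 1; a very common term
  approaches 0).

The working hypotheses are directional: poorer cognition predicts fewer
unique terms, shorter words, and less obscure vocabulary.

## Query cleaning

Cleaning is a three-step procedure, each step validated against a word
corpus (a plain `word<TAB>count` table; a compact curated English list with
synthetic counts is bundled, and any larger frequency corpus can be plugged
in):

1. **Normalization.** Accented Latin letters are transliterated to ASCII
   via an explicit mapping table (base R has no Unicode compatibility
   decomposition and we deliberately avoid heavier string dependencies);
   anything else outside printable ASCII is treated as unreadable and
   removed, punctuation is deleted in place (so hyphenated forms join
   rather than split), letters are lowercased, and whitespace runs become
   single token separators.
2. **Spell correction.** A token found in the corpus (or purely numeric)
   passes through. Otherwise candidates are generated in three tiers tried
   strictly in order — single-letter deletions, adjacent transpositions,
   single-letter insertions — and the first tier containing any in-corpus
   candidate supplies the correction; the candidate with the highest corpus
   frequency wins, ties broken lexicographically so the result is
   deterministic. If no tier hits, the token is left as is. Letter
   *substitutions* are intentionally not generated; the corrector is
   deliberately minimal so that its behaviour is fully enumerable, and the
   test suite checks it against an exhaustive brute-force oracle.
3. **Lemmatization.** Ordered suffix rules (`ies>y`, `es>`, `s>`, `ing>`,
   `ing>e`, `ed>`, `ed>e`, `ves>f`) are applied and the first candidate
   root that is itself a corpus word is returned; otherwise the token is
   unchanged. Single-character roots are rejected. Corpus validation is
   what keeps the rule table honest: "wolves" reduces to "wolf", while
   "dies" reduces to "die" (a dictionary-validated rule table does not
   reproduce the "dy"-type artifacts of suffix-only stemmers).

Cleaning is idempotent: corrected tokens are corpus words, corpus words are
fixed points of correction, and lemmas are validated, so cleaning cleaned
text is a no-op (a property test enforces this).

Searches whose queries clean to zero tokens are retained and flagged; they
count as searches in per-subject denominators but contribute no tokens.

## Windowing and attrition

Only queries from the four major general-purpose engines (Google, Bing,
Yahoo, Ask.com; label matching is canonicalized over case, scheme, paths
and common domain variants) are search queries in the intended sense —
site-internal searches are excluded. Records are then restricted to ±91
calendar days (a configurable "3 months", inclusive bounds, time of day
ignored) around each subject's neuropsychological evaluation; subjects with
no surviving records are flagged excluded. The pipeline manifest counts
records and subjects at every stage so attrition reconciles exactly.

## Composite cognitive z-score

Raw scores from a battery spanning five domains (working memory,
attention/processing speed, memory, executive function, visuospatial) are
z-normalized against reference norms — mean and SD of each test in a
cognitively intact cohort — with a per-test direction flag so that timed
tests (Trail Making A/B), where larger raw scores are worse, contribute
sign-flipped z-scores. The composite is the unweighted mean over available
tests (default) or the mean of domain means (option; the two readings of
"averaged within five domains" are both defensible, so both are exposed).
Missing tests are skipped and counted. The bundled norms table is labelled
synthetic: real analyses must norm on their own intact reference cohort.

## The directional models

Each lexical metric enters its own ordinary least squares model of the
composite z, adjusted for age, sex (female = 1) and years of education:

z_i = b0 + b_age age_i + b_sex female_i + b_edu edu_i + b_m metric_i + e_i

`lexical_lm()` reports the metric's **one-sided** p-value (the direction is
hypothesized before fitting: half the two-sided p when the estimate has the
hypothesized sign, else one minus half), two-sided p-values for covariates,
R², and variance inflation factors computed from auxiliary regressions
(VIF_j = 1/(1 − R²_j)), flagging any value at or above 2.5. Rank-deficient
designs are refused with the collinear columns named; perfect collinearity
in the VIF computation reports `Inf`. No multiple-testing correction is
applied across the three models, and the report says so. The
`extreme_contrast()` helper converts a coefficient into the predicted
outcome difference between the subjects at the extremes of the metric,
`b × (x_max − x_min)`.

## The synthetic cohort generator

No raw data from the motivating study design are publicly deposited, so
validation runs against a synthetic generator whose defaults *are* the
published study conditions; they are fixed once, not tuned per run:

* **Covariates.** Age is truncated-normal with post-truncation mean 81.1
  and SD 10.5, floor 62 (the underlying parameters are solved numerically
  so the *post-truncation* moments match); sex is Bernoulli with
  35/42 female; education is rounded normal 15.5 (2.0).
* **Search volume.** Per-subject counts are lognormal with median 22. The
  printed interquartile range (7.3) is arithmetically incompatible with
  the printed range (1–718) and total (2915 searches by 42 subjects), so
  the generator matches the median and the implied mean 2915/42 instead,
  giving sigma = sqrt(2 log(mean/median)) ≈ 1.52 — a heavy right tail, as
  observed.
* **Searches.** Word counts per search are 1 + Poisson(2.08), capped at
  22, matching mean 3.08.
* **Vocabulary.** 12,000 pseudo-words with Zipf(0.9) base weights; word
  lengths are drawn from a rounded truncated normal with mean 5.77 and SD
  2.23. Final letters avoid s/d/g so no lemmatizer suffix rule can fire on
  a pristine base word, which makes cleaning exactly idempotent on
  synthetic text by construction. The generator emits its own corpus, so
  the cleaning stage is exercised with a consistent dictionary.
* **Per-subject metric targets.** Obscurity targets follow a scaled Beta
  with mean 0.25, SD 0.11 on [0.044, 0.52], rank-correlated −0.23 with
  log search volume (prolific searchers inflate the frequency table with
  their own words, so their obscurity runs low). Unique-terms targets
  follow a scaled Beta on [0.5, 3.1] whose *mean is implied by the
  intercept identity*: given the Model-1 coefficients and the covariate
  means, a cohort z-mean of 0.16 pins the metric mean at about 2.27 —
  inside the printed range, and the one choice that makes the published
  intercept, covariate means and cohort z-mean mutually consistent.
* **Cognition.** Metrics are drawn first and the composite is generated
  conditionally, z = Xb + N(0, sigma), with sigma solved per cohort from
  the target R² via the expectation identity
  E[R²] ≈ 1 − sigma²(n−p−1) / ((n−1)(s_f² + sigma²)), where s_f² is the
  realized variance of the true linear predictor. Targeting the *sample*
  R² at n = 42 rather than the population value corrects the upward
  small-sample bias of R² (about +0.05 at these sizes); with it, the
  published coefficient SEs (0.13 for unique terms, 0.68 for obscurity)
  and the cohort z SD (≈0.56) all emerge without further tuning. Raw test
  scores consistent with each subject's composite are emitted with
  centered per-test scatter, so the cognition module recomputes the
  composite exactly (up to 2-decimal score rounding).
* **Token realization and calibration.** Each subject draws tokens from
  the Zipfian vocabulary with two knobs: a rank-bias temperature (flattens
  or sharpens the exponent; rarer words at higher temperature) and a
  repeat probability (each token after the first repeats an earlier own
  token with probability rho). Fresh draws sample the subject's word set
  *without replacement* (a desired rank already used probes to the next
  free rank, path-compressed), so the distinct vocabulary equals the
  number of fresh slots and the unique-terms metric is directly and
  monotonically controlled by rho, independently of the temperature. All
  randomness is pre-drawn per subject, making each knob's response
  deterministic and monotone — the precondition for bisection. Calibration
  runs in two sweeps over subjects: rho first (tolerance 0.1 on
  unique terms), then temperature against a self-consistent objective
  (others' counts plus the candidate tokens' own multiplicities;
  tolerance 0.025 on obscurity), updating the running cohort table after
  each subject. Unreachable targets settle at the knob boundary and are
  flagged; the metric response is a step function for very small subjects,
  so a converged flag is also recorded per knob.
* **Corruption.** A final pass injects single-letter typos (5%, the three
  recoverable kinds), inflectional suffixes (12%), accented vowels (2%),
  stray punctuation (8%), capitalization (20%) and occasional numeric
  tokens (1%), recording pristine truth. With all rates zero the cleaned
  pipeline reproduces the pristine tokens byte-for-byte; at default rates
  about 99% of tokens are restored. Non-major-engine rows and
  outside-window rows are added so the ingest filters have real work.
* A mild topic structure (12 interleaved rank-bands; half the searches
  draw from the subject's band) gives the co-occurrence graph non-trivial
  communities; its parameters are arbitrary defaults.

### What the generator does and does not emulate

It reproduces the published marginal distributions, the effect structure,
and the text-level corruption processes the cleaning stage must undo. It
does **not** emulate query semantics, autofill artifacts, engine ranking,
session structure, or real word-frequency profiles (pseudo-words have no
meaning), so passing tests demonstrate the pipeline's correctness and the
estimator's statistical behaviour under the stated conditions — not
performance on real search histories. One structural tension is accepted
and flagged rather than hidden: a prolific searcher with a very low
obscurity target may need hundreds of distinct words that are all
cohort-common, which the fixed cohort token mass cannot supply; those
subjects clamp at the temperature floor, leaving the realized cohort mean
obscurity roughly 8–11% above 0.25 (well inside the ±20% acceptance band
for that quantity, and documented in the truth table via clamp flags).

## Problem sizes and numerical choices

The validation studies run at the sizes the package documents as its own
choices: 20 seeded default cohorts of n = 42 for the descriptive
calibration checks, and 500 replicate cohorts per effect configuration for
parameter recovery (about 90 seconds end to end on one core). Replicates
whose design is degenerate (for example, an all-female cohort, probability
≈ 0.05% each) are skipped and counted. Bisection runs at most 40 iterations
per knob; spell-correction tie-breaks are frequency-then-lexicographic;
the OLS path is `stats::lm` with the normal-equation solution reserved for
the test oracle; VIF auxiliary regressions use `stats::lm.fit`. Seeds: the
log-generation stream is derived from the cohort seed by a fixed LCG step
so cohort and text layers are independently reproducible; every public
entry point is deterministic given its seed.

## Known limitations

* The obscurity measure is self-referential (the analyzed cohort defines
  the frequency table); an external table can be supplied to
  `subject_profiles()` to break the circularity.
* The literal reading of "unique terms per search" (tokens over searches)
  contradicts the word "unique" and cannot fall below 1, whereas observed
  minima do; the default is distinct vocabulary over searches, with the
  literal variant available via `unique_terms_mode = "tokens"`.
* The printed IQR of search counts is ignored as internally inconsistent
  (see above); the median and total are matched instead.
* The spell corrector is intentionally minimal (no substitutions, no
  context); the lemmatizer's rule table is small. Both are pluggable via
  the corpus and rule-table arguments.
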