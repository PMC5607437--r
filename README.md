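# searchlex

Lexical analysis of everyday Internet search queries as a marker of
cognitive function in older adults.

## The problem

Language production declines early in Alzheimer disease and related
dementias — vocabulary narrows and generative fluency drops years before a
clinical diagnosis. Search-engine queries typed during routine computer use
are a continuously available, ecologically valid sample of language
production. searchlex is for researchers with (a) timestamped per-subject
query logs, (b) a clinical table with raw neuropsychological test scores,
and (c) reference norms from a cognitively intact cohort, who want to test
whether simple lexical properties of a person's searches track their
cognitive state.

## What it computes

For each subject, after restricting to the four major search engines and a
±91-day window around the cognitive evaluation, queries are cleaned in
three corpus-validated steps (ASCII normalization, tiered spell correction
by deletions → adjacent transpositions → insertions, suffix lemmatization
with dictionary validation), and three metrics are derived:

* **unique terms per search** `u_i = |distinct vocabulary_i| / n_searches_i`
* **mean word length** `l_i = total letters_i / total tokens_i`
* **mean term obscurity** `o_i = mean over token instances of 1 / f(t)`,
  where `f(t)` is the term's count across *all* subjects' cleaned tokens.

Cognition is summarized as a composite z-score: each raw test score is
z-normalized against intact-cohort norms (timed tests sign-flipped) and
averaged across a five-domain battery. Each metric `m` then enters its own
directional ordinary least squares model

```
z_i = b0 + b_age age_i + b_sex female_i + b_edu education_i + b_m m_i + e_i
```

with a one-sided p-value for `b_m` (direction hypothesized in advance),
variance-inflation diagnostics (flag at VIF ≥ 2.5), and extreme-contrast
predictions `b_m (m_max − m_min)`. A term co-occurrence network (nodes =
terms, edges weighted by co-search counts, optional hub exclusion) can be
exported as TSV + GEXF for external visualization. A calibrated synthetic
cohort generator reproduces the published study conditions with full ground
truth, so every stage is testable end to end.

## Worked example

```r
library(searchlex)

corpus <- default_corpus()
clean_query("Where are cooking classes in Portland?", corpus)$tokens
#> [1] "where"    "are"      "cook"     "class"    "in"       "portland"

# a fully synthetic study with known truth
study    <- simulate_study(generator_config(seed = 1))
records  <- window_to_evaluation(filter_engine(study$records), study$clinical)
cleaned  <- clean_searches(records, study$corpus)
cleaned
#> <cleaned_searches> 1901 searches, 5883 tokens, 42 subjects; 380 tokens spell-corrected

tab      <- term_frequency_table(cleaned)
profiles <- subject_profiles(cleaned, tab)
print(cohort_descriptives(profiles, cleaned, tab), digits = 2)
#> Cohort descriptives (42 subjects, 1901 searches, 5883 tokens)
#>   Number of searches, median (IQR): 14 (15.75)   range 1-521
#>   Words per search,   mean (SD):    3.09 (1.42)   range 1-9
#>   Letters per word,   mean (SD):    5.83 (2.12)   range 2-14
#>   Word obscurity,     mean (SD):    0.3 (0.11)   range 0.11-0.5

composites <- composite_scores(study$clinical, study$norms)
d <- merge(profiles, composites, by = "subject_id")
d <- merge(d, study$clinical[c("subject_id", "age", "sex", "education")],
           by = "subject_id")
d$female <- as.integer(d$sex == "female")

fit <- lexical_lm(cognitive_z ~ age + female + education + unique_terms_per_search,
                  d, metric = "unique_terms_per_search")
summary(fit)
#> Directional lexical model: cognitive_z ~ age + female + education + unique_terms_per_search
#>                         estimate       se   p_value     sided
#> (Intercept)              1.74500 0.741600 0.0240800 two-sided
#> age                     -0.02429 0.006228 0.0003904 two-sided
#> female                   0.34630 0.162500 0.0397200 two-sided
#> education               -0.06665 0.030500 0.0352900 two-sided
#> unique_terms_per_search  0.54610 0.126400 0.0000561 one-sided
#> n = 42, R-squared = 0.565 (adj. 0.518)
#> VIF: age 1.16, female 1.13, education 1.03, unique_terms_per_search 1.06

extreme_contrast(fit)
#> [1] 1.003782
```

Reading the output: each additional distinct term per search predicts about
half a point more composite cognitive z in this synthetic cohort (the
generating coefficient is 0.39; a single n = 42 cohort estimates it with
SE ≈ 0.13), older age predicts lower cognition, collinearity is negligible
(all VIF < 2.5), and the subject with the richest search vocabulary is
predicted to score about 1.0 z-points above the subject with the poorest.

`lexical_models(d, ...)` fits all three metric models at once and prints a
staircase comparison table; `run_pipeline(pipeline_config(simulate = TRUE,
seed = 1), "out/")` executes everything — ingest through network export —
and writes an attrition manifest. On real data, point `pipeline_config()`
at your log/clinical/norms/corpus files instead.

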