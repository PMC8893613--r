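---
title: "Methods: phrase mining, prevalence intervals and Bayes-factor trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phrase mining, prevalence intervals and Bayes-factor trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(almostsig)
```

`almostsig` measures the use of "almost significant" phrasing in clinical
trial reports: fixed expressions used to describe results whose *P* value
approaches but exceeds the conventional 0.05 threshold. This vignette
documents the statistical model behind each stage, the tunable parameters
and their defaults, the numerical choices, and what the synthetic
evaluation corpus does and does not establish.

## Text normalization

All matching operates on normalized text. `normalize_text()` applies, in
order: lowercasing; Unicode canonical decomposition (NFD) followed by
removal of combining diacritical marks; mapping of the curly quote
variants U+2018–U+201F to ASCII quotes and of en/em dashes and the Unicode
minus (U+2013, U+2014, U+2212) to a plain hyphen; collapse of every
whitespace run (including newlines and non-breaking spaces) to a single
space. The function is total and idempotent, which the test suite asserts
on fuzzed Unicode input.

Two deliberate boundaries of this dialect:

* The multiplication sign U+00D7 is **kept**, because the *P*-value
  grammar must recognize mantissa–power-of-ten tokens such as
  `1.2 × 10-3`.
* De-hyphenation of line-broken words is **not** attempted. Converter
  output from PDF extraction does break words across lines, but silently
  joining hyphenated fragments risks manufacturing phrase matches that are
  not in the text; we prefer a conservative miss over a fabricated hit.

The corpus readers apply a publication time-frame filter of January 1990
through September 2020. Records that carry a month are filtered at month
resolution; records without a month are kept whenever 1990 ≤ year ≤ 2020.
Month metadata is frequently absent in bibliographic exports, and
year-level retention keeps the filter predictable; the read/kept/dropped
counts are always reported so the effect of the filter is visible.
Duplicate record identifiers are an error, not a silent deduplication.

## Dictionary matching

Matching is plain exact substring search over the normalized text — the
behaviour of `grep` over cleaned text — with no word-boundary requirement
by default. A `word_boundary = TRUE` variant exists for sensitivity
analysis; it is strictly more conservative. No fuzzy or elastic matching
is offered: elastic matching can silently cross a negation and change the
meaning of a match.

Three policies required a decision where reasonable people could differ:

* **All occurrences are reported**, including repeated occurrences of the
  same phrase in one document and overlapping occurrences of different
  phrases. Document-level statistics use "at least one occurrence";
  hit-level statistics keep every occurrence. This preserves the
  distinction between phrase-positive documents and total phrase hits.
* **Nested phrases**: when a hit's span is strictly contained in the span
  of a longer phrase's hit ("marginally significant" inside "only
  marginally significant"), the shorter hit is annotated `subsumed_by`.
  Per-phrase document counts are emitted in both variants — counting all
  hits (`docs_all`) and excluding subsumed hits (`docs_unsubsumed`) —
  because there is no single right answer to whether a nested occurrence
  should count for the inner phrase.
* **Self-overlapping occurrences** of a single phrase are counted
  (overlap-aware search). Real dictionary phrases contain spaces and
  cannot overlap themselves, so this only matters for the scanner's
  equivalence with a brute-force all-substrings oracle, which the test
  suite checks on hundreds of randomized corpora.

The shipped dictionary has exactly 505 entries and is a **synthetic
stand-in**: the published phrase list is not redistributable in full, so
the file contains the 56 phrases printed with their corpus frequencies
plus template-generated variants from the same linguistic families
("a … trend", "… significant", "failed to reach …", "on the verge of …").
Every entry is a fixed point of `normalize_text()`; duplicates in a
dictionary file are collapsed with a warning.

## P-value extraction

For each phrase hit we examine the window of `width = 100` characters
directly following the phrase (clipped at the document end) and take the
**first** token matching the grammar

```
["("] "p" ["value"|"values"] (= | < | > | <= | >= | ≤ | ≥) number
```

where `number` is a plain decimal (`0.052`, `.06`), e-notation (`3e-4`)
or a mantissa–power-of-ten form (`1.2 × 10-3`, `1.2 x 10^-3`). Two
precision-over-recall guards mimic careful human extraction: the `p` must
not be immediately preceded by an alphanumeric character (so `bp = 0.3`
is not a *P* value), and parsed numbers above 1 (percentages, ratios) are
rejected with the scan continuing at the next token. Only the first
accepted token per window counts — the analysis models "the" directly
referred *P* value, singular; later tokens in the window are ignored.
Long-range referrals (tables, figures, earlier sentences) are out of
scope by design.

For inequality tokens such as `p < 0.06` the numeric literal 0.06 is used
for categorization and the comparator is retained in the output for
auditing. Categories use closed mid-band boundaries: below when
value < 0.05, mid when 0.05 ≤ value ≤ 0.15, above when value > 0.15; both
boundary values belong to the mid band because the band is described as
"between 0.05 and 0.15" while the lower band is strictly "< 0.05".

Summary quantiles use linear interpolation between order statistics
(R's default type 7), pinned so that summaries are reproducible across
implementations. `format_pvalue()` is the canonical inverse printer; the
suite fuzzes print-then-parse round trips over the grammar (10,000 cases)
and requires exact recovery to printed precision (3 significant digits).

## Prevalence and confidence intervals

Documents are binned by publication year, anchored at 1990: yearly bins
for the overall series (31 bins), 3-year bins for per-phrase series
(1990–92 … 2017–19, plus a terminal partial bin holding 2020 alone). The
final collection year is incomplete in the emulated design (collection
stopped in September), so the 2020 partial bin is **excluded from trend
fitting by default** (`include_partial_bin = TRUE` restores it). Bins
with zero documents are dropped and counted; bins with documents but zero
hits contribute a prevalence of 0 — a 0/0 bin carries no information
while a 0/n bin does.

The 95% interval for a binned proportion is the continuity-corrected
Wilson score interval (Newcombe's closed form), the interval that solves
|p̂ − p| − 1/(2n) = z√(p(1−p)/n) for each endpoint, clipped to [0, 1]
with L = 0 at x = 0 and U = 1 at x = n. The critical value is pinned at
z = 1.959964 for bit-stable output. The test suite checks the closed form
against an independent numerical inversion of the defining equation at
tolerance 1e-9, against the base-R continuity-corrected proportion test
at corpus scale, and for 93–97% empirical coverage over 2,000 binomial
replicates at n = 5,000, p = 0.0865 (the correction makes the interval
slightly conservative). Exact Clopper–Pearson and Bayesian intervals are
deliberately out of scope.

## Bayes-factor trend scoring

Evidence for temporal change in a phrase's binned prevalence series is
the JZS Bayes factor comparing the one-covariate linear regression
against the intercept-only model:

$$\mathrm{BF}_{10} \;=\; \int_0^\infty (1+g)^{(n-2)/2}\,
  \bigl(1 + g(1-R^2)\bigr)^{-(n-1)/2}\, \pi(g)\, dg,$$

with $\pi(g)$ the inverse-gamma(1/2, $n r^2/2$) density — the
mixture-of-g representation of the Zellner–Siow Cauchy prior on the
standardized slope. The default prior scale is the conventional "medium"
r = √2/4. The data enter only through n and R², so the Bayes factor is
invariant to affine rescaling of time and to shifting the response, which
the suite asserts numerically.

Numerical evaluation: the integrand is computed in log space and the
integral is taken after the substitution v = g/(c+g) with the scale
c = s + nR²/(1−R²) + 1 matched to where the mass of the integrand sits
(prior scale plus likelihood peak). This keeps the transformed peak
interior for any R², so adaptive quadrature (relative tolerance 1e-8,
with max-subtraction before exponentiating) is stable from R² = 0 up to
1 − 10⁻¹²; at R² ≥ 1 − 10⁻¹⁵ the integral is reported as infinite, which
is its true limit. Correctness is established by two independent oracles
— a fine trapezoid grid on the transformed axis and a stratified
Monte-Carlo average over the inverse-gamma mixing distribution — agreeing
to three significant digits across n ∈ {5, 10, 31} and
R² ∈ {0, 0.3, 0.6, 0.9, 0.99}.

Series enter the trend fit as unweighted per-bin prevalence point
estimates against bin midpoint years. Weighting bins by inverse variance
is a defensible alternative; the unweighted fit matches how temporal
prevalence data are conventionally modeled and keeps the Bayes factor a
function of (n, R²) alone. Phrases need at least `min_timepoints = 5`
nonzero-denominator bins to be evaluated; with 3-year bins over 1990–2019
a fully observed phrase has 10 time points. Evidence bands are
≤ 3.2 (bare mention), 3.2–10 (substantial), 10–100 (strong), > 100
(decisive), with each band closed at its upper bound — the source
taxonomy is silent about ties, so the boundary convention is pinned here.
The reported trend table suppresses Bayes factors below 2.0 in its report
variant while the full table retains every phrase.

An OLS fit (slope, intercept, R², ±1.959964 standard errors of the mean
response) accompanies each Bayes factor for display; when the response is
constant the total sum of squares is zero and R² is defined as 0.

## The synthetic corpus generator

`generate_corpus()` produces corpora with the statistical structure the
analysis assumes, plus exact ground truth:

* **Occurrence model.** Each configured phrase is inserted into a
  document of year $t$ with probability
  $\pi(t) = \mathrm{logistic}(\mathrm{logit}(\pi_0) + \beta\,(t - t_{mid}))$,
  at most once per (document, phrase) pair, at a uniformly chosen word
  gap. Anchoring $\pi_0$ at the midpoint year keeps the baseline
  interpretable independently of the slope.
* **Direct referrals.** With probability `referral_prob = 0.41` an
  inserted phrase is immediately followed by a formatted *P* token. The
  ground truth records the parsed value of the printed token, so
  bookkeeping is exact to printed precision.
* **P-value mixture.** Bands below/mid/above are drawn with weights
  0.25 / 0.68 / 0.07. Within bands: below is 0.001 + 0.049·Beta(0.7, 1)
  (so that about a fifth of below-band draws fall under 0.006), mid is
  0.05 + 0.1·Beta(0.806, 3.07), calibrated so the **overall** mixture has
  median ≈ 0.06 and 75th percentile ≈ 0.08, and above is
  0.15 + 0.35·Beta(0.5, 3), concentrated near 0.15 so the overall 95th
  percentile sits at ≈ 0.15. These reproduce the published quantile
  structure of extracted *P* values without claiming knowledge of the
  unobserved density.
* **Filler specificity.** Filler text is sampled from a fixed clinical
  vocabulary screened so that no dictionary-phrase word of four or more
  characters occurs as a substring of any filler word. Every dictionary
  phrase contains at least one such word, and phrases cross word
  boundaries only through literal spaces, so filler-only text provably
  contains no phrase; the screen runs at generation time (it is checked,
  not assumed) and a property test scans a filler-only corpus against all
  505 phrases expecting zero hits.
* **Determinism.** All randomness flows from the single config seed;
  identical seeds give byte-identical corpora.

What the generator does **not** emulate: linguistically realistic prose,
document length variation, hyphenation and layout artifacts of PDF
conversion, correlation between phrases within a document, publication
bias. Passing tests on synthetic corpora therefore establish the
correctness of the pipeline's logic and calibration of its statistics
under the assumed generating model — not robustness to the messiness of
real converted full texts.

## Evaluation scales

The simulation studies in the test suite use sizes chosen to make
binomial tolerances tight while keeping the default run practical:
prevalence-tracking checks use 2,000 documents per year; extraction-rate
recovery uses about 10,000 inserted phrases; the mixture calibration
check uses 10,000 draws with 3-standard-deviation binomial tolerances;
interval coverage uses 2,000 replicates at n = 5,000. The trend-recovery
study injects a threefold rise in occurrence (0.001 → 0.003 over
1990–2019, i.e. β ≈ 0.038 per year on the log-odds scale) at 20,000
documents per year and requires a decisive Bayes factor in at least 90%
of 50 seeded replicates, with a constant companion phrase exceeding the
substantial threshold in at most 10%; a direct binomial-level power
computation for this design gives ≈ 96% decisive and ≈ 2% null
exceedance, so the requirement is attainable but not slack. Filler length
is reduced to 8–12 words per document in the large simulations; filler
length does not enter any statistic.

## Known limitations

* Exact matching underestimates prevalence: paraphrases and unlisted
  variants are invisible, and the no-de-hyphenation policy loses matches
  broken across lines.
* The shipped dictionary is a synthetic stand-in (see above); analyses of
  real corpora should substitute the full published list via
  `load_dictionary(path)`.
* Comparator-only tokens ("p < 0.06") contribute their numeric literal,
  which overstates precision for inequalities; the comparator column
  preserves the information needed to reanalyze.
* The Bayes factor model treats binned prevalence as homoscedastic
  Gaussian; bins differ in denominator, and a weighted or binomial
  observation model would be a natural extension.
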