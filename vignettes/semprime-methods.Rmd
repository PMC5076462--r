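---
title: "Distributional similarity and lexical priming: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributional similarity and lexical priming: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semprime)
```

# What the package models

`semprime` implements the complete computational apparatus of an
item-level lexical priming study driven by distributional semantics: it
builds LSA-type and HAL-type semantic spaces from a tokenized corpus,
generates prime–target stimulus material stratified by cosine
similarity, simulates lexical-decision reaction times from a crossed
random-effects generative model, and fits the mixed-effects analyses
that test whether cosine similarity predicts priming.

The scientific question behind this machinery: if word pairs are
*constructed* so that their distributional similarity is uniformly
spread over $[0,1]$ — rather than selected post hoc from pairs already
known to prime — does higher cosine similarity predict faster lexical
decisions on the target?

# Semantic spaces

Two count models share one weighting and reduction pipeline.

* **LSA-type**: a word × document matrix; cell $(w,d)$ counts tokens of
  $w$ in document $d$. Captures syntagmatic/associative structure.
* **HAL-type**: a symmetric word × word matrix; two *content* words
  co-occur when they fall within a window of `window` content words
  (default 3, each side) inside one sentence. Counts are flat
  (unweighted by distance), pairs never cross sentence boundaries, and
  the diagonal is held at zero. Captures paradigmatic/semantic
  structure.

Raw counts are weighted by positive pointwise mutual information,
$\max(0, \log \frac{n_{wc}\,N}{n_{w\cdot}\,n_{\cdot c}})$, with natural
log and marginals taken from the vocabulary-restricted count matrix
itself. The weighted matrix is reduced by truncated SVD; word vectors
are $U_k \Sigma_k$, which preserves the row geometry (hence all row
cosines) of the weighted matrix at full rank. The alternative
conventions ($U_k$ alone, or row-normalized vectors) rescale rows and
are *not* cosine-faithful at full rank; reference toolchains rarely
document their convention, so we chose the one with the defensible
invariant and verify that invariant in the test suite.
Component signs are fixed deterministically (largest loading positive)
so spaces are reproducible bit-for-bit.

Word similarity is the cosine of the angle between vectors. Negative
cosines are clamped to zero wherever similarity classes are involved;
this generalizes the clamping rule reference analyses apply to noisy
small-corpus spaces, and makes every class interval a subset
of $[0,1]$.

Other conventions worth stating: tokens are case-sensitive and not
lemmatized; vocabulary rank ties break lexicographically; the window is
symmetric (the directionally ambiguous phrase "a window of three
content words" is resolved as ±3); content-word status comes from the
corpus annotation, not a built-in stopword list.

# Stimulus generation

The pseudo-random item algorithm stratifies cosine similarity into ten
contiguous classes ($[0,0.09), [0.09,0.18), \ldots, [0.81,1]$; the
half-open convention resolves the overlapping printed endpoints, with
the last class closed so 1 belongs to a class):

1. draw a pool of 300 eligible words (concrete nouns, length 4–9,
   frequency class 10–15); split it randomly into 200 targets and 100
   nonword-trial primes;
2. assign targets to classes as equally as possible (20 per class);
3. for each target, sample a prime uniformly from the words whose
   clamped cosine lies in the target's class and which satisfy the
   prime constraints (concrete noun, length 4–10, frequency class
   9–16), excluding words already used;
4. if no candidate exists, re-assign the target uniformly to another
   class (with replacement over classes; budget 20 attempts per
   target) and retry;
5. generate 100 nonword targets as consonant/vowel-pattern shuffles of
   sampled target words — a deliberate, declared stand-in for
   phonotactic generators: lengths match the reference distribution by
   construction, but the strings make no claim to language-specific
   phonotactics;
6. verify matching: t-tests that nonword and word targets do not differ
   in length and that word- and nonword-trial primes do not differ in
   length or frequency; Pearson checks that cosine is uncorrelated with
   length and frequency covariates. The checks are diagnostic by
   default; `generate_matched_item_set()` adds a bounded
   regenerate-until-pass loop for callers who need a certified set,
   since the reference design reports the property without stating its
   mechanism.

Frequency classes follow the Leipzig convention,
$\mathrm{round}(\log_2 f_{\max}/f_w)$. Blocks are assembled as a random
partition (4 blocks of 50 word + 25 nonword trials) and block order is
balanced over participants by a cyclic Latin square; trial order within
blocks is randomized per participant at simulation time. SOA (1000 ms)
and timeout (3000 ms) ride along as schedule metadata only — no
stimulus presentation is implemented.

# The synthetic corpus generator

No raw reaction times or corpus-scale spaces are available to rebuild
the original study, so the package carries a first-class synthetic data
module. Its job is to emulate exactly the statistical features the rest
of the pipeline consumes.

**Lexicon.** `vocab_size` content words (default 1200) with Zipfian
frequencies (exponent 1) scaled to the corpus token budget, plus 25
high-frequency function words that carry the head of the frequency
distribution. Frequency classes are computed from the frequencies; with
the default budget the eligible constraint ranges (classes 9–16) are
populated by several hundred words each. At desk scale the uppermost
classes (13–16) correspond to below-one expected token counts and are
sparse or absent; the constraint machinery treats the ranges as bounds,
not as required occupancy.

**Corpus.** Content words sit on a ring of `n_categories` latent
micro-categories (default 400, i.e. three words per category, assigned
round-robin over frequency rank so each category spans the frequency
range). Each document samples one category uniformly and, with
probability `mix_prob`, a second category at a geometrically decaying
ring distance (`mix_decay`, default 0.95); content tokens are drawn
frequency-proportionally from the document's categories, interleaved
with function words. Ring distance therefore translates into a smooth
co-occurrence gradient, and the derived spaces produce cosines covering
all ten similarity classes. A fraction of within-category word pairs is
designated near-synonymous; partners substitute for each other in half
of their token slots, so they share context profiles exactly and land
in the top band.

The defaults (4000 documents × 8 sentences × 12 tokens ≈ 384k tokens)
were chosen once so that eligible medium-frequency words carry enough
occurrences (roughly 20–50) for stable vectors; the default reduction
for these desk-scale spaces is $k = 12$. The reference study setting — $k = 300$ over a 100,000-word vocabulary from a
~880-million-token corpus — is honored by the builder (any `k` up to
the matrix rank) and exercised in the conformance tests; a
300-dimension space over a 1200-word desk-scale vocabulary would keep
mostly sampling noise beyond the ~hundred genuine latent directions,
which dilutes cosines toward zero and empties the upper similarity
bands. Latent dimensionality should scale with the data, and these
defaults do.

What the generator does **not** emulate: real word-frequency
covariance with length and concreteness, German morphology and
phonotactics, topical burstiness, or any semantics beyond the ring
geometry. Passing tests on synthetic data therefore certify the
pipeline's *mechanics and calibration*, not conclusions about any
natural language.

**Reaction times.** Word-trial log RTs follow
$$\log RT_{ij} = \beta_0 + \beta_{cos}\,cos_i + \beta_{lT}\,lenT_i +
\beta_{fT}\,fcT_i + \beta_{lP}\,lenP_i + \beta_{fP}\,fcP_i +
S_j^\top(1, cos_i, lenT_i, fcT_i) + I_i + \varepsilon_{ij}$$
with $S_j \sim MVN(0, \Sigma_S)$, $I_i \sim N(0,\sigma_I^2)$,
$\varepsilon \sim N(0,\sigma_\varepsilon^2)$, covariates uncentered.
Defaults: $\beta_{cos} = -0.05$ (within the range of reported
estimates), error rate 1.7%, RT-outlier rate 0.4% (uniform on
1501–3000 ms, emulating timeout-range responses; the generator does not
produce sub-100 ms anticipations), $\beta_0$ set so median RT ≈ 600 ms
(no mean RTs are reported to match), subject counts 44/43. The true
variance components of the original data are unrecoverable; the
defaults are declared, not fitted: intercept SD 0.10, cosine slope SD
0.02, covariate slope SDs 0.003, item SD 0.04, residual SD 0.15,
uncorrelated by default (the fitted models still estimate a full
covariance). Nonword trials share $\beta_0$, the subject and item
intercepts and the residual, but carry no covariate effects — they are
excluded by the analysis anyway.

# Analysis

Preprocessing applies, in order: word trials only; subjects then items
with word-trial error rates > 25% removed; error trials removed; RTs
outside $[100, 1500]$ ms removed (bounds exclusive as stated — "under
100 ms or over 1500 ms" — so 100 and 1500 survive; the percentage is
reported on the post-error-exclusion base); natural-log RTs appended.

The baseline model, in lme4 notation:

```
log_rt ~ length_target + freq_class_target + length_prime + freq_class_prime
         + (cosine + length_target + freq_class_target | subject) + (1 | item)
```

The by-subject *random* cosine slope is present in the baseline, before
any cosine *fixed* effect is tested — the maximal-random-effects
discipline. The cosine model adds the fixed effect; both are fitted by
maximum likelihood (not REML) so the likelihood-ratio test
$\chi^2 = 2\Delta\log L$ on one degree of freedom is valid. Wald
intervals use $\hat\beta \mp 1.959964\,SE$ at the 0.95 level. AIC is
$2k - 2\log L$ with $k$ counting fixed effects, free covariance
parameters and the residual variance. The pooled analysis concatenates
both experiments (disjoint subjects) and replaces the item intercept
with crossed random intercepts for primes and for targets — the same
targets recur across experiments with different primes — while keeping
the by-subject slopes and adding no by-target slopes; its cosine model
has $k = 6 + 10 + 2 + 1 = 19$ parameters.

Numerical choices. `fit_lmem()` standardizes covariates internally
before optimization and back-transforms estimates, their covariance and
the random-effect covariances to the original scale. Because the
random parts use full unstructured covariances, standardization is an
exact affine reparameterization — the maximized likelihood, $k$ and AIC
are invariant — but it conditions the profiled deviance far better on
these raw scales (lengths 4–10, frequency classes 9–16) and roughly
halves fit time. Boundary (singular) fits are expected under the
generative defaults (small slope SDs, zero correlations) and are
flagged rather than "fixed"; an optional fallback refits with diagonal
covariance on the raw scale for callers who want it. Replication loops
use a mildly loosened optimizer stopping tolerance (`opt_tol = 1e-4`),
which leaves estimates and standard errors unchanged to ~1e-4 while
cutting fit time roughly in half; warm starting values (`theta()`) are
supported but are not used for calibration, because restarting at a
boundary estimate can stall the optimizer. The LRT clamps $\chi^2$ at zero; two identical
fits give $\chi^2 = 0$, $p = 1$.

# Calibration, problem sizes and limitations

The test suite verifies, among other properties: exact agreement of
count and PPMI matrices with brute-force oracles; cosine preservation
at full rank ($10^{-6}$); the design counts (200 pairs, 20 per class,
100 nonwords, 4 × (50 + 25) blocks); type-I error of the cosine LRT in
$[0.03, 0.07]$ over 500 null replications at 20 subjects × 100 items;
mean $\hat\beta_{cos}$ within 2 Monte-Carlo SEs of $-0.05$ and 95%
Wald coverage in $[0.92, 0.98]$ over 200 replications at 43 × 200; and
band feasibility (every class holding ≥ 5 eligible primes for ≥ 95% of
targets) across seeds on default corpora. These replication counts and
sizes are the package's chosen operating points: large enough for the
binomial error of the checked rates to sit well inside the asserted
intervals, small enough to run routinely.

Known limitations: the nonword generator is not phonotactically
German; the synthetic corpus has no morphology, syntax or topical
drift; exact lme4 optimizer settings of the original analyses are
unknown, so refits of real data would differ in trailing digits; and
the desk-scale spaces are not the published spaces — none of the
original inferential statistics on real reaction times are recomputed
here, only the self-contained printed arithmetic (Wald interval, AIC,
$\chi^2$ tails) and the stated design counts.

# A worked run

```{r, eval = FALSE}
library(semprime)

cfg <- run_config(out_dir = "run1", master_seed = 1)
res <- run_pipeline(cfg)

res$analyses$exp1.cosine_lsa     # LSA predictor on experiment 1
res$pooled$hal$model_comparison  # pooled AIC / logL comparison
autoplot(res$analyses$exp1.cosine_lsa)
```

Each stage derives its seed from the master seed and the stage name, so
the manifest written alongside the artifacts is reproducible from the
config alone.
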