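---
title: "Methods: decision-theoretic rough-set reduction and PNN classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decision-theoretic rough-set reduction and PNN classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roughpnn)
```

This vignette documents the model behind `roughpnn`, the choices made where
the design was genuinely open, and what the package's tests do and do not
demonstrate.

## The decision table

All functions operate on a *decision table*: a tibble with opaque sample
ids, a factor of decision labels (two classes in the diagnostic setting,
benign and malignant), and `K` real-valued condition attributes `a1..aK`
addressed by their 1-based index. For the Wisconsin diagnostic layout,
attributes 1–10 are the means, 11–20 the standard errors and 21–30 the
worst values of ten nuclear measurements, so printed attribute subsets such
as `{21, 27, 22, ...}` are addressable verbatim.

## Neighborhood granulation

The granule of a sample is the closed Euclidean ball of radius δ in the
feature space restricted to the current attribute subset. Two conventions
matter and are fixed throughout:

* **Metric.** Plain (unnormalized) Euclidean distance over the selected
  attributes. This gives the two monotonicity properties the tests assert:
  granules grow with δ and shrink as attributes are added.
* **Boundary.** A distance exactly equal to δ is inside (closed ball), with
  a `1e-12` slack on the squared distance against floating-point dust.

Granulation is scale-sensitive, so tables are min–max scaled to `[0, 1]`
per attribute — fitted on the training portion only, to avoid test-set
leakage — before any radius is interpreted. The default δ = 0.15 (scaled
units) was chosen so that granules on a WBCD-sized table are neither
singletons nor the whole universe for small attribute subsets; it is a
plain argument everywhere.

## Granule statistics and the generated loss matrix

For a target class X, each granule yields `p_x = |g ∩ X| / |g|`,
`s_x = |g ∩ X| / |X|` and `s_c = |g ∩ X^C| / |X^C|`. The two significances
read the granule against the *global* class distribution: a granule that
captures half of all X samples is more consequential than one capturing a
sliver, regardless of its local purity. This counting definition is a
reconstruction — the quantity is described in the literature as the
importance of local classes within the global distribution, but no closed
form is printed — and it satisfies the properties the rest of the machinery
needs: both lie in `[0, 1]`, `s_x = 0` exactly when the granule contains no
X samples, and both are computable from the raw class counts alone.

The six losses are generated from a single compensation coefficient
ξ ∈ (0, 0.4] (the decision-maker's tolerance of uncertainty): correct
actions cost nothing, wrong accept/reject cost the significances, and the
deferral costs are `s_x (p_x − ξ)` and `s_c (1 − p_x − ξ)`. As printed,
these deferral factors can go negative (whenever `p_x < ξ` or
`1 − p_x < ξ`); negative losses would invert the Bayes ordering of the
actions, so both are clamped at zero and the clamp is treated as a
degenerate-threshold signal (below).

## Thresholds, regions, and the overall risk

The thresholds come from the standard decision-theoretic comparison of
expected losses of the three actions:

α = (λ_PN − λ_BN) / ((λ_PN − λ_BN) + (λ_BP − λ_PP)),
β = (λ_BN − λ_NN) / ((λ_BN − λ_NN) + (λ_NP − λ_BP)).

For the generated matrices one can show that whenever both deferral losses
are strictly positive, the denominators are positive and β < α always
holds (the difference of the defining products reduces to `2ξ s_x s_c`, a
positive quantity). When either deferral loss is clamped to zero the
ordering assumption `λ_PP < λ_BP < λ_NP` (or its negative-side twin) fails;
the implementation then collapses to a two-way decision at
γ = λ_PN / (λ_PN + λ_NP) with an empty boundary region. Pure granules land
in the right region with zero contribution under this rule, which is what
makes consistent tables have exactly zero risk.

Ties at the thresholds accept: `P ≥ α` is positive, `P ≤ β` negative. The
overall risk sums the region-wise expected losses one-vs-rest over both
classes (summing over classes is the default; a single target class can be
requested — with two classes the two views are nearly symmetric, and the
default avoids privileging either).

## Attribute reduction

A subset B is a reduct when (1) its risk is no worse than the full set's
and (2) every proper subset has strictly greater risk. Condition (1) is
applied *non-strictly* (within a `1e-8` tolerance): on a consistent table
every sufficiently informative subset ties the full set at exactly zero
risk, and under a strict reading no reduct would ever exist there — while
the evidently intended answer is the smallest subset attaining the full-set
risk. Strictness lives in condition (2), which is what enforces minimality.

The search is greedy: start from the best singleton, add the attribute with
the largest risk decrease while one exists, then delete attributes whose
removal does not increase risk. If the forward pass stalls above the
full-set risk (possible in principle for greedy search), the search
restarts from the full set with backward elimination, which cannot end
above it. Finally, when the surviving subset has at most
`minimality_limit = 10` attributes, an exact refinement enumerates all of
its subsets and keeps the minimal-risk one, breaking ties by cardinality
and then by lowest labels; choosing the tie-break this way provably yields
a subset all of whose proper subsets are strictly worse, so condition (2)
holds in full on small reducts. Above the limit (enumeration of `2^|B|`
subsets becomes unaffordable around |B| ≈ 12) only single-deletion
minimality is guaranteed. All other ties go to the lowest attribute label,
making the search deterministic.

`exhaustive_reduct()` is the independent check: it enumerates every subset
(capped at 10 attributes), applies conditions (1)–(2) literally, and picks
by the same tie rule. The test suite drives both over random tables and
asserts that the greedy result is admissible whenever the oracle finds any
admissible subset.

## The PNN classifier

The PNN is a Parzen-window density classifier: Gaussian kernels of width σ
on all stored training vectors, class-wise means, prior weighting by class
frequency, argmax output with ties to the first class level. Internally
all accumulation is log-domain (log-sum-exp), so predictions remain exact
when the raw kernels underflow — the documented contract is that scores
equal the naive evaluation wherever the naive evaluation does not
underflow, and the nearest-neighbor limit at σ = 10⁻⁴ is exercised
directly in the tests.

**Scaling for the classifier.** The kernel is scale-sensitive, and the two
pipeline stages use different units deliberately: granulation uses min–max
`[0, 1]` units (δ = 0.15 is meaningful there), while PNN inputs are
z-scored to unit SD. The default spread σ = 0.75 and the sweep range
(0.5, 1.5] are meaningful *in SD units*: across that range the classifier
moves from a sharp, nearly nearest-neighbor rule toward a smooth prior-
dominated one, which is the regime the spread sweep is designed to map.
Had the same min–max units been used, the entire sweep range would sit far
above any within-class distance, every kernel would be effectively flat,
and the classifier would collapse to majority voting — measurably so: on
the bundled synthetic table the training accuracy pins at exactly the
majority rate. Both scalings are fitted on the training portion only and
travel with the model (a fitted `pnn` can carry its `scaling_stats` and
apply them to new data automatically).

## The synthetic generator

`synthetic_spec()`/`generate_table()` draw seeded two-class tables with
three kinds of attributes: informative (class-conditional Gaussians, unit
within-class SD, means `class_separation` apart per dimension), redundant
(linear functions of the informative block plus Gaussian noise — either
random combinations, or one-parent "paired" children emulating the
mean/SE/worst triplets of the Wisconsin features), and pure noise
(class-independent standard Gaussians). `wbcd_like_spec()` fixes the
WBCD-shaped instance: 357 + 212 samples, 10 informative parents, 20 paired
children, no pure noise, separation 1.2 SD per informative dimension. The
separation was chosen once, a priori, to match the difficulty of the real
data: 1.2 SD per dimension over 10 informative dimensions gives a
between-class Mahalanobis distance near 3.8, i.e. a Bayes error of roughly
3%, the same order as the error rates reported for well-tuned classifiers
on the real table.

What the generator does *not* emulate: the skewed, strictly positive
marginals of real cytometry features, their heteroscedasticity across
classes, and the full 10-feature correlation structure. Passing tests on
synthetic tables therefore demonstrate the *mechanics* (reduction removes
what carries no class signal; the classifier realizes the available
separation), not clinical performance. The pipeline's numbers on the real
WDBC file will differ; the package reports them when given the file but
never asserts them.

## Problem sizes and numerical choices

The test suite and the acceptance script size their experiments as
follows: oracle-vs-greedy comparisons use 30 random tables of up to 40
samples and 8 attributes (the exhaustive oracle is exponential in
attributes); the recovery experiment uses 20 replicates of 200-sample,
8-attribute tables; the end-to-end pipeline runs on the full 569 × 30
synthetic table. Risk comparisons use an absolute `1e-8` tolerance;
membership uses a `1e-12` squared-distance slack; the mixture identity of
the PNN holds to `1e-10` relative. Degenerate inputs are handled
explicitly: constant attributes scale to zero, zero-radius granules fall
back to coordinate-identical samples, empty global classes and zero
spreads are rejected with typed errors.

## Known limitations

* Condition (2) is verified in full only up to 10-attribute reducts; larger
  reducts are single-deletion minimal.
* The significance definition is a reconstruction (see above); other
  readings (e.g. granule-size weighting) would change the risk surface and
  hence the selected subsets.
* The whole-table granulation is O(n²) in memory per attribute; tables
  beyond a few thousand samples need a different engine.
* Multi-class support is one-vs-rest in the risk only; the classifier is
  naturally multi-class, but the reduction has been exercised mainly on
  two-class tables.
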