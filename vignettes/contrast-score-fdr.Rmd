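---
title: "Contrast-score FDR control: model, procedures and design choices"
author: "clipfdr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrast-score FDR control: model, procedures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clipfdr)
```

# The measurement model

The input is a pair of non-negative matrices: $X \in \mathbb{R}_{\ge 0}^{d
\times m}$ (experimental condition) and $Y \in \mathbb{R}_{\ge 0}^{d
\times n}$ (background condition), one row per feature. Feature $j$ has
unknown expected signals $\mu_{Xj}$ and $\mu_{Yj}$; the *uninteresting*
(null) features are those with $\mu_{Xj} = \mu_{Yj}$. Two assumptions
carry the whole theory:

1. measurement errors are independent across features and replicates;
2. every uninteresting feature has its $m + n$ measurements identically
   distributed across all replicates of both conditions.

Nothing is assumed about the distributional form, about variance
homogeneity across features, or about the number of replicates. The
non-negativity requirement is a modelling convention (counts and
intensities live there); data on other scales should be shifted or
transformed upstream, and `MeasurementPair()` refuses negative entries
with an error saying so. Between-sample normalization (e.g., library-size
scaling) is likewise the caller's responsibility: the package never
rescales columns silently.

# Contrast scores

For a single feature with replicate vectors $x, y$ the package provides
three summaries: the *minus* statistic $\bar{x} - \bar{y}$, the *max*
statistic $\max(\bar{x}, \bar{y}) \cdot \operatorname{sign}(\bar{x} -
\bar{y})$, and the pooled-variance two-sample $t$ statistic. The $t$
statistic is exposed for completeness and experimentation; the default
pipelines use mean-based statistics only, because with few replicates the
extra variance estimation in $t$ costs power while the FDR guarantee
never required a pivotal statistic in the first place. If the pooled
variance is zero with unequal means, the $t$ summary returns a signed
infinity with a warning (ranking semantics survive for constant
replicates); with equal means it errors.

**Equal-replicate enrichment (m = n).** The contrast score is computed
directly per feature (minus score by default). Under assumption 2 the
null scores are symmetric about zero: the background columns are natural
negative controls and no permutation machinery is needed.

**Unequal designs and differential analysis.** Permutations of the
pooled $m+n$ columns that assign the same $m$-subset to the
pseudo-experimental group are equivalent; there are $\binom{m+n}{m}$
equivalence classes, and for differential analysis with $m = n$ a class
and its complement collapse into one (the statistic is an absolute
value), leaving $\binom{2m}{m}/2$. Differential analysis therefore needs
$m + n \ge 3$; a 1vs1 differential design is rejected with an error. For
the identity class and $h$ sampled non-identity classes the per-class
statistic is the minus statistic (its absolute value for differential
analysis), and sorting the $h+1$ values $T^{(0)} \ge \dots \ge T^{(h)}$
gives the score. The default combining rule is the *maximum* contrast
score: $+|T^{(0)}|$ when the identity statistic is the strict unique
maximum, $0$ when the top two sorted values tie, $-|T^{(0)}|$ otherwise.
The *minus* combining rule ($T^{(0)} - T^{(1)}$ if the identity attains
the maximum, $T^{(1)} - T^{(0)}$ otherwise) is also available.

Tie handling is deliberately conservative: a permuted class tying with
the identity at the top yields score 0 under both rules, so ties can
never manufacture positive evidence. This matters for count data, where
exact ties are common.

# Thresholding procedures

Both procedures scan the candidate set $\mathcal{C} = \{|C_j| : C_j \ne
0\}$ in increasing order and return the smallest cutoff whose estimated
false discovery proportion is at most the target $q$:

* **BC** (direct scores): $\dfrac{\#\{C_j \le -t\} + 1}{\#\{C_j \ge t\}
  \vee 1} \le q$;
* **GZ** (permutation scores from $h$ classes): $\dfrac{1/h + \#\{C_j \le
  -t\}/h}{\#\{C_j \ge t\} \vee 1} \le q$.

Discoveries are the features with $C_j \ge$ cutoff (ties at the cutoff
are discoveries). If no candidate qualifies, the cutoff is $+\infty$ and
the discovery set is empty. The implementation counts tails from one
sorted copy of the scores ($O(d \log d)$); the test suite keeps an
independent quadratic scan as an oracle and checks agreement on a
thousand random instances. `NaN` scores are rejected at validation
(their ordering in the counting sets would be undefined); $\pm\infty$
scores are legal and counted in the tails.

`featureFdrEstimates()` extends the cutoff rule to a per-feature
quantity: the smallest ratio achievable at any candidate threshold at or
below the feature's score, clipped to $[0,1]$, with 1 for non-positive
scores. Thresholding these estimates at any $q$ reproduces the
corresponding procedure's discovery set exactly — they are convenient
for reporting "discoveries at every target", but they are score-based
FDR estimates, not p-values, and are labelled as such in the output
tables.

# Defaults and auto-resolution

`runClipper()` resolves `score = "auto"`, `procedure = "auto"` as
follows: enrichment with $m = n$ uses direct minus scores with BC;
enrichment with $m \ne n$ and all differential analyses use permutation
statistics with the maximum score and GZ. These combinations were chosen
for power: with equal replicates the direct minus score with BC
dominates, while in permutation settings the maximum score pairs
naturally with GZ's $1/h$ accounting. Explicit overrides are honoured
where defined (either direct score with BC when $m = n$; either
combining rule with GZ). BC is exposed only for the equal-replicate
enrichment construction — its symmetry argument is tied to the natural
negative controls, and the package does not offer it on permutation
scores.

The number of sampled classes defaults to *exhaustive* whenever $h_{\max}
= \binom{m+n}{m} - 1 \le 100$ (covering every design up to about 4vs4,
plus 2vs1, 3vs1, ...), and to $h = 100$ classes sampled without
replacement otherwise. Exhaustive plans are deterministic and
seed-independent; sampled plans draw class *ranks* and convert them to
column subsets by lexicographic unranking, so a plan is reproducible from
$(m, n, \text{mode}, h, \text{seed})$ on any platform. The FDR guarantee
holds for every $h \ge 1$; larger $h$ mainly stabilizes the score
distribution, with rapidly diminishing returns beyond roughly 100
classes. Plan sampling and data generation restore the caller's RNG
state afterwards.

Features that are identically zero everywhere are retained with score 0:
silently dropping features would change $d$ and the numerator of the
ratio, so any filtering must be an explicit caller decision.

# The synthetic-data generator

`simulationConfig()` / `generateDataset()` emulate a controlled
two-condition study: a replicate design $(m, n)$; gaussian, poisson or
negative-binomial measurements; a *homogeneous* background (one shared
background mean, default 5 for counts and 0 for gaussian) or a
*heterogeneous* one (feature-specific means, Gamma(shape 2, scale 5) for
counts, Uniform(0, 10) for gaussian); a fraction `pi1` (default 0.1) of
interesting features whose experimental mean is moved by a 3-fold effect
(up, or up/down with equal probability for differential analysis);
gaussian noise sd 1; negative-binomial size 2. Options add outliers (one
random replicate of a feature multiplied by `outlierFactor` with
probability `outlierRate`) and block dependence (features within blocks
of 50 share a per-replicate latent gaussian factor, coupled through a
gaussian copula so every marginal distribution is preserved exactly).

Choices worth flagging:

* **Gaussian truncation.** Gaussian draws are truncated at zero to
  respect the non-negative measurement scale. The truncation is one fixed
  transform applied to every replicate, so null features remain exactly
  identically distributed — assumption 2 holds by construction, which a
  rank test in the test suite verifies on pooled null residuals.
* **Effect semantics.** The effect is a fold change by default. A fold
  change is inert on a zero-mean background (the gaussian homogeneous
  default), so `effectKind = "shift"` is available for that corner;
  defaults are never changed behind the user's back.
* **Parameters vs noise.** In the measurement model the per-feature
  means and the identity of the interesting features are fixed unknowns,
  not randomness. `generateDataset()` draws everything from one seed for
  convenience, but `runBenchmark()` separates the two layers: one
  parameter configuration (drawn from `parameterSeed`) is shared by all
  replicate datasets, and only measurement noise varies. This is the
  correct Monte-Carlo estimate of FDR — an expectation over noise given
  the signal structure — and it is also what exposes baseline methods
  whose validity quietly requires feature parameters to be exchangeable
  across features.

What the generator does *not* emulate: real-data artefacts such as
batch effects, library-size differences, mean-variance trends estimated
from data, alignment or quantification noise, and arbitrary long-range
dependence. Passing benchmarks here demonstrates the procedures'
statistical behaviour under the stated assumptions, not end-to-end
performance on any particular omics platform.

# Baselines

For benchmarking, the package implements the classical p-value routes
minimally but correctly: pooled empirical p-values (the feature's
experimental average ranked against all features' background averages,
with an add-one correction $(1 + \#\{\bar{Y}_k \ge \bar{X}_j\})/(d+1)$
so p-values are never zero); paired parametric tests per feature
(pooled-variance gaussian $t$; the conditional-binomial poisson test; a
deliberately misformulated "2as1" variant that treats the background
mean as a known constant, reproducing a common analysis mistake); BH
thresholding via `stats::p.adjust`; and Storey thresholding with a
single fixed $\lambda$ (default 0.5) rather than the smoothed
$\lambda$-grid estimator — sufficient for benchmarking, and exactly
reducible to BH at $\lambda = 0$.

# Validation results and their limits

The test suite and `scripts/acceptance.R` compute, not assume, the
following (problem sizes chosen to make the Monte-Carlo errors small
while keeping the default run light: $d = 2000$ features with 50–200
replicate datasets in the tests, $d = 10000$ with 200 datasets in the
acceptance script):

* the default pipelines keep mean FDP at or below $q$ (within three
  Monte-Carlo standard errors) at $q = 0.05$ in the three headline
  settings, and across $q \in \{0.01, \dots, 0.10\}$ in all six designs
  (1vs1/2vs1/3vs3/10vs10 enrichment, 2vs1/3vs3 differential) for
  gaussian heterogeneous data — also in the presence of 1% ten-fold
  outliers, where the correctly specified paired test loses control;
* the misformulated one-sample comparator fails catastrophically in the
  2vs1 poisson setting (mean FDP $\approx 0.86$ at $q = 0.05$);
* the identity statistic's rank among the per-class statistics is
  uniform under the global null (goodness-of-fit on 5000 features).

Two honest caveats. First, under this generator's heterogeneous gaussian
background (uniform means, constant variance) the pooled empirical
baseline *does* control the FDR empirically — its well-documented
failure requires stronger forms of heterogeneity (e.g., feature-specific
variances) than this generator produces; the corresponding benchmark
assertion documents that gap rather than papering over it. Second, power
in the negative-binomial differential setting is very low at the default
size 2 and 3-fold effect: with variance $\mu + \mu^2/2$ the within-null
spread swamps a 3-fold mean change at three replicates, and the
procedure is conservative by design rather than anti-conservative. FDR
control holds throughout; power is reported as measured.

# Known limitations

* Two conditions only; no covariates, batch-effect regression, or
  multi-condition designs. The contrast-score construction would extend,
  but none of that is implemented.
* The informative statistic is the sample mean; features interesting in
  variance or shape but not mean are invisible by design.
* Permutation scores at very small designs (e.g., 2vs1, $h_{\max} = 2$)
  are coarse: with few classes the score distribution is discrete and
  power is limited — inherent to the design, not the implementation.
* The GZ path's $1/h$ additive term makes very small discovery sets
  unreachable at small $q$ and small $h$: at least $\lceil 1/(hq)
  \rceil$ discoveries must clear the cutoff simultaneously.
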