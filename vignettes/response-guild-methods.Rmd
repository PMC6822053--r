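---
title: "Response guilds, production functions and Mantel inference: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response guilds, production functions and Mantel inference: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respguild)
```

## The model

`respguild` treats covariation in species' population dynamics as an
integrated record of how species respond to multivariate environmental
change. Two species whose interannual changes in abundance correlate
strongly have, by construction, responded similarly to whatever mixture of
weather, land use and biotic drivers acted over the monitoring period; no
driver needs to be identified or measured. The analysis has four stages.

**Dynamics distance.** Let $x_i(t)$ be species $i$'s standardized log
abundance index in year $t$. Interannual changes are
$\Delta_i(t) = x_i(t) - x_i(t-1)$; a change is missing iff either source
year is missing. For each pair the Pearson correlation $r_{ij}$ is taken
over the years in which both changes are observed (complete pairs), and
transformed to a distance $d_{ij} = 1 - r_{ij}$, so 0 means perfectly
synchronous, 1 uncorrelated, 2 perfectly opposite dynamics. Correlation is
invariant to per-species affine transforms, so the choice of
standardization (we z-score each species' series) cannot change $d$ — a
property the test suite asserts directly.

**Response guilds.** Agglomerative clustering of $d$ (via `hclust`) builds
a dendrogram; cutting all branches below a threshold allocates species to
guilds. Because published analyses of this kind rarely report their numeric
thresholds, cuts are specified by target guild count $k$ as the
reproducible interface (heights are also accepted). Cuts at several $k$
give nested partitions — a species table across resolutions.

**Production functions.** Per-species functional roles are scored from
traits, each index scaled so its maximum is exactly 1:

* relative national density $D = OA / \max(OA)$, with $O$ the mean number
  of occupied 10-km squares and $A$ the mean survey count;
* larval biomass provisioning $B = DL / \max(DL)$, with $L$ larval length
  in mm (assumes biomass proportional to length, and larval density
  proportional to adult density);
* wildflower outcrossing pollination $P = DM / \max(DM)$, with $M$ a
  mobility index (mobile, abundant species move more pollen);
* per-plant-family pollination $P_x = DMX / \max(DMX)$, with $X \in
  \{0,1\}$ the family-visitation flag; the maximum is over species for
  that family, and non-visitors score exactly 0;
* cultural function $C = Y / \max(Y)$, with $Y$ a species' mean count in a
  public mass-participation survey; species outside the published
  most-recorded list (18 species; configurable `top_n`) score exactly 0.

A missing required input ($L$ for $B$; $M$ for $P$, $P_x$) makes the score
missing, never zero: zero is reserved for true zeros ($X = 0$, not
surveyed). Denominators are computed over species with complete inputs.

**Association tests.** Each function-score vector is z-scored over the
species with defined scores and expanded into a matrix of absolute
pairwise differences (for a single score this is the Euclidean distance);
species with missing scores are excluded listwise and reported. Mean
patristic distances over a set of candidate phylogenies summarize genetic
distance. Each matrix is compared with $d$ by a permutation Mantel test.

## The Mantel implementation

The statistic is the Pearson correlation of the strictly-lower-triangle
entries. Under joint row/column permutation it is a strictly increasing
function of the classical cross-product statistic $\sum_{i<j} d_{ij}
m_{ij}$, so the two give identical permutation rankings and identical
p-values (asserted by a test). The default tail is `greater`: the working
hypothesis is always positive matrix association, so a negative observed r
yields a large p.

With $m$ sampled permutations the one-tailed p is
$(\#\{r_\pi \ge r_{\mathrm{obs}}\} + 1)/(m + 1)$ — the standard continuity
correction for sampled nulls, which bounds p below by $1/(m+1)$ and makes
the test exact-level when $\alpha (m+1)$ is an integer. When $n! \le m$
the test switches to exhaustive enumeration of all $n!$ permutations and
the correction is dropped (the full null is available). Ties are counted
as extreme (comparison at tolerance $10^{-12}$), the conservative
direction.

Confidence limits for r are a 2.5%/97.5% percentile bootstrap that
resamples *species* with replacement and recomputes r on the induced
submatrices, dropping self-pairs of duplicated species. Published tables
in this literature report such limits without describing the method;
species-level resampling is our choice and is labelled as such. Percentile
intervals need not contain the observed r in pathological cases; they are
reported as uncertainty summaries, not test inversions.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `min_pairs` | 10 | years | correlations on fewer overlapping changes are noise-dominated; pairs below it are reported as undefined, and clustering refuses matrices with holes |
| linkage `method` | `complete` | — | `hclust`'s default; the method is recorded in every output and is a config option |
| `cut_k` | 2, 4, 6, 10 | guilds | the four published resolutions of the motivating analysis; any k or height works |
| `n_perm` | 9999 | permutations | resolution of 1e-4 on p at exact level for α·(m+1) integer |
| `n_boot` | 500 | resamples | percentile-CI stability at two decimals |
| `top_n` | 18 | species | length of the published most-recorded list behind C; an artifact of that survey, hence configurable |

## What the synthetic generator emulates

`community_config()` defaults describe the motivating study system: 54
species × 39 years (1976–2014 labelling), ~5% of cells missing completely
at random (a species' first two years are never removed, keeping every
series analyzable), four guilds, and a 1,000-tree set. Where the study
conditions do not pin a value we chose once: within-guild change
correlation ρ = 0.6 (strong but imperfect synchrony, of the order seen
between congeneric butterflies), density-dependence strength φ = 0.2, and
branch-length noise 0.2 across trees.

Dynamics are generated as $\Delta_i(t) = \sqrt{\rho}\, \ell_i^\top e(t) +
\sqrt{1-\rho}\,\varepsilon_i(t)$ with iid standard-normal drivers
$e_g(t)$, one per guild. In `guild_blocks` mode $\ell_i$ is the indicator
of species $i$'s guild, so the expected change-correlation is exactly ρ
within guilds and 0 between — an analytic target the tests check by Monte
Carlo. In `brownian_loadings` mode the loadings evolve by Brownian motion
along a pure-birth tree (unit birth rate, rescaled to height 1 so
comparisons are scale-free) and are row-normalized, making the expected
correlation ρ times the cosine of two species' loading vectors; closely
related species then respond alike, which is what the phylogenetic Mantel
comparison is designed to detect. Abundance series integrate the changes
by $x_t = (1-\varphi) x_{t-1} + \Delta_t$, $x_0 = 0$: φ = 0 is a random
walk whose differences return the changes exactly; φ > 0 adds mean
reversion, mimicking density dependence.

Trait tables draw O, A as positive lognormal-shaped integers, L and M
lognormal (15% of species missing L, emulating real trait coverage), X as
per-family Bernoulli flags, and Y for exactly `top_n` species. The
`clustered` scenario multiplies guild-1 occupancy 25-fold and places all Y
scores in guild 1, creating a known positive dynamics–function
association; `dispersed` spreads them at random, a null.

What the generator does **not** emulate: observation error in the index
itself, temporal autocorrelation or trends in the drivers, interspecific
interactions (competition, shared parasitoids) beyond shared drivers,
non-Gaussian heavy-tailed population crashes, and non-random missingness
(real gaps concentrate in early years and rare species). Passing tests
therefore demonstrate that the machinery recovers known structure under
the model's own assumptions — not that those assumptions hold for any
particular monitoring scheme.

## Numerical choices and degenerate inputs

* Species names are canonicalized (underscores to spaces, whitespace
  collapsed, genus capitalized) before any matrix is aligned; alignment
  sorts species so outputs are order-stable across runs, and equal-height
  merges are resolved on a canonically sorted matrix for bit-reproducible
  dendrograms.
* Constant abundance series cannot be z-scored and are excluded with a
  warning naming the species; all-zero $OA$, families nobody visits, and
  zero-variance score vectors are errors, not silent zeros.
* Published score tables print censored cells (`<0.001`, `>0.001`); the
  fixture stores them as 0.0005 with a companion `_censored` flag and
  nothing downstream relies on more than their sign.
* Whether association tests should drop species with missing scores
  listwise or pairwise is genuinely open; we exclude listwise (the matrix
  stays a valid single-score Euclidean distance) and report the exclusion
  list.
* The pipeline derives per-stage seeds from one master seed (fixed small
  offsets), so stages are individually reproducible; every output table
  carries the package version, seed and a config hash as comment headers,
  and reruns are byte-identical.

## Problem sizes used by the test suite

The suite validates calibration and power at sizes chosen to make the
statistical checks sharp: type-I error over 1,000 independent 20-species
matrix pairs at 199 permutations; guild recovery over 50 replicates of
40 species × 4 guilds × 100 years at ρ = 0.8 (adjusted Rand ≥ 0.9
demanded in ≥ 90% of replicates); heritability detection over 15
replicates of 25 species with 10 trees, with a matched no-heritability
null required to yield approximately uniform p; and one full study-scale
run (54 × 39, 9,999 permutations, six comparisons) checked for
reproducibility. These sizes were fixed by pilot calibration of the
generator before being frozen into the tests.

## Known limitations

* Complete-pairs correlation matrices are not guaranteed positive
  semidefinite under heavy missingness; the distance transform and
  clustering are unaffected, but treat eigen-analyses of such matrices
  with care.
* Averaged patristic distances over a tree set are generally not additive
  on any single tree; the average is a distance summary, not a tree.
* The Mantel test conditions on the observed matrices; like all Mantel
  inference it can be liberal when distances carry strong
  autocorrelation. No partial Mantel or correlogram is provided.
* Production functions are deliberately simple proxies (density × one
  effect trait); they inherit the assumptions listed above, and a score of
  1 means "largest in this community", never an absolute rate of function
  delivery.
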