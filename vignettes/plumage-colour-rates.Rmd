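---
title: "Rates and directions of plumage colour evolution: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rates and directions of plumage colour evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plumrates)
```

`plumrates` implements a complete comparative pipeline for asking how fast,
and in which directions, plumage colour evolves across a bird phylogeny, and
whether the two sexes differ. This vignette is the package's own account of
the models it fits, the choices behind them, and what the synthetic-data
tests can and cannot show.

## The colourspace model

Avian colour vision is tetrachromatic. A colour patch is described by the
stimulation of the four cone classes of the violet-sensitive (VS) visual
system, `v, s, m, l`. Dividing each by their sum removes the achromatic
(luminance) dimension and leaves a point on the 3-simplex; the affine map

```
x = sqrt(3/2) (1 - 2s - m - v) / 2
y = (-1 + 3m + v) / (2 sqrt(2))
z = v - 1/4
```

projects the simplex into the regular tetrahedron whose achromatic point is
the origin and whose four pure-receptor vertices sit at distance 0.75 from
it, with the `v` vertex on the vertical axis. This is the standard avian
tetrahedral colourspace convention; the map is invertible on the simplex
(`tetrahedral_to_stimuli()`), which the generator exploits to encode
simulated colours as receptor channels. Where colours arrive as device
(camera) channel values, `fit_device_mapping()` fits an ordinary
least-squares polynomial map (degree 1 by default, degree 2 optional, no
regularisation) from device channels to each receptor and reports the
per-receptor Pearson correlation between fitted and known values as the
validation diagnostic.

Because relative cone stimuli are strongly correlated, analyses use the
first two axes of a single centred PCA fitted to the species x sex x patch
mean points pooled over all patches and both sexes — one common colour plane
rather than per-patch axes, so that directions are comparable across
patches. Axis signs are fixed (largest-magnitude loading positive) for
reproducibility.

Dichromatism is the per-patch Euclidean distance between male and female
mean points in `(x, y, z)`, aggregated across patches by the mean (the usual
proxy) or the maximum ("maximum extent" variant). Colour mechanism classes
are assigned by dominant stimulation: relative `l` at or above 0.4 is
carotenoid-consistent, otherwise relative `v + s` at or above 0.55 is
structural-consistent, else intermediate. The thresholds are configurable;
the defaults are chosen so the three regions are exhaustive, mutually
exclusive, and place the achromatic centre in the intermediate class.

## The variable-rates model

Colour evolves by multivariate Brownian motion whose rate can shift on
branches or whole clades. A configuration is a set of events; each event is
either a branch event (rescaling its single branch) or a clade event
(rescaling every branch strictly below the focal branch's child node, so an
n-tip clade covers its 2n - 2 branches). The effective scalar of a branch is
the product of the events covering it, and the variance accumulated along
branch j is `r_j t_j R`, with `R` the among-trait covariance. The likelihood
is evaluated by Felsenstein's pruning algorithm (one Gaussian contrast per
internal node plus a root term), in O(tips) per trait block.

Only relative rates are identified: multiplying every scalar by c is
indistinguishable from rescaling `R`. The sampler therefore centres the log
effective scalars (geometric mean fixed to 1) inside the likelihood and
reports rates on that relative scale.

Posterior inference is by reversible-jump MCMC with six move types: birth
and death of events, scalar resizing, event relocation, random-walk updates
of the Cholesky factor of `R`, and root-state updates. Priors: the event
count is Poisson with mean 2 (configurable; truncated by the number of
available (branch, type) slots), event locations are uniform over free
slots, log scalars are Normal(0, 1), the Cholesky parameters of `R` and the
root have broad Normal priors (sd 5 and 10). Proposing a new event's scalar
from its prior makes the reversible-jump acceptance ratio collapse to the
likelihood ratio times `mean/(K+1)` for a birth and `K/mean` for a death —
transparent, and it means a prior-only chain samples the (truncated) Poisson
exactly, which the test suite verifies by a chi-squared goodness of fit on
10,000 samples.

Chain defaults are 1e6 iterations, 25% burn-in and thinning 1000 at
empirical scale; the simulation studies in the tests use 1e5 iterations with
thinning 100 on 64-tip trees, which the convergence checks (independent
chains correlating above 0.9 on per-branch mean scalars) support at that
size.

### Summaries, and a caveat on "where is the shift?"

`summarise_rate_phenogram()` returns the per-branch posterior mean scalar,
the rate-scaled lengths `l_j = mean(r_j) t_j`, and three per-branch
posterior probabilities: that any event covers the branch, that a branch
event sits on it, and that a clade event has it as focal branch.
`detect_shifts()` lists branches exceeding a threshold (0.99 by
convention).

One genuine limitation of location-based summaries deserves emphasis. A
single true clade shift can be represented by the sampler as a clade event
at the stem, or as a clade event at a daughter branch plus branch events on
the remainder, and the posterior legitimately spreads mass across these
equivalent configurations; short internal branches inside the clade also
carry almost no information about their own scalar. Both effects depress
per-location and per-branch-coverage probabilities even when the clade's
rate elevation is certain. The representation-invariant question "did this
clade shift?" is answered by `clade_shift_pp()`: the posterior probability
that the clade's mean log relative rate exceeds the background's (default),
or the probability that some clade event lies within the clade region
("events" variant). In the package's power study (64 tips, one 10+-tip
clade scaled by 10, two traits, 1e5 iterations, 20 replicates) the
rate-contrast probability exceeds 0.99 in every replicate, while the
per-location and min-coverage variants reach 0.99 in only 16/20 and 14/20 —
the difference is representation splitting, not detection failure.

## TRES: species-level rates

Given a mean rate phenogram, the trait-rate equal-splits metric for tip i is
the weighted average of the rate-scaled branch lengths along its root path,

    m_i = sum_j w_j l_j / sum_j w_j,  w_j = 1 / 2^(j-1),

with j = 1 the terminal edge. Weights halve rootward, so the metric is
dominated by recent rates but retains the longer-term history; it is a
convex combination of the path values, bounded by the path's minimum and
maximum, and edges beyond depth ~20 are numerically irrelevant. The root
itself carries no edge. A variant applies the same weights to the posterior
mean scalars instead of the scaled lengths. Downstream analyses use log10
TRES.

## Comparing the sexes: phylogenetic RMA

Male and female log10 TRES are related by reduced major axis (standardised
major axis) regression, the symmetric line fit appropriate when both
variables carry error: slope `sign(cov) sqrt(var_y / var_x)` through the
GLS means, with evolutionary variances and covariance estimated by GLS on a
lambda-transformed tree. A single lambda is estimated for the bivariate pair
by maximising the profile likelihood on [0, 1] (the trait covariance is
profiled out at its ML value); on a star tree the profile is flat and the
fit is flagged unidentifiable, in which case the estimate reduces exactly to
ordinary RMA. The slope test against a hypothesised value follows Clarke's
(1980) rotation formulation: `T = |log|b| - log|b0|| / sqrt((1 - r2)/(n -
2))` referred to a t distribution with non-integer degrees of freedom `2 +
(n - 2)/(1 + r2/2)`. Under equal-rate bivariate Brownian simulation the
test rejects a unit slope at close to the nominal 5% level, and a true
slope of 1.5 (300 tips, trait correlation 0.8 — a value chosen to mimic the
strong between-sex rate correlation real plumage data show) is recovered to
within 0.1 with essentially full power.

## Direction of recent divergence

For each tip, patch and sex, the divergence trajectory is the vector from
the maximum-likelihood (GLS under Brownian motion, two-pass message
passing) reconstruction of the tip's parent node to the observed tip in the
common PC plane. Its angle (degrees in [0, 360)) is the direction of recent
colour evolution, and the attached rate is the tip's patch-specific TRES.
Zero-magnitude trajectories have no direction and are dropped with a
warning rather than assigned an arbitrary angle.

`segment_rate_test()` partitions trajectories into half-open 20-degree
segments (angle exactly 360 wraps to 0) and compares each segment's
observed mean rate with a null built by permuting rate labels over all
trajectories with angles fixed — the minimal exchangeable null, preserving
both the rate distribution and the angular distribution. The null is not
corrected for the 18 simultaneous segment tests; each segment's flag is
marginal, matching the per-segment confidence-band presentation the
analysis feeds. Bands are the 2.5/97.5 percentiles of the permuted means,
p-values are two-sided empirical with the +1 correction, and fewer than 100
permutations are refused. Permuted rates are allocated to segments in a
rotation-invariant order (largest count first, ties by observed mean), so
with a fixed seed the bands are exactly reproducible, independent of input
row order, and flags co-rotate exactly when all angles are shifted by a
multiple of the segment width.

## The synthetic-data generator

Every stage is exercised on data with known ground truth:

* **Trees** come from a forward birth-death simulation conditioned on the
  tip count (extinct realisations are redrawn, never silently accepted
  smaller), stopped one waiting time after the last speciation so terminal
  branches are positive. Under pure birth the expected root-to-tip depth has
  the closed form `sum(1/(k lambda))`, k = 2..n, used as the test oracle.
* **Regimes** place disjoint clade and branch shifts with log-normal
  (median-1) scalars, mirroring the multiplicative model the sampler fits.
* **Colours** evolve as 2-D Brownian motion per patch and sex. "Fast"
  terminal branches — those above the 0.9 quantile of terminal scalars, a
  threshold made explicit because directional bias of fast divergence is an
  empirical finding rather than a generative law — can have their terminal
  displacement direction redrawn from a von Mises distribution around a
  target angle. Specimen replicates add isotropic Gaussian noise, the
  simplest model of intraspecific colour variation. A fixed offset added to
  male values programs dichromatism; with `shared_sex_draw = TRUE` the
  sexes share the Brownian realisation so measured dichromatism equals the
  programmed offset up to specimen noise, which is what the recovery tests
  assert. All values are rescaled by one factor (stored as `pc_scale`) to
  fit inside the tetrahedron and are encoded as receptor channels by the
  inverse projection, so the colourspace module round-trips them exactly.
* Dichromatism is otherwise an emergent property of sex-specific regimes,
  not a generator dial: no rule linking dichromatism to rate is built in.

What passing tests do **not** show about real data: the generator makes no
attempt to mimic museum-image acquisition noise, patch segmentation error,
phylogenetic uncertainty, or the empirical tree shape of a real radiation;
rates and directions live in an idealised PC plane from the start. The
tests establish that the estimators are correct and calibrated under their
own model, not that the model is adequate for any particular dataset.

## Numerical choices and degenerate inputs

Contrast variances in the pruning likelihood are floored at 1e-12 to guard
coincident zero-length branches; an all-zero receptor record has undefined
chromaticity and is an error; points outside the tetrahedron (negative
stimuli beyond 1e-9) are rejected; RMA refuses zero-variance traits, and a
perfect correlation gives T = 0 (slope equal to the hypothesis) or infinity
(different) rather than 0/0; lambda optimisation compares the interior
optimum against both boundaries. The initial `R` in the sampler is the
ridge-stabilised tip covariance and the initial root the trait means.

## Problem sizes

The test suite and the acceptance script run the simulation studies at the
sizes stated above — 64-tip trees and 1e5-iteration chains for the MCMC
calibration and power studies (20 replicates each), 300-tip trees for the
200-replicate RMA size study and 50-replicate power study, 2,000
trajectories and 1,000 permutations for the 200 + 100 replicate segment
studies, and a 16-tip, 2-patch, 2e4-iteration end-to-end pipeline run
executed twice for the determinism check. The full pipeline at these test
settings completes in seconds; empirical-scale settings (hundreds of tips,
10 patches, 1e6 iterations) are minutes to hours per chain.

## Known limitations

Single fixed topology per run (robustness to alternative trees is a loop,
not new machinery); no Ornstein-Uhlenbeck or directional-trend models; no
receptor-noise (JND) discriminability; no marginal-likelihood estimation;
location-based shift summaries dilute under representation splitting as
described above; the mechanism-category thresholds are a configurable
convention, not an estimated boundary.
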