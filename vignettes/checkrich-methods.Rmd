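---
title: "Methods: quantifying checklist richness bias against structured surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying checklist richness bias against structured surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(checkrich)
```

## The problem

Semi-structured checklists record birds with whatever duration and skill
their observer brings, so a checklist's species list is an
effort-truncated, detection-filtered sample of the local community.
Structured point-count programs fix the protocol — here the reference
design is 10 points surveyed 6 min each (a 60-min visit), twice a year,
March–July, from sunrise to sunrise + 4 h — and trained volunteers, so
their per-visit richness is a usable (if still imperfect) silver standard.
`checkrich` makes the comparison explicit: filter checklists to the
protocol window, estimate richness on both sides, express each checklist
as a relative bias against its site's reference, and model bias as a
function of duration so that datasets can be compared at one standardized
duration.

## Richness estimation

Each abundance sample (one checklist, or one survey visit pooled across
its points after removing the far distance band) is reduced to
`(S_obs, f1, f2, n)`.  The Chao1 lower bound infers undetected species
from the rare tail:

$$\hat S = S_{obs} + \frac{n-1}{n}\,\frac{f_1^2}{2 f_2} \quad (f_2 > 0),
\qquad
\hat S = S_{obs} + \frac{n-1}{n}\,\frac{f_1 (f_1 - 1)}{2} \quad (f_2 = 0).$$

The small-sample-corrected form above is the default because it is the
convention of the widely used estimation software family for individual
abundance samples, and it is defined for every sample (including
`f2 = 0`, where the classic `f1^2/2f2` form breaks down).  The classic
variant is retained as an option for sensitivity analysis.  Edge cases are
pinned down explicitly: no singletons means the estimate equals `S_obs`
exactly; a single singleton with no doubletons adds 0 under the corrected
form; an empty sample reports estimate 0 with a warning rather than an
error.  Estimates are never rounded internally.

Assumptions worth stating: Chao1 is a *lower* bound, is exact only under
homogeneous detectability of the rare species, and is quadratically
sensitive to the singleton count — which is why the package carries the
singleton percentage `100 f1 / S_obs` as a first-class diagnostic.

## Bias and the reference

For site $i$ with per-visit mean observed richness $A_i$ (and mean Chao1
$B_i$), a checklist with observed richness $O_{ij}$ (Chao1 $E_{ij}$)
scores

$$\mathrm{bias} = \frac{O_{ij} - A_i}{A_i},$$

and analogously for the other three numerator/reference combinations.
Bias is scale-equivariant and bounded below by −1.  Visits that were
conducted but yielded no focal-species records contribute richness 0 to
the site mean rather than being dropped silently — dropping them would
inflate $A_i$; the choice is switchable (`drop_empty_visits`).

## The effort model

Bias against duration $x$ is fitted with the shifted power function
$y = a x^b - 1$, anchored so $y = 0$ means parity with the reference.
Fitting is damped Gauss–Newton (Levenberg–Marquardt) on the analytic
Jacobian ($\partial y/\partial a = x^b$,
$\partial y/\partial b = a x^b \ln x$), initialized from the log–log
regression of $\log(y+1)$ on $\log x$ over points with $y + 1 > 0$
(exact for noiseless data), with fallback start (0.2, 0.3).  Convergence
uses a relative tolerance of 1e-10 on the residual sum of squares and the
parameter step, with at most 500 iterations; non-convergence is flagged on
the result, never silently ignored.  Standard errors come from
$\hat\sigma^2 (J^\top J)^{-1}$ at the optimum, t statistics are
estimate/SE, and p values are two-sided from the t distribution on
$n - 2$ degrees of freedom (the standard nonlinear-least-squares
convention; the result object carries the full covariance).

Uncertainty in the fitted curve is propagated three ways: the primary
95% band draws 10,000 parameter pairs from the bivariate normal at the
estimates with the fit covariance and takes pointwise 2.5/97.5 percentiles
(seeded; a non-positive-semidefinite covariance is repaired by clipping
eigenvalues at zero, with a warning); first- and second-order
Taylor-expansion (delta-method) bands are produced for parity with the
standard propagation toolchain and labelled as such.  The three agree in
the linearization regime; with large parameter uncertainty the Monte-Carlo
band is wider mid-range and should be preferred.

The standardized comparison evaluates bias and completeness
$100(1 + \mathrm{bias})$ at 60 min — one full survey visit — and the
parity duration solves $a x^b - 1 = 0$ analytically as
$x = (1/a)^{1/b}$, reported as "none" outside the observed 6–200 min
range.  For $b \le 0$ with $a < 1$ the curve stays below parity
everywhere above 1 min, so no crossing is reported there either.

## Filtering

The alignment rules (protocol/completeness/approval flags; start time in
[sunrise, sunrise + 4 h]; March–July 2010–2017; distance ≤ 4 km; duration
≥ 6 min — both boundaries inclusive) and culling rules ("X" count drops
the whole checklist; a missing count drops only that species row;
group-shared duplicates reduce to the lexicographically smallest event
identifier) are applied in a fixed documented order, with every removed
record attributed to the *first* rule that rejected it, so the attrition
ledger always reconciles: input = kept + sum of removals.  The order and
the group-representative rule are package conventions — the data sources
do not dictate them — and all thresholds live in `filter_config()`.

Sunrise comes from the NOAA solar-position approximation (Fourier-series
declination and equation of time, zenith 90.833°), accurate to about
±2 min at subtropical latitudes — well inside a 4-hour window; a
precomputed `sunrise_sec` column overrides it for exact reproducibility.
Buffer membership uses an axis-aligned 2 × 2 km square under a local
equirectangular projection (cos-latitude longitude scaling); at 2 km scale
the planar error is orders of magnitude below the buffer size.  Coastline
intersection is a per-site boolean attribute rather than a GIS operation,
and coordinate equality against survey points is tested at 6 decimal
places (~0.1 m) by default — both configurable, both conventions the
package documents rather than inherits.

## The synthetic-data generator

No generative model is dictated by the data sources; the generator is a
stand-in built so every pipeline stage has something realistic to chew on,
with known truth:

* **Community**: `species_count_true` (default 135, matching the scale of
  a subtropical breeding-bird community) relative abundances from a ranked
  log-normal (`sdlog` 1), the standard community-ecology default.
* **Detection**: each species is an independent Poisson encounter process;
  over `t` minutes a species with rate $r$ is detected with probability
  $1 - e^{-r \cdot \mathrm{skill} \cdot \mathrm{weather} \cdot t}$.  Rates
  default to `0.02/min` scaled by relative abundance, so an average
  species has ~70% detection in a 60-min skill-1 survey and the rare tail
  generates singletons.  This model was chosen because it has closed-form
  expectations (the tests exploit them) and reproduces
  singleton inflation at short duration.
* **Counts**: detected species draw zero-truncated Poisson counts with the
  same mean intensity, guaranteeing the positive integers real checklists
  carry.
* **Observers**: checklist observers draw skill from U(0.4, 1) and a
  weather multiplier from U(0.7, 1); structured-survey observers sit at
  skill 1 — this skill gap, plus duration, is what generates negative
  checklist bias.
* **Design**: checklist durations are log-uniform on 6–200 min; survey
  sites run 8 years × 2 visits × 10 points × 6 min, with per-point
  distance bands (0–25 / 25–100 / >100 m at probabilities 0.3/0.5/0.2).
* **Defects**, injected at fixed configurable rates so the culling rules
  have work to do: "X" counts (0.05), missing counts (0.05), group-shared
  duplicates (0.10), survey-style location names (0.03), coordinates equal
  to survey points (0.02), non-focal species (0.05), out-of-buffer
  locations (0.10); site-level attrition knobs: coastal 0.10, short point
  complement 0.10.

Everything is driven by one seed via derived sub-seeds; identical seed and
config give byte-identical written datasets.

What the generator does *not* emulate: spatial habitat structure and
between-site community turnover (all sites share one community),
within-season phenology, observer-specific list length habits, taxonomic
error, and — importantly — the empirical covariance structure between
duration, skill and singleton share found in real checklist corpora.
Passing tests therefore demonstrate correctness of the *machinery* and the
qualitative detection-model signatures, not calibration to any real
dataset.

## What the synthetic pipeline does and does not reproduce

Three signatures are checked over ≥20 seeded end-to-end runs: Chao1-based
completeness at 60 min is at least the observed completeness (it is, in
essentially every run — Chao1 can only add species); the singleton
percentage falls with duration (it does); and the bias value rises with
the singleton percentage.  The third holds in the real-data analyses this
package is built around but *not* in the generator's raw records: under
the independent-encounter detection model, duration simultaneously raises
observed richness and suppresses singletons, and this confound dominates,
making the raw singleton–bias association negative.  The mechanism behind
the real-data relation is nevertheless present and tested: the Chao1
*inflation* component of bias (estimated minus observed bias for the same
checklist) correlates positively with the singleton share in every run.
We kept the generator honest rather than reshaping it to force the raw
sign, and the corresponding end-to-end assertion is expected to fail under
these study conditions; treat it as a documented divergence between the
stand-in generator and real checklist corpora.

## Problem sizes and numerical conventions in the test suite

Exhaustive Chao1 oracle checks run over every abundance vector with
`n ≤ 8` (51 partitions) against a brute-force evaluation, plus 10,000
random samples for the lower-bound invariant.  Power-fit calibration uses
200 replicates at n = 564 points with Gaussian noise σ = 0.27 (the scale
of the published observed-vs-observed fit), requiring both parameters
within 3 SE of truth in ≥95% of replicates; grid-search oracle equivalence
is checked on ≤20-point datasets to 5e-4.  End-to-end property runs use
4 sites × 15 checklists with the 135-species community, 20 seeds.  These
sizes were chosen to exercise the asymptotics that matter while keeping
the default suite fast enough to run habitually.

Ties and degenerate inputs: species label permutations never change any
output; duplicate species rows are summed before tallying; empty samples
report missing singleton percentages; a run in which no checklist survives
filtering aborts at the bias stage with a stage-tagged error naming the
problem rather than producing an empty report.

## Known limitations

* Chao1 variance/CIs per sample, other estimators (Chao2, ACE, jackknife)
  and coverage-based rarefaction are out of scope; only the point estimate
  is used.
* The reference standard is itself an imperfect survey; `B_i` mitigates
  but does not remove this.
* No habitat-stratified comparison and no GIS; coastal status is an input
  attribute.
* The effort model is a single two-parameter family; no asymptotic
  (Michaelis–Menten / Weibull) alternatives or model selection.
* The sunrise approximation targets low/mid latitudes; polar edge cases
  return `NA` and such records fail the sunrise rule.
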