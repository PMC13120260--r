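---
title: "Building multipurpose biomarker indices from z-scored endpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building multipurpose biomarker indices from z-scored endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbindex)
```

## The problem

Ecotoxicologic pathology studies routinely measure heterogeneous endpoints
— ultrastructural widths in nanometres, follicle counts per section, area
ratios, discriminant factor scores — on the same exposure groups.  Each
endpoint is informative on its own, but organ-level conclusions ("this
exposure is nephrotoxic *and* thyroid-disrupting") require putting them on a
common scale and aggregating them.  `mbindex` implements a hierarchical
composite-index workflow for exactly this situation, in the tradition of
integrated biomarker response (IBR) scoring: features are standardised,
direction-aligned, pooled as replicates into pathophysiologically themed
subindices (e.g. nephrotoxic, thyrotoxic, immunotoxic) and finally into one
multipurpose index, with a fully nonparametric inference layer on top.

The motivating application is the common carp (*Cyprinus carpio*)
mesonephros, which uniquely combines nephrons, hematopoietic interstitium
and thyroid follicles in one organ, exposed to the persistent pollutant
PFOA at 0, 200 ng L⁻¹ and 2 mg L⁻¹.  The packaged reference table
(`inst/extdata/table1_carp_pfoa.csv`) holds 12 morphological features × 3
exposure groups from that cohort.

## The model

### Standardisation

Each feature contributes one *representative value* per group (a mean,
median, ratio or factor score).  For feature $f$ with group values $X_g$,

$$ z_{fg} = d_f \cdot \frac{X_g - \mu_f}{\sigma_f}, $$

where $\mu_f$ and $\sigma_f$ are the mean and **sample** (n−1 denominator)
standard deviation across groups, and $d_f \in \{+1, -1\}$ is the
*direction of effect*: the sign making larger $z$ mean greater pathological
alteration.  The sample-SD convention is forced by the worked example the
reference analysis documents: the pedicel-width triple (228, 228, 286) must
give $\sigma = 33.49$, not the population value 27.34.

Direction matters for endpoints that *decrease* under toxic response.  In
the reference table, thyroid follicle cross-sectional area and perimeter
shrink under goitrogenic activation (829 → 295 µm²), so they carry
$d = -1$; the other ten features carry $+1$.  Direction is applied as a
final sign flip, after standardisation (the two orders commute up to sign;
applying it last keeps $\mu, \sigma$ auditable on the raw scale).

### Pooling and inference

Features act as replicates: a subindex's sample for group $g$ is the vector
of its member features' $z_{fg}$, and the multipurpose index pools all
features.  Features are never re-weighted (a `weight` column is accepted
but defaults to 1 and is flagged experimental).  On each pooled set the
package computes:

* the **tie-corrected Kruskal–Wallis** statistic
  $H = \left[\tfrac{12}{N(N+1)} \sum_g n_g (\bar R_g - \tfrac{N+1}{2})^2\right]
  / \left[1 - \tfrac{\sum_t (t^3 - t)}{N^3 - N}\right]$
  on pooled mid-ranks, with the asymptotic $\chi^2_{k-1}$ upper-tail p;
* **rank epsilon-squared** $\varepsilon^2 = H/(N-1)$;
* a **Monte Carlo permutation p**: pooled replicates are randomly
  reassigned to groups (sizes preserved) $B$ times and
  $\hat p = (1 + \#\{H^* \ge H\})/(B+1)$;
* **Dunn pairwise comparisons** on the pooled ranking, with the
  tie-corrected standard error and two-sided normal p-values, adjusted by
  **Holm's step-down** within one index's family of pairs;
* **rank-biserial correlations** $r_{rb} = (\text{favorable} -
  \text{unfavorable})/(n_i n_j)$ over all cross pairs, ties half-credited.

Tie correction is *always* applied in both H and the Dunn SE — with handfuls
of replicates and exact z ties, the corrected and uncorrected statistics
differ materially (11.45 vs 10.65 for the reference nephrotoxic subindex).

```{r}
ft <- read_feature_table(system.file("extdata", "table1_carp_pfoa.csv",
                                     package = "mbindex"))
reports <- analyse_table(ft, B = 2000, seed = 1)
summary_tables(reports)$omnibus[, c("index", "H_rounded", "p_rounded",
                                    "epsilon_sq_rounded")]
```

## Numerical choices

**Exact ties are load-bearing.**  Three glomerular features of the
reference table share the pattern $(x, x, y)$ — mathematically all three
z-score to $(-1/\sqrt3, -1/\sqrt3, 2/\sqrt3)$ and must pool as a 6-fold and
a 3-fold tie, which the tie corrections then consume.  Standardising raw
floats breaks these ties in the last ulp and visibly shifts H.
`zscore_feature()` therefore first maps each feature's values affinely onto
$[0, 1]$ — a mathematical no-op for z-scores (they are affine-invariant),
but exact in floating point for affinely equivalent patterns, so equal
patterns yield bitwise-equal z rows.  No jitter is ever added; exact ties
in raw values stay exact in z.

**Permutation counting.**  $H^* \ge H_{obs}$ is evaluated with an absolute
slack of 1e−9 so permutations that tie the observed statistic (common under
heavy tie structure) always count.  The add-one estimator keeps
$\hat p > 0$; the interval around it is Clopper–Pearson binomial (the
conservative exact choice; the convention this mirrors uses a normal
approximation, which is anti-conservative at extreme counts).  Exhaustive
enumeration (`exact_permutation_p()`) provides ground truth for small
designs — 1680 assignments for group sizes 3/3/3 — and backs the Monte
Carlo calibration tests.

**ε² bootstrap CI.**  `analyse_index()` reports a seeded percentile
bootstrap CI (default 2000 resamples, within-group resampling) for ε².
With 3–12 replicates per group this interval is noisy and exploratory; it
is deliberately *not* validated against any published interval (the
reference analysis prints CIs whose method is unstated and which can
exclude the point estimate).

**Degenerate inputs.**  A zero-variance feature raises a typed
`mbi_constant_feature` condition (droppable with a warning via
`on_constant = "drop"`); an all-identical pooled sample leaves H undefined
(the tie correction divides by zero) and raises `mbi_degenerate_data`.

## The synthetic world

`generator_spec()`/`generate_table()` emulate a features × groups table of
representative values: value = baseline + scale·magnitude·offset + Gaussian
noise, with per-shape offset vectors over (reference, low, high) doses:

| shape            | offsets        | emulates                                  |
|------------------|----------------|-------------------------------------------|
| `null`           | (0, 0, 0)      | unresponsive endpoint                      |
| `monotonic_up`   | (0, 0.5, 1)    | dose-related activation                    |
| `monotonic_down` | (1, 0.5, 0)    | dose-related loss (direction −1)           |
| `u_shaped`       | (0, −1, −0.2)  | low-dose trough (direction −1)             |
| `inverted_u`     | (0, 1, 0.2)    | low-dose peak (endocrine-disruptor-like)   |
| `plateau`        | (0, 0, 1)      | high-dose-only damage                      |

Any explicit offset vector can be supplied verbatim; with noise → 0 and a
table's own values as offsets the generator reproduces that table exactly.
Noise is applied to the representative values directly — the generator does
*not* simulate per-animal variation (no per-fish data are published for the
reference cohort), so a green simulation says nothing about
individual-level inference.

The three-archetype world used in the acceptance simulation (5 plateau
nephrotoxic features, 2 + 2 inverted-U/U-shaped thyrotoxic features, 3
monotonic immunotoxic features; magnitude 2) is calibrated by effect size:
`noise_sd = 0.25` makes the simulated per-subindex $\varepsilon^2$ land on
the 0.8–0.9 scale the reference analysis reports.  At that signal strength
every index rejects essentially always at $\alpha = 0.05$ and the
multipurpose index's rejection rate is at least each subindex's.  **This
dominance is regime-dependent**: at weaker signal-to-noise (e.g. noise 0.5
at the same magnitude) the cleanest subindex saturates first — a 5/5/5
design with one group fully separated cannot fall under
$H = 9.375$ — while archetypes with *conflicting* group orderings (thyroid
peaks at low dose, nephron at high dose) dilute the pooled omnibus slightly
below it.  The aggregation argument for the multipurpose index is therefore
about *contrast coverage* (each subindex misses at least one pairwise
contrast; the pooled index covers both exposure contrasts), not uniform
omnibus power.

Under an all-null spec the asymptotic test on tiny groups is conservative
and discrete: enumeration of all 1680 rank assignments for sizes (3,3,3)
puts the attainable size near 0.011 at nominal 0.05, and the acceptance
suite checks simulated rejection never exceeds the 0.10 ceiling (plus an
a-priori Monte Carlo allowance).

## Quantification helpers

Two endpoint types the reference cohort needed de novo are reduced to
their computational cores: `area_fraction()` (classified-pixel area over
ROI area, from aligned binary masks; segmentation itself is out of scope)
and `effete_proportion()` (count ratio).  Multiple ROIs per group aggregate
by the unweighted mean of per-ROI fractions by default (ROIs as
replicates); `aggregate = "pixel_pooled"` pools pixel counts instead.
Masks load from PNG, ASCII PBM or 0/1 CSV; TIFF is not supported (no TIFF
reader among the package's dependencies).

## Reporting

`render_radar()` draws one closed polygon per group over one axis per
feature, subindex blocks occupying contiguous sectors in table row order,
radial range symmetric at $\pm\lceil 10\,\max|z|\rceil / 10$ so nothing is
clipped.  The figure is a *view*: the returned `radar_spec$series` is the
z-matrix itself, never a recomputation.  `run_pipeline()` (and the
`inst/cli/mbi.R` script) writes the z-score CSV, the two report TSVs, the
radar SVG and a log with seed, B and the direction vector; numeric outputs
are byte-stable for a fixed config and seed.

## Known limitations

* Z-scores are cohort-internal: scores standardised across this study's
  groups are not comparable across studies or species, and are not
  absolute toxicity thresholds.
* Representative values are consumed as given (means and medians mixed, as
  in the reference table); the package does not recompute them from raw
  per-animal data and group sample sizes behind each representative value
  are unknown to it.
* With three groups per feature, every z row is a deterministic function
  of the value pattern; replicates within an index are therefore not
  independent draws, and the inference layer's p-values should be read in
  the exploratory, hypothesis-driven spirit of composite indicators.
* Equal weighting is a deliberate neutrality choice, not an optimality
  claim; the weight column exists for sensitivity analyses.
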