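---
title: "Ecological habitat scoring of tumour sections: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecological habitat scoring of tumour sections: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecohab)
```

## The model

A tumour section, after upstream nuclear detection and classification,
is a marked point pattern: one point per nucleus, marked `cancer`,
`stromal` or `lymphocyte`. The package treats the microenvironment as an
ecological system in which stromal cells act as a *resource* for cancer
cells and lymphocytes as a predatory *hazard*, and asks how the spatial
arrangement of the two — not their overall abundance — relates to
outcome.

A square grid of side 100 µm is laid over the section. Each square `i`
holding at least one cancer cell is a *habitat* and is classified by two
thresholds proportional to its cancer-cell count `n_c`:

* resource high (R+) iff `n_str > k_str · n_c`, with `k_str = 0.5`;
* hazard high (H+) iff `n_lym > k_lym · n_c`, with `k_lym = 0.2`.

This yields four habitats: R+H+, R+H−, R−H+ and R−H−. The lymphocyte
constant is the smaller of the two because lymphocytes sit one trophic
level above their cancer "prey"; `k_str = 0.5` keeps reactive stroma at
the tumour margin from inflating the high-resource class, labelling
roughly a quarter of habitats R+, while `k_lym = 0.2` splits habitats
into two roughly even hazard groups.

The **local EcoScore** condenses the habitat counts into one balance of
cancer-favouring against cancer-inhibiting conditions:

    EcoScore = (R+H+ + R+H−) / R−H+

R+H− is the most permissive habitat, R+H+ favours immune-evading
clones that can still exploit the resource, and R−H+ is primarily
tumour-inhibiting. R−H− — typically the interior of tumour nests with
few non-tumour cells — carries little information about cancer–host
interaction and never enters the score.

The **global EcoScore** captures longer-range structure. Getis-Ord
Gi* applied to the gridded lymphocyte and stromal counts flags
significant spatial clusters ("hotspots") of each class; for every
habitat square the centre-to-centre distances to the nearest lymphocyte
and stromal hotspot are computed, and the score is

    GlobalEcoScore = Σ d_lym / Σ d_str

over the habitat squares. Values above 1 mean habitats sit closer to
resources than to hazards.

## Conventions and numerical choices

* **Units.** Everything internal is micrometres; pixel-unit inputs are
  converted at read time (default 5 µm/pixel). The coordinate origin is
  the top-left of the section with y increasing downward, the usual
  image convention; nothing downstream depends on that choice because
  all statistics are translation- and reflection-invariant.
* **Binning.** Grid squares are half-open intervals
  `[x0 + i·s, x0 + (i+1)·s)`, so a cell on a shared edge belongs to
  exactly one square.
* **Threshold direction.** "High" abundance means strictly greater than
  the threshold. With `k_lym = 0.2` this guarantees a square with fewer
  than five cancer cells still needs at least one lymphocyte to be H+;
  a `≥` rule would let zero lymphocytes count as high hazard there.
* **Two-section pooling.** When a patient has two sections, habitat
  counts are pooled, which equals a weighted average of section
  fractions with weights proportional to each section's number of
  classified squares. Pooling is the only weighting for which the
  patient-level summary is independent of how the tumour was split
  across sections.
* **Degenerate scores.** A zero denominator with a positive numerator
  yields `+Inf`, which every rank-based downstream step (percentile
  splits, Spearman correlations) handles naturally; `0/0` is undefined
  and the patient is excluded from score-based groupings with a
  warning, never silently imputed.
* **Percentile splits.** All cohort splits (EcoScore 40th percentile,
  mutational burden 45th, SCNA 25th/75th, resource median) use the
  inverse-ECDF quantile — the smallest attained value whose empirical
  CDF reaches the target — with the boundary going to the *low* group.
  An attained cutoff behaves predictably with ties and with infinite
  scores; the `≤`-low rule is applied identically everywhere.
* **Hotspots.** The Gi* neighbourhood is all squares whose centres lie
  within 100 µm, i.e. the square itself plus its rook neighbours at the
  default size. Counts are taken on the full rectangular grid covering
  the section, empty squares included, because a cluster is elevated
  relative to the whole section. One-sided upper-tail normal p-values
  are corrected across squares by Benjamini–Hochberg at α = 0.05. If
  every square has the same count the z-field is defined as identically
  zero: a featureless section has no hotspots. When a section has no
  hotspot of one class at all, the distances for that class are capped
  at the bounding-box diagonal and the sample flagged, keeping the
  global score defined while marking it as boundary-dominated.
* **Survival.** All analyses use five-year overall survival: times
  beyond 60 months are administratively censored at 60 (a reader
  option, on by default). Cox models use Efron tie handling. The
  optimal-cutpoint search tries every 5th percentile from 15 to 85 and
  declares significance at log-rank p < 0.003 — the 0.05 level
  Bonferroni-corrected for 15 candidates, applied at that printed
  precision rather than as 0.05/15 — selecting the smallest significant
  p. The Jonckheere–Terpstra trend statistic is the sum of pairwise
  Mann-Whitney counts over ordered group pairs (ties counted half),
  with an exact permutation p-value up to n = 10 and the tie-corrected
  normal approximation beyond; for more than two ordered groups the
  k-group log-rank test is the global test.

## The synthetic cohort generator

Real inputs are whole-slide coordinates from an upstream nuclear
classifier; the generator produces cohorts with the spatial and
survival structure the analysis assumes so that every stage is testable
without any download.

* **Cancer** cells follow a Thomas-type cluster process — Poisson
  parents, Gaussian offspring (s.d. 100 µm) — producing compact tumour
  nests whose interiors contain few non-tumour cells. The process is
  conditioned on at least one nest, since an empty section has no
  habitats, and positions are wrapped on the torus so realized counts
  keep their Poisson distributions.
* **Stroma** is uniform inside randomly placed circular patches
  (default radius 300 µm); patch number tunes the geometry from patchy,
  resource-poor sections to well-mixed, resource-rich ones.
* **Lymphocytes** mix a uniform background with a fraction |ρ| placed
  inside cancer nests (ρ > 0) or excluded from them (ρ < 0), so
  co-localization — the driver of high hazard — can be varied at fixed
  abundance.
* **Cohorts** place patients on a ladder of archetypes: stromal patch
  number rises and ρ falls across the cohort, moving the expected
  EcoScore monotonically. An optional `gap` parameter opens a hole in
  the ladder around its 40th-percentile point for stability analyses
  that require between-group separation to exceed within-patient grid
  noise. Survival times are exponential with the hazard multiplied by
  `exp(β_eco)` for patients the *pipeline itself* scores as high
  EcoScore (and optionally by a mutational-burden effect restricted to
  one resource stratum), so recovery tests exercise the full chain from
  coordinates to hazard ratios rather than a latent label. Censoring is
  independent uniform with the upper bound calibrated to the requested
  rate. Mutational burden is drawn through a Gaussian copula against
  realized lymphocyte abundance with a requested correlation (rejected
  above |r| = 0.95 as infeasible).

Default study-scale conditions are 20 patients with two 2000 × 2000 µm
sections of roughly 2,400 cells each, baseline hazard 0.03 per month
(median survival about 23 months, typical of advanced serous ovarian
carcinoma), β_eco = log 2 and 30% censoring. The robustness analyses
use larger 3000 × 3000 µm sections (about 5,100 cells) with `gap = 0.3`
so that the score separation at the dichotomization boundary is at
least twice the within-patient grid-shift noise. Simulation-based
checks use 500 patients × 100 replicates for Cox coverage and 300 (50
replicates) / 200 (200 replicates) patients for the threshold-search
recovery and null analyses — sizes at which the binomial noise of the
checked proportions is small against their acceptance margins.

What the generator does **not** emulate: nuclear segmentation error and
class confusion, tissue folds and staining artefacts, anisotropic or
curved tumour–stroma interfaces, vascular structure, and any dependence
of censoring on covariates. Passing tests therefore validate the
statistical machinery and its spatial logic, not the upstream image
analysis, and say nothing about biological effect sizes in real
cohorts.

## Open design points, resolved

* The exact hotspot statistic, neighbourhood and multiplicity control
  are choices here: Gi* on gridded counts is the standard gridded
  hotspot method, and BH control keeps power on sections with many
  squares where Bonferroni would be needlessly strict.
* The quantile estimator for percentile splits is unstated in most
  descriptions of such pipelines; inverse-ECDF was chosen so cutoffs
  are attained values (see above). Cohorts with heavy ties near a
  cutoff may split differently under interpolating estimators.
* Whether thresholds compare with `>` or `≥` is likewise a choice;
  `>` is implemented for the small-count reason above.
* For >2 ordered survival groups (the SCNA three-group split) the
  global k-group log-rank test is used rather than a trend test.
* Multivariate Cox covariate sets are configuration, not fixed logic:
  `cox_fit()` takes any covariate list.

## Limitations

* EcoScores are undefined on sections without cancer-containing
  squares and degenerate (0/0) when a section has no R−H+ habitat and
  no R+ habitat; both cases are surfaced, not imputed.
* The global EcoScore depends on the hotspot significance level and is
  capped by section geometry when a class has no hotspots; flagged
  samples should be interpreted with care.
* The threshold search controls family-wise error under the null but,
  like any optimal-cutpoint procedure, the selected percentile's effect
  size is optimistic without external validation; validating the chosen
  percentile in an independent cohort is the intended use.
* At the default 100 µm square size, squares average only a few dozen
  cells; classifications of individual squares are noisy, and only
  cohort-level aggregates are meant to be interpreted.
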