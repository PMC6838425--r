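# ecohab

Ecological habitat scoring of tumour histology from classified cell
coordinates.

High-grade serous ovarian carcinoma sections, after automated nuclear
detection and classification, reduce to a marked point pattern: cancer,
stromal and lymphocyte nuclei with coordinates. `ecohab` treats the
microenvironment as an ecological system — stromal cells as a *resource*
for the tumour, lymphocytes as a predatory *hazard* — and quantifies the
spatial balance between the two. It is aimed at computational
pathology / tumour-ecology groups who have cell coordinates and clinical
follow-up and want reproducible habitat scoring and survival
stratification.

## The method

A 100 µm square grid is laid over each section. Every square with at
least one cancer cell is a *habitat*, classified by thresholds
proportional to its cancer count `n_c`: resource-high (R+) iff
`n_str > 0.5 · n_c`, hazard-high (H+) iff `n_lym > 0.2 · n_c`. The four
habitats combine into the **local EcoScore**

```
EcoScore = (R+H+ + R+H−) / R−H+
```

(R−H−, the nest interior, is excluded). Getis-Ord Gi* hotspot detection
on the gridded lymphocyte and stromal counts yields the **global
EcoScore**, `Σ d_lym / Σ d_str`, the ratio of summed nearest-hotspot
distances over the habitat squares. Cohorts are dichotomized at the
40th percentile of the local score; survival machinery includes
Kaplan-Meier/log-rank/Cox (Efron ties, five-year overall survival), a
Bonferroni-corrected optimal-percentile threshold search (15 candidates,
p < 0.003), resource-stratified prognosis of genomic measures, and
Jonckheere/Wilcoxon/Spearman association tests. A marked point-process
simulator (Thomas-process tumour nests, patchy stromal fields, tunable
cancer–lymphocyte co-localization, survival tied to the
pipeline-computed groups) makes every stage testable end to end.

## Worked example

```r
library(ecohab)

sl <- simulate_slide(slide_sim_params(rho = 0.3), patient_id = "P1", seed = 3)
sl
#> <slide_cell_map> patient P1 section S1: 1941 cells (cancer 737, lymphocyte 392, stromal 812)

hm <- habitat_map(sl)                     # 100 um grid, k_str 0.5, k_lym 0.2
hm
#> <habitat_map> patient P1 section S1: 316 occupied squares (RpHp 4, RpHm 9, RmHp 44, RmHm 40, none 219)

local_ecoscore(summarize_habitats(hm))
#>   patient_id  ecoscore
#> 1         P1 0.2954545

run_sample(sl)$global_ecoscore
#> [1] 0.3257726
```

Of the 316 occupied squares, 97 contain cancer cells and are habitats.
The local EcoScore 0.30 means pro-tumour habitats (R+H+ + R+H− = 13)
are heavily outnumbered by tumour-inhibiting ones (R−H+ = 44): a
hazard-tilted section, consistent with the positive lymphocyte
co-localization (`rho = 0.3`) it was simulated with. The global score
0.33 < 1 points the same way — habitat squares sit much closer to
lymphocyte hotspots than to stromal ones.

The `analysis/` scripts chain the full workflow on a simulated
20-patient cohort — `01_simulate.R` through `05_survival.R` — writing
tables under `results/`. For example:

```
$ Rscript analysis/02_habitats_ecoscore.R
20 patients scored; EcoScore cutoff (40th pct) = 0.803
groups: 8 low / 12 high EcoScore; 10 low / 10 high resource
combined EcoScore x mutational-burden: 6 aggressive
```

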