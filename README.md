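# metaboextract

Statistical evaluation of sample-extraction procedures for untargeted
LC-HRMS metabolomics, built for the setting where six extraction methods
(one-phase `I`/`II`, two-phase `III`/`IV`, and bead-homogenized variants
`III_B`/`IV_B`) are compared on zebrafish-larvae extracts across four
analytical runs (Phenyl-Hexyl / HILIC × positive / negative ionization).

Starting from a peak-picked feature table (features × samples peak areas
with `NA` = not detected), the package provides:

* **Pooled-QC drift correction** — per-feature multiplicative drift
  estimated by lowess of log QC area on injection order (QC-RLSC style),
  normalized to median 1 over the QC injections.
* **Univariate statistics** — one-way ANOVA across groups
  (`F = MS_between / MS_within`), Welch's t contrasts against the
  reference extraction, Bonferroni correction `p_adj = min(1, m·p)`, star
  categories, and detected-feature counting.
* **Targeted panel evaluation** — 5 ppm / 10 s matching of internal
  standards and molecules of interest (MoInt) to features, normalization
  to the reference extraction's mean area, and mean / SD / CV summaries
  (`CV% = 100·s/x̄`).
* **PC-DFA** — ANOVA-gated feature selection, centered PCA by SVD,
  Kaiser–Guttman component retention (eigenvalue > mean eigenvalue,
  minimum two components), Fisher discriminant axes maximizing
  `|W_b| / |W_w|`, nearest-centroid classification, and Monte Carlo
  cross-validation reporting accuracy and Cohen's
  `κ = (p_o − p_e)/(1 − p_e)`.
* **Pathway analysis** — exact hypergeometric over-representation
  `P(X ≥ k)` and topological impact as the hit share of total
  relative-betweenness centrality.
* **Decision matrix** — a qualitative per-method scorecard (feature
  count, panel recovery, panel CV) as ratios to the cross-group median,
  rendered as ordinal arrows.
* **Synthetic data** — a seeded generator with recorded ground truth
  (log-normal baselines, multiplicative noise and drift, left-censoring,
  group-specific effects) so every stage has a parameter-recovery test.

The bundled registry transcribes the published detection panel: 34
positive-mode and 16 negative-mode MoInt records (35 unique compounds, 31
with KEGG identifiers) plus nine internal standards across three spike
solutions.

## Worked example

```r
library(metaboextract)

cfg <- default_paper_scenario(seed = 42, n_features = 300)
sim <- simulate_feature_table(cfg)
sim$table
#> FeatureTable: 333 features x 37 samples
#>   run: RP_PHENYL_HEXYL/POS
#>   samples per group: I=5 II=5 III=5 IV=5 III_B=5 IV_B=5 QC=7
#>   missing areas: 1956 (15.9%)

reg <- read_registry(moint_registry_path())
lib <- read_pathway_library(pathway_library_path())
bundle <- run_pipeline(sim$table, reg, pathway_library = lib,
                       mccv_iter = 200, seed = 42)

bundle$scorecards[, c("group", "feature_count", "moint_area",
                      "moint_cv_pct")]
#>   group feature_count moint_area moint_cv_pct
#> 1     I         258.0  1.0000000     9.799402
#> 2    II         258.0  0.8625039    17.301979
#> 3   III         233.0  1.4281133    14.757160
#> 4 III_B         313.0  2.2063194    19.758355
#> 5    IV         231.8  1.3941047    15.045004
#> 6  IV_B         313.0  2.1982794    19.062090
```

Reading the scorecard: the two-phase methods (III, IV) detect fewer
features than the reference one-phase method I (lipophilic metabolites
are lost to the discarded chloroform phase) but recover the MoInt panel
~1.4× better (amino-acid gain); bead homogenization (`_B`) yields the
highest feature counts and recoveries at the cost of the highest CVs;
extraction II pairs reference-level counts with the worst one-phase
precision. The `*_arrow` columns condense the same numbers into the
five-level ordinal scale of the final decision matrix.

```r
bundle$mccv
#> Monte Carlo cross-validation: 200 iterations, 30% held out
#>   mean accuracy: 0.421   Cohen's kappa: 0.305
```

Six-class accuracy is modest because extractions III and IV (and III_B
vs IV_B) are statistically identical in this scenario by construction;
collapsing the pooled confusion matrix to the three method families
(one-phase / two-phase / bead-homogenized) gives accuracy 1.0 — the
separation the multivariate analysis is meant to show.

```r
head(as.data.frame(bundle$pathways), 4)
#>                       pathway size hits            p impact
#> 1 Aminoacyl-tRNA biosynthesis   12   12 6.083461e-05    0.0
#> 2           Purine metabolism    6    5 1.040970e-01    1.0
#> 3          Lysine degradation    5    4 1.871089e-01    0.7
#> 4       Pyrimidine metabolism    3    2 5.150060e-01    1.0
```

The top pathway illustrates why enrichment and impact are reported
together: aminoacyl-tRNA biosynthesis collects every amino-acid hit
(strong p-value) but its pathway graph carries no centrality, so its
topological impact is 0.

## Command line

```sh
Rscript -e 'metaboextract::run_cli()' simulate --seed 1 \
    --n-features 300 --out-prefix sim
Rscript -e 'metaboextract::run_cli()' run --in-areas sim_areas.csv \
    --in-samples sim_samples.csv \
    --registry "$(Rscript -e 'cat(metaboextract::moint_registry_path())')" \
    --out-dir results/
```

Subcommands: `simulate`, `correct`, `stats`, `targeted`, `pcdfa`,
`pathways`, `run`.

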