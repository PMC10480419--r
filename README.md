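# fidelitr

Rank-correlation benchmarking of preclinical cancer models against the
tissues they are meant to represent.

Cancer cell lines and patient-derived xenografts (PDXs) only imperfectly
recapitulate the transcriptomes of human tumors and non-diseased tissues,
and the degree of fidelity depends on the model class, the tissue, and the
gene set you look at. `fidelitr` is for computational biologists who need
to score that fidelity reproducibly: it takes a genes × samples expression
matrix (raw counts + gene lengths, or TPM) and a sample-metadata table,
and answers *how strongly does each model correlate with each tissue
group, is a model's own tissue of origin the group it correlates with
most, which model class wins per tissue, and which individual genes and
gene sets does a model reproduce or miss?*

## The statistics

For model sample *m* and tissue group *g* (a tissue × disease-state cell
of the tissue cohort), the package computes pairwise Spearman correlations
ρ(*m*, *t*) against every tissue sample *t* in *g* over a chosen gene
subset and summarises them as the per-model median
ρ̃<sub>m,g</sub> = median<sub>t∈g</sub> ρ(*m*, *t*). On top of this it
builds:

* **matched-origin specificity** — the percentage of models whose
  top-ranked group (by ρ̃, strict ties) is their own matched tumor group;
* **model-class comparisons** — Wilcoxon rank-sum tests (Mann–Whitney U)
  of cell-line vs PDX ρ̃ per tissue group, Bonferroni-corrected within the
  family;
* **gene subsets** — top-*k* most-variable genes of a reference cohort,
  tumor-purity-correlated genes (per-cohort Spearman vs purity, BH,
  |ρ| ≥ 0.3, unioned), and tissue-specific high/low sets from z-scores of
  per-tissue means;
* **per-gene classification** — quantile-paired per-gene correlation
  between a model group and a tissue group, classified at p < 0.05, with
  hypergeometric over-representation of classes against GMT collections.

A negative-binomial synthetic-cohort generator (`simulate_cohort()`)
provides tissue identity signals, tumor-purity admixture and tunable
model drift with full ground-truth labels, so the entire pipeline is
testable end to end without external data.

## Worked example

```r
library(fidelitr)
library(dplyr)

sim     <- simulate_cohort(sim_config(seed = 1))   # 3 tissues, 2000 genes
tpm     <- counts_to_tpm(sim$counts)
records <- model_to_tissue(tpm, sim$metadata)      # full gene set

specificity(records)
#> <specificity_summary> gene subset 'all'
#> # A tibble: 3 × 3
#>   model_type percent_best_match n_models
#>   <chr>                   <dbl>    <int>
#> 1 cell_line                 100       90
#> 2 pdx                       100       90
#> 3 all                       100      180

compare_model_types(records) %>%
  filter(disease_state == "tumor") %>%
  select(tissue_group, median_rho_cell_line, median_rho_pdx, U, p_adj, winner)
#> # A tibble: 3 × 6
#>   tissue_group median_rho_cell_line median_rho_pdx     U    p_adj winner
#>   <chr>                       <dbl>          <dbl> <dbl>    <dbl> <chr>
#> 1 tissueA                     0.707          0.750  1800 7.38e-10 pdx
#> 2 tissueB                     0.702          0.746  1800 7.38e-10 pdx
#> 3 tissueC                     0.701          0.745  1800 7.38e-10 pdx

length(purity_gene_union(purity_correlated_genes(tpm, sim$metadata)))
#> [1] 227
```

Every model ranks its matched tumor group first (specificity 100% for
both classes here — the generator's default drift makes both classes
recognisable, just unequally faithful), and PDXs (drift sd 0.3)
significantly out-correlate cell lines (drift sd 1.0) in every tumor
group. The detector flags 227 genes, the 200 ground-truth
purity-responsive genes plus a ~1.5% false-flag rate. `tidy()`,
`glance()` and `autoplot()` methods on the result objects give per-model
tables and heatmap/violin views; `run_pipeline(run_config(), out_dir)`
chains every stage and writes TSV/JSON outputs with a checksummed
manifest.

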