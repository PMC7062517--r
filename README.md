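# balchimera

Donor-versus-recipient chimerism of airway macrophages from sex-mismatched
lung-transplant bronchoalveolar lavage (BAL) droplet scRNA-seq — as a tested,
reusable R pipeline with a ground-truth simulator.

## The problem

After lung transplantation, the airway macrophage (AM) pool of the graft can
either self-maintain from donor-derived cells or be replaced by recipient
monocytes. In a sex-mismatched transplant the two genotypes are separable
from transcription alone: **XIST** (the X-inactivation lncRNA) is expressed
in female but not male somatic cells, and **RPS4Y1** (Y-linked ribosomal
protein S4) only in male cells. A cell with `XIST > 0, RPS4Y1 = 0` in a
female recipient of a male lung is recipient-derived; the mirrored pattern
marks donor cells. Counting these cells per BAL sample quantifies chimerism
— the fraction of AMs replaced by peripherally derived cells.

`balchimera` implements the full droplet-processing path needed for that
readout, plus a simulator with known ground truth so every stage is testable:

| stage | function(s) |
|---|---|
| synthetic chimeric droplet experiments (counts or reads) | `sim_config()`, `simulate_counts()`, `simulate_reads()` |
| barcode whitelist correction (Hamming-1, posterior ≥ 0.975), UMI filtering (`>10` Phred, no homopolymers) and directional UMI merging | `correct_barcode()`, `filter_umi()`, `correct_umis()`, `build_count_matrix()` |
| cell calling: nearest-rank 99th percentile of the top *expected-cells* totals, retain within an order of magnitude | `call_cells()` |
| QC: 3×MAD on four metrics, >20% mito / >50% ribo caps, <1% prevalence gene filter, mito/ribo family discard | `compute_qc()`, `mad_outliers()`, `hard_filters()`, `filter_genes()`, `drop_gene_families()`, `qc_pipeline()` |
| log-normalization, PCA, kNN-graph modularity clustering | `normalize_log()`, `pca_embed()`, `cluster_modularity()` |
| sex → origin calls and per-sample chimerism | `assign_sex()`, `map_origin()`, `summarize_chimerism()`, `estimate_chimerism_fraction()` |
| exact nonparametric statistics | `mann_whitney_u()`, `spearman_rho()` |
| Matrix-Market IO, config, CLI, end-to-end driver | `read_mtx_triplet()`, `write_mtx_triplet()`, `run_config()`, `run_pipeline()`, `cli_main()` |

The sex model behind `estimate_chimerism_fraction()`: each cell of the
matching sex expresses its sex transcript with Poisson rate λ, so it is
detected with probability `d = 1 − exp(−λ)`. With observed exclusive-positive
fractions `p_R`, `p_D`, the chimerism fraction is recovered as
`f̂ = (p_R/d_R) / (p_R/d_R + p_D/d_D)`, with a Wilson-style interval.

## Worked example

Four simulated sex-mismatched samples (female recipients of male lungs) at
true recipient fractions 0.85, 0.90, 0.90, 0.95:

```r
library(balchimera)
samples <- lapply(1:4, function(i) list(
  id = paste0("S", i), recipient_sex = "female", donor_sex = "male",
  sim = list(n_cells = 400, n_ambient_droplets = 800, mean_cell_umis = 500,
             mean_ambient_umis = 15,
             chimerism_fraction = c(0.85, 0.9, 0.9, 0.95)[i])))
res <- run_pipeline(run_config(samples, expected_cells = 400, seed = 11))
res$table
res$test
```

```
 sample recipient_sex donor_sex n_cells pct_xist_pos pct_rps4y1_pos
     S1        female      male     302        61.59          12.58
     S2        female      male     311        57.56           7.40
     S3        female      male     312        57.69           7.37
     S4        female      male     302        66.56           3.97
 pct_ambiguous pct_unassigned pct_recipient pct_donor
             0          25.83         83.04         16.96
             0          35.05         88.61         11.39
             0          34.94         88.67         11.33
             0          29.47         94.37          5.63

np_test (exact, two_sided): statistic 0, p = 0.02857
```

Reading this: `pct_xist_pos` / `pct_rps4y1_pos` are the percentages of all
QC-passing cells that are exclusively XIST+ or exclusively RPS4Y1+ (they do
not sum to 100 because ~30% of cells drop both transcripts — the same reason
only ~60% of cells could be sex-matched in real BAL data). Among assignable
cells, the recipient share tracks the simulated truth. The exact
Mann-Whitney U test (n = 4 vs 4, U = 0, p = 0.029) confirms recipient
percentages exceed donor percentages across samples — the majority of AMs
are peripherally derived.

A command-line interface wraps the same stages
(`simulate | demux | callcells | qc | reduce | assign | summarize | stats |
run`):

```sh
Rscript inst/cli/balchimera run --config run.json --out outdir --seed 11
```

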