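---
title: "Methods: sex-transcript chimerism from droplet scRNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-transcript chimerism from droplet scRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(balchimera)
```

## The measurement

In a sex-mismatched lung transplant, recipient- and donor-derived cells in
bronchoalveolar lavage differ in sex and can be told apart by two robust,
tissue-independent transcripts: XIST, expressed from the inactive X
chromosome in female somatic cells only, and RPS4Y1, a Y-linked ribosomal
protein expressed in male cells only. The per-cell rule is deliberately
minimal — *expression greater than zero*, applied to raw UMI counts of
quality-passing cells:

| XIST | RPS4Y1 | sex call | origin (female recipient, male donor) |
|---|---|---|---|
| >0 | 0 | female | recipient |
| 0 | >0 | male | donor |
| >0 | >0 | both | ambiguous (doublet / ambient contamination) |
| 0 | 0 | neither | unassigned (dropout) |

Percentages of exclusively-XIST+ and exclusively-RPS4Y1+ cells are reported
over **all** QC-passing cells in a sample, so the two columns do not sum to
100: at typical BAL sequencing depth a third or more of cells drop both
transcripts. The recipient/donor split is reported separately among
assignable cells only, and is undefined (not 0/0) when nothing is
assignable. Double-positive cells form their own "ambiguous" class and are
excluded from the split; the upstream literature does not say how
double-positives were handled, and folding them into either side would bias
the split in an unknown direction.

## The dropout model and the corrected estimator

The simulator (and the estimator derived from it) models each sex transcript
as Poisson with rate λ per expressing cell, so the probability a cell of the
matching sex is detected is $d = 1 - e^{-\lambda}$. For a chimerism fraction
$f$ (recipient share of true cells), the expected assignable fraction is

$$P(\text{assignable}) = f\,(1 - e^{-\lambda_R}) + (1-f)\,(1 - e^{-\lambda_D}),$$

which `expected_assignable_fraction()` returns in closed form and the
simulation converges to (this is one of the acceptance checks). Inverting
the same model, the dropout-corrected chimerism estimate from observed
exclusive-positive fractions $p_R, p_D$ is

$$\hat f = \frac{p_R/d_R}{p_R/d_R + p_D/d_D},$$

with a Wilson score interval computed on the recipient share among
assignable cells and mapped through the (monotone) correction. With equal
rates the correction cancels and $\hat f$ reduces to the raw split. The
estimator is consistent on simulated data; coverage of the 95% interval is
checked over 50 seeded replicates in the acceptance suite.

## Droplet processing rules

**Barcode correction.** Reads whose barcode is on the whitelist pass
unchanged. Otherwise every whitelist entry at Hamming distance exactly 1 is
scored by posterior $\propto$ abundance(candidate) $\times 10^{-q/10}$,
where $q$ is the Phred score at the mismatched base; the argmax is accepted
iff its normalized posterior is at least 0.975. The 0.975 cutoff is the
convention of the upstream droplet software generation this pipeline
mirrors; the source text cites quality and the barcode-count distribution
but no number.

**UMI handling.** A UMI is kept iff it is not a homopolymer and all bases
have Phred > 10 (strict). Within one barcode and gene, a UMI is merged into
another at Hamming distance 1 with *strictly* greater read support, in a
single pass over UMIs in descending (read support, lexicographic) order —
strictness means equal-support pairs never merge, and the fixed order makes
merge chains deterministic. A (barcode, UMI) pair observed with several
genes goes to the gene with most reads and is dropped entirely on a tie;
the source is silent here and dropping is the conservative choice. Each
surviving distinct (barcode, UMI, gene) triple contributes exactly one
count.

**Cell calling.** With an expected cell count $E$ (10,000 at full scale;
hundreds at desk scale), the robust maximum is the nearest-rank 99th
percentile of the top $\min(E, n)$ barcode totals, and every barcode with
total $\ge$ robust_max/10 (inclusive) is called. Nearest-rank is exact on
integer totals and needs no interpolation convention; "within an order of
magnitude" is read as the inclusive lower bound. The rule is scale-invariant
and monotone, and on >10× bimodal simulations it recovers the true cell set
exactly.

**Quality filtering.** Four per-cell metrics — library size, genes
detected, % mitochondrial counts, % ribosomal-protein counts — are computed
once, over *all* called cells, before any removal (so the MAD statistics
match the all-cells wording). A cell is an outlier if any metric deviates
from its median by more than 3 × raw MAD (no 1.4826 consistency factor: the
rule is a literal reading, not a normal-theory z-score). The literal text
says "higher than", which could mean one-sided; both readings are
implemented (`two_sided = FALSE` gives the high-side-only rule) and the
two-sided literal-deviation reading is the default. A MAD of zero flags
every cell off the median, which is the natural limit of the rule. Hard caps
(>20% mito, >50% ribo, strict) are applied to the survivors as a separate
logged stage — the source applies both rules in two passages, so both run,
each with its own count. Genes detected in <1% of cells are then removed,
and finally all mitochondrial (`MT-`) and ribosomal-protein (`RPS`/`RPL`)
genes are discarded before normalization so the abundant families cannot
drive clustering. Family membership is by name prefix — reproducible with no
annotation download — with one deliberate exception: XIST, RPS4Y1, CD68 and
MARCO are always family "other". RPS4Y1 is nominally a ribosomal-protein
gene, but removing the male marker would destroy the assay; the side effect
is that RPS4Y1 counts are excluded from % ribosomal. Sex calls are made on
the cell-QC-passing matrix *before* the gene-level filters, so a sex
transcript that is lowly prevalent in a small sample cannot be silently
deleted by the 1% rule.

**Normalization, embedding, clustering.** Counts are library-size
log-normalized, $\ln(1 + 10^4 \cdot c_{gj}/L_j)$ — the source names the
normalization step but not the formula, so the convention of the named
downstream framework generation is used. PCA is a gene-centered SVD with
each component's sign fixed by its largest-magnitude loading, making the
embedding bit-reproducible. Clustering is greedy modularity maximization on
an unweighted union kNN graph built on Euclidean distance in PC space. The
source sentence conflates t-SNE and modularity clustering; here t-SNE is
treated as visualization only (out of scope) and communities are found on
the PC graph, where "cell–cell distance matrix constructed on these
principal components" is literal. Defaults: 10 components, 15 neighbors.
Note the usual resolution behaviour of modularity on sparse graphs: at
small k a homogeneous group may split into sub-communities (two clean
Gaussian blobs resolve exactly at the default k = 15, but k = 10 can split
one blob).

## What the simulator emulates — and what it does not

`simulate_counts()` draws, per droplet: a log-normal library-size target
(mean 1,000 UMIs for cells, 20 for ambient droplets, sdlog 0.3); Poisson
sex-transcript counts in cells of the matching sex only (default rate 1.2,
i.e. ~70% detection, the ballpark at which a majority but far from all real
BAL cells could be sex-matched); Poisson CD68/MARCO markers in the
macrophage population (90% of cells — BAL is AM-dominated); and a
multinomial background over a 200-gene panel whose weights put 10% of
counts on 13 `MT-` genes and 25% on 20 `RPS`/`RPL` genes, with two disjoint
background programs separating macrophage from non-macrophage cells.
`simulate_reads()` expands counts into reads with per-droplet-unique UMIs,
1 + Poisson(mean − 1) duplicate reads per molecule, and substitution-only
per-base errors (default 0.005) with lowered Phred at each error base —
matching the Hamming-distance correction rules downstream. The cohort
composition is exact (round(f·n) recipient cells), so parameter-recovery
error comes from dropout and QC subsampling, not cohort sampling.

Deliberately **not** emulated: ambient droplets carry no sex transcripts by
default (contamination is configurable but off, isolating the assignment
logic), no indels, no chemistry-accurate read layout, no doublets, no
between-sample batch effects, no negative-binomial overdispersion (Poisson
gives the closed-form dropout oracles; real data are overdispersed). A green
simulation test therefore establishes correctness of the *rules*, not
robustness to every artifact of real libraries — in particular the
ambiguous-cell class is essentially empty in default simulations, whereas
real data contain doublets.

## Numerical and determinism choices

All randomness flows from one root seed; per-sample streams are derived by
fixed integer arithmetic, and simulation functions restore the caller's RNG
state. Exact Mann-Whitney p-values come from complete enumeration of all
$\binom{m+n}{m}$ assignments when $m+n \le 12$ (924 at the cap; the relevant
group sizes are 4–9 per arm), with midrank ties handled exactly and
two-sided $p = \min(1, 2\times$ smaller tail$)$; beyond the cap a
tie-corrected normal approximation with continuity correction is used. The
U convention counts $x_i < y_j$ pairs; the mirrored convention changes U to
$mn-U$ and no p-value. Exact Spearman p-values enumerate all $n!$ rank
permutations for $n \le 8$. Percentages are computed at full precision and
rendered at 2 decimals; the written chimerism table is byte-identical across
reruns with the same config and seed. Matrix-Market output is written as
`coordinate integer general` with row-major triplets so rewrites are
byte-identical; reading uses the standard Matrix parser.

## Known limitations

- The zero-threshold sex rule has no shrinkage against ambient
  contamination; with contaminated ambient profiles the ambiguous class
  grows and the raw split biases toward the contaminating sex. The
  dropout-corrected estimator assumes exclusive expression.
- The dropout correction needs λ values; in practice these must be
  estimated from same-sex reference samples, which the pipeline does not
  automate.
- Greedy modularity is resolution-limited; it is used as the deterministic
  default, not as the best available community detector.
- The MAD rule's sidedness in the original analysis is unknowable from the
  text; both variants are provided and results at desk scale are reported
  with the two-sided default.
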