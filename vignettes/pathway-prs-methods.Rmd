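---
title: "Pathway-specific polygenic scores for brain structure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-specific polygenic scores for brain structure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`pathprs` computes clumping-and-thresholding polygenic scores. Given
discovery-GWAS per-SNP effects $\hat\beta_j$ and P-values $p_j$, and a
target cohort with alt-allele dosages $g_{ij} \in [0,2]$, the score for
sample $i$ is

$$\mathrm{PRS}_i \;=\; \sum_{j \in W} \hat\beta_j\, g_{ij},$$

a weighted *sum*, not PLINK's per-allele average: the two differ by a
positive per-column factor, and every downstream association statistic is
invariant to affine rescaling of the score (a property the test suite
asserts), so the simpler definition is used. The weight set $W$ is built
by composing five filters in a fixed order — pathway restriction (pathway
scores only), APOE-region masking, P-thresholding, LD clumping — and the
resulting score grid is crossed with every ROI in a covariate-adjusted
ordinary-least-squares regression:

$$y_{\mathrm{ROI}} = \alpha + \gamma\,\mathrm{PRS} + X\delta + \varepsilon,$$

with $X$ = age, sex, intracranial volume, site, genotyping array and the
leading ancestry principal components. The reported quantities per cell
are $\hat\gamma$ (with t-based 95% CI and P-value), the incremental
$\Delta R^2 = R^2(y \sim X + s) - R^2(y \sim X)$ on identical
complete-case rows, a Benjamini–Hochberg q-value, and a comparison of
$\Delta R^2$ against the same quantity for a score built from the APOE
region alone.

Modelling assumptions worth making explicit: effects are additive in
dosage; the discovery betas are on a single per-A1-allele scale (odds
ratios must be log-transformed before ingestion); LD in the target cohort
is an adequate stand-in for discovery LD when clumping; and ROI measures
are conditionally Gaussian enough for OLS inference.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `maf_min` | 0.01 | frequency | variants with MAF < 1% are removed |
| `variant_call_min` | 0.98 | fraction | SNP call rate < 98% removed |
| `sample_call_min` | 0.97 | fraction | samples < 97% complete removed |
| `hwe_p_min` | 1e-4 | P-value | HWE χ² P below this removed |
| `roi_outlier_sd` | 2.5 | SD | ROI values beyond ±2.5 SD set missing |
| `r2_max` | 0.2 | r² | clumping removes neighbours above this |
| `window_kb` | 500 | kb | hard clumping window, both sides |
| `p_thresholds` | 0.5 … 1e-7 | P | score ladder; primary 0.001 |
| `gene_window_kb` | 0 | kb | SNP-to-gene flank; 0 = gene body only |
| `n_pcs` | 5 | — | ancestry PCs recomputed post-QC |

The threshold ladder follows the protocol's stated secondary thresholds
read literally: $0.1\times10^{-5} = 10^{-6}$ and
$0.1\times10^{-6} = 10^{-7}$. The gene window defaults to 0 kb because a
flanking window is an assumption; the flag makes window-based annotations
reproducible without baking one in.

## Design choices where the design was open

* **Clump within the pathway, not genome-wide.** Whether pathway scores
  inherit genome-wide index SNPs or are clumped inside the restricted SNP
  set is ambiguous in the protocol ("clumped and scored as described
  above"). Clumping within the pathway keeps the best *pathway* SNP per
  LD block rather than discarding a pathway SNP because a non-pathway
  neighbour had a smaller P; `clump_scope = "genomewide"` preserves the
  alternative.
* **LD from the target cohort.** No external reference panel: each
  dataset clumps against its own dosage correlations, which is why two
  cohorts end up with different post-QC SNP counts for the same pathway.
* **Boundary conventions.** P-thresholding is inclusive ($p \le P^T$);
  the APOE interval is closed; clumping removes neighbours with
  $r^2 > r^2_{max}$ strictly; ties in P during clumping break toward the
  smaller base position, making the output invariant to input order.
* **Sample filter before variant filters**, mirroring PLINK's
  sample-then-variant ordering; MAF is computed on the post-sample-filter
  matrix. The three variant predicates are evaluated on the same matrix,
  so their internal order cannot change the retained set (asserted as a
  property test).
* **HWE on hard calls.** Fractional dosages are rounded to {0,1,2} for
  genotype counting only; scores always use the raw dosages. Monomorphic
  sites return HWE $p = 1$ with a flag (there is no deviation to test);
  they are instead caught by the MAF filter.
* **Outlier removal is a single pass**: mean and SD per ROI come from all
  non-missing values before any removal, and removal is per-ROI, so a
  sample outlying on one ROI keeps its other measures.
* **Scores are z-standardized before regression** (default), so betas are
  per score-SD; `standardize = FALSE` restores raw per-score-unit betas.
  P-values and $\Delta R^2$ are identical either way.
* **FDR blocks** are (ROI family × APOE mode × threshold): all score
  labels × all family ROIs corrected together, families and APOE modes
  corrected separately, matching the "scores × family ROIs" correction
  scheme; `fdr_scope = "joint"` pools families for sensitivity analyses.
* **t-quantile CIs**, not ±1.96·SE: exact small-sample behaviour and
  consistency with standard regression output.

## Numerical details and degenerate inputs

PCs are computed by SVD of per-variant standardized, mean-imputed dosages;
components are sign-fixed (largest-magnitude loading positive) and the
requested count is truncated to the numerical rank with a warning.
Zero-variance variants yield undefined dosage correlations; clumping
defines their $r^2$ as 0, so a constant variant can never remove
neighbours. A constant score or rank-deficient design is flagged
unestimable and excluded from its FDR block's $m$ — never silently
pseudo-inverted; `delta_r2()` alone remains defined under collinearity
(the nested fits coincide, $\Delta R^2 = 0$). Empty score columns (no SNP
survives the filters) are recorded as all-missing with
`n_snps_used = 0` rather than aborting the grid. Missing dosages inside a
score are mean-imputed as twice the alt-allele frequency (the PLINK
`--score` convention); `missing_policy = "omit"` skips the term.

## What the synthetic generator emulates — and what it does not

`sim_config()` defines a desk-scale generative law with the structural
features the analysis relies on:

* **LD-block genotypes**: haplotypes per block from an exchangeable
  latent Gaussian (correlation `within_block_r`, default 0.8) thresholded
  at each variant's MAF quantile; dosage = sum of two haplotypes; blocks
  independent. This gives direct control over the $r^2$ clumping consumes.
* **A discovery GWAS** on an independent cohort from the same law:
  quantitative liability = planted effects × dosage + Gaussian noise,
  per-SNP marginal OLS betas and P-values. A quantitative liability
  rather than logistic case–control keeps the weights' scale irrelevant
  downstream (scores only need relative weights) at a fraction of the
  cost; a log-OR reading of the betas changes nothing but units.
* **Overlapping pathways and an APOE-like region**: the default three
  pathways copy the structure of the published gene-set table — two
  lipid/tau-like sets sharing genes and containing the large-effect
  region, one large immune-like set excluding it — with one planted
  large-effect SNP (default 0.3) at the region's start.
* **ROI phenotypes**: ROI = location + scale × (sign × effect ×
  standardized pathway component + covariate term + N(0, noise));
  `effect_size` is therefore a standardized coefficient (default 0.15
  where planted, the magnitude used in the power analyses). Opposite
  `sign` entries reproduce the older/younger direction-flip design.
  Ancestry PCs entering the covariates are computed from the simulated
  genotypes themselves, mirroring the real pipeline's circularity.

Deliberately *not* emulated: realistic human LD maps and recombination
(the exchangeable-block law has no decay with distance within a block),
demographic structure beyond what PCs can see, binary-trait
ascertainment, imputation uncertainty, and site/scanner effects on ROIs.
Passing tests therefore demonstrate the pipeline's statistical
correctness under its own assumptions, not performance on real cohort
data, whose headline regression estimates depend on restricted
individual-level inputs.

Default study conditions: 2000 target samples, 4000 discovery samples,
500 SNPs in blocks of 10 tiling 50 genes on one chromosome, MAF uniform
in (0.05, 0.5), 1% missing calls. The heavier properties scale this: the
type-I experiment uses 50 null cohorts of 1000 samples (no planted
effects, ten null ROIs) and checks the grid-wide fraction of cells at
p < 0.05; the power experiment uses 50 replicates of the default planted
design. The null experiment's scores are built at $P^T = 0.5$: under a
null discovery GWAS the 0.001 threshold admits ~0.5 SNPs in expectation,
which would leave most columns empty, and the type-I property does not
depend on the threshold. The threshold-trend experiment plants dense weak
effects (every SNP ~ N(0, 0.05)) so that lenient thresholds add true
signal, and checks per seed that $\Delta R^2$ rises from the stringent to
the lenient end of the ladder (endpoint comparison plus a positive
Spearman rank trend across the ladder) — with a finite evaluation cohort,
adjacent-threshold increments at the lenient end sit below estimation
noise, so strict elementwise monotonicity over all eight points is not
the operative statement of "more SNPs, more variance explained".

## Known limitations

* Clumping is greedy and single-threaded; for hundreds of thousands of
  SNPs an indexed LD lookup would be needed.
* No support for indels, multi-allelic sites, BGEN/PLINK-binary inputs,
  or X-chromosome dosage conventions.
* No relatedness pruning, heterozygosity checks or sex checks; the QC
  implemented is exactly the protocol's five filters.
* Strand-ambiguous (palindromic) SNPs are always dropped rather than
  frequency-resolved.
* OLS only: no mixed models, robust errors, or site-stratified
  meta-analysis.
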