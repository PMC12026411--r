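---
title: "Methods: cell type-specific eTR mapping with sceTR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell type-specific eTR mapping with sceTR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`sceTR` maps tandem repeat (TR) length variation to cell type-specific
pseudobulk gene expression in a two-cohort design. The unit of analysis
is the triple (TR locus, gene, cell type). The association model in
each cohort and cell type is ordinary least squares,

$$ y = W\alpha + g\beta + \epsilon, $$

with $y$ the gene's pseudobulk expression across samples, inverse-normal
transformed to a standard normal (ranks mapped to quantiles at
$r/(n+1)$, ties averaged), $g$ the summed repeat dosage — the sum of the
two allele repeat counts of the diploid genotype; for SNVs the
non-reference allele count — and $W$ the covariates. Classical
homoskedastic standard errors and a two-sided $t$ test give the
per-variant p-value. The transform makes effect sizes comparable across
genes and robust to expression outliers; because it is rank-based, any
strictly monotone distortion of the raw pseudobulk values leaves results
unchanged.

Per-cohort statistics are pooled with a DerSimonian–Laird random-effects
meta-analysis. We deliberately use the moment estimator and the normal
reference for the pooled $z$, with no small-sample (Knapp–Hartung)
adjustment, because that is how two-batch eQTL meta-analyses of this
kind are conventionally run; the calibration consequences at $k=2$ are
quantified below.

Downstream of association, the pipeline applies, in order: gene-level
Cauchy (ACAT) combination of TR p-values; Storey q-values across genes
within each cell type with significance at FDR < 5%; a pairwise
cell-type-specificity classifier; single-causal-variant fine-mapping on
the meta-analytic summary statistics; conditional analysis; and
enumeration-based colocalization against external trait summary
statistics.

# Tunable parameters

All thresholds live in `pipelineThresholds()` with these defaults, each
the standard value for this kind of study:

| parameter | default | meaning |
|---|---|---|
| `window` | 100000 bases | cis window on each side of the gene body (closed interval) |
| `mask_below`, `mask_above` | 30, 20 repeats | genotype masking window around the locus modal allele |
| `min_call_rate` | 0.90 | locus-level call-rate floor, after masking |
| `min_het` | 0.00995 | expected heterozygosity floor; equals a non-major allele frequency of 0.5% via $H = 1-\sum p^2$ |
| `hwe_p` | 1e-6 | exact binomial Hardy–Weinberg floor |
| `min_maf` | 0.01 | SNV minor allele frequency floor |
| `min_expressed_fraction` | 0.01 | fraction of cells expressing a gene for it to be testable in a cell type |
| `fdr` | 0.05 | Storey q-value significance level |
| `min_pip` | 0.7 | posterior inclusion probability for candidate causality |
| `min_pp_h4` | 0.8 | colocalization posterior floor |
| `min_r2` | 0.5 | LD floor between the sc-eTR and a cataloged GWAS variant |
| `genomewide_p` | 5e-8 | GWAS eligibility and conditional persistence threshold |
| `methylation_window`, `methylation_min_sd` | 5000 bases, 0.02 | CpG pairing distance and variability floor |

Boundaries are inclusive on the passing side (a call rate of exactly
0.90 passes), since the failing conditions are stated as strict
inequalities.

# The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
so every stage can be exercised with a known answer:

- **TR genotypes** follow a stepwise mutation model: each allele is the
  locus modal allele plus a signed sum of unit steps, the number of
  steps Geometric($1-p_{step}$), each step $\pm 1$ with equal
  probability, truncated at one repeat. The default
  $p_{step} = 0.3$ is a free parameter chosen to give the tight,
  mode-centred allele distribution seen in population TR callsets
  (over 97% of alleles within 10 repeats of the mode); real per-locus
  mutation parameters are unknown and not estimated here.
- **Tag SNVs**: each TR gets one tag SNV whose haplotype allele copies
  the indicator of the TR allele exceeding the mode and is flipped with
  a probability solved analytically (from the empirical haplotype
  moments) so the realized dosage $r^2$ hits `ld_target`. The default
  0.45 reflects the moderate LD typically observed between TRs and
  their best neighboring SNV. The maximum achievable $r^2$ against a
  binary indicator is bounded; if the target exceeds it, the flip
  probability is zero and LD sits at that bound.
- **Expression**: $y = W\alpha + g_c\beta + \text{batch} +
  N(0, \sigma)$ per gene, cell type and cohort, with $g_c$ the centred
  summed dosage, per-gene covariate loadings shared across cell types,
  a cohort intercept shift (default 0.2) emulating batch effects, and
  $\sigma$ = `noise_sd` (default 1). Effects are planted from an
  explicit `effect_table`, so shared, cell-type-specific and
  opposite-sign architectures are all expressible; a plant on a gene
  expressed in under 1% of cells in every cell type warns that it is
  untestable.
- **Covariates** (sex, age, 12 genotype-PC and 6 expression-PC
  surrogates) are generated directly as independent draws rather than
  derived from a PCA of the simulated genotypes — the analysis only
  requires that they enter $W$; the PCA itself is upstream plumbing.
- **Geometry**: loci sit on one artificial chromosome at 250 kb spacing
  with each gene's TSS 20 kb from its locus, so cis-window membership
  is exact by construction and windows of different genes do not
  overlap.
- **Methylation**: CpG sites 2 kb from a locus, with methylation a
  logistic transform of a baseline plus a linear repeat-dosage effect
  plus latent noise, keeping probabilities in $[0,1]$.
- **Truth sets**: caller/truth genotype pairs where the caller equals
  the truth minus a per-locus constant offset plus sporadic random
  errors, so offset scoring should adopt exactly the planted map.

What the generator does *not* emulate — and therefore what passing
tests do not establish about real data: read-level artifacts (stutter,
coverage, mapping bias), genuine population structure and relatedness
(the PC surrogates are noise, not confounders), LD beyond one tag per
TR plus the constructed ladders, non-normal expression noise,
cell-level count sparsity (pseudobulk only), and selection effects on
allele frequencies. Results on real cohorts additionally depend on the
genotyping engine's error process, which here is reduced to offsets and
sporadic errors.

# Numerical choices

- **ACAT tail**: the combined p-value is the Cauchy survival function
  of the weighted statistic; the summand $\tan((0.5-p)\pi)$ is
  evaluated as $1/\text{tanpi}(p)$, which is exact for small and
  near-one $p$, with the standard $1/(p\pi)$ stabilization below
  1e-15. Inputs outside $(0,1)$ are clipped to
  $[10^{-300}, 1-10^{-16}]$ with a warning.
- **Storey q-values** use a single fixed $\lambda = 0.5$ for
  $\hat\pi_0$ (deterministic; the smoother variant would add df choices
  the procedure does not need), and reduce exactly to
  Benjamini–Hochberg when $\hat\pi_0 = 1$.
- **HWE** at multiallelic loci collapses to heterozygote vs homozygote
  and uses the exact two-sided binomial test (tail summation, as
  `binom.test`) of the observed heterozygote count against
  $\mathrm{Bin}(n, 1-\sum p^2)$.
- **Masking granularity**: one out-of-window allele voids the whole
  diploid call — a summed dosage with one voided allele would be
  undefined.
- **Fine-mapping** maximizes the marginal likelihood of the
  one-causal-variant model over a prior-variance grid
  {0.001, 0.005, 0.01, 0.0225, 0.05, 0.1} (0.0225 = $(0.15\,
  \mathrm{sd}_Y)^2$ at $\mathrm{sd}_Y = 1$, the quantitative-trait
  prior also used for colocalization); PIPs are the softmax of the log
  ABFs at the selected value, so they sum to one exactly. Variants
  outside the 95% credible set are flagged `pruned`, not zeroed, so
  both views are available.
- **Colocalization** accumulates all hypothesis masses in log space;
  with a single shared variant the H3 configuration space is empty and
  its mass is exactly zero (handled as $-\infty$, not underflow).
- **Ties** are broken deterministically everywhere: lead/top selection
  by (p, coordinate, id); offset adoption by (score, smaller
  |offset|, negative first); modal alleles by the smaller allele.
- **Degenerate inputs** fail loudly: constant dosages, rank-deficient
  designs, all-equal expression vectors, empty tables and collinear
  conditioning variants ($r^2 > 0.999$) are errors, not silent NAs.
- **Coordinates** are 1-based closed inside the package (the
  `GRanges` convention); BED I/O converts to 0-based half-open at the
  boundary. The catalog-merge overlap fraction is measured against the
  candidate locus (the natural reading of "overlapped existing included
  loci by 66% or more"); a reciprocal mode is available.

# Design decisions in open territory

- "Observed heterozygosity" is implemented as frequency-based expected
  heterozygosity $1 - \sum p^2$, because the stated 0.00995
  correspondence to a 0.5% non-major allele frequency is exactly
  $2pq$; the direct heterozygote fraction is also reported.
- The specificity rule uses strict inequalities on both sides: a
  comparison with $p_{meta} = p_{origin}$ is neither shared nor counted
  toward specificity.
- Gene-level ACAT combines TR p-values for eTR discovery; the same
  machinery runs separately for SNVs.
- Fine-mapping consumes meta-analytic summary statistics (not
  per-cohort ones), and the one-causal-variant model removes the need
  for a full LD matrix — which is also why it sidesteps the known
  instability of multi-credible-set summary-statistic fine-mapping when
  multiallelic TR vs biallelic SNV LD is imperfectly represented.
- Conditional analysis runs per cohort with the conditioning dosage
  appended to $W$, then pools the two conditional estimates with the
  same DL meta.
- GWAS effect-allele alignment for SNVs: records matching with ref/alt
  swapped are harmonized with the study-2 sign flipped. Posterior
  colocalization masses depend on $z^2$ only, so this affects reported
  directions, not the H0–H4 partition.

# Problem sizes and calibration behaviour

The test suite and `scripts/acceptance.R` exercise the pipeline at
sizes chosen to make Monte-Carlo bands tight while staying lightweight:
null calibration on two cohorts of 500 samples and 200 genes; coverage
of a planted $\beta = 0.5$ at $n = 1000$ over 500 replicates;
fine-mapping over 200 windows of 21 variants at $n = 1000$;
colocalization over 100 replicate pairs of 30-variant windows;
specificity over 30 shared and 30 single-cell-type plants across 6 cell
types. Generator defaults (cohorts of 950 and 975, 28 cell types)
mirror the full-scale design and remain the package defaults.

One calibration property deserves explicit mention. Under the
permutation null the per-cohort OLS p-values are exactly uniform, but
the pooled two-study DL p-values are mildly conservative: truncating
$\tau^2$ at zero and using the normal reference at $k = 2$ yields an
empirical type-I error slightly below nominal (about 0.04 at
$\alpha = 0.05$ in our null simulations), and a
Kolmogorov–Smirnov test against uniformity can detect this deflation at
a few hundred tests. This is a property of the published pooling
procedure, not of this implementation — the per-cohort statistics pass
the same tests exactly — and it errs on the conservative side for
discovery.

# Known limitations

- Single causal variant per window ($L = 1$); allelic series and
  multiple independent signals fold into one credible set.
- No kinship/mixed-model adjustment; covariate surrogates stand in for
  genuine structure correction.
- TR effects are modeled as linear in summed repeat length;
  length-threshold ("binary switch") regulation is outside the model
  class.
- Colocalization assumes the two studies' LD comes from comparable
  populations; it is enumeration-based and sees only the supplied
  summary statistics.
- Methylation analysis treats probabilities as the phenotype after
  inverse-normal transformation, without a logit pre-transform.
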