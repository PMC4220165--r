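---
title: "Controlling population structure and platform bias in merged genotype cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Controlling population structure and platform bias in merged genotype cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Large association studies routinely merge genotype data collected at
different recruitment sites on different genotyping arrays. Principal
components computed on the merged genotype matrix are the standard device
for capturing genetic ancestry, but nothing in the mathematics restricts
them to ancestry: any systematic, many-variant pattern that separates
groups of samples will surface as a component. Three such patterns matter
in practice:

* **population structure** — the signal we want;
* **platform and site batch effects** — probe-level miscoding, differential
  missingness and imputation behavior that differ by array, and, because
  biobank participants are not randomized to arrays, are confounded with
  site and often with ancestry composition;
* **local genomic artifacts** — regions of extreme long-range LD such as
  the MHC/HLA region on chromosome 6 and the chromosome 8p23 inversion,
  which can capture an entire component on their own.

`pcstrat` implements two complementary strategies. The *conventional*
route filters variants carefully and then decomposes the merged sample
covariance matrix. The *projection* ("loadings") route sidesteps study-side
artifacts altogether: SNP loadings are estimated from an external,
artifact-free reference panel, and every study sample is projected onto
them. A platform effect that does not exist in the panel cannot enter the
loadings, so the projected scores carry ancestry but not batch structure —
and the association model needs fewer covariates (no site-platform factor),
saving degrees of freedom.

## Models

### Conventional PCA

Dosages are coded additively (0/1/2 copies of the alternate allele). Each
variant column is centered at its mean; under the default `patterson`
scaling it is also divided by `sqrt(p(1-p))`, `p` being half the mean
dosage, which puts every variant on the same drift-variance scale.
Missing calls are mean-imputed (zero after centering), which leaves column
means untouched. The samples-by-samples covariance of the standardized
matrix `Z` is eigendecomposed; sample scores are `U d` and the SNP loadings
are the corresponding variant-space singular vectors, recovered as
`Z'U d^{-1}`. The sample-space and variant-space decompositions are
mathematically equivalent; `fit_pca()` computes the former (cheaper when
markers outnumber samples) and the test suite pins the equivalence against
a dense SVD.

Variance-explained fractions are eigenvalues over the covariance trace, so
they sum to one over all components. `scree()` tabulates the leading
fractions; the default `k = 10` reflects the usual practice that the first
ten eigenvectors are the ones worth inspecting.

### Reference-panel projection

From a panel of `B` unrelated samples, the marker covariance
`Sigma = sum_a (X_a - Xbar)(X_a - Xbar)'` is decomposed and the top-k
eigenvectors `e_l` retained as SNP loadings, along with the per-variant
panel means `Xbar`. A study sample `X_j` receives the score

```
t_jl = (X_j - Xbar)' e_l
```

i.e. its centered genotype vector projected onto the l-th loading. The
panel covariance is left unstandardized by default (`center_only`), which
is the plain-covariance formulation of the method; eigenvectors are
invariant to the `1/B` normalization, and the stored eigenvalues adopt the
`1/B` convention. When the study set *is* the panel, `t_jl` reproduces the
panel's own conventional PCA scores exactly — this self-projection
identity is the mathematical heart of the method and is asserted to 1e-8
in the tests at a 200-sample by 2,000-variant scale.

Two practical complications are handled at the boundary:

* **variant matching**: study variants are matched to model variants on
  (chrom, pos), with alleles harmonized exactly as in `merge_cohorts()` —
  ref/alt swaps recode `d -> 2 - d`, strand complements pass through, and
  strand-ambiguous A/T and C/G SNPs are excluded because their orientation
  cannot be determined;
* **missingness**: the inner product is restricted to matched non-missing
  variants and rescaled by `M_model / M_used` per sample, keeping score
  magnitudes comparable across samples with different missingness. This
  rescale is a convention of this package (reference projection is usually
  run on complete imputed data); it is pinned by a test showing that
  masking 5% of genotypes moves scores by well under 5% RMS of the score
  spread.

## The variant-selection checklist

`apply_variant_qc()` runs five steps in a fixed order, each returning a
subset of the input variants and never touching surviving dosages:

| step | default | rationale |
|---|---|---|
| autosomes only | chrom 1–22 | sex chromosomes separate samples by sex, not ancestry |
| MAF | `> 0.05`, strict | rare variants carry little covariance signal and are noisy under platform error |
| missingness | `< 0.02`, strict | differential missingness is itself a platform signature |
| LD pruning | `|r| > 0.5`, 500 kbp window | redundant correlated variants overweight local genomic regions |
| region exclusion | HLA chr6:25–35 Mb, chr8 inversion chr8:6–16 Mb (build 37) | known long-range LD artifacts that can capture a component |

Numerical conventions worth stating: thresholds use strict inequalities, so
boundary cases are deterministic (MAF exactly 0.05 is removed). Pruning
thresholds the *magnitude of r*, not r²; the protocol literature is
ambiguous between the two readings and `ld_r_max` is configurable. The
greedy scan runs left to right within each chromosome, keeping the
earlier-position variant on conflict, with positional ties broken toward
the higher-MAF variant; the window is basepair distance between positions,
not a variant count. Zero-variance variants have undefined correlation and
never trigger a removal — they are flagged instead. The default exclusion
list is ordinary data shipped as a data.frame, replaceable by any BED file
(BED's 0-based half-open intervals are converted at the boundary; variant
coordinates are 1-based inclusive throughout).

## Diagnostics

`pc_genotype_correlation()` computes, per variant, the absolute Pearson
correlation between dosage and one score column. An ancestry component
correlates modestly but genome-wide; a component captured by a local
artifact shows a contiguous block of near-1 correlations.
`flag_artifact_regions()` makes the visual screen operational: sliding
1-Mb windows (quarter-window step) whose mean correlation exceeds 3 times
the genome-wide mean are merged and clipped to the variants they contain.
The window and fold defaults are screening values chosen once for this
package — the underlying protocol inspects the plots visually — and both
are tunable.

Ancestry assignment follows the median convention: per self-reported
group, the median (Q2) and SD of PC1 and PC2 define a box Q2 ± k·SD per
axis, with the historical multipliers k = 2 (African), 4 (European), 1
(Hispanic). A sample inside exactly one box takes that label; inside
several, `"ambiguous"` (the boxes genuinely overlap and we prefer honesty
over a priority order); inside none, `"unassigned"`. The box is the
literal reading of "median ± k·SD per axis"; an elliptical variant with
the same half-widths is available (`mode = "ellipse"`) and is necessarily
a subset of the box.

## Association and calibration

`logistic_gwas()` fits, per variant, a maximum-likelihood logistic
regression of the binary phenotype on dosage plus covariates (IRLS via
`stats::glm.fit`), reporting the 1-df Wald chi-square — the same test
PLINK's logistic scan reports. Samples missing a dosage are dropped for
that variant only. Separation is declared at `|beta| > 10` and
non-convergent or degenerate variants come back as flagged `NA` rows.
The genomic inflation factor is `median(chisq) / 0.4549364`. The two
covariate strategies being compared are: conventional scores plus a
site-platform factor, versus projection scores alone — the latter is the
more parsimonious model, and on simulated data both hold lambda near 1
under the null.

## The simulator

`simulate_cohort()` draws K populations under the Balding-Nichols model:
ancestral frequencies uniform on [0.1, 0.9], population frequencies
Beta(p(1-F)/F, (1-p)(1-F)/F) with variance p(1-p)F, genotypes
Binomial(2, p). An optional admixed group mixes two parental frequency
vectors at a per-sample Beta-distributed proportion, which produces the
familiar PC1 cline. Hudson's estimator applied to a simulated pair of
populations recovers the configured F within 0.02 at M = 5,000 — the
parameter-recovery check in the tests.

The default design encodes the canonical confounded biobank: two sites,
each genotyped exclusively on its own platform (platform = site), with
population membership balanced across sites so that the platform axis is
orthogonal to the ancestry axis and the two claims — "conventional PCA
picks up the platform", "projection does not" — are separately testable.

**Platform artifact model.** The default (`error_model = "miscode"`) makes
each affected variant (20% of variants by default), with probability equal
to the platform's error rate (0.05), systematically allele-miscoded on
that platform: every sample genotyped on it reads `2 - d`. This is how
array batch effects actually behave — a probe is miscoded or captures a
different local haplotype *consistently*, not at random per genotype — and
it is what makes the batch effect visible to PCA, as the strong platform
bands in real merged biobank data are. A per-genotype random alternative
(`error_model = "noise"`, symmetric ±1 steps clipped to [0, 2]) is also
provided; it inflates variance without displacing platform means, and at
realistic rates conventional PCA cannot see it — a useful negative
control, but not a model of the observed phenomenon. Per-platform
missingness masks affected variants at the platform's missing rate.
`inject_ld_block()` separately plants a contiguous run of near-duplicate
variants to emulate an inversion-like region of extreme local LD.

What the simulator does *not* emulate: realistic LD maps (variants are
independent given ancestry), imputation error structure, relatedness, and
sex-linked variation. Passing tests therefore demonstrate the logic of the
methods — that projection removes platform axes the conventional route
retains, that flagged regions coincide with planted artifacts — not their
behavior under real LD, which is why the artifact-region exclusion step
exists at all.

A single global seed drives every draw through named substreams
(frequencies, cohort, panel, phenotype, block), so each stage is
independently reproducible and two runs of the same configuration are
bit-identical.

## Numerical choices

* Component signs are arbitrary; they are fixed by making each component's
  largest-magnitude loading positive, so results are deterministic and
  comparable across runs.
* Decompositions use the symmetric eigensolver on the smaller-side
  covariance; no randomized SVD, no tolerance-dependent iteration.
* Eigenvalues below `1e-12` of the leading one are treated as numerical
  zeros; their loadings are zeroed rather than divided by noise.
* Reference models serialize as a single plain-text archive with 17
  significant digits, which round-trips IEEE doubles exactly; a version
  line guards against format drift and truncated files fail loudly.
* Monomorphic variants are an error under Patterson scaling (the scale is
  zero) with a message pointing at `filter_maf()`; under plain centering
  they are harmless zero columns.

## Validation scales

The test suite validates at sizes chosen to finish in minutes while
leaving the claimed effects comfortably detectable: self-projection at
200 samples by 2,000 variants; platform-bias suppression at 600 samples by
5,000 variants over five seeds; null-calibration of the association scan
at 1,000 samples by 20,000 variants; LD-pruning equivalence against an
exhaustive oracle on fifty 10-by-30 fixtures; artifact-block recovery on a
2-Mb block in a 40-Mb chromosome over five seeds.

## Known limitations

* Projection scores are not shrinkage-corrected; with very small panels
  and many markers, projected scores of out-of-panel samples shrink toward
  the origin relative to panel scores. The panel sizes validated here
  (hundreds of samples) are far from that regime.
* The `.ped` dialect carries no ref/alt designation; the reader codes the
  minor observed allele as alt (tie broken alphabetically), so round-trip
  identity holds only when alt is the minor allele. Use VCF, `.raw` or the
  dosage TSV when exact allele orientation matters.
* Multi-allelic sites are dropped with a warning; split them upstream.
* Sample-level QC (call rate, heterozygosity, relatedness) is out of
  scope; the projection route is precisely the tool that tolerates
  relatedness in the study set, but the panel must be unrelated.
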