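---
title: "Mapping homologous cell types across species with CAT overlap of ranked marker genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping homologous cell types across species with CAT overlap of ranked marker genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthocat)
library(dplyr)
```

## The problem

Sorted immune-cell populations — here, mononuclear phagocytes (MPs):
macrophages, monocytes and dendritic cells — are far better characterized in
mouse than in human. Deciding which human population corresponds to which
mouse population from bulk RNA-seq of sorted cells is harder than it sounds:
absolute expression levels are not comparable across species, replicate
numbers are small (3–6 per population), and genes shared across many related
populations ("core signature" genes) dominate naive correlation-based
matching. orthocat implements a pipeline built around two ideas:

1. **Marker scores that reward exclusivity.** A gene is a useful marker for
   a subtype only if it is *both* highly expressed there *and* higher there
   than in every other subtype of the same species.
2. **Correspondence-at-the-top (CAT).** Two subtypes from different species
   are compared through the overlap of their ranked marker lists at every
   list size $k = 1 \dots L$, and matched by the mean overlap — a statistic
   that does not depend on choosing one arbitrary set size.

## The pipeline

### Shared coordinate system

Counts from the two species are restricted to autosomal 1:1 orthologs
(`read_ortholog_map()` drops every gene participating in more than one pair
and, when chromosome annotation is present, every sex-chromosome pair, so
donor sex cannot masquerade as a species difference). After
`restrict_to_orthologs()`, genes in both matrices are identified by the
ortholog-*pair* ID, which makes cross-species set intersections well
defined.

### Normalization

* **Eligibility.** A gene must exceed 1 count per million in at least 3
  samples (`cpm_filter()`). Because the cross-species matrix must stay
  row-aligned, a gene has to pass in *both* species — the conservative
  completion of the per-species filter.
* **VST.** `vst_counts()` defaults to $\log_2(\text{count}/s_j + 1)$ with
  median-of-ratios size factors $s_j$ (geometric-mean reference over genes
  with all-positive counts; library-size factors with a warning when no such
  gene exists). Everything downstream uses medians, ranks and linear-model
  contrasts, which need only a monotone variance-stabilizing transform; the
  interface is pluggable (`method = "deseq"` calls DESeq2's VST) for users
  who want the dispersion-trend version.
* **Subject regression.** Donors contribute samples to several subtypes, so
  donor identity is a random intercept, not a nuisance fixed effect.
  `regress_subject()` fits per gene $y = \mu + b_{subject} + \varepsilon$
  (REML) and returns $\hat\mu + \hat\varepsilon$, i.e. the values minus the
  subject BLUPs. When the random-intercept variance is not supported (see
  *Mixed-model details*), the gene keeps its original values and is flagged
  `singular_fit_fallback`: nothing is regressed out of a donor effect the
  model cannot identify.
* **Quantile normalization.** `quantile_normalize()` forces every sample of
  both species onto the common distribution of mean order statistics
  (limma's implementation; ties receive the mean of the reference values
  they span). This is what makes expression values comparable across
  species at all.
* **Shared HVGs.** `select_hvg()` intersects the per-species top-2000
  genes by variance; the package uses plain log-scale variance, which is
  invariant to the log base, rather than any particular dispersion-binning
  dialect.

### Marker scores

For gene $g$ and subtype $t$ within one species,

$$ s(g, t) = m(g, t) \cdot Z(g, t) $$

* $m(g,t)$ — median of $g$ over $t$'s samples divided by the median over
  *all* samples of the species ($+\,\varepsilon = 10^{-8}$), computed on the
  quantile-normalized values. Housekeeping genes get $m \approx 1$
  everywhere; a gene expressed in a minority of subtypes gets a large $m$
  where it is on. Degenerate cases: subtype median 0 gives $m = 0$; overall
  median 0 with a positive subtype median keeps the subtype median itself.
* $Z(g,t)$ — per gene, a linear mixed model
  $y \sim \text{subtype} + (1\,|\,\text{subject})$ is fitted on the VST
  values (the quantile-normalized values are used everywhere *except* this
  testing route). All pairwise contrasts of $t$ against the other subtypes
  give two-sided p-values $p_i$ and effect signs; the directional rule maps
  $p_i \mapsto p_i$ when $t$ is higher and $p_i \mapsto \max(p_i, 1-p_i)$
  when lower (an exactly-zero estimate counts as "lower" — conservative for
  markerhood), and the unweighted Stouffer combination
  $Z = \sum_i \Phi^{-1}(1-p_i') / \sqrt{m}$ aggregates them. A gene elevated
  in two subtypes collects at least one non-positive contribution from each
  elevated subtype's viewpoint, which is precisely why core genes sink.
* **Gate.** Genes enter the ranking only when the overall mixed-model
  F-test for any subtype effect survives Benjamini–Hochberg adjustment at
  $\alpha = 0.05$ *and* $Z > 0$. Ranks are assigned by decreasing $s$, ties broken by higher $m$,
  then gene ID, so tables are reproducible byte for byte.

### Mixed-model details

Fitting one `lmer()` per gene per species is far too slow for genome-wide
use, so orthocat fits the single-random-intercept model for *all* genes at
once: with $V = I + \lambda Z Z^\top$ and $\lambda = \sigma_b^2 /
\sigma_e^2$, $V^{-1}$ reduces to per-subject shrinkage weights
$\lambda/(1 + \lambda n_s)$, and the profiled REML criterion for every gene
at one $\lambda$ costs a few small matrix products. A shared grid plus
per-gene Brent refinement gives the REML estimates; the test suite checks
them against lme4 ($\hat\beta$ to $10^{-6}$, variance components to
$10^{-2}$ relative).

Three decisions matter for inference:

* **Singular-fit rule.** The raw REML boundary estimate is positive about
  half the time when the true subject variance is zero, and that selection
  couples with the residual-variance estimate, visibly inflating the F-test
  no matter which degrees-of-freedom method is used. orthocat therefore
  retains a gene's random intercept only when it improves the restricted
  deviance by more than $\chi^2_{1,0.95}$ (a restricted LRT against the
  boundary; under the half-and-half mixture null this keeps ~2.5% of
  genes). Genes below the threshold are classed singular and fall back to
  ordinary least squares — the singular-fit fallback, sharpened into a
  likelihood-based call. With strong
  real subject effects the statistic is enormous and the mixed model is
  essentially always kept. `reml_keep_threshold = 0` restores raw lme4
  boundary semantics.
* **Degrees of freedom.** The default `df_method = "kenward-roger"` uses
  the Kackar–Harville-adjusted coefficient covariance with Kenward–Roger
  moment matching, computed natively from closed-form ingredient matrices;
  `"satterthwaite"` (native, matching lmerTest to ~$10^{-3}$ in p),
  `"residual"` ($n - k$), and `"lmertest"` (slow per-gene refit, the
  cross-check oracle) are alternatives. On null cohorts the default's raw
  F p-values are uniform (KS) and its empirical size at 0.05 is ~5%.
* **Degenerate genes.** Zero-variance genes get $p = 1$ and never rank.

### CAT homology

`cat_curve()` computes $\text{overlap}_k = |top_k(\text{ref}) \cap
top_k(\text{cand})| / k$ incrementally — a shared gene enters the running
intersection at $k = \max$ of its two list positions, so a single
`tabulate` + `cumsum` covers all $k$; the test suite proves equality with
the naive per-$k$ set intersection. `mean_cat()` averages $k = 1 \dots L$
($L = 1000$); shorter lists are averaged over their effective length with a
warning (small simulations rarely support 1000 eligible markers per
subtype, the compendium scale does). `assign_homologs()` takes the row
maximum; ties report every tied candidate in lexicographic order. The
curve is symmetric in its two lists, but assignment need not be reciprocal
— subtype X's best partner may itself prefer a third subtype, a biological
signal rather than a bug. `scale_rows_minmax()` reproduces the row-scaled
correspondence heatmap convention, and `spearman_correspondence()` is
included only as the correlation baseline the CAT approach replaces.

### Signature comparison

`top_n_signature()` re-derives published signature sets against the
compendium universe: out-of-universe genes are removed, genes listed more
than once in a cluster are dropped entirely, and the top 20 by the
publication's own ranking statistic survive. `emd_auc_score()` implements
the product of the 1-D earth mover's distance (integral of CDF differences;
equal to the $L_1$ distance between quantile functions) and the rank AUC
(Mann–Whitney $U/(n_1 n_2)$, ties one half, in-cluster high $\Rightarrow$
AUC $> 0.5$). `signature_profile()` averages per-gene min-max-scaled
expression per (cluster, subtype) for heatmap-style display. These scores originate in
scRNA-seq cluster analysis, where "samples" are cells; applied here to the
quantile-normalized bulk values, the substitution is deliberate and
documented.

## The synthetic cohort generator

`simulate_cohort()` provides ground truth for every stage. What it
emulates:

* two species with a complete 1:1 ortholog pairing;
* 15 and 9 subtypes with 4 replicate samples each (sorted compendia
  typically run 3–6);
* donors *crossed* with subtypes — replicate $r$ of every subtype comes
  from donor $1 + (r-1 \bmod 4)$, as in sorts where one donor's tissue
  yields every population at once — with a Normal$(0, 0.3)$ log2 intercept
  per donor shared by all genes of that donor's samples;
* species-private gene baselines (log2 SD 1.5 around equal proportions), so
  cross-species correspondence can only come from marker structure, never
  from shared absolute levels;
* negative-binomial counts, $\mathrm{Var} = \mu + \alpha\mu^2$ with
  $\alpha = 0.1$, library sizes uniform in $[5\times10^5, 2\times10^6]$;
  marker and donor effects multiply the mean without per-sample
  renormalization;
* per-subtype marker programs: 50 genes, $+4$ log2 units in their subtype
  only, disjoint within a species; for each planted homolog pair a fraction
  $\rho$ of markers are the *same ortholog* in both species and $1-\rho$
  are species-private. $\rho$ is the conservation dial the recovery tests
  sweep.

What it does **not** emulate — and hence what passing tests do not show
about real data: gene–gene correlation, gene-specific donor effects,
batch/protocol differences between the two species' platforms,
compositional library effects, or the paper-scale ~12,000-gene, 93-sample
compendium (tests run at 600–2,000 genes for speed; the generator defaults
document the full scale).

A note on the donor model: because the donor intercept is shared by all
genes of a sample, it is mathematically a library-size perturbation, and
median-of-ratios size factors absorb it. Subject regression on such
cohorts therefore correctly falls back for most genes (the true residual
donor variance *is* zero after normalization); criterion-style tests of
the regression use directly simulated Gaussian donor data instead, where
the effect survives normalization by construction.

## Numerical choices

* $\varepsilon = 10^{-8}$ in the scaled-median denominator; p-values
  clipped to $[10^{-300}, 1 - 10^{-16}]$ before normal inversion.
* $\lambda$ searched on $\{0\} \cup 10^{[-6, 6]}$ (41-point grid) with
  Brent refinement in the bracketing interval; boundary kept when at least
  as good.
* Variance-parameter covariance for Satterthwaite/KR from a central-
  difference Hessian of the closed-form restricted deviance (relative step
  $10^{-4}$).
* Ties: marker ranks break by (score, scaled median, gene ID); HVG ranks
  by (variance, gene ID); assignment ties report all candidates.
  Everything downstream of the generator is deterministic — rerunning the
  pipeline on the same inputs is byte-identical.

## Problem sizes used by the checks

The test-suite and acceptance script run the oracle comparisons at
$G = 5000$, $L = 1000$ (100 list pairs; 200 random-baseline replicates),
recovery and monotonicity on 2,000-gene cohorts with 8 subtypes per
species, 4 planted pairs and 4 samples per subtype across 5 seeds and
$\rho \in \{0, 0.25, 0.5, 0.75, 1\}$, null calibration on a 2,000-gene
zero-effect cohort at the full 15/9-subtype design, and the
subject-regression oracle at 20 donors × 4 samples. These sizes keep the
complete run within a desktop-scale budget while leaving every comparison
at the scale its approximation needs.

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(
  n_genes = 2000, n_subtypes_a = 8, n_subtypes_b = 8,
  homolog_pairs = data.frame(subtype_a = sprintf("A%02d", 1:4),
                             subtype_b = sprintf("B%02d", 1:4)),
  samples_per_subtype = 4, seed = 21
)
cohort <- simulate_cohort(cfg)

prep <- preprocess_cross_species(
  cohort$counts_a, cohort$counts_b, cohort$meta_a, cohort$meta_b,
  cohort$orthologs, hvg_top = 500
)

qn_a <- subset_samples(prep$qn, cohort$meta_a$sample_id)
qn_b <- subset_samples(prep$qn, cohort$meta_b$sample_id)
markers_a <- marker_scores(qn_a, cohort$meta_a, test_values = prep$vst_a)
markers_b <- marker_scores(qn_b, cohort$meta_b, test_values = prep$vst_b)

hom <- cat_homology(markers_a, markers_b, l = 1000)
hom
tidy(hom)
glance(hom)
autoplot(hom)          # CAT curve panels, best match highlighted
plot_mean_cat(hom)     # row-scaled correspondence heatmap
```

## Known limitations

* The alignment/embedding stage of the original workflow (CCA, dynamic
  time warping, t-SNE) is out of scope; `spearman_correspondence()` exists
  only as a baseline for comparison.
* The EMD×AUC scores are computed on bulk quantile-normalized values, not
  on the single-cell normalized counts of the method's origin.
* At very small sample counts (≤ ~36 samples) the mixed-model F-test's
  small-sample approximations retain a fraction of a percent of size
  inflation; the BH-gated eligibility decision is insensitive to this.
* Marker lists shorter than $L$ are averaged over their effective length;
  comparisons between pairs with very different effective lengths should
  be read with care (the package warns and records the effective $L$).
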