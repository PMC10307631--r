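---
title: "Methods: attributing fibroblast activation states to cytokine exposures"
author: "flscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attributing fibroblast activation states to cytokine exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flscape)
```

# Overview

Synovial fibroblasts (fibroblast-like synoviocytes, FLS) adopt distinct
activation states in inflamed tissue. `flscape` implements the computational
chain used to attribute such states to candidate cytokine exposures:

1. **Bulk stimulation DE** — derive directed cytokine-response gene
   signatures from in vitro stimulation experiments (NB-Wald test).
2. **Signature scoring** — score those signatures on single cells and
   spatial spots with bin-matched control genes.
3. **Single-cell DE and enrichment** — hurdle-model DE with a
   detection-rate covariate; preranked GSEA.
4. **Motif deviations** — chromVAR-style per-cell TF-motif accessibility
   deviations with matched background peaks, expression gating and
   per-state ranking.
5. **Spatial topics** — LDA grade-of-membership models of spot counts with
   Bayes-factor model selection and Poisson-KL marker genes.
6. **Colocalization** — spot-wise Pearson correlation of signatures and
   topic proportions, and hex-neighborhood "dampening" contrasts.

Every stage is exercisable on the built-in synthetic generators, which
plant known ground truth (DE sets, cell states, mixing proportions, motif
activities) so recovery and calibration are testable without any external
download.

# Synthetic data model

All generators are seed-deterministic; `with_seed()` protects the caller's
RNG stream.

**Bulk counts.** Negative-binomial with the mean/dispersion
parameterization Var = μ + αμ², constant dispersion per dataset (default
α = 0.05, typical of 3′ bulk RNA-seq of cultured cells). Stimulated
conditions multiply the per-gene baseline by 2^(signed log2 effect);
combinations add effects in log2 space and may be rescaled to emulate
attenuation (the DLL4-style co-stimulation). Per-sample depth factors are
log-normal (σ = 0.1) so size-factor code is exercised. Three replicates per
condition by default, matching routine stimulation designs.

**Single cells.** Cells × genes NB counts; library sizes log-normal with
median ≈ 6,000 molecules (typical snRNA-seq depth), σ = 0.3. Cytokine
programs act multiplicatively on the per-state expression profile.
Mitochondrial genes carry the reserved `MT-` prefix and a 5% baseline
share, so QC fractions are computable from names alone. Planted QC
failures are configurable: low-depth cells are drawn well below the
1,024-molecule filter, high-mito cells are raised to a 40% mitochondrial
share (default 5% of cells each).

**Spatial spots.** Per spot, topic proportions ω ~ Dirichlet(α) and counts
~ Multinomial(depth, ωᵀθ); totals are exact by construction. Coordinates
lie on an axial hex grid — each interior spot has exactly six neighbors,
the Visium geometry — with neighbor offsets
(±1, 0), (0, ±1), (+1, −1), (−1, +1).

**Accessibility.** Bernoulli peak × cell matrix with
logit = peak intercept + cell depth offset + Σ motif effects of the cell's
state. The peak intercept depends on GC content (slope 1.5 on the centered
fraction), so GC is a genuine confounder that background matching must
absorb.

What the generators do **not** emulate: gene–gene correlation beyond the
planted programs, doublets, batch effects, spatial autocorrelation of ω
beyond the Dirichlet draw, and realistic mean–variance trends across
genes. Passing recovery tests therefore demonstrates correctness of the
estimators under the stated model, not robustness to every artifact of
real tissue data.

# Bulk differential expression

The DE core is a per-gene NB GLM with log link, design
intercept + condition indicator, and log size-factor offsets; size factors
are median-of-ratios against the geometric-mean reference. Dispersion
estimation follows the standard shrinkage recipe:

* gene-wise dispersion by **Cox–Reid adjusted** profile maximum likelihood
  (the adjustment — half the log-determinant of the Fisher information —
  removes most of the downward ML bias at 3 + 3 samples; without it the
  null rejection rate roughly doubles);
* a parametric trend α(μ) = a/μ + b fitted by iteratively trimmed least
  squares across well-expressed genes, with a median fallback when the fit
  degenerates;
* a log-normal prior centered on the trend whose width is the MAD-based
  spread of log residuals minus the expected sampling variance
  (trigamma((m − 2)/2)), floored at 0.0625; the reported dispersion is the
  MAP.

The Wald statistic is the condition coefficient over its information-based
standard error; p-values are two-sided normal. One BH family per
condition-vs-control contrast; genes whose mean normalized count falls
below 1 are reported with `p_adj = NA` and excluded from the family
(independent filtering keeps the family honest on sparse synthetic data).
Optional fold-change shrinkage is the normal-normal posterior mean (ridge)
with a data-driven prior scale from the 95th percentile of |MLE|; the Wald
test always uses the MLE.

Signatures are the genes with adjusted p below α (default 0.05), split by
sign. The DLL4 "dampening" summary pairs each signature gene's fold change
under cytokine-alone and cytokine-plus-DLL4 stimulation; shrinkage toward
zero is signed so that attenuation is positive for both up- and
down-regulated genes, summarized by per-direction medians and Wilcoxon
signed-rank tests.

# Signature scoring

The normalized matrix (ln(1 + s·c/total), s = 100,000 for cells, the
median total for spots) is gene-wise z-scored; genes are placed in 25
equal-occupancy mean-expression bins; each signature gene draws 50 control
genes from the non-signature members of its bin (25/50 are the common
defaults for control-gene matching). The per-observation score is the mean
z of up genes minus the mean of their per-gene control means, minus the
same contrast for down genes; the column is finally z-scored. Two
numerical choices matter:

* the reference term averages **per-gene control means**, so a signature
  containing every gene scores exactly zero (each gene's reference
  collapses to its bin mean) — a useful identity test;
* when a bin holds no non-signature gene the full bin mean is used
  deterministically; when it holds fewer than 50 the pool is sampled with
  replacement (with a warning).

Control draws are made in canonical (sorted) gene order, making scores
invariant to gene and observation order at a fixed seed. Down-regulated
genes subtract from the score; directed scoring is what lets "response"
and "dampening" point in opposite directions, and can be disabled by
omitting the down set.

# Hurdle DE and preranked GSEA

The two-part single-cell model regresses detection (logistic) and positive
log-expression (Gaussian) on condition + cngeneson, where cngeneson is the
z-scored number of detected genes per cell — the cellular detection rate,
whose inclusion absorbs the main technical covariate of droplet data. The
hurdle statistic sums the two likelihood-ratio components (χ², 2 df; 1 df
when the continuous part is inestimable). Bonferroni correction is applied
over tested genes; genes detected in fewer than 5 cells are skipped, and
mitochondrial/ribosomal/MALAT1-like genes are masked by default. Perfect
separation in the logistic part falls back to a small-ridge IRLS fit and
flags the gene.

GSEA uses the weighted Kolmogorov–Smirnov running sum with weight
|rank statistic| and exponent 1; ranks from a DE table are
−log(p) × log2 fold change. The null permutes gene labels (2,000 draws by
default); NES divides by the mean |null ES| of matching sign and the
p-value uses the matching-sign tail with +1 smoothing, so the attainable
floor is 1/(n_perm + 1). Ties in the ranking are broken by gene id for
reproducibility.

# Motif deviations

The expected accessibility of motif m in cell i is E = T_m · d_i/D — the
motif's total accessible count times the cell's share of the grand total.
The package defines the raw deviation as the fractional excess
(obs − E)/E **mean-centered across cells per motif**; centering makes the
per-motif deviations sum to zero by construction (a conservation check)
and leaves z-scores unchanged in everything that matters downstream, since
the same centering is applied to every background replicate.

Backgrounds match each peak to its Mahalanobis-nearest 2% neighborhood in
the space of z-scored GC and z-scored log mean accessibility (floored at
25 peaks so small panels remain stable; 50 background draws by default). A
degenerate covariance falls back to rank-based matching with a warning.
The z-score is (raw − mean_bg)/sd_bg; motifs with zero background variance
or no matched peaks are flagged and excluded from ranking.

Motifs are gated per state by TF expression: admitted iff any mapped TF is
detected in **strictly more than** 20% of the state's cells; motifs whose
TFs are absent from the expression matrix are excluded everywhere (the
conservative reading of the filter). Per state, gated motifs are ranked by
a tie-corrected normal-approximation Wilcoxon one-vs-rest test on the
z-score matrix, BH-corrected within state, top six reported.

# Spatial topic models

Genes detected in fewer than 10 spots or more than 95% of spots are
removed before fitting (both boundaries inclusive on the keep side). Note
that on dense synthetic panels — few genes at high depth — the 95% rule
can remove most genes; the recovery experiments therefore fit on the
generated counts directly, which is also the regime the generator defines.

The sampler is collapsed Gibbs over token-topic assignments with symmetric
priors α = 1/K (ω) and β = 0.1 (θ); defaults are 1,000 sweeps, half
burn-in, thinning 10, all configurable. θ and ω are posterior means over
post-burn-in thinned states. The recovery experiments in the tests use
2,000 spots × depth 2,000 with 200 sweeps (and 60 sweeps per candidate K
for model selection) — the separated-topic regime mixes fast and the
Bayes-factor margins are orders of magnitude larger than sweep-to-sweep
noise. Model selection approximates the log Bayes factor against the K = 1
multinomial null BIC-style: 2·ΔlogLik − Δdf·ln(N_tokens) with
df = K(G − 1) + S(K − 1); the maximizer wins, ties to the smallest K. The
approximation is exposed in the per-K table so alternative penalties can
be swapped in.

Per-topic markers maximize the Poisson Kullback–Leibler score
min_{k′≠k} [θ_k′g − θ_kg + θ_kg ln(θ_kg/θ_k′g)] — discriminability against
the nearest competing topic, treating each gene's topic probability as a
Poisson rate (floored at 10⁻¹²). The score is nonnegative, zero iff the
nearest competitor matches, and degree-1 homogeneous in the θ pair.
Label switching in all recovery comparisons is resolved by exhaustive
permutation matching on row-wise Jensen–Shannon divergence (K ≤ 8).

# Colocalization and neighborhood contrasts

Signature scores and topic proportions are correlated across spots
(Pearson; combined or per sample). The dampening contrast partitions spots
into anchor-high (top decile of the anchor score by default), adjacent
(hex neighbors of anchor-high spots) and distal, and tests the ordered
three-group contrast with a Monte-Carlo Jonckheere–Terpstra permutation
test (two-sided, 999 permutations). The anchor quantile must lie strictly
inside (0, 1); adjacency never crosses sample boundaries and is invariant
to translating the grid.

# Design choices that were genuinely open

* **Dispersion machinery**: gene-wise MAP against an a/μ + b trend was
  chosen over exact replication of any particular package; the Cox–Reid
  adjustment was added after the unadjusted profile MLE proved biased at
  n = 3 + 3 (measurably: the null rejection rate at p < 0.05 was ~0.12).
* **Fold-change shrinkage**: a normal-normal posterior mean rather than a
  full penalized refit — the estimator enters only plots and the
  dampening summary, and the approximation error is far below the paired
  attenuation effect it measures.
* **Deviation centering** (above): the conservation property was preferred
  over the uncentered fractional deviation; rankings are unaffected.
* **Hurdle fallback**: ridge-IRLS on separation instead of omitting the
  gene, so planted strong effects (which separate perfectly) remain
  testable.
* **Bayes factor**: a BIC-style penalty, because any practical "Bayes
  factor" for LDA is itself an approximation; the per-K table makes the
  choice auditable.
* **Effect sizes**: the cytokine programs' planted log2 effects (default
  2) are configuration, not biology — bulk stimulation experiments of this
  design typically show on the order of a thousand DE genes with effects
  of this magnitude, but the defaults are exposed and not asserted as
  measured values.

# Known limitations

* The NB trend fit assumes a monotone mean–dispersion relationship; data
  with strong dispersion outliers rely on the trimming loop.
* The Gibbs sampler stores token-level assignments; extremely deep count
  matrices (≫10⁷ tokens) are better served by thinning depth first.
* Background matching uses two covariates (GC, mean accessibility); no
  per-cell bias term beyond the depth-proportional expectation is fitted.
* The hurdle model's Gaussian part assumes roughly log-normal positive
  expression; heavy zero-inflation beyond detection is not modeled.
* Problem sizes in the tests (2,000 spots, 400-gene panels, 200–400 cells
  per group, 5,000-gene bulk panels) were chosen as the smallest instances
  at which the planted-recovery and calibration properties are stable;
  they are stated in each test.

# A worked miniature

```{r mini, eval = TRUE}
p <- cytokine_program("TNF", up_genes = 1:40, down_genes = 41:80,
                      log2fc_up = 2, log2fc_down = 2)
gb <- generate_bulk(list(p), n_genes = 600, seed = 1)
de <- nb_wald_de(gb$bulk, "TNF")
sig <- derive_signature(de, alpha = 0.05)
sig
```

```{r mini2, eval = TRUE}
states <- list(state_spec("resting", 150),
               state_spec("inflamed", 150, programs = list(p)))
sc <- generate_single_cell(states, n_genes = 600, seed = 2,
                           low_depth_frac = 0, high_mito_frac = 0)
expr <- normalize_log(sc$counts)
s <- suppressWarnings(score_signature(expr, sig, seed = 3))
tapply(s, sc$truth$state_of_cell[names(s)], mean)
```
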