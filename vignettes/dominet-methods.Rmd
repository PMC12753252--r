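---
title: "Dominance-based centrality analysis of multi-site brain networks: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominance-based centrality analysis of multi-site brain networks: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dominet)
```

## The problem

Neurodegenerative disease does not displace the hubs of the brain's
functional network so much as erode their *dominance*: regions that once
organised information flow lose their grip while their anatomical position
is unchanged. Classical centrality indices (degree, betweenness,
eigenvector, ...) emphasise direct connectivity and can miss this erosion,
particularly for secondary hubs whose influence is exerted through indirect,
multi-step routes. `dominet` implements an analysis pipeline built around
**DomiRank centrality**, a dominance score derived from explicit
competition-relaxation dynamics, and embeds it in the full multi-site
workflow used in case-control imaging studies: per-subject network
construction, cross-site mega-analysis, attack-robustness profiling,
leave-one-site-out prediction, and imaging-transcriptomics association.

Because clinical imaging cohorts are access-restricted, the package ships a
synthetic cohort generator with *planted, known effects*. Every stage of the
pipeline can therefore be validated against ground truth, and all
statistical machinery is exercised at realistic scale without any subject
data.

## DomiRank centrality

Let $A$ be the binary adjacency matrix of a connected network of $N$
regions. DomiRank $\Gamma \in \mathbb{R}^N$ is the steady state of

$$\dot\Gamma = \alpha A(\theta\mathbf{1} - \Gamma) - \beta\Gamma,$$

where each node draws dominance from its neighbours' remaining capacity
($\theta$ is the capacity scale, fixed to 1) and relaxes at rate $\beta$.
Writing $\sigma = \alpha/\beta$, the fixed point has the closed form

$$\Gamma = \theta\sigma\,(\sigma A + I)^{-1} A\mathbf{1}.$$

`domirank()` solves the linear system $(\sigma A + I)\Gamma =
\sigma\theta A\mathbf{1}$ directly (LAPACK, with a residual check at
$10^{-8}$) rather than iterating the dynamics; at the network sizes of
parcellated brain graphs (a few hundred nodes) the solve is exact and
costs milliseconds. Scores can be *negative*: a node surrounded by strong
competitors is dominated, which is precisely the information classical
metrics discard.

**Feasibility.** $(\sigma A + I)$ is nonsingular, and the dynamics stable,
exactly when $0 < \sigma < -1/\lambda_N$, with $\lambda_N$ the most negative
eigenvalue of $A$ (`sigma_feasible_interval()`). At $\sigma \to 0$, $\Gamma /
(\sigma\theta) \to A\mathbf{1}$: DomiRank degenerates to degree. Larger
$\sigma$ weighs global structure progressively more heavily.

**Choosing $\sigma$.** Following the metric's origin in network
dismantling, `select_sigma()` scans 100 candidates evenly spaced across the
feasible interval (endpoints excluded, fractions $j/101$ of the bound) and
picks the candidate whose DomiRank-ordered targeted attack destroys the
network fastest — minimal area under the largest-connected-component (LCC)
curve. The attack during the scan is non-adaptive (the ranking is frozen
from the intact network), matching the robustness analysis; an adaptive
variant is available behind a flag for exploration. Ties go to the smallest
candidate, making the scan deterministic.

In cohort runs one $\sigma$ is shared by all subjects ("template" mode,
the default): it is selected on the mean healthy-control network, with the
scan capped at 95% of the smallest per-subject feasibility bound so the
shared value is valid for every individual network. A per-subject scan is
available (`sigma = "per_subject"`), but a shared value keeps the metric
comparable across subjects and is dramatically cheaper at cohort scale;
this is the package's design choice where the field's practice is not
settled.

## Network construction

`compute_fc()` computes pairwise Pearson correlations between regional time
series, clips them to $\pm(1-10^{-7})$, and applies the Fisher
z-transformation ($\operatorname{atanh}$), zeroing the diagonal. Negative
correlations (expected after global-signal regression) are retained.

`threshold_mst()` binarises at a fixed **proportional density** (default
4%, i.e. exactly $\operatorname{round}(0.04\,N(N-1)/2)$ edges — 1205 for
$N = 246$; rounding is half-away-from-zero) so all subjects have identical
edge counts. Connectivity is guaranteed by a spanning-tree backbone: the
maximum-weight spanning tree on signed z is retained first, then the
strongest remaining edges in descending signed z until the budget is met.
(The "minimum spanning tree" of this literature is interpreted as the
maximum-weight tree on correlation strength; a literal minimum tree would
preserve the *weakest* edges, contradicting its purpose.) Equal-weight ties
break lexicographically on region ids, so the construction is fully
deterministic; for densities $d_1 < d_2$ the non-tree edges nest
monotonically. An absolute z-cutoff mode (same tree backbone) supports
sensitivity analyses, as does ranking by $|z|$ instead of signed z.

The seven classical centralities (degree, strength, betweenness, closeness,
harmonic, eigenvector, PageRank) are delegated to igraph with standard
conventions: shortest-path metrics normalised, eigenvector nonnegative with
unit Euclidean norm, PageRank damping 0.85, strength summing the retained
Fisher-z weights (the only weights the pipeline preserves).

## Attack robustness

`targeted_attack_curve()` removes nodes in descending order of a centrality
ranking (ties: ascending region id) and records the LCC fraction,
normalised by the original $N$, after every removal — so curves start at 1
for connected input and end at 0. Internally the curve is computed by the
reverse (union-find percolation) construction, which is exact and linear in
edges; tests verify it against brute-force component recomputation.
`lcc_area()` integrates the curve by the trapezoid rule; group-level curves
are means of subject curves.

## Multi-site mega-analysis

Within each site, `site_group_test()` fits `value ~ group + age + sex` per
region and takes the t statistic of the group coefficient — equivalent to a
covariate-residualised two-sample test when slopes are shared. Sites are
then combined by the signed, sample-size-weighted Liptak–Stouffer rule
(`stouffer_combine()`):

$$z_i = \operatorname{sign}(t_i)\,\Phi^{-1}(1 - p_i/2), \qquad
z = \frac{\sum_i w_i z_i}{\sqrt{\sum_i w_i^2}}, \qquad w_i = \sqrt{n_i}.$$

Attaching the sign of the site t statistic makes increases and decreases
combine directionally — two equal effects of opposite sign cancel to
$z = 0$. The transform is evaluated in its upper-tail form
`qnorm(p/2, lower.tail = FALSE)` so that extremely small p-values keep
finite z. Regions are corrected with standard Benjamini–Hochberg
(`fdr_bh()`, via `p.adjust`); tests verify the rejection set against an
exhaustive step-up oracle.

## Prediction and cognition association

`loso_classify()` implements leave-one-site-out cross-validation: per fold,
features are z-scored with training statistics only (no leakage), a
linear-kernel SVM ($C = 1$) with Platt-style probability calibration is
fitted, and the held-out site is scored (ACC/SEN/SPE and AUC; the
calibration's internal cross-validation is seeded, so reports are
reproducible). `loso_regress_scores()` predicts cognition (MMSE) with
linear support-vector regression under the same folding; the headline
correlation is the mean of per-site correlations (sites with constant
actual scores report missing), with pooled r, RMSE and $R^2$ alongside.
`cognition_association()` maps region-wise cognition coupling with age,
sex and site (categorical) as covariates, BH-corrected across regions.

## Imaging-transcriptomics PLS

`pls_fit()` links a regional statistic map (e.g. the combined z map of the
AD-vs-HC contrast) to a regions × genes expression matrix by partial least
squares (NIPALS, univariate response; gene columns and response
standardised; regions without expression coverage are dropped through an
explicit alignment mask). For each component the explained-variance share
is reported in *both* blocks — the gene block (the headline quantity) and
the response — because published phrasing is often ambiguous about which is
meant. Component orientation is fixed so the component-1 score–response
correlation is nonnegative.

Inference: `pls_permutation()` permutes the region labels of the response
($p = (1 + \#\{\mathrm{perm} \ge \mathrm{obs}\})/(B+1)$, statistic =
component-1 gene-block share; an exact mode enumerates all permutations for
tiny region counts). The null is a naive label permutation — it does not
preserve spatial autocorrelation, a known limitation of this class of
analysis. `pls_bootstrap()` resamples regions with replacement, sign-aligns
each resample's component to the full model, and reports per-gene weight
SEs and stability Z; degenerate resamples are redrawn and counted.
`rank_top_genes()` ranks by absolute full-model component-1 weight (ties by
gene identifier), and `hypergeom_enrich()` performs upper-tail
hypergeometric gene-set tests (verified equivalent to one-sided Fisher
exact) with BH correction across sets — a transparent stand-in for
web-based enrichment platforms.

A note on monotonicity: explained-variance shares of successive PLS
components are *not* mathematically guaranteed to decrease; on random data
small inversions (a few percent, relative) occur regularly. The package's
tests therefore assert that component 1 is dominant and later shares
decline up to that numerical allowance, rather than strict monotonicity.

## The synthetic cohort generator

`generate_cohort()` emulates a multi-site case-control resting-state study.
Its model, and the reasoning behind each default:

* **Baseline connectivity.** Regions belong to 20 contiguous community
  blocks (~12 regions each, the scale of resting-state subnetworks), with
  within-community correlation 0.45 and between-community correlation 0.08
  — magnitudes typical of parcellated FC after global-signal regression.
  The default dimensions are 246 regions × 170 time points.
* **Planted effects** are expressed in Fisher-z units on designated edges
  and applied before back-transforming to correlations, so a configured
  `dz = 0.5` is exactly the shift the pipeline's own measurement scale
  should recover. The hub-attenuation helper reduces *all* of a designated
  region's within-community edges; attenuating only part of a tightly
  correlated block is geometrically infeasible (it breaks positive
  definiteness) at these effect sizes. Requested covariances that are
  still infeasible fail fast, naming the violated leading minor.
* **Disease heterogeneity.** Each patient draws a severity multiplier
  (mean 1, SD 0.25, clipped at 1.4 to stay inside the feasible correlation
  cone) scaling their planted shifts; MCI receives half the AD shift.
* **Site and covariate effects** are Fisher-z offsets on within-community
  edges (site SD 0.05; age slope −0.002/year centred at 68; +0.01 for male
  sex) — scanner and demographic effects modulate measured coupling where
  the coupling lives, and weak between-community correlations stay at
  baseline so offsets cannot leave the feasible cone.
* **Demographics and cognition.** Age ~ N(68, 7); sex Bernoulli(0.5).
  MMSE group means 28.5/25/16 with SDs 2/3/6 (MoCA 26/22/13, same SDs),
  clamped to [0, 30], with a loading of 4 points per unit of excess
  severity so that cognition declines with planted effect magnitude — the
  coupling that downstream pseudoprobability-cognition correlations probe.
* **Reproducibility.** The global seed is expanded into per-subject
  substreams, so extending the cohort never changes earlier subjects'
  draws, and identical configurations are bit-identical.
* **The seven-site preset** (`seven_site_config()`) uses per-site HC/MCI/AD
  sizes 41/34/44, 21/23/24, 24/33/37, 42/16/66, 64/93/39, 21/18/33,
  42/37/41 (793 subjects) with ten attenuated hub regions at `dz = 0.5`.

What the generator deliberately does **not** emulate: hemodynamics and
autocorrelated BOLD noise, motion artefacts, spatially smooth parcellation
leakage, non-Gaussian tails, or site differences in time-series length.
Passing tests therefore demonstrate that the *statistical machinery* is
correct and calibrated under a known multivariate-normal model — not that
effect sizes of real cohorts will be recovered with the same power.

`generate_gene_expression()` plants a spatially covarying component in a
regions × genes matrix: designated signal genes follow a supplied regional
map with Gaussian noise, all others are pure noise, and the signal-gene
identities are recorded for scoring.

## Numerical choices and degenerate inputs

* Correlations are clipped to $\pm(1-10^{-7})$ before atanh; zero-variance
  regions are an error naming the region.
* Edge budgets round half away from zero; budgets below $N-1$ edges are an
  error stating the minimum feasible density ($2/N$).
* $\sigma$ exactly at the pole $-1/\lambda_N$ raises a singular-system
  error; the scan excludes both endpoints.
* Attack-ranking ties break by ascending region id; threshold ties
  lexicographically on (min id, max id).
* p-values of exactly 0 entering the Stouffer combination are clipped to
  the smallest positive double with a warning; combined p is clipped the
  same way before BH.
* Constant maps have undefined correlation: `similarity_map()` warns and
  returns missing rather than guessing.
* Single-site designs drop the site term from the cognition-association
  model; genuinely rank-deficient designs are an error.

## Problem sizes used by the test-suite

The packaged checks run the machinery at the following scales, chosen to
exercise every stage at full fidelity where it matters (the seven-site
preset, 246-region networks at 4% density, 100-candidate σ scans) and at
reduced size where only calibration is at stake: null-calibration studies
use 7 sites × 20 subjects/group × 40 regions × 60 time points with 200
replicates; permutation-uniformity studies use B = 99 with 200 replicates;
the planted-effect recovery study runs the full 793-subject preset over 10
seeds. The acceptance script runs one full preset replicate with 1000 PLS
permutations and 200 bootstrap resamples.

## Known limitations

* The permutation null for the transcriptomic stage ignores spatial
  autocorrelation; on real atlases this inflates significance relative to
  spin-style nulls.
* The mega-analysis assumes shared covariate slopes across groups within a
  site and fixed effects across sites (no random-effects heterogeneity
  model, no ComBat-style harmonisation).
* Strength is computed on retained Fisher-z weights only; no weighted
  variants of the shortest-path metrics are provided.
* The SVM stages use fixed hyperparameters (linear kernel, C = 1) by
  design; no nested tuning is performed.
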