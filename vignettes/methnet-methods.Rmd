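---
title: "methnet: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methnet: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`methnet` implements an integrative analysis that links differential
cytosine methylation, measured as per-site methylated/total read counts
from whole-genome bisulfite sequencing, to differential gene expression
through protein–protein interaction (PPI) network structure. This vignette
is the package's own account of the statistics it computes, the tunable
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely
open.

## 1. The site-level model: divergence and signal detection

For one individual at one cytosine, the data are counts $(k, n)$ of
methylated and total reads, giving a methylation level $p = k/n$. The
comparison is always against a *pooled reference group* of healthy
individuals (counts summed per site), which anchors the analysis in the
natural variability of a normal population rather than in a single
control sample.

Per site and individual, `site_divergence()` computes

* the signed **total variation** $TV = p_s - p_r$ (the methylation level
  difference),
* its **Bayesian-corrected** variant $TVB$ using posterior-mean levels
  $\tilde p = (k + a)/(n + a + b)$ under a Beta$(a, b)$ prior
  (Jeffreys $a = b = 1/2$ by default: with counts as low as a handful of
  reads, raw proportions are noisy and the correction shrinks them toward
  $1/2$ without committing to an informative prior),
* the squared **Hellinger divergence** between the two Bernoulli
  distributions,
  $HD = (\sqrt{p_s} - \sqrt{p_r})^2 + (\sqrt{1-p_s} - \sqrt{1-p_r})^2$,
  optionally (default on) multiplied by the coverage weight
  $w = 2 n_s n_r / (n_s + n_r)$, which up-weights well-covered sites; the
  unweighted form is available via `weighted = FALSE` and is the one with
  the closed maximal value 2,
* a two-sided **Fisher exact** p-value on the 2×2 (meth, unmeth) ×
  (sample, reference) table. The p-value is computed by a vectorized
  summation of hypergeometric point probabilities and is tested against
  `stats::fisher.test` as an oracle.

A site is a **DMP** (differentially methylated position) for an individual
when (i) its BH-adjusted Fisher p-value is at most `alpha` (default 0.05)
and (ii) its Hellinger divergence reaches the **Youden-index cutoff**:
among candidate sites, control-individual divergences form the negative
class and patient divergences the positive class, and the cutoff maximizes
$J = \mathrm{sensitivity} + \mathrm{specificity} - 1$ over all observed
score values (score ≥ cutoff classified positive). Ties in $J$ are broken
toward the smallest qualifying cutoff, a total rule that makes the
estimator deterministic. This second filter is the signal-detection step:
Fisher significance alone admits the natural variability that healthy
individuals also display, and the ROC cutoff learned from the
control/patient contrast removes most of it.

## 2. Region-level testing: DMGs and DMERs

DMP counts are aggregated per region (gene bodies or enhancers; intervals
are 0-based half-open everywhere inside the package) and per individual,
and tested with a count GLM:

$$\text{count} \sim \text{group}, \qquad
  \text{offset} = \log(\text{length}/1000),$$

under Poisson, quasi-Poisson or negative-binomial (default) families. The
offset makes coefficients DMP densities per kb. The reported p-value is a
likelihood-ratio test of the group term, BH-adjusted across tested
regions. A region is differentially methylated when `p_adj <= alpha`
(0.05), `|log2fc| > 1`, and the minimum-count filter passed. The filters
commute; tests verify the DM set is order-independent.

Defaults mirror the stated operating point of the analysis the package
reproduces: minimum 8 DMPs per individual, LRT, BH, α = 0.05, |log2FC| > 1.
The minimum-count rule is read strictly: a region is retained when *every*
individual of at least one group has ≥ 8 DMPs, which protects the GLM from
the small-count regime where it is least stable; the threshold is a
parameter.

**Numerical choice — NB dispersion.** The NB size parameter is estimated
per region by maximum likelihood *under the null model* (intercept +
offset), with a method-of-moments fallback when the ML fit fails, and the
LRT is computed with that dispersion fixed. Estimating the dispersion
under the alternative with seven individuals overfits it and makes the
chi-square LRT strongly anticonservative (type-I error near 0.13 at
nominal 0.05 in our null simulations); null-model estimation restores
calibration (the acceptance suite checks the empirical type-I error over
2000 null regions against the [0.03, 0.07] band).

`log2fc` is computed from observed group mean counts with a 0.5
pseudo-count (zero counts occur at fixture scale), so Poisson and NB
families agree exactly on the point estimate. Enhancers reported per
tissue are first collapsed by `span_enhancers()` to the maximal region
spanning all tissues; `overlap_filter()` implements the ≥ 500 bp
intersection rule between differentially methylated enhancers and genes.

## 3. Network stage

`build_graph()` thresholds the PPI edge table on the combined confidence
score (0.4 "medium" for network construction, 0.7 for cluster mapping)
and can iterate a minimum-degree filter to a fixed point.
`centralities()` uses standard unweighted definitions — degree,
betweenness (raw shortest-path-pair counts by default, since graph-tool
dialects differ on normalization; a normalized variant is behind a flag),
closeness and radiality within connected components, local clustering
coefficient, average shortest path over reachable nodes, and stress (raw
number of shortest paths through the node). Betweenness and the
degree/transitivity machinery come from igraph; stress and radiality are
computed by exact BFS path counting, and every metric is tested against an
independent all-pairs brute-force oracle on small graphs. The
Cytoscape-specific "centroid" centrality has no published definition we
could adopt and is deliberately excluded.

Hub detection is K-means (k = 3 by default) on z-scored betweenness,
degree, closeness and clustering coefficient. Base R's Hartigan–Wong
K-means with 50 random restarts stands in for k-means++ initialization
(not available in the supported stack); with 50 restarts on ≤ a few
hundred nodes the initialization scheme is immaterial. Cluster stability
is the clusterboot-style mean Jaccard similarity over bootstrap resamples
of the nodes, with the conventional ≥ 0.75 threshold flagging stable
clusters, and cluster separation is validated by a MANOVA Pillai trace
plus pairwise F tests. Ward clustering of per-gene methylation signal
(1 − Pearson correlation across individuals, `ward.D2`) reports *ordinary*
bootstrap support over resampled individuals — deliberately not the
multiscale-bootstrap AU p-values of pvclust, whose machinery is large and
tangential; the two are not comparable and the documentation says so.

`map_clusters_to_network()` quantifies how much of a gene cluster survives
as the main connected component of the PPI network built on it, against a
null of uniformly drawn same-size gene subsets. The sampling universe is a
parameter (default: the union of the clusters) because the source analysis
does not fix it.

## 4. Concordance of pathway enrichments

Enrichment is a one-sided hypergeometric test per pathway, BH-adjusted.
Pathways passing the FDR < 4×10⁻⁴ screen in at least one gene set are
scored $P = (\#\text{genes in pathway}) \times sig$ with the discretized
significance $sig = 3, 2, 1$ for FDR p in $(0, 10^{-6}]$,
$(10^{-6}, 10^{-5}]$, $(10^{-5}, 10^{-4}]$ and $sig = 0$ for pathways not
enriched in a set. Two open points were closed as follows: interval
endpoints are half-open on the left and closed on the right (so
$p = 10^{-5}$ maps to 2), and the band $(10^{-4}, 4\times 10^{-4})$ — which
the screen admits but the scale does not cover — receives $sig = 1$ by
default (`extended = TRUE`), because a pathway explicitly "considered"
but scored 0 would be indistinguishable from a non-enriched one; the flag
restores the strict scale.

Between the two score vectors the package computes Lin's concordance
correlation coefficient
$\rho_{cc} = 2\,\mathrm{cov}(x,y) / (\sigma_x^2 + \sigma_y^2 + (\bar x - \bar y)^2)$
(sample moments; nonparametric bootstrap percentile CI rather than the
Bayesian variant, whose prior is unspecified — the sample estimator is
exactly the quantity the bootstrap targets), Kendall's coefficient of
concordance with tie correction and an independent-rank permutation test,
an OLS agreement regression restricted to pathways with both scores
positive, Bland–Altman limits at mean ± 2σ of the differences, and the
Jaccard overlap of the enriched sets (default min 7 genes).

## 5. Dependence between methylation and expression change

Per gene, methylation change is summarized as the density of
$|p|$, $|TV|$, $|TVB|$ or $|HD|$ per kb — the sum of the magnitude over
the region divided by its length times 1000 — differenced between group
means; expression change as $|\log_2 FC|$. Dependence is assessed three
ways: Spearman's rank correlation (t approximation for n > 30; exhaustive
permutation for n ≤ 8; seeded Monte-Carlo permutation between — full
enumeration of n! permutations is infeasible beyond 8), a
**Farlie–Gumbel–Morgenstern copula** fit by maximum likelihood on rank
pseudo-observations $u_i = r_i/(n+1)$, and a Gaussian product-kernel
2D-KDE with Scott's-rule bandwidths $\hat\sigma\,n^{-1/6}$ on a grid
extended three bandwidths beyond the data.

The FGM density $c(u,v;\theta) = 1 + \theta(1-2u)(1-2v)$ has a concave
log-likelihood in $\theta$, so a golden-section maximization on
$[-1, 1]$ is exact (tests compare against a dense grid); boundary
solutions are flagged. Closed forms $\tau = 2\theta/9$ and
$\rho_S = \theta/3$ are reported, and $\theta > 0$ is the positive
quadrant dependence regime. Estimation is rank-based, not parametric in
the marginals, because only the dependence structure is of interest. One
copula is fitted per density metric (the pooled-versus-per-metric question
was open; per-metric is the more informative choice).

## 6. PCA gene scoring

Individuals are points in the space of per-gene signal densities
(covariance PCA by default — densities share units; correlation PCA
behind `scale = TRUE`). Components with eigenvalue > 1 are retained
(Guttman–Kaiser), and each gene's **PC-score** is the absolute value of
its PC1 loading times a display scale (default 100). Only the ranking is
contractual: the source analysis reports scores on an unreported scale,
so the constant is configurable and the tests pin rank order, the
orthonormality of loadings, and recovery of planted discriminatory genes.
`prcomp`'s SVD route is numerically equivalent to the small-Gram-matrix
trick for individuals ≪ genes and is used directly.

## 7. What the synthetic generator emulates — and what it does not

`sim_config()` states the world the tests operate in:

| parameter | default | why |
|---|---|---|
| individuals | 4 reference + 4 control + 3 patients | the study design being emulated |
| baseline methylation | Beta(2, 8) per site, shared | low-methylated background with room for +0.4 shifts |
| individual wobble | N(0, 0.03) | natural inter-individual variability |
| epimutations | rate 0.01, shift 0.3–0.5 | rare large individual deviations; these are why control individuals also yield DMPs |
| coverage | NB(mean 30, size 10) + 1 | realistic WGBS coverage with overdispersion |
| planted signal | δ = 0.4 in 40/200 genes, 20% hypomethylated | strong-effect regime, hypermethylation-dominated with a hypo minority |
| expression coupling | FGM θ = 0.9 on ranks | positive quadrant dependence between methylation density and fold change |
| PPI | preferential attachment, m = 2; 8 designated hubs forced onto top-degree nodes | scale-free-like topology with known hubs |
| pathways | 10 signal (two-thirds planted signal genes around a hub) + 30 null | gives the enrichment stage genuinely enriched and null pathways |

An earlier 50-gene draft of this world was degenerate: no pathway could
reach the sig scale's p < 10⁻⁴ in a 50-gene universe, so the concordance
stage had no input. The universe was enlarged to 200 genes and signal
pathways were tied to the planted genes; this is scale selection for a
non-degenerate world, not threshold tuning.

The generator does **not** emulate: intergenic sites, strand-merged CpG
dyads, genome-scale site counts, read-level error, linkage between
neighboring sites (sites are conditionally independent given the latent
level), realistic pathway overlap structure, or literature-derived PPI
confidence calibration. A green end-to-end test therefore establishes that
the pipeline recovers the structure it assumes at desk scale — not that it
reproduces genome-scale counts from the original study, which require the
original WGBS accessions.

## 8. Degenerate inputs and edge rules

* Empty reference set, empty background universe, constant score vectors,
  zero-variance CCC inputs, all-tied rating matrices: errors.
* All scores identical in the Youden search: cutoff at that value with
  J = 0 and a warning. No candidate sites after the Fisher filter: empty
  DMP set with a warning.
* Constant-signal genes are dropped (with a warning) before correlation
  clustering; singleton graph components take 0 for path-based
  centralities; GLM non-convergence flags the region and removes it from
  the BH family.
* Probability shifts that leave [0, 1] during simulation are truncated,
  never errors.

## 9. Known limitations

* The per-region NB dispersion is a 7-observation estimate even under the
  null; regions with extreme overdispersion can still be miscalibrated.
* Bootstrap Jaccard stability on very small clusters (< 5 nodes) is
  noisy; the 0.75 rule is a convention, not an inference.
* The FGM copula can only represent |τ| ≤ 2/9; stronger dependence will
  push θ to the boundary, which the fit flags but cannot repair.
* Kendall's W permutation p with two raters is discrete; at small n its
  null distribution is coarse (the tests account for this).
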