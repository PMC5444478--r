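---
title: "Models and methods in seminalseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in seminalseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind `seminalseq`, the
choices that were genuinely open when the package was designed, and what
the synthetic-data generator does and does not emulate.

# The gene-activity model

Deciding whether a gene is transcribed at all — as opposed to measurably
*differentially* expressed — is posed as a Bayesian decision problem. For
gene $g$ in sample $i$ the read count is negative binomial,

$$ y_{gi} \sim \mathrm{NB}(\mu_{gi}, \phi_g), \qquad
   \mathrm{Var}(y_{gi}) = \mu_{gi} + \phi_g \mu_{gi}^2, $$

$$ \log \mu_{gi} = \beta_{g,c(i)} + u_{\ell(i)} + \log N_i + o_g, $$

with one fixed effect $\beta_{g,c}$ per genotype × stage cell $c$ (six in
the standard design), a Gaussian sequencing-lane effect $u_\ell$ whose
precision carries a vague Gamma(0.5, 0.005) prior, the TMM-effective
library size $N_i$, and a per-gene capture offset $o_g$ estimated as an
additive natural-cubic-spline smooth (4 df per covariate) of log gene
length and GC content. Within a gene the log dispersion
$\lambda_g = \log\phi_g$ is constant across samples.

Across genes, the cell effects are exchangeable draws
$\beta_{g,c} \sim N(m_c, v_c)$ (unrestricted means, diagonal covariance)
and $\lambda_g \sim N(m_\phi, v_\phi)$. These cross-gene distributions act
as empirical-Bayes priors: weakly measured genes are shrunk toward the
transcriptome-wide behaviour, which is what makes a posterior activity
statement meaningful at four replicates.

**Inference.** Each gene's joint posterior over
$(\beta_{g,1..6}, u_{1..L}, \lambda_g, \log\tau)$ is approximated by a
Laplace step: the mode of log-prior + NB log-likelihood is found by
bounded quasi-Newton optimization (analytic gradients; restarts on
non-convergence; a gene that still fails falls back to its prior and is
flagged), and the Gaussian approximation comes from the inverse Hessian at
the mode. Hyperparameters are estimated by moment matching — the prior
variance of a cell effect is updated to the variance of posterior means
plus the mean posterior variance — iterated to a relative change below
$10^{-3}$ (at most 25 iterations). The lane-precision prior stays fixed
and vague; it is a nuisance, not a target. NB posteriors in this regime
are smooth and close to log-concave, so the Laplace approximation is
accurate at a small fraction of the cost of full posterior sampling; the
package verifies it against closed-form Poisson limits and
parameter-recovery simulations rather than against an MCMC reference.

**The activity rule.** A gene is active in a cell iff
$P_{gts}(T) = \Pr(\beta_{g,c} > T \mid y) > 0.5$ (strictly), evaluated
under the Gaussian marginal. The threshold $T$ is a scientific choice, not
an estimate: no count level is "zero transcription" in an absolute sense.
The default ties $T$ to the only count scale the analysis otherwise uses —
the five-read expression filter:
$T = \log 5 - \mathrm{median}_i \log N_i$, i.e. a gene at the boundary is
expected to yield five reads in the median-depth sample. `fit_activity()`
exposes `threshold` directly; published per-cell active-gene counts from
any particular dataset cannot pin down the value their authors used, so it
must be stated explicitly in any analysis.

**Numerical floors.** Posterior standard deviations are floored at
$10^{-6}$, prior variances at $10^{-6}$, and dispersion is bounded in
$[10^{-8}, 10^3]$; the log lane precision is bounded in $[-20, 20]$. The
crude initializer uses per-cell pooled rates
$\log\big((\sum y + 0.5)/\sum e^{\text{offset}}\big)$, clamped within six
units of the prior mean.

# Normalization

* **Expression filter** — a gene passes iff some genotype × stage cell has
  every replicate at or above `min_count` (default 5). The scope is
  per-cell by default because the differential contrasts are per stage;
  `scope = "genotype"` instead requires the bound across all samples of
  one genotype. Raising `min_count` can only shrink the passing set.
* **TMM** — factors come from the trimmed-mean-of-M-values method with its
  published defaults (30% M-trim, 5% A-trim, inverse-asymptotic-variance
  weights, reference chosen by the upper-quartile rule), rescaled to
  geometric mean 1. The test suite re-derives the doubly-trimmed weighted
  mean step by step and requires agreement to $10^{-10}$.
* **FPKM** — `count / (length/1e3) / (effective_size/1e6)`, using
  TMM-effective library sizes by default (`use_effective = FALSE` gives
  raw column sums) so that the expression matrix and the activity model
  share one notion of depth.
* **Length/GC offset** — per-gene mean $\log((y + 0.5)/N_i)$ regressed on
  `ns(log length, 4) + ns(gc, 4)`; fitted values centred to mean zero. A
  spline term is dropped when its covariate is constant; fewer than 50
  genes is refused as unstable.

# Differential expression and dynamics

Linear models run on $\log_2(\mathrm{FPKM} + 0.5)$ over filtered genes.
The pseudocount 0.5 stabilizes zeros; the scale and pseudocount are
exposed because neither is forced by the data. The sequencing lane enters
as a random effect through a consensus intra-lane correlation (per-gene
REML estimates combined on the atanh scale), and per-stage WT − MUT
contrasts are fitted by generalized least squares with that block
structure. Gene-wise variances are moderated by fitting a scaled
inverse-chi-square across genes (digamma/trigamma moment equations), and
p-values are adjusted by Benjamini–Hochberg — the default of the linear
modelling framework used, since the original procedure is identified only
as FDR control. One consensus correlation and one moderation fit are
shared across the three stages for stability at this scale. The DE rule is
the conjunction `q < fdr` and `|log2FC| >= lfc` (defaults 0.05 and 1).

Dynamics re-use the identical machinery within each genotype with
contrasts later-stage minus earlier-stage. Each transition is UP if
`q < fdr` and `log2FC >= lfc`, DOWN with the opposite sign, else SAME;
the all-SAME label is reported as NONE. Over $t$ stages this yields the
$3^{t-1}-1$ non-constant patterns. The rule-based assignment is the
authoritative clustering because it is reproducible from stated
thresholds; K-means on z-scored stage profiles (Lloyd's algorithm,
k-means++ seeding, 25 restarts, best within-cluster sum of squares) is
provided as a companion view for figure-style summaries, not as the
definition of a pattern.

# Promoter motifs

Promoters are the `promoter_len` (default 1000) bases immediately 5' of
the ATG — the translation start, not the transcription start site, which
is what the annotation schema's `atg_pos` must encode. Minus-strand genes
take the downstream window reverse-complemented; windows are clipped at
contig edges with a warning. Scanning is exact and counts overlapping
occurrences; `N` never matches. The default scans the sense strand only:
the hexamer GCGGCG is non-palindromic, so `both_strands = TRUE` genuinely
changes results and is surfaced as an explicit option rather than a
default.

# Enrichment

All enrichment uses the 2×2 chi-square with Yates' continuity correction,
$\sum (\max(|O-E| - 0.5, 0))^2 / E$ on 1 df, the correction floored at
zero so near-null tables cannot overshoot. Expected category counts come
from the distribution of a background set: by default the activity union
("expressed" genes) when an activity result is available, else the
filter-passing set — the notion of "expressed" is a configuration choice
(`background`), not a fact of the data. Genes in several categories count
once per category; under-representation is tested at the same alpha as
over-representation. Synteny enrichment compares a gene set's
non-syntenic fraction against a reference universe; when the set is a
subset of the reference the rows are positively dependent and the test is
slightly conservative, which matches how such printed contingencies are
normally presented.

# The synthetic-data generator

`simulate_experiment()` draws from exactly the generative model the
activity caller assumes — NB counts with per-gene lognormal dispersion,
Gaussian lane effects on the log scale, lognormal library sizes, a
parametric capture surface $a\log(\mathrm{len}) + \text{quadratic}(gc)$ —
plus truth labels for every planted feature: activity status (including
genotype-exclusive genes), DE genes with one signed $|\log_2FC| \ge 1$
effect applied at all stages, dynamic patterns with per-transition effects,
synteny labels whose non-syntenic odds are multiplied among DE genes, and
motif-free promoters with GCGGCG planted in a recorded fraction of DE
genes.

Defaults describe a desk-scale embryo experiment: 2 genotypes × 3 stages
× 4 replicates, 4 lanes (lane $=$ replicate index, as when one flow-cell
lane carries one replicate of every library), lane sd 0.05, baseline
log-relative-abundance $N(\log 10^{-4}, 1.5^2)$ (median 100 reads at a
million-read library), 20% inactive genes at an expected half read, 2.5%
genotype-exclusive genes per genotype, 10% DE genes with
$|\log_2FC| = 1 + \mathrm{Exp}(1)$, dispersion lognormal around 0.1,
non-syntenic base rate 0.39 with odds multiplier 2.7 among DE genes, and
motif planting in 37% of DE-gene promoters. Pattern quotas are opt-in.

What it does **not** emulate: read-level artefacts (mapping ambiguity,
positional bias, stacked-read removal), splice structure, correlated
gene–gene expression, batch structure beyond lanes, stage-varying DE
effects, and annotation errors. Passing tests therefore demonstrate that
the estimators recover the model they assume at realistic sizes — not that
the model captures every property of real maize embryo libraries.

# Problem sizes and observed behaviour

The test suite runs recovery experiments at 2000 genes (the smallest size
at which hyperparameter moment-matching is comfortably stable) and unit
checks at 200–600 genes; the end-to-end pipeline test uses 240 genes. At
the 2000-gene settings used in the acceptance checks, activity calling
with effects placed two log-units either side of the threshold reaches
sensitivity and specificity above 0.99; the moderated test's null
rejection rate at $p<0.05$ sits near 0.042 (slightly conservative, from
lane blocking plus moderation); per-call observed FDR under planted DE is
3–6%; and dynamic-pattern recovery is close to its boundary at ~0.90 —
the misses are almost entirely weakly expressed carriers whose transition
estimates land just outside the significance or fold-change gate, and the
label is essentially never flipped outright. Fitting 2000 gene posteriors
through one empirical-Bayes pass takes on the order of a minute on a
single core.

# Known limitations

* The Laplace marginal can understate tail probabilities for genes with
  very low counts and large dispersion; the activity decision only needs
  the posterior mass above a threshold, where the effect is second-order.
* The moment-matching update treats posterior variances as exact; at a few
  hundred genes the estimated prior variance is mildly biased upward.
* Activity calls across cells of one gene share data through the lane and
  dispersion parameters, so per-cell calls are not independent decisions.
* FPKM-scale linear modelling loses efficiency for very low counts
  relative to count-based models; the pattern-recovery boundary above is
  the visible consequence.
* `compare_genotype_patterns` counts only exact label agreement; near-miss
  overlaps (one transition differing) are not summarized.
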