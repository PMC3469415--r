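---
title: "Inferring directed genetic influence networks from multiple phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring directed genetic influence networks from multiple phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ginet)
```

## The problem and the model

A population segregating several genetic variants, measured for two or more
quantitative phenotypes, carries more information about genetic interactions
than either phenotype alone. A pairwise regression with an interaction term
detects *statistical epistasis* — the double-variant phenotype deviating
from additivity — but not which variant modifies the other. `ginet`
implements a reparametrization of epistasis into **directed influences**
that becomes identifiable precisely when the phenotypes are *partially
pleiotropic*: they share part of their genetic basis (so variants affect
both) but not all of it (so the two phenotypes respond in distinguishable
proportions).

The pipeline, in the order `run_influence_analysis()` executes it:

1. **Standardization and eigentraits.** Each phenotype is mean-centered and
   scaled to unit sample SD (n−1 denominator), removing arbitrary assay
   scales, then the matrix is factored by SVD,
   $P = U\,\mathrm{diag}(S)\,V^{T}$. The columns of $U$ — *eigentraits* —
   are orthogonal composite phenotypes, which makes per-eigentrait
   regressions independent in their design and optimizes covariate choice.
   The full decomposition is kept (no truncation), so everything done on
   eigentraits can be recomposed onto the original phenotypes without any
   loss of fit quality: ordinary least squares is linear in the response,
   hence coefficients estimated against $U$ and multiplied by
   $\mathrm{diag}(S) V^T$ equal coefficients estimated against $P$ directly.
   This identity is tested to 1e-10.

2. **Single-locus scans and covariates.** Per locus and eigentrait,
   $y = \mu + \beta x + \varepsilon$ by OLS, where $x \in [0,1]$ is the
   variant-allele probability (0 = reference allele). Loci with statistic
   $|\beta|/\mathrm{SE} \ge 3.55$ are *strong-effect variants* and enter
   subsequent pairwise fits as covariates, per eigentrait. The default
   3.55 corresponds to p < 0.01 under a 10,000-permutation extreme-value
   calibration at the original study's scale (218 samples, 5 loci, 2
   eigentraits); `single_locus_threshold()` recalibrates it for other
   designs by fitting a Gumbel distribution (maximum likelihood via BFGS on
   location/log-scale) to per-permutation maxima taken over loci and
   eigentraits jointly — the strictest accounting of the multiplicity.

3. **Pairwise fits.** For each locus pair and eigentrait $j$:
   $y_j = \mu_j + \beta_{1j} x_1 + \beta_{2j} x_2 + \beta_{12j} x_1 x_2 +
   \text{covariates} + \varepsilon$, excluding the pair itself from the
   covariate list. Because covariate sets differ between eigentraits, the
   coefficient covariance *across* eigentraits is assembled with
   seemingly-unrelated-regressions cross blocks,
   $\mathrm{Cov}(\theta_j, \theta_l) = \sigma_{jl} (X_j^T X_j)^{-1} X_j^T
   X_l (X_l^T X_l)^{-1}$, with residual covariance normalized as
   $\sigma_{jl} = e_j^T e_l / \sqrt{(n-p_j)(n-p_l)}$ so the diagonal equals
   the usual OLS estimate. These cross terms feed the error propagation
   below. Samples missing a genotype at the pair or a covariate locus are
   excluded from that fit only.

4. **Activity changes δ.** The reparametrization at the core of the method:
   $\beta_{12j} = \delta_1 \beta_{1j} + \delta_2 \beta_{2j}$, where
   $\delta_v$ is the change in variant $v$'s phenotype-relevant activity
   when the partner variant is present, assumed shared across phenotypes.
   With two eigentraits this is an exact change of variables (solve the
   2×2 main-effect matrix $B$); with more it is a least-squares fit via the
   pseudoinverse, and the residual norm is reported as a goodness-of-fit
   diagnostic of the shared-δ assumption. Matrix inversion can amplify
   noise, so a condition-number guard (default 1e8) flags near-singular
   $B$ as invalid instead of returning silently huge values.

5. **Influence coefficients γ.** A lone variant has baseline activity 1,
   so the partner's activity after interaction is $1 + \delta$. Writing
   each activity change as an influence times the partner's activity,
   $\delta_1 = \gamma_{1\leftarrow 2}(1+\delta_2)$ and
   $\delta_2 = \gamma_{2\leftarrow 1}(1+\delta_1)$, gives
   $\gamma_{1\leftarrow 2} = \delta_1/(1+\delta_2)$ and symmetrically for
   the other direction. Negative γ is suppression, positive enhancement.
   Directions with $|1+\delta|$ below 1e-8 are flagged undefined rather
   than divided through.

6. **Error propagation.** Variances of δ, γ, and recomposed effects come
   from the delta method over the full coefficient covariance (including
   the cross-eigentrait terms): analytic Jacobians through the linear
   solve and the γ algebra, central finite differences (relative step
   1e-6) for arbitrary user functions via `propagate_variance()`. The γ
   standard errors are verified against a 100,000-draw Monte-Carlo oracle
   to within 5% (measured ~0.3%).

7. **Significance.** The test statistic is |coefficient|/SE throughout,
   because it exists both for regression coefficients and for quantities
   derived from them. Pairwise coefficients are tested against **tandem
   permutations**: one shared row shuffle applied to the two tested
   genotype columns only, which retains the pair's mutual linkage while
   breaking genotype–phenotype association; covariates stay at observed
   values. The entire pipeline (fit → δ → γ → statistics) is re-evaluated
   per permutation, in compiled code. Empirical p-values use the add-one
   estimator $(r+1)/(n+1)$, which is valid at any permutation count and
   never exactly zero. P-values come from the empirical distributions
   directly — no extreme-value fit is used in the pairwise path, because
   fitted tails would overstate significance relative to the slightly
   heavier empirical tails.

8. **Averaging and the network.** Variant-to-phenotype coefficients are
   recomposed per pair model and averaged over all models containing the
   variant, with root-mean-square error
   $\sqrt{\overline{\mathrm{var}}/m}$ over the $m$ models — an
   independence approximation (the models share data), which is why their
   significance is *not* taken from a normal approximation but from
   per-permutation null averages (below). Variant-to-variant influences
   are uniquely determined per pair and are not averaged. Edges with Holm-
   adjusted p < α (default 0.05) form the directed network; sign is the
   coefficient sign, weight its magnitude.

## Numerical and design choices

* **SVD sign convention.** Each right singular vector is flipped (with its
  left partner) so its largest-magnitude loading is positive; output is
  reproducible across LAPACK builds.
* **Synchronized permutations.** Permutation index $b$ applies the *same*
  row shuffle to every pair (the shuffle sequence derives only from the
  master seed). Marginally, each pair's null is unchanged; jointly, the
  null of the averaged variant-to-phenotype statistic preserves the strong
  correlation between pair models that share a variant. With independent
  per-pair permutations that correlation is destroyed under the null and
  the averaged statistic becomes badly anticonservative (measured ~58%
  familywise false-edge rate on all-null data, versus the nominal 5%).
  Synchronization also makes results independent of pair processing order.
* **One Holm family.** All coefficients that can become network edges —
  the directed influences and the averaged variant-to-phenotype effects —
  are adjusted as a single family. Keeping two separate families (a
  defensible alternative) would control each class at α but bound the
  network-wide familywise error only at 2α; the package's stated guarantee
  is network-wide, so one family it is. Holm is valid under the dependence
  the synchronized permutations induce.
* **Guards.** Condition bound 1e8 on the main-effect matrix; 1e-8 on the
  γ denominators; rank-deficient pairwise designs (e.g. no double-variant
  samples, or identical genotype columns) are flagged `inestimable` and
  skipped with a reason, never fit.
* **Empirical p granularity.** With $n$ permutations the smallest
  achievable raw p is $1/(n+1)$; after Holm over $m$ coefficients the
  smallest adjusted p is $m/(n+1)$. Permutation counts must be chosen with
  the family size in mind (e.g. 1,000 permutations and 30 coefficients
  give a floor of 0.03).

## The synthetic-data generator

`simulate_genotypes()` draws independent Bernoulli loci (default frequency
0.5, optionally underrepresented alleles, optional Gaussian-copula linkage
for stressing the tandem permutation). `simulate_truth()` draws sparse
directed γ (default four influences with |γ| uniform in [0.3, 1]), solves
the coupled activity relations in closed form
($\delta_1 = \gamma_{12}(1+\gamma_{21})/(1-\gamma_{12}\gamma_{21})$),
resampling draws whose algebra degenerates, and derives per-pair
interaction coefficients. Main effects are drawn uniformly in ±[0.5, 1.5]
per locus × phenotype — every locus affects every phenotype at
phenotypically meaningful size, a deliberately harder setting than a
sparse-effect design. `simulate_phenotypes()` runs the pairwise regression
model forward (all true pairs' interaction terms plus Gaussian noise,
default SD 0.25 against main effects of order 1), which is exactly the
model class the inference fits, so noise-free single-interaction data are
recovered to machine precision.

What the generator does **not** emulate: mechanistic pathway dynamics,
selection-induced genotype dropout, genotyping error, non-Gaussian
phenotype noise, and batch structure in expression data. Passing recovery
tests on these simulations therefore demonstrates correctness of the
inference machinery under its own model assumptions, not robustness to
real-data pathologies.

## What the benchmark shows, and known limitations

The acceptance benchmark (`scripts/acceptance.R`) runs 50 replicate
populations of 500 samples, 6 loci, and 4 planted influences at noise SD
0.25 with 1,000 tandem permutations per pair, plus 200 all-null
populations for calibration. Problem sizes were chosen so the whole script
runs in minutes on one CPU. Three structural findings to keep in mind when
reading its output:

* **Direction resolvability is data-dependent.** The δ solve inverts the
  pair's main-effect matrix $B$. When a pair's two main-effect vectors
  across phenotypes are nearly collinear (ill-conditioned $B$ — which
  random main effects produce regularly), the interaction is detectable
  but its *direction* is statistically unresolvable: γ errors blow up and
  the edge is honestly reported insignificant. Recovery of planted
  directed influences is therefore substantially below 100% under random
  truths, concentrated in ill-conditioned pairs, at any sample size. This
  mirrors the method's stated reliance on complementary phenotype
  information; an inferred network maps the influences the data can
  resolve, not all influences that exist.
* **Cross-pair contamination.** Each pairwise fit models only its own
  interaction term; other pairs' true interactions remain in the residual
  and correlate with the fitted terms at finite-sample order
  $1/\sqrt{n}$ (exactly zero in expectation for independent centered
  loci). Under dense truths this biases neighboring pairs' coefficients
  and produces reverse-direction and shared-locus false positives beyond
  what the null calibration alone would predict — the per-possible-edge
  false-positive rate stays within a few percent, but the share of false
  edges among *discovered* edges can be sizable. The tandem-permutation
  null cannot represent this contamination because permuting the pair
  destroys it.
* **Calibration under the global null is clean**: familywise false-edge
  rate at the nominal level and uniform permutation p-values (KS test),
  so discoveries on truly null data are controlled as advertised.

For the expression mode, phenotype rows are appended scaled to SD 2 (the
scale of log2-ratio microarray data, where ±2 is a four-fold change) and
act as negligible-weight markers: on a 5,000-gene synthetic instance their
inclusion perturbs mode sample patterns by less than 1e-3. Mode gene sets
use gene-weight mean ± 2 SD computed over genes only (the appended
phenotype rows are markers, not genes, and are excluded — the alternative
inclusion changes thresholds negligibly at realistic gene counts).
Enrichment uses the one-sided Fisher/hypergeometric tail; GO-style
interdependent terms get a gene-name-permutation FDR estimate (default
1,000 permutations at cutoff 1e-4), TF-target panels a Bonferroni factor
for the number of factors tested. Using leading modes as composite
phenotypes for the pair scan skips re-standardization (they are already
orthonormal); adding modes beyond the informative ones adds least-squares
rows with no signal to the δ solve, so significance weakens monotonically
on fixed data — tested as non-decreasing p-values for a fixed true
influence as modes go 3 → 5.

## Parameter reference

| parameter | default | where | meaning |
|---|---|---|---|
| `covariate_threshold` | 3.55 | scans | single-locus \|β\|/SE cutoff for strong-effect covariates (p < 0.01 at the original calibration) |
| `n_perm` | 100,000 (pipeline), 1,000 (desk-scale runs) | significance | tandem permutations per pair |
| `alpha` | 0.05 | network | adjusted-p cutoff for edges |
| `cond_bound` | 1e8 | influences | condition-number guard on the main-effect matrix |
| `tol` | 1e-8 | influences | γ denominator guard |
| `target_sd` | 2 | expression | SD of appended phenotype rows |
| `k_sd` | 2 | expression | mode-weight threshold for gene sets |
| `noise_sd` | 0.25 | synthetic | phenotype noise SD against O(1) main effects |
| `effect_range` | [0.3, 1] | synthetic | magnitude range of planted influences |

All seeds are explicit arguments; identical seeds give bit-identical
results, including across pair processing orders.
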