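# ginet — directed genetic influence networks from multi-phenotype populations

`ginet` infers **directed, signed genetic-interaction networks** from a
genotyped population measured for two or more partially pleiotropic
quantitative phenotypes. Classical pairwise epistasis scans report that two
variants interact; they do not say *which variant modifies the other, in
which direction, and by how much*. When the measured phenotypes share part
of their genetic basis but not all of it (partial pleiotropy), that
complementary information is enough to reparametrize statistical epistasis
into **variant-to-variant influences**: directed coefficients γ where
γ < 0 means suppression and γ > 0 enhancement. The approach was developed
for a haploid yeast cross segregating five mating-pathway perturbations
scored for mating efficiency and pheromone response, and applies to any
population with variant-allele probabilities and ≥ 2 quantitative
phenotypes (including SVD modes of expression data as composite
phenotypes).

## The model

1. **Eigentraits.** Phenotypes are mean-centered, scaled to unit SD, and
   factored by SVD, `P = U diag(S) Vᵀ`. The columns of `U` are orthogonal
   composite phenotypes ("eigentraits"); for two positively correlated
   phenotypes they are the normalized sum and difference. No truncation is
   done, so results recompose to the original phenotypes without loss.
2. **Single-locus scans.** Per locus and eigentrait, `y = μ + βx + ε` by
   OLS, with `x` the variant-allele probability. Loci with
   `|β|/SE ≥ 3.55` (p < 0.01 under a 10,000-permutation extreme-value
   calibration) become *strong-effect covariates*.
3. **Pairwise scans.** For every locus pair, per eigentrait `j`:
   `y_j = μ_j + β_1j x₁ + β_2j x₂ + β_12j x₁x₂ + covariates + ε`.
   A significant interaction coefficient `β_12j` is statistical epistasis.
4. **Activity changes.** The interaction coefficients across eigentraits
   are reparametrized by `β_12j = δ₁ β_1j + δ₂ β_2j`: δ₁ is the inferred
   change in variant 1's activity caused by the presence of variant 2,
   shared across phenotypes (solved exactly for 2 eigentraits, by least
   squares for more).
5. **Influences.** Writing each activity change as an influence times the
   partner's activity, `δ₁ = γ₁←₂ (1 + δ₂)` and `δ₂ = γ₂←₁ (1 + δ₁)`,
   gives the directed influence coefficients
   `γ₁←₂ = δ₁ / (1 + δ₂)`, `γ₂←₁ = δ₂ / (1 + δ₁)`.
6. **Errors and significance.** Standard errors propagate from the full
   OLS coefficient covariance by the delta method (`Var f = Σ_pq ∂f/∂θ_p
   ∂f/∂θ_q Cov(θ_p, θ_q)`). Significance uses |coefficient|/SE statistics
   against **tandem permutations** — the two tested genotype columns are
   row-shuffled jointly, preserving their linkage — with empirical
   p-values and Holm step-down control of the familywise error rate.
   Variant-to-phenotype effects are recomposed per pair via `diag(S) Vᵀ`,
   averaged across all pairwise models containing the variant, and tested
   against per-permutation null averages.
7. **Network.** Edges with adjusted p < 0.05: directed variant→variant
   influences (taken per pair; uniquely determined, not averaged) and
   averaged variant→phenotype effects. Export as TSV, SIF, or GraphML.

A synthetic-data module generates populations with known ground-truth
influence networks (the generative model is the pairwise regression model
run forward), so every stage of the inference has recovery tests.

## Worked example

Simulate a study-scale population (218 strains, 5 loci, 3 planted
influences), run the full analysis, and inspect the network — from the
shell via the bundled CLI:

```sh
Rscript inst/cli/ginet simulate --n 218 --loci 5 --influences 3 --seed 17 --out demo
Rscript inst/cli/ginet run --genotypes demo_genotypes.tsv \
    --phenotypes demo_phenotypes.tsv --nperm-pair 2000 --seed 1 --out demo_run
```

```
influence_scan: 5 loci, 10 pairs, 2000 permutations/pair (seed 1)
influence_network: 7 nodes, 13 edges (adjusted p < 0.05)
   from to              type       coef     p_adj
1    L2 L1   variant-variant  1.2762557 0.0149925
2    L4 L2   variant-variant -0.4074401 0.0149925
3    L5 L4   variant-variant -1.0955335 0.0149925
4    L1 P1 variant-phenotype  0.6012712 0.0149925
...
```

The three variant-variant edges are exactly the planted truth
(`demo_truth.tsv`: L1←L2 at γ = 0.93, L2←L4 at γ = −0.36, L4←L5 at
γ = −0.86), each recovered with the correct sign: `coef` is the directed
influence γ (positive = enhancement, negative = suppression), and the
remaining rows are the averaged variant-to-phenotype effects. Equivalent
calls from R:

```r
library(ginet)
tr <- simulate_truth(loci = 5, phenotypes = 2, n_influences = 3, seed = 17)
G  <- simulate_genotypes(218, 5, seed = 18)
ph <- simulate_phenotypes(G, tr, seed = 19)
res <- run_influence_analysis(G, ph, n_perm = 2000, seed = 1)
res$network
```

The results bundle (`--out DIR` / `out_dir =`) contains `eigentraits.tsv`,
`single_locus.tsv`, `pairwise.tsv`, `influences.tsv`, `effects.tsv`,
`network.tsv`, `network.graphml`, and `run.json` (seeds, permutation
counts, covariate sets).

Expression mode: `augment_with_phenotypes()` appends phenotypes (scaled to
SD 2) as rows of a genes × samples log2-ratio matrix,
`decompose_expression()` extracts SVD modes with per-mode variance
fractions, `mode_gene_sets()` takes ±2 SD gene sets, `enrichment()` tests
annotation terms (Fisher exact; gene-name-permutation FDR for GO,
Bonferroni for TF targets), and `modes_as_phenotypes()` feeds the leading
modes back into the pair scan as composite phenotypes.

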