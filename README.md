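# sevnet — severity-matched symptom network analysis

`sevnet` asks a concrete question from psychiatric epidemiology: **does the
structure of symptom interrelations change across levels of illness
severity?** It is written for researchers comparing psychometric networks
between groups that differ in symptom severity — a comparison that is
confounded out of the box, because severer groups endorse more symptoms,
which inflates item variances and hence every covariance-based network
statistic.

The package implements the full severity-matched comparison pipeline:

1. **Prevalence-matched binarization.** Per group g and symptom domain d, an
   integer cutoff c(g, d) on the domain sum score (endorsed iff score ≥
   cutoff) is fitted so all groups reach a common target prevalence. Binary
   variance is p(1 − p), so matched prevalences mean matched variances:
   severity is removed as a confound before any network is estimated.
2. **Ising network estimation (eLasso).** Per group, a pairwise Markov
   random field P(x) ∝ exp(Σ τᵢxᵢ + Σ βᵢⱼxᵢxⱼ) over the binary domains is
   estimated by nodewise L1-penalised logistic regressions with EBIC
   (−2ℓ + k·log n + 2γk·log(p−1), γ = 0.25) penalty selection, AND-rule
   symmetrisation, and edge weight = mean of the two directed coefficients.
3. **Network comparison.** Global strength S = Σᵢ<ⱼ |wᵢⱼ| is compared for
   every pair of groups by a permutation test (pool the individuals,
   regroup at the original sizes, refit both networks, repeat); structural
   similarity is summarised by Spearman correlations of edge weights and
   Jaccard indices of edge sets.
4. **Community detection.** Walktrap and Girvan–Newman partitions scored by
   weighted Newman modularity Q, with Q > 0.30 flagged as clear structure,
   plus adjusted-Rand comparison of community assignments across groups.
5. **Stability.** Bootstrap percentile CIs and selection frequencies per
   edge, and a parallel unweighted (presence/absence) re-analysis.

Because the kind of cohort data this targets is typically
access-restricted, the package also ships a **synthetic cohort generator**
with a known Ising ground truth (11 domains; a planted ADHD-like triple and
a depression/anxiety-like quadruple; four severity groups with ordered
severity offsets and floor effects), exact enumeration and Gibbs samplers
for small binary Markov random fields, and an exhaustive modularity oracle —
so every stage of the pipeline is testable against exact answers.

## Worked example

```r
library(sevnet)

spec <- cohort_spec(seed = 1)          # 4 groups: 492 / 205 / 291 / 303
cohort <- generate_ordinal_cohort(spec)

scheme <- fit_thresholds(cohort$domain_scores, cohort$group_labels)
binary <- apply_thresholds(cohort$domain_scores, cohort$group_labels, scheme)
scheme$cutoffs[, 1:4]
#>   DEP NCOG WOR FEAR
#> 1   3    3   3    3
#> 2   4    4   4    4
#> 3   4    4   4    4
#> 4   5    5   5    5
```

The most severe group gets the highest cutoffs — the severity correction.
Post-threshold prevalences are comparable across groups (maximum cross-group
range 0.08, inside the integer-cutoff discreteness bound), and
`variance_equality_test(binary)` finds no significant variance differences
(Brown–Forsythe p-values 0.12–0.97 across the 11 domains).

```r
report <- pairwise_comparison_report(binary, n_permutations = 500, seed = 1)
round(report$strengths, 3)
#> group1 group2 group3 group4
#>  8.535  9.440  5.107  7.423
report$comparisons[, c("group_a", "group_b", "difference", "p_value")]
#>   group_a group_b difference p_value
#> 1       1       2      0.905  0.6667
#> 2       1       3      3.428  0.0259
#> 3       1       4      1.112  0.3892
#> 4       2       3      4.333  0.0299
#> 5       2       4      2.017  0.1657
#> 6       3       4      2.316  0.0898
```

All four groups share one latent dependence structure; the residual
strength differences come from finite samples and from severity-dependent
attenuation of the ordinal emission, and only the comparisons against the
sparsest fitted network (group 3) dip below 0.05 before any multiplicity
correction. Edge-weight Spearman correlations between groups run 0.86–0.99
and Jaccard indices 0.73–1.00. Community detection recovers the planted
structure in every group:

```r
parts <- lapply(report$networks, walktrap_communities)
community_report(parts)$summary
#>    group n_communities modularity_Q algorithm clear_structure
#> 1 group1             5        0.495  walktrap            TRUE
#> 2 group2             6        0.443  walktrap            TRUE
#> 3 group3             6        0.497  walktrap            TRUE
#> 4 group4             6        0.477  walktrap            TRUE
parts$group1
#> Partition (walktrap): 5 communities, Q = 0.4946
#> $`1`
#> [1] "DEP"  "NCOG" "WOR"  "FEAR"
#> $`2`
#> [1] "FAT" "ATT" "HYP" "IMP"
#> ...
```

The depression/anxiety-like quadruple (DEP/NCOG/WOR/FEAR) and the ADHD-like
triple (ATT/HYP/IMP) form separate communities in each group, each with
Q above the 0.30 clear-structure convention (in group 1 a spurious FAT–ATT
edge attaches fatigue to the ADHD community — the kind of instability the
stability stage exists to flag). `bootstrap_edges()` then quantifies edge
uncertainty, and `robustness_reanalysis()` repeats strength, comparison and
community results on unweighted networks.

One call runs everything and writes CSV/JSON/GraphML artifacts:

```r
res <- run_pipeline(pipeline_config(spec = cohort_spec(),
                                    n_permutations = 500, n_boot = 250,
                                    seed = 1, out_dir = "out"))
```

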