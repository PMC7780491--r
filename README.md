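# migmod

Systems-genetics pipeline for finding gene co-expression modules enriched
in rare functional variants that segregate with disease in families — the
analysis design used to study Mendelian-like migraine pedigrees, packaged
as reusable, tested R functions with synthetic-data generators for every
input.

## Who this is for

Statistical geneticists integrating two data types on one gene universe:

- **expression** (bulk RNA-seq or single-nuclei counts, genes × samples),
  from which tissue-specific co-expression modules are derived, and
- **whole-genome variant calls** for disease pedigrees (plus optional
  sporadic-case and population-control cohorts), from which per-gene rare
  functional mutation status is derived.

The pipeline asks: *do rare, functional, co-segregating mutations pile up
in particular co-expression modules, and does that excess replicate in an
independent cohort?*

## The method in brief

1. **Network.** Keep the top genes by connectivity
   `k_i = Σ_j |cor(x_i, x_j)|`; build the unsigned weighted adjacency
   `a_ij = |cor|^β`, with β the smallest power whose connectivity
   distribution meets the scale-free criterion (signed R² ≥ 0.8). Convert
   to topological-overlap dissimilarity
   `1 − (l_ij + a_ij) / (min(k_i,k_j) + 1 − a_ij)`, averaged over 100
   leave-10%-out sample resamples (a *consensus* TOM).
2. **Modules.** Average-linkage clustering with adaptive branch pruning;
   clusters under 30 genes fall into the unassigned "grey" label; modules
   are named by the conventional color sequence, largest = turquoise.
   Modules are validated by permutation: mean within-module overlap vs
   same-size random gene sets.
3. **Mutated genes.** A gene is *mutated* when it carries a variant that is
   (i) in one of eight functional classes (frameshift/non-frameshift
   indels, non-synonymous SNV, splice site, stop-gain/loss), (ii) rare
   (population MAF < 5%, missing ⇒ rare), and (iii) co-segregating with
   affection in ≥ 1 family under a dominant model with penetrance ≥ 0.9.
   Genes with variants but none qualifying are *non-mutated*; genes with no
   observable variation are excluded.
4. **Burden.** Per module, a one-tailed Fisher exact test on mutated vs
   non-mutated genes inside vs outside the module, Bonferroni-corrected
   over tested modules; modules whose mutated genes have significantly
   higher intolerance scores (RVIS) are excluded beforehand. Replication =
   significant burden in an independent case cohort but not in population
   controls, tested separately.
5. **Annotation.** Expression-weighted cell-type enrichment (summed
   specificity vs 10 000 bootstrap gene sets) and binomial pathway
   over-representation with BH-FDR.

Every input has a synthetic generator with known ground truth
(`simulate_modular_expression()`, `simulate_families()`,
`simulate_variant_table()`, `simulate_specificity_data()`), so the whole
pipeline is testable end to end without access to any cohort data.

## Worked example

Plant five 50-gene modules (within-module correlation 0.7) among 200 noise
genes, enrich one module for segregating rare variants in 40 simulated
families (qualifying rate 0.35 vs 0.05 background), and run discovery:

```r
library(migmod)

sim  <- simulate_modular_expression(n_background = 200, module_sizes = rep(50, 5),
                                    n_samples = 100, within_module_cor = 0.7, seed = 1)
fams <- simulate_families(40, penetrance = 0.9, phenocopy_rate = 0, seed = 101)
truth <- sim$truth$true_module_labels
sv   <- simulate_variant_table(names(truth), truth, enriched_module = "module_1",
                               families = fams, qualifying_rate_base = 0.05,
                               qualifying_rate_enriched = 0.35, seed = 301)

cfg  <- run_config(expression = sim$expr, vcf = sv$variants,
                   ped = lapply(fams, `[[`, "pedigree"),
                   k = 450, powers = 1:30, n_resamples = 100,
                   n_permutations = 1000, seed = 77)
disc <- run_discovery(cfg)
#> expression: 450 genes x 100 samples
#> soft threshold: power 23 (signed R^2 0.821)
#> modules: 5 detected (+ 216 grey genes)
#> genes: 450 detectable, 43 mutated, 0 undetected

disc$burden[, c("module", "a", "b", "c", "d", "odds_ratio", "p_adj", "significant")]
#>      module  a  b  c   d odds_ratio    p_adj significant
#> 1 turquoise 19 31 24 376      9.602 1.48e-08        TRUE
#> 2     brown  4 44 39 363      0.846 1.00e+00       FALSE
#> 3     green  2 37 41 370      0.488 1.00e+00       FALSE
#> 4    yellow  5 43 38 364      1.114 1.00e+00       FALSE
#> 5      blue  1 48 42 359      0.178 1.00e+00       FALSE
```

Reading the table: `a`/`b` are mutated/non-mutated genes inside the module,
`c`/`d` the same outside (only genes with detectable variation count). The
planted enrichment surfaces as the turquoise module — 19 of its 50 genes
carry qualifying co-segregating variants against a ~10% background rate,
odds ratio 9.6, Bonferroni-adjusted p ≈ 1.5e-08 — while the four undisturbed
modules stay at the null. `run_replication()` then takes case/control
cohort VCFs and flags modules significant in cases but not controls.

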