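## Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

## Planted-module expression: 5 modules of 50 genes at r = 0.7 plus 200
## background genes, 100 samples — the standard recovery fixture.
recovery_sim <- function() cached("recovery_sim",
  simulate_modular_expression(n_background = 200, module_sizes = rep(50, 5),
                              n_samples = 100, within_module_cor = 0.7,
                              seed = 1))

## Full network stage on the recovery fixture: soft threshold over a wide
## power scan, consensus TOM with the default 100 leave-10%-out resamples.
recovery_network <- function() cached("recovery_network", {
  sim <- recovery_sim()
  fit <- pick_soft_threshold(sim$expr, candidate_powers = 1:30)
  net <- consensus_tom(sim$expr, fit$power, n_resamples = 100,
                       leave_out_fraction = 0.1, seed = stage_seed(1, "net"))
  list(sim = sim, fit = fit, net = net,
       modules = detect_modules(net, min_module_size = 30))
})

## The same planted expression at the conventional unsigned-network power 6:
## overlap magnitudes at very high powers are exponentially sensitive to the
## realized within-module correlation, so permutation-calibration checks use
## a moderate power where every planted module keeps non-degenerate overlap.
validation_network <- function() cached("validation_network", {
  sim <- recovery_sim()
  consensus_tom(sim$expr, beta = 6, n_resamples = 50,
                leave_out_fraction = 0.1, seed = stage_seed(1, "valnet"))
})

## Family cohort shared by the variant-side tests (40 families, dominant
## allele at penetrance 0.9, no phenocopies).
family_cohort <- function() cached("family_cohort",
  simulate_families(40, n_generations = 3, children_per_couple = 3,
                    penetrance = 0.9, phenocopy_rate = 0, seed = 101))

## A small synthetic module assignment over 1000 genes: ten blocks of 100,
## the last labeled grey.
toy_modules <- function() {
  genes <- sprintf("G%04d", 1:1000)
  stats::setNames(rep(c("turquoise", "blue", "brown", "yellow", "green",
                        "red", "black", "pink", "magenta", "grey"),
                      each = 100), genes)
}

## Build a pedigree from inline PED text (whitespace separated rows).
ped_from_text <- function(text) {
  path <- withr::local_tempfile(fileext = ".ped",
                                .local_envir = parent.frame())
  writeLines(text, path)
  read_pedigrees(path)
}

## A pedigree of unrelated founders with given affection flags, plus a
## genotype vector: the minimal input for segregation-rule checks.
segregation_case <- function(affected, dosage) {
  n <- length(affected)
  ids <- sprintf("P%02d", seq_len(n))
  ped <- ped_from_text(paste("F1", ids, "0 0 1",
                             ifelse(affected, "2", "1")))[["F1"]]
  list(ped = ped, genotypes = stats::setNames(dosage, ids),
       variant = data.frame(chrom = "1", pos = 1L, ref = "A", alt = "T",
                            consequence = "nonsynonymous_SNV", maf = 0.001,
                            gene = "G1"))
}
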