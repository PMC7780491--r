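test_that("functional classes and the MAF filter follow the stated rules", {
  expect_true(is_functional("stopgain"))
  expect_true(all(is_functional(FUNCTIONAL_CLASSES)))
  expect_false(is_functional("other"))        # synonymous etc. map to other
  expect_false(is_functional("unknown_thing" == "never"))

  expect_true(passes_maf(0.049))
  expect_false(passes_maf(0.05))              # strict inequality
  expect_true(passes_maf(NA_real_))           # absent from reference => rare
  expect_true(passes_maf(0))
  expect_equal(passes_maf(c(0.01, NA, 0.2)), c(TRUE, TRUE, FALSE))
})

test_that("maximum credible allele frequency matches the closed forms", {
  expect_equal(max_credible_af(1, "monoallelic", 1, 1, 1), 0.5)
  expect_equal(max_credible_af(1, "biallelic", 1, 1, 1), 1.0)
  expect_equal(max_credible_af(0.2, "biallelic", 1, 0.05, 0.9),
               sqrt(0.2 / 0.9) * 0.05, tolerance = 1e-12)
  expect_equal(max_credible_af(0.001, "monoallelic", 0.5, 0.1, 0.8),
               0.001 * 0.5 * 0.1 / (2 * 0.8), tolerance = 1e-12)
  expect_error(max_credible_af(0.2, "monoallelic", penetrance = 0),
               "penetrance")
})

test_that("the dominant segregation rule reproduces its truth table", {
  model <- segregation_model(penetrance_min = 0.9)

  ## 4 affected carriers + 3 unaffected non-carriers: segregates
  cs <- segregation_case(affected = rep(c(TRUE, FALSE), c(4, 3)),
                         dosage = rep(c(1L, 0L), c(4, 3)))
  expect_true(segregates_in_family(cs$variant, cs$genotypes, cs$ped, model))

  ## any affected non-carrier breaks condition (a)
  cs2 <- segregation_case(affected = rep(c(TRUE, FALSE), c(4, 3)),
                          dosage = c(1L, 1L, 1L, 0L, 0L, 0L, 0L))
  expect_false(segregates_in_family(cs2$variant, cs2$genotypes, cs2$ped, model))

  ## 9 affected carriers + 1 unaffected carrier: 0.9 >= 0.9 passes
  cs3 <- segregation_case(affected = rep(c(TRUE, FALSE), c(9, 1)),
                          dosage = rep(1L, 10))
  expect_true(segregates_in_family(cs3$variant, cs3$genotypes, cs3$ped, model))

  ## 8 affected + 2 unaffected carriers: 0.8 < 0.9 fails
  cs4 <- segregation_case(affected = rep(c(TRUE, FALSE), c(8, 2)),
                          dosage = rep(1L, 10))
  expect_false(segregates_in_family(cs4$variant, cs4$genotypes, cs4$ped, model))

  ## unknown-phenotype members are excluded from both counts
  ped_unk <- ped_from_text(c("F1 a 0 0 1 2", "F1 b 0 0 1 1",
                             "F1 u 0 0 1 0"))$F1
  gt <- c(a = 1L, b = 0L, u = 1L)     # unknown carrier must not dilute
  expect_true(segregates_in_family(cs$variant, gt, ped_unk, model))

  ## no genotyped affected member: FALSE with a warning
  gt_na <- c(a = NA_integer_, b = 0L, u = 1L)
  expect_warning(
    out <- segregates_in_family(cs$variant, gt_na, ped_unk, model),
    "genotyped")
  expect_false(out)
})

test_that("familial gene status recovers planted truth with clean recall", {
  fams <- family_cohort()
  genes <- sprintf("G%04d", 1:1000)
  sv <- simulate_variant_table(genes, toy_modules(), "turquoise", fams,
                               qualifying_rate_base = 0.05,
                               qualifying_rate_enriched = 0.30, seed = 71)
  st <- gene_status_familial(sv$variants, fams, genes)
  ## every gene got a common variant, so nothing is undetected
  expect_true(all(st$status != "undetected"))
  ## all planted causal genes called mutated
  expect_equal(mean(st$status[st$gene %in% sv$truth$causal_genes] == "mutated"),
               1.0)
  ## nothing outside the planted truth is called mutated
  expect_true(all(st$gene[st$status == "mutated"] %in% sv$truth$causal_genes))
  ## family counts match the generator ledger
  counts <- table(sv$truth$causal_variants$gene)
  for (g in names(counts))
    expect_gte(st$n_families[st$gene == g], 1L)
})

test_that("status handles undetected genes and non-qualifying variants", {
  fams <- family_cohort()[1:2]
  individuals <- unlist(lapply(fams, function(f) f$pedigree$members$individual_id))
  v <- data.frame(chrom = "1", pos = c(100L, 200L),
                  ref = "A", alt = "T",
                  consequence = c("other", "nonsynonymous_SNV"),
                  maf = c(0.3, 0.2),      # second one functional but common
                  gene = c("G1", "G2"), stringsAsFactors = FALSE)
  gt <- matrix(1L, 2, length(individuals),
               dimnames = list(NULL, individuals))
  vt <- migmod:::new_variant_table(v, gt)
  st <- gene_status_familial(vt, fams, c("G1", "G2", "G3"))
  expect_equal(stats::setNames(st$status, st$gene),
               c(G1 = "non_mutated", G2 = "non_mutated", G3 = "undetected"))
})

test_that("cohort status needs a carrier and calibrates to the base rate", {
  genes <- sprintf("G%04d", 1:400)
  sv <- simulate_variant_table(genes, qualifying_rate_base = 0.08,
                               seed = 72, cohort_size = 150)
  st <- gene_status_cohort(sv$variants, genes)
  n_mut <- sum(st$status == "mutated")
  expect_gte(n_mut, qbinom(0.005, 400, 0.08))
  expect_lte(n_mut, qbinom(0.995, 400, 0.08))

  ## a qualifying variant nobody carries does not make a gene mutated
  v <- data.frame(chrom = "1", pos = 1L, ref = "A", alt = "T",
                  consequence = "stopgain", maf = 0.001, gene = "G1",
                  stringsAsFactors = FALSE)
  vt0 <- migmod:::new_variant_table(v, matrix(0L, 1, 3,
           dimnames = list(NULL, c("i1", "i2", "i3"))))
  expect_equal(gene_status_cohort(vt0, "G1")$status, "non_mutated")
  vt1 <- migmod:::new_variant_table(v, matrix(c(0L, 1L, 0L), 1, 3,
           dimnames = list(NULL, c("i1", "i2", "i3"))))
  expect_equal(gene_status_cohort(vt1, "G1")$status, "mutated")
})

test_that("status respects MAF monotonicity and familial/cohort nesting", {
  fams <- family_cohort()[1:10]
  genes <- sprintf("G%04d", 1:200)
  sv <- simulate_variant_table(genes, families = fams,
                               qualifying_rate_base = 0.2, seed = 73)
  mutated_at <- function(thr) {
    st <- gene_status_familial(sv$variants, fams, genes, maf_threshold = thr)
    st$gene[st$status == "mutated"]
  }
  m1 <- mutated_at(0.01); m2 <- mutated_at(0.05); m3 <- mutated_at(0.5)
  expect_true(all(m1 %in% m2))
  expect_true(all(m2 %in% m3))

  st_fam <- gene_status_familial(sv$variants, fams, genes)
  st_coh <- gene_status_cohort(sv$variants, genes)
  fam_mut <- st_fam$gene[st_fam$status == "mutated"]
  coh_mut <- st_coh$gene[st_coh$status == "mutated"]
  expect_true(all(fam_mut %in% coh_mut))
})
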