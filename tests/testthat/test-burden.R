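## Enumeration oracle: upper-tail hypergeometric probability from binomial
## coefficients only (independent of dhyper).
enum_upper_tail <- function(a, b, c_, d) {
  N <- a + b + c_ + d; K <- a + c_; n <- a + b
  xs <- max(0, K + n - N):min(K, n)
  masses <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  sum(masses[xs >= a])
}

test_that("one-tailed Fisher matches closed forms and enumeration", {
  expect_equal(fisher_one_tailed(matrix(c(1, 0, 0, 1), 2))$p, 0.5)
  expect_equal(fisher_one_tailed(matrix(c(0, 0, 5, 7), 2))$p, 1)

  t1 <- matrix(c(10, 20, 90, 880), 2)
  expect_equal(fisher_one_tailed(t1)$p, enum_upper_tail(10, 90, 20, 880),
               tolerance = 1e-12)
  ## agreement with the standard exact test implementation
  expect_equal(fisher_one_tailed(t1)$p,
               fisher.test(t1, alternative = "greater")$p.value,
               tolerance = 1e-12)
  ## odds ratio: plain cross product, +0.5 everywhere when a cell is 0
  expect_equal(fisher_one_tailed(t1)$odds_ratio, (10 * 880) / (90 * 20))
  expect_equal(fisher_one_tailed(matrix(c(3, 0, 4, 8), 2))$odds_ratio,
               (3.5 * 8.5) / (4.5 * 0.5))
  expect_error(fisher_one_tailed(matrix(c(-1, 0, 1, 2), 2)), "non-negative")
})

test_that("Fisher p agrees with enumeration over random tables", {
  withr::with_seed(81, {
    for (i in 1:200) {
      cells <- rmultinom(1, sample(4:80, 1), runif(4))[, 1]
      tab <- matrix(cells, 2)
      expect_equal(fisher_one_tailed(tab)$p,
                   enum_upper_tail(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                   tolerance = 1e-10)
    }
  })
})

test_that("intolerance-score filter excludes only tolerant-mutated modules", {
  genes <- paste0("g", 1:40)
  modules <- stats::setNames(rep(c("m1", "m2"), each = 20), genes)
  status <- data.frame(
    gene = genes,
    status = rep(rep(c("mutated", "non_mutated"), each = 10), 2),
    n_families = 0L)

  ## clear separation: mutated genes far more tolerant -> excluded
  scores <- stats::setNames(c(rep(3, 10), rep(0, 10),
                              rnorm(20, 0, 0.1)), genes)
  res <- suppressWarnings(rvis_module_filter(modules, status, scores))
  expect_true(res$excluded[res$module == "m1"])
  expect_false(res$excluded[res$module == "m2"])

  ## identical distributions -> retained
  same <- stats::setNames(rep(c(1, 2), 20), genes)
  res2 <- rvis_module_filter(modules, status, same)
  expect_false(any(res2$excluded))

  ## one-sidedness: mutated genes LESS tolerant -> retained regardless
  flip <- stats::setNames(c(rep(0, 10), rep(3, 10), rnorm(20)), genes)
  res3 <- rvis_module_filter(modules, status, flip)
  expect_false(res3$excluded[res3$module == "m1"])

  expect_error(rvis_module_filter(modules, status, numeric()), "score")
})

test_that("burden test counts, adjusts, and reports intervals correctly", {
  modules <- toy_modules()
  status <- data.frame(gene = names(modules), status = "non_mutated",
                       n_families = 0L, stringsAsFactors = FALSE)
  ## plant 30 mutated in turquoise, 45 spread outside, 5 undetected
  status$status[1:30] <- "mutated"
  status$status[seq(101, 981, by = 20)] <- "mutated"
  status$status[996:1000] <- "undetected"
  tested <- setdiff(unique(modules), "grey")
  res <- module_burden_test(modules, status, tested)
  tq <- res[res$module == "turquoise", ]
  expect_equal(c(tq$a, tq$b), c(30, 70))
  expect_equal(tq$a + tq$b + tq$c + tq$d, 995)   # undetected excluded
  expect_equal(res$p_adj, pmin(1, res$p * length(tested)))
  expect_true(tq$significant)
  expect_true(tq$ci_low > 1)
  expect_true(all(res$ci_low <= res$odds_ratio & res$odds_ratio <= res$ci_high))
  ## grey genes stay in the background counts
  expect_equal(unique(res$a + res$b + res$c + res$d), 995)
})

test_that("burden test has power for planted enrichment across seeds", {
  fams <- family_cohort()
  genes <- sprintf("G%04d", 1:1000)
  modules <- toy_modules()
  tested <- setdiff(unique(modules), "grey")
  hits <- vapply(1:20, function(s) {
    sv <- simulate_variant_table(genes, modules, "turquoise", fams,
                                 qualifying_rate_base = 0.05,
                                 qualifying_rate_enriched = 0.30,
                                 seed = 9000 + s)
    st <- gene_status_familial(sv$variants, fams, genes)
    res <- module_burden_test(modules, st, tested)
    res$significant[res$module == "turquoise"]
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("burden test keeps its family-wise error under the null", {
  fams <- family_cohort()[1:10]
  genes <- sprintf("G%03d", 1:200)
  modules <- stats::setNames(rep(c("m1", "m2", "m3", "m4", "m5"), each = 40),
                             genes)
  any_hit <- vapply(1:100, function(s) {
    sv <- simulate_variant_table(genes, families = fams,
                                 qualifying_rate_base = 0.05,
                                 seed = 20000 + s)
    st <- gene_status_familial(sv$variants, fams, genes)
    res <- module_burden_test(modules, st, unique(modules))
    any(res$significant)
  }, TRUE)
  expect_lte(mean(any_hit), 0.05 + 3 * sqrt(0.05 * 0.95 / 100))
})

test_that("replication follows the cases-yes controls-no rule", {
  mk <- function(p_adj) data.frame(module = c("brown", "yellow", "salmon"),
                                   p_adj = p_adj,
                                   significant = p_adj < 0.05)
  cases <- mk(c(0.01, 0.01, 0.20))
  controls <- mk(c(0.80, 0.01, 0.80))
  rep <- replication_decision(cases, controls)
  ## brown: significant in cases only -> replicated
  expect_true(rep$replicated[rep$module == "brown"])
  ## yellow: significant in both cohorts -> not replicated
  expect_false(rep$replicated[rep$module == "yellow"])
  ## salmon: no case signal -> not replicated
  expect_false(rep$replicated[rep$module == "salmon"])
  expect_error(replication_decision(cases, controls[1:2, ]), "modules")
})

test_that("Bonferroni adjustment is the capped closed form", {
  modules <- stats::setNames(rep(paste0("m", 1:8), each = 40),
                             paste0("g", 1:320))
  status <- data.frame(gene = names(modules),
                       status = rep("non_mutated", 320))
  status$status[c(1:12, seq(50, 320, by = 25))] <- "mutated"
  res <- module_burden_test(modules, status, paste0("m", 1:8))
  expect_equal(res$p_adj, pmin(1, res$p * 8))
})
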