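## Module-level mutation-burden testing: intolerance-score exclusion,
## one-tailed Fisher exact test with Bonferroni correction, replication.

#' Exclude modules whose mutated genes are unusually mutation-tolerant
#'
#' Per non-grey module, a one-sided Welch t-test of the hypothesis that the
#' mean intolerance score of its mutated genes exceeds that of its
#' non-mutated genes. Higher scores mean greater tolerance to functional
#' variation, so a module whose mutated genes score significantly higher is
#' excluded as a likely false positive. Undetected genes and genes without a
#' score are ignored; modules with fewer than two scored genes in either
#' group are retained with a warning. If both groups have zero variance the
#' t-statistic is undefined and a direct mean comparison decides.
#'
#' @param modules Named character vector gene -> module label.
#' @param status Status table from [gene_status_familial()].
#' @param scores Named numeric vector of per-gene scores (e.g. RVIS).
#' @param alpha Exclusion level (default 0.05).
#' @return Data frame: `module`, `n_mutated`, `n_non_mutated`,
#'   `mean_mutated`, `mean_non_mutated`, `t`, `p`, `excluded`.
#' @export
rvis_module_filter <- function(modules, status, scores, alpha = 0.05) {
  if (!length(scores)) stop_format("empty score table")
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1, open_lower = TRUE)
  labels <- setdiff(unique(modules), "grey")
  st <- stats::setNames(status$status, status$gene)
  rows <- lapply(labels, function(lab) {
    genes <- names(modules)[modules == lab]
    g_mut <- genes[st[genes] %in% "mutated"]
    g_non <- genes[st[genes] %in% "non_mutated"]
    s_mut <- scores[intersect(g_mut, names(scores))]
    s_non <- scores[intersect(g_non, names(scores))]
    out <- data.frame(module = lab, n_mutated = length(s_mut),
                      n_non_mutated = length(s_non),
                      mean_mutated = mean(s_mut), mean_non_mutated = mean(s_non),
                      t = NA_real_, p = NA_real_, excluded = FALSE)
    if (length(s_mut) < 2L || length(s_non) < 2L) {
      warning(sprintf(
        "module '%s': fewer than 2 scored genes in a group; retained", lab))
      return(out)
    }
    if (stats::sd(s_mut) == 0 && stats::sd(s_non) == 0) {
      out$excluded <- mean(s_mut) > mean(s_non)
      out$p <- if (out$excluded) 0 else 1
      return(out)
    }
    tt <- stats::t.test(s_mut, s_non, alternative = "greater",
                        var.equal = FALSE)
    out$t <- unname(tt$statistic)
    out$p <- tt$p.value
    out$excluded <- tt$p.value < alpha
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-tailed Fisher exact test for mutated-gene enrichment
#'
#' For a 2x2 table `[[a, b], [c, d]]` (mutated/non-mutated genes inside the
#' module vs outside), the p-value is the upper-tail hypergeometric
#' probability `P(X >= a)` with margins fixed — the enrichment direction is
#' more mutated genes in the module. The odds ratio is the cross-product
#' `a*d / (b*c)`, with the Haldane–Anscombe +0.5 continuity correction
#' applied to all cells when any cell is zero (the exact p-value is never
#' corrected).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List with `odds_ratio` and `p`.
#' @export
fisher_one_tailed <- function(table) {
  if (!is.matrix(table) || any(dim(table) != 2L))
    stop_format("expected a 2x2 count matrix")
  if (any(table < 0) || any(table != round(table)))
    stop_format("counts must be non-negative integers")
  a <- table[1L, 1L]; b <- table[1L, 2L]
  c_ <- table[2L, 1L]; d <- table[2L, 2L]
  N <- a + b + c_ + d
  K <- a + c_          # mutated genes overall
  n <- a + b           # module size
  if (N == 0) stop_format("all counts are zero")
  if (K == 0) {
    p <- 1
  } else {
    xs <- a:min(K, n)
    cn <- choose(N, n)
    ## binomial-coefficient products are exact in double precision for
    ## small tables (dhyper works in log space and loses the last ulp)
    p <- if (is.finite(cn) && cn < 1e300)
      sum(choose(K, xs) * choose(N - K, n - xs)) / cn
    else
      sum(stats::dhyper(xs, K, N - K, n))
    p <- min(1, p)
  }
  tt <- if (any(table == 0)) table + 0.5 else table
  or <- (tt[1L, 1L] * tt[2L, 2L]) / (tt[1L, 2L] * tt[2L, 1L])
  list(odds_ratio = or, p = p)
}

#' Per-module mutation-burden test with Bonferroni correction
#'
#' For each tested module, builds the 2x2 table of mutated vs non-mutated
#' genes inside the module against all other network genes (undetected genes
#' are excluded everywhere; unassigned grey genes count in the background),
#' applies [fisher_one_tailed()], Bonferroni-adjusts over the number of
#' tested modules, and reports the Haldane–Anscombe odds ratio with its
#' log-normal 95% confidence interval.
#'
#' @param modules Named character vector gene -> module label.
#' @param status Status table from [gene_status_familial()] or
#'   [gene_status_cohort()].
#' @param tested_modules Module labels to test (normally the modules
#'   retained by [rvis_module_filter()]).
#' @return Data frame: `module`, `a`, `b`, `c`, `d`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p`, `p_adj`, `significant`.
#' @export
module_burden_test <- function(modules, status, tested_modules) {
  st <- stats::setNames(status$status, status$gene)
  included <- names(modules)[st[names(modules)] %in% c("mutated", "non_mutated")]
  mutated <- st[included] == "mutated"
  rows <- lapply(tested_modules, function(lab) {
    in_mod <- modules[included] == lab
    if (!sum(in_mod)) {
      warning(sprintf("module '%s' has no genes with detectable variation; skipped",
                      lab))
      return(NULL)
    }
    a <- sum(in_mod & mutated); b <- sum(in_mod & !mutated)
    c_ <- sum(!in_mod & mutated); d <- sum(!in_mod & !mutated)
    ft <- fisher_one_tailed(matrix(c(a, c_, b, d), 2L))
    cells <- c(a, b, c_, d)
    if (any(cells == 0)) cells <- cells + 0.5
    se <- sqrt(sum(1 / cells))
    data.frame(module = lab, a = a, b = b, c = c_, d = d,
               odds_ratio = ft$odds_ratio,
               ci_low = exp(log(ft$odds_ratio) - 1.96 * se),
               ci_high = exp(log(ft$odds_ratio) + 1.96 * se),
               p = ft$p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$p_adj <- pmin(1, out$p * nrow(out))
  out$significant <- out$p_adj < 0.05
  rownames(out) <- NULL
  out
}

#' Replication decision across independent case and control cohorts
#'
#' A candidate module replicates when its mutation burden is significant
#' (Bonferroni-adjusted p < 0.05) in the case cohort but not in the control
#' cohort, each cohort tested on its own status table.
#'
#' @param case_results,control_results Data frames from
#'   [module_burden_test()], covering the same modules.
#' @return Data frame: `module`, `case_p_adj`, `control_p_adj`, `replicated`.
#' @export
replication_decision <- function(case_results, control_results) {
  if (!setequal(case_results$module, control_results$module))
    stop_format("case and control results cover different modules")
  i <- match(case_results$module, control_results$module)
  data.frame(module = case_results$module,
             case_p_adj = case_results$p_adj,
             control_p_adj = control_results$p_adj[i],
             replicated = case_results$significant &
               !control_results$significant[i])
}
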