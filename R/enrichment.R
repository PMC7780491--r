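## Functional annotation: expression-weighted cell-type enrichment via
## specificity bootstrap, and binomial pathway over-representation with
## Benjamini-Hochberg adjustment.

#' Cell-type specificity from mean expression
#'
#' Specificity of gene g for cell type c is its mean expression in c divided
#' by the sum of its mean expression over all types, so each row sums to 1.
#' Genes with zero total expression carry no information and are dropped
#' with a warning.
#'
#' @param cell_mean_expression Non-negative genes x cell-types matrix.
#' @return Row-normalized specificity matrix.
#' @export
specificity_from_means <- function(cell_mean_expression) {
  m <- cell_mean_expression
  if (!is.matrix(m) || !is.numeric(m)) stop_format("expected a numeric matrix")
  if (any(m < 0)) stop_format("mean expression must be non-negative")
  totals <- rowSums(m)
  zero <- totals == 0
  if (any(zero)) {
    warning(sprintf("%d gene(s) with zero total expression dropped", sum(zero)))
    m <- m[!zero, , drop = FALSE]
    totals <- totals[!zero]
  }
  m / totals
}

#' Expression-weighted cell-type enrichment of a gene set
#'
#' Per cell type, the observed statistic is the summed specificity of the
#' target genes; the null distribution is built from `n_bootstrap` random
#' gene sets of the same size drawn uniformly without replacement from all
#' genes of the specificity matrix. The one-sided empirical p-value uses
#' add-one smoothing; p-values are Benjamini-Hochberg adjusted across cell
#' types.
#'
#' @param spec Specificity matrix from [specificity_from_means()].
#' @param target_genes Gene identifiers of the set under test (genes absent
#'   from `spec` are dropped with a warning; at least 2 must remain).
#' @param n_bootstrap Number of bootstrap gene sets (default 10000).
#' @param seed Integer seed.
#' @return Data frame per cell type: `cell_type`, `observed`, `null_mean`,
#'   `null_sd`, `fold_change`, `p`, `p_adj`, `significant`.
#' @export
ewce_test <- function(spec, target_genes, n_bootstrap = 10000, seed) {
  check_scalar_number(n_bootstrap, "n_bootstrap", lower = 1, integerish = TRUE)
  check_scalar_number(seed, "seed", integerish = TRUE)
  target <- intersect(target_genes, rownames(spec))
  dropped <- setdiff(target_genes, target)
  if (length(dropped))
    warning(sprintf("%d target gene(s) absent from the specificity matrix dropped",
                    length(dropped)))
  if (length(target) < 2L)
    stop_format("fewer than 2 target genes present in the specificity matrix")
  observed <- colSums(spec[target, , drop = FALSE])
  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(b) {
      colSums(spec[sample.int(nrow(spec), length(target)), , drop = FALSE])
    }, numeric(ncol(spec)))
  })
  ## bootstrap draws in rows, cell types in columns
  boot <- if (is.null(dim(boot))) matrix(boot, ncol = 1L) else t(boot)
  null_mean <- colMeans(boot)
  p <- vapply(seq_len(ncol(spec)), function(j)
    (1 + sum(boot[, j] >= observed[j])) / (1 + n_bootstrap), 0)
  out <- data.frame(cell_type = colnames(spec), observed = observed,
                    null_mean = null_mean,
                    null_sd = apply(boot, 2L, stats::sd),
                    fold_change = observed / null_mean,
                    p = p, p_adj = bh_adjust(p))
  out$significant <- out$p_adj < 0.05
  rownames(out) <- NULL
  out
}

#' Binomial over-representation of pathways in a gene set
#'
#' For a pathway with `K` genes in the reference universe of size `N`, and a
#' query of `n` genes overlapping it in `k`, the p-value is the binomial
#' upper tail `P(X >= k)` with `X ~ Binomial(n, K / N)` (so an empty overlap
#' gives p = 1 exactly). P-values are Benjamini-Hochberg adjusted across
#' pathways; significance is adjusted p < 0.05.
#'
#' @param query Gene set under test (must lie within `reference`).
#' @param reference Gene universe (the gene list used for network
#'   construction).
#' @param pathways Named list of pathway gene sets; each is intersected
#'   with the reference.
#' @return Data frame per pathway: `pathway`, `n_pathway`, `n_overlap`,
#'   `expected`, `p`, `p_adj`, `significant`.
#' @export
pathway_overrepresentation <- function(query, reference, pathways) {
  if (!length(reference)) stop_format("empty reference gene universe")
  if (!all(query %in% reference))
    stop_format("query genes must be a subset of the reference universe")
  N <- length(reference)
  n <- length(query)
  rows <- lapply(names(pathways), function(pw) {
    set <- intersect(pathways[[pw]], reference)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- if (k == 0) 1 else
      stats::pbinom(k - 1, n, K / N, lower.tail = FALSE)
    data.frame(pathway = pw, n_pathway = K, n_overlap = k,
               expected = n * K / N, p = p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < 0.05
  rownames(out) <- NULL
  out
}
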