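## Weighted co-expression network construction: connectivity-based gene
## selection, soft-threshold fitting against scale-free topology, topological
## overlap, and the leave-out consensus TOM.

## Pearson correlation across rows of `expr`, with zero-variance genes
## contributing 0 correlation (warning) instead of NA.
safe_gene_cor <- function(expr) {
  sds <- apply(expr, 1L, stats::sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero))
    warning(sprintf("%d zero-variance gene(s); their correlations set to 0",
                    sum(zero)))
  cc <- suppressWarnings(stats::cor(t(expr)))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  cc
}

#' Select the most highly connected genes
#'
#' Gene connectivity is the sum of absolute Pearson correlations with every
#' other gene; the `k` genes with the largest connectivity are retained, in
#' their original input order. Ties are broken by input order.
#'
#' @param expr Numeric genes x samples matrix.
#' @param k Number of genes to keep (<= number of genes).
#' @return The filtered expression matrix.
#' @export
select_top_connected <- function(expr, k) {
  validate_expression_matrix(expr, min_samples = 3L)
  check_scalar_number(k, "k", lower = 1, upper = nrow(expr), integerish = TRUE)
  if (k == nrow(expr)) return(expr)
  cc <- safe_gene_cor(expr)
  connectivity <- rowSums(abs(cc)) - 1   # exclude self-correlation
  keep <- sort(order(-connectivity, seq_len(nrow(expr)))[seq_len(k)])
  expr[keep, , drop = FALSE]
}

#' Soft-thresholded adjacency matrix
#'
#' Unsigned weighted network: `a_ij = |cor(x_i, x_j)|^beta`, unit diagonal.
#'
#' @param expr Numeric genes x samples matrix.
#' @param beta Soft-threshold power (>= 1).
#' @return Symmetric adjacency matrix with entries in `[0, 1]`.
#' @export
adjacency_matrix <- function(expr, beta) {
  validate_expression_matrix(expr, min_samples = 3L)
  check_scalar_number(beta, "beta", lower = 1)
  a <- abs(safe_gene_cor(expr))^beta
  diag(a) <- 1
  a
}

#' Fit the scale-free topology criterion over candidate powers
#'
#' For each candidate power the connectivities `k_i = sum_j a_ij (j != i)`
#' are binned into 10 equal-count bins; the signed fit statistic is the R^2
#' of `log10(frequency)` on `log10(mean k)` with the sign of the slope
#' flipped, so a decreasing (scale-free-like) relationship scores positive.
#' The chosen power is the smallest candidate whose signed R^2 reaches
#' `r2_target`; if none does, the best-fitting power is returned with a
#' warning.
#'
#' @param expr Numeric genes x samples matrix.
#' @param candidate_powers Integer powers to scan (default 1..20).
#' @param r2_target Signed R^2 required (default 0.8).
#' @param n_bins Number of connectivity bins (default 10).
#' @return An object of class `soft_threshold_fit`: a list with `fit_table`
#'   (power, signed_r2, mean_connectivity), `power` (the chosen one) and
#'   `r2_target`.
#' @export
pick_soft_threshold <- function(expr, candidate_powers = 1:20,
                                r2_target = 0.8, n_bins = 10) {
  validate_expression_matrix(expr, min_samples = 3L)
  if (!length(candidate_powers)) stop_format("no candidate powers supplied")
  check_scalar_number(r2_target, "r2_target", lower = 0, upper = 1)
  cc_abs <- abs(safe_gene_cor(expr))
  fits <- lapply(candidate_powers, function(beta) {
    a <- cc_abs^beta
    k <- rowSums(a) - 1
    if (max(k) - min(k) < .Machine$double.eps^0.5)
      stop_format("degenerate fit: all connectivities identical at power %g", beta)
    c(signed_r2 = scale_free_fit(k, n_bins), mean_connectivity = mean(k))
  })
  fit_table <- data.frame(power = candidate_powers, do.call(rbind, fits))
  hit <- which(fit_table$signed_r2 >= r2_target)
  if (length(hit)) {
    power <- fit_table$power[hit[1L]]
  } else {
    power <- fit_table$power[which.max(fit_table$signed_r2)]
    warning(sprintf(
      "no candidate power reaches signed R^2 >= %.2f; using power %d (R^2 = %.3f)",
      r2_target, power, max(fit_table$signed_r2)))
  }
  structure(list(fit_table = fit_table, power = power, r2_target = r2_target),
            class = "soft_threshold_fit")
}

## Signed scale-free fit statistic from a connectivity vector: R^2 of
## log10 p(k) on log10 mean(k) over equal-width connectivity bins, with the
## sign of the slope flipped so a decreasing (power-law-like) relationship
## scores positive.
scale_free_fit <- function(k, n_bins = 10) {
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = nlevels(bin)) / length(k)
  mean_k <- as.numeric(tapply(k, bin, mean))
  keep <- freq > 0 & !is.na(mean_k) & mean_k > 0
  if (sum(keep) < 3L) return(NA_real_)
  fit <- stats::lm(log10(freq[keep]) ~ log10(mean_k[keep]))
  r2 <- summary(fit)$r.squared
  unname(-sign(stats::coef(fit)[2L]) * r2)
}

#' @export
print.soft_threshold_fit <- function(x, ...) {
  cat(sprintf("<soft_threshold_fit> chosen power %d (signed R^2 target %.2f)\n",
              x$power, x$r2_target))
  print(x$fit_table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Topological overlap dissimilarity
#'
#' For an adjacency matrix `A`, the topological overlap of genes i and j is
#' `(l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `l_ij = sum_u a_iu a_uj` over `u != i, j` and `k_i` is the connectivity of
#' i. The returned dissimilarity is one minus the overlap, with a zero
#' diagonal; fully disconnected pairs get dissimilarity 1.
#'
#' @param adjacency Symmetric matrix with entries in `[0, 1]` and unit
#'   diagonal.
#' @return Symmetric dissimilarity matrix in `[0, 1]`.
#' @export
tom_dissimilarity <- function(adjacency) {
  validate_adjacency(adjacency)
  a <- adjacency
  k <- rowSums(a) - 1
  aa <- a %*% a
  l <- aa - 2 * a              # removes u = i and u = j terms (diag(a) = 1)
  kmin <- outer(k, k, pmin)
  denom <- kmin + 1 - a
  w <- (l + a) / denom
  w[denom <= 0] <- 0           # isolated pair: no overlap
  d <- 1 - w
  diag(d) <- 0
  d[d < 0] <- 0
  d[d > 1] <- 1
  d
}

validate_adjacency <- function(a) {
  if (!is.matrix(a) || nrow(a) != ncol(a))
    stop_format("adjacency must be a square matrix")
  if (max(abs(a - t(a))) > 1e-10) stop_format("adjacency must be symmetric")
  if (min(a) < 0 || max(a) > 1) stop_format("adjacency entries must lie in [0, 1]")
  if (max(abs(diag(a) - 1)) > 1e-10) stop_format("adjacency diagonal must be 1")
  invisible(a)
}

#' Consensus topological overlap network over sample resamples
#'
#' Recomputes the TOM dissimilarity `n_resamples` times, each time on a
#' uniformly drawn subset of `ceiling((1 - leave_out_fraction) * n_samples)`
#' samples (without replacement), at a fixed soft-threshold power, and
#' averages the dissimilarities element-wise. The full-data adjacency is
#' stored alongside. With `leave_out_fraction = 0` the consensus equals the
#' full-data TOM exactly.
#'
#' @param expr Numeric genes x samples matrix.
#' @param beta Soft-threshold power, fitted once on all samples.
#' @param n_resamples Number of leave-out networks (default 100).
#' @param leave_out_fraction Fraction of samples left out each time
#'   (default 0.1); must leave at least 3 samples.
#' @param seed Integer seed for the resampling.
#' @return An object of class `gene_network`: gene ids, `beta`, full-data
#'   `adjacency`, `consensus_dissimilarity`, and the resampling settings.
#' @export
consensus_tom <- function(expr, beta, n_resamples = 100,
                          leave_out_fraction = 0.1, seed) {
  validate_expression_matrix(expr, min_samples = 3L)
  check_scalar_number(n_resamples, "n_resamples", lower = 1, integerish = TRUE)
  check_scalar_number(leave_out_fraction, "leave_out_fraction",
                      lower = 0, upper = 1, open_upper = TRUE)
  check_scalar_number(seed, "seed", integerish = TRUE)
  n_samples <- ncol(expr)
  n_keep <- ceiling((1 - leave_out_fraction) * n_samples)
  if (n_keep < 3L)
    stop_format("leave_out_fraction %.2f leaves %d samples; at least 3 required",
                leave_out_fraction, n_keep)
  adjacency <- adjacency_matrix(expr, beta)
  if (leave_out_fraction == 0) {
    consensus <- tom_dissimilarity(adjacency)
  } else {
    n_genes <- nrow(expr)
    consensus <- matrix(0, n_genes, n_genes)
    withr::with_seed(seed, {
      for (b in seq_len(n_resamples)) {
        keep <- sample.int(n_samples, n_keep)
        consensus <- consensus +
          tom_dissimilarity(adjacency_matrix(expr[, keep, drop = FALSE], beta))
      }
    })
    consensus <- consensus / n_resamples
    dimnames(consensus) <- dimnames(adjacency)
  }
  structure(list(gene_ids = rownames(expr), beta = beta,
                 adjacency = adjacency,
                 consensus_dissimilarity = consensus,
                 n_resamples = n_resamples,
                 leave_out_fraction = leave_out_fraction),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf(
    "<gene_network> %d genes, beta = %g, %d resamples leaving out %.0f%% of samples\n",
    length(x$gene_ids), x$beta, x$n_resamples, 100 * x$leave_out_fraction))
  invisible(x)
}
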