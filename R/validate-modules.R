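#' Permutation validation of detected modules
#'
#' For each module, the observed statistic is the mean topological overlap
#' (one minus the consensus dissimilarity) over unordered gene pairs within
#' the module. The null distribution is built by drawing, `n_permutations`
#' times, the same number of genes uniformly without replacement from all
#' network genes and recomputing the statistic. The one-sided empirical
#' p-value uses add-one smoothing, `p = (1 + #{perm >= obs}) / (1 + B)`, so
#' it is never exactly zero. The grey (unassigned) set is tested like any
#' other module and reported alongside.
#'
#' @param network A `gene_network`.
#' @param modules Named character vector gene -> module label.
#' @param n_permutations Number of random gene sets per module (default 1000).
#' @param seed Integer seed.
#' @return Data frame with one row per module: `module`, `size`, `observed`,
#'   `perm_mean`, `perm_sd`, `p`.
#' @export
validate_modules <- function(network, modules, n_permutations = 1000, seed) {
  stopifnot(inherits(network, "gene_network"))
  check_scalar_number(n_permutations, "n_permutations", lower = 100,
                      integerish = TRUE)
  check_scalar_number(seed, "seed", integerish = TRUE)
  overlap <- 1 - network$consensus_dissimilarity
  genes <- network$gene_ids
  if (!all(names(modules) %in% genes))
    stop_format("module assignment contains genes absent from the network")
  labels <- unique(modules)
  mean_pair_overlap <- function(idx) {
    s <- length(idx)
    (sum(overlap[idx, idx]) - s) / (s * (s - 1))   # off-diagonal mean; diag = 1
  }
  rows <- lapply(labels, function(lab) {
    idx <- match(names(modules)[modules == lab], genes)
    s <- length(idx)
    if (s < 2L) {
      warning(sprintf("module '%s' has fewer than 2 genes; skipped", lab))
      return(NULL)
    }
    obs <- mean_pair_overlap(idx)
    perm <- withr::with_seed(stage_seed(seed, paste0("validate_", lab)), {
      vapply(seq_len(n_permutations), function(b)
        mean_pair_overlap(sample.int(length(genes), s)), 0)
    })
    data.frame(module = lab, size = s, observed = obs,
               perm_mean = mean(perm), perm_sd = stats::sd(perm),
               p = (1 + sum(perm >= obs)) / (1 + n_permutations))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
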