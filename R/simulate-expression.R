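#' Simulate an expression matrix with planted co-expressed modules
#'
#' Each module is driven by one latent standard-normal sample vector; a
#' member gene's profile is `sqrt(r) * latent + sqrt(1 - r) * noise`, so the
#' expected pairwise correlation between any two genes of the same module is
#' exactly `r`. Background genes are independent standard-normal noise.
#'
#' @param n_background Number of unstructured background genes.
#' @param module_sizes Integer vector of module sizes (each >= 2).
#' @param n_samples Number of samples (>= 10).
#' @param within_module_cor Target expected within-module correlation,
#'   strictly between 0 and 1.
#' @param seed Integer seed; the output is a pure function of the arguments.
#' @return A list with `expr` (numeric matrix, genes x samples; module genes
#'   first) and `truth` (a `simulation_truth`: `true_module_labels` named by
#'   gene, `generator_config`).
#' @export
simulate_modular_expression <- function(n_background, module_sizes, n_samples,
                                        within_module_cor, seed) {
  check_scalar_number(n_background, "n_background", lower = 0, integerish = TRUE)
  if (length(module_sizes) && any(module_sizes < 2))
    stop_format("every module size must be >= 2")
  check_scalar_number(n_samples, "n_samples", lower = 10, integerish = TRUE)
  check_scalar_number(within_module_cor, "within_module_cor",
                      lower = 0, upper = 1, open_lower = TRUE, open_upper = TRUE)
  check_scalar_number(seed, "seed", integerish = TRUE)

  r <- within_module_cor
  n_mod_genes <- sum(module_sizes)
  n_genes <- n_mod_genes + n_background
  withr::with_seed(seed, {
    latent <- matrix(stats::rnorm(length(module_sizes) * n_samples),
                     nrow = length(module_sizes))
    noise <- matrix(stats::rnorm(n_genes * n_samples), nrow = n_genes)
  })
  expr <- sqrt(1 - r) * noise
  labels <- rep("background", n_genes)
  row <- 0L
  for (m in seq_along(module_sizes)) {
    idx <- row + seq_len(module_sizes[m])
    expr[idx, ] <- expr[idx, ] + sqrt(r) * matrix(latent[m, ], module_sizes[m],
                                                  n_samples, byrow = TRUE)
    labels[idx] <- paste0("module_", m)
    row <- row + module_sizes[m]
  }
  ## background rows keep unit variance
  if (n_background > 0) {
    bg <- (n_mod_genes + 1L):n_genes
    expr[bg, ] <- noise[bg, ]
  }
  genes <- sprintf("G%04d", seq_len(n_genes))
  dimnames(expr) <- list(genes, sprintf("S%03d", seq_len(n_samples)))
  truth <- new_simulation_truth(
    true_module_labels = stats::setNames(labels, genes),
    generator_config = list(
      generator = "simulate_modular_expression", n_background = n_background,
      module_sizes = module_sizes, n_samples = n_samples,
      within_module_cor = r, seed = seed))
  list(expr = expr, truth = truth)
}

new_simulation_truth <- function(...) {
  structure(list(...), class = "simulation_truth")
}
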