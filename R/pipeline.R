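## End-to-end orchestration: discovery (network -> modules -> segregation ->
## burden) and replication in independent case/control cohorts.

#' Assemble a pipeline run configuration
#'
#' Inputs may be given as file paths (read with the package's readers) or as
#' already-loaded objects. Numeric parameters default to the pipeline's
#' standard settings: top 5000 genes by connectivity, scale-free fit target
#' R^2 = 0.8 over powers 1..20, 100 leave-10%-out resamples for the
#' consensus TOM, minimum module size 30, MAF < 5%, penetrance bound 0.9,
#' 1000 validation permutations and 10000 enrichment bootstraps.
#'
#' @param expression Expression matrix or TSV path (genes x samples).
#' @param vcf Familial cohort `variant_table` or VCF path.
#' @param ped Pedigree list or PED path.
#' @param scores Optional named score vector (e.g. RVIS) or TSV path.
#' @param case_vcf,control_vcf Optional replication cohorts
#'   (`variant_table` or VCF path).
#' @param k,powers,r2_target,n_resamples,leave_out,min_module_size,
#'   maf_threshold,penetrance_min,alpha,n_permutations,n_bootstrap Numeric
#'   parameters; see above.
#' @param seed Integer run seed; per-stage seeds are derived from it with
#'   [stage_seed()].
#' @param output_dir Optional directory for tab-separated stage outputs and
#'   the JSON run summary.
#' @return A `run_config` list.
#' @export
run_config <- function(expression, vcf, ped, scores = NULL,
                       case_vcf = NULL, control_vcf = NULL,
                       k = 5000, powers = 1:20, r2_target = 0.8,
                       n_resamples = 100, leave_out = 0.1,
                       min_module_size = 30, maf_threshold = 0.05,
                       penetrance_min = 0.9, alpha = 0.05,
                       n_permutations = 1000, n_bootstrap = 10000,
                       seed, output_dir = NULL) {
  check_scalar_number(seed, "seed", integerish = TRUE)
  structure(list(
    expression = expression, vcf = vcf, ped = ped, scores = scores,
    case_vcf = case_vcf, control_vcf = control_vcf,
    k = k, powers = powers, r2_target = r2_target,
    n_resamples = n_resamples, leave_out = leave_out,
    min_module_size = min_module_size, maf_threshold = maf_threshold,
    penetrance_min = penetrance_min, alpha = alpha,
    n_permutations = n_permutations, n_bootstrap = n_bootstrap,
    seed = seed, output_dir = output_dir), class = "run_config")
}

resolve_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

pipeline_log <- function(verbose, ...) {
  if (verbose) message(sprintf(...))
}

#' Run the discovery arm of the pipeline
#'
#' Executes the full discovery chain: connectivity-based gene selection,
#' soft-threshold fitting, consensus TOM, module detection, permutation
#' validation, familial mutation-status calling, intolerance-score module
#' exclusion, and the per-module burden test. Reruns with an identical
#' configuration (including the seed) are reproducible.
#'
#' @param config A [run_config()].
#' @param verbose Log per-stage gene/module counts (default TRUE).
#' @return List with `network`, `fit`, `modules`, `validity`, `status`,
#'   `rvis`, `burden`, and `summary` (named counts echoed into the JSON run
#'   summary when `output_dir` is set).
#' @export
run_discovery <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  expr <- resolve_input(config$expression, read_expression_matrix)
  pipeline_log(verbose, "expression: %d genes x %d samples", nrow(expr), ncol(expr))
  expr <- select_top_connected(expr, min(config$k, nrow(expr)))
  fit <- pick_soft_threshold(expr, config$powers, config$r2_target)
  pipeline_log(verbose, "soft threshold: power %d (signed R^2 %.3f)",
               fit$power, fit$fit_table$signed_r2[match(fit$power, fit$fit_table$power)])
  network <- consensus_tom(expr, fit$power, config$n_resamples,
                           config$leave_out,
                           seed = stage_seed(config$seed, "consensus_tom"))
  modules <- detect_modules(network, config$min_module_size)
  n_mod <- length(setdiff(unique(modules), "grey"))
  pipeline_log(verbose, "modules: %d detected (+ %d grey genes)",
               n_mod, sum(modules == "grey"))
  validity <- validate_modules(network, modules, config$n_permutations,
                               seed = stage_seed(config$seed, "validate"))
  families <- resolve_input(config$ped, read_pedigrees)
  vt <- resolve_input(config$vcf, read_variant_table)
  status <- gene_status_familial(
    vt, families, genes = network$gene_ids,
    model = segregation_model(config$penetrance_min),
    maf_threshold = config$maf_threshold)
  pipeline_log(verbose, "genes: %d detectable, %d mutated, %d undetected",
               sum(status$status != "undetected"),
               sum(status$status == "mutated"),
               sum(status$status == "undetected"))
  candidates <- setdiff(unique(modules), "grey")
  rvis <- NULL
  if (!is.null(config$scores)) {
    scores <- resolve_input(config$scores, read_score_table)
    rvis <- rvis_module_filter(modules, status, scores, config$alpha)
    candidates <- rvis$module[!rvis$excluded]
    pipeline_log(verbose, "intolerance filter: %d of %d modules retained",
                 length(candidates), nrow(rvis))
  }
  burden <- module_burden_test(modules, status, candidates)
  result <- list(network = network, fit = fit, modules = modules,
                 validity = validity, status = status, rvis = rvis,
                 burden = burden,
                 summary = list(
                   n_genes = length(network$gene_ids),
                   power = fit$power,
                   n_modules = n_mod,
                   n_grey = sum(modules == "grey"),
                   n_detectable = sum(status$status != "undetected"),
                   n_mutated = sum(status$status == "mutated"),
                   n_modules_tested = if (is.null(burden)) 0L else nrow(burden),
                   significant_modules = if (is.null(burden)) character() else
                     burden$module[burden$significant]))
  if (!is.null(config$output_dir)) write_discovery(result, config)
  result
}

write_discovery <- function(result, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$output_dir, name)
  write_module_assignment(result$modules, out("modules.tsv"))
  utils::write.table(result$fit$fit_table, out("soft_threshold.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$validity, out("module_validity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$status[, c("gene", "status", "n_families")],
                     out("gene_status.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$rvis))
    utils::write.table(result$rvis, out("rvis_filter.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$burden))
    utils::write.table(result$burden, out("module_burden.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- config[!vapply(config, function(x)
    is.matrix(x) || is.list(x) && !is.null(x) && !is.character(x), TRUE)]
  jsonlite::write_json(
    list(config = cfg, summary = result$summary),
    out("run_summary.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}

#' Run the replication arm of the pipeline
#'
#' Calls per-gene mutation status in the sporadic case cohort and the
#' population control cohort separately (no pooling), runs the burden test
#' restricted to the candidate modules in each cohort, and applies the
#' replication rule: significant burden in cases and not in controls.
#'
#' @param config A [run_config()] with `case_vcf` and `control_vcf` set.
#' @param discovery Result of [run_discovery()].
#' @param candidate_modules Modules to replicate (default: the discovery
#'   arm's significant modules).
#' @param verbose Log cohort gene counts (default TRUE).
#' @return List with `case_burden`, `control_burden`, `replication`.
#' @export
run_replication <- function(config, discovery,
                            candidate_modules = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$case_vcf) || is.null(config$control_vcf))
    stop_format("replication requires both case_vcf and control_vcf")
  if (is.null(candidate_modules))
    candidate_modules <- discovery$summary$significant_modules
  if (!length(candidate_modules)) {
    pipeline_log(verbose, "no candidate modules to replicate")
    return(list(case_burden = NULL, control_burden = NULL, replication = NULL))
  }
  genes <- discovery$network$gene_ids
  modules <- discovery$modules
  cohort_burden <- function(input, label) {
    vt <- resolve_input(input, read_variant_table)
    status <- gene_status_cohort(vt, genes, config$maf_threshold)
    pipeline_log(verbose, "%s cohort: %d detectable, %d mutated genes", label,
                 sum(status$status != "undetected"),
                 sum(status$status == "mutated"))
    module_burden_test(modules, status, candidate_modules)
  }
  case_burden <- cohort_burden(config$case_vcf, "case")
  control_burden <- cohort_burden(config$control_vcf, "control")
  replication <- replication_decision(case_burden, control_burden)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(replication,
                       file.path(config$output_dir, "replication.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(case_burden = case_burden, control_burden = control_burden,
       replication = replication)
}
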