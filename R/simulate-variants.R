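## Synthetic cohort variant tables with known ground truth.

## Mix of functional classes used for planted qualifying variants; dominated
## by non-synonymous SNVs as in real coding variation.
.functional_class_probs <- c(
  frameshift_deletion = 0.015, frameshift_insertion = 0.015,
  nonframeshift_deletion = 0.02, nonframeshift_insertion = 0.02,
  nonsynonymous_SNV = 0.88, splice_site = 0.02, stopgain = 0.02,
  stoploss = 0.01)

#' Simulate a cohort variant table with a planted module enrichment
#'
#' Every gene receives one common non-functional variant (so the gene is
#' detectable downstream). Independently, each gene receives a rare
#' functional variant with probability `qualifying_rate_base` — or
#' `qualifying_rate_enriched` for genes of `enriched_module` — whose MAF is
#' drawn uniformly from `[1e-4, 0.04]`. In familial mode (`families`
#' supplied) the qualifying variant is placed on the carrier genotypes of one
#' family in which such a variant co-segregates with affection under the
#' default dominant model; in cohort mode (`families = NULL`,
#' `cohort_size` supplied) it is given to a few random carriers.
#'
#' @param gene_universe Character vector of gene identifiers.
#' @param modules Named character vector gene -> module label (may be `NULL`
#'   when no enrichment is requested).
#' @param enriched_module Module label to enrich, or `NULL`.
#' @param families List of [simulate_family()] results, or `NULL` for cohort
#'   mode.
#' @param qualifying_rate_base,qualifying_rate_enriched Per-gene probabilities
#'   in `[0, 1]` of receiving a rare functional segregating variant.
#' @param seed Integer seed.
#' @param cohort_size Number of individuals in cohort mode.
#' @param model Segregation model used to pick eligible target families.
#' @return A list with `variants` (a `variant_table`) and `truth` (a
#'   `simulation_truth` with `causal_genes`, `causal_variants` — a data frame
#'   of (gene, family) pairs — and `generator_config`).
#' @export
simulate_variant_table <- function(gene_universe, modules = NULL,
                                   enriched_module = NULL, families = NULL,
                                   qualifying_rate_base = 0.05,
                                   qualifying_rate_enriched = 0.3,
                                   seed, cohort_size = NULL,
                                   model = segregation_model()) {
  check_scalar_number(qualifying_rate_base, "qualifying_rate_base", 0, 1)
  check_scalar_number(qualifying_rate_enriched, "qualifying_rate_enriched", 0, 1)
  check_scalar_number(seed, "seed", integerish = TRUE)
  if (!is.null(enriched_module)) {
    if (is.null(modules) || !(enriched_module %in% modules))
      stop_format("enriched module '%s' not present in the module assignment",
                  enriched_module)
  }
  if (is.null(families)) {
    if (is.null(cohort_size))
      stop_format("either 'families' or 'cohort_size' must be supplied")
    individuals <- sprintf("IND%05d", seq_len(cohort_size))
    eligible <- character()
  } else {
    individuals <- unlist(lapply(families, function(f)
      f$pedigree$members$individual_id), use.names = FALSE)
    ## families in which a variant on the carrier set co-segregates with
    ## affection under the dominant rule
    ## a family with no affected members is simply ineligible, not an anomaly
    eligible <- names(families)[vapply(families, function(f) {
      vt1 <- carrier_variant_stub(f, individuals)
      suppressWarnings(
        segregates_in_family(vt1$variants[1L, ], vt1$genotypes[1L, ],
                             f$pedigree, model))
    }, TRUE)]
    if (!length(eligible) &&
        (qualifying_rate_base > 0 || qualifying_rate_enriched > 0))
      stop_format("no simulated family can carry a co-segregating variant under the model; increase penetrance or family count")
  }
  n_gene <- length(gene_universe)
  n_ind <- length(individuals)
  rate <- rep(qualifying_rate_base, n_gene)
  if (!is.null(enriched_module)) {
    in_enriched <- gene_universe %in% names(modules)[modules == enriched_module]
    rate[in_enriched] <- qualifying_rate_enriched
  }

  withr::with_seed(seed, {
    common_maf <- stats::runif(n_gene, 0.05, 0.5)
    common_gt <- matrix(stats::rbinom(n_gene * n_ind, 2L,
                                      rep(common_maf, times = n_ind)),
                        nrow = n_gene)
    qualifies <- stats::runif(n_gene) < rate
    q_idx <- which(qualifies)
    q_maf <- stats::runif(length(q_idx), 1e-4, 0.04)
    q_csq <- sample(names(.functional_class_probs), length(q_idx),
                    replace = TRUE, prob = .functional_class_probs)
    q_gt <- matrix(0L, length(q_idx), n_ind,
                   dimnames = list(NULL, individuals))
    q_family <- character(length(q_idx))
    if (length(q_idx)) {
      if (is.null(families)) {
        for (j in seq_along(q_idx)) {
          carriers <- sample.int(n_ind, sample(1:3, 1L))
          q_gt[j, carriers] <- 1L
          q_family[j] <- NA_character_
        }
      } else {
        q_family <- sample(eligible, length(q_idx), replace = TRUE)
        for (j in seq_along(q_idx)) {
          carr <- names(which(families[[q_family[j]]]$carriers))
          q_gt[j, match(carr, individuals)] <- 1L
        }
      }
    }
  })

  variants <- data.frame(
    chrom = "1",
    pos = c(seq_len(n_gene) * 1000L, q_idx * 1000L + 1L),
    ref = "A",
    alt = "T",
    consequence = c(rep("other", n_gene), q_csq),
    maf = c(common_maf, q_maf),
    gene = c(gene_universe, gene_universe[q_idx]),
    stringsAsFactors = FALSE)
  genotypes <- rbind(common_gt, q_gt)
  colnames(genotypes) <- individuals
  truth <- new_simulation_truth(
    causal_genes = gene_universe[q_idx],
    causal_variants = data.frame(gene = gene_universe[q_idx],
                                 family = q_family,
                                 stringsAsFactors = FALSE),
    generator_config = list(
      generator = "simulate_variant_table", n_genes = n_gene,
      enriched_module = enriched_module,
      qualifying_rate_base = qualifying_rate_base,
      qualifying_rate_enriched = qualifying_rate_enriched,
      n_individuals = n_ind, seed = seed))
  list(variants = new_variant_table(variants, genotypes), truth = truth)
}

## One-row variant table placing a heterozygous variant on a family's carriers.
carrier_variant_stub <- function(fam, individuals) {
  gt <- matrix(0L, 1L, length(individuals),
               dimnames = list(NULL, individuals))
  carr <- names(which(fam$carriers))
  gt[1L, match(carr, individuals)] <- 1L
  list(variants = data.frame(chrom = "1", pos = 1L, ref = "A", alt = "T",
                             consequence = "nonsynonymous_SNV", maf = 0.001,
                             gene = "STUB", stringsAsFactors = FALSE),
       genotypes = gt)
}

#' Simulate a cell-type mean-expression matrix with known markers
#'
#' Marker genes have 10-fold higher mean expression in their own cell type
#' than elsewhere; all remaining genes are (up to a little uniform noise)
#' evenly expressed across types, so their specificity is close to
#' `1 / n_types`.
#'
#' @param n_genes Total number of genes.
#' @param cell_types Character vector of cell-type labels.
#' @param n_marker_per_type Markers per type;
#'   `n_marker_per_type * length(cell_types)` must not exceed `n_genes`.
#' @param seed Integer seed.
#' @return A list with `means` (genes x types matrix), `markers` (named list
#'   of marker gene ids per type) and `truth`.
#' @export
simulate_specificity_data <- function(n_genes, cell_types, n_marker_per_type,
                                      seed) {
  check_scalar_number(n_genes, "n_genes", lower = 1, integerish = TRUE)
  check_scalar_number(n_marker_per_type, "n_marker_per_type", lower = 1,
                      integerish = TRUE)
  check_scalar_number(seed, "seed", integerish = TRUE)
  n_types <- length(cell_types)
  if (n_marker_per_type * n_types > n_genes)
    stop_format("markers (%d x %d) exceed the gene count %d",
                n_marker_per_type, n_types, n_genes)
  genes <- sprintf("G%04d", seq_len(n_genes))
  withr::with_seed(seed, {
    means <- matrix(stats::runif(n_genes * n_types, 0.95, 1.05),
                    nrow = n_genes, dimnames = list(genes, cell_types))
  })
  markers <- vector("list", n_types)
  names(markers) <- cell_types
  row <- 0L
  for (t in seq_len(n_types)) {
    idx <- row + seq_len(n_marker_per_type)
    means[idx, t] <- means[idx, t] * 10
    markers[[t]] <- genes[idx]
    row <- row + n_marker_per_type
  }
  truth <- new_simulation_truth(
    markers = markers,
    generator_config = list(generator = "simulate_specificity_data",
                            n_genes = n_genes, cell_types = cell_types,
                            n_marker_per_type = n_marker_per_type, seed = seed))
  list(means = means, markers = markers, truth = truth)
}
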