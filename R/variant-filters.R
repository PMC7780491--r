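## Rare functional variant filters and pedigree segregation under a dominant
## model with a penetrance bound; per-gene mutated / non-mutated /
## undetected calls.

#' Dominant segregation model with penetrance bounds
#'
#' @param penetrance_min,penetrance_max Penetrance bounds; the lower bound is
#'   the operative one: in a family, the fraction of variant carriers that
#'   are affected must reach `penetrance_min`.
#' @return An object of class `segregation_model`.
#' @export
segregation_model <- function(penetrance_min = 0.9, penetrance_max = 1) {
  check_scalar_number(penetrance_min, "penetrance_min", lower = 0, upper = 1,
                      open_lower = TRUE)
  check_scalar_number(penetrance_max, "penetrance_max",
                      lower = penetrance_min, upper = 1)
  structure(list(penetrance_min = penetrance_min,
                 penetrance_max = penetrance_max,
                 inheritance = "dominant"),
            class = "segregation_model")
}

#' Is a variant in a functional consequence class?
#'
#' True for the eight coding-impact classes in [FUNCTIONAL_CLASSES];
#' anything else — including records whose annotation could not be parsed
#' and fell back to `"other"` — is not functional.
#'
#' @param consequence Character vector of consequence classes (or a
#'   one-row slice of `variant_table$variants`).
#' @return Logical vector.
#' @export
is_functional <- function(consequence) {
  if (is.data.frame(consequence)) consequence <- consequence$consequence
  consequence %in% FUNCTIONAL_CLASSES
}

#' Does a variant pass the population-rarity filter?
#'
#' True when the population allele frequency is strictly below `threshold`,
#' or is missing: absence from the reference database is taken as evidence
#' of extreme rarity, never coerced to 0 silently.
#'
#' @param maf Numeric vector of population allele frequencies (`NA` =
#'   missing), or a one-row slice of `variant_table$variants`.
#' @param threshold Rarity cut-off (default 0.05, i.e. MAF < 5%).
#' @return Logical vector.
#' @export
passes_maf <- function(maf, threshold = 0.05) {
  if (is.data.frame(maf)) maf <- maf$maf
  check_scalar_number(threshold, "threshold", lower = 0, upper = 1)
  is.na(maf) | maf < threshold
}

#' Maximum credible population allele frequency for a causal variant
#'
#' The standard disease-genetics calculation: for a monoallelic
#' (dominant-acting) architecture the maximum credible allele frequency is
#' `prevalence * genetic_heterogeneity * allelic_heterogeneity /
#' (2 * penetrance)`; for a biallelic (recessive) architecture it is
#' `sqrt(prevalence * genetic_heterogeneity / penetrance) *
#' allelic_heterogeneity`.
#'
#' @param prevalence Disease prevalence in (0, 1].
#' @param inheritance `"monoallelic"` or `"biallelic"`.
#' @param genetic_heterogeneity Fraction of cases attributable to the gene.
#' @param allelic_heterogeneity Fraction of the gene's attributable cases
#'   due to the single allele.
#' @param penetrance Penetrance in (0, 1].
#' @return The allele-frequency cut-off.
#' @export
max_credible_af <- function(prevalence,
                            inheritance = c("monoallelic", "biallelic"),
                            genetic_heterogeneity = 1,
                            allelic_heterogeneity = 1,
                            penetrance = 1) {
  inheritance <- match.arg(inheritance)
  for (nm in c("prevalence", "genetic_heterogeneity",
               "allelic_heterogeneity", "penetrance"))
    check_scalar_number(get(nm), nm, lower = 0, upper = 1, open_lower = TRUE)
  if (inheritance == "monoallelic")
    prevalence * genetic_heterogeneity * allelic_heterogeneity / (2 * penetrance)
  else
    sqrt(prevalence * genetic_heterogeneity / penetrance) * allelic_heterogeneity
}

#' Does a variant co-segregate with affection in one family?
#'
#' Under the dominant model a variant segregates when (a) every affected
#' family member with a non-missing genotype carries at least one alternate
#' allele, and (b) among genotyped members with known phenotype, the
#' fraction of carriers that are affected reaches the model's
#' `penetrance_min`. Members with unknown affection status are excluded from
#' both counts.
#'
#' @param variant One-row slice of `variant_table$variants` (carried along
#'   for interface symmetry; the decision uses only the genotypes).
#' @param genotypes Named dosage vector (individual id -> 0/1/2/NA) for the
#'   variant.
#' @param family A pedigree object.
#' @param model A [segregation_model()].
#' @return `TRUE` or `FALSE`; families without any genotyped affected member
#'   yield `FALSE` with a warning.
#' @export
segregates_in_family <- function(variant, genotypes, family,
                                 model = segregation_model()) {
  stopifnot(inherits(family, "pedigree"), inherits(model, "segregation_model"))
  m <- family$members
  dos <- genotypes[m$individual_id]
  genotyped <- !is.na(dos)
  known <- m$affected != "unknown"
  affected <- m$affected == "yes"
  if (!any(affected & genotyped)) {
    warning(sprintf("family %s has no genotyped affected member", family$family_id))
    return(FALSE)
  }
  if (any(affected & genotyped & dos == 0)) return(FALSE)
  carriers <- genotyped & known & dos >= 1
  if (!sum(carriers)) return(FALSE)
  sum(carriers & affected) / sum(carriers) >= model$penetrance_min
}

## Vectorized segregation over the rows of a genotype matrix for one family.
segregation_over_rows <- function(gt, family, model) {
  m <- family$members
  cols <- match(m$individual_id, colnames(gt))
  if (anyNA(cols))
    stop_format("family %s has members without genotype columns",
                family$family_id)
  dos <- gt[, cols, drop = FALSE]
  genotyped <- !is.na(dos)
  known <- m$affected != "unknown"
  affected <- m$affected == "yes"
  aff_gt <- sweep(genotyped, 2L, affected, `&`)
  any_aff_gt <- rowSums(aff_gt) > 0
  aff_noncarrier <- rowSums(aff_gt & !is.na(dos) & dos == 0, na.rm = TRUE) > 0
  carrier <- genotyped & !is.na(dos) & dos >= 1
  carrier_known <- sweep(carrier, 2L, known, `&`)
  n_carrier <- rowSums(carrier_known)
  n_aff_carrier <- rowSums(sweep(carrier_known, 2L, affected, `&`))
  ok <- any_aff_gt & !aff_noncarrier & n_carrier > 0 &
    n_aff_carrier / pmax(n_carrier, 1L) >= model$penetrance_min
  ok
}

#' Per-gene mutation status from family segregation
#'
#' A gene is `mutated` when at least one of its variants is functional, rare,
#' and co-segregates with affection in at least one family; `non_mutated`
#' when it has at least one variant but none qualifying; `undetected` when no
#' variant at all was observed in the cohort — undetected genes are excluded
#' from downstream burden testing. The per-gene family count is the number
#' of distinct families with a qualifying co-segregating variant in the gene.
#'
#' @param variants A `variant_table`.
#' @param families List of pedigree objects (or [simulate_family()] results).
#' @param genes Gene identifiers under test (the network gene list).
#' @param model A [segregation_model()].
#' @param maf_threshold Rarity cut-off (default 0.05).
#' @return Data frame with columns `gene`, `status`, `n_families`, and a
#'   list column `qualifying` of row indices into `variants$variants`.
#' @export
gene_status_familial <- function(variants, families, genes,
                                 model = segregation_model(),
                                 maf_threshold = 0.05) {
  stopifnot(inherits(variants, "variant_table"))
  families <- lapply(families, function(f)
    if (inherits(f, "pedigree")) f else f$pedigree)
  v <- variants$variants
  candidate <- which(is_functional(v$consequence) &
                     passes_maf(v$maf, maf_threshold) &
                     v$gene %in% genes)
  ## family-by-candidate segregation matrix
  seg <- matrix(FALSE, length(candidate), length(families))
  if (length(candidate)) {
    gt <- variants$genotypes[candidate, , drop = FALSE]
    for (j in seq_along(families))
      seg[, j] <- segregation_over_rows(gt, families[[j]], model)
  }
  seg_any <- rowSums(seg) > 0
  build_status(genes, v, candidate, seg_any,
               n_families_fun = function(rows)
                 sum(colSums(seg[rows, , drop = FALSE]) > 0))
}

#' Per-gene mutation status in an unrelated cohort
#'
#' Cohort analogue of [gene_status_familial()]: no pedigree structure, so a
#' gene is `mutated` as soon as one functional rare variant is carried by at
#' least one individual.
#'
#' @inheritParams gene_status_familial
#' @return Data frame as in [gene_status_familial()] (`n_families` is `NA`).
#' @export
gene_status_cohort <- function(variants, genes, maf_threshold = 0.05) {
  stopifnot(inherits(variants, "variant_table"))
  v <- variants$variants
  candidate <- which(is_functional(v$consequence) &
                     passes_maf(v$maf, maf_threshold) &
                     v$gene %in% genes)
  carried <- rowSums(variants$genotypes[candidate, , drop = FALSE] >= 1,
                     na.rm = TRUE) > 0
  build_status(genes, v, candidate, carried, n_families_fun = NULL)
}

build_status <- function(genes, v, candidate, qualifying_flag, n_families_fun) {
  detected <- genes %in% v$gene
  qual_rows <- candidate[qualifying_flag]
  qual_by_gene <- split(qual_rows, factor(v$gene[qual_rows], levels = genes))
  cand_pos <- match(qual_rows, candidate)
  status <- ifelse(!detected, "undetected",
                   ifelse(lengths(qual_by_gene) > 0, "mutated", "non_mutated"))
  n_families <- rep(NA_integer_, length(genes))
  if (!is.null(n_families_fun)) {
    pos_by_gene <- split(cand_pos, factor(v$gene[qual_rows], levels = genes))
    n_families <- vapply(seq_along(genes), function(i) {
      if (status[i] != "mutated") return(0L)
      as.integer(n_families_fun(pos_by_gene[[i]]))
    }, 0L)
    n_families[status == "undetected"] <- NA_integer_
  }
  out <- data.frame(gene = genes, status = status, n_families = n_families,
                    stringsAsFactors = FALSE)
  out$qualifying <- unname(qual_by_gene)
  rownames(out) <- NULL
  out
}
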