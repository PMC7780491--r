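#' Read a genes-by-samples expression matrix
#'
#' Reads a tab-separated file whose first column holds gene identifiers and
#' whose header row holds sample identifiers. Row and column order are
#' preserved. Duplicate identifiers and non-numeric cells are format errors.
#'
#' @param path Path to a tab-separated expression file.
#' @return A numeric matrix with gene identifiers as row names and sample
#'   identifiers as column names.
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) stop_format("expression file '%s' has no sample columns", path)
  genes <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  dup_g <- genes[duplicated(genes)]
  if (length(dup_g))
    stop_format("duplicate gene identifier(s) in '%s': %s", path,
                paste(unique(dup_g), collapse = ", "))
  dup_s <- samples[duplicated(samples)]
  if (length(dup_s))
    stop_format("duplicate sample identifier(s) in '%s': %s", path,
                paste(unique(dup_s), collapse = ", "))
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(genes, samples))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop_format("non-numeric or non-finite value at gene '%s', sample '%s' in '%s'",
                genes[bad[1L, 1L]], samples[bad[1L, 2L]], path)
  vals
}

#' Write an expression matrix as tab-separated text
#'
#' @param expr Numeric matrix, genes in rows (named), samples in columns (named).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  validate_expression_matrix(expr)
  df <- data.frame(gene_id = rownames(expr), expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_expression_matrix <- function(expr, min_samples = 1L) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop_format("expression must be a numeric matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop_format("expression matrix must carry gene and sample identifiers")
  if (anyDuplicated(rownames(expr))) stop_format("duplicate gene identifiers")
  if (anyDuplicated(colnames(expr))) stop_format("duplicate sample identifiers")
  if (any(!is.finite(expr))) stop_format("expression matrix contains non-finite values")
  if (ncol(expr) < min_samples)
    stop_format("expression matrix has %d samples; at least %d required",
                ncol(expr), min_samples)
  invisible(expr)
}

#' Read a two-column gene score table (e.g. RVIS)
#'
#' @param path Tab-separated file: gene identifier, numeric score. A header
#'   line is detected automatically (non-numeric second field).
#' @return Named numeric vector of scores keyed by gene.
#' @export
read_score_table <- function(path) {
  first <- utils::read.delim(path, header = FALSE, sep = "\t", nrows = 1L,
                             colClasses = "character")
  has_header <- is.na(suppressWarnings(as.numeric(first[[2L]])))
  df <- utils::read.delim(path, header = has_header, sep = "\t",
                          colClasses = c("character", "numeric"))
  genes <- df[[1L]]
  if (anyDuplicated(genes))
    stop_format("duplicate gene in score table: %s",
                genes[duplicated(genes)][1L])
  scores <- df[[2L]]
  if (any(!is.finite(scores))) stop_format("non-finite score in '%s'", path)
  stats::setNames(scores, genes)
}

#' Read pathway gene sets in GMT format
#'
#' Thin wrapper over [fgsea::gmtPathways()] adding the validation the
#' pipeline relies on (unique pathway names, non-empty gene sets).
#'
#' @param path Path to a GMT file (pathway, description, genes...).
#' @return Named list of character gene-identifier vectors.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets)))
    stop_format("duplicate pathway name in '%s'", path)
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty))
    stop_format("empty gene set(s) in '%s': %s", path,
                paste(empty, collapse = ", "))
  sets
}

#' Write a module assignment as a two-column table
#'
#' @param modules Named character vector mapping gene to module label.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_module_assignment <- function(modules, path) {
  utils::write.table(
    data.frame(gene = names(modules), module = unname(modules)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
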