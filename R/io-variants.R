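## Variant tables: cohort genotypes with per-gene consequence and population
## allele-frequency annotations, one record per (variant, annotated gene).

#' Consequence classes counted as functional
#'
#' The eight coding-impact classes used by the rarity/functionality filter:
#' frameshift and non-frameshift indels, non-synonymous SNVs, splice-site,
#' stop-gain and stop-loss changes.
#'
#' @export
FUNCTIONAL_CLASSES <- c(
  "frameshift_deletion", "frameshift_insertion",
  "nonframeshift_deletion", "nonframeshift_insertion",
  "nonsynonymous_SNV", "splice_site", "stopgain", "stoploss")

CONSEQUENCE_CLASSES <- c(FUNCTIONAL_CLASSES, "other")

new_variant_table <- function(variants, genotypes) {
  stopifnot(is.data.frame(variants), is.matrix(genotypes),
            nrow(variants) == nrow(genotypes))
  if (any(variants$pos < 1L)) stop_format("variant position must be >= 1")
  bad_gt <- genotypes[!is.na(genotypes)]
  if (length(bad_gt) && !all(bad_gt %in% 0:2))
    stop_format("genotype dosages must be 0, 1, 2 or missing")
  variants$consequence <- ifelse(
    variants$consequence %in% CONSEQUENCE_CLASSES, variants$consequence, "other")
  structure(list(variants = variants, genotypes = genotypes),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table> %d records (%d genes) x %d individuals\n",
              nrow(x$variants), length(unique(x$variants$gene)),
              ncol(x$genotypes)))
  invisible(x)
}

#' Read an annotated VCF into a variant table
#'
#' Parses a VCF v4.x with per-sample GT and INFO keys carrying the population
#' allele frequency, the consequence class, and the annotated gene(s).
#' Multi-allelic sites are split into biallelic records; per-allele
#' (Number=A) INFO values are matched to their allele. Multi-gene annotations
#' (separated by `|`, `&` or `;`) are expanded to one record per gene.
#' Phased and unphased genotypes are read identically as alt-allele dosage;
#' half-missing calls (`./1`) are treated as missing. A missing population
#' frequency stays missing (`NA`) — it is never coerced to 0.
#'
#' @param path Path to a VCF file.
#' @param maf_field INFO key of the population allele frequency.
#' @param consequence_field INFO key of the consequence class; strings outside
#'   the known classes map to `"other"`.
#' @param gene_field INFO key of the annotated gene identifier(s).
#' @return A `variant_table`: `$variants` data frame (chrom, pos, ref, alt,
#'   consequence, maf, gene) aligned row-wise with a `$genotypes` integer
#'   dosage matrix (individuals in columns).
#' @export
read_variant_table <- function(path, maf_field = "POPMAF",
                               consequence_field = "CSQCLASS",
                               gene_field = "GENE") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  gt_raw <- vcf@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2L)
    stop_format("VCF '%s' carries no per-sample genotypes", path)
  if (!all(grepl("(^|:)GT(:|$)", gt_raw[, "FORMAT"])))
    stop_format("VCF '%s': GT missing from FORMAT", path)
  samples <- colnames(gt_raw)[-1L]
  gt_field <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt_field)))
    gt_field <- matrix(gt_field, nrow = nrow(fix), dimnames = list(NULL, samples))

  info <- fix[, "INFO"]
  get_info <- function(key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    out <- rep(NA_character_, length(info))
    hit <- grepl(paste0("(^|;)", key, "="), info)
    out[hit] <- sub(paste0("^;?", key, "="), "", m)
    out
  }
  maf_raw <- get_info(maf_field)
  csq_raw <- get_info(consequence_field)
  gene_raw <- get_info(gene_field)

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    n_alt <- length(alts)
    pick_allele <- function(raw) {
      if (is.na(raw)) return(rep(NA_character_, n_alt))
      parts <- strsplit(raw, ",", fixed = TRUE)[[1L]]
      if (length(parts) == n_alt) parts else rep(parts[1L], n_alt)
    }
    mafs <- pick_allele(maf_raw[i])
    csqs <- pick_allele(csq_raw[i])
    genes <- pick_allele(gene_raw[i])
    ## dosage of allele k per sample from the GT string
    gt_split <- strsplit(gt_field[i, ], "[/|]")
    for (k in seq_len(n_alt)) {
      dos <- vapply(gt_split, function(al) {
        if (length(al) == 0L || anyNA(al) || any(al == "." | al == ""))
          return(NA_integer_)
        sum(al == as.character(k))
      }, integer(1L))
      maf_k <- suppressWarnings(as.numeric(mafs[k]))
      if (!is.na(mafs[k]) && mafs[k] != "." && is.na(maf_k)) {
        warning(sprintf("unparsable %s '%s' at %s:%s; recorded as missing",
                        maf_field, mafs[k], fix[i, "CHROM"], fix[i, "POS"]))
      }
      csq_k <- csqs[k]
      if (is.na(csq_k) || !(csq_k %in% CONSEQUENCE_CLASSES)) csq_k <- "other"
      gene_k <- genes[k]
      if (is.na(gene_k) || gene_k == ".") {
        warning(sprintf("record at %s:%s allele %s has no %s annotation; dropped",
                        fix[i, "CHROM"], fix[i, "POS"], alts[k], gene_field))
        next
      }
      for (g in strsplit(gene_k, "[|&;]")[[1L]]) {
        rows[[i]] <- c(rows[[i]], list(list(
          chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
          ref = fix[i, "REF"], alt = alts[k], consequence = csq_k,
          maf = maf_k, gene = g, dosage = dos)))
      }
    }
  }
  rows <- unlist(rows, recursive = FALSE)
  if (!length(rows))
    return(new_variant_table(
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), consequence = character(),
                 maf = numeric(), gene = character()),
      matrix(integer(), 0L, length(samples), dimnames = list(NULL, samples))))
  variants <- data.frame(
    chrom = vapply(rows, `[[`, "", "chrom"),
    pos = vapply(rows, `[[`, 0L, "pos"),
    ref = vapply(rows, `[[`, "", "ref"),
    alt = vapply(rows, `[[`, "", "alt"),
    consequence = vapply(rows, `[[`, "", "consequence"),
    maf = vapply(rows, `[[`, 0, "maf"),
    gene = vapply(rows, `[[`, "", "gene"),
    stringsAsFactors = FALSE)
  genotypes <- do.call(rbind, lapply(rows, `[[`, "dosage"))
  colnames(genotypes) <- samples
  new_variant_table(variants, genotypes)
}

#' Write a variant table as a VCF
#'
#' Emits a minimal VCF v4.2 with GENE/CSQCLASS/POPMAF INFO keys and per-sample
#' GT, the inverse of [read_variant_table()] on its defaults. Records sharing
#' a site are written as separate biallelic lines.
#'
#' @param vt A `variant_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(vt, path) {
  stopifnot(inherits(vt, "variant_table"))
  v <- vt$variants
  samples <- colnames(vt$genotypes)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=A,Type=String,Description=\"Annotated gene\">",
    "##INFO=<ID=CSQCLASS,Number=A,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=POPMAF,Number=A,Type=Float,Description=\"Population allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[vt$genotypes + 1L],
                   nrow = nrow(v))
  gt_str[is.na(gt_str)] <- "./."
  info <- paste0("GENE=", v$gene, ";CSQCLASS=", v$consequence,
                 ifelse(is.na(v$maf), "", paste0(";POPMAF=", v$maf)))
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info, "GT",
                apply(gt_str, 1L, paste, collapse = "\t"), sep = "\t")
  if (nrow(v) == 0L) body <- character()
  writeLines(c(header, body), path)
  invisible(path)
}
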