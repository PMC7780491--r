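#' Read pedigrees from a 6-column PED file
#'
#' Pre-makeped PED: family, individual, father, mother, sex, phenotype.
#' Phenotype coding 2 = affected, 1 = unaffected, 0 or -9 = unknown; sex
#' 1 = male, 2 = female, anything else unknown; parent "0" = founder.
#'
#' @param path Path to a whitespace-delimited PED file.
#' @return A named list of pedigree objects (one per family id), each a list
#'   with `family_id` and a `members` data frame holding `individual_id`,
#'   `father_id`, `mother_id` (NA for founders), `sex` and `affected`
#'   (`"yes"`, `"no"`, `"unknown"`).
#' @export
read_pedigrees <- function(path) {
  df <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(df) < 6L) stop_format("PED file '%s' needs 6 columns", path)
  df <- df[, 1:6]
  names(df) <- c("family_id", "individual_id", "father_id", "mother_id",
                 "sex", "phenotype")
  peds <- lapply(split(df, factor(df$family_id, levels = unique(df$family_id))),
                 function(fam) {
    members <- data.frame(
      individual_id = fam$individual_id,
      father_id = ifelse(fam$father_id == "0", NA_character_, fam$father_id),
      mother_id = ifelse(fam$mother_id == "0", NA_character_, fam$mother_id),
      sex = ifelse(fam$sex %in% c("1", "2"), fam$sex, "unknown"),
      affected = unname(c("2" = "yes", "1" = "no")[fam$phenotype]),
      stringsAsFactors = FALSE)
    members$affected[is.na(members$affected)] <- "unknown"
    new_pedigree(fam$family_id[1L], members)
  })
  peds
}

new_pedigree <- function(family_id, members) {
  rownames(members) <- NULL
  if (anyDuplicated(members$individual_id))
    stop_format("family %s: duplicate individual id", family_id)
  for (col in c("father_id", "mother_id")) {
    known <- members[[col]][!is.na(members[[col]])]
    missing_parent <- setdiff(known, members$individual_id)
    if (length(missing_parent))
      stop_format("family %s: parent id '%s' not a family member",
                  family_id, missing_parent[1L])
  }
  ## no individual may be its own ancestor
  idx <- stats::setNames(seq_len(nrow(members)), members$individual_id)
  for (start in seq_len(nrow(members))) {
    seen <- logical(nrow(members))
    frontier <- start
    while (length(frontier)) {
      parents <- c(members$father_id[frontier], members$mother_id[frontier])
      frontier <- idx[parents[!is.na(parents)]]
      if (any(frontier == start))
        stop_format("family %s: '%s' is its own ancestor (cyclic parentage)",
                    family_id, members$individual_id[start])
      frontier <- frontier[!seen[frontier]]
      seen[frontier] <- TRUE
    }
  }
  structure(list(family_id = family_id, members = members),
            class = "pedigree")
}

#' Write pedigrees to a 6-column PED file
#'
#' @param pedigrees A list of pedigree objects (see [read_pedigrees()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigrees <- function(pedigrees, path) {
  rows <- lapply(pedigrees, function(ped) {
    m <- ped$members
    data.frame(
      family = ped$family_id,
      individual = m$individual_id,
      father = ifelse(is.na(m$father_id), "0", m$father_id),
      mother = ifelse(is.na(m$mother_id), "0", m$mother_id),
      sex = ifelse(m$sex %in% c("1", "2"), m$sex, "0"),
      phenotype = c(yes = "2", no = "1", unknown = "0")[m$affected])
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  n_aff <- sum(x$members$affected == "yes")
  cat(sprintf("<pedigree> family %s: %d members, %d affected, %d founders\n",
              x$family_id, nrow(x$members), n_aff,
              sum(is.na(x$members$father_id) & is.na(x$members$mother_id))))
  invisible(x)
}
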