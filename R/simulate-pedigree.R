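#' Simulate a multi-generation pedigree with a segregating causal allele
#'
#' Builds a monogamous, non-consanguineous family: the two generation-1
#' founders have `children_per_couple` children; every child in a
#' non-terminal generation marries an unrelated founder spouse and has
#' `children_per_couple` children in turn. One generation-1 founder carries a
#' single copy of a causal allele, transmitted to each child with probability
#' 1/2 (gene dropping). Carriers are affected with probability `penetrance`,
#' non-carriers with probability `phenocopy_rate`.
#'
#' @param n_generations Number of generations (>= 2).
#' @param children_per_couple Children born to each couple (>= 1).
#' @param penetrance P(affected | carrier), in (0, 1].
#' @param phenocopy_rate P(affected | non-carrier), in [0, 1).
#' @param seed Integer seed.
#' @param family_id Family identifier used in member ids.
#' @return A list with `pedigree` (see [read_pedigrees()]) and `carriers`,
#'   a named logical vector over the family members.
#' @export
simulate_family <- function(n_generations = 3, children_per_couple = 3,
                            penetrance = 1, phenocopy_rate = 0, seed,
                            family_id = "FAM1") {
  check_scalar_number(n_generations, "n_generations", lower = 2, integerish = TRUE)
  check_scalar_number(children_per_couple, "children_per_couple", lower = 1,
                      integerish = TRUE)
  check_scalar_number(penetrance, "penetrance", lower = 0, upper = 1,
                      open_lower = TRUE)
  check_scalar_number(phenocopy_rate, "phenocopy_rate", lower = 0, upper = 1,
                      open_upper = TRUE)
  check_scalar_number(seed, "seed", integerish = TRUE)

  withr::with_seed(seed, {
    counter <- 0L
    next_id <- function() {
      counter <<- counter + 1L
      sprintf("%s_I%03d", family_id, counter)
    }
    members <- list()
    add_member <- function(id, father, mother, sex, carrier) {
      members[[id]] <<- list(id = id, father = father, mother = mother,
                             sex = sex, carrier = carrier)
      id
    }
    f1 <- add_member(next_id(), NA, NA, "1", TRUE)   # carrier founder
    f2 <- add_member(next_id(), NA, NA, "2", FALSE)
    couples <- list(c(f1, f2))
    for (gen in 2:n_generations) {
      next_couples <- list()
      for (cp in couples) {
        father <- members[[cp[1L]]]; mother <- members[[cp[2L]]]
        for (k in seq_len(children_per_couple)) {
          carrier <- (father$carrier || mother$carrier) &&
            stats::runif(1) < 0.5
          sex <- sample(c("1", "2"), 1L)
          child <- add_member(next_id(), father$id, mother$id, sex, carrier)
          if (gen < n_generations) {
            spouse_sex <- if (sex == "1") "2" else "1"
            spouse <- add_member(next_id(), NA, NA, spouse_sex, FALSE)
            next_couples[[length(next_couples) + 1L]] <-
              if (sex == "1") c(child, spouse) else c(spouse, child)
          }
        }
      }
      couples <- next_couples
    }
    carriers <- vapply(members, `[[`, TRUE, "carrier")
    affected <- ifelse(carriers,
                       stats::runif(length(members)) < penetrance,
                       stats::runif(length(members)) < phenocopy_rate)
  })
  mem_df <- data.frame(
    individual_id = vapply(members, `[[`, "", "id"),
    father_id = vapply(members, function(m) as.character(m$father), ""),
    mother_id = vapply(members, function(m) as.character(m$mother), ""),
    sex = vapply(members, `[[`, "", "sex"),
    affected = ifelse(affected, "yes", "no"),
    stringsAsFactors = FALSE)
  list(pedigree = new_pedigree(family_id, mem_df),
       carriers = stats::setNames(unname(carriers), mem_df$individual_id))
}

#' Simulate a cohort of families
#'
#' Convenience wrapper around [simulate_family()] producing `n_families`
#' independent families with distinct ids and per-family child seeds derived
#' from `seed`.
#'
#' @inheritParams simulate_family
#' @param n_families Number of families.
#' @return List of [simulate_family()] results, named by family id.
#' @export
simulate_families <- function(n_families, n_generations = 3,
                              children_per_couple = 3, penetrance = 1,
                              phenocopy_rate = 0, seed) {
  check_scalar_number(n_families, "n_families", lower = 1, integerish = TRUE)
  fams <- lapply(seq_len(n_families), function(i) {
    simulate_family(n_generations, children_per_couple, penetrance,
                    phenocopy_rate,
                    seed = stage_seed(seed, paste0("family", i)),
                    family_id = sprintf("FAM%03d", i))
  })
  names(fams) <- vapply(fams, function(f) f$pedigree$family_id, "")
  fams
}
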