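#' @keywords internal
"_PACKAGE"

## Internal helpers shared across the package.

stop_format <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                open_lower = FALSE, open_upper = FALSE,
                                integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_format("'%s' must be a single finite number", name)
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_format("'%s' = %g is outside its valid range %s%g, %g%s", name, x,
                if (open_lower) "(" else "[", lower, upper,
                if (open_upper) ")" else "]")
  if (integerish && x != round(x))
    stop_format("'%s' must be an integer", name)
  invisible(x)
}

#' Derive a reproducible child seed for a named pipeline stage
#'
#' A single run seed fans out to per-stage seeds by hashing the stage name,
#' so each stage's random stream is reproducible independently of the order
#' in which stages execute.
#'
#' @param seed Integer run seed.
#' @param stage Character stage name.
#' @return A single integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  check_scalar_number(seed, "seed", integerish = TRUE)
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  ## double arithmetic stays exact well beyond 2^31 * 2654435
  as.integer((abs(seed) * 2654435 + h * 97) %% 2147483647)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same gene set,
#' used to score recovered module assignments against simulation truth
#' (the unassigned "grey" label counts as a class of its own).
#'
#' @param a,b Label vectors of equal length.
#' @return A number <= 1; 1 means identical partitions, 0 is the chance level.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_format("labelings differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

## Benjamini-Hochberg via base R; kept behind one name so both enrichment
## families adjust identically.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
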