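# Carrier-status tabulation and the 2x2 chi-square carrier-enrichment
# test; per-trait-group Tier-1 gene distribution.

#' Uncorrected (or Yates-corrected) 2x2 chi-square test
#'
#' Pearson chi-square on a 2x2 table laid out as row 1 = diagnosed
#' (carriers, non-carriers), row 2 = non-diagnosed (carriers,
#' non-carriers), computed from the closed form
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with 1 degree of freedom and an
#' upper-tail p-value. No continuity correction is applied by default; with
#' `correct = TRUE` the Yates-corrected statistic
#' `N (|ad - bc| - N/2)^2 / (...)` is returned instead (always smaller on a
#' non-degenerate table).
#'
#' @param a,b Diagnosed carriers and non-carriers.
#' @param c,d Non-diagnosed carriers and non-carriers.
#' @param correct Apply the Yates continuity correction.
#' @return List of class `contingency_result`: `table`, `chi2`, `df` (= 1),
#'   `p`, `odds_ratio` (`NA` when any cell is zero), `n`, `correct`.
#' @export
#' @examples
#' chi_square_2x2(50, 24, 11, 23)
chi_square_2x2 <- function(a, b, c, d, correct = FALSE) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  n <- a + b + c + d
  if (n <= 0) stop("empty table")
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    stop("chi-square test undefined: a table margin is zero")
  }
  delta <- abs(a * d - b * c)
  if (correct) delta <- max(0, delta - n / 2)
  chi2 <- n * delta^2 / prod(margins)
  structure(list(
    table = matrix(cells, 2, 2, byrow = TRUE,
                   dimnames = list(c("diagnosed", "non_diagnosed"),
                                   c("carrier", "non_carrier"))),
    chi2 = chi2, df = 1L,
    p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
    odds_ratio = if (all(cells > 0)) (a * d) / (b * c) else NA_real_,
    n = n, correct = correct
  ), class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("chi2(%d, N = %d) = %.4f%s, p = %.3g, OR = %.3g\n",
              x$df, x$n, x$chi2,
              if (x$correct) " [Yates]" else "", x$p, x$odds_ratio))
  invisible(x)
}

#' Tier-1 carrier status per individual
#'
#' Flags each cohort member carrying at least one prioritised variant in a
#' Tier-1 gene, using the report's carrier lists (inherited carriers and de
#' novo children).
#'
#' @param cohort A `fam_cohort` data frame.
#' @param prioritised Prioritised-variant data frame with `tier` and
#'   `carriers` columns (comma-separated ids).
#' @return Data frame `individual_id`, `diagnosis`, `tier1_carrier`.
#' @export
tier1_carrier_status <- function(cohort, prioritised) {
  hits <- prioritised[!is.na(prioritised$tier) & prioritised$tier == 1L, ,
                      drop = FALSE]
  carrier_ids <- unique(unlist(strsplit(hits$carriers, ",", fixed = TRUE)))
  data.frame(individual_id = cohort$individual_id,
             diagnosis = cohort$diagnosis,
             tier1_carrier = cohort$individual_id %in% carrier_ids,
             stringsAsFactors = FALSE)
}

#' Carrier-by-diagnosis contingency table
#'
#' Builds the 2x2 table of Tier-1 carrier status against diagnosis.
#' Individuals with a suspected or unknown diagnosis are excluded from the
#' table entirely: the non-diagnosed row contains only members confirmed
#' non-autistic (who did not themselves suspect an autism diagnosis).
#'
#' @param diagnosis Character vector of diagnosis statuses.
#' @param carrier Logical vector of Tier-1 carrier flags.
#' @return Named integer vector `a`, `b`, `c`, `d` (diagnosed carriers /
#'   non-carriers, non-diagnosed carriers / non-carriers).
#' @export
carrier_contingency <- function(diagnosis, carrier) {
  stopifnot(length(diagnosis) == length(carrier))
  dx <- diagnosis == "diagnosed"
  na <- diagnosis == "non_autistic"
  c(a = sum(dx & carrier), b = sum(dx & !carrier),
    c = sum(na & carrier), d = sum(na & !carrier))
}

#' Tier-1 carrier enrichment test
#'
#' Convenience wrapper: flags Tier-1 carriers ([tier1_carrier_status()]),
#' tabulates them against diagnosis ([carrier_contingency()], suspected and
#' unknown individuals excluded) and runs [chi_square_2x2()].
#'
#' @inheritParams tier1_carrier_status
#' @param correct Apply the Yates continuity correction.
#' @return A `contingency_result`.
#' @export
tier1_enrichment <- function(cohort, prioritised, correct = FALSE) {
  st <- tier1_carrier_status(cohort, prioritised)
  tab <- carrier_contingency(st$diagnosis, st$tier1_carrier)
  chi_square_2x2(tab["a"], tab["b"], tab["c"], tab["d"], correct = correct)
}

#' Distribution of Tier-1 genes across trait groups
#'
#' For each trait subgroup, counts the distinct Tier-1 genes having at
#' least one prioritised variant labelled with that group. A gene labelled
#' with different groups in different families counts once in each.
#'
#' @param prioritised Prioritised-variant data frame with `gene`, `tier`
#'   and either `trait_level` or a parseable `label` column.
#' @return Named integer vector with counts for `BAP`, `MAP`, `NAP`.
#' @export
tier1_trait_distribution <- function(prioritised) {
  x <- prioritised
  if (is.null(x$trait_level)) x$trait_level <- parse_label(x$label)$trait_level
  t1 <- x[!is.na(x$tier) & x$tier == 1L & x$trait_level != "none", ,
          drop = FALSE]
  vapply(c(BAP = "BAP", MAP = "MAP", NAP = "NAP"), function(lv) {
    length(unique(t1$gene[t1$trait_level == lv]))
  }, 0L)
}
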