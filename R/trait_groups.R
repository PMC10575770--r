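# Autistic-trait subgroup bands on standardised questionnaire scores.

.TRAIT_LEVELS <- c("AVERAGE", "BAP", "MAP", "NAP")
.INSTRUMENTS <- c("adult-AQ", "adolescent-AQ", "child-AQ", "Q-CHAT")

#' Trait subgroup levels
#'
#' The four autistic-trait subgroups in increasing order of severity:
#' `AVERAGE` (below 1 SD above the normative mean), `BAP` (broad autistic
#' phenotype, 1--2 SD), `MAP` (medium, 2--3 SD) and `NAP` (narrow, 3+ SD).
#'
#' @return Character vector of the four ordered level names.
#' @export
trait_levels <- function() .TRAIT_LEVELS

#' Coerce to an ordered trait-group factor
#'
#' @param x Character vector of trait-group names.
#' @return Ordered factor with levels `AVERAGE < BAP < MAP < NAP`.
#' @export
trait_factor <- function(x) factor(x, levels = .TRAIT_LEVELS, ordered = TRUE)

#' Names of the supported trait instruments
#'
#' @return Character vector: adult, adolescent and child AQ, and Q-CHAT.
#' @export
trait_instruments <- function() .INSTRUMENTS

#' Assign an autistic-trait subgroup from a questionnaire score
#'
#' Places scores into standard-deviation bands above the instrument's
#' normative mean: `NAP` at `mean + 3*sd` and above, `MAP` at
#' `[mean + 2*sd, mean + 3*sd)`, `BAP` at `[mean + 1*sd, mean + 2*sd)`,
#' and `AVERAGE` below. Bands are closed at the lower edge and open at the
#' upper edge, so a score exactly at `mean + 2*sd` is `MAP`, not `BAP`.
#'
#' @param score Numeric vector of raw total scores. Must be finite.
#' @param norm_mean,norm_sd Normative mean and standard deviation of the
#'   instrument in the reference population (`norm_sd > 0`). Norms are
#'   configuration, not package constants: supply them per instrument.
#' @return Ordered factor of trait groups, same length as `score`.
#' @export
#' @examples
#' assign_trait_group(c(20, 27, 30, 36), norm_mean = 20, norm_sd = 5)
assign_trait_group <- function(score, norm_mean, norm_sd) {
  if (!is.numeric(norm_mean) || !is.numeric(norm_sd) ||
      any(!is.finite(norm_mean)) || any(!is.finite(norm_sd))) {
    stop("instrument norms (norm_mean, norm_sd) must be supplied and finite")
  }
  if (any(norm_sd <= 0)) stop("norm_sd must be > 0")
  if (!is.numeric(score) || any(!is.finite(score))) {
    stop("trait scores must be finite numbers")
  }
  z <- (score - norm_mean) / norm_sd
  lev <- ifelse(z >= 3, "NAP", ifelse(z >= 2, "MAP", ifelse(z >= 1, "BAP", "AVERAGE")))
  trait_factor(lev)
}

#' Read instrument norm configuration
#'
#' Loads a YAML file (or validates a list) mapping instrument names to their
#' normative `mean` and `sd`. Instrument names must come from
#' [trait_instruments()].
#'
#' @param x Path to a YAML file, or a named list like
#'   `list("adult-AQ" = list(mean = 16.4, sd = 6.25))`.
#' @return Validated named list of `list(mean, sd)` entries.
#' @export
read_instrument_norms <- function(x) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  if (!is.list(x) || is.null(names(x)) || any(names(x) == "")) {
    stop("instrument norms must be a named list or YAML mapping")
  }
  bad <- setdiff(names(x), .INSTRUMENTS)
  if (length(bad)) {
    stop("unknown instrument(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(.INSTRUMENTS, collapse = ", "))
  }
  for (nm in names(x)) {
    e <- x[[nm]]
    if (is.null(e$mean) || is.null(e$sd) || !is.finite(e$mean) || !is.finite(e$sd)) {
      stop("instrument ", nm, " must provide finite mean and sd")
    }
    if (e$sd <= 0) stop("instrument ", nm, ": sd must be > 0")
  }
  x
}
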