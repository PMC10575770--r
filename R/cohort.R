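# Cohort model: pedigrees, diagnosis status, trait subgroups, trios.

.DIAGNOSES <- c("diagnosed", "suspected", "non_autistic", "unknown")

.norm_diagnosis <- function(x) {
  x <- trimws(tolower(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% .DIAGNOSES] <- x[x %in% .DIAGNOSES]
  # standard PED phenotype coding fallback
  out[is.na(out) & x == "2"] <- "diagnosed"
  out[is.na(out) & x == "1"] <- "non_autistic"
  out[is.na(out) & x %in% c("0", "-9", ".", "na", "")] <- "unknown"
  if (anyNA(out)) {
    stop("unrecognised diagnosis value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

#' Read a PLINK-style PED file
#'
#' Whitespace-delimited, six mandatory columns (family, individual, father,
#' mother, sex, phenotype) with the founder marker `"0"` for missing parents
#' and sex coded 1 = male, 2 = female, 0 = unknown. Diagnosis status is taken
#' from an optional seventh column (values `diagnosed`, `suspected`,
#' `non_autistic`, `unknown`, or numeric PED phenotype codes), from a side
#' table, or -- failing both -- from the standard phenotype column
#' (2 = diagnosed, 1 = non_autistic, else unknown). The seventh column exists
#' because standard PED phenotype coding cannot express "suspected".
#'
#' @param path Path to the PED file (plain or gzip).
#' @param diagnosis_table Optional data frame with columns `individual_id`
#'   and `diagnosis`, overriding the file's phenotype column.
#' @return Data frame with columns `family_id`, `individual_id`, `father_id`,
#'   `mother_id`, `sex`, `diagnosis`.
#' @export
read_ped <- function(path, diagnosis_table = NULL) {
  ped <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(ped) < 6) stop("PED file must have at least 6 columns: ", path)
  out <- data.frame(
    family_id = ped[[1]], individual_id = ped[[2]],
    father_id = ped[[3]], mother_id = ped[[4]],
    sex = c("1" = "male", "2" = "female")[ped[[5]]],
    stringsAsFactors = FALSE
  )
  out$sex[is.na(out$sex)] <- "unknown"
  if (!is.null(diagnosis_table)) {
    m <- match(out$individual_id, diagnosis_table$individual_id)
    if (anyNA(m)) stop("diagnosis table missing individual(s): ",
                       paste(out$individual_id[is.na(m)], collapse = ", "))
    out$diagnosis <- .norm_diagnosis(diagnosis_table$diagnosis[m])
  } else if (ncol(ped) >= 7) {
    out$diagnosis <- .norm_diagnosis(ped[[7]])
  } else {
    out$diagnosis <- .norm_diagnosis(ped[[6]])
  }
  out
}

.check_pedigree <- function(ped) {
  if (anyDuplicated(ped$individual_id)) {
    stop("duplicate individual id(s): ",
         paste(unique(ped$individual_id[duplicated(ped$individual_id)]),
               collapse = ", "))
  }
  for (col in c("father_id", "mother_id")) {
    p <- ped[[col]]
    declared <- p != "0"
    ok <- !declared | mapply(function(pid, fid) {
      i <- match(pid, ped$individual_id)
      !is.na(i) && ped$family_id[i] == fid
    }, p, ped$family_id)
    if (!all(ok)) {
      stop("dangling parent reference(s): ",
           paste(unique(p[!ok]), collapse = ", "),
           " (parents must resolve within the family or be the founder marker '0')")
    }
  }
  # no individual may be its own ancestor
  parent_of <- function(id) {
    i <- match(id, ped$individual_id)
    setdiff(c(ped$father_id[i], ped$mother_id[i]), "0")
  }
  for (id in ped$individual_id) {
    frontier <- parent_of(id)
    seen <- character()
    while (length(frontier)) {
      if (id %in% frontier) stop("pedigree cycle: ", id, " is its own ancestor")
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(lapply(frontier, parent_of))), seen)
    }
  }
  invisible(ped)
}

#' Assemble a cohort from pedigree, trait scores and instrument norms
#'
#' Joins the pedigree with per-individual trait scores, derives each scored
#' individual's trait subgroup via [assign_trait_group()] using the norms of
#' their instrument, and validates referential integrity (no duplicate ids,
#' parents resolve within the family, no pedigree cycles, every trait row
#' matches a pedigree member). Individuals with unknown diagnosis are
#' retained and reported via a message; families with fewer than three
#' diagnosed members raise a warning (they are kept, but are not "highly
#' multiplex").
#'
#' @param ped Path to a PED file or a data frame as returned by [read_ped()].
#' @param traits Optional path to a CSV/TSV file (or data frame) with columns
#'   `individual_id`, `instrument`, `score`.
#' @param norms Instrument norms: path or list accepted by
#'   [read_instrument_norms()]. Required when `traits` is given.
#' @param diagnosis_table Passed to [read_ped()] when `ped` is a path.
#' @return Data frame of class `fam_cohort` with one row per individual and
#'   columns `family_id`, `individual_id`, `father_id`, `mother_id`, `sex`,
#'   `diagnosis`, `trait_score`, `instrument`, `trait_group`.
#' @export
load_cohort <- function(ped, traits = NULL, norms = NULL, diagnosis_table = NULL) {
  if (is.character(ped)) ped <- read_ped(ped, diagnosis_table = diagnosis_table)
  .check_pedigree(ped)
  ped$trait_score <- NA_real_
  ped$instrument <- NA_character_
  if (!is.null(traits)) {
    if (is.character(traits)) {
      traits <- if (grepl("\\.csv(\\.gz)?$", traits)) {
        utils::read.csv(traits, stringsAsFactors = FALSE)
      } else {
        utils::read.delim(traits, stringsAsFactors = FALSE)
      }
    }
    need <- c("individual_id", "instrument", "score")
    if (!all(need %in% names(traits))) {
      stop("trait table must have columns: ", paste(need, collapse = ", "))
    }
    if (anyDuplicated(traits$individual_id)) {
      stop("duplicate trait rows for: ",
           paste(unique(traits$individual_id[duplicated(traits$individual_id)]),
                 collapse = ", "))
    }
    m <- match(traits$individual_id, ped$individual_id)
    if (anyNA(m)) {
      stop("trait rows for unknown individual(s): ",
           paste(traits$individual_id[is.na(m)], collapse = ", "))
    }
    norms <- read_instrument_norms(norms)
    missing_norm <- setdiff(unique(traits$instrument), names(norms))
    if (length(missing_norm)) {
      stop("no norms configured for instrument(s): ",
           paste(missing_norm, collapse = ", "))
    }
    ped$trait_score[m] <- as.numeric(traits$score)
    ped$instrument[m] <- traits$instrument
  }
  grp <- rep(NA_character_, nrow(ped))
  scored <- !is.na(ped$trait_score) & !is.na(ped$instrument)
  for (ins in unique(ped$instrument[scored])) {
    sel <- scored & ped$instrument == ins
    grp[sel] <- as.character(assign_trait_group(
      ped$trait_score[sel], norms[[ins]]$mean, norms[[ins]]$sd))
  }
  ped$trait_group <- trait_factor(grp)

  n_unknown <- sum(ped$diagnosis == "unknown")
  if (n_unknown > 0) {
    message(n_unknown, " individual(s) with unknown diagnosis retained")
  }
  fam <- .family_table(ped)
  if (any(!fam$highly_multiplex)) {
    warning("family(ies) with fewer than 3 diagnosed members: ",
            paste(fam$family_id[!fam$highly_multiplex], collapse = ", "),
            call. = FALSE)
  }
  class(ped) <- c("fam_cohort", "data.frame")
  ped
}

.family_table <- function(cohort) {
  sp <- split(cohort, cohort$family_id)
  out <- data.frame(
    family_id = names(sp),
    n_members = vapply(sp, nrow, 0L),
    n_diagnosed = vapply(sp, function(f) sum(f$diagnosis == "diagnosed"), 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$highly_multiplex <- out$n_diagnosed >= 3L
  out
}

#' Per-family summary of a cohort
#'
#' @param cohort A `fam_cohort` data frame from [load_cohort()].
#' @return Data frame with `family_id`, `n_members`, `n_diagnosed` and the
#'   `highly_multiplex` flag (TRUE iff at least three diagnosed members).
#' @export
family_table <- function(cohort) .family_table(cohort)

#' @export
print.fam_cohort <- function(x, ...) {
  fam <- .family_table(x)
  cat("fam_cohort:", nrow(x), "individuals in", nrow(fam), "families;",
      sum(x$diagnosis == "diagnosed"), "diagnosed,",
      sum(x$diagnosis == "suspected"), "suspected,",
      sum(!is.na(x$trait_score)), "with trait scores\n")
  invisible(x)
}

#' Enumerate genotyped parent-parent-child trios
#'
#' Returns one trio per child whose declared father and mother are both
#' cohort members and whose three members are all in `genotyped_ids`.
#' In three-generation pedigrees an individual can appear both as a child of
#' one trio and as a parent of another. Output order is deterministic
#' (family, then child id), and invariant under permutation of the cohort
#' rows.
#'
#' @param cohort A `fam_cohort` data frame.
#' @param genotyped_ids Character vector of individuals with genotype data;
#'   defaults to every cohort member. Must be nonempty.
#' @return Data frame with columns `family_id`, `child`, `father`, `mother`
#'   (possibly zero rows).
#' @export
enumerate_trios <- function(cohort, genotyped_ids = cohort$individual_id) {
  if (length(genotyped_ids) == 0) stop("genotyped_ids must be nonempty")
  keep <- cohort$father_id != "0" & cohort$mother_id != "0" &
    cohort$individual_id %in% genotyped_ids &
    cohort$father_id %in% genotyped_ids &
    cohort$mother_id %in% genotyped_ids &
    cohort$father_id %in% cohort$individual_id &
    cohort$mother_id %in% cohort$individual_id
  out <- data.frame(
    family_id = cohort$family_id[keep],
    child = cohort$individual_id[keep],
    father = cohort$father_id[keep],
    mother = cohort$mother_id[keep],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$family_id, out$child), , drop = FALSE]
  rownames(out) <- NULL
  out
}
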