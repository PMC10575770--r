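# Within-family segregation: diagnosis-based and trait-based prioritisation
# and the cross-family gene/approach summary.

#' Build a carrier set at one site
#'
#' Carriers are individuals with a het or hom-alt genotype passing the
#' read-support filter (hom-alt genotypes count as carriers: dominant-model
#' reading); non-carriers are read-support-passing hom-ref genotypes.
#' Individuals with missing genotypes, or calls failing read support,
#' belong to neither set -- but any non-missing het/hom-alt genotype is
#' recorded in `raw_carriers`, which the segregation rules use for their
#' "must be absent in ..." vetoes.
#'
#' @param ids Character vector of individual ids at the site.
#' @param gt,depth,alt_reads Parallel vectors of genotype class, depth and
#'   alternate reads (see [read_vcf()]).
#' @param cfg A [filter_config()].
#' @return List with `carriers`, `non_carriers`, `raw_carriers`.
#' @export
carrier_set <- function(ids, gt, depth, alt_reads, cfg = filter_config()) {
  pass <- passes_read_support(gt, depth, alt_reads, cfg)
  carrier_gt <- gt %in% c("het", "hom_alt")
  list(carriers = ids[carrier_gt & pass],
       non_carriers = ids[gt == "hom_ref" & pass],
       raw_carriers = ids[carrier_gt])
}

#' Diagnosis-based segregation rule
#'
#' A variant segregates with diagnosis in a family iff (1) it is shared by
#' at least two diagnosed members, and (2) no non-autistic member carries
#' it. Suspected-diagnosis and unknown-diagnosis individuals neither count
#' toward the two required diagnosed carriers nor veto: the rule's "not
#' autistic" set is strictly `non_autistic`.
#'
#' @param cs Carrier set from [carrier_set()].
#' @param family Data frame of the family's members with columns
#'   `individual_id` and `diagnosis`.
#' @param cfg A [filter_config()]; `veto_on_raw_genotype` selects whether
#'   the absence requirement inspects raw carriers or only
#'   read-support-passing carriers.
#' @return `TRUE` or `FALSE`.
#' @export
diagnosis_segregation <- function(cs, family, cfg = filter_config()) {
  diagnosed <- family$individual_id[family$diagnosis == "diagnosed"]
  non_autistic <- family$individual_id[family$diagnosis == "non_autistic"]
  veto <- if (cfg$veto_on_raw_genotype) cs$raw_carriers else cs$carriers
  sum(cs$carriers %in% diagnosed) >= 2 && !any(veto %in% non_autistic)
}

#' Trait-based segregation rule
#'
#' Assigns the most specific trait level a variant segregates with: a BAP
#' variant may be carried by BAP, MAP and NAP members, a MAP variant only by
#' MAP and NAP members, and a NAP variant only by NAP members; in every case
#' at least two carriers in the level or above are required and the variant
#' must be absent from everyone else. Equivalently the assigned level is the
#' minimum trait group over the variant's carriers, provided that minimum is
#' at least BAP and at least two read-support-passing scored carriers exist.
#' Unscored individuals neither count toward the carrier quota nor veto.
#'
#' @inheritParams diagnosis_segregation
#' @param family Data frame with columns `individual_id` and `trait_group`
#'   (ordered factor from [trait_factor()], `NA` for unscored members).
#' @return One of `"BAP"`, `"MAP"`, `"NAP"`, or `"none"`.
#' @export
trait_segregation <- function(cs, family, cfg = filter_config()) {
  grp <- setNames(as.character(family$trait_group), family$individual_id)
  veto_ids <- if (cfg$veto_on_raw_genotype) cs$raw_carriers else cs$carriers
  veto_grp <- grp[veto_ids]
  veto_grp <- veto_grp[!is.na(veto_grp)]
  if (any(veto_grp == "AVERAGE")) return("none")
  pass_grp <- grp[cs$carriers]
  pass_grp <- pass_grp[!is.na(pass_grp)]
  if (length(pass_grp) < 2) return("none")
  lev <- as.character(min(trait_factor(c(veto_grp, pass_grp))))
  if (lev == "AVERAGE") "none" else lev
}

.make_label <- function(trait_level, diagnosis_hit) {
  parts <- character()
  if (!is.na(trait_level) && trait_level != "none") parts <- trait_level
  if (isTRUE(diagnosis_hit)) parts <- c(parts, "Diagnosis")
  paste(parts, collapse = "/")
}

#' Parse trait/diagnosis labels
#'
#' Splits report labels such as `"NAP/Diagnosis"`, `"MAP"` or `"Diagnosis"`
#' into their trait-level and diagnosis components.
#'
#' @param label Character vector of labels.
#' @return Data frame with columns `trait_level` (`"none"` when absent) and
#'   `diagnosis_hit`.
#' @export
parse_label <- function(label) {
  parts <- strsplit(label, "/", fixed = TRUE)
  trait <- vapply(parts, function(p) {
    lv <- intersect(p, c("BAP", "MAP", "NAP"))
    if (length(lv)) lv[[1]] else "none"
  }, "")
  data.frame(trait_level = trait,
             diagnosis_hit = vapply(parts, function(p) "Diagnosis" %in% p, TRUE),
             stringsAsFactors = FALSE)
}

.empty_prioritised <- function() {
  data.frame(gene = character(), origin = character(), family = character(),
             trait_level = character(), diagnosis_hit = logical(),
             label = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), aa_change = character(),
             dbsnp = character(), maf_nfe = numeric(), sift = character(),
             polyphen = character(), carriers = character(),
             stringsAsFactors = FALSE)
}

#' Prioritise variants within one family
#'
#' Applies, independently of every other family, the full inherited-variant
#' prioritisation: keep sites that are rare and damaging
#' ([is_rare_damaging()]) in constrained genes ([is_constrained()]), build
#' the family's carrier set at each, and emit the variant when the
#' diagnosis rule and/or the trait rule fires for the requested mode.
#'
#' @param family Data frame of one family's cohort rows (subset of a
#'   `fam_cohort`).
#' @param geno `fam_geno` genotypes from [read_vcf()] (any superset of the
#'   family's samples).
#' @param ann Annotation data frame from [read_annotation_table()]; joined
#'   to genotype sites by exact `(chrom, pos, ref, alt)` match, with a
#'   message counting unmatched genotype sites.
#' @param constraint Constraint table from [read_constraint_table()].
#' @param cfg A [filter_config()].
#' @param mode `"both"` (default), `"diagnosis"` or `"trait"`.
#' @return Data frame of prioritised variants (possibly empty) with columns
#'   `gene`, `origin`, `family`, `trait_level`, `diagnosis_hit`, `label`,
#'   site and annotation fields, and the comma-separated carrier ids.
#' @export
prioritise_family <- function(family, geno, ann, constraint,
                              cfg = filter_config(),
                              mode = c("both", "diagnosis", "trait")) {
  mode <- match.arg(mode)
  members <- intersect(geno$samples, family$individual_id)
  out <- .empty_prioritised()
  if (length(members) == 0) return(out)

  if (mode %in% c("both", "diagnosis")) {
    n_dx <- sum(family$diagnosis[family$individual_id %in% members] ==
                  "diagnosed")
    if (n_dx < 2) {
      warning("family ", family$family_id[1], ": fewer than 2 diagnosed ",
              "genotyped members; diagnosis rule cannot fire", call. = FALSE)
      if (mode == "diagnosis") return(out)
    }
  }

  m <- match(geno$sites$key, ann$key)
  n_drop <- sum(is.na(m))
  if (n_drop > 0) {
    message(n_drop, " genotype site(s) without annotation dropped")
  }
  keep_site <- which(!is.na(m))
  ann_m <- ann[m[keep_site], , drop = FALSE]
  eligible <- is_rare_damaging(ann_m, cfg, context = "inherited") &
    is_constrained(ann_m$gene, constraint, cfg)
  keep_site <- keep_site[eligible]
  ann_m <- ann_m[eligible, , drop = FALSE]

  rows <- vector("list", length(keep_site))
  for (j in seq_along(keep_site)) {
    k <- keep_site[j]
    cs <- carrier_set(members,
                      geno$gt[k, members],
                      geno$depth[k, members],
                      geno$alt_reads[k, members], cfg)
    dx <- if (mode %in% c("both", "diagnosis")) {
      diagnosis_segregation(cs, family, cfg)
    } else FALSE
    lvl <- if (mode %in% c("both", "trait")) {
      trait_segregation(cs, family, cfg)
    } else "none"
    if (!dx && lvl == "none") next
    a <- ann_m[j, ]
    rows[[j]] <- data.frame(
      gene = a$gene, origin = "inherited", family = family$family_id[1],
      trait_level = lvl, diagnosis_hit = dx, label = .make_label(lvl, dx),
      chrom = a$chrom, pos = a$pos, ref = a$ref, alt = a$alt,
      aa_change = a$aa_change, dbsnp = a$dbsnp, maf_nfe = a$maf_nfe,
      sift = a$sift, polyphen = a$polyphen_hdiv,
      carriers = paste(sort(cs$carriers), collapse = ","),
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows)) rbind(out, do.call(rbind, rows)) else out
}

#' Prioritise variants across all families
#'
#' Runs [prioritise_family()] on every family of the cohort; families are
#' processed independently and the cohort result is the concatenation of
#' the per-family results (ordered by family id).
#'
#' @param cohort A `fam_cohort` data frame.
#' @inheritParams prioritise_family
#' @return Data frame of prioritised variants across families.
#' @export
prioritise_cohort <- function(cohort, geno, ann, constraint,
                              cfg = filter_config(),
                              mode = c("both", "diagnosis", "trait")) {
  mode <- match.arg(mode)
  fams <- split(as.data.frame(cohort), cohort$family_id)
  res <- lapply(fams[sort(names(fams))], prioritise_family,
                geno = geno, ann = ann, constraint = constraint,
                cfg = cfg, mode = mode)
  out <- do.call(rbind, c(res, list(.empty_prioritised())))
  rownames(out) <- NULL
  out
}

#' Cross-family gene summary and approach Venn counts
#'
#' Collapses prioritised variants (inherited and/or de novo) to one row per
#' distinct gene, recording the families it was hit in, its best (highest)
#' trait level, and the approach that implicated it: `trait_only`,
#' `diagnosis_only`, or `both` when the gene has at least one trait-labelled
#' and at least one diagnosis-labelled variant anywhere in the cohort. The
#' Venn counts are over distinct genes (a gene hit in several families
#' counts once).
#'
#' @param prioritised Data frame with columns `gene`, `family` and either
#'   (`trait_level`, `diagnosis_hit`) or a `label` column to parse; a `tier`
#'   column is carried through when present.
#' @return List with `genes` (one row per gene: `gene`, `families`,
#'   `n_variants`, `approach`, `best_trait_level`, and `tier` if supplied)
#'   and `venn` (named counts `both`, `trait_only`, `diagnosis_only`).
#' @export
summarise_genes <- function(prioritised) {
  x <- prioritised
  if (is.null(x$trait_level) || is.null(x$diagnosis_hit)) {
    pl <- parse_label(x$label)
    x$trait_level <- pl$trait_level
    x$diagnosis_hit <- pl$diagnosis_hit
  }
  if (nrow(x) == 0) {
    return(list(
      genes = data.frame(gene = character(), families = character(),
                         n_variants = integer(), approach = character(),
                         best_trait_level = character(),
                         stringsAsFactors = FALSE),
      venn = c(both = 0L, trait_only = 0L, diagnosis_only = 0L)))
  }
  sp <- split(x, x$gene)
  genes <- do.call(rbind, lapply(sp, function(g) {
    has_trait <- any(g$trait_level != "none")
    has_dx <- any(g$diagnosis_hit)
    lv <- g$trait_level[g$trait_level != "none"]
    data.frame(
      gene = g$gene[1],
      families = paste(sort(unique(g$family)), collapse = ","),
      n_variants = nrow(g),
      approach = if (has_trait && has_dx) "both"
                 else if (has_trait) "trait_only" else "diagnosis_only",
      best_trait_level = if (length(lv))
        as.character(max(trait_factor(lv))) else "none",
      tier = if (!is.null(g$tier)) suppressWarnings(min(g$tier, na.rm = TRUE))
             else NA_integer_,
      stringsAsFactors = FALSE)
  }))
  genes <- genes[order(genes$gene), , drop = FALSE]
  rownames(genes) <- NULL
  if (is.null(x$tier)) {
    genes$tier <- NULL
  } else {
    genes$tier[!is.finite(genes$tier)] <- NA
  }
  venn <- c(both = sum(genes$approach == "both"),
            trait_only = sum(genes$approach == "trait_only"),
            diagnosis_only = sum(genes$approach == "diagnosis_only"))
  list(genes = genes, venn = venn)
}
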