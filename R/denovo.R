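# Five-criterion trio de novo filter over jointly represented trio
# genotypes. Upstream trio calling (e.g. VarScan2's trio mode) is assumed
# looser than these criteria, so applying them to jointly genotyped sites
# from any caller reproduces the filter's intent.

#' Assemble per-trio read evidence at every site
#'
#' @param trios Data frame from [enumerate_trios()].
#' @param geno `fam_geno` object from [read_vcf()]. Trios with a member
#'   absent from the genotype samples are skipped with a warning.
#' @return Data frame with one row per (trio, site): ids, site fields and
#'   `child_gt`, `child_depth`, `child_alt`, `father_depth`, `father_alt`,
#'   `mother_depth`, `mother_alt`.
#' @export
trio_site_evidence <- function(trios, geno) {
  keep <- trios$child %in% geno$samples &
    trios$father %in% geno$samples & trios$mother %in% geno$samples
  if (any(!keep)) {
    warning("skipping ", sum(!keep), " trio(s) with members missing from ",
            "the genotype data", call. = FALSE)
    trios <- trios[keep, , drop = FALSE]
  }
  n_site <- nrow(geno$sites)
  out <- lapply(seq_len(nrow(trios)), function(i) {
    tr <- trios[i, ]
    data.frame(
      family_id = tr$family_id, child = tr$child, father = tr$father,
      mother = tr$mother,
      geno$sites,
      child_gt = geno$gt[, tr$child],
      child_depth = geno$depth[, tr$child],
      child_alt = geno$alt_reads[, tr$child],
      father_depth = geno$depth[, tr$father],
      father_alt = geno$alt_reads[, tr$father],
      mother_depth = geno$depth[, tr$mother],
      mother_alt = geno$alt_reads[, tr$mother],
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(NULL)))
  if (is.null(res)) {
    res <- cbind(data.frame(family_id = character(), child = character(),
                            father = character(), mother = character(),
                            stringsAsFactors = FALSE),
                 geno$sites[0, ],
                 data.frame(child_gt = character(),
                            child_depth = numeric(), child_alt = numeric(),
                            father_depth = numeric(), father_alt = numeric(),
                            mother_depth = numeric(), mother_alt = numeric()))
  }
  rownames(res) <- NULL
  res
}

#' De novo candidate predicate
#'
#' Applies the five trio criteria to each evidence row: (1) read depth
#' strictly greater than `dn_min_depth` in child, father and mother;
#' (2) child alternate reads at least `dn_min_child_alt`; (3) heterozygous
#' de novo status in the child -- the genotype call must be het when
#' available (otherwise the alternate fraction window stands in) -- with
#' child alternate fraction above `dn_min_child_af` and the variant absent
#' in each parent (per-parent alternate fraction below `dn_max_parent_af`);
#' (4) gnomAD NFE frequency at most `dn_maf_threshold` or absent;
#' (5) a disruptive class: damaging missense (SIFT `D`, PolyPhen-2 `D`/`P`),
#' frameshift indel, stop gain/loss, or splicing. Candidate genes must
#' additionally have pLI at least `dn_pli_threshold`; a gene absent from
#' the constraint table fails that gate. Missing read evidence fails
#' closed. The decision is symmetric in the two parents.
#'
#' @param evidence Data frame with the read-evidence columns of
#'   [trio_site_evidence()] plus annotation columns `gene`, `func_class`,
#'   `maf_nfe`, `sift`, `polyphen_hdiv`.
#' @param constraint Constraint table from [read_constraint_table()].
#' @param cfg A [filter_config()].
#' @return Logical vector, one element per evidence row.
#' @export
is_de_novo_candidate <- function(evidence, constraint,
                                 cfg = filter_config()) {
  e <- evidence
  num <- function(x) ifelse(is.na(x), -Inf, x)
  depth_ok <- num(e$child_depth) > cfg$dn_min_depth &
    num(e$father_depth) > cfg$dn_min_depth &
    num(e$mother_depth) > cfg$dn_min_depth
  child_alt_ok <- num(e$child_alt) >= cfg$dn_min_child_alt
  child_af <- ifelse(is.na(e$child_alt) | is.na(e$child_depth) |
                       e$child_depth == 0, -Inf, e$child_alt / e$child_depth)
  het_ok <- if (!is.null(e$child_gt)) {
    ifelse(e$child_gt == "missing" | is.na(e$child_gt),
           child_af > cfg$dn_min_child_af, e$child_gt == "het")
  } else rep(TRUE, nrow(e))
  parent_af <- function(alt, depth) {
    ifelse(is.na(alt) | is.na(depth) | depth == 0, Inf, alt / depth)
  }
  parents_absent <-
    parent_af(e$father_alt, e$father_depth) < cfg$dn_max_parent_af &
    parent_af(e$mother_alt, e$mother_depth) < cfg$dn_max_parent_af
  damaging <- is_rare_damaging(
    data.frame(func_class = e$func_class, maf_nfe = e$maf_nfe,
               sift = e$sift, polyphen_hdiv = e$polyphen_hdiv,
               stringsAsFactors = FALSE),
    cfg, context = "de_novo")
  m <- match(toupper(e$gene), toupper(constraint$gene))
  pli <- constraint$pli[m]
  pli_ok <- !is.na(pli) & pli >= cfg$dn_pli_threshold
  if (any(is.na(m))) {
    message(sum(is.na(m)), " evidence row(s) with gene absent from the ",
            "constraint table fail the pLI gate")
  }
  depth_ok & child_alt_ok & child_af > cfg$dn_min_child_af & het_ok &
    parents_absent & damaging & pli_ok
}

#' Scan trios for de novo candidates
#'
#' Joins annotations onto the genotype sites, evaluates
#' [is_de_novo_candidate()] for every (trio, site) pair, and returns the
#' candidates in deterministic order (family, child, chrom, pos).
#'
#' @param trios Data frame from [enumerate_trios()].
#' @param geno `fam_geno` object from [read_vcf()].
#' @param ann Annotation table from [read_annotation_table()].
#' @param constraint Constraint table from [read_constraint_table()].
#' @param cfg A [filter_config()].
#' @return Data frame of candidates: trio ids, site, gene, annotation
#'   fields, read evidence and child alternate fraction.
#' @export
scan_trios <- function(trios, geno, ann, constraint,
                       cfg = filter_config()) {
  ev <- trio_site_evidence(trios, geno)
  m <- match(ev$key, ann$key)
  ev$gene <- ann$gene[m]
  ev$func_class <- ann$func_class[m]
  ev$maf_nfe <- ann$maf_nfe[m]
  ev$sift <- ann$sift[m]
  ev$polyphen_hdiv <- ann$polyphen_hdiv[m]
  ev$aa_change <- ann$aa_change[m]
  ev$dbsnp <- ann$dbsnp[m]
  ev <- ev[!is.na(m), , drop = FALSE]
  if (nrow(ev) == 0) return(ev)
  hit <- is_de_novo_candidate(ev, constraint, cfg)
  out <- ev[hit, , drop = FALSE]
  out <- out[order(out$family_id, out$child, out$chrom, out$pos), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Format de novo candidates as report rows
#'
#' Labels each candidate with the carrier child's trait group and diagnosis
#' (`"BAP/Diagnosis"` style) and reshapes to the [write_report()] schema
#' with `origin = "de_novo"`.
#'
#' @param candidates Data frame from [scan_trios()].
#' @param cohort A `fam_cohort` data frame (for the child's phenotype).
#' @return Data frame in the prioritised-variant schema.
#' @export
denovo_report_rows <- function(candidates, cohort) {
  if (nrow(candidates) == 0) return(.empty_prioritised())
  m <- match(candidates$child, cohort$individual_id)
  lvl <- as.character(cohort$trait_group[m])
  lvl[is.na(lvl) | lvl == "AVERAGE"] <- "none"
  dx <- cohort$diagnosis[m] == "diagnosed"
  data.frame(
    gene = candidates$gene, origin = "de_novo",
    family = candidates$family_id, trait_level = lvl, diagnosis_hit = dx,
    label = mapply(.make_label, lvl, dx, USE.NAMES = FALSE),
    chrom = candidates$chrom, pos = candidates$pos,
    ref = candidates$ref, alt = candidates$alt,
    aa_change = candidates$aa_change, dbsnp = candidates$dbsnp,
    maf_nfe = candidates$maf_nfe, sift = candidates$sift,
    polyphen = candidates$polyphen_hdiv, carriers = candidates$child,
    stringsAsFactors = FALSE)
}
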