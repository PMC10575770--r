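# Variant-level and gene-level eligibility filters applied before
# segregation and de novo analysis.

#' Filter configuration
#'
#' Collects every tunable threshold of the variant-level, gene-level and
#' trio de novo filters.
#'
#' Defaults follow the pipeline's published operating point: inherited
#' variants must be rare (gnomAD NFE MAF < 1%), supported by at least 10
#' reads with heterozygotes showing at least 33% alternate reads, and fall
#' in constrained genes (pLI >= 0.9 or LOEUF < 0.37). The de novo filter is
#' stricter: depth > 20 in all trio members, child alternate reads >= 8 with
#' alternate fraction > 40%, each parent's alternate fraction < 5%, MAF
#' <= 1% (note `<=`, unlike the inherited `<`), and pLI >= 0.9. Splicing
#' variants qualify only on the de novo side unless
#' `splicing_in_inherited = TRUE`. A variant with no NFE frequency passes
#' the frequency gate when `missing_maf_is_rare` (absence from gnomAD must
#' not disqualify ultra-rare variants).
#'
#' @param maf_threshold Inherited-filter NFE frequency bound (strict `<`).
#' @param min_depth Minimum supporting reads per genotype call.
#' @param min_het_alt_fraction Minimum alternate-read fraction for
#'   heterozygous calls.
#' @param pli_threshold pLI bound, compared with `>=`.
#' @param loeuf_threshold LOEUF bound (first decile), compared with `<`.
#' @param constraint_mode How pLI and LOEUF combine: `"union"` (default,
#'   either metric suffices), `"intersection"`, `"pli_only"`, `"loeuf_only"`.
#' @param missing_maf_is_rare Treat absent NFE frequency as rare.
#' @param splicing_in_inherited Let splicing variants qualify in the
#'   inherited filter too.
#' @param veto_on_raw_genotype Segregation "absent in ..." rules veto on any
#'   non-missing carrier genotype, not only read-support-passing ones.
#' @param dn_min_depth De novo: depth must exceed this in all three samples
#'   (strict `>`).
#' @param dn_min_child_alt De novo: minimum child alternate reads (`>=`).
#' @param dn_min_child_af De novo: child alternate fraction bound
#'   (strict `>`).
#' @param dn_max_parent_af De novo: per-parent alternate fraction bound
#'   (strict `<`).
#' @param dn_maf_threshold De novo NFE frequency bound (`<=`).
#' @param dn_pli_threshold De novo pLI gate (`>=`).
#' @return List of class `famseg_filters`.
#' @export
filter_config <- function(maf_threshold = 0.01,
                          min_depth = 10,
                          min_het_alt_fraction = 0.33,
                          pli_threshold = 0.9,
                          loeuf_threshold = 0.37,
                          constraint_mode = c("union", "intersection",
                                              "pli_only", "loeuf_only"),
                          missing_maf_is_rare = TRUE,
                          splicing_in_inherited = FALSE,
                          veto_on_raw_genotype = TRUE,
                          dn_min_depth = 20,
                          dn_min_child_alt = 8,
                          dn_min_child_af = 0.40,
                          dn_max_parent_af = 0.05,
                          dn_maf_threshold = 0.01,
                          dn_pli_threshold = 0.9) {
  constraint_mode <- match.arg(constraint_mode)
  stopifnot(maf_threshold >= 0, maf_threshold <= 1,
            min_depth >= 0, min_het_alt_fraction >= 0,
            min_het_alt_fraction <= 1,
            pli_threshold >= 0, pli_threshold <= 1, loeuf_threshold >= 0,
            dn_min_depth >= 0, dn_min_child_alt >= 0,
            dn_min_child_af >= 0, dn_min_child_af <= 1,
            dn_max_parent_af >= 0, dn_max_parent_af <= 1,
            dn_maf_threshold >= 0, dn_maf_threshold <= 1,
            dn_pli_threshold >= 0, dn_pli_threshold <= 1)
  structure(list(
    maf_threshold = maf_threshold, min_depth = min_depth,
    min_het_alt_fraction = min_het_alt_fraction,
    pli_threshold = pli_threshold, loeuf_threshold = loeuf_threshold,
    constraint_mode = constraint_mode,
    missing_maf_is_rare = missing_maf_is_rare,
    splicing_in_inherited = splicing_in_inherited,
    veto_on_raw_genotype = veto_on_raw_genotype,
    dn_min_depth = dn_min_depth, dn_min_child_alt = dn_min_child_alt,
    dn_min_child_af = dn_min_child_af, dn_max_parent_af = dn_max_parent_af,
    dn_maf_threshold = dn_maf_threshold, dn_pli_threshold = dn_pli_threshold
  ), class = "famseg_filters")
}

#' Read-support filter for genotype calls
#'
#' A call passes when its depth reaches `min_depth` and, for heterozygous
#' calls, at least `min_het_alt_fraction` of reads carry the alternate
#' allele. Missing depth (or missing alternate count for a het call) fails
#' closed.
#'
#' @param gt Character vector of genotype classes (`hom_ref`, `het`,
#'   `hom_alt`, `missing`).
#' @param depth,alt_reads Numeric vectors of total and alternate-allele
#'   read counts.
#' @param cfg A [filter_config()].
#' @return Logical vector.
#' @export
passes_read_support <- function(gt, depth, alt_reads,
                                cfg = filter_config()) {
  depth_ok <- !is.na(depth) & depth >= cfg$min_depth
  het <- gt == "het"
  frac_ok <- !het |
    (!is.na(alt_reads) & !is.na(depth) & depth > 0 &
       alt_reads / depth >= cfg$min_het_alt_fraction)
  called <- gt %in% c("hom_ref", "het", "hom_alt")
  called & depth_ok & frac_ok
}

#' Rare-damaging variant filter
#'
#' A variant qualifies when it passes the population-frequency gate and its
#' functional class is disruptive. Stop-gain/loss and frameshift indels
#' always qualify; missense (`nonsynonymous_snv`) qualifies only when SIFT
#' calls it deleterious (`D`) and PolyPhen-2 HDIV calls it at least possibly
#' damaging (`D` or `P`); synonymous and `other` never qualify. Splicing
#' qualifies in the de novo context (and in the inherited context only when
#' configured). The frequency gate is `maf < maf_threshold` for inherited
#' variants, `maf <= dn_maf_threshold` for de novo candidates; an absent
#' frequency passes iff `missing_maf_is_rare`.
#'
#' @param ann Data frame with columns `func_class`, `maf_nfe`, `sift`,
#'   `polyphen_hdiv` (e.g. from [read_annotation_table()]).
#' @param cfg A [filter_config()].
#' @param context `"inherited"` or `"de_novo"`.
#' @return Logical vector, one element per annotation row.
#' @export
is_rare_damaging <- function(ann, cfg = filter_config(),
                             context = c("inherited", "de_novo")) {
  context <- match.arg(context)
  maf <- ann$maf_nfe
  rare <- if (context == "inherited") {
    !is.na(maf) & maf < cfg$maf_threshold
  } else {
    !is.na(maf) & maf <= cfg$dn_maf_threshold
  }
  rare <- rare | (is.na(maf) & cfg$missing_maf_is_rare)

  fc <- ann$func_class
  always <- fc %in% c("stopgain", "stoploss",
                      "frameshift_insertion", "frameshift_deletion")
  missense <- fc == "nonsynonymous_snv" &
    !is.na(ann$sift) & ann$sift == "D" &
    !is.na(ann$polyphen_hdiv) & ann$polyphen_hdiv %in% c("D", "P")
  splice_ok <- fc == "splicing" &
    (context == "de_novo" | cfg$splicing_in_inherited)
  rare & (always | missense | splice_ok)
}

#' Gene-constraint filter
#'
#' Decides gene eligibility from pLI and LOEUF. Under the default `union`
#' mode a gene passes when pLI >= `pli_threshold` or LOEUF <
#' `loeuf_threshold`; `intersection` requires both, and the single-metric
#' modes consult one score only. A gene absent from the constraint table
#' (or with the relevant score absent) fails.
#'
#' @param gene Character vector of gene symbols.
#' @param constraint Data frame `gene`, `pli`, `loeuf`
#'   (see [read_constraint_table()]).
#' @param cfg A [filter_config()].
#' @return Logical vector, one element per gene.
#' @export
is_constrained <- function(gene, constraint, cfg = filter_config()) {
  m <- match(toupper(gene), toupper(constraint$gene))
  pli <- constraint$pli[m]
  loeuf <- constraint$loeuf[m]
  pli_ok <- !is.na(pli) & pli >= cfg$pli_threshold
  loeuf_ok <- !is.na(loeuf) & loeuf < cfg$loeuf_threshold
  switch(cfg$constraint_mode,
         union = pli_ok | loeuf_ok,
         intersection = pli_ok & loeuf_ok,
         pli_only = pli_ok,
         loeuf_only = loeuf_ok)
}
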