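# End-to-end orchestration: load -> filter -> segregate -> de novo ->
# tiers -> summarise -> enrich, with a run manifest of per-stage counts.

#' Run the full prioritisation pipeline
#'
#' Loads the cohort and variant data, prioritises inherited variants per
#' family ([prioritise_cohort()]), scans trios for de novo candidates
#' ([scan_trios()]), annotates evidence tiers, summarises genes and
#' approach Venn counts, and runs the Tier-1 carrier enrichment test.
#' Every input may be given as a file path or as the corresponding
#' in-memory object. All analysis stages are deterministic; randomness
#' lives only in [simulate_cohort()].
#'
#' When `out_dir` is given, writes `report.tsv` (the [write_report()]
#' format), `gene_summary.tsv`, `venn.json`, `enrichment.json` and
#' `manifest.json`.
#'
#' @param ped PED path or cohort data frame accepted by [load_cohort()].
#' @param traits Trait-score table path or data frame.
#' @param norms Instrument norms (path or list).
#' @param vcf VCF path or a `fam_geno` object.
#' @param annotations Annotation table path or data frame.
#' @param constraint Constraint table path or data frame.
#' @param tiers Tier-source YAML path or [tier_sources()] object (optional;
#'   without it genes are untiered and no enrichment test is run).
#' @param out_dir Optional output directory.
#' @param cfg A [filter_config()].
#' @param mode Segregation mode: `"both"`, `"diagnosis"` or `"trait"`.
#' @return List with `report` (all prioritised variants), `genes`, `venn`,
#'   `trait_distribution`, `enrichment` (a `contingency_result` or `NULL`)
#'   and `manifest`.
#' @export
run_all <- function(ped, traits = NULL, norms = NULL, vcf, annotations,
                    constraint, tiers = NULL, out_dir = NULL,
                    cfg = filter_config(),
                    mode = c("both", "diagnosis", "trait")) {
  mode <- match.arg(mode)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", what, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cohort <- stage("load_cohort", {
    if (is.data.frame(ped) && inherits(ped, "fam_cohort")) ped
    else load_cohort(ped, traits, norms)
  })
  geno <- stage("read_vcf",
                if (inherits(vcf, "fam_geno")) vcf else read_vcf(vcf))
  ann <- stage("read_annotation",
               if (is.data.frame(annotations)) annotations
               else read_annotation_table(annotations))
  constraint <- stage("read_constraint",
                      if (is.data.frame(constraint)) constraint
                      else read_constraint_table(constraint))
  tiers <- stage("read_tiers", {
    if (is.null(tiers) || inherits(tiers, "tier_sources")) tiers
    else read_tier_sources(tiers)
  })

  matched <- geno$sites$key %in% ann$key
  ann_m <- ann[match(geno$sites$key[matched], ann$key), , drop = FALSE]
  rare <- is_rare_damaging(ann_m, cfg, context = "inherited")
  eligible <- rare & is_constrained(ann_m$gene, constraint, cfg)

  inherited <- stage("segregation",
                     prioritise_cohort(cohort, geno, ann, constraint, cfg,
                                       mode = mode))
  trios <- enumerate_trios(cohort, genotyped_ids = geno$samples)
  denovo <- stage("de_novo", {
    if (nrow(trios)) scan_trios(trios, geno, ann, constraint, cfg)
    else NULL
  })
  dn_rows <- if (!is.null(denovo)) denovo_report_rows(denovo, cohort)
             else .empty_prioritised()
  report <- rbind(inherited, dn_rows)

  if (!is.null(tiers)) report <- annotate_tiers(report, tiers)
  summ <- stage("summarise", summarise_genes(report))
  trait_dist <- if (!is.null(tiers)) tier1_trait_distribution(report)
                else NULL
  enrich <- NULL
  if (!is.null(tiers) && nrow(report)) {
    st <- tier1_carrier_status(cohort, report)
    tab <- carrier_contingency(st$diagnosis, st$tier1_carrier)
    enrich <- tryCatch(
      chi_square_2x2(tab[["a"]], tab[["b"]], tab[["c"]], tab[["d"]]),
      error = function(e) {
        message("enrichment test skipped: ", conditionMessage(e))
        NULL
      })
  }

  manifest <- list(
    n_individuals = nrow(cohort),
    n_families = length(unique(cohort$family_id)),
    n_diagnosed = sum(cohort$diagnosis == "diagnosed"),
    n_samples = length(geno$samples),
    n_trios = nrow(trios),
    funnel = list(
      n_sites = nrow(geno$sites),
      n_annotated = sum(matched),
      n_rare_damaging = sum(rare),
      n_eligible_constrained = sum(eligible),
      n_prioritised_inherited = nrow(inherited),
      n_denovo_candidates = if (is.null(denovo)) 0L else nrow(denovo)),
    venn = as.list(summ$venn),
    mode = mode,
    config = unclass(cfg))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(out_dir, "report.tsv"))
    utils::write.table(summ$genes, file.path(out_dir, "gene_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = ".")
    jsonlite::write_json(as.list(summ$venn), file.path(out_dir, "venn.json"),
                         auto_unbox = TRUE)
    if (!is.null(enrich)) {
      jsonlite::write_json(
        list(a = enrich$table[1, 1], b = enrich$table[1, 2],
             c = enrich$table[2, 1], d = enrich$table[2, 2],
             chi2 = enrich$chi2, df = enrich$df, p = enrich$p),
        file.path(out_dir, "enrichment.json"), auto_unbox = TRUE,
        digits = NA)
    }
    cfg_file <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, cfg_file, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  list(report = report, genes = summ$genes, venn = summ$venn,
       trait_distribution = trait_dist, enrichment = enrich,
       manifest = manifest)
}
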