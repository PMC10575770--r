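# Shared builders and independent oracles used across the test files.

# --- tiny pedigree / cohort builders -------------------------------------

make_family <- function(ids, diagnosis, trait_group = NULL,
                        family_id = "fam1") {
  data.frame(
    family_id = family_id, individual_id = ids,
    father_id = "0", mother_id = "0",
    sex = "unknown", diagnosis = diagnosis,
    trait_score = NA_real_, instrument = NA_character_,
    trait_group = trait_factor(
      if (is.null(trait_group)) rep(NA_character_, length(ids))
      else trait_group),
    stringsAsFactors = FALSE)
}

make_carrier_set <- function(carriers, all_ids) {
  list(carriers = carriers,
       non_carriers = setdiff(all_ids, carriers),
       raw_carriers = carriers)
}

# fam_geno object built directly from a genotype-class matrix
make_geno <- function(sites, gt, depth = NULL, alt = NULL) {
  ids <- colnames(gt)
  if (is.null(depth)) depth <- matrix(30, nrow(gt), ncol(gt),
                                      dimnames = dimnames(gt))
  if (is.null(alt)) {
    alt <- matrix(0, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    alt[gt == "het"] <- 15
    alt[gt == "hom_alt"] <- 30
  }
  sites$key <- site_key(sites$chrom, sites$pos, sites$ref, sites$alt)
  structure(list(sites = sites, samples = ids, gt = gt,
                 depth = depth, alt_reads = alt), class = "fam_geno")
}

write_tiny_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

# --- independent oracles --------------------------------------------------

# Literal restatement of the diagnosis rule: shared by >= 2 diagnosed
# members and absent from every non-autistic member.
oracle_diagnosis <- function(carriers, family) {
  diagnosed <- family$individual_id[family$diagnosis == "diagnosed"]
  non_autistic <- family$individual_id[family$diagnosis == "non_autistic"]
  length(intersect(carriers, diagnosed)) >= 2 &&
    length(intersect(carriers, non_autistic)) == 0
}

# Literal restatement of the trait rules, walked from the most specific
# band down: a level-L variant is carried only by members of level L or
# above, by at least two scored individuals; unscored carriers are ignored.
oracle_trait <- function(carriers, family) {
  grp <- setNames(as.character(family$trait_group), family$individual_id)
  g <- grp[carriers]
  g <- g[!is.na(g)]
  for (lv in c("NAP", "MAP", "BAP")) {
    allowed <- .TRAIT_ORACLE_ALLOWED[[lv]]
    if (length(g) >= 2 && all(g %in% allowed)) return(lv)
  }
  "none"
}
.TRAIT_ORACLE_ALLOWED <- list(NAP = "NAP", MAP = c("MAP", "NAP"),
                              BAP = c("BAP", "MAP", "NAP"))

# all subsets of a character vector
all_subsets <- function(ids) {
  unlist(lapply(0:length(ids), function(k)
    combn(ids, k, simplify = FALSE)), recursive = FALSE)
}
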