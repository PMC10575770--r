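# Readers and writers for the formats the pipeline touches: multi-sample
# VCF, Annovar-style annotation tables, constraint tables, gene lists, and
# the prioritisation report.

.FUNC_CLASSES <- c("nonsynonymous_snv", "stopgain", "stoploss",
                   "frameshift_insertion", "frameshift_deletion",
                   "splicing", "synonymous", "other")

.FUNC_MAP <- c(
  "nonsynonymous snv" = "nonsynonymous_snv",
  "nonsynonymous_snv" = "nonsynonymous_snv",
  "missense" = "nonsynonymous_snv",
  "stopgain" = "stopgain", "stop-gain" = "stopgain", "stop gain" = "stopgain",
  "stoploss" = "stoploss", "stop-loss" = "stoploss", "stop loss" = "stoploss",
  "frameshift insertion" = "frameshift_insertion",
  "frameshift_insertion" = "frameshift_insertion",
  "frameshift deletion" = "frameshift_deletion",
  "frameshift_deletion" = "frameshift_deletion",
  "splicing" = "splicing", "splice" = "splicing",
  "synonymous snv" = "synonymous", "synonymous" = "synonymous",
  "synonymous_snv" = "synonymous"
)

#' Site key
#'
#' Canonical `chrom:pos:ref:alt` key used to join genotype sites with
#' annotation rows after biallelic decomposition. Coordinates are 1-based
#' VCF convention throughout.
#'
#' @param chrom,pos,ref,alt Vectors describing biallelic sites.
#' @return Character vector of keys.
#' @export
site_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

.gt_class <- function(gt, allele) {
  out <- rep("missing", length(gt))
  known <- !is.na(gt) & !grepl(".", gt, fixed = TRUE)
  if (any(known)) {
    copies <- vapply(strsplit(gt[known], "[/|]"),
                     function(a) sum(a == allele), 0L)
    lab <- ifelse(copies >= 2, "hom_alt", ifelse(copies == 1, "het", "hom_ref"))
    out[known] <- lab
  }
  out
}

#' Read genotypes from a multi-sample VCF
#'
#' Parses a VCF v4.2 (plain or bgzip/gzip) with `GT` and `AD` (and
#' optionally `DP`) FORMAT fields via \pkg{vcfR}, decomposes multiallelic
#' records into one biallelic site per alternate allele, and extracts per
#' sample the genotype class relative to that allele (`hom_ref`, `het`,
#' `hom_alt`, `missing`), the read depth (`DP` when present, else the sum of
#' `AD`) and the alternate-allele read count. A genotype containing any `.`
#' allele is `missing`; for a multiallelic genotype the class counts copies
#' of the focal alternate allele only.
#'
#' @param path Path to the VCF.
#' @param samples Optional character vector restricting (and ordering) the
#'   samples; an absent sample is an error.
#' @return An object of class `fam_geno`: a list with `sites` (data frame
#'   `chrom`, `pos`, `id`, `ref`, `alt`, `key`), `samples`, and site-by-sample
#'   matrices `gt`, `depth`, `alt_reads`.
#' @export
read_vcf <- function(path, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0) stop("no variant records in ", path)
  all_samples <- colnames(v@gt)[-1]
  if (is.null(samples)) {
    samples <- all_samples
  } else if (!all(samples %in% all_samples)) {
    stop("sample(s) absent from VCF: ",
         paste(setdiff(samples, all_samples), collapse = ", "))
  }
  GT <- vcfR::extract.gt(v, element = "GT")
  AD <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
  DP <- tryCatch(suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)),
                 error = function(e) NULL)
  as_mat <- function(m) {
    if (is.null(m)) return(NULL)
    m <- matrix(m, nrow = nrow(fix), dimnames = list(NULL, all_samples))
    m[, samples, drop = FALSE]
  }
  GT <- as_mat(GT); AD <- as_mat(AD); DP <- as_mat(DP)

  alt_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  rows <- rep(seq_along(alt_list), lengths(alt_list))
  aidx <- unlist(lapply(lengths(alt_list), seq_len), use.names = FALSE)
  sites <- data.frame(
    chrom = fix[rows, "CHROM"],
    pos = as.integer(fix[rows, "POS"]),
    id = ifelse(is.na(fix[rows, "ID"]) | fix[rows, "ID"] == ".", NA_character_,
                fix[rows, "ID"]),
    ref = fix[rows, "REF"],
    alt = unlist(alt_list, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  sites$key <- site_key(sites$chrom, sites$pos, sites$ref, sites$alt)

  n_site <- nrow(sites)
  n_samp <- length(samples)
  gt <- matrix("missing", n_site, n_samp, dimnames = list(NULL, samples))
  depth <- matrix(NA_real_, n_site, n_samp, dimnames = list(NULL, samples))
  alt_reads <- matrix(NA_real_, n_site, n_samp, dimnames = list(NULL, samples))
  ad_split <- if (!is.null(AD)) {
    matrix(lapply(AD, function(x) suppressWarnings(as.numeric(strsplit(
      if (is.na(x)) "" else x, ",", fixed = TRUE)[[1]]))), nrow = nrow(AD))
  } else NULL
  for (k in seq_len(n_site)) {
    r <- rows[k]; i <- aidx[k]
    gt[k, ] <- .gt_class(GT[r, ], as.character(i))
    for (s in seq_len(n_samp)) {
      ad <- if (!is.null(ad_split)) ad_split[[r, s]] else numeric()
      a <- if (length(ad) >= i + 1) ad[i + 1] else NA_real_
      d <- if (!is.null(DP) && !is.na(DP[r, s])) DP[r, s] else
        if (length(ad) && !anyNA(ad)) sum(ad) else NA_real_
      alt_reads[k, s] <- a
      depth[k, s] <- d
    }
  }
  structure(list(sites = sites, samples = samples, gt = gt,
                 depth = depth, alt_reads = alt_reads),
            class = "fam_geno")
}

#' @export
print.fam_geno <- function(x, ...) {
  cat("fam_geno:", nrow(x$sites), "biallelic sites x", length(x$samples),
      "samples\n")
  invisible(x)
}

.normalise_func <- function(x) {
  key <- trimws(tolower(as.character(x)))
  out <- unname(.FUNC_MAP[key])
  unknown <- is.na(out) & !is.na(key) & key != "" & key != "."
  if (any(unknown)) {
    warning("unknown functional class token(s) mapped to 'other': ",
            paste(unique(x[unknown]), collapse = ", "), call. = FALSE)
    out[unknown] <- "other"
  }
  out
}

.dot_na <- function(x) {
  x <- as.character(x)
  x[x %in% c(".", "", "NA")] <- NA_character_
  x
}

#' Read a variant annotation table
#'
#' Reads an Annovar-style TSV of per-variant annotations: gene symbol,
#' functional class, gnomAD NFE allele frequency, SIFT and PolyPhen-2 HDIV
#' calls. `.` and empty cells become absent values; functional-class tokens
#' are normalised to the closed set (`nonsynonymous_snv`, `stopgain`,
#' `stoploss`, `frameshift_insertion`, `frameshift_deletion`, `splicing`,
#' `synonymous`, `other`) with a warning for unknown tokens. The Annovar
#' `"-"` allele style for indels is accepted verbatim; joining to genotypes
#' is by exact `(chrom, pos, ref, alt)` match.
#'
#' @param path Path to the TSV (plain or gzip).
#' @param col_map Named character vector mapping the canonical column names
#'   (`chrom`, `pos`, `ref`, `alt`, `gene`, `func_class`, `maf_nfe`, `sift`,
#'   `polyphen_hdiv`, and optional `aa_change`, `dbsnp`) to the file's
#'   headers. Defaults to the canonical names themselves.
#' @return Data frame of annotated variants with a `key` column.
#' @export
read_annotation_table <- function(path, col_map = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  canon <- c("chrom", "pos", "ref", "alt", "gene", "func_class",
             "maf_nfe", "sift", "polyphen_hdiv", "aa_change", "dbsnp")
  map <- setNames(canon, canon)
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  required <- c("chrom", "pos", "ref", "alt", "gene", "func_class",
                "maf_nfe", "sift", "polyphen_hdiv")
  have <- map[required] %in% names(tab)
  if (nrow(tab) == 0 && !all(have)) {
    # empty file with full header still parses; truly absent columns error
  }
  if (!all(have)) {
    stop("annotation table missing column(s): ",
         paste(map[required][!have], collapse = ", "))
  }
  out <- data.frame(
    chrom = tab[[map["chrom"]]],
    pos = as.integer(tab[[map["pos"]]]),
    ref = tab[[map["ref"]]],
    alt = tab[[map["alt"]]],
    gene = toupper(tab[[map["gene"]]]),
    func_class = if (nrow(tab)) .normalise_func(tab[[map["func_class"]]])
                 else character(),
    maf_nfe = suppressWarnings(as.numeric(.dot_na(tab[[map["maf_nfe"]]]))),
    sift = .dot_na(tab[[map["sift"]]]),
    polyphen_hdiv = .dot_na(tab[[map["polyphen_hdiv"]]]),
    stringsAsFactors = FALSE
  )
  out$aa_change <- if (map["aa_change"] %in% names(tab))
    .dot_na(tab[[map["aa_change"]]]) else rep(NA_character_, nrow(tab))
  out$dbsnp <- if (map["dbsnp"] %in% names(tab))
    .dot_na(tab[[map["dbsnp"]]]) else rep(NA_character_, nrow(tab))
  bad_maf <- !is.na(out$maf_nfe) & (out$maf_nfe < 0 | out$maf_nfe > 1)
  if (any(bad_maf)) stop("maf_nfe outside [0,1] at row(s): ",
                         paste(which(bad_maf), collapse = ", "))
  out$key <- site_key(out$chrom, out$pos, out$ref, out$alt)
  out
}

#' Read a gene list
#'
#' One symbol per line; blank lines and `#` comments ignored; symbols are
#' uppercased and deduplicated.
#'
#' @param path Path to the list file.
#' @return Character vector of unique uppercase symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[x != "" & !startsWith(x, "#")]
  unique(toupper(x))
}

#' Read a gene constraint table
#'
#' TSV with columns `gene`, `pli`, `loeuf` (case-insensitive headers).
#' `.` cells become absent; any other non-numeric value is an error.
#'
#' @param path Path to the TSV.
#' @return Data frame `gene` (uppercase), `pli`, `loeuf`.
#' @export
read_constraint_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  names(tab) <- tolower(names(tab))
  need <- c("gene", "pli", "loeuf")
  if (!all(need %in% names(tab))) {
    stop("constraint table must have columns gene, pli, loeuf")
  }
  num <- function(x, what) {
    x <- .dot_na(x)
    v <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(v)
    if (any(bad)) stop("non-numeric ", what, " value(s): ",
                       paste(unique(x[bad]), collapse = ", "))
    v
  }
  out <- data.frame(gene = toupper(tab$gene),
                    pli = num(tab$pli, "pLI"),
                    loeuf = num(tab$loeuf, "LOEUF"),
                    stringsAsFactors = FALSE)
  bad <- !is.na(out$pli) & (out$pli < 0 | out$pli > 1)
  if (any(bad)) stop("pLI outside [0,1] for: ",
                     paste(out$gene[bad], collapse = ", "))
  out
}

.REPORT_COLS <- c("gene", "origin", "family", "label", "chrom", "pos",
                  "ref", "alt", "aa_change", "dbsnp", "maf_nfe", "sift",
                  "polyphen", "tier", "carriers")

#' Write the prioritisation report
#'
#' TSV with one row per prioritised variant per family: gene, origin
#' (`inherited` / `de_novo`), family, trait/diagnosis label, position,
#' alleles, amino-acid change, dbSNP id, gnomAD NFE frequency, SIFT and
#' PolyPhen calls, evidence tier and carrier ids. Rows are sorted
#' deterministically by (tier, gene, family); absent values are written `.`.
#'
#' @param x Data frame of prioritised variants (may be empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  for (col in .REPORT_COLS) if (is.null(x[[col]])) x[[col]] <- NA
  x <- x[, .REPORT_COLS, drop = FALSE]
  if (nrow(x)) {
    tier_ord <- ifelse(is.na(x$tier), Inf, as.numeric(x$tier))
    x <- x[order(tier_ord, x$gene, x$family, x$pos), , drop = FALSE]
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Read a prioritisation report back
#'
#' Inverse of [write_report()]: parses the TSV, restoring absent values and
#' column types so that a write/read round trip is the identity on the
#' report records.
#'
#' @param path Path to a report TSV.
#' @return Data frame with the report columns.
#' @export
read_report <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".",
                         colClasses = "character")
  if (!nrow(x)) {
    x <- as.data.frame(setNames(rep(list(character()), length(.REPORT_COLS)),
                                .REPORT_COLS), stringsAsFactors = FALSE)
  }
  x$pos <- as.integer(x$pos)
  x$maf_nfe <- as.numeric(x$maf_nfe)
  x$tier <- as.integer(x$tier)
  x
}
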