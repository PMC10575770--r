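# Evidence-tier classification of candidate genes from named gene lists.
# Tier 1: robust autism / severe neurodevelopmental-disorder genes (SFARI
# S/1-3, SPARK, large exome studies, DDG2P monoallelic, DBDGD). Tier 2:
# suggestive autism / ID / epilepsy / ADHD genes. Tier 3: brain-expressed
# or synaptic genes. Precedence 1 > 2 > 3.

#' Construct a tier-source collection
#'
#' @param tier1,tier2,tier3 Named lists of character vectors of gene
#'   symbols, one entry per source database. Symbols are uppercased.
#' @return List of class `tier_sources`.
#' @export
tier_sources <- function(tier1 = list(), tier2 = list(), tier3 = list()) {
  fix <- function(tl) {
    stopifnot(is.list(tl))
    if (length(tl) && (is.null(names(tl)) || any(names(tl) == ""))) {
      stop("every tier source must be named")
    }
    lapply(tl, function(g) unique(toupper(g)))
  }
  out <- list(tier1 = fix(tier1), tier2 = fix(tier2), tier3 = fix(tier3))
  nm <- c(names(out$tier1), names(out$tier2), names(out$tier3))
  if (anyDuplicated(nm)) {
    stop("duplicate source name(s): ", paste(nm[duplicated(nm)], collapse = ", "))
  }
  structure(out, class = "tier_sources")
}

#' Read tier sources from a YAML config
#'
#' The config maps tiers to source names to gene-list file paths, e.g.
#' `tier1: {SFARI: sfari.txt}`; relative paths resolve against the config
#' file's directory. Lists are read with [read_gene_list()].
#'
#' @param path Path to the YAML config.
#' @return A [tier_sources()] object.
#' @export
read_tier_sources <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(path)
  load_tier <- function(tl) {
    if (is.null(tl)) return(list())
    lapply(tl, function(p) {
      if (!file.exists(p)) p <- file.path(base, p)
      read_gene_list(p)
    })
  }
  tier_sources(tier1 = load_tier(cfg$tier1),
               tier2 = load_tier(cfg$tier2),
               tier3 = load_tier(cfg$tier3))
}

#' Bundled fixture tier sources
#'
#' Small synthetic subsets of the public databases (SFARI, DDG2P, DBDGD,
#' AutDB, SynaptomeDB), sufficient to tier the bundled prioritisation
#' table. Real database snapshots are deliberately not shipped (licensing
#' and versioning); point [read_tier_sources()] at full downloads for real
#' analyses.
#'
#' @return A [tier_sources()] object.
#' @export
bundled_tier_sources <- function() {
  read_tier_sources(system.file("extdata", "genelists", "tiers.yml",
                                package = "famseg", mustWork = TRUE))
}

#' Assign evidence tiers to genes
#'
#' Each gene receives the highest-precedence tier (1 > 2 > 3) with at least
#' one supporting source; matching is case-insensitive on uppercased
#' symbols, with no alias resolution. Genes in no source get tier `NA`
#' (none) and no supporting sources. Adding a gene to a lower tier never
#' changes a higher-tier assignment.
#'
#' @param gene Character vector of gene symbols.
#' @param sources A [tier_sources()] object.
#' @return Data frame `gene`, `tier` (integer or `NA`),
#'   `supporting_sources` (comma-separated source names of the assigned
#'   tier; empty iff tier is `NA`).
#' @export
assign_tier <- function(gene, sources) {
  stopifnot(inherits(sources, "tier_sources"))
  g <- toupper(gene)
  tier <- rep(NA_integer_, length(g))
  supp <- character(length(g))
  for (t in 1:3) {
    tl <- sources[[paste0("tier", t)]]
    if (!length(tl)) next
    hits <- vapply(g, function(x) {
      paste(names(tl)[vapply(tl, function(s) x %in% s, TRUE)], collapse = ",")
    }, "")
    take <- is.na(tier) & hits != ""
    tier[take] <- t
    supp[take] <- hits[take]
  }
  data.frame(gene = gene, tier = tier, supporting_sources = supp,
             stringsAsFactors = FALSE)
}

#' Annotate prioritised variants or gene summaries with tiers
#'
#' Adds (or overwrites) a `tier` column by looking each row's gene up with
#' [assign_tier()]; unlisted genes get `NA`.
#'
#' @param x Data frame with a `gene` column.
#' @param sources A [tier_sources()] object.
#' @return `x` with `tier` and `supporting_sources` columns.
#' @export
annotate_tiers <- function(x, sources) {
  ta <- assign_tier(x$gene, sources)
  x$tier <- ta$tier
  x$supporting_sources <- ta$supporting_sources
  x
}
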