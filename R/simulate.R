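# Seeded synthetic multiplex-cohort generator: pedigrees, diagnosis and
# trait scores, planted segregating / de novo variants, Mendelian noise
# variants, read-depth evidence, and the matching annotation, constraint
# and gene-list side files, plus a truth table for recovery checks.

.SIM_NORMS <- list(
  "adult-AQ" = list(mean = 16.4, sd = 6.25),
  "adolescent-AQ" = list(mean = 17.8, sd = 6.5),
  "child-AQ" = list(mean = 7.6, sd = 4.1),
  "Q-CHAT" = list(mean = 26.7, sd = 7.8)
)
.SIM_SCORE_CAP <- c("adult-AQ" = 50, "adolescent-AQ" = 50,
                    "child-AQ" = 50, "Q-CHAT" = 100)

#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. The default `"study"`
#' layout is a fixed 21-family, 112-individual pedigree: 76 diagnosed
#' members, 4 suspected, exactly ten families with four or more diagnosed
#' members, and one reduced family ("10") with only two diagnosed members
#' and an unrecruited father. The `"random"` layout draws nuclear (or
#' three-generation) families of configurable size instead.
#'
#' Trait scores are drawn on the instrument's standard-deviation scale:
#' diagnosed members at `z_diagnosed` (SD units above the normative mean)
#' with spread `sd_diagnosed`, suspected members at `z_suspected`, everyone
#' else at `z_background`, truncated to the instrument's score range.
#' Read evidence uses depth ~ Poisson(`depth_lambda`) and alternate reads ~
#' Binomial(depth, f) with f = 0.5 for heterozygotes and `base_error` for
#' non-carriers; planted variants are guaranteed (by resampling) to pass
#' the configured read-support or de novo depth gates, so a noise-free run
#' recovers them exactly.
#'
#' @param layout `"study"` (default) or `"random"`.
#' @param n_families,n_children Random layout: number of families and range
#'   of children per family.
#' @param generations Random layout: 2 for nuclear families, 3 to extend
#'   each family's first child with a spouse and two grandchildren.
#' @param p_diagnosed_child,p_diagnosed_parent Random layout diagnosis
#'   probabilities.
#' @param norms Instrument norms used for scoring (see
#'   [read_instrument_norms()]).
#' @param z_diagnosed,sd_diagnosed,z_suspected,sd_suspected,z_background,sd_background
#'   Trait-score model, in SD units.
#' @param n_diagnosis_plants Number of dominant diagnosis-segregating
#'   variants planted on founders (rejection-sampled until >= 2 diagnosed
#'   carriers and no non-autistic carrier).
#' @param n_trait_plants Named counts of trait-level plants per level,
#'   e.g. `c(BAP = 4, MAP = 4, NAP = 4)`.
#' @param n_denovo_plants De novo variants planted in distinct trio
#'   children (parents hom-ref).
#' @param n_noise Background variants with honest Mendelian transmission
#'   from a random founder.
#' @param noise_pass_rate Fraction of noise variants given a qualifying
#'   (rare, damaging, constrained) annotation; the rest fail one randomly
#'   chosen gate (common frequency, benign prediction, unconstrained gene,
#'   or synonymous class).
#' @param depth_lambda Mean sequencing depth.
#' @param base_error Per-read error rate generating alternate reads in
#'   non-carriers.
#' @param genotype_error Probability that a noise-site genotype is recorded
#'   incorrectly (het/hom-ref flip), creating Mendelian violations.
#' @param planted_maf NFE frequency written for planted variants (absent
#'   for every second plant, emulating ultra-rare variants).
#' @param filters The [filter_config()] whose gates planted evidence is
#'   guaranteed to pass.
#' @param seed Integer seed; identical seeds give byte-identical bundles.
#' @param max_retries Rejection-sampling bound per plant.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(layout = c("study", "random"),
                       n_families = 6, n_children = c(2, 4),
                       generations = 2,
                       p_diagnosed_child = 0.6, p_diagnosed_parent = 0.4,
                       norms = .SIM_NORMS,
                       z_diagnosed = 3.1, sd_diagnosed = 0.8,
                       z_suspected = 2.5, sd_suspected = 0.8,
                       z_background = 0.9, sd_background = 1.0,
                       n_diagnosis_plants = 12,
                       n_trait_plants = c(BAP = 4, MAP = 4, NAP = 4),
                       n_denovo_plants = 6,
                       n_noise = 40, noise_pass_rate = 0.3,
                       depth_lambda = 30, base_error = 0.002,
                       genotype_error = 0, planted_maf = 5e-4,
                       filters = filter_config(),
                       seed = 1, max_retries = 10000) {
  layout <- match.arg(layout)
  stopifnot(generations %in% c(2, 3),
            p_diagnosed_child >= 0, p_diagnosed_child <= 1,
            n_diagnosis_plants >= 0, all(n_trait_plants >= 0),
            n_denovo_plants >= 0, n_noise >= 0,
            noise_pass_rate >= 0, noise_pass_rate <= 1,
            depth_lambda > 0, genotype_error >= 0, genotype_error <= 1)
  norms <- read_instrument_norms(norms)
  structure(as.list(environment()), class = "sim_config")
}

# Fixed study-shaped pedigree: see sim_config() docs.
.study_pedigree <- function() {
  rows <- list()
  add <- function(fam, id, fa, mo, dx) {
    rows[[length(rows) + 1]] <<- data.frame(
      family_id = fam, individual_id = id, father_id = fa, mother_id = mo,
      sex = NA_character_, diagnosis = dx, stringsAsFactors = FALSE)
  }
  for (f in 1:21) {
    fam <- as.character(f)
    fa_id <- paste0("F", f, "_FA"); mo_id <- paste0("F", f, "_MO")
    if (f == 10) {
      # reduced family: father not recruited, two diagnosed children
      add(fam, mo_id, "0", "0", "non_autistic")
      add(fam, paste0("F", f, "_C1"), "0", mo_id, "diagnosed")
      add(fam, paste0("F", f, "_C2"), "0", mo_id, "diagnosed")
      next
    }
    n_child <- if (f <= 9) 4 else 3
    n_dx_child <- if (f <= 4) 4 else if (f <= 9) 3 else if (f == 11) 3 else 2
    mo_dx <- if (f %in% 12:14) "suspected" else "non_autistic"
    add(fam, fa_id, "0", "0", "diagnosed")
    add(fam, mo_id, "0", "0", mo_dx)
    for (k in seq_len(n_child)) {
      dx <- if (k <= n_dx_child) "diagnosed"
            else if (f == 16 && k == 3) "suspected" else "non_autistic"
      add(fam, paste0("F", f, "_C", k), fa_id, mo_id, dx)
    }
  }
  ped <- do.call(rbind, rows)
  ped$sex <- ifelse(grepl("_FA$", ped$individual_id), "male",
                    ifelse(grepl("_MO$", ped$individual_id), "female", NA))
  # 21 mothers + 29 female children = 50 females
  idx <- which(is.na(ped$sex))
  ped$sex[idx] <- c(rep("female", min(29, length(idx))),
                    rep("male", max(0, length(idx) - 29)))
  ped$instrument <- ifelse(ped$father_id == "0" & ped$mother_id == "0",
                           "adult-AQ", "child-AQ")
  ped$instrument[ped$individual_id %in%
                   paste0("F", 1:9, "_C1")] <- "adolescent-AQ"
  ped
}

.random_pedigree <- function(cfg) {
  rows <- list()
  for (f in seq_len(cfg$n_families)) {
    fam <- as.character(f)
    fa <- paste0("F", f, "_FA"); mo <- paste0("F", f, "_MO")
    dx_p <- function() if (stats::runif(1) < cfg$p_diagnosed_parent)
      "diagnosed" else "non_autistic"
    rows[[length(rows) + 1]] <- data.frame(
      family_id = fam, individual_id = c(fa, mo),
      father_id = "0", mother_id = "0", sex = c("male", "female"),
      diagnosis = c(dx_p(), dx_p()), stringsAsFactors = FALSE)
    nc <- sample(seq(cfg$n_children[1], cfg$n_children[2]), 1)
    kids <- paste0("F", f, "_C", seq_len(nc))
    rows[[length(rows) + 1]] <- data.frame(
      family_id = fam, individual_id = kids, father_id = fa, mother_id = mo,
      sex = rep(c("male", "female"), length.out = nc),
      diagnosis = ifelse(stats::runif(nc) < cfg$p_diagnosed_child,
                         "diagnosed", "non_autistic"),
      stringsAsFactors = FALSE)
    if (cfg$generations == 3) {
      sp <- paste0("F", f, "_SP")
      gc <- paste0("F", f, "_G", 1:2)
      rows[[length(rows) + 1]] <- data.frame(
        family_id = fam, individual_id = sp, father_id = "0",
        mother_id = "0", sex = "female", diagnosis = "non_autistic",
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        family_id = fam, individual_id = gc, father_id = kids[1],
        mother_id = sp, sex = c("male", "female"),
        diagnosis = ifelse(stats::runif(2) < cfg$p_diagnosed_child,
                           "diagnosed", "non_autistic"),
        stringsAsFactors = FALSE)
    }
  }
  ped <- do.call(rbind, rows)
  ped$instrument <- ifelse(ped$father_id == "0" & ped$mother_id == "0",
                           "adult-AQ", "child-AQ")
  ped
}

# transmit one founder allele through a family (parents precede children)
.transmit <- function(ped, founder) {
  copies <- setNames(integer(nrow(ped)), ped$individual_id)
  copies[founder] <- 1L
  for (i in seq_len(nrow(ped))) {
    id <- ped$individual_id[i]
    if (id == founder) next
    got <- 0L
    for (p in c(ped$father_id[i], ped$mother_id[i])) {
      if (p == "0" || !(p %in% names(copies))) next
      cp <- copies[[p]]
      if (cp == 2L) got <- got + 1L
      else if (cp == 1L) got <- got + stats::rbinom(1, 1, 0.5)
    }
    copies[id] <- got
  }
  copies
}

.pick <- function(x) if (length(x) == 1) x else x[sample.int(length(x), 1)]

.sim_scores <- function(ped, cfg) {
  z <- numeric(nrow(ped))
  z[ped$diagnosis == "diagnosed"] <-
    stats::rnorm(sum(ped$diagnosis == "diagnosed"),
                 cfg$z_diagnosed, cfg$sd_diagnosed)
  z[ped$diagnosis == "suspected"] <-
    stats::rnorm(sum(ped$diagnosis == "suspected"),
                 cfg$z_suspected, cfg$sd_suspected)
  rest <- !(ped$diagnosis %in% c("diagnosed", "suspected"))
  z[rest] <- stats::rnorm(sum(rest), cfg$z_background, cfg$sd_background)
  mean_i <- vapply(ped$instrument, function(i) cfg$norms[[i]]$mean, 0)
  sd_i <- vapply(ped$instrument, function(i) cfg$norms[[i]]$sd, 0)
  cap <- .SIM_SCORE_CAP[ped$instrument]
  pmin(pmax(mean_i + z * sd_i, 0), cap)
}

.sim_sites <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- bases[sample.int(4, n, replace = TRUE)]
  alt <- vapply(ref, function(r) .pick(setdiff(bases, r)), "")
  data.frame(
    gene = sprintf("SIMG%04d", seq_len(n)),
    chrom = as.character(((seq_len(n) - 1) %% 22) + 1),
    pos = as.integer(1e6 + seq_len(n) * 50000 +
                       sample.int(40000, n, replace = TRUE)),
    ref = ref, alt = alt, stringsAsFactors = FALSE)
}

#' Generate a synthetic multiplex cohort bundle
#'
#' Builds the pedigree, draws diagnosis-conditional trait scores, plants
#' diagnosis-segregating, trait-level and de novo variants (all obeying
#' honest Mendelian transmission, placed by rejection sampling rather than
#' painted onto phenotypes), adds Mendelian background noise variants, and
#' draws per-call read evidence. When `dir` is given the full file bundle is
#' written: `cohort.ped`, `traits.csv`, `cohort.vcf`, `annotations.tsv`,
#' `constraint.tsv`, `norms.yml`, `genelists/` (tier lists + `tiers.yml`)
#' and `truth.tsv`. Identical seeds give byte-identical files.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory (created if needed).
#' @return List with the in-memory objects (`ped`, `cohort`, `geno`, `ann`,
#'   `constraint`, `tiers`, `truth`, allele-`copies` matrix and its
#'   pre-error state) and, when `dir` is given, the file `paths`.
#' @export
simulate_cohort <- function(cfg = sim_config(), dir = NULL) {
  set.seed(cfg$seed)
  ped <- if (cfg$layout == "study") .study_pedigree() else .random_pedigree(cfg)
  ped$trait_score <- .sim_scores(ped, cfg)
  ids <- ped$individual_id
  n_ind <- length(ids)
  grp <- rep(NA_character_, n_ind)
  for (ins in unique(ped$instrument)) {
    sel <- ped$instrument == ins
    grp[sel] <- as.character(assign_trait_group(
      ped$trait_score[sel], cfg$norms[[ins]]$mean, cfg$norms[[ins]]$sd))
  }
  ped$trait_group <- trait_factor(grp)

  n_trait <- sum(cfg$n_trait_plants)
  n_plant <- cfg$n_diagnosis_plants + n_trait + cfg$n_denovo_plants
  n_var <- n_plant + cfg$n_noise
  sites <- .sim_sites(n_var)
  fams <- split(ped, ped$family_id)
  founders_of <- lapply(fams, function(f)
    f$individual_id[f$father_id == "0" & f$mother_id == "0"])

  copies <- matrix(0L, n_var, n_ind, dimnames = list(NULL, ids))
  truth <- data.frame(key = character(n_var), gene = sites$gene,
                      family = NA_character_, category = NA_character_,
                      carriers = NA_character_, stringsAsFactors = FALSE)
  v <- 0L

  plant_segregating <- function(v, category, ok_family, ok_founder, ok_result) {
    elig <- names(fams)[vapply(names(fams), function(fn) {
      ok_family(fams[[fn]]) &&
        length(Filter(function(id) ok_founder(fams[[fn]], id),
                      founders_of[[fn]])) > 0
    }, TRUE)]
    if (!length(elig)) {
      stop("unsatisfiable plant: no family can host a ", category,
           " variant under the configured pedigree")
    }
    fam <- .pick(elig)
    f <- fams[[fam]]
    fnd <- Filter(function(id) ok_founder(f, id), founders_of[[fam]])
    for (try in seq_len(cfg$max_retries)) {
      cp <- .transmit(f, .pick(fnd))
      if (ok_result(f, cp)) {
        copies[v, names(cp)] <<- cp
        truth$family[v] <<- fam
        truth$category[v] <<- category
        truth$carriers[v] <<- paste(sort(names(cp)[cp > 0]), collapse = ",")
        return(invisible(NULL))
      }
    }
    stop("unsatisfiable plant: ", category, " in family ", fam,
         " not achieved in ", cfg$max_retries, " transmissions")
  }

  dx_of <- function(f) setNames(f$diagnosis, f$individual_id)
  grp_of <- function(f) setNames(as.character(f$trait_group), f$individual_id)

  for (i in seq_len(cfg$n_diagnosis_plants)) {
    v <- v + 1L
    plant_segregating(
      v, "diagnosis",
      ok_family = function(f) sum(f$diagnosis == "diagnosed") >= 2,
      ok_founder = function(f, id) dx_of(f)[[id]] != "non_autistic",
      ok_result = function(f, cp) {
        carrier <- names(cp)[cp > 0]
        dx <- dx_of(f)
        sum(dx[carrier] == "diagnosed") >= 2 &&
          !any(dx[carrier] == "non_autistic")
      })
  }
  for (lv in names(cfg$n_trait_plants)) {
    for (i in seq_len(cfg$n_trait_plants[[lv]])) {
      v <- v + 1L
      lv_f <- trait_factor(lv)
      plant_segregating(
        v, paste0("trait_", lv),
        ok_family = function(f) {
          g <- trait_factor(grp_of(f))
          sum(!is.na(g) & g >= lv_f) >= 2 && any(!is.na(g) & g == lv_f)
        },
        ok_founder = function(f, id) {
          g <- grp_of(f)[[id]]
          is.na(g) || trait_factor(g) >= lv_f
        },
        ok_result = function(f, cp) {
          g <- trait_factor(grp_of(f)[names(cp)[cp > 0]])
          g <- g[!is.na(g)]
          length(g) >= 2 && min(g) == lv_f
        })
    }
  }
  trios <- enumerate_trios(structure(ped, class = c("fam_cohort", "data.frame")))
  dn_children <- character(0)
  if (cfg$n_denovo_plants > 0) {
    if (nrow(trios) < cfg$n_denovo_plants) {
      stop("unsatisfiable plant: ", cfg$n_denovo_plants,
           " de novo variants requested but only ", nrow(trios),
           " genotyped trios exist")
    }
    dn_children <- sample(trios$child, cfg$n_denovo_plants)
    for (ch in dn_children) {
      v <- v + 1L
      copies[v, ch] <- 1L
      truth$family[v] <- ped$family_id[match(ch, ids)]
      truth$category[v] <- "de_novo"
      truth$carriers[v] <- ch
    }
  }
  noise_pass <- logical(0)
  pre_error <- NULL
  if (cfg$n_noise > 0) {
    noise_pass <- stats::runif(cfg$n_noise) < cfg$noise_pass_rate
    for (i in seq_len(cfg$n_noise)) {
      v <- v + 1L
      fam <- .pick(names(fams))
      cp <- .transmit(fams[[fam]], .pick(founders_of[[fam]]))
      copies[v, names(cp)] <- cp
      truth$family[v] <- fam
      truth$category[v] <- "noise"
      truth$carriers[v] <- paste(sort(names(cp)[cp > 0]), collapse = ",")
    }
    pre_error <- copies
    if (cfg$genotype_error > 0) {
      noise_rows <- (n_plant + 1):n_var
      flip <- matrix(stats::runif(length(noise_rows) * n_ind) <
                       cfg$genotype_error, length(noise_rows), n_ind)
      blk <- copies[noise_rows, , drop = FALSE]
      was_ref <- flip & blk == 0L
      was_het <- flip & blk == 1L
      blk[was_ref] <- 1L
      blk[was_het] <- 0L
      copies[noise_rows, ] <- blk
    }
  }
  if (is.null(pre_error)) pre_error <- copies

  sim_ann <- .sim_annotations(sites, truth, noise_pass, cfg)
  constraint <- sim_ann$constraint
  ann <- sim_ann$ann
  sites <- sim_ann$sites  # frameshift refs gain their anchor base
  ev <- .sim_read_evidence(copies, truth, ped, dn_children, cfg)
  geno <- structure(list(
    sites = data.frame(chrom = sites$chrom, pos = sites$pos,
                       id = NA_character_, ref = sites$ref, alt = sites$alt,
                       key = site_key(sites$chrom, sites$pos, sites$ref,
                                      sites$alt),
                       stringsAsFactors = FALSE),
    samples = ids,
    gt = matrix(c("hom_ref", "het", "hom_alt")[copies + 1L], n_var, n_ind,
                dimnames = list(NULL, ids)),
    depth = ev$depth, alt_reads = ev$alt), class = "fam_geno")
  truth$key <- geno$sites$key
  truth <- cbind(truth["key"], sites[c("chrom", "pos", "ref", "alt")],
                 truth[c("gene", "family", "category", "carriers")])

  plant_genes <- truth$gene[truth$category %in%
                              c("diagnosis", "de_novo")]
  trait_genes <- truth$gene[startsWith(truth$category, "trait_")]
  noise_genes <- truth$gene[truth$category == "noise"]
  tiers <- tier_sources(
    tier1 = list(SimPanel1 = plant_genes),
    tier2 = if (length(trait_genes)) list(SimPanel2 = trait_genes) else list(),
    tier3 = if (length(noise_genes)) {
      list(SimPanel3 = noise_genes[seq_along(noise_genes) %% 5 == 0])
    } else list())

  cohort <- ped
  class(cohort) <- c("fam_cohort", "data.frame")
  out <- list(cfg = cfg, ped = ped, cohort = cohort, geno = geno, ann = ann,
              constraint = constraint, tiers = tiers, truth = truth,
              copies = copies, copies_pre_error = pre_error)
  if (!is.null(dir)) out$paths <- .write_bundle(out, dir)
  out
}

.sim_annotations <- function(sites, truth, noise_pass, cfg) {
  n <- nrow(sites)
  func <- rep("nonsynonymous_snv", n)
  sift <- rep("D", n); poly <- rep("D", n)
  maf <- rep(NA_real_, n)
  pli <- rep(0.99, n); loeuf <- rep(0.10, n)
  planted <- truth$category != "noise"
  # every second plant carries a printed rare frequency, the rest are
  # absent from the reference population
  maf[planted][seq_len(sum(planted)) %% 2 == 0] <- cfg$planted_maf
  ptv <- planted & seq_len(n) %% 5 == 0 & truth$category != "de_novo"
  func[ptv] <- rep(c("stopgain", "frameshift_deletion"),
                   length.out = sum(ptv))
  sift[func != "nonsynonymous_snv"] <- NA
  poly[func != "nonsynonymous_snv"] <- NA

  noise_idx <- which(truth$category == "noise")
  for (j in seq_along(noise_idx)) {
    i <- noise_idx[j]
    maf[i] <- cfg$planted_maf
    if (noise_pass[j]) next
    mode <- .pick(c("common", "benign", "unconstrained", "synonymous"))
    switch(mode,
           common = { maf[i] <- 0.05 },
           benign = { sift[i] <- "T"; poly[i] <- "B" },
           unconstrained = { pli[i] <- 0.01; loeuf[i] <- 1.5 },
           synonymous = { func[i] <- "synonymous"
                          sift[i] <- NA; poly[i] <- NA })
  }
  # frameshift deletions use anchored-base VCF alleles
  fs <- func == "frameshift_deletion"
  sites$ref[fs] <- paste0(sites$ref[fs], "A")
  ann <- data.frame(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
    gene = sites$gene, func_class = func, maf_nfe = maf, sift = sift,
    polyphen_hdiv = poly,
    aa_change = sprintf("p.X%dY", seq_len(n)), dbsnp = NA_character_,
    stringsAsFactors = FALSE)
  ann$key <- site_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  list(ann = ann, sites = sites,
       constraint = data.frame(gene = sites$gene, pli = pli, loeuf = loeuf,
                               stringsAsFactors = FALSE))
}

.sim_read_evidence <- function(copies, truth, ped, dn_children, cfg) {
  n_var <- nrow(copies); n_ind <- ncol(copies)
  flt <- cfg$filters
  depth <- matrix(stats::rpois(n_var * n_ind, cfg$depth_lambda),
                  n_var, n_ind, dimnames = dimnames(copies))
  p_alt <- c(cfg$base_error, 0.5, 1 - cfg$base_error)[copies + 1L]
  alt <- matrix(stats::rbinom(n_var * n_ind, depth, p_alt),
                n_var, n_ind, dimnames = dimnames(copies))
  ids <- colnames(copies)
  redraw_until <- function(v, s, ok) {
    for (try in seq_len(cfg$max_retries)) {
      d <- stats::rpois(1, cfg$depth_lambda)
      a <- stats::rbinom(1, d, c(cfg$base_error, 0.5,
                                 1 - cfg$base_error)[copies[v, s] + 1L])
      if (ok(d, a)) { depth[v, s] <<- d; alt[v, s] <<- a; return(NULL) }
    }
    stop("could not draw qualifying read evidence")
  }
  seg <- which(truth$category == "diagnosis" |
                 startsWith(truth$category, "trait_"))
  for (v in seg) {
    for (s in which(copies[v, ] > 0)) {
      gt <- c("hom_ref", "het", "hom_alt")[copies[v, s] + 1L]
      if (!passes_read_support(gt, depth[v, s], alt[v, s], flt)) {
        redraw_until(v, ids[s], function(d, a)
          passes_read_support(gt, d, a, flt))
      }
    }
  }
  dn <- which(truth$category == "de_novo")
  for (v in dn) {
    ch <- truth$carriers[v]
    i <- match(ch, ids)
    if (!(depth[v, i] > flt$dn_min_depth && alt[v, i] >= flt$dn_min_child_alt &&
          alt[v, i] / depth[v, i] > flt$dn_min_child_af)) {
      redraw_until(v, ch, function(d, a)
        d > flt$dn_min_depth && a >= flt$dn_min_child_alt &&
          a / d > flt$dn_min_child_af)
    }
    r <- match(ch, ped$individual_id)
    for (p in c(ped$father_id[r], ped$mother_id[r])) {
      i <- match(p, ids)
      if (!(depth[v, i] > flt$dn_min_depth &&
            alt[v, i] / depth[v, i] < flt$dn_max_parent_af)) {
        redraw_until(v, p, function(d, a)
          d > flt$dn_min_depth && d > 0 && a / d < flt$dn_max_parent_af)
      }
    }
  }
  list(depth = depth, alt = alt)
}

.write_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gl_dir <- file.path(dir, "genelists")
  dir.create(gl_dir, showWarnings = FALSE)
  ped <- sim$ped
  paths <- list(
    ped = file.path(dir, "cohort.ped"),
    traits = file.path(dir, "traits.csv"),
    vcf = file.path(dir, "cohort.vcf"),
    annotations = file.path(dir, "annotations.tsv"),
    constraint = file.path(dir, "constraint.tsv"),
    norms = file.path(dir, "norms.yml"),
    tiers = file.path(gl_dir, "tiers.yml"),
    truth = file.path(dir, "truth.tsv"))
  phen <- c(diagnosed = "2", suspected = "0", non_autistic = "1",
            unknown = "0")[ped$diagnosis]
  writeLines(paste(ped$family_id, ped$individual_id, ped$father_id,
                   ped$mother_id,
                   c(male = "1", female = "2")[ped$sex], phen,
                   ped$diagnosis, sep = "\t"), paths$ped)
  tr <- data.frame(individual_id = ped$individual_id,
                   instrument = ped$instrument,
                   score = sprintf("%.4f", ped$trait_score))
  utils::write.table(tr, paths$traits, sep = ",", quote = FALSE,
                     row.names = FALSE)
  .write_vcf(sim$geno, paths$vcf)
  ann <- sim$ann
  ann$maf_nfe <- ifelse(is.na(ann$maf_nfe), ".",
                        format(ann$maf_nfe, scientific = FALSE, trim = TRUE))
  utils::write.table(
    ann[c("chrom", "pos", "ref", "alt", "gene", "func_class", "maf_nfe",
          "sift", "polyphen_hdiv", "aa_change", "dbsnp")],
    paths$annotations, sep = "\t", quote = FALSE, row.names = FALSE,
    na = ".")
  utils::write.table(sim$constraint, paths$constraint, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = ".")
  norms_out <- lapply(sim$cfg$norms, function(x)
    list(mean = x$mean, sd = x$sd))
  yaml::write_yaml(norms_out, paths$norms)
  tier_cfg <- list()
  for (t in c("tier1", "tier2", "tier3")) {
    tl <- sim$tiers[[t]]
    if (!length(tl)) next
    tier_cfg[[t]] <- list()
    for (src in names(tl)) {
      fn <- paste0(tolower(src), ".txt")
      writeLines(tl[[src]], file.path(gl_dir, fn))
      tier_cfg[[t]][[src]] <- fn
    }
  }
  yaml::write_yaml(tier_cfg, paths$tiers)
  utils::write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  paths
}

.write_vcf <- function(geno, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=famseg-simulate",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$samples), collapse = "\t"))
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               missing = "./.")
  body <- vapply(seq_len(nrow(geno$sites)), function(k) {
    cells <- sprintf("%s:%d:%d,%d", gt_code[geno$gt[k, ]],
                     as.integer(geno$depth[k, ]),
                     as.integer(geno$depth[k, ] - geno$alt_reads[k, ]),
                     as.integer(geno$alt_reads[k, ]))
    paste(c(geno$sites$chrom[k], geno$sites$pos[k], ".",
            geno$sites$ref[k], geno$sites$alt[k], ".", "PASS", ".",
            "GT:DP:AD", cells), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
}

#' Count Mendelian violations
#'
#' For every genotyped child with both parents genotyped, counts
#' (child, site) genotype configurations impossible under Mendelian
#' transmission: a het child of two hom-ref (or two hom-alt) parents, a
#' hom-alt child with a hom-ref parent, or a hom-ref child with a hom-alt
#' parent. Sites listed in `exclude_keys` (e.g. planted de novo variants)
#' are skipped; missing genotypes never count.
#'
#' @param geno `fam_geno` object.
#' @param ped Pedigree data frame (`individual_id`, `father_id`,
#'   `mother_id`).
#' @param exclude_keys Character vector of site keys to ignore.
#' @return Integer violation count.
#' @export
mendelian_check <- function(geno, ped, exclude_keys = NULL) {
  cp <- matrix(NA_integer_, nrow(geno$sites), length(geno$samples),
               dimnames = list(NULL, geno$samples))
  cp[geno$gt == "hom_ref"] <- 0L
  cp[geno$gt == "het"] <- 1L
  cp[geno$gt == "hom_alt"] <- 2L
  keep <- !(geno$sites$key %in% exclude_keys)
  total <- 0L
  for (i in seq_len(nrow(ped))) {
    fa <- ped$father_id[i]; mo <- ped$mother_id[i]
    ch <- ped$individual_id[i]
    if (fa == "0" || mo == "0") next
    if (!all(c(ch, fa, mo) %in% geno$samples)) next
    cc <- cp[keep, ch]; p1 <- cp[keep, fa]; p2 <- cp[keep, mo]
    bad <- (cc == 1L & ((p1 == 0L & p2 == 0L) | (p1 == 2L & p2 == 2L))) |
      (cc == 2L & (p1 == 0L | p2 == 0L)) |
      (cc == 0L & (p1 == 2L | p2 == 2L))
    total <- total + sum(bad, na.rm = TRUE)
  }
  total
}
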