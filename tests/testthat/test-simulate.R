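study_sim <- function(seed, ...) {
  simulate_cohort(sim_config(seed = seed, ...))
}

test_that("the default cohort matches the study shape", {
  sim <- study_sim(1, n_noise = 0)
  expect_equal(nrow(sim$ped), 112)
  expect_equal(sum(sim$ped$diagnosis == "diagnosed"), 76)
  expect_equal(sum(sim$ped$diagnosis == "suspected"), 4)
  expect_equal(sum(sim$ped$sex == "female"), 50)
  ft <- family_table(sim$cohort)
  expect_equal(nrow(ft), 21)
  # every family is highly multiplex except the reduced family "10"
  expect_equal(ft$family_id[!ft$highly_multiplex], "10")
  expect_equal(sum(ft$n_diagnosed >= 4), 10)

  # the written bundle loads back to the same cohort counts, with the
  # reduced family flagged
  d <- tempfile()
  sim <- study_sim(1, n_noise = 0)
  paths <- simulate_cohort(sim_config(seed = 1, n_noise = 0), dir = d)$paths
  expect_warning(
    co <- suppressMessages(load_cohort(paths$ped, paths$traits, paths$norms)),
    "10")
  expect_equal(nrow(co), 112)
  expect_equal(sum(co$diagnosis == "diagnosed"), 76)
  expect_equal(as.character(co$trait_group), as.character(sim$ped$trait_group))
})

test_that("identical seeds give byte-identical bundles, different seeds differ", {
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  simulate_cohort(sim_config(seed = 5), dir = d1)
  simulate_cohort(sim_config(seed = 5), dir = d2)
  simulate_cohort(sim_config(seed = 6), dir = d3)
  for (f in c("cohort.vcf", "cohort.ped", "traits.csv", "annotations.tsv",
              "constraint.tsv", "truth.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  expect_false(identical(unname(tools::md5sum(file.path(d1, "cohort.vcf"))),
                         unname(tools::md5sum(file.path(d3, "cohort.vcf")))))
})

test_that("written VCF parses back to the in-memory genotypes", {
  d <- tempfile()
  sim <- simulate_cohort(sim_config(layout = "random", n_families = 4,
                                    n_diagnosis_plants = 2,
                                    n_trait_plants = c(BAP = 0, MAP = 0, NAP = 0),
                                    n_denovo_plants = 1, n_noise = 10,
                                    seed = 33), dir = d)
  g <- read_vcf(sim$paths$vcf)
  expect_equal(g$sites$key, sim$geno$sites$key)
  expect_identical(g$gt, sim$geno$gt)
  expect_equal(g$depth, sim$geno$depth + 0)
  expect_equal(g$alt_reads, sim$geno$alt_reads + 0)
  ann <- read_annotation_table(sim$paths$annotations)
  expect_setequal(ann$key, sim$ann$key)
})

test_that("noise-free cohorts are Mendelian apart from planted de novos", {
  sim <- study_sim(77, n_noise = 30, genotype_error = 0)
  dn_keys <- sim$truth$key[sim$truth$category == "de_novo"]
  expect_equal(mendelian_check(sim$geno, sim$ped, exclude_keys = dn_keys), 0)
  expect_equal(mendelian_check(sim$geno, sim$ped),
               length(dn_keys))
})

test_that("genotype-error violations sit within 3 sigma of the model", {
  eps <- 0.01
  sim <- study_sim(123, n_noise = 60, genotype_error = eps,
                   n_denovo_plants = 0)
  obs <- mendelian_check(sim$geno, sim$ped)
  # expectation computed from the generator's own error model: enumerate
  # the 2^3 toggle patterns per (child, site) on the pre-error genotypes
  viol <- function(cc, p1, p2) {
    (cc == 1 && ((p1 == 0 && p2 == 0) || (p1 == 2 && p2 == 2))) ||
      (cc == 2 && (p1 == 0 || p2 == 0)) ||
      (cc == 0 && (p1 == 2 || p2 == 2))
  }
  toggle <- function(g) if (g == 2) 2 else 1 - g
  p_viol <- function(cc, p1, p2) {
    pr <- 0
    for (tc in 0:1) for (t1 in 0:1) for (t2 in 0:1) {
      g <- c(if (tc) toggle(cc) else cc,
             if (t1) toggle(p1) else p1,
             if (t2) toggle(p2) else p2)
      w <- prod(ifelse(c(tc, t1, t2) == 1, eps, 1 - eps))
      if (viol(g[1], g[2], g[3])) pr <- pr + w
    }
    pr
  }
  pre <- sim$copies_pre_error
  noise <- which(sim$truth$category == "noise")
  ids <- sim$ped$individual_id
  mu <- 0; v2 <- 0
  for (i in seq_along(ids)) {
    fa <- sim$ped$father_id[i]; mo <- sim$ped$mother_id[i]
    if (fa == "0" || mo == "0") next
    for (k in noise) {
      p <- p_viol(pre[k, ids[i]], pre[k, fa], pre[k, mo])
      mu <- mu + p; v2 <- v2 + p * (1 - p)
    }
  }
  expect_gt(mu, 1)  # the configuration actually exercises the model
  expect_lt(abs(obs - mu), 3 * sqrt(v2) + 1e-9)
})

test_that("allele transmission at noise sites is unbiased", {
  trials <- 0; carried <- 0
  for (seed in 1:4) {
    sim <- simulate_cohort(sim_config(layout = "random", n_families = 8,
                                      n_children = c(3, 4),
                                      n_diagnosis_plants = 0,
                                      n_trait_plants = c(BAP = 0, MAP = 0,
                                                         NAP = 0),
                                      n_denovo_plants = 0, n_noise = 80,
                                      seed = 1000 + seed))
    cp <- sim$copies
    for (i in seq_len(nrow(sim$ped))) {
      fa <- sim$ped$father_id[i]; mo <- sim$ped$mother_id[i]
      if (fa == "0" || mo == "0") next
      ch <- sim$ped$individual_id[i]
      het1 <- (cp[, fa] == 1 & cp[, mo] == 0) |
        (cp[, mo] == 1 & cp[, fa] == 0)
      trials <- trials + sum(het1)
      carried <- carried + sum(cp[het1, ch] > 0)
    }
  }
  expect_gt(trials, 500)
  p_hat <- carried / trials
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / trials))
})

test_that("unsatisfiable plants fail loudly", {
  # a cohort with no diagnosed members cannot host a diagnosis plant
  cfg <- sim_config(layout = "random", n_families = 2,
                    p_diagnosed_child = 0, p_diagnosed_parent = 0,
                    n_diagnosis_plants = 1,
                    n_trait_plants = c(BAP = 0, MAP = 0, NAP = 0),
                    n_denovo_plants = 0, n_noise = 0, seed = 2)
  expect_error(simulate_cohort(cfg), "unsatisfiable plant")
  # more de novo plants than trios
  cfg2 <- sim_config(layout = "random", n_families = 1, n_children = c(1, 1),
                     n_diagnosis_plants = 0,
                     n_trait_plants = c(BAP = 0, MAP = 0, NAP = 0),
                     n_denovo_plants = 5, n_noise = 0, seed = 2)
  expect_error(simulate_cohort(cfg2), "trios")
})

test_that("three-generation layouts produce trios at both levels", {
  sim <- simulate_cohort(sim_config(layout = "random", n_families = 2,
                                    generations = 3, n_children = c(2, 2),
                                    n_diagnosis_plants = 0,
                                    n_trait_plants = c(BAP = 0, MAP = 0,
                                                       NAP = 0),
                                    n_denovo_plants = 0, n_noise = 5,
                                    seed = 9))
  tr <- enumerate_trios(sim$cohort)
  # the first child is both a trio child and a parent of grandchildren
  expect_true(all(paste0("F", 1:2, "_C1") %in% tr$child))
  expect_true(all(paste0("F", 1:2, "_C1") %in% tr$father))
})
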