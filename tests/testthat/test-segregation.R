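cfg <- filter_config()

test_that("diagnosis rule needs two diagnosed carriers and a clean background", {
  fam <- make_family(c("d1", "d2", "d3", "n1", "s1"),
                     c("diagnosed", "diagnosed", "diagnosed",
                       "non_autistic", "suspected"))
  ids <- fam$individual_id
  expect_true(diagnosis_segregation(make_carrier_set(c("d1", "d2"), ids), fam))
  expect_false(diagnosis_segregation(make_carrier_set("d1", ids), fam))
  expect_false(diagnosis_segregation(
    make_carrier_set(c("d1", "d2", "n1"), ids), fam))
  # suspected members may carry without vetoing but do not count
  expect_true(diagnosis_segregation(
    make_carrier_set(c("d1", "d2", "s1"), ids), fam))
  expect_false(diagnosis_segregation(
    make_carrier_set(c("d1", "s1"), ids), fam))
  # a raw (read-support-failing) non-autistic carrier still vetoes
  cs <- list(carriers = c("d1", "d2"), non_carriers = character(),
             raw_carriers = c("d1", "d2", "n1"))
  expect_false(diagnosis_segregation(cs, fam))
  expect_true(diagnosis_segregation(
    cs, fam, filter_config(veto_on_raw_genotype = FALSE)))
})

test_that("trait rule returns the minimum carrier band", {
  fam <- make_family(c("a", "b", "c", "d", "e"), "unknown",
                     c("NAP", "MAP", "BAP", "AVERAGE", NA))
  ids <- fam$individual_id
  expect_equal(trait_segregation(make_carrier_set(c("a", "b"), ids), fam), "MAP")
  expect_equal(trait_segregation(make_carrier_set("a", ids), fam), "none")
  expect_equal(trait_segregation(make_carrier_set(c("c", "d"), ids), fam), "none")
  expect_equal(trait_segregation(make_carrier_set(c("a", "b", "c"), ids), fam),
               "BAP")
  # unscored carriers neither count nor veto
  expect_equal(trait_segregation(make_carrier_set(c("a", "e"), ids), fam),
               "none")
  expect_equal(trait_segregation(make_carrier_set(c("a", "b", "e"), ids), fam),
               "MAP")
  # raising any carrier above the current minimum leaves the level unchanged
  fam2 <- make_family(c("a", "b", "c"), "unknown", c("MAP", "MAP", "NAP"))
  expect_equal(trait_segregation(
    make_carrier_set(c("a", "b", "c"), fam2$individual_id), fam2), "MAP")
  fam3 <- make_family(c("a", "b", "c"), "unknown", c("MAP", "NAP", "NAP"))
  expect_equal(trait_segregation(
    make_carrier_set(c("a", "b", "c"), fam3$individual_id), fam3), "MAP")
})

test_that("segregation rules match a brute-force oracle on small families", {
  set.seed(99)
  statuses <- c("diagnosed", "suspected", "non_autistic", "unknown")
  groups <- c("AVERAGE", "BAP", "MAP", "NAP", NA)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    fam <- make_family(paste0("i", seq_len(n)),
                       sample(statuses, n, replace = TRUE),
                       sample(groups, n, replace = TRUE))
    ids <- fam$individual_id
    for (sub in all_subsets(ids)) {
      cs <- make_carrier_set(sub, ids)
      expect_equal(diagnosis_segregation(cs, fam),
                   oracle_diagnosis(sub, fam),
                   info = paste("diag", rep, paste(sub, collapse = "+")))
      expect_equal(trait_segregation(cs, fam),
                   oracle_trait(sub, fam),
                   info = paste("trait", rep, paste(sub, collapse = "+")))
    }
  }
})

test_that("diagnosis hits are monotone in non-autistic carriers", {
  set.seed(7)
  fam <- make_family(paste0("i", 1:6),
                     c("diagnosed", "diagnosed", "diagnosed",
                       "non_autistic", "non_autistic", "suspected"))
  ids <- fam$individual_id
  for (sub in all_subsets(ids)) {
    hit <- diagnosis_segregation(make_carrier_set(sub, ids), fam)
    for (na_id in intersect(c("i4", "i5"), sub)) {
      # removing a non-autistic carrier never un-prioritises
      expect_true(!hit ||
        diagnosis_segregation(make_carrier_set(setdiff(sub, na_id), ids), fam))
    }
    for (na_id in setdiff(c("i4", "i5"), sub)) {
      # adding one never creates a hit
      expect_false(
        diagnosis_segregation(make_carrier_set(c(sub, na_id), ids), fam) &&
          !hit)
    }
  }
})

test_that("family prioritisation recovers planted variants and only them", {
  fam <- make_family(c("d1", "d2", "d3", "n1"),
                     c("diagnosed", "diagnosed", "diagnosed", "non_autistic"),
                     c("NAP", "NAP", "MAP", "AVERAGE"))
  sites <- data.frame(chrom = "1", pos = c(100L, 200L, 300L),
                      id = NA_character_, ref = "A", alt = "T",
                      stringsAsFactors = FALSE)
  gt <- matrix("hom_ref", 3, 4,
               dimnames = list(NULL, fam$individual_id))
  gt[1, c("d1", "d2", "d3")] <- "het"       # clean diagnosis+trait hit
  gt[2, c("d1", "d2", "n1")] <- "het"       # vetoed by the non-autistic carrier
  gt[3, c("d1", "d2")] <- "het"             # hit, but gene not constrained
  geno <- make_geno(sites, gt)
  ann <- data.frame(chrom = "1", pos = c(100L, 200L, 300L), ref = "A",
                    alt = "T", gene = c("G1", "G2", "G3"),
                    func_class = "stopgain", maf_nfe = NA_real_,
                    sift = NA_character_, polyphen_hdiv = NA_character_,
                    aa_change = NA_character_, dbsnp = NA_character_,
                    stringsAsFactors = FALSE)
  ann$key <- site_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  con <- data.frame(gene = c("G1", "G2", "G3"), pli = c(0.99, 0.99, 0.1),
                    loeuf = c(0.1, 0.1, 1.2), stringsAsFactors = FALSE)
  out <- prioritise_family(fam, geno, ann, con, cfg)
  expect_equal(out$gene, "G1")
  expect_equal(out$label, "MAP/Diagnosis")
  expect_equal(out$carriers, "d1,d2,d3")

  # diagnosis mode needs two diagnosed genotyped members
  fam2 <- make_family(c("d1", "n1"), c("diagnosed", "non_autistic"))
  geno2 <- make_geno(sites, gt[, c("d1", "n1"), drop = FALSE])
  expect_warning(
    out2 <- prioritise_family(fam2, geno2, ann, con, cfg, mode = "diagnosis"),
    "fewer than 2 diagnosed")
  expect_equal(nrow(out2), 0)
})

test_that("cohort results are the concatenation of independent families", {
  rp <- table1_replay()
  whole <- suppressMessages(
    prioritise_cohort(rp$cohort, rp$geno, rp$ann, rp$constraint))
  per_fam <- lapply(split(as.data.frame(rp$cohort), rp$cohort$family_id),
                    function(f) suppressMessages(
                      prioritise_family(f, rp$geno, rp$ann, rp$constraint)))
  manual <- do.call(rbind, per_fam[sort(names(per_fam))])
  rownames(manual) <- NULL
  expect_equal(whole, manual)
})

test_that("gene summaries classify approaches across families", {
  toy <- data.frame(
    gene = c("A", "A", "B", "C"),
    family = c("f1", "f2", "f1", "f3"),
    trait_level = c("NAP", "none", "MAP", "none"),
    diagnosis_hit = c(FALSE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  s <- summarise_genes(toy)
  expect_equal(unname(s$venn), c(1L, 1L, 1L))
  expect_equal(s$genes$approach[s$genes$gene == "A"], "both")
  expect_equal(s$genes$families[s$genes$gene == "A"], "f1,f2")
  expect_equal(s$genes$best_trait_level[s$genes$gene == "A"], "NAP")
  empty <- summarise_genes(toy[0, ])
  expect_equal(unname(empty$venn), c(0L, 0L, 0L))
})
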