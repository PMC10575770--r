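cfg <- filter_config()

test_that("read-support gates follow the depth and het-fraction thresholds", {
  expect_false(passes_read_support("het", 9, 5, cfg))
  expect_true(passes_read_support("het", 30, 10, cfg))   # 0.333 >= 0.33
  expect_false(passes_read_support("het", 30, 9, cfg))   # 0.30 < 0.33
  expect_true(passes_read_support("hom_ref", 10, 0, cfg))
  expect_true(passes_read_support("hom_alt", 10, 10, cfg))
  # missing evidence fails closed
  expect_false(passes_read_support("het", NA, 10, cfg))
  expect_false(passes_read_support("het", 30, NA, cfg))
  expect_false(passes_read_support("missing", 30, 15, cfg))
})

test_that("rare-damaging decisions match the qualifying-set definition", {
  mk <- function(func, maf, sift, poly) {
    data.frame(func_class = func, maf_nfe = maf, sift = sift,
               polyphen_hdiv = poly, stringsAsFactors = FALSE)
  }
  # frequency gate dominates
  expect_false(is_rare_damaging(mk("nonsynonymous_snv", 0.02, "D", "D"), cfg))
  # absent MAF is treated as rare
  expect_true(is_rare_damaging(mk("stopgain", NA, NA, NA), cfg))
  expect_false(is_rare_damaging(mk("stopgain", NA, NA, NA),
                                filter_config(missing_maf_is_rare = FALSE)))

  # exhaustive missense truth table over SIFT x PolyPhen calls:
  # only SIFT D with PolyPhen D or P qualifies
  grid <- expand.grid(sift = c("D", "T", NA),
                      poly = c("D", "P", "B", NA),
                      stringsAsFactors = FALSE)
  got <- is_rare_damaging(mk("nonsynonymous_snv", 0.005, grid$sift,
                             grid$poly), cfg)
  want <- !is.na(grid$sift) & grid$sift == "D" &
    !is.na(grid$poly) & grid$poly %in% c("D", "P")
  expect_equal(got, want)

  # disruptive classes qualify regardless of predictor calls
  for (fc in c("stopgain", "stoploss", "frameshift_insertion",
               "frameshift_deletion")) {
    expect_true(is_rare_damaging(mk(fc, 0.001, NA, NA), cfg))
  }
  # synonymous/other never; splicing only on the de novo side by default
  expect_false(is_rare_damaging(mk("synonymous", 0.001, "D", "D"), cfg))
  expect_false(is_rare_damaging(mk("other", 0.001, "D", "D"), cfg))
  expect_false(is_rare_damaging(mk("splicing", 0.001, NA, NA), cfg))
  expect_true(is_rare_damaging(mk("splicing", 0.001, NA, NA), cfg,
                               context = "de_novo"))
  expect_true(is_rare_damaging(mk("splicing", 0.001, NA, NA),
                               filter_config(splicing_in_inherited = TRUE)))
  # de novo frequency bound is <=, inherited is <
  expect_false(is_rare_damaging(mk("stopgain", 0.01, NA, NA), cfg))
  expect_true(is_rare_damaging(mk("stopgain", 0.01, NA, NA), cfg,
                               context = "de_novo"))
})

test_that("lowering the MAF threshold never admits new variants", {
  set.seed(42)
  ann <- data.frame(
    func_class = "stopgain",
    maf_nfe = c(NA, runif(60, 0, 0.03)),
    sift = NA_character_, polyphen_hdiv = NA_character_,
    stringsAsFactors = FALSE)
  thresholds <- sort(runif(8, 0, 0.03), decreasing = TRUE)
  prev <- rep(TRUE, nrow(ann))
  for (t in thresholds) {
    cur <- is_rare_damaging(ann, filter_config(maf_threshold = t))
    expect_true(all(!cur | prev))  # cur subset of prev
    prev <- cur
  }
})

test_that("constraint gating respects mode semantics", {
  con <- data.frame(gene = c("A", "B", "C", "D"),
                    pli = c(0.95, 0.5, NA, 0.9),
                    loeuf = c(NA, 0.30, 0.80, 0.37),
                    stringsAsFactors = FALSE)
  expect_equal(is_constrained(c("A", "B", "C", "D", "ZZZ"), con, cfg),
               c(TRUE, TRUE, FALSE, TRUE, FALSE))
  # pLI threshold is >=, LOEUF strict <
  expect_true(is_constrained("D", con, cfg))
  expect_false(is_constrained("D", con,
                              filter_config(constraint_mode = "loeuf_only")))
  inter <- filter_config(constraint_mode = "intersection")
  expect_equal(is_constrained(c("A", "B"), con, inter), c(FALSE, FALSE))

  # intersection pass set is a subset of the union pass set
  set.seed(5)
  rnd <- data.frame(gene = paste0("g", 1:50),
                    pli = ifelse(runif(50) < 0.2, NA, runif(50)),
                    loeuf = ifelse(runif(50) < 0.2, NA, runif(50, 0, 2)),
                    stringsAsFactors = FALSE)
  u <- is_constrained(rnd$gene, rnd, cfg)
  i <- is_constrained(rnd$gene, rnd, inter)
  expect_true(all(!i | u))
})
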