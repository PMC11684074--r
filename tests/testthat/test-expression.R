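test_that("TNM staging follows the printed rules", {
  expect_equal(classify_tnm("T2", "N0", "M0"), "primary")
  expect_equal(classify_tnm("T3", "N2", "M1"), "metastasized")
  expect_equal(classify_tnm("T1", "NX", "M0"), "excluded")
  expect_equal(classify_tnm("TX", "N0", "M0"), "excluded")
  expect_equal(classify_tnm("T2a", "N1b", "M0"), "metastasized")  # sub-stages
  # N0 + M1 matches no printed rule: excluded strictly, staged inclusively
  expect_warning(strict <- classify_tnm("T2", "N0", "M1"), "no staging rule")
  expect_equal(strict, "excluded")
  expect_equal(classify_tnm("T2", "N0", "M1", mode = "inclusive"), "metastasized")
  expect_error(classify_tnm("2", "N0", "M0"), "malformed")
})

make_toy_study <- function() {
  md <- data.frame(
    sample_id = c("n1", "n2", "p1", "p2", "m1", "m2", "x1"),
    cancer_type = "CT1", source = c("normal", "normal", rep("tumour", 5)),
    T = c("T0", "T0", "T1", "T2", "T3", "T2", "T1"),
    N = c("N0", "N0", "N0", "N0", "N1", "N2", "NX"),
    M = c("M0", "M0", "M0", "M0", "M0", "M1", "M0"),
    stringsAsFactors = FALSE)
  mat <- matrix(seq_len(2 * 7), nrow = 2,
                dimnames = list(c("g1", "g2"), md$sample_id))
  expression_study(mat, md)
}

test_that("cohorts partition samples and exclude missing TNM codes", {
  study <- suppressMessages(build_cohorts(make_toy_study()))
  co <- study$cohorts$CT1
  expect_setequal(co$normal, c("n1", "n2"))
  expect_setequal(co$primary, c("p1", "p2"))
  expect_setequal(co$metastatic, c("m1", "m2"))
  expect_false("x1" %in% unlist(co))
  expect_true(all(unlist(co) %in% colnames(study$matrix)))
})

test_that("a cancer type lacking a cohort has that transition skipped", {
  study <- make_toy_study()
  study$metadata <- study$metadata[study$metadata$source != "normal", ]
  study$matrix <- study$matrix[, study$metadata$sample_id]
  study <- suppressMessages(build_cohorts(study))
  cands <- data.frame(symbol = "g1", emt_connectivity = 1, total_degree = 1,
                      status = "final", doids = "", stringsAsFactors = FALSE)
  class(cands) <- c("candidate_table", "data.frame")
  expect_warning(hits <- suppressMessages(call_hits(cands, study)),
                 "normal_primary transition skipped")
  expect_true(all(hits$transition == "primary_metastatic"))
})

test_that("fold change uses later/earlier cohort means with an epsilon guard", {
  fc <- fold_change(c(1, 2, 3), c(6, 8, 10))
  expect_equal(fc$fc, 4, tolerance = 1e-3)
  expect_equal(fc$log2fc, 2, tolerance = 1e-3)
  expect_equal(fold_change(c(5, 5), c(5, 5))$log2fc, 0)
  expect_message(z <- fold_change(c(0, 0), c(1, 1)), "pseudocount")
  expect_equal(z$fc, (1 + 0.001) / 0.001)
  # antisymmetry when eps is negligible
  ab <- fold_change(c(10, 12), c(30, 34))$log2fc
  ba <- fold_change(c(30, 34), c(10, 12))$log2fc
  expect_equal(ab, -ba, tolerance = 1e-4)
})

test_that("Kruskal-Wallis reproduces the hand-computed rank statistic", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  # H = 12/(6*7) * (6^2/3 + 15^2/3) - 3*7 = 3.857...
  expect_equal(kw$h_stat, 3.857143, tolerance = 1e-6)
  expect_equal(kw$p_value, 0.04953461, tolerance = 1e-6)
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2)))$p_value, 1)
  # rank invariance under permutation of sample order
  a <- kruskal_wallis(list(c(3, 1, 7, 2), c(9, 4, 8)))
  b <- kruskal_wallis(list(c(7, 2, 3, 1), c(8, 9, 4)))
  expect_identical(a, b)
  expect_error(kruskal_wallis(list(1:3)), "length")
})

test_that("tiers follow the printed bands with strict bounds", {
  expect_equal(stratify(2.5, 0.0005), "high")
  expect_equal(stratify(1.5, 0.005), "medium")
  expect_equal(stratify(1.5, 0.03), "low")
  expect_equal(stratify(-2.5, 0.0005), "high")   # |log2FC| is signless
  expect_equal(stratify(0.5, 0.2), "non_significant")
  expect_equal(stratify(2.5, 0.005), "unclassified")  # strong FC, mid p
  expect_equal(stratify(1.5, 0.0005), "unclassified") # mid FC, strong p
})

test_that("the five tiers are mutually exclusive and exhaustive", {
  set.seed(77)
  l2fc <- runif(500, -4, 4)
  p <- runif(500)
  tiers <- stratify(l2fc, p)
  expect_true(all(tiers %in% c("high", "medium", "low", "non_significant",
                               "unclassified")))
  # boundary points land in exactly one bucket (unclassified, by strictness)
  expect_equal(stratify(2, 0.0005), "unclassified")
  expect_equal(stratify(3, 0.001), "unclassified")
  expect_equal(stratify(1.5, 0.05), "unclassified")
})

test_that("Kruskal-Wallis type-I error is calibrated at the nominal level", {
  n_sig <- 0
  n_sim <- 500
  withr::with_seed(42, {
    for (i in seq_len(n_sim)) {
      a <- rlnorm(20, 3, 1); b <- rlnorm(20, 3, 1)
      if (kruskal_wallis(list(a, b))$p_value < 0.05) n_sig <- n_sig + 1
    }
  })
  rate <- n_sig / n_sim
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("hit calling flags planted primary-to-metastatic effects only", {
  cfg <- synth_config(seed = 15)
  res <- run_planted_pipeline(15, cfg)
  pm <- res$hits[res$hits$transition == "primary_metastatic", ]
  np <- res$hits[res$hits$transition == "normal_primary", ]
  expect_gte(sum(pm$is_hit & pm$gene %in% res$planted), 9)
  expect_false(any(np$is_hit))  # hits are transition-specific by definition
  expect_true(all(res$hits$is_hit ==
                  (res$hits$transition == "primary_metastatic" &
                   res$hits$tier %in% c("high", "medium"))))
  # a gene planted only in normal->primary is not a hit
  cfg2 <- synth_config(seed = 16, planted_transition = "normal_primary")
  res2 <- run_planted_pipeline(16, cfg2)
  pm2 <- res2$hits[res2$hits$transition == "primary_metastatic", ]
  expect_lte(sum(pm2$is_hit & pm2$gene %in% res2$planted), 2)
  np2 <- res2$hits[res2$hits$transition == "normal_primary", ]
  expect_gte(sum(np2$tier %in% c("high", "medium") &
                 np2$gene %in% res2$planted), 8)
})

test_that("candidates absent from the matrix are skipped with a note", {
  study <- suppressMessages(build_cohorts(make_toy_study()))
  cands <- data.frame(symbol = c("g1", "ghost"),
                      emt_connectivity = 1, total_degree = 1,
                      status = "final", doids = "", stringsAsFactors = FALSE)
  class(cands) <- c("candidate_table", "data.frame")
  expect_message(hits <- suppressWarnings(call_hits(cands, study)), "absent")
  expect_false("ghost" %in% hits$gene)
})
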