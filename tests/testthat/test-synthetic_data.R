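test_that("generators are deterministic and leave the global RNG untouched", {
  set.seed(999)
  before <- .Random.seed
  p1 <- gen_variant_panel(12, block_spec = list(c(4, 0.8), c(4, 0), c(4, 0)),
                          seed = 5)
  expect_identical(.Random.seed, before)
  p2 <- gen_variant_panel(12, block_spec = list(c(4, 0.8), c(4, 0), c(4, 0)),
                          seed = 5)
  expect_identical(p1, p2)

  c1 <- gen_cohort(p1$truth, 50, timepoints = 8, n_metabolites = 2,
                   truth = cohort_truth(0.1, seed = 3))
  c2 <- gen_cohort(p1$truth, 50, timepoints = 8, n_metabolites = 2,
                   truth = cohort_truth(0.1, seed = 3))
  expect_identical(c1, c2)

  t1 <- gen_two_sample(10, two_sample_truth(0.1, seed = 4))
  t2 <- gen_two_sample(10, two_sample_truth(0.1, seed = 4))
  expect_identical(t1, t2)
})

test_that("a single-variant panel has an identity LD matrix", {
  p <- gen_variant_panel(1, seed = 1)
  expect_equal(unname(p$ld), matrix(1))
})

test_that("an all-singleton panel is fully retained by clumping", {
  p <- gen_variant_panel(72, seed = 8)
  expect_equal(max(abs(p$ld[upper.tri(p$ld)])), 0)
  expect_equal(length(ld_clump(p$stats, p$ld, 0.001)), 72L)
})

test_that("block structure yields one clumping survivor per correlated block", {
  p <- gen_variant_panel(6, block_spec = list(c(3, 0.9), c(1, 0), c(1, 0),
                                              c(1, 0)), seed = 7)
  kept <- ld_clump(p$stats, p$ld, 0.001)
  expect_equal(length(kept), 4L)
  expect_equal(kept, oracle_clump(p$stats$id, p$stats$p, p$ld, 0.001))
  # cross-block r2 exactly zero; within correlated block near target
  block1 <- p$truth$id[p$truth$block == 1]
  others <- setdiff(p$truth$id, block1)
  expect_equal(max(abs(p$ld[block1, others])), 0)
  within <- p$ld[block1, block1][upper.tri(diag(3))]
  expect_true(all(within > 0.8 & within <= 1))
})

test_that("panel p-values are genome-wide significant and invariants hold", {
  p <- gen_variant_panel(40, seed = 13)
  expect_true(all(p$stats$p < 5e-8))
  expect_true(all(p$truth$maf > 0 & p$truth$maf <= 0.5))
  expect_true(all(is.finite(p$truth$weight)))
  expect_error(gen_variant_panel(5, block_spec = list(c(3, 0.5))),
               "sum to n_variants")
})

test_that("dosage means track 2*MAF within sampling error", {
  p <- gen_variant_panel(20, block_spec = list(c(5, 0.7), c(5, 0), c(5, 0),
                                               c(5, 0)), seed = 17)
  cc <- gen_cohort(p$truth, 2000, timepoints = 8, n_metabolites = 1,
                   truth = cohort_truth(0, seed = 18))
  means <- colMeans(cc$dosages)
  expected <- 2 * p$truth$maf
  se3 <- 3 * sqrt(2 * p$truth$maf * (1 - p$truth$maf) / 2000)
  expect_true(all(abs(means - expected) <= se3))
  expect_true(all(cc$dosages >= 0 & cc$dosages <= 2))
})

test_that("standardized metabolites have near-unit marginal SD", {
  p <- gen_variant_panel(30, seed = 19)
  cc <- gen_cohort(p$truth, 3000, timepoints = c(8, 25), n_metabolites = 4,
                   truth = cohort_truth(c(0.1, 0.05, 0, 0), seed = 20))
  for (col in grep("met", names(cc$cohort), value = TRUE)) {
    expect_equal(sd(cc$cohort[[col]]), 1, tolerance = 0.08)
  }
})

test_that("a noiseless single-SNP metabolite is an affine function of dosage", {
  p <- gen_variant_panel(1, seed = 21)
  cc <- gen_cohort(p$truth, 100, timepoints = 8, n_metabolites = 1,
                   truth = cohort_truth(1, noise_sd = 0, sex_effect = 0,
                                        age_effect = 0, standardize = FALSE,
                                        seed = 22))
  g <- cc$dosages[, 1]
  m <- cc$cohort$met001_8
  slope <- p$truth$weight[1] / log(2)  # theta * w / ln 2 per allele
  expect_equal(m, slope * g, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("null-effect cohorts give scan estimates centred on zero", {
  p <- gen_variant_panel(20, seed = 23)
  w <- weights_from_stats(p$stats)
  est <- vapply(1:30, function(s) {
    cc <- gen_cohort(p$truth, 400, timepoints = 8, n_metabolites = 1,
                     truth = cohort_truth(0, seed = 3000 + s))
    sc <- grs_table(cc$dosages, w)
    suppressMessages(run_scan(cc$cohort, sc))$beta_per_doubling
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est)), 3 * mc_se + 1e-12)
})

test_that("two-sample truth objects enforce their invariants", {
  expect_error(two_sample_truth(0.1, 0.2, "none"), "requires prop_invalid = 0")
  expect_error(two_sample_truth(0.1, 1.2, "balanced"), "\\[0, 1\\]")
  expect_warning(two_sample_truth(0.1, 0.6, "directional", 0.1),
                 "violated by design")
  tr <- two_sample_truth(0.1, 0.3, "balanced", pleiotropy_sd = 0.05, seed = 2)
  expect_equal(tr$prop_invalid, 0.3)
})

test_that("two-sample outcome betas follow theta * bx plus pleiotropy", {
  tr <- two_sample_truth(0.2, seed = 25)
  ts <- gen_two_sample(500, tr, se_exposure = 1e-6, se_outcome = 1e-6)
  # nearly noiseless: by/bx = theta
  expect_equal(ts$outcome$beta / ts$exposure$beta, rep(0.2, 500),
               tolerance = 1e-3)
  expect_true(all(ts$exposure$p < 5e-8))
  expect_equal(ts$exposure$effect_allele, ts$outcome$effect_allele)
})

test_that("balanced pleiotropy is mean-zero and directional is not", {
  bal <- gen_two_sample(400, two_sample_truth(0, 0.5, "balanced",
                                              pleiotropy_sd = 0.2, seed = 26),
                        se_outcome = 1e-4)
  invalid <- bal$truth$invalid
  expect_equal(length(invalid), 200L)
  resid <- bal$outcome$beta[invalid]
  expect_lt(abs(mean(resid)), 3 * sd(resid) / sqrt(length(invalid)))

  dir_ts <- suppressWarnings(gen_two_sample(
    400, suppressWarnings(two_sample_truth(0, 0.5, "directional",
                                           pleiotropy_sd = 0.2, seed = 27)),
    se_outcome = 1e-4))
  resid_d <- dir_ts$outcome$beta[dir_ts$truth$invalid]
  expect_gt(mean(resid_d), 0.15)
})

test_that("synthetic outputs round-trip through the i/o layer", {
  p <- gen_variant_panel(8, seed = 29)
  dir <- withr::local_tempdir()
  write_summary_stats(p$stats, file.path(dir, "stats.tsv"))
  write_ld_matrix(p$ld, file.path(dir, "ld.tsv"))
  write_truth(p$truth, file.path(dir, "truth.yaml"))
  back <- read_summary_stats(file.path(dir, "stats.tsv"))
  expect_equal(back$beta, p$stats$beta, tolerance = 1e-11)
  expect_equal(read_ld_matrix(file.path(dir, "ld.tsv")), p$ld,
               tolerance = 1e-11)
  tr <- read_truth(file.path(dir, "truth.yaml"))
  expect_equal(tr$weight, p$truth$weight, tolerance = 1e-5)
})
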