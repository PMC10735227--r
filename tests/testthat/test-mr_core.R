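test_that("instrument selection applies the p-filter before clumping", {
  st <- make_stats(sprintf("rs%d", 1:10), beta = 0.1, se = 0.01,
                   p = rep(1e-9, 10))
  expect_setequal(select_instruments(st), st$id)

  weak <- make_stats(sprintf("rs%d", 1:5), beta = 0.1, se = 0.02, p = 1e-6)
  expect_error(select_instruments(weak), "uninstrumentable")
})

test_that("selection on a generated LD-blocked panel keeps one variant per block", {
  panel <- gen_variant_panel(6, block_spec = list(c(3, 0.9), c(1, 0),
                                                  c(1, 0), c(1, 0)), seed = 7)
  kept <- select_instruments(panel$stats, panel$ld)
  expect_equal(length(kept), 4L)
  expect_equal(sum(kept %in% panel$truth$id[panel$truth$block == 1]), 1L)
})

test_that("harmonization flips swapped alleles and resolves palindromes by frequency", {
  ex <- make_stats("rs1", beta = 0.1, se = 0.01, p = 1e-9,
                   ea = "A", oa = "G", eaf = 0.3)
  ou <- make_stats("rs1", beta = -0.05, se = 0.02, p = 0.01,
                   ea = "G", oa = "A", eaf = 0.7)
  hs <- harmonize(ex, ou)
  expect_equal(hs$beta_out, 0.05)
  expect_equal(hs$eaf_out, 0.3)

  # palindromic with ambiguous frequency: dropped (here the only variant)
  exp_pal <- make_stats("rs2", beta = 0.1, se = 0.01, p = 1e-9,
                        ea = "A", oa = "T", eaf = 0.5)
  out_pal <- make_stats("rs2", beta = 0.05, se = 0.02, p = 0.01,
                        ea = "A", oa = "T", eaf = 0.5)
  expect_error(suppressMessages(harmonize(exp_pal, out_pal)), "no instruments")

  # palindromic, frequencies on opposite sides of 0.5: outcome flipped
  exp_pal2 <- make_stats("rs3", beta = 0.1, se = 0.01, p = 1e-9,
                         ea = "A", oa = "T", eaf = 0.10)
  out_pal2 <- make_stats("rs3", beta = 0.05, se = 0.02, p = 0.01,
                         ea = "A", oa = "T", eaf = 0.88)
  hs3 <- harmonize(exp_pal2, out_pal2)
  expect_equal(hs3$beta_out, -0.05)
  expect_equal(hs3$eaf_out, 0.12)
})

test_that("incompatible allele pairs and absent instruments are dropped with reasons", {
  ex <- make_stats(c("rs1", "rs2", "rs3"), beta = 0.1, se = 0.01, p = 1e-9,
                   ea = "A", oa = "G", eaf = 0.3)
  ou_df <- data.frame(id = c("rs1", "rs2"),
                      effect_allele = c("A", "A"), other_allele = c("G", "C"),
                      eaf = 0.3, beta = 0.05, se = 0.02, p = 0.01)
  ou <- summary_stats(ou_df, trait = "out")
  expect_message(hs <- harmonize(ex, ou), "dropped 2")
  expect_equal(hs$id, "rs1")
  drops <- attr(hs, "drops")
  expect_setequal(drops$reason,
                  c("incompatible alleles", "absent from outcome"))
})

test_that("a scrambled-allele synthetic pair is fully restored by harmonization", {
  clean <- gen_two_sample(30, two_sample_truth(0.1, seed = 9))
  scrambled <- gen_two_sample(30, two_sample_truth(0.1, seed = 9),
                              scramble_alleles = TRUE)
  hs_clean <- harmonize(clean$exposure, clean$outcome)
  hs_scr <- harmonize(scrambled$exposure, scrambled$outcome)
  expect_equal(hs_scr$beta_out, hs_clean$beta_out, tolerance = 1e-12)
  expect_equal(hs_scr$eaf_out, hs_clean$eaf_out, tolerance = 1e-12)
})

test_that("Wald ratios follow the first-order delta rule", {
  wr <- wald_ratio(0.1, 0.02, 0.05, 0.01)
  expect_equal(wr$ratio, 0.5)
  expect_equal(wr$se, 0.1)
  wr2 <- wald_ratio(-0.1, 0.02, 0.05, 0.01)
  expect_equal(wr2$ratio, -0.5)
  expect_equal(wr2$se, 0.1)
  expect_equal(wald_ratio(1, 0.1, 0.37, 0.1)$ratio, 0.37)
  expect_error(wald_ratio(0, 0.1, 0.1, 0.1), "zero exposure")
})

test_that("IVW reproduces the hand-derived three-instrument example", {
  hs <- make_hs(bx = c(1, 1, 1), sx = 0.01,
                by = c(0.2, 0.3, 0.4), sy = c(0.1, 0.1, 0.2))
  est <- ivw_random_effects(hs)
  expect_equal(est$beta, 0.26667, tolerance = 1e-4)
  expect_equal(est$q_stat, 1.0, tolerance = 1e-10)
  expect_equal(est$q_df, 2L)
  # Q below its expectation: multiplier floored at 1, SE stays fixed-effect
  expect_equal(est$se, 0.06667, tolerance = 1e-4)
  expect_equal(est$ci_low, est$beta - 1.96 * est$se, tolerance = 1e-10)
})

test_that("IVW equals weighted least squares through the origin", {
  set.seed(23)
  for (rep in 1:100) {
    n <- sample(3:100, 1)
    bx <- runif(n, 0.03, 0.2) * sample(c(-1, 1), n, TRUE)
    hs <- make_hs(bx, sx = 0.01, by = 0.1 * bx + rnorm(n, 0, 0.05),
                  sy = runif(n, 0.02, 0.1))
    est <- ivw_random_effects(hs)
    expect_equal(est$beta, oracle_wls_origin(hs$beta_exp, hs$beta_out,
                                             hs$se_out), tolerance = 1e-10)
    # multiplicative random-effects SE never below fixed-effect SE
    w <- (hs$se_out / abs(hs$beta_exp))^-2
    expect_gte(est$se, sum(w)^-0.5 - 1e-12)
  }
})

test_that("homogeneous ratios give Q = 0 and a single instrument falls back", {
  hs <- make_hs(c(0.1, 0.2, 0.4), 0.01, c(0.05, 0.10, 0.20), 0.02)
  est <- ivw_random_effects(hs)
  expect_equal(est$q_stat, 0, tolerance = 1e-20)
  expect_equal(est$beta, 0.5, tolerance = 1e-12)

  single <- make_hs(0.1, 0.02, 0.05, 0.01)
  est1 <- ivw_random_effects(single)
  expect_equal(est1$beta, 0.5)
  expect_equal(est1$se, 0.1)
  expect_match(est1$method, "single instrument")
})

test_that("the weighted median reproduces hand interpolation and the unweighted case", {
  hs_eq <- make_hs(c(1, 1, 1), 0.01, c(1, 2, 3), 1)
  expect_equal(weighted_median(hs_eq, n_boot = 0)$beta, 2)

  # weights (0.5, 0.25, 0.25): s = (0.25, 0.625, 0.875), interpolate
  hs_w <- make_hs(c(1, 1, 1), 0.01, c(1, 2, 3), c(1/sqrt(2), 1, 1))
  expect_equal(weighted_median(hs_w, n_boot = 0)$beta, 1 + 0.25 / 0.375,
               tolerance = 1e-10)
  expect_equal(weighted_median(hs_w, n_boot = 0)$beta, 1.6667,
               tolerance = 1e-4)

  expect_error(weighted_median(make_hs(c(1, 1), 0.01, c(1, 2), 1), 0),
               ">= 3")
})

test_that("equal-weight weighted medians equal the sample median for odd counts", {
  set.seed(29)
  for (rep in 1:200) {
    n <- sample(c(3, 5, 7, 9, 11), 1)
    ratios <- rnorm(n)
    hs <- make_hs(rep(1, n), 0.01, ratios, 1)
    expect_equal(weighted_median(hs, n_boot = 0)$beta, median(ratios),
                 tolerance = 1e-10)
  }
})

test_that("the weighted mode matches direct grid-density evaluation", {
  hs <- make_hs(rep(1, 4), 0.01, c(0.1, 0.1, 0.1, 0.9), 1)
  est <- weighted_mode(hs, n_boot = 0)
  orc <- oracle_mode_grid(c(0.1, 0.1, 0.1, 0.9), rep(1, 4))
  expect_equal(est$beta, orc, tolerance = 1e-12)
  # majority cluster dominates; kernel smoothing pulls the mode slightly
  # toward the outlier but it stays near the cluster
  expect_lt(abs(est$beta - 0.1), 0.05)

  set.seed(31)
  for (rep in 1:50) {
    n <- sample(4:30, 1)
    ratios <- rnorm(n, 0.2, 0.3)
    sy <- runif(n, 0.5, 2)
    hs <- make_hs(rep(1, n), 0.01, ratios, sy)
    expect_equal(weighted_mode(hs, n_boot = 0)$beta,
                 oracle_mode_grid(ratios, sy^-2), tolerance = 1e-12)
  }
})

test_that("identical ratios give a point-mass mode with zero SE", {
  hs <- make_hs(c(0.1, 0.2, 0.5), 0.01, c(0.03, 0.06, 0.15), 0.02)
  est <- weighted_mode(hs, n_boot = 100)
  expect_equal(est$beta, 0.3, tolerance = 1e-12)
  expect_equal(est$se, 0)
})

test_that("bootstrap SEs are reproducible under a seed and stable across seeds", {
  ts <- gen_two_sample(30, two_sample_truth(0.1, seed = 41))
  hs <- harmonize(ts$exposure, ts$outcome)
  a <- weighted_median(hs, n_boot = 2000, seed = 5)
  b <- weighted_median(hs, n_boot = 2000, seed = 5)
  expect_identical(a$se, b$se)
  c2 <- weighted_median(hs, n_boot = 2000, seed = 6)
  expect_lt(abs(a$se - c2$se) / a$se, 0.05)

  m1 <- weighted_mode(hs, n_boot = 2000, seed = 5)
  m2 <- weighted_mode(hs, n_boot = 2000, seed = 6)
  expect_lt(abs(m1$se - m2$se) / m1$se, 0.05)
})

test_that("estimators are sign-equivariant in the exposure betas", {
  ts <- gen_two_sample(20, two_sample_truth(0.15, seed = 43))
  hs <- harmonize(ts$exposure, ts$outcome)
  neg <- hs
  neg$beta_exp <- -neg$beta_exp
  expect_equal(ivw_random_effects(neg)$beta, -ivw_random_effects(hs)$beta,
               tolerance = 1e-12)
  expect_equal(weighted_median(neg, n_boot = 0)$beta,
               -weighted_median(hs, n_boot = 0)$beta, tolerance = 1e-12)
  expect_equal(weighted_mode(neg, n_boot = 0)$beta,
               -weighted_mode(hs, n_boot = 0)$beta, tolerance = 1e-9)
})

test_that("instrument strength follows (beta/se)^2 with a weak-instrument flag", {
  hs <- make_hs(c(0.6, 0.632455532, 0.7), c(0.1, 0.1, 0.1), 0.1, 0.05)
  s <- instrument_strength(hs)
  expect_equal(s$f[1], 36, tolerance = 1e-10)
  expect_equal(s$f_min, 36, tolerance = 1e-10)
  expect_equal(s$f_median, 40, tolerance = 1e-6)
  expect_false(s$weak)

  weak <- make_hs(0.1, 0.1, 0.05, 0.05)
  expect_warning(sw <- instrument_strength(weak), "weak")
  expect_equal(sw$f_min, 1)
  expect_true(sw$weak)
})

test_that("odds-ratio conversion exponentiates estimate and bounds once only", {
  est <- mrtri:::mr_estimate_row("IVW-RE", 0, 0.05, 10L)
  or0 <- to_odds_ratio(est)
  expect_equal(or0$beta, 1)

  est2 <- mrtri:::mr_estimate_row("IVW-RE", log(2), 0.05, 10L)
  expect_equal(to_odds_ratio(est2)$beta, 2, tolerance = 1e-12)

  est3 <- mrtri:::mr_estimate_row("IVW-RE", 0.1, 0.05, 10L)
  est3$ci_low <- 0.02; est3$ci_high <- 0.18
  or3 <- to_odds_ratio(est3)
  expect_equal(or3$beta, 1.1052, tolerance = 1e-4)
  expect_equal(or3$ci_low, 1.0202, tolerance = 1e-4)
  expect_equal(or3$ci_high, 1.1972, tolerance = 1e-4)
  expect_equal(or3$se, 0.05)  # SE stays on the log scale
  expect_error(to_odds_ratio(or3), "already")
})

test_that("reverse runs scale to per-doubling and forward runs to odds ratios", {
  ts <- gen_two_sample(25, two_sample_truth(0.1, seed = 47))
  rev <- run_mr(ts$exposure, list(met1 = ts$outcome), direction = "reverse",
                n_boot = 50)
  expect_equal(unique(rev$scale), "per-doubling")
  kept <- select_instruments(ts$exposure)
  ivw_raw <- ivw_random_effects(harmonize(ts$exposure, ts$outcome, kept))
  expect_equal(rev$beta[rev$method == "IVW-RE"], ivw_raw$beta * log(2),
               tolerance = 1e-12)
  expect_true(all(c("f_min", "f_median", "p_fdr") %in% names(rev)))

  fwd <- run_mr(list(met1 = ts$exposure), ts$outcome, direction = "forward",
                n_boot = 50)
  expect_equal(unique(fwd$scale), "OR")
  expect_equal(fwd$beta[fwd$method == "IVW-RE"], exp(ivw_raw$beta),
               tolerance = 1e-12)
  expect_equal(fwd$ci_low[fwd$method == "IVW-RE"], exp(ivw_raw$ci_low),
               tolerance = 1e-12)
  # p-values unchanged by either rescaling
  expect_equal(rev$p[rev$method == "IVW-RE"], ivw_raw$p, tolerance = 1e-12)
  expect_equal(fwd$p[fwd$method == "IVW-RE"], ivw_raw$p, tolerance = 1e-12)
})
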