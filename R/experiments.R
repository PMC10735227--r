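# Simulation experiments: parameter recovery, calibration, and robustness
# of the estimators under the generative models the synthetic module
# encodes. These drivers are what the package's own validation runs; they
# are exported so the studies can be reproduced or extended.

#' Estimator calibration under valid instruments
#'
#' Repeatedly generates clean two-sample data (no pleiotropy) with a known
#' causal effect and re-estimates it with IVW, weighted median, and
#' weighted mode. Reports each method's mean point estimate with its
#' Monte-Carlo standard error, and the empirical coverage of the IVW 95%
#' confidence interval.
#'
#' @param n_reps Number of simulation replicates.
#' @param n_instruments Instruments per replicate.
#' @param theta True causal effect.
#' @param seed Base seed; replicate r uses `seed * 1000 + r`.
#' @param se_exposure,se_outcome Per-variant standard errors.
#' @return List: `mean` (named, per method), `mc_se` (named), `coverage`
#'   (IVW), `theta`, `n_reps`.
#' @export
calibration_experiment <- function(n_reps = 500L, n_instruments = 50L,
                                   theta = 0.1, seed = 1L,
                                   se_exposure = 0.01, se_outcome = 0.05) {
  est <- matrix(NA_real_, n_reps, 3L,
                dimnames = list(NULL, c("ivw", "median", "mode")))
  covered <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    ts <- gen_two_sample(n_instruments,
                         two_sample_truth(theta, seed = seed * 1000 + r),
                         se_exposure = se_exposure, se_outcome = se_outcome)
    hs <- harmonize(ts$exposure, ts$outcome)
    iv <- ivw_random_effects(hs)
    est[r, "ivw"] <- iv$beta
    covered[r] <- iv$ci_low <= theta && theta <= iv$ci_high
    est[r, "median"] <- weighted_median(hs, n_boot = 0)$beta
    est[r, "mode"] <- weighted_mode(hs, n_boot = 0)$beta
  }
  list(mean = colMeans(est),
       mc_se = apply(est, 2L, stats::sd) / sqrt(n_reps),
       coverage = mean(covered), theta = theta, n_reps = n_reps)
}

#' Robustness ordering under directional pleiotropy
#'
#' Generates two-sample data in which a fraction of instruments carry a
#' directional (positive-mean) pleiotropic path to the outcome, and
#' measures each estimator's bias. With fewer than half the instruments
#' invalid, the weighted median and weighted mode should be markedly less
#' biased than IVW.
#'
#' @inheritParams calibration_experiment
#' @param prop_invalid Fraction of directionally pleiotropic instruments.
#' @param pleiotropy_sd Scale of the pleiotropic effects.
#' @return List: `bias` (named, per method), `mc_se` (named), `theta`,
#'   `n_reps`.
#' @export
pleiotropy_experiment <- function(n_reps = 500L, n_instruments = 50L,
                                  theta = 0.1, prop_invalid = 0.4,
                                  pleiotropy_sd = 0.1, seed = 1L,
                                  se_exposure = 0.01, se_outcome = 0.02) {
  est <- matrix(NA_real_, n_reps, 3L,
                dimnames = list(NULL, c("ivw", "median", "mode")))
  for (r in seq_len(n_reps)) {
    tr <- two_sample_truth(theta, prop_invalid, "directional",
                           pleiotropy_sd = pleiotropy_sd,
                           seed = seed * 1000 + r)
    ts <- gen_two_sample(n_instruments, tr, se_exposure = se_exposure,
                         se_outcome = se_outcome)
    hs <- harmonize(ts$exposure, ts$outcome)
    est[r, "ivw"] <- ivw_random_effects(hs)$beta
    est[r, "median"] <- weighted_median(hs, n_boot = 0)$beta
    est[r, "mode"] <- weighted_mode(hs, n_boot = 0)$beta
  }
  list(bias = colMeans(est) - theta,
       mc_se = apply(est, 2L, stats::sd) / sqrt(n_reps),
       theta = theta, n_reps = n_reps)
}

#' Scan parameter recovery on synthetic cohorts
#'
#' Generates repeated cohorts downstream of one liability panel, runs the
#' full GRS scan, and compares the mean recovered per-doubling estimate of
#' the causal metabolites with the generative truth; also reports the
#' FDR-flag rate among null metabolites.
#'
#' @param n_seeds Number of cohort replicates.
#' @param n_individuals Cohort size per replicate.
#' @param n_snps Panel size.
#' @param n_causal,n_null Causal and null metabolite counts.
#' @param theta Per-doubling effect of the causal metabolites (SD units).
#' @param seed Base seed.
#' @return List: `mean_estimate`, `mc_se`, `null_flag_rate`,
#'   `null_flag_mc_se`, `theta`, `n_seeds`.
#' @export
scan_recovery_experiment <- function(n_seeds = 200L, n_individuals = 5000L,
                                     n_snps = 65L, n_causal = 20L,
                                     n_null = 20L, theta = 0.05, seed = 1L) {
  panel <- gen_variant_panel(n_snps, seed = seed)
  w <- weights_from_stats(panel$stats)
  thetas <- c(rep(theta, n_causal), rep(0, n_null))
  causal_mean <- numeric(n_seeds)
  null_rate <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    cc <- gen_cohort(panel$truth, n_individuals, timepoints = 18,
                     n_metabolites = n_causal + n_null,
                     truth = cohort_truth(thetas, seed = seed * 1000 + s))
    sc <- grs_table(cc$dosages, w)
    res <- suppressMessages(run_scan(cc$cohort, sc))
    causal <- res$metabolite %in% cc$truth$metabolites[seq_len(n_causal)]
    causal_mean[s] <- mean(res$beta_per_doubling[causal])
    null_rate[s] <- mean(res$flag[!causal])
  }
  list(mean_estimate = mean(causal_mean),
       mc_se = stats::sd(causal_mean) / sqrt(n_seeds),
       null_flag_rate = mean(null_rate),
       null_flag_mc_se = stats::sd(null_rate) / sqrt(n_seeds),
       theta = theta, n_seeds = n_seeds)
}

#' End-to-end triangulation recovery
#'
#' Builds a complete synthetic study in which a chosen subset of
#' metabolites is causal in every stream's sense — downstream of the
#' liability score in the cohort, affected by liability in the reverse
#' two-sample world, and causal for disease in the forward world, all
#' with consistent directions — then runs the scan, both MR directions,
#' and the triangulation classifier, and compares the recovered
#' consistent-causal-candidate list with the generated causal set.
#'
#' @param seed Integer seed.
#' @param n_metabolites Total metabolites.
#' @param n_causal Number of causal metabolites (alternating signs).
#' @param n_individuals Cohort size for the scan stream.
#' @param n_snps Liability panel size.
#' @param n_instruments Instruments per MR trait.
#' @param effect Effect magnitude used in all three streams.
#' @param n_boot Bootstrap resamples inside [run_mr].
#' @return List: `candidates`, `causal`, `classes` (the triangulation
#'   table), `summary`.
#' @export
triangulation_recovery_experiment <- function(seed = 1L,
                                              n_metabolites = 15L,
                                              n_causal = 5L,
                                              n_individuals = 3000L,
                                              n_snps = 60L,
                                              n_instruments = 40L,
                                              effect = 0.15,
                                              n_boot = 200L) {
  mets <- sprintf("met%03d", seq_len(n_metabolites))
  dir_k <- rep(c(1, -1), length.out = n_causal)
  thetas <- stats::setNames(rep(0, n_metabolites), mets)
  thetas[seq_len(n_causal)] <- effect * dir_k

  # scan stream
  panel <- gen_variant_panel(n_snps, weight_sd = 0.1, seed = seed * 7 + 1)
  cc <- gen_cohort(panel$truth, n_individuals, timepoints = 18,
                   n_metabolites = n_metabolites,
                   truth = cohort_truth(unname(thetas), seed = seed * 7 + 2))
  sc <- grs_table(cc$dosages, weights_from_stats(panel$stats))
  scan <- suppressMessages(run_scan(cc$cohort, sc))

  # reverse stream: liability -> metabolites
  rev_set <- gen_reverse_set(n_instruments, thetas, seed = seed * 7 + 3,
                             se_outcome = 0.02)
  rev <- run_mr(rev_set$exposure, rev_set$outcomes, direction = "reverse",
                n_boot = n_boot, seed = seed * 7 + 4)

  # forward stream: metabolites -> disease
  fwd_set <- gen_forward_set(n_instruments, thetas, seed = seed * 7 + 5,
                             se_outcome = 0.02)
  fwd <- run_mr(fwd_set$exposures, fwd_set$outcome, direction = "forward",
                n_boot = n_boot, seed = seed * 7 + 6)

  rows <- classify_consistency(scan, rev, fwd)
  list(candidates = rows$metabolite[rows$class == "consistent-causal-candidate"],
       causal = mets[seq_len(n_causal)],
       classes = rows,
       summary = summarize_triangulation(rows))
}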