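# Synthetic-data generators. The real inputs (cohort genotypes and
# metabolite measures; disease and metabolite GWAS summary statistics) are
# managed-access, so these generators produce data with the statistical
# structure the pipeline assumes: an LD-blocked disease-liability panel,
# a longitudinal cohort whose metabolites are partly downstream of the
# liability score, and paired two-sample summary statistics with
# configurable horizontal pleiotropy. Every generator draws all its
# randomness from a single seeded stream and leaves the global RNG state
# untouched.

NONPALINDROMIC_PAIRS <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                                 "G", "A", "G", "T", "T", "C", "T", "G"),
                               ncol = 2L, byrow = TRUE)

#' Truth parameters for a synthetic cohort
#'
#' @param theta Per-metabolite effect, in SD units of metabolite per
#'   doubling of genetic liability. Recycled or length `n_metabolites`;
#'   zeros mark null metabolites.
#' @param noise_sd Residual SD of each metabolite; `NULL` (with
#'   `standardize = TRUE`) chooses it so the marginal variance is ~1.
#' @param sex_effect,age_effect Covariate effects in SD units (age effect
#'   per year, applied to age centred at the time-point mean).
#' @param standardize Aim for unit marginal SD by absorbing the explained
#'   variance into the noise term (keeps `theta` on its stated scale).
#' @param seed Integer seed.
#' @return List of class `cohort_truth`.
#' @export
cohort_truth <- function(theta, noise_sd = NULL, sex_effect = 0.1,
                         age_effect = 0.01, standardize = TRUE,
                         seed = 1L) {
  structure(list(theta = theta, noise_sd = noise_sd,
                 sex_effect = sex_effect, age_effect = age_effect,
                 standardize = standardize, seed = as.integer(seed)),
            class = "cohort_truth")
}

#' Truth parameters for a paired two-sample dataset
#'
#' @param theta True causal effect of the exposure on the outcome, per
#'   unit exposure.
#' @param prop_invalid Fraction of instruments with a horizontal
#'   pleiotropic path to the outcome.
#' @param mode Pleiotropy mode: `"none"`, `"balanced"` (zero-mean), or
#'   `"directional"` (positive-mean).
#' @param pleiotropy_sd Scale of the pleiotropic effects: balanced draws
#'   `Normal(0, sd)`, directional draws `Normal(+sd, sd/2)`.
#' @param seed Integer seed.
#' @return List of class `two_sample_truth`.
#' @export
two_sample_truth <- function(theta, prop_invalid = 0,
                             mode = c("none", "balanced", "directional"),
                             pleiotropy_sd = 0, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "none" && prop_invalid != 0) {
    stop("mode 'none' requires prop_invalid = 0", call. = FALSE)
  }
  if (prop_invalid < 0 || prop_invalid > 1) {
    stop("prop_invalid must lie in [0, 1]", call. = FALSE)
  }
  if (mode == "directional" && prop_invalid >= 0.5) {
    warning("half or more of the instruments are directionally invalid: ",
            "the weighted-median consistency assumption is violated by design",
            call. = FALSE)
  }
  structure(list(theta = theta, prop_invalid = prop_invalid, mode = mode,
                 pleiotropy_sd = pleiotropy_sd, seed = as.integer(seed)),
            class = "two_sample_truth")
}

# Latent Gaussian correlation giving a target allele-level correlation r
# after dichotomizing both margins at qnorm(maf). Solved numerically from
# the bivariate-normal orthant probability.
latent_rho_for_allele_corr <- function(r, maf) {
  if (r <= 0) return(0)
  t <- stats::qnorm(maf)
  phi_of <- function(rho) {
    if (rho >= 1) return(1)
    p11 <- stats::integrate(function(z) {
      stats::pnorm((t - rho * z) / sqrt(1 - rho^2)) * stats::dnorm(z)
    }, -Inf, t, rel.tol = 1e-9)$value
    (p11 - maf^2) / (maf * (1 - maf))
  }
  if (phi_of(0.9999) <= r) return(0.9999)
  stats::uniroot(function(rho) phi_of(rho) - r, c(1e-6, 0.9999),
                 tol = 1e-7)$root
}

# Draw an n x J dosage matrix for a blocked panel via a Gaussian copula:
# two latent allele draws per individual, equicorrelated within block.
draw_dosages <- function(n, maf, blocks, block_r2) {
  J <- length(maf)
  g <- matrix(0L, n, J)
  for (b in unique(blocks)) {
    cols <- which(blocks == b)
    k <- length(cols)
    r2 <- block_r2[b]
    if (k == 1L || r2 <= 0) {
      for (j in cols) g[, j] <- stats::rbinom(n, 2L, maf[j])
      next
    }
    rho <- latent_rho_for_allele_corr(sqrt(r2), mean(maf[cols]))
    cmat <- matrix(rho, k, k); diag(cmat) <- 1
    L <- chol(cmat)
    thr <- stats::qnorm(maf[cols])
    for (draw in 1:2) {
      z <- matrix(stats::rnorm(n * k), n, k) %*% L
      g[, cols] <- g[, cols] + (z < matrix(thr, n, k, byrow = TRUE))
    }
  }
  g
}

#' Generate a disease-liability variant panel
#'
#' Produces a disease summary-statistics table (observed betas are the
#' true liability weights plus small estimation noise, with standard
#' errors scaled so every p-value is genome-wide significant), a
#' block-diagonal empirical LD matrix, and the generative truth. LD
#' blocks are realised through a Gaussian copula over latent allele
#' scores sized to hit the target r-squared approximately; the matrix
#' returned is the empirical r-squared of a seeded reference sample
#' (cross-block and zero-target entries are exactly 0 by construction),
#' and it — not the target — is what clumping sees.
#'
#' @param n_variants Number of variants (>= 1).
#' @param maf_range Minor-allele-frequency interval within `(0, 0.5]`.
#' @param weight_sd SD of the true per-allele log-odds weights.
#' @param block_spec List of `c(size, r2)` pairs partitioning the panel;
#'   `NULL` makes every variant its own block (no LD).
#' @param seed Integer seed.
#' @param z_range Range of the |z|-statistics assigned to the panel;
#'   the default keeps all p-values below 5e-8.
#' @param n_ref Size of the reference sample used for the empirical LD
#'   matrix.
#' @return List: `stats` ([summary_stats]), `ld` (matrix), `truth`
#'   (`panel_truth`: `id`, `maf`, `weight`, `block`, `block_r2`, `seed`).
#' @export
gen_variant_panel <- function(n_variants, maf_range = c(0.05, 0.5),
                              weight_sd = 0.05, block_spec = NULL,
                              seed = 1L, z_range = c(6, 15),
                              n_ref = 2000L) {
  if (n_variants < 1L) stop("n_variants must be >= 1", call. = FALSE)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  }
  if (is.null(block_spec)) {
    block_spec <- lapply(seq_len(n_variants), function(i) c(1, 0))
  }
  sizes <- vapply(block_spec, `[`, numeric(1), 1L)
  r2s <- vapply(block_spec, `[`, numeric(1), 2L)
  r2s[is.na(r2s)] <- 0
  if (sum(sizes) != n_variants) {
    stop("block sizes must sum to n_variants", call. = FALSE)
  }
  if (any(r2s < 0 | r2s > 1)) stop("block r2 must lie in [0, 1]", call. = FALSE)

  withr::with_seed(seed, {
    ids <- sprintf("rs%05d", seq_len(n_variants))
    maf <- stats::runif(n_variants, maf_range[1], maf_range[2])
    weight <- stats::rnorm(n_variants, 0, weight_sd)
    blocks <- rep(seq_along(sizes), times = sizes)
    # tightly linked variants have near-identical allele frequencies;
    # sharing one MAF per correlated block also keeps the copula's
    # realized r-squared close to its target
    for (b in which(r2s > 0)) {
      cols <- which(blocks == b)
      if (length(cols) > 1L) maf[cols] <- maf[cols[1L]]
    }

    beta <- weight + stats::rnorm(n_variants, 0, 0.02 * weight_sd)
    z <- stats::runif(n_variants, z_range[1], z_range[2])
    se <- pmax(abs(beta), 1e-6 * weight_sd) / z
    p <- 2 * stats::pnorm(-abs(beta) / se)

    pair <- NONPALINDROMIC_PAIRS[
      sample.int(nrow(NONPALINDROMIC_PAIRS), n_variants, replace = TRUE), ,
      drop = FALSE]

    # empirical LD from a reference sample; block-diagonal by construction
    ld <- diag(n_variants)
    dimnames(ld) <- list(ids, ids)
    if (any(r2s > 0)) {
      ref <- draw_dosages(n_ref, maf, blocks, r2s)
      for (b in which(r2s > 0)) {
        cols <- which(blocks == b)
        if (length(cols) > 1L) {
          ld[cols, cols] <- stats::cor(ref[, cols])^2
          diag(ld)[cols] <- 1
        }
      }
    }

    stats <- summary_stats(
      data.frame(id = ids,
                 chrom = as.character(sample.int(22L, n_variants, replace = TRUE)),
                 pos = sort(sample.int(1e8L, n_variants)),
                 effect_allele = pair[, 1L], other_allele = pair[, 2L],
                 eaf = maf, beta = beta, se = se, p = p,
                 stringsAsFactors = FALSE),
      trait = "disease", units = "logOR")

    truth <- structure(list(id = ids, maf = maf, weight = weight,
                            block = blocks, block_r2 = r2s,
                            seed = as.integer(seed)),
                       class = "panel_truth")
    list(stats = stats, ld = ld, truth = truth)
  })
}

#' Generate a longitudinal cohort downstream of a liability panel
#'
#' Dosages are Hardy-Weinberg draws (copula-correlated within LD blocks);
#' the liability score is `S_i = sum_j w_j g_ij` in log-odds units; each
#' metabolite at each time point is
#' `M = theta_k * S / ln(2) + sex and age effects + Gaussian noise`,
#' so `theta_k` is exactly the SD-unit effect per doubling of liability
#' that the scan estimates. With `standardize = TRUE` the noise SD is
#' chosen so the marginal metabolite variance is ~1.
#'
#' @param panel A `panel_truth` from [gen_variant_panel].
#' @param n_individuals Cohort size (>= 10).
#' @param timepoints Ages (years) of the repeated clinic visits.
#' @param n_metabolites Number of metabolites.
#' @param truth A [cohort_truth]; its `theta` is recycled to
#'   `n_metabolites`.
#' @return List: `dosages` (matrix with a `counted_allele` attribute),
#'   `cohort` (data frame: `id`, `sex`, `age_<tp>`, `met###_<tp>`), and
#'   `truth` (the input, with `theta` expanded and the realised
#'   `noise_sd` recorded).
#' @export
gen_cohort <- function(panel, n_individuals, timepoints = c(8, 16, 18, 25),
                       n_metabolites = 20L, truth = cohort_truth(0.05)) {
  if (n_individuals < 10L) stop("n_individuals must be >= 10", call. = FALSE)
  if (!length(timepoints)) stop("timepoints must be non-empty", call. = FALSE)
  theta <- rep_len(truth$theta, n_metabolites)

  withr::with_seed(truth$seed, {
    g <- draw_dosages(n_individuals, panel$maf, panel$block, panel$block_r2)
    dimnames(g) <- list(sprintf("id%05d", seq_len(n_individuals)), panel$id)
    storage.mode(g) <- "double"

    liab <- as.vector(g %*% panel$weight)       # log-odds units
    dbl <- liab / log(2)                        # doublings of liability
    sex <- stats::rbinom(n_individuals, 1L, 0.5)

    var_liab <- sum(panel$weight^2 * 2 * panel$maf * (1 - panel$maf))
    noise_sd <- truth$noise_sd
    if (is.null(noise_sd)) {
      if (!truth$standardize) stop("noise_sd must be given when standardize = FALSE",
                                   call. = FALSE)
      explained <- theta^2 * var_liab / log(2)^2 +
        truth$sex_effect^2 * 0.25 + truth$age_effect^2 / 12
      if (any(explained >= 1)) {
        stop("explained variance >= 1; cannot standardize", call. = FALSE)
      }
      noise_sd <- sqrt(1 - explained)
    } else {
      noise_sd <- rep_len(noise_sd, n_metabolites)
    }

    cohort <- data.frame(id = rownames(g), sex = sex,
                         stringsAsFactors = FALSE)
    met_names <- sprintf("met%03d", seq_len(n_metabolites))
    for (tp in timepoints) {
      age <- tp + stats::runif(n_individuals, -0.5, 0.5)
      cohort[[paste0("age_", tp)]] <- age
      for (k in seq_len(n_metabolites)) {
        m <- theta[k] * dbl + truth$sex_effect * sex +
          truth$age_effect * (age - mean(age)) +
          stats::rnorm(n_individuals, 0, noise_sd[k])
        cohort[[paste0(met_names[k], "_", tp)]] <- m
      }
    }
    # dosages count the effect allele of the panel's stats by construction,
    # so no counted_allele attribute (orientation already matches weights)
    out_truth <- truth
    out_truth$theta <- theta
    out_truth$noise_sd <- noise_sd
    out_truth$metabolites <- met_names
    list(dosages = g, cohort = cohort, truth = out_truth)
  })
}

#' Generate paired exposure/outcome two-sample summary statistics
#'
#' True exposure effects are drawn with random sign and magnitude around
#' `exposure_beta`; observed exposure betas add sampling noise
#' `se_exposure`. Outcome betas follow
#' `by_j = theta * bx_true_j + alpha_j + noise`, with `alpha_j = 0` for
#' valid instruments and drawn per the pleiotropy mode otherwise
#' (balanced: `Normal(0, sd)`; directional: `Normal(+sd, sd/2)`).
#' Alleles are consistent between the two tables unless
#' `scramble_alleles = TRUE`, which swaps the outcome's allele labels
#' (negating its beta and complementing its frequency) for a random half
#' of the variants — useful for exercising harmonization.
#'
#' @param n_instruments Number of instruments (>= 3).
#' @param truth A [two_sample_truth].
#' @param se_exposure,se_outcome Reported standard errors (> 0).
#' @param exposure_beta Typical magnitude of the true exposure effects;
#'   true effects are `sign * Uniform(0.5, 1.5) * exposure_beta`.
#' @param scramble_alleles Swap outcome allele labels for a random half
#'   of the variants.
#' @return List: `exposure`, `outcome` ([summary_stats]), `truth` (the
#'   input with the invalid-instrument index set recorded).
#' @export
gen_two_sample <- function(n_instruments, truth, se_exposure = 0.01,
                           se_outcome = 0.05, exposure_beta = 0.1,
                           scramble_alleles = FALSE) {
  if (n_instruments < 3L) stop("n_instruments must be >= 3", call. = FALSE)
  if (se_exposure <= 0 || se_outcome <= 0) stop("SEs must be > 0", call. = FALSE)

  withr::with_seed(truth$seed, {
    ids <- sprintf("rs%05d", seq_len(n_instruments))
    # instruments are reported with the exposure-raising allele as the
    # effect allele (the usual convention), so true exposure effects are
    # positive; this also keeps directional pleiotropy directional on the
    # Wald-ratio scale
    bx_true <- stats::runif(n_instruments, 0.5, 1.5) * exposure_beta
    bx <- bx_true + stats::rnorm(n_instruments, 0, se_exposure)

    n_invalid <- round(truth$prop_invalid * n_instruments)
    invalid <- sort(sample.int(n_instruments, n_invalid))
    alpha <- numeric(n_instruments)
    if (n_invalid > 0L) {
      alpha[invalid] <- switch(truth$mode,
        none = 0,
        balanced = stats::rnorm(n_invalid, 0, truth$pleiotropy_sd),
        directional = stats::rnorm(n_invalid, truth$pleiotropy_sd,
                                   truth$pleiotropy_sd / 2))
    }
    by <- truth$theta * bx_true + alpha +
      stats::rnorm(n_instruments, 0, se_outcome)

    eaf <- stats::runif(n_instruments, 0.1, 0.9)
    pair <- NONPALINDROMIC_PAIRS[
      sample.int(nrow(NONPALINDROMIC_PAIRS), n_instruments, replace = TRUE), ,
      drop = FALSE]
    base <- data.frame(id = ids,
                       chrom = as.character(sample.int(22L, n_instruments,
                                                       replace = TRUE)),
                       pos = sort(sample.int(1e8L, n_instruments)),
                       effect_allele = pair[, 1L], other_allele = pair[, 2L],
                       eaf = eaf, stringsAsFactors = FALSE)

    ex <- base
    ex$beta <- bx; ex$se <- se_exposure
    ex$p <- pmax(2 * stats::pnorm(-abs(bx) / se_exposure), 1e-300)

    ou <- base
    ou$beta <- by; ou$se <- se_outcome
    ou$p <- pmax(2 * stats::pnorm(-abs(by) / se_outcome), 1e-300)
    if (scramble_alleles) {
      flip <- sample(c(TRUE, FALSE), n_instruments, replace = TRUE)
      tmp <- ou$effect_allele[flip]
      ou$effect_allele[flip] <- ou$other_allele[flip]
      ou$other_allele[flip] <- tmp
      ou$beta[flip] <- -ou$beta[flip]
      ou$eaf[flip] <- 1 - ou$eaf[flip]
    }

    out_truth <- truth
    out_truth$invalid <- invalid
    out_truth$bx_true <- bx_true
    list(exposure = summary_stats(ex, trait = "exposure", units = "SD"),
         outcome = summary_stats(ou, trait = "outcome", units = "SD"),
         truth = out_truth)
  })
}

draw_instrument_base <- function(n, se_exposure, exposure_beta, prefix = "rs") {
  bx_true <- stats::runif(n, 0.5, 1.5) * exposure_beta
  bx <- bx_true + stats::rnorm(n, 0, se_exposure)
  pair <- NONPALINDROMIC_PAIRS[
    sample.int(nrow(NONPALINDROMIC_PAIRS), n, replace = TRUE), , drop = FALSE]
  list(bx_true = bx_true,
       base = data.frame(id = sprintf("%s%05d", prefix, seq_len(n)),
                         chrom = as.character(sample.int(22L, n, replace = TRUE)),
                         pos = sort(sample.int(1e8L, n)),
                         effect_allele = pair[, 1L], other_allele = pair[, 2L],
                         eaf = stats::runif(n, 0.1, 0.9),
                         beta = bx, se = se_exposure,
                         p = pmax(2 * stats::pnorm(-abs(bx) / se_exposure),
                                  1e-300),
                         stringsAsFactors = FALSE))
}

#' Generate a coherent reverse-MR study: one exposure, many outcomes
#'
#' One disease instrument set is drawn once, and each metabolite outcome
#' table is generated against it with its own causal effect
#' (`by = theta_k * bx_true + noise`), so the whole family can be run
#' through [run_mr] in the reverse direction exactly as a real analysis
#' would be.
#'
#' @param n_instruments Number of disease instruments.
#' @param thetas Named numeric vector: true effect of disease liability on
#'   each metabolite (per unit log-odds; zeros are nulls).
#' @param seed Integer seed.
#' @param se_exposure,se_outcome,exposure_beta As in [gen_two_sample].
#' @return List: `exposure` ([summary_stats]), `outcomes` (named list of
#'   [summary_stats]), `thetas`.
#' @export
gen_reverse_set <- function(n_instruments, thetas, seed = 1L,
                            se_exposure = 0.01, se_outcome = 0.05,
                            exposure_beta = 0.1) {
  withr::with_seed(seed, {
    ins <- draw_instrument_base(n_instruments, se_exposure, exposure_beta)
    outcomes <- lapply(thetas, function(th) {
      ou <- ins$base
      by <- th * ins$bx_true + stats::rnorm(n_instruments, 0, se_outcome)
      ou$beta <- by
      ou$se <- se_outcome
      ou$p <- pmax(2 * stats::pnorm(-abs(by) / se_outcome), 1e-300)
      summary_stats(ou, trait = "metabolite", units = "SD")
    })
    list(exposure = summary_stats(ins$base, trait = "disease",
                                  units = "logOR"),
         outcomes = outcomes, thetas = thetas)
  })
}

#' Generate a coherent forward-MR study: many exposures, one outcome
#'
#' Each metabolite gets its own instrument panel (globally unique variant
#' ids); the single disease outcome table stacks all instruments, each
#' affecting disease only through its metabolite
#' (`by = theta_k * bx_true + noise`, log-odds units).
#'
#' @inheritParams gen_reverse_set
#' @param thetas Named numeric vector: true log-odds effect of each
#'   metabolite on disease per unit of metabolite.
#' @return List: `exposures` (named list of [summary_stats]), `outcome`
#'   ([summary_stats]), `thetas`.
#' @export
gen_forward_set <- function(n_instruments, thetas, seed = 1L,
                            se_exposure = 0.01, se_outcome = 0.05,
                            exposure_beta = 0.1) {
  withr::with_seed(seed, {
    exposures <- list()
    outcome_rows <- list()
    for (k in seq_along(thetas)) {
      ins <- draw_instrument_base(n_instruments, se_exposure, exposure_beta,
                                  prefix = sprintf("m%02dv", k))
      exposures[[names(thetas)[k]]] <-
        summary_stats(ins$base, trait = names(thetas)[k], units = "SD")
      ou <- ins$base
      by <- thetas[k] * ins$bx_true + stats::rnorm(n_instruments, 0, se_outcome)
      ou$beta <- by
      ou$se <- se_outcome
      ou$p <- pmax(2 * stats::pnorm(-abs(by) / se_outcome), 1e-300)
      outcome_rows[[k]] <- ou
    }
    list(exposures = exposures,
         outcome = summary_stats(do.call(rbind, outcome_rows),
                                 trait = "disease", units = "logOR"),
         thetas = thetas)
  })
}
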