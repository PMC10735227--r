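#' Linear regression with heteroskedasticity-robust standard errors
#'
#' Ordinary least squares for the exposure term with a
#' heteroskedasticity-consistent sandwich standard error (HC1 scaling by
#' default, the conventional "robust" flavour; HC3 available). The p-value
#' uses the normal approximation, matching large-sample practice in
#' genetic association analysis.
#'
#' @param outcome Numeric outcome vector.
#' @param exposure Numeric exposure vector (the GRS in the scan).
#' @param covariates Optional numeric matrix of adjustment covariates.
#' @param flavour Sandwich flavour, `"HC1"` (default) or `"HC3"`.
#' @return List: `beta`, `se`, `p`, `n` for the exposure term.
#' @export
robust_linreg <- function(outcome, exposure, covariates = NULL,
                          flavour = c("HC1", "HC3")) {
  flavour <- match.arg(flavour)
  if (is.null(covariates)) {
    dat <- data.frame(outcome = outcome, exposure = exposure)
  } else {
    covariates <- as.matrix(covariates)
    dat <- data.frame(outcome = outcome, exposure = exposure, covariates)
  }
  n <- nrow(dat)
  if (n <= ncol(dat) + 2L) stop("too few observations for the design", call. = FALSE)
  fit <- stats::lm(outcome ~ ., data = dat)
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  vc <- sandwich::vcovHC(fit, type = flavour)
  beta <- stats::coef(fit)[["exposure"]]
  se <- sqrt(vc["exposure", "exposure"])
  z <- if (se > 0) beta / se else if (beta == 0) 0 else Inf
  list(beta = beta, se = se, p = 2 * stats::pnorm(-abs(z)), n = n)
}

#' Rescale an estimate to per-doubling of genetic liability
#'
#' Estimates from a regression on a log-odds-scale liability score are
#' multiplied by log(2) = 0.693 so that they read as the difference in
#' outcome per doubling of the odds of disease. The Wald p-value is
#' unchanged (the scaling is applied to the point estimate, standard
#' error, and both interval bounds alike).
#'
#' @param beta,se Estimate and standard error on the per-unit-log-odds
#'   scale.
#' @param ci_low,ci_high Optional interval bounds; computed as
#'   `beta +/- 1.96 * se` when omitted.
#' @return List: `beta`, `se`, `ci_low`, `ci_high`, each multiplied by
#'   log(2).
#' @export
scale_per_doubling <- function(beta, se, ci_low = NULL, ci_high = NULL) {
  if (is.null(ci_low)) ci_low <- beta - 1.96 * se
  if (is.null(ci_high)) ci_high <- beta + 1.96 * se
  k <- log(2)
  list(beta = beta * k, se = se * k, ci_low = ci_low * k, ci_high = ci_high * k)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values, returned in input order and capped at 1.
#'
#' @param pvalues Numeric vector of raw p-values in `(0, 1]`.
#' @return Adjusted p-values, same order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues) | pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Metabolome-wide GRS association scan
#'
#' Regresses each (rank-inverse-normal transformed) metabolite at each
#' time point on the liability score, adjusted for sex and centred age,
#' with HC1 robust standard errors; rescales estimates to per-doubling of
#' liability; and applies Benjamini-Hochberg FDR adjustment within each
#' time point x sensitivity family across metabolites.
#'
#' @param cohort Cohort data frame (see [gen_cohort] for the layout).
#' @param scores A [grs_table] data frame, or a named list of them — one
#'   per sensitivity setting (e.g. `list(all = ..., no_fads = ...)`, the
#'   second scored from a region-excluded weight set). A single unnamed
#'   table is labelled `"all"`.
#' @param timepoints,metabolites Subsets to scan; defaults to everything
#'   present in the cohort.
#' @param int_transform Apply [rank_inverse_normal] to each metabolite
#'   within time point before regression (default `TRUE`).
#' @param offset Rank offset passed to the transformation.
#' @param flavour Robust-SE flavour, passed to [robust_linreg].
#' @param alpha FDR threshold used for the association flag.
#' @return Data frame with one row per metabolite x time point x
#'   sensitivity: `metabolite`, `timepoint`, `n`, `beta_per_doubling`,
#'   `se`, `ci_low`, `ci_high`, `p`, `p_fdr`, `n_snps`, `sensitivity`,
#'   `flag`.
#' @export
run_scan <- function(cohort, scores, timepoints = NULL, metabolites = NULL,
                     int_transform = TRUE, offset = 3/8,
                     flavour = "HC1", alpha = 0.05) {
  if (is.data.frame(scores)) scores <- list(all = scores)
  if (is.null(names(scores)) || any(names(scores) == "")) {
    stop("each sensitivity score table must be named", call. = FALSE)
  }
  if (is.null(timepoints)) timepoints <- cohort_timepoints(cohort)
  if (is.null(metabolites)) metabolites <- cohort_metabolites(cohort)

  rows <- list()
  for (sens in names(scores)) {
    sc <- scores[[sens]]
    n_snps <- max(sc$n_snps)
    for (tp in timepoints) {
      work <- cohort
      if (int_transform) {
        for (m in metabolites) {
          col <- paste0(m, "_", tp)
          work[[col]] <- rank_inverse_normal(work[[col]], offset = offset)
        }
      }
      fam <- lapply(metabolites, function(m) {
        d <- build_design(work, m, tp, sc)
        fit <- robust_linreg(d$outcome, d$exposure, d$covariates,
                             flavour = flavour)
        sca <- scale_per_doubling(fit$beta, fit$se)
        data.frame(metabolite = m, timepoint = tp, n = fit$n,
                   beta_per_doubling = sca$beta, se = sca$se,
                   ci_low = sca$ci_low, ci_high = sca$ci_high,
                   p = fit$p, stringsAsFactors = FALSE)
      })
      fam <- do.call(rbind, fam)
      fam$p_fdr <- bh_adjust(fam$p)
      fam$n_snps <- n_snps
      fam$sensitivity <- sens
      rows[[length(rows) + 1L]] <- fam
    }
  }
  out <- do.call(rbind, rows)
  out$flag <- out$p_fdr < alpha
  rownames(out) <- NULL
  out
}
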