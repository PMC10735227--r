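# Two-sample MR machinery. All estimators operate on a harmonized
# instrument table and return one-row "mr_estimate" data frames so that
# run_mr() can stack them across traits and methods.

#' Select genetic instruments from exposure summary statistics
#'
#' Filters to genome-wide significance and then LD-clumps, the standard
#' two-step instrument selection (independence at r-squared below the
#' threshold, association at p below the threshold).
#'
#' @param exposure A [summary_stats] object.
#' @param ld LD matrix covering the significant candidates; `NULL` treats
#'   all candidates as mutually independent.
#' @param p_threshold Significance threshold, `5e-8` by default.
#' @param r2_threshold Clumping threshold, `0.001` by default.
#' @return Character vector of instrument ids.
#' @export
select_instruments <- function(exposure, ld = NULL, p_threshold = 5e-8,
                               r2_threshold = 0.001) {
  hits <- exposure[exposure$p < p_threshold, , drop = FALSE]
  if (nrow(hits) == 0L) {
    stop("uninstrumentable exposure: no variant passes p < ",
         format(p_threshold), call. = FALSE)
  }
  if (is.null(ld)) {
    ld <- diag(nrow(hits))
    dimnames(ld) <- list(hits$id, hits$id)
  }
  ld <- ld[intersect(rownames(ld), hits$id), intersect(colnames(ld), hits$id),
           drop = FALSE]
  ld_clump(hits, ld, r2_threshold)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the two tables to a common effect allele per variant. Where the
#' outcome's alleles are swapped relative to the exposure, the outcome
#' beta is sign-flipped and its frequency complemented. Palindromic
#' variants (A/T or C/G) cannot be aligned from alleles alone: they are
#' aligned by allele frequency when both frequencies are available and
#' unambiguous, and dropped when a frequency is missing or falls in the
#' ambiguity window. Variants with incompatible allele pairs, and
#' instruments absent from the outcome, are dropped. All drops are
#' recorded with reasons in the `drops` attribute.
#'
#' @param exposure,outcome [summary_stats] objects sharing variant ids.
#' @param instruments Optional id subset (e.g. from
#'   [select_instruments]); defaults to all exposure variants.
#' @param ambiguity_window Frequency window within which a palindromic
#'   variant is considered unresolvable; default `c(0.42, 0.58)`.
#' @return A data frame of class `harmonized_set`: `id`, `effect_allele`,
#'   `other_allele`, `beta_exp`, `se_exp`, `eaf_exp`, `beta_out`,
#'   `se_out`, `eaf_out`; attributes `exposure`, `outcome`, `drops`.
#' @export
harmonize <- function(exposure, outcome, instruments = NULL,
                      ambiguity_window = c(0.42, 0.58)) {
  if (is.null(instruments)) instruments <- exposure$id
  ex <- exposure[match(instruments, exposure$id), , drop = FALSE]
  drops <- data.frame(id = character(0), reason = character(0),
                      stringsAsFactors = FALSE)
  note <- function(id, reason) {
    rbind(drops, data.frame(id = id, reason = reason, stringsAsFactors = FALSE))
  }

  idx <- match(ex$id, outcome$id)
  absent <- is.na(idx)
  if (any(absent)) drops <- note(ex$id[absent], "absent from outcome")
  ex <- ex[!absent, , drop = FALSE]
  ou <- outcome[idx[!absent], , drop = FALSE]

  keep <- rep(TRUE, nrow(ex))
  beta_out <- ou$beta
  eaf_out <- ou$eaf
  complement <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(nrow(ex))) {
    ea <- ex$effect_allele[i]; oa <- ex$other_allele[i]
    pea <- ou$effect_allele[i]; poa <- ou$other_allele[i]
    palindromic <- ea == complement[[oa]]
    if (palindromic) {
      if (!(pea %in% c(ea, oa)) || !(poa %in% c(ea, oa)) || pea == poa) {
        keep[i] <- FALSE
        drops <- note(ex$id[i], "incompatible alleles")
        next
      }
      f_ex <- ex$eaf[i]; f_ou <- ou$eaf[i]
      ambiguous <- function(f) is.na(f) ||
        (f > ambiguity_window[1] && f < ambiguity_window[2])
      if (ambiguous(f_ex) || ambiguous(f_ou)) {
        keep[i] <- FALSE
        drops <- note(ex$id[i], "palindromic, frequency ambiguous")
        next
      }
      # align by frequency: the outcome's stated effect allele is taken to
      # be the exposure's effect allele iff the frequencies sit on the
      # same side of 0.5
      same_side <- (f_ex < 0.5) == (f_ou < 0.5)
      if (!same_side) {
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
      }
    } else {
      if (pea == ea && poa == oa) {
        # already aligned
      } else if (pea == oa && poa == ea) {
        beta_out[i] <- -beta_out[i]
        if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
      } else if (pea == complement[[ea]] && poa == complement[[oa]]) {
        # other strand, same orientation
      } else if (pea == complement[[oa]] && poa == complement[[ea]]) {
        beta_out[i] <- -beta_out[i]
        if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
      } else {
        keep[i] <- FALSE
        drops <- note(ex$id[i], "incompatible alleles")
      }
    }
  }
  hs <- data.frame(id = ex$id,
                   effect_allele = ex$effect_allele,
                   other_allele = ex$other_allele,
                   beta_exp = ex$beta, se_exp = ex$se, eaf_exp = ex$eaf,
                   beta_out = beta_out, se_out = ou$se, eaf_out = eaf_out,
                   stringsAsFactors = FALSE)[keep, , drop = FALSE]
  if (nrow(hs) == 0L) {
    stop("no instruments survive harmonization", call. = FALSE)
  }
  if (nrow(drops)) {
    message(sprintf("harmonize: dropped %d instrument(s) (%s)", nrow(drops),
                    paste(unique(drops$reason), collapse = "; ")))
  }
  rownames(hs) <- NULL
  structure(hs,
            exposure = attr(exposure, "trait") %||% "exposure",
            outcome = attr(outcome, "trait") %||% "outcome",
            drops = drops,
            class = c("harmonized_set", "data.frame"))
}

#' Per-variant Wald ratio
#'
#' The causal estimate from a single instrument: outcome association
#' divided by exposure association, with the first-order delta-method
#' standard error `se_out / |beta_exp|`.
#'
#' @param bx,sx Exposure beta and SE.
#' @param by,sy Outcome beta and SE.
#' @return List: `ratio`, `se`.
#' @export
wald_ratio <- function(bx, sx, by, sy) {
  if (any(bx == 0)) stop("Wald ratio undefined for zero exposure beta",
                         call. = FALSE)
  list(ratio = by / bx, se = sy / abs(bx))
}

mr_estimate_row <- function(method, beta, se, n_snps, q = NA_real_,
                            q_df = NA_integer_, scale = "per-SD") {
  z <- if (!is.na(se) && se > 0) beta / se else NA_real_
  data.frame(method = method, beta = beta, se = se,
             ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
             p = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)),
             n_snps = as.integer(n_snps),
             q_stat = q, q_df = as.integer(q_df),
             scale = scale, stringsAsFactors = FALSE)
}

#' Random-effects inverse-variance-weighted estimator
#'
#' Precision-weighted average of per-variant Wald ratios with weights
#' `1/se_j^2`. Cochran's Q measures heterogeneity; the multiplicative
#' random-effects standard error inflates the fixed-effect SE by
#' `sqrt(Q / (L - 1))`, floored at 1, so it never falls below the
#' fixed-effect SE. With a single instrument the estimate falls back to
#' the Wald ratio (method labelled accordingly).
#'
#' @param hs A `harmonized_set`.
#' @return One-row `mr_estimate` data frame with Q and its degrees of
#'   freedom.
#' @export
ivw_random_effects <- function(hs) {
  wr <- wald_ratio(hs$beta_exp, hs$se_exp, hs$beta_out, hs$se_out)
  L <- length(wr$ratio)
  if (L < 2L) {
    return(mr_estimate_row("wald-ratio (single instrument)", wr$ratio,
                           wr$se, 1L))
  }
  w <- wr$se^-2
  beta <- sum(w * wr$ratio) / sum(w)
  se_fixed <- sum(w)^-0.5
  q <- sum(w * (wr$ratio - beta)^2)
  se <- se_fixed * max(1, sqrt(q / (L - 1)))
  mr_estimate_row("IVW-RE", beta, se, L, q = q, q_df = L - 1L)
}

weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  wp <- weights[ord] / sum(weights)
  s <- cumsum(wp) - wp / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  j <- max(which(s < 0.5))
  r[j] + (0.5 - s[j]) / (s[j + 1] - s[j]) * (r[j + 1] - r[j])
}

weighted_mode_point <- function(ratios, weights, phi = 1, n_grid = 512L) {
  med <- stats::median(ratios)
  h <- phi * 1.4826 * stats::median(abs(ratios - med))
  if (h == 0) {
    wp <- weights / sum(weights)
    mu <- sum(wp * ratios)
    h <- phi * sqrt(sum(wp * (ratios - mu)^2))
  }
  if (h == 0) {
    if (max(ratios) == min(ratios)) return(ratios[1])
    stop("degenerate ratio spread; cannot form kernel bandwidth", call. = FALSE)
  }
  grid <- seq(min(ratios) - 3 * h, max(ratios) + 3 * h, length.out = n_grid)
  dens <- colSums(weights * stats::dnorm(outer(ratios, grid, `-`) / h))
  grid[which.max(dens)]
}

boot_se <- function(hs, point_fun, n_boot, seed) {
  if (n_boot < 1L) return(NA_real_)
  withr::with_seed(seed, {
    J <- nrow(hs)
    est <- vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(J, hs$beta_exp, hs$se_exp)
      by <- stats::rnorm(J, hs$beta_out, hs$se_out)
      ratios <- by / bx
      weights <- (hs$se_out / abs(bx))^-2
      point_fun(ratios, weights)
    }, numeric(1))
    stats::sd(est)
  })
}

#' Weighted-median estimator
#'
#' The weight-ordered 50th percentile of the Wald ratios, consistent when
#' at least half the instrument weight comes from valid (non-pleiotropic)
#' instruments. Ratios are sorted; with standardized inverse-variance
#' weights `w'_j` the cumulative midpoint is `s_j = sum_{k<=j} w'_k -
#' w'_j/2` and the estimate interpolates linearly between the ratios
#' bracketing s = 0.5. The standard error comes from a parametric
#' bootstrap: per-variant betas are resampled from their reported normal
#' sampling distributions.
#'
#' @param hs A `harmonized_set` with at least 3 instruments.
#' @param n_boot Bootstrap resamples (default 1000); `0` skips the SE
#'   (point estimate only, `se`/`p` set `NA`).
#' @param seed Seed for the bootstrap generator.
#' @return One-row `mr_estimate` data frame.
#' @export
weighted_median <- function(hs, n_boot = 1000L, seed = 1L) {
  if (nrow(hs) < 3L) stop("weighted median needs >= 3 instruments", call. = FALSE)
  wr <- wald_ratio(hs$beta_exp, hs$se_exp, hs$beta_out, hs$se_out)
  beta <- weighted_median_point(wr$ratio, wr$se^-2)
  se <- boot_se(hs, weighted_median_point, n_boot, seed)
  mr_estimate_row("weighted-median", beta, se, nrow(hs))
}

#' Weighted-mode estimator
#'
#' Locates the maximum of a Gaussian-kernel-smoothed, inverse-variance
#' weighted density of the Wald ratios: consistent when the most common
#' amount of pleiotropy is zero (the zero-modal-pleiotropy assumption,
#' ZEMPA), even if most instruments are invalid. Bandwidth is
#' `phi * 1.4826 * MAD(ratios)` with a weighted-SD fallback when the MAD
#' is zero; the density is evaluated on a fixed 512-point grid spanning
#' the ratio range plus 3 bandwidths each side. SE by parametric
#' bootstrap as for the weighted median.
#'
#' @param hs A `harmonized_set` with at least 3 instruments.
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot,seed As in [weighted_median].
#' @return One-row `mr_estimate` data frame.
#' @export
weighted_mode <- function(hs, phi = 1, n_boot = 1000L, seed = 1L) {
  if (nrow(hs) < 3L) stop("weighted mode needs >= 3 instruments", call. = FALSE)
  wr <- wald_ratio(hs$beta_exp, hs$se_exp, hs$beta_out, hs$se_out)
  if (max(wr$ratio) == min(wr$ratio)) {
    return(mr_estimate_row("weighted-mode", wr$ratio[1], 0, nrow(hs)))
  }
  point <- function(r, w) weighted_mode_point(r, w, phi = phi)
  beta <- point(wr$ratio, wr$se^-2)
  se <- boot_se(hs, point, n_boot, seed)
  mr_estimate_row("weighted-mode", beta, se, nrow(hs))
}

#' Instrument-strength (F-statistic) diagnostics
#'
#' Per-variant `F_j = (beta_exp_j / se_exp_j)^2`, with the minimum and
#' median summarised; a minimum below 10 conventionally signals weak
#' instruments and raises a warning flag.
#'
#' @param hs A `harmonized_set`.
#' @return List: `f` (per variant), `f_min`, `f_median`, `weak` (logical).
#' @export
instrument_strength <- function(hs) {
  f <- (hs$beta_exp / hs$se_exp)^2
  out <- list(f = f, f_min = min(f), f_median = stats::median(f),
              weak = min(f) < 10)
  if (out$weak) {
    warning(sprintf("weak instrument(s): minimum F = %.1f < 10", out$f_min),
            call. = FALSE)
  }
  out
}

#' Exponentiate a log-odds-scale MR estimate to the odds-ratio scale
#'
#' The point estimate and interval bounds are exponentiated; the standard
#' error is retained on the log scale (so p-values are unchanged).
#'
#' @param est One-row `mr_estimate` data frame on the log-odds scale.
#' @return The estimate with `beta`, `ci_low`, `ci_high` exponentiated and
#'   `scale` set to `"OR"`.
#' @export
to_odds_ratio <- function(est) {
  if (any(est$scale == "OR")) {
    stop("estimate already on the odds-ratio scale", call. = FALSE)
  }
  est$beta <- exp(est$beta)
  est$ci_low <- exp(est$ci_low)
  est$ci_high <- exp(est$ci_high)
  est$scale <- "OR"
  est
}

scale_estimate_per_doubling <- function(est) {
  sca <- scale_per_doubling(est$beta, est$se, est$ci_low, est$ci_high)
  est$beta <- sca$beta; est$se <- sca$se
  est$ci_low <- sca$ci_low; est$ci_high <- sca$ci_high
  est$scale <- "per-doubling"
  est
}

#' Run a full two-sample MR analysis in one direction
#'
#' Pipeline: instrument selection (p-threshold then LD clumping),
#' harmonization, estimation with up to three methods, instrument-strength
#' diagnostics, FDR adjustment across traits within each method, and
#' direction-specific scaling. The reverse direction (disease liability
#' as exposure, metabolites as outcomes) multiplies estimates by log(2)
#' so they read per doubling of liability; the forward direction
#' (metabolites as exposures, disease as outcome) exponentiates log-odds
#' estimates to odds ratios per SD of metabolite.
#'
#' @param exposure A [summary_stats] object, or (forward direction) a
#'   named list of them, one per metabolite.
#' @param outcome A [summary_stats] object, or (reverse direction) a
#'   named list of them, one per metabolite.
#' @param direction `"reverse"` or `"forward"`.
#' @param ld LD matrix, a named list of LD matrices keyed like the
#'   exposure list, or `NULL` for mutually independent candidates.
#' @param p_threshold,r2_threshold Instrument-selection thresholds.
#' @param methods Subset of `c("ivw", "median", "mode")`.
#' @param n_boot,seed Bootstrap controls for the median/mode SEs.
#' @param exclude_regions Optional region labels removed from the
#'   disease instrument set before selection (sensitivity analysis);
#'   requires region tags on the stats (see [exclude_region]).
#' @param region_map Optional id-to-tag map for the exclusion.
#' @param alpha FDR threshold for the association flag.
#' @return Data frame with one row per exposure x outcome x method:
#'   trait labels, `method`, `n_snps`, `beta`, `se`, `ci_low`, `ci_high`,
#'   `p`, `q_stat`, `q_df`, `f_min`, `f_median`, `scale`, `p_fdr`,
#'   `flag`.
#' @export
run_mr <- function(exposure, outcome, direction = c("reverse", "forward"),
                   ld = NULL, p_threshold = 5e-8, r2_threshold = 0.001,
                   methods = c("ivw", "median", "mode"),
                   n_boot = 1000L, seed = 1L,
                   exclude_regions = NULL, region_map = NULL,
                   alpha = 0.05) {
  direction <- match.arg(direction)
  methods <- match.arg(methods, c("ivw", "median", "mode"),
                       several.ok = TRUE)
  exposures <- if (is.data.frame(exposure)) {
    stats::setNames(list(exposure), attr(exposure, "trait") %||% "exposure")
  } else exposure
  outcomes <- if (is.data.frame(outcome)) {
    stats::setNames(list(outcome), attr(outcome, "trait") %||% "outcome")
  } else outcome
  ld_for <- function(name) {
    if (is.null(ld)) NULL
    else if (is.list(ld)) ld[[name]]
    else ld
  }

  rows <- list()
  for (ex_name in names(exposures)) {
    ex <- exposures[[ex_name]]
    if (!is.null(exclude_regions)) {
      ex <- exclude_region(ex, exclude_regions, region_map)
    }
    instruments <- select_instruments(ex, ld_for(ex_name),
                                      p_threshold, r2_threshold)
    for (ou_name in names(outcomes)) {
      hs <- harmonize(ex, outcomes[[ou_name]], instruments)
      strength <- instrument_strength(hs)
      ests <- list()
      if ("ivw" %in% methods) ests$ivw <- ivw_random_effects(hs)
      if ("median" %in% methods && nrow(hs) >= 3L) {
        ests$median <- weighted_median(hs, n_boot = n_boot, seed = seed)
      }
      if ("mode" %in% methods && nrow(hs) >= 3L) {
        ests$mode <- weighted_mode(hs, n_boot = n_boot, seed = seed)
      }
      est <- do.call(rbind, ests)
      est <- if (direction == "reverse") scale_estimate_per_doubling(est)
             else to_odds_ratio(est)
      est$exposure <- ex_name
      est$outcome <- ou_name
      est$f_min <- strength$f_min
      est$f_median <- strength$f_median
      rows[[length(rows) + 1L]] <- est
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # FDR across traits within each method family
  out$p_fdr <- NA_real_
  for (m in unique(out$method)) {
    sel <- out$method == m & !is.na(out$p)
    if (any(sel)) out$p_fdr[sel] <- bh_adjust(out$p[sel])
  }
  out$flag <- !is.na(out$p_fdr) & out$p_fdr < alpha
  front <- c("exposure", "outcome", "method", "n_snps", "beta", "se",
             "ci_low", "ci_high", "p", "p_fdr", "q_stat", "q_df",
             "f_min", "f_median", "scale", "flag")
  out[, front]
}
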