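#' Greedy LD clumping
#'
#' Prunes a candidate variant set so that no two retained variants are in
#' linkage disequilibrium above `r2_threshold`. Candidates are visited in
#' order of ascending p-value (ties broken by lexicographic variant id, for
#' determinism) and accepted if and only if their r-squared with every
#' already-accepted variant is at or below the threshold — i.e. the
#' lowest-p variant of each correlated group is retained.
#'
#' @param candidates A [summary_stats] object.
#' @param ld LD matrix (r-squared, symmetric, unit diagonal) covering every
#'   candidate id.
#' @param r2_threshold Retention threshold in `[0, 1)`; the conventional
#'   value for strict independence is `0.001`.
#' @return Character vector of retained variant ids, in acceptance order.
#' @export
ld_clump <- function(candidates, ld, r2_threshold = 0.001) {
  validate_ld_matrix(ld)
  if (r2_threshold < 0 || r2_threshold >= 1) {
    stop("r2_threshold must lie in [0, 1)", call. = FALSE)
  }
  absent <- setdiff(candidates$id, rownames(ld))
  if (length(absent)) {
    stop("candidate(s) missing from the LD matrix: ",
         paste(utils::head(absent, 5L), collapse = ", "), call. = FALSE)
  }
  ord <- order(candidates$p, candidates$id)
  ids <- candidates$id[ord]
  kept <- character(0)
  for (v in ids) {
    if (!length(kept) || all(ld[v, kept] <= r2_threshold)) {
      kept <- c(kept, v)
    }
  }
  kept
}

#' Score individuals with an externally weighted GRS
#'
#' The raw score for individual i is `sum_j w_j * g_ij / m_i`, where the
#' sum runs over the weight variants with a non-missing dosage for that
#' individual and `m_i` is their count (so scores stay comparable under
#' sporadic missingness). With `denominator = "all"` the divisor is the
#' full weight-variant count instead; with `"none"` the undivided weighted
#' sum — the individual's genetic liability in log-odds units — is
#' returned.
#'
#' Dosages count copies of the allele named by
#' `attr(dosages, "counted_allele")` (a named character vector); where that
#' allele differs from the weight's effect allele the dosage is flipped to
#' `2 - g` before scoring. Without the attribute, dosages are assumed
#' already oriented to the effect alleles.
#'
#' @param dosages Numeric matrix (individuals x variants) with values in
#'   `[0, 2]`, missing allowed.
#' @param weights A [grs_weights] object.
#' @param denominator One of `"nonmissing"` (default), `"all"`, `"none"`.
#' @return Named numeric vector of per-individual scores; individuals with
#'   all dosages missing get `NA`.
#' @export
score_grs <- function(dosages, weights,
                      denominator = c("nonmissing", "all", "none")) {
  denominator <- match.arg(denominator)
  validate_dosages(dosages)
  shared <- intersect(weights$id, colnames(dosages))
  if (!length(shared)) {
    stop("no overlap between weight variants and dosage matrix", call. = FALSE)
  }
  w <- weights$weight[match(shared, weights$id)]
  g <- dosages[, shared, drop = FALSE]
  counted <- attr(dosages, "counted_allele")
  if (!is.null(counted)) {
    ea <- weights$effect_allele[match(shared, weights$id)]
    flip <- counted[shared] != ea
    if (any(flip)) g[, flip] <- 2 - g[, flip, drop = FALSE]
  }
  contrib <- sweep(g, 2L, w, `*`)
  sums <- rowSums(contrib, na.rm = TRUE)
  m_i <- rowSums(!is.na(g))
  sums[m_i == 0L] <- NA_real_
  denom <- switch(denominator,
                  nonmissing = m_i,
                  all = rep(length(shared), nrow(g)),
                  none = rep(1, nrow(g)))
  out <- sums / ifelse(denom == 0, NA_real_, denom)
  names(out) <- rownames(dosages)
  out
}

#' Per-individual GRS table (raw, log-odds sum, and z-scored)
#'
#' Convenience wrapper around [score_grs] returning the quantities the
#' scan consumes: `score_sum` is the weighted allele count in log-odds
#' units (the scale on which a `log(2)` multiplier converts estimates to
#' per-doubling of liability), `score_avg` the per-variant average, and
#' `score_z` its z-standardization (reported descriptively).
#'
#' @inheritParams score_grs
#' @return Data frame: `id`, `n_snps`, `score_sum`, `score_avg`, `score_z`.
#' @export
grs_table <- function(dosages, weights) {
  avg <- score_grs(dosages, weights, denominator = "nonmissing")
  shared <- intersect(weights$id, colnames(dosages))
  n_used <- rowSums(!is.na(dosages[, shared, drop = FALSE]))
  data.frame(id = rownames(dosages),
             n_snps = as.integer(n_used),
             score_sum = avg * n_used,
             score_avg = avg,
             score_z = zscore(avg),
             stringsAsFactors = FALSE)
}

#' Z-standardize a numeric vector
#'
#' Centres to mean 0 and scales to sample SD 1 over the non-missing
#' entries; missing values are preserved.
#'
#' @param values Numeric vector with at least two non-missing values and
#'   non-zero spread.
#' @return Standardized vector of the same length.
#' @export
zscore <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2L) stop("need at least 2 non-missing values", call. = FALSE)
  s <- stats::sd(values[ok])
  if (s == 0) stop("cannot z-score a constant vector", call. = FALSE)
  (values - mean(values[ok])) / s
}

#' Drop variants falling in named gene regions
#'
#' Removes records whose gene-region tag is in `regions` — e.g. the FADS
#' cluster (FADS1/2/3), whose variants influence lipid metabolites
#' directly and are a canonical pleiotropy concern. Tags come from the
#' table's `region` column or an explicit id-to-tag map.
#'
#' @param x A [summary_stats] or [grs_weights] object.
#' @param regions Character vector of region labels to exclude.
#' @param region_map Optional named character vector (variant id -> tag)
#'   overriding / supplementing the `region` column.
#' @return `x` with the tagged records removed; a message reports the
#'   count, and a warning is raised if nothing survives.
#' @export
exclude_region <- function(x, regions = "FADS", region_map = NULL) {
  tags <- if (!is.null(x$region)) as.character(x$region) else
    rep(NA_character_, nrow(x))
  if (!is.null(region_map)) {
    hit <- match(x$id, names(region_map))
    tags[!is.na(hit)] <- region_map[hit[!is.na(hit)]]
  }
  drop <- !is.na(tags) & tags %in% regions
  message(sprintf("exclude_region: removed %d of %d variant(s) tagged %s",
                  sum(drop), nrow(x), paste(regions, collapse = "/")))
  out <- x[!drop, , drop = FALSE]
  for (a in c("trait", "units")) attr(out, a) <- attr(x, a)
  class(out) <- class(x)
  if (nrow(out) == 0L) {
    warning("all variants excluded by region filter", call. = FALSE)
  }
  out
}
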