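#' Rank-based inverse normal transformation
#'
#' Maps the value with rank r among n non-missing observations to the
#' standard-normal quantile at `(r - offset) / (n - 2*offset + 1)`. Ties
#' receive their average rank, missing values are preserved, and the map
#' is monotone, so the output is invariant to any strictly monotone
#' transformation of the input. The default Blom offset of 3/8 is the
#' common choice for normalising metabolite concentrations before
#' association testing.
#'
#' @param values Numeric vector with at least 3 non-missing values, not
#'   all identical.
#' @param offset Rank offset in `[0, 0.5]`; 3/8 by default.
#' @return Transformed vector, same length and missingness pattern.
#' @export
rank_inverse_normal <- function(values, offset = 3/8) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 3L) stop("need at least 3 non-missing values", call. = FALSE)
  v <- values[ok]
  if (max(v) == min(v)) {
    stop("all values identical; transformation undefined", call. = FALSE)
  }
  r <- rank(v, ties.method = "average")
  q <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  out <- rep(NA_real_, length(values))
  out[ok] <- q
  out
}

#' Assemble a complete-case regression design for one time point
#'
#' Joins the cohort's metabolite outcome at one time point with the GRS
#' and the covariates the scan adjusts for (sex, and age at the time of
#' metabolite assessment, centred). Rows with any missing element are
#' dropped (complete-case analysis, so n differs by clinic visit); a
#' single-sex cohort has the sex column dropped with a warning rather
#' than producing a rank-deficient fit.
#'
#' @param cohort Cohort data frame: `id`, `sex` (0/1), `age_<tp>`, and
#'   metabolite columns named `<metabolite>_<tp>`.
#' @param metabolite Metabolite name.
#' @param timepoint Time-point label (e.g. `"8"`).
#' @param scores Data frame from [grs_table]; the `score_sum` column (the
#'   log-odds-scale liability score) enters the model as exposure.
#' @return List with `outcome`, `exposure`, `covariates` (matrix, may have
#'   zero columns), and `n`.
#' @export
build_design <- function(cohort, metabolite, timepoint, scores) {
  age_col <- paste0("age_", timepoint)
  met_col <- paste0(metabolite, "_", timepoint)
  for (col in c(age_col, met_col)) {
    if (is.null(cohort[[col]])) {
      stop("cohort has no column '", col, "'", call. = FALSE)
    }
  }
  sc <- scores$score_sum[match(cohort$id, scores$id)]
  df <- data.frame(outcome = cohort[[met_col]],
                   exposure = sc,
                   sex = cohort$sex,
                   age = cohort[[age_col]])
  cc <- stats::complete.cases(df)
  n_drop <- sum(!cc)
  if (n_drop > 0L) {
    message(sprintf("build_design: dropped %d incomplete row(s) for %s at %s",
                    n_drop, metabolite, timepoint))
  }
  df <- df[cc, , drop = FALSE]
  if (nrow(df) < 10L) {
    stop("fewer than 10 complete rows; unfit for regression", call. = FALSE)
  }
  covars <- cbind(sex = as.numeric(df$sex),
                  age = df$age - mean(df$age))
  keep <- apply(covars, 2L, function(x) stats::sd(x) > 0)
  if (!keep["sex"]) {
    warning("single-sex stratum: sex covariate dropped", call. = FALSE)
  }
  covars <- covars[, keep, drop = FALSE]
  list(outcome = df$outcome, exposure = df$exposure,
       covariates = covars, n = nrow(df))
}

#' Names of the metabolite columns present in a cohort table
#' @param cohort Cohort data frame.
#' @return Character vector of metabolite names.
#' @export
cohort_metabolites <- function(cohort) {
  cols <- setdiff(names(cohort), c("id", "sex"))
  cols <- cols[!startsWith(cols, "age_")]
  unique(sub("_[^_]+$", "", cols))
}

#' Time-point labels present in a cohort table
#' @param cohort Cohort data frame.
#' @return Character vector of time-point labels.
#' @export
cohort_timepoints <- function(cohort) {
  sub("^age_", "", grep("^age_", names(cohort), value = TRUE))
}
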