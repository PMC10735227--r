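#' @keywords internal
"_PACKAGE"

VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a validated GWAS summary-statistics table
#'
#' A `summary_stats` object is a data frame with one row per variant and the
#' columns `id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `p` and (optionally) `region`. Effect sizes are on the
#' log-odds scale for disease traits and in SD units for metabolite traits.
#'
#' @param x Data frame holding at least `id`, `effect_allele`,
#'   `other_allele`, `beta`, `se` and `p`. `chrom`, `pos`, `eaf` and
#'   `region` are optional and filled with `NA` when absent.
#' @param trait Trait name (e.g. `"CRC"` or a metabolite label).
#' @param units Unit of `beta`: `"logOR"` for disease, `"SD"` for
#'   metabolites.
#' @return A data frame of class `summary_stats` with attributes `trait`
#'   and `units`.
#' @export
summary_stats <- function(x, trait = "trait", units = "logOR") {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (col in c("chrom", "pos", "eaf", "region")) {
    if (is.null(x[[col]])) x[[col]] <- NA
  }
  x <- x[, c("id", "chrom", "pos", "effect_allele", "other_allele",
             "eaf", "beta", "se", "p", "region")]
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  validate_summary_stats(x)
  structure(x,
            trait = trait, units = units,
            class = c("summary_stats", "data.frame"))
}

validate_summary_stats <- function(x) {
  if (nrow(x) == 0L) stop("summary statistics table is empty", call. = FALSE)
  need <- c("id", "effect_allele", "other_allele", "beta", "se", "p")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dup <- unique(x$id[duplicated(x$id)])
  if (length(dup)) {
    stop("duplicate variant id(s): ", paste(utils::head(dup, 5L), collapse = ", "),
         call. = FALSE)
  }
  bad_allele <- !(x$effect_allele %in% VALID_ALLELES) |
    !(x$other_allele %in% VALID_ALLELES)
  if (any(bad_allele)) {
    stop("invalid allele code(s) for variant(s): ",
         paste(utils::head(x$id[bad_allele], 5L), collapse = ", "), call. = FALSE)
  }
  same <- x$effect_allele == x$other_allele
  if (any(same)) {
    stop("effect allele equals other allele for: ",
         paste(utils::head(x$id[same], 5L), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(x$beta))) stop("non-finite beta values", call. = FALSE)
  if (any(!is.finite(x$se) | x$se <= 0)) {
    stop("se must be finite and > 0; offending variant(s): ",
         paste(utils::head(x$id[!is.finite(x$se) | x$se <= 0], 5L),
               collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(x$p) | x$p <= 0 | x$p > 1)) {
    stop("p-values must lie in (0, 1]; offending variant(s): ",
         paste(utils::head(x$id[!is.finite(x$p) | x$p <= 0 | x$p > 1], 5L),
               collapse = ", "), call. = FALSE)
  }
  eaf_ok <- is.na(x$eaf) | (x$eaf > 0 & x$eaf < 1)
  if (!all(eaf_ok)) {
    stop("effect-allele frequencies must lie in (0, 1) or be missing",
         call. = FALSE)
  }
  invisible(x)
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("Summary statistics: %s (%s), %d variants\n",
              attr(x, "trait"), attr(x, "units"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Construct a set of external GRS weights
#'
#' @param id Variant identifiers (unique).
#' @param effect_allele Allele whose dosage the weight applies to.
#' @param weight Per-allele weight, log-odds units.
#' @param trait Source trait label (e.g. `"CRC"`, `"colon"`, `"rectal"`).
#' @return A data frame of class `grs_weights`.
#' @export
grs_weights <- function(id, effect_allele, weight, trait = "CRC") {
  if (anyDuplicated(id)) stop("duplicate variant ids in weights", call. = FALSE)
  if (any(!is.finite(weight))) stop("weights must be finite", call. = FALSE)
  effect_allele <- toupper(effect_allele)
  if (!all(effect_allele %in% VALID_ALLELES)) {
    stop("invalid effect allele in weights", call. = FALSE)
  }
  structure(data.frame(id = as.character(id),
                       effect_allele = effect_allele,
                       weight = as.numeric(weight),
                       stringsAsFactors = FALSE),
            trait = trait,
            class = c("grs_weights", "data.frame"))
}

#' Extract GRS weights from a disease summary-statistics table
#'
#' Uses the reported effect sizes as external weights, the convention for
#' externally weighted risk scores.
#'
#' @param stats A `summary_stats` object for the disease trait.
#' @return A `grs_weights` object.
#' @export
weights_from_stats <- function(stats) {
  grs_weights(stats$id, stats$effect_allele, stats$beta,
              trait = attr(stats, "trait") %||% "trait")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_ld_matrix <- function(ld) {
  if (!is.matrix(ld) || nrow(ld) != ncol(ld)) {
    stop("LD matrix must be square", call. = FALSE)
  }
  if (is.null(rownames(ld)) || is.null(colnames(ld)) ||
      !identical(rownames(ld), colnames(ld))) {
    stop("LD matrix must carry identical row and column variant ids",
         call. = FALSE)
  }
  if (max(abs(ld - t(ld))) > 1e-8) stop("LD matrix must be symmetric", call. = FALSE)
  if (any(ld < -1e-12 | ld > 1 + 1e-12)) {
    stop("LD r-squared values must lie in [0, 1]", call. = FALSE)
  }
  if (max(abs(diag(ld) - 1)) > 1e-8) {
    stop("LD matrix diagonal must be 1", call. = FALSE)
  }
  invisible(ld)
}

validate_dosages <- function(dosages) {
  if (!is.matrix(dosages)) stop("dosages must be a matrix", call. = FALSE)
  if (is.null(rownames(dosages)) || is.null(colnames(dosages))) {
    stop("dosage matrix must carry individual and variant ids", call. = FALSE)
  }
  bad <- which(!is.na(dosages) & (dosages < 0 | dosages > 2), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("dosage outside [0, 2] at individual '%s', variant '%s'",
                 rownames(dosages)[bad[1L, 1L]], colnames(dosages)[bad[1L, 2L]]),
         call. = FALSE)
  }
  invisible(dosages)
}
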