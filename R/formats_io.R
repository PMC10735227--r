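# Tab-separated text is the native interchange format throughout: GWAS
# summary statistics have no single standard, so readers resolve columns
# through a dialect (a canonical-name -> file-column mapping) with common
# header synonyms built in.

SUMSTAT_SYNONYMS <- list(
  id = c("id", "snp", "rsid", "variant_id", "markername"),
  chrom = c("chrom", "chr", "chromosome"),
  pos = c("pos", "bp", "position", "base_pair_location"),
  effect_allele = c("effect_allele", "ea", "a1", "allele1"),
  other_allele = c("other_allele", "oa", "a2", "allele2", "non_effect_allele"),
  eaf = c("eaf", "effect_allele_frequency", "freq", "af"),
  beta = c("beta", "b", "effect", "logor"),
  se = c("se", "standard_error", "stderr"),
  p = c("p", "pval", "p_value", "pvalue"),
  region = c("region", "gene_region", "locus")
)

resolve_dialect <- function(header, dialect = NULL) {
  header_lc <- tolower(header)
  out <- list()
  for (canon in names(SUMSTAT_SYNONYMS)) {
    if (!is.null(dialect) && !is.null(dialect[[canon]])) {
      hit <- match(tolower(dialect[[canon]]), header_lc)
    } else {
      hit <- match(SUMSTAT_SYNONYMS[[canon]], header_lc)
      hit <- hit[!is.na(hit)][1]
    }
    if (length(hit) && !is.na(hit)) out[[canon]] <- header[hit]
  }
  out
}

#' Read a GWAS summary-statistics table
#'
#' Reads delimited text, maps columns through a dialect, upper-cases
#' alleles, drops rows whose mandatory fields cannot be parsed (with a
#' message giving the count), and validates the result.
#'
#' @param path Path to a tab- (or otherwise) delimited text file with a
#'   header row.
#' @param dialect Optional named list mapping canonical column names
#'   (`id`, `effect_allele`, `other_allele`, `beta`, `se`, `p`, and
#'   optionally `chrom`, `pos`, `eaf`, `region`) to the file's column
#'   names. Common synonyms (SNP, A1/A2, pval, ...) are recognised
#'   automatically.
#' @param trait,units Trait label and effect-size units recorded on the
#'   returned object.
#' @param sep Field separator, tab by default.
#' @return A [summary_stats] object.
#' @export
read_summary_stats <- function(path, dialect = NULL, trait = "trait",
                               units = "logOR", sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""),
                           colClasses = "character", check.names = FALSE)
  cols <- resolve_dialect(names(raw), dialect)
  mandatory <- c("id", "effect_allele", "other_allele", "beta", "se", "p")
  absent <- setdiff(mandatory, names(cols))
  if (length(absent)) {
    stop("cannot resolve mandatory column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(id = raw[[cols$id]], stringsAsFactors = FALSE)
  df$effect_allele <- toupper(raw[[cols$effect_allele]])
  df$other_allele <- toupper(raw[[cols$other_allele]])
  for (num in c("beta", "se", "p", "eaf", "pos")) {
    df[[num]] <- if (!is.null(cols[[num]])) {
      suppressWarnings(as.numeric(raw[[cols[[num]]]]))
    } else NA_real_
  }
  df$chrom <- if (!is.null(cols$chrom)) raw[[cols$chrom]] else NA_character_
  df$region <- if (!is.null(cols$region)) raw[[cols$region]] else NA_character_

  parseable <- !is.na(df$id) & !is.na(df$effect_allele) &
    !is.na(df$other_allele) & !is.na(df$beta) & !is.na(df$se) & !is.na(df$p)
  n_bad <- sum(!parseable)
  if (n_bad > 0L) {
    message(sprintf("read_summary_stats: rejected %d row(s) with unparseable mandatory fields", n_bad))
    df <- df[parseable, , drop = FALSE]
  }
  summary_stats(df, trait = trait, units = units)
}

#' Write a summary-statistics table to tab-separated text
#'
#' @param stats A [summary_stats] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  write_table_12sig(as.data.frame(stats), path)
}

#' Write a results table to tab-separated text
#'
#' Numeric columns are written with 12 significant digits so that a
#' write/read round trip is lossless at that precision. When the rows carry
#' odds-ratio-scale estimates (`scale == "OR"`), the effect and interval
#' columns are renamed `or`, `or_ci_low`, `or_ci_high`.
#'
#' @param rows Non-empty data frame of scan, MR, or triangulation results.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(rows, path) {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0L) stop("refusing to write an empty results table", call. = FALSE)
  if (!is.null(rows$scale) && all(rows$scale == "OR") &&
      all(c("beta", "ci_low", "ci_high") %in% names(rows))) {
    names(rows)[match(c("beta", "ci_low", "ci_high"), names(rows))] <-
      c("or", "or_ci_low", "or_ci_high")
  }
  write_table_12sig(rows, path)
}

#' Read a results table written by [write_results]
#' @param path Path to the file.
#' @return A data frame.
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), check.names = FALSE)
}

write_table_12sig <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), NA, sprintf("%.12g", out[[j]]))
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write to ", path, ": ", conditionMessage(ok),
                        call. = FALSE)
  invisible(path)
}

#' Read a dosage matrix from rectangular tab-separated text
#'
#' The file has one header row of variant ids, one row per individual, and
#' the individual id in the first column. Values must lie in `[0, 2]`;
#' `NA` and empty fields are missing.
#'
#' @param path Path to the file.
#' @return Numeric matrix (individuals x variants) with dimnames.
#' @export
read_dosages <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          check.names = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  validate_dosages(m)
  m
}

#' Write a dosage matrix to rectangular tab-separated text
#' @param dosages Numeric matrix with individual rownames and variant
#'   colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosages <- function(dosages, path) {
  validate_dosages(dosages)
  df <- data.frame(iid = rownames(dosages), dosages, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table_12sig(df, path)
}

#' Read a pairwise LD (r-squared) matrix
#' @param path Tab-separated file: variant-id header, id first column.
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
read_ld_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  validate_ld_matrix(m)
  m
}

#' Write a pairwise LD (r-squared) matrix
#' @param ld Symmetric matrix with variant-id dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  validate_ld_matrix(ld)
  df <- data.frame(id = rownames(ld), ld, check.names = FALSE)
  write_table_12sig(df, path)
}

#' Write a cohort table to tab-separated text
#' @param cohort Cohort data frame (one row per individual).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write_table_12sig(as.data.frame(cohort), path)
}

#' Read a cohort table written by [write_cohort]
#' @param path Path to the file.
#' @return A data frame.
#' @export
read_cohort <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), check.names = FALSE)
}

#' Write a generative-truth sidecar file
#'
#' Records every parameter of a synthetic-data call as YAML so a run can be
#' audited or reproduced.
#'
#' @param truth A truth object (list) from the synthetic-data generators.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  yaml::write_yaml(unclass_recursive(truth), path)
  invisible(path)
}

#' Read a truth sidecar written by [write_truth]
#' @param path Path to the YAML file.
#' @return A list.
#' @export
read_truth <- function(path) yaml::read_yaml(path)

unclass_recursive <- function(x) {
  if (is.data.frame(x)) return(as.list(as.data.frame(x)))
  if (is.list(x)) return(lapply(unclass(x), unclass_recursive))
  x
}
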