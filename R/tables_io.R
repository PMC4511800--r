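#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble
NULL

# Canonical TSV dialect: tab-separated, UTF-8, '.' decimal point. Thousands
# separators are rejected on read so that transcription slips ("250,000")
# surface immediately instead of silently parsing as something else.

assoc_required_cols <- c("disease", "snp_id", "risk_allele_freq")
assoc_optional_cols <- c("sample_size", "p_value")

check_required <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "Schema error in '%s': missing required column(s): %s",
      path, paste(missing, collapse = ", ")
    ), class = "riskspectra_schema_error")
  }
}

# strict numeric parse: no thousands separators, no stray text
parse_strict_num <- function(x, col, path) {
  x <- trimws(x)
  bad_comma <- which(grepl(",", x, fixed = TRUE))
  if (length(bad_comma) > 0) {
    abort(sprintf(
      "Validation error in '%s', column '%s', row %d: thousands separators are not accepted ('%s')",
      path, col, bad_comma[1], x[bad_comma[1]]
    ), class = "riskspectra_validation_error")
  }
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(x))
  if (length(bad) > 0) {
    abort(sprintf(
      "Validation error in '%s', column '%s', row %d: not a number ('%s')",
      path, col, bad[1], x[bad[1]]
    ), class = "riskspectra_validation_error")
  }
  out
}

read_tsv_chr <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: '%s'", path), class = "riskspectra_io_error")
  }
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE, na = c("", "NA"))
}

#' Read a table of reported disease-SNP associations
#'
#' Reads the tab-separated association table that drives the whole analysis:
#' one row per reported disease-SNP association, with the frequency of the
#' risk-associated allele measured in controls. Columns `disease`, `snp_id`
#' and `risk_allele_freq` are required; `sample_size` and `p_value` are
#' optional and recorded as `NA` where absent.
#'
#' Every row is validated: `risk_allele_freq` must lie strictly inside (0, 1),
#' `p_value` (when present) in (0, 1], `sample_size` must be a positive whole
#' number, and `disease` / `snp_id` must be non-empty. Validation failures
#' report the offending data row. Values are never coerced into range.
#'
#' @param path Path to a TSV file.
#' @param p_threshold Optional genome-wide significance filter: keep only rows
#'   with `p_value <= p_threshold` (rows with unknown p-value are dropped when
#'   a threshold is set, with a message). Default `NULL` keeps everything.
#' @return A tibble with columns `disease`, `snp_id`, `risk_allele_freq`,
#'   `sample_size`, `p_value`, in file order.
#' @seealso [write_association_table()], [gen_association_table()]
#' @export
read_association_table <- function(path, p_threshold = NULL) {
  df <- read_tsv_chr(path)
  check_required(df, assoc_required_cols, path)
  out <- tibble(
    disease = trimws(df$disease),
    snp_id = trimws(df$snp_id),
    risk_allele_freq = parse_strict_num(df$risk_allele_freq, "risk_allele_freq", path),
    sample_size = if ("sample_size" %in% names(df))
      parse_strict_num(df$sample_size, "sample_size", path) else NA_real_,
    p_value = if ("p_value" %in% names(df))
      parse_strict_num(df$p_value, "p_value", path) else NA_real_
  )
  validate_association(out, path)
  if (!is.null(p_threshold)) {
    keep <- !is.na(out$p_value) & out$p_value <= p_threshold
    inform(sprintf("p-value filter (<= %g): kept %d of %d records",
                   p_threshold, sum(keep), nrow(out)))
    out <- out[keep, , drop = FALSE]
  }
  out
}

#' @keywords internal
validate_association <- function(df, path = "<in-memory>") {
  fail <- function(row, msg) {
    abort(sprintf("Validation error in '%s', row %d: %s", path, row, msg),
          class = "riskspectra_validation_error")
  }
  f <- df$risk_allele_freq
  bad <- which(!is.finite(f) | f <= 0 | f >= 1)
  if (length(bad) > 0)
    fail(bad[1], sprintf("risk_allele_freq = %s is outside (0, 1)", f[bad[1]]))
  bad <- which(is.na(df$disease) | !nzchar(df$disease))
  if (length(bad) > 0) fail(bad[1], "empty disease label")
  bad <- which(is.na(df$snp_id) | !nzchar(df$snp_id))
  if (length(bad) > 0) fail(bad[1], "empty snp_id")
  n <- df$sample_size
  bad <- which(!is.na(n) & (n <= 0 | n != floor(n)))
  if (length(bad) > 0)
    fail(bad[1], sprintf("sample_size = %s is not a positive integer", n[bad[1]]))
  p <- df$p_value
  bad <- which(!is.na(p) & (p <= 0 | p > 1))
  if (length(bad) > 0)
    fail(bad[1], sprintf("p_value = %s is outside (0, 1]", p[bad[1]]))
  invisible(df)
}

#' Write an association table
#'
#' Inverse of [read_association_table()]: writing then re-reading is the
#' identity on validated tables.
#'
#' @param df Association tibble (validated before writing).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(df, path) {
  validate_association(as_tibble(df))
  cols <- c(assoc_required_cols, intersect(assoc_optional_cols, names(df)))
  readr::write_tsv(df[cols], path, progress = FALSE)
  invisible(path)
}

#' Read per-disease literature co-occurrence counts
#'
#' Reads the abstract-count table behind the environment/lifestyle index:
#' per disease, the number of PubMed abstracts mentioning the disease
#' (`n_disease`), the disease AND "environment" (`n_env`), the disease AND
#' "lifestyle" (`n_lifestyle`), and optionally the disease AND "exposure"
#' (`n_exposure`, used by the extended index). When the `n_exposure` column
#' is absent it is recorded as `NA`.
#'
#' @param path Path to a TSV with header
#'   `disease n_disease n_env n_lifestyle [n_exposure]`.
#' @return Tibble with the columns above; zero rows is valid.
#' @seealso [compute_eli()], [eli_table()]
#' @export
read_literature_counts <- function(path) {
  df <- read_tsv_chr(path)
  check_required(df, c("disease", "n_disease", "n_env", "n_lifestyle"), path)
  out <- tibble(
    disease = trimws(df$disease %||% character(0)),
    n_disease = parse_strict_num(df$n_disease, "n_disease", path),
    n_env = parse_strict_num(df$n_env, "n_env", path),
    n_lifestyle = parse_strict_num(df$n_lifestyle, "n_lifestyle", path),
    n_exposure = if ("n_exposure" %in% names(df))
      parse_strict_num(df$n_exposure, "n_exposure", path) else NA_real_
  )
  validate_literature_counts(out, path)
  out
}

#' @keywords internal
validate_literature_counts <- function(df, path = "<in-memory>") {
  fail <- function(row, msg) {
    abort(sprintf("Validation error in '%s', row %d: %s", path, row, msg),
          class = "riskspectra_validation_error")
  }
  if (nrow(df) == 0) return(invisible(df))
  bad <- which(is.na(df$disease) | !nzchar(df$disease))
  if (length(bad) > 0) fail(bad[1], "empty disease label")
  bad <- which(!is.finite(df$n_disease) | df$n_disease < 1)
  if (length(bad) > 0) fail(bad[1], "n_disease must be >= 1")
  for (col in c("n_env", "n_lifestyle", "n_exposure")) {
    x <- df[[col]]
    bad <- which(!is.na(x) & (x < 0 | x > df$n_disease))
    if (length(bad) > 0)
      fail(bad[1], sprintf("%s = %s is outside [0, n_disease]", col, x[bad[1]]))
  }
  invisible(df)
}

#' Write a literature-count table
#'
#' @param df Literature-count tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_literature_counts <- function(df, path) {
  df <- as_tibble(df)
  validate_literature_counts(df)
  cols <- c("disease", "n_disease", "n_env", "n_lifestyle")
  if ("n_exposure" %in% names(df) && any(!is.na(df$n_exposure)))
    cols <- c(cols, "n_exposure")
  readr::write_tsv(df[cols], path, progress = FALSE)
  invisible(path)
}

#' Read a SNP id list (platform manifest or selected-SNP set)
#'
#' One rsID per line; lines starting with `#` are comments. Duplicate ids are
#' collapsed to set semantics (a message reports the unique count). An empty
#' list is an error: a manifest must be non-empty.
#'
#' @param path Path to the id list.
#' @return Character vector of unique SNP ids.
#' @export
read_snp_ids <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: '%s'", path), class = "riskspectra_io_error")
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  ids <- unique(lines)
  if (length(ids) == 0) {
    abort(sprintf("Empty SNP list in '%s': a manifest must contain at least one id", path),
          class = "riskspectra_validation_error")
  }
  inform(sprintf("Read %d unique SNP ids from '%s' (%d lines)",
                 length(ids), basename(path), length(lines)))
  ids
}

#' Write a SNP id list
#'
#' @param ids Character vector of SNP ids (deduplicated on write).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_ids <- function(ids, path) {
  writeLines(unique(as.character(ids)), path)
  invisible(path)
}

# deterministic join key for disease labels: trimmed, case-folded
disease_key <- function(x) tolower(trimws(x))
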