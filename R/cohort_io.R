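# Data model and file formats.
#
# Expression matrices are plain numeric matrices (probes x samples) with
# unique rownames (probe ids) and colnames (sample ids), on the log2 scale.
# Clinical tables are data.frames with a fixed column contract.  Both travel
# as tab-delimited text.

.clinical_required <- c("sample_id", "dmfs_time", "dmfs_event", "er_status",
                        "ln_status", "tumor_size_class", "grade", "age_years",
                        "treatment", "study")

.clinical_levels <- list(
  er_status        = c("+", "-", "unknown"),
  ln_status        = c("-", "+", "unknown"),
  tumor_size_class = c("T1", "T2", "T3", "unknown"),
  grade            = c("1", "2", "3", "unknown"),
  treatment        = c("none", "tamoxifen", "chemotherapy", "unknown")
)

#' Validate an expression matrix
#'
#' Checks the invariants every downstream operation assumes: unique probe and
#' sample identifiers and finite, non-missing numeric values.  Missing values
#' are rejected outright; imputation is deliberately not provided because the
#' normalized arrays this pipeline targets are complete.
#'
#' @param x numeric matrix, probes in rows, samples in columns.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("expression must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stopf("expression matrix must carry probe rownames and sample colnames")
  dup <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup))
    stopf("duplicated probe id(s): %s", paste(dup, collapse = ", "))
  dup <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup))
    stopf("duplicated sample id(s): %s", paste(dup, collapse = ", "))
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stopf("non-finite/missing value at probe '%s', sample '%s'",
          rownames(x)[bad[1L]], colnames(x)[bad[2L]])
  }
  invisible(x)
}

#' Read a probes-by-samples expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of probe
#' identifiers.  Any non-numeric or missing cell is a hard error naming the
#' offending probe and sample; ragged rows and duplicate probed ids are
#' rejected.
#'
#' @param path file path.
#' @return numeric matrix with probe rownames and sample colnames.
#' @export
read_expression <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L)
    stopf("ragged rows in '%s': field counts %s", path,
          paste(unique(nf), collapse = ", "))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character",
                           na.strings = NULL)
  if (ncol(raw) < 2L) stopf("expression file needs >= 1 sample column")
  probes <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  dup <- unique(probes[duplicated(probes)])
  if (length(dup))
    stopf("duplicated probe id(s) in '%s': %s", path, paste(dup, collapse = ", "))
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)))
  )
  if (nrow(raw) == 1L) vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, samples))
  if (any(!is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)[1L, ]
    stopf("non-numeric or missing value '%s' at probe '%s', sample '%s'",
          raw[bad[1L], bad[2L] + 1L], probes[bad[1L]], samples[bad[2L]])
  }
  dimnames(vals) <- list(probes, samples)
  validate_expression(vals)
  vals
}

#' Write an expression matrix to TSV
#'
#' Values are written with 12 significant digits so that a read/write
#' round-trip reproduces the matrix to that precision.
#'
#' @param x expression matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  validate_expression(x)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("probe_id", colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1L, function(r)
    paste(formatC(r, digits = 12, format = "g"), collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Construct/validate a clinical table
#'
#' Enforces the column contract used throughout the package: distant
#' metastasis-free survival (`dmfs_time` in years, `dmfs_event` 0/1) plus the
#' standard clinical covariates.  Unknown categorical values are retained as
#' the explicit level `"unknown"` and excluded listwise per analysis.
#'
#' @param df data.frame with at least the required columns (see Details).
#' @return the validated data.frame, with categorical columns as character.
#' @export
clinical_table <- function(df) {
  miss <- setdiff(.clinical_required, names(df))
  if (length(miss))
    stopf("clinical table missing column(s): %s", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stopf("duplicated sample_id in clinical table")
  df$dmfs_time <- as.numeric(df$dmfs_time)
  df$dmfs_event <- as.numeric(df$dmfs_event)
  if (any(!is.finite(df$dmfs_time)) || any(df$dmfs_time < 0))
    stopf("dmfs_time must be finite and >= 0")
  if (!all(df$dmfs_event %in% c(0, 1)))
    stopf("dmfs_event must be 0/1")
  if (any(df$dmfs_event == 1 & df$dmfs_time <= 0))
    stopf("events require dmfs_time > 0")
  for (col in names(.clinical_levels)) {
    df[[col]] <- as.character(df[[col]])
    bad <- setdiff(unique(df[[col]]), .clinical_levels[[col]])
    if (length(bad))
      stopf("column '%s' has disallowed value(s): %s", col,
            paste(bad, collapse = ", "))
  }
  df$age_years <- suppressWarnings(as.numeric(df$age_years))
  df$study <- as.character(df$study)
  if (!is.null(df$subtype)) df$subtype <- as.character(df$subtype)
  df
}

#' Read a clinical table from TSV
#'
#' @param path file path.
#' @param time_unit `"years"` (default) or `"months"`; months are converted
#'   to years by division by 12.
#' @return validated clinical data.frame.
#' @export
read_clinical <- function(path, time_unit = c("years", "months")) {
  time_unit <- match.arg(time_unit)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character",
                          na.strings = c("NA", ""))
  if (time_unit == "months") {
    df$dmfs_time <- as.numeric(df$dmfs_time) / 12
  }
  clinical_table(df)
}

#' Write a clinical table to TSV
#' @param clinical validated clinical data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene mapping
#'
#' Two-column TSV (`probe_id`, `gene_symbol`).  Every probe maps to exactly
#' one gene; many probes per gene are allowed.
#'
#' @param path file path.
#' @return named character vector, names = probe ids, values = gene symbols.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character")
  if (ncol(df) < 2L) stopf("probe map needs two columns")
  if (anyDuplicated(df[[1L]]))
    stopf("probe map has duplicated probe id(s)")
  stats::setNames(df[[2L]], df[[1L]])
}

#' Write a probe-to-gene mapping
#' @param probe_map named character vector (probe -> gene).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_map <- function(probe_map, path) {
  utils::write.table(
    data.frame(probe_id = names(probe_map), gene_symbol = unname(probe_map)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Intersect probe sets across expression matrices
#'
#' Mirrors multi-platform integration where only probe sets common to all
#' chip types are retained.  The result is sorted, hence deterministic and
#' invariant to input order.
#'
#' @param matrices list of expression matrices (>= 1).
#' @return sorted character vector of shared probe ids.
#' @export
intersect_probes <- function(matrices) {
  if (!is.list(matrices) || !length(matrices))
    stopf("need at least one expression matrix")
  ids <- lapply(matrices, function(m) {
    if (is.null(rownames(m))) stopf("matrix without probe rownames")
    rownames(m)
  })
  common <- Reduce(intersect, ids)
  if (!length(common)) stopf("empty probe intersection")
  sort(common)
}

#' Delimit follow-up to a fixed horizon
#'
#' Administratively censors observations beyond `horizon_years`: samples with
#' `dmfs_time > horizon` are set to the horizon with `dmfs_event = 0`.
#' Events exactly at the horizon are kept (closed interval).  Idempotent.
#'
#' @param clinical clinical data.frame.
#' @param horizon_years positive horizon, default 10 years.
#' @return clinical table with delimited follow-up.
#' @export
delimit_followup <- function(clinical, horizon_years = 10) {
  if (!is.numeric(horizon_years) || horizon_years <= 0)
    stopf("horizon must be > 0")
  if (any(clinical$dmfs_time < 0)) stopf("negative dmfs_time")
  over <- clinical$dmfs_time > horizon_years
  clinical$dmfs_event[over] <- 0
  clinical$dmfs_time[over] <- horizon_years
  clinical
}
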