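# Nearest-centroid intrinsic subtype classification: Single Sample
# Predictor (Spearman correlation with a minimum-correlation floor) and
# Claudin-Low assignment (Euclidean distance).

#' Construct/validate a centroid set
#'
#' @param mat numeric matrix, genes in rows (unique symbols), one column per
#'   subtype (>= 2).
#' @return the matrix with class `centroid_set`.
#' @export
centroid_set <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) stopf("centroids must be a numeric matrix")
  if (is.null(rownames(mat))) stopf("centroid rows must be named by gene symbol")
  if (anyDuplicated(rownames(mat))) stopf("duplicate gene symbols in centroids")
  if (ncol(mat) < 2L) stopf("need >= 2 subtype centroids")
  class(mat) <- c("centroid_set", class(mat))
  mat
}

#' Read a centroid table (genes x subtypes TSV)
#' @param path file path; first column gene symbol, one column per subtype.
#' @return a `centroid_set`.
#' @export
read_centroids <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE)
  m <- as.matrix(df[-1L])
  rownames(m) <- as.character(df[[1L]])
  centroid_set(m)
}

# collapse probes to gene symbols by averaging
.collapse_genes <- function(expr, probe_map) {
  genes <- probe_map[rownames(expr)]
  keep <- !is.na(genes)
  x <- expr[keep, , drop = FALSE]
  genes <- genes[keep]
  gsum <- rowsum(x, group = genes)
  gsum / as.numeric(table(genes)[rownames(gsum)])
}

.shared_centered <- function(expr, probe_map, centroids) {
  gmat <- .collapse_genes(expr, probe_map)
  shared <- intersect(rownames(gmat), rownames(centroids))
  if (!length(shared)) stopf("no genes shared with centroids")
  if (length(shared) < 2L) stopf("need >= 2 genes shared with centroids")
  if (length(shared) < 10L)
    warning(sprintf("only %d genes shared with centroids", length(shared)))
  # per-gene mean centering across samples, before any per-sample comparison
  g <- gmat[shared, , drop = FALSE]
  list(x = g - rowMeans(g), cent = centroids[shared, , drop = FALSE])
}

#' Single Sample Predictor subtype classification
#'
#' Collapses probes to genes by averaging, mean-centers each gene across
#' samples, then assigns each sample the subtype whose centroid attains the
#' highest Spearman correlation over the shared genes.  Samples whose best
#' correlation does not exceed `min_corr` are left `"UNASSIGNED"`.  Exact
#' ties are broken by centroid column order and flagged.
#'
#' @param expr expression matrix.
#' @param probe_map named character vector probe -> gene symbol.
#' @param centroids a `centroid_set`.
#' @param min_corr minimum correlation floor (default 0.1).
#' @return data.frame `sample_id`, `subtype`, `best_corr`, `tie`; the full
#'   sample-by-centroid correlation matrix is attached as attribute
#'   `"correlations"`.
#' @export
ssp_classify <- function(expr, probe_map, centroids, min_corr = 0.1) {
  sc <- .shared_centered(expr, probe_map, centroids)
  R <- stats::cor(sc$x, sc$cent, method = "spearman")
  best <- apply(R, 1L, max)
  pick <- apply(R, 1L, which.max)
  tie <- apply(R, 1L, function(r) sum(r == max(r)) > 1L)
  lab <- colnames(sc$cent)[pick]
  lab[best <= min_corr] <- "UNASSIGNED"
  out <- data.frame(sample_id = colnames(expr), subtype = lab,
                    best_corr = as.numeric(best), tie = tie,
                    row.names = NULL)
  attr(out, "correlations") <- R
  out
}

#' Claudin-Low classification by Euclidean nearest centroid
#'
#' Assigns each sample to the nearest centroid by Euclidean distance over
#' the shared, per-gene mean-centered genes.  A sample is labelled `CL` only
#' if the Claudin-Low centroid is its strictly nearest centroid (ties are
#' conservatively not-CL).  Downstream, a CL call overrides the SSP label.
#'
#' @param expr expression matrix.
#' @param probe_map named character vector probe -> gene symbol.
#' @param cl_centroids a `centroid_set` containing a Claudin-Low centroid
#'   alongside the other subtypes.
#' @param cl_label column name of the Claudin-Low centroid.
#' @return data.frame `sample_id`, `claudin_low` (logical), `nearest`;
#'   distances attached as attribute `"distances"`.
#' @export
claudin_low_classify <- function(expr, probe_map, cl_centroids,
                                 cl_label = "Claudin-Low") {
  if (!cl_label %in% colnames(cl_centroids))
    stopf("no centroid column named '%s'", cl_label)
  sc <- .shared_centered(expr, probe_map, cl_centroids)
  # squared Euclidean distances sample x centroid
  D <- outer(colSums(sc$x^2), colSums(sc$cent^2), "+") -
    2 * crossprod(sc$x, sc$cent)
  nearest_i <- apply(D, 1L, which.min)
  strict <- vapply(seq_len(nrow(D)), function(i)
    sum(D[i, ] == min(D[i, ])) == 1L, logical(1))
  nearest <- colnames(sc$cent)[nearest_i]
  is_cl <- nearest == cl_label & strict
  out <- data.frame(sample_id = colnames(expr), claudin_low = is_cl,
                    nearest = nearest, row.names = NULL)
  attr(out, "distances") <- sqrt(pmax(D, 0))
  out
}

#' Combine SSP and Claudin-Low calls
#'
#' Claudin-Low overrides the SSP label; disagreements are flagged.
#'
#' @param ssp result of [ssp_classify()].
#' @param cl result of [claudin_low_classify()].
#' @return data.frame `sample_id`, `subtype`, `ssp_subtype`, `cl_override`.
#' @export
combine_subtype_calls <- function(ssp, cl) {
  stopifnot(identical(ssp$sample_id, cl$sample_id))
  lab <- ssp$subtype
  lab[cl$claudin_low] <- "Claudin-Low"
  data.frame(sample_id = ssp$sample_id, subtype = lab,
             ssp_subtype = ssp$subtype,
             cl_override = cl$claudin_low & ssp$subtype != "Claudin-Low",
             row.names = NULL)
}

#' Write centroids to TSV
#' @param centroids a `centroid_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_centroids <- function(centroids, path) {
  df <- data.frame(gene_symbol = rownames(centroids),
                   as.data.frame(unclass(centroids), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
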