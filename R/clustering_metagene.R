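# Hierarchical clustering, nested-branch subcluster extraction, metagene
# scoring, and tertile machinery.

# Pearson correlation of matrix rows via BLAS (much faster than cor(t(x))
# for thousands of probes); rows must be non-constant.
.row_cor <- function(x) {
  xs <- x - rowMeans(x)
  xs <- xs / sqrt(rowSums(xs^2))
  cc <- tcrossprod(xs)
  cc[cc > 1] <- 1
  cc[cc < -1] <- -1
  cc
}

#' Mean-center probe rows
#'
#' Centers each probe (gene) row to mean zero.  Columns (samples) are left
#' untouched: centering is on genes only.
#'
#' @param expr expression matrix.
#' @return centered matrix.
#' @export
mean_center <- function(expr) {
  if (!nrow(expr)) stopf("empty matrix")
  expr - rowMeans(expr)
}

#' Average-linkage hierarchical clustering of probes
#'
#' Distance is one minus correlation.  `"pearson"` uses the centered Pearson
#' correlation of probe rows; `"uncentered_pearson"` uses the cosine of the
#' raw rows (the uncentered correlation used for heatmap-style clustering).
#'
#' @param expr expression matrix (>= 2 probes).
#' @param metric `"pearson"` (default) or `"uncentered_pearson"`.
#' @param linkage only `"average"` is supported.
#' @return object of class `mg_dendrogram`: list with the `hclust` fit, the
#'   probe `labels` and the `metric`.
#' @export
hcluster <- function(expr, metric = c("pearson", "uncentered_pearson"),
                     linkage = "average") {
  metric <- match.arg(metric)
  if (!identical(linkage, "average")) stopf("only average linkage supported")
  if (nrow(expr) < 2L) stopf("need >= 2 probes")
  if (metric == "pearson") {
    sds <- apply(expr, 1L, stats::sd)
    if (any(sds == 0))
      stopf("zero-variance probe(s) under pearson metric: %s",
            paste(rownames(expr)[sds == 0], collapse = ", "))
    cc <- .row_cor(expr)
  } else {
    nrm <- sqrt(rowSums(expr^2))
    if (any(nrm == 0))
      stopf("zero-norm probe(s) under uncentered metric: %s",
            paste(rownames(expr)[nrm == 0], collapse = ", "))
    cc <- tcrossprod(expr / nrm)
  }
  d <- 1 - cc
  d[d < 0] <- 0  # numerical guard
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  structure(list(hclust = hc, labels = rownames(expr), metric = metric),
            class = "mg_dendrogram")
}

#' @export
print.mg_dendrogram <- function(x, ...) {
  cat(sprintf("Average-linkage dendrogram over %d probes (%s distance)\n",
              length(x$labels), x$metric))
  invisible(x)
}

#' Export a dendrogram as a Newick string
#' @param dend an `mg_dendrogram`.
#' @param path optional file; if `NULL` the Newick string is returned.
#' @return Newick string (invisibly if written to file).
#' @export
dendrogram_newick <- function(dend, path = NULL) {
  phy <- ape::as.phylo(dend$hclust)
  if (is.null(path)) ape::write.tree(phy)
  else {
    ape::write.tree(phy, file = path)
    invisible(path)
  }
}

# leaf members of each internal node of an hclust merge matrix
.node_members <- function(merge) {
  n_nodes <- nrow(merge)
  members <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) {
    left <- merge[i, 1L]
    right <- merge[i, 2L]
    members[[i]] <- c(
      if (left < 0) -left else members[[left]],
      if (right < 0) -right else members[[right]]
    )
  }
  members
}

.avg_pairwise_r <- function(C, idx) {
  k <- length(idx)
  (sum(C[idx, idx]) - k) / (k * (k - 1))
}

#' Extract maximal subclusters at an average-correlation threshold
#'
#' Walks the dendrogram from the root and returns every maximal branch (no
#' qualifying ancestor) whose leaf set has at least `min_size` members and an
#' average pairwise Pearson correlation of at least `r_threshold`, computed
#' on the expression rows.  Returned subclusters are disjoint by
#' construction and sorted by size, largest first.
#'
#' @param dend an `mg_dendrogram` over the rows of `expr`.
#' @param expr the expression matrix the dendrogram was built from.
#' @param r_threshold average-correlation threshold (default 0.6).
#' @param min_size minimal branch size (default 10).
#' @return list of `subcluster` objects (`probes`,
#'   `average_pairwise_correlation`, `size`, `label`); possibly empty.
#' @export
extract_subclusters <- function(dend, expr, r_threshold = 0.6, min_size = 10) {
  if (!inherits(dend, "mg_dendrogram")) stopf("need an mg_dendrogram")
  labs <- dend$labels
  if (!all(labs %in% rownames(expr)))
    stopf("dendrogram leaves missing from expression matrix")
  x <- expr[labs, , drop = FALSE]
  C <- .row_cor(x)
  merge <- dend$hclust$merge
  members <- .node_members(merge)
  qualifies <- function(idx)
    length(idx) >= max(2L, min_size) &&
      .avg_pairwise_r(C, idx) >= r_threshold
  found <- list()
  # iterative DFS from the root; stop descending once a node qualifies
  stack <- nrow(merge)
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (node < 0) next  # singleton leaf, cannot qualify (min_size >= 2)
    idx <- members[[node]]
    if (qualifies(idx)) {
      found[[length(found) + 1L]] <- idx
    } else {
      stack <- c(stack, merge[node, 1L], merge[node, 2L])
    }
  }
  found <- found[order(vapply(found, length, numeric(1)), decreasing = TRUE)]
  lapply(seq_along(found), function(i) {
    idx <- found[[i]]
    structure(list(probes = labs[idx],
                   average_pairwise_correlation = .avg_pairwise_r(C, idx),
                   size = length(idx),
                   label = paste0("subcluster_", i)),
              class = "subcluster")
  })
}

#' @export
print.subcluster <- function(x, ...) {
  cat(sprintf("%s: %d probes, avg pairwise r = %.3f\n",
              x$label, x$size, x$average_pairwise_correlation))
  invisible(x)
}

#' Build a metagene from a probe list
#'
#' Per sample, the metagene value is the mean over genes of the mean over
#' each gene's probes, i.e. probe sets mapping to the same gene are first
#' averaged together before cross-gene averaging, guarding against
#' overrepresentation of any one gene.
#'
#' @param expr expression matrix.
#' @param probes probe ids (subset of `rownames(expr)`).
#' @param probe_map named character vector probe -> gene symbol covering
#'   `probes`.
#' @param name metagene name (e.g. `"proliferation"`, `"B/P"`).
#' @return list with `values` (named per-sample metagene values) and
#'   `definition` (class `metagene_definition`: `name`, `probes`, `collapse`
#'   gene -> probes, `tertile_cutpoints` initially `NULL`).
#' @export
build_metagene <- function(expr, probes, probe_map, name = "custom") {
  probes <- unique(as.character(probes))
  if (!length(probes)) stopf("empty probe list")
  miss <- setdiff(probes, rownames(expr))
  if (length(miss))
    stopf("probe(s) absent from expression matrix: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  genes <- probe_map[probes]
  if (any(is.na(genes)))
    stopf("probe(s) missing from probe map: %s",
          paste(utils::head(probes[is.na(genes)], 5), collapse = ", "))
  x <- expr[probes, , drop = FALSE]
  # collapse probes to genes by averaging, then average across genes
  gsum <- rowsum(x, group = genes)
  gcnt <- as.numeric(table(genes)[rownames(gsum)])
  gmat <- gsum / gcnt
  values <- colMeans(gmat)
  def <- structure(list(name = name,
                        probes = as.character(probes),
                        collapse = split(as.character(probes), genes),
                        tertile_cutpoints = NULL),
                   class = "metagene_definition")
  list(values = values, definition = def)
}

#' Score a metagene definition on a (possibly new) cohort
#' @param expr expression matrix containing the definition's probes.
#' @param definition a `metagene_definition`.
#' @return named per-sample metagene values.
#' @export
metagene_values <- function(expr, definition) {
  gm <- stats::setNames(
    rep(names(definition$collapse), lengths(definition$collapse)),
    unlist(definition$collapse))
  build_metagene(expr, definition$probes, gm, definition$name)$values
}

#' Tertile cut-points of a metagene distribution
#'
#' Empirical 1/3 and 2/3 quantiles using the linear-interpolation definition
#' (R quantile type 7).  The definition is pinned because cut-points are
#' serialized and applied across cohorts.
#'
#' @param values numeric vector with at least 3 distinct values.
#' @return named vector `c(q1, q2)` with `q1 < q2`.
#' @export
tertile_cutpoints <- function(values) {
  if (length(unique(values)) < 3L)
    stopf("need >= 3 distinct values for tertile cut-points")
  q <- stats::quantile(values, c(1 / 3, 2 / 3), type = 7, names = FALSE)
  if (q[1L] >= q[2L]) stopf("degenerate cut-points (q1 >= q2)")
  c(q1 = q[1L], q2 = q[2L])
}

#' Assign tertile levels from fixed cut-points
#'
#' Level 1 (low) if `v <= q1`, 2 (intermediate) if `q1 < v <= q2`, 3 (high)
#' if `v > q2`.  Boundary ties go to the lower tertile.
#'
#' @param values named per-sample metagene values.
#' @param cutpoints `c(q1, q2)` with `q1 < q2`, typically from
#'   [tertile_cutpoints()] on a training cohort.
#' @return named integer vector of levels in \{1, 2, 3\}.
#' @export
assign_tertiles <- function(values, cutpoints) {
  if (cutpoints[1L] >= cutpoints[2L]) stopf("require q1 < q2")
  lev <- ifelse(values <= cutpoints[1L], 1L,
                ifelse(values <= cutpoints[2L], 2L, 3L))
  stats::setNames(as.integer(lev), names(values))
}

#' Serialize a metagene definition as JSON
#' @param definition a `metagene_definition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metagene_definition <- function(definition, path) {
  write_json_result(list(
    name = definition$name,
    probes = definition$probes,
    collapse = definition$collapse,
    tertile_cutpoints = as.list(definition$tertile_cutpoints)
  ), path)
}

#' Read a metagene definition from JSON
#' @param path file path.
#' @return a `metagene_definition`.
#' @export
read_metagene_definition <- function(path) {
  j <- read_json_config(path)
  cp <- NULL
  if (length(j$tertile_cutpoints))
    cp <- c(q1 = j$tertile_cutpoints$q1, q2 = j$tertile_cutpoints$q2)
  structure(list(name = j$name,
                 probes = unlist(j$probes),
                 collapse = lapply(j$collapse, unlist),
                 tertile_cutpoints = cp),
            class = "metagene_definition")
}
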