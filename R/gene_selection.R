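# Genome-wide per-probe Cox screening with FDR control.

#' Per-probe Cox proportional-hazards screen
#'
#' Fits one univariable Cox model per probe with the probe's log2 expression
#' as a single continuous covariate and collects the likelihood-ratio test
#' p-value; q-values are computed by [adjust_fdr()].  Follow-up is assumed
#' already delimited to the analysis horizon (see [delimit_followup()]).
#'
#' Probes constant across samples are reported with `p = 1` and flagged
#' `"constant"`; the screen continues.
#'
#' @param expr expression matrix (probes x samples).
#' @param clinical clinical table; samples are aligned on `sample_id`.
#' @param fdr_method passed to [adjust_fdr()].
#' @return data.frame of class `gene_survival_table`: one row per probe with
#'   `probe_id`, `coefficient`, `hazard_ratio`, `ci95_low`, `ci95_high`,
#'   `lrt_p`, `q_value`, `direction` (`favorable` for HR < 1, else
#'   `adverse`), `flag`.
#' @export
screen_genes <- function(expr, clinical, fdr_method = c("BH", "storey")) {
  fdr_method <- match.arg(fdr_method)
  ids <- intersect(colnames(expr), clinical$sample_id)
  if (!length(ids)) stopf("no samples shared between expression and clinical")
  x <- expr[, ids, drop = FALSE]
  cl <- clinical[match(ids, clinical$sample_id), ]
  times <- cl$dmfs_time
  events <- cl$dmfs_event
  if (sum(events) < 1) stopf("no events in aligned cohort")
  y <- survival::Surv(times, events)
  ctrl <- survival::coxph.control(eps = 1e-9, iter.max = 50)
  rn <- as.character(seq_along(times))
  m <- nrow(x)
  coefs <- se <- pvals <- rep(NA_real_, m)
  flag <- rep("", m)
  for (i in seq_len(m)) {
    v <- x[i, ]
    if (max(v) - min(v) == 0) {
      pvals[i] <- 1
      flag[i] <- "constant"
      next
    }
    fit <- tryCatch(
      survival::coxph.fit(matrix(v, ncol = 1L), y, strata = NULL,
                          offset = NULL, init = NULL, control = ctrl,
                          weights = NULL, method = "breslow", rownames = rn),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$coefficients[1L])) {
      pvals[i] <- 1
      flag[i] <- "fit_failed"
      next
    }
    coefs[i] <- fit$coefficients[1L]
    se[i] <- sqrt(fit$var[1L, 1L])
    pvals[i] <- stats::pchisq(2 * (fit$loglik[2L] - fit$loglik[1L]),
                              df = 1, lower.tail = FALSE)
  }
  q <- adjust_fdr(pvals, method = fdr_method)
  out <- data.frame(
    probe_id = rownames(x),
    coefficient = coefs,
    hazard_ratio = exp(coefs),
    ci95_low = exp(coefs - 1.96 * se),
    ci95_high = exp(coefs + 1.96 * se),
    lrt_p = pvals,
    q_value = q,
    direction = ifelse(is.na(coefs), NA_character_,
                       ifelse(coefs < 0, "favorable", "adverse")),
    flag = flag,
    row.names = NULL
  )
  attr(out, "n_used") <- length(ids)
  attr(out, "n_events") <- sum(events)
  attr(out, "fdr_method") <- fdr_method
  class(out) <- c("gene_survival_table", "data.frame")
  out
}

#' FDR adjustment of p-values
#'
#' Benjamini-Hochberg step-up q-values by default (monotone, clipped to 1).
#' `method = "storey"` additionally rescales by the Storey null-proportion
#' estimate at `lambda = 0.5`.
#'
#' @param p_values p-values in \[0, 1\]; NaN is an error.
#' @param method `"BH"` (default) or `"storey"`.
#' @param lambda tuning parameter for the Storey estimate.
#' @return q-values, same length as `p_values`.
#' @export
adjust_fdr <- function(p_values, method = c("BH", "storey"), lambda = 0.5) {
  method <- match.arg(method)
  if (any(is.na(p_values))) stopf("NaN/NA p-values")
  if (any(p_values < 0 | p_values > 1)) stopf("p-values outside [0, 1]")
  q <- stats::p.adjust(p_values, method = "BH")
  if (method == "storey") {
    pi0 <- min(1, mean(p_values > lambda) / (1 - lambda))
    q <- pmin(1, pi0 * q)
  }
  q
}

#' Select prognostic probes by dual thresholds
#'
#' Probes must satisfy both the raw likelihood-ratio p-value and the
#' FDR q-value thresholds; input order is preserved.
#'
#' @param table a `gene_survival_table`.
#' @param p_thresh raw p threshold (default 0.01).
#' @param q_thresh q-value threshold (default 0.10).
#' @return character vector of selected probe ids.
#' @export
select_prognostic <- function(table, p_thresh = 0.01, q_thresh = 0.10) {
  keep <- table$lrt_p < p_thresh & table$q_value < q_thresh
  table$probe_id[keep]
}

#' Write a gene survival table as TSV
#' @param table a `gene_survival_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_survival_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
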