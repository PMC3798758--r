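# Covariate-balanced cohort randomization.
#
# The cohort is repeatedly split at random into two halves; the first split
# for which every monitored standardized difference is below the threshold
# AND the two-group survival log-rank p exceeds its floor is accepted.

#' Balance criteria for iterative randomization
#'
#' @param max_std_diff_pct accept only splits with every monitored
#'   standardized difference strictly below this percentage (default 10).
#' @param min_logrank_p accept only splits whose two-group DMFS log-rank
#'   p-value strictly exceeds this floor (default 0.99).
#' @param monitored_variables clinical columns to monitor.  `dmfs_time` is
#'   treated as continuous, `dmfs_event` as binary, everything else as
#'   categorical (max per-level standardized difference).
#' @param max_iterations iteration cap (default 10000).
#' @return list of class `balance_criteria`.
#' @export
balance_criteria <- function(max_std_diff_pct = 10,
                             min_logrank_p = 0.99,
                             monitored_variables = c("dmfs_time", "dmfs_event",
                                                     "study", "subtype",
                                                     "er_status"),
                             max_iterations = 10000L) {
  stopifnot(max_std_diff_pct >= 0, min_logrank_p >= 0, min_logrank_p < 1,
            max_iterations >= 1)
  structure(list(max_std_diff_pct = max_std_diff_pct,
                 min_logrank_p = min_logrank_p,
                 monitored_variables = monitored_variables,
                 max_iterations = as.integer(max_iterations)),
            class = "balance_criteria")
}

#' Standardized difference between two groups
#'
#' Scale-free between-group difference in percent.  Continuous:
#' `100 |m_a - m_b| / sqrt((s_a^2 + s_b^2)/2)` with sample variances.
#' Binary: same with `p(1-p)` variances.  Categorical with more than two
#' levels: maximum over per-level binary standardized differences.
#'
#' Zero pooled variance with unequal means returns `Inf`; two identical
#' constant groups return 0.
#'
#' @param a,b values in the two groups (non-empty).
#' @param kind one of `"continuous"`, `"binary"`, `"categorical"`.
#' @return standardized difference in percent.
#' @export
standardized_difference <- function(a, b,
                                    kind = c("continuous", "binary",
                                             "categorical")) {
  kind <- match.arg(kind)
  if (!length(a) || !length(b)) stopf("both groups must be non-empty")
  switch(kind,
    continuous = {
      a <- as.numeric(a); b <- as.numeric(b)
      num <- abs(mean(a) - mean(b))
      den <- sqrt((stats::var(a) + stats::var(b)) / 2)
      if (den == 0) if (num == 0) 0 else Inf else 100 * num / den
    },
    binary = {
      a <- as.numeric(a); b <- as.numeric(b)
      if (!all(c(a, b) %in% c(0, 1))) stopf("binary kind requires 0/1 values")
      pa <- mean(a); pb <- mean(b)
      num <- abs(pa - pb)
      den <- sqrt((pa * (1 - pa) + pb * (1 - pb)) / 2)
      if (den == 0) if (num == 0) 0 else Inf else 100 * num / den
    },
    categorical = {
      a <- as.character(a); b <- as.character(b)
      levs <- union(unique(a), unique(b))
      if (length(levs) <= 1L) return(0)
      max(vapply(levs, function(l)
        standardized_difference(as.numeric(a == l), as.numeric(b == l),
                                "binary"),
        numeric(1)))
    })
}

.monitored_kind <- function(var) {
  if (var %in% c("dmfs_time", "age_years")) "continuous"
  else if (var == "dmfs_event") "binary"
  else "categorical"
}

.split_diagnostics <- function(clinical, idx_a, criteria) {
  a <- clinical[idx_a, , drop = FALSE]
  b <- clinical[-idx_a, , drop = FALSE]
  diffs <- vapply(criteria$monitored_variables, function(v)
    standardized_difference(a[[v]], b[[v]], .monitored_kind(v)), numeric(1))
  names(diffs) <- criteria$monitored_variables
  diffs
}

#' Iteratively randomize a cohort into two balanced halves
#'
#' Repeats uniform half-splits from a seeded RNG and returns the first split
#' meeting all criteria.  For odd cohorts the group sizes differ by one, the
#' larger group chosen at random each iteration.  On failure an error of
#' class `mg_split_error` is raised carrying the best split found (smallest
#' maximum standardized difference) in its `best` field.
#'
#' @param clinical clinical data.frame (all monitored variables present).
#' @param criteria a [balance_criteria()] object.
#' @param seed integer RNG seed; recorded in the result.
#' @return list of class `split_result`: `group_a_ids`, `group_b_ids`,
#'   `achieved_std_diffs` (percent, named), `logrank_p`, `iterations_used`,
#'   `seed`.
#' @export
balanced_split <- function(clinical, criteria = balance_criteria(), seed = 1L) {
  n <- nrow(clinical)
  if (n < 2L) stopf("need >= 2 samples")
  miss <- setdiff(criteria$monitored_variables, names(clinical))
  if (length(miss))
    stopf("monitored variable(s) absent from clinical table: %s",
          paste(miss, collapse = ", "))
  half <- n %/% 2L
  best <- NULL
  best_max <- Inf
  res <- with_seed(seed, {
    out <- NULL
    for (it in seq_len(criteria$max_iterations)) {
      sz <- if (n %% 2L == 0L) half else half + stats::rbinom(1L, 1L, 0.5)
      idx_a <- sample.int(n, sz)
      diffs <- .split_diagnostics(clinical, idx_a, criteria)
      if (max(diffs) < best_max) {
        best_max <- max(diffs)
        best <- list(idx_a = idx_a, diffs = diffs, iteration = it)
      }
      if (all(diffs < criteria$max_std_diff_pct)) {
        grp <- factor(ifelse(seq_len(n) %in% idx_a, "A", "B"))
        lr <- logrank_test_vec(clinical$dmfs_time, clinical$dmfs_event, grp)
        if (lr$p_value > criteria$min_logrank_p) {
          out <- list(idx_a = idx_a, diffs = diffs, logrank_p = lr$p_value,
                      iterations = it)
          break
        }
      }
    }
    out
  })
  if (is.null(res)) {
    best_split <- NULL
    if (!is.null(best)) {
      grp <- factor(ifelse(seq_len(n) %in% best$idx_a, "A", "B"))
      lr <- tryCatch(
        logrank_test_vec(clinical$dmfs_time, clinical$dmfs_event, grp),
        error = function(e) NULL)
      best_split <- list(group_a_ids = clinical$sample_id[best$idx_a],
                         group_b_ids = clinical$sample_id[-best$idx_a],
                         achieved_std_diffs = best$diffs,
                         logrank_p = if (is.null(lr)) NA_real_ else lr$p_value)
    }
    cond <- structure(
      class = c("mg_split_error", "error", "condition"),
      list(message = sprintf(
             "balanced_split: no acceptable split in %d iterations (best max std diff %.2f%%)",
             criteria$max_iterations, best_max),
           call = sys.call(-1), best = best_split))
    stop(cond)
  }
  structure(list(group_a_ids = clinical$sample_id[res$idx_a],
                 group_b_ids = clinical$sample_id[-res$idx_a],
                 achieved_std_diffs = res$diffs,
                 logrank_p = res$logrank_p,
                 iterations_used = res$iterations,
                 seed = as.integer(seed),
                 criteria = criteria),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("Balanced split: %d vs %d samples, %d iteration(s), seed %d\n",
              length(x$group_a_ids), length(x$group_b_ids),
              x$iterations_used, x$seed))
  cat(sprintf("  log-rank p = %.4f; standardized differences (%%):\n",
              x$logrank_p))
  print(round(x$achieved_std_diffs, 2))
  invisible(x)
}

#' Serialize a split result as JSON
#' @param split a `split_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_split_result <- function(split, path) {
  write_json_result(list(
    group_a_ids = split$group_a_ids,
    group_b_ids = split$group_b_ids,
    achieved_std_diffs = as.list(split$achieved_std_diffs),
    logrank_p = split$logrank_p,
    iterations_used = split$iterations_used,
    seed = split$seed
  ), path)
}
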