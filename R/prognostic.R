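# Conditional-prognosis analyses: tertile-stratified survival, multivariable
# Cox models, and the combinatorial immune-tertile profile classifier.

.align_tertiles <- function(tertiles, sample_id) {
  v <- tertiles[sample_id]
  stats::setNames(as.integer(v), sample_id)
}

#' Tertile-conditional survival analysis
#'
#' Within each stratum (proliferation tertile by default, optionally crossed
#' with subtype and/or treatment), runs for every immune metagene a 3-group
#' Kaplan-Meier + log-rank test across the metagene's tertiles and a
#' univariable Cox model with the tertile level (1/2/3) as an ordinal
#' covariate.  Strata with fewer than `min_n` samples or zero events are
#' skipped with a recorded reason rather than silently dropped.
#'
#' @param immune_tertiles named list of per-sample tertile assignments (one
#'   element per metagene, each a named integer vector in \{1,2,3\}).
#' @param prolif_tertiles named per-sample proliferation tertile assignment.
#' @param clinical clinical table.
#' @param strata_by subset of `c("proliferation_tertile", "subtype",
#'   "treatment")` defining the strata.
#' @param min_n minimum stratum size analyzed (default 10).
#' @return object of class `stratified_result`: `summary` data.frame (one
#'   row per stratum x metagene) and `detail` list with KM curves.
#' @export
conditional_analysis <- function(immune_tertiles, prolif_tertiles, clinical,
                                 strata_by = "proliferation_tertile",
                                 min_n = 10) {
  allowed <- c("proliferation_tertile", "subtype", "treatment")
  bad <- setdiff(strata_by, allowed)
  if (length(bad)) stopf("unknown stratum key(s): %s", paste(bad, collapse = ", "))
  if (!length(strata_by)) stopf("need at least one stratum key")
  ids <- clinical$sample_id
  parts <- list()
  if ("proliferation_tertile" %in% strata_by) {
    pt <- .align_tertiles(prolif_tertiles, ids)
    parts$prolif <- factor(c("P^L", "P^I", "P^H")[pt],
                           levels = c("P^L", "P^I", "P^H"))
  }
  if ("subtype" %in% strata_by) {
    if (is.null(clinical$subtype)) stopf("clinical table lacks 'subtype'")
    parts$subtype <- factor(clinical$subtype)
  }
  if ("treatment" %in% strata_by) parts$treatment <- factor(clinical$treatment)
  stratum <- interaction(parts, sep = " | ", drop = TRUE, lex.order = TRUE)

  summary_rows <- list()
  detail <- list()
  for (s in levels(stratum)) {
    in_s <- which(stratum == s & !is.na(stratum))
    for (mg in names(immune_tertiles)) {
      tl <- .align_tertiles(immune_tertiles[[mg]], ids)[in_s]
      ok <- !is.na(tl)
      idx <- in_s[ok]
      n <- length(idx)
      nev <- sum(clinical$dmfs_event[idx])
      row <- data.frame(stratum = s, metagene = mg, n = n, n_events = nev,
                        logrank_p = NA_real_, hazard_ratio = NA_real_,
                        ci95_low = NA_real_, ci95_high = NA_real_,
                        cox_p = NA_real_, skipped = FALSE,
                        reason = "", stringsAsFactors = FALSE)
      if (n < min_n || nev == 0) {
        row$skipped <- TRUE
        row$reason <- if (n < min_n) sprintf("n < %d", min_n) else "no events"
        summary_rows[[length(summary_rows) + 1L]] <- row
        next
      }
      tms <- clinical$dmfs_time[idx]
      evs <- clinical$dmfs_event[idx]
      lev <- .align_tertiles(immune_tertiles[[mg]], ids)[idx]
      grp <- factor(c("low", "intermediate", "high")[lev],
                    levels = c("low", "intermediate", "high"))
      lr <- tryCatch(
        if (nlevels(droplevels(grp)) >= 2L)
          logrank_test_vec(tms, evs, grp) else NULL,
        error = function(e) NULL)
      cx <- tryCatch(cox_fit(as.numeric(lev), tms, evs),
                     error = function(e) NULL)
      if (!is.null(lr)) row$logrank_p <- lr$p_value
      if (!is.null(cx)) {
        row$hazard_ratio <- cx$table$hazard_ratio[1L]
        row$ci95_low <- cx$table$ci95_low[1L]
        row$ci95_high <- cx$table$ci95_high[1L]
        row$cox_p <- cx$table$wald_p[1L]
      }
      if (is.null(lr) && is.null(cx)) {
        row$skipped <- TRUE
        row$reason <- "tests failed (degenerate stratum)"
      }
      km <- lapply(split(seq_along(tms), droplevels(grp)), function(i)
        km_estimate(tms[i], evs[i]))
      detail[[paste(s, mg, sep = " :: ")]] <-
        list(km = km, logrank = lr, cox = cx)
      summary_rows[[length(summary_rows) + 1L]] <- row
    }
  }
  structure(list(summary = do.call(rbind, summary_rows), detail = detail,
                 strata_by = strata_by, min_n = min_n,
                 tertile_coding = "ordinal 1/2/3 (low/intermediate/high)"),
            class = "stratified_result")
}

#' @export
print.stratified_result <- function(x, ...) {
  cat("Stratified tertile survival analysis (tertiles coded 1/2/3)\n")
  print(x$summary, digits = 3)
  invisible(x)
}

# conventional covariate coding for multivariable models; returns NA where
# a value is unknown so complete-case restriction can act on it.
.conventional_covariates <- function(clinical) {
  data.frame(
    ln_status = ifelse(clinical$ln_status == "unknown", NA,
                       as.numeric(clinical$ln_status == "+")),
    tumor_size = ifelse(clinical$tumor_size_class == "unknown", NA,
                        match(clinical$tumor_size_class, c("T1", "T2", "T3"))),
    grade = as.numeric(match(clinical$grade, c("1", "2", "3"))),
    age_gt40 = ifelse(is.na(clinical$age_years), NA,
                      as.numeric(clinical$age_years > 40)),
    er_positive = ifelse(clinical$er_status == "unknown", NA,
                         as.numeric(clinical$er_status == "+")),
    treated = ifelse(clinical$treatment == "unknown", NA,
                     as.numeric(clinical$treatment != "none"))
  )
}

#' Multivariable Cox models over immune metagene tertiles
#'
#' Fits, inside a single stratum (by default the high proliferation
#' tertile), all pairwise combinations of the immune metagenes and the full
#' three-metagene model, each with ordinal 1/2/3 tertile coding.  With
#' `include_conventional = TRUE` a further model adds the conventional
#' covariates: lymph-node status (+ vs -), tumor size (T1/T2/T3 ordinal),
#' grade (ordinal), age (> 40 vs <= 40), ER status (+ = 1 vs - = 0) and
#' systemic treatment (any vs none).  Complete cases only; the coding
#' direction of every covariate is recorded in the output.
#'
#' @param immune_tertiles named list of per-sample tertile assignments.
#' @param clinical clinical table.
#' @param stratum logical vector over `clinical` rows selecting the stratum
#'   (e.g. high proliferation tertile), or `NULL` for all samples.
#' @param include_conventional add the conventional-covariate model.
#' @return list of class `multivariable_result`: per-model [cox_fit()]
#'   results plus a combined coefficient `table`.
#' @export
multivariable_models <- function(immune_tertiles, clinical, stratum = NULL,
                                 include_conventional = FALSE) {
  ids <- clinical$sample_id
  if (is.null(stratum)) stratum <- rep(TRUE, nrow(clinical))
  mg <- names(immune_tertiles)
  if (length(mg) < 2L) stopf("need >= 2 metagenes")
  tert <- vapply(immune_tertiles, function(t)
    as.numeric(.align_tertiles(t, ids)), numeric(nrow(clinical)))
  colnames(tert) <- mg

  specs <- list()
  if (length(mg) >= 2L)
    for (cmb in utils::combn(mg, 2L, simplify = FALSE))
      specs[[paste(cmb, collapse = " + ")]] <- cmb
  if (length(mg) >= 3L) specs[[paste(mg, collapse = " + ")]] <- mg

  conv <- .conventional_covariates(clinical)
  fit_one <- function(cols, with_conv) {
    X <- tert[, cols, drop = FALSE]
    if (with_conv) X <- cbind(X, as.matrix(conv))
    keep <- stratum & stats::complete.cases(X)
    if (!sum(keep)) stopf("no complete cases in stratum")
    evs <- clinical$dmfs_event[keep]
    if (sum(evs) == 0) stopf("no events")
    cox_fit(X[keep, , drop = FALSE], clinical$dmfs_time[keep], evs)
  }
  fits <- lapply(specs, fit_one, with_conv = FALSE)
  if (include_conventional)
    fits[[paste(c(mg, "conventional"), collapse = " + ")]] <-
      fit_one(mg, with_conv = TRUE)
  tabs <- do.call(rbind, lapply(names(fits), function(nm) {
    t <- fits[[nm]]$table
    t$model <- nm
    t$n <- fits[[nm]]$n_used
    t
  }))
  structure(list(models = fits, table = tabs,
                 coding = c(
                   metagenes = "tertile level 1/2/3 (low/intermediate/high)",
                   ln_status = "1 = positive vs 0 = negative",
                   tumor_size = "ordinal T1=1, T2=2, T3=3",
                   grade = "ordinal 1/2/3",
                   age_gt40 = "1 = age > 40 years",
                   er_positive = "1 = ER+ vs 0 = ER-",
                   treated = "1 = any systemic treatment vs 0 = none")),
            class = "multivariable_result")
}

#' @export
print.multivariable_result <- function(x, ...) {
  cat("Multivariable Cox models (tertiles coded 1/2/3)\n")
  print(x$table[, c("model", "term", "hazard_ratio", "ci95_low",
                    "ci95_high", "wald_p", "n")], digits = 3)
  invisible(x)
}

#' Combinatorial immune-tertile profile
#'
#' Classifies each sample's triple of immune tertile levels by its counts of
#' low (1) and high (3) tertiles: `all_high` (3,3,3 pattern),
#' `two_high_plus_intermediate`, `two_high_plus_low`, `one_high` (one high,
#' no low), `ge1_low` (any remaining profile with at least one low) and
#' `all_intermediate`.  Permutation-invariant across the three metagenes.
#'
#' @param levels matrix/data.frame with one row per sample and 3 columns of
#'   tertile levels, or a single length-3 vector.
#' @return data.frame `n_low`, `n_high`, `group` (one row per sample).
#' @export
combinatorial_profile <- function(levels) {
  if (is.null(dim(levels))) levels <- matrix(levels, nrow = 1L)
  levels <- as.matrix(levels)
  if (ncol(levels) != 3L) stopf("need exactly 3 tertile levels per sample")
  if (!all(levels %in% 1:3)) stopf("invalid tertile level (must be 1, 2 or 3)")
  n_low <- rowSums(levels == 1L)
  n_high <- rowSums(levels == 3L)
  group <- ifelse(n_high == 3L, "all_high",
           ifelse(n_high == 2L & n_low == 0L, "two_high_plus_intermediate",
           ifelse(n_high == 2L & n_low == 1L, "two_high_plus_low",
           ifelse(n_high == 1L & n_low == 0L, "one_high",
           ifelse(n_low >= 1L, "ge1_low", "all_intermediate")))))
  out <- data.frame(n_low = n_low, n_high = n_high, group = group,
                    stringsAsFactors = FALSE)
  if (!is.null(rownames(levels))) out$sample_id <- rownames(levels)
  out
}

#' Compare immune-profile groups by survival
#'
#' Kaplan-Meier + log-rank across a named partition of profile classes
#' within a stratum (e.g. all-high vs at-least-one-low inside the high
#' proliferation tertile of a treatment subgroup).
#'
#' @param profiles result of [combinatorial_profile()] with `sample_id`
#'   column, aligned to `clinical`.
#' @param clinical clinical table.
#' @param stratum logical vector over `clinical` rows, or `NULL`.
#' @param grouping named list mapping group name -> character vector of
#'   profile classes (must define >= 2 groups).
#' @return list of class `profile_comparison`: `km` curves per group,
#'   `logrank`, `n` per group.
#' @export
compare_profiles <- function(profiles, clinical, stratum = NULL, grouping) {
  if (!is.list(grouping) || length(grouping) < 2L)
    stopf("grouping must name >= 2 groups")
  if (is.null(stratum)) stratum <- rep(TRUE, nrow(clinical))
  prof <- profiles$group[match(clinical$sample_id, profiles$sample_id)]
  member <- rep(NA_character_, nrow(clinical))
  for (g in names(grouping))
    member[prof %in% grouping[[g]]] <- g
  keep <- stratum & !is.na(member)
  sizes <- table(factor(member[keep], levels = names(grouping)))
  if (any(sizes == 0))
    stopf("empty comparison group(s): %s",
          paste(names(sizes)[sizes == 0], collapse = ", "))
  tms <- clinical$dmfs_time[keep]
  evs <- clinical$dmfs_event[keep]
  grp <- factor(member[keep], levels = names(grouping))
  lr <- logrank_test_vec(tms, evs, grp)
  km <- lapply(split(seq_along(tms), grp), function(i)
    km_estimate(tms[i], evs[i]))
  structure(list(km = km, logrank = lr, n = as.list(sizes)),
            class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat("Immune-profile survival comparison\n  n per group:",
      paste(sprintf("%s=%d", names(x$n), unlist(x$n)), collapse = ", "), "\n")
  print(x$logrank)
  invisible(x)
}
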