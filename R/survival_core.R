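# Survival engine: Kaplan-Meier, k-group log-rank, Cox PH.
#
# KM and the log-rank test are small closed forms and implemented directly.
# Cox fitting delegates to survival::coxph.fit with the conventions pinned
# here: Breslow tie handling, Wald confidence intervals at 1.96 SE, and a
# likelihood-ratio test against the null model.  All tests are two-sided.

#' Kaplan-Meier product-limit estimate
#'
#' @param times follow-up times (>= 0).
#' @param events event indicators (0 = censored, 1 = event).
#' @param group_label optional label stored on the curve.
#' @return object of class `km_curve`: data.frame with one row per distinct
#'   event time (`time`, `n_risk`, `n_event`, `survival`).
#' @export
km_estimate <- function(times, events, group_label = NULL) {
  if (!length(times)) stopf("empty input")
  if (length(times) != length(events)) stopf("length mismatch")
  if (any(times < 0)) stopf("negative times")
  if (!all(events %in% c(0, 1))) stopf("events must be 0/1")
  te <- sort(unique(times[events == 1]))
  n_risk <- vapply(te, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(te, function(t) sum(times == t & events == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = te, n_risk = n_risk, n_event = n_event,
                    survival = surv)
  attr(out, "n") <- length(times)
  attr(out, "group_label") <- group_label
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a KM curve at arbitrary times
#' @param curve a `km_curve`.
#' @param at times at which to evaluate S(t).
#' @return numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, at) {
  vapply(at, function(t) {
    i <- which(curve$time <= t)
    if (!length(i)) 1 else curve$survival[max(i)]
  }, numeric(1))
}

#' k-group log-rank test
#'
#' Standard observed-minus-expected chi-square over the pooled risk sets with
#' hypergeometric variance, df = k - 1, two-sided p from the chi-square
#' distribution.
#'
#' @param groups either a list of length >= 2, each element a list/data.frame
#'   with components `times` and `events`, or the result of splitting via the
#'   `times`,`events`,`group` triple interface (see [logrank_test_vec()]).
#' @return list with `chi2`, `df`, `p_value`, per-group observed and expected
#'   event counts; class `logrank_test`.
#' @export
logrank_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stopf("need >= 2 groups")
  times <- unlist(lapply(groups, function(g) g$times))
  events <- unlist(lapply(groups, function(g) g$events))
  sizes <- vapply(groups, function(g) length(g$times), numeric(1))
  if (any(sizes == 0)) stopf("empty group")
  g <- rep(seq_along(groups), sizes)
  labs <- names(groups) %||% as.character(seq_along(groups))
  logrank_test_vec(times, events, factor(g, labels = labs))
}

#' k-group log-rank test (vector interface)
#'
#' @param times,events pooled follow-up data.
#' @param group factor of group membership.
#' @return as [logrank_test()].
#' @export
logrank_test_vec <- function(times, events, group) {
  group <- droplevels(as.factor(group))
  k <- nlevels(group)
  if (k < 2L) stopf("need >= 2 groups")
  if (!all(events %in% c(0, 1))) stopf("events must be 0/1")
  if (sum(events) == 0) stopf("no events")
  te <- sort(unique(times[events == 1]))
  gi <- as.integer(group)
  # at-risk counts per group at each event time
  nrisk <- matrix(0, length(te), k)
  devt <- matrix(0, length(te), k)
  for (j in seq_len(k)) {
    tj <- sort(times[gi == j])
    nrisk[, j] <- length(tj) - findInterval(te, tj, left.open = TRUE)
    ej <- times[gi == j & events == 1]
    if (length(ej)) {
      tab <- table(factor(ej, levels = te))
      devt[, j] <- as.numeric(tab)
    }
  }
  ntot <- rowSums(nrisk)
  dtot <- rowSums(devt)
  P <- nrisk / ntot
  E <- dtot * P
  w <- ifelse(ntot > 1, dtot * (ntot - dtot) / (ntot - 1), 0)
  # V = sum_t w_t (diag(p_t) - p_t p_t')
  V <- diag(colSums(w * P), k) - crossprod(P, w * P)
  O <- colSums(devt)
  Evec <- colSums(E)
  d <- (O - Evec)[-k]
  chi2 <- if (all(abs(d) < 1e-12)) 0 else {
    Vi <- V[-k, -k, drop = FALSE]
    as.numeric(t(d) %*% solve(Vi, d))
  }
  p <- stats::pchisq(chi2, df = k - 1, lower.tail = FALSE)
  structure(list(chi2 = chi2, df = k - 1, p_value = p,
                 observed = stats::setNames(O, levels(group)),
                 expected = stats::setNames(Evec, levels(group))),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi2 = %.4g, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Maximizes the Breslow partial likelihood (Newton iterations via the
#' survival package), reporting per-covariate hazard ratios with Wald 95%
#' confidence intervals at 1.96 standard errors and a model likelihood-ratio
#' test against the null.
#'
#' @param covariates numeric vector or matrix (n x p), no missing values and
#'   no constant columns.
#' @param times,events follow-up data.
#' @return object of class `cox_result`: list with `table` (term, coef,
#'   hazard_ratio, ci95_low, ci95_high, wald_p), `lrt_stat`, `lrt_df`,
#'   `lrt_p`, `n_used`, `n_events`, `ties`.
#' @export
cox_fit <- function(covariates, times, events) {
  x <- as.matrix(covariates)
  storage.mode(x) <- "double"
  times <- as.numeric(times)
  events <- as.numeric(events)
  if (is.null(colnames(x)))
    colnames(x) <- if (ncol(x) == 1L) "x" else paste0("x", seq_len(ncol(x)))
  n <- length(times)
  if (nrow(x) != n || length(events) != n) stopf("length mismatch")
  if (any(!is.finite(x))) stopf("missing/non-finite covariate values")
  if (!all(events %in% c(0, 1))) stopf("events must be 0/1")
  if (sum(events) < 1) stopf("no events")
  const <- apply(x, 2L, function(c) max(c) - min(c) == 0)
  if (any(const))
    stopf("constant covariate(s): %s", paste(colnames(x)[const], collapse = ", "))
  y <- survival::Surv(times, events)
  fit <- survival::coxph.fit(
    x, y, strata = NULL, offset = NULL, init = NULL,
    control = survival::coxph.control(eps = 1e-9, iter.max = 100),
    weights = NULL, method = "breslow", rownames = as.character(seq_len(n))
  )
  beta <- fit$coefficients
  if (any(!is.finite(beta)) || any(abs(beta) > 15))
    stopf("monotone likelihood (perfect separation); coefficients diverge")
  if (fit$iter >= 100) stopf("Cox fit did not converge in 100 iterations")
  se <- sqrt(diag(as.matrix(fit$var)))
  tab <- data.frame(
    term = colnames(x),
    coef = as.numeric(beta),
    se = se,
    hazard_ratio = exp(as.numeric(beta)),
    ci95_low = exp(as.numeric(beta) - 1.96 * se),
    ci95_high = exp(as.numeric(beta) + 1.96 * se),
    wald_p = 2 * stats::pnorm(-abs(as.numeric(beta) / se)),
    row.names = NULL
  )
  lrt <- 2 * (fit$loglik[2L] - fit$loglik[1L])
  structure(list(
    table = tab,
    lrt_stat = lrt,
    lrt_df = ncol(x),
    lrt_p = stats::pchisq(lrt, df = ncol(x), lower.tail = FALSE),
    n_used = n,
    n_events = sum(events),
    ties = "breslow",
    loglik = fit$loglik
  ), class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH fit (Breslow ties): n = %d, events = %d\n",
              x$n_used, x$n_events))
  print(x$table, digits = 4)
  cat(sprintf("LRT: chi2 = %.4g on %d df, p = %.4g\n",
              x$lrt_stat, x$lrt_df, x$lrt_p))
  invisible(x)
}

#' Write KM curves as TSV
#' @param curves named list of `km_curve` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_km_curves <- function(curves, path) {
  rows <- do.call(rbind, lapply(names(curves), function(nm) {
    c <- curves[[nm]]
    data.frame(group = nm, time = c$time, survival = c$survival,
               at_risk = c$n_risk, events = c$n_event)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
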