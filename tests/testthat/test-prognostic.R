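# fixture: cohort with tertiles reconstructed from the planted modules
.prog_fixture <- function(seed, n = 600, ...) {
  sim <- simulate_cohort(sim_config(n_samples = as.integer(n), seed = seed,
                                    ...))
  tert <- lapply(c(proliferation = "proliferation", `B/P` = "B/P",
                   `T/NK` = "T/NK", `M/D` = "M/D"), function(m) {
    pr <- names(sim$truth$probe_modules)[sim$truth$probe_modules == m]
    bm <- build_metagene(sim$expression, pr, sim$probe_map, m)
    assign_tertiles(bm$values, tertile_cutpoints(bm$values))
  })
  list(sim = sim, clinical = delimit_followup(sim$clinical),
       prolif = tert$proliferation,
       immune = tert[c("B/P", "T/NK", "M/D")])
}

.prog_ph_stratum <- function(fx)
  as.numeric(fx$prolif[fx$clinical$sample_id]) == 3

test_that("conditional_analysis reports per-stratum tests and bookkeeping", {
  fx <- .prog_fixture(401)
  res <- conditional_analysis(fx$immune, fx$prolif, fx$clinical)
  s <- res$summary
  expect_setequal(unique(s$stratum), c("P^L", "P^I", "P^H"))
  expect_equal(nrow(s), 9)  # 3 strata x 3 metagenes
  # stratum sizes partition the cohort
  expect_equal(sum(s$n[s$metagene == "B/P"]), nrow(fx$clinical))
  # protective immune effect confined to the high-proliferation stratum
  hi <- s[s$stratum == "P^H" & s$metagene == "B/P", ]
  expect_lt(hi$hazard_ratio, 1)
  expect_lt(hi$cox_p, 0.05)
  # KM detail present for analyzed strata
  expect_true("P^H :: B/P" %in% names(res$detail))
  expect_error(conditional_analysis(fx$immune, fx$prolif, fx$clinical,
                                    strata_by = "nope"), "unknown stratum")
})

test_that("conditional_analysis skips degenerate strata with a reason", {
  cl <- make_clinical(c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 0, 0, 0))
  tert <- setNames(rep(1:3, 2), cl$sample_id)
  prolif <- setNames(rep(c(1L, 3L), each = 3), cl$sample_id)
  res <- conditional_analysis(list(bp = tert), prolif, cl, min_n = 2)
  expect_true(all(res$summary$skipped))
  expect_true(all(res$summary$reason == "no events"))
  # min_n gate
  res2 <- conditional_analysis(list(bp = tert), prolif, cl, min_n = 10)
  expect_true(all(grepl("n <", res2$summary$reason)))
})

test_that("permuted survival removes conditional significance", {
  fx <- .prog_fixture(402)
  perm <- fx$clinical
  set.seed(403)
  idx <- sample.int(nrow(perm))
  perm[, c("dmfs_time", "dmfs_event")] <-
    perm[idx, c("dmfs_time", "dmfs_event")]
  res <- conditional_analysis(fx$immune, fx$prolif, perm)
  s <- res$summary[!res$summary$skipped, ]
  expect_lte(sum(s$cox_p < 0.05, na.rm = TRUE), 3)
})

test_that("independent metagenes retain joint significance", {
  ok <- vapply(1:5, function(i) {
    fx <- .prog_fixture(410 + i, n = 800, immune_intercorrelation = 0)
    ph <- .prog_ph_stratum(fx)
    mv <- multivariable_models(fx$immune[c("B/P", "T/NK")], fx$clinical,
                               stratum = ph)
    t <- mv$models[["B/P + T/NK"]]$table
    all(t$wald_p < 0.05)
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("redundant metagenes widen jointly and lose significance", {
  fx <- .prog_fixture(420, n = 800)
  # two half-metagenes built from the same planted module
  pr <- names(fx$sim$truth$probe_modules)[
    fx$sim$truth$probe_modules == "B/P"]
  halves <- split(pr, rep(1:2, length.out = length(pr)))
  copies <- lapply(halves, function(p) {
    bm <- build_metagene(fx$sim$expression, p, fx$sim$probe_map, "copy")
    assign_tertiles(bm$values, tertile_cutpoints(bm$values))
  })
  names(copies) <- c("bp_a", "bp_b")
  ph <- .prog_ph_stratum(fx)
  joint <- multivariable_models(copies, fx$clinical, stratum = ph)
  jt <- joint$models[["bp_a + bp_b"]]$table
  uni <- lapply(names(copies), function(nm) {
    keep <- ph
    cox_fit(as.numeric(copies[[nm]][fx$clinical$sample_id])[keep],
            fx$clinical$dmfs_time[keep], fx$clinical$dmfs_event[keep])
  })
  for (k in 1:2) {
    expect_gt(jt$se[k], uni[[k]]$table$se)  # collinearity inflates SEs
  }
  expect_lte(sum(jt$wald_p < 0.05), 1)  # at most one stays significant
})

test_that("multivariable_models fits the expected model set and codings", {
  fx <- .prog_fixture(430, n = 800)
  ph <- .prog_ph_stratum(fx)
  mv <- multivariable_models(fx$immune, fx$clinical, stratum = ph,
                             include_conventional = TRUE)
  expect_setequal(names(mv$models),
                  c("B/P + T/NK", "B/P + M/D", "T/NK + M/D",
                    "B/P + T/NK + M/D", "B/P + T/NK + M/D + conventional"))
  conv <- mv$models[["B/P + T/NK + M/D + conventional"]]
  expect_setequal(conv$table$term,
                  c("B/P", "T/NK", "M/D", "ln_status", "tumor_size", "grade",
                    "age_gt40", "er_positive", "treated"))
  expect_true(all(c("metagenes", "er_positive") %in% names(mv$coding)))
  # complete-case restriction: n with conventional <= n without
  expect_lte(conv$n_used, mv$models[["B/P + T/NK + M/D"]]$n_used)
  # all-censored stratum errors out
  cl0 <- fx$clinical
  cl0$dmfs_event <- 0
  expect_error(multivariable_models(fx$immune, cl0, stratum = ph),
               "no events")
})

test_that("combinatorial_profile implements the tertile taxonomy", {
  expect_equal(combinatorial_profile(c(1, 1, 1))$group, "ge1_low")
  expect_equal(combinatorial_profile(c(1, 1, 1))$n_low, 3)
  expect_equal(combinatorial_profile(c(3, 3, 3))$group, "all_high")
  expect_equal(combinatorial_profile(c(3, 3, 2))$group,
               "two_high_plus_intermediate")
  expect_equal(combinatorial_profile(c(3, 3, 1))$group, "two_high_plus_low")
  expect_equal(combinatorial_profile(c(3, 2, 2))$group, "one_high")
  expect_equal(combinatorial_profile(c(2, 2, 2))$group, "all_intermediate")
  expect_error(combinatorial_profile(c(0, 2, 3)), "invalid")
  expect_error(combinatorial_profile(c(1, 2)), "exactly 3")
  # permutation invariance
  set.seed(440)
  for (i in 1:20) {
    tr <- sample(1:3, 3, replace = TRUE)
    base <- combinatorial_profile(tr)
    for (p in list(c(2, 1, 3), c(3, 1, 2), c(2, 3, 1)))
      expect_identical(combinatorial_profile(tr[p])$group, base$group)
  }
})

test_that("compare_profiles reproduces the min-effect pattern", {
  wins <- vapply(1:10, function(i) {
    set.seed(450 + i)
    n <- 600
    f <- matrix(rnorm(3 * n), ncol = 3)
    lev <- apply(f, 2, function(v) {
      cp <- quantile(v, c(1 / 3, 2 / 3), type = 7)
      ifelse(v <= cp[1], 1L, ifelse(v <= cp[2], 2L, 3L))
    })
    rownames(lev) <- sprintf("s%04d", seq_len(n))
    # hazard is a step function of the minimum immune factor
    eta <- 1.3 * (apply(f, 1, min) < qnorm(1 / 3))
    tm <- pmin(rexp(n, 0.08 * exp(eta)), 10)
    ev <- as.numeric(tm < 10)
    cl <- make_clinical(pmax(tm, 1e-6), ev, ids = rownames(lev))
    prof <- combinatorial_profile(lev)
    # relabel by low count for the pairwise null comparison
    prof_low <- prof
    prof_low$group <- ifelse(prof$n_low >= 1, paste0("low", prof$n_low),
                             prof$group)
    p_pairwise <- compare_profiles(prof_low, cl,
                                   grouping = list(low1 = "low1",
                                                   low2 = "low2",
                                                   low3 = "low3"))$logrank$p_value
    p_high <- compare_profiles(prof, cl,
                               grouping = list(
                                 all_high = "all_high",
                                 ge1_low = c("ge1_low", "two_high_plus_low")
                               ))$logrank$p_value
    p_pairwise > 0.05 && p_high < 0.05
  }, logical(1))
  expect_gte(mean(wins), 0.7)
})

test_that("compare_profiles validates groupings", {
  fx <- .prog_fixture(460, n = 200)
  lev <- vapply(fx$immune, function(t) t[fx$clinical$sample_id],
                integer(nrow(fx$clinical)))
  rownames(lev) <- fx$clinical$sample_id
  prof <- combinatorial_profile(lev)
  expect_error(compare_profiles(prof, fx$clinical,
                                grouping = list(a = "all_high")), ">= 2")
  expect_error(compare_profiles(prof, fx$clinical,
                                grouping = list(a = "all_high",
                                                b = "no_such_class")),
               "empty")
})
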