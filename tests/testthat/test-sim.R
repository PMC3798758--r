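test_that("simulate_cohort is deterministic given its seed", {
  cfg <- sim_config(n_samples = 120L, n_genes_total = 200L,
                    module_sizes = c(proliferation = 15, `B/P` = 12,
                                     `T/NK` = 10, `M/D` = 10),
                    seed = 301)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  # a different seed changes the draw
  c <- simulate_cohort(sim_config(n_samples = 120L, n_genes_total = 200L,
                                  module_sizes = cfg$module_sizes,
                                  seed = 302))
  expect_false(identical(a$expression, c$expression))
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(n_samples = 0), "n_samples")
  expect_error(sim_config(n_genes_total = 50L), "exceed")
  expect_error(sim_config(immune_intercorrelation = 1), "intercorrelation")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
})

test_that("planted within-module correlation matches the closed form", {
  # loading 1, noise 1, no batch: r = 1 / (1 + 1) = 0.5
  rs <- sapply(1:3, function(i) {
    sim <- simulate_cohort(sim_config(seed = 310 + i,
                                      within_module_loading = 1,
                                      noise_sd = 1, batch_sd = 0,
                                      probe_redundancy_rate = 0))
    mean(sapply(c("proliferation", "B/P", "T/NK", "M/D"), function(m) {
      pr <- names(sim$truth$probe_modules)[sim$truth$probe_modules == m]
      C <- cor(t(sim$expression[pr, ]))
      mean(C[upper.tri(C)])
    }))
  })
  expect_equal(mean(rs), 0.5, tolerance = 0.05)
})

test_that("raising the censoring rate never adds events (coupled seeds)", {
  for (i in 1:5) {
    lo <- simulate_cohort(sim_config(n_samples = 300L, seed = 320 + i,
                                     censor_rate = 0.03))
    hi <- simulate_cohort(sim_config(n_samples = 300L, seed = 320 + i,
                                     censor_rate = 0.25))
    expect_lte(sum(hi$clinical$dmfs_event), sum(lo$clinical$dmfs_event))
  }
})

test_that("null immune effects yield per-tertile HRs near 1", {
  # 50 replicates; the stratified immune HR CI should cover 1 ~95% of the time
  covered <- vapply(1:50, function(i) {
    sim <- simulate_cohort(sim_config(n_samples = 400L, seed = 330 + i,
                                      beta_immune_high = 0,
                                      beta_immune_low = 0))
    pr <- names(sim$truth$probe_modules)[sim$truth$probe_modules == "B/P"]
    bm <- build_metagene(sim$expression, pr, sim$probe_map, "B/P")
    tert <- assign_tertiles(bm$values, tertile_cutpoints(bm$values))
    ph <- names(sim$truth$prolif_tertile)[sim$truth$prolif_tertile == 3]
    cl <- sim$clinical[sim$clinical$sample_id %in% ph, ]
    f <- cox_fit(as.numeric(tert[cl$sample_id]), cl$dmfs_time,
                 cl$dmfs_event)
    f$table$ci95_low <= 1 && f$table$ci95_high >= 1
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("simulate_null_cohort separates null and alternative probes", {
  expect_error(simulate_null_cohort(sim_config(seed = 1), n_null = 0,
                                    n_alt = 0), "empty design")
  nc <- simulate_null_cohort(sim_config(n_samples = 150L, seed = 340),
                             n_null = 20, n_alt = 5)
  expect_setequal(rownames(nc$expression),
                  c(nc$truth$null_probes, nc$truth$alt_probes))
  expect_equal(ncol(nc$expression), 150)
  expect_true(all(nc$clinical$dmfs_event %in% c(0, 1)))
})

test_that("immune factors carry the configured intercorrelation", {
  sim <- simulate_cohort(sim_config(n_samples = 2000L, seed = 350,
                                    immune_intercorrelation = 0.4))
  F <- sim$truth$factors
  cors <- cor(F[, c("B/P", "T/NK", "M/D")])
  expect_equal(mean(cors[upper.tri(cors)]), 0.4, tolerance = 0.06)
  expect_lt(max(abs(cor(F[, "proliferation"], F[, 2:4]))), 0.1)
})

test_that("written cohorts are readable by the pipeline readers", {
  sim <- simulate_cohort(sim_config(n_samples = 60L, n_genes_total = 120L,
                                    module_sizes = c(proliferation = 12,
                                                     `B/P` = 10, `T/NK` = 10,
                                                     `M/D` = 10),
                                    seed = 360))
  d <- withr::local_tempdir()
  write_cohort(sim, d)
  expr <- read_expression(file.path(d, "expression.tsv"))
  expect_equal(expr, sim$expression, tolerance = 1e-10)
  clin <- read_clinical(file.path(d, "clinical.tsv"))
  expect_equal(clin$dmfs_time, sim$clinical$dmfs_time, tolerance = 1e-6)
  pm <- read_probe_map(file.path(d, "probe_map.tsv"))
  expect_identical(pm, sim$probe_map)
  cfg <- jsonlite::read_json(file.path(d, "sim_config.json"),
                             simplifyVector = TRUE)
  expect_equal(cfg$seed, 360)
})
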