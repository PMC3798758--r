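test_that("mean_center centers genes only", {
  x <- rbind(a = c(1, 2, 3), b = c(4, 4, 10))
  colnames(x) <- paste0("s", 1:3)
  cx <- mean_center(x)
  expect_equal(cx["a", ], c(s1 = -1, s2 = 0, s3 = 1))
  expect_true(all(abs(rowMeans(cx)) < 1e-12))
  # idempotence
  expect_equal(mean_center(cx), cx)
  # columns are NOT forced to zero
  expect_gt(max(abs(colMeans(cx))), 0.1)
})

test_that("hcluster handles canonical small cases", {
  a <- c(1, 2, 3, 4)
  x <- rbind(p1 = a, p2 = 2 * a, p3 = -a, p4 = -2 * a + 1)
  colnames(x) <- paste0("s", 1:4)
  d <- hcluster(x, metric = "pearson")
  h <- sort(d$hclust$height)
  # two perfectly correlated pairs merge at 0, then join at distance 2
  expect_equal(h[1:2], c(0, 0), tolerance = 1e-12)
  expect_equal(h[3], 2, tolerance = 1e-12)
  # zero-variance probe rejected by name
  x2 <- rbind(p1 = c(1, 2, 3), flatprobe = c(5, 5, 5))
  colnames(x2) <- paste0("s", 1:3)
  expect_error(hcluster(x2), "flatprobe")
  expect_error(hcluster(x[1, , drop = FALSE]), ">= 2")
})

test_that("hcluster equals brute-force average linkage on small instances", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    x <- matrix(rnorm(n * 12), n, dimnames = list(paste0("p", 1:n),
                                                  paste0("s", 1:12)))
    dend <- hcluster(x, metric = "pearson")
    D <- 1 - cor(t(x))
    bf <- bf_average_linkage(D)
    expect_equal(sort(dend$hclust$height), sort(bf$heights),
                 tolerance = 1e-9)
    # identical merge member sets (order-free comparison)
    sets_pkg <- lapply(hclust_sets(dend$hclust), paste, collapse = ",")
    sets_bf <- lapply(bf$sets, paste, collapse = ",")
    expect_setequal(unlist(sets_pkg), unlist(sets_bf))
  }
  # uncentered metric uses the cosine of raw rows
  x <- matrix(abs(rnorm(40)) + 1, 4, dimnames = list(paste0("p", 1:4),
                                                     paste0("s", 1:10)))
  dend <- hcluster(x, metric = "uncentered_pearson")
  nrm <- sqrt(rowSums(x^2))
  D <- 1 - tcrossprod(x / nrm)
  bf <- bf_average_linkage(D)
  expect_equal(sort(dend$hclust$height), sort(bf$heights), tolerance = 1e-9)
})

test_that("extract_subclusters recovers planted blocks exactly", {
  # within-r 0.8 (loading 2, noise 1), no background pool
  exact <- vapply(1:5, function(i) {
    x <- make_block_expr(c(30, 25, 20), n_background = 0, n_samples = 400,
                         loading = 2, seed = 110 + i)
    sc <- extract_subclusters(hcluster(x), x, r_threshold = 0.6,
                              min_size = 10)
    length(sc) == 3 &&
      setequal(
        lapply(sc, function(s) sort(s$probes)),
        lapply(split(rownames(x), attr(x, "block")), sort))
  }, logical(1))
  expect_true(all(exact))
})

test_that("extract_subclusters respects threshold, size and disjointness", {
  # fully independent probes: nothing qualifies
  x <- make_block_expr(integer(0), n_background = 100, n_samples = 200,
                       loading = 0, seed = 120)
  expect_length(extract_subclusters(hcluster(x), x), 0)
  # realized within-r near 0.5 stays below the 0.6 threshold
  x <- make_block_expr(30, n_background = 0, n_samples = 500, loading = 1,
                       seed = 121)
  expect_length(extract_subclusters(hcluster(x), x, r_threshold = 0.6), 0)
  # planted modules: disjoint subclusters, each satisfying the threshold
  x <- make_block_expr(c(30, 25, 20), n_background = 300, n_samples = 300,
                       loading = 2, seed = 122)
  sc <- extract_subclusters(hcluster(x), x, r_threshold = 0.6, min_size = 10)
  expect_gte(length(sc), 3)
  all_probes <- unlist(lapply(sc, `[[`, "probes"))
  expect_identical(anyDuplicated(all_probes), 0L)
  for (s in sc) {
    expect_gte(s$size, 10)
    expect_gte(s$average_pairwise_correlation, 0.6)
    # reported average matches an independent recomputation
    C <- cor(t(x[s$probes, ]))
    expect_equal(s$average_pairwise_correlation,
                 mean(C[upper.tri(C)]), tolerance = 1e-10)
  }
})

test_that("build_metagene collapses probes before cross-gene averaging", {
  x <- rbind(pA1 = c(2, 2), pA2 = c(4, 2), pB1 = c(9, 5))
  colnames(x) <- c("s1", "s2")
  pm <- c(pA1 = "GA", pA2 = "GA", pB1 = "GB")
  bm <- build_metagene(x, rownames(x), pm, "demo")
  # gene GA collapses to (3, 2); metagene = mean(collapsed, GB)
  expect_equal(unname(bm$values), c((3 + 9) / 2, (2 + 5) / 2))
  # NOT the naive all-probe mean
  expect_false(isTRUE(all.equal(unname(bm$values[1]), mean(c(2, 4, 9)))))
  # all probes one gene: metagene = probe mean
  bm1 <- build_metagene(x[1:2, ], c("pA1", "pA2"), pm, "one")
  expect_equal(unname(bm1$values), c(3, 2))
  # listing a probe twice changes nothing (collapse guards overrepresentation)
  bm2 <- build_metagene(x, c(rownames(x), "pA1"), pm, "dup")
  expect_equal(unname(bm2$values), unname(bm$values))
  expect_error(build_metagene(x, character(0), pm), "empty")
  # definitions rescore identically on a new cohort via metagene_values
  expect_equal(metagene_values(x, bm$definition), bm$values)
})

test_that("metagene reconstructs its latent factor on synthetic data", {
  sim <- simulate_cohort(sim_config(seed = 130))
  pr <- names(sim$truth$probe_modules)[sim$truth$probe_modules == "B/P"]
  bm <- build_metagene(sim$expression, pr, sim$probe_map, "B/P")
  expect_gte(cor(bm$values, sim$truth$factors[, "B/P"]), 0.9)
})

test_that("tertile cut-points use type-7 quantiles and validate input", {
  cp <- tertile_cutpoints(1:9)
  expect_equal(unname(cp), c(3.667, 6.333), tolerance = 1e-3)
  expect_error(tertile_cutpoints(rep(5, 10)), "distinct")
  # n divisible by 3 with distinct values: exactly n/3 per tertile
  set.seed(131)
  v <- rnorm(30)
  tert <- assign_tertiles(setNames(v, paste0("s", 1:30)),
                          tertile_cutpoints(v))
  expect_equal(as.vector(table(tert)), rep(10L, 3))
})

test_that("assign_tertiles applies the boundary-low convention", {
  cp <- c(q1 = 1, q2 = 2)
  v <- setNames(c(1, 1 + 1e-9, 2, 2 + 1e-9, 0.5), paste0("s", 1:5))
  expect_equal(unname(assign_tertiles(v, cp)), c(1L, 2L, 2L, 3L, 1L))
  expect_error(assign_tertiles(v, c(q1 = 2, q2 = 1)), "q1 < q2")
  # training cut-points reproduce the training partition
  set.seed(132)
  vals <- setNames(rnorm(60), paste0("s", 1:60))
  cp <- tertile_cutpoints(vals)
  tert <- assign_tertiles(vals, cp)
  expect_true(all(vals[tert == 1] <= cp[1]))
  expect_true(all(vals[tert == 3] > cp[2]))
})

test_that("metagene values are stable across cohort halves", {
  sim <- simulate_cohort(sim_config(seed = 140))
  pr <- names(sim$truth$probe_modules)[sim$truth$probe_modules == "T/NK"]
  ids <- colnames(sim$expression)
  h1 <- ids[seq(1, length(ids), 2)]
  full <- build_metagene(sim$expression, pr, sim$probe_map, "T/NK")$values
  half <- build_metagene(sim$expression[, h1], pr, sim$probe_map,
                         "T/NK")$values
  expect_gt(cor(full[h1], half), 0.95)
})

test_that("metagene definitions and dendrograms serialize round-trip", {
  x <- rbind(pA1 = c(1, 2, 3, 6), pA2 = c(2, 3, 4, 5), pB1 = c(9, 5, 2, 1))
  colnames(x) <- paste0("s", 1:4)
  pm <- c(pA1 = "GA", pA2 = "GA", pB1 = "GB")
  bm <- build_metagene(x, rownames(x), pm, "demo")
  bm$definition$tertile_cutpoints <- tertile_cutpoints(bm$values)
  f <- withr::local_tempfile(fileext = ".json")
  write_metagene_definition(bm$definition, f)
  back <- read_metagene_definition(f)
  expect_equal(back$probes, bm$definition$probes)
  expect_equal(back$tertile_cutpoints, bm$definition$tertile_cutpoints,
               tolerance = 1e-12)
  expect_equal(metagene_values(x, back), bm$values)
  nwk <- dendrogram_newick(hcluster(x))
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, rownames(x))
})
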