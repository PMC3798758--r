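# Synthetic multi-study expression + survival cohorts.
#
# The generator plants the latent structure the analysis pipeline assumes:
# one proliferation factor and three intercorrelated immune factors (B/P-,
# T/NK- and M/D-like), gene modules loading on them, probe-level redundancy,
# per-study batch offsets, clinical covariates with simple dependencies on
# proliferation, and exponential survival whose immune effects are active
# only in the top (and optionally bottom) proliferation tertile.

#' Simulation configuration
#'
#' Defaults describe a "realistic desk-scale" multi-study breast-cancer-like
#' cohort: 800 samples from 4 studies, 2000 gene probes including four
#' planted modules of 30/25/20/20 genes, ~30% distant-metastasis events
#' within 10 years, and a protective immune effect confined to the top
#' proliferation tertile.
#'
#' @param n_samples number of samples.
#' @param n_studies number of study (batch) labels.
#' @param n_genes_total total genes (modules included).
#' @param module_sizes named counts for the planted modules, in order
#'   proliferation, B/P, T/NK, M/D.
#' @param probe_redundancy_rate fraction of genes carrying 2 probe sets.
#' @param within_module_loading loading of module genes on their latent
#'   factor (log2 units per factor SD).  The default `sqrt(3)` with
#'   `noise_sd = 1` gives a realized within-module correlation near 0.75.
#' @param immune_intercorrelation pairwise correlation among the three
#'   immune latent factors, in \[0, 1).
#' @param batch_sd SD of per-gene, per-study offsets (log2 units).
#' @param noise_sd probe-level Gaussian noise SD (log2 units).
#' @param baseline_hazard_rate events per year at covariate zero.
#' @param beta_prolif log-hazard per SD of the proliferation factor.
#' @param beta_immune_high log-hazard per SD of each immune factor, applied
#'   only in the top proliferation tertile (negative = protective).
#' @param beta_immune_low log-hazard applied in the bottom tertile
#'   (default 0; positive values emulate low-proliferation inversions).
#' @param censor_rate exponential dropout rate per year.
#' @param followup_horizon administrative censoring horizon (years).
#' @param er_slope log-odds of ER-negative status per SD of proliferation.
#' @param seed integer RNG seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 800L,
                       n_studies = 4L,
                       n_genes_total = 2000L,
                       module_sizes = c(proliferation = 30L, `B/P` = 25L,
                                        `T/NK` = 20L, `M/D` = 20L),
                       probe_redundancy_rate = 0.2,
                       within_module_loading = sqrt(3),
                       immune_intercorrelation = 0.4,
                       batch_sd = 0.3,
                       noise_sd = 1,
                       baseline_hazard_rate = 0.045,
                       beta_prolif = 0.8,
                       beta_immune_high = -0.6,
                       beta_immune_low = 0,
                       censor_rate = 0.06,
                       followup_horizon = 15,
                       er_slope = 0.8,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_studies = as.integer(n_studies),
              n_genes_total = as.integer(n_genes_total),
              module_sizes = module_sizes,
              probe_redundancy_rate = probe_redundancy_rate,
              within_module_loading = within_module_loading,
              immune_intercorrelation = immune_intercorrelation,
              batch_sd = batch_sd,
              noise_sd = noise_sd,
              baseline_hazard_rate = baseline_hazard_rate,
              beta_prolif = beta_prolif,
              beta_immune_high = beta_immune_high,
              beta_immune_low = beta_immune_low,
              censor_rate = censor_rate,
              followup_horizon = followup_horizon,
              er_slope = er_slope,
              seed = as.integer(seed))
  if (cfg$n_samples < 1L) stopf("non-positive n_samples")
  if (cfg$n_studies < 1L) stopf("need >= 1 study")
  if (length(cfg$module_sizes) != 4L)
    stopf("module_sizes must have 4 entries (proliferation, B/P, T/NK, M/D)")
  if (sum(cfg$module_sizes) > cfg$n_genes_total)
    stopf("module sizes exceed total gene count")
  if (cfg$immune_intercorrelation < 0 || cfg$immune_intercorrelation >= 1)
    stopf("immune_intercorrelation must be in [0, 1)")
  for (f in c("batch_sd", "noise_sd", "baseline_hazard_rate", "censor_rate"))
    if (cfg[[f]] < 0) stopf("%s must be >= 0", f)
  if (cfg$followup_horizon <= 0) stopf("followup_horizon must be > 0")
  structure(cfg, class = "sim_config")
}

.module_names <- c("proliferation", "B/P", "T/NK", "M/D")

# latent factors: f_P independent; immune factors share a common component u
# so that cor(f_j, f_k) = immune_intercorrelation for j != k.
.sim_factors <- function(n, rho) {
  f_P <- stats::rnorm(n)
  a <- sqrt(rho)
  u <- stats::rnorm(n)
  imm <- vapply(1:3, function(k) a * u + sqrt(1 - rho) * stats::rnorm(n),
                numeric(n))
  cbind(proliferation = f_P, `B/P` = imm[, 1L], `T/NK` = imm[, 2L],
        `M/D` = imm[, 3L])
}

.sim_clinical_covariates <- function(n, f_P, er_slope, study) {
  # unknown fractions loosely follow a typical multi-study breast cohort
  mk_unknown <- function(x, rate) {
    x[stats::runif(n) < rate] <- "unknown"
    x
  }
  er <- ifelse(stats::runif(n) <
                 stats::plogis(stats::qlogis(0.24) + er_slope * f_P), "-", "+")
  grade_lat <- f_P + stats::rnorm(n)
  grade <- as.character(cut(grade_lat,
                            stats::quantile(grade_lat, c(0, .22, .62, 1)),
                            labels = c("1", "2", "3"), include.lowest = TRUE))
  ln <- ifelse(stats::runif(n) < 0.22, "+", "-")
  size <- sample(c("T1", "T2", "T3"), n, replace = TRUE,
                 prob = c(0.55, 0.42, 0.03))
  age <- pmax(25, round(stats::rnorm(n, 56, 12)))
  treat <- ifelse(stats::runif(n) < 0.5, "none",
                  ifelse(er == "+" & stats::runif(n) < 0.7,
                         "tamoxifen", "chemotherapy"))
  # intrinsic-like subtype mix shifting with proliferation
  base <- log(c(LumA = 0.31, LumB = 0.19, Basal = 0.23,
                `HER2-E` = 0.09, `Claudin-Low` = 0.05, unknown = 0.13))
  slope <- c(LumA = -0.9, LumB = 0.3, Basal = 0.4, `HER2-E` = 0.3,
             `Claudin-Low` = 0, unknown = 0)
  logits <- outer(f_P, slope) + rep(base, each = n)
  pr <- exp(logits)
  pr <- pr / rowSums(pr)
  subtype <- vapply(seq_len(n), function(i)
    sample(names(base), 1L, prob = pr[i, ]), character(1))
  data.frame(
    er_status = mk_unknown(er, 0.10),
    ln_status = mk_unknown(ln, 0.01),
    tumor_size_class = mk_unknown(size, 0.10),
    grade = mk_unknown(grade, 0.25),
    age_years = ifelse(stats::runif(n) < 0.2, NA, age),
    treatment = mk_unknown(treat, 0.01),
    study = study,
    subtype = subtype,
    stringsAsFactors = FALSE
  )
}

.sim_survival <- function(cfg, eta) {
  n <- length(eta)
  t_event <- stats::rexp(n, rate = cfg$baseline_hazard_rate * exp(eta))
  t_cens <- if (cfg$censor_rate > 0) stats::rexp(n, rate = cfg$censor_rate)
            else rep(Inf, n)
  t_cens <- pmin(t_cens, cfg$followup_horizon)
  time <- pmin(t_event, t_cens)
  event <- as.numeric(t_event <= t_cens)
  # guard: events at exactly time 0 are impossible under rexp, but keep the
  # clinical contract (event => time > 0) safe against underflow
  time[time <= 0] <- .Machine$double.eps
  list(time = time, event = event)
}

#' Simulate a multi-study expression + survival cohort
#'
#' Expression is baseline + module loading x latent factor + per-study batch
#' offset + Gaussian probe noise; genes chosen for probe redundancy carry two
#' probe sets sharing the gene-level signal with independent probe noise.
#' Survival is exponential given covariates with log-hazard
#' `beta_prolif * f_P + 1[top P tertile] * beta_immune_high * (f_B + f_T + f_M)
#'  + 1[bottom P tertile] * beta_immune_low * (f_B + f_T + f_M)`,
#' independent exponential censoring, and administrative censoring at the
#' follow-up horizon.  Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `expression` (probes x samples), `clinical` (validated
#'   clinical table), `probe_map` (probe -> gene), and `truth` (per-gene and
#'   per-probe module labels, per-sample latent `factors`, true proliferation
#'   tertile, study label).
#' @export
simulate_cohort <- function(config) {
  cfg <- if (inherits(config, "sim_config")) config else do.call(sim_config, config)
  with_seed(cfg$seed, {
    n <- cfg$n_samples
    G <- cfg$n_genes_total
    fac <- .sim_factors(n, cfg$immune_intercorrelation)
    study <- paste0("study_", sample.int(cfg$n_studies, n, replace = TRUE))

    gene_ids <- sprintf("g%04d", seq_len(G))
    module <- rep("background", G)
    off <- 0L
    for (k in seq_along(.module_names)) {
      sz <- cfg$module_sizes[[k]]
      module[(off + 1L):(off + sz)] <- .module_names[k]
      off <- off + sz
    }
    baseline <- stats::rnorm(G, mean = 7, sd = 1)

    # gene-level signal: baseline + loading * factor + batch offset
    signal <- matrix(rep(baseline, n), nrow = G)
    for (k in seq_along(.module_names)) {
      rows <- which(module == .module_names[k])
      signal[rows, ] <- signal[rows, ] +
        cfg$within_module_loading * rep(fac[, k], each = length(rows))
    }
    if (cfg$batch_sd > 0) {
      studies <- unique(study)
      delta <- matrix(stats::rnorm(G * length(studies), sd = cfg$batch_sd),
                      nrow = G, dimnames = list(NULL, studies))
      signal <- signal + delta[, study, drop = FALSE]
    }

    two_probes <- stats::runif(G) < cfg$probe_redundancy_rate
    dup_genes <- gene_ids[two_probes]
    probe_gene <- c(gene_ids, dup_genes)
    probe_ids <- c(paste0(gene_ids, "_p1"),
                   if (length(dup_genes)) paste0(dup_genes, "_p2"))
    ord <- order(probe_gene, probe_ids)
    probe_gene <- probe_gene[ord]
    probe_ids <- probe_ids[ord]
    gi <- match(probe_gene, gene_ids)
    expr <- signal[gi, , drop = FALSE] +
      matrix(stats::rnorm(length(gi) * n, sd = cfg$noise_sd), nrow = length(gi))
    sample_ids <- sprintf("s%05d", seq_len(n))
    dimnames(expr) <- list(probe_ids, sample_ids)

    # true proliferation tertile on the latent factor, population terciles
    cp <- stats::quantile(fac[, 1L], c(1 / 3, 2 / 3), type = 7, names = FALSE)
    p_tert <- ifelse(fac[, 1L] <= cp[1L], 1L, ifelse(fac[, 1L] <= cp[2L], 2L, 3L))
    imm_sum <- rowSums(fac[, 2:4])
    eta <- cfg$beta_prolif * fac[, 1L] +
      (p_tert == 3L) * cfg$beta_immune_high * imm_sum +
      (p_tert == 1L) * cfg$beta_immune_low * imm_sum
    surv <- .sim_survival(cfg, eta)

    cov <- .sim_clinical_covariates(n, fac[, 1L], cfg$er_slope, study)
    clinical <- clinical_table(data.frame(
      sample_id = sample_ids,
      dmfs_time = surv$time,
      dmfs_event = surv$event,
      cov, stringsAsFactors = FALSE))

    truth <- list(
      gene_modules = stats::setNames(module, gene_ids),
      probe_modules = stats::setNames(module[gi], probe_ids),
      factors = `rownames<-`(fac, sample_ids),
      prolif_tertile = stats::setNames(p_tert, sample_ids),
      study = stats::setNames(study, sample_ids)
    )
    list(expression = expr,
         clinical = clinical,
         probe_map = stats::setNames(probe_gene, probe_ids),
         truth = truth,
         config = cfg)
  })
}

#' Simulate a null-screen cohort for FDR-control experiments
#'
#' Generates `n_null` probes independent of survival and `n_alt` probes tied
#' to a shared latent risk factor that enters the log-hazard, so each
#' alternative probe carries approximately `alt_effect` log-hazard per SD.
#'
#' @param config a [sim_config()]; only sample-level fields are used.
#' @param n_null number of null probes (default 450).
#' @param n_alt number of survival-associated probes (default 50).
#' @param alt_effect log-hazard per SD of the risk factor (default 0.5).
#' @param alt_noise_sd probe-level noise around the risk factor; small so
#'   each alternative probe tracks the factor closely.
#' @return list with `expression`, `clinical` (minimal columns), and `truth`
#'   (`null_probes`, `alt_probes`).
#' @export
simulate_null_cohort <- function(config, n_null = 450L, n_alt = 50L,
                                 alt_effect = 0.5, alt_noise_sd = 0.3) {
  cfg <- if (inherits(config, "sim_config")) config else do.call(sim_config, config)
  n_null <- as.integer(n_null)
  n_alt <- as.integer(n_alt)
  if (n_null + n_alt == 0L) stopf("empty design: no null and no alternative genes")
  with_seed(cfg$seed, {
    n <- cfg$n_samples
    r <- stats::rnorm(n)
    null_ids <- if (n_null) sprintf("null%04d", seq_len(n_null)) else character(0)
    alt_ids <- if (n_alt) sprintf("alt%04d", seq_len(n_alt)) else character(0)
    xn <- matrix(stats::rnorm(n_null * n, mean = 7), nrow = n_null, ncol = n)
    xa <- matrix(0, nrow = n_alt, ncol = n)
    if (n_alt > 0)
      xa <- xa + rep(r, each = n_alt) + 7 +
        matrix(stats::rnorm(n_alt * n, sd = alt_noise_sd), nrow = n_alt)
    expr <- rbind(xn, xa)
    sample_ids <- sprintf("s%05d", seq_len(n))
    dimnames(expr) <- list(c(null_ids, alt_ids), sample_ids)
    surv <- .sim_survival(cfg, alt_effect * r)
    clinical <- data.frame(sample_id = sample_ids,
                           dmfs_time = surv$time,
                           dmfs_event = surv$event,
                           study = "study_1",
                           stringsAsFactors = FALSE)
    list(expression = expr, clinical = clinical,
         truth = list(null_probes = null_ids, alt_probes = alt_ids))
  })
}

#' Synthetic centroid set plus a cohort drawn from it
#'
#' Supports subtype-classifier testing without external centroid downloads:
#' draws `n_genes` centroid profiles per subtype, then samples each cohort
#' member from a randomly chosen centroid plus Gaussian noise.
#'
#' @param n_genes number of centroid genes.
#' @param subtypes subtype names.
#' @param n_per_class samples per subtype.
#' @param centroid_sd SD of centroid profiles.
#' @param noise_sd sample-level noise SD.
#' @param seed RNG seed.
#' @return list with `centroids` (a `centroid_set`), `expression` (one probe
#'   per gene), `probe_map`, and `true_subtype`.
#' @export
simulate_subtype_cohort <- function(n_genes = 60L,
                                    subtypes = c("LumA", "LumB", "Basal",
                                                 "HER2-E", "Claudin-Low"),
                                    n_per_class = 20L,
                                    centroid_sd = 1,
                                    noise_sd = 0.5,
                                    seed = 1L) {
  with_seed(seed, {
    genes <- sprintf("cg%03d", seq_len(n_genes))
    cent <- matrix(stats::rnorm(n_genes * length(subtypes), sd = centroid_sd),
                   nrow = n_genes, dimnames = list(genes, subtypes))
    cent <- cent - rowMeans(cent)
    lab <- rep(subtypes, each = n_per_class)
    n <- length(lab)
    expr <- cent[, lab, drop = FALSE] +
      matrix(stats::rnorm(n_genes * n, sd = noise_sd), nrow = n_genes)
    probes <- paste0(genes, "_p1")
    rownames(expr) <- probes
    colnames(expr) <- sprintf("t%04d", seq_len(n))
    list(centroids = centroid_set(cent),
         expression = expr,
         probe_map = stats::setNames(genes, probes),
         true_subtype = stats::setNames(lab, colnames(expr)))
  })
}

#' Write a simulated cohort to a directory
#'
#' Emits the same TSV formats the pipeline readers consume, the ground truth
#' as TSV sidecars, and the configuration as JSON.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$expression, file.path(dir, "expression.tsv"))
  write_clinical(sim$clinical, file.path(dir, "clinical.tsv"))
  write_probe_map(sim$probe_map, file.path(dir, "probe_map.tsv"))
  truth <- data.frame(sample_id = rownames(sim$truth$factors),
                      sim$truth$factors,
                      prolif_tertile = sim$truth$prolif_tertile,
                      study = sim$truth$study,
                      check.names = FALSE)
  utils::write.table(truth, file.path(dir, "truth_samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(probe_id = names(sim$truth$probe_modules),
               module = unname(sim$truth$probe_modules)),
    file.path(dir, "truth_probes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_json_result(unclass(sim$config), file.path(dir, "sim_config.json"))
  invisible(dir)
}
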