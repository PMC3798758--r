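# End-to-end orchestration: randomize -> screen -> cluster -> metagenes ->
# cross-applied tertiles -> conditional analyses, with per-stage artifacts
# and a reproducible run manifest.

#' Pipeline configuration
#'
#' Either `paths` (expression/clinical/probe-map TSVs, optional centroids)
#' or `synthetic = TRUE` with a [sim_config()] must be supplied.
#'
#' @param paths named list with `expression`, `clinical`, `probe_map` and
#'   optionally `centroids` file paths; ignored when `synthetic`.
#' @param synthetic generate the cohort with [simulate_cohort()].
#' @param sim a [sim_config()] used when `synthetic`.
#' @param output_dir artifact directory.
#' @param p_thresh,q_thresh screening thresholds (defaults 0.01 / 0.10).
#' @param r_threshold,min_size subcluster extraction parameters.
#' @param min_corr SSP minimum correlation floor.
#' @param horizon_years follow-up delimiting horizon (default 10).
#' @param max_std_diff_pct,min_logrank_p,max_iterations randomization
#'   balance criteria.
#' @param min_n minimum stratum size for conditional analyses.
#' @param seed integer seed driving every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(paths = NULL, synthetic = is.null(paths),
                            sim = sim_config(), output_dir = tempfile("mgrun"),
                            p_thresh = 0.01, q_thresh = 0.10,
                            r_threshold = 0.6, min_size = 10,
                            min_corr = 0.1, horizon_years = 10,
                            max_std_diff_pct = 10, min_logrank_p = 0.99,
                            max_iterations = 10000L, min_n = 10,
                            seed = 1L) {
  stopifnot(p_thresh > 0, p_thresh <= 1, q_thresh >= 0, q_thresh <= 1,
            r_threshold > 0, r_threshold <= 1, min_size >= 2,
            horizon_years > 0)
  structure(list(paths = paths, synthetic = synthetic, sim = sim,
                 output_dir = output_dir, p_thresh = p_thresh,
                 q_thresh = q_thresh, r_threshold = r_threshold,
                 min_size = min_size, min_corr = min_corr,
                 horizon_years = horizon_years,
                 max_std_diff_pct = max_std_diff_pct,
                 min_logrank_p = min_logrank_p,
                 max_iterations = as.integer(max_iterations),
                 min_n = min_n, seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

# name subclusters by majority ground-truth module when annotations exist
.annotate_subclusters <- function(subclusters, annotations) {
  if (is.null(annotations)) return(subclusters)
  lapply(subclusters, function(sc) {
    lab <- annotations[sc$probes]
    lab <- lab[!is.na(lab) & lab != "background"]
    if (length(lab)) {
      tab <- sort(table(lab), decreasing = TRUE)
      if (tab[1L] >= length(sc$probes) / 2) sc$label <- names(tab)[1L]
    }
    sc
  })
}

.analyze_direction <- function(train_ids, test_ids, expr, clinical, probe_map,
                               cfg, annotations, log) {
  tr_expr <- expr[, train_ids, drop = FALSE]
  tr_clin <- clinical[match(train_ids, clinical$sample_id), ]
  te_expr <- expr[, test_ids, drop = FALSE]
  te_clin <- clinical[match(test_ids, clinical$sample_id), ]

  gst <- .stage("screen_genes", screen_genes(tr_expr, tr_clin))
  selected <- select_prognostic(gst, cfg$p_thresh, cfg$q_thresh)
  log(sprintf("screen: %d/%d probes selected (p < %g, q < %g)",
              length(selected), nrow(gst), cfg$p_thresh, cfg$q_thresh))
  if (length(selected) < cfg$min_size)
    stopf("no probes selected (got %d, need >= min_size = %d)",
          length(selected), cfg$min_size)

  dend <- .stage("hcluster", hcluster(tr_expr[selected, , drop = FALSE]))
  subclusters <- .stage("extract_subclusters",
    extract_subclusters(dend, tr_expr, cfg$r_threshold, cfg$min_size))
  subclusters <- .annotate_subclusters(subclusters, annotations)
  log(sprintf("subclusters: %d extracted (sizes %s)", length(subclusters),
              paste(vapply(subclusters, `[[`, numeric(1), "size"),
                    collapse = "/")))
  if (!length(subclusters)) stopf("no subclusters extracted")

  metagenes <- lapply(subclusters, function(sc) {
    bm <- build_metagene(tr_expr, sc$probes, probe_map, sc$label)
    bm$definition$tertile_cutpoints <- tertile_cutpoints(bm$values)
    bm$subcluster <- sc
    bm
  })
  names(metagenes) <- vapply(metagenes, function(m) m$definition$name,
                             character(1))

  # training cut-points applied to the held-out half
  test_tertiles <- lapply(metagenes, function(m)
    assign_tertiles(metagene_values(te_expr, m$definition),
                    m$definition$tertile_cutpoints))

  prolif_name <- if ("proliferation" %in% names(metagenes)) "proliferation"
                 else names(metagenes)[1L]
  immune_names <- setdiff(names(metagenes), prolif_name)
  result <- list(gene_survival = gst, selected = selected,
                 dendrogram = dend, metagenes = metagenes,
                 test_tertiles = test_tertiles,
                 proliferation_metagene = prolif_name)
  if (length(immune_names)) {
    result$conditional <- .stage("conditional_analysis",
      conditional_analysis(test_tertiles[immune_names],
                           test_tertiles[[prolif_name]], te_clin,
                           min_n = cfg$min_n))
    if (length(immune_names) >= 2L) {
      ph <- .align_tertiles(test_tertiles[[prolif_name]],
                            te_clin$sample_id) == 3L
      result$multivariable <- tryCatch(
        multivariable_models(test_tertiles[immune_names], te_clin,
                             stratum = ph, include_conventional = TRUE),
        error = function(e) {
          log(sprintf("multivariable models skipped: %s", conditionMessage(e)))
          NULL
        })
    }
    if (length(immune_names) >= 3L) {
      imm3 <- immune_names[1:3]
      lev <- vapply(test_tertiles[imm3], function(t)
        .align_tertiles(t, te_clin$sample_id), integer(nrow(te_clin)))
      rownames(lev) <- te_clin$sample_id
      profiles <- combinatorial_profile(lev)
      ph <- .align_tertiles(test_tertiles[[prolif_name]],
                            te_clin$sample_id) == 3L
      result$profiles <- profiles
      result$profile_comparison <- tryCatch(
        compare_profiles(profiles, te_clin, stratum = ph,
                         grouping = list(
                           all_high = "all_high",
                           not_all_high = c("two_high_plus_intermediate",
                                            "two_high_plus_low", "one_high",
                                            "ge1_low", "all_intermediate"))),
        error = function(e) {
          log(sprintf("profile comparison skipped: %s", conditionMessage(e)))
          NULL
        })
    }
  }
  result
}

.write_direction <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_survival_table(res$gene_survival,
                            file.path(dir, "gene_survival.tsv"))
  writeLines(res$selected, file.path(dir, "selected_probes.txt"))
  dendrogram_newick(res$dendrogram, file.path(dir, "dendrogram.nwk"))
  for (nm in names(res$metagenes)) {
    safe <- gsub("[^A-Za-z0-9]+", "_", nm)
    write_metagene_definition(res$metagenes[[nm]]$definition,
                              file.path(dir, paste0("metagene_", safe, ".json")))
  }
  tert <- data.frame(sample_id = names(res$test_tertiles[[1L]]),
                     lapply(res$test_tertiles, unname),
                     check.names = FALSE)
  utils::write.table(tert, file.path(dir, "test_tertiles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(res$conditional))
    utils::write.table(res$conditional$summary,
                       file.path(dir, "conditional_analysis.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$multivariable))
    utils::write.table(res$multivariable$table,
                       file.path(dir, "multivariable_models.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full discovery and validation pipeline
#'
#' Executes: follow-up delimiting, iterative balanced randomization into two
#' halves, then for each training/testing direction a per-probe Cox screen
#' with dual p/q selection, average-linkage clustering of the selected
#' probes, subcluster extraction at the average-correlation threshold,
#' metagene construction with training tertile cut-points, cross-applied
#' tertile assignment on the held-out half, and the conditional,
#' multivariable and combinatorial-profile analyses.  Every intermediate
#' artifact is written below `config$output_dir` together with a JSON
#' manifest recording parameters, seeds and per-stage counts.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with `split`, the two per-
#'   direction result bundles (`AtoB`, `BtoA`), and `manifest` (invisibly
#'   also written as JSON).
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log <- function(msg) {
    log_lines <<- c(log_lines, msg)
    message("[metaprog] ", msg)
  }

  annotations <- NULL
  if (cfg$synthetic) {
    sim <- .stage("simulate", simulate_cohort(cfg$sim))
    expr <- sim$expression
    clinical <- sim$clinical
    probe_map <- sim$probe_map
    annotations <- sim$truth$probe_modules
    log(sprintf("simulated cohort: %d probes x %d samples",
                nrow(expr), ncol(expr)))
  } else {
    expr <- .stage("read_expression", read_expression(cfg$paths$expression))
    clinical <- .stage("read_clinical", read_clinical(cfg$paths$clinical))
    probe_map <- .stage("read_probe_map", read_probe_map(cfg$paths$probe_map))
  }
  clinical <- .stage("delimit_followup",
                     delimit_followup(clinical, cfg$horizon_years))

  monitored <- c("dmfs_time", "dmfs_event", "study", "er_status")
  if (!is.null(clinical$subtype)) monitored <- c(monitored, "subtype")
  crit <- balance_criteria(cfg$max_std_diff_pct, cfg$min_logrank_p,
                           monitored, cfg$max_iterations)
  split <- .stage("balanced_split",
                  balanced_split(clinical, crit, seed = cfg$seed))
  log(sprintf("balanced split after %d iteration(s): max std diff %.2f%%, log-rank p %.3f",
              split$iterations_used, max(split$achieved_std_diffs),
              split$logrank_p))
  write_split_result(split, file.path(cfg$output_dir, "split.json"))

  res_ab <- .analyze_direction(split$group_a_ids, split$group_b_ids,
                               expr, clinical, probe_map, cfg, annotations, log)
  res_ba <- .analyze_direction(split$group_b_ids, split$group_a_ids,
                               expr, clinical, probe_map, cfg, annotations, log)
  .write_direction(res_ab, file.path(cfg$output_dir, "train_A_test_B"))
  .write_direction(res_ba, file.path(cfg$output_dir, "train_B_test_A"))

  manifest <- list(
    package = "metaprog",
    version = as.character(utils::packageVersion("metaprog")),
    seed = cfg$seed,
    parameters = cfg[c("p_thresh", "q_thresh", "r_threshold", "min_size",
                       "min_corr", "horizon_years", "max_std_diff_pct",
                       "min_logrank_p", "min_n")],
    tie_handling = "breslow",
    tertile_coding = "ordinal 1/2/3; boundary ties to lower tertile",
    n_samples = nrow(clinical),
    n_probes = nrow(expr),
    subclusters = list(
      AtoB = lapply(res_ab$metagenes, function(m)
        list(name = m$definition$name, size = length(m$definition$probes))),
      BtoA = lapply(res_ba$metagenes, function(m)
        list(name = m$definition$name, size = length(m$definition$probes)))),
    log = log_lines
  )
  write_json_result(manifest, file.path(cfg$output_dir, "manifest.json"))
  structure(list(split = split, AtoB = res_ab, BtoA = res_ba,
                 manifest = manifest, config = cfg),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("metaprog pipeline run\n")
  cat(sprintf("  cohort: %d samples; split %d/%d\n", x$manifest$n_samples,
              length(x$split$group_a_ids), length(x$split$group_b_ids)))
  cat(sprintf("  subclusters A->B: %s\n",
              paste(names(x$AtoB$metagenes), collapse = ", ")))
  cat(sprintf("  subclusters B->A: %s\n",
              paste(names(x$BtoA$metagenes), collapse = ", ")))
  cat(sprintf("  artifacts: %s\n", x$config$output_dir))
  invisible(x)
}
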