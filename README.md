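# metaprog

Supervised metagene discovery and proliferation-conditional survival
analysis for bulk tumor expression cohorts.

## The problem

Tumor-infiltrating immune cells carry prognostic information in breast
cancer, but that information is *conditional*: immune gene signatures
predict distant metastasis-free survival (DMFS) almost exclusively in
highly proliferative tumors.  Quantifying this requires a pipeline, not a
single test — balanced cohort randomization, genome-wide survival
screening with false-discovery control, clustering-based signature
(metagene) discovery, cross-applied tertile stratification, and stratified
survival models.  `metaprog` packages that pipeline for statisticians and
computational biologists, together with a synthetic multi-study cohort
generator so every stage is testable without access to the original
patient data.

## The method in brief

1. **Balanced randomization** — iterative uniform half-splits accepted when
   every monitored covariate's standardized difference
   `100·|m̄_a − m̄_b| / √((s_a² + s_b²)/2)` is < 10% and the two-group DMFS
   log-rank p exceeds 0.99.
2. **Per-probe Cox screen** — one univariable proportional-hazards model
   per probe set (log2 expression, continuous); keep probes with
   likelihood-ratio p < 0.01 **and** Benjamini–Hochberg q < 0.10.
3. **Subcluster extraction** — average-linkage clustering on 1 − Pearson
   correlation; report maximal branches of ≥ 10 probes whose average
   pairwise correlation is ≥ 0.6.
4. **Metagenes and tertiles** — per-sample mean of a subcluster's genes
   (probes of the same gene averaged first); tertile cut-points (type-7
   quantiles) fixed on the training half, applied to the test half.
5. **Conditional prognosis** — within each proliferation tertile
   (P^L/P^I/P^H): Kaplan–Meier + log-rank across immune tertiles and Cox
   models with the ordinal 1/2/3 tertile coding (Breslow ties, Wald 95%
   CIs); multivariable and combinatorial immune-profile analyses on top.

## Worked example

A full two-way discovery/validation run on a synthetic cohort at the scale
of the motivating study (1,954 samples, four planted gene modules):

```r
library(metaprog)
cfg <- pipeline_config(
  sim = sim_config(n_samples = 1954L, seed = 11),
  output_dir = "mg_run", seed = 11)
res <- run_pipeline(cfg)
#> [metaprog] simulated cohort: 2407 probes x 1954 samples
#> [metaprog] balanced split after 88 iteration(s): max std diff 6.06%, log-rank p 0.996
#> [metaprog] screen: 134/2407 probes selected (p < 0.01, q < 0.1)
#> [metaprog] subclusters: 4 extracted (sizes 38/33/27/24)
#> [metaprog] screen: 133/2407 probes selected (p < 0.01, q < 0.1)
#> [metaprog] subclusters: 4 extracted (sizes 37/33/27/24)
print(res)
#> metaprog pipeline run
#>   cohort: 1954 samples; split 977/977
#>   subclusters A->B: proliferation, B/P, T/NK, M/D
#>   subclusters B->A: proliferation, B/P, T/NK, M/D
#>   artifacts: mg_run
```

Both training directions recover all four planted modules.  The
conditional analysis of the B/P (B-cell/plasma-cell-like) metagene on the
held-out half shows the planted structure — a strong protective effect of
high immune tertiles confined to the high-proliferation stratum:

```r
s <- res$AtoB$conditional$summary
s[s$metagene == "B/P", ]
#>  stratum metagene   n n_events logrank_p hazard_ratio ci95_low ci95_high    cox_p
#>      P^L      B/P 349       45  8.35e-01        0.949    0.657     1.370 7.79e-01
#>      P^I      B/P 316       90  7.77e-01        1.055    0.818     1.361 6.81e-01
#>      P^H      B/P 312      164  5.06e-17        0.401    0.321     0.501 7.29e-16
```

Reading the P^H row: among highly proliferative test-half tumors, each
one-tertile step up in B/P metagene expression multiplies the hazard of
distant metastasis by 0.40 (95% CI 0.32–0.50); in the low and intermediate
proliferation tertiles the same metagene is prognostically null — exactly
the conditional behaviour the generator plants and the motivating analysis
reports in real cohorts.

Every stage is also available as a standalone function
(`balanced_split()`, `screen_genes()`, `extract_subclusters()`,
`build_metagene()`, `conditional_analysis()`, `multivariable_models()`,
`combinatorial_profile()`, `ssp_classify()`, …) and as CLI subcommands via
`inst/cli/metaprog` (`simulate`, `randomize`, `select-genes`, `cluster`,
`metagene`, `subtype`, `analyze`, `run-all`).

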