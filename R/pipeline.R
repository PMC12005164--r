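# End-to-end orchestration: simulate -> normalize -> test -> imprint ->
# group -> conserve -> cluster -> tissue -> report.

#' Configuration for the full analysis pipeline
#'
#' Bundles every tunable of the pipeline with the field-standard defaults:
#' imprinting thresholds 0.9/0.3 (bias 0.8/0.4), the 1 and 5 RPM expression
#' filters, k = 9 developmental clusters, and the >= 4 genotype filter for
#' the conservation summary. All randomness descends from `seed`.
#'
#' @param out_dir Directory for stage outputs and the JSON report.
#' @param seed Integer master seed (mandatory).
#' @param sim A [sim_config()]; defaults to the standard synthetic
#'   experiment with presence sets covering `panel_genotypes`.
#' @param thresholds An [imprint_thresholds()].
#' @param panel_genotypes Alternate genotypes for the 14-DAP conservation
#'   panel.
#' @param panel_maintain Per-class probability the imprinting pattern is
#'   maintained in an alternate genotype (passed to
#'   [simulate_genotype_panel()]); the default declines from constitutive
#'   to transient classes.
#' @param k Number of expression clusters.
#' @param min_genotypes Conservation summary genotype floor.
#' @param syntelog_dropout Dropout rate of the simulated syntelog map.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed,
                            sim = NULL,
                            thresholds = imprint_thresholds(),
                            panel_genotypes = c("W22", "Ki11", "Oh43",
                                                "NC358", "CML333"),
                            panel_maintain = c(
                              MEG_constitutive = 0.9, PEG_constitutive = 0.9,
                              MEG_transient = 0.35, PEG_transient = 0.35,
                              maternal_bias = 0.7, paternal_bias = 0.7
                            ),
                            k = 9, min_genotypes = 4,
                            syntelog_dropout = 0.05) {
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory")
  seed <- as.integer(seed)
  if (is.null(sim)) {
    sim <- sim_config(seed = seed,
                      genotypes = c("B73", panel_genotypes))
  }
  structure(list(
    out_dir = out_dir, seed = seed, sim = sim, thresholds = thresholds,
    panel_genotypes = panel_genotypes, panel_maintain = panel_maintain,
    k = k, min_genotypes = min_genotypes,
    syntelog_dropout = syntelog_dropout
  ), class = "pipeline_config")
}

run_stage <- function(name, expr) {
  inform(paste0("[", name, "] running"))
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Run the full imprinting analysis pipeline
#'
#' Executes every stage on a simulated experiment with known truth, writes
#' each stage's output as TSV under `cfg$out_dir`, and a JSON report of the
#' headline tallies (imprinted counts per time point, group sizes,
#' conservation means per group, DE overlap bins, panel counts, the
#' thresholds used, and genes dropped at every filter). Deterministic given
#' the seed: a rerun writes byte-identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  thr <- cfg$thresholds
  pth <- function(f) file.path(cfg$out_dir, f)

  sim <- run_stage("simulate", simulate_experiment(cfg$sim))
  write_counts(sim$counts, pth("counts.tsv"), pth("meta.tsv"))
  readr::write_tsv(sim$truth, pth("truth.tsv"))

  expr <- run_stage("normalize", rpm_normalize(sim$counts))

  de_imp <- run_stage("test",
    test_imprinting(sim$counts, lfc_threshold = thr$lfc, alpha = thr$alpha))
  readr::write_tsv(de_imp, pth("imprint_tests.tsv"))

  profile <- run_stage("imprint", imprint_profile(expr, de_imp, thr))
  readr::write_tsv(profile, pth("imprint_profile.tsv"))
  imprint_counts <- profile |>
    dplyr::filter(.data$status %in% c("MEG", "PEG")) |>
    dplyr::count(.data$dap, .data$genome, .data$status, name = "n")

  groups <- run_stage("group", suppressMessages(assign_groups(profile, thr)))
  readr::write_tsv(groups, pth("groups.tsv"))
  gsum <- group_summary(groups)
  bias_tab <- bias_consistency(profile, thr)
  readr::write_tsv(bias_tab, pth("bias_consistency.tsv"))

  ref <- cfg$sim$genotype_pair[1]
  de_tc <- run_stage("timecourse",
    de_vs_baseline(sim$counts, direction = ref,
                   baseline_dap = min(cfg$sim$dap_set),
                   lfc_threshold = thr$lfc, alpha = thr$alpha))
  readr::write_tsv(de_tc, pth("de_timecourse.tsv"))
  overlap <- de_overlap(de_tc)

  clusters <- run_stage("cluster", {
    traj <- suppressMessages(max_normalize(dap_means(expr, ref)))
    model <- fit_kmeans(traj, k = cfg$k, seed = cfg$seed + 500L)
    recip <- suppressMessages(
      max_normalize(dap_means(expr, cfg$sim$genotype_pair[2])))
    list(model = model,
         transfer = transfer_consistency(model, recip))
  })
  readr::write_tsv(clusters$model$assignments, pth("clusters.tsv"))
  readr::write_tsv(clusters$model$centroids, pth("centroids.tsv"))

  conserve <- run_stage("conserve", {
    panel <- simulate_genotype_panel(sim$truth, cfg$sim,
                                     cfg$panel_genotypes,
                                     maintain_prob = cfg$panel_maintain,
                                     seed = cfg$seed + 100L)
    syn <- simulate_syntelogs(sim$truth, cfg$panel_genotypes,
                              dropout_rate = cfg$syntelog_dropout,
                              seed = cfg$seed + 300L)
    tab <- build_genotype_table(panel, syn, thr, reference = ref)
    ref_calls <- groups |>
      dplyr::filter(.data$genome == ref,
                    .data$direction %in% c("MEG", "PEG")) |>
      dplyr::transmute(b73_gene_id = .data$gene, direction = .data$direction,
                       group = .data$group)
    scores <- percent_same_imprint(tab, ref_calls)
    list(table = tab,
         scores = scores,
         by_group = conservation_by_group(scores, ref_calls,
                                          cfg$min_genotypes),
         counts = panel_counts(tab),
         syntelogs = syn)
  })
  write_syntelog_table(conserve$syntelogs, pth("syntelogs.tsv"),
                       reference = ref)
  readr::write_tsv(conserve$scores, pth("conservation.tsv"))
  readr::write_tsv(conserve$counts, pth("panel_counts.tsv"))

  tissue <- run_stage("tissue", {
    atl <- simulate_tissue_atlas(sim$truth, seed = cfg$seed + 200L)
    calls <- classify_tissue(atl$atlas)
    mdr1 <- simulate_mdr1_list(atl$truth, seed = cfg$seed + 400L)
    xtab <- crosstab_groups_tissue(groups, calls, mdr1$degs, mdr1$universe)
    list(atlas = atl, calls = calls, crosstab = xtab)
  })
  readr::write_tsv(tissue$atlas$atlas, pth("atlas.tsv"))
  readr::write_tsv(tissue$calls, pth("tissue_calls.tsv"))
  readr::write_tsv(tissue$crosstab, pth("tissue_crosstab.tsv"))

  report <- list(
    seed = cfg$seed,
    thresholds = unclass(thr),
    n_genes = sum(cfg$sim$n_genes),
    n_gene_alleles = length(unique(sim$counts$gene_id)),
    imprinted_per_dap = imprint_counts,
    group_sizes = gsum,
    dropped = list(
      never_imprinted = length(unique(profile$gene_id)) -
        length(unique(groups$gene_id)),
      filtered_low_expression =
        sum(groups$group == "filtered_low_expression")
    ),
    de_overlap = overlap,
    bias_consistency = bias_tab,
    conservation_by_group = conserve$by_group$summary,
    panel_counts = conserve$counts,
    cluster_sizes = clusters$model$size,
    transfer_consistency = clusters$transfer
  )
  jsonlite::write_json(report, pth("report.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  inform(paste0("report written to ", pth("report.json")))
  invisible(report)
}
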