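# Cross-genotype conservation of parental bias via single-copy syntelogs.
#
# Each alternate genotype contributes one reciprocal-cross experiment with
# the reference; the reference-mapped allele (the common parent) carries the
# RER and status used, and a gene is assessable in a genotype only through a
# single-copy syntelog row — genes with identical sequence (no informative
# variants) or multi-copy pan-gene rows never enter the table.

#' Build the per-genotype imprinting table
#'
#' For each genotype's reciprocal-cross experiment: RPM-normalizes, runs the
#' maternal-vs-paternal fold-change test, computes RER on direction means
#' for the reference-mapped alleles, and joins to reference gene IDs through
#' the single-copy syntelog map.
#'
#' @param panel Named list (by genotype) of long count tibbles, each a
#'   reciprocal pair of the reference with that genotype at one time point
#'   (e.g. from [simulate_genotype_panel()]).
#' @param syntelogs Single-copy syntelog map ([read_syntelog_table()] /
#'   [simulate_syntelogs()]).
#' @param thr An [imprint_thresholds()].
#' @param reference Reference genome name (default `"B73"`).
#' @return Tibble: `b73_gene_id`, `genotype`, `maternal_rpm`,
#'   `paternal_rpm`, `rer`, `padj`, `expressed` (maternal + paternal mean
#'   RPM >= `thr$expr_min`), `bias_status`
#'   (`maternal`/`paternal`/`none`), `imprint_status` (`MEG`/`PEG`/`none`).
#' @export
build_genotype_table <- function(panel, syntelogs,
                                 thr = imprint_thresholds(),
                                 reference = "B73") {
  stopifnot(is.list(panel), !is.null(names(panel)))
  purrr::imap_dfr(panel, function(counts, genotype) {
    check_counts(counts)
    if (length(unique(counts$maternal)) < 2) {
      abort(paste0("genotype ", genotype,
                   " is missing one reciprocal direction"))
    }
    expr <- rpm_normalize(counts)
    de <- test_imprinting(counts, lfc_threshold = thr$lfc, alpha = thr$alpha)
    prof <- imprint_profile(expr, de, thr)
    prof <- prof[prof$genome == reference, ]
    syn <- syntelogs[syntelogs$genotype == genotype, ]
    prof <- prof[prof$gene %in% syn$b73_gene_id, ]
    tibble::tibble(
      b73_gene_id = prof$gene,
      genotype = genotype,
      maternal_rpm = prof$maternal_rpm,
      paternal_rpm = prof$paternal_rpm,
      rer = prof$rer,
      padj = prof$padj,
      expressed = (prof$maternal_rpm + prof$paternal_rpm) >= thr$expr_min,
      bias_status = dplyr::case_when(
        !((prof$maternal_rpm + prof$paternal_rpm) >= thr$expr_min) ~ "none",
        is.na(prof$rer) ~ "none",
        prof$rer > thr$maternal_bias_rer ~ "maternal",
        prof$rer < thr$paternal_bias_rer ~ "paternal",
        TRUE ~ "none"
      ),
      imprint_status = dplyr::case_when(
        prof$status == "MEG" ~ "MEG",
        prof$status == "PEG" ~ "PEG",
        TRUE ~ "none"
      )
    )
  })
}

#' Percent-same-imprint conservation score
#'
#' For each gene with a reference imprinting direction: the number of
#' genotypes in which the gene is parentally biased in that direction
#' (lenient RER thresholds, no significance gate), divided by the number of
#' genotypes with an expressed syntelog. Genes with no expressed syntelog
#' are dropped.
#'
#' @param table Genotype table from [build_genotype_table()] (or any tibble
#'   with `b73_gene_id`, `genotype`, `expressed`, `bias_status`).
#' @param reference_calls Tibble with `b73_gene_id` and `direction`
#'   (`"MEG"`/`"PEG"`), typically derived from the time-series group
#'   assignments.
#' @return Tibble per gene: `direction`, `n_genotypes_expressed`,
#'   `n_genotypes_same_bias`, `percent_same_imprint` in `[0, 1]`.
#' @export
percent_same_imprint <- function(table, reference_calls) {
  ref <- reference_calls[reference_calls$direction %in% c("MEG", "PEG"), ]
  joined <- dplyr::inner_join(table, ref, by = "b73_gene_id")
  out <- joined |>
    dplyr::group_by(.data$b73_gene_id, .data$direction) |>
    dplyr::summarise(
      n_genotypes_expressed = sum(.data$expressed),
      n_genotypes_same_bias = sum(
        .data$expressed &
          .data$bias_status ==
            ifelse(.data$direction[1] == "MEG", "maternal", "paternal")
      ),
      .groups = "drop"
    )
  out <- out[out$n_genotypes_expressed > 0, ]
  out$percent_same_imprint <- out$n_genotypes_same_bias /
    out$n_genotypes_expressed
  out
}

#' Conservation by temporal-consistency group
#'
#' Distribution and mean of percent-same-imprint per (group x direction),
#' restricted to genes with an expressed syntelog in at least
#' `min_genotypes` genotypes.
#'
#' @param scores Result of [percent_same_imprint()].
#' @param assignments Tibble with `b73_gene_id` and `group` (e.g.
#'   [assign_groups()] output with reference gene IDs).
#' @param min_genotypes Minimum genotypes with an expressed syntelog
#'   (default 4).
#' @return List with `genes` (per-gene scores joined to groups) and
#'   `summary` (per group x direction: `n`, `mean_percent`,
#'   `median_percent`).
#' @export
conservation_by_group <- function(scores, assignments, min_genotypes = 4) {
  joined <- dplyr::inner_join(
    scores[scores$n_genotypes_expressed >= min_genotypes, ],
    assignments[, c("b73_gene_id", "group")],
    by = "b73_gene_id"
  )
  summary <- joined |>
    dplyr::group_by(.data$group, .data$direction) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_percent = mean(.data$percent_same_imprint),
      median_percent = median(.data$percent_same_imprint),
      .groups = "drop"
    )
  list(genes = joined, summary = summary)
}

#' Per-genotype imprinted and biased gene counts
#'
#' Counts, per genotype, genes meeting the stringent imprinting thresholds
#' and genes meeting the lenient bias thresholds (among expressed
#' syntelogs), in each direction.
#'
#' @param table Genotype table from [build_genotype_table()].
#' @return Tibble per genotype: `n_meg`, `n_peg`, `n_maternal_bias`,
#'   `n_paternal_bias`, `n_expressed`.
#' @export
panel_counts <- function(table) {
  table |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(
      n_meg = sum(.data$imprint_status == "MEG"),
      n_peg = sum(.data$imprint_status == "PEG"),
      n_maternal_bias = sum(.data$expressed & .data$bias_status == "maternal"),
      n_paternal_bias = sum(.data$expressed & .data$bias_status == "paternal"),
      n_expressed = sum(.data$expressed),
      .groups = "drop"
    )
}

#' Plot conservation by group
#'
#' Percent-same-imprint distributions per temporal-consistency group and
#' direction (the stepwise-conservation view).
#'
#' @param conservation Result of [conservation_by_group()].
#' @return A ggplot object.
#' @export
plot_conservation <- function(conservation) {
  ggplot2::ggplot(conservation$genes,
                  ggplot2::aes(x = .data$group,
                               y = .data$percent_same_imprint,
                               fill = .data$direction)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "temporal-consistency group",
                  y = "fraction of genotypes with same parental bias",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
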