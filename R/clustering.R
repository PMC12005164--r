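# Developmental expression clustering: replicate-mean RPM trajectories,
# per-gene max normalization, seeded k-means, and transfer of cluster labels
# to the reciprocal cross direction.

#' Replicate-mean expression trajectories for one cross direction
#'
#' Averages RPM by time point within one cross direction, summing allele
#' rows per gene model first (the single-reference view used for
#' clustering).
#'
#' @param expr Long count tibble with `rpm` ([rpm_normalize()]).
#' @param direction Maternal genotype selecting the direction.
#' @return Long tibble: `gene`, `dap`, `mean_rpm`.
#' @export
dap_means <- function(expr, direction) {
  check_counts(expr, need_rpm = TRUE)
  sub <- expr[expr$maternal == direction, ]
  if (nrow(sub) == 0) abort(paste0("no samples with maternal parent ", direction))
  sub |>
    dplyr::group_by(.data$gene, .data$sample_id, .data$dap) |>
    dplyr::summarise(rpm = sum(.data$rpm), .groups = "drop") |>
    dplyr::group_by(.data$gene, .data$dap) |>
    dplyr::summarise(mean_rpm = mean(.data$rpm), .groups = "drop")
}

#' Max-normalize expression trajectories
#'
#' Divides each gene's per-time-point mean expression by its maximum, so
#' every retained gene ranges over `[0, 1]` with maximum exactly 1. Genes
#' with all-zero expression are dropped (their count is messaged). If a
#' gene's maximum is reached at several time points they all take value 1;
#' `max_dap` reports the earliest. Idempotent.
#'
#' @param traj Long tibble `gene`, `dap`, and a value column (`mean_rpm` or
#'   `value`).
#' @return Long tibble `gene`, `dap`, `value` (max 1 per gene), `max_dap`.
#' @examples
#' traj <- tibble::tibble(gene = "g1", dap = c(11, 14, 17, 21),
#'                        mean_rpm = c(2, 4, 8, 4))
#' max_normalize(traj)
#' @export
max_normalize <- function(traj) {
  val_col <- if ("value" %in% names(traj)) "value" else "mean_rpm"
  out <- traj |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(.max = max(.data[[val_col]])) |>
    dplyr::ungroup()
  dropped <- unique(out$gene[out$.max <= 0])
  if (length(dropped)) {
    inform(sprintf("dropping %d gene(s) with no expression", length(dropped)))
    out <- out[!out$gene %in% dropped, ]
  }
  out$value <- out[[val_col]] / out$.max
  out |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(max_dap = min(.data$dap[.data$value == 1])) |>
    dplyr::ungroup() |>
    dplyr::select("gene", "dap", "value", "max_dap")
}

#' Seeded k-means clustering of normalized trajectories
#'
#' Clusters max-normalized trajectories into `k` clusters with
#' `stats::kmeans` (Euclidean distance on the per-time-point values,
#' `nstart` random restarts keeping the lowest within-cluster sum of
#' squares), seeded for determinism. Cluster labels are canonicalized by
#' centroid peak time, then by peak sharpness (centroid max minus mean,
#' descending), so labels are stable under gene-order permutations.
#'
#' @param traj Output of [max_normalize()].
#' @param k Number of clusters (default 9).
#' @param seed Integer seed (mandatory).
#' @param nstart Random restarts (default 25).
#' @return Object of class `traj_kmeans` with `$assignments` (tibble
#'   `gene`, `cluster`), `$centroids` (tibble `cluster`, `dap`, `value`),
#'   `$k`, `$tot_withinss`, `$totss`, `$seed`.
#' @export
fit_kmeans <- function(traj, k = 9, seed, nstart = 25) {
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory")
  wide <- tidyr::pivot_wider(traj[, c("gene", "dap", "value")],
                             names_from = "dap", values_from = "value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene
  if (nrow(m) < k) {
    abort(sprintf("only %d trajectories for k = %d clusters", nrow(m), k))
  }
  fit <- withr::with_seed(seed, kmeans(m, centers = k, nstart = nstart,
                                       iter.max = 100))
  daps <- as.numeric(colnames(m))
  centers <- fit$centers
  peak_dap <- daps[apply(centers, 1, which.max)]
  sharpness <- apply(centers, 1, max) - rowMeans(centers)
  ord <- order(peak_dap, -sharpness)
  relabel <- match(seq_len(k), ord)

  assignments <- tibble::tibble(gene = rownames(m),
                                cluster = relabel[fit$cluster])
  centroids <- tibble::tibble(
    cluster = rep(seq_len(k), each = length(daps)),
    dap = rep(daps, k),
    value = as.vector(t(centers[ord, , drop = FALSE]))
  )
  structure(list(
    assignments = assignments, centroids = centroids, k = k,
    tot_withinss = fit$tot.withinss, totss = fit$totss,
    withinss = fit$withinss[ord], size = fit$size[ord],
    iter = fit$iter, seed = seed, data = traj
  ), class = "traj_kmeans")
}

#' @export
print.traj_kmeans <- function(x, ...) {
  cat("<traj_kmeans>", x$k, "clusters over",
      nrow(x$assignments), "genes; total within-SS",
      format(x$tot_withinss, digits = 4), "\n")
  invisible(x)
}

#' @rdname fit_kmeans
#' @param x A `traj_kmeans` object.
#' @param ... Unused.
#' @export
tidy.traj_kmeans <- function(x, ...) {
  x$centroids |>
    tidyr::pivot_wider(names_from = "dap", values_from = "value",
                       names_prefix = "dap_") |>
    dplyr::mutate(size = x$size, withinss = x$withinss)
}

#' @rdname fit_kmeans
#' @export
glance.traj_kmeans <- function(x, ...) {
  tibble::tibble(k = x$k, n_genes = nrow(x$assignments),
                 totss = x$totss, tot_withinss = x$tot_withinss,
                 betweenss_ratio = 1 - x$tot_withinss / x$totss,
                 iter = x$iter)
}

#' @rdname fit_kmeans
#' @param data Trajectory tibble to label (defaults to the fitted data).
#' @export
augment.traj_kmeans <- function(x, data = x$data, ...) {
  dplyr::inner_join(data, x$assignments, by = "gene")
}

#' @rdname fit_kmeans
#' @param object A `traj_kmeans` object.
#' @export
autoplot.traj_kmeans <- function(object, ...) {
  ggplot2::ggplot(augment(object),
                  ggplot2::aes(x = .data$dap, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$gene), alpha = 0.05) +
    ggplot2::geom_line(data = object$centroids, colour = "red",
                       linewidth = 1) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "days after pollination",
                  y = "max-normalized expression") +
    ggplot2::theme_minimal()
}

#' Transfer cluster labels to the reciprocal direction
#'
#' Each gene of the reciprocal direction inherits the cluster of the same
#' gene from the fitted direction (identity transfer); genes absent from
#' either direction are dropped. This enables the reciprocal-consistency
#' check: if dynamics are shared, the reciprocal trajectories grouped by
#' transferred label should track the fitted centroids.
#'
#' @param model A [fit_kmeans()] model.
#' @param reciprocal_traj Max-normalized trajectories of the reciprocal
#'   direction.
#' @return Tibble `gene`, `dap`, `value`, `cluster` for the shared genes.
#' @export
transfer_clusters <- function(model, reciprocal_traj) {
  out <- dplyr::inner_join(reciprocal_traj[, c("gene", "dap", "value")],
                           model$assignments, by = "gene")
  if (nrow(out) == 0) abort("no genes shared between the two directions")
  out
}

#' Reciprocal-transfer consistency
#'
#' Pearson correlation, per cluster, between the fitted centroid and the
#' mean reciprocal-direction trajectory of the transferred genes.
#'
#' @param model A [fit_kmeans()] model.
#' @param reciprocal_traj Max-normalized reciprocal trajectories.
#' @return Tibble `cluster`, `n_genes`, `correlation`.
#' @export
transfer_consistency <- function(model, reciprocal_traj) {
  transferred <- transfer_clusters(model, reciprocal_traj)
  mean_traj <- transferred |>
    dplyr::group_by(.data$cluster, .data$dap) |>
    dplyr::summarise(value = mean(.data$value),
                     n_genes = dplyr::n(), .groups = "drop")
  joined <- dplyr::inner_join(mean_traj, model$centroids,
                              by = c("cluster", "dap"),
                              suffix = c("_recip", "_centroid"))
  joined |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n_genes = .data$n_genes[1],
      correlation = cor(.data$value_recip, .data$value_centroid),
      .groups = "drop"
    )
}
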