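#' Reciprocal expression ratio
#'
#' `RER = maternal / (maternal + paternal)` on RPM-scale expression measured
#' across reciprocal crosses. Values run from 0 (all transcripts paternal) to
#' 1 (all maternal); because triploid endosperm carries two maternal genome
#' copies to one paternal copy, a biparentally expressed gene with equal
#' per-copy expression sits at 2/3 (~0.66), not 0.5. Undefined (`NA`) when
#' both inputs are zero.
#'
#' @param maternal_rpm,paternal_rpm Nonnegative RPM values (vectorized).
#' @return Numeric vector in `[0, 1]`, `NA` where both inputs are zero.
#' @examples
#' compute_rer(2, 1)    # dosage null: 2/3
#' compute_rer(10, 0)   # fully maternal
#' @export
compute_rer <- function(maternal_rpm, paternal_rpm) {
  if (any(maternal_rpm < 0, na.rm = TRUE) ||
      any(paternal_rpm < 0, na.rm = TRUE)) {
    abort("RPM inputs to compute_rer() must be nonnegative")
  }
  total <- maternal_rpm + paternal_rpm
  ifelse(total > 0, maternal_rpm / total, NA_real_)
}

#' Thresholds for imprinting and parental-bias calls
#'
#' The stringent, significance-gated imprinting cutoffs (RER >= 0.9 for
#' MEGs, <= 0.3 for PEGs) and the lenient bias cutoffs (> 0.8 maternal,
#' < 0.4 paternal) that do not require statistical support, plus the test
#' parameters and the 1 RPM expression gate. The invariant
#' `peg_rer < paternal_bias_rer < 2/3 < maternal_bias_rer < meg_rer` is
#' enforced; the paternal bias cutoff can be tightened to 0.3 where a
#' stricter bias definition is wanted.
#'
#' @param meg_rer,peg_rer Significance-gated imprinting cutoffs.
#' @param maternal_bias_rer,paternal_bias_rer Lenient bias cutoffs.
#' @param alpha FDR level for the imprinting test.
#' @param lfc Log2 fold-change threshold of the test.
#' @param expr_min Mean RPM below which a gene-allele is `not_expressed`.
#' @return An object of class `imprint_thresholds`.
#' @export
imprint_thresholds <- function(meg_rer = 0.9, peg_rer = 0.3,
                               maternal_bias_rer = 0.8,
                               paternal_bias_rer = 0.4,
                               alpha = 0.05, lfc = 1, expr_min = 1) {
  if (!(peg_rer <= paternal_bias_rer && paternal_bias_rer < 2 / 3 &&
        2 / 3 < maternal_bias_rer && maternal_bias_rer < meg_rer)) {
    abort("thresholds must satisfy peg <= paternal_bias < 2/3 < maternal_bias < meg")
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  structure(list(meg_rer = meg_rer, peg_rer = peg_rer,
                 maternal_bias_rer = maternal_bias_rer,
                 paternal_bias_rer = paternal_bias_rer,
                 alpha = alpha, lfc = lfc, expr_min = expr_min),
            class = "imprint_thresholds")
}

#' @export
print.imprint_thresholds <- function(x, ...) {
  cat(sprintf(
    "<imprint_thresholds> MEG >= %.2g / PEG <= %.2g (padj < %.2g, |lfc| > %.2g); bias > %.2g / < %.2g; expressed >= %.2g RPM\n",
    x$meg_rer, x$peg_rer, x$alpha, x$lfc,
    x$maternal_bias_rer, x$paternal_bias_rer, x$expr_min))
  invisible(x)
}

# The admissible status labels, in the order used for factors.
imprint_status_levels <- c("MEG", "PEG", "maternal_bias", "paternal_bias",
                           "biparental", "not_expressed")

#' Call imprinting / parental-bias status
#'
#' The status rule, applied per gene-allele per time point:
#' `not_expressed` below the expression gate; `MEG` when RER meets the
#' stringent maternal cutoff *and* the fold-change test is significant;
#' `PEG` symmetrically; otherwise `maternal_bias` / `paternal_bias` when the
#' lenient cutoffs are exceeded (no significance required); otherwise
#' `biparental`. Total and vectorized; missing `padj` (untestable gene)
#' counts as non-significant.
#'
#' @param rer RER values (may be `NA` only where `mean_rpm` is 0).
#' @param padj Adjusted p-values from the imprinting test.
#' @param mean_rpm Mean RPM across all samples of the time point.
#' @param thr An [imprint_thresholds()].
#' @return Character vector of statuses.
#' @examples
#' thr <- imprint_thresholds()
#' call_status(c(0.95, 0.95, 0.66), c(0.001, 0.2, 0.9), c(10, 10, 10), thr)
#' @export
call_status <- function(rer, padj, mean_rpm, thr = imprint_thresholds()) {
  stopifnot(inherits(thr, "imprint_thresholds"))
  sig <- !is.na(padj) & padj < thr$alpha
  dplyr::case_when(
    mean_rpm < thr$expr_min ~ "not_expressed",
    is.na(rer) ~ "not_expressed",
    rer >= thr$meg_rer & sig ~ "MEG",
    rer <= thr$peg_rer & sig ~ "PEG",
    rer > thr$maternal_bias_rer ~ "maternal_bias",
    rer < thr$paternal_bias_rer ~ "paternal_bias",
    TRUE ~ "biparental"
  )
}

#' Per-gene-allele, per-time-point imprinting profile
#'
#' Joins replicate-mean RPM by inheritance direction (maternal = samples in
#' which the allele's source genome was the maternal parent) with the
#' imprinting test results, computes RER on the direction means, and calls
#' status per time point via [call_status()].
#'
#' @param expr Long count tibble with an `rpm` column ([rpm_normalize()]).
#' @param de Imprinting test results from [test_imprinting()] covering the
#'   same gene-alleles and time points.
#' @param thr An [imprint_thresholds()].
#' @return A tibble of class `imprint_profile`: one row per gene-allele per
#'   dap with `maternal_rpm`, `paternal_rpm`, `mean_rpm`, `rer`, `padj`,
#'   `status`.
#' @export
imprint_profile <- function(expr, de, thr = imprint_thresholds()) {
  check_counts(expr, need_rpm = TRUE)
  prof <- expr |>
    dplyr::mutate(direction = ifelse(.data$maternal == .data$genome,
                                     "maternal", "paternal")) |>
    dplyr::group_by(.data$gene_id, .data$genome, .data$gene, .data$dap) |>
    dplyr::summarise(
      maternal_rpm = mean(.data$rpm[.data$direction == "maternal"]),
      paternal_rpm = mean(.data$rpm[.data$direction == "paternal"]),
      mean_rpm = mean(.data$rpm),
      .groups = "drop"
    )
  missing_dap <- setdiff(unique(prof$dap), unique(de$dap))
  if (length(missing_dap)) {
    abort(paste0("test results missing for DAP ",
                 paste(missing_dap, collapse = ", ")))
  }
  out <- dplyr::left_join(prof,
                          de[, c("gene_id", "dap", "log2fc", "padj")],
                          by = c("gene_id", "dap"))
  out$rer <- compute_rer(out$maternal_rpm, out$paternal_rpm)
  out$status <- call_status(out$rer, out$padj, out$mean_rpm, thr)
  class(out) <- c("imprint_profile", class(out))
  out
}

#' Per-gene summary of an imprinting profile
#'
#' For each gene-allele: number of time points imprinted, the imprinting
#' direction (`MEG`, `PEG`, `mixed`, or `none`), and the number of time
#' points at which the RER meets the lenient parental-bias threshold in the
#' imprinting direction (the bias-consistency count).
#'
#' @param profile An [imprint_profile()].
#' @param thr An [imprint_thresholds()].
#' @return One-row-per-gene-allele tibble with `direction`, `n_imprinted`,
#'   `n_bias_met`, `n_expressed`, `mean_rpm_overall`.
#' @export
profile_summary <- function(profile, thr = imprint_thresholds()) {
  profile |>
    dplyr::group_by(.data$gene_id, .data$genome, .data$gene) |>
    dplyr::summarise(
      n_imprinted = sum(.data$status %in% c("MEG", "PEG")),
      direction = direction_of(.data$status),
      n_bias_met = {
        d <- direction_of(.data$status)
        if (d == "MEG") sum(.data$rer > thr$maternal_bias_rer, na.rm = TRUE)
        else if (d == "PEG") sum(.data$rer < thr$paternal_bias_rer, na.rm = TRUE)
        else 0L
      },
      n_expressed = sum(.data$mean_rpm >= thr$expr_min),
      mean_rpm_overall = mean(.data$mean_rpm),
      .groups = "drop"
    )
}

direction_of <- function(status) {
  has_meg <- any(status == "MEG")
  has_peg <- any(status == "PEG")
  if (has_meg && has_peg) "mixed"
  else if (has_meg) "MEG"
  else if (has_peg) "PEG"
  else "none"
}

#' Plot RER trajectories of an imprinting profile
#'
#' RER over developmental time for each gene-allele, colored by status, with
#' the dosage-null (2/3), imprinting, and bias thresholds as reference
#' lines. With many genes, pass a subset.
#'
#' @param object An [imprint_profile()].
#' @param thr An [imprint_thresholds()] (for the reference lines).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.imprint_profile <- function(object, thr = imprint_thresholds(), ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$dap, y = .data$rer,
                               group = .data$gene_id)) +
    ggplot2::geom_line(alpha = 0.25) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status), size = 1) +
    ggplot2::geom_hline(yintercept = 2 / 3, linetype = 2) +
    ggplot2::geom_hline(yintercept = c(thr$meg_rer, thr$peg_rer),
                        colour = "grey30") +
    ggplot2::geom_hline(yintercept = c(thr$maternal_bias_rer,
                                       thr$paternal_bias_rer),
                        colour = "grey70") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "days after pollination", y = "RER (maternal fraction)",
                  colour = "status") +
    ggplot2::theme_minimal()
}
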