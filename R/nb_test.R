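# Negative-binomial fold-change-threshold testing.
#
# The maternal-vs-paternal imprinting contrast tests the composite null
# |log2FC| <= theta with a Wald construction: two one-sided tests at +theta
# and -theta, p = 2 * min(p+, p-) capped at 1 ("greater_abs"). Group means
# are estimated on library-size-corrected counts (size factor = library
# total / 1e6, so fitted group means are in RPM units); the Wald variance of
# log(q) for a group is 1/(q * S) + alpha * S2 / S^2 with S = sum of size
# factors, S2 = sum of squared size factors, alpha the NB dispersion.

#' Method-of-moments negative-binomial dispersion
#'
#' Raw per-gene dispersion estimate from replicate counts within one or more
#' groups, before any shrinkage: on size-factor-normalized counts `y = k/s`
#' with group mean `q`, solves `Var(y) = q * mean(1/s) + alpha * q^2` for
#' `alpha`, pooling groups by their degrees of freedom, and truncates at
#' zero. For unit size factors this is the familiar
#' `(var - mean) / mean^2`.
#'
#' @param counts Numeric matrix, genes x samples (raw counts).
#' @param group Factor/vector of group labels, one per column.
#' @param size_factors Numeric vector of per-sample size factors (default 1).
#' @return Numeric vector of per-gene dispersions (`NA` for genes with no
#'   replicated information or zero mean).
#' @export
dispersion_mom <- function(counts, group, size_factors = rep(1, ncol(counts))) {
  counts <- as.matrix(counts)
  stopifnot(length(group) == ncol(counts),
            length(size_factors) == ncol(counts))
  y <- sweep(counts, 2, size_factors, "/")
  num <- rep(0, nrow(counts))
  den <- rep(0, nrow(counts))
  df <- 0
  for (g in unique(group)) {
    j <- which(group == g)
    if (length(j) < 2) next
    q <- rowMeans(y[, j, drop = FALSE])
    v <- apply(y[, j, drop = FALSE], 1, var)
    shot <- q * mean(1 / size_factors[j])  # Poisson part of Var(y)
    w <- length(j) - 1
    num <- num + w * (v - shot)
    den <- den + w * q^2
    df <- df + w
  }
  if (df == 0) return(rep(NA_real_, nrow(counts)))
  alpha <- num / den
  alpha[den == 0] <- NA_real_
  pmax(alpha, 0)
}

# Shrink raw dispersions toward a fitted mean-dispersion trend
# alpha_tr(q) = a0 + a1/q (the parametric trend of standard bulk RNA-seq
# practice), with weight proportional to the per-gene residual degrees of
# freedom against a fixed prior weight.
shrink_dispersion <- function(alpha_raw, mean_norm, df, prior_df = 4,
                              floor = 1e-8) {
  ok <- is.finite(alpha_raw) & is.finite(mean_norm) & mean_norm > 0
  fit_ok <- ok & alpha_raw > 0
  if (sum(fit_ok) >= 10) {
    fit <- lm(alpha_raw[fit_ok] ~ I(1 / mean_norm[fit_ok]))
    a <- pmax(coef(fit), 0)
    trend <- a[1] + a[2] / mean_norm
  } else {
    trend <- rep(mean(alpha_raw[fit_ok]) %||% 0, length(alpha_raw))
    trend[!is.finite(trend)] <- 0
  }
  trend <- pmax(trend, floor)
  w <- df / (df + prior_df)
  out <- ifelse(is.finite(alpha_raw), w * alpha_raw + (1 - w) * trend, trend)
  pmax(out, floor)
}

#' Estimate per-gene dispersions with trend shrinkage
#'
#' Method-of-moments estimates ([dispersion_mom()]) shrunk toward a fitted
#' mean-dispersion trend and floored at `1e-8`. All-zero genes are flagged
#' untestable (`NA`).
#'
#' @inheritParams dispersion_mom
#' @param prior_df Prior weight (in degrees of freedom) given to the trend.
#' @return Tibble with per-gene `mean_norm`, `dispersion_raw`, `dispersion`
#'   (shrunk), and `untestable`.
#' @export
estimate_dispersion <- function(counts, group,
                                size_factors = rep(1, ncol(counts)),
                                prior_df = 4) {
  counts <- as.matrix(counts)
  raw <- dispersion_mom(counts, group, size_factors)
  y <- sweep(counts, 2, size_factors, "/")
  mean_norm <- rowMeans(y)
  df <- sum(vapply(unique(group), function(g) max(sum(group == g) - 1, 0),
                   numeric(1)))
  shrunk <- shrink_dispersion(raw, mean_norm, df, prior_df)
  untestable <- rowSums(counts) == 0
  shrunk[untestable] <- NA_real_
  tibble::tibble(
    gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    mean_norm = mean_norm,
    dispersion_raw = raw,
    dispersion = shrunk,
    untestable = untestable
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (monotone in rank, capped at 1), with
#' input validation: p-values must lie in `[0, 1]` and contain no `NaN`.
#'
#' @param pvalues Numeric vector of p-values.
#' @return Numeric vector of adjusted p-values, same order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.nan(pvalues))) abort("NaN p-value passed to bh_adjust()")
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    abort("p-values must be in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

# Core Wald machinery, vectorized over genes. countsA/countsB: matrices of
# the two contrast groups; sA/sB size factors. Returns per-gene estimates
# and the p-value for the requested alternative.
nb_wald <- function(countsA, countsB, sA, sB, dispersion, lfc_threshold = 1,
                    alternative = c("greater_abs", "two_sided")) {
  alternative <- match.arg(alternative)
  kA <- rowSums(countsA); kB <- rowSums(countsB)
  SA <- sum(sA); SB <- sum(sB)
  SA2 <- sum(sA^2); SB2 <- sum(sB^2)
  untestable <- (kA + kB) == 0 | !is.finite(dispersion)

  # zero-count groups get half a read for estimation so the Wald statistic
  # stays finite; flagged via the estimate itself (infinite lfc avoided)
  qA <- ifelse(kA == 0, 0.5, kA) / SA
  qB <- ifelse(kB == 0, 0.5, kB) / SB
  log2fc <- log2(qA / qB)

  vA <- 1 / (qA * SA) + dispersion * SA2 / SA^2
  vB <- 1 / (qB * SB) + dispersion * SB2 / SB^2
  se <- sqrt(vA + vB) / log(2)

  if (alternative == "greater_abs") {
    p_up <- pnorm((log2fc - lfc_threshold) / se, lower.tail = FALSE)
    p_dn <- pnorm((log2fc + lfc_threshold) / se, lower.tail = TRUE)
    pvalue <- pmin(1, 2 * pmin(p_up, p_dn))
  } else {
    pvalue <- 2 * pnorm(abs(log2fc) / se, lower.tail = FALSE)
  }
  pvalue[untestable] <- 1

  tibble::tibble(
    maternal_mean = qA, paternal_mean = qB,
    log2fc = ifelse(untestable, NA_real_, log2fc),
    se = se, pvalue = pvalue, untestable = untestable
  )
}

#' Negative-binomial fold-change-threshold test between two sample groups
#'
#' Tests, per gene, the composite null `|log2FC| <= lfc_threshold` against
#' `|log2FC| > lfc_threshold` (`alternative = "greater_abs"`, the imprinting
#' contract) or the plain null `log2FC = 0` (`"two_sided"`) with a Wald
#' statistic on library-size-corrected NB group means. Dispersion is
#' estimated by moments and shrunk toward a mean-dispersion trend
#' ([estimate_dispersion()]). Genes with zero counts across both groups are
#' excluded from testing and from the BH denominator (p and padj `NA`,
#' `untestable = TRUE`).
#'
#' @param counts Gene x sample count matrix.
#' @param groupA,groupB Column indices (or names) of the two groups; the
#'   log2 fold change is A over B.
#' @param size_factors Per-sample size factors, columns of `counts`
#'   (default: column totals / 1e6, so group means are RPM-scale).
#' @param lfc_threshold Fold-change threshold on the log2 scale (default 1).
#' @param alternative `"greater_abs"` or `"two_sided"`.
#' @param alpha FDR level used for the `significant` flag.
#' @return Tibble per gene: group means, `log2fc`, `se`, `pvalue`, `padj`,
#'   `significant` (requires `padj < alpha` *and* the point estimate beyond
#'   the threshold), `untestable`.
#' @export
test_fold_change <- function(counts, groupA, groupB,
                             size_factors = colSums(counts) / 1e6,
                             lfc_threshold = 1,
                             alternative = c("greater_abs", "two_sided"),
                             alpha = 0.05) {
  alternative <- match.arg(alternative)
  counts <- as.matrix(counts)
  if (length(groupA) == 0 || length(groupB) == 0) {
    abort("both contrast groups must be non-empty")
  }
  jA <- if (is.character(groupA)) match(groupA, colnames(counts)) else groupA
  jB <- if (is.character(groupB)) match(groupB, colnames(counts)) else groupB
  if (anyNA(jA) || anyNA(jB)) abort("unknown sample in contrast groups")

  group <- rep(NA_character_, ncol(counts))
  group[jA] <- "A"; group[jB] <- "B"
  used <- !is.na(group)
  disp <- estimate_dispersion(counts[, used, drop = FALSE], group[used],
                              size_factors[used])

  res <- nb_wald(counts[, jA, drop = FALSE], counts[, jB, drop = FALSE],
                 size_factors[jA], size_factors[jB], disp$dispersion,
                 lfc_threshold, alternative)
  res <- dplyr::mutate(res,
    gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    dispersion = disp$dispersion,
    .before = 1
  )
  res$pvalue[res$untestable] <- NA_real_
  res$padj <- NA_real_
  res$padj[!res$untestable] <- bh_adjust(res$pvalue[!res$untestable])
  beyond <- if (alternative == "greater_abs") {
    abs(res$log2fc) > lfc_threshold
  } else {
    abs(res$log2fc) > lfc_threshold
  }
  res$significant <- !res$untestable & !is.na(res$padj) &
    res$padj < alpha & beyond
  res
}

#' Maternal-vs-paternal imprinting test per time point
#'
#' For every gene-allele and time point, contrasts samples in which the
#' allele's source genome was inherited maternally against the reciprocal
#' direction, pooling both cross directions as the reciprocal expression
#' ratio method prescribes, with the `greater_abs` composite null at
#' `lfc_threshold` (default 1, i.e. significantly more than 2-fold beyond
#' the 2:1 genome dosage). BH adjustment is applied within each time point
#' across testable genes.
#'
#' @param counts Long count tibble (see [read_counts()]).
#' @param lfc_threshold,alpha Test parameters (defaults 1 and 0.05).
#' @return Tibble per gene-allele per dap: `maternal_mean`, `paternal_mean`
#'   (RPM-scale), `log2fc`, `pvalue`, `padj`, `significant`, `untestable`.
#' @export
test_imprinting <- function(counts, lfc_threshold = 1, alpha = 0.05) {
  check_counts(counts)
  m <- counts_matrix(counts)
  meta <- sample_table(counts)
  meta <- meta[match(colnames(m), meta$sample_id), ]
  totals <- colSums(m)
  genomes <- split_gene_id(rownames(m))$genome

  purrr::map_dfr(sort(unique(meta$dap)), function(d) {
    in_dap <- meta$dap == d
    purrr::map_dfr(unique(genomes), function(gn) {
      rows <- which(genomes == gn)
      jA <- which(in_dap & meta$maternal == gn)  # allele inherited maternally
      jB <- which(in_dap & meta$paternal == gn)
      if (length(jA) < 2 || length(jB) < 2) {
        abort(sprintf(
          "need >= 2 samples per direction for genome %s at %d DAP", gn, d))
      }
      res <- test_fold_change(m[rows, c(jA, jB), drop = FALSE],
                              groupA = seq_along(jA),
                              groupB = length(jA) + seq_along(jB),
                              size_factors = totals[c(jA, jB)] / 1e6,
                              lfc_threshold = lfc_threshold,
                              alternative = "greater_abs", alpha = alpha)
      dplyr::mutate(res, genome = gn, dap = d, .after = "gene_id")
    })
  })
}

#' Differential expression versus the earliest time point
#'
#' Within one cross direction, tests each later time point against the
#' baseline (11 DAP by default): two-sided NB Wald test with BH FDR, a gene
#' called DE when `padj < alpha` and `|log2fc| > lfc_threshold`, matching
#' the usual "log2FC > 1, FDR < 0.05" convention. Allele rows of the same
#' gene model are summed first, emulating single-reference mapping.
#'
#' @param counts Long count tibble.
#' @param direction Maternal genotype selecting the cross direction.
#' @param baseline_dap Baseline time point (default 11).
#' @param lfc_threshold,alpha Calling thresholds.
#' @return Tibble per gene per contrast `"<dap>_vs_<baseline>"`, with
#'   `log2fc`, `pvalue`, `padj`, `de` and `sign` (`"up"`/`"down"`).
#' @seealso [de_overlap()]
#' @export
de_vs_baseline <- function(counts, direction, baseline_dap = 11,
                           lfc_threshold = 1, alpha = 0.05) {
  check_counts(counts)
  sub <- counts[counts$maternal == direction, ]
  if (nrow(sub) == 0) abort(paste0("no samples with maternal parent ", direction))
  if (!baseline_dap %in% sub$dap) {
    abort(sprintf("baseline time point %s missing", baseline_dap))
  }
  # sum allele rows per gene model (single-reference view)
  gene_counts <- sub |>
    dplyr::group_by(.data$gene, .data$sample_id, .data$dap) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  wide <- tidyr::pivot_wider(gene_counts[, c("gene", "sample_id", "count")],
                             names_from = "sample_id", values_from = "count",
                             values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE]); rownames(m) <- wide$gene
  smeta <- dplyr::distinct(sub[, c("sample_id", "dap")])
  smeta <- smeta[match(colnames(m), smeta$sample_id), ]
  totals <- colSums(m)

  later <- sort(setdiff(unique(smeta$dap), baseline_dap))
  purrr::map_dfr(later, function(d) {
    jA <- which(smeta$dap == d)
    jB <- which(smeta$dap == baseline_dap)
    if (length(jA) < 2 || length(jB) < 2) {
      abort(sprintf("need >= 2 replicates at %s and %s DAP", d, baseline_dap))
    }
    res <- test_fold_change(m[, c(jA, jB), drop = FALSE],
                            groupA = seq_along(jA),
                            groupB = length(jA) + seq_along(jB),
                            size_factors = totals[c(jA, jB)] / 1e6,
                            lfc_threshold = lfc_threshold,
                            alternative = "two_sided", alpha = alpha)
    dplyr::transmute(res,
      gene = .data$gene_id,
      contrast = sprintf("%d_vs_%d", d, as.integer(baseline_dap)),
      dap = d,
      log2fc = .data$log2fc, pvalue = .data$pvalue, padj = .data$padj,
      de = .data$significant,
      sign = dplyr::case_when(
        !.data$significant ~ NA_character_,
        .data$log2fc > 0 ~ "up",
        TRUE ~ "down"
      )
    )
  })
}

#' Overlap of DE calls across time-point contrasts
#'
#' Counts, separately for up- and downregulated genes, how many genes are DE
#' in exactly 1, 2, or all of the later-vs-baseline comparisons.
#'
#' @param de Result of [de_vs_baseline()].
#' @return Tibble with `sign`, `n_contrasts`, `n_genes`, `fraction` (of the
#'   genes DE in at least one contrast with that sign).
#' @export
de_overlap <- function(de) {
  hits <- de[!is.na(de$sign), ]
  if (nrow(hits) == 0) {
    return(tibble::tibble(sign = character(), n_contrasts = integer(),
                          n_genes = integer(), fraction = numeric()))
  }
  hits |>
    dplyr::count(.data$sign, .data$gene, name = "n_contrasts") |>
    dplyr::count(.data$sign, .data$n_contrasts, name = "n_genes") |>
    dplyr::group_by(.data$sign) |>
    dplyr::mutate(fraction = .data$n_genes / sum(.data$n_genes)) |>
    dplyr::ungroup()
}
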