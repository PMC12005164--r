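# Temporal-consistency classification of imprinted genes.
#
# Rules are applied hierarchically (first match wins), which makes the four
# groups disjoint:
#   filtered_low_expression : mean RPM across the time points < 1
#   Group 1 : expressed (>= 1 RPM) at every time point and imprinted in the
#             same direction at every time point
#   Group 2 : imprinted in the same direction at every time point at which
#             it is expressed (>= 1 RPM)
#   Group 3 : at every non-imprinted time point the status is the
#             same-direction parental bias
#   Group 4 : >= 5 RPM at every time point and the gene gains/loses
#             imprinting (>= 1 time point neither imprinted nor
#             same-direction-biased)
#   unassigned otherwise.
# Genes imprinted in both directions at different time points (never
# expected; direction "mixed") skip Groups 1-3 and the Group-4 bias clause
# never matches for them.

bias_of <- function(direction) {
  c(MEG = "maternal_bias", PEG = "paternal_bias")[direction]
}

#' Assign temporal-consistency groups
#'
#' Classifies each gene-allele of an imprinting profile into the four
#' temporal-consistency groups (see the rule listing in the package source
#' and the methods vignette). The unit is the gene-allele: calls from the
#' two reciprocally mapped genomes are classified independently.
#'
#' Genes with no imprinted time point cannot be grouped; they are dropped
#' with a message (`strict = TRUE` turns this into an error, matching the
#' single-gene contract that callers pre-filter).
#'
#' @param profile An [imprint_profile()].
#' @param thr An [imprint_thresholds()].
#' @param strict Error (instead of dropping) on never-imprinted genes.
#' @return Tibble per gene-allele: `direction`, `group` (one of `"1".."4"`,
#'   `"unassigned"`, `"filtered_low_expression"`), and a `rationale` trace
#'   of the rule that fired.
#' @export
assign_groups <- function(profile, thr = imprint_thresholds(),
                          strict = FALSE) {
  wide <- profile |>
    dplyr::arrange(.data$dap) |>
    dplyr::group_by(.data$gene_id, .data$genome, .data$gene) |>
    dplyr::summarise(
      status = list(.data$status),
      rpm = list(.data$mean_rpm),
      .groups = "drop"
    )

  imprinted_any <- vapply(wide$status,
                          function(s) any(s %in% c("MEG", "PEG")), logical(1))
  if (any(!imprinted_any)) {
    if (strict) {
      abort(sprintf("%d gene(s) have no imprinted time point; pre-filter them",
                    sum(!imprinted_any)))
    }
    inform(sprintf("dropping %d gene-allele(s) never called imprinted",
                   sum(!imprinted_any)))
    wide <- wide[imprinted_any, ]
  }
  if (nrow(wide) == 0) {
    return(tibble::tibble(gene_id = character(), genome = character(),
                          gene = character(), direction = character(),
                          group = character(), rationale = character()))
  }

  # matrix form: genes x daps
  S <- do.call(rbind, wide$status)
  R <- do.call(rbind, wide$rpm)
  n <- nrow(S)

  has_meg <- rowSums(S == "MEG") > 0
  has_peg <- rowSums(S == "PEG") > 0
  dir <- ifelse(has_meg & has_peg, "mixed", ifelse(has_meg, "MEG", "PEG"))
  mixed <- dir == "mixed"

  expressed <- R >= thr$expr_min
  dir_mat <- matrix(dir, n, ncol(S))
  imp <- S == dir_mat
  imp[mixed, ] <- (S == "MEG" | S == "PEG")[mixed, ]
  bias_mat <- matrix(unname(bias_of(dir)), n, ncol(S))
  biased <- !is.na(bias_mat) & S == bias_mat  # mixed: never same-dir biased

  low <- rowMeans(R) < thr$expr_min
  g1 <- !mixed & rowSums(!expressed) == 0 & rowSums(!imp) == 0
  g2 <- !mixed & rowSums(expressed & !imp) == 0
  g3 <- !mixed & rowSums(!(imp | biased)) == 0
  g4 <- rowSums(R < 5) == 0 & rowSums(!(imp | biased)) > 0

  group <- rep("unassigned", n)
  rationale <- rep("no rule matched", n)
  set <- function(mask, g, why) {
    pick <- mask & group == "unassigned" & rationale == "no rule matched"
    group[pick] <<- g
    rationale[pick] <<- why
  }
  set(low, "filtered_low_expression", sprintf("mean RPM < %g", thr$expr_min))
  set(g1, "1", "expressed and imprinted (same direction) at all time points")
  set(g2, "2", "imprinted (same direction) at every expressed time point")
  set(g3, "3", "same-direction parental bias at every non-imprinted time point")
  set(g4, "4", ">= 5 RPM throughout, gains/loses imprinting")

  dplyr::bind_cols(wide[, c("gene_id", "genome", "gene")],
                   tibble::tibble(direction = dir, group = group,
                                  rationale = rationale))
}

#' Parental-bias consistency of imprinted genes
#'
#' Reproduces the bias-consistency tabulation: imprinted genes are split
#' into those imprinted at a single time point vs multiple time points, and
#' cross-tabulated (separately for MEGs and PEGs) by the number of time
#' points (1..4) at which their RER meets the lenient parental-bias
#' threshold in the imprinting direction.
#'
#' @param profile An [imprint_profile()].
#' @param thr An [imprint_thresholds()].
#' @return Tibble with `direction`, `multiplicity` (`"single"`/`"multiple"`),
#'   `n_bias_met`, `n_genes`, `fraction` (within direction x multiplicity).
#' @export
bias_consistency <- function(profile, thr = imprint_thresholds()) {
  summ <- profile_summary(profile, thr)
  summ <- summ[summ$direction %in% c("MEG", "PEG") & summ$n_imprinted > 0, ]
  summ$multiplicity <- ifelse(summ$n_imprinted > 1, "multiple", "single")
  summ |>
    dplyr::count(.data$direction, .data$multiplicity, .data$n_bias_met,
                 name = "n_genes") |>
    dplyr::group_by(.data$direction, .data$multiplicity) |>
    dplyr::mutate(fraction = .data$n_genes / sum(.data$n_genes)) |>
    dplyr::ungroup()
}

#' Group counts and percentages by imprinting direction
#'
#' Tallies group assignments per direction; percentages are over the genes
#' passing the 1 RPM expression filter in that direction (groups 1-4 plus
#' unassigned).
#'
#' @param assignments Result of [assign_groups()].
#' @return Tibble with `direction`, `group`, `n`, `percent`.
#' @export
group_summary <- function(assignments) {
  if (nrow(assignments) == 0) {
    return(tibble::tibble(direction = character(), group = character(),
                          n = integer(), percent = numeric()))
  }
  assignments |>
    dplyr::count(.data$direction, .data$group, name = "n") |>
    dplyr::group_by(.data$direction) |>
    dplyr::mutate(
      percent = 100 * .data$n /
        max(sum(.data$n[.data$group != "filtered_low_expression"]), 1L)
    ) |>
    dplyr::ungroup()
}

#' Bar plot of group sizes by direction
#'
#' @param assignments Result of [assign_groups()].
#' @return A ggplot object.
#' @export
plot_group_summary <- function(assignments) {
  summ <- group_summary(assignments)
  summ <- summ[!summ$group %in% "filtered_low_expression", ]
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$group, y = .data$n,
                                     fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "temporal-consistency group", y = "genes",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
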