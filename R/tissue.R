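#' Classify genes as endosperm-preferred or multitissue
#'
#' Against a 10-tissue RPM expression atlas, a gene is endosperm-preferred
#' when strictly more than 65% of its summed atlas expression comes from the
#' endosperm replicate columns, multitissue when expressed more broadly, and
#' `not_expressed_in_atlas` when its atlas row is all zero (or the gene is
#' absent). Invariant to global rescaling of the atlas.
#'
#' @param atlas Wide tibble: `gene_id` plus one numeric column per tissue
#'   replicate.
#' @param endosperm_pattern Regular expression selecting the endosperm
#'   columns (default matches names starting `"endosperm"`).
#' @param threshold Endosperm fraction above which a gene is
#'   endosperm-preferred (strict inequality; default 0.65).
#' @return Tibble `gene_id`, `endosperm_fraction`, `class`.
#' @examples
#' atlas <- tibble::tibble(gene_id = c("a", "b"),
#'                         endosperm_1 = c(70, 1), leaf = c(20, 5),
#'                         root = c(10, 4))
#' classify_tissue(atlas)
#' @export
classify_tissue <- function(atlas, endosperm_pattern = "^endosperm",
                            threshold = 0.65) {
  value_cols <- setdiff(names(atlas), "gene_id")
  endo_cols <- grep(endosperm_pattern, value_cols, value = TRUE)
  if (length(endo_cols) == 0) abort("no endosperm columns in atlas")
  vals <- as.matrix(atlas[, value_cols])
  if (any(vals < 0)) abort("atlas values must be nonnegative")
  total <- rowSums(vals)
  endo <- rowSums(vals[, endo_cols, drop = FALSE])
  frac <- ifelse(total > 0, endo / total, NA_real_)
  tibble::tibble(
    gene_id = atlas$gene_id,
    endosperm_fraction = frac,
    class = dplyr::case_when(
      total == 0 ~ "not_expressed_in_atlas",
      frac > threshold ~ "endosperm_preferred",
      TRUE ~ "multitissue"
    )
  )
}

#' Cross-tabulate imprinting groups, tissue class and a mutant DE list
#'
#' Joins temporal-consistency group assignments with tissue-preference
#' calls and an externally supplied mutant-vs-WT DE gene list, producing
#' counts per (group x direction x tissue class x DE status). Genes outside
#' the DE study's detected universe fall into the `"not_detected"` bin;
#' genes absent from the atlas are `not_expressed_in_atlas`.
#'
#' @param assignments [assign_groups()] output (or any tibble with `gene`,
#'   `direction`, `group`).
#' @param tissue_calls [classify_tissue()] output.
#' @param degs Character vector of DE gene IDs.
#' @param universe Character vector of all genes detected in the DE study;
#'   `NULL` means only `degs` were detected.
#' @return Tibble with `group`, `direction`, `tissue_class`, `de_status`
#'   (`"DE"`, `"not_DE"`, `"not_detected"`), `n`.
#' @export
crosstab_groups_tissue <- function(assignments, tissue_calls, degs,
                                   universe = NULL) {
  joined <- dplyr::left_join(assignments, tissue_calls,
                             by = c(gene = "gene_id"))
  joined$tissue_class <- joined$class %||% NA_character_
  joined$tissue_class[is.na(joined$tissue_class)] <- "not_expressed_in_atlas"
  in_universe <- if (is.null(universe)) joined$gene %in% degs
                 else joined$gene %in% universe
  joined$de_status <- dplyr::case_when(
    joined$gene %in% degs ~ "DE",
    in_universe ~ "not_DE",
    TRUE ~ "not_detected"
  )
  dplyr::count(joined, .data$group, .data$direction, .data$tissue_class,
               .data$de_status, name = "n")
}
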