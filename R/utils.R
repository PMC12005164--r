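# Internal helpers shared across modules.

# Gene-allele IDs are namespaced "<genome>:<gene>" so that rows from the two
# parental assemblies of a concatenated-genome count table stay unambiguous.
make_gene_id <- function(genome, gene) paste0(genome, ":", gene)

#' Split namespaced gene-allele IDs
#'
#' Gene-allele IDs carry their source genome as a `"<genome>:<gene>"` prefix.
#' This helper splits them back into their parts.
#'
#' @param gene_id Character vector of namespaced IDs.
#' @return A tibble with columns `gene_id`, `genome`, `gene`.
#' @examples
#' split_gene_id(c("B73:Zm00001eb000010", "W22:Zm00004b000010"))
#' @export
split_gene_id <- function(gene_id) {
  stopifnot(is.character(gene_id))
  pos <- regexpr(":", gene_id, fixed = TRUE)
  if (any(pos < 0)) {
    abort(paste0("gene_id without a '<genome>:' prefix: ",
                 gene_id[which(pos < 0)[1]]))
  }
  tibble::tibble(
    gene_id = gene_id,
    genome = substr(gene_id, 1L, pos - 1L),
    gene = substr(gene_id, pos + 1L, nchar(gene_id))
  )
}

# Columns every long allele-count tibble must carry.
count_cols <- c("gene_id", "genome", "sample_id", "maternal", "paternal",
                "dap", "replicate", "count")

check_counts <- function(counts, need_rpm = FALSE, arg = "counts") {
  if (!is.data.frame(counts)) abort(sprintf("`%s` must be a data frame", arg))
  need <- count_cols
  if (need_rpm) need <- c(need, "rpm")
  missing <- setdiff(need, names(counts))
  if (length(missing)) {
    abort(sprintf("`%s` is missing columns: %s", arg,
                  paste(missing, collapse = ", ")))
  }
  if (any(counts$count < 0)) abort("counts must be nonnegative")
  if (any(counts$count != floor(counts$count))) {
    abort("counts must be integers")
  }
  invisible(counts)
}

check_meta <- function(meta) {
  need <- c("sample_id", "maternal", "paternal", "dap", "replicate")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    abort(paste0("sample metadata is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (any(meta$maternal == meta$paternal)) {
    abort("maternal and paternal genotype must differ for every sample")
  }
  key <- paste(meta$maternal, meta$paternal, meta$dap, meta$replicate)
  if (anyDuplicated(key)) {
    abort("duplicate (maternal, paternal, dap, replicate) combination in metadata")
  }
  if (anyDuplicated(meta$sample_id)) abort("duplicate sample_id in metadata")
  invisible(meta)
}

# Pivot a long count tibble to a gene x sample integer matrix.
counts_matrix <- function(counts, value = "count") {
  wide <- tidyr::pivot_wider(
    counts[, c("gene_id", "sample_id", value)],
    names_from = "sample_id", values_from = dplyr::all_of(value),
    values_fill = 0
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene_id
  m
}

sample_table <- function(counts) {
  dplyr::distinct(
    counts[, c("sample_id", "maternal", "paternal", "dap", "replicate")]
  )
}

library_totals <- function(counts) {
  dplyr::summarise(dplyr::group_by(counts, .data$sample_id),
                   total = sum(.data$count), .groups = "drop")
}
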