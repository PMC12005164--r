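#' Read an allele-resolved count table with its sample metadata
#'
#' Reads a genes x samples TSV of uniquely-assigned read counts (first column
#' gene-allele IDs namespaced `"<genome>:<gene>"`, one column per sample) and a
#' sample metadata TSV (columns `sample_id`, `maternal`, `paternal`, `dap`,
#' `replicate`), validates both, and returns the long tidy form that every
#' downstream stage of the package consumes.
#'
#' Counts must be nonnegative integers with no missing values: upstream
#' counting tools emit zeros, not NAs. Every sample column must have a
#' metadata row, and both reciprocal cross directions must be present.
#'
#' @param path Path to the count TSV.
#' @param meta_path Path to the sample metadata TSV.
#' @return A tibble with one row per gene-allele per sample and columns
#'   `gene_id`, `genome`, `gene`, `sample_id`, `maternal`, `paternal`, `dap`,
#'   `replicate`, `count`.
#' @seealso [write_counts()], [rpm_normalize()]
#' @export
read_counts <- function(path, meta_path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(),
    gene_id = readr::col_character()
  ))
  if (names(wide)[1] != "gene_id") names(wide)[1] <- "gene_id"
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE)
  check_meta(meta)

  if (anyDuplicated(wide$gene_id)) {
    abort(paste0("duplicate gene-allele ID in count table: ",
                 wide$gene_id[anyDuplicated(wide$gene_id)][1]))
  }
  sample_ids <- names(wide)[-1]
  orphan <- setdiff(sample_ids, meta$sample_id)
  if (length(orphan)) {
    abort(paste0("no metadata for sample column(s): ",
                 paste(orphan, collapse = ", ")))
  }

  long <- tidyr::pivot_longer(wide, -"gene_id",
                              names_to = "sample_id", values_to = "count")
  bad <- which(is.na(long$count) | long$count < 0 |
                 long$count != floor(long$count))
  if (length(bad)) {
    abort(sprintf(
      "invalid count (must be a nonnegative integer) at gene %s, sample %s: %s",
      long$gene_id[bad[1]], long$sample_id[bad[1]], long$count[bad[1]]
    ))
  }

  parts <- split_gene_id(long$gene_id)
  out <- dplyr::left_join(
    dplyr::mutate(long, genome = parts$genome, gene = parts$gene),
    meta,
    by = "sample_id"
  )
  out <- out[, c("gene_id", "genome", "gene", "sample_id", "maternal",
                 "paternal", "dap", "replicate", "count")]
  check_counts(out)
  tibble::as_tibble(out)
}

#' Write a count experiment back to TSV
#'
#' Inverse of [read_counts()]: writes the wide genes x samples count table and
#' the sample metadata table. Round-trips losslessly.
#'
#' @param counts Long count tibble as returned by [read_counts()] or
#'   [simulate_experiment()].
#' @param path Output path for the count TSV.
#' @param meta_path Output path for the metadata TSV.
#' @return Invisibly, `counts`.
#' @export
write_counts <- function(counts, path, meta_path) {
  check_counts(counts)
  wide <- tidyr::pivot_wider(counts[, c("gene_id", "sample_id", "count")],
                             names_from = "sample_id", values_from = "count",
                             values_fill = 0)
  readr::write_tsv(wide, path)
  readr::write_tsv(sample_table(counts), meta_path)
  invisible(counts)
}

#' Reads-per-million normalization
#'
#' Adds an `rpm` column: `count / library_total * 1e6`, where the library
#' total for each sample is the sum of counts over *all* gene-allele rows of
#' the concatenated-genome table (both parental genomes together), mirroring
#' normalization by total uniquely mapped reads per library.
#'
#' @param counts Long count tibble.
#' @return `counts` with an added `rpm` column.
#' @examples
#' cfg <- sim_config(n_genes = c(biparental = 20), seed = 1)
#' sim <- simulate_experiment(cfg)
#' expr <- rpm_normalize(sim$counts)
#' # each sample's RPM sums to 1e6
#' dplyr::summarise(dplyr::group_by(expr, sample_id), total = sum(rpm))
#' @export
rpm_normalize <- function(counts) {
  check_counts(counts)
  totals <- library_totals(counts)
  zero <- totals$sample_id[totals$total == 0]
  if (length(zero)) {
    abort(paste0("sample(s) with an all-zero library: ",
                 paste(zero, collapse = ", ")))
  }
  out <- dplyr::left_join(counts, totals, by = "sample_id")
  out$rpm <- out$count / out$total * 1e6
  out$total <- NULL
  out
}

#' Read a pan-gene table into a single-copy syntelog map
#'
#' Parses a pan-gene TSV (first column pan-gene ID, one column per genome
#' holding comma-separated member gene IDs, empty cell = absent) and retains
#' only single-copy pairs between the reference genome and each requested
#' alternate genotype: rows where both the reference and the alternate genome
#' list exactly one member gene. Multi-copy rows are dropped, so each
#' `(reference gene, genotype)` pair appears at most once.
#'
#' @param path Path to the pan-gene TSV.
#' @param genotypes Character vector of alternate genotype column names to
#'   retain.
#' @param reference Reference genome column name (default `"B73"`).
#' @return A tibble with columns `b73_gene_id`, `genotype`, `alt_gene_id`,
#'   `copy_count` (always 1 after filtering).
#' @export
read_syntelog_table <- function(path, genotypes, reference = "B73") {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ))
  missing <- setdiff(c(reference, genotypes), names(tab))
  if (length(missing)) {
    abort(paste0("genotype column(s) absent from pan-gene table: ",
                 paste(missing, collapse = ", ")))
  }
  split_members <- function(x) {
    lapply(x, function(cell) {
      if (is.na(cell) || !nzchar(cell)) character(0)
      else strsplit(cell, ",", fixed = TRUE)[[1]]
    })
  }
  ref_members <- split_members(tab[[reference]])
  out <- purrr::map_dfr(genotypes, function(g) {
    alt_members <- split_members(tab[[g]])
    keep <- lengths(ref_members) == 1L & lengths(alt_members) == 1L
    tibble::tibble(
      b73_gene_id = unlist(ref_members[keep]),
      genotype = g,
      alt_gene_id = unlist(alt_members[keep]),
      copy_count = 1L
    )
  })
  dplyr::distinct(out, .data$b73_gene_id, .data$genotype, .keep_all = TRUE)
}

#' Write a syntelog map as a pan-gene style TSV
#'
#' @param syntelogs Tibble from [read_syntelog_table()] or
#'   [simulate_syntelogs()].
#' @param path Output path.
#' @param reference Reference genome name.
#' @return Invisibly, `syntelogs`.
#' @export
write_syntelog_table <- function(syntelogs, path, reference = "B73") {
  wide <- tidyr::pivot_wider(
    syntelogs[, c("b73_gene_id", "genotype", "alt_gene_id")],
    names_from = "genotype", values_from = "alt_gene_id"
  )
  wide <- dplyr::mutate(wide, pan_gene_id = paste0("pan_", dplyr::row_number()),
                        .before = 1)
  names(wide)[names(wide) == "b73_gene_id"] <- reference
  readr::write_tsv(wide, path, na = "")
  invisible(syntelogs)
}
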