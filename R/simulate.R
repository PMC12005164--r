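#' Configuration for a simulated reciprocal-cross experiment
#'
#' Builds the configuration object consumed by [simulate_experiment()] and the
#' companion generators. Defaults describe the study conditions the package is
#' exercised under: two reciprocal cross directions, four developmental time
#' points (11/14/17/21 days after pollination), three biological replicates,
#' 5e6-read libraries, and a gene panel spanning the imprinting classes of
#' interest (constitutive and transient MEGs/PEGs, parental-bias genes,
#' biparental genes, silent genes, and a handful of very highly expressed
#' zein-like genes that stress RPM normalization).
#'
#' @param n_genes Named integer vector of genes per class. Valid classes:
#'   `MEG_constitutive`, `PEG_constitutive`, `MEG_transient`, `PEG_transient`,
#'   `maternal_bias`, `paternal_bias`, `biparental`, `silent`, `zein_like`.
#' @param genotype_pair Length-2 character vector, reference first; the two
#'   parents of the reciprocal cross.
#' @param genotypes All genotype names the truth table covers (reference plus
#'   alternates); used for presence/absence and syntelog simulation.
#' @param dap_set Integer time points (days after pollination).
#' @param replicates Biological replicates per direction per time point
#'   (must be >= 2).
#' @param library_size Mean sequenced reads per library.
#' @param library_cv Coefficient of variation of library sizes (lognormal).
#' @param nb_dispersion Negative-binomial dispersion alpha (Var = mu + alpha
#'   mu^2) shared by all genes.
#' @param pav_rate Probability that a gene is absent from each non-reference
#'   genome (presence/absence variation).
#' @param seed Integer seed; mandatory, reproducibility is part of the
#'   contract.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = c(
                         MEG_constitutive = 400, PEG_constitutive = 100,
                         MEG_transient = 130, PEG_transient = 70,
                         maternal_bias = 250, paternal_bias = 150,
                         biparental = 1800, silent = 50, zein_like = 10
                       ),
                       genotype_pair = c("B73", "W22"),
                       genotypes = genotype_pair,
                       dap_set = c(11L, 14L, 17L, 21L),
                       replicates = 3L,
                       library_size = 5e6,
                       library_cv = 0.15,
                       nb_dispersion = 0.05,
                       pav_rate = 0.03,
                       seed = NULL) {
  if (is.null(seed)) abort("`seed` is mandatory: simulations must be reproducible")
  known <- c("MEG_constitutive", "PEG_constitutive", "MEG_transient",
             "PEG_transient", "maternal_bias", "paternal_bias",
             "biparental", "silent", "zein_like")
  bad <- setdiff(names(n_genes), known)
  if (length(bad)) abort(paste0("unknown gene class: ", paste(bad, collapse = ", ")))
  if (replicates < 2) abort("`replicates` must be >= 2")
  if (nb_dispersion <= 0) abort("`nb_dispersion` must be > 0")
  if (length(genotype_pair) != 2 || genotype_pair[1] == genotype_pair[2]) {
    abort("`genotype_pair` must name two distinct genotypes")
  }
  structure(list(
    n_genes = n_genes, genotype_pair = genotype_pair,
    genotypes = union(genotype_pair, genotypes), dap_set = as.integer(dap_set),
    replicates = as.integer(replicates), library_size = library_size,
    library_cv = library_cv, nb_dispersion = nb_dispersion,
    pav_rate = pav_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", sum(x$n_genes), "genes;",
      paste(x$genotype_pair, collapse = " x "), "reciprocals;",
      length(x$dap_set), "time points x", x$replicates, "replicates;",
      "seed", x$seed, "\n")
  invisible(x)
}

# Per-gene truth: maternal transcript fraction and nominal RPM trajectory for
# each class. Fractions are fractions of *transcripts* from maternal alleles,
# so the biparental dosage value is 2/3 (two maternal genome copies : one
# paternal).
build_truth <- function(cfg) {
  ndap <- length(cfg$dap_set)
  ref <- cfg$genotype_pair[1]
  alts <- setdiff(cfg$genotypes, ref)

  one_class <- function(class, n) {
    if (n == 0) return(NULL)
    gene <- sprintf("%s_%04d", abbreviate_class(class), seq_len(n))
    # nominal RPM level and trajectory shape
    level <- switch(class,
      MEG_constitutive = rlnorm(n, log(60), 0.5),
      PEG_constitutive = rlnorm(n, log(60), 0.5),
      MEG_transient = rlnorm(n, log(120), 0.4),
      PEG_transient = rlnorm(n, log(120), 0.4),
      maternal_bias = rlnorm(n, log(80), 0.5),
      paternal_bias = rlnorm(n, log(80), 0.5),
      biparental = {
        # a low-expression tail is generated deliberately so that the 1 RPM
        # expression filters see genes straddling the boundary
        low <- runif(n) < 0.1
        ifelse(low, rlnorm(n, log(1.5), 0.5), rlnorm(n, log(150), 1))
      },
      silent = rep(0, n),
      zein_like = 10^runif(n, log10(1.5e4), log10(1.5e5))
    )
    shape_sd <- if (class %in% c("MEG_transient", "PEG_transient")) 0.2 else 0.3
    shape <- matrix(exp(rnorm(n * ndap, 0, shape_sd)), n, ndap)
    if (class == "zein_like") {
      # storage-protein archetype: sharp peak near 17 DAP
      peak <- vapply(cfg$dap_set, function(d) {
        c(`11` = 0.1, `14` = 0.4, `17` = 1, `21` = 0.6)[as.character(d)] %||% 0.5
      }, numeric(1))
      peak[is.na(peak)] <- 0.5
      shape <- shape * matrix(peak, n, ndap, byrow = TRUE)
    }
    base <- level * shape

    mf <- matrix(2 / 3, n, ndap)
    imprint_daps <- replicate(n, integer(0), simplify = FALSE)
    if (class == "MEG_constitutive") {
      mf[] <- 0.97
      imprint_daps <- replicate(n, seq_len(ndap), simplify = FALSE)
    } else if (class == "PEG_constitutive") {
      mf[] <- 0.03
      imprint_daps <- replicate(n, seq_len(ndap), simplify = FALSE)
    } else if (class %in% c("MEG_transient", "PEG_transient")) {
      # imprinted at 1..(ndap-1) time points, biparental elsewhere
      imprint_daps <- lapply(seq_len(n), function(i) {
        k <- sample(seq_len(max(1, ndap - 1)), 1)
        sort(sample(ndap, k))
      })
      f_on <- if (class == "MEG_transient") 0.97 else 0.03
      for (i in seq_len(n)) mf[i, imprint_daps[[i]]] <- f_on
    } else if (class %in% c("maternal_bias", "paternal_bias")) {
      # the Group-3 archetype: imprinted at exactly one time point, biased in
      # the same direction (lenient band, not meeting the imprint cutoffs)
      # everywhere else
      f_on <- if (class == "maternal_bias") 0.97 else 0.03
      f_bias <- if (class == "maternal_bias") 0.85 else 0.35
      mf[] <- f_bias
      imprint_daps <- lapply(seq_len(n), function(i) sample(ndap, 1))
      for (i in seq_len(n)) mf[i, imprint_daps[[i]]] <- f_on
    }

    present <- lapply(seq_len(n), function(i) {
      keep <- alts[runif(length(alts)) >= cfg$pav_rate]
      c(ref, keep)
    })

    tibble::tibble(
      gene = rep(gene, each = ndap),
      class = class,
      dap = rep(cfg$dap_set, n),
      maternal_fraction = as.vector(t(mf)),
      base_rpm = as.vector(t(base)),
      genotypes = rep(vapply(present, paste, "", collapse = ","), each = ndap)
    )
  }

  out <- purrr::imap_dfr(as.list(cfg$n_genes), function(n, class) {
    one_class(class, n)
  })
  out
}

abbreviate_class <- function(class) {
  c(MEG_constitutive = "megc", PEG_constitutive = "pegc",
    MEG_transient = "megt", PEG_transient = "pegt",
    maternal_bias = "mbia", paternal_bias = "pbia",
    biparental = "bipa", silent = "sile", zein_like = "zein")[class]
}

#' Simulate an allele-resolved reciprocal-cross count experiment
#'
#' Draws a negative-binomial count experiment with known per-gene imprinting
#' truth. For each gene and library, the gene-level count is NB with mean
#' `base_rpm(dap) * library_size / 1e6` and dispersion `cfg$nb_dispersion`;
#' the maternal-allele count is then binomial conditional on that total with
#' probability equal to the gene's maternal transcript fraction, so total
#' expression trajectories are independent of imprinting class. The same gene
#' model appears as two gene-allele rows, one per parental genome; in each
#' cross direction the allele whose genome is the maternal parent receives
#' the maternal share. Genes absent from a genome (presence/absence
#' variation) have no allele row there, and their reads on the absent allele
#' are lost, as with real concatenated-genome mapping.
#'
#' @param cfg A [sim_config()].
#' @param truth Optional pre-built truth table (as returned in `$truth`);
#'   rebuilt from `cfg` when `NULL`.
#' @param pair Genotype pair to cross (defaults to `cfg$genotype_pair`).
#' @param dap_set Time points to generate (defaults to `cfg$dap_set`).
#' @param seed Seed for the draw; defaults to `cfg$seed`.
#' @return A list with `counts` (long count tibble, see [read_counts()]) and
#'   `truth` (per gene x dap: class, maternal fraction, nominal RPM,
#'   genotype presence).
#' @examples
#' cfg <- sim_config(n_genes = c(biparental = 50, MEG_constitutive = 10),
#'                   seed = 42)
#' sim <- simulate_experiment(cfg)
#' dplyr::count(sim$truth[!duplicated(sim$truth$gene), ], class)
#' @export
simulate_experiment <- function(cfg, truth = NULL, pair = cfg$genotype_pair,
                                dap_set = cfg$dap_set, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(seed)) abort("`seed` is mandatory")
  withr::with_seed(seed, {
    if (is.null(truth)) truth <- build_truth(cfg)
    counts <- draw_counts(cfg, truth, pair, dap_set)
  })
  list(counts = counts, truth = truth)
}

draw_counts <- function(cfg, truth, pair, dap_set) {
  truth <- truth[truth$dap %in% dap_set, ]
  genes <- truth[!duplicated(truth$gene), c("gene", "genotypes")]

  meta <- tidyr::expand_grid(
    direction = c("fwd", "rev"),
    dap = dap_set,
    replicate = seq_len(cfg$replicates)
  )
  meta$maternal <- ifelse(meta$direction == "fwd", pair[1], pair[2])
  meta$paternal <- ifelse(meta$direction == "fwd", pair[2], pair[1])
  meta$sample_id <- sprintf("%sx%s_%02d_r%d", meta$maternal, meta$paternal,
                            meta$dap, meta$replicate)
  meta <- meta[, c("sample_id", "maternal", "paternal", "dap", "replicate")]

  sdlog <- sqrt(log(1 + cfg$library_cv^2))
  lib <- rlnorm(nrow(meta), log(cfg$library_size) - sdlog^2 / 2, sdlog)
  names(lib) <- meta$sample_id

  grid <- dplyr::inner_join(
    truth[, c("gene", "dap", "maternal_fraction", "base_rpm")],
    meta, by = "dap", relationship = "many-to-many"
  )
  mu <- grid$base_rpm * lib[grid$sample_id] / 1e6
  total <- rnbinom(nrow(grid), mu = mu, size = 1 / cfg$nb_dispersion)
  mat_count <- rbinom(nrow(grid), total, grid$maternal_fraction)

  present <- strsplit(genes$genotypes, ",", fixed = TRUE)
  names(present) <- genes$gene
  has_allele <- function(genome) {
    vapply(present[grid$gene], function(p) genome %in% p, logical(1))
  }

  allele_rows <- function(genome) {
    is_mat <- grid$maternal == genome
    keep <- has_allele(genome)
    tibble::tibble(
      gene_id = make_gene_id(genome, grid$gene[keep]),
      genome = genome,
      gene = grid$gene[keep],
      sample_id = grid$sample_id[keep],
      maternal = grid$maternal[keep],
      paternal = grid$paternal[keep],
      dap = grid$dap[keep],
      replicate = grid$replicate[keep],
      count = ifelse(is_mat[keep], mat_count[keep],
                     total[keep] - mat_count[keep])
    )
  }
  counts <- dplyr::bind_rows(allele_rows(pair[1]), allele_rows(pair[2]))
  counts <- dplyr::arrange(counts, .data$gene_id, .data$sample_id)
  counts$count <- as.integer(counts$count)
  counts
}

#' Simulate a panel of single-time-point reciprocal crosses
#'
#' Generates one reciprocal-cross experiment per alternate genotype crossed
#' with the reference, at one time point, reusing the main experiment's truth.
#' With probability `1 - maintain_prob` an imprinted/biased gene reverts to
#' the biparental transcript fraction (2/3) in a given genotype, emulating
#' genotype-variable imprinting.
#'
#' @param truth Truth table from [simulate_experiment()].
#' @param cfg The [sim_config()] used for the main experiment.
#' @param genotypes Alternate genotypes to cross with the reference.
#' @param dap Time point for the panel (default 14).
#' @param maintain_prob Probability an imprinting/bias pattern is maintained
#'   in each alternate genotype; either a scalar or a vector named by gene
#'   class (classes not named keep their pattern with probability 1).
#' @param seed Base seed; each genotype uses `seed + index`.
#' @return Named list (by genotype) of long count tibbles.
#' @export
simulate_genotype_panel <- function(truth, cfg, genotypes, dap = 14L,
                                    maintain_prob = 0.8, seed = cfg$seed) {
  ref <- cfg$genotype_pair[1]
  out <- purrr::imap(setNames(genotypes, genotypes), function(g, nm) {
    i <- match(g, genotypes)
    withr::with_seed(seed + i, {
      t_g <- truth[truth$dap == dap, ]
      p <- if (is.null(names(maintain_prob))) {
        rep(maintain_prob[1], nrow(t_g))
      } else {
        ifelse(t_g$class %in% names(maintain_prob),
               unname(maintain_prob[t_g$class]), 1)
      }
      revert <- runif(nrow(t_g)) > p
      t_g$maternal_fraction[revert & t_g$maternal_fraction != 2 / 3] <- 2 / 3
      draw_counts(cfg, t_g, pair = c(ref, g), dap_set = dap)
    })
  })
  out
}

#' Simulate a 10-tissue expression atlas
#'
#' Assigns each gene an endosperm expression share (endosperm-preferred genes
#' above, multitissue genes below the 65% rule by construction) and spreads
#' its expression over endosperm replicate columns and nine other tissues.
#' At `noise_sd = 0` the constructed shares are exact, so
#' [classify_tissue()] recovers the truth perfectly.
#'
#' @param truth Truth table from [simulate_experiment()].
#' @param seed Integer seed.
#' @param endosperm_reps Number of endosperm replicate columns.
#' @param noise_sd Lognormal noise sd applied per cell.
#' @param p_endo_preferred Named numeric: probability a gene of each class is
#'   endosperm-preferred; unnamed scalar applies to all classes.
#' @return List with `atlas` (wide tibble: `gene_id` + tissue columns, the
#'   endosperm columns named `endosperm_*`) and `truth` (per gene:
#'   `endosperm_share`, `endosperm_preferred`).
#' @export
simulate_tissue_atlas <- function(truth, seed, endosperm_reps = 2,
                                  noise_sd = 0,
                                  p_endo_preferred = c(
                                    MEG_constitutive = 0.7, PEG_constitutive = 0.5,
                                    MEG_transient = 0.4, PEG_transient = 0.4,
                                    maternal_bias = 0.4, paternal_bias = 0.4,
                                    biparental = 0.15, silent = 0.15,
                                    zein_like = 0.95
                                  )) {
  if (nrow(truth) == 0) abort("`truth` must be non-empty")
  genes <- truth |>
    dplyr::group_by(.data$gene, .data$class) |>
    dplyr::summarise(level = mean(.data$base_rpm), .groups = "drop")
  other_tissues <- c("leaf", "root", "tassel", "ear", "seedling",
                     "anther", "silk", "husk", "embryo")
  withr::with_seed(seed, {
    p <- if (is.null(names(p_endo_preferred))) {
      rep(p_endo_preferred[1], nrow(genes))
    } else {
      unname(p_endo_preferred[genes$class])
    }
    preferred <- runif(nrow(genes)) < p
    share <- ifelse(preferred, runif(nrow(genes), 0.75, 0.95),
                    runif(nrow(genes), 0.05, 0.4))
    endo_cols <- paste0("endosperm_", seq_len(endosperm_reps))
    n_other <- length(other_tissues)
    atlas <- matrix(0, nrow(genes), endosperm_reps + n_other,
                    dimnames = list(genes$gene, c(endo_cols, other_tissues)))
    atlas[, endo_cols] <- genes$level * share / endosperm_reps
    w <- matrix(runif(nrow(genes) * n_other, 0.5, 1.5), ncol = n_other)
    w <- w / rowSums(w)
    atlas[, other_tissues] <- genes$level * (1 - share) * w
    if (noise_sd > 0) {
      atlas <- atlas * matrix(rlnorm(length(atlas), 0, noise_sd),
                              nrow = nrow(atlas))
    }
  })
  list(
    atlas = dplyr::bind_cols(tibble::tibble(gene_id = genes$gene),
                             tibble::as_tibble(atlas)),
    truth = tibble::tibble(gene_id = genes$gene, class = genes$class,
                           endosperm_share = share,
                           endosperm_preferred = preferred & genes$level > 0)
  )
}

#' Simulate a single-copy syntelog map
#'
#' Each gene present in a genotype (per the truth table's presence sets,
#' independently thinned at `dropout_rate`) yields exactly one single-copy
#' syntelog pair with the reference.
#'
#' @param truth Truth table from [simulate_experiment()].
#' @param genotypes Alternate genotypes to map.
#' @param dropout_rate Probability an otherwise-present pair is missing from
#'   the pan-gene resource (e.g. uninformative or multi-copy upstream).
#' @param seed Integer seed.
#' @return Tibble with columns `b73_gene_id`, `genotype`, `alt_gene_id`,
#'   `copy_count`.
#' @export
simulate_syntelogs <- function(truth, genotypes, dropout_rate = 0, seed = 1L) {
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort("`dropout_rate` must be in [0, 1)")
  }
  genes <- truth[!duplicated(truth$gene), c("gene", "genotypes")]
  present <- strsplit(genes$genotypes, ",", fixed = TRUE)
  withr::with_seed(seed, {
    out <- purrr::map_dfr(genotypes, function(g) {
      in_g <- vapply(present, function(p) g %in% p, logical(1))
      keep <- in_g & runif(nrow(genes)) >= dropout_rate
      tibble::tibble(
        b73_gene_id = genes$gene[keep],
        genotype = g,
        alt_gene_id = paste0(g, "_", genes$gene[keep]),
        copy_count = 1L
      )
    })
  })
  out
}

#' Simulate a mutant-vs-WT differential expression gene list
#'
#' Emulates an externally published mutant-vs-wild-type DE comparison (the
#' glycosylase-mutant contrast used to annotate imprinted genes): a detected
#' universe of genes plus the subset called DE, with endosperm-preferred
#' genes enriched among the DE calls.
#'
#' @param atlas_truth `$truth` from [simulate_tissue_atlas()].
#' @param seed Integer seed.
#' @param detect_prob Probability a gene is in the detected universe.
#' @param de_prob_endo,de_prob_other DE probability for endosperm-preferred
#'   vs other detected genes.
#' @return List with `degs` and `universe` (character vectors of gene IDs).
#' @export
simulate_mdr1_list <- function(atlas_truth, seed, detect_prob = 0.9,
                               de_prob_endo = 0.8, de_prob_other = 0.1) {
  withr::with_seed(seed, {
    detected <- atlas_truth$gene_id[runif(nrow(atlas_truth)) < detect_prob]
    t_d <- atlas_truth[atlas_truth$gene_id %in% detected, ]
    p <- ifelse(t_d$endosperm_preferred, de_prob_endo, de_prob_other)
    degs <- t_d$gene_id[runif(nrow(t_d)) < p]
  })
  list(degs = degs, universe = detected)
}
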