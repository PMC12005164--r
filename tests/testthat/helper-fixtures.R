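# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# A compact simulated experiment covering all gene classes.
small_sim <- function(seed = 101, ...) {
  cfg <- sim_config(
    n_genes = c(MEG_constitutive = 20, PEG_constitutive = 10,
                MEG_transient = 10, PEG_transient = 10,
                maternal_bias = 10, paternal_bias = 10,
                biparental = 60, silent = 4, zein_like = 2),
    seed = seed, ...
  )
  list(cfg = cfg, sim = simulate_experiment(cfg))
}

# Hand-built truth table: one row per gene x dap with explicit maternal
# fractions and expression trajectories, for targeted recovery tests.
make_truth <- function(genes, daps = c(11, 14, 17, 21)) {
  rows <- lapply(names(genes), function(g) {
    gs <- genes[[g]]
    tibble::tibble(
      gene = g,
      class = gs$class %||% "biparental",
      dap = daps,
      maternal_fraction = rep_len(gs$mf, length(daps)),
      base_rpm = rep_len(gs$rpm, length(daps)),
      genotypes = gs$genotypes %||% "B73,W22"
    )
  })
  dplyr::bind_rows(rows)
}

# Build an imprint_profile-shaped tibble directly from status/rpm (and
# optionally rer) vectors, one gene per list element.
make_profile <- function(genes, daps = c(11, 14, 17, 21)) {
  rows <- lapply(names(genes), function(g) {
    gs <- genes[[g]]
    tibble::tibble(
      gene_id = paste0("B73:", g), genome = "B73", gene = g,
      dap = daps,
      status = gs$status,
      mean_rpm = rep_len(gs$rpm, length(daps)),
      rer = rep_len(gs$rer %||% NA_real_, length(daps)),
      padj = rep_len(gs$padj %||% NA_real_, length(daps))
    )
  })
  dplyr::bind_rows(rows)
}

# Four separable trajectory archetypes over the standard time points.
archetypes <- list(
  early = c(1, 0.5, 0.2, 0.1),
  mid = c(0.2, 1, 0.4, 0.2),
  late = c(0.1, 0.3, 0.6, 1),
  peak17 = c(0.1, 0.2, 1, 0.3)
)

planted_traj <- function(n_per = 50, noise = 0.02, seed = 26) {
  withr::with_seed(seed, {
    rows <- purrr::imap_dfr(archetypes, function(shape, nm) {
      tibble::tibble(
        gene = sprintf("%s_%02d", nm, rep(seq_len(n_per), each = 4)),
        dap = rep(c(11, 14, 17, 21), n_per),
        mean_rpm = pmax(rep(shape, n_per) + rnorm(4 * n_per, 0, noise), 0)
      )
    })
  })
  rows
}

# Long count tibble for one cross direction with per-dap Poisson means;
# `means` is a named list gene -> vector of per-dap expected counts.
make_direction_counts <- function(means, daps = c(11, 14, 17, 21),
                                  reps = 3, seed = 1,
                                  maternal = "B73", paternal = "W22") {
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(gene = names(means), dap = daps,
                               replicate = seq_len(reps))
    grid$mu <- vapply(seq_len(nrow(grid)), function(i) {
      means[[grid$gene[i]]][match(grid$dap[i], daps)]
    }, numeric(1))
    grid$count <- rpois(nrow(grid), grid$mu)
    tibble::tibble(
      gene_id = paste0(maternal, ":", grid$gene),
      genome = maternal, gene = grid$gene,
      sample_id = sprintf("%sx%s_%02d_r%d", maternal, paternal,
                          grid$dap, grid$replicate),
      maternal = maternal, paternal = paternal,
      dap = grid$dap, replicate = grid$replicate,
      count = as.integer(grid$count)
    )
  })
}
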