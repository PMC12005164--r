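thr <- imprint_thresholds()

# Convenience: construct a genotype table row block for one gene.
gt_rows <- function(gene, genotypes, expressed, bias) {
  tibble::tibble(
    b73_gene_id = gene, genotype = genotypes,
    maternal_rpm = 10, paternal_rpm = 5, rer = NA_real_, padj = NA_real_,
    expressed = expressed, bias_status = bias, imprint_status = "none"
  )
}

test_that("genotype tables join panel calls through single-copy syntelogs", {
  base <- sim_config(
    n_genes = c(MEG_constitutive = 15, biparental = 40),
    seed = 23, pav_rate = 0,
    genotypes = c("B73", "W22", "Ki11")
  )
  truth <- simulate_experiment(base)$truth
  panel <- simulate_genotype_panel(truth, base, c("W22", "Ki11"), dap = 14,
                                   maintain_prob = 1)
  syn <- simulate_syntelogs(truth, c("W22", "Ki11"), dropout_rate = 0,
                            seed = 24)
  tab <- build_genotype_table(panel, syn, thr)
  n_genes <- length(unique(truth$gene))
  expect_equal(nrow(tab), n_genes * 2)

  # dropping a gene from one genotype's syntelogs removes just that row
  drop_gene <- tab$b73_gene_id[1]
  syn2 <- syn[!(syn$b73_gene_id == drop_gene & syn$genotype == "W22"), ]
  tab2 <- build_genotype_table(panel, syn2, thr)
  expect_equal(nrow(tab2), n_genes * 2 - 1)
  expect_false(any(tab2$b73_gene_id == drop_gene & tab2$genotype == "W22"))

  # a fully maintained constitutive MEG is maternally biased in all genotypes
  megs <- tab[grepl("megc_", tab$b73_gene_id), ]
  per_gene <- tapply(megs$bias_status == "maternal", megs$b73_gene_id, all)
  expect_gte(mean(per_gene), 0.9)

  # a one-direction experiment is rejected
  half <- panel
  half$W22 <- half$W22[half$W22$maternal == "B73", ]
  expect_error(build_genotype_table(half, syn, thr), "reciprocal")
})

test_that("percent-same-imprint is exact arithmetic on constructed tables", {
  tab <- dplyr::bind_rows(
    gt_rows("gA", paste0("gt", 1:8), expressed = TRUE,
            bias = c(rep("maternal", 6), rep("none", 2))),
    gt_rows("gB", paste0("gt", 1:4), expressed = TRUE, bias = "none"),
    gt_rows("gC", paste0("gt", 1:5),
            expressed = c(TRUE, TRUE, TRUE, FALSE, FALSE),
            bias = c("paternal", "paternal", "none", "paternal", "none"))
  )
  ref <- tibble::tibble(b73_gene_id = c("gA", "gB", "gC"),
                        direction = c("MEG", "MEG", "PEG"))
  sc <- percent_same_imprint(tab, ref)
  expect_equal(sc$percent_same_imprint[sc$b73_gene_id == "gA"], 6 / 8)
  expect_equal(sc$percent_same_imprint[sc$b73_gene_id == "gB"], 0)
  # unexpressed genotypes drop out of both numerator and denominator
  expect_equal(sc$n_genotypes_expressed[sc$b73_gene_id == "gC"], 3)
  expect_equal(sc$percent_same_imprint[sc$b73_gene_id == "gC"], 2 / 3)
  expect_true(all(sc$percent_same_imprint >= 0 & sc$percent_same_imprint <= 1))

  # invariant under genotype reordering
  sc2 <- percent_same_imprint(tab[sample(nrow(tab)), ], ref)
  expect_equal(dplyr::arrange(sc2, b73_gene_id), dplyr::arrange(sc, b73_gene_id))
})

test_that("group-wise conservation respects the 4-genotype floor and ordering", {
  mk <- function(gene, n_expr, n_bias) {
    gt_rows(gene, paste0("gt", seq_len(n_expr)), TRUE,
            c(rep("maternal", n_bias), rep("none", n_expr - n_bias)))
  }
  tab <- dplyr::bind_rows(
    mk("a1", 8, 8), mk("a2", 8, 7),   # group 1: high conservation
    mk("b1", 8, 6), mk("b2", 8, 5),   # group 2
    mk("c1", 8, 4), mk("c2", 8, 3),   # group 3
    mk("d1", 8, 1), mk("d2", 8, 0),   # group 4
    mk("e1", 3, 3)                    # expressed in only 3 genotypes
  )
  genes <- c("a1", "a2", "b1", "b2", "c1", "c2", "d1", "d2", "e1")
  ref <- tibble::tibble(b73_gene_id = genes, direction = "MEG")
  groups <- tibble::tibble(
    b73_gene_id = genes,
    group = c("1", "1", "2", "2", "3", "3", "4", "4", "1")
  )
  sc <- percent_same_imprint(tab, ref)
  cons <- conservation_by_group(sc, groups, min_genotypes = 4)
  expect_false("e1" %in% cons$genes$b73_gene_id)
  means <- setNames(cons$summary$mean_percent, cons$summary$group)
  expect_true(means[["1"]] > means[["2"]])
  expect_true(means[["2"]] > means[["3"]])
  expect_true(means[["3"]] > means[["4"]])
})

test_that("panel counts agree with an independent recount", {
  withr::local_seed(25)
  tab <- tibble::tibble(
    b73_gene_id = rep(sprintf("g%02d", 1:30), 3),
    genotype = rep(c("W22", "Ki11", "Oh43"), each = 30),
    maternal_rpm = 1, paternal_rpm = 1,
    rer = runif(90), padj = runif(90),
    expressed = runif(90) > 0.2,
    bias_status = sample(c("maternal", "paternal", "none"), 90, TRUE),
    imprint_status = sample(c("MEG", "PEG", "none"), 90, TRUE,
                            prob = c(0.2, 0.2, 0.6))
  )
  got <- panel_counts(tab)
  for (g in unique(tab$genotype)) {
    sub <- tab[tab$genotype == g, ]
    expect_equal(got$n_meg[got$genotype == g], sum(sub$imprint_status == "MEG"))
    expect_equal(got$n_maternal_bias[got$genotype == g],
                 sum(sub$expressed & sub$bias_status == "maternal"))
  }

  pure_bip <- dplyr::mutate(tab, imprint_status = "none", bias_status = "none")
  got2 <- panel_counts(pure_bip)
  expect_true(all(got2$n_meg == 0 & got2$n_peg == 0))
})
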