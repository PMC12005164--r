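thr <- imprint_thresholds()

test_that("the four archetype profiles land in their groups", {
  prof <- make_profile(list(
    g1 = list(status = rep("MEG", 4), rpm = c(5, 8, 9, 4)),
    g2 = list(status = c("not_expressed", "MEG", "MEG", "not_expressed"),
              rpm = c(0.2, 6, 7, 0.3)),
    g3 = list(status = c("MEG", "maternal_bias", "maternal_bias",
                         "maternal_bias"), rpm = c(3, 3, 3, 3)),
    g4 = list(status = c("MEG", "MEG", "biparental", "biparental"),
              rpm = c(6, 7, 8, 9)),
    g4_low = list(status = c("MEG", "MEG", "biparental", "biparental"),
                  rpm = c(2, 3, 4, 3)),
    filtered = list(status = c("MEG", "not_expressed", "not_expressed",
                               "not_expressed"), rpm = c(0.9, 0.1, 0.2, 0.1))
  ))
  out <- assign_groups(prof, thr)
  got <- setNames(out$group, out$gene)
  expect_equal(got[["g1"]], "1")
  expect_equal(got[["g2"]], "2")
  expect_equal(got[["g3"]], "3")
  expect_equal(got[["g4"]], "4")
  expect_equal(got[["g4_low"]], "unassigned")
  expect_equal(got[["filtered"]], "filtered_low_expression")
})

test_that("never-imprinted genes are dropped, or rejected when strict", {
  prof <- make_profile(list(
    ok = list(status = rep("MEG", 4), rpm = rep(5, 4)),
    never = list(status = rep("biparental", 4), rpm = rep(5, 4))
  ))
  expect_message(out <- assign_groups(prof, thr), "1 gene")
  expect_equal(out$gene, "ok")
  expect_error(assign_groups(prof, thr, strict = TRUE), "pre-filter")
})

test_that("group rules agree with the scalar oracle on random profiles", {
  withr::local_seed(18)
  statuses <- c("MEG", "PEG", "maternal_bias", "paternal_bias",
                "biparental", "not_expressed")
  rpm_levels <- c(0.4, 2.5, 8)
  genes <- list()
  for (i in 1:400) {
    s <- sample(statuses, 4, replace = TRUE)
    if (!any(s %in% c("MEG", "PEG"))) s[sample(4, 1)] <- sample(c("MEG", "PEG"), 1)
    genes[[sprintf("r%03d", i)]] <-
      list(status = s, rpm = sample(rpm_levels, 4, replace = TRUE))
  }
  prof <- make_profile(genes)
  out <- assign_groups(prof, thr)
  want <- vapply(genes[out$gene], function(g) {
    assign_group_oracle(g$status, g$rpm)
  }, character(1))
  expect_equal(setNames(out$group, out$gene), want)
})

test_that("groups partition: Group 1 implies all-dap imprinting, disjoint labels", {
  withr::local_seed(19)
  sim <- small_sim(seed = 19)$sim
  prof <- imprint_profile(rpm_normalize(sim$counts),
                          test_imprinting(sim$counts))
  out <- suppressMessages(assign_groups(prof, thr))
  expect_equal(anyDuplicated(out$gene_id), 0)
  g1 <- out$gene_id[out$group == "1"]
  per_gene <- prof |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(all_imp = all(status %in% c("MEG", "PEG")))
  expect_true(all(per_gene$all_imp[per_gene$gene_id %in% g1]))
})

test_that("bias-consistency counts match a hand-rolled recount", {
  # constructed saturation: every multi-dap MEG biased at all four daps
  sat <- make_profile(list(
    m1 = list(status = c("MEG", "MEG", "maternal_bias", "maternal_bias"),
              rpm = rep(10, 4), rer = c(0.95, 0.93, 0.85, 0.82)),
    m2 = list(status = c("MEG", "MEG", "MEG", "MEG"),
              rpm = rep(10, 4), rer = c(0.95, 0.96, 0.97, 0.98)),
    s1 = list(status = c("MEG", "biparental", "biparental", "biparental"),
              rpm = rep(10, 4), rer = c(0.95, 0.7, 0.6, 0.5))
  ))
  tab <- bias_consistency(sat, thr)
  multi <- tab[tab$multiplicity == "multiple", ]
  expect_equal(multi$n_bias_met, 4)
  expect_equal(multi$fraction, 1)
  single <- tab[tab$multiplicity == "single", ]
  expect_equal(single$n_bias_met, 1)

  # random cohort vs the oracle
  withr::local_seed(20)
  genes <- list()
  for (i in 1:120) {
    s <- sample(c("MEG", "PEG", "maternal_bias", "biparental"), 4,
                replace = TRUE, prob = c(0.3, 0.3, 0.2, 0.2))
    genes[[sprintf("b%03d", i)]] <- list(
      status = s, rpm = rep(10, 4), rer = runif(4)
    )
  }
  prof <- make_profile(genes)
  got <- bias_consistency(prof, thr)
  oracle <- bias_consistency_oracle(prof, thr)
  want <- dplyr::count(oracle, direction, multiplicity, n_bias_met,
                       name = "n_genes")
  expect_equal(as.data.frame(got[, names(want)]),
               as.data.frame(dplyr::arrange(want, direction, multiplicity,
                                            n_bias_met)))
})

test_that("each simulated archetype maps to its group under strong effects", {
  cfg <- sim_config(
    n_genes = c(MEG_constitutive = 40, MEG_transient = 40,
                maternal_bias = 60, paternal_bias = 60, biparental = 60),
    nb_dispersion = 0.01, seed = 77, pav_rate = 0
  )
  sim <- simulate_experiment(cfg)
  prof <- imprint_profile(rpm_normalize(sim$counts),
                          test_imprinting(sim$counts))
  out <- suppressMessages(assign_groups(prof, thr))
  cls <- sim$truth[!duplicated(sim$truth$gene), c("gene", "class")]
  m <- dplyr::inner_join(out, cls, by = "gene")
  acc <- function(class, grp) mean(m$group[m$class %in% class] == grp)
  expect_gte(acc("MEG_constitutive", "1"), 0.9)
  expect_gte(acc("MEG_transient", "4"), 0.9)
  expect_gte(acc(c("maternal_bias", "paternal_bias"), "3"), 0.9)
})

test_that("group summaries tally counts and percentages", {
  prof <- make_profile(setNames(lapply(1:10, function(i) {
    list(status = rep("MEG", 4), rpm = rep(6, 4))
  }), paste0("m", 1:10)))
  out <- assign_groups(prof, thr)
  summ <- group_summary(out)
  expect_equal(summ$n[summ$direction == "MEG" & summ$group == "1"], 10)
  expect_equal(summ$percent[summ$direction == "MEG" & summ$group == "1"], 100)

  empty <- out[0, ]
  expect_equal(nrow(group_summary(empty)), 0)
})
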