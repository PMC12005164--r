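test_that("method-of-moments dispersion recovers known noise regimes", {
  withr::local_seed(5)
  n <- 1000
  # Poisson: var = mean, alpha ~ 0
  pois <- matrix(rpois(200 * n, 50), nrow = 200)
  a_pois <- dispersion_mom(pois, group = rep("A", n))
  expect_lt(median(a_pois), 0.005)

  # NB with alpha = 2: var = mean + 2 mean^2
  nb <- matrix(rnbinom(200 * n, mu = 50, size = 1 / 2), nrow = 200)
  a_nb <- dispersion_mom(nb, group = rep("A", n))
  expect_lt(abs(median(a_nb) - 2) / 2, 0.15)

  # constant counts: variance 0, floored at 0
  const <- matrix(7, nrow = 3, ncol = 4)
  expect_equal(dispersion_mom(const, rep("A", 4)), rep(0, 3))
})

test_that("shrunk dispersions are floored and all-zero genes flagged", {
  withr::local_seed(6)
  m <- rbind(matrix(rnbinom(50 * 6, mu = 100, size = 10), ncol = 6),
             rep(0, 6))
  est <- estimate_dispersion(m, group = rep(c("A", "B"), each = 3))
  expect_true(all(est$dispersion[!est$untestable] >= 1e-8))
  expect_true(est$untestable[51])
  expect_true(is.na(est$dispersion[51]))
})

test_that("bh_adjust matches hand-computed and brute-force step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.1, NaN)), "NaN")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")

  withr::local_seed(7)
  for (i in 1:25) {
    p <- runif(sample(1:100, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_bruteforce(p))
  }
})

test_that("the threshold Wald test behaves at the null and under strong effects", {
  withr::local_seed(8)
  # identical counts in both groups: lfc ~ 0, never significant
  k <- matrix(rnbinom(100 * 3, mu = 300, size = 20), ncol = 3)
  same <- cbind(k, k)
  res <- test_fold_change(same, 1:3, 4:6, size_factors = rep(1, 6))
  expect_true(all(abs(res$log2fc) < 0.01))
  expect_false(any(res$significant))

  # 8x maternal excess, tight dispersion, n = 3 vs 3: significant
  strong <- cbind(matrix(rnbinom(200 * 3, mu = 2400, size = 50), ncol = 3),
                  matrix(rnbinom(200 * 3, mu = 300, size = 50), ncol = 3))
  res2 <- test_fold_change(strong, 1:3, 4:6, size_factors = rep(1, 6))
  expect_gte(mean(res2$significant), 0.9)
  expect_lt(abs(median(res2$log2fc) - 3), 0.2)
})

test_that("swapping contrast groups negates log2fc and preserves p-values", {
  withr::local_seed(9)
  m <- cbind(matrix(rnbinom(150 * 3, mu = 800, size = 8), ncol = 3),
             matrix(rnbinom(150 * 3, mu = 150, size = 8), ncol = 3))
  ab <- test_fold_change(m, 1:3, 4:6, size_factors = rep(1, 6))
  ba <- test_fold_change(m, 4:6, 1:3, size_factors = rep(1, 6))
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$pvalue, ba$pvalue)
})

test_that("power rises with effect size and replicate number", {
  withr::local_seed(10)
  power_at <- function(fold, reps) {
    m <- cbind(matrix(rnbinom(300 * reps, mu = 500 * fold, size = 1 / 0.05),
                      ncol = reps),
               matrix(rnbinom(300 * reps, mu = 500, size = 1 / 0.05),
                      ncol = reps))
    mean(test_fold_change(m, seq_len(reps), reps + seq_len(reps),
                          size_factors = rep(1, 2 * reps))$significant)
  }
  p4 <- power_at(4, 3); p8 <- power_at(8, 3); p16 <- power_at(16, 3)
  expect_true(p4 <= p8 + 0.05 && p8 <= p16 + 0.05)
  expect_gte(power_at(8, 6), p8 - 0.05)
})

test_that("time-course DE recovers planted induction patterns", {
  counts <- make_direction_counts(list(
    flat = c(500, 500, 500, 500),
    induced_all = c(500, 2000, 2000, 2000),
    induced_17 = c(500, 500, 2100, 500),
    repressed_all = c(2000, 450, 450, 450)
  ), seed = 12)
  de <- de_vs_baseline(counts, direction = "B73", baseline_dap = 11)
  expect_equal(nrow(de), 4 * 3)
  expect_true(all(is.na(de$sign[de$gene == "flat"])))
  expect_equal(sum(de$sign[de$gene == "induced_all"] == "up", na.rm = TRUE), 3)
  hits17 <- de[de$gene == "induced_17" & !is.na(de$sign), ]
  expect_equal(hits17$contrast, "17_vs_11")

  ov <- de_overlap(de)
  expect_equal(ov$n_genes[ov$sign == "up" & ov$n_contrasts == 3], 1)
  expect_equal(ov$n_genes[ov$sign == "up" & ov$n_contrasts == 1], 1)
  expect_equal(ov$n_genes[ov$sign == "down" & ov$n_contrasts == 3], 1)

  expect_error(de_vs_baseline(counts, direction = "W22"), "W22")
  expect_error(de_vs_baseline(counts, direction = "B73", baseline_dap = 9),
               "baseline")
})
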