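# Independent brute-force oracles, coded directly from the rule definitions
# and kept deliberately naive (scalar loops, no shared code with the package
# implementation).

# Step-up FDR adjustment by direct enumeration: for each p, the minimum over
# all p' >= p of n * p' / rank(p').
bh_bruteforce <- function(p) {
  n <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(n * ranked[i:n] / (i:n)))
  }
  out <- numeric(n)
  out[ord] <- adj
  out
}

# Scalar status rule table (mirrors the published decision rules, written
# as an explicit branch enumeration).
call_status_oracle <- function(rer, padj, mean_rpm, thr) {
  if (mean_rpm < thr$expr_min) return("not_expressed")
  if (is.na(rer)) return("not_expressed")
  sig <- !is.na(padj) && padj < thr$alpha
  if (sig && rer >= thr$meg_rer) return("MEG")
  if (sig && rer <= thr$peg_rer) return("PEG")
  if (rer > thr$maternal_bias_rer) return("maternal_bias")
  if (rer < thr$paternal_bias_rer) return("paternal_bias")
  "biparental"
}

# Scalar temporal-group rule evaluator over one gene's status and RPM
# vectors (ordered by time point). Precedence: low-expression filter, then
# Groups 1 -> 2 -> 3 -> 4, else unassigned. Genes imprinted in both
# directions ("mixed") skip Groups 1-3 and have no same-direction bias.
assign_group_oracle <- function(status, rpm, expr_min = 1, strict_rpm = 5) {
  n_meg <- sum(status == "MEG")
  n_peg <- sum(status == "PEG")
  stopifnot(n_meg + n_peg > 0)
  dir <- if (n_meg > 0 && n_peg > 0) "mixed" else if (n_meg > 0) "MEG" else "PEG"

  if (mean(rpm) < expr_min) return("filtered_low_expression")

  if (dir != "mixed") {
    bias_lab <- if (dir == "MEG") "maternal_bias" else "paternal_bias"
    imprinted <- status == dir
    same_bias <- status == bias_lab
    all_expressed <- TRUE
    for (r in rpm) if (r < expr_min) all_expressed <- FALSE
    if (all_expressed && all(imprinted)) return("1")
    ok2 <- TRUE
    for (i in seq_along(status)) {
      if (rpm[i] >= expr_min && !imprinted[i]) ok2 <- FALSE
    }
    if (ok2) return("2")
    ok3 <- TRUE
    for (i in seq_along(status)) {
      if (!imprinted[i] && !same_bias[i]) ok3 <- FALSE
    }
    if (ok3) return("3")
  } else {
    imprinted <- status %in% c("MEG", "PEG")
    same_bias <- rep(FALSE, length(status))
  }
  if (all(rpm >= strict_rpm) && any(!imprinted & !same_bias)) return("4")
  "unassigned"
}

# Hand-rolled recount of the bias-consistency cross-tabulation.
bias_consistency_oracle <- function(profile, thr) {
  genes <- unique(profile$gene_id)
  rows <- list()
  for (g in genes) {
    sub <- profile[profile$gene_id == g, ]
    n_meg <- sum(sub$status == "MEG")
    n_peg <- sum(sub$status == "PEG")
    if (n_meg + n_peg == 0 || (n_meg > 0 && n_peg > 0)) next
    dir <- if (n_meg > 0) "MEG" else "PEG"
    n_imp <- max(n_meg, n_peg)
    met <- if (dir == "MEG") {
      sum(sub$rer > thr$maternal_bias_rer, na.rm = TRUE)
    } else {
      sum(sub$rer < thr$paternal_bias_rer, na.rm = TRUE)
    }
    rows[[g]] <- data.frame(
      direction = dir,
      multiplicity = if (n_imp > 1) "multiple" else "single",
      n_bias_met = met
    )
  }
  do.call(rbind, rows)
}

# Adjusted Rand index between two labelings (contingency-table formula).
adjusted_rand <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
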