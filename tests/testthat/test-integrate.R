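test_that("condition means average detected replicates only", {
  cmap <- c(p1 = "parental", p2 = "parental", p3 = "parental",
            r1 = "res1", r2 = "res1", r3 = "res1")
  m <- rbind(fA = c(1, 2, 3, 4, 5, 6), fB = c(2, NA, 4, 1, 1, NA))
  colnames(m) <- names(cmap)
  cm <- condition_means(m, cmap)
  expect_equal(cm["fA", "parental"], 2)
  expect_equal(cm["fA", "res1"], 5)
  expect_equal(cm["fB", "parental"], 3)  # mean of the two detected
  expect_equal(cm["fB", "res1"], 1)
  # a condition with < 2 detected replicates is marked missing
  m2 <- m
  m2["fB", c("r1", "r2")] <- NA
  cm2 <- condition_means(m2, cmap)
  expect_true(is.na(cm2["fB", "res1"]))
  expect_identical(attr(cm2, "complete"), c(TRUE, FALSE))
  # matches direct recomputation on simulated data
  cfg <- sim_config(n_mirnas = 10, n_genes = 10, n_edges = 5, seed = 6)
  sim <- simulate_expression(simulate_truth(cfg), cfg)
  cm3 <- condition_means(sim$cp, sim$condition_map)
  for (cond in unique(sim$condition_map)) {
    cols <- names(sim$condition_map)[sim$condition_map == cond]
    expect_equal(unname(cm3[, cond]), unname(rowMeans(sim$cp[, cols])))
  }
})

test_that("negated correlation encodes inverse abundance-expression evidence", {
  conds <- c("parental", "res1", "res2", "res3")
  cpm <- matrix(c(25, 27, 24, 26), 1, 4, dimnames = list("m1", conds))
  # gene means numerically identical to the Cp means: entry -1
  # (high Cp = low abundance tracking high expression = inverse regulation)
  gm <- matrix(c(25, 27, 24, 26, 5, 3, 6, 4, 7, 7, 7, 7), 3, 4,
               byrow = TRUE, dimnames = list(c("g_same", "g_neg", "g_flat"),
                                             conds))
  r <- correlate(cpm, gm)
  expect_equal(r["m1", "g_same"], -1)
  expect_equal(r["m1", "g_neg"], 1)
  expect_true(is.na(r["m1", "g_flat"]))  # zero variance: undefined
  expect_equal(attr(r, "n_undefined"), 1L)
  expect_error(correlate(cpm[, 1:2, drop = FALSE], gm[, 1:2, drop = FALSE]),
               ">= 3")
})

test_that("functional-target inference applies inclusive threshold gates", {
  corr <- matrix(c(-0.95, -0.79, -0.85, -0.80), 2, 2, byrow = TRUE,
                 dimnames = list(c("m1", "m2"), c("g1", "g2")))
  pred <- data.frame(
    mirna = c("m1", "m1", "m2", "m2", "m2", "m1"),
    gene = c("g1", "g2", "g1", "g1", "g2", "g2"),
    predictor = c("A", "A", "A", "B", "A", "B"),
    stringsAsFactors = FALSE)
  fts <- infer_functional_targets(corr, pred)
  # m1-g1: r -0.95 but support 1 -> excluded
  # m1-g2: r -0.79 -> excluded (strict -0.8 boundary)
  # m2-g1: r -0.85, support 2 -> kept
  # m2-g2: r -0.80 (inclusive) but support 1 -> excluded
  expect_equal(nrow(fts), 1)
  expect_equal(fts$mirna, "m2")
  expect_equal(fts$gene, "g1")
  expect_equal(fts$support, 2L)

  # boundary inclusivity of r at support 2
  pred2 <- rbind(pred, data.frame(mirna = "m2", gene = "g2", predictor = "B"))
  fts2 <- infer_functional_targets(corr, pred2)
  expect_true(any(fts2$mirna == "m2" & fts2$gene == "g2"))

  # monotone filters: tightening thresholds never adds pairs
  set.seed(4)
  corr_big <- matrix(runif(100, -1, 1), 10, 10,
                     dimnames = list(paste0("m", 1:10), paste0("g", 1:10)))
  pred_big <- expand.grid(mirna = paste0("m", 1:10), gene = paste0("g", 1:10),
                          predictor = c("A", "B", "C"),
                          stringsAsFactors = FALSE)
  pred_big <- pred_big[runif(nrow(pred_big)) < 0.5, ]
  base_keys <- with(infer_functional_targets(corr_big, pred_big, -0.5, 1),
                    paste(mirna, gene))
  for (thr in c(-0.6, -0.8, -0.9)) {
    k <- with(infer_functional_targets(corr_big, pred_big, thr, 1),
              paste(mirna, gene))
    expect_true(all(k %in% base_keys))
  }
  for (ms in 2:3) {
    k <- with(infer_functional_targets(corr_big, pred_big, -0.5, ms),
              paste(mirna, gene))
    expect_true(all(k %in% base_keys))
  }
})

test_that("regulation coverage counts accounted-for DE genes", {
  fts <- data.frame(mirna = c("m1", "m1", "m2"),
                    gene = c("g1", "g2", "g3"),
                    r = c(-0.9, -0.85, -0.95), support = c(2L, 3L, 2L),
                    stringsAsFactors = FALSE)
  universe <- paste0("g", 1:10)
  # all DE genes targeted by DE miRNAs
  cov1 <- regulation_coverage(c("g1", "g2"), fts, c("m1", "m2"), universe)
  expect_equal(cov1$fraction, 1)
  # no DE miRNAs: nothing is accounted for
  cov0 <- regulation_coverage(c("g1", "g2"), fts, character(), universe)
  expect_equal(cov0$fraction, 0)
  # empty DE gene set: undefined
  expect_true(is.na(regulation_coverage(character(), fts, "m1",
                                        universe)$fraction))
  # 3 of 5 DE genes are targets of DE miRNAs: fraction 0.6, table checks out
  cov <- regulation_coverage(paste0("g", 1:5), fts, c("m1", "m2"), universe)
  expect_equal(cov$fraction, 0.6)
  expect_equal(unname(cov$table["DE", "targeted"]), 3)
  expect_equal(unname(cov$table["DE", "notTargeted"]), 2)
  expect_equal(unname(cov$table["notDE", "targeted"]), 0)
  expect_equal(unname(cov$table["notDE", "notTargeted"]), 5)
  expect_equal(sum(cov$table), length(universe))
})

test_that("negated Cp correlation agrees with abundance correlation", {
  cfg <- sim_config(n_mirnas = 8, n_genes = 20, n_edges = 8,
                    cp_bias_amplitude = 0, seed = 9)
  sim <- simulate_expression(simulate_truth(cfg), cfg)
  mm_cp <- condition_means(sim$cp, sim$condition_map)
  mm_ab <- condition_means(sim$abundance, sim$condition_map)
  gm <- condition_means(sim$expr, sim$condition_map)
  r_cp <- correlate(mm_cp, gm)
  r_ab <- stats::cor(t(mm_ab), t(gm))
  # with an affine Cp map (no bias), negated Cp correlation equals the
  # abundance-expression correlation up to replicate noise
  expect_lt(max(abs(r_cp - r_ab), na.rm = TRUE), 0.2)
})
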