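test_that("simulation is deterministic and respects requested sizes", {
  cfg <- sim_config(n_mirnas = 30, n_genes = 200, n_edges = 150, seed = 1)
  tr_a <- simulate_truth(cfg)
  tr_b <- simulate_truth(cfg)
  expect_identical(tr_a, tr_b)
  s1 <- simulate_expression(tr_a, cfg)
  s2 <- simulate_expression(tr_b, cfg)
  expect_identical(s1$cp, s2$cp)
  expect_identical(s1$expr, s2$expr)
  p1 <- simulate_predictions(tr_a, cfg)
  expect_identical(p1, simulate_predictions(tr_b, cfg))

  # edge density 150 / (30 * 200), edges are distinct pairs
  expect_equal(nrow(tr_a$edges), 150)
  expect_equal(nrow(unique(tr_a$edges[, c("mirna", "gene")])), 150)
  expect_true(all(tr_a$edges$strength > 0))
  expect_true(all(tr_a$edges$mirna %in% tr_a$mirna_ids))
  expect_true(all(tr_a$edges$gene %in% tr_a$gene_ids))
  # both shift signs represented
  expect_true(any(tr_a$shifts > 0) && any(tr_a$shifts < 0))
})

test_that("degenerate truth configurations behave as declared", {
  cfg0 <- sim_config(n_edges = 0, seed = 1)
  expect_equal(nrow(simulate_truth(cfg0)$edges), 0)
  cfg_over <- sim_config(n_mirnas = 3, n_genes = 4, n_edges = 13, seed = 1)
  expect_error(simulate_truth(cfg_over), "12")
})

test_that("Cp is anti-monotone in abundance and inverse coupling is planted", {
  # zero noise, zero bias, one strong edge: negated Cp-expression
  # correlation over condition means is <= -0.99
  cfg <- sim_config(n_mirnas = 5, n_genes = 10, n_edges = 1,
                    cp_noise_sd = 0, expr_noise_sd = 0,
                    cp_bias_amplitude = 0,
                    edge_strength_range = c(1, 1), seed = 7)
  truth <- simulate_truth(cfg)
  sim <- simulate_expression(truth, cfg)
  # anti-monotone: within each sample Cp ranks reverse abundance ranks
  for (j in seq_len(ncol(sim$cp)))
    expect_equal(rank(sim$cp[, j]), rank(-sim$abundance[, j]))
  mm <- condition_means(sim$cp, sim$condition_map)
  gm <- condition_means(sim$expr, sim$condition_map)
  e <- truth$edges
  r <- -stats::cor(mm[e$mirna[1], ], gm[e$gene[1], ])
  expect_lte(r, -0.99)
})

test_that("null network yields near-zero planted correlations on average", {
  cfg <- sim_config(n_mirnas = 10, n_genes = 30, n_edges = 0, seed = 3)
  sim <- simulate_expression(simulate_truth(cfg), cfg)
  mm <- condition_means(sim$cp, sim$condition_map)
  gm <- condition_means(sim$expr, sim$condition_map)
  r <- correlate(mm, gm)
  expect_lt(abs(mean(r, na.rm = TRUE)), 0.15)
})

test_that("prediction tables honour support contracts", {
  cfg <- sim_config(seed = 2)
  truth <- simulate_truth(cfg)
  pred <- simulate_predictions(truth, cfg)
  expect_false(any(duplicated(pred)))
  supp <- prediction_support(pred)
  expect_true(all(supp$support <= cfg$n_predictors))
  # every true edge supported by >= 2 distinct predictors
  key <- paste(supp$mirna, supp$gene)
  ekey <- paste(truth$edges$mirna, truth$edges$gene)
  expect_true(all(ekey %in% key))
  expect_true(all(supp$support[match(ekey, key)] >= 2))

  # decoy rate 0: pair set equals the truth edge set
  cfg0 <- sim_config(decoy_rate = 0, seed = 2)
  truth0 <- simulate_truth(cfg0)
  pred0 <- simulate_predictions(truth0, cfg0)
  expect_setequal(unique(paste(pred0$mirna, pred0$gene)),
                  paste(truth0$edges$mirna, truth0$edges$gene))
})

test_that("simulated reads follow the abundance multinomial", {
  cfg <- sim_config(n_mirnas = 6, n_reads = 10000, adapter = NULL, seed = 5)
  truth <- simulate_truth(cfg)
  ref <- simulate_reference(truth, cfg)
  out <- simulate_reads(truth, ref, cfg)
  # no adapter, no errors: every read equals a reference sequence exactly
  expect_true(all(out$reads$sequence %in% ref))
  expect_equal(sum(out$counts), 10000)
  # empirical proportions within 3 sigma of the multinomial expectation
  prob <- 2^truth$baseline_log2 / sum(2^truth$baseline_log2)
  sigma <- sqrt(prob * (1 - prob) * 10000)
  expect_true(all(abs(out$counts - 10000 * prob) <= 3 * sigma + 1))

  # concentrated abundance: all reads from the abundant miRNA
  out1 <- simulate_reads(truth, ref, cfg,
                         abundance = stats::setNames(
                           c(100, rep(0, 5)), names(ref)))
  expect_true(all(out1$reads$sequence == ref[[1]]))
  expect_error(simulate_reads(truth, character(), cfg), "empty")
})

test_that("cohort labels follow the logistic model", {
  cfg <- sim_config(cohort_sizes = c(52, 60, 40), seed = 11)
  cohorts <- simulate_cohorts(cfg)
  expect_length(cohorts, 3)
  expect_equal(vapply(cohorts, function(co) nrow(co$x), 0), c(52, 60, 40))
  # label counts within the binomial 95% band of the design prevalences
  prev <- c(0.5, 0.5, 0.475)
  for (k in 1:3) {
    n <- nrow(cohorts[[k]]$x)
    lo <- stats::qbinom(0.025, n, prev[k])
    hi <- stats::qbinom(0.975, n, prev[k])
    expect_gte(sum(cohorts[[k]]$label), lo)
    expect_lte(sum(cohorts[[k]]$label), hi)
  }

  # strong single-marker effect: training AUC > 0.8 at n = 500
  cfg1 <- sim_config(cohort_sizes = c(500, 40), markers = c("m1", "m2"),
                     marker_beta = c(3, 0), cohort_intercepts = c(0, 0),
                     seed = 4)
  co <- simulate_cohorts(cfg1)[[1]]
  expect_gt(roc_auc(co$x[, "m1"], co$label)$auc, 0.8)

  # all-null coefficients: single-miRNA AUC near 0.5
  cfg0 <- sim_config(marker_beta = c(0, 0, 0, 0), cohort_sizes = c(400, 40),
                     seed = 6)
  co0 <- simulate_cohorts(cfg0)[[1]]
  auc0 <- roc_auc(co0$x[, cfg0$markers[1]], co0$label)$auc
  expect_lt(abs(auc0 - 0.5), 3 * 0.5 / sqrt(nrow(co0$x)))
})
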