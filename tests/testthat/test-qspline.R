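test_that("melt peak counting distinguishes products from ripple", {
  tt <- seq(65, 95, length.out = 121)
  gauss <- function(mu, h, sd = 1.2) h * exp(-(tt - mu)^2 / (2 * sd^2))
  # -dF/dT with a single bump <=> F = cumulative of a negative bump
  f_of_d <- function(d) rev(cumsum(rev(d))) # so that -diff(F) ~ d
  one <- f_of_d(gauss(80, 10))
  expect_equal(count_melt_peaks(tt, one), 1L)
  two <- f_of_d(gauss(76, 10) + gauss(84, 10))
  expect_equal(count_melt_peaks(tt, two), 2L)
  # 5%-height ripple stays below the 20% prominence threshold
  ripple <- f_of_d(gauss(80, 10) + gauss(88, 0.5))
  expect_equal(count_melt_peaks(tt, ripple), 1L)
  # but a 30%-height second product is called
  second <- f_of_d(gauss(80, 10) + gauss(88, 3))
  expect_equal(count_melt_peaks(tt, second), 2L)

  expect_error(count_melt_peaks(tt[1:10], one[1:10]), ">= 20")
  expect_error(count_melt_peaks(rev(tt), one), "increasing")

  qc <- melt_qc(list(good = data.frame(temperature = tt, fluorescence = one),
                     bad = data.frame(temperature = tt, fluorescence = two)))
  expect_identical(qc$flagged, c(FALSE, TRUE))
})

test_that("qspline offsets vanish for identical samples and recover shifts", {
  set.seed(1)
  base <- sort(runif(80, 20, 32))
  cp <- cbind(s1 = base, s2 = base, s3 = base)
  rownames(cp) <- sprintf("m%02d", 1:80)
  model <- fit_qspline(cp)
  for (j in colnames(cp))
    expect_lt(max(abs(qspline_offset(model, j, base))), 1e-6)
  expect_equal(apply_normalization(cp, model), cp, tolerance = 1e-8)

  # one sample globally shifted by +2: its offset is -2 * (m-1)/m
  m <- 4
  cp2 <- cbind(s1 = base + 2, s2 = base, s3 = base, s4 = base)
  rownames(cp2) <- rownames(cp)
  mod2 <- fit_qspline(cp2)
  off <- qspline_offset(mod2, "s1", base + 2)
  expect_equal(off, rep(-2 * (m - 1) / m, length(base)), tolerance = 1e-6)
})

test_that("normalization preserves ranks, missingness and clamps extremes", {
  cfg <- sim_config(n_mirnas = 120, n_genes = 5, n_edges = 0,
                    de_fraction = 0, seed = 4)
  sim <- simulate_expression(simulate_truth(cfg), cfg)
  cp <- sim$cp
  cp[c(3, 50), 1] <- NA
  model <- fit_qspline(cp)
  norm <- apply_normalization(cp, model)
  expect_identical(is.na(norm), is.na(cp))
  for (j in colnames(cp)) {
    ok <- !is.na(cp[, j])
    expect_equal(rank(norm[ok, j]), rank(cp[ok, j]))
  }
  # outside the fitted range: boundary offset applies
  j <- colnames(cp)[1]
  top <- max(cp[, j], na.rm = TRUE)
  expect_equal(qspline_offset(model, j, top + 5),
               qspline_offset(model, j, top))
  expect_error(fit_qspline(cp[1:10, ]), "< 30")
})

test_that("SEM reduction matches direct arithmetic and is 0 at identity", {
  cmap <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  raw <- rbind(f1 = c(20, 22, 25, 27), f2 = c(30, 31, 33, 36))
  colnames(raw) <- names(cmap)
  norm <- rbind(f1 = c(20.5, 21.5, 25.5, 26.5), f2 = c(30.2, 30.8, 34, 35))
  colnames(norm) <- names(cmap)
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  before <- mean(c(sem(raw[1, 1:2]), sem(raw[1, 3:4]),
                   sem(raw[2, 1:2]), sem(raw[2, 3:4])))
  after <- mean(c(sem(norm[1, 1:2]), sem(norm[1, 3:4]),
                  sem(norm[2, 1:2]), sem(norm[2, 3:4])))
  expect_equal(sem_reduction(raw, norm, cmap), 100 * (1 - after / before))
  expect_equal(sem_reduction(raw, raw, cmap), 0)
  expect_error(sem_reduction(raw[, 1, drop = FALSE],
                             norm[, 1, drop = FALSE], cmap[1]),
               "replicate")
})

test_that("planted smooth bias is recovered and grows SEM reduction", {
  rms_for <- function(amplitude, seed = 1) {
    cfg <- sim_config(n_mirnas = 750, n_genes = 5, n_edges = 0,
                      de_fraction = 0, cp_bias_amplitude = amplitude,
                      cp_noise_sd = 0.2, seed = seed)
    sim <- simulate_expression(simulate_truth(cfg), cfg)
    model <- fit_qspline(sim$cp)
    norm <- apply_normalization(sim$cp, model)
    rms <- vapply(colnames(sim$cp), function(j) {
      a <- model$anchors[, j]
      sqrt(mean((qspline_offset(model, j, a) -
                   planted_offset(sim, j, a))^2))
    }, numeric(1))
    list(rms = rms, sem = sem_reduction(sim$cp, norm, sim$condition_map))
  }
  strong <- rms_for(1.5)
  expect_lt(max(strong$rms), 0.1)
  expect_gt(strong$sem, 0)
  weak <- rms_for(0.5)
  expect_gt(strong$sem, weak$sem)

  # per-sample deciles match the target distribution after normalization;
  # this checks the fitted monotone map, so measurement noise (which
  # enters the empirical deciles directly and is deliberately not chased
  # by the smoothing spline) is kept moderate
  cfg <- sim_config(n_mirnas = 750, n_genes = 5, n_edges = 0,
                    de_fraction = 0, cp_bias_amplitude = 1.5,
                    cp_noise_sd = 0.1, seed = 1)
  sim <- simulate_expression(simulate_truth(cfg), cfg)
  model <- fit_qspline(sim$cp)
  norm <- apply_normalization(sim$cp, model)
  dec <- apply(norm, 2, stats::quantile, probs = seq(0.1, 0.9, 0.1))
  tgt <- stats::approx(model$probs, model$target,
                       xout = seq(0.1, 0.9, 0.1))$y
  expect_lt(max(abs(dec - tgt)), 0.05)
})

test_that("renormalizing normalized data is a near-identity", {
  cfg <- sim_config(n_mirnas = 400, n_genes = 5, n_edges = 0,
                    de_fraction = 0, cp_bias_amplitude = 1.5,
                    cp_noise_sd = 0.2, seed = 2)
  sim <- simulate_expression(simulate_truth(cfg), cfg)
  model <- fit_qspline(sim$cp)
  norm <- apply_normalization(sim$cp, model)
  m2 <- fit_qspline(norm)
  resid <- vapply(colnames(norm), function(j)
    max(abs(qspline_offset(m2, j, m2$anchors[, j]))), numeric(1))
  expect_lt(max(resid), 0.05)
})
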