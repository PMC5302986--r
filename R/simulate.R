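#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. The defaults define
#' the reference study conditions used throughout the test suite: a panel of
#' 30 miRNAs and 200 genes linked by 150 regulatory edges, profiled in one
#' parental and three resistant conditions with three biological replicates
#' each, with plate-level signal-dependent Cp bias and decoy target
#' predictions stressing the downstream filters.
#'
#' @param n_mirnas,n_genes,n_edges number of miRNAs, genes and planted
#'   regulatory edges.
#' @param n_conditions number of cell-line conditions (first is the parental
#'   reference); must be >= 4 so that correlation over condition means has
#'   enough support.
#' @param replicates biological replicates per condition.
#' @param de_fraction fraction of miRNAs given condition-specific log2
#'   abundance shifts (signs split across miRNAs).
#' @param shift_range magnitude range (log2 units) of per-condition shifts of
#'   shifted miRNAs; the lower end sits above the 0.7 candidate threshold so
#'   shifted miRNAs are discoverable.
#' @param edge_strength_range range of per-edge repression strengths
#'   (log2 expression units per log2 miRNA abundance unit).
#' @param cp_slope,cp_intercept affine map from log2 abundance to Cp:
#'   `Cp = intercept - slope * log2_abundance` (slope > 0, so abundance and
#'   Cp are anti-monotone).
#' @param cp_noise_sd,expr_noise_sd replicate-level Gaussian noise (Cp units,
#'   log2 expression units).
#' @param cp_bias_amplitude scale (Cp units) of the smooth per-sample
#'   signal-dependent Cp bias (0 disables it).
#' @param decoy_rate fraction of non-edge miRNA-gene pairs that receive decoy
#'   target predictions.
#' @param decoy_support_prob geometric success probability for decoy support
#'   counts; most decoys get support 1 (below the >=2 gate), some pass it.
#' @param n_predictors number of emulated target-prediction tools.
#' @param predictors names of the emulated tools.
#' @param n_reads reads to draw in [simulate_reads()].
#' @param read_length sequenced read length (nt) when an adapter is appended.
#' @param adapter 3' adapter sequence appended to reads shorter than
#'   `read_length` (set `NULL` for adapter-free reads).
#' @param cohort_sizes per-cohort patient counts.
#' @param cohort_intercepts per-cohort logistic intercepts; defaults give
#'   recurrence prevalences near 0.5/0.5/0.475.
#' @param markers marker miRNA names used by [simulate_cohorts()].
#' @param marker_beta logistic coefficients (per standardized log2 unit) of
#'   the markers in the recurrence model.
#' @param seed integer seed; a fixed seed makes every generator output
#'   byte-identical across runs.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_truth()], [simulate_expression()],
#'   [simulate_predictions()], [simulate_reads()], [simulate_cohorts()]
#' @export
sim_config <- function(n_mirnas = 30, n_genes = 200, n_edges = 150,
                       n_conditions = 4, replicates = 3,
                       de_fraction = 1.0, shift_range = c(0.8, 3),
                       edge_strength_range = c(0.6, 1.5),
                       cp_slope = 1.0, cp_intercept = 35,
                       cp_noise_sd = 0.2, expr_noise_sd = 0.2,
                       cp_bias_amplitude = 1.5,
                       decoy_rate = 0.1, decoy_support_prob = 0.7,
                       n_predictors = 6,
                       predictors = c("miRanda", "miRDB", "miRWalk",
                                      "PicTar", "RNA22", "TargetScan"),
                       n_reads = 10000, read_length = 36,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       cohort_sizes = c(52, 60, 40),
                       cohort_intercepts = c(0, 0, -0.1),
                       markers = c("miR-190b", "miR-516a-5p",
                                   "miR-29b", "miR-203"),
                       marker_beta = c(1.5, -1.5, 0, 0),
                       seed = 1L) {
  counts <- c(n_mirnas = n_mirnas, n_genes = n_genes,
              n_conditions = n_conditions, replicates = replicates,
              n_predictors = n_predictors, n_reads = n_reads,
              read_length = read_length)
  if (any(counts <= 0))
    stop("all counts must be positive; offending: ",
         paste(names(counts)[counts <= 0], collapse = ", "), call. = FALSE)
  if (n_edges < 0) stop("n_edges must be >= 0", call. = FALSE)
  if (n_conditions < 4)
    stop("need >= 4 conditions (1 parental + >= 3 resistant)", call. = FALSE)
  if (de_fraction < 0 || de_fraction > 1)
    stop("de_fraction must be in [0, 1]", call. = FALSE)
  if (cp_slope <= 0) stop("cp_slope must be > 0", call. = FALSE)
  if (n_predictors < 2) stop("need >= 2 predictors", call. = FALSE)
  if (length(predictors) < n_predictors)
    predictors <- paste0("predictor", seq_len(n_predictors))
  if (length(cohort_sizes) < 2) stop("need >= 2 cohorts", call. = FALSE)
  if (any(cohort_sizes < 20)) stop("each cohort needs n >= 20", call. = FALSE)
  if (length(cohort_intercepts) != length(cohort_sizes))
    cohort_intercepts <- rep_len(cohort_intercepts, length(cohort_sizes))
  if (length(marker_beta) != length(markers))
    stop("marker_beta must have one coefficient per marker", call. = FALSE)
  seed <- as.integer(seed)

  structure(list(
    n_mirnas = n_mirnas, n_genes = n_genes, n_edges = n_edges,
    n_conditions = n_conditions, replicates = replicates,
    de_fraction = de_fraction, shift_range = shift_range,
    edge_strength_range = edge_strength_range,
    cp_slope = cp_slope, cp_intercept = cp_intercept,
    cp_noise_sd = cp_noise_sd, expr_noise_sd = expr_noise_sd,
    cp_bias_amplitude = cp_bias_amplitude,
    decoy_rate = decoy_rate, decoy_support_prob = decoy_support_prob,
    n_predictors = n_predictors,
    predictors = predictors[seq_len(n_predictors)],
    n_reads = n_reads, read_length = read_length, adapter = adapter,
    cohort_sizes = cohort_sizes, cohort_intercepts = cohort_intercepts,
    markers = markers, marker_beta = marker_beta,
    seed = seed), class = "sim_config")
}

#' Draw a planted regulatory ground truth
#'
#' Samples the regulatory network and condition effects that every other
#' generator realizes: miRNA and gene identifiers, repression edges with
#' strictly positive strengths, per-condition log2 abundance shifts for a
#' configurable fraction of miRNAs (both signs represented), and baseline
#' log2 abundances.
#'
#' While `n_edges <= n_genes` each edge is assigned a distinct target gene,
#' so every planted edge is identifiable from a pairwise correlation over
#' condition means; with more edges than genes, genes acquire multiple
#' regulators and pairwise correlations are attenuated.
#'
#' @param config a [sim_config()].
#' @return An object of class `regulatory_truth`: list with `mirna_ids`,
#'   `gene_ids`, `edges` (data.frame `mirna`, `gene`, `strength`),
#'   `shifts` (miRNA x condition matrix of log2 shifts, reference column 0),
#'   `conditions`, `baseline_log2` (named, miRNA), `gene_baseline` (named).
#' @export
simulate_truth <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n_pairs <- config$n_mirnas * config$n_genes
  if (config$n_edges > n_pairs)
    stop(sprintf("requested %d edges but only %d miRNA x gene pairs exist",
                 config$n_edges, n_pairs), call. = FALSE)

  with_seed(config$seed, {
    mirna_ids <- sprintf("miR-sim-%02d", seq_len(config$n_mirnas))
    gene_ids <- sprintf("GENE%03d", seq_len(config$n_genes))
    conditions <- c("parental",
                    paste0("resistant", seq_len(config$n_conditions - 1L)))

    if (config$n_edges == 0) {
      edges <- data.frame(mirna = character(), gene = character(),
                          strength = numeric(), stringsAsFactors = FALSE)
    } else if (config$n_edges <= config$n_genes) {
      edges <- data.frame(
        mirna = sample(mirna_ids, config$n_edges, replace = TRUE),
        gene = sample(gene_ids, config$n_edges, replace = FALSE),
        stringsAsFactors = FALSE)
    } else {
      idx <- sample.int(n_pairs, config$n_edges, replace = FALSE)
      edges <- data.frame(
        mirna = mirna_ids[(idx - 1L) %% config$n_mirnas + 1L],
        gene = gene_ids[(idx - 1L) %/% config$n_mirnas + 1L],
        stringsAsFactors = FALSE)
    }
    if (nrow(edges))
      edges$strength <- stats::runif(nrow(edges),
                                     config$edge_strength_range[1],
                                     config$edge_strength_range[2])
    else edges$strength <- numeric()

    n_de <- round(config$de_fraction * config$n_mirnas)
    de_idx <- if (n_de > 0) sort(sample.int(config$n_mirnas, n_de)) else integer()
    shifts <- matrix(0, config$n_mirnas, config$n_conditions,
                     dimnames = list(mirna_ids, conditions))
    if (n_de > 0) {
      # Signs are drawn per (miRNA, condition): the resistant conditions
      # model independently derived clones, which share some but not all
      # alterations. This also makes each shifted miRNA's condition
      # profile individually identifiable -- with one global sign per
      # miRNA, all same-sign miRNAs would load on the single
      # parental-vs-resistant axis and their profiles would be mutually
      # collinear, leaving the planted edges unrecoverable by pairwise
      # correlation even at zero noise. Both signs are represented across
      # the shifted set by construction.
      n_res <- config$n_conditions - 1L
      for (m in de_idx) {
        mag <- stats::runif(n_res, config$shift_range[1],
                            config$shift_range[2])
        sgn <- sample(c(-1, 1), n_res, replace = TRUE)
        shifts[m, -1L] <- sgn * mag
      }
    }

    baseline <- stats::runif(config$n_mirnas, 6, 12)
    names(baseline) <- mirna_ids
    gene_baseline <- stats::runif(config$n_genes, 5, 11)
    names(gene_baseline) <- gene_ids

    structure(list(mirna_ids = mirna_ids, gene_ids = gene_ids,
                   edges = edges, shifts = shifts, conditions = conditions,
                   baseline_log2 = baseline, gene_baseline = gene_baseline,
                   config = config), class = "regulatory_truth")
  })
}

# Smooth per-sample signal-dependent Cp bias b_j(x): a low-order polynomial
# of the standardized signal z = (x - mid)/halfspan over the expected Cp
# range. Coefficients are centered across samples (the across-sample mean
# bias is not identifiable by quantile normalization to the mean target)
# and clipped so the distorted map x + b(x) stays strictly increasing.
make_bias <- function(n_samples, amplitude, cp_range) {
  coefs <- matrix(stats::rnorm(n_samples * 2L, sd = 0.5), n_samples, 2L)
  coefs <- sweep(coefs, 2L, colMeans(coefs))
  halfspan <- diff(cp_range) / 2
  mid <- mean(cp_range)
  # keep |b'(x)| <= 0.4: plate distortions shift and warp the Cp scale
  # gently, they do not compress it severely, and g(x) = x + b(x) must
  # stay well away from flat for the distortion to be recoverable at all;
  # one global shrink factor so the biases keep averaging to zero across
  # samples
  slope_bound <- amplitude * (abs(coefs[, 1L]) + 4 * abs(coefs[, 2L])) / halfspan
  shrink <- min(1, 0.4 / max(slope_bound, 1e-12))
  coefs <- coefs * shrink
  list(coefs = coefs, mid = mid, halfspan = halfspan, amplitude = amplitude)
}

bias_value <- function(bias, j, x) {
  z <- (x - bias$mid) / bias$halfspan
  bias$amplitude * (bias$coefs[j, 1L] * z + bias$coefs[j, 2L] * (2 * z^2 - 1))
}

#' Simulate paired Cp and expression matrices from a planted truth
#'
#' Realizes the inverse-coupling assumption at the heart of the integrative
#' analysis: gene log2 expression is its baseline minus the sum over
#' incoming edges of (edge strength x centered condition-level miRNA log2
#' abundance) plus Gaussian noise, while miRNA Cp is an affine, decreasing
#' function of log2 abundance plus a smooth per-sample signal-dependent
#' bias and Gaussian noise. Lower Cp therefore means higher abundance, and
#' a planted edge shows up as a strong *negative* correlation between the
#' miRNA's abundance and its target -- equivalently a strong *positive*
#' Cp-expression correlation that the negation step downstream flips.
#'
#' @param truth a [simulate_truth()] result.
#' @param config a [sim_config()]; defaults to the one stored in `truth`.
#' @return An object of class `mirtam_sim`: list with `cp` (miRNA x sample),
#'   `expr` (gene x sample), `abundance` (log2, miRNA x sample),
#'   `condition_map` (named character, sample -> condition), `bias`
#'   (internal bias parameters) and `truth`.
#' @export
simulate_expression <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "regulatory_truth"), inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    conditions <- truth$conditions
    samples <- as.vector(vapply(conditions, function(cn)
      paste0(cn, "_r", seq_len(config$replicates)), character(config$replicates)))
    cond_of <- rep(conditions, each = config$replicates)
    names(cond_of) <- samples

    # condition-level log2 abundance, then per-sample replication
    cond_abund <- truth$baseline_log2 + truth$shifts  # miRNA x condition
    abundance <- cond_abund[, cond_of, drop = FALSE]
    colnames(abundance) <- samples

    # gene expression: baseline - sum(strength * centered miRNA abundance)
    centered <- cond_abund - rowMeans(cond_abund)
    effect <- matrix(0, config$n_genes, length(conditions),
                     dimnames = list(truth$gene_ids, conditions))
    if (nrow(truth$edges)) {
      for (e in seq_len(nrow(truth$edges))) {
        g <- truth$edges$gene[e]
        m <- truth$edges$mirna[e]
        effect[g, ] <- effect[g, ] - truth$edges$strength[e] * centered[m, ]
      }
    }
    expr <- truth$gene_baseline + effect[, cond_of, drop = FALSE]
    colnames(expr) <- samples
    expr <- expr + stats::rnorm(length(expr), sd = config$expr_noise_sd)

    # Cp: affine in log2 abundance, then smooth per-sample bias, then noise
    cp_true <- config$cp_intercept - config$cp_slope * abundance
    cp_range <- range(cp_true)
    if (diff(cp_range) < 1) cp_range <- cp_range + c(-1, 1)
    bias <- make_bias(length(samples), config$cp_bias_amplitude, cp_range)
    cp <- cp_true
    for (j in seq_along(samples))
      cp[, j] <- cp_true[, j] + bias_value(bias, j, cp_true[, j])
    cp <- cp + stats::rnorm(length(cp), sd = config$cp_noise_sd)

    structure(list(cp = cp, expr = expr, abundance = abundance,
                   condition_map = cond_of, bias = bias, truth = truth,
                   config = config), class = "mirtam_sim")
  })
}

#' Ground-truth normalization offset of a simulated sample
#'
#' The generator distorts true Cp values `x` into observed values
#' `g(x) = x + b(x)`. The correction a normalization method should apply to
#' an *observed* value `y` is `-b(g^-1(y))`; this helper inverts `g`
#' numerically and returns that ideal offset, for comparison with a fitted
#' normalization model.
#'
#' @param sim a [simulate_expression()] result.
#' @param sample sample id or index.
#' @param y observed Cp values.
#' @return Numeric vector of ideal additive offsets, same length as `y`.
#' @export
planted_offset <- function(sim, sample, y) {
  stopifnot(inherits(sim, "mirtam_sim"))
  j <- if (is.character(sample)) match(sample, colnames(sim$cp)) else sample
  if (is.na(j)) stop("unknown sample: ", sample, call. = FALSE)
  grid <- seq(sim$bias$mid - 1.5 * sim$bias$halfspan,
              sim$bias$mid + 1.5 * sim$bias$halfspan, length.out = 2001)
  gy <- grid + bias_value(sim$bias, j, grid)
  x_of_y <- stats::approx(gy, grid, xout = y, rule = 2)$y
  -bias_value(sim$bias, j, x_of_y)
}

#' Simulate a multi-tool target-prediction table
#'
#' Every planted edge is supported by at least two distinct predictors
#' (prediction tools are assumed to recover true targets redundantly);
#' decoy (non-edge) pairs enter at `decoy_rate` with support counts drawn
#' from a geometric distribution truncated to the number of predictors, so
#' most decoys carry support 1 (below the >=2 support gate) but some pass
#' it and must be removed by the correlation filter.
#'
#' @param truth a [simulate_truth()] result.
#' @param config a [sim_config()]; defaults to the one stored in `truth`.
#' @return A data.frame with columns `mirna`, `gene`, `predictor`
#'   (unique triples).
#' @export
simulate_predictions <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "regulatory_truth"), inherits(config, "sim_config"))
  npred <- config$n_predictors
  preds <- config$predictors
  with_seed(config$seed + 2L, {
    rows <- list()
    if (nrow(truth$edges)) {
      support <- 2L + stats::rbinom(nrow(truth$edges), npred - 2L, 0.35)
      for (e in seq_len(nrow(truth$edges))) {
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = truth$edges$mirna[e], gene = truth$edges$gene[e],
          predictor = sample(preds, support[e]), stringsAsFactors = FALSE)
      }
    }
    if (config$decoy_rate > 0) {
      edge_key <- paste(truth$edges$mirna, truth$edges$gene)
      all_pairs <- expand.grid(mirna = truth$mirna_ids, gene = truth$gene_ids,
                               KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      non_edges <- all_pairs[!(paste(all_pairs$mirna, all_pairs$gene) %in%
                                 edge_key), , drop = FALSE]
      n_decoy <- stats::rbinom(1L, nrow(non_edges), config$decoy_rate)
      if (n_decoy > 0) {
        pick <- non_edges[sample.int(nrow(non_edges), n_decoy), , drop = FALSE]
        # truncated geometric on {1..npred}: support 1 most likely
        supp <- pmin(1L + stats::rgeom(n_decoy, config$decoy_support_prob), npred)
        for (d in seq_len(n_decoy)) {
          rows[[length(rows) + 1L]] <- data.frame(
            mirna = pick$mirna[d], gene = pick$gene[d],
            predictor = sample(preds, supp[d]), stringsAsFactors = FALSE)
        }
      }
    }
    if (!length(rows))
      return(data.frame(mirna = character(), gene = character(),
                        predictor = character(), stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
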