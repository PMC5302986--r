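#' Count peaks in a qPCR melting curve
#'
#' Assays whose primers amplify more than one product show more than one
#' peak in the negative derivative of fluorescence with respect to
#' temperature. Fluorescence is smoothed with a centered moving average
#' before differentiation, local maxima of -dF/dT are located, and peaks
#' below `prominence` times the largest peak height are treated as ripple
#' and ignored.
#'
#' @param temperature increasing temperature grid (degrees C, >= 20 points).
#' @param fluorescence fluorescence values on the grid.
#' @param prominence minimum peak height as a fraction of the largest peak
#'   height (default 0.2).
#' @param window moving-average window (grid points, odd; default 3).
#' @return Integer peak count. Assays with a count > 1 should be excluded
#'   from downstream analysis (see [melt_qc()]).
#' @export
count_melt_peaks <- function(temperature, fluorescence, prominence = 0.2,
                             window = 3L) {
  if (length(temperature) < 20)
    stop("melting curve needs >= 20 grid points", call. = FALSE)
  if (length(fluorescence) != length(temperature))
    stop("temperature and fluorescence lengths differ", call. = FALSE)
  if (any(diff(temperature) <= 0))
    stop("temperatures must be strictly increasing", call. = FALSE)

  f <- stats::filter(fluorescence, rep(1 / window, window), sides = 2)
  f <- as.numeric(f)
  # moving average is NA at the edges; fall back to the raw signal there
  f[is.na(f)] <- fluorescence[is.na(f)]
  d <- -diff(f) / diff(temperature)

  n <- length(d)
  if (n < 3) return(0L)
  is_max <- d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n]
  heights <- d[2:(n - 1)][is_max]
  heights <- heights[heights > 0]
  if (!length(heights)) return(0L)
  sum(heights >= prominence * max(heights))
}

#' Melting-curve QC over a set of assays
#'
#' @param curves named list of data.frames (`temperature`, `fluorescence`),
#'   as returned by [read_melt_curves()].
#' @inheritParams count_melt_peaks
#' @return data.frame `assay`, `peaks`, `flagged` (TRUE when more than one
#'   peak was found).
#' @export
melt_qc <- function(curves, prominence = 0.2, window = 3L) {
  peaks <- vapply(curves, function(d)
    count_melt_peaks(d$temperature, d$fluorescence, prominence, window),
    integer(1))
  data.frame(assay = names(curves), peaks = unname(peaks),
             flagged = unname(peaks) > 1L, stringsAsFactors = FALSE)
}

#' Fit a signal-dependent quantile-spline normalization model
#'
#' qPCR Cp values carry smooth, plate-specific, signal-dependent distortions.
#' This fits, per sample, an additive offset as a smooth function of the Cp
#' signal: per-sample Cp quantiles are computed at a ladder of anchors, the
#' target distribution is (by default) the across-sample mean of those
#' quantiles, the anchor-wise offsets (target minus sample quantile) are
#' interpolated by a cubic smoothing spline (smoothness chosen by
#' generalized cross-validation), and the final map `x + offset(x)` is made
#' non-decreasing by isotonic adjustment so within-sample ranks are
#' preserved.
#'
#' @param cp miRNA x sample Cp matrix (missing values allowed).
#' @param target `"mean"` (default) or a numeric vector of target quantiles,
#'   one per anchor.
#' @param n_anchors number of quantile anchors (default 101).
#' @param df_max cap on the smoothing spline effective degrees of freedom
#'   (default 8); anchor-offset errors are correlated across neighbouring
#'   quantiles, which makes plain GCV undersmooth.
#' @return An object of class `qspline_model`: per sample, an offset
#'   function tabulated on a grid, plus the target quantiles.
#' @export
fit_qspline <- function(cp, target = "mean", n_anchors = 101L,
                        df_max = 8) {
  if (ncol(cp) < 2) stop("need >= 2 samples", call. = FALSE)
  detected <- colSums(!is.na(cp))
  if (any(detected < 30))
    stop("sample(s) with < 30 detected features: ",
         paste(colnames(cp)[detected < 30], collapse = ", "), call. = FALSE)
  shared <- sum(stats::complete.cases(cp))
  if (shared < 30)
    stop("need >= 30 features detected in every sample", call. = FALSE)

  # plotting positions: the exact extremes (sample min/max) are noise-
  # dominated order statistics and are not used as anchors
  probs <- (seq_len(n_anchors) - 0.5) / n_anchors
  q <- apply(cp, 2L, stats::quantile, probs = probs, na.rm = TRUE, names = FALSE)
  if (identical(target, "mean")) target_q <- rowMeans(q)
  else {
    if (!is.numeric(target) || length(target) != n_anchors)
      stop("'target' must be \"mean\" or a numeric vector of length n_anchors",
           call. = FALSE)
    target_q <- target
  }

  samples <- colnames(cp)
  maps <- vector("list", length(samples))
  names(maps) <- samples
  for (j in seq_along(samples)) {
    x <- q[, j]
    off <- target_q - x
    obs_range <- range(cp[, j], na.rm = TRUE)
    if (max(x) - min(x) < 1e-8) {
      # degenerate (constant) sample: constant offset
      grid <- c(x[1] - 1, x[1] + 1)
      o_grid <- rep(mean(off), 2L)
    } else {
      # GCV smoothing, with the effective df capped: neighbouring anchor
      # offsets share the same order statistics, so their errors are
      # strongly correlated and GCV (which assumes independent errors)
      # undersmooths badly, producing non-monotone boundary wiggle
      fit <- stats::smooth.spline(x, off, cv = FALSE)
      if (fit$df > df_max) fit <- stats::smooth.spline(x, off, df = df_max)
      # tabulate over the sample's full observed range, not just the
      # anchor span, so the few points beyond the outermost anchors get
      # the spline's extrapolation rather than a clamped constant
      grid <- seq(obs_range[1], obs_range[2], length.out = 201L)
      o_grid <- stats::predict(fit, grid)$y
      # isotonic adjustment of the final map f(x) = x + offset(x)
      f <- grid + o_grid
      iso <- stats::isoreg(grid, f)
      o_grid <- iso$yf - grid
    }
    maps[[j]] <- list(grid = grid, offset = o_grid)
  }
  structure(list(maps = maps, target = target_q, probs = probs,
                 anchors = q), class = "qspline_model")
}

#' Evaluate a fitted per-sample offset function
#'
#' @param model a [fit_qspline()] model.
#' @param sample sample id.
#' @param x Cp values; values outside the fitted range are clamped to the
#'   boundary offset.
#' @return Additive offsets (Cp units).
#' @export
qspline_offset <- function(model, sample, x) {
  stopifnot(inherits(model, "qspline_model"))
  m <- model$maps[[sample]]
  if (is.null(m)) stop("model has no sample '", sample, "'", call. = FALSE)
  stats::approx(m$grid, m$offset, xout = x, rule = 2)$y
}

#' Apply a quantile-spline normalization model
#'
#' Adds each sample's fitted offset to its raw Cp values. Missing values
#' stay missing; values outside the fitted signal range receive the
#' boundary offset.
#'
#' @param cp miRNA x sample Cp matrix.
#' @param model a [fit_qspline()] model fitted on the same samples.
#' @return Normalized Cp matrix of the same shape.
#' @export
apply_normalization <- function(cp, model) {
  stopifnot(inherits(model, "qspline_model"))
  missing <- setdiff(colnames(cp), names(model$maps))
  if (length(missing))
    stop("model lacks sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- cp
  for (j in colnames(cp)) {
    ok <- !is.na(cp[, j])
    out[ok, j] <- cp[ok, j] + qspline_offset(model, j, cp[ok, j])
  }
  out
}

#' Reduction in replicate standard error after normalization
#'
#' For every (feature, condition) with >= 2 detected replicates the standard
#' error of the mean is computed before and after normalization; the return
#' value is `100 * (1 - mean(after) / mean(before))`, the percent reduction
#' in mean replicate SEM.
#'
#' @param raw,normalized Cp matrices with identical layout.
#' @param condition_map named character vector (sample -> condition).
#' @return Percent reduction (positive = normalization helped).
#' @export
sem_reduction <- function(raw, normalized, condition_map) {
  condition_map <- check_condition_map(colnames(raw), condition_map)
  sem_mean <- function(m) {
    sems <- c()
    for (cond in unique(condition_map)) {
      cols <- names(condition_map)[condition_map == cond]
      if (length(cols) < 2) next
      sub <- m[, cols, drop = FALSE]
      n_det <- rowSums(!is.na(sub))
      sd_f <- apply(sub, 1L, stats::sd, na.rm = TRUE)
      keep <- n_det >= 2
      sems <- c(sems, (sd_f / sqrt(n_det))[keep])
    }
    if (!length(sems)) stop("no condition with >= 2 replicates", call. = FALSE)
    mean(sems)
  }
  before <- sem_mean(raw)
  after <- sem_mean(normalized)
  100 * (1 - after / before)
}
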