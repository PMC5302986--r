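#' Fit a ridge-stabilized logistic recurrence classifier
#'
#' Maximum-likelihood logistic regression of the binary recurrence label on
#' the selected marker miRNAs, fitted by Newton-Raphson with a tiny ridge
#' penalty (`lambda`, default 1e-6, on the slopes only) so that separable
#' data still yield finite coefficients. Marker expressions are
#' standardized with center/scale learned on the fit cohort; the stored
#' parameters are reapplied verbatim to any test cohort.
#'
#' @param cohort a `cohort_dataset` (list with `x`, `label`; see
#'   [simulate_cohorts()]), or a sample x miRNA matrix if `label` is given.
#' @param combo character vector of marker miRNA ids to include.
#' @param label binary labels, required when `cohort` is a bare matrix.
#' @param lambda ridge penalty on slope coefficients (default 1e-6).
#' @param max_iter,tol Newton iteration cap (500) and gradient-norm
#'   convergence tolerance (1e-8).
#' @return Object of class `mirtam_logit`: `coef` (intercept + slopes on
#'   the standardized scale), `center`, `scale`, `combo`, `converged`,
#'   `iterations`.
#' @export
fit_logistic <- function(cohort, combo, label = NULL, lambda = 1e-6,
                         max_iter = 500L, tol = 1e-8) {
  if (inherits(cohort, "cohort_dataset")) {
    x <- cohort$x
    y <- cohort$label
  } else {
    x <- cohort
    y <- label
  }
  if (is.null(y)) stop("labels required", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("cohort has a single outcome class; cannot fit", call. = FALSE)
  miss <- setdiff(combo, colnames(x))
  if (length(miss))
    stop("combo miRNA(s) absent from cohort: ",
         paste(miss, collapse = ", "), call. = FALSE)
  xm <- x[, combo, drop = FALSE]
  center <- colMeans(xm)
  scale_ <- apply(xm, 2L, stats::sd)
  scale_[scale_ == 0] <- 1
  z <- sweep(sweep(xm, 2L, center), 2L, scale_, "/")
  X <- cbind(`(Intercept)` = 1, z)
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- numeric(p)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    g <- drop(crossprod(X, y - mu)) - drop(pen %*% beta)
    if (sqrt(sum(g^2)) < tol) { converged <- TRUE; break }
    w <- mu * (1 - mu)
    H <- crossprod(X, X * w) + pen
    step <- solve(H, g)
    # halve the step while it worsens the penalized log-likelihood
    ll <- function(b) {
      e <- drop(X %*% b)
      sum(y * e - log1p(exp(e))) - 0.5 * drop(crossprod(b, pen %*% b))
    }
    ll0 <- ll(beta)
    for (h in 0:10) {
      cand <- beta + step / 2^h
      if (ll(cand) >= ll0 - 1e-12) { beta <- cand; break }
    }
  }
  structure(list(coef = stats::setNames(drop(beta), colnames(X)),
                 center = center, scale = scale_, combo = combo,
                 converged = converged, iterations = it),
            class = "mirtam_logit")
}

#' Predicted recurrence probabilities
#'
#' @param object a [fit_logistic()] model.
#' @param newdata a `cohort_dataset` or sample x miRNA matrix.
#' @param ... unused.
#' @return Numeric vector of recurrence probabilities.
#' @export
predict.mirtam_logit <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "cohort_dataset")) newdata$x else newdata
  miss <- setdiff(object$combo, colnames(x))
  if (length(miss))
    stop("test cohort lacks miRNA(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  z <- sweep(sweep(x[, object$combo, drop = FALSE], 2L, object$center),
             2L, object$scale, "/")
  eta <- object$coef[1] + drop(z %*% object$coef[-1])
  stats::plogis(eta)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps thresholds over the unique score values (ties grouped onto a
#' single ROC vertex) and accumulates (FPR, TPR) points; the AUC is the
#' trapezoid area, which equals the tie-corrected Mann-Whitney U statistic
#' divided by `n1 * n0`. Invariant under strictly monotone transforms of
#' the scores; flipping all labels maps AUC to 1 - AUC.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary labels (0/1), both classes present.
#' @return List of class `mirtam_roc`: `auc`, `roc` (data.frame `fpr`,
#'   `tpr`, monotone non-decreasing in both coordinates).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("scores and labels lengths differ", call. = FALSE)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 0/1", call. = FALSE)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  grp_end <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(y)[grp_end]
  fp <- cumsum(1 - y)[grp_end]
  tpr <- c(0, tp / n1)
  fpr <- c(0, fp / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(auc = auc, roc = data.frame(fpr = fpr, tpr = tpr)),
            class = "mirtam_roc")
}

#' Cross-cohort AUC matrix over miRNA combinations
#'
#' For every (fit cohort, combination) a classifier is fitted with
#' [fit_logistic()] and evaluated with [roc_auc()] on *every* cohort.
#' Rows where fit and test cohort coincide are flagged `"training"`
#' (optimistic, resubstitution performance); all others are
#' `"independent test"` performance.
#'
#' @param cohorts list of `cohort_dataset` objects (>= 2).
#' @param combos list of character vectors (marker combinations, each of
#'   size 1-3 typically).
#' @return data.frame `fit_cohort`, `test_cohort`, `combo` (ids joined by
#'   `+`), `auc`, `role`.
#' @export
cross_cohort_matrix <- function(cohorts, combos) {
  if (length(cohorts) < 2) stop("need >= 2 cohorts", call. = FALSE)
  if (!is.list(combos)) combos <- list(combos)
  ids <- vapply(cohorts, function(co) co$id, "")
  rows <- list()
  for (combo in combos) {
    for (i in seq_along(cohorts)) {
      fit <- fit_logistic(cohorts[[i]], combo)
      for (j in seq_along(cohorts)) {
        sc <- predict(fit, cohorts[[j]])
        auc <- roc_auc(sc, cohorts[[j]]$label)$auc
        rows[[length(rows) + 1L]] <- data.frame(
          fit_cohort = ids[i], test_cohort = ids[j],
          combo = paste(combo, collapse = "+"), auc = auc,
          role = if (i == j) "training" else "independent test",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
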