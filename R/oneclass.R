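# Data-driven SIMCA (DD-SIMCA) one-class modelling.
#
# A PCA model of the target class yields, for every sample, a score
# distance SD (Mahalanobis distance within the retained components) and an
# orthogonal distance OD (squared residual norm). Each distance is treated
# as a scaled chi-square variable whose scale and degrees of freedom are
# estimated from the training set, either by the method of moments or by
# robust (median/IQR quantile-matching) estimators. The full decision
# statistic c = N_SD * SD / SD0 + N_OD * OD / OD0 is compared to the
# chi-square quantile with N_SD + N_OD degrees of freedom.

# Estimate (dof, scale) of a scaled chi-square sample: x ~ scale * chi2_N / N.
estimate_chisq_dof <- function(x, mode = c("moments", "robust"),
                               what = "distance") {
  mode <- match.arg(mode)
  if (mode == "moments") {
    m <- mean(x); v <- stats::var(x)
    if (!is.finite(v) || v <= 0 || m <= 0) {
      warning(sprintf("zero-variance %s; dof set to 1", what), call. = FALSE)
      return(list(dof = 1L, scale = max(m, .Machine$double.eps)))
    }
    list(dof = max(1L, as.integer(round(2 * m^2 / v))), scale = m)
  } else {
    M <- stats::median(x)
    R <- stats::IQR(x)
    if (!is.finite(R) || R <= 0 || M <= 0) {
      warning(sprintf("degenerate robust %s estimate; dof set to 1", what),
              call. = FALSE)
      return(list(dof = 1L, scale = max(M, .Machine$double.eps)))
    }
    cand <- 1:250
    ratio <- (stats::qchisq(0.75, cand) - stats::qchisq(0.25, cand)) /
      stats::qchisq(0.5, cand)
    dof <- cand[which.min(abs(ratio - R / M))]
    # scale such that median(scale * chi2_N / N) = M
    list(dof = dof, scale = dof * M / stats::qchisq(0.5, dof))
  }
}

#' Fit a DD-SIMCA one-class model
#'
#' @param x Target-class feature matrix (samples x features; needs at least
#'   `n_components + 2` samples).
#' @param n_components Number of principal components of the target model.
#' @param alpha Type-I error target (default 0.05): the expected fraction
#'   of genuine target samples rejected.
#' @param mode Parameter estimation: `"moments"` (mean/variance) or
#'   `"robust"` (median/IQR quantile matching, less sensitive to training
#'   outliers).
#' @param alpha_out Extreme significance level at which training samples
#'   are flagged (and reported, never silently removed) as potential
#'   outliers (default 0.01).
#' @return Object of class `ddsimca_model`.
#' @export
fit_ddsimca <- function(x, n_components = 2L, alpha = 0.05,
                        mode = c("moments", "robust"), alpha_out = 0.01) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (nrow(x) < n_components + 2L)
    stop("need at least n_components + 2 target samples", call. = FALSE)
  pca <- fit_pca(x, n_components)
  sd_i <- rowSums(sweep(pca$scores^2, 2, pca$eigenvalues, "/"))
  resid <- sweep(x, 2, pca$mean) - pca$scores %*% t(pca$loadings)
  od_i <- rowSums(resid^2)
  est_sd <- estimate_chisq_dof(sd_i, mode, "score distance")
  use_od <- any(od_i > max(sd_i, 1) * 1e-12)
  est_od <- if (use_od) estimate_chisq_dof(od_i, mode, "orthogonal distance")
            else list(dof = 0L, scale = 1)
  dof_total <- est_sd$dof + est_od$dof
  c_train <- est_sd$dof * sd_i / est_sd$scale +
    if (use_od) est_od$dof * od_i / est_od$scale else 0
  model <- structure(list(
    pca = pca, n_components = as.integer(n_components), alpha = alpha,
    mode = mode, sd_train = sd_i, od_train = od_i,
    sd0 = est_sd$scale, od0 = est_od$scale,
    n_sd = est_sd$dof, n_od = est_od$dof, use_od = use_od,
    c_crit = stats::qchisq(1 - alpha, dof_total),
    dof_total = dof_total,
    train_outlier_flags = c_train > stats::qchisq(1 - alpha_out, dof_total),
    alpha_out = alpha_out),
    class = "ddsimca_model")
  model
}

#' @export
print.ddsimca_model <- function(x, ...) {
  cat(sprintf(
    "<ddsimca_model> a=%d, %s estimates: N_SD=%d SD0=%.4g, N_OD=%d OD0=%.4g, alpha=%.3g, c_crit=%.3f\n",
    x$n_components, x$mode, x$n_sd, x$sd0, x$n_od, x$od0, x$alpha, x$c_crit))
  if (any(x$train_outlier_flags))
    cat(sprintf("  %d training sample(s) flagged at alpha_out=%.3g\n",
                sum(x$train_outlier_flags), x$alpha_out))
  invisible(x)
}

ddsimca_distances <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$pca$mean))
    stop("feature dimension mismatch with the trained model", call. = FALSE)
  t <- predict(model$pca, x)
  sd_i <- rowSums(sweep(t^2, 2, model$pca$eigenvalues, "/"))
  resid <- sweep(x, 2, model$pca$mean) - t %*% t(model$pca$loadings)
  od_i <- rowSums(resid^2)
  list(sd = sd_i, od = od_i)
}

#' Accept or reject query samples against a DD-SIMCA model
#'
#' @param model A `ddsimca_model`.
#' @param x Query feature matrix on the training feature space.
#' @param alpha Optional alpha overriding the model's (smaller alpha gives
#'   a larger acceptance region).
#' @return Data frame with `sd`, `od`, `c`, `accepted`.
#' @export
predict_membership <- function(model, x, alpha = model$alpha) {
  d <- ddsimca_distances(model, x)
  cc <- model$n_sd * d$sd / model$sd0 +
    if (model$use_od) model$n_od * d$od / model$od0 else 0
  crit <- stats::qchisq(1 - alpha, model$dof_total)
  data.frame(sd = d$sd, od = d$od, c = cc, accepted = cc <= crit)
}

#' One-class specificity against alien classes
#'
#' Fraction of non-target samples rejected by the model, per class and
#' pooled (the pooled rate is the sample-weighted mean of per-class rates).
#'
#' @param model A `ddsimca_model`.
#' @param x Alien feature matrix.
#' @param labels Optional class labels for per-class breakdown.
#' @return List with `pooled`, `per_class` (named vector), `n`.
#' @export
specificity <- function(model, x, labels = NULL) {
  pred <- predict_membership(model, x)
  rej <- !pred$accepted
  per_class <- if (!is.null(labels))
    vapply(split(rej, labels), mean, numeric(1)) else NULL
  list(pooled = mean(rej), per_class = per_class, n = nrow(as.matrix(x)))
}

#' Choose the number of components by leave-one-out sensitivity
#'
#' For each candidate component count, each target sample is held out in
#' turn, the model is refitted on the rest, and the held-out sample's
#' membership is tested; sensitivity is the acceptance fraction. The
#' candidate with the highest leave-one-out sensitivity wins, ties going to
#' the smallest (most parsimonious) count.
#'
#' @param x Target-class feature matrix.
#' @param candidates Candidate component counts (infeasible ones, needing
#'   more than `nrow(x) - 3` components, are dropped).
#' @param alpha Type-I error target.
#' @param mode Estimation mode passed to [fit_ddsimca()].
#' @return List with `chosen`, `sensitivity` (named by candidate), `alpha`.
#' @export
select_components_by_sensitivity <- function(x, candidates = 1:3,
                                             alpha = 0.05,
                                             mode = "moments") {
  x <- as.matrix(x)
  n <- nrow(x)
  feasible <- candidates[candidates <= n - 3L & candidates >= 1L]
  if (!length(feasible)) stop("no feasible candidate component count",
                              call. = FALSE)
  sens <- vapply(feasible, function(a) {
    acc <- vapply(seq_len(n), function(i) {
      m <- suppressWarnings(
        fit_ddsimca(x[-i, , drop = FALSE], a, alpha, mode))
      predict_membership(m, x[i, , drop = FALSE])$accepted
    }, logical(1))
    mean(acc)
  }, numeric(1))
  names(sens) <- feasible
  chosen <- feasible[which.max(sens)]  # which.max takes the first maximum
  list(chosen = chosen, sensitivity = sens, alpha = alpha)
}
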