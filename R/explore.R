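# Data exploration: PCA with bootstrap loading stability, Hotelling T2 /
# Q-residual outlier screening, and canonical correspondence analysis.

#' Fit a principal component analysis
#'
#' Mean-centered PCA by singular value decomposition. The per-component sign
#' is fixed so the largest-magnitude loading entry is positive, which makes
#' bootstrap cosines and score plots reproducible. The full eigenvalue
#' spectrum (sample variances along all principal axes) is retained for the
#' Q-residual threshold even when fewer loadings are kept.
#'
#' @param x Numeric matrix, samples x features (>= 2 samples).
#' @param n_components Number of components to retain (default 10, capped
#'   at `min(nrow - 1, ncol)`).
#' @return Object of class `pca_model` with `mean`, `loadings`,
#'   `eigenvalues` (retained), `all_eigenvalues`, `scores`,
#'   `explained_variance`, `cumulative_variance`, `n`, `n_components`.
#' @export
fit_pca <- function(x, n_components = 10L) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 2L) stop("PCA needs >= 2 samples", call. = FALSE)
  r <- min(n - 1L, p)
  if (n_components > r)
    stop(sprintf("n_components (%d) exceeds min(samples - 1, features) = %d",
                 n_components, r), call. = FALSE)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc, nu = 0, nv = r)
  eig <- sv$d[seq_len(r)]^2 / (n - 1L)
  load <- sv$v
  # sign convention: largest-magnitude entry of each loading positive
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  keep <- seq_len(n_components)
  total <- sum(eig)
  structure(list(mean = mu, loadings = load[, keep, drop = FALSE],
                 eigenvalues = eig[keep], all_eigenvalues = eig,
                 scores = xc %*% load[, keep, drop = FALSE],
                 explained_variance = eig[keep] / total,
                 cumulative_variance = cumsum(eig[keep]) / total,
                 n = n, n_components = as.integer(n_components)),
            class = "pca_model")
}

#' Project new samples onto a fitted PCA
#'
#' @param object A `pca_model`.
#' @param newdata Matrix with the same feature columns as the training data.
#' @param ... Unused.
#' @return Score matrix, samples x retained components.
#' @export
predict.pca_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$mean))
    stop("feature dimension mismatch", call. = FALSE)
  sweep(newdata, 2, object$mean) %*% object$loadings
}

#' Bootstrap stability of PCA loadings
#'
#' Refits the PCA on row resamples (with replacement) and reports, per
#' retained component, the absolute cosine between the original and
#' resampled loading vectors (the absolute value absorbs the sign
#' indeterminacy). Cosines near 1 indicate a component that represents a
#' stable pattern rather than sampling noise. Degenerate resamples with
#' zero total variance are skipped and counted.
#'
#' @param x Samples x features matrix (>= 3 samples).
#' @param n_components Components to assess.
#' @param n_boot Number of bootstrap resamples (default 100).
#' @param seed Integer seed.
#' @return Object of class `stability_report`: `cosines` (resamples x
#'   components), `mean_cosine`, `n_boot`, `n_skipped`.
#' @export
bootstrap_stability <- function(x, n_components = 10L, n_boot = 100L,
                                seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("bootstrap stability needs >= 3 samples",
                         call. = FALSE)
  ref <- fit_pca(x, n_components)
  with_seed(seed, {
    cos_rows <- vector("list", n_boot)
    skipped <- 0L
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(x), replace = TRUE)
      xb <- x[idx, , drop = FALSE]
      if (sum(apply(xb, 2, stats::var)) <= 0) {
        skipped <- skipped + 1L
        next
      }
      fb <- tryCatch(fit_pca(xb, n_components), error = function(e) NULL)
      if (is.null(fb)) {
        skipped <- skipped + 1L
        next
      }
      cos_rows[[b]] <- abs(colSums(ref$loadings * fb$loadings))
    }
    cosines <- do.call(rbind, cos_rows[!vapply(cos_rows, is.null, logical(1))])
    structure(list(cosines = cosines,
                   mean_cosine = colMeans(cosines),
                   n_boot = as.integer(n_boot), n_skipped = skipped),
              class = "stability_report")
  })
}

#' Hotelling T2 / Q-residual outlier screening
#'
#' For each sample, T2 is the Mahalanobis distance inside the retained PC
#' subspace (score sums of squares over eigenvalues) and Q is the squared
#' residual norm off that subspace. The T2 control limit comes from the
#' F-distribution relation for PCA scores; the Q limit uses the
#' Jackson-Mudholkar approximation from the residual eigenvalues. A sample
#' is flagged when T2 or Q (default rule `"or"`, configurable to `"and"`)
#' exceeds its limit at the given confidence.
#'
#' @param model A `pca_model` fitted on `x` (or on a documented superset).
#' @param x The samples x features matrix to screen.
#' @param confidence Confidence level of both limits (default 0.99).
#' @param rule `"or"` (flag if either statistic exceeds) or `"and"`.
#' @return Object of class `outlier_report`: per-sample `t2`, `q`,
#'   thresholds `t2_limit`, `q_limit`, logical `flags`, and the rule.
#' @export
detect_outliers <- function(model, x, confidence = 0.99,
                            rule = c("or", "and")) {
  rule <- match.arg(rule)
  stopifnot(inherits(model, "pca_model"))
  x <- as.matrix(x)
  xc <- sweep(x, 2, model$mean)
  t <- xc %*% model$loadings
  t2 <- rowSums(sweep(t^2, 2, model$eigenvalues, "/"))
  resid <- xc - t %*% t(model$loadings)
  q <- rowSums(resid^2)
  a <- model$n_components
  n <- model$n
  t2_limit <- if (n > a)
    a * (n - 1) * (n + 1) / (n * (n - a)) * stats::qf(confidence, a, n - a)
  else Inf
  lam <- model$all_eigenvalues
  resid_eig <- lam[-seq_len(a)]
  resid_eig <- resid_eig[resid_eig > max(lam[1] * 1e-12, 0)]
  if (!length(resid_eig)) {
    warning("retained components span the data; Q rule disabled",
            call. = FALSE)
    q_limit <- Inf
  } else {
    th1 <- sum(resid_eig); th2 <- sum(resid_eig^2); th3 <- sum(resid_eig^3)
    h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
    if (!is.finite(h0) || h0 < 1e-3) h0 <- 1e-3
    z <- stats::qnorm(confidence)
    q_limit <- th1 * (z * sqrt(2 * th2 * h0^2) / th1 + 1 +
                        th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
  }
  flags <- if (rule == "or") (t2 > t2_limit) | (q > q_limit)
           else (t2 > t2_limit) & (q > q_limit)
  structure(list(t2 = t2, q = q, t2_limit = t2_limit, q_limit = q_limit,
                 flags = flags, confidence = confidence, rule = rule),
            class = "outlier_report")
}

#' Drop flagged outliers and recompile the dataset
#'
#' @param dataset A `spectral_dataset`.
#' @param report An `outlier_report` aligned with the dataset rows.
#' @return The dataset without flagged samples, labels and one-hot matrix
#'   recompiled.
#' @export
remove_outliers_and_recompile <- function(dataset, report) {
  stopifnot(inherits(report, "outlier_report"),
            length(report$flags) == length(dataset$spectra))
  if (all(report$flags)) stop("all samples flagged as outliers",
                              call. = FALSE)
  if (!any(report$flags)) return(dataset)
  subset_dataset(dataset, !report$flags)
}

#' Canonical correspondence analysis (native implementation)
#'
#' Constrained ordination of a non-negative response matrix (here the
#' one-hot taxon labels) by explanatory variables (band intensities),
#' following ter Braak: the chi-square standardized response matrix is
#' projected, with row weights, onto the explanatory variables by weighted
#' least squares, and the fitted matrix is decomposed by SVD. Explanatory
#' variables are standardized (mean 0, sd 1) before fitting. Site scores
#' are returned in scaling 1 (site-focused: scores multiplied by the square
#' root of their eigenvalue); scaling 2 (species-focused) is available.
#'
#' @param response Samples x classes non-negative matrix with positive row
#'   sums; every class must have at least one sample.
#' @param explanatory Samples x variables numeric matrix.
#' @param scaling 1 (default) or 2.
#' @return Object of class `cca_result`: `eigenvalues`, `site_scores` (LC),
#'   `wa_scores`, `class_scores`, `biplot_scores`, `total_inertia`,
#'   `constrained_inertia`, `scaling`.
#' @export
fit_cca <- function(response, explanatory, scaling = 1) {
  Y <- as.matrix(response)
  X <- as.matrix(explanatory)
  if (any(Y < 0)) stop("response must be non-negative", call. = FALSE)
  if (any(rowSums(Y) <= 0)) stop("response rows must have positive sums",
                                 call. = FALSE)
  if (any(colSums(Y) <= 0))
    stop("class(es) with zero samples in response", call. = FALSE)
  stopifnot(nrow(Y) == nrow(X), scaling %in% c(1, 2))
  tot <- sum(Y)
  P <- Y / tot
  r <- rowSums(P); cw <- colSums(P)
  Qbar <- (P - outer(r, cw)) / outer(sqrt(r), sqrt(cw))
  total_inertia <- sum(Qbar^2)
  # standardize explanatory variables, then weight rows by sqrt(r) about
  # the r-weighted mean
  X <- scale(X)
  keep <- apply(X, 2, function(v) all(is.finite(v)))
  if (!all(keep)) {
    warning("dropping constant explanatory variable(s)", call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  wmean <- colSums(X * r)
  Xr <- sweep(X, 2, wmean) * sqrt(r)
  qrX <- qr(Xr)
  if (qrX$rank < ncol(Xr))
    warning("rank-deficient explanatory matrix; using pseudoinverse fit",
            call. = FALSE)
  fitted <- qr.fitted(qrX, Qbar)
  k_max <- min(qrX$rank, ncol(Y) - 1L)
  sv <- svd(fitted)
  pos <- which(sv$d^2 > max(sv$d[1]^2 * 1e-12, 1e-300))
  k <- min(length(pos), k_max)
  if (k < 1L) stop("no constrained axes recovered", call. = FALSE)
  d <- sv$d[seq_len(k)]
  U <- sv$u[, seq_len(k), drop = FALSE]
  V <- sv$v[, seq_len(k), drop = FALSE]
  eig <- d^2
  # back-transform from chi-square coordinates
  site_lc <- U / sqrt(r)          # linear-combination site scores
  class_sc <- V / sqrt(cw)
  wa <- (Qbar %*% V) / sqrt(r)    # weighted-average site scores
  wa <- sweep(wa, 2, d, "/")
  if (scaling == 1) {
    site_lc <- sweep(site_lc, 2, sqrt(eig), "*")
    wa <- sweep(wa, 2, sqrt(eig), "*")
  } else {
    class_sc <- sweep(class_sc, 2, sqrt(eig), "*")
  }
  biplot <- stats::cor(Xr, U)
  ax <- paste0("CCA", seq_len(k))
  colnames(site_lc) <- colnames(wa) <- colnames(class_sc) <-
    colnames(biplot) <- ax
  rownames(class_sc) <- colnames(Y)
  rownames(biplot) <- colnames(X)
  structure(list(eigenvalues = stats::setNames(eig, ax),
                 site_scores = site_lc, wa_scores = wa,
                 class_scores = class_sc, biplot_scores = biplot,
                 total_inertia = total_inertia,
                 constrained_inertia = sum(eig), scaling = scaling),
            class = "cca_result")
}
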