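# Supervised binary discrimination: stratified 70/30 split, train-only PCA
# projection, SMOTE class balancing, LDA with escalation to an RBF SVM
# tuned by leave-one-out grid search, and the five standard performance
# metrics with Prototaxites fixed as the positive class.

POSITIVE_CLASS <- "Prototaxites"

#' Stratified train/test split
#'
#' Allocates per-class test counts by largest-remainder rounding toward the
#' global target `round(n * test_fraction)`, so the global 70/30 split is
#' respected within rounding while each lineage keeps its ratio. Assignment
#' within a class is random given the seed.
#'
#' @param labels Character vector of class labels (every class needs >= 2
#'   samples), or a `spectral_dataset`.
#' @param test_fraction Fraction of samples for the test set (default 0.30).
#' @param seed Integer seed.
#' @return Object of class `split_plan`: `train`, `test` (integer indices),
#'   `allocation` (per-class test counts), `test_fraction`, `seed`.
#' @export
stratified_split <- function(labels, test_fraction = 0.30, seed = 1L) {
  if (inherits(labels, "spectral_dataset")) labels <- labels$labels
  counts <- table(labels)
  if (any(counts < 2L))
    stop(sprintf("class(es) with < 2 samples cannot be stratified: %s",
                 paste(names(counts)[counts < 2], collapse = ", ")),
         call. = FALSE)
  n <- length(labels)
  target <- round(n * test_fraction)
  if (target < 1L) stop("test set would be empty", call. = FALSE)
  quota <- as.numeric(counts) * test_fraction
  base <- floor(quota)
  rem <- quota - base
  give <- target - sum(base)
  if (give > 0) {
    extra <- order(rem, decreasing = TRUE)[seq_len(give)]
    base[extra] <- base[extra] + 1L
  } else if (give < 0) {
    take <- order(rem, decreasing = FALSE)
    taken <- 0L
    for (i in take) {
      if (taken == -give) break
      if (base[i] > 0) { base[i] <- base[i] - 1L; taken <- taken + 1L }
    }
  }
  alloc <- stats::setNames(as.integer(base), names(counts))
  test <- with_seed(seed, {
    unlist(lapply(names(counts), function(cl) {
      idx <- which(labels == cl)
      sample(idx, alloc[[cl]])
    }), use.names = FALSE)
  })
  test <- sort(test)
  structure(list(train = setdiff(seq_len(n), test), test = test,
                 allocation = alloc, test_fraction = test_fraction,
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' SMOTE minority oversampling
#'
#' Balances class counts by appending synthetic minority points, each drawn
#' on the segment between a random minority sample and one of its k nearest
#' minority neighbours (Euclidean): `x + u * (x_nn - x)`, `u ~ U(0, 1)`.
#' Applied to training data only (after any projection) to avoid leakage.
#'
#' @param features Numeric matrix of training features.
#' @param labels Class labels, one per row.
#' @param k Number of nearest neighbours (default 5; reduced with a warning
#'   when the minority class is smaller than k + 1).
#' @param seed Integer seed.
#' @return List with the augmented `features`, `labels`, and `n_synthetic`.
#' @export
smote <- function(features, labels, k = 5L, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  counts <- table(labels)
  n_max <- max(counts)
  syn_x <- list(); syn_y <- character(0)
  with_seed(seed, {
    for (cl in names(counts)) {
      need <- n_max - counts[[cl]]
      if (need == 0) next
      idx <- which(labels == cl)
      n_min <- length(idx)
      if (n_min < 2L)
        stop(sprintf("SMOTE needs >= 2 samples in class '%s'", cl),
             call. = FALSE)
      kk <- k
      if (kk > n_min - 1L) {
        kk <- n_min - 1L
        warning(sprintf("k reduced to %d for class '%s'", kk, cl),
                call. = FALSE)
      }
      xm <- features[idx, , drop = FALSE]
      dmat <- as.matrix(stats::dist(xm))
      diag(dmat) <- Inf
      nn <- t(apply(dmat, 1, function(d) order(d)[seq_len(kk)]))
      base_i <- sample.int(n_min, need, replace = TRUE)
      nb_i <- vapply(base_i, function(i) nn[i, sample.int(kk, 1)], integer(1))
      u <- stats::runif(need)
      newx <- xm[base_i, , drop = FALSE] +
        u * (xm[nb_i, , drop = FALSE] - xm[base_i, , drop = FALSE])
      syn_x[[cl]] <- newx
      syn_y <- c(syn_y, rep(cl, need))
    }
  })
  aug <- do.call(rbind, c(list(features), syn_x))
  rownames(aug) <- NULL
  list(features = aug, labels = c(labels, syn_y),
       n_synthetic = length(syn_y))
}

#' Fit Gaussian linear discriminant analysis
#'
#' Equal-covariance Gaussian LDA: class means, pooled within-class
#' covariance (ridge 1e-8 x mean diagonal added, with a warning, if it is
#' numerically singular), empirical priors, and the linear discriminant
#' `delta_c(x) = x' S^-1 mu_c - mu_c' S^-1 mu_c / 2 + log pi_c`; prediction
#' is the argmax class.
#'
#' @param x Training feature matrix.
#' @param y Class labels (exactly two classes).
#' @return Object of class `ftirtax_classifier` (kind `"lda"`).
#' @export
fit_lda <- function(x, y) {
  x <- as.matrix(x)
  y <- as.character(y)
  cls <- sort(unique(y))
  if (length(cls) < 2L) stop("LDA needs two classes", call. = FALSE)
  if (length(cls) > 2L) stop("only binary LDA is supported", call. = FALSE)
  mu <- lapply(cls, function(cl) colMeans(x[y == cl, , drop = FALSE]))
  names(mu) <- cls
  n <- nrow(x); p <- ncol(x)
  S <- matrix(0, p, p)
  for (cl in cls) {
    xc <- sweep(x[y == cl, , drop = FALSE], 2, mu[[cl]])
    S <- S + crossprod(xc)
  }
  S <- S / (n - length(cls))
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv) || !all(is.finite(Sinv))) {
    warning("pooled covariance singular; adding ridge 1e-8", call. = FALSE)
    S <- S + diag(1e-8 * mean(diag(S)) + 1e-12, p)
    Sinv <- solve(S)
  }
  priors <- table(y)[cls] / n
  w <- lapply(cls, function(cl) as.numeric(Sinv %*% mu[[cl]]))
  names(w) <- cls
  b <- vapply(cls, function(cl)
    -0.5 * sum(mu[[cl]] * w[[cl]]) + log(priors[[cl]]), numeric(1))
  structure(list(kind = "lda", classes = cls, means = mu, cov = S,
                 priors = as.numeric(priors), w = w, b = b,
                 positive = if (POSITIVE_CLASS %in% cls) POSITIVE_CLASS
                            else cls[1]),
            class = "ftirtax_classifier")
}

#' Fit an RBF SVM with leave-one-out grid search
#'
#' For every (C, gamma) pair the training set is scored by leave-one-out
#' cross-validated accuracy; the model is then refitted on the full
#' training set at the best pair. Ties are broken toward the smallest C,
#' then the smallest gamma (simplest model first). Features are used as
#' given (no internal rescaling: inputs are PC scores).
#'
#' @param x Training feature matrix (>= 3 samples, two classes).
#' @param y Class labels.
#' @param C_grid,gamma_grid Candidate values.
#' @param seed Unused by the deterministic LOO loop; kept for interface
#'   symmetry.
#' @return Object of class `ftirtax_classifier` (kind `"svm-rbf"`) with
#'   `best_C`, `best_gamma`, `loo_accuracy`, `grid` (full LOO table).
#' @export
fit_svm_grid <- function(x, y, C_grid = c(0.01, 0.1, 1, 10, 100),
                         gamma_grid = c(0.001, 0.01, 0.1, 1), seed = 1L) {
  x <- as.matrix(x)
  y <- factor(as.character(y))
  if (nlevels(y) != 2L) stop("SVM task must be binary", call. = FALSE)
  if (nrow(x) < 3L) stop("need >= 3 training samples", call. = FALSE)
  n <- nrow(x)
  grid <- expand.grid(C = sort(C_grid), gamma = sort(gamma_grid))
  grid$loo_accuracy <- NA_real_
  for (g in seq_len(nrow(grid))) {
    ok <- 0L
    feasible <- TRUE
    for (i in seq_len(n)) {
      yi <- y[-i]
      if (nlevels(droplevels(yi)) < 2L) { feasible <- FALSE; break }
      fit <- tryCatch(
        e1071::svm(x[-i, , drop = FALSE], droplevels(yi),
                   kernel = "radial", cost = grid$C[g],
                   gamma = grid$gamma[g], scale = FALSE),
        error = function(e) NULL)
      if (is.null(fit)) { feasible <- FALSE; break }
      pred <- predict(fit, x[i, , drop = FALSE])
      ok <- ok + (as.character(pred) == as.character(y[i]))
    }
    if (feasible) grid$loo_accuracy[g] <- ok / n
  }
  if (all(is.na(grid$loo_accuracy)))
    stop("all grid points degenerate", call. = FALSE)
  # best accuracy; ties -> smallest C then smallest gamma (grid is sorted
  # with C varying fastest, so re-order explicitly)
  ord <- order(-grid$loo_accuracy, grid$C, grid$gamma, na.last = TRUE)
  best <- grid[ord[1L], ]
  fit <- e1071::svm(x, y, kernel = "radial", cost = best$C,
                    gamma = best$gamma, scale = FALSE)
  structure(list(kind = "svm-rbf", classes = levels(y), fit = fit,
                 best_C = best$C, best_gamma = best$gamma,
                 loo_accuracy = best$loo_accuracy, grid = grid,
                 positive = if (POSITIVE_CLASS %in% levels(y)) POSITIVE_CLASS
                            else levels(y)[1]),
            class = "ftirtax_classifier")
}

#' Predict class labels
#'
#' @param object A `ftirtax_classifier`.
#' @param newdata Feature matrix.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.ftirtax_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$kind == "lda") {
    delta <- vapply(object$classes, function(cl)
      as.numeric(newdata %*% object$w[[cl]]) + object$b[[cl]],
      numeric(nrow(newdata)))
    delta <- matrix(delta, nrow = nrow(newdata))
    object$classes[max.col(delta, ties.method = "first")]
  } else {
    as.character(predict(object$fit, newdata))
  }
}

#' Binary performance metrics
#'
#' Confusion matrix and the five metrics (accuracy, precision, recall, F1,
#' MCC) with Prototaxites as the positive class whenever present. When any
#' factor of the MCC denominator is zero, MCC is defined as 0 with a
#' warning.
#'
#' @param model A `ftirtax_classifier`.
#' @param x Test feature matrix (non-empty).
#' @param y True labels (must be within the model's two classes).
#' @return Object of class `metrics_report`: `confusion` (TP, FP, FN, TN),
#'   `accuracy`, `precision`, `recall`, `f1`, `mcc`, `positive`.
#' @export
evaluate <- function(model, x, y) {
  y <- as.character(y)
  if (!length(y)) stop("empty test set", call. = FALSE)
  bad <- setdiff(unique(y), model$classes)
  if (length(bad))
    stop(sprintf("label(s) outside the model's classes: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  pred <- predict(model, x)
  metrics_from_predictions(pred, y, model$positive)
}

metrics_from_predictions <- function(pred, truth, positive) {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  tn <- sum(pred != positive & truth != positive)
  acc <- (tp + tn) / (tp + fp + fn + tn)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom <= 0) {
    warning("zero factor in MCC denominator; MCC set to 0", call. = FALSE)
    mcc <- 0
  } else {
    mcc <- (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  }
  structure(list(confusion = c(TP = tp, FP = fp, FN = fn, TN = tn),
                 accuracy = acc, precision = prec, recall = rec, f1 = f1,
                 mcc = mcc, positive = positive),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "confusion TP=%d FP=%d FN=%d TN=%d | acc %.3f prec %.3f rec %.3f F1 %.3f MCC %.3f\n",
    x$confusion["TP"], x$confusion["FP"], x$confusion["FN"],
    x$confusion["TN"], x$accuracy, x$precision, x$recall, x$f1, x$mcc))
  invisible(x)
}

loo_accuracy <- function(x, y, fit_fun) {
  n <- nrow(x)
  ok <- 0L
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (length(unique(yi)) < 2L) return(NA_real_)
    m <- fit_fun(x[-i, , drop = FALSE], yi)
    ok <- ok + (predict(m, x[i, , drop = FALSE]) == y[i])
  }
  ok / n
}

#' Learning curve
#'
#' Repeatedly subsamples stratified fractions of the data, fits the given
#' model kind, and records leave-one-out accuracy, to check whether the
#' sample size is sufficient. Fraction 1.0 is deterministic (sd 0).
#' Fractions leaving any class with < 2 samples are skipped with a warning.
#'
#' @param x Feature matrix.
#' @param y Labels.
#' @param kind `"lda"` or `"svm-rbf"` (fixed `C`, `gamma`).
#' @param fractions Numeric vector in (0, 1].
#' @param n_repeats Subsample repeats per fraction (default 5).
#' @param seed Integer seed.
#' @param C,gamma SVM parameters when `kind = "svm-rbf"`.
#' @return Data frame with `fraction`, `mean_accuracy`, `sd_accuracy`, `n`.
#' @export
learning_curve <- function(x, y, kind = c("lda", "svm-rbf"),
                           fractions = seq(0.3, 1, by = 0.1),
                           n_repeats = 5L, seed = 1L, C = 1, gamma = 0.1) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  y <- as.character(y)
  fit_fun <- if (kind == "lda") fit_lda else function(xx, yy)
    structure(list(kind = "svm-rbf",
                   classes = sort(unique(yy)),
                   fit = e1071::svm(xx, factor(yy), kernel = "radial",
                                    cost = C, gamma = gamma, scale = FALSE),
                   positive = POSITIVE_CLASS),
              class = "ftirtax_classifier")
  rows <- list()
  for (f in fractions) {
    accs <- c()
    for (rep in seq_len(if (f >= 1) 1L else n_repeats)) {
      idx <- if (f >= 1) seq_along(y) else with_seed(
        derive_seed(seed, round(f * 1000) + rep), {
          unlist(lapply(unique(y), function(cl) {
            ii <- which(y == cl)
            sample(ii, max(2L, round(length(ii) * f)))
          }))
        })
      if (min(table(y[idx])) < 2L) next
      a <- loo_accuracy(x[idx, , drop = FALSE], y[idx], fit_fun)
      if (!is.na(a)) accs <- c(accs, a)
    }
    if (!length(accs)) {
      warning(sprintf("fraction %.2f infeasible; skipped", f), call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      fraction = f, mean_accuracy = mean(accs),
      sd_accuracy = if (length(accs) > 1) stats::sd(accs) else 0,
      n = length(accs))
  }
  do.call(rbind, rows)
}

TASK_NEGATIVES <- list(
  "vs-bacteria" = "Bacteria",
  "vs-fungi" = "Fungi",
  "vs-chitinous" = c("Fungi", "Arthropoda"),
  "vs-plants" = "Plantae")

#' Run one binary discrimination task end to end
#'
#' Composes the supervised stage: subset the relevant classes, preprocess
#' raw spectra (ATR recipe) if needed, stratified 70/30 split by lineage,
#' PCA fitted on the training rows only (2 components for the nearly
#' balanced vs-bacteria task, 4 otherwise), projection of the test rows,
#' SMOTE balancing of the training scores when the class imbalance exceeds
#' 1.25, LDA first, escalating to the grid-searched RBF SVM when the LDA
#' leave-one-out accuracy falls below the threshold (default 0.95). Train
#' metrics are computed on the real (non-synthetic) training samples.
#'
#' @param dataset A labelled `spectral_dataset`.
#' @param task One of `"vs-bacteria"`, `"vs-fungi"`, `"vs-chitinous"`,
#'   `"vs-plants"`.
#' @param config Optional overrides: `test_fraction`, `n_pcs`, `smote_k`,
#'   `smote_imbalance`, `lda_threshold`, `C_grid`, `gamma_grid`, `seed`,
#'   `preprocess` (logical or recipe name).
#' @return List of class `binary_task_result`: `task`, `model`, `split`,
#'   `pca`, `train_metrics`, `test_metrics`, `audit`.
#' @export
run_binary_task <- function(dataset, task = names(TASK_NEGATIVES),
                            config = list()) {
  task <- match.arg(task)
  neg <- TASK_NEGATIVES[[task]]
  cfg <- utils::modifyList(list(
    test_fraction = 0.30,
    n_pcs = if (task == "vs-bacteria") 2L else 4L,
    smote_k = 5L, smote_imbalance = 1.25, lda_threshold = 0.95,
    C_grid = c(0.01, 0.1, 1, 10, 100), gamma_grid = c(0.001, 0.01, 0.1, 1),
    seed = 1L, preprocess = TRUE), config)
  need <- c(POSITIVE_CLASS, neg)
  missing_cls <- setdiff(need, unique(dataset$labels))
  if (length(missing_cls))
    stop(sprintf("dataset lacks class(es): %s",
                 paste(missing_cls, collapse = ", ")), call. = FALSE)
  sub <- subset_dataset(dataset, dataset$labels %in% need)
  raw <- all(vapply(sub$spectra, function(s) length(s$history) == 0L,
                    logical(1)))
  if (raw && !isFALSE(cfg$preprocess)) {
    recipe <- if (is.character(cfg$preprocess)) cfg$preprocess else "atr-paper"
    sub <- apply_recipe(sub, recipe)
  }
  x <- as_matrix(sub)
  lineage <- sub$labels
  ybin <- ifelse(lineage == POSITIVE_CLASS, POSITIVE_CLASS, task_negative_name(task))
  split <- stratified_split(lineage, cfg$test_fraction, cfg$seed)
  pca <- fit_pca(x[split$train, , drop = FALSE], n_components = cfg$n_pcs)
  tr_scores <- pca$scores
  te_scores <- predict(pca, x[split$test, , drop = FALSE])
  ytr <- ybin[split$train]; yte <- ybin[split$test]
  counts <- table(ytr)
  imbalance <- max(counts) / min(counts)
  smoted <- imbalance > cfg$smote_imbalance
  if (smoted) {
    aug <- smote(tr_scores, ytr, k = cfg$smote_k,
                 seed = derive_seed(cfg$seed, 2L))
    fit_x <- aug$features; fit_y <- aug$labels
  } else {
    fit_x <- tr_scores; fit_y <- ytr
  }
  lda_model <- fit_lda(fit_x, fit_y)
  lda_loo <- loo_accuracy(fit_x, fit_y, fit_lda)
  escalated <- is.na(lda_loo) || lda_loo < cfg$lda_threshold
  model <- if (escalated)
    fit_svm_grid(fit_x, fit_y, cfg$C_grid, cfg$gamma_grid,
                 seed = derive_seed(cfg$seed, 3L))
  else lda_model
  train_metrics <- evaluate(model, tr_scores, ytr)
  test_metrics <- evaluate(model, te_scores, yte)
  structure(list(
    task = task, model = model, split = split, pca = pca,
    train_metrics = train_metrics, test_metrics = test_metrics,
    audit = list(n_train = length(split$train), n_test = length(split$test),
                 n_pcs = cfg$n_pcs, smote_applied = smoted,
                 imbalance_ratio = as.numeric(imbalance),
                 lda_loo_accuracy = lda_loo, escalated_to_svm = escalated,
                 best_C = if (escalated) model$best_C else NA,
                 best_gamma = if (escalated) model$best_gamma else NA,
                 test_fraction = cfg$test_fraction, seed = cfg$seed,
                 lda_threshold = cfg$lda_threshold)),
    class = "binary_task_result")
}

task_negative_name <- function(task) {
  switch(task, "vs-bacteria" = "Bacteria", "vs-fungi" = "Fungi",
         "vs-chitinous" = "Chitinous", "vs-plants" = "Plantae")
}
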