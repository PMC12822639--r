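test_that("stratified split follows largest-remainder allocation", {
  labs <- rep(c("Prototaxites", "Fungi"), times = c(12, 24))
  plan <- stratified_split(labs, 0.30, seed = 1)
  # oracle: global target round(36 * .3) = 11; floors 3 + 7; remainder .6
  # beats .2, so Prototaxites receives the extra slot
  expect_equal(plan$allocation[["Prototaxites"]], 4L)
  expect_equal(plan$allocation[["Fungi"]], 7L)
  expect_length(plan$test, 11)
  expect_length(intersect(plan$train, plan$test), 0)
  expect_setequal(c(plan$train, plan$test), seq_along(labs))
  plan2 <- stratified_split(labs, 0.30, seed = 1)
  expect_identical(plan, plan2)
  expect_error(stratified_split(labs, 0, seed = 1), "empty")
  expect_error(stratified_split(c("A", "A", "B"), 0.3), "< 2 samples")
})

test_that("SMOTE balances classes with on-segment synthetic points", {
  x <- withr::with_seed(2, rbind(matrix(rnorm(16), 8, 2),
                                 matrix(rnorm(48, 5), 24, 2)))
  y <- rep(c("Prototaxites", "Fungi"), times = c(8, 24))
  aug <- smote(x, y, k = 5, seed = 3)
  expect_equal(aug$n_synthetic, 16)
  expect_equal(as.integer(table(aug$labels)), c(24L, 24L))
  syn <- aug$features[33:48, ]
  real <- x[1:8, ]
  on_segment <- vapply(seq_len(nrow(syn)), function(i) {
    s <- syn[i, ]
    any(vapply(1:7, function(a) any(vapply((a + 1):8, function(b) {
      u <- real[b, ] - real[a, ]; v <- s - real[a, ]
      cr <- abs(u[1] * v[2] - u[2] * v[1])
      tpar <- sum(v * u) / sum(u * u)
      cr < 1e-10 && tpar >= -1e-10 && tpar <= 1 + 1e-10
    }, logical(1))), logical(1)))
  }, logical(1))
  expect_true(all(on_segment))
  aug2 <- smote(x, y, k = 5, seed = 3)
  expect_identical(aug, aug2)
  expect_warning(smote(x[c(1:3, 9:20), ], y[c(1:3, 9:20)], k = 5, seed = 1),
                 "k reduced")
  expect_error(smote(x[c(1, 9:12), ], y[c(1, 9:12)]), ">= 2")
})

test_that("LDA separates point masses and respects mirror symmetry", {
  x <- rbind(matrix(rep(c(0, 0), 5), ncol = 2, byrow = TRUE) +
               withr::with_seed(1, matrix(rnorm(10, 0, 1e-3), 5)),
             matrix(rep(c(4, 4), 5), ncol = 2, byrow = TRUE) +
               withr::with_seed(2, matrix(rnorm(10, 0, 1e-3), 5)))
  y <- rep(c("Fungi", "Prototaxites"), each = 5)
  m <- fit_lda(x, y)
  expect_identical(predict(m, x), y)
  # mirrored classes with equal priors: discriminants agree at the origin
  xm <- rbind(withr::with_seed(3, matrix(rnorm(20, 2), 10)),
              -withr::with_seed(3, matrix(rnorm(20, 2), 10)))
  ym <- rep(c("Fungi", "Prototaxites"), each = 10)
  mm <- fit_lda(xm, ym)
  d0 <- vapply(mm$classes, function(cl) mm$b[[cl]], numeric(1))
  expect_lt(abs(d0[1] - d0[2]), 1e-10)
  expect_error(fit_lda(x, rep("Fungi", 10)), "two classes")
})

test_that("LDA agrees with the MASS reference implementation", {
  x <- withr::with_seed(4, rbind(matrix(rnorm(40), 20, 2),
                                 matrix(rnorm(40, 2.5), 20, 2)))
  y <- rep(c("Fungi", "Prototaxites"), each = 20)
  m <- fit_lda(x, y)
  ref <- MASS::lda(x, grouping = factor(y))
  grid <- as.matrix(expand.grid(seq(-2, 5, by = 0.5), seq(-2, 5, by = 0.5)))
  colnames(grid) <- NULL
  expect_identical(predict(m, grid),
                   as.character(predict(ref, grid)$class))
})

test_that("well-separated Gaussian clouds give perfect LOO accuracy", {
  x <- withr::with_seed(5, rbind(matrix(rnorm(24), 12, 2),
                                 matrix(rnorm(24, 6), 12, 2)))
  y <- rep(c("Fungi", "Prototaxites"), each = 12)
  expect_equal(ftirtax:::loo_accuracy(x, y, fit_lda), 1)
  m <- fit_svm_grid(x, y)
  expect_equal(m$loo_accuracy, 1)
  expect_true(m$best_C %in% c(0.01, 0.1, 1, 10, 100))
  expect_true(m$best_gamma %in% c(0.001, 0.01, 0.1, 1))
})

test_that("SVM grid ties resolve to the smallest C then smallest gamma", {
  # trivially separable, far apart: most grid points reach LOO accuracy 1
  x <- rbind(matrix(c(0, 0.1, -0.1, 0.05, 0.02, -0.04), 3, 2),
             matrix(c(100, 100.1, 99.9, 100.05, 100.02, 99.96), 3, 2))
  y <- rep(c("Fungi", "Prototaxites"), each = 3)
  m <- fit_svm_grid(x, y, C_grid = c(1, 10), gamma_grid = c(0.01, 0.1))
  top <- m$grid[m$grid$loo_accuracy == max(m$grid$loo_accuracy), ]
  expect_equal(m$best_C, min(top$C))
  expect_equal(m$best_gamma, min(top$gamma[top$C == m$best_C]))
})

test_that("metrics match their defining formulas", {
  x <- matrix(0, 4, 1)  # features unused by the direct-formula check below
  perfect <- ftirtax:::metrics_from_predictions(
    rep(c("Prototaxites", "Fungi"), each = 2),
    rep(c("Prototaxites", "Fungi"), each = 2), "Prototaxites")
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$f1, 1)
  # TP=4, TN=25, FP=2, FN=1 -> MCC = 98 / sqrt(21060)
  truth <- c(rep("Prototaxites", 5), rep("Fungi", 27))
  pred <- c(rep("Prototaxites", 4), "Fungi",
            rep("Prototaxites", 2), rep("Fungi", 25))
  m <- ftirtax:::metrics_from_predictions(pred, truth, "Prototaxites")
  expect_equal(unname(m$confusion), c(4L, 2L, 1L, 25L))
  expect_equal(m$mcc, 98 / sqrt(21060), tolerance = 1e-12)
  expect_equal(m$accuracy, 29 / 32)
  # all-one-class predictions: zero-factor convention sets MCC to 0
  expect_warning(
    z <- ftirtax:::metrics_from_predictions(
      rep("Fungi", 10), rep(c("Fungi", "Prototaxites"), 5), "Prototaxites"),
    "MCC")
  expect_equal(z$mcc, 0)
})

test_that("learning curves are deterministic at full fraction and improve with data", {
  x <- withr::with_seed(6, rbind(matrix(rnorm(60), 30, 2),
                                 matrix(rnorm(60, 3), 30, 2)))
  y <- rep(c("Fungi", "Prototaxites"), each = 30)
  lc <- learning_curve(x, y, "lda", fractions = c(0.3, 1.0), n_repeats = 3,
                       seed = 2)
  expect_equal(nrow(lc), 2)
  expect_equal(lc$sd_accuracy[lc$fraction == 1], 0)
  expect_gte(lc$mean_accuracy[lc$fraction == 1],
             lc$mean_accuracy[lc$fraction == 0.3])
})

test_that("binary tasks run end to end with an audit trail and no leakage", {
  ds <- generate_dataset(study_design(seed = 42))
  proc <- apply_recipe(ds, "atr-paper")
  res <- run_binary_task(proc, "vs-bacteria", config = list(seed = 7))
  expect_gte(res$test_metrics$accuracy, 0.9)
  expect_equal(res$audit$n_pcs, 2L)
  res_ch <- run_binary_task(proc, "vs-chitinous", config = list(seed = 7))
  expect_equal(res_ch$audit$n_train + res_ch$audit$n_test - 12L, 36L)
  expect_equal(res_ch$audit$n_pcs, 4L)
  audit <- res_ch$audit
  expect_true(all(c("n_train", "n_test", "n_pcs", "smote_applied",
                    "lda_loo_accuracy", "escalated_to_svm", "test_fraction",
                    "seed") %in% names(audit)))
  expect_error(run_binary_task(subset_dataset(proc, proc$labels == "Fungi"),
                               "vs-fungi"), "lacks class")
  # leakage check: altering only test-row spectra leaves the fit unchanged
  res1 <- run_binary_task(proc, "vs-fungi", config = list(seed = 7))
  sub <- subset_dataset(proc, proc$labels %in% c("Prototaxites", "Fungi"))
  tampered <- sub
  for (i in res1$split$test)
    tampered$spectra[[i]]$absorbance <-
      tampered$spectra[[i]]$absorbance + 0.5
  res2 <- suppressWarnings(
    run_binary_task(tampered, "vs-fungi", config = list(seed = 7)))
  expect_identical(res1$split$test, res2$split$test)
  if (res1$model$kind == "lda" && res2$model$kind == "lda") {
    expect_equal(res1$model$w, res2$model$w, tolerance = 1e-10)
    expect_equal(res1$model$b, res2$model$b, tolerance = 1e-10)
  }
  expect_equal(res1$pca$loadings, res2$pca$loadings, tolerance = 1e-10)
})
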