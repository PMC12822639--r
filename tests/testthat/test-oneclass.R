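test_that("moment estimation recovers chi-square degrees of freedom", {
  x <- withr::with_seed(1, 1.7 * rchisq(5000, 4) / 4)
  est <- ftirtax:::estimate_chisq_dof(x, "moments")
  expect_equal(est$dof, 4L)
  expect_equal(est$scale, 1.7, tolerance = 0.05)
  est_r <- ftirtax:::estimate_chisq_dof(x, "robust")
  expect_lte(abs(est_r$dof - 4L), 1)
  # robust and moments agree within one dof on clean data
  x2 <- withr::with_seed(2, 3 * rchisq(1000, 6) / 6)
  expect_lte(abs(ftirtax:::estimate_chisq_dof(x2, "moments")$dof -
                   ftirtax:::estimate_chisq_dof(x2, "robust")$dof), 1)
})

test_that("degenerate equal distances fall back to one degree of freedom", {
  expect_warning(
    est <- ftirtax:::estimate_chisq_dof(rep(2, 6), "moments"), "dof set to 1")
  expect_equal(est$dof, 1L)
  # four points on a circle: every score distance equals 1.5 with two
  # retained components, so the score-distance variance is zero
  x <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  expect_warning(m <- fit_ddsimca(x, 2, mode = "moments"), "dof set to 1")
  expect_equal(m$n_sd, 1L)
})

test_that("the training centroid has zero score distance", {
  x <- withr::with_seed(3, matrix(rnorm(60), 20, 3))
  m <- fit_ddsimca(x, 2)
  d <- predict_membership(m, matrix(m$pca$mean, nrow = 1))
  expect_equal(d$sd, 0, tolerance = 1e-20)
  expect_error(predict_membership(m, matrix(0, 1, 5)), "dimension")
})

test_that("raising alpha strictly shrinks the acceptance region", {
  x <- withr::with_seed(4, matrix(rnorm(200), 50, 4))
  m <- fit_ddsimca(x, 2, alpha = 0.05)
  q <- withr::with_seed(5, matrix(rnorm(400), 100, 4))
  strict <- predict_membership(m, q, alpha = 0.20)
  loose <- predict_membership(m, q, alpha = 0.01)
  expect_true(all(loose$accepted[strict$accepted]))
  expect_gte(sum(loose$accepted), sum(strict$accepted))
})

test_that("in-class acceptance approximates the nominal level", {
  prof <- default_profiles()$Prototaxites
  g <- default_grid()
  gen_feats <- function(n, seed0) {
    sp <- lapply(seq_len(n), function(i)
      generate_spectrum(prof, g, seed = ftirtax:::derive_seed(seed0, i),
                        sample_id = "p", taxon = "Prototaxites"))
    suppressWarnings(extract_band_matrix(new_spectral_dataset(sp)))
  }
  m <- fit_ddsimca(gen_feats(600, 31), 2, alpha = 0.05, mode = "moments")
  cov <- mean(predict_membership(m, gen_feats(2000, 77))$accepted)
  expect_gt(cov, 0.91)
  expect_lt(cov, 0.985)
})

test_that("specificity separates distant aliens and is a weighted mean", {
  x <- withr::with_seed(6, matrix(rnorm(120), 30, 4))
  m <- fit_ddsimca(x, 2)
  sds <- apply(x, 2, sd)
  aliens <- withr::with_seed(7, matrix(rnorm(80), 20, 4)) +
    matrix(10 * sds, 20, 4, byrow = TRUE)
  labs <- rep(c("Bacteria", "Plantae"), each = 10)
  sp <- specificity(m, aliens, labs)
  expect_equal(sp$pooled, 1)
  expect_equal(sp$pooled,
               sum(sp$per_class * table(labs)[names(sp$per_class)]) /
                 length(labs))
  # aliens indistinguishable from the target class are mostly accepted
  twin <- specificity(m, withr::with_seed(8, matrix(rnorm(120), 30, 4)))
  expect_lt(twin$pooled, 0.4)
})

test_that("accept/reject decisions are invariant under common rescaling", {
  x <- withr::with_seed(9, matrix(rnorm(120), 30, 4))
  q <- withr::with_seed(10, matrix(rnorm(60, 0.5), 15, 4))
  d1 <- predict_membership(fit_ddsimca(x, 2), q)
  d2 <- predict_membership(fit_ddsimca(5 * x, 2), 5 * q)
  expect_identical(d1$accepted, d2$accepted)
  expect_equal(d1$c, d2$c, tolerance = 1e-8)
})

test_that("the acceptance region is convex in the scaled distance plane", {
  x <- withr::with_seed(11, matrix(rnorm(200), 50, 4))
  m <- fit_ddsimca(x, 2)
  d <- predict_membership(m, x)
  acc <- which(d$accepted)
  pairs <- utils::combn(acc[seq_len(min(10, length(acc)))], 2)
  for (j in seq_len(ncol(pairs))) {
    mid_c <- m$n_sd * mean(d$sd[pairs[, j]]) / m$sd0 +
      m$n_od * mean(d$od[pairs[, j]]) / m$od0
    expect_lte(mid_c, m$c_crit + 1e-12)
  }
})

test_that("component selection by sensitivity honors its contract", {
  x <- withr::with_seed(12, matrix(rnorm(25 * 6), 25, 6))
  single <- select_components_by_sensitivity(x, 2)
  expect_equal(single$chosen, 2)
  expect_length(single$sensitivity, 1)
  sel <- select_components_by_sensitivity(x, 1:4)
  expect_true(all(sel$sensitivity >= 0 & sel$sensitivity <= 1))
  expect_true(sel$chosen %in% 1:4)
  # ties resolve to the smallest candidate
  expect_equal(sel$chosen,
               as.integer(names(sel$sensitivity)[
                 which.max(sel$sensitivity)]))
  expect_error(select_components_by_sensitivity(x[1:3, ], 5:8), "feasible")
})

test_that("training outliers are flagged and reported, not removed", {
  x <- withr::with_seed(13, matrix(rnorm(120), 30, 4))
  x[4, ] <- x[4, ] + 15
  m <- fit_ddsimca(x, 2, mode = "robust")
  expect_true(m$train_outlier_flags[4])
  expect_equal(length(m$sd_train), 30)  # nothing was dropped
})
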