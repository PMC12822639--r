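test_that("default design reproduces the study's per-class counts", {
  d <- study_design()
  expect_equal(d$total, 102)
  expect_equal(d$counts[["Prototaxites"]], 12)
  expect_equal(d$counts[["Plantae"]], 37)
  ds <- generate_dataset(d, seed = 5)
  expect_length(ds$spectra, 102)
  tab <- table(ds$labels)
  expect_equal(tab[["Fungi"]], 24)
  expect_equal(tab[["Arthropoda"]], 12)
  expect_equal(tab[["Bacteria"]], 10)
  expect_equal(tab[["Oomycetes"]], 4)
  expect_equal(tab[["Amoebae"]], 3)
  expect_equal(tab[["Prototaxites"]], 12)
  expect_equal(nrow(ds$onehot), 102)
  expect_true(all(rowSums(ds$onehot) == 1))
})

test_that("default profiles encode the class contrasts by construction", {
  pr <- default_profiles()
  chit <- c("Fungi", "Arthropoda", "Oomycetes", "Amoebae")
  rest <- c("Bacteria", "Plantae", "Prototaxites")
  for (band in c("amide_I", "amide_II", "n_products", "carboxylate")) {
    lo <- max(vapply(rest, function(cl) pr[[cl]]$band_means[[band]],
                     numeric(1)))
    hi <- min(vapply(chit, function(cl) pr[[cl]]$band_means[[band]],
                     numeric(1)))
    expect_gt(hi, lo)
  }
  ali <- vapply(names(pr), function(cl)
    pr[[cl]]$band_means[["ch2_asym"]] + pr[[cl]]$band_means[["ch3_asym"]],
    numeric(1))
  expect_identical(names(which.max(ali)), "Bacteria")
  combined <- vapply(names(pr), function(cl)
    sum(pr[[cl]]$band_means[c("amide_I", "amide_II", "n_products",
                              "carboxylate", "ch2_asym", "ch3_asym")]),
    numeric(1))
  expect_identical(names(which.min(combined)), "Prototaxites")
  expect_gt(pr$Prototaxites$band_means[["aromatic_cc"]], 0)
  expect_gt(pr$Prototaxites$band_means[["carbonyl"]], 0)
  expect_lt(pr$Prototaxites$band_means[["amide_I"]],
            pr$Fungi$band_means[["amide_I"]])
  expect_true(all(vapply(pr, function(p) p$silica_mean > 0, logical(1))))
})

test_that("generation is seed-deterministic and the noise-free limit is the band sum", {
  pr <- default_profiles()$Fungi
  g <- default_grid()
  s1 <- generate_spectrum(pr, g, seed = 99)
  s2 <- generate_spectrum(pr, g, seed = 99)
  expect_identical(s1$absorbance, s2$absorbance)
  s3 <- generate_spectrum(pr, g, seed = 100)
  expect_false(identical(s1$absorbance, s3$absorbance))
  nf <- generate_spectrum(noise_free_profile(), g, seed = 1)
  expect_equal(nf$absorbance, band_sum(noise_free_profile(), g),
               tolerance = 1e-12)
  expect_error(generate_spectrum(pr, numeric(0), seed = 1), "empty grid")
})

test_that("aliphatic peak height tracks the profile's CH2 mean", {
  g <- default_grid()
  means <- seq(0.1, 0.8, length.out = 200)
  heights <- vapply(seq_along(means), function(i) {
    p <- default_profiles()$Bacteria
    p$band_means[["ch2_asym"]] <- means[i]
    s <- generate_spectrum(p, g, seed = 4000 + i)
    max(s$absorbance[g >= 2910 & g <= 2940])
  }, numeric(1))
  expect_gt(stats::cor(means, heights), 0.9)
})

test_that("two different master seeds change values but not labels", {
  d <- study_design(counts = c(Fungi = 4, Prototaxites = 3))
  a <- generate_dataset(d, seed = 1)
  b <- generate_dataset(d, seed = 2)
  expect_identical(a$labels, b$labels)
  expect_false(identical(as_matrix(a), as_matrix(b)))
  # a zero-count class is absent
  d0 <- study_design(counts = c(Fungi = 4, Prototaxites = 3, Bacteria = 0))
  expect_false("Bacteria" %in% generate_dataset(d0, seed = 1)$labels)
  expect_error(generate_dataset(study_design(counts = c(Fungi = 2)),
                                profiles = list()), "missing profile")
})

test_that("generated amide-I contrast between Fungi and Prototaxites is strong", {
  ds <- generate_dataset(study_design(counts = c(Fungi = 20,
                                                 Prototaxites = 20)),
                         seed = 8)
  bm <- suppressWarnings(extract_band_matrix(ds))
  fu <- bm[ds$labels == "Fungi", "amide_I"]
  pt <- bm[ds$labels == "Prototaxites", "amide_I"]
  noise_sd <- default_profiles()$Fungi$noise_sd
  expect_gt(mean(fu) - mean(pt), 2 * noise_sd)
})

test_that("outlier injection perturbs, converges and records history", {
  s <- generate_spectrum(default_profiles()$Fungi, default_grid(), seed = 3)
  tiny <- inject_outlier(s, "spike", magnitude = 1e-9, seed = 7)
  expect_lt(max(abs(tiny$absorbance - s$absorbance)), 1e-8)
  sp <- inject_outlier(s, "spike", magnitude = 0.5, seed = 7)
  expect_gt(max(abs(sp$absorbance - s$absorbance)), 0.4)
  last <- sp$history[[length(sp$history)]]
  expect_identical(last$step, "inject_outlier")
  expect_identical(last$kind, "spike")
  jump <- inject_outlier(s, "baseline-jump", magnitude = 0.3, seed = 2)
  expect_equal(sort(unique(round(jump$absorbance - s$absorbance, 9))),
               c(0, 0.3))
  expect_error(inject_outlier(s, "spike", magnitude = -1), "positive")
  expect_error(inject_outlier(s, "wrong-class-mixture", magnitude = 1),
               "mix_profile")
  mix <- inject_outlier(s, "wrong-class-mixture", magnitude = 1, seed = 1,
                        mix_profile = default_profiles()$Bacteria)
  expect_gt(max(mix$absorbance - s$absorbance), 0.5)
})
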