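# Synthetic spectrum generator
#
# Emulates the study design of a multi-taxon chert assemblage: seven taxon
# classes with fixed per-class sample counts, class-specific band-intensity
# profiles, a shared silica matrix band near 1615 cm^-1, low-order baseline
# drift, and additive Gaussian noise. Band shapes are Gaussian; widths below
# are Gaussian standard deviations in cm^-1 (FWHM roughly 15-40 cm^-1).

# Band set used by the generator: the six feature bands plus an aromatic
# C=C and a carbonyl band so that taxa depleted in amide and aliphatic
# signal still carry organic structure.
GEN_BANDS <- data.frame(
  name   = c("amide_I", "amide_II", "n_products", "carboxylate",
             "aromatic_cc", "carbonyl", "ch2_asym", "ch3_asym"),
  center = c(1655, 1545, 1590, 1560, 1600, 1710, 2925, 2960),
  sd     = c(15, 13, 8, 8, 12, 11, 8, 7),
  stringsAsFactors = FALSE)

SILICA_CENTER <- 1615
SILICA_SD <- 17

#' Study design for synthetic datasets
#'
#' Default per-class sample counts match the analysed assemblage: Plantae
#' 37, Fungi 24, Arthropoda 12, Bacteria 10, Oomycetes 4, Amoebae 3 and
#' Prototaxites 12 (102 samples in total), on a 650-4000 cm^-1 grid at
#' 4 cm^-1 steps.
#'
#' @param counts Named integer vector of per-class sample counts.
#' @param grid Wavenumber grid (ascending, cm^-1).
#' @param seed Integer master seed.
#' @return Object of class `study_design`.
#' @export
study_design <- function(counts = c(Plantae = 37, Fungi = 24,
                                    Arthropoda = 12, Bacteria = 10,
                                    Oomycetes = 4, Amoebae = 3,
                                    Prototaxites = 12),
                         grid = seq(650, 4000, by = 4), seed = 1L) {
  stopifnot(!is.null(names(counts)), all(counts >= 0),
            all(names(counts) %in% TAXON_CLASSES))
  structure(list(counts = counts, grid = as.numeric(grid),
                 seed = as.integer(seed), total = sum(counts)),
            class = "study_design")
}

#' Class-specific spectral profile
#'
#' @param band_means Named numeric vector of mean band heights (absorbance,
#'   relative to a silica band of mean height 1), named after the
#'   generator's band set.
#' @param band_cv Coefficient of variation of band heights across samples
#'   (lognormal multiplicative scatter; 0 disables it).
#' @param silica_mean,silica_cv Mean and CV of the silica matrix band.
#' @param baseline_scale Standard deviation of the degree-2 baseline
#'   polynomial coefficients (0 disables drift).
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param jitter_sd Standard deviation of per-band center jitter (cm^-1).
#' @return Object of class `class_profile`.
#' @export
class_profile <- function(band_means, band_cv = 0.12, silica_mean = 1,
                          silica_cv = 0.08, baseline_scale = 0.02,
                          noise_sd = 0.01, jitter_sd = 2) {
  stopifnot(all(band_means >= 0), band_cv >= 0, silica_mean >= 0,
            noise_sd >= 0, jitter_sd >= 0)
  miss <- setdiff(GEN_BANDS$name, names(band_means))
  if (length(miss))
    stop(sprintf("band_means missing: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  structure(list(band_means = band_means[GEN_BANDS$name], band_cv = band_cv,
                 silica_mean = silica_mean, silica_cv = silica_cv,
                 baseline_degree = 2L, baseline_scale = baseline_scale,
                 noise_sd = noise_sd, jitter_sd = jitter_sd),
            class = "class_profile")
}

#' Default class profiles
#'
#' Encodes the qualitative contrasts the classification relies on:
#' chitinous classes (Fungi, Arthropoda, Oomycetes, Amoebae) are rich in
#' amide I/II, N-bearing products and carboxylate; Bacteria dominate the
#' aliphatic CHx bands; Prototaxites and Plantae are depleted in both, with
#' Prototaxites carrying the lowest combined amide + aliphatic signal but a
#' clear aromatic/carbonyl fingerprint. The numeric levels are generator
#' parameters of this package, not measured fossil values. The Prototaxites
#' CH3:CH2 mean ratio is 0.75, emulating the reported aliphatic signature.
#'
#' @return Named list of [class_profile()] objects, one per taxon class.
#' @export
default_profiles <- function() {
  m <- function(...) {
    v <- c(...)
    names(v) <- GEN_BANDS$name
    v
  }
  #            amideI amideII Nprod  COO-  aromC=C C=O   CH2   CH3
  list(
    Prototaxites = class_profile(m(0.06, 0.05, 0.05, 0.05, 0.45, 0.35, 0.10, 0.075)),
    Fungi        = class_profile(m(0.55, 0.45, 0.40, 0.38, 0.25, 0.28, 0.30, 0.24)),
    Arthropoda   = class_profile(m(0.60, 0.50, 0.42, 0.40, 0.22, 0.26, 0.32, 0.25)),
    Oomycetes    = class_profile(m(0.50, 0.42, 0.38, 0.36, 0.24, 0.27, 0.28, 0.22)),
    Amoebae      = class_profile(m(0.52, 0.44, 0.39, 0.37, 0.23, 0.26, 0.29, 0.23)),
    Bacteria     = class_profile(m(0.16, 0.13, 0.12, 0.14, 0.18, 0.20, 0.80, 0.60)),
    Plantae      = class_profile(m(0.14, 0.11, 0.10, 0.12, 0.35, 0.30, 0.16, 0.13))
  )
}

#' Generate one synthetic spectrum
#'
#' The spectrum is a sum of Gaussian bands (centers jittered, heights drawn
#' from a lognormal with the profile's mean and CV), a silica matrix band at
#' 1615 cm^-1, a random degree-2 baseline polynomial and i.i.d. Gaussian
#' noise. Bit-identical output for identical `(profile, grid, seed)`.
#'
#' @param profile A [class_profile()].
#' @param grid Ascending wavenumber grid (cm^-1).
#' @param seed Integer seed.
#' @param sample_id,taxon,instrument_mode Metadata for the spectrum.
#' @return A [new_spectrum()].
#' @export
generate_spectrum <- function(profile, grid, seed, sample_id = "synthetic",
                              taxon = "unknown", instrument_mode = "atr") {
  stopifnot(inherits(profile, "class_profile"))
  grid <- as.numeric(grid)
  if (!length(grid)) stop("empty grid", call. = FALSE)
  with_seed(seed, {
    nb <- nrow(GEN_BANDS)
    jit <- if (profile$jitter_sd > 0)
      stats::rnorm(nb + 1L, 0, profile$jitter_sd) else numeric(nb + 1L)
    lh <- function(mean, cv) {
      if (mean == 0) return(0)
      if (cv == 0) return(mean)
      sdl <- sqrt(log(1 + cv^2))
      mean * exp(stats::rnorm(1, -sdl^2 / 2, sdl))
    }
    heights <- vapply(seq_len(nb), function(i)
      lh(profile$band_means[[i]], profile$band_cv), numeric(1))
    silica_h <- lh(profile$silica_mean, profile$silica_cv)
    a <- numeric(length(grid))
    for (i in seq_len(nb))
      a <- a + heights[i] *
        exp(-(grid - GEN_BANDS$center[i] - jit[i])^2 / (2 * GEN_BANDS$sd[i]^2))
    a <- a + silica_h *
      exp(-(grid - SILICA_CENTER - jit[nb + 1L])^2 / (2 * SILICA_SD^2))
    if (profile$baseline_scale > 0) {
      co <- stats::rnorm(3, 0, profile$baseline_scale)
      x <- 2 * (grid - min(grid)) / (max(grid) - min(grid)) - 1
      a <- a + co[1] + co[2] * x + co[3] * x^2
    }
    if (profile$noise_sd > 0)
      a <- a + stats::rnorm(length(grid), 0, profile$noise_sd)
    new_spectrum(grid, a, sample_id = sample_id, taxon = taxon,
                 instrument_mode = instrument_mode)
  })
}

#' Generate a labelled synthetic dataset
#'
#' Produces exactly the designed number of spectra per class, in design
#' order, with per-sample seeds derived from the master seed by a counter so
#' that any single sample can be regenerated in isolation. Changing only the
#' seed changes absorbance values but not shapes or labels.
#'
#' @param design A [study_design()].
#' @param profiles Named list of [class_profile()] covering every class with
#'   a nonzero count.
#' @param seed Integer master seed; defaults to the design's seed.
#' @return A [new_spectral_dataset()].
#' @export
generate_dataset <- function(design = study_design(),
                             profiles = default_profiles(),
                             seed = design$seed) {
  stopifnot(inherits(design, "study_design"))
  active <- names(design$counts)[design$counts > 0]
  miss <- setdiff(active, names(profiles))
  if (length(miss))
    stop(sprintf("missing profile for class(es): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  spectra <- list()
  idx <- 0L
  for (cls in active) {
    for (j in seq_len(design$counts[[cls]])) {
      idx <- idx + 1L
      spectra[[idx]] <- generate_spectrum(
        profiles[[cls]], design$grid, seed = derive_seed(seed, idx),
        sample_id = sprintf("%s_%02d", cls, j), taxon = cls)
    }
  }
  new_spectral_dataset(spectra,
                       class_order = TAXON_CLASSES[TAXON_CLASSES %in% active])
}

#' Inject a synthetic outlier into a spectrum
#'
#' Three perturbation kinds for exercising outlier screening:
#' \describe{
#'   \item{`spike`}{adds a narrow Gaussian (sd 4 cm^-1) of height
#'     `magnitude` at a random grid position at least 50 cm^-1 away from
#'     every generator band center.}
#'   \item{`baseline-jump`}{adds a step of height `magnitude` from a random
#'     grid position onward.}
#'   \item{`wrong-class-mixture`}{blends in `magnitude` times the noise-free
#'     band sum of another class's profile.}
#' }
#' The injection is recorded in the spectrum's history.
#'
#' @param spectrum A `spectrum`.
#' @param kind One of `"spike"`, `"baseline-jump"`, `"wrong-class-mixture"`.
#' @param magnitude Positive scale factor (absorbance units for spike/jump).
#' @param seed Integer seed.
#' @param mix_profile A [class_profile()]; required for
#'   `"wrong-class-mixture"`.
#' @return The perturbed `spectrum`.
#' @export
inject_outlier <- function(spectrum, kind = c("spike", "baseline-jump",
                                              "wrong-class-mixture"),
                           magnitude, seed = 1L, mix_profile = NULL) {
  kind <- match.arg(kind)
  if (magnitude <= 0) stop("magnitude must be positive", call. = FALSE)
  wn <- spectrum$wavenumbers
  out <- with_seed(seed, {
    s <- spectrum
    if (kind == "spike") {
      centers <- c(GEN_BANDS$center, SILICA_CENTER)
      ok <- which(vapply(wn, function(v) min(abs(v - centers)) > 50,
                         logical(1)))
      if (!length(ok)) ok <- seq_along(wn)
      pos <- wn[sample(ok, 1)]
      s$absorbance <- s$absorbance +
        magnitude * exp(-(wn - pos)^2 / (2 * 4^2))
      record_step(s, "inject_outlier",
                  list(kind = kind, magnitude = magnitude, position = pos))
    } else if (kind == "baseline-jump") {
      pos <- sample(seq_along(wn), 1)
      s$absorbance <- s$absorbance +
        magnitude * (seq_along(wn) >= pos)
      record_step(s, "inject_outlier",
                  list(kind = kind, magnitude = magnitude, position = wn[pos]))
    } else {
      if (is.null(mix_profile))
        stop("wrong-class-mixture needs mix_profile", call. = FALSE)
      pure <- numeric(length(wn))
      for (i in seq_len(nrow(GEN_BANDS)))
        pure <- pure + mix_profile$band_means[[i]] *
          exp(-(wn - GEN_BANDS$center[i])^2 / (2 * GEN_BANDS$sd[i]^2))
      s$absorbance <- s$absorbance + magnitude * pure
      record_step(s, "inject_outlier",
                  list(kind = kind, magnitude = magnitude))
    }
  })
  out
}
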