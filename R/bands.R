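#' Define an absorption band
#'
#' @param name Short band name.
#' @param assignment Molecular moiety the band is assigned to.
#' @param center Band center in cm^-1.
#' @param half_window Half-width of the peak-search window (cm^-1).
#' @param integration_window Length-2 numeric `[lo, hi]` for area mode; must
#'   contain the center.
#' @return Object of class `band_definition`.
#' @export
band_definition <- function(name, assignment, center, half_window,
                            integration_window = center + c(-2, 2) * half_window) {
  stopifnot(half_window > 0, length(integration_window) == 2,
            integration_window[1] <= center, center <= integration_window[2])
  structure(list(name = name, assignment = assignment, center = center,
                 half_window = half_window,
                 integration_window = as.numeric(integration_window)),
            class = "band_definition")
}

#' Default band table
#'
#' The six biologically informative bands used for feature extraction:
#' amide I and II, a nitrogen-bearing fossilization-product band, a
#' carboxylate band, and the asymmetric CH2 and CH3 stretches. Centers are
#' literature-standard values for kerogenised organic matter; all windows
#' are plain list fields, so a caller with better assignments can override
#' any of them.
#'
#' The first four bands fall inside the fingerprint analysis window
#' (1445-1750 cm^-1), the aliphatic pair inside 2760-3000 cm^-1.
#'
#' @return List of six [band_definition()] objects.
#' @export
default_band_table <- function() {
  list(
    band_definition("amide_I",     "amide I (C=O stretch, protein products)",
                    1655, 25, c(1620, 1690)),
    band_definition("amide_II",    "amide II (N-H bend / C-N stretch)",
                    1545, 20, c(1510, 1580)),
    band_definition("n_products",  "N-bearing fossilization products",
                    1590, 12, c(1566, 1614)),
    band_definition("carboxylate", "carboxylate COO- symmetric stretch",
                    1560, 12, c(1536, 1584)),
    band_definition("ch2_asym",    "aliphatic CH2 asymmetric stretch",
                    2925, 15, c(2895, 2955)),
    band_definition("ch3_asym",    "aliphatic CH3 asymmetric stretch",
                    2960, 12, c(2936, 2984))
  )
}

#' Band intensity of one spectrum
#'
#' `height` mode returns the maximum absorbance within `center +/-
#' half_window`. `area` mode returns the trapezoidal integral over the
#' integration window above a local linear baseline drawn between the
#' window's endpoint absorbances. Negative results are clipped to zero with
#' a warning.
#'
#' @param spectrum A `spectrum`.
#' @param band A [band_definition()].
#' @param mode `"height"` or `"area"`.
#' @return Non-negative scalar.
#' @export
band_intensity <- function(spectrum, band, mode = c("height", "area")) {
  mode <- match.arg(mode)
  wn <- spectrum$wavenumbers; a <- spectrum$absorbance
  if (mode == "height") {
    sel <- wn >= band$center - band$half_window &
           wn <= band$center + band$half_window
    if (!any(sel))
      stop(sprintf("band '%s' search window outside spectrum grid", band$name),
           call. = FALSE)
    v <- max(a[sel])
  } else {
    sel <- wn >= band$integration_window[1] & wn <= band$integration_window[2]
    if (sum(sel) < 2L)
      stop(sprintf("band '%s' integration window outside spectrum grid",
                   band$name), call. = FALSE)
    x <- wn[sel]; y <- a[sel]
    base <- y[1] + (y[length(y)] - y[1]) * (x - x[1]) / (x[length(x)] - x[1])
    yy <- y - base
    v <- sum(diff(x) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
  }
  if (v < 0) {
    warning(sprintf("negative %s for band '%s' clipped to 0", mode, band$name),
            call. = FALSE)
    v <- 0
  }
  v
}

#' Extract the samples x bands feature matrix
#'
#' @param dataset A `spectral_dataset`. A warning is issued if spectra carry
#'   no preprocessing history (features are normally extracted from
#'   preprocessed spectra).
#' @param bands List of [band_definition()]; defaults to
#'   [default_band_table()].
#' @param mode `"height"` or `"area"`.
#' @return Numeric matrix, one row per sample (in dataset order), one column
#'   per band (in band-table order).
#' @export
extract_band_matrix <- function(dataset, bands = default_band_table(),
                                mode = c("height", "area")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "spectral_dataset"))
  if (all(vapply(dataset$spectra, function(s) length(s$history) == 0L,
                 logical(1))))
    warning("extracting band features from raw (unpreprocessed) spectra",
            call. = FALSE)
  m <- t(vapply(dataset$spectra, function(s)
    vapply(bands, function(b) band_intensity(s, b, mode), numeric(1)),
    numeric(length(bands))))
  dimnames(m) <- list(vapply(dataset$spectra, `[[`, character(1), "sample_id"),
                      vapply(bands, `[[`, character(1), "name"))
  m
}

#' Aliphatic CH3/CH2 ratio and chain-length estimate
#'
#' The ratio R32 of the asymmetric CH3 stretch (~2960 cm^-1) to the
#' asymmetric CH2 stretch (~2925 cm^-1) tracks aliphatic chain length and
#' branching: the lower the ratio, the longer and less branched the chains.
#' The chain length estimate comes from [estimate_chain_length()].
#'
#' @param spectrum A `spectrum` covering both aliphatic bands.
#' @param mode `"height"` (default; ratio of peak intensities) or `"area"`.
#' @param k Absorptivity calibration constant passed to
#'   [estimate_chain_length()].
#' @return List of class `aliphatic_ratio` with `ch2_value`, `ch3_value`,
#'   `ratio`, `chain_length_estimate`, `k`.
#' @export
ch3_ch2_ratio <- function(spectrum, mode = c("height", "area"), k = 2.625) {
  mode <- match.arg(mode)
  bands <- default_band_table()
  ch2 <- band_intensity(spectrum, bands[[5L]], mode)
  ch3 <- band_intensity(spectrum, bands[[6L]], mode)
  if (ch2 <= 0)
    stop("CH2 intensity is zero; CH3/CH2 ratio undefined", call. = FALSE)
  r <- ch3 / ch2
  structure(list(ch2_value = ch2, ch3_value = ch3, ratio = r,
                 chain_length_estimate = estimate_chain_length(r, k), k = k),
            class = "aliphatic_ratio")
}

#' @export
print.aliphatic_ratio <- function(x, ...) {
  cat(sprintf("CH3/CH2 ratio %.3f  (CH3 %.4g / CH2 %.4g)  ~%.1f carbons\n",
              x$ratio, x$ch3_value, x$ch2_value, x$chain_length_estimate))
  invisible(x)
}

#' Aliphatic chain length from the CH3/CH2 ratio
#'
#' Models an n-alkane chain with two terminal CH3 groups and n - 2 CH2
#' groups, with a CH2:CH3 absorptivity ratio k, so that
#' R32 = 2k / (n - 2), i.e. n = 2k / R32 + 2. The default k = 2.625 anchors
#' a ratio of 0.75 to a chain of nine carbons. The mapping is strictly
#' decreasing in the ratio, with n -> 2 as the ratio grows and n -> Inf as
#' it approaches zero.
#'
#' @param ratio Positive CH3/CH2 intensity ratio.
#' @param k Calibration constant (> 0).
#' @return Estimated number of carbons (>= 2).
#' @export
estimate_chain_length <- function(ratio, k = 2.625) {
  stopifnot(k > 0)
  if (any(ratio <= 0)) stop("ratio must be positive", call. = FALSE)
  2 * k / ratio + 2
}
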