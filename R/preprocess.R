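# Preprocessing steps
#
# Each step takes and returns a `spectrum`, appends exactly one history
# entry, and is composable through apply_recipe(). Three built-in recipes
# mirror the three acquisition modes (ATR microscope, transmission
# benchtop, synchrotron).

#' Truncate a spectrum to analysis windows
#'
#' Retains grid points falling inside any of the given closed intervals,
#' concatenated in ascending order. Typical use removes hydroxyl, intense
#' silica, atmospheric CO2 and high-wavenumber silica-overtone regions,
#' keeping the fingerprint (1445-1750 cm^-1) and aliphatic (2760-3000
#' cm^-1) windows.
#'
#' @param spectrum A `spectrum`.
#' @param windows List of length-2 numeric vectors `c(lo, hi)`; must be
#'   disjoint and ordered.
#' @return Truncated `spectrum`.
#' @export
truncate_spectrum <- function(spectrum, windows) {
  if (is.numeric(windows)) windows <- list(windows)
  lo <- vapply(windows, `[`, numeric(1), 1)
  hi <- vapply(windows, `[`, numeric(1), 2)
  if (any(lo >= hi)) stop("each window needs lo < hi", call. = FALSE)
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  if (length(lo) > 1 && any(lo[-1] <= hi[-length(hi)]))
    stop("truncation windows must be disjoint", call. = FALSE)
  wn <- spectrum$wavenumbers
  keep <- rep(FALSE, length(wn))
  for (i in seq_along(lo)) keep <- keep | (wn >= lo[i] & wn <= hi[i])
  if (!any(keep)) stop("no points in windows", call. = FALSE)
  out <- spectrum
  out$wavenumbers <- wn[keep]
  out$absorbance <- spectrum$absorbance[keep]
  record_step(out, "truncate", list(windows = Map(c, lo, hi)))
}

# Asymmetric least squares baseline (Eilers-Boelens). Penalised weighted
# smoother with asymmetric weights: points above the baseline (peaks) get
# weight p, points below get 1 - p.
.als_cache <- new.env(parent = emptyenv())

# lambda * t(D2) %*% D2 for the second-difference operator, cached per
# (n, lambda) since every spectrum of a dataset shares the grid length.
als_penalty <- function(n, lambda, dense) {
  key <- sprintf("%d_%g_%d", n, lambda, dense)
  hit <- .als_cache[[key]]
  if (!is.null(hit)) return(hit)
  D <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                          diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                           rep(1, n - 2L)))
  DtD <- lambda * Matrix::crossprod(D)
  if (dense) DtD <- as.matrix(DtD)
  .als_cache[[key]] <- DtD
  DtD
}

als_baseline <- function(y, lambda = 1e5, p = 0.01, iters = 10L) {
  n <- length(y)
  dense <- n <= 600   # dense Cholesky beats sparse dispatch for short spectra
  DtD <- als_penalty(n, lambda, dense)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(iters)) {
    if (dense) {
      A <- DtD
      diag(A) <- diag(A) + w
      R <- chol(A)
      z <- backsolve(R, forwardsolve(t(R), w * y))
    } else {
      z <- as.numeric(Matrix::solve(Matrix::Diagonal(n, w) + DtD, w * y))
    }
    w <- ifelse(y > z, p, 1 - p)
  }
  z
}

# Rubberband baseline: lower convex hull of (wavenumber, absorbance),
# linearly interpolated between hull vertices.
rubberband_baseline <- function(x, y) {
  n <- length(x)
  # Andrew's monotone chain, lower hull only (x already ascending).
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1L]; b <- hull[length(hull)]
      cross <- (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a])
      if (cross <= 0) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  stats::approx(x[hull], y[hull], xout = x, method = "linear",
                ties = "ordered")$y
}

#' Baseline correction
#'
#' Subtracts an estimated smooth baseline. `"als"` (default) is asymmetric
#' least squares with smoothness `lambda`, asymmetry `p` and a fixed number
#' of reweighting iterations; `"rubberband"` subtracts the lower convex hull
#' of the spectrum.
#'
#' @param spectrum A `spectrum` with at least 8 points and finite values.
#' @param method `"als"` or `"rubberband"`.
#' @param lambda,p,iters ALS parameters.
#' @return Baseline-corrected `spectrum`.
#' @export
baseline_correct <- function(spectrum, method = c("als", "rubberband"),
                             lambda = 1e5, p = 0.01, iters = 10L) {
  method <- match.arg(method)
  y <- spectrum$absorbance
  if (length(y) < 8L) stop("baseline correction needs >= 8 points",
                           call. = FALSE)
  if (!all(is.finite(y))) stop("non-finite absorbance values", call. = FALSE)
  base <- if (method == "als") als_baseline(y, lambda, p, iters)
          else rubberband_baseline(spectrum$wavenumbers, y)
  out <- spectrum
  out$absorbance <- y - base
  record_step(out, "baseline_correct",
              list(method = method,
                   lambda = if (method == "als") lambda else NA,
                   p = if (method == "als") p else NA))
}

#' Gaussian smoothing
#'
#' Convolution with a unit-area Gaussian kernel of standard deviation
#' `sigma_points` grid points, with reflect padding at the edges. The
#' built-in recipes use sigma = 2 points as their "light" smoothing.
#'
#' @param spectrum A `spectrum`.
#' @param sigma_points Positive kernel standard deviation, in grid points.
#' @return Smoothed `spectrum`.
#' @export
gaussian_smooth <- function(spectrum, sigma_points = 2) {
  stopifnot(sigma_points > 0)
  y <- spectrum$absorbance
  n <- length(y)
  r <- max(1L, ceiling(4 * sigma_points))
  k <- exp(-(-r:r)^2 / (2 * sigma_points^2))
  k <- k / sum(k)
  pad <- c(y[pmin(r + 1L, n):2L], y, y[(n - 1L):pmax(n - r, 1L)])
  # reflect padding assumes r < n; clamp for very short spectra
  if (r >= n) {
    idx <- c(rev(seq_len(n)[-1]), seq_len(n), rev(seq_len(n))[-1])
    while (length(idx) < n + 2 * r) idx <- c(idx[1], idx, idx[length(idx)])
    pad <- y[idx[seq_len(n + 2 * r)]]
  }
  sm <- stats::convolve(pad, rev(k), type = "filter")
  out <- spectrum
  out$absorbance <- sm
  record_step(out, "gaussian_smooth", list(sigma_points = sigma_points))
}

#' Normalize on the silica overtone peak
#'
#' Divides the whole spectrum by the maximum absorbance found inside the
#' search window, so that the reference peak (nominally the chert silica
#' overtone at 1615 cm^-1) becomes exactly 1. The window rather than the
#' exact position is searched because peak apexes shift a few cm^-1 between
#' samples.
#'
#' @param spectrum A `spectrum`.
#' @param search_window Length-2 numeric, default `c(1585, 1645)`.
#' @return Normalized `spectrum`.
#' @export
normalize_silica <- function(spectrum, search_window = c(1585, 1645)) {
  wn <- spectrum$wavenumbers
  sel <- wn >= search_window[1] & wn <= search_window[2]
  if (!any(sel)) stop("silica search window does not intersect the grid",
                      call. = FALSE)
  m <- max(spectrum$absorbance[sel])
  if (m <= 0) stop("non-positive reference peak", call. = FALSE)
  out <- spectrum
  out$absorbance <- spectrum$absorbance / m
  record_step(out, "normalize_silica",
              list(window = search_window, reference = m))
}

#' Vector (Euclidean) normalization
#'
#' Divides the absorbance by its Euclidean norm; the output has unit norm
#' and the operation is idempotent.
#'
#' @param spectrum A `spectrum` with nonzero norm.
#' @return Normalized `spectrum`.
#' @export
vector_normalize <- function(spectrum) {
  nrm <- sqrt(sum(spectrum$absorbance^2))
  if (nrm <= 0) stop("zero-norm spectrum cannot be vector-normalized",
                     call. = FALSE)
  out <- spectrum
  out$absorbance <- spectrum$absorbance / nrm
  record_step(out, "vector_normalize", list())
}

#' Savitzky-Golay filtering / differentiation
#'
#' Local polynomial filtering on a uniform grid; with `deriv > 0` the
#' result is the derivative of that order, scaled by the grid spacing so
#' units are per (cm^-1)^deriv. Endpoints are fitted one-sided and should
#' be excluded from derivative-based band picking.
#'
#' @param spectrum A `spectrum` on a uniform grid.
#' @param window Odd window length (> polyorder).
#' @param polyorder Polynomial order (>= deriv).
#' @param deriv Derivative order (default 0).
#' @return Filtered `spectrum`.
#' @export
savitzky_golay <- function(spectrum, window, polyorder = 2L, deriv = 0L) {
  stopifnot(window %% 2 == 1, window > polyorder, polyorder >= deriv)
  d <- diff(spectrum$wavenumbers)
  if (max(abs(d - d[1])) > 1e-6 * abs(d[1]))
    stop("Savitzky-Golay requires a uniform grid; regrid() first",
         call. = FALSE)
  y <- signal::sgolayfilt(spectrum$absorbance, p = polyorder, n = window,
                          m = deriv, ts = d[1])
  out <- spectrum
  out$absorbance <- y
  record_step(out, "savitzky_golay",
              list(window = window, polyorder = polyorder, deriv = deriv))
}

#' Built-in preprocessing recipes
#'
#' \describe{
#'   \item{`atr-paper`}{truncate to 1445-1750 and 2760-3000 cm^-1, ALS
#'     baseline, light Gaussian smoothing, silica-peak normalization.}
#'   \item{`benchtop-paper`}{Gaussian smoothing, ALS baseline, second
#'     derivative by Savitzky-Golay (window 21, order 2).}
#'   \item{`synchrotron-paper`}{truncate to 1440-3000 cm^-1, second
#'     derivative by Savitzky-Golay (window 9, order 2), Gaussian
#'     smoothing, vector normalization.}
#'   \item{`synchrotron-ratio`}{as `synchrotron-paper` but with baseline
#'     correction instead of the derivative, for aliphatic band-ratio
#'     work.}
#' }
#'
#' @param name Recipe name.
#' @return A list of step descriptors usable with [apply_recipe()].
#' @export
preprocess_recipe <- function(name = c("atr-paper", "benchtop-paper",
                                       "synchrotron-paper",
                                       "synchrotron-ratio")) {
  name <- match.arg(name)
  switch(name,
    "atr-paper" = list(
      list(step = "truncate", windows = list(c(1445, 1750), c(2760, 3000))),
      list(step = "baseline", method = "als"),
      list(step = "gaussian_smooth", sigma_points = 2),
      list(step = "normalize_silica", search_window = c(1585, 1645))),
    "benchtop-paper" = list(
      list(step = "gaussian_smooth", sigma_points = 2),
      list(step = "baseline", method = "als"),
      list(step = "savitzky_golay", window = 21, polyorder = 2, deriv = 2)),
    "synchrotron-paper" = list(
      list(step = "truncate", windows = list(c(1440, 3000))),
      list(step = "savitzky_golay", window = 9, polyorder = 2, deriv = 2),
      list(step = "gaussian_smooth", sigma_points = 2),
      list(step = "vector_normalize")),
    "synchrotron-ratio" = list(
      list(step = "truncate", windows = list(c(1440, 3000))),
      list(step = "baseline", method = "als"),
      list(step = "gaussian_smooth", sigma_points = 2),
      list(step = "vector_normalize")))
}

apply_step <- function(spec, st) {
  switch(st$step,
    truncate = truncate_spectrum(spec, st$windows),
    baseline = baseline_correct(spec, method = st$method %||% "als",
                                lambda = st$lambda %||% 1e5,
                                p = st$p %||% 0.01,
                                iters = st$iters %||% 10L),
    gaussian_smooth = gaussian_smooth(spec, st$sigma_points %||% 2),
    normalize_silica = normalize_silica(
      spec, st$search_window %||% c(1585, 1645)),
    vector_normalize = vector_normalize(spec),
    savitzky_golay = savitzky_golay(spec, st$window,
                                    st$polyorder %||% 2L, st$deriv %||% 0L),
    regrid = regrid_one(spec, st$target_grid),
    stop(sprintf("unknown preprocessing step '%s'", st$step), call. = FALSE))
}

#' Apply a preprocessing recipe to every spectrum of a dataset
#'
#' Steps are applied in order; an empty recipe returns the dataset
#' unchanged. Step errors are annotated with the failing sample's id.
#' Step order matters: e.g. truncating away the silica window before
#' normalizing on it is an error.
#'
#' @param dataset A `spectral_dataset`.
#' @param recipe A recipe name (see [preprocess_recipe()]) or a list of step
#'   descriptors.
#' @return The preprocessed `spectral_dataset`.
#' @export
apply_recipe <- function(dataset, recipe) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  if (is.character(recipe)) recipe <- preprocess_recipe(recipe)
  if (!length(recipe)) return(dataset)
  spectra <- lapply(dataset$spectra, function(s) {
    for (st in recipe) {
      s <- tryCatch(apply_step(s, st), error = function(e)
        stop(sprintf("sample '%s', step '%s': %s", s$sample_id, st$step,
                     conditionMessage(e)), call. = FALSE))
    }
    s
  })
  new_spectral_dataset(spectra, class_order = colnames(dataset$onehot))
}
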