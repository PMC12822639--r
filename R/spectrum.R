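#' @keywords internal
"_PACKAGE"

# Closed vocabulary of taxon classes used throughout the pipeline. "unknown"
# is permitted on prediction inputs only, never as a training label.
TAXON_CLASSES <- c("Prototaxites", "Fungi", "Arthropoda", "Bacteria",
                   "Plantae", "Oomycetes", "Amoebae")

INSTRUMENT_MODES <- c("atr", "transmission", "synchrotron")

#' Taxon class vocabulary
#'
#' The closed set of taxon labels recognised by the pipeline, in the fixed
#' column order used for one-hot encoding.
#'
#' @return Character vector of the seven class names.
#' @export
taxon_classes <- function() TAXON_CLASSES

#' Construct a single infrared spectrum
#'
#' A `spectrum` holds one sample's absorbance trace on a strictly increasing
#' wavenumber grid (cm^-1), together with its taxon label, acquisition mode
#' and an append-only history of preprocessing steps. Input in descending
#' wavenumber order (the common acquisition convention, e.g. 4000 down to
#' 650 cm^-1) is reversed to the canonical ascending order.
#'
#' @param wavenumbers Numeric vector of wavenumbers in cm^-1, strictly
#'   monotonic, all positive, length >= 2.
#' @param absorbance Numeric vector of absorbance values, same length.
#' @param sample_id Sample identifier.
#' @param taxon Taxon label (one of [taxon_classes()]) or `"unknown"`.
#' @param instrument_mode One of `"atr"`, `"transmission"`, `"synchrotron"`.
#' @param history List of preprocessing step descriptors (normally empty at
#'   construction).
#' @return Object of class `spectrum`.
#' @export
new_spectrum <- function(wavenumbers, absorbance, sample_id = "sample",
                         taxon = "unknown", instrument_mode = "atr",
                         history = list()) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) < 2L)
    stop("a spectrum needs at least 2 points", call. = FALSE)
  if (length(wavenumbers) != length(absorbance))
    stop("wavenumbers and absorbance must have equal length", call. = FALSE)
  if (anyNA(wavenumbers) || anyNA(absorbance))
    stop("spectrum contains missing values", call. = FALSE)
  if (any(wavenumbers <= 0))
    stop("wavenumbers must be positive", call. = FALSE)
  d <- diff(wavenumbers)
  if (all(d < 0)) {            # descending input: normalise to ascending
    wavenumbers <- rev(wavenumbers)
    absorbance <- rev(absorbance)
  } else if (!all(d > 0)) {
    stop("wavenumbers must be strictly monotonic", call. = FALSE)
  }
  if (!identical(taxon, "unknown") && !taxon %in% TAXON_CLASSES)
    stop(sprintf("unknown taxon label '%s'", taxon), call. = FALSE)
  instrument_mode <- match.arg(instrument_mode, INSTRUMENT_MODES)
  structure(list(sample_id = as.character(sample_id), taxon = taxon,
                 instrument_mode = instrument_mode,
                 wavenumbers = wavenumbers, absorbance = absorbance,
                 history = history),
            class = "spectrum")
}

# Append one history entry; history is append-only by construction.
record_step <- function(spec, step, params = list()) {
  spec$history <- c(spec$history, list(c(list(step = step), params)))
  spec
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s [%s, %s]  %d points, %.0f-%.0f cm-1, %d steps\n",
              x$sample_id, x$taxon, x$instrument_mode,
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers),
              length(x$history)))
  invisible(x)
}

#' One-hot encode taxon labels
#'
#' Each sample is encoded as a 0/1 row with a single 1 in the column of its
#' class; the column order is fixed and recorded in the matrix's dimnames.
#'
#' @param labels Character vector of taxon labels.
#' @param class_order Ordered character vector of classes; every label must
#'   appear in it.
#' @return Integer matrix, `length(labels)` x `length(class_order)`.
#' @export
one_hot <- function(labels, class_order = taxon_classes()) {
  bad <- setdiff(unique(labels), class_order)
  if (length(bad))
    stop(sprintf("label(s) not in class order: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  m <- matrix(0L, nrow = length(labels), ncol = length(class_order),
              dimnames = list(NULL, class_order))
  m[cbind(seq_along(labels), match(labels, class_order))] <- 1L
  m
}

#' Assemble spectra into a dataset on a shared grid
#'
#' @param spectra List of [new_spectrum()] objects, all on an identical
#'   wavenumber grid.
#' @param class_order Column order for the one-hot label matrix; defaults to
#'   the classes present, in vocabulary order.
#' @return Object of class `spectral_dataset` with elements `spectra`,
#'   `labels`, `onehot`, and the common `wavenumbers` grid.
#' @export
new_spectral_dataset <- function(spectra, class_order = NULL) {
  if (!length(spectra)) stop("empty dataset", call. = FALSE)
  grid <- spectra[[1L]]$wavenumbers
  same <- vapply(spectra, function(s)
    length(s$wavenumbers) == length(grid) &&
      isTRUE(all.equal(s$wavenumbers, grid, tolerance = 1e-10)), logical(1))
  if (!all(same))
    stop("all spectra must share an identical wavenumber grid; regrid() first",
         call. = FALSE)
  labels <- unname(vapply(spectra, `[[`, character(1), "taxon"))
  if (is.null(class_order)) {
    present <- setdiff(unique(labels), "unknown")
    class_order <- TAXON_CLASSES[TAXON_CLASSES %in% present]
    if (!length(class_order)) class_order <- TAXON_CLASSES
  }
  oh <- if (all(labels == "unknown")) {
    matrix(0L, length(labels), length(class_order),
           dimnames = list(NULL, class_order))
  } else if (any(labels == "unknown")) {
    stop("datasets mixing 'unknown' with labelled samples are not supported",
         call. = FALSE)
  } else one_hot(labels, class_order)
  structure(list(spectra = spectra, labels = labels, onehot = oh,
                 wavenumbers = grid),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d spectra x %d points (%.0f-%.0f cm-1)\n",
              length(x$spectra), length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  print(table(x$labels))
  invisible(x)
}

#' @export
length.spectral_dataset <- function(x) length(x$spectra)

#' Absorbance matrix of a dataset
#'
#' @param dataset A `spectral_dataset`.
#' @return Numeric matrix, samples x wavenumbers, with sample ids as row
#'   names and wavenumbers as column names.
#' @export
as_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  m <- t(vapply(dataset$spectra, `[[`, numeric(length(dataset$wavenumbers)),
                "absorbance"))
  rownames(m) <- vapply(dataset$spectra, `[[`, character(1), "sample_id")
  colnames(m) <- format(dataset$wavenumbers, trim = TRUE)
  m
}

#' Subset a dataset by sample index
#'
#' Labels and the one-hot matrix are recompiled for the retained samples.
#'
#' @param dataset A `spectral_dataset`.
#' @param idx Integer or logical index of samples to keep.
#' @param class_order Optional class order for the recompiled one-hot matrix;
#'   defaults to the original column order restricted to classes present.
#' @return A `spectral_dataset`.
#' @export
subset_dataset <- function(dataset, idx, class_order = NULL) {
  spectra <- dataset$spectra[idx]
  if (!length(spectra)) stop("subset would be empty", call. = FALSE)
  if (is.null(class_order)) {
    keep <- colnames(dataset$onehot)
    class_order <- keep[keep %in% vapply(spectra, `[[`, character(1), "taxon")]
    if (!length(class_order)) class_order <- colnames(dataset$onehot)
  }
  new_spectral_dataset(spectra, class_order = class_order)
}

#' Interpolate spectra onto a new wavenumber grid
#'
#' Linear interpolation; the target grid must lie within the span of every
#' spectrum (no extrapolation).
#'
#' @param dataset A `spectral_dataset` (or single `spectrum`).
#' @param target_grid Numeric vector of target wavenumbers (ascending).
#' @return Regridded object of the same class.
#' @export
regrid <- function(dataset, target_grid) {
  target_grid <- sort(as.numeric(target_grid))
  if (inherits(dataset, "spectrum")) return(regrid_one(dataset, target_grid))
  stopifnot(inherits(dataset, "spectral_dataset"))
  spectra <- lapply(dataset$spectra, regrid_one, target_grid = target_grid)
  new_spectral_dataset(spectra, class_order = colnames(dataset$onehot))
}

regrid_one <- function(spec, target_grid) {
  lo <- min(spec$wavenumbers); hi <- max(spec$wavenumbers)
  if (min(target_grid) < lo - 1e-9 || max(target_grid) > hi + 1e-9)
    stop(sprintf(
      "regrid would extrapolate: target [%.6g, %.6g] outside data span [%.6g, %.6g]",
      min(target_grid), max(target_grid), lo, hi), call. = FALSE)
  a <- stats::approx(spec$wavenumbers, spec$absorbance, xout = target_grid,
                     method = "linear", ties = "ordered")$y
  out <- spec
  out$wavenumbers <- target_grid
  out$absorbance <- a
  record_step(out, "regrid",
              list(n = length(target_grid), lo = min(target_grid),
                   hi = max(target_grid)))
}
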