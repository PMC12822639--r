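#' Read spectra from disk
#'
#' Three plain-text dialects are supported:
#' \describe{
#'   \item{`wide-csv`}{header `wavenumber,<id1>,<id2>,...`; one absorbance
#'     column per sample.}
#'   \item{`long-csv`}{columns `sample_id, wavenumber, absorbance, taxon`
#'     (taxon optional; missing labels default to `"unknown"`).}
#'   \item{`jcamp-minimal`}{a single-block JCAMP-DX file with an
#'     `##XYDATA=(XY..XY)` or `(X++(Y..Y))` table of AFFN numbers; one
#'     spectrum per file. Full JCAMP dialect coverage is a non-goal.}
#' }
#' Spectra are returned in canonical ascending-wavenumber order whatever the
#' file order.
#'
#' @param path File path.
#' @param dialect One of `"wide-csv"`, `"long-csv"`, `"jcamp-minimal"`.
#' @param labels Optional path to a sidecar CSV `sample_id,taxon` assigning
#'   labels to wide-csv or JCAMP samples.
#' @param instrument_mode Acquisition mode recorded on each spectrum.
#' @return A [new_spectral_dataset()].
#' @export
load_spectra <- function(path, dialect = c("wide-csv", "long-csv",
                                           "jcamp-minimal"),
                         labels = NULL, instrument_mode = "atr") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lab <- NULL
  if (!is.null(labels)) {
    lab_df <- utils::read.csv(labels, stringsAsFactors = FALSE)
    lab <- stats::setNames(lab_df$taxon, lab_df$sample_id)
  }
  spectra <- switch(dialect,
    "wide-csv" = read_wide_csv(path, lab, instrument_mode),
    "long-csv" = read_long_csv(path, instrument_mode),
    "jcamp-minimal" = list(read_jcamp(path, lab, instrument_mode)))
  new_spectral_dataset(spectra)
}

check_numeric_col <- function(x, what, path) {
  y <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(y) & !is.na(x) & nzchar(trimws(x)))
  if (length(bad) || anyNA(y))
    stop(sprintf("non-numeric %s in %s at data row %d",
                 what, path, if (length(bad)) bad[1] else which(is.na(y))[1]),
         call. = FALSE)
  y
}

read_wide_csv <- function(path, lab, instrument_mode) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2L) stop("wide CSV needs a wavenumber column plus >= 1 sample",
                          call. = FALSE)
  wn <- check_numeric_col(df[[1L]], "wavenumber", path)
  if (anyDuplicated(wn))
    stop(sprintf("duplicate wavenumber %.6g in %s", wn[duplicated(wn)][1], path),
         call. = FALSE)
  lapply(names(df)[-1L], function(id) {
    a <- check_numeric_col(df[[id]], sprintf("absorbance for '%s'", id), path)
    taxon <- if (!is.null(lab) && id %in% names(lab)) lab[[id]] else "unknown"
    new_spectrum(wn, a, sample_id = id, taxon = taxon,
                 instrument_mode = instrument_mode)
  })
}

read_long_csv <- function(path, instrument_mode) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "wavenumber", "absorbance")
  if (!all(need %in% names(df)))
    stop(sprintf("long CSV must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  df$wavenumber <- check_numeric_col(as.character(df$wavenumber),
                                     "wavenumber", path)
  df$absorbance <- check_numeric_col(as.character(df$absorbance),
                                     "absorbance", path)
  has_taxon <- "taxon" %in% names(df)
  lapply(split(df, factor(df$sample_id, levels = unique(df$sample_id))),
         function(d) {
    if (anyDuplicated(d$wavenumber))
      stop(sprintf("duplicate wavenumber within sample '%s'", d$sample_id[1]),
           call. = FALSE)
    taxon <- if (has_taxon) as.character(d$taxon[1]) else "unknown"
    if (is.na(taxon) || !nzchar(taxon)) taxon <- "unknown"
    new_spectrum(d$wavenumber, d$absorbance, sample_id = d$sample_id[1],
                 taxon = taxon, instrument_mode = instrument_mode)
  })
}

# Minimal JCAMP-DX: one ##XYDATA block, AFFN numbers, (XY..XY) pairs or
# (X++(Y..Y)) with FIRSTX/LASTX/NPOINTS/XFACTOR/YFACTOR.
read_jcamp <- function(path, lab, instrument_mode) {
  lines <- readLines(path, warn = FALSE)
  ldr <- function(name, default = NA) {
    hit <- grep(sprintf("^##%s=", name), lines, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) return(default)
    trimws(sub("^##[^=]*=", "", hit[1]))
  }
  title <- ldr("TITLE", "jcamp")
  start <- grep("^##XYDATA=", lines, ignore.case = TRUE)
  if (!length(start)) stop("no ##XYDATA block found", call. = FALSE)
  form <- toupper(ldr("XYDATA"))
  ends <- grep("^##", lines)
  stop_at <- ends[ends > start[1]]
  body <- lines[(start[1] + 1L):(if (length(stop_at)) stop_at[1] - 1L
                                 else length(lines))]
  nums <- lapply(body, function(l)
    suppressWarnings(as.numeric(strsplit(trimws(l), "[,;[:space:]]+")[[1]])))
  if (any(vapply(nums, anyNA, logical(1))))
    stop(sprintf("non-numeric value in XYDATA of %s", path), call. = FALSE)
  if (grepl("X\\+\\+", form)) {
    xf <- as.numeric(ldr("XFACTOR", 1)); yf <- as.numeric(ldr("YFACTOR", 1))
    xs <- c(); ys <- c()
    for (row in nums) {
      xs <- c(xs, row[1]); ys <- c(ys, row[-1])
      # X of subsequent Ys is implicit; filled below from FIRSTX/LASTX
    }
    npt <- as.numeric(ldr("NPOINTS", length(ys) + length(nums) - length(nums)))
    firstx <- as.numeric(ldr("FIRSTX", xs[1]))
    lastx <- as.numeric(ldr("LASTX", NA))
    y <- unlist(lapply(nums, function(r) r[-1])) * yf
    n <- length(y)
    if (is.na(lastx)) stop("X++(Y..Y) form requires ##LASTX", call. = FALSE)
    x <- seq(firstx * xf, lastx * xf, length.out = n)
  } else {
    flat <- unlist(nums)
    if (length(flat) %% 2L != 0L)
      stop("odd number of values in (XY..XY) data", call. = FALSE)
    x <- flat[seq(1, length(flat), 2)]
    y <- flat[seq(2, length(flat), 2)]
  }
  if (anyDuplicated(x)) stop("duplicate wavenumbers in JCAMP data",
                             call. = FALSE)
  taxon <- if (!is.null(lab) && title %in% names(lab)) lab[[title]]
           else "unknown"
  new_spectrum(x, y, sample_id = title, taxon = taxon,
               instrument_mode = instrument_mode)
}

#' Write spectra to CSV
#'
#' Values are written with 15 significant digits so a save/load round trip
#' preserves them to at least 12 significant digits.
#'
#' @param dataset A `spectral_dataset`.
#' @param path Output file path.
#' @param dialect `"wide-csv"` or `"long-csv"`.
#' @return `path`, invisibly.
#' @export
save_spectra <- function(dataset, path, dialect = c("wide-csv", "long-csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(dataset, "spectral_dataset"))
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  if (dialect == "wide-csv") {
    m <- as_matrix(dataset)
    df <- data.frame(wavenumber = fmt(dataset$wavenumbers),
                     apply(t(m), 2, fmt), check.names = FALSE)
    names(df)[-1L] <- rownames(m)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    rows <- do.call(rbind, lapply(dataset$spectra, function(s)
      data.frame(sample_id = s$sample_id, wavenumber = fmt(s$wavenumbers),
                 absorbance = fmt(s$absorbance), taxon = s$taxon)))
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
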