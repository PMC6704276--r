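#' MSI dataset
#'
#' In-memory model of a mass spectrometry imaging acquisition: one spectrum
#' per pixel on a regular grid. Pixel coordinates are 0-based `(x, y)` grid
#' positions (x = column, y = row, y down); `pitch` is the physical spacing
#' between adjacent pixels in micrometers (70 um for the acquisitions this
#' pipeline targets).
#'
#' @param coords n x 2 integer matrix of unique pixel grid positions.
#' @param spectra n x m matrix of non-negative intensities, one row per
#'   pixel.
#' @param mz strictly increasing numeric m/z axis of length m.
#' @param pitch pixel spacing in micrometers.
#' @return an object of class `"msi_dataset"`.
#' @export
msi_dataset <- function(coords, spectra, mz, pitch = 70) {
  coords <- as_points(coords)
  spectra <- as.matrix(spectra)
  mz <- as.numeric(mz)
  if (nrow(coords) != nrow(spectra))
    stop("coords and spectra disagree on the number of pixels")
  if (ncol(spectra) != length(mz))
    stop("spectra column count does not match the m/z axis length")
  if (anyDuplicated(paste(coords[, 1], coords[, 2])))
    stop("duplicate pixel coordinates")
  if (any(coords < 0) || any(coords != round(coords)))
    stop("coords must be non-negative integers")
  if (any(spectra < 0)) stop("intensities must be non-negative")
  if (length(mz) > 1 && any(diff(mz) <= 0))
    stop("m/z axis must be strictly increasing")
  stopifnot(pitch > 0)
  structure(list(coords = coords, spectra = spectra, mz = mz, pitch = pitch),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("<msi_dataset> %d pixels x %d channels, m/z %.6g-%.6g, pitch %g um\n",
              nrow(x$spectra), ncol(x$spectra), min(x$mz), max(x$mz), x$pitch))
  invisible(x)
}

#' Grid dimensions of an MSI dataset
#' @param ds an [msi_dataset()].
#' @return `c(height, width)` in pixels (0-based coords imply max + 1).
#' @export
grid_shape <- function(ds) {
  stopifnot(inherits(ds, "msi_dataset"))
  c(height = max(ds$coords[, 2]) + 1, width = max(ds$coords[, 1]) + 1)
}

#' Normalize every spectrum to its total ion current
#'
#' Divides each spectrum by its summed intensity so every retained spectrum
#' sums to 1. Pixels whose spectrum is entirely zero carry no usable TIC and
#' are dropped; their count and coordinates are attached as attribute
#' `"dropped"`. Idempotent.
#'
#' @param ds an [msi_dataset()].
#' @return a TIC-normalized `msi_dataset`; attribute `"dropped"` holds the
#'   coordinates of removed zero-TIC pixels (possibly 0 rows).
#' @export
tic_normalize <- function(ds) {
  stopifnot(inherits(ds, "msi_dataset"))
  tic <- rowSums(ds$spectra)
  keep <- tic > 0
  if (!any(keep)) stop("all spectra have zero total ion current")
  dropped <- ds$coords[!keep, , drop = FALSE]
  if (nrow(dropped) > 0)
    message(nrow(dropped), " pixel(s) with zero total ion current dropped")
  out <- msi_dataset(ds$coords[keep, , drop = FALSE],
                     ds$spectra[keep, , drop = FALSE] / tic[keep],
                     ds$mz, ds$pitch)
  attr(out, "dropped") <- dropped
  out
}

#' Read / write an MSI dataset as a delimited matrix
#'
#' Plain-text dialect: a first comment line `#mz<TAB>v1<TAB>...` holding the
#' m/z axis and a second `#pitch<TAB>p`, then a TSV table with header
#' `x  y  channel_1 .. channel_n` and one row per pixel.
#'
#' @param ds an [msi_dataset()].
#' @param path file path.
#' @return `write_msi_matrix()` returns `path` invisibly;
#'   `read_msi_matrix()` returns an `msi_dataset`.
#' @export
write_msi_matrix <- function(ds, path) {
  stopifnot(inherits(ds, "msi_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(c("#mz", format(ds$mz, digits = 15, trim = TRUE)),
                     collapse = "\t"),
               paste("#pitch", format(ds$pitch, digits = 15), sep = "\t")),
             con)
  tab <- data.frame(x = ds$coords[, 1], y = ds$coords[, 2], ds$spectra)
  names(tab) <- c("x", "y", paste0("channel_", seq_along(ds$mz)))
  utils::write.table(format(tab, digits = 15, trim = TRUE), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_msi_matrix
#' @export
read_msi_matrix <- function(path) {
  head2 <- readLines(path, n = 2L)
  if (!startsWith(head2[1], "#mz"))
    stop("malformed matrix file (line 1): expected '#mz' header in ", path)
  mz <- as.numeric(strsplit(head2[1], "\t")[[1]][-1])
  pitch <- if (length(head2) > 1 && startsWith(head2[2], "#pitch"))
    as.numeric(strsplit(head2[2], "\t")[[1]][2]) else 70
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (!all(c("x", "y") %in% names(tab)))
    stop("malformed matrix file: missing x/y columns in ", path)
  msi_dataset(as.matrix(tab[, c("x", "y")]),
              as.matrix(tab[, setdiff(names(tab), c("x", "y"))]),
              mz, pitch)
}

#' Read an MSI dataset, dispatching on format
#'
#' @param path path to a `.imzML` file (continuous mode, with its `.ibd`
#'   sibling) or to a delimited matrix file.
#' @param format `"auto"` (by extension), `"imzml"`, or `"matrix"`.
#' @return an [msi_dataset()].
#' @export
read_msi <- function(path, format = c("auto", "imzml", "matrix")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.imzml$", path, ignore.case = TRUE)) "imzml"
              else "matrix"
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format, imzml = read_imzml(path), matrix = read_msi_matrix(path))
}
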