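#' Construct a fluorescence histogram
#'
#' A histogram is the unit of raw data: binned per-nucleus fluorescence
#' intensities for one dye and one run, containing both the sample peak and
#' the internal-standard peak.
#'
#' @param bin_centers numeric, strictly increasing fluorescence channel values
#'   (arbitrary units).
#' @param counts non-negative particle counts per bin; at least one particle
#'   in total.
#' @param dye `"AT_SELECTIVE"` (e.g. DAPI) or `"INTERCALATING"` (e.g. PI).
#' @param meta free-form list of run annotations (specimen id, instrument...).
#' @return An object of class `fcm_histogram`.
#' @export
fcm_histogram <- function(bin_centers, counts,
                          dye = c("AT_SELECTIVE", "INTERCALATING"),
                          meta = list()) {
  dye <- match.arg(dye)
  bin_centers <- as.numeric(bin_centers)
  counts <- as.numeric(counts)
  gs_assert(length(bin_centers) == length(counts) && length(counts) > 0,
            "invalid-histogram", "bin_centers and counts must have equal, positive length")
  gs_assert(all(is.finite(bin_centers)) && all(diff(bin_centers) > 0),
            "invalid-histogram", "bin_centers must be finite and strictly increasing")
  gs_assert(all(is.finite(counts)) && all(counts >= 0),
            "invalid-histogram", "counts must be finite and non-negative")
  gs_assert(sum(counts) >= 1, "empty-histogram", "histogram contains no particles")
  structure(list(bin_centers = bin_centers, counts = counts, dye = dye,
                 meta = meta),
            class = "fcm_histogram")
}

#' @export
print.fcm_histogram <- function(x, ...) {
  cat(sprintf("fcm_histogram: %d bins, %.0f particles, dye %s\n",
              length(x$counts), sum(x$counts), x$dye))
  invisible(x)
}

#' Read a histogram from a two-column channel/count text file
#'
#' Expects plain TSV (or whitespace-delimited) text with columns
#' channel and count; a single header line is detected and dropped.
#'
#' @param path file path.
#' @inheritParams fcm_histogram
#' @return An `fcm_histogram`.
#' @export
read_histogram <- function(path, dye = c("AT_SELECTIVE", "INTERCALATING"),
                           meta = list()) {
  dye <- match.arg(dye)
  gs_assert(file.exists(path), "file-not-found", paste("no such file:", path))
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(trimws(first),
                                                           "[\t ,]+")[[1]][1])))
  tab <- read.table(path, header = has_header, sep = "", comment.char = "#")
  gs_assert(ncol(tab) >= 2, "invalid-histogram",
            "expected two columns: channel, count")
  meta$source <- path
  fcm_histogram(tab[[1]], tab[[2]], dye = dye, meta = meta)
}

#' Write a histogram as two-column TSV
#'
#' @param hist an `fcm_histogram`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "fcm_histogram"))
  write.table(data.frame(channel = hist$bin_centers, count = hist$counts),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
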