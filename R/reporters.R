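#' A centroided MS2 spectrum
#'
#' Minimal carrier for reporter-ion extraction: paired m/z and intensity
#' arrays plus a scan identifier. The m/z array must be sorted ascending
#' (centroided peak lists are) and intensities non-negative.
#'
#' @param scan_id Scan identifier (coerced to character).
#' @param mz Numeric vector of mass-to-charge values in Thomson, ascending.
#' @param intensity Numeric vector of non-negative abundances, same length.
#' @return An object of class `ms2_spectrum`.
#' @export
#' @examples
#' spectrum("scan1", mz = c(126.1277, 127.1248), intensity = c(1e5, 2e5))
spectrum <- function(scan_id, mz = numeric(0), intensity = numeric(0)) {
  mz <- as.numeric(mz); intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("'mz' and 'intensity' must have equal length")
  if (is.unsorted(mz))
    stop("'mz' must be sorted ascending (centroided peak list)")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(scan_id = as.character(scan_id), mz = mz,
                 intensity = intensity),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum> %s: %d peaks\n", x$scan_id, length(x$mz)))
  invisible(x)
}

#' A set of isobaric reporter channels
#'
#' @param name Label-set identifier (e.g. `"tmtpro18"`).
#' @param labels Character vector of channel labels.
#' @param mz Theoretical reporter m/z per channel (Th), all distinct.
#' @return An object of class `channel_set`.
#' @seealso [tmt_channels()] for the shipped TMT/TMTpro tables.
#' @export
channel_set <- function(name, labels, mz) {
  stopifnot(length(labels) == length(mz), length(mz) >= 1L)
  if (anyDuplicated(mz)) stop("theoretical m/z values must be distinct")
  if (anyDuplicated(labels)) stop("channel labels must be distinct")
  structure(list(name = name, labels = as.character(labels),
                 mz = as.numeric(mz)),
            class = "channel_set")
}

# Monoisotopic reporter-ion m/z of the TMT / TMTpro reagent series.
# Standard chemistry constants for the commercial label sets.
.TMT_MZ <- c(
  "126"  = 126.127726, "127N" = 127.124761, "127C" = 127.131081,
  "128N" = 128.128116, "128C" = 128.134436, "129N" = 129.131471,
  "129C" = 129.137790, "130N" = 130.134825, "130C" = 130.141145,
  "131N" = 131.138180, "131C" = 131.144500, "132N" = 132.141535,
  "132C" = 132.147855, "133N" = 133.144890, "133C" = 133.151210,
  "134N" = 134.148245, "134C" = 134.154565, "135N" = 135.151480
)

#' Built-in TMT and TMTpro reporter channel tables
#'
#' Returns the theoretical reporter-ion m/z values of the standard 10-,
#' 11-, 16- and 18-plex isobaric label sets.
#'
#' @param name One of `"tmt10"`, `"tmt11"`, `"tmtpro16"`, `"tmtpro18"`.
#' @return A [channel_set()].
#' @export
#' @examples
#' tmt_channels("tmtpro18")
tmt_channels <- function(name = c("tmtpro18", "tmtpro16", "tmt11", "tmt10")) {
  name <- match.arg(name)
  n <- switch(name, tmt10 = 10L, tmt11 = 11L, tmtpro16 = 16L, tmtpro18 = 18L)
  channel_set(name, names(.TMT_MZ)[seq_len(n)], unname(.TMT_MZ[seq_len(n)]))
}

#' @export
print.channel_set <- function(x, ...) {
  cat(sprintf("<channel_set> %s: %d channels (%.4f-%.4f Th)\n",
              x$name, length(x$mz), min(x$mz), max(x$mz)))
  invisible(x)
}

#' Extract reporter-ion intensities from one spectrum
#'
#' For each channel, a closed window of `tol_ppm` parts per million around
#' the theoretical reporter m/z is searched and the intensity of the most
#' intense peak inside the window is returned; no interpolation or
#' summation. An empty window yields `NA` (missing), never 0. Equal-
#' intensity ties are broken by the peak closest in m/z to the theoretical
#' value, then by the lower m/z.
#'
#' @param spec An [spectrum()] object.
#' @param channels A [channel_set()].
#' @param tol_ppm Half-width of the relative extraction window in ppm
#'   (default 20).
#' @return Data frame with one row per channel: `scan_id`, `channel`,
#'   `theoretical_mz`, `peak_mz`, `intensity` (`NA` when no peak is in
#'   window).
#' @export
extract_reporters <- function(spec, channels, tol_ppm = 20) {
  stopifnot(inherits(spec, "ms2_spectrum"), inherits(channels, "channel_set"))
  if (tol_ppm <= 0) stop("'tol_ppm' must be positive")
  mz <- spec$mz
  nchan <- length(channels$mz)
  peak_mz <- rep(NA_real_, nchan)
  inten <- rep(NA_real_, nchan)
  if (length(mz)) {
    for (k in seq_len(nchan)) {
      mz0 <- channels$mz[k]
      lo <- mz0 * (1 - tol_ppm * 1e-6)
      hi <- mz0 * (1 + tol_ppm * 1e-6)
      # closed interval on both ends; mz sorted so a range scan suffices
      i1 <- findInterval(lo, mz, left.open = TRUE) + 1L
      i2 <- findInterval(hi, mz)
      if (i1 <= i2) {
        idx <- i1:i2
        best <- idx[order(-spec$intensity[idx], abs(mz[idx] - mz0), mz[idx])[1L]]
        peak_mz[k] <- mz[best]
        inten[k] <- spec$intensity[best]
      }
    }
  }
  data.frame(scan_id = spec$scan_id, channel = channels$labels,
             theoretical_mz = channels$mz, peak_mz = peak_mz,
             intensity = inten, stringsAsFactors = FALSE)
}

#' Roll scan-level reporter intensities up to a protein-by-channel table
#'
#' Extracts reporters from every spectrum and sums the scan-level
#' intensities of each protein's spectra per channel. A missing scan-level
#' value contributes 0 to the sum, but a protein whose scans are all
#' missing in a channel stays missing there.
#'
#' @param spectra List of [spectrum()] objects.
#' @param channels A [channel_set()].
#' @param psm_map Data frame with columns `scan_id` and `protein` assigning
#'   each scan to one protein; duplicate scan assignments are rejected.
#' @param tol_ppm Extraction window half-width in ppm.
#' @return Numeric matrix, proteins x channels, `NA` where every
#'   contributing scan was missing.
#' @export
extract_batch <- function(spectra, channels, psm_map, tol_ppm = 20) {
  stopifnot(is.list(spectra), inherits(channels, "channel_set"),
            is.data.frame(psm_map),
            all(c("scan_id", "protein") %in% names(psm_map)))
  if (anyDuplicated(psm_map$scan_id))
    stop("duplicate scan assignment in 'psm_map'")
  scan_ids <- vapply(spectra, `[[`, character(1), "scan_id")
  missing_scans <- setdiff(psm_map$scan_id, scan_ids)
  if (length(missing_scans))
    stop("psm_map references unknown scan(s): ",
         paste(utils::head(missing_scans, 5), collapse = ", "))

  prot <- sort(unique(psm_map$protein))
  out <- matrix(NA_real_, length(prot), length(channels$mz),
                dimnames = list(prot, channels$labels))
  for (i in seq_len(nrow(psm_map))) {
    sp <- spectra[[match(psm_map$scan_id[i], scan_ids)]]
    rec <- extract_reporters(sp, channels, tol_ppm)
    p <- match(psm_map$protein[i], prot)
    obs <- !is.na(rec$intensity)
    cur <- out[p, ]
    cur[obs] <- ifelse(is.na(cur[obs]), 0, cur[obs]) + rec$intensity[obs]
    out[p, ] <- cur
  }
  out
}

#' Read and write spectra in the JSON peak-list fixture format
#'
#' The fixture format is a JSON array of objects
#' `{"scan_id": ..., "mz": [...], "intensity": [...]}` with centroided,
#' m/z-sorted peak lists.
#'
#' @param path File path.
#' @param spectra List of [spectrum()] objects (for writing).
#' @return `read_spectra_json()` returns a list of [spectrum()] objects.
#' @export
read_spectra_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lapply(raw, function(s)
    spectrum(s$scan_id, unlist(s$mz), unlist(s$intensity)))
}

#' @rdname read_spectra_json
#' @export
write_spectra_json <- function(spectra, path) {
  out <- lapply(spectra, function(s)
    list(scan_id = s$scan_id, mz = s$mz, intensity = s$intensity))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read centroided MS2 spectra from an mzML file
#'
#' Thin wrapper over the `mzR` reader; requires the `mzR` package.
#' Profile-mode files are rejected implicitly by the sortedness check of
#' [spectrum()] only if malformed; callers should supply centroided data.
#'
#' @param path Path to an mzML file.
#' @param ms_level Keep spectra of this MS level (default 2).
#' @return List of [spectrum()] objects.
#' @export
read_spectra_mzml <- function(path, ms_level = 2L) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the 'mzR' package")
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh), add = TRUE)
  hd <- mzR::header(fh)
  keep <- which(hd$msLevel == ms_level)
  lapply(keep, function(i) {
    pk <- mzR::peaks(fh, i)
    o <- order(pk[, 1L])
    spectrum(scan_id = as.character(hd$acquisitionNum[i]),
             mz = pk[o, 1L], intensity = pk[o, 2L])
  })
}
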