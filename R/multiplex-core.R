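#' Multiplexed TMA core image
#'
#' Container for one tissue-microarray core imaged in several fluorescence
#' channels, one intensity raster per marker. The required markers are
#' DAPI (nuclei), PanEpi (pooled pan-cytokeratin + E-cadherin epithelial
#' channel), VIM (vimentin) and aSMA (alpha-smooth muscle actin); CAV2
#' (Caveolin-2, endothelium) is optional.
#'
#' @param channels named list of numeric matrices, all of identical
#'   dimensions, intensities >= 0. Names are marker names.
#' @param core_id core identifier.
#' @param patient_id patient identifier.
#' @param pixel_size physical pixel size in micrometres (metadata only).
#' @return an object of class `multiplex_core`.
#' @export
multiplex_core <- function(channels, core_id = "core", patient_id = NA_character_,
                           pixel_size = NULL) {
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == ""))
    stop("`channels` must be a named list of matrices")
  miss <- setdiff(.REQUIRED_MARKERS, names(channels))
  if (length(miss))
    stop("missing required marker channel(s): ", paste(miss, collapse = ", "))
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1))))
    stop("all channels must be matrices")
  d0 <- dims[[1L]]
  if (!all(vapply(dims, function(d) identical(d, d0), logical(1))))
    stop("all channel rasters must share identical dimensions")
  for (nm in names(channels)) {
    if (anyNA(channels[[nm]]) || any(channels[[nm]] < 0))
      stop("channel ", nm, " contains negative or missing intensities")
  }
  structure(
    list(core_id = as.character(core_id),
         patient_id = as.character(patient_id),
         channels = channels,
         pixel_size = pixel_size),
    class = "multiplex_core")
}

#' @export
print.multiplex_core <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("<multiplex_core> %s (patient %s): %d x %d px, markers: %s\n",
              x$core_id, x$patient_id, d[1L], d[2L],
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @export
dim.multiplex_core <- function(x) dim(x$channels[[1L]])

.core_channel <- function(core, marker) {
  ch <- core$channels[[marker]]
  if (is.null(ch)) stop("core ", core$core_id, " has no ", marker, " channel")
  ch
}

#' Write a core to a multi-channel TIFF with a JSON sidecar
#'
#' Channels are stored as one 32-bit float page each, scaled into `[0, 1]`
#' by a per-channel factor recorded in the sidecar (`<stem>.json`) together
#' with channel order and identifiers, so intensities round-trip.
#'
#' @param core a [multiplex_core()].
#' @param dir output directory (created if needed).
#' @return invisibly, the TIFF path.
#' @export
write_core <- function(core, dir) {
  stopifnot(inherits(core, "multiplex_core"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scales <- vapply(core$channels, function(ch) max(1, max(ch)), numeric(1))
  pages <- mapply(function(ch, s) ch / s, core$channels, scales, SIMPLIFY = FALSE)
  tif <- file.path(dir, paste0(core$core_id, ".tif"))
  tiff::writeTIFF(pages, tif, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(core_id = core$core_id, patient_id = core$patient_id,
               channels = names(core$channels), scales = as.list(scales),
               pixel_size = core$pixel_size)
  jsonlite::write_json(meta, file.path(dir, paste0(core$core_id, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(tif)
}

#' Read a core written by [write_core()]
#'
#' @param tif path to the multi-channel TIFF; the sidecar `<stem>.json`
#'   must sit next to it.
#' @return a [multiplex_core()].
#' @export
read_core <- function(tif) {
  sidecar <- sub("\\.tiff?$", ".json", tif)
  if (!file.exists(sidecar)) stop("missing sidecar for ", tif)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tif, all = TRUE)
  if (length(pages) != length(meta$channels))
    stop("channel count mismatch between TIFF and sidecar for ", tif)
  chans <- mapply(function(p, s) p * s, pages, as.numeric(meta$scales),
                  SIMPLIFY = FALSE)
  names(chans) <- meta$channels
  multiplex_core(chans, core_id = meta$core_id, patient_id = meta$patient_id,
                 pixel_size = meta$pixel_size)
}

#' Write / read a label raster as an 8-bit single-channel TIFF
#'
#' Integer label codes (0-255) are stored exactly.
#'
#' @param labels integer matrix of label codes.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_label_raster <- function(labels, path) {
  stopifnot(max(labels) <= 255L, min(labels) >= 0L)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(labels / 255, path, bits.per.sample = 8L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_label_raster
#' @export
read_label_raster <- function(path) {
  m <- tiff::readTIFF(path)
  storage.mode(m) <- "double"
  r <- round(m * 255)
  storage.mode(r) <- "integer"
  r
}
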