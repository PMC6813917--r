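#' Tissue mask of a core
#'
#' Union of the smoothed DAPI and PanEpi channels above a robust background
#' threshold, morphologically closed, hole-filled and lightly dilated so
#' that sparsely nucleated stroma is bridged into a solid tissue region.
#' Per channel, foreground requires exceeding both the Otsu threshold of
#' the smoothed channel and `median + 6 * mad`, so a channel without real
#' signal (e.g. PanEpi on an epithelium-free core) contributes nothing.
#'
#' @param core a [multiplex_core()].
#' @param min_tissue_frac minimum fraction of the raster the mask must
#'   cover; below it the core is flagged low-quality (attribute
#'   `"low_quality"`), never silently dropped.
#' @param sigma Gaussian smoothing sd in pixels.
#' @param closing_radius radius (px) of the disc used for morphological
#'   closing; bridges the spacing between stromal nuclei.
#' @param dilate_radius radius (px) of an optional final dilation; the
#'   default 0 keeps the boundary accuracy-optimal, a positive value
#'   trades boundary precision for guaranteed tissue coverage.
#' @return logical matrix with attribute `low_quality`.
#' @export
tissue_mask <- function(core, min_tissue_frac = 0.1, sigma = 2,
                        closing_radius = 15, dilate_radius = 0) {
  stopifnot(inherits(core, "multiplex_core"))
  u <- matrix(FALSE, nrow(core$channels[[1L]]), ncol(core$channels[[1L]]))
  for (marker in c("DAPI", "PanEpi")) {
    ch <- .core_channel(core, marker)
    if (diff(range(ch)) <= .Machine$double.eps) next
    # signal-presence guard on the raw channel: a channel whose upper tail
    # sits within the noise band around the background contributes nothing
    if (stats::quantile(ch, 0.999, names = FALSE) <=
        stats::median(ch) + 6 * stats::mad(ch)) next
    sm <- EBImage::gblur(ch, sigma = sigma)
    u <- u | (sm > .otsu(as.numeric(sm)))
  }
  if (any(u)) {
    u <- .tidy_mask(u, closing_radius)
    if (dilate_radius > 0) {
      u <- .dilate_mask(u, dilate_radius)
      u <- .tidy_mask(u, closing_radius)
    }
  }
  low <- mean(u) < min_tissue_frac
  attr(u, "low_quality") <- low
  u
}

#' Epithelium mask from the PanEpi channel
#'
#' Pixels whose lightly smoothed PanEpi intensity is strictly above the
#' threshold, intersected with the tissue mask, with small specks removed.
#' The threshold is either a fixed configured value (emulating a manually
#' set cutoff chosen to exclude all stroma) or `"otsu"`, computed within
#' the tissue mask.
#'
#' @param core a [multiplex_core()].
#' @param threshold numeric intensity cutoff (>= 0) or `"otsu"`.
#' @param tissue optional tissue mask; computed by [tissue_mask()] if absent.
#' @param sigma Gaussian smoothing sd in pixels.
#' @param min_area connected components smaller than this (px) are removed.
#' @return logical matrix (subset of `tissue`).
#' @export
epithelium_mask <- function(core, threshold = "otsu", tissue = NULL,
                            sigma = 1, min_area = 64) {
  stopifnot(inherits(core, "multiplex_core"))
  if (is.null(tissue)) tissue <- tissue_mask(core)
  ch <- .core_channel(core, "PanEpi")
  if (!identical(dim(tissue), dim(ch))) stop("tissue mask shape mismatch")
  sm <- EBImage::gblur(ch, sigma = sigma)
  if (identical(threshold, "otsu")) {
    if (!any(tissue)) return(structure(tissue & FALSE, threshold = NA_real_))
    thr <- .otsu(sm[tissue])
  } else {
    if (!is.numeric(threshold) || threshold < 0)
      stop("threshold must be a non-negative number or \"otsu\"")
    thr <- threshold
    if (thr > max(ch))
      warning("PanEpi threshold ", thr, " exceeds channel maximum; empty epithelium mask")
  }
  m <- (sm > thr) & tissue
  m <- .drop_small(m, min_area)
  attr(m, "threshold") <- thr
  m
}

#' Compartment masks: tissue, epithelium, stroma
#'
#' Validates the compartment partition and derives the stroma as tissue
#' minus epithelium, so `epithelium | stroma == tissue` and
#' `epithelium & stroma` is empty by construction.
#'
#' @param tissue,epithelium logical matrices of identical shape;
#'   `epithelium` must be a subset of `tissue`.
#' @return object of class `compartment_masks` with elements `tissue`,
#'   `epithelium`, `stroma`.
#' @export
compartment_masks <- function(tissue, epithelium) {
  if (!identical(dim(tissue), dim(epithelium)))
    stop("tissue and epithelium masks differ in shape")
  tissue <- tissue & TRUE; epithelium <- epithelium & TRUE  # strip attributes
  if (any(epithelium & !tissue))
    stop("epithelium mask extends outside the tissue mask")
  structure(list(tissue = tissue,
                 epithelium = epithelium,
                 stroma = tissue & !epithelium),
            class = "compartment_masks")
}

#' Stromal compartment of validated masks
#'
#' @param masks a [compartment_masks()].
#' @return logical stroma raster.
#' @export
stroma_mask <- function(masks) {
  stopifnot(inherits(masks, "compartment_masks"))
  masks$stroma
}

#' Segment one core into compartments
#'
#' Convenience wrapper running [tissue_mask()] and [epithelium_mask()] and
#' returning validated [compartment_masks()]. The low-quality flag of the
#' tissue mask is propagated as attribute `"low_quality"`.
#'
#' @inheritParams epithelium_mask
#' @param min_tissue_frac,sigma_tissue,closing_radius,dilate_radius passed
#'   to [tissue_mask()].
#' @param sigma_epi,min_epi_area passed to [epithelium_mask()].
#' @return a [compartment_masks()] with attribute `low_quality`.
#' @export
segment_compartments <- function(core, threshold = "otsu",
                                 min_tissue_frac = 0.1, sigma_tissue = 2,
                                 closing_radius = 15, dilate_radius = 0,
                                 sigma_epi = 1, min_epi_area = 64) {
  tis <- tissue_mask(core, min_tissue_frac = min_tissue_frac,
                     sigma = sigma_tissue, closing_radius = closing_radius,
                     dilate_radius = dilate_radius)
  epi <- epithelium_mask(core, threshold = threshold, tissue = tis,
                         sigma = sigma_epi, min_area = min_epi_area)
  m <- compartment_masks(tis, epi)
  attr(m, "low_quality") <- attr(tis, "low_quality")
  m
}

#' @export
print.compartment_masks <- function(x, ...) {
  cat(sprintf("<compartment_masks> %d x %d px: tissue %d, epithelium %d, stroma %d px\n",
              nrow(x$tissue), ncol(x$tissue), sum(x$tissue),
              sum(x$epithelium), sum(x$stroma)))
  invisible(x)
}
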