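#' Binarize a marker channel within a region
#'
#' Marker positivity is defined as intensity strictly above the resolved
#' threshold (ties are negative); pixels outside `region` are always
#' negative.
#'
#' @param channel numeric intensity raster.
#' @param region logical raster delimiting where positivity is evaluated.
#' @param method a single number (fixed threshold), the string `"otsu"`
#'   (Otsu's threshold over the region's intensities), or
#'   `list(quantile = q)` (the q-th linear-interpolation quantile of the
#'   region's intensities).
#'
#' @details For `"otsu"` a bimodality guard protects against channels with
#' no real signal (Otsu always splits, even pure noise): the split is kept
#' only if the two classes it defines are separated by more than six
#' background standard deviations; otherwise the channel is declared
#' negative throughout the region (threshold set to the region maximum).
#'
#' @return logical raster with attribute `"threshold"`.
#' @export
binarize_marker <- function(channel, region, method = "otsu") {
  if (!identical(dim(channel), dim(region))) stop("channel/region shape mismatch")
  data_driven <- !is.numeric(method)
  if (data_driven && !any(region))
    stop("empty region: a data-driven threshold (otsu/quantile) needs pixels")
  thr <-
    if (is.numeric(method) && length(method) == 1L) {
      as.numeric(method)
    } else if (identical(method, "otsu")) {
      vals <- channel[region]
      t0 <- .otsu(vals)
      lo <- vals[vals <= t0]; hi <- vals[vals > t0]
      if (length(hi) && length(lo) > 1L &&
          (mean(hi) - mean(lo)) <= 6 * stats::sd(lo)) max(vals) else t0
    } else if (is.list(method) && !is.null(method$quantile)) {
      stats::quantile(channel[region], method$quantile, names = FALSE, type = 7)
    } else stop("method must be a number, \"otsu\", or list(quantile = q)")
  pos <- region & (channel > thr)
  attr(pos, "threshold") <- thr
  pos
}

#' Classify stromal pixels from marker positivity rasters
#'
#' Truth table applied within the stroma, with endothelial precedence:
#' CAV2+ pixels are endothelium regardless of the other markers; otherwise
#' VIM+/aSMA- is fibroblast, VIM+/aSMA+ is myofibroblast, aSMA+/VIM- is
#' smooth muscle and double-negative pixels are residual (`other_stroma`).
#' When no CAV2 raster is supplied the endothelium class is unused.
#'
#' @param vim_pos,asma_pos logical positivity rasters.
#' @param cav2_pos logical positivity raster or `NULL` (CAV2 not stained).
#' @param stroma logical stroma mask.
#' @return object of class `stromal_class_raster`: integer matrix coded per
#'   [stromal_class_codes()].
#' @export
classify_stromal_pixels <- function(vim_pos, asma_pos, cav2_pos = NULL, stroma) {
  d <- dim(stroma)
  if (!identical(dim(vim_pos), d) || !identical(dim(asma_pos), d) ||
      (!is.null(cav2_pos) && !identical(dim(cav2_pos), d)))
    stop("positivity rasters and stroma mask differ in shape")
  s <- .SC_CODES
  lab <- matrix(s[["outside_stroma"]], d[1L], d[2L])
  lab[stroma] <- s[["other_stroma"]]
  lab[stroma & vim_pos & !asma_pos] <- s[["fibroblast"]]
  lab[stroma & vim_pos & asma_pos] <- s[["myofibroblast"]]
  lab[stroma & !vim_pos & asma_pos] <- s[["smooth_muscle"]]
  if (!is.null(cav2_pos)) lab[stroma & cav2_pos] <- s[["endothelium"]]
  structure(lab, class = "stromal_class_raster")
}

#' Stromal classifier label codes
#' @return named integer vector mapping class names to raster codes.
#' @export
stromal_class_codes <- function() .SC_CODES

#' Pixel counts per stromal class
#'
#' @param classes a [classify_stromal_pixels()] result.
#' @return named integer vector over the five stromal classes.
#' @export
class_areas <- function(classes) {
  stopifnot(inherits(classes, "stromal_class_raster"))
  n <- tabulate(unclass(classes) + 1L, nbins = 6L)
  stats::setNames(n[.SC_CODES[.STROMAL_CLASSES] + 1L], .STROMAL_CLASSES)
}

#' @export
print.stromal_class_raster <- function(x, ...) {
  a <- class_areas(x)
  cat("<stromal_class_raster>", paste(names(a), a, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Nucleus-anchored stromal cell detection
#'
#' Nuclei are connected components of the thresholded, smoothed DAPI
#' channel; with `split = TRUE` touching nuclei are separated by a
#' distance-transform watershed. Components outside the `[min_area,
#' max_area]` range are discarded. A cell belongs to the stroma iff its
#' centroid lies in the stroma mask, otherwise to the epithelium. Mean
#' marker intensities are taken over the nucleus dilated by `ring_radius`
#' pixels (a cytoplasmic-ring proxy).
#'
#' @param core a [multiplex_core()] (DAPI required; all channels measured).
#' @param stroma logical stroma mask.
#' @param sigma DAPI smoothing sd (px).
#' @param threshold DAPI threshold: number or `"otsu"` (whole raster).
#' @param min_area,max_area nucleus area bounds in pixels.
#' @param split split touching nuclei by watershed.
#' @param ring_radius dilation radius (px) for the intensity region.
#' @return a `cell_table` data frame: cell_id, core_id, row, col,
#'   nucleus_area, `mean_<marker>` columns, compartment, class (`NA` until
#'   [classify_cells()]).
#' @export
segment_stromal_nuclei <- function(core, stroma, sigma = 1, threshold = "otsu",
                                   min_area = 5, max_area = 400,
                                   split = TRUE, ring_radius = 2) {
  stopifnot(inherits(core, "multiplex_core"))
  dapi <- .core_channel(core, "DAPI")
  if (!identical(dim(dapi), dim(stroma))) stop("stroma mask shape mismatch")
  empty <- .empty_cell_table(core)
  if (diff(range(dapi)) <= .Machine$double.eps) return(empty)
  sm <- EBImage::gblur(dapi, sigma = sigma)
  thr <- if (identical(threshold, "otsu")) .otsu(as.numeric(sm)) else threshold
  m <- sm > thr
  if (!any(m)) return(empty)
  lab <- if (split) {
    EBImage::watershed(EBImage::distmap(.as01(m)), tolerance = 1, ext = 1)
  } else {
    EBImage::bwlabel(.as01(m))
  }
  lab <- matrix(as.integer(round(as.numeric(lab))), nrow(m), ncol(m))
  nlab <- max(lab)
  if (nlab == 0L) return(empty)
  areas <- tabulate(lab[lab > 0L], nbins = nlab)
  keep <- which(areas >= min_area & areas <= max_area)
  if (!length(keep)) return(empty)

  nr <- nrow(lab)
  idx_by_cell <- split(which(lab > 0L), lab[lab > 0L])
  markers <- names(core$channels)
  out <- vector("list", length(keep))
  brush <- EBImage::makeBrush(2L * as.integer(ring_radius) + 1L, shape = "disc")
  for (i in seq_along(keep)) {
    id <- keep[i]
    idx <- idx_by_cell[[as.character(id)]]
    rows <- (idx - 1L) %% nr + 1L
    cols <- (idx - 1L) %/% nr + 1L
    crow <- mean(rows); ccol <- mean(cols)
    # dilate the nucleus footprint within a padded bounding box
    r0 <- max(1L, min(rows) - ring_radius); r1 <- min(nrow(lab), max(rows) + ring_radius)
    c0 <- max(1L, min(cols) - ring_radius); c1 <- min(ncol(lab), max(cols) + ring_radius)
    sub <- matrix(0, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- 1
    ring <- .mask(EBImage::dilate(sub, brush))
    rij <- which(ring, arr.ind = TRUE)
    ridx <- (c0 + rij[, 2L] - 2L) * nr + (r0 + rij[, 1L] - 1L)
    means <- vapply(markers, function(mk) mean(core$channels[[mk]][ridx]),
                    numeric(1))
    out[[i]] <- c(row = crow, col = ccol, nucleus_area = areas[id], means)
  }
  tab <- as.data.frame(do.call(rbind, out))
  names(tab) <- c("row", "col", "nucleus_area", paste0("mean_", markers))
  cent <- cbind(pmin(pmax(round(tab$row), 1L), nrow(lab)),
                pmin(pmax(round(tab$col), 1L), ncol(lab)))
  tab <- cbind(cell_id = seq_len(nrow(tab)), core_id = core$core_id, tab,
               compartment = ifelse(stroma[cent], "stroma", "epithelium"),
               class = NA_character_, stringsAsFactors = FALSE)
  class(tab) <- c("cell_table", "data.frame")
  tab
}

.empty_cell_table <- function(core) {
  markers <- names(core$channels)
  tab <- data.frame(cell_id = integer(), core_id = character(),
                    row = numeric(), col = numeric(), nucleus_area = numeric(),
                    stringsAsFactors = FALSE)
  for (mk in markers) tab[[paste0("mean_", mk)]] <- numeric()
  tab$compartment <- character(); tab$class <- character()
  class(tab) <- c("cell_table", "data.frame")
  tab
}

#' Classify detected cells by marker positivity
#'
#' Per-cell positivity is mean marker intensity strictly above its cutoff;
#' the same precedence as [classify_stromal_pixels()] applies (CAV2 first
#' when a CAV2 cutoff is given). Epithelial cells are left unclassified.
#'
#' @param cells a `cell_table` from [segment_stromal_nuclei()].
#' @param thresholds named numeric vector of intensity cutoffs; `VIM` and
#'   `aSMA` are required, `CAV2` optional.
#' @return the cell table with `class` filled for stromal cells.
#' @export
classify_cells <- function(cells, thresholds) {
  stopifnot(inherits(cells, "cell_table"))
  need <- c("VIM", "aSMA")
  miss <- setdiff(need, names(thresholds))
  if (length(miss))
    stop("missing required threshold(s): ", paste(miss, collapse = ", "))
  if (nrow(cells) == 0L) return(cells)
  st <- cells$compartment == "stroma"
  vim <- cells$mean_VIM > thresholds[["VIM"]]
  asma <- cells$mean_aSMA > thresholds[["aSMA"]]
  cls <- rep(NA_character_, nrow(cells))
  cls[st] <- "other_stroma"
  cls[st & vim & !asma] <- "fibroblast"
  cls[st & vim & asma] <- "myofibroblast"
  cls[st & !vim & asma] <- "smooth_muscle"
  if ("CAV2" %in% names(thresholds) && "mean_CAV2" %in% names(cells)) {
    cav2 <- cells$mean_CAV2 > thresholds[["CAV2"]]
    cls[st & cav2] <- "endothelium"
  }
  cells$class <- cls
  cells
}
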