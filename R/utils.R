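# Shared label encodings and small numeric helpers.

# Ground-truth label codes written by the simulator.
.GT_CODES <- c(
  non_tissue    = 0L,
  epithelium    = 1L,
  fibroblast    = 2L,
  myofibroblast = 3L,
  smooth_muscle = 4L,
  endothelium   = 5L,
  immune        = 6L,
  other_stroma  = 7L
)

# Stromal classifier output codes.
.SC_CODES <- c(
  outside_stroma = 0L,
  fibroblast     = 1L,
  myofibroblast  = 2L,
  smooth_muscle  = 3L,
  endothelium    = 4L,
  other_stroma   = 5L
)

.STROMAL_CLASSES <- c("fibroblast", "myofibroblast", "smooth_muscle",
                      "endothelium", "other_stroma")

.REQUIRED_MARKERS <- c("DAPI", "PanEpi", "VIM", "aSMA")
.ALL_MARKERS <- c("DAPI", "PanEpi", "VIM", "aSMA", "CAV2")

#' Otsu threshold of a numeric vector
#'
#' Histogram-based Otsu threshold computed on the value range of `x`
#' (256 levels). Scale-equivariant: multiplying `x` by a constant scales
#' the returned threshold by the same constant.
#'
#' @param x numeric vector of intensities.
#' @param levels number of histogram levels.
#' @return threshold value; values strictly above it are "positive".
#' @keywords internal
.otsu <- function(x, levels = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("cannot compute Otsu threshold of an empty region")
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  EBImage::otsu(matrix(x, ncol = 1L), range = r, levels = levels)
}

# Jaccard index of two binary masks.
.jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# logical matrix -> 0/1 numeric for EBImage morphology, and back
.as01 <- function(m) {
  storage.mode(m) <- "double"
  m
}

.mask <- function(m) m > 0.5

# Morphological tidy step used by the tissue mask: closing then hole fill.
.tidy_mask <- function(m, radius) {
  if (!any(m)) return(m)
  k <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  .mask(EBImage::fillHull(EBImage::closing(.as01(m), k)))
}

.dilate_mask <- function(m, radius) {
  if (radius <= 0 || !any(m)) return(m)
  k <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  .mask(EBImage::dilate(.as01(m), k))
}

# Remove connected components smaller than min_area pixels.
.drop_small <- function(m, min_area) {
  if (min_area <= 1 || !any(m)) return(m)
  lab <- EBImage::bwlabel(.as01(m))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  array(lab %in% keep, dim = dim(m))
}

# Evaluate with a private RNG stream seeded by `seed`; restores caller state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
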