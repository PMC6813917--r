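#' Unsupervised stromal phenotype clustering
#'
#' Patients are clustered by agglomerative average linkage on Euclidean
#' distance over their stromal class proportions (optionally standardized
#' per class); the classes themselves are clustered by average linkage on
#' correlation distance (1 - Pearson r). The patient dendrogram is cut to
#' exactly `k` clusters, and cluster ids are relabelled deterministically
#' by the lexicographic order of the cluster centroids so the result is
#' invariant to patient ordering.
#'
#' @param x numeric matrix or data frame, patients x classes (e.g.
#'   `fib_frac`, `myo_frac`, `smc_frac`); row names are patient ids.
#' @param k number of clusters (1 <= k <= n patients).
#' @param scaling `"unit_variance"` (center and scale each class column to
#'   variance 1, matching scaled-heatmap conventions) or `"none"`.
#' @return object of class `cluster_result`: `assignment` (named integer
#'   vector, ids 1..k), `k`, `col_hclust` (patients), `row_hclust`
#'   (classes), `scaling`, `scaled` (the matrix clustered).
#' @export
cluster_patients <- function(x, k, scaling = c("unit_variance", "none")) {
  scaling <- match.arg(scaling)
  m <- as.matrix(x)
  if (anyNA(m)) stop("missing values in the composition matrix")
  n <- nrow(m)
  if (k < 1L || k > n) stop("k must lie between 1 and the number of patients (", n, ")")
  if (is.null(rownames(m))) rownames(m) <- sprintf("p%d", seq_len(n))
  sds <- apply(m, 2L, stats::sd)
  degenerate <- all(sds == 0)  # identical patients: all distances zero
  if (!degenerate && any(sds == 0))
    stop("constant class column(s) under correlation distance: ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  sm <- if (scaling == "unit_variance" && !degenerate) scale(m) else m

  col_h <- stats::hclust(stats::dist(sm, method = "euclidean"),
                         method = "average")
  row_h <- if (degenerate) {
    z <- matrix(0, ncol(m), ncol(m), dimnames = list(colnames(m), colnames(m)))
    stats::hclust(stats::as.dist(z), method = "average")
  } else {
    stats::hclust(stats::as.dist(1 - stats::cor(sm)), method = "average")
  }
  raw <- stats::cutree(col_h, k = k)

  # canonical ids: order clusters by centroid, lexicographically over columns
  cent <- do.call(rbind, lapply(split(seq_len(n), raw), function(i)
    colMeans(sm[i, , drop = FALSE])))
  ord <- do.call(order, as.data.frame(cent))
  remap <- integer(length(ord)); remap[ord] <- seq_along(ord)
  assignment <- stats::setNames(remap[raw], rownames(m))

  structure(list(assignment = assignment, k = as.integer(k),
                 col_hclust = col_h, row_hclust = row_h,
                 scaling = scaling, scaled = sm),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d patients in %d cluster(s) (%s scaling)\n",
              length(x$assignment), x$k, x$scaling))
  print(table(cluster = x$assignment))
  invisible(x)
}

#' @export
plot.cluster_result <- function(x, ...) {
  stats::heatmap(t(x$scaled),
                 Rowv = stats::as.dendrogram(x$row_hclust),
                 Colv = stats::as.dendrogram(x$col_hclust),
                 scale = "none", ...)
  invisible(x)
}

#' Quartile categorization of a patient-level variable
#'
#' Cut points at the 25th/50th/75th percentiles (linear-interpolation
#' quantile definition, R type 7). A value lands in category `c` iff it is
#' strictly above the (c-1)-th cut and at most the c-th; ties at a cut go
#' to the lower category, so category 1 is closed below. Degenerate cuts
#' (ties between percentiles) collapse categories downwards.
#'
#' @param values numeric vector with at least 4 finite values.
#' @return integer vector of categories 1..4 (`NA` preserved).
#' @export
quartile_categorize <- function(values) {
  fin <- values[is.finite(values)]
  if (length(fin) < 4L) stop("need at least 4 finite values to form quartiles")
  q <- stats::quantile(fin, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  out <- 1L + (values > q[1L]) + (values > q[2L]) + (values > q[3L])
  as.integer(out)
}
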