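#' Normalize marker intensities across TMA cores
#'
#' For each marker independently, a core's channel is divided by its robust
#' scale statistic (by default the 99th percentile of intensities within
#' the core's tissue mask) and multiplied by the cohort median of those
#' statistics. Per-core multiplicative gain differences cancel while the
#' cohort-level intensity scale is preserved; applying the normalization
#' twice equals applying it once.
#'
#' A blank channel (zero scale statistic) is left unscaled, the core is
#' flagged (attribute `"flags"`) and a warning is raised.
#'
#' @param cores list of [multiplex_core()] objects, all with the same
#'   marker set.
#' @param tissues optional list of tissue masks aligned with `cores`;
#'   computed via [tissue_mask()] if absent.
#' @param prob probability level of the per-core quantile scale statistic.
#' @return the list of cores with normalized channels; each core carries a
#'   `"norm_scales"` attribute (marker -> scale applied) and possibly
#'   `"flags"`.
#' @export
normalize_intensities <- function(cores, tissues = NULL, prob = 0.99) {
  if (length(cores) < 1L) stop("need at least one core")
  stopifnot(all(vapply(cores, inherits, logical(1), "multiplex_core")))
  markers <- names(cores[[1L]]$channels)
  for (co in cores)
    if (!setequal(names(co$channels), markers))
      stop("all cores must share the same marker set")
  if (is.null(tissues)) tissues <- lapply(cores, tissue_mask)

  for (mk in markers) {
    s <- vapply(seq_along(cores), function(i) {
      tis <- tissues[[i]]
      v <- cores[[i]]$channels[[mk]][tis]
      if (!length(v)) v <- as.numeric(cores[[i]]$channels[[mk]])
      stats::quantile(v, prob, names = FALSE, type = 7)
    }, numeric(1))
    ok <- s > 0
    if (!any(ok)) {
      warning("marker ", mk, " is blank in every core; left unscaled")
      for (i in seq_along(cores))
        attr(cores[[i]], "flags") <- union(attr(cores[[i]], "flags"),
                                           paste0("blank_channel:", mk))
      next
    }
    anchor <- stats::median(s[ok])
    for (i in seq_along(cores)) {
      if (!ok[i]) {
        warning("core ", cores[[i]]$core_id, ": blank ", mk,
                " channel left unscaled")
        attr(cores[[i]], "flags") <- union(attr(cores[[i]], "flags"),
                                           paste0("blank_channel:", mk))
        next
      }
      cores[[i]]$channels[[mk]] <- cores[[i]]$channels[[mk]] * (anchor / s[i])
      sc <- attr(cores[[i]], "norm_scales")
      sc[[mk]] <- anchor / s[i]
      attr(cores[[i]], "norm_scales") <- sc
    }
  }
  cores
}

#' Per-core composition and intensity metrics
#'
#' Relative class areas are reported against total stroma (including the
#' unstained residual class), the stromal fraction against tissue, and
#' mean normalized intensities per marker in the full core (tissue),
#' epithelium and stroma. Cell-count fractions are filled only when a
#' classified cell table is supplied. An empty stroma yields missing
#' fractions and a flagged core rather than an error.
#'
#' @param core a (normalized) [multiplex_core()].
#' @param masks a [compartment_masks()].
#' @param classes a [classify_stromal_pixels()] raster.
#' @param cells optional classified `cell_table` ([classify_cells()]).
#' @param immune_area_frac VIM+ immune area as a fraction of stroma
#'   (ground truth in synthetic mode, or an emulated visual score input);
#'   `NA` if unknown.
#' @return object of class `core_metrics`.
#' @export
compute_core_metrics <- function(core, masks, classes, cells = NULL,
                                 immune_area_frac = NA_real_) {
  stopifnot(inherits(core, "multiplex_core"),
            inherits(masks, "compartment_masks"),
            inherits(classes, "stromal_class_raster"))
  tissue_area <- sum(masks$tissue)
  epi_area <- sum(masks$epithelium)
  stroma_area <- sum(masks$stroma)
  flags <- attr(core, "flags")

  areas <- class_areas(classes)
  if (stroma_area > 0L) {
    area_frac <- areas / stroma_area
  } else {
    area_frac <- stats::setNames(rep(NA_real_, length(areas)), names(areas))
    flags <- union(flags, "empty_stroma")
  }
  count_frac <- NULL
  if (!is.null(cells)) {
    sc <- cells[cells$compartment == "stroma" & !is.na(cells$class), ]
    count_frac <- if (nrow(sc) > 0L) {
      tab <- table(factor(sc$class, levels = .STROMAL_CLASSES))
      as.numeric(tab) / nrow(sc)
    } else rep(NA_real_, length(.STROMAL_CLASSES))
    names(count_frac) <- .STROMAL_CLASSES
  }

  mean_int <- list()
  for (mk in names(core$channels)) {
    ch <- core$channels[[mk]]
    mean_int[[mk]] <- c(
      full = if (tissue_area) mean(ch[masks$tissue]) else NA_real_,
      epithelium = if (epi_area) mean(ch[masks$epithelium]) else NA_real_,
      stroma = if (stroma_area) mean(ch[masks$stroma]) else NA_real_)
  }

  structure(list(core_id = core$core_id, patient_id = core$patient_id,
                 tissue_area = tissue_area, epithelium_area = epi_area,
                 stroma_area = stroma_area,
                 stroma_frac = if (tissue_area) stroma_area / tissue_area else NA_real_,
                 class_area_frac = area_frac,
                 class_count_frac = count_frac,
                 mean_norm_intensity = mean_int,
                 immune_area_frac = immune_area_frac,
                 flags = flags %||% character()),
            class = "core_metrics")
}

#' @export
print.core_metrics <- function(x, ...) {
  cat(sprintf("<core_metrics> %s (patient %s): stroma %d px (%.1f%% of tissue)\n",
              x$core_id, x$patient_id, x$stroma_area, 100 * x$stroma_frac))
  print(round(x$class_area_frac, 3))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Flatten core metrics into a data frame
#'
#' @param metrics list of [compute_core_metrics()] results.
#' @return data frame, one row per core, with `*_area_frac`,
#'   `*_count_frac` (if present), `<marker>_<compartment>` intensity
#'   columns, `immune_area_frac` and a `flagged` indicator.
#' @export
metrics_table <- function(metrics) {
  rows <- lapply(metrics, function(m) {
    stopifnot(inherits(m, "core_metrics"))
    row <- data.frame(core_id = m$core_id, patient_id = m$patient_id,
                      tissue_area = m$tissue_area,
                      epithelium_area = m$epithelium_area,
                      stroma_area = m$stroma_area,
                      stroma_frac = m$stroma_frac,
                      stringsAsFactors = FALSE)
    for (cl in names(m$class_area_frac))
      row[[paste0(cl, "_area_frac")]] <- m$class_area_frac[[cl]]
    if (!is.null(m$class_count_frac))
      for (cl in names(m$class_count_frac))
        row[[paste0(cl, "_count_frac")]] <- m$class_count_frac[[cl]]
    for (mk in names(m$mean_norm_intensity))
      for (cp in names(m$mean_norm_intensity[[mk]]))
        row[[paste0(mk, "_", cp)]] <- m$mean_norm_intensity[[mk]][[cp]]
    row$immune_area_frac <- m$immune_area_frac
    row$flagged <- length(m$flags) > 0L
    row$flags <- paste(m$flags, collapse = ";")
    row
  })
  do.call(rbind, rows)
}

#' Aggregate core metrics into one patient record
#'
#' Unweighted arithmetic mean over the patient's unflagged cores for every
#' fraction and intensity; flagged cores are excluded and `n_cores` records
#' the number actually used. A patient with zero unflagged cores is
#' excluded: the function returns `NULL` and emits a message naming the
#' reason.
#'
#' @param metrics list of [compute_core_metrics()] for one patient.
#' @param clinical_row 1-row data frame with this patient's covariates
#'   (patient_id, age, gleason_group, crpc, time, event).
#' @return 1-row data frame (the patient record), or `NULL` if excluded.
#' @export
aggregate_patient <- function(metrics, clinical_row) {
  stopifnot(length(metrics) >= 1L)
  pid <- unique(vapply(metrics, function(m) m$patient_id, character(1)))
  if (length(pid) != 1L) stop("metrics mix several patients: ",
                              paste(pid, collapse = ", "))
  if (!is.null(clinical_row) && !identical(as.character(clinical_row$patient_id), pid))
    stop("clinical row is for patient ", clinical_row$patient_id,
         ", metrics for ", pid)
  ok <- vapply(metrics, function(m) length(m$flags) == 0L, logical(1))
  if (!any(ok)) {
    message("patient ", pid, " excluded: no unflagged cores (",
            paste(unique(unlist(lapply(metrics, `[[`, "flags"))), collapse = ", "), ")")
    return(NULL)
  }
  tab <- metrics_table(metrics[ok])
  num <- vapply(tab, is.numeric, logical(1))
  agg <- as.data.frame(lapply(tab[num], mean), stringsAsFactors = FALSE)
  rec <- cbind(data.frame(patient_id = pid, n_cores = sum(ok),
                          stringsAsFactors = FALSE),
               agg[setdiff(names(agg), c("flagged"))])
  # friendlier aliases for the headline class fractions
  rec$fib_frac <- rec$fibroblast_area_frac
  rec$myo_frac <- rec$myofibroblast_area_frac
  rec$smc_frac <- rec$smooth_muscle_area_frac
  if (!is.null(clinical_row))
    rec <- cbind(rec, clinical_row[setdiff(names(clinical_row), "patient_id")])
  rec
}

#' Aggregate a whole cohort
#'
#' @param metrics list of [compute_core_metrics()] over all cores.
#' @param clinical data frame of per-patient covariates.
#' @return data frame of patient records (excluded patients dropped, with
#'   messages); attribute `"excluded"` lists their ids.
#' @export
aggregate_patients <- function(metrics, clinical) {
  pids <- vapply(metrics, function(m) m$patient_id, character(1))
  out <- list(); excluded <- character()
  for (pid in unique(pids)) {
    crow <- clinical[clinical$patient_id == pid, , drop = FALSE]
    if (nrow(crow) == 0L) {
      message("patient ", pid, " excluded: no clinical record")
      excluded <- c(excluded, pid)
      next
    }
    rec <- aggregate_patient(metrics[pids == pid], crow[1L, , drop = FALSE])
    if (is.null(rec)) excluded <- c(excluded, pid) else out[[pid]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(res) && !all(is.na(res$immune_area_frac)))
    res$immune_score <- immune_score(res$immune_area_frac)
  attr(res, "excluded") <- excluded
  res
}

#' Immune-content score of the stroma
#'
#' Categorizes the fraction of stromal area occupied by VIM-positive
#' immune cells: below 1% is `low`, 1-5% (boundaries included) is
#' `medium`, above 5% is `high`.
#'
#' @param x numeric vector of fractions in `[0, 1]`.
#' @return factor with levels `low`, `medium`, `high`.
#' @export
immune_score <- function(x) {
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad)) stop("immune area fraction outside [0, 1]: ",
                     paste(format(x[bad]), collapse = ", "))
  out <- ifelse(is.na(x), NA_character_,
                ifelse(x < 0.01, "low", ifelse(x <= 0.05, "medium", "high")))
  factor(out, levels = c("low", "medium", "high"))
}
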