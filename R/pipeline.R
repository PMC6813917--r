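#' Pipeline configuration
#'
#' Bundles every tunable of the analysis with documented defaults:
#' channel names, per-marker positivity thresholds (number, `"otsu"` or
#' `list(quantile = q)`), segmentation parameters, classification mode,
#' normalization quantile, clustering settings, survival covariates and
#' the master seed.
#'
#' @param mode `"pixel"`, `"cell"` or `"both"` classification.
#' @param thresholds named list of per-marker threshold specs for
#'   `PanEpi`, `VIM`, `aSMA`, `CAV2`.
#' @param cav2_exclusion apply CAV2 endothelial precedence when the CAV2
#'   channel is present.
#' @param segmentation list of mask parameters (see [tissue_mask()],
#'   [epithelium_mask()], [segment_stromal_nuclei()]).
#' @param normalization list with `prob`, the scale-statistic quantile.
#' @param clustering list with `k` and `scaling`.
#' @param survival list with `class_covariates`, `adjust` and `fdr_q`.
#' @param seed master seed for any randomized step.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("pixel", "cell", "both"),
                            thresholds = list(PanEpi = "otsu", VIM = "otsu",
                                              aSMA = "otsu", CAV2 = "otsu"),
                            cav2_exclusion = TRUE,
                            segmentation = list(),
                            normalization = list(prob = 0.99),
                            clustering = list(k = 3L, scaling = "unit_variance"),
                            survival = list(
                              class_covariates = c("fib_frac", "myo_frac", "smc_frac"),
                              adjust = c("gleason_group", "age"),
                              fdr_q = 0.2),
                            seed = 1L) {
  mode <- match.arg(mode)
  seg_defaults <- list(min_tissue_frac = 0.1, sigma_tissue = 2,
                       closing_radius = 15, dilate_radius = 0,
                       sigma_epi = 1, min_epi_area = 64,
                       nucleus = list(sigma = 1, min_area = 5, max_area = 400,
                                      split = TRUE, ring_radius = 2))
  segmentation <- utils::modifyList(seg_defaults, segmentation)
  if (is.null(clustering$k) || clustering$k < 1L) stop("clustering k must be >= 1")
  structure(list(mode = mode, thresholds = thresholds,
                 cav2_exclusion = isTRUE(cav2_exclusion),
                 segmentation = segmentation,
                 normalization = normalization, clustering = clustering,
                 survival = survival, seed = as.integer(seed)),
            class = "pipeline_config")
}

# ---- in-memory analysis ------------------------------------------------------

#' Analyse a cohort of cores in memory
#'
#' Runs the full analysis chain on in-memory objects: tissue QC,
#' cross-core intensity normalization, compartment segmentation, stromal
#' classification (pixel and/or cell mode), per-core metrics, per-patient
#' aggregation, quartiles and phenotype clustering, and the survival
#' battery (univariate Cox per class, multivariate fibroblast model,
#' Kaplan-Meier by fibroblast quartile, Schoenfeld check,
#' Benjamini-Hochberg over the univariate class p-values).
#'
#' @param cores list of [multiplex_core()] objects.
#' @param clinical per-patient clinical data frame (patient_id, age,
#'   gleason_group, crpc, time, event).
#' @param config a [pipeline_config()].
#' @param truth_labels optional named list of ground-truth label rasters
#'   (per core id); used to fill the immune area fraction in synthetic
#'   mode.
#' @return object of class `stromaplex_run` with elements `core_metrics`,
#'   `patients`, `clusters`, `survival`, `masks`, `classes`, `cells`,
#'   `excluded`, `config`.
#' @export
analyze_cohort <- function(cores, clinical, config = pipeline_config(),
                           truth_labels = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(cores) == 0L) stop("stage read_cores: no cores to analyse")
  ids <- vapply(cores, function(co) co$core_id, character(1))
  names(cores) <- ids
  seg <- config$segmentation

  stage <- "tissue_qc"
  res <- tryCatch({
    tissues <- lapply(cores, tissue_mask,
                      min_tissue_frac = seg$min_tissue_frac,
                      sigma = seg$sigma_tissue,
                      closing_radius = seg$closing_radius,
                      dilate_radius = seg$dilate_radius)
    low <- vapply(tissues, attr, logical(1), "low_quality")

    stage <- "normalize"
    cores <- normalize_intensities(cores, tissues = tissues,
                                   prob = config$normalization$prob %||% 0.99)

    stage <- "compartments"
    masks <- vector("list", length(cores)); names(masks) <- ids
    for (id in ids) {
      epi <- epithelium_mask(cores[[id]],
                             threshold = config$thresholds$PanEpi %||% "otsu",
                             tissue = tissues[[id]], sigma = seg$sigma_epi,
                             min_area = seg$min_epi_area)
      masks[[id]] <- compartment_masks(tissues[[id]], epi)
      if (low[[id]])
        attr(cores[[id]], "flags") <- union(attr(cores[[id]], "flags"),
                                            "low_quality_tissue")
    }

    stage <- "classify"
    classes <- vector("list", length(cores)); names(classes) <- ids
    cells <- if (config$mode %in% c("cell", "both"))
      stats::setNames(vector("list", length(cores)), ids) else NULL
    for (id in ids) {
      co <- cores[[id]]; mk <- masks[[id]]
      classes[[id]] <- classify_core_pixels(co, mk, config)
      if (!is.null(cells)) {
        nuc <- seg$nucleus
        ct <- segment_stromal_nuclei(co, mk$stroma, sigma = nuc$sigma,
                                     threshold = "otsu",
                                     min_area = nuc$min_area,
                                     max_area = nuc$max_area,
                                     split = nuc$split,
                                     ring_radius = nuc$ring_radius)
        thr <- attr(classes[[id]], "thresholds")
        cells[[id]] <- classify_cells(ct, thr)
      }
    }

    stage <- "quantify"
    metrics <- vector("list", length(cores))
    for (i in seq_along(ids)) {
      id <- ids[i]
      imm <- NA_real_
      if (!is.null(truth_labels[[id]])) {
        g <- .GT_CODES
        lr <- truth_labels[[id]]
        st_n <- sum(!(lr %in% g[c("non_tissue", "epithelium")]))
        if (st_n > 0) imm <- sum(lr == g[["immune"]]) / st_n
      }
      metrics[[i]] <- compute_core_metrics(cores[[id]], masks[[id]],
                                           classes[[id]],
                                           cells = cells[[id]],
                                           immune_area_frac = imm)
    }

    stage <- "aggregate"
    patients <- aggregate_patients(metrics, clinical)
    if (is.null(patients) || nrow(patients) == 0L)
      stop("no patients survived aggregation")

    stage <- "phenotype"
    clusters <- NULL
    if (nrow(patients) >= 4L) {
      patients$fib_quartile <- quartile_categorize(patients$fib_frac)
      patients$myo_quartile <- quartile_categorize(patients$myo_frac)
      patients$smc_quartile <- quartile_categorize(patients$smc_frac)
    }
    if (nrow(patients) >= max(3L, config$clustering$k)) {
      cm <- as.matrix(patients[, c("fib_frac", "myo_frac", "smc_frac")])
      rownames(cm) <- patients$patient_id
      clusters <- tryCatch(
        cluster_patients(cm, k = config$clustering$k,
                         scaling = config$clustering$scaling %||% "unit_variance"),
        error = function(e) {
          message("clustering skipped: ", conditionMessage(e)); NULL
        })
      if (!is.null(clusters))
        patients$cluster <- unname(clusters$assignment[patients$patient_id])
    }

    stage <- "survive"
    surv_res <- run_survival(patients, config$survival)

    structure(list(core_metrics = metrics_table(metrics),
                   patients = patients, clusters = clusters,
                   survival = surv_res,
                   masks = masks, classes = classes, cells = cells,
                   normalized_cores = cores,
                   excluded = attr(patients, "excluded") %||% character(),
                   config = config),
              class = "stromaplex_run")
  }, error = function(e) {
    stop("stage ", stage, " failed: ", conditionMessage(e), call. = FALSE)
  })
  res
}

# Pixel classification of one core under a config (thresholds resolved
# within the stroma); returns the class raster with attribute "thresholds".
classify_core_pixels <- function(core, masks, config) {
  stroma <- masks$stroma
  if (!any(stroma)) {
    cls <- classify_stromal_pixels(stroma, stroma, NULL, stroma)
    attr(cls, "thresholds") <- c(VIM = NA_real_, aSMA = NA_real_)
    return(cls)
  }
  binz <- function(marker) {
    spec <- config$thresholds[[marker]] %||% "otsu"
    binarize_marker(.core_channel(core, marker), stroma, method = spec)
  }
  vim <- binz("VIM"); asma <- binz("aSMA")
  cav2 <- NULL
  if (config$cav2_exclusion && "CAV2" %in% names(core$channels))
    cav2 <- binz("CAV2")
  cls <- classify_stromal_pixels(vim, asma, cav2, stroma)
  thr <- c(VIM = attr(vim, "threshold"), aSMA = attr(asma, "threshold"))
  if (!is.null(cav2)) thr <- c(thr, CAV2 = attr(cav2, "threshold"))
  attr(cls, "thresholds") <- thr
  cls
}

# The survival battery over an aggregated patient table.
run_survival <- function(patients, spec) {
  cls <- intersect(spec$class_covariates %||%
                     c("fib_frac", "myo_frac", "smc_frac"),
                   names(patients))
  adjust <- intersect(spec$adjust %||% c("gleason_group", "age"),
                      names(patients))
  uni <- list()
  for (cv in cls) {
    uni[[cv]] <- tryCatch(cox_fit(patients, class_covariates = cv),
                          error = function(e) conditionMessage(e))
  }
  multi <- tryCatch(cox_fit(patients, class_covariates = cls[1L],
                            adjust = adjust),
                    error = function(e) conditionMessage(e))
  zph <- if (inherits(multi, "stromal_cox"))
    tryCatch(schoenfeld_test(multi), error = function(e) conditionMessage(e))
  km <- NULL
  if ("fib_quartile" %in% names(patients) &&
      length(unique(patients$fib_quartile)) >= 2L && sum(patients$event) >= 1L)
    km <- km_logrank(patients$time, patients$event, patients$fib_quartile)
  ps <- vapply(uni, function(u)
    if (inherits(u, "stromal_cox")) u$table$wald_p[1L] else NA_real_, numeric(1))
  bh <- if (all(is.finite(ps))) bh_adjust(ps, q = spec$fdr_q %||% 0.2) else NULL
  list(univariate = uni, multivariate = multi, schoenfeld = zph,
       km_fib_quartile = km, bh = bh, univariate_p = ps)
}

#' @export
print.stromaplex_run <- function(x, ...) {
  cat(sprintf("<stromaplex_run> %d cores, %d patients (%d excluded)\n",
              nrow(x$core_metrics), nrow(x$patients), length(x$excluded)))
  if (inherits(x$survival$multivariate, "stromal_cox")) {
    cat("multivariate Cox:\n"); print(x$survival$multivariate)
  }
  invisible(x)
}

# ---- disk stages -------------------------------------------------------------

.compartment_raster <- function(masks) {
  r <- matrix(0L, nrow(masks$tissue), ncol(masks$tissue))
  r[masks$epithelium] <- 1L
  r[masks$stroma] <- 2L
  r
}

.read_input_cores <- function(input_dir) {
  tifs <- sort(list.files(file.path(input_dir, "cores"),
                          pattern = "\\.tiff?$", full.names = TRUE))
  if (!length(tifs)) stop("stage read_cores: no core TIFFs in ",
                          file.path(input_dir, "cores"))
  lapply(tifs, read_core)
}

.read_truth_labels <- function(input_dir, ids) {
  dir <- file.path(input_dir, "labels")
  if (!dir.exists(dir)) return(NULL)
  out <- list()
  for (id in ids) {
    f <- file.path(dir, paste0(id, "_truth.tif"))
    if (file.exists(f)) out[[id]] <- read_label_raster(f)
  }
  if (length(out)) out else NULL
}

#' Run the full pipeline on a cohort directory
#'
#' Reads cores (multi-channel TIFFs with sidecars under `cores/`), the
#' clinical table (`clinical.csv`) and optional ground-truth label rasters
#' (`labels/`) from `input_dir`, runs [analyze_cohort()], and writes to
#' `out_dir`: cached intermediates (compartment and class label rasters),
#' `tables/core_metrics.csv`, `tables/patients.csv`,
#' `results/survival.json`, `results/clusters.csv`, the effective
#' `config.json` and a run manifest (config hash, seed, versions, per-stage
#' retention counts with exclusion reasons). Any stage failure aborts with
#' the stage name; partial outputs are kept and the manifest carries a
#' FAILED marker.
#'
#' @param input_dir cohort directory (as written by [write_cohort()]).
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @return the [analyze_cohort()] result, invisibly.
#' @export
run_pipeline <- function(input_dir, out_dir, config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.txt")
  on_fail <- function(e) {
    cat(c("STATUS: FAILED", conditionMessage(e)),
        file = manifest_path, sep = "\n", append = file.exists(manifest_path))
    stop(e)
  }
  tryCatch({
    cores <- .read_input_cores(input_dir)
    clin_path <- file.path(input_dir, "clinical.csv")
    if (!file.exists(clin_path)) stop("stage read_cores: missing clinical.csv")
    clinical <- utils::read.csv(clin_path, stringsAsFactors = FALSE)
    ids <- vapply(cores, function(co) co$core_id, character(1))
    truth <- .read_truth_labels(input_dir, ids)

    run <- analyze_cohort(cores, clinical, config, truth_labels = truth)

    # cached intermediates so single stages can be re-run
    for (id in names(run$masks)) {
      write_core(run$normalized_cores[[id]], file.path(out_dir, "normalized"))
      write_label_raster(.compartment_raster(run$masks[[id]]),
                         file.path(out_dir, "masks", paste0(id, "_compartments.tif")))
      write_label_raster(unclass(run$classes[[id]]),
                         file.path(out_dir, "classes", paste0(id, "_classes.tif")))
      if (!is.null(run$cells) && !is.null(run$cells[[id]])) {
        dir.create(file.path(out_dir, "cells"), showWarnings = FALSE)
        utils::write.csv(run$cells[[id]],
                         file.path(out_dir, "cells", paste0(id, "_cells.csv")),
                         row.names = FALSE)
      }
    }
    dir.create(file.path(out_dir, "tables"), showWarnings = FALSE)
    dir.create(file.path(out_dir, "results"), showWarnings = FALSE)
    utils::write.csv(run$core_metrics,
                     file.path(out_dir, "tables", "core_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(run$patients,
                     file.path(out_dir, "tables", "patients.csv"),
                     row.names = FALSE)
    if (!is.null(run$clusters))
      utils::write.csv(data.frame(patient_id = names(run$clusters$assignment),
                                  cluster = unname(run$clusters$assignment)),
                       file.path(out_dir, "results", "clusters.csv"),
                       row.names = FALSE)
    jsonlite::write_json(.survival_json(run$survival),
                         file.path(out_dir, "results", "survival.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")

    cfg_path <- file.path(out_dir, "config.json")
    jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                         digits = NA, force = TRUE)
    .write_manifest(manifest_path, config, cfg_path, cores, run)
    invisible(run)
  }, error = on_fail)
}

.survival_json <- function(sr) {
  conv <- function(u) if (inherits(u, "stromal_cox"))
    list(n = u$n, n_events = u$n_events, n_excluded = u$n_excluded,
         table = u$table) else list(error = u)
  list(univariate = lapply(sr$univariate, conv),
       multivariate = conv(sr$multivariate),
       schoenfeld = if (is.data.frame(sr$schoenfeld)) sr$schoenfeld else
         list(error = sr$schoenfeld),
       logrank_fib_quartile = if (!is.null(sr$km_fib_quartile))
         sr$km_fib_quartile$logrank,
       bh = if (!is.null(sr$bh))
         list(q = sr$bh$q, reject = sr$bh$reject, adjusted = sr$bh$adjusted))
}

.write_manifest <- function(path, config, cfg_path, cores, run) {
  flagged <- run$core_metrics$core_id[run$core_metrics$flagged]
  reasons <- run$core_metrics$flags[run$core_metrics$flagged]
  lines <- c(
    "STATUS: OK",
    paste0("config_md5: ", unname(tools::md5sum(cfg_path))),
    paste0("seed: ", config$seed),
    paste0("stromaplex_version: ",
           as.character(utils::packageVersion("stromaplex"))),
    paste0("r_version: ", R.version.string),
    paste0("cores_in: ", length(cores)),
    paste0("cores_flagged: ", length(flagged)),
    if (length(flagged)) paste0("  flagged_core: ", flagged, " (", reasons, ")"),
    paste0("patients_in: ", nrow(run$patients) + length(run$excluded)),
    paste0("patients_retained: ", nrow(run$patients)),
    paste0("patients_excluded: ", length(run$excluded)),
    if (length(run$excluded)) paste0("  excluded_patient: ", run$excluded))
  writeLines(lines, path)
}

# ---- single-stage re-runs from cached intermediates -------------------------

.read_cached_cores <- function(out_dir, sub = "normalized") {
  tifs <- sort(list.files(file.path(out_dir, sub), pattern = "\\.tiff?$",
                          full.names = TRUE))
  if (!length(tifs)) stop("no cached cores under ", file.path(out_dir, sub))
  cores <- lapply(tifs, read_core)
  names(cores) <- vapply(cores, function(co) co$core_id, character(1))
  cores
}

.read_cached_masks <- function(out_dir, ids) {
  out <- list()
  for (id in ids) {
    r <- read_label_raster(file.path(out_dir, "masks",
                                     paste0(id, "_compartments.tif")))
    out[[id]] <- compartment_masks(r > 0L, r == 1L)
  }
  out
}

#' Re-run single pipeline stages from cached intermediates
#'
#' Each stage reads what the previous one wrote under `out_dir` (and the
#' original `input_dir` where raw inputs are needed) and rewrites only its
#' own outputs, reproducing the corresponding slice of [run_pipeline()].
#'
#' @param out_dir pipeline output directory holding the cache.
#' @param config the same [pipeline_config()] used for the full run.
#' @param input_dir original cohort directory (needed by `quantify` for
#'   the clinical table and ground-truth labels).
#' @return invisibly, the recomputed stage output.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_segment <- function(out_dir, config = pipeline_config()) {
  cores <- .read_cached_cores(out_dir)
  seg <- config$segmentation
  for (id in names(cores)) {
    m <- segment_compartments(cores[[id]],
                              threshold = config$thresholds$PanEpi %||% "otsu",
                              min_tissue_frac = seg$min_tissue_frac,
                              sigma_tissue = seg$sigma_tissue,
                              closing_radius = seg$closing_radius,
                              dilate_radius = seg$dilate_radius,
                              sigma_epi = seg$sigma_epi,
                              min_epi_area = seg$min_epi_area)
    write_label_raster(.compartment_raster(m),
                       file.path(out_dir, "masks",
                                 paste0(id, "_compartments.tif")))
  }
  invisible(NULL)
}

#' @rdname pipeline_stages
#' @export
stage_classify <- function(out_dir, config = pipeline_config()) {
  cores <- .read_cached_cores(out_dir)
  masks <- .read_cached_masks(out_dir, names(cores))
  for (id in names(cores)) {
    cls <- classify_core_pixels(cores[[id]], masks[[id]], config)
    write_label_raster(unclass(cls),
                       file.path(out_dir, "classes",
                                 paste0(id, "_classes.tif")))
    if (config$mode %in% c("cell", "both")) {
      nuc <- config$segmentation$nucleus
      ct <- segment_stromal_nuclei(cores[[id]], masks[[id]]$stroma,
                                   sigma = nuc$sigma, threshold = "otsu",
                                   min_area = nuc$min_area,
                                   max_area = nuc$max_area, split = nuc$split,
                                   ring_radius = nuc$ring_radius)
      ct <- classify_cells(ct, attr(cls, "thresholds"))
      dir.create(file.path(out_dir, "cells"), showWarnings = FALSE)
      utils::write.csv(ct, file.path(out_dir, "cells",
                                     paste0(id, "_cells.csv")),
                       row.names = FALSE)
    }
  }
  invisible(NULL)
}

#' @rdname pipeline_stages
#' @export
stage_quantify <- function(out_dir, config = pipeline_config(),
                           input_dir = NULL) {
  cores <- .read_cached_cores(out_dir)
  ids <- names(cores)
  masks <- .read_cached_masks(out_dir, ids)
  truth <- if (!is.null(input_dir)) .read_truth_labels(input_dir, ids)
  clin_path <- file.path(input_dir %||% out_dir, "clinical.csv")
  clinical <- utils::read.csv(clin_path, stringsAsFactors = FALSE)
  metrics <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    lab <- read_label_raster(file.path(out_dir, "classes",
                                       paste0(id, "_classes.tif")))
    cls <- structure(lab, class = "stromal_class_raster")
    cf <- file.path(out_dir, "cells", paste0(id, "_cells.csv"))
    cells <- if (file.exists(cf)) {
      ct <- utils::read.csv(cf, stringsAsFactors = FALSE)
      class(ct) <- c("cell_table", "data.frame")
      ct
    }
    imm <- NA_real_
    if (!is.null(truth[[id]])) {
      g <- .GT_CODES
      st_n <- sum(!(truth[[id]] %in% g[c("non_tissue", "epithelium")]))
      if (st_n > 0) imm <- sum(truth[[id]] == g[["immune"]]) / st_n
    }
    metrics[[i]] <- compute_core_metrics(cores[[id]], masks[[id]], cls,
                                         cells = cells,
                                         immune_area_frac = imm)
  }
  patients <- aggregate_patients(metrics, clinical)
  if (nrow(patients) >= 4L) {
    patients$fib_quartile <- quartile_categorize(patients$fib_frac)
    patients$myo_quartile <- quartile_categorize(patients$myo_frac)
    patients$smc_quartile <- quartile_categorize(patients$smc_frac)
  }
  dir.create(file.path(out_dir, "tables"), showWarnings = FALSE)
  utils::write.csv(metrics_table(metrics),
                   file.path(out_dir, "tables", "core_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(patients, file.path(out_dir, "tables", "patients.csv"),
                   row.names = FALSE)
  invisible(patients)
}

#' @rdname pipeline_stages
#' @export
stage_phenotype <- function(out_dir, config = pipeline_config()) {
  patients <- utils::read.csv(file.path(out_dir, "tables", "patients.csv"),
                              stringsAsFactors = FALSE)
  cm <- as.matrix(patients[, c("fib_frac", "myo_frac", "smc_frac")])
  rownames(cm) <- patients$patient_id
  cl <- cluster_patients(cm, k = config$clustering$k,
                         scaling = config$clustering$scaling %||% "unit_variance")
  dir.create(file.path(out_dir, "results"), showWarnings = FALSE)
  utils::write.csv(data.frame(patient_id = names(cl$assignment),
                              cluster = unname(cl$assignment)),
                   file.path(out_dir, "results", "clusters.csv"),
                   row.names = FALSE)
  invisible(cl)
}

#' @rdname pipeline_stages
#' @export
stage_survive <- function(out_dir, config = pipeline_config()) {
  patients <- utils::read.csv(file.path(out_dir, "tables", "patients.csv"),
                              stringsAsFactors = FALSE)
  sr <- run_survival(patients, config$survival)
  dir.create(file.path(out_dir, "results"), showWarnings = FALSE)
  jsonlite::write_json(.survival_json(sr),
                       file.path(out_dir, "results", "survival.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(sr)
}
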