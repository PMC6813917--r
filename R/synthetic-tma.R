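#' Target stromal composition of a synthetic core
#'
#' Area fractions of the stromal compartment for each simulated class, plus
#' the epithelial fraction of total tissue area. The six stromal fractions
#' must sum to 1.
#'
#' @param fib,myo,smc,endo,imm,other stromal area fractions in `[0, 1]` for
#'   fibroblasts, myofibroblasts, smooth muscle, endothelium, immune cells
#'   and unstained residual stroma.
#' @param epi_frac epithelial fraction of tissue area, in `[0, 1)`.
#' @return object of class `stromal_composition`.
#' @export
stromal_composition <- function(fib = 0.25, myo = 0.09, smc = 0.30,
                                endo = 0.03, imm = 0.03, other = 0.30,
                                epi_frac = 0.35) {
  fr <- c(fib = fib, myo = myo, smc = smc, endo = endo, imm = imm, other = other)
  if (any(fr < 0)) stop("stromal fractions must be non-negative")
  s <- sum(fr)
  if (abs(s - 1) > 1e-9)
    stop(sprintf("stromal fractions must sum to 1 (got %.12g)", s))
  if (epi_frac < 0 || epi_frac >= 1) stop("epi_frac must lie in [0, 1)")
  structure(c(as.list(fr), list(epi_frac = epi_frac)),
            class = "stromal_composition")
}

#' Parameters of the proportional-hazards survival simulator
#'
#' Event times are exponential with rate
#' `baseline_hazard * exp(log_hr_per_10pct * 10 * p)` where `p` is the
#' patient's fibroblast fraction of stroma, so the covariate is on the same
#' "per 10 percentage points" scale the Cox model reports. Administrative
#' censoring at `censor_time`. Patient fibroblast fractions are drawn from
#' `Beta(fib_dist_alpha, fib_dist_beta)`.
#'
#' @param baseline_hazard events per unit time at `p = 0`; must be > 0.
#' @param log_hr_per_10pct log hazard ratio per 10-percentage-point increase
#'   in the fibroblast proportion.
#' @param censor_time administrative censoring horizon (> 0).
#' @param fib_dist_alpha,fib_dist_beta Beta shape parameters (> 0).
#' @return object of class `survival_sim_params`.
#' @export
survival_sim_params <- function(baseline_hazard = 0.005,
                                log_hr_per_10pct = log(2),
                                censor_time = 120,
                                fib_dist_alpha = 2, fib_dist_beta = 6) {
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (censor_time <= 0) stop("censor_time must be positive")
  if (fib_dist_alpha <= 0 || fib_dist_beta <= 0) stop("Beta shapes must be positive")
  structure(list(baseline_hazard = baseline_hazard,
                 log_hr_per_10pct = log_hr_per_10pct,
                 censor_time = censor_time,
                 fib_dist_alpha = fib_dist_alpha,
                 fib_dist_beta = fib_dist_beta),
            class = "survival_sim_params")
}

# ---- shape rasterizers (matrix indices of painted pixels) -------------------

# Rotated filled ellipse; returns linear indices into an nr x nc matrix.
.ellipse_idx <- function(nr, nc, cy, cx, a, b, theta) {
  e <- max(a, b)
  r0 <- max(1L, floor(cy - e)); r1 <- min(nr, ceiling(cy + e))
  c0 <- max(1L, floor(cx - e)); c1 <- min(nc, ceiling(cx + e))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  dy <- rows - cy; dx <- cols - cx
  ct <- cos(theta); st <- sin(theta)
  u <- outer(dy, dx, function(y, x) (ct * x + st * y) / a)
  v <- outer(dy, dx, function(y, x) (-st * x + ct * y) / b)
  inside <- u * u + v * v <= 1
  ij <- which(inside, arr.ind = TRUE)
  (cols[ij[, 2L]] - 1L) * nr + rows[ij[, 1L]]
}

# Circular annulus (vessel cross-section).
.annulus_idx <- function(nr, nc, cy, cx, r_out, width) {
  r0 <- max(1L, floor(cy - r_out)); r1 <- min(nr, ceiling(cy + r_out))
  c0 <- max(1L, floor(cx - r_out)); c1 <- min(nc, ceiling(cx + r_out))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  d2 <- outer((rows - cy)^2, (cols - cx)^2, `+`)
  inside <- d2 <= r_out^2 & d2 >= max(0, r_out - width)^2
  ij <- which(inside, arr.ind = TRUE)
  (cols[ij[, 2L]] - 1L) * nr + rows[ij[, 1L]]
}

.disc_idx <- function(nr, nc, cy, cx, r) .ellipse_idx(nr, nc, cy, cx, r, r, 0)

# Per-class object geometry. Foreground body sizes are kept comparable across
# classes so area-based and count-based fractions agree on sparse cores.
.draw_object <- function(class, nr, nc, cy, cx) {
  switch(class,
    fibroblast = {
      idx <- .ellipse_idx(nr, nc, cy, cx, stats::runif(1, 4.5, 6.5),
                          stats::runif(1, 2.0, 3.0), stats::runif(1, 0, pi))
      list(idx = idx, nuc_r = 2.0)
    },
    myofibroblast = {
      idx <- .ellipse_idx(nr, nc, cy, cx, stats::runif(1, 4.5, 6.5),
                          stats::runif(1, 2.0, 3.0), stats::runif(1, 0, pi))
      list(idx = idx, nuc_r = 2.0)
    },
    smooth_muscle = {
      idx <- .ellipse_idx(nr, nc, cy, cx, stats::runif(1, 7, 10),
                          stats::runif(1, 1.6, 2.2), stats::runif(1, 0, pi))
      list(idx = idx, nuc_r = 2.0)
    },
    endothelium = {
      idx <- .annulus_idx(nr, nc, cy, cx, stats::runif(1, 4, 5.5), 2.2)
      list(idx = idx, nuc_r = 1.8)
    },
    immune = {
      idx <- .disc_idx(nr, nc, cy, cx, stats::runif(1, 2.2, 3.0))
      list(idx = idx, nuc_r = 2.4)
    },
    stop("unknown object class ", class))
}

# ---- core generator ---------------------------------------------------------

#' Generate one synthetic multiplexed TMA core with ground truth
#'
#' Renders a circular tissue core on a dark background: elliptical gland
#' clusters form the epithelium (PanEpi+, nucleated), and the stroma is
#' populated with spindle-shaped fibroblasts (VIM+ only), spindle
#' myofibroblasts (VIM+ aSMA+), elongated smooth-muscle bundles (aSMA+
#' only), ring-shaped endothelium (CAV2+ VIM+), small round immune cells
#' (VIM+, dense nucleus) and unstained residual stroma. Every cellular
#' object carries one DAPI nucleus; sparse nuclei are also scattered in
#' unstained stroma and glands. All channels share a background offset of
#' 5% of the foreground level, are multiplied by `gain`, perturbed with
#' Gaussian noise of sd `noise_sd` and clipped at 0.
#'
#' Objects placed later overwrite earlier stromal labels where they
#' overlap; object centres are drawn from still-unassigned stromal pixels
#' and a bounded top-up pass refills eroded classes, so realized fractions
#' track the request to within about 0.05 on cores with >= 1e4 stromal
#' pixels. Realized fractions are always recomputed from the final label
#' raster and are therefore exact by construction.
#'
#' @param composition a [stromal_composition()].
#' @param width,height raster size in pixels, each >= 64.
#' @param noise_sd Gaussian noise standard deviation (intensity units;
#'   foreground is 100).
#' @param gain per-core multiplicative gain applied to all channels.
#' @param seed integer seed; identical arguments and seed give bit-identical
#'   output. The caller's RNG state is left untouched.
#' @param foreground foreground intensity level (default 100; background
#'   offset is 5% of it).
#' @return list with elements `core` (a [multiplex_core()] with channels
#'   DAPI, PanEpi, VIM, aSMA, CAV2) and `truth` (class `core_ground_truth`:
#'   `label_raster` coded per [ground_truth_codes()], `realized_fractions`,
#'   `objects` data frame, `seed`).
#' @export
generate_core <- function(composition, width = 512L, height = 512L,
                          noise_sd = 5, gain = 1, seed = 1L,
                          foreground = 100) {
  stopifnot(inherits(composition, "stromal_composition"))
  if (width < 64L || height < 64L) stop("width and height must be >= 64 pixels")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (gain <= 0) stop("gain must be positive")
  .with_seed(seed, .generate_core_impl(composition, as.integer(width),
                                       as.integer(height), noise_sd, gain,
                                       as.integer(seed), foreground))
}

.generate_core_impl <- function(comp, width, height, noise_sd, gain, seed,
                                foreground) {
  nr <- height; nc <- width
  bg <- 0.05 * foreground

  # circular tissue core
  radius <- 0.46 * min(nr, nc)
  cy0 <- (nr + 1) / 2; cx0 <- (nc + 1) / 2
  d2 <- outer((seq_len(nr) - cy0)^2, (seq_len(nc) - cx0)^2, `+`)
  tissue <- d2 <= radius^2
  tissue_n <- sum(tissue)

  lab <- matrix(.GT_CODES[["non_tissue"]], nr, nc)
  lab[tissue] <- .GT_CODES[["other_stroma"]]

  nuc_centers <- list()  # rows: (row, col, r)

  # --- epithelium: elliptical gland clusters ---------------------------------
  epi_target <- round(comp$epi_frac * tissue_n)
  scale_ax <- 0.045 * min(nr, nc)
  if (epi_target > 0L) {
    if (scale_ax < 2) stop("image too small to place any gland")
    epi_n <- 0L; attempts <- 0L
    max_attempts <- 4000L
    tissue_idx <- which(tissue)
    while (epi_n < epi_target && attempts < max_attempts) {
      attempts <- attempts + 1L
      ctr <- tissue_idx[sample.int(length(tissue_idx), 1L)]
      cy <- (ctr - 1L) %% nr + 1L; cx <- (ctr - 1L) %/% nr + 1L
      a <- stats::runif(1, 0.7, 1.4) * scale_ax
      b <- a * stats::runif(1, 0.55, 0.85)
      idx <- .ellipse_idx(nr, nc, cy, cx, a, b, stats::runif(1, 0, pi))
      idx <- idx[tissue[idx]]
      new <- idx[lab[idx] != .GT_CODES[["epithelium"]]]
      lab[idx] <- .GT_CODES[["epithelium"]]
      epi_n <- epi_n + length(new)
      # nuclei sprinkled through the gland
      n_nuc <- max(1L, round(length(idx) / 60))
      if (length(idx)) {
        picks <- idx[sample.int(length(idx), min(n_nuc, length(idx)))]
        nuc_centers[[length(nuc_centers) + 1L]] <-
          cbind((picks - 1L) %% nr + 1L, (picks - 1L) %/% nr + 1L, 1.8)
      }
    }
  }
  epi_mask <- lab == .GT_CODES[["epithelium"]]
  stroma <- tissue & !epi_mask
  stroma_n <- sum(stroma)
  if (stroma_n == 0L) stop("composition left no stromal pixels")

  # --- stromal object placement ----------------------------------------------
  class_order <- c("fibroblast", "myofibroblast", "smooth_muscle",
                   "endothelium", "immune")
  fr <- c(fibroblast = comp$fib, myofibroblast = comp$myo,
          smooth_muscle = comp$smc, endothelium = comp$endo,
          immune = comp$imm)
  targets <- round(fr * stroma_n)
  cnt <- stats::setNames(integer(5L), class_order)
  objects <- list()
  other_code <- .GT_CODES[["other_stroma"]]

  # Cached pool of unassigned stromal pixels; entries may go stale as objects
  # paint over them, so draws are validated and the pool refreshed on demand.
  pool <- which(lab == other_code)
  draw_center <- function() {
    for (try in 1:50) {
      if (!length(pool)) return(NA_integer_)
      ctr <- pool[sample.int(length(pool), 1L)]
      if (lab[ctr] == other_code) return(ctr)
    }
    pool <<- which(lab == other_code)
    if (!length(pool)) return(NA_integer_)
    pool[sample.int(length(pool), 1L)]
  }

  place_class <- function(cls) {
    code <- .GT_CODES[[cls]]
    attempts <- 0L
    max_attempts <- 2000L + ceiling(targets[[cls]] / 5)
    while (cnt[[cls]] < targets[[cls]] && attempts < max_attempts) {
      attempts <- attempts + 1L
      ctr <- draw_center()
      if (is.na(ctr)) break
      cy <- (ctr - 1L) %% nr + 1L; cx <- (ctr - 1L) %/% nr + 1L
      obj <- .draw_object(cls, nr, nc, cy, cx)
      idx <- obj$idx[stroma[obj$idx]]
      if (!length(idx)) next
      old <- lab[idx]
      for (oc in class_order)
        cnt[[oc]] <<- cnt[[oc]] - sum(old == .GT_CODES[[oc]])
      lab[idx] <<- code
      cnt[[cls]] <<- cnt[[cls]] + length(idx)
      objects[[length(objects) + 1L]] <<-
        data.frame(class = cls, row = cy, col = cx, nuc_r = obj$nuc_r)
      nuc_centers[[length(nuc_centers) + 1L]] <<- cbind(cy, cx, obj$nuc_r)
    }
  }

  for (cls in class_order) if (targets[[cls]] > 0L) place_class(cls)
  # top-up: classes eroded by later overwrites
  for (pass in 1:3) {
    deficit <- targets - cnt
    if (all(deficit <= pmax(1, 0.01 * stroma_n))) break
    for (cls in class_order) if (deficit[[cls]] > 0) place_class(cls)
  }

  # unstained stroma is still cellular: one nucleus per ~45 px, the same
  # footprint as the stained classes, so count- and area-based fractions agree
  rest <- which(lab == other_code)
  if (length(rest)) {
    n_rest <- max(1L, round(length(rest) / 45))
    picks <- rest[sample.int(length(rest), min(n_rest, length(rest)))]
    prow <- (picks - 1L) %% nr + 1L; pcol <- (picks - 1L) %/% nr + 1L
    nuc_centers[[length(nuc_centers) + 1L]] <- cbind(prow, pcol, 2.0)
    objects[[length(objects) + 1L]] <-
      data.frame(class = "other_stroma", row = prow, col = pcol, nuc_r = 2.0)
  }

  # --- render channels --------------------------------------------------------
  nuc <- matrix(FALSE, nr, nc)
  nucs <- do.call(rbind, nuc_centers)
  if (!is.null(nucs)) {
    for (i in seq_len(nrow(nucs)))
      nuc[.disc_idx(nr, nc, nucs[i, 1L], nucs[i, 2L], nucs[i, 3L])] <- TRUE
  }

  g <- .GT_CODES
  render <- function(ind) {
    ch <- matrix(bg, nr, nc)
    ch[ind] <- bg + foreground
    ch <- ch * gain
    if (noise_sd > 0) ch <- ch + stats::rnorm(length(ch), 0, noise_sd)
    pmax(ch, 0)
  }
  channels <- list(
    DAPI   = render(nuc),
    PanEpi = render(lab == g[["epithelium"]]),
    VIM    = render(lab %in% g[c("fibroblast", "myofibroblast",
                                 "endothelium", "immune")]),
    aSMA   = render(lab %in% g[c("myofibroblast", "smooth_muscle")]),
    CAV2   = render(lab == g[["endothelium"]])
  )

  realized <- .realized_fractions(lab)
  core <- multiplex_core(channels, core_id = sprintf("core_s%d", seed))
  truth <- structure(
    list(label_raster = lab,
         realized_fractions = realized,
         objects = if (length(objects)) do.call(rbind, objects) else
           data.frame(class = character(), row = numeric(), col = numeric(),
                      nuc_r = numeric()),
         seed = seed),
    class = "core_ground_truth")
  list(core = core, truth = truth)
}

#' Ground-truth label codes used by the simulator
#'
#' @return named integer vector mapping class names to raster codes.
#' @export
ground_truth_codes <- function() .GT_CODES

#' Realized class fractions of a ground-truth label raster
#'
#' Stromal class pixel counts divided by the stromal pixel count, plus the
#' realized epithelial fraction of tissue. Exact by construction.
#'
#' @param labels integer label raster coded per [ground_truth_codes()].
#' @return named list of fractions (`fib`, `myo`, `smc`, `endo`, `imm`,
#'   `other`, `epi_frac`).
#' @export
realized_fractions <- function(labels) {
  g <- .GT_CODES
  n <- tabulate(labels + 1L, nbins = 8L)  # codes 0..7
  tissue_n <- sum(n[-1L])                  # everything but non_tissue
  stroma_n <- tissue_n - n[g[["epithelium"]] + 1L]
  f <- function(cls) if (stroma_n > 0) n[g[[cls]] + 1L] / stroma_n else NA_real_
  list(fib = f("fibroblast"), myo = f("myofibroblast"),
       smc = f("smooth_muscle"), endo = f("endothelium"),
       imm = f("immune"), other = f("other_stroma"),
       epi_frac = if (tissue_n > 0) n[g[["epithelium"]] + 1L] / tissue_n else NA_real_)
}

.realized_fractions <- function(labels) realized_fractions(labels)

# ---- cohort generator -------------------------------------------------------

#' Generate a synthetic TMA cohort with known survival structure
#'
#' Patient `i` receives a fibroblast fraction `p_i ~ Beta(alpha, beta)`; the
#' remaining stromal mass is split among myofibroblast / smooth muscle /
#' endothelium / immune / other by a Dirichlet draw with concentration
#' `dirichlet` (default `c(1.5, 5, 0.5, 0.5, 5)`, a smooth-muscle-rich
#' prostate-like stroma). Event times follow the proportional-hazards law of
#' [survival_sim_params()]; age is Normal(65, 8) truncated at 40, Gleason
#' group is sampled with probabilities `gleason_probs` over `<7 / 7 / >7`,
#' and a castration-resistance flag with probability `crpc_prob`.
#'
#' @param n_patients number of patients (>= 2).
#' @param cores_per_patient cores imaged per patient (>= 1).
#' @param surv a [survival_sim_params()].
#' @param image_params list of arguments for [generate_core()] (width,
#'   height, noise_sd, gain; a per-core gain is drawn log-normally with
#'   sdlog `gain_sdlog` when gain is not fixed).
#' @param seed master seed; per-patient and per-core streams are derived
#'   from it deterministically.
#' @param render_images if `FALSE`, no images are rendered and only the
#'   clinical and truth tables are returned (composition-level simulation
#'   for estimator calibration).
#' @param dirichlet,gleason_probs,crpc_prob,epi_beta,gain_sdlog cohort
#'   hyper-parameters; see Details.
#' @return list with `cores` (named list of `generate_core()` results, or
#'   `NULL`), `clinical` (data frame: patient_id, age, gleason_group, crpc,
#'   time, event), and `truth` (data frame of true per-patient fractions
#'   plus the simulation parameters as attribute `"params"`).
#' @export
generate_cohort <- function(n_patients, cores_per_patient = 1L,
                            surv = survival_sim_params(),
                            image_params = list(width = 256L, height = 256L,
                                                noise_sd = 5, gain = NULL),
                            seed = 1L, render_images = TRUE,
                            dirichlet = c(myo = 1.5, smc = 5, endo = 0.5,
                                          imm = 0.5, other = 5),
                            gleason_probs = c(lt7 = 0.47, eq7 = 0.25, gt7 = 0.28),
                            crpc_prob = 0.23,
                            epi_beta = c(8, 12),
                            gain_sdlog = 0.2) {
  if (n_patients < 2L) stop("n_patients must be >= 2")
  if (cores_per_patient < 1L) stop("cores_per_patient must be >= 1")
  stopifnot(inherits(surv, "survival_sim_params"))
  .with_seed(seed, {
    n <- as.integer(n_patients)
    p <- stats::rbeta(n, surv$fib_dist_alpha, surv$fib_dist_beta)
    w <- matrix(stats::rgamma(n * 5L, shape = rep(dirichlet, each = n)), n, 5L)
    w <- w / rowSums(w)
    rest <- (1 - p) * w
    colnames(rest) <- c("myo", "smc", "endo", "imm", "other")
    epi <- stats::rbeta(n, epi_beta[1L], epi_beta[2L])

    age <- stats::rnorm(n, 65, 8)
    while (any(age < 40)) age[age < 40] <- stats::rnorm(sum(age < 40), 65, 8)
    gleason <- sample(names(gleason_probs), n, replace = TRUE,
                      prob = gleason_probs)
    crpc <- stats::rbinom(n, 1L, crpc_prob)

    rate <- surv$baseline_hazard * exp(surv$log_hr_per_10pct * 10 * p)
    t_event <- stats::rexp(n, rate)
    time <- pmin(t_event, surv$censor_time)
    event <- as.integer(t_event <= surv$censor_time)

    pid <- sprintf("P%04d", seq_len(n))
    clinical <- data.frame(patient_id = pid, age = age,
                           gleason_group = gleason, crpc = crpc,
                           time = time, event = event,
                           stringsAsFactors = FALSE)
    truth <- data.frame(patient_id = pid, true_fib_frac = p,
                        true_myo_frac = rest[, "myo"],
                        true_smc_frac = rest[, "smc"],
                        true_endo_frac = rest[, "endo"],
                        true_imm_frac = rest[, "imm"],
                        true_other_frac = rest[, "other"],
                        epi_frac = epi, stringsAsFactors = FALSE)
    attr(truth, "params") <- c(unclass(surv),
                               list(seed = as.integer(seed),
                                    n_patients = n,
                                    cores_per_patient = as.integer(cores_per_patient)))

    cores <- NULL
    if (render_images) {
      n_cores <- n * as.integer(cores_per_patient)
      core_seeds <- sample.int(2147483646L, n_cores)
      gains <- if (is.null(image_params$gain))
        stats::rlnorm(n_cores, 0, gain_sdlog) else rep(image_params$gain, n_cores)
      cores <- vector("list", n_cores)
      nm <- character(n_cores)
      k <- 0L
      for (i in seq_len(n)) {
        comp <- stromal_composition(fib = p[i], myo = rest[i, "myo"],
                                    smc = rest[i, "smc"], endo = rest[i, "endo"],
                                    imm = rest[i, "imm"], other = rest[i, "other"],
                                    epi_frac = epi[i])
        for (j in seq_len(cores_per_patient)) {
          k <- k + 1L
          res <- generate_core(comp,
                               width = image_params$width %||% 256L,
                               height = image_params$height %||% 256L,
                               noise_sd = image_params$noise_sd %||% 5,
                               gain = gains[k], seed = core_seeds[k])
          res$core$core_id <- sprintf("%s_C%d", pid[i], j)
          res$core$patient_id <- pid[i]
          nm[k] <- res$core$core_id
          cores[[k]] <- res
        }
      }
      names(cores) <- nm
    }
    list(cores = cores, clinical = clinical, truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulated cohort to disk
#'
#' Cores go to `dir/cores` as multi-channel TIFFs with sidecars, ground
#' truth label rasters to `dir/labels`, and the clinical and truth tables
#' to `clinical.csv` / `truth.csv`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cohort$cores)) {
    for (res in cohort$cores) {
      write_core(res$core, file.path(dir, "cores"))
      write_label_raster(res$truth$label_raster,
                         file.path(dir, "labels",
                                   paste0(res$core$core_id, "_truth.tif")))
    }
  }
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  p <- attr(cohort$truth, "params")
  if (!is.null(p))
    jsonlite::write_json(p, file.path(dir, "sim_params.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
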