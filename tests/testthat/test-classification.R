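test_that("binarize_marker resolves fixed, quantile and otsu thresholds", {
  ch <- matrix(runif(400, 1, 2), 20, 20)
  region <- matrix(TRUE, 20, 20)
  expect_true(all(binarize_marker(ch, region, method = 0)))
  expect_false(any(binarize_marker(ch, region, method = list(quantile = 1))))
  # bimodal: background 10, foreground 100, equal mass -> exactly foreground
  ch2 <- matrix(10, 20, 20); ch2[, 11:20] <- 100
  pos <- binarize_marker(ch2, region, method = "otsu")
  expect_identical(pos & TRUE, ch2 == 100)
  # outside region always negative
  reg2 <- region; reg2[1:10, ] <- FALSE
  expect_false(any(binarize_marker(ch2, reg2, method = 0)[1:10, ]))
  expect_error(binarize_marker(ch, matrix(FALSE, 20, 20), method = "otsu"),
               "empty region")
})

test_that("otsu bimodality guard declares pure-noise channels negative", {
  set.seed(5)
  noise <- matrix(abs(rnorm(2500, 5, 1)), 50, 50)
  region <- matrix(TRUE, 50, 50)
  expect_false(any(binarize_marker(noise, region, method = "otsu")))
  # ...but keeps genuine foreground even when rare (2% positive mass)
  ch <- noise; ch[1:5, 1:10] <- 100 + rnorm(50)
  pos <- binarize_marker(ch, region, method = "otsu")
  expect_equal(sum(pos), 50)
})

test_that("pixel truth table follows the marker combinations with CAV2 precedence", {
  s <- stromal_class_codes()
  one <- function(vim, asma, cav2) {
    m <- matrix(TRUE, 1, 1)
    lab <- classify_stromal_pixels(matrix(vim, 1, 1), matrix(asma, 1, 1),
                                   matrix(cav2, 1, 1), m)
    unclass(lab)[1, 1]
  }
  expect_identical(one(TRUE, FALSE, FALSE), s[["fibroblast"]])
  expect_identical(one(TRUE, TRUE, FALSE), s[["myofibroblast"]])
  expect_identical(one(FALSE, TRUE, FALSE), s[["smooth_muscle"]])
  expect_identical(one(TRUE, FALSE, TRUE), s[["endothelium"]])
  expect_identical(one(FALSE, FALSE, FALSE), s[["other_stroma"]])
})

test_that("all-negative stroma is entirely residual and named classes are empty", {
  st <- matrix(c(TRUE, FALSE), 10, 10)
  f <- matrix(FALSE, 10, 10)
  lab <- classify_stromal_pixels(f, f, NULL, st)
  a <- class_areas(lab)
  expect_equal(unname(a[c("fibroblast", "myofibroblast", "smooth_muscle",
                          "endothelium")]), rep(0L, 4))
  expect_equal(unname(a[["other_stroma"]]), sum(st))
})

test_that("stromal classes are exhaustive and exclusive over the stroma", {
  set.seed(11)
  for (rep in 1:5) {
    st <- matrix(runif(900) < 0.6, 30, 30)
    vim <- matrix(runif(900) < 0.4, 30, 30)
    asma <- matrix(runif(900) < 0.4, 30, 30)
    cav2 <- matrix(runif(900) < 0.1, 30, 30)
    lab <- classify_stromal_pixels(vim, asma, cav2, st)
    expect_equal(sum(class_areas(lab)), sum(st))
    expect_true(all(unclass(lab)[!st] == 0L))
  }
  expect_error(classify_stromal_pixels(matrix(TRUE, 2, 2), matrix(TRUE, 2, 3),
                                       NULL, matrix(TRUE, 2, 2)), "shape")
})

test_that("nucleus segmentation finds isolated nuclei exactly and splits on demand", {
  # blank DAPI -> empty table
  expect_equal(nrow(segment_stromal_nuclei(flat_core(64, 0),
                                           matrix(TRUE, 64, 64))), 0L)
  # K well-separated nuclei -> exactly K stromal cells
  n <- 96
  dapi <- matrix(5, n, n)
  centers <- expand.grid(r = c(20, 48, 76), c = c(20, 48, 76))
  for (i in seq_len(nrow(centers))) {
    rr <- centers$r[i] + (-2:2); cc <- centers$c[i] + (-2:2)
    dapi[rr, cc][outer(-2:2, -2:2, function(a, b) a^2 + b^2) <= 4] <- 105
  }
  core <- multiplex_core(list(DAPI = dapi, PanEpi = matrix(5, n, n),
                              VIM = matrix(5, n, n), aSMA = matrix(5, n, n)),
                         core_id = "k9")
  ct <- segment_stromal_nuclei(core, matrix(TRUE, n, n))
  expect_equal(nrow(ct), 9L)
  expect_true(all(ct$compartment == "stroma"))
  # two overlapping nuclei: split -> 2 cells, no split -> 1 cell
  dapi2 <- matrix(5, 44, 44)
  for (ctr in list(c(16, 22), c(27, 22))) {
    ij <- which(outer((1:44) - ctr[1], (1:44) - ctr[2],
                      function(a, b) a^2 + b^2) <= 36, arr.ind = TRUE)
    dapi2[ij] <- 105
  }
  core2 <- multiplex_core(list(DAPI = dapi2, PanEpi = matrix(5, 44, 44),
                               VIM = matrix(5, 44, 44),
                               aSMA = matrix(5, 44, 44)), core_id = "pair")
  st <- matrix(TRUE, 44, 44)
  expect_equal(nrow(segment_stromal_nuclei(core2, st, split = TRUE)), 2L)
  expect_equal(nrow(segment_stromal_nuclei(core2, st, split = FALSE)), 1L)
})

test_that("cell classification applies the truth table to mean intensities", {
  ct <- data.frame(cell_id = 1:4, core_id = "x", row = 1, col = 1,
                   nucleus_area = 10,
                   mean_DAPI = 50, mean_PanEpi = 1,
                   mean_VIM = c(50, 50, 5, 5),
                   mean_aSMA = c(5, 50, 50, 5),
                   mean_CAV2 = c(5, 5, 5, 5),
                   compartment = "stroma", class = NA_character_,
                   stringsAsFactors = FALSE)
  class(ct) <- c("cell_table", "data.frame")
  out <- classify_cells(ct, c(VIM = 20, aSMA = 20, CAV2 = 20))
  expect_equal(out$class, c("fibroblast", "myofibroblast", "smooth_muscle",
                            "other_stroma"))
  # CAV2 precedence and epithelial cells left unclassified
  ct$mean_CAV2[1] <- 90
  ct$compartment[4] <- "epithelium"
  out2 <- classify_cells(ct, c(VIM = 20, aSMA = 20, CAV2 = 20))
  expect_equal(out2$class[1], "endothelium")
  expect_true(is.na(out2$class[4]))
  # thresholds above everything -> all residual
  out3 <- classify_cells(ct, c(VIM = 1e5, aSMA = 1e5))
  expect_true(all(out3$class[out3$compartment == "stroma"] == "other_stroma"))
  expect_error(classify_cells(ct, c(VIM = 20)), "aSMA")
})

test_that("pixel-mode and cell-mode fractions agree on a sparse noise-free core", {
  comp <- stromal_composition(fib = 0.15, myo = 0.10, smc = 0.10, endo = 0,
                              imm = 0, other = 0.65, epi_frac = 0.25)
  res <- generate_core(comp, 256, 256, noise_sd = 0, seed = 3)
  cl <- classify_generated(res)
  ct <- segment_stromal_nuclei(res$core, cl$masks$stroma)
  ct <- classify_cells(ct, attr(cl$classes, "thresholds"))
  st <- ct[ct$compartment == "stroma" & !is.na(ct$class), ]
  count_frac <- table(factor(st$class, levels = names(cl$fractions))) / nrow(st)
  expect_lt(max(abs(cl$fractions - as.numeric(count_frac))), 0.05)
})

test_that("CAV2 exclusion removes the vessel share from the fibroblast class", {
  comp <- stromal_composition(fib = 0.3, myo = 0.1, smc = 0.2, endo = 0.1,
                              imm = 0, other = 0.3, epi_frac = 0.3)
  res <- generate_core(comp, 256, 256, noise_sd = 2, seed = 14)
  with_cav2 <- classify_generated(res, pipeline_config())
  no_cav2 <- classify_generated(res, pipeline_config(cav2_exclusion = FALSE))
  drop <- no_cav2$fractions[["fibroblast"]] - with_cav2$fractions[["fibroblast"]]
  truth_vessel_share <- res$truth$realized_fractions$endo
  expect_gt(drop, 0)
  expect_lt(abs(drop - truth_vessel_share), 0.03)
})

test_that("per-pixel accuracy against marker-defined truth stays high under noise", {
  res <- generate_core(stromal_composition(), 256, 256, noise_sd = 5, seed = 15)
  cl <- classify_generated(res)
  ref <- marker_truth(res$truth$label_raster)
  gt_st <- res$truth$label_raster >= ground_truth_codes()[["fibroblast"]]
  expect_gte(mean(unclass(cl$classes)[gt_st] == ref[gt_st]), 0.9)
})
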