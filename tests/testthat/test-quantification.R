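make_test_core <- function(id, gain = 1, n = 64, seed = 1) {
  set.seed(seed)
  d2 <- outer((seq_len(n) - n / 2)^2, (seq_len(n) - n / 2)^2, `+`)
  disc <- d2 <= (0.45 * n)^2
  mk <- function(fg_frac) {
    ch <- matrix(5, n, n)
    ch[disc & matrix(runif(n * n) < fg_frac, n, n)] <- 105
    ch * gain
  }
  multiplex_core(list(DAPI = mk(0.3), PanEpi = mk(0.2), VIM = mk(0.25),
                      aSMA = mk(0.25)), core_id = id, patient_id = "P1")
}

test_that("normalization cancels per-core gain and is idempotent", {
  a <- make_test_core("a", gain = 1, seed = 2)
  b <- make_test_core("b", gain = 3, seed = 2)  # same content, 3x gain
  tis <- list(matrix(TRUE, 64, 64), matrix(TRUE, 64, 64))
  out <- normalize_intensities(list(a, b), tissues = tis)
  for (mk in names(a$channels))
    expect_equal(out[[1]]$channels[[mk]], out[[2]]$channels[[mk]],
                 tolerance = 1e-12)
  # single core: identity rescale
  one <- normalize_intensities(list(a), tissues = tis[1])
  expect_identical(one[[1]]$channels, a$channels)
  # idempotence
  again <- normalize_intensities(out, tissues = tis)
  for (mk in names(a$channels))
    expect_equal(again[[1]]$channels[[mk]], out[[1]]$channels[[mk]],
                 tolerance = 1e-12)
})

test_that("blank channels are flagged, warned about and left unscaled", {
  a <- make_test_core("a", seed = 3)
  b <- make_test_core("b", seed = 4)
  b$channels$VIM <- matrix(0, 64, 64)
  tis <- list(matrix(TRUE, 64, 64), matrix(TRUE, 64, 64))
  expect_warning(out <- normalize_intensities(list(a, b), tissues = tis),
                 "blank")
  expect_true("blank_channel:VIM" %in% attr(out[[2]], "flags"))
  expect_identical(out[[2]]$channels$VIM, b$channels$VIM)
})

test_that("core metrics follow from pixel arithmetic", {
  n <- 40
  tissue <- matrix(FALSE, n, n); tissue[1:25, 1:40] <- TRUE  # 1000 px
  epi <- matrix(FALSE, n, n); epi[1:15, 1:40] <- TRUE        # 600 px
  m <- compartment_masks(tissue, epi)
  s <- stromal_class_codes()
  lab <- matrix(s[["outside_stroma"]], n, n)
  st_idx <- which(m$stroma)
  lab[st_idx[1:100]] <- s[["fibroblast"]]
  lab[st_idx[101:200]] <- s[["myofibroblast"]]
  lab[st_idx[201:400]] <- s[["other_stroma"]]
  cls <- structure(lab, class = "stromal_class_raster")
  core <- flat_core(n, 1); core$patient_id <- "P1"
  met <- compute_core_metrics(core, m, cls)
  expect_equal(met$stroma_frac, 0.4)
  expect_equal(unname(met$class_area_frac[c("fibroblast", "myofibroblast",
                                            "other_stroma")]),
               c(0.25, 0.25, 0.5))
  expect_equal(sum(met$class_area_frac), 1)
  # all-fibroblast stroma
  lab2 <- matrix(s[["outside_stroma"]], n, n)
  lab2[m$stroma] <- s[["fibroblast"]]
  met2 <- compute_core_metrics(core, m,
                               structure(lab2, class = "stromal_class_raster"))
  expect_equal(unname(met2$class_area_frac[["fibroblast"]]), 1)
  expect_equal(unname(met2$class_area_frac[["smooth_muscle"]]), 0)
})

test_that("empty stroma yields flagged, missing fractions rather than an error", {
  n <- 20
  tissue <- matrix(TRUE, n, n)
  m <- compartment_masks(tissue, tissue)  # stroma empty
  cls <- structure(matrix(0L, n, n), class = "stromal_class_raster")
  met <- compute_core_metrics(flat_core(n, 1), m, cls)
  expect_true(all(is.na(met$class_area_frac)))
  expect_true("empty_stroma" %in% met$flags)
})

test_that("patient aggregation is the unweighted mean over unflagged cores", {
  mk_metric <- function(fib, flagged = FALSE) {
    n <- 40
    tissue <- matrix(FALSE, n, n); tissue[1:25, ] <- TRUE
    epi <- matrix(FALSE, n, n); epi[1:5, ] <- TRUE
    m <- compartment_masks(tissue, epi)
    s <- stromal_class_codes()
    lab <- matrix(s[["outside_stroma"]], n, n)
    st <- which(m$stroma)
    k <- round(fib * length(st))
    if (k > 0) lab[st[1:k]] <- s[["fibroblast"]]
    lab[st[(k + 1):length(st)]] <- s[["other_stroma"]]
    core <- flat_core(n, 1); core$patient_id <- "P1"
    core$core_id <- paste0("c", fib)
    if (flagged) attr(core, "flags") <- "low_quality_tissue"
    compute_core_metrics(core, m, structure(lab, class = "stromal_class_raster"))
  }
  clin <- data.frame(patient_id = "P1", age = 70, time = 10, event = 1)
  rec <- aggregate_patient(list(mk_metric(0.2), mk_metric(0.4)), clin)
  expect_equal(rec$fib_frac, 0.3, tolerance = 1e-9)
  expect_equal(rec$n_cores, 2L)
  # flagged core excluded from the mean
  rec2 <- aggregate_patient(list(mk_metric(0.2), mk_metric(0.4),
                                 mk_metric(0.9, flagged = TRUE)), clin)
  expect_equal(rec2$fib_frac, 0.3, tolerance = 1e-9)
  expect_equal(rec2$n_cores, 2L)
  # single core passes through; mean bounded by core range
  rec1 <- aggregate_patient(list(mk_metric(0.2)), clin)
  expect_equal(rec1$fib_frac, rec$fib_frac - 0.1, tolerance = 1e-9)
  expect_true(rec2$fib_frac >= 0.2 - 1e-9 && rec2$fib_frac <= 0.4 + 1e-9)
  # all cores flagged -> patient excluded with a message
  expect_message(out <- aggregate_patient(list(mk_metric(0.2, TRUE)), clin),
                 "excluded")
  expect_null(out)
})

test_that("immune score maps the stated percentage bands", {
  expect_equal(as.character(immune_score(c(0.004, 0.03, 0.08))),
               c("low", "medium", "high"))
  # boundary values land in the closed middle band
  expect_equal(as.character(immune_score(c(0.01, 0.05))),
               c("medium", "medium"))
  expect_equal(as.character(immune_score(0.0099)), "low")
  expect_equal(as.character(immune_score(0.0501)), "high")
  expect_error(immune_score(1.2), "\\[0, 1\\]")
  expect_error(immune_score(-0.1), "\\[0, 1\\]")
})

test_that("metrics are invariant to a single core's gain after normalization", {
  cores <- lapply(1:3, function(i) make_test_core(paste0("c", i), seed = i))
  tis <- replicate(3, matrix(TRUE, 64, 64), simplify = FALSE)
  base <- normalize_intensities(cores, tissues = tis)
  cores2 <- cores
  for (mk in names(cores2[[2]]$channels))
    cores2[[2]]$channels[[mk]] <- cores2[[2]]$channels[[mk]] * 2
  scaled <- normalize_intensities(cores2, tissues = tis)
  for (i in 1:3) for (mk in names(base[[i]]$channels)) {
    rel <- abs(scaled[[i]]$channels[[mk]] - base[[i]]$channels[[mk]]) /
      pmax(base[[i]]$channels[[mk]], 1e-12)
    expect_lt(max(rel), 1e-6)
  }
})
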