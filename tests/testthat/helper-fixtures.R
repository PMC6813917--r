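# Shared fixtures, all built in code.

jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# A minimal core with constant channels (useful for mask edge cases).
flat_core <- function(n = 64, value = 0) {
  ch <- matrix(value, n, n)
  multiplex_core(list(DAPI = ch, PanEpi = ch, VIM = ch, aSMA = ch),
                 core_id = "flat")
}

# Disc-shaped core whose tissue is uniformly marker-positive.
disc_core <- function(n = 96, fg = 100, markers = c("DAPI", "PanEpi")) {
  d2 <- outer((seq_len(n) - n / 2)^2, (seq_len(n) - n / 2)^2, `+`)
  disc <- d2 <= (0.4 * n)^2
  mk <- function(on) matrix(ifelse(disc & on, fg, 0), n, n)
  chans <- list(DAPI = mk("DAPI" %in% markers),
                PanEpi = mk("PanEpi" %in% markers),
                VIM = mk("VIM" %in% markers),
                aSMA = mk("aSMA" %in% markers))
  list(core = multiplex_core(chans, core_id = "disc"), tissue = disc)
}

# Marker-defined reference labels: simulated immune cells are VIM+/aSMA-,
# so the truth-table class they belong to is fibroblast.
marker_truth <- function(label_raster) {
  g <- ground_truth_codes()
  s <- stromal_class_codes()
  map <- integer(8)
  map[g[["fibroblast"]] + 1L] <- s[["fibroblast"]]
  map[g[["myofibroblast"]] + 1L] <- s[["myofibroblast"]]
  map[g[["smooth_muscle"]] + 1L] <- s[["smooth_muscle"]]
  map[g[["endothelium"]] + 1L] <- s[["endothelium"]]
  map[g[["immune"]] + 1L] <- s[["fibroblast"]]
  map[g[["other_stroma"]] + 1L] <- s[["other_stroma"]]
  matrix(map[label_raster + 1L], nrow(label_raster), ncol(label_raster))
}

# Marker-defined ground-truth stromal fractions (immune folded into
# fibroblast) from a generated core's truth.
marker_truth_fractions <- function(truth) {
  rf <- truth$realized_fractions
  c(fibroblast = rf$fib + rf$imm, myofibroblast = rf$myo,
    smooth_muscle = rf$smc, endothelium = rf$endo, other_stroma = rf$other)
}

# Segment + pixel-classify one generated core with defaults.
classify_generated <- function(res, config = pipeline_config()) {
  tis <- tissue_mask(res$core)
  masks <- compartment_masks(tis, epithelium_mask(res$core, tissue = tis))
  cls <- stromaplex:::classify_core_pixels(res$core, masks, config)
  list(masks = masks, classes = cls,
       fractions = class_areas(cls) / max(1L, sum(class_areas(cls))))
}

# Simulated exponential survival data with a binary covariate (no PH
# violation), for Cox null checks.
sim_null_cox <- function(n, seed) {
  set.seed(seed)
  x <- stats::rbinom(n, 1, 0.5)
  t <- stats::rexp(n, 0.1)
  cens <- stats::rexp(n, 0.05)
  data.frame(time = pmin(t, cens), event = as.integer(t <= cens),
             fib_frac = x / 10)
}
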