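#' Kaplan-Meier curves with a log-rank test across groups
#'
#' Product-limit estimator per group; with two or more groups the log-rank
#' chi-square statistic (groups - 1 degrees of freedom) and its p-value
#' are attached. With a single group the curve alone is returned and a
#' notice emitted.
#'
#' @param time positive follow-up times.
#' @param event event indicators (0 censored / 1 event); at least one event.
#' @param group optional per-subject category; default one group.
#' @return object of class `km_curve`: `curves` (data frame with group,
#'   time, n_risk, n_event, surv), `logrank` (list chisq/df/p or `NULL`),
#'   and the underlying `survfit` object.
#' @export
km_logrank <- function(time, event, group = NULL) {
  if (any(time <= 0)) stop("all times must be positive")
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) stop("event must be 0/1")
  if (sum(event) < 1L) stop("need at least one event")
  if (is.null(group)) group <- rep("all", length(time))
  group <- as.factor(group)
  df <- data.frame(time = time, event = event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata <- if (is.null(fit$strata)) {
    rep(levels(group)[1L], length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  curves <- data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, surv = fit$surv,
                       stringsAsFactors = FALSE)
  logrank <- NULL
  if (nlevels(group) >= 2L) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
    dfree <- length(sd$n) - 1L
    logrank <- list(chisq = sd$chisq, df = dfree,
                    p = stats::pchisq(sd$chisq, dfree, lower.tail = FALSE))
  } else {
    message("single group: log-rank test omitted")
  }
  structure(list(curves = curves, logrank = logrank, fit = fit),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve>", length(unique(x$curves$group)), "group(s)\n")
  if (!is.null(x$logrank))
    cat(sprintf("log-rank chisq = %.3f on %d df, p = %.4g\n",
                x$logrank$chisq, x$logrank$df, x$logrank$p))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  plot(x$fit, ...)
  invisible(x)
}

#' Cox proportional-hazards regression on stromal class proportions
#'
#' Partial-likelihood maximization (Efron tie handling by default) of
#' cancer-specific survival on stromal class fractions and clinical
#' adjusters. Class-fraction covariates are entered as `fraction * 10`, so
#' one covariate unit equals a 10-percentage-point change of the stromal
#' proportion and the reported hazard ratio reads "per 10% change".
#' Gleason group is encoded as indicators against the reference level
#' `">7"` (`gt7`), whose hazard ratio is 1 by construction. Only
#' complete cases enter the fit; constant covariates are dropped with a
#' warning, and monotone-likelihood separation is rejected with a
#' diagnostic naming the covariate.
#'
#' @param records data frame of patient records with columns `time`,
#'   `event`, the class-fraction covariates and any adjusters.
#' @param class_covariates names of fraction-valued columns (each in
#'   `[0, 1]`) to enter on the x10 scale.
#' @param adjust names of adjustment columns (e.g. `"gleason_group"`,
#'   `"age"`).
#' @param ties `"efron"` or `"breslow"`.
#' @param gleason_ref reference level for `gleason_group`.
#' @return object of class `stromal_cox`: coefficient `table` (term, coef,
#'   se, hazard_ratio, ci95_low, ci95_high, wald_p), `n`, `n_events`,
#'   `n_excluded`, `ties`, and the underlying `coxph` fit.
#' @export
cox_fit <- function(records, class_covariates = "fib_frac",
                    adjust = character(), ties = c("efron", "breslow"),
                    gleason_ref = "gt7") {
  ties <- match.arg(ties)
  need <- c("time", "event", class_covariates, adjust)
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack column(s): ", paste(miss, collapse = ", "))

  df <- records[, need, drop = FALSE]
  cc <- stats::complete.cases(df)
  n_excluded <- sum(!cc)
  df <- df[cc, , drop = FALSE]
  if (nrow(df) == 0L) stop("no complete cases")
  if (sum(df$event) < 1L) stop("no events among complete cases")

  terms <- character()
  for (cv in class_covariates) {
    v <- df[[cv]]
    if (any(v < -1e-9 | v > 1 + 1e-9))
      stop("class covariate ", cv, " is not a fraction in [0, 1]")
    nm <- paste0(cv, "_x10")
    df[[nm]] <- 10 * v
    terms <- c(terms, nm)
  }
  for (ad in adjust) {
    if (ad == "gleason_group") {
      df[[ad]] <- stats::relevel(factor(df[[ad]]), ref = gleason_ref)
    }
    terms <- c(terms, ad)
  }
  # drop constant covariates up front
  const <- vapply(terms, function(tm) {
    v <- df[[tm]]
    if (is.factor(v) || is.character(v)) length(unique(v)) < 2L else
      stats::sd(v) == 0
  }, logical(1))
  if (any(const)) {
    warning("constant covariate(s) dropped: ",
            paste(terms[const], collapse = ", "))
    terms <- terms[!const]
  }
  if (!length(terms)) stop("no usable covariates")

  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(terms, collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = ties)
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  bad <- !is.finite(co) | abs(co) > 15 | se > 50
  if (any(bad))
    stop("monotone likelihood (separation) in covariate(s): ",
         paste(names(co)[bad], collapse = ", "))
  tab <- data.frame(term = names(co), coef = unname(co), se = unname(se),
                    hazard_ratio = exp(unname(co)),
                    ci95_low = exp(unname(co) - stats::qnorm(0.975) * unname(se)),
                    ci95_high = exp(unname(co) + stats::qnorm(0.975) * unname(se)),
                    wald_p = 2 * stats::pnorm(-abs(unname(co) / unname(se))),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, n = fit$n, n_events = fit$nevent,
                 n_excluded = n_excluded, ties = ties, fit = fit,
                 data = df, terms = terms),
            class = "stromal_cox")
}

#' @export
print.stromal_cox <- function(x, digits = 3, ...) {
  cat(sprintf("<stromal_cox> n = %d, events = %d (%d excluded, %s ties)\n",
              x$n, x$n_events, x$n_excluded, x$ties))
  tab <- x$table
  tab$hr_ci <- sprintf("%.*f (%.*f-%.*f)", digits, tab$hazard_ratio,
                       digits, tab$ci95_low, digits, tab$ci95_high)
  print(data.frame(term = tab$term, `HR (95% CI)` = tab$hr_ci,
                   p = signif(tab$wald_p, 3), check.names = FALSE),
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.stromal_cox <- function(object, ...) summary(object$fit, ...)

#' @export
coef.stromal_cox <- function(object, ...) stats::coef(object$fit)

#' Schoenfeld test of the proportional-hazards assumption
#'
#' Correlation of the scaled Schoenfeld residuals with (transformed) event
#' time, chi-square p-value per covariate. Degenerate residuals yield a
#' missing p with a notice instead of an error.
#'
#' @param fit a [cox_fit()] result.
#' @param transform time transform (`"km"`, `"identity"`, `"rank"`).
#' @return data frame: term, chisq, df, p.
#' @export
schoenfeld_test <- function(fit, transform = "km") {
  stopifnot(inherits(fit, "stromal_cox"))
  if (fit$n_events < 2L)
    stop("insufficient events for the Schoenfeld test (need >= 2)")
  zph <- tryCatch(survival::cox.zph(fit$fit, transform = transform,
                                    global = FALSE),
                  error = function(e) NULL)
  if (is.null(zph)) {
    message("degenerate Schoenfeld residuals: p reported missing")
    return(data.frame(term = fit$terms, chisq = NA_real_, df = NA_real_,
                      p = NA_real_, stringsAsFactors = FALSE))
  }
  tab <- as.data.frame(zph$table)
  data.frame(term = rownames(tab), chisq = tab$chisq, df = tab$df, p = tab$p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up control
#'
#' Sorts the p-values ascending, finds the largest rank `i` with
#' `p(i) <= i * q / m`, and rejects all hypotheses of rank at most `i`.
#' Also returns the monotone BH-adjusted p-values.
#'
#' @param pvalues p-values in `[0, 1]`.
#' @param q target false discovery rate in `(0, 1)` (the analysis default
#'   is 0.2, i.e. 20% FDR).
#' @return list with `reject` (logical, original order), `adjusted`,
#'   `q`, and `n_rejected`.
#' @export
bh_adjust <- function(pvalues, q = 0.2) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  m <- length(pvalues)
  ord <- order(pvalues)
  ps <- pvalues[ord]
  below <- which(ps <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(below)) reject[ord[seq_len(max(below))]] <- TRUE
  list(reject = reject,
       adjusted = stats::p.adjust(pvalues, method = "BH"),
       q = q, n_rejected = sum(reject))
}

#' Group-comparison tests
#'
#' Thin dispatch over the standard tests used for cohort comparisons:
#' Mann-Whitney U (two groups), Kruskal-Wallis with pairwise Dunn post-hoc
#' (run only when the omnibus p < `alpha_omnibus`), chi-square on a
#' contingency table (no continuity correction), Shapiro-Wilk normality,
#' and Pearson correlation (`y` required).
#'
#' Dunn's z statistics use the rank-sum formulation with tie correction;
#' pairwise p-values are two-sided with Holm adjustment.
#'
#' @param values numeric (or categorical for `chi_square`) per-subject
#'   values.
#' @param groups per-subject categories (unused for `shapiro_wilk` and
#'   `pearson`).
#' @param test one of `"mann_whitney"`, `"kruskal_wallis_dunn"`,
#'   `"chi_square"`, `"shapiro_wilk"`, `"pearson"`.
#' @param y second numeric vector for `pearson`.
#' @param alpha_omnibus omnibus threshold gating the Dunn post-hoc.
#' @return list: `method`, `statistic`, `p`, and for the Kruskal-Wallis
#'   route a `pairwise` data frame (or `NULL` when not run).
#' @export
compare_groups <- function(values, groups = NULL,
                           test = c("mann_whitney", "kruskal_wallis_dunn",
                                    "chi_square", "shapiro_wilk", "pearson"),
                           y = NULL, alpha_omnibus = 0.05) {
  test <- match.arg(test)
  switch(test,
    mann_whitney = {
      g <- as.factor(groups)
      if (nlevels(g) != 2L) stop("Mann-Whitney requires exactly 2 groups")
      ht <- stats::wilcox.test(values ~ g, exact = FALSE)
      list(method = "mann_whitney", statistic = unname(ht$statistic),
           p = ht$p.value)
    },
    kruskal_wallis_dunn = {
      g <- as.factor(groups)
      if (nlevels(g) < 2L) stop("Kruskal-Wallis requires >= 2 groups")
      ht <- stats::kruskal.test(values, g)
      pw <- if (ht$p.value < alpha_omnibus && nlevels(g) > 2L)
        .dunn_posthoc(values, g) else NULL
      list(method = "kruskal_wallis_dunn",
           statistic = unname(ht$statistic), p = ht$p.value, pairwise = pw)
    },
    chi_square = {
      tab <- table(values, groups)
      if (any(dim(tab) < 2L)) stop("chi-square needs a 2-way table")
      ht <- stats::chisq.test(tab, correct = FALSE)
      list(method = "chi_square", statistic = unname(ht$statistic),
           p = ht$p.value)
    },
    shapiro_wilk = {
      ht <- stats::shapiro.test(values)
      list(method = "shapiro_wilk", statistic = unname(ht$statistic),
           p = ht$p.value)
    },
    pearson = {
      if (is.null(y)) stop("pearson requires `y`")
      ht <- stats::cor.test(values, y, method = "pearson")
      list(method = "pearson", statistic = unname(ht$estimate),
           p = ht$p.value)
    })
}

# Dunn's pairwise post-hoc z tests on the joint ranks, with tie correction.
.dunn_posthoc <- function(values, g) {
  r <- rank(values)
  n <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  v0 <- n * (n + 1) / 12 - tie_term
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2L)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    se <- sqrt(v0 * (1 / ns[[a]] + 1 / ns[[b]]))
    z[j] <- (rbar[[a]] - rbar[[b]]) / se
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], z = z, p = p,
             p_adj = stats::p.adjust(p, method = "holm"),
             stringsAsFactors = FALSE)
}
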