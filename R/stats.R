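#' Ordinary least squares fit
#'
#' Shared regression core for partial correlation and mediation. The design
#' matrix must include its intercept column explicitly.
#'
#' @param y Response vector.
#' @param design n x p predictor matrix (with intercept), full column rank.
#' @return List with `coefficients` (named) and `residuals`.
#' @export
fit_ols <- function(y, design) {
  design <- as.matrix(design)
  if (nrow(design) < ncol(design) + 1) {
    stop("need more observations than predictors", call. = FALSE)
  }
  fit <- stats::lm.fit(design, y)
  if (fit$rank < ncol(design)) {
    nm <- colnames(design)
    if (is.null(nm)) nm <- paste0("V", seq_len(ncol(design)))
    dropped <- nm[fit$qr$pivot[(fit$rank + 1):ncol(design)]]
    stop(sprintf("rank-deficient design: collinear column(s) %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  list(coefficients = fit$coefficients, residuals = fit$residuals)
}

#' Covariate-adjusted partial correlation
#'
#' Pearson correlation between the residuals of `x` and `y` after each is
#' regressed on an intercept plus the covariates; the significance test
#' uses t = pr sqrt((n-2-k)/(1-pr^2)) on n-2-k degrees of freedom,
#' two-sided.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional matrix/data.frame of nuisance covariates.
#' @return List with `pr`, `p`, `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length", call. = FALSE)
  if (is.null(covariates) || NCOL(covariates) == 0 ||
      (is.matrix(covariates) && ncol(covariates) == 0)) {
    k <- 0L
    rx <- x - mean(x)
    ry <- y - mean(y)
  } else {
    z <- as.matrix(covariates)
    k <- ncol(z)
    if (n <= k + 3) stop("too few observations for the covariate count",
                         call. = FALSE)
    design <- cbind(`(Intercept)` = 1, z)
    rx <- fit_ols(x, design)$residuals
    ry <- fit_ols(y, design)$residuals
  }
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("zero residual variance", call. = FALSE)
  }
  pr <- stats::cor(rx, ry)
  df <- n - 2L - k
  tval <- pr * sqrt(df / max(1 - pr^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  list(pr = pr, p = p, df = df)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values and rejection flags at level `q`.
#'
#' @param pvalues Vector of raw p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return List with `p_adjusted` and `rejected`.
#' @export
fdr_bh <- function(pvalues, q = 0.05) {
  if (any(pvalues < 0 | pvalues > 1 | is.na(pvalues))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  adj <- stats::p.adjust(pvalues, method = "BH")
  list(p_adjusted = adj, rejected = adj <= q)
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition with F on (g-1, n-g) degrees of
#' freedom.
#'
#' @param values Numeric response.
#' @param groups Group labels (>= 2 groups, each with >= 2 observations).
#' @return List with `F`, `p`, `df`, `group_means`.
#' @export
oneway_anova <- function(values, groups) {
  g <- factor(groups)
  tabs <- table(g)
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(tabs < 2)) {
    stop(sprintf("degenerate group %s (fewer than 2 observations)",
                 names(tabs)[tabs < 2][1]), call. = FALSE)
  }
  a <- stats::anova(stats::lm(values ~ g))
  list(F = a[["F value"]][1], p = a[["Pr(>F)"]][1],
       df = c(a$Df[1], a$Df[2]),
       group_means = tapply(values, g, mean))
}

#' Bonferroni post hoc pairwise comparisons
#'
#' All pairwise pooled-variance two-sample t-tests; each p-value is
#' multiplied by the number of pairs and capped at 1.
#'
#' @inheritParams oneway_anova
#' @return `data.frame` with columns `group1`, `group2`, `t`, `p_raw`,
#'   `p_adjusted`.
#' @export
bonferroni_posthoc <- function(values, groups) {
  g <- factor(groups)
  tabs <- table(g)
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(tabs < 2)) {
    stop(sprintf("degenerate group %s (fewer than 2 observations)",
                 names(tabs)[tabs < 2][1]), call. = FALSE)
  }
  prs <- utils::combn(levels(g), 2)
  m <- ncol(prs)
  out <- lapply(seq_len(m), function(i) {
    v1 <- values[g == prs[1, i]]
    v2 <- values[g == prs[2, i]]
    tt <- stats::t.test(v1, v2, var.equal = TRUE)
    data.frame(group1 = prs[1, i], group2 = prs[2, i],
               t = unname(tt$statistic), p_raw = tt$p.value,
               p_adjusted = min(1, tt$p.value * m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# pivoting OLS used by the mediation models: aliased columns get NA,
# mirroring lm(). A perfectly collinear direct path (e.g. a noise-free
# mediator) then resolves to c' = 0 rather than an error.
med_coef <- function(y, design) {
  stats::lm.fit(design, y)$coefficients
}

#' Bootstrap mediation analysis
#'
#' Decomposes the total effect of an exposure `x` on an outcome `y` into an
#' indirect path through the mediator `m` (a x b) and a direct path (c'),
#' with c = a x b + c' as unstandardized OLS coefficients: a from
#' m ~ x + covariates, b and c' from y ~ m + x + covariates, c from
#' y ~ x + covariates. The indirect effect's confidence interval is a
#' percentile bootstrap over subject resampling; it is significant when the
#' interval excludes 0. A categorical exposure is indicator-coded against
#' its first level, yielding one relative effect per remaining level.
#'
#' @param x Exposure (numeric, or factor for categorical).
#' @param m Mediator (numeric).
#' @param y Outcome (numeric).
#' @param covariates Optional matrix/data.frame of nuisance covariates.
#' @param n_boot Bootstrap realizations (default 10000).
#' @param rng_seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return Object of class `mediation_result` (or a list of them, one per
#'   non-reference exposure level): `a`, `b`, `c`, `c_prime`, `indirect`,
#'   `boot_ci`, `n_boot`, `significant`, `level`.
#' @export
mediate <- function(x, m, y, covariates = NULL, n_boot = 10000,
                    rng_seed = NULL, conf = 0.95) {
  n <- length(y)
  stopifnot(length(m) == n)
  z <- if (is.null(covariates)) NULL else as.matrix(covariates)
  if (is.factor(x) || is.character(x)) {
    xf <- factor(x)
    xmat <- stats::model.matrix(~xf)[, -1, drop = FALSE]
    colnames(xmat) <- levels(xf)[-1]
  } else {
    xmat <- matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, "x"))
  }
  if (n <= NCOL(z) + 4) stop("too few complete cases", call. = FALSE)
  if (anyNA(x) || anyNA(m) || anyNA(y) || (!is.null(z) && anyNA(z))) {
    stop("complete cases required", call. = FALSE)
  }
  des_a <- cbind(`(Intercept)` = 1, xmat, z)
  des_b <- cbind(`(Intercept)` = 1, m = m, xmat, z)
  lev <- colnames(xmat)
  nl <- length(lev)
  fa <- med_coef(m, des_a)
  fb <- med_coef(y, des_b)
  fc <- med_coef(y, des_a)
  a_hat <- fa[lev]
  b_hat <- fb[["m"]]
  cp_hat <- fb[lev]
  c_hat <- fc[lev]
  if (anyNA(a_hat) || is.na(b_hat)) {
    stop("rank-deficient design: exposure or mediator is collinear with the covariates",
         call. = FALSE)
  }
  cp_hat[is.na(cp_hat)] <- 0 # direct path aliased by a noise-free mediator
  if (!is.null(rng_seed)) set.seed(rng_seed)
  boot_ind <- matrix(NA_real_, n_boot, nl)
  for (bidx in seq_len(n_boot)) {
    ok <- FALSE
    for (try in 1:10) {
      idx <- sample.int(n, n, replace = TRUE)
      ca <- med_coef(m[idx], des_a[idx, , drop = FALSE])
      cb <- med_coef(y[idx], des_b[idx, , drop = FALSE])
      if (!anyNA(ca[lev]) && !is.na(cb[["m"]])) {
        boot_ind[bidx, ] <- ca[lev] * cb[["m"]]
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("bootstrap draw rank-deficient after 10 retries",
                  call. = FALSE)
  }
  alpha <- (1 - conf) / 2
  res <- lapply(seq_len(nl), function(l) {
    ci <- unname(stats::quantile(boot_ind[, l], c(alpha, 1 - alpha),
                                 type = 6))
    structure(list(a = unname(a_hat[l]), b = b_hat,
                   c = unname(c_hat[l]), c_prime = unname(cp_hat[l]),
                   indirect = unname(a_hat[l]) * b_hat,
                   boot_ci = ci, n_boot = n_boot,
                   significant = ci[1] > 0 || ci[2] < 0,
                   level = lev[l]),
              class = "mediation_result")
  })
  if (nl == 1) res[[1]] else stats::setNames(res, lev)
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "<mediation_result%s> a=%.4f b=%.4f c'=%.4f c=%.4f indirect=%.4f\n",
    if (x$level %in% c("x", "")) "" else paste0(" [", x$level, "]"),
    x$a, x$b, x$c_prime, x$c, x$indirect))
  cat(sprintf("  bootstrap CI [%.4f, %.4f] (%d draws)%s\n",
              x$boot_ci[1], x$boot_ci[2], x$n_boot,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Stage-1 association screen
#'
#' For a diversity exposure, runs a covariate-adjusted partial correlation
#' per network metric and corrects the family by Benjamini-Hochberg FDR;
#' for the enterotype exposure, runs a one-way ANOVA per metric (with
#' Bonferroni post hoc comparisons attached). Metrics flagged as derived
#' from functional connectivity automatically gain frame-wise displacement
#' as an extra covariate.
#'
#' @param cohort `data.frame` with one row per subject.
#' @param metric_columns Names of the metric columns to screen.
#' @param exposure `"shannon"`, `"simpson"` or `"enterotype"`.
#' @param covariates Covariate column names (default age, sex, BMI).
#' @param fc_metrics Subset of `metric_columns` that are FC-derived.
#' @param fd_column Column holding frame-wise displacement (default "fd").
#' @param q FDR level / ANOVA alpha (default 0.05).
#' @param family Label for the FDR family (default derived from the call).
#' @return `data.frame`: `exposure`, `metric`, `family`, `estimate`, `p`,
#'   `p_adjusted`, `significant`. For the enterotype exposure the post hoc
#'   tables are attached as attribute `"posthoc"`.
#' @export
association_screen <- function(cohort, metric_columns,
                               exposure = c("shannon", "simpson",
                                            "enterotype"),
                               covariates = c("age", "sex", "bmi"),
                               fc_metrics = character(),
                               fd_column = "fd", q = 0.05,
                               family = NULL) {
  exposure <- match.arg(exposure)
  missing_cols <- setdiff(c(metric_columns, covariates,
                            if (exposure != "enterotype") exposure
                            else "enterotype"),
                          names(cohort))
  if (length(missing_cols) > 0) {
    stop(sprintf("unknown column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (is.null(family)) {
    family <- sprintf("%s_x_%d_metrics", exposure, length(metric_columns))
  }
  if (exposure == "enterotype") {
    rows <- lapply(metric_columns, function(mc) {
      an <- oneway_anova(cohort[[mc]], cohort$enterotype)
      data.frame(exposure = exposure, metric = mc, family = family,
                 estimate = an$F, p = an$p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$p_adjusted <- out$p
    out$significant <- out$p < q
    ph <- lapply(metric_columns[out$significant], function(mc)
      bonferroni_posthoc(cohort[[mc]], cohort$enterotype))
    names(ph) <- metric_columns[out$significant]
    attr(out, "posthoc") <- ph
    return(out)
  }
  rows <- lapply(metric_columns, function(mc) {
    covs <- covariates
    if (mc %in% fc_metrics) covs <- union(covs, fd_column)
    pc <- partial_correlation(cohort[[exposure]], cohort[[mc]],
                              cohort[, covs, drop = FALSE])
    data.frame(exposure = exposure, metric = mc, family = family,
               estimate = pc$pr, p = pc$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  adj <- fdr_bh(out$p, q)
  out$p_adjusted <- adj$p_adjusted
  out$significant <- adj$rejected
  out
}
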