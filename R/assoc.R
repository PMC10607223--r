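#' Normality gate
#'
#' Shapiro-Wilk at `alpha` on the raw values; if rejected, the natural-log
#' transform is tested; if that is rejected too (or the values are not
#' strictly positive, or are constant), the nonparametric route is taken.
#' This is the routing step ahead of every univariate comparison: it decides
#' whether group means are compared by t/ANOVA (raw or log scale) or by
#' rank tests.
#'
#' @param values numeric vector, `n >= 3`.
#' @param alpha gate level (default 0.05).
#' @return list `route` (`"normal-raw"`, `"normal-log"` or
#'   `"nonparametric"`), `p_raw`, `p_log`, `transform` (`"none"` or `"log"`).
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3) stop("need at least 3 values")
  p_raw <- tryCatch(stats::shapiro.test(values)$p.value, error = function(e) NA_real_)
  if (!is.na(p_raw) && p_raw >= alpha) {
    return(list(route = "normal-raw", p_raw = p_raw, p_log = NA_real_,
                transform = "none"))
  }
  if (any(values <= 0)) {
    return(list(route = "nonparametric", p_raw = p_raw, p_log = NA_real_,
                transform = "none"))
  }
  p_log <- tryCatch(stats::shapiro.test(log(values))$p.value,
                    error = function(e) NA_real_)
  if (!is.na(p_log) && p_log >= alpha) {
    return(list(route = "normal-log", p_raw = p_raw, p_log = p_log,
                transform = "log"))
  }
  list(route = "nonparametric", p_raw = p_raw, p_log = p_log, transform = "none")
}

#' Univariate group comparison
#'
#' Two groups: pooled-variance t-test on the gated scale (Welch by option)
#' or Mann-Whitney on the nonparametric route. Three or more groups: one-way
#' ANOVA with Bonferroni-adjusted pairwise post hoc, or Kruskal-Wallis with
#' Bonferroni-adjusted pairwise Mann-Whitney. Descriptives are always
#' reported on the original scale as mean (SD) per level. A parametric
#' route with any group below 2 observations falls back to the
#' nonparametric test with a warning.
#'
#' @param y outcome values.
#' @param group group labels (2 or more non-empty levels).
#' @param gate optional [normality_gate()] result for `y` (computed if
#'   `NULL`).
#' @param var_equal pooled-variance t-test (default `TRUE`, matching the
#'   OLS equivalence of the multivariate step); `FALSE` gives Welch.
#' @return object of class `uv_result`: `test`, `p_uv`, `route`,
#'   `descriptives` (level, n, mean, sd), `pairwise` (Bonferroni-adjusted
#'   matrix, `NULL` for 2 groups).
#' @export
univariate_test <- function(y, group, gate = NULL, var_equal = TRUE) {
  ok <- !is.na(y) & !is.na(group)
  y <- y[ok]; group <- droplevels(factor(group[ok]))
  k <- nlevels(group)
  if (k < 2) stop("need at least 2 non-empty groups")
  if (is.null(gate)) gate <- normality_gate(y)
  route <- gate$route
  n_per <- table(group)
  if (route != "nonparametric" && any(n_per < 2)) {
    warning("group with fewer than 2 observations; falling back to the nonparametric test")
    route <- "nonparametric"
  }
  yt <- if (route == "normal-log") log(y) else y

  desc <- do.call(rbind, lapply(levels(group), function(l) {
    v <- y[group == l]
    data.frame(level = l, n = length(v), mean = mean(v), sd = stats::sd(v))
  }))

  pairwise <- NULL
  if (route == "nonparametric") {
    if (k == 2) {
      sp <- split(y, group)
      p <- suppressWarnings(stats::wilcox.test(sp[[1]], sp[[2]], exact = FALSE)$p.value)
      if (is.nan(p)) p <- 1  # fully tied data carry no evidence
      test <- "Mann-Whitney"
    } else {
      p <- stats::kruskal.test(y, group)$p.value
      test <- "Kruskal-Wallis"
      pairwise <- suppressWarnings(
        stats::pairwise.wilcox.test(y, group, p.adjust.method = "bonferroni",
                                    exact = FALSE)$p.value)
    }
  } else {
    if (k == 2) {
      p <- stats::t.test(yt ~ group, var.equal = var_equal)$p.value
      test <- if (var_equal) "t-test" else "Welch t-test"
    } else {
      p <- summary(stats::aov(yt ~ group))[[1]][["Pr(>F)"]][1]
      test <- "ANOVA"
      pairwise <- stats::pairwise.t.test(yt, group, p.adjust.method = "bonferroni",
                                         pool.sd = TRUE)$p.value
    }
  }
  structure(list(test = test, p_uv = unname(p), route = route,
                 transform = if (route == "normal-log") "log" else "none",
                 descriptives = desc, pairwise = pairwise,
                 n = length(y), k = k),
            class = "uv_result")
}

#' @export
print.uv_result <- function(x, ...) {
  cat(sprintf("%s (%s route): p_uv = %.4g over %d groups, n = %d\n",
              x$test, x$route, x$p_uv, x$k, x$n))
  d <- x$descriptives
  for (i in seq_len(nrow(d))) {
    cat(sprintf("  %-12s n=%-3d %s (%s)\n", d$level[i], d$n[i],
                format(d$mean[i], digits = 6), format(d$sd[i], digits = 4)))
  }
  invisible(x)
}

#' Multivariate linear regression of screened predictors
#'
#' Ordinary least squares of the (possibly log-transformed) outcome on the
#' predictors that passed the univariate screen. Aliased (collinear)
#' predictors are dropped with a warning and the model refitted. Reports
#' the non-standardised coefficient, its p-value and the model R^2.
#'
#' @param data data.frame containing outcome and predictors.
#' @param outcome outcome column name.
#' @param predictors character vector of predictor column names.
#' @param transform `"none"` or `"log"` (the gate's chosen scale).
#' @return object of class `mv_result`: `coefficients` data.frame (term,
#'   beta, p_mv), `r_squared`, `n`, `fit` (the `lm` object), `dropped`.
#' @export
multivariate_fit <- function(data, outcome, predictors, transform = "none") {
  stopifnot(length(predictors) >= 1)
  d <- data[c(outcome, predictors)]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) <= length(predictors) + 2) stop("too few observations for the model")
  y <- if (transform == "log") log(d[[outcome]]) else d[[outcome]]
  d$.y <- y
  mk_fit <- function(preds) {
    form <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", preds), collapse = " + ")))
    stats::lm(form, data = d)
  }
  # map coefficient columns to predictors via the model's assign vector, so
  # that collinearity is attributed to the right predictor even when names
  # share a prefix
  pred_of_coef <- function(fit, preds) {
    c(NA_character_, preds)[fit$assign + 1L]
  }
  fit <- mk_fit(predictors)
  dropped <- character()
  if (anyNA(stats::coef(fit))) {
    bad <- unique(pred_of_coef(fit, predictors)[is.na(stats::coef(fit))])
    keep <- setdiff(predictors, bad)
    dropped <- setdiff(predictors, keep)
    warning("dropping collinear predictor(s): ", paste(dropped, collapse = ", "))
    if (!length(keep)) stop("all predictors collinear")
    fit <- mk_fit(keep)
    predictors <- keep
    if (anyNA(stats::coef(fit))) stop("predictors remain collinear after refit")
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  structure(list(
    coefficients = data.frame(term = rownames(ct)[-1],
                              predictor = pred_of_coef(fit, predictors)[-1],
                              beta = unname(ct[-1, 1]),
                              p_mv = unname(ct[-1, 4]), stringsAsFactors = FALSE),
    r_squared = sm$r.squared, n = nrow(d), transform = transform,
    outcome = outcome, fit = fit, dropped = dropped),
    class = "mv_result")
}

#' @export
print.mv_result <- function(x, ...) {
  cat(sprintf("Linear model for %s%s: R2 = %.3f, n = %d\n", x$outcome,
              if (x$transform == "log") " (log scale)" else "", x$r_squared, x$n))
  cf <- x$coefficients
  for (i in seq_len(nrow(cf))) {
    cat(sprintf("  %-28s beta = %10.4g  p_mv = %.4g\n", cf$term[i], cf$beta[i], cf$p_mv[i]))
  }
  invisible(x)
}

#' Paired pre/post change test
#'
#' Paired t-test on `followup - baseline`; the change is summarised as mean
#' (SD). Degenerate zero-variance differences do not raise: an all-zero
#' difference gives p = 1, a constant non-zero shift is reported as
#' significant at the machine floor, both with `degenerate = TRUE`.
#'
#' @param baseline,followup paired numeric vectors of equal length, n >= 3.
#' @return list `mean_change`, `sd_change`, `p`, `n`, `degenerate`.
#' @export
paired_change <- function(baseline, followup) {
  if (length(baseline) != length(followup)) stop("length mismatch between baseline and followup")
  ok <- !is.na(baseline) & !is.na(followup)
  d <- followup[ok] - baseline[ok]
  if (length(d) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(d) == 0) {
    p <- if (mean(d) == 0) 1 else .Machine$double.xmin
    return(list(mean_change = mean(d), sd_change = 0, p = p, n = length(d),
                degenerate = TRUE))
  }
  tt <- stats::t.test(d)
  list(mean_change = mean(d), sd_change = stats::sd(d), p = tt$p.value,
       n = length(d), degenerate = FALSE)
}

#' Incidence test for a 2 x k event table
#'
#' Pearson chi-squared when every expected count is at least 5, otherwise
#' the Fisher exact test (two-sided; for 2 x 2 this sums the hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table).
#'
#' @param tab 2 x k matrix of non-negative integer counts (rows: event /
#'   no event; columns: groups).
#' @return object of class `incidence_result`: `table`, `test`, `p`,
#'   `expected`, `proportions` (per-column event proportion).
#' @export
#' @examples
#' incidence_test(matrix(c(28, 0, 30, 6), 2))$p  # Fisher, 0.031
incidence_test <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2) stop("expected a 2 x k table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) && any(colSums(tab) == 0)) stop("empty margin")
  if (any(colSums(tab) == 0)) stop("empty margin")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    p <- stats::fisher.test(tab)$p.value
    test <- "fisher"
  } else {
    p <- stats::chisq.test(tab, correct = FALSE)$p.value
    test <- "chi2"
  }
  structure(list(table = tab, test = test, p = p, expected = expected,
                 proportions = tab[1, ] / colSums(tab)),
            class = "incidence_result")
}

#' @export
print.incidence_result <- function(x, ...) {
  cat(sprintf("%s test: p = %.4g\n", if (x$test == "fisher") "Fisher exact" else "Chi-squared",
              x$p))
  print(x$table)
  invisible(x)
}

#' Univariate-to-multivariate association cascade
#'
#' The full screening cascade for one outcome: the normality gate fixes the
#' analysis scale, every candidate predictor is screened univariately, and
#' the predictors with `p_uv < alpha` enter one multivariate linear model on
#' the gated scale. With no predictor passing the screen, no model is
#' fitted.
#'
#' @param data subject-level analysis data.frame.
#' @param outcome outcome column name (continuous).
#' @param predictors character vector of categorical predictor columns.
#' @param alpha screening level (default 0.05).
#' @param min_level_n predictor levels with fewer observations are not
#'   collapsed, but the predictor is flagged in the result.
#' @return object of class `assoc_cascade`: `gate`, `univariate` (list of
#'   `uv_result`), `screen` (data.frame predictor/test/p_uv/selected),
#'   `multivariate` (`mv_result` or `NULL`).
#' @export
assoc_cascade <- function(data, outcome, predictors, alpha = 0.05,
                          min_level_n = 2L) {
  y_all <- data[[outcome]]
  if (is.null(y_all)) stop("unknown outcome column: ", outcome)
  gate <- normality_gate(y_all[!is.na(y_all)])
  uv <- list()
  for (p in predictors) {
    g <- data[[p]]
    if (is.null(g)) stop("unknown predictor column: ", p)
    keep <- !is.na(y_all) & !is.na(g)
    if (length(unique(g[keep])) < 2) next
    uv[[p]] <- tryCatch(suppressWarnings(univariate_test(y_all[keep], g[keep], gate = gate)),
                        error = function(e) NULL)
  }
  uv <- Filter(Negate(is.null), uv)
  screen <- data.frame(
    predictor = names(uv),
    test = vapply(uv, function(u) u$test, ""),
    p_uv = vapply(uv, function(u) u$p_uv, 0),
    stringsAsFactors = FALSE)
  screen$selected <- !is.na(screen$p_uv) & screen$p_uv < alpha
  mv <- NULL
  sel <- screen$predictor[screen$selected]
  if (length(sel)) {
    mv <- tryCatch(suppressWarnings(
      multivariate_fit(data, outcome, sel, transform = gate$transform)),
      error = function(e) NULL)
  }
  structure(list(outcome = outcome, gate = gate, univariate = uv,
                 screen = screen, multivariate = mv, alpha = alpha),
            class = "assoc_cascade")
}

#' @export
print.assoc_cascade <- function(x, ...) {
  cat(sprintf("Association cascade for %s (%s route)\n", x$outcome, x$gate$route))
  s <- x$screen
  if (!nrow(s)) { cat("  no testable predictors\n"); return(invisible(x)) }
  for (i in order(s$p_uv)) {
    cat(sprintf("  %-28s %-14s p_uv = %.4g%s\n", s$predictor[i], s$test[i],
                s$p_uv[i], if (s$selected[i]) "  *" else ""))
  }
  if (!is.null(x$multivariate)) { cat("Multivariate step:\n"); print(x$multivariate) }
  else cat("No predictor passed the univariate screen; no model fitted.\n")
  invisible(x)
}

#' @export
summary.assoc_cascade <- function(object, ...) {
  s <- object$screen
  s$outcome <- object$outcome
  if (!is.null(object$multivariate)) {
    cf <- object$multivariate$coefficients
    s$p_mv <- NA_real_; s$beta <- NA_real_
    for (i in seq_len(nrow(s))) {
      hit <- which(cf$predictor == s$predictor[i])
      if (length(hit)) { s$p_mv[i] <- cf$p_mv[hit[1]]; s$beta[i] <- cf$beta[hit[1]] }
    }
    s$r_squared <- object$multivariate$r_squared
  } else {
    s$p_mv <- NA_real_; s$beta <- NA_real_; s$r_squared <- NA_real_
  }
  s[c("outcome", "predictor", "test", "p_uv", "selected", "beta", "p_mv", "r_squared")]
}
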