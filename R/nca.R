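#' Pre-process below-quantification samples
#'
#' Applies the BLOQ handling convention before any parameter is computed:
#' samples are sorted by time; below-quantification (BLOQ) samples before the
#' first quantifiable one are set to concentration 0 (so the pre-dose flag
#' contributes a leading zero trapezoid); BLOQ samples embedded between
#' quantifiable samples are excluded; of any trailing BLOQ run only the first
#' sample is retained, flagged, and excluded from both the AUC and the
#' terminal-slope fit. A profile with no quantifiable sample is returned
#' flagged non-evaluable rather than raising an error.
#'
#' @param profile data.frame with `time_h`, `conc_ng_ml` and optionally
#'   `bloq_flag` (inferred from `NA`/`< lloq` concentrations if absent).
#' @param lloq lower limit of quantification (used only when `bloq_flag` is
#'   absent).
#' @return the cleaned profile with logical columns `use_auc` and
#'   `use_lambda`; attribute `evaluable` (logical) and `reason`.
#' @export
preprocess_bloq <- function(profile, lloq = NULL) {
  stopifnot(all(c("time_h", "conc_ng_ml") %in% names(profile)))
  p <- profile[order(profile$time_h), , drop = FALSE]
  if (anyDuplicated(p$time_h)) stop("duplicate sampling times")
  if (is.null(p$bloq_flag)) {
    below <- if (is.null(lloq)) FALSE else p$conc_ng_ml < lloq
    p$bloq_flag <- as.integer(is.na(p$conc_ng_ml) | below)
  }
  quant <- p$bloq_flag == 0
  if (!any(quant)) {
    out <- p[0, ]
    attr(out, "evaluable") <- FALSE
    attr(out, "reason") <- "no quantifiable samples"
    return(out)
  }
  first_q <- which(quant)[1]
  last_q <- which(quant)[length(which(quant))]
  keep <- rep(TRUE, nrow(p))
  # leading BLOQ -> zero concentration, kept
  lead <- seq_len(nrow(p)) < first_q
  p$conc_ng_ml[lead] <- 0
  # embedded BLOQ -> dropped
  keep[!quant & seq_len(nrow(p)) > first_q & seq_len(nrow(p)) < last_q] <- FALSE
  # trailing BLOQ -> keep only the first, unused downstream
  trail <- which(!quant & seq_len(nrow(p)) > last_q)
  if (length(trail) > 1) keep[trail[-1]] <- FALSE
  out <- p[keep, , drop = FALSE]
  q2 <- out$bloq_flag == 0
  out$use_auc <- q2 | out$time_h < out$time_h[which(q2)[1]]
  out$use_lambda <- q2
  rownames(out) <- NULL
  attr(out, "evaluable") <- TRUE
  attr(out, "reason") <- NA_character_
  out
}

#' Maximum concentration and its time
#'
#' `Cmax` is the maximum observed (quantifiable) concentration and `tmax`
#' its sampling time; ties are broken by the earliest time.
#' @param profile cleaned profile from [preprocess_bloq()] (or any data.frame
#'   with `time_h`, `conc_ng_ml`).
#' @return named numeric `c(Cmax, tmax)`.
#' @export
cmax_tmax <- function(profile) {
  conc <- profile$conc_ng_ml
  q <- !is.na(conc) & (if (is.null(profile$bloq_flag)) TRUE else profile$bloq_flag == 0)
  if (!any(q)) stop("no quantifiable samples")
  i <- which(q)[which.max(conc[q])]
  c(Cmax = conc[i], tmax = profile$time_h[i])
}

#' Trapezoidal area under the curve
#'
#' Plain linear trapezoid over the retained samples up to the last
#' quantifiable sample at or before `end_time`:
#' `sum (t_{i+1} - t_i) (C_i + C_{i+1}) / 2`. A log-linear-down variant
#' (logarithmic interpolation on declining segments) is available but off by
#' default.
#'
#' @param profile cleaned profile ([preprocess_bloq()] output or a plain
#'   `time_h`/`conc_ng_ml` data.frame).
#' @param end_time anchor for the last quantifiable sample (default 48 h).
#' @param method `"linear"` (default) or `"linlog"`.
#' @return AUC to the last quantifiable sample, ng*h/mL.
#' @export
auc_trapezoidal <- function(profile, end_time = 48, method = c("linear", "linlog")) {
  method <- match.arg(method)
  use <- if (is.null(profile$use_auc)) !is.na(profile$conc_ng_ml) else profile$use_auc
  p <- profile[use & profile$time_h <= end_time, , drop = FALSE]
  t <- p$time_h; c_ <- p$conc_ng_ml
  if (length(t) < 2) stop("need at least 2 retained samples for the trapezoidal rule")
  dt <- diff(t)
  if (method == "linear") {
    sum(dt * (c_[-length(c_)] + c_[-1]) / 2)
  } else {
    c1 <- c_[-length(c_)]; c2 <- c_[-1]
    seg <- dt * (c1 + c2) / 2
    down <- c2 < c1 & c2 > 0 & c1 > 0
    seg[down] <- dt[down] * (c1[down] - c2[down]) / log(c1[down] / c2[down])
    sum(seg)
  }
}

#' Terminal elimination slope
#'
#' Fits ordinary least squares of `log C` against time over a terminal tail
#' of quantifiable points strictly after `tmax` and returns
#' `Ke = -slope`. The default tail-selection rule considers every tail of at
#' least 3 points (never including `tmax`) and keeps the one maximising the
#' adjusted R^2 (ties within 1e-4 go to the longer tail); `rule = "last3"`
#' always uses the last three points. A non-declining best tail (`Ke <= 0`)
#' makes the profile non-evaluable.
#'
#' @param profile cleaned profile from [preprocess_bloq()].
#' @param rule `"best_adjr2"` (default) or `"last3"`.
#' @return list with `Ke` (1/h), `n_points`, `adj_r2`, `intercept`, and the
#'   fitted tail (`time_h`, `log_conc`); `NULL` fields and
#'   `reason` when non-evaluable.
#' @export
terminal_slope <- function(profile, rule = c("best_adjr2", "last3")) {
  rule <- match.arg(rule)
  use <- if (is.null(profile$use_lambda)) !is.na(profile$conc_ng_ml) else profile$use_lambda
  p <- profile[use, , drop = FALSE]
  ct <- cmax_tmax(p)
  post <- p[p$time_h > ct["tmax"] & p$conc_ng_ml > 0, , drop = FALSE]
  m <- nrow(post)
  if (m < 3) {
    return(list(Ke = NA_real_, n_points = NA_integer_, adj_r2 = NA_real_,
                reason = "fewer than 3 quantifiable points after tmax"))
  }
  t <- post$time_h; y <- log(post$conc_ng_ml)
  fit_tail <- function(k) {
    idx <- (m - k + 1):m
    ols_line(t[idx], y[idx])
  }
  ks <- if (rule == "last3") 3L else 3:m
  fits <- lapply(ks, fit_tail)
  adj <- vapply(fits, function(f) f$adj_r2, 0)
  slope <- vapply(fits, function(f) f$slope, 0)
  ok <- slope < 0
  if (!any(ok)) {
    return(list(Ke = NA_real_, n_points = NA_integer_, adj_r2 = NA_real_,
                reason = "no declining terminal phase"))
  }
  best <- max(adj[ok])
  cand <- which(ok & adj >= best - 1e-4)
  pick <- cand[which.max(ks[cand])]  # prefer the longer tail on ties
  f <- fits[[pick]]
  k <- ks[pick]
  list(Ke = -f$slope, n_points = as.integer(k), adj_r2 = f$adj_r2,
       intercept = f$intercept,
       tail = data.frame(time_h = t[(m - k + 1):m], log_conc = y[(m - k + 1):m]),
       reason = NA_character_)
}

ols_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  yhat <- my + slope * (x - mx)
  sse <- sum((y - yhat)^2)
  sst <- sum((y - my)^2)
  r2 <- if (sst > 0) 1 - sse / sst else 1
  adj <- if (n > 2) 1 - (1 - r2) * (n - 1) / (n - 2) else r2
  list(slope = slope, intercept = my - slope * mx, r2 = r2, adj_r2 = adj)
}

#' Extrapolate the AUC to infinity
#'
#' `AUCinf = AUCt + C_last / Ke`, where `C_last` is the last quantifiable
#' concentration. Also reports the extrapolated percentage
#' `100 (AUCinf - AUCt) / AUCinf` with a warning flag above 20%.
#' @param auc_t AUC to the last quantifiable sample.
#' @param c_last last quantifiable concentration (> 0).
#' @param ke terminal elimination rate constant (> 0).
#' @return list `AUCinf`, `pct_extrapolated`, `flag_extrapolation`.
#' @export
extrapolate_auc <- function(auc_t, c_last, ke) {
  if (!is.finite(ke) || ke <= 0) stop("Ke must be positive")
  if (c_last < 0) stop("C_last must be >= 0")
  auc_inf <- auc_t + c_last / ke
  pct <- 100 * (auc_inf - auc_t) / auc_inf
  list(AUCinf = auc_inf, pct_extrapolated = pct,
       flag_extrapolation = pct > 20)
}

#' Dose and dose/weight normalisation
#'
#' Divides exposure metrics by the dose (`X/D = X / dose`) and by the
#' dose/weight ratio (`X/DW = X * weight / dose`), the correction used to
#' compare exposure across doses and body sizes (units ng*h*kg/mL*mg for
#' AUC/DW).
#' @param x named numeric with `AUCinf` and `Cmax` (an [nca()] coefficient
#'   vector works).
#' @param dose dose in mg (> 0).
#' @param weight body weight in kg (> 0).
#' @return named numeric `AUCinf_d`, `Cmax_d`, `AUCinf_dw`, `Cmax_dw`.
#' @export
dw_normalize <- function(x, dose, weight) {
  if (dose <= 0 || weight <= 0) stop("dose and weight must be > 0")
  c(AUCinf_d = unname(x[["AUCinf"]] / dose),
    Cmax_d = unname(x[["Cmax"]] / dose),
    AUCinf_dw = unname(x[["AUCinf"]] * weight / dose),
    Cmax_dw = unname(x[["Cmax"]] * weight / dose))
}

#' Non-compartmental analysis of one profile
#'
#' The NCA estimator: BLOQ pre-processing, observed `Cmax`/`tmax`,
#' trapezoidal `AUCt` to the last quantifiable sample at or before
#' `end_time`, terminal-slope `Ke` (with `t1/2 = ln 2 / Ke`), extrapolation
#' `AUCinf = AUCt + C_last/Ke` and dose / dose-weight normalisation.
#'
#' @param profile data.frame `time_h`, `conc_ng_ml`, optional `bloq_flag`.
#' @param dose dose in mg.
#' @param weight body weight in kg.
#' @param lloq lower limit of quantification (ng/mL); used to infer BLOQ
#'   flags when the profile has none.
#' @param end_time AUCt anchor (default 48 h).
#' @param lambda_rule terminal tail selection, see [terminal_slope()].
#' @param auc_method see [auc_trapezoidal()].
#' @return object of class `nca`; non-evaluable profiles give an object with
#'   `evaluable = FALSE` and a `reason` instead of an error.
#' @seealso [coef.nca()], [plot.nca()], [residuals.nca()]
#' @export
#' @examples
#' prof <- data.frame(time_h = c(0, 1, 2, 4, 8, 12, 24),
#'                    conc_ng_ml = c(NA, 40, 60, 45, 22, 11, 1.5),
#'                    bloq_flag = c(1, 0, 0, 0, 0, 0, 0))
#' fit <- nca(prof, dose = 12.5, weight = 70)
#' coef(fit)
nca <- function(profile, dose, weight, lloq = NULL, end_time = 48,
                lambda_rule = c("best_adjr2", "last3"),
                auc_method = c("linear", "linlog")) {
  lambda_rule <- match.arg(lambda_rule)
  auc_method <- match.arg(auc_method)
  if (dose <= 0 || weight <= 0) stop("dose and weight must be > 0")
  cleaned <- preprocess_bloq(profile, lloq)
  out <- structure(list(data = cleaned, dose = dose, weight = weight,
                        end_time = end_time, evaluable = FALSE,
                        reason = attr(cleaned, "reason")), class = "nca")
  if (!isTRUE(attr(cleaned, "evaluable"))) return(out)

  ct <- cmax_tmax(cleaned)
  quant <- cleaned[cleaned$bloq_flag == 0 & cleaned$time_h <= end_time, ]
  if (nrow(quant) < 2) { out$reason <- "fewer than 2 quantifiable samples"; return(out) }
  auc_t <- auc_trapezoidal(cleaned, end_time = end_time, method = auc_method)
  ts <- terminal_slope(cleaned, rule = lambda_rule)
  if (!is.finite(ts$Ke) || ts$Ke <= 0) { out$reason <- ts$reason; return(out) }
  c_last <- quant$conc_ng_ml[nrow(quant)]
  ext <- extrapolate_auc(auc_t, c_last, ts$Ke)

  est <- c(Cmax = unname(ct["Cmax"]), tmax = unname(ct["tmax"]),
           AUCt = auc_t, AUCinf = ext$AUCinf, Ke = ts$Ke,
           t_half = log(2) / ts$Ke)
  out$estimates <- c(est, dw_normalize(est, dose, weight))
  out$diagnostics <- list(n_lambda_points = ts$n_points, adj_r2_lambda = ts$adj_r2,
                          pct_extrapolated = ext$pct_extrapolated,
                          flag_extrapolation = ext$flag_extrapolation,
                          lambda_intercept = ts$intercept, lambda_tail = ts$tail)
  out$evaluable <- TRUE
  out$reason <- NA_character_
  out
}

#' @export
print.nca <- function(x, digits = 4, ...) {
  cat("Non-compartmental analysis (dose", x$dose, "mg, weight",
      format(x$weight, digits = 4), "kg)\n")
  if (!x$evaluable) {
    cat("  non-evaluable:", x$reason, "\n")
    return(invisible(x))
  }
  e <- x$estimates
  cat(sprintf("  Cmax %s ng/mL at tmax %s h\n",
              format(e[["Cmax"]], digits = digits), format(e[["tmax"]])))
  cat(sprintf("  AUCt %s, AUCinf %s ng*h/mL (%.1f%% extrapolated%s)\n",
              format(e[["AUCt"]], digits = digits),
              format(e[["AUCinf"]], digits = digits),
              x$diagnostics$pct_extrapolated,
              if (x$diagnostics$flag_extrapolation) ", > 20% flagged" else ""))
  cat(sprintf("  Ke %s 1/h (t1/2 %s h; %d points, adj R2 %s)\n",
              format(e[["Ke"]], digits = digits),
              format(e[["t_half"]], digits = digits),
              x$diagnostics$n_lambda_points,
              format(x$diagnostics$adj_r2_lambda, digits = 4)))
  invisible(x)
}

#' Extract NCA parameter estimates
#' @param object an [nca()] fit.
#' @param ... unused.
#' @return named numeric vector (raw and dose/weight-normalised parameters),
#'   or `NULL` for a non-evaluable profile.
#' @export
coef.nca <- function(object, ...) {
  if (!object$evaluable) return(NULL)
  object$estimates
}

#' @export
summary.nca <- function(object, ...) {
  print(object)
  if (object$evaluable) {
    cat("  normalised:",
        paste(sprintf("%s = %s", c("AUCinf/D", "Cmax/D", "AUCinf/DW", "Cmax/DW"),
                      format(object$estimates[c("AUCinf_d", "Cmax_d",
                                                "AUCinf_dw", "Cmax_dw")],
                             digits = 4)), collapse = ", "), "\n")
  }
  invisible(object)
}

#' Terminal-fit residuals
#' @param object an [nca()] fit.
#' @param ... unused.
#' @return residuals of the log-linear terminal fit at the tail points.
#' @export
residuals.nca <- function(object, ...) {
  if (!object$evaluable) return(NULL)
  d <- object$diagnostics
  d$lambda_tail$log_conc - (d$lambda_intercept - object$estimates[["Ke"]] * d$lambda_tail$time_h)
}

#' Plot a concentration-time profile with its terminal fit
#' @param x an [nca()] fit.
#' @param log_y logical; log-scale concentration axis.
#' @param ... passed to [plot.default()].
#' @export
plot.nca <- function(x, log_y = TRUE, ...) {
  d <- x$data[x$data$bloq_flag == 0 | x$data$conc_ng_ml == 0, ]
  plot(d$time_h, pmax(d$conc_ng_ml, 1e-12), log = if (log_y) "y" else "",
       xlab = "time (h)", ylab = "concentration (ng/mL)", pch = 16, ...)
  if (x$evaluable) {
    tl <- x$diagnostics$lambda_tail
    tt <- seq(min(tl$time_h), max(x$data$time_h), length.out = 50)
    graphics::lines(tt, exp(x$diagnostics$lambda_intercept - x$estimates[["Ke"]] * tt),
                    lty = 2)
  }
  invisible(x)
}

#' Aggregate crossover formulations
#'
#' Collapses per-period NCA results to one row per subject and drug:
#' `mean_TR` takes the arithmetic mean of every parameter across all test
#' and reference periods (the policy for drugs whose test formulations were
#' all bioequivalent), `reference_only` keeps the reference-period
#' parameters, averaged across reference replicates if more than one.
#'
#' @param results data.frame of per-period results: `subject`, `drug`,
#'   `period`, `formulation` plus numeric parameter columns.
#' @param policy `"mean_TR"` or `"reference_only"`; may be a named vector
#'   keyed by drug.
#' @return data.frame, one row per subject x drug.
#' @export
aggregate_formulations <- function(results, policy = "mean_TR") {
  stopifnot(all(c("subject", "drug", "formulation") %in% names(results)))
  num_cols <- names(results)[vapply(results, is.numeric, TRUE) &
                               !names(results) %in% c("period")]
  pieces <- lapply(split(results, results[c("subject", "drug")], drop = TRUE),
                   function(d) {
    pol <- if (length(policy) > 1 || !is.null(names(policy))) {
      policy[[d$drug[1]]]
    } else policy
    if (!pol %in% c("mean_TR", "reference_only")) stop("unknown policy: ", pol)
    keep <- if (pol == "reference_only") d$formulation == "R" else rep(TRUE, nrow(d))
    if (!any(keep)) stop("no reference period for subject ", d$subject[1],
                         " / ", d$drug[1], " under reference_only")
    out <- d[1, c("subject", "drug"), drop = FALSE]
    for (cc in num_cols) out[[cc]] <- mean(d[[cc]][keep])
    out$n_periods_used <- sum(keep)
    out
  })
  out <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  out[order(out$drug, out$subject), , drop = FALSE]
}

#' Run NCA over a concentration table
#'
#' Splits a long concentration table into subject x drug x period x
#' formulation profiles, fits [nca()] to each, and aggregates periods by the
#' per-drug crossover policy. Profiles that cannot be evaluated (all-BLOQ,
#' no declining terminal phase, too few points) are excluded listwise and
#' logged with their reason.
#'
#' @param concentrations data.frame with columns `subject`, `drug`, `period`,
#'   `formulation`, `dose_mg`, `weight_kg`, `time_h`, `conc_ng_ml`,
#'   `bloq_flag`.
#' @param policy per-drug aggregation policy (named vector or single string);
#'   defaults to the crossover convention: arithmetic T/R mean for valsartan
#'   and hydrochlorothiazide, reference periods only for olmesartan.
#' @param ... passed to [nca()].
#' @return aggregated results data.frame; attributes `per_period` (unaggregated
#'   results) and `non_evaluable` (exclusion log).
#' @export
nca_table <- function(concentrations,
                      policy = c(valsartan = "mean_TR",
                                 olmesartan = "reference_only",
                                 hydrochlorothiazide = "mean_TR"),
                      ...) {
  req <- c("subject", "drug", "period", "formulation", "dose_mg", "weight_kg",
           "time_h", "conc_ng_ml", "bloq_flag")
  missing_cols <- setdiff(req, names(concentrations))
  if (length(missing_cols)) stop("missing columns: ", paste(missing_cols, collapse = ", "))
  keys <- concentrations[c("subject", "drug", "period", "formulation")]
  groups <- split(concentrations, interaction(keys, drop = TRUE))
  ng <- length(groups)
  est_names <- c("Cmax", "tmax", "AUCt", "AUCinf", "Ke", "t_half",
                 "AUCinf_d", "Cmax_d", "AUCinf_dw", "Cmax_dw")
  est_mat <- matrix(NA_real_, ng, length(est_names) + 3L,
                    dimnames = list(NULL, c(est_names, "n_lambda_points",
                                            "adj_r2_lambda", "pct_extrapolated")))
  keys1 <- data.frame(subject = vapply(groups, function(g) as.character(g$subject[1]), ""),
                      drug = vapply(groups, function(g) as.character(g$drug[1]), ""),
                      period = vapply(groups, function(g) g$period[1], 0L),
                      formulation = vapply(groups, function(g) as.character(g$formulation[1]), ""),
                      stringsAsFactors = FALSE, row.names = NULL)
  reasons <- rep(NA_character_, ng)
  for (i in seq_len(ng)) {
    g <- groups[[i]]
    fit <- nca(g[c("time_h", "conc_ng_ml", "bloq_flag")],
               dose = g$dose_mg[1], weight = g$weight_kg[1], ...)
    if (!fit$evaluable) {
      reasons[i] <- fit$reason
    } else {
      est_mat[i, ] <- c(fit$estimates[est_names],
                        fit$diagnostics$n_lambda_points,
                        fit$diagnostics$adj_r2_lambda,
                        fit$diagnostics$pct_extrapolated)
    }
  }
  ok <- is.na(reasons)
  if (!any(ok)) stop("no evaluable profiles in the concentration table")
  per_period <- cbind(keys1[ok, , drop = FALSE],
                      as.data.frame(est_mat[ok, , drop = FALSE]))
  rownames(per_period) <- NULL
  bad <- if (any(!ok)) list(cbind(keys1[!ok, , drop = FALSE],
                                  reason = reasons[!ok])) else list()
  agg_cols <- c("subject", "drug", "period", "formulation", "Cmax", "tmax",
                "AUCt", "AUCinf", "Ke", "t_half", "AUCinf_d", "Cmax_d",
                "AUCinf_dw", "Cmax_dw")
  agg <- aggregate_formulations(per_period[agg_cols], policy)
  attr(agg, "per_period") <- per_period
  attr(agg, "non_evaluable") <- if (length(bad))
    do.call(rbind, c(bad, list(make.row.names = FALSE))) else
    data.frame(subject = character(), drug = character(), period = integer(),
               formulation = character(), reason = character())
  agg
}
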