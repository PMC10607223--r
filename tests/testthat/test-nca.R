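test_that("BLOQ preprocessing applies the leading/embedded/trailing rules", {
  prof <- data.frame(
    time_h = c(0, 0.5, 1, 2, 4, 8, 12, 24, 36, 48),
    conc_ng_ml = c(NA, NA, 10, 20, NA, 12, 6, 3, NA, NA),
    bloq_flag = c(1, 1, 0, 0, 1, 0, 0, 0, 1, 1))
  cl <- preprocess_bloq(prof)
  expect_true(attr(cl, "evaluable"))
  # leading BLOQ become zeros
  expect_equal(cl$conc_ng_ml[cl$time_h %in% c(0, 0.5)], c(0, 0))
  # embedded BLOQ at t=4 dropped
  expect_false(4 %in% cl$time_h)
  # only the first trailing BLOQ retained, excluded from AUC and slope
  expect_true(36 %in% cl$time_h)
  expect_false(48 %in% cl$time_h)
  expect_false(cl$use_auc[cl$time_h == 36])
  expect_false(cl$use_lambda[cl$time_h == 36])

  # one embedded BLOQ among 17 points leaves 16
  t17 <- c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 6, 8, 10, 12, 24, 36, 48)
  conc <- 100 * exp(-0.1 * t17); conc[1] <- NA; conc[9] <- NA
  p17 <- data.frame(time_h = t17, conc_ng_ml = conc,
                    bloq_flag = as.integer(is.na(conc)))
  expect_equal(nrow(preprocess_bloq(p17)), 16L)

  # all-BLOQ profile is non-evaluable, not an error
  allb <- data.frame(time_h = c(0, 1, 2), conc_ng_ml = rep(NA_real_, 3),
                     bloq_flag = c(1, 1, 1))
  expect_false(attr(preprocess_bloq(allb), "evaluable"))
})

test_that("Cmax/tmax are the observed maximum with earliest-time tie-break", {
  p <- data.frame(time_h = c(1, 2, 4), conc_ng_ml = c(5, 9, 3))
  expect_equal(cmax_tmax(p), c(Cmax = 9, tmax = 2))
  tie <- data.frame(time_h = c(1, 2, 3), conc_ng_ml = c(5, 9, 9))
  expect_equal(cmax_tmax(tie)[["tmax"]], 2)
  # stable under input reordering (profiles are re-sorted canonically)
  shuf <- tie[c(3, 1, 2), ]
  expect_equal(cmax_tmax(preprocess_bloq(shuf))[["tmax"]], 2)
})

test_that("trapezoidal AUC matches hand-computed fixtures and the analytic integral", {
  tri <- data.frame(time_h = c(0, 1, 2), conc_ng_ml = c(0, 10, 0))
  expect_equal(auc_trapezoidal(tri), 10)
  trap <- data.frame(time_h = 0:3, conc_ng_ml = c(0, 10, 10, 0))
  expect_equal(auc_trapezoidal(trap), 20)
  expect_error(auc_trapezoidal(tri[1, , drop = FALSE]), "at least 2")

  # dense noise-free one-compartment profile: within 1% of the closed form
  CL <- 5.85; V <- 73.4; ka <- 0.73; D <- 160
  tt <- seq(0, 200, length.out = 200)
  p <- data.frame(time_h = tt, conc_ng_ml = oracle_conc(tt, D, CL, V, ka))
  expect_equal(auc_trapezoidal(p, end_time = 200),
               oracle_auc_t(200, D, CL, V, ka), tolerance = 0.01)
})

test_that("terminal slope recovers an exact exponential and defines t1/2", {
  tt <- c(0, 2, 6, 8, 12, 24, 48)
  p <- data.frame(time_h = tt, conc_ng_ml = 100 * exp(-0.1 * tt))
  ts <- terminal_slope(preprocess_bloq(p))
  expect_equal(ts$Ke, 0.1, tolerance = 1e-10)
  expect_equal(ts$adj_r2, 1, tolerance = 1e-10)
  # tmax is at t=0 here; every later point is eligible and the tie on
  # adjusted R^2 goes to the longest tail
  expect_equal(ts$n_points, 6L)
  expect_equal(log(2) / 0.0866, 8.0, tolerance = 0.01)

  # fewer than 3 post-tmax points -> non-evaluable
  short <- data.frame(time_h = c(0, 1, 2, 3), conc_ng_ml = c(0, 10, 8, 6))
  expect_true(is.na(terminal_slope(preprocess_bloq(short))$Ke))
  # rising terminal phase -> non-evaluable
  rise <- data.frame(time_h = 0:5, conc_ng_ml = c(1, 2, 3, 4, 5, 6))
  expect_true(is.na(terminal_slope(preprocess_bloq(rise))$Ke))

  # fixed last-3 rule uses exactly 3 points
  expect_equal(terminal_slope(preprocess_bloq(p), rule = "last3")$n_points, 3L)
})

test_that("AUC extrapolation follows AUCinf = AUCt + C_last/Ke", {
  ext <- extrapolate_auc(100, 5, 0.1)
  expect_equal(ext$AUCinf, 150)
  expect_equal(ext$pct_extrapolated, 100 * 50 / 150)
  expect_true(ext$flag_extrapolation)
  expect_equal(extrapolate_auc(100, 0, 0.1)$AUCinf, 100)
  expect_error(extrapolate_auc(100, 5, 0), "positive")
})

test_that("dose/weight normalisation and its round-trip", {
  x <- c(AUCinf = 1000, Cmax = 50)
  n <- dw_normalize(x, dose = 12.5, weight = 70)
  expect_equal(n[["AUCinf_d"]], 80)
  expect_equal(n[["AUCinf_dw"]], 5600)
  # weight numerically equal to dose: /DW equals the raw value
  expect_equal(dw_normalize(x, dose = 70, weight = 70)[["AUCinf_dw"]], 1000)
  # round-trip
  expect_equal(n[["AUCinf_dw"]] * 12.5 / 70, 1000)
  expect_error(dw_normalize(x, 0, 70), "> 0")
})

test_that("nca() satisfies the internal identities on a realistic fixture", {
  CL <- 23.6; V <- 330; ka <- 1.7; D <- 25
  tt <- c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 6, 8, 10, 12, 24, 36, 48)
  conc <- oracle_conc(tt, D, CL, V, ka)
  fit <- nca(data.frame(time_h = tt, conc_ng_ml = conc), dose = D,
             weight = 70, lloq = 1.01)
  expect_s3_class(fit, "nca")
  expect_true(fit$evaluable)
  est <- coef(fit)
  expect_gte(est[["AUCinf"]], est[["AUCt"]])
  expect_equal(est[["t_half"]], log(2) / est[["Ke"]])
  expect_true(est[["tmax"]] %in% tt)
  expect_gte(fit$diagnostics$pct_extrapolated, 0)
  expect_lt(fit$diagnostics$pct_extrapolated, 100)
  # t1/2 recovery within 5% of ln2 V/CL even on the sparse clinical schedule
  expect_equal(est[["t_half"]], log(2) * V / CL, tolerance = 0.05)
  expect_equal(est[["AUCinf_dw"]], est[["AUCinf"]] * 70 / 25)

  # on a dense noise-free schedule the recovery is tight: AUCinf within 2%
  # of D/CL and near-zero terminal-fit residuals
  td <- c(0, seq(0.25, 48, by = 0.25))
  dfit <- nca(data.frame(time_h = td, conc_ng_ml = oracle_conc(td, D, CL, V, ka)),
              dose = D, weight = 70, lloq = 1.01)
  expect_equal(coef(dfit)[["AUCinf"]], oracle_auc_inf(D, CL), tolerance = 0.02)
  expect_equal(coef(dfit)[["Ke"]], CL / V, tolerance = 0.02)
  expect_lt(max(abs(residuals(dfit))), 0.05)
})

test_that("linearity: scaling concentrations scales exposure, not times or slopes", {
  tt <- c(0, 1, 2, 3, 4, 6, 8, 12, 24, 48)
  conc <- oracle_conc(tt, 40, 7.46, 99.1, 1.05)
  f1 <- nca(data.frame(time_h = tt, conc_ng_ml = conc), dose = 40, weight = 70,
            lloq = 0.001)
  f2 <- nca(data.frame(time_h = tt, conc_ng_ml = 3 * conc), dose = 40,
            weight = 70, lloq = 0.001)
  e1 <- coef(f1); e2 <- coef(f2)
  expect_equal(e2[["Cmax"]], 3 * e1[["Cmax"]])
  expect_equal(e2[["AUCt"]], 3 * e1[["AUCt"]])
  expect_equal(e2[["AUCinf"]], 3 * e1[["AUCinf"]])
  expect_equal(e2[["tmax"]], e1[["tmax"]])
  expect_equal(e2[["Ke"]], e1[["Ke"]])
  expect_equal(e2[["t_half"]], e1[["t_half"]])
})

test_that("observed tmax approaches the closed-form mode as sampling densifies", {
  CL <- 5.85; V <- 73.4; ka <- 0.73
  tt <- c(0, seq(0.05, 48, by = 0.05))
  p <- data.frame(time_h = tt, conc_ng_ml = oracle_conc(tt, 160, CL, V, ka))
  est <- cmax_tmax(preprocess_bloq(p, lloq = 0))
  expect_equal(est[["tmax"]], oracle_tmax(CL, V, ka), tolerance = 0.02)
})

test_that("formulation aggregation follows the per-drug crossover policy", {
  res <- data.frame(subject = c("S1", "S1"), drug = "olmesartan",
                    period = 1:2, formulation = c("T", "R"),
                    AUCinf = c(100, 120), tmax = c(2, 3))
  expect_equal(aggregate_formulations(res, "mean_TR")$AUCinf, 110)
  expect_equal(aggregate_formulations(res, "reference_only")$AUCinf, 120)
  # identical periods: both policies agree
  same <- res; same$AUCinf <- c(100, 100); same$tmax <- 2
  expect_equal(aggregate_formulations(same, "mean_TR")$AUCinf,
               aggregate_formulations(same, "reference_only")$AUCinf)
  # reference_only without an R period fails
  tonly <- res; tonly$formulation <- c("T", "T")
  expect_error(aggregate_formulations(tonly, "reference_only"), "reference")
  # named per-drug policies
  two <- rbind(res, transform(res, drug = "valsartan"))
  agg <- aggregate_formulations(two, c(olmesartan = "reference_only",
                                       valsartan = "mean_TR"))
  expect_equal(agg$AUCinf[agg$drug == "olmesartan"], 120)
  expect_equal(agg$AUCinf[agg$drug == "valsartan"], 110)
})

test_that("nca_table logs non-evaluable profiles instead of failing", {
  tt <- c(0, 1, 2, 4, 8, 12, 24, 48)
  good <- data.frame(subject = "S1", drug = "olmesartan", period = 1L,
                     formulation = "R", dose_mg = 40, weight_kg = 70,
                     time_h = tt,
                     conc_ng_ml = oracle_conc(tt, 40, 7.46, 99.1, 1.05),
                     bloq_flag = 0L)
  good$bloq_flag[1] <- 1L; good$conc_ng_ml[1] <- NA
  bad <- good; bad$subject <- "S2"; bad$conc_ng_ml <- NA; bad$bloq_flag <- 1L
  res <- nca_table(rbind(good, bad), policy = "reference_only")
  expect_equal(nrow(res), 1L)
  log <- attr(res, "non_evaluable")
  expect_equal(log$subject, "S2")
  expect_match(log$reason, "no quantifiable")
})
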