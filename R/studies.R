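#' Single-drug study cohort
#'
#' Builds a one-trial configuration in which every subject receives the
#' given drug and dose, simulates one reference-period profile per subject,
#' runs the NCA engine, and returns the subject-level analysis table with
#' the genotype and phenotype predictor columns attached. This is the
#' workhorse of the effect-recovery and null-calibration studies.
#'
#' @param n cohort size.
#' @param drug,dose drug name and dose (mg).
#' @param seed master seed.
#' @param error_cv residual CV of the simulated assay.
#' @param config optional pre-built [cohort_config()] to modify (effects are
#'   taken from it; use [null_effects()] for a null cohort).
#' @return data.frame of aggregated NCA parameters with `sex`, `weight`,
#'   genotype columns for the transporter variants and a `CYP2D6` phenotype
#'   column.
#' @export
single_drug_cohort <- function(n, drug, dose, seed, error_cv = 0.15,
                               config = NULL) {
  cfg <- if (is.null(config)) {
    cohort_config(n_subjects = n, master_seed = seed, error_cv = error_cv)
  } else {
    config$n_subjects <- as.integer(n)
    config$master_seed <- as.integer(seed)
    config
  }
  cfg$trials <- data.frame(trial = 1L, n = as.integer(n),
                           valsartan = NA_real_, olmesartan = NA_real_,
                           hydrochlorothiazide = NA_real_)
  cfg$trials[[drug]] <- dose

  demo <- sample_demographics(cfg)
  gen <- sample_genotypes(demo, cfg$variant_freqs, cfg$star_freqs,
                          cfg$cyp2d6_cn_probs,
                          seed = substream_seed(cfg$master_seed, "genotypes"))
  phen <- phenotype_from_diplotypes(gen$diplotypes, gen$cyp2d6_cn)
  pk <- assign_pk_parameters(demo, drug, gen$genotypes, phen, cfg,
                             seed = substream_seed(cfg$master_seed, "pk"))
  prof <- simulate_profiles(pk, rep(dose, n), cfg$schedule, cfg$lloq[[drug]],
                            cfg$error_cv,
                            seed = substream_seed(cfg$master_seed, "profiles"))
  prof$drug <- drug; prof$period <- 1L; prof$formulation <- "R"
  prof$dose_mg <- dose
  prof$weight_kg <- demo$weight[match(prof$subject, demo$subject)]
  res <- nca_table(prof[c("subject", "drug", "period", "formulation", "dose_mg",
                          "weight_kg", "time_h", "conc_ng_ml", "bloq_flag")],
                   policy = "reference_only")
  out <- merge(res, demo[c("subject", "sex", "weight")], by = "subject")
  for (rs in c("rs1045642", "rs34059508")) {
    g <- gen$genotypes[gen$genotypes$rsid == rs, c("subject", "genotype")]
    names(g)[2] <- rs
    out <- merge(out, g, by = "subject")
  }
  p6 <- phen[phen$gene == "CYP2D6", c("subject", "phenotype")]
  names(p6)[2] <- "CYP2D6"
  merge(out, p6, by = "subject")
}

# the four injected-effect study definitions: simulated drug/dose, outcome,
# merged predictor coding and the direction the effect must produce
EFFECT_STUDIES <- list(
  abcb1_ka = list(
    drug = "valsartan", dose = 160, outcome = "tmax",
    coding = function(d) factor(ifelse(d$rs1045642 == "T/T", "T/T", "rest"),
                                c("rest", "T/T")),
    direction = +1),   # T/T homozygotes absorb slower: higher tmax
  slc22a1_cl = list(
    drug = "hydrochlorothiazide", dose = 25, outcome = "AUCinf_dw",
    coding = function(d) factor(ifelse(d$rs34059508 == "G/G", "G/G", "A carrier"),
                                c("G/G", "A carrier")),
    direction = +1),   # reduced OCT1 clearance: higher exposure in carriers
  cyp2d6_ke = list(
    drug = "valsartan", dose = 160, outcome = "t_half",
    coding = function(d) factor(ifelse(d$CYP2D6 == "PM", "PM", "rest"),
                                c("rest", "PM")),
    direction = +1),   # poor metabolisers eliminate slower: longer t1/2
  sex_exposure = list(
    drug = "hydrochlorothiazide", dose = 25, outcome = "AUCinf_d",
    coding = function(d) factor(d$sex, c("male", "female")),
    direction = +1))   # women: lower clearance, higher dose-corrected AUC

#' Effect-recovery study
#'
#' For one of the four injected covariate effects (ABCB1 rs1045642 T/T on
#' valsartan absorption, SLC22A1 rs34059508 on hydrochlorothiazide
#' clearance, CYP2D6 poor-metaboliser status on valsartan elimination, sex
#' on hydrochlorothiazide dose-corrected exposure), repeatedly simulates a
#' single-drug cohort, runs the NCA + univariate/multivariate cascade on
#' the relevant outcome, and records whether the estimated effect carries
#' the injected sign and whether the univariate screen detects it at
#' `alpha`.
#'
#' @param effect one of `"abcb1_ka"`, `"slc22a1_cl"`, `"cyp2d6_ke"`,
#'   `"sex_exposure"`.
#' @param n cohort size per replicate.
#' @param reps number of replicates.
#' @param seed integer seed; replicate r uses `seed + r` internally.
#' @param alpha detection level (default 0.05).
#' @return list `effect`, `n`, `reps`, `sign_rate`, `detect_rate`,
#'   `usable` (replicates with both groups represented).
#' @export
sign_recovery_study <- function(effect, n = 200, reps = 200, seed = 1,
                                alpha = 0.05) {
  spec <- EFFECT_STUDIES[[match.arg(effect, names(EFFECT_STUDIES))]]
  base <- (as.numeric(seed) %% 1e6) * 1000  # replicate seeds stay below 2^31
  sign_ok <- detect <- logical(0)
  for (r in seq_len(reps)) {
    d <- single_drug_cohort(n, spec$drug, spec$dose, seed = base + r)
    grp <- spec$coding(d)
    if (nlevels(droplevels(grp)) < 2) next
    y <- d[[spec$outcome]]
    # effect estimate: cascade beta when the screen selects the predictor,
    # group-mean difference otherwise
    dd <- data.frame(y = y, g = grp)
    cs <- assoc_cascade(dd, "y", "g", alpha = alpha)
    diff_est <- if (!is.null(cs$multivariate)) {
      cs$multivariate$coefficients$beta[1]
    } else {
      mean(y[grp == levels(grp)[2]]) - mean(y[grp == levels(grp)[1]])
    }
    sign_ok <- c(sign_ok, sign(diff_est) == spec$direction)
    detect <- c(detect, any(cs$screen$selected))
  }
  list(effect = effect, n = n, reps = reps, usable = length(sign_ok),
       sign_rate = mean(sign_ok), detect_rate = mean(detect))
}

#' Null-calibration study
#'
#' Simulates cohorts with every covariate effect switched off
#' ([null_effects()]) and runs the association stage on outcomes and
#' predictors that carry no true signal; the fraction of univariate
#' p-values below `alpha` estimates the cascade's type-I error rate. Two
#' quasi-independent screens are used per replicate: sex on t1/2 (under
#' the null configuration elimination is sex-free; dose/weight-corrected
#' exposure is not usable here because body weight itself differs by sex)
#' and the rs1045642 three-level genotype on dose/weight-corrected AUC.
#'
#' @param reps replicates.
#' @param n cohort size per replicate (default 58, a trial-sized cohort).
#' @param seed integer seed.
#' @param alpha nominal level.
#' @return list `reps`, `n_tests`, `type1_rate`, `selected_rate` (fraction
#'   of replicates in which the focal predictor entered the multivariate
#'   step).
#' @export
null_calibration_study <- function(reps = 500, n = 58, seed = 1, alpha = 0.05) {
  cfg0 <- null_effects(cohort_config(n_subjects = n, master_seed = 1))
  base <- (as.numeric(seed) %% 1e6) * 1000
  hits <- integer(0); sel_focal <- logical(0)
  for (r in seq_len(reps)) {
    d <- single_drug_cohort(n, "hydrochlorothiazide", 25,
                            seed = base + r, config = cfg0)
    p1 <- tryCatch(suppressWarnings(
      univariate_test(d$t_half, d$sex)$p_uv), error = function(e) NA_real_)
    g3 <- factor(d$rs1045642, c("T/T", "T/C", "C/C"))
    p2 <- tryCatch(suppressWarnings(
      univariate_test(d$AUCinf_dw, g3)$p_uv), error = function(e) NA_real_)
    hits <- c(hits, c(p1, p2)[!is.na(c(p1, p2))] < alpha)
    sel_focal <- c(sel_focal, !is.na(p1) && p1 < alpha)
  }
  list(reps = reps, n_tests = length(hits), type1_rate = mean(hits),
       selected_rate = mean(sel_focal))
}
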