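#' Sample cohort demographics
#'
#' Draws per-sex age, height and weight, assigns trials and self-reported
#' biogeographic origin, and enforces the trial inclusion bounds (age 18-55,
#' BMI 18.5-30 kg/m^2). Because the configured moments describe the
#' *post-inclusion* cohort, the sampler moment-matches: pre-truncation means
#' and SDs are solved (closed-form truncated-normal moments, deterministic)
#' so that the truncated draws reproduce the configured mean/SD for age and
#' weight; weight bounds are subject-specific (`18.5 h^2` to `30 h^2` given
#' sampled height).
#'
#' @param config a [cohort_config()].
#' @param seed optional integer; defaults to the demographics substream of
#'   the configuration's master seed.
#' @return data.frame with columns `subject`, `sex`, `age`, `height`,
#'   `weight`, `bmi`, `trial`, `origin`.
#' @export
sample_demographics <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  if (n < 1) stop("n_subjects must be >= 1")
  if (is.null(seed)) seed <- substream_seed(config$master_seed, "demographics")
  set.seed(seed)

  n_f <- round(n * config$sex_ratio)
  sex <- sample(rep(c("female", "male"), c(n_f, n - n_f)))
  trial <- sample(rep(config$trials$trial, apportion(n, config$trials$n)))
  origin <- sample(rep(names(config$origin_probs), apportion(n, config$origin_probs)))

  dem <- config$demographics
  age <- height <- weight <- numeric(n)
  for (s in unique(sex)) {
    i <- which(sex == s)
    par <- dem[[s]]
    height[i] <- stats::rnorm(length(i), par$height[1], par$height[2])
    ap <- solve_tnorm(par$age[1], par$age[2], dem$age_range[1], dem$age_range[2])
    age[i] <- rtnorm(length(i), ap["mu"], ap["sigma"], dem$age_range[1], dem$age_range[2])
    # match weight moments under the BMI bounds, averaged over the height
    # distribution (fixed quantile grid keeps this deterministic)
    hgrid <- stats::qnorm((seq_len(41) - 0.5) / 41, par$height[1], par$height[2])
    wp <- solve_tnorm(par$weight[1], par$weight[2],
                      dem$bmi_range[1] * hgrid^2, dem$bmi_range[2] * hgrid^2)
    weight[i] <- rtnorm(length(i), wp["mu"], wp["sigma"],
                        dem$bmi_range[1] * height[i]^2, dem$bmi_range[2] * height[i]^2)
  }

  data.frame(subject = sprintf("S%03d", seq_len(n)), sex = sex,
             age = age, height = height, weight = weight,
             bmi = weight / height^2, trial = trial, origin = origin,
             stringsAsFactors = FALSE)
}

# largest-remainder apportionment of n among weights
apportion <- function(n, weights) {
  q <- n * weights / sum(weights)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Sample genotypes under Hardy-Weinberg equilibrium
#'
#' Plain transporter variants are drawn allele-by-allele per locus
#' (independent loci, HWE). Star-allele genes are drawn at the haplotype
#' level: two star alleles per subject from the configured star-allele
#' frequencies, then expanded into the variant calls their definitions imply,
#' so that haplotype structure (e.g. both CYP2D6 *4-defining variants in cis)
#' is preserved and diplotype truth is available for testing the caller.
#' CYP2D6 copy number is drawn from the configured distribution (default:
#' always 2); copy number 1 replaces one drawn allele by the deletion allele
#' *5 (variant calls then look homozygous for the retained haplotype), and
#' copy number 0 yields missing calls.
#'
#' @param subjects data.frame from [sample_demographics()] (only `subject`
#'   is used).
#' @param variant_freqs named list rsID -> named allele-frequency vector.
#' @param star_freqs named list gene -> named star-allele frequency vector
#'   (including `*1`).
#' @param cn_probs named probability vector over CYP2D6 copy numbers.
#' @param seed integer seed.
#' @return list with `genotypes` (long data.frame: `subject`, `rsid`,
#'   `allele1`, `allele2`, `genotype`), `cyp2d6_cn` (`subject`, `cn`) and
#'   `diplotypes` (`subject`, `gene`, `allele1`, `allele2`, `diplotype`) --
#'   the simulation truth used by round-trip tests.
#' @export
sample_genotypes <- function(subjects, variant_freqs, star_freqs,
                             cn_probs = c("2" = 1), seed = 1L) {
  n <- nrow(subjects)
  ids <- subjects$subject
  for (rs in names(variant_freqs)) {
    if (abs(sum(variant_freqs[[rs]]) - 1) > 0.02) {
      stop("allele frequencies for ", rs, " do not sum to 1")
    }
    variant_freqs[[rs]] <- variant_freqs[[rs]] / sum(variant_freqs[[rs]])
  }
  if (abs(sum(cn_probs) - 1) > 1e-8) stop("copy-number probabilities must sum to 1")
  set.seed(seed)

  draw_pairs <- function(alleles, freqs) {
    i1 <- sample.int(length(alleles), n, replace = TRUE, prob = freqs)
    i2 <- sample.int(length(alleles), n, replace = TRUE, prob = freqs)
    lo <- pmin(i1, i2); hi <- pmax(i1, i2)  # canonical order: reference first
    data.frame(allele1 = alleles[lo], allele2 = alleles[hi],
               stringsAsFactors = FALSE)
  }

  geno <- list()
  for (rs in names(variant_freqs)) {
    f <- variant_freqs[[rs]]
    p <- draw_pairs(names(f), f)
    geno[[rs]] <- data.frame(subject = ids, rsid = rs, p,
                             genotype = paste0(p$allele1, "/", p$allele2),
                             stringsAsFactors = FALSE)
  }

  dip <- list()
  for (g in names(star_freqs)) {
    f <- star_freqs[[g]]
    p <- draw_pairs(names(f), f)
    dip[[g]] <- data.frame(subject = ids, gene = g, p,
                           stringsAsFactors = FALSE)
  }

  cn <- as.integer(sample(names(cn_probs), n, replace = TRUE, prob = cn_probs))
  if ("CYP2D6" %in% names(dip)) {
    d <- dip$CYP2D6
    d$allele2[cn == 1] <- "*5"
    d$allele1[cn == 0] <- "*5"; d$allele2[cn == 0] <- "*5"
    dip$CYP2D6 <- d
  }
  dip <- do.call(rbind, c(dip, list(make.row.names = FALSE)))
  dip$diplotype <- paste0(dip$allele1, "/", dip$allele2)

  # expand star alleles into the variant calls their definitions imply
  defs <- pgx_definitions()
  star_rs <- split(defs$definitions, defs$definitions$gene)
  for (g in intersect(names(star_freqs), names(star_rs))) {
    dg <- dip[dip$gene == g, ]
    rsids <- unique(star_rs[[g]]$rsid)
    for (rs in rsids) {
      ref <- defs$variants$ref_allele[defs$variants$rsid == rs]
      var_of <- function(star) {
        hit <- defs$definitions$variant_allele[defs$definitions$gene == g &
                                                 defs$definitions$allele == star &
                                                 defs$definitions$rsid == rs]
        if (length(hit)) hit else ref
      }
      a1 <- vapply(dg$allele1, var_of, "")
      a2 <- vapply(dg$allele2, var_of, "")
      if (g == "CYP2D6") {
        # a deleted CYP2D6 haplotype (*5) carries no sequence: report the
        # retained one (assays read homozygous); whole-gene loss is missing
        a1[dg$allele1 == "*5"] <- a2[dg$allele1 == "*5"]
        a2[dg$allele2 == "*5"] <- a1[dg$allele2 == "*5"]
        miss <- dg$allele1 == "*5" & dg$allele2 == "*5"
        a1[miss] <- NA; a2[miss] <- NA
      }
      swap <- !is.na(a1) & a1 != ref & !is.na(a2) & a2 == ref
      tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
      geno[[paste0(g, ".", rs)]] <- data.frame(
        subject = dg$subject, rsid = rs, allele1 = a1, allele2 = a2,
        genotype = ifelse(is.na(a1), NA, paste0(a1, "/", a2)),
        stringsAsFactors = FALSE)
    }
  }

  genotypes <- do.call(rbind, c(geno, list(make.row.names = FALSE)))
  list(genotypes = genotypes,
       cyp2d6_cn = data.frame(subject = ids, cn = cn, stringsAsFactors = FALSE),
       diplotypes = dip)
}

#' Assign individual pharmacokinetic parameters
#'
#' Base one-compartment parameters for the drug are combined with
#' between-subject lognormal variability (correlated CL/V, independent ka;
#' medians equal the base values) and the configured multiplicative covariate
#' effects. A `ke` effect multiplies the elimination rate constant by scaling
#' `V_F` inversely while `CL_F` is untouched, so exposure (AUC = D/CL) is
#' unchanged. With every multiplier at 1 the population is covariate-free.
#'
#' @param subjects demographics data.frame (needs `subject`, `sex`).
#' @param drug one of `"valsartan"`, `"olmesartan"`, `"hydrochlorothiazide"`.
#' @param genotypes long genotype data.frame from [sample_genotypes()].
#' @param phenotypes data.frame `subject`, `gene`, `phenotype` (needed only
#'   when a phenotype effect is active).
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return data.frame `subject`, `drug`, `CL_F`, `V_F`, `ka`, `tlag`, `ke`.
#' @export
assign_pk_parameters <- function(subjects, drug, genotypes = NULL,
                                 phenotypes = NULL, config, seed = 1L) {
  base <- config$pk[[drug]]
  if (is.null(base)) stop("unknown drug: ", drug)
  n <- nrow(subjects)
  mult <- list(CL = rep(1, n), V = rep(1, n), ka = rep(1, n))

  for (e in config$effects) {
    if (!identical(e$drug, drug) || e$mult == 1) next
    ind <- switch(e$type,
      sex = subjects$sex %in% e$levels,
      genotype = {
        if (is.null(genotypes)) stop("active effect needs genotypes for ", e$target)
        g <- genotypes[genotypes$rsid == e$target, c("subject", "genotype")]
        if (!nrow(g)) stop("active effect needs genotypes for ", e$target)
        g$genotype[match(subjects$subject, g$subject)] %in% e$levels
      },
      phenotype = {
        if (is.null(phenotypes)) stop("active effect needs phenotypes for ", e$target)
        p <- phenotypes[phenotypes$gene == e$target, c("subject", "phenotype")]
        if (!nrow(p)) stop("active effect needs phenotypes for ", e$target)
        p$phenotype[match(subjects$subject, p$subject)] %in% e$levels
      },
      stop("unknown effect type: ", e$type))
    ind[is.na(ind)] <- FALSE
    m <- ifelse(ind, e$mult, 1)
    if (e$param == "CL") mult$CL <- mult$CL * m
    else if (e$param == "V") mult$V <- mult$V * m
    else if (e$param == "ka") mult$ka <- mult$ka * m
    else if (e$param == "ke") mult$V <- mult$V / m
    else stop("unknown effect parameter: ", e$param)
  }

  set.seed(seed)
  b <- config$bsv
  sd_cl <- sqrt(log(1 + b$cv_cl^2))
  sd_v <- sqrt(log(1 + b$cv_v^2))
  sd_ka <- sqrt(log(1 + b$cv_ka^2))
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n); z3 <- stats::rnorm(n)
  CL <- base[["CL_F"]] * mult$CL * exp(sd_cl * z1)
  V <- base[["V_F"]] * mult$V * exp(sd_v * (b$corr_cl_v * z1 +
                                              sqrt(1 - b$corr_cl_v^2) * z2))
  ka <- base[["ka"]] * mult$ka * exp(sd_ka * z3)
  ke <- CL / V
  ka[abs(ka - ke) < 1e-8] <- ka[abs(ka - ke) < 1e-8] * (1 + 1e-6)

  data.frame(subject = subjects$subject, drug = drug, CL_F = CL, V_F = V,
             ka = ka, tlag = base[["tlag"]], ke = CL / V,
             stringsAsFactors = FALSE)
}

#' Simulate one concentration-time profile
#'
#' One-compartment first-order absorption model
#' `C(t) = 1000 D/V_F * ka/(ka-ke) * (exp(-ke (t-tlag)) - exp(-ka (t-tlag)))`
#' for `t > tlag` (0 before), in ng/mL for dose in mg and `V_F` in litres,
#' multiplied by mean-one lognormal proportional error. Samples below the
#' lower limit of quantification are flagged and their concentration withheld
#' (`NA`); the pre-dose sample is always below quantification.
#'
#' @param params one-row data.frame (or named list) with `CL_F`, `V_F`, `ka`,
#'   `tlag`.
#' @param dose dose in mg (>= 0; a zero dose yields an all-BLOQ profile).
#' @param schedule strictly increasing sampling times in hours, starting at 0.
#' @param lloq lower limit of quantification, ng/mL.
#' @param error_cv proportional residual CV (0 = noise-free).
#' @param seed integer seed.
#' @return data.frame `time_h`, `conc_ng_ml` (`NA` when flagged), `bloq_flag`.
#' @export
simulate_profile <- function(params, dose, schedule, lloq, error_cv = 0.15,
                             seed = 1L) {
  if (any(schedule < 0)) stop("negative times in schedule")
  if (is.unsorted(schedule, strictly = TRUE)) stop("schedule must be strictly increasing")
  if (schedule[1] != 0) stop("schedule must start at 0 (pre-dose)")
  if (dose < 0) stop("dose must be >= 0")
  ke <- params$CL_F / params$V_F
  if (abs(params$ka - ke) < 1e-12) stop("ka equals ke; degenerate profile")
  set.seed(seed)
  conc <- one_cpt_conc(schedule, dose, params$CL_F, params$V_F, params$ka, params$tlag)
  if (error_cv > 0) {
    sdlog <- sqrt(log(1 + error_cv^2))
    conc <- conc * exp(stats::rnorm(length(conc), 0, sdlog) - sdlog^2 / 2)
  }
  bloq <- conc < lloq
  data.frame(time_h = schedule,
             conc_ng_ml = ifelse(bloq, NA_real_, conc),
             bloq_flag = as.integer(bloq))
}

# noise-free model prediction, vectorised over times (ng/mL)
one_cpt_conc <- function(t, dose, CL, V, ka, tlag = 0) {
  ke <- CL / V
  tt <- pmax(t - tlag, 0)
  c0 <- 1000 * dose / V
  out <- c0 * ka / (ka - ke) * (exp(-ke * tt) - exp(-ka * tt))
  out[t <= tlag] <- 0
  out
}

# batch profile simulation for a set of subjects (one period); row-wise over
# params_df, vectorised over the schedule
simulate_profiles <- function(params_df, dose, schedule, lloq, error_cv, seed,
                              period_scale = NULL) {
  set.seed(seed)
  n <- nrow(params_df)
  nt <- length(schedule)
  if (is.null(period_scale)) period_scale <- rep(1, n)
  cmat <- matrix(0, n, nt)
  for (i in seq_len(n)) {
    cmat[i, ] <- one_cpt_conc(schedule, dose[i], params_df$CL_F[i],
                              params_df$V_F[i], params_df$ka[i],
                              params_df$tlag[i]) * period_scale[i]
  }
  if (error_cv > 0) {
    sdlog <- sqrt(log(1 + error_cv^2))
    cmat <- cmat * exp(matrix(stats::rnorm(n * nt, 0, sdlog), n, nt) - sdlog^2 / 2)
  }
  bloq <- cmat < lloq
  data.frame(subject = rep(params_df$subject, each = nt),
             time_h = rep(schedule, n),
             conc_ng_ml = ifelse(t(bloq), NA_real_, t(cmat))[seq_len(n * nt)],
             bloq_flag = as.integer(t(bloq)),
             stringsAsFactors = FALSE)
}

#' Simulate safety outcomes
#'
#' Per-ADR Bernoulli draws with logit equal to `intercept + slope * z`, where
#' `z` is the subject's cohort-standardised log AUCinf (an `intercept` of
#' `-Inf` gives probability exactly 0). Blood pressure, heart rate and QTc
#' are drawn from the configured basal distributions plus treatment-linked
#' changes at 3 h and 6 h; the 6 h systolic fall is sex-specific and the 6 h
#' heart-rate rise depends on the trial's drug set. QTc is recorded pre-dose
#' and at 6 h only (the ECG schedule).
#'
#' @param subjects demographics data.frame (`subject`, `sex`, `trial`).
#' @param exposure data.frame `subject`, `z` (standardised log exposure).
#' @param adr_model,bp_model model components of a [cohort_config()].
#' @param trial_drugs data.frame `trial` plus logical `has_olmesartan`,
#'   `has_hctz` (used for the heart-rate trial grouping).
#' @param seed integer seed.
#' @return wide data.frame: one row per subject with ADR indicator columns
#'   and `SBP`/`DBP`/`HR` at basal, 3 h, 6 h plus `QTc_basal`, `QTc_t6`.
#' @export
simulate_safety <- function(subjects, exposure, adr_model, bp_model,
                            trial_drugs, seed = 1L) {
  n <- nrow(subjects)
  z <- exposure$z[match(subjects$subject, exposure$subject)]
  z[is.na(z)] <- 0
  set.seed(seed)

  out <- data.frame(subject = subjects$subject, stringsAsFactors = FALSE)
  for (term in names(adr_model$terms)) {
    m <- adr_model$terms[[term]]
    p <- stats::plogis(m$intercept + m$slope * z)
    out[[term]] <- as.integer(stats::runif(n) < p)
  }
  adr_cols <- names(adr_model$terms)
  out$any_adr <- as.integer(rowSums(out[, adr_cols, drop = FALSE]) > 0)

  bs <- bp_model$basal
  out$SBP_basal <- stats::rnorm(n, bs$SBP[1], bs$SBP[2])
  out$DBP_basal <- stats::rnorm(n, bs$DBP[1], bs$DBP[2])
  out$HR_basal <- stats::rnorm(n, bs$HR[1], bs$HR[2])
  out$QTc_basal <- stats::rnorm(n, bs$QTc[1], bs$QTc[2])

  ch <- bp_model$change
  sex_change <- function(spec) {
    m <- vapply(subjects$sex, function(s) spec[[s]][1], 0)
    s <- vapply(subjects$sex, function(s) spec[[s]][2], 0)
    stats::rnorm(n, m, s)
  }
  out$SBP_t3 <- out$SBP_basal + sex_change(ch$SBP_t3)
  out$SBP_t6 <- out$SBP_basal + sex_change(ch$SBP_t6)
  out$DBP_t3 <- out$DBP_basal + sex_change(ch$DBP_t3)
  out$DBP_t6 <- out$DBP_basal + sex_change(ch$DBP_t6)
  out$HR_t3 <- out$HR_basal + sex_change(ch$HR_t3)

  td <- trial_drugs[match(subjects$trial, trial_drugs$trial), ]
  hr_group <- ifelse(td$has_olmesartan, "olmesartan",
                     ifelse(td$has_hctz, "valsartan_hctz", "valsartan_only"))
  hm <- vapply(hr_group, function(g) ch$HR_t6[[g]][1], 0)
  hs <- vapply(hr_group, function(g) ch$HR_t6[[g]][2], 0)
  out$HR_t6 <- out$HR_basal + stats::rnorm(n, hm, hs)
  out$QTc_t6 <- out$QTc_basal + stats::rnorm(n, ch$QTc_t6[1], ch$QTc_t6[2])
  out
}

#' Simulate a complete synthetic cohort
#'
#' Runs every generator stage in order (demographics, genotypes,
#' genotype-to-phenotype truth, per-drug PK parameters, per-period
#' concentration profiles, safety) under the configuration's seed substreams
#' and assembles the four analysis tables. Valsartan trials use a replicated
#' crossover (periods T, R, T, R); olmesartan and hydrochlorothiazide use a
#' standard two-period T/R crossover. Identical configurations (including
#' `master_seed`) give byte-identical cohorts.
#'
#' @param config a [cohort_config()].
#' @return object of class `pk_cohort`: list with `demographics`,
#'   `genotypes`, `cyp2d6_cn`, `concentrations`, `safety` and a `truth`
#'   element (`diplotypes`, `phenotypes`, `pk_parameters`) available for
#'   recovery testing but never consumed by the analysis stages.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  demo <- sample_demographics(config)
  gen <- sample_genotypes(demo, config$variant_freqs, config$star_freqs,
                          config$cyp2d6_cn_probs,
                          seed = substream_seed(config$master_seed, "genotypes"))
  phen <- phenotype_from_diplotypes(gen$diplotypes, gen$cyp2d6_cn)

  drugs <- c("valsartan", "olmesartan", "hydrochlorothiazide")
  conc <- list(); pk_true <- list()
  for (d in seq_along(drugs)) {
    drug <- drugs[d]
    doses <- config$trials[[drug]]
    trials_with <- config$trials$trial[!is.na(doses)]
    sub <- demo[demo$trial %in% trials_with, ]
    if (!nrow(sub)) next
    pk <- assign_pk_parameters(sub, drug, gen$genotypes, phen, config,
                               seed = substream_seed(config$master_seed, "pk", d))
    pk_true[[drug]] <- pk
    dose <- doses[match(sub$trial, config$trials$trial)]
    forms <- if (drug == "valsartan") c("T", "R", "T", "R") else c("T", "R")
    sd_iov <- if (config$iov_cv > 0) sqrt(log(1 + config$iov_cv^2)) else 0
    for (p in seq_along(forms)) {
      pseed <- substream_seed(config$master_seed, "profiles", d * 10 + p)
      scale <- if (sd_iov > 0) {
        set.seed(pseed + 1L)
        exp(stats::rnorm(nrow(sub), 0, sd_iov) - sd_iov^2 / 2)
      } else NULL
      prof <- simulate_profiles(pk, dose, config$schedule,
                                config$lloq[[drug]], config$error_cv,
                                seed = pseed, period_scale = scale)
      prof$drug <- drug
      prof$period <- p
      prof$formulation <- forms[p]
      prof$dose_mg <- rep(dose, each = length(config$schedule))
      prof$weight_kg <- rep(sub$weight, each = length(config$schedule))
      conc[[paste(drug, p)]] <- prof
    }
  }
  concentrations <- do.call(rbind, c(conc, list(make.row.names = FALSE)))
  concentrations <- concentrations[, c("subject", "drug", "period", "formulation",
                                       "dose_mg", "weight_kg", "time_h",
                                       "conc_ng_ml", "bloq_flag")]

  # exposure truth for the safety model: standardised log AUCinf per drug,
  # averaged over the subject's drugs
  zs <- lapply(names(pk_true), function(drug) {
    pk <- pk_true[[drug]]
    doses <- config$trials[[drug]]
    dose <- doses[match(demo$trial[match(pk$subject, demo$subject)],
                        config$trials$trial)]
    la <- log(1000 * dose / pk$CL_F)
    data.frame(subject = pk$subject, z = as.numeric(scale(la)))
  })
  zall <- do.call(rbind, zs)
  zmean <- stats::aggregate(z ~ subject, zall, mean)

  trial_drugs <- data.frame(
    trial = config$trials$trial,
    has_olmesartan = !is.na(config$trials$olmesartan),
    has_hctz = !is.na(config$trials$hydrochlorothiazide))
  safety <- simulate_safety(demo, zmean, config$adr_model, config$bp_model,
                            trial_drugs,
                            seed = substream_seed(config$master_seed, "safety"))

  structure(list(demographics = demo, genotypes = gen$genotypes,
                 cyp2d6_cn = gen$cyp2d6_cn, concentrations = concentrations,
                 safety = safety,
                 truth = list(diplotypes = gen$diplotypes, phenotypes = phen,
                              pk_parameters = do.call(rbind, c(pk_true, list(make.row.names = FALSE))))),
            class = "pk_cohort")
}

#' @export
print.pk_cohort <- function(x, ...) {
  cat("Synthetic PK cohort:", nrow(x$demographics), "subjects,",
      length(unique(x$concentrations$drug)), "drugs,",
      nrow(x$concentrations), "concentration records\n")
  invisible(x)
}
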