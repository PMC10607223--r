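test_that("demographic sampling hits the configured moments and bounds", {
  cfg <- cohort_config(n_subjects = 10000, master_seed = 101)
  demo <- sample_demographics(cfg)
  expect_equal(nrow(demo), 10000)
  # BMI inclusion bounds and BMI identity
  expect_true(all(demo$bmi >= 18.5 & demo$bmi <= 30))
  expect_equal(demo$bmi, demo$weight / demo$height^2)
  expect_true(all(demo$age >= 18 & demo$age <= 55))
  # female weight moments match the configured cohort values within 2 SE
  w <- demo$weight[demo$sex == "female"]
  expect_lt(abs(mean(w) - 60.56), 2 * sd(w) / sqrt(length(w)))
  m <- demo$weight[demo$sex == "male"]
  expect_lt(abs(mean(m) - 78.77), 2 * sd(m) / sqrt(length(m)))

  # sex_ratio boundary: 0 gives an all-male cohort
  cfg0 <- cohort_config(n_subjects = 50, master_seed = 1, sex_ratio = 0)
  expect_true(all(sample_demographics(cfg0)$sex == "male"))

  # determinism: same seed, identical cohorts
  expect_identical(sample_demographics(cfg), demo)
  expect_error(cohort_config(n_subjects = 0), ">= 1")
})

test_that("trial assignment mirrors the configured per-trial sizes", {
  cfg <- cohort_config(master_seed = 3)
  demo <- sample_demographics(cfg)
  expect_equal(as.integer(table(demo$trial)), c(6L, 4L, 8L, 8L, 12L, 10L, 16L))
  expect_equal(sum(demo$sex == "female"), 27L)
})

test_that("genotype sampling follows Hardy-Weinberg expectations", {
  cfg <- cohort_config(n_subjects = 10000, master_seed = 5)
  demo <- sample_demographics(cfg)
  gen <- sample_genotypes(demo, cfg$variant_freqs, cfg$star_freqs,
                          cfg$cyp2d6_cn_probs, seed = 17)
  g <- gen$genotypes

  # rs34059508 heterozygote fraction near 2 p q = 0.0392 (3 SE binomial band)
  het <- mean(g$genotype[g$rsid == "rs34059508"] == "G/A")
  p_exp <- 2 * 0.98 * 0.02
  expect_lt(abs(het - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 10000))

  # tri-allelic rs2032582: all six genotype classes match multinomial HWE
  f <- cfg$variant_freqs$rs2032582
  cls <- outer(names(f), names(f), paste, sep = "/")
  expprob <- outer(f, f)
  exp6 <- diag(expprob)
  het_pairs <- which(upper.tri(expprob), arr.ind = TRUE)
  labs <- c(diag(cls), cls[het_pairs])
  probs <- c(exp6, 2 * expprob[het_pairs])
  obs <- table(factor(g$genotype[g$rsid == "rs2032582"], levels = labs))
  chi <- suppressWarnings(stats::chisq.test(as.integer(obs), p = probs))
  expect_gt(chi$p.value, 0.001)

  # degenerate frequency: an absent allele never appears
  vf <- list(rs1045642 = c(T = 1, C = 0))
  g0 <- sample_genotypes(demo[1:200, ], vf, cfg$star_freqs["CYP3A5"], seed = 2)
  expect_true(all(g0$genotypes$genotype[g0$genotypes$rsid == "rs1045642"] == "T/T"))

  # invalid frequencies are rejected
  expect_error(sample_genotypes(demo[1:5, ], list(rs1 = c(A = 0.5, B = 0.2)),
                                cfg$star_freqs["CYP3A5"], seed = 1),
               "sum to 1")
  # star-allele genotypes also follow HWE: CYP3A5 *3/*3 fraction
  dip <- gen$diplotypes
  f33 <- mean(dip$diplotype[dip$gene == "CYP3A5"] == "*3/*3")
  expect_lt(abs(f33 - 0.924^2), 3 * sqrt(0.924^2 * (1 - 0.924^2) / 10000))
})

test_that("Hardy-Weinberg goodness of fit holds across seeds", {
  # chi-square GOF on genotype counts vs HWE at n = 2000, a sweep of seeds;
  # rejections at alpha = 0.001 should be rare
  cfg <- cohort_config(n_subjects = 2000, master_seed = 9)
  demo <- sample_demographics(cfg)
  rejections <- 0L; tests <- 0L
  for (seed in 1:20) {
    gen <- sample_genotypes(demo, cfg$variant_freqs["rs1045642"],
                            cfg$star_freqs["SLCO1B1"], seed = seed)
    gg <- gen$genotypes[gen$genotypes$rsid == "rs1045642", ]
    p <- cfg$variant_freqs$rs1045642
    probs <- c("T/T" = unname(p["T"]^2), "T/C" = unname(2 * p["T"] * p["C"]),
               "C/C" = unname(p["C"]^2))
    obs <- table(factor(gg$genotype, levels = names(probs)))
    pv <- suppressWarnings(stats::chisq.test(as.integer(obs), p = probs)$p.value)
    tests <- tests + 1L
    if (pv < 0.001) rejections <- rejections + 1L
  }
  expect_lte(rejections, 1L)
})

test_that("covariate effects move PK parameters as their closed forms predict", {
  cfg <- recovery_config(200, seed = 31)
  demo <- sample_demographics(cfg)
  gen <- sample_genotypes(demo, cfg$variant_freqs, cfg$star_freqs,
                          cfg$cyp2d6_cn_probs, seed = 7)

  # all effects at 1: parameters are independent of genotype (identical to a
  # genotype-free assignment under the same seed)
  null_cfg <- null_effects(cfg)
  pk_null <- assign_pk_parameters(demo, "valsartan", gen$genotypes, NULL,
                                  null_cfg, seed = 5)
  pk_nogeno <- assign_pk_parameters(demo, "valsartan", NULL, NULL, null_cfg,
                                    seed = 5)
  expect_identical(pk_null, pk_nogeno)

  # ABCB1 rs1045642 T/T ka x 0.5 -> higher median model tmax in T/T
  phen <- pkpgx:::phenotype_from_diplotypes(gen$diplotypes, gen$cyp2d6_cn)
  pk <- assign_pk_parameters(demo, "valsartan", gen$genotypes, phen, cfg, seed = 5)
  gg <- gen$genotypes[gen$genotypes$rsid == "rs1045642", ]
  tt <- gg$genotype[match(pk$subject, gg$subject)] == "T/T"
  tmax_model <- log(pk$ka / pk$ke) / (pk$ka - pk$ke)
  expect_gt(median(tmax_model[tt]), median(tmax_model[!tt]))

  # SLC22A1 G/A CL x 0.76 -> mean AUCinf/DW ratio approaches 1/0.76
  cfg_h <- recovery_config(5000, seed = 33, drug = "hydrochlorothiazide",
                           dose = 25)
  demo_h <- sample_demographics(cfg_h)
  gen_h <- sample_genotypes(demo_h, cfg_h$variant_freqs, cfg_h$star_freqs,
                            cfg_h$cyp2d6_cn_probs, seed = 11)
  pk_h <- assign_pk_parameters(demo_h, "hydrochlorothiazide", gen_h$genotypes,
                               NULL, cfg_h, seed = 13)
  auc_dw <- (1000 * 25 / pk_h$CL_F) * demo_h$weight / 25
  ga <- gen_h$genotypes$genotype[gen_h$genotypes$rsid == "rs34059508"][
    match(pk_h$subject, gen_h$genotypes$subject[gen_h$genotypes$rsid == "rs34059508"])]
  sexes <- demo_h$sex[match(pk_h$subject, demo_h$subject)]
  male <- sexes == "male"
  ratio <- mean(auc_dw[male & ga == "G/A"]) / mean(auc_dw[male & ga == "G/G"])
  expect_equal(ratio, 1 / 0.76, tolerance = 0.1)

  expect_error(assign_pk_parameters(demo, "aspirin", NULL, NULL, cfg, 1),
               "unknown drug")
  # an active phenotype effect without phenotypes is an error
  expect_error(assign_pk_parameters(demo, "valsartan", gen$genotypes, NULL,
                                    cfg, 1), "phenotypes")
})

test_that("profile simulation honours the model, LLOQ and lag", {
  params <- data.frame(subject = "S1", CL_F = 5.85, V_F = 73.4, ka = 0.73,
                       tlag = 0.5)
  sched <- c(0, 0.5, 1, 2, 4, 8, 12, 24, 48)

  # zero dose: everything below the limit of quantification
  p0 <- simulate_profile(params, 0, sched, lloq = 20.02, error_cv = 0.15, seed = 1)
  expect_true(all(p0$bloq_flag == 1))

  # pre-dose and pre-lag samples are exactly zero before error
  pf <- simulate_profile(params, 160, sched, lloq = 20.02, error_cv = 0, seed = 1)
  expect_equal(pf$bloq_flag[pf$time_h <= 0.5], c(1, 1))

  # noise-free dense profile: trapezoidal AUC within 1% of D/CL
  dense <- c(0, seq(0.1, 300, by = 0.1))
  pd <- simulate_profile(params, 160, dense, lloq = 0, error_cv = 0, seed = 1)
  auc <- sum(diff(pd$time_h) * (head(pd$conc_ng_ml, -1) + tail(pd$conc_ng_ml, -1)) / 2)
  expect_equal(auc, oracle_auc_inf(160, 5.85), tolerance = 0.01)

  # model linearity: doubling the dose exactly doubles noise-free concentrations
  p1 <- simulate_profile(params, 160, sched, lloq = 0, error_cv = 0, seed = 1)
  p2 <- simulate_profile(params, 320, sched, lloq = 0, error_cv = 0, seed = 1)
  expect_equal(p2$conc_ng_ml, 2 * p1$conc_ng_ml)

  # guards
  expect_error(simulate_profile(params, 160, c(0, -1, 2), 1, 0, 1), "negative")
  expect_error(simulate_profile(params, 160, c(1, 2, 3), 1, 0, 1), "start at 0")
  bad <- params; bad$ka <- bad$CL_F / bad$V_F
  expect_error(simulate_profile(bad, 160, sched, 1, 0, 1), "ka equals ke")
})

test_that("safety simulation links ADRs to exposure and matches the BP model", {
  cfg <- cohort_config(n_subjects = 1000, master_seed = 77)
  demo <- sample_demographics(cfg)
  z <- data.frame(subject = demo$subject, z = rnorm(nrow(demo)))
  td <- data.frame(trial = 1:7, has_olmesartan = c(F, F, F, F, T, T, T),
                   has_hctz = c(F, T, T, T, T, T, T))

  # probability-zero sentinel: no ADRs at all
  m0 <- list(terms = list(headache = list(intercept = -Inf, slope = 0)))
  s0 <- simulate_safety(demo, z, m0, cfg$bp_model, td, seed = 3)
  expect_equal(sum(s0$headache), 0L)

  # positive slope: mean exposure is higher in the ADR-positive group
  m1 <- list(terms = list(headache = list(intercept = 0, slope = 1)))
  s1 <- simulate_safety(demo, z, m1, cfg$bp_model, td, seed = 3)
  expect_gt(mean(z$z[s1$headache == 1]), mean(z$z[s1$headache == 0]))

  # configured mean SBP change at 6 h is recovered within 3 SE
  s2 <- simulate_safety(demo, z, cfg$adr_model, cfg$bp_model, td, seed = 9)
  men <- demo$sex == "male"
  d6 <- s2$SBP_t6[men] - s2$SBP_basal[men]
  expect_lt(abs(mean(d6) - (-3.57)), 3 * sd(d6) / sqrt(length(d6)))
  d6f <- s2$SBP_t6[!men] - s2$SBP_basal[!men]
  expect_lt(abs(mean(d6f) - (-10.91)), 3 * sd(d6f) / sqrt(length(d6f)))
})

test_that("the full cohort is deterministic and dose-linear", {
  cfg <- cohort_config(n_subjects = 16, master_seed = 2024)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1, c2)
  # different seed changes the draw
  c3 <- simulate_cohort(cohort_config(n_subjects = 16, master_seed = 2025))
  expect_false(identical(c1$concentrations, c3$concentrations))
  # schema of the concentration table
  expect_named(c1$concentrations,
               c("subject", "drug", "period", "formulation", "dose_mg",
                 "weight_kg", "time_h", "conc_ng_ml", "bloq_flag"))
  # every subject appears for every drug of their trial
  tr <- cfg$trials
  for (drug in c("valsartan", "olmesartan", "hydrochlorothiazide")) {
    expected <- c1$demographics$subject[
      c1$demographics$trial %in% tr$trial[!is.na(tr[[drug]])]]
    got <- unique(c1$concentrations$subject[c1$concentrations$drug == drug])
    expect_setequal(got, expected)
  }
  # valsartan is a replicated four-period crossover, the others two-period
  per <- tapply(c1$concentrations$period, c1$concentrations$drug, max)
  expect_equal(per[["valsartan"]], 4L)
  expect_equal(per[["hydrochlorothiazide"]], 2L)
})
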