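# Independent oracles used across the suite. These are deliberately written
# from first principles (closed forms / brute-force enumeration), not via the
# package's own code paths.

# closed-form one-compartment oral model, ng/mL for dose mg, V litres
oracle_conc <- function(t, dose, CL, V, ka, tlag = 0) {
  ke <- CL / V
  tt <- pmax(t - tlag, 0)
  out <- 1000 * dose / V * ka / (ka - ke) * (exp(-ke * tt) - exp(-ka * tt))
  out[t <= tlag] <- 0
  out
}

oracle_auc_inf <- function(dose, CL) 1000 * dose / CL

oracle_tmax <- function(CL, V, ka, tlag = 0) {
  ke <- CL / V
  log(ka / ke) / (ka - ke) + tlag
}

# analytic AUC from 0 to upper limit T (integral of the model)
oracle_auc_t <- function(Tend, dose, CL, V, ka, tlag = 0) {
  ke <- CL / V
  Tt <- max(Tend - tlag, 0)
  1000 * dose / V * ka / (ka - ke) *
    ((1 - exp(-ke * Tt)) / ke - (1 - exp(-ka * Tt)) / ka)
}

# brute-force two-sided Fisher exact p for a 2x2 table: enumerate every table
# with the observed margins and sum the probabilities of those no more likely
# than the observed one
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(support, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# single-drug cohort configuration used by recovery / calibration studies:
# every subject in one trial, one T and one R period simulated downstream
recovery_config <- function(n, seed, drug = "valsartan", dose = 160,
                            error_cv = 0.15) {
  cfg <- cohort_config(n_subjects = n, master_seed = seed, error_cv = error_cv)
  cfg$trials <- data.frame(trial = 1L, n = n,
                           valsartan = NA_real_, olmesartan = NA_real_,
                           hydrochlorothiazide = NA_real_)
  cfg$trials[[drug]] <- dose
  cfg
}

# simulate a single-drug cohort and return the aggregated NCA table merged
# with demographics, genotypes (wide, selected rsids) and phenotypes
simulate_and_analyse <- function(cfg, drug, rsids = character(),
                                 genes = character()) {
  demo <- sample_demographics(cfg)
  gen <- sample_genotypes(demo, cfg$variant_freqs, cfg$star_freqs,
                          cfg$cyp2d6_cn_probs,
                          seed = cfg$master_seed + 1L)
  phen <- if (length(genes)) {
    tr <- pkpgx:::phenotype_from_diplotypes(gen$diplotypes, gen$cyp2d6_cn)
    tr[tr$gene %in% genes, ]
  } else NULL
  pk <- assign_pk_parameters(demo, drug, gen$genotypes, phen, cfg,
                             seed = cfg$master_seed + 2L)
  dose <- cfg$trials[[drug]][1]
  prof <- pkpgx:::simulate_profiles(pk, rep(dose, nrow(demo)), cfg$schedule,
                                    cfg$lloq[[drug]], cfg$error_cv,
                                    seed = cfg$master_seed + 3L)
  prof$drug <- drug; prof$period <- 1L; prof$formulation <- "R"
  prof$dose_mg <- dose
  prof$weight_kg <- demo$weight[match(prof$subject, demo$subject)]
  res <- nca_table(prof[c("subject", "drug", "period", "formulation",
                          "dose_mg", "weight_kg", "time_h", "conc_ng_ml",
                          "bloq_flag")], policy = "reference_only")
  out <- merge(res, demo, by = "subject")
  for (rs in rsids) {
    g <- gen$genotypes[gen$genotypes$rsid == rs, c("subject", "genotype")]
    names(g)[2] <- rs
    out <- merge(out, g, by = "subject")
  }
  if (!is.null(phen)) {
    for (ge in genes) {
      p <- phen[phen$gene == ge, c("subject", "phenotype")]
      names(p)[2] <- ge
      out <- merge(out, p, by = "subject")
    }
  }
  attr(out, "pk_truth") <- pk
  out
}
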