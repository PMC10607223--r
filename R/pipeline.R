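CONC_COLS <- c("subject", "drug", "period", "formulation", "dose_mg",
               "weight_kg", "time_h", "conc_ng_ml", "bloq_flag")
DEMO_COLS <- c("subject", "sex", "age", "height", "weight", "bmi", "trial", "origin")
GENO_COLS <- c("subject", "rsid", "allele1", "allele2", "genotype")

#' Read and validate the four analysis tables
#'
#' Tab-separated tables with fixed schemas (dot decimal separators, times in
#' hours, concentrations in ng/mL). Validation errors name the offending
#' file, missing columns, or the line numbers of duplicated
#' subject-drug-period-time rows.
#'
#' @param paths named list/vector with elements `concentrations`,
#'   `demographics`, `genotypes`, `safety` and optionally `cyp2d6_cn`.
#' @return list of validated data.frames (class `pk_dataset`).
#' @export
read_tables <- function(paths) {
  need <- c("concentrations", "demographics", "genotypes", "safety")
  miss <- setdiff(need, names(paths))
  if (length(miss)) stop("missing table path(s): ", paste(miss, collapse = ", "))
  rd <- function(name, required_cols = NULL) {
    f <- paths[[name]]
    if (is.null(f) || !file.exists(f)) stop("file not found for ", name, ": ", f)
    tab <- utils::read.delim(f, stringsAsFactors = FALSE)
    if (!nrow(tab)) stop("empty ", name, " table: ", f, " (no data rows)")
    if (!is.null(required_cols)) {
      mc <- setdiff(required_cols, names(tab))
      if (length(mc)) stop(name, " table ", f, " is missing column(s): ",
                           paste(mc, collapse = ", "))
    }
    tab
  }
  conc <- rd("concentrations", CONC_COLS)
  key <- do.call(paste, c(conc[c("subject", "drug", "period", "formulation", "time_h")],
                          sep = "\r"))
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate concentration rows (subject x drug x period x time) at line(s): ",
         paste(dup + 1L, collapse = ", "))
  }
  out <- list(concentrations = conc,
              demographics = rd("demographics", DEMO_COLS),
              genotypes = rd("genotypes", GENO_COLS),
              safety = rd("safety", c("subject")))
  if (!is.null(paths$cyp2d6_cn) && file.exists(paths$cyp2d6_cn)) {
    out$cyp2d6_cn <- rd("cyp2d6_cn", c("subject", "cn"))
  }
  structure(out, class = "pk_dataset")
}

#' Write a cohort's tables to a directory
#' @param cohort a `pk_cohort` (or `pk_dataset`) list of tables.
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_tables <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("concentrations", "demographics", "genotypes", "safety", "cyp2d6_cn")
  paths <- character()
  for (t in tabs) {
    if (is.null(cohort[[t]])) next
    f <- file.path(dir, paste0(t, ".tsv"))
    utils::write.table(format_num_df(cohort[[t]]), f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[t] <- f
  }
  invisible(paths)
}

# fixed-precision numeric formatting so that equal seeds give byte-identical
# files regardless of platform printing defaults
format_num_df <- function(d) {
  for (cc in names(d)) {
    if (is.double(d[[cc]])) {
      y <- trimws(formatC(d[[cc]], digits = 10, format = "g"))
      y[is.na(d[[cc]])] <- "NA"
      d[[cc]] <- y
    }
  }
  d
}

# outcomes and predictors of the association battery
PK_OUTCOMES <- c("AUCinf_dw", "Cmax_dw", "tmax", "t_half")
TRANSPORTER_RSIDS <- c("rs1045642", "rs2032582", "rs1128503", "rs2273697",
                       "rs2231142", "rs12208357", "rs34059508", "rs72552763")
VALSARTAN_GENES <- c("CYP2A6", "CYP2B6", "CYP2C8", "CYP2C9", "CYP2C19",
                     "CYP2D6", "CYP3A4", "CYP3A5", "UGT1A1")

#' Build the merged subject-level analysis table
#'
#' One row per subject and drug: aggregated NCA parameters joined with
#' demographics, transporter genotypes (wide), gene phenotypes (wide) and
#' the merged predictor codings of [default_group_rules()].
#'
#' @param nca_results output of [nca_table()].
#' @param demographics,genotypes,phenotypes the corresponding tables.
#' @return data.frame.
#' @export
build_analysis_table <- function(nca_results, demographics, genotypes, phenotypes) {
  d <- merge(nca_results, demographics, by = "subject")
  d$trial <- factor(d$trial)
  for (rs in intersect(TRANSPORTER_RSIDS, unique(genotypes$rsid))) {
    g <- genotypes[genotypes$rsid == rs, c("subject", "genotype")]
    names(g)[2] <- rs
    d <- merge(d, g, by = "subject", all.x = TRUE)
  }
  for (gene in unique(phenotypes$gene)) {
    p <- phenotypes[phenotypes$gene == gene, c("subject", "phenotype")]
    names(p)[2] <- gene
    d <- merge(d, p, by = "subject", all.x = TRUE)
  }
  rules <- default_group_rules()
  rules <- Filter(function(r) r$column %in% names(d), rules)
  d <- analysis_groups(d, rules)
  d[order(d$drug, d$subject), ]
}

#' Run the full analysis pipeline
#'
#' Chains the stages in order: simulate (or read) the cohort tables, NCA
#' with per-drug crossover aggregation, genotype-to-phenotype translation,
#' the per-drug association battery (PK outcomes against sex, origin,
#' trial, transporter genotypes, merged codings and -- for valsartan --
#' metabolising-enzyme phenotypes), paired pharmacodynamic tests and ADR
#' incidence tests. Writes one TSV per stage plus a text report whose
#' tables are formatted as mean (standard deviation); every number in the
#' report is recomputable from the stage TSVs. Fully deterministic given
#' the configuration seed.
#'
#' @param config a [cohort_config()] (simulated input), or a `pk_dataset`
#'   from [read_tables()].
#' @param out_dir output directory; `NULL` skips file output.
#' @param alpha univariate screening level.
#' @return list (class `pk_report`) with `nca`, `phenotypes`,
#'   `associations` (tidy data.frame), `pd_tests`, `incidence`, `tables`
#'   (file paths) -- invisibly when writing.
#' @export
run_pipeline <- function(config, out_dir = NULL, alpha = 0.05) {
  t0 <- Sys.time()
  if (inherits(config, "cohort_config")) {
    cohort <- simulate_cohort(config)
    log_stage("simulate", sprintf("n=%d seed=%d", nrow(cohort$demographics),
                                  config$master_seed))
  } else if (inherits(config, c("pk_dataset", "pk_cohort"))) {
    cohort <- config
    log_stage("read", sprintf("n=%d", length(unique(cohort$demographics$subject))))
  } else stop("config must be a cohort_config or a pk_dataset")

  nca_res <- nca_table(cohort$concentrations)
  log_stage("nca", sprintf("profiles=%d evaluable=%d excluded=%d",
                           nrow(attr(nca_res, "per_period")) + nrow(attr(nca_res, "non_evaluable")),
                           nrow(attr(nca_res, "per_period")),
                           nrow(attr(nca_res, "non_evaluable"))))

  phen <- pgx_table(cohort$genotypes, cohort$cyp2d6_cn)
  log_stage("pgx", sprintf("assignments=%d indeterminate=%d", nrow(phen),
                           sum(phen$indeterminate)))

  at <- build_analysis_table(nca_res, cohort$demographics, cohort$genotypes, phen)
  merged_cols <- c("rs1045642_TT", "rs1128503_TT", "rs2032582_TT",
                   "SLCO1B1_func", "CYP2D6_PM")
  assoc_rows <- list(); cascades <- list()
  for (drug in unique(at$drug)) {
    dd <- at[at$drug == drug, ]
    preds <- c("sex", "origin", "trial", TRANSPORTER_RSIDS, "SLCO1B1",
               intersect(merged_cols, names(dd)))
    if (drug == "valsartan") preds <- c(preds, VALSARTAN_GENES)
    preds <- intersect(preds, names(dd))
    for (oc in PK_OUTCOMES) {
      cs <- assoc_cascade(dd, oc, preds, alpha = alpha)
      cascades[[paste(drug, oc)]] <- cs
      s <- summary(cs)
      if (nrow(s)) { s$drug <- drug; assoc_rows[[paste(drug, oc)]] <- s }
    }
  }
  associations <- do.call(rbind, c(assoc_rows, list(make.row.names = FALSE)))
  associations <- associations[c("drug", setdiff(names(associations), "drug"))]
  log_stage("associate", sprintf("tests=%d selected=%d", nrow(associations),
                                 sum(associations$selected)))

  saf <- cohort$safety
  pd <- list(
    SBP_t3 = paired_change(saf$SBP_basal, saf$SBP_t3),
    SBP_t6 = paired_change(saf$SBP_basal, saf$SBP_t6),
    DBP_t3 = paired_change(saf$DBP_basal, saf$DBP_t3),
    DBP_t6 = paired_change(saf$DBP_basal, saf$DBP_t6),
    HR_t3 = paired_change(saf$HR_basal, saf$HR_t3),
    HR_t6 = paired_change(saf$HR_basal, saf$HR_t6),
    QTc_t6 = paired_change(saf$QTc_basal, saf$QTc_t6))
  pd_tests <- data.frame(measure = names(pd),
                         mean_change = vapply(pd, `[[`, 0, "mean_change"),
                         sd_change = vapply(pd, `[[`, 0, "sd_change"),
                         p = vapply(pd, `[[`, 0, "p"),
                         n = vapply(pd, `[[`, 0L, "n"), row.names = NULL)

  incid <- incidence_battery(saf, cohort$demographics, cohort$genotypes)
  log_stage("safety", sprintf("pd_tests=%d incidence_tests=%d", nrow(pd_tests),
                              nrow(incid)))

  out <- structure(list(nca = nca_res, phenotypes = phen, analysis_table = at,
                        associations = associations, cascades = cascades,
                        pd_tests = pd_tests, incidence = incid,
                        non_evaluable = attr(nca_res, "non_evaluable")),
                   class = "pk_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(d, f) utils::write.table(
      format_num_df(d), file.path(out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wr(as.data.frame(nca_res), "nca_results.tsv")
    wr(phen, "phenotypes.tsv")
    wr(associations, "associations.tsv")
    wr(pd_tests, "pd_tests.tsv")
    wr(incid, "safety_incidence.tsv")
    writeLines(render_report(out), file.path(out_dir, "report.txt"))
    out$tables <- file.path(out_dir, c("nca_results.tsv", "phenotypes.tsv",
                                       "associations.tsv", "pd_tests.tsv",
                                       "safety_incidence.tsv", "report.txt"))
    log_stage("report", sprintf("dir=%s elapsed=%.1fs", out_dir,
                                as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    return(invisible(out))
  }
  out
}

log_stage <- function(stage, msg) {
  message(sprintf("[pkpgx] %-10s %s", stage, msg))
}

# ADR incidence versus sex, origin, pharmacotherapy size and the merged
# transporter-genotype groups
incidence_battery <- function(safety, demographics, genotypes) {
  d <- merge(safety, demographics, by = "subject")
  rows <- list()
  add <- function(label, event, group) {
    ok <- !is.na(event) & !is.na(group)
    tab <- table(factor(event[ok], levels = c(1, 0)), group[ok])
    if (ncol(tab) < 2) return()
    r <- incidence_test(as.matrix(tab))
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = label, test = r$test, p = r$p,
      counts = paste(apply(tab, 2, paste, collapse = "/"), collapse = ", "),
      stringsAsFactors = FALSE)
  }
  adr_terms <- intersect(c("any_adr", "headache", "dizziness",
                           "postural_dizziness", "nausea"), names(d))
  for (term in adr_terms) {
    add(paste0(term, " ~ sex"), d[[term]], d$sex)
    add(paste0(term, " ~ origin"), d[[term]], d$origin)
  }
  for (rs in c("rs1045642", "rs34059508")) {
    g <- genotypes[genotypes$rsid == rs, c("subject", "genotype")]
    gg <- g$genotype[match(d$subject, g$subject)]
    if (all(is.na(gg))) next
    for (term in adr_terms) add(paste0(term, " ~ ", rs), d[[term]], gg)
  }
  if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE))) else
    data.frame(comparison = character(), test = character(), p = numeric(),
               counts = character())
}

#' @export
print.pk_report <- function(x, ...) {
  cat("pkpgx analysis report\n")
  cat(sprintf("  NCA: %d subject-drug results (%d profiles excluded)\n",
              nrow(x$nca), nrow(x$non_evaluable)))
  cat(sprintf("  associations screened: %d (selected: %d)\n",
              nrow(x$associations), sum(x$associations$selected)))
  sel <- x$associations[x$associations$selected, ]
  for (i in seq_len(nrow(sel))) {
    cat(sprintf("   %-20s %-12s %-16s p_uv=%.4g p_mv=%s\n", sel$drug[i],
                sel$outcome[i], sel$predictor[i], sel$p_uv[i],
                ifelse(is.na(sel$p_mv[i]), "-", sprintf("%.4g", sel$p_mv[i]))))
  }
  invisible(x)
}

# plain-text report: per-drug descriptive tables as mean (SD), then the
# association, pharmacodynamic and incidence summaries
render_report <- function(report) {
  fmt <- function(m, s) sprintf("%s (%s)", format(m, digits = 6), format(s, digits = 4))
  lines <- c("Pharmacokinetic / pharmacogenetic analysis report",
             strrep("=", 50), "")
  at <- report$analysis_table
  for (drug in unique(at$drug)) {
    dd <- at[at$drug == drug, ]
    lines <- c(lines, sprintf("%s (n = %d)", drug, nrow(dd)), strrep("-", 40))
    for (oc in PK_OUTCOMES) {
      lines <- c(lines, sprintf("  %s", oc))
      for (g in c("sex")) {
        for (l in unique(dd[[g]])) {
          v <- dd[[oc]][dd[[g]] == l]
          lines <- c(lines, sprintf("    %-10s n=%-3d %s", l, length(v),
                                    fmt(mean(v), stats::sd(v))))
        }
      }
    }
    lines <- c(lines, "")
  }
  lines <- c(lines, "Selected associations (p_uv < alpha)", strrep("-", 40))
  sel <- report$associations[report$associations$selected, ]
  if (nrow(sel)) {
    for (i in seq_len(nrow(sel))) {
      lines <- c(lines, sprintf("  %-20s %-12s %-18s p_uv=%.4g beta=%s p_mv=%s R2=%s",
                                sel$drug[i], sel$outcome[i], sel$predictor[i], sel$p_uv[i],
                                ifelse(is.na(sel$beta[i]), "-", sprintf("%.4g", sel$beta[i])),
                                ifelse(is.na(sel$p_mv[i]), "-", sprintf("%.4g", sel$p_mv[i])),
                                ifelse(is.na(sel$r_squared[i]), "-", sprintf("%.3f", sel$r_squared[i]))))
    }
  } else lines <- c(lines, "  none")
  lines <- c(lines, "", "Paired pharmacodynamic changes (mean (SD), paired t-test)",
             strrep("-", 40))
  pd <- report$pd_tests
  for (i in seq_len(nrow(pd))) {
    lines <- c(lines, sprintf("  %-8s %s  p=%.4g  n=%d", pd$measure[i],
                              fmt(pd$mean_change[i], pd$sd_change[i]), pd$p[i], pd$n[i]))
  }
  lines <- c(lines, "", "ADR incidence tests", strrep("-", 40))
  inc <- report$incidence
  for (i in seq_len(nrow(inc))) {
    lines <- c(lines, sprintf("  %-34s %-7s p=%.4g  [%s]", inc$comparison[i],
                              inc$test[i], inc$p[i], inc$counts[i]))
  }
  lines
}
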