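# cached fixture loader: PharmVar-style allele definitions, per-variant
# reference/alternate alleles, and the per-allele function/activity table
pgx_env <- new.env(parent = emptyenv())

#' Bundled pharmacogene tables
#'
#' Loads (and caches) the bundled allele-definition, variant and
#' allele-function fixtures. The reference allele (`*1`) of every gene is
#' defined implicitly as the absence of all defining variants.
#' @return list `definitions` (gene, allele, rsid, variant_allele),
#'   `variants` (rsid, gene, ref_allele, alt_alleles) and `functions`
#'   (gene, allele, activity, function_class).
#' @export
pgx_definitions <- function() {
  if (!is.null(pgx_env$defs)) return(pgx_env$defs)
  read_fix <- function(f) utils::read.delim(
    system.file("extdata", f, package = "pkpgx", mustWork = TRUE),
    comment.char = "#", stringsAsFactors = FALSE)
  defs <- list(definitions = read_fix("allele_definitions.tsv"),
               variants = read_fix("variants.tsv"),
               functions = read_fix("allele_function.tsv"))
  pgx_env$defs <- defs
  defs
}

# CYP2D6 activity-score cut-offs (CPIC-style): 0 -> PM, (0, 1] -> IM,
# (1, 2.25] -> NM, > 2.25 -> UM
cyp2d6_bins <- function(score) {
  ifelse(score == 0, "PM",
         ifelse(score <= 1, "IM", ifelse(score <= 2.25, "NM", "UM")))
}

#' Call a star-allele diplotype from variant genotypes
#'
#' Enumerates all unordered pairs of the gene's defined star alleles (plus
#' the implicit reference `*1`) and keeps the pairs whose summed
#' variant-allele counts match the observed genotype at every defining
#' locus. Because phase is unknown, several pairs can be consistent; the
#' nesting rule prefers the pair containing the allele defined by the most
#' variants (then the largest total), and any remaining alternatives are
#' reported with an `ambiguous` flag. Combinations matching no pair are
#' `"indeterminate"`. For CYP2D6 a copy number of 1 calls the retained
#' haplotype against the deletion allele `*5`; copy number 0 is `*5/*5`.
#'
#' @param gene gene symbol present in the bundled definitions.
#' @param calls data.frame `rsid`, `allele1`, `allele2` covering the gene's
#'   defining variants (absent rows are taken as homozygous reference; `NA`
#'   alleles make the call indeterminate).
#' @param definitions optional [pgx_definitions()] list.
#' @param copy_number gene copy number (CYP2D6 only; default 2).
#' @return list `gene`, `allele1`, `allele2`, `diplotype`, `ambiguous`,
#'   `alternatives` (character vector), `indeterminate`.
#' @export
#' @examples
#' calls <- data.frame(rsid = c("rs3892097", "rs1065852"),
#'                     allele1 = c("G", "C"), allele2 = c("A", "T"))
#' call_diplotype("CYP2D6", calls)$diplotype
call_diplotype <- function(gene, calls, definitions = pgx_definitions(),
                           copy_number = 2L) {
  defs <- definitions$definitions[definitions$definitions$gene == gene, ]
  if (!nrow(defs)) stop("no allele definitions for gene ", gene)
  vars <- definitions$variants[definitions$variants$gene == gene, ]
  rsids <- unique(defs$rsid)

  res <- function(a1 = NA, a2 = NA, ambiguous = FALSE, alternatives = character(),
                  indeterminate = FALSE) {
    list(gene = gene, allele1 = a1, allele2 = a2,
         diplotype = if (indeterminate) NA_character_ else paste0(a1, "/", a2),
         ambiguous = ambiguous, alternatives = alternatives,
         indeterminate = indeterminate)
  }
  if (copy_number == 0) return(res("*5", "*5"))

  # observed count of each defining variant allele
  obs <- stats::setNames(integer(length(rsids)), rsids)
  for (rs in rsids) {
    row <- calls[calls$rsid == rs, , drop = FALSE]
    ref <- vars$ref_allele[vars$rsid == rs]
    if (!nrow(row)) next                      # absent -> homozygous reference
    al <- c(row$allele1[1], row$allele2[1])
    if (anyNA(al)) return(res(indeterminate = TRUE))
    valid <- c(ref, strsplit(vars$alt_alleles[vars$rsid == rs], ",")[[1]])
    if (!all(al %in% valid)) stop("allele not in the defined set for ", rs)
    obs[rs] <- sum(al != ref)
  }

  star <- unique(defs$allele)
  nvar <- vapply(star, function(s) sum(defs$allele == s), 0L)
  count_of <- function(s, rs) {
    if (s == "*1") 0L else sum(defs$allele == s & defs$rsid == rs)
  }
  hap_counts <- vapply(rsids, function(rs)
    vapply(c("*1", star), count_of, 0L, rs = rs), integer(length(star) + 1L))
  if (length(rsids) == 1L) hap_counts <- matrix(hap_counts, ncol = 1L,
                                                dimnames = list(c("*1", star), rsids))
  haps <- rownames(hap_counts)

  if (copy_number == 1) {
    hit <- haps[apply(hap_counts, 1, function(h) all(2L * h == obs))]
    if (!length(hit)) return(res(indeterminate = TRUE))
    sc <- nvar[hit]; sc[is.na(sc)] <- 0L
    pick <- hit[order(-sc, hit)][1]
    return(res(pick, "*5", ambiguous = length(hit) > 1,
               alternatives = setdiff(paste0(hit, "/*5"), paste0(pick, "/*5"))))
  }

  pairs <- which(upper.tri(matrix(0, length(haps), length(haps)), diag = TRUE),
                 arr.ind = TRUE)
  consistent <- apply(pairs, 1, function(ij)
    all(hap_counts[ij[1], ] + hap_counts[ij[2], ] == obs))
  if (!any(consistent)) return(res(indeterminate = TRUE))
  cand <- pairs[consistent, , drop = FALSE]
  nv <- function(h) if (h == "*1") 0L else nvar[[h]]
  score_max <- apply(cand, 1, function(ij) max(nv(haps[ij[1]]), nv(haps[ij[2]])))
  score_tot <- apply(cand, 1, function(ij) nv(haps[ij[1]]) + nv(haps[ij[2]]))
  lab <- apply(cand, 1, function(ij) {
    a <- haps[sort(ij)]
    paste0(a[1], "/", a[2])
  })
  ord <- order(-score_max, -score_tot, lab)
  best <- cand[ord[1], ]
  a <- haps[sort(best)]
  res(a[1], a[2], ambiguous = length(unique(lab)) > 1,
      alternatives = setdiff(unique(lab), paste0(a[1], "/", a[2])))
}

#' CYP2D6 phenotype from diplotype and copy number
#'
#' The activity score sums the per-allele activity values of the gene
#' copies: with the usual two copies it is the sum over the diplotype; a
#' duplication (copy number > 2) counts the higher-activity allele once per
#' extra copy; with one copy, the retained (non-`*5`) allele contributes
#' alone; zero copies score 0. Categories use CPIC-style cut-offs: 0 poor
#' metaboliser (PM), (0, 1] intermediate (IM), (1, 2.25] normal (NM),
#' above 2.25 ultrarapid (UM).
#'
#' @param diplotype string `"*x/*y"` or a list from [call_diplotype()].
#' @param copy_number non-negative integer (default 2).
#' @return list `gene`, `diplotype`, `activity_score`, `phenotype`.
#' @export
#' @examples
#' cyp2d6_phenotype("*4/*4")$phenotype        # "PM"
#' cyp2d6_phenotype("*1/*1", 3)$phenotype     # "UM"
cyp2d6_phenotype <- function(diplotype, copy_number = 2L) {
  if (is.list(diplotype)) diplotype <- diplotype$diplotype
  if (copy_number < 0 || copy_number != round(copy_number)) {
    stop("copy_number must be a non-negative integer")
  }
  if (is.na(diplotype)) {
    return(list(gene = "CYP2D6", diplotype = NA_character_,
                activity_score = NA_real_, phenotype = "indeterminate"))
  }
  al <- strsplit(diplotype, "/", fixed = TRUE)[[1]]
  fn <- pgx_definitions()$functions
  act <- function(a) {
    v <- fn$activity[fn$gene == "CYP2D6" & fn$allele == a]
    if (!length(v) || is.na(v)) stop("unknown CYP2D6 allele activity: ", a)
    v
  }
  score <- if (copy_number == 0) 0 else if (copy_number == 1) {
    kept <- setdiff(al, "*5")
    if (!length(kept)) 0 else act(kept[1])
  } else {
    a1 <- act(al[1]); a2 <- act(al[2])
    a1 + a2 + (copy_number - 2) * max(a1, a2)
  }
  list(gene = "CYP2D6", diplotype = diplotype, activity_score = score,
       phenotype = cyp2d6_bins(score))
}

#' Function-class phenotype for non-CYP2D6 genes
#'
#' Combines the two alleles' bundled function classes into the gene's
#' phenotype convention: transporter function NF/DF/PF for SLCO1B1 (none /
#' one / two decreased- or no-function alleles) and metaboliser categories
#' (PM/IM/NM/RM/UM) for the CYP genes and UGT1A1 from the unordered pair of
#' function classes (two deficient alleles PM, one IM, two normal NM,
#' increased-function alleles shift towards RM/UM); CYP2C9 uses its bundled
#' numeric activity values (2 NM, 1-1.5 IM, below 1 PM).
#'
#' @param gene gene symbol (not CYP2D6; see [cyp2d6_phenotype()]).
#' @param diplotype string `"*x/*y"` or [call_diplotype()] result.
#' @return list `gene`, `diplotype`, `phenotype`.
#' @export
#' @examples
#' function_phenotype("SLCO1B1", "*5/*15")$phenotype  # "PF"
#' function_phenotype("CYP3A5", "*3/*3")$phenotype    # "PM"
function_phenotype <- function(gene, diplotype) {
  if (is.list(diplotype)) diplotype <- diplotype$diplotype
  if (is.na(diplotype)) {
    return(list(gene = gene, diplotype = NA_character_, phenotype = "indeterminate"))
  }
  fn <- pgx_definitions()$functions
  fg <- fn[fn$gene == gene, ]
  if (!nrow(fg)) stop("no function table for gene ", gene)
  al <- strsplit(diplotype, "/", fixed = TRUE)[[1]]
  cls <- vapply(al, function(a) {
    v <- fg$function_class[fg$allele == a]
    if (!length(v)) stop("allele ", a, " absent from the ", gene, " function table")
    v
  }, "")
  if (gene == "SLCO1B1") {
    n_bad <- sum(cls %in% c("decreased", "no"))
    phen <- c("NF", "DF", "PF")[n_bad + 1L]
  } else if (gene == "CYP2C9") {
    score <- sum(vapply(al, function(a) fg$activity[fg$allele == a], 0))
    phen <- if (score >= 2) "NM" else if (score >= 1) "IM" else "PM"
  } else {
    # metaboliser category from the unordered pair of function classes
    key <- paste(sort(cls), collapse = "+")
    phen <- switch(key,
      "no+no" = "PM",
      "decreased+no" = "PM",
      "decreased+decreased" = "PM",
      "no+normal" = "IM",
      "decreased+normal" = "IM",
      "increased+no" = "IM",
      "decreased+increased" = "IM",
      "normal+normal" = "NM",
      "increased+normal" = "RM",
      "increased+increased" = "UM",
      stop("no phenotype rule for function classes ", key))
  }
  list(gene = gene, diplotype = diplotype, phenotype = phen)
}

# phenotype truth table straight from simulated diplotypes (used by the
# generator; the analysis path goes through call_diplotype first). The
# translation is evaluated once per unique diplotype (x copy number for
# CYP2D6) and mapped back, which keeps large cohorts cheap.
phenotype_from_diplotypes <- function(diplotypes, cyp2d6_cn) {
  out <- diplotypes[c("subject", "gene", "diplotype")]
  out$activity_score <- NA_real_
  out$phenotype <- NA_character_
  for (g in unique(out$gene)) {
    i <- which(out$gene == g)
    if (g == "CYP2D6") {
      cn <- cyp2d6_cn$cn[match(out$subject[i], cyp2d6_cn$subject)]
      key <- paste(out$diplotype[i], cn)
      uk <- !duplicated(key)
      ph <- Map(cyp2d6_phenotype, out$diplotype[i][uk], cn[uk])
      idx <- match(key, key[uk])
      out$activity_score[i] <- vapply(ph, `[[`, 0, "activity_score")[idx]
      out$phenotype[i] <- vapply(ph, `[[`, "", "phenotype")[idx]
    } else {
      key <- out$diplotype[i]
      uk <- !duplicated(key)
      ph <- lapply(key[uk], function(d) function_phenotype(g, d))
      out$phenotype[i] <- vapply(ph, `[[`, "", "phenotype")[match(key, key[uk])]
    }
  }
  rownames(out) <- NULL
  out
}

#' Translate a genotype table into per-gene phenotypes
#'
#' Runs [call_diplotype()] per subject and gene over a long genotype table,
#' then assigns phenotypes ([cyp2d6_phenotype()] for CYP2D6 with the copy
#' number side table, [function_phenotype()] otherwise). Every subject x
#' gene combination receives exactly one row; unresolvable genotype
#' combinations are reported as `"indeterminate"`.
#'
#' @param genotypes long data.frame `subject`, `rsid`, `allele1`, `allele2`.
#' @param cyp2d6_cn optional data.frame `subject`, `cn`.
#' @param genes genes to translate (default: all genes with bundled
#'   definitions present in the table).
#' @return data.frame `subject`, `gene`, `diplotype`, `activity_score`,
#'   `phenotype`, `ambiguous`, `indeterminate`.
#' @export
pgx_table <- function(genotypes, cyp2d6_cn = NULL, genes = NULL) {
  defs <- pgx_definitions()
  gene_of <- defs$variants$gene[match(genotypes$rsid, defs$variants$rsid)]
  if (anyNA(gene_of)) stop("unknown rsID(s): ",
                           paste(unique(genotypes$rsid[is.na(gene_of)]), collapse = ", "))
  star_genes <- unique(defs$definitions$gene)
  if (is.null(genes)) genes <- intersect(star_genes, unique(gene_of))
  subjects <- unique(genotypes$subject)
  rows <- list()
  for (g in genes) {
    grs <- unique(defs$definitions$rsid[defs$definitions$gene == g])
    sub_tab <- genotypes[genotypes$rsid %in% grs, , drop = FALSE]
    for (s in subjects) {
      calls <- sub_tab[sub_tab$subject == s, c("rsid", "allele1", "allele2")]
      cn <- if (g == "CYP2D6" && !is.null(cyp2d6_cn)) {
        v <- cyp2d6_cn$cn[match(s, cyp2d6_cn$subject)]
        if (is.na(v)) 2L else v
      } else 2L
      dp <- call_diplotype(g, calls, defs, copy_number = cn)
      ph <- if (g == "CYP2D6") cyp2d6_phenotype(dp, cn) else function_phenotype(g, dp)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, gene = g, diplotype = if (is.na(dp$diplotype)) NA_character_ else dp$diplotype,
        activity_score = if (g == "CYP2D6") ph$activity_score else NA_real_,
        phenotype = ph$phenotype, ambiguous = dp$ambiguous,
        indeterminate = dp$indeterminate, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Build analysis predictor columns
#'
#' Emits the grouped predictor codings used by the association stage: the
#' full categorical coding passes through, and each rule adds a merged
#' coding (e.g. `rs2032582` T/T versus the merged T/G + G/A + G/G group, or
#' SLCO1B1 normal function versus decreased-plus-poor). Groups smaller than
#' `floor` subjects are flagged in the `small_groups` attribute.
#'
#' @param data data.frame of subject-level predictors.
#' @param rules list of rules: `list(name =, column =, groups = named list
#'   of level vectors)`. `NULL` rules mean identity pass-through.
#' @param floor minimum group size before flagging (default 2).
#' @return `data` with one factor column appended per rule; attribute
#'   `small_groups`.
#' @export
#' @examples
#' d <- data.frame(rs2032582 = c("T/T", "T/G", "G/G", "G/A"))
#' r <- list(list(name = "rs2032582_TT", column = "rs2032582",
#'                groups = list("T/T" = "T/T", rest = c("T/G", "G/A", "G/G"))))
#' analysis_groups(d, r)$rs2032582_TT
analysis_groups <- function(data, rules = NULL, floor = 2L) {
  if (is.null(rules) || !length(rules)) return(data)
  small <- list()
  for (r in rules) {
    if (!r$column %in% names(data)) stop("rule references unknown column: ", r$column)
    x <- as.character(data[[r$column]])
    lv <- unlist(r$groups, use.names = FALSE)
    unknown <- setdiff(stats::na.omit(unique(x)), lv)
    if (length(unknown)) stop("rule ", r$name, " does not cover level(s): ",
                              paste(unknown, collapse = ", "))
    new <- rep(NA_character_, length(x))
    for (g in names(r$groups)) new[x %in% r$groups[[g]]] <- g
    f <- factor(new, levels = names(r$groups))
    data[[r$name]] <- f
    cnt <- table(f)
    if (any(cnt > 0 & cnt < floor)) {
      small[[r$name]] <- names(cnt)[cnt > 0 & cnt < floor]
    }
  }
  attr(data, "small_groups") <- small
  data
}

#' Default merged-group rules
#'
#' The reference-homozygote-versus-rest and merged-phenotype codings used in
#' the association battery (rs1045642 T/T vs rest, rs2032582 T/T vs rest,
#' rs1128503 T/T vs rest, SLCO1B1 NF vs DF+PF, CYP2D6 PM vs rest).
#' @return list of rules for [analysis_groups()].
#' @export
default_group_rules <- function() {
  list(
    list(name = "rs1045642_TT", column = "rs1045642",
         groups = list("T/T" = "T/T", rest = c("T/C", "C/C"))),
    list(name = "rs1128503_TT", column = "rs1128503",
         groups = list("T/T" = "T/T", rest = c("T/C", "C/C"))),
    list(name = "rs2032582_TT", column = "rs2032582",
         groups = list("T/T" = "T/T", rest = c("T/G", "T/A", "G/A", "G/G", "A/A"))),
    list(name = "SLCO1B1_func", column = "SLCO1B1",
         groups = list(NF = "NF", "DF+PF" = c("DF", "PF"))),
    list(name = "CYP2D6_PM", column = "CYP2D6",
         groups = list(PM = "PM", rest = c("UM", "NM", "IM"), indeterminate = "indeterminate"))
  )
}
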