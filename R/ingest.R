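#' Thresholds for de novo candidate filtering
#'
#' All inequalities are strict, matching how the cutoffs are stated:
#' depth > 10 and GQ > 20 in all three trio members, popmax and TOPMed
#' allele frequency < 0.01, proband alternate depth > 4 with allele
#' fraction > 0.2, parental alternate depth < 2, caller posterior > 0.7.
#'
#' @param min_depth,min_gq trio-wide read depth / genotype quality bounds.
#' @param maf_max,topmed_max allele-frequency bounds (missing passes).
#' @param min_alt_depth,min_vaf proband alternate-allele support bounds.
#' @param max_parent_alt parental alternate depth bound (strict `<`).
#' @param min_posterior de novo caller posterior bound.
#' @param posterior_missing `"pass_warn"` treats a missing posterior as
#'   passing with a warning; `"fail"` aborts the run.
#' @return list of thresholds.
#' @export
ingest_filters <- function(min_depth = 10, min_gq = 20, maf_max = 0.01,
                           topmed_max = 0.01, min_alt_depth = 4,
                           min_vaf = 0.2, max_parent_alt = 2,
                           min_posterior = 0.7,
                           posterior_missing = c("pass_warn", "fail")) {
  list(min_depth = min_depth, min_gq = min_gq, maf_max = maf_max,
       topmed_max = topmed_max, min_alt_depth = min_alt_depth,
       min_vaf = min_vaf, max_parent_alt = max_parent_alt,
       min_posterior = min_posterior,
       posterior_missing = match.arg(posterior_missing))
}

AUTOSOMES <- c(as.character(1:22), paste0("chr", 1:22))

#' Filter de novo candidates for one trio
#'
#' Applies the candidate filters in a fixed order and records, for every
#' excluded candidate, exactly the first rule that failed (audit trail).
#' Filtering is order-independent in the input rows: any permutation
#' yields the same survivor set.
#'
#' @param rows long-format trio rows for one family: one row per
#'   (variant, role) with columns `family_id`, `role`
#'   (`proband`/`mother`/`father`), `individual_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `depth`, `GQ`, `alt_depth`, and on the proband rows the
#'   site annotation (`gene_id`, `var_class`, `rate_quality`,
#'   `popmax_af`, `topmed_af`, `dn_posterior`, score columns).
#' @param config an [ingest_filters()] list.
#' @return list with `records` (surviving de novo records, one per
#'   candidate, annotated from the proband row) and `audit` (per-candidate
#'   first failing rule, `"pass"` for survivors).
#' @export
filter_de_novo <- function(rows, config = ingest_filters()) {
  roles <- c("proband", "mother", "father")
  stopifnot(all(roles %in% rows$role), length(unique(rows$family_id)) == 1)
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  pb <- rows[rows$role == "proband", , drop = FALSE]
  pb <- pb[order(key(pb)), , drop = FALSE]
  mo <- rows[rows$role == "mother", , drop = FALSE]
  fa <- rows[rows$role == "father", , drop = FALSE]
  mo <- mo[match(key(pb), key(mo)), , drop = FALSE]
  fa <- fa[match(key(pb), key(fa)), , drop = FALSE]
  if (anyNA(mo$individual_id) || anyNA(fa$individual_id))
    stop("incomplete trio: parental rows missing for some candidates")

  n <- nrow(pb)
  fail <- rep(NA_character_, n)
  mark <- function(cond, rule) {
    bad <- is.na(fail) & !is.na(cond) & !cond
    fail[bad] <<- rule
  }
  mark(pb$chrom %in% AUTOSOMES, "autosome")
  mark(pb$depth > config$min_depth & mo$depth > config$min_depth &
         fa$depth > config$min_depth, "depth")
  mark(pb$GQ > config$min_gq & mo$GQ > config$min_gq &
         fa$GQ > config$min_gq, "GQ")
  if ("rate_quality" %in% names(pb))
    mark(is.na(pb$rate_quality) | pb$rate_quality == TRUE |
           pb$rate_quality == "high", "rate_quality")
  if ("popmax_af" %in% names(pb))
    mark(is.na(pb$popmax_af) | pb$popmax_af < config$maf_max, "popmax_af")
  if ("topmed_af" %in% names(pb))
    mark(is.na(pb$topmed_af) | pb$topmed_af < config$topmed_max,
         "topmed_af")
  mark(pb$alt_depth > config$min_alt_depth, "proband_alt_depth")
  mark(pb$alt_depth / pb$depth > config$min_vaf, "proband_vaf")
  mark(mo$alt_depth < config$max_parent_alt &
         fa$alt_depth < config$max_parent_alt, "parent_alt_depth")
  if (!"dn_posterior" %in% names(pb) || all(is.na(pb$dn_posterior))) {
    if (config$posterior_missing == "fail")
      stop("de novo posterior column missing")
    warning("de novo posterior missing; candidates treated as passing")
  } else {
    mark(is.na(pb$dn_posterior) | pb$dn_posterior > config$min_posterior,
         "dn_posterior")
  }
  audit <- data.frame(chrom = pb$chrom, pos = pb$pos, ref = pb$ref,
                      alt = pb$alt,
                      first_fail = ifelse(is.na(fail), "pass", fail),
                      stringsAsFactors = FALSE)
  rec <- pb[is.na(fail), , drop = FALSE]
  rec$role <- NULL
  rownames(rec) <- NULL
  list(records = rec, audit = audit)
}

#' Proband-level QC over de novo calls
#'
#' Excludes probands with more than `max_dnm` high-confidence de novo
#' calls (suspected parental mosaicism; "over 150" is strict, exactly 150
#' is retained); collapses de novo variants shared within a family (all
#' copies removed, since clonal sperm mosaicism can duplicate a single
#' event across siblings); and in families with several affected
#' probands keeps one (the lowest `individual_id` unless overridden).
#'
#' @param records cohort-wide de novo records with `family_id`,
#'   `individual_id`, `chrom`, `pos`, `ref`, `alt`.
#' @param max_dnm exclusion threshold on per-proband call counts.
#' @param proband_override optional named character vector
#'   (family -> individual) selecting the retained sibling.
#' @return list with `qc` (per-proband decisions and reasons) and
#'   `records` (retained, deduplicated records).
#' @export
proband_qc <- function(records, max_dnm = 150L, proband_override = NULL) {
  vkey <- paste(records$family_id, records$chrom, records$pos,
                records$ref, records$alt, sep = ":")
  pkey <- paste(vkey, records$individual_id)
  shared <- vkey %in% vkey[duplicated(pkey) | duplicated(vkey)]
  # a variant key seen under >1 individual of the family is familial
  dup_tab <- table(unique(data.frame(vkey, id = records$individual_id))$vkey)
  familial <- vkey %in% names(dup_tab)[dup_tab > 1]
  rec <- records[!familial, , drop = FALSE]

  counts <- table(records$individual_id)  # counts before dedup: call load
  fam_of <- tapply(records$family_id, records$individual_id,
                   function(x) x[1])
  ids <- names(counts)
  excluded <- as.integer(counts) > max_dnm
  reason <- ifelse(excluded, sprintf("more than %d de novo calls", max_dnm),
                   "")
  # one proband per family among the non-excluded
  keep_id <- character(0)
  for (f in unique(fam_of)) {
    cand <- ids[fam_of == f & !excluded]
    if (length(cand) == 0) next
    pick <- if (!is.null(proband_override) && f %in% names(proband_override))
      proband_override[[f]] else sort(cand)[1]
    keep_id <- c(keep_id, pick)
    sib <- setdiff(cand, pick)
    excluded[ids %in% sib] <- TRUE
    reason[ids %in% sib] <- "affected sibling of selected proband"
  }
  qc <- data.frame(family_id = unname(fam_of), individual_id = ids,
                   dnm_count = as.integer(counts), excluded = excluded,
                   reason = reason, stringsAsFactors = FALSE)
  rec <- rec[rec$individual_id %in% ids[!excluded], , drop = FALSE]
  rownames(rec) <- NULL
  list(qc = qc, records = rec)
}

#' Consanguinity and relatedness gate for comphet analysis
#'
#' A trio enters compound heterozygous analysis only if parent-parent
#' kinship is below 0.15, both parent-child kinships lie within
#' 0.5 +/- 0.075, at least one IBD region supports each parent-child
#' relationship, and no parent-parent IBD segment exceeds 3 Mb (long
#' shared segments indicate consanguinity, which violates the allele
#' independence assumption). Missing IBD data fails the gate.
#'
#' @param trios data.frame with columns `family_id`, `kinship_parents`,
#'   `kinship_mother_child`, `kinship_father_child`, `ibd_mother_child`,
#'   `ibd_father_child` (region counts) and `max_parent_ibd_mb`.
#' @return the data.frame with logical `pass` and a `reason` column.
#' @export
consanguinity_gate <- function(trios) {
  need <- c("kinship_parents", "kinship_mother_child",
            "kinship_father_child", "ibd_mother_child", "ibd_father_child",
            "max_parent_ibd_mb")
  stopifnot(all(need %in% names(trios)))
  reason <- rep("", nrow(trios))
  flag <- function(cond, r) {
    bad <- reason == "" & (is.na(cond) | !cond)
    reason[bad] <<- r
  }
  flag(trios$kinship_parents < 0.15, "parent-parent kinship >= 0.15")
  flag(abs(trios$kinship_mother_child - 0.5) <= 0.075,
       "mother-child kinship outside 0.5 +/- 0.075")
  flag(abs(trios$kinship_father_child - 0.5) <= 0.075,
       "father-child kinship outside 0.5 +/- 0.075")
  flag(trios$ibd_mother_child >= 1, "no mother-child IBD region")
  flag(trios$ibd_father_child >= 1, "no father-child IBD region")
  flag(trios$max_parent_ibd_mb <= 3, "parent-parent IBD segment > 3 Mb")
  trios$pass <- reason == ""
  trios$reason <- reason
  trios
}

#' Rare-variant filters for inherited variants
#'
#' @param maf_max popmax allele-frequency bound (strict `<`), default
#'   0.001; tighter than the de novo bound because inherited variants are
#'   standing variation.
#' @param score_floor per-class minimum score, matching the floors of the
#'   possible-variant space.
#' @param score_floor_col per-class column holding the floored score.
#' @return list of settings.
#' @export
comphet_filters <- function(maf_max = 0.001,
                            score_floor = c(CS = -Inf, CI = -Inf,
                                            IS = 0.05, II = 0.05),
                            score_floor_col = c(CS = NA, CI = NA,
                                                IS = "spliceai",
                                                II = "spliceai")) {
  list(maf_max = maf_max, score_floor = score_floor,
       score_floor_col = score_floor_col)
}

#' Detect compound heterozygous configurations for one proband
#'
#' Pairs every qualifying maternally transmitted variant with every
#' paternally transmitted variant in the same gene (reduction to one
#' configuration per gene happens in the tests); proband-homozygous sites
#' with both parents heterozygous form a single configuration flagged
#' homozygous. Rows without a resolvable parent of origin (both parents
#' carrying the same heterozygous allele) are excluded from both
#' configurations and counts. Genome-wide per-class transmitted counts are
#' returned alongside, computed under the same filters.
#'
#' @param variants phased rows for one proband: `individual_id`,
#'   `gene_id`, `parent_of_origin` (`M`, `D`, or NA for unphasable),
#'   `var_class`, `chrom`, `pos`, `ref`, `alt`, `zygosity` (`het`/`hom`),
#'   `popmax_af`, score columns.
#' @param config a [comphet_filters()] list.
#' @return list with `configs` (flat configuration rows with `m_`/`d_`
#'   prefixed sides), `counts` (1-row maternal/paternal class-count
#'   matrices), and `n_unphased`.
#' @export
detect_comphets <- function(variants, config = comphet_filters()) {
  stopifnot(length(unique(variants$individual_id)) == 1)
  id <- variants$individual_id[1]
  v <- variants
  n_unphased <- sum(is.na(v$parent_of_origin) & v$zygosity != "hom")
  v <- v[v$zygosity == "hom" | !is.na(v$parent_of_origin), , drop = FALSE]
  if ("popmax_af" %in% names(v))
    v <- v[is.na(v$popmax_af) | v$popmax_af < config$maf_max, ,
           drop = FALSE]
  keep <- rep(TRUE, nrow(v))
  for (cl in VARIANT_CLASSES) {
    coln <- config$score_floor_col[[cl]]
    if (is.na(coln) || !coln %in% names(v)) next
    i <- v$var_class == cl
    keep[i] <- !is.na(v[[coln]][i]) &
      v[[coln]][i] >= config$score_floor[[cl]]
  }
  v <- v[keep, , drop = FALSE]

  score_cols <- setdiff(names(v),
                        c("individual_id", "gene_id", "parent_of_origin",
                          "var_class", "chrom", "pos", "ref", "alt",
                          "zygosity", "popmax_af", "family_id",
                          "mu_rate", "rate_quality"))
  is_hom <- v$zygosity == "hom"
  # homozygous sites represent one allele transmitted by each parent
  m_side <- is_hom | (!is.na(v$parent_of_origin) & v$parent_of_origin == "M")
  d_side <- is_hom | (!is.na(v$parent_of_origin) & v$parent_of_origin == "D")
  nm <- matrix(as.integer(table(factor(v$var_class[m_side],
                                       VARIANT_CLASSES))),
               nrow = 1, dimnames = list(id, VARIANT_CLASSES))
  nd <- matrix(as.integer(table(factor(v$var_class[d_side],
                                       VARIANT_CLASSES))),
               nrow = 1, dimnames = list(id, VARIANT_CLASSES))

  side_tab <- function(rows, side) {
    out <- data.frame(class = v$var_class[rows], chrom = v$chrom[rows],
                      pos = v$pos[rows], stringsAsFactors = FALSE)
    for (s in score_cols) out[[s]] <- v[[s]][rows]
    names(out) <- paste0(side, "_", c("class", "chrom", "pos", score_cols))
    out
  }
  g_m <- unique(v$gene_id[m_side & !is_hom])
  g_d <- unique(v$gene_id[d_side & !is_hom])
  cand <- union(intersect(g_m, g_d), unique(v$gene_id[is_hom]))
  configs <- list()
  for (g in cand) {
    mi <- which(v$gene_id == g & m_side & !is_hom)
    di <- which(v$gene_id == g & d_side & !is_hom)
    hi <- which(v$gene_id == g & is_hom)
    if (length(mi) && length(di)) {
      grid <- expand.grid(mi = mi, di = di)
      configs[[length(configs) + 1L]] <- cbind(
        data.frame(individual_id = id, gene_id = g,
                   is_homozygous = FALSE, stringsAsFactors = FALSE),
        side_tab(grid$mi, "m"), side_tab(grid$di, "d"))
    }
    if (length(hi)) {
      configs[[length(configs) + 1L]] <- cbind(
        data.frame(individual_id = id, gene_id = g,
                   is_homozygous = TRUE, stringsAsFactors = FALSE),
        side_tab(hi, "m"), side_tab(hi, "d"))
    }
  }
  cfg <- if (length(configs)) do.call(rbind, configs) else
    data.frame(individual_id = character(0), gene_id = character(0),
               is_homozygous = logical(0))
  rownames(cfg) <- NULL
  list(configs = cfg, counts = list(maternal = nm, paternal = nd),
       n_unphased = n_unphased)
}

#' Detect configurations and parental counts across a cohort
#'
#' Applies [detect_comphets()] per proband and stacks results.
#'
#' @param variants phased rows across probands (see [detect_comphets()]).
#' @param config a [comphet_filters()] list.
#' @return list with `configs`, `counts` (individual-by-class maternal and
#'   paternal matrices) and `n_unphased`.
#' @export
cohort_comphets <- function(variants, config = comphet_filters()) {
  ids <- unique(variants$individual_id)
  cfgs <- vector("list", length(ids))
  nm <- matrix(0L, length(ids), length(VARIANT_CLASSES),
               dimnames = list(ids, VARIANT_CLASSES))
  nd <- nm
  unph <- 0L
  sp <- split(seq_len(nrow(variants)), variants$individual_id)
  for (i in seq_along(ids)) {
    r <- detect_comphets(variants[sp[[ids[i]]], , drop = FALSE], config)
    cfgs[[i]] <- r$configs
    nm[i, ] <- r$counts$maternal[1, ]
    nd[i, ] <- r$counts$paternal[1, ]
    unph <- unph + r$n_unphased
  }
  cfgs <- cfgs[vapply(cfgs, nrow, integer(1)) > 0]
  configs <- if (length(cfgs)) do.call(rbind, cfgs) else
    data.frame(individual_id = character(0), gene_id = character(0),
               is_homozygous = logical(0))
  list(configs = configs, counts = list(maternal = nm, paternal = nd),
       n_unphased = unph)
}

#' Parental-age diagnostics for de novo counts
#'
#' Log-linear Poisson regression of per-proband de novo counts on paternal
#' and maternal age, reporting age-adjusted counts and the Pearson
#' dispersion statistic against the Poisson expectation. Diagnostic only:
#' the recurrence tests condition on observed counts and are never
#' altered by this fit.
#'
#' @param counts data.frame with `individual_id`, `dnm_count`,
#'   `father_age`, `mother_age`.
#' @return list with the fitted `glm`, `coefficients`, `dispersion`
#'   (approximately 1 for Poisson-distributed adjusted counts), and
#'   `adjusted` counts scaled to the cohort-mean age; NULL (with warning)
#'   when ages are missing.
#' @export
parental_age_qc <- function(counts) {
  if (!all(c("father_age", "mother_age") %in% names(counts)) ||
      anyNA(counts$father_age) || anyNA(counts$mother_age)) {
    warning("parental ages missing; age QC skipped")
    return(NULL)
  }
  if (nrow(counts) < 3) stop("too few probands for an age fit")
  fit <- glm(dnm_count ~ father_age + mother_age, family = poisson(),
             data = counts)
  pear <- residuals(fit, type = "pearson")
  disp <- sum(pear^2) / fit$df.residual
  adjusted <- counts$dnm_count * mean(fit$fitted.values) / fit$fitted.values
  list(fit = fit, coefficients = coef(fit), dispersion = disp,
       adjusted = adjusted)
}
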