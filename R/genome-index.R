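#' Predictor registry: which score column drives each variant class
#'
#' Coding SNVs (class `CS`) may carry several interchangeable
#' deleteriousness predictors (the test is run once per predictor and the
#' runs are Cauchy-combined); coding indels (`CI`) and the intronic classes
#' (`IS`, `II`) each use exactly one score source (by default a general
#' coding score for indels and a splice-impact score for intronic space).
#'
#' @param cs character vector of coding-SNV predictor column names.
#' @param ci single column name scoring coding indels.
#' @param is,ii single column name scoring intronic SNVs / indels
#'   (typically the same splice predictor, held fixed across runs).
#' @return named list with one character vector per variant class.
#' @export
predictor_registry <- function(cs = c("alphamissense", "primateai3d",
                                      "cadd", "revel"),
                               ci = "cadd", is = "spliceai",
                               ii = "spliceai") {
  stopifnot(length(ci) == 1L, length(is) == 1L, length(ii) == 1L,
            length(cs) >= 1L)
  list(CS = cs, CI = ci, IS = is, II = ii)
}

#' Filters defining the possible-variant space
#'
#' Sites failing these filters are excluded from mutational-target
#' computation (they are not part of the possible-variant space), mirroring
#' the filters applied to observed variants. Defaults: rate-model quality
#' flag required; population-maximum allele frequency below 0.01 for SNV
#' classes and at most 0.001 for the count-approximated indel classes;
#' a minimum splice-score floor of 0.05 for intronic classes (only the
#' lowest-scoring intronic variants are disregarded) and no floor for
#' coding classes; indel sites in the bottom allele-number decile dropped
#' when an allele-number column is supplied.
#'
#' @param maf_max named per-class upper bounds on popmax allele frequency
#'   (strict `<` for SNV classes, `<=` for indel classes, matching how the
#'   cutoffs are stated).
#' @param score_floor named per-class minimum score (sites strictly below
#'   are dropped).
#' @param require_rate_quality drop sites whose rate-quality flag is FALSE.
#' @param drop_an_bottom_decile drop indel sites in the bottom decile of
#'   allele number, when available.
#' @return a list of filter settings.
#' @export
genome_filters <- function(maf_max = c(CS = 0.01, CI = 0.001,
                                       IS = 0.01, II = 0.001),
                           score_floor = c(CS = -Inf, CI = -Inf,
                                           IS = 0.05, II = 0.05),
                           require_rate_quality = TRUE,
                           drop_an_bottom_decile = TRUE) {
  stopifnot(all(VARIANT_CLASSES %in% names(maf_max)),
            all(VARIANT_CLASSES %in% names(score_floor)))
  list(maf_max = maf_max, score_floor = score_floor,
       require_rate_quality = require_rate_quality,
       drop_an_bottom_decile = drop_an_bottom_decile)
}

#' Build the mutational-target index over the possible-variant space
#'
#' For every (gene, variant class, predictor) triple the index holds the
#' sorted unique scores of possible variants and the suffix rate mass
#' `mu(s) = sum of per-site mutation rates over sites with score >= s`.
#' The gene's total target is the suffix mass at the minimum score. SNV
#' classes use the supplied per-generation mutation rates; indel classes
#' (`CI`, `II`) use possible-variant *counts* binned on scores rounded to
#' the nearest hundredth as the rate proxy, so indel mass is unnormalized
#' counts until genome-level class normalization.
#'
#' @param sites data.frame of possible variants with columns `gene_id`,
#'   `var_class`, `mu_rate` (ignored for indel classes), optional
#'   `rate_quality` (logical), `popmax_af`, `allele_number`, and one column
#'   per predictor score (NA for missing).
#' @param predictors a [predictor_registry()]; entries whose column is
#'   absent from `sites` are dropped.
#' @param filters a [genome_filters()].
#' @param normalize scale every class so gene targets sum to 1 genome-wide
#'   (required before computing Poisson intensities).
#' @return an object of class `genome_index`.
#' @export
genome_index <- function(sites, predictors = predictor_registry(),
                         filters = genome_filters(), normalize = TRUE) {
  stopifnot(is.data.frame(sites), nrow(sites) > 0,
            all(c("gene_id", "var_class") %in% names(sites)))
  bad <- !sites$var_class %in% VARIANT_CLASSES
  if (any(bad)) stop("unknown variant class: ",
                     paste(unique(sites$var_class[bad]), collapse = ", "))
  snv <- sites$var_class %in% c("CS", "IS")
  if (any(snv) && (!"mu_rate" %in% names(sites) ||
                   anyNA(sites$mu_rate[snv]) || any(sites$mu_rate[snv] < 0)))
    stop("SNV sites require nonnegative mu_rate")

  dt <- data.table::as.data.table(sites)
  if (filters$require_rate_quality && "rate_quality" %in% names(dt))
    dt <- dt[is.na(rate_quality) | rate_quality == TRUE |
               rate_quality == "high"]
  if ("popmax_af" %in% names(dt)) {
    mm <- filters$maf_max
    keep <- rep(TRUE, nrow(dt))
    af <- dt$popmax_af
    known <- !is.na(af)
    isnv <- dt$var_class %in% c("CS", "IS")
    keep[known & isnv] <- af[known & isnv] < mm[dt$var_class[known & isnv]]
    keep[known & !isnv] <- af[known & !isnv] <= mm[dt$var_class[known & !isnv]]
    dt <- dt[keep]
  }
  if (filters$drop_an_bottom_decile && "allele_number" %in% names(dt)) {
    for (cl in c("CI", "II")) {
      an <- dt$allele_number[dt$var_class == cl]
      if (any(!is.na(an))) {
        cut <- quantile(an, 0.1, na.rm = TRUE, names = FALSE)
        dt <- dt[!(var_class == cl & !is.na(allele_number) &
                     allele_number < cut)]
      }
    }
  }
  if (nrow(dt) == 0) stop("no sites survive the possible-variant filters")

  preds <- lapply(predictors, function(p) p[p %in% names(dt)])
  if (!any(lengths(preds) > 0)) stop("no predictor column found in sites")

  idx <- list()
  class_totals <- numeric(0)
  for (cl in VARIANT_CLASSES) {
    for (pr in preds[[cl]]) {
      sub <- dt[var_class == cl & !is.na(get(pr))]
      if (nrow(sub) == 0) next
      sc <- sub[[pr]]
      sc <- sc[sc >= filters$score_floor[[cl]]]
      sub <- sub[get(pr) >= filters$score_floor[[cl]]]
      if (nrow(sub) == 0) next
      if (cl %in% c("CI", "II")) {
        tab <- data.table::data.table(gene_id = sub$gene_id,
                                      score = round(sub[[pr]], 2),
                                      mass = 1)
      } else {
        tab <- data.table::data.table(gene_id = sub$gene_id,
                                      score = sub[[pr]],
                                      mass = sub$mu_rate)
      }
      agg <- tab[, .(mass = sum(mass)), by = .(gene_id, score)]
      data.table::setorder(agg, gene_id, score)
      agg[, suffix := rev(cumsum(rev(mass))), by = gene_id]
      parts <- split(agg, by = "gene_id", keep.by = TRUE)
      for (p in parts) {
        idx[[idx_key(p$gene_id[1], cl, pr)]] <-
          list(scores = p$score, suffix = p$suffix)
      }
      class_totals[[class_key(cl, pr)]] <-
        sum(agg[agg[, .I[1], by = gene_id]$V1]$suffix)
    }
  }
  zero <- names(class_totals)[class_totals <= 0]
  if (length(zero)) {
    warning("dropping class/predictor with zero total mass: ",
            paste(gsub("\r", "/", zero), collapse = ", "))
    class_totals <- class_totals[!names(class_totals) %in% zero]
  }
  obj <- structure(list(idx = idx, class_totals = class_totals,
                        predictors = preds, filters = filters,
                        normalized = FALSE, fingerprint = NULL),
                   class = "genome_index")
  obj$fingerprint <- index_fingerprint(obj)
  if (normalize) obj <- normalize_class_targets(obj) else obj
}

#' Normalize per-class gene targets to sum to one genome-wide
#'
#' For each variant class (and predictor) the per-gene targets are scaled
#' so they sum to 1 over the genome. Per-variant to per-gene target ratios
#' are unchanged; the normalized scale is what Poisson intensities require.
#'
#' @param index a `genome_index`.
#' @return the index with normalization applied.
#' @export
normalize_class_targets <- function(index) {
  stopifnot(inherits(index, "genome_index"))
  index$normalized <- TRUE
  index
}

index_scale <- function(index, var_class, predictor) {
  if (!index$normalized) return(1)
  tot <- index$class_totals[[class_key(var_class, predictor)]]
  if (is.null(tot) || is.na(tot)) NA_real_ else tot
}

#' Gene-level mutational target
#'
#' Total mutation-rate mass of all possible variants of one class in a
#' gene, on the normalized scale if the index is normalized.
#'
#' @param index a `genome_index`.
#' @param gene_id,var_class,predictor identify the target.
#' @param missing_ok return NA instead of erroring when the gene has no
#'   possible variants for this class/predictor.
#' @return the target mass (or NA).
#' @export
gene_target <- function(index, gene_id, var_class, predictor,
                        missing_ok = FALSE) {
  e <- index$idx[[idx_key(gene_id, var_class, predictor)]]
  if (is.null(e)) {
    if (missing_ok) return(NA_real_)
    stop("gene ", gene_id, " has no possible ", var_class,
         " variants under predictor ", predictor)
  }
  e$suffix[1] / index_scale(index, var_class, predictor)
}

#' Variant-level mutational target
#'
#' Rate mass of all possible variants in the gene/class with score at least
#' as high as the queried score. Ties include the queried variant's own
#' rate, so the result is strictly positive; a query below the minimum
#' observed score returns the whole-gene target, and a query above the
#' maximum returns the mass of the top score (observed variants are
#' themselves part of the possible space, so this only triggers on
#' out-of-space input).
#'
#' @param index a `genome_index`.
#' @param gene_id,var_class,predictor identify the target index.
#' @param score numeric vector of query scores.
#' @return numeric vector of target masses.
#' @export
variant_target <- function(index, gene_id, var_class, predictor, score) {
  e <- index$idx[[idx_key(gene_id, var_class, predictor)]]
  if (is.null(e))
    stop("gene ", gene_id, " has no possible ", var_class,
         " variants under predictor ", predictor)
  suffix_mass(e, score, var_class) /
    index_scale(index, var_class, predictor)
}

# Raw suffix mass (score >= query) from one gene/class index entry.
suffix_mass <- function(e, score, var_class) {
  if (var_class %in% c("CI", "II")) score <- round(score, 2)
  k <- findInterval(score, e$scores)
  n <- length(e$scores)
  exact <- k >= 1 & k <= n & e$scores[pmax(k, 1L)] == score
  i <- ifelse(exact, k, k + 1L)
  i <- pmin(pmax(i, 1L), n)
  e$suffix[i]
}

#' Per-variant to per-gene target ratio (uniform under the null)
#' @inheritParams variant_target
#' @return numeric vector of ratios in (0, 1].
#' @export
target_ratio <- function(index, gene_id, var_class, predictor, score) {
  e <- index$idx[[idx_key(gene_id, var_class, predictor)]]
  if (is.null(e))
    stop("gene ", gene_id, " has no possible ", var_class,
         " variants under predictor ", predictor)
  suffix_mass(e, score, var_class) / e$suffix[1]
}

#' All gene-level targets for one class/predictor
#'
#' @param index a `genome_index`.
#' @param var_class,predictor the class/predictor pair.
#' @return named numeric vector of targets over genes (normalized scale if
#'   the index is normalized).
#' @export
gene_targets <- function(index, var_class, predictor) {
  keys <- names(index$idx)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  sel <- vapply(parts, function(p) p[2] == var_class && p[3] == predictor,
                logical(1))
  if (!any(sel)) return(setNames(numeric(0), character(0)))
  g <- vapply(parts[sel], `[`, character(1), 1)
  v <- vapply(index$idx[sel], function(e) e$suffix[1], numeric(1))
  setNames(v / index_scale(index, var_class, predictor), g)
}

#' Count-based rate approximation for indel classes
#'
#' Indels lack a basepair-resolution mutation rate model, so the joint
#' rate/score distribution is approximated by counting possible indels per
#' score bin (score rounded to the nearest hundredth); the cumulative count
#' over a bin and all higher-score bins stands in for the mutational target
#' at that score.
#'
#' @param scores numeric vector of indel deleteriousness scores.
#' @param popmax_af optional allele frequencies; sites above `maf_max` are
#'   excluded.
#' @param allele_number optional allele numbers; bottom-decile sites are
#'   excluded when supplied.
#' @param maf_max allele-frequency cutoff (keep `<=`), default 0.001.
#' @return object of class `indel_rate_approx`: a data.frame with columns
#'   `score` (ascending bin), `count` and `cum_ge` (cumulative count at or
#'   above the bin).
#' @export
build_indel_approx <- function(scores, popmax_af = NULL,
                               allele_number = NULL, maf_max = 0.001) {
  stopifnot(all(is.finite(scores)))
  keep <- rep(TRUE, length(scores))
  if (!is.null(popmax_af))
    keep <- keep & (is.na(popmax_af) | popmax_af <= maf_max)
  if (!is.null(allele_number) && any(!is.na(allele_number))) {
    cut <- quantile(allele_number, 0.1, na.rm = TRUE, names = FALSE)
    keep <- keep & (is.na(allele_number) | allele_number >= cut)
  }
  sc <- round(scores[keep], 2)
  if (length(sc) == 0) stop("no indels survive filtering")
  tab <- sort(table(sc))
  bins <- sort(unique(sc))
  counts <- as.integer(table(factor(sc, levels = bins)))
  structure(data.frame(score = bins, count = counts,
                       cum_ge = rev(cumsum(rev(counts)))),
            class = c("indel_rate_approx", "data.frame"))
}

# Order-independent fingerprint of the possible-variant space, so that
# cross-cohort summary statistics are only combined over identical spaces.
index_fingerprint <- function(index) {
  keys <- names(index$idx)
  lines <- vapply(seq_along(keys), function(i) {
    e <- index$idx[[i]]
    paste(gsub("\r", "|", keys[i]), length(e$scores),
          fmt_num(e$suffix[1]), fmt_num(sum(e$scores)),
          fmt_num(sum(e$suffix)), sep = "|")
  }, character(1))
  md5_of_text(sort(lines))
}

#' @export
print.genome_index <- function(x, ...) {
  keys <- strsplit(names(x$idx), "\r", fixed = TRUE)
  cls <- vapply(keys, `[`, character(1), 2)
  prd <- vapply(keys, `[`, character(1), 3)
  cat("Mutational-target index over",
      length(unique(vapply(keys, `[`, character(1), 1))), "genes\n")
  for (k in sort(unique(paste(cls, prd)))) {
    cat("  ", k, ": ", sum(paste(cls, prd) == k), " gene indexes\n", sep = "")
  }
  cat("  normalized:", x$normalized,
      "\n  fingerprint:", x$fingerprint, "\n")
  invisible(x)
}
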