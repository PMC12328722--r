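# Compound heterozygous configurations are represented as flat rows:
#   individual_id, gene_id, is_homozygous, m_class, d_class,
#   m_<predictor> / d_<predictor> score columns for the two sides.

ch_assignment <- function(index, cs_predictor) {
  a <- list()
  for (cl in VARIANT_CLASSES) {
    a[[cl]] <- if (cl == "CS") cs_predictor else index$predictors[[cl]][1]
  }
  a
}

# Per-side variant targets (normalized scale); NA when the gene lacks the
# class/predictor index.
ch_side_target <- function(configs, index, side, assignment) {
  cls <- configs[[paste0(side, "_class")]]
  out <- rep(NA_real_, nrow(configs))
  for (cl in unique(cls)) {
    pr <- assignment[[cl]]
    coln <- paste0(side, "_", pr)
    if (!coln %in% names(configs)) next
    rows <- which(cls == cl & !is.na(configs[[coln]]))
    for (g in unique(configs$gene_id[rows])) {
      i <- rows[configs$gene_id[rows] == g]
      if (!idx_key(g, cl, pr) %in% names(index$idx)) next
      out[i] <- variant_target(index, g, cl, pr, configs[[coln]][i])
    }
  }
  out
}

#' Mutational target of a compound heterozygous configuration
#'
#' The squared maximum of the two per-variant mutational targets,
#' `max(mu_{g,vM}, mu_{g,vD})^2`: taking the max means both alleles must be
#' deleterious for the configuration to be surprising (a single deleterious
#' allele may indicate carrier status only). A homozygous configuration
#' uses its single allele's target on both sides.
#'
#' @param configs configuration data.frame (see [detect_comphets()]).
#' @param index a normalized [genome_index()].
#' @param cs_predictor coding-SNV predictor for this run.
#' @return numeric vector of squared targets (NA where a side is not
#'   resolvable in the index).
#' @export
comphet_target <- function(configs, index, cs_predictor =
                             index$predictors$CS[1]) {
  a <- ch_assignment(index, cs_predictor)
  tm <- ch_side_target(configs, index, "m", a)
  td <- ch_side_target(configs, index, "d", a)
  pmax(tm, td)^2
}

# Sum over individuals of n_M[,tM] * n_D[,tD]: class-pair cross counts.
parental_cross_counts <- function(parental_counts) {
  nm <- parental_counts$maternal
  nd <- parental_counts$paternal
  stopifnot(is.matrix(nm), is.matrix(nd), all(dim(nm) == dim(nd)))
  crossprod(nm, nd)  # [tM, tD]
}

#' Cohort-level compound heterozygous recurrence test
#'
#' Per gene, sums residuals `1 - target / max(mu_{g,tM}, mu_{g,tD})^2` over
#' observed configurations (16 class-pair types), computes the expected
#' configuration count `lambda^c = sum_{tM,tD} mu_{g,tM} mu_{g,tD} *
#' sum_j n_{M,tM,j} n_{D,tD,j}` conditioned on each individual's observed
#' parental rare-variant counts, and evaluates significance through the
#' Irwin-Hall/Poisson mixture. One run per coding-SNV predictor,
#' Cauchy-combined; no constraint weighting (no constraint estimates exist
#' for recessive selection).
#'
#' @param configs configuration data.frame; consanguineous probands must
#'   already be excluded ([consanguinity_gate()]).
#' @param index a normalized [genome_index()].
#' @param parental_counts list with `maternal` and `paternal`
#'   individual-by-class count matrices of qualifying inherited rare
#'   variants (columns CS, CI, IS, II).
#' @param cs_predictors coding-SNV predictors to run.
#' @return object of class `ramedies_ch` with per-gene results.
#' @export
ramedies_ch <- function(configs, index, parental_counts,
                        cs_predictors = index$predictors$CS) {
  stopifnot(inherits(index, "genome_index"), index$normalized)
  if (nrow(configs) == 0) {
    warning("no compound heterozygous configurations")
    return(structure(list(results = NULL, n_tested = 0L,
                          index_fingerprint = index$fingerprint),
                     class = "ramedies_ch"))
  }
  cross <- parental_cross_counts(parental_counts)
  runs <- list()
  for (pr in cs_predictors) {
    run <- ch_build_run(configs, index, pr, cross)
    if (!is.null(run)) runs[[pr]] <- run
  }
  ch_combine_runs(runs, index$fingerprint)
}

# Per-run summary structure for the CH test (the meta-analysis serializes
# exactly this): per gene sorted residuals, K, per-class gene targets,
# plus the cohort class-pair cross counts.
ch_build_run <- function(configs, index, cs_predictor, cross) {
  a <- ch_assignment(index, cs_predictor)
  tgt <- comphet_target(configs, index, cs_predictor)
  ok <- !is.na(tgt)
  cc <- configs[ok, , drop = FALSE]
  tgt <- tgt[ok]
  if (nrow(cc) == 0) return(NULL)
  genes <- list()
  for (g in unique(cc$gene_id)) {
    i <- which(cc$gene_id == g)
    mu_g <- vapply(VARIANT_CLASSES, function(cl)
      gene_target(index, g, cl, a[[cl]], missing_ok = TRUE), numeric(1))
    mu_g[is.na(mu_g)] <- 0
    names(mu_g) <- VARIANT_CLASSES
    denom <- pmax(mu_g[cc$m_class[i]], mu_g[cc$d_class[i]])^2
    genes[[g]] <- list(residuals = sort(pmin(pmax(1 - tgt[i] / denom,
                                                  0), 1)),
                       K = length(i), mu_per_class = mu_g)
  }
  list(cs_predictor = cs_predictor, cross_counts = cross, genes = genes)
}

ch_eval_run <- function(run) {
  gn <- names(run$genes)
  if (length(gn) == 0) return(NULL)
  y <- vapply(run$genes, function(e) sum(e$residuals), numeric(1))
  k <- vapply(run$genes, function(e) e$K, numeric(1))
  lam <- vapply(run$genes, function(e) {
    mu <- e$mu_per_class[VARIANT_CLASSES]
    sum(outer(mu, mu) * run$cross_counts[VARIANT_CLASSES, VARIANT_CLASSES])
  }, numeric(1))
  p <- poisson_mixture_pvalue(y, lam)
  data.frame(gene_id = gn, K = as.integer(k), y_c = y, lambda_c = lam,
             p_raw = p$p_raw, p_conditional = p$p_conditional,
             row.names = NULL, stringsAsFactors = FALSE)
}

ch_combine_runs <- function(runs, fingerprint) {
  evals <- lapply(runs, ch_eval_run)
  evals <- evals[!vapply(evals, is.null, logical(1))]
  if (length(evals) == 0) {
    warning("no resolvable configurations")
    return(structure(list(results = NULL, runs = runs, n_tested = 0L,
                          index_fingerprint = fingerprint),
                     class = "ramedies_ch"))
  }
  genes <- sort(unique(unlist(lapply(evals, function(e) e$gene_id))))
  gather <- function(field) {
    m <- sapply(names(evals), function(pr) {
      e <- evals[[pr]]
      e[[field]][match(genes, e$gene_id)]
    })
    matrix(m, nrow = length(genes), dimnames = list(genes, names(evals)))
  }
  p_cauchy <- apply(gather("p_conditional"), 1,
                    function(p) cauchy_combine(pmin(p[!is.na(p)], 1 - 1e-15)))
  res <- data.frame(gene_id = genes,
                    K = as.integer(apply(gather("K"), 1, max, na.rm = TRUE)),
                    p_cauchy = p_cauchy,
                    p_adj = bh_adjust(p_cauchy),
                    p_bonferroni = pmin(1, p_cauchy * length(genes)),
                    stringsAsFactors = FALSE)
  for (pr in names(evals)) {
    e <- evals[[pr]]
    m <- match(genes, e$gene_id)
    res[[paste0("y.", pr)]] <- e$y_c[m]
    res[[paste0("lambda.", pr)]] <- e$lambda_c[m]
    res[[paste0("p_raw.", pr)]] <- e$p_raw[m]
    res[[paste0("p_cond.", pr)]] <- e$p_conditional[m]
  }
  res <- res[order(res$p_cauchy, res$gene_id), ]
  rownames(res) <- NULL
  structure(list(results = res, runs = runs, n_tested = length(genes),
                 index_fingerprint = fingerprint),
            class = "ramedies_ch")
}

#' @export
print.ramedies_ch <- function(x, n = 10L, ...) {
  cat("Cohort compound heterozygous recurrence test (", x$n_tested,
      " genes tested)\n", sep = "")
  if (!is.null(x$results))
    print(head(x$results[, c("gene_id", "K", "p_cauchy", "p_adj",
                             "p_bonferroni")], n), digits = 4)
  invisible(x)
}

#' Genome-wide squared mutational targets per class pair
#'
#' For every maternal/paternal class pair, the per-gene products
#' `mu_{i,tM} * mu_{i,tD}` over all genes (normalized scale) and their
#' genome-wide sum, precomputed for fast rescaling of observed
#' configuration targets.
#'
#' @param index a normalized [genome_index()].
#' @param cs_predictor coding-SNV predictor for this run.
#' @return object of class `genome_squared_targets`: per class pair, the
#'   sorted product vector, its cumulative sums and total.
#' @export
genome_squared_targets <- function(index,
                                   cs_predictor = index$predictors$CS[1]) {
  a <- ch_assignment(index, cs_predictor)
  per_class <- list()
  for (cl in VARIANT_CLASSES) {
    per_class[[cl]] <- gene_targets(index, cl, a[[cl]])
  }
  genes <- sort(unique(unlist(lapply(per_class, names))))
  mat <- sapply(VARIANT_CLASSES, function(cl) {
    v <- per_class[[cl]][genes]
    v[is.na(v)] <- 0
    v
  })
  mat <- matrix(mat, nrow = length(genes),
                dimnames = list(genes, VARIANT_CLASSES))
  pairs <- list()
  total <- 0
  for (tm in VARIANT_CLASSES) for (td in VARIANT_CLASSES) {
    pr <- mat[, tm] * mat[, td]
    pr <- pr[pr > 0]
    if (length(pr) == 0) next
    s <- sort(unname(pr))
    pairs[[paste(tm, td)]] <- list(sorted = s, cum = cumsum(s),
                                   total = sum(s))
    total <- total + sum(s)
  }
  structure(list(pairs = pairs, total = total, assignment = a,
                 gene_products = mat),
            class = "genome_squared_targets")
}

#' Genome-rescaled target of a compound heterozygous configuration
#'
#' Probability-scale rescaling of a configuration's squared target: the
#' summed gene-level squared target mass at or below the observed value,
#' over all class pairs and genes, divided by the total squared target
#' mass. Uniform on (0, 1] under the null; monotone in the raw target.
#'
#' @param raw numeric vector of raw squared configuration targets.
#' @param gst a [genome_squared_targets()] object.
#' @return numeric vector in \[0, 1\].
#' @export
ind_rescaled_target <- function(raw, gst) {
  num <- numeric(length(raw))
  for (pp in gst$pairs) {
    k <- findInterval(raw, pp$sorted)
    below <- ifelse(k >= 1, pp$cum[pmax(k, 1)], 0)
    below[k < 1] <- 0
    num <- num + below + raw * (length(pp$sorted) - k)
  }
  pmin(1, num / gst$total)
}

#' Individual-level compound heterozygous test
#'
#' For each individual: every gene's best (smallest-target) configuration
#' is rescaled genome-wide; the statistic is the minimum rescaled target
#' `y~` over the `K` genes carrying configurations. Given `K`,
#' `P = 1 - (1 - y~)^K`; overall significance mixes over
#' `K ~ Poisson(lambda~)` with
#' `lambda~ = sum_{tM,tD} n_{M,tM} n_{D,tD} sum_i mu_{i,tM} mu_{i,tD}`,
#' conditioned on at least one configuration; the mixture has the closed
#' form `(1 - exp(-lambda~ y~)) / (1 - exp(-lambda~))`.
#'
#' @param configs configuration data.frame across individuals.
#' @param index a normalized [genome_index()].
#' @param parental_counts list of `maternal` / `paternal` count matrices
#'   with rownames identifying individuals.
#' @param cs_predictors coding-SNV predictors; per-run results are
#'   Cauchy-combined.
#' @return object of class `ramedies_ind` whose `results` data.frame is
#'   the ranked (individual, gene) list.
#' @export
ramedies_ind <- function(configs, index, parental_counts,
                         cs_predictors = index$predictors$CS) {
  stopifnot(inherits(index, "genome_index"), index$normalized)
  if (nrow(configs) == 0) {
    warning("no compound heterozygous configurations")
    return(structure(list(results = NULL,
                          index_fingerprint = index$fingerprint),
                     class = "ramedies_ind"))
  }
  nm <- parental_counts$maternal
  nd <- parental_counts$paternal
  per_run <- list()
  for (pr in cs_predictors) {
    gst <- genome_squared_targets(index, pr)
    tgt <- comphet_target(configs, index, pr)
    ok <- !is.na(tgt)
    cc <- configs[ok, , drop = FALSE]
    cc$raw <- tgt[ok]
    if (nrow(cc) == 0) next
    # keep the minimum-target configuration per (individual, gene)
    o <- order(cc$individual_id, cc$gene_id, cc$raw)
    cc <- cc[o, , drop = FALSE]
    keep <- !duplicated(cc[, c("individual_id", "gene_id")])
    n_dropped <- sum(!keep)
    if (n_dropped > 0)
      message(n_dropped, " extra configuration(s) per gene dropped ",
              "(minimum-target kept)")
    cc <- cc[keep, , drop = FALSE]
    cc$mu_tilde <- ind_rescaled_target(cc$raw, gst)
    rows <- list()
    for (id in unique(cc$individual_id)) {
      sub <- cc[cc$individual_id == id, , drop = FALSE]
      k <- nrow(sub)
      best <- which.min(sub$mu_tilde)
      y <- sub$mu_tilde[best]
      lam <- 0
      for (tm in VARIANT_CLASSES) for (td in VARIANT_CLASSES) {
        pp <- gst$pairs[[paste(tm, td)]]
        if (is.null(pp)) next
        lam <- lam + nm[id, tm] * nd[id, td] * pp$total
      }
      p_k <- 1 - (1 - y)^k
      p_all <- if (lam > 0) expm1(-lam * y) / expm1(-lam) else p_k
      rows[[id]] <- data.frame(individual_id = id,
                               best_gene = sub$gene_id[best],
                               y_tilde = y, K = k, lambda_tilde = lam,
                               p_given_K = p_k, p_overall = p_all,
                               stringsAsFactors = FALSE)
    }
    per_run[[pr]] <- do.call(rbind, rows)
  }
  if (length(per_run) == 0) {
    warning("no resolvable configurations")
    return(structure(list(results = NULL,
                          index_fingerprint = index$fingerprint),
                     class = "ramedies_ind"))
  }
  ids <- sort(unique(unlist(lapply(per_run, function(e) e$individual_id))))
  gather <- function(field) {
    m <- sapply(names(per_run), function(pr) {
      e <- per_run[[pr]]
      e[[field]][match(ids, e$individual_id)]
    })
    matrix(m, nrow = length(ids), dimnames = list(ids, names(per_run)))
  }
  pmat <- gather("p_overall")
  p_comb <- apply(pmat, 1, function(p) cauchy_combine(pmin(p[!is.na(p)], 1 - 1e-15)))
  # best gene / y~ taken from the run giving the smallest p_overall
  bestrun <- apply(pmat, 1, function(p) names(per_run)[which.min(p)])
  pick <- function(field) vapply(seq_along(ids), function(i) {
    e <- per_run[[bestrun[i]]]
    e[[field]][match(ids[i], e$individual_id)]
  }, if (field == "best_gene") character(1) else numeric(1))
  res <- data.frame(individual_id = ids,
                    best_gene = pick("best_gene"),
                    y_tilde = pick("y_tilde"),
                    K = as.integer(pick("K")),
                    lambda_tilde = pick("lambda_tilde"),
                    p_given_K = pick("p_given_K"),
                    p_overall = p_comb,
                    stringsAsFactors = FALSE)
  for (pr in names(per_run)) {
    e <- per_run[[pr]]
    res[[paste0("p_overall.", pr)]] <-
      e$p_overall[match(ids, e$individual_id)]
  }
  res <- rank_cohort(res)
  structure(list(results = res, index_fingerprint = index$fingerprint),
            class = "ramedies_ind")
}

#' Deterministic ranking of individual-level results
#'
#' Ascending by overall p; ties broken by smaller rescaled target, then by
#' gene id, then individual id, so repeated runs produce identical output.
#'
#' @param results the `results` data.frame of a `ramedies_ind` object (or
#'   compatible).
#' @return the data.frame reordered, with a `rank` column.
#' @export
rank_cohort <- function(results) {
  stopifnot(nrow(results) >= 1)
  o <- order(results$p_overall, results$y_tilde, results$best_gene,
             results$individual_id)
  out <- results[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' @export
print.ramedies_ind <- function(x, n = 10L, ...) {
  cat("Individual-level compound heterozygous prioritization\n")
  if (!is.null(x$results))
    print(head(x$results[, c("rank", "individual_id", "best_gene", "K",
                             "y_tilde", "p_overall")], n), digits = 4)
  invisible(x)
}

#' Diagnostic enrichment of a ranked patient-gene list
#'
#' For every cutoff `k`, a one-sided Fisher exact test compares the
#' proportion of confirmed diagnoses at ranks `<= k` against ranks `> k`;
#' the overall enrichment statistic is the minimum over `k`, and its
#' significance comes from recomputing the minimum under random
#' permutations of the labels (with the +1 pseudo-count correction).
#'
#' @param labels logical vector of diagnosis labels in ranked order.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed for the permutations.
#' @return list with `best_k`, `min_fisher_p`, `permutation_p`, and the
#'   per-cutoff `per_k_p`.
#' @export
diagnosis_enrichment <- function(labels, n_perm = 10000L, seed = 7L) {
  labels <- as.logical(labels)
  n <- length(labels)
  stopifnot(n >= 2, !anyNA(labels))
  m <- sum(labels)
  if (m == 0) return(list(best_k = NA_integer_, min_fisher_p = 1,
                          permutation_p = 1, per_k_p = rep(1, n - 1)))
  ks <- seq_len(n - 1)
  min_stat <- function(lab) {
    x <- cumsum(lab)[ks]
    min(phyper(x - 1, m, n - m, ks, lower.tail = FALSE))
  }
  x <- cumsum(labels)[ks]
  per_k <- phyper(x - 1, m, n - m, ks, lower.tail = FALSE)
  obs <- min(per_k)
  best_k <- ks[which.min(per_k)]
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) min_stat(sample(labels)),
                 numeric(1))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  list(best_k = best_k, min_fisher_p = obs,
       permutation_p = (1 + sum(perm <= obs)) / (1 + n_perm),
       per_k_p = per_k)
}

#' Expected share of false-positive hits in a recurrently hit gene
#'
#' When a gene collects `K` observed events but only `lambda` were expected
#' across a cohort of `N` probands, the number of coincidental (non-causal)
#' hits among the `K` is modeled as Binomial(`K`, `min(lambda / N, 1)`).
#'
#' @param K observed event count (>= 1).
#' @param lambda expected event count (>= 0).
#' @param N cohort size (>= 1).
#' @return list with the per-trial probability `p`, the `mean` count of
#'   false positives, and `prob_ge(x)`, the upper-tail function
#'   `P(X >= x)`.
#' @export
false_positive_estimate <- function(K, lambda, N) {
  stopifnot(K >= 1, N >= 1)
  if (lambda < 0) stop("lambda must be nonnegative")
  p <- min(lambda / N, 1)
  list(p = p, mean = K * p,
       prob_ge = function(x) stats::pbinom(x - 1, K, p, lower.tail = FALSE))
}
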