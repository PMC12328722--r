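dn_mode_classes <- function(mode) {
  switch(mode,
         missense = "CS",
         exonic   = c("CS", "CI"),
         genome   = VARIANT_CLASSES,
         stop("unknown mode: ", mode))
}

# Resolve records of one class/predictor against the index: per-record
# uniform residuals 1 - mu_{g,v,t}/mu_{g,t}. Records in genes absent from
# this class/predictor index are dropped (returned count is logged by the
# caller).
resolve_residuals <- function(records, index, var_class, predictor) {
  sub <- records[records$var_class == var_class, , drop = FALSE]
  if (!predictor %in% names(sub)) return(NULL)
  sub <- sub[!is.na(sub[[predictor]]), , drop = FALSE]
  # observed variants obey the same floors that define the possible space
  floor_s <- index$filters$score_floor[[var_class]]
  if (is.finite(floor_s))
    sub <- sub[sub[[predictor]] >= floor_s, , drop = FALSE]
  if (nrow(sub) == 0) return(NULL)
  keys <- idx_key(sub$gene_id, var_class, predictor)
  present <- keys %in% names(index$idx)
  dropped <- sum(!present)
  sub <- sub[present, , drop = FALSE]
  if (nrow(sub) == 0)
    return(list(tab = NULL, dropped = dropped))
  ratio <- numeric(nrow(sub))
  for (g in unique(sub$gene_id)) {
    i <- which(sub$gene_id == g)
    ratio[i] <- target_ratio(index, g, var_class, predictor,
                             sub[[predictor]][i])
  }
  list(tab = data.frame(individual_id = sub$individual_id,
                        gene_id = sub$gene_id, var_class = var_class,
                        residual = 1 - ratio, stringsAsFactors = FALSE),
       dropped = dropped)
}

#' Per-gene de novo recurrence statistic
#'
#' Sum of uniform residuals `1 - mu_{g,v,t}/mu_{g,t}` over the observed de
#' novo variants in one gene, across variant classes; under the null the
#' sum follows the Irwin-Hall distribution with `K = sum_t K_t` summands.
#'
#' @param records data.frame of de novo records for one gene: columns
#'   `gene_id`, `var_class`, `individual_id`, and score columns.
#' @param index a normalized [genome_index()].
#' @param assignment named list/vector mapping variant class to the
#'   predictor column used for it in this run.
#' @return list with `y_prime`, `K_per_class` (named integer vector) and
#'   the individual `residuals`.
#' @export
dn_gene_statistic <- function(records, index, assignment) {
  stopifnot(length(unique(records$gene_id)) == 1)
  res <- list()
  for (cl in intersect(names(assignment), unique(records$var_class))) {
    r <- resolve_residuals(records, index, cl, assignment[[cl]])
    if (!is.null(r$tab)) res[[cl]] <- r$tab$residual
  }
  kpc <- vapply(res, length, integer(1))
  list(y_prime = sum(sort(unlist(res, use.names = FALSE))),
       K_per_class = kpc,
       residuals = unlist(res, use.names = FALSE))
}

#' Expected de novo count in a gene given cohort-wide counts
#'
#' `lambda' = sum_t mu_{g,t} * sum_j n_{j,t}` where `n_{j,t}` is individual
#' `j`'s genome-wide count of qualifying de novos of class `t`. Classes for
#' which the gene has no possible variants contribute zero.
#'
#' @param gene_id gene identifier.
#' @param index a normalized [genome_index()].
#' @param class_counts named numeric vector of cohort-total qualifying de
#'   novo counts per variant class.
#' @param assignment named mapping from class to predictor column.
#' @return the Poisson intensity `lambda'`.
#' @export
dn_lambda <- function(gene_id, index, class_counts, assignment) {
  stopifnot(index$normalized)
  lam <- 0
  for (cl in names(assignment)) {
    if (is.na(class_counts[cl] %||% NA)) next
    mu <- gene_target(index, gene_id, cl, assignment[[cl]],
                      missing_ok = TRUE)
    if (!is.na(mu)) lam <- lam + mu * class_counts[[cl]]
  }
  lam
}

# Build the per-run summary structure (the same structure the meta-analysis
# serializes): per gene sorted residuals, per-class K, per-class gene
# targets; plus cohort class totals.
dn_build_run <- function(records, index, classes, cs_predictor, counts) {
  assignment <- list()
  for (cl in classes) {
    assignment[[cl]] <- if (cl == "CS") cs_predictor else
      index$predictors[[cl]][1]
  }
  tabs <- list()
  dropped <- 0L
  for (cl in classes) {
    r <- resolve_residuals(records, index, cl, assignment[[cl]])
    if (is.null(r)) next
    dropped <- dropped + r$dropped
    if (!is.null(r$tab)) tabs[[cl]] <- r$tab
  }
  if (dropped > 0)
    warning(dropped, " record(s) not resolvable in the index were dropped")
  if (length(tabs) == 0) return(NULL)
  all_tab <- do.call(rbind, tabs)
  # qualifying cohort counts per class, from resolvable records, unless
  # externally supplied
  if (is.null(counts)) {
    class_counts <- vapply(classes, function(cl)
      sum(all_tab$var_class == cl), numeric(1))
  } else {
    class_counts <- vapply(classes, function(cl) {
      if (is.matrix(counts)) sum(counts[, cl]) else sum(counts[[cl]])
    }, numeric(1))
  }
  names(class_counts) <- classes
  genes <- list()
  for (g in unique(all_tab$gene_id)) {
    sub <- all_tab[all_tab$gene_id == g, , drop = FALSE]
    kpc <- vapply(classes, function(cl) sum(sub$var_class == cl),
                  integer(1))
    names(kpc) <- classes
    mu <- vapply(classes, function(cl)
      gene_target(index, g, cl, assignment[[cl]], missing_ok = TRUE),
      numeric(1))
    mu[is.na(mu)] <- 0
    names(mu) <- classes
    genes[[g]] <- list(residuals = sort(sub$residual), K_per_class = kpc,
                       mu_per_class = mu)
  }
  list(assignment = assignment, cs_predictor = cs_predictor,
       class_counts = class_counts, genes = genes)
}

# Evaluate one run: per-gene y', lambda', p_raw, p_conditional.
dn_eval_run <- function(run) {
  gn <- names(run$genes)
  if (length(gn) == 0) return(NULL)
  y <- vapply(run$genes, function(e) sum(e$residuals), numeric(1))
  k <- vapply(run$genes, function(e) sum(e$K_per_class), numeric(1))
  lam <- vapply(run$genes, function(e)
    sum(e$mu_per_class * run$class_counts[names(e$mu_per_class)]),
    numeric(1))
  p <- poisson_mixture_pvalue(y, lam)
  data.frame(gene_id = gn, K = as.integer(k), y_prime = y,
             lambda_prime = lam, p_raw = p$p_raw,
             p_conditional = p$p_conditional,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cohort-level de novo recurrence test
#'
#' For every gene with at least one qualifying de novo, computes the
#' recurrence statistic `y'` (sum of uniform target residuals across
#' variant classes), its Poisson intensity `lambda'`, and the raw and
#' conditional Irwin-Hall/Poisson mixture significance. One run is
#' performed per coding-SNV predictor (indel and intronic contributions
#' use their fixed predictors and are shared across runs); the per-run
#' conditional p-values are Cauchy-combined, Bonferroni-adjusted over the
#' tested genes, and converted to constraint-weighted Q-values with
#' Benjamini-Hochberg adjustment.
#'
#' @param denovos data.frame of de novo records: `individual_id`,
#'   `gene_id`, `var_class`, plus one column per predictor score. Within-
#'   family duplicates are assumed already collapsed (see [proband_qc()]).
#' @param index a normalized [genome_index()].
#' @param counts optional externally supplied per-class cohort counts of
#'   qualifying de novos (named vector or individual-by-class matrix);
#'   derived from the resolvable records when NULL.
#' @param mode `"missense"` (coding SNVs with missense-specialized
#'   predictors), `"exonic"` (adds coding indels and general predictors) or
#'   `"genome"` (adds intronic classes).
#' @param cs_predictors coding-SNV predictors to run; defaults to the
#'   index's registry (restricted to missense-specialized predictors in
#'   missense mode when present).
#' @param weights optional [constraint_weights()] table; genes without an
#'   entry get weight 1.
#' @return object of class `ramedies_dn` with a `results` data.frame (one
#'   row per tested gene) and per-run detail.
#' @export
ramedies_dn <- function(denovos, index, counts = NULL,
                        mode = c("genome", "exonic", "missense"),
                        cs_predictors = NULL, weights = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(index, "genome_index"), index$normalized)
  classes <- dn_mode_classes(mode)
  if (is.null(cs_predictors)) {
    cs_predictors <- index$predictors$CS
    if (mode == "missense") {
      sp <- intersect(c("alphamissense", "primateai3d"), cs_predictors)
      if (length(sp)) cs_predictors <- sp
    }
  }
  if (nrow(denovos) == 0 || length(cs_predictors) == 0) {
    warning("no qualifying de novo records")
    return(structure(list(results = NULL, runs = list(), mode = mode,
                          n_tested = 0L,
                          index_fingerprint = index$fingerprint),
                     class = "ramedies_dn"))
  }
  runs <- list()
  for (pr in cs_predictors) {
    run <- dn_build_run(denovos, index, classes, pr, counts)
    if (!is.null(run)) runs[[pr]] <- run
  }
  out <- dn_combine_runs(runs, index$fingerprint, mode, weights)
  out
}

# Shared tail of the DN pipeline, also used by the meta-analysis path so
# pooled and meta results are computed by identical code.
dn_combine_runs <- function(runs, fingerprint, mode, weights) {
  if (length(runs) == 0) {
    warning("no qualifying de novo records")
    return(structure(list(results = NULL, runs = list(), mode = mode,
                          n_tested = 0L, index_fingerprint = fingerprint),
                     class = "ramedies_dn"))
  }
  evals <- lapply(runs, dn_eval_run)
  genes <- sort(unique(unlist(lapply(evals, function(e) e$gene_id))))
  n_tested <- length(genes)
  gather <- function(field) {
    m <- sapply(names(evals), function(pr) {
      e <- evals[[pr]]
      e[[field]][match(genes, e$gene_id)]
    })
    matrix(m, nrow = n_tested, dimnames = list(genes, names(evals)))
  }
  pc_mat <- gather("p_conditional")
  p_cauchy <- apply(pc_mat, 1, function(p) cauchy_combine(pmin(p[!is.na(p)], 1 - 1e-15)))
  k_tot <- apply(gather("K"), 1, function(k) max(k, na.rm = TRUE))
  w <- rep(1, n_tested)
  if (!is.null(weights)) {
    m <- match(genes, weights$gene_id)
    w[!is.na(m)] <- weights$weight[m[!is.na(m)]]
  }
  q <- p_cauchy / w
  res <- data.frame(gene_id = genes, K = as.integer(k_tot),
                    p_cauchy = p_cauchy, weight = w, Q = q,
                    Q_adj = bh_adjust(q),
                    p_bonferroni = pmin(1, p_cauchy * n_tested),
                    row.names = NULL, stringsAsFactors = FALSE)
  for (pr in names(evals)) {
    e <- evals[[pr]]
    m <- match(genes, e$gene_id)
    res[[paste0("p_raw.", pr)]] <- e$p_raw[m]
    res[[paste0("p_cond.", pr)]] <- e$p_conditional[m]
    res[[paste0("y.", pr)]] <- e$y_prime[m]
    res[[paste0("lambda.", pr)]] <- e$lambda_prime[m]
  }
  res <- res[order(res$Q_adj, res$p_cauchy, res$gene_id), ]
  rownames(res) <- NULL
  structure(list(results = res, runs = runs, mode = mode,
                 n_tested = n_tested, index_fingerprint = fingerprint),
            class = "ramedies_dn")
}

#' @export
print.ramedies_dn <- function(x, n = 10L, ...) {
  cat("Cohort de novo recurrence test (", x$mode, " mode, ",
      length(x$runs), " predictor run(s), ", x$n_tested,
      " genes tested)\n", sep = "")
  if (is.null(x$results)) {
    cat("  no qualifying records\n")
    return(invisible(x))
  }
  cols <- c("gene_id", "K", "p_cauchy", "weight", "Q", "Q_adj",
            "p_bonferroni")
  print(head(x$results[, cols], n), digits = 4)
  invisible(x)
}

#' @export
summary.ramedies_dn <- function(object, fdr = 0.05, ...) {
  r <- object$results
  cat("Genes tested:", object$n_tested, "\n")
  if (!is.null(r)) {
    cat("Bonferroni-significant (0.05):", sum(r$p_bonferroni < 0.05), "\n")
    cat(sprintf("Weighted FDR %d%%: %d\n", round(100 * fdr),
                sum(r$Q_adj < fdr)))
  }
  invisible(object)
}

#' QQ plot of conditional de novo p-values
#'
#' Under the null the per-gene conditional p-values (genes with at least
#' one event) are uniform; this plots observed against expected quantiles
#' on the -log10 scale for each predictor run.
#'
#' @param x a `ramedies_dn` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ramedies_dn <- function(x, ...) {
  if (is.null(x$results)) return(invisible(x))
  cols <- grep("^p_cond\\.", names(x$results), value = TRUE)
  first <- TRUE
  for (i in seq_along(cols)) {
    p <- sort(x$results[[cols[i]]])
    p <- p[!is.na(p)]
    e <- -log10((seq_along(p) - 0.5) / length(p))
    o <- -log10(rev(p))
    if (first) {
      graphics::plot(e, o, xlab = "expected -log10 p",
                     ylab = "observed -log10 p", col = i, ...)
      graphics::abline(0, 1, lty = 2)
      first <- FALSE
    } else graphics::points(e, o, col = i)
  }
  invisible(x)
}

#' Decile-based constraint weights for the weighted FDR procedure
#'
#' Genes are sorted ascending by their constraint value (posterior
#' selection against heterozygous loss of function), split into 10
#' equal-size bins (remainder spread over the first bins), and each gene's
#' weight is 10 times the fraction of dominant-disease genes falling in its
#' bin. Genes without a constraint value get weight 1. The dominant-disease
#' denominator counts only constraint-scored dominant genes, so the mean
#' weight over scored genes is exactly 1.
#'
#' @param constraint named numeric vector: gene id -> constraint value (NA
#'   allowed).
#' @param dd_genes character vector of exclusively-dominant disease genes.
#' @param n_bins number of bins (default 10 deciles).
#' @return data.frame of class `constraint_weights` with columns
#'   `gene_id`, `constraint`, `bin`, `weight`.
#' @export
constraint_weights <- function(constraint, dd_genes, n_bins = 10L) {
  stopifnot(!is.null(names(constraint)))
  scored <- constraint[!is.na(constraint)]
  out <- data.frame(gene_id = names(constraint),
                    constraint = unname(constraint),
                    bin = NA_integer_, weight = 1,
                    stringsAsFactors = FALSE)
  if (length(scored) < 10) {
    warning("fewer than 10 constraint-scored genes; all weights set to 1")
  } else {
    ord <- order(scored, names(scored))           # stable, reproducible
    genes_sorted <- names(scored)[ord]
    n <- length(genes_sorted)
    sizes <- rep(n %/% n_bins, n_bins)
    if (n %% n_bins > 0) sizes[seq_len(n %% n_bins)] <-
        sizes[seq_len(n %% n_bins)] + 1L
    bin_of <- rep(seq_len(n_bins), times = sizes)
    dd <- intersect(dd_genes, genes_sorted)
    if (length(dd) == 0) {
      warning("no dominant-disease gene has a constraint value; ",
              "all weights set to 1")
    } else {
      dd_in_bin <- vapply(seq_len(n_bins), function(b)
        sum(genes_sorted[bin_of == b] %in% dd), numeric(1))
      wt <- n_bins * dd_in_bin / length(dd)
      m <- match(out$gene_id, genes_sorted)
      out$bin[!is.na(m)] <- bin_of[m[!is.na(m)]]
      out$weight[!is.na(m)] <- wt[bin_of[m[!is.na(m)]]]
    }
  }
  class(out) <- c("constraint_weights", "data.frame")
  out
}

#' Constraint-weighted FDR adjustment
#'
#' Divides each p-value by its gene's weight to form Q-values, then applies
#' Benjamini-Hochberg step-up over the Q-values (values above 1 allowed
#' before adjustment, capped after). With all-unit weights this is plain
#' BH.
#'
#' @param p numeric vector of p-values.
#' @param w numeric vector of positive gene weights, recycled.
#' @return list with `Q` and `Q_adj`.
#' @export
weighted_fdr <- function(p, w = 1) {
  stopifnot(all(p > 0), all(w > 0))
  w <- rep_len(w, length(p))
  q <- p / w
  list(Q = q, Q_adj = bh_adjust(q))
}
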