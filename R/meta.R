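#' Export deidentified per-gene summary statistics
#'
#' The shareable summary holds, per predictor run and gene: the sorted
#' uniform residuals, the per-class event counts, and the per-class gene
#' targets; plus the cohort-total class counts (or class-pair cross counts
#' for the compound heterozygous test) and the fingerprint of the
#' possible-variant space. No individual identifiers, loci, or alleles are
#' present, yet the pooled-cohort test is exactly reconstructible.
#'
#' @param fit a `ramedies_dn` or `ramedies_ch` object.
#' @param cohort label for this cohort.
#' @return object of class `cohort_summary`.
#' @export
export_summary <- function(fit, cohort = "cohort") {
  stopifnot(inherits(fit, c("ramedies_dn", "ramedies_ch")))
  kind <- if (inherits(fit, "ramedies_dn")) "dn" else "ch"
  structure(list(schema = "ramedies-summary-1", kind = kind,
                 cohort = cohort,
                 mode = if (kind == "dn") fit$mode else NULL,
                 fingerprint = fit$index_fingerprint,
                 runs = fit$runs),
            class = "cohort_summary")
}

#' Write / read a cohort summary as JSON
#'
#' Numbers are serialized at full precision so export/import round-trips
#' are bit-exact.
#'
#' @param summary a `cohort_summary`.
#' @param path JSON file path.
#' @return `path` (write) or the `cohort_summary` (read).
#' @export
write_cohort_summary <- function(summary, path) {
  stopifnot(inherits(summary, "cohort_summary"))
  named_list <- function(v) as.list(setNames(as.list(unname(v)), names(v)))
  x <- unclass(summary)
  x$runs <- lapply(x$runs, function(run) {
    if (!is.null(run[["class_counts"]]))
      run[["class_counts"]] <- named_list(run[["class_counts"]])
    if (!is.null(run[["cross_counts"]])) {
      m <- run[["cross_counts"]]
      run[["cross_counts"]] <- lapply(seq_len(nrow(m)),
                                 function(i) as.list(unname(m[i, ])))
    }
    run[["genes"]] <- lapply(run[["genes"]], function(g) {
      if (!is.null(g$K_per_class)) g$K_per_class <- named_list(g$K_per_class)
      g$mu_per_class <- named_list(g$mu_per_class)
      g$residuals <- as.list(unname(g$residuals))
      g
    })
    run
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_cohort_summary
#' @export
read_cohort_summary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopifnot(identical(x$schema, "ramedies-summary-1"))
  num <- function(v) vapply(v, as.numeric, numeric(1))
  runs <- lapply(x$runs, function(run) {
    out <- list()
    if (!is.null(run[["assignment"]]))
      out$assignment <- lapply(run[["assignment"]], as.character)
    if (!is.null(run[["cs_predictor"]]))
      out$cs_predictor <- as.character(run[["cs_predictor"]])
    if (!is.null(run[["class_counts"]])) {
      cc <- num(run[["class_counts"]])
      names(cc) <- names(run[["class_counts"]])
      out$class_counts <- cc
    }
    if (!is.null(run[["cross_counts"]])) {
      cm <- do.call(rbind, lapply(run[["cross_counts"]], num))
      dimnames(cm) <- list(VARIANT_CLASSES, VARIANT_CLASSES)
      out$cross_counts <- cm
    }
    out$genes <- lapply(run[["genes"]], function(g) {
      e <- list(residuals = num(g[["residuals"]]))
      if (!is.null(g[["K_per_class"]])) {
        k <- num(g[["K_per_class"]])
        names(k) <- names(g[["K_per_class"]])
        e$K_per_class <- k
      }
      if (!is.null(g[["K"]])) e$K <- as.integer(g[["K"]][[1]])
      mu <- num(g[["mu_per_class"]])
      names(mu) <- names(g[["mu_per_class"]])
      e$mu_per_class <- mu
      e
    })
    out
  })
  structure(list(schema = x$schema, kind = x$kind, cohort = x$cohort,
                 mode = x$mode %||% NULL, fingerprint = x$fingerprint,
                 runs = runs),
            class = "cohort_summary")
}

#' Combine cohort summaries and rerun the pooled test
#'
#' Per gene and run, residual lists are concatenated (and re-sorted) and
#' event counts summed; cohort class counts (or class-pair cross counts)
#' are summed; the standard test is then evaluated by the same code path
#' as a pooled-cohort run, so the meta-analysis reproduces pooled
#' significance exactly. Summaries over different possible-variant spaces
#' (mismatched index fingerprints) are refused.
#'
#' @param summaries list of `cohort_summary` objects (all the same kind).
#' @param weights optional [constraint_weights()] for the DN test.
#' @return a `ramedies_dn` or `ramedies_ch` object.
#' @export
combine_and_test <- function(summaries, weights = NULL) {
  stopifnot(length(summaries) >= 1,
            all(vapply(summaries, inherits, logical(1), "cohort_summary")))
  fps <- vapply(summaries, function(s) s$fingerprint, character(1))
  if (length(unique(fps)) != 1)
    stop("index fingerprints differ; summaries were computed over ",
         "different possible-variant spaces and cannot be combined")
  kinds <- unique(vapply(summaries, function(s) s$kind, character(1)))
  stopifnot(length(kinds) == 1)
  run_names <- sort(unique(unlist(lapply(summaries,
                                         function(s) names(s$runs)))))
  merged <- list()
  for (rn in run_names) {
    parts <- lapply(summaries, function(s) s$runs[[rn]])
    parts <- parts[!vapply(parts, is.null, logical(1))]
    base <- parts[[1]]
    if (kinds == "dn") {
      cc <- Reduce(`+`, lapply(parts, function(p)
        p$class_counts[names(base$class_counts)]))
      genes <- merge_gene_lists(parts, dn = TRUE)
      merged[[rn]] <- list(assignment = base$assignment,
                           cs_predictor = base$cs_predictor,
                           class_counts = cc, genes = genes)
    } else {
      cr <- Reduce(`+`, lapply(parts, function(p)
        p$cross_counts[VARIANT_CLASSES, VARIANT_CLASSES]))
      genes <- merge_gene_lists(parts, dn = FALSE)
      merged[[rn]] <- list(cs_predictor = base$cs_predictor,
                           cross_counts = cr, genes = genes)
    }
  }
  if (kinds == "dn") {
    dn_combine_runs(merged, fps[1], summaries[[1]]$mode %||% "genome",
                    weights)
  } else {
    ch_combine_runs(merged, fps[1])
  }
}

merge_gene_lists <- function(parts, dn) {
  genes <- sort(unique(unlist(lapply(parts, function(p) names(p$genes)))))
  out <- list()
  for (g in genes) {
    es <- lapply(parts, function(p) p$genes[[g]])
    es <- es[!vapply(es, is.null, logical(1))]
    mu <- es[[1]]$mu_per_class
    for (e in es[-1]) {
      if (max(abs(e$mu_per_class[names(mu)] - mu)) > 1e-12)
        stop("gene targets differ across summaries for gene ", g)
    }
    resid <- sort(unlist(lapply(es, function(e) e$residuals),
                         use.names = FALSE))
    if (dn) {
      k <- Reduce(`+`, lapply(es, function(e)
        e$K_per_class[names(es[[1]]$K_per_class)]))
      out[[g]] <- list(residuals = resid, K_per_class = k,
                       mu_per_class = mu)
    } else {
      out[[g]] <- list(residuals = resid,
                       K = sum(vapply(es, function(e) e$K, numeric(1))),
                       mu_per_class = mu)
    }
  }
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  ng <- length(unique(unlist(lapply(x$runs, function(r) names(r$genes)))))
  cat("Deidentified cohort summary (", x$kind, " test, cohort '",
      x$cohort, "')\n  runs: ", paste(names(x$runs), collapse = ", "),
      "\n  genes with events: ", ng,
      "\n  index fingerprint: ", x$fingerprint, "\n", sep = "")
  invisible(x)
}
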