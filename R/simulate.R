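# Run code under a fixed RNG seed, restoring the caller's RNG state, so
# every generator is a pure function of (spec, seed).
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  force(code)
}

#' Parameters of a synthetic trio cohort
#'
#' The generator emulates the statistical structure the recurrence tests
#' assume: genes composed of possible-variant sites with per-site germline
#' mutation rates (log-normal across sites) and continuous deleteriousness
#' scores; de novo events landing rate-proportionally with per-proband
#' class counts around the genome-wide averages of 78.3 de novo SNVs and
#' 9.5 de novo indels, split between coding and intronic space by the
#' coding fraction; and inherited rare variants with negative-binomial
#' per-parent counts (population-structure overdispersion the compound
#' heterozygous test must tolerate by conditioning). Coding-SNV predictor
#' scores are correlated through a Gaussian copula so Cauchy combination
#' is exercised under dependence. No nucleotide-level realism is
#' attempted.
#'
#' @param n_genes number of genes.
#' @param sites_per_class expected possible-variant sites per gene per
#'   class.
#' @param rate_meanlog,rate_sdlog log-normal parameters for per-site SNV
#'   mutation rates (defaults around 1e-8 per generation with ~e-fold
#'   spread).
#' @param cs_predictors coding-SNV predictor score columns to simulate.
#' @param cs_cor pairwise Gaussian-copula correlation between them.
#' @param n_trios number of trios.
#' @param dnm_snv_mean,dnm_indel_mean genome-wide mean de novo SNV/indel
#'   counts per proband.
#' @param coding_fraction fraction of each mutation type falling in coding
#'   space.
#' @param age_slope per-year log-linear paternal-age effect on de novo
#'   counts (0 = no age structure).
#' @param inherited_mean named per-class means of qualifying rare variants
#'   inherited per parent.
#' @param inherited_size negative-binomial size (dispersion) for inherited
#'   counts.
#' @param seed mandatory RNG seed.
#' @return list of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_genes = 2000L,
                                  sites_per_class = c(CS = 150, CI = 40,
                                                      IS = 400, II = 80),
                                  rate_meanlog = log(1e-8),
                                  rate_sdlog = 1,
                                  cs_predictors = c("alphamissense",
                                                    "primateai3d"),
                                  cs_cor = 0.6,
                                  n_trios = 300L,
                                  dnm_snv_mean = 78.3,
                                  dnm_indel_mean = 9.5,
                                  coding_fraction = 0.025,
                                  age_slope = 0,
                                  inherited_mean = c(CS = 40, CI = 10,
                                                     IS = 150, II = 30),
                                  inherited_size = 20,
                                  seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(n_genes >= 2, all(sites_per_class > 0), n_trios >= 1,
            dnm_snv_mean > 0, dnm_indel_mean > 0,
            coding_fraction > 0, coding_fraction < 1,
            all(inherited_mean >= 0), inherited_size > 0,
            cs_cor >= 0, cs_cor < 1)
  dnm_mean <- c(CS = dnm_snv_mean * coding_fraction,
                CI = dnm_indel_mean * coding_fraction,
                IS = dnm_snv_mean * (1 - coding_fraction),
                II = dnm_indel_mean * (1 - coding_fraction))
  structure(list(n_genes = as.integer(n_genes),
                 sites_per_class = sites_per_class,
                 rate_meanlog = rate_meanlog, rate_sdlog = rate_sdlog,
                 cs_predictors = cs_predictors, cs_cor = cs_cor,
                 n_trios = as.integer(n_trios), dnm_mean = dnm_mean,
                 age_slope = age_slope,
                 inherited_mean = inherited_mean[VARIANT_CLASSES],
                 inherited_size = inherited_size,
                 seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

#' Simulate a synthetic genome of possible-variant sites
#'
#' @param spec a [synthetic_cohort_spec()].
#' @return data.frame of sites: `gene_id`, `var_class`, `chrom`, `pos`,
#'   `ref`, `alt`, `mu_rate` (NA for indel classes, whose mass is the
#'   site count), `rate_quality`, `popmax_af`, and score columns
#'   (coding-SNV predictors plus `cadd` and `spliceai`).
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  with_seed(spec$seed, {
    genes <- sprintf("g%04d", seq_len(spec$n_genes))
    gene_chrom <- sample(as.character(1:22), spec$n_genes, replace = TRUE)
    parts <- list()
    pos_offset <- 0L  # keep (chrom, pos) unique genome-wide
    for (cl in VARIANT_CLASSES) {
      n_sites <- pmax(1L, rpois(spec$n_genes, spec$sites_per_class[[cl]]))
      n <- sum(n_sites)
      gid <- rep(genes, n_sites)
      is_indel <- cl %in% c("CI", "II")
      d <- data.frame(gene_id = gid, var_class = cl,
                      chrom = rep(gene_chrom, n_sites),
                      pos = pos_offset + seq_len(n),
                      ref = if (is_indel) "AT" else "A",
                      alt = if (is_indel) "A" else "G",
                      mu_rate = if (is_indel) NA_real_ else
                        rlnorm(n, spec$rate_meanlog, spec$rate_sdlog),
                      rate_quality = TRUE, popmax_af = NA_real_,
                      stringsAsFactors = FALSE)
      for (pr in spec$cs_predictors) d[[pr]] <- NA_real_
      d$cadd <- NA_real_
      d$spliceai <- NA_real_
      if (cl == "CS") {
        k <- length(spec$cs_predictors)
        sigma <- matrix(spec$cs_cor, k, k)
        diag(sigma) <- 1
        z <- matrix(rnorm(n * k), n, k) %*% chol(sigma)
        u <- pnorm(z)
        for (j in seq_len(k)) d[[spec$cs_predictors[j]]] <- u[, j]
        d$cadd <- runif(n) * 40
      } else if (cl == "CI") {
        d$cadd <- runif(n) * 40
      } else {
        d$spliceai <- runif(n)
      }
      parts[[cl]] <- d
      pos_offset <- pos_offset + n
    }
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  })
}

site_mass <- function(genome) {
  ifelse(genome$var_class %in% c("CI", "II"), 1, genome$mu_rate)
}

#' Simulate a null de novo cohort
#'
#' Per proband and variant class the de novo count is Poisson around the
#' class mean (optionally modulated log-linearly by paternal age); each
#' event lands on a possible site with probability proportional to its
#' rate mass. No gene carries signal.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param genome a [simulate_genome()] table.
#' @param seed optional override of `spec$seed` (so several cohorts can be
#'   drawn over one genome).
#' @return list with `records` (de novo record rows), `counts`
#'   (individual-by-class matrix of simulated event counts, before any
#'   possible-space qualification), and `trios` (ids and parental ages).
#' @export
simulate_null_dn_cohort <- function(spec, genome, seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  with_seed(seed, {
    ids <- sprintf("P%04d", seq_len(spec$n_trios))
    fams <- sprintf("F%04d", seq_len(spec$n_trios))
    father_age <- round(rnorm(spec$n_trios, 33, 6))
    mother_age <- round(rnorm(spec$n_trios, 31, 5))
    counts <- matrix(0L, spec$n_trios, length(VARIANT_CLASSES),
                     dimnames = list(ids, VARIANT_CLASSES))
    recs <- list()
    mass <- site_mass(genome)
    for (cl in VARIANT_CLASSES) {
      lam <- spec$dnm_mean[[cl]] *
        exp(spec$age_slope * (father_age - mean(father_age)))
      n_j <- rpois(spec$n_trios, lam)
      counts[, cl] <- n_j
      tot <- sum(n_j)
      if (tot == 0) next
      rows <- which(genome$var_class == cl)
      picked <- rows[sample.int(length(rows), tot, replace = TRUE,
                                prob = mass[rows])]
      r <- genome[picked, , drop = FALSE]
      r$individual_id <- rep(ids, n_j)
      r$family_id <- rep(fams, n_j)
      recs[[cl]] <- r
    }
    records <- do.call(rbind, recs)
    rownames(records) <- NULL
    list(records = records, counts = counts,
         trios = data.frame(family_id = fams, individual_id = ids,
                            father_age = father_age,
                            mother_age = mother_age,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate phased inherited rare variants for a cohort
#'
#' Per proband, parent, and class, the transmitted rare-variant count is
#' negative binomial around the class mean; variants are placed
#' rate-proportionally and independently per parent, so compound
#' heterozygous configurations arise purely by coincidence in genes.
#'
#' @inheritParams simulate_null_dn_cohort
#' @return list with `variants` (phased rows: `individual_id`, `gene_id`,
#'   `parent_of_origin`, `zygosity`, site columns) and `counts` (list of
#'   maternal/paternal individual-by-class matrices of simulated counts).
#' @export
simulate_inherited_cohort <- function(spec, genome,
                                      seed = spec$seed + 2L) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  with_seed(seed, {
    ids <- sprintf("P%04d", seq_len(spec$n_trios))
    mass <- site_mass(genome)
    nm <- matrix(0L, spec$n_trios, length(VARIANT_CLASSES),
                 dimnames = list(ids, VARIANT_CLASSES))
    nd <- nm
    rows_all <- list()
    for (origin in c("M", "D")) {
      for (cl in VARIANT_CLASSES) {
        mu <- spec$inherited_mean[[cl]]
        if (mu == 0) next
        n_j <- rnbinom(spec$n_trios, size = spec$inherited_size, mu = mu)
        if (origin == "M") nm[, cl] <- n_j else nd[, cl] <- n_j
        tot <- sum(n_j)
        if (tot == 0) next
        rows <- which(genome$var_class == cl)
        picked <- rows[sample.int(length(rows), tot, replace = TRUE,
                                  prob = mass[rows])]
        r <- genome[picked, , drop = FALSE]
        r$individual_id <- rep(ids, n_j)
        r$parent_of_origin <- origin
        r$zygosity <- "het"
        rows_all[[paste(origin, cl)]] <- r
      }
    }
    variants <- do.call(rbind, rows_all)
    rownames(variants) <- NULL
    list(variants = variants,
         counts = list(maternal = nm, paternal = nd))
  })
}

#' Spike causal signal into a simulated cohort
#'
#' Adds de novo events (or one in-trans inherited pair per carrier) at
#' sites in the top score quantile of the target gene, with truth labels
#' for recovery and enrichment testing. The added rows are returned so
#' removing them restores the null cohort exactly.
#'
#' @param cohort a [simulate_null_dn_cohort()] (mode `"dn"`) or
#'   [simulate_inherited_cohort()] (mode `"comphet"`) result.
#' @param genome the matching genome table.
#' @param gene target gene id.
#' @param carriers number of probands to modify.
#' @param score_quantile sites at or above this quantile of the gene's
#'   score distribution are eligible.
#' @param mode `"dn"` or `"comphet"`.
#' @param var_class class of the spiked variants (default CS).
#' @param predictor score column defining the quantile.
#' @param seed RNG seed.
#' @return list with the modified `cohort`, `truth` labels, and the
#'   `added` rows.
#' @export
spike_in <- function(cohort, genome, gene, carriers,
                     score_quantile = 0.99, mode = c("dn", "comphet"),
                     var_class = "CS", predictor = "alphamissense",
                     seed = 1L) {
  mode <- match.arg(mode)
  with_seed(seed, {
    sub <- genome[genome$gene_id == gene & genome$var_class == var_class &
                    !is.na(genome[[predictor]]), , drop = FALSE]
    if (nrow(sub) == 0) stop("gene ", gene, " has no ", var_class,
                             " sites with ", predictor, " scores")
    cut <- quantile(sub[[predictor]], score_quantile, names = FALSE)
    top <- sub[sub[[predictor]] >= cut, , drop = FALSE]
    if (nrow(top) == 0) stop("no sites at or above the score quantile")
    if (mode == "dn") {
      ids <- rownames(cohort$counts)
      stopifnot(carriers <= length(ids))
      who <- sample(ids, carriers)
      add <- top[sample.int(nrow(top), carriers, replace = TRUE), ,
                 drop = FALSE]
      add$individual_id <- who
      add$family_id <- cohort$records$family_id[
        match(who, cohort$records$individual_id)]
      add$family_id[is.na(add$family_id)] <- paste0("F_", who)
      cohort$records <- rbind(cohort$records, add)
      cohort$counts[who, var_class] <- cohort$counts[who, var_class] + 1L
    } else {
      ids <- rownames(cohort$counts$maternal)
      stopifnot(carriers <= length(ids))
      who <- sample(ids, carriers)
      am <- top[sample.int(nrow(top), carriers, replace = TRUE), ,
                drop = FALSE]
      ad <- top[sample.int(nrow(top), carriers, replace = TRUE), ,
                drop = FALSE]
      am$individual_id <- who; am$parent_of_origin <- "M"
      ad$individual_id <- who; ad$parent_of_origin <- "D"
      am$zygosity <- "het"; ad$zygosity <- "het"
      add <- rbind(am, ad)
      cohort$variants <- rbind(cohort$variants, add)
      cohort$counts$maternal[who, var_class] <-
        cohort$counts$maternal[who, var_class] + 1L
      cohort$counts$paternal[who, var_class] <-
        cohort$counts$paternal[who, var_class] + 1L
    }
    if (mode == "dn") rownames(cohort$records) <- NULL else
      rownames(cohort$variants) <- NULL
    list(cohort = cohort,
         truth = data.frame(individual_id = who, gene_id = gene,
                            stringsAsFactors = FALSE),
         added = add)
  })
}
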