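# Shared fixtures and Monte Carlo oracles, all built in code.

# Three-site single-gene index used by the worked target examples.
toy_gene_sites <- function() {
  data.frame(gene_id = "g1", var_class = "CS",
             mu_rate = c(0.3, 0.5, 0.2), rate_quality = TRUE,
             popmax_af = NA_real_, alphamissense = c(0.9, 0.5, 0.1),
             stringsAsFactors = FALSE)
}

toy_registry <- function() predictor_registry(cs = "alphamissense")

# Single-class index whose gene targets are the supplied per-gene rates.
# sites get scores 1..n per gene (rate vectors ordered low->high score).
index_from_rates <- function(rates_by_gene, normalize = TRUE) {
  rows <- do.call(rbind, lapply(names(rates_by_gene), function(g) {
    r <- rates_by_gene[[g]]
    data.frame(gene_id = g, var_class = "CS", mu_rate = r,
               rate_quality = TRUE, popmax_af = NA_real_,
               alphamissense = seq_along(r), stringsAsFactors = FALSE)
  }))
  genome_index(rows, toy_registry(), normalize = normalize)
}

# Small synthetic cohort spec used across module tests.
small_spec <- function(seed, n_genes = 120L, n_trios = 40L) {
  synthetic_cohort_spec(n_genes = n_genes, n_trios = n_trios, seed = seed,
                        sites_per_class = c(CS = 40, CI = 12,
                                            IS = 90, II = 25))
}

# Monte Carlo oracle for the Poisson/Irwin-Hall mixture at the statistic
# level: K ~ Pois(lambda), y | K a sum of K uniforms.
mc_mixture <- function(y_obs, lambda, n = 1e6, seed = 1) {
  withr::with_seed(seed, {
    k <- rpois(n, lambda)
    tot <- sum(k)
    grp <- rep.int(seq_len(n), k)
    ysim <- numeric(n)
    if (tot > 0) {
      s <- rowsum(runif(tot), grp)
      ysim[as.integer(rownames(s))] <- s[, 1]
    }
    p_raw <- mean(k >= 1 & ysim >= y_obs)
    list(p_raw = p_raw, se = sqrt(p_raw * (1 - p_raw) / n),
         p_conditional = p_raw / mean(k >= 1))
  })
}

# Site-level resampling oracle for the de novo test on one gene: events
# are redrawn at positions proportional to site rates; the residual is
# the suffix-mass ratio of the drawn site.
mc_dn_site_oracle <- function(rates, scores, y_obs, lambda, n = 1e6,
                              seed = 1) {
  o <- order(scores)
  r <- rates[o]
  suffix <- rev(cumsum(rev(r)))
  resid_site <- 1 - suffix / sum(r)
  withr::with_seed(seed, {
    k <- rpois(n, lambda)
    tot <- sum(k)
    grp <- rep.int(seq_len(n), k)
    ysim <- numeric(n)
    if (tot > 0) {
      idx <- sample.int(length(r), tot, replace = TRUE, prob = r)
      s <- rowsum(resid_site[idx], grp)
      ysim[as.integer(rownames(s))] <- s[, 1]
    }
    p_raw <- mean(k >= 1 & ysim >= y_obs)
    list(p_raw = p_raw, se = sqrt(p_raw * (1 - p_raw) / n))
  })
}

# Site-level resampling oracle for the compound het test on one gene:
# configurations are redrawn as independent rate-proportional maternal and
# paternal sites; the residual is 1 - max(suffix_M, suffix_D)^2 / mu_g^2.
mc_ch_site_oracle <- function(rates, scores, y_obs, lambda, n = 1e6,
                              seed = 1) {
  o <- order(scores)
  r <- rates[o]
  u_site <- rev(cumsum(rev(r))) / sum(r)
  withr::with_seed(seed, {
    k <- rpois(n, lambda)
    tot <- sum(k)
    grp <- rep.int(seq_len(n), k)
    ysim <- numeric(n)
    if (tot > 0) {
      im <- sample.int(length(r), tot, replace = TRUE, prob = r)
      id <- sample.int(length(r), tot, replace = TRUE, prob = r)
      resid <- 1 - pmax(u_site[im], u_site[id])^2
      s <- rowsum(resid, grp)
      ysim[as.integer(rownames(s))] <- s[, 1]
    }
    p_raw <- mean(k >= 1 & ysim >= y_obs)
    list(p_raw = p_raw, se = sqrt(p_raw * (1 - p_raw) / n))
  })
}

# Long-format trio rows for one family: 8 de novo candidates of which
# exactly five fail one filter each (GQ, popmax AF, proband VAF, parental
# alt depth, caller posterior) and three survive.
toy_trio_rows <- function() {
  n <- 8
  base_site <- function(role, id, depth, gq, alt) {
    data.frame(family_id = "F1", role = role, individual_id = id,
               chrom = as.character(1:n), pos = 1000 + 1:n,
               ref = "A", alt = "G", genotype = NA_character_,
               depth = depth, GQ = gq, alt_depth = alt,
               stringsAsFactors = FALSE)
  }
  pb <- base_site("proband", "kid", depth = rep(50, n), gq = rep(99, n),
                  alt = rep(25, n))
  mo <- base_site("mother", "mom", depth = rep(50, n), gq = rep(99, n),
                  alt = rep(0, n))
  fa <- base_site("father", "dad", depth = rep(50, n), gq = rep(99, n),
                  alt = rep(0, n))
  pb$gene_id <- paste0("g", 1:n)
  pb$var_class <- "CS"
  pb$rate_quality <- TRUE
  pb$popmax_af <- NA_real_
  pb$topmed_af <- NA_real_
  pb$dn_posterior <- 0.99
  pb$alphamissense <- 0.5
  # candidate 2: proband GQ fails (20 is not > 20)
  pb$GQ[2] <- 20
  # candidate 3: common variant
  pb$popmax_af[3] <- 0.02
  # candidate 4: low proband allele fraction (10/50 = 0.2 is not > 0.2)
  pb$alt_depth[4] <- 10
  # candidate 5: mother carries 2 alternate reads
  mo$alt_depth[5] <- 2
  # candidate 6: weak caller posterior (0.7 is not > 0.7)
  pb$dn_posterior[6] <- 0.7
  rbind(pb,
        cbind(mo, pb[, setdiff(names(pb), names(mo))]),
        cbind(fa, pb[, setdiff(names(pb), names(fa))]))
}
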