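# One-gene single-class index with chosen suffix masses:
# scores (1,2,3) -> suffix (total, mid, top).
one_gene_index <- function(rates, normalize = FALSE)
  index_from_rates(list(g = rates), normalize = normalize)

cfg_row <- function(m_score, d_score, id = "p1", gene = "g",
                    hom = FALSE) {
  data.frame(individual_id = id, gene_id = gene, is_homozygous = hom,
             m_class = "CS", m_chrom = "1", m_pos = 1,
             m_alphamissense = m_score,
             d_class = "CS", d_chrom = "1", d_pos = 2,
             d_alphamissense = d_score, stringsAsFactors = FALSE)
}

test_that("configuration target is the squared max of per-variant targets", {
  # suffix masses: score 3 -> 0.3, score 2 -> 0.4, total 1.0
  ix <- one_gene_index(c(0.6, 0.1, 0.3))
  expect_equal(comphet_target(cfg_row(3, 2), ix), 0.16)
  # homozygous: one allele, used on both sides
  ix2 <- one_gene_index(c(0.6, 0.2, 0.2))
  expect_equal(comphet_target(cfg_row(3, 3, hom = TRUE), ix2), 0.04)
  # with gene total 2.0, per-variant targets 0.3/0.4: the squared-target
  # ratio against mu_g^2 is 0.16 / 4 = 0.04
  ix3 <- one_gene_index(c(1.6, 0.1, 0.3))
  tgt <- comphet_target(cfg_row(3, 2), ix3)
  expect_equal(tgt, 0.16)
  expect_equal(tgt / gene_target(ix3, "g", "CS", "alphamissense")^2, 0.04)
})

test_that("cohort CH intensity conditions on parental counts", {
  # normalized target of gene g is 0.001
  ix <- index_from_rates(list(g = 1, h = 999))
  nm <- matrix(0, 2, 4, dimnames = list(c("p1", "p2"),
                                        c("CS", "CI", "IS", "II")))
  nd <- nm
  nm[, "CS"] <- c(100, 80); nd[, "CS"] <- c(120, 90)
  cfg <- cfg_row(1, 1)
  fit <- ramedies_ch(cfg, ix, list(maternal = nm, paternal = nd),
                     cs_predictors = "alphamissense")
  r <- fit$results
  expect_equal(r$lambda.alphamissense, 1e-6 * (100 * 120 + 80 * 90))
  # single configuration at vanishing lambda: p tends to the squared ratio
  ix2 <- index_from_rates(list(g = c(0.5, 0.45, 0.05), h = 1e6))
  nm2 <- nm[1, , drop = FALSE]; nd2 <- nd[1, , drop = FALSE]
  nm2[] <- 0; nd2[] <- 0; nm2[, "CS"] <- 1; nd2[, "CS"] <- 1
  fit2 <- ramedies_ch(cfg_row(3, 3), ix2,
                      list(maternal = nm2, paternal = nd2),
                      cs_predictors = "alphamissense")
  expect_equal(fit2$results$p_cauchy, 0.05^2, tolerance = 1e-4)
  expect_warning(ramedies_ch(cfg_row(1, 1)[0, ], ix,
                             list(maternal = nm, paternal = nd)),
                 "no compound")
})

test_that("genome rescaling of configuration targets is exact", {
  # hand-built squared-target landscape {0.04, 0.01}
  gst <- list(pairs = list("CS CS" = list(sorted = c(0.01, 0.04),
                                          cum = c(0.01, 0.05),
                                          total = 0.05)),
              total = 0.05)
  expect_equal(ind_rescaled_target(0.02, gst), (0.02 + 0.01) / 0.05)
  expect_equal(ind_rescaled_target(0.5, gst), 1)       # saturation
  expect_equal(ind_rescaled_target(0, gst), 0)
  # monotone in the raw target
  r <- sort(runif(50) * 0.06)
  expect_true(all(diff(ind_rescaled_target(r, gst)) >= 0))
})

test_that("rescaled targets from an index are invariant to rate rescaling", {
  rates <- list(a = c(2, 1), b = c(4, 3), c = 5)
  ix1 <- index_from_rates(rates)
  ix2 <- index_from_rates(lapply(rates, `*`, 7))
  g1 <- genome_squared_targets(ix1, "alphamissense")
  g2 <- genome_squared_targets(ix2, "alphamissense")
  raw <- c(1e-3, 0.05, 0.2)
  expect_equal(ind_rescaled_target(raw, g1), ind_rescaled_target(raw, g2))
})

test_that("individual-level probabilities follow the order-statistic form", {
  expect_equal(1 - (1 - 0.2)^3, 0.488)
  ix <- index_from_rates(list(g = c(0.5, 0.45, 0.05), h = c(7, 3)))
  nm <- matrix(0, 1, 4, dimnames = list("p1", c("CS", "CI", "IS", "II")))
  nm[, "CS"] <- 2
  cfg <- rbind(cfg_row(3, 2), cfg_row(1, 1, gene = "h"))
  cfg$m_alphamissense[2] <- 1; cfg$d_alphamissense[2] <- 1
  fit <- ramedies_ind(cfg, ix, list(maternal = nm, paternal = nm),
                      cs_predictors = "alphamissense")
  r <- fit$results
  expect_equal(r$K, 2L)
  expect_equal(r$p_given_K, 1 - (1 - r$y_tilde)^2)
  # closed-form mixture equals the truncated sum
  lam <- r$lambda_tilde; y <- r$y_tilde
  ks <- 1:200
  direct <- sum((1 - (1 - y)^ks) * dpois(ks, lam)) / (1 - dpois(0, lam))
  expect_equal(r$p_overall, direct, tolerance = 1e-12)
})

test_that("multiple configurations per gene reduce to the smallest target", {
  ix <- index_from_rates(list(g = c(0.5, 0.45, 0.05), h = c(7, 3)))
  nm <- matrix(1, 1, 4, dimnames = list("p1", c("CS", "CI", "IS", "II")))
  cfg <- rbind(cfg_row(3, 3), cfg_row(1, 1))
  expect_message(
    fit <- ramedies_ind(cfg, ix, list(maternal = nm, paternal = nm),
                        cs_predictors = "alphamissense"),
    "dropped")
  expect_equal(fit$results$K, 1L)
  tgt <- comphet_target(cfg, ix, "alphamissense")
  gst <- genome_squared_targets(ix, "alphamissense")
  expect_equal(fit$results$y_tilde,
               ind_rescaled_target(min(tgt), gst))
})

test_that("ranking is deterministic and permutation invariant", {
  res <- data.frame(individual_id = c("b", "a", "c", "d"),
                    best_gene = c("g2", "g1", "g3", "g1"),
                    y_tilde = c(0.5, 0.1, 0.1, 0.3),
                    p_overall = c(0.5, 0.01, 0.01, 0.5))
  r1 <- rank_cohort(res)
  expect_equal(r1$individual_id, c("a", "c", "d", "b"))
  withr::with_seed(2, {
    r2 <- rank_cohort(res[sample(4), ])
  })
  expect_equal(r1$individual_id, r2$individual_id)
  expect_equal(rank_cohort(r1)$individual_id, r1$individual_id)
})

test_that("diagnostic enrichment matches enumeration and handles edges", {
  e <- diagnosis_enrichment(c(TRUE, TRUE, FALSE, FALSE), n_perm = 500,
                            seed = 3)
  expect_equal(e$min_fisher_p, 1 / 6, tolerance = 1e-12)
  expect_equal(e$best_k, 2L)
  expect_equal(diagnosis_enrichment(rep(FALSE, 5))$permutation_p, 1)
  expect_equal(diagnosis_enrichment(rep(TRUE, 5))$min_fisher_p, 1)
  # permutation p is conservative-uniform for random labels
  withr::with_seed(8, {
    ps <- replicate(60, {
      lab <- sample(c(rep(TRUE, 3), rep(FALSE, 9)))
      diagnosis_enrichment(lab, n_perm = 200, seed = sample.int(1e6, 1))$
        permutation_p
    })
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.9)
})

test_that("false-positive share follows the binomial model", {
  fp <- false_positive_estimate(5, 1.0, 100)
  expect_equal(fp$mean, 0.05)
  expect_equal(fp$prob_ge(1), 1 - (1 - 0.01)^5)
  expect_equal(false_positive_estimate(3, 0, 10)$prob_ge(1), 0)
  expect_equal(false_positive_estimate(4, 50, 10)$mean, 4)  # capped
  expect_error(false_positive_estimate(2, -1, 10), "nonnegative")
})

test_that("squared max of two in-gene uniform draws is uniform", {
  withr::with_seed(19, {
    n <- 3000
    rate <- rexp(n)
    score <- runif(n)
    suffix <- rev(cumsum(rev(rate[order(score)])))
    u_site <- (suffix / sum(rate))[rank(score)]
    im <- sample.int(n, 2e4, replace = TRUE, prob = rate)
    id <- sample.int(n, 2e4, replace = TRUE, prob = rate)
    u <- pmax(u_site[im], u_site[id])^2
    expect_gt(suppressWarnings(ks.test(u, "punif"))$p.value, 0.001)
  })
})
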