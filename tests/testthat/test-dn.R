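test_that("per-gene statistic sums uniform target residuals", {
  # suffix masses: score 3 -> 0.05, score 2 -> 0.5, score 1 -> 1.0
  ix <- index_from_rates(list(g = c(0.5, 0.45, 0.05)))
  assign <- list(CS = "alphamissense")
  rec <- function(scores)
    data.frame(individual_id = paste0("p", seq_along(scores)),
               gene_id = "g", var_class = "CS", alphamissense = scores)
  one <- dn_gene_statistic(rec(3), ix, assign)
  expect_equal(one$y_prime, 0.95)
  expect_equal(sum(one$K_per_class), 1)
  two <- dn_gene_statistic(rec(c(3, 2)), ix, assign)
  expect_equal(two$y_prime, 1.45)
  # a variant at the gene's lowest possible score contributes nothing
  low <- dn_gene_statistic(rec(1), ix, assign)
  expect_equal(low$y_prime, 0)
})

test_that("Poisson intensity composes targets with cohort counts", {
  # two-gene genome; normalized target of gene a is 0.001
  ix <- index_from_rates(list(a = 1, b = 999))
  assign <- list(CS = "alphamissense")
  expect_equal(dn_lambda("a", ix, c(CS = 200), assign), 0.2)
  expect_equal(dn_lambda("a", ix, c(CS = 0), assign), 0)
  # additivity across classes
  spec <- small_spec(seed = 41)
  g <- simulate_genome(spec)
  ix2 <- genome_index(g, predictor_registry(cs = spec$cs_predictors))
  a2 <- list(CS = "alphamissense", CI = "cadd")
  cnt <- c(CS = 100, CI = 40)
  lam_both <- dn_lambda("g0001", ix2, cnt, a2)
  lam_cs <- dn_lambda("g0001", ix2, cnt["CS"], a2["CS"])
  lam_ci <- dn_lambda("g0001", ix2, cnt["CI"], a2["CI"])
  expect_equal(lam_both, lam_cs + lam_ci)
})

test_that("cohort test limits, predictor dropout and Cauchy behavior", {
  # gene g is a vanishing share of the genome, so lambda -> 0 and the
  # single event's p tends to its in-gene target ratio
  ix <- index_from_rates(list(g = c(0.5, 0.45, 0.05), h = 1e6))
  dn <- data.frame(individual_id = "p1", gene_id = "g", var_class = "CS",
                   alphamissense = 3)
  fit <- ramedies_dn(dn, ix, counts = c(CS = 1), mode = "missense",
                     cs_predictors = "alphamissense")
  r <- fit$results
  expect_equal(r$p_cauchy, 0.05, tolerance = 1e-4)
  # identical p's across predictors combine to themselves
  expect_equal(cauchy_combine(rep(0.0375, 4)), 0.0375, tolerance = 1e-12)
  # a gene missing one predictor's scores is tested under the others only
  sites <- rbind(toy_gene_sites(),
                 within(toy_gene_sites(), gene_id <- "g2"))
  sites$primateai3d <- sites$alphamissense
  sites$primateai3d[sites$gene_id == "g2"] <- NA
  ix2 <- genome_index(sites, predictor_registry(
    cs = c("alphamissense", "primateai3d")))
  dn2 <- data.frame(individual_id = c("p1", "p2"),
                    gene_id = c("g1", "g2"), var_class = "CS",
                    alphamissense = 0.9, primateai3d = 0.9)
  fit2 <- suppressWarnings(ramedies_dn(dn2, ix2, mode = "missense"))
  r2 <- fit2$results
  expect_true(is.na(r2$p_cond.primateai3d[r2$gene_id == "g2"]))
  expect_false(is.na(r2$p_cond.alphamissense[r2$gene_id == "g2"]))
  expect_false(is.na(r2$p_cauchy[r2$gene_id == "g2"]))
  expect_warning(ramedies_dn(dn[0, ], ix), "no qualifying")
})

test_that("constraint weights follow the decile dominant-gene fraction", {
  withr::with_seed(9, {
    genes <- sprintf("G%04d", 1:1000)
    cons <- setNames(runif(1000), genes)
    # 100 dominant genes spread 10 per decile: all weights exactly 1
    ord <- names(sort(cons))
    dd_even <- unlist(lapply(0:9, function(b) ord[b * 100 + 1:10]))
    w <- constraint_weights(cons, dd_even)
    expect_equal(w$weight, rep(1, 1000))
    # 30 of 100 dominant genes in one bin: its genes get weight 3
    dd_skew <- c(ord[1:30], ord[101 + 1:70])
    w2 <- constraint_weights(cons, dd_skew)
    expect_equal(unique(w2$weight[match(ord[1:100], w2$gene_id)]), 3.0)
    # genes without a constraint value get weight 1
    cons2 <- cons; cons2[5] <- NA
    w3 <- constraint_weights(cons2, dd_skew)
    expect_equal(w3$weight[5], 1)
    expect_true(is.na(w3$bin[5]))
    # mean weight over scored genes is exactly 1
    expect_lt(abs(mean(w2$weight) - 1), 1e-9)
  })
  expect_warning(constraint_weights(setNames(runif(5), letters[1:5]),
                                    "a"), "fewer than 10")
  expect_warning(constraint_weights(setNames(runif(20), letters[1:20]),
                                    character(0)), "all weights")
})

test_that("weighted FDR equals plain BH at unit weights and divides Q", {
  withr::with_seed(31, {
    p <- runif(40)
    expect_equal(weighted_fdr(p, 1)$Q_adj, p.adjust(p, "BH"))
    expect_equal(weighted_fdr(0.01, 2)$Q, 0.005)
    # raising one gene's weight never worsens its adjusted Q
    for (i in 1:10) {
      w <- rexp(40) + 0.1
      j <- sample(40, 1)
      w2 <- w; w2[j] <- 2 * w[j]
      expect_lte(weighted_fdr(p, w2)$Q_adj[j], weighted_fdr(p, w)$Q_adj[j])
    }
  })
})

test_that("null cohort gives uniform conditional p-values per gene", {
  spec <- small_spec(seed = 53, n_genes = 250, n_trios = 60)
  g <- simulate_genome(spec)
  ix <- genome_index(g, predictor_registry(cs = spec$cs_predictors))
  dn <- simulate_null_dn_cohort(spec, g)
  fit <- ramedies_dn(dn$records, ix, mode = "genome",
                     cs_predictors = "alphamissense")
  p <- fit$results$p_cond.alphamissense
  p <- p[!is.na(p)]
  expect_gt(length(p), 200)
  expect_gt(ks.test(p, "punif")$p.value, 0.001)
})
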