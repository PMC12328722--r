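test_that("generators are pure functions of spec and seed", {
  spec <- small_spec(seed = 71, n_genes = 60, n_trios = 15)
  expect_identical(simulate_genome(spec), simulate_genome(spec))
  g <- simulate_genome(spec)
  a <- simulate_null_dn_cohort(spec, g)
  b <- simulate_null_dn_cohort(spec, g)
  expect_identical(a$records, b$records)
  expect_identical(simulate_inherited_cohort(spec, g)$variants,
                   simulate_inherited_cohort(spec, g)$variants)
  expect_error(synthetic_cohort_spec(n_genes = 10), "seed")
})

test_that("simulated site rates follow the specified log-normal", {
  spec <- small_spec(seed = 72, n_genes = 200, n_trios = 5)
  g <- simulate_genome(spec)
  r <- g$mu_rate[g$var_class == "CS"]
  expect_gt(ks.test(log(r), "pnorm", spec$rate_meanlog,
                    spec$rate_sdlog)$p.value, 0.001)
  expect_true(all(is.na(g$mu_rate[g$var_class %in% c("CI", "II")])))
  # (chrom, pos) keys are unique so trio VCF rows are well defined
  expect_false(any(duplicated(paste(g$chrom, g$pos))))
})

test_that("null cohorts have the configured count structure", {
  spec <- small_spec(seed = 73, n_genes = 150, n_trios = 120)
  g <- simulate_genome(spec)
  dn <- simulate_null_dn_cohort(spec, g)
  for (cl in c("CS", "IS")) {
    m <- mean(dn$counts[, cl])
    se <- sqrt(spec$dnm_mean[[cl]] / nrow(dn$counts))
    expect_lt(abs(m - spec$dnm_mean[[cl]]), 3 * se + 1e-9)
  }
  # per-gene hit counts are proportional to gene targets
  ix <- genome_index(g, predictor_registry(cs = spec$cs_predictors))
  mu <- gene_targets(ix, "IS", "spliceai")
  rec <- dn$records[dn$records$var_class == "IS" &
                      dn$records$spliceai >= 0.05, ]
  obs <- table(factor(rec$gene_id, names(mu)))
  expected <- mu * sum(obs)
  chi <- sum((as.integer(obs) - expected)^2 / expected)
  expect_gt(pchisq(chi, length(mu) - 1, lower.tail = FALSE), 1e-4)
})

test_that("inherited cohorts reproduce the analytic coincidence rate", {
  spec <- synthetic_cohort_spec(n_genes = 400, n_trios = 150, seed = 74,
                                sites_per_class = c(CS = 40, CI = 12,
                                                    IS = 90, II = 25),
                                inherited_mean = c(CS = 12, CI = 4,
                                                   IS = 40, II = 8))
  g <- simulate_genome(spec)
  ix <- genome_index(g, predictor_registry(cs = spec$cs_predictors))
  inh <- simulate_inherited_cohort(spec, g)
  cc <- cohort_comphets(inh$variants)
  fit <- ramedies_ch(cc$configs, ix, cc$counts,
                     cs_predictors = "alphamissense")
  r <- fit$results
  ratio <- sum(r$K) / sum(r$lambda.alphamissense)
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.2)
  # zero-mean classes yield no variants
  spec0 <- synthetic_cohort_spec(n_genes = 50, n_trios = 5, seed = 75,
                                 inherited_mean = c(CS = 5, CI = 0,
                                                    IS = 5, II = 0))
  inh0 <- simulate_inherited_cohort(spec0, simulate_genome(spec0))
  expect_false(any(inh0$variants$var_class %in% c("CI", "II")))
})

test_that("spike-ins label carriers, sit in the top quantile, and revert", {
  spec <- small_spec(seed = 76, n_genes = 80, n_trios = 40)
  g <- simulate_genome(spec)
  dn <- simulate_null_dn_cohort(spec, g)
  sp <- spike_in(dn, g, gene = "g0010", carriers = 5, seed = 5)
  expect_equal(nrow(sp$truth), 5)
  expect_equal(nrow(sp$cohort$records), nrow(dn$records) + 5)
  cut <- quantile(g$alphamissense[g$gene_id == "g0010" &
                                    g$var_class == "CS"], 0.99)
  expect_true(all(sp$added$alphamissense >= cut))
  # removing the added rows restores the null cohort exactly
  restored <- sp$cohort$records[seq_len(nrow(dn$records)), ]
  expect_identical(restored, dn$records)
  expect_error(spike_in(dn, g, gene = "nope", carriers = 2),
               "no CS sites")
})

test_that("emitted trio VCFs round-trip through ingestion", {
  skip_if_not_installed("vcfR")
  spec <- small_spec(seed = 78, n_genes = 40, n_trios = 3)
  g <- simulate_genome(spec)
  dn <- simulate_null_dn_cohort(spec, g)
  dir <- file.path(tempdir(), "vcfsim")
  out <- emit_trio_vcf(dn, spec, dir)
  ped <- read_ped(out$ped)
  expect_equal(nrow(ped), 9)
  got <- list()
  for (fam in names(out$vcf)) {
    rows <- read_trio_vcf(out$vcf[[fam]],
                          ped[ped$family_id == fam, ])
    fd <- filter_de_novo(rows)
    got[[fam]] <- fd$records
  }
  rec <- do.call(rbind, got)
  # zero-noise ingestion recovers the simulated record set exactly
  key <- function(d) sort(paste(d$chrom, d$pos, d$gene_id, d$var_class))
  expect_equal(key(rec), key(dn$records))
})

test_that("configured filter-failure fractions are honored", {
  skip_if_not_installed("vcfR")
  spec <- small_spec(seed = 79, n_genes = 60, n_trios = 8)
  g <- simulate_genome(spec)
  dn <- simulate_null_dn_cohort(spec, g)
  dir <- file.path(tempdir(), "vcfnoise")
  out <- emit_trio_vcf(dn, spec, dir, fail_frac = c(gq = 0.1))
  ped <- read_ped(out$ped)
  n_pass <- 0L
  for (fam in names(out$vcf)) {
    rows <- read_trio_vcf(out$vcf[[fam]], ped[ped$family_id == fam, ])
    fd <- filter_de_novo(rows)
    n_pass <- n_pass + nrow(fd$records)
  }
  n <- nrow(dn$records)
  se <- sqrt(n * 0.1 * 0.9)
  expect_lt(abs((n - n_pass) - 0.1 * n), 3 * se + 1e-9)
})
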