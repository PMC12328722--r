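test_that("de novo filters keep the hand-derived survivor set", {
  rows <- toy_trio_rows()
  out <- filter_de_novo(rows)
  expect_equal(sort(out$records$gene_id), c("g1", "g7", "g8"))
  expect_equal(sum(out$audit$first_fail == "pass"), 3)
  aud <- out$audit
  expect_equal(aud$first_fail[order(as.integer(aud$chrom))],
               c("pass", "GQ", "popmax_af", "proband_vaf",
                 "parent_alt_depth", "dn_posterior", "pass", "pass"))
  # every excluded candidate carries exactly one failing rule
  expect_true(all(out$audit$first_fail != ""))
})

test_that("boundary values follow the printed strict inequalities", {
  rows <- toy_trio_rows()
  # depth exactly 10 in the mother: not > 10, excluded
  rows$depth[rows$role == "mother" & rows$chrom == "1"] <- 10
  out <- filter_de_novo(rows)
  expect_equal(out$audit$first_fail[out$audit$chrom == "1"], "depth")
  rows2 <- toy_trio_rows()
  rows2$depth[rows2$role == "proband" & rows2$chrom == "1"] <- 11
  rows2$GQ[rows2$role == "proband" & rows2$chrom == "1"] <- 21
  rows2$alt_depth[rows2$role == "proband" & rows2$chrom == "1"] <- 5
  # depth 11, GQ 21, alt 5, VAF 5/11 > 0.2, posterior 0.99: survives
  out2 <- filter_de_novo(rows2)
  expect_true("g1" %in% out2$records$gene_id)
  # chrX candidates are never de novo candidates here
  rows3 <- toy_trio_rows()
  rows3$chrom[rows3$chrom == "1"] <- "chrX"
  out3 <- filter_de_novo(rows3)
  expect_equal(out3$audit$first_fail[out3$audit$chrom == "chrX"],
               "autosome")
})

test_that("filtering is order-independent", {
  rows <- toy_trio_rows()
  withr::with_seed(4, {
    shuf <- rows[sample(nrow(rows)), ]
  })
  a <- filter_de_novo(rows)
  b <- filter_de_novo(shuf)
  expect_equal(a$records[order(a$records$gene_id), ],
               b$records[order(b$records$gene_id), ],
               ignore_attr = TRUE)
})

test_that("proband QC enforces the call-count cap and dedups families", {
  mk <- function(id, fam, n, chrom_start = 1) {
    data.frame(family_id = fam, individual_id = id,
               chrom = "1", pos = chrom_start + seq_len(n),
               ref = "A", alt = "G", stringsAsFactors = FALSE)
  }
  rec <- rbind(mk("p_heavy", "f1", 151), mk("p_ok", "f2", 150),
               mk("sib1", "f3", 5, 1000), mk("sib2", "f3", 5, 2000))
  # one shared de novo between the f3 siblings
  rec$pos[rec$individual_id == "sib2"][1] <-
    rec$pos[rec$individual_id == "sib1"][1]
  q <- proband_qc(rec)
  qc <- q$qc
  expect_true(qc$excluded[qc$individual_id == "p_heavy"])   # 151 > 150
  expect_false(qc$excluded[qc$individual_id == "p_ok"])     # exactly 150
  # sibling selection keeps the lowest id; shared variant dropped entirely
  expect_false(qc$excluded[qc$individual_id == "sib1"])
  expect_true(qc$excluded[qc$individual_id == "sib2"])
  kept <- q$records[q$records$family_id == "f3", ]
  expect_equal(nrow(kept), 4)                 # 5 minus the shared variant
  expect_true(all(kept$individual_id == "sib1"))
  # override selects the other sibling
  q2 <- proband_qc(rec, proband_override = c(f3 = "sib2"))
  expect_true(q2$qc$excluded[q2$qc$individual_id == "sib1"])
})

test_that("consanguinity gate applies every relatedness rule", {
  base <- data.frame(family_id = "f", kinship_parents = 0.01,
                     kinship_mother_child = 0.5,
                     kinship_father_child = 0.5,
                     ibd_mother_child = 20, ibd_father_child = 20,
                     max_parent_ibd_mb = 0.5)
  expect_true(consanguinity_gate(base)$pass)
  cases <- list(
    c("kinship_parents", 0.2, "parent-parent kinship"),
    c("kinship_mother_child", 0.4, "mother-child"),
    c("kinship_father_child", 0.65, "father-child"),
    c("ibd_mother_child", 0, "no mother-child"),
    c("max_parent_ibd_mb", 4, "IBD segment > 3 Mb"))
  for (cs in cases) {
    x <- base
    x[[cs[1]]] <- as.numeric(cs[2])
    g <- consanguinity_gate(x)
    expect_false(g$pass)
    expect_match(g$reason, cs[3])
  }
  x <- base; x$max_parent_ibd_mb <- NA
  expect_false(consanguinity_gate(x)$pass)    # missing IBD data fails
})

test_that("comphet detection pairs in trans and flags homozygotes", {
  v <- function(gene, origin, zyg = "het", pos = 1, spliceai = NA,
                cls = "CS") {
    data.frame(individual_id = "p1", gene_id = gene,
               parent_of_origin = origin, var_class = cls,
               chrom = "1", pos = pos, ref = "A", alt = "G",
               zygosity = zyg, popmax_af = NA_real_,
               alphamissense = 0.5, spliceai = spliceai,
               stringsAsFactors = FALSE)
  }
  r <- detect_comphets(rbind(v("g1", "M", pos = 1), v("g1", "D", pos = 2)))
  expect_equal(nrow(r$configs), 1)
  expect_false(r$configs$is_homozygous)
  # two maternal variants never form a configuration
  r2 <- detect_comphets(rbind(v("g1", "M", 1), v("g1", "M", pos = 2)))
  expect_equal(nrow(r2$configs), 0)
  expect_equal(unname(r2$counts$maternal[1, "CS"]), 2L)
  # homozygous recessive site: one configuration, counted on both sides
  r3 <- detect_comphets(v("g1", NA, zyg = "hom"))
  expect_equal(nrow(r3$configs), 1)
  expect_true(r3$configs$is_homozygous)
  expect_equal(unname(r3$counts$maternal[1, "CS"]), 1L)
  expect_equal(unname(r3$counts$paternal[1, "CS"]), 1L)
  # unphasable doubly-het sites are excluded and logged
  r4 <- detect_comphets(rbind(v("g1", NA), v("g1", "D", pos = 2)))
  expect_equal(nrow(r4$configs), 0)
  expect_equal(r4$n_unphased, 1L)
  # configurations per gene never exceed n_M x n_D
  r5 <- detect_comphets(rbind(v("g1", "M", 1), v("g1", "M", 2),
                              v("g1", "D", 3), v("g1", "D", 4),
                              v("g1", "D", 5)))
  expect_equal(nrow(r5$configs), 6)
  expect_lte(nrow(r5$configs),
             r5$counts$maternal[1, "CS"] * r5$counts$paternal[1, "CS"])
  # intronic variants under the splice floor drop from counts and pairs
  r6 <- detect_comphets(rbind(v("g1", "M", 1, cls = "IS",
                               spliceai = 0.01),
                              v("g1", "D", 2)))
  expect_equal(nrow(r6$configs), 0)
  expect_equal(unname(r6$counts$maternal[1, "IS"]), 0L)
})

test_that("parental-age diagnostics report dispersion near one", {
  withr::with_seed(77, {
    ages <- data.frame(father_age = round(rnorm(400, 33, 6)),
                       mother_age = round(rnorm(400, 31, 5)))
    lam <- exp(2 + 0.02 * (ages$father_age - 33))
    counts <- cbind(ages, dnm_count = rpois(400, lam),
                    individual_id = paste0("p", 1:400))
    fit <- parental_age_qc(counts)
    expect_lt(abs(fit$dispersion - 1), 0.25)
    expect_gt(fit$coefficients["father_age"], 0.01)
    # constant counts: no age effect
    counts2 <- counts; counts2$dnm_count <- 50
    fit2 <- parental_age_qc(counts2)
    expect_lt(abs(fit2$coefficients["father_age"]), 1e-6)
    expect_error(parental_age_qc(counts[1, ]), "too few")
    counts3 <- counts; counts3$father_age[1] <- NA
    expect_warning(expect_null(parental_age_qc(counts3)), "missing")
  })
})
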