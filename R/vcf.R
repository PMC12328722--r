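# Trio VCF adapter: thin translation between annotated trio VCFs and the
# canonical long-format trio rows. Annotations (gene, class, rates,
# scores, frequencies, caller posterior) must already be present as INFO
# fields; no external annotator is called. Coordinates are 1-based and
# multi-allelic sites must be pre-split.

#' Read a PED family-structure file
#'
#' @param path whitespace-separated PED file (family, individual, father,
#'   mother, sex, phenotype).
#' @return data.frame with those columns.
#' @export
read_ped <- function(path) {
  p <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  names(p) <- c("family_id", "individual_id", "father", "mother",
                "sex", "phenotype")[seq_len(ncol(p))]
  p
}

#' Read an annotated trio VCF into canonical trio rows
#'
#' Emits one row per (variant, trio member) with genotype, depth, GQ and
#' alternate depth, and the site annotation taken from INFO fields named
#' after the canonical columns (`gene_id`, `var_class`, `mu_rate`,
#' `rate_quality`, `popmax_af`, `topmed_af`, `dn_posterior`, score
#' columns). Roles are inferred from the PED (proband = affected child
#' whose two parents are samples in the file).
#'
#' @param vcf_path VCF file (plain or bgzipped).
#' @param ped a [read_ped()] data.frame.
#' @param score_cols INFO keys to carry through as score columns.
#' @return long-format data.frame suitable for [filter_de_novo()].
#' @export
read_trio_vcf <- function(vcf_path, ped,
                          score_cols = c("alphamissense", "primateai3d",
                                         "cadd", "revel", "spliceai")) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required to read VCF input")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE)))
    stop("multi-allelic sites must be pre-split")
  samples <- colnames(v@gt)[-1]
  kid <- ped$individual_id[ped$phenotype == 2 &
                             ped$father %in% samples &
                             ped$mother %in% samples]
  if (length(kid) != 1)
    stop("expected exactly one affected child with both parents present")
  roles <- c(proband = kid,
             mother = ped$mother[ped$individual_id == kid],
             father = ped$father[ped$individual_id == kid])
  fam <- ped$family_id[ped$individual_id == kid]

  info_keys <- c("gene_id", "var_class", "mu_rate", "rate_quality",
                 "popmax_af", "topmed_af", "dn_posterior", score_cols)
  info <- lapply(info_keys, function(k)
    suppressWarnings(vcfR::extract.info(v, element = k)))
  names(info) <- info_keys
  num_keys <- setdiff(info_keys, c("gene_id", "var_class", "rate_quality"))

  gt <- function(field, sample) {
    m <- vcfR::extract.gt(v, element = field, as.numeric = field != "GT")
    m[, sample]
  }
  ad_alt <- function(sample) {
    ad <- vcfR::extract.gt(v, element = "AD")[, sample]
    as.numeric(vapply(strsplit(ad, ","), function(x)
      if (length(x) >= 2) x[2] else NA_character_, character(1)))
  }
  out <- list()
  for (role in names(roles)) {
    s <- roles[[role]]
    d <- data.frame(family_id = fam, role = role, individual_id = s,
                    chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]),
                    ref = fix[, "REF"], alt = fix[, "ALT"],
                    genotype = gt("GT", s),
                    depth = gt("DP", s), GQ = gt("GQ", s),
                    alt_depth = ad_alt(s), stringsAsFactors = FALSE)
    d$gene_id <- info$gene_id
    d$var_class <- info$var_class
    d$rate_quality <- is.na(info$rate_quality) |
      info$rate_quality %in% c("1", "TRUE", "high")
    for (k in num_keys) d[[k]] <- suppressWarnings(as.numeric(info[[k]]))
    out[[role]] <- d
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Emit synthetic trio VCFs and a PED file
#'
#' Writes one VCF per simulated family holding the proband's de novo
#' candidate sites with trio genotypes (GT:DP:GQ:AD) and the site
#' annotation as INFO fields. Configured fractions of candidates are
#' given values that fail each de novo filter, to exercise ingestion
#' end to end; with all fractions zero, ingestion recovers the simulated
#' record set exactly.
#'
#' @param cohort a [simulate_null_dn_cohort()] result.
#' @param spec the matching [synthetic_cohort_spec()].
#' @param dir output directory.
#' @param fail_frac named fractions among `gq`, `maf`, `vaf`,
#'   `parent_alt`, `posterior` of candidates forced to fail that filter.
#' @param seed RNG seed for failure assignment.
#' @return list with `vcf` (paths per family) and `ped` path.
#' @export
emit_trio_vcf <- function(cohort, spec, dir,
                          fail_frac = c(gq = 0, maf = 0, vaf = 0,
                                        parent_alt = 0, posterior = 0),
                          seed = spec$seed + 3L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- cohort$records
  trios <- cohort$trios
  score_cols <- intersect(c(spec$cs_predictors, "cadd", "spliceai"),
                          names(rec))
  with_seed(seed, {
    draw <- function(f) {
      frac <- if (f %in% names(fail_frac)) fail_frac[[f]] else 0
      runif(nrow(rec)) < frac
    }
    fail_gq <- draw("gq"); fail_maf <- draw("maf")
    fail_vaf <- draw("vaf"); fail_par <- draw("parent_alt")
    fail_post <- draw("posterior")

    gq_p <- ifelse(fail_gq, 15, 99)
    paf <- ifelse(fail_maf, 0.05, NA)
    alt_dp <- ifelse(fail_vaf, 5, 25)
    dp_p <- ifelse(fail_vaf, 50, 50)  # VAF 0.1 vs 0.5
    par_ad <- ifelse(fail_par, 3, 0)
    post <- ifelse(fail_post, 0.5, 0.99)

    info <- vapply(seq_len(nrow(rec)), function(i) {
      kv <- c(gene_id = rec$gene_id[i], var_class = rec$var_class[i],
              mu_rate = if (is.na(rec$mu_rate[i])) NULL else
                fmt_num(rec$mu_rate[i]),
              rate_quality = "1",
              dn_posterior = fmt_num(post[i]))
      if (!is.na(paf[i])) kv <- c(kv, popmax_af = fmt_num(paf[i]))
      for (s in score_cols) {
        if (!is.na(rec[[s]][i]))
          kv <- c(kv, setNames(fmt_num(rec[[s]][i]), s))
      }
      paste(paste0(names(kv), "=", kv), collapse = ";")
    }, character(1))

    ped_rows <- list()
    paths <- character(0)
    for (i in seq_len(nrow(trios))) {
      id <- trios$individual_id[i]
      fam <- trios$family_id[i]
      mo <- paste0(id, "_mo"); fa <- paste0(id, "_fa")
      ped_rows[[fam]] <- data.frame(
        family_id = fam, individual_id = c(id, mo, fa),
        father = c(fa, "0", "0"), mother = c(mo, "0", "0"),
        sex = c(0, 2, 1), phenotype = c(2, 1, 1))
      ri <- which(rec$individual_id == id)
      path <- file.path(dir, paste0(fam, ".vcf"))
      hdr <- c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
               "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      id, "\t", mo, "\t", fa))
      body <- if (length(ri)) {
        o <- ri[order(rec$chrom[ri], rec$pos[ri])]
        pb_fmt <- sprintf("0/1:%d:%d:%d,%d", dp_p[o], gq_p[o],
                          dp_p[o] - alt_dp[o], alt_dp[o])
        par_fmt <- sprintf("0/0:50:99:%d,%d", 50 - par_ad[o], par_ad[o])
        sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tGT:DP:GQ:AD\t%s\t%s\t%s",
                rec$chrom[o], rec$pos[o], rec$ref[o], rec$alt[o],
                info[o], pb_fmt, par_fmt, par_fmt)
      } else character(0)
      writeLines(c(hdr, body), path)
      paths[fam] <- path
    }
    ped_path <- file.path(dir, "cohort.ped")
    utils::write.table(do.call(rbind, ped_rows), ped_path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    list(vcf = paths, ped = ped_path)
  })
}
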