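#' @importFrom stats dpois ppois qpois pnorm phyper rpois runif rnorm rlnorm
#'   rbinom rnbinom p.adjust glm poisson residuals coef setNames aggregate
#'   ks.test quantile
#' @importFrom utils head tail
#' @import data.table
NULL

# Variant classes: coding SNV, coding indel, intronic SNV, intronic indel.
VARIANT_CLASSES <- c("CS", "CI", "IS", "II")

#' @keywords internal
is_variant_class <- function(x) x %in% VARIANT_CLASSES

# Internal key for (gene, class, predictor) triples. \r never appears in ids.
idx_key <- function(gene_id, var_class, predictor) {
  paste(gene_id, var_class, predictor, sep = "\r")
}

class_key <- function(var_class, predictor) {
  paste(var_class, predictor, sep = "\r")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a tab-separated table with '.' as the missing marker
#'
#' Strict TSV dialect used throughout: tab-separated, header row, '.' for
#' missing, no quoting. Comment lines starting with '#' (provenance headers)
#' are skipped.
#'
#' @param path file path.
#' @return a `data.frame`.
#' @export
read_tsv_strict <- function(path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = ".", header = TRUE,
                          data.table = FALSE, showProgress = FALSE)
  dt
}

#' Write a tab-separated table with '.' as the missing marker
#'
#' @param x data.frame to write.
#' @param path output path.
#' @param header optional character vector of provenance lines written as
#'   '#'-prefixed comments before the column header.
#' @export
write_tsv_strict <- function(x, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  close(con)
  on.exit()
  data.table::fwrite(x, path, sep = "\t", na = ".", quote = FALSE,
                     append = length(header) > 0, col.names = TRUE)
  invisible(path)
}

# md5 of a character vector via a temp file (deterministic, locale-free).
md5_of_text <- function(lines) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(lines, tf, sep = "\n", useBytes = TRUE)
  unname(tools::md5sum(tf))
}

# Format numbers canonically for fingerprinting (round-trip stable).
fmt_num <- function(x) sprintf("%.12g", x)
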