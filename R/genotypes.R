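#' @importFrom rlang .data abort warn
#' @importFrom dplyr %>%
NULL

# Metadata columns of a genotype tibble; everything else is an accession.
GENO_META <- c("marker_id", "chromosome", "position", "source",
               "allele_ref", "allele_alt")

#' Accession columns of a genotype tibble
#'
#' A genotype tibble has one row per marker, the metadata columns
#' `marker_id`, `chromosome`, `position`, `source`, `allele_ref`,
#' `allele_alt`, and one integer column per accession holding the alternate
#' allele dosage: 0 (homozygous reference-class allele), 2 (homozygous
#' alternate-class allele) or `NA` (missing; heterozygous calls are recoded
#' to missing on ingest because the panel consists of inbred lines).
#'
#' @param gt A genotype tibble.
#' @return Character vector of accession column names.
#' @export
accessions <- function(gt) {
  setdiff(names(gt), GENO_META)
}

#' Extract the dosage matrix from a genotype tibble
#'
#' @param gt A genotype tibble (see [accessions()]).
#' @return Integer matrix, markers x accessions, entries 0/2/`NA`, with
#'   `marker_id` rownames.
#' @export
genotype_matrix <- function(gt) {
  acc <- accessions(gt)
  m <- as.matrix(gt[, acc, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- gt$marker_id
  m
}

assert_genotype_tibble <- function(gt, arg = "gt") {
  missing_cols <- setdiff(GENO_META, names(gt))
  if (length(missing_cols) > 0) {
    abort(sprintf("`%s` is not a genotype tibble: missing column(s) %s",
                  arg, paste(missing_cols, collapse = ", ")))
  }
  if (length(accessions(gt)) == 0) {
    abort(sprintf("`%s` has no accession columns", arg))
  }
  bad <- !as.vector(genotype_matrix(gt)) %in% c(0L, 2L, NA_integer_)
  if (any(bad, na.rm = TRUE)) {
    abort(sprintf(
      "`%s` contains calls other than 0/2/NA; heterozygous or unrecoded data?",
      arg))
  }
  invisible(gt)
}

new_genotype_tibble <- function(meta, dosage) {
  stopifnot(nrow(meta) == nrow(dosage))
  dplyr::bind_cols(tibble::as_tibble(meta),
                   tibble::as_tibble(as.data.frame(dosage)))
}
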