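# Small in-code fixtures and independent oracles shared across tests.

# Build a genotype tibble from a dosage matrix (markers x accessions).
geno_tibble <- function(dosage, chromosome = "chrA01", position = NULL,
                        source = "array") {
  n <- nrow(dosage)
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- sprintf("acc%02d", seq_len(ncol(dosage)))
  }
  meta <- tibble::tibble(
    marker_id = sprintf("m%03d", seq_len(n)),
    chromosome = rep_len(chromosome, n),
    position = as.integer(position %||% (seq_len(n) * 1000L)),
    source = source,
    allele_ref = "A",
    allele_alt = "B")
  dplyr::bind_cols(meta, tibble::as_tibble(as.data.frame(dosage)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-pool panel for scan tests: n1 winter + n2 spring (+ optional others).
two_pool_panel <- function(n1, n2, n_semi = 0, n_swede = 0) {
  tibble::tibble(
    accession = sprintf("acc%02d", seq_len(n1 + n2 + n_semi + n_swede)),
    morphotype = c(rep("winter", n1), rep("spring", n2),
                   rep("semi_winter", n_semi), rep("swede", n_swede)))
}

# Independent high-precision chi-square(df = 3) upper tail on the -log10
# scale, via the closed form S(x) = 2*Phibar(sqrt(x)) + sqrt(2x/pi) e^{-x/2}
# evaluated in log space. Shares no code path with pchisq's incomplete
# gamma.
chisq3_neglog10_oracle <- function(x) {
  ifelse(x == 0, 0, {
    la <- log(2) + stats::pnorm(sqrt(x), lower.tail = FALSE, log.p = TRUE)
    lb <- 0.5 * log(2 * x / pi) - x / 2
    hi <- pmax(la, lb)
    -(hi + log1p(exp(pmin(la, lb) - hi))) / log(10)
  })
}

# chi-square(df = 1) upper tail: p = erfc(sqrt(x/2)) = 2*Phibar(sqrt(x)).
chisq1_p_oracle <- function(x) 2 * stats::pnorm(-sqrt(x))

# Minimal VCF writer for ingest tests.
write_test_vcf <- function(path, rows, samples) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, rows), path)
  path
}

vcf_row <- function(chrom, pos, id, ref, alt, mq, dp, gts) {
  paste(c(chrom, pos, id, ref, alt, "99", "PASS",
          sprintf("MQ=%s;DP=%s", mq, dp), "GT", gts), collapse = "\t")
}
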