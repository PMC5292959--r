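test_that("array ingest recodes heterozygous calls to missing and keeps homozygotes", {
  tab <- tibble::tibble(
    marker_id = c("m1", "m2"),
    chromosome = "chrA01",
    position = c(100L, 200L),
    s1 = c("AA", "AA"),
    s2 = c("AB", "BB"),
    s3 = c("BB", "BB"))
  gt <- read_array_genotypes(tab)
  m <- genotype_matrix(gt)
  expect_true(is.na(m["m1", "s2"]))          # het -> missing
  expect_identical(m["m1", c("s1", "s3")], c(s1 = 0L, s3 = 2L))
  expect_identical(unname(m["m2", ]), c(0L, 2L, 2L)) # all-homozygous kept
  expect_identical(unique(gt$source), "array")
})

test_that("array ingest rejects malformed tables with informative errors", {
  tab <- tibble::tibble(marker_id = c("m1", "m1"), chromosome = "c",
                        position = c(1L, 2L), s1 = c("AA", "AA"))
  expect_error(read_array_genotypes(tab), "duplicated marker_id")

  tab2 <- tibble::tibble(marker_id = "m1", chromosome = "c", position = 1L,
                         s1 = "A?")
  expect_error(read_array_genotypes(tab2), "unknown genotype code.*m1.*s1")
})

test_that("VCF SNP ingest maps genotypes to dosages and drops het calls", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, c(
    vcf_row("chrA01", 500, "snp1", "G", "T", 50, 40,
            c("0/0", "1/1", "0/1", "./.")),
    vcf_row("chrA01", 900, ".", "C", "A", 50, 40,
            c("1|1", "0|0", "0/0", "1/1"))),
    samples = paste0("s", 1:4))
  gt <- read_vcf_snps(path)
  m <- genotype_matrix(gt)
  expect_identical(unname(m[1, ]), c(0L, 2L, NA, NA))
  expect_identical(unname(m[2, ]), c(2L, 0L, 0L, 2L))
  expect_identical(gt$marker_id, c("snp1", "chrA01_900")) # fallback id
  expect_identical(unique(gt$source), "seq_snp")
})

test_that("InDel filter keeps MQ>=30 and DP>=10, boundary inclusive", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, c(
    vcf_row("chrA01", 100, "i1", "A", "ATT", 30, 10, c("0/0", "1/1")),
    vcf_row("chrA01", 200, "i2", "ACC", "A", 29, 100, c("0/0", "1/1")),
    vcf_row("chrA01", 300, "i3", "A", "AG", 60, 9, c("0/0", "1/1")),
    vcf_row("chrA01", 400, "i4", "A", "AG", ".", 50, c("0/0", "1/1"))),
    samples = c("s1", "s2"))
  rec <- read_vcf_indels(path)
  expect_identical(rec$kind, c("insertion", "deletion", "insertion",
                               "insertion"))
  expect_warning(kept <- filter_indel_calls(rec), "lacking MQ or DP")
  expect_identical(kept$marker_id, "i1")     # MQ 29 and DP 9 both dropped
})

test_that("InDel recoding produces the AA/CC/TT pseudo-SNP scheme", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, c(
    vcf_row("chrA01", 100, "ins", "A", "ATT", 60, 50,
            c("0/0", "1/1", "0/1")),
    vcf_row("chrA01", 200, "del", "ACC", "A", 60, 50,
            c("1/1", "0/0", "./."))),
    samples = c("s1", "s2", "s3"))
  gt <- recode_indels(read_vcf_indels(path))
  expect_identical(gt$allele_ref, c("A", "A"))
  expect_identical(gt$allele_alt, c("C", "T")) # insertion CC, deletion TT
  m <- genotype_matrix(gt)
  expect_identical(unname(m[1, ]), c(0L, 2L, NA))  # het -> missing
  expect_identical(unname(m[2, ]), c(2L, 0L, NA))
  expect_identical(unique(gt$source), "seq_indel")
})

test_that("merge intersects accessions, dedups by min missingness, sorts by position", {
  a <- geno_tibble(matrix(c(0L, 2L, 2L, 0L, NA, 2L), 2, 3),
                   position = c(500L, 100L))
  b <- geno_tibble(matrix(c(0L, 2L, 0L), 1, 3), position = 500L)
  b$marker_id <- "dup_of_m001"
  b$source <- "seq_snp"

  merged <- merge_and_sort(a, b)
  expect_identical(merged$position, c(100L, 500L))    # sorted
  # at position 500 the copy with fewer missing calls wins (b has none)
  expect_identical(merged$marker_id[merged$position == 500L], "dup_of_m001")

  c_ <- geno_tibble(matrix(0L, 1, 2), position = 999L)
  names(c_)[7:8] <- c("x1", "x2")
  expect_error(merge_and_sort(a, c_), "no accession is shared")
})

test_that("merging disjoint marker sets concatenates without loss", {
  a <- geno_tibble(matrix(c(0L, 2L), 1, 2), position = 100L)
  b <- geno_tibble(matrix(c(2L, 0L), 1, 2), position = 300L,
                   chromosome = "chrC03")
  b$marker_id <- "m900"
  merged <- merge_and_sort(a, b)
  expect_identical(nrow(merged), 2L)
  expect_false(any(duplicated(merged$marker_id)))
})

test_that("QC thresholds are strict as specified", {
  # 10 accessions; marker call rate exactly 0.9 must be dropped
  m_rate <- c(rep(0L, 4), rep(2L, 5), NA)          # call rate 0.9
  m_keep <- c(rep(0L, 5), rep(2L, 5))              # call rate 1, MAF 0.5
  m_maf <- c(rep(0L, 9), 2L)                       # MAF 0.1 -> kept
  m_mono <- rep(0L, 10)                            # MAF 0 -> dropped
  gt <- geno_tibble(rbind(m_rate, m_keep, m_maf, m_mono))
  out <- qc_filter(gt)
  expect_identical(out$marker_id, c("m002", "m003"))

  # MAF exactly 0.01: 100 accessions, one alt homozygote
  m_edge <- c(2L, rep(0L, 99))
  gt2 <- geno_tibble(rbind(m_edge, rep(c(0L, 2L), 50)))
  expect_identical(qc_filter(gt2)$marker_id, "m002")

  # fully called MAF-0.5 matrix passes unchanged
  gt3 <- geno_tibble(matrix(rep(c(0L, 2L), each = 5), 4, 10, byrow = TRUE))
  expect_identical(qc_filter(gt3), gt3)
})

test_that("individual call-rate filter is strict and runs after marker filters", {
  # 5 markers x 5 accessions: acc1 has individual call rate exactly 0.8
  dos <- matrix(rep(c(0L, 2L, 0L, 2L, 0L), 5), 5, 5, byrow = TRUE)
  dos[1, 1] <- NA                                  # acc1: 4/5 called
  gt <- geno_tibble(dos)
  out <- qc_filter(gt, marker_callrate = 0.5, maf = 0.01,
                   ind_callrate = 0.8)
  expect_false("acc01" %in% accessions(out))       # 0.8 exactly -> dropped
  expect_identical(length(accessions(out)), 4L)
})

test_that("qc_filter is idempotent on a structured panel", {
  cfg <- sim_config(n_markers = 800, n_split_regions_ws = 2,
                    n_split_regions_swede = 1, missing_rate = 0.08,
                    seed = 11)
  gt <- simulate_panel(cfg)$genotypes
  once <- qc_filter(gt)
  expect_identical(qc_filter(once), once)
})

test_that("genotype TSV round-trips exactly", {
  gt <- geno_tibble(matrix(c(0L, 2L, NA, 2L, 0L, 0L), 2, 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(gt, path)
  expect_identical(read_genotypes(path), gt)
})
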