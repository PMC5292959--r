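cov_fixture <- function(counts_mat, totals) {
  n <- nrow(counts_mat)
  counts <- dplyr::bind_cols(
    tibble::tibble(region_id = sprintf("r%02d", seq_len(n)),
                   chromosome = "chrA01",
                   start = seq_len(n) * 10000L,
                   stop = seq_len(n) * 10000L + 2999L),
    tibble::as_tibble(as.data.frame(counts_mat)))
  list(counts = counts,
       totals = tibble::tibble(accession = colnames(counts_mat),
                               total_reads = totals))
}

test_that("coverage normalization applies the exact formula", {
  m <- matrix(c(1000, 0), 1, 2, dimnames = list(NULL, c("g1", "g2")))
  fx <- cov_fixture(m, c(1e5, 1e5))
  norm <- normalize_coverage(fx$counts, fx$totals,
                             genome_length = 1e6, read_length = 100)
  expect_equal(norm$g1, 100)           # 1000 * 1e6 / (1e5 * 100)
  expect_equal(norm$g2, 0)             # zero reads -> zero coverage

  # doubling a genotype's total aligned reads halves its coverage
  fx2 <- cov_fixture(m, c(2e5, 1e5))
  norm2 <- normalize_coverage(fx2$counts, fx2$totals,
                              genome_length = 1e6, read_length = 100)
  expect_equal(norm2$g1, 50)

  fx3 <- cov_fixture(m, c(1e5, 0))
  expect_warning(norm3 <- normalize_coverage(fx3$counts, fx3$totals,
                                             1e6, 100),
                 "zero aligned reads")
  expect_false("g2" %in% names(norm3))
})

test_that("CNV calls use strict ratio thresholds with boundary ratios normal", {
  # 4 genotypes around a mean of 100: ratios 0.4, 0.5, 1.5, 1.6
  mk_norm <- function(vals) {
    dplyr::bind_cols(
      tibble::tibble(region_id = "r01", chromosome = "chrA01",
                     start = 1L, stop = 3000L),
      tibble::as_tibble(as.data.frame(matrix(
        vals, 1, dimnames = list(NULL, paste0("g", seq_along(vals)))))))
  }
  vals <- c(40, 50, 150, 160) # mean 100
  calls <- call_cnv(mk_norm(vals))
  expect_equal(calls$ref_cov, rep(100, 4))
  expect_identical(calls$call,
                   c("deletion", "normal", "normal", "duplication"))

  # all equal -> all ratios 1, all normal
  eq <- call_cnv(mk_norm(rep(123, 4)))
  expect_true(all(eq$ratio == 1) && all(eq$call == "normal"))

  # low-coverage regions are excluded before calling
  expect_warning(low <- call_cnv(mk_norm(c(2, 2, 2, 2))), "coverage floor")
  expect_identical(nrow(low), 0L)
})

test_that("calling is scale-invariant in the raw counts", {
  set.seed(4)
  m <- matrix(rpois(40, 800), 4, 10,
              dimnames = list(NULL, sprintf("g%02d", 1:10)))
  m[2, 1:2] <- 60 # clear deletions
  fx <- cov_fixture(m, rep(2e6, 10))
  norm1 <- normalize_coverage(fx$counts, fx$totals, 8.5e8, 100)
  fx2 <- cov_fixture(m * 7, rep(2e6 * 7, 10))
  norm2 <- normalize_coverage(fx2$counts, fx2$totals, 8.5e8, 100)
  c1 <- call_cnv(norm1, min_mean_coverage = 0)
  c2 <- call_cnv(norm2, min_mean_coverage = 0)
  expect_identical(c1$call, c2$call)
})

test_that("median reference is available as an alternative", {
  vals <- c(100, 100, 100, 1000) # mean 325 vs median 100
  norm <- dplyr::bind_cols(
    tibble::tibble(region_id = "r01", chromosome = "chrA01",
                   start = 1L, stop = 3000L),
    tibble::as_tibble(as.data.frame(matrix(
      vals, 1, dimnames = list(NULL, paste0("g", 1:4))))))
  med <- call_cnv(norm, ref_stat = "median")
  expect_identical(med$call, c("normal", "normal", "normal", "duplication"))
  mean_ <- call_cnv(norm)
  expect_identical(mean_$call[1:3], rep("deletion", 3)) # 100/325 < 0.5
})

test_that("pool summary counts injected swede events and respects panel size", {
  cfg <- sim_config(
    n_markers = 100, n_split_regions_ws = 1, n_split_regions_swede = 0,
    n_regions_cov = 12, seed = 41,
    cnv_events = tibble::tibble(
      region = 3L,
      accessions = list(sprintf("acc%03d", 261:268)), # 8 of the 11 swedes
      kind = "duplication", fold = 2.5),
    hnrt_pairs = tibble::tibble(region_a = integer(),
                                region_c = integer(),
                                accessions = integer()))
  sim <- simulate_panel(cfg)
  stopifnot(all(sim$panel$morphotype[261:268] == "swede"))
  norm <- normalize_coverage(sim$coverage$counts, sim$coverage$totals,
                             cfg$genome_length, cfg$read_length)
  calls <- call_cnv(norm)
  summ <- cnv_pool_summary(calls, sim$panel)
  hit <- summ[summ$region_id == "cov003" & summ$pool == "swede", ]
  expect_identical(hit$duplications, 8L)
  expect_true(all(summ$deletions + summ$duplications <= summ$n))
  expect_true(all(summ$n[summ$pool == "swede"] == 11))
})

test_that("HNRT flags require the joint A-duplication / C-deletion pattern", {
  calls <- tibble::tibble(
    region_id = rep(c("regA", "regC"), each = 3),
    accession = rep(c("g1", "g2", "g3"), 2),
    norm_cov = 1, ref_cov = 1, ratio = 1,
    call = c("duplication", "duplication", "normal",   # A member
             "deletion", "normal", "deletion"))        # C member
  pairs <- tibble::tibble(region_a = "regA", region_c = "regC")
  hits <- flag_hnrt(calls, pairs)
  expect_identical(hits$accession, "g1")  # g2 dup-only, g3 del-only

  expect_error(flag_hnrt(calls, tibble::tibble(region_a = "nope",
                                               region_c = "regC")),
               "unknown region")
})

test_that("injected HNRT events are recovered completely from clean coverage", {
  cfg <- sim_config(
    n_markers = 100, n_split_regions_ws = 1, n_split_regions_swede = 0,
    n_regions_cov = 10, seed = 43,
    cnv_events = tibble::tibble(region = integer(), accessions = integer(),
                                kind = character(), fold = double()),
    hnrt_pairs = tibble::tibble(region_a = 2L, region_c = 9L,
                                accessions = 6L))
  sim <- simulate_panel(cfg)
  norm <- normalize_coverage(sim$coverage$counts, sim$coverage$totals,
                             cfg$genome_length, cfg$read_length)
  calls <- call_cnv(norm)
  pairs <- tibble::tibble(region_a = "cov002", region_c = "cov009")
  hits <- flag_hnrt(calls, pairs)
  expect_setequal(hits$accession, sim$truth$hnrt$accession)
})
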