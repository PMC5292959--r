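test_that("polarization assigns alleles by the pool frequency ratio", {
  # 10 winter + 10 spring; marker 1: alt frequent in winter -> alt = winter
  # marker 2: alt frequent in spring -> alt = spring
  # marker 3: equal frequencies -> excluded
  w <- cbind(c(rep(2L, 9), 0L), c(rep(0L, 9), 2L), rep(2L, 10))
  s <- cbind(c(rep(0L, 9), 2L), c(rep(2L, 9), 0L), rep(2L, 10))
  gt <- geno_tibble(cbind(t(w), t(s)))   # markers x (winter, spring)
  panel <- two_pool_panel(10, 10)
  pools <- pool_spec(panel, "winter_spring")

  expect_warning(pc <- polarize(gt, pools), "cannot be polarized")
  expect_identical(nrow(pc), 2L)                       # ratio-1 marker gone
  expect_identical(pc$pool1_allele, c("alt", "ref"))
  # cells for marker 1: winter allele (alt) in 9 winters and 1 spring
  expect_identical(unname(unlist(pc[1, c("n11", "n12", "n21", "n22")])),
                   c(9, 1, 1, 9))
})

test_that("suitability test reproduces the worked pass/fail cases", {
  pools <- structure(list(n1 = 139, n2 = 114), class = "pool_spec")
  counts <- tibble::tibble(n11 = c(139, 132, 60), n21 = 0, n12 = 0,
                           n22 = c(114, 101, 50))
  out <- suitability_test(counts, pools)

  expect_equal(out$suit_chisq[1], 0)                   # exact concordance
  expect_equal(out$suit_p[1], 1)
  expect_true(out$suit_pass[1])

  # observed (132, 101): chi2 = 49/139 + 169/114, independent df-1 oracle
  chi <- 49 / 139 + 169 / 114
  expect_equal(out$suit_chisq[2], chi)
  expect_equal(out$suit_p[2], chisq1_p_oracle(chi), tolerance = 1e-12)
  expect_true(out$suit_pass[2])                        # p ~ 0.18 > 0.1

  expect_false(out$suit_pass[3])                       # (60, 50): p << 0.1
  expect_gt(out$suit_chisq[3], 2.7)
})

test_that("suitability expectation can be renormalized to the observed total", {
  pools <- structure(list(n1 = 139, n2 = 114), class = "pool_spec")
  counts <- tibble::tibble(n11 = 120, n21 = 0, n12 = 0, n22 = 98)
  literal <- suitability_test(counts, pools)
  renorm <- suitability_test(counts, pools, expected = "observed_total")
  # proportion 120/218 ~ 139/253, so the renormalized gate is near zero
  expect_lt(renorm$suit_chisq, 0.1)
  expect_gt(literal$suit_chisq, renorm$suit_chisq)
})

test_that("split test reproduces printed table rows to the printed decimal", {
  ws <- split_chisq_cells(c(132, 129), c(13, 7), c(4, 5), c(101, 106),
                          139, 114)
  expect_equal(round(ws$neg_log10_p, 1), c(39.3, 41.7))
  sw <- split_chisq_cells(260, 0, 0, 11, 260, 11)
  expect_equal(round(sw$neg_log10_p, 1), 57.7)
  # expectation equals half the full pool sizes even with missing calls:
  # the first row sums to 250 of 253 genotypes yet still gives 39.3
  expect_lt(sum(c(132, 13, 4, 101)), 253)
})

test_that("split statistic is zero at expectation and symmetric in allele labels", {
  at_exp <- split_chisq_cells(69.5, 57, 69.5, 57, 139, 114)
  expect_equal(at_exp$chisq, 0)
  expect_equal(at_exp$neg_log10_p, 0)

  a <- split_chisq_cells(120, 10, 19, 104, 139, 114)
  b <- split_chisq_cells(19, 104, 120, 10, 139, 114)  # labels swapped
  expect_equal(a$chisq, b$chisq)
  expect_equal(a$neg_log10_p, b$neg_log10_p)

  expect_error(split_chisq_cells(-1, 0, 0, 0, 139, 114), "nonnegative")
})

test_that("log-space tail matches the closed-form df-3 oracle over chi2 in [0, 300]", {
  set.seed(123)
  chi <- c(0, runif(997, 0, 300), 299.9, 300)
  impl <- chisq_neg_log10_p(chi, df = 3)
  oracle <- chisq3_neglog10_oracle(chi)
  expect_lt(max(abs(impl - oracle)), 1e-3)
})

test_that("selection keeps the top quantile with ties included", {
  stats <- tibble::tibble(
    marker_id = sprintf("m%04d", 1:1000),
    chromosome = "chrA01", position = 1:1000 * 1000L,
    neg_log10_p = c(1000:2, 2))                        # tie at the bottom
  out <- select_split_markers(stats, top_frac = 0.001)
  expect_identical(sum(out$selected), 1L)              # ceil(1) = 1 marker
  expect_identical(attr(out, "threshold"), 1000)

  out2 <- select_split_markers(stats, top_frac = 0.002)
  expect_identical(sum(out2$selected), 2L)             # 2000 * 0.1% style

  # ties at the threshold are all kept
  stats$neg_log10_p <- c(rep(50, 3), rep(1, 997))
  out3 <- select_split_markers(stats, top_frac = 0.002)
  expect_identical(sum(out3$selected), 3L)

  # only suitability passers are eligible
  stats$suit_pass <- c(FALSE, rep(TRUE, 999))
  out4 <- select_split_markers(stats, top_frac = 0.001)
  expect_false(out4$selected[1])
  expect_error(select_split_markers(stats[0, ]), "no marker")
})

test_that("region grouping chains markers within the gap and splits across it", {
  stats <- tibble::tibble(
    marker_id = paste0("m", 1:4),
    chromosome = c("chrA01", "chrA01", "chrA01", "chrC03"),
    position = c(1000000L, 1005000L, 2500000L, 1000000L),
    neg_log10_p = c(40, 45, 41, 39),
    selected = TRUE)
  reg <- group_regions(stats, max_gap = 1e6)
  expect_identical(nrow(reg), 3L)       # 1.0 & 2.5 Mb split; chrC03 separate
  r1 <- reg[reg$chromosome == "chrA01" & reg$start == 1000000L, ]
  expect_identical(r1$n_markers, 2L)    # 5 kb apart -> one region
  expect_identical(r1$best_marker, "m2")
  expect_identical(r1$end, 1005000L)
})

test_that("perfect injected split markers hit the analytic ceiling and top ranks", {
  cfg <- sim_config(n_markers = 2000, n_split_regions_ws = 2,
                    n_split_regions_swede = 0, markers_per_split_region = 5,
                    concordance = 1, missing_rate = 0, seed = 21)
  sim <- simulate_panel(cfg)
  scan <- split_scan(sim$genotypes, sim$panel, "winter_spring",
                     top_frac = 10 / 2000)
  inj <- sim$truth$split_markers$marker_id

  # every injected marker scores the analytic value for cells (139,0,0,114)
  analytic <- split_chisq_cells(139, 0, 0, 114, 139, 114)$neg_log10_p
  got <- unname(scan$stats$neg_log10_p[match(inj, scan$stats$marker_id)])
  expect_equal(got, rep(analytic, length(inj)))

  # and occupies exactly the top ranks of the -log10 p ordering
  ord <- order(scan$stats$neg_log10_p, decreasing = TRUE)
  expect_setequal(scan$stats$marker_id[ord[seq_along(inj)]], inj)
  expect_setequal(scan$stats$marker_id[scan$stats$selected], inj)
})

test_that("background allele frequencies differ between pools only by noise", {
  devs <- purrr::map_dbl(1:20, function(s) {
    cfg <- sim_config(n_markers = 300, n_split_regions_ws = 1,
                      n_split_regions_swede = 1, missing_rate = 0,
                      seed = 1000 + s)
    sim <- simulate_panel(cfg)
    bg <- dplyr::filter(sim$genotypes,
                        !marker_id %in% sim$truth$split_markers$marker_id)
    m <- genotype_matrix(bg)
    panel <- sim$panel
    w <- m[, panel$accession[panel$morphotype == "winter"]]
    s_ <- m[, panel$accession[panel$morphotype == "spring"]]
    mean(rowMeans(w == 2) / 2 - rowMeans(s_ == 2) / 2)
  })
  # mean frequency gap across pools, averaged over markers, is ~0 +- SE
  se <- sqrt(0.25 / 300 / 139 + 0.25 / 300 / 114) # crude upper bound on SE
  expect_lt(abs(mean(devs)), 5 * se)
})

test_that("scan results expose tidy, glance and a threshold consistent with selection", {
  cfg <- sim_config(n_markers = 1500, n_split_regions_ws = 2,
                    n_split_regions_swede = 1, seed = 9)
  sim <- simulate_panel(cfg)
  scan <- split_scan(sim$genotypes, sim$panel, "winter_spring",
                     top_frac = 24 / 1500)
  td <- tidy(scan)
  expect_true(all(c("suit_pass", "neg_log10_p", "selected") %in% names(td)))
  expect_true(all(td$selected <= td$suit_pass))        # selected => pass
  expect_true(all(td$neg_log10_p[td$selected] >= scan$threshold))
  g <- glance(scan)
  expect_identical(g$n_selected, sum(td$selected))
  expect_identical(g$n_regions, nrow(scan$regions))
})
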