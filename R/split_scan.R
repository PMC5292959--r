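MORPHOTYPES <- c("winter", "semi_winter", "spring", "swede")

assert_panel <- function(panel) {
  if (!all(c("accession", "morphotype") %in% names(panel))) {
    abort("panel must have columns `accession` and `morphotype`")
  }
  bad <- setdiff(unique(panel$morphotype), MORPHOTYPES)
  if (length(bad) > 0) {
    abort(sprintf("unknown morphotype(s): %s (expected %s)",
                  paste(bad, collapse = ", "),
                  paste(MORPHOTYPES, collapse = ", ")))
  }
  if (anyDuplicated(panel$accession)) abort("duplicated accession in panel")
  invisible(panel)
}

#' Define polarization and test pools for a morphotype contrast
#'
#' For the winter-spring contrast, alleles are polarized on the winter pool
#' (winter + swede accessions) against the spring pool (semi-winter +
#' spring), while the chi-square tests count alleles in the winter pool
#' without swedes (N1) versus the spring pool without semi-winter types
#' (N2). For the swede contrast, swedes are tested against all other
#' accessions, and the same pools serve for polarization.
#'
#' @param panel Tibble with columns `accession` and `morphotype` (values
#'   `winter`, `semi_winter`, `spring`, `swede`).
#' @param contrast `"winter_spring"` or `"swede"`.
#' @return A `pool_spec` list: accession sets `polar_1`, `polar_2`,
#'   `test_1`, `test_2`, pool sizes `n1`, `n2`, and allele `labels`
#'   (pool-1 label first).
#' @export
pool_spec <- function(panel, contrast = c("winter_spring", "swede")) {
  contrast <- match.arg(contrast)
  assert_panel(panel)
  mt <- split(panel$accession, factor(panel$morphotype, MORPHOTYPES))
  ps <- if (contrast == "winter_spring") {
    list(polar_1 = c(mt$winter, mt$swede),
         polar_2 = c(mt$semi_winter, mt$spring),
         test_1 = mt$winter,
         test_2 = mt$spring,
         labels = c("winter", "spring"))
  } else {
    nonswede <- setdiff(panel$accession, mt$swede)
    list(polar_1 = nonswede,
         polar_2 = mt$swede,
         test_1 = nonswede,
         test_2 = mt$swede,
         labels = c("non_swede", "swede"))
  }
  if (length(ps$test_1) == 0 || length(ps$test_2) == 0) {
    abort(sprintf("contrast %s: a test pool is empty", contrast))
  }
  structure(c(ps, list(contrast = contrast,
                       n1 = length(ps$test_1), n2 = length(ps$test_2))),
            class = "pool_spec")
}

#' @export
print.pool_spec <- function(x, ...) {
  cat(sprintf("%s contrast: %s pool N1 = %d vs %s pool N2 = %d\n",
              x$contrast, x$labels[1], x$n1, x$labels[2], x$n2))
  invisible(x)
}

#' Polarize marker alleles by pool allele-frequency ratio
#'
#' For every biallelic marker the frequency of the alternate allele is
#' computed in each polarization pool; the ratio pool-1 : pool-2 assigns the
#' alternate allele to pool 1 when it exceeds 1 and to pool 2 when it is
#' below 1 (the other allele takes the complementary label). Markers whose
#' ratio is exactly 1 (equal frequencies, including both zero) cannot be
#' polarized and are excluded with a warning. Cell counts are then taken
#' over the test pools: `n11`/`n21` are the pool-1/pool-2 allele carrier
#' counts in test pool 1, `n12`/`n22` the same in test pool 2 (non-missing
#' homozygous calls).
#'
#' @param gt A genotype tibble.
#' @param pools A [pool_spec()].
#' @return Tibble of polarized counts: marker metadata, `pool1_allele`
#'   (`"ref"` or `"alt"`), and cells `n11`, `n12`, `n21`, `n22`.
#' @export
polarize <- function(gt, pools) {
  assert_genotype_tibble(gt)
  m <- genotype_matrix(gt)
  need <- unique(c(pools$polar_1, pools$polar_2, pools$test_1, pools$test_2))
  missing_acc <- setdiff(need, colnames(m))
  if (length(missing_acc) > 0) {
    abort(sprintf("accessions in pools but not genotypes: %s",
                  paste(utils::head(missing_acc, 5), collapse = ", ")))
  }

  f1 <- rowMeans(m[, pools$polar_1, drop = FALSE] == 2L, na.rm = TRUE)
  f2 <- rowMeans(m[, pools$polar_2, drop = FALSE] == 2L, na.rm = TRUE)
  # alt to pool 1 if f1/f2 > 1, pool 2 if < 1; excluded if equal (incl. 0/0)
  alt_to_1 <- f1 > f2
  excluded <- is.na(f1) | is.na(f2) | f1 == f2
  if (any(excluded)) {
    warn(sprintf("excluding %d marker(s) that cannot be polarized (equal or undefined pool frequencies)",
                 sum(excluded)))
  }

  t1 <- m[, pools$test_1, drop = FALSE]
  t2 <- m[, pools$test_2, drop = FALSE]
  alt1 <- rowSums(t1 == 2L, na.rm = TRUE)
  ref1 <- rowSums(t1 == 0L, na.rm = TRUE)
  alt2 <- rowSums(t2 == 2L, na.rm = TRUE)
  ref2 <- rowSums(t2 == 0L, na.rm = TRUE)

  out <- tibble::tibble(
    marker_id = gt$marker_id,
    chromosome = gt$chromosome,
    position = gt$position,
    pool1_allele = unname(ifelse(alt_to_1, "alt", "ref")),
    n11 = unname(ifelse(alt_to_1, alt1, ref1)),
    n12 = unname(ifelse(alt_to_1, alt2, ref2)),
    n21 = unname(ifelse(alt_to_1, ref1, alt1)),
    n22 = unname(ifelse(alt_to_1, ref2, alt2))
  )
  out[!excluded, ]
}

#' Suitability test: can the marker explain a full morphotype split?
#'
#' First-stage gate of the scan. The observed concordant counts (pool-1
#' allele carriers in test pool 1, pool-2 allele carriers in test pool 2)
#' are compared against the full-concordance expectation by a chi-square
#' test with 1 degree of freedom; a marker passes when p > `alpha`. With
#' `expected = "pool_sizes"` (default) the expectation is literally
#' (N1, N2); `"observed_total"` renormalizes it to the observed concordant
#' total, which is insensitive to missing calls.
#'
#' @param counts Polarized-count tibble from [polarize()].
#' @param pools The [pool_spec()] used for polarization.
#' @param alpha Pass threshold on the p-value (pass iff p > alpha).
#' @param expected Expectation convention, see Details.
#' @return `counts` with columns `suit_chisq`, `suit_p`, `suit_pass` added.
#' @export
suitability_test <- function(counts, pools, alpha = 0.1,
                             expected = c("pool_sizes", "observed_total")) {
  expected <- match.arg(expected)
  if (pools$n1 <= 0 || pools$n2 <= 0) abort("expected pool sizes must be > 0")
  o1 <- counts$n11
  o2 <- counts$n22
  if (expected == "pool_sizes") {
    e1 <- pools$n1
    e2 <- pools$n2
  } else {
    tot <- o1 + o2
    e1 <- tot * pools$n1 / (pools$n1 + pools$n2)
    e2 <- tot * pools$n2 / (pools$n1 + pools$n2)
  }
  chi <- (o1 - e1)^2 / e1 + (o2 - e2)^2 / e2
  p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  dplyr::mutate(counts, suit_chisq = chi, suit_p = p, suit_pass = p > alpha)
}

#' Four-cell split chi-square against the equal-frequency expectation
#'
#' Scores how far a marker's polarized allele counts deviate from a random
#' (pool-independent, 50/50) allele distribution: each of the four cells is
#' compared to half the corresponding full test-pool size (e.g. expected
#' 69.5/57/69.5/57 for pools of 139 and 114, or 130/5.5/130/5.5 for 260 vs
#' 11). The statistic is chi-square with 3 degrees of freedom; its upper
#' tail is evaluated in log space and reported as `neg_log10_p`. The
#' expectation uses the full pool sizes even when some calls are missing at
#' the marker.
#'
#' @param counts Polarized-count tibble (columns `n11`, `n12`, `n21`,
#'   `n22`), e.g. from [suitability_test()].
#' @param pools The [pool_spec()].
#' @return `counts` with `split_chisq` and `neg_log10_p` added.
#' @seealso [split_chisq_cells()] for scoring raw cell counts directly.
#' @export
split_test <- function(counts, pools) {
  res <- split_chisq_cells(counts$n11, counts$n12, counts$n21, counts$n22,
                           pools$n1, pools$n2)
  dplyr::mutate(counts, split_chisq = res$chisq,
                neg_log10_p = res$neg_log10_p)
}

#' @rdname split_test
#' @param n11,n12,n21,n22 Cell counts: pool-1 allele in test pool 1 and 2,
#'   pool-2 allele in test pool 1 and 2.
#' @param n1,n2 Full test-pool sizes.
#' @export
split_chisq_cells <- function(n11, n12, n21, n22, n1, n2) {
  cells <- cbind(n11, n12, n21, n22)
  if (any(cells < 0, na.rm = TRUE)) abort("cell counts must be nonnegative")
  h1 <- rep_len(n1 / 2, nrow(cells))
  h2 <- rep_len(n2 / 2, nrow(cells))
  e <- cbind(h1, h2, h1, h2)
  chi <- rowSums((cells - e)^2 / e)
  tibble::tibble(chisq = chi, neg_log10_p = chisq_neg_log10_p(chi, df = 3))
}

#' Select split markers as the top quantile of -log10 p
#'
#' Keeps the top `top_frac` of the scanned markers by `neg_log10_p`,
#' restricted to suitability-passing markers: `n_keep = ceiling(top_frac *
#' n_total)` where `n_total` is the number of markers that entered the scan
#' (defaulting to `nrow(stats)`), the threshold is the `n_keep`-th largest
#' `neg_log10_p` among passing markers, and every passing marker at or
#' above the threshold is selected (ties included).
#'
#' @param stats Tibble from [split_test()] (with `suit_pass` if the
#'   suitability gate was run; absent, all markers are eligible).
#' @param top_frac Fraction of scanned markers to keep (default 0.001).
#' @param n_total Denominator for the quantile; default `nrow(stats)`.
#' @return `stats` with a logical `selected` column; the threshold is
#'   attached as attribute `threshold`.
#' @export
select_split_markers <- function(stats, top_frac = 0.001, n_total = NULL) {
  if (nrow(stats) == 0) abort("no marker statistics to select from")
  n_total <- n_total %||% nrow(stats)
  eligible <- if ("suit_pass" %in% names(stats)) stats$suit_pass else
    rep(TRUE, nrow(stats))
  n_keep <- ceiling(top_frac * n_total)
  vals <- sort(stats$neg_log10_p[eligible], decreasing = TRUE)
  threshold <- if (length(vals) == 0) Inf else
    vals[min(n_keep, length(vals))]
  out <- dplyr::mutate(stats,
                       selected = eligible & .data$neg_log10_p >= threshold)
  attr(out, "threshold") <- threshold
  out
}

#' Group selected split markers into genomic regions
#'
#' Single-linkage chaining: consecutive selected markers on the same
#' chromosome join one region while the gap between neighbours is at most
#' `max_gap`; a larger gap starts a new region.
#'
#' @param stats Marker statistics with `selected`, `chromosome`,
#'   `position`.
#' @param max_gap Maximum within-region gap in bp (default 1 Mb).
#' @return Tibble of regions: `region_id`, `chromosome`, `start`, `end`,
#'   `n_markers`, `marker_ids` (list-column), `best_marker`,
#'   `best_neg_log10_p`.
#' @export
group_regions <- function(stats, max_gap = 1e6) {
  sel <- stats %>%
    dplyr::filter(.data$selected) %>%
    dplyr::arrange(.data$chromosome, .data$position)
  if (nrow(sel) == 0) {
    return(tibble::tibble(region_id = character(), chromosome = character(),
                          start = integer(), end = integer(),
                          n_markers = integer(), marker_ids = list(),
                          best_marker = character(),
                          best_neg_log10_p = double()))
  }
  new_chrom <- c(TRUE, sel$chromosome[-1] != sel$chromosome[-nrow(sel)])
  gap <- c(0, diff(sel$position))
  sel$region <- cumsum(new_chrom | (!new_chrom & gap > max_gap))

  sel %>%
    dplyr::group_by(.data$region) %>%
    dplyr::summarise(
      chromosome = dplyr::first(.data$chromosome),
      start = min(.data$position),
      end = max(.data$position),
      n_markers = dplyr::n(),
      marker_ids = list(.data$marker_id),
      best_marker = .data$marker_id[which.max(.data$neg_log10_p)],
      best_neg_log10_p = max(.data$neg_log10_p),
      .groups = "drop") %>%
    dplyr::mutate(region_id = sprintf("%s:%d-%d", .data$chromosome,
                                      .data$start, .data$end)) %>%
    dplyr::select("region_id", dplyr::everything(), -"region")
}

#' Two-stage split-marker scan
#'
#' Runs the full scan for one contrast: polarize alleles on the
#' polarization pools, gate markers by the suitability chi-square (df 1, p >
#' `alpha`), score the four polarized cells against the equal-frequency
#' expectation (df 3, log-space p), select the top `top_frac` of scanned
#' markers among the suitability passers, and chain the selected markers
#' into regions.
#'
#' @param gt A genotype tibble.
#' @param panel Panel tibble (`accession`, `morphotype`).
#' @param contrast `"winter_spring"` or `"swede"`.
#' @param top_frac Selection quantile (default 0.001, i.e. top 0.1%).
#' @param alpha Suitability pass level (default 0.1).
#' @param max_gap Region chaining gap in bp (default 1 Mb).
#' @param suit_expected Suitability expectation convention, see
#'   [suitability_test()].
#' @return An object of class `split_scan`: `stats` (per-marker tibble),
#'   `regions`, `threshold`, `pools`, and the parameters used.
#' @export
split_scan <- function(gt, panel, contrast = c("winter_spring", "swede"),
                       top_frac = 0.001, alpha = 0.1, max_gap = 1e6,
                       suit_expected = c("pool_sizes", "observed_total")) {
  contrast <- match.arg(contrast)
  suit_expected <- match.arg(suit_expected)
  pools <- pool_spec(panel, contrast)

  stats <- polarize(gt, pools) %>%
    suitability_test(pools, alpha = alpha, expected = suit_expected) %>%
    split_test(pools) %>%
    select_split_markers(top_frac = top_frac)

  structure(list(
    stats = stats,
    regions = group_regions(stats, max_gap = max_gap),
    threshold = attr(stats, "threshold"),
    pools = pools,
    params = list(contrast = contrast, top_frac = top_frac, alpha = alpha,
                  max_gap = max_gap, suit_expected = suit_expected)
  ), class = "split_scan")
}

#' @export
print.split_scan <- function(x, ...) {
  print(x$pools)
  cat(sprintf(
    "%d markers scanned, %d passed suitability, %d selected (threshold -log10 p >= %.1f), %d region(s)\n",
    nrow(x$stats), sum(x$stats$suit_pass), sum(x$stats$selected),
    x$threshold, nrow(x$regions)))
  invisible(x)
}

#' @method tidy split_scan
#' @export
tidy.split_scan <- function(x, ...) x$stats

#' @method glance split_scan
#' @export
glance.split_scan <- function(x, ...) {
  tibble::tibble(
    contrast = x$params$contrast,
    n_markers = nrow(x$stats),
    n_suitable = sum(x$stats$suit_pass),
    n_selected = sum(x$stats$selected),
    threshold = x$threshold,
    n_regions = nrow(x$regions))
}

#' Manhattan-style plot of a split scan
#'
#' @param object A `split_scan`.
#' @param ... Unused.
#' @return A ggplot of -log10 p by position, selected markers highlighted.
#' @method autoplot split_scan
#' @export
autoplot.split_scan <- function(object, ...) {
  df <- dplyr::filter(object$stats, .data$suit_pass)
  ggplot2::ggplot(df, ggplot2::aes(.data$position / 1e6, .data$neg_log10_p,
                                   colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.7, size = 0.8) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::facet_wrap(~chromosome, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "position (Mb)",
                  y = expression(-log[10](p)),
                  colour = "split marker") +
    ggplot2::theme_minimal()
}

#' Write split regions as BED
#'
#' Converts 1-based inclusive region coordinates to BED's 0-based
#' half-open convention; the score column carries the best member
#' -log10 p.
#'
#' @param regions Region tibble from [group_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- tibble::tibble(
    chrom = regions$chromosome,
    start = regions$start - 1L,
    end = regions$end,
    name = regions$region_id,
    score = round(regions$best_neg_log10_p, 2),
    strand = ".")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
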