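#' Normalize target-region read coverage
#'
#' Applies, per region and genotype,
#' `normalized = reads_in_region * genome_length /
#' (total_aligned_reads * read_length)`,
#' which removes library-size differences and puts every genotype's
#' coverage on a genome-wide-average scale. Genotypes with zero total
#' aligned reads are excluded with a warning.
#'
#' @param counts Coverage tibble: `region_id`, `chromosome`, `start`,
#'   `stop` (1-based inclusive), then one raw read-count column per
#'   genotype.
#' @param totals Tibble `accession`, `total_reads` (genome-wide aligned
#'   reads per genotype).
#' @param genome_length Total reference genome length in bp.
#' @param read_length Average read length in bp.
#' @return Tibble in the same layout as `counts` with normalized coverage
#'   values.
#' @export
normalize_coverage <- function(counts, totals, genome_length,
                               read_length) {
  meta_cols <- c("region_id", "chromosome", "start", "stop")
  acc <- setdiff(names(counts), meta_cols)
  tot <- totals$total_reads[match(acc, totals$accession)]
  if (anyNA(tot)) {
    abort(sprintf("no total read count for genotype(s): %s",
                  paste(utils::head(acc[is.na(tot)], 5), collapse = ", ")))
  }
  zero <- tot == 0
  if (any(zero)) {
    warn(sprintf("excluding %d genotype(s) with zero aligned reads",
                 sum(zero)))
    acc <- acc[!zero]
    tot <- tot[!zero]
  }
  raw <- as.matrix(counts[, acc, drop = FALSE])
  norm <- sweep(raw * genome_length / read_length, 2, tot, "/")
  dplyr::bind_cols(counts[, intersect(meta_cols, names(counts))],
                   tibble::as_tibble(as.data.frame(norm)))
}

#' Call copy-number state per region and genotype
#'
#' The population reference for a region is the arithmetic mean (or median)
#' of the normalized coverage over all genotypes, the tested genotype
#' included. A genotype is called a deletion when its coverage ratio to the
#' reference is strictly below 0.5 and a duplication when strictly above
#' 1.5; ratios of exactly 0.5 or 1.5 are `normal`. Regions whose reference
#' falls below `min_mean_coverage` are excluded before calling (low-coverage
#' targets are uninformative), as are regions with a zero reference.
#'
#' @param norm Normalized coverage tibble from [normalize_coverage()].
#' @param min_mean_coverage Mean normalized coverage floor (default 10).
#' @param ref_stat `"mean"` (default) or `"median"` population reference.
#' @param del_ratio,dup_ratio Call thresholds (defaults 0.5 and 1.5, both
#'   strict).
#' @return Long tibble of calls: `region_id`, `accession`, `norm_cov`,
#'   `ref_cov`, `ratio`, `call` (`deletion`/`normal`/`duplication`).
#' @export
call_cnv <- function(norm, min_mean_coverage = 10,
                     ref_stat = c("mean", "median"),
                     del_ratio = 0.5, dup_ratio = 1.5) {
  ref_stat <- match.arg(ref_stat)
  meta_cols <- c("region_id", "chromosome", "start", "stop")
  acc <- setdiff(names(norm), meta_cols)
  if (length(acc) < 2) abort("need at least two genotypes to call CNVs")
  x <- as.matrix(norm[, acc, drop = FALSE])

  ref <- if (ref_stat == "mean") rowMeans(x) else
    apply(x, 1, stats::median)
  drop <- ref < min_mean_coverage | ref == 0
  if (any(drop)) {
    warn(sprintf("skipping %d region(s) below the coverage floor or with zero reference",
                 sum(drop)))
  }
  keep <- which(!drop)

  tibble::tibble(
    region_id = rep(norm$region_id[keep], times = length(acc)),
    accession = rep(acc, each = length(keep)),
    norm_cov = as.vector(x[keep, , drop = FALSE]),
    ref_cov = rep(ref[keep], times = length(acc))
  ) %>%
    dplyr::mutate(
      ratio = .data$norm_cov / .data$ref_cov,
      call = dplyr::case_when(
        .data$ratio < del_ratio ~ "deletion",
        .data$ratio > dup_ratio ~ "duplication",
        TRUE ~ "normal"))
}

#' Summarize CNV calls per region and morphotype pool
#'
#' Counts deletion and duplication carriers per region in the swede and
#' non-swede pools (or per morphotype) and reports the region's mean
#' normalized coverage.
#'
#' @param calls CNV call tibble from [call_cnv()].
#' @param panel Panel tibble (`accession`, `morphotype`).
#' @param by `"swede_pool"` (default; swede vs non-swede) or
#'   `"morphotype"`.
#' @return Tibble with one row per region and pool: deletion and
#'   duplication counts plus `mean_coverage`.
#' @export
cnv_pool_summary <- function(calls, panel, by = c("swede_pool",
                                                  "morphotype")) {
  by <- match.arg(by)
  assert_panel(panel)
  df <- dplyr::left_join(calls, panel, by = "accession")
  df$pool <- if (by == "swede_pool") {
    ifelse(df$morphotype == "swede", "swede", "non_swede")
  } else {
    as.character(df$morphotype)
  }
  df %>%
    dplyr::group_by(.data$region_id, .data$pool) %>%
    dplyr::summarise(
      deletions = sum(.data$call == "deletion"),
      duplications = sum(.data$call == "duplication"),
      n = dplyr::n(),
      mean_coverage = mean(.data$norm_cov),
      .groups = "drop")
}

#' Flag homoeologous non-reciprocal translocation (HNRT) candidates
#'
#' In an allopolyploid, replacement of a C-subgenome segment by its
#' A-subgenome homoeolog shows up as a duplication of the A-subgenome
#' region co-occurring with a deletion of the paired C-subgenome region in
#' the same genotype. Given a map of homoeologous region pairs, every
#' genotype with that joint pattern is flagged.
#'
#' @param calls CNV call tibble from [call_cnv()].
#' @param pairs Tibble `region_a`, `region_c` of homoeologous region ids.
#' @return Tibble `accession`, `region_a`, `region_c` of flagged
#'   genotype-pair combinations.
#' @export
flag_hnrt <- function(calls, pairs) {
  known <- unique(calls$region_id)
  bad <- setdiff(c(pairs$region_a, pairs$region_c), known)
  if (length(bad) > 0) {
    abort(sprintf("homoeolog map names unknown region(s): %s",
                  paste(utils::head(bad, 5), collapse = ", ")))
  }
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    a <- dplyr::filter(calls, .data$region_id == pairs$region_a[i],
                       .data$call == "duplication")
    c_ <- dplyr::filter(calls, .data$region_id == pairs$region_c[i],
                        .data$call == "deletion")
    hit <- intersect(a$accession, c_$accession)
    tibble::tibble(accession = hit,
                   region_a = pairs$region_a[i],
                   region_c = pairs$region_c[i])
  })
}
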