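#' Classify accession haplotypes across split regions
#'
#' For every accession and split region, the polarized state of each member
#' split marker is read off the genotype calls (pool-1 allele, pool-2
#' allele, or missing) and the region is classified: all non-missing states
#' pool-1 (and at least one observed) gives `clear_1`, all pool-2 gives
#' `clear_2`, both present gives `mixed`, and all markers missing gives
#' `deleted`. Partially missing but otherwise concordant haplotypes count
#' as clear unless `require_complete = TRUE`. Classification does not
#' depend on marker order within the region.
#'
#' @param gt A genotype tibble covering the split markers.
#' @param scan A `split_scan` object, or a list with elements `stats`
#'   (with `selected`, `pool1_allele`) and `regions` (from
#'   [group_regions()]).
#' @param require_complete If `TRUE`, a clear call requires every member
#'   marker to be observed; partially missing haplotypes become `mixed`.
#' @return Tibble of haplotype calls: `accession`, `region_id`, `state`
#'   (`clear_1`, `clear_2`, `mixed`, `deleted`), plus `label_1`/`label_2`
#'   attributes naming the pools.
#' @export
classify_haplotypes <- function(gt, scan, require_complete = FALSE) {
  assert_genotype_tibble(gt)
  stats <- scan$stats
  regions <- scan$regions
  if (nrow(regions) == 0) abort("no split regions to classify")

  sel <- dplyr::filter(stats, .data$selected)
  m <- genotype_matrix(gt)
  acc <- colnames(m)

  calls <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    ids <- regions$marker_ids[[i]]
    ridx <- match(ids, rownames(m))
    if (anyNA(ridx)) {
      abort(sprintf("region %s: split marker(s) absent from genotypes",
                    regions$region_id[i]))
    }
    sub <- m[ridx, , drop = FALSE]
    # orient dosage so 2 always means "carries the pool-1 allele"
    p1 <- sel$pool1_allele[match(ids, sel$marker_id)]
    flip <- p1 == "ref"
    sub[flip, ] <- 2L - sub[flip, , drop = FALSE]

    n_obs <- colSums(!is.na(sub))
    n_p1 <- colSums(sub == 2L, na.rm = TRUE)
    n_p2 <- colSums(sub == 0L, na.rm = TRUE)
    state <- dplyr::case_when(
      n_obs == 0 ~ "deleted",
      n_p1 > 0 & n_p2 > 0 ~ "mixed",
      require_complete & n_obs < nrow(sub) ~ "mixed",
      n_p1 == n_obs ~ "clear_1",
      TRUE ~ "clear_2")
    tibble::tibble(accession = acc, region_id = regions$region_id[i],
                   state = state)
  })
  attr(calls, "labels") <- scan$pools$labels
  calls
}

#' Tabulate haplotype states by region and morphotype
#'
#' Produces the per-region contingency counts of clear/mixed/deleted states
#' overall and by morphotype, and the per-accession histogram of how many
#' regions each accession carries in each clear state. Mixed haplotypes are
#' excluded from the clear-region counts, and the `mixed` count of
#' single-marker regions is reported as `NA` (a single marker cannot be
#' internally discordant).
#'
#' @param calls Haplotype-call tibble from [classify_haplotypes()].
#' @param panel Panel tibble (`accession`, `morphotype`).
#' @param regions Optional region tibble; when given, single-marker regions
#'   get `mixed = NA` in the summary.
#' @return List with `by_region` (region x state counts, total and per
#'   morphotype) and `per_accession` (accession, morphotype, n_clear_1,
#'   n_clear_2).
#' @export
haplotype_distribution <- function(calls, panel, regions = NULL) {
  assert_panel(panel)
  df <- dplyr::left_join(calls, panel, by = "accession")

  by_region <- df %>%
    dplyr::count(.data$region_id, .data$state) %>%
    tidyr::pivot_wider(names_from = "state", values_from = "n",
                       values_fill = 0L)
  for (s in c("clear_1", "clear_2", "mixed", "deleted")) {
    if (!s %in% names(by_region)) by_region[[s]] <- 0L
  }
  if (!is.null(regions)) {
    single <- regions$region_id[regions$n_markers == 1]
    by_region$mixed[by_region$region_id %in% single] <- NA_integer_
  }

  by_morphotype <- df %>%
    dplyr::count(.data$region_id, .data$morphotype, .data$state)

  per_accession <- df %>%
    dplyr::group_by(.data$accession, .data$morphotype) %>%
    dplyr::summarise(n_clear_1 = sum(.data$state == "clear_1"),
                     n_clear_2 = sum(.data$state == "clear_2"),
                     .groups = "drop")

  list(by_region = by_region,
       by_morphotype = by_morphotype,
       per_accession = per_accession)
}
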