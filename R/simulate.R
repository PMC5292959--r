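CHROMOSOMES <- c(paste0("chrA", sprintf("%02d", 1:10)),
                 paste0("chrC", sprintf("%02d", 1:9)))

#' Configuration for the synthetic panel generator
#'
#' Encodes the study conditions the generator emulates: a structured
#' *B. napus*-like diversity panel of 271 inbred accessions (139 winter, 7
#' semi-winter, 114 spring, 11 swede by default), genome-wide biallelic
#' markers of which a small minority form pool-diagnostic haplotype blocks,
#' and target-capture coverage with injected deletion/duplication events,
#' optionally as reciprocal A/C-subgenome (HNRT-like) pairs.
#'
#' Background markers share one alternate-allele frequency across all
#' pools (drawn uniformly on 0.05-0.95 per marker). Split markers come in
#' blocks of `markers_per_split_region` with block-identical carrier sets:
#' exactly `round(concordance * pool size)` members of each pool carry
#' their pool's diagnostic allele. Coverage counts are Poisson with
#' genotype-specific library sizes; CNV carriers' expected counts are
#' multiplied by the event fold.
#'
#' @param pool_sizes Named counts for `winter`, `semi_winter`, `spring`,
#'   `swede`.
#' @param n_markers Total marker count (background + injected).
#' @param n_split_regions_ws,n_split_regions_swede Injected diagnostic
#'   regions for the winter-spring and swede contrasts.
#' @param markers_per_split_region Markers per diagnostic block (default
#'   12, matching a ~300 kb block at the panel's ~40 markers/Mb density).
#' @param concordance Fraction of pool members carrying the diagnostic
#'   allele at split markers (1 = perfectly diagnostic).
#' @param missing_rate Independent per-call missingness.
#' @param n_regions_cov Number of target-capture coverage regions.
#' @param mean_coverage Baseline normalized coverage per region (regions
#'   vary uniformly 0.7-1.7x around it, cf. captured-gene coverages in the
#'   1000-1700 range).
#' @param cnv_events `NULL` (inject a default set of three deletions and
#'   three duplications), an empty tibble (none), or a tibble with columns
#'   `region` (integer index into the coverage regions), `accessions`
#'   (list-column of accession ids, or integer count to sample), `kind`
#'   (`deletion`/`duplication`) and `fold`.
#' @param hnrt_pairs `NULL` (one default pair), empty tibble, or tibble
#'   with columns `region_a`, `region_c` (indices) and `accessions` as
#'   above; carriers get fold 2 on the A member and fold 0 on the C member.
#' @param genome_length,read_length Reference genome size and average read
#'   length in bp used by the coverage normalization.
#' @param seed Integer seed fixing all randomness.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(pool_sizes = c(winter = 139, semi_winter = 7,
                                      spring = 114, swede = 11),
                       n_markers = 10000,
                       n_split_regions_ws = 10,
                       n_split_regions_swede = 5,
                       markers_per_split_region = 12,
                       concordance = 0.95,
                       missing_rate = 0.05,
                       n_regions_cov = 50,
                       mean_coverage = 1000,
                       cnv_events = NULL,
                       hnrt_pairs = NULL,
                       genome_length = 8.5e8,
                       read_length = 100,
                       seed = 1) {
  if (!all(MORPHOTYPES %in% names(pool_sizes))) {
    abort(sprintf("pool_sizes must name all of: %s",
                  paste(MORPHOTYPES, collapse = ", ")))
  }
  if (any(pool_sizes <= 0)) abort("pool sizes must be positive")
  for (fr in c(concordance = concordance, missing_rate = missing_rate)) {
    if (fr < 0 || fr > 1) abort("fractions must lie in [0, 1]")
  }
  n_inj <- (n_split_regions_ws + n_split_regions_swede) *
    markers_per_split_region
  if (n_markers <= n_inj) {
    abort("n_markers must exceed the number of injected split markers")
  }
  if (n_regions_cov < 2) abort("need at least two coverage regions")
  structure(list(
    pool_sizes = pool_sizes[MORPHOTYPES],
    n_markers = n_markers,
    n_split_regions_ws = n_split_regions_ws,
    n_split_regions_swede = n_split_regions_swede,
    markers_per_split_region = markers_per_split_region,
    concordance = concordance,
    missing_rate = missing_rate,
    n_regions_cov = n_regions_cov,
    mean_coverage = mean_coverage,
    cnv_events = cnv_events,
    hnrt_pairs = hnrt_pairs,
    genome_length = genome_length,
    read_length = read_length,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a structured panel with known ground truth
#'
#' Generates the morphotype panel, genotype tibble, target-capture
#' coverage tables and a `truth` record consistent with them. All
#' randomness derives from `config$seed` (stage-level sub-seeds are drawn
#' from it), so two calls with the same configuration are identical.
#'
#' @param config A [sim_config()].
#' @return A `morphosplit_sim` list: `panel` (accession, morphotype),
#'   `genotypes` (genotype tibble), `coverage` (list: `counts`, `totals`),
#'   and `truth` (split markers and regions per contrast, expected CNV
#'   calls, HNRT carriers, morphotype-derived cluster labels).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, 3)
  })
  panel <- make_panel(config)
  geno <- withr::with_seed(sub_seeds[1], make_genotypes(config, panel))
  cov <- withr::with_seed(sub_seeds[2], make_coverage(config, panel))

  truth <- list(
    split_markers = geno$truth_markers,
    split_regions = geno$truth_regions,
    cnv_calls = cov$truth,
    hnrt = cov$hnrt_truth,
    clusters = dplyr::mutate(panel, cluster = dplyr::case_when(
      morphotype == "winter" ~ 1L,
      morphotype %in% c("spring", "semi_winter") ~ 2L,
      TRUE ~ 3L))
  )
  structure(list(panel = panel, genotypes = geno$gt,
                 coverage = cov[c("counts", "totals")], truth = truth),
            class = "morphosplit_sim")
}

#' @export
print.morphosplit_sim <- function(x, ...) {
  cat(sprintf(
    "synthetic panel: %d accessions (%s), %d markers, %d coverage regions\n",
    nrow(x$panel),
    paste(table(factor(x$panel$morphotype, MORPHOTYPES)), collapse = "/"),
    nrow(x$genotypes), nrow(x$coverage$counts)))
  invisible(x)
}

make_panel <- function(config) {
  ps <- config$pool_sizes
  tibble::tibble(
    accession = sprintf("acc%03d", seq_len(sum(ps))),
    morphotype = rep(names(ps), ps))
}

# Deterministic placement: split regions occupy their own chromosome slots,
# far apart; markers within a block are 25 kb apart (~300 kb span).
place_split_regions <- function(n, offset = 0) {
  idx <- seq_len(n) - 1 + offset
  tibble::tibble(
    chromosome = CHROMOSOMES[(idx %% length(CHROMOSOMES)) + 1],
    start = 5e6 + (idx %/% length(CHROMOSOMES)) * 1.2e7)
}

make_genotypes <- function(config, panel) {
  n_acc <- nrow(panel)
  spacing <- 25000L
  n_ws <- config$n_split_regions_ws
  n_sw <- config$n_split_regions_swede
  mpr <- config$markers_per_split_region
  n_bg <- config$n_markers - (n_ws + n_sw) * mpr

  mt <- split(panel$accession, factor(panel$morphotype, MORPHOTYPES))
  chrom_len <- ceiling(config$genome_length / length(CHROMOSOMES))

  # background: common alternate-allele frequency across all pools
  bg_chrom <- sample(CHROMOSOMES, n_bg, replace = TRUE)
  bg_pos <- sample.int(chrom_len, n_bg, replace = TRUE)
  bg_p <- stats::runif(n_bg, 0.05, 0.95)
  bg_dos <- 2L * (matrix(stats::runif(n_bg * n_acc), n_bg, n_acc) < bg_p)

  # split blocks: exact per-pool carrier counts, block-identical haplotypes
  block <- function(regions, pool1_groups, pool2_groups, contrast,
                    region_offset) {
    n_reg <- nrow(regions)
    if (n_reg == 0) {
      return(list(dos = matrix(integer(), 0, n_acc),
                  meta = tibble::tibble(), truth = tibble::tibble(),
                  rtruth = tibble::tibble()))
    }
    dos <- matrix(0L, n_reg * mpr, n_acc)
    meta <- vector("list", n_reg)
    truth <- vector("list", n_reg)
    for (r in seq_len(n_reg)) {
      carrier1 <- unlist(lapply(pool1_groups, function(g) {
        sample(g, round(config$concordance * length(g)))
      }))
      carrier2 <- unlist(lapply(pool2_groups, function(g) {
        sample(g, round(config$concordance * length(g)))
      }))
      # pool-2 members not carrying their pool's allele carry pool-1's
      pool2_all <- unlist(pool2_groups)
      has_allele1 <- c(carrier1, setdiff(pool2_all, carrier2))
      idx <- match(has_allele1, panel$accession)
      # alternate allele is the pool-1 allele for even regions, pool-2 odd
      alt_is_pool1 <- (r %% 2) == 0
      rows <- (r - 1) * mpr + seq_len(mpr)
      v <- rep(0L, n_acc)
      v[idx] <- 2L
      if (!alt_is_pool1) v <- 2L - v
      dos[rows, ] <- matrix(v, mpr, n_acc, byrow = TRUE)
      pos <- regions$start[r] + (seq_len(mpr) - 1L) * spacing
      ids <- sprintf("split_%s_r%02d_m%02d", contrast,
                     r + region_offset, seq_len(mpr))
      meta[[r]] <- tibble::tibble(
        marker_id = ids, chromosome = regions$chromosome[r],
        position = as.integer(pos))
      truth[[r]] <- tibble::tibble(
        marker_id = ids, contrast = contrast,
        region = sprintf("%s_r%02d", contrast, r + region_offset),
        chromosome = regions$chromosome[r],
        position = as.integer(pos),
        alt_is_pool1 = alt_is_pool1)
    }
    rtruth <- dplyr::bind_rows(truth) %>%
      dplyr::group_by(.data$region, .data$contrast, .data$chromosome) %>%
      dplyr::summarise(start = min(.data$position),
                       end = max(.data$position), .groups = "drop")
    list(dos = dos, meta = dplyr::bind_rows(meta),
         truth = dplyr::bind_rows(truth), rtruth = rtruth)
  }

  ws <- block(place_split_regions(n_ws),
              list(mt$winter, mt$swede),
              list(mt$spring, mt$semi_winter),
              "winter_spring", 0)
  sw <- block(place_split_regions(n_sw, offset = n_ws),
              list(setdiff(panel$accession, mt$swede)),
              list(mt$swede),
              "swede", 0)

  meta <- dplyr::bind_rows(
    tibble::tibble(marker_id = sprintf("bg%06d", seq_len(n_bg)),
                   chromosome = bg_chrom, position = bg_pos),
    ws$meta, sw$meta)
  dosage <- rbind(bg_dos, ws$dos, sw$dos)

  if (config$missing_rate > 0) {
    dosage[matrix(stats::runif(length(dosage)), nrow(dosage)) <
             config$missing_rate] <- NA_integer_
  }
  colnames(dosage) <- panel$accession
  meta <- meta %>%
    dplyr::mutate(source = "array", allele_ref = "A", allele_alt = "B") %>%
    dplyr::select(dplyr::all_of(GENO_META))

  gt <- new_genotype_tibble(meta, dosage) %>%
    dplyr::arrange(.data$chromosome, .data$position)

  list(gt = gt,
       truth_markers = dplyr::bind_rows(ws$truth, sw$truth),
       truth_regions = dplyr::bind_rows(ws$rtruth, sw$rtruth))
}

default_cnv_events <- function(config, panel) {
  tibble::tibble(
    region = 1:6,
    accessions = 8L,
    kind = rep(c("deletion", "duplication"), each = 3),
    fold = rep(c(0, 2), each = 3))
}

make_coverage <- function(config, panel) {
  n_acc <- nrow(panel)
  n_reg <- config$n_regions_cov
  regions <- tibble::tibble(
    region_id = sprintf("cov%03d", seq_len(n_reg)),
    chromosome = CHROMOSOMES[(seq_len(n_reg) - 1) %% length(CHROMOSOMES) + 1],
    start = 1e6 + ((seq_len(n_reg) - 1) %/% length(CHROMOSOMES)) * 50000L)
  regions$stop <- regions$start + 2999L

  totals <- tibble::tibble(
    accession = panel$accession,
    total_reads = round(stats::rlnorm(n_acc, log(2e7), 0.2)))

  # per-region baseline normalized coverage
  region_cov <- config$mean_coverage * stats::runif(n_reg, 0.7, 1.7)

  events <- config$cnv_events %||% default_cnv_events(config, panel)
  hnrt <- config$hnrt_pairs %||%
    tibble::tibble(region_a = 7L, region_c = 8L, accessions = 8L)
  resolve_acc <- function(a) {
    if (is.numeric(a)) sample(panel$accession, a) else a
  }
  if (nrow(events) > 0 && !is.list(events$accessions)) {
    events$accessions <- lapply(events$accessions, resolve_acc)
  }
  if (nrow(hnrt) > 0 && !is.list(hnrt$accessions)) {
    hnrt$accessions <- lapply(hnrt$accessions, resolve_acc)
  }

  fold <- matrix(1, n_reg, n_acc, dimnames = list(regions$region_id,
                                                  panel$accession))
  truth <- list()
  apply_event <- function(region_idx, acc, f, kind) {
    fold[region_idx, acc] <<- f
    truth[[length(truth) + 1]] <<- tibble::tibble(
      region_id = regions$region_id[region_idx], accession = acc,
      kind = kind, fold = f)
  }
  if (nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      apply_event(events$region[i], events$accessions[[i]],
                  events$fold[i], events$kind[i])
    }
  }
  hnrt_truth <- tibble::tibble(accession = character(),
                               region_a = character(),
                               region_c = character())
  if (nrow(hnrt) > 0) {
    for (i in seq_len(nrow(hnrt))) {
      acc <- hnrt$accessions[[i]]
      apply_event(hnrt$region_a[i], acc, 2, "duplication")
      apply_event(hnrt$region_c[i], acc, 0, "deletion")
      hnrt_truth <- dplyr::bind_rows(hnrt_truth, tibble::tibble(
        accession = acc,
        region_a = regions$region_id[hnrt$region_a[i]],
        region_c = regions$region_id[hnrt$region_c[i]]))
    }
  }

  # expected raw reads so that normalized coverage hits the target:
  # reads = ncov * totals * read_length / genome_length
  lam <- outer(region_cov, totals$total_reads *
                 config$read_length / config$genome_length) * fold
  counts <- matrix(stats::rpois(length(lam), lam), n_reg, n_acc,
                   dimnames = dimnames(fold))

  list(counts = dplyr::bind_cols(regions,
                                 tibble::as_tibble(as.data.frame(counts))),
       totals = totals,
       truth = dplyr::bind_rows(truth),
       hnrt_truth = hnrt_truth)
}

#' Write a simulated panel in the formats the ingest functions read
#'
#' Emits the array-dialect genotype TSV (letter-pair calls, optionally with
#' injected heterozygous cells to exercise the het-to-missing recode rule),
#' the panel TSV, coverage count/total TSVs and a truth JSON.
#'
#' @param sim A `morphosplit_sim` from [simulate_panel()].
#' @param dir Output directory (created if needed).
#' @param het_rate Fraction of non-missing calls rewritten as heterozygous
#'   letter pairs in the array TSV (default 0).
#' @param seed Seed for the heterozygous-cell draw.
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir, het_rate = 0, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt <- sim$genotypes
  m <- genotype_matrix(gt)
  letters_mat <- matrix(NA_character_, nrow(m), ncol(m),
                        dimnames = dimnames(m))
  ref2 <- paste0(gt$allele_ref, gt$allele_ref)
  alt2 <- paste0(gt$allele_alt, gt$allele_alt)
  het2 <- paste0(gt$allele_ref, gt$allele_alt)
  for (j in seq_len(ncol(m))) {
    letters_mat[, j] <- ifelse(is.na(m[, j]), NA_character_,
                               ifelse(m[, j] == 0L, ref2, alt2))
  }
  if (het_rate > 0) {
    withr::with_seed(seed, {
      flip <- !is.na(letters_mat) &
        matrix(stats::runif(length(letters_mat)), nrow(letters_mat)) < het_rate
    })
    letters_mat[flip] <- matrix(het2, nrow(m), ncol(m))[flip]
  }
  arr <- dplyr::bind_cols(gt[, c("marker_id", "chromosome", "position")],
                          tibble::as_tibble(as.data.frame(letters_mat)))
  readr::write_tsv(arr, file.path(dir, "array_genotypes.tsv"), na = "--")
  readr::write_tsv(sim$panel, file.path(dir, "panel.tsv"))
  readr::write_tsv(sim$coverage$counts, file.path(dir, "coverage_counts.tsv"))
  readr::write_tsv(sim$coverage$totals, file.path(dir, "coverage_totals.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
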