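PIPELINE_KEYS <- list(
  top = c("seed", "out_dir", "simulate", "inputs", "qc", "structure",
          "scan", "cnv", "candidates"),
  simulate = c("pool_sizes", "n_markers", "n_split_regions_ws",
               "n_split_regions_swede", "markers_per_split_region",
               "concordance", "missing_rate", "n_regions_cov",
               "mean_coverage", "genome_length", "read_length"),
  inputs = c("array", "snp_vcf", "indel_vcf", "panel", "coverage_counts",
             "coverage_totals"),
  qc = c("marker_callrate", "maf", "ind_callrate", "min_mq", "min_depth"),
  structure = c("n_components", "k_min", "k_max", "n_restarts", "k"),
  scan = c("contrasts", "top_frac", "alpha", "max_gap", "suit_expected"),
  cnv = c("genome_length", "read_length", "min_mean_coverage", "ref_stat"),
  candidates = c("annotation", "window")
)

validate_config <- function(cfg) {
  check <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown) > 0) {
      abort(sprintf("unknown configuration key(s) in %s: %s",
                    where, paste(unknown, collapse = ", ")))
    }
  }
  check(cfg, PIPELINE_KEYS$top, "config")
  for (s in intersect(names(cfg), names(PIPELINE_KEYS)[-1])) {
    check(cfg[[s]], PIPELINE_KEYS[[s]], s)
  }
  invisible(cfg)
}

#' Run the full split-marker analysis pipeline
#'
#' Orchestrates simulate (or ingest) -> QC -> population structure ->
#' split scans -> haplotype classification -> CNV calling -> candidate
#' genes from one configuration (a YAML file or an equivalent nested
#' list), writing every stage's tables to `out_dir` together with a run
#' manifest (parameters, seed, package version, input checksums). Reruns
#' with the same configuration and seed reproduce identical tables.
#'
#' Stage parameters default to the panel-analysis values: QC call rate
#' 0.9 / MAF 0.01 / individual call rate 0.8, suitability alpha 0.1, top
#' fraction 0.001, CNV ratio thresholds 0.5 and 1.5, 1 Mb candidate
#' window, k range 1-15.
#'
#' @param config Path to a YAML file or a named list. Top-level keys:
#'   `seed`, `out_dir`, and optional stage blocks `simulate` (synthetic
#'   run; fields as [sim_config()]), `inputs` (paths: `array`, `snp_vcf`,
#'   `indel_vcf`, `panel`, `coverage_counts`, `coverage_totals`), `qc`,
#'   `structure`, `scan`, `cnv`, `candidates`. Unknown keys raise an
#'   error naming them.
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  validate_config(cfg)
  seed <- as.integer(cfg$seed %||% 1)
  out_dir <- cfg$out_dir %||% abort("config needs `out_dir`")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  input_files <- character()

  # --- inputs: simulate or ingest ---------------------------------------
  if (!is.null(cfg$simulate)) {
    sc <- do.call(sim_config, c(cfg$simulate, list(seed = seed)))
    sim <- simulate_panel(sc)
    panel <- sim$panel
    gt <- sim$genotypes
    coverage <- sim$coverage
    res$sim <- sim
  } else if (!is.null(cfg$inputs)) {
    inp <- cfg$inputs
    if (is.null(inp$panel)) abort("inputs stage needs `panel`")
    input_files <- unlist(inp[c("array", "snp_vcf", "indel_vcf", "panel",
                                "coverage_counts", "coverage_totals")])
    panel <- readr::read_tsv(inp$panel, col_types = "cc")
    assert_panel(panel)
    parts <- list()
    if (!is.null(inp$array)) {
      parts$array <- read_array_genotypes(inp$array)
    }
    if (!is.null(inp$snp_vcf)) {
      parts$snp <- read_vcf_snps(inp$snp_vcf)
    }
    if (!is.null(inp$indel_vcf)) {
      qc <- cfg$qc %||% list()
      parts$indel <- read_vcf_indels(inp$indel_vcf) %>%
        filter_indel_calls(min_mq = qc$min_mq %||% 30,
                           min_depth = qc$min_depth %||% 10) %>%
        recode_indels()
    }
    if (length(parts) == 0) abort("inputs stage names no genotype source")
    gt <- do.call(merge_and_sort, unname(parts))
    coverage <- NULL
    if (!is.null(inp$coverage_counts) && !is.null(inp$coverage_totals)) {
      coverage <- list(
        counts = readr::read_tsv(inp$coverage_counts,
                                 show_col_types = FALSE),
        totals = readr::read_tsv(inp$coverage_totals,
                                 show_col_types = FALSE))
    }
  } else {
    abort("config needs a `simulate` or an `inputs` stage")
  }
  readr::write_tsv(panel, file.path(out_dir, "panel.tsv"))
  write_genotypes(gt, file.path(out_dir, "genotypes_merged.tsv"))

  # --- QC ----------------------------------------------------------------
  qc <- cfg$qc %||% list()
  gt <- qc_filter(gt,
                  marker_callrate = qc$marker_callrate %||% 0.9,
                  maf = qc$maf %||% 0.01,
                  ind_callrate = qc$ind_callrate %||% 0.8)
  panel <- dplyr::filter(panel, .data$accession %in% accessions(gt))
  write_genotypes(gt, file.path(out_dir, "genotypes_qc.tsv"))
  res$genotypes <- gt

  # --- population structure ---------------------------------------------
  st <- cfg$structure %||% list()
  struct <- population_structure(
    gt,
    n_components = st$n_components %||% 4,
    k_range = (st$k_min %||% 1):(st$k_max %||% 15),
    n_restarts = st$n_restarts %||% 25,
    k = st$k,
    seed = seed)
  readr::write_tsv(tibble::as_tibble(struct$dist, rownames = "accession"),
                   file.path(out_dir, "distance.tsv"))
  readr::write_tsv(tidy(struct$ordination), file.path(out_dir, "coords.tsv"))
  readr::write_tsv(struct$clustering$wss, file.path(out_dir, "wss.tsv"))
  readr::write_tsv(tidy(struct$clustering),
                   file.path(out_dir, "clusters.tsv"))
  res$structure <- struct

  # --- split scans + haplotypes -----------------------------------------
  sc_par <- cfg$scan %||% list()
  contrasts <- sc_par$contrasts %||% c("winter_spring", "swede")
  res$scans <- list()
  for (ct in contrasts) {
    scan <- split_scan(gt, panel, contrast = ct,
                       top_frac = sc_par$top_frac %||% 0.001,
                       alpha = sc_par$alpha %||% 0.1,
                       max_gap = sc_par$max_gap %||% 1e6,
                       suit_expected = sc_par$suit_expected %||%
                         "pool_sizes")
    readr::write_tsv(dplyr::select(scan$stats, -dplyr::any_of("marker_ids")),
                     file.path(out_dir, sprintf("scan_%s_stats.tsv", ct)))
    if (nrow(scan$regions) > 0) {
      write_regions_bed(scan$regions,
                        file.path(out_dir, sprintf("regions_%s.bed", ct)))
      calls <- classify_haplotypes(gt, scan)
      dist <- haplotype_distribution(calls, panel, scan$regions)
      readr::write_tsv(calls,
                       file.path(out_dir,
                                 sprintf("haplotypes_%s.tsv", ct)))
      readr::write_tsv(dist$by_region,
                       file.path(out_dir,
                                 sprintf("haplotype_counts_%s.tsv", ct)))
      res$scans[[ct]] <- list(scan = scan, haplotypes = calls,
                              distribution = dist)
    } else {
      res$scans[[ct]] <- list(scan = scan)
    }
  }

  # --- CNV ---------------------------------------------------------------
  if (!is.null(coverage)) {
    cv <- cfg$cnv %||% list()
    norm <- normalize_coverage(coverage$counts, coverage$totals,
                               genome_length = cv$genome_length %||% 8.5e8,
                               read_length = cv$read_length %||% 100)
    calls <- call_cnv(norm,
                      min_mean_coverage = cv$min_mean_coverage %||% 10,
                      ref_stat = cv$ref_stat %||% "mean")
    readr::write_tsv(calls, file.path(out_dir, "cnv_calls.tsv"))
    readr::write_tsv(cnv_pool_summary(calls, panel),
                     file.path(out_dir, "cnv_summary.tsv"))
    res$cnv <- calls
  }

  # --- candidate genes ---------------------------------------------------
  if (!is.null(cfg$candidates)) {
    ann <- read_gene_annotation(cfg$candidates$annotation)
    input_files <- c(input_files, cfg$candidates$annotation)
    for (ct in names(res$scans)) {
      scan <- res$scans[[ct]]$scan
      if (nrow(scan$regions) == 0) next
      cand <- genes_near_markers(scan, ann,
                                 window = cfg$candidates$window %||% 1e6)
      readr::write_tsv(cand,
                       file.path(out_dir,
                                 sprintf("candidates_%s.tsv", ct)))
      res$scans[[ct]]$candidates <- cand
    }
  }

  # --- manifest ----------------------------------------------------------
  manifest <- list(
    package = "morphosplit",
    version = as.character(utils::packageVersion("morphosplit")),
    seed = seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    input_checksums = as.list(tools::md5sum(
      input_files[file.exists(input_files %||% character())]))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(res)
}
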