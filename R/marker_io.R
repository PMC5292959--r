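#' Read SNP-array genotype calls
#'
#' Reads the array dialect: a TSV with columns `marker_id`, `chromosome`,
#' `position`, followed by one column per accession containing two-letter
#' genotype strings (e.g. `"AA"`, `"AB"`, `"CC"`). Heterozygous calls (the
#' two letters differ) are treated as missing values, as are empty strings,
#' `"--"` and `"NN"`. Each marker must be biallelic over the panel; the two
#' homozygous classes observed are mapped to dosage 0 (alphabetically first
#' allele) and 2.
#'
#' @param x Path to a TSV file, or a data frame already in that layout.
#' @return A genotype tibble (see [accessions()]) with `source = "array"`.
#' @export
read_array_genotypes <- function(x) {
  tab <- if (is.character(x)) {
    readr::read_tsv(x, col_types = readr::cols(
      marker_id = readr::col_character(),
      chromosome = readr::col_character(),
      position = readr::col_double(),
      .default = readr::col_character()
    ))
  } else {
    tibble::as_tibble(x)
  }
  need <- c("marker_id", "chromosome", "position")
  if (!all(need %in% names(tab))) {
    abort(paste("array genotype table must have columns",
                paste(need, collapse = ", ")))
  }
  acc <- setdiff(names(tab), need)
  if (anyDuplicated(acc)) {
    abort(sprintf("duplicated accession column(s): %s",
                  paste(unique(acc[duplicated(acc)]), collapse = ", ")))
  }
  if (anyDuplicated(tab$marker_id)) {
    abort(sprintf("duplicated marker_id(s): %s",
                  paste(unique(tab$marker_id[duplicated(tab$marker_id)]),
                        collapse = ", ")))
  }

  calls <- as.matrix(tab[, acc, drop = FALSE])
  calls[calls %in% c("", "--", "NN", "NA")] <- NA_character_
  ok <- is.na(calls) | grepl("^[A-Za-z]{2}$", calls)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    abort(sprintf("unknown genotype code '%s' at marker '%s', accession '%s'",
                  calls[bad[1], bad[2]], tab$marker_id[bad[1]], acc[bad[2]]))
  }
  a1 <- substr(calls, 1, 1)
  a2 <- substr(calls, 2, 2)
  het <- !is.na(calls) & a1 != a2
  a1[het] <- NA_character_ # heterozygous -> missing

  dosage <- matrix(NA_integer_, nrow(calls), ncol(calls),
                   dimnames = list(NULL, acc))
  allele_ref <- allele_alt <- rep(NA_character_, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    al <- sort(unique(stats::na.omit(a1[i, ])))
    if (length(al) > 2) {
      abort(sprintf("marker '%s' has more than two alleles: %s",
                    tab$marker_id[i], paste(al, collapse = ", ")))
    }
    if (length(al) >= 1) {
      allele_ref[i] <- al[1]
      dosage[i, ] <- ifelse(is.na(a1[i, ]), NA_integer_,
                            ifelse(a1[i, ] == al[1], 0L, 2L))
    }
    allele_alt[i] <- if (length(al) == 2) al[2] else NA_character_
  }

  meta <- tibble::tibble(
    marker_id = tab$marker_id,
    chromosome = tab$chromosome,
    position = as.integer(tab$position),
    source = "array",
    allele_ref = allele_ref,
    allele_alt = allele_alt
  )
  new_genotype_tibble(meta, dosage)
}

#' Read biallelic SNPs from a VCF into a genotype tibble
#'
#' Multiallelic records are dropped with a warning. Genotypes `0/0` map to
#' dosage 0, `1/1` to dosage 2; heterozygous and missing genotypes become
#' `NA` (the panel consists of inbred lines).
#'
#' @param path Path to a VCF (v4.x) file.
#' @return A genotype tibble with `source = "seq_snp"`.
#' @export
read_vcf_snps <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v),
                                         stringsAsFactors = FALSE))
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warn(sprintf("dropping %d multiallelic record(s)", sum(multi)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- !multi
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]

  dosage <- gt_to_dosage(gt)
  ids <- fix$ID
  no_id <- is.na(ids) | ids == "." | ids == ""
  ids[no_id] <- paste0(fix$CHROM[no_id], "_", fix$POS[no_id])
  meta <- tibble::tibble(
    marker_id = ids,
    chromosome = fix$CHROM,
    position = as.integer(fix$POS),
    source = "seq_snp",
    allele_ref = fix$REF,
    allele_alt = fix$ALT
  )
  new_genotype_tibble(meta, dosage)
}

# "0/0" or "0|0" -> 0; "1/1" -> 2; anything het or missing -> NA
gt_to_dosage <- function(gt) {
  g <- gsub("|", "/", gt, fixed = TRUE)
  d <- matrix(NA_integer_, nrow(g), ncol(g), dimnames = dimnames(g))
  d[g == "0/0"] <- 0L
  d[g == "1/1"] <- 2L
  d
}

#' Read InDel records from a VCF
#'
#' Returns one row per InDel with its mapping quality (`MQ`) and read depth
#' (`DP`) pulled from the INFO field, the event kind inferred from allele
#' lengths, and one column per accession coded `"ref"`, `"alt"`, `"het"` or
#' `NA`.
#'
#' @param path Path to a VCF file of InDel calls.
#' @return A tibble of InDel records.
#' @export
read_vcf_indels <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v),
                                         stringsAsFactors = FALSE))
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warn(sprintf("dropping %d multiallelic record(s)", sum(multi)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "MQ")))
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "DP")))
  keep <- !multi
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  mq <- mq[keep]
  dp <- dp[keep]

  g <- gsub("|", "/", gt, fixed = TRUE)
  state <- matrix(NA_character_, nrow(g), ncol(g), dimnames = dimnames(g))
  state[g == "0/0"] <- "ref"
  state[g == "1/1"] <- "alt"
  state[g %in% c("0/1", "1/0")] <- "het"

  ids <- fix$ID
  no_id <- is.na(ids) | ids == "." | ids == ""
  ids[no_id] <- paste0(fix$CHROM[no_id], "_", fix$POS[no_id])
  meta <- tibble::tibble(
    marker_id = ids,
    chromosome = fix$CHROM,
    position = as.integer(fix$POS),
    kind = ifelse(nchar(fix$ALT) > nchar(fix$REF), "insertion", "deletion"),
    mq = mq,
    depth = dp
  )
  dplyr::bind_cols(meta, tibble::as_tibble(as.data.frame(state)))
}

#' Filter InDel records on mapping quality and depth
#'
#' Records are kept if and only if `mq >= min_mq` and `depth >= min_depth`
#' (so MQ 30 / DP 10 pass at the defaults while MQ 29 or DP 9 do not).
#' Records missing either field are rejected with a warning.
#'
#' @param records InDel record tibble from [read_vcf_indels()].
#' @param min_mq Minimum mapping quality (phred), default 30.
#' @param min_depth Minimum read depth, default 10.
#' @return Filtered tibble.
#' @export
filter_indel_calls <- function(records, min_mq = 30, min_depth = 10) {
  no_field <- is.na(records$mq) | is.na(records$depth)
  if (any(no_field)) {
    warn(sprintf("rejecting %d InDel record(s) lacking MQ or DP",
                 sum(no_field)))
  }
  dplyr::filter(records,
                !is.na(.data$mq), !is.na(.data$depth),
                .data$mq >= min_mq, .data$depth >= min_depth)
}

#' Recode InDel records as pseudo-SNP genotypes
#'
#' Reference alleles are coded as the homozygous `A` class (dosage 0),
#' insertion carriers as `C` and deletion carriers as `T` (dosage 2);
#' heterozygous calls become missing.
#'
#' @param records Filtered InDel record tibble.
#' @return A genotype tibble with `source = "seq_indel"`.
#' @export
recode_indels <- function(records) {
  acc <- setdiff(names(records),
                 c("marker_id", "chromosome", "position", "kind",
                   "mq", "depth"))
  state <- as.matrix(records[, acc, drop = FALSE])
  dosage <- matrix(NA_integer_, nrow(state), ncol(state),
                   dimnames = list(NULL, acc))
  dosage[state == "ref"] <- 0L
  dosage[state == "alt"] <- 2L
  meta <- tibble::tibble(
    marker_id = records$marker_id,
    chromosome = records$chromosome,
    position = as.integer(records$position),
    source = "seq_indel",
    allele_ref = "A",
    allele_alt = ifelse(records$kind == "insertion", "C", "T")
  )
  new_genotype_tibble(meta, dosage)
}

#' Merge genotype tibbles from several sources and sort by position
#'
#' Accessions are intersected across the inputs (with a warning when any
#' input carries extra accessions). Markers duplicated at the same
#' (chromosome, position, allele pair) are collapsed to the record with the
#' fewest missing calls (first-seen wins ties). The result is sorted by
#' chromosome then position, stably for ties.
#'
#' @param ... Two or more genotype tibbles (e.g. array, sequencing SNP and
#'   recoded InDel matrices).
#' @return One merged genotype tibble.
#' @export
merge_and_sort <- function(...) {
  parts <- purrr::compact(list(...))
  stopifnot(length(parts) >= 1)
  purrr::walk(parts, assert_genotype_tibble)

  acc_sets <- purrr::map(parts, accessions)
  shared <- purrr::reduce(acc_sets, intersect)
  if (length(shared) == 0) {
    abort("no accession is shared by all inputs")
  }
  if (any(lengths(acc_sets) > length(shared))) {
    warn(sprintf(
      "accession sets differ across inputs; keeping the %d shared accessions",
      length(shared)))
  }
  parts <- purrr::map(parts, ~ .x[, c(GENO_META, shared)])
  merged <- dplyr::bind_rows(parts)

  n_miss <- rowSums(is.na(genotype_matrix(merged)))
  allele_key <- purrr::map2_chr(merged$allele_ref, merged$allele_alt,
                                ~ paste(sort(c(.x, .y)), collapse = "/"))
  merged <- merged %>%
    dplyr::mutate(.miss = n_miss, .akey = allele_key, .ord = dplyr::row_number()) %>%
    dplyr::arrange(.data$.miss, .data$.ord) %>%
    dplyr::distinct(.data$chromosome, .data$position, .data$.akey,
                    .keep_all = TRUE) %>%
    dplyr::arrange(.data$chromosome, .data$position, .data$.ord) %>%
    dplyr::select(-".miss", -".akey", -".ord")

  if (anyDuplicated(merged$marker_id)) {
    dup <- unique(merged$marker_id[duplicated(merged$marker_id)])
    abort(sprintf("marker_id(s) not unique after merge: %s",
                  paste(utils::head(dup, 5), collapse = ", ")))
  }
  merged
}

#' Quality-filter a merged genotype tibble
#'
#' Markers are kept when their call rate is strictly greater than
#' `marker_callrate` and their minor allele frequency strictly greater than
#' `maf` (allele counts are twice the homozygous genotype counts, missing
#' excluded); accessions are then kept when their individual call rate over
#' the retained markers is strictly greater than `ind_callrate`. Marker
#' filters run before the individual filter, each applied once.
#'
#' @param gt A genotype tibble.
#' @param marker_callrate Minimum (exclusive) per-marker call rate.
#' @param maf Minimum (exclusive) minor allele frequency.
#' @param ind_callrate Minimum (exclusive) per-accession call rate.
#' @return The filtered genotype tibble.
#' @export
qc_filter <- function(gt, marker_callrate = 0.9, maf = 0.01,
                      ind_callrate = 0.8) {
  assert_genotype_tibble(gt)
  m <- genotype_matrix(gt)

  callrate <- rowMeans(!is.na(m))
  f_alt <- rowMeans(m == 2, na.rm = TRUE) # == alt allele frequency (inbred)
  f_alt[is.nan(f_alt)] <- 0
  maf_obs <- pmin(f_alt, 1 - f_alt)
  keep_marker <- callrate > marker_callrate & maf_obs > maf

  m2 <- m[keep_marker, , drop = FALSE]
  if (nrow(m2) == 0) abort("all markers removed by QC filters")
  ind_rate <- colMeans(!is.na(m2))
  keep_ind <- ind_rate > ind_callrate
  if (!any(keep_ind)) abort("all accessions removed by QC filters")

  out <- gt[keep_marker, c(GENO_META, accessions(gt)[keep_ind])]
  tibble::as_tibble(out)
}

#' Write / read the canonical merged genotype TSV
#'
#' The canonical format stores the metadata columns followed by accession
#' dosage columns (0/2/NA).
#'
#' @param gt A genotype tibble.
#' @param path Output (or input) TSV path.
#' @return `write_genotypes()` returns `path` invisibly; `read_genotypes()`
#'   returns a genotype tibble.
#' @export
write_genotypes <- function(gt, path) {
  assert_genotype_tibble(gt)
  readr::write_tsv(gt, path)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  gt <- readr::read_tsv(path, col_types = readr::cols(
    marker_id = readr::col_character(),
    chromosome = readr::col_character(),
    position = readr::col_integer(),
    source = readr::col_character(),
    allele_ref = readr::col_character(),
    allele_alt = readr::col_character(),
    .default = readr::col_integer()
  ))
  assert_genotype_tibble(gt)
  gt
}

`%||%` <- function(a, b) if (is.null(a)) b else a
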