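#' Read a gene annotation from GFF3 or a gene table
#'
#' GFF3 files are read with `ape::read.gff`; rows of type `gene` are kept
#' and `gene_id` / `name` parsed from the `ID=` and `Name=` attributes. A
#' TSV alternative with columns `gene_id`, `chromosome`, `start`, `stop`
#' (1-based inclusive) and optionally `name` is accepted as-is.
#'
#' @param path Path to a `.gff`/`.gff3` or TSV file.
#' @return Tibble `gene_id`, `chromosome`, `start`, `stop`, `name`.
#' @export
read_gene_annotation <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    g <- ape::read.gff(path)
    g <- g[g$type == "gene", , drop = FALSE]
    attr_field <- function(x, key) {
      hit <- regexpr(paste0("(^|;)", key, "=[^;]+"), x)
      out <- rep(NA_character_, length(x))
      got <- hit > 0
      out[got] <- sub(paste0("^;?", key, "="), "", regmatches(x, hit))
      out
    }
    ann <- tibble::tibble(
      gene_id = attr_field(as.character(g$attributes), "ID"),
      chromosome = as.character(g$seqid),
      start = as.integer(g$start),
      stop = as.integer(g$end),
      name = attr_field(as.character(g$attributes), "Name"))
  } else {
    ann <- readr::read_tsv(path, col_types = readr::cols(
      gene_id = readr::col_character(),
      chromosome = readr::col_character(),
      start = readr::col_integer(),
      stop = readr::col_integer(),
      .default = readr::col_character()))
    if (!"name" %in% names(ann)) ann$name <- NA_character_
  }
  if (any(ann$start > ann$stop)) abort("gene annotation has start > stop")
  ann
}

#' Candidate genes near split markers
#'
#' For each split region, reports every annotated gene lying within
#' `window` bp of any member split marker (genes on other chromosomes are
#' skipped). The distance is measured from the closest member marker to the
#' nearest gene boundary, in kbp; a marker inside the gene interval gives
#' distance 0.0. Increasing the window can only add candidates.
#'
#' @param scan A `split_scan` object, or a list with `stats` (selected
#'   markers with positions) and `regions`.
#' @param annotation Gene annotation tibble from [read_gene_annotation()].
#' @param window Maximum marker-to-gene distance in bp (default 1 Mb).
#' @return Tibble `region_id`, `gene_id`, `name`, `chromosome`,
#'   `gene_start`, `gene_stop`, `closest_marker`, `distance_kbp`, sorted by
#'   region then distance.
#' @export
genes_near_markers <- function(scan, annotation, window = 1e6) {
  stats <- dplyr::filter(scan$stats, .data$selected)
  regions <- scan$regions
  purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    mk <- dplyr::filter(stats,
                        .data$marker_id %in% regions$marker_ids[[i]])
    genes <- dplyr::filter(annotation,
                           .data$chromosome == regions$chromosome[i])
    if (nrow(genes) == 0) return(NULL)
    purrr::map_dfr(seq_len(nrow(genes)), function(j) {
      inside <- mk$position >= genes$start[j] & mk$position <= genes$stop[j]
      d <- ifelse(inside, 0,
                  pmin(abs(mk$position - genes$start[j]),
                       abs(mk$position - genes$stop[j])))
      if (min(d) > window) return(NULL)
      tibble::tibble(
        region_id = regions$region_id[i],
        gene_id = genes$gene_id[j],
        name = genes$name[j],
        chromosome = genes$chromosome[j],
        gene_start = genes$start[j],
        gene_stop = genes$stop[j],
        closest_marker = mk$marker_id[which.min(d)],
        distance_kbp = min(d) / 1000)
    })
  }) %>%
    dplyr::arrange(.data$region_id, .data$distance_kbp)
}
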