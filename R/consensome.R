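#' Build per-node consensomes from a peak-strength table
#'
#' A consensome ranks, for one pathway node (the ChIP-Seq IP antigen), all
#' genes by the mean of their peak strengths across that node's datasets.
#' A dataset in which a gene has no record contributes strength 0 to the
#' mean: a dataset that detected no peak for the gene is treated as
#' evidence of absence. Genes whose mean strength is 0 for a node are
#' excluded from that node's list (they are not targeted, not
#' bottom-ranked); `M` below is the number of genes retained.
#'
#' Ranking and percentiles: ranks are averaged within ties (`rank` is a
#' permutation of `1..M` up to tie averaging); the percentile of a gene is
#' `100 * (M - r_min) / M` where `r_min` is the best (minimum) position of
#' its tie block, so tied genes share the block's maximum percentile.
#' Percentiles therefore lie in `[0, 100)`, non-increasing in rank, and
#' are invariant to rescaling all strengths by a positive constant.
#'
#' @param peaks A peak-strength table: tibble with columns `dataset_id`,
#'   `node`, `gene`, `strength` (>= 0, one record per dataset/node/gene;
#'   every dataset belongs to exactly one node).
#' @param annotations Optional tibble keyed by `node` with e.g.
#'   `category`, `class`, `family`, joined onto the result.
#' @return A tibble of class `consensome_tbl` with columns `node, gene,
#'   mean_strength, rank, percentile, n_datasets` (plus annotation
#'   columns), sorted by node then rank.
#' @export
build_consensomes <- function(peaks, annotations = NULL) {
  validate_peak_table(peaks)
  n_ds <- peaks |>
    dplyr::distinct(.data$node, .data$dataset_id) |>
    dplyr::count(.data$node, name = "n_datasets")
  cons <- peaks |>
    dplyr::group_by(.data$node, .data$gene) |>
    dplyr::summarise(total = sum(.data$strength), .groups = "drop") |>
    dplyr::left_join(n_ds, by = "node") |>
    dplyr::mutate(mean_strength = .data$total / .data$n_datasets) |>
    dplyr::filter(.data$mean_strength > 0) |>
    dplyr::group_by(.data$node) |>
    dplyr::mutate(
      rank = rank(-.data$mean_strength, ties.method = "average"),
      .r_min = dplyr::min_rank(dplyr::desc(.data$mean_strength)),
      .m = dplyr::n(),
      percentile = 100 * (.data$.m - .data$.r_min) / .data$.m
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$node, .data$rank, .data$gene) |>
    dplyr::select("node", "gene", "mean_strength", "rank", "percentile",
                  "n_datasets")
  if (!is.null(annotations)) {
    cons <- dplyr::left_join(cons, annotations, by = "node")
  }
  structure(cons, class = c("consensome_tbl", class(cons)))
}

validate_peak_table <- function(peaks) {
  need <- c("dataset_id", "node", "gene", "strength")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) {
    abort(paste0("peak table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(peaks) == 0L) abort("peak table is empty")
  if (any(peaks$strength < 0, na.rm = TRUE)) abort("peak strengths must be >= 0")
  if (anyNA(peaks$strength)) abort("peak table: missing strength values")
  dup <- duplicated(peaks[c("dataset_id", "node", "gene")])
  if (any(dup)) abort("peak table: duplicated (dataset_id, node, gene) records")
  multi <- peaks |>
    dplyr::distinct(.data$dataset_id, .data$node) |>
    dplyr::count(.data$dataset_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(multi)) {
    abort(sprintf("dataset(s) mapped to more than one node: %s",
                  paste(multi$dataset_id, collapse = ", ")))
  }
  invisible(peaks)
}

#' Extract high-confidence transcriptional targets (HCTs)
#'
#' Genes in the top `100 - cutoff` percent of a node's consensome are its
#' high-confidence transcriptional targets (default cutoff 95, i.e. the
#' top 5 percent). Membership is the tie-expanded top
#' `ceiling((1 - cutoff/100) * M)` genes of each node, which coincides
#' with the rule `percentile >= cutoff` whenever `(1 - cutoff/100) * M` is
#' an integer and guarantees a non-empty set for any non-empty consensome
#' (small consensomes keep at least their top gene). Tie blocks straddling
#' the boundary are included whole.
#'
#' @param consensomes A `consensome_tbl` from [build_consensomes()].
#' @param cutoff Percentile cutoff in (0, 100), default 95.
#' @return A tibble of class `hct_tbl` with columns `node, gene, rank,
#'   percentile, cutoff`; use [hct_sets()] for a named list of symbol
#'   vectors.
#' @export
extract_hcts <- function(consensomes, cutoff = 95) {
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= 100) {
    abort("cutoff must lie strictly between 0 and 100")
  }
  if (nrow(consensomes) == 0L) {
    warn("empty consensome: returning an empty HCT set")
    out <- tibble(node = character(), gene = character(), rank = numeric(),
                  percentile = numeric(), cutoff = numeric())
    return(structure(out, class = c("hct_tbl", class(out))))
  }
  out <- consensomes |>
    dplyr::group_by(.data$node) |>
    dplyr::mutate(
      .r_min = dplyr::min_rank(dplyr::desc(.data$mean_strength)),
      # M - floor(cutoff*M/100) rather than ceiling((1 - cutoff/100)*M):
      # algebraically identical for non-integer products but immune to the
      # floating-point drift of (1 - cutoff/100)
      .keep_n = dplyr::n() - floor(cutoff * dplyr::n() / 100 + 1e-9)
    ) |>
    dplyr::filter(.data$.r_min <= .data$.keep_n) |>
    dplyr::ungroup() |>
    dplyr::mutate(cutoff = cutoff) |>
    dplyr::select("node", "gene", "rank", "percentile", "cutoff")
  structure(out, class = c("hct_tbl", class(out)))
}

#' Named list of HCT symbol vectors
#'
#' @param hcts An `hct_tbl` from [extract_hcts()].
#' @return A named list, one character vector of gene symbols per node.
#' @export
hct_sets <- function(hcts) {
  split(hcts$gene, hcts$node)
}

#' Read a ranked-target (peak-strength) TSV
#'
#' Reads the tab-separated dialect `dataset_id, node, gene, strength`
#' (header required) used for ChIP-Atlas-style processed target lists. An
#' optional `window_kb` column gives the transcription-start-site window
#' stringency of each row; rows at other stringencies than `window_kb`
#' (default 5 kb) are dropped and the count reported via a message.
#'
#' @param path Path to the TSV.
#' @param window_kb Stringency (kb from TSS) to retain, default 5.
#' @return A validated peak-strength tibble.
#' @export
read_ranked_targets <- function(path, window_kb = 5) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("dataset_id", "node", "gene", "strength")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")))
  }
  strength <- suppressWarnings(as.numeric(raw$strength))
  bad <- which(is.na(strength))
  if (length(bad)) {
    abort(sprintf("%s: unparseable strength value(s) at data line(s) %s",
                  path, paste(head(bad, 5L), collapse = ", ")))
  }
  if (any(strength < 0)) {
    abort(sprintf("%s: negative strength at data line(s) %s", path,
                  paste(head(which(strength < 0), 5L), collapse = ", ")))
  }
  out <- tibble(dataset_id = raw$dataset_id, node = raw$node,
                gene = raw$gene, strength = strength)
  if ("window_kb" %in% names(raw)) {
    wk <- suppressWarnings(as.numeric(raw$window_kb))
    keep <- !is.na(wk) & wk == window_kb
    dropped <- sum(!keep)
    if (dropped > 0L) {
      inform(sprintf("%s: dropped %d row(s) at stringencies other than %g kb",
                     path, dropped, window_kb))
    }
    out <- out[keep, , drop = FALSE]
  }
  validate_peak_table(out)
  out
}

#' Write a consensome table to TSV
#'
#' @param consensomes A `consensome_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consensome <- function(consensomes, path) {
  readr::write_tsv(as_tibble(consensomes), path)
  invisible(path)
}
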