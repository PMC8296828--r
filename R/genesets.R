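#' Construct a gene set
#'
#' A gene set is a named collection of gene symbols tagged with the species
#' whose symbol convention it uses (mouse Title-case, human UPPER-case).
#' Duplicate symbols are removed with a warning; membership comparisons
#' elsewhere in the package are always performed on the case-normalized
#' join key (see [normalize_symbols()]), so sets from different sources
#' join reliably even when capitalisation differs.
#'
#' @param symbols Character vector of gene symbols.
#' @param name Name of the set.
#' @param species Species tag, `"mouse"` or `"human"`.
#' @param allow_empty Permit an empty set (default `FALSE`).
#' @return An object of class `gene_set`: a list with elements `name`,
#'   `species` and `symbols`.
#' @examples
#' gene_set(c("Ifit1", "Rsad2"), name = "markers", species = "mouse")
#' @export
gene_set <- function(symbols, name = "set", species = c("mouse", "human"),
                     allow_empty = FALSE) {
  species <- match.arg(species)
  symbols <- as.character(symbols)
  symbols <- symbols[!is.na(symbols) & nzchar(symbols)]
  dup <- duplicated(normalize_symbols(symbols, species))
  if (any(dup)) {
    warn(sprintf("gene set '%s': %d duplicated symbol(s) removed", name, sum(dup)))
    symbols <- symbols[!dup]
  }
  if (!allow_empty && length(symbols) == 0L) {
    abort(sprintf("gene set '%s' is empty", name))
  }
  structure(list(name = name, species = species, symbols = symbols),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s (%s): %d symbols\n", x$name, x$species,
              length(x$symbols)))
  cat(" ", paste(head(x$symbols, 8L), collapse = ", "),
      if (length(x$symbols) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$symbols)

#' @export
as_tibble.gene_set <- function(x, ...) {
  tibble(set = x$name, species = x$species, symbol = x$symbols)
}

as_gene_set <- function(x, name = "set", species = "mouse") {
  if (inherits(x, "gene_set")) return(x)
  gene_set(x, name = name, species = species, allow_empty = TRUE)
}

#' Normalize gene symbols to a species-independent join key
#'
#' Mouse symbols are conventionally Title-case (`Rsad2`) and human symbols
#' UPPER-case (`RSAD2`); cross-species joins in this package are performed
#' on the upper-cased key, which is idempotent and preserves the display
#' form wherever sets are printed.
#'
#' @param symbols Character vector of symbols.
#' @param species Species tag (recorded for validation only; the key is
#'   the same for both conventions).
#' @return Character vector of join keys, same length as `symbols`.
#' @examples
#' normalize_symbols("Rsad2", "mouse") # "RSAD2"
#' @export
normalize_symbols <- function(symbols, species = c("mouse", "human")) {
  match.arg(species)
  toupper(as.character(symbols))
}

key_of <- function(x) toupper(as.character(x))

#' Derive up- and down-regulated gene sets from a differential-expression table
#'
#' Applies the fold-change / p-value filter used to call the weight-gain
#' "prone" (up: FC > `fc_up`) and "resistant" (down: FC < `fc_down`) gene
#' sets. Inequalities are strict on both fold change and p-value, and the
#' p-value is the unadjusted one. The default down cutoff is 0.75 rather
#' than 1/1.25 = 0.8; both are exposed.
#'
#' @param de A differential-expression table with columns `gene`, `fc`
#'   (linear fold change, prone/resistant) and `p`; a `log2fc` column is
#'   accepted and checked for consistency if present.
#' @param fc_up Upper fold-change threshold (> 1), default 1.25.
#' @param fc_down Lower fold-change threshold (in (0, 1)), default 0.75.
#' @param p_max P-value threshold, default 0.05.
#' @param species Species tag for the returned sets.
#' @return A list with `gene_set` elements `up` and `down` (possibly empty).
#' @examples
#' de <- tibble::tibble(gene = c("A", "B"), fc = c(1.5, 0.5), p = c(0.01, 0.01))
#' derive_de_gene_sets(de)
#' @export
derive_de_gene_sets <- function(de, fc_up = 1.25, fc_down = 0.75,
                                p_max = 0.05, species = "mouse") {
  validate_de_table(de)
  if (!(is.numeric(fc_up) && is.numeric(fc_down) && is.numeric(p_max) &&
        fc_down > 0 && fc_down < 1 && fc_up > 1 && p_max > 0 && p_max <= 1)) {
    abort("thresholds must satisfy 0 < fc_down < 1 < fc_up and 0 < p_max <= 1")
  }
  up <- de$gene[de$fc > fc_up & de$p < p_max]
  down <- de$gene[de$fc < fc_down & de$p < p_max]
  list(
    up = gene_set(up, name = "up", species = species, allow_empty = TRUE),
    down = gene_set(down, name = "down", species = species, allow_empty = TRUE)
  )
}

validate_de_table <- function(de) {
  need <- c("gene", "fc", "p")
  miss <- setdiff(need, names(de))
  if (length(miss)) {
    abort(paste0("DE table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(de$fc <= 0, na.rm = TRUE)) abort("DE table: fc must be > 0")
  if (any(de$p < 0 | de$p > 1, na.rm = TRUE)) abort("DE table: p must lie in [0, 1]")
  if (anyDuplicated(de$gene)) abort("DE table: duplicated gene symbols")
  if ("log2fc" %in% names(de)) {
    bad <- abs(de$log2fc - log2(de$fc)) > 1e-9
    if (any(bad, na.rm = TRUE)) abort("DE table: log2fc inconsistent with fc")
  }
  invisible(de)
}

#' Read gene sets from a GMT file
#'
#' GMT is the tab-separated format `name<TAB>description<TAB>symbol...`,
#' one set per line. Duplicate symbols within a line are dropped with a
#' warning; duplicate set names are an error.
#'
#' @param path Path to the GMT file.
#' @param species Species tag to apply to every set.
#' @return A named list of `gene_set` objects.
#' @export
read_gmt <- function(path, species = "mouse") {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(sprintf("empty gene-set file: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names_)) {
    abort(sprintf("duplicate set name(s) in %s: %s", path,
                  paste(unique(names_[duplicated(names_)]), collapse = ", ")))
  }
  sets <- lapply(fields, function(f) {
    syms <- if (length(f) > 2L) f[-(1:2)] else character()
    gene_set(syms, name = f[[1L]], species = species, allow_empty = TRUE)
  })
  stats::setNames(sets, names_)
}

#' Write gene sets to a GMT file
#'
#' @param sets A `gene_set` or list of `gene_set` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$species, s$symbols), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a one-column TSV of gene symbols as a gene set
#'
#' @param path Path to a headerless or single-header-column TSV.
#' @param name,species Passed to [gene_set()].
#' @param header Does the file carry a header row? Default `FALSE`.
#' @return A `gene_set`.
#' @export
read_gene_set_tsv <- function(path, name = basename(path), species = "mouse",
                              header = FALSE) {
  lines <- readr::read_lines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (header && length(lines)) lines <- lines[-1L]
  if (length(lines) == 0L) abort(sprintf("empty gene-set file: %s", path))
  gene_set(lines, name = name, species = species)
}

#' Read and write differential-expression tables
#'
#' The on-disk dialect is a TSV with columns `gene, fc, log2fc, p`.
#'
#' @param path File path.
#' @return A tibble (`read_de_table`) or `path` invisibly (`write_de_table`).
#' @export
read_de_table <- function(path) {
  de <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  validate_de_table(de)
  as_tibble(de)
}

#' @param de A DE table as produced by [simulate_de_table()] or read in.
#' @rdname read_de_table
#' @export
write_de_table <- function(de, path) {
  validate_de_table(de)
  readr::write_tsv(de, path)
  invisible(path)
}
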