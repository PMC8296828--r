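#' One-sided gene-set overlap (overrepresentation) test
#'
#' Tests whether two gene sets drawn from a common universe of `universe`
#' genes overlap more than expected by chance, using the upper-tail
#' hypergeometric probability P(X >= k). The 2x2 table is
#' `a = k, b = n1 - k, c = n2 - k, d = N - n1 - n2 + k` and the reported
#' odds ratio is the sample cross-product ratio `a*d / (b*c)` (defined as 0
#' when `k = 0` and `Inf`, flagged, when `b*c = 0` with `k > 0`). The
#' conditional maximum-likelihood estimate reported by Fisher-test
#' implementations is available with `or_method = "conditional"`. The test
#' is symmetric in its two sets.
#'
#' @param set1,set2 `gene_set` objects or character vectors of symbols.
#'   Overlap is computed on case-normalized symbols.
#' @param universe Universe size (a count), or a character vector of
#'   symbols defining the universe explicitly (both sets must then be
#'   subsets of it).
#' @param or_method `"cross_product"` (default) or `"conditional"`
#'   (conditional MLE via [stats::fisher.test()]).
#' @return An object of class `overlap_result`; see [tidy.overlap_result()].
#' @examples
#' overlap_test(c("A", "B", "C"), c("B", "C", "D"), universe = 20)
#' @export
overlap_test <- function(set1, set2, universe = 30000,
                         or_method = c("cross_product", "conditional")) {
  or_method <- match.arg(or_method)
  s1 <- unique(key_of(if (inherits(set1, "gene_set")) set1$symbols else set1))
  s2 <- unique(key_of(if (inherits(set2, "gene_set")) set2$symbols else set2))
  if (is.character(universe)) {
    uni <- unique(key_of(universe))
    extra <- setdiff(union(s1, s2), uni)
    if (length(extra)) {
      abort(sprintf("%d set symbol(s) not in the declared universe (e.g. %s)",
                    length(extra), extra[[1L]]))
    }
    N <- length(uni)
  } else {
    N <- as.integer(universe)
  }
  k <- length(intersect(s1, s2))
  overlap_stats(k = k, n1 = length(s1), n2 = length(s2), N = N,
                or_method = or_method,
                genes = intersect(s1, s2))
}

#' Overlap statistics from pre-tabulated margins
#'
#' The counting-free core of [overlap_test()]: takes the overlap count and
#' margins directly. Useful when the sets themselves are unavailable and
#' only published counts are (e.g. checking printed results).
#'
#' @param k Overlap count.
#' @param n1,n2 Set sizes.
#' @param N Universe size.
#' @param or_method See [overlap_test()].
#' @param genes Optional character vector of the overlapping symbols.
#' @return An `overlap_result`.
#' @export
overlap_stats <- function(k, n1, n2, N,
                          or_method = c("cross_product", "conditional"),
                          genes = NULL) {
  or_method <- match.arg(or_method)
  k <- as.integer(k); n1 <- as.integer(n1); n2 <- as.integer(n2); N <- as.integer(N)
  if (n1 > N || n2 > N) abort("universe smaller than a set: need n1, n2 <= N")
  if (k < max(0L, n1 + n2 - N) || k > min(n1, n2)) {
    abort(sprintf("impossible overlap k = %d for margins n1 = %d, n2 = %d, N = %d",
                  k, n1, n2, N))
  }
  a <- k; b <- n1 - k; c_ <- n2 - k; d <- N - n1 - n2 + k
  p <- phyper(k - 1L, n1, N - n1, n2, lower.tail = FALSE)
  flags <- character()
  if (or_method == "conditional") {
    or <- unname(stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2),
                                    alternative = "greater")$estimate)
  } else if (k == 0L) {
    or <- 0
    flags <- c(flags, "zero_overlap")
  } else if (b == 0L || c_ == 0L) {
    or <- Inf
    flags <- c(flags, "infinite_or")
  } else {
    or <- (as.numeric(a) * d) / (as.numeric(b) * c_)
  }
  structure(
    list(k = k, n1 = n1, n2 = n2, N = N, odds_ratio = or, p = p, q = NA_real_,
         or_method = or_method, flags = flags, genes = genes),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> k = %d / n1 = %d, n2 = %d, N = %d\n",
              x$k, x$n1, x$n2, x$N))
  cat(sprintf("  odds ratio (%s) = %.4g, one-sided p = %.4g", x$or_method,
              x$odds_ratio, x$p))
  if (!is.na(x$q)) cat(sprintf(", q = %.4g", x$q))
  cat("\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy an overlap result into a one-row tibble
#'
#' @param x An `overlap_result`.
#' @param ... Unused.
#' @return A one-row tibble with columns `k, n1, n2, N, odds_ratio, p, q,
#'   flags`.
#' @export
tidy.overlap_result <- function(x, ...) {
  tibble(k = x$k, n1 = x$n1, n2 = x$n2, N = x$N,
         odds_ratio = x$odds_ratio, p = x$p, q = x$q,
         flags = paste(x$flags, collapse = ";"))
}

#' @rdname tidy.overlap_result
#' @export
glance.overlap_result <- function(x, ...) {
  tibble(N = x$N, or_method = x$or_method,
         expected_k = x$n1 * x$n2 / x$N, observed_k = x$k)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, delegated to
#' [stats::p.adjust()] with `method = "BH"`; exported so that every batch
#' analysis in the package names one q-value routine.
#'
#' @param p Numeric vector of p-values in `[0, 1]`. `NA` is not accepted.
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' HCT intersection analysis of a query gene set against every node
#'
#' For each pathway node, tests the overlap between `query` and that
#' node's high-confidence transcriptional target (HCT) set with
#' [overlap_test()], then adjusts across all nodes in one
#' Benjamini-Hochberg batch. This is the workhorse that, run against a
#' consensome corpus, identifies transcription-factor nodes whose targets
#' are overrepresented in a differential-expression gene set.
#'
#' @param query A `gene_set` (or character vector) of query genes.
#' @param hcts A named list of HCT gene sets (character vectors or
#'   `gene_set`s), or an HCT tibble from [extract_hcts()].
#' @param universe Universe size; 30,000 (a conservative mouse
#'   transcribed-gene estimate) by default.
#' @param annotations Optional tibble with a `node` column plus e.g.
#'   `category`, `class`, `family`, joined onto the result.
#' @param or_method Odds-ratio estimator, see [overlap_test()].
#' @return A tibble of class `hct_intersection`, one row per node, sorted
#'   by ascending q then p, with columns `node, k, n1, n2, N, odds_ratio,
#'   p, q, sig05, sig01, error` (the `error` column carries a per-node
#'   failure message instead of aborting the batch). Attributes record the
#'   universe and query name.
#' @export
hct_intersection_analysis <- function(query, hcts, universe = 30000,
                                      annotations = NULL,
                                      or_method = "cross_product") {
  qset <- if (inherits(query, "gene_set")) query else
    gene_set(query, name = "query", species = "mouse")
  if (length(qset$symbols) == 0L) abort("query gene set is empty")
  hct_list <- as_hct_list(hcts)
  if (length(hct_list) == 0L) abort("no HCT sets supplied")

  rows <- purrr::imap(hct_list, function(genes, node) {
    res <- tryCatch(
      tidy(overlap_test(qset$symbols, genes, universe = universe,
                        or_method = or_method)),
      error = function(e) NULL
    )
    if (is.null(res)) {
      err <- tryCatch(
        overlap_test(qset$symbols, genes, universe = universe,
                     or_method = or_method),
        error = function(e) conditionMessage(e)
      )
      tibble(node = node, k = NA_integer_, n1 = NA_integer_, n2 = NA_integer_,
             N = as.integer(universe), odds_ratio = NA_real_, p = NA_real_,
             error = as.character(err))
    } else {
      dplyr::mutate(res, node = node, error = NA_character_,
                    .before = 1L)
    }
  })
  out <- dplyr::bind_rows(rows)
  ok <- !is.na(out$p)
  out$q <- NA_real_
  out$q[ok] <- bh_fdr(out$p[ok])
  out <- out |>
    dplyr::mutate(sig05 = .data$q < 0.05, sig01 = .data$q < 0.01) |>
    dplyr::select(!dplyr::any_of("flags")) |>
    dplyr::arrange(.data$q, .data$p, .data$node)
  if (!is.null(annotations)) {
    out <- dplyr::left_join(out, annotations, by = "node")
  }
  structure(out,
            class = c("hct_intersection", class(out)),
            universe = as.integer(universe), query = qset$name)
}

as_hct_list <- function(hcts) {
  if (is.data.frame(hcts)) {
    if (!all(c("node", "gene") %in% names(hcts))) {
      abort("HCT table must have columns node and gene")
    }
    return(split(hcts$gene, hcts$node))
  }
  if (!is.list(hcts) || is.null(names(hcts)) || any(!nzchar(names(hcts)))) {
    abort("hcts must be a named list of gene sets or an HCT table")
  }
  lapply(hcts, function(s) if (inherits(s, "gene_set")) s$symbols else s)
}

#' Phenotype enrichment among significant nodes
#'
#' Tests whether nodes reaching significance in an HCT intersection
#' analysis are overrepresented for nodes whose encoding genes carry a
#' phenotype annotation (e.g. Mammalian Phenotype Ontology "decreased
#' total body fat mass" / "slow postnatal weight gain"). The universe is
#' the set of tested nodes, and phenotype membership is decided on the
#' genes encoding the nodes, joined case-insensitively.
#'
#' @param significant_nodes Character vector of significant node symbols.
#' @param node_universe Character vector of all tested node symbols.
#' @param phenotype_genes A `gene_set` (or character vector) of
#'   phenotype-annotated gene symbols.
#' @param or_method See [overlap_test()].
#' @return An `overlap_result` with `N = length(node_universe)`,
#'   `n1 = length(significant_nodes)` and
#'   `n2 = |node_universe intersect phenotype_genes|`.
#' @export
phenotype_node_enrichment <- function(significant_nodes, node_universe,
                                      phenotype_genes,
                                      or_method = "cross_product") {
  sig <- unique(key_of(significant_nodes))
  uni <- unique(key_of(node_universe))
  if (length(setdiff(sig, uni))) {
    abort("significant_nodes must be a subset of node_universe")
  }
  pheno <- key_of(if (inherits(phenotype_genes, "gene_set"))
    phenotype_genes$symbols else phenotype_genes)
  pheno_in_uni <- intersect(uni, pheno)
  overlap_stats(k = length(intersect(sig, pheno_in_uni)),
                n1 = length(sig), n2 = length(pheno_in_uni),
                N = length(uni), or_method = or_method,
                genes = intersect(sig, pheno_in_uni))
}

#' Double-log plot coordinates for enrichment scatter plots
#'
#' Maps an odds ratio and p-value to `x = log10(OR)`,
#' `y = log10(-log10 p)`; the second log on the y axis compresses the very
#' large p-value range typical of genome-scale intersection analyses.
#' Points with `p >= 0.999` or `OR = 0` cannot be placed on this scale and
#' are returned flagged as unplottable rather than dropped; `p = 0` is
#' clipped to `p_floor` and flagged.
#'
#' @param or Numeric vector of odds ratios (>= 0).
#' @param p Numeric vector of p-values in `(0, 1]` (0 is clipped).
#' @param p_floor Floor applied to `p = 0`, default `1e-300`.
#' @return A tibble with columns `odds_ratio, p, x, y, unplottable, note`.
#' @examples
#' doublelog_coords(3.0, 9.7e-7) # x ~ 0.477, y ~ 0.779
#' @export
doublelog_coords <- function(or, p, p_floor = 1e-300) {
  if (length(or) != length(p)) abort("or and p must have equal length")
  if (any(or < 0, na.rm = TRUE)) abort("odds ratios must be >= 0")
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  note <- character(length(p))
  floored <- !is.na(p) & p == 0
  note[floored] <- "p_floored"
  p_use <- ifelse(floored, p_floor, p)
  unplottable <- is.na(or) | is.na(p_use) | or == 0 | p_use >= 0.999
  note[!is.na(p) & p >= 0.999] <- "p_near_one"
  note[!is.na(or) & or == 0] <- paste0(note[!is.na(or) & or == 0], ";or_zero")
  x <- ifelse(unplottable, NA_real_, log10(or))
  y <- ifelse(unplottable, NA_real_, log10(-log10(p_use)))
  tibble(odds_ratio = or, p = p, x = x, y = y,
         unplottable = unplottable, note = sub("^;", "", note))
}
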