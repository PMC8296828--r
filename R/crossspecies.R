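#' Map a gene set across species through an ortholog table
#'
#' Translates a gene set into the target species using an ortholog map
#' (`src_gene, dst_gene` pairs). Under the default `"any"` policy a
#' target-species gene is included as soon as at least one source gene
#' maps to it, so one-to-many orthology expands the set. Joins are
#' case-insensitive; the count of unmapped source genes is recorded as an
#' attribute and reported via a message.
#'
#' @param set A `gene_set` (or character vector).
#' @param map Ortholog tibble with columns `src_gene, dst_gene` and
#'   optional `src_species, dst_species` tags.
#' @param policy Mapping policy; only `"any"` is currently defined.
#' @param dst_species Species tag of the result (taken from the map when
#'   it carries one).
#' @return A `gene_set` in the target species; `attr(, "unmapped")` holds
#'   the unmapped source symbols.
#' @export
map_orthologs <- function(set, map, policy = "any", dst_species = NULL) {
  policy <- match.arg(policy, "any")
  s <- as_gene_set(set)
  if (!is.null(map$src_species) && !all(map$src_species == s$species)) {
    abort(sprintf("ortholog map source species does not match set species '%s'",
                  s$species))
  }
  dst_species <- dst_species %||% unique(map$dst_species) %||%
    setdiff(c("mouse", "human"), s$species)
  dst_species <- dst_species[[1L]]
  keys <- key_of(s$symbols)
  hit <- key_of(map$src_gene) %in% keys
  mapped <- unique(map$dst_gene[hit])
  unmapped <- s$symbols[!keys %in% key_of(map$src_gene)]
  if (length(unmapped)) {
    inform(sprintf("map_orthologs: %d of %d symbol(s) had no ortholog",
                   length(unmapped), length(s$symbols)))
  }
  out <- gene_set(sort(mapped), name = s$name, species = dst_species,
                  allow_empty = TRUE)
  attr(out, "unmapped") <- unmapped
  out
}

#' Cross-species gene-set overlap
#'
#' Maps `setB` into `setA`'s species through the ortholog map, intersects
#' on case-normalized symbols, and scores the overlap with
#' [overlap_test()]. This is the comparison used to find
#' differential-expression markers shared between a mouse gene set and a
#' human one (e.g. the conserved interferon-responsive weight-gain
#' markers).
#'
#' @param setA A `gene_set` in the analysis species.
#' @param setB A `gene_set` in the other species.
#' @param map Ortholog map with `src_gene` in `setB`'s species. Pass
#'   `NULL` for a pure case-insensitive symbol join.
#' @param universe Universe size for the hypergeometric test. The default
#'   30,000 is a conservative transcribed-gene estimate; set it explicitly
#'   for any publication-grade comparison.
#' @param or_method See [overlap_test()].
#' @return A list with `intersection` (a `gene_set` in `setA`'s species,
#'   display symbols taken from `setA`) and `result` (an
#'   `overlap_result`).
#' @export
cross_species_gene_overlap <- function(setA, setB, map = NULL,
                                       universe = 30000,
                                       or_method = "cross_product") {
  a <- as_gene_set(setA)
  b <- as_gene_set(setB, species = setdiff(c("mouse", "human"), a$species))
  b_mapped <- if (is.null(map)) b else map_orthologs(b, map,
                                                     dst_species = a$species)
  keys_a <- key_of(a$symbols)
  keys_b <- key_of(b_mapped$symbols)
  inter_keys <- intersect(keys_a, keys_b)
  inter <- a$symbols[keys_a %in% inter_keys]
  res <- overlap_stats(k = length(inter_keys), n1 = length(unique(keys_a)),
                       n2 = length(unique(keys_b)), N = universe,
                       or_method = or_method, genes = sort(inter))
  list(
    intersection = gene_set(sort(inter),
                            name = paste0(a$name, "_x_", b$name),
                            species = a$species, allow_empty = TRUE),
    result = res
  )
}

#' Enzyme-class enrichment within a gene set
#'
#' Tests whether genes annotated to particular functional classes (e.g.
#' the E2 ubiquitin-conjugating and E3 ubiquitin ligase enzyme classes)
#' are overrepresented in a gene set, against a hypergeometric universe of
#' annotated genes (default 24,703, the size of a curated
#' signaling-pathway annotation universe).
#'
#' @param genes A `gene_set` (or character vector), e.g. a cross-species
#'   intersection.
#' @param class_annotations Tibble with columns `gene` and `class` (plus
#'   optional `category`, `family`).
#' @param classes_of_interest Character vector of class labels counted as
#'   hits.
#' @param universe Universe size, default 24703.
#' @param n_class_universe Number of genes of the classes of interest in
#'   the whole universe. When `NULL` (default) it is counted from
#'   `class_annotations`, which is then assumed to cover the universe.
#' @param or_method See [overlap_test()].
#' @return An `overlap_result` whose `genes` element lists the in-class
#'   members of `genes`.
#' @export
enzyme_class_enrichment <- function(genes, class_annotations,
                                    classes_of_interest,
                                    universe = 24703,
                                    n_class_universe = NULL,
                                    or_method = "cross_product") {
  g <- as_gene_set(genes)
  miss <- setdiff(c("gene", "class"), names(class_annotations))
  if (length(miss)) {
    abort(paste0("class annotation table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  ann <- class_annotations
  class_genes <- unique(key_of(ann$gene[ann$class %in% classes_of_interest]))
  keys <- unique(key_of(g$symbols))
  hits <- intersect(keys, class_genes)
  n2 <- n_class_universe %||% length(class_genes)
  overlap_stats(k = length(hits), n1 = length(keys), n2 = n2, N = universe,
                or_method = or_method,
                genes = sort(g$symbols[key_of(g$symbols) %in% hits]))
}

#' Cross-species consensome-percentile conservation matrix
#'
#' For a handful of genes of interest, lines up their percentile rankings
#' in every node's consensome in two species and keeps the (gene, node)
#' pairs where the gene is a high-confidence target in at least one
#' species (rule `"any"`, default) or in both (rule `"both"`). Node
#' identities are matched across species case-insensitively (orthologous
#' transcription factors share their symbol up to case); percentiles are
#' taken verbatim from the consensome tables, never recomputed.
#'
#' @param genes Character vector (or `gene_set`) of genes, in the first
#'   species' symbol convention.
#' @param consensomes_a,consensomes_b `consensome_tbl`s for the two
#'   species (a = same species as `genes`, b = the other).
#' @param map Optional ortholog map translating `genes` into species b;
#'   `NULL` means identity-up-to-case.
#' @param cutoff HCT percentile cutoff, default 95.
#' @param rule `"any"` or `"both"`.
#' @return A tibble of class `conservation_matrix`: `gene, node,
#'   percentile_a, percentile_b, hct_a, hct_b`, one row per retained
#'   (gene, node) pair; genes absent from both consensomes are reported in
#'   `attr(, "missing_genes")`.
#' @export
conservation_matrix <- function(genes, consensomes_a, consensomes_b,
                                map = NULL, cutoff = 95,
                                rule = c("any", "both")) {
  rule <- match.arg(rule)
  g <- as_gene_set(genes)
  gene_keys <- key_of(g$symbols)
  b_keys <- gene_keys
  if (!is.null(map)) {
    hit <- key_of(map$src_gene) %in% gene_keys
    b_of_a <- split(key_of(map$dst_gene[hit]), key_of(map$src_gene[hit]))
  } else {
    b_of_a <- stats::setNames(as.list(gene_keys), gene_keys)
  }

  hct_a <- extract_hcts(consensomes_a, cutoff = cutoff)
  hct_b <- extract_hcts(consensomes_b, cutoff = cutoff)
  lookup <- function(cons, hct) {
    dplyr::mutate(as_tibble(cons),
                  node_key = key_of(.data$node),
                  gene_key = key_of(.data$gene),
                  is_hct = paste(.data$node, .data$gene) %in%
                    paste(hct$node, hct$gene)) |>
      dplyr::select("node_key", "gene_key", "percentile", "is_hct")
  }
  la <- lookup(consensomes_a, hct_a)
  lb <- lookup(consensomes_b, hct_b)

  rows <- purrr::map(seq_along(g$symbols), function(i) {
    gk <- gene_keys[[i]]
    bks <- b_of_a[[gk]] %||% character()
    a_rows <- la[la$gene_key == gk, ]
    b_rows <- lb[lb$gene_key %in% bks, ]
    nodes <- union(a_rows$node_key, b_rows$node_key)
    if (length(nodes) == 0L) return(NULL)
    tibble(gene = g$symbols[[i]], node_key = nodes) |>
      dplyr::left_join(a_rows, by = c("node_key" = "node_key")) |>
      dplyr::rename(percentile_a = "percentile", hct_a = "is_hct") |>
      dplyr::select(!dplyr::any_of("gene_key")) |>
      dplyr::left_join(b_rows, by = c("node_key" = "node_key"),
                       relationship = "many-to-many") |>
      dplyr::rename(percentile_b = "percentile", hct_b = "is_hct") |>
      dplyr::select(!dplyr::any_of("gene_key"))
  })
  out <- dplyr::bind_rows(rows)
  missing_genes <- g$symbols[!vapply(seq_along(g$symbols), function(i) {
    gk <- gene_keys[[i]]
    gk %in% la$gene_key || any((b_of_a[[gk]] %||% character()) %in% lb$gene_key)
  }, logical(1))]
  if (nrow(out) == 0L) {
    out <- tibble(gene = character(), node_key = character(),
                  percentile_a = numeric(), hct_a = logical(),
                  percentile_b = numeric(), hct_b = logical())
  }
  out <- out |>
    dplyr::mutate(hct_a = !is.na(.data$hct_a) & .data$hct_a,
                  hct_b = !is.na(.data$hct_b) & .data$hct_b) |>
    dplyr::filter(if (rule == "any") .data$hct_a | .data$hct_b
                  else .data$hct_a & .data$hct_b) |>
    dplyr::rename(node = "node_key") |>
    dplyr::arrange(.data$gene, .data$node)
  structure(out, class = c("conservation_matrix", class(out)),
            cutoff = cutoff, rule = rule, missing_genes = missing_genes)
}

#' Conservation of significant nodes between two intersection analyses
#'
#' Given the nodes significant in species B's HCT intersection analysis,
#' maps them into species A, keeps those that were tested in species A
#' (untested orthologs are excluded and counted), and asks whether they
#' are overrepresented among species A's significant nodes. Margins:
#' `n1` = mapped-and-tested species-B hits, `n2` = species-A significant
#' nodes, `N` = species-A tested nodes.
#'
#' @param sig_nodes_b Nodes significant in species B.
#' @param tested_nodes_a All nodes tested in species A.
#' @param sig_nodes_a Nodes significant in species A (subset of
#'   `tested_nodes_a`).
#' @param map Optional node ortholog map (`src_gene` = species-B node
#'   symbols); `NULL` means identity-up-to-case.
#' @param or_method See [overlap_test()].
#' @return An `overlap_result`; `attr(, "untested")` lists species-B nodes
#'   whose orthologs were not tested in species A.
#' @export
conserved_node_overlap <- function(sig_nodes_b, tested_nodes_a, sig_nodes_a,
                                   map = NULL, or_method = "cross_product") {
  tested <- unique(key_of(tested_nodes_a))
  sig_a <- unique(key_of(sig_nodes_a))
  if (length(setdiff(sig_a, tested))) {
    abort("sig_nodes_a must be a subset of tested_nodes_a")
  }
  b_keys <- unique(key_of(sig_nodes_b))
  if (!is.null(map)) {
    hit <- key_of(map$src_gene) %in% b_keys
    mapped <- unique(key_of(map$dst_gene[hit]))
  } else {
    mapped <- b_keys
  }
  in_a <- intersect(mapped, tested)
  untested <- setdiff(mapped, tested)
  if (length(untested)) {
    inform(sprintf("conserved_node_overlap: %d mapped node(s) not tested in species A",
                   length(untested)))
  }
  res <- overlap_stats(k = length(intersect(in_a, sig_a)),
                       n1 = length(in_a), n2 = length(sig_a),
                       N = length(tested), or_method = or_method,
                       genes = sort(intersect(in_a, sig_a)))
  attr(res, "untested") <- untested
  res
}
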