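id_map <- function(src) {
  tibble::tibble(src_gene = src, dst_gene = toupper(src),
                 src_species = "mouse", dst_species = "human")
}

test_that("ortholog mapping translates symbol case and counts unmapped genes", {
  set <- gene_set(c("Rsad2", "Ifit1"), species = "mouse")
  out <- map_orthologs(set, id_map(c("Rsad2", "Ifit1", "Gata1")))
  expect_setequal(out$symbols, c("RSAD2", "IFIT1"))
  expect_equal(out$species, "human")

  expect_message(
    empty <- map_orthologs(set, id_map(character()), dst_species = "human"),
    "2 of 2")
  expect_length(empty$symbols, 0)
  expect_length(attr(empty, "unmapped"), 2)

  one_two <- dplyr::bind_rows(id_map("Rsad2"),
                              tibble::tibble(src_gene = "Rsad2",
                                             dst_gene = "RSAD2B",
                                             src_species = "mouse",
                                             dst_species = "human"))
  both <- map_orthologs(gene_set("Rsad2", species = "mouse"), one_two)
  expect_setequal(both$symbols, c("RSAD2", "RSAD2B"))

  human_set <- gene_set("RSAD2", species = "human")
  expect_error(map_orthologs(human_set, id_map("Rsad2")), "species")
})

test_that("ortholog mapping is monotone in its input set", {
  set.seed(7)
  genes <- paste0("Gene", 1:50)
  map <- id_map(sample(genes, 35))
  small <- gene_set(sample(genes, 10), species = "mouse")
  big <- gene_set(union(small$symbols, sample(genes, 20)), species = "mouse")
  suppressMessages({
    m_small <- map_orthologs(small, map)
    m_big <- map_orthologs(big, map)
  })
  expect_true(all(m_small$symbols %in% m_big$symbols))
})

test_that("cross-species overlap recovers the published conserved marker genes", {
  # the four-gene mouse/human weight-gain marker table, embedded in
  # synthetic surrounding sets
  markers <- readr::read_tsv(
    system.file("extdata", "cross_species_markers.tsv", package = "consensnet"),
    show_col_types = FALSE)
  mouse_set <- gene_set(c(markers$mouse_symbol, paste0("Mfill", 1:30)),
                        name = "aiwg_prone_mouse", species = "mouse")
  human_set <- gene_set(c(markers$human_symbol, paste0("HFILL", 31:60)),
                        name = "aiwg_prone_human", species = "human")
  map <- tibble::tibble(
    src_gene = human_set$symbols,
    dst_gene = c(markers$mouse_symbol,
                 paste0("Hfill", 31:60)),
    src_species = "human", dst_species = "mouse")
  res <- cross_species_gene_overlap(mouse_set, human_set, map,
                                    universe = 30000)
  expect_setequal(res$intersection$symbols,
                  c("Rhd", "Ifit1", "Ifitm3", "Rsad2"))
  expect_equal(res$result$k, 4L)
  expect_true(all(markers$fc_mouse >= 1.25) && all(markers$fc_human >= 1.25))
})

test_that("cross-species overlap handles disjoint and identical sets", {
  a <- gene_set(paste0("Aa", 1:10), species = "mouse")
  b <- gene_set(paste0("BB", 1:10), species = "human")
  rev_map <- tibble::tibble(src_gene = paste0("CC", 1:5),
                            dst_gene = paste0("Cc", 1:5),
                            src_species = "human", dst_species = "mouse")
  suppressMessages(
    dis <- cross_species_gene_overlap(a, b, rev_map, universe = 100))
  expect_equal(dis$result$k, 0L)
  expect_equal(dis$result$p, 1)

  bb <- gene_set(toupper(a$symbols), species = "human")
  same <- cross_species_gene_overlap(
    a, bb, tibble::tibble(src_gene = bb$symbols, dst_gene = a$symbols,
                          src_species = "human", dst_species = "mouse"),
    universe = 100)
  expect_equal(same$result$k, 10L)
  # maximal overlap attains the minimal p for these margins
  expect_equal(same$result$p, overlap_stats(10, 10, 10, 100)$p)
})

test_that("enzyme-class counting on the published intersection table", {
  ann <- readr::read_tsv(
    system.file("extdata", "aiwgp_hwgbmi_intersection_annotations.tsv",
                package = "consensnet"),
    show_col_types = FALSE)
  expect_equal(nrow(ann), 40L)
  res <- enzyme_class_enrichment(
    ann$gene, ann,
    classes_of_interest = c("E2 ubiquitin conjugating enzymes",
                            "E3 ubiquitin ligases"),
    universe = 24703, n_class_universe = 382)
  expect_equal(res$n1, 40L)
  expect_equal(res$k, 6L)
  expect_setequal(res$genes,
                  c("Ube2f", "Ube2h", "Mkrn1", "Marchf8", "Trim10", "Trim58"))

  none <- enzyme_class_enrichment(ann$gene, ann, classes_of_interest = character(),
                                  n_class_universe = 0)
  expect_equal(none$k, 0L)
  expect_equal(none$p, 1)
  all_in <- enzyme_class_enrichment(c("Ube2f", "Ube2h"), ann,
                                    classes_of_interest = "E2 ubiquitin conjugating enzymes",
                                    n_class_universe = 10)
  expect_equal(all_in$k, all_in$n1)
})

test_that("conservation matrix honours the HCT inclusion rule", {
  cons_tbl <- function(genes, strengths, node = "Stat1") {
    build_consensomes(tibble::tibble(dataset_id = "d1", node = node,
                                     gene = genes, strength = strengths))
  }
  # 40 genes; GeneA top-ranked (HCT), GeneB mid-pack
  genes_a <- c("Genea", "Geneb", sprintf("Flt%02d", 1:38))
  mouse <- cons_tbl(genes_a, c(100, 50, 98 - (1:38)))
  human <- cons_tbl(toupper(genes_a), c(60, 99, 98 - (1:38)), node = "STAT1")

  m_any <- conservation_matrix(c("Genea", "Geneb", "Genec"), mouse, human)
  expect_setequal(m_any$gene, c("Genea", "Geneb"))
  row_a <- m_any[m_any$gene == "Genea", ]
  expect_true(row_a$hct_a)  # mouse top gene
  expect_false(row_a$hct_b) # human mid-pack
  expect_equal(attr(m_any, "missing_genes"), "Genec")
  # percentiles come straight from the consensome tables
  expect_equal(row_a$percentile_a,
               mouse$percentile[mouse$gene == "Genea"])

  m_both <- conservation_matrix(c("Genea", "Geneb"), mouse, human,
                                rule = "both")
  expect_equal(nrow(m_both), 0L)

  # identical corpora in both species: every retained cell is HCT twice
  human_same <- cons_tbl(toupper(genes_a), c(100, 50, 98 - (1:38)),
                         node = "STAT1")
  m_id <- conservation_matrix("Genea", mouse, human_same, rule = "both")
  expect_true(all(m_id$hct_a) && all(m_id$hct_b))
})

test_that("conserved-node overlap counts mapped, tested and significant nodes", {
  tested_a <- paste0("Node", 1:20)
  sig_a <- paste0("Node", 1:6)
  sig_b <- toupper(paste0("Node", c(1:5, 7, 9)))
  res <- conserved_node_overlap(sig_b, tested_a, sig_a)
  expect_equal(res$n1, 7L)
  expect_equal(res$k, 5L)
  expect_equal(res$N, 20L)

  suppressMessages(
    res2 <- conserved_node_overlap(c(sig_b, "NOPE"), tested_a, sig_a))
  expect_equal(res2$n1, 7L)
  expect_equal(attr(res2, "untested"), "NOPE")

  none <- conserved_node_overlap(toupper(paste0("Node", 10:12)), tested_a, sig_a)
  expect_equal(none$k, 0L)
  expect_equal(none$p, 1)
})

test_that("shared planted drivers reach significance in both species' analyses", {
  hits <- vapply(1:40, function(i) {
    cfg <- sim_config(n_genes = 600, n_nodes = 10, n_driver_nodes = 1,
                      targets_per_node = 40, driver_enrichment = 0.8,
                      de_effect_lfc = 1, noise_sd = 0.5,
                      n_prone_genes = 40, n_resistant_genes = 20,
                      background_rate = 0.4, seed = 5000 + i)
    run_one <- function(species) {
      corpus <- simulate_corpus(cfg, species = species)
      de <- simulate_de_table(cfg, corpus$truth)
      sets <- derive_de_gene_sets(de, species = species)
      hct <- extract_hcts(build_consensomes(corpus$peaks))
      it <- hct_intersection_analysis(sets$up, hct, universe = cfg$n_genes)
      list(sig = it$node[!is.na(it$q) & it$q < 0.05],
           driver = corpus$truth$driver_nodes)
    }
    m <- run_one("mouse")
    h <- run_one("human")
    (m$driver %in% m$sig) && (toupper(m$driver) %in% h$sig)
  }, logical(1))
  expect_gte(sum(hits), 36) # >= 90% of seeds
})
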