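test_that("generators are deterministic in config + seed and vary with seed", {
  cfg1 <- sim_fixture_cfg(seed = 1)
  a <- simulate_corpus(cfg1)
  b <- simulate_corpus(cfg1)
  expect_identical(a, b)
  c2 <- simulate_corpus(sim_fixture_cfg(seed = 2))
  expect_false(identical(a$peaks, c2$peaks))

  expect_identical(simulate_de_table(cfg1, a$truth),
                   simulate_de_table(cfg1, a$truth))
  expect_identical(simulate_cohort(cfg1), simulate_cohort(cfg1))
  expect_identical(simulate_aux_maps(cfg1, a$truth),
                   simulate_aux_maps(cfg1, a$truth))
})

test_that("per-node top-k mean strengths recover planted targets at low noise", {
  cfg <- sim_config(n_genes = 100, n_nodes = 3, targets_per_node = 10,
                    noise_sd = 0.1, n_prone_genes = 10, n_resistant_genes = 5,
                    n_driver_nodes = 1, seed = 7)
  corpus <- simulate_corpus(cfg)
  cons <- build_consensomes(corpus$peaks)
  for (nd in corpus$truth$node_universe) {
    cn <- cons[cons$node == nd, ]
    topk <- cn$gene[order(cn$rank)][1:10]
    expect_gte(length(intersect(topk, corpus$truth$true_targets[[nd]])), 9)
  }
})

test_that("planted truth is structurally consistent", {
  cfg <- sim_fixture_cfg(seed = 4)
  corpus <- simulate_corpus(cfg)
  tr <- corpus$truth
  expect_true(all(tr$driver_nodes %in% tr$node_universe))
  expect_setequal(names(tr$true_targets), tr$node_universe)
  expect_length(intersect(tr$prone_genes, tr$resistant_genes), 0)
  expect_length(tr$prone_genes, cfg$n_prone_genes)
  expect_length(tr$resistant_genes, cfg$n_resistant_genes)
  # driver enrichment: the configured fraction of prone genes lies in the
  # driver target pool
  pool <- unique(unlist(tr$true_targets[tr$driver_nodes]))
  expect_equal(sum(tr$prone_genes %in% pool) >=
                 round(cfg$driver_enrichment * cfg$n_prone_genes), TRUE)
  ds_nodes <- dplyr::distinct(corpus$peaks, dataset_id, node) |>
    dplyr::count(node)
  expect_true(all(ds_nodes$n >= cfg$datasets_per_node[1] &
                    ds_nodes$n <= cfg$datasets_per_node[2]))
})

test_that("human-species corpora use upper-case symbol conventions", {
  cfg <- sim_fixture_cfg(seed = 6)
  hs <- simulate_corpus(cfg, species = "human")
  expect_true(all(hs$peaks$gene == toupper(hs$peaks$gene)))
  expect_true(all(hs$truth$node_universe == toupper(hs$truth$node_universe)))
  ms <- simulate_corpus(cfg, species = "mouse")
  expect_setequal(toupper(ms$truth$prone_genes), hs$truth$prone_genes)
})

test_that("a fully planted small universe gives a complete DE table", {
  cfg <- sim_config(n_genes = 10, n_nodes = 1, n_driver_nodes = 1,
                    targets_per_node = 2, n_prone_genes = 6,
                    n_resistant_genes = 4, driver_enrichment = 0, seed = 5)
  corpus <- simulate_corpus(cfg)
  de <- simulate_de_table(cfg, corpus$truth)
  expect_equal(nrow(de), 10L)
  expect_setequal(de$gene, corpus$truth$gene_universe)
  expect_true(all(de$fc > 0))
  expect_equal(de$log2fc, log2(de$fc))
  expect_error(simulate_de_table(sim_fixture_cfg(seed = 5), corpus$truth),
               "universe")
})

test_that("ortholog map generation honours drop and duplication fractions", {
  cfg <- sim_fixture_cfg(seed = 10)
  corpus <- simulate_corpus(cfg)
  aux0 <- simulate_aux_maps(cfg, corpus$truth, drop_fraction = 0)
  expect_equal(nrow(aux0$ortholog_map), cfg$n_genes)
  expect_equal(key_back <- tolower(aux0$ortholog_map$dst_gene),
               tolower(aux0$ortholog_map$src_gene))

  aux2 <- simulate_aux_maps(cfg, corpus$truth, drop_fraction = 0.2)
  expect_equal(nrow(aux2$ortholog_map), round(0.8 * cfg$n_genes))

  auxm <- simulate_aux_maps(cfg, corpus$truth, many_to_many_fraction = 0.1)
  expect_equal(nrow(auxm$ortholog_map), cfg$n_genes + round(0.1 * cfg$n_genes))

  aux1 <- simulate_aux_maps(cfg, corpus$truth, phenotype_rate = 1,
                            phenotype_extra = 0)
  expect_true(all(corpus$truth$driver_nodes %in% aux1$phenotype_set$symbols))
})

test_that("cohort trajectories have the right shape and planted recovery", {
  cfg <- sim_fixture_cfg(seed = 11)
  cohort <- simulate_cohort(cfg)
  expect_equal(nrow(cohort), 40 * 15)
  expect_equal(sum(!is.na(cohort$intake)), 40 * 14)
  expect_true(all(cohort$body_weight > 0))

  # noiseless limit: top-5/bottom-5 assignment is exact
  cfg0 <- sim_fixture_cfg(gain_sd = 0, seed = 11)
  cohort0 <- simulate_cohort(cfg0)
  planted <- attr(cohort0, "planted")
  ass <- assign_cohorts(cohort0, k = 5)
  expect_setequal(prone_ids(ass),
                  planted$animal_id[planted$planted_group == "prone"])
  expect_setequal(resistant_ids(ass),
                  planted$animal_id[planted$planted_group == "resistant"])
})

test_that("Monte-Carlo cohort recovery succeeds in at least 95% of seeds", {
  hits <- vapply(1:100, function(i) {
    cfg <- sim_fixture_cfg(gain_sd = 0.3, seed = 2000 + i)
    cohort <- simulate_cohort(cfg)
    planted <- attr(cohort, "planted")
    ass <- assign_cohorts(cohort, k = 5)
    setequal(prone_ids(ass),
             planted$animal_id[planted$planted_group == "prone"]) &&
      setequal(resistant_ids(ass),
               planted$animal_id[planted$planted_group == "resistant"])
  }, logical(1))
  expect_gte(sum(hits), 95)
})

test_that("qPCR generator plants the requested expression differences", {
  cfg <- sim_fixture_cfg(seed = 13)
  q <- simulate_qpcr(cfg, genes = c("Agrp", "Pomc"),
                     effects = c(Agrp = 2, Pomc = -1), ct_sd = 1e-9)
  dd <- ddct_relative_expression(q, reference_group = "resistant")
  g <- dd$groups
  expect_equal(g$mean_rq[g$gene == "Agrp" & g$group == "prone"], 4,
               tolerance = 1e-6)
  expect_equal(g$mean_rq[g$gene == "Pomc" & g$group == "prone"], 0.5,
               tolerance = 1e-6)
  expect_equal(g$mean_rq[g$group == "resistant"], c(1, 1), tolerance = 1e-6)
})

test_that("invalid configurations name the offending field", {
  expect_error(sim_config(n_genes = 0), "'n_genes'")
  expect_error(sim_config(driver_enrichment = 1.2), "'driver_enrichment'")
  expect_error(sim_config(noise_sd = -1), "'noise_sd'")
  expect_error(sim_config(datasets_per_node = c(5, 2)), "'datasets_per_node'")
  expect_error(sim_config(n_driver_nodes = 99, n_nodes = 3), "'n_driver_nodes'")
  expect_error(
    simulate_corpus(sim_config(n_genes = 50, targets_per_node = 10,
                               n_nodes = 3, n_driver_nodes = 1,
                               n_prone_genes = 40, n_resistant_genes = 5,
                               driver_enrichment = 1)),
    "driver target pool")
})
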