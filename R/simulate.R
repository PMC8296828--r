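#' Simulation configuration for the synthetic regulatory corpus
#'
#' Bundles every knob of the synthetic-data generators and validates it
#' once. The defaults describe a desk-scale study with the same design as
#' the olanzapine weight-gain experiment the package models: 40 animals
#' followed for 14 days with top-5/bottom-5 cohorting (mean gains 6.3 g
#' prone vs 1.3 g resistant), a mouse gene universe, a corpus of
#' transcription-factor nodes each backed by several ChIP-Seq-like
#' datasets, and planted driver nodes whose high-confidence targets are
#' enriched in the prone differential-expression gene set.
#'
#' Identical configuration plus seed yields identical outputs; each
#' generator draws from its own seed offset so adding one generator call
#' never perturbs another's stream.
#'
#' @param n_genes Size of the gene universe.
#' @param n_nodes Number of pathway nodes (ChIP-Seq IP antigens).
#' @param datasets_per_node Length-2 integer range (min, max) of datasets
#'   per node.
#' @param n_driver_nodes Number of planted driver nodes.
#' @param targets_per_node True transcriptional targets per node.
#' @param driver_enrichment Fraction of planted prone genes drawn from the
#'   driver nodes' true targets (0-1).
#' @param de_effect_lfc Mean log2 fold change of planted DE genes (0 gives
#'   a null-mode table with no signal anywhere).
#' @param noise_sd Standard deviation of peak-strength (log scale) and
#'   expression noise; 0 is the exact noiseless limit (background peak
#'   records vanish and planted effects are recovered exactly).
#' @param n_prone_genes,n_resistant_genes Planted DE gene-set sizes.
#' @param background_rate Per-dataset probability that a non-target gene
#'   receives a background peak record.
#' @param target_strength Median peak strength of true-target records.
#' @param n_prone,n_resistant Cohort sizes (top/bottom weight gainers).
#' @param n_animals Animals in the cohort.
#' @param days Days of treatment (weights recorded on days `0..days`).
#' @param prone_gain,resistant_gain Mean total weight gain (g) of planted
#'   prone / resistant animals; intermediate animals sit at the midpoint.
#' @param gain_sd Standard deviation of total weight gain (g).
#' @param seed Integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_nodes = 20,
                       datasets_per_node = c(2, 5), n_driver_nodes = 2,
                       targets_per_node = 50, driver_enrichment = 0.5,
                       de_effect_lfc = 1, noise_sd = 0.5,
                       n_prone_genes = 100, n_resistant_genes = 50,
                       background_rate = 0.5, target_strength = 10,
                       n_prone = 5, n_resistant = 5, n_animals = 40,
                       days = 14, prone_gain = 6.3, resistant_gain = 1.3,
                       gain_sd = 0.3, seed = 1) {
  cfg <- list(n_genes = n_genes, n_nodes = n_nodes,
              datasets_per_node = datasets_per_node,
              n_driver_nodes = n_driver_nodes,
              targets_per_node = targets_per_node,
              driver_enrichment = driver_enrichment,
              de_effect_lfc = de_effect_lfc, noise_sd = noise_sd,
              n_prone_genes = n_prone_genes,
              n_resistant_genes = n_resistant_genes,
              background_rate = background_rate,
              target_strength = target_strength,
              n_prone = n_prone, n_resistant = n_resistant,
              n_animals = n_animals, days = days, prone_gain = prone_gain,
              resistant_gain = resistant_gain, gain_sd = gain_sd,
              seed = seed)
  for (f in c("n_genes", "n_nodes", "n_driver_nodes", "targets_per_node",
              "n_prone_genes", "n_resistant_genes", "n_prone", "n_resistant",
              "n_animals", "days")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v)) {
      abort(sprintf("sim_config: '%s' must be an integer count >= 1", f))
    }
  }
  if (!(length(datasets_per_node) == 2L && all(datasets_per_node >= 1) &&
        datasets_per_node[1] <= datasets_per_node[2])) {
    abort("sim_config: 'datasets_per_node' must be an increasing (min, max) pair >= 1")
  }
  if (!is.numeric(driver_enrichment) || driver_enrichment < 0 ||
      driver_enrichment > 1) {
    abort("sim_config: 'driver_enrichment' must lie in [0, 1]")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    abort("sim_config: 'noise_sd' must be >= 0")
  }
  if (!is.numeric(background_rate) || background_rate < 0 || background_rate > 1) {
    abort("sim_config: 'background_rate' must lie in [0, 1]")
  }
  if (n_driver_nodes > n_nodes) {
    abort("sim_config: 'n_driver_nodes' cannot exceed 'n_nodes'")
  }
  if (targets_per_node > n_genes) {
    abort("sim_config: 'targets_per_node' cannot exceed 'n_genes'")
  }
  if (n_prone + n_resistant > n_animals) {
    abort("sim_config: 'n_prone' + 'n_resistant' cannot exceed 'n_animals'")
  }
  if (n_prone_genes + n_resistant_genes > n_genes) {
    abort("sim_config: planted gene sets cannot exceed 'n_genes'")
  }
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed)) {
    abort("sim_config: 'seed' must be a single integer")
  }
  structure(cfg, class = "sim_config")
}

sim_genes <- function(cfg) sprintf("Simg%04d", seq_len(cfg$n_genes))
sim_nodes <- function(cfg) sprintf("Tfx%03d", seq_len(cfg$n_nodes))

# Seed offsets per generator; one stream per call so generators are
# independent of call order.
SEED_OFFSETS <- c(corpus = 0L, de = 11L, aux = 23L, cohort = 37L, qpcr = 53L)

sim_seed <- function(cfg, which) as.integer(cfg$seed) + SEED_OFFSETS[[which]]

#' Generate a synthetic ChIP-Seq peak-strength corpus with planted truth
#'
#' Emulates a corpus of processed ChIP-Seq target lists: each node gets a
#' random number of datasets, its true targets receive log-normal peak
#' strengths (median `target_strength`, log-sd `noise_sd`) in every
#' dataset, and non-target genes receive sparse exponential background
#' records (mean `noise_sd`, per-dataset inclusion probability
#' `background_rate`). At `noise_sd = 0` background records vanish and the
#' per-node mean-strength ranking recovers the planted targets exactly.
#' The returned truth also fixes the planted prone/resistant DE gene sets,
#' with a `driver_enrichment` fraction of prone genes drawn from the
#' driver nodes' true targets.
#'
#' @param cfg A [sim_config()].
#' @param species `"mouse"` (Title-case symbols) or `"human"`
#'   (UPPER-case).
#' @return A list with elements `peaks` (peak-strength tibble:
#'   `dataset_id, node, gene, strength`) and `truth` (class `sim_truth`:
#'   `driver_nodes`, `true_targets` named list over all nodes,
#'   `prone_genes`, `resistant_genes`, `gene_universe`, `node_universe`,
#'   `species`).
#' @export
simulate_corpus <- function(cfg, species = c("mouse", "human")) {
  species <- match.arg(species)
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(sim_seed(cfg, "corpus"), {
    plan <- sim_corpus_plan(cfg)
    peaks <- sim_corpus_peaks(cfg, plan)
  })
  truth <- structure(
    list(driver_nodes = plan$driver_nodes, true_targets = plan$true_targets,
         prone_genes = plan$prone_genes, resistant_genes = plan$resistant_genes,
         gene_universe = plan$genes, node_universe = plan$nodes,
         species = species),
    class = "sim_truth")
  if (species == "human") {
    truth$driver_nodes <- toupper(truth$driver_nodes)
    truth$true_targets <- lapply(truth$true_targets, toupper)
    names(truth$true_targets) <- toupper(names(truth$true_targets))
    truth$prone_genes <- toupper(truth$prone_genes)
    truth$resistant_genes <- toupper(truth$resistant_genes)
    truth$gene_universe <- toupper(truth$gene_universe)
    truth$node_universe <- toupper(truth$node_universe)
    peaks$node <- toupper(peaks$node)
    peaks$gene <- toupper(peaks$gene)
  }
  list(peaks = peaks, truth = truth)
}

# Planted structure: drivers, per-node targets, prone/resistant DE sets.
sim_corpus_plan <- function(cfg) {
  genes <- sim_genes(cfg)
  nodes <- sim_nodes(cfg)
  driver_nodes <- sort(sample(nodes, cfg$n_driver_nodes))
  true_targets <- lapply(stats::setNames(nodes, nodes), function(nd) {
    sort(sample(genes, cfg$targets_per_node))
  })
  pool <- sort(unique(unlist(true_targets[driver_nodes], use.names = FALSE)))
  n_drv <- round(cfg$driver_enrichment * cfg$n_prone_genes)
  if (n_drv > length(pool)) {
    abort(sprintf(paste0("sim_config: driver_enrichment * n_prone_genes = %d ",
                         "exceeds the driver target pool (%d genes)"),
                  n_drv, length(pool)))
  }
  prone_from_pool <- sample(pool, n_drv)
  rest_pool <- setdiff(genes, pool)
  prone <- c(prone_from_pool,
             sample(rest_pool, cfg$n_prone_genes - n_drv))
  resistant <- sample(setdiff(genes, prone), cfg$n_resistant_genes)
  list(genes = genes, nodes = nodes, driver_nodes = driver_nodes,
       true_targets = true_targets, prone_genes = sort(prone),
       resistant_genes = sort(resistant))
}

sim_corpus_peaks <- function(cfg, plan) {
  rng <- cfg$datasets_per_node
  rows <- purrr::map(plan$nodes, function(nd) {
    n_ds <- if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1L)
    targets <- plan$true_targets[[nd]]
    non_targets <- setdiff(plan$genes, targets)
    purrr::map(seq_len(n_ds), function(j) {
      ds <- sprintf("%s_ds%02d", nd, j)
      tgt <- tibble(dataset_id = ds, node = nd, gene = targets,
                    strength = rlnorm(length(targets),
                                      meanlog = log(cfg$target_strength),
                                      sdlog = cfg$noise_sd))
      if (cfg$noise_sd > 0 && cfg$background_rate > 0 && length(non_targets)) {
        bg <- non_targets[runif(length(non_targets)) < cfg$background_rate]
        if (length(bg)) {
          tgt <- dplyr::bind_rows(tgt, tibble(
            dataset_id = ds, node = nd, gene = bg,
            strength = rexp(length(bg), rate = 1 / cfg$noise_sd)))
        }
      }
      tgt
    })
  })
  dplyr::bind_rows(rows)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %s: %d genes, %d nodes (%d drivers), planted DE %d up / %d down\n",
              x$species, length(x$gene_universe), length(x$node_universe),
              length(x$driver_nodes), length(x$prone_genes),
              length(x$resistant_genes)))
  invisible(x)
}

#' Generate a synthetic differential-expression table
#'
#' Planted prone genes draw log2 fold changes from
#' `Normal(de_effect_lfc, noise_sd)`, resistant genes from the mirrored
#' distribution, and all other genes from `Normal(0, noise_sd)`. The
#' p-value of a gene is the two-sided normal tail of its observed log2
#' fold change at scale `noise_sd`, so null genes carry Uniform(0, 1)
#' p-values and planted genes small ones. With `de_effect_lfc = 0` the
#' table is an exact null; with `noise_sd = 0` planted genes get their
#' mean effect exactly with vanishing p and null genes get fc = 1, p = 1.
#'
#' @param cfg A [sim_config()].
#' @param truth A `sim_truth` from [simulate_corpus()] over the same gene
#'   universe.
#' @return A DE tibble with columns `gene, fc, log2fc, p`.
#' @export
simulate_de_table <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  genes <- truth$gene_universe
  if (length(genes) != cfg$n_genes) {
    abort("simulate_de_table: truth and config disagree on the gene universe")
  }
  mu <- numeric(length(genes))
  mu[genes %in% truth$prone_genes] <- cfg$de_effect_lfc
  mu[genes %in% truth$resistant_genes] <- -cfg$de_effect_lfc
  withr::with_seed(sim_seed(cfg, "de"), {
    if (cfg$noise_sd > 0) {
      lfc <- rnorm(length(genes), mean = mu, sd = cfg$noise_sd)
      p <- 2 * pnorm(-abs(lfc) / cfg$noise_sd)
    } else {
      lfc <- mu
      p <- ifelse(abs(mu) > 0, 1e-300, 1)
    }
  })
  tibble(gene = genes, fc = 2^lfc, log2fc = lfc, p = pmax(p, 1e-300))
}

#' Generate auxiliary maps and gene sets for cross-species analyses
#'
#' Produces (i) an ortholog map that is identity-up-to-case (mouse
#' Title-case to human UPPER-case) with a configurable fraction of dropped
#' and of duplicated (one-to-many) entries, (ii) a phenotype gene set over
#' the node-encoding symbols that covers driver nodes at a configurable
#' rate, and (iii) a human weight-gain/BMI-like gene set overlapping the
#' planted prone genes.
#'
#' @param cfg A [sim_config()].
#' @param truth A mouse `sim_truth`.
#' @param drop_fraction Fraction of genes absent from the ortholog map.
#' @param many_to_many_fraction Fraction of mapped genes that also map to
#'   a second synthetic human symbol.
#' @param phenotype_rate Fraction of driver nodes covered by the
#'   phenotype set.
#' @param phenotype_extra Non-driver nodes additionally included.
#' @param hwgbmi_size Size of the human weight-gain/BMI-like set.
#' @param hwgbmi_overlap Fraction of it drawn from (orthologs of) planted
#'   prone genes.
#' @return A list with `ortholog_map` (tibble `src_gene, dst_gene,
#'   src_species, dst_species`), `phenotype_set` and `hwgbmi_set`
#'   (`gene_set`s).
#' @export
simulate_aux_maps <- function(cfg, truth, drop_fraction = 0,
                              many_to_many_fraction = 0,
                              phenotype_rate = 0.8, phenotype_extra = 2,
                              hwgbmi_size = 50, hwgbmi_overlap = 0.8) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  genes <- truth$gene_universe
  withr::with_seed(sim_seed(cfg, "aux"), {
    keep <- genes
    n_drop <- round(drop_fraction * length(genes))
    if (n_drop > 0) keep <- setdiff(keep, sample(genes, n_drop))
    map <- tibble(src_gene = keep, dst_gene = toupper(keep),
                  src_species = "mouse", dst_species = "human")
    n_multi <- round(many_to_many_fraction * length(keep))
    if (n_multi > 0) {
      dup <- sample(keep, n_multi)
      map <- dplyr::bind_rows(map, tibble(
        src_gene = dup, dst_gene = paste0(toupper(dup), "B"),
        src_species = "mouse", dst_species = "human"))
    }
    drivers <- truth$driver_nodes
    n_cov <- round(phenotype_rate * length(drivers))
    pheno <- sample(drivers, n_cov)
    others <- setdiff(truth$node_universe, drivers)
    if (phenotype_extra > 0 && length(others)) {
      pheno <- c(pheno, sample(others, min(phenotype_extra, length(others))))
    }
    n_hit <- min(round(hwgbmi_overlap * hwgbmi_size), length(truth$prone_genes))
    hwg <- c(sample(truth$prone_genes, n_hit),
             sample(setdiff(genes, truth$prone_genes), hwgbmi_size - n_hit))
  })
  list(
    ortholog_map = map,
    phenotype_set = gene_set(sort(pheno), name = "weight_phenotype",
                             species = "mouse", allow_empty = TRUE),
    hwgbmi_set = gene_set(sort(toupper(hwg)), name = "hwg_bmi_like",
                          species = "human")
  )
}

#' Generate a synthetic cohort of weight and intake trajectories
#'
#' Each animal gets a body-weight trajectory on days `0..days` and a
#' daily-intake record on days `1..days`. Planted prone animals draw
#' their total gain from `Normal(prone_gain, gain_sd)`, resistant animals
#' from `Normal(resistant_gain, gain_sd)`, and the remaining animals from
#' the midpoint; trajectory endpoints carry the drawn gain exactly (noise
#' perturbs interior days only), so at `gain_sd = 0` top-k/bottom-k
#' cohorting recovers the planted groups exactly. Prone animals eat more
#' (3.1 vs 2.6 g/day on average, the difference reported in the study the
#' generator emulates).
#'
#' @param cfg A [sim_config()].
#' @return A tibble of class `cohort_tbl` with columns `animal_id, day,
#'   body_weight, intake` (`intake` is `NA` on day 0); the planted group
#'   of each animal is in `attr(, "planted")`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_animals
  ids <- sprintf("M%03d", seq_len(n))
  withr::with_seed(sim_seed(cfg, "cohort"), {
    group <- rep("intermediate", n)
    group[sample.int(n, cfg$n_prone + cfg$n_resistant)] <-
      c(rep("prone", cfg$n_prone), rep("resistant", cfg$n_resistant))
    mid_gain <- (cfg$prone_gain + cfg$resistant_gain) / 2
    gain_mu <- c(prone = cfg$prone_gain, resistant = cfg$resistant_gain,
                 intermediate = mid_gain)[group]
    gain <- rnorm(n, gain_mu, cfg$gain_sd)
    w0 <- rnorm(n, 20, 0.5 * min(1, cfg$gain_sd / 0.3))
    intake_mu <- c(prone = 3.1, resistant = 2.6,
                   intermediate = 2.85)[group]
    rows <- purrr::map(seq_len(n), function(i) {
      d <- 0:cfg$days
      wiggle <- c(0, rnorm(cfg$days - 1, 0, cfg$gain_sd / 4), 0)
      tibble(animal_id = ids[i], day = d,
             body_weight = w0[i] + gain[i] * d / cfg$days + wiggle,
             intake = c(NA_real_, pmax(0.5, rnorm(cfg$days, intake_mu[i],
                                                  0.1 + cfg$gain_sd / 3))))
    })
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("cohort_tbl", class(out)),
            planted = tibble(animal_id = ids, planted_group = group,
                             planted_gain = gain))
}

#' Generate a synthetic qPCR cycle-threshold table
#'
#' Two housekeeping genes (`Pgk1`, `Hprt`) anchor each sample; every
#' target gene receives a baseline delta-Ct of 5 cycles, shifted in the
#' prone group by `-effects[gene]` cycles so that the planted
#' delta-delta-Ct of a gene equals `-effects[gene]` and its expected
#' relative quantity in the prone group is `2^effects[gene]`.
#'
#' @param cfg A [sim_config()].
#' @param genes Character vector of target genes.
#' @param effects Named numeric vector (per target gene) of planted log2
#'   expression differences, prone relative to resistant; unnamed scalars
#'   recycle.
#' @param n_per_group Samples per group.
#' @param ct_sd Measurement noise on each Ct value (cycles).
#' @return A tibble `sample_id, group, gene, ct` including housekeeping
#'   rows.
#' @export
simulate_qpcr <- function(cfg, genes, effects = 1, n_per_group = 5,
                          ct_sd = 0.1) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(names(effects))) {
    effects <- stats::setNames(rep_len(effects, length(genes)), genes)
  }
  samples <- tibble(
    sample_id = sprintf("S%02d", seq_len(2 * n_per_group)),
    group = rep(c("prone", "resistant"), each = n_per_group))
  withr::with_seed(sim_seed(cfg, "qpcr"), {
    rows <- purrr::pmap(samples, function(sample_id, group) {
      hk_ct <- rnorm(2, 20, ct_sd)
      shift <- if (group == "prone") -unname(effects[genes]) else
        rep(0, length(genes))
      tibble(sample_id = sample_id, group = group,
             gene = c("Pgk1", "Hprt", genes),
             ct = c(hk_ct, rnorm(length(genes), 25 + shift, ct_sd)))
    })
  })
  dplyr::bind_rows(rows)
}

#' Write synthetic (or real) pipeline inputs to disk
#'
#' Writers for the package's plain-text dialects: peak-strength TSV
#' (`dataset_id, node, gene, strength`), ortholog TSV
#' (`src_gene, dst_gene, ...`) and cohort CSV.
#'
#' @param x The table to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(x, path) {
  validate_peak_table(x)
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
write_ortholog_map <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
write_cohort_csv <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}

#' Read an ortholog map TSV (`src_gene, dst_gene`, optional species columns)
#'
#' @param path Path to the TSV.
#' @param src_species,dst_species Species tags applied when the file does
#'   not carry them.
#' @return A tibble `src_gene, dst_gene, src_species, dst_species`.
#' @export
read_ortholog_map <- function(path, src_species = "mouse",
                              dst_species = "human") {
  map <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  miss <- setdiff(c("src_gene", "dst_gene"), names(map))
  if (length(miss)) {
    abort(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")))
  }
  if (!"src_species" %in% names(map)) map$src_species <- src_species
  if (!"dst_species" %in% names(map)) map$dst_species <- dst_species
  as_tibble(map)
}

#' Read a cohort CSV (`animal_id, day, body_weight, intake`)
#'
#' @param path Path to the CSV.
#' @return A `cohort_tbl` tibble.
#' @export
read_cohort_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  miss <- setdiff(c("animal_id", "day", "body_weight"), names(x))
  if (length(miss)) {
    abort(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")))
  }
  structure(as_tibble(x), class = c("cohort_tbl", class(as_tibble(x))))
}
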