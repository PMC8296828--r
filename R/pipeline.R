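#' Default run configuration
#'
#' The resolved defaults behind [run_pipeline()]: fold-change thresholds
#' 1.25 (up) and 0.75 (down) at p < 0.05, HCT cutoff at the 95th
#' percentile, significance at q < 0.05, a 30,000-gene universe for
#' gene-level tests (replaced by the simulated universe size in simulate
#' mode unless set explicitly) and 24,703 for annotation-universe tests.
#'
#' @return A nested list of defaults.
#' @export
default_run_config <- function() {
  list(
    thresholds = list(fc_up = 1.25, fc_down = 0.75, p_max = 0.05,
                      hct_cutoff = 95, q_sig = 0.05),
    universes = list(gene_universe = NULL, spp_universe = 24703),
    species = "mouse",
    seed = 1
  )
}

merge_config <- function(base, extra) {
  for (nm in names(extra)) {
    if (is.list(base[[nm]]) && is.list(extra[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], extra[[nm]])
    } else {
      base[[nm]] <- extra[[nm]]
    }
  }
  base
}

validate_run_config <- function(config) {
  th <- config$thresholds
  if (!(th$fc_down > 0 && th$fc_down < 1)) {
    abort("config error: 'thresholds.fc_down' must lie in (0, 1)")
  }
  if (!(th$fc_up > 1)) abort("config error: 'thresholds.fc_up' must be > 1")
  if (!(th$p_max > 0 && th$p_max <= 1)) {
    abort("config error: 'thresholds.p_max' must lie in (0, 1]")
  }
  if (!(th$hct_cutoff > 0 && th$hct_cutoff < 100)) {
    abort("config error: 'thresholds.hct_cutoff' must lie in (0, 100)")
  }
  if (!(th$q_sig > 0 && th$q_sig < 1)) {
    abort("config error: 'thresholds.q_sig' must lie in (0, 1)")
  }
  if (!is.null(config$universes$gene_universe) &&
      config$universes$gene_universe < 1) {
    abort("config error: 'universes.gene_universe' must be >= 1")
  }
  if (is.null(config$simulate) && is.null(config$inputs)) {
    abort("config error: provide either a 'simulate' block or an 'inputs' block")
  }
  invisible(config)
}

#' Run the full consensome analysis pipeline
#'
#' Config-driven orchestration: simulate (or read) the inputs, derive the
#' up/down differential-expression gene sets, build consensomes and HCT
#' sets, run the HCT intersection analysis for both gene sets, the
#' phenotype-node enrichment and the cross-species overlap where the
#' needed inputs exist, write every table as TSV/CSV/GMT under `out_dir`,
#' and write a `manifest.json` recording the resolved configuration and,
#' for every output file, its MD5 checksum and row count. Runs are
#' deterministic for a fixed config and seed. A failure of one node-level
#' test is reported in the intersection table's `error` column and never
#' aborts the batch; stage progress goes to standard error.
#'
#' @param config Path to a YAML file or a nested list. Recognised blocks:
#'   `simulate` ([sim_config()] fields), `inputs` (paths: `de`, `targets`,
#'   optional `ortholog_map`, `phenotype_gmt`), `thresholds` (`fc_up`,
#'   `fc_down`, `p_max`, `hct_cutoff`, `q_sig`), `universes`
#'   (`gene_universe`, `spp_universe`), `species`, `seed`.
#' @param out_dir Output directory (created if needed); defaults to
#'   `config$out_dir` or a session temporary directory.
#' @return The manifest, invisibly, as a list; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- merge_config(default_run_config(), config)
  validate_run_config(config)
  out_dir <- out_dir %||% config$out_dir %||% file.path(tempdir(), "consensnet_run")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  stage <- function(msg) message(sprintf("[consensnet] %s", msg))

  files <- list()
  keep <- function(name, path, tbl) {
    files[[name]] <<- list(path = path, rows = nrow(tbl))
    invisible(path)
  }

  aux <- NULL; truth <- NULL; cohort <- NULL
  if (!is.null(config$simulate)) {
    stage("simulating inputs")
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% config$seed
    cfg <- do.call(sim_config, sim_args)
    corpus <- simulate_corpus(cfg, species = config$species)
    truth <- corpus$truth
    peaks <- corpus$peaks
    de <- simulate_de_table(cfg, truth)
    aux <- simulate_aux_maps(cfg, truth)
    cohort <- simulate_cohort(cfg)
    gene_universe <- config$universes$gene_universe %||% cfg$n_genes
    keep("peaks", write_peak_table(peaks, file.path(out_dir, "peaks.tsv")), peaks)
    keep("cohort", write_cohort_csv(cohort, file.path(out_dir, "cohort.csv")), cohort)
    keep("ortholog_map",
         write_ortholog_map(aux$ortholog_map, file.path(out_dir, "ortholog_map.tsv")),
         aux$ortholog_map)
  } else {
    stage("reading inputs")
    de <- read_de_table(config$inputs$de)
    peaks <- read_ranked_targets(config$inputs$targets)
    if (!is.null(config$inputs$ortholog_map)) {
      aux <- list(ortholog_map = read_ortholog_map(config$inputs$ortholog_map))
    }
    gene_universe <- config$universes$gene_universe %||% 30000
  }
  keep("de", write_de_table(de, file.path(out_dir, "de.tsv")), de)

  stage("deriving gene sets")
  sets <- derive_de_gene_sets(de, fc_up = th$fc_up, fc_down = th$fc_down,
                              p_max = th$p_max, species = config$species)
  keep("gene_sets", write_gmt(sets, file.path(out_dir, "gene_sets.gmt")),
       tibble(x = seq_along(sets)))

  stage("building consensomes")
  cons <- build_consensomes(peaks)
  hct <- extract_hcts(cons, cutoff = th$hct_cutoff)
  keep("consensomes", write_consensome(cons, file.path(out_dir, "consensomes.tsv")), cons)
  keep("hct", {
    p <- file.path(out_dir, "hct.tsv"); readr::write_tsv(as_tibble(hct), p); p
  }, hct)

  stage("HCT intersection analysis")
  inter <- list()
  for (side in c("up", "down")) {
    s <- sets[[side]]
    if (length(s$symbols) == 0L) next
    tbl <- hct_intersection_analysis(s, hct, universe = gene_universe)
    inter[[side]] <- tbl
    keep(paste0("intersections_", side), {
      p <- file.path(out_dir, paste0("intersections_", side, ".tsv"))
      readr::write_tsv(as_tibble(tbl), p); p
    }, tbl)
  }

  enrich <- list()
  if (!is.null(inter$up) && !is.null(aux$phenotype_set)) {
    stage("phenotype-node enrichment")
    sig_nodes <- inter$up$node[!is.na(inter$up$q) & inter$up$q < th$q_sig]
    if (length(sig_nodes)) {
      pheno <- tidy(phenotype_node_enrichment(
        sig_nodes, unique(inter$up$node), aux$phenotype_set))
      enrich$phenotype <- pheno
      keep("phenotype_enrichment", {
        p <- file.path(out_dir, "phenotype_enrichment.tsv")
        readr::write_tsv(pheno, p); p
      }, pheno)
    }
  }
  if (!is.null(aux$hwgbmi_set) && length(sets$up$symbols)) {
    stage("cross-species overlap")
    xs <- cross_species_gene_overlap(sets$up, aux$hwgbmi_set,
                                     map = NULL, universe = gene_universe)
    xs_tbl <- dplyr::mutate(tidy(xs$result),
                            genes = paste(xs$intersection$symbols, collapse = ";"))
    enrich$cross_species <- xs_tbl
    keep("cross_species", {
      p <- file.path(out_dir, "cross_species.tsv")
      readr::write_tsv(xs_tbl, p); p
    }, xs_tbl)
  }
  if (!is.null(cohort)) {
    assignment <- assign_cohorts(cohort, k = min(5, floor(dplyr::n_distinct(cohort$animal_id) / 2)))
    keep("cohort_assignment", {
      p <- file.path(out_dir, "cohort_assignment.tsv")
      readr::write_tsv(as_tibble(assignment), p); p
    }, assignment)
  }

  stage("writing manifest")
  manifest <- list(
    package = "consensnet",
    version = as.character(utils::packageVersion("consensnet")),
    config = config,
    universe = gene_universe,
    n_significant_nodes = if (!is.null(inter$up))
      sum(inter$up$q < th$q_sig, na.rm = TRUE) else 0L,
    files = lapply(files, function(f) {
      list(path = basename(f$path), rows = f$rows,
           md5 = unname(tools::md5sum(f$path)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
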