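# Orchestration: one config, one output directory, deterministic artifacts.
# interactions -> network -> centralities (+ random baseline comparison) ->
# expression -> enrichment -> ranking -> reports + manifest.

run_config_defaults <- list(
  min_fold = 2, extreme_fold = 8, degree_threshold = "mean",
  min_sum_degree = 1000, alpha = 0.05, seed = 1,
  network_mode = "induced", max_bridge_len = 2,
  degrees_from = "global", fc_cap = 2^12, detection_limit = 37,
  n_perm = 999, mirna_col = "mirna", gene_col = "gene"
)

#' Read and validate a pipeline run configuration
#'
#' One flat YAML document. Required keys: `interactions` (list of
#' `{path, source}` entries), `graph`, `universe`, `plates`, `gene_sets`
#' (file paths), `reference`, `case`, `calibrator`. Optional keys with
#' defaults: min_fold (2), extreme_fold (8), degree_threshold ("mean" or a
#' number), min_sum_degree (1000), alpha (0.05), seed (1), network_mode
#' ("induced"/"bridged"), max_bridge_len (2), degrees_from
#' ("global"/"seed-network"), fc_cap, detection_limit (37), n_perm (999),
#' mirna_col, gene_col. Unknown keys are hard errors; all referenced paths
#' must exist.
#'
#' @param path YAML file.
#' @return a validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a config list (as parsed from YAML).
#' @export
validate_run_config <- function(cfg) {
  required <- c("interactions", "graph", "universe", "plates", "gene_sets",
                "reference", "case", "calibrator")
  known <- c(required, names(run_config_defaults))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop_config("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0) {
    stop_config("missing config keys: ", paste(missing, collapse = ", "))
  }
  for (k in names(run_config_defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- run_config_defaults[[k]]
  }
  for (k in c("min_fold", "extreme_fold", "min_sum_degree", "alpha",
              "max_bridge_len", "fc_cap", "detection_limit", "n_perm")) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0) {
      stop_config("config key '", k, "' must be a positive number")
    }
  }
  if (!is.list(cfg$interactions)) stop_config("'interactions' must be a list of {path, source}")
  for (entry in cfg$interactions) {
    if (is.null(entry$path) || is.null(entry$source)) {
      stop_config("each interactions entry needs 'path' and 'source'")
    }
  }
  paths <- c(vapply(cfg$interactions, `[[`, "", "path"),
             cfg$graph, cfg$universe, cfg$plates, cfg$gene_sets)
  absent <- paths[!file.exists(paths)]
  if (length(absent) > 0) {
    stop_config("input file(s) not found: ", paste(absent, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

run_stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    failed <- file.path(out_dir, "failed")
    dir.create(failed, showWarnings = FALSE, recursive = TRUE)
    keep <- list.files(out_dir, full.names = TRUE, pattern = "\\.(tsv|sif|json)$")
    file.copy(keep, failed)
    log_msg("pipeline", "stage '", name, "' failed: ", conditionMessage(e))
    stop(errorCondition(
      paste0("stage '", name, "' failed: ", conditionMessage(e)),
      class = c("mirdegree_stage_error", class(e))))
  })
}

#' Run the full workflow
#'
#' Executes every stage against the configured inputs and writes its
#' artifacts into `out_dir`: merged interaction table, seed and
#' random-baseline networks (SIF) with centrality profiles and their
#' statistical comparison, fold-change report, enrichment table for the
#' dysregulated-miRNA targets, ranking table, quadrant plot data, and a
#' machine-readable manifest (input checksums, seed, package version). All
#' outputs are pure functions of (inputs, config, seed).
#'
#' @param cfg a validated `run_config` (see [read_run_config()]).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
run_all <- function(cfg, out_dir) {
  cfg <- validate_run_config(unclass(cfg))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- function(f) file.path(out_dir, f)

  inter <- run_stage("interactions", out_dir, {
    tabs <- lapply(cfg$interactions, function(e) {
      load_interactions(e$path, e$source,
                        mirna_col = cfg$mirna_col, gene_col = cfg$gene_col)
    })
    universe <- read_universe(cfg$universe)
    merged <- filter_by_universe(merge_tables(tabs), universe)
    write_interactions(merged, art("merged_interactions.tsv"))
    list(table = merged, universe = universe)
  })

  expr <- run_stage("expression", out_dir, {
    ct <- load_ct(cfg$plates, detection_limit = cfg$detection_limit)
    ct <- interplate_calibrate(ct, cfg$calibrator)
    dct <- global_mean_normalize(ct)
    fct <- fold_changes(dct, cfg$reference, cfg$case,
                        fc_cap = cfg$fc_cap, min_fold = cfg$min_fold)
    write_fold_changes(fct, art("fold_changes.tsv"))
    fct
  })

  nets <- run_stage("network", out_dir, {
    global <- load_graph(cfg$graph)
    dys <- expr$mirna[expr$dysregulated]
    seeds <- unique(unlist(lapply(dys, targets_of, table = inter$table)))
    if (length(seeds) == 0) {
      stop_arg("no validated targets found for the dysregulated miRNAs")
    }
    seed_net <- build_seed_network(global, seeds, mode = cfg$network_mode,
                                   max_bridge_len = cfg$max_bridge_len)
    baseline <- sample_random_proteins(
      intersect(inter$universe, global$nodes),
      min(length(seeds), length(intersect(inter$universe, global$nodes))),
      seed = cfg$seed)
    rand_net <- build_seed_network(global, baseline, mode = cfg$network_mode,
                                   max_bridge_len = cfg$max_bridge_len)
    write_graph(seed_net, art("seed_network.sif"), "sif")
    write_graph(rand_net, art("random_network.sif"), "sif")
    prof_seed <- centrality_profile(seed_net, "targets")
    prof_rand <- centrality_profile(rand_net, "random")
    write_tsv_file(prof_seed, art("centralities_targets.tsv"))
    write_tsv_file(prof_rand, art("centralities_random.tsv"))
    cmp <- compare_networks(prof_seed, prof_rand, n_perm = cfg$n_perm,
                            seed = cfg$seed)
    write_tsv_file(cmp, art("network_comparison.tsv"))
    list(global = global, seed_net = seed_net, seeds = seeds)
  })

  run_stage("enrichment", out_dir, {
    sets <- read_gmt(cfg$gene_sets)
    enr <- hypergeometric_enrichment(nets$seeds, sets, inter$universe,
                                     alpha = cfg$alpha)
    write_tsv_file(enr, art("enrichment.tsv"))
    enr
  })

  ranking <- run_stage("ranking", out_dir, {
    deg_graph <- if (cfg$degrees_from == "seed-network") nets$seed_net
                 else nets$global
    degrees <- degree_centrality(deg_graph)
    r <- rank_mirnas(expr, inter$table, degrees,
                     threshold = degree_threshold(cfg$degree_threshold))
    write_tsv_file(as.data.frame(r), art("ranking.tsv"))
    qd <- export_quadrant_plot_data(r)
    qd_out <- as.data.frame(qd)
    write_tsv_file(qd_out, art("quadrant_data.tsv"))
    r
  })

  artifacts <- c("merged_interactions.tsv", "fold_changes.tsv",
                 "seed_network.sif", "random_network.sif",
                 "centralities_targets.tsv", "centralities_random.tsv",
                 "network_comparison.tsv", "enrichment.tsv",
                 "ranking.tsv", "quadrant_data.tsv")
  input_paths <- c(vapply(cfg$interactions, `[[`, "", "path"),
                   cfg$graph, cfg$universe, cfg$plates, cfg$gene_sets)
  manifest <- list(
    package_version = as.character(utils::packageVersion("mirdegree")),
    seed = cfg$seed,
    inputs = as.list(tools::md5sum(input_paths)),
    artifacts = stats::setNames(
      as.list(unname(tools::md5sum(file.path(out_dir, artifacts)))),
      artifacts),
    candidates = select_candidates(ranking, cfg$min_sum_degree)
  )
  jsonlite::write_json(manifest, art("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_msg("pipeline", "run complete: ", length(artifacts),
          " artifacts in ", out_dir)
  invisible(manifest)
}

#' Replay a printed ranking fixture
#'
#' Builds a `mirna_ranking` directly from a table of published per-miRNA
#' values (fold difference and summed target node degree), bypassing the
#' graph and expression stages. Fixture columns: mirna, fold,
#' mir2disease_flag, sum_degree. A printed fold of 0 (miRNA lost entirely in
#' the case condition) is kept, with log10 fold floored at -log10(fc_cap).
#'
#' @param fixture path to the TSV fixture, or an equivalent data.frame.
#' @param threshold a [degree_threshold()] ("mean" by default, i.e. the mean
#'   summed degree of the fixture's miRNAs).
#' @param fc_cap cap used to place fold-0 entries on the log scale.
#' @return a `mirna_ranking`.
#' @export
replay_fixture <- function(fixture, threshold = degree_threshold("mean"),
                           fc_cap = 2^12) {
  df <- if (is.character(fixture)) read_tsv_file(fixture) else fixture
  need <- c("mirna", "fold", "mir2disease_flag", "sum_degree")
  for (col in need) {
    if (!col %in% names(df)) stop_format("fixture missing column '", col, "'")
  }
  fold <- suppressWarnings(as.numeric(df$fold))
  sum_degree <- suppressWarnings(as.numeric(df$sum_degree))
  if (anyNA(fold) || anyNA(sum_degree)) {
    stop_format("non-numeric fold or sum_degree in fixture")
  }
  lfc <- ifelse(fold > 0, log10(fold), -log10(fc_cap))
  rank_from_values(normalize_mirna_id(df$mirna), fold, lfc, sum_degree,
                   n_targets_in_network = rep(NA_integer_, nrow(df)),
                   threshold = threshold)
}

#' Path to the packaged published-ranking fixture
#'
#' The packaged TSV of the 25 top-ranked dysregulated miRNAs (id, fold
#' difference case vs reference, miR2Disease listing flag, summed node degree
#' of proven targets), for [replay_fixture()].
#'
#' @return file path.
#' @export
table3_fixture <- function() {
  system.file("extdata", "table3.tsv", package = "mirdegree", mustWork = TRUE)
}
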