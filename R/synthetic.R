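# Synthetic inputs for every stage: scale-free PPI graphs, hub-biased
# miRNA->target assignment, and two-condition duplicate qPCR plates with
# planted fold changes and plate offsets.

#' Specification for synthetic data generation
#'
#' Bundles the generator parameters; generation is a pure function of the
#' spec (same spec, same bytes out). Defaults emulate the study design the
#' package targets: a scale-free protein network, miRNAs with ten validated
#' targets each drawn with hub bias, two conditions profiled in duplicate
#' (two RNA-input replicates) on one plate per (sample, replicate) with a
#' spike-in calibrator, Gaussian Ct noise of 0.2 cycles, and plate offsets of
#' about one cycle.
#'
#' @param n_nodes proteins in the synthetic PPI graph.
#' @param edges_per_new_node preferential-attachment edges per added node
#'   (>= 1, < n_nodes).
#' @param n_mirnas synthetic miRNAs per target-assignment call.
#' @param targets_per_mirna validated targets drawn per miRNA.
#' @param hub_bias_alpha target-sampling weight exponent: probability
#'   proportional to (degree + 1)^alpha; 0 = uniform, 1 = hub-biased.
#' @param planted_log2fc named numeric vector of planted log2 fold changes
#'   (case vs reference) keyed by miRNA id; miRNAs not named are null. NULL
#'   means all null.
#' @param ct_noise_sd Gaussian noise on each Ct, cycles.
#' @param plate_offsets named per-plate Ct offsets (cycles); NULL draws them
#'   uniformly from [-1.5, 1.5].
#' @param detection_limit Ct at or above which a well reads undetected.
#' @param baseline_ct_range range of per-miRNA baseline Ct values.
#' @param seed single integer seed from which all randomness flows.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_nodes = 500, edges_per_new_node = 2,
                           n_mirnas = 40, targets_per_mirna = 10,
                           hub_bias_alpha = 1, planted_log2fc = NULL,
                           ct_noise_sd = 0.2, plate_offsets = NULL,
                           detection_limit = 37,
                           baseline_ct_range = c(18, 30), seed = 1) {
  if (n_nodes <= edges_per_new_node || edges_per_new_node < 1) {
    stop_arg("need n_nodes > edges_per_new_node >= 1")
  }
  if (n_mirnas < 1 || targets_per_mirna < 1) stop_arg("counts must be positive")
  if (targets_per_mirna > n_nodes) stop_arg("targets_per_mirna exceeds n_nodes")
  if (ct_noise_sd < 0) stop_arg("ct_noise_sd must be >= 0")
  if (hub_bias_alpha < 0) stop_arg("hub_bias_alpha must be >= 0")
  structure(list(n_nodes = n_nodes, edges_per_new_node = edges_per_new_node,
                 n_mirnas = n_mirnas, targets_per_mirna = targets_per_mirna,
                 hub_bias_alpha = hub_bias_alpha,
                 planted_log2fc = planted_log2fc,
                 ct_noise_sd = ct_noise_sd, plate_offsets = plate_offsets,
                 detection_limit = detection_limit,
                 baseline_ct_range = baseline_ct_range,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a scale-free PPI graph
#'
#' Barabási–Albert preferential attachment (via igraph), undirected and
#' connected, with `edges_per_new_node` edges added per new node. Node
#' symbols are G0001, G0002, ...
#'
#' @param spec a [synthetic_spec()].
#' @param seed RNG seed (defaults to the spec's).
#' @return a `ppi_graph`.
#' @export
generate_ppi <- function(spec, seed = spec$seed) {
  ig <- with_seed(seed, igraph::sample_pa(
    spec$n_nodes, power = 1, m = spec$edges_per_new_node, directed = FALSE))
  igraph::V(ig)$name <- sprintf("G%04d", seq_len(spec$n_nodes))
  from_igraph(ig)
}

#' Assign synthetic miRNA targets with tunable hub bias
#'
#' For each synthetic miRNA, samples `targets_per_mirna` distinct proteins
#' with probability proportional to (degree + 1)^alpha — alpha = 0 is the
#' uniform control, alpha = 1 preferentially targets hubs (the +1 keeps
#' isolated nodes sampleable).
#'
#' @param g a `ppi_graph`.
#' @param spec a [synthetic_spec()].
#' @param alpha hub-bias exponent (defaults to the spec's).
#' @param mirna_prefix id prefix for the synthetic miRNAs.
#' @param seed RNG seed (defaults to the spec's).
#' @return an `interaction_table` with source label "synthetic".
#' @export
assign_targets <- function(g, spec, alpha = spec$hub_bias_alpha,
                           mirna_prefix = "syn-miR-", seed = spec$seed) {
  if (spec$targets_per_mirna > n_nodes(g)) {
    stop_arg("targets_per_mirna exceeds graph size")
  }
  deg <- degree_centrality(g)
  w <- (as.numeric(deg) + 1)^alpha
  ids <- normalize_mirna_id(paste0(mirna_prefix, seq_len(spec$n_mirnas)))
  picks <- with_seed(seed, lapply(seq_len(spec$n_mirnas), function(i) {
    sample(g$nodes, spec$targets_per_mirna, prob = w)
  }))
  df <- data.frame(mirna = rep(ids, each = spec$targets_per_mirna),
                   gene = unlist(picks), sources = "synthetic",
                   stringsAsFactors = FALSE)
  df <- df[order(df$mirna, df$gene), ]
  df <- df[!duplicated(paste(df$mirna, df$gene, sep = "\t")), ]
  new_interaction_table(df)
}

#' Generate two-condition duplicate qPCR plates with planted fold changes
#'
#' Each (sample, replicate) combination is laid out on its own plate with a
#' spike-in calibrator well. A miRNA's Ct is its baseline plus the plate
#' offset plus Gaussian noise; in the case sample the planted log2 fold
#' change is subtracted (higher expression = lower Ct). Total miRNA content
#' is conserved: the null (unplanted) miRNAs of the case sample absorb a
#' common compensating Ct shift of sum(planted effects) / n_null cycles, the
#' compositional "dilution" seen in real panels. Under this
#' constant-total-content condition the panel mean Ct is identical in both
#' samples, so global-mean normalization recovers every planted fold exactly
#' when noise is 0 (nulls carry the small dilution shift instead). Ct values
#' at or above the detection limit read as undetected.
#'
#' @param spec a [synthetic_spec()]; `planted_log2fc` names must be a subset
#'   of `mirna_ids`.
#' @param mirna_ids panel of miRNA ids.
#' @param reference_sample,case_sample sample ids.
#' @param replicates replicate ids (RNA-input duplicates by default).
#' @param calibrator_id spike-in assay id (planted offset only, no effect,
#'   noise-free so its per-plate mean identifies the offset exactly when
#'   `ct_noise_sd = 0`).
#' @param seed RNG seed (defaults to the spec's).
#' @return a `ct_table`; ground truth (baselines, planted effects, plate
#'   offsets) in `attr(, "ground_truth")`.
#' @export
generate_plates <- function(spec, mirna_ids,
                            reference_sample = "P69", case_sample = "M12",
                            replicates = c("rep25ng", "rep50ng"),
                            calibrator_id = "UniSp3", seed = spec$seed) {
  mirna_ids <- normalize_mirna_id(mirna_ids)
  planted <- spec$planted_log2fc
  if (is.null(planted)) planted <- numeric(0)
  if (length(planted) > 0 && !all(names(planted) %in% mirna_ids)) {
    stop_arg("planted_log2fc names must be a subset of mirna_ids")
  }
  effect <- stats::setNames(rep(0, length(mirna_ids)), mirna_ids)
  effect[names(planted)] <- planted
  samples <- c(reference_sample, case_sample)
  plates <- as.vector(outer(samples, replicates,
                            function(s, r) paste("plate", s, r, sep = "_")))
  with_seed(seed, {
    baseline <- stats::setNames(
      stats::runif(length(mirna_ids), spec$baseline_ct_range[1],
                   spec$baseline_ct_range[2]), mirna_ids)
    offsets <- spec$plate_offsets
    if (is.null(offsets)) {
      offsets <- stats::setNames(stats::runif(length(plates), -1.5, 1.5),
                                 plates)
    } else {
      if (length(offsets) != length(plates)) {
        stop_arg("plate_offsets must have one value per plate (",
                 length(plates), ")")
      }
      if (is.null(names(offsets))) names(offsets) <- plates
    }
    rows <- list()
    # conserve total content: nulls absorb the planted mass as dilution
    is_null <- effect == 0
    dilution <- if (any(is_null)) sum(effect) / sum(is_null) else 0
    case_shift <- ifelse(is_null, dilution, 0)
    for (s in samples) {
      for (r in replicates) {
        plate <- paste("plate", s, r, sep = "_")
        ct <- baseline + offsets[plate] +
          stats::rnorm(length(mirna_ids), 0, spec$ct_noise_sd)
        if (s == case_sample) ct <- ct - effect + case_shift
        rows[[length(rows) + 1]] <- data.frame(
          plate_id = plate, sample_id = s, replicate_id = r,
          mirna_id = mirna_ids, ct = ct, stringsAsFactors = FALSE)
        # calibrator: plate offset only, no biology, no noise
        rows[[length(rows) + 1]] <- data.frame(
          plate_id = plate, sample_id = s, replicate_id = r,
          mirna_id = normalize_mirna_id(calibrator_id),
          ct = 20 + offsets[plate], stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    df$ct[df$ct >= spec$detection_limit] <- NA_real_
    out <- new_ct_table(df, detection_limit = spec$detection_limit)
    attr(out, "ground_truth") <- list(
      baseline = baseline,
      planted_log2fc = effect,
      plate_offsets = offsets - mean(offsets),
      null_dilution = dilution)
    out
  })
}

#' Write a complete synthetic input bundle
#'
#' Graph (SIF), interactions (TSV), Ct plates (TSV) and a ground-truth
#' manifest (TSV of planted log2 fold changes) for test harnesses and CLI
#' runs.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
write_synthetic_inputs <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- generate_ppi(spec)
  inter <- assign_targets(g, spec)
  plates <- generate_plates(spec, unique(inter$mirna))
  gt <- attr(plates, "ground_truth")
  files <- c(graph = file.path(dir, "ppi.sif"),
             interactions = file.path(dir, "interactions.tsv"),
             plates = file.path(dir, "plates.tsv"),
             truth = file.path(dir, "ground_truth.tsv"),
             universe = file.path(dir, "universe.txt"))
  write_graph(g, files["graph"], "sif")
  write_interactions(inter, files["interactions"])
  write_ct(plates, files["plates"])
  write_tsv_file(data.frame(mirna = names(gt$planted_log2fc),
                            planted_log2fc = unname(gt$planted_log2fc)),
                 files["truth"])
  writeLines(g$nodes, files["universe"])
  files
}
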