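# The core statistic: score each dysregulated miRNA by the summed PPI degree
# of its validated targets, classify into expression-vs-connectivity
# quadrants, and select candidates.

#' Degree threshold specification for quadrant assignment
#'
#' @param value "mean" (threshold = arithmetic mean of the summed degrees
#'   over the ranked miRNAs) or a fixed non-negative number.
#' @return a `degree_threshold` list with `method` and `value`.
#' @export
degree_threshold <- function(value = "mean") {
  if (identical(value, "mean")) {
    structure(list(method = "mean", value = NA_real_),
              class = "degree_threshold")
  } else {
    v <- suppressWarnings(as.numeric(value))
    if (is.na(v) || v < 0) stop_arg("degree threshold must be 'mean' or a non-negative number")
    structure(list(method = "fixed", value = v), class = "degree_threshold")
  }
}

#' Summed target degree of one miRNA
#'
#' Sum of PPI node degrees over the miRNA's validated targets that are
#' present in the degree map; absent targets contribute 0 and are counted
#' separately.
#'
#' @param mirna_id miRNA identifier.
#' @param interactions an `interaction_table`.
#' @param degrees named integer vector of node degrees (e.g. from
#'   [degree_centrality()]).
#' @return list with `sum_degree` and `n_targets_in_network`.
#' @export
sum_target_degree <- function(mirna_id, interactions, degrees) {
  targets <- targets_of(interactions, mirna_id)
  present <- targets[targets %in% names(degrees)]
  list(sum_degree = sum(degrees[present]),
       n_targets_in_network = length(present))
}

new_mirna_ranking <- function(df, threshold) {
  rownames(df) <- NULL
  structure(df, class = c("mirna_ranking", "data.frame"),
            threshold = threshold)
}

#' @export
print.mirna_ranking <- function(x, ...) {
  th <- attr(x, "threshold")
  cat(sprintf("mirna_ranking: %d dysregulated miRNAs (degree threshold %s = %.4g)\n",
              nrow(x), th$method, th$value))
  NextMethod()
  invisible(x)
}

rank_from_values <- function(mirna, fold, log10_fc, sum_degree,
                             n_targets_in_network, threshold) {
  if (length(mirna) == 0) {
    warning("no dysregulated miRNAs to rank")
    th <- threshold
    if (th$method == "mean") th$value <- NA_real_
    return(new_mirna_ranking(
      data.frame(mirna = character(), fold = numeric(), log10_fc = numeric(),
                 n_targets_in_network = integer(), sum_degree = numeric(),
                 quadrant = character(), rank = integer()), th))
  }
  th <- threshold
  if (th$method == "mean") th$value <- mean(sum_degree)
  quadrant <- paste0(ifelse(sum_degree > th$value, "high", "low"), "-",
                     ifelse(log10_fc > 0, "onco", "supp"))
  ord <- order(-sum_degree, mirna)
  df <- data.frame(mirna = mirna, fold = fold, log10_fc = log10_fc,
                   n_targets_in_network = n_targets_in_network,
                   sum_degree = sum_degree, quadrant = quadrant,
                   stringsAsFactors = FALSE)[ord, ]
  df$rank <- seq_len(nrow(df))
  new_mirna_ranking(df, th)
}

#' Rank dysregulated miRNAs by summed target degree
#'
#' Restricts the fold-change table to dysregulated miRNAs, scores each by the
#' summed PPI degree of its validated targets, assigns a quadrant
#' (high/low connectivity x oncomiR/suppressor), and ranks by summed degree
#' descending, ties broken by miRNA id ascending. A miRNA whose consensus
#' fold is floored at 0 (lost entirely in the case condition) is kept, with
#' its log10 fold placed at -log10(fc_cap) so it plots at the suppressor
#' extreme.
#'
#' @param fct a `fold_change_table`.
#' @param interactions an `interaction_table` of validated targets.
#' @param degrees named degree vector (see [sum_target_degree()]).
#' @param threshold a [degree_threshold()] ("mean" by default).
#' @return a `mirna_ranking` data.frame with columns mirna, fold, log10_fc,
#'   n_targets_in_network, sum_degree, quadrant, rank.
#' @export
rank_mirnas <- function(fct, interactions, degrees,
                        threshold = degree_threshold("mean")) {
  dys <- fct[fct$dysregulated, , drop = FALSE]
  fc_cap <- attr(fct, "fc_cap")
  if (is.null(fc_cap)) fc_cap <- 2^12
  lfc <- dys$log10_fc
  floored <- !is.na(dys$fc_consensus) & dys$fc_consensus == 0
  lfc[floored] <- -log10(fc_cap)
  sd <- lapply(dys$mirna, sum_target_degree, interactions = interactions,
               degrees = degrees)
  rank_from_values(dys$mirna, dys$fc_consensus, lfc,
                   vapply(sd, `[[`, numeric(1), "sum_degree"),
                   vapply(sd, `[[`, integer(1), "n_targets_in_network"),
                   threshold)
}

#' Select high-connectivity candidate miRNAs
#'
#' miRNAs whose summed target degree strictly exceeds `min_sum_degree`,
#' ordered by rank.
#'
#' @param r a `mirna_ranking`.
#' @param min_sum_degree selection cutoff (default 1000).
#' @return character vector of miRNA ids.
#' @export
select_candidates <- function(r, min_sum_degree = 1000) {
  r$mirna[r$sum_degree > min_sum_degree][order(r$rank[r$sum_degree > min_sum_degree])]
}

#' Quadrant-plot data for a ranking
#'
#' Per-miRNA (log10 fold, summed degree, quadrant) plus the two reference
#' lines: a vertical line at log10 fold 0 (oncomiR/suppressor boundary) and a
#' horizontal line at the resolved degree threshold.
#'
#' @param r a `mirna_ranking`.
#' @return data.frame with columns mirna, log10_fc, sum_degree, quadrant;
#'   reference lines in `attr(, "vline")` and `attr(, "hline")`.
#' @export
export_quadrant_plot_data <- function(r) {
  df <- as.data.frame(r)[, c("mirna", "log10_fc", "sum_degree", "quadrant")]
  structure(df, vline = 0, hline = attr(r, "threshold")$value)
}

#' Plot expression change against summed target degree
#'
#' The quadrant scatter: x = log10 consensus fold (case vs reference),
#' y = summed PPI degree of validated targets, with the oncomiR/suppressor
#' boundary at x = 0 and the connectivity threshold as a horizontal line.
#'
#' @param r a `mirna_ranking`.
#' @param label_min_sum_degree label points above this summed degree.
#' @param ... passed to [plot()].
#' @return invisibly, the plotted data.
#' @export
plot_quadrants <- function(r, label_min_sum_degree = 1000, ...) {
  d <- export_quadrant_plot_data(r)
  plot(d$log10_fc, d$sum_degree,
       xlab = "log10 fold change (case / reference)",
       ylab = "sum of target node degrees",
       pch = 19, ...)
  abline(v = attr(d, "vline"), lty = 2)
  abline(h = attr(d, "hline"), lty = 2)
  lab <- d$sum_degree > label_min_sum_degree
  if (any(lab)) {
    text(d$log10_fc[lab], d$sum_degree[lab], d$mirna[lab], pos = 3, cex = 0.7)
  }
  invisible(d)
}
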