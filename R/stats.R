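# Statistical machinery: random-baseline sampling, ANOVA and permutation
# comparison of centrality distributions, and hypergeometric gene-set
# over-representation with Bonferroni correction.

#' Sample a random protein baseline
#'
#' Uniform sample without replacement from a background gene set;
#' deterministic for a fixed seed. Mirrors the construction of a control
#' network from proteins chosen without regard to miRNA status.
#'
#' @param background character vector (set) of gene symbols.
#' @param n sample size, at most `length(background)`.
#' @param seed integer RNG seed.
#' @return character vector of `n` sampled symbols, sorted.
#' @export
sample_random_proteins <- function(background, n, seed = 1) {
  background <- unique(background)
  if (n > length(background)) {
    stop_arg("n (", n, ") exceeds background size (", length(background), ")")
  }
  sort(with_seed(seed, sample(background, n)))
}

#' One-way analysis of variance
#'
#' Classical one-way fixed-effects F test: F on (k - 1, N - k) degrees of
#' freedom with the upper-tail p-value.
#'
#' @param groups list of >= 2 numeric vectors, each with >= 2 values; the
#'   pooled values must not all be identical.
#' @return list with `F`, `p`, `df1`, `df2`, `group_means`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop_arg("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2)) {
    stop_arg("every group needs at least 2 values")
  }
  y <- unlist(groups, use.names = FALSE)
  if (length(unique(y)) == 1) stop_arg("all values identical: F undefined")
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic), p = unname(ft$p.value),
       df1 = unname(ft$parameter[1]), df2 = unname(ft$parameter[2]),
       group_means = vapply(groups, mean, numeric(1)))
}

#' Two-sided permutation test for a difference in means
#'
#' Tests |mean(a) - mean(b)| under random relabelling, with add-one
#' smoothing: p = (1 + #\{permuted statistic >= observed\}) / (n_perm + 1).
#' With `exhaustive = TRUE` all distinct label assignments are enumerated
#' instead (small samples only).
#'
#' @param a,b numeric vectors.
#' @param n_perm number of random permutations (>= 1).
#' @param seed integer RNG seed.
#' @param exhaustive enumerate all assignments of `length(a)` labels.
#' @return p-value in (0, 1].
#' @export
permutation_test <- function(a, b, n_perm = 999, seed = 1, exhaustive = FALSE) {
  if (!exhaustive && n_perm < 1) stop_arg("n_perm must be >= 1")
  pooled <- c(a, b)
  na <- length(a)
  obs <- abs(mean(a) - mean(b))
  stat <- function(ia) {
    abs(mean(pooled[ia]) - mean(pooled[-ia]))
  }
  eps <- 1e-12
  if (exhaustive) {
    combos <- utils::combn(length(pooled), na)
    stats <- apply(combos, 2, stat)
    n <- ncol(combos)
  } else {
    stats <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      stat(sample(length(pooled), na))
    }, numeric(1)))
    n <- n_perm
  }
  (1 + sum(stats >= obs - eps)) / (n + 1)
}

#' Compare two centrality profiles metric by metric
#'
#' For each of degree, closeness and stress, compares the per-node value
#' vectors of the two graphs with a one-way ANOVA and (optionally) a
#' permutation test on the difference in means. The permutation companion is
#' recommended for interpretation: centrality distributions are heavy-tailed
#' and violate ANOVA's normality assumption.
#'
#' @param profA,profB `centrality_profile` objects (non-empty).
#' @param n_perm permutations for the companion test; 0 disables it.
#' @param seed integer RNG seed for the permutation test.
#' @return data.frame with one row per metric: metric, mean_a, mean_b, F,
#'   p_anova, p_perm, n_perm.
#' @export
compare_networks <- function(profA, profB, n_perm = 999, seed = 1) {
  if (nrow(profA) == 0 || nrow(profB) == 0) {
    stop_arg("both centrality profiles must be non-empty")
  }
  metrics <- c("degree", "closeness", "stress")
  rows <- lapply(metrics, function(m) {
    for (p in list(profA, profB)) {
      if (!m %in% names(p)) stop_arg("metric '", m, "' missing from profile")
    }
    a <- profA[[m]]
    b <- profB[[m]]
    if (length(unique(c(a, b))) == 1) {
      # no variation anywhere: means equal by construction
      f <- 0; p_anova <- 1
    } else {
      res <- one_way_anova(list(a, b))
      f <- res$F; p_anova <- res$p
    }
    p_perm <- if (n_perm > 0) permutation_test(a, b, n_perm, seed) else NA_real_
    data.frame(metric = m, mean_a = mean(a), mean_b = mean(b),
               F = f, p_anova = p_anova, p_perm = p_perm, n_perm = n_perm,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: set name, description, then member genes, tab-separated.
#'
#' @param path GMT file.
#' @return named list of uppercase gene-symbol vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  sets <- fgsea::gmtPathways(path)
  lapply(sets, function(g) unique(normalize_gene_symbol(g)))
}

#' Hypergeometric gene-set over-representation
#'
#' For each gene set, tests whether the query over-represents the set
#' relative to uniform draws from the background:
#' p_raw = P(X >= overlap) with population |background|, successes
#' |set ∩ background|, draws |query ∩ background|. Bonferroni correction
#' multiplies by the number of sets actually tested (those with a non-empty
#' background intersection). Query genes outside the background are dropped
#' with a logged count.
#'
#' @param query character vector of query gene symbols.
#' @param gene_sets named list of gene-symbol vectors (e.g. from
#'   [read_gmt()]).
#' @param background non-empty character vector, the gene universe.
#' @param alpha significance level applied to the Bonferroni-corrected p.
#' @return data.frame sorted by p_bonferroni (ties by pathway_id) with
#'   columns pathway_id, overlap, pathway_size, query_size, background_size,
#'   p_raw, p_bonferroni, neg_log10_p, significant.
#' @export
hypergeometric_enrichment <- function(query, gene_sets, background,
                                      alpha = 0.05) {
  background <- unique(normalize_gene_symbol(background))
  background <- background[nzchar(background)]
  if (length(background) == 0) stop_arg("background must be non-empty")
  query <- unique(normalize_gene_symbol(query))
  q_in <- intersect(query, background)
  if (length(q_in) < length(query)) {
    log_msg("stats", length(query) - length(q_in),
            " query genes outside background dropped")
  }
  sets_bg <- lapply(gene_sets, function(s) {
    intersect(unique(normalize_gene_symbol(s)), background)
  })
  tested <- vapply(sets_bg, length, 1L) > 0
  if (any(!tested)) {
    log_msg("stats", sum(!tested),
            " gene sets with empty background intersection dropped")
  }
  sets_bg <- sets_bg[tested]
  m <- length(sets_bg)
  if (m == 0) {
    return(data.frame(pathway_id = character(), overlap = integer(),
                      pathway_size = integer(), query_size = integer(),
                      background_size = integer(), p_raw = numeric(),
                      p_bonferroni = numeric(), neg_log10_p = numeric(),
                      significant = logical()))
  }
  B <- length(background)
  q <- length(q_in)
  res <- data.frame(
    pathway_id = names(sets_bg),
    overlap = vapply(sets_bg, function(s) length(intersect(s, q_in)), 1L),
    pathway_size = vapply(sets_bg, length, 1L),
    query_size = q,
    background_size = B,
    stringsAsFactors = FALSE
  )
  res$p_raw <- stats::phyper(res$overlap - 1, res$pathway_size,
                             B - res$pathway_size, q, lower.tail = FALSE)
  res$p_bonferroni <- pmin(1, res$p_raw * m)
  res$neg_log10_p <- -log10(res$p_bonferroni)
  res$significant <- res$p_bonferroni < alpha
  res <- res[order(res$p_bonferroni, res$pathway_id), ]
  rownames(res) <- NULL
  res
}
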