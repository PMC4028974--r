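# Validated miRNA -> target interaction tables: load, merge, de-duplicate,
# expression-filter, and per-miRNA target lookup.

new_interaction_table <- function(df, universe = NULL) {
  stopifnot(all(c("mirna", "gene", "sources") %in% names(df)))
  rownames(df) <- NULL
  structure(df, class = c("interaction_table", "data.frame"),
            universe = universe)
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf("interaction_table: %d miRNA-target pairs, %d miRNAs, %d genes%s\n",
              nrow(x), length(unique(x$mirna)), length(unique(x$gene)),
              if (is.null(attr(x, "universe"))) "" else
                sprintf(" (universe of %d genes applied)",
                        length(attr(x, "universe")))))
  NextMethod()
  invisible(x)
}

#' Load a validated miRNA-target interaction table
#'
#' Reads a TSV with a header row, normalizes identifiers (miRNA ids via
#' [normalize_mirna_id()], gene symbols uppercased), collapses duplicate rows
#' to one record per distinct (miRNA, gene) pair, and tags every record with
#' the originating database label.
#'
#' @param path TSV file with at least a miRNA-id column and a gene-symbol
#'   column.
#' @param source_label database label recorded on every record (e.g.
#'   "tarbase", "mirecords").
#' @param mirna_col,gene_col column names holding the miRNA id and gene
#'   symbol (source dumps differ in their headers).
#' @param species_prefix optional miRNA-id prefix filter (e.g. "hsa"); rows
#'   with other prefixes are dropped with a logged count.
#' @return an `interaction_table` (data.frame with columns mirna, gene,
#'   sources).
#' @export
load_interactions <- function(path, source_label,
                              mirna_col = "mirna", gene_col = "gene",
                              species_prefix = NULL) {
  df <- read_tsv_file(path, colClasses = "character")
  for (col in c(mirna_col, gene_col)) {
    if (!col %in% names(df)) {
      stop_format("missing required column '", col, "' in ", path)
    }
  }
  if (nrow(df) == 0) {
    warning("empty interaction file: ", path)
    return(new_interaction_table(
      data.frame(mirna = character(), gene = character(),
                 sources = character())))
  }
  mirna <- normalize_mirna_id(df[[mirna_col]])
  gene <- normalize_gene_symbol(df[[gene_col]])
  keep <- nzchar(mirna) & nzchar(gene)
  if (any(!keep)) log_msg("interactions", sum(!keep), " blank rows dropped")
  mirna <- mirna[keep]; gene <- gene[keep]
  if (!is.null(species_prefix)) {
    sp <- startsWith(mirna, paste0(tolower(species_prefix), "-"))
    if (any(!sp)) {
      log_msg("interactions", sum(!sp), " non-", species_prefix, " rows dropped")
    }
    mirna <- mirna[sp]; gene <- gene[sp]
  }
  pairs <- !duplicated(paste(mirna, gene, sep = "\t"))
  out <- data.frame(mirna = mirna[pairs], gene = gene[pairs],
                    sources = source_label, stringsAsFactors = FALSE)
  out <- out[order(out$mirna, out$gene), ]
  new_interaction_table(out)
}

#' Merge interaction tables into one non-redundant table
#'
#' Takes the union of (miRNA, gene) pairs across tables; a pair present in
#' several tables appears once with the union of its source labels
#' (semicolon-joined, sorted).
#'
#' @param tables list of `interaction_table` objects (at least one).
#' @return a merged `interaction_table`.
#' @export
merge_tables <- function(tables) {
  if (length(tables) < 1) stop_arg("merge_tables needs at least one table")
  df <- do.call(rbind, lapply(tables, function(t) as.data.frame(t)[
    , c("mirna", "gene", "sources"), drop = FALSE]))
  if (nrow(df) == 0) {
    return(new_interaction_table(df))
  }
  key <- paste(df$mirna, df$gene, sep = "\t")
  src <- vapply(split(df$sources, key), function(s) {
    paste(sort(unique(unlist(strsplit(s, ";", fixed = TRUE)))), collapse = ";")
  }, character(1))
  first <- df[!duplicated(key), c("mirna", "gene")]
  first$sources <- unname(src[paste(first$mirna, first$gene, sep = "\t")])
  first <- first[order(first$mirna, first$gene), ]
  new_interaction_table(first)
}

#' Restrict an interaction table to an expressed-gene universe
#'
#' Keeps only records whose target gene is in the supplied universe (e.g.
#' transcripts expressed in the tissue under study) and records the universe
#' on the table.
#'
#' @param table an `interaction_table`.
#' @param universe non-empty character vector of expressed gene symbols.
#' @return the filtered `interaction_table`.
#' @export
filter_by_universe <- function(table, universe) {
  universe <- unique(normalize_gene_symbol(universe))
  universe <- universe[nzchar(universe)]
  if (length(universe) == 0) stop_arg("universe must be non-empty")
  keep <- table$gene %in% universe
  if (any(!keep)) {
    log_msg("interactions", sum(!keep), " records outside universe dropped")
  }
  new_interaction_table(as.data.frame(table)[keep, , drop = FALSE],
                        universe = universe)
}

#' Validated targets of one miRNA
#'
#' @param table an `interaction_table`.
#' @param mirna_id miRNA identifier (normalized before lookup, so case
#'   variants of the same id match).
#' @return character vector (set) of target gene symbols; empty if the miRNA
#'   is absent.
#' @export
targets_of <- function(table, mirna_id) {
  id <- normalize_mirna_id(mirna_id)
  unique(table$gene[table$mirna == id])
}

#' Read an expressed-gene universe file
#'
#' One gene symbol per line; blank lines and lines starting with "#" ignored.
#'
#' @param path universe file.
#' @return character vector of uppercase gene symbols.
#' @export
read_universe <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(normalize_gene_symbol(lines))
}

#' Write an interaction table as TSV
#'
#' Columns mirna, gene, sources (semicolon-joined, sorted).
#'
#' @param table an `interaction_table`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_interactions <- function(table, path) {
  write_tsv_file(as.data.frame(table)[, c("mirna", "gene", "sources")], path)
}
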