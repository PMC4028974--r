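# Shared helpers: identifier normalization, logging, seeded RNG, typed errors.

#' Normalize a miRNA identifier
#'
#' Lowercases the identifier (species prefix, arm suffixes) and restores the
#' conventional capitalization of the "miR" core token, so that e.g.
#' "HSA-MIR-1", "hsa-mir-1" and "hsa-miR-1" all map to "hsa-miR-1".
#' "let"-family ids (hsa-let-7a) are already lowercase and pass through.
#'
#' @param x character vector of miRNA identifiers.
#' @return normalized character vector.
#' @export
#' @examples
#' normalize_mirna_id(c("HSA-MIR-21", "hsa-let-7a "))
normalize_mirna_id <- function(x) {
  x <- tolower(trimws(x))
  gsub("(^|-)mir(?=-|$)", "\\1miR", x, perl = TRUE)
}

#' Normalize a gene symbol
#'
#' Trims whitespace and uppercases (HGNC convention).
#'
#' @param x character vector of gene symbols.
#' @return normalized character vector.
#' @export
normalize_gene_symbol <- function(x) {
  toupper(trimws(x))
}

# Timestamped, stage-scoped logging to stderr (message()), optionally teed to a
# file set by options(mirdegree.log_file = path).
log_msg <- function(stage, ...) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, paste0(...))
  lf <- getOption("mirdegree.log_file", NULL)
  if (!is.null(lf)) cat(line, "\n", file = lf, append = TRUE, sep = "")
  message(line)
}

# Typed conditions so the CLI can map failures to exit codes
# (config 2, data format 3, stage computation 4).
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("mirdegree_config_error", "error")))
}
stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("mirdegree_format_error", "error")))
}
stop_arg <- function(...) {
  stop(errorCondition(paste0(...), class = c("mirdegree_argument_error", "error")))
}

# Evaluate expr under a fixed RNG seed without touching global RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

read_tsv_file <- function(path, ...) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
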