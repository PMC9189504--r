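`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stopf("invalid config: '%s' must be a single positive number", name)
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stopf("invalid config: '%s' must be a single non-negative number", name)
  invisible(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("invalid config: '%s' must lie in [0, 1]", name)
  invisible(x)
}

#' Derive a child RNG seed from a base seed and an index
#'
#' Keeps every derived seed a valid 32-bit integer so the same stream is
#' reproduced on any platform.
#' @noRd
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %%
               2147483647)
}

#' MD5 hash of a configuration object (via canonical JSON)
#' @noRd
config_hash <- function(obj) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null"), tf)
  unname(tools::md5sum(tf))
}

parscan_version <- function() {
  as.character(utils::packageVersion("parscan"))
}

#' Standard provenance header written at the top of every text output
#' @noRd
ps_header <- function(seed = NA, hash = NULL) {
  c(sprintf("# parscan version=%s", parscan_version()),
    sprintf("# seed=%s", as.character(seed)),
    if (!is.null(hash)) sprintf("# config_hash=%s", hash))
}

#' Write a data frame as TSV with a provenance header
#' @noRd
write_tsv_header <- function(df, path, seed = NA, hash = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(ps_header(seed, hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_header()]
#' @noRd
read_tsv_header <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  data.table::as.data.table(df)
}
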