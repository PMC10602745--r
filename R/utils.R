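# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All generator functions funnel their randomness through this.
with_rng_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Write a data.frame as TSV/CSV with '#'-prefixed provenance header lines
# recording every parameter that shaped the table.
write_provenance_table <- function(df, path, provenance = list(),
                                   sep = c("\t", ",")) {
  sep <- match.arg(sep)
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("# dualsip %s", as.character(utils::packageVersion("dualsip"))), con)
  for (nm in names(provenance)) {
    v <- provenance[[nm]]
    writeLines(sprintf("# %s: %s", nm, paste(format(v, trim = TRUE), collapse = ",")), con)
  }
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Read a table written by write_provenance_table (or any '#'-commented
# delimited file); provenance lines are returned as an attribute.
read_provenance_table <- function(path, sep = "\t") {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  attr(df, "provenance") <- sub("^#\\s*", "", hdr)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
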