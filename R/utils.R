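# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stream RNG seed from a root seed
#'
#' Permutation replicates and per-species simulations each use their own
#' derived seed so that results are reproducible and independent of the order
#' in which streams are consumed. The derivation is a fixed affine map modulo
#' a Mersenne prime; the result is always a positive 32-bit integer.
#'
#' @param seed root seed (integer).
#' @param stream stream index (integer >= 0).
#' @return an integer seed suitable for [set.seed()].
#' @export
derive_seed <- function(seed, stream) {
  s <- (abs(as.double(seed)) %% 2147483647) * 69621 + abs(as.double(stream)) * 48271
  as.integer(s %% 2147483646) + 1L
}

# Write a data.frame as plain TSV, optionally preceded by '#' comment lines
# describing the columns (units/definitions).
write_tsv <- function(df, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Deterministic polynomial hash of a string (mod 2^31 - 1), returned as 8 hex
# digits. Used for config hashes in run manifests; not cryptographic.
config_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
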