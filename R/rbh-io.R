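#' Read a multi-species ortholog table in the .rbh dialect
#'
#' Reads a tab-separated file with a header row naming, for each species tag,
#' the columns `<TAG>_gene`, `<TAG>_scaf` and `<TAG>_pos` (a configurable
#' column mapping adapts other layouts). Positions may be arbitrary
#' coordinates (e.g. base pairs); they are rank-transformed on read to
#' 0-based gene ranks per chromosome, since only gene order matters
#' downstream.
#'
#' Rows violating the single-copy invariant (a gene id appearing in more than
#' one row for the same species) are a validation error by default; with
#' `on_invalid = "drop"` all offending rows are removed and reported in a
#' warning instead.
#'
#' @param path path to the TSV file.
#' @param species character vector of species tags to read; `NULL` infers the
#'   tags from the header (every column ending in `_gene`, in order of
#'   appearance).
#' @param outgroup outgroup tag; defaults to the last species tag.
#' @param col_map optional named list mapping the roles `gene`, `scaf`, `pos`
#'   to `sprintf`-style templates with `%s` for the tag; default
#'   `list(gene = "%s_gene", scaf = "%s_scaf", pos = "%s_pos")`.
#' @param on_invalid `"error"` (default) or `"drop"`.
#' @return an [ortholog_table()]. Columns not claimed by any species are kept
#'   and survive a [write_rbh()] round-trip.
#' @export
read_rbh <- function(path, species = NULL, outgroup = NULL,
                     col_map = list(gene = "%s_gene", scaf = "%s_scaf",
                                    pos = "%s_pos"),
                     on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (is.null(species)) {
    suffix <- sub("%s", "", col_map$gene, fixed = TRUE)
    gene_cols <- names(raw)[endsWith(names(raw), suffix)]
    species <- sub(paste0(suffix, "$"), "", gene_cols)
    # a tag qualifies only when all three of its columns are present; other
    # *_gene-suffixed columns are ordinary extra columns
    species <- species[vapply(species, function(tag)
      all(vapply(c("gene", "scaf", "pos"), function(r)
        sprintf(col_map[[r]], tag) %in% names(raw), logical(1L))),
      logical(1L))]
    if (length(species) < 2L) {
      stop("could not infer at least two species tags from the header of ",
           path)
    }
  }
  # normalise columns to the internal <TAG>_gene/_scaf/_pos names
  d <- data.frame(row.names = seq_len(nrow(raw)))
  for (tag in species) {
    for (role in c("gene", "scaf", "pos")) {
      src <- sprintf(col_map[[role]], tag)
      if (!src %in% names(raw)) {
        stop("file ", path, " has no column '", src, "' for species ", tag)
      }
      d[[paste0(tag, "_", role)]] <- raw[[src]]
    }
    d[[paste0(tag, "_pos")]] <- as.numeric(d[[paste0(tag, "_pos")]])
  }
  claimed <- unlist(lapply(c("gene", "scaf", "pos"), function(r)
    sprintf(col_map[[r]], species)))
  for (extra in setdiff(names(raw), claimed)) d[[extra]] <- raw[[extra]]

  if (on_invalid == "drop" && nrow(d) > 0L) {
    bad <- rep(FALSE, nrow(d))
    for (tag in species) {
      g <- d[[paste0(tag, "_gene")]]
      bad <- bad | g %in% g[duplicated(g)]
    }
    if (any(bad)) {
      warning(sum(bad), " row(s) dropped for violating the single-copy ",
              "invariant")
      d <- d[!bad, , drop = FALSE]
    }
  }
  d <- rerank_positions(d, species)
  ortholog_table(d, species, outgroup %||% species[length(species)])
}

#' Write an ortholog table in the .rbh dialect
#'
#' Inverse of [read_rbh()]: `read_rbh(write_rbh(x, f))` reproduces `x`
#' exactly (positions are already gene ranks, so the rank transform on read
#' is the identity). Extra columns are written after the species columns.
#'
#' @param x an [ortholog_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rbh <- function(x, path) {
  stopifnot(inherits(x, "ortholog_table"))
  core <- unlist(lapply(x$species, function(tag)
    paste0(tag, c("_gene", "_scaf", "_pos"))))
  cols <- c(core, setdiff(names(x$data), core))
  utils::write.table(x$data[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}
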