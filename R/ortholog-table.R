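#' Multi-species single-copy ortholog table
#'
#' The central data container: one row per ortholog group, and for every
#' species a gene id, a chromosome (scaffold) id and an integer gene-rank
#' position on that chromosome. One species is designated the outgroup; the
#' remainder form the ingroup. Columns follow the tab-separated `.rbh`
#' dialect: `<TAG>_gene`, `<TAG>_scaf`, `<TAG>_pos` for each species tag.
#' Any additional columns are carried along untouched.
#'
#' Validated invariants: every requested species has all three columns; no
#' gene id occurs in two rows for the same species (single-copy orthologs);
#' chromosome ids are non-empty; positions are non-negative and unique within
#' each (species, chromosome). Positions are gene ranks, not base-pair
#' coordinates — only order and adjacency matter to any downstream
#' computation. [read_rbh()] rank-transforms whatever coordinates it is
#' given.
#'
#' @param data a data.frame with the per-species columns described above.
#' @param species character vector of species tags, length >= 2, in the order
#'   used to form merged combination identifiers.
#' @param outgroup tag of the outgroup species; defaults to the last tag.
#' @return an object of class `ortholog_table` with elements `data`,
#'   `species`, `outgroup`.
#' @seealso [read_rbh()], [write_rbh()], [cross_reference_clusters()]
#' @examples
#' d <- data.frame(A_gene = c("a1", "a2"), A_scaf = "chr1", A_pos = 0:1,
#'                 B_gene = c("b1", "b2"), B_scaf = "chrI", B_pos = 0:1)
#' ortholog_table(d, species = c("A", "B"), outgroup = "B")
#' @export
ortholog_table <- function(data, species, outgroup = species[length(species)]) {
  if (!is.data.frame(data)) stop("`data` must be a data.frame")
  species <- as.character(species)
  if (length(species) < 2L) stop("an ortholog table needs at least 2 species")
  if (anyDuplicated(species)) stop("duplicated species tags")
  if (!outgroup %in% species) {
    stop("outgroup '", outgroup, "' is not among the species tags")
  }
  for (tag in species) {
    need <- paste0(tag, c("_gene", "_scaf", "_pos"))
    miss <- setdiff(need, names(data))
    if (length(miss) > 0L) {
      stop("missing column(s) for species ", tag, ": ",
           paste(miss, collapse = ", "))
    }
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  rownames(data) <- NULL
  for (tag in species) {
    g <- as.character(data[[paste0(tag, "_gene")]])
    dup <- unique(g[duplicated(g)])
    if (length(dup) > 0L) {
      stop("duplicate gene id(s) for species ", tag, ": ",
           paste(utils::head(dup, 5L), collapse = ", "),
           if (length(dup) > 5L) ", ..." else "")
    }
    sc <- as.character(data[[paste0(tag, "_scaf")]])
    if (anyNA(sc) || any(!nzchar(sc))) {
      stop("empty chromosome id(s) for species ", tag)
    }
    pos <- data[[paste0(tag, "_pos")]]
    if (anyNA(pos) || any(pos < 0)) {
      stop("positions for species ", tag, " must be non-negative")
    }
    if (anyDuplicated(paste(sc, pos))) {
      stop("duplicate position within a chromosome for species ", tag,
           " (positions must be unique gene ranks)")
    }
    data[[paste0(tag, "_gene")]] <- g
    data[[paste0(tag, "_scaf")]] <- sc
    data[[paste0(tag, "_pos")]] <- as.integer(pos)
  }
  structure(list(data = data, species = species, outgroup = outgroup),
            class = "ortholog_table")
}

#' @export
print.ortholog_table <- function(x, ...) {
  cat("Ortholog table: ", nrow(x$data), " single-copy ortholog groups, ",
      length(x$species), " species\n", sep = "")
  for (tag in x$species) {
    nc <- length(unique(x$data[[paste0(tag, "_scaf")]]))
    cat("  ", tag, if (tag == x$outgroup) " (outgroup)" else "",
        ": ", nc, " chromosomes\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.ortholog_table <- function(object, ...) {
  chroms <- lapply(object$species, function(tag) {
    table(object$data[[paste0(tag, "_scaf")]])
  })
  names(chroms) <- object$species
  structure(list(n_rows = nrow(object$data), species = object$species,
                 outgroup = object$outgroup, chrom_sizes = chroms),
            class = "summary.ortholog_table")
}

#' @export
print.summary.ortholog_table <- function(x, ...) {
  cat("Ortholog table:", x$n_rows, "rows\n")
  for (tag in x$species) {
    sz <- x$chrom_sizes[[tag]]
    cat("  ", tag, if (tag == x$outgroup) " (outgroup)" else "", ": ",
        length(sz), " chromosomes, gene counts ",
        paste(as.integer(sz), collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

# Character matrix of chromosome ids, rows = ortholog groups, one column per
# requested species tag.
chrom_matrix <- function(x, species = x$species) {
  m <- vapply(species, function(tag) x$data[[paste0(tag, "_scaf")]],
              character(nrow(x$data)))
  if (nrow(x$data) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, species))
  if (nrow(x$data) == 0L) m <- matrix(character(0), nrow = 0L, ncol = length(species),
                                      dimnames = list(NULL, species))
  m
}

# Ingroup species in table order.
ingroup_species <- function(x) setdiff(x$species, x$outgroup)

# Rank-transform positions to 0-based gene ranks per (species, chromosome),
# preserving relative order (ties broken by row order).
rerank_positions <- function(data, species) {
  for (tag in species) {
    sc <- data[[paste0(tag, "_scaf")]]
    pos <- as.double(data[[paste0(tag, "_pos")]])
    r <- stats::ave(pos, sc, FUN = function(p) rank(p, ties.method = "first") - 1)
    data[[paste0(tag, "_pos")]] <- as.integer(r)
  }
  data
}

#' Restrict an ortholog table to a subset of species
#'
#' @param x an [ortholog_table()].
#' @param species tags to keep (order preserved as given).
#' @param outgroup outgroup tag for the restricted table; defaults to the
#'   original outgroup if it is kept, otherwise the last kept tag.
#' @return an `ortholog_table` over the requested species; extra columns are
#'   dropped.
#' @export
subset_species <- function(x, species,
                           outgroup = if (x$outgroup %in% species) x$outgroup
                                      else species[length(species)]) {
  stopifnot(inherits(x, "ortholog_table"))
  miss <- setdiff(species, x$species)
  if (length(miss) > 0L) stop("unknown species: ", paste(miss, collapse = ", "))
  cols <- as.vector(t(outer(species, c("_gene", "_scaf", "_pos"), paste0)))
  ortholog_table(x$data[, cols, drop = FALSE], species, outgroup)
}

#' Duplicate a species within an ortholog table
#'
#' Adds a new species whose gene locations are an exact copy of an existing
#' one, under fresh gene ids and chromosome names with a one-to-one mapping
#' to the originals. This is the "duplicated species" control used to probe
#' permutation null models: the copy is perfectly correlated with its source,
#' so a sound null model must not treat it as independent evidence.
#'
#' @param x an [ortholog_table()].
#' @param from tag of the species to copy.
#' @param to tag for the new species.
#' @return an `ortholog_table` with the extra species appended.
#' @export
copy_species <- function(x, from, to) {
  stopifnot(inherits(x, "ortholog_table"))
  if (!from %in% x$species) stop("unknown species: ", from)
  if (to %in% x$species) stop("species tag already present: ", to)
  d <- x$data
  d[[paste0(to, "_gene")]] <- paste0(to, "_", d[[paste0(from, "_gene")]])
  d[[paste0(to, "_scaf")]] <- paste0(to, "_", d[[paste0(from, "_scaf")]])
  d[[paste0(to, "_pos")]] <- d[[paste0(from, "_pos")]]
  ortholog_table(d, c(x$species, to), x$outgroup)
}
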