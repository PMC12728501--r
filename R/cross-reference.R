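#' Cross-reference pairwise best hits into N-way ortholog clusters
#'
#' Builds fully consistent single-copy ortholog clusters from directed
#' pairwise similarity hits: a cluster is one gene per species such that
#' every pair of members are reciprocal best hits of each other (a clique in
#' the reciprocal-best-hit graph). Hits with E-value at or above
#' `evalue_max` are discarded first. A gene whose minimal E-value against a
#' target species is tied between two targets has no unique best hit there
#' and joins no cluster — ties are resolved conservatively, not arbitrarily.
#' Each gene appears in at most one cluster by construction (it has at most
#' one reciprocal best partner per species).
#'
#' @param hits data.frame of directed hits with columns `species_a`,
#'   `gene_a`, `species_b`, `gene_b`, `evalue`: each row is a similarity hit
#'   of `gene_a` (in species_a) against `gene_b` (in species_b). Both
#'   directions of every species pair must be represented (an aligner's
#'   all-vs-all output has this form).
#' @param locations data.frame with columns `species`, `gene`, `chrom`,
#'   `pos` giving each gene's chromosome and position; positions are
#'   rank-transformed per chromosome in the output.
#' @param species character vector of tags (N >= 2) defining cluster size
#'   and column order of the result.
#' @param outgroup outgroup tag for the resulting table.
#' @param evalue_max hits must have E-value strictly below this threshold
#'   (default 0.1).
#' @return an [ortholog_table()] with one row per N-way clique.
#' @export
cross_reference_clusters <- function(hits, locations, species,
                                     outgroup = species[length(species)],
                                     evalue_max = 0.1) {
  species <- as.character(species)
  if (length(species) < 2L) stop("need at least 2 species")
  need <- c("species_a", "gene_a", "species_b", "gene_b", "evalue")
  miss <- setdiff(need, names(hits))
  if (length(miss) > 0L) stop("hits is missing column(s): ",
                              paste(miss, collapse = ", "))
  if (any(hits$evalue < 0)) stop("negative E-values in hits")

  hits <- hits[hits$evalue < evalue_max &
                 hits$species_a %in% species & hits$species_b %in% species, ,
               drop = FALSE]

  pairs <- utils::combn(species, 2L)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    fwd <- any(hits$species_a == a & hits$species_b == b)
    rev <- any(hits$species_a == b & hits$species_b == a)
    if (!fwd || !rev) {
      stop("no hits for species pair ", a, "-", b,
           " (both directions are required)")
    }
  }

  # best[(a,b)]: named vector gene_a -> unique best gene_b, NA if tied
  best <- new.env(parent = emptyenv())
  for (a in species) for (b in setdiff(species, a)) {
    h <- hits[hits$species_a == a & hits$species_b == b, , drop = FALSE]
    if (nrow(h) == 0L) next
    sp <- split(h[, c("gene_b", "evalue")], h$gene_a)
    bb <- vapply(sp, function(d) {
      i <- which(d$evalue == min(d$evalue))
      tgt <- unique(d$gene_b[i])
      if (length(tgt) == 1L) tgt else NA_character_
    }, character(1L))
    assign(paste(a, b, sep = "\r"), bb, envir = best)
  }
  best_of <- function(a, b, g) {
    v <- get0(paste(a, b, sep = "\r"), envir = best)
    if (is.null(v)) return(NA_character_)
    out <- v[g]
    if (is.null(out)) NA_character_ else unname(out)
  }

  # seed on the first species; a clique is determined by its member there
  s1 <- species[1L]
  seeds <- sort(unique(hits$gene_a[hits$species_a == s1]))
  rows <- list()
  for (g in seeds) {
    memb <- stats::setNames(c(g, rep(NA_character_, length(species) - 1L)),
                            species)
    ok <- TRUE
    for (b in species[-1L]) {
      memb[b] <- best_of(s1, b, g)
      if (is.na(memb[b])) { ok <- FALSE; break }
    }
    if (!ok) next
    # all ordered pairs must be each other's unique best hit
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1L, j]; b <- pairs[2L, j]
      if (!identical(best_of(a, b, memb[a]), unname(memb[b])) ||
          !identical(best_of(b, a, memb[b]), unname(memb[a]))) {
        ok <- FALSE; break
      }
    }
    if (ok) rows[[length(rows) + 1L]] <- memb
  }

  loc_key <- paste(locations$species, locations$gene, sep = "\r")
  d <- data.frame(row.names = seq_along(rows))
  for (tag in species) {
    genes <- vapply(rows, `[[`, character(1L), tag)
    if (length(genes) == 0L) {
      d[[paste0(tag, "_gene")]] <- character(0)
      d[[paste0(tag, "_scaf")]] <- character(0)
      d[[paste0(tag, "_pos")]] <- integer(0)
      next
    }
    idx <- match(paste(tag, genes, sep = "\r"), loc_key)
    if (anyNA(idx)) {
      stop("no location for gene(s) of species ", tag, ": ",
           paste(utils::head(genes[is.na(idx)], 5L), collapse = ", "))
    }
    d[[paste0(tag, "_gene")]] <- genes
    d[[paste0(tag, "_scaf")]] <- as.character(locations$chrom[idx])
    d[[paste0(tag, "_pos")]] <- as.numeric(locations$pos[idx])
  }
  d <- rerank_positions(d, species)
  ortholog_table(d, species, outgroup)
}
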