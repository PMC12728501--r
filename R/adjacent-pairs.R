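#' Conserved adjacent ortholog pairs
#'
#' Finds pairs of ortholog groups whose genes sit immediately next to each
#' other on a chromosome in several species. Two neighboring genes staying
#' neighbors (or at least co-chromosomal) across distant species is strong
#' small-scale evidence of shared descent, independent of chromosome-level
#' enrichment: the chance of the same adjacent pairing arising twice is
#' minute.
#'
#' Adjacency is computed on gene ranks *within the table's gene set*: after
#' restriction to single-copy orthologs, two rows are adjacent in a species
#' if no other retained ortholog lies between them on that chromosome
#' (absolute rank difference of 1 among retained genes). Intervening genes
#' that are not in the table do not break adjacency under this definition —
#' the operational rule is deliberately explicit because published variants
#' differ on this point. Per species, a pair is classified as `adjacent`,
#' `same_chromosome`, or `different_chromosome`; `adjacent` implies
#' `same_chromosome`.
#'
#' @param x an [ortholog_table()].
#' @param min_adjacent minimum number of species in which the pair must be
#'   adjacent (>= 1).
#' @param min_cochrom minimum number of species in which the pair must be at
#'   least co-chromosomal (adjacency counts). Must be >= `min_adjacent`.
#' @return a data.frame with one row per reported pair: `row_i`, `row_j`
#'   (ortholog-table row indices, `row_i < row_j`), per-species
#'   `<TAG>_status` and `<TAG>_scaf` columns, and `n_adjacent`,
#'   `n_cochrom`.
#' @export
find_adjacent_pairs <- function(x, min_adjacent = length(x$species) - 1L,
                                min_cochrom = length(x$species)) {
  stopifnot(inherits(x, "ortholog_table"))
  S <- length(x$species)
  if (min_adjacent < 1L) stop("min_adjacent must be >= 1")
  if (min_adjacent > S || min_cochrom > S) {
    stop("thresholds cannot exceed the number of species (", S, ")")
  }
  if (min_cochrom < min_adjacent) {
    stop("min_cochrom must be >= min_adjacent (adjacent implies ",
         "co-chromosomal)")
  }
  n <- nrow(x$data)
  if (n < 2L) {
    return(empty_adjacent_result(x$species))
  }

  # rank of each row's gene on its chromosome, per species, within the
  # table's gene set
  ranks <- lapply(x$species, function(tag) {
    sc <- x$data[[paste0(tag, "_scaf")]]
    pos <- x$data[[paste0(tag, "_pos")]]
    stats::ave(as.double(pos), sc, FUN = function(p) rank(p, ties.method = "first"))
  })
  names(ranks) <- x$species

  # candidate pairs: adjacent in at least one species (necessary since
  # min_adjacent >= 1)
  cand_i <- integer(0); cand_j <- integer(0)
  for (tag in x$species) {
    sc <- x$data[[paste0(tag, "_scaf")]]
    ord <- base::order(sc, ranks[[tag]])
    same <- sc[ord[-length(ord)]] == sc[ord[-1L]]
    a <- ord[-length(ord)][same]
    b <- ord[-1L][same]
    cand_i <- c(cand_i, pmin(a, b))
    cand_j <- c(cand_j, pmax(a, b))
  }
  keep <- !duplicated(paste(cand_i, cand_j))
  cand_i <- cand_i[keep]; cand_j <- cand_j[keep]
  if (length(cand_i) == 0L) return(empty_adjacent_result(x$species))

  status <- matrix(NA_character_, length(cand_i), S,
                   dimnames = list(NULL, x$species))
  for (tag in x$species) {
    sc <- x$data[[paste0(tag, "_scaf")]]
    same_chrom <- sc[cand_i] == sc[cand_j]
    adj <- same_chrom & abs(ranks[[tag]][cand_i] - ranks[[tag]][cand_j]) == 1
    status[, tag] <- ifelse(adj, "adjacent",
                            ifelse(same_chrom, "same_chromosome",
                                   "different_chromosome"))
  }
  n_adj <- rowSums(status == "adjacent")
  n_co <- rowSums(status != "different_chromosome")
  hit <- n_adj >= min_adjacent & n_co >= min_cochrom
  if (!any(hit)) return(empty_adjacent_result(x$species))

  out <- data.frame(row_i = cand_i[hit], row_j = cand_j[hit])
  for (tag in x$species) {
    out[[paste0(tag, "_status")]] <- status[hit, tag]
    out[[paste0(tag, "_scaf")]] <- x$data[[paste0(tag, "_scaf")]][cand_i[hit]]
  }
  out$n_adjacent <- n_adj[hit]
  out$n_cochrom <- n_co[hit]
  out <- out[base::order(-out$n_adjacent, out$row_i), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_adjacent_result <- function(species) {
  out <- data.frame(row_i = integer(0), row_j = integer(0))
  for (tag in species) {
    out[[paste0(tag, "_status")]] <- character(0)
    out[[paste0(tag, "_scaf")]] <- character(0)
  }
  out$n_adjacent <- integer(0)
  out$n_cochrom <- integer(0)
  out
}
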