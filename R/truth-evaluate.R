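#' Precision and recall of recovered combinations against simulation truth
#'
#' Scores the significant chromosome combinations of a [linkage_fisher()]
#' fit or a [build_hierarchy()] result against the ground truth of the
#' [simulate_genomes()] run that produced the table. A combination counts as
#' a true positive iff all its chromosomes share a common majority ALG: for
#' each chromosome the plurality ALG label(s) of its surviving genes are
#' taken, and the intersection across the combination's chromosomes must be
#' non-empty. Recall is the fraction of planted ALGs appearing as the common
#' majority ALG of at least one recovered combination; precision is the
#' fraction of recovered combinations that are true positives (reported as
#' `NA` when nothing was recovered).
#'
#' @param result a `linkage_fisher` or `synteny_hierarchy` object fitted to
#'   `sim$table`.
#' @param sim the `evolved_genomes` object the table came from.
#' @return list with `precision`, `recall`, `n_recovered`, `n_true_positive`,
#'   `recovered_algs` (character).
#' @export
truth_evaluate <- function(result, sim) {
  stopifnot(inherits(sim, "evolved_genomes"))
  tags <- sim$table$species
  if (inherits(result, "linkage_fisher")) {
    combos <- result$tests[result$tests$significant, tags, drop = FALSE]
  } else if (inherits(result, "synteny_hierarchy")) {
    fs <- final_survivors(result)
    if (!all(tags %in% names(fs))) {
      stop("hierarchy and simulation use different species")
    }
    combos <- fs[, tags, drop = FALSE]
  } else {
    stop("result must be a linkage_fisher or synteny_hierarchy object")
  }
  known <- unlist(lapply(tags, function(tag)
    rownames(sim$truth$chrom_alg[[tag]])))
  if (nrow(combos) > 0L &&
      !all(unlist(combos) %in% known)) {
    stop("combination refers to chromosomes absent from the simulation truth")
  }

  majority <- function(tag, chrom) {
    counts <- sim$truth$chrom_alg[[tag]][chrom, ]
    names(counts)[counts == max(counts) & counts > 0]
  }
  algs <- names(sim$ancestor$alg_sizes)
  tp <- logical(nrow(combos))
  hit_algs <- character(0)
  for (i in seq_len(nrow(combos))) {
    common <- Reduce(intersect, lapply(tags, function(tag)
      majority(tag, combos[i, tag])))
    tp[i] <- length(common) > 0L
    hit_algs <- union(hit_algs, common)
  }
  recovered_algs <- intersect(algs, hit_algs)
  list(precision = if (nrow(combos) == 0L) NA_real_ else mean(tp),
       recall = length(recovered_algs) / length(algs),
       n_recovered = nrow(combos),
       n_true_positive = sum(tp),
       recovered_algs = recovered_algs)
}
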