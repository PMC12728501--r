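#' Flat exact linkage test over all observed chromosome combinations
#'
#' The core significance test. Each row's ingroup chromosome ids are joined
#' (in ingroup species order) into a single merged identifier, e.g. three
#' ids `HCA7`, `RES2`, `EMU19` become `HCA7_RES2_EMU19`. Every observed pair
#' (merged ingroup combination, outgroup chromosome) with at least
#' `min_count` shared orthologs is a hypothesis of chromosome orthology, and
#' is tested with the upper-tail hypergeometric probability
#' ([hypergeom_tail()]) of its 2x2 contingency table. The whole family of
#' observed pairs is then Benjamini-Hochberg corrected at level `alpha`.
#'
#' This is the "flat" family: every combination observed in the data is
#' tested against the outgroup in one pass. [build_hierarchy()] offers the
#' alternative that first reduces the family to well-supported metazoan
#' (ingroup) combinations.
#'
#' @param x an [ortholog_table()] with a designated outgroup.
#' @param alpha FDR level for BH rejection (default 0.05).
#' @param min_count minimum shared-ortholog count for a combination to enter
#'   the tested family (default 1 = every observed combination).
#' @return an object of class `linkage_fisher`: list with `tests` (a
#'   data.frame with per-species chromosome columns, `ingroup_id`,
#'   `outgroup_chrom`, `k`, `K_in`, `K_out`, `N`, `p_raw`, `q_bh`,
#'   `significant`, ordered by `p_raw`), `alpha`, `min_count`, `n_rows`,
#'   `family_size`, `outgroup`, `ingroup`, `call`.
#' @examples
#' sim <- simulate_genomes(ancestral_genome(alg_sizes = c(30, 30, 30)),
#'                         n_species = 4, seed = 1)
#' fit <- linkage_fisher(sim$table)
#' summary(fit)
#' @export
linkage_fisher <- function(x, alpha = 0.05, min_count = 1L) {
  stopifnot(inherits(x, "ortholog_table"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (min_count < 1L) stop("min_count must be >= 1")
  ing <- ingroup_species(x)
  combos <- count_linked_groups(x, c(ing, x$outgroup))
  combos <- combos[combos$count >= min_count, , drop = FALSE]
  if (nrow(combos) == 0L) stop("no chromosome combination reaches min_count")

  in_id <- do.call(paste, c(combos[ing], list(sep = "_")))
  out_chrom <- combos[[x$outgroup]]
  # marginals over the full table
  full_in_id <- do.call(paste, c(lapply(ing, function(tag)
    x$data[[paste0(tag, "_scaf")]]), list(sep = "_")))
  full_out <- x$data[[paste0(x$outgroup, "_scaf")]]
  K_in <- as.integer(table(full_in_id)[in_id])
  K_out <- as.integer(table(full_out)[out_chrom])
  N <- nrow(x$data)
  k <- combos$count
  p_raw <- stats::phyper(k - 1, K_in, N - K_in, K_out, lower.tail = FALSE)
  bh <- bh_correct(p_raw, alpha)

  tests <- data.frame(combos[c(ing, x$outgroup)],
                      ingroup_id = in_id, outgroup_chrom = out_chrom,
                      k = k, K_in = K_in, K_out = K_out, N = N,
                      p_raw = p_raw, q_bh = bh$q, significant = bh$reject,
                      stringsAsFactors = FALSE)
  tests <- tests[order(tests$p_raw, -tests$k), , drop = FALSE]
  rownames(tests) <- NULL
  structure(list(tests = tests, alpha = alpha, min_count = min_count,
                 n_rows = N, family_size = nrow(tests),
                 outgroup = x$outgroup, ingroup = ing,
                 call = match.call()),
            class = "linkage_fisher")
}

#' @export
print.linkage_fisher <- function(x, n = 10L, ...) {
  cat("Exact linkage test (hypergeometric tail, BH-corrected)\n")
  cat("  ingroup: ", paste(x$ingroup, collapse = ", "),
      "; outgroup: ", x$outgroup, "\n", sep = "")
  cat("  ", x$n_rows, " orthologs; family of ", x$family_size,
      " observed combinations; ", sum(x$tests$significant),
      " significant at alpha = ", x$alpha, "\n", sep = "")
  top <- utils::head(x$tests[, c("ingroup_id", "outgroup_chrom", "k",
                                 "K_in", "K_out", "p_raw", "q_bh",
                                 "significant")], n)
  top$p_raw <- signif(top$p_raw, 2)
  top$q_bh <- signif(top$q_bh, 2)
  print(top, row.names = FALSE)
  if (nrow(x$tests) > n) cat("  ... and", nrow(x$tests) - n, "more\n")
  invisible(x)
}

#' @export
summary.linkage_fisher <- function(object, ...) {
  sig <- object$tests[object$tests$significant, , drop = FALSE]
  structure(list(family_size = object$family_size, alpha = object$alpha,
                 n_significant = nrow(sig), significant = sig),
            class = "summary.linkage_fisher")
}

#' @export
print.summary.linkage_fisher <- function(x, ...) {
  cat("Family of", x$family_size, "combination hypotheses;",
      x$n_significant, "significant at BH alpha", x$alpha, "\n")
  if (x$n_significant > 0L) {
    sig <- x$significant[, c("ingroup_id", "outgroup_chrom", "k", "K_in",
                             "K_out", "p_raw", "q_bh")]
    sig$p_raw <- signif(sig$p_raw, 2)
    sig$q_bh <- signif(sig$q_bh, 2)
    print(sig, row.names = FALSE)
  }
  invisible(x)
}

#' Plot method: standardized-residual heatmap of ingroup combinations vs
#' outgroup chromosomes
#'
#' Restricted to ingroup combinations that pass the test family's
#' `min_count`; cells are colored by standardized Pearson residuals of the
#' observed-count matrix.
#'
#' @param x a `linkage_fisher` object.
#' @param ... passed to the residual heatmap plot method.
#' @export
plot.linkage_fisher <- function(x, ...) {
  tab <- stats::xtabs(k ~ ingroup_id + outgroup_chrom, data = x$tests)
  plot(standardized_residuals(unclass(tab)), ...)
}
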