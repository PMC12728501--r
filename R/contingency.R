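#' 2x2 contingency table for a chromosome-combination overlap
#'
#' Summarises the overlap between an ingroup chromosome combination and an
#' outgroup chromosome over the ortholog table:
#' * `k` — orthologs on both the ingroup combination and the outgroup
#'   chromosome,
#' * `K_out` — total orthologs on the outgroup chromosome,
#' * `K_in` — total orthologs on the ingroup combination (any outgroup
#'   chromosome),
#' * `N` — total orthologs in the dataset.
#'
#' The cells are `((k, K_out - k), (K_in - k, N - K_out - K_in + k))`; all
#' must be non-negative and they always sum to `N`. Ortholog counts stand in
#' for chromosome sizes: a large overlap on large chromosomes is less
#' surprising than the same overlap on small ones, and the table encodes
#' exactly that.
#'
#' @param k,K_out,K_in,N the four counts described above.
#' @return an object of class `contingency_table` with elements `k`, `K_out`,
#'   `K_in`, `N` and the 2x2 `cells` matrix.
#' @examples
#' contingency_table(k = 15, K_out = 182, K_in = 27, N = 1874)
#' @export
contingency_table <- function(k, K_out, K_in, N) {
  cells <- matrix(c(k, K_in - k, K_out - k, N - K_out - K_in + k), 2L, 2L)
  if (any(cells < 0)) {
    stop("inconsistent counts: cells ((", cells[1, 1], ",", cells[1, 2],
         "),(", cells[2, 1], ",", cells[2, 2], ")) contain a negative entry")
  }
  structure(list(k = k, K_out = K_out, K_in = K_in, N = N,
                 cells = cells),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("2x2 contingency table ((", x$cells[1, 1], ",", x$cells[1, 2], "),(",
      x$cells[2, 1], ",", x$cells[2, 2], "))\n", sep = "")
  cat("  k = ", x$k, " shared, K_out = ", x$K_out, ", K_in = ", x$K_in,
      ", N = ", x$N, "\n", sep = "")
  invisible(x)
}

as_contingency <- function(x) {
  if (inherits(x, "contingency_table")) return(x)
  if (is.matrix(x) && all(dim(x) == 2L)) {
    return(contingency_table(k = x[1, 1], K_out = x[1, 1] + x[1, 2],
                             K_in = x[1, 1] + x[2, 1], N = sum(x)))
  }
  stop("expected a contingency_table or a 2x2 matrix")
}

#' Build a contingency table for an observed chromosome combination
#'
#' @param x an [ortholog_table()].
#' @param ingroup named character vector mapping each ingroup species tag to
#'   a chromosome id.
#' @param outgroup_chrom chromosome id in the outgroup species.
#' @return a [contingency_table()].
#' @export
build_contingency <- function(x, ingroup, outgroup_chrom) {
  stopifnot(inherits(x, "ortholog_table"))
  tags <- names(ingroup)
  bad <- setdiff(tags, ingroup_species(x))
  if (length(bad) > 0L) stop("not ingroup species: ", paste(bad, collapse = ", "))
  in_match <- rep(TRUE, nrow(x$data))
  for (tag in tags) {
    in_match <- in_match & x$data[[paste0(tag, "_scaf")]] == ingroup[[tag]]
  }
  out_match <- x$data[[paste0(x$outgroup, "_scaf")]] == outgroup_chrom
  k <- sum(in_match & out_match)
  if (k == 0L) {
    stop("combination never observed: ", paste(ingroup, collapse = "_"),
         " with ", outgroup_chrom)
  }
  contingency_table(k = k, K_out = sum(out_match), K_in = sum(in_match),
                    N = nrow(x$data))
}

#' Upper-tail hypergeometric probability of a chromosome overlap
#'
#' The probability of seeing `k` or more shared orthologs if the `K_in`
#' orthologs of the ingroup combination were scattered at random over the
#' outgroup genome: `P(X >= k)` for `X ~ Hypergeometric(N, K_in, K_out)`,
#' computed as the survival function at `k - 1`. The parameterisation is
#' symmetric in `K_in`/`K_out` and equals the one-sided Fisher exact test on
#' the 2x2 table. Degenerate tables (`k = 0`, or an empty margin) return 1.
#'
#' @param ct a [contingency_table()] or a 2x2 matrix
#'   `((k, K_out-k), (K_in-k, N-K_out-K_in+k))`.
#' @return the tail probability, a number in \[0, 1\].
#' @examples
#' hypergeom_tail(contingency_table(k = 15, K_out = 182, K_in = 27, N = 1874))
#' @export
hypergeom_tail <- function(ct) {
  ct <- as_contingency(ct)
  if (ct$k == 0 || ct$K_in == 0 || ct$K_out == 0) return(1)
  stats::phyper(ct$k - 1, ct$K_in, ct$N - ct$K_in, ct$K_out,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg correction with rejection flags
#'
#' Step-up FDR adjustment of a family of p-values, with rejection at
#' `adjusted <= alpha`.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return list with `q` (adjusted values, same order as input) and `reject`
#'   (logical vector).
#' @export
bh_correct <- function(pvals, alpha = 0.05) {
  if (length(pvals) > 0 && (anyNA(pvals) || any(pvals < 0 | pvals > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  q <- stats::p.adjust(pvals, method = "BH")
  list(q = q, reject = q <= alpha)
}
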