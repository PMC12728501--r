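#' Hierarchical buildup of multi-species chromosome combinations
#'
#' Builds candidate ancestral chromosome combinations one species at a time.
#' Level 1 tests every observed chromosome pair of the first two species in
#' `order`; level L >= 2 tests only extensions of the level-(L-1) survivors
#' by one chromosome of the next species. The last species in `order` is the
#' outgroup, so the final level is the metazoan-vs-unicellular comparison
#' restricted to ingroup combinations that already carry strong support.
#' Benjamini-Hochberg correction is applied within each level's family, all
#' at the same `alpha`: shrinking the family this way raises power for the
#' hard outgroup comparison at the price of never seeing combinations whose
#' support only emerges with all species jointly.
#'
#' Each level's test is the same exact statistic as [linkage_fisher()]:
#' for a parent combination with `K_in` orthologs and a new chromosome with
#' `K_out` orthologs out of `N`, the upper-tail hypergeometric probability
#' of the observed overlap.
#'
#' By default all levels count over the rows of the single N-way table `x`.
#' In pairwise-ortholog mode (`level_tables`), each level is given its own
#' ortholog table over the species seen so far, so early levels can use the
#' larger ortholog sets available without the outgroup.
#'
#' @param x an [ortholog_table()].
#' @param order character vector: a permutation of the species tags ending
#'   with the outgroup. Defaults to ingroup species in table order followed
#'   by the outgroup.
#' @param alpha BH level shared across levels (default 0.05).
#' @param min_count minimum shared orthologs for a combination to be tested
#'   (default 1).
#' @param level_tables optional list of `ortholog_table`s, one per level
#'   (length `length(order) - 1`); table L must contain species
#'   `order[1..(L+1)]`. `NULL` (default) uses `x` at every level.
#' @return an object of class `synteny_hierarchy`: list with `levels` (one
#'   element per level: `species_added`, `tests` data.frame, `survivors`
#'   data.frame of per-species chromosome columns + `combo_id`, `residuals`
#'   a [standardized_residuals()] object), plus `order`, `alpha`,
#'   `min_count`, `call`.
#' @export
build_hierarchy <- function(x, order = NULL, alpha = 0.05, min_count = 1L,
                            level_tables = NULL) {
  stopifnot(inherits(x, "ortholog_table"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  order <- order %||% c(ingroup_species(x), x$outgroup)
  if (length(order) < 2L) stop("need at least 2 species")
  if (!setequal(order, x$species) || length(order) != length(x$species)) {
    stop("`order` must be a permutation of the table's species tags")
  }
  if (order[length(order)] != x$outgroup) {
    stop("`order` must end with the outgroup (", x$outgroup, ")")
  }
  n_levels <- length(order) - 1L
  if (!is.null(level_tables) && length(level_tables) != n_levels) {
    stop("level_tables must have one table per level (", n_levels, ")")
  }

  levels <- vector("list", n_levels)
  survivors <- NULL # data.frame of per-species chrom columns for order[1..L]
  for (L in seq_len(n_levels)) {
    tbl <- if (is.null(level_tables)) x else level_tables[[L]]
    stopifnot(inherits(tbl, "ortholog_table"))
    seen <- order[seq_len(L)]
    new_sp <- order[L + 1L]
    if (!all(c(seen, new_sp) %in% tbl$species)) {
      stop("level ", L, " table lacks species ",
           paste(setdiff(c(seen, new_sp), tbl$species), collapse = ", "))
    }
    # "\r"-joined keys are used for all matching and marginal counting;
    # "_"-joined merged ids are display/reporting only
    seen_cols <- lapply(seen, function(tag) tbl$data[[paste0(tag, "_scaf")]])
    parent_key <- do.call(paste, c(seen_cols, list(sep = "\r")))
    parent_id <- do.call(paste, c(seen_cols, list(sep = "_")))
    new_chrom <- tbl$data[[paste0(new_sp, "_scaf")]]
    N <- nrow(tbl$data)
    K_in_tab <- table(parent_key)
    K_out_tab <- table(new_chrom)

    if (L == 1L) {
      keep <- rep(TRUE, N)
    } else {
      surv_key <- do.call(paste, c(survivors[seen], list(sep = "\r")))
      keep <- parent_key %in% surv_key
    }
    if (!any(keep)) {
      levels[[L]] <- list(species_added = new_sp,
                          tests = empty_level_tests(seen, new_sp),
                          survivors = NULL, residuals = NULL)
      survivors <- NULL
      next
    }
    pair_key <- paste(parent_key[keep], new_chrom[keep], sep = "\r")
    first <- !duplicated(pair_key)
    k <- tabulate(match(pair_key, pair_key[first]), nbins = sum(first))
    row_first <- which(keep)[first]
    sel <- k >= min_count
    row_first <- row_first[sel]; k <- k[sel]
    pid <- parent_id[row_first]
    nch <- new_chrom[row_first]
    if (length(k) == 0L) {
      levels[[L]] <- list(species_added = new_sp,
                          tests = empty_level_tests(seen, new_sp),
                          survivors = NULL, residuals = NULL)
      survivors <- NULL
      next
    }
    K_in <- as.integer(K_in_tab[parent_key[row_first]])
    K_out <- as.integer(K_out_tab[nch])
    p_raw <- stats::phyper(k - 1, K_in, N - K_in, K_out, lower.tail = FALSE)
    bh <- bh_correct(p_raw, alpha)

    # per-species chromosome assignment of each tested combination, read
    # directly off a representative row (merged ids are display-only and
    # would be ambiguous if chromosome names contain "_")
    chrom_cols <- lapply(seen, function(tag)
      tbl$data[[paste0(tag, "_scaf")]][row_first])
    names(chrom_cols) <- seen
    tests <- data.frame(chrom_cols, check.names = FALSE,
                        stringsAsFactors = FALSE)
    tests[[new_sp]] <- nch
    tests$parent_id <- pid
    tests$combo_id <- paste(pid, nch, sep = "_")
    tests$k <- k; tests$K_in <- K_in; tests$K_out <- K_out; tests$N <- N
    tests$p_raw <- p_raw; tests$q_bh <- bh$q; tests$significant <- bh$reject
    tests <- tests[base::order(tests$p_raw, -tests$k), , drop = FALSE]
    rownames(tests) <- NULL

    surv <- tests[tests$significant, c(seen, new_sp, "combo_id"),
                  drop = FALSE]
    surv <- surv[!duplicated(surv$combo_id), , drop = FALSE]
    rownames(surv) <- NULL

    obs <- stats::xtabs(stats::as.formula("count ~ parent + new"),
                        data = data.frame(parent = parent_id[keep],
                                          new = new_chrom[keep],
                                          count = 1))
    res <- standardized_residuals(unclass(obs))

    levels[[L]] <- list(species_added = new_sp, tests = tests,
                        survivors = surv, residuals = res)
    survivors <- if (nrow(surv) > 0L) surv else NULL
  }
  structure(list(levels = levels, order = order, alpha = alpha,
                 min_count = min_count, call = match.call()),
            class = "synteny_hierarchy")
}

empty_level_tests <- function(seen, new_sp) {
  d <- data.frame(matrix(character(0), 0L, length(seen) + 1L),
                  stringsAsFactors = FALSE)
  names(d) <- c(seen, new_sp)
  d$parent_id <- character(0); d$combo_id <- character(0)
  d$k <- integer(0); d$K_in <- integer(0); d$K_out <- integer(0)
  d$N <- integer(0); d$p_raw <- numeric(0); d$q_bh <- numeric(0)
  d$significant <- logical(0)
  d
}

#' Significant combinations at the final level of a hierarchy
#'
#' @param x a `synteny_hierarchy`.
#' @return data.frame of surviving full combinations (per-species chromosome
#'   columns + `combo_id`), or a 0-row data.frame if none survive.
#' @export
final_survivors <- function(x) {
  stopifnot(inherits(x, "synteny_hierarchy"))
  last <- x$levels[[length(x$levels)]]
  if (is.null(last$survivors)) {
    return(empty_level_tests(x$order[-length(x$order)],
                             x$order[length(x$order)])[, c(x$order, "combo_id")])
  }
  last$survivors
}

#' @export
print.synteny_hierarchy <- function(x, ...) {
  cat("Hierarchical synteny buildup over",
      paste(x$order, collapse = " -> "), "\n")
  for (L in seq_along(x$levels)) {
    lv <- x$levels[[L]]
    n_surv <- if (is.null(lv$survivors)) 0L else nrow(lv$survivors)
    cat("  level ", L, " (+", lv$species_added, "): ",
        nrow(lv$tests), " combinations tested, ", n_surv,
        " significant at BH alpha ", x$alpha, "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.synteny_hierarchy <- function(object, ...) {
  fs <- final_survivors(object)
  structure(list(order = object$order, alpha = object$alpha,
                 n_levels = length(object$levels), final = fs),
            class = "summary.synteny_hierarchy")
}

#' @export
print.summary.synteny_hierarchy <- function(x, ...) {
  cat("Hierarchy over", paste(x$order, collapse = " -> "),
      ":", nrow(x$final), "full combinations significant at BH alpha",
      x$alpha, "\n")
  if (nrow(x$final) > 0L) print(x$final, row.names = FALSE)
  invisible(x)
}

#' @export
plot.synteny_hierarchy <- function(x, levels = seq_along(x$levels), ...) {
  op <- graphics::par(mfrow = c(1, length(levels)))
  on.exit(graphics::par(op))
  for (L in levels) {
    r <- x$levels[[L]]$residuals
    if (!is.null(r)) {
      plot(r, main = paste0("level ", L, " (+",
                            x$levels[[L]]$species_added, ")"), ...)
    }
  }
  invisible(x)
}

#' Standardized Pearson residuals of a count matrix
#'
#' For an observed count matrix with expected values `E_ij = r_i c_j / N`
#' under independence, computes `(O_ij - E_ij) / sqrt(E_ij (1 - r_i/N)
#' (1 - c_j/N))` per cell, together with the omnibus chi-squared statistic
#' `sum (O - E)^2 / E`. Cells whose expected value is zero (a zero row or
#' column margin) have undefined residuals (NA) and are excluded from the
#' statistic. These residuals color the comparison heatmaps; they are
#' diagnostics, not part of the exact tests.
#'
#' @param observed non-negative count matrix with positive grand total.
#' @return an object of class `synteny_residuals`: list with `observed`,
#'   `expected`, `residuals`, `statistic`, `df`.
#' @export
standardized_residuals <- function(observed) {
  O <- as.matrix(observed)
  if (length(O) == 0L) stop("empty matrix")
  if (any(O < 0) || anyNA(O)) stop("counts must be non-negative")
  N <- sum(O)
  if (N <= 0) stop("grand total must be positive")
  rs <- rowSums(O); cs <- colSums(O)
  E <- outer(rs, cs) / N
  ok <- E > 0
  stat <- sum(((O - E)^2 / E)[ok])
  denom <- sqrt(E * outer(1 - rs / N, 1 - cs / N))
  R <- (O - E) / denom
  R[!is.finite(R)] <- NA_real_
  structure(list(observed = O, expected = E, residuals = R,
                 statistic = stat,
                 df = max(0L, (nrow(O) - 1L) * (ncol(O) - 1L))),
            class = "synteny_residuals")
}

#' @export
print.synteny_residuals <- function(x, ...) {
  cat("Standardized Pearson residuals: ", nrow(x$observed), " x ",
      ncol(x$observed), " cells; omnibus chi-squared = ",
      signif(x$statistic, 4), " on ", x$df, " df\n", sep = "")
  invisible(x)
}

#' @export
plot.synteny_residuals <- function(x, zlim = NULL, main = NULL, ...) {
  R <- x$residuals
  R[is.na(R)] <- 0
  lim <- zlim %||% c(-1, 1) * max(abs(R), 1)
  pal <- grDevices::colorRampPalette(c("#2166ac", "white", "#b2182b"))(63)
  graphics::image(seq_len(ncol(R)), seq_len(nrow(R)), t(R)[, rev(seq_len(nrow(R))), drop = FALSE],
                  zlim = lim, col = pal, axes = FALSE, xlab = "", ylab = "",
                  main = main %||% "standardized Pearson residuals", ...)
  graphics::axis(1, seq_len(ncol(R)), colnames(R) %||% seq_len(ncol(R)),
                 las = 2, cex.axis = 0.6)
  graphics::axis(2, seq_len(nrow(R)), rev(rownames(R) %||% seq_len(nrow(R))),
                 las = 2, cex.axis = 0.6)
  invisible(x)
}

#' Write a residual matrix (counts + residuals) as TSV, optionally a PNG
#'
#' @param x a [standardized_residuals()] object.
#' @param path output TSV path; written in long format with columns `row`,
#'   `col`, `observed`, `expected`, `residual` (NA where undefined).
#' @param image_path optional PNG path for a heatmap rendering.
#' @return `path`, invisibly.
#' @export
export_heatmap <- function(x, path, image_path = NULL) {
  stopifnot(inherits(x, "synteny_residuals"))
  O <- x$observed
  rn <- rownames(O) %||% as.character(seq_len(nrow(O)))
  cn <- colnames(O) %||% as.character(seq_len(ncol(O)))
  d <- data.frame(row = rep(rn, times = ncol(O)),
                  col = rep(cn, each = nrow(O)),
                  observed = as.vector(O),
                  expected = as.vector(x$expected),
                  residual = as.vector(x$residuals))
  write_tsv(d, path, comments = c(
    "row/col: chromosome (or merged combination) identifiers",
    "observed: shared single-copy ortholog count",
    "expected: count expected under independence (row*col/total)",
    "residual: standardized Pearson residual, NA where margin is zero"))
  if (!is.null(image_path)) {
    grDevices::png(image_path, width = 800, height = 800)
    plot(x)
    grDevices::dev.off()
  }
  invisible(path)
}
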