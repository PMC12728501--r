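#' Count linked-ortholog groups per chromosome combination
#'
#' For every distinct tuple of per-species chromosome ids observed across the
#' table's rows, counts how many ortholog groups fall on exactly that tuple.
#' The counts sum to the number of rows: every ortholog group lies on exactly
#' one combination.
#'
#' @param x an [ortholog_table()].
#' @param species tags defining the tuple (default: all species in table
#'   order).
#' @return a data.frame with one chromosome-id column per species plus a
#'   `count` column, ordered by decreasing count.
#' @export
count_linked_groups <- function(x, species = x$species) {
  stopifnot(inherits(x, "ortholog_table"))
  cm <- chrom_matrix(x, species)
  if (nrow(cm) == 0L) {
    out <- as.data.frame(cm)
    out$count <- integer(0)
    return(out)
  }
  key <- do.call(paste, c(lapply(seq_len(ncol(cm)), function(j) cm[, j]),
                          list(sep = "\r")))
  first <- !duplicated(key)
  out <- as.data.frame(cm[first, , drop = FALSE], stringsAsFactors = FALSE)
  names(out) <- species
  out$count <- tabulate(match(key, key[first]), nbins = sum(first))
  out <- out[order(-out$count), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Shuffle the gene-to-chromosome assignment of one or all species
#'
#' The permutation underlying both null models: for each shuffled species,
#' the (chromosome, position) location labels are permuted among the genes.
#' This preserves exactly the multiset of per-chromosome gene counts — no
#' chromosome changes size — while destroying any association between gene
#' identity and chromosome. `mode = "all"` shuffles every species
#' independently (treating all genomes as unrelated); `mode = "single"`
#' shuffles only `target`, leaving the correlation structure among the other
#' species intact.
#'
#' @param x an [ortholog_table()].
#' @param mode `"single"` or `"all"`.
#' @param target species tag to shuffle (required for `mode = "single"`).
#' @param seed root RNG seed.
#' @param rep replicate index; replicate `r` under seed `s` is deterministic
#'   and independent of other replicates (see [derive_seed()]).
#' @return a shuffled `ortholog_table`.
#' @export
shuffle_table <- function(x, mode = c("single", "all"), target = NULL,
                          seed = 1L, rep = 1L) {
  stopifnot(inherits(x, "ortholog_table"))
  mode <- match.arg(mode)
  tags <- if (mode == "all") x$species else {
    if (is.null(target)) stop("mode = \"single\" requires `target`")
    if (!target %in% x$species) stop("unknown species: ", target)
    target
  }
  set.seed(derive_seed(seed, rep))
  d <- x$data
  n <- nrow(d)
  for (tag in tags) {
    perm <- sample.int(n)
    d[[paste0(tag, "_scaf")]] <- d[[paste0(tag, "_scaf")]][perm]
    d[[paste0(tag, "_pos")]] <- d[[paste0(tag, "_pos")]][perm]
  }
  ortholog_table(d, x$species, x$outgroup)
}

#' Null distribution of linked-group sizes under repeated shuffling
#'
#' Repeatedly shuffles the table ([shuffle_table()] semantics) and tallies,
#' across all replicates, the sizes of every observed chromosome combination
#' — i.e. the frequency with which a random combination is supported by 1,
#' 2, ... shared orthologs. Comparing `mode = "all"` with `mode = "single"`
#' on a table containing closely related (or duplicated) species shows the
#' all-species strategy drains mass from the right tail: random large groups
#' become rarer, so observed groups look more significant than they should.
#'
#' @inheritParams shuffle_table
#' @param n_reps number of randomizations.
#' @return an object of class `group_size_null`: list with `counts` (named
#'   integer vector, names are group sizes), `n_reps`, `mode`, `target`,
#'   `seed`.
#' @export
shuffle_null <- function(x, mode = c("single", "all"), target = NULL,
                         n_reps = 1000L, seed = 1L) {
  stopifnot(inherits(x, "ortholog_table"), n_reps >= 1L)
  mode <- match.arg(mode)
  if (mode == "single") {
    if (is.null(target)) stop("mode = \"single\" requires `target`")
    if (!target %in% x$species) stop("unknown species: ", target)
  }
  tags <- x$species
  codes <- lapply(tags, function(tag)
    as.integer(factor(x$data[[paste0(tag, "_scaf")]])))
  names(codes) <- tags
  nlev <- vapply(codes, function(v) max(v, 1L), integer(1L))
  mult <- cumprod(c(1, as.double(nlev[-length(nlev)])))
  names(mult) <- tags
  n <- nrow(x$data)
  if (n == 0L) stop("cannot shuffle an empty table")
  shuffled <- if (mode == "all") tags else target
  fixed_key <- 0
  for (tag in setdiff(tags, shuffled)) {
    fixed_key <- fixed_key + (codes[[tag]] - 1) * mult[[tag]]
  }
  acc <- integer(0)
  for (r in seq_len(n_reps)) {
    set.seed(derive_seed(seed, r))
    key <- fixed_key
    for (tag in shuffled) {
      key <- key + (codes[[tag]][sample.int(n)] - 1) * mult[[tag]]
    }
    sizes <- rle(sort.int(key, method = "quick"))$lengths
    m <- max(sizes)
    if (m > length(acc)) acc <- c(acc, integer(m - length(acc)))
    acc <- acc + tabulate(sizes, nbins = length(acc))
  }
  structure(list(counts = stats::setNames(acc, seq_along(acc)),
                 n_reps = as.integer(n_reps), mode = mode,
                 target = if (mode == "single") target else NULL,
                 seed = seed),
            class = "group_size_null")
}

#' @export
print.group_size_null <- function(x, ...) {
  cat("Group-size null distribution (", x$mode, "-species shuffle",
      if (!is.null(x$target)) paste0(" of ", x$target), ", ",
      x$n_reps, " randomizations)\n", sep = "")
  nz <- x$counts[x$counts > 0]
  cat("  sizes observed:", paste(names(nz), collapse = " "), "\n")
  cat("  frequencies:  ", paste(nz, collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.group_size_null <- function(x, log = TRUE, ...) {
  cnt <- x$counts
  h <- if (log) log10(cnt + 1) else cnt
  graphics::barplot(h, names.arg = names(cnt),
                    xlab = "number of linked orthologs",
                    ylab = if (log) "log10(frequency + 1)" else "frequency",
                    main = paste0("shuffle ", x$mode,
                                  if (!is.null(x$target))
                                    paste0(" (", x$target, ")")), ...)
  invisible(x)
}

#' Group-size false discovery rate estimates from a permutation null
#'
#' For each group size N present in the observed data, estimates an FDR as
#' the expected number of random combinations of size >= N per randomization
#' divided by the observed number of combinations of size >= N, clamped to
#' \[0, 1\]. This reconstructs the group-size-level FDR statistic used by
#' shuffle-based synteny screens; unlike [linkage_fisher()] it ignores
#' chromosome sizes, attaching one FDR to each group size averaged over all
#' chromosomes.
#'
#' @param observed result of [count_linked_groups()] (or an integer vector of
#'   combination sizes).
#' @param null a `group_size_null` built from the same table.
#' @return data.frame with columns `size`, `n_observed_ge` (observed
#'   combinations of at least that size), `n_random_ge` (expected per
#'   randomization), `fdr`.
#' @export
fdr_by_group_size <- function(observed, null) {
  stopifnot(inherits(null, "group_size_null"))
  sizes <- if (is.data.frame(observed)) observed$count else as.integer(observed)
  if (length(sizes) == 0L) {
    return(data.frame(size = integer(0), n_observed_ge = integer(0),
                      n_random_ge = numeric(0), fdr = numeric(0)))
  }
  null_sizes <- as.integer(names(null$counts))
  out_sizes <- sort(unique(sizes))
  n_obs_ge <- vapply(out_sizes, function(s) sum(sizes >= s), integer(1L))
  n_rand_ge <- vapply(out_sizes, function(s)
    sum(null$counts[null_sizes >= s]) / null$n_reps, numeric(1L))
  data.frame(size = out_sizes, n_observed_ge = n_obs_ge,
             n_random_ge = n_rand_ge,
             fdr = pmin(1, n_rand_ge / n_obs_ge))
}
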