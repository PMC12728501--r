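#' Ancestral genome with planted linkage groups
#'
#' Describes the common ancestor from which [simulate_genomes()] evolves
#' each species: a set of genes partitioned into ancestral linkage groups
#' (ALGs), one ancestral chromosome per ALG, genes in a fixed ancestral
#' order.
#'
#' @param alg_sizes integer vector of genes per ALG.
#' @param alg_names optional ALG labels (default `ALG1`, `ALG2`, ...).
#' @return an object of class `ancestral_genome`: list with `n_genes`,
#'   `genes` (ids), `alg` (named factor gene -> ALG), `alg_sizes`.
#' @export
ancestral_genome <- function(alg_sizes, alg_names = NULL) {
  alg_sizes <- as.integer(alg_sizes)
  if (length(alg_sizes) < 1L || any(alg_sizes < 1L)) {
    stop("alg_sizes must be positive integers")
  }
  alg_names <- alg_names %||% paste0("ALG", seq_along(alg_sizes))
  if (length(alg_names) != length(alg_sizes)) {
    stop("alg_names must match alg_sizes in length")
  }
  n <- sum(alg_sizes)
  genes <- sprintf("g%05d", seq_len(n))
  alg <- factor(rep(alg_names, alg_sizes), levels = alg_names)
  names(alg) <- genes
  structure(list(n_genes = n, genes = genes, alg = alg,
                 alg_sizes = stats::setNames(alg_sizes, alg_names)),
            class = "ancestral_genome")
}

#' @export
print.ancestral_genome <- function(x, ...) {
  cat("Ancestral genome:", x$n_genes, "genes in", length(x$alg_sizes),
      "linkage groups (sizes", paste(x$alg_sizes, collapse = " "), ")\n")
  invisible(x)
}

#' Per-species chromosome-evolution parameters
#'
#' @param n_fusions number of chromosome fusions (each joins two random
#'   chromosomes end to end). Must leave at least one chromosome:
#'   `n_fusions <= n_algs - 1`.
#' @param mixing fraction in \[0, 1\] of each fused chromosome's genes that are
#'   repositioned uniformly along it after fusion. 0 models fusion without
#'   mixing (the two ancestral blocks stay intact); 1 models complete
#'   intra-chromosomal scrambling. Fusion-with-mixing is the variant argued
#'   to be effectively irreversible and hence phylogenetically informative.
#' @param n_fissions number of fissions (a random chromosome with >= 2 genes
#'   splits at a uniform internal breakpoint).
#' @param translocation_rate per-gene probability of moving to a uniformly
#'   chosen other chromosome (at a uniform insertion point).
#' @param loss_rate per-gene probability of being lost in this species.
#' @return an object of class `evolution_params`.
#' @export
evolution_params <- function(n_fusions = 0L, mixing = 0, n_fissions = 0L,
                             translocation_rate = 0, loss_rate = 0) {
  if (mixing < 0 || mixing > 1) stop("mixing must be in [0, 1]")
  if (translocation_rate < 0 || translocation_rate > 1) {
    stop("translocation_rate must be in [0, 1]")
  }
  if (loss_rate < 0 || loss_rate > 1) stop("loss_rate must be in [0, 1]")
  if (n_fusions < 0L || n_fissions < 0L) stop("event counts must be >= 0")
  structure(list(n_fusions = as.integer(n_fusions), mixing = mixing,
                 n_fissions = as.integer(n_fissions),
                 translocation_rate = translocation_rate,
                 loss_rate = loss_rate),
            class = "evolution_params")
}

#' Simulate descendant genomes from an ancestor with planted linkage groups
#'
#' Evolves each species independently from the ancestor. Each species starts
#' with one chromosome per ALG and then applies, in a fixed order for
#' reproducibility: fusions, post-fusion mixing, fissions, per-gene
#' translocations, per-gene losses. Genes lost in *any* species drop the
#' whole ortholog row, mimicking the single-copy filtering of
#' reciprocal-best-hit ortholog sets. Positions are 0-based gene ranks among
#' surviving genes.
#'
#' @param ancestor an [ancestral_genome()].
#' @param params either a single [evolution_params()] applied to every
#'   species, or a named list of them (names = species tags).
#' @param n_species number of species when `params` is a single object
#'   (tags default to `SP1`, `SP2`, ...).
#' @param species optional species tags (overrides names of `params`).
#' @param outgroup outgroup tag; default the last species.
#' @param seed root seed; species `i` evolves under [derive_seed()]`(seed, i)`,
#'   so adding a species never changes the others.
#' @return an object of class `evolved_genomes`: list with `table` (an
#'   [ortholog_table()]; the extra column `ancestor_gene` links rows to
#'   ancestral genes), `truth` (list: `alg`, the gene -> ALG map, and
#'   `chrom_alg`, per species a table of ALG membership counts per
#'   chromosome), `ancestor`, `params`, `seed`.
#' @examples
#' anc <- ancestral_genome(alg_sizes = c(30, 30, 30))
#' sim <- simulate_genomes(anc, evolution_params(translocation_rate = 0.05),
#'                         n_species = 4, seed = 7)
#' sim$table
#' @export
simulate_genomes <- function(ancestor, params = evolution_params(),
                             n_species = NULL, species = NULL,
                             outgroup = NULL, seed = 1L) {
  stopifnot(inherits(ancestor, "ancestral_genome"))
  if (inherits(params, "evolution_params")) {
    if (is.null(n_species) && is.null(species)) {
      stop("give n_species or species tags when params is a single object")
    }
    tags <- species %||% paste0("SP", seq_len(n_species))
    params <- stats::setNames(rep(list(params), length(tags)), tags)
  } else {
    stopifnot(is.list(params), all(vapply(params, inherits, TRUE,
                                          "evolution_params")))
    tags <- species %||% names(params)
    if (is.null(tags)) stop("params list must be named with species tags")
    names(params) <- tags
  }
  if (length(tags) < 2L) stop("need at least 2 species")
  outgroup <- outgroup %||% tags[length(tags)]

  genomes <- vector("list", length(tags))
  names(genomes) <- tags
  for (i in seq_along(tags)) {
    set.seed(derive_seed(seed, i))
    genomes[[i]] <- evolve_one_species(ancestor, params[[tags[i]]])
  }

  # single-copy filtering: a row survives iff the gene survives everywhere
  surviving <- Reduce(intersect, lapply(genomes, function(g) g$present))
  surviving <- ancestor$genes[ancestor$genes %in% surviving]

  d <- data.frame(ancestor_gene = surviving, stringsAsFactors = FALSE)
  truth_chrom_alg <- vector("list", length(tags))
  names(truth_chrom_alg) <- tags
  for (tag in tags) {
    g <- genomes[[tag]]
    chrom_of <- g$chrom_of[surviving]
    chrom_names <- paste0(tag, match(chrom_of, unique(chrom_of)))
    # rank among surviving genes, following the evolved within-chromosome
    # order
    ord <- g$order_of[surviving]
    pos <- stats::ave(ord, chrom_names, FUN = function(o)
      rank(o, ties.method = "first") - 1)
    d[[paste0(tag, "_gene")]] <- paste0(tag, "_", surviving)
    d[[paste0(tag, "_scaf")]] <- chrom_names
    d[[paste0(tag, "_pos")]] <- as.integer(pos)
    truth_chrom_alg[[tag]] <- table(chrom_names,
                                    as.character(ancestor$alg[surviving]))
  }
  d <- d[c(setdiff(names(d), "ancestor_gene"), "ancestor_gene")]
  tab <- ortholog_table(d, tags, outgroup)
  structure(list(table = tab,
                 truth = list(alg = ancestor$alg[surviving],
                              chrom_alg = truth_chrom_alg),
                 ancestor = ancestor, params = params, seed = seed),
            class = "evolved_genomes")
}

# Evolve one species. Chromosomes are character vectors of ancestral gene
# ids; events operate on that list. Returns the surviving gene set plus, for
# each gene, its chromosome index and within-chromosome order.
evolve_one_species <- function(ancestor, p) {
  chroms <- split(ancestor$genes, ancestor$alg)
  chroms <- unname(chroms)
  if (p$n_fusions > length(chroms) - 1L) {
    stop("n_fusions (", p$n_fusions, ") exceeds available fusions (",
         length(chroms) - 1L, ")")
  }
  fused <- logical(length(chroms))
  for (f in seq_len(p$n_fusions)) {
    pair <- sample.int(length(chroms), 2L)
    merged <- c(chroms[[pair[1L]]], chroms[[pair[2L]]])
    chroms[[pair[1L]]] <- merged
    fused[pair[1L]] <- TRUE
    chroms <- chroms[-pair[2L]]
    fused <- fused[-pair[2L]]
  }
  if (p$mixing > 0) {
    for (ci in which(fused)) {
      v <- chroms[[ci]]
      n_move <- round(p$mixing * length(v))
      if (n_move < 1L) next
      move <- sample.int(length(v), n_move)
      moved <- v[move]
      rest <- v[-move]
      for (g in moved) {
        at <- sample.int(length(rest) + 1L, 1L)
        rest <- append(rest, g, after = at - 1L)
      }
      chroms[[ci]] <- rest
    }
  }
  for (f in seq_len(p$n_fissions)) {
    big <- which(lengths(chroms) >= 2L)
    if (length(big) == 0L) break
    ci <- big[sample.int(length(big), 1L)]
    v <- chroms[[ci]]
    cut <- sample.int(length(v) - 1L, 1L)
    chroms[[ci]] <- v[seq_len(cut)]
    chroms[[length(chroms) + 1L]] <- v[-seq_len(cut)]
  }
  if (p$translocation_rate > 0 && length(chroms) >= 2L) {
    # destination drawn uniformly over all chromosomes so that rate -> 1
    # fully decouples chromosome from linkage group (a draw equal to the
    # source is an intra-chromosomal move)
    all_genes <- unlist(chroms, use.names = FALSE)
    moves <- all_genes[stats::runif(length(all_genes)) < p$translocation_rate]
    for (g in moves) {
      src <- which(vapply(chroms, function(v) g %in% v, logical(1L)))[1L]
      dst <- sample.int(length(chroms), 1L)
      if (length(chroms[[src]]) == 1L && dst != src) next # keep non-empty
      chroms[[src]] <- setdiff(chroms[[src]], g)
      at <- sample.int(length(chroms[[dst]]) + 1L, 1L)
      chroms[[dst]] <- append(chroms[[dst]], g, after = at - 1L)
    }
  }
  present <- unlist(chroms, use.names = FALSE)
  if (p$loss_rate > 0) {
    present <- present[stats::runif(length(present)) >= p$loss_rate]
  }
  chrom_of <- integer(0); order_of <- integer(0); gene_ids <- character(0)
  for (ci in seq_along(chroms)) {
    v <- chroms[[ci]]
    gene_ids <- c(gene_ids, v)
    chrom_of <- c(chrom_of, rep(ci, length(v)))
    order_of <- c(order_of, seq_along(v))
  }
  names(chrom_of) <- gene_ids
  names(order_of) <- gene_ids
  list(present = present, chrom_of = chrom_of, order_of = order_of)
}

#' @export
print.evolved_genomes <- function(x, ...) {
  cat("Simulated genome set (seed ", x$seed, "): ", sep = "")
  cat(length(x$table$species), "species,",
      nrow(x$table$data), "surviving ortholog rows,",
      length(x$ancestor$alg_sizes), "planted linkage groups\n")
  invisible(x)
}

#' @rdname simulate_genomes
#' @param object an `ancestral_genome` (for the [stats::simulate()] generic).
#' @param nsim unused (one genome set per call).
#' @param ... passed on to [simulate_genomes()].
#' @export
simulate.ancestral_genome <- function(object, nsim = 1, seed = 1L, ...) {
  simulate_genomes(object, seed = seed, ...)
}
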