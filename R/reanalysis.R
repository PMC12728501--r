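#' End-to-end reanalysis: flat test, hierarchy, permutation null
#'
#' Runs the full pipeline from one configuration: reads the ortholog table,
#' fits the flat exact linkage test ([linkage_fisher()]), the hierarchical
#' buildup ([build_hierarchy()]), the permutation null histogram
#' ([shuffle_null()]) and conserved adjacent pairs
#' ([find_adjacent_pairs()]), and writes everything as TSV plus a run
#' manifest (seed, package version, configuration hash). Identical
#' configurations produce byte-identical statistical outputs.
#'
#' The configuration is a named list or the path of a YAML file with fields:
#' `rbh` (input table path), `species` (tags, optional — inferred from the
#' header), `outgroup`, `order` (optional species order for the hierarchy,
#' ending with the outgroup), `alpha` (default 0.05), `min_count` (default
#' 1), `null` (list: `mode` "single"/"all", `target`, `reps`, `seed`),
#' `adjacent` (list: `min_adjacent`, `min_cochrom`), `out_dir`.
#'
#' The comparison table `flat_vs_hierarchy.tsv` carries one row per
#' flat-family combination with a `metazoan_status` column: `supported` when
#' the combination's ingroup part survived all pre-outgroup levels of the
#' hierarchy and the full combination was significant there, otherwise
#' `x` (the metazoan chromosomal combination was not supported) — an
#' explicit status, never a silently missing row.
#'
#' @param config named list or YAML file path.
#' @return (invisibly) an object of class `synlink_report`: list of output
#'   paths and the fitted objects.
#' @export
run_reanalysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  alpha <- config$alpha %||% 0.05
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("config error: alpha must be in (0, 1)")
  }
  min_count <- config$min_count %||% 1L
  if (is.null(config$rbh)) stop("config error: missing input path `rbh`")
  if (is.null(config$out_dir)) stop("config error: missing `out_dir`")
  null_cfg <- config$null %||% list()
  null_mode <- null_cfg$mode %||% "single"
  if (!null_mode %in% c("single", "all")) {
    stop("config error: null$mode must be 'single' or 'all'")
  }
  n_reps <- null_cfg$reps %||% 1000L
  seed <- null_cfg$seed %||% 1L

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  message("[ingest] reading ", config$rbh)
  tab <- read_rbh(config$rbh, species = config$species,
                  outgroup = config$outgroup)
  message("[ingest] ", nrow(tab$data), " ortholog rows, ",
          length(tab$species), " species (outgroup ", tab$outgroup, ")")

  message("[test] flat exact linkage test")
  flat <- linkage_fisher(tab, alpha = alpha, min_count = min_count)
  message("[test] family size ", flat$family_size, ", ",
          sum(flat$tests$significant), " significant")
  flat_out <- flat$tests
  flat_out$p_raw <- format(flat_out$p_raw, digits = 17)
  flat_out$q_bh <- format(flat_out$q_bh, digits = 17)
  write_tsv(flat_out, out("tests_flat.tsv"), comments = c(
    "one row per observed (ingroup combination, outgroup chromosome) pair",
    "k: shared orthologs; K_in/K_out: orthologs on the ingroup combination / outgroup chromosome; N: total orthologs",
    "p_raw: upper-tail hypergeometric probability of >= k shared orthologs",
    "q_bh: Benjamini-Hochberg adjusted value over the whole family",
    paste0("significant: q_bh <= alpha = ", alpha)))

  message("[hierarchy] hierarchical buildup")
  hier <- build_hierarchy(tab, order = config$order, alpha = alpha,
                          min_count = min_count)
  for (L in seq_along(hier$levels)) {
    lv <- hier$levels[[L]]
    message("[hierarchy] level ", L, " (+", lv$species_added, "): ",
            nrow(lv$tests), " tested, ",
            if (is.null(lv$survivors)) 0L else nrow(lv$survivors),
            " significant")
    lt <- lv$tests
    lt$p_raw <- format(lt$p_raw, digits = 17)
    lt$q_bh <- format(lt$q_bh, digits = 17)
    write_tsv(lt, out(sprintf("tests_hierarchy_level%d.tsv", L)),
              comments = c(
      sprintf("hierarchy level %d: extensions by species %s", L,
              lv$species_added),
      "columns as in tests_flat.tsv; parent_id/combo_id are merged chromosome identifiers"))
    if (!is.null(lv$residuals)) {
      export_heatmap(lv$residuals,
                     out(sprintf("residuals_level%d.tsv", L)))
    }
  }

  message("[null] ", null_mode, "-species shuffle, ", n_reps,
          " randomizations")
  null <- shuffle_null(tab, mode = null_mode,
                       target = null_cfg$target %||% tab$outgroup,
                       n_reps = n_reps, seed = seed)
  hist_df <- data.frame(size = as.integer(names(null$counts)),
                        frequency = as.integer(null$counts))
  write_tsv(hist_df, out("null_histogram.tsv"), comments = c(
    "size: number of linked orthologs supporting a chromosome combination",
    sprintf("frequency: occurrences over %d randomizations (%s-species shuffle)",
            null$n_reps, null$mode)))

  adj_cfg <- config$adjacent %||% list()
  adj <- find_adjacent_pairs(
    tab,
    min_adjacent = adj_cfg$min_adjacent %||% (length(tab$species) - 1L),
    min_cochrom = adj_cfg$min_cochrom %||% length(tab$species))
  message("[adjacent] ", nrow(adj), " conserved adjacent pairs")
  write_tsv(adj, out("adjacent_pairs.tsv"), comments = c(
    "conserved adjacent ortholog pairs; row_i/row_j index the input table",
    "<TAG>_status: adjacent | same_chromosome | different_chromosome",
    "n_adjacent/n_cochrom: species counts meeting each status"))

  # flat vs hierarchy comparison with explicit support status
  fs <- final_survivors(hier)
  fs_key <- if (nrow(fs) > 0L) {
    do.call(paste, c(fs[tab$species], list(sep = "\r")))
  } else character(0)
  flat_key <- do.call(paste, c(flat$tests[tab$species], list(sep = "\r")))
  cmp <- flat$tests[, c("ingroup_id", "outgroup_chrom", "k", "q_bh",
                        "significant")]
  names(cmp)[4:5] <- c("flat_q_bh", "flat_significant")
  cmp$metazoan_status <- ifelse(flat_key %in% fs_key, "supported", "x")
  cmp$flat_q_bh <- format(as.numeric(cmp$flat_q_bh), digits = 17)
  write_tsv(cmp, out("flat_vs_hierarchy.tsv"), comments = c(
    "comparison of the flat test family with the hierarchical buildup",
    "metazoan_status: 'supported' if the full combination survives the hierarchy,",
    "'x' if the (metazoan) chromosomal combination was not supported there"))

  cfg_canon <- yaml::as.yaml(config[base::order(names(config))])
  manifest <- list(
    package = "synlink",
    version = as.character(utils::packageVersion("synlink")),
    seed = seed,
    n_null_reps = n_reps,
    alpha = alpha,
    min_count = min_count,
    n_ortholog_rows = nrow(tab$data),
    flat_family_size = flat$family_size,
    config_hash = config_hash(cfg_canon),
    config = config)
  yaml::write_yaml(manifest, out("manifest.yaml"))

  res <- structure(list(paths = list(
    flat = out("tests_flat.tsv"),
    hierarchy = out(sprintf("tests_hierarchy_level%d.tsv",
                            seq_along(hier$levels))),
    null = out("null_histogram.tsv"),
    adjacent = out("adjacent_pairs.tsv"),
    comparison = out("flat_vs_hierarchy.tsv"),
    manifest = out("manifest.yaml")),
    flat = flat, hierarchy = hier, null = null, adjacent = adj),
    class = "synlink_report")
  invisible(res)
}

#' @export
print.synlink_report <- function(x, ...) {
  cat("synlink reanalysis report\n")
  cat("  flat: ", sum(x$flat$tests$significant), "/",
      x$flat$family_size, " combinations significant\n", sep = "")
  fs <- final_survivors(x$hierarchy)
  cat("  hierarchy: ", nrow(fs), " full combinations significant\n",
      sep = "")
  cat("  outputs in ", dirname(x$paths$flat), "\n", sep = "")
  invisible(x)
}
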