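planted_sim <- function(seed = 3, rate = 0.03) {
  simulate_genomes(ancestral_genome(alg_sizes = rep(30, 3)),
                   evolution_params(translocation_rate = rate),
                   n_species = 4, seed = seed)
}

test_that("the hierarchy recovers planted combinations level by level", {
  sim <- planted_sim()
  hier <- build_hierarchy(sim$table)
  expect_length(hier$levels, 3L)
  fs <- final_survivors(hier)
  expect_equal(nrow(fs), 3L)
  ev <- truth_evaluate(hier, sim)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
})

test_that("survivors at each level nest within the previous level", {
  sim <- planted_sim(seed = 12, rate = 0.08)
  hier <- build_hierarchy(sim$table)
  ord <- hier$order
  for (L in 2:length(hier$levels)) {
    cur <- hier$levels[[L]]$survivors
    prev <- hier$levels[[L - 1L]]$survivors
    if (is.null(cur) || nrow(cur) == 0L) next
    seen <- ord[seq_len(L)]
    proj <- do.call(paste, c(cur[seen], list(sep = "\r")))
    prev_key <- do.call(paste, c(prev[seen], list(sep = "\r")))
    expect_true(all(proj %in% prev_key))
  }
})

test_that("a two-species hierarchy equals the flat test on pairs", {
  tab <- subset_species(planted_sim()$table, c("SP1", "SP4"),
                        outgroup = "SP4")
  hier <- build_hierarchy(tab)
  flat <- linkage_fisher(tab)
  expect_length(hier$levels, 1L)
  ht <- hier$levels[[1]]$tests
  key_h <- paste(ht$SP1, ht$SP4)
  key_f <- paste(flat$tests$SP1, flat$tests$SP4)
  expect_setequal(key_h, key_f)
  m <- match(key_f, key_h)
  expect_equal(ht$p_raw[m], flat$tests$p_raw)
  expect_equal(ht$q_bh[m], flat$tests$q_bh)
})

test_that("final-level p-values equal flat p-values for shared combinations", {
  # the hierarchy changes the testing family, not the final-level statistic
  sim <- planted_sim(seed = 21)
  hier <- build_hierarchy(sim$table)
  flat <- linkage_fisher(sim$table)
  last <- hier$levels[[length(hier$levels)]]$tests
  tags <- sim$table$species
  key_h <- do.call(paste, c(last[tags], list(sep = "\r")))
  key_f <- do.call(paste, c(flat$tests[tags], list(sep = "\r")))
  shared <- intersect(key_h, key_f)
  expect_gt(length(shared), 0L)
  expect_equal(last$p_raw[match(shared, key_h)],
               flat$tests$p_raw[match(shared, key_f)])
})

test_that("a fully shuffled table yields (almost) no final survivors", {
  hits <- 0L
  for (s in 1:5) {
    sim <- planted_sim(seed = s)
    sh <- shuffle_table(sim$table, "all", seed = s + 100)
    hier <- build_hierarchy(sh)
    hits <- hits + nrow(final_survivors(hier))
  }
  expect_lte(hits, 1L)
})

test_that("standardized residuals match their closed form and base R", {
  r <- standardized_residuals(matrix(c(10, 0, 0, 10), 2, 2))
  expect_equal(r$statistic, 20)
  expect_equal(sign(r$residuals), matrix(c(1, -1, -1, 1), 2))
  expect_equal(abs(r$residuals), matrix(sqrt(20), 2, 2))
  # independent cross-check on a random matrix
  set.seed(77)
  O <- matrix(rpois(20, 6), 4, 5)
  ours <- standardized_residuals(O)
  ref <- suppressWarnings(chisq.test(O))
  expect_equal(ours$residuals, ref$stdres, ignore_attr = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(sum(ours$observed - ours$expected), 0)
})

test_that("residual edge cases: expected-equal matrix, margins, 1x1", {
  O <- outer(c(2, 3), c(4, 6)) / 5 # equals its own expectation
  r <- standardized_residuals(O)
  expect_true(all(abs(r$residuals) < 1e-12))
  expect_equal(r$statistic, 0)
  # zero column margin: undefined cells excluded from the statistic
  rz <- standardized_residuals(matrix(c(3, 1, 0, 0), 2, 2))
  expect_true(all(is.na(rz$residuals[, 2])))
  expect_true(is.finite(rz$statistic))
  r1 <- standardized_residuals(matrix(5, 1, 1))
  expect_true(is.na(r1$residuals[1, 1]))
  expect_equal(r1$statistic, 0)
  expect_error(standardized_residuals(matrix(numeric(0), 0, 0)), "empty")
  expect_error(standardized_residuals(matrix(0, 2, 2)), "positive")
})

test_that("heatmap export writes counts and residuals as TSV", {
  sim <- planted_sim()
  hier <- build_hierarchy(sim$table)
  f <- tempfile(fileext = ".tsv")
  export_heatmap(hier$levels[[1]]$residuals, f)
  d <- read.delim(f, comment.char = "#")
  r <- hier$levels[[1]]$residuals
  expect_equal(nrow(d), length(r$observed))
  expect_named(d, c("row", "col", "observed", "expected", "residual"))
  # hot cells sit exactly at the planted pairings
  hot <- d[d$residual > 5 & !is.na(d$residual), ]
  expect_equal(nrow(hot), 3L)
  expect_error(export_heatmap(list(), f))
})

test_that("signal-noise separation degrades as added species diverge more", {
  # each successive species is more rearranged relative to the ancestor, so
  # the residual margin between planted cells and the strongest background
  # cell must shrink level by level — true positives and noise blur as
  # phylogenetic distance grows
  margin <- function(hier, L) {
    r <- hier$levels[[L]]$residuals$residuals
    r[is.na(r)] <- 0
    planted <- apply(r, 1, max)
    background <- max(r[r < matrix(planted, nrow(r), ncol(r))])
    min(planted) - background
  }
  prm <- list(SP1 = evolution_params(translocation_rate = 0.02),
              SP2 = evolution_params(translocation_rate = 0.02),
              SP3 = evolution_params(translocation_rate = 0.12),
              SP4 = evolution_params(translocation_rate = 0.3))
  for (s in 1:4) {
    sim <- simulate_genomes(ancestral_genome(alg_sizes = rep(30, 3)), prm,
                            seed = s)
    hier <- build_hierarchy(sim$table)
    margins <- vapply(seq_along(hier$levels), function(L) margin(hier, L),
                      numeric(1))
    expect_true(all(diff(margins) < 0), label = paste("seed", s))
  }
})
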