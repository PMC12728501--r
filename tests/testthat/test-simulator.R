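test_that("zero-event evolution maps combinations one-to-one onto ALGs", {
  anc <- ancestral_genome(alg_sizes = c(20, 15, 10))
  sim <- simulate_genomes(anc, evolution_params(), n_species = 4, seed = 1)
  expect_equal(nrow(sim$table$data), 45L)
  cnt <- count_linked_groups(sim$table)
  expect_equal(nrow(cnt), 3L)
  expect_setequal(cnt$count, c(20L, 15L, 10L))
  # ground truth covers all surviving genes
  expect_equal(length(sim$truth$alg), 45L)
  # each chromosome holds exactly one ALG
  for (tag in sim$table$species) {
    m <- sim$truth$chrom_alg[[tag]]
    expect_true(all(rowSums(m > 0) == 1))
  }
})

test_that("simulation is deterministic given a seed and varies across seeds", {
  anc <- ancestral_genome(alg_sizes = rep(20, 4))
  p <- evolution_params(n_fusions = 1, mixing = 0.5,
                        translocation_rate = 0.1, loss_rate = 0.05)
  s1 <- simulate_genomes(anc, p, n_species = 3, seed = 6)
  s2 <- simulate_genomes(anc, p, n_species = 3, seed = 6)
  expect_table_equal(s1$table, s2$table)
  s3 <- simulate_genomes(anc, p, n_species = 3, seed = 7)
  expect_false(identical(s1$table$data, s3$table$data))
})

test_that("fusion without mixing concatenates: one ALG's ranks precede the other's", {
  anc <- ancestral_genome(alg_sizes = c(12, 12))
  sim <- simulate_genomes(anc, list(
    A = evolution_params(n_fusions = 1, mixing = 0),
    B = evolution_params()), seed = 9)
  d <- sim$table$data
  fusedA <- names(which(table(d$A_scaf) == 24))
  expect_length(fusedA, 1L)
  on_fused <- d$A_scaf == fusedA
  alg <- as.character(sim$truth$alg)
  r1 <- d$A_pos[on_fused & alg == "ALG1"]
  r2 <- d$A_pos[on_fused & alg == "ALG2"]
  expect_true(max(r1) < min(r2) || max(r2) < min(r1))
})

test_that("full mixing interleaves the fused blocks", {
  anc <- ancestral_genome(alg_sizes = c(30, 30))
  sim <- simulate_genomes(anc, list(
    A = evolution_params(n_fusions = 1, mixing = 1),
    B = evolution_params()), seed = 10)
  d <- sim$table$data
  alg <- as.character(sim$truth$alg)
  r1 <- d$A_pos[alg == "ALG1"]
  r2 <- d$A_pos[alg == "ALG2"]
  # blocks overlap rather than stack end to end
  expect_true(min(r2) < max(r1) && min(r1) < max(r2))
})

test_that("gene loss drops whole rows, mimicking single-copy filtering", {
  anc <- ancestral_genome(alg_sizes = rep(50, 2))
  sim <- simulate_genomes(anc, evolution_params(loss_rate = 0.2),
                          n_species = 3, seed = 11)
  expect_lt(nrow(sim$table$data), 100L)
  # survivors are exactly the genes present in every species
  expect_setequal(names(sim$truth$alg), sim$table$data$ancestor_gene)
  # expected survival ~ 0.8^3 = 0.512
  expect_gt(nrow(sim$table$data), 100 * 0.3)
  expect_lt(nrow(sim$table$data), 100 * 0.75)
})

test_that("saturated translocation decouples chromosomes from ALGs", {
  anc <- ancestral_genome(alg_sizes = rep(40, 3))
  pvals <- vapply(1:5, function(s) {
    sim <- simulate_genomes(anc, list(
      A = evolution_params(),
      B = evolution_params(translocation_rate = 1)), seed = s)
    tab <- table(sim$table$data$B_scaf, as.character(sim$truth$alg))
    suppressWarnings(chisq.test(tab)$p.value)
  }, numeric(1))
  # no systematic ALG-chromosome association remains
  expect_gt(mean(pvals > 0.01), 0.5)
  expect_gt(min(pvals), 1e-4)
})

test_that("fusions beyond the available chromosome count error", {
  anc <- ancestral_genome(alg_sizes = rep(10, 3))
  expect_error(simulate_genomes(anc, evolution_params(n_fusions = 3),
                                n_species = 2, seed = 1), "exceeds")
})

test_that("a copied species reproduces the duplicated-species construction", {
  sim <- simulate_genomes(ancestral_genome(alg_sizes = rep(20, 4)),
                          evolution_params(), n_species = 2, seed = 13)
  trio <- copy_species(sim$table, "SP1", "SP1b")
  cnt <- count_linked_groups(trio, c("SP1", "SP1b"))
  expect_identical(cnt$SP1b, paste0("SP1b_", cnt$SP1))
  # group sizes over the trio equal those of the underlying pair
  pair_cnt <- count_linked_groups(sim$table)
  trio_cnt <- count_linked_groups(trio)
  expect_equal(sort(trio_cnt$count), sort(pair_cnt$count))
})

test_that("truth evaluation scores recovered combinations correctly", {
  sim <- simulate_genomes(ancestral_genome(alg_sizes = rep(30, 3)),
                          evolution_params(), n_species = 4, seed = 15)
  fit <- linkage_fisher(sim$table)
  ev <- truth_evaluate(fit, sim)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$n_recovered, 3L)

  # a fully translocated species destroys recall for 4-way combinations
  sim2 <- simulate_genomes(ancestral_genome(alg_sizes = rep(30, 3)), list(
    SP1 = evolution_params(), SP2 = evolution_params(),
    SP3 = evolution_params(),
    SP4 = evolution_params(translocation_rate = 1)), seed = 16)
  fit2 <- linkage_fisher(sim2$table, min_count = 1)
  ev2 <- truth_evaluate(fit2, sim2)
  expect_equal(ev2$recall, 0)

  # empty recovery: precision undefined, recall 0
  fit3 <- fit
  fit3$tests$significant <- FALSE
  ev3 <- truth_evaluate(fit3, sim)
  expect_true(is.na(ev3$precision))
  expect_equal(ev3$recall, 0)
})

test_that("pipeline recall on planted 30-gene ALGs is high at low noise", {
  # regression bound on the whole simulate -> test -> evaluate loop
  recalls <- vapply(1:8, function(s) {
    sim <- simulate_genomes(ancestral_genome(alg_sizes = rep(30, 3)),
                            evolution_params(translocation_rate = 0.05),
                            n_species = 4, seed = s)
    truth_evaluate(linkage_fisher(sim$table), sim)$recall
  }, numeric(1))
  expect_gte(mean(recalls), 0.9)
})
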