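# Independent oracle: P(X >= k) for a hypergeometric overlap by exhaustive
# enumeration of all C(N, K_out) draws of the outgroup-chromosome gene set.
enum_tail <- function(k, K_in, K_out, N) {
  if (k <= 0) return(1)
  if (K_out == 0 || K_in == 0) return(if (k > 0) 0 + (k <= 0) else 1)
  draws <- utils::combn(N, K_out)
  hits <- colSums(draws <= K_in) # genes 1..K_in are the "successes"
  mean(hits >= k)
}

test_that("the worked-example contingency table reproduces its tail p-value", {
  ct <- contingency_table(k = 15, K_out = 182, K_in = 27, N = 1874)
  expect_equal(unname(ct$cells[1, ]), c(15, 167))
  expect_equal(unname(ct$cells[2, ]), c(12, 1680))
  expect_equal(sum(ct$cells), 1874)
  expect_equal(signif(hypergeom_tail(ct), 2), 2.3e-09)
})

test_that("contingency tables are counted from the table exactly", {
  tab <- toy_contingency_table()
  ct <- build_contingency(tab, c(A = "c1"), "d1")
  expect_equal(ct$k, 2); expect_equal(ct$K_out, 4)
  expect_equal(ct$K_in, 3); expect_equal(ct$N, 10)
  expect_equal(unname(ct$cells), matrix(c(2, 1, 2, 5), 2))

  # degenerate full overlap: combination covers all rows
  d <- data.frame(A_gene = paste0("a", 1:4), A_scaf = "c1", A_pos = 0:3,
                  B_gene = paste0("b", 1:4), B_scaf = "d1", B_pos = 0:3)
  full <- ortholog_table(d, c("A", "B"))
  ctf <- build_contingency(full, c(A = "c1"), "d1")
  expect_equal(unname(ctf$cells), matrix(c(4, 0, 0, 0), 2))
  expect_error(build_contingency(tab, c(A = "c1"), "d3"), "never observed")
  expect_error(contingency_table(k = 5, K_out = 4, K_in = 10, N = 20),
               "negative")
})

test_that("hypergeometric tail matches hand-enumerated and degenerate cases", {
  # exhaustive enumeration of C(10,5) draws gives exactly 1/2
  expect_equal(hypergeom_tail(contingency_table(k = 2, K_out = 5, K_in = 3,
                                                N = 10)), 0.5)
  expect_equal(enum_tail(2, 3, 5, 10), 0.5)
  # k = 0 covers the whole support
  expect_equal(hypergeom_tail(contingency_table(0, 5, 3, 10)), 1)
  # guarded degenerate marginals
  expect_equal(hypergeom_tail(contingency_table(0, 0, 3, 10)), 1)
  expect_equal(hypergeom_tail(contingency_table(0, 5, 0, 10)), 1)
})

test_that("tail probability is symmetric in margins and under transposition", {
  grid <- expand.grid(k = 1:4, K_in = 4:8, K_out = 4:8)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (g$k > min(g$K_in, g$K_out)) next
    N <- 30
    p1 <- hypergeom_tail(contingency_table(g$k, g$K_out, g$K_in, N))
    p2 <- hypergeom_tail(contingency_table(g$k, g$K_in, g$K_out, N))
    expect_equal(p1, p2)
    m <- matrix(c(g$k, g$K_in - g$k, g$K_out - g$k, N - g$K_in - g$K_out + g$k),
                2, 2)
    expect_equal(hypergeom_tail(m), hypergeom_tail(t(m)))
  }
})

test_that("tail probability agrees with exhaustive enumeration for small N", {
  for (N in c(5L, 8L, 11L)) {
    for (K_in in 0:N) for (K_out in seq(0L, N, by = 2L)) {
      k_min <- max(1L, K_in + K_out - N)
      k_max <- min(K_in, K_out)
      if (k_max < k_min) next
      for (k in k_min:k_max) {
        expect_equal(hypergeom_tail(contingency_table(k, K_out, K_in, N)),
                     enum_tail(k, K_in, K_out, N),
                     tolerance = 1e-12,
                     label = sprintf("N=%d K_in=%d K_out=%d k=%d",
                                     N, K_in, K_out, k))
      }
    }
  }
})

test_that("tail probability decreases as unrelated rows are added", {
  # fixed overlap on growing totals: the same shared count becomes more
  # surprising as the dataset grows
  k <- 5; K_in <- 10; K_out <- 12
  p <- vapply(seq(30, 300, by = 30), function(N)
    hypergeom_tail(contingency_table(k, K_out, K_in, N)), numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("BH adjustment matches the hand step-up computation", {
  res <- bh_correct(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_equal(res$q, rep(0.04, 4))
  expect_true(all(res$reject))
  res1 <- bh_correct(rep(1, 3))
  expect_equal(res1$q, rep(1, 3))
  expect_false(any(res1$reject))
  res2 <- bh_correct(0.05, alpha = 0.05)
  expect_equal(res2$q, 0.05)
  expect_true(res2$reject)
  expect_error(bh_correct(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH matches the textbook step-up definition on random vectors", {
  # independent oracle: sort, adjust by m/i, enforce monotonicity from the top
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    adj <- pmin(adj, 1)
    out <- numeric(m)
    out[o] <- adj
    out
  }
  set.seed(2024)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_correct(p)$q, bh_oracle(p))
  }
})

test_that("the flat family tests every observed combination once", {
  sim <- simulate_genomes(ancestral_genome(alg_sizes = rep(30, 3)),
                          evolution_params(translocation_rate = 0.03),
                          n_species = 4, seed = 5)
  fit <- linkage_fisher(sim$table)
  expect_false(anyDuplicated(paste(fit$tests$ingroup_id,
                                   fit$tests$outgroup_chrom)) > 0)
  cnt <- count_linked_groups(sim$table)
  expect_equal(fit$family_size, nrow(cnt))
  expect_equal(sum(fit$tests$k), nrow(sim$table$data))
  # planted combinations significant, background not
  ev <- truth_evaluate(fit, sim)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
})

test_that("a single-row table is degenerate but contract-clean", {
  d <- data.frame(A_gene = "a1", A_scaf = "c1", A_pos = 0L,
                  B_gene = "b1", B_scaf = "d1", B_pos = 0L)
  fit <- linkage_fisher(ortholog_table(d, c("A", "B")))
  expect_equal(nrow(fit$tests), 1L)
  expect_equal(fit$tests$p_raw, 1)
  expect_false(fit$tests$significant)
})

test_that("min_count shrinks the tested family monotonically", {
  sim <- simulate_genomes(ancestral_genome(alg_sizes = rep(25, 4)),
                          evolution_params(translocation_rate = 0.1),
                          n_species = 3, seed = 8)
  f1 <- linkage_fisher(sim$table, min_count = 1)
  f2 <- linkage_fisher(sim$table, min_count = 3)
  expect_lt(f2$family_size, f1$family_size)
  expect_true(all(f2$tests$k >= 3))
})
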