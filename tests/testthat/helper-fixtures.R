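# Fixtures are built in code: small hand-written tables with known structure.

# Two species, four rows, hand-checkable chromosome combinations:
# rows 1,2 on (c1, d1); row 3 on (c1, d2); row 4 on (c2, d2).
toy_pair_table <- function() {
  d <- data.frame(
    A_gene = paste0("a", 1:4),
    A_scaf = c("c1", "c1", "c1", "c2"),
    A_pos = c(0L, 1L, 2L, 0L),
    B_gene = paste0("b", 1:4),
    B_scaf = c("d1", "d1", "d2", "d2"),
    B_pos = c(0L, 1L, 0L, 1L),
    stringsAsFactors = FALSE)
  ortholog_table(d, c("A", "B"), outgroup = "B")
}

# 10-row two-species toy with known contingency counts for combination
# (c1, d1): k = 2, K_in = 3 (rows on c1), K_out = 4 (rows on d1).
toy_contingency_table <- function() {
  d <- data.frame(
    A_gene = paste0("a", 1:10),
    A_scaf = c("c1", "c1", "c1", "c2", "c2", "c2", "c3", "c3", "c3", "c3"),
    A_pos = c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L, 2L, 3L),
    B_gene = paste0("b", 1:10),
    B_scaf = c("d1", "d1", "d2", "d1", "d1", "d2", "d2", "d3", "d3", "d3"),
    B_pos = c(0L, 1L, 0L, 2L, 3L, 1L, 2L, 0L, 1L, 2L),
    stringsAsFactors = FALSE)
  ortholog_table(d, c("A", "B"), outgroup = "B")
}

# Write an rbh-dialect TSV fixture and return its path.
toy_rbh_file <- function(dir = tempdir()) {
  path <- file.path(dir, "toy.rbh")
  lines <- c(
    "COW_gene\tCOW_scaf\tCOW_pos\tHCA_gene\tHCA_scaf\tHCA_pos\tnote",
    "XP_1\tCOW1\t100\tH_1\tHCA2\t5\tfirst",
    "XP_2\tCOW1\t300\tH_2\tHCA2\t9\tsecond",
    "XP_3\tCOW3\t50\tH_3\tHCA7\t2\tthird")
  writeLines(lines, path)
  path
}

# A structured multi-chromosome pair used for shuffling tests: correlated
# A/B locations (8 chromosomes each) so real linkage structure exists.
structured_pair <- function(n_per_alg = 25, n_algs = 8, seed = 42) {
  sim <- simulate_genomes(
    ancestral_genome(alg_sizes = rep(n_per_alg, n_algs)),
    params = list(A = evolution_params(n_fusions = 2, mixing = 0.5,
                                       translocation_rate = 0.02),
                  C = evolution_params(n_fusions = 1,
                                       translocation_rate = 0.1)),
    outgroup = "C", seed = seed)
  sim$table
}

expect_table_equal <- function(a, b) {
  expect_identical(a$species, b$species)
  expect_identical(a$outgroup, b$outgroup)
  expect_equal(a$data, b$data, ignore_attr = TRUE)
}
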