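test_that("ancestor generation is deterministic and respects the config", {
  cfg <- sim_config(n_blocks = 7L, n_chromosomes = 7L, colour_count = 7L,
                    seed = 3L)
  a1 <- generate_ancestor(cfg)
  a2 <- generate_ancestor(cfg)
  expect_identical(a1, a2)
  expect_length(a1$genome$chromosomes, 7L)
  expect_true(all(lengths(a1$genome$chromosomes) == 1L))
  expect_equal(sort(unique(a1$colours)), 1:7)
  gc <- cfg$gene_count
  expect_true(all(a1$gene_counts >= gc$min & a1$gene_counts <= gc$max))
})

test_that("branch evolution applies the configured number of operations", {
  anc <- generate_ancestor(sim_config(n_blocks = 40L, n_chromosomes = 5L,
                                      seed = 4L))$genome
  ev0 <- evolve_genome(anc, list(n_ops = 0L,
                                 mix = c(reversal = 1, translocation = 0,
                                         fusion = 0, fission = 0),
                                 segment_mean = 2), seed = 1L)
  expect_identical(ev0$genome$chromosomes, anc$chromosomes)
  expect_equal(nrow(ev0$scenario), 0L)

  ev1 <- evolve_genome(anc, list(n_ops = 1L,
                                 mix = c(reversal = 1, translocation = 0,
                                         fusion = 0, fission = 0),
                                 segment_mean = 2), seed = 2L)
  expect_equal(dcj_distance(anc, ev1$genome), 1L)
  expect_equal(ev1$scenario$type, "reversal")

  set.seed(9)
  for (k in c(3L, 6L)) {
    ev <- evolve_genome(anc, list(n_ops = k,
                                  mix = c(reversal = .5, translocation = .3,
                                          fusion = .1, fission = .1),
                                  segment_mean = 2), seed = 20L + k)
    expect_lte(dcj_distance(anc, ev$genome), k)
    expect_identical(block_ids(ev$genome), block_ids(anc))
  }
})

test_that("pairwise emission merges exactly the conserved chained runs", {
  # identical leaves, tight gaps, no fragmentation: one block per chromosome
  counts <- setNames(rep(20, 12), 1:12)
  g <- block_genome(split(1:12, rep(1:3, each = 4)), "X")
  pl <- granulome:::genome_placement(g, counts, function(key) 0L)
  tab <- emit_pairwise_table(pl, pl, "ga", "gb", rep(1L, 12))
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$ga_genes == 80L))
  expect_true(all(tab$gb_strand == "+"))

  # a reversed interior segment becomes its own pairwise block
  g2 <- block_genome(list(c(1L, -3L, -2L, 4L), 5:8, 9:12), "Y")
  pl2 <- granulome:::genome_placement(g2, counts, function(key) 0L)
  tab2 <- emit_pairwise_table(pl, pl2, "ga", "gb", rep(1L, 12))
  run_sizes <- sort(tab2$ga_genes[tab2$ga_scaffold == "s001"])
  expect_equal(run_sizes, c(20, 20, 40))
  rev_run <- tab2[tab2$ga_genes == 40 & tab2$ga_scaffold == "s001", ]
  expect_equal(rev_run$gb_strand, "-")

  # gaps above the chaining threshold split runs even when conserved
  pl3 <- granulome:::genome_placement(g, counts, function(key) 100L)
  tab3 <- emit_pairwise_table(pl3, pl3, "ga", "gb", rep(1L, 12),
                              chain_gap = 20L)
  expect_equal(nrow(tab3), 12L)
})

test_that("gap model: ancestral junctions share one gap, novel junctions differ", {
  cfg <- sim_config(n_blocks = 30L, n_chromosomes = 3L, seed = 8L)
  anc <- generate_ancestor(cfg)
  expect_length(anc$junction_gaps, 27L)   # n - chromosomes junctions
  sim <- simulate_dataset(small_sim(8))
  # same seed gives byte-identical tables
  sim2 <- simulate_dataset(small_sim(8))
  expect_identical(sim$tables, sim2$tables)
  expect_identical(sim$truth$pairwise, sim2$truth$pairwise)
})

test_that("erosion lowers per-genome gene counts but never below one", {
  sim <- simulate_dataset(small_sim(13))
  for (g in names(sim$truth$eroded_counts)) {
    er <- sim$truth$eroded_counts[[g]]
    expect_true(all(er >= 1))
    expect_true(all(er <= sim$truth$gene_counts))
  }
  sim0 <- simulate_dataset(small_sim(13, erosion_rate = 0))
  expect_true(all(sim0$truth$eroded_counts$pivot ==
                  pmax(1, sim0$truth$gene_counts)))
})

test_that("noise relocations and scenarios are recorded in the truth", {
  sim <- simulate_dataset(small_sim(21))
  sc <- sim$truth$scenarios$pivot
  expect_equal(sum(sc$type == "noise_relocation"), 4L)
  expect_true(all(sc$type %in% c("reversal", "translocation", "fusion",
                                 "fission", "noise_relocation", "skipped")))
  # leaves keep the full block content
  for (l in sim$truth$leaves)
    expect_identical(block_ids(l), block_ids(sim$truth$ancestor))
})

test_that("random genomes have the requested shape", {
  set.seed(2)
  g <- random_genome(50, 5)
  expect_length(g$chromosomes, 5L)
  expect_equal(block_ids(g), 1:50)
})
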