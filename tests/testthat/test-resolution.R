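test_that("apply_level deletes exactly the blocks below the threshold", {
  t <- three_block_table(genes = c(5L, 15L))
  l0 <- apply_level(t, 0L)
  expect_equal(nrow(l0$retained), 2L)
  expect_equal(nrow(l0$deleted), 0L)
  l10 <- apply_level(t, 10L)
  expect_equal(l10$retained$block_id, 2L)
  expect_equal(l10$deleted$block_id, 1L)
  l99 <- apply_level(t, 99L)
  expect_equal(nrow(l99$retained), 0L)
  expect_error(apply_level(t, -1L), "non-negative")
})

test_that("block size for the level filter is the worst genome's count", {
  t <- three_block_table()
  t$g2_genes[1] <- 3L
  l <- apply_level(t, 10L)          # min over genomes = 3 -> deleted
  expect_equal(l$deleted$block_id, 1L)
  l2 <- apply_level(t, 10L, size_method = "max")
  expect_equal(nrow(l2$deleted), 0L)
})

test_that("neighbours merge only when close on all three genomes", {
  m <- merge_neighbours(three_block_table(gaps = c(100L, 100L, 100L)))
  expect_equal(nrow(m), 1L)
  expect_equal(m$g1_genes, 70L)     # gene counts add
  expect_true(m$polarity_determinate)
  expect_equal(m$g1_start, 1L)
  expect_equal(m$g1_end, 186L)

  m2 <- merge_neighbours(three_block_table(gaps = c(100L, 100L, 300L)))
  expect_equal(nrow(m2), 2L)
  refused <- attr(m2, "refused")
  expect_equal(refused$genome, "g3")
  expect_equal(refused$gap, 300L)

  m3 <- merge_neighbours(three_block_table(colours = c(1L, 2L)))
  expect_equal(nrow(m3), 2L)        # same-colour rule
  m4 <- merge_neighbours(three_block_table(colours = c(1L, 2L)),
                         colour_rule = FALSE)
  expect_equal(nrow(m4), 1L)
})

test_that("order-inconsistent pairs never merge; polarity conflicts merge indeterminately", {
  # (+a,+b) in two genomes but (+b,+a) in the third: not adjacent-consistent
  m <- merge_neighbours(three_block_table(order3 = c(2L, 1L)))
  expect_equal(nrow(m), 2L)
  # (+a,+b) vs (+a,-b): merged, polarity indeterminate in g3
  m2 <- merge_neighbours(three_block_table(strand3 = c("+", "-")))
  expect_equal(nrow(m2), 1L)
  expect_false(m2$polarity_determinate)
  ind <- attr(m2, "indeterminate")
  expect_equal(ind$genome, "g3")
  # reversed whole occurrence (-b,-a) is consistent: merged, determinate
  m3 <- merge_neighbours(three_block_table(order3 = c(2L, 1L),
                                           strand3 = c("-", "-")))
  expect_equal(nrow(m3), 1L)
  expect_true(m3$polarity_determinate)
  expect_equal(m3$g3_strand, "-")
})

test_that("merging only coarsens the genomes, never reorders them", {
  set.seed(31)
  sim <- simulate_dataset(small_sim(31))
  tw <- build_three_way(sim$tables$ab, sim$tables$bc, sim$tables$ca, "pivot")
  al <- apply_level(tw, 20L)
  merged <- merge_neighbours(al$retained, al$deleted)
  for (g in genomes_of_table(tw)) {
    before <- genome_from_table(al$retained, g)
    after <- genome_from_table(merged, g)
    # distances are invariant under contraction of the merged neighbours
    expect_lte(n_blocks(after), n_blocks(before))
  }
  # contraction never increases a pairwise distance; indeterminate mergers
  # absorb single-block polarity conflicts, so distances may drop
  gb <- lapply(genomes_of_table(tw), function(g) genome_from_table(al$retained, g))
  ga <- lapply(genomes_of_table(tw), function(g) genome_from_table(merged, g))
  expect_lte(dcj_distance(ga[[1]], ga[[2]]), dcj_distance(gb[[1]], gb[[2]]))
  expect_lte(dcj_distance(ga[[1]], ga[[3]]), dcj_distance(gb[[1]], gb[[3]]))
})

test_that("determinate-only mergers preserve every pairwise distance", {
  # all three genomes agree on order and orientation: contraction is exact
  t <- three_block_table(gaps = c(10L, 10L, 10L))
  m <- merge_neighbours(t)
  expect_equal(nrow(m), 1L)
  pre <- lapply(c("g1", "g2", "g3"), function(g) genome_from_table(t, g))
  post <- lapply(c("g1", "g2", "g3"), function(g) genome_from_table(m, g))
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(dcj_distance(post[[i]], post[[j]]),
                 dcj_distance(pre[[i]], pre[[j]]))
})

test_that("sweep conserves gene content and is monotone in L", {
  sim <- simulate_dataset(small_sim(12))
  tw <- build_three_way(sim$tables$ab, sim$tables$bc, sim$tables$ca, "pivot")
  sw <- sweep_resolution(tw, resolution_schedule(levels = c(0L, 20L, 40L, 70L)))
  rep <- sw$report
  expect_equal(rep$blocks_deleted[1], 0L)   # level 0 excludes nothing
  expect_true(all(rep$genes_not_included + rep$genes_remaining ==
                  sw$total_genes))
  expect_true(all(diff(rep$blocks_remaining) <= 0))
  expect_true(all(diff(rep$genes_remaining) <= 0))
  expect_true(all(rep$blocks_after_mergers <= rep$blocks_remaining))
  expect_equal(rep$genes_remaining[1], sw$total_genes)
})

test_that("polarity local search finds the exhaustive optimum", {
  base <- list(c(1L, 2L, 3L, 4L), c(5L, 6L))
  A <- block_genome(base, "A")
  B <- block_genome(base, "B")
  flip <- function(g, b) {
    g$chromosomes <- lapply(g$chromosomes, function(ch) {
      ch[abs(ch) == b] <- -ch[abs(ch) == b]; ch
    })
    g
  }
  # k = 0: nothing to do, exactly one objective evaluation
  evals <- 0L
  obj <- function(gs) {
    evals <<- evals + 1L
    dcj_median(gs[[1]], gs[[2]], gs[[3]])$total_score
  }
  r0 <- resolve_polarity(list(A = A, B = B, C = A),
                         data.frame(block_id = integer(0),
                                    genome = character(0)), objective = obj)
  expect_equal(evals, 1L)
  expect_equal(r0$score, 0)

  # k = 1: flipping block 2 in C makes the genomes identical
  C1 <- flip(A, 2L); C1$name <- "C"
  r1 <- resolve_polarity(list(A = A, B = B, C = C1),
                         data.frame(block_id = 2L, genome = "C"))
  expect_equal(r1$score, 0)
  expect_equal(r1$flips, 1L)

  # k = 2: local search matches brute force over all four assignments
  C2 <- flip(flip(A, 2L), 5L); C2$name <- "C"
  ind <- data.frame(block_id = c(2L, 5L), genome = "C")
  brute <- Inf
  for (f2 in c(FALSE, TRUE)) for (f5 in c(FALSE, TRUE)) {
    g <- C2
    if (f2) g <- flip(g, 2L)
    if (f5) g <- flip(g, 5L)
    brute <- min(brute, dcj_median(A, B, g)$total_score)
  }
  r2 <- resolve_polarity(list(A = A, B = B, C = C2), ind)
  expect_equal(r2$score, brute)
})
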