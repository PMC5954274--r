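test_that("DCJ distance matches the textbook examples", {
  A <- block_genome(list(1:3), "A")
  expect_equal(dcj_distance(A, A), 0L)
  expect_equal(dcj_distance(A, block_genome(list(c(1L, -2L, 3L)))), 1L)
  # chromosome order and orientation are free
  expect_equal(dcj_distance(block_genome(list(1:2, 3:4)),
                            block_genome(list(c(-4L, -3L), 1:2))), 0L)
  expect_error(dcj_distance(A, block_genome(list(1:2))), "block content")
})

test_that("DCJ distance equals BFS over single operations (3 blocks, exhaustive)", {
  n <- 3L
  Bs <- o_all_linear_genomes(n)
  for (As in o_canonical_structures(n)) {
    bfs <- o_bfs_distances(n, As)
    gA <- block_genome(As)
    for (Bc in Bs)
      expect_equal(dcj_distance(gA, block_genome(Bc)),
                   o_lookup_distance(bfs, Bc, n))
  }
})

test_that("breakpoint distance counts lost adjacencies, telomeres at half", {
  A <- block_genome(list(1:3), "A")
  expect_equal(breakpoint_distance(A, A), 0)
  # both interior adjacencies of (1 2 3) are absent from (1 -2 3)
  expect_equal(breakpoint_distance(A, block_genome(list(c(1L, -2L, 3L)))), 2)
  # independent set-difference oracle on random pairs
  set.seed(61)
  adj_set <- function(g) {
    keys <- character(0); tels <- character(0)
    for (chr in g$chromosomes) {
      b <- abs(chr)
      left <- ifelse(chr > 0, paste0(b, "t"), paste0(b, "h"))
      right <- ifelse(chr > 0, paste0(b, "h"), paste0(b, "t"))
      if (length(chr) > 1)
        keys <- c(keys, paste(pmin(right[-length(chr)], left[-1]),
                              pmax(right[-length(chr)], left[-1])))
      tels <- c(tels, left[1], right[length(chr)])
    }
    list(adj = keys, tel = tels)
  }
  for (i in 1:25) {
    A <- o_random_genome(8, sample(1:3, 1), "A")
    B <- o_random_genome(8, sample(1:3, 1), "B")
    sa <- adj_set(A); sb <- adj_set(B)
    oracle <- n_blocks(A) - length(intersect(sa$adj, sb$adj)) -
      length(intersect(sa$tel, sb$tel)) / 2
    expect_equal(breakpoint_distance(A, B), oracle)
  }
})

test_that("DCJ distance is a metric and bounded by breakpoints", {
  set.seed(62)
  for (i in 1:20) {
    A <- o_random_genome(10, sample(1:3, 1), "A")
    B <- o_random_genome(10, sample(1:3, 1), "B")
    C <- o_random_genome(10, sample(1:3, 1), "C")
    dab <- dcj_distance(A, B); dba <- dcj_distance(B, A)
    expect_identical(dab, dba)
    expect_lte(dcj_distance(A, C), dab + dcj_distance(B, C))
    b <- breakpoint_distance(A, B)
    expect_gte(b, dab)
    expect_lte(b, 2 * dab)
  }
})

test_that("reuse rate spans [1,2] and errors on identical genomes", {
  A <- block_genome(list(1:3), "A")
  expect_error(reuse_rate(A, A), "identical")
  expect_equal(reuse_rate(A, block_genome(list(c(1L, -2L, 3L)))), 1)
  set.seed(63)
  for (i in 1:30) {
    A <- o_random_genome(12, 2, "A")
    B <- o_random_genome(12, 2, "B")
    r <- reuse_rate(A, B)
    expect_gte(r, 1); expect_lte(r, 2)
  }
})

test_that("sorting scenarios have length d and valid classified steps", {
  A <- block_genome(list(1:3), "A")
  expect_equal(nrow(sort_scenario(A, A)), 0L)
  B <- block_genome(list(c(1L, -2L, 3L)), "B")
  for (pr in c("translocations", "reversals")) {
    sc <- sort_scenario(A, B, pr)
    expect_equal(nrow(sc), 1L)
    expect_equal(sc$type, "reversal")
  }
  # a pure tail exchange is one translocation
  D <- block_genome(list(1:2, 3:5), "D")
  E <- block_genome(list(c(1L, 4L, 5L), c(3L, 2L)), "E")
  expect_equal(sort_scenario(D, E)$type, "translocation")
  # fusion and fission
  expect_equal(sort_scenario(block_genome(list(1:2, 3:4)),
                             block_genome(list(1:4)))$type, "fusion")
  expect_equal(sort_scenario(block_genome(list(1:4)),
                             block_genome(list(1:2, 3:4)))$type, "fission")
})

test_that("both priority modes sort optimally; every prefix reduces distance", {
  set.seed(64)
  for (i in 1:10) {
    A <- o_random_genome(8, 2, "A")
    B <- o_random_genome(8, 2, "B")
    d <- dcj_distance(A, B)
    for (pr in c("translocations", "reversals")) {
      sc <- sort_scenario(A, B, pr)
      expect_equal(nrow(sc), d)
      expect_equal(attr(sc, "distance"), d)
    }
  }
})

test_that("priority modes bracket the greedy translocation counts", {
  set.seed(65)
  for (i in 1:15) {
    A <- o_random_genome(9, 3, "A")
    B <- o_random_genome(9, 3, "B")
    ct <- scenario_counts(sort_scenario(A, B, "translocations"))
    cr <- scenario_counts(sort_scenario(A, B, "reversals"))
    expect_gte(ct[["translocation"]], cr[["translocation"]])
    expect_gte(cr[["reversal"]], ct[["reversal"]])
  }
})

test_that("normalized totals divide by the block count", {
  expect_equal(normalized_total(0, 100), 0)
  expect_equal(normalized_total(50, 200), 0.25)
  expect_error(normalized_total(5, 0), "positive")
})
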