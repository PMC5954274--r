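brute_median_score <- function(A, B, C, candidates) {
  best <- Inf
  for (mc in candidates) {
    m <- block_genome(mc)
    s <- dcj_distance(m, A) + dcj_distance(m, B) + dcj_distance(m, C)
    if (s < best) best <- s
  }
  best
}

test_that("degenerate median cases are exact", {
  A <- o_random_genome(6, 2, "A")
  C <- o_random_genome(6, 2, "C")
  r <- dcj_median(A, A, A, enumerate_all = TRUE)
  expect_equal(r$total_score, 0L)
  expect_true(same_genome(r$medians[[1]], A))
  r2 <- dcj_median(A, A, C)
  expect_equal(r2$total_score, dcj_distance(A, C))
  expect_error(dcj_median(A, A, o_random_genome(5, 1, "X")), "block content")
})

test_that("median score equals exhaustive minimization on 4 blocks", {
  set.seed(71)
  cands <- o_all_linear_genomes(4)
  for (i in 1:40) {
    A <- o_random_genome(4, sample(1:2, 1), "A")
    B <- o_random_genome(4, sample(1:2, 1), "B")
    C <- o_random_genome(4, sample(1:2, 1), "C")
    bf <- brute_median_score(A, B, C, cands)
    for (rd in c("shared", "none")) {
      r <- dcj_median(A, B, C, reduce = rd)
      expect_equal(r$total_score, bf)
      expect_gte(r$total_score, r$lower_bound)
    }
  }
})

test_that("lower-bound sandwich holds on random instances", {
  set.seed(72)
  for (i in 1:10) {
    A <- o_random_genome(6, 2, "A")
    B <- o_random_genome(6, 2, "B")
    C <- o_random_genome(6, 2, "C")
    r <- dcj_median(A, B, C)
    lb <- ceiling((dcj_distance(A, B) + dcj_distance(A, C) +
                   dcj_distance(B, C)) / 2)
    ub <- min(dcj_distance(A, B) + dcj_distance(A, C),
              dcj_distance(A, B) + dcj_distance(B, C),
              dcj_distance(A, C) + dcj_distance(B, C))
    expect_gte(r$total_score, lb)
    expect_lte(r$total_score, ub)
    expect_equal(sum(r$distances), r$total_score)
  }
})

test_that("every enumerated median achieves the optimal score", {
  set.seed(73)
  A <- o_random_genome(5, 2, "A")
  B <- o_random_genome(5, 1, "B")
  C <- o_random_genome(5, 2, "C")
  r <- dcj_median(A, B, C, enumerate_all = TRUE, reduce = "none")
  prof <- median_distance_profile(r, A, B, C)
  expect_equal(nrow(prof), r$n_medians)
  expect_true(all(rowSums(prof) == r$total_score))
  expect_length(attr(prof, "means"), 3)
  # medians are distinct in canonical form
  keys <- vapply(r$medians, function(m)
    paste(vapply(m$chromosomes, paste, "", collapse = " "), collapse = "|"),
    "")
  expect_false(anyDuplicated(keys) > 0)
})

test_that("true ancestor is recovered for small divergence", {
  set.seed(74)
  hits <- 0L
  for (i in 1:10) {
    anc <- generate_ancestor(sim_config(n_blocks = 30L, n_chromosomes = 4L,
                                        seed = 74L + i))
    leaves <- lapply(1:3, function(k)
      evolve_genome(anc$genome,
                    list(n_ops = 2L,
                         mix = c(reversal = .5, translocation = .5,
                                 fusion = 0, fission = 0),
                         segment_mean = 2), seed = 740L + 10L * i + k,
                    name = paste0("L", k))$genome)
    r <- dcj_median(leaves[[1]], leaves[[2]], leaves[[3]],
                    enumerate_all = TRUE)
    anc_sum <- sum(vapply(leaves, function(l)
      dcj_distance(anc$genome, l), numeric(1)))
    expect_gte(anc_sum, r$total_score)
    if (any(vapply(r$medians, same_genome, logical(1), b = anc$genome)))
      hits <- hits + 1L
  }
  # with two operations per branch the ancestor is usually an exact median
  expect_gte(hits, 5L)
})

test_that("breakpoint median maximizes the matching weight exactly", {
  set.seed(75)
  for (i in 1:12) {
    A <- o_random_genome(5, sample(1:2, 1), "A")
    B <- o_random_genome(5, sample(1:2, 1), "B")
    C <- o_random_genome(5, 1, "C")
    m <- suppressMessages(breakpoint_median(A, B, C))
    # brute-force matching oracle over candidate adjacencies
    ids <- sort(unique(abs(unlist(A$chromosomes))))
    expect_equal(attr(m, "matching_weight"),
                 o_bp_matching_weight(A, B, C),
                 tolerance = 1e-9)
  }
  A <- o_random_genome(6, 2, "A")
  expect_true(same_genome(breakpoint_median(A, A, A), A))
})

test_that("weight-dominant input is returned as breakpoint median", {
  A <- o_random_genome(7, 2, "A")
  C <- o_random_genome(7, 2, "C")
  m <- suppressMessages(breakpoint_median(A, A, C))
  # every A-adjacency has weight >= 2, beating any C-only alternative
  expect_equal(breakpoint_distance(m, A), 0)
})
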