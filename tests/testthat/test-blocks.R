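# pairwise tables for the three-way construction tests: pivot "rh" with
# counterparts "co" (table ab) and "gr" (table bc)

test_that("informative-scaffold filter keeps only rearrangement signal", {
  # s1: two blocks conserved (adjacent, same orientation) in the other
  # genome -> dropped; s2: single block -> dropped; s3: pair split across
  # two chromosomes of the other genome -> retained
  t <- make_table(list(
    rh = list(c("s1", 1, 10, "+", 10), c("s1", 11, 20, "+", 10),
              c("s2", 1, 10, "+", 10),
              c("s3", 1, 10, "+", 10), c("s3", 11, 20, "+", 10)),
    co = list(c("c1", 1, 10, "+", 10), c("c1", 11, 20, "+", 10),
              c("c1", 21, 30, "+", 10),
              c("c2", 1, 10, "+", 10), c("c3", 1, 10, "+", 10))))
  out <- filter_informative_scaffolds(t, "rh")
  expect_equal(attr(out, "scaffolds_kept"), "s3")
  expect_equal(sort(out$block_id), c(4L, 5L))
  expect_error(filter_informative_scaffolds(t, "zz"), "not placed")
})

test_that("adjacency with inconsistent orientation counts as broken", {
  # pair adjacent in both genomes, but the second block is inverted in the
  # counterpart: the extremity adjacency differs -> scaffold retained
  t <- make_table(list(
    rh = list(c("s1", 1, 10, "+", 10), c("s1", 11, 20, "+", 10)),
    co = list(c("c1", 1, 10, "+", 10), c("c1", 11, 20, "-", 10))))
  out <- filter_informative_scaffolds(t, "rh")
  expect_equal(attr(out, "scaffolds_kept"), "s1")
})

test_that("coincident pairwise blocks give one three-way block", {
  ab <- make_table(list(rh = list(c("s1", 1, 100, "+", 90)),
                        co = list(c("c1", 1, 100, "+", 85))))
  bc <- make_table(list(rh = list(c("s1", 1, 100, "+", 90)),
                        gr = list(c("g1", 201, 300, "-", 80))))
  tw <- build_three_way(ab, bc, pivot_genome = "rh")
  expect_equal(nrow(tw), 1L)
  expect_equal(tw$rh_start, 1L)
  expect_equal(tw$rh_end, 100L)
  expect_equal(tw$gr_strand, "-")
  expect_setequal(genomes_of_table(tw), c("rh", "co", "gr"))
})

test_that("partial overlaps split at interior boundaries, counterparts map linearly", {
  ab <- make_table(list(rh = list(c("s1", 1, 100, "+", 100)),
                        co = list(c("c1", 1, 100, "+", 100))))
  bc <- make_table(list(rh = list(c("s1", 1, 40, "+", 40),
                                  c("s1", 61, 100, "+", 40)),
                        gr = list(c("g1", 1, 40, "+", 40),
                                  c("g1", 61, 100, "+", 40))),
                   ids = 1:2)
  tw <- build_three_way(ab, bc, pivot_genome = "rh")
  expect_equal(nrow(tw), 2L)
  expect_equal(tw$rh_start, c(1L, 61L))
  expect_equal(tw$rh_end, c(40L, 100L))
  # the other counterpart interval is split at the same boundaries
  expect_equal(tw$co_start, c(1L, 61L))
  expect_equal(tw$co_end, c(40L, 100L))
  # pivot intervals are disjoint and inside both parents
  expect_true(all(tw$rh_end[-nrow(tw)] < tw$rh_start[-1]))
})

test_that("disjoint pivot intervals and colour conflicts yield no record", {
  ab <- make_table(list(rh = list(c("s1", 1, 40, "+", 40)),
                        co = list(c("c1", 1, 40, "+", 40))))
  bc <- make_table(list(rh = list(c("s1", 50, 90, "+", 40)),
                        gr = list(c("g1", 1, 40, "+", 40))))
  expect_equal(nrow(build_three_way(ab, bc, pivot_genome = "rh")), 0L)

  bc2 <- make_table(list(rh = list(c("s1", 1, 40, "+", 40)),
                         gr = list(c("g1", 1, 40, "+", 40))),
                    colours = 2L)
  expect_message(tw <- build_three_way(ab, bc2, pivot_genome = "rh"),
                 "conflicting colours")
  expect_equal(nrow(tw), 0L)
})

test_that("negative-strand counterparts map trims from the far end", {
  ab <- make_table(list(rh = list(c("s1", 1, 100, "+", 100)),
                        co = list(c("c1", 1, 100, "-", 100))))
  bc <- make_table(list(rh = list(c("s1", 1, 40, "+", 40)),
                        gr = list(c("g1", 1, 40, "+", 40))))
  tw <- build_three_way(ab, bc, pivot_genome = "rh")
  # keeping pivot genes 1-40 of a reversed counterpart keeps its genes 61-100
  expect_equal(tw$co_start, 61L)
  expect_equal(tw$co_end, 100L)
})

test_that("three-way construction recovers true pairwise distances", {
  # splitting/merging of blocks never crosses a breakpoint shared by all
  # genomes, so the extracted genomes preserve all pairwise DCJ distances
  for (s in c(2, 9)) {
    sim <- simulate_dataset(small_sim(s, pivot_scaffolds = 0L))
    tw <- build_three_way(sim$tables$ab, sim$tables$bc, sim$tables$ca,
                          pivot_genome = "pivot")
    gs <- lapply(c("pivot", "sister", "outgroup"),
                 function(g) genome_from_table(tw, g))
    got <- c(dcj_distance(gs[[1]], gs[[2]]), dcj_distance(gs[[1]], gs[[3]]),
             dcj_distance(gs[[2]], gs[[3]]))
    expect_equal(got, unname(sim$truth$pairwise))
  }
})
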