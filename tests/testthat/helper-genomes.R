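# fixture builders shared across test files

# a minimal three-genome block table; per-genome placements given as
# list(genome = list(c(scaffold, start, end, strand, genes), ...))
make_table <- function(placements, colours = NULL, ids = NULL) {
  n <- length(placements[[1]])
  ids <- ids %||% seq_len(n)
  df <- data.frame(block_id = ids,
                   colour = colours %||% rep(1L, n),
                   polarity_determinate = TRUE,
                   stringsAsFactors = FALSE)
  for (g in names(placements)) {
    p <- placements[[g]]
    df[[paste0(g, "_scaffold")]] <- vapply(p, function(x) as.character(x[1]), "")
    df[[paste0(g, "_start")]] <- vapply(p, function(x) as.integer(x[2]), 0L)
    df[[paste0(g, "_end")]] <- vapply(p, function(x) as.integer(x[3]), 0L)
    df[[paste0(g, "_strand")]] <- vapply(p, function(x) as.character(x[4]), "")
    df[[paste0(g, "_genes")]] <- vapply(p, function(x) as.integer(x[5]), 0L)
  }
  block_table(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a two-block, three-genome table with configurable per-genome gap, order,
# strands and colours of the pair on genome g3 (one scaffold per genome)
three_block_table <- function(strand3 = c("+", "+"), order3 = c(1L, 2L),
                              gaps = c(100L, 100L, 100L), colours = c(1L, 1L),
                              genes = c(30L, 40L)) {
  sp <- function(gap, ord, strands) {
    gap <- as.integer(gap)
    s1 <- c(1L, 41L + gap)        # separation is exactly `gap` genes
    e1 <- c(40L, 41L + gap + 45L)
    pos <- match(1:2, ord)   # physical position of block 1 and block 2
    list(c("s1", s1[pos[1]], e1[pos[1]], strands[1], genes[1]),
         c("s1", s1[pos[2]], e1[pos[2]], strands[2], genes[2]))
  }
  placements <- list(g1 = sp(gaps[1], c(1L, 2L), c("+", "+")),
                     g2 = sp(gaps[2], c(1L, 2L), c("+", "+")),
                     g3 = sp(gaps[3], order3, strand3))
  make_table(placements, colours = colours)
}

# small simulation config that keeps every stage fast in tests
small_sim <- function(seed, pivot_scaffolds = 12L, ...) {
  sim_config(n_blocks = 60L, n_chromosomes = 8L, seed = seed,
             branches = list(
               pivot = list(n_ops = 8L,
                            mix = c(reversal = 0.35, translocation = 0.55,
                                    fusion = 0.05, fission = 0.05),
                            segment_mean = 2, noise = 4L),
               sister = list(n_ops = 2L,
                             mix = c(reversal = 0.65, translocation = 0.10,
                                     fusion = 0.25, fission = 0),
                             segment_mean = 3, noise = 0L),
               outgroup = list(n_ops = 4L,
                               mix = c(reversal = 0.60, translocation = 0.20,
                                       fusion = 0.10, fission = 0.10),
                               segment_mean = 3, noise = 1L)),
             pivot_scaffolds = pivot_scaffolds, ...)
}
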