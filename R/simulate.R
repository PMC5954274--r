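#' Simulation configuration
#'
#' Study conditions for the synthetic data generator: a coloured ancestor in
#' the post-triplication regime (21 chromosomes, one colour each), three
#' descendant genomes produced by genome-specific rearrangement regimes, a
#' lognormal block gene-count distribution, fractionation-style erosion of
#' gene counts, and scaffold-level fragmentation of the pivot genome.
#'
#' The default branch regimes encode the qualitative asymmetry the analysis
#' is designed to expose: the `pivot` leaf is fast-evolving and
#' translocation-rich with fine-scale (short-segment) operations, the
#' `sister` leaf is conservative with mostly reversals and a few fusions,
#' and the `outgroup` branch is intermediate.
#'
#' @param n_blocks number of ancestral synteny blocks (default 204).
#' @param n_chromosomes ancestral chromosome count (default 21).
#' @param colour_count number of colour labels (default 21).
#' @param genome_names names of the three leaves (pivot first).
#' @param branches named list (one per leaf) of lists with `n_ops`, `mix`
#'   (probabilities for reversal/translocation/fusion/fission),
#'   `segment_mean` (mean rearranged-segment length in blocks) and `noise`
#'   (number of small blocks spuriously relocated in that leaf, emulating
#'   ortholog/out-paralog misassignment and assembly noise; such blocks
#'   inflate apparent distance at full resolution and drop out of the
#'   analysis once the level exceeds their gene count).
#' @param gene_count list with `min`, `median`, `max` for the per-block gene
#'   counts (lognormal around the median, clamped).
#' @param gap list with `median` and `sdlog` for the unaligned gene runs
#'   separating neighbouring blocks (lognormal).  Junctions inherited from
#'   the ancestor keep one shared gap size in every genome; junctions
#'   created by rearrangement get fresh per-genome draws.
#' @param chain_gap maximum inter-block gap (genes) the emulated aligner
#'   bridges when chaining neighbouring blocks into one maximal pairwise
#'   block (default 20, the DAGChainer-like default regime).
#' @param erosion_rate Poisson mean of genes lost per block end per genome
#'   (fractionation; default 2).
#' @param pivot_scaffolds target scaffold count for the fragmented pivot
#'   assembly (default 30).
#' @param seed mandatory global seed; all stage seeds fan out from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_blocks = 204L, n_chromosomes = 21L,
                       colour_count = 21L,
                       genome_names = c("pivot", "sister", "outgroup"),
                       branches = NULL,
                       gene_count = list(min = 5L, median = 60L, max = 600L),
                       gap = list(median = 30, sdlog = 1.2),
                       chain_gap = 20L,
                       erosion_rate = 2, pivot_scaffolds = 30L, seed = 1L) {
  if (is.null(branches))
    branches <- list(
      pivot = list(n_ops = 24L,
                   mix = c(reversal = 0.35, translocation = 0.55,
                           fusion = 0.05, fission = 0.05),
                   segment_mean = 2, noise = 12L),
      sister = list(n_ops = 6L,
                    mix = c(reversal = 0.65, translocation = 0.10,
                            fusion = 0.25, fission = 0),
                    segment_mean = 3, noise = 1L),
      outgroup = list(n_ops = 12L,
                      mix = c(reversal = 0.60, translocation = 0.20,
                              fusion = 0.10, fission = 0.10),
                      segment_mean = 3, noise = 3L))
  names(branches) <- genome_names
  for (b in branches) {
    if (abs(sum(b$mix) - 1) > 1e-9)
      stop("branch operation mix must sum to 1")
  }
  if (n_blocks < n_chromosomes) stop("need n_blocks >= n_chromosomes")
  if (is.null(seed)) stop("seed is mandatory")
  structure(list(n_blocks = as.integer(n_blocks),
                 n_chromosomes = as.integer(n_chromosomes),
                 colour_count = as.integer(colour_count),
                 genome_names = genome_names, branches = branches,
                 gene_count = gene_count, gap = gap,
                 chain_gap = as.integer(chain_gap),
                 erosion_rate = erosion_rate,
                 pivot_scaffolds = as.integer(pivot_scaffolds),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# one global seed fans out to fixed per-stage seeds
fan_out_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate the coloured ancestor genome
#'
#' Blocks `1..n` are laid contiguously on the chromosomes (balanced sizes);
#' the colour of a block is the chromosome it originates from (mapped into
#' `1..colour_count`); gene counts are drawn from the configured lognormal
#' distribution.  Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `genome` (a [block_genome] named "ancestor"), `colours`
#'   (integer per block) and `gene_counts` (numeric per block, named by
#'   block id).
#' @export
generate_ancestor <- function(cfg) {
  set.seed(fan_out_seeds(cfg$seed, 10L)[1])
  n <- cfg$n_blocks
  k <- cfg$n_chromosomes
  bounds <- round(seq(0, n, length.out = k + 1L))
  chromosomes <- lapply(seq_len(k), function(i) (bounds[i] + 1L):bounds[i + 1L])
  colours <- integer(n)
  for (i in seq_len(k))
    colours[chromosomes[[i]]] <- ((i - 1L) %% cfg$colour_count) + 1L
  gc <- cfg$gene_count
  sdlog <- log(gc$max / gc$median) / 3
  counts <- round(stats::rlnorm(n, meanlog = log(gc$median), sdlog = sdlog))
  counts <- pmin(pmax(counts, gc$min), gc$max)
  names(counts) <- as.character(seq_len(n))
  genome <- block_genome(chromosomes, name = "ancestor")
  # one shared unaligned-gap size per ancestral junction
  keys <- adjacency_keys(genome)
  gaps <- round(stats::rlnorm(length(keys), log(cfg$gap$median),
                              cfg$gap$sdlog))
  names(gaps) <- keys
  list(genome = genome, colours = colours, gene_counts = counts,
       junction_gaps = gaps)
}

#' Evolve a genome along one branch
#'
#' Applies `n_ops` operations drawn from the branch's type mix: reversals of
#' a random within-chromosome segment (geometric length, mean
#' `segment_mean` blocks), reciprocal translocations exchanging terminal
#' segments of two chromosomes, fusions and fissions.  Operations that are
#' impossible in the current state (e.g. a translocation with one
#' chromosome) or degenerate (whole-chromosome reversal) are resampled and
#' logged in the scenario.  No circular chromosomes are ever produced.
#'
#' @param genome starting [block_genome].
#' @param branch_cfg list with `n_ops`, `mix`, `segment_mean`.
#' @param seed RNG seed for this branch.
#' @param name name for the resulting genome.
#' @return list with `genome` and `scenario` (data.frame of realized
#'   operations).
#' @export
evolve_genome <- function(genome, branch_cfg, seed, name = genome$name) {
  set.seed(seed)
  chrs <- genome$chromosomes
  p_seg <- 1 / branch_cfg$segment_mean
  scen <- list()
  types <- names(branch_cfg$mix)
  for (k in seq_len(branch_cfg$n_ops)) {
    done <- FALSE
    for (try in 1:40) {
      type <- sample(types, 1L, prob = branch_cfg$mix)
      res <- switch(type,
        reversal = op_reversal(chrs, p_seg),
        translocation = op_translocation(chrs, p_seg),
        fusion = op_fusion(chrs),
        fission = op_fission(chrs))
      if (!is.null(res)) {
        chrs <- res$chrs
        scen[[length(scen) + 1L]] <- data.frame(
          op = k, type = type, detail = res$detail,
          stringsAsFactors = FALSE)
        done <- TRUE
        break
      }
    }
    if (!done)
      scen[[length(scen) + 1L]] <- data.frame(
        op = k, type = "skipped", detail = "no feasible operation",
        stringsAsFactors = FALSE)
  }
  scenario <- if (length(scen)) do.call(rbind, scen)
  else data.frame(op = integer(0), type = character(0),
                  detail = character(0), stringsAsFactors = FALSE)
  list(genome = block_genome(chrs, name = name), scenario = scenario)
}

op_reversal <- function(chrs, p_seg) {
  w <- lengths(chrs)
  i <- sample.int(length(chrs), 1L, prob = w)
  len <- w[i]
  a <- sample.int(len, 1L)
  seg <- min(len - a + 1L, 1L + stats::rgeom(1L, p_seg))
  b <- a + seg - 1L
  if (a == 1L && b == len) return(NULL)  # whole-chromosome flip: no-op
  chr <- chrs[[i]]
  chrs[[i]] <- append(chr[-(a:b)], -rev(chr[a:b]), after = a - 1L)
  list(chrs = chrs, detail = paste0("chr", i, ":", a, "-", b))
}

op_translocation <- function(chrs, p_seg) {
  if (length(chrs) < 2L) return(NULL)
  w <- lengths(chrs)
  ij <- sample.int(length(chrs), 2L, prob = w)
  c1 <- chrs[[ij[1]]]; c2 <- chrs[[ij[2]]]
  # exchanged tails may be empty on one side (a terminal-segment move)
  t1 <- min(length(c1), stats::rgeom(1L, p_seg))
  t2 <- min(length(c2), stats::rgeom(1L, p_seg))
  if (t1 + t2 == 0L) return(NULL)
  n1 <- c(vec_head(c1, length(c1) - t1), vec_tail(c2, length(c2) - t2))
  n2 <- c(vec_head(c2, length(c2) - t2), vec_tail(c1, length(c1) - t1))
  if (!length(n1) || !length(n2)) return(NULL)
  if (t1 == length(c1) && t2 == length(c2)) return(NULL)  # whole swap
  chrs[[ij[1]]] <- n1; chrs[[ij[2]]] <- n2
  list(chrs = chrs,
       detail = paste0("chr", ij[1], "x chr", ij[2], " tails ", t1, "/", t2))
}

op_fusion <- function(chrs) {
  if (length(chrs) < 2L) return(NULL)
  ij <- sample.int(length(chrs), 2L)
  b <- chrs[[ij[2]]]
  if (stats::runif(1) < 0.5) b <- -rev(b)
  chrs[[ij[1]]] <- c(chrs[[ij[1]]], b)
  chrs <- chrs[-ij[2]]
  list(chrs = chrs, detail = paste0("chr", ij[1], "+chr", ij[2]))
}

# spurious relocation of small blocks (out-paralog misassignment / assembly
# noise): excise each block and reinsert it at a uniform random junction
# with a random sign
relocate_blocks <- function(g, blocks) {
  chrs <- g$chromosomes
  for (b in blocks) {
    hit <- which(vapply(chrs, function(chr) any(abs(chr) == b), logical(1)))
    if (!length(hit)) next
    chr <- chrs[[hit[1]]]
    chrs[[hit[1]]] <- chr[abs(chr) != b]
    chrs <- chrs[lengths(chrs) > 0L]
    i <- sample.int(length(chrs), 1L, prob = lengths(chrs))
    pos <- sample.int(length(chrs[[i]]) + 1L, 1L) - 1L
    sb <- b * sample(c(-1L, 1L), 1L)
    chrs[[i]] <- append(chrs[[i]], sb, after = pos)
  }
  block_genome(chrs, name = g$name)
}

op_fission <- function(chrs) {
  elig <- which(lengths(chrs) >= 2L)
  if (!length(elig)) return(NULL)
  i <- if (length(elig) == 1L) elig
  else sample(elig, 1L, prob = lengths(chrs)[elig])
  cut <- sample.int(length(chrs[[i]]) - 1L, 1L)
  chr <- chrs[[i]]
  chrs[[i]] <- vec_head(chr, cut)
  chrs[[length(chrs) + 1L]] <- vec_tail(chr, cut)
  list(chrs = chrs, detail = paste0("chr", i, ":", cut))
}

# per-block placement of a genome: cumulative gene-index coordinates along
# each scaffold (scaffold = chromosome unless a fragmentation map is given),
# with unaligned gene runs between neighbouring blocks supplied by gap_fn
# (keyed by the extremity adjacency of the junction)
genome_placement <- function(g, gene_counts, gap_fn = function(key) 0L,
                             scaffold_breaks = NULL) {
  rows <- list()
  scf_id <- 0L
  for (i in seq_along(g$chromosomes)) {
    chr <- g$chromosomes[[i]]
    breaks_here <- scaffold_breaks[[i]] %||% integer(0)
    pieces <- split(seq_along(chr),
                    cumsum(seq_along(chr) %in% (breaks_here + 1L)))
    for (pc in pieces) {
      scf_id <- scf_id + 1L
      sc <- sprintf("s%03d", scf_id)
      pos <- 0L
      prev_signed <- NULL
      for (j in pc) {
        b <- abs(chr[j])
        signed <- chr[j]
        if (!is.null(prev_signed)) {
          rgt <- if (prev_signed > 0) 2L * abs(prev_signed)
          else 2L * abs(prev_signed) - 1L
          lft <- if (signed > 0) 2L * b - 1L else 2L * b
          pos <- pos + gap_fn(paste(min(rgt, lft), max(rgt, lft)))
        }
        gcnt <- gene_counts[[as.character(b)]]
        rows[[length(rows) + 1L]] <- data.frame(
          block = b, scaffold = sc, start = pos + 1L, end = pos + gcnt,
          sign = sign(chr[j]), genes = gcnt, stringsAsFactors = FALSE)
        pos <- pos + gcnt
        prev_signed <- signed
      }
    }
  }
  do.call(rbind, rows)
}

# gap function for one leaf: ancestral junctions keep the shared ancestral
# gap; novel junctions (created by rearrangement) get fresh draws, cached so
# both pairwise tables see identical coordinates
make_gap_fn <- function(anc_gaps, gap_cfg) {
  cache <- new.env(parent = emptyenv())
  function(key) {
    g <- anc_gaps[key]
    if (!is.na(g)) return(as.integer(g))
    got <- cache[[key]]
    if (is.null(got)) {
      got <- as.integer(round(stats::rlnorm(1, log(gap_cfg$median),
                                            gap_cfg$sdlog)))
      cache[[key]] <- got
    }
    got
  }
}

#' Emit a SynMap-like pairwise block table for two leaves
#'
#' Maximal runs of blocks that are adjacent with consistent orientation in
#' both genomes (and share a colour) are emitted as single merged pairwise
#' blocks, as SynMap reports maximal blocks; coordinates are cumulative
#' gene indices along each scaffold.  The strand of a record is `+` for the
#' first genome (the reading frame of the run) and reflects the run's
#' direction in the second genome.
#'
#' @param placeA,placeB placements of the two genomes (see
#'   [simulate_dataset()] internals): data.frames with columns `block`,
#'   `scaffold`, `start`, `end`, `sign`, `genes`.
#' @param nameA,nameB genome names for the table columns.
#' @param colours integer colour per block (indexed by block id).
#' @param chain_gap maximum unaligned gap (genes) bridged when chaining, in
#'   either genome (default 20).
#' @return a two-genome [block_table].
#' @export
emit_pairwise_table <- function(placeA, placeB, nameA, nameB, colours,
                                chain_gap = 20L) {
  pa <- placeA[order(placeA$scaffold, placeA$start), ]
  idxB <- match(seq_len(max(placeB$block)), placeB$block)
  # adjacency keys of genome B (within scaffolds)
  keysB <- character(0)
  for (sc in unique(placeB$scaffold)) {
    pb <- placeB[placeB$scaffold == sc, ]
    pb <- pb[order(pb$start), ]
    if (nrow(pb) < 2L) next
    signed <- pb$block * pb$sign
    right <- ifelse(signed > 0, 2L * pb$block, 2L * pb$block - 1L)
    left <- ifelse(signed > 0, 2L * pb$block - 1L, 2L * pb$block)
    keysB <- c(keysB, paste(pmin(right[-nrow(pb)], left[-1]),
                            pmax(right[-nrow(pb)], left[-1])))
  }
  runs <- list()
  cur <- integer(0)
  flush <- function() {
    if (length(cur)) runs[[length(runs) + 1L]] <<- cur
    cur <<- integer(0)
  }
  for (r in seq_len(nrow(pa))) {
    if (!length(cur)) { cur <- r; next }
    prev <- cur[length(cur)]
    same_scf <- pa$scaffold[r] == pa$scaffold[prev]
    same_col <- colours[pa$block[r]] == colours[pa$block[prev]]
    sp <- pa$block[prev] * pa$sign[prev]
    sr <- pa$block[r] * pa$sign[r]
    rgt <- if (sp > 0) 2L * pa$block[prev] else 2L * pa$block[prev] - 1L
    lft <- if (sr > 0) 2L * pa$block[r] - 1L else 2L * pa$block[r]
    key <- paste(min(rgt, lft), max(rgt, lft))
    chainable <- FALSE
    if (same_scf && same_col && key %in% keysB) {
      gapA <- pa$start[r] - pa$end[prev] - 1L
      bp <- placeB[idxB[pa$block[prev]], ]
      bc <- placeB[idxB[pa$block[r]], ]
      gapB <- max(bp$start, bc$start) - min(bp$end, bc$end) - 1L
      chainable <- gapA <= chain_gap && gapB <= chain_gap
    }
    if (chainable) cur <- c(cur, r)
    else { flush(); cur <- r }
  }
  flush()
  rows <- lapply(seq_along(runs), function(k) {
    rr <- runs[[k]]
    blocks <- pa$block[rr]
    bB <- placeB[idxB[blocks], ]
    if (length(rr) == 1L) {
      strandB <- if (pa$sign[rr] == bB$sign[1]) "+" else "-"
    } else {
      strandB <- if (bB$start[1] < bB$start[nrow(bB)]) "+" else "-"
    }
    row <- data.frame(block_id = k, colour = colours[blocks[1]],
                      polarity_determinate = TRUE, stringsAsFactors = FALSE)
    row[[paste0(nameA, "_scaffold")]] <- pa$scaffold[rr[1]]
    row[[paste0(nameA, "_start")]] <- min(pa$start[rr])
    row[[paste0(nameA, "_end")]] <- max(pa$end[rr])
    row[[paste0(nameA, "_strand")]] <- "+"
    row[[paste0(nameA, "_genes")]] <- sum(pa$genes[rr])
    row[[paste0(nameB, "_scaffold")]] <- bB$scaffold[1]
    row[[paste0(nameB, "_start")]] <- min(bB$start)
    row[[paste0(nameB, "_end")]] <- max(bB$end)
    row[[paste0(nameB, "_strand")]] <- strandB
    row[[paste0(nameB, "_genes")]] <- sum(bB$genes)
    row
  })
  block_table(do.call(rbind, rows))
}

#' Simulate a full three-genome dataset with ground truth
#'
#' Runs the generator end to end: coloured ancestor, three leaves evolved
#' under their branch regimes, per-genome fractionation erosion of gene
#' counts, scaffold fragmentation of the pivot assembly, and the three
#' SynMap-like pairwise block tables.
#'
#' @param cfg a [sim_config()].
#' @return list with `tables` (named list `ab` = pivot/sister, `bc` =
#'   pivot/outgroup, `ca` = sister/outgroup) and `truth` (ancestor, leaves,
#'   scenarios, colours, true and eroded gene counts, true pairwise DCJ
#'   distances, placements).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  seeds <- fan_out_seeds(cfg$seed, 10L)
  anc <- generate_ancestor(cfg)
  gn <- cfg$genome_names
  leaves <- list()
  scenarios <- list()
  for (i in 1:3) {
    br <- cfg$branches[[gn[i]]]
    ev <- evolve_genome(anc$genome, br, seeds[1L + i], name = gn[i])
    g <- ev$genome
    scen <- ev$scenario
    k_noise <- br$noise %||% 0L
    if (k_noise > 0L) {
      small <- which(anc$gene_counts <= cfg$gene_count$median)
      pick <- sample(small, min(k_noise, length(small)))
      g <- relocate_blocks(g, pick)
      scen <- rbind(scen, data.frame(
        op = nrow(scen) + seq_along(pick), type = "noise_relocation",
        detail = paste0("block ", pick), stringsAsFactors = FALSE))
    }
    leaves[[gn[i]]] <- g
    scenarios[[gn[i]]] <- scen
  }
  # fractionation: eroded per-genome gene counts (ends of blocks lose genes)
  counts <- list()
  for (i in 1:3) {
    set.seed(seeds[4L + i])
    loss <- stats::rpois(cfg$n_blocks, cfg$erosion_rate) +
      stats::rpois(cfg$n_blocks, cfg$erosion_rate)
    cg <- pmax(1, anc$gene_counts - loss)
    names(cg) <- names(anc$gene_counts)
    counts[[gn[i]]] <- cg
  }
  # pivot scaffold fragmentation at random block boundaries
  set.seed(seeds[8])
  piv <- leaves[[gn[1]]]
  n_breaks <- max(0L, cfg$pivot_scaffolds - length(piv$chromosomes))
  interior <- do.call(rbind, lapply(seq_along(piv$chromosomes), function(i) {
    k <- length(piv$chromosomes[[i]])
    if (k < 2L) NULL else data.frame(chr = i, pos = seq_len(k - 1L))
  }))
  breaks <- vector("list", length(piv$chromosomes))
  if (!is.null(interior) && n_breaks > 0L) {
    pick <- interior[sample.int(nrow(interior),
                                min(n_breaks, nrow(interior))), ]
    for (i in seq_along(breaks))
      breaks[[i]] <- sort(pick$pos[pick$chr == i])
  }
  placements <- list()
  for (i in 1:3) {
    set.seed(seeds[8L] + i)   # novel-junction gap draws, per leaf
    gap_fn <- make_gap_fn(anc$junction_gaps, cfg$gap)
    placements[[gn[i]]] <- genome_placement(
      if (i == 1L) piv else leaves[[gn[i]]], counts[[gn[i]]], gap_fn,
      if (i == 1L) breaks else NULL)
  }
  tables <- list(
    ab = emit_pairwise_table(placements[[gn[1]]], placements[[gn[2]]],
                             gn[1], gn[2], anc$colours, cfg$chain_gap),
    bc = emit_pairwise_table(placements[[gn[1]]], placements[[gn[3]]],
                             gn[1], gn[3], anc$colours, cfg$chain_gap),
    ca = emit_pairwise_table(placements[[gn[2]]], placements[[gn[3]]],
                             gn[2], gn[3], anc$colours, cfg$chain_gap))
  truth <- list(ancestor = anc$genome, colours = anc$colours,
                gene_counts = anc$gene_counts, eroded_counts = counts,
                leaves = leaves, scenarios = scenarios,
                placements = placements,
                pairwise = c(
                  ab = dcj_distance(leaves[[gn[1]]], leaves[[gn[2]]]),
                  bc = dcj_distance(leaves[[gn[1]]], leaves[[gn[3]]]),
                  ca = dcj_distance(leaves[[gn[2]]], leaves[[gn[3]]])),
                ancestor_sum = sum(vapply(leaves, function(l)
                  dcj_distance(anc$genome, l), numeric(1))))
  list(tables = tables, truth = truth, cfg = cfg)
}

#' Random signed block genome
#'
#' Uniform random block order, signs, and chromosome breaks; used for
#' null-model comparisons (independent genomes) and breakpoint-reuse
#' experiments.
#'
#' @param n_blocks number of blocks.
#' @param n_chromosomes number of (linear) chromosomes.
#' @param name genome name.
#' @return a [block_genome].
#' @export
random_genome <- function(n_blocks, n_chromosomes = 1L, name = "random") {
  ord <- sample.int(n_blocks) * sample(c(-1L, 1L), n_blocks, replace = TRUE)
  if (n_chromosomes > 1L) {
    cuts <- sort(sample.int(n_blocks - 1L, n_chromosomes - 1L))
    bounds <- c(0L, cuts, n_blocks)
    chrs <- lapply(seq_len(n_chromosomes),
                   function(i) ord[(bounds[i] + 1L):bounds[i + 1L]])
  } else chrs <- list(ord)
  block_genome(chrs, name = name)
}
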