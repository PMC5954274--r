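# Three-way synteny block construction from pairwise block tables, and the
# informativeness filter on pivot scaffolds.

# extremity adjacency keys of a genome, using raw block ids
adjacency_keys <- function(g) {
  keys <- character(0)
  for (chr in g$chromosomes) {
    if (length(chr) < 2L) next
    b <- abs(chr)
    right <- ifelse(chr > 0, 2L * b, 2L * b - 1L)
    left <- ifelse(chr > 0, 2L * b - 1L, 2L * b)
    a1 <- right[-length(right)]
    a2 <- left[-1]
    keys <- c(keys, paste(pmin(a1, a2), pmax(a1, a2)))
  }
  keys
}

#' Filter pivot scaffolds that carry rearrangement information
#'
#' A pivot scaffold is informative when it contains at least two successive
#' synteny blocks whose counterparts are not successive — not adjacent in
#' block order, or adjacent with inconsistent relative orientation — in at
#' least one of the other genomes.  Scaffolds with a single block, or whose
#' block order is perfectly conserved in every other genome, say nothing
#' about the divergence of the pivot and are dropped.
#'
#' @param t a [block_table] placing `pivot_genome` and at least one other
#'   genome.
#' @param pivot_genome name of the pivot genome.
#' @return the filtered [block_table]; attribute `scaffolds_kept` lists the
#'   retained pivot scaffolds.
#' @export
filter_informative_scaffolds <- function(t, pivot_genome) {
  gn <- genomes_of_table(t)
  if (!pivot_genome %in% gn)
    stop("pivot genome '", pivot_genome, "' is not placed in this table")
  others <- setdiff(gn, pivot_genome)
  if (!length(others)) stop("table places no genome besides the pivot")
  if (!nrow(t)) return(t)
  other_keys <- lapply(others, function(g)
    adjacency_keys(genome_from_table(t, g)))
  scf <- as.character(t[[paste0(pivot_genome, "_scaffold")]])
  st <- t[[paste0(pivot_genome, "_start")]]
  strand <- t[[paste0(pivot_genome, "_strand")]]
  keep_scaffold <- character(0)
  for (sc in unique(scf)) {
    i <- which(scf == sc)
    i <- i[order(st[i])]
    if (length(i) < 2L) next
    sgn <- ifelse(strand[i] == "-", -1L, 1L)
    ids <- t$block_id[i]
    b <- abs(ids)
    signed <- b * sgn
    right <- ifelse(signed > 0, 2L * b, 2L * b - 1L)
    left <- ifelse(signed > 0, 2L * b - 1L, 2L * b)
    keys <- paste(pmin(right[-length(right)], left[-1]),
                  pmax(right[-length(right)], left[-1]))
    broken <- vapply(keys, function(k)
      any(!vapply(other_keys, function(ok) k %in% ok, logical(1))),
      logical(1))
    if (any(broken)) keep_scaffold <- c(keep_scaffold, sc)
  }
  out <- t[scf %in% keep_scaffold, , drop = FALSE]
  out <- block_table(as.data.frame(out))
  attr(out, "scaffolds_kept") <- sort(keep_scaffold)
  out
}

# normalize a pairwise record list so the pivot strand is "+"
normalize_pivot_strand <- function(df, pivot, other) {
  flip <- df[[paste0(pivot, "_strand")]] == "-"
  df[[paste0(pivot, "_strand")]][flip] <- "+"
  os <- paste0(other, "_strand")
  df[[os]][flip] <- ifelse(df[[os]][flip] == "+", "-", "+")
  df
}

# map a pivot-span cut offset into the counterpart span (linear, rounding
# toward the interior, i.e. trims round up); offsets are 0..P gene
# boundaries.  Ceiling guarantees sibling sub-blocks of one parent map to
# disjoint counterpart intervals.
map_cut <- function(off, P, Cp) as.integer(ceiling(off * Cp / P))

#' Build three-way synteny blocks from two pairwise tables
#'
#' Sorts the pairwise blocks of the `ab` and `bc` tables along the pivot
#' genome and intersects their pivot intervals.  Wherever the two pairwise
#' blocks only partially overlap, the overlap is split at the interior
#' boundaries, so one pairwise block can yield several three-way blocks;
#' counterpart intervals in the two non-pivot genomes are split at the same
#' boundaries, mapped linearly from the pivot span (rounding toward the
#' interior).  Colour is inherited from the parents, which must agree;
#' conflicting parents are skipped with a message.  The third pairwise table
#' (`ca`, not containing the pivot) is used only to cross-check colours of
#' the non-pivot genomes when supplied.
#'
#' @param ab a [block_table] placing the pivot and a second genome.
#' @param bc a [block_table] placing the pivot and the third genome.
#' @param ca optional [block_table] of the two non-pivot genomes (consistency
#'   checking only).
#' @param pivot_genome genome name present in both `ab` and `bc`.
#' @return a three-genome [block_table]; pivot intervals of the records are
#'   pairwise disjoint, each contained in exactly one parent interval from
#'   each pairwise table.  Attribute `skipped_colour_conflicts` counts
#'   records dropped for colour disagreement.
#' @export
build_three_way <- function(ab, bc, ca = NULL, pivot_genome) {
  g_ab <- genomes_of_table(ab)
  g_bc <- genomes_of_table(bc)
  if (!pivot_genome %in% g_ab || !pivot_genome %in% g_bc)
    stop("pivot genome '", pivot_genome, "' must be placed in both tables")
  oa <- setdiff(g_ab, pivot_genome)
  oc <- setdiff(g_bc, pivot_genome)
  if (length(oa) != 1L || length(oc) != 1L)
    stop("each pairwise table must place exactly two genomes")
  if (oa == oc) stop("the two tables place the same genome pair")
  A <- as.data.frame(normalize_pivot_strand(as.data.frame(ab), pivot_genome, oa))
  C <- as.data.frame(normalize_pivot_strand(as.data.frame(bc), pivot_genome, oc))
  ps <- paste0(pivot_genome, "_scaffold")
  p1 <- paste0(pivot_genome, "_start")
  p2 <- paste0(pivot_genome, "_end")
  pgn <- paste0(pivot_genome, "_genes")
  rows <- list()
  skipped <- 0L
  next_id <- 1L
  for (sc in sort(unique(c(as.character(A[[ps]]), as.character(C[[ps]]))))) {
    ia <- which(as.character(A[[ps]]) == sc)
    ic <- which(as.character(C[[ps]]) == sc)
    if (!length(ia) || !length(ic)) next
    ia <- ia[order(A[[p1]][ia])]
    ic <- ic[order(C[[p1]][ic])]
    for (i in ia) for (j in ic) {
      lo <- max(A[[p1]][i], C[[p1]][j])
      hi <- min(A[[p2]][i], C[[p2]][j])
      if (lo > hi) next
      if (!is.na(A$colour[i]) && !is.na(C$colour[j]) &&
          A$colour[i] != C$colour[j]) {
        skipped <- skipped + 1L
        next
      }
      place_a <- map_subinterval(A, i, oa, pivot_genome, lo, hi)
      place_c <- map_subinterval(C, j, oc, pivot_genome, lo, hi)
      if (is.null(place_a) || is.null(place_c)) { skipped <- skipped + 1L; next }
      piv_genes <- max(1L, round(
        A[[pgn]][i] * (hi - lo + 1) / (A[[p2]][i] - A[[p1]][i] + 1)))
      piv_genes <- min(piv_genes, hi - lo + 1L)
      row <- data.frame(block_id = next_id,
                        colour = A$colour[i] %||% C$colour[j],
                        polarity_determinate = TRUE,
                        stringsAsFactors = FALSE)
      row$colour <- if (is.na(A$colour[i])) C$colour[j] else A$colour[i]
      row[[ps]] <- as.character(A[[ps]][i])
      row[[p1]] <- lo; row[[p2]] <- hi
      row[[paste0(pivot_genome, "_strand")]] <- "+"
      row[[pgn]] <- piv_genes
      for (nm in names(place_a)) row[[nm]] <- place_a[[nm]]
      for (nm in names(place_c)) row[[nm]] <- place_c[[nm]]
      rows[[length(rows) + 1L]] <- row
      next_id <- next_id + 1L
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else {
    tmpl <- data.frame(block_id = integer(0), colour = integer(0),
                       polarity_determinate = logical(0))
    for (g in c(pivot_genome, oa, oc)) {
      tmpl[[paste0(g, "_scaffold")]] <- character(0)
      tmpl[[paste0(g, "_start")]] <- integer(0)
      tmpl[[paste0(g, "_end")]] <- integer(0)
      tmpl[[paste0(g, "_strand")]] <- character(0)
      tmpl[[paste0(g, "_genes")]] <- integer(0)
    }
    tmpl
  }
  if (skipped > 0L)
    message("build_three_way: skipped ", skipped,
            " overlap(s) with conflicting colours or empty counterparts")
  res <- block_table(out)
  attr(res, "skipped_colour_conflicts") <- skipped
  res
}

# place the sub-interval [lo, hi] of parent record `i` (pivot coordinates)
# into the counterpart genome `other`; returns named list of the five
# counterpart columns, or NULL when the mapped span collapses
map_subinterval <- function(df, i, other, pivot, lo, hi) {
  p1 <- df[[paste0(pivot, "_start")]][i]
  p2 <- df[[paste0(pivot, "_end")]][i]
  P <- p2 - p1 + 1L
  cs <- df[[paste0(other, "_start")]][i]
  ce <- df[[paste0(other, "_end")]][i]
  Cp <- ce - cs + 1L
  strand <- df[[paste0(other, "_strand")]][i]
  off1 <- lo - p1        # genes trimmed off the left of the pivot span
  off2 <- p2 - hi        # trimmed off the right
  t1 <- map_cut(off1, P, Cp)
  t2 <- map_cut(off2, P, Cp)
  if (strand == "-") { tmp <- t1; t1 <- t2; t2 <- tmp }
  s <- cs + t1
  e <- ce - t2
  if (s > e) return(NULL)  # counterpart too short for this piece: drop
  genes_parent <- df[[paste0(other, "_genes")]][i]
  genes <- max(1L, round(genes_parent * (e - s + 1) / Cp))
  genes <- min(genes, e - s + 1L)
  out <- list()
  out[[paste0(other, "_scaffold")]] <- as.character(df[[paste0(other, "_scaffold")]][i])
  out[[paste0(other, "_start")]] <- as.integer(s)
  out[[paste0(other, "_end")]] <- as.integer(e)
  out[[paste0(other, "_strand")]] <- strand
  out[[paste0(other, "_genes")]] <- as.integer(genes)
  out
}
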