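#' Resolution schedule
#'
#' The resolution (granularity) of the analysis is set by a minimum block
#' size `L` in genes: at level `L` every block with fewer than `L` genes is
#' ignored, and surviving neighbours closer than `merge_gap` genes on all
#' three genomes (counting genes of deleted blocks lying between) are
#' combined, by default only when they carry the same ancestral colour.
#'
#' @param levels strictly increasing integer levels (default 0,10,...,70;
#'   level 0 keeps everything).
#' @param merge_gap maximum gene gap for merging neighbours (default 250).
#' @param colour_rule require equal colour for a merger (default `TRUE`).
#' @return a list of class `resolution_schedule`.
#' @export
resolution_schedule <- function(levels = seq(0L, 70L, by = 10L),
                                merge_gap = 250L, colour_rule = TRUE) {
  levels <- as.integer(levels)
  if (any(diff(levels) <= 0L)) stop("levels must be strictly increasing")
  if (merge_gap <= 0L) stop("merge_gap must be positive")
  structure(list(levels = levels, merge_gap = as.integer(merge_gap),
                 colour_rule = isTRUE(colour_rule)),
            class = "resolution_schedule")
}

# block size used by the level filter: worst-case gene count across the
# placed genomes (conservative under fractionation); "mean"/"max" available
block_sizes <- function(t, method = c("min", "mean", "max")) {
  method <- match.arg(method)
  gn <- genomes_of_table(t)
  m <- do.call(cbind, lapply(gn, function(g) t[[paste0(g, "_genes")]]))
  if (!nrow(t)) return(numeric(0))
  apply(m, 1, match.arg(method))
}

#' Delete blocks below a resolution level
#'
#' @param t a [block_table].
#' @param L minimum block size in genes; `L = 0` keeps everything.
#' @param size_method how to summarize per-genome gene counts into one block
#'   size: `"min"` (default), `"mean"` or `"max"`.
#' @return list with `retained` and `deleted` [block_table]s.
#' @export
apply_level <- function(t, L, size_method = "min") {
  if (L < 0L) stop("L must be non-negative")
  if (!nrow(t)) return(list(retained = t, deleted = t[integer(0), ]))
  sz <- block_sizes(t, size_method)
  keep <- sz >= L
  list(retained = block_table(as.data.frame(t[keep, , drop = FALSE])),
       deleted = block_table(as.data.frame(t[!keep, , drop = FALSE])))
}

# per-genome neighbour structure of the retained records: for each record
# index, the following record on the same scaffold (by start), and the gap
neighbour_frame <- function(t, g) {
  scf <- as.character(t[[paste0(g, "_scaffold")]])
  st <- t[[paste0(g, "_start")]]
  en <- t[[paste0(g, "_end")]]
  nxt <- rep(NA_integer_, nrow(t))
  gap <- rep(NA_integer_, nrow(t))
  for (sc in unique(scf)) {
    i <- which(scf == sc)
    i <- i[order(st[i])]
    if (length(i) > 1L) {
      nxt[i[-length(i)]] <- i[-1]
      gap[i[-length(i)]] <- st[i[-1]] - en[i[-length(i)]] - 1L
    }
  }
  list(nxt = nxt, gap = gap)
}

# orientation signature of an ordered record pair (r, s) on genome g:
# c(order_dir, x, y) where order_dir is +1 when r precedes s, and (x, y) is
# the implied internal structure of the would-be merged segment read r-first
pair_signature <- function(t, g, r, s) {
  scf <- as.character(t[[paste0(g, "_scaffold")]])
  if (scf[r] != scf[s]) return(NULL)
  st <- t[[paste0(g, "_start")]]
  sr <- if (t[[paste0(g, "_strand")]][r] == "-") -1L else 1L
  ss <- if (t[[paste0(g, "_strand")]][s] == "-") -1L else 1L
  if (st[r] < st[s]) c(1L, sr, ss) else c(-1L, -sr, -ss)
}

#' Merge neighbouring blocks after a level deletion
#'
#' Iteratively combines pairs of retained records that are adjacent (no
#' retained record between them) on all placed genomes with an inter-block
#' gap below `gap` genes on all of them — the gap is measured in gene
#' indices, so genes of deleted blocks in between are automatically counted
#' — and, when `colour_rule` is set, of equal colour.  The two parts must
#' read in a consistent order on every genome (up to whole-segment
#' reversal); when they do but the polarity of one part disagrees between
#' genomes, the merger proceeds with `polarity_determinate = FALSE` and the
#' disagreeing genome is recorded in the `indeterminate` attribute (for
#' [resolve_polarity()]).  Mergers are applied left-to-right along the first
#' genome of the table and repeated to a fixpoint; refused candidates are
#' recorded in the `refused` attribute.
#'
#' @param t retained [block_table] (from [apply_level()]).
#' @param deleted deleted records (their genes are already accounted for by
#'   the gene-index gaps; accepted for interface completeness).
#' @param gap maximum gene gap (default 250).
#' @param colour_rule require equal colours (default `TRUE`).
#' @param pivot_genome genome along which candidate pairs are scanned
#'   (default: first genome of the table).
#' @return the merged [block_table] with attributes `indeterminate`
#'   (data.frame block_id/genome) and `refused` (data.frame).
#' @export
merge_neighbours <- function(t, deleted = NULL, gap = 250L,
                             colour_rule = TRUE, pivot_genome = NULL) {
  gn <- genomes_of_table(t)
  pivot_genome <- pivot_genome %||% gn[1]
  df <- as.data.frame(t)
  indeterminate <- data.frame(block_id = integer(0), genome = character(0),
                              stringsAsFactors = FALSE)
  refused <- data.frame(block_id_1 = integer(0), block_id_2 = integer(0),
                        genome = character(0), gap = integer(0),
                        reason = character(0), stringsAsFactors = FALSE)
  repeat {
    changed <- FALSE
    if (nrow(df) < 2L) break
    nb <- lapply(gn, function(g) neighbour_frame(df, g))
    names(nb) <- gn
    piv <- nb[[pivot_genome]]
    ord <- order(as.character(df[[paste0(pivot_genome, "_scaffold")]]),
                 df[[paste0(pivot_genome, "_start")]])
    for (r in ord) {
      s <- piv$nxt[r]
      if (is.na(s)) next
      verdict <- merge_verdict(df, gn, nb, r, s, gap, colour_rule)
      if (identical(verdict$ok, TRUE)) {
        mg <- merged_record(df, gn, r, s, verdict)
        if (length(verdict$odd_genomes))
          indeterminate <- rbind(indeterminate, data.frame(
            block_id = mg$block_id, genome = verdict$odd_genomes,
            stringsAsFactors = FALSE))
        # the surviving record may itself carry earlier indeterminacy
        old_ids <- c(df$block_id[r], df$block_id[s])
        indeterminate$block_id[indeterminate$block_id %in% old_ids] <-
          mg$block_id
        df <- df[-s, , drop = FALSE]
        rr <- if (s < r) r - 1L else r
        df[rr, ] <- mg[names(df)]
        changed <- TRUE
        break
      } else if (!is.null(verdict$log)) {
        refused <- rbind(refused, verdict$log)
      }
    }
    if (!changed) break
  }
  indeterminate <- unique(indeterminate)
  out <- block_table(df)
  attr(out, "indeterminate") <- indeterminate
  attr(out, "refused") <- unique(refused)
  out
}

merge_verdict <- function(df, gn, nb, r, s, gap, colour_rule) {
  log1 <- function(genome, gp, reason)
    list(ok = FALSE, log = data.frame(
      block_id_1 = df$block_id[r], block_id_2 = df$block_id[s],
      genome = genome, gap = gp, reason = reason, stringsAsFactors = FALSE))
  if (colour_rule && !is.na(df$colour[r]) && !is.na(df$colour[s]) &&
      df$colour[r] != df$colour[s])
    return(list(ok = FALSE, log = NULL))  # colour mismatch: not a candidate
  sigs <- list()
  for (g in gn) {
    fr <- nb[[g]]
    adj <- !is.na(fr$nxt[r]) && fr$nxt[r] == s
    adj_rev <- !is.na(fr$nxt[s]) && fr$nxt[s] == r
    if (!adj && !adj_rev)
      return(log1(g, NA_integer_, "not adjacent"))
    gp <- if (adj) fr$gap[r] else fr$gap[s]
    if (gp >= gap)
      return(log1(g, gp, "gap too large"))
    sigs[[g]] <- pair_signature(df, g, r, s)
  }
  # order consistency: no genome may flip both parts relative to another
  ref <- sigs[[1]]
  odd <- character(0)
  for (g in gn[-1]) {
    dx <- sigs[[g]][2] != ref[2]
    dy <- sigs[[g]][3] != ref[3]
    if (dx && dy)
      return(log1(g, NA_integer_, "inconsistent order"))
    if (dx || dy) odd <- c(odd, g)
  }
  list(ok = TRUE, sigs = sigs, odd_genomes = odd,
       determinate = length(odd) == 0L)
}

merged_record <- function(df, gn, r, s, verdict) {
  mg <- df[r, , drop = FALSE]
  mg$block_id <- min(df$block_id[r], df$block_id[s])
  mg$polarity_determinate <- verdict$determinate &&
    df$polarity_determinate[r] && df$polarity_determinate[s]
  for (g in gn) {
    st <- paste0(g, "_start"); en <- paste0(g, "_end")
    mg[[st]] <- min(df[[st]][r], df[[st]][s])
    mg[[en]] <- max(df[[en]][r], df[[en]][s])
    mg[[paste0(g, "_genes")]] <- df[[paste0(g, "_genes")]][r] +
      df[[paste0(g, "_genes")]][s]
    # merged unit reads r-then-s; its strand on g is "+" iff r precedes s
    mg[[paste0(g, "_strand")]] <- if (verdict$sigs[[g]][1] > 0) "+" else "-"
  }
  mg
}

#' Resolve indeterminate block polarities by local search
#'
#' After mergers, some blocks have an ambiguous orientation in one genome.
#' Starting from the signs as given, the search scans the indeterminate
#' blocks in block-id order, flips one sign at a time, re-evaluates the
#' objective (by default the DCJ median total score of the three genomes),
#' and keeps strict improvements; full passes repeat until none improves
#' (first-improvement, deterministic, at most `max_passes` passes).
#'
#' @param genomes named list of three [block_genome]s.
#' @param indeterminate data.frame with columns `block_id`, `genome`.
#' @param objective function(list of genomes) -> numeric score to minimize;
#'   default: DCJ median total score.
#' @param max_passes safety cap on full passes (default 20).
#' @return list with `genomes` (signs resolved), `score`, `flips` (number of
#'   accepted flips) and `evaluations`.
#' @export
resolve_polarity <- function(genomes, indeterminate, objective = NULL,
                             max_passes = 20L) {
  if (is.null(objective))
    objective <- function(gs)
      dcj_median(gs[[1]], gs[[2]], gs[[3]])$total_score
  evals <- 0L
  score <- objective(genomes); evals <- evals + 1L
  flips <- 0L
  if (nrow(indeterminate)) {
    indeterminate <- indeterminate[order(indeterminate$block_id,
                                         indeterminate$genome), ]
    for (pass in seq_len(max_passes)) {
      improved <- FALSE
      for (k in seq_len(nrow(indeterminate))) {
        b <- indeterminate$block_id[k]
        g <- indeterminate$genome[k]
        cand <- genomes
        cand[[g]] <- flip_block_sign(cand[[g]], b)
        sc <- objective(cand); evals <- evals + 1L
        if (sc < score) {
          genomes <- cand
          score <- sc
          flips <- flips + 1L
          improved <- TRUE
        }
      }
      if (!improved) break
    }
  }
  list(genomes = genomes, score = score, flips = flips, evaluations = evals)
}

flip_block_sign <- function(g, block_id) {
  g$chromosomes <- lapply(g$chromosomes, function(chr) {
    chr[abs(chr) == block_id] <- -chr[abs(chr) == block_id]
    chr
  })
  g
}

#' Sweep a three-way block table across resolution levels
#'
#' For each level of the schedule: delete blocks below the level, merge
#' surviving neighbours, extract the three genomes, and tabulate what was
#' lost.  Gene content is conserved at every level:
#' `genes_not_included + genes_remaining` equals the table total.
#'
#' @param t a three-genome [block_table].
#' @param schedule a [resolution_schedule()].
#' @param size_method passed to [apply_level()].
#' @param gene_genome genome whose gene counts the report columns use
#'   (default: first genome of the table, conventionally the pivot).
#' @return list of class `resolution_sweep` with `report` (one row per
#'   level: `level`, `blocks_deleted`, `blocks_remaining`,
#'   `blocks_after_mergers`, `genes_not_included`, `genes_remaining`) and
#'   `levels`, a list per level holding the merged `table`, `genomes`
#'   (named list) and the `indeterminate` records.
#' @export
sweep_resolution <- function(t, schedule = resolution_schedule(),
                             size_method = "min", gene_genome = NULL) {
  gn <- genomes_of_table(t)
  gene_genome <- gene_genome %||% gn[1]
  gcol <- paste0(gene_genome, "_genes")
  total_genes <- sum(t[[gcol]])
  rows <- list()
  per_level <- list()
  for (L in schedule$levels) {
    al <- apply_level(t, L, size_method)
    merged <- merge_neighbours(al$retained, al$deleted,
                               gap = schedule$merge_gap,
                               colour_rule = schedule$colour_rule,
                               pivot_genome = gn[1])
    genomes <- lapply(gn, function(g) genome_from_table(merged, g))
    names(genomes) <- gn
    genes_rem <- sum(al$retained[[gcol]])
    rows[[length(rows) + 1L]] <- data.frame(
      level = L,
      blocks_deleted = nrow(al$deleted),
      blocks_remaining = nrow(al$retained),
      blocks_after_mergers = nrow(merged),
      genes_not_included = total_genes - genes_rem,
      genes_remaining = genes_rem)
    per_level[[as.character(L)]] <- list(
      table = merged, genomes = genomes,
      indeterminate = attr(merged, "indeterminate"),
      deleted = al$deleted)
  }
  structure(list(report = do.call(rbind, rows), levels = per_level,
                 schedule = schedule, total_genes = total_genes),
            class = "resolution_sweep")
}

#' @export
print.resolution_sweep <- function(x, ...) {
  cat("<resolution_sweep> ", nrow(x$report), " level(s), ",
      x$total_genes, " genes total\n", sep = "")
  print(x$report, row.names = FALSE)
  invisible(x)
}
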