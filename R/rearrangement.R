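# Extremity encoding: after relabelling blocks to 1..N, block b has tail
# extremity 2b-1 and head extremity 2b.  A genome is represented internally
# by an involution `partner`: partner[x] = extremity adjacent to x, or 0 when
# x is telomeric.  All distances are read off the two-genome adjacency graph.

ext_tail <- function(b) 2L * b - 1L
ext_head <- function(b) 2L * b
ext_mate <- function(x) ifelse(x %% 2L == 1L, x + 1L, x - 1L)
ext_block <- function(x) (x + 1L) %/% 2L

# shared relabelling 1..N for two or more genomes with equal unsigned content
content_map <- function(...) {
  gs <- list(...)
  ids <- lapply(gs, block_ids)
  ref <- ids[[1]]
  for (k in seq_along(ids)[-1]) {
    if (!identical(ids[[k]], ref)) {
      only_a <- setdiff(ref, ids[[k]])
      only_b <- setdiff(ids[[k]], ref)
      stop("genomes differ in block content; private to '", gs[[1]]$name,
           "': {", paste(only_a, collapse = ","), "}, private to '",
           gs[[k]]$name, "': {", paste(only_b, collapse = ","), "}")
    }
  }
  ref
}

# partner involution of a genome under a block-id relabelling
genome_partners <- function(g, ids) {
  n <- length(ids)
  partner <- integer(2L * n)
  for (chr in g$chromosomes) {
    b <- match(abs(chr), ids)
    pos <- ifelse(chr > 0, 1L, -1L)
    left <- ifelse(pos > 0, ext_tail(b), ext_head(b))
    right <- ifelse(pos > 0, ext_head(b), ext_tail(b))
    if (length(b) > 1L) {
      a1 <- right[-length(right)]
      a2 <- left[-1]
      partner[a1] <- a2
      partner[a2] <- a1
    }
    partner[left[1]] <- 0L
    partner[right[length(right)]] <- 0L
  }
  partner
}

# cycles C and even-edge paths I of the two-genome adjacency graph
adjacency_components <- function(pA, pB) {
  n <- length(pA)
  visited <- logical(n)
  C <- 0L; I <- 0L
  for (x in seq_len(n)) {
    if (visited[x] || (pA[x] != 0L && pB[x] != 0L)) next
    # path component starting at a telomeric extremity
    visited[x] <- TRUE
    edges <- 0L
    useA <- pA[x] != 0L
    cur <- x
    repeat {
      nxt <- if (useA) pA[cur] else pB[cur]
      if (nxt == 0L) break
      edges <- edges + 1L
      visited[nxt] <- TRUE
      cur <- nxt
      useA <- !useA
    }
    if (edges %% 2L == 0L) I <- I + 1L
  }
  for (x in seq_len(n)) {
    if (visited[x]) next
    C <- C + 1L
    cur <- x; useA <- TRUE
    repeat {
      visited[cur] <- TRUE
      nxt <- if (useA) pA[cur] else pB[cur]
      cur <- nxt; useA <- !useA
      if (cur == x && useA) break
    }
  }
  list(C = C, I = I)
}

dcj_from_partners <- function(pA, pB) {
  cp <- adjacency_components(pA, pB)
  length(pA) / 2 - cp$C - cp$I / 2
}

#' DCJ distance between two genomes
#'
#' The double-cut-and-join distance `d = N - (C + I/2)` read from the
#' adjacency graph of the two genomes, where `N` is the number of shared
#' blocks, `C` the number of cycles and `I` the number of odd paths.
#'
#' @param A,B [block_genome] objects with identical unsigned block content.
#' @return a non-negative integer.
#' @examples
#' dcj_distance(block_genome(list(1:3)), block_genome(list(c(1L, -2L, 3L))))
#' @export
dcj_distance <- function(A, B) {
  ids <- content_map(A, B)
  d <- dcj_from_partners(genome_partners(A, ids), genome_partners(B, ids))
  as.integer(round(d))
}

#' Breakpoint distance between two genomes
#'
#' Multichromosomal convention: `b = N - a - e/2` with `a` the number of
#' shared interior adjacencies and `e` the number of shared telomeric
#' extremities.  Under this convention the reuse statistic `r = 2d/b` spans
#' exactly `[1, 2]` for DCJ distance `d`.
#'
#' @param A,B [block_genome] objects with identical unsigned block content.
#' @return a non-negative number (multiple of 1/2).
#' @export
breakpoint_distance <- function(A, B) {
  ids <- content_map(A, B)
  pA <- genome_partners(A, ids)
  pB <- genome_partners(B, ids)
  a <- sum(pA != 0L & pA == pB) / 2
  e <- sum(pA == 0L & pB == 0L)
  length(ids) - a - e / 2
}

#' Breakpoint reuse statistic r = 2d/b
#'
#' Compares the DCJ rearrangement distance `d` with the breakpoint count `b`.
#' `r` is 1 when every operation created two new breakpoints and tends to 2
#' as the two genomes approach independent random block orders.
#'
#' @param A,B [block_genome] objects with identical unsigned block content.
#' @return a number in `[1, 2]`.
#' @export
reuse_rate <- function(A, B) {
  b <- breakpoint_distance(A, B)
  if (b == 0) stop("reuse rate undefined: genomes are identical (b = 0)")
  2 * dcj_distance(A, B) / b
}

#' Normalize a distance or median score by block count
#' @param score total distance or median score.
#' @param n_blocks number of blocks involved at that resolution level.
#' @return `score / n_blocks`.
#' @export
normalized_total <- function(score, n_blocks) {
  if (n_blocks <= 0) stop("n_blocks must be positive")
  score / n_blocks
}

# rebuild chromosome list from a partner involution; NULL if any chromosome
# would be circular
partners_to_chromosomes <- function(partner, ids) {
  n2 <- length(partner)
  visited <- logical(n2)
  chromosomes <- list()
  tels <- which(partner == 0L)
  for (x in tels) {
    if (visited[x]) next
    chr <- integer(0)
    cur <- x
    repeat {
      visited[cur] <- TRUE
      m <- ext_mate(cur)
      visited[m] <- TRUE
      b <- ext_block(cur)
      chr <- c(chr, if (cur %% 2L == 1L) b else -b)
      nxt <- partner[m]
      if (nxt == 0L) break
      cur <- nxt
    }
    chromosomes[[length(chromosomes) + 1L]] <- chr
  }
  if (!all(visited)) return(NULL)  # leftover cycles = circular chromosomes
  lapply(chromosomes, function(chr) {
    v <- ids[abs(chr)]
    as.integer(v * sign(chr))
  })
}

# chromosome index per extremity, for operation classification
extremity_chromosomes <- function(g, ids) {
  n <- length(ids)
  chrom <- integer(2L * n)
  for (i in seq_along(g$chromosomes)) {
    b <- match(abs(g$chromosomes[[i]]), ids)
    chrom[ext_tail(b)] <- i
    chrom[ext_head(b)] <- i
  }
  chrom
}

#' Greedy optimal sorting scenario between two genomes
#'
#' Produces one optimal DCJ scenario from `A` to `B` by repeatedly applying a
#' distance-reducing operation that keeps every chromosome linear, choosing
#' among the available operations by type priority.  Each applied operation
#' is classified as a reversal (both cuts on one chromosome, chromosome count
#' unchanged), translocation (cuts on two chromosomes, two products), fusion
#' (chromosome count decreases) or fission (increases).  Running with both
#' priority modes brackets the translocation/reversal counts attainable by
#' the greedy scheme.
#'
#' @param A,B [block_genome] objects with identical unsigned block content.
#' @param priority `"translocations"` or `"reversals"`: which of the two
#'   operation types to prefer when both are available.
#' @return an object of class `dcj_scenario`: a data.frame with one row per
#'   operation (`step`, `type`, `join`), with attributes `priority` and
#'   `distance`.  `nrow` always equals `dcj_distance(A, B)`.
#' @export
sort_scenario <- function(A, B, priority = c("translocations", "reversals")) {
  priority <- match.arg(priority)
  pref <- if (priority == "translocations")
    c("translocation", "reversal", "fusion", "fission")
  else c("reversal", "translocation", "fusion", "fission")
  ids <- content_map(A, B)
  pa <- genome_partners(A, ids)
  pb <- genome_partners(B, ids)
  d0 <- as.integer(round(dcj_from_partners(pa, pb)))

  # depth-first over priority-ordered candidates with backtracking: when
  # the greedy chain never dead-ends this is the plain greedy scenario;
  # otherwise alternative choices are explored.  `extra` allows neutral
  # (distance-preserving) unlocking steps for genomes whose unoriented
  # components admit no optimal linear-safe scenario at all.
  env <- new.env(parent = emptyenv())
  env$nodes <- 0L
  search <- function(cur, pa, d, extra) {
    if (d == 0L) return(list())
    env$nodes <- env$nodes + 1L
    if (env$nodes > 20000L) return(NULL)
    cand <- enumerate_sorting_ops(cur, pa, pb, ids, d)
    rank <- vapply(cand, function(op)
      match(op$type, pref) * 1e9 + op$key, numeric(1))
    for (op in cand[order(rank)]) {
      rest <- search(block_genome(op$chromosomes, name = cur$name),
                     op$partner, d - 1L, extra)
      if (!is.null(rest))
        return(c(list(list(type = op$type, label = op$label)), rest))
    }
    # primary candidates exhausted: complete the neighbourhood so that a
    # failure here proves no optimal linear-safe continuation exists
    seen <- vapply(cand, function(op) paste(op$partner, collapse = " "), "")
    full <- enumerate_sorting_ops(cur, pa, pb, ids, d, complete = TRUE)
    full <- full[!vapply(full, function(op)
      paste(op$partner, collapse = " ") %in% seen, logical(1))]
    rank <- vapply(full, function(op)
      match(op$type, pref) * 1e9 + op$key, numeric(1))
    for (op in full[order(rank)]) {
      rest <- search(block_genome(op$chromosomes, name = cur$name),
                     op$partner, d - 1L, extra)
      if (!is.null(rest))
        return(c(list(list(type = op$type, label = op$label)), rest))
    }
    if (extra > 0L) {
      neut <- enumerate_neutral_ops(cur, pa, pb, ids, d)
      rank <- vapply(neut, function(op)
        match(op$type, pref) * 1e9 + op$key, numeric(1))
      for (op in neut[order(rank)]) {
        rest <- search(block_genome(op$chromosomes, name = cur$name),
                       op$partner, d, extra - 1L)
        if (!is.null(rest))
          return(c(list(list(type = op$type, label = op$label)), rest))
      }
    }
    NULL
  }
  path <- NULL
  for (extra in 0:3) {
    env$nodes <- 0L
    path <- search(A, pa, d0, extra)
    if (!is.null(path)) {
      if (extra > 0L)
        warning("no optimal linear-safe scenario exists; ", extra,
                " neutral unlocking step(s) added (length exceeds the ",
                "DCJ distance)")
      break
    }
  }
  if (is.null(path))
    stop("unable to construct a linear-safe sorting scenario")
  out <- if (length(path))
    data.frame(step = seq_along(path),
               type = vapply(path, function(s) s$type, ""),
               join = vapply(path, function(s) s$label, ""),
               stringsAsFactors = FALSE)
  else data.frame(step = integer(0), type = character(0),
                  join = character(0), stringsAsFactors = FALSE)
  structure(out, class = c("dcj_scenario", "data.frame"),
            priority = priority, distance = d0)
}

# distance-preserving linear operations used to unlock genomes whose
# remaining differences are unoriented components: reversals internal to
# one chromosome that keep the distance unchanged
enumerate_neutral_ops <- function(cur, pa, pb, ids, d) {
  chrom <- extremity_chromosomes(cur, ids)
  n_chr <- length(cur$chromosomes)
  out <- list()
  n2 <- length(pa)
  adj <- which(pa > seq_len(n2))
  for (i in seq_along(adj)) {
    a <- adj[i]; b <- pa[a]
    for (j in seq_along(adj)) {
      if (j <= i) next
      cc <- adj[j]; dd <- pa[cc]
      if (chrom[a] != chrom[cc]) next
      for (sw in 1:2) {
        pnew <- pa
        if (sw == 1L) {
          pnew[a] <- cc; pnew[cc] <- a; pnew[b] <- dd; pnew[dd] <- b
        } else {
          pnew[a] <- dd; pnew[dd] <- a; pnew[b] <- cc; pnew[cc] <- b
        }
        if (dcj_from_partners(pnew, pb) != d) next
        chrs <- partners_to_chromosomes(pnew, ids)
        if (is.null(chrs) || length(chrs) != n_chr) next
        out[[length(out) + 1L]] <- list(
          partner = pnew, chromosomes = chrs, type = "reversal",
          key = min(a, cc) * 1e4 + max(a, cc),
          label = paste0(ext_label(min(a, cc), ids), "|",
                         ext_label(max(a, cc), ids)))
      }
    }
  }
  out
}

# DCJ operations that reduce the distance by 1 and keep the genome linear:
# by default those derived from target adjacencies/telomeres (always
# sufficient on the greedy path); with `complete = TRUE` the full DCJ
# neighbourhood, used when backtracking must prove nonexistence
enumerate_sorting_ops <- function(cur, pa, pb, ids, d, complete = FALSE) {
  chrom <- extremity_chromosomes(cur, ids)
  n_chr <- length(cur$chromosomes)
  out <- list()
  add_candidate <- function(pnew, cut_chrs, x, y) {
    if (dcj_from_partners(pnew, pb) != d - 1) return()
    chrs <- partners_to_chromosomes(pnew, ids)
    if (is.null(chrs)) return()  # circular intermediate: forbidden
    dchr <- length(chrs) - n_chr
    type <- if (dchr == -1L) "fusion"
    else if (dchr == 1L) "fission"
    else if (length(unique(cut_chrs)) == 1L) "reversal"
    else "translocation"
    out[[length(out) + 1L]] <<- list(
      partner = pnew, chromosomes = chrs, type = type,
      key = min(x, y) * 1e4 + max(x, y),
      label = paste0(ext_label(x, ids), ifelse(y > 0,
                     paste0("|", ext_label(y, ids)), "|tel")))
  }
  n2 <- length(pa)
  if (!complete) {
    for (x in seq_len(n2)) {
      y <- pb[x]
      if (y > x) {            # target interior adjacency {x, y}
        if (pa[x] == y) next  # already present
        u <- pa[x]; v <- pa[y]
        pnew <- pa
        pnew[x] <- y; pnew[y] <- x
        if (u != 0L && v != 0L) { pnew[u] <- v; pnew[v] <- u }
        else if (u != 0L) pnew[u] <- 0L
        else if (v != 0L) pnew[v] <- 0L
        add_candidate(pnew, c(chrom[x], chrom[y]), x, y)
      } else if (y == 0L && pa[x] != 0L) {  # target telomere at x
        u <- pa[x]
        pnew <- pa
        pnew[x] <- 0L; pnew[u] <- 0L
        add_candidate(pnew, chrom[x], x, 0L)
      }
    }
  } else {
    adj <- which(pa > seq_len(n2))
    tel <- which(pa == 0L)
    for (i in seq_along(adj)) {
      a <- adj[i]; b <- pa[a]
      # single cut (fission)
      pnew <- pa; pnew[a] <- 0L; pnew[b] <- 0L
      add_candidate(pnew, chrom[a], a, 0L)
      # with another adjacency, both rejoinings
      for (j in seq_along(adj)) {
        if (j <= i) next
        cc <- adj[j]; dd <- pa[cc]
        pnew <- pa
        pnew[a] <- cc; pnew[cc] <- a; pnew[b] <- dd; pnew[dd] <- b
        add_candidate(pnew, c(chrom[a], chrom[cc]), min(a, cc), max(a, cc))
        pnew <- pa
        pnew[a] <- dd; pnew[dd] <- a; pnew[b] <- cc; pnew[cc] <- b
        add_candidate(pnew, c(chrom[a], chrom[dd]), min(a, dd), max(a, dd))
      }
      # with a telomere
      for (t in tel) {
        pnew <- pa
        pnew[a] <- t; pnew[t] <- a; pnew[b] <- 0L
        add_candidate(pnew, c(chrom[a], chrom[t]), min(a, t), max(a, t))
        pnew <- pa
        pnew[b] <- t; pnew[t] <- b; pnew[a] <- 0L
        add_candidate(pnew, c(chrom[b], chrom[t]), min(b, t), max(b, t))
      }
    }
    if (length(tel) >= 2L)
      for (i in seq_along(tel)[-length(tel)]) for (j in (i + 1L):length(tel)) {
        pnew <- pa
        pnew[tel[i]] <- tel[j]; pnew[tel[j]] <- tel[i]
        add_candidate(pnew, c(chrom[tel[i]], chrom[tel[j]]),
                      tel[i], tel[j])
      }
  }
  out
}

ext_label <- function(x, ids) {
  paste0(ids[ext_block(x)], if (x %% 2L == 1L) "t" else "h")
}

#' Translocation/reversal tally of a scenario
#' @param sc a `dcj_scenario` from [sort_scenario()].
#' @return named integer vector over the four operation types.
#' @export
scenario_counts <- function(sc) {
  types <- c("reversal", "translocation", "fusion", "fission")
  out <- vapply(types, function(tp) sum(sc$type == tp), integer(1))
  names(out) <- types
  out
}
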