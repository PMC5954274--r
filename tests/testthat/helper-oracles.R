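# Independent oracles used by the test suite.  Everything here is written
# from first principles (partner involutions, explicit single-DCJ moves,
# exhaustive enumeration) and shares no code path with the package's
# distance/median/matching implementations.

# --- state representation: partner involution over extremities 1..2n, 0 =
#     telomere; circular chromosomes are allowed (no telomere on the cycle).

o_mate <- function(x) ifelse(x %% 2L == 1L, x + 1L, x - 1L)

# decompose a partner vector into linear and circular chromosomes
o_decompose <- function(partner) {
  n2 <- length(partner)
  visited <- logical(n2)
  lin <- list(); circ <- list()
  for (x in which(partner == 0L)) {
    if (visited[x]) next
    chr <- integer(0); cur <- x
    repeat {
      visited[cur] <- TRUE
      m <- o_mate(cur); visited[m] <- TRUE
      b <- (cur + 1L) %/% 2L
      chr <- c(chr, if (cur %% 2L == 1L) b else -b)
      nxt <- partner[m]
      if (nxt == 0L) break
      cur <- nxt
    }
    lin[[length(lin) + 1L]] <- chr
  }
  for (x in seq_len(n2)) {
    if (visited[x]) next
    chr <- integer(0); cur <- x
    repeat {
      visited[cur] <- TRUE
      m <- o_mate(cur); visited[m] <- TRUE
      b <- (cur + 1L) %/% 2L
      chr <- c(chr, if (cur %% 2L == 1L) b else -b)
      cur <- partner[m]
      if (cur == x) break
    }
    circ[[length(circ) + 1L]] <- chr
  }
  list(lin = lin, circ = circ)
}

o_vec_str <- function(v) paste(v, collapse = " ")

o_canon_lin <- function(chr) {
  a <- o_vec_str(chr); b <- o_vec_str(-rev(chr))
  if (a <= b) a else b
}

o_canon_circ <- function(chr) {
  k <- length(chr)
  best <- NULL
  for (v in list(chr, -rev(chr)))
    for (i in seq_len(k)) {
      rot <- o_vec_str(c(v[i:k], v[seq_len(i - 1L)]))
      if (is.null(best) || rot < best) best <- rot
    }
  best
}

o_state_key <- function(partner) {
  d <- o_decompose(partner)
  parts <- c(paste0("L", vapply(d$lin, o_canon_lin, character(1))),
             paste0("C", vapply(d$circ, o_canon_circ, character(1))))
  paste(sort(parts), collapse = " | ")
}

o_partner_from_chromosomes <- function(chromosomes, n, circular = NULL) {
  partner <- integer(2L * n)
  ends <- function(chr) {
    left <- ifelse(chr > 0, 2L * abs(chr) - 1L, 2L * abs(chr))
    right <- ifelse(chr > 0, 2L * abs(chr), 2L * abs(chr) - 1L)
    list(left = left, right = right)
  }
  for (chr in chromosomes) {
    e <- ends(chr)
    k <- length(chr)
    if (k > 1L) {
      partner[e$right[-k]] <- e$left[-1]
      partner[e$left[-1]] <- e$right[-k]
    }
    partner[e$left[1]] <- 0L
    partner[e$right[k]] <- 0L
  }
  for (chr in (circular %||% list())) {
    e <- ends(chr)
    k <- length(chr)
    nxt <- c(seq_len(k)[-1], 1L)
    partner[e$right] <- e$left[nxt]
    partner[e$left[nxt]] <- e$right
  }
  partner
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all genomes reachable by one DCJ operation
o_neighbors <- function(partner) {
  n2 <- length(partner)
  adj <- which(partner > seq_len(n2))        # adjacency reps (x < partner[x])
  adj <- lapply(which(seq_len(n2) < partner), function(x) c(x, partner[x]))
  tel <- which(partner == 0L)
  out <- list()
  push <- function(p) out[[length(out) + 1L]] <<- p
  na <- length(adj)
  if (na >= 2L)
    for (i in seq_len(na - 1L)) for (j in (i + 1L):na) {
      p1 <- adj[[i]]; p2 <- adj[[j]]
      for (sw in 1:2) {
        q <- partner
        if (sw == 1L) { a <- p1[1]; b <- p2[1]; cc <- p1[2]; dd <- p2[2] }
        else { a <- p1[1]; b <- p2[2]; cc <- p1[2]; dd <- p2[1] }
        q[a] <- b; q[b] <- a; q[cc] <- dd; q[dd] <- cc
        push(q)
      }
    }
  if (na >= 1L && length(tel) >= 1L)
    for (i in seq_len(na)) for (t in tel) {
      p1 <- adj[[i]]
      for (sw in 1:2) {
        q <- partner
        keep <- if (sw == 1L) p1[2] else p1[1]
        move <- if (sw == 1L) p1[1] else p1[2]
        q[move] <- t; q[t] <- move; q[keep] <- 0L
        push(q)
      }
    }
  if (length(tel) >= 2L) {
    for (i in seq_len(length(tel) - 1L)) for (j in (i + 1L):length(tel)) {
      q <- partner
      q[tel[i]] <- tel[j]; q[tel[j]] <- tel[i]
      push(q)
    }
  }
  for (i in seq_len(na)) {          # single cut: adjacency -> two telomeres
    q <- partner
    q[adj[[i]][1]] <- 0L; q[adj[[i]][2]] <- 0L
    push(q)
  }
  out
}

# Build (once per block count) the full DCJ state graph over all genomes on
# blocks 1..n, linear and circular chromosomes included, as states + integer
# adjacency lists.  BFS over this graph is the shortest-path oracle.
o_state_graph <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    idx <- new.env(hash = TRUE, parent = emptyenv())
    states <- list()
    edges <- list()
    start <- o_partner_from_chromosomes(list(seq_len(n)), n)
    assign(o_state_key(start), 1L, envir = idx)
    states[[1L]] <- start
    head <- 1L
    while (head <= length(states)) {
      cur <- states[[head]]
      nb <- o_neighbors(cur)
      ids <- integer(length(nb))
      for (k in seq_along(nb)) {
        kk <- o_state_key(nb[[k]])
        id <- idx[[kk]]
        if (is.null(id)) {
          id <- length(states) + 1L
          assign(kk, id, envir = idx)
          states[[id]] <- nb[[k]]
        }
        ids[k] <- id
      }
      edges[[head]] <- unique(ids)
      head <- head + 1L
    }
    g <- list(states = states, edges = edges, index = idx)
    cache[[key]] <<- g
    g
  }
})

# BFS distances from one genome to every state, via the cached state graph
o_bfs_distances <- function(n, chromosomes) {
  g <- o_state_graph(n)
  start_key <- o_state_key(o_partner_from_chromosomes(chromosomes, n))
  s <- g$index[[start_key]]
  dist <- rep(NA_integer_, length(g$states))
  dist[s] <- 0L
  queue <- s
  while (length(queue)) {
    nxt <- integer(0)
    for (v in queue) {
      nb <- g$edges[[v]]
      new <- nb[is.na(dist[nb])]
      dist[new] <- dist[v] + 1L
      nxt <- c(nxt, new)
    }
    queue <- nxt
  }
  list(graph = g, dist = dist)
}

o_lookup_distance <- function(bfs, chromosomes, n) {
  key <- o_state_key(o_partner_from_chromosomes(chromosomes, n))
  id <- bfs$graph$index[[key]]
  if (is.null(id)) stop("oracle: state not in graph")
  bfs$dist[id]
}

# --- exhaustive enumeration of all LINEAR genomes on blocks 1..n (each a
#     list of chromosomes), deduplicated up to chromosome order/orientation
o_all_linear_genomes <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    seen <- new.env(hash = TRUE, parent = emptyenv())
    out <- list()
    perms <- function(v) {
      if (length(v) <= 1L) return(list(v))
      res <- list()
      for (i in seq_along(v))
        for (p in perms(v[-i])) res[[length(res) + 1L]] <- c(v[i], p)
      res
    }
    for (p in perms(seq_len(n))) {
      for (smask in 0:(2^n - 1L)) {
        signs <- ifelse(bitwAnd(smask, 2L^(seq_len(n) - 1L)) > 0L, -1L, 1L)
        sp <- p * signs[seq_len(n)]
        for (bmask in 0:(2^(n - 1L) - 1L)) {
          cuts <- which(bitwAnd(bmask, 2L^(seq_len(n - 1L) - 1L)) > 0L)
          bounds <- c(0L, cuts, n)
          chrs <- lapply(seq_len(length(bounds) - 1L), function(i)
            sp[(bounds[i] + 1L):bounds[i + 1L]])
          k <- paste(sort(vapply(chrs, o_canon_lin, character(1))),
                     collapse = " | ")
          if (is.null(seen[[k]])) {
            assign(k, TRUE, envir = seen)
            out[[length(out) + 1L]] <- chrs
          }
        }
      }
    }
    cache[[key]] <<- out
    out
  }
})

# all distinct multichromosomal structures (partitions of n) as canonical
# chromosome lists 1..k1 | k1+1..k2 | ...
o_canonical_structures <- function(n) {
  parts <- function(n, maxp) {
    if (n == 0L) return(list(integer(0)))
    res <- list()
    for (p in seq_len(min(n, maxp)))
      for (tl in parts(n - p, p)) res[[length(res) + 1L]] <- c(p, tl)
    res
  }
  lapply(parts(n, n), function(sz) {
    b <- cumsum(c(0L, sz))
    lapply(seq_along(sz), function(i) (b[i] + 1L):b[i + 1L])
  })
}

# --- brute-force maximum matching weight for the breakpoint median: DFS
#     over extremities, each either telomeric (1/2 per genome agreeing) or
#     matched along a candidate adjacency (weight = genomes containing it)
o_bp_matching_weight <- function(A, B, C) {
  gs <- list(A, B, C)
  ids <- sort(unique(abs(unlist(A$chromosomes))))
  n2 <- 2L * length(ids)
  partner_of <- function(g) {
    p <- integer(n2)
    for (chr in g$chromosomes) {
      b <- match(abs(chr), ids)
      left <- ifelse(chr > 0, 2L * b - 1L, 2L * b)
      right <- ifelse(chr > 0, 2L * b, 2L * b - 1L)
      if (length(b) > 1L) {
        p[right[-length(b)]] <- left[-1]
        p[left[-1]] <- right[-length(b)]
      }
      p[left[1]] <- 0L
      p[right[length(b)]] <- 0L
    }
    p
  }
  pg <- lapply(gs, partner_of)
  telw <- (pg[[1]] == 0L) + (pg[[2]] == 0L) + (pg[[3]] == 0L)
  edges <- list(); we <- numeric(0)
  seen <- new.env(parent = emptyenv())
  for (g in 1:3) for (x in seq_len(n2)) {
    y <- pg[[g]][x]
    if (y > x) {
      k <- paste(x, y)
      if (is.null(seen[[k]])) {
        seen[[k]] <- length(edges) + 1L
        edges[[length(edges) + 1L]] <- c(x, y)
        we <- c(we, 1)
      } else we[seen[[k]]] <- we[seen[[k]]] + 1
    }
  }
  rec <- function(act) {
    if (!length(act)) return(0)
    x <- act[1]; rest <- act[-1]
    best <- telw[x] / 2 + rec(rest)
    for (i in seq_along(edges)) {
      e <- edges[[i]]
      y <- if (e[1] == x) e[2] else if (e[2] == x) e[1] else next
      if (!(y %in% rest)) next
      best <- max(best, we[i] + rec(setdiff(rest, y)))
    }
    best
  }
  rec(seq_len(n2))
}

# random genome generator for property tests (independent of the package's
# simulator): uniform signed order with uniform chromosome breaks
o_random_genome <- function(n, n_chr = 1L, name = "g") {
  ord <- sample.int(n) * sample(c(-1L, 1L), n, replace = TRUE)
  if (n_chr > 1L) {
    cuts <- sort(sample.int(n - 1L, n_chr - 1L))
    bounds <- c(0L, cuts, n)
    chrs <- lapply(seq_len(n_chr), function(i) ord[(bounds[i] + 1L):bounds[i + 1L]])
  } else chrs <- list(ord)
  block_genome(chrs, name = name)
}
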