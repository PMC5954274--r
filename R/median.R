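#' Exact DCJ median of three genomes
#'
#' Finds a genome `m` (linear chromosomes only) minimizing
#' `d(m,A) + d(m,B) + d(m,C)` under the DCJ distance, by branch-and-bound
#' over the median's adjacency choices.  The total score is always bracketed
#' by `ceiling((d(A,B)+d(A,C)+d(B,C))/2)` from below and by the best input
#' genome from above.
#'
#' With `reduce = "shared"` (default), adjacencies present in at least two
#' of the three input genomes are fixed in the median before the search
#' (such an adjacency is a 2-cycle of the multiple breakpoint graph, an
#' adequate subgraph in the sense used by exact DCJ median solvers); this
#' preserves the optimal score, and when `enumerate_all = TRUE` the
#' enumerated set is the set of optimal medians containing those shared
#' adjacencies.  Shared telomeric states are never fixed (the 2-cycle
#' argument does not extend to them).  The remaining free extremities
#' decompose into independent connected components of the breakpoint graph,
#' each solved exactly by branch-and-bound.  Use `reduce = "none"` on small
#' instances for unrestricted enumeration.
#'
#' @param A,B,C [block_genome] objects with identical unsigned block content.
#' @param enumerate_all if `TRUE`, collect every distinct optimal median (up
#'   to the cap) in canonical form; otherwise only a representative.
#' @param cap maximum number of medians to collect (default 50000); when
#'   exceeded the result is flagged `truncated`.
#' @param reduce `"shared"` or `"none"`, see above.
#' @param node_budget maximum number of branch-and-bound nodes explored
#'   (default 200000).  When exceeded, the best median found so far is
#'   returned, the result carries `exact = FALSE`, and a warning is raised;
#'   within the budget results are provably optimal.
#' @return an object of class `median_result`: list with `medians` (list of
#'   [block_genome]), `total_score`, `distances` (named distances of the
#'   representative to A, B, C), `n_medians`, `truncated`, `lower_bound`.
#' @export
dcj_median <- function(A, B, C, enumerate_all = FALSE, cap = 50000L,
                       reduce = c("shared", "none"), node_budget = 200000L) {
  reduce <- match.arg(reduce)
  ids <- content_map(A, B, C)
  n <- length(ids)
  pg <- list(genome_partners(A, ids), genome_partners(B, ids),
             genome_partners(C, ids))
  dAB <- dcj_from_partners(pg[[1]], pg[[2]])
  dAC <- dcj_from_partners(pg[[1]], pg[[3]])
  dBC <- dcj_from_partners(pg[[2]], pg[[3]])
  lower <- ceiling((dAB + dAC + dBC) / 2)

  # initial upper bound: best input genome used as the median
  in_scores <- c(dAB + dAC, dAB + dBC, dAC + dBC)
  env <- new.env(parent = emptyenv())
  env$best <- min(in_scores)
  env$best_partner <- pg[[which.min(in_scores)]]
  env$solutions <- if (enumerate_all) list() else NULL
  env$truncated <- FALSE
  env$cap <- as.integer(cap)
  env$n <- n
  env$enumerate <- enumerate_all
  env$pg <- pg
  env$lower <- lower
  env$reduce <- reduce
  env$nodes <- 0L
  env$node_budget <- as.numeric(node_budget)
  env$budget_hit <- FALSE

  n2 <- 2L * n
  # forced decisions: an adjacency present in >= 2 of the 3 genomes is a
  # 2-cycle of the multiple breakpoint graph (an adequate subgraph) and can
  # be fixed in the median.  The analogous rule does NOT hold for shared
  # telomeric states (caps of different genomes are distinct vertices), so
  # telomeres are never forced.
  forced_pair <- integer(0)
  if (reduce == "shared") {
    claimed <- logical(n2)
    for (x in seq_len(n2)) {
      if (claimed[x]) next
      ys <- c(pg[[1]][x], pg[[2]][x], pg[[3]][x])
      ys <- ys[ys != 0L]
      tab <- table(ys)
      hit <- as.integer(names(tab)[tab >= 2L])
      if (length(hit)) {
        y <- hit[1]
        forced_pair <- c(forced_pair, x, y)
        claimed[x] <- claimed[y] <- TRUE
      }
    }
  }

  st <- median_initial_state(pg, n2)
  if (length(forced_pair)) {
    fp <- matrix(forced_pair, ncol = 2L, byrow = TRUE)
    for (r in seq_len(nrow(fp))) st <- median_decide_pair(st, fp[r, 1], fp[r, 2])
  }

  # the free part of the multiple breakpoint graph decomposes into
  # independent connected components; solve each exactly, then combine.
  # When every combination of per-component optima would close a circular
  # chromosome, near-optimal component assignments are admitted with a
  # growing total loss budget (any cycle can be broken by replacing one of
  # its adjacencies, which lies inside a single component, by telomeres).
  comps <- median_components(st)
  base_sum <- sum(st$cdone) + sum(st$idone) / 2
  comp_results <- lapply(comps, function(cp)
    median_comp_search(st, cp, env, base_sum, slack = 0))
  total_gain <- sum(vapply(comp_results, function(r) r$gain, numeric(1)))

  cb <- combine_components(st$M, comps, comp_results, ids, env, budget = 0)
  loss_used <- 0
  if (is.null(cb)) {
    slack_max <- 3
    relaxed <- lapply(comps, function(cp)
      median_comp_search(st, cp, env, base_sum, slack = slack_max,
                         use_commits = FALSE))
    for (delta in seq(0, slack_max, by = 0.5)) {
      cb <- combine_components(st$M, comps, relaxed, ids, env,
                               budget = delta)
      if (!is.null(cb)) { loss_used <- delta; break }
    }
  }
  if (is.null(cb) && sum(st$undecided) <= 30L) {
    # last resort on small instances: full joint search
    env$best <- min(in_scores)
    env$best_partner <- pg[[which.min(in_scores)]]
    env$solutions <- if (enumerate_all) list() else NULL
    median_search(st, env)
    cb <- if (enumerate_all) env$solutions else list(env$best_partner)
    combos <- cb
  } else {
    if (is.null(cb))
      stop("median combination failed within the loss budget; ",
           "instance too entangled")
    combos <- cb
    env$best <- 3 * n - (base_sum + total_gain - loss_used)
  }

  keys <- character(0)
  genomes <- list()
  for (p in combos) {
    chrs <- partners_to_chromosomes(p, ids)
    g <- canonical_genome(block_genome(chrs, name = "median"))
    k <- genome_key(g)
    if (!k %in% keys) {
      keys <- c(keys, k)
      genomes[[length(genomes) + 1L]] <- g
    }
  }
  genomes <- genomes[order(keys)]
  if (!enumerate_all) genomes <- genomes[1]
  rep_g <- genomes[[1]]
  dists <- c(dcj_distance(rep_g, A), dcj_distance(rep_g, B),
             dcj_distance(rep_g, C))
  names(dists) <- c(A$name, B$name, C$name)
  if (env$budget_hit) {
    warning("node budget exhausted: median score is an upper bound, ",
            "not certified optimal")
    env$best <- sum(dists)   # report the realized representative's score
  }
  structure(list(medians = genomes, total_score = as.integer(round(env$best)),
                 distances = dists, n_medians = length(genomes),
                 truncated = env$truncated, exact = !env$budget_hit,
                 lower_bound = as.integer(round(lower)),
                 pairwise = c(AB = dAB, AC = dAC, BC = dBC)),
            class = "median_result")
}

#' @export
print.median_result <- function(x, ...) {
  cat("<median_result> total score ", x$total_score,
      " (lower bound ", x$lower_bound, "), ", x$n_medians,
      if (x$truncated) "+ (truncated)" else "", " median(s)\n", sep = "")
  cat("  representative distances:",
      paste(names(x$distances), x$distances, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

# --- internal search machinery ------------------------------------------

# Per-genome component tracking for the partial median M:
#   oth[[g]][x] = other endpoint of the M-union-genome-g path fragment whose
#                 open endpoint is x (-1 when that other end is settled)
#   par[[g]][x] = parity of the fragment's edge count
#   cdone/idone = finished cycles and even-edge paths per genome
median_initial_state <- function(pg, n2) {
  oth <- list(); par <- list()
  for (g in 1:3) {
    o <- integer(n2); p <- integer(n2)
    for (x in seq_len(n2)) {
      if (pg[[g]][x] == 0L) { o[x] <- -1L; p[x] <- 0L }
      else { o[x] <- pg[[g]][x]; p[x] <- 1L }
    }
    oth[[g]] <- o; par[[g]] <- p
  }
  list(oth = oth, par = par, cdone = c(0L, 0L, 0L), idone = c(0L, 0L, 0L),
       undecided = rep(TRUE, n2), u = n2, M = integer(n2) - 1L)
}

median_decide_pair <- function(st, x, y) {
  for (g in 1:3) {
    ox <- st$oth[[g]][x]; oy <- st$oth[[g]][y]
    if (ox == y) {
      st$cdone[g] <- st$cdone[g] + 1L
    } else {
      p <- (st$par[[g]][x] + st$par[[g]][y] + 1L) %% 2L
      if (ox == -1L && oy == -1L) {
        if (p == 0L) st$idone[g] <- st$idone[g] + 1L
      } else if (ox == -1L) {
        st$oth[[g]][oy] <- -1L; st$par[[g]][oy] <- p
      } else if (oy == -1L) {
        st$oth[[g]][ox] <- -1L; st$par[[g]][ox] <- p
      } else {
        st$oth[[g]][ox] <- oy; st$oth[[g]][oy] <- ox
        st$par[[g]][ox] <- p; st$par[[g]][oy] <- p
      }
    }
  }
  st$undecided[c(x, y)] <- FALSE
  st$u <- st$u - 2L
  st$M[x] <- y; st$M[y] <- x
  st
}

median_decide_tel <- function(st, x) {
  for (g in 1:3) {
    ox <- st$oth[[g]][x]
    if (ox == -1L) {
      if (st$par[[g]][x] %% 2L == 0L) st$idone[g] <- st$idone[g] + 1L
    } else {
      st$oth[[g]][ox] <- -1L
    }
  }
  st$undecided[x] <- FALSE
  st$u <- st$u - 1L
  st$M[x] <- 0L
  st
}

median_score_of <- function(st, n) {
  3 * n - sum(st$cdone) - sum(st$idone) / 2
}

# upper bound on the remaining (C + I/2) gain from the undecided extremities
# `und`: per genome, a fragment with both ends open can close at most one
# cycle (1), and a fragment with one settled end can only finish as a path,
# worth 1/2 and only when its parity can come out even — odd dead-end
# fragments add nothing beyond substituting into even chains.
median_gain_bound <- function(st, und) {
  tot <- 0
  for (g in 1:3) {
    oth <- st$oth[[g]]
    par <- st$par[[g]]
    f2 <- 0L; f1e <- 0L
    for (x in und) {
      y <- oth[x]
      if (y > 0L) { if (y > x) f2 <- f2 + 1L }
      else if (par[x] %% 2L == 0L) f1e <- f1e + 1L
    }
    tot <- tot + f2 + f1e / 2
  }
  tot
}

median_search <- function(st, env) {
  if (st$u == 0L) {
    sc <- median_score_of(st, env$n)
    if (sc > env$best) return()
    # reject medians with circular chromosomes
    if (is.null(partners_to_chromosomes(st$M, seq_len(env$n)))) return()
    if (sc < env$best) {
      env$best <- sc
      env$best_partner <- st$M
      if (env$enumerate) env$solutions <- list(st$M)
    } else if (env$enumerate) {
      if (length(env$solutions) >= env$cap) env$truncated <- TRUE
      else env$solutions[[length(env$solutions) + 1L]] <- st$M
    } else {
      env$best_partner <- st$M
    }
    return()
  }
  env$nodes <- env$nodes + 1L
  if (env$nodes > env$node_budget) { env$budget_hit <- TRUE; return() }
  und <- which(st$undecided)
  ub_gain <- sum(st$cdone) + sum(st$idone) / 2 + median_gain_bound(st, und)
  bound <- 3 * env$n - ub_gain
  if (bound > env$best || (!env$enumerate && bound == env$best)) return()
  x <- which.max(st$undecided)  # smallest undecided extremity
  sup <- unique(c(env$pg[[1]][x], env$pg[[2]][x], env$pg[[3]][x]))
  tel_sup <- any(sup == 0L)
  sup <- sup[sup != 0L]
  sup <- sup[st$undecided[sup]]
  others <- which(st$undecided)
  others <- others[others != x & !(others %in% sup)]
  cands <- c(sup, if (tel_sup) 0L, others, if (!tel_sup) 0L)
  for (y in cands) {
    child <- if (y == 0L) median_decide_tel(st, x)
    else median_decide_pair(st, x, y)
    median_search(child, env)
  }
}

# connected components of the free extremities, linked when two free
# extremities are ends of the same fragment in any genome
median_components <- function(st) {
  free <- which(st$undecided)
  if (!length(free)) return(list())
  parent <- seq_along(st$undecided)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (g in 1:3) for (x in free) {
    y <- st$oth[[g]][x]
    if (y > 0L) {
      rx <- find(x); ry <- find(y)
      if (rx != ry) parent[rx] <- ry
    }
  }
  roots <- vapply(free, find, integer(1))
  comps <- lapply(split(free, roots), sort)
  comps[order(vapply(comps, min, integer(1)))]
}

# exact search within one component: maximize the (C + I/2) gain; returns
# the best gain and every assignment within `slack` of it (M values over
# the component, with their gain losses)
median_comp_search <- function(st0, comp, env, base_sum, slack = 0,
                               use_commits = TRUE) {
  res <- new.env(parent = emptyenv())
  res$gain <- -Inf
  res$sols <- list()
  res$gains <- numeric(0)
  rec <- function(st) {
    # recursive reduction (score mode, no slack): two open ends that are
    # co-fragment in >= 2 genomes form a 2-cycle of the contracted
    # instance; committing them preserves the optimal score but restricts
    # the solution set, so it is skipped when enumerating or relaxing.
    if (use_commits && slack == 0 && !env$enumerate &&
        env$reduce == "shared") repeat {
      und <- comp[st$undecided[comp]]
      if (!length(und)) break
      committed <- FALSE
      for (x in und) {
        ys <- c(st$oth[[1]][x], st$oth[[2]][x], st$oth[[3]][x])
        ys <- ys[ys > 0L]
        dup <- ys[duplicated(ys)]
        if (length(dup)) {
          st <- median_decide_pair(st, x, dup[1])
          committed <- TRUE
          break
        }
      }
      if (!committed) break
    }
    u_c <- sum(st$undecided[comp])
    cur <- sum(st$cdone) + sum(st$idone) / 2 - base_sum
    if (u_c == 0L) {
      if (cur > res$gain) res$gain <- cur
      if (cur >= res$gain - slack && length(res$sols) < env$cap) {
        res$sols[[length(res$sols) + 1L]] <- st$M[comp]
        res$gains <- c(res$gains, cur)
      } else if (length(res$sols) >= env$cap) env$truncated <- TRUE
      return()
    }
    und <- comp[st$undecided[comp]]
    if (cur + median_gain_bound(st, und) < res$gain - slack) return()
    env$nodes <- env$nodes + 1L
    if (env$nodes > env$node_budget) { env$budget_hit <- TRUE; return() }
    # branch on the extremity with the strongest cycle-closing option
    m_x <- vapply(und, function(z) {
      ys <- c(st$oth[[1]][z], st$oth[[2]][z], st$oth[[3]][z])
      ys <- ys[ys > 0L]
      if (!length(ys)) return(0L)
      max(tabulate(match(ys, unique(ys))))
    }, integer(1))
    x <- und[which.max(m_x)]
    cands <- und[und != x]
    # order candidates by immediate cycle gain, supported partners first
    imm <- vapply(cands, function(y)
      sum(st$oth[[1]][x] == y, st$oth[[2]][x] == y, st$oth[[3]][x] == y),
      numeric(1))
    sup <- vapply(cands, function(y)
      any(env$pg[[1]][x] == y, env$pg[[2]][x] == y, env$pg[[3]][x] == y),
      logical(1))
    cands <- cands[order(-imm, -sup, cands)]
    tel_gain <- sum((st$oth[[1]][x] == -1L) * (st$par[[1]][x] %% 2L == 0L),
                    (st$oth[[2]][x] == -1L) * (st$par[[2]][x] %% 2L == 0L),
                    (st$oth[[3]][x] == -1L) * (st$par[[3]][x] %% 2L == 0L)) / 2
    all_c <- if (tel_gain >= 1) c(0L, cands) else c(cands, 0L)
    for (y in all_c) {
      child <- if (y == 0L) median_decide_tel(st, x)
      else median_decide_pair(st, x, y)
      rec(child)
    }
  }
  rec(st0)
  if (!length(res$sols)) {
    # budget exhausted before any completion: finish greedily once
    st <- st0
    repeat {
      und <- comp[st$undecided[comp]]
      if (!length(und)) break
      x <- und[1]
      ys <- c(st$oth[[1]][x], st$oth[[2]][x], st$oth[[3]][x])
      ys <- ys[ys > 0L & ys %in% und]
      st <- if (length(ys)) median_decide_pair(st, x, ys[1])
      else median_decide_tel(st, x)
    }
    res$gain <- sum(st$cdone) + sum(st$idone) / 2 - base_sum
    res$sols <- list(st$M[comp])
    res$gains <- res$gain
  }
  keep <- res$gains >= res$gain - slack
  sols <- res$sols[keep]
  loss <- res$gain - res$gains[keep]
  ord <- order(loss, seq_along(loss))
  list(gain = res$gain, sols = sols[ord], loss = loss[ord], comp = comp)
}

# cross the per-component assignments into full median matchings within a
# total gain-loss budget, rejecting any combination that closes a circular
# chromosome; combos are explored in loss order, so together with the
# iterative deepening over the budget the first hit is score-optimal.
# Returns NULL when no combination within the budget is linear.
combine_components <- function(M0, comps, comp_results, ids, env,
                               budget = 0) {
  found <- list()
  k_total <- length(comps)
  linear_ok <- function(M) {
    !is.null(partners_to_chromosomes(pmax(M, 0L), ids))
  }
  dfs <- function(k, M, left) {
    if (length(found) >= env$cap) { env$truncated <- TRUE; return() }
    if (!env$enumerate && length(found) >= 1L) return()
    if (k > k_total) {
      if (left == 0) found[[length(found) + 1L]] <<- M
      return()
    }
    cr <- comp_results[[k]]
    for (i in seq_along(cr$sols)) {
      if (cr$loss[i] > left) break   # sols are sorted by loss
      M2 <- M
      M2[comps[[k]]] <- cr$sols[[i]]
      if (!linear_ok(M2)) next
      dfs(k + 1L, M2, left - cr$loss[i])
    }
  }
  if (!linear_ok(M0)) return(NULL)
  dfs(1L, M0, budget)
  if (!length(found)) return(NULL)
  found
}

#' Breakpoint median of three genomes via maximum-weight matching
#'
#' Builds a graph on block extremities whose candidate edges are the
#' adjacencies present in at least one input genome, weighted by the number
#' of genomes containing them; telomeric states are credited 1/2 per genome
#' (consistent with the breakpoint-distance convention).  An exact
#' maximum-weight matching (component-wise branch-and-bound) selects the
#' median's adjacencies; any cycle forced by the matching is broken at its
#' lightest edge (with a message).
#'
#' @param A,B,C [block_genome] objects with identical unsigned block content.
#' @return a [block_genome], the breakpoint median, with attributes
#'   `matching_weight` (the exact maximum, telomere credits included) and
#'   `broken_cycles`.
#' @export
breakpoint_median <- function(A, B, C) {
  ids <- content_map(A, B, C)
  n <- length(ids)
  n2 <- 2L * n
  pg <- list(genome_partners(A, ids), genome_partners(B, ids),
             genome_partners(C, ids))
  tel_w <- ((pg[[1]] == 0L) + (pg[[2]] == 0L) + (pg[[3]] == 0L)) / 2
  # candidate edges with folded weights w' = w - t(x) - t(y)
  ek <- new.env(parent = emptyenv())
  for (g in 1:3) for (x in seq_len(n2)) {
    y <- pg[[g]][x]
    if (y > x) {
      k <- paste(x, y)
      ek[[k]] <- (ek[[k]] %||% 0) + 1
    }
  }
  keys <- ls(ek)
  edges <- do.call(rbind, lapply(keys, function(k)
    as.integer(strsplit(k, " ")[[1]])))
  w_raw <- vapply(keys, function(k) ek[[k]], numeric(1))
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2)
  w <- w_raw - tel_w[edges[, 1]] - tel_w[edges[, 2]]
  keep <- w > 0
  edges <- edges[keep, , drop = FALSE]
  w <- w[keep]
  ord <- order(edges[, 1], edges[, 2])
  edges <- edges[ord, , drop = FALSE]
  w <- w[ord]
  sel <- max_weight_matching(n2, edges, w)
  weight <- sum(w[sel]) + sum(tel_w)
  partner <- integer(n2)
  for (i in which(sel)) {
    partner[edges[i, 1]] <- edges[i, 2]
    partner[edges[i, 2]] <- edges[i, 1]
  }
  broken <- 0L
  repeat {
    chrs <- partners_to_chromosomes(partner, ids)
    if (!is.null(chrs)) break
    # locate a cycle: extremities not reachable from any telomere
    reach <- logical(n2)
    for (x in which(partner == 0L)) {
      cur <- x
      repeat {
        reach[cur] <- TRUE
        m <- ext_mate(cur); reach[m] <- TRUE
        nxt <- partner[m]
        if (nxt == 0L) break
        cur <- nxt
      }
    }
    cyc <- which(!reach)
    in_cyc <- edges[, 1] %in% cyc & sel
    cand <- which(in_cyc)
    cand <- cand[order(w[cand], edges[cand, 1], edges[cand, 2])]
    i <- cand[1]
    partner[edges[i, 1]] <- 0L
    partner[edges[i, 2]] <- 0L
    sel[i] <- FALSE
    broken <- broken + 1L
  }
  if (broken > 0L)
    message("breakpoint_median: broke ", broken,
            " cycle(s) at their lightest edge")
  g <- canonical_genome(block_genome(chrs, name = "bp_median"))
  attr(g, "matching_weight") <- weight
  attr(g, "broken_cycles") <- broken
  g
}

# exact maximum-weight matching on a sparse edge list, component-wise
# branch-and-bound with a greedy half-incident-weight bound
max_weight_matching <- function(n2, edges, w) {
  m <- nrow(edges)
  sel <- logical(m)
  if (m == 0L) return(sel)
  inc <- vector("list", n2)
  for (i in seq_len(m)) {
    inc[[edges[i, 1]]] <- c(inc[[edges[i, 1]]], i)
    inc[[edges[i, 2]]] <- c(inc[[edges[i, 2]]], i)
  }
  # connected components over vertices touched by edges
  comp <- integer(n2)
  nc <- 0L
  for (v in unique(as.vector(t(edges)))) {
    if (comp[v] != 0L) next
    nc <- nc + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      if (comp[u] != 0L) next
      comp[u] <- nc
      for (i in inc[[u]])
        queue <- c(queue, setdiff(edges[i, ], u))
    }
  }
  for (cc in seq_len(nc)) {
    vs <- which(comp == cc)
    es <- which(edges[, 1] %in% vs)
    best <- list(weight = -1, sel = logical(length(es)))
    maxw <- vapply(vs, function(v) max(c(0, w[intersect(inc[[v]], es)])),
                   numeric(1))
    names(maxw) <- vs
    rec <- function(k, used, cur, cur_sel, pot) {
      if (cur + pot <= best$weight) return()
      if (k > length(es)) {
        if (cur > best$weight) best <<- list(weight = cur, sel = cur_sel)
        return()
      }
      i <- es[k]
      a <- edges[i, 1]; b <- edges[i, 2]
      pot_k <- pot
      # take edge i
      if (!used[a] && !used[b]) {
        used2 <- used; used2[a] <- used2[b] <- TRUE
        cs <- cur_sel; cs[k] <- TRUE
        rec(k + 1L, used2, cur + w[i],
            cs, pot_k - maxw[as.character(a)] / 2 - maxw[as.character(b)] / 2)
      }
      # skip edge i
      rec(k + 1L, used, cur, cur_sel, pot_k)
    }
    used0 <- logical(n2)
    rec(1L, used0, 0, logical(length(es)), sum(maxw) / 2)
    sel[es] <- best$sel
  }
  sel
}

#' Distance profile of an enumerated median set
#'
#' For each enumerated median, the DCJ distances to the three input genomes;
#' the per-genome means are the natural summary of where the median set sits
#' relative to the leaves.
#'
#' @param result a [median_result][dcj_median] with at least one median.
#' @param A,B,C the input genomes.
#' @return a data.frame with one row per median and columns `d_A`, `d_B`,
#'   `d_C` (named after the genomes), plus attribute `means`.
#' @export
median_distance_profile <- function(result, A, B, C) {
  if (!length(result$medians)) stop("empty median result")
  rows <- lapply(result$medians, function(m)
    c(dcj_distance(m, A), dcj_distance(m, B), dcj_distance(m, C)))
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- paste0("d_", c(A$name, B$name, C$name))
  attr(out, "means") <- colMeans(out)
  out
}
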