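#' Conserved syntenies and chromosome length fractions
#'
#' For every chromosome `i` of genome `B`, counts the number `c^(i)` of
#' distinct chromosomes of genome `A` contributing at least one block to `i`
#' (the number of conserved syntenies on `i`), and computes the gene-length
#' fractions `p` (chromosomes of A) and `q` (chromosomes of B).  These are
#' the observables of the probabilistic translocation-count estimator.
#'
#' @param A,B [block_genome] objects with identical unsigned block content.
#' @param block_lengths gene counts per block: a numeric vector named by
#'   block id, or `NULL` for unit lengths.
#' @return list with elements `c_i` (integer per B chromosome), `p`, `q`
#'   (length fractions summing to 1), `c`, `d` (chromosome counts of A and
#'   B) and `S = sum(c_i)`.
#' @export
conserved_syntenies <- function(A, B, block_lengths = NULL) {
  ids <- content_map(A, B)
  if (is.null(block_lengths)) {
    block_lengths <- rep(1, length(ids))
    names(block_lengths) <- ids
  }
  if (is.null(names(block_lengths)))
    names(block_lengths) <- ids
  len_of <- function(chr) sum(block_lengths[as.character(abs(chr))])
  chrom_of_A <- integer(max(ids))
  for (i in seq_along(A$chromosomes))
    chrom_of_A[abs(A$chromosomes[[i]])] <- i
  c_i <- vapply(B$chromosomes, function(chr)
    length(unique(chrom_of_A[abs(chr)])), integer(1))
  p <- vapply(A$chromosomes, len_of, numeric(1))
  q <- vapply(B$chromosomes, len_of, numeric(1))
  list(c_i = c_i, p = p / sum(p), q = q / sum(q),
       c = length(A$chromosomes), d = length(B$chromosomes),
       S = sum(c_i))
}

#' Estimate the translocation count from conserved syntenies
#'
#' A non-constructive probabilistic estimator of the number of
#' translocations `t` separating genome B from genome A, driven only by the
#' conserved-synteny counts `c^(i)` and the chromosome length fractions.
#' Assuming a uniform density of breakpoints, the chromosome that partners
#' chromosome `i` in a translocation is `j` with probability
#' `p_i(j) = p(j) / (1 - p(i))`, and after `t^(i)` translocations chromosome
#' `i` carries no fragment of `j` with probability about
#' `(1 - p_i(j))^{t^(i)}` (second-order events neglected).  With
#' `t^(i) = 2 t p(i)` this yields three solvable moment equations:
#'
#' * `eq5` (equal chromosome numbers):
#'   `c^2 - S = sum_i sum_{j != i} (1 - p_i(j))^{2 t p(i)}`
#' * `eq6` (general): `c d - S = ((d-1)/d) sum_i sum_j (1 - q(j))^{2 p(i) t}`
#' * `eq7` (near-equal chromosome lengths, closed form):
#'   `1 - S/(c d) = (1 - 1/d)^{1 + 2 t / c}`
#'
#' where `S = sum_i c^(i)`.  `factor2_omitted = TRUE` drops the factor 2
#' (appropriate when breakpoint reuse is high, where each translocation
#' effectively marks only one chromosome); this exactly doubles the `eq7`
#' estimate and so only rescales comparisons, it is not a consistent
#' estimator of `t` itself.
#'
#' @param est_input output of [conserved_syntenies()] (or a compatible list
#'   with `c_i`, `p`, `q`, `c`, `d`).
#' @param variant one of `"eq7"` (default), `"eq6"`, `"eq5"`.
#' @param factor2_omitted drop the factor 2 in `t^(i) = 2 t p(i)` (default
#'   `TRUE`, the scale used for resolution-trend comparisons).
#' @param tol bisection tolerance for `eq5`/`eq6` (default 1e-9).
#' @return object of class `translocation_estimate`: list with `t_hat`,
#'   `variant`, `factor2_omitted` and the inputs.
#' @export
estimate_t <- function(est_input, variant = c("eq7", "eq6", "eq5"),
                       factor2_omitted = TRUE, tol = 1e-9) {
  variant <- match.arg(variant)
  c_i <- est_input$c_i
  p <- est_input$p
  q <- est_input$q
  cc <- est_input$c
  d <- est_input$d
  S <- sum(c_i)
  if (any(c_i < 1L) || any(c_i > cc))
    stop("conserved-synteny counts must satisfy 1 <= c^(i) <= c")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop("chromosome length fractions must sum to 1")
  if (d < 2L) stop("degenerate: translocations undefined for d = 1")
  K <- if (factor2_omitted) 1 else 2
  if (variant == "eq7") {
    if (S >= cc * d)
      stop("S = sum(c_i) >= c*d: estimate is infinite (complete mixing)")
    t_hat <- (cc / K) * (log(1 - S / (cc * d)) / log(1 - 1 / d) - 1)
  } else {
    if (variant == "eq5") {
      if (length(c_i) != cc)
        stop("eq5 assumes equal chromosome numbers (c = d); use eq6")
      lhs <- cc^2 - S
      rhs <- function(t) {
        tot <- 0
        for (i in seq_len(cc)) {
          pij <- p[-i] / (1 - p[i])
          tot <- tot + sum((1 - pij)^(K * t * p[i]))
        }
        tot
      }
    } else {
      lhs <- cc * d - S
      rhs <- function(t) {
        (d - 1) / d * sum(outer(p, q, function(pi, qj) (1 - qj)^(K * pi * t)))
      }
    }
    if (lhs >= rhs(0)) {
      t_hat <- 0
    } else {
      lo <- 0
      hi <- 50 * cc * d
      while (rhs(hi) > lhs) hi <- hi * 2
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (rhs(mid) > lhs) lo <- mid else hi <- mid
      }
      t_hat <- (lo + hi) / 2
    }
  }
  if (t_hat < 0) {
    warning("negative estimate clamped to 0")
    t_hat <- 0
  }
  structure(list(t_hat = t_hat, variant = variant,
                 factor2_omitted = factor2_omitted, c_i = c_i, p = p, q = q,
                 c = cc, d = d, S = S),
            class = "translocation_estimate")
}

#' @export
print.translocation_estimate <- function(x, ...) {
  cat("<translocation_estimate> t_hat = ", format(x$t_hat, digits = 4),
      " (", x$variant, if (x$factor2_omitted) ", factor 2 omitted" else "",
      "; c = ", x$c, ", d = ", x$d, ", S = ", x$S, ")\n", sep = "")
  invisible(x)
}

#' Simulate a pure translocation history
#'
#' Applies `t` reciprocal translocations to a genome, picking the two
#' breakpoints uniformly by gene length across distinct chromosomes
#' (interior gene boundaries only), as the estimator's model assumes.
#'
#' @param g a [block_genome] with at least two chromosomes.
#' @param t number of translocations.
#' @param block_lengths numeric vector named by block id, or `NULL` for unit
#'   lengths.
#' @return the rearranged [block_genome].
#' @export
apply_random_translocations <- function(g, t, block_lengths = NULL) {
  ids <- block_ids(g)
  if (is.null(block_lengths)) {
    block_lengths <- rep(1, length(ids))
    names(block_lengths) <- ids
  }
  chrs <- g$chromosomes
  if (length(chrs) < 2L) stop("need at least two chromosomes")
  for (k in seq_len(t)) {
    for (try in 1:50) {
      wlen <- vapply(chrs, function(chr)
        sum(block_lengths[as.character(abs(chr))]), numeric(1))
      ij <- sample.int(length(chrs), 2L, prob = wlen)
      c1 <- chrs[[ij[1]]]; c2 <- chrs[[ij[2]]]
      if (length(c1) < 2L || length(c2) < 2L) next
      # interior cut, uniform by gene length of the flanked boundary
      w1 <- block_lengths[as.character(abs(c1))]
      w2 <- block_lengths[as.character(abs(c2))]
      p1 <- sample.int(length(c1) - 1L, 1L,
                       prob = (w1[-length(w1)] + w1[-1]) / 2)
      p2 <- sample.int(length(c2) - 1L, 1L,
                       prob = (w2[-length(w2)] + w2[-1]) / 2)
      chrs[[ij[1]]] <- c(vec_head(c1, p1), vec_tail(c2, p2))
      chrs[[ij[2]]] <- c(vec_head(c2, p2), vec_tail(c1, p1))
      break
    }
  }
  block_genome(chrs, name = g$name)
}

#' Recovery experiment for the translocation estimator
#'
#' Simulates translocation histories of known size `t_true` on a genome with
#' `c` chromosomes, re-estimates `t` from the conserved-synteny counts, and
#' tabulates mean estimate, bias and RMSE.  The estimator is consistent only
#' in the small-`t` regime (second-order exchanges are neglected); for
#' `t_true` approaching `c^2` it systematically underestimates.
#'
#' Note `factor2_omitted = FALSE` here by default: the factor-2 form is the
#' estimator of `t`; the omitted form is exactly twice it and is only meant
#' for relative comparisons across resolution levels.
#'
#' @param c,d chromosome counts (translocations preserve the count, so the
#'   simulated `d` equals `c`; `d` is accepted for interface symmetry and
#'   must equal `c`).
#' @param n_blocks number of blocks distributed evenly over chromosomes.
#' @param t_true vector of true translocation counts to simulate.
#' @param reps replicates per `t_true`.
#' @param seed RNG seed.
#' @param variant,factor2_omitted passed to [estimate_t()].
#' @return data.frame with one row per `t_true`: `t_true`, `mean_t_hat`,
#'   `bias`, `rmse`, `reps`.
#' @export
recovery_experiment <- function(c = 8L, d = c, n_blocks = 400L, t_true = 0:10,
                                reps = 100L, seed = 1L, variant = "eq7",
                                factor2_omitted = FALSE) {
  if (d != c) stop("translocation-only histories preserve chromosome count")
  set.seed(seed)
  per <- n_blocks %/% c
  anc <- block_genome(split(seq_len(per * c), rep(seq_len(c), each = per)),
                      name = "ancestor")
  rows <- lapply(t_true, function(tt) {
    est <- vapply(seq_len(reps), function(r) {
      g <- apply_random_translocations(anc, tt)
      estimate_t(conserved_syntenies(anc, g), variant = variant,
                 factor2_omitted = factor2_omitted)$t_hat
    }, numeric(1))
    data.frame(t_true = tt, mean_t_hat = mean(est), bias = mean(est) - tt,
               rmse = sqrt(mean((est - tt)^2)), reps = reps)
  })
  do.call(rbind, rows)
}
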