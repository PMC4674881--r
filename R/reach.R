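#' The empty xy-polynomial
#'
#' The reachability computation maintains a growing polynomial over the set
#' of already-processed edges. Each non-free term records one partial edge
#' configuration (the subset of processed edges assumed present) and its
#' probability; two free coefficients accumulate the probability mass of
#' configurations already decided reachable (`b`, the coefficient of the
#' free variable for "target reachable") or unreachable (`c`).
#'
#' Total probability is conserved at every step: `b + c + sum(coeff) == 1`.
#'
#' @return an `xy_polynomial`: list with `processed` (integer edge indices),
#'   `present` (list of integer vectors, one per non-free term), `coeff`
#'   (numeric term probabilities), and scalars `b`, `c`.
#' @seealso [multiply_binomial()], [collapse_polynomial()], [reachability()]
#' @export
xy_polynomial <- function() {
  structure(
    list(processed = integer(0), present = list(integer(0)), coeff = 1,
         b = 0, c = 0),
    class = "xy_polynomial"
  )
}

#' @export
print.xy_polynomial <- function(x, ...) {
  cat(sprintf("xy-polynomial over %d processed edge(s): %d live term(s), b = %.6g, c = %.6g\n",
              length(x$processed), length(x$coeff), x$b, x$c))
  invisible(x)
}

#' Multiply an edge binomial into the polynomial
#'
#' Edge `e` with existence probability `p` contributes the binomial
#' `p*x_e + (1-p)*y_e`. Each live term splits into a present branch
#' (coefficient times `p`, with `e` added to its present set) and an absent
#' branch (coefficient times `1-p`). The free coefficients are unchanged:
#' the free variables absorb both branches (`b*p + b*(1-p) = b`). Branches
#' with exactly zero coefficient (p equal to 0 or 1) are dropped.
#'
#' @param F an `xy_polynomial`.
#' @param e integer edge index, not yet processed.
#' @param p existence probability in `[0, 1]`.
#' @return the updated `xy_polynomial` with `e` added to `processed`.
#' @export
multiply_binomial <- function(F, e, p) {
  e <- as.integer(e)
  if (e %in% F$processed) stop("edge ", e, " already processed")
  if (!is.finite(p) || p < 0 || p > 1) stop("probability outside [0, 1]")
  q <- 1 - p
  pres <- c(
    if (p > 0) lapply(F$present, function(s) c(s, e)),
    if (q > 0) F$present
  )
  co <- c(
    if (p > 0) F$coeff * p,
    if (q > 0) F$coeff * q
  )
  F$processed <- c(F$processed, e)
  F$present <- pres
  F$coeff <- co
  F
}

#' Does an edge subset contain a source-to-target path?
#'
#' @param net a `probnet`.
#' @param present integer vector of edge indices assumed present.
#' @param sources,targets node identifier sets. A node lying in both sets
#'   counts as a zero-length path, so the answer is `TRUE` regardless of
#'   `present`.
#' @return `TRUE` iff the directed graph restricted to `present` contains a
#'   path from some source to some target.
#' @export
has_path <- function(net, present, sources = net$sources,
                     targets = net$targets) {
  idx <- .net_index(net)
  s <- match(sources, net$nodes); t <- match(targets, net$nodes)
  if (anyNA(s) || anyNA(t)) stop("sources/targets must be network nodes")
  any(.reach_set(idx, as.integer(present), s)[t])
}

#' Does an absent edge subset cut all source-to-target paths?
#'
#' @param net a `probnet`.
#' @param absent integer vector of edge indices assumed absent.
#' @param sources,targets node identifier sets.
#' @return `TRUE` iff the graph containing every edge except those in
#'   `absent` has no path from sources to targets -- i.e. even if every
#'   undecided edge turns out to exist, the targets stay unreachable.
#' @export
is_cut <- function(net, absent, sources = net$sources,
                   targets = net$targets) {
  rest <- setdiff(seq_len(nrow(net$edges)), as.integer(absent))
  !has_path(net, rest, sources, targets)
}

#' Collapse decided terms into the free coefficients
#'
#' Applies the two collapse rules to every live term: if the term's present
#' edge set already contains a source-to-target path, the term's probability
#' moves to `b` (decided reachable); otherwise, if its absent edge set
#' (processed minus present) is a cut -- no path can exist even if all
#' remaining edges are present -- the probability moves to `c` (decided
#' unreachable). Surviving terms are neither decided reachable nor decided
#' unreachable. Collapsing is idempotent and conserves total probability.
#'
#' @param F an `xy_polynomial`.
#' @param net the `probnet` the edge indices refer to.
#' @param sources,targets node identifier sets.
#' @return the collapsed `xy_polynomial`.
#' @export
collapse_polynomial <- function(F, net, sources = net$sources,
                                targets = net$targets) {
  if (!length(F$coeff)) return(F)
  idx <- .net_index(net)
  s <- match(sources, net$nodes); t <- match(targets, net$nodes)
  if (anyNA(s) || anyNA(t)) stop("sources/targets must be network nodes")
  m <- nrow(net$edges)
  keep <- logical(length(F$coeff))
  b_add <- 0; c_add <- 0
  # memoize path/cut verdicts per edge-set key within this pass
  memo <- new.env(parent = emptyenv())
  check <- function(edge_set, s, t) {
    key <- paste0("k", paste(edge_set, collapse = ","))
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    res <- any(.reach_set(idx, edge_set, s)[t])
    memo[[key]] <- res
    res
  }
  all_edges <- seq_len(m)
  for (i in seq_along(F$coeff)) {
    pres <- F$present[[i]]
    if (check(pres, s, t)) {
      b_add <- b_add + F$coeff[i]
    } else {
      absent <- setdiff(F$processed, pres)
      possible <- setdiff(all_edges, absent)
      if (!any(.reach_set(idx, possible, s)[t])) {
        c_add <- c_add + F$coeff[i]
      } else {
        keep[i] <- TRUE
      }
    }
  }
  F$b <- F$b + b_add
  F$c <- F$c + c_add
  F$present <- F$present[keep]
  F$coeff <- F$coeff[keep]
  F
}

#' Deterministic edge processing order
#'
#' Orders edges breadth-first from the source set over the underlying
#' topology (distance of the edge's tail node from the sources), ties broken
#' by input edge index; edges whose tail is unreachable from the sources are
#' appended in input order. The reachability value does not depend on the
#' order (a tested property); processing source-adjacent edges first merely
#' lets path/cut collapses trigger early, keeping the polynomial small.
#'
#' @param net a `probnet`.
#' @param sources node set to start from (defaults to the network's).
#' @return an integer permutation of `seq_len(nrow(net$edges))`.
#' @export
edge_order <- function(net, sources = net$sources) {
  idx <- .net_index(net)
  m <- nrow(net$edges)
  if (m == 0) return(integer(0))
  s <- match(sources, net$nodes)
  if (anyNA(s)) stop("sources must be network nodes")
  dist <- rep(Inf, idx$n)
  dist[s] <- 0
  frontier <- s
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- unique(idx$head[idx$tail %in% frontier])
    nxt <- nxt[dist[nxt] > d]
    dist[nxt] <- d
    frontier <- nxt
  }
  order(dist[idx$tail], seq_len(m))
}

#' Exact signal reachability probability
#'
#' Computes the probability that a signal propagates from at least one
#' source to at least one target, i.e. the total probability mass of the
#' deterministic instances (edge subsets) that contain a directed
#' source-to-target path. Edges are assumed to exist independently with
#' their stated probabilities.
#'
#' The computation multiplies one binomial per edge into an xy-polynomial
#' and, after every multiplication, collapses terms that are already decided
#' (present set contains a path, or absent set is a cut) into the free
#' reachable/unreachable coefficients, which keeps the number of live terms
#' far below the worst-case `2^|E|`. Before building the polynomial, edges
#' that cannot lie on any source-to-target path (tail unreachable from the
#' sources, or head that never reaches a target) are dropped; their
#' marginalization cannot change the result.
#'
#' @param net a `probnet`.
#' @param sources,targets non-empty node identifier sets (default: the
#'   network's receptor and reporter sets). A node in both sets makes the
#'   result 1 (zero-length path).
#' @param order optional explicit edge processing order (integer permutation
#'   of the edge indices); default [edge_order()]. Exposed mainly for the
#'   order-invariance tests.
#' @param debug if `TRUE`, assert after every multiplication and collapse
#'   that `b + c + sum(coeff)` equals 1 within `1e-12`, and that no live
#'   term survives the final edge.
#' @param term_cap stop with a resource error if the number of live terms
#'   ever exceeds this cap (default `2^22`); the theoretical worst case is
#'   exponential in the edge count.
#' @return the reachability probability, a number in `[0, 1]`.
#' @examples
#' net <- probnet(data.frame(from = c("s", "s", "v", "w"),
#'                           to = c("v", "w", "t", "t"),
#'                           p = 0.5),
#'                sources = "s", targets = "t")
#' reachability(net) # 0.4375 = 1 - (1 - 0.25)^2
#' @export
reachability <- function(net, sources = net$sources, targets = net$targets,
                         order = NULL, debug = FALSE, term_cap = 2^22) {
  sources <- unique(as.character(sources))
  targets <- unique(as.character(targets))
  if (length(sources) == 0 || length(targets) == 0) {
    stop("sources and targets must be non-empty")
  }
  if (!all(sources %in% net$nodes) || !all(targets %in% net$nodes)) {
    stop("sources/targets must be subsets of the node set")
  }
  if (length(intersect(sources, targets))) return(1)
  m <- nrow(net$edges)
  if (m == 0) return(0)

  if (is.null(order)) {
    # prune edges that cannot appear on any source->target path
    idx <- .net_index(net)
    s <- match(sources, net$nodes); t <- match(targets, net$nodes)
    fwd <- .reach_set(idx, seq_len(m), s)
    ridx <- list(n = idx$n, tail = idx$head, head = idx$tail)
    bwd <- .reach_set(ridx, seq_len(m), t)
    relevant <- which(fwd[idx$tail] & bwd[idx$head])
    if (!length(relevant)) return(0)
    sub <- probnet(net$edges[relevant, , drop = FALSE],
                   sources = sources, targets = targets,
                   nodes = unique(c(net$edges$from[relevant],
                                    net$edges$to[relevant],
                                    sources, targets)))
    ord <- edge_order(sub, sources)
  } else {
    ord <- as.integer(order)
    if (length(ord) != m || anyDuplicated(ord) ||
        any(ord < 1) || any(ord > m)) {
      stop("order must be a permutation of the edge indices")
    }
    sub <- net
  }

  .reach_engine(sub, sources, targets, ord, debug = debug,
                term_cap = term_cap)
}

# Vectorized xy-polynomial engine. Semantically identical to repeated
# multiply_binomial() + collapse_polynomial() (the exported step-by-step
# primitives), but live terms are held as one logical matrix (terms x
# edges, TRUE = edge present) so that the path and cut checks for all
# terms run as fixed-point sweeps over whole columns instead of one BFS
# per term.
.reach_engine <- function(net, sources, targets, ord, debug = FALSE,
                          term_cap = 2^22) {
  idx <- .net_index(net)
  m <- nrow(net$edges)
  s <- match(sources, net$nodes)
  t_ids <- match(targets, net$nodes)

  P <- matrix(FALSE, nrow = 1, ncol = m)     # term x edge presence
  coeff <- 1
  processed <- logical(m)
  b <- 0; c <- 0

  # closure over, per term, the edges marked present in `pres` (a terms x m
  # logical matrix); returns terms x 1 logical: some target reached
  reaches <- function(pres, cols) {
    k <- nrow(pres)
    visited <- matrix(FALSE, nrow = k, ncol = idx$n)
    visited[, s] <- TRUE
    repeat {
      changed <- FALSE
      for (j in cols) {
        upd <- pres[, j] & visited[, idx$tail[j]] & !visited[, idx$head[j]]
        if (any(upd)) {
          visited[upd, idx$head[j]] <- TRUE
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    rowSums(visited[, t_ids, drop = FALSE]) > 0
  }

  for (e in ord) {
    p <- net$edges$p[e]
    k <- nrow(P)
    # multiply the binomial p*x_e + (1-p)*y_e into every live term
    if (p >= 1) {
      P[, e] <- TRUE
    } else if (p > 0) {
      P <- rbind(P, P)
      P[seq_len(k), e] <- TRUE
      coeff <- c(coeff * p, coeff * (1 - p))
    }
    processed[e] <- TRUE
    if (debug && abs(b + c + sum(coeff) - 1) > 1e-12) {
      stop("conservation violated after multiply")
    }
    # collapse: present set contains a path -> b; absent set is a cut
    # (even all undecided edges present reach no target) -> c
    path <- reaches(P, which(processed))
    possible <- P
    if (any(!processed)) possible[, !processed] <- TRUE
    cut <- !reaches(possible, seq_len(m))
    b <- b + sum(coeff[path])
    c <- c + sum(coeff[cut & !path])
    keep <- !path & !cut
    P <- P[keep, , drop = FALSE]
    coeff <- coeff[keep]
    if (debug && abs(b + c + sum(coeff) - 1) > 1e-12) {
      stop("conservation violated after collapse")
    }
    if (length(coeff) > term_cap) {
      stop(sprintf("live-term count %d exceeds term cap %d",
                   length(coeff), term_cap))
    }
  }
  if (length(coeff)) {
    # every fully decided instance has a path or a cut, so this cannot
    # happen once all edges are processed
    stop("internal error: undecided terms after processing all edges")
  }
  if (debug && abs(b + c - 1) > 1e-12) {
    stop("internal error: b + c != 1 after final edge")
  }
  b
}

.check_conservation <- function(F, where) {
  tot <- F$b + F$c + sum(F$coeff)
  if (abs(tot - 1) > 1e-12) {
    stop(sprintf("conservation violated after %s: total %.17g", where, tot))
  }
  if (any(F$coeff < 0) || F$b < 0 || F$c < 0) {
    stop("negative coefficient in xy-polynomial")
  }
  invisible(TRUE)
}

#' Brute-force reachability by enumerating deterministic instances
#'
#' Enumerates all `2^|E|` deterministic instances (subsets of present
#' edges), computes each instance's probability as the product of its
#' present-edge probabilities and absent-edge complements, and sums the
#' probabilities of the instances containing a source-to-target path. Exact
#' up to floating-point summation; serves as the independent oracle for
#' [reachability()] and is deliberately implemented on a different principle
#' (full enumeration plus fixed-point closure, no polynomial).
#'
#' @inheritParams reachability
#' @param max_edges refuse networks with more edges than this (default 20;
#'   the enumeration is exponential).
#' @return the reachability probability.
#' @export
reachability_bruteforce <- function(net, sources = net$sources,
                                    targets = net$targets, max_edges = 20) {
  sources <- unique(as.character(sources))
  targets <- unique(as.character(targets))
  if (length(sources) == 0 || length(targets) == 0) {
    stop("sources and targets must be non-empty")
  }
  if (length(intersect(sources, targets))) return(1)
  m <- nrow(net$edges)
  if (m > max_edges) {
    stop(sprintf("%d edges exceeds enumeration bound %d", m, max_edges))
  }
  if (m == 0) return(0)
  idx <- .net_index(net)
  s <- match(sources, net$nodes); t <- match(targets, net$nodes)
  k <- 2^m
  bits <- matrix(FALSE, nrow = k, ncol = m)
  for (j in seq_len(m)) {
    bits[, j] <- rep(c(FALSE, TRUE), each = 2^(j - 1), length.out = k)
  }
  prob <- rep(1, k)
  for (j in seq_len(m)) {
    prob <- prob * ifelse(bits[, j], idx$p[j], 1 - idx$p[j])
  }
  visited <- matrix(FALSE, nrow = k, ncol = idx$n)
  visited[, s] <- TRUE
  repeat {
    changed <- FALSE
    for (j in seq_len(m)) {
      upd <- bits[, j] & visited[, idx$tail[j]] & !visited[, idx$head[j]]
      if (any(upd)) {
        visited[upd, idx$head[j]] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  reach <- rowSums(visited[, t, drop = FALSE]) > 0
  sum(prob[reach])
}
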