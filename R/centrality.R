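#' Essentiality probability of a node for one source-target pair
#'
#' A node `v` is essential for the pair `(s, t)` in a deterministic instance
#' if removing `v` (with all its incident edges) disconnects `s` from `t`.
#' Its essentiality probability is the drop in reachability caused by the
#' removal:
#' `C_v(G, s, t) = P_reach(G, s, t) - P_reach(G', s, t)`,
#' where `G'` is the network without `v`. Removal can never increase
#' reachability, so the value lies in `[0, P_reach(G, s, t)]`; negative
#' floating-point noise within `1e-9` is clamped to zero, larger negatives
#' raise an internal-consistency error.
#'
#' @param net a `probnet`.
#' @param v the node whose essentiality is measured; must differ from `s`
#'   and `t`.
#' @param s,t single source and target node identifiers.
#' @return the essentiality probability in `[0, 1]`.
#' @export
pair_essentiality <- function(net, v, s, t) {
  if (!v %in% net$nodes) stop("node not in network: ", v)
  if (v %in% c(s, t)) {
    stop("essentiality is defined for intermediary nodes: v must differ from s and t")
  }
  before <- reachability(net, s, t)
  after <- reachability(remove_node(net, v), s, t)
  d <- before - after
  if (d < -1e-9) {
    stop(sprintf("internal error: node removal increased reachability by %g", -d))
  }
  max(d, 0)
}

#' Probabilistic node centrality
#'
#' The centrality of `v` is the expected number of source-target pairs for
#' which `v` is essential. The per-pair essentiality indicators are
#' independent-parameter Bernoulli variables, so their total follows a
#' Poisson-binomial distribution whose mean is simply the sum of the
#' per-pair essentiality probabilities:
#' `E[X_v] = sum over s in S, t in T of C_v(G, s, t)`.
#'
#' @param net a `probnet` with non-empty source and target sets.
#' @param v a node identifier.
#' @param include_terminal_pairs if `FALSE` (default), pairs where `v` is
#'   itself the source or the target are excluded from the sum: essentiality
#'   formalizes relay importance, and counting a receptor as essential for
#'   its own pairs would trivially inflate every terminal node's score. Set
#'   `TRUE` to instead count those pairs as fully essential (removal of an
#'   endpoint always disconnects the pair).
#' @return the expected essential-pair count, in `[0, |S| * |T|]`.
#' @seealso [centrality_table()] for all nodes at once with the
#'   deterministic-betweenness comparison.
#' @export
node_centrality <- function(net, v, include_terminal_pairs = FALSE) {
  if (!v %in% net$nodes) stop("node not in network: ", v)
  total <- 0
  for (s in net$sources) {
    for (t in net$targets) {
      if (s == t) next
      if (v %in% c(s, t)) {
        if (include_terminal_pairs) {
          total <- total + reachability(net, s, t)
        }
        next
      }
      total <- total + pair_essentiality(net, v, s, t)
    }
  }
  total
}

#' Deterministic betweenness centrality of the underlying topology
#'
#' Shortest-path betweenness on the directed underlying graph with every
#' edge treated as certainly present and unweighted, normalized by
#' `(|V| - 1) * (|V| - 2)`. This is the conventional deterministic
#' centrality against which the probabilistic measure is compared.
#'
#' @param net a `probnet`.
#' @return a named numeric vector over all nodes.
#' @export
deterministic_betweenness <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = net$nodes)
  )
  raw <- igraph::betweenness(g, directed = TRUE, weights = NA)
  n <- length(net$nodes)
  denom <- if (n > 2) (n - 1) * (n - 2) else 1
  out <- raw[net$nodes] / denom
  names(out) <- net$nodes
  out
}

#' Per-node disagreement between two centrality rankings
#'
#' For each node `x`, counts the nodes `y` whose position relative to `x`
#' differs between the two rankings (`y` more central than `x` in one and
#' less central in the other), normalized by the total number of nodes.
#' Pairs tied in either ranking count as agreeing.
#'
#' @param rank_a,rank_b either named numeric score vectors (ranked by
#'   descending score) or character vectors listing the nodes from most to
#'   least central. Both must cover the same node set.
#' @return a named numeric vector of per-node disagreement values in
#'   `[0, 1]`.
#' @export
rank_disagreement <- function(rank_a, rank_b) {
  as_scores <- function(r) {
    if (is.character(r)) {
      s <- rev(seq_along(r))
      names(s) <- r
      s
    } else {
      if (is.null(names(r))) stop("score vectors must be named by node")
      r
    }
  }
  a <- as_scores(rank_a)
  b <- as_scores(rank_b)
  if (!setequal(names(a), names(b)) || length(a) != length(b)) {
    stop("rankings must cover the same node set")
  }
  b <- b[names(a)]
  n <- length(a)
  out <- numeric(n)
  names(out) <- names(a)
  for (i in seq_len(n)) {
    da <- sign(a[i] - a)
    db <- sign(b[i] - b)
    out[i] <- sum(da * db < 0) / n
  }
  out
}

#' Centrality table: probabilistic vs deterministic centrality for all nodes
#'
#' Computes, for every node, the probabilistic centrality (expected
#' essential-pair count over all source-target pairs), the deterministic
#' betweenness of the underlying certain topology, the two descending ranks
#' (ties broken by node identifier), and the per-node rank disagreement.
#'
#' @param net a `probnet` with non-empty source and target sets.
#' @param include_terminal_pairs passed to [node_centrality()].
#' @return a data frame with columns `node`, `prob_centrality`,
#'   `det_betweenness`, `prob_rank`, `det_rank`, `disagreement`, ordered by
#'   `prob_rank`.
#' @export
centrality_table <- function(net, include_terminal_pairs = FALSE) {
  if (length(net$sources) == 0 || length(net$targets) == 0) {
    stop("network must have non-empty source and target sets")
  }
  nodes <- net$nodes
  prob <- vapply(nodes, function(v) {
    node_centrality(net, v, include_terminal_pairs = include_terminal_pairs)
  }, numeric(1))
  det <- deterministic_betweenness(net)[nodes]
  rank_by <- function(x) {
    ord <- order(-x, nodes)
    r <- integer(length(x))
    r[ord] <- seq_along(x)
    r
  }
  dis <- rank_disagreement(stats::setNames(prob, nodes),
                           stats::setNames(det, nodes))
  out <- data.frame(
    node = nodes,
    prob_centrality = unname(prob),
    det_betweenness = unname(det),
    prob_rank = rank_by(prob),
    det_rank = rank_by(det),
    disagreement = unname(dis[nodes]),
    stringsAsFactors = FALSE
  )
  out[order(out$prob_rank), , drop = FALSE]
}
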