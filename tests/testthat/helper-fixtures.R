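# Shared fixtures and independent oracles for the test suite.

# s -> a -> t chain with the given edge probabilities
fixture_chain <- function(p = c(0.5, 0.5)) {
  probnet(data.frame(from = c("s", "a"), to = c("a", "t"), p = p),
          sources = "s", targets = "t")
}

# s -> {v, w} -> t diamond, all edges with probability p
fixture_diamond <- function(p = 0.5) {
  probnet(data.frame(from = c("s", "s", "v", "w"),
                     to = c("v", "w", "t", "t"), p = p),
          sources = "s", targets = "t")
}

# Random directed network drawn from the *current* RNG stream:
# n_nodes in 4..10, up to max_edges edges, uniform probabilities, random
# disjoint source/target picks.
random_net <- function(max_nodes = 10, max_edges = 14) {
  n <- sample(4:max_nodes, 1)
  nodes <- paste0("n", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  m <- sample(3:max_edges, 1)
  e <- pairs[sample(nrow(pairs), min(m, nrow(pairs))), , drop = FALSE]
  e$p <- runif(nrow(e))
  S <- sample(nodes, sample(1:2, 1))
  T <- sample(setdiff(nodes, S), sample(1:2, 1))
  probnet(e, sources = S, targets = T, nodes = nodes)
}

# Independent betweenness oracle: enumerate every simple path between each
# ordered node pair, keep the shortest ones, and count fractions through
# each intermediate node. Exponential; only for tiny graphs.
betweenness_oracle <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  adj <- lapply(nodes, function(v) net$edges$to[net$edges$from == v])
  names(adj) <- nodes
  score <- stats::setNames(numeric(n), nodes)
  all_paths <- function(cur, goal, visited) {
    if (cur == goal) return(list(visited))
    out <- list()
    for (nx in adj[[cur]]) {
      if (!nx %in% visited) {
        out <- c(out, all_paths(nx, goal, c(visited, nx)))
      }
    }
    out
  }
  for (s in nodes) for (t in nodes) {
    if (s == t) next
    paths <- all_paths(s, t, s)
    if (!length(paths)) next
    len <- vapply(paths, length, integer(1))
    sp <- paths[len == min(len)]
    sigma <- length(sp)
    for (v in setdiff(nodes, c(s, t))) {
      through <- sum(vapply(sp, function(p) v %in% p, logical(1)))
      score[v] <- score[v] + through / sigma
    }
  }
  denom <- if (n > 2) (n - 1) * (n - 2) else 1
  score / denom
}

# Exhaustive hypergeometric upper-tail oracle: enumerate every size-d subset
# of 1..Tn, with 1..N the "annotated" elements, and count subsets containing
# at least n annotated ones.
hyper_tail_oracle <- function(Tn, N, d, n) {
  subsets <- utils::combn(Tn, d)
  hits <- colSums(subsets <= N) >= n
  mean(hits)
}

# Pairwise rank-disagreement oracle: direct double loop over strict order
# flips between two score vectors.
disagreement_oracle <- function(a, b) {
  b <- b[names(a)]
  n <- length(a)
  out <- stats::setNames(numeric(n), names(a))
  for (x in names(a)) {
    cnt <- 0
    for (y in names(a)) {
      if (x == y) next
      if ((a[x] > a[y] && b[x] < b[y]) || (a[x] < a[y] && b[x] > b[y])) {
        cnt <- cnt + 1
      }
    }
    out[x] <- cnt / n
  }
  out
}

# Minimal OBO fixture writer; `extra` appends raw lines.
write_obo <- function(terms, extra = character(0)) {
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  lines <- c("format-version: 1.2", "")
  for (tm in terms) {
    lines <- c(lines, "[Term]", paste0("id: ", tm$id))
    for (pa in tm$is_a %||% character(0)) {
      lines <- c(lines, paste0("is_a: ", pa, " ! parent"))
    }
    for (pa in tm$part_of %||% character(0)) {
      lines <- c(lines, paste0("relationship: part_of ", pa, " ! parent"))
    }
    lines <- c(lines, "")
  }
  writeLines(c(lines, extra), path)
  path
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# all 120 permutations of 1:5, one per row
gtools_permutations_5 <- function() {
  rec <- function(v) {
    if (length(v) == 1) return(matrix(v, 1))
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], rec(v[-i]))
    }))
  }
  unname(rec(1:5))
}
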