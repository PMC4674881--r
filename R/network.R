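#' Construct a probabilistic network
#'
#' A probabilistic network is a directed graph in which every edge carries an
#' independent existence probability, together with designated source
#' (receptor) and target (reporter) node sets. It summarizes `2^|E|`
#' deterministic instances, one per subset of edges assumed present.
#'
#' @param edges a data frame with character columns `from`, `to` and numeric
#'   column `p` (existence probability in `[0, 1]`). Row order is preserved
#'   and defines the edge indices used throughout the package.
#' @param sources character vector of source (receptor) node identifiers.
#' @param targets character vector of target (reporter) node identifiers.
#'   Sources and targets may overlap.
#' @param nodes optional character vector of node identifiers; defaults to
#'   the union of edge endpoints, sources and targets. Isolated nodes are
#'   allowed.
#' @param allow_empty_roles if `TRUE`, permit empty source/target sets
#'   (needed transiently, e.g. after [remove_node()] deletes the only
#'   receptor). Reachability queries always require non-empty sets.
#'
#' @return an object of class `probnet`: a list with elements `nodes`,
#'   `edges` (data frame `from`, `to`, `p`), `sources`, `targets`.
#'
#' @details Node identifiers are case-sensitive opaque strings. Self-loops
#'   and duplicate `(from, to)` pairs are rejected: a self-loop cannot lie on
#'   any source-to-target path and would break the cut logic, and the
#'   reachability polynomial associates exactly one binomial per edge, so
#'   parallel edges must be pre-merged by the user. Edges are directed;
#'   signals flow only along the edge direction.
#'
#' @examples
#' net <- probnet(
#'   data.frame(from = c("s", "a"), to = c("a", "t"), p = c(0.5, 0.5)),
#'   sources = "s", targets = "t"
#' )
#' reachability(net)
#' @export
probnet <- function(edges, sources, targets, nodes = NULL,
                    allow_empty_roles = FALSE) {
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(), p = numeric())
  }
  stopifnot(is.data.frame(edges))
  if (!all(c("from", "to", "p") %in% names(edges))) {
    stop("edges must have columns 'from', 'to', 'p'")
  }
  edges <- data.frame(from = as.character(edges$from),
                      to = as.character(edges$to),
                      p = as.numeric(edges$p),
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  sources <- as.character(sources)
  targets <- as.character(targets)
  if (is.null(nodes)) {
    nodes <- unique(c(edges$from, edges$to, sources, targets))
  } else {
    nodes <- unique(as.character(nodes))
  }
  net <- structure(
    list(nodes = nodes, edges = edges, sources = sources, targets = targets),
    class = "probnet"
  )
  validate_probnet(net, allow_empty_roles = allow_empty_roles)
  net
}

#' Validate a probabilistic network
#'
#' Checks the structural invariants of a [probnet()]: endpoints are known
#' nodes, no self-loops, no duplicate edges, probabilities in `[0, 1]`, and
#' sources/targets are subsets of the node set.
#'
#' @param net a `probnet` object.
#' @param allow_empty_roles if `FALSE` (default), sources and targets must be
#'   non-empty.
#' @return `net`, invisibly; errors describe the first violated invariant.
#' @export
validate_probnet <- function(net, allow_empty_roles = FALSE) {
  e <- net$edges
  if (anyDuplicated(net$nodes)) stop("duplicate node identifiers")
  bad <- !(e$from %in% net$nodes) | !(e$to %in% net$nodes)
  if (any(bad)) stop("edge endpoint not in node set: ",
                     e$from[bad][1], " -> ", e$to[bad][1])
  if (any(e$from == e$to)) {
    stop("self-loop not allowed: ", e$from[e$from == e$to][1])
  }
  key <- paste(e$from, e$to, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop("duplicate edge: ", e$from[i], " -> ", e$to[i])
  }
  if (any(!is.finite(e$p)) || any(e$p < 0) || any(e$p > 1)) {
    stop("edge probability outside [0, 1]")
  }
  if (!all(net$sources %in% net$nodes)) stop("source node not in node set")
  if (!all(net$targets %in% net$nodes)) stop("target node not in node set")
  if (!allow_empty_roles) {
    if (length(net$sources) == 0) stop("source set is empty")
    if (length(net$targets) == 0) stop("target set is empty")
  }
  invisible(net)
}

#' @export
print.probnet <- function(x, ...) {
  cat(sprintf(
    "Probabilistic signaling network: %d nodes, %d edges, %d sources, %d targets\n",
    length(x$nodes), nrow(x$edges), length(x$sources), length(x$targets)))
  if (nrow(x$edges) > 0) {
    cat(sprintf("  edge probabilities in [%.3g, %.3g]\n",
                min(x$edges$p), max(x$edges$p)))
  }
  invisible(x)
}

#' Normalize a raw confidence score to a probability
#'
#' Interaction databases on the STRING scale report confidence as an integer
#' in `[1, 1000]`, where 1000 means 100\% confidence. This converts such a
#' score to an existence probability by dividing by 1000.
#'
#' @param score numeric vector of scores in `[1, 1000]`.
#' @return `score / 1000`, a probability in `(0, 1]`.
#' @examples
#' normalize_confidence(1000) # 1.0
#' normalize_confidence(500)  # 0.5
#' @export
normalize_confidence <- function(score) {
  score <- as.numeric(score)
  if (any(!is.finite(score)) || any(score < 1) || any(score > 1000)) {
    stop("confidence score must be in [1, 1000]")
  }
  score / 1000
}

# Split non-comment TSV lines into fields, keeping original line numbers for
# error messages.
.read_tsv_lines <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE), lineno = keep)
}

#' Read a probabilistic network from edge-list and roles files
#'
#' @param edge_path path to a tab-separated edge list. Three columns:
#'   source node, target node, existence probability in `[0, 1]`. An optional
#'   fourth column carries a raw confidence score on the `[1, 1000]` scale;
#'   when present it is normalized by [normalize_confidence()] and used as
#'   the probability (overriding column 3). Lines starting with `#` and blank
#'   lines are ignored; no header.
#' @param roles_path path to a tab-separated roles file with two columns:
#'   node identifier and role, one of `source`, `target`, `internal`. A node
#'   may appear on several lines (e.g. both `source` and `target`).
#' @return a validated [probnet()]. The node set is the union of edge
#'   endpoints and role-file nodes.
#' @seealso [write_network()]
#' @export
read_network <- function(edge_path, roles_path) {
  el <- .read_tsv_lines(edge_path)
  n <- length(el$fields)
  from <- character(n); to <- character(n); p <- numeric(n)
  for (i in seq_len(n)) {
    f <- el$fields[[i]]
    if (length(f) < 3 || length(f) > 4) {
      stop(sprintf("%s line %d: expected 3 or 4 tab-separated fields, got %d",
                   edge_path, el$lineno[i], length(f)))
    }
    from[i] <- f[1]; to[i] <- f[2]
    if (length(f) == 4) {
      sc <- suppressWarnings(as.numeric(f[4]))
      if (is.na(sc)) stop(sprintf("%s line %d: non-numeric confidence score",
                                  edge_path, el$lineno[i]))
      p[i] <- normalize_confidence(sc)
    } else {
      pv <- suppressWarnings(as.numeric(f[3]))
      if (is.na(pv)) stop(sprintf("%s line %d: non-numeric probability",
                                  edge_path, el$lineno[i]))
      if (pv < 0 || pv > 1) {
        stop(sprintf("%s line %d: probability %g outside [0, 1]",
                     edge_path, el$lineno[i], pv))
      }
      p[i] <- pv
    }
  }
  rl <- .read_tsv_lines(roles_path)
  role_node <- character(0); role_kind <- character(0)
  for (i in seq_along(rl$fields)) {
    f <- rl$fields[[i]]
    if (length(f) != 2) {
      stop(sprintf("%s line %d: expected 2 tab-separated fields",
                   roles_path, rl$lineno[i]))
    }
    if (!f[2] %in% c("source", "target", "internal")) {
      stop(sprintf("%s line %d: unknown role '%s'", roles_path, rl$lineno[i],
                   f[2]))
    }
    role_node <- c(role_node, f[1]); role_kind <- c(role_kind, f[2])
  }
  probnet(
    edges = data.frame(from = from, to = to, p = p, stringsAsFactors = FALSE),
    sources = unique(role_node[role_kind == "source"]),
    targets = unique(role_node[role_kind == "target"]),
    nodes = unique(c(from, to, role_node))
  )
}

#' Write a probabilistic network to edge-list and roles files
#'
#' Emits the same tab-separated dialect that [read_network()] reads:
#' three-column edge list (probabilities printed with up to 12 significant
#' digits) and a two-column roles file listing, for every node in node-set
#' order, its `source` and/or `target` roles, or `internal`.
#'
#' @param net a `probnet`.
#' @param edge_path,roles_path output file paths.
#' @return `net`, invisibly.
#' @export
write_network <- function(net, edge_path, roles_path) {
  e <- net$edges
  writeLines(sprintf("%s\t%s\t%s", e$from, e$to,
                     vapply(e$p, function(x) format(x, digits = 12),
                            character(1))),
             edge_path)
  lines <- character(0)
  for (v in net$nodes) {
    rl <- character(0)
    if (v %in% net$sources) rl <- c(rl, "source")
    if (v %in% net$targets) rl <- c(rl, "target")
    if (length(rl) == 0) rl <- "internal"
    lines <- c(lines, paste(v, rl, sep = "\t"))
  }
  writeLines(lines, roles_path)
  invisible(net)
}

#' Remove a node and all its incident edges
#'
#' Constructs the modified network obtained by deleting `v` together with
#' every incoming and outgoing edge. Used by the centrality module to ask
#' how much the source-to-target reachability relies on `v`.
#'
#' @param net a `probnet`.
#' @param v a node identifier present in `net`.
#' @return a new `probnet` without `v`; `v` is also dropped from the source
#'   and target sets if present (which may leave them empty).
#' @export
remove_node <- function(net, v) {
  if (!v %in% net$nodes) stop("node not in network: ", v)
  keep <- net$edges$from != v & net$edges$to != v
  probnet(
    edges = net$edges[keep, , drop = FALSE],
    sources = setdiff(net$sources, v),
    targets = setdiff(net$targets, v),
    nodes = setdiff(net$nodes, v),
    allow_empty_roles = TRUE
  )
}

#' Attach virtual super-terminals for a set-to-set reachability query
#'
#' Adds one virtual super-source wired to every node of `src_set` and wires
#' every node of `tgt_set` to one virtual super-sink, all with existence
#' probability exactly 1. Reachability from the super-source to the
#' super-sink then equals the probability that at least one `tgt_set` node
#' is reachable from at least one `src_set` node.
#'
#' [reachability()] already accepts node sets directly (its path and cut
#' checks are defined on sets); this explicit construction is provided as
#' the equivalent reduction, and the equality is part of the test suite.
#'
#' @param net a `probnet`.
#' @param src_set,tgt_set non-empty subsets of the node set.
#' @return a `probnet` whose sources are the single super-source and whose
#'   targets are the single super-sink. Virtual node names avoid collision
#'   with existing identifiers.
#' @export
augment_terminals <- function(net, src_set, tgt_set) {
  src_set <- unique(as.character(src_set))
  tgt_set <- unique(as.character(tgt_set))
  if (length(src_set) == 0 || length(tgt_set) == 0) {
    stop("src_set and tgt_set must be non-empty")
  }
  if (!all(src_set %in% net$nodes) || !all(tgt_set %in% net$nodes)) {
    stop("src_set/tgt_set must be subsets of the node set")
  }
  ss <- ".SUPER_SOURCE"; tt <- ".SUPER_SINK"
  while (ss %in% net$nodes) ss <- paste0(ss, ".")
  while (tt %in% net$nodes) tt <- paste0(tt, ".")
  extra <- data.frame(
    from = c(rep(ss, length(src_set)), tgt_set),
    to = c(src_set, rep(tt, length(tgt_set))),
    p = 1,
    stringsAsFactors = FALSE
  )
  probnet(
    edges = rbind(net$edges, extra),
    sources = ss, targets = tt,
    nodes = c(net$nodes, ss, tt)
  )
}

# Internal: integer-indexed view of a network for the graph algorithms.
.net_index <- function(net) {
  list(
    n = length(net$nodes),
    tail = match(net$edges$from, net$nodes),
    head = match(net$edges$to, net$nodes),
    p = net$edges$p
  )
}

# Internal: node indices reachable from `start` (indices) using the edge
# subset `present` (edge indices), by fixed-point sweeps.
.reach_set <- function(idx, present, start) {
  visited <- logical(idx$n)
  visited[start] <- TRUE
  if (length(present)) {
    et <- idx$tail[present]; eh <- idx$head[present]
    repeat {
      new <- eh[visited[et] & !visited[eh]]
      if (!length(new)) break
      visited[new] <- TRUE
    }
  }
  visited
}

# Internal RNG scoping: evaluate `code` under set.seed(seed), restoring the
# caller's RNG state afterwards. seed = NULL leaves the RNG stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
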