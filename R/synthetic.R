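#' Generate a layered synthetic probabilistic signaling network
#'
#' Emulates the receptor-to-reporter structure of a signaling pathway: a
#' layer of source nodes (receptors), a layer of internal relays, and a
#' layer of target nodes (reporters), with directed edges sampled
#' independently between consecutive layers and existence probabilities
#' drawn uniformly from `prob_range`. Every target is guaranteed to be
#' topologically reachable from at least one source (extra edges are added
#' where sampling left a target stranded), so the all-edges-present
#' topology reaches every reporter.
#'
#' Optionally, the first `boosted_targets` targets are given systematically
#' more reliable paths: the probabilities of their incoming edges, and of
#' the edges feeding their parent relays, are raised by
#' `p <- p + boost * (1 - p)`. This plants a high-reachability signal used
#' by the planted-enrichment recovery experiments.
#'
#' @param n_sources,n_internal,n_targets layer sizes (positive integers).
#' @param density probability of each possible between-layer edge, in
#'   `(0, 1]` (default 0.4).
#' @param prob_range range for uniform edge probabilities
#'   (default `c(0.2, 0.95)`, a spread comparable to normalized interaction
#'   confidence scores).
#' @param boosted_targets number of targets receiving boosted paths
#'   (default 0).
#' @param boost path-probability boost in `[0, 1]` (default 0.5).
#' @param seed optional integer seed; identical seeds give identical
#'   networks, and the caller's RNG state is restored.
#' @return a validated `probnet` with node names `S1..`, `M1..`, `T1..`.
#' @export
generate_network <- function(n_sources = 3, n_internal = 6, n_targets = 10,
                             density = 0.4, prob_range = c(0.2, 0.95),
                             boosted_targets = 0, boost = 0.5, seed = NULL) {
  stopifnot(n_sources >= 1, n_internal >= 1, n_targets >= 1,
            density > 0, density <= 1,
            length(prob_range) == 2, prob_range[1] >= 0, prob_range[2] <= 1,
            prob_range[1] <= prob_range[2],
            boosted_targets >= 0, boosted_targets <= n_targets,
            boost >= 0, boost <= 1)
  with_seed(seed, {
    src <- paste0("S", seq_len(n_sources))
    mid <- paste0("M", seq_len(n_internal))
    tgt <- paste0("T", seq_len(n_targets))
    draw_layer <- function(a, b) {
      grid <- expand.grid(from = a, to = b, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
      grid[stats::runif(nrow(grid)) < density, , drop = FALSE]
    }
    e1 <- draw_layer(src, mid)
    e2 <- draw_layer(mid, tgt)
    # connectivity guarantee: every target must sit behind a relay that a
    # source feeds
    fed <- unique(e1$to)
    if (!length(fed)) {
      m <- sample(mid, 1)
      e1 <- rbind(e1, data.frame(from = sample(src, 1), to = m,
                                 stringsAsFactors = FALSE))
      fed <- m
    }
    for (t in tgt) {
      parents <- e2$from[e2$to == t]
      if (!any(parents %in% fed)) {
        m <- if (length(fed) > 1) sample(fed, 1) else fed
        if (any(e2$from == m & e2$to == t)) next
        e2 <- rbind(e2, data.frame(from = m, to = t,
                                   stringsAsFactors = FALSE))
      }
    }
    edges <- rbind(e1, e2)
    edges$p <- stats::runif(nrow(edges), prob_range[1], prob_range[2])
    if (boosted_targets > 0) {
      btgt <- tgt[seq_len(boosted_targets)]
      in_b <- edges$to %in% btgt
      feeders <- unique(edges$from[in_b])
      in_f <- edges$to %in% feeders
      raise <- in_b | in_f
      edges$p[raise] <- edges$p[raise] + boost * (1 - edges$p[raise])
    }
    probnet(edges, sources = src, targets = tgt,
            nodes = c(src, mid, tgt))
  })
}

#' Generate a synthetic annotation table, optionally with a planted term
#'
#' Assigns each network node 1 to 4 terms drawn uniformly from a synthetic
#' term pool. If a planted term is requested, it is additionally assigned to
#' the `planted_count` targets with the highest set-source reachability
#' (computed with [reachability()]) and to one source, so the planted term
#' is both enrichable (its targets occupy the top reachability ranks) and
#' applicable to term-reachability analysis.
#'
#' @param net a `probnet`.
#' @param n_terms size of the background term pool (default 8); term ids are
#'   `GO:SYN0001` style synthetic identifiers.
#' @param terms_per_gene range of background terms per gene
#'   (default `c(1, 4)`).
#' @param planted_term optional identifier for the planted term
#'   (e.g. `"GO:PLANTED"`); `NULL` plants nothing.
#' @param planted_count number of top-reachability targets annotated with
#'   the planted term; must not exceed the target count.
#' @param seed optional integer seed (RNG state restored).
#' @return an annotation data frame with columns `gene`, `term`.
#' @export
generate_annotations <- function(net, n_terms = 8, terms_per_gene = c(1, 4),
                                 planted_term = NULL, planted_count = 0,
                                 seed = NULL) {
  stopifnot(n_terms >= 1, planted_count >= 0)
  if (planted_count > length(net$targets)) {
    stop("planted_count exceeds the number of targets")
  }
  pool <- sprintf("GO:SYN%04d", seq_len(n_terms))
  with_seed(seed, {
    rows <- lapply(net$nodes, function(g) {
      k <- sample(seq(terms_per_gene[1], terms_per_gene[2]), 1)
      data.frame(gene = g, term = sample(pool, min(k, n_terms)),
                 stringsAsFactors = FALSE)
    })
    ann <- do.call(rbind, rows)
    if (!is.null(planted_term) && planted_count > 0) {
      ranking <- target_reachability_ranking(net)
      top <- ranking$target[seq_len(planted_count)]
      ann <- rbind(ann, data.frame(
        gene = c(top, sample(net$sources, 1)),
        term = planted_term, stringsAsFactors = FALSE))
    }
    unique(ann)
  })
}
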