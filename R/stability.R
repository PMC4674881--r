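#' Perturb edge probabilities
#'
#' Draws each edge's probability independently and uniformly at random from
#' the interval `[p - delta, p + delta]` intersected with `[0, 1]` -- a
#' truncated uniform, not a draw-then-clamp (clamping would put point mass
#' at 0 and 1). The topology is unchanged. `delta = 0` returns the
#' probabilities unchanged, exactly.
#'
#' @param net a `probnet`.
#' @param delta non-negative maximum probability change.
#' @param seed optional integer seed; the caller's RNG state is restored
#'   afterwards. With `NULL` the current RNG stream is used.
#' @return a new `probnet` with redrawn probabilities.
#' @export
perturb_probabilities <- function(net, delta, seed = NULL) {
  if (!is.finite(delta) || delta < 0) stop("delta must be >= 0")
  with_seed(seed, {
    p <- net$edges$p
    lo <- pmax(0, p - delta)
    hi <- pmin(1, p + delta)
    net$edges$p <- stats::runif(length(p), lo, hi)
    net
  })
}

#' Perturb topology by degree-preserving edge shuffling
#'
#' Performs `round(delta * |E| / 2)` swap operations. Each swap picks two
#' distinct random edges `(u1, v1)` and `(u2, v2)`, replaces them with
#' `(u1, v2)` and `(u2, v1)`, and assigns the two old edge probabilities to
#' the two new edges in random order. Every node keeps its in-degree and
#' out-degree, and the multiset of edge probabilities is conserved. Swaps
#' that would create a self-loop or a duplicate edge are rejected and
#' resampled, with a bounded retry budget.
#'
#' @param net a `probnet`.
#' @param delta fraction of edges to shuffle, in `[0, 1]`.
#' @param seed optional integer seed (RNG state restored afterwards).
#' @param swaps override the swap count (default `round(delta * |E| / 2)`).
#' @param max_retries total rejection budget (default `100 * max(swaps, 1)`).
#' @return a new `probnet` with shuffled topology.
#' @export
perturb_topology <- function(net, delta, seed = NULL, swaps = NULL,
                             max_retries = NULL) {
  if (!is.finite(delta) || delta < 0 || delta > 1) {
    stop("delta must be in [0, 1]")
  }
  m <- nrow(net$edges)
  if (is.null(swaps)) swaps <- round(delta * m / 2)
  if (swaps == 0) return(net)
  if (m < 2) stop("need at least 2 edges to shuffle")
  if (is.null(max_retries)) max_retries <- 100 * max(swaps, 1)
  with_seed(seed, {
    from <- net$edges$from; to <- net$edges$to; p <- net$edges$p
    done <- 0; tries <- 0
    while (done < swaps) {
      if (tries >= max_retries) {
        stop(sprintf(
          "edge shuffling retry budget exhausted after %d swaps of %d",
          done, swaps))
      }
      tries <- tries + 1
      ij <- sample.int(m, 2)
      i <- ij[1]; j <- ij[2]
      nf1 <- from[i]; nt1 <- to[j]
      nf2 <- from[j]; nt2 <- to[i]
      if (nf1 == nt1 || nf2 == nt2) next
      key <- paste(from, to, sep = "\r")
      k1 <- paste(nf1, nt1, sep = "\r"); k2 <- paste(nf2, nt2, sep = "\r")
      # duplicates checked against all surviving edges and the other new edge
      if (k1 == k2) next
      if (any(key[-c(i, j)] %in% c(k1, k2))) next
      from[i] <- nf1; to[i] <- nt1
      from[j] <- nf2; to[j] <- nt2
      if (stats::runif(1) < 0.5) {
        tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
      }
      done <- done + 1
    }
    probnet(data.frame(from = from, to = to, p = p, stringsAsFactors = FALSE),
            sources = net$sources, targets = net$targets, nodes = net$nodes)
  })
}

#' Mean reachability change under a perturbation
#'
#' Averages, over all source-target pairs, the difference in reachability
#' probability between the perturbed and the original network:
#' `(1 / (|S| * |T|)) * sum over (s, t) of
#'  [P_reach(perturbed, s, t) - P_reach(original, s, t)]`.
#' A large magnitude indicates instability; a negative sign indicates a drop
#' in reachability (the network becoming unresponsive to external signals),
#' a positive sign a rise (over-sensitivity).
#'
#' @param net the original `probnet`.
#' @param perturbed the perturbed network; must have the same source and
#'   target sets.
#' @param base_reach optional precomputed per-pair reachability of `net`
#'   (as returned with `attr(, "pairs")`), to avoid recomputation across
#'   replicates.
#' @return the mean change, in `[-1, 1]`.
#' @export
stability_delta <- function(net, perturbed, base_reach = NULL) {
  if (!setequal(net$sources, perturbed$sources) ||
      !setequal(net$targets, perturbed$targets)) {
    stop("original and perturbed networks must share sources and targets")
  }
  pairs <- expand.grid(s = net$sources, t = net$targets,
                       stringsAsFactors = FALSE)
  if (is.null(base_reach)) {
    base_reach <- mapply(function(s, t) reachability(net, s, t),
                         pairs$s, pairs$t)
  }
  pert <- mapply(function(s, t) reachability(perturbed, s, t),
                 pairs$s, pairs$t)
  mean(pert - base_reach)
}

#' Stability curve over a perturbation-strength grid
#'
#' For each perturbation strength `delta`, generates `replicates`
#' independently perturbed networks (each replicate's RNG stream is derived
#' from the master seed) and records the mean reachability change of each,
#' plus the grand mean per `delta`.
#'
#' @param net a `probnet`.
#' @param model `"probability"` (edge-probability perturbation) or
#'   `"topology"` (degree-preserving shuffling).
#' @param deltas numeric grid of perturbation strengths.
#' @param replicates perturbed networks per grid point (default 30).
#' @param seed master integer seed; sub-seeds per (delta, replicate) are
#'   derived from it, so runs are reproducible bit-for-bit.
#' @return a `stability_curve` object: list with `model`, `deltas`,
#'   `replicates`, `seed`, `results` (data frame `delta`, `replicate`,
#'   `delta_reach`) and `summary` (data frame `delta`, `mean_delta`,
#'   `sd_delta`, `replicates`).
#' @export
stability_curve <- function(net, model = c("probability", "topology"),
                            deltas, replicates = 30, seed = NULL) {
  model <- match.arg(model)
  if (replicates < 1) stop("replicates must be >= 1")
  sub_seeds <- with_seed(seed,
    matrix(sample.int(.Machine$integer.max, length(deltas) * replicates),
           nrow = length(deltas)))
  pairs <- expand.grid(s = net$sources, t = net$targets,
                       stringsAsFactors = FALSE)
  base_reach <- mapply(function(s, t) reachability(net, s, t),
                       pairs$s, pairs$t)
  res <- expand.grid(replicate = seq_len(replicates), delta = deltas)
  res <- res[, c("delta", "replicate")]
  res$delta_reach <- NA_real_
  for (di in seq_along(deltas)) {
    for (r in seq_len(replicates)) {
      pert <- if (model == "probability") {
        perturb_probabilities(net, deltas[di], seed = sub_seeds[di, r])
      } else {
        perturb_topology(net, deltas[di], seed = sub_seeds[di, r])
      }
      row <- (di - 1) * replicates + r
      res$delta_reach[row] <- stability_delta(net, pert,
                                             base_reach = base_reach)
    }
  }
  summ <- do.call(rbind, lapply(seq_along(deltas), function(di) {
    v <- res$delta_reach[res$delta == deltas[di]]
    data.frame(delta = deltas[di], mean_delta = mean(v),
               sd_delta = stats::sd(v), replicates = replicates)
  }))
  structure(
    list(model = model, deltas = deltas, replicates = replicates,
         seed = seed, results = res, summary = summ),
    class = "stability_curve"
  )
}

#' @export
print.stability_curve <- function(x, ...) {
  cat(sprintf("Stability curve (%s perturbation, %d replicates per delta%s)\n",
              x$model, x$replicates,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
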