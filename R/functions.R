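#' Read a gene-to-term annotation table
#'
#' @param path tab-separated file with two columns, gene identifier and term
#'   identifier; `#` comment lines and blank lines ignored, no header.
#' @return an annotation data frame with character columns `gene`, `term`
#'   (one row per assignment, duplicates removed).
#' @export
read_annotations <- function(path) {
  tl <- .read_tsv_lines(path)
  gene <- character(0); term <- character(0)
  for (i in seq_along(tl$fields)) {
    f <- tl$fields[[i]]
    if (length(f) != 2) {
      stop(sprintf("%s line %d: expected 2 tab-separated fields",
                   path, tl$lineno[i]))
    }
    gene <- c(gene, f[1]); term <- c(term, f[2])
  }
  unique(data.frame(gene = gene, term = term, stringsAsFactors = FALSE))
}

#' Write an annotation table
#' @param annotations data frame with columns `gene`, `term`.
#' @param path output file path.
#' @return `annotations`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  writeLines(paste(annotations$gene, annotations$term, sep = "\t"), path)
  invisible(annotations)
}

# genes annotated with `term`, as a character vector
.term_genes <- function(annotations, term) {
  unique(annotations$gene[annotations$term == term])
}

#' Term depths from an OBO-style ontology file
#'
#' Parses a minimal OBO dialect: `[Term]` stanzas with `id:`, `is_a:` and
#' `relationship: part_of` lines (obsolete terms skipped). The depth of a
#' term is the length of the shortest chain of is-a / part-of links from any
#' root (a term with no parents); roots have depth 0.
#'
#' @param ontology_path path to the ontology file.
#' @return a named integer vector mapping term identifier to depth.
#' @export
term_depths <- function(ontology_path) {
  lines <- readLines(ontology_path)
  ids <- character(0)
  parents <- list()
  cur_id <- NA_character_; cur_par <- character(0)
  in_term <- FALSE; obsolete <- FALSE
  flush <- function() {
    if (in_term && !is.na(cur_id) && !obsolete) {
      ids <<- c(ids, cur_id)
      parents[[cur_id]] <<- cur_par
    }
  }
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (grepl("^\\[", ln)) {
      flush()
      in_term <- identical(ln, "[Term]")
      cur_id <- NA_character_; cur_par <- character(0); obsolete <- FALSE
      next
    }
    if (!in_term) next
    if (grepl("^id:", ln)) {
      cur_id <- sub("^id:\\s*", "", ln)
    } else if (grepl("^is_a:", ln)) {
      cur_par <- c(cur_par, sub("\\s*!.*$", "", sub("^is_a:\\s*", "", ln)))
    } else if (grepl("^relationship:\\s*part_of\\s", ln)) {
      cur_par <- c(cur_par,
                   sub("\\s*!.*$", "",
                       sub("^relationship:\\s*part_of\\s+", "", ln)))
    } else if (grepl("^is_obsolete:\\s*true", ln)) {
      obsolete <- TRUE
    }
  }
  flush()
  if (anyDuplicated(ids)) stop("duplicate term id in ontology")
  for (id in ids) {
    unknown <- setdiff(parents[[id]], ids)
    if (length(unknown)) {
      stop("unknown parent term: ", unknown[1], " (referenced by ", id, ")")
    }
  }
  depth <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  roots <- ids[vapply(ids, function(i) length(parents[[i]]) == 0, logical(1))]
  if (length(ids) && !length(roots)) stop("ontology has a cycle (no root term)")
  depth[roots] <- 0L
  # children adjacency for BFS from the roots
  children <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) for (pa in parents[[id]]) {
    children[[pa]] <- c(children[[pa]], id)
  }
  frontier <- roots
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(children[frontier], use.names = FALSE))
    nxt <- nxt[!is.na(nxt)]
    nxt <- nxt[is.na(depth[nxt])]
    depth[nxt] <- d
    frontier <- nxt
  }
  if (anyNA(depth)) {
    stop("ontology has a cycle involving term: ", ids[is.na(depth)][1])
  }
  depth
}

#' Drop generic (shallow) terms from an annotation table
#'
#' Terms in the top levels of the ontology hierarchy are generic and
#' annotate very many genes, so they are removed before enrichment analysis.
#' By default the top five levels (depths 0 through 4) are dropped; terms
#' with no depth information are kept, with a warning.
#'
#' @param annotations data frame with columns `gene`, `term`.
#' @param depths named integer vector from [term_depths()].
#' @param max_generic_depth deepest level still considered generic
#'   (default 4, i.e. the top five levels 0..4 are removed).
#' @return the filtered annotation data frame. Genes whose every term was
#'   generic simply no longer appear; they remain valid network nodes.
#' @export
filter_generic_terms <- function(annotations, depths, max_generic_depth = 4) {
  d <- depths[annotations$term]
  missing <- is.na(d)
  if (any(missing)) {
    warning(sprintf("%d annotation(s) with unknown term depth kept: %s",
                    sum(missing),
                    paste(unique(annotations$term[missing]), collapse = ", ")))
  }
  annotations[missing | d > max_generic_depth, , drop = FALSE]
}

#' Rank target nodes by set-source reachability
#'
#' For every target (reporter) node, computes the probability that a signal
#' from at least one source reaches it, and sorts the targets by descending
#' probability, ties broken by node identifier so the ranking is
#' deterministic.
#'
#' @param net a `probnet`.
#' @return a data frame with columns `target`, `probability`, ordered from
#'   most to least reachable.
#' @export
target_reachability_ranking <- function(net) {
  if (length(net$targets) == 0) stop("network has no targets")
  pr <- vapply(net$targets,
               function(t) reachability(net, net$sources, t), numeric(1))
  ord <- order(-pr, net$targets)
  data.frame(target = net$targets[ord], probability = unname(pr[ord]),
             stringsAsFactors = FALSE)
}

#' Hypergeometric enrichment of a term among the most reachable targets
#'
#' Given the reachability ranking of the targets, tries every cutoff
#' `d in 1..|T|`: the top-`d` targets form the candidate set, `n` of which
#' are annotated with the term, out of `N` annotated targets overall. The
#' enrichment value at `d` is the hypergeometric upper tail
#' `P(X >= n | |T|, d, N)` -- the probability that a random size-`d` subset
#' of the targets contains at least `n` annotated ones -- computed by direct
#' summation of the probability mass from `n` to `min(N, d)`. The reported
#' enrichment is the minimum over all `d`. Lower values mean the annotated
#' targets are concentrated among the most reachable ones; values at or
#' below 0.1 are conventionally called highly enriched.
#'
#' @param term a term identifier.
#' @param ranking data frame from [target_reachability_ranking()].
#' @param annotations data frame with columns `gene`, `term`.
#' @return a one-row data frame: `term`, `N` (annotated targets), `best_d`,
#'   `n` (annotated among the top `best_d`), `enrichment` in `(0, 1]`.
#' @export
term_enrichment <- function(term, ranking, annotations) {
  ann <- .term_genes(annotations, term)
  flag <- ranking$target %in% ann
  N <- sum(flag)
  if (N == 0) stop("term annotates no target node: ", term)
  Tn <- nrow(ranking)
  ncum <- cumsum(flag)
  tails <- vapply(seq_len(Tn), function(d) {
    n <- ncum[d]
    sum(stats::dhyper(n:min(N, d), N, Tn - N, d))
  }, numeric(1))
  best <- which.min(tails)
  data.frame(term = term, N = N, best_d = best, n = ncum[best],
             enrichment = tails[best], stringsAsFactors = FALSE)
}

#' Enrichment of every term annotating the targets
#'
#' @param net a `probnet`.
#' @param annotations data frame with columns `gene`, `term`. Annotated
#'   genes that are not network targets are ignored for enrichment.
#' @param threshold enrichment value at or below which a term is flagged
#'   highly enriched (default 0.1). No multiple-testing correction is
#'   applied; the raw threshold is the convention here.
#' @param ranking optional precomputed [target_reachability_ranking()].
#' @return a data frame with one row per term that annotates at least one
#'   target: `term`, `N`, `best_d`, `n`, `enrichment`, `highly_enriched`,
#'   ordered by ascending enrichment (ties by term id).
#' @export
enrichment_table <- function(net, annotations, threshold = 0.1,
                             ranking = NULL) {
  if (is.null(ranking)) ranking <- target_reachability_ranking(net)
  terms <- sort(unique(annotations$term[annotations$gene %in% net$targets]))
  if (!length(terms)) {
    return(data.frame(term = character(), N = integer(), best_d = integer(),
                      n = integer(), enrichment = numeric(),
                      highly_enriched = logical()))
  }
  out <- do.call(rbind, lapply(terms, term_enrichment, ranking = ranking,
                               annotations = annotations))
  out$highly_enriched <- out$enrichment <= threshold
  out[order(out$enrichment, out$term), , drop = FALSE]
}

#' Reachability probability of an annotation term
#'
#' A term's reachability is the probability that a signal travels from any
#' source annotated with the term to any target annotated with it. Terms
#' that annotate no source or no target are not applicable (returned as
#' `NA`, which is distinct from a reachability of 0).
#'
#' @param net a `probnet`.
#' @param annotations data frame with columns `gene`, `term`.
#' @param term a term identifier.
#' @return the reachability probability, or `NA_real_` if the term is not
#'   applicable.
#' @export
term_reachability <- function(net, annotations, term) {
  genes <- .term_genes(annotations, term)
  S_a <- intersect(net$sources, genes)
  T_a <- intersect(net$targets, genes)
  if (length(S_a) == 0 || length(T_a) == 0) return(NA_real_)
  reachability(net, S_a, T_a)
}

#' Reachability of all applicable terms, ranked
#'
#' @param net a `probnet`.
#' @param annotations data frame with columns `gene`, `term`.
#' @return a data frame with columns `term`, `n_sources`, `n_targets`
#'   (annotated source/target counts) and `probability`, for terms that
#'   annotate at least one source and one target, ordered by descending
#'   probability (ties by term id).
#' @export
term_reachability_table <- function(net, annotations) {
  terms <- sort(unique(annotations$term))
  rows <- lapply(terms, function(a) {
    genes <- .term_genes(annotations, a)
    S_a <- intersect(net$sources, genes)
    T_a <- intersect(net$targets, genes)
    if (length(S_a) == 0 || length(T_a) == 0) return(NULL)
    data.frame(term = a, n_sources = length(S_a), n_targets = length(T_a),
               probability = reachability(net, S_a, T_a),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(), n_sources = integer(),
                      n_targets = integer(), probability = numeric()))
  }
  out[order(-out$probability, out$term), , drop = FALSE]
}

#' Protein-by-term reachability matrix
#'
#' Entry `(i, j)` is the probability that a signal from protein `i` reaches
#' at least one target annotated with term `j`. A protein that is itself an
#' annotated target of the term reaches it with probability 1 (zero-length
#' path).
#'
#' @param net a `probnet`.
#' @param annotations data frame with columns `gene`, `term`. Only terms
#'   annotating at least one target contribute a column; unknown annotated
#'   genes are ignored with a warning.
#' @return a numeric matrix, rows all network proteins, columns terms.
#' @seealso [cluster_matrix()] for the clustered heat-map ordering.
#' @export
protein_term_matrix <- function(net, annotations) {
  unknown <- setdiff(unique(annotations$gene), net$nodes)
  if (length(unknown)) {
    warning("annotated genes not in the network ignored: ",
            paste(unknown, collapse = ", "))
  }
  terms <- sort(unique(annotations$term))
  term_targets <- lapply(terms, function(a) {
    intersect(net$targets, .term_genes(annotations, a))
  })
  keep <- lengths(term_targets) > 0
  terms <- terms[keep]; term_targets <- term_targets[keep]
  if (!length(terms)) stop("no term annotates any target node")
  mat <- matrix(0, nrow = length(net$nodes), ncol = length(terms),
                dimnames = list(net$nodes, terms))
  for (j in seq_along(terms)) {
    for (v in net$nodes) {
      mat[v, j] <- reachability(net, v, term_targets[[j]])
    }
  }
  mat
}

#' Protein-by-protein reachability matrix
#'
#' Entry `(i, j)` is the probability that a signal from protein `i` reaches
#' protein `j`; the diagonal is 1 (a protein reaches itself by the
#' zero-length path). Unlike [protein_term_matrix()], this needs no
#' annotation knowledge.
#'
#' @param net a `probnet`.
#' @return a square numeric matrix over all network proteins.
#' @export
protein_protein_matrix <- function(net) {
  n <- length(net$nodes)
  mat <- matrix(0, nrow = n, ncol = n,
                dimnames = list(net$nodes, net$nodes))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      mat[i, j] <- if (i == j) 1 else
        reachability(net, net$nodes[i], net$nodes[j])
    }
  }
  mat
}

#' Hierarchically cluster the rows of a reachability matrix
#'
#' Agglomerative clustering of the matrix rows (default: Euclidean distance
#' between row vectors, average linkage), for identifying groups of proteins
#' with similar reachability profiles and ordering heat-map rows.
#'
#' @param mat a numeric matrix with at least 2 rows and finite entries.
#' @param distance `"euclidean"` (default) or `"correlation"`
#'   (one minus Pearson correlation of the rows).
#' @param linkage linkage method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return a `reach_clustering` object: list with `hclust` (the merge
#'   tree), `order` (dendrogram leaf order, row indices), `labels` and
#'   `matrix` (the input reordered by leaf order).
#' @export
cluster_matrix <- function(mat, distance = c("euclidean", "correlation"),
                           linkage = "average") {
  distance <- match.arg(distance)
  if (!is.matrix(mat) || nrow(mat) < 2) {
    stop("matrix must have at least 2 rows")
  }
  if (any(!is.finite(mat))) stop("matrix entries must be finite")
  d <- if (distance == "euclidean") {
    stats::dist(mat)
  } else {
    stats::as.dist(1 - stats::cor(t(mat)))
  }
  hc <- stats::hclust(d, method = linkage)
  structure(
    list(hclust = hc, order = hc$order,
         labels = rownames(mat)[hc$order],
         matrix = mat[hc$order, , drop = FALSE]),
    class = "reach_clustering"
  )
}

#' @export
print.reach_clustering <- function(x, ...) {
  cat(sprintf("Hierarchical clustering of %d rows; leaf order: %s\n",
              nrow(x$matrix),
              paste(utils::head(x$labels, 10), collapse = ", ")))
  invisible(x)
}
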