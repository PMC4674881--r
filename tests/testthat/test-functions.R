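test_that("term depths are shortest root-to-term chains", {
  path <- write_obo(list(
    list(id = "GO:0001"),                                   # root
    list(id = "GO:0002", is_a = "GO:0001"),
    list(id = "GO:0003", is_a = "GO:0002"),
    list(id = "GO:0004", part_of = "GO:0003"),
    # diamond: two chains of length 2 and 3 reach GO:0005 -> depth 2
    list(id = "GO:0005", is_a = c("GO:0002", "GO:0004"))
  ))
  d <- term_depths(path)
  expect_equal(unname(d[c("GO:0001", "GO:0002", "GO:0003", "GO:0004",
                          "GO:0005")]),
               c(0L, 1L, 2L, 3L, 2L))
})

test_that("ontology cycles and dangling parents are rejected", {
  cyc <- write_obo(list(
    list(id = "GO:0001"),
    list(id = "GO:0002", is_a = "GO:0003"),
    list(id = "GO:0003", is_a = "GO:0002")
  ))
  expect_error(term_depths(cyc), "cycle")
  dangling <- write_obo(list(list(id = "GO:0001", is_a = "GO:9999")))
  expect_error(term_depths(dangling), "unknown parent")
})

test_that("generic-term filtering removes the top five levels", {
  ann <- data.frame(gene = c("g1", "g1", "g2", "g3"),
                    term = c("A", "B", "A", "C"))
  depths <- c(A = 4L, B = 5L)
  expect_warning(out <- filter_generic_terms(ann, depths), "unknown term depth")
  expect_setequal(out$term, c("B", "C"))   # depth 4 removed, 5 kept, C kept
  expect_false("g2" %in% out$gene)         # only generic terms: drops out
})

test_that("targets are ranked by set-source reachability, deterministically", {
  net <- probnet(data.frame(from = c("s", "a"), to = c("a", "t1"),
                            p = c(0.5, 0.5)),
                 sources = "s", targets = c("t1", "t2"),
                 nodes = c("s", "a", "t1", "t2"))
  rk <- target_reachability_ranking(net)
  expect_equal(rk$target, c("t1", "t2"))
  expect_equal(rk$probability, c(0.25, 0))

  # reachability ties broken by identifier ascending
  sym <- probnet(data.frame(from = c("s", "s"), to = c("tB", "tA"), p = 0.5),
                 sources = "s", targets = c("tB", "tA"))
  expect_equal(target_reachability_ranking(sym)$target, c("tA", "tB"))
})

test_that("enrichment minimizes the hypergeometric upper tail over all cutoffs", {
  targets <- paste0("t", 1:10)
  ranking <- data.frame(target = targets, probability = seq(1, 0.1, by = -0.1))
  # 3 annotated targets occupying ranks 1-3: best at d = 3, tail = 1/120
  ann <- data.frame(gene = targets[1:3], term = "A")
  rec <- term_enrichment("A", ranking, ann)
  expect_equal(rec$best_d, 3)
  expect_equal(rec$n, 3)
  expect_equal(rec$enrichment, 1 / choose(10, 3), tolerance = 1e-12)

  # saturated term: n = d at every cutoff, tail identically 1
  sat <- data.frame(gene = targets, term = "B")
  expect_equal(term_enrichment("B", ranking, sat)$enrichment, 1)

  expect_error(term_enrichment("C", ranking, ann), "annotates no target")
})

test_that("the tail equals exhaustive subset enumeration", {
  for (Tn in c(4, 6, 8)) {
    ranking <- data.frame(target = paste0("t", 1:Tn),
                          probability = seq(1, 0, length.out = Tn))
    for (N in 1:Tn) {
      for (d in 1:Tn) {
        # place the N annotated targets at arbitrary ranks
        set.seed(Tn * 100 + N * 10 + d)
        ann_at <- sample(Tn, N)
        n <- sum(ann_at <= d)
        got <- sum(stats::dhyper(n:min(N, d), N, Tn - N, d))
        expect_equal(got, hyper_tail_oracle(Tn, N, d, n), tolerance = 1e-12)
      }
    }
  }
})

test_that("minimizing over cutoffs never exceeds any fixed-cutoff tail", {
  targets <- paste0("t", 1:8)
  ranking <- data.frame(target = targets, probability = seq(1, 0.3, length.out = 8))
  set.seed(3)
  for (i in 1:10) {
    N <- sample(1:8, 1)
    ann <- data.frame(gene = sample(targets, N), term = "X")
    rec <- term_enrichment("X", ranking, ann)
    expect_true(rec$enrichment > 0 && rec$enrichment <= 1)
    flag <- ranking$target %in% ann$gene
    for (d in 1:8) {
      n <- sum(flag[1:d])
      expect_lte(rec$enrichment,
                 sum(stats::dhyper(n:min(N, d), N, 8 - N, d)) + 1e-15)
    }
  }
})

test_that("term reachability runs from annotated sources to annotated targets", {
  net <- probnet(data.frame(from = c("s1", "s2"), to = c("t1", "t1"), p = 0.5),
                 sources = c("s1", "s2"), targets = "t1")
  ann <- data.frame(gene = c("s1", "s2", "t1"), term = "A")
  expect_equal(term_reachability(net, ann, "A"), 0.75, tolerance = 1e-12)

  one <- probnet(data.frame(from = "s", to = "t", p = 0.7), "s", "t")
  expect_equal(term_reachability(one, data.frame(gene = c("s", "t"),
                                                 term = "B"), "B"), 0.7)

  # annotated target unreachable in topology: probability 0, not NA
  iso <- probnet(data.frame(from = "s", to = "t", p = 0.7), "s",
                 c("t", "u"), nodes = c("s", "t", "u"))
  expect_equal(term_reachability(iso, data.frame(gene = c("s", "u"),
                                                 term = "C"), "C"), 0)

  # term annotating no source: not applicable, distinct from 0
  expect_true(is.na(term_reachability(one, data.frame(gene = "t",
                                                      term = "D"), "D")))

  tab <- term_reachability_table(net, rbind(ann,
                                            data.frame(gene = "t1", term = "Z")))
  expect_equal(tab$term, "A")   # Z annotates no source, excluded
})

test_that("reachability matrices follow the zero-length-path convention", {
  # chain s -> a -> t, p = 0.5 each
  net <- fixture_chain()
  ppm <- protein_protein_matrix(net)
  expect_equal(unname(diag(ppm)), rep(1, 3))
  expect_equal(ppm["s", "t"], 0.25)
  expect_equal(ppm["t", "s"], 0)

  ann <- data.frame(gene = c("t", "ghost"), term = "A")
  expect_warning(ptm <- protein_term_matrix(net, ann), "ghost")
  expect_equal(ptm["t", "A"], 1)       # annotated target reaches itself
  expect_equal(ptm["s", "A"], 0.25)
  expect_equal(ptm["a", "A"], 0.5)
})

test_that("matrix cells match the enumeration oracle on a 5-node fixture", {
  set.seed(17)
  net <- random_net(max_nodes = 5, max_edges = 8)
  ppm <- protein_protein_matrix(net)
  for (i in net$nodes) for (j in net$nodes) {
    expected <- if (i == j) 1 else reachability_bruteforce(net, i, j)
    expect_equal(ppm[i, j], expected, tolerance = 1e-10)
  }
})

test_that("clustering merges identical rows first and keeps blocks contiguous", {
  m <- rbind(a = c(1, 0, 0), b = c(1, 0, 0), c = c(0, 1, 1))
  cl <- cluster_matrix(m)
  expect_equal(cl$hclust$height[1], 0)
  first_pair <- rownames(m)[abs(cl$hclust$merge[1, ])]
  expect_setequal(first_pair, c("a", "b"))

  # two well-separated blocks stay contiguous in the leaf order
  blocks <- rbind(matrix(rep(c(1, 1, 0, 0), 3), nrow = 3, byrow = TRUE),
                  matrix(rep(c(0, 0, 1, 1), 3), nrow = 3, byrow = TRUE))
  rownames(blocks) <- paste0("r", 1:6)
  set.seed(8)
  blocks <- blocks + matrix(runif(24, 0, 0.01), nrow = 6)
  lo <- cluster_matrix(blocks)$order
  pos <- match(1:3, lo)   # the first block's rows sit in 3 adjacent leaves
  expect_equal(max(pos) - min(pos), 2)

  # permutation equivariance: same partition at the 2-cluster level
  perm <- sample(6)
  lo2 <- cluster_matrix(blocks[perm, , drop = FALSE])
  cut1 <- stats::cutree(cluster_matrix(blocks)$hclust, k = 2)
  cut2 <- stats::cutree(lo2$hclust, k = 2)[rownames(blocks)]
  expect_equal(length(unique(paste(cut1, cut2))), 2)

  expect_error(cluster_matrix(m[1, , drop = FALSE]), "at least 2 rows")
})
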