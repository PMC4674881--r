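test_that("the empty polynomial is the unit of the binomial product", {
  F <- xy_polynomial()
  expect_length(F$processed, 0)
  expect_equal(F$coeff, 1)
  expect_identical(F$present, list(integer(0)))
  expect_equal(F$b + F$c + sum(F$coeff), 1)
})

test_that("multiplying binomials splits terms and conserves probability", {
  F <- multiply_binomial(xy_polynomial(), 1, 0.3)
  expect_equal(sort(F$coeff), c(0.3, 0.7))
  expect_equal(F$processed, 1L)
  expect_equal(F$b + F$c + sum(F$coeff), 1)

  # p = 1: absent branch has coefficient 0 and is dropped
  F1 <- multiply_binomial(xy_polynomial(), 1, 1)
  expect_length(F1$coeff, 1)
  expect_equal(F1$coeff, 1)
  expect_equal(F1$present[[1]], 1L)

  # two multiplications give the four instance probabilities
  p1 <- 0.3; p2 <- 0.8
  F2 <- multiply_binomial(multiply_binomial(xy_polynomial(), 1, p1), 2, p2)
  expect_setequal(round(F2$coeff, 12),
                  round(c(p1 * p2, p1 * (1 - p2),
                          (1 - p1) * p2, (1 - p1) * (1 - p2)), 12))
  expect_equal(sum(F2$coeff), 1)

  expect_error(multiply_binomial(F, 1, 0.5), "already processed")
})

test_that("path and cut checks follow set semantics", {
  chain <- fixture_chain()
  expect_true(has_path(chain, c(1, 2)))
  expect_false(has_path(chain, 1))
  expect_true(is_cut(chain, 2))     # severing a->t cuts the only path
  expect_false(is_cut(chain, integer(0)))

  diam <- fixture_diamond()
  expect_false(is_cut(diam, 1))     # s->w->t survives

  # a node in both roles is a zero-length path, edges irrelevant
  both <- probnet(data.frame(from = "a", to = "b", p = 0.5),
                  sources = "a", targets = "a", nodes = c("a", "b"))
  expect_true(has_path(both, integer(0)))
})

test_that("collapse moves decided terms to the free coefficients and is idempotent", {
  one <- probnet(data.frame(from = "s", to = "t", p = 0.4), "s", "t")
  F <- multiply_binomial(xy_polynomial(), 1, 0.4)
  F <- collapse_polynomial(F, one)
  expect_length(F$coeff, 0)
  expect_equal(F$b, 0.4)
  expect_equal(F$c, 0.6)

  # in the chain, after processing only s->a: the absent branch is already a
  # cut (severing s->a kills the only path), the present branch is undecided
  chain <- fixture_chain()
  F <- collapse_polynomial(multiply_binomial(xy_polynomial(), 1, 0.5), chain)
  expect_length(F$coeff, 1)
  expect_equal(F$present[[1]], 1L)
  expect_equal(F$c, 0.5)
  expect_equal(F$b, 0)

  F2 <- collapse_polynomial(F, chain)
  expect_equal(F2[c("coeff", "b", "c")], F[c("coeff", "b", "c")])
})

test_that("reachability reproduces closed-form motifs", {
  one <- probnet(data.frame(from = "s", to = "t", p = 0.4), "s", "t")
  expect_equal(reachability(one), 0.4, tolerance = 1e-12)
  expect_equal(reachability(fixture_chain()), 0.25, tolerance = 1e-12)
  expect_equal(reachability(fixture_diamond()), 0.4375, tolerance = 1e-12)

  set.seed(7)
  for (i in 1:25) {
    p <- runif(4)
    expect_equal(reachability(fixture_chain(p[1:2])), p[1] * p[2],
                 tolerance = 1e-12)
    two_path <- probnet(
      data.frame(from = c("s", "v", "s", "w"), to = c("v", "t", "w", "t"),
                 p = p),
      sources = "s", targets = "t")
    expect_equal(reachability(two_path),
                 1 - (1 - p[1] * p[2]) * (1 - p[3] * p[4]),
                 tolerance = 1e-12)
  }
})

test_that("brute-force enumeration handles deterministic limits and tiny chains", {
  # 3-node chain, both p = 0.5: each instance has probability 1/4, one has
  # the full path
  expect_equal(reachability_bruteforce(fixture_chain()), 0.25)
  # all p in {0,1}: reachability equals plain graph reachability
  expect_equal(reachability_bruteforce(fixture_chain(c(1, 1))), 1)
  expect_equal(reachability_bruteforce(fixture_chain(c(1, 0))), 0)
  expect_equal(reachability(fixture_chain(c(1, 1))), 1)
  expect_equal(reachability(fixture_chain(c(1, 0))), 0)
  expect_error(reachability_bruteforce(fixture_diamond(), max_edges = 3),
               "enumeration bound")
})

test_that("polynomial reachability agrees with the enumeration oracle", {
  set.seed(101)
  for (i in 1:50) {
    net <- random_net()
    expect_equal(reachability(net), reachability_bruteforce(net),
                 tolerance = 1e-10)
  }
})

test_that("reachability is invariant to the edge processing order", {
  set.seed(202)
  for (i in 1:10) {
    net <- random_net(max_edges = 10)
    ref <- reachability(net, order = seq_len(nrow(net$edges)))
    for (k in 1:3) {
      ord <- sample(nrow(net$edges))
      expect_equal(reachability(net, order = ord), ref, tolerance = 1e-12)
    }
  }
})

test_that("edge_order is BFS from the sources with input-index tie-break", {
  chain <- fixture_chain()
  expect_equal(edge_order(chain), c(1L, 2L))
  star <- probnet(data.frame(from = c("s", "s", "s"),
                             to = c("a", "b", "c"), p = 0.5),
                  "s", "a")
  expect_equal(edge_order(star), c(1L, 2L, 3L))
  # edges unreachable from the sources come last, in input order
  mixed <- probnet(data.frame(from = c("x", "s"), to = c("y", "t"), p = 0.5),
                   "s", "t", nodes = c("x", "y", "s", "t"))
  expect_equal(edge_order(mixed), c(2L, 1L))
})

test_that("increasing one edge probability never decreases reachability", {
  set.seed(303)
  for (i in 1:10) {
    net <- random_net(max_edges = 10)
    j <- sample(nrow(net$edges), 1)
    lower <- reachability(net)
    net$edges$p[j] <- min(1, net$edges$p[j] + runif(1, 0, 1 - net$edges$p[j]))
    expect_gte(reachability(net) - lower, -1e-12)
  }
})

test_that("set reachability dominates every member pair", {
  set.seed(404)
  for (i in 1:10) {
    net <- random_net(max_edges = 10)
    set_val <- reachability(net)
    for (s in net$sources) for (t in net$targets) {
      expect_gte(set_val - reachability(net, s, t), -1e-12)
    }
  }
})

test_that("degenerate queries are rejected and caps are honoured", {
  chain <- fixture_chain()
  expect_error(reachability(chain, character(0), "t"), "non-empty")
  expect_error(reachability(chain, "s", character(0)), "non-empty")
  expect_error(reachability(chain, "s", "zz"), "subsets of the node set")
  # a wide two-layer bundle cannot collapse early: the term cap trips
  expect_error(
    reachability(
      probnet(data.frame(from = c(rep("s", 4), paste0("m", 1:4)),
                         to = c(paste0("m", 1:4), rep("t", 4)), p = 0.5),
              "s", "t"),
      term_cap = 2),
    "term cap")
})

test_that("reachability matches stepping the exported polynomial primitives", {
  set.seed(606)
  for (i in 1:10) {
    net <- random_net(max_edges = 10)
    F <- xy_polynomial()
    for (e in edge_order(net)) {
      F <- multiply_binomial(F, e, net$edges$p[e])
      F <- collapse_polynomial(F, net)
    }
    # termination: after the last edge every instance is decided
    expect_length(F$coeff, 0)
    expect_equal(F$b + F$c, 1, tolerance = 1e-12)
    expect_equal(F$b, reachability(net), tolerance = 1e-12)
  }
})

test_that("debug mode asserts conservation at every step", {
  set.seed(505)
  for (i in 1:10) {
    net <- random_net(max_edges = 10)
    expect_silent(p <- reachability(net, debug = TRUE))
    expect_true(p >= 0 && p <= 1)
  }
})
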