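test_that("cograph recognition matches the canonical small cases", {
  p4 <- adj_from_edges(letters[1:4], list(c("a", "b"), c("b", "c"), c("c", "d")))
  expect_false(is_cograph(p4))
  k4 <- adj_from_edges(letters[1:4],
                       combn(letters[1:4], 2, simplify = FALSE))
  expect_true(is_cograph(k4))
  tri2 <- adj_from_edges(letters[1:6],
                         list(c("a", "b"), c("b", "c"), c("a", "c"),
                              c("d", "e"), c("e", "f"), c("d", "f")))
  expect_true(is_cograph(tri2))
  expect_true(is_cograph(matrix(FALSE, 1, 1)))
})

test_that("decomposition route agrees with the induced-P4 oracle on all small graphs", {
  for (n in 2:5) {
    each_labeled_graph(n, function(adj) {
      expect_identical(is_cograph(adj), !has_p4_oracle(adj))
    })
  }
})

test_that("the R recursion fallback agrees with the compiled core", {
  set.seed(99)
  for (i in 1:40) {
    n <- sample(5:12, 1)
    adj <- matrix(runif(n * n) < 0.35, n, n)
    adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
    diag(adj) <- FALSE
    dimnames(adj) <- list(paste0("v", 1:n), paste0("v", 1:n))
    expect_identical(
      intronless:::is_cograph_r(adj, seq_len(n)),
      intronless:::cograph_check_masks(intronless:::adjacency_masks(adj)))
  }
})

test_that("cograph editing fixes a lone P4 with the minimum single edit", {
  p4 <- adj_from_edges(letters[1:4], list(c("a", "b"), c("b", "c"), c("c", "d")))
  ed <- cograph_edit(p4)
  expect_true(is_cograph(ed$graph))
  expect_equal(ed$n_edits, 1L)
  # brute force: some single-edge change must repair a P4, none with zero
  fixes <- 0L
  for (pair in combn(4, 2, simplify = FALSE)) {
    mod <- p4
    mod[pair[1], pair[2]] <- !mod[pair[1], pair[2]]
    mod[pair[2], pair[1]] <- mod[pair[1], pair[2]]
    if (!has_p4_oracle(mod)) fixes <- fixes + 1L
  }
  expect_gt(fixes, 0L)
})

test_that("cograph editing is the identity on cographs and respects species", {
  k3 <- adj_from_edges(letters[1:3], list(c("a", "b"), c("b", "c"), c("a", "c")))
  ed <- cograph_edit(k3)
  expect_equal(ed$n_edits, 0L)
  expect_identical(ed$graph, k3)
  # same-species edges are never introduced: a,c mouse; b,d rat
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, 4, name = letters[1:4],
                            species = c("mouse", "rat", "mouse", "rat"))
  g <- igraph::add_edges(g, c("a", "b", "b", "c", "c", "d"))
  ed2 <- cograph_edit(g)
  expect_true(is_cograph(ed2$graph))
  if (nrow(ed2$added) > 0L) {
    sp <- c(a = "mouse", b = "rat", c = "mouse", d = "rat")
    expect_false(any(sp[ed2$added$gene_a] == sp[ed2$added$gene_b]))
  }
})

test_that("noise-free simulated orthology graphs need zero edits", {
  lad <- species_ladder()
  hs <- simulate_families(lad, simulation_config(dup_rate = 0.4, loss_rate = 0.2),
                          seed = 60, n = 15)
  for (h in hs) {
    if (nrow(h$genes) < 2L) next
    g <- true_orthology_graph(h)
    expect_true(is_cograph(g))
    expect_equal(cograph_edit(g)$n_edits, 0L)
  }
})

test_that("modular decomposition produces the canonical cotree", {
  k3 <- adj_from_edges(letters[1:3], list(c("a", "b"), c("b", "c"), c("a", "c")))
  ct <- modular_decomposition(k3)
  expect_equal(ct$type, "series")
  expect_true(all(vapply(ct$children, function(c) c$type == "leaf", logical(1))))
  empty3 <- adj_from_edges(letters[1:3], list())
  ct2 <- modular_decomposition(empty3)
  expect_equal(ct2$type, "parallel")
  # complete bipartite {a1,a2} x {b1,b2}: series root over two parallel children
  kb <- adj_from_edges(c("a1", "a2", "b1", "b2"),
                       list(c("a1", "b1"), c("a1", "b2"),
                            c("a2", "b1"), c("a2", "b2")))
  ct3 <- modular_decomposition(kb)
  expect_equal(ct3$type, "series")
  expect_setequal(vapply(ct3$children, `[[`, character(1), "type"),
                  c("parallel", "parallel"))
  p4 <- adj_from_edges(letters[1:4], list(c("a", "b"), c("b", "c"), c("c", "d")))
  expect_error(modular_decomposition(p4), "prime")
})

test_that("the cotree reconstructs its graph exactly on all 5-vertex cographs", {
  for (n in 2:5) {
    each_labeled_graph(n, function(adj) {
      if (!is_cograph(adj)) return(invisible())
      rec <- cotree_to_adjacency(modular_decomposition(adj))
      nm <- rownames(adj)
      expect_identical(rec[nm, nm], adj)
    })
  }
})

test_that("event labeling maps series to speciation and parallel to duplication", {
  smap <- c(m1 = "mouse", r1 = "rat", m2 = "mouse", h1 = "human", h2 = "human")
  pair <- adj_from_edges(c("m1", "r1"), list(c("m1", "r1")))
  tr <- label_events(modular_decomposition(pair), smap)
  expect_equal(tr$event, "speciation")
  twin <- adj_from_edges(c("m1", "m2"), list())
  tr2 <- label_events(modular_decomposition(twin), smap)
  expect_equal(tr2$event, "duplication")
  # complete bipartite {m1,m2} x {h1,h2}: speciation root, duplication children
  kb <- adj_from_edges(c("m1", "m2", "h1", "h2"),
                       list(c("m1", "h1"), c("m1", "h2"),
                            c("m2", "h1"), c("m2", "h2")))
  tr3 <- label_events(modular_decomposition(kb), smap)
  expect_equal(tr3$event, "speciation")
  expect_setequal(vapply(tr3$children, `[[`, character(1), "event"),
                  c("duplication", "duplication"))
  expect_equal(attr(tr3, "n_inconsistent"), 0L)
  # same species adjacent across a speciation -> flagged, not repaired
  bad <- adj_from_edges(c("m1", "m2"), list(c("m1", "m2")))
  tr4 <- label_events(modular_decomposition(bad), smap)
  expect_equal(attr(tr4, "n_inconsistent"), 1L)
  expect_true(tr4$inconsistent)
  expect_error(label_events(modular_decomposition(pair), c(m1 = "mouse")),
               "missing")
})
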