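lad <- species_ladder()

leaf <- function(gene, species) list(event = "leaf", node = species, gene = gene)
spec_node <- function(...) list(event = "speciation", children = list(...),
                                inconsistent = FALSE)
dup_node <- function(...) list(event = "duplication", children = list(...))

test_that("hand-checked reconciliations give the expected images and losses", {
  # speciation(mouse, rat) maps to Muridae with no losses
  r1 <- reconcile(spec_node(leaf("m1", "mouse"), leaf("r1", "rat")), lad)
  expect_equal(r1$root_image, "Muridae")
  expect_equal(r1$losses, 0L)
  expect_equal(r1$duplications, 0L)
  expect_equal(r1$speciations, 1L)

  # duplication above Muridae where the second copy lost its rat lineage
  r2 <- reconcile(dup_node(spec_node(leaf("m1", "mouse"), leaf("r1", "rat")),
                           leaf("m2", "mouse")), lad)
  expect_equal(r2$root_image, "Muridae")
  expect_equal(r2$duplications, 1L)
  expect_equal(r2$losses, 1L)
  expect_equal(names(r2$loss_branches), "rat")

  # a single gene maps to its species with no events
  r3 <- reconcile(leaf("m1", "mouse"), lad)
  expect_equal(r3$root_image, "mouse")
  expect_equal(r3$duplications + r3$losses + r3$speciations, 0L)
  expect_equal(unname(r3$presence["mouse"]), 1L)

  # mouse/rat/human trio: collapsed speciation chain refined against the
  # ladder, inferring the chimp loss
  k3 <- spec_node(leaf("m1", "mouse"), leaf("r1", "rat"), leaf("h1", "human"))
  r4 <- reconcile(k3, lad)
  expect_equal(r4$root_image, "Eutheria")
  expect_equal(r4$speciations, 2L)
  expect_equal(r4$losses, 1L)
  expect_equal(names(r4$loss_branches), "chimp")
})

test_that("a full no-event family implies presence one along the whole ladder", {
  h <- simulate_gene_family(lad, simulation_config(dup_rate = 0, loss_rate = 0),
                            seed = 3)
  g <- true_orthology_graph(h)
  tr <- label_events(modular_decomposition(g),
                     stats::setNames(h$genes$species, h$genes$gene))
  rec <- reconcile(tr, lad)
  expect_equal(rec$losses, 0L)
  expect_equal(rec$duplications, 0L)
  expect_true(all(rec$presence == 1L))
  summ <- summarize_histories(list(rec), lad)
  expect_true(all(summ$presence == 1L))
})

test_that("reconciliation is ancestor-preserving on simulated batches", {
  hs <- simulate_families(lad, simulation_config(dup_rate = 0.5, loss_rate = 0.3),
                          seed = 200, n = 30)
  for (h in hs) {
    if (nrow(h$genes) < 2L) next
    g <- true_orthology_graph(h)
    groups <- cluster_orthogroups(g)
    for (members in groups) {
      sg <- igraph::induced_subgraph(g, members)
      tr <- label_events(modular_decomposition(sg),
                         stats::setNames(h$genes$species, h$genes$gene))
      rec <- reconcile(tr, lad)
      img <- rec$images
      inner <- img[!is.na(img$parent_image), , drop = FALSE]
      ok <- mapply(function(anc, desc) intronless:::is_ladder_ancestor(lad, anc, desc),
                   inner$parent_image, inner$image)
      expect_true(all(ok))
      expect_equal(rec$inconsistent, 0L)
    }
  }
})

test_that("inferred duplication and loss counts equal the recoverable planted counts", {
  cfg <- simulation_config(dup_rate = 0.3, loss_rate = 0.2)
  hs <- simulate_families(lad, cfg, seed = 300, n = 80)
  genes <- do.call(rbind, lapply(hs, `[[`, "genes"))
  smap <- stats::setNames(genes$species, genes$gene)
  edges <- best_bidirectional_hits(emit_similarity(hs, noise = 0, seed = 1), smap)
  g <- build_orthology_graph(edges, smap)
  inf <- infer_histories(g, cluster_orthogroups(g), lad)
  expect_equal(sum(vapply(inf, function(x) x$n_edits, integer(1))), 0L)
  summ <- summarize_histories(lapply(inf, `[[`, "reconciliation"), lad)
  obs_tab <- function(field) {
    v <- stats::setNames(rep(0L, length(lad$nodes)), lad$nodes)
    for (h in hs) {
      t <- h$observable[[field]]
      v[names(t)] <- v[names(t)] + as.integer(t)
    }
    v
  }
  expect_equal(summ$duplications, unname(obs_tab("dup_branches")[summ$node]))
  expect_equal(summ$losses, unname(obs_tab("loss_branches")[summ$node]))
})

test_that("edge recall decays under similarity noise but is perfect without it", {
  hs <- simulate_families(lad, simulation_config(dup_rate = 0.3, loss_rate = 0.2),
                          seed = 400, n = 30)
  genes <- do.call(rbind, lapply(hs, `[[`, "genes"))
  smap <- stats::setNames(genes$species, genes$gene)
  truth <- do.call(rbind, lapply(hs, `[[`, "ortho_pairs"))
  want <- paste(truth$gene_a, truth$gene_b)
  recall <- vapply(c(0, 0.1, 0.45), function(noise) {
    e <- best_bidirectional_hits(emit_similarity(hs, noise = noise, seed = 9), smap)
    mean(want %in% paste(e$gene_a, e$gene_b))
  }, numeric(1))
  expect_equal(recall[1L], 1)
  expect_lt(recall[3L], 1)
  expect_lte(recall[3L], recall[2L] + 0.02)
})

test_that("summaries of an empty batch are all zero", {
  summ <- summarize_histories(list(), lad)
  expect_true(all(summ$duplications == 0L & summ$losses == 0L & summ$presence == 0L))
  expect_setequal(summ$node, lad$nodes)
})

test_that("event trees serialize to labeled Newick", {
  tr <- spec_node(leaf("m1", "mouse"), leaf("r1", "rat"))
  expect_equal(event_tree_newick(tr), "(m1,r1)S;")
  td <- dup_node(leaf("m1", "mouse"), leaf("m2", "mouse"))
  expect_equal(event_tree_newick(td), "(m1,m2)D;")
})
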