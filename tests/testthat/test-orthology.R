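smap4 <- c(a = "mouse", b = "rat", c = "mouse", d = "human")

rec <- function(q, s, pid, score = pid * 10) {
  data.frame(qseqid = q, sseqid = s, pident = pid, length = 300,
             bitscore = score, stringsAsFactors = FALSE)
}

test_that("BBH accepts mutual best hits at or above the identity threshold", {
  records <- rbind(rec("a", "b", 60), rec("b", "a", 60))
  expect_equal(best_bidirectional_hits(records, smap4)$gene_a, "a")
  # 49.9 both ways: below the inclusive 50 threshold
  low <- rbind(rec("a", "b", 49.9), rec("b", "a", 49.9))
  expect_equal(nrow(best_bidirectional_hits(low, smap4)), 0L)
  # exactly 50.0: boundary is inclusive
  edge <- rbind(rec("a", "b", 50), rec("b", "a", 50))
  expect_equal(nrow(best_bidirectional_hits(edge, smap4)), 1L)
})

test_that("BBH requires reciprocity of the best hit", {
  # a's best in rat is b, but b's best in mouse is c
  records <- rbind(rec("a", "b", 70), rec("b", "a", 60), rec("b", "c", 80),
                   rec("c", "b", 80))
  out <- best_bidirectional_hits(records, smap4)
  expect_equal(nrow(out), 1L)
  expect_equal(out$gene_a, "b")
  expect_equal(out$gene_b, "c")
})

test_that("exact co-best ties keep all candidate partners", {
  # b (rat) hits mouse genes a and c with identical score and identity
  records <- rbind(rec("b", "a", 70), rec("b", "c", 70),
                   rec("a", "b", 70), rec("c", "b", 70))
  out <- best_bidirectional_hits(records, smap4)
  expect_equal(nrow(out), 2L)
})

test_that("BBH output is symmetric in record direction and monotone in threshold", {
  lad <- species_ladder()
  hs <- simulate_families(lad, simulation_config(dup_rate = 0.4, loss_rate = 0.2),
                          seed = 50, n = 10)
  genes <- do.call(rbind, lapply(hs, `[[`, "genes"))
  smap <- stats::setNames(genes$species, genes$gene)
  records <- emit_similarity(hs, noise = 0, seed = 8)
  flipped <- records
  flipped$qseqid <- records$sseqid
  flipped$sseqid <- records$qseqid
  e1 <- best_bidirectional_hits(records, smap)
  e2 <- best_bidirectional_hits(flipped, smap)
  expect_equal(e1[c("gene_a", "gene_b")], e2[c("gene_a", "gene_b")])
  # raising the threshold never adds edges, also under noisy scores
  noisy <- emit_similarity(hs, noise = 0.2, seed = 8)
  base <- best_bidirectional_hits(noisy, smap, min_identity = 40)
  for (thr in c(50, 60, 75, 90)) {
    sub <- best_bidirectional_hits(noisy, smap, min_identity = thr)
    expect_true(all(paste(sub$gene_a, sub$gene_b) %in%
                      paste(base$gene_a, base$gene_b)))
  }
})

test_that("the orthology graph keeps isolated genes and rejects bad edges", {
  none <- data.frame(gene_a = character(), gene_b = character())
  g <- build_orthology_graph(none, smap4[1:3])
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 0L)
  dup_edges <- data.frame(gene_a = c("a", "a"), gene_b = c("b", "b"))
  g2 <- build_orthology_graph(dup_edges, smap4)
  expect_equal(igraph::ecount(g2), 1L)
  same <- data.frame(gene_a = "a", gene_b = "c")
  expect_error(build_orthology_graph(same, smap4), "same-species")
})

test_that("orthogroups are connected components of non-isolated genes", {
  smap <- c(a1 = "mouse", a2 = "rat", a3 = "human",
            b1 = "mouse", b2 = "rat", b3 = "human", lone = "chick")
  edges <- data.frame(
    gene_a = c("a1", "a1", "a2", "b1", "b1", "b2"),
    gene_b = c("a2", "a3", "a3", "b2", "b3", "b3"))
  g <- build_orthology_graph(edges, smap)
  groups <- cluster_orthogroups(g)
  expect_length(groups, 2L)
  expect_setequal(lengths(groups), c(3L, 3L))
  expect_false("lone" %in% unlist(groups))
  tab <- orthogroup_table(groups, smap)
  expect_equal(nrow(tab), 6L)
  # empty graph -> no orthogroups
  g0 <- build_orthology_graph(data.frame(gene_a = character(), gene_b = character()),
                              smap)
  g0 <- igraph::delete_edges(g0, igraph::E(g0))
  expect_length(cluster_orthogroups(g0), 0L)
})

test_that("noise-free simulation recovers one orthogroup per family with perfect edges", {
  lad <- species_ladder()
  hs <- simulate_families(lad, simulation_config(dup_rate = 0, loss_rate = 0),
                          seed = 77, n = 8)
  genes <- do.call(rbind, lapply(hs, `[[`, "genes"))
  smap <- stats::setNames(genes$species, genes$gene)
  edges <- best_bidirectional_hits(emit_similarity(hs, noise = 0, seed = 1), smap)
  truth <- do.call(rbind, lapply(hs, `[[`, "ortho_pairs"))
  expect_setequal(paste(edges$gene_a, edges$gene_b),
                  paste(truth$gene_a, truth$gene_b))
  groups <- cluster_orthogroups(build_orthology_graph(edges, smap))
  expect_length(groups, 8L)
})
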