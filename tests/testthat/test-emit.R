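lad <- species_ladder()

test_that("emitted annotations round-trip to the planted architecture", {
  cfg <- simulation_config(dup_rate = 0.3, loss_rate = 0.2, switch_prob = 0.15,
                           decoy_fraction = 0)
  hs <- simulate_families(lad, cfg, seed = 21, n = 10)
  out <- withr::local_tempdir()
  em <- emit_annotations(hs, cfg, out, seed = 3)
  models <- list()
  for (sp in names(em$paths)) models <- c(models, read_annotation(em$paths[[sp]], sp))
  expect_equal(length(models), nrow(em$planted))
  ds <- build_datasets(models)
  merged <- merge(em$planted, ds$calls, by = "gene")
  expect_equal(nrow(merged), nrow(em$planted))
  expect_true(all(merged$class.x == merged$class.y))
  # IG genes are emitted with exactly one transcript and one exon
  ig_ids <- em$planted$gene[em$planted$class == "IG"]
  for (id in ig_ids[seq_len(min(5, length(ig_ids)))]) {
    m <- models[[id]]
    expect_length(m$transcripts, 1L)
    expect_equal(nrow(m$transcripts[[1L]]$exons), 1L)
  }
})

test_that("planted decoys exercise each exclusion and curation filter", {
  cfg <- simulation_config(dup_rate = 0, loss_rate = 0, decoy_fraction = 1)
  hs <- simulate_families(lad, cfg, seed = 5, n = 4)
  out <- withr::local_tempdir()
  em <- emit_annotations(hs, cfg, out, seed = 3)
  models <- list()
  for (sp in names(em$paths)) models <- c(models, read_annotation(em$paths[[sp]], sp))
  ds <- build_datasets(models)
  merged <- merge(em$planted, ds$calls, by = "gene")
  expect_true(all(merged$class.x == merged$class.y))
  expect_true(all(merged$reason.x == merged$reason.y))
  # the uiSEG decoy (single CDS exon, two exons overall) must be MEG
  ui <- merged[grepl("uiseg", merged$gene), , drop = FALSE]
  expect_gt(nrow(ui), 0L)
  expect_true(all(ui$class.y == "MEG" & ui$reason.y == "utr_intron"))
})

test_that("annotation emission rejects unknown species", {
  h <- simulate_gene_family(lad, simulation_config(dup_rate = 0, loss_rate = 0),
                            seed = 1)
  h$genes$species[1L] <- "cat"
  expect_error(emit_annotations(list(h), simulation_config(),
                                withr::local_tempdir()),
               "unknown species")
})

test_that("noise-free similarity reproduces the true orthology through BBH", {
  cfg <- simulation_config(dup_rate = 0.4, loss_rate = 0.2)
  hs <- simulate_families(lad, cfg, seed = 31, n = 25)
  genes <- do.call(rbind, lapply(hs, `[[`, "genes"))
  smap <- stats::setNames(genes$species, genes$gene)
  recs <- emit_similarity(hs, noise = 0, seed = 1)
  # no same-species records, identities in (0, 100]
  expect_false(any(smap[recs$qseqid] == smap[recs$sseqid]))
  expect_true(all(recs$pident > 0 & recs$pident <= 100))
  edges <- best_bidirectional_hits(recs, smap)
  truth <- do.call(rbind, lapply(hs, `[[`, "ortho_pairs"))
  got <- paste(edges$gene_a, edges$gene_b)
  want <- paste(truth$gene_a, truth$gene_b)
  expect_setequal(got, want)
})

test_that("similarity emission is written in the BLAST tabular dialect", {
  h <- simulate_gene_family(lad, simulation_config(dup_rate = 0, loss_rate = 0),
                            seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  emit_similarity(h, noise = 0, seed = 1, path = path)
  back <- read_similarity(path)
  expect_named(back, c("qseqid", "sseqid", "pident", "length", "bitscore"))
  expect_equal(nrow(back), 2 * choose(7, 2))
})

test_that("count emission is reproducible and plants truth labels correctly", {
  cfg <- simulation_config(n_genes = 300)
  a <- emit_counts(cfg, seed = 9)
  b <- emit_counts(cfg, seed = 9)
  expect_identical(a, b)
  expect_true(is.integer(a$counts))
  expect_equal(dim(a$counts), c(300L, 8L))
  # planted NE genes sit below the expression floor
  ne <- a$truth$gene[a$truth$class == "NE"]
  expect_true(all(ne %in% expression_floor(a$counts)))
  # a gene with all-zero counts is labeled NE by the floor
  zero <- rownames(a$counts)[rowSums(a$counts) == 0]
  expect_true(all(zero %in% expression_floor(a$counts)))
})

test_that("PTM emission respects planted proportions and degenerate inputs", {
  tab <- emit_ptm_table(c(Acetylation = 0, Methylation = 0.3),
                        c(Acetylation = 0.1, Methylation = 0.3),
                        n_ig = 400, n_meg = 400, seed = 4)
  res <- classify_all_ptms(tab, n_ig = 400, n_meg = 400)
  acetyl <- res$comparisons[res$comparisons$ptm == "Acetylation", ]
  expect_equal(acetyl$class, "unique-MEG")
  expect_error(emit_ptm_table(c(A = 0.1), c(A = 0.1), n_ig = 0, n_meg = 10),
               "positive")
  # equal proportions classify as similar in most replicates
  similar <- vapply(1:20, function(s) {
    t2 <- emit_ptm_table(c(X = 0.2), c(X = 0.2), 500, 500, seed = s)
    classify_all_ptms(t2, 500, 500)$comparisons$class == "similar"
  }, logical(1))
  expect_gte(mean(similar), 0.9)
})
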