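#' Write per-species GTF annotations for simulated families
#'
#' Every extant gene of the supplied histories becomes a gene record in its
#' species' GTF file, with transcript/exon/CDS rows laid out so that the true
#' architecture is recoverable by [classify_gene()]: IGs get one transcript
#' with a single exon whose CDS sits inside it; MEGs get one transcript with
#' three exons and a CDS spanning all of them. Genes of the same family are
#' placed contiguously along the chromosome so that family loci can be
#' compared with [extract_locus()].
#'
#' A configurable fraction of decoy records exercises the exclusion and
#' curation filters: mitochondrial genes (contig `MT`), non-coding biotypes,
#' multi-transcript genes, and single-coding-exon genes with an extra UTR exon
#' (uiSEGs, which must classify as MEG).
#'
#' @param histories list of [simulate_gene_family()] histories.
#' @param config a [simulation_config()]; `config$decoy_fraction` controls the
#'   number of decoys per species.
#' @param outdir directory for the GTF files (created if needed).
#' @param seed integer seed (strand assignment and decoy placement).
#' @return Invisibly, a list with `paths` (named per-species file paths) and
#'   `planted` (data frame of every emitted gene with its expected
#'   classification and reason).
#' @export
emit_annotations <- function(histories, config, outdir, seed = 1L) {
  stopifnot(length(histories) >= 1L)
  if (inherits(histories, "true_history")) histories <- list(histories)
  set.seed(as.integer(seed))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ladder <- species_ladder()
  genes <- do.call(rbind, lapply(histories, `[[`, "genes"))
  bad <- setdiff(unique(genes$species), ladder$species)
  if (length(bad) > 0L) stop("unknown species name(s): ", paste(bad, collapse = ", "))

  paths <- character(0)
  planted <- list()
  for (sp in ladder$species) {
    sub <- genes[genes$species == sp, , drop = FALSE]
    lines <- character(0)
    cursor <- 1000L
    for (i in seq_len(nrow(sub))) {
      strand <- sample(c("+", "-"), 1L)
      rec <- gene_gtf_lines(sub$gene[i], "chr1", cursor, strand, sub$architecture[i])
      lines <- c(lines, rec$lines)
      cursor <- rec$end + 1000L
    }
    planted[[length(planted) + 1L]] <- data.frame(
      gene = sub$gene, species = sp,
      class = sub$architecture,
      reason = ifelse(sub$architecture == "IG", "ok", "multi_exon"),
      stringsAsFactors = FALSE
    )
    n_decoy <- round(config$decoy_fraction * nrow(sub))
    if (n_decoy > 0L) {
      types <- rep(c("mito", "noncoding", "multitx", "uiseg"), length.out = n_decoy)
      for (i in seq_len(n_decoy)) {
        id <- sprintf("%s_decoy_%s_%d", sp, types[i], i)
        rec <- decoy_gtf_lines(id, types[i], cursor)
        lines <- c(lines, rec$lines)
        cursor <- rec$end + 1000L
        planted[[length(planted) + 1L]] <- data.frame(
          gene = id, species = sp,
          class = switch(types[i], mito = "EXCLUDED", noncoding = "EXCLUDED", "MEG"),
          reason = switch(types[i], mito = "mitochondrial", noncoding = "non_coding",
                          multitx = "multi_transcript", uiseg = "utr_intron"),
          stringsAsFactors = FALSE
        )
      }
    }
    path <- file.path(outdir, paste0(sp, ".gtf"))
    writeLines(lines, path)
    paths[sp] <- path
  }
  invisible(list(paths = paths, planted = do.call(rbind, planted)))
}

gtf_line <- function(seqname, feature, start, end, strand, attrs) {
  at <- paste(sprintf('%s "%s";', names(attrs), unname(attrs)), collapse = " ")
  paste(seqname, "sim", feature, start, end, ".", strand, ".", at, sep = "\t")
}

gene_gtf_lines <- function(gene_id, seqname, start, strand, arch) {
  tx <- paste0(gene_id, "_t1")
  ga <- c(gene_id = gene_id, gene_biotype = "protein_coding")
  ta <- c(gene_id = gene_id, transcript_id = tx,
          gene_biotype = "protein_coding", transcript_biotype = "protein_coding")
  if (arch == "IG") {
    end <- start + 899L
    lines <- c(
      gtf_line(seqname, "gene", start, end, strand, ga),
      gtf_line(seqname, "transcript", start, end, strand, ta),
      gtf_line(seqname, "exon", start, end, strand, ta),
      gtf_line(seqname, "CDS", start + 150L, start + 749L, strand, ta)
    )
  } else {
    ex <- list(c(0L, 199L), c(300L, 599L), c(700L, 899L))
    cds <- list(c(100L, 199L), c(300L, 599L), c(700L, 799L))
    end <- start + 899L
    lines <- c(
      gtf_line(seqname, "gene", start, end, strand, ga),
      gtf_line(seqname, "transcript", start, end, strand, ta),
      vapply(ex, function(e) gtf_line(seqname, "exon", start + e[1L], start + e[2L], strand, ta), character(1)),
      vapply(cds, function(e) gtf_line(seqname, "CDS", start + e[1L], start + e[2L], strand, ta), character(1))
    )
  }
  list(lines = lines, end = end)
}

decoy_gtf_lines <- function(gene_id, type, start) {
  end <- start + 899L
  tx <- paste0(gene_id, "_t1")
  if (type == "mito") {
    ga <- c(gene_id = gene_id, gene_biotype = "protein_coding")
    ta <- c(ga, transcript_id = tx)
    lines <- c(
      gtf_line("MT", "gene", start, end, "+", ga),
      gtf_line("MT", "transcript", start, end, "+", ta),
      gtf_line("MT", "exon", start, end, "+", ta),
      gtf_line("MT", "CDS", start + 100L, start + 700L, "+", ta)
    )
  } else if (type == "noncoding") {
    ga <- c(gene_id = gene_id, gene_biotype = "lincRNA")
    ta <- c(ga, transcript_id = tx)
    lines <- c(
      gtf_line("chr1", "gene", start, end, "+", ga),
      gtf_line("chr1", "transcript", start, end, "+", ta),
      gtf_line("chr1", "exon", start, end, "+", ta)
    )
  } else if (type == "multitx") {
    ga <- c(gene_id = gene_id, gene_biotype = "protein_coding")
    t2 <- paste0(gene_id, "_t2")
    ta1 <- c(ga, transcript_id = tx)
    ta2 <- c(ga, transcript_id = t2)
    lines <- c(
      gtf_line("chr1", "gene", start, end, "+", ga),
      gtf_line("chr1", "transcript", start, end, "+", ta1),
      gtf_line("chr1", "exon", start, end, "+", ta1),
      gtf_line("chr1", "CDS", start + 100L, start + 700L, "+", ta1),
      gtf_line("chr1", "transcript", start, start + 500L, "+", ta2),
      gtf_line("chr1", "exon", start, start + 500L, "+", ta2),
      gtf_line("chr1", "CDS", start + 100L, start + 400L, "+", ta2)
    )
  } else { # uiseg: two exons, CDS confined to the second (intron in the 5' UTR)
    ga <- c(gene_id = gene_id, gene_biotype = "protein_coding")
    ta <- c(ga, transcript_id = tx)
    lines <- c(
      gtf_line("chr1", "gene", start, end, "+", ga),
      gtf_line("chr1", "transcript", start, end, "+", ta),
      gtf_line("chr1", "exon", start, start + 99L, "+", ta),
      gtf_line("chr1", "exon", start + 300L, end, "+", ta),
      gtf_line("chr1", "CDS", start + 400L, start + 800L, "+", ta)
    )
  }
  list(lines = lines, end = end)
}

#' Emit a pairwise similarity table consistent with the true orthology
#'
#' Stands in for an all-against-all peptide alignment. Every cross-species
#' gene pair within a family receives a percent identity determined by the
#' clade of the pair's last common ancestor: truly orthologous pairs get
#' identities well above the 50% reciprocal-best-hit threshold (95 down to 75
#' from Muridae-level to Vertebrata-level splits, so co-orthologs of one gene
#' tie exactly), paralogous pairs get 40. With `noise > 0`, independent
#' Gaussian jitter (sd `20 * noise` identity points) is added per direction.
#' Same-species pairs are never emitted. Records are written in the BLAST
#' tabular dialect (qseqid, sseqid, pident, length, bitscore), one row per
#' direction.
#'
#' @param histories list of `true_history` objects (or a single one).
#' @param noise noise fraction in `[0, 0.5)`.
#' @param seed integer seed.
#' @param path optional output TSV path (headerless, tab-separated).
#' @return Data frame of similarity records (invisibly if `path` is given).
#' @export
emit_similarity <- function(histories, noise = 0, seed = 1L, path = NULL) {
  stopifnot(noise >= 0, noise < 0.5)
  if (inherits(histories, "true_history")) histories <- list(histories)
  set.seed(as.integer(seed))
  rank <- c(Muridae = 1, Primates = 1, Eutheria = 2, Theria = 3,
            Tetrapoda = 4, Vertebrata = 5)
  recs <- list()
  for (h in histories) {
    info <- pair_lca_table(h)
    if (nrow(info) == 0L) next
    base <- ifelse(info$event == "speciation", 95 - 5 * (rank[info$node] - 1), 40)
    recs[[length(recs) + 1L]] <- data.frame(
      qseqid = c(info$gene_a, info$gene_b),
      sseqid = c(info$gene_b, info$gene_a),
      pident = rep(base, 2L),
      stringsAsFactors = FALSE
    )
  }
  if (length(recs) == 0L) {
    out <- data.frame(qseqid = character(), sseqid = character(),
                      pident = numeric(), length = integer(), bitscore = numeric())
  } else {
    out <- do.call(rbind, recs)
    if (noise > 0) {
      out$pident <- out$pident + stats::rnorm(nrow(out), 0, 20 * noise)
    }
    out$pident <- pmin(100, pmax(1, round(out$pident, 2)))
    out$length <- 300L
    out$bitscore <- round(out$pident * 10, 1)
  }
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(out))
  }
  out
}

# cross-species gene pairs of one family with the event and ladder node of
# their last common ancestor
pair_lca_table <- function(history) {
  sp <- stats::setNames(history$genes$species, history$genes$gene)
  acc <- list()
  walk <- function(node) {
    if (node$event %in% c("leaf", "loss")) return(invisible())
    gs <- lapply(node$children, genes_under)
    for (i in seq_along(gs)) {
      for (j in seq_along(gs)) {
        if (j <= i) next
        if (length(gs[[i]]) && length(gs[[j]])) {
          grid <- expand.grid(gene_a = gs[[i]], gene_b = gs[[j]],
                              stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
          grid$event <- node$event
          grid$node <- node$node
          acc[[length(acc) + 1L]] <<- grid
        }
      }
    }
    lapply(node$children, walk)
    invisible()
  }
  walk(history$tree)
  if (length(acc) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      event = character(), node = character()))
  }
  out <- do.call(rbind, acc)
  out[sp[out$gene_a] != sp[out$gene_b], , drop = FALSE]
}

#' Emit a synthetic count matrix with planted differential expression
#'
#' Generates an integer gene-by-sample matrix under the study's two-condition
#' design (`replicates` vs `replicates` samples, default 4 vs 4). Counts are
#' negative binomial with configured mean and dispersion; a planted fraction
#' of genes has the condition-B mean shifted by `2^lfc` (UP) or `2^-lfc` (DN);
#' planted not-expressed (NE) genes get near-zero counts below the expression
#' floor. Truth labels are returned alongside.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; identical seeds give identical matrices.
#' @return List with `counts` (integer matrix), `design` (sample/condition
#'   data frame) and `truth` (gene, planted class UP/DN/NC/NE).
#' @export
emit_counts <- function(config, seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(as.integer(seed))
  n <- config$n_genes
  r <- config$replicates
  n_ne <- round(config$ne_fraction * n)
  n_de <- round(config$de_fraction * n)
  n_up <- floor(n_de / 2)
  n_dn <- n_de - n_up
  cls <- sample(c(rep("NE", n_ne), rep("UP", n_up), rep("DN", n_dn),
                  rep("NC", n - n_ne - n_de)))
  base <- stats::rlnorm(n, meanlog = log(config$mean_count), sdlog = 0.5)
  mu_a <- base
  mu_b <- base * ifelse(cls == "UP", 2^config$lfc,
                        ifelse(cls == "DN", 2^-config$lfc, 1))
  size <- 1 / config$dispersion
  counts <- matrix(0L, nrow = n, ncol = 2L * r,
                   dimnames = list(sprintf("gene%04d", seq_len(n)),
                                   c(sprintf("A%d", seq_len(r)), sprintf("B%d", seq_len(r)))))
  for (j in seq_len(r)) {
    counts[, j] <- stats::rnbinom(n, mu = mu_a, size = size)
    counts[, r + j] <- stats::rnbinom(n, mu = mu_b, size = size)
  }
  ne <- cls == "NE"
  if (any(ne)) {
    counts[ne, ] <- matrix(stats::rpois(sum(ne) * 2L * r, 0.3),
                           nrow = sum(ne), ncol = 2L * r)
  }
  storage.mode(counts) <- "integer"
  design <- data.frame(sample = colnames(counts),
                       condition = rep(c("A", "B"), each = r),
                       stringsAsFactors = FALSE)
  list(counts = counts, design = design,
       truth = data.frame(gene = rownames(counts), class = cls,
                          stringsAsFactors = FALSE))
}

#' Emit a PTM annotation table with planted proportion differences
#'
#' For each PTM type, the number of modified proteins per class is binomial at
#' the stated proportion; the modified proteins are sampled uniformly. A PTM
#' with proportion zero in one class therefore appears in zero proteins of
#' that class (the downstream "unique" case).
#'
#' @param props_ig,props_meg named numeric vectors (PTM type -> proportion in
#'   `[0,1]`); names are unified across the two vectors, missing entries are 0.
#' @param n_ig,n_meg number of IG / MEG proteins (> 0).
#' @param seed integer seed.
#' @return Long data frame (protein_id, ptm_type, class) with one row per
#'   modified protein per PTM.
#' @export
emit_ptm_table <- function(props_ig, props_meg, n_ig, n_meg, seed = 1L) {
  if (n_ig <= 0L || n_meg <= 0L) stop("n_ig and n_meg must be positive")
  stopifnot(all(props_ig >= 0), all(props_ig <= 1),
            all(props_meg >= 0), all(props_meg <= 1))
  set.seed(as.integer(seed))
  ptms <- union(names(props_ig), names(props_meg))
  ig_ids <- sprintf("IGp%04d", seq_len(n_ig))
  meg_ids <- sprintf("MEGp%04d", seq_len(n_meg))
  rows <- list()
  for (p in ptms) {
    for (side in c("IG", "MEG")) {
      prop <- if (side == "IG") props_ig[p] else props_meg[p]
      if (is.na(prop)) prop <- 0
      n <- if (side == "IG") n_ig else n_meg
      ids <- if (side == "IG") ig_ids else meg_ids
      k <- stats::rbinom(1L, n, prop)
      if (k > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = sample(ids, k), ptm_type = p, class = side,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(protein_id = character(), ptm_type = character(),
                      class = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
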