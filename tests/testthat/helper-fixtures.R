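# shared fixture builders ----------------------------------------------------

# a gene_model from exon/CDS interval lists (one transcript unless more given)
make_gene <- function(id = "g1", species = "mouse", seqname = "chr1",
                      strand = "+", biotype = "protein_coding",
                      exons = list(c(1, 900)), cds = list(c(151, 750)),
                      extra_tx = list()) {
  to_mat <- function(iv) {
    if (is.null(iv) || length(iv) == 0L) return(NULL)
    m <- do.call(rbind, iv)
    colnames(m) <- c("start", "end")
    m
  }
  txs <- c(list(list(transcript_id = paste0(id, "_t1"),
                     biotype = biotype,
                     exons = to_mat(exons), cds = to_mat(cds))),
           extra_tx)
  gene_model(id, species, seqname, strand, biotype, txs)
}

# adjacency matrix from vertex names and an edge list of name pairs
adj_from_edges <- function(vertices, edges) {
  adj <- matrix(FALSE, length(vertices), length(vertices),
                dimnames = list(vertices, vertices))
  for (e in edges) {
    adj[e[1L], e[2L]] <- TRUE
    adj[e[2L], e[1L]] <- TRUE
  }
  adj
}

# independent induced-P4 oracle: exhaustive subset search over combn
has_p4_oracle <- function(adj) {
  n <- nrow(adj)
  if (n < 4L) return(FALSE)
  any(apply(utils::combn(n, 4L), 2L, function(q) {
    sub <- adj[q, q]
    deg <- rowSums(sub)
    sum(sub) / 2L == 3L && max(deg) == 2L && min(deg) == 1L
  }))
}

# presence profile over the six non-mouse species
make_profile <- function(present, gene = "m1", arch = "IG") {
  others <- c("rat", "human", "chimp", "opossum", "chick", "zebrafish")
  orthologs <- stats::setNames(lapply(others, function(s) {
    if (s %in% present) paste0(s, "_o1") else character()
  }), others)
  archs <- stats::setNames(lapply(others, function(s) {
    if (s %in% present) arch else character()
  }), others)
  list(gene = gene, orthologs = orthologs, arch = archs)
}

# all labeled graphs on n vertices as adjacency matrices (generator)
each_labeled_graph <- function(n, fn) {
  m <- n * (n - 1L) / 2L
  pairs <- t(utils::combn(n, 2L))
  nm <- letters[seq_len(n)]
  for (code in 0:(2^m - 1L)) {
    adj <- matrix(FALSE, n, n, dimnames = list(nm, nm))
    bits <- bitwAnd(bitwShiftR(code, 0:(m - 1L)), 1L) == 1L
    for (e in which(bits)) {
      adj[pairs[e, 1L], pairs[e, 2L]] <- TRUE
      adj[pairs[e, 2L], pairs[e, 1L]] <- TRUE
    }
    fn(adj)
  }
}
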