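#' Read a BLAST-tabular similarity file
#'
#' Reads a headerless tab-separated similarity table in the BLAST tabular
#' dialect. The first five columns are taken as qseqid, sseqid, pident,
#' length, bitscore; extra columns are ignored.
#'
#' @param path file path.
#' @return Data frame with columns qseqid, sseqid, pident, length, bitscore.
#' @export
read_similarity <- function(path) {
  if (!file.exists(path)) stop("similarity file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 5L) stop("similarity table needs at least 5 columns")
  df <- df[, 1:5]
  names(df) <- c("qseqid", "sseqid", "pident", "length", "bitscore")
  df
}

#' Best bidirectional hits
#'
#' Computes reciprocal-best-hit orthology candidates from directed similarity
#' records. For each query gene, the best hits in each target species are the
#' records with maximal bitscore, ties resolved in favour of higher identity;
#' remaining exact ties are all kept as co-best candidates, so a gene may
#' form edges with several co-orthologs in one species. An undirected edge
#' (a, b) is reported iff b is among a's best hits in b's species, a is among
#' b's best hits in a's species, and both directions reach `min_identity`
#' percent identity (the boundary is inclusive: exactly 50.0 passes the
#' default threshold; the threshold is applied to accepted pairs, so raising
#' it never adds edges).
#'
#' @param records data frame with qseqid, sseqid, pident, bitscore (both
#'   directions may be present; self hits are ignored).
#' @param species_map named character vector, gene id -> species.
#' @param min_identity percent-identity threshold in (0, 100].
#' @return Data frame of edges (gene_a, gene_b, pident) with gene_a <
#'   gene_b lexicographically, sorted; pident is the smaller of the two
#'   directions' identities.
#' @export
best_bidirectional_hits <- function(records, species_map, min_identity = 50) {
  stopifnot(min_identity > 0, min_identity <= 100)
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      pident = numeric(), stringsAsFactors = FALSE)
  if (nrow(records) == 0L) return(empty)
  unknown <- setdiff(unique(c(records$qseqid, records$sseqid)), names(species_map))
  if (length(unknown) > 0L) {
    stop("gene(s) missing from species map: ", paste(utils::head(unknown, 5L), collapse = ", "))
  }
  r <- records[records$qseqid != records$sseqid, , drop = FALSE]
  if (nrow(r) == 0L) return(empty)
  r$tsp <- unname(species_map[r$sseqid])
  r <- r[unname(species_map[r$qseqid]) != r$tsp, , drop = FALSE]
  if (nrow(r) == 0L) return(empty)
  # deduplicate repeated directed records: keep highest (score, identity)
  key <- paste(r$qseqid, r$sseqid)
  r <- r[order(key, -r$bitscore, -r$pident), , drop = FALSE]
  r <- r[!duplicated(paste(r$qseqid, r$sseqid)), , drop = FALSE]
  # best hits per (query, target species): max score, then max identity,
  # keeping all exact co-best ties
  grp <- paste(r$qseqid, r$tsp, sep = "\r")
  best_score <- tapply(r$bitscore, grp, max)[grp]
  r <- r[r$bitscore == best_score, , drop = FALSE]
  grp <- paste(r$qseqid, r$tsp, sep = "\r")
  best_id <- tapply(r$pident, grp, max)[grp]
  r <- r[r$pident == best_id, , drop = FALSE]
  dir_key <- paste(r$qseqid, r$sseqid, sep = "\r")
  rev_key <- paste(r$sseqid, r$qseqid, sep = "\r")
  mutual <- rev_key %in% dir_key
  r <- r[mutual, , drop = FALSE]
  # identity threshold applies to the accepted reciprocal pair: both
  # directions must reach it (so raising it can only remove edges)
  pass <- r$pident >= min_identity
  key_ok <- paste(r$qseqid, r$sseqid, sep = "\r")[pass]
  r <- r[pass & paste(r$sseqid, r$qseqid, sep = "\r") %in% key_ok, , drop = FALSE]
  if (nrow(r) == 0L) return(empty)
  a <- pmin(r$qseqid, r$sseqid)
  b <- pmax(r$qseqid, r$sseqid)
  pid <- tapply(r$pident, paste(a, b, sep = "\r"), min)
  ids <- strsplit(names(pid), "\r", fixed = TRUE)
  out <- data.frame(gene_a = vapply(ids, `[`, character(1), 1L),
                    gene_b = vapply(ids, `[`, character(1), 2L),
                    pident = as.numeric(pid), stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build an orthology graph from BBH edges
#'
#' Genes are nodes (attributed with their species), accepted best
#' bidirectional hits are undirected edges. Genes without any edge are kept
#' as isolated nodes. Self loops and duplicate edges are collapsed; an edge
#' between genes of the same species is an error.
#'
#' @param edges data frame with columns gene_a, gene_b (e.g. from
#'   [best_bidirectional_hits()]).
#' @param species_map named character vector, gene id -> species; defines the
#'   node set.
#' @return An undirected [igraph::graph] with vertex attributes `name` and
#'   `species`.
#' @export
build_orthology_graph <- function(edges, species_map) {
  missing <- setdiff(unique(c(edges$gene_a, edges$gene_b)), names(species_map))
  if (length(missing) > 0L) {
    stop("edge gene(s) not in species map: ", paste(utils::head(missing, 5L), collapse = ", "))
  }
  same <- species_map[edges$gene_a] == species_map[edges$gene_b]
  if (any(same)) {
    stop("same-species edge(s) requested, e.g. ",
         edges$gene_a[same][1L], " - ", edges$gene_b[same][1L])
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(species_map),
                            name = names(species_map),
                            species = unname(species_map))
  if (nrow(edges) > 0L) {
    g <- igraph::add_edges(g, rbind(edges$gene_a, edges$gene_b))
  }
  igraph::simplify(g)
}

#' Cluster an orthology graph into orthogroups
#'
#' Orthogroups are the connected components of the orthology graph restricted
#' to non-isolated genes. Optionally, components whose edge density falls
#' below `density_threshold` are split recursively at a minimum edge cut
#' (a light-weight stand-in for spectral clustering; components are exact on
#' noise-free data).
#'
#' @param graph an orthology graph from [build_orthology_graph()].
#' @param split_low_density split sparse components at minimum cuts?
#' @param density_threshold edge-density threshold in (0, 1] used when
#'   splitting.
#' @return Named list of orthogroups (character vectors of gene ids).
#' @export
cluster_orthogroups <- function(graph, split_low_density = FALSE,
                                density_threshold = 0.5) {
  deg <- igraph::degree(graph)
  g <- igraph::induced_subgraph(graph, igraph::V(graph)[deg > 0])
  if (igraph::vcount(g) == 0L) return(structure(list(), names = character()))
  comp <- igraph::components(g)
  groups <- split(igraph::V(g)$name, comp$membership)
  if (split_low_density) {
    split_one <- function(members) {
      sg <- igraph::induced_subgraph(g, members)
      n <- igraph::vcount(sg)
      if (n < 3L) return(list(members))
      dens <- igraph::ecount(sg) / (n * (n - 1) / 2)
      if (dens >= density_threshold) return(list(members))
      cut <- igraph::min_cut(sg, value.only = FALSE)
      p1 <- igraph::V(sg)$name[as.integer(cut$partition1)]
      p2 <- igraph::V(sg)$name[as.integer(cut$partition2)]
      c(split_one(p1), split_one(p2))
    }
    groups <- unlist(lapply(groups, split_one), recursive = FALSE)
  }
  groups <- unname(groups)
  names(groups) <- sprintf("OG%04d", seq_along(groups))
  groups
}

#' Orthogroup membership as a data frame
#'
#' @param groups named list from [cluster_orthogroups()].
#' @param species_map named character vector, gene id -> species.
#' @return Data frame (group, gene, species).
#' @export
orthogroup_table <- function(groups, species_map) {
  if (length(groups) == 0L) {
    return(data.frame(group = character(), gene = character(),
                      species = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    group = rep(names(groups), lengths(groups)),
    gene = unlist(groups, use.names = FALSE),
    species = unname(species_map[unlist(groups, use.names = FALSE)]),
    stringsAsFactors = FALSE
  )
}
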