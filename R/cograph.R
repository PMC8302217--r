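# -- graph plumbing ----------------------------------------------------------

# accept an igraph or a logical/numeric adjacency matrix; return a logical
# adjacency matrix with dimnames plus the species attribute when available
as_adjacency <- function(graph) {
  if (igraph::is_igraph(graph)) {
    adj <- igraph::as_adjacency_matrix(graph, sparse = FALSE) > 0
    sp <- if ("species" %in% igraph::vertex_attr_names(graph)) {
      stats::setNames(igraph::V(graph)$species, igraph::V(graph)$name)
    } else NULL
    return(list(adj = adj, species = sp))
  }
  adj <- graph > 0
  if (is.null(rownames(adj))) {
    nm <- paste0("v", seq_len(nrow(adj)))
    dimnames(adj) <- list(nm, nm)
  }
  list(adj = adj, species = NULL)
}

adjacency_masks <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    bits <- which(adj[i, ])
    if (length(bits) == 0L) return(0L)
    as.integer(sum(bitwShiftL(1L, bits - 1L)))
  }, integer(1))
}

#' Test whether a graph is a cograph
#'
#' A valid orthology relation is a cograph: a graph with no induced path on
#' four vertices, equivalently a graph whose modular decomposition contains
#' only series and parallel nodes. The test recursively splits the graph into
#' connected components and complement components; hitting a subset connected
#' in both the graph and its complement (a prime module) means the graph is
#' not a cograph. Graphs with at most 30 vertices are checked by a compiled
#' core; larger graphs fall back to the same recursion in R.
#'
#' @param graph an [igraph::graph] or adjacency matrix.
#' @return TRUE iff the graph is a cograph (P4-free).
#' @export
is_cograph <- function(graph) {
  adj <- as_adjacency(graph)$adj
  n <- nrow(adj)
  if (n <= 1L) return(TRUE)
  if (n <= 30L) return(cograph_check_masks(adjacency_masks(adj)))
  is_cograph_r(adj, seq_len(n))
}

# pure-R recursion used above 30 vertices (and as a bridge check in tests)
is_cograph_r <- function(adj, verts) {
  if (length(verts) <= 1L) return(TRUE)
  comps <- adjacency_components(adj, verts)
  if (length(comps) == 1L) {
    cadj <- !adj
    diag(cadj) <- FALSE
    comps <- adjacency_components(cadj, verts)
    if (length(comps) == 1L) return(FALSE)
  }
  all(vapply(comps, function(cc) is_cograph_r(adj, cc), logical(1)))
}

adjacency_components <- function(adj, verts) {
  remaining <- verts
  comps <- list()
  while (length(remaining) > 0L) {
    comp <- remaining[1L]
    frontier <- comp
    while (length(frontier) > 0L) {
      nb <- unique(unlist(lapply(frontier, function(v) verts[adj[v, verts]])))
      nb <- setdiff(nb, comp)
      comp <- c(comp, nb)
      frontier <- nb
    }
    comps[[length(comps) + 1L]] <- comp
    remaining <- setdiff(remaining, comp)
  }
  comps
}

# all induced P4s as a matrix of vertex-index quadruples (rows, path order
# not normalized; each row is the 4-set)
find_induced_p4s <- function(adj) {
  n <- nrow(adj)
  if (n < 4L) return(matrix(integer(), ncol = 4L))
  quads <- utils::combn(n, 4L)
  hits <- apply(quads, 2L, function(q) {
    sub <- adj[q, q]
    e <- sum(sub) / 2L
    if (e != 3L) return(FALSE)
    deg <- rowSums(sub)
    max(deg) == 2L && min(deg) == 1L
  })
  t(quads[, hits, drop = FALSE])
}

#' Edit a graph into a cograph
#'
#' Orthology estimates from noisy similarity data need not be valid
#' (cograph) relations. This greedy heuristic locates induced P4s and
#' resolves each by the single-edge change (addition or deletion within the
#' offending quadruple) that destroys the most remaining P4s; ties prefer
#' deletion over addition and then the lexicographically smallest gene pair.
#' Edges between genes of the same species are never introduced.
#'
#' @param graph an [igraph::graph] (with a `species` vertex attribute if
#'   same-species additions must be forbidden) or adjacency matrix.
#' @return List with `graph` (edited, same representation as input),
#'   `added` and `removed` (data frames of gene pairs) and `n_edits`.
#' @export
cograph_edit <- function(graph) {
  parts <- as_adjacency(graph)
  adj <- parts$adj
  species <- parts$species
  n <- nrow(adj)
  nm <- rownames(adj)
  orig <- adj
  max_iter <- n * n + 10L
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    p4s <- find_induced_p4s(adj)
    if (nrow(p4s) == 0L) break
    # candidate single-edge toggles: pairs inside any offending quadruple
    cand <- unique(do.call(rbind, lapply(seq_len(nrow(p4s)), function(r) {
      t(utils::combn(sort(p4s[r, ]), 2L))
    })))
    if (!is.null(species)) {
      add <- !adj[cand]
      same <- species[nm[cand[, 1L]]] == species[nm[cand[, 2L]]]
      cand <- cand[!(add & same), , drop = FALSE]
    }
    destroyed <- vapply(seq_len(nrow(cand)), function(r) {
      inq <- (p4s[, 1L] %in% cand[r, ]) + (p4s[, 2L] %in% cand[r, ]) +
        (p4s[, 3L] %in% cand[r, ]) + (p4s[, 4L] %in% cand[r, ])
      sum(inq == 2L)
    }, numeric(1))
    is_removal <- adj[cand]
    ord <- order(-destroyed, !is_removal, nm[cand[, 1L]], nm[cand[, 2L]])
    pick <- cand[ord[1L], ]
    adj[pick[1L], pick[2L]] <- !adj[pick[1L], pick[2L]]
    adj[pick[2L], pick[1L]] <- adj[pick[1L], pick[2L]]
  }
  if (iter >= max_iter) stop("cograph editing did not converge")
  changed <- which(adj != orig & upper.tri(adj), arr.ind = TRUE)
  added <- changed[adj[changed], , drop = FALSE]
  removed <- changed[!adj[changed], , drop = FALSE]
  pair_df <- function(m) {
    data.frame(gene_a = nm[m[, 1L]], gene_b = nm[m[, 2L]],
               stringsAsFactors = FALSE)
  }
  out_graph <- if (igraph::is_igraph(graph)) {
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    if (!is.null(species)) igraph::V(g)$species <- unname(species[igraph::V(g)$name])
    g
  } else adj
  list(graph = out_graph, added = pair_df(added), removed = pair_df(removed),
       n_edits = nrow(added) + nrow(removed))
}

#' Modular decomposition of a cograph into its cotree
#'
#' Recursively decomposes a cograph: a disconnected (sub)graph becomes a
#' parallel node over its connected components, a graph with disconnected
#' complement becomes a series node over the complement components. The
#' result is the canonical cotree (no series child of a series node, no
#' parallel child of a parallel node): two genes are adjacent iff their least
#' common ancestor in the cotree is a series node.
#'
#' @param graph an [igraph::graph] or adjacency matrix; must be a cograph.
#' @return Nested cotree: internal nodes `list(type = "series"|"parallel",
#'   children = ...)`, leaves `list(type = "leaf", gene = <id>)`.
#' @export
modular_decomposition <- function(graph) {
  adj <- as_adjacency(graph)$adj
  nm <- rownames(adj)
  rec <- function(verts) {
    if (length(verts) == 1L) return(list(type = "leaf", gene = nm[verts]))
    comps <- adjacency_components(adj, verts)
    if (length(comps) > 1L) {
      return(list(type = "parallel", children = lapply(comps, rec)))
    }
    cadj <- !adj
    diag(cadj) <- FALSE
    comps <- adjacency_components(cadj, verts)
    if (length(comps) > 1L) {
      return(list(type = "series", children = lapply(comps, rec)))
    }
    stop("prime module encountered (graph is not a cograph); run cograph_edit() first")
  }
  if (nrow(adj) == 0L) stop("empty graph has no cotree")
  rec(seq_len(nrow(adj)))
}

#' Reconstruct adjacency from a cotree
#'
#' Inverse of [modular_decomposition()]; used for round-trip checks.
#'
#' @param cotree a cotree as returned by [modular_decomposition()].
#' @return Logical adjacency matrix over the cotree's genes.
#' @export
cotree_to_adjacency <- function(cotree) {
  genes <- cotree_genes(cotree)
  adj <- matrix(FALSE, length(genes), length(genes),
                dimnames = list(genes, genes))
  fill <- function(node) {
    if (node$type == "leaf") return(invisible())
    gs <- lapply(node$children, cotree_genes)
    if (node$type == "series") {
      for (i in seq_along(gs)) {
        for (j in seq_along(gs)) {
          if (j <= i) next
          adj[gs[[i]], gs[[j]]] <<- TRUE
          adj[gs[[j]], gs[[i]]] <<- TRUE
        }
      }
    }
    lapply(node$children, fill)
    invisible()
  }
  fill(cotree)
  adj
}

cotree_genes <- function(node) {
  if (node$type == "leaf") return(node$gene)
  unlist(lapply(node$children, cotree_genes))
}

#' Label a cotree with evolutionary events
#'
#' Series nodes of the cotree correspond to speciations (their descendant
#' genes are pairwise orthologous across children) and parallel nodes to
#' duplications. A speciation node whose child subtrees share a species on
#' opposite sides is biologically impossible and is flagged as inconsistent,
#' not silently repaired.
#'
#' @param cotree a cotree from [modular_decomposition()].
#' @param species_map named character vector, gene id -> species.
#' @return An event tree (class `event_tree`): nested nodes
#'   `list(event = "speciation"|"duplication", children, inconsistent)` with
#'   leaves `list(event = "leaf", node = <species>, gene = <id>)`. The
#'   attribute `n_inconsistent` counts flagged speciation nodes.
#' @export
label_events <- function(cotree, species_map) {
  n_bad <- 0L
  rec <- function(node) {
    if (node$type == "leaf") {
      sp <- species_map[node$gene]
      if (is.na(sp)) stop("gene missing from species map: ", node$gene)
      return(list(event = "leaf", node = unname(sp), gene = node$gene))
    }
    children <- lapply(node$children, rec)
    event <- if (node$type == "series") "speciation" else "duplication"
    bad <- FALSE
    if (event == "speciation") {
      sps <- lapply(children, tree_species)
      for (i in seq_along(sps)) {
        for (j in seq_along(sps)) {
          if (j <= i) next
          if (length(intersect(sps[[i]], sps[[j]])) > 0L) bad <- TRUE
        }
      }
      if (bad) n_bad <<- n_bad + 1L
    }
    list(event = event, children = children, inconsistent = bad)
  }
  out <- rec(cotree)
  structure(out, class = "event_tree", n_inconsistent = n_bad)
}

#' Serialize an event tree as Newick
#'
#' Internal nodes are labeled with their event (`D` duplication, `S`
#' speciation); leaves with their gene id.
#'
#' @param tree an `event_tree` (from [label_events()]) or a simulated event
#'   tree.
#' @return A Newick string.
#' @export
event_tree_newick <- function(tree) {
  rec <- function(node) {
    if (node$event == "leaf") return(node$gene)
    if (node$event == "loss") return(paste0("LOSS_", node$node))
    lab <- if (node$event == "speciation") "S" else "D"
    paste0("(", paste(vapply(node$children, rec, character(1)), collapse = ","),
           ")", lab)
  }
  paste0(rec(tree), ";")
}
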