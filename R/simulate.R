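#' Configuration for the gene-family simulator
#'
#' Bundles every tunable of the synthetic-data generator: duplication/loss
#' rates (expected events per species-tree branch per lineage), the
#' probability that the ancestral gene is intronless, the per-branch
#' probability that a lineage switches architecture (IG <-> MEG), the noise
#' scale for similarity emission, and the count-matrix parameters for the
#' two-condition expression design (4 vs 4 samples).
#'
#' @param dup_rate expected duplications per branch per lineage (>= 0).
#' @param loss_rate expected losses per branch per lineage (>= 0).
#' @param n_families number of gene families to simulate.
#' @param ig_prob probability the family's ancestral gene is intronless.
#' @param switch_prob per-branch probability that a lineage switches
#'   architecture class.
#' @param similarity_noise noise scale for [emit_similarity()], in `[0, 0.5)`.
#' @param decoy_fraction fraction of decoy records added per species by
#'   [emit_annotations()] (mitochondrial, non-coding, multi-transcript and
#'   UTR-intron decoys, cycled).
#' @param n_genes,mean_count,dispersion,de_fraction,ne_fraction,lfc count-matrix
#'   parameters for [emit_counts()]: number of genes, negative-binomial mean
#'   and dispersion, fraction of planted differentially expressed genes
#'   (split evenly UP/DN), fraction of planted not-expressed genes, and the
#'   planted absolute log2 fold change.
#' @param replicates samples per condition (fixed design is `replicates` vs
#'   `replicates`; must be >= 2).
#' @param seed default random seed used by [run_pipeline()].
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(dup_rate = 0.3, loss_rate = 0.2, n_families = 100,
                              ig_prob = 0.5, switch_prob = 0.1,
                              similarity_noise = 0, decoy_fraction = 0,
                              n_genes = 2000, mean_count = 100, dispersion = 0.05,
                              de_fraction = 0.1, ne_fraction = 0.2, lfc = 2,
                              replicates = 4, seed = 1L) {
  stopifnot(
    is.finite(dup_rate), dup_rate >= 0,
    is.finite(loss_rate), loss_rate >= 0,
    n_families >= 1,
    ig_prob >= 0, ig_prob <= 1,
    switch_prob >= 0, switch_prob <= 1,
    similarity_noise >= 0, similarity_noise < 0.5,
    decoy_fraction >= 0, decoy_fraction <= 1,
    de_fraction >= 0, de_fraction <= 1,
    ne_fraction >= 0, ne_fraction <= 1,
    de_fraction + ne_fraction <= 1,
    dispersion > 0, mean_count > 0,
    replicates >= 2
  )
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate one gene family along the species ladder
#'
#' A single ancestral gene is placed at the root of the ladder and evolved
#' towards the tips. On every branch each lineage experiences duplication and
#' loss events at the configured per-branch rates (Poisson process, uniform
#' position on the branch); at each species-tree node surviving lineages
#' speciate. Architecture (IG/MEG) is inherited and switches with probability
#' `switch_prob` per branch traversal.
#'
#' The returned history carries the full event tree, the extant genes with
#' their species and true architecture, the true orthology relation (gene
#' pairs whose last common ancestor is a speciation), raw event counts, and
#' *observable* event counts. Observable counts are what a most-parsimonious
#' reconstruction can recover: copies whose descendants all went extinct leave
#' no trace, so they are obtained by pruning extinct subtrees, canonicalizing
#' the remaining event tree, and re-reading duplications and losses off the
#' ladder with a direct tree walk (independent of the graph-based inference in
#' [modular_decomposition()]/[reconcile()]).
#'
#' @param ladder a [species_ladder()].
#' @param config a [simulation_config()].
#' @param seed integer seed; identical seeds reproduce identical output.
#' @param family family identifier used as gene-id prefix.
#' @return An object of class `true_history`.
#' @export
simulate_gene_family <- function(ladder, config, seed, family = "fam1") {
  stopifnot(inherits(ladder, "species_ladder"), inherits(config, "simulation_config"))
  set.seed(as.integer(seed))
  counters <- new.env(parent = emptyenv())
  rate <- config$dup_rate + config$loss_rate

  new_gene <- function(species) {
    k <- (if (is.null(counters[[species]])) 0L else counters[[species]]) + 1L
    counters[[species]] <- k
    sprintf("%s_%s_g%d", family, species, k)
  }

  arrive <- function(node, arch, flip = TRUE) {
    if (flip && stats::runif(1) < config$switch_prob) {
      arch <- if (arch == "IG") "MEG" else "IG"
    }
    if (node %in% ladder$species) {
      return(list(event = "leaf", node = node, gene = new_gene(node), arch = arch))
    }
    kids <- ladder$children[[node]]
    list(event = "speciation", node = node,
         children = list(branch_from(kids[1L], arch, 0), branch_from(kids[2L], arch, 0)))
  }

  branch_from <- function(node, arch, t) {
    dt <- if (rate > 0) stats::rexp(1, rate) else Inf
    if (t + dt >= 1) return(arrive(node, arch))
    if (stats::runif(1) < config$dup_rate / rate) {
      list(event = "duplication", node = node,
           children = list(branch_from(node, arch, t + dt), branch_from(node, arch, t + dt)))
    } else {
      list(event = "loss", node = node)
    }
  }

  root_arch <- if (stats::runif(1) < config$ig_prob) "IG" else "MEG"
  tree <- arrive(ladder$root, root_arch, flip = FALSE)

  genes <- collect_extant(tree)
  pairs <- true_orthology_pairs(tree)
  structure(
    list(
      family = family,
      tree = tree,
      genes = genes,
      ortho_pairs = pairs,
      events_raw = raw_event_counts(tree),
      observable = observable_events(tree, ladder, genes, pairs),
      config = config,
      seed = as.integer(seed)
    ),
    class = "true_history"
  )
}

#' @export
print.true_history <- function(x, ...) {
  cat(sprintf("Gene family %s: %d extant genes in %d species; %d true orthologous pairs\n",
              x$family, nrow(x$genes), length(unique(x$genes$species)), nrow(x$ortho_pairs)))
  cat(sprintf("  raw events: %d duplications, %d losses; observable: %d duplications, %d losses\n",
              x$events_raw$duplications, x$events_raw$losses,
              x$observable$duplications, x$observable$losses))
  invisible(x)
}

#' Simulate a batch of gene families
#'
#' @inheritParams simulate_gene_family
#' @param n number of families (defaults to `config$n_families`).
#' @return List of [simulate_gene_family()] histories, one per family.
#' @export
simulate_families <- function(ladder, config, seed, n = config$n_families) {
  lapply(seq_len(n), function(i) {
    simulate_gene_family(ladder, config, seed = as.integer(seed) + i,
                         family = sprintf("fam%03d", i))
  })
}

# -- internal helpers on event trees -----------------------------------------

collect_extant <- function(node) {
  if (node$event == "leaf") {
    return(data.frame(gene = node$gene, species = node$node,
                      architecture = node$arch, stringsAsFactors = FALSE))
  }
  if (node$event == "loss") {
    return(data.frame(gene = character(), species = character(),
                      architecture = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(node$children, collect_extant))
}

genes_under <- function(node) {
  if (node$event == "leaf") return(node$gene)
  if (node$event == "loss") return(character())
  unlist(lapply(node$children, genes_under))
}

true_orthology_pairs <- function(tree) {
  acc <- list()
  walk <- function(node) {
    if (node$event %in% c("leaf", "loss")) return(invisible())
    gs <- lapply(node$children, genes_under)
    if (node$event == "speciation") {
      for (i in seq_along(gs)) {
        for (j in seq_along(gs)) {
          if (j <= i) next
          if (length(gs[[i]]) && length(gs[[j]])) {
            grid <- expand.grid(a = gs[[i]], b = gs[[j]],
                                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
            acc[[length(acc) + 1L]] <<- grid
          }
        }
      }
    }
    lapply(node$children, walk)
    invisible()
  }
  walk(tree)
  if (length(acc) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  }
  ab <- do.call(rbind, acc)
  data.frame(gene_a = pmin(ab$a, ab$b), gene_b = pmax(ab$a, ab$b),
             stringsAsFactors = FALSE)
}

raw_event_counts <- function(tree) {
  dup <- character(); loss <- character(); spec <- character()
  walk <- function(node) {
    if (node$event == "duplication") dup <<- c(dup, node$node)
    if (node$event == "loss") loss <<- c(loss, node$node)
    if (node$event == "speciation") spec <<- c(spec, node$node)
    if (!is.null(node$children)) lapply(node$children, walk)
    invisible()
  }
  walk(tree)
  list(duplications = length(dup), losses = length(loss), speciations = length(spec),
       dup_branches = table(dup), loss_branches = table(loss))
}

# prune to a subset of extant genes and suppress unary nodes
prune_to_genes <- function(node, keep) {
  if (node$event == "leaf") {
    return(if (node$gene %in% keep) node else NULL)
  }
  if (node$event == "loss") return(NULL)
  kids <- Filter(Negate(is.null), lapply(node$children, prune_to_genes, keep = keep))
  if (length(kids) == 0L) return(NULL)
  if (length(kids) == 1L) return(kids[[1L]])
  node$children <- kids
  node
}

# connected components of the true orthology relation (plain union-find,
# independent of the igraph-based pipeline route)
orthology_components <- function(genes, pairs) {
  parent <- stats::setNames(genes, genes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs$gene_a[i]); rb <- find(pairs$gene_b[i])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(genes, find, character(1))
  split(genes, roots)
}

# merge adjacent like-labeled internal nodes (canonical multifurcating form)
canonicalize_tree <- function(node) {
  if (node$event %in% c("leaf", "loss")) return(node)
  kids <- lapply(node$children, canonicalize_tree)
  out <- list()
  for (k in kids) {
    if (k$event == node$event && !is.null(k$children)) {
      out <- c(out, k$children)
    } else {
      out <- c(out, list(k))
    }
  }
  node$children <- out
  node
}

tree_species <- function(node) {
  if (node$event == "leaf") return(node$node)
  unique(unlist(lapply(node$children, tree_species)))
}

# Observable (recoverable) event counts: what a most-parsimonious
# reconstruction from the orthology relation can see. Copies whose
# descendants all died leave no trace, and copies whose descendants fall in
# different connected components of the orthology relation are reconstructed
# per component; so the true tree is restricted to each component's genes,
# canonicalized, and walked directly against the ladder. Losses are read off
# skipped ladder nodes; multifurcating speciations are resolved through the
# induced (Steiner) subtree of the ladder spanning the children's images.
observable_events <- function(tree, ladder, genes, pairs) {
  dup_at <- character(); loss_at <- character(); n_spec <- 0L

  image <- function(node) ladder_mrca(ladder, tree_species(node))

  charge_path <- function(from, to, skip_first) {
    # losses at the off-path side of every ladder node passed silently.
    # skip_first: the speciation at `from` was itself an (accounted) event,
    # so `from` is not charged.
    p <- ladder_path_down(ladder, from, to)
    if (length(p) < 2L) return(invisible())
    idx <- seq_len(length(p) - 1L)
    if (skip_first) idx <- idx[-1L]
    for (i in idx) {
      loss_at <<- c(loss_at, ladder_other_child(ladder, p[i], p[i + 1L]))
    }
    invisible()
  }

  walk <- function(node) {
    if (node$event == "leaf") return(invisible())
    imgs <- vapply(node$children, image, character(1))
    here <- image(node)
    if (node$event == "duplication") {
      dup_at <<- c(dup_at, rep(here, length(node$children) - 1L))
      for (i in seq_along(node$children)) {
        charge_path(here, imgs[i], skip_first = FALSE)
      }
    } else { # speciation: Steiner-subtree accounting
      nxt <- list()
      for (i in seq_along(node$children)) {
        p <- ladder_path_down(ladder, here, imgs[i])
        for (j in seq_len(length(p) - 1L)) {
          nxt[[p[j]]] <- unique(c(nxt[[p[j]]], p[j + 1L]))
        }
      }
      for (w in names(nxt)) {
        if (length(nxt[[w]]) == 2L) {
          n_spec <<- n_spec + 1L
        } else {
          loss_at <<- c(loss_at, ladder_other_child(ladder, w, nxt[[w]]))
        }
      }
    }
    lapply(node$children, walk)
    invisible()
  }
  if (nrow(genes) > 0L) {
    for (comp in orthology_components(genes$gene, pairs)) {
      sub <- prune_to_genes(tree, comp)
      if (is.null(sub)) next
      walk(canonicalize_tree(sub))
    }
  }
  list(duplications = length(dup_at), losses = length(loss_at),
       speciations = n_spec,
       dup_branches = table(dup_at), loss_branches = table(loss_at))
}

#' True orthology graph of simulated histories
#'
#' Builds the ground-truth orthology graph (genes as nodes, true orthologous
#' pairs as edges) for one or more simulated families.
#'
#' @param histories a `true_history` or list of them.
#' @return An [igraph::graph] with vertex attributes `name` and `species`.
#' @export
true_orthology_graph <- function(histories) {
  if (inherits(histories, "true_history")) histories <- list(histories)
  genes <- do.call(rbind, lapply(histories, `[[`, "genes"))
  pairs <- do.call(rbind, lapply(histories, `[[`, "ortho_pairs"))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(genes), name = genes$gene, species = genes$species)
  if (nrow(pairs) > 0L) {
    g <- igraph::add_edges(g, rbind(pairs$gene_a, pairs$gene_b))
  }
  g
}
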