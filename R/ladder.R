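#' The fixed seven-taxon species ladder
#'
#' The comparative analyses in this package are carried out on a fixed, rooted,
#' binary species tree over seven vertebrates: mouse, rat, human, chimp,
#' opossum, chick and zebrafish. Internal nodes carry the clade labels used for
#' conservation-age assignment (Muridae, Primates, Eutheria, Theria, Tetrapoda,
#' Vertebrata).
#'
#' @return An object of class `species_ladder`: a list with the underlying
#'   [ape::read.tree()] phylogeny (`$tree`), node bookkeeping (parents,
#'   children, root-paths) and the set of species names.
#' @examples
#' ladder <- species_ladder()
#' ladder_mrca(ladder, c("mouse", "rat"))      # "Muridae"
#' ladder_mrca(ladder, c("mouse", "zebrafish")) # "Vertebrata"
#' @export
species_ladder <- function() {
  nwk <- "(((((mouse,rat)Muridae,(human,chimp)Primates)Eutheria,opossum)Theria,chick)Tetrapoda,zebrafish)Vertebrata;"
  tree <- ape::read.tree(text = nwk)
  labels <- c(tree$tip.label, tree$node.label)
  parent <- stats::setNames(rep(NA_character_, length(labels)), labels)
  children <- stats::setNames(vector("list", length(labels)), labels)
  for (i in seq_len(nrow(tree$edge))) {
    from <- labels[tree$edge[i, 1L]]
    to <- labels[tree$edge[i, 2L]]
    parent[to] <- from
    children[[from]] <- c(children[[from]], to)
  }
  root <- setdiff(labels, names(parent)[!is.na(parent)])
  # path from root down to each node, inclusive
  path <- stats::setNames(vector("list", length(labels)), labels)
  for (nm in labels) {
    p <- nm
    cur <- nm
    while (!is.na(parent[cur])) {
      cur <- unname(parent[cur])
      p <- c(cur, p)
    }
    path[[nm]] <- unname(p)
  }
  depth <- vapply(path, length, integer(1)) - 1L
  structure(
    list(
      tree = tree,
      species = tree$tip.label,
      nodes = labels,
      internal = tree$node.label,
      parent = parent,
      children = children,
      root = root,
      path = path,
      depth = depth
    ),
    class = "species_ladder"
  )
}

#' @export
print.species_ladder <- function(x, ...) {
  cat("Species ladder:", ape::write.tree(x$tree), "\n")
  invisible(x)
}

#' Most recent common ancestor of a set of species on the ladder
#'
#' @param ladder a [species_ladder()] object.
#' @param species character vector of ladder node names (species or clades).
#' @return The name of the lowest ladder node ancestral to (or equal to) all
#'   of `species`.
#' @export
ladder_mrca <- function(ladder, species) {
  stopifnot(length(species) >= 1L)
  bad <- setdiff(species, ladder$nodes)
  if (length(bad) > 0L) {
    stop("unknown ladder node(s): ", paste(bad, collapse = ", "))
  }
  paths <- ladder$path[species]
  shortest <- min(vapply(paths, length, integer(1)))
  anc <- ladder$root
  for (i in seq_len(shortest)) {
    step <- vapply(paths, `[`, character(1), i)
    if (length(unique(step)) == 1L) anc <- step[1L] else break
  }
  unname(anc)
}

# path of node names from `anc` down to `desc`, inclusive of both endpoints
ladder_path_down <- function(ladder, anc, desc) {
  p <- ladder$path[[desc]]
  i <- match(anc, p)
  if (is.na(i)) stop(anc, " is not an ancestor of ", desc)
  p[i:length(p)]
}

# number of edges between ancestor `anc` and descendant `desc`
ladder_dist <- function(ladder, anc, desc) {
  length(ladder_path_down(ladder, anc, desc)) - 1L
}

# the child of `node` not equal to `toward`
ladder_other_child <- function(ladder, node, toward) {
  kids <- ladder$children[[node]]
  setdiff(kids, toward)
}

# the child of `node` whose subtree contains `desc`
ladder_child_toward <- function(ladder, node, desc) {
  p <- ladder_path_down(ladder, node, desc)
  if (length(p) < 2L) stop("no step from ", node, " toward ", desc)
  p[2L]
}

# species (tips) under a ladder node
ladder_species_under <- function(ladder, node) {
  if (node %in% ladder$species) return(node)
  unlist(lapply(ladder$children[[node]], ladder_species_under, ladder = ladder))
}

is_ladder_ancestor <- function(ladder, anc, desc) {
  anc %in% ladder$path[[desc]]
}

#' Conservation-age clade labels, youngest to oldest
#'
#' The five age groups used to stratify mouse genes by how broadly their
#' orthologs are conserved, plus the `mouse-specific` label for genes with no
#' ortholog in any other species.
#'
#' @return Character vector ordered from youngest (`mouse-specific`) to oldest
#'   (`Vertebrata`).
#' @export
age_levels <- function() {
  c("mouse-specific", "Muridae", "Eutheria", "Theria", "Tetrapoda", "Vertebrata")
}
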