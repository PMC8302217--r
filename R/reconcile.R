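#' Reconcile an event-labeled gene tree with the species ladder
#'
#' Embeds the gene tree into the species ladder by LCA mapping: every node is
#' mapped to the lowest ladder node containing all its descendant species.
#' Gene losses are read off the embedding: whenever a lineage passes a ladder
#' speciation silently (its parent's image and its own image skip
#' intermediate ladder nodes) the off-path side of each skipped node is
#' counted as a loss; copies created by a duplication mapped to ladder node X
#' are charged from X downward. Multifurcating speciation nodes (collapsed
#' speciation chains in the canonical cotree) are resolved against the ladder
#' by grouping children according to the side of the image their own images
#' fall in.
#'
#' Duplications are counted as arity minus one per parallel node and
#' attributed to the branch above the node's image; losses are attributed to
#' the branch above the lost (skipped) ladder child.
#'
#' @param tree an `event_tree` from [label_events()] (a single leaf is
#'   allowed).
#' @param ladder a [species_ladder()].
#' @return An object of class `reconciliation`: totals of duplications,
#'   losses and speciations, per-branch tables (`dup_branches`,
#'   `loss_branches`), inferred gene presence per ladder node (`presence`),
#'   the root image, a node-image table (`images`, with parent images for
#'   ancestor-preservation checks) and the count of inconsistently labeled
#'   speciation nodes encountered.
#' @export
reconcile <- function(tree, ladder) {
  stopifnot(inherits(ladder, "species_ladder"))
  dup_at <- character(); loss_at <- character(); n_spec <- 0L
  inconsistent <- 0L
  presence <- stats::setNames(integer(length(ladder$nodes)), ladder$nodes)
  images <- list()
  node_id <- 0L

  image_of <- function(node) ladder_mrca(ladder, tree_species(node))

  note_image <- function(event, img, parent_img) {
    node_id <<- node_id + 1L
    images[[node_id]] <<- data.frame(node = node_id, event = event,
                                     image = img, parent_image = parent_img,
                                     stringsAsFactors = FALSE)
  }

  handle <- function(node, entry, parent_img) {
    img <- image_of(node)
    if (!is_ladder_ancestor(ladder, entry, img)) {
      stop("reconciliation error: image ", img, " not under entry point ", entry)
    }
    note_image(node$event, img, parent_img)
    # silent descent from the entry point to the node's image
    at <- entry
    while (at != img) {
      presence[at] <<- presence[at] + 1L
      nxt <- ladder_child_toward(ladder, at, img)
      loss_at <<- c(loss_at, ladder_other_child(ladder, at, nxt))
      at <- nxt
    }
    if (node$event == "leaf") {
      presence[img] <<- presence[img] + 1L
      return(invisible())
    }
    if (node$event == "duplication") {
      dup_at <<- c(dup_at, rep(img, length(node$children) - 1L))
      for (child in node$children) handle(child, img, img)
      return(invisible())
    }
    # speciation
    presence[img] <<- presence[img] + 1L
    if (isTRUE(node$inconsistent)) inconsistent <<- inconsistent + 1L
    imgs <- vapply(node$children, image_of, character(1))
    ambiguous <- which(imgs == img)
    proper <- which(imgs != img)
    if (img %in% ladder$species || length(proper) == 0L) {
      # degenerate: cannot resolve against the ladder (flagged upstream)
      inconsistent <<- inconsistent + as.integer(length(ambiguous) > 1L)
      for (child in node$children) handle(child, img, img)
      return(invisible())
    }
    sides <- vapply(imgs[proper], function(z) ladder_child_toward(ladder, img, z),
                    character(1))
    groups <- split(proper, sides)
    if (length(groups) < 2L) inconsistent <<- inconsistent + 1L
    n_spec <<- n_spec + 1L
    for (w in names(groups)) {
      idx <- groups[[w]]
      if (length(idx) == 1L) {
        handle(node$children[[idx]], w, img)
      } else {
        virtual <- list(event = "speciation", children = node$children[idx],
                        inconsistent = FALSE)
        handle(virtual, w, img)
      }
    }
    # children spanning both sides of the image cannot arise from a valid
    # speciation; process them in place and flag
    if (length(ambiguous) > 0L) {
      inconsistent <<- inconsistent + 1L
      for (idx in ambiguous) handle(node$children[[idx]], img, img)
    }
    invisible()
  }

  root_img <- image_of(tree)
  handle(tree, root_img, NA_character_)
  structure(
    list(
      root_image = root_img,
      duplications = length(dup_at),
      losses = length(loss_at),
      speciations = n_spec,
      dup_branches = table(dup_at),
      loss_branches = table(loss_at),
      presence = presence,
      images = do.call(rbind, images),
      inconsistent = inconsistent
    ),
    class = "reconciliation"
  )
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf("<reconciliation> root at %s: %d duplications, %d losses, %d speciations%s\n",
              x$root_image, x$duplications, x$losses, x$speciations,
              if (x$inconsistent > 0L) sprintf(" (%d inconsistent nodes)", x$inconsistent) else ""))
  invisible(x)
}

#' Aggregate reconciliations into per-clade gains, losses and presence
#'
#' Sums duplications, losses and inferred ancestral gene presence per ladder
#' node/branch over a batch of families (the per-clade gain/loss layout of
#' the study's evolutionary summary).
#'
#' @param reconciliations list of [reconcile()] results (may be empty).
#' @param ladder a [species_ladder()].
#' @return Data frame (node, duplications, losses, presence) covering every
#'   ladder node; totals over families.
#' @export
summarize_histories <- function(reconciliations, ladder = species_ladder()) {
  out <- data.frame(node = ladder$nodes,
                    duplications = 0L, losses = 0L, presence = 0L,
                    stringsAsFactors = FALSE)
  rownames(out) <- out$node
  for (rec in reconciliations) {
    d <- rec$dup_branches
    l <- rec$loss_branches
    out[names(d), "duplications"] <- out[names(d), "duplications"] + as.integer(d)
    out[names(l), "losses"] <- out[names(l), "losses"] + as.integer(l)
    out$presence <- out$presence + as.integer(rec$presence[out$node])
  }
  rownames(out) <- NULL
  out
}

#' Infer evolutionary histories for a batch of orthogroups
#'
#' Convenience wrapper running the full gene-tree route for each orthogroup:
#' induced orthology subgraph, cograph check (and greedy edit if needed),
#' modular decomposition, event labeling and reconciliation.
#'
#' @param graph an orthology graph ([build_orthology_graph()]).
#' @param groups orthogroups ([cluster_orthogroups()]).
#' @param ladder a [species_ladder()].
#' @return List per orthogroup with elements `tree` (event tree),
#'   `reconciliation`, and `n_edits` (cograph edits applied).
#' @export
infer_histories <- function(graph, groups, ladder = species_ladder()) {
  species_map <- stats::setNames(igraph::V(graph)$species, igraph::V(graph)$name)
  lapply(groups, function(members) {
    sg <- igraph::induced_subgraph(graph, members)
    n_edits <- 0L
    if (!is_cograph(sg)) {
      ed <- cograph_edit(sg)
      sg <- ed$graph
      n_edits <- ed$n_edits
    }
    cotree <- modular_decomposition(sg)
    tree <- label_events(cotree, species_map)
    list(tree = tree, reconciliation = reconcile(tree, ladder),
         n_edits = n_edits)
  })
}
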