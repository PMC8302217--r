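#' Build per-gene ortholog presence profiles
#'
#' For every focal-species (mouse) gene, collects its orthologs in each of
#' the six other species — the direct neighbors in the orthology graph — and
#' their architecture classes. Profiles are the substrate of conservation-age
#' assignment and of the per-genome architecture table.
#'
#' @param graph an orthology graph ([build_orthology_graph()]).
#' @param arch_calls data frame of architecture calls (columns gene, class;
#'   e.g. `build_datasets(...)$calls` pooled over species). Genes absent from
#'   the calls are classed "Other".
#' @param focal focal species (default "mouse").
#' @param focal_genes optionally restrict to these focal-species gene ids.
#' @return List of profiles: each `list(gene, orthologs, arch)` where
#'   `orthologs` and `arch` are per-species named lists over the six
#'   non-focal species.
#' @export
presence_profiles <- function(graph, arch_calls, focal = "mouse",
                              focal_genes = NULL) {
  ladder <- species_ladder()
  others <- setdiff(ladder$species, focal)
  sp <- stats::setNames(igraph::V(graph)$species, igraph::V(graph)$name)
  cls <- stats::setNames(arch_calls$class, arch_calls$gene)
  focal_ids <- names(sp)[sp == focal]
  if (!is.null(focal_genes)) focal_ids <- intersect(focal_ids, focal_genes)
  lapply(focal_ids, function(g) {
    nb <- igraph::neighbors(graph, g)$name
    orthologs <- lapply(stats::setNames(others, others),
                        function(s) nb[sp[nb] == s])
    arch <- lapply(orthologs, function(ids) {
      a <- unname(cls[ids])
      a[is.na(a) | !a %in% c("IG", "MEG")] <- "Other"
      a
    })
    list(gene = g, orthologs = orthologs, arch = arch)
  })
}

#' Assign a conservation age to one presence profile
#'
#' In `strict` mode (the default) the age is the largest clade of the
#' cumulative ladder such that an ortholog is present in *every* species the
#' clade requires: rat gives Muridae; rat + human + chimp give Eutheria;
#' adding opossum gives Theria; adding chick, Tetrapoda; adding zebrafish,
#' Vertebrata. In `deepest` mode the age is the clade of the ladder MRCA of
#' the focal species plus every species with any ortholog. A gene with no
#' ortholog anywhere is `mouse-specific` in both modes.
#'
#' @param profile one profile from [presence_profiles()].
#' @param mode `"strict"` or `"deepest"`.
#' @param ladder a [species_ladder()].
#' @return One-row data frame (gene, age, mode).
#' @export
assign_age <- function(profile, mode = c("strict", "deepest"),
                       ladder = species_ladder()) {
  mode <- match.arg(mode)
  present <- names(profile$orthologs)[lengths(profile$orthologs) > 0L]
  if (length(present) == 0L) {
    return(data.frame(gene = profile$gene, age = "mouse-specific", mode = mode,
                      stringsAsFactors = FALSE))
  }
  if (mode == "strict") {
    required <- list(
      Muridae = "rat",
      Eutheria = c("rat", "human", "chimp"),
      Theria = c("rat", "human", "chimp", "opossum"),
      Tetrapoda = c("rat", "human", "chimp", "opossum", "chick"),
      Vertebrata = c("rat", "human", "chimp", "opossum", "chick", "zebrafish")
    )
    age <- "mouse-specific"
    for (clade in names(required)) {
      if (all(required[[clade]] %in% present)) age <- clade else break
    }
  } else {
    mrca <- ladder_mrca(ladder, c("mouse", present))
    age <- if (mrca == "Primates") "Eutheria" else mrca
  }
  data.frame(gene = profile$gene, age = age, mode = mode,
             stringsAsFactors = FALSE)
}

#' Assign conservation ages to a batch of profiles
#'
#' @inheritParams assign_age
#' @param profiles list from [presence_profiles()].
#' @return Data frame (gene, age, mode) with `age` a factor ordered by
#'   [age_levels()].
#' @export
assign_ages <- function(profiles, mode = c("strict", "deepest"),
                        ladder = species_ladder()) {
  mode <- match.arg(mode)
  out <- do.call(rbind, lapply(profiles, assign_age, mode = mode, ladder = ladder))
  if (is.null(out)) {
    out <- data.frame(gene = character(), age = character(), mode = character(),
                      stringsAsFactors = FALSE)
  }
  out$age <- factor(out$age, levels = age_levels())
  out
}

#' Per-genome architecture conservation table
#'
#' For each non-focal genome, counts the focal-species genes whose orthologs
#' in that genome are majority-IG, majority-MEG, or Other (ties and
#' unclassifiable orthologs fall to Other). `Total` is the row sum — the
#' number of focal genes with at least one ortholog in that genome.
#'
#' @param profiles list from [presence_profiles()].
#' @return Data frame with columns Genome, IGs, MEGs, Others, Total.
#' @export
architecture_table <- function(profiles) {
  species <- setdiff(species_ladder()$species, "mouse")
  counts <- matrix(0L, nrow = length(species), ncol = 3L,
                   dimnames = list(species, c("IG", "MEG", "Other")))
  for (p in profiles) {
    for (s in species) {
      a <- p$arch[[s]]
      if (length(a) == 0L) next
      n_ig <- sum(a == "IG"); n_meg <- sum(a == "MEG")
      cls <- if (n_ig > n_meg) "IG" else if (n_meg > n_ig) "MEG" else "Other"
      counts[s, cls] <- counts[s, cls] + 1L
    }
  }
  data.frame(Genome = species,
             IGs = counts[, "IG"], MEGs = counts[, "MEG"],
             Others = counts[, "Other"], Total = rowSums(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Architecture-conservation fractions per genome and pooled
#'
#' Computes, per genome row, the percentage of ortholog-bearing focal genes
#' whose orthologs conserve the IG architecture (100 * IGs / Total), both
#' rounded to the nearest integer and at two decimals, and the pooled
#' percentage over all rows (100 * sum(IGs) / sum(Total)). Rows with zero
#' total are skipped with a notice.
#'
#' @param table a data frame with columns Genome, IGs, MEGs, Others, Total
#'   (as from [architecture_table()]).
#' @return List with `rows` (Genome, pct_int, pct) and `pooled`
#'   (pct_int, pct).
#' @export
conservation_fractions <- function(table) {
  stopifnot(all(c("Genome", "IGs", "Total") %in% names(table)))
  zero <- table$Total == 0
  if (any(zero)) {
    message("skipping zero-total row(s): ", paste(table$Genome[zero], collapse = ", "))
  }
  tb <- table[!zero, , drop = FALSE]
  pct <- 100 * tb$IGs / tb$Total
  pooled <- 100 * sum(tb$IGs) / sum(tb$Total)
  list(
    rows = data.frame(Genome = tb$Genome,
                      pct_int = round(pct), pct = round(pct, 2),
                      stringsAsFactors = FALSE),
    pooled = list(pct_int = round(pooled), pct = round(pooled, 2))
  )
}
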