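#' Extract a locus map from an annotation
#'
#' Collects the genes of one species overlapping a genomic region (any
#' overlap counts), ordered by start coordinate and tagged with their
#' orthogroup where known.
#'
#' @param genes list of [gene_model()] objects (e.g. from
#'   [read_annotation()]).
#' @param species species name (recorded in the locus map).
#' @param chrom chromosome/contig name.
#' @param start,end 1-based inclusive region bounds.
#' @param orthogroups named character vector gene id -> orthogroup id (genes
#'   without a group get NA).
#' @return Object of class `locus_map`: data frame (gene, start, end,
#'   strand, group) sorted by start, with attributes `species` and `span`.
#' @export
extract_locus <- function(genes, species, chrom, start, end,
                          orthogroups = character()) {
  stopifnot(start <= end)
  rows <- list()
  for (g in genes) {
    if (!identical(g$seqname, chrom)) next
    ex <- do.call(rbind, lapply(g$transcripts, `[[`, "exons"))
    gs <- min(ex[, 1L]); ge <- max(ex[, 2L])
    if (ge < start || gs > end) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g$gene_id, start = gs, end = ge, strand = g$strand,
      group = if (g$gene_id %in% names(orthogroups)) unname(orthogroups[g$gene_id]) else NA_character_,
      stringsAsFactors = FALSE
    )
  }
  df <- if (length(rows) == 0L) {
    data.frame(gene = character(), start = integer(), end = integer(),
               strand = character(), group = character(), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    out[order(out$start), , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df, class = c("locus_map", "data.frame"), species = species,
            span = if (nrow(df) > 0L) max(df$end) - min(df$start) + 1L else 0L)
}

#' Pairwise synteny comparison of two loci
#'
#' Compares two orthogroup-tagged locus maps: orthogroups present in both
#' loci are matches (with order indices and strand agreement per matched
#' copy pair, first copies paired in coordinate order); orthogroups present
#' in A but absent from B are losses; orthogroups with more copies in B than
#' in A are expansions. Order inversions are detected as maximal descending
#' runs in the sequence of matched B indices taken in A order. Every
#' orthogroup present in either locus lands in exactly one category
#' (matched, lost, or gained; expansions annotate matches/gains).
#'
#' @param a,b `locus_map` objects from [extract_locus()].
#' @return Object of class `synteny_report`: list with `matches` (data
#'   frame), `losses`, `gains`, `expansions` (character vectors of
#'   orthogroup ids), `inversions` (count of maximal descending runs) and
#'   `strand_flips` (matched groups whose strands disagree).
#' @export
pairwise_synteny <- function(a, b) {
  ga <- a$group[!is.na(a$group)]
  gb <- b$group[!is.na(b$group)]
  shared <- intersect(unique(ga), unique(gb))
  losses <- setdiff(unique(ga), unique(gb))
  gains <- setdiff(unique(gb), unique(ga))
  copies_a <- table(ga)
  copies_b <- table(gb)
  all_groups <- union(unique(ga), unique(gb))
  expansions <- all_groups[
    ifelse(is.na(copies_b[all_groups]), 0L, copies_b[all_groups]) >
      ifelse(is.na(copies_a[all_groups]), 0L, copies_a[all_groups])
  ]
  matches <- do.call(rbind, lapply(shared, function(grp) {
    ia <- which(a$group %in% grp)[1L]
    ib <- which(b$group %in% grp)[1L]
    data.frame(group = grp, idx_a = ia, idx_b = ib,
               strand_a = a$strand[ia], strand_b = b$strand[ib],
               stringsAsFactors = FALSE)
  }))
  if (is.null(matches)) {
    matches <- data.frame(group = character(), idx_a = integer(),
                          idx_b = integer(), strand_a = character(),
                          strand_b = character(), stringsAsFactors = FALSE)
  }
  matches <- matches[order(matches$idx_a), , drop = FALSE]
  rownames(matches) <- NULL
  inversions <- 0L
  if (nrow(matches) > 1L) {
    descending <- diff(matches$idx_b) < 0
    runs <- rle(descending)
    inversions <- sum(runs$values)
  }
  flips <- matches$group[matches$strand_a != matches$strand_b]
  structure(
    list(matches = matches, losses = losses, gains = gains,
         expansions = unname(expansions), inversions = inversions,
         strand_flips = flips,
         species = c(attr(a, "species"), attr(b, "species"))),
    class = "synteny_report"
  )
}

#' @export
print.synteny_report <- function(x, ...) {
  cat(sprintf("<synteny_report> %s vs %s: %d matches, %d losses, %d gains, %d expansions, %d inversion run(s), %d strand flip(s)\n",
              x$species[1L], x$species[2L], nrow(x$matches), length(x$losses),
              length(x$gains), length(x$expansions), x$inversions,
              length(x$strand_flips)))
  invisible(x)
}

#' Expression summary of a gene cluster
#'
#' Summarizes a locus/cluster gene list against differential-expression
#' calls: total members, IG members, members per DE class, up-regulated
#' members and expressed members (anything not NE). Cluster genes missing
#' from the DE calls are counted as NE with a warning.
#'
#' @param cluster data frame with columns gene and is_ig (logical).
#' @param de_calls a `de_calls` data frame from [classify_de()].
#' @return List with `members`, `ig_members`, `up_members`,
#'   `expressed_members` and `classes` (named UP/DN/NC/NE counts summing to
#'   `members`).
#' @export
cluster_expression_summary <- function(cluster, de_calls) {
  cls <- stats::setNames(as.character(de_calls$class), de_calls$gene)
  missing <- setdiff(cluster$gene, names(cls))
  if (length(missing) > 0L) {
    warning("cluster gene(s) missing from DE calls, counted as NE: ",
            paste(missing, collapse = ", "))
  }
  member_cls <- ifelse(cluster$gene %in% names(cls), cls[cluster$gene], "NE")
  classes <- table(factor(member_cls, levels = c("UP", "DN", "NC", "NE")))
  list(
    members = nrow(cluster),
    ig_members = sum(cluster$is_ig),
    up_members = as.integer(classes["UP"]),
    expressed_members = nrow(cluster) - as.integer(classes["NE"]),
    classes = classes
  )
}
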