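#' Construct a gene model
#'
#' A `gene_model` holds one annotated gene: its identifiers, location, biotype
#' and transcript structures (exon and CDS intervals, 1-based inclusive, GTF
#' convention). It is the substrate of [classify_gene()].
#'
#' @param gene_id gene identifier.
#' @param species species name.
#' @param seqname chromosome/contig name.
#' @param strand "+" or "-".
#' @param biotype gene biotype (e.g. "protein_coding").
#' @param transcripts list of transcripts, each a list with `transcript_id`,
#'   `biotype`, `exons` (2-column start/end matrix) and `cds` (2-column matrix
#'   or NULL).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, species, seqname, strand, biotype, transcripts) {
  stopifnot(length(transcripts) >= 1L)
  for (tx in transcripts) {
    ex <- tx$exons
    stopifnot(is.matrix(ex), ncol(ex) == 2L, nrow(ex) >= 1L)
    if (nrow(ex) > 1L) {
      o <- order(ex[, 1L])
      stopifnot(all(ex[o, 1L][-1L] > ex[o, 2L][-nrow(ex)]))
    }
    if (!is.null(tx$cds) && nrow(tx$cds) > 0L) {
      covered <- apply(tx$cds, 1L, function(iv) {
        any(ex[, 1L] <= iv[1L] & ex[, 2L] >= iv[2L])
      })
      if (!all(covered)) stop("CDS interval not covered by exons in gene ", gene_id)
    }
  }
  structure(list(gene_id = gene_id, species = species, seqname = seqname,
                 strand = strand, biotype = biotype, transcripts = transcripts),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%s %s, %d transcript(s)\n",
              x$gene_id, x$species, x$seqname, x$strand, x$biotype,
              length(x$transcripts)))
  invisible(x)
}

#' Read a GTF annotation into gene models
#'
#' Parses a GTF file with [rtracklayer::import()] and assembles one
#' [gene_model()] per gene carrying at least one transcript. Malformed lines
#' (wrong field count, missing `gene_id`) are reported with their line
#' numbers before parsing.
#'
#' @param path GTF file path.
#' @param species species name attached to every gene model.
#' @return Named list of `gene_model` objects (possibly empty).
#' @export
read_annotation <- function(path, species) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  raw <- readLines(path)
  keep <- !grepl("^#", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  if (length(lineno) == 0L) return(list())
  fields <- strsplit(raw[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    stop("malformed GTF line(s) (expected 9 tab-separated fields): line ",
         paste(lineno[nf != 9L], collapse = ", "))
  }
  no_gene <- !vapply(fields, function(f) grepl("gene_id", f[9L], fixed = TRUE),
                     logical(1))
  if (any(no_gene)) {
    stop("GTF record lacking gene_id attribute: line ",
         paste(lineno[no_gene], collapse = ", "))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$strand <- as.character(df$strand)
  df$seqnames <- as.character(df$seqnames)
  if (is.null(df$gene_biotype)) df$gene_biotype <- "protein_coding"
  if (is.null(df$transcript_id)) df$transcript_id <- NA_character_
  out <- list()
  for (gid in unique(df$gene_id)) {
    sub <- df[df$gene_id == gid, , drop = FALSE]
    tx_ids <- unique(sub$transcript_id[!is.na(sub$transcript_id)])
    if (length(tx_ids) == 0L) next
    txs <- lapply(tx_ids, function(tid) {
      tsub <- sub[!is.na(sub$transcript_id) & sub$transcript_id == tid, , drop = FALSE]
      ex <- tsub[tsub$type == "exon", c("start", "end"), drop = FALSE]
      cds <- tsub[tsub$type == "CDS", c("start", "end"), drop = FALSE]
      ex <- as.matrix(ex[order(ex$start), , drop = FALSE])
      list(transcript_id = tid,
           biotype = if (!is.null(tsub$transcript_biotype)) tsub$transcript_biotype[1L] else NA_character_,
           exons = ex,
           cds = if (nrow(cds) > 0L) as.matrix(cds[order(cds$start), , drop = FALSE]) else NULL)
    })
    txs <- Filter(function(tx) nrow(tx$exons) >= 1L, txs)
    if (length(txs) == 0L) next
    biotype <- sub$gene_biotype[1L]
    if (is.na(biotype)) biotype <- "protein_coding"
    out[[gid]] <- gene_model(gid, species, sub$seqnames[1L], sub$strand[1L],
                             biotype, txs)
  }
  out
}

#' Classify a gene as IG, MEG or excluded
#'
#' Applies the ordered architecture cascade: (1) non-protein-coding biotype is
#' excluded; (2) genes on a mitochondrial contig are excluded; (3) genes with
#' no CDS on any transcript are excluded as incompletely annotated; (4) genes
#' with more than one transcript are MEG (`multi_transcript`), as are genes
#' whose CDS spans two or more exons (`multi_exon`); (5) a single-transcript
#' gene whose CDS is confined to one exon but which carries additional
#' (untranslated) exons has an intron in a UTR and is MEG (`utr_intron`, the
#' uiSEG case); (6) anything left is a true intronless gene (IG): one
#' transcript, one exon, no intron anywhere.
#'
#' @param gene a [gene_model()].
#' @param mito_names contig names treated as mitochondrial.
#' @return A one-row data frame (gene, species, class, reason). Class is
#'   `EXCLUDED` iff reason is one of mitochondrial/non_coding/
#'   incomplete_annotation; class is `IG` iff reason is `ok`.
#' @export
classify_gene <- function(gene, mito_names = c("MT", "chrM", "chrMT")) {
  stopifnot(inherits(gene, "gene_model"))
  call <- function(class, reason) {
    data.frame(gene = gene$gene_id, species = gene$species, class = class,
               reason = reason, stringsAsFactors = FALSE)
  }
  if (!identical(gene$biotype, "protein_coding")) {
    return(call("EXCLUDED", "non_coding"))
  }
  if (gene$seqname %in% mito_names) {
    return(call("EXCLUDED", "mitochondrial"))
  }
  has_cds <- vapply(gene$transcripts,
                    function(tx) !is.null(tx$cds) && nrow(tx$cds) > 0L, logical(1))
  if (!any(has_cds)) {
    return(call("EXCLUDED", "incomplete_annotation"))
  }
  if (length(gene$transcripts) > 1L) {
    return(call("MEG", "multi_transcript"))
  }
  tx <- gene$transcripts[[1L]]
  cds_exons <- unique(apply(tx$cds, 1L, function(iv) {
    which(tx$exons[, 1L] <= iv[1L] & tx$exons[, 2L] >= iv[2L])[1L]
  }))
  if (length(cds_exons) > 1L || nrow(tx$cds) > 1L) {
    return(call("MEG", "multi_exon"))
  }
  if (nrow(tx$exons) > 1L) {
    return(call("MEG", "utr_intron"))
  }
  call("IG", "ok")
}

#' Partition annotated genes into IG and MEG datasets
#'
#' Classifies every gene with [classify_gene()] and returns the disjoint IG
#' and MEG id sets together with the per-reason census. The three sets
#' (IG, MEG, excluded) always partition the input.
#'
#' @param genes list of [gene_model()] objects.
#' @param mito_names contig names treated as mitochondrial.
#' @return List with `ig`, `meg`, `excluded` (character id vectors), `calls`
#'   (full classification data frame) and `summary` (counts per reason).
#' @export
build_datasets <- function(genes, mito_names = c("MT", "chrM", "chrMT")) {
  if (length(genes) == 0L) {
    calls <- data.frame(gene = character(), species = character(),
                        class = character(), reason = character(),
                        stringsAsFactors = FALSE)
  } else {
    calls <- do.call(rbind, lapply(genes, classify_gene, mito_names = mito_names))
    rownames(calls) <- NULL
  }
  list(
    ig = calls$gene[calls$class == "IG"],
    meg = calls$gene[calls$class == "MEG"],
    excluded = calls$gene[calls$class == "EXCLUDED"],
    calls = calls,
    summary = table(reason = calls$reason)
  )
}
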