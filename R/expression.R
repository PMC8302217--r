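#' Counts-per-million normalization
#'
#' `cpm[g, s] = count[g, s] / library_size[s] * 1e6`. Library sizes default
#' to column sums.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param lib_sizes optional per-sample library sizes (all > 0).
#' @return Numeric matrix of CPM values, same dimensions as `counts`.
#' @export
cpm_normalize <- function(counts, lib_sizes = colSums(counts)) {
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  sweep(counts, 2L, lib_sizes, "/") * 1e6
}

#' Expression floor: the not-expressed (NE) gene set
#'
#' A gene counts as expressed iff at least `min_samples` of its samples have
#' a read count of at least `min_count`; everything else is not expressed
#' (NE). The defaults encode "count >= 5 in >= 4 of 8 samples". The
#' conventional phrasing of such rules is ambiguous between two readings;
#' the converse one (NE iff count < `min_count` in fewer than `min_samples`
#' samples) is available as `rule = "literal"`. An additional CPM cutoff can
#' be supplied, in which case samples must also reach `cpm_cutoff` CPM to
#' count toward the floor.
#'
#' @param counts genes x samples count matrix.
#' @param min_count count threshold (positive).
#' @param min_samples sample threshold (positive).
#' @param rule `"expressed_if"` (default) or `"literal"`.
#' @param cpm_cutoff optional CPM threshold applied jointly with `min_count`.
#' @return Character vector of NE gene ids.
#' @export
expression_floor <- function(counts, min_count = 5, min_samples = 4,
                             rule = c("expressed_if", "literal"),
                             cpm_cutoff = NULL) {
  stopifnot(min_count > 0, min_samples > 0)
  rule <- match.arg(rule)
  pass <- counts >= min_count
  if (!is.null(cpm_cutoff)) {
    pass <- pass & cpm_normalize(counts) >= cpm_cutoff
  }
  ne <- if (rule == "expressed_if") {
    rowSums(pass) < min_samples
  } else {
    rowSums(!pass) < min_samples
  }
  rownames(counts)[ne]
}

#' Per-gene differential expression test between two conditions
#'
#' Computes, for every gene, the log2 fold change of condition B over
#' condition A from mean CPM with a pseudo-count, and a p-value from a
#' pluggable simple test: `logcpm_t` (Welch t-test on log2(CPM +
#' pseudo-count), the default) or `binomial` (exact binomial test on pooled
#' counts against the library-size proportion). Full-scale analyses normally
#' delegate this step to a dedicated, dispersion-moderated DE engine; the
#' tests here are deliberate, clearly-labeled stand-ins — the downstream
#' classification rules are what this package commits to.
#'
#' @param counts genes x samples integer matrix.
#' @param condition character/factor of length `ncol(counts)` with two
#'   levels; the second level is the "B" (later) condition.
#' @param method `"logcpm_t"` or `"binomial"`.
#' @param pseudo pseudo-count added to mean CPM for fold changes.
#' @return Data frame (gene, log2FC, p).
#' @export
de_test <- function(counts, condition, method = c("logcpm_t", "binomial"),
                    pseudo = 0.5) {
  method <- match.arg(method)
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L) stop("exactly two conditions required")
  a <- condition == levels(condition)[1L]
  b <- condition == levels(condition)[2L]
  if (sum(a) < 2L || sum(b) < 2L) stop("need >= 2 replicates per condition")
  cpm <- cpm_normalize(counts)
  lfc <- log2((rowMeans(cpm[, b, drop = FALSE]) + pseudo) /
                (rowMeans(cpm[, a, drop = FALSE]) + pseudo))
  if (method == "logcpm_t") {
    lc <- log2(cpm + pseudo)
    p <- vapply(seq_len(nrow(counts)), function(i) {
      xa <- lc[i, a]; xb <- lc[i, b]
      if (stats::var(xa) == 0 && stats::var(xb) == 0) {
        return(if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0)
      }
      stats::t.test(xb, xa)$p.value
    }, numeric(1))
  } else {
    la <- sum(counts[, a]); lb <- sum(counts[, b])
    prob <- lb / (la + lb)
    p <- vapply(seq_len(nrow(counts)), function(i) {
      sa <- sum(counts[i, a]); sb <- sum(counts[i, b])
      if (sa + sb == 0L) return(1)
      stats::binom.test(sb, sa + sb, p = prob)$p.value
    }, numeric(1))
  }
  data.frame(gene = rownames(counts), log2FC = unname(lfc), p = unname(p),
             stringsAsFactors = FALSE)
}

#' Classify genes into UP / DN / NC / NE
#'
#' The not-expressed set overrides everything; otherwise a gene is UP if its
#' p-value is at most `alpha` with positive log2 fold change, DN with
#' negative log2 fold change, and NC (no change) otherwise.
#'
#' @param results data frame (gene, log2FC, p) from [de_test()].
#' @param ne_set character vector of NE gene ids (from
#'   [expression_floor()]); ids absent from `results` are appended as NE
#'   calls with undefined statistics.
#' @param alpha significance threshold.
#' @return Object of class `de_calls`: data frame (gene, log2FC, p, class)
#'   plus a `tally` attribute (see [de_tally()]).
#' @export
classify_de <- function(results, ne_set = character(), alpha = 0.05) {
  cls <- ifelse(results$p <= alpha & results$log2FC > 0, "UP",
                ifelse(results$p <= alpha & results$log2FC < 0, "DN", "NC"))
  cls[results$gene %in% ne_set] <- "NE"
  out <- data.frame(gene = results$gene, log2FC = results$log2FC,
                    p = results$p, class = cls, stringsAsFactors = FALSE)
  extra <- setdiff(ne_set, results$gene)
  if (length(extra) > 0L) {
    out <- rbind(out, data.frame(gene = extra, log2FC = NA_real_, p = NA_real_,
                                 class = "NE", stringsAsFactors = FALSE))
  }
  out$class <- factor(out$class, levels = c("UP", "DN", "NC", "NE"))
  structure(out, class = c("de_calls", "data.frame"))
}

#' Tally differential-expression classes
#'
#' Counts UP/DN/NC/NE calls and their percentages of all classified genes
#' (percentages at two decimals recompute exactly from the integer counts).
#'
#' @param calls a `de_calls` data frame from [classify_de()], or a named
#'   integer vector of class counts.
#' @return Data frame (class, n, pct).
#' @export
de_tally <- function(calls) {
  counts <- if (is.data.frame(calls)) {
    table(factor(calls$class, levels = c("UP", "DN", "NC", "NE")))
  } else {
    calls[c("UP", "DN", "NC", "NE")]
  }
  n <- as.integer(counts)
  data.frame(class = c("UP", "DN", "NC", "NE"), n = n,
             pct = round(100 * n / sum(n), 2), stringsAsFactors = FALSE)
}

#' Strongly differentially expressed genes
#'
#' The subset of UP/DN calls with |log2FC| at or above a threshold (default
#' 2), the study set used for functional enrichment.
#'
#' @param calls a `de_calls` data frame.
#' @param lfc_threshold absolute log2 fold-change threshold.
#' @return Character vector of gene ids.
#' @export
strong_de <- function(calls, lfc_threshold = 2) {
  calls$gene[calls$class %in% c("UP", "DN") &
               !is.na(calls$log2FC) & abs(calls$log2FC) >= lfc_threshold]
}
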