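#' Hypergeometric over-representation analysis
#'
#' For every annotation term, tests whether the study set contains more
#' term-bearing genes than expected under sampling without replacement from
#' the background: with N background genes, K of them carrying the term, and
#' a study set of size n containing k carriers, the p-value is the upper
#' tail P(X >= k) of the hypergeometric distribution. Terms absent from the
#' background (K = 0) are skipped. Benjamini-Hochberg q-values are attached
#' and results are sorted by p.
#'
#' @param study character vector of study gene ids (must be a subset of
#'   `background`).
#' @param background character vector of background ("universe") gene ids.
#' @param terms term map: data frame (gene, term) or named list gene ->
#'   character vector of terms. Genes without terms are allowed.
#' @return Data frame (term, k, K, n, N, p, q) sorted by increasing p.
#' @export
hypergeom_enrich <- function(study, background, terms) {
  study <- unique(study)
  background <- unique(background)
  if (length(background) == 0L) stop("background must be non-empty")
  if (!all(study %in% background)) {
    stop("study set is not a subset of the background")
  }
  tm <- if (is.data.frame(terms)) {
    data.frame(gene = terms[[1L]], term = terms[[2L]], stringsAsFactors = FALSE)
  } else {
    data.frame(gene = rep(names(terms), lengths(terms)),
               term = unlist(terms, use.names = FALSE), stringsAsFactors = FALSE)
  }
  tm <- unique(tm[tm$gene %in% background, , drop = FALSE])
  N <- length(background)
  n <- length(study)
  K <- table(tm$term)
  k <- table(factor(tm$term[tm$gene %in% study], levels = names(K)))
  res <- data.frame(term = names(K), k = as.integer(k), K = as.integer(K),
                    n = n, N = N, stringsAsFactors = FALSE)
  res <- res[res$K > 0L, , drop = FALSE]
  res$p <- stats::phyper(res$k - 1L, res$K, res$N - res$K, res$n,
                         lower.tail = FALSE)
  res <- res[order(res$p, res$term), , drop = FALSE]
  res$q <- adjust_bh(res$p)
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; output order matches input
#' order and q-values are capped at 1.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values.
#' @export
adjust_bh <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}
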