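#' Compare one PTM's prevalence between IG and MEG proteins
#'
#' Two-proportion z-test with pooled variance:
#' `z = (p1 - p2) / sqrt(p(1-p) (1/n1 + 1/n2))` where `p` is the pooled
#' proportion; the p-value is two-sided normal. Classification follows the
#' study's rules: a PTM present in exactly one class is "unique" to it
#' (decided before any test); otherwise p >= alpha means "similar" and
#' p < alpha means enriched in whichever class has the higher relative
#' percentage.
#'
#' @param ptm PTM type label.
#' @param k_ig,n_ig modified and total IG proteins (`n_ig > 0`, `k <= n`).
#' @param k_meg,n_meg modified and total MEG proteins.
#' @param alpha significance threshold.
#' @param continuity apply a continuity correction (|p1 - p2| reduced by
#'   `(1/n1 + 1/n2)/2`)? Off by default.
#' @return One-row data frame (ptm, k_ig, n_ig, k_meg, n_meg, z, p, class)
#'   with class in similar / IG-enriched / MEG-enriched / unique-IG /
#'   unique-MEG.
#' @export
compare_ptm <- function(ptm, k_ig, n_ig, k_meg, n_meg, alpha = 0.05,
                        continuity = FALSE) {
  if (n_ig <= 0L || n_meg <= 0L) stop("class totals must be positive")
  stopifnot(k_ig >= 0, k_meg >= 0, k_ig <= n_ig, k_meg <= n_meg)
  row <- function(z, p, class) {
    data.frame(ptm = ptm, k_ig = k_ig, n_ig = n_ig, k_meg = k_meg,
               n_meg = n_meg, z = z, p = p, class = class,
               stringsAsFactors = FALSE)
  }
  if (k_ig == 0L && k_meg > 0L) return(row(NA_real_, NA_real_, "unique-MEG"))
  if (k_meg == 0L && k_ig > 0L) return(row(NA_real_, NA_real_, "unique-IG"))
  if (k_ig == 0L && k_meg == 0L) return(row(0, 1, "similar"))
  p1 <- k_ig / n_ig
  p2 <- k_meg / n_meg
  pool <- (k_ig + k_meg) / (n_ig + n_meg)
  se <- sqrt(pool * (1 - pool) * (1 / n_ig + 1 / n_meg))
  diff <- p1 - p2
  if (continuity) diff <- sign(diff) * max(0, abs(diff) - (1 / n_ig + 1 / n_meg) / 2)
  z <- if (se == 0) 0 else diff / se
  p <- 2 * stats::pnorm(-abs(z))
  class <- if (p >= alpha) "similar" else if (p1 > p2) "IG-enriched" else "MEG-enriched"
  row(z, p, class)
}

#' Classify every PTM type in an annotation table
#'
#' Aggregates a long table of modified proteins (protein_id, ptm_type, class
#' IG|MEG) into per-PTM counts and runs [compare_ptm()] on each. Totals per
#' class default to the number of distinct proteins observed in the table
#' but should normally be supplied (proteins with no PTM never appear in
#' the table).
#'
#' @param table long data frame with columns protein_id, ptm_type, class.
#' @param n_ig,n_meg total IG / MEG proteins.
#' @param alpha significance threshold.
#' @param continuity passed to [compare_ptm()].
#' @return List with `comparisons` (one row per PTM type) and `summary`
#'   (class census).
#' @export
classify_all_ptms <- function(table, n_ig = NULL, n_meg = NULL, alpha = 0.05,
                              continuity = FALSE) {
  if (nrow(table) == 0L) {
    cmp <- data.frame(ptm = character(), k_ig = integer(), n_ig = integer(),
                      k_meg = integer(), n_meg = integer(), z = numeric(),
                      p = numeric(), class = character(), stringsAsFactors = FALSE)
    return(list(comparisons = cmp, summary = table(factor(character()))))
  }
  stopifnot(all(table$class %in% c("IG", "MEG")))
  if (is.null(n_ig)) n_ig <- length(unique(table$protein_id[table$class == "IG"]))
  if (is.null(n_meg)) n_meg <- length(unique(table$protein_id[table$class == "MEG"]))
  ptms <- sort(unique(table$ptm_type))
  cmp <- do.call(rbind, lapply(ptms, function(p) {
    sub <- table[table$ptm_type == p, , drop = FALSE]
    compare_ptm(p,
                k_ig = length(unique(sub$protein_id[sub$class == "IG"])),
                n_ig = n_ig,
                k_meg = length(unique(sub$protein_id[sub$class == "MEG"])),
                n_meg = n_meg,
                alpha = alpha, continuity = continuity)
  }))
  rownames(cmp) <- NULL
  list(comparisons = cmp, summary = table(class = cmp$class))
}

#' Screen for microprotein candidates
#'
#' Microproteins (miPs) are short single-domain proteins that heterodimerize
#' with larger multi-domain proteins and modulate them. A protein is a
#' candidate iff its length is at most `max_length` amino acids, it carries
#' exactly one annotated domain, and some other protein of length at least
#' `partner_min_length` carries that domain among two or more domains. The
#' thresholds are this package's documented defaults, not published values.
#'
#' @param proteins data frame with columns id, length, domains (domains
#'   either a list-column of character vectors or a semicolon-joined
#'   string).
#' @param max_length maximum candidate length (aa).
#' @param partner_min_length minimum partner length (aa).
#' @return Data frame (id, length, domain, partner) of candidates with one
#'   row per (candidate, qualifying partner is the first found).
#' @export
screen_microproteins <- function(proteins, max_length = 250,
                                 partner_min_length = 400) {
  stopifnot(all(proteins$length > 0))
  doms <- proteins$domains
  if (!is.list(doms)) {
    doms <- strsplit(as.character(doms), ";", fixed = TRUE)
    doms <- lapply(doms, function(d) trimws(d[nzchar(trimws(d))]))
  }
  n_dom <- lengths(doms)
  out <- list()
  for (i in seq_len(nrow(proteins))) {
    if (proteins$length[i] > max_length || n_dom[i] != 1L) next
    dom <- doms[[i]]
    partner <- which(
      seq_len(nrow(proteins)) != i &
        proteins$length >= partner_min_length &
        n_dom >= 2L &
        vapply(doms, function(d) dom %in% d, logical(1))
    )
    if (length(partner) > 0L) {
      out[[length(out) + 1L]] <- data.frame(
        id = proteins$id[i], length = proteins$length[i], domain = dom,
        partner = proteins$id[partner[1L]], stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(id = character(), length = numeric(), domain = character(),
                      partner = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
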