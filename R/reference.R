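#' Reference summary tables for the mouse IG/MEG comparison
#'
#' Small plain-text tables shipped with the package as worked-example inputs:
#' the per-genome ortholog architecture counts of mouse intronless genes
#' (`"ig_orthologs"`) and of mouse multi-exon genes (`"meg_orthologs"`), the
#' UP/DN/NC/NE class tallies of the embryonic-telencephalon differential
#' expression comparison (`"de_counts"`), and the beta-protocadherin cluster
#' gene list with architecture flags and DE classes (`"pcdhb_cluster"`).
#'
#' The ortholog and DE tables carry the reported study totals. In the
#' protocadherin table only the totals (22 members, 18 IGs, 9 up-regulated,
#' one not-expressed member) and the identity of the nine up-regulated genes
#' are reported values; the per-gene architecture flags of the remaining
#' members and the identity of the single not-expressed member are synthetic
#' placeholders consistent with those totals.
#'
#' @param which one of "ig_orthologs", "meg_orthologs", "de_counts",
#'   "pcdhb_cluster".
#' @return The requested table as a data frame.
#' @examples
#' conservation_fractions(reference_table("ig_orthologs"))$rows
#' @export
reference_table <- function(which = c("ig_orthologs", "meg_orthologs",
                                      "de_counts", "pcdhb_cluster")) {
  which <- match.arg(which)
  file <- switch(which,
                 ig_orthologs = "mouse_ig_ortholog_counts.tsv",
                 meg_orthologs = "mouse_meg_ortholog_counts.tsv",
                 de_counts = "telencephalon_de_counts.tsv",
                 pcdhb_cluster = "pcdhb_cluster.tsv")
  path <- system.file("extdata", file, package = "intronless", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
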