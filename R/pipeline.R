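#' Pipeline configuration
#'
#' Bundles the simulation settings, stage thresholds and stage toggles of
#' [run_pipeline()].
#'
#' @param outdir run directory (created by [run_pipeline()]).
#' @param sim a [simulation_config()].
#' @param min_identity BBH percent-identity threshold.
#' @param alpha significance threshold for DE and PTM tests.
#' @param min_count,min_samples expression-floor parameters.
#' @param age_mode conservation-age rule, "strict" or "deepest".
#' @param seed master seed for every stochastic stage.
#' @param stages named logical vector toggling stages (architecture,
#'   orthology, evolution, conservation, expression, enrichment, ptm,
#'   synteny); missing names default to TRUE.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("igrun"), sim = simulation_config(),
                            min_identity = 50, alpha = 0.05,
                            min_count = 5, min_samples = 4,
                            age_mode = c("strict", "deepest"), seed = 1L,
                            stages = logical()) {
  age_mode <- match.arg(age_mode)
  all_stages <- c("architecture", "orthology", "evolution", "conservation",
                  "expression", "enrichment", "ptm", "synteny")
  on <- stats::setNames(rep(TRUE, length(all_stages)), all_stages)
  on[names(stages)] <- stages
  stopifnot(min_identity > 0, min_identity <= 100, alpha > 0, alpha < 1)
  structure(list(outdir = outdir, sim = sim, min_identity = min_identity,
                 alpha = alpha, min_count = min_count, min_samples = min_samples,
                 age_mode = age_mode, seed = as.integer(seed), stages = on),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline on simulated data
#'
#' Simulates gene families with known ground truth, writes every intermediate
#' input to the run directory, and executes the enabled stages end to end:
#' annotation emission and IG/MEG classification; similarity emission, best
#' bidirectional hits, orthology graph and orthogroups; gene-tree inference
#' and reconciliation with per-clade gain/loss summaries; conservation ages
#' and the per-genome architecture table; count emission and UP/DN/NC/NE
#' classification; term enrichment of the up-regulated set; PTM comparison;
#' and a mouse-vs-rat locus synteny report. A manifest records parameters
#' and seed; reruns with an identical configuration reproduce identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a named list of stage results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  ladder <- species_ladder()
  on <- config$stages
  res <- list()

  histories <- simulate_families(ladder, config$sim, seed = config$seed)
  genes <- do.call(rbind, lapply(histories, `[[`, "genes"))
  species_map <- stats::setNames(genes$species, genes$gene)
  res$histories <- histories

  calls <- NULL
  if (on[["architecture"]]) {
    emitted <- emit_annotations(histories, config$sim,
                                file.path(config$outdir, "annotations"),
                                seed = config$seed)
    models <- list()
    for (sp in names(emitted$paths)) {
      models <- c(models, read_annotation(emitted$paths[sp], sp))
    }
    datasets <- build_datasets(models)
    calls <- datasets$calls
    write_tsv(calls, file.path(config$outdir, "architecture_calls.tsv"))
    jsonlite::write_json(as.list(datasets$summary),
                         file.path(config$outdir, "architecture_summary.json"),
                         auto_unbox = TRUE)
    res$architecture <- datasets
    res$annotations <- emitted
  }

  graph <- NULL; groups <- NULL
  if (on[["orthology"]]) {
    sim_path <- file.path(config$outdir, "similarity.tsv")
    emit_similarity(histories, noise = config$sim$similarity_noise,
                    seed = config$seed, path = sim_path)
    records <- read_similarity(sim_path)
    edges <- best_bidirectional_hits(records, species_map,
                                     min_identity = config$min_identity)
    graph <- build_orthology_graph(edges, species_map)
    groups <- cluster_orthogroups(graph)
    write_tsv(edges, file.path(config$outdir, "bbh_edges.tsv"))
    write_tsv(orthogroup_table(groups, species_map),
              file.path(config$outdir, "orthogroups.tsv"))
    res$orthology <- list(edges = edges, graph = graph, groups = groups)
  }

  if (on[["evolution"]] && !is.null(graph)) {
    hist_inf <- infer_histories(graph, groups, ladder)
    summary <- summarize_histories(lapply(hist_inf, `[[`, "reconciliation"), ladder)
    write_tsv(summary, file.path(config$outdir, "clade_gains_losses.tsv"))
    writeLines(vapply(hist_inf, function(h) event_tree_newick(h$tree), character(1)),
               file.path(config$outdir, "gene_trees.nwk"))
    res$evolution <- list(histories = hist_inf, summary = summary)
  }

  if (on[["conservation"]] && !is.null(graph) && !is.null(calls)) {
    profiles <- presence_profiles(graph, calls)
    ages <- assign_ages(profiles, mode = config$age_mode)
    tab <- architecture_table(profiles)
    write_tsv(ages, file.path(config$outdir, "conservation_ages.tsv"))
    write_tsv(tab, file.path(config$outdir, "architecture_table.tsv"))
    res$conservation <- list(profiles = profiles, ages = ages, table = tab,
                             fractions = conservation_fractions(tab))
  }

  de_calls <- NULL
  if (on[["expression"]]) {
    cm <- emit_counts(config$sim, seed = config$seed)
    ne <- expression_floor(cm$counts, config$min_count, config$min_samples)
    de <- de_test(cm$counts, cm$design$condition)
    de_calls <- classify_de(de, ne, alpha = config$alpha)
    tally <- de_tally(de_calls)
    write_tsv(de_calls, file.path(config$outdir, "de_calls.tsv"))
    jsonlite::write_json(tally, file.path(config$outdir, "de_tally.json"))
    res$expression <- list(counts = cm, calls = de_calls, tally = tally)
  }

  if (on[["enrichment"]] && !is.null(de_calls)) {
    set.seed(config$seed + 7L)
    tested <- de_calls$gene[de_calls$class != "NE"]
    terms <- data.frame(
      gene = sample(tested, size = max(1L, round(length(tested) * 0.6)), replace = TRUE),
      term = sample(sprintf("T%02d", 1:12),
                    size = max(1L, round(length(tested) * 0.6)), replace = TRUE),
      stringsAsFactors = FALSE
    )
    study <- de_calls$gene[de_calls$class == "UP"]
    enr <- hypergeom_enrich(intersect(study, tested), tested, terms)
    write_tsv(enr, file.path(config$outdir, "enrichment.tsv"))
    res$enrichment <- enr
  }

  if (on[["ptm"]]) {
    tab <- emit_ptm_table(
      props_ig = c(Acetylation = 0.3, Phosphorylation = 0.2, Sumoylation = 0.1),
      props_meg = c(Acetylation = 0.1, Phosphorylation = 0.5, Nitration = 0.05),
      n_ig = 300, n_meg = 600, seed = config$seed + 11L
    )
    ptm <- classify_all_ptms(tab, n_ig = 300, n_meg = 600, alpha = config$alpha)
    write_tsv(ptm$comparisons, file.path(config$outdir, "ptm_comparisons.tsv"))
    res$ptm <- ptm
  }

  if (on[["synteny"]] && on[["architecture"]] && !is.null(groups)) {
    group_map <- stats::setNames(
      rep(names(groups), lengths(groups)), unlist(groups, use.names = FALSE))
    loci <- lapply(c("mouse", "rat"), function(sp) {
      models <- read_annotation(res$annotations$paths[[sp]], sp)
      extract_locus(models, sp, "chr1", 1L, .Machine$integer.max, group_map)
    })
    report <- pairwise_synteny(loci[[1L]], loci[[2L]])
    jsonlite::write_json(
      list(matches = report$matches, losses = report$losses,
           gains = report$gains, expansions = report$expansions,
           inversions = report$inversions),
      file.path(config$outdir, "synteny_mouse_rat.json"), auto_unbox = TRUE)
    res$synteny <- report
  }

  manifest <- list(
    package = "intronless",
    version = as.character(utils::packageVersion("intronless")),
    seed = config$seed,
    parameters = config[c("min_identity", "alpha", "min_count", "min_samples",
                          "age_mode")],
    stages = as.list(config$stages),
    sim = unclass(config$sim)
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(res)
}
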