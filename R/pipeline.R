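#' Pipeline configuration
#'
#' Bundles every input and threshold of the end-to-end analysis. Either
#' supply counted libraries (`libraries`, a named list with at least `A`
#' and `C`) or a [synthetic_config()] from which they are generated.
#'
#' @param libraries named list of `mimotope_library` objects (`A`, `C`,
#'   optionally `G`, `B`) or NULL to generate synthetically.
#' @param synthetic a [synthetic_config()] used when `libraries` is NULL.
#' @param exclusion_sequences peptides to discard as target-unrelated.
#' @param min_count,max_count copy-number retention window applied to the
#'   pooled counts (NULL = skip the filter).
#' @param max_distance LCS-distance edge criterion.
#' @param alpha FDR level for differential calls.
#' @param min_cluster_size minimal workable cluster size.
#' @param pssm_pseudocount PSSM pseudocount.
#' @param epitopes optional epitope data.frame (`id`, `sequence`).
#' @param proteome optional named character vector / `AAStringSet`.
#' @param rng_seed master seed; per-stage seeds are derived from it.
#' @param out_dir optional output directory for TSV/GraphML/JSON
#'   artifacts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(libraries = NULL,
                            synthetic = synthetic_config(),
                            exclusion_sequences = character(0),
                            min_count = NULL, max_count = NULL,
                            max_distance = 4, alpha = 0.05,
                            min_cluster_size = 4,
                            pssm_pseudocount = 1 / 20,
                            epitopes = NULL, proteome = NULL,
                            rng_seed = 42, out_dir = NULL) {
  stopifnot(max_distance >= 0, alpha > 0, alpha < 1, min_cluster_size >= 1)
  structure(list(libraries = libraries, synthetic = synthetic,
                 exclusion_sequences = exclusion_sequences,
                 min_count = min_count, max_count = max_count,
                 max_distance = max_distance, alpha = alpha,
                 min_cluster_size = min_cluster_size,
                 pssm_pseudocount = pssm_pseudocount,
                 epitopes = epitopes, proteome = proteome,
                 rng_seed = as.integer(rng_seed), out_dir = out_dir),
            class = "pipeline_config")
}

.stage_seed <- function(master, stage) {
  (as.integer(master) + 7919L * stage) %% .Machine$integer.max
}

#' Run the full Igome analysis pipeline
#'
#' Orchestrates ingestion/pooling, graph construction, topology
#' statistics, differential neighborhoods, the significant-neighborhood
#' (NG) induced subgraph, recursive Louvain clustering of both NG and the
#' whole graph, per-cluster differential calls, PSSM models of the called
#' clusters, optional epitope/proteome scans, external-library neighbor
#' counts, diversity estimation and the entropy profile. Deterministic
#' given the master seed.
#'
#' @param config a [pipeline_config()].
#' @return list of class `igome_report` with per-stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(config = config)

  libs <- config$libraries
  truth <- NULL
  if (is.null(libs)) {
    syn <- config$synthetic
    syn$rng_seed <- .stage_seed(config$rng_seed, 1L)
    fams <- generate_families(syn)
    libs <- generate_libraries(fams, syn)
    truth <- attr(libs, "truth")
    report$families <- fams
  }
  if (!all(c("A", "C") %in% names(libs)))
    stop("pipeline needs at least libraries A and C")

  pooled <- pool_libraries(libs[c("A", "C")])
  report$overlaps <- attr(pooled, "overlaps")
  if (!is.null(config$min_count))
    pooled <- filter_copy_number(pooled, config$min_count,
                                 config$max_count %||% Inf)
  if (length(config$exclusion_sequences))
    pooled <- apply_exclusion_list(pooled, config$exclusion_sequences)
  report$pooled <- pooled

  g <- build_graph(pooled, config$max_distance)
  report$graph <- g
  report$graph_stats <- graph_stats(g)

  labels <- cohort_labels(g)
  nb <- differential_neighborhoods(g, labels, alpha = config$alpha)
  report$neighborhoods <- nb

  sig_centers <- nb$sequence[nb$call != "ns"]
  if (length(sig_centers) > 0) {
    sig_vertices <- unique(unlist(igraph::ego(
      g, order = 1, nodes = match(sig_centers, igraph::V(g)$name))))
    ng <- induced_igome_subgraph(g, sig_vertices)
    report$ng_graph <- ng
    tree_ng <- recursive_louvain(ng, seed = .stage_seed(config$rng_seed, 2L),
                                 min_size = config$min_cluster_size)
    part_ng <- cut_tree_partition(tree_ng, ng, config$min_cluster_size)
    report$ng_partition <- part_ng
    report$ng_calls <- differential_clusters(part_ng, g,
                                             alpha = config$alpha)
  }

  tree_wg <- recursive_louvain(g, seed = .stage_seed(config$rng_seed, 3L),
                               min_size = config$min_cluster_size)
  part_wg <- cut_tree_partition(tree_wg, g, config$min_cluster_size)
  report$wg_partition <- part_wg
  report$wg_calls <- differential_clusters(part_wg, g, alpha = config$alpha)

  called <- report$wg_calls[report$wg_calls$call != "ns", , drop = FALSE]
  if (nrow(called) > 0) {
    report$pssm_models <- lapply(called$cluster, function(cl)
      build_pssm(part_wg$clusters[[cl]],
                 pseudocount = config$pssm_pseudocount, cluster_id = cl))
    if (!is.null(config$epitopes))
      report$epitope_hits <- scan_epitopes(report$pssm_models,
                                           config$epitopes)
    if (!is.null(config$proteome)) {
      called_seqs <- unique(unlist(part_wg$clusters[called$cluster]))
      report$proteome_hits <- exact_proteome_match(called_seqs,
                                                   config$proteome)
    }
  }

  vseq <- igraph::V(g)$name
  profile <- data.frame(sequence = vseq,
                        degree = igraph::degree(g),
                        entropy = mm_entropy(vseq),
                        stringsAsFactors = FALSE)
  profile$entropy_class <- classify_entropy(profile$entropy)
  for (x in intersect(c("G", "B", "I"), names(libs))) {
    profile[[paste0("n_", x)]] <-
      external_neighbor_counts(vseq, libs[[x]]$sequence,
                               config$max_distance)
  }
  report$vertex_profile <- profile

  if (all(c("G", "B") %in% names(libs))) {
    report$gb_partial_correlation <- partial_correlation(
      log1p(profile$n_G), log1p(profile$degree),
      controls = log1p(profile$n_B))
  }
  if ("B" %in% names(libs)) {
    ov <- length(intersect(libs$B$sequence, pooled$sequence))
    report$diversity <- if (ov >= 1)
      capture_recapture(nrow(libs$B), nrow(pooled), ov,
                        seed = .stage_seed(config$rng_seed, 4L))
      else NULL
  }
  if (!is.null(truth)) {
    report$truth <- truth
    report$recovery <- planted_recovery(nb, truth, alpha = config$alpha)
  }

  if (!is.null(config$out_dir)) .write_report(report, config$out_dir)
  class(report) <- "igome_report"
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Recovery of planted differential families
#'
#' Per-vertex sensitivity/specificity of the differential-neighborhood
#' calls against the planted truth of the synthetic generator: a member
#' of a shifted family counts as recovered when its neighborhood is
#' called significant in the planted direction.
#'
#' @param neighborhoods a `neighborhood_result`.
#' @param truth the `truth` attribute of [generate_libraries()].
#' @param alpha FDR level.
#' @return list: `sensitivity`, `false_positive_rate`, `n_shifted`,
#'   `n_null`.
#' @export
planted_recovery <- function(neighborhoods, truth, alpha = 0.05) {
  m <- merge(neighborhoods, truth, by = "sequence", all.x = TRUE)
  m$shifted[is.na(m$shifted)] <- FALSE
  shifted <- m[m$shifted, , drop = FALSE]
  null <- m[!m$shifted, , drop = FALSE]
  list(sensitivity = if (nrow(shifted)) mean(shifted$q_value <= alpha &
         shifted$call == shifted$direction) else NA_real_,
       false_positive_rate = if (nrow(null)) mean(null$q_value <= alpha)
         else NA_real_,
       n_shifted = nrow(shifted), n_null = nrow(null))
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_library_tsv(report$pooled, file.path(out_dir, "pooled.tsv"))
  export_graphml(report$graph, file.path(out_dir, "graph.graphml"))
  utils::write.table(as.data.frame(report$neighborhoods),
                     file.path(out_dir, "neighborhoods.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(report$wg_calls),
                     file.path(out_dir, "cluster_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$vertex_profile,
                     file.path(out_dir, "vertex_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$pssm_models))
    write_pssm_json(report$pssm_models, file.path(out_dir, "pssm.json"))
  smry <- list(
    n_vertices = report$graph_stats$n_vertices,
    n_edges = report$graph_stats$n_edges,
    degree_assortativity = report$graph_stats$degree_assortativity,
    n_significant_neighborhoods =
      attr(report$neighborhoods, "summary")$n_significant,
    cluster_summary = attr(report$wg_calls, "summary"),
    diversity = if (!is.null(report$diversity))
      report$diversity[c("estimate", "interval_5_95")] else NULL)
  jsonlite::write_json(smry, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.igome_report <- function(x, ...) {
  gs <- x$graph_stats
  cat(sprintf("Igome analysis report: graph %d vertices / %d edges\n",
              gs$n_vertices, gs$n_edges))
  print(x$neighborhoods)
  print(x$wg_calls)
  invisible(x)
}
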