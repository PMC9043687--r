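#' Per-vertex cohort labels from membership flags
#'
#' Derives `"A"`, `"C"` or `"AC"` per vertex from the comma-separated
#' `libs` vertex attribute (or a supplied vector).
#'
#' @param g igraph graph with a `libs` vertex attribute.
#' @return character vector over vertices.
#' @export
cohort_labels <- function(g) {
  libs <- igraph::vertex_attr(g, "libs")
  if (is.null(libs)) stop("graph has no 'libs' vertex attribute")
  flags <- strsplit(libs, ",")
  vapply(flags, function(f) {
    a <- "A" %in% f; c <- "C" %in% f
    if (a && c) "AC" else if (a) "A" else if (c) "C"
    else stop("vertex not labeled A or C")
  }, character(1))
}

.label_weights <- function(labels) {
  wA <- ifelse(labels == "A", 1, ifelse(labels == "AC", 0.5, 0))
  wC <- ifelse(labels == "C", 1, ifelse(labels == "AC", 0.5, 0))
  list(A = wA, C = wC)
}

#' Weighted cohort fraction under the half-split rule
#'
#' Sequences present in both cohorts contribute half a count to each, so
#' the weighted fraction of cohort `C` over `n_A_only + n_C_only +
#' n_common` sequences is `(n_C_only + n_common / 2) / total`.
#'
#' @param n_A_only,n_C_only,n_common sequence counts.
#' @return fraction of `C` mass in (0, 1).
#' @export
weighted_label_fraction <- function(n_A_only, n_C_only, n_common) {
  (n_C_only + n_common / 2) / (n_A_only + n_C_only + n_common)
}

#' Cohort composition of every closed vertex neighborhood
#'
#' Each vertex's closed neighborhood (the vertex and all its graph
#' neighbors) is the smallest continuous fragment of an antibody
#' footprint; its composition is the half-split-weighted count of `A` and
#' `C` members.
#'
#' @param g igraph graph.
#' @param labels per-vertex labels in `{"A","C","AC"}`; default derived
#'   via [cohort_labels()].
#' @param closed include the center vertex (default TRUE).
#' @return data.frame: `sequence`, `size`, `weight_A`, `weight_C`.
#' @export
neighborhood_composition <- function(g, labels = cohort_labels(g),
                                     closed = TRUE) {
  w <- .label_weights(labels)
  adj <- igraph::as_adj_list(g)
  nb_sum <- function(v) {
    idx <- as.integer(adj[[v]])
    if (closed) idx <- c(idx, v)
    c(sum(w$A[idx]), sum(w$C[idx]), length(idx))
  }
  m <- vapply(seq_len(igraph::vcount(g)), nb_sum, numeric(3))
  data.frame(sequence = igraph::V(g)$name,
             size = m[3, ], weight_A = m[1, ], weight_C = m[2, ],
             stringsAsFactors = FALSE)
}

#' Two-sided proportion or exact binomial test
#'
#' For more than 30 elements, a one-sample z-test of a proportion without
#' continuity correction; for 30 or fewer, an exact two-sided binomial
#' test. Half-integer weights (from the half-split rule) are rounded to
#' the nearest integer (ties to even) for the exact branch.
#'
#' @param k observed (possibly half-integer) count of the tested class.
#' @param n total (possibly half-integer) neighborhood or cluster size.
#' @param p0 null fraction in (0, 1).
#' @return two-sided p-value.
#' @examples
#' proportion_or_binomial_test(3, 20, 0.5)  # ~0.0018, exact branch n <= 30
#' @export
proportion_or_binomial_test <- function(k, n, p0) {
  stopifnot(p0 > 0, p0 < 1, k >= 0, k <= n + 1e-9)
  if (n == 0) {
    warning("empty neighborhood; p = 1")
    return(1)
  }
  if (n > 30) return(proportion_z_test(k, n, p0))
  stats::binom.test(round(k), round(n), p = p0)$p.value
}

#' Two-sided one-sample z-test of a proportion (no continuity correction)
#'
#' @inheritParams proportion_or_binomial_test
#' @return two-sided p-value.
#' @examples
#' proportion_z_test(3, 20, 0.5)  # ~0.0018
#' @export
proportion_z_test <- function(k, n, p0) {
  z <- (k / n - p0) / sqrt(p0 * (1 - p0) / n)
  2 * stats::pnorm(-abs(z))
}

#' Differential cohort representation of graph neighborhoods
#'
#' Tests every vertex's closed-neighborhood `C` weight against the global
#' weighted `C` fraction, corrects with Benjamini-Hochberg over all
#' vertices and calls each significant neighborhood for the
#' overrepresented cohort.
#'
#' @param g igraph graph.
#' @param labels per-vertex labels (default [cohort_labels()]).
#' @param alpha FDR level (default 0.05).
#' @param null_fraction null `C` fraction; default the global weighted
#'   fraction of the graph's vertices.
#' @return data.frame of class `neighborhood_result`: `sequence`, `size`,
#'   `weight_A`, `weight_C`, `log2_fold` (A over C), `p_value`,
#'   `q_value`, `call` in `{A, C, ns}`; attributes `null_fraction`,
#'   `summary`.
#' @export
differential_neighborhoods <- function(g, labels = cohort_labels(g),
                                       alpha = 0.05, null_fraction = NULL) {
  comp <- neighborhood_composition(g, labels)
  w <- .label_weights(labels)
  if (is.null(null_fraction)) null_fraction <- sum(w$C) / length(labels)
  p <- mapply(proportion_or_binomial_test, comp$weight_C, comp$size,
              MoreArgs = list(p0 = null_fraction))
  q <- stats::p.adjust(p, method = "BH")
  eps <- 0.5  # half-count smoothing for empty-side folds
  fold <- log2((comp$weight_A + eps) / (comp$weight_C + eps))
  call <- ifelse(q > alpha, "ns",
                 ifelse(comp$weight_C / comp$size > null_fraction, "C", "A"))
  out <- cbind(comp, data.frame(log2_fold = fold, p_value = p, q_value = q,
                                call = call, stringsAsFactors = FALSE))
  n_sig <- sum(call != "ns")
  attr(out, "null_fraction") <- null_fraction
  attr(out, "summary") <- list(
    n_significant = n_sig,
    share_C_called = if (n_sig > 0) sum(call == "C") / n_sig else NA_real_,
    global_C_fraction = null_fraction)
  class(out) <- c("neighborhood_result", "data.frame")
  out
}

#' @export
print.neighborhood_result <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(paste0("Differential neighborhoods: %d vertices, %d significant",
                     " (%.1f%% C-called; global C fraction %.1f%%)\n"),
              nrow(x), s$n_significant, 100 * s$share_C_called,
              100 * s$global_C_fraction))
  invisible(x)
}

#' Induced subgraph of a vertex set
#'
#' @param g igraph graph.
#' @param vertices vertex names or indices (non-empty).
#' @export
induced_igome_subgraph <- function(g, vertices) {
  if (length(vertices) == 0) stop("vertex set is empty")
  igraph::induced_subgraph(g, vertices)
}

#' Recursive Louvain clustering
#'
#' Applies Louvain community detection, then re-clusters each community's
#' induced subgraph recursively, yielding a tree. Recursion stops when a
#' community is smaller than `2 * min_size`, when Louvain returns a
#' single community, or when the modularity of the split falls below
#' `min_modularity` (default 0.3, the conventional floor for meaningful
#' community structure -- below it a dense community is treated as one
#' cluster rather than shattered). Deterministic given `seed`.
#'
#' @param g igraph graph.
#' @param seed integer seed.
#' @param min_size minimal workable cluster size (default 4).
#' @param min_modularity stop descending when a split scores below this.
#' @param max_depth recursion cap (default 10).
#' @return tree of class `louvain_tree`: nested lists with fields
#'   `vertices` (names), `level`, `modularity`, `children`.
#' @export
recursive_louvain <- function(g, seed = 1, min_size = 4,
                              min_modularity = 0.3, max_depth = 10) {
  recurse <- function(sub, level, seed) {
    node <- list(vertices = igraph::V(sub)$name, level = level,
                 modularity = NA_real_, children = NULL)
    if (igraph::vcount(sub) < 2 * min_size || level >= max_depth)
      return(node)
    set.seed(seed)
    cl <- igraph::cluster_louvain(sub)
    memb <- igraph::membership(cl)
    mod <- igraph::modularity(sub, memb)
    if (max(memb) < 2 || mod < min_modularity) return(node)
    node$modularity <- mod
    node$children <- lapply(sort(unique(memb)), function(k) {
      vs <- which(memb == k)
      recurse(igraph::induced_subgraph(sub, vs), level + 1,
              seed + 1000L * level + k)
    })
    node
  }
  structure(recurse(g, 0L, as.integer(seed)), class = "louvain_tree")
}

.tree_depth <- function(node) {
  if (is.null(node$children)) return(node$level)
  max(vapply(node$children, .tree_depth, numeric(1)))
}

.cut_at_depth <- function(node, depth) {
  if (is.null(node$children) || node$level >= depth)
    return(list(node$vertices))
  unlist(lapply(node$children, .cut_at_depth, depth = depth),
         recursive = FALSE)
}

#' Cut a Louvain tree into a flat partition
#'
#' Evaluates every tree depth as a flat partition and selects the depth
#' that maximizes the number of clusters of at least `min_size` vertices
#' (ties go to the shallower depth). Clusters below `min_size` are
#' discarded and reported.
#'
#' @param tree a `louvain_tree`.
#' @param g the clustered graph (for the partition's modularity).
#' @param min_size minimal workable cluster size (default 4).
#' @return list of class `cluster_partition`: `clusters` (named list of
#'   vertex-name vectors), `membership` (named integer vector over
#'   retained vertices), `depth`, `modularity`, `n_discarded`,
#'   `discarded_vertices`.
#' @export
cut_tree_partition <- function(tree, g = NULL, min_size = 4) {
  depths <- seq_len(max(.tree_depth(tree), 1))
  counts <- vapply(depths, function(d) {
    cl <- .cut_at_depth(tree, d)
    sum(lengths(cl) >= min_size)
  }, numeric(1))
  best <- depths[which.max(counts)]  # which.max takes the first (shallowest)
  clusters <- .cut_at_depth(tree, best)
  keep <- lengths(clusters) >= min_size
  if (!any(keep)) warning("no cluster reaches the minimal size")
  discarded <- unlist(clusters[!keep])
  clusters <- clusters[keep]
  names(clusters) <- sprintf("cl%03d", seq_along(clusters))
  membership <- rep(seq_along(clusters), lengths(clusters))
  names(membership) <- unlist(clusters)
  modularity <- NA_real_
  if (!is.null(g)) {
    memb_full <- rep(NA_integer_, igraph::vcount(g))
    idx <- match(names(membership), igraph::V(g)$name)
    memb_full[idx] <- membership
    # discarded vertices become singleton communities for the score
    free <- which(is.na(memb_full))
    memb_full[free] <- seq_along(free) + length(clusters)
    modularity <- igraph::modularity(g, memb_full)
  }
  structure(list(clusters = clusters, membership = membership,
                 depth = best, modularity = modularity,
                 n_discarded = sum(!keep),
                 discarded_vertices = discarded),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  sz <- lengths(x$clusters)
  cat(sprintf(paste0("Cluster partition: %d clusters (sizes %d-%d) at depth",
                     " %d, modularity %.3f; %d undersized discarded\n"),
              length(x$clusters), if (length(sz)) min(sz) else 0,
              if (length(sz)) max(sz) else 0, x$depth, x$modularity,
              x$n_discarded))
  invisible(x)
}

#' Differential cohort representation of clusters
#'
#' Tests each cluster's half-split `C` weight against the global weighted
#' fraction (BH-corrected), calls clusters for the overrepresented
#' cohort, and summarizes the A-vs-C asymmetry: a proportion/binomial
#' test on the *counts* of called clusters (null 0.5: both cohorts
#' equally likely to dominate a cluster) and a rank-sum test on their
#' sizes.
#'
#' @param partition a `cluster_partition`.
#' @param labels named per-vertex labels in `{"A","C","AC"}` (names =
#'   sequences), or a graph to derive them from.
#' @param alpha FDR level (default 0.05).
#' @param null_fraction null `C` fraction; default the global weighted
#'   fraction over the partition's vertices.
#' @return data.frame of class `cluster_calls`: `cluster`, `size`,
#'   `weight_A`, `weight_C`, `log2_fold`, `p_value`, `q_value`, `call`;
#'   attribute `summary` with the count test and size test.
#' @export
differential_clusters <- function(partition, labels, alpha = 0.05,
                                  null_fraction = NULL) {
  if (inherits(labels, "igraph")) {
    l <- cohort_labels(labels)
    names(l) <- igraph::V(labels)$name
    labels <- l
  }
  seqs <- names(partition$membership)
  lab <- labels[seqs]
  if (anyNA(lab)) stop("labels missing for some clustered vertices")
  w <- .label_weights(lab)
  if (is.null(null_fraction)) null_fraction <- sum(w$C) / length(lab)
  rows <- lapply(seq_along(partition$clusters), function(k) {
    vs <- partition$clusters[[k]]
    i <- match(vs, seqs)
    wA <- sum(w$A[i]); wC <- sum(w$C[i]); n <- length(vs)
    data.frame(cluster = names(partition$clusters)[k], size = n,
               weight_A = wA, weight_C = wC,
               log2_fold = log2((wA + 0.5) / (wC + 0.5)),
               p_value = proportion_or_binomial_test(wC, n, null_fraction),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$call <- ifelse(out$q_value > alpha, "ns",
                     ifelse(out$weight_C / out$size > null_fraction,
                            "C", "A"))
  nA <- sum(out$call == "A"); nC <- sum(out$call == "C")
  # cluster-count asymmetry: z-test of the A share against 0.5
  count_p <- if (nA + nC > 0) proportion_z_test(nA, nA + nC, 0.5)
             else NA_real_
  size_p <- if (nA > 0 && nC > 0)
    stats::wilcox.test(out$size[out$call == "A"],
                       out$size[out$call == "C"], exact = FALSE)$p.value
    else NA_real_
  attr(out, "summary") <- list(n_A_clusters = nA, n_C_clusters = nC,
                               count_test_p = count_p, size_test_p = size_p,
                               null_fraction = null_fraction)
  class(out) <- c("cluster_calls", "data.frame")
  out
}

#' @export
print.cluster_calls <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(paste0("Cluster calls: %d clusters, %d A-called, %d C-called",
                     " (count test p = %.3g)\n"),
              nrow(x), s$n_A_clusters, s$n_C_clusters, s$count_test_p))
  invisible(x)
}
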