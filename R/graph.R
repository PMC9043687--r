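#' Adjacency under the LCS edge criterion
#'
#' Finds every unordered pair of sequences whose plain LCS distance is at
#' most `max_distance` (default 4: two 7-mers sharing a common
#' subsequence of 5+ residues). The default implementation is a C++
#' all-pairs scan with a residue-multiset prefilter; `method = "oracle"`
#' runs a plain R dynamic-programming double loop and is guaranteed to
#' return identical output (it exists as the reference the accelerated
#' path is tested against).
#'
#' @param sequences character vector of unique peptides.
#' @param max_distance LCS-distance cutoff (default 4).
#' @param method `"cpp"` (default) or `"oracle"`.
#' @return data.frame with integer columns `i`, `j` (1-based indices,
#'   `i < j`).
#' @export
build_adjacency <- function(sequences, max_distance = 4,
                            method = c("cpp", "oracle")) {
  method <- match.arg(method)
  if (anyDuplicated(sequences)) stop("sequences must be unique")
  if (method == "cpp") {
    m <- .cpp_adjacency_pairs(sequences, as.integer(max_distance))
    return(data.frame(i = m[, 1], j = m[, 2]))
  }
  n <- length(sequences)
  ei <- integer(0); ej <- integer(0)
  eq <- .identity_matrix()
  for (i in seq_len(max(n - 1, 0))) {
    d <- .cpp_pair_metric(rep(sequences[i], n - i),
                          sequences[(i + 1):n], "lcs", AA_ALPHABET, eq)
    hit <- which(d <= max_distance)
    ei <- c(ei, rep(i, length(hit)))
    ej <- c(ej, i + hit)
  }
  data.frame(i = ei, j = ej)
}

#' Build the mimotope sequence graph
#'
#' Simple undirected graph over the library's sequences with edges given
#' by the LCS criterion. Sequences with no neighbor (singletons) are
#' dropped and their count recorded as a graph attribute.
#'
#' @param lib a `mimotope_library`, or a character vector of sequences.
#' @param max_distance LCS-distance edge criterion (default 4).
#' @param keep_singletons retain isolated vertices (default FALSE).
#' @return an `igraph` graph; vertex attributes `name` (sequence), `libs`
#'   and `count` when available; graph attribute `singletons`.
#' @export
build_graph <- function(lib, max_distance = 4, keep_singletons = FALSE) {
  seqs <- if (is.data.frame(lib)) lib$sequence else lib
  adj <- build_adjacency(seqs, max_distance)
  g <- igraph::make_empty_graph(n = length(seqs), directed = FALSE)
  igraph::V(g)$name <- seqs
  if (is.data.frame(lib)) {
    if (!is.null(lib$libs)) igraph::V(g)$libs <- lib$libs
    if (!is.null(lib$count)) igraph::V(g)$count <- lib$count
  }
  if (nrow(adj) > 0)
    g <- igraph::add_edges(g, rbind(adj$i, adj$j))
  iso <- which(igraph::degree(g) == 0)
  n_singletons <- length(iso)
  if (!keep_singletons && n_singletons > 0)
    g <- igraph::delete_vertices(g, iso)
  if (igraph::vcount(g) == 0) stop("graph is empty after singleton removal")
  g <- igraph::set_graph_attr(g, "singletons", n_singletons)
  g <- igraph::set_graph_attr(g, "max_distance", max_distance)
  g
}

#' Topology statistics of a mimotope graph
#'
#' @param g an igraph graph.
#' @return list with vertex/edge counts, degree sequence, global and mean
#'   local transitivity, eigencentrality, degree assortativity.
#' @export
graph_stats <- function(g) {
  deg <- igraph::degree(g)
  local_cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  list(n_vertices = igraph::vcount(g),
       n_edges = igraph::ecount(g),
       degree = deg,
       transitivity_global = igraph::transitivity(g, type = "global"),
       transitivity_mean_local = mean(local_cc),
       local_clustering = local_cc,
       eigencentrality = eigencentrality(g),
       degree_assortativity = igraph::assortativity_degree(g))
}

#' Fit an exponential model to the binned degree distribution
#'
#' Splits the degree range into `n_bins` equal-width bins and fits
#' `log(count) ~ degree` by least squares on the positive-mass bins.
#'
#' @param g igraph graph (or a numeric degree vector).
#' @param n_bins number of linear bins (default 50).
#' @return list: `histogram` (bin mids, counts), `r_squared`, `rate`
#'   (absolute slope), `fit` (the `lm` object).
#' @export
degree_distribution_fit <- function(g, n_bins = 50) {
  deg <- if (is.numeric(g)) g else igraph::degree(g)
  rng <- range(deg)
  if (diff(rng) == 0) stop("degenerate degree distribution (all equal)")
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- hist(deg, breaks = br, plot = FALSE)
  pos <- h$counts > 0
  if (sum(pos) < 3) stop("fewer than 3 positive-mass bins")
  fit <- stats::lm(log(h$counts[pos]) ~ h$mids[pos])
  list(histogram = data.frame(mid = h$mids, count = h$counts),
       r_squared = summary(fit)$r.squared,
       rate = abs(unname(stats::coef(fit)[2])),
       fit = fit)
}

#' Assortativity within degree-stratified induced subgraphs
#'
#' Sorts vertices into `n_bins` equal-count bins by degree and computes,
#' for the induced subgraph of each bin, the assortativity of a vertex
#' attribute (or of degree itself). This separates genuine attribute
#' homophily from the mechanical contribution of degree assortativity.
#'
#' @param g igraph graph.
#' @param attribute `"degree"` or the name of a numeric vertex attribute,
#'   or a numeric vector over vertices.
#' @param n_bins number of degree bins (default 20).
#' @param min_vertices bins smaller than this are reported as `NA`.
#' @return data.frame: `bin`, `mean_degree`, `n_vertices`, `n_edges`,
#'   `assortativity`; attribute `overall` holds the whole-graph value.
#' @export
degree_stratified_assortativity <- function(g, attribute = "degree",
                                            n_bins = 20, min_vertices = 10) {
  deg <- igraph::degree(g)
  vals <- if (is.numeric(attribute)) attribute
          else if (identical(attribute, "degree")) deg
          else igraph::vertex_attr(g, attribute)
  if (is.null(vals)) stop("unknown vertex attribute: ", attribute)
  if (length(unique(vals)) == 1) {
    warning("attribute is constant; assortativity undefined")
    overall <- NA_real_
  } else if (identical(attribute, "degree")) {
    overall <- igraph::assortativity_degree(g)
  } else {
    overall <- igraph::assortativity(g, values = vals, directed = FALSE)
  }
  o <- order(deg)
  bin <- integer(length(deg))
  bin[o] <- ceiling(seq_along(o) / (length(o) / n_bins))
  bin <- pmin(bin, n_bins)
  res <- lapply(seq_len(n_bins), function(b) {
    vs <- which(bin == b)
    row <- data.frame(bin = b, mean_degree = mean(deg[vs]),
                      n_vertices = length(vs), n_edges = NA_integer_,
                      assortativity = NA_real_)
    if (length(vs) < min_vertices) return(row)
    sg <- igraph::induced_subgraph(g, vs)
    row$n_edges <- igraph::ecount(sg)
    if (row$n_edges == 0) return(row)
    sub_vals <- vals[vs]
    row$assortativity <-
      if (identical(attribute, "degree")) igraph::assortativity_degree(sg)
      else if (length(unique(sub_vals)) == 1) NA_real_
      else igraph::assortativity(sg, values = sub_vals, directed = FALSE)
    row
  })
  out <- do.call(rbind, res)
  attr(out, "overall") <- overall
  out
}

#' Shortest-path length profile and diameter estimate
#'
#' Breadth-first searches from `n_sources` sampled vertices (or from
#' every vertex in exact mode) give the cumulative fraction of finite
#' shortest paths by length and the maximum observed eccentricity, a
#' lower bound on the diameter (exact when all sources are used).
#'
#' @param g igraph graph.
#' @param n_sources number of BFS sources (default 1000; all vertices if
#'   fewer, which makes the result exact).
#' @param seed integer seed for source sampling.
#' @return list: `profile` (length, n_paths, cumulative_fraction),
#'   `diameter` (max observed finite distance), `exact` flag,
#'   `disconnected_pairs` count.
#' @export
path_length_profile <- function(g, n_sources = 1000, seed = 1) {
  n <- igraph::vcount(g)
  exact <- n <= n_sources
  src <- if (exact) seq_len(n) else {
    set.seed(seed)
    sample.int(n, n_sources)
  }
  d <- as.vector(igraph::distances(g, v = src))
  d <- d[d > 0]
  inf <- is.infinite(d)
  d <- d[!inf]
  tab <- table(d)
  lens <- as.integer(names(tab))
  profile <- data.frame(length = lens, n_paths = as.integer(tab),
                        cumulative_fraction = cumsum(as.integer(tab)) / length(d))
  list(profile = profile,
       diameter = if (length(d)) max(d) else NA_real_,
       exact = exact,
       disconnected_pairs = sum(inf))
}

#' Eigenvector centrality by power iteration
#'
#' Principal-eigenvector scores of the adjacency matrix, computed per
#' connected component and scaled so the maximum score in each component
#' is 1.
#'
#' @param g igraph graph.
#' @param tol convergence tolerance (default 1e-10).
#' @param max_iter iteration cap; non-convergence is an error.
#' @return numeric vector of per-vertex scores in [0, 1].
#' @export
eigencentrality <- function(g, tol = 1e-10, max_iter = 100000) {
  comps <- igraph::components(g)
  out <- numeric(igraph::vcount(g))
  adj <- igraph::as_adj_list(g)
  for (cid in seq_len(comps$no)) {
    vs <- which(comps$membership == cid)
    if (length(vs) == 1) { out[vs] <- 1; next }
    pos <- integer(igraph::vcount(g)); pos[vs] <- seq_along(vs)
    nb <- lapply(adj[vs], function(a) pos[as.integer(a)])
    x <- rep(1 / sqrt(length(vs)), length(vs))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      # iterate on A + I: same eigenvectors, no oscillation on bipartite
      # components
      y <- vapply(nb, function(k) sum(x[k]), numeric(1)) + x
      ny <- sqrt(sum(y^2))
      if (ny == 0) { y <- x; break }
      y <- y / ny
      if (max(abs(y - x)) < tol) { x <- y; converged <- TRUE; break }
      x <- y
    }
    if (!converged && length(vs) > 1)
      stop("power iteration did not converge in ", max_iter,
           " iterations (component of size ", length(vs), ")")
    out[vs] <- x / max(x)
  }
  out
}

#' Export a graph to GraphML with scaled vertex attributes
#'
#' Numeric vertex attributes are min-max scaled to [0, 1] (suffix
#' `_scaled`) alongside the raw values, ready for external layout and
#' rendering tools.
#'
#' @param g igraph graph.
#' @param path output path.
#' @param scale_attributes add min-max scaled copies of numeric
#'   attributes.
#' @export
export_graphml <- function(g, path, scale_attributes = TRUE) {
  if (scale_attributes) {
    for (a in igraph::vertex_attr_names(g)) {
      v <- igraph::vertex_attr(g, a)
      if (is.numeric(v) && length(unique(v)) > 1) {
        g <- igraph::set_vertex_attr(g, paste0(a, "_scaled"),
                                     value = (v - min(v)) / diff(range(v)))
      }
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Edge list as TSV
#' @param g igraph graph.
#' @param path output path.
#' @export
write_edgelist_tsv <- function(g, path) {
  el <- igraph::as_edgelist(g)
  utils::write.table(data.frame(from = el[, 1], to = el[, 2]), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
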