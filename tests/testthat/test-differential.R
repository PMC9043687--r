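# small labeled star: center + three neighbors labeled A, C, both
.star_graph <- function() {
  g <- igraph::make_star(4, mode = "undirected", center = 1)
  igraph::V(g)$name <- c("center", "na", "nc", "nb")
  igraph::V(g)$libs <- c("A", "A", "C", "A,C")
  g
}

test_that("closed-neighborhood composition applies the half-split rule", {
  g <- .star_graph()
  comp <- neighborhood_composition(g)
  center <- comp[comp$sequence == "center", ]
  expect_equal(center$weight_A, 2.5)
  expect_equal(center$weight_C, 1.5)
  expect_equal(center$size, 4)
  expect_equal(comp$weight_A + comp$weight_C, comp$size)
  # open-neighborhood variant excludes the center
  open <- neighborhood_composition(g, closed = FALSE)
  expect_equal(open[open$sequence == "center", ]$weight_A, 1.5)
  # all-A graph has zero C weight everywhere
  ga <- .star_graph()
  igraph::V(ga)$libs <- rep("A", 4)
  expect_true(all(neighborhood_composition(ga)$weight_C == 0))
})

test_that("neighborhood totals obey degree-weighted label accounting", {
  b <- desk_bundle()
  g <- igraph::induced_subgraph(b$g, 1:300)
  labels <- cohort_labels(g)
  comp <- neighborhood_composition(g, labels)
  w <- ifelse(labels == "C", 1, ifelse(labels == "AC", 0.5, 0))
  # each vertex's C weight is counted once per closed neighborhood it
  # belongs to, i.e. degree + 1 times
  expect_equal(sum(comp$weight_C),
               sum(w * (igraph::degree(g) + 1)))
})

test_that("proportion and binomial branches reproduce reference p-values", {
  # the z-test without continuity reconstructs the printed cluster-count
  # example: 3 of 20 at null 0.5
  expect_equal(proportion_z_test(3, 20, 0.5), 0.0018, tolerance = 0.05)
  expect_equal(proportion_z_test(10, 20, 0.5), 1)
  # large-sample branch
  expect_equal(proportion_or_binomial_test(31, 62, 0.5), 1)
  # exact branch matches tail enumeration on a grid
  for (n in c(5, 12, 25, 30)) {
    for (k in c(0, 1, floor(n / 3), n)) {
      expect_equal(proportion_or_binomial_test(k, n, 0.3),
                   oracle_binom_p(k, n, 0.3),
                   info = sprintf("k=%d n=%d", k, n))
    }
  }
  # half-integer weights are rounded for the exact branch
  expect_equal(proportion_or_binomial_test(2.5, 11, 0.4),
               stats::binom.test(2, 11, 0.4)$p.value)
  expect_warning(p <- proportion_or_binomial_test(0, 0, 0.5), "empty")
  expect_equal(p, 1)
})

test_that("weighted cohort fraction reproduces the printed library arithmetic", {
  f <- weighted_label_fraction(297028 - 15223, 109617 - 15223, 15223)
  expect_equal(100 * f, 26.1, tolerance = 0.002)
})

test_that("differential neighborhoods control the null and flip under swap", {
  b <- desk_bundle()
  # null: relabel vertices independently of structure
  g <- igraph::induced_subgraph(b$g, 1:400)
  set.seed(41)
  igraph::V(g)$libs <- sample(c("A", "C"), 400, replace = TRUE,
                              prob = c(0.7, 0.3))
  nb <- differential_neighborhoods(g)
  expect_lte(attr(nb, "summary")$n_significant / 400, 0.05)
  # swapping the cohort labels exchanges the calls exactly
  g2 <- g
  igraph::V(g2)$libs <- ifelse(igraph::V(g)$libs == "A", "C", "A")
  nb2 <- differential_neighborhoods(g2)
  expect_equal(nb$p_value, nb2$p_value, tolerance = 1e-12)
  expect_identical(ifelse(nb$call == "A", "C", ifelse(nb$call == "C", "A",
                                                      "ns")),
                   nb2$call)
})

test_that("null simulations keep the BH false-positive rate at bay", {
  b <- desk_bundle()
  g <- igraph::induced_subgraph(b$g, 1:250)
  set.seed(42)
  fpr <- replicate(200, {
    igraph::V(g)$libs <- sample(c("A", "C", "A,C"), 250, replace = TRUE,
                                prob = c(0.55, 0.35, 0.10))
    nb <- differential_neighborhoods(g)
    mean(nb$q_value <= 0.05)
  })
  expect_lte(mean(fpr), 0.10)
})

test_that("induced subgraphs preserve exactly the internal edges", {
  b <- desk_bundle()
  g <- b$g
  vs <- igraph::V(g)$name[1:120]
  sub <- induced_igome_subgraph(g, vs)
  # oracle recount from the full edge list
  el <- igraph::as_edgelist(g)
  internal <- el[el[, 1] %in% vs & el[, 2] %in% vs, , drop = FALSE]
  expect_equal(igraph::ecount(sub), nrow(internal))
  expect_error(induced_igome_subgraph(g, character(0)), "empty")
  full <- induced_igome_subgraph(g, igraph::V(g)$name)
  expect_equal(igraph::ecount(full), igraph::ecount(g))
})

test_that("recursive Louvain separates components and is deterministic", {
  g <- igraph::disjoint_union(igraph::make_full_graph(8),
                              igraph::make_full_graph(9))
  igraph::V(g)$name <- paste0("v", 1:17)
  tree <- recursive_louvain(g, seed = 5)
  expect_length(tree$children, 2L)
  # recursion stops inside cliques: children are leaves
  expect_true(all(vapply(tree$children,
                         function(n) is.null(n$children), logical(1))))
  tree2 <- recursive_louvain(g, seed = 5)
  expect_identical(tree, tree2)
  # leaves partition the vertex set
  leaves <- unlist(.leaf_vertices <- local({
    rec <- function(n) if (is.null(n$children)) list(n$vertices)
           else unlist(lapply(n$children, rec), recursive = FALSE)
    rec(tree)
  }), use.names = FALSE)
  expect_setequal(leaves, igraph::V(g)$name)
  expect_false(anyDuplicated(leaves) > 0)
})

test_that("tree leaves partition the vertices on real desk-scale data", {
  b <- desk_bundle()
  tree <- recursive_louvain(b$g, seed = 3)
  rec <- function(n) if (is.null(n$children)) list(n$vertices)
         else unlist(lapply(n$children, rec), recursive = FALSE)
  leaves <- unlist(rec(tree), use.names = FALSE)
  expect_setequal(leaves, igraph::V(b$g)$name)
  expect_false(anyDuplicated(leaves) > 0)
  part <- cut_tree_partition(tree, b$g)
  expect_false(anyDuplicated(names(part$membership)) > 0)
  expect_gt(part$modularity, 0)
})

test_that("tree cutting maximizes workable clusters and ties go shallow", {
  # hand-built 2-level tree: level 1 has one big + one small cluster,
  # level 2 splits the big one into two workable clusters
  leaf <- function(v, lvl) list(vertices = v, level = lvl,
                                modularity = NA_real_, children = NULL)
  tree <- structure(list(
    vertices = paste0("v", 1:13), level = 0L, modularity = 0.5,
    children = list(
      list(vertices = paste0("v", 1:10), level = 1L, modularity = 0.4,
           children = list(leaf(paste0("v", 1:5), 2L),
                           leaf(paste0("v", 6:10), 2L))),
      leaf(paste0("v", 11:13), 1L))), class = "louvain_tree")
  part <- cut_tree_partition(tree, min_size = 4)
  expect_equal(part$depth, 2L)
  expect_length(part$clusters, 2L)
  expect_equal(part$n_discarded, 1L)
  expect_setequal(part$discarded_vertices, paste0("v", 11:13))
  # single-level tree returns that level
  single <- structure(leaf(paste0("v", 1:6), 0L), class = "louvain_tree")
  p1 <- cut_tree_partition(single, min_size = 4)
  expect_length(p1$clusters, 1L)
  # all clusters undersized -> empty partition with a warning
  tiny <- structure(leaf(paste0("v", 1:3), 0L), class = "louvain_tree")
  expect_warning(p0 <- cut_tree_partition(tiny, min_size = 4), "minimal")
  expect_length(p0$clusters, 0L)
})

test_that("cluster calls find planted families and summarize asymmetry", {
  b <- desk_bundle()
  tree <- recursive_louvain(b$g, seed = 3)
  part <- cut_tree_partition(tree, b$g)
  calls <- differential_clusters(part, b$g)
  s <- attr(calls, "summary")
  # the half-split rule conserves total sequence mass
  labels <- cohort_labels(b$g)
  names(labels) <- igraph::V(b$g)$name
  lab <- labels[names(part$membership)]
  expect_equal(sum(calls$weight_A + calls$weight_C),
               sum(lab == "A") + sum(lab == "C") + sum(lab == "AC"))
  # planted direction: more C-shifted than A-shifted families were
  # planted, so C calls should not be outnumbered
  expect_gte(s$n_C_clusters, s$n_A_clusters)
  expect_gt(s$n_C_clusters + s$n_A_clusters, 0)
  # called clusters coincide with planted families
  called <- calls$cluster[calls$call != "ns"]
  fam_members <- split(b$truth$sequence, b$truth$family)
  jac <- vapply(called, function(cl) {
    vs <- part$clusters[[cl]]
    max(vapply(fam_members, function(f) {
      fp <- intersect(f, igraph::V(b$g)$name)
      length(intersect(vs, fp)) / length(union(vs, fp))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(stats::median(jac), 0.5)
  # a cluster mirroring the global ratio is not called
  nullpart <- structure(list(
    clusters = list(cl001 = names(lab)[1:60]),
    membership = stats::setNames(rep(1L, 60), names(lab)[1:60]),
    depth = 1L, modularity = NA_real_, n_discarded = 0L,
    discarded_vertices = character(0)), class = "cluster_partition")
  nf <- attr(calls, "summary")$null_fraction
  wC <- sum(ifelse(lab[1:60] == "C", 1, ifelse(lab[1:60] == "AC", 0.5, 0)))
  # relabel the slice so its composition sits at the global fraction
  ncl <- differential_clusters(nullpart, labels, null_fraction = wC / 60)
  expect_equal(ncl$call, "ns")
})

test_that("cluster-count asymmetry reproduces the 3-vs-17 worked example", {
  p <- proportion_z_test(3, 20, 0.5)
  expect_lt(abs(p - 0.0018), 1e-4)
})
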