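test_that("parallel edges obey the share-face-xor-share-vertex rule", {
  tri <- build_complex(interaction_network(c("a", "a", "b"),
                                           c("b", "c", "c")))
  expect_equal(parallel_edges(tri, c("a", "b")), character(0))
  path <- build_complex(interaction_network(c("a", "b"), c("b", "c")))
  expect_equal(parallel_edges(path, c("a", "b")), "b|c")
  two <- build_complex(toy_complexes()$two_faces)
  expect_equal(parallel_edges(two, c("a", "c")), "a|d")
  expect_error(parallel_edges(tri, c("a", "z")), "not in complex")
})

test_that("unit-weight closed forms hold", {
  toys <- toy_complexes()
  # filled triangle: 2D curvature 3 on every edge
  tri <- manual_weighted_complex(build_complex(toys$filled_triangle))
  expect_equal(unname(forman_ricci_2d(tri)), rep(3, 3))
  # two faces sharing edge ab: F(ab) = 4
  two <- manual_weighted_complex(build_complex(toys$two_faces))
  expect_equal(forman_ricci_2d(two, c("a", "b")), 4)
  # 1D closed form 4 - deg(u) - deg(v) on arbitrary graphs
  for (seed in 1:10) {
    set.seed(seed)
    g <- igraph::sample_gnp(12, 0.35)
    el <- igraph::as_edgelist(g)
    if (nrow(el) < 2) next
    net <- interaction_network(sprintf("v%02d", el[, 1]),
                               sprintf("v%02d", el[, 2]))
    cx <- build_complex(net)
    wc <- manual_weighted_complex(cx)
    F1 <- forman_ricci_1d(wc)
    deg <- stats::setNames(tabulate(match(c(cx$edges$from, cx$edges$to),
                                          net$vertices),
                                    nbins = length(net$vertices)),
                           net$vertices)
    expected <- 4 - deg[cx$edges$from] - deg[cx$edges$to]
    expect_equal(unname(F1[cx$edges$key]), unname(expected))
  }
  # specific instances of the closed form
  expect_equal(unname(forman_ricci_1d(
    manual_weighted_complex(build_complex(toys$isolated_edge)))), 2)
  expect_equal(unname(forman_ricci_1d(
    manual_weighted_complex(build_complex(toys$cycle6)))), rep(0, 6))
  expect_equal(unname(forman_ricci_1d(
    manual_weighted_complex(build_complex(toys$path3)))), c(1, 1))
})

test_that("2D curvature reduces to 1D when the complex has no faces", {
  for (seed in 1:10) {
    wc <- random_weighted_complex(14, 0.22, seed)
    faceless <- wc
    faceless$complex$faces <- wc$complex$faces[0, ]
    faceless$complex$edge_faces <- list()
    faceless$complex$vertex_faces <- list()
    faceless$w_face <- numeric(0)
    expect_equal(forman_ricci_2d(faceless), forman_ricci_1d(faceless))
  }
  sq <- manual_weighted_complex(build_complex(toy_complexes()$face_free))
  expect_equal(forman_ricci_2d(sq), forman_ricci_1d(sq))
})

test_that("optimised curvature equals the naive literal evaluator", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- sample(6:25, 1)
    wc <- random_weighted_complex(n, runif(1, 0.2, 0.6), seed)
    expect_lt(max(abs(forman_ricci_2d(wc) - oracle_forman(wc, "2D"))), 1e-10)
    expect_lt(max(abs(forman_ricci_1d(wc) - oracle_forman(wc, "1D"))), 1e-10)
  }
})

test_that("nonpositive weights are rejected", {
  wc <- manual_weighted_complex(build_complex(toy_complexes()$path3))
  wc$w_edge["a|b"] <- -1
  expect_error(forman_ricci_1d(wc), "positive")
  expect_error(manual_weighted_complex(
    build_complex(toy_complexes()$path3), w_vertex = 0), "positive")
})

test_that("vertex contraction averages incident-edge curvature", {
  toys <- toy_complexes()
  tri <- build_complex(toys$filled_triangle)
  Fv <- vertex_curvature(forman_ricci_2d(manual_weighted_complex(tri)), tri)
  expect_equal(unname(Fv), rep(3, 3))
  path <- build_complex(toys$path3)
  Fv2 <- vertex_curvature(forman_ricci_1d(manual_weighted_complex(path)),
                          path)
  expect_equal(Fv2[["b"]], 1)   # (1 + 1) / 2
  expect_equal(Fv2[["a"]], 1)   # single incident edge: equals F(e)
  # isolated vertices are excluded
  iso <- build_complex(interaction_network("a", "b",
                                           vertices = c("a", "b", "z")))
  Fv3 <- vertex_curvature(forman_ricci_1d(manual_weighted_complex(iso)), iso)
  expect_setequal(names(Fv3), c("a", "b"))
})

test_that("global average is the stationary-weighted dot product", {
  tri <- build_complex(toy_complexes()$filled_triangle)
  Fv <- vertex_curvature(forman_ricci_2d(manual_weighted_complex(tri)), tri)
  expect_equal(global_average_curvature(
    Fv, c(a = 1 / 3, b = 1 / 3, c = 1 / 3)), 3)
  expect_equal(global_average_curvature(Fv, c(a = 1, b = 0, c = 0)),
               Fv[["a"]])
  set.seed(1)
  pi <- prop.table(runif(3))
  names(pi) <- c("a", "b", "c")
  expect_equal(global_average_curvature(Fv, pi),
               sum(pi[names(Fv)] * Fv))
  expect_error(global_average_curvature(Fv, c(a = 0.5, z = 0.5)),
               "different vertices")
})

test_that("curvature results are invariant to vertex relabelling", {
  set.seed(3)
  net <- synthetic_network(25, 5, 1.5, seed = 3)
  net <- restrict_network(net, net$vertices, TRUE, verbose = FALSE)
  x <- stats::setNames(rlnorm(length(net$vertices)), net$vertices)
  res <- curvature_pipeline(weight_complex(build_complex(net), x), "2D")
  # permute labels
  perm <- stats::setNames(sprintf("z%02d", sample(length(net$vertices))),
                          net$vertices)
  sk <- skeleton_edges(net)
  net2 <- interaction_network(perm[sk$from], perm[sk$to])
  x2 <- stats::setNames(unname(x), unname(perm[names(x)]))
  res2 <- curvature_pipeline(weight_complex(build_complex(net2), x2), "2D")
  expect_equal(res2$global_average, res$global_average, tolerance = 1e-12)
  expect_equal(res2$entropy, res$entropy, tolerance = 1e-12)
  expect_equal(unname(res2$vertex_curvature[perm[names(res$vertex_curvature)]]),
               unname(res$vertex_curvature), tolerance = 1e-12)
})

test_that("adding a face raises the curvature of its boundary edges", {
  for (seed in 1:6) {
    wc <- random_weighted_complex(12, 0.45, seed)
    if (!nrow(wc$complex$faces)) next
    drop <- nrow(wc$complex$faces)  # drop the last face
    boundary <- unlist(wc$complex$faces[drop, c("e12", "e13", "e23")])
    smaller <- wc
    smaller$complex <- build_without_face(wc$complex, drop)
    smaller$w_face <- wc$w_face[-drop]
    F_with <- forman_ricci_2d(wc)
    F_without <- forman_ricci_2d(smaller)
    expect_true(all(F_with[boundary] > F_without[boundary]))
  }
})

test_that("pipeline orchestrates edge, vertex and global results", {
  tri <- interaction_network(c("a", "a", "b"), c("b", "c", "c"))
  cx <- build_complex(tri)
  wc <- weight_complex(cx, c(a = 1, b = 2, c = 3))
  res <- curvature_pipeline(wc, "2D")
  expect_named(res$edge_curvature, cx$edges$key)
  expect_equal(res$global_average,
               sum(wc$stationary[names(res$vertex_curvature)] *
                   res$vertex_curvature))
  expect_equal(res$entropy, entropy_rate(wc$transition, wc$stationary))
  # face-free complex: 2D pipeline equals 1D pipeline exactly
  sq <- interaction_network(c("a", "b", "c", "d"), c("b", "c", "d", "a"))
  wq <- weight_complex(build_complex(sq),
                       c(a = 1, b = 2, c = 3, d = 4))
  expect_equal(curvature_pipeline(wq, "2D")$edge_curvature,
               curvature_pipeline(wq, "1D")$edge_curvature)
})

test_that("per-sample profiles match single-sample pipelines", {
  set.seed(9)
  net <- synthetic_network(20, 4, 1, seed = 9)
  net <- restrict_network(net, net$vertices, TRUE, verbose = FALSE)
  cx <- build_complex(net)
  expr <- matrix(rlnorm(length(net$vertices) * 3), ncol = 3,
                 dimnames = list(net$vertices, paste0("s", 1:3)))
  prof <- curvature_by_sample(cx, expr)
  for (s in 1:3) {
    wc <- weight_complex(cx, expr[, s])
    r2 <- curvature_pipeline(wc, "2D")
    expect_equal(prof$summary$global_2d[s], r2$global_average)
    expect_equal(prof$summary$entropy[s], r2$entropy)
    expect_equal(prof$vertex_2d[names(r2$vertex_curvature), s],
                 r2$vertex_curvature)
  }
})
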