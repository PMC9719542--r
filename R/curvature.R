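#' Parallel edges of an edge
#'
#' In Forman's discretisation, an edge \eqn{e_i} is *parallel* to `e` when
#' it shares a face or a vertex with `e` but not both. These are the
#' interference terms of the curvature formula. For a complex whose faces
#' are triangles, two edges sharing a face always share a vertex, so the
#' parallel edges of `e` are exactly the edges meeting `e` in one vertex
#' without a common face; this function nevertheless applies the literal
#' definition.
#'
#' @param complex A `simplicial_complex`.
#' @param e Edge as a length-2 character vector `c(u, v)` or a key
#'   `"u|v"`.
#' @return Character vector of parallel edge keys (sorted).
#' @export
parallel_edges <- function(complex, e) {
  key <- if (length(e) == 2) edge_key(e[1], e[2]) else as.character(e)
  ed <- complex$edges
  if (!key %in% ed$key) stop("edge not in complex: ", key)
  uv <- strsplit(key, "|", fixed = TRUE)[[1]]
  faces_e <- complex$edge_faces[[key]]
  if (is.null(faces_e)) faces_e <- integer(0)
  other <- ed[ed$key != key, , drop = FALSE]
  if (!nrow(other)) return(character(0))
  shares_vertex <- other$from %in% uv | other$to %in% uv
  shares_face <- vapply(other$key, function(k) {
    f <- complex$edge_faces[[k]]
    !is.null(f) && length(intersect(f, faces_e)) > 0
  }, logical(1))
  sort(other$key[xor(shares_vertex, shares_face)])
}

# Vectorised Forman-Ricci curvature for all skeleton edges.
#
# 2D (full) form per edge e = (u, v):
#   F(e) = w(e) [ sum_{f>e} w(e)/w(f) + (w(u)+w(v))/w(e)
#                 - sum_{e_i || e} | sum_{f>e,e_i} sqrt(w(e)w(e_i))/w(f)
#                                   - sum_{v<e,e_i} w(v)/sqrt(w(e)w(e_i)) | ]
# With triangular faces the parallel set reduces to edges sharing exactly
# one vertex and no face, and the inner face sum is empty, so each parallel
# edge contributes w(shared vertex)/sqrt(w(e)w(e_i)). The 1D form drops all
# face terms and takes every vertex-sharing edge as parallel.
forman_ricci_edges <- function(weighted, model = c("2D", "1D")) {
  model <- match.arg(model)
  cx <- weighted$complex
  ed <- cx$edges
  if (!nrow(ed)) return(stats::setNames(numeric(0), character(0)))
  w_e <- weighted$w_edge[ed$key]
  w_v <- weighted$w_vertex
  if (any(!is.finite(w_e)) || any(w_e <= 0) ||
      any(!is.finite(w_v)) || any(w_v <= 0)) {
    stop("all weights must be strictly positive and finite")
  }
  inv_sqrt <- 1 / sqrt(w_e)
  # A[v] = sum over edges incident to v of 1/sqrt(w(e'))
  A_tab <- tapply(c(inv_sqrt, inv_sqrt), c(ed$from, ed$to), sum)
  A <- stats::setNames(as.numeric(A_tab), names(A_tab))
  wu <- w_v[ed$from]
  wv <- w_v[ed$to]
  # vertex-sharing parallel sum (1D sense): all edges meeting an endpoint
  par_sum <- inv_sqrt * (wu * (A[ed$from] - inv_sqrt) +
                         wv * (A[ed$to] - inv_sqrt))
  vertex_term <- (wu + wv) / w_e
  if (model == "1D") {
    F <- w_e * (vertex_term - par_sum)
    return(stats::setNames(unname(F), ed$key))
  }
  face_term <- stats::setNames(numeric(nrow(ed)), ed$key)
  correction <- stats::setNames(numeric(nrow(ed)), ed$key)
  fc <- cx$faces
  if (nrow(fc)) {
    w_f <- weighted$w_face
    # sum_{f>e} w(e)/w(f)
    ft <- tapply(rep(1 / w_f, 3), c(fc$e12, fc$e13, fc$e23), sum)
    face_term[names(ft)] <- face_term[names(ft)] + as.numeric(ft) *
      weighted$w_edge[names(ft)]
    # edges co-facial with e share a vertex with e but are not parallel:
    # remove their contribution from the vertex-sharing parallel sum
    main <- c(fc$e12, fc$e12, fc$e13, fc$e13, fc$e23, fc$e23)
    partner <- c(fc$e13, fc$e23, fc$e12, fc$e23, fc$e12, fc$e13)
    shared <- c(fc$v1, fc$v2, fc$v1, fc$v3, fc$v2, fc$v3)
    val <- w_v[shared] / sqrt(weighted$w_edge[main] * weighted$w_edge[partner])
    corr <- tapply(val, main, sum)
    correction[names(corr)] <- as.numeric(corr)
  }
  F <- w_e * (face_term + vertex_term - (par_sum - correction))
  stats::setNames(unname(F), ed$key)
}

#' Forman-Ricci curvature of an edge, 2D (hypergraph) form
#'
#' Full curvature on the weighted 2-complex: face terms reward membership
#' in triangles, vertex terms reward the endpoints, and parallel-edge terms
#' penalise edges that meet `e` in a vertex or face but not both.
#'
#' @param weighted A `weighted_complex`.
#' @param e Optional edge (`c(u, v)` or `"u|v"`); when omitted, curvature
#'   of every skeleton edge is returned as a named vector.
#' @return Numeric curvature value(s).
#' @export
forman_ricci_2d <- function(weighted, e = NULL) {
  F <- forman_ricci_edges(weighted, "2D")
  if (is.null(e)) return(F)
  key <- if (length(e) == 2) edge_key(e[1], e[2]) else as.character(e)
  if (!key %in% names(F)) stop("edge not in complex: ", key)
  unname(F[key])
}

#' Forman-Ricci curvature of an edge, 1D (graph) form
#'
#' The face-free restriction of the curvature formula: only vertex and
#' parallel-edge (vertex-sharing) terms remain. With unit weights it
#' reduces to the classical \eqn{4 - \deg(u) - \deg(v)}.
#'
#' @inheritParams forman_ricci_2d
#' @return Numeric curvature value(s).
#' @export
forman_ricci_1d <- function(weighted, e = NULL) {
  F <- forman_ricci_edges(weighted, "1D")
  if (is.null(e)) return(F)
  key <- if (length(e) == 2) edge_key(e[1], e[2]) else as.character(e)
  if (!key %in% names(F)) stop("edge not in complex: ", key)
  unname(F[key])
}

#' Contract edge curvature to vertices
#'
#' \eqn{F(v) = \frac{1}{\deg(v)} \sum_{e_v \sim v} F(e_v)} over the edges
#' incident to each vertex (edge degree, undirected sense). Isolated
#' vertices are excluded.
#'
#' @param edge_curvature Named vector of per-edge curvatures (names are
#'   edge keys), as returned by [forman_ricci_2d()]/[forman_ricci_1d()].
#' @param complex The `simplicial_complex` the curvatures were computed on.
#' @return Named numeric vector of vertex curvatures.
#' @export
vertex_curvature <- function(edge_curvature, complex) {
  ed <- complex$edges
  if (!setequal(names(edge_curvature), ed$key)) {
    stop("edge curvature must cover exactly the skeleton edges")
  }
  Fe <- edge_curvature[ed$key]
  sums <- tapply(c(Fe, Fe), c(ed$from, ed$to), sum)
  degs <- tapply(rep(1L, 2 * nrow(ed)), c(ed$from, ed$to), sum)
  out <- as.numeric(sums) / as.numeric(degs)
  stats::setNames(out, names(sums))[sort(names(sums))]
}

#' Global average curvature
#'
#' \eqn{F_{GA} = \sum_i \pi_i F(v_i)}: the per-sample scalar obtained by
#' averaging vertex curvature under the stationary distribution of the
#' interaction walk.
#'
#' @param vertex_curv Named vector from [vertex_curvature()].
#' @param stationary Named stationary distribution on the same vertices.
#' @return Scalar global average.
#' @export
global_average_curvature <- function(vertex_curv, stationary) {
  if (!setequal(names(vertex_curv), names(stationary))) {
    stop("vertex curvature and stationary distribution cover different vertices")
  }
  sum(stationary[names(vertex_curv)] * vertex_curv)
}

#' Full curvature result for one weighted complex
#'
#' Computes per-edge curvature (1D or 2D form), its vertex contraction, the
#' stationary-weighted global average and the walk's entropy rate.
#'
#' @param weighted A `weighted_complex` (with a stationary distribution).
#' @param model `"2D"` or `"1D"`.
#' @return Object of class `curvature_result`: list with `model`,
#'   `edge_curvature`, `vertex_curvature`, `global_average`, `entropy`.
#' @export
curvature_pipeline <- function(weighted, model = c("2D", "1D")) {
  model <- match.arg(model)
  if (is.null(weighted$stationary)) {
    stop("weighted complex carries no stationary distribution")
  }
  Fe <- forman_ricci_edges(weighted, model)
  Fv <- vertex_curvature(Fe, weighted$complex)
  ga <- global_average_curvature(Fv, weighted$stationary)
  sr <- entropy_rate(weighted$transition, weighted$stationary)
  structure(list(model = model, edge_curvature = Fe, vertex_curvature = Fv,
                 global_average = ga, entropy = sr),
            class = "curvature_result")
}

#' @export
print.curvature_result <- function(x, ...) {
  cat(sprintf("curvature_result (%s): %d edges, global average %.6g, entropy %.6g\n",
              x$model, length(x$edge_curvature), x$global_average, x$entropy))
  invisible(x)
}

#' Per-sample curvature profiles of an expression matrix
#'
#' Runs the weighting and curvature pipeline once per sample (column):
#' mass-action transition matrix, stationary distribution, resistance
#' weights, then Forman-Ricci curvature in the requested model(s) and the
#' entropy rate.
#'
#' @param complex A `simplicial_complex` whose vertices all appear as rows
#'   of `expr`.
#' @param expr Strictly positive genes x samples matrix (normalise with
#'   [normalize_expression()] first).
#' @param model `"both"` (default), `"1D"` or `"2D"`.
#' @param config A [weighting_config()].
#' @return List with `summary` (data.frame: sample, entropy, and global
#'   averages per model) and vertex-curvature matrices `vertex_1d` /
#'   `vertex_2d` (genes x samples) for the requested models.
#' @export
curvature_by_sample <- function(complex, expr, model = c("both", "1D", "2D"),
                                config = weighting_config()) {
  model <- match.arg(model)
  verts <- complex$skeleton$vertices
  missing <- setdiff(verts, rownames(expr))
  if (length(missing)) {
    stop("expression matrix lacks network genes, e.g. ",
         paste(utils::head(missing, 3), collapse = ", "),
         "; use restrict_network() first")
  }
  samples <- colnames(expr)
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(expr)))
  do_1d <- model %in% c("both", "1D")
  do_2d <- model %in% c("both", "2D")
  v1 <- if (do_1d) matrix(NA_real_, length(verts), ncol(expr),
                          dimnames = list(verts, samples))
  v2 <- if (do_2d) matrix(NA_real_, length(verts), ncol(expr),
                          dimnames = list(verts, samples))
  sr <- ga1 <- ga2 <- rep(NA_real_, ncol(expr))
  for (s in seq_len(ncol(expr))) {
    wc <- weight_complex(complex, expr[verts, s], config)
    if (do_1d) {
      r1 <- curvature_pipeline(wc, "1D")
      v1[names(r1$vertex_curvature), s] <- r1$vertex_curvature
      ga1[s] <- r1$global_average
      sr[s] <- r1$entropy
    }
    if (do_2d) {
      r2 <- curvature_pipeline(wc, "2D")
      v2[names(r2$vertex_curvature), s] <- r2$vertex_curvature
      ga2[s] <- r2$global_average
      sr[s] <- r2$entropy
    }
  }
  summary <- data.frame(sample = samples, entropy = sr,
                        stringsAsFactors = FALSE)
  if (do_1d) summary$global_1d <- ga1
  if (do_2d) summary$global_2d <- ga2
  out <- list(summary = summary)
  if (do_1d) out$vertex_1d <- v1
  if (do_2d) out$vertex_2d <- v2
  out
}
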