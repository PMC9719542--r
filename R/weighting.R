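#' Read a gene-expression matrix
#'
#' TSV/CSV with the gene identifier in the first column and one column per
#' sample. Values must be nonnegative (normalised counts or similar).
#'
#' @param path File path.
#' @return Numeric matrix, genes in rows (rownames), samples in columns.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  genes <- as.character(dt[[1]])
  if (anyDuplicated(genes)) stop("duplicate gene identifiers in ", path)
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (any(m < 0, na.rm = TRUE)) stop("negative expression values in ", path)
  m
}

#' Normalise an expression matrix
#'
#' `cpm_log1p` rescales each sample to a total of 1e6 and applies
#' `log(1 + x)`; `none` leaves values untouched. The pseudocount is added
#' after the transform so that every entry is strictly positive, which the
#' mass-action weighting requires.
#'
#' @param matrix Nonnegative numeric matrix, genes x samples.
#' @param method `"none"` or `"cpm_log1p"`.
#' @param pseudocount Positive value added to every entry after the
#'   transform (default `1e-3`).
#' @return Matrix of the same shape, strictly positive when
#'   `pseudocount > 0`.
#' @export
normalize_expression <- function(matrix, method = c("none", "cpm_log1p"),
                                 pseudocount = 1e-3) {
  method <- match.arg(method)
  if (any(matrix < 0)) stop("expression values must be nonnegative")
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  totals <- colSums(matrix)
  if (any(totals == 0)) {
    bad <- colnames(matrix)[totals == 0]
    if (is.null(bad)) bad <- which(totals == 0)
    stop("all-zero sample(s): ", paste(bad, collapse = ", "))
  }
  out <- switch(method,
    none = matrix,
    cpm_log1p = log1p(sweep(matrix, 2, totals, "/") * 1e6))
  out + pseudocount
}

#' Mass-action transition matrix
#'
#' Under the mass-action law the propensity of interaction (i, j) is
#' \eqn{x_i x_j} for expression-derived protein levels x. Row-normalising
#' over the neighbours N(i) of the undirected skeleton (the \eqn{x_i}
#' factor cancels) gives the random-walk transition probabilities
#' \deqn{p_{ij} = x_j / \sum_{k \in N(i)} x_k.}
#'
#' @param network An `interaction_network` (its undirected skeleton is
#'   used) or a `simplicial_complex`.
#' @param x Strictly positive named vector of expression values covering
#'   all network vertices.
#' @return Object of class `transition_matrix`: list with `order` (vertex
#'   names), `P` (dense row-stochastic matrix, support on skeleton edges
#'   only), `x` (values in order) and `neighbor_sum`
#'   (\eqn{S_i = \sum_{k \in N(i)} x_k}). Isolated vertices get an all-zero
#'   row and are listed in `isolated`.
#' @export
mass_action_transition <- function(network, x) {
  if (inherits(network, "simplicial_complex")) network <- network$skeleton
  verts <- network$vertices
  if (is.null(names(x))) {
    if (length(x) != length(verts)) {
      stop("'x' must be named or match the vertex count")
    }
    names(x) <- verts
  }
  missing <- setdiff(verts, names(x))
  if (length(missing)) {
    stop("expression values missing for: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  xv <- as.numeric(x[verts])
  if (any(!is.finite(xv)) || any(xv <= 0)) {
    stop("'x' must be strictly positive and finite on all vertices")
  }
  n <- length(verts)
  sk <- skeleton_edges(network)
  i <- match(sk$from, verts)
  j <- match(sk$to, verts)
  S <- numeric(n)
  add <- tapply(c(xv[j], xv[i]), c(i, j), sum)
  S[as.integer(names(add))] <- add
  P <- matrix(0, n, n, dimnames = list(verts, verts))
  if (nrow(sk)) {
    P[cbind(i, j)] <- xv[j] / S[i]
    P[cbind(j, i)] <- xv[i] / S[j]
  }
  isolated <- verts[S == 0]
  structure(list(order = verts, P = P, x = stats::setNames(xv, verts),
                 neighbor_sum = stats::setNames(S, verts),
                 isolated = isolated),
            class = "transition_matrix")
}

#' Stationary distribution of the interaction walk
#'
#' The mass-action chain on an undirected skeleton is reversible with the
#' closed-form stationary distribution
#' \deqn{\pi_i \propto x_i \sum_{k \in N(i)} x_k} (detailed balance:
#' \eqn{\pi_i p_{ij} = x_i x_j / Z} is symmetric). `method = "power"`
#' iterates \eqn{\pi \leftarrow \pi P} to a 1e-12 residual instead and is
#' retained as an independent route for verification and for chains
#' supplied without mass-action structure.
#'
#' @param transition A `transition_matrix`.
#' @param method `"closed_form"` (default for mass-action chains) or
#'   `"power"`.
#' @param tol,max_iter Power-iteration residual tolerance and cap.
#' @return Named probability vector `pi` with `pi %*% P = pi`.
#' @export
stationary_distribution <- function(transition,
                                    method = c("closed_form", "power"),
                                    tol = 1e-12, max_iter = 100000L) {
  method <- match.arg(method)
  P <- transition$P
  n <- length(transition$order)
  if (length(transition$isolated)) {
    stop("chain has isolated vertices (",
         paste(utils::head(transition$isolated, 5), collapse = ", "),
         "); restrict the network to its largest connected component first")
  }
  g <- igraph::graph_from_adjacency_matrix(P > 0, mode = "max")
  if (igraph::components(g)$no > 1) {
    stop("chain is disconnected; restrict to the largest connected component")
  }
  if (method == "closed_form") {
    w <- transition$x * transition$neighbor_sum
    pi <- w / sum(w)
  } else {
    # lazy chain (I + P) / 2: same stationary distribution, aperiodic,
    # so bipartite skeletons cannot make the iteration oscillate
    pi <- rep(1 / n, n)
    for (iter in seq_len(max_iter)) {
      Pp <- as.numeric(pi %*% P)
      if (max(abs(Pp - pi)) < tol) break
      pi <- (pi + Pp) / 2
      pi <- pi / sum(pi)
    }
  }
  stats::setNames(as.numeric(pi), transition$order)
}

#' Entropy rate of the interaction walk
#'
#' Local entropy \eqn{S_i = -\sum_j p_{ij} \log p_{ij}} (natural log)
#' averaged under the stationary distribution:
#' \eqn{SR = \sum_i \pi_i S_i}. A scalar heterogeneity/robustness proxy for
#' the weighted network; bounded by \eqn{\log} of the maximum degree.
#'
#' @param transition A `transition_matrix`.
#' @param stationary Stationary distribution from
#'   [stationary_distribution()].
#' @param normalize Divide by \eqn{\log} of the maximum degree (off by
#'   default).
#' @return Entropy rate (nats).
#' @export
entropy_rate <- function(transition, stationary, normalize = FALSE) {
  P <- transition$P
  terms <- P * log(P)
  terms[P == 0] <- 0
  S <- -rowSums(terms)
  sr <- sum(stationary[transition$order] * S)
  if (normalize) {
    kmax <- max(rowSums(P > 0))
    if (kmax > 1) sr <- sr / log(kmax)
  }
  sr
}

#' Weighting options
#'
#' @param symmetrization How the two directed probabilities of an edge are
#'   combined before inversion: `"mean"` (default), `"min"`, `"max"`.
#' @param vertex_weight `"stationary"` (w(v) = pi_v, default) or
#'   `"expression"` (w(v) = x_v). A results-sensitive choice.
#' @param face_rule Face weight from the three boundary-edge weights:
#'   `"gm2"` (default, \eqn{(w_1 w_2 w_3)^{2/3}}, area-like), `"product"`,
#'   `"mean"`, `"max"`.
#' @return List of class `weighting_config`.
#' @export
weighting_config <- function(symmetrization = c("mean", "min", "max"),
                             vertex_weight = c("stationary", "expression"),
                             face_rule = c("gm2", "product", "mean", "max")) {
  structure(list(symmetrization = match.arg(symmetrization),
                 vertex_weight = match.arg(vertex_weight),
                 face_rule = match.arg(face_rule)),
            class = "weighting_config")
}

#' Geometric weights on a complex (resistance quasimetric)
#'
#' Turns interaction probabilities into geometric weights: the edge weight
#' is the inverse of the (symmetrised) interaction probability, so likely
#' interactions are short edges and unlikely interactions long ones. Vertex
#' weights default to the stationary probabilities and face weights are
#' derived from the boundary-edge weights.
#'
#' @param complex A `simplicial_complex`.
#' @param transition A `transition_matrix` on the same skeleton.
#' @param stationary Stationary distribution (required unless
#'   `config$vertex_weight == "expression"`).
#' @param config A [weighting_config()].
#' @return Object of class `weighted_complex`: list with `complex`,
#'   `w_vertex`, `w_edge` (named by edge key), `w_face` (per face row),
#'   `transition`, `stationary`, `config`. All weights strictly positive.
#' @export
geometric_weights <- function(complex, transition, stationary = NULL,
                              config = weighting_config()) {
  verts <- complex$skeleton$vertices
  if (!identical(sort(transition$order), sort(verts))) {
    stop("transition matrix and complex have different vertex sets")
  }
  ed <- complex$edges
  P <- transition$P
  i <- match(ed$from, transition$order)
  j <- match(ed$to, transition$order)
  pij <- P[cbind(i, j)]
  pji <- P[cbind(j, i)]
  pbar <- switch(config$symmetrization,
                 mean = (pij + pji) / 2,
                 min = pmin(pij, pji),
                 max = pmax(pij, pji))
  if (any(pbar <= 0)) {
    stop("nonpositive symmetrised probability on some edge; ",
         "use a positive pseudocount upstream")
  }
  w_edge <- stats::setNames(1 / pbar, ed$key)
  if (config$vertex_weight == "stationary") {
    if (is.null(stationary)) {
      stop("stationary distribution required for vertex_weight = 'stationary'")
    }
    w_vertex <- stationary[verts]
  } else {
    w_vertex <- transition$x[verts]
  }
  if (any(!is.finite(w_vertex)) || any(w_vertex <= 0)) {
    stop("vertex weights must be strictly positive and finite")
  }
  fc <- complex$faces
  if (nrow(fc)) {
    w1 <- w_edge[fc$e12]; w2 <- w_edge[fc$e13]; w3 <- w_edge[fc$e23]
    w_face <- switch(config$face_rule,
                     gm2 = (w1 * w2 * w3)^(2 / 3),
                     product = w1 * w2 * w3,
                     mean = (w1 + w2 + w3) / 3,
                     max = pmax(w1, w2, w3))
    w_face <- unname(w_face)
  } else {
    w_face <- numeric(0)
  }
  structure(list(complex = complex,
                 w_vertex = stats::setNames(as.numeric(w_vertex), verts),
                 w_edge = w_edge, w_face = w_face,
                 transition = transition, stationary = stationary,
                 config = config),
            class = "weighted_complex")
}

#' One-call weighting of a complex for a single sample
#'
#' Convenience wrapper: mass-action transition matrix, closed-form
#' stationary distribution and geometric weights for one expression vector.
#'
#' @param complex A `simplicial_complex`.
#' @param x Strictly positive named expression vector covering the
#'   vertices.
#' @param config A [weighting_config()].
#' @return A `weighted_complex`.
#' @export
weight_complex <- function(complex, x, config = weighting_config()) {
  tm <- mass_action_transition(complex$skeleton, x)
  pi <- stationary_distribution(tm)
  geometric_weights(complex, tm, pi, config)
}

#' Weighted complex from explicit weights
#'
#' Builds a `weighted_complex` directly from user-supplied weights instead
#' of the mass-action pipeline, e.g. unit weights for the combinatorial
#' curvature closed forms. Scalars are recycled.
#'
#' @param complex A `simplicial_complex`.
#' @param w_vertex Positive vertex weights (scalar or named vector).
#' @param w_edge Positive edge weights (scalar or vector named by edge
#'   key).
#' @param w_face Positive face weights (scalar or vector along the face
#'   rows).
#' @param transition,stationary Optional chain carried along for
#'   [curvature_pipeline()].
#' @return A `weighted_complex`.
#' @export
manual_weighted_complex <- function(complex, w_vertex = 1, w_edge = 1,
                                    w_face = 1, transition = NULL,
                                    stationary = NULL) {
  verts <- complex$skeleton$vertices
  keys <- complex$edges$key
  nf <- nrow(complex$faces)
  wv <- if (length(w_vertex) == 1) stats::setNames(rep(w_vertex, length(verts)), verts)
        else w_vertex[verts]
  we <- if (length(w_edge) == 1) stats::setNames(rep(w_edge, length(keys)), keys)
        else w_edge[keys]
  wf <- if (length(w_face) == 1) rep(w_face, nf) else as.numeric(w_face)
  if (any(!is.finite(wv)) || any(wv <= 0) ||
      any(!is.finite(we)) || any(we <= 0) ||
      (nf && (any(!is.finite(wf)) || any(wf <= 0)))) {
    stop("all weights must be strictly positive and finite")
  }
  structure(list(complex = complex, w_vertex = wv, w_edge = we, w_face = wf,
                 transition = transition, stationary = stationary,
                 config = NULL),
            class = "weighted_complex")
}
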