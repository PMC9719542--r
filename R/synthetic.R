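#' Toy fixture networks with known curvature
#'
#' Small named networks covering the structural cases of the curvature
#' formulas. Expected values under unit weights:
#' \itemize{
#'   \item `isolated_edge`: 1D curvature 2 on the single edge.
#'   \item `path3` (a-b-c): 1D curvatures (1, 1); no faces.
#'   \item `cycle6`: 1D curvature 0 on every edge (4 - 2 - 2).
#'   \item `star5` (hub + 5 leaves): 1D curvature -2 per edge (4 - 5 - 1).
#'   \item `filled_triangle` (undirected K3): one face; 2D curvature 3 on
#'     every edge.
#'   \item `ffl` (a->b, b->c, a->c): one feedforward face.
#'   \item `fbl` (a->b, b->c, c->a): one feedback face.
#'   \item `two_faces` (triangles abc and abd sharing edge ab): 2D
#'     curvature 4 on the shared edge ab.
#'   \item `face_free` (4-cycle): no faces; 2D reduces to 1D (all zeros).
#' }
#'
#' @return Named list of `interaction_network` objects.
#' @export
toy_complexes <- function() {
  list(
    isolated_edge = interaction_network("a", "b"),
    path3 = interaction_network(c("a", "b"), c("b", "c")),
    cycle6 = interaction_network(letters[1:6], c(letters[2:6], "a")),
    star5 = interaction_network(rep("hub", 5), paste0("leaf", 1:5)),
    filled_triangle = interaction_network(c("a", "a", "b"),
                                          c("b", "c", "c")),
    ffl = interaction_network(c("a", "b", "a"), c("b", "c", "c"),
                              directed = TRUE),
    fbl = interaction_network(c("a", "b", "c"), c("b", "c", "a"),
                              directed = TRUE),
    two_faces = interaction_network(c("a", "a", "b", "a", "b"),
                                    c("b", "c", "c", "d", "d")),
    face_free = interaction_network(c("a", "b", "c", "d"),
                                    c("b", "c", "d", "a"))
  )
}

#' Generate a synthetic interaction network
#'
#' Edges are laid down in two phases: a uniform G(n, m) phase and a
#' wedge-closure phase that picks an open path u-c-v (centre chosen with
#' probability proportional to the number of open wedges it anchors) and
#' closes it into a triangle. `triangle_enrichment` sets the odds of the
#' closure phase: 0 gives a plain uniform G(n, m) sample, larger values an
#' increasing triangle excess over a random network of the same size.
#' Closure targets concentrate on high-degree vertices, giving the mild
#' right-skewed degree distribution typical of interaction networks.
#'
#' @param n_vertices Number of vertices.
#' @param target_mean_degree Desired mean skeleton degree (sets
#'   `m = round(n * k / 2)`).
#' @param triangle_enrichment Nonnegative; fraction
#'   `triangle_enrichment / (1 + triangle_enrichment)` of edges are placed
#'   by wedge closure.
#' @param directed_fraction Fraction of skeleton edges made one-way (a
#'   random direction); the rest become reciprocal arc pairs. 0 returns an
#'   undirected network.
#' @param seed Integer seed; fixed seed reproduces the network exactly.
#' @return An `interaction_network`.
#' @export
synthetic_network <- function(n_vertices, target_mean_degree,
                              triangle_enrichment = 0,
                              directed_fraction = 0, seed = 1L) {
  if (n_vertices < 4) stop("need at least 4 vertices")
  if (triangle_enrichment < 0) stop("triangle_enrichment must be >= 0")
  if (directed_fraction < 0 || directed_fraction > 1) {
    stop("directed_fraction must be in [0, 1]")
  }
  m_total <- round(n_vertices * target_mean_degree / 2)
  max_m <- n_vertices * (n_vertices - 1) / 2
  if (m_total > max_m) stop("target_mean_degree infeasible for n_vertices")
  if (m_total < 1) stop("target_mean_degree too small: no edges")
  local_seed(seed, {
    frac <- triangle_enrichment / (1 + triangle_enrichment)
    m_closure <- round(m_total * frac)
    m_rand <- m_total - m_closure
    adj <- matrix(FALSE, n_vertices, n_vertices)
    el <- matrix(0L, m_total, 2)
    n_e <- 0L
    add_edge <- function(u, v) {
      n_e <<- n_e + 1L
      el[n_e, ] <<- c(u, v)
      adj[u, v] <<- TRUE
      adj[v, u] <<- TRUE
    }
    g0 <- igraph::sample_gnm(n_vertices, m_rand, directed = FALSE)
    el0 <- igraph::as_edgelist(g0, names = FALSE)
    for (r in seq_len(nrow(el0))) add_edge(el0[r, 1], el0[r, 2])
    deg <- tabulate(el[seq_len(n_e), ], nbins = n_vertices)
    added <- 0L
    stalls <- 0L
    while (added < m_closure) {
      wedge_w <- deg * (deg - 1)
      if (sum(wedge_w) > 0 && stalls < 50L) {
        c0 <- sample.int(n_vertices, 1, prob = wedge_w)
        nb <- which(adj[c0, ])
        uv <- nb[sample.int(length(nb), 2)]
        if (!adj[uv[1], uv[2]]) {
          add_edge(uv[1], uv[2])
          deg[uv] <- deg[uv] + 1L
          added <- added + 1L
          stalls <- 0L
        } else {
          stalls <- stalls + 1L
        }
      } else {
        # fall back to a uniform non-edge when closures are exhausted
        repeat {
          uv <- sample.int(n_vertices, 2)
          if (!adj[uv[1], uv[2]]) break
        }
        add_edge(uv[1], uv[2])
        deg[uv] <- deg[uv] + 1L
        added <- added + 1L
        stalls <- 0L
      }
    }
    el <- el[seq_len(n_e), , drop = FALSE]
    fmt <- paste0("g%0", nchar(as.character(n_vertices)), "d")
    from <- sprintf(fmt, el[, 1])
    to <- sprintf(fmt, el[, 2])
    verts <- sprintf(fmt, seq_len(n_vertices))
    if (directed_fraction == 0) {
      interaction_network(from, to, vertices = verts)
    } else {
      one_way <- stats::runif(nrow(el)) < directed_fraction
      flip <- stats::runif(nrow(el)) < 0.5
      a <- ifelse(flip, to, from)
      b <- ifelse(flip, from, to)
      f2 <- c(a, b[!one_way])
      t2 <- c(b, a[!one_way])
      interaction_network(f2, t2, directed = TRUE, vertices = verts)
    }
  })
}

#' Specification for a synthetic two-group expression experiment
#'
#' @param n_genes Number of genes (ignored when `genes` are passed to
#'   [synthetic_expression()]).
#' @param n_per_group Samples per group.
#' @param n_planted Number of genes receiving the expression shift in
#'   group B.
#' @param effect_size Multiplicative shift (> 0) applied to the mean of
#'   planted genes in group B; 1 means exchangeable groups.
#' @param dispersion Negative-binomial overdispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param base_mean_log,base_sd_log Log-normal parameters of the per-gene
#'   baseline means.
#' @param seed Integer seed.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 200, n_per_group = 50, n_planted = 20,
                           effect_size = 4, dispersion = 0.3,
                           base_mean_log = log(50), base_sd_log = 1,
                           seed = 1L) {
  if (effect_size <= 0) stop("effect_size must be > 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  structure(list(n_genes = n_genes, n_per_group = n_per_group,
                 n_planted = n_planted, effect_size = effect_size,
                 dispersion = dispersion, base_mean_log = base_mean_log,
                 base_sd_log = base_sd_log, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Simulate a two-group expression matrix with planted shifts
#'
#' Negative-binomial counts per gene and sample; a random subset of genes
#' has its group-B mean multiplied by `effect_size` (applied before any
#' normalisation, so downstream normalisation choices are exercised).
#'
#' @param spec A [synthetic_spec()].
#' @param genes Optional character vector of gene identifiers (e.g. the
#'   vertices of a [synthetic_network()]); overrides `spec$n_genes`.
#' @return List with `matrix` (genes x samples counts), `labels`
#'   (data.frame `sample`, `group` in `"A"`/`"B"`) and `truth` (planted
#'   gene identifiers).
#' @export
synthetic_expression <- function(spec, genes = NULL) {
  if (is.null(genes)) genes <- sprintf("g%04d", seq_len(spec$n_genes))
  genes <- as.character(genes)
  ng <- length(genes)
  if (spec$n_planted > ng) stop("n_planted exceeds the number of genes")
  local_seed(spec$seed, {
    planted <- sort(sample(genes, spec$n_planted))
    mu <- stats::rlnorm(ng, spec$base_mean_log, spec$base_sd_log)
    names(mu) <- genes
    n <- spec$n_per_group
    size <- if (spec$dispersion > 0) 1 / spec$dispersion else Inf
    mu_b <- mu
    mu_b[planted] <- mu_b[planted] * spec$effect_size
    draw <- function(m) {
      matrix(stats::rnbinom(ng * n, mu = rep(m, n), size = size),
             nrow = ng, dimnames = list(genes, NULL))
    }
    a <- draw(mu)
    b <- draw(mu_b)
    mat <- cbind(a, b)
    samples <- c(sprintf("A%03d", seq_len(n)), sprintf("B%03d", seq_len(n)))
    colnames(mat) <- samples
    labels <- data.frame(sample = samples,
                         group = rep(c("A", "B"), each = n),
                         stringsAsFactors = FALSE)
    list(matrix = mat, labels = labels, truth = planted)
  })
}
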