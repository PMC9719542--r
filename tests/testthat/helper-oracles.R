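# Independent oracles, deliberately naive: set-based literal evaluations
# of the definitions, kept separate from the package's optimized paths.

# Brute-force face enumeration over all C(n,3) vertex triples.
oracle_faces <- function(network) {
  verts <- network$vertices
  sk <- skeleton_edges(network)
  und <- paste(sk$from, sk$to)
  has_und <- function(u, v) paste(min(u, v), max(u, v)) %in% und
  arcs <- paste(network$edges$from, network$edges$to)
  has_arc <- function(u, v) paste(u, v) %in% arcs
  out <- list()
  if (length(verts) < 3) {
    return(data.frame(v1 = character(), v2 = character(), v3 = character(),
                      orientation = character(), stringsAsFactors = FALSE))
  }
  combs <- utils::combn(sort(verts), 3)
  for (ci in seq_len(ncol(combs))) {
    tr <- combs[, ci]
    a <- tr[1]; b <- tr[2]; c <- tr[3]
    if (!(has_und(a, b) && has_und(a, c) && has_und(b, c))) next
    if (!network$directed) {
      out[[length(out) + 1]] <- c(a, b, c, "undirected")
      next
    }
    fb <- (has_arc(a, b) && has_arc(b, c) && has_arc(c, a)) ||
          (has_arc(b, a) && has_arc(c, b) && has_arc(a, c))
    out[[length(out) + 1]] <- c(a, b, c, if (fb) "feedback" else "feedforward")
  }
  if (!length(out)) {
    return(data.frame(v1 = character(), v2 = character(), v3 = character(),
                      orientation = character(), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, out)
  data.frame(v1 = m[, 1], v2 = m[, 2], v3 = m[, 3], orientation = m[, 4],
             stringsAsFactors = FALSE)
}

# Literal evaluation of the Forman-Ricci formula: loops and explicit set
# intersections, including the absolute-value parallel term with both its
# shared-face and shared-vertex inner sums.
oracle_forman <- function(wc, model = "2D") {
  cx <- wc$complex
  ed <- cx$edges
  fc <- cx$faces
  face_edges <- if (nrow(fc)) {
    lapply(seq_len(nrow(fc)), function(i) c(fc$e12[i], fc$e13[i], fc$e23[i]))
  } else list()
  faces_of <- function(key) {
    if (!length(face_edges)) return(integer(0))
    which(vapply(face_edges, function(fe) key %in% fe, logical(1)))
  }
  res <- numeric(nrow(ed))
  names(res) <- ed$key
  for (r in seq_len(nrow(ed))) {
    e <- ed$key[r]
    uv <- c(ed$from[r], ed$to[r])
    we <- wc$w_edge[[e]]
    fe <- if (model == "2D") faces_of(e) else integer(0)
    t_face <- if (length(fe)) sum(we / wc$w_face[fe]) else 0
    t_vert <- sum(wc$w_vertex[uv]) / we
    t_par <- 0
    for (r2 in seq_len(nrow(ed))) {
      if (r2 == r) next
      e2 <- ed$key[r2]
      uv2 <- c(ed$from[r2], ed$to[r2])
      we2 <- wc$w_edge[[e2]]
      shared_v <- intersect(uv, uv2)
      shared_f <- if (model == "2D") intersect(fe, faces_of(e2)) else integer(0)
      is_par <- if (model == "2D") {
        xor(length(shared_v) > 0, length(shared_f) > 0)
      } else {
        length(shared_v) > 0
      }
      if (!is_par) next
      inner_f <- if (length(shared_f)) {
        sum(sqrt(we * we2) / wc$w_face[shared_f])
      } else 0
      inner_v <- if (length(shared_v)) {
        sum(wc$w_vertex[shared_v]) / sqrt(we * we2)
      } else 0
      t_par <- t_par + abs(inner_f - inner_v)
    }
    res[r] <- we * (t_face + t_vert - t_par)
  }
  res
}

# Random connected-ish weighted complex on n vertices with lognormal weights.
random_weighted_complex <- function(n, p = 0.35, seed = 1) {
  net <- local({
    set.seed(seed)
    g <- igraph::sample_gnp(n, p)
    el <- igraph::as_edgelist(g, names = FALSE)
    if (nrow(el) < 1) el <- matrix(c(1, 2), 1)
    interaction_network(sprintf("v%02d", el[, 1]), sprintf("v%02d", el[, 2]),
                        vertices = sprintf("v%02d", seq_len(n)))
  })
  cx <- build_complex(net)
  set.seed(seed + 1000)
  manual_weighted_complex(
    cx,
    w_vertex = stats::setNames(rlnorm(length(net$vertices), 0, 0.7),
                               net$vertices),
    w_edge = stats::setNames(rlnorm(nrow(cx$edges), 0, 0.7), cx$edges$key),
    w_face = if (nrow(cx$faces)) rlnorm(nrow(cx$faces), 0, 0.7) else 1)
}

# Exact two-sided rank-sum p-value by enumeration of all labelings.
oracle_wilcoxon_exact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  obs <- sum(r[seq_len(na)])
  combs <- utils::combn(n, na)
  stats <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- mean(stats)
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# BH step-up q-values, written independently of stats::p.adjust.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Hypergeometric upper tail by direct pmf summation.
oracle_hyper_tail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}
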