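#' Construct an interaction network
#'
#' Low-level constructor for the 1-dimensional skeleton of the model: a set
#' of protein/gene vertices plus pairwise interactions, optionally directed
#' and optionally carrying integer confidence scores (STRING convention,
#' 0--1000).
#'
#' Self-loops are dropped, duplicate (ordered, or unordered when
#' `directed = FALSE`) pairs are collapsed keeping the maximum score, and
#' vertices are stored in lexicographic order so downstream computations are
#' deterministic.
#'
#' @param from,to Character vectors of endpoint identifiers (equal length).
#' @param score Optional integer/numeric confidence per pair; defaults to
#'   `NA` (unscored).
#' @param directed Logical; if `TRUE`, `from -> to` ordered pairs are kept,
#'   otherwise pairs are canonicalised with `from < to`.
#' @param vertices Optional character vector of vertices to include even if
#'   isolated.
#' @return An object of class `interaction_network`: a list with elements
#'   `vertices` (sorted character), `edges` (data.frame `from`, `to`,
#'   `score`) and `directed`.
#' @export
interaction_network <- function(from, to, score = NULL, directed = FALSE,
                                vertices = NULL) {
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) != length(to)) {
    stop("'from' and 'to' must have the same length")
  }
  if (is.null(score)) score <- rep(NA_real_, length(from))
  score <- as.numeric(score)
  keep <- from != to
  from <- from[keep]; to <- to[keep]; score <- score[keep]
  if (!directed) {
    lo <- pmin(from, to)
    hi <- pmax(from, to)
    from <- lo; to <- hi
  }
  if (length(from)) {
    key <- paste(from, to, sep = "\r")
    o <- order(key, -xtfrm(score), method = "radix")
    dup <- duplicated(key[o])
    o <- o[!dup]
    o <- o[order(from[o], to[o], method = "radix")]
    edges <- data.frame(from = from[o], to = to[o], score = score[o],
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(), to = character(),
                        score = numeric(), stringsAsFactors = FALSE)
  }
  verts <- sort(unique(c(edges$from, edges$to, as.character(vertices))))
  structure(list(vertices = verts, edges = edges, directed = directed),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d vertices, %d %s edges\n",
              length(x$vertices), nrow(x$edges),
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

# canonical "u|v" key for an unordered vertex pair
edge_key <- function(u, v) {
  paste(pmin(u, v), pmax(u, v), sep = "|")
}

#' Undirected skeleton edge list
#'
#' Collapses reciprocal directed pairs to single undirected edges. Topology,
#' weighting and curvature all operate on this skeleton; arc directions only
#' matter for face-orientation classification.
#'
#' @param network An `interaction_network`.
#' @return data.frame with columns `from`, `to` (`from < to`), sorted.
#' @export
skeleton_edges <- function(network) {
  e <- network$edges
  if (!nrow(e)) {
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  }
  lo <- pmin(e$from, e$to)
  hi <- pmax(e$from, e$to)
  key <- paste(lo, hi, sep = "\r")
  keep <- !duplicated(key)
  out <- data.frame(from = lo[keep], to = hi[keep], stringsAsFactors = FALSE)
  out[order(out$from, out$to, method = "radix"), , drop = FALSE]
}

# skeleton as an igraph object (vertex names preserved)
skeleton_igraph <- function(network) {
  sk <- skeleton_edges(network)
  igraph::graph_from_data_frame(sk, directed = FALSE,
                                vertices = data.frame(name = network$vertices))
}

#' Read an interaction network from an edge-list file
#'
#' Accepts STRING `protein.links`-style files (space- or tab-delimited, a
#' header naming at least two identifier columns and score columns) as well
#' as plain 2--3 column edge lists. Rows whose score falls below `cutoff`
#' are discarded; self-loops are dropped and duplicate pairs collapsed
#' keeping the maximum score.
#'
#' @param path Path to the edge-list file (TSV/SSV with header).
#' @param score_column Name of the score column used for filtering. Ignored
#'   when `cutoff <= 0` and the column is absent.
#' @param cutoff Minimum score to keep an edge (STRING scores are integers
#'   in 0--1000; 400 is the conventional medium-confidence threshold).
#' @param directed Should the pairs be interpreted as ordered?
#' @param columns Character vector of length 2 naming the identifier
#'   columns; defaults to the first two columns of the file.
#' @param alias Optional data.frame (or path to a 2-column TSV) mapping
#'   identifiers in the file to preferred symbols; unmapped rows are dropped
#'   with a message.
#' @param verbose Emit messages about dropped rows.
#' @return An `interaction_network`.
#' @export
load_interaction_network <- function(path, score_column = "combined_score",
                                     cutoff = 400, directed = FALSE,
                                     columns = NULL, alias = NULL,
                                     verbose = TRUE) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  if (ncol(dt) < 2) stop("edge-list file needs at least two columns: ", path)
  if (is.null(columns)) columns <- names(dt)[1:2]
  if (!all(columns %in% names(dt))) {
    stop("identifier columns not found: ", paste(columns, collapse = ", "))
  }
  from <- as.character(dt[[columns[1]]])
  to <- as.character(dt[[columns[2]]])
  bad <- which(is.na(from) | is.na(to) | from == "" | to == "")
  if (length(bad)) {
    stop("malformed edge row(s) at line(s): ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  }
  score <- rep(NA_real_, nrow(dt))
  if (score_column %in% names(dt)) {
    score <- suppressWarnings(as.numeric(dt[[score_column]]))
    badsc <- which(is.na(score) & !is.na(dt[[score_column]]))
    if (length(badsc)) {
      stop("non-numeric score at line(s): ",
           paste(utils::head(badsc + 1L, 5), collapse = ", "))
    }
  } else if (cutoff > 0) {
    stop("score column '", score_column, "' not present but cutoff = ",
         cutoff, " requested")
  }
  if (!is.null(alias)) {
    if (is.character(alias) && length(alias) == 1) {
      alias <- data.table::fread(alias, header = TRUE, data.table = FALSE,
                                 showProgress = FALSE)
    }
    map <- stats::setNames(as.character(alias[[2]]), as.character(alias[[1]]))
    from2 <- unname(map[from]); to2 <- unname(map[to])
    unmapped <- is.na(from2) | is.na(to2)
    if (verbose && any(unmapped)) {
      message(sum(unmapped), " row(s) dropped: identifier not in alias table")
    }
    from <- from2[!unmapped]; to <- to2[!unmapped]; score <- score[!unmapped]
  }
  if (cutoff > 0) {
    keep <- !is.na(score) & score >= cutoff
    if (verbose) {
      message(sum(!keep), " row(s) below score cutoff ", cutoff, " dropped")
    }
    from <- from[keep]; to <- to[keep]; score <- score[keep]
  }
  n_loops <- sum(from == to)
  if (verbose && n_loops > 0) {
    message(n_loops, " self-loop row(s) dropped")
  }
  interaction_network(from, to, score, directed = directed)
}

#' Restrict a network to a gene set
#'
#' Intersects the vertex set with `genes` (typically the genes measured in
#' an expression matrix) and optionally keeps only the largest (weakly)
#' connected component, as required before Markov-chain weighting.
#'
#' @param network An `interaction_network`.
#' @param genes Character vector of identifiers to keep.
#' @param keep_largest_component Retain only the largest connected
#'   component of the restricted skeleton.
#' @param verbose Message the number of vertices discarded.
#' @return The restricted `interaction_network`.
#' @export
restrict_network <- function(network, genes, keep_largest_component = TRUE,
                             verbose = TRUE) {
  if (!length(genes)) stop("'genes' must be nonempty")
  genes <- as.character(genes)
  keep_v <- intersect(network$vertices, genes)
  if (!length(keep_v)) {
    stop("no network vertices overlap the supplied gene set")
  }
  e <- network$edges
  e <- e[e$from %in% keep_v & e$to %in% keep_v, , drop = FALSE]
  net <- interaction_network(e$from, e$to, e$score,
                             directed = network$directed, vertices = keep_v)
  if (keep_largest_component) {
    g <- skeleton_igraph(net)
    comp <- igraph::components(g, mode = "weak")
    main <- igraph::V(g)$name[comp$membership == which.max(comp$csize)]
    e <- net$edges
    e <- e[e$from %in% main & e$to %in% main, , drop = FALSE]
    net <- interaction_network(e$from, e$to, e$score,
                               directed = network$directed, vertices = main)
  }
  if (verbose) {
    dropped <- length(network$vertices) - length(net$vertices)
    if (dropped > 0) message(dropped, " vertex/vertices discarded by restriction")
  }
  net
}

#' Sample an Erdos-Renyi G(n, m) network
#'
#' Uniform sample of exactly `n_edges` distinct edges on `n_vertices`
#' labelled vertices with no self-loops, used as the random null against
#' which the face count of the real interaction network is compared.
#'
#' @param n_vertices,n_edges Graph size.
#' @param seed Integer seed; a fixed seed reproduces the edge set exactly.
#' @param directed Sample ordered pairs instead of unordered.
#' @return An `interaction_network` with vertices `"v1" ... "vn"` (zero-padded).
#' @export
erdos_renyi_network <- function(n_vertices, n_edges, seed = 1L,
                                directed = FALSE) {
  max_m <- if (directed) {
    as.numeric(n_vertices) * (n_vertices - 1)
  } else {
    as.numeric(n_vertices) * (n_vertices - 1) / 2
  }
  if (n_edges > max_m) {
    stop("n_edges = ", n_edges, " exceeds the maximum ", max_m,
         " for a simple graph on ", n_vertices, " vertices")
  }
  g <- local_seed(seed, igraph::sample_gnm(n_vertices, n_edges,
                                           directed = directed))
  el <- igraph::as_edgelist(g, names = FALSE)
  fmt <- paste0("v%0", nchar(as.character(n_vertices)), "d")
  interaction_network(sprintf(fmt, el[, 1]), sprintf(fmt, el[, 2]),
                      directed = directed,
                      vertices = sprintf(fmt, seq_len(n_vertices)))
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
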