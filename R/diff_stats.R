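#' Per-gene differential statistics between two sample groups
#'
#' Two-sided Wilcoxon rank-sum test per gene on any per-gene, per-sample
#' quantity (vertex curvature or expression), with Benjamini-Hochberg FDR
#' control. `delta` is `mean(group B) - mean(group A)` and `direction` its
#' sign. Genes constant across both groups get `p = 1` and are flagged.
#'
#' @param values_a,values_b Genes x samples matrices with identical
#'   rownames; at least 2 samples per group.
#' @param alpha FDR level defining the `significant` column (default 0.05).
#' @return data.frame (one row per gene): `gene`, `statistic` (rank-sum U),
#'   `p_value`, `q_value`, `delta`, `direction` (+1/-1/0), `significant`,
#'   `flagged` (constant gene).
#' @export
differential_table <- function(values_a, values_b, alpha = 0.05) {
  if (!identical(rownames(values_a), rownames(values_b))) {
    stop("the two matrices must have identical gene rownames")
  }
  if (ncol(values_a) < 2 || ncol(values_b) < 2) {
    stop("need at least 2 samples per group")
  }
  genes <- rownames(values_a)
  n <- length(genes)
  stat <- p <- delta <- numeric(n)
  flagged <- logical(n)
  for (g in seq_len(n)) {
    a <- values_a[g, ]
    b <- values_b[g, ]
    delta[g] <- mean(b) - mean(a)
    if (length(unique(c(a, b))) == 1L) {
      stat[g] <- length(a) * length(b) / 2
      p[g] <- 1
      flagged[g] <- TRUE
      next
    }
    wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
    stat[g] <- unname(wt$statistic)
    p[g] <- wt$p.value
  }
  q <- stats::p.adjust(p, method = "BH")
  data.frame(gene = genes, statistic = stat, p_value = p, q_value = q,
             delta = delta, direction = sign(delta),
             significant = q < alpha, flagged = flagged,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Intersection-region counts of named sets
#'
#' Counts of every membership region of a collection of sets (the numbers
#' behind a Venn diagram of significant-gene overlaps).
#'
#' @param sets Named list (>= 2 elements) of character vectors.
#' @return data.frame with one logical column per set, a `region` label
#'   like `"FR_1D&FR_2D"`, and `count`; all 2^k - 1 nonempty-membership
#'   regions are reported (possibly with count 0). Counts sum to the size
#'   of the union.
#' @export
overlap_counts <- function(sets) {
  if (length(sets) < 2 || is.null(names(sets))) {
    stop("'sets' must be a named list of at least two sets")
  }
  sets <- lapply(sets, unique)
  universe <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL, names(sets)))
  k <- length(sets)
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))[-1, , drop = FALSE]
  colnames(grid) <- names(sets)
  pattern <- apply(member, 1, paste, collapse = "\r")
  counts <- apply(grid, 1, function(row) {
    sum(pattern == paste(row, collapse = "\r"))
  })
  region <- apply(grid, 1, function(row) {
    paste(names(sets)[as.logical(row)], collapse = "&")
  })
  out <- data.frame(grid, region = region, count = as.integer(counts),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(rowSums(grid), region), , drop = FALSE]
}

#' Rank-based AUC of a score against binary labels
#'
#' Mann-Whitney estimate of the area under the ROC curve: the probability
#' that a random positive outscores a random negative, ties counting 1/2.
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (logical, 0/1, or 2-level factor; the
#'   higher/TRUE level is the positive class).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_binary_labels(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  u <- sort(unique(labels))
  if (length(u) != 2) stop("labels must have exactly two levels")
  labels == u[2]
}

#' DeLong comparison of two paired AUCs
#'
#' Compares the AUCs of two scores measured on the same samples using
#' DeLong's covariance estimate for correlated ROC curves and a two-sided
#' normal test on the AUC difference.
#'
#' @param scores_1,scores_2 Numeric score vectors on identical samples.
#' @param labels Binary labels shared by both scores.
#' @return List with `auc_1`, `auc_2`, `p_value`.
#' @export
delong_compare <- function(scores_1, scores_2, labels) {
  if (length(scores_1) != length(scores_2) ||
      length(scores_1) != length(labels)) {
    stop("scores and labels must have equal length")
  }
  pos <- as_binary_labels(labels)
  r1 <- pROC::roc(response = pos, predictor = scores_1, quiet = TRUE,
                  direction = "<", levels = c(FALSE, TRUE))
  r2 <- pROC::roc(response = pos, predictor = scores_2, quiet = TRUE,
                  direction = "<", levels = c(FALSE, TRUE))
  auc1 <- as.numeric(pROC::auc(r1))
  auc2 <- as.numeric(pROC::auc(r2))
  if (isTRUE(all.equal(scores_1, scores_2))) {
    return(list(auc_1 = auc1, auc_2 = auc2, p_value = 1))
  }
  tst <- tryCatch(
    pROC::roc.test(r1, r2, method = "delong", paired = TRUE),
    error = function(e) stop("DeLong test failed: ", conditionMessage(e)))
  p <- as.numeric(tst$p.value)
  if (is.nan(p)) p <- 1  # identical rank patterns -> zero variance of the difference
  list(auc_1 = auc1, auc_2 = auc2, p_value = p)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[[`, character(1), 1))
}

#' Gene-set overrepresentation with curvature shifts
#'
#' One-sided hypergeometric tail test \eqn{P(X \ge n_{overlap})} of a hit
#' list against each gene set (intersected with the background), BH FDR
#' across sets, and the mean shift (e.g. mean \eqn{\Delta Ric_{2D}}) of the
#' overlapping genes.
#'
#' @param hits Character vector of significant genes (subset of
#'   `background`).
#' @param background Character vector: the tested universe (typically all
#'   network genes present in the expression matrix).
#' @param gene_sets Named list of character vectors (e.g. [read_gmt()]).
#' @param deltas Optional named per-gene shift used for `mean_delta`.
#' @return data.frame per retained set: `set`, `set_size` (within
#'   background), `n_overlap`, `p_value`, `fdr`, `mean_delta`; ranked by
#'   FDR then p. Sets with empty background intersection are skipped with
#'   a message.
#' @export
enrichment <- function(hits, background, gene_sets, deltas = NULL) {
  background <- unique(as.character(background))
  hits <- unique(as.character(hits))
  if (!all(hits %in% background)) {
    stop("hits must be a subset of the background")
  }
  N <- length(background)
  n_hit <- length(hits)
  keep <- vapply(gene_sets, function(s) any(s %in% background), logical(1))
  if (any(!keep)) {
    message(sum(!keep), " gene set(s) skipped: no overlap with background")
  }
  gene_sets <- gene_sets[keep]
  if (!length(gene_sets)) {
    return(data.frame(set = character(), set_size = integer(),
                      n_overlap = integer(), p_value = numeric(),
                      fdr = numeric(), mean_delta = numeric(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], background)
    ov <- intersect(s, hits)
    K <- length(s)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n_hit, lower.tail = FALSE)
    md <- if (!is.null(deltas) && k > 0) {
      mean(deltas[ov], na.rm = TRUE)
    } else NA_real_
    data.frame(set = nm, set_size = K, n_overlap = k, p_value = p,
               mean_delta = md, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$fdr, out$p_value, out$set),
             c("set", "set_size", "n_overlap", "p_value", "fdr", "mean_delta")]
  rownames(out) <- NULL
  out
}
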