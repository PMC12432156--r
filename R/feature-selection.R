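#' Laplacian score of each feature
#'
#' Unsupervised feature informativeness on a k-nearest-neighbor sample graph
#' with heat-kernel weights `w_ij = exp(-||x_i - x_j||^2 / bandwidth)`
#' (symmetrized by taking the max of the two directed kNN claims, no
#' self-loops). With degree matrix `D`, Laplacian `L = D - W`, and the
#' degree-weighted mean removed from each feature
#' `f~ = f - (f' D 1 / 1' D 1) 1`, the score of feature `r` is
#' `(f~' L f~) / (f~' D f~)`. Lower scores mark features that vary smoothly
#' along the sample manifold, i.e. more informative structure.
#'
#' @param X Numeric matrix, samples x features (cleaned and scaled).
#' @param n_neighbors Neighborhood size; default 10, capped at n - 1.
#' @param bandwidth Heat-kernel bandwidth; default: median squared pairwise
#'   distance.
#' @return Named numeric vector of scores (constant features get `Inf`).
#' @export
laplacian_score <- function(X, n_neighbors = 10, bandwidth = NULL) {
  assert_matrix_like(X, "X")
  n <- nrow(X)
  if (n < 3) of_abort("Laplacian score needs at least 3 samples.")
  if (!all(is.finite(X))) of_abort("`X` must be finite.")
  k <- min(n_neighbors, n - 1)
  D2 <- pairwise_sqdist(X)
  if (is.null(bandwidth)) {
    off <- D2[upper.tri(D2)]
    bandwidth <- stats::median(off)
    if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 1
  }
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(D2[i, ])
    nb <- setdiff(ord, i)[seq_len(k)]
    W[i, nb] <- exp(-D2[i, nb] / bandwidth)
  }
  W <- pmax(W, t(W))
  diag(W) <- 0
  deg <- rowSums(W)
  sumdeg <- sum(deg)
  # f~ = f - weighted mean; score = (f~' L f~) / (f~' D f~)
  wmean <- as.numeric(crossprod(X, deg)) / sumdeg
  Ft <- sweep(X, 2, wmean)                    # n x p, mean-removed
  den <- colSums(Ft^2 * deg)                  # f~' D f~
  # f~' L f~ = f~' D f~ - f~' W f~
  num <- den - colSums(Ft * (W %*% Ft))
  scores <- ifelse(den < 1e-12, Inf, num / den)
  names(scores) <- colnames(X)
  scores
}

#' Select features by score with redundancy pruning
#'
#' Keeps the best-scoring `ceiling(top_fraction * p)` features (never fewer
#' than `min_features`), then scans them in score order and drops any feature
#' whose absolute Pearson correlation with an already-kept feature exceeds
#' `redundancy_threshold`. Score ties break lexicographically on feature ID.
#'
#' @param X Samples x features matrix (columns named).
#' @param scores Scores from [laplacian_score()] (lower = better).
#' @param top_fraction Fraction of features to keep before pruning.
#' @param min_features Floor on the selected count (before pruning;
#'   pruning never drops below it either).
#' @param redundancy_threshold Absolute correlation above which the
#'   worse-scoring duplicate is dropped; 1 disables pruning.
#' @return Character vector of selected feature IDs, best first.
#' @export
select_features <- function(X, scores, top_fraction = 0.2, min_features = 20,
                            redundancy_threshold = 0.8) {
  p <- ncol(X)
  if (length(scores) != p) of_abort("`scores` must align with the columns of `X`.")
  ids <- colnames(X) %||% as.character(seq_len(p))
  if (min_features > p) {
    of_warn(sprintf("min_features (%d) exceeds available features (%d); keeping all.",
                    min_features, p))
    min_features <- p
  }
  k <- max(min(ceiling(top_fraction * p), p), min_features)
  ord <- order(scores, ids)
  top <- ord[seq_len(k)]
  if (redundancy_threshold >= 1) return(ids[top])
  kept <- integer()
  for (j in top) {
    if (length(kept) == 0) {
      kept <- j
      next
    }
    cors <- abs(suppressWarnings(stats::cor(X[, j], X[, kept, drop = FALSE])))
    cors[is.na(cors)] <- 0
    if (all(cors <= redundancy_threshold)) kept <- c(kept, j)
  }
  # never prune below the floor: re-add best-scoring dropped features
  if (length(kept) < min(min_features, k)) {
    extra <- setdiff(top, kept)
    kept <- c(kept, extra[seq_len(min(min_features, k) - length(kept))])
  }
  ids[kept]
}

#' Read a feature-interaction edge list
#'
#' Two-column (optionally three; the weight column is ignored) comma- or
#' tab-separated file of feature ID pairs, the user-supplied stand-in for a
#' protein/gene interaction network.
#'
#' @param path File path.
#' @return Two-column character matrix of edges.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) of_abort(sprintf("missing edge list: %s", path))
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 2) of_abort("edge list must have at least two columns.")
  as.matrix(df[, 1:2])
}

#' Restrict features to an interaction graph
#'
#' Drops features absent from the graph's node set and edges with a missing
#' endpoint; used to prepare inputs for the graph-convolutional architecture.
#'
#' @param X Samples x features matrix.
#' @param edge_list Two-column matrix/data frame of feature-ID pairs.
#' @return List with `x` (restricted matrix), `edges` (induced integer edge
#'   matrix, 1-based indices into the retained columns), and
#'   `features` (retained feature IDs).
#' @export
restrict_to_graph <- function(X, edge_list) {
  edge_list <- as.matrix(edge_list)
  if (nrow(edge_list) == 0) of_abort("empty edge list.")
  nodes <- unique(c(edge_list[, 1], edge_list[, 2]))
  feats <- colnames(X) %||% as.character(seq_len(ncol(X)))
  keep <- feats[feats %in% nodes]
  if (length(keep) == 0) of_abort("no overlap between features and the interaction graph.")
  idx <- stats::setNames(seq_along(keep), keep)
  e1 <- idx[edge_list[, 1]]
  e2 <- idx[edge_list[, 2]]
  ok <- !is.na(e1) & !is.na(e2) & e1 != e2
  edges <- unique(cbind(pmin(e1[ok], e2[ok]), pmax(e1[ok], e2[ok])))
  dimnames(edges) <- NULL
  list(x = X[, keep, drop = FALSE], edges = edges, features = keep)
}
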