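# ---- batch alignment ---------------------------------------------------------

#' Reciprocal-PCA mutual-nearest-neighbor batch alignment
#'
#' Fits PCA independently on the reference and moving batches, projects each
#' batch into the other's principal-component space, and declares anchor
#' pairs where two samples are mutual k-nearest neighbors in *both*
#' reciprocal projections. Every moving sample is then corrected by a
#' Gaussian-kernel weighted average of the anchor displacement vectors
#' (bandwidth = median moving-sample-to-anchor distance). The reference batch
#' is never moved.
#'
#' @param emb_ref,emb_mov Embedding matrices (samples x dimensions).
#' @param n_pcs Principal components used for the reciprocal projections
#'   (default 20, capped by the data).
#' @param k_anchors Mutual-neighbor k (default 5).
#' @return An `alignment_result`: `aligned` (corrected moving embeddings),
#'   `anchors` (two-column index matrix: ref, mov), `method`, parameters.
#' @export
rpca_mnn_align <- function(emb_ref, emb_mov, n_pcs = 20, k_anchors = 5) {
  assert_matrix_like(emb_ref, "emb_ref"); assert_matrix_like(emb_mov, "emb_mov")
  n_pcs <- min(n_pcs, ncol(emb_ref), nrow(emb_ref) - 1, nrow(emb_mov) - 1)
  if (n_pcs < 1) of_abort("both batches need at least n_pcs + 1 samples.")
  pr_ref <- stats::prcomp(emb_ref, rank. = n_pcs)
  pr_mov <- stats::prcomp(emb_mov, rank. = n_pcs)
  # each batch is centered on its own mean before projecting onto the other's
  # loadings, so a location shift between batches does not break neighbor search
  proj <- function(X, pr) sweep(X, 2, colMeans(X)) %*% pr$rotation
  mnn_pairs <- function(A, B, k) {
    # mutual kNN between rows of A (ref) and B (mov)
    d <- pairwise_sqdist(A, B)
    k1 <- min(k, ncol(d)); k2 <- min(k, nrow(d))
    nn_ab <- t(apply(d, 1, function(r) order(r)[seq_len(k1)]))
    nn_ba <- t(apply(d, 2, function(r) order(r)[seq_len(k2)]))
    pairs <- list()
    for (i in seq_len(nrow(d))) {
      for (j in nn_ab[i, ]) {
        if (i %in% nn_ba[j, ]) pairs[[length(pairs) + 1]] <- c(i, j)
      }
    }
    if (length(pairs) == 0) return(matrix(integer(), 0, 2))
    do.call(rbind, pairs)
  }
  A1 <- proj(emb_ref, pr_ref); B1 <- proj(emb_mov, pr_ref)
  p1 <- mnn_pairs(A1, B1, k_anchors)
  p2 <- mnn_pairs(proj(emb_ref, pr_mov), proj(emb_mov, pr_mov), k_anchors)
  key1 <- paste(p1[, 1], p1[, 2]); key2 <- paste(p2[, 1], p2[, 2])
  anchors <- p1[key1 %in% key2, , drop = FALSE]
  if (nrow(anchors) == 0) of_abort("no mutual-nearest-neighbor anchors found; increase k_anchors.")
  # refine to mutual-best 1-1 pairs: scan pairs by projection-space distance,
  # keeping a pair only when neither endpoint is already anchored
  pd <- sqrt(rowSums((A1[anchors[, 1], , drop = FALSE] -
                        B1[anchors[, 2], , drop = FALSE])^2))
  ord <- order(pd)
  used_i <- logical(nrow(emb_ref)); used_j <- logical(nrow(emb_mov))
  keep <- logical(nrow(anchors))
  for (r in ord) {
    i <- anchors[r, 1]; j <- anchors[r, 2]
    if (!used_i[i] && !used_j[j]) {
      keep[r] <- TRUE
      used_i[i] <- TRUE; used_j[j] <- TRUE
    }
  }
  anchors <- anchors[keep, , drop = FALSE]
  disp <- emb_ref[anchors[, 1], , drop = FALSE] - emb_mov[anchors[, 2], , drop = FALSE]
  d <- sqrt(pairwise_sqdist(emb_mov, emb_mov[anchors[, 2], , drop = FALSE]))
  h <- stats::median(d)
  if (!is.finite(h) || h <= 0) h <- 1
  w <- exp(-(d / h)^2)
  w <- w / pmax(rowSums(w), 1e-12)
  aligned <- emb_mov + w %*% disp
  structure(list(method = "rpca_mnn", aligned = aligned, anchors = anchors,
                 parameters = list(n_pcs = n_pcs, k_anchors = k_anchors, bandwidth = h)),
            class = "alignment_result")
}

# Exact rectangular assignment is not needed: the exact solver handles the
# equal-size uniform-weight case via the Jonker-Volgenant shortest augmenting
# path algorithm (square cost matrix).
lap_jv <- function(cost) {
  n <- nrow(cost)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)  # p[j+1] = row assigned to column j (0 = none)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, n)
    way <- integer(n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      free <- which(!used[2:(n + 1)])
      cur <- cost[i0, free] - u[i0 + 1] - v[free + 1]
      upd <- cur < minv[free]
      minv[free[upd]] <- cur[upd]
      way[free[upd]] <- j0
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedj <- which(used)
      u[p[usedj] + 1] <- u[p[usedj] + 1] + delta
      v[usedj] <- v[usedj] - delta
      minv[!used[2:(n + 1)]] <- minv[!used[2:(n + 1)]] - delta
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  assign[p[2:(n + 1)]] <- seq_len(n)
  assign  # column index per row
}

logsumexp_rows <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

# Log-domain Sinkhorn iterations for entropic optimal transport.
sinkhorn_log <- function(C, a, b, reg, max_iter = 100000, tol = 1e-7) {
  f <- numeric(length(a)); g <- numeric(length(b))
  loga <- log(a); logb <- log(b)
  for (it in seq_len(max_iter)) {
    Mf <- (sweep(-C, 2, g, "+")) / reg
    f <- reg * (loga - logsumexp_rows(Mf))
    Mg <- (sweep(-C, 1, f, "+")) / reg
    g <- reg * (logb - logsumexp_rows(t(Mg)))
    plan <- exp((outer(f, g, "+") - C) / reg)
    err <- max(abs(rowSums(plan) - a), abs(colSums(plan) - b))
    if (err < tol) return(list(plan = plan, err = err, iterations = it, converged = TRUE))
  }
  list(plan = plan, err = err, iterations = max_iter, converged = FALSE)
}

#' Optimal-transport batch alignment
#'
#' Computes a transport plan between the moving and reference batches under
#' squared-Euclidean cost and maps each moving sample by barycentric
#' projection `T(x_i) = sum_j plan_ij y_j / sum_j plan_ij`. With
#' `regularization = 0` the plan is the exact optimum (equal batch sizes with
#' uniform weights; solved as an assignment problem); with
#' `regularization > 0` entropic (log-domain Sinkhorn) iterations are used
#' and arbitrary weights/sizes are supported.
#'
#' @param emb_ref,emb_mov Embedding matrices (samples x dimensions).
#' @param weights_mov,weights_ref Sample weights summing to 1 (default
#'   uniform).
#' @param regularization Entropic regularization (0 = exact).
#' @return An `alignment_result` with `aligned`, `plan`, marginal error, and
#'   parameters.
#' @export
ot_align <- function(emb_ref, emb_mov, weights_mov = NULL, weights_ref = NULL,
                     regularization = 0) {
  assert_matrix_like(emb_ref, "emb_ref"); assert_matrix_like(emb_mov, "emb_mov")
  n <- nrow(emb_mov); m <- nrow(emb_ref)
  a <- weights_mov %||% rep(1 / n, n)
  b <- weights_ref %||% rep(1 / m, m)
  if (abs(sum(a) - 1) > 1e-8 || abs(sum(b) - 1) > 1e-8) {
    of_abort("weights must sum to 1 on each side.")
  }
  C <- pairwise_sqdist(emb_mov, emb_ref)
  if (regularization == 0) {
    uniform <- max(abs(a - 1 / n)) < 1e-12 && max(abs(b - 1 / m)) < 1e-12
    if (n != m || !uniform) {
      of_abort("the exact solver requires equal batch sizes with uniform weights; set `regularization` > 0.")
    }
    asg <- lap_jv(C)
    plan <- matrix(0, n, m)
    plan[cbind(seq_len(n), asg)] <- 1 / n
    err <- 0; converged <- TRUE; iterations <- NA_integer_
  } else {
    # scale cost for numerical comparability of reg across embedding scales
    sc <- stats::median(C[C > 0])
    if (!is.finite(sc) || sc <= 0) sc <- 1
    res <- sinkhorn_log(C / sc, a, b, regularization)
    if (!res$converged) {
      of_abort(sprintf("entropic iterations did not converge (marginal error %.3g).", res$err))
    }
    plan <- res$plan; err <- res$err; converged <- TRUE; iterations <- res$iterations
  }
  aligned <- (plan %*% emb_ref) / pmax(rowSums(plan), 1e-300)
  structure(list(method = "optimal_transport", aligned = aligned, plan = plan,
                 marginal_error = err,
                 parameters = list(regularization = regularization,
                                   iterations = iterations)),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> method: %s; %d moving samples aligned\n",
              x$method, nrow(x$aligned)))
  invisible(x)
}

# ---- clustering ---------------------------------------------------------------

#' Cluster sample embeddings with silhouette-based model selection
#'
#' Runs k-means over a range of k (or Louvain community detection on a
#' Jaccard-weighted kNN graph over a range of resolutions), scores each
#' candidate by mean silhouette width on the embedding distances, and returns
#' the best.
#'
#' @param emb Embedding matrix (samples x dimensions).
#' @param method `"kmeans"` or `"louvain"`.
#' @param k_range Candidate cluster counts (k-means).
#' @param resolutions Candidate resolutions (Louvain).
#' @param knn Neighborhood size for the Louvain graph (default 15).
#' @param seed Integer seed.
#' @return A `clustering_result`: `labels`, `chosen` (k or resolution),
#'   `candidates` (tibble of silhouettes), `method`.
#' @export
cluster_embeddings <- function(emb, method = c("kmeans", "louvain"),
                               k_range = 2:8, resolutions = c(0.25, 0.5, 1, 2),
                               knn = 15, seed = 1) {
  method <- match.arg(method)
  assert_matrix_like(emb, "emb")
  n <- nrow(emb)
  dd <- stats::dist(emb)
  cands <- list()
  best <- list(sil = -Inf)
  if (method == "kmeans") {
    if (n < max(k_range) + 1) of_abort("need more samples than max(k_range).")
    for (k in k_range) {
      km <- tryCatch(with_seed(derive_seed(seed, k),
                               stats::kmeans(emb, centers = k, nstart = 10, iter.max = 50)),
                     error = function(e) NULL)
      if (is.null(km) || length(unique(km$cluster)) < 2) next
      sil <- mean(cluster::silhouette(km$cluster, dd)[, 3])
      if (!is.finite(sil)) next
      cands[[length(cands) + 1]] <- tibble::tibble(candidate = k, silhouette = sil)
      if (sil > best$sil) best <- list(sil = sil, labels = km$cluster, chosen = k)
    }
  } else {
    g <- knn_jaccard_graph(emb, min(knn, n - 1))
    for (r in resolutions) {
      cl <- tryCatch(with_seed(derive_seed(seed, round(100 * r)),
                               igraph::cluster_louvain(g, resolution = r)),
                     error = function(e) NULL)
      if (is.null(cl)) next
      labs <- igraph::membership(cl)
      if (length(unique(labs)) < 2) next
      sil <- mean(cluster::silhouette(as.integer(labs), dd)[, 3])
      if (!is.finite(sil)) next
      cands[[length(cands) + 1]] <- tibble::tibble(candidate = r, silhouette = sil)
      if (sil > best$sil) best <- list(sil = sil, labels = as.integer(labs), chosen = r)
    }
  }
  if (length(cands) == 0) of_abort("silhouette undefined for every candidate (degenerate embedding).")
  structure(list(method = method, labels = unname(best$labels), chosen = best$chosen,
                 silhouette = best$sil,
                 candidates = dplyr::bind_rows(cands)),
            class = "clustering_result")
}

knn_jaccard_graph <- function(emb, k) {
  d <- pairwise_sqdist(emb)
  diag(d) <- Inf
  n <- nrow(emb)
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) adj[i, nn[i, ]] <- TRUE
  edges <- list(); weights <- numeric()
  for (i in seq_len(n)) {
    for (j in nn[i, ]) {
      if (j > i || !adj[j, i]) {
        inter <- sum(adj[i, ] & adj[j, ])
        uni <- sum(adj[i, ] | adj[j, ])
        edges[[length(edges) + 1]] <- c(i, j)
        weights <- c(weights, inter / uni)
      }
    }
  }
  e <- do.call(rbind, edges)
  igraph::graph_from_edgelist(e, directed = FALSE) |>
    igraph::set_edge_attr("weight", value = pmax(weights, 1e-6))
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> %s: %d clusters (candidate %s, silhouette %.3f)\n",
              x$method, length(unique(x$labels)), format(x$chosen), x$silhouette))
  invisible(x)
}

#' Adjusted mutual information between two labelings
#'
#' Mutual information corrected for chance under the permutation model:
#' `AMI = (MI - E[MI]) / (mean(H_a, H_b) - E[MI])`. 1 for identical
#' partitions (up to relabeling), ~0 for independent ones.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Scalar AMI.
#' @export
adjusted_mutual_information <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) of_abort("label vectors differ in length.")
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  a <- rowSums(tab); b <- colSums(tab)
  mi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      nij <- tab[i, j]
      if (nij > 0) mi <- mi + (nij / n) * log(n * nij / (a[i] * b[j]))
    }
  }
  ha <- -sum((a / n) * log(a / n))
  hb <- -sum((b / n) * log(b / n))
  # expected MI under the permutation (hypergeometric) model
  emi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      lo <- max(1, a[i] + b[j] - n)
      hi <- min(a[i], b[j])
      if (hi < lo) next
      nij <- lo:hi
      lp <- lgamma(a[i] + 1) - lgamma(nij + 1) - lgamma(a[i] - nij + 1) +
        lgamma(n - a[i] + 1) - lgamma(b[j] - nij + 1) - lgamma(n - a[i] - b[j] + nij + 1) -
        (lgamma(n + 1) - lgamma(b[j] + 1) - lgamma(n - b[j] + 1))
      emi <- emi + sum(exp(lp) * (nij / n) * log(n * nij / (a[i] * b[j])))
    }
  }
  denom <- (ha + hb) / 2 - emi
  if (abs(denom) < 1e-12) return(if (abs(mi - emi) < 1e-12) 1 else 0)
  unname((mi - emi) / denom)
}
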