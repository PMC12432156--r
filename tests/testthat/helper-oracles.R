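# Independent brute-force oracles used across test files. These deliberately
# re-derive each quantity with naive loops / explicit enumeration so they
# share no code with the package implementations they check.

oracle_cox <- function(risk, time, event) {
  ev <- which(event == 1)
  if (length(ev) == 0) return(0)
  total <- 0
  for (i in ev) {
    rs <- which(time >= time[i])
    total <- total + (risk[i] - log(sum(exp(risk[rs]))))
  }
  -total / length(ev)
}

oracle_mmd <- function(z, p, bw) {
  kmean <- function(a, b) {
    s <- 0
    for (i in seq_len(nrow(a))) {
      for (j in seq_len(nrow(b))) {
        s <- s + exp(-sum((a[i, ] - b[j, ])^2) / bw)
      }
    }
    s / (nrow(a) * nrow(b))
  }
  kmean(z, z) + kmean(p, p) - 2 * kmean(z, p)
}

oracle_triplet <- function(a, p, n, margin) {
  vals <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    dp <- sqrt(sum((a[i, ] - p[i, ])^2))
    dn <- sqrt(sum((a[i, ] - n[i, ])^2))
    vals[i] <- max(0, dp - dn + margin)
  }
  mean(vals)
}

oracle_cindex <- function(risk, time, event) {
  num <- 0; den <- 0
  n <- length(risk)
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    for (j in seq_len(n)) {
      if (time[j] > time[i]) {
        den <- den + 1
        if (risk[i] > risk[j]) num <- num + 1
        else if (risk[i] == risk[j]) num <- num + 0.5
      }
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

oracle_confusion_metrics <- function(truth, pred, levels) {
  K <- length(levels)
  cm <- matrix(0, K, K, dimnames = list(levels, levels))
  for (i in seq_along(truth)) cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1
  n <- sum(cm)
  recalls <- diag(cm) / rowSums(cm)
  prec <- diag(cm) / colSums(cm)
  prec[is.nan(prec)] <- 0
  f1 <- ifelse(prec + recalls > 0, 2 * prec * recalls / (prec + recalls), 0)
  support <- rowSums(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  present <- support > 0
  list(
    balanced_accuracy = mean(recalls[present]),
    f1_weighted = sum((f1 * support)[present]) / n,
    kappa = (po - pe) / (1 - pe)
  )
}

# Laplacian score computed with explicit dense graph matrices.
oracle_laplacian <- function(X, k, bandwidth) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(D2[i, ])
    nb <- setdiff(ord, i)[seq_len(min(k, n - 1))]
    W[i, nb] <- exp(-D2[i, nb] / bandwidth)
  }
  W <- pmax(W, t(W))  # symmetrize: edge if either endpoint claims it
  diag(W) <- 0
  Dm <- diag(rowSums(W))
  L <- Dm - W
  one <- rep(1, n)
  scores <- numeric(ncol(X))
  for (r in seq_len(ncol(X))) {
    f <- X[, r]
    ft <- f - as.numeric((t(f) %*% Dm %*% one) / (t(one) %*% Dm %*% one)) * one
    den <- as.numeric(t(ft) %*% Dm %*% ft)
    scores[r] <- if (den < 1e-12) Inf else as.numeric(t(ft) %*% L %*% ft) / den
  }
  scores
}

# Multinomial logistic oracle used to probe planted categorical signal.
# Returns a closure mapping a matrix of inputs to predicted class labels.
nnet_multinom_safe <- function(X, f) {
  df <- data.frame(.y = f, X = I(X))
  fit <- nnet::multinom(.y ~ X, data = df, trace = FALSE)
  function(newdata) as.character(predict(fit, newdata = data.frame(X = I(newdata))))
}

# Laplacian score of a single replacement feature vector under the sample
# graph built from X (graph fixed, feature varied).
oracle_laplacian_fixed_graph <- function(X, f, k, bandwidth) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(D2[i, ])
    nb <- setdiff(ord, i)[seq_len(min(k, n - 1))]
    W[i, nb] <- exp(-D2[i, nb] / bandwidth)
  }
  W <- pmax(W, t(W)); diag(W) <- 0
  Dm <- diag(rowSums(W)); L <- Dm - W; one <- rep(1, n)
  ft <- f - as.numeric((t(f) %*% Dm %*% one) / (t(one) %*% Dm %*% one)) * one
  as.numeric(t(ft) %*% L %*% ft) / as.numeric(t(ft) %*% Dm %*% ft)
}
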