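#' Loss functions for multi-task training
#'
#' The framework trains every supervisor head against a task-appropriate
#' loss and tolerates missing labels by masking: a sample whose label for a
#' given task is missing contributes nothing to that task's loss value or
#' gradient. All losses here return a `task_loss` object carrying the value
#' and the number of observed (unmasked) samples that produced it.
#'
#' @name losses
NULL

task_loss <- function(value, n_observed, task_name = NA_character_) {
  structure(
    list(task_name = task_name, value = value, n_observed = n_observed),
    class = "task_loss"
  )
}

#' @export
print.task_loss <- function(x, ...) {
  cat(sprintf("<task_loss> %s: %.6g (n = %d)\n",
              x$task_name %||% "?", x$value, x$n_observed))
  invisible(x)
}

resolve_mask <- function(mask, n, extra_na = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, n)
  mask <- as.logical(mask)
  if (length(mask) != n) of_abort("`mask` length must match the number of samples.")
  mask[is.na(mask)] <- FALSE
  if (!is.null(extra_na)) mask <- mask & !extra_na
  mask
}

#' Masked mean-squared-error loss
#'
#' Mean of squared prediction errors over unmasked samples; the loss used for
#' continuous (regression) target variables.
#'
#' @param pred Numeric vector of predictions.
#' @param target Numeric vector of true values (may contain `NA`).
#' @param mask Logical vector; `FALSE` entries are excluded. `NA` targets are
#'   always excluded. Default: all observed.
#' @param task_name Optional label carried into the result.
#' @return A `task_loss` with fields `value` and `n_observed`. With no
#'   observed samples the value is 0 and `n_observed` is 0.
#' @export
masked_mse <- function(pred, target, mask = NULL, task_name = "regression") {
  if (length(pred) != length(target)) of_abort("`pred` and `target` lengths differ.")
  m <- resolve_mask(mask, length(pred), extra_na = is.na(target))
  n <- sum(m)
  if (n == 0) return(task_loss(0, 0L, task_name))
  task_loss(mean((pred[m] - target[m])^2), as.integer(n), task_name)
}

# Gradient of masked_mse w.r.t. pred (same length as pred).
masked_mse_grad <- function(pred, target, mask = NULL) {
  m <- resolve_mask(mask, length(pred), extra_na = is.na(target))
  g <- numeric(length(pred))
  n <- sum(m)
  if (n > 0) g[m] <- 2 * (pred[m] - target[m]) / n
  g
}

log_softmax <- function(logits) {
  mx <- apply(logits, 1, max)
  z <- logits - mx
  z - log(rowSums(exp(z)))
}

softmax <- function(logits) {
  mx <- apply(logits, 1, max)
  e <- exp(logits - mx)
  e / rowSums(e)
}

#' Masked cross-entropy loss
#'
#' Mean negative log-softmax of the true class over unmasked samples; the
#' loss used for categorical target variables.
#'
#' @param logits Numeric matrix, samples x classes (unnormalized scores).
#' @param class_codes Integer vector of true class codes in `0..K-1`
#'   (`NA` allowed; masked out).
#' @param mask Logical vector as in [masked_mse()].
#' @param task_name Optional label.
#' @return A `task_loss`.
#' @export
masked_cross_entropy <- function(logits, class_codes, mask = NULL,
                                 task_name = "classification") {
  assert_matrix_like(logits, "logits")
  n <- nrow(logits)
  if (length(class_codes) != n) of_abort("`class_codes` length must match rows of `logits`.")
  m <- resolve_mask(mask, n, extra_na = is.na(class_codes))
  if (sum(m) == 0) return(task_loss(0, 0L, task_name))
  codes <- class_codes[m]
  if (any(codes < 0 | codes >= ncol(logits))) {
    of_abort("class code out of range for an unmasked sample.")
  }
  ls <- log_softmax(logits[m, , drop = FALSE])
  picked <- ls[cbind(seq_len(sum(m)), codes + 1L)]
  task_loss(-mean(picked), as.integer(sum(m)), task_name)
}

# Gradient w.r.t. logits: (softmax - onehot) / n_obs on unmasked rows.
masked_cross_entropy_grad <- function(logits, class_codes, mask = NULL) {
  n <- nrow(logits)
  m <- resolve_mask(mask, n, extra_na = is.na(class_codes))
  g <- matrix(0, n, ncol(logits))
  nobs <- sum(m)
  if (nobs == 0) return(g)
  p <- softmax(logits[m, , drop = FALSE])
  idx <- cbind(seq_len(nobs), class_codes[m] + 1L)
  p[idx] <- p[idx] - 1
  g[m, ] <- p / nobs
  g
}

#' Cox proportional-hazards loss
#'
#' Negative Breslow partial log-likelihood averaged over events, the loss
#' attached to a survival head. The risk set for an event at time t contains
#' every unmasked sample with follow-up time >= t (the event's own sample
#' included). Higher risk scores mean earlier expected events.
#'
#' @param risk Numeric vector of model risk scores (log relative hazards).
#' @param time Non-negative follow-up times.
#' @param event 0/1 event indicators (1 = event observed).
#' @param mask Logical vector; samples with missing time or event are masked.
#' @param task_name Optional label.
#' @return A `task_loss`; zero unmasked events gives value 0, `n_observed` 0,
#'   with a warning.
#' @export
cox_ph_loss <- function(risk, time, event, mask = NULL, task_name = "survival") {
  n <- length(risk)
  if (length(time) != n || length(event) != n) of_abort("survival inputs differ in length.")
  m <- resolve_mask(mask, n, extra_na = is.na(time) | is.na(event))
  if (any(time[m] < 0)) of_abort("negative follow-up time.")
  if (any(!event[m] %in% c(0, 1))) of_abort("event indicators must be 0 or 1.")
  r <- risk[m]; t <- time[m]; e <- event[m]
  n_events <- sum(e == 1)
  if (n_events == 0) {
    of_warn("Cox loss: no unmasked events; loss is 0.")
    return(task_loss(0, 0L, task_name))
  }
  # log of the risk-set sum for each event, computed stably
  ll <- 0
  for (i in which(e == 1)) {
    rs <- r[t >= t[i]]
    mx <- max(rs)
    ll <- ll + r[i] - (mx + log(sum(exp(rs - mx))))
  }
  task_loss(-ll / n_events, as.integer(n_events), task_name)
}

# Gradient of cox_ph_loss w.r.t. risk. Standard Breslow score contribution.
cox_ph_loss_grad <- function(risk, time, event, mask = NULL) {
  n <- length(risk)
  m <- resolve_mask(mask, n, extra_na = is.na(time) | is.na(event))
  g <- numeric(n)
  idx <- which(m)
  r <- risk[idx]; t <- time[idx]; e <- event[idx]
  ev <- which(e == 1)
  if (length(ev) == 0) return(g)
  gr <- numeric(length(idx))
  er <- exp(r - max(r))
  for (i in ev) {
    at_risk <- t >= t[i]
    S <- sum(er[at_risk])
    gr[i] <- gr[i] - 1
    gr[at_risk] <- gr[at_risk] + er[at_risk] / S
  }
  g[idx] <- gr / length(ev)
  g
}

gaussian_kernel_mean <- function(a, b, bandwidth) {
  mean(exp(-pairwise_sqdist(a, b) / bandwidth))
}

#' Maximum mean discrepancy between a latent batch and a normal prior
#'
#' Biased V-statistic estimate of squared MMD between the rows of
#' `latent_batch` and draws from a standard multivariate normal, under the
#' Gaussian kernel `k(a, b) = exp(-||a - b||^2 / bandwidth)`. Used by the
#' variational architectures to pull sample embeddings toward an isotropic
#' Gaussian.
#'
#' @param latent_batch Numeric matrix, samples x latent dimensions.
#' @param n_prior_samples Number of prior draws; defaults to the batch size.
#' @param bandwidth Positive kernel bandwidth; defaults to `2 * latent_dim`.
#' @param seed Optional seed controlling the prior draws.
#' @param prior Optional pre-drawn prior matrix (overrides `n_prior_samples`).
#' @return Non-negative scalar MMD^2 estimate.
#' @export
mmd_loss <- function(latent_batch, n_prior_samples = nrow(latent_batch),
                     bandwidth = 2 * ncol(latent_batch), seed = NULL,
                     prior = NULL) {
  assert_matrix_like(latent_batch, "latent_batch")
  if (nrow(latent_batch) == 0) of_abort("empty latent batch.")
  if (!is.numeric(bandwidth) || bandwidth <= 0) of_abort("`bandwidth` must be > 0.")
  d <- ncol(latent_batch)
  if (is.null(prior)) {
    prior <- with_seed(seed, matrix(stats::rnorm(n_prior_samples * d), n_prior_samples, d))
  }
  kzz <- gaussian_kernel_mean(latent_batch, latent_batch, bandwidth)
  kpp <- gaussian_kernel_mean(prior, prior, bandwidth)
  kzp <- gaussian_kernel_mean(latent_batch, prior, bandwidth)
  kzz + kpp - 2 * kzp
}

# Gradient of mmd_loss w.r.t. latent_batch given a fixed prior matrix.
mmd_loss_grad <- function(latent_batch, prior, bandwidth) {
  n <- nrow(latent_batch); m <- nrow(prior)
  kzz <- exp(-pairwise_sqdist(latent_batch, latent_batch) / bandwidth)
  kzp <- exp(-pairwise_sqdist(latent_batch, prior) / bandwidth)
  # d/dz_i of mean kzz: (2/n^2) * sum_j k(z_i,z_j) * (-2 (z_i - z_j) / bw)
  rz <- rowSums(kzz)
  gz <- (rz * latent_batch - kzz %*% latent_batch) * (-4 / (bandwidth * n^2))
  rp <- rowSums(kzp)
  gp <- (rp * latent_batch - kzp %*% prior) * (-2 / (bandwidth * n * m))
  gz - 2 * gp
}

#' Triplet margin loss
#'
#' Mean over triplets of `max(0, ||a - p|| - ||a - n|| + margin)`, pulling
#' same-class embeddings (`positive`) toward each anchor and pushing
#' different-class embeddings (`negative`) away by at least `margin`.
#'
#' @param anchor,positive,negative Numeric matrices with one row per triplet
#'   and identical dimensions.
#' @param margin Non-negative margin; default 1.
#' @return Scalar loss.
#' @export
triplet_loss <- function(anchor, positive, negative, margin = 1) {
  assert_matrix_like(anchor, "anchor")
  if (!all(dim(anchor) == dim(positive)) || !all(dim(anchor) == dim(negative))) {
    of_abort("triplet inputs must share dimensions.")
  }
  dp <- sqrt(rowSums((anchor - positive)^2))
  dn <- sqrt(rowSums((anchor - negative)^2))
  mean(pmax(0, dp - dn + margin))
}

# Gradients of triplet loss w.r.t. anchor, positive, negative.
triplet_loss_grad <- function(anchor, positive, negative, margin = 1) {
  dp <- sqrt(rowSums((anchor - positive)^2))
  dn <- sqrt(rowSums((anchor - negative)^2))
  active <- (dp - dn + margin) > 0
  n <- nrow(anchor)
  eps <- 1e-12
  up <- (anchor - positive) / (dp + eps)   # d dp / d anchor
  un <- (anchor - negative) / (dn + eps)   # d dn / d anchor
  w <- as.numeric(active) / n
  list(
    anchor = w * (up - un),
    positive = -w * up,
    negative = w * un
  )
}

#' Combine per-task losses, optionally with uncertainty weighting
#'
#' With weighting disabled the total loss is the plain sum of the terms.
#' With weighting enabled each term is scaled by a trainable log-variance
#' parameter `s_t`: `total = sum_t exp(-s_t) * L_t + s_t`, which lets the
#' optimizer down-weight noisy tasks (the stationary point of `s_t` is
#' `log L_t`).
#'
#' @param task_losses Named list of `task_loss` objects or numeric values.
#' @param aux_losses Optional named list of auxiliary terms (reconstruction,
#'   MMD) treated as additional tasks.
#' @param log_vars Named numeric vector of `s_t` parameters, one per term
#'   (names matching), used only when `enabled = TRUE`. Missing names
#'   default to 0.
#' @param enabled Logical; apply uncertainty weighting?
#' @return Scalar total loss.
#' @export
combine_losses <- function(task_losses, aux_losses = list(), log_vars = NULL,
                           enabled = FALSE) {
  terms <- c(task_losses, aux_losses)
  if (length(terms) == 0) of_abort("no loss terms to combine.")
  vals <- vapply(terms, function(t) if (inherits(t, "task_loss")) t$value else as.numeric(t), 0)
  if (!enabled) return(sum(vals))
  s <- stats::setNames(rep(0, length(vals)), names(vals))
  if (!is.null(log_vars)) {
    common <- intersect(names(s), names(log_vars))
    s[common] <- log_vars[common]
  }
  sum(exp(-s) * vals + s)
}
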