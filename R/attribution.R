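#' Integrated gradients feature attribution
#'
#' For model output `F` (the class logit for classification targets, the
#' predicted value for regression, the risk score for survival), the
#' attribution of feature i at input x with baseline b is
#' `(x_i - b_i) * mean_k dF/dx_i evaluated at b + (k/steps)(x - b)` for
#' `k = 1..steps` (a right-Riemann approximation of the path integral).
#' Exact for linear models at any step count, and satisfying the completeness
#' axiom `sum_i IG_i = F(x) - F(b)` as `steps` grows.
#'
#' @param model A trained `of_model`.
#' @param inputs Named list of samples x features matrices (harmonized scale).
#' @param target Target name.
#' @param class_idx 0-based class index (classification targets only).
#' @param baseline Named list of baseline matrices, a single numeric constant
#'   (default 0 — the training mean in the scaled feature space), or `NULL`.
#' @param steps Number of path steps (>= 8; default 64). Ignored when
#'   `exact = TRUE`.
#' @param exact Compute the path integral exactly instead of by Riemann sum.
#'   In evaluation mode every architecture here is piecewise linear along the
#'   straight path (ReLU networks attributed at a logit/score output), so the
#'   gradient is piecewise constant in the path parameter; the exact
#'   integrator locates each ReLU crossing stage by stage and sums
#'   segment-midpoint gradients weighted by segment length, making the
#'   completeness identity hold to machine precision.
#' @return Named list (per modality) of samples x features attribution
#'   matrices.
#' @export
integrated_gradients <- function(model, inputs, target, class_idx = NULL,
                                 baseline = 0, steps = 64, exact = FALSE) {
  if (!exact && steps < 8) of_abort("`steps` must be >= 8.")
  mods <- model$modalities
  base <- resolve_baseline(baseline, inputs, mods)
  if (exact) {
    return(integrated_gradients_exact(model, inputs, base, target, class_idx))
  }
  acc <- lapply(mods, function(m) inputs[[m]] * 0)
  names(acc) <- mods
  for (k in seq_len(steps)) {
    xk <- lapply(mods, function(m) base[[m]] + (k / steps) * (inputs[[m]] - base[[m]]))
    names(xk) <- mods
    g <- model_output_grad(model, xk, target, class_idx)
    for (m in mods) acc[[m]] <- acc[[m]] + g$dX[[m]]
  }
  out <- lapply(mods, function(m) (inputs[[m]] - base[[m]]) * acc[[m]] / steps)
  names(out) <- mods
  out
}

# All ReLU pre-activation values of a forward pass, grouped into stages in
# network topological order. Within a path segment on which every earlier
# stage keeps its activation pattern, the next stage's pre-activations are
# linear in the path parameter.
relu_stages <- function(model, fw) {
  stages <- list()
  cc <- fw$caches
  if (model$spec$architecture == "GNN") {
    for (l in seq_along(cc$gnn$conv)) {
      stages[[length(stages) + 1]] <- as.numeric(cc$gnn$conv[[l]]$P)
    }
  } else {
    encs <- if (model$spec$fusion == "early") list(cc$enc$fused) else cc$enc
    depth <- max(vapply(encs, function(e) length(e$Z), 0L)) - 1L
    for (l in seq_len(depth)) {
      stages[[length(stages) + 1]] <-
        unlist(lapply(encs, function(e) as.numeric(e$Z[[l]])))
    }
  }
  for (t in names(cc$heads)) {
    hz <- cc$heads[[t]]$Z
    for (l in seq_len(length(hz) - 1L)) {
      stages[[length(stages) + 1]] <- as.numeric(hz[[l]])
    }
  }
  stages
}

integrated_gradients_exact <- function(model, inputs, base, target, class_idx) {
  mods <- model$modalities
  n <- nrow(inputs[[mods[1]]])
  out <- lapply(mods, function(m) inputs[[m]] * 0)
  names(out) <- mods
  for (s in seq_len(n)) {
    xs <- lapply(mods, function(m) inputs[[m]][s, , drop = FALSE])
    bs <- lapply(mods, function(m) base[[m]][s, , drop = FALSE])
    names(xs) <- mods; names(bs) <- mods
    at <- function(t) {
      xt <- lapply(mods, function(m) bs[[m]] + t * (xs[[m]] - bs[[m]]))
      names(xt) <- mods
      xt
    }
    pre_at <- function(t) relu_stages(model, model_forward(model, at(t), train = FALSE))
    bounds <- c(0, 1)
    n_stages <- length(pre_at(0))
    for (st in seq_len(n_stages)) {
      vals <- lapply(bounds, function(t) pre_at(t)[[st]])
      new_b <- bounds
      for (k in seq_len(length(bounds) - 1)) {
        za <- vals[[k]]; zb <- vals[[k + 1]]
        cross <- which(za * zb < 0)
        if (length(cross)) {
          tt <- bounds[k] + (bounds[k + 1] - bounds[k]) * za[cross] / (za[cross] - zb[cross])
          new_b <- c(new_b, tt)
        }
      }
      bounds <- sort(unique(pmin(pmax(new_b, 0), 1)))
    }
    mids <- (bounds[-1] + bounds[-length(bounds)]) / 2
    lens <- diff(bounds)
    for (k in seq_along(mids)) {
      g <- model_output_grad(model, at(mids[k]), target, class_idx)
      for (m in mods) {
        out[[m]][s, ] <- out[[m]][s, ] + g$dX[[m]][1, ] * lens[k]
      }
    }
    for (m in mods) out[[m]][s, ] <- out[[m]][s, ] * (xs[[m]][1, ] - bs[[m]][1, ])
  }
  out
}

resolve_baseline <- function(baseline, inputs, mods) {
  if (is.null(baseline)) baseline <- 0
  if (is.numeric(baseline) && length(baseline) == 1) {
    b <- lapply(mods, function(m) inputs[[m]] * 0 + baseline)
    names(b) <- mods
    return(b)
  }
  baseline[mods]
}

#' GradientSHAP feature attribution
#'
#' Monte-Carlo estimate of the expected gradient along random interpolation
#' points: for each of `n_samples` draws, pick a baseline row `b`, a uniform
#' interpolation coefficient `u`, add Gaussian noise `sd = noise_sd`, and
#' accumulate `(x - b) * dF/dx` at the perturbed point. For a linear model
#' with zero noise this expectation equals the integrated-gradients value.
#'
#' @param model A trained `of_model`.
#' @param inputs Named list of samples x features matrices.
#' @param target Target name.
#' @param class_idx 0-based class index (classification only).
#' @param baseline_samples Named list of baseline matrices (>= 1 row each), or
#'   a single constant (default 0).
#' @param n_samples Monte-Carlo draws (default 32).
#' @param noise_sd Gaussian smoothing noise (default 0.1; must be >= 0).
#' @param seed Integer seed (draws are reproducible).
#' @return Named list (per modality) of attribution matrices.
#' @export
gradient_shap <- function(model, inputs, target, class_idx = NULL,
                          baseline_samples = 0, n_samples = 32, noise_sd = 0.1,
                          seed = 1) {
  if (noise_sd < 0) of_abort("`noise_sd` must be >= 0.")
  mods <- model$modalities
  bl <- if (is.numeric(baseline_samples) && length(baseline_samples) == 1) {
    b <- lapply(mods, function(m) inputs[[m]][1, , drop = FALSE] * 0 + baseline_samples)
    names(b) <- mods
    b
  } else {
    baseline_samples[mods]
  }
  nb <- nrow(bl[[1]])
  n <- nrow(inputs[[mods[1]]])
  acc <- lapply(mods, function(m) inputs[[m]] * 0)
  names(acc) <- mods
  with_seed(seed, {
    for (s in seq_len(n_samples)) {
      u <- stats::runif(n)
      bi <- sample.int(nb, n, replace = TRUE)
      xk <- list(); diffs <- list()
      for (m in mods) {
        B <- bl[[m]][bi, , drop = FALSE]
        X <- inputs[[m]]
        P <- u * X + (1 - u) * B
        if (noise_sd > 0) P <- P + matrix(stats::rnorm(length(P), sd = noise_sd),
                                          nrow(P), ncol(P))
        xk[[m]] <- P
        diffs[[m]] <- X - B
      }
      g <- model_output_grad(model, xk, target, class_idx)
      for (m in mods) acc[[m]] <- acc[[m]] + diffs[[m]] * g$dX[[m]]
    }
  })
  out <- lapply(mods, function(m) acc[[m]] / n_samples)
  names(out) <- mods
  out
}

#' Rank features by mean absolute attribution
#'
#' Aggregates per-sample attributions into a marker table: per feature, the
#' mean absolute attribution across samples, and a relative importance scaled
#' so the best marker has value 1.
#'
#' @param attributions Named list (per modality) of samples x features
#'   attribution matrices, as returned by [integrated_gradients()] or
#'   [gradient_shap()].
#' @param target Target name recorded in the table.
#' @param class_label Optional class label recorded in the table.
#' @param top_n Rows to keep (default 10; `Inf` for all).
#' @return A tibble (`attribution_table`) with columns `target`, `class`,
#'   `modality`, `feature`, `raw_importance`, `relative_importance`, sorted
#'   descending.
#' @export
rank_markers <- function(attributions, target = NA_character_,
                         class_label = NA_character_, top_n = 10) {
  rows <- list()
  for (m in names(attributions)) {
    A <- attributions[[m]]
    raw <- colMeans(abs(A))
    rows[[m]] <- tibble::tibble(modality = m,
                                feature = colnames(A) %||% as.character(seq_along(raw)),
                                raw_importance = unname(raw))
  }
  tab <- dplyr::bind_rows(rows)
  mx <- max(tab$raw_importance)
  if (mx <= 0) {
    of_warn("all attributions are zero; empty marker table.")
    return(tibble::tibble(target = character(), class = character(),
                          modality = character(), feature = character(),
                          raw_importance = numeric(), relative_importance = numeric()))
  }
  tab <- tab |>
    dplyr::mutate(target = target, class = class_label,
                  relative_importance = raw_importance / mx, .before = 1) |>
    dplyr::arrange(dplyr::desc(relative_importance)) |>
    dplyr::relocate(target, class, modality, feature, raw_importance, relative_importance)
  utils::head(tab, top_n)
}

#' Marker tables for every target (and class) of a model
#'
#' Convenience wrapper running [integrated_gradients()] (or
#' [gradient_shap()]) on the test split for each target — and each class of
#' each categorical target — and stacking the ranked marker tables.
#'
#' @param model A trained `of_model`.
#' @param bundle A `harmonized_bundle`.
#' @param method `"integrated_gradients"` or `"gradient_shap"`.
#' @param top_n Markers per (target, class).
#' @param steps,n_samples,noise_sd,seed Passed through to the method.
#' @return A tibble of ranked markers.
#' @export
compute_markers <- function(model, bundle,
                            method = c("integrated_gradients", "gradient_shap"),
                            top_n = 10, steps = 64, n_samples = 32,
                            noise_sd = 0.1, seed = 1) {
  method <- match.arg(method)
  x <- bundle$x_test %||% bundle$x_train
  out <- list()
  for (t in names(model$targets_info)) {
    kind <- model$targets_info[[t]]$kind
    class_set <- if (kind == "classification") {
      seq_len(model$targets_info[[t]]$n_classes) - 1L
    } else {
      NA_integer_
    }
    for (ci in class_set) {
      attr <- if (method == "integrated_gradients") {
        integrated_gradients(model, x, t, class_idx = if (is.na(ci)) NULL else ci,
                             steps = steps)
      } else {
        gradient_shap(model, x, t, class_idx = if (is.na(ci)) NULL else ci,
                      n_samples = n_samples, noise_sd = noise_sd, seed = seed)
      }
      lbl <- if (is.na(ci)) NA_character_ else names(sort(model$code_maps[[t]]))[ci + 1L]
      out[[length(out) + 1]] <- rank_markers(attr, t, lbl, top_n)
    }
  }
  dplyr::bind_rows(out)
}
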