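#' Training policy
#'
#' @param val_fraction Fraction of training samples held out for validation
#'   (default 0.2, the standard 80/20 split). Mutually exclusive with
#'   `k_folds`.
#' @param k_folds Optional fold count for k-fold cross-validation.
#' @param early_stop_patience Stop when the validation loss has not improved
#'   for this many epochs (default 10).
#' @param hpo_iterations Iterations for [hpo_search()] when run through the
#'   pipeline.
#' @param seed Integer seed governing splits, initialization, batching.
#' @return A `training_policy` object.
#' @export
training_policy <- function(val_fraction = 0.2, k_folds = NULL,
                            early_stop_patience = 10, hpo_iterations = 10,
                            seed = 1) {
  if (is.null(k_folds)) {
    if (!(is.numeric(val_fraction) && val_fraction > 0 && val_fraction < 1)) {
      of_abort("`val_fraction` must be in (0, 1).")
    }
  } else if (!is_count(k_folds) || k_folds < 2) {
    of_abort("`k_folds` must be >= 2.")
  }
  structure(list(val_fraction = val_fraction, k_folds = k_folds,
                 early_stop_patience = early_stop_patience,
                 hpo_iterations = hpo_iterations, seed = seed),
            class = "training_policy")
}

stratum_labels <- function(bundle, idx = NULL) {
  cls <- names(bundle$y_train)[vapply(bundle$y_train,
                                      function(l) l$kind == "classification", TRUE)]
  if (length(cls) == 0) return(NULL)
  y <- bundle$y_train[[cls[1]]]$y
  if (!is.null(idx)) y <- y[idx]
  y
}

#' Split training samples into train/validation sets or k folds
#'
#' Disjoint, exhaustive, seed-reproducible; stratified on the first
#' classification target when every class has at least 2 samples (otherwise
#' falls back to an unstratified split with a warning).
#'
#' @param bundle A `harmonized_bundle`.
#' @param policy A [training_policy()].
#' @return With `val_fraction`: list with `train_idx`, `val_idx`. With
#'   `k_folds`: list of integer fold index vectors.
#' @export
split_train_val <- function(bundle, policy = training_policy()) {
  n <- nrow(bundle$x_train[[1]])
  strata <- stratum_labels(bundle)
  with_seed(policy$seed, {
    groups <- if (!is.null(strata) && !anyNA(strata) &&
                  all(table(strata) >= max(2, policy$k_folds %||% 2))) {
      split(seq_len(n), strata)
    } else {
      if (!is.null(strata) && any(table(strata) < 2)) {
        of_warn("a class has fewer than 2 samples; falling back to unstratified split.")
      }
      list(seq_len(n))
    }
    if (is.null(policy$k_folds)) {
      val <- integer()
      for (g in groups) {
        k <- round(length(g) * policy$val_fraction)
        if (length(g) > 1 && k >= 1) val <- c(val, sample(g, k))
      }
      # guarantee a non-empty validation set
      if (length(val) == 0) val <- sample(n, max(1, round(n * policy$val_fraction)))
      list(train_idx = sort(setdiff(seq_len(n), val)), val_idx = sort(val))
    } else {
      folds <- vector("list", policy$k_folds)
      offset <- 0L
      for (g in groups) {
        g <- sample(g)
        # continue the round-robin across strata so overall fold sizes
        # differ by at most one
        fold_of <- ((seq_along(g) - 1L + offset) %% policy$k_folds) + 1L
        offset <- offset + length(g)
        for (f in seq_len(policy$k_folds)) {
          folds[[f]] <- c(folds[[f]], g[fold_of == f])
        }
      }
      lapply(folds, sort)
    }
  })
}

# Core gradient-descent loop shared by train_once and finetune. Returns the
# updated model plus a history tibble.
run_training_loop <- function(model, x_tr, y_tr, x_val, y_val, lr, batch_size,
                              max_epochs, patience, seed, freeze = character()) {
  n <- nrow(x_tr[[1]])
  state <- adam_init(model$theta)
  best <- list(loss = Inf, theta = model$theta, epoch = 0L)
  hist <- list()
  with_seed(seed, {
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      nb <- max(1, ceiling(n / batch_size))
      tr_loss <- 0
      for (b in seq_len(nb)) {
        idx <- ord[(((b - 1) * batch_size) + 1):min(b * batch_size, n)]
        xb <- lapply(x_tr, function(m) m[idx, , drop = FALSE])
        yb <- lapply(y_tr, function(l) {
          o <- l
          for (f in intersect(names(l), c("y", "time", "event", "mask"))) o[[f]] <- l[[f]][idx]
          o
        })
        lg <- model_loss_grads(model, xb, yb, train = TRUE)
        if (!is.finite(lg$total)) {
          bad <- names(lg$parts)[!is.finite(lg$parts)]
          of_abort(sprintf("non-finite training loss at epoch %d (term: %s).",
                           epoch, paste(bad, collapse = ", ")))
        }
        st <- adam_step(model$theta, lg$grads, state, lr, freeze = freeze)
        model$theta <- st$theta
        state <- st$state
        tr_loss <- tr_loss + lg$total * length(idx)
      }
      tr_loss <- tr_loss / n
      vl <- model_loss_grads(model, x_val, y_val, train = FALSE, compute_grads = FALSE)
      if (!is.finite(vl$total)) {
        bad <- names(vl$parts)[!is.finite(vl$parts)]
        of_abort(sprintf("non-finite validation loss at epoch %d (term: %s).",
                         epoch, paste(bad, collapse = ", ")))
      }
      hist[[epoch]] <- c(epoch = epoch, train_loss = tr_loss, val_loss = vl$total)
      if (vl$total < best$loss - 1e-9) {
        best <- list(loss = vl$total, theta = model$theta, epoch = epoch)
      } else if (epoch - best$epoch >= patience) {
        break
      }
    }
  })
  model$theta <- best$theta
  h <- tibble::as_tibble(do.call(rbind, hist))
  model$history <- h
  model$best_val_loss <- best$loss
  model
}

#' Train one model on a harmonized bundle
#'
#' Splits the training data (80/20 by default), optimizes all parameters with
#' Adam against the summed (or uncertainty-weighted) task losses, stops early
#' when the total validation loss stops improving, and restores the
#' best-validation parameters.
#'
#' @param spec A [model_spec()].
#' @param bundle A `harmonized_bundle`.
#' @param policy A [training_policy()].
#' @param edges GNN only: integer edge matrix (see [build_model()]).
#' @return A trained `of_model` with a `history` tibble (per-epoch train and
#'   validation loss) and `val_idx` recording the held-out validation rows.
#' @export
train_once <- function(spec, bundle, policy = training_policy(), edges = NULL) {
  sp <- split_train_val(bundle, policy)
  if (!is.null(policy$k_folds)) {
    of_abort("train_once expects a single split; use k-fold policies with hpo/evaluation loops.")
  }
  model <- build_model(spec, bundle, edges = edges, seed = derive_seed(policy$seed, 11))
  tr <- bundle_subset(bundle, "train", sp$train_idx)
  va <- bundle_subset(bundle, "train", sp$val_idx)
  model <- run_training_loop(model, tr$x, tr$y, va$x, va$y,
                             lr = spec$hyper$lr, batch_size = spec$hyper$batch_size,
                             max_epochs = spec$hyper$max_epochs,
                             patience = policy$early_stop_patience,
                             seed = derive_seed(policy$seed, 12))
  model$val_idx <- sp$val_idx
  model$train_idx <- sp$train_idx
  model
}

# ---- Bayesian sequential hyperparameter optimization ------------------------

#' Default hyperparameter search space
#'
#' @param architecture Architecture name; the GNN space adds node embedding
#'   size, convolution count, and convolution type.
#' @return A list of parameter definitions (name, type, bounds/values).
#' @export
default_search_space <- function(architecture = "DirectPred") {
  space <- list(
    list(name = "latent_dim", type = "int", lower = 16, upper = 128),
    list(name = "hidden_dim_factor", type = "real", lower = 0.2, upper = 0.5),
    list(name = "lr", type = "logreal", lower = 1e-4, upper = 1e-2),
    list(name = "supervisor_hidden_dim", type = "int", lower = 8, upper = 32),
    list(name = "batch_size", type = "cat", values = c(32L, 64L, 128L))
  )
  if (architecture == "GNN") {
    space <- c(space, list(
      list(name = "node_embedding_dim", type = "int", lower = 4, upper = 32),
      list(name = "num_convs", type = "int", lower = 1, upper = 4),
      list(name = "conv_type", type = "cat", values = CONV_TYPES)
    ))
  }
  space
}

sample_space <- function(space) {
  cfg <- list()
  for (p in space) {
    cfg[[p$name]] <- switch(p$type,
      int = sample(seq(p$lower, p$upper), 1),
      real = stats::runif(1, p$lower, p$upper),
      logreal = 10^stats::runif(1, log10(p$lower), log10(p$upper)),
      cat = p$values[[sample.int(length(p$values), 1)]]
    )
  }
  cfg
}

encode_config <- function(space, cfg) {
  vapply(space, function(p) {
    v <- cfg[[p$name]]
    switch(p$type,
      int = (as.numeric(v) - p$lower) / (p$upper - p$lower),
      real = (v - p$lower) / (p$upper - p$lower),
      logreal = (log10(v) - log10(p$lower)) / (log10(p$upper) - log10(p$lower)),
      cat = (match(v, p$values) - 1) / max(length(p$values) - 1, 1)
    )
  }, 0)
}

# Gaussian-process posterior (RBF kernel, fixed lengthscale in the unit cube)
# and expected improvement for minimization.
gp_ei <- function(X, y, Xcand, lengthscale = 0.25, noise = 1e-4) {
  ymu <- mean(y); ysd <- stats::sd(y)
  if (!is.finite(ysd) || ysd < 1e-12) ysd <- 1
  ys <- (y - ymu) / ysd
  K <- exp(-pairwise_sqdist(X) / (2 * lengthscale^2)) + diag(noise + 1e-8, nrow(X))
  Ks <- exp(-pairwise_sqdist(Xcand, X) / (2 * lengthscale^2))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  mu <- as.numeric(Ks %*% alpha)
  v <- forwardsolve(t(L), t(Ks))
  s2 <- pmax(1 - colSums(v^2), 1e-12)
  s <- sqrt(s2)
  fbest <- min(ys)
  imp <- fbest - mu
  zz <- imp / s
  ei <- imp * stats::pnorm(zz) + s * stats::dnorm(zz)
  ei
}

#' Bayesian sequential hyperparameter search
#'
#' The first `n_init` configurations are sampled uniformly from the search
#' space; each subsequent configuration maximizes the expected improvement of
#' a Gaussian-process surrogate fitted to the (configuration, final
#' validation loss) pairs observed so far, over a pool of random candidates.
#' The train/validation split is fixed across trials (seeded from the policy)
#' so trials are comparable.
#'
#' @param spec_template A [model_spec()] whose hyperparameters are replaced
#'   trial by trial.
#' @param bundle A `harmonized_bundle`.
#' @param space Search space from [default_search_space()] (bounds may be
#'   overridden).
#' @param n_iter Total number of trials.
#' @param policy A [training_policy()]; `policy$seed` fixes the split.
#' @param n_init Random initial trials before the surrogate takes over.
#' @param objective Objective function `function(spec) -> numeric` (defaults
#'   to the final validation loss of [train_once()]); replaceable for
#'   testing the optimizer itself.
#' @param edges GNN edge matrix, passed through.
#' @return List with `best_spec` (the argmin trial's `model_spec`),
#'   `best_model` (its trained model, when the default objective is used),
#'   and `trials` (a tibble logging every configuration and its loss).
#' @export
hpo_search <- function(spec_template, bundle, space = NULL, n_iter = 10,
                       policy = training_policy(), n_init = 5,
                       objective = NULL, edges = NULL) {
  if (!is_count(n_iter)) of_abort("`n_iter` must be >= 1.")
  space <- space %||% default_search_space(spec_template$architecture)
  if (n_iter < n_init) {
    of_warn(sprintf("n_iter (%d) < n_init (%d): all trials are random search.",
                    n_iter, n_init))
  }
  models <- list()
  default_obj <- is.null(objective)
  if (default_obj) {
    objective <- function(spec) {
      m <- train_once(spec, bundle, policy, edges = edges)
      models[[length(models) + 1]] <<- m
      m$best_val_loss
    }
  }
  spec_with <- function(cfg) {
    h <- spec_template$hyper
    for (nm in names(cfg)) h[[nm]] <- cfg[[nm]]
    sp <- spec_template
    sp$hyper <- do.call(hyper_config, c(h[setdiff(names(h), NULL)], list(validate = FALSE)))
    sp
  }
  trials <- list()
  X <- NULL; yv <- numeric()
  for (it in seq_len(n_iter)) {
    cfg <- with_seed(derive_seed(policy$seed, 1000 + it), {
      if (it <= n_init || length(yv) < 2) {
        sample_space(space)
      } else {
        cands <- replicate(256, sample_space(space), simplify = FALSE)
        Xc <- do.call(rbind, lapply(cands, encode_config, space = space))
        ei <- gp_ei(X, yv, Xc)
        cands[[which.max(ei)]]
      }
    })
    sp <- spec_with(cfg)
    loss <- objective(sp)
    X <- rbind(X, encode_config(space, cfg))
    yv <- c(yv, loss)
    trials[[it]] <- tibble::as_tibble(c(list(iteration = it, val_loss = loss),
                                        cfg))
  }
  trials <- dplyr::bind_rows(trials)
  best_i <- which.min(yv)
  out <- list(best_spec = spec_with(as.list(trials[best_i,
                 setdiff(names(trials), c("iteration", "val_loss"))])),
              trials = trials)
  if (default_obj) out$best_model <- models[[best_i]]
  out
}

# ---- fine-tuning -------------------------------------------------------------

#' Fine-tuning policy
#'
#' @param holdin_fraction Fraction of test samples used for tuning; the rest
#'   are returned as the untouched evaluation set.
#' @param lr_grid Learning rates to try.
#' @param freeze_strategies Any of `"freeze_none"`, `"freeze_encoders"`,
#'   `"freeze_heads"`.
#' @param cv_folds Cross-validation folds on the held-in portion (default 5).
#' @param patience Early-stop patience during fine-tuning (default 3).
#' @param max_epochs Epoch cap per fine-tuning run.
#' @param seed Integer seed.
#' @return A `finetune_policy` object.
#' @export
finetune_policy <- function(holdin_fraction = 0.5,
                            lr_grid = c(1e-4, 1e-3, 1e-2),
                            freeze_strategies = c("freeze_none", "freeze_encoders", "freeze_heads"),
                            cv_folds = 5, patience = 3, max_epochs = 50, seed = 1) {
  if (!(holdin_fraction > 0 && holdin_fraction < 1)) {
    of_abort("`holdin_fraction` must be in (0, 1).")
  }
  structure(list(holdin_fraction = holdin_fraction, lr_grid = lr_grid,
                 freeze_strategies = freeze_strategies, cv_folds = cv_folds,
                 patience = patience, max_epochs = max_epochs, seed = seed),
            class = "finetune_policy")
}

freeze_components <- function(strategy, model) {
  enc <- intersect(names(model$theta), c("encoders", "embed", "convs", "latent"))
  switch(strategy,
         freeze_none = character(),
         freeze_encoders = enc,
         freeze_heads = "heads",
         of_abort(sprintf("unknown freeze strategy '%s'.", strategy)))
}

#' Fine-tune a trained model on part of the test set
#'
#' A grid over learning rates and parameter-freezing strategies is evaluated
#' by k-fold cross-validation on a held-in portion of the test samples; the
#' winning combination is then retrained on the whole held-in portion (early
#' stopping, low patience). The held-out indices are returned so evaluation
#' never touches tuning samples.
#'
#' @param trained A trained `of_model`.
#' @param bundle The `harmonized_bundle` whose test split supplies samples.
#' @param policy A [finetune_policy()].
#' @return List with `model` (fine-tuned), `heldout_idx`, `holdin_idx`, and
#'   `grid` (a tibble of CV losses per combination).
#' @export
finetune <- function(trained, bundle, policy = finetune_policy()) {
  n <- nrow(bundle$x_test[[1]])
  n_in <- round(n * policy$holdin_fraction)
  if (n_in < max(5, policy$cv_folds)) {
    of_abort("held-in portion too small for the requested cross-validation.")
  }
  holdin <- with_seed(derive_seed(policy$seed, 21), sort(sample.int(n, n_in)))
  heldout <- setdiff(seq_len(n), holdin)
  folds <- with_seed(derive_seed(policy$seed, 22), {
    f <- rep(seq_len(policy$cv_folds), length.out = n_in)
    split(holdin, sample(f))
  })
  grid <- list()
  best <- list(loss = Inf)
  for (lr in policy$lr_grid) {
    for (strategy in policy$freeze_strategies) {
      freeze <- freeze_components(strategy, trained)
      cv_losses <- numeric(length(folds))
      for (f in seq_along(folds)) {
        va_idx <- folds[[f]]
        tr_idx <- setdiff(holdin, va_idx)
        tr <- bundle_subset(bundle, "test", tr_idx)
        va <- bundle_subset(bundle, "test", va_idx)
        m <- trained
        m <- run_training_loop(m, tr$x, tr$y, va$x, va$y, lr = lr,
                               batch_size = trained$spec$hyper$batch_size,
                               max_epochs = policy$max_epochs,
                               patience = policy$patience,
                               seed = derive_seed(policy$seed, 23 + f),
                               freeze = freeze)
        cv_losses[f] <- m$best_val_loss
      }
      cv <- mean(cv_losses)
      grid[[length(grid) + 1]] <- tibble::tibble(lr = lr, strategy = strategy,
                                                 cv_loss = cv)
      if (cv < best$loss) best <- list(loss = cv, lr = lr, strategy = strategy)
    }
  }
  # retrain the winner on the full held-in portion (80/20 internal split for
  # the early-stop callback)
  inner <- with_seed(derive_seed(policy$seed, 31), {
    v <- sample(holdin, max(1, round(n_in * 0.2)))
    list(tr = setdiff(holdin, v), va = sort(v))
  })
  tr <- bundle_subset(bundle, "test", inner$tr)
  va <- bundle_subset(bundle, "test", inner$va)
  final <- run_training_loop(trained, tr$x, tr$y, va$x, va$y, lr = best$lr,
                             batch_size = trained$spec$hyper$batch_size,
                             max_epochs = policy$max_epochs,
                             patience = policy$patience,
                             seed = derive_seed(policy$seed, 32),
                             freeze = freeze_components(best$strategy, trained))
  list(model = final, heldout_idx = heldout, holdin_idx = holdin,
       grid = dplyr::bind_rows(grid),
       winner = tibble::tibble(lr = best$lr, strategy = best$strategy))
}
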