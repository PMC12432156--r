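ARCHITECTURES <- c("DirectPred", "supervised_vae", "CrossModalPred",
                   "MultiTripletNetwork", "GNN")
CONV_TYPES <- c("GraphConv", "GCNConv", "SAGEConv")

#' Hyperparameter configuration
#'
#' One point in the hyperparameter search space. Defaults and bounds follow
#' the framework's standard search-space table: `latent_dim` 16–128,
#' `hidden_dim_factor` 0.2–0.5 (hidden layer size relative to its input
#' layer), `lr` 1e-4–1e-2 (log scale), `supervisor_hidden_dim` 8–32,
#' `max_epochs` fixed at 500, `batch_size` a power of two in 32–128; GNN
#' extras: `node_embedding_dim` 4–32, `num_convs` 1–4,
#' `conv_type` GraphConv/GCNConv/SAGEConv, relu activation.
#'
#' @param latent_dim Embedding dimension per encoder.
#' @param hidden_dim_factor Hidden layer size as a fraction of its input size.
#' @param lr Adam learning rate.
#' @param supervisor_hidden_dim Hidden units in each supervisor MLP head.
#' @param max_epochs Training epoch cap.
#' @param batch_size Minibatch size (power of two).
#' @param node_embedding_dim,num_convs,conv_type,activation GNN settings.
#' @param validate Enforce the search-space bounds? Disable to explore
#'   values outside the standard ranges.
#' @return A `hyper_config` object.
#' @export
hyper_config <- function(latent_dim = 32, hidden_dim_factor = 0.3, lr = 1e-3,
                         supervisor_hidden_dim = 16, max_epochs = 500,
                         batch_size = 32, node_embedding_dim = 8,
                         num_convs = 2, conv_type = "GraphConv",
                         activation = "relu", validate = TRUE) {
  h <- structure(list(latent_dim = as.integer(latent_dim),
                      hidden_dim_factor = hidden_dim_factor, lr = lr,
                      supervisor_hidden_dim = as.integer(supervisor_hidden_dim),
                      max_epochs = as.integer(max_epochs),
                      batch_size = as.integer(batch_size),
                      node_embedding_dim = as.integer(node_embedding_dim),
                      num_convs = as.integer(num_convs),
                      conv_type = conv_type, activation = activation),
                 class = "hyper_config")
  if (validate) {
    bad <- character()
    chk <- function(ok, msg) if (!ok) bad <<- c(bad, msg)
    chk(h$latent_dim >= 16 && h$latent_dim <= 128, "latent_dim must be in [16, 128]")
    chk(h$hidden_dim_factor >= 0.2 && h$hidden_dim_factor <= 0.5,
        "hidden_dim_factor must be in [0.2, 0.5]")
    chk(h$lr >= 1e-4 && h$lr <= 1e-2, "lr must be in [1e-4, 1e-2]")
    chk(h$supervisor_hidden_dim >= 8 && h$supervisor_hidden_dim <= 32,
        "supervisor_hidden_dim must be in [8, 32]")
    chk(h$batch_size %in% c(32L, 64L, 128L), "batch_size must be a power of two in [32, 128]")
    chk(h$node_embedding_dim >= 4 && h$node_embedding_dim <= 32,
        "node_embedding_dim must be in [4, 32]")
    chk(h$num_convs >= 1 && h$num_convs <= 4, "num_convs must be in [1, 4]")
    chk(h$conv_type %in% CONV_TYPES, "unknown conv_type")
    chk(identical(h$activation, "relu"), "activation is fixed to relu")
    if (length(bad)) of_abort(c("invalid hyper_config:", bad))
  }
  h
}

#' Declare a model architecture
#'
#' @param architecture One of `"DirectPred"` (multi-task feed-forward
#'   predictor), `"supervised_vae"` (variational autoencoder with MMD prior
#'   matching), `"CrossModalPred"` (encoder over input modalities, decoders
#'   reconstructing a possibly different output subset),
#'   `"MultiTripletNetwork"` (DirectPred plus triplet contrastive loss on the
#'   first categorical target), or `"GNN"` (graph convolutions over a
#'   feature-interaction network; early fusion only).
#' @param fusion `"early"` (modalities concatenated before one encoder) or
#'   `"intermediate"` (one encoder per modality, latents concatenated before
#'   the heads).
#' @param input_modalities Modalities to encode (default: all in the bundle).
#' @param output_modalities CrossModalPred only: modalities to reconstruct.
#' @param hyper A [hyper_config()].
#' @param uncertainty_weighting Learn per-task log-variance loss weights?
#' @param triplet_margin Margin for the triplet loss.
#' @param mmd_bandwidth Gaussian-kernel bandwidth for the MMD term; default
#'   `2 * embedding_width`.
#' @return A `model_spec` object.
#' @export
model_spec <- function(architecture, fusion = c("intermediate", "early"),
                       input_modalities = NULL, output_modalities = NULL,
                       hyper = hyper_config(), uncertainty_weighting = FALSE,
                       triplet_margin = 1, mmd_bandwidth = NULL) {
  architecture <- match.arg(architecture, ARCHITECTURES)
  fusion <- match.arg(fusion)
  if (architecture == "GNN" && fusion != "early") {
    of_abort("the GNN architecture supports early fusion only.")
  }
  if (architecture == "CrossModalPred" &&
      (is.null(output_modalities) || length(output_modalities) == 0)) {
    of_abort("CrossModalPred requires non-empty `output_modalities`.")
  }
  structure(list(architecture = architecture, fusion = fusion,
                 input_modalities = input_modalities,
                 output_modalities = output_modalities,
                 hyper = hyper,
                 uncertainty_weighting = uncertainty_weighting,
                 triplet_margin = triplet_margin,
                 mmd_bandwidth = mmd_bandwidth),
            class = "model_spec")
}

#' Plan an encoder's layer sizes
#'
#' A fully connected stack `input_dim -> ceiling(hidden_dim_factor *
#' input_dim) -> latent_dim` with ReLU between layers. A hidden size
#' computing to zero is floored at 1 with a warning.
#'
#' @param input_dim Input feature count (>= 1).
#' @param hyper A [hyper_config()].
#' @param out_mult Output width multiplier (2 for variational encoders that
#'   emit mean and log-variance).
#' @return Integer vector of layer sizes.
#' @export
build_encoder <- function(input_dim, hyper, out_mult = 1) {
  if (!is_count(input_dim)) of_abort("`input_dim` must be >= 1.")
  hidden <- ceiling(hyper$hidden_dim_factor * input_dim)
  if (hidden < 1) {
    of_warn("hidden layer size computed to 0; floored at 1.")
    hidden <- 1
  }
  c(input_dim, hidden, hyper$latent_dim * out_mult)
}

#' Fuse modality arrays by feature-axis concatenation
#'
#' Early fusion concatenates raw modality matrices before a single encoder;
#' intermediate fusion concatenates per-modality latents before the heads.
#' Both are column concatenation of sample-aligned matrices.
#'
#' @param arrays Named list of samples x features matrices.
#' @param mode `"early"` or `"intermediate"` (semantics identical here;
#'   recorded for provenance).
#' @return Single fused matrix.
#' @export
fuse <- function(arrays, mode = c("early", "intermediate")) {
  mode <- match.arg(mode)
  ns <- vapply(arrays, nrow, 0L)
  if (length(unique(ns)) != 1) of_abort("modality arrays have mismatched sample counts.")
  do.call(cbind, unname(arrays))
}

#' Plan the supervisor MLP heads
#'
#' One small MLP per target: `embedding_width -> supervisor_hidden_dim ->
#' output`, with output 1 for regression, `n_classes` logits for
#' classification, and 1 unbounded risk score for survival.
#'
#' @param embedding_width Width of the fused embedding.
#' @param targets_info Named list with `kind` and (for classification)
#'   `n_classes` per target.
#' @param supervisor_hidden_dim Hidden layer width.
#' @return Named list of integer layer-size plans.
#' @export
attach_heads <- function(embedding_width, targets_info, supervisor_hidden_dim) {
  if (!is_count(embedding_width)) of_abort("`embedding_width` must be >= 1.")
  plans <- list()
  for (nm in names(targets_info)) {
    ti <- targets_info[[nm]]
    out <- switch(ti$kind,
                  regression = 1L,
                  survival = 1L,
                  classification = {
                    if ((ti$n_classes %||% 0) < 2) {
                      of_abort(sprintf("classification target '%s' needs >= 2 classes.", nm))
                    }
                    as.integer(ti$n_classes)
                  },
                  of_abort(sprintf("unknown task kind '%s'.", ti$kind)))
    plans[[nm]] <- c(embedding_width, supervisor_hidden_dim, out)
  }
  plans
}

targets_info_from_labels <- function(labels) {
  lapply(labels, function(l) list(kind = l$kind, n_classes = l$n_classes))
}

#' Build an untrained model from a spec and a harmonized bundle
#'
#' Initializes every encoder, decoder, head, and (when enabled) uncertainty
#' weight; a fixed seed yields bit-identical initial parameters.
#'
#' @param spec A [model_spec()].
#' @param bundle A `harmonized_bundle` (only dimensions and label kinds are
#'   read here).
#' @param edges GNN only: integer edge matrix over the fused feature columns,
#'   as produced by [restrict_to_graph()].
#' @param seed Integer seed for parameter initialization.
#' @return An `of_model` object.
#' @export
build_model <- function(spec, bundle, edges = NULL, seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  mods <- spec$input_modalities %||% names(bundle$x_train)
  missing <- setdiff(mods, names(bundle$x_train))
  if (length(missing)) of_abort(sprintf("input modalities not in bundle: %s",
                                        paste(missing, collapse = ", ")))
  all_dims <- vapply(bundle$x_train, ncol, 0L)
  input_dims <- all_dims[mods]
  targets_info <- targets_info_from_labels(bundle$y_train)
  if (length(targets_info) == 0 && spec$architecture != "supervised_vae") {
    of_abort(sprintf("%s requires at least one target variable.", spec$architecture))
  }
  h <- spec$hyper
  is_vae <- spec$architecture %in% c("supervised_vae", "CrossModalPred")
  out_mods <- if (spec$architecture == "CrossModalPred") {
    bad <- setdiff(spec$output_modalities, names(bundle$x_train))
    if (length(bad)) of_abort(sprintf("output modalities not in bundle: %s",
                                      paste(bad, collapse = ", ")))
    spec$output_modalities
  } else if (spec$architecture == "supervised_vae") {
    mods
  } else {
    character()
  }
  emb_width <- if (spec$fusion == "early") h$latent_dim else h$latent_dim * length(mods)
  theta <- with_seed(seed, {
    th <- list()
    if (spec$architecture == "GNN") {
      if (is.null(edges) || nrow(edges) == 0) of_abort("GNN requires a non-empty feature graph.")
      d <- h$node_embedding_dim
      th$embed <- list(w = stats::rnorm(d, sd = 1), b = numeric(d))
      th$convs <- lapply(seq_len(h$num_convs), function(i) {
        if (h$conv_type == "GCNConv") {
          list(W = matrix(stats::rnorm(d * d, sd = sqrt(2 / d)), d, d), b = numeric(d))
        } else {
          list(W1 = matrix(stats::rnorm(d * d, sd = sqrt(2 / d)), d, d),
               W2 = matrix(stats::rnorm(d * d, sd = sqrt(2 / d)), d, d),
               b = numeric(d))
        }
      })
      th$latent <- list(W = matrix(stats::rnorm(d * h$latent_dim, sd = sqrt(2 / d)),
                                   d, h$latent_dim),
                        b = numeric(h$latent_dim))
    } else if (spec$fusion == "early") {
      th$encoders <- list(fused = mlp_init(build_encoder(sum(input_dims), h,
                                                         out_mult = if (is_vae) 2 else 1)))
    } else {
      th$encoders <- lapply(mods, function(m) {
        mlp_init(build_encoder(input_dims[[m]], h, out_mult = if (is_vae) 2 else 1))
      })
      names(th$encoders) <- mods
    }
    if (is_vae) {
      th$decoders <- lapply(out_mods, function(m) {
        hidden <- max(ceiling(h$hidden_dim_factor * all_dims[[m]]), 1)
        mlp_init(c(emb_width, hidden, all_dims[[m]]))
      })
      names(th$decoders) <- out_mods
    }
    if (length(targets_info)) {
      plans <- attach_heads(emb_width, targets_info, h$supervisor_hidden_dim)
      th$heads <- lapply(plans, mlp_init)
    }
    if (spec$uncertainty_weighting) {
      terms <- names(targets_info)
      if (is_vae) terms <- c(terms, "reconstruction", "mmd")
      if (spec$architecture == "MultiTripletNetwork") terms <- c(terms, "triplet")
      th$log_vars <- stats::setNames(numeric(length(terms)), terms)
    }
    th
  })
  structure(list(spec = spec, theta = theta,
                 modalities = mods, output_modalities = out_mods,
                 input_dims = input_dims,
                 embedding_width = emb_width,
                 targets_info = targets_info,
                 edges = edges,
                 code_maps = bundle$code_maps,
                 history = NULL),
            class = "of_model")
}

#' @export
print.of_model <- function(x, ...) {
  cat(sprintf("<of_model> %s (%s fusion), modalities: %s; embedding width %d; heads: %s\n",
              x$spec$architecture, x$spec$fusion,
              paste(x$modalities, collapse = "+"), x$embedding_width,
              if (length(x$targets_info)) paste(names(x$targets_info), collapse = ", ") else "none"))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epochs; best val loss %.4g\n",
                nrow(x$history), min(x$history$val_loss)))
  }
  invisible(x)
}

# ---- forward passes ---------------------------------------------------------

check_input_widths <- function(model, x) {
  for (m in model$modalities) {
    if (is.null(x[[m]])) of_abort(sprintf("missing modality '%s' in input.", m))
    if (ncol(x[[m]]) != model$input_dims[[m]]) {
      of_abort(sprintf("modality '%s': %d features supplied, %d expected from training.",
                       m, ncol(x[[m]]), model$input_dims[[m]]))
    }
  }
}

# Adjacency operator for the configured convolution, cached on first use.
gnn_operator <- function(model, p) {
  e <- model$edges
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(p, p))
  ct <- model$spec$hyper$conv_type
  if (ct == "GraphConv") return(A)
  if (ct == "SAGEConv") {
    deg <- Matrix::rowSums(A)
    di <- ifelse(deg > 0, 1 / deg, 0)
    return(Matrix::Diagonal(x = di) %*% A)
  }
  # GCNConv: symmetric normalization with self-loops
  Ai <- A + Matrix::Diagonal(p)
  dh <- 1 / sqrt(Matrix::rowSums(Ai))
  Matrix::Diagonal(x = dh) %*% Ai %*% Matrix::Diagonal(x = dh)
}

# Forward pass. x: named list of samples x features matrices (all modalities
# the model needs: inputs, and for CrossModalPred also outputs when computing
# losses). Returns embedding, per-target predictions, reconstructions, and
# caches for the backward pass.
#' Run a model forward
#'
#' Evaluation-mode forward passes are deterministic (the variational
#' architectures use the latent mean); in training mode the latent is a
#' single reparameterized draw.
#'
#' @param model An `of_model`.
#' @param x Named list of samples x features matrices.
#' @param train Training mode? (stochastic latent draw for VAEs).
#' @return List with `embedding` (samples x embedding_width), `preds` (named
#'   list: matrices of logits for classification, vectors otherwise),
#'   `recons` (named list, variational architectures only), and internal
#'   caches.
#' @export
model_forward <- function(model, x, train = FALSE) {
  check_input_widths(model, x)
  spec <- model$spec
  th <- model$theta
  is_vae <- spec$architecture %in% c("supervised_vae", "CrossModalPred")
  ld <- spec$hyper$latent_dim
  caches <- list()
  if (spec$architecture == "GNN") {
    X <- fuse(x[model$modalities], "early")
    n <- nrow(X); p <- ncol(X)
    M <- gnn_operator(model, p)
    Mbig <- Matrix::Diagonal(n) %x% M
    xvec <- as.numeric(t(X))  # sample-major node order
    d <- spec$hyper$node_embedding_dim
    H <- outer(xvec, th$embed$w) + rep(th$embed$b, each = length(xvec))
    conv_caches <- list()
    for (l in seq_along(th$convs)) {
      cv <- th$convs[[l]]
      MH <- as.matrix(Mbig %*% H)
      P <- if (spec$hyper$conv_type == "GCNConv") {
        MH %*% cv$W + rep(cv$b, each = nrow(H))
      } else {
        H %*% cv$W1 + MH %*% cv$W2 + rep(cv$b, each = nrow(H))
      }
      conv_caches[[l]] <- list(H = H, MH = MH, P = P)
      H <- pmax(P, 0)
    }
    G <- rowsum(H, group = rep(seq_len(n), each = p), reorder = FALSE) / p
    emb <- G %*% th$latent$W + rep(th$latent$b, each = n)
    caches$gnn <- list(X = X, xvec = xvec, Mbig = Mbig, conv = conv_caches,
                       Hlast = H, G = G, n = n, p = p)
    embedding <- emb
  } else if (spec$fusion == "early") {
    Xf <- fuse(x[model$modalities], "early")
    fw <- mlp_forward(th$encoders$fused, Xf)
    caches$enc <- list(fused = fw)
    if (is_vae) {
      mu <- fw$out[, seq_len(ld), drop = FALSE]
      lv <- pmin(pmax(fw$out[, ld + seq_len(ld), drop = FALSE], -10), 10)
      eps <- if (train) matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu)) else 0 * mu
      z <- mu + exp(0.5 * lv) * eps
      caches$vae <- list(fused = list(mu = mu, lv = lv, eps = eps, raw = fw$out))
      embedding <- z
    } else {
      embedding <- fw$out
    }
  } else {
    latents <- list(); enc_caches <- list(); vae_caches <- list()
    for (m in model$modalities) {
      fw <- mlp_forward(th$encoders[[m]], x[[m]])
      enc_caches[[m]] <- fw
      if (is_vae) {
        mu <- fw$out[, seq_len(ld), drop = FALSE]
        lv <- pmin(pmax(fw$out[, ld + seq_len(ld), drop = FALSE], -10), 10)
        eps <- if (train) matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu)) else 0 * mu
        z <- mu + exp(0.5 * lv) * eps
        vae_caches[[m]] <- list(mu = mu, lv = lv, eps = eps)
        latents[[m]] <- z
      } else {
        latents[[m]] <- fw$out
      }
    }
    caches$enc <- enc_caches
    if (is_vae) caches$vae <- vae_caches
    embedding <- fuse(latents, "intermediate")
  }
  rownames(embedding) <- rownames(x[[model$modalities[1]]])

  recons <- list()
  if (is_vae) {
    caches$dec <- list()
    for (m in model$output_modalities) {
      fw <- mlp_forward(th$decoders[[m]], embedding)
      caches$dec[[m]] <- fw
      recons[[m]] <- fw$out
    }
  }

  preds <- list(); caches$heads <- list()
  for (t in names(model$targets_info)) {
    fw <- mlp_forward(th$heads[[t]], embedding)
    caches$heads[[t]] <- fw
    preds[[t]] <- if (model$targets_info[[t]]$kind == "classification") fw$out else fw$out[, 1]
  }
  list(embedding = embedding, preds = preds, recons = recons, caches = caches)
}

# Backward through the encoder stack given d(embedding); accumulates encoder
# parameter grads into `acc` and returns input gradients per modality.
encoder_backward <- function(model, x, fw, dEmb, acc_env) {
  spec <- model$spec
  th <- model$theta
  ld <- spec$hyper$latent_dim
  is_vae <- spec$architecture %in% c("supervised_vae", "CrossModalPred")
  dX <- list()
  if (spec$architecture == "GNN") {
    g <- fw$caches$gnn
    dG <- tcrossprod(dEmb, th$latent$W)  # dEmb %*% t(W)
    acc_env$grads$latent$W <- acc_env$grads$latent$W + crossprod(g$G, dEmb)
    acc_env$grads$latent$b <- acc_env$grads$latent$b + colSums(dEmb)
    dH <- dG[rep(seq_len(g$n), each = g$p), , drop = FALSE] / g$p
    for (l in rev(seq_along(th$convs))) {
      cc <- g$conv[[l]]
      cv <- th$convs[[l]]
      dP <- dH * (cc$P > 0)
      if (spec$hyper$conv_type == "GCNConv") {
        acc_env$grads$convs[[l]]$W <- acc_env$grads$convs[[l]]$W + crossprod(cc$MH, dP)
        acc_env$grads$convs[[l]]$b <- acc_env$grads$convs[[l]]$b + colSums(dP)
        dH <- as.matrix(Matrix::crossprod(g$Mbig, dP %*% t(cv$W)))
      } else {
        acc_env$grads$convs[[l]]$W1 <- acc_env$grads$convs[[l]]$W1 + crossprod(cc$H, dP)
        acc_env$grads$convs[[l]]$W2 <- acc_env$grads$convs[[l]]$W2 + crossprod(cc$MH, dP)
        acc_env$grads$convs[[l]]$b <- acc_env$grads$convs[[l]]$b + colSums(dP)
        dH <- dP %*% t(cv$W1) + as.matrix(Matrix::crossprod(g$Mbig, dP %*% t(cv$W2)))
      }
    }
    # node embedding layer: H0 = outer(xvec, w) + b
    acc_env$grads$embed$w <- acc_env$grads$embed$w + as.numeric(crossprod(dH, g$xvec))
    acc_env$grads$embed$b <- acc_env$grads$embed$b + colSums(dH)
    dxvec <- as.numeric(dH %*% model$theta$embed$w)
    dXf <- matrix(dxvec, g$n, g$p, byrow = TRUE)
    # split fused gradient back into modalities
    off <- 0
    for (m in model$modalities) {
      w <- model$input_dims[[m]]
      dX[[m]] <- dXf[, off + seq_len(w), drop = FALSE]
      off <- off + w
    }
    return(dX)
  }
  if (spec$fusion == "early") {
    fwE <- fw$caches$enc$fused
    if (is_vae) {
      vc <- fw$caches$vae$fused
      dmu <- dEmb
      dlv <- dEmb * vc$eps * 0.5 * exp(0.5 * vc$lv)
      dlv[vc$lv <= -10 | vc$lv >= 10] <- 0
      dOut <- cbind(dmu, dlv)
    } else {
      dOut <- dEmb
    }
    bk <- mlp_backward(th$encoders$fused, fwE, dOut)
    acc_env$grads$encoders$fused <- nested_add(acc_env$grads$encoders$fused, bk$grads)
    off <- 0
    for (m in model$modalities) {
      w <- model$input_dims[[m]]
      dX[[m]] <- bk$dX[, off + seq_len(w), drop = FALSE]
      off <- off + w
    }
  } else {
    off <- 0
    for (m in model$modalities) {
      dz <- dEmb[, off + seq_len(ld), drop = FALSE]
      off <- off + ld
      if (is_vae) {
        vc <- fw$caches$vae[[m]]
        dmu <- dz
        dlv <- dz * vc$eps * 0.5 * exp(0.5 * vc$lv)
        dlv[vc$lv <= -10 | vc$lv >= 10] <- 0
        dOut <- cbind(dmu, dlv)
      } else {
        dOut <- dz
      }
      bk <- mlp_backward(th$encoders[[m]], fw$caches$enc[[m]], dOut)
      acc_env$grads$encoders[[m]] <- nested_add(acc_env$grads$encoders[[m]], bk$grads)
      dX[[m]] <- bk$dX
    }
  }
  dX
}

# Sample within-batch triplets keyed on the first categorical target.
sample_triplets <- function(codes) {
  ok <- which(!is.na(codes))
  trip <- list()
  for (i in ok) {
    pos <- ok[codes[ok] == codes[i] & ok != i]
    neg <- ok[codes[ok] != codes[i]]
    if (length(pos) == 0 || length(neg) == 0) next
    trip[[length(trip) + 1]] <- c(i,
                                  if (length(pos) == 1) pos else sample(pos, 1),
                                  if (length(neg) == 1) neg else sample(neg, 1))
  }
  if (length(trip) == 0) return(NULL)
  do.call(rbind, trip)
}

# Compute total loss, per-term parts, parameter gradients, and (optionally)
# input gradients for one batch.
model_loss_grads <- function(model, x, y, train = TRUE, compute_grads = TRUE,
                             warn_empty_triplet = FALSE) {
  spec <- model$spec
  th <- model$theta
  fw <- model_forward(model, x, train = train)
  n <- nrow(fw$embedding)
  is_vae <- spec$architecture %in% c("supervised_vae", "CrossModalPred")

  parts <- list(); dpreds <- list()
  for (t in names(model$targets_info)) {
    kind <- model$targets_info[[t]]$kind
    lab <- y[[t]]
    if (kind == "regression") {
      parts[[t]] <- masked_mse(fw$preds[[t]], lab$y, lab$mask, t)
      if (compute_grads) dpreds[[t]] <- cbind(masked_mse_grad(fw$preds[[t]], lab$y, lab$mask))
    } else if (kind == "classification") {
      parts[[t]] <- masked_cross_entropy(fw$preds[[t]], lab$y, lab$mask, t)
      if (compute_grads) dpreds[[t]] <- masked_cross_entropy_grad(fw$preds[[t]], lab$y, lab$mask)
    } else {
      parts[[t]] <- suppressWarnings(cox_ph_loss(fw$preds[[t]], lab$time, lab$event, lab$mask, t))
      if (compute_grads) dpreds[[t]] <- cbind(cox_ph_loss_grad(fw$preds[[t]], lab$time, lab$event, lab$mask))
    }
  }

  aux <- list()
  mmd_prior <- NULL
  if (is_vae) {
    # reconstruction: MSE against the output-modality ground truth
    rec <- 0
    for (m in model$output_modalities) {
      rec <- rec + mean((x[[m]] - fw$recons[[m]])^2)
    }
    aux$reconstruction <- rec / length(model$output_modalities)
    bw <- spec$mmd_bandwidth %||% (2 * model$embedding_width)
    mmd_prior <- matrix(stats::rnorm(n * model$embedding_width), n, model$embedding_width)
    aux$mmd <- mmd_loss(fw$embedding, bandwidth = bw, prior = mmd_prior)
  }
  trip_idx <- NULL
  if (spec$architecture == "MultiTripletNetwork") {
    cat_t <- names(model$targets_info)[vapply(model$targets_info,
                                              function(i) i$kind == "classification", TRUE)]
    if (length(cat_t) == 0) of_abort("MultiTripletNetwork requires a categorical target.")
    trip_idx <- sample_triplets(y[[cat_t[1]]]$y)
    if (is.null(trip_idx)) {
      if (warn_empty_triplet) of_warn("single-class batch: triplet term skipped.")
      aux$triplet <- 0
    } else {
      aux$triplet <- triplet_loss(fw$embedding[trip_idx[, 1], , drop = FALSE],
                                  fw$embedding[trip_idx[, 2], , drop = FALSE],
                                  fw$embedding[trip_idx[, 3], , drop = FALSE],
                                  spec$triplet_margin)
    }
  }

  uw <- spec$uncertainty_weighting
  lv <- if (uw) th$log_vars else NULL
  total <- combine_losses(parts, aux, log_vars = lv, enabled = uw)
  term_weight <- function(nm) if (uw) exp(-unname(lv[nm])) else 1

  grads <- NULL
  if (compute_grads) {
    acc <- new.env(parent = emptyenv())
    acc$grads <- nested_zeros(th)
    dEmb <- matrix(0, n, model$embedding_width)
    for (t in names(model$targets_info)) {
      wgt <- term_weight(t)
      bk <- mlp_backward(th$heads[[t]], fw$caches$heads[[t]], dpreds[[t]] * wgt)
      acc$grads$heads[[t]] <- nested_add(acc$grads$heads[[t]], bk$grads)
      dEmb <- dEmb + bk$dX
    }
    if (is_vae) {
      wr <- term_weight("reconstruction")
      for (m in model$output_modalities) {
        dRec <- 2 * (fw$recons[[m]] - x[[m]]) /
          (length(fw$recons[[m]]) * length(model$output_modalities)) * wr
        bk <- mlp_backward(th$decoders[[m]], fw$caches$dec[[m]], dRec)
        acc$grads$decoders[[m]] <- nested_add(acc$grads$decoders[[m]], bk$grads)
        dEmb <- dEmb + bk$dX
      }
      bw <- spec$mmd_bandwidth %||% (2 * model$embedding_width)
      dEmb <- dEmb + mmd_loss_grad(fw$embedding, mmd_prior, bw) * term_weight("mmd")
    }
    if (!is.null(trip_idx)) {
      tg <- triplet_loss_grad(fw$embedding[trip_idx[, 1], , drop = FALSE],
                              fw$embedding[trip_idx[, 2], , drop = FALSE],
                              fw$embedding[trip_idx[, 3], , drop = FALSE],
                              spec$triplet_margin)
      wtr <- term_weight("triplet")
      for (r in seq_len(nrow(trip_idx))) {
        dEmb[trip_idx[r, 1], ] <- dEmb[trip_idx[r, 1], ] + tg$anchor[r, ] * wtr
        dEmb[trip_idx[r, 2], ] <- dEmb[trip_idx[r, 2], ] + tg$positive[r, ] * wtr
        dEmb[trip_idx[r, 3], ] <- dEmb[trip_idx[r, 3], ] + tg$negative[r, ] * wtr
      }
    }
    encoder_backward(model, x, fw, dEmb, acc)
    if (uw) {
      vals <- c(vapply(parts, function(p) p$value, 0),
                vapply(aux, as.numeric, 0))
      gl <- acc$grads$log_vars
      for (nm in names(gl)) {
        gl[nm] <- -exp(-unname(lv[nm])) * unname(vals[nm]) + 1
      }
      acc$grads$log_vars <- gl
    }
    grads <- acc$grads
  }
  part_vals <- c(vapply(parts, function(p) p$value, 0), vapply(aux, as.numeric, 0))
  list(total = total, parts = part_vals,
       n_observed = vapply(parts, function(p) p$n_observed, 0L),
       grads = grads, forward = fw)
}

# Gradient of one scalar model output w.r.t. every input feature, evaluated
# in deterministic (evaluation) mode. Used by the attribution module.
model_output_grad <- function(model, x, target, class_idx = NULL) {
  fw <- model_forward(model, x, train = FALSE)
  n <- nrow(fw$embedding)
  kind <- model$targets_info[[target]]$kind
  if (is.null(kind)) of_abort(sprintf("unknown target '%s'.", target))
  out_width <- if (kind == "classification") model$targets_info[[target]]$n_classes else 1L
  dOut <- matrix(0, n, out_width)
  col <- if (kind == "classification") {
    if (is.null(class_idx)) of_abort("classification attribution needs `class_idx` (0-based).")
    class_idx + 1L
  } else 1L
  dOut[, col] <- 1
  acc <- new.env(parent = emptyenv())
  acc$grads <- nested_zeros(model$theta)
  bk <- mlp_backward(model$theta$heads[[target]], fw$caches$heads[[target]], dOut)
  dX <- encoder_backward(model, x, fw, bk$dX, acc)
  out_val <- if (kind == "classification") fw$preds[[target]][, col] else fw$preds[[target]]
  list(dX = dX, output = out_val)
}

#' Predict from a trained model
#'
#' @param object An `of_model`.
#' @param newdata Named list of samples x features matrices (harmonized with
#'   the training scalers), or a `harmonized_bundle`.
#' @param split When `newdata` is a bundle: `"test"` (default) or `"train"`.
#' @param ... Unused.
#' @return List with `preds` (per target: class-probability matrices for
#'   classification, numeric vectors otherwise), `embedding`, and for the
#'   variational architectures `recons`.
#' @export
predict.of_model <- function(object, newdata, split = "test", ...) {
  x <- if (inherits(newdata, "harmonized_bundle")) {
    if (split == "test") newdata$x_test else newdata$x_train
  } else {
    newdata
  }
  fw <- model_forward(object, x, train = FALSE)
  preds <- fw$preds
  for (t in names(preds)) {
    if (object$targets_info[[t]]$kind == "classification") {
      pr <- softmax(preds[[t]])
      map <- object$code_maps[[t]]
      if (!is.null(map)) colnames(pr) <- names(sort(map))
      preds[[t]] <- pr
    }
  }
  list(preds = preds, embedding = fw$embedding, recons = fw$recons)
}
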