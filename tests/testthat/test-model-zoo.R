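tiny_hyper <- function(...) {
  hyper_config(latent_dim = 16, hidden_dim_factor = 0.3, lr = 1e-3,
               supervisor_hidden_dim = 8, batch_size = 32,
               node_embedding_dim = 4, num_convs = 1, validate = TRUE, ...)
}

tiny_bundle <- function(n = 24, p1 = 10, p2 = 6, seed = 1, survival = FALSE) {
  set.seed(seed)
  x1 <- matrix(rnorm(n * p1), n, p1, dimnames = list(paste0("s", 1:n), paste0("a", 1:p1)))
  x2 <- matrix(rnorm(n * p2), n, p2, dimnames = list(paste0("s", 1:n), paste0("b", 1:p2)))
  y <- list(
    cl = list(kind = "classification", y = sample(0:2, n, TRUE),
              mask = rep(TRUE, n), n_classes = 3L),
    sc = list(kind = "regression", y = rnorm(n), mask = rep(TRUE, n))
  )
  if (survival) {
    y$os <- list(kind = "survival", time = rexp(n), event = rbinom(n, 1, 0.7),
                 mask = rep(TRUE, n))
  }
  structure(list(x_train = list(rna = x1, cnv = x2), x_test = NULL,
                 y_train = y, code_maps = list(cl = c(A = 0L, B = 1L, C = 2L)),
                 task_spec = NULL),
            class = "harmonized_bundle")
}

grad_check_model <- function(arch, fusion, seed = 3, survival = FALSE, uw = FALSE,
                             edges = NULL, n_checks = 12) {
  b <- tiny_bundle(seed = seed, survival = survival)
  sp <- model_spec(arch, fusion, hyper = tiny_hyper(),
                   output_modalities = if (arch == "CrossModalPred") "cnv",
                   uncertainty_weighting = uw)
  m <- build_model(sp, b, edges = edges, seed = seed)
  x <- b$x_train; y <- b$y_train
  # fix all stochastic elements (VAE eps, MMD prior, triplet draws) per call
  lg_at <- function(model) {
    set.seed(99)
    model_loss_grads(model, x, y, train = TRUE)
  }
  base <- lg_at(m)
  h <- 1e-5
  # probe a deterministic sample of leaf coordinates across components
  paths <- list()
  walk <- function(node, path) {
    if (is.numeric(node)) {
      paths[[length(paths) + 1]] <<- path
    } else {
      for (nm in seq_along(node)) walk(node[[nm]], c(path, nm))
    }
  }
  walk(m$theta, integer())
  set.seed(7)
  worst <- 0
  for (rep in seq_len(n_checks)) {
    pth <- paths[[sample.int(length(paths), 1)]]
    get_leaf <- function(th) { for (i in pth) th <- th[[i]]; th }
    set_leaf <- function(th, val) {
      if (length(pth) == 1) { th[[pth]] <- val; return(th) }
      th[[pth[1]]] <- set_leaf(th[[pth[1]]], val); th
    }
    set_leaf <- function(th, val) {
      rec <- function(node, d) {
        if (d > length(pth)) return(val)
        node[[pth[d]]] <- rec(node[[pth[d]]], d + 1)
        node
      }
      rec(th, 1)
    }
    leaf <- get_leaf(m$theta)
    ii <- sample.int(length(leaf), 1)
    gl <- get_leaf(base$grads)[ii]
    lp <- leaf; lp[ii] <- lp[ii] + h
    lm <- leaf; lm[ii] <- lm[ii] - h
    mp <- m; mp$theta <- set_leaf(m$theta, lp)
    mm <- m; mm$theta <- set_leaf(m$theta, lm)
    num <- (lg_at(mp)$total - lg_at(mm)$total) / (2 * h)
    worst <- max(worst, abs(num - gl) / max(1, abs(num)))
  }
  worst
}

test_that("encoder/fusion/head plans follow the width rules", {
  h <- hyper_config(latent_dim = 64, hidden_dim_factor = 0.3)
  expect_equal(build_encoder(1000, h), c(1000, 300, 64))
  expect_warning(plan <- build_encoder(1, hyper_config(hidden_dim_factor = 0.2,
                                                       validate = FALSE)), NA)
  # fusion widths
  a <- matrix(0, 5, 100); b2 <- matrix(0, 5, 50)
  expect_equal(ncol(fuse(list(a, b2), "early")), 150)
  expect_error(fuse(list(a, matrix(0, 4, 3))), "mismatched sample counts")
  # heads: 3 targets -> outputs 1, 4, 1
  plans <- attach_heads(128, list(r = list(kind = "regression"),
                                  c = list(kind = "classification", n_classes = 4),
                                  s = list(kind = "survival")), 16)
  expect_equal(vapply(plans, function(p) p[3], 0), c(r = 1, c = 4, s = 1))
  expect_error(attach_heads(128, list(c = list(kind = "classification", n_classes = 1)), 16),
               ">= 2 classes")
})

test_that("model spec invariants are enforced", {
  expect_error(model_spec("GNN", "intermediate"), "early fusion only")
  expect_error(model_spec("CrossModalPred", "early"), "output_modalities")
  b <- tiny_bundle()
  b0 <- b; b0$y_train <- list()
  expect_error(build_model(model_spec("DirectPred", hyper = tiny_hyper()), b0),
               "at least one target")
  # supervised_vae tolerates zero targets (pure reconstruction + MMD)
  m <- build_model(model_spec("supervised_vae", hyper = tiny_hyper()), b0, seed = 1)
  expect_null(m$theta$heads)
  lg <- model_loss_grads(m, b0$x_train, list(), train = TRUE)
  expect_setequal(names(lg$parts), c("reconstruction", "mmd"))
  # hyper_config bounds
  expect_error(hyper_config(latent_dim = 4), "latent_dim")
  expect_error(hyper_config(batch_size = 48), "power of two")
})

test_that("embedding widths follow the fusion rule and eval mode is deterministic", {
  b <- tiny_bundle()
  for (arch in c("DirectPred", "supervised_vae")) {
    for (fusion in c("early", "intermediate")) {
      sp <- model_spec(arch, fusion, hyper = tiny_hyper())
      m <- build_model(sp, b, seed = 2)
      fw <- model_forward(m, b$x_train, train = FALSE)
      want <- if (fusion == "early") 16 else 32
      expect_equal(ncol(fw$embedding), want)
      expect_equal(dim(fw$preds$cl), c(24, 3))
      expect_length(fw$preds$sc, 24)
      fw2 <- model_forward(m, b$x_train, train = FALSE)
      expect_identical(fw$preds, fw2$preds)
    }
  }
  # identical seeds give identical initial parameters
  sp <- model_spec("DirectPred", "intermediate", hyper = tiny_hyper())
  m1 <- build_model(sp, b, seed = 5); m2 <- build_model(sp, b, seed = 5)
  expect_identical(m1$theta, m2$theta)
  # wrong feature width errors
  xb <- b$x_train; xb$rna <- xb$rna[, 1:5]
  expect_error(model_forward(m1, xb), "features supplied")
})

test_that("whole-model gradients match finite differences (all architectures)", {
  expect_lt(grad_check_model("DirectPred", "intermediate", survival = TRUE), 1e-4)
  expect_lt(grad_check_model("DirectPred", "early"), 1e-4)
  expect_lt(grad_check_model("supervised_vae", "intermediate"), 1e-4)
  expect_lt(grad_check_model("CrossModalPred", "early"), 1e-4)
  expect_lt(grad_check_model("MultiTripletNetwork", "intermediate"), 1e-4)
  edges <- cbind(sample(1:16, 12, TRUE), sample(1:16, 12, TRUE))
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  for (ct in c("GraphConv", "GCNConv", "SAGEConv")) {
    expect_lt(grad_check_model("GNN", "early", edges = edges, n_checks = 8), 1e-4)
  }
  # uncertainty weighting path
  expect_lt(grad_check_model("DirectPred", "intermediate", uw = TRUE), 1e-4)
})

test_that("masked-out tasks contribute no gradient to the encoders", {
  b <- tiny_bundle()
  b$y_train$sc$mask <- rep(FALSE, 24)
  sp <- model_spec("DirectPred", "intermediate", hyper = tiny_hyper())
  m <- build_model(sp, b, seed = 4)
  lg <- model_loss_grads(m, b$x_train, b$y_train, train = TRUE)
  # the regression head's own parameters receive zero gradient
  expect_equal(omicfuse:::nested_max_abs(lg$grads$heads$sc), 0)
  # and the encoder gradient equals that of a model without the target at all
  b2 <- b; b2$y_train$sc <- NULL
  m2 <- build_model(sp, b2, seed = 4)
  m2$theta$encoders <- m$theta$encoders
  m2$theta$heads$cl <- m$theta$heads$cl
  lg2 <- model_loss_grads(m2, b2$x_train, b2$y_train, train = TRUE)
  expect_equal(lg$grads$encoders, lg2$grads$encoders, tolerance = 1e-12)
})

test_that("VAE loss parts are consistent with the standalone losses", {
  b <- tiny_bundle()
  sp <- model_spec("supervised_vae", "intermediate", hyper = tiny_hyper(),
                   mmd_bandwidth = 32)
  m <- build_model(sp, b, seed = 6)
  set.seed(42)
  lg <- model_loss_grads(m, b$x_train, b$y_train, train = FALSE, compute_grads = FALSE)
  fw <- model_forward(m, b$x_train, train = FALSE)
  rec <- mean(c(mean((b$x_train$rna - fw$recons$rna)^2),
                mean((b$x_train$cnv - fw$recons$cnv)^2)))
  expect_equal(unname(lg$parts["reconstruction"]), rec, tolerance = 1e-12)
  # MMD part matches mmd_loss on the emitted embedding (same prior seed)
  set.seed(42)
  lg2 <- model_loss_grads(m, b$x_train, b$y_train, train = FALSE, compute_grads = FALSE)
  expect_equal(lg$parts["mmd"], lg2$parts["mmd"])
  expect_gte(lg$parts[["mmd"]], -1e-12)
})

test_that("CrossModalPred reconstructs only the output modalities", {
  b <- tiny_bundle()
  sp <- model_spec("CrossModalPred", "early", input_modalities = "rna",
                   output_modalities = "cnv", hyper = tiny_hyper())
  m <- build_model(sp, b, seed = 7)
  fw <- model_forward(m, b$x_train, train = FALSE)
  expect_named(fw$recons, "cnv")
  expect_equal(dim(fw$recons$cnv), dim(b$x_train$cnv))
  # input = output = all modalities reduces to the supervised_vae layout
  sp2 <- model_spec("CrossModalPred", "intermediate",
                    output_modalities = c("rna", "cnv"), hyper = tiny_hyper())
  m2 <- build_model(sp2, b, seed = 7)
  fw2 <- model_forward(m2, b$x_train, train = FALSE)
  expect_setequal(names(fw2$recons), c("rna", "cnv"))
})

test_that("triplet sampling skips single-class batches and is seed-reproducible", {
  b <- tiny_bundle()
  sp <- model_spec("MultiTripletNetwork", "intermediate", hyper = tiny_hyper())
  m <- build_model(sp, b, seed = 8)
  yb <- b$y_train
  yb$cl$y <- rep(0L, 24)  # single class
  expect_warning(
    lg <- model_loss_grads(m, b$x_train, yb, train = TRUE, warn_empty_triplet = TRUE),
    "triplet term skipped")
  expect_equal(unname(lg$parts["triplet"]), 0)
  set.seed(11); t1 <- omicfuse:::sample_triplets(b$y_train$cl$y)
  set.seed(11); t2 <- omicfuse:::sample_triplets(b$y_train$cl$y)
  expect_identical(t1, t2)
})

test_that("GNN convolutions follow their update rules on hand-checkable graphs", {
  # star graph: node 1 is the hub connected to 2..5
  edges <- cbind(rep(1L, 4), 2:5)
  n <- 6; p <- 5
  set.seed(13)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(paste0("s", 1:n), paste0("g", 1:p)))
  b <- tiny_bundle(n = n)
  b$x_train <- list(g = X)
  b$y_train$sc <- NULL
  sp <- model_spec("GNN", "early", hyper = tiny_hyper(conv_type = "SAGEConv"))
  m <- build_model(sp, b, edges = edges, seed = 14)
  # identity-ish weights: W1 = I, W2 = I, b = 0, embed w = 1s, b = 0
  d <- 4
  m$theta$embed$w <- rep(1, d); m$theta$embed$b <- rep(0, d)
  m$theta$convs[[1]]$W1 <- diag(d); m$theta$convs[[1]]$W2 <- diag(d)
  m$theta$convs[[1]]$b <- rep(0, d)
  fw <- model_forward(m, b$x_train)
  # after the conv, the hub's (pre-pool) value = relu(x_hub + mean(leaves)),
  # replicated across the d embedding channels
  g <- fw$caches$gnn
  H <- g$Hlast
  hub_rows <- seq(1, by = p, length.out = n)  # node 1 of each sample block
  for (s in 1:n) {
    want <- pmax(X[s, 1] + mean(X[s, 2:5]), 0)
    expect_equal(unname(H[hub_rows[s], ]), rep(want, d), tolerance = 1e-12)
  }
  # zero-edge GraphConv equals the per-feature linear path (no neighbor term)
  sp2 <- model_spec("GNN", "early", hyper = tiny_hyper(conv_type = "GraphConv"))
  # single disconnected edgeless graph is rejected; use one isolated pair far
  # from the rest so most nodes have no neighbors
  edges2 <- cbind(1L, 2L)
  m2 <- build_model(sp2, b, edges = edges2, seed = 15)
  m2$theta$convs[[1]]$W2 <- m2$theta$convs[[1]]$W2 * 0
  fw2 <- model_forward(m2, b$x_train)
  # with W2 = 0 the adjacency cannot matter
  m3 <- m2; m3$edges <- cbind(c(1L, 3L), c(2L, 4L))
  fw3 <- model_forward(m3, b$x_train)
  expect_equal(fw2$embedding, fw3$embedding, tolerance = 1e-12)
})
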