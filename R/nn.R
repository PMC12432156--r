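# Minimal feed-forward neural-network engine: explicit matrices, ReLU
# nonlinearities, hand-derived reverse-mode gradients, and Adam. Kept
# deliberately small — just what the encoder/decoder/head architectures and
# the gradient-based attribution methods need.

# ---- nested parameter containers -------------------------------------------

is_param_leaf <- function(x) is.numeric(x)

nested_map <- function(x, f) {
  if (is_param_leaf(x)) return(f(x))
  lapply(x, nested_map, f = f)
}

nested_map2 <- function(x, y, f) {
  if (is_param_leaf(x)) return(f(x, y))
  out <- x
  for (nm in seq_along(x)) out[[nm]] <- nested_map2(x[[nm]], y[[nm]], f)
  out
}

nested_zeros <- function(x) nested_map(x, function(a) a * 0)

nested_add <- function(x, y) nested_map2(x, y, `+`)

nested_max_abs <- function(x) {
  if (is_param_leaf(x)) return(if (length(x)) max(abs(x)) else 0)
  max(vapply(x, nested_max_abs, 0), 0)
}

# ---- multilayer perceptron --------------------------------------------------

# sizes: integer vector c(in, hidden..., out); ReLU between layers, linear out.
mlp_init <- function(sizes) {
  L <- length(sizes) - 1
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- sizes[l]
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / fan_in)),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b)
}

mlp_forward <- function(mlp, X) {
  L <- length(mlp$W)
  A <- vector("list", L + 1)
  Z <- vector("list", L)
  A[[1]] <- X
  n <- nrow(X)
  for (l in seq_len(L)) {
    Z[[l]] <- A[[l]] %*% mlp$W[[l]] + rep(mlp$b[[l]], each = n)
    A[[l + 1]] <- if (l < L) pmax(Z[[l]], 0) else Z[[l]]
  }
  list(out = A[[L + 1]], A = A, Z = Z)
}

# dOut: gradient w.r.t. the MLP output (n x out). Returns parameter grads and
# the gradient w.r.t. the input matrix.
mlp_backward <- function(mlp, cache, dOut) {
  L <- length(mlp$W)
  gW <- vector("list", L); gb <- vector("list", L)
  dZ <- dOut
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(cache$A[[l]], dZ)
    gb[[l]] <- colSums(dZ)
    dA <- tcrossprod(dZ, mlp$W[[l]])
    if (l > 1) dZ <- dA * (cache$Z[[l - 1]] > 0)
  }
  list(grads = list(W = gW, b = gb), dX = dA)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(theta) {
  list(m = nested_zeros(theta), v = nested_zeros(theta), t = 0L)
}

# freeze: optional character vector of top-level theta component names whose
# parameters are not updated.
adam_step <- function(theta, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, freeze = character()) {
  state$t <- state$t + 1L
  t <- state$t
  upd_leaf <- function(th, g, m, v) {
    m2 <- beta1 * m + (1 - beta1) * g
    v2 <- beta2 * v + (1 - beta2) * g^2
    mh <- m2 / (1 - beta1^t)
    vh <- v2 / (1 - beta2^t)
    list(theta = th - lr * mh / (sqrt(vh) + eps), m = m2, v = v2)
  }
  walk <- function(th, g, m, v, frozen) {
    if (is_param_leaf(th)) {
      if (frozen) return(list(theta = th, m = m, v = v))
      return(upd_leaf(th, g, m, v))
    }
    out_t <- th; out_m <- m; out_v <- v
    for (nm in seq_along(th)) {
      r <- walk(th[[nm]], g[[nm]], m[[nm]], v[[nm]], frozen)
      out_t[[nm]] <- r$theta; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
    }
    list(theta = out_t, m = out_m, v = out_v)
  }
  out_t <- theta; out_m <- state$m; out_v <- state$v
  for (nm in names(theta)) {
    r <- walk(theta[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]],
              frozen = nm %in% freeze)
    out_t[[nm]] <- r$theta; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
  }
  list(theta = out_t, state = list(m = out_m, v = out_v, t = t))
}
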