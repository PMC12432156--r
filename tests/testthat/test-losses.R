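test_that("masked MSE matches hand computation and honors masks", {
  expect_equal(masked_mse(c(1, 2), c(1, 2))$value, 0)
  l <- masked_mse(c(0, 0), c(1, 3))
  expect_equal(l$value, 5)
  expect_equal(l$n_observed, 2L)
  # all-masked batch contributes nothing
  l0 <- masked_mse(c(0, 0), c(1, 3), mask = c(FALSE, FALSE))
  expect_equal(l0$value, 0)
  expect_equal(l0$n_observed, 0L)
  # NA targets are masked implicitly
  expect_equal(masked_mse(c(0, 0), c(1, NA))$value, 1)
  # padding a batch with masked samples never changes the value
  expect_equal(
    masked_mse(c(0, 0, 9, 9), c(1, 3, 0, 0), mask = c(TRUE, TRUE, FALSE, FALSE))$value,
    5
  )
})

test_that("masked cross-entropy matches softmax hand computations", {
  # uniform logits over K classes -> log K
  for (K in c(2, 3, 7)) {
    lg <- matrix(0, 4, K)
    l <- masked_cross_entropy(lg, rep(0L, 4))
    expect_equal(l$value, log(K), tolerance = 1e-12)
  }
  # 2-class, logits (ln 3, 0), true class 0 -> -ln(3/4)
  lg <- matrix(c(log(3), 0), 1, 2)
  expect_equal(masked_cross_entropy(lg, 0L)$value, -log(3 / 4), tolerance = 1e-12)
  # all masked -> 0
  expect_equal(masked_cross_entropy(lg, 0L, mask = FALSE)$value, 0)
  # out-of-range unmasked code errors
  expect_error(masked_cross_entropy(lg, 5L), "out of range")
})

test_that("Cox loss matches explicit risk-set enumeration on random instances", {
  # singleton with an event: risk - log exp(risk) = 0
  expect_equal(cox_ph_loss(2.3, 1, 1)$value, 0)
  # worked 3-sample example
  r <- c(2, 1, 0)
  v <- cox_ph_loss(r, c(1, 2, 3), c(1, 1, 1))$value
  expect_equal(v, -((2 - log(exp(2) + exp(1) + 1)) + (1 - log(exp(1) + 1)) + 0) / 3,
               tolerance = 1e-12)
  # no events -> 0 with warning
  expect_warning(l <- cox_ph_loss(r, c(1, 2, 3), c(0, 0, 0)), "no unmasked events")
  expect_equal(l$value, 0)
  # 50 random instances vs brute-force oracle
  set.seed(11)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    risk <- rnorm(n)
    time <- rexp(n)
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    expect_equal(cox_ph_loss(risk, time, event)$value,
                 oracle_cox(risk, time, event), tolerance = 1e-10)
  }
})

test_that("Cox loss is invariant to shifting all risk scores", {
  set.seed(4)
  risk <- rnorm(20); time <- rexp(20); event <- rbinom(20, 1, 0.6)
  event[1] <- 1
  a <- cox_ph_loss(risk, time, event)$value
  b <- cox_ph_loss(risk + 17.5, time, event)$value
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("MMD matches the O(n^2) double-loop oracle and is non-negative", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(4:16, 1); m <- sample(4:16, 1); d <- sample(2:5, 1)
    z <- matrix(rnorm(n * d), n, d)
    p <- matrix(rnorm(m * d), m, d)
    bw <- 2 * d
    got <- mmd_loss(z, bandwidth = bw, prior = p)
    expect_equal(got, oracle_mmd(z, p, bw), tolerance = 1e-10)
    expect_gte(got, -1e-12)
  }
  # identical samples -> exactly 0
  z <- matrix(rnorm(12), 4, 3)
  expect_equal(mmd_loss(z, prior = z), 0, tolerance = 1e-14)
  # far-away latent: cross term vanishes
  z10 <- matrix(10, 8, 2) + matrix(rnorm(16, sd = 0.01), 8, 2)
  p <- matrix(rnorm(16), 8, 2)
  v <- mmd_loss(z10, bandwidth = 4, prior = p)
  expect_equal(v, oracle_mmd(z10, p, 4), tolerance = 1e-10)
  expect_error(mmd_loss(z, bandwidth = 0), "bandwidth")
})

test_that("triplet loss matches hand distances and the degenerate identity", {
  a <- matrix(c(0, 0), 1, 2)
  p <- matrix(c(0, 1), 1, 2)
  n <- matrix(c(0, 3), 1, 2)
  expect_equal(triplet_loss(a, p, n, margin = 1), 0)
  expect_equal(triplet_loss(a, p, n, margin = 3), 1)
  # a = p, far negative -> 0
  expect_equal(triplet_loss(a, a, n, margin = 1), 0)
  # a = p = n -> margin
  expect_equal(triplet_loss(a, a, a, margin = 0.7), 0.7)
  # random batch vs oracle
  set.seed(5)
  A <- matrix(rnorm(30), 10, 3); P <- matrix(rnorm(30), 10, 3); N <- matrix(rnorm(30), 10, 3)
  expect_equal(triplet_loss(A, P, N, 1.2), oracle_triplet(A, P, N, 1.2), tolerance = 1e-12)
})

test_that("combine_losses sums plainly when disabled and weights when enabled", {
  tl <- list(a = task_loss(1, 5L), b = task_loss(2.5, 5L))
  expect_equal(combine_losses(tl), 3.5)
  # enabled with all s_t = 0 reduces to the plain sum
  expect_equal(combine_losses(tl, log_vars = c(a = 0, b = 0), enabled = TRUE), 3.5)
  # analytic gradient d/ds = -exp(-s) L + 1 checked by central differences
  L <- c(a = 0.8, b = 2.0)
  s <- c(a = 0.3, b = -0.5)
  f <- function(sv) combine_losses(as.list(L), log_vars = sv, enabled = TRUE)
  h <- 1e-6
  for (nm in names(s)) {
    sp <- s; sm <- s
    sp[nm] <- sp[nm] + h; sm[nm] <- sm[nm] - h
    num <- (f(sp) - f(sm)) / (2 * h)
    expect_equal(num, -exp(-s[[nm]]) * L[[nm]] + 1, tolerance = 1e-5)
  }
  expect_error(combine_losses(list()), "no loss terms")
})

test_that("loss gradients agree with finite differences", {
  set.seed(31)
  h <- 1e-6
  # MSE
  pred <- rnorm(6); targ <- rnorm(6); mask <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  g <- masked_mse_grad(pred, targ, mask)
  for (i in seq_along(pred)) {
    pp <- pred; pm <- pred; pp[i] <- pp[i] + h; pm[i] <- pm[i] - h
    num <- (masked_mse(pp, targ, mask)$value - masked_mse(pm, targ, mask)$value) / (2 * h)
    expect_equal(g[i], num, tolerance = 1e-4)
  }
  # cross-entropy
  lg <- matrix(rnorm(12), 4, 3); cls <- c(0L, 2L, NA, 1L)
  G <- masked_cross_entropy_grad(lg, cls)
  for (i in 1:4) for (j in 1:3) {
    lp <- lg; lm <- lg; lp[i, j] <- lp[i, j] + h; lm[i, j] <- lm[i, j] - h
    num <- (masked_cross_entropy(lp, cls)$value - masked_cross_entropy(lm, cls)$value) / (2 * h)
    expect_equal(G[i, j], num, tolerance = 1e-4)
  }
  # Cox
  risk <- rnorm(8); time <- rexp(8); event <- rbinom(8, 1, 0.7); event[1] <- 1
  g <- cox_ph_loss_grad(risk, time, event)
  for (i in 1:8) {
    rp <- risk; rm <- risk; rp[i] <- rp[i] + h; rm[i] <- rm[i] - h
    num <- (cox_ph_loss(rp, time, event)$value - cox_ph_loss(rm, time, event)$value) / (2 * h)
    expect_equal(g[i], num, tolerance = 1e-4)
  }
  # MMD (fixed prior)
  z <- matrix(rnorm(8), 4, 2); p <- matrix(rnorm(10), 5, 2); bw <- 4
  G <- mmd_loss_grad(z, p, bw)
  for (i in 1:4) for (j in 1:2) {
    zp <- z; zm <- z; zp[i, j] <- zp[i, j] + h; zm[i, j] <- zm[i, j] - h
    num <- (mmd_loss(zp, bandwidth = bw, prior = p) - mmd_loss(zm, bandwidth = bw, prior = p)) / (2 * h)
    expect_equal(G[i, j], num, tolerance = 1e-4)
  }
  # triplet
  A <- matrix(rnorm(6), 3, 2); P <- matrix(rnorm(6), 3, 2); N <- matrix(rnorm(6), 3, 2)
  gr <- triplet_loss_grad(A, P, N, 1)
  for (i in 1:3) for (j in 1:2) {
    Ap <- A; Am <- A; Ap[i, j] <- Ap[i, j] + h; Am[i, j] <- Am[i, j] - h
    num <- (triplet_loss(Ap, P, N, 1) - triplet_loss(Am, P, N, 1)) / (2 * h)
    expect_equal(gr$anchor[i, j], num, tolerance = 1e-4)
  }
})
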