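spec_small <- synthetic_spec(
  n_train = 100, n_test = 40, latent_dim_true = 4,
  modalities = list(rna = list(n_features = 30, noise_sd = 0.3),
                    cnv = list(n_features = 20, noise_sd = 0.3)),
  targets = list(class_label = list(kind = "categorical", effect_size = 2, n_classes = 3),
                 score = list(kind = "numeric", effect_size = 2, noise_sd = 0.1)),
  seed = 7
)

test_that("latent generation is deterministic under the seed and matches normal moments", {
  a <- generate_latent(spec_small)
  b <- generate_latent(spec_small)
  expect_identical(a, b)
  expect_equal(dim(a$latent), c(100, 4))
  # 1-d latent at n = 400: sample moments near standard normal
  s1 <- synthetic_spec(n_train = 400, latent_dim_true = 1,
                       modalities = spec_small$modalities, seed = 3)
  z <- generate_latent(s1)$latent
  expect_lt(abs(mean(z)), 0.2)
  expect_lt(abs(stats::sd(z) - 1), 0.2)
  expect_error(generate_latent(spec_small, n = 0), "positive count")
})

test_that("modalities are linear latent maps with the stated rank and PCA structure", {
  z <- generate_latent(spec_small)$latent
  m0 <- generate_modality(z, "rna", 25, noise_sd = 0)
  expect_lte(qr(m0$values)$rank, 4)
  expect_equal(m0$feature_ids, sprintf("feat_rna_%d", 1:25))
  # determinism
  expect_identical(m0, generate_modality(z, "rna", 25, noise_sd = 0))
  # PCA recovers the 4-dimensional latent variance
  s4 <- synthetic_spec(n_train = 400, latent_dim_true = 4,
                       modalities = spec_small$modalities, seed = 5)
  z4 <- generate_latent(s4)$latent
  m <- generate_modality(z4, "rna", 200, noise_sd = 0.1)
  pv <- prcomp(t(m$values))$sdev^2
  expect_gte(sum(pv[1:4]) / sum(pv), 0.9)
  expect_error(generate_modality(z, "rna", 0), "n_features")
})

test_that("targets carry the planted signal at the stated effect sizes", {
  set.seed(1)
  z <- matrix(rnorm(400 * 4), 400, 4)
  rownames(z) <- paste0("s", 1:400)
  # numeric: OLS on the true latent recovers R^2 >= 0.95
  tg <- generate_targets(z, list(y = list(kind = "numeric", effect_size = 2, noise_sd = 0.1)),
                         seed = 2)
  fit <- lm(tg$metadata$y ~ z)
  expect_gte(summary(fit)$r.squared, 0.95)
  # null categorical effect: labels independent of latent
  tg0 <- generate_targets(z, list(cl = list(kind = "categorical", effect_size = 0, n_classes = 3)),
                          seed = 3)
  f <- as.factor(tg0$metadata$cl)
  pred <- nnet_multinom_safe(z, f)(z)
  ba <- mean(vapply(levels(f), function(l) mean(pred[f == l] == l), 0))
  expect_lt(ba, 0.45)  # near chance (1/3) on training data itself
  # survival: censoring_rate 0 -> all events
  tgs <- generate_targets(z, list(os = list(kind = "survival", effect_size = 1,
                                            censoring_rate = 0)), seed = 4)
  expect_true(all(tgs$metadata$os_event == 1))
  # requested censoring approximately achieved
  tgc <- generate_targets(z, list(os = list(kind = "survival", effect_size = 1,
                                            censoring_rate = 0.3)), seed = 5)
  expect_lt(abs(mean(tgc$metadata$os_event == 0) - 0.3), 0.1)
  expect_error(generate_targets(z, list(x = list(kind = "wavelet")), seed = 1), "unknown kind")
})

test_that("survival construction orders risk correctly (C-index of the true predictor)", {
  set.seed(9)
  z <- matrix(rnorm(400 * 4), 400, 4)
  rownames(z) <- paste0("s", 1:400)
  tg <- generate_targets(z, list(os = list(kind = "survival", effect_size = 1,
                                           censoring_rate = 0.2)), seed = 6)
  ci <- concordance_index(tg$truth$os$linear_predictor,
                          tg$metadata$os_time, tg$metadata$os_event)
  expect_gte(ci, 0.7)
})

test_that("batch shift is an affine per-feature change with identity at (0, 1)", {
  z <- generate_latent(spec_small)$latent
  m <- generate_modality(z, "rna", 40, noise_sd = 0.2)
  expect_identical(apply_batch_shift(m, 0, 1), m)
  shifted <- apply_batch_shift(m, offset = 5, scale = 1, seed = 3)
  d <- rowMeans(shifted$values) - rowMeans(m$values)
  expect_lt(abs(mean(d) - 5), 0.8)
  expect_error(apply_batch_shift(m, 1, scale = -2), "positive")
})

test_that("label masking blanks exactly the requested count and nothing else", {
  md <- tibble::tibble(sample_id = paste0("s", 1:100),
                       a = rnorm(100), b = sample(letters[1:3], 100, TRUE))
  expect_identical(mask_labels(md, "a", 0), md)
  m1 <- mask_labels(md, "a", 1)
  expect_true(all(is.na(m1$a)))
  m3 <- mask_labels(md, "a", 0.3, seed = 4)
  expect_equal(sum(is.na(m3$a)), 30)
  expect_identical(m3$b, md$b)
  expect_error(mask_labels(md, "zz", 0.5), "unknown variable")
})

test_that("signal monotonicity: categorical separability is non-decreasing in effect size", {
  for (sd_seed in 1:3) {
    accs <- vapply(c(0, 0.5, 1, 2), function(es) {
      set.seed(100 + sd_seed)
      z <- matrix(rnorm(300 * 3), 300, 3)
      rownames(z) <- paste0("s", 1:300)
      tg <- generate_targets(z, list(cl = list(kind = "categorical", effect_size = es,
                                               n_classes = 3)), seed = 10 + sd_seed)
      f <- factor(tg$metadata$cl)
      tr <- 1:200; te <- 201:300
      fit <- nnet_multinom_safe(z[tr, ], f[tr])
      pred <- fit(z[te, ])
      mean(vapply(intersect(levels(f), unique(f[te])), function(l) {
        mean(pred[f[te] == l] == l)
      }, 0))
    }, 0)
    # allow tiny Monte-Carlo wiggle while requiring the overall trend
    expect_true(all(diff(accs) > -0.05))
    expect_gt(accs[4], accs[1])
  }
})

test_that("the full simulator is reproducible and writes a readable folder layout", {
  d1 <- simulate_multiomics(spec_small)
  d2 <- simulate_multiomics(spec_small)
  expect_identical(d1$train$modalities$rna$values, d2$train$modalities$rna$values)
  expect_identical(d1$test$metadata, d2$test$metadata)
  td <- withr::local_tempdir()
  write_dataset(d1, td)
  back <- read_omics_dataset(file.path(td, "train"), file.path(td, "test"))
  expect_equal(back$train$modalities$rna$values, d1$train$modalities$rna$values,
               tolerance = 1e-12)
  expect_equal(back$test$modalities$cnv$values, d1$test$modalities$cnv$values,
               tolerance = 1e-12)
  expect_equal(back$train$metadata$class_label, d1$train$metadata$class_label)
})
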