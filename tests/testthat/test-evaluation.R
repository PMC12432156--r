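test_that("regression metrics match their closed forms", {
  tr <- evaluate_regression(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(tr), c(mse = 0, r_squared = 1, pearson_r = 1))
  # constant prediction at the truth mean gives R^2 = 0
  truth <- c(1, 2, 3, 6)
  expect_warning(r0 <- evaluate_regression(rep(mean(truth), 4), truth), "undefined")
  expect_equal(r0$r_squared, 0)
  # hand-computed case
  p <- c(1, 2, 3); t2 <- c(2, 2, 2 + 1e-3)
  got <- evaluate_regression(p, t2)
  expect_equal(got$mse, mean((p - t2)^2))
  expect_equal(got$r_squared, 1 - sum((t2 - p)^2) / sum((t2 - mean(t2))^2))
  expect_equal(got$pearson_r, cor(p, t2))
  expect_error(evaluate_regression(1, 1), "at least 2")
})

test_that("classification metrics match explicit confusion-matrix oracles", {
  # worked example: truth AABB, pred ABBB -> balanced accuracy 0.75
  got <- evaluate_classification(c("A", "B", "B", "B"), c("A", "A", "B", "B"))
  expect_equal(got$balanced_accuracy, 0.75)
  # perfect predictions
  pm <- diag(3)[c(1, 2, 3, 1), ]; colnames(pm) <- c("a", "b", "c")
  perfect <- evaluate_classification(pm, c("a", "b", "c", "a"))
  expect_equal(perfect$balanced_accuracy, 1)
  expect_equal(perfect$f1_weighted, 1)
  expect_equal(perfect$auroc_weighted, 1)
  expect_equal(perfect$kappa, 1)
  expect_error(evaluate_classification(c("a", "a"), c("a", "a")), ">= 2 classes")
  # 100 random instances vs the oracle
  set.seed(2)
  for (i in 1:100) {
    K <- sample(2:4, 1); n <- sample(8:30, 1)
    lev <- letters[1:K]
    truth <- sample(lev, n, TRUE)
    while (length(unique(truth)) < 2) truth <- sample(lev, n, TRUE)
    scores <- matrix(rnorm(n * K), n, K, dimnames = list(NULL, lev))
    got <- evaluate_classification(scores, truth)
    pred <- lev[max.col(scores, ties.method = "first")]
    want <- oracle_confusion_metrics(truth, pred, lev)
    expect_equal(got$balanced_accuracy, want$balanced_accuracy, tolerance = 1e-10)
    expect_equal(got$f1_weighted, want$f1_weighted, tolerance = 1e-10)
    expect_equal(got$kappa, want$kappa, tolerance = 1e-10)
  }
})

test_that("weighted AUROC matches pROC on binary and multiclass data", {
  set.seed(4)
  for (i in 1:20) {
    n <- 40
    truth <- sample(c("x", "y"), n, TRUE)
    while (length(unique(truth)) < 2) truth <- sample(c("x", "y"), n, TRUE)
    sc <- cbind(x = rnorm(n), y = rnorm(n))
    got <- evaluate_classification(sc, truth)
    aucs <- vapply(c("x", "y"), function(cl) {
      as.numeric(pROC::auc(pROC::roc(truth == cl, sc[, cl], quiet = TRUE,
                                     direction = "<")))
    }, 0)
    w <- table(factor(truth, c("x", "y"))) / n
    expect_equal(got$auroc_weighted, sum(aucs * as.numeric(w)), tolerance = 1e-10)
  }
})

test_that("concordance index matches exhaustive pair enumeration", {
  # hand case: perfectly anti-ordered times
  expect_equal(concordance_index(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1)
  # all risks tied -> 0.5
  expect_equal(concordance_index(rep(1, 5), 1:5, rep(1, 5)), 0.5)
  set.seed(6)
  for (i in 1:100) {
    n <- sample(4:15, 1)
    risk <- sample(rnorm(5), n, TRUE)  # induce ties
    time <- sample(rexp(6), n, TRUE)
    event <- rbinom(n, 1, 0.6)
    got <- suppressWarnings(concordance_index(risk, time, event))
    want <- oracle_cindex(risk, time, event)
    if (is.na(want)) {
      expect_warning(expect_true(is.na(concordance_index(risk, time, event))))
    } else {
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
  # negated risk flips concordance (up to tie mass)
  risk <- rnorm(50); time <- rexp(50); event <- rbinom(50, 1, 0.7)
  c1 <- concordance_index(risk, time, event)
  c2 <- concordance_index(-risk, time, event)
  expect_equal(c1, 1 - c2, tolerance = 1e-10)
  # near 0.5 for random risks at large n
  set.seed(7)
  cr <- concordance_index(rnorm(2000), rexp(2000), rbinom(2000, 1, 0.7))
  expect_lt(abs(cr - 0.5), 0.05)
})

test_that("concordance index agrees with the survival package", {
  set.seed(8)
  risk <- rnorm(80); time <- rexp(80); event <- rbinom(80, 1, 0.6)
  want <- survival::concordance(survival::Surv(time, event) ~ risk, reverse = TRUE)$concordance
  expect_equal(concordance_index(risk, time, event), want, tolerance = 1e-10)
})

test_that("paired bootstrap pairs indices, reports CIs and detects planted differences", {
  set.seed(9)
  n <- 60
  truth <- sample(c("a", "b"), n, TRUE)
  acc <- function(pred, tr) mean(pred == tr)
  # identical predictions: zero difference, p ~ 1
  pb <- paired_bootstrap(truth, truth, truth, acc, n_boot = 100, seed = 1)
  expect_equal(pb$mean_diff, 0)
  expect_gte(pb$p_value, 0.99)
  expect_equal(nrow(pb$replicates), 100)
  # identical resample indices for both models in every replicate: a metric
  # that depends only on the resampled truth must agree exactly
  idx_metric <- function(pred, tr) sum(as.integer(factor(tr, c("a", "b"))))
  pb2 <- paired_bootstrap(truth, rev(truth), truth, idx_metric, n_boot = 50, seed = 2)
  expect_identical(pb2$replicates$model_a, pb2$replicates$model_b)
  # planted difference: A perfect, B random -> CI excludes 0, p < 0.01
  predA <- truth
  predB <- sample(c("a", "b"), n, TRUE)
  pb3 <- paired_bootstrap(predA, predB, truth, acc, n_boot = 100, seed = 3)
  expect_gt(pb3$ci_diff[1], 0)
  expect_lt(pb3$p_value, 0.01)
})

test_that("classical baselines recover separable synthetic signal", {
  spec <- synthetic_spec(
    n_train = 120, n_test = 60, latent_dim_true = 3,
    modalities = list(rna = list(n_features = 30, noise_sd = 0.3)),
    targets = list(cl = list(kind = "categorical", effect_size = 3, n_classes = 2)),
    seed = 21
  )
  b <- harmonize(simulate_multiomics(spec), task_spec(c(cl = "classification")))
  res <- run_baselines(b, "cl", cv_folds = 3, seed = 1)
  expect_setequal(res$metrics$learner, c("random_forest", "svm", "xgboost"))
  expect_true(all(res$metrics$f1_weighted >= 0.9))
  # survival baseline
  specs <- synthetic_spec(
    n_train = 150, n_test = 80, latent_dim_true = 3,
    modalities = list(rna = list(n_features = 30, noise_sd = 0.3)),
    targets = list(os = list(kind = "survival", effect_size = 1.5, censoring_rate = 0.2)),
    seed = 22
  )
  bs <- harmonize(simulate_multiomics(specs), task_spec(c(os = "survival")))
  rs <- run_baselines(bs, "os", cv_folds = 3, seed = 1)
  expect_equal(rs$metrics$learner, "random_survival_forest")
  expect_gt(rs$metrics$c_index, 0.6)
  expect_error(run_baselines(b, "nope"), "unknown target")
})
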