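#' Regression metrics
#'
#' Mean squared error, `R^2 = 1 - SS_res/SS_tot`, and Pearson correlation over
#' observed pairs.
#'
#' @param pred,truth Numeric vectors (NAs in `truth` dropped pairwise).
#' @return A one-row tibble with `mse`, `r_squared`, `pearson_r`.
#' @export
evaluate_regression <- function(pred, truth) {
  ok <- !is.na(truth) & !is.na(pred)
  pred <- pred[ok]; truth <- truth[ok]
  if (length(pred) < 2) of_abort("need at least 2 observed pairs.")
  ss_res <- sum((truth - pred)^2)
  ss_tot <- sum((truth - mean(truth))^2)
  r <- if (ss_tot < 1e-300 || stats::var(pred) == 0) {
    of_warn("Pearson correlation undefined (zero variance); reported as NA.")
    NA_real_
  } else {
    stats::cor(pred, truth)
  }
  tibble::tibble(mse = mean((pred - truth)^2),
                 r_squared = 1 - ss_res / ss_tot,
                 pearson_r = r)
}

# Rank-based one-vs-rest AUROC (Mann-Whitney form).
auroc_binary <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Area under the precision-recall curve by the step interpolation used for
# average precision.
aupr_binary <- function(score, positive) {
  n1 <- sum(positive)
  if (n1 == 0 || n1 == length(positive)) return(NA_real_)
  ord <- order(score, decreasing = TRUE)
  pos <- positive[ord]
  tp <- cumsum(pos)
  prec <- tp / seq_along(pos)
  sum(prec[pos]) / n1
}

#' Classification metrics
#'
#' Balanced accuracy (mean per-class recall), prevalence-weighted F1, AUROC
#' and AUPR (one-vs-rest), and Cohen's kappa.
#'
#' @param pred_scores Matrix of class scores/probabilities (samples x classes,
#'   columns named by class) or a vector of predicted labels (in which case
#'   the rank-based metrics are NA).
#' @param truth Vector of true class labels.
#' @return One-row tibble with `balanced_accuracy`, `f1_weighted`,
#'   `auroc_weighted`, `aupr_weighted`, `kappa`.
#' @export
evaluate_classification <- function(pred_scores, truth) {
  truth <- as.character(truth)
  ok <- !is.na(truth)
  if (is.matrix(pred_scores)) {
    pred_scores <- pred_scores[ok, , drop = FALSE]
  } else {
    pred_scores <- pred_scores[ok]
  }
  truth <- truth[ok]
  if (length(unique(truth)) < 2) of_abort("need >= 2 classes present in truth.")
  if (is.matrix(pred_scores)) {
    classes <- colnames(pred_scores) %||% as.character(seq_len(ncol(pred_scores)) - 1)
    pred <- classes[max.col(pred_scores, ties.method = "first")]
  } else {
    classes <- sort(unique(c(truth, as.character(pred_scores))))
    pred <- as.character(pred_scores)
  }
  extra <- setdiff(unique(truth), classes)
  if (length(extra)) {
    of_warn(sprintf("truth classes outside the prediction classes excluded: %s",
                    paste(extra, collapse = ", ")))
    keep <- truth %in% classes
    truth <- truth[keep]; pred <- pred[keep]
    if (is.matrix(pred_scores)) pred_scores <- pred_scores[keep, , drop = FALSE]
  }
  lev <- classes
  cm <- table(factor(truth, lev), factor(pred, lev))
  n <- sum(cm)
  support <- rowSums(cm)
  present <- support > 0
  recall <- diag(cm) / pmax(support, 1)
  precision <- diag(cm) / pmax(colSums(cm), 1)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (pe >= 1) 0 else (po - pe) / (1 - pe)
  w <- support / n
  auroc <- aupr <- NA_real_
  if (is.matrix(pred_scores)) {
    au <- vapply(lev, function(cl) {
      auroc_binary(pred_scores[, cl], truth == cl)
    }, 0)
    ap <- vapply(lev, function(cl) {
      aupr_binary(pred_scores[, cl], truth == cl)
    }, 0)
    auroc <- sum(au[present] * w[present], na.rm = TRUE) / sum(w[present][!is.na(au[present])])
    aupr <- sum(ap[present] * w[present], na.rm = TRUE) / sum(w[present][!is.na(ap[present])])
  }
  tibble::tibble(balanced_accuracy = mean(recall[present]),
                 f1_weighted = sum(f1[present] * w[present]) / sum(w[present]),
                 auroc_weighted = auroc,
                 aupr_weighted = aupr,
                 kappa = kappa)
}

#' Harrell's concordance index
#'
#' Over comparable pairs — an event sample i and any sample j with a longer
#' follow-up time — the fraction where the model assigns i the higher risk;
#' risk ties count 0.5. Higher risk is expected to mean earlier events.
#'
#' @param risk Numeric risk scores.
#' @param time,event Follow-up times and 0/1 event indicators.
#' @return Scalar in \[0, 1\], or NA (with a warning) when no pair is
#'   comparable.
#' @export
concordance_index <- function(risk, time, event) {
  ok <- !(is.na(risk) | is.na(time) | is.na(event))
  risk <- risk[ok]; time <- time[ok]; event <- event[ok]
  ev <- which(event == 1)
  num <- 0; den <- 0
  for (i in ev) {
    later <- time > time[i]
    den <- den + sum(later)
    num <- num + sum(risk[i] > risk[later]) + 0.5 * sum(risk[i] == risk[later])
  }
  if (den == 0) {
    of_warn("no comparable pairs; concordance undefined.")
    return(NA_real_)
  }
  num / den
}

#' Evaluate a trained model on the test split
#'
#' @param model A trained `of_model`.
#' @param bundle The `harmonized_bundle`.
#' @param split `"test"` (default) or `"train"`.
#' @param idx Optional row indices within the split (e.g. fine-tuning
#'   held-out samples).
#' @return A tibble with one row per (target, metric).
#' @export
evaluate_model <- function(model, bundle, split = "test", idx = NULL) {
  xs <- if (split == "test") bundle$x_test else bundle$x_train
  ys <- if (split == "test") bundle$y_test else bundle$y_train
  if (!is.null(idx)) {
    sub <- bundle_subset(bundle, split, idx)
    xs <- sub$x; ys <- sub$y
  }
  pr <- predict(model, xs)
  rows <- list()
  for (t in names(model$targets_info)) {
    kind <- model$targets_info[[t]]$kind
    lab <- ys[[t]]
    metrics <- if (kind == "regression") {
      evaluate_regression(pr$preds[[t]][lab$mask], lab$y[lab$mask])
    } else if (kind == "classification") {
      map <- model$code_maps[[t]]
      truth <- names(sort(map))[lab$y[lab$mask] + 1L]
      evaluate_classification(pr$preds[[t]][lab$mask, , drop = FALSE], truth)
    } else {
      tibble::tibble(c_index = concordance_index(pr$preds[[t]][lab$mask],
                                                 lab$time[lab$mask], lab$event[lab$mask]))
    }
    rows[[t]] <- tidyr::pivot_longer(metrics, dplyr::everything(),
                                     names_to = "metric", values_to = "value") |>
      dplyr::mutate(target = t, task = kind, .before = 1)
  }
  dplyr::bind_rows(rows)
}

# ---- classical baselines -----------------------------------------------------

#' Classical machine-learning baselines on the same task
#'
#' Trains random forests, support-vector machines, and gradient-boosted trees
#' (regression/classification) or random survival forests (survival) on the
#' early-fused training features, tuning each over a small default grid by
#' k-fold cross-validation on the training data, then evaluates on the test
#' split with the same metrics as the neural models.
#'
#' @param bundle A `harmonized_bundle`.
#' @param target Name of the target to model (default: the first).
#' @param cv_folds Cross-validation folds (default 5).
#' @param seed Integer seed.
#' @param learners Subset of `c("random_forest", "svm", "xgboost")`.
#' @return List with `metrics` (tibble: learner x metric) and `predictions`
#'   (named list of test-set predictions).
#' @export
run_baselines <- function(bundle, target = names(bundle$y_train)[1], cv_folds = 5,
                          seed = 1, learners = c("random_forest", "svm", "xgboost")) {
  lab <- bundle$y_train[[target]]
  if (is.null(lab)) of_abort(sprintf("unknown target '%s'.", target))
  kind <- lab$kind
  Xtr <- fuse(bundle$x_train, "early")
  Xte <- fuse(bundle$x_test, "early")
  keep <- lab$mask
  Xtr <- Xtr[keep, , drop = FALSE]
  if (kind == "survival") {
    return(run_survival_baseline(bundle, target, Xtr, Xte, keep, cv_folds, seed))
  }
  ytr <- lab$y[keep]
  if (kind == "classification") {
    map <- bundle$code_maps[[target]]
    levs <- names(sort(map))
    ytr_f <- factor(levs[ytr + 1L], levels = levs)
  }
  folds <- with_seed(derive_seed(seed, 1), {
    sample(rep(seq_len(cv_folds), length.out = nrow(Xtr)))
  })
  cv_score <- function(fit_fun, pred_fun, grid) {
    scores <- vapply(seq_len(nrow(grid)), function(g) {
      errs <- vapply(seq_len(cv_folds), function(f) {
        tr <- folds != f; va <- !tr
        fit <- fit_fun(Xtr[tr, , drop = FALSE],
                       if (kind == "classification") ytr_f[tr] else ytr[tr],
                       grid[g, , drop = FALSE])
        p <- pred_fun(fit, Xtr[va, , drop = FALSE])
        if (kind == "classification") {
          mean(as.character(p) != as.character(ytr_f[va]))
        } else {
          mean((p - ytr[va])^2)
        }
      }, 0)
      mean(errs)
    }, 0)
    grid[which.min(scores), , drop = FALSE]
  }
  out_metrics <- list(); out_preds <- list()
  run_learner <- function(name, grid, fit_fun, pred_fun, score_fun) {
    best <- with_seed(derive_seed(seed, 2), cv_score(fit_fun, pred_fun, grid))
    fit <- with_seed(derive_seed(seed, 3), {
      fit_fun(Xtr, if (kind == "classification") ytr_f else ytr, best[1, , drop = FALSE])
    })
    pred <- score_fun(fit, Xte)
    out_preds[[name]] <<- pred
    te <- bundle$y_test[[target]]
    m <- if (kind == "classification") {
      truth <- names(sort(bundle$code_maps[[target]]))[te$y[te$mask] + 1L]
      evaluate_classification(pred[te$mask, , drop = FALSE], truth)
    } else {
      evaluate_regression(pred[te$mask], te$y[te$mask])
    }
    out_metrics[[name]] <<- dplyr::mutate(m, learner = name, .before = 1)
  }
  if ("random_forest" %in% learners) {
    grid <- expand.grid(mtry_frac = c(0.1, 0.33, 0.6), ntree = c(200))
    fit_fun <- function(X, y, prm) {
      randomForest::randomForest(X, y, ntree = prm$ntree,
                                 mtry = max(1, floor(prm$mtry_frac * ncol(X))))
    }
    pred_fun <- function(fit, X) predict(fit, X)
    score_fun <- function(fit, X) {
      if (kind == "classification") predict(fit, X, type = "prob") else predict(fit, X)
    }
    run_learner("random_forest", grid, fit_fun, pred_fun, score_fun)
  }
  if ("svm" %in% learners) {
    grid <- expand.grid(cost = c(0.1, 1, 10))
    fit_fun <- function(X, y, prm) {
      e1071::svm(X, y, cost = prm$cost, probability = (kind == "classification"))
    }
    pred_fun <- function(fit, X) predict(fit, X)
    score_fun <- function(fit, X) {
      if (kind == "classification") {
        attr(predict(fit, X, probability = TRUE), "probabilities")[, levels(ytr_f), drop = FALSE]
      } else {
        predict(fit, X)
      }
    }
    run_learner("svm", grid, fit_fun, pred_fun, score_fun)
  }
  if ("xgboost" %in% learners) {
    grid <- expand.grid(max_depth = c(2, 4), nrounds = c(50, 150))
    fit_fun <- function(X, y, prm) {
      if (kind == "classification") {
        K <- length(levels(y))
        dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
        xgboost::xgb.train(params = list(objective = "multi:softprob",
                                         num_class = K,
                                         max_depth = prm$max_depth, nthread = 1),
                           data = dtrain, nrounds = prm$nrounds, verbose = 0)
      } else {
        dtrain <- xgboost::xgb.DMatrix(X, label = y)
        xgboost::xgb.train(params = list(objective = "reg:squarederror",
                                         max_depth = prm$max_depth, nthread = 1),
                           data = dtrain, nrounds = prm$nrounds, verbose = 0)
      }
    }
    as_prob_matrix <- function(p, n) {
      pm <- if (is.matrix(p)) p else matrix(p, n, byrow = TRUE)
      colnames(pm) <- levels(ytr_f)
      pm
    }
    pred_fun <- function(fit, X) {
      p <- predict(fit, xgboost::xgb.DMatrix(X))
      if (kind == "classification") {
        levels(ytr_f)[max.col(as_prob_matrix(p, nrow(X)))]
      } else {
        p
      }
    }
    score_fun <- function(fit, X) {
      p <- predict(fit, xgboost::xgb.DMatrix(X))
      if (kind == "classification") as_prob_matrix(p, nrow(X)) else p
    }
    run_learner("xgboost", grid, fit_fun, pred_fun, score_fun)
  }
  list(metrics = dplyr::bind_rows(out_metrics), predictions = out_preds)
}

run_survival_baseline <- function(bundle, target, Xtr, Xte, keep, cv_folds, seed) {
  lab <- bundle$y_train[[target]]
  time <- lab$time[keep]; event <- lab$event[keep]
  grid <- expand.grid(mtry_frac = c(0.1, 0.33, 0.6), num.trees = 300)
  folds <- with_seed(derive_seed(seed, 1), sample(rep(seq_len(cv_folds), length.out = nrow(Xtr))))
  dtr <- data.frame(Xtr, check.names = TRUE)
  fit_one <- function(rows, prm) {
    df <- dtr[rows, , drop = FALSE]
    df$.time <- time[rows]; df$.event <- event[rows]
    ranger::ranger(survival::Surv(.time, .event) ~ ., data = df,
                   num.trees = prm$num.trees,
                   mtry = max(1, floor(prm$mtry_frac * ncol(Xtr))),
                   num.threads = 1, seed = derive_seed(seed, 5))
  }
  risk_of <- function(fit, X) {
    # expected cumulative hazard as the risk score
    p <- predict(fit, data.frame(X, check.names = TRUE), num.threads = 1)
    rowSums(p$chf)
  }
  cv <- vapply(seq_len(nrow(grid)), function(g) {
    mean(vapply(seq_len(cv_folds), function(f) {
      tr <- which(folds != f); va <- which(folds == f)
      fit <- fit_one(tr, grid[g, , drop = FALSE])
      ci <- concordance_index(risk_of(fit, Xtr[va, , drop = FALSE]), time[va], event[va])
      if (is.na(ci)) 0.5 else 1 - ci
    }, 0))
  }, 0)
  best <- grid[which.min(cv), , drop = FALSE]
  fit <- fit_one(seq_len(nrow(Xtr)), best[1, , drop = FALSE])
  te <- bundle$y_test[[target]]
  risk <- risk_of(fit, Xte)
  ci <- concordance_index(risk[te$mask], te$time[te$mask], te$event[te$mask])
  list(metrics = tibble::tibble(learner = "random_survival_forest", c_index = ci),
       predictions = list(random_survival_forest = risk))
}

# ---- paired bootstrap --------------------------------------------------------

#' Paired bootstrap comparison of two models
#'
#' Draws `n_boot` resamples of test instances with replacement, computes the
#' metric for both prediction sets on identical indices in every replicate,
#' reports 95% percentile confidence intervals per model, and a paired
#' two-sided t-test on the per-replicate differences. Replicates on which the
#' metric is undefined (e.g. a single-class resample) are redrawn, keeping
#' `n_boot` constant.
#'
#' @param preds_a,preds_b Predictions for models A and B on the same test
#'   instances (vectors, or matrices with one row per instance).
#' @param truth List or vector of ground truth; passed to `metric`.
#' @param metric Function `(preds, truth_subset) -> scalar`.
#' @param n_boot Number of replicates (default 100).
#' @param seed Integer seed.
#' @return A `bootstrap_comparison` object: tibble of replicate scores,
#'   CIs, mean difference, t statistic and p-value.
#' @export
paired_bootstrap <- function(preds_a, preds_b, truth, metric, n_boot = 100, seed = 1) {
  n <- if (is.matrix(preds_a)) nrow(preds_a) else length(preds_a)
  nb <- if (is.matrix(preds_b)) nrow(preds_b) else length(preds_b)
  if (n != nb) of_abort("predictions are not aligned on the same test instances.")
  take <- function(p, idx) if (is.matrix(p)) p[idx, , drop = FALSE] else p[idx]
  sub_truth <- function(tr, idx) {
    if (is.list(tr) && !is.data.frame(tr)) lapply(tr, function(v) v[idx]) else tr[idx]
  }
  scores_a <- numeric(n_boot); scores_b <- numeric(n_boot)
  redraws <- 0L
  with_seed(seed, {
    b <- 1L
    while (b <= n_boot) {
      idx <- sample.int(n, n, replace = TRUE)
      sa <- tryCatch(suppressWarnings(metric(take(preds_a, idx), sub_truth(truth, idx))),
                     error = function(e) NA_real_)
      sb <- tryCatch(suppressWarnings(metric(take(preds_b, idx), sub_truth(truth, idx))),
                     error = function(e) NA_real_)
      if (is.na(sa) || is.na(sb)) {
        redraws <- redraws + 1L
        if (redraws > 50 * n_boot) of_abort("metric undefined on nearly every bootstrap replicate.")
        next
      }
      scores_a[b] <- sa; scores_b[b] <- sb
      b <- b + 1L
    }
  })
  d <- scores_a - scores_b
  tt <- if (stats::sd(d) < 1e-15) {
    list(statistic = c(t = 0), p.value = 1)
  } else {
    stats::t.test(scores_a, scores_b, paired = TRUE)
  }
  structure(list(
    replicates = tibble::tibble(replicate = seq_len(n_boot),
                                model_a = scores_a, model_b = scores_b),
    ci_a = stats::quantile(scores_a, c(0.025, 0.975), names = FALSE),
    ci_b = stats::quantile(scores_b, c(0.025, 0.975), names = FALSE),
    ci_diff = stats::quantile(d, c(0.025, 0.975), names = FALSE),
    mean_diff = mean(d),
    t_statistic = unname(tt$statistic),
    p_value = tt$p.value,
    n_boot = n_boot, redraws = redraws, seed = seed
  ), class = "bootstrap_comparison")
}

#' @export
print.bootstrap_comparison <- function(x, ...) {
  cat(sprintf("<bootstrap_comparison> %d replicates\n", x$n_boot))
  cat(sprintf("  A: mean %.4f [%.4f, %.4f]\n", mean(x$replicates$model_a), x$ci_a[1], x$ci_a[2]))
  cat(sprintf("  B: mean %.4f [%.4f, %.4f]\n", mean(x$replicates$model_b), x$ci_b[1], x$ci_b[2]))
  cat(sprintf("  diff %.4f [%.4f, %.4f]; paired t = %.3f, p = %.3g\n",
              x$mean_diff, x$ci_diff[1], x$ci_diff[2], x$t_statistic, x$p_value))
  invisible(x)
}
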