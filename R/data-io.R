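#' Construct an omics matrix
#'
#' The basic container for one data modality: a numeric features x samples
#' matrix with unique feature and sample IDs. Missing entries are allowed on
#' input and handled by [clean_modality()].
#'
#' @param values Numeric matrix, features x samples.
#' @param modality_name Label for the modality.
#' @param feature_ids,sample_ids Character vectors; default to dimnames.
#' @return An `omics_matrix` object.
#' @export
omics_matrix <- function(values, modality_name = "omics",
                         feature_ids = rownames(values),
                         sample_ids = colnames(values)) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids)) feature_ids <- paste0("feat_", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    of_abort("ID lengths inconsistent with matrix dimensions.")
  }
  if (anyDuplicated(feature_ids)) of_abort(sprintf(
    "duplicate feature IDs in modality '%s': %s", modality_name,
    paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", ")))
  if (anyDuplicated(sample_ids)) of_abort(sprintf(
    "duplicate sample IDs in modality '%s': %s", modality_name,
    paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(list(modality_name = modality_name,
                 feature_ids = feature_ids,
                 sample_ids = sample_ids,
                 values = values),
            class = "omics_matrix")
}

as_omics_matrix <- function(x) {
  if (inherits(x, "omics_matrix")) return(x)
  omics_matrix(x)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> '%s': %d features x %d samples\n",
              x$modality_name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

write_omics_csv <- function(m, path) {
  df <- data.frame(feature_id = m$feature_ids, m$values,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_omics_csv <- function(path, modality_name) {
  if (!file.exists(path)) of_abort(sprintf("missing file: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) of_abort(sprintf("%s: expected feature-ID column plus samples.", path))
  fid <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & col != "" & toupper(col) != "NA")
      if (length(bad)) {
        of_abort(sprintf("%s: non-numeric value '%s' at row %d, column '%s'.",
                         path, col[bad[1]], bad[1], names(vals)[j]))
      }
      vals[[j]] <- num
    }
  }
  omics_matrix(as.matrix(vals), modality_name = modality_name,
               feature_ids = fid, sample_ids = names(vals))
}

#' Read a train/test multi-omics dataset from disk
#'
#' Expects `<train_dir>` and `<test_dir>` to each contain one
#' `omics_<modality>.csv` per requested modality plus `clin.csv`. Samples are
#' restricted, per split, to the IDs present in every modality file *and* the
#' metadata; modalities are restricted to the names available in both splits.
#'
#' @param train_dir,test_dir Folder paths.
#' @param modality_names Modalities to load; default: every `omics_*.csv`
#'   common to the two folders.
#' @param on_modality_mismatch `"intersect"` (proceed on the common set, with
#'   a warning) or `"error"`.
#' @return List with `train` and `test`, each containing `modalities` (named
#'   list of `omics_matrix`, sample-aligned) and `metadata` (tibble with a
#'   `sample_id` column).
#' @export
read_omics_dataset <- function(train_dir, test_dir, modality_names = NULL,
                               on_modality_mismatch = c("intersect", "error")) {
  on_modality_mismatch <- match.arg(on_modality_mismatch)
  list_mods <- function(dir) {
    f <- list.files(dir, pattern = "^omics_.*\\.csv$")
    sub("^omics_(.*)\\.csv$", "\\1", f)
  }
  tr_mods <- list_mods(train_dir)
  te_mods <- list_mods(test_dir)
  if (is.null(modality_names)) {
    modality_names <- intersect(tr_mods, te_mods)
    if (!setequal(tr_mods, te_mods)) {
      msg <- sprintf("modalities differ between splits (train: %s; test: %s); using common set {%s}.",
                     paste(tr_mods, collapse = ","), paste(te_mods, collapse = ","),
                     paste(modality_names, collapse = ","))
      if (on_modality_mismatch == "error") of_abort(msg) else of_warn(msg)
    }
  }
  if (length(modality_names) == 0) of_abort("no modality common to train and test.")

  read_split <- function(dir) {
    mods <- lapply(modality_names, function(nm) {
      read_omics_csv(file.path(dir, paste0("omics_", nm, ".csv")), nm)
    })
    names(mods) <- modality_names
    clin_path <- file.path(dir, "clin.csv")
    if (!file.exists(clin_path)) of_abort(sprintf("missing file: %s", clin_path))
    meta <- utils::read.csv(clin_path, check.names = FALSE, stringsAsFactors = FALSE)
    id_col <- if ("sample_id" %in% names(meta)) "sample_id" else names(meta)[1]
    meta$sample_id <- as.character(meta[[id_col]])
    if (anyDuplicated(meta$sample_id)) of_abort(sprintf("%s: duplicate sample IDs.", clin_path))
    common <- Reduce(intersect, c(lapply(mods, function(m) m$sample_ids),
                                  list(meta$sample_id)))
    if (length(common) == 0) of_abort(sprintf("%s: empty sample intersection across files.", dir))
    dropped <- sum(vapply(mods, function(m) length(setdiff(m$sample_ids, common)), 0L)) +
      length(setdiff(meta$sample_id, common))
    if (dropped > 0) of_log("%s: dropped %d sample entries outside the common ID set", dir, dropped)
    mods <- lapply(mods, function(m) {
      omics_matrix(m$values[, common, drop = FALSE], m$modality_name,
                   m$feature_ids, common)
    })
    meta <- tibble::as_tibble(meta[match(common, meta$sample_id), , drop = FALSE])
    list(modalities = mods, metadata = meta)
  }
  list(train = read_split(train_dir), test = read_split(test_dir))
}

#' Clean one training modality
#'
#' Imputes missing entries to the per-feature median, drops samples whose
#' values are entirely missing, and removes low-variance features: those with
#' variance at or below the `variance_quantile` quantile of the per-feature
#' variance distribution (zero-variance features always go).
#'
#' @param m An `omics_matrix` (features x samples).
#' @param variance_quantile Quantile cutoff in \[0, 1); default 0.01.
#' @param impute Impute missing values? Default TRUE.
#' @return The cleaned `omics_matrix`.
#' @export
clean_modality <- function(m, variance_quantile = 0.01, impute = TRUE) {
  m <- as_omics_matrix(m)
  v <- m$values
  if (length(v) == 0) of_abort("empty modality.")
  all_na_sample <- colSums(!is.na(v)) == 0
  if (any(all_na_sample)) {
    of_log("modality '%s': dropping %d all-missing samples", m$modality_name, sum(all_na_sample))
    v <- v[, !all_na_sample, drop = FALSE]
  }
  if (impute && anyNA(v)) {
    med <- apply(v, 1, stats::median, na.rm = TRUE)
    med[is.na(med)] <- 0
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- med[idx[, 1]]
  }
  vars <- apply(v, 1, stats::var)
  vars[is.na(vars)] <- 0
  # zero-variance features always go; among the rest, drop those at or below
  # the variance_quantile quantile of the variance distribution
  cut <- stats::quantile(vars, variance_quantile, names = FALSE)
  keep <- vars > 0 & vars >= cut
  if (!any(keep)) {
    of_abort(sprintf("modality '%s': all features removed by the variance filter; lower `variance_quantile`.",
                     m$modality_name))
  }
  if (sum(!keep) > 0) {
    of_log("modality '%s': removed %d low-variance features", m$modality_name, sum(!keep))
  }
  omics_matrix(v[keep, , drop = FALSE], m$modality_name,
               m$feature_ids[keep], colnames(v))
}

#' Fit a leakage-safe per-feature scaler on training data
#'
#' Optionally applies `log1p`, then centers and scales every feature to mean
#' 0 and (population) standard deviation 1. The returned scaler stores the
#' training centers/scales and is the only statistic ever applied to test
#' data.
#'
#' @param m Cleaned training `omics_matrix`.
#' @param log_transform Apply `log1p` first? Requires non-negative values.
#' @return List with `matrix` (the transformed training `omics_matrix`) and
#'   `scaler` (centers, scales, log flag, feature IDs).
#' @export
fit_scaler <- function(m, log_transform = FALSE) {
  m <- as_omics_matrix(m)
  v <- m$values
  if (log_transform) {
    if (any(v < 0, na.rm = TRUE)) of_abort("log transform requested but negative values present.")
    v <- log1p(v)
  }
  centers <- rowMeans(v)
  n <- ncol(v)
  scales <- sqrt(rowMeans((v - centers)^2))  # population sd (ddof 0)
  if (any(scales <= 0)) of_abort("zero-variance feature reached fit_scaler; clean first.")
  vt <- (v - centers) / scales
  scaler <- structure(list(modality_name = m$modality_name,
                           feature_ids = m$feature_ids,
                           centers = centers, scales = scales,
                           log_transform = log_transform),
                      class = "omics_scaler")
  list(matrix = omics_matrix(vt, m$modality_name, m$feature_ids, m$sample_ids),
       scaler = scaler)
}

#' Transform test data with train-fitted statistics only
#'
#' Restricts a test modality to the training-selected features (in training
#' order) and applies the train-fitted log/center/scale transform. No test
#' statistic is ever computed, so a distribution shift in the test data
#' remains visible after transformation.
#'
#' @param test Test `omics_matrix`.
#' @param scaler An `omics_scaler` from [fit_scaler()].
#' @param selected_features Features to keep (training order); defaults to
#'   every feature the scaler knows.
#' @return Transformed `omics_matrix` (selected features x samples).
#' @export
harmonize_test <- function(test, scaler, selected_features = scaler$feature_ids) {
  test <- as_omics_matrix(test)
  stopifnot(inherits(scaler, "omics_scaler"))
  missing <- setdiff(selected_features, test$feature_ids)
  if (length(missing)) {
    of_abort(sprintf("modality '%s': %d selected features absent from test data: %s%s",
                     test$modality_name, length(missing),
                     paste(utils::head(missing, 5), collapse = ", "),
                     if (length(missing) > 5) ", ..." else ""))
  }
  pos <- match(selected_features, scaler$feature_ids)
  if (anyNA(pos)) of_abort("selected features not covered by the scaler.")
  v <- test$values[selected_features, , drop = FALSE]
  if (anyNA(v)) {
    # impute with *training* centers (back-transformed if needed)
    fill <- scaler$centers[pos]
    if (scaler$log_transform) fill <- expm1(fill)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- fill[idx[, 1]]
  }
  if (scaler$log_transform) {
    if (any(v < 0)) of_abort("log transform fitted but test values are negative.")
    v <- log1p(v)
  }
  v <- (v - scaler$centers[pos]) / scaler$scales[pos]
  omics_matrix(v, test$modality_name, selected_features, test$sample_ids)
}

#' One-hot encode clinical covariates as an extra modality
#'
#' Categorical columns expand to one indicator column per level; numeric
#' columns pass through with missing entries imputed to the median. Constant
#' columns are dropped with a warning. The result is a modality named
#' `"covariates"` that fuses like any omics layer.
#'
#' @param metadata Tibble with `sample_id` plus covariate columns.
#' @param covariates Character vector of column names; empty gives an
#'   empty modality.
#' @return An `omics_matrix` (possibly with zero features).
#' @export
encode_covariates <- function(metadata, covariates) {
  missing <- setdiff(covariates, names(metadata))
  if (length(missing)) of_abort(sprintf("unknown covariate column(s): %s",
                                        paste(missing, collapse = ", ")))
  n <- nrow(metadata)
  cols <- list()
  for (cv in covariates) {
    x <- metadata[[cv]]
    if (is.numeric(x)) {
      if (anyNA(x)) x[is.na(x)] <- stats::median(x, na.rm = TRUE)
      if (stats::var(x) == 0) {
        of_warn(sprintf("covariate '%s' is constant; dropped.", cv))
        next
      }
      cols[[cv]] <- x
    } else {
      x <- as.character(x)
      x[is.na(x)] <- "missing"
      lev <- sort(unique(x))
      if (length(lev) < 2) {
        of_warn(sprintf("covariate '%s' has a single level; dropped.", cv))
        next
      }
      for (l in lev) cols[[paste0(cv, "_", l)]] <- as.numeric(x == l)
    }
  }
  vals <- if (length(cols)) t(as.matrix(as.data.frame(cols, check.names = FALSE))) else
    matrix(0, 0, n)
  omics_matrix(vals, "covariates",
               feature_ids = names(cols) %||% character(),
               sample_ids = metadata$sample_id %||% paste0("s", seq_len(n)))
}

#' Declare the prediction tasks
#'
#' @param targets Named character vector or list mapping target variable name
#'   to task kind: `"regression"`, `"classification"`, or `"survival"`. A
#'   survival entry's name is the base name of a `<name>_time` /
#'   `<name>_event` column pair, or supply `survival_cols`.
#' @param survival_cols Optional named list mapping a survival target name to
#'   `c(time =, event =)` column names.
#' @param covariates Optional metadata columns used as an extra input
#'   modality.
#' @return A `task_spec` object.
#' @export
task_spec <- function(targets = c(), survival_cols = NULL, covariates = character()) {
  targets <- unlist(targets)
  if (length(targets) > 0 && is.null(names(targets))) {
    of_abort("`targets` must be named: c(variable = kind).")
  }
  bad <- setdiff(unname(targets), c("regression", "classification", "survival"))
  if (length(bad)) of_abort(sprintf("unknown task kind(s): %s", paste(bad, collapse = ", ")))
  structure(list(targets = targets, survival_cols = survival_cols,
                 covariates = covariates),
            class = "task_spec")
}

survival_columns <- function(spec, name) {
  sc <- spec$survival_cols[[name]]
  if (!is.null(sc)) return(c(time = unname(sc[["time"]]), event = unname(sc[["event"]])))
  c(time = paste0(name, "_time"), event = paste0(name, "_event"))
}

#' Encode target labels into arrays and missing-label masks
#'
#' Classification labels are mapped to integer codes `0..K-1` using a code
#' map fitted on training labels only; test labels outside the training codes
#' are masked with a warning. Survival targets become a (time, event) pair
#' with a joint mask (missing when either member is). Regression targets pass
#' through.
#'
#' @param metadata Metadata tibble.
#' @param spec A [task_spec()].
#' @param code_maps Optional previously fitted code maps (use the training
#'   maps when encoding test labels).
#' @return List with `labels` (named list; each regression/classification
#'   entry has `y` and `mask`, each survival entry `time`, `event`, `mask`),
#'   and `code_maps`.
#' @export
encode_targets <- function(metadata, spec, code_maps = NULL) {
  labels <- list()
  maps <- code_maps %||% list()
  for (nm in names(spec$targets)) {
    kind <- spec$targets[[nm]]
    if (kind == "survival") {
      sc <- survival_columns(spec, nm)
      for (cl in sc) if (!cl %in% names(metadata)) of_abort(sprintf("missing survival column '%s'.", cl))
      time <- as.numeric(metadata[[sc[["time"]]]])
      event <- as.numeric(metadata[[sc[["event"]]]])
      mask <- !(is.na(time) | is.na(event))
      if (any(event[mask] %notin% c(0, 1))) of_abort(sprintf("target '%s': event values must be 0/1.", nm))
      if (any(time[mask] < 0)) of_abort(sprintf("target '%s': negative times.", nm))
      labels[[nm]] <- list(kind = kind, time = time, event = event, mask = mask)
    } else {
      if (!nm %in% names(metadata)) of_abort(sprintf("missing target column '%s'.", nm))
      x <- metadata[[nm]]
      if (kind == "classification") {
        x <- as.character(x)
        if (is.null(maps[[nm]])) {
          lev <- sort(unique(x[!is.na(x)]))
          if (length(lev) < 2) of_abort(sprintf("target '%s': needs >= 2 classes in training.", nm))
          maps[[nm]] <- stats::setNames(seq_along(lev) - 1L, lev)
        }
        map <- maps[[nm]]
        codes <- unname(map[x])
        unseen <- !is.na(x) & is.na(codes)
        if (any(unseen)) {
          of_warn(sprintf("target '%s': %d labels unseen in training were masked.", nm, sum(unseen)))
        }
        labels[[nm]] <- list(kind = kind, y = as.integer(codes), mask = !is.na(codes),
                             n_classes = length(map))
      } else {
        y <- as.numeric(x)
        labels[[nm]] <- list(kind = kind, y = y, mask = !is.na(y))
      }
    }
  }
  list(labels = labels, code_maps = maps)
}

`%notin%` <- function(x, table) !(x %in% table)

#' Harmonize a train/test dataset into model-ready arrays
#'
#' The full leakage-safe import pipeline: clean each training modality
#' (impute, variance-filter), optionally select features by Laplacian score,
#' fit per-feature scalers on training data, transform the test split with
#' those training statistics only, encode covariates and targets, and align
#' sample order across modalities within each split.
#'
#' @param dataset Either a `multiomics_dataset` from [simulate_multiomics()]
#'   or the list returned by [read_omics_dataset()].
#' @param spec A [task_spec()].
#' @param variance_quantile Low-variance filter quantile (see
#'   [clean_modality()]).
#' @param feature_top_fraction If < 1, keep this fraction of features per
#'   modality by Laplacian score (see [select_features()]).
#' @param min_features Floor on the per-modality selected feature count.
#' @param redundancy_threshold Absolute-correlation pruning threshold.
#' @param log_transform Per-modality named logical (or single flag).
#' @return A `harmonized_bundle`: per-modality `train`/`test` arrays
#'   (samples x features), label arrays and masks, fitted scalers, selected
#'   feature lists, and class-code maps.
#' @export
harmonize <- function(dataset, spec,
                      variance_quantile = 0.01,
                      feature_top_fraction = 1,
                      min_features = 20,
                      redundancy_threshold = 0.8,
                      log_transform = FALSE) {
  train <- dataset$train; test <- dataset$test
  mods <- names(train$modalities)
  x_train <- list(); x_test <- list(); scalers <- list(); selected <- list()
  for (nm in mods) {
    lg <- if (length(log_transform) > 1) isTRUE(log_transform[[nm]]) else isTRUE(log_transform)
    cleaned <- clean_modality(train$modalities[[nm]], variance_quantile)
    fs <- fit_scaler(cleaned, log_transform = lg)
    Xt <- t(fs$matrix$values)  # samples x features
    sel <- colnames(Xt)
    if (feature_top_fraction < 1) {
      sc <- laplacian_score(Xt)
      sel <- select_features(Xt, sc, top_fraction = feature_top_fraction,
                             min_features = min_features,
                             redundancy_threshold = redundancy_threshold)
      Xt <- Xt[, sel, drop = FALSE]
    }
    x_train[[nm]] <- Xt
    scalers[[nm]] <- fs$scaler
    selected[[nm]] <- sel
    if (!is.null(test)) {
      ht <- harmonize_test(test$modalities[[nm]], fs$scaler, sel)
      x_test[[nm]] <- t(ht$values)
    }
  }
  if (length(spec$covariates) > 0) {
    cv_tr <- encode_covariates(train$metadata, spec$covariates)
    if (nrow(cv_tr$values) > 0) {
      fs <- fit_scaler(cv_tr)
      x_train[["covariates"]] <- t(fs$matrix$values)
      scalers[["covariates"]] <- fs$scaler
      selected[["covariates"]] <- fs$scaler$feature_ids
      if (!is.null(test)) {
        cv_te <- encode_covariates(test$metadata, spec$covariates)
        ht <- harmonize_test(cv_te, fs$scaler, fs$scaler$feature_ids)
        x_test[["covariates"]] <- t(ht$values)
      }
    }
  }
  enc_tr <- encode_targets(train$metadata, spec)
  enc_te <- if (!is.null(test)) encode_targets(test$metadata, spec, enc_tr$code_maps) else NULL
  structure(list(
    x_train = x_train,
    x_test = if (is.null(test)) NULL else x_test,
    y_train = enc_tr$labels,
    y_test = if (is.null(test)) NULL else enc_te$labels,
    code_maps = enc_tr$code_maps,
    scalers = scalers,
    selected_features = selected,
    task_spec = spec,
    train_sample_ids = rownames(x_train[[1]]),
    test_sample_ids = if (is.null(test)) NULL else rownames(x_test[[1]])
  ), class = "harmonized_bundle")
}

#' @export
print.harmonized_bundle <- function(x, ...) {
  dims <- vapply(x$x_train, ncol, 0L)
  cat(sprintf("<harmonized_bundle> %d train / %s test samples; modalities: %s\n",
              nrow(x$x_train[[1]]),
              if (is.null(x$x_test)) "0" else nrow(x$x_test[[1]]),
              paste(sprintf("%s(%d)", names(dims), dims), collapse = ", ")))
  invisible(x)
}

# Subset a bundle's split ("train" or "test") to row indices, returning
# x (list of matrices) and y (label list subset).
bundle_subset <- function(bundle, split = c("train", "test"), idx) {
  split <- match.arg(split)
  xs <- if (split == "train") bundle$x_train else bundle$x_test
  ys <- if (split == "train") bundle$y_train else bundle$y_test
  x <- lapply(xs, function(m) m[idx, , drop = FALSE])
  y <- lapply(ys, function(l) {
    out <- l
    for (f in intersect(names(l), c("y", "time", "event", "mask"))) out[[f]] <- l[[f]][idx]
    out
  })
  list(x = x, y = y)
}
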