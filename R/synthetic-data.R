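#' Specify a synthetic multi-omics dataset
#'
#' Builds the specification object consumed by [simulate_multiomics()]. The
#' generator draws a shared low-dimensional latent representation per sample,
#' maps it linearly (plus Gaussian noise) into each omics modality, and drives
#' continuous, categorical, and right-censored survival outcomes from the same
#' latent — the regime the multi-modal encoders are designed to exploit.
#'
#' @param n_train,n_test Sample counts per split.
#' @param latent_dim_true Dimension of the shared latent.
#' @param modalities Named list: each element `list(n_features =, noise_sd =)`.
#' @param targets Named list: each element `list(kind = "numeric"|"categorical"|"survival",
#'   effect_size =, n_classes =, censoring_rate =)` (the last two only where
#'   relevant).
#' @param label_missing_frac Fraction of labels per target to blank out.
#' @param batch_shift Named numeric vector (per modality) of mean offsets
#'   applied to the *test* split, emulating a batch / domain shift; 0 = none.
#' @param n_clusters If > 1, the latent is drawn as a Gaussian mixture with
#'   this many well-separated components instead of a single standard normal;
#'   the component label is exposed as a `cluster` column in the metadata.
#' @param cluster_sep Distance scale between mixture component means.
#' @param seed Integer seed; the whole dataset is a pure function of the spec
#'   plus this seed.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_train = 200,
                           n_test = 100,
                           latent_dim_true = 4,
                           modalities = list(
                             rna = list(n_features = 100, noise_sd = 0.5),
                             cnv = list(n_features = 100, noise_sd = 0.5)
                           ),
                           targets = list(
                             class_label = list(kind = "categorical",
                                                effect_size = 2, n_classes = 3)
                           ),
                           label_missing_frac = 0,
                           batch_shift = NULL,
                           n_clusters = 1,
                           cluster_sep = 4,
                           seed = 42) {
  spec <- structure(
    list(n_train = n_train, n_test = n_test,
         latent_dim_true = latent_dim_true,
         modalities = modalities, targets = targets,
         label_missing_frac = label_missing_frac,
         batch_shift = batch_shift,
         n_clusters = n_clusters, cluster_sep = cluster_sep,
         seed = seed),
    class = "synthetic_spec"
  )
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  bad <- character()
  if (!is_count(spec$n_train)) bad <- c(bad, "n_train must be a positive count")
  if (!(is_count(spec$n_test) || identical(spec$n_test, 0L) || identical(spec$n_test, 0))) {
    bad <- c(bad, "n_test must be a non-negative count")
  }
  if (!is_count(spec$latent_dim_true)) bad <- c(bad, "latent_dim_true must be a positive count")
  if (length(spec$modalities) < 1 || is.null(names(spec$modalities))) {
    bad <- c(bad, "modalities must be a named list")
  } else {
    for (nm in names(spec$modalities)) {
      m <- spec$modalities[[nm]]
      if (!is_count(m$n_features %||% 0)) bad <- c(bad, sprintf("modality '%s': n_features >= 1 required", nm))
      if (!is.numeric(m$noise_sd %||% -1) || m$noise_sd < 0) bad <- c(bad, sprintf("modality '%s': noise_sd must be >= 0", nm))
    }
  }
  for (nm in names(spec$targets)) {
    t <- spec$targets[[nm]]
    if (!(t$kind %||% "") %in% c("numeric", "categorical", "survival")) {
      bad <- c(bad, sprintf("target '%s': unknown kind", nm))
    }
    if (identical(t$kind, "categorical") && (t$n_classes %||% 0) < 2) {
      bad <- c(bad, sprintf("target '%s': n_classes >= 2 required", nm))
    }
    if (identical(t$kind, "survival") && !is_fraction(t$censoring_rate %||% 0)) {
      bad <- c(bad, sprintf("target '%s': censoring_rate must be in [0,1]", nm))
    }
  }
  if (!is_fraction(spec$label_missing_frac)) bad <- c(bad, "label_missing_frac must be in [0,1]")
  if (!is_count(spec$n_clusters)) bad <- c(bad, "n_clusters must be a positive count")
  if (length(bad)) of_abort(c("invalid synthetic_spec:", bad))
  invisible(spec)
}

#' Draw the shared latent matrix
#'
#' Rows are i.i.d. draws from a standard multivariate normal (or, when
#' `spec$n_clusters > 1`, a mixture of spherical normals with separated
#' means). Every downstream signal in the synthetic dataset flows from this
#' matrix.
#'
#' @param spec A [synthetic_spec()].
#' @param n Number of samples (defaults to `spec$n_train`).
#' @param seed Seed override (defaults to `spec$seed`).
#' @param center_seed Seed fixing the mixture component means (defaults to
#'   `seed`). Kept separate so train and test splits share one set of
#'   centers while drawing independent samples.
#' @return List with `latent` (n x latent_dim_true matrix) and `cluster`
#'   (integer component labels, all 1 when `n_clusters == 1`).
#' @export
generate_latent <- function(spec, n = spec$n_train, seed = spec$seed,
                            center_seed = seed) {
  validate_synthetic_spec(spec)
  if (!is_count(n)) of_abort("invalid synthetic_spec: n must be a positive count")
  d <- spec$latent_dim_true
  if (spec$n_clusters > 1) {
    # component means rescaled so the *minimum pairwise* center distance
    # equals cluster_sep — the separation parameter then means what it says
    # regardless of the random draw
    centers <- with_seed(center_seed,
                         matrix(stats::rnorm(spec$n_clusters * d),
                                spec$n_clusters, d))
    centers <- centers / max(min(stats::dist(centers)), 1e-9) * spec$cluster_sep
  }
  with_seed(seed, {
    if (spec$n_clusters > 1) {
      cl <- sample.int(spec$n_clusters, n, replace = TRUE)
      z <- centers[cl, , drop = FALSE] + matrix(stats::rnorm(n * d), n, d)
    } else {
      cl <- rep(1L, n)
      z <- matrix(stats::rnorm(n * d), n, d)
    }
    rownames(z) <- paste0("s", seq_len(n))
    list(latent = z, cluster = cl)
  })
}

#' Map a latent matrix into one omics modality
#'
#' `X = latent %*% t(W) + noise`, with loading matrix `W` (features x latent)
#' drawn once from `N(0, 1)` under `loading_seed` and i.i.d. Gaussian noise.
#' Returned in the features x samples orientation used by the on-disk format.
#'
#' @param latent Samples x latent matrix.
#' @param modality_name Label used in feature IDs (`feat_<name>_<i>`).
#' @param n_features Number of features to generate.
#' @param noise_sd Noise standard deviation (>= 0).
#' @param loading_seed Seed fixing `W`.
#' @param noise_seed Seed for the noise draws.
#' @return An `omics_matrix` (see [omics_matrix()]).
#' @export
generate_modality <- function(latent, modality_name, n_features, noise_sd = 0.5,
                              loading_seed = 1, noise_seed = 2) {
  if (!is.matrix(latent) || nrow(latent) == 0) of_abort("`latent` must be a non-empty matrix.")
  if (!is_count(n_features)) of_abort("`n_features` must be >= 1.")
  d <- ncol(latent)
  W <- with_seed(loading_seed, matrix(stats::rnorm(n_features * d), n_features, d))
  X <- latent %*% t(W)
  if (noise_sd > 0) {
    X <- X + with_seed(noise_seed,
                       matrix(stats::rnorm(length(X), sd = noise_sd), nrow(X), ncol(X)))
  }
  fid <- sprintf("feat_%s_%d", modality_name, seq_len(n_features))
  sid <- rownames(latent) %||% paste0("s", seq_len(nrow(latent)))
  omics_matrix(t(X), modality_name = modality_name,
               feature_ids = fid, sample_ids = sid)
}

# Calibrate an exponential censoring rate by bisection so that the realized
# censoring fraction approximates `target` for event times `et`.
calibrate_censoring <- function(et, target, tol = 0.005) {
  if (target <= 0) return(0)
  if (target >= 1) return(Inf)
  # P(censored) = mean P(C < T_i) with C ~ Exp(rc): increasing in rc
  pc <- function(rc) mean(1 - exp(-rc * et))
  lo <- 1e-8; hi <- 1e8
  for (it in 1:200) {
    mid <- sqrt(lo * hi)
    if (pc(mid) < target) lo <- mid else hi <- mid
    if (abs(pc(mid) - target) < tol) break
  }
  sqrt(lo * hi)
}

#' Generate outcome variables from the latent
#'
#' Numeric targets are noisy linear reads of the latent; categorical targets
#' are argmax draws of a softmax over class scores `latent %*% B` (class
#' separation grows with `effect_size`); survival targets draw event times
#' from an exponential with rate `exp(latent %*% gamma)` and overlay
#' independent exponential censoring whose rate is calibrated by bisection to
#' hit the requested censoring fraction.
#'
#' @param latent Samples x latent matrix.
#' @param target_specs Named list as in [synthetic_spec()].
#' @param seed Integer seed for the outcome noise and censoring draws.
#' @param coef_seed Integer seed for the generating coefficients. Use the
#'   same `coef_seed` across train and test splits so both are labeled by the
#'   same decision boundaries (defaults to `seed`).
#' @return List with `metadata` (a tibble; survival targets occupy
#'   `<name>_time` and `<name>_event` column pairs) and `truth` (per-target
#'   generating coefficients, for oracle checks).
#' @export
generate_targets <- function(latent, target_specs, seed = 1, coef_seed = seed) {
  if (!is.matrix(latent) || nrow(latent) == 0) of_abort("`latent` must be a non-empty matrix.")
  n <- nrow(latent); d <- ncol(latent)
  meta <- tibble::tibble(sample_id = rownames(latent) %||% paste0("s", seq_len(n)))
  truth <- list()
  coefs <- with_seed(coef_seed, {
    out <- list()
    for (nm in names(target_specs)) {
      ts <- target_specs[[nm]]
      es <- ts$effect_size %||% 1
      out[[nm]] <- if (identical(ts$kind, "categorical")) {
        list(B = matrix(stats::rnorm(d * ts$n_classes), d, ts$n_classes) * es)
      } else {
        v <- stats::rnorm(d)
        list(beta = v / sqrt(sum(v^2)) * es)
      }
    }
    out
  })
  with_seed(seed, {
    for (nm in names(target_specs)) {
      ts <- target_specs[[nm]]
      if (identical(ts$kind, "numeric")) {
        beta <- coefs[[nm]]$beta
        noise_sd <- ts$noise_sd %||% 0.5
        y <- as.numeric(latent %*% beta) + stats::rnorm(n, sd = noise_sd)
        meta[[nm]] <- y
        truth[[nm]] <- list(beta = beta)
      } else if (identical(ts$kind, "categorical")) {
        K <- ts$n_classes
        B <- coefs[[nm]]$B
        lns <- ts$label_noise_sd %||% 0.25
        scores <- latent %*% B + matrix(stats::rnorm(n * K, sd = max(lns, 1e-9)), n, K)
        lab <- paste0("class", max.col(scores))
        meta[[nm]] <- lab
        truth[[nm]] <- list(B = B)
      } else if (identical(ts$kind, "survival")) {
        gamma <- coefs[[nm]]$beta
        lp <- as.numeric(latent %*% gamma)
        et <- stats::rexp(n, rate = exp(lp))
        cr <- ts$censoring_rate %||% 0
        rc <- calibrate_censoring(et, cr)
        if (is.infinite(rc)) {
          ct <- rep(0, n)
        } else if (rc == 0) {
          ct <- rep(Inf, n)
        } else {
          ct <- stats::rexp(n, rate = rc)
        }
        meta[[paste0(nm, "_time")]] <- pmin(et, ct)
        meta[[paste0(nm, "_event")]] <- as.integer(et <= ct)
        truth[[nm]] <- list(gamma = gamma, linear_predictor = lp)
      } else {
        of_abort(sprintf("target '%s': unknown kind '%s'", nm, ts$kind %||% "?"))
      }
    }
  })
  list(metadata = meta, truth = truth)
}

#' Apply a per-feature affine batch shift to an omics matrix
#'
#' Emulates a batch / platform effect: each feature value becomes
#' `scale * x + offset_f`, where per-feature offsets are drawn around
#' `offset` (sd = |offset| / 4) so the shift is not perfectly uniform.
#' `offset = 0, scale = 1` is the identity.
#'
#' @param m An `omics_matrix`.
#' @param offset Mean per-feature additive shift.
#' @param scale Positive multiplicative factor.
#' @param seed Seed for the per-feature offset draws.
#' @return The shifted `omics_matrix`.
#' @export
apply_batch_shift <- function(m, offset = 0, scale = 1, seed = 1) {
  m <- as_omics_matrix(m)
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0) {
    of_abort("`scale` must be a single positive number.")
  }
  if (offset == 0 && scale == 1) return(m)
  p <- nrow(m$values)
  offs <- with_seed(seed, stats::rnorm(p, mean = offset, sd = abs(offset) / 4))
  m$values <- m$values * scale + offs
  m
}

#' Blank out a fraction of one metadata variable
#'
#' Sets exactly `floor(fraction * n)` entries of `variable` to `NA`,
#' chosen uniformly at random, leaving every other column untouched. Missing
#' labels are tolerated downstream through the masked losses.
#'
#' @param metadata A data frame with one row per sample.
#' @param variable Column to mask; for survival pass the time column name and
#'   both members of the pair are masked jointly if the event column
#'   (`sub("_time$", "_event", variable)`) exists.
#' @param fraction Fraction in \[0, 1\].
#' @param seed Seed.
#' @return The metadata tibble with `NA`s inserted.
#' @export
mask_labels <- function(metadata, variable, fraction, seed = 1) {
  if (!variable %in% names(metadata)) {
    of_abort(sprintf("unknown variable '%s' in metadata.", variable))
  }
  if (!is_fraction(fraction)) of_abort("`fraction` must be in [0, 1].")
  metadata <- tibble::as_tibble(metadata)
  n <- nrow(metadata)
  k <- floor(fraction * n)
  if (k == 0) return(metadata)
  idx <- with_seed(seed, sample.int(n, k))
  metadata[[variable]][idx] <- NA
  partner <- sub("_time$", "_event", variable)
  if (!identical(partner, variable) && partner %in% names(metadata)) {
    metadata[[partner]][idx] <- NA
  }
  metadata
}

#' Simulate a complete train/test multi-omics dataset
#'
#' Runs the full generator: shared latent per split, one linear-plus-noise
#' modality per entry of `spec$modalities` (loadings shared between splits so
#' train and test live in the same feature space), outcomes from the latent,
#' optional label masking, and optional batch shift applied to the test
#' split.
#'
#' @param spec A [synthetic_spec()].
#' @return A `multiomics_dataset`: list with `train` / `test`, each holding
#'   `modalities` (named list of `omics_matrix`) and `metadata` (tibble),
#'   plus `truth` (generating parameters) and `spec`.
#' @export
simulate_multiomics <- function(spec) {
  validate_synthetic_spec(spec)
  make_split <- function(n, split_seed, shift) {
    lt <- generate_latent(spec, n = n, seed = split_seed,
                          center_seed = derive_seed(spec$seed, 460))
    mods <- list()
    i <- 0
    for (nm in names(spec$modalities)) {
      i <- i + 1
      mspec <- spec$modalities[[nm]]
      m <- generate_modality(lt$latent, nm, mspec$n_features, mspec$noise_sd,
                             loading_seed = derive_seed(spec$seed, 100 + i),
                             noise_seed = derive_seed(split_seed, 200 + i))
      if (shift && !is.null(spec$batch_shift) && !is.null(spec$batch_shift[[nm]]) &&
          spec$batch_shift[[nm]] != 0) {
        m <- apply_batch_shift(m, offset = spec$batch_shift[[nm]], scale = 1,
                               seed = derive_seed(spec$seed, 300 + i))
      }
      mods[[nm]] <- m
    }
    tg <- generate_targets(lt$latent, spec$targets,
                           seed = derive_seed(split_seed, 400),
                           coef_seed = derive_seed(spec$seed, 450))
    meta <- tg$metadata
    if (spec$n_clusters > 1) meta$cluster <- paste0("c", lt$cluster)
    if (spec$label_missing_frac > 0) {
      for (nm in names(spec$targets)) {
        col <- if (identical(spec$targets[[nm]]$kind, "survival")) paste0(nm, "_time") else nm
        meta <- mask_labels(meta, col, spec$label_missing_frac,
                            seed = derive_seed(split_seed, 500))
      }
    }
    list(modalities = mods, metadata = meta, latent = lt$latent, truth = tg$truth)
  }
  train <- make_split(spec$n_train, derive_seed(spec$seed, 1), shift = FALSE)
  test <- if (spec$n_test > 0) {
    make_split(spec$n_test, derive_seed(spec$seed, 2), shift = TRUE)
  } else {
    NULL
  }
  structure(list(train = train, test = test, spec = spec), class = "multiomics_dataset")
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  cat(sprintf("<multiomics_dataset> %d train / %d test samples, %d modalities (%s)\n",
              x$spec$n_train, x$spec$n_test, length(x$spec$modalities),
              paste(names(x$spec$modalities), collapse = ", ")))
  invisible(x)
}

#' Write a simulated dataset to the on-disk folder layout
#'
#' Writes `<dir>/train/` and `<dir>/test/`, each containing one
#' `omics_<modality>.csv` per modality (features x samples, first column
#' feature IDs, header of sample IDs) plus `clin.csv` (samples x variables) —
#' the layout [read_omics_dataset()] consumes.
#'
#' @param dataset A `multiomics_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "multiomics_dataset"))
  for (split in c("train", "test")) {
    s <- dataset[[split]]
    if (is.null(s)) next
    sd <- file.path(dir, split)
    dir.create(sd, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(s$modalities)) {
      write_omics_csv(s$modalities[[nm]], file.path(sd, paste0("omics_", nm, ".csv")))
    }
    meta <- s$metadata
    utils::write.csv(meta, file.path(sd, "clin.csv"), row.names = FALSE)
  }
  invisible(dir)
}
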