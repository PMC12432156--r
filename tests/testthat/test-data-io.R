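make_toy_dirs <- function(root, drop_clin_sample = FALSE) {
  set.seed(2)
  sids <- paste0("s", 1:4)
  for (split in c("train", "test")) {
    d <- file.path(root, split)
    dir.create(d, recursive = TRUE)
    for (nm in c("rna", "cnv")) {
      m <- omicfuse:::omics_matrix(matrix(rnorm(12), 3, 4,
                                          dimnames = list(paste0(nm, 1:3), sids)), nm)
      omicfuse:::write_omics_csv(m, file.path(d, paste0("omics_", nm, ".csv")))
    }
    meta <- data.frame(sample_id = sids, grade = c("a", "a", "b", "b"), age = 1:4)
    if (drop_clin_sample && split == "train") meta <- meta[-2, ]
    write.csv(meta, file.path(d, "clin.csv"), row.names = FALSE)
  }
  root
}

test_that("read_omics_dataset loads and aligns a valid folder pair", {
  td <- make_toy_dirs(withr::local_tempdir())
  ds <- read_omics_dataset(file.path(td, "train"), file.path(td, "test"))
  expect_setequal(names(ds$train$modalities), c("rna", "cnv"))
  expect_equal(ncol(ds$train$modalities$rna$values), 4)
  expect_identical(ds$train$modalities$rna$sample_ids,
                   ds$train$modalities$cnv$sample_ids)
  expect_identical(ds$train$metadata$sample_id, ds$train$modalities$rna$sample_ids)
})

test_that("samples missing from clin.csv are dropped by intersection", {
  td <- make_toy_dirs(withr::local_tempdir(), drop_clin_sample = TRUE)
  ds <- read_omics_dataset(file.path(td, "train"), file.path(td, "test"))
  expect_equal(ncol(ds$train$modalities$rna$values), 3)
  expect_false("s2" %in% ds$train$metadata$sample_id)
  expect_equal(ncol(ds$test$modalities$rna$values), 4)
})

test_that("format errors are reported with names and coordinates", {
  td <- make_toy_dirs(withr::local_tempdir())
  file.remove(file.path(td, "test", "omics_cnv.csv"))
  # modality mismatch: intersection with warning, or error when configured
  expect_warning(ds <- read_omics_dataset(file.path(td, "train"), file.path(td, "test")),
                 "common set")
  expect_named(ds$train$modalities, "rna")
  expect_error(read_omics_dataset(file.path(td, "train"), file.path(td, "test"),
                                  on_modality_mismatch = "error"), "differ")
  # explicit request for a missing modality file
  expect_error(read_omics_dataset(file.path(td, "train"), file.path(td, "test"),
                                  modality_names = c("rna", "cnv")), "missing file")
  # non-numeric cell named with coordinates
  bad <- file.path(td, "train", "omics_rna.csv")
  lines <- readLines(bad)
  lines[2] <- sub(",[^,]*$", ",oops", lines[2])
  writeLines(lines, bad)
  expect_error(read_omics_dataset(file.path(td, "train"), file.path(td, "test"),
                                  modality_names = "rna"),
               "non-numeric value 'oops' at row 1")
  # duplicate sample IDs
  expect_error(omics_matrix(matrix(0, 2, 2), "x", c("f1", "f2"), c("s1", "s1")),
               "duplicate sample IDs")
})

test_that("cleaning imputes medians, drops zero-variance features and empty samples", {
  v <- rbind(c(1, 2, 3, NA), c(5, 5, 5, 5), c(0, 1, 4, 9))
  m <- omics_matrix(v, "rna", c("f1", "f2", "f3"), paste0("s", 1:4))
  cl <- clean_modality(m, variance_quantile = 0)
  expect_false("f2" %in% cl$feature_ids)     # constant feature removed
  expect_equal(cl$values["f1", "s4"], 2)     # median of {1,2,3}
  # an all-missing sample is dropped
  v2 <- rbind(c(1, 2, NA), c(4, 5, NA))
  m2 <- omics_matrix(v2, "rna", c("f1", "f2"), paste0("s", 1:3))
  cl2 <- clean_modality(m2, variance_quantile = 0)
  expect_equal(cl2$sample_ids, c("s1", "s2"))
  # removing everything errors with advice
  m3 <- omics_matrix(matrix(1, 2, 3), "rna", c("f1", "f2"), paste0("s", 1:3))
  expect_error(clean_modality(m3), "variance")
})

test_that("scaler centers to mean 0 and population sd 1; log transform guards sign", {
  set.seed(3)
  m <- omics_matrix(matrix(rexp(50), 5, 10), "rna")
  fs <- fit_scaler(m)
  expect_lt(max(abs(rowMeans(fs$matrix$values))), 1e-9)
  expect_lt(max(abs(sqrt(rowMeans(fs$matrix$values^2)) - 1)), 1e-9)
  # {2, 4} centers to {-1, +1} under the population-sd convention (sd = 1)
  m2 <- omics_matrix(matrix(c(2, 4), 1, 2), "x", "f1", c("s1", "s2"))
  expect_equal(as.numeric(fit_scaler(m2)$matrix$values), c(-1, 1))
  mneg <- omics_matrix(matrix(c(-1, 1, 0, 2), 2, 2), "x")
  expect_error(fit_scaler(mneg, log_transform = TRUE), "negative")
})

test_that("test harmonization uses train statistics only (leakage invariant)", {
  set.seed(4)
  tr <- omics_matrix(matrix(rnorm(200, mean = 3), 10, 20), "rna")
  fs <- fit_scaler(tr)
  # identical test -> identical transform
  same <- harmonize_test(tr, fs$scaler)
  expect_equal(same$values, fs$matrix$values, tolerance = 1e-12)
  # shifted test keeps its shift: mean approx +10 / scale, never re-centered
  shifted <- tr
  shifted$values <- shifted$values + 10
  ht <- harmonize_test(shifted, fs$scaler)
  expect_equal(rowMeans(ht$values), 10 / fs$scaler$scales, tolerance = 1e-9)
  # recomputing a scaler on test data gives a different transform: proof the
  # train statistics were used
  leaky <- fit_scaler(shifted)$matrix$values
  expect_gt(max(abs(leaky - ht$values)), 1)
  # missing selected feature is a hard error
  sub <- omics_matrix(tr$values[-1, , drop = FALSE], "rna",
                      tr$feature_ids[-1], tr$sample_ids)
  expect_error(harmonize_test(sub, fs$scaler), "absent from test")
})

test_that("covariate encoding one-hots categoricals and median-imputes numerics", {
  md <- tibble::tibble(sample_id = paste0("s", 1:6),
                       grade = c("A", "B", "C", "A", "B", "C"),
                       age = c(1, NA, 3, 2, 2, 2),
                       constant = rep("x", 6))
  cv <- encode_covariates(md, c("grade", "age"))
  oh <- cv$values[grep("^grade_", rownames(cv$values)), ]
  expect_true(all(colSums(oh) == 1))
  expect_equal(ncol(cv$values), 6)
  expect_equal(unname(cv$values["age", 2]), 2)  # median of {1,3,2,2,2}
  expect_warning(cv2 <- encode_covariates(md, c("grade", "constant")), "single level")
  expect_false(any(grepl("constant", rownames(cv2$values))))
  expect_equal(nrow(encode_covariates(md, character())$values), 0)
})

test_that("target encoding maps classes on train codes, masks NA and unseen labels", {
  md <- tibble::tibble(sample_id = paste0("s", 1:3), cl = c("A", "A", "B"))
  sp <- task_spec(c(cl = "classification"))
  enc <- encode_targets(md, sp)
  expect_equal(enc$labels$cl$y, c(0L, 0L, 1L))
  expect_true(all(enc$labels$cl$mask))
  md2 <- tibble::tibble(sample_id = "s9", cl = NA_character_)
  enc2 <- encode_targets(md2, sp, enc$code_maps)
  expect_false(enc2$labels$cl$mask)
  md3 <- tibble::tibble(sample_id = "s9", cl = "Z")
  expect_warning(enc3 <- encode_targets(md3, sp, enc$code_maps), "unseen")
  expect_false(enc3$labels$cl$mask)
  # survival jointly masks when either member missing
  mds <- tibble::tibble(sample_id = paste0("s", 1:3),
                        os_time = c(5, 3, NA), os_event = c(1, NA, 1))
  encs <- encode_targets(mds, task_spec(c(os = "survival")))
  expect_equal(encs$labels$os$mask, c(TRUE, FALSE, FALSE))
})

test_that("harmonize aligns samples and preserves feature order across splits", {
  spec <- synthetic_spec(n_train = 60, n_test = 30,
                         modalities = list(rna = list(n_features = 40, noise_sd = 0.4),
                                           cnv = list(n_features = 30, noise_sd = 0.4)),
                         seed = 11)
  ds <- simulate_multiomics(spec)
  b <- harmonize(ds, task_spec(c(class_label = "classification")),
                 feature_top_fraction = 0.5, min_features = 10)
  for (nm in names(b$x_train)) {
    expect_identical(colnames(b$x_train[[nm]]), colnames(b$x_test[[nm]]))
    expect_identical(rownames(b$x_train[[nm]]), rownames(b$x_train[[1]]))
  }
  expect_true(all(vapply(b$x_train, ncol, 0L) >= 10))
  expect_equal(length(b$y_train$class_label$y), 60)
})
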