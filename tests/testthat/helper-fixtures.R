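# A hand-built exactly-linear model F(x) = 2 x1 + 3 x2, constructed with the
# relu(x) - relu(-x) = x identity so the network is linear end to end.
linear_fixture <- function() {
  b <- structure(list(
    x_train = list(m = matrix(0, 2, 2, dimnames = list(c("s1", "s2"), c("f1", "f2")))),
    y_train = list(y = list(kind = "regression", y = c(0, 0), mask = c(TRUE, TRUE))),
    code_maps = list()
  ), class = "harmonized_bundle")
  sp <- model_spec("DirectPred", "early",
                   hyper = hyper_config(latent_dim = 2, hidden_dim_factor = 0.5,
                                        supervisor_hidden_dim = 4, validate = FALSE))
  m <- build_model(sp, b, seed = 1)
  I2 <- diag(2)
  m$theta$encoders$fused <- list(W = list(cbind(I2, -I2), rbind(I2, -I2)),
                                 b = list(numeric(4), numeric(2)))
  m$theta$heads$y <- list(W = list(cbind(I2, -I2), matrix(c(2, 3, -2, -3), 4, 1)),
                          b = list(numeric(4), numeric(1)))
  m$embedding_width <- 2L
  m
}
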