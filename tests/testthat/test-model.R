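# small shared fixtures: tiny images + a feature block with a plantable
# linear signal
tiny_inputs <- function(n, h = 22L, w = 40L, m = 6L, shift = 0, seed = 1L) {
  set.seed(seed)
  ximg <- array(rnorm(h * w * n), dim = c(h, w, n))
  y <- rep(c(0, 1), length.out = n)
  xfeat <- matrix(rnorm(n * m), n, m)
  xfeat[y == 1, 1] <- xfeat[y == 1, 1] + shift
  list(ximg = ximg, xfeat = xfeat, y = y)
}

test_that("network shape arithmetic matches a live forward pass", {
  cfg <- model_config()
  d <- network_dims(128L, 1655L, 10L, cfg)
  # closed form: conv 7x7 then 2x2 pool, twice
  expect_equal(d$h1, 122L); expect_equal(d$w1, 1649L)
  expect_equal(d$h2, 61L);  expect_equal(d$w2, 824L)
  expect_equal(d$h3, 55L);  expect_equal(d$w3, 818L)
  expect_equal(d$h4, 27L);  expect_equal(d$w4, 409L)
  expect_equal(d$q, 8L * 27L * 409L)
  expect_equal(d$input_dim, d$q + 10L)
  expect_equal(d$units, rep(d$input_dim, 2L))  # "input_dim" resolves

  # cross-check the same arithmetic by running the network at desk scale
  d2 <- network_dims(30L, 200L, 4L, model_config(n_layers = 1L))
  expect_equal(d2$q, 8L * ((30L - 6L) %/% 2L - 6L) %/% 2L *
                 ((200L - 6L) %/% 2L - 6L) %/% 2L)
  set.seed(1)
  params <- prohl:::init_params(d2)
  expect_identical(dim(params$Wd[[1]]), c(d2$input_dim, d2$input_dim))
  p <- nn_forward_cpp(params, array(rnorm(30 * 200), c(30, 200, 1)),
                      matrix(rnorm(4), 1, 4), d2)
  expect_true(p > 0 && p < 1)
})

test_that("shape guards reject collapsing inputs at build time", {
  expect_error(network_dims(8L, 100L, 5L, model_config(kernel_size = 9L)),
               "smaller than the 9x9 kernel")
  # second block collapse: first pool leaves fewer rows than the kernel
  expect_error(network_dims(16L, 100L, 5L, model_config(kernel_size = 7L)),
               "second block")
})

test_that("training is reproducible and the forward pass is batch invariant", {
  inp <- tiny_inputs(40, shift = 3)
  cfg <- model_config(max_epochs = 3L, batch_size = 16L, seed = 11L)
  va <- tiny_inputs(16, shift = 3, seed = 2L)
  m1 <- train_model(inp$ximg, inp$xfeat, inp$y, va$ximg, va$xfeat, va$y, cfg)
  m2 <- train_model(inp$ximg, inp$xfeat, inp$y, va$ximg, va$xfeat, va$y, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$log, m2$log)

  p_all <- predict_model(m1, va$ximg, va$xfeat)$probability_long_lived
  p_sub <- predict_model(m1, va$ximg[, , 5:9, drop = FALSE],
                         va$xfeat[5:9, , drop = FALSE])$probability_long_lived
  expect_equal(p_sub, p_all[5:9], tolerance = 1e-6)
})

test_that("same seed gives identical initial weights", {
  d <- network_dims(22L, 40L, 6L, model_config(seed = 3L))
  set.seed(3); a <- prohl:::init_params(d)
  set.seed(3); b <- prohl:::init_params(d)
  expect_identical(a, b)
})

test_that("early stopping waits out the patience window", {
  # improvement only at epoch 1, patience 5 -> stop at epoch 6
  res <- early_stop_epoch(c(0.5, 0.6, 0.7, 0.6, 0.6, 0.6, 0.6, 0.55), 5L)
  expect_equal(res$stop_epoch, 6L)
  expect_equal(res$best_epoch, 1L)
  # monotone improvement runs the full budget
  res2 <- early_stop_epoch(seq(1, 0.1, length.out = 8), 5L)
  expect_equal(res2$stop_epoch, 8L)
  expect_equal(res2$best_epoch, 8L)
})

test_that("a strong linear signal is learnable to near-perfect training MCC", {
  inp <- tiny_inputs(400, shift = 3, seed = 5L)
  va <- tiny_inputs(80, shift = 3, seed = 6L)
  # regularisation off: this is a raw capacity/optimisation check
  cfg <- model_config(n_layers = 1L, max_epochs = 30L, patience = 99L,
                      dropout = 0, seed = 7L)
  m <- train_model(inp$ximg, inp$xfeat, inp$y, va$ximg, va$xfeat, va$y, cfg)
  pred <- predict_model(m, inp$ximg, inp$xfeat)
  truth <- ifelse(inp$y == 1, "long_lived", "short_lived")
  mcc <- compute_metrics(confusion_counts(truth, pred$predicted_class))["MCC"]
  expect_gte(unname(mcc), 0.95)
})

test_that("an exact 0.5 probability is classed long-lived", {
  d <- network_dims(22L, 40L, 2L, model_config(n_layers = 1L))
  set.seed(1)
  params <- prohl:::init_params(d)
  zeroed <- rapply(params, function(x) x * 0, how = "replace")
  m <- structure(list(params = zeroed, dims = d,
                      config = model_config(n_layers = 1L)),
                 class = "prohl_model")
  pred <- predict_model(m, array(rnorm(22 * 40 * 3), c(22, 40, 3)),
                        matrix(rnorm(6), 3, 2))
  expect_true(all(pred$probability_long_lived == 0.5))
  expect_true(all(pred$predicted_class == "long_lived"))
})

test_that("empty splits and non-finite losses are rejected", {
  inp <- tiny_inputs(10)
  cfg <- model_config(max_epochs = 1L)
  expect_error(train_model(inp$ximg, inp$xfeat, inp$y,
                           inp$ximg[, , 0, drop = FALSE],
                           inp$xfeat[0, , drop = FALSE], numeric(0), cfg),
               "empty")
})
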