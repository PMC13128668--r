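test_that("the default grid enumerates 1,296 configurations in stable order", {
  configs <- enumerate_grid(default_grid())
  expect_length(configs, 1296L)
  expect_length(unique(vapply(configs, function(c)
    paste(c$kernel_size, c$n_filters, c$n_layers, format(c$n_units),
          c$dropout, c$learning_rate, c$max_epochs, c$batch_size), "")),
    1296L)
  again <- enumerate_grid(default_grid())
  expect_identical(configs, again)
  # earlier axes vary slowest
  expect_equal(configs[[1]]$kernel_size, 7L)
  expect_equal(configs[[1296]]$kernel_size, 9L)
  expect_equal(configs[[1]]$batch_size, 32L)
  expect_equal(configs[[2]]$batch_size, 64L)
})

test_that("degenerate grids work and empty axes are rejected", {
  g <- default_grid()
  for (ax in names(g)) g[[ax]] <- g[[ax]][1]
  expect_length(enumerate_grid(g), 1L)
  g$dropout <- numeric(0)
  expect_error(enumerate_grid(g), "empty grid axis")
  expect_length(enumerate_grid(reduced_grid()), 8L)
})

test_that("stratified folds partition the data with balanced class counts", {
  labels <- rep(c("long_lived", "short_lived"), each = 50)
  folds <- kfold_split(labels, k = 10L, seed = 4L)
  expect_length(folds, 10L)
  val_all <- sort(unlist(lapply(folds, `[[`, "val")))
  expect_identical(val_all, 1:100)  # union = everything, disjoint
  for (f in folds) {
    expect_length(f$val, 10L)
    expect_equal(sum(labels[f$val] == "long_lived"), 5L)
    expect_identical(sort(c(f$train, f$val)), 1:100)
  }
  expect_identical(kfold_split(labels, 10L, seed = 4L), folds)
  expect_false(identical(kfold_split(labels, 10L, seed = 5L), folds))
  expect_warning(kfold_split(c(rep("long_lived", 30), rep("short_lived", 5)),
                             k = 10L), "fewer than k")
  expect_error(kfold_split(rep("long_lived", 30), k = 3L), "both classes")
})

test_that("select_best maximises mean MCC with first-wins tie-breaking", {
  fake <- function(mcc) structure(list(config = list(tag = mcc),
                                       mean = c(MCC = mcc)),
                                  class = "prohl_cv_result")
  expect_equal(select_best(list(fake(0.5)))$index, 1L)
  expect_equal(select_best(list(fake(0.5), fake(0.7)))$index, 2L)
  expect_equal(select_best(list(fake(0.7), fake(0.7)))$index, 1L)
  expect_equal(select_best(list(NULL, fake(0.2)))$index, 2L)
  expect_error(select_best(list(NULL, NULL)), "all configurations failed")
})

test_that("cross-validation aggregates fold metrics with standard errors", {
  data <- tiny_bundle()
  cv <- cross_validate(model_config(max_epochs = 3L, seed = 2L), data,
                       k = 3L, seed = 1L)
  expect_equal(nrow(cv$fold_metrics), 3L)
  expect_equal(unname(cv$mean["ACC"]), mean(cv$fold_metrics$ACC))
  expect_equal(unname(cv$se["MCC"]),
               sd(cv$fold_metrics$MCC) / sqrt(3))
  expect_true(all(cv$fold_metrics$ACC >= 0 & cv$fold_metrics$ACC <= 1))
})

test_that("grid search reports every configuration and ranks by MCC", {
  data <- tiny_bundle()
  g <- reduced_grid()
  g$n_layers <- 1L
  g$max_epochs <- 2L
  g$batch_size <- c(16L, 32L)  # 2 configs
  configs <- enumerate_grid(g, seed = 2L)
  gs <- grid_search(configs, data, k = 2L, seed = 1L)
  expect_equal(nrow(gs$table), length(configs))
  expect_false(any(gs$table$failed))
  expect_equal(gs$table$index[gs$table$rank == 1L], gs$best$index)
  expect_equal(unname(gs$best$cv$mean["MCC"]), max(gs$table$mean_MCC))
})
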