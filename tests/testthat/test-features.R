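make_two_class <- function(n_per = 30, p = 12, shift = 0, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per * p), ncol = p,
              dimnames = list(NULL, paste0("f", 1:p)))
  x[1:n_per, 1] <- x[1:n_per, 1] + shift
  list(x = x, y = rep(c("short_lived", "long_lived"), each = n_per))
}

test_that("z-score fitting uses the sample convention and flags constants", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  zs <- fit_zscore(x)
  expect_equal(unname(zs$mean), c(2, 5))
  expect_equal(unname(zs$sd[1]), sd(c(1, 2, 3)))  # n-1 convention
  expect_identical(unname(zs$keep), c(TRUE, FALSE))
  z <- prohl:::apply_zscore(zs, x)
  expect_equal(mean(z[, 1]), 0)
  expect_equal(var(z[, 1]), 1)
  expect_error(fit_zscore(x[1, , drop = FALSE]), "2 rows")
})

test_that("ANOVA F equals the squared pooled t and selects planted shifts", {
  d <- make_two_class(n_per = 25, p = 20, seed = 2)
  a <- anova_select(d$x, d$y, alpha = 0.01)
  for (j in 1:20) {
    tt <- t.test(d$x[d$y == "short_lived", j], d$x[d$y == "long_lived", j],
                 var.equal = TRUE)
    expect_equal(unname(a$F[j]), unname(tt$statistic^2), tolerance = 1e-10)
    expect_equal(unname(a$p[j]), tt$p.value, tolerance = 1e-10)
  }
  # a feature identical in both classes is discarded
  x <- d$x
  x[, 2] <- rep(seq_len(25), 2)
  a2 <- anova_select(x, d$y, alpha = 0.01)
  expect_false(a2$keep[2])
  expect_gt(a2$p[2], 0.9)
  # a 3-pooled-SD shift with n = 50 per class is kept with p << 0.01
  d3 <- make_two_class(n_per = 50, p = 5, shift = 3, seed = 3)
  a3 <- anova_select(d3$x, d3$y, alpha = 0.01)
  expect_true(a3$keep[1])
  expect_lt(a3$p[1], 1e-10)
  expect_error(anova_select(d$x[c(1, 26, 27), ], d$y[c(1, 26, 27)]), ">= 2")
})

test_that("selection is threshold-monotone", {
  d <- make_two_class(n_per = 40, p = 50, shift = 1, seed = 4)
  k1 <- anova_select(d$x, d$y, alpha = 0.001)$keep
  k2 <- anova_select(d$x, d$y, alpha = 0.05)$keep
  expect_true(all(k2[k1]))  # selected(0.001) subset of selected(0.05)
})

test_that("PCA keeps the smallest basis reaching the variance target", {
  set.seed(5)
  t_ <- rnorm(100)
  line <- cbind(t_, 2 * t_, -t_, 0.5 * t_, 3 * t_) +
    matrix(rnorm(500, sd = 1e-6), ncol = 5)
  pc <- fit_pca(line, 0.95)
  expect_equal(ncol(pc$rotation), 1L)
  expect_gt(sum(pc$explained), 0.9999)

  iso <- matrix(rnorm(2000 * 10), ncol = 10)
  k <- ncol(fit_pca(iso, 0.95)$rotation)
  expect_true(k %in% c(9L, 10L))
  rot <- fit_pca(iso, 1.0)$rotation
  expect_equal(unname(t(rot) %*% rot), diag(ncol(rot)), tolerance = 1e-8)
  expect_error(fit_pca(matrix(0, 5, 3), 0.95), "degenerate")
})

test_that("fitted state never leaks validation rows", {
  d <- make_two_class(n_per = 30, p = 25, shift = 1.5, seed = 6)
  xs <- matrix(rnorm(60 * 8), ncol = 8)
  tr <- c(1:20, 31:50)
  full <- fit_feature_state(d$x, xs, d$y, train_idx = tr)
  sub <- fit_feature_state(d$x[tr, ], xs[tr, ], d$y[tr])
  expect_identical(state_checksum(full), state_checksum(sub))
  # perturbing validation rows changes nothing
  d$x[21, ] <- d$x[21, ] + 100
  xs[21, ] <- xs[21, ] - 50
  expect_identical(state_checksum(fit_feature_state(d$x, xs, d$y,
                                                    train_idx = tr)),
                   state_checksum(full))
})

test_that("applying state reproduces fit-time dimensions and guards names", {
  d <- make_two_class(n_per = 30, p = 25, shift = 2, seed = 7)
  xs <- matrix(rnorm(60 * 8), ncol = 8)
  st <- fit_feature_state(d$x, xs, d$y)
  out <- apply_feature_state(st, d$x, xs)
  expect_equal(nrow(out), 60)
  expect_equal(ncol(out), sum(st$anova$keep) + ncol(st$pca$rotation))
  expect_setequal(unique(attr(out, "provenance")), c("phys", "embedding"))
  bad <- d$x
  colnames(bad)[1] <- "renamed"
  expect_error(apply_feature_state(st, bad, xs), "do not match")
  # an all-false mask still yields a usable (embedding-only) block
  st0 <- fit_feature_state(make_two_class(n_per = 20, p = 6, seed = 8)$x,
                           xs[1:40, ], d$y[c(1:20, 31:50)],
                           feature_config(anova_alpha = 1e-12))
  out0 <- apply_feature_state(st0, make_two_class(n_per = 20, p = 6, seed = 8)$x,
                              xs[1:40, ])
  expect_true(all(attr(out0, "provenance") == "embedding") ||
                sum(st0$anova$keep) == ncol(out0) - ncol(st0$pca$rotation))
  expect_equal(nrow(out0), 40)
})
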