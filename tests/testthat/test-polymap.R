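test_that("design rows evaluate the ten monomials in order", {
  expect_equal(design_row(0, 0), c(1, rep(0, 9)))
  expect_equal(design_row(1, 1), rep(1, 10))
  expect_equal(design_row(2, 3), c(1, 2, 3, 6, 4, 9, 12, 18, 8, 27))
  expect_equal(design_matrix(c(2, 0), c(3, 0)),
               rbind(design_row(2, 3), design_row(0, 0)))
})

test_that("the train/validation split is disjoint, exhaustive and seeded", {
  ids <- seq_len(1189)
  sp <- split_train_validation(ids, seed = 5)
  expect_length(sp$train, 700L)
  expect_length(sp$validation, 489L)
  expect_length(intersect(sp$train, sp$validation), 0L)
  expect_setequal(c(sp$train, sp$validation), ids)
  expect_identical(sp, split_train_validation(ids, seed = 5))
  sp2 <- split_train_validation(ids, seed = 6)
  expect_false(identical(sp$train, sp2$train))
  expect_error(split_train_validation(seq_len(500)), "1189")
  expect_identical(length(split_train_validation(seq_len(500),
                                                 n_train = 300L)$train), 300L)
})

test_that("least-squares coefficients are exactly recovered and order invariant", {
  set.seed(3)
  D <- runif(200, 0, 2.4)
  K <- runif(200, -5, 10)
  a_true <- c(0.5, -1, 2, 0.3, 0, 1.5, -0.2, 0.1, 0.05, -0.04)
  X <- design_matrix(D, K)
  y <- as.numeric(X %*% a_true)
  m <- fit_polymap(D, K, y, 2 * y)
  expect_equal(m$coef_D0, a_true, tolerance = 1e-8)
  expect_equal(m$coef_L, 2 * a_true, tolerance = 1e-8)
  # constant target -> intercept only
  m2 <- fit_polymap(D, K, rep(7, 200), rep(30, 200))
  expect_equal(m2$coef_D0, c(7, rep(0, 9)), tolerance = 1e-8)
  # permuting rows leaves coefficients unchanged
  p <- sample(200)
  m3 <- fit_polymap(D[p], K[p], y[p], 2 * y[p])
  expect_equal(m3$coef_D0, m$coef_D0, tolerance = 1e-10)
  # perfect polynomial ground truth -> zero validation error
  sc <- predict_and_score(m, D[1:50], K[1:50], y[1:50], 2 * y[1:50])
  expect_lt(max(abs(sc$errors$err_D0)), 1e-7)
})

test_that("rank-deficient designs fall back to a minimum-norm fit", {
  D <- rep(1, 20)
  K <- rep(2, 20)
  expect_warning(m <- fit_polymap(D, K, rnorm(20), rnorm(20)), "rank")
  expect_length(m$coef_D0, 10L)
  expect_false(anyNA(m$coef_D0))
})

test_that("models refuse silent cross-context application", {
  set.seed(4)
  D <- runif(40, 0, 2)
  K <- runif(40, -1, 3)
  ctx <- list(delta = 20, Delta = 75, bmax = 1500, snr = 20)
  m <- fit_polymap(D, K, D + K, D - K, context = ctx)
  expect_error(predict(m, D, K), "context")
  expect_error(predict(m, D, K, context = list(delta = 20, Delta = 25,
                                               bmax = 1500, snr = 20)),
               "context")
  expect_silent(predict(m, D, K, context = ctx))
  expect_silent(predict(m, D, K, override = TRUE))
})

test_that("noiseless invertible mappings do not overfit the 10-parameter model", {
  # synthetic ground truth where (D0, L) -> (D, K) is smooth and invertible
  set.seed(8)
  D0 <- runif(1189, 0.2, 2.4)
  L <- runif(1189, 11, 59)
  D <- 0.3 + 0.7 * D0 - 0.002 * L
  K <- 0.2 + 0.04 * L - 0.3 * D0
  sp <- split_train_validation(seq_len(1189), seed = 2)
  m <- fit_polymap(D[sp$train], K[sp$train], D0[sp$train], L[sp$train])
  r2 <- function(y, yhat) 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  pr_t <- predict(m, D[sp$train], K[sp$train])
  pr_v <- predict(m, D[sp$validation], K[sp$validation])
  expect_gt(r2(D0[sp$validation], pr_v$D0_hat),
            r2(D0[sp$train], pr_t$D0_hat) - 0.05)
  expect_gt(r2(L[sp$validation], pr_v$L_hat),
            r2(L[sp$train], pr_t$L_hat) - 0.05)
})
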