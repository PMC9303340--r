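make_blobs <- function(n_per, seed = 1) {
  with_seed <- hepatosim:::with_seed
  with_seed(seed, {
    D <- c(rnorm(n_per, 0.4, 0.05), rnorm(n_per, 1.0, 0.05),
           rnorm(n_per, 1.8, 0.05))
    K <- c(rnorm(n_per, 2, 0.2), rnorm(n_per, 0.5, 0.2),
           rnorm(n_per, -0.5, 0.2))
    lab <- factor(rep(c("small", "medium", "large"), each = n_per),
                  levels = c("small", "medium", "large"))
    data.frame(D = D, K = K, lab = lab)
  })
}

test_that("cell-size discretization uses left-inclusive boundaries", {
  expect_identical(as.character(discretize_size(c(11, 28, 28.000001, 42,
                                                  42.1, 60))),
                   c("small", "small", "medium", "medium", "large", "large"))
  expect_error(discretize_size(-3), "positive")
})

test_that("well-separated classes are classified nearly perfectly", {
  d <- make_blobs(120, seed = 2)
  idx <- hepatosim:::with_seed(3, sample(nrow(d), 200))
  m <- fit_classifier(d$D[idx], d$K[idx], d$lab[idx])
  a <- classify_accuracy(m, d$D[-idx], d$K[-idx], d$lab[-idx])
  expect_gt(a$accuracy, 0.95)
  expect_true(all(a$per_class > 0.9))
  expect_identical(sum(a$confusion), length(d$lab[-idx]))
})

test_that("per-class recalls follow the confusion table; absent classes give NA", {
  d <- make_blobs(80, seed = 4)
  m <- fit_classifier(d$D, d$K, d$lab)
  # validation set missing the large class entirely
  sub <- d[d$lab != "large", ]
  a <- classify_accuracy(m, sub$D, sub$K, sub$lab)
  expect_true(is.na(a$per_class["large"]))
  expect_false(anyNA(a$per_class[c("small", "medium")]))
  # recalls equal row-normalized confusion diagonal
  full <- classify_accuracy(m, d$D, d$K, d$lab)
  recalls <- diag(full$confusion) / rowSums(full$confusion)
  expect_equal(unname(full$per_class), unname(recalls))
})

test_that("labels independent of features score at chance within the permutation band", {
  with_seed <- hepatosim:::with_seed
  d <- with_seed(5, data.frame(D = runif(300, 0, 2), K = runif(300, -1, 3)))
  lab <- with_seed(6, factor(sample(c("small", "medium", "large"), 300,
                                    replace = TRUE, prob = c(0.4, 0.3, 0.3)),
                             levels = c("small", "medium", "large")))
  tr <- 1:200; va <- 201:300
  m <- fit_classifier(d$D[tr], d$K[tr], lab[tr])
  a <- classify_accuracy(m, d$D[va], d$K[va], lab[va])
  iv <- permutation_interval(d$D[tr], d$K[tr], lab[tr],
                             d$D[va], d$K[va], lab[va],
                             n_perm = 150L, seed = 7)
  expect_gte(a$accuracy, iv$lo - 0.05)
  expect_lte(a$accuracy, iv$hi + 0.05)
  # the interval brackets the class-prior maximum for null features
  expect_lt(iv$lo, 0.45)
  expect_gt(iv$hi, 0.25)
})

test_that("permutation intervals are reproducible and degenerate at n_perm = 1", {
  d <- make_blobs(40, seed = 8)
  tr <- 1:80; va <- 81:120
  iv1 <- permutation_interval(d$D[tr], d$K[tr], d$lab[tr],
                              d$D[va], d$K[va], d$lab[va],
                              n_perm = 20L, seed = 9)
  iv2 <- permutation_interval(d$D[tr], d$K[tr], d$lab[tr],
                              d$D[va], d$K[va], d$lab[va],
                              n_perm = 20L, seed = 9)
  expect_identical(iv1, iv2)
  iv3 <- permutation_interval(d$D[tr], d$K[tr], d$lab[tr],
                              d$D[va], d$K[va], d$lab[va],
                              n_perm = 1L, seed = 10)
  expect_identical(iv3$lo, iv3$hi)
})

test_that("duplicating the training set leaves the decision function unchanged", {
  # the duplicated likelihood has the same maximizer; overlapping classes
  # keep it finite and well-conditioned
  with_seed <- hepatosim:::with_seed
  d <- with_seed(11, {
    n <- 60
    data.frame(D = c(rnorm(n, 0.5, 0.25), rnorm(n, 1.0, 0.25),
                     rnorm(n, 1.5, 0.25)),
               K = c(rnorm(n, 1.5, 0.6), rnorm(n, 0.8, 0.6),
                     rnorm(n, 0.1, 0.6)),
               lab = factor(rep(c("small", "medium", "large"), each = n),
                            levels = c("small", "medium", "large")))
  })
  m1 <- fit_classifier(d$D, d$K, d$lab)
  m2 <- fit_classifier(rep(d$D, 2), rep(d$K, 2), rep(d$lab, 2))
  grid <- expand.grid(D = seq(0.2, 2, 0.3), K = seq(-1, 2.5, 0.5))
  expect_identical(predict(m1, grid$D, grid$K), predict(m2, grid$D, grid$K))
})

test_that("training requires all three classes", {
  d <- make_blobs(30, seed = 12)
  sub <- d[d$lab != "medium", ]
  expect_error(fit_classifier(sub$D, sub$K, sub$lab), "three classes")
})
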