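# two classes separated in feature 1, noise-free in the class direction
separable_toy <- function(n1 = 10, n2 = 8, p = 6, seed = 2) {
  set.seed(seed)
  x <- matrix(rnorm((n1 + n2) * p, sd = 0.1), ncol = p)
  x[, 1] <- c(rep(0, n1), rep(5, n2)) + rnorm(n1 + n2, sd = 1e-6)
  list(x = x, y = c(rep(1L, n1), rep(2L, n2)))
}

test_that("a separable binary problem is solved with one factor", {
  toy <- separable_toy()
  model <- fit_plsda(toy$x, toy$y, 1, "binary")
  expect_identical(predict_classes(model, toy$x), toy$y)
  expect_equal(evaluate(toy$y, predict_classes(model, toy$x))$ccr, 100)
})

test_that("full-rank PLS reproduces the least-squares fit", {
  set.seed(4)
  n <- 20; p <- 5
  x <- matrix(rnorm(n * p), ncol = p)
  y <- sample(1:2, n, replace = TRUE)
  while (length(unique(y)) < 2) y <- sample(1:2, n, replace = TRUE)
  model <- fit_plsda(x, y, p, "binary")
  fitted_pls <- predict_codes(model, x)[, 1]
  # oracle: ordinary least squares on centered data
  fit_ols <- lm.fit(cbind(1, x), y)
  expect_equal(fitted_pls, unname(fit_ols$fitted.values), tolerance = 1e-8)

  # multiclass responses too
  y3 <- rep(1:3, length.out = n)
  m3 <- fit_plsda(x, y3, p, "multiclass")
  fitted3 <- predict_codes(m3, x)
  ind <- sapply(1:3, function(k) as.numeric(y3 == k))
  ols3 <- lm.fit(cbind(1, x), ind)
  expect_equal(unname(fitted3), unname(ols3$fitted.values), tolerance = 1e-8)
})

test_that("centering identity: the mean input predicts the mean code", {
  toy <- separable_toy()
  model <- fit_plsda(toy$x, toy$y, 3, "binary")
  expect_equal(model$y_means, mean(toy$y))
  yhat <- predict_codes(model, matrix(colMeans(toy$x), 1))
  expect_equal(yhat[1, 1], mean(toy$y), tolerance = 1e-10)
})

test_that("decision rules: 1.5 midpoint for binary, argmax with low-index ties", {
  toy <- separable_toy()
  model <- fit_plsda(toy$x, toy$y, 1, "binary")
  # build inputs whose predicted codes hit 1.0, 1.5 and 2.0 exactly by
  # inverting the single-coefficient model along its regression direction
  b <- model$regression_coefficients[, 1]
  xb <- sum(b^2)
  probe <- function(target) {
    matrix(model$x_means + (target - model$y_means) * b / xb, 1)
  }
  expect_equal(predict_codes(model, probe(1.0))[1, 1], 1.0, tolerance = 1e-8)
  expect_identical(predict_classes(model, probe(1.0)), 1L)
  expect_identical(predict_classes(model, probe(2.0)), 2L)
  expect_identical(predict_classes(model, probe(1.5)), 2L)   # boundary -> class 2

  # multiclass argmax
  toy3 <- list(x = rbind(diag(3) * 4 + 1, diag(3) * 4 + 1), y = rep(1:3, 2))
  m3 <- fit_plsda(toy3$x, toy3$y, 2, "multiclass")
  expect_identical(predict_classes(m3, toy3$x), toy3$y)
})

test_that("training fit errors on degenerate inputs", {
  toy <- separable_toy()
  expect_error(fit_plsda(toy$x, rep(1L, 18), 1, "binary"),
               class = "herbscreen_invalid_argument")
  expect_error(fit_plsda(toy$x, toy$y, 40, "binary"),
               class = "herbscreen_invalid_argument")
  expect_error(predict_classes(fit_plsda(toy$x, toy$y, 1, "binary"),
                               matrix(0, 1, 3)),
               class = "herbscreen_invalid_argument")
})

test_that("cross-validation picks the smallest factor count on ties and is fold-exact", {
  toy <- separable_toy(n1 = 12, n2 = 9)
  cv <- cross_validate_lv(toy$x, toy$y, "binary", folds = 3, max_factors = 4,
                          seed = 5)
  expect_equal(cv$ccr[1], 100)
  expect_identical(cv$n_factors, 1L)
  expect_length(cv$ccr, 4L)

  # oracle: manual fold loop refitting a separate model per (fold, k)
  set.seed(31)
  x <- matrix(rnorm(24 * 8), ncol = 8)
  x[, 1] <- x[, 1] + rep(c(0, 2), each = 12)
  y <- rep(1:2, each = 12L)
  cv2 <- cross_validate_lv(x, y, "binary", folds = 4, max_factors = 3, seed = 9)
  pred <- matrix(NA_integer_, 24, 3)
  for (f in 1:4) {
    tr <- cv2$fold_assignment != f
    for (k in 1:3) {
      mk <- fit_plsda(x[tr, ], y[tr], k, "binary")
      pred[!tr, k] <- predict_classes(mk, x[!tr, , drop = FALSE])
    }
  }
  expect_equal(cv2$ccr, 100 * colMeans(pred == y))
})

test_that("cross-validation honours the requested factor grid size", {
  set.seed(6)
  x <- matrix(rnorm(44 * 40), ncol = 40)
  y <- rep(1:2, each = 22L)
  x[, 3] <- x[, 3] + (y == 1) * 1.5
  cv <- cross_validate_lv(x, y, "binary", folds = 10, max_factors = 30, seed = 2)
  expect_length(cv$ccr, 30L)
})

test_that("stratification failure is signalled when a class cannot reach every fold", {
  set.seed(10)
  x <- matrix(rnorm(12 * 4), ncol = 4)
  y <- c(rep(1L, 11), 2L)                     # the single class-2 member
  expect_error(cross_validate_lv(x, y, "binary", folds = 3, max_factors = 2, seed = 1),
               class = "herbscreen_stratification_failure")
})

test_that("adding factors never increases the training residual norm", {
  set.seed(12)
  x <- matrix(rnorm(25 * 10), ncol = 10)
  y <- sample(1:2, 25, replace = TRUE)
  res <- sapply(1:8, function(k) {
    m <- fit_plsda(x, y, k, "binary")
    sum((predict_codes(m, x)[, 1] - y)^2)
  })
  expect_true(all(diff(res) <= 1e-10))
})

test_that("permuting the training rows leaves predictions unchanged", {
  toy <- separable_toy(n1 = 9, n2 = 9)
  perm <- sample(18)
  m1 <- fit_plsda(toy$x, toy$y, 4, "binary")
  m2 <- fit_plsda(toy$x[perm, ], toy$y[perm], 4, "binary")
  probe <- matrix(rnorm(5 * 6), ncol = 6)
  expect_equal(predict_codes(m1, probe), predict_codes(m2, probe),
               tolerance = 1e-10)
})

test_that("latent scores agree with an independent NIPALS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(14)
  x <- matrix(rnorm(30 * 12), ncol = 12)
  y <- rep(1:2, each = 15L)
  x[, 1] <- x[, 1] + (y == 1) * 2
  model <- fit_plsda(x, y, 3, "binary")
  ref <- mixOmics::pls(x, matrix(as.numeric(y), ncol = 1), ncomp = 3,
                       scale = FALSE, mode = "regression")
  for (a in 1:3) {
    r <- abs(cor(model$scores[, a], ref$variates$X[, a]))
    expect_gt(r, 0.999)
  }
})

test_that("classification reports count confusions at full and display precision", {
  truth <- c(rep(1L, 45), rep(2L, 5))
  pred <- truth; pred[1:3] <- 2L                 # 47 of 50 correct
  rep1 <- evaluate(truth, pred)
  expect_equal(rep1$ccr, 94)
  expect_identical(rep1$ccr_display, 94)

  truth2 <- c(rep(1L, 13), rep(2L, 4))
  pred2 <- truth2; pred2[17] <- 1L               # 16 of 17 correct
  rep2 <- evaluate(truth2, pred2)
  expect_equal(rep2$ccr, 1600 / 17)
  expect_identical(rep2$ccr_display, 94)

  rep3 <- evaluate(1:3, 1:3)
  expect_equal(rep3$ccr, 100)
  expect_true(all(rep3$confusion[upper.tri(rep3$confusion)] == 0))
  expect_true(all(rep3$confusion[lower.tri(rep3$confusion)] == 0))

  expect_error(evaluate(c(1, 2), c(1, 3), classes = 1:2),
               class = "herbscreen_invalid_argument")
  expect_error(evaluate(1:3, 1:2), class = "herbscreen_invalid_argument")
})
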