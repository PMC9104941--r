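test_that("dataset splitting uses largest-remainder sizes and partitions", {
  spl <- split_dataset(33, seed = 1)
  expect_length(spl$train, 23)
  expect_length(spl$validation, 5)
  expect_length(spl$test, 5)
  all_idx <- sort(c(spl$train, spl$validation, spl$test))
  expect_identical(all_idx, 1:33)
  expect_identical(split_dataset(33, seed = 5), split_dataset(33, seed = 5))
  # stratification: both classes present in every split
  labels <- rep(c(0, 1), c(18, 15))
  spl2 <- split_dataset(labels, seed = 2)
  for (part in spl2)
    expect_setequal(unique(labels[part]), c(0, 1))
})

test_that("network initialization matches the 8-16-1 architecture", {
  m <- init_network(7, seed = 1)
  expect_identical(radarvitals:::mlp_n_params(m), 225)
  expect_identical(init_network(7, seed = 4), init_network(7, seed = 4))
  zero <- radarvitals:::mlp_set_params(m, numeric(225))
  expect_equal(radarvitals:::mlp_forward(zero, runif(7))$output, 0.5)
})

test_that("the Jacobian agrees with central finite differences", {
  set.seed(5)
  m <- init_network(3, c(4, 3, 1), seed = 11)
  x <- matrix(runif(15), 5, 3)
  y <- runif(5)
  jr <- mlp_residuals(m, x, y)
  g <- as.numeric(crossprod(jr$J, jr$r))
  th <- radarvitals:::mlp_get_params(m)
  eps <- 1e-6
  half_sse <- function(mod) 0.5 * sum(mlp_residuals(mod, x, y)$r^2)
  fd <- vapply(seq_along(th), function(k) {
    tp <- th; tp[k] <- tp[k] + eps
    tm <- th; tm[k] <- tm[k] - eps
    (half_sse(radarvitals:::mlp_set_params(m, tp)) -
       half_sse(radarvitals:::mlp_set_params(m, tm))) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-5)
})

test_that("LM steps interpolate between Gauss-Newton and gradient descent", {
  set.seed(2)
  J <- matrix(rnorm(40), 10, 4)
  r <- rnorm(10)
  gn <- -as.numeric(solve(crossprod(J), crossprod(J, r)))
  s0 <- lm_step(J, r, 1e-10)
  expect_lt(sqrt(sum((s0 - gn)^2)) / sqrt(sum(gn^2)), 1e-6)
  s_inf <- lm_step(J, r, 1e8)
  gdir <- -as.numeric(crossprod(J, r))
  cosine <- sum(s_inf * gdir) / sqrt(sum(s_inf^2) * sum(gdir^2))
  expect_gte(cosine, 0.999)
})

test_that("LM solves a linear least-squares problem in one step", {
  set.seed(9)
  X <- cbind(1, rnorm(20))
  y <- as.numeric(X %*% c(2, -1)) + rnorm(20, 0, 0.1)
  theta <- c(5, 5)   # arbitrary start; linear residuals
  r <- as.numeric(X %*% theta) - y
  theta1 <- theta + lm_step(X, r, 1e-12)
  expect_equal(unname(theta1), unname(coef(lm(y ~ X[, 2]))),
               tolerance = 1e-8)
})

test_that("accepted-step training MSE is strictly decreasing", {
  co <- simulate_rr_cohort(60, 0.5, seed = 3)
  fx <- cohort_features(co)
  sc <- fit_scaler(fx$x)
  xs <- apply_scaler(sc, fx$x)
  fit <- train_lm(init_network(7, seed = 1), xs, fx$y, max_epochs = 8)
  mses <- fit$history$train_mse[fit$history$accepted]
  expect_true(all(diff(mses) < 0))
  expect_true(all(fit$history$mu > 0))
})

test_that("training is deterministic end to end and learns the cohort", {
  r1 <- run_arrhythmia_demo(n_subjects = 120, seed = 5)
  r2 <- run_arrhythmia_demo(n_subjects = 120, seed = 5)
  expect_identical(radarvitals:::mlp_get_params(r1$model),
                   radarvitals:::mlp_get_params(r2$model))
  expect_identical(r1$subject_table, r2$subject_table)
  expect_gte(r1$train_accuracy, 0.9)
  expect_gte(r1$test_accuracy, 0.8)
})

test_that("single-class training data is refused", {
  co <- simulate_rr_cohort(20, 0, seed = 1)
  fx <- cohort_features(co)
  expect_error(train_lm(init_network(7, seed = 1), fx$x, fx$y),
               "single class")
  expect_error(run_arrhythmia_demo(n_subjects = 20, class_mix = 0, seed = 1))
})

test_that("prediction is pure, thresholded and dimension-checked", {
  m <- init_network(7, seed = 2)
  zero <- radarvitals:::mlp_set_params(m, numeric(225))
  p <- predict(zero, runif(7))
  expect_equal(p$probability, 0.5)
  expect_identical(p$label, "arrhythmia")   # >= 0.5 threshold
  x <- runif(7)
  expect_identical(predict(m, x), predict(m, x))
  expect_error(predict(m, runif(5)), "dimension")
})

test_that("positive path weights give monotone responses", {
  m <- init_network(2, c(2, 2, 1), seed = 1)
  p <- radarvitals:::mlp_n_params(m)
  m <- radarvitals:::mlp_set_params(m, rep(0.5, p))
  lo <- predict(m, c(0.1, 0.5))$probability
  hi <- predict(m, c(0.9, 0.5))$probability
  expect_gte(hi, lo)
})

test_that("confusion counts partition the data and swap symmetrically", {
  y <- c(1, 1, 0, 0, 1)
  p <- c(1, 0, 0, 1, 1)
  cm <- confusion_and_accuracy(y, p)
  expect_equal(cm$tn + cm$fp + cm$fn + cm$tp, 5)
  expect_equal(cm$accuracy, 3 / 5)
  ident <- confusion_and_accuracy(y, y)
  expect_equal(ident$fp + ident$fn, 0)
  expect_equal(ident$accuracy, 1)
  sw <- confusion_and_accuracy(1 - y, 1 - p)
  expect_equal(sw$tp, cm$tn)
  expect_equal(sw$fn, cm$fp)
  expect_error(confusion_and_accuracy(y, p[1:3]), "equal length")
})

test_that("models serialize to JSON and restore identically", {
  dir <- withr::local_tempdir()
  res <- run_arrhythmia_demo(n_subjects = 40, seed = 8)
  path <- file.path(dir, "model.json")
  write_mlp_json(res$model, path)
  m2 <- read_mlp_json(path)
  co <- simulate_rr_cohort(10, 0.5, seed = 30)
  fx <- cohort_features(co)
  expect_equal(predict(res$model, fx$x)$probability,
               predict(m2, fx$x)$probability, tolerance = 1e-12)
})
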