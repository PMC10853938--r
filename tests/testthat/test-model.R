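test_that("the transform projects onto leading components with fixed dimensions and signs", {
  set.seed(21)
  X <- matrix(rnorm(300 * 20), 300, 20)
  tr <- fit_transform(X, n_drop = 9)
  expect_equal(tr$reduced_dim, 11)
  expect_equal(dim(tr$rotation), c(20, 11))
  # orthonormal columns
  expect_equal(unname(crossprod(tr$rotation)), diag(11), tolerance = 1e-10)
  # sign convention: the largest-absolute loading of each column is positive
  for (j in 1:11) {
    expect_gt(tr$rotation[which.max(abs(tr$rotation[, j])), j], 0)
  }
  expect_error(apply_transform(tr, rnorm(19)), "does not match")
})

test_that("the transform is an affine map: center maps to zero and linearity holds", {
  set.seed(22)
  X <- matrix(rnorm(200 * 12), 200, 12)
  tr <- fit_transform(X, n_drop = 3)
  expect_equal(unname(apply_transform(tr, tr$center)),
               rep(0, 9), tolerance = 1e-12)
  x <- rnorm(12)
  y <- rnorm(12)
  lhs <- apply_transform(tr, 0.3 * x + 0.7 * y)
  rhs <- 0.3 * apply_transform(tr, x) + 0.7 * apply_transform(tr, y)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("dropping nothing yields a lossless orthonormal rotation of the standardized data", {
  set.seed(23)
  X <- matrix(rnorm(150 * 8), 150, 8)
  tr <- fit_transform(X, n_drop = 0)
  Z <- sweep(sweep(X, 2, tr$center), 2, tr$scale, `/`)
  red <- apply_transform(tr, X)
  # reconstruction through the pseudo-inverse (= transpose) is exact
  expect_equal(red %*% t(tr$rotation), Z, tolerance = 1e-10)
})

test_that("a duplicated feature column costs one component, matching the eigenvalue oracle", {
  set.seed(24)
  X <- matrix(rnorm(200 * 10), 200, 10)
  Xd <- cbind(X, X[, 1])
  tr <- fit_transform(Xd, n_drop = 1)
  Z <- sweep(sweep(Xd, 2, colMeans(Xd)), 2, apply(Xd, 2, sd), `/`)
  ev <- eigen(crossprod(Z) / (nrow(Z) - 1), symmetric = TRUE)$values
  # the duplicate makes exactly one eigenvalue (numerically) zero
  expect_lt(ev[11], 1e-10)
  # so dropping one component loses no variance
  red <- apply_transform(tr, Xd)
  expect_equal(sum(apply(red, 2, stats::var)), sum(ev[1:10]), tolerance = 1e-8)
  expect_error(fit_transform(Xd, n_drop = 0), "rank")
})

test_that("parameter counts match the closed formula and an explicit enumeration", {
  expect_equal(count_parameters(c(49, 16, 8, 1)), 945)
  expect_equal(count_parameters(c(52, 14, 7, 1)), 855)
  expect_equal(count_parameters(c(1, 1, 1, 1)), 6)
  net <- network_spec(c(5, 4, 3, 1), seed = 1)
  enumerated <- sum(vapply(net$layers,
                           function(l) length(l$W) + length(l$b), numeric(1)))
  expect_equal(count_parameters(net), enumerated)
})

test_that("degenerate networks predict the output bias", {
  net <- network_spec(c(4, 3, 2, 1), seed = 2)
  for (l in seq_along(net$layers)) net$layers[[l]]$W[] <- 0
  net$layers[[3]]$b <- -1.3
  x <- matrix(rnorm(20), 5, 4)
  expect_equal(predict(net, x), rep(-1.3, 5))
  # saturated rectifiers: hidden biases so negative every unit is dead
  net2 <- network_spec(c(4, 3, 2, 1), seed = 3)
  net2$layers[[1]]$b <- rep(-1e6, 3)
  net2$layers[[3]]$b <- -1.3
  expect_equal(predict(net2, matrix(rnorm(40), 10, 4)), rep(-1.3, 10))
})

test_that("the forward pass matches pencil-and-paper arithmetic on a 2-2-1 network", {
  net <- network_spec(c(2, 2, 1), seed = 1)
  net$layers[[1]]$W <- matrix(c(1, -1, 0.5, 2), 2, 2)
  net$layers[[1]]$b <- c(0.1, -0.2)
  net$layers[[2]]$W <- matrix(c(1.5, -0.5), 2, 1)
  net$layers[[2]]$b <- 0.25
  x <- c(0.4, -0.3)
  z1 <- c(0.4 * 1 + (-0.3) * (-1) + 0.1, 0.4 * 0.5 + (-0.3) * 2 - 0.2)
  a1 <- pmax(z1, 0)
  manual <- 1.5 * a1[1] - 0.5 * a1[2] + 0.25
  expect_equal(predict(net, x), manual, tolerance = 1e-12)
})

test_that("training is seed-reproducible, ignores zero-weight records, and collapses under heavy regularization", {
  set.seed(31)
  X <- matrix(rnorm(120 * 6), 120, 6)
  y <- drop(X %*% c(1, -1, 0.5, 0, 0, 0)) + rnorm(120, sd = 0.2)
  cfg <- training_config(epochs = 25, batch_size = 120, seed = 9)
  f1 <- train_network(X, y, config = cfg, hidden = c(4, 3))
  f2 <- train_network(X, y, config = cfg, hidden = c(4, 3))
  expect_identical(f1$net$layers, f2$net$layers)

  # records with zero weight leave the fitted parameters untouched
  y_poisoned <- y
  y_poisoned[101:120] <- 1e3
  w <- c(rep(1, 100), rep(0, 20))
  g1 <- train_network(X, y, weights = w, config = cfg, hidden = c(4, 3))
  g2 <- train_network(X, y_poisoned, weights = w, config = cfg, hidden = c(4, 3))
  expect_identical(g1$net$layers, g2$net$layers)

  # lambda -> large drives the weights to zero and predictions to a constant
  h <- train_network(X, y, l2 = 1e4, hidden = c(4, 3),
                     config = training_config(epochs = 800, batch_size = 120,
                                              seed = 9))
  expect_lt(sd(predict(h$net, X)), 0.02)
})

test_that("training recovers a linear law at the noise floor and reports the metric set", {
  set.seed(32)
  X <- matrix(rnorm(800 * 8), 800, 8)
  y <- drop(X %*% c(1, -1, 0.5, 0.3, -0.6, 0, 0, 0)) + 2 + rnorm(800, sd = 0.1)
  fit <- train_network(X, y, config = training_config(epochs = 250, seed = 2),
                       hidden = c(14, 7))
  expect_lt(fit$metrics_val[["rmse"]], 0.2)
  expect_named(fit$metrics_val,
               c("msd", "mae", "rmse", "slope", "intercept", "r2"))
  expect_gt(fit$metrics_val[["r2"]], 0.98)
  expect_equal(fit$metrics_val[["slope"]], 1, tolerance = 0.05)
  # loss history is finite and decreasing overall
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_lt(utils::tail(fit$history$train_loss, 1), fit$history$train_loss[1])
})

test_that("training warns when records are fewer than parameters", {
  set.seed(33)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rnorm(40)
  expect_warning(
    train_network(X, y, config = training_config(epochs = 2, seed = 1),
                  hidden = c(14, 7)),
    "fewer records")
})

test_that("a full solvation model round-trips through its text archive", {
  ds <- make_dataset(150, seed = 4)
  suppressWarnings(
    model <- train_solvation_model(ds$raw, ds$y, ds$schema,
                                   weights = ds$weights,
                                   config = training_config(epochs = 20,
                                                            seed = 2),
                                   strata = ds$meta$class))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  mol <- ds$molecules[[3]]
  solv <- ds$meta$solvent[3]
  expect_equal(predict_solvation(back, mol, solv),
               predict_solvation(model, mol, solv), tolerance = 1e-12)
  expect_identical(back$net$sizes, model$net$sizes)
  expect_equal(back$schema$length, model$schema$length)
})
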