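test_that("initialization is seeded, shaped by the architecture", {
  arch <- network_architecture(11, c(3, 8))
  m1 <- init_network(arch, 42)
  m2 <- init_network(arch, 42)
  expect_identical(m1, m2)
  expect_false(identical(m1, init_network(arch, 43)))
  expect_equal(lapply(m1$weights, dim),
               list(c(3L, 11L), c(8L, 3L), c(1L, 8L)))
  expect_equal(lengths(m1$biases), c(3L, 8L, 1L))
  expect_true(all(vapply(m1$biases, function(b) all(b == 0), logical(1))))
  tiny <- init_network(network_architecture(1, c(1, 1)), 1)
  expect_equal(sum(lengths(tiny$weights)), 3L)
})

test_that("forward reproduces a hand-computed chain of logistic layers", {
  arch <- network_architecture(2, c(2, 2))
  m <- init_network(arch, 1)
  m$weights <- list(matrix(c(0.5, -0.3, 0.2, 0.8), 2, 2),
                    matrix(c(1, -1, 0.5, 0.25), 2, 2),
                    matrix(c(2, -1.5), 1, 2))
  m$biases <- list(c(0.1, -0.2), c(0, 0.3), -0.4)
  s <- function(z) 1 / (1 + exp(-z))
  x <- c(0.7, -1.2)
  by_hand <- s(m$weights[[3]] %*%
                 s(m$weights[[2]] %*% s(m$weights[[1]] %*% x + m$biases[[1]]) +
                     m$biases[[2]]) + m$biases[[3]])
  expect_equal(forward(m, x), as.vector(by_hand), tolerance = 1e-12)
  # all-zero parameters give logistic(0) = 0.5 regardless of input
  mz <- init_network(arch, 1)
  for (l in 1:3) mz$weights[[l]][] <- 0
  expect_equal(forward(mz, c(100, -100)), 0.5)
  expect_error(forward(m, c(1, 2, 3)), "dimension")
})

test_that("training separates separable features and is seed-deterministic", {
  set.seed(1)
  n <- 300
  X <- rbind(matrix(rnorm(n * 3, 5), n, 3), matrix(rnorm(n * 3, 0), n, 3))
  y <- c(rep(1, n), rep(0, n))
  cfg <- training_config(epochs = 100, seed = 2, batch_size = 128)
  fit <- fit_mlp(X, y, network_architecture(3, c(3, 8)), cfg)
  expect_gte(auc(roc(forward(fit, X), y == 1)), 0.999)
  fit2 <- fit_mlp(X, y, network_architecture(3, c(3, 8)), cfg)
  expect_identical(fit$weights, fit2$weights)
  expect_identical(fit$biases, fit2$biases)
  expect_error(fit_mlp(X, rep(1, nrow(X)), network_architecture(3, c(3, 8)),
                       cfg), "single class")
})

test_that("the two-hidden-layer network solves XOR below the linear bound", {
  set.seed(2)
  nx <- 150
  X <- rbind(cbind(rnorm(nx, 0, 0.15), rnorm(nx, 0, 0.15)),
             cbind(rnorm(nx, 1, 0.15), rnorm(nx, 1, 0.15)),
             cbind(rnorm(nx, 0, 0.15), rnorm(nx, 1, 0.15)),
             cbind(rnorm(nx, 1, 0.15), rnorm(nx, 0, 0.15)))
  y <- c(rep(0, 2 * nx), rep(1, 2 * nx))
  fit <- fit_mlp(X, y, network_architecture(2, c(3, 8)),
                 training_config(epochs = 2000, seed = 3, batch_size = 128))
  expect_lt(mean((forward(fit, X) - y)^2), 0.05)   # linear floor is 0.25
})

test_that("prediction maps stacks to bounded images, checks depth", {
  set.seed(3)
  img <- matrix(runif(400), 20, 20)
  st <- multiscale_response(img, c(1.5, 2.0), L = 7, T = 7, kappa = 4)
  model <- init_network(network_architecture(2, c(3, 8)), 5)
  out <- predict_image(model, st)
  expect_identical(dim(out), dim(img))
  expect_true(all(out > 0 & out < 1))
  # constant stack -> constant output
  stc <- st
  stc$responses <- lapply(stc$responses, function(r) r * 0 + 0.3)
  expect_equal(max(predict_image(model, stc)) - min(predict_image(model, stc)), 0)
  m1 <- init_network(network_architecture(3, c(3, 8)), 5)
  expect_error(predict_image(m1, st), "depth")
})

test_that("train_network samples both classes from stacks and learns them", {
  ph <- clean_phantom(1, size = 96)
  st <- multiscale_response(ph$image, c(1.5, 2.0, 2.5), L = 9, T = 9, kappa = 6)
  cfg <- training_config(epochs = 60, seed = 4, batch_size = 512)
  model <- train_network(list(st), list(ph$gt_mask), cfg = cfg)
  resp <- predict_image(model, st)
  expect_gte(auc(roc(resp, ph$gt_mask)), 0.9)
  expect_error(train_network(list(st), list(ph$gt_mask & FALSE), cfg = cfg),
               "single class")
  expect_error(
    train_network(list(st), list(ph$gt_mask),
                  network_architecture(7, c(3, 8)), cfg),
    "n_inputs")
})

test_that("validation-based early stopping halts before the epoch budget", {
  set.seed(5)
  n <- 400
  X <- rbind(matrix(rnorm(n * 2, 4), n, 2), matrix(rnorm(n * 2, 0), n, 2))
  y <- c(rep(1, n), rep(0, n))
  fit <- fit_mlp(X, y, network_architecture(2, c(3, 8)),
                 training_config(epochs = 500, seed = 6, batch_size = 128,
                                 validation_fraction = 0.25, patience = 10))
  expect_lt(length(fit$history$loss), 500L)
  expect_gte(max(fit$history$validation_auc, na.rm = TRUE), 0.995)
})

test_that("the Levenberg-Marquardt option fits a small separable problem", {
  skip_if_not_installed("minpack.lm")
  set.seed(7)
  n <- 150
  X <- rbind(matrix(rnorm(n * 2, 2.5), n, 2), matrix(rnorm(n * 2, 0), n, 2))
  y <- c(rep(1, n), rep(0, n))
  fit <- suppressWarnings(
    fit_mlp(X, y, network_architecture(2, c(2, 2)),
            training_config(optimizer = "lm", epochs = 100, seed = 8)))
  # full-batch LM from one deterministic init can stop in a local minimum;
  # require a clearly useful fit and a strongly reduced squared error
  expect_gte(auc(roc(forward(fit, X), y == 1)), 0.9)
  losses <- fit$history$loss
  expect_lt(losses[length(losses)], 0.4 * losses[1L])
})

test_that("models round-trip through serialization bit-exactly", {
  set.seed(9)
  X <- matrix(rnorm(200), 100, 2)
  y <- rep(c(0, 1), 50)
  fit <- fit_mlp(X, y, network_architecture(2, c(3, 8)),
                 training_config(epochs = 20, seed = 10, batch_size = 32))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  expect_identical(back$weights, fit$weights)
  expect_identical(back$biases, fit$biases)
  expect_identical(back$input_norm, fit$input_norm)
  expect_identical(back$architecture, fit$architecture)
  expect_identical(forward(back, X[3, ]), forward(fit, X[3, ]))
  expect_error(read_model(withr::local_tempfile(lines = "{}",
                                                fileext = ".json")))
})

test_that("architecture search scores the grid and breaks ties minimally", {
  ph <- clean_phantom(2, size = 80, n_vessels = 2)
  st <- multiscale_response(ph$image, c(1.5, 2.5), L = 7, T = 7, kappa = 4)
  res <- architecture_search(list(st), list(ph$gt_mask), grid_max = 2,
                             cfg = training_config(epochs = 40, seed = 11,
                                                   batch_size = 512))
  expect_equal(dim(res$table), c(2L, 2L))
  expect_equal(sum(!is.na(res$table)), 4L)
  expect_s3_class(res$best_model, "network_model")
  expect_identical(res$best_model$architecture$hidden_sizes,
                   as.integer(res$best))
  # trivially separable features: every cell reaches A_z = 1 exactly, so
  # the tie rule must return the smallest architecture
  gt <- matrix(rep(c(TRUE, FALSE), each = 200), 20, 20)
  st_sep <- structure(
    list(responses = list(10 * gt, 10 * gt - 5), sigmas = c(1.5, 2.5),
         L = 7L, T = 7L, kappa = 4L),
    class = "response_stack")
  res_tie <- architecture_search(list(st_sep), list(gt), grid_max = 2,
                                 cfg = training_config(epochs = 80, seed = 12,
                                                       batch_size = 128))
  expect_true(all(res_tie$table == 1))
  expect_equal(res_tie$best, c(1L, 1L))
})
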