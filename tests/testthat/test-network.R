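finite_diff_jacobian <- function(net, X, eps = 1e-6) {
  th <- huculnet:::pack_params(net)
  K <- net$topology$output_dim
  J <- matrix(0, nrow(X) * K, length(th))
  for (p in seq_along(th)) {
    tp <- th; tp[p] <- tp[p] + eps
    tm <- th; tm[p] <- tm[p] - eps
    yp <- forward(huculnet:::unpack_params(net, tp), X)
    ym <- forward(huculnet:::unpack_params(net, tm), X)
    J[, p] <- as.vector((yp - ym) / (2 * eps))
  }
  J
}

test_that("initialization is seed-deterministic with correct shapes", {
  topo <- network_topology(10, 12L, 1)
  a <- init_network(topo, seed = 2)
  b <- init_network(topo, seed = 2)
  expect_identical(a$layers, b$layers)
  expect_identical(dim(a$layers[[1]]$W), c(12L, 10L))
  expect_identical(dim(a$layers[[2]]$W), c(1L, 12L))
  expect_length(a$layers[[1]]$b, 12L)
  expect_error(network_topology(10, c(4, 4, 4)), "1 or 2 hidden layers")
})

test_that("forward pass matches hand computation", {
  topo <- network_topology(3, 4L, 2, "tanh")
  net <- init_network(topo, seed = 1)
  for (l in seq_along(net$layers)) {
    net$layers[[l]]$W[] <- 0
    net$layers[[l]]$b[] <- 0
  }
  expect_equal(forward(net, matrix(rnorm(15), 5, 3)),
               matrix(0, 5, 2))

  one <- network_topology(1, 1L, 1, "tanh")
  n1 <- init_network(one, seed = 1)
  n1$layers[[1]]$W[] <- 0.7; n1$layers[[1]]$b[] <- 0.1
  n1$layers[[2]]$W[] <- -1.3; n1$layers[[2]]$b[] <- 0.2
  x <- 0.4
  expect_equal(forward(n1, matrix(x))[1, 1],
               tanh(-1.3 * tanh(0.7 * x + 0.1) + 0.2))

  net2 <- init_network(network_topology(5, c(6, 4), 3, "tanh"), seed = 3)
  out <- forward(net2, matrix(rnorm(50), 10, 5))
  expect_true(all(out > -1 & out < 1))
  expect_error(forward(net2, matrix(0, 2, 4)), "columns")
})

test_that("analytic Jacobian matches central finite differences", {
  for (cfg in list(list(topo = network_topology(4, 5L, 1, "linear"), n = 7),
                   list(topo = network_topology(3, c(5, 3), 2, "tanh"), n = 6))) {
    net <- init_network(cfg$topo, seed = 11)
    X <- withr::with_seed(8, matrix(rnorm(cfg$n * cfg$topo$input_dim),
                                    cfg$n, cfg$topo$input_dim))
    J <- huculnet:::net_jacobian(net, X)$J
    Jfd <- finite_diff_jacobian(net, X)
    expect_lt(max(abs(J - Jfd)) / max(abs(Jfd)), 1e-5)
  }
})

test_that("LM fits a line, a constant, and XOR", {
  x <- matrix(seq(-1, 1, length.out = 20), 20, 1)
  net <- train_network(network_topology(1, 8L, 1, "linear"), x, 2 * x - 1,
                       training_config(seed = 3))
  expect_lt(net$final_mse, 1e-4)

  const <- train_network(network_topology(1, 8L, 1, "linear"), x,
                         rep(0.37, 20), training_config(seed = 4))
  expect_lt(const$final_mse, 1e-5)  # the configured mse_goal stop
  expect_lt(max(abs(forward(const, x) - 0.37)), 1e-2)

  Xx <- matrix(c(-1, -1, -1, 1, 1, -1, 1, 1), 4, 2, byrow = TRUE)
  yx <- c(-1, 1, 1, -1)
  xor_net <- train_network(network_topology(2, 8L, 1, "linear"), Xx, yx,
                           training_config(seed = 1, n_restarts = 5))
  expect_lt(xor_net$final_mse, 1e-2)
})

test_that("accepted-step training MSE is monotone nonincreasing", {
  for (s in 1:3) {
    X <- withr::with_seed(s, matrix(rnorm(60), 30, 2))
    y <- tanh(X[, 1] - 0.5 * X[, 2]) + withr::with_seed(s + 50, rnorm(30, 0, 0.1))
    net <- lm_train(init_network(network_topology(2, 6L, 1, "linear"), seed = s),
                    X, y, training_config(seed = s, max_epochs = 60))
    expect_true(all(diff(net$history) <= 0))
    expect_equal(net$final_mse, net$history[length(net$history)])
  }
})

test_that("training rejects non-finite inputs", {
  X <- matrix(c(1, NA), 2, 1)
  expect_error(lm_train(init_network(network_topology(1, 4L, 1), seed = 1),
                        X, c(0, 1)), "non-finite")
})

test_that("network JSON serialization round-trips", {
  net <- train_network(network_topology(2, c(5, 3), 1, "linear"),
                       matrix(rnorm(20), 10, 2), rnorm(10),
                       training_config(seed = 6, max_epochs = 20, n_restarts = 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_network(net, path)
  back <- read_network(path)
  X <- matrix(rnorm(10), 5, 2)
  expect_equal(forward(back, X), forward(net, X))
})

test_that("cross-validation is deterministic and partitions every row", {
  ds <- simulate_dataset(synthetic_config(n_horses = 60, years = 2015:2018,
                                          starters_per_year = 15, seed = 23L))$dataset
  cfg <- training_config(seed = 5, max_epochs = 30, n_restarts = 1)
  a <- crossval(ds, hidden = 8L, task = "position", config = cfg, n_repeats = 2)
  b <- crossval(ds, hidden = 8L, task = "position", config = cfg, n_repeats = 2)
  expect_identical(a$per_repeat, b$per_repeat)
  expect_identical(a$n, nrow(ds$starts))
  expect_error(crossval(ds, n_folds = 1L), "n_folds")

  nine <- hucul_dataset(ds$roster,
                        ds$starts[ds$starts$championship_year == 2015L,
                                  setdiff(names(ds$starts), "age")][1:9, ],
                        validate = FALSE)
  r9 <- crossval(nine, hidden = 4L, task = "group",
                 config = training_config(seed = 2, max_epochs = 10, n_restarts = 1))
  expect_identical(r9$n, 9L)
  expect_identical(sum(r9$confusion), 9L)
})

test_that("report averaging equals the mean of per-repeat metrics", {
  ds <- simulate_dataset(synthetic_config(n_horses = 60, years = 2015:2018,
                                          starters_per_year = 15, seed = 24L))$dataset
  r <- crossval(ds, hidden = 6L, task = "group",
                config = training_config(seed = 3, max_epochs = 30, n_restarts = 1),
                n_repeats = 3)
  expect_equal(r$mean[["efficiency"]], mean(r$per_repeat$efficiency),
               tolerance = 1e-12)
  expect_equal(r$mean[["strong_efficiency"]],
               mean(r$per_repeat$strong_efficiency), tolerance = 1e-12)
})
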