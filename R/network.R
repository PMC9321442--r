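# Feedforward tanh networks trained with the Levenberg-Marquardt
# method, written from first principles: batch forward pass, analytic
# per-sample Jacobian by backpropagation, damped Gauss-Newton updates
# with the classic accept/reject lambda schedule.

#' Network topology
#'
#' Hidden layers use the tanh transfer; the output layer is linear for
#' position regression (one unit) or tanh for the three-unit
#' strong/medium/weak classifier. One or two hidden layers are
#' supported, matching the study grids ([prediction_topologies()] and
#' [classification_topologies()]).
#'
#' @param input_dim Number of input features.
#' @param hidden Integer vector of 1 or 2 hidden-layer widths.
#' @param output_dim 1 (position) or 3 (groups).
#' @param output_transfer `"linear"` or `"tanh"`.
#' @return An object of class `network_topology`.
#' @export
network_topology <- function(input_dim, hidden, output_dim = 1,
                             output_transfer = c("linear", "tanh")) {
  output_transfer <- match.arg(output_transfer)
  hidden <- as.integer(hidden)
  if (length(hidden) < 1 || length(hidden) > 2) {
    stop("config error: 1 or 2 hidden layers supported", call. = FALSE)
  }
  if (any(hidden < 1) || input_dim < 1 || output_dim < 1) {
    stop("config error: layer widths must be >= 1", call. = FALSE)
  }
  structure(list(input_dim = as.integer(input_dim), hidden = hidden,
                 output_dim = as.integer(output_dim),
                 output_transfer = output_transfer),
            class = "network_topology")
}

#' Study topology grids
#'
#' Hidden-layer width presets: six for position prediction (8, 10, 12
#' single-layer; 7&5, 8&4, 9&3 double-layer) and eight for group
#' classification (8, 12, 16; 10&4, 12&6, 12&8, 14&6, 14&7).
#'
#' @return List of integer vectors of hidden widths.
#' @export
prediction_topologies <- function() {
  list(8L, 10L, 12L, c(7L, 5L), c(8L, 4L), c(9L, 3L))
}

#' @rdname prediction_topologies
#' @export
classification_topologies <- function() {
  list(8L, 12L, 16L, c(10L, 4L), c(12L, 6L), c(12L, 8L), c(14L, 6L), c(14L, 7L))
}

#' Levenberg-Marquardt training configuration
#'
#' @param max_epochs Maximum accepted-step iterations.
#' @param mse_goal Stop when training MSE falls below this.
#' @param lambda_init,lambda_up,lambda_down,lambda_max Damping
#'   schedule: lambda is multiplied by `lambda_down` (< 1) after an
#'   accepted step and by `lambda_up` (> 1) after a rejected one;
#'   training stops if lambda exceeds `lambda_max`.
#' @param grad_tol Stop when the infinity norm of the gradient falls
#'   below this.
#' @param seed Integer seed for weight initialization.
#' @param n_restarts Independent restarts in [train_network()]; the
#'   restart with the best validation MSE is kept.
#' @return An object of class `training_config`.
#' @export
training_config <- function(max_epochs = 200, mse_goal = 1e-5,
                            lambda_init = 1e-3, lambda_up = 10,
                            lambda_down = 0.1, lambda_max = 1e10,
                            grad_tol = 1e-7, seed = 1L, n_restarts = 3L) {
  stopifnot(max_epochs >= 1, mse_goal > 0, lambda_init > 0, lambda_max > 0,
            grad_tol > 0, n_restarts >= 1)
  if (!(lambda_up > 1 && lambda_down < 1 && lambda_down > 0)) {
    stop("config error: need lambda_up > 1 > lambda_down > 0", call. = FALSE)
  }
  structure(list(max_epochs = as.integer(max_epochs), mse_goal = mse_goal,
                 lambda_init = lambda_init, lambda_up = lambda_up,
                 lambda_down = lambda_down, lambda_max = lambda_max,
                 grad_tol = grad_tol, seed = as.integer(seed),
                 n_restarts = as.integer(n_restarts)),
            class = "training_config")
}

layer_dims <- function(topology) {
  c(topology$input_dim, topology$hidden, topology$output_dim)
}

#' Initialize an untrained network
#'
#' Weights drawn from Normal(0, 1/sqrt(fan-in)), biases zero;
#' deterministic given the seed.
#'
#' @param topology A [network_topology()].
#' @param seed Integer seed.
#' @return An object of class `trained_network` with empty history.
#' @export
init_network <- function(topology, seed = 1L) {
  stopifnot(inherits(topology, "network_topology"))
  dims <- layer_dims(topology)
  withr::with_seed(as.integer(seed), {
    layers <- lapply(seq_len(length(dims) - 1), function(l) {
      list(W = matrix(stats::rnorm(dims[l + 1] * dims[l], 0, 1 / sqrt(dims[l])),
                      dims[l + 1], dims[l]),
           b = rep(0, dims[l + 1]))
    })
    structure(list(topology = topology, layers = layers,
                   history = numeric(0), final_mse = NA_real_,
                   val_mse = NA_real_, seed = as.integer(seed)),
              class = "trained_network")
  })
}

#' @export
print.trained_network <- function(x, ...) {
  cat("<trained_network> ", x$topology$input_dim, "-",
      paste(x$topology$hidden, collapse = "-"), "-", x$topology$output_dim,
      " (", x$topology$output_transfer, " output), ",
      length(x$history), " accepted LM steps, training MSE ",
      formatC(x$final_mse, digits = 4, format = "g"), "\n", sep = "")
  invisible(x)
}

# Forward pass keeping all activations (for the Jacobian).
net_forward_full <- function(net, X) {
  A <- list(X)
  L <- length(net$layers)
  for (l in seq_len(L)) {
    Z <- X %*% t(net$layers[[l]]$W) + rep(net$layers[[l]]$b, each = nrow(X))
    X <- if (l < L || net$topology$output_transfer == "tanh") tanh(Z) else Z
    A[[l + 1]] <- X
  }
  A
}

#' Forward pass
#'
#' @param net A `trained_network`.
#' @param X Numeric matrix, one row per sample, `input_dim` columns.
#' @return Numeric matrix of outputs, one row per sample.
#' @export
forward <- function(net, X) {
  X <- as.matrix(X)
  if (ncol(X) != net$topology$input_dim) {
    stop("input has ", ncol(X), " columns; network expects ",
         net$topology$input_dim, call. = FALSE)
  }
  A <- net_forward_full(net, X)
  A[[length(A)]]
}

pack_params <- function(net) {
  unlist(lapply(net$layers, function(l) c(as.vector(l$W), l$b)), use.names = FALSE)
}

unpack_params <- function(net, theta) {
  i <- 0L
  for (l in seq_along(net$layers)) {
    W <- net$layers[[l]]$W
    nw <- length(W)
    nb <- nrow(W)
    net$layers[[l]]$W <- matrix(theta[i + seq_len(nw)], nrow(W), ncol(W))
    net$layers[[l]]$b <- theta[i + nw + seq_len(nb)]
    i <- i + nw + nb
  }
  net
}

# Analytic Jacobian of the network outputs with respect to all
# parameters, stacked output-by-output (rows: output 1 over all
# samples, then output 2, ...). Returns list(J, Y).
net_jacobian <- function(net, X) {
  A <- net_forward_full(net, X)
  L <- length(net$layers)
  N <- nrow(X)
  K <- net$topology$output_dim
  sizes <- vapply(net$layers, function(l) length(l$W) + length(l$b), numeric(1))
  offsets <- cumsum(c(0, sizes))
  P <- offsets[L + 1]
  Y <- A[[L + 1]]
  J <- matrix(0, N * K, P)
  for (k in seq_len(K)) {
    rows <- (k - 1) * N + seq_len(N)
    gk <- if (net$topology$output_transfer == "tanh") 1 - Y[, k]^2 else rep(1, N)
    # output layer: only row k of W_L is active
    Hin <- ncol(net$layers[[L]]$W)
    Ain <- A[[L]]
    colW <- offsets[L] + (seq_len(Hin) - 1) * K + k
    J[rows, colW] <- gk * Ain
    J[rows, offsets[L] + K * Hin + k] <- gk
    if (L > 1) {
      d <- (1 - Ain^2) * outer(gk, net$layers[[L]]$W[k, ])
      for (l in seq(L - 1, 1)) {
        Hl <- nrow(net$layers[[l]]$W)
        Hi <- ncol(net$layers[[l]]$W)
        Aprev <- A[[l]]
        blk <- offsets[l]
        idxW <- blk + seq_len(Hl * Hi)
        J[rows, idxW] <- d[, rep(seq_len(Hl), times = Hi)] *
          Aprev[, rep(seq_len(Hi), each = Hl), drop = FALSE]
        J[rows, blk + Hl * Hi + seq_len(Hl)] <- d
        if (l > 1) {
          d <- (1 - Aprev^2) * (d %*% net$layers[[l]]$W)
        }
      }
    }
  }
  list(J = J, Y = Y)
}

#' Train a network with the Levenberg-Marquardt method
#'
#' Iteratively solves (J'J + lambda I) delta = J'e, where J is the
#' analytic Jacobian of the outputs and e the residual vector. Steps
#' that reduce the sum of squared errors are accepted (lambda shrinks);
#' others are rejected (lambda grows). Stops at `max_epochs`,
#' `mse_goal`, `grad_tol`, or when lambda exceeds `lambda_max`. The
#' recorded history of accepted-step MSEs is strictly decreasing.
#'
#' @param net An initialized `trained_network`.
#' @param X Input matrix (samples x features).
#' @param Y Target matrix (samples x outputs) or vector.
#' @param config A [training_config()].
#' @return The trained `trained_network` with `history` and
#'   `final_mse` filled in.
#' @export
lm_train <- function(net, X, Y, config = training_config()) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 1,
            ncol(Y) == net$topology$output_dim)
  if (any(!is.finite(X)) || any(!is.finite(Y))) {
    stop("training error: non-finite inputs or targets", call. = FALSE)
  }
  N <- nrow(X); K <- ncol(Y)
  theta <- pack_params(net)
  P <- length(theta)
  lambda <- config$lambda_init
  sse_of <- function(th) {
    out <- forward(unpack_params(net, th), X)
    sum((Y - out)^2)
  }
  sse <- sse_of(theta)
  if (!is.finite(sse)) stop("training error: non-finite initial loss", call. = FALSE)
  history <- sse / (N * K)
  for (epoch in seq_len(config$max_epochs)) {
    if (sse / (N * K) <= config$mse_goal) break
    jb <- net_jacobian(unpack_params(net, theta), X)
    r <- as.vector(Y - jb$Y)
    g <- crossprod(jb$J, r)
    if (max(abs(g)) < config$grad_tol) break
    JtJ <- crossprod(jb$J)
    accepted <- FALSE
    while (!accepted && lambda <= config$lambda_max) {
      delta <- tryCatch(solve(JtJ + diag(lambda, P), g), error = function(e) NULL)
      if (!is.null(delta)) {
        theta_new <- theta + as.vector(delta)
        sse_new <- sse_of(theta_new)
        if (is.finite(sse_new) && sse_new < sse) {
          theta <- theta_new
          sse <- sse_new
          lambda <- max(lambda * config$lambda_down, 1e-20)
          accepted <- TRUE
        } else {
          lambda <- lambda * config$lambda_up
        }
      } else {
        lambda <- lambda * config$lambda_up
      }
    }
    if (!accepted) break
    history <- c(history, sse / (N * K))
  }
  net <- unpack_params(net, theta)
  net$history <- history
  net$final_mse <- sse / (N * K)
  net
}

#' Train with restarts, keeping the best validation MSE
#'
#' Runs [lm_train()] from `n_restarts` independent initializations
#' (seeds `config$seed`, `config$seed + 1`, ...). A deterministic 20%
#' slice of the training rows is held out as an internal validation
#' set for restart selection (never the evaluation data); with fewer
#' than ten rows, selection falls back to training MSE.
#'
#' @param topology A [network_topology()].
#' @param X,Y Training inputs and targets.
#' @param config A [training_config()].
#' @return The best `trained_network`; `val_mse` holds its internal
#'   validation MSE.
#' @export
train_network <- function(topology, X, Y, config = training_config()) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  N <- nrow(X)
  use_val <- N >= 10
  val_idx <- if (use_val) {
    withr::with_seed(config$seed, sample.int(N, max(1, floor(N / 5))))
  } else integer(0)
  fit_idx <- setdiff(seq_len(N), val_idx)
  best <- NULL
  for (r in seq_len(config$n_restarts)) {
    net0 <- init_network(topology, seed = config$seed + r - 1L)
    net <- lm_train(net0, X[fit_idx, , drop = FALSE], Y[fit_idx, , drop = FALSE],
                    config)
    score <- if (use_val) {
      mean((Y[val_idx, , drop = FALSE] -
              forward(net, X[val_idx, , drop = FALSE]))^2)
    } else net$final_mse
    net$val_mse <- score
    if (is.null(best) || score < best$val_mse) best <- net
  }
  best
}

#' Repeated k-fold cross-validation of position or group models
#'
#' Mirrors the study protocol: the data are split so that each model
#' is trained on 2/3 and tested on the held-out 1/3 (3 folds by
#' default, every record tested exactly once per repeat), the split is
#' repeated `n_repeats` times with derived seeds, and metrics are
#' averaged. Encodings are fitted on the training folds only.
#'
#' For `task = "position"` the network has one linear output trained on
#' scaled positions; predictions are decoded to integer positions and
#' summarized with [banded_accuracy()]. For `task = "group"` it has
#' three tanh outputs trained on the fuzzy memberships; the arg-max
#' group is compared with the group of the actual position
#' (overall efficiency = correct/all, plus the efficiency restricted
#' to actual positions 1-3).
#'
#' @param dataset A `hucul_dataset`.
#' @param spec A [feature_spec()].
#' @param hidden Hidden-layer widths (1 or 2 values).
#' @param task `"position"` or `"group"`.
#' @param config A [training_config()]; `config$seed` is the master
#'   seed for folds and restarts.
#' @param n_folds Number of folds (>= 2; default 3 gives the 2/3-1/3
#'   split).
#' @param n_repeats Number of repeated CV rounds.
#' @return An object of class `evaluation_report`.
#' @export
crossval <- function(dataset, spec = feature_spec(), hidden = 12L,
                     task = c("position", "group"),
                     config = training_config(), n_folds = 3L, n_repeats = 1L) {
  task <- match.arg(task)
  if (n_folds < 2) stop("config error: n_folds must be >= 2", call. = FALSE)
  starts <- dataset$starts
  N <- nrow(starts)
  if (N < n_folds) stop("config error: fewer rows than folds", call. = FALSE)
  per_repeat <- vector("list", n_repeats)
  confusion <- matrix(0L, 3, 3, dimnames = list(predicted = GROUP_LEVELS,
                                                actual = GROUP_LEVELS))
  for (rep_i in seq_len(n_repeats)) {
    rep_seed <- config$seed + 1000L * rep_i
    folds <- withr::with_seed(rep_seed, sample(rep_len(seq_len(n_folds), N)))
    pred_all <- integer(N)
    pred_grp <- character(N)
    for (f in seq_len(n_folds)) {
      test_idx <- which(folds == f)
      train_idx <- which(folds != f)
      Xall <- encode_features(dataset, spec, fit_rows = train_idx)
      cap <- attr(Xall, "field_cap")
      fold_cfg <- config
      fold_cfg$seed <- rep_seed + 10L * f
      topo <- network_topology(ncol(Xall), hidden,
                               output_dim = if (task == "position") 1L else 3L,
                               output_transfer = if (task == "position") "linear" else "tanh")
      if (task == "position") {
        y <- position_target(starts$position[train_idx], cap)
        net <- train_network(topo, Xall[train_idx, , drop = FALSE], y, fold_cfg)
        out <- forward(net, Xall[test_idx, , drop = FALSE])
        pred_all[test_idx] <- target_position(out[, 1], cap)
      } else {
        Ytr <- 2 * fuzzy_memberships(starts$position[train_idx]) - 1
        net <- train_network(topo, Xall[train_idx, , drop = FALSE], Ytr, fold_cfg)
        out <- forward(net, Xall[test_idx, , drop = FALSE])
        pred_grp[test_idx] <- as.character(decode_group(out))
      }
    }
    if (task == "position") {
      ba <- banded_accuracy(pred_all, starts$position)
      per_repeat[[rep_i]] <- tibble::tibble(
        repeat_i = rep_i, band_0 = ba$bands[["0"]],
        cum_0_3 = ba$cum_0_3, cum_0_6 = ba$cum_0_6)
    } else {
      actual <- position_group(starts$position)
      predicted <- factor(pred_grp, levels = GROUP_LEVELS)
      confusion <- confusion + table(predicted = predicted, actual = actual)
      eff <- accuracy_index(sum(predicted == actual), N)
      seff <- strong_group_efficiency(predicted, starts$position)
      per_repeat[[rep_i]] <- tibble::tibble(
        repeat_i = rep_i, efficiency = eff, strong_efficiency = seff)
    }
  }
  per <- dplyr::bind_rows(per_repeat)
  means <- colMeans(per[, setdiff(names(per), "repeat_i")])
  structure(list(task = task, hidden = hidden, n_folds = n_folds,
                 n_repeats = n_repeats, n = N,
                 config = config, per_repeat = per, mean = means,
                 confusion = if (task == "group") confusion else NULL),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> task=", x$task, ", hidden=",
      paste(x$hidden, collapse = "&"), ", ", x$n_folds, "-fold x ",
      x$n_repeats, " repeats, n=", x$n, "\n", sep = "")
  for (nm in names(x$mean)) {
    cat("  mean ", nm, ": ", formatC(x$mean[[nm]], digits = 4, format = "g"),
        "\n", sep = "")
  }
  invisible(x)
}

#' Save or load a trained network as JSON
#'
#' Plain-text serialization of topology, weights and biases.
#'
#' @param net A `trained_network`.
#' @param path File path.
#' @return `read_network()` returns the reconstructed network.
#' @export
write_network <- function(net, path) {
  obj <- list(topology = unclass(net$topology),
              layers = lapply(net$layers, function(l)
                list(W = as.vector(l$W), nrow = nrow(l$W), ncol = ncol(l$W),
                     b = l$b)),
              final_mse = net$final_mse, seed = net$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  topo <- network_topology(obj$topology$input_dim, obj$topology$hidden,
                           obj$topology$output_dim, obj$topology$output_transfer)
  layers <- lapply(seq_len(nrow(obj$layers)), function(i) {
    l <- obj$layers[i, ]
    list(W = matrix(l$W[[1]], l$nrow, l$ncol), b = as.numeric(l$b[[1]]))
  })
  structure(list(topology = topo, layers = layers, history = numeric(0),
                 final_mse = obj$final_mse, val_mse = NA_real_,
                 seed = obj$seed),
            class = "trained_network")
}
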