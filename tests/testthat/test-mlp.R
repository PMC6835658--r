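test_that("initialization is seed-deterministic with consistent shapes", {
  cfg <- mlp_config(c(3, 8, 5), "linear", seed = 7)
  net1 <- init_mlp(cfg)
  net2 <- init_mlp(cfg)
  expect_identical(net1$W, net2$W)
  expect_identical(net1$b, net2$b)
  expect_equal(dim(net1$W[[1]]), c(3, 8))
  expect_equal(dim(net1$W[[2]]), c(8, 5))
  expect_true(all(unlist(net1$W) >= -0.5 & unlist(net1$W) <= 0.5))

  net3 <- init_mlp(mlp_config(c(3, 8, 5), "linear", seed = 8))
  expect_false(identical(net1$W, net3$W))

  expect_error(mlp_config(c(3), "linear"), "length >= 2")
  expect_error(mlp_config(c(3, 0, 2), "linear"), "sizes >= 1")
  expect_error(mlp_config(c(3, 4, 2), c("linear", "relu")), "linear")
})

test_that("backprop gradients match central finite differences", {
  # depths 1-5 hidden layers, both activation families
  loss_at <- function(net, X, Y) {
    printletr:::mlp_loss(
      printletr:::mlp_forward_pass(net, X)[[length(net$W) + 1]], Y)
  }
  set.seed(42)
  for (depth in c(1, 2, 5)) {
    for (act in c("linear", "log_sigmoid")) {
      sizes <- c(3, rep(4, depth), 2)
      acts <- c(rep(act, depth), "linear")
      net <- init_mlp(mlp_config(sizes, acts, seed = depth * 10))
      X <- matrix(runif(5 * 3), 5, 3)
      Y <- matrix(runif(5 * 2), 5, 2)
      g <- printletr:::mlp_gradients(net, X, Y)
      eps <- 1e-5
      rel_err <- function(a, b) abs(a - b) / max(abs(b), 1e-8)
      for (l in seq_along(net$W)) {
        # probe the corner coordinates of each layer
        idx <- rbind(c(1, 1), c(nrow(net$W[[l]]), ncol(net$W[[l]])))
        for (r in seq_len(nrow(idx))) {
          i <- idx[r, 1]; j <- idx[r, 2]
          up <- net; up$W[[l]][i, j] <- up$W[[l]][i, j] + eps
          dn <- net; dn$W[[l]][i, j] <- dn$W[[l]][i, j] - eps
          num <- (loss_at(up, X, Y) - loss_at(dn, X, Y)) / (2 * eps)
          expect_lt(rel_err(g$W[[l]][i, j], num), 1e-6,
                    label = sprintf("W gradient rel err, depth %d act %s layer %d",
                                    depth, act, l))
        }
        upb <- net; upb$b[[l]][1] <- upb$b[[l]][1] + eps
        dnb <- net; dnb$b[[l]][1] <- dnb$b[[l]][1] - eps
        numb <- (loss_at(upb, X, Y) - loss_at(dnb, X, Y)) / (2 * eps)
        expect_lt(rel_err(g$b[[l]][1], numb), 1e-6,
                  label = sprintf("b gradient rel err, depth %d act %s layer %d",
                                  depth, act, l))
      }
    }
  }
})

test_that("an all-linear network reaches the closed-form least-squares loss", {
  set.seed(3)
  X <- matrix(runif(30 * 3, 0, 10), 30, 3)
  B <- matrix(c(1, -2, 3, 0.5, 1, -1), 3, 2)
  Y <- X %*% B + 2
  cfg <- mlp_config(c(3, 8, 2), "linear", max_epochs = 4000,
                    patience = 1000, seed = 2)
  net <- train_backprop(init_mlp(cfg), X, Y)

  # oracle: ordinary least squares on the scaled data
  Xs <- printletr:::apply_scaling(X, net$scaling$x)
  Ys <- printletr:::apply_scaling(Y, net$scaling$y)
  ls_fit <- lm.fit(cbind(1, Xs), Ys)
  ls_loss <- sum(ls_fit$residuals^2) / (2 * length(Ys))
  expect_equal(tail(net$history, 1), ls_loss,
               tolerance = 1e-6 + 1e-6 * max(ls_loss, 1))
})

test_that("a zero learning rate leaves weights untouched", {
  set.seed(9)
  X <- matrix(runif(12), 4, 3)
  Y <- matrix(runif(8), 4, 2)
  cfg <- mlp_config(c(3, 5, 2), "linear", learning_rate = 0,
                    max_epochs = 10, patience = 100, seed = 4)
  net0 <- init_mlp(cfg)
  trained <- train_backprop(net0, X, Y)
  expect_equal(trained$W, net0$W)
  expect_equal(trained$b, net0$b)
})

test_that("training loss decreases monotonically at a small learning rate", {
  set.seed(5)
  X <- matrix(runif(30), 10, 3)
  Y <- X %*% matrix(c(1, 2, 3), 3, 1)
  cfg <- mlp_config(c(3, 4, 1), "linear", learning_rate = 0.01,
                    momentum = 0, max_epochs = 500, patience = 1000,
                    seed = 6)
  net <- train_backprop(init_mlp(cfg), X, Y)
  expect_true(all(diff(net$history) <= 1e-12))
})

test_that("training is bit-identical across reruns", {
  st <- generate_study(8, seed = 12)
  x <- as.matrix(st$formulations[, c("pegda", "peg400", "water")])
  y <- t(sapply(st$profiles, function(p) p$released))
  cfg <- mlp_config(c(3, 6, 6), "linear", max_epochs = 300,
                    patience = 100, seed = 3)
  n1 <- train_backprop(init_mlp(cfg), x, y)
  n2 <- train_backprop(init_mlp(cfg), x, y)
  expect_identical(n1$history, n2$history)
  expect_identical(n1$W, n2$W)
})

test_that("architecture search ranks the grid deterministically", {
  set.seed(8)
  X <- matrix(runif(40 * 3, 0, 10), 40, 3)
  Y <- X %*% matrix(c(2, 1, 3, -1, 0.5, 2), 3, 2)
  tmpl <- mlp_config(c(1, 1), "linear", max_epochs = 400, patience = 100,
                     seed = 10)
  s1 <- architecture_search(X[1:30, ], Y[1:30, ], X[31:40, ], Y[31:40, ],
                            hidden_layers = 1:2, nodes = c(4, 6),
                            template = tmpl)
  expect_equal(nrow(s1$leaderboard), 4)
  s2 <- architecture_search(X[1:30, ], Y[1:30, ], X[31:40, ], Y[31:40, ],
                            hidden_layers = 1:2, nodes = c(4, 6),
                            template = tmpl)
  expect_identical(s1$leaderboard, s2$leaderboard)
  expect_equal(s1$best_config$layer_sizes[1], 3L)

  # on linearly generated data no deeper linear net beats one hidden
  # layer by more than tolerance: all grid cells reach near-zero RMS
  best_1layer <- min(s1$leaderboard$rms[s1$leaderboard$hidden_layers == 1])
  best_deeper <- min(s1$leaderboard$rms[s1$leaderboard$hidden_layers == 2])
  expect_lt(abs(best_1layer - best_deeper), 0.02)
})

test_that("release prediction handles both published input layouts", {
  st <- generate_study(10, ground_truth(noise_sd = 0.5), seed = 14)
  x3 <- as.matrix(st$formulations[, c("pegda", "peg400", "water")])
  y <- t(sapply(st$profiles, function(p) p$released))
  y5 <- y[, match(c(1, 2, 4, 6, 8), st$times)]

  nn1 <- train_backprop(
    init_mlp(mlp_config(c(3, 8, 5), "linear", max_epochs = 2000,
                        patience = 200, seed = 2)),
    x3[1:8, ], y5[1:8, ], x3[9:10, ], y5[9:10, ])
  pred <- predict_release(nn1, st$formulations[10, ])
  expect_equal(nrow(pred), 5)
  expect_equal(pred$time_h, c(1, 2, 4, 6, 8))
  expect_true(all(pred$released_pct >= 0 & pred$released_pct <= 100))

  # 4-input variant takes exposure time; refusing it is an error
  x4 <- cbind(x3, exposure_time_rule(st$formulations$water))
  y4 <- y[, match(c(2, 4, 6, 8), st$times)]
  nn2 <- train_backprop(
    init_mlp(mlp_config(c(4, 5, 5, 6, 5, 6, 4),
                        c(rep("log_sigmoid", 5), "linear"),
                        max_epochs = 500, patience = 100, seed = 3)),
    x4[1:9, ], y4[1:9, ], x4[10, , drop = FALSE], y4[10, , drop = FALSE])
  expect_error(predict_release(nn2, st$formulations[1, ]),
               "exposure_time")
  pred2 <- predict_release(nn2, st$formulations[1, ], exposure_time = 600)
  expect_equal(nrow(pred2), 4)
})

test_that("a trained surrogate predicts held-out synthetic formulations well", {
  st <- generate_study(11, ground_truth(noise_sd = 2), seed = 18)
  x <- as.matrix(st$formulations[, c("pegda", "peg400", "water")])
  y <- t(sapply(st$profiles, function(p) p$released))
  tr <- 1:8; te <- 9:11
  net <- train_backprop(
    init_mlp(mlp_config(c(3, 8, ncol(y)), "linear", max_epochs = 4000,
                        patience = 400, seed = 5)),
    x[tr, ], y[tr, ])
  pred <- printletr::mlp_predict(net, x[te, ])
  r2 <- cor(as.numeric(y[te, ]), as.numeric(pred))^2
  expect_gte(r2, 0.9)
})

test_that("cross-check: the all-linear surrogate agrees with an nnet skip-layer linear model", {
  # independent reference: nnet with size 0 and a skip layer is exactly a
  # linear model; our all-linear MLP must reach the same fit on the same
  # scaled data
  st <- generate_study(12, ground_truth(noise_sd = 1), seed = 22)
  x <- as.matrix(st$formulations[, c("pegda", "peg400", "water")])
  y8 <- vapply(st$profiles, function(p) p$released[6], numeric(1))
  net <- train_backprop(
    init_mlp(mlp_config(c(3, 6, 1), "linear", max_epochs = 4000,
                        patience = 500, seed = 7)),
    x, matrix(y8, ncol = 1))
  xs <- printletr:::apply_scaling(x, net$scaling$x)
  ys <- printletr:::apply_scaling(matrix(y8, ncol = 1), net$scaling$y)
  ref <- nnet::nnet(xs, ys, size = 0, skip = TRUE, linout = TRUE,
                    trace = FALSE, reltol = 1e-12)
  ours <- printletr:::mlp_forward_pass(net, xs)[[3]]
  expect_equal(as.numeric(ours), as.numeric(ref$fitted.values),
               tolerance = 1e-3)
})

test_that("weight bundles survive a YAML round trip", {
  st <- generate_study(6, seed = 25)
  x <- as.matrix(st$formulations[, c("pegda", "peg400", "water")])
  y <- t(sapply(st$profiles, function(p) p$released))
  net <- train_backprop(
    init_mlp(mlp_config(c(3, 4, ncol(y)), "linear", max_epochs = 200,
                        patience = 50, seed = 1)), x, y)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_mlp(net, path)
  back <- read_mlp(path)
  expect_equal(lapply(back$W, unname), lapply(net$W, unname),
               tolerance = 1e-12)
  expect_equal(printletr::mlp_predict(back, x[1, ]),
               printletr::mlp_predict(net, x[1, ]), tolerance = 1e-9)
})

test_that("divergent training reports the failing epoch", {
  set.seed(2)
  X <- matrix(runif(30, 0, 10), 10, 3)
  Y <- X %*% matrix(c(5, 5, 5), 3, 1)
  # absurdly large learning rate cannot converge
  cfg <- mlp_config(c(3, 10, 1), "linear", learning_rate = 1,
                    momentum = 0.99, max_epochs = 5000, patience = 5000,
                    seed = 3)
  expect_error(train_backprop(init_mlp(cfg), X, Y), "diverged|epoch")
})
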