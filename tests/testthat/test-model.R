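# pure-R reference forward pass (evaluation mode) used as oracle
conv_same_ref <- function(W, x, k) {
  C_in <- nrow(x)
  L <- ncol(x)
  h <- (k - 1) / 2
  out <- matrix(0, nrow(W), L)
  for (t in seq_len(L)) {
    for (o in -h:h) {
      tt <- t + o
      if (tt < 1 || tt > L) next
      cols <- (o + h) * C_in + seq_len(C_in)
      out[, t] <- out[, t] + W[, cols, drop = FALSE] %*% x[, tt]
    }
  }
  out
}

bn_eval_ref <- function(x, g, b, rm, rv) {
  sweep(sweep(x, 1, rm) * (g / sqrt(rv + 1e-5)), 1, b, `+`)
}

block_forward_ref <- function(w, x) {
  b1 <- conv_same_ref(w$W1, x, 1)
  c3 <- conv_same_ref(w$W3, conv_same_ref(w$Wb3, x, 1), 3)
  c5 <- conv_same_ref(w$W5, conv_same_ref(w$Wb5, x, 1), 5)
  c7 <- conv_same_ref(w$W7, conv_same_ref(w$Wb7, x, 1), 7)
  P <- rbind(b1, c3, c5, c7)
  I <- bn_eval_ref(P, w$gi, w$bi, w$rmi, w$rvi)
  R <- bn_eval_ref(conv_same_ref(w$Wr, x, 1), w$gr, w$br, w$rmr, w$rvr)
  pmax(I + R, 0)
}

test_that("compiled forward pass matches the pure-R reference", {
  model <- inception_model(model_spec(n_blocks = 2), seed = 21)
  set.seed(22)
  # give the (zero-initialized) head nontrivial weights so the oracle
  # comparison exercises the full path
  model$weights$head$W[] <- rnorm(128, 0, 0.05)
  model$weights$head$b <- 0.1
  x <- matrix(rnorm(2 * 40), 2, 40)
  y1 <- block_forward_ref(model$weights$blocks[[1]], x)
  y2 <- block_forward_ref(model$weights$blocks[[2]], y1)
  z <- as.vector(model$weights$head$W %*% y2) + model$weights$head$b
  p_ref <- 1 / (1 + exp(-z))
  p_cpp <- predict_proba(model, array(x, c(1, 2, 40)))
  expect_equal(as.vector(p_cpp), p_ref, tolerance = 1e-10)
  expect_equal(inception_block_forward(model, x, 1), y1, tolerance = 1e-10)
})

test_that("inception blocks emit 128 channels and preserve length", {
  model <- inception_model(model_spec(n_blocks = 3), seed = 1)
  set.seed(2)
  y <- inception_block_forward(model, matrix(rnorm(200), 2, 100), 1)
  expect_equal(dim(y), c(128, 100))
  expect_true(all(y >= 0)) # ReLU output
  y2 <- inception_block_forward(model, y, 2) # interior block: 128 -> 128
  expect_equal(dim(y2), c(128, 100))
  expect_error(inception_block_forward(model, y, 1), "input channels")

  for (T_ in c(7, 31, 64)) {
    p <- predict_proba(model, array(rnorm(2 * T_ * 4), c(4, 2, T_)))
    expect_equal(dim(p), c(4, T_))
  }
})

test_that("forward output is a deterministic probability field", {
  model <- inception_model(model_spec(n_blocks = 2), seed = 5)
  set.seed(6)
  X <- array(rnorm(50 * 2 * 100), c(50, 2, 100))
  p <- predict_proba(model, X)
  expect_equal(dim(p), c(50, 100))
  expect_true(all(p > 0 & p < 1))
  expect_identical(predict_proba(model, X), p) # eval mode is deterministic
  # a freshly initialized model sits near maximum uncertainty
  expect_lt(abs(mean(p) - 0.5), 0.2)
  # the zero head makes that exact: sigmoid(0) = 0.5 everywhere
  expect_equal(as.vector(p), rep(0.5, 5000))

  expect_error(predict_proba(model, array(0, c(2, 3, 50))), "N x 2 x T")
  expect_error(predict_proba(model, array(0, c(2, 2, 3))), "kernel")
})

test_that("model structure follows the spec: blocks, head, channel ledger", {
  spec <- model_spec(n_blocks = 4)
  model <- inception_model(spec, seed = 9)
  expect_length(model$weights$blocks, 4)
  expect_equal(dim(model$weights$head$W), c(1, 128)) # 128 -> 1 pointwise + bias
  expect_length(model$weights$head$b, 1)
  # first block expands 2 channels, later blocks bottleneck 128 -> 32
  expect_equal(dim(model$weights$blocks[[1]]$Wb7), c(32, 2))
  expect_equal(dim(model$weights$blocks[[2]]$Wb7), c(32, 128))
  expect_equal(dim(model$weights$blocks[[2]]$W7), c(32, 32 * 7))
  expect_equal(dim(model$weights$blocks[[2]]$Wr), c(128, 128))

  ledger <- count_channels(spec)
  expect_equal(ledger$c_in, c(2, 128, 128, 128))
  expect_equal(ledger$branch, rep(32, 4))
  expect_equal(ledger$concat, rep(128, 4))
  expect_true(all(ledger$ok))

  bad <- model_spec(kernel_sizes = c(1, 3, 5))
  expect_equal(count_channels(bad)$concat[1], 96)
  expect_false(any(count_channels(bad)$ok))
  expect_error(inception_model(bad), "fixed at kernel sizes")
})

test_that("initialization is reproducible under a seed", {
  a <- inception_model(model_spec(n_blocks = 2), seed = 77)
  b <- inception_model(model_spec(n_blocks = 2), seed = 77)
  expect_identical(a$weights, b$weights)
})

test_that("analytic gradients match central finite differences", {
  model <- inception_model(model_spec(n_blocks = 2), seed = 31)
  set.seed(32)
  X <- array(rnorm(3 * 2 * 12), c(3, 2, 12))
  Y <- matrix(rbinom(36, 1, 0.5), 3, 12)
  g <- sprintgc:::.cpp_loss_grads(model$weights, X, Y)
  eps <- 1e-6
  fd_block <- function(b, nm, k) {
    wp <- model$weights
    wm <- model$weights
    wp$blocks[[b]][[nm]][k] <- wp$blocks[[b]][[nm]][k] + eps
    wm$blocks[[b]][[nm]][k] <- wm$blocks[[b]][[nm]][k] - eps
    (sprintgc:::.cpp_loss_grads(wp, X, Y)$loss -
      sprintgc:::.cpp_loss_grads(wm, X, Y)$loss) / (2 * eps)
  }
  for (nm in c("W1", "Wb3", "W3", "Wb5", "W5", "Wb7", "W7", "Wr", "gi", "bi", "gr", "br")) {
    for (b in 1:2) {
      expect_equal(g$blocks[[b]][[nm]][1], fd_block(b, nm, 1), tolerance = 1e-4)
      expect_equal(g$blocks[[b]][[nm]][7], fd_block(b, nm, 7), tolerance = 1e-4)
    }
  }
  wp <- model$weights
  wp$head$W[1] <- wp$head$W[1] + eps
  wm <- model$weights
  wm$head$W[1] <- wm$head$W[1] - eps
  fd <- (sprintgc:::.cpp_loss_grads(wp, X, Y)$loss -
    sprintgc:::.cpp_loss_grads(wm, X, Y)$loss) / (2 * eps)
  expect_equal(g$head$W[1], fd, tolerance = 1e-4)
})
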