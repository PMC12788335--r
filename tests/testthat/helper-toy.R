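# Small shared fixtures, built in code at test time.

# short synthetic runs for fast training smoke tests
toy_runs <- function(n = 6, n_steps = 5, seed = 5) {
  cfg <- gait_sim_config(n_steps = n_steps, seed = seed)
  lapply(seq_len(n), function(i) {
    generate_run(cfg, sprintf("T%02d", (i + 1) %/% 2), sprintf("R%d", i), "left")
  })
}

# one trained toy model, cached for the whole test session
.toy_cache <- new.env(parent = emptyenv())
toy_fit <- function() {
  if (is.null(.toy_cache$fit)) {
    runs <- toy_runs()
    tr <- build_dataset(runs[1:4], window = 50, stride = 10)
    va <- build_dataset(runs[5:6], window = 50, stride = 10)
    model <- inception_model(model_spec(n_blocks = 6, lr = 0.01), seed = 3)
    .toy_cache$fit <- fit_gc_model(model, tr, va,
      train_config(max_epochs = 15, batch_size = 50, patience = 6),
      seed = 3
    )
    .toy_cache$runs <- runs
  }
  list(fit = .toy_cache$fit, runs = .toy_cache$runs)
}

# brute-force Rand index by explicit enumeration of all frame pairs
rand_index_brute <- function(a, b) {
  L <- length(a)
  agree <- 0
  total <- 0
  for (i in 1:(L - 1)) {
    for (j in (i + 1):L) {
      total <- total + 1
      if ((a[i] == a[j]) == (b[i] == b[j])) agree <- agree + 1
    }
  }
  agree / total
}

# exhaustive symmetric nearest-neighbour distances
transition_distances_brute <- function(p, t) {
  one <- function(from, to) {
    vapply(from, function(x) {
      best <- Inf
      for (y in to) best <- min(best, abs(x - y))
      best
    }, numeric(1))
  }
  c(one(t, p), one(p, t))
}

# exact two-sided signed-rank p-value by enumerating all 2^n sign vectors
wilcoxon_exact_brute <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}
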