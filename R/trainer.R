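#' Training configuration
#'
#' Adam optimization of per-timestep binary cross-entropy with early
#' stopping on the validation loss: training terminates once the validation
#' BCE has failed to improve (strictly) for `patience` consecutive epochs,
#' and the weights from the best-validation epoch are restored.
#'
#' @param max_epochs Maximum number of epochs (default 30).
#' @param batch_size Minibatch size in windows (default 50).
#' @param patience Consecutive non-improving epochs tolerated (default 5).
#' @return A `gc_train_config` list.
#' @export
train_config <- function(max_epochs = 30, batch_size = 50, patience = 5) {
  if (batch_size < 1) abort("batch_size must be at least 1")
  if (patience >= max_epochs) abort("patience must be smaller than max_epochs")
  structure(list(
    max_epochs = as.integer(max_epochs),
    batch_size = as.integer(batch_size),
    patience = as.integer(patience)
  ), class = "gc_train_config")
}

#' Early-stopping bookkeeping on a loss sequence
#'
#' Pure reference implementation of the stopping rule applied during
#' training: "improvement" means strictly lower than the best value seen so
#' far; training stops after the first epoch at which `patience` consecutive
#' epochs have failed to improve.
#'
#' @param val_loss Numeric vector of per-epoch validation losses.
#' @param patience Consecutive non-improving epochs tolerated.
#' @return List with `stop_epoch` (last epoch run) and `best_epoch`.
#' @export
early_stopping_trace <- function(val_loss, patience) {
  best <- Inf
  best_epoch <- 0L
  since <- 0L
  for (e in seq_along(val_loss)) {
    if (val_loss[e] < best) {
      best <- val_loss[e]
      best_epoch <- e
      since <- 0L
    } else {
      since <- since + 1L
    }
    if (since >= patience) {
      return(list(stop_epoch = e, best_epoch = best_epoch))
    }
  }
  list(stop_epoch = length(val_loss), best_epoch = best_epoch)
}

#' Train the contact classifier
#'
#' Minibatch Adam on shuffled windows, mean per-timestep binary
#' cross-entropy, early stopping on validation BCE (evaluation-mode forward
#' with running batch-norm statistics), restoration of best-epoch weights.
#' With a fixed `seed` the loss history is bit-reproducible.
#'
#' @param model An untrained (or pre-trained) `gc_model`.
#' @param train_set,val_set `gc_dataset`/`gc_windows` objects with label
#'   tensors (see [build_dataset()]); window sizes must agree.
#' @param config A [train_config()].
#' @param seed RNG seed governing minibatch shuffling.
#' @return A `gc_fit`: the trained model plus `history` (tibble `epoch`,
#'   `train_loss`, `val_loss`), `best_epoch`, `epochs_run`,
#'   `stopped_early`, `config` and `seed`.
#' @export
fit_gc_model <- function(model, train_set, val_set, config = train_config(),
                         seed = NULL) {
  stopifnot(inherits(model, "gc_model"), inherits(config, "gc_train_config"))
  for (s in list(train_set, val_set)) {
    if (is.null(s$Y)) abort("training requires label tensors (Y) in both sets")
    if (dim(s$X)[1] == 0) abort("training requires nonempty window sets")
  }
  if (train_set$window != val_set$window) abort("train and validation window sizes differ")
  res <- local_seed(seed, .cpp_train(
    model$weights,
    train_set$X, train_set$Y, val_set$X, val_set$Y,
    lr = model$spec$lr, batch_size = config$batch_size,
    max_epochs = config$max_epochs, patience = config$patience
  ))
  model$weights <- res$weights
  model$trained <- TRUE
  structure(list(
    model = model,
    history = tibble(
      epoch = seq_along(res$train_loss),
      train_loss = res$train_loss, val_loss = res$val_loss
    ),
    best_epoch = res$best_epoch,
    best_val_loss = res$best_val_loss,
    epochs_run = res$epochs_run,
    stopped_early = res$stopped_early,
    config = config, seed = seed,
    window = train_set$window, stride = train_set$stride
  ), class = "gc_fit")
}

#' @export
print.gc_fit <- function(x, ...) {
  cat(sprintf(
    "<gc_fit> %d blocks, window %d / stride %d; %d epochs (best %d, val BCE %.4f)%s\n",
    x$model$spec$n_blocks, x$window, x$stride, x$epochs_run, x$best_epoch,
    x$best_val_loss, if (x$stopped_early) ", stopped early" else ""
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a fitted contact model
#'
#' @param x A `gc_fit`.
#' @param ... Unused.
#' @return Tibble with one row per (epoch, loss type): `epoch`, `metric`,
#'   `loss`.
#' @export
tidy.gc_fit <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"epoch", names_to = "metric", values_to = "loss")
}

#' One-row summary of a fitted contact model
#'
#' @param x A `gc_fit`.
#' @param ... Unused.
#' @return One-row tibble: blocks, window, stride, lr, epochs run, best
#'   epoch, best validation BCE, early-stop flag.
#' @export
glance.gc_fit <- function(x, ...) {
  tibble(
    n_blocks = x$model$spec$n_blocks, window = x$window, stride = x$stride,
    lr = x$model$spec$lr, epochs_run = x$epochs_run,
    best_epoch = x$best_epoch, best_val_loss = x$best_val_loss,
    stopped_early = x$stopped_early
  )
}

#' Hyperparameter grid
#'
#' The search space over window size, stride, block count and learning rate.
#' Defaults reproduce the full tuning grid of the source study; combinations
#' with `stride >= window` are skipped at enumeration time.
#'
#' @param window,stride,n_blocks,lr Candidate values.
#' @return A `gc_tune_grid` list.
#' @export
tune_grid_spec <- function(window = c(25, 50, 75, 100, 150, 200),
                           stride = c(5, 10, 15, 20, 25, 30),
                           n_blocks = c(6, 9, 12, 15, 18, 21),
                           lr = c(0.01, 0.001, 0.0001)) {
  structure(list(window = window, stride = stride, n_blocks = n_blocks, lr = lr),
    class = "gc_tune_grid"
  )
}

#' Enumerate valid hyperparameter combinations
#'
#' Cartesian product of the grid minus combinations with
#' `stride >= window`, in deterministic order. The default grid yields 612
#' combinations (648 minus 36 skipped).
#'
#' @param grid A [tune_grid_spec()].
#' @return Tibble with columns `window`, `stride`, `n_blocks`, `lr`.
#' @export
enumerate_grid <- function(grid = tune_grid_spec()) {
  stopifnot(inherits(grid, "gc_tune_grid"))
  combos <- tidyr::expand_grid(
    window = grid$window, stride = grid$stride,
    n_blocks = grid$n_blocks, lr = grid$lr
  )
  dplyr::filter(combos, .data$stride < .data$window)
}

#' Grid-search hyperparameter tuning against validation mean Hausdorff
#'
#' For each grid combination: build TRAIN/VAL datasets at that (window,
#' stride), train with early stopping, predict the VAL streams end to end
#' (including postprocessing, so model selection is not driven by easily
#' removable false spikes), and score the mean of per-stream mean Hausdorff
#' distances between predicted and true transitions. The leaderboard is
#' ranked ascending; ties break toward fewer blocks, then larger stride
#' (the cheaper model).
#'
#' @param train_runs,val_runs Lists of labelled [gc_run()] streams.
#' @param grid A [tune_grid_spec()].
#' @param config A [train_config()].
#' @param seed Master seed; per-combination seeds are derived
#'   deterministically from it and the combination index.
#' @return List with `best` (one-row tibble), `leaderboard` (tibble ranked
#'   by objective, including epochs run and a list column of per-stream
#'   postprocessed predictions), and `best_fit` (the refitted best
#'   `gc_fit`).
#' @export
tune_gc <- function(train_runs, val_runs, grid = tune_grid_spec(),
                    config = train_config(), seed = 1L) {
  combos <- enumerate_grid(grid)
  if (!nrow(combos)) abort("grid contains no valid combination")
  if (!length(train_runs) || !length(val_runs)) abort("TRAIN and VAL must be nonempty")
  rows <- vector("list", nrow(combos))
  fits <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    seed_i <- as.integer((as.double(seed) + 7919 * i) %% .Machine$integer.max)
    res <- tryCatch(
      tune_one(train_runs, val_runs, cb, config, seed_i),
      error = function(e) list(error = conditionMessage(e))
    )
    if (!is.null(res$error)) {
      rows[[i]] <- dplyr::mutate(cb,
        objective = Inf, epochs_run = NA_integer_,
        best_epoch = NA_integer_, error = res$error,
        predictions = list(NULL)
      )
    } else {
      rows[[i]] <- dplyr::mutate(cb,
        objective = res$objective, epochs_run = res$fit$epochs_run,
        best_epoch = res$fit$best_epoch, error = NA_character_,
        predictions = list(res$predictions)
      )
      fits[[i]] <- res$fit
    }
  }
  leaderboard <- dplyr::bind_rows(rows)
  if (all(!is.finite(leaderboard$objective))) {
    abort(paste(
      "all grid combinations failed:",
      paste(unique(stats::na.omit(leaderboard$error)), collapse = "; ")
    ))
  }
  ord <- order(leaderboard$objective, leaderboard$n_blocks, -leaderboard$stride)
  leaderboard <- leaderboard[ord, ]
  fits <- fits[ord]
  list(
    best = leaderboard[1, setdiff(names(leaderboard), "predictions")],
    leaderboard = leaderboard,
    best_fit = fits[[1]]
  )
}

tune_one <- function(train_runs, val_runs, cb, config, seed_i) {
  tr <- build_dataset(train_runs, cb$window, cb$stride)
  va <- build_dataset(val_runs, cb$window, cb$stride)
  model <- inception_model(model_spec(n_blocks = cb$n_blocks, lr = cb$lr),
    seed = seed_i
  )
  fit <- fit_gc_model(model, tr, va, config, seed = seed_i)
  preds <- lapply(val_runs, function(r) {
    predict_contacts(fit, r, postprocess = TRUE)
  })
  hd <- vapply(seq_along(val_runs), function(j) {
    truth <- extract_segments(val_runs[[j]]$label, fs = attr(val_runs[[j]], "fs"))
    pred <- preds[[j]]$segments
    if (!nrow(pred) || !nrow(truth)) {
      return(NA_real_)
    }
    mean(transition_distances(all_transitions(pred), all_transitions(truth)))
  }, numeric(1))
  objective <- if (anyNA(hd)) Inf else mean(hd)
  list(
    objective = objective, fit = fit,
    predictions = lapply(preds, function(p) p$binary)
  )
}
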