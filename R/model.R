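#' Specification of the inception-block contact classifier
#'
#' The classifier stacks `n_blocks` inception blocks. Each block runs four
#' parallel convolutional branches over the temporal axis with kernel sizes
#' 1, 3, 5 and 7: the kernel-1 branch is a single pointwise convolution to 32
#' channels; the wider branches first apply a pointwise bottleneck to 32
#' channels and then their temporal convolution (32 -> 32). Branch outputs
#' are concatenated (4 x 32 = 128 channels), batch-normalized, summed with a
#' batch-normalized pointwise residual projection of the block input, and
#' passed through ReLU. Convolutions are "same"-padded so every block
#' preserves sequence length; convolutions followed by batch norm carry no
#' bias. A pointwise 128 -> 1 convolution with bias and a sigmoid maps the
#' last block's features to one contact probability per timestep. No
#' activation or normalization is applied inside the branches; batch norm
#' appears only after the concatenation and after the residual projection.
#'
#' @param n_blocks Number of inception blocks (tuned value in the source
#'   study: 18).
#' @param lr Adam learning rate used when the model is trained (tuned: 0.01).
#' @param in_channels Input channels (2: resultant acceleration and angular
#'   velocity).
#' @param kernel_sizes,branch_filters Fixed at `c(1,3,5,7)` and 32; exposed
#'   for the channel-ledger arithmetic in [count_channels()].
#' @return A `gc_model_spec` list; `concat_channels` is derived as
#'   `length(kernel_sizes) * branch_filters` and must equal 128 for the
#'   compiled network.
#' @export
model_spec <- function(n_blocks = 18, lr = 0.01, in_channels = 2,
                       kernel_sizes = c(1, 3, 5, 7), branch_filters = 32) {
  if (n_blocks < 1) abort("n_blocks must be at least 1")
  spec <- list(
    n_blocks = as.integer(n_blocks), lr = lr,
    in_channels = as.integer(in_channels),
    kernel_sizes = as.integer(kernel_sizes),
    branch_filters = as.integer(branch_filters),
    concat_channels = length(kernel_sizes) * as.integer(branch_filters)
  )
  structure(spec, class = "gc_model_spec")
}

# Kaiming-uniform (fan-in, ReLU gain) weight matrix
kaiming_uniform <- function(n_out, fan_in) {
  bound <- sqrt(6 / fan_in)
  matrix(runif(n_out * fan_in, -bound, bound), n_out, fan_in)
}

new_block_weights <- function(c_in) {
  bf <- 32L
  list(
    W1 = kaiming_uniform(bf, c_in),
    Wb3 = kaiming_uniform(bf, c_in), W3 = kaiming_uniform(bf, bf * 3),
    Wb5 = kaiming_uniform(bf, c_in), W5 = kaiming_uniform(bf, bf * 5),
    Wb7 = kaiming_uniform(bf, c_in), W7 = kaiming_uniform(bf, bf * 7),
    Wr = kaiming_uniform(128L, c_in),
    gi = rep(1, 128), bi = rep(0, 128), gr = rep(1, 128), br = rep(0, 128),
    rmi = rep(0, 128), rvi = rep(1, 128), rmr = rep(0, 128), rvr = rep(1, 128)
  )
}

#' Initialize an inception contact model
#'
#' Convolution weights are drawn Kaiming-uniform (fan-in scaling); batch-norm
#' scale/shift start at 1/0 and running statistics at 0/1. The classifier
#' head starts at zero, so an untrained model outputs probability 0.5
#' (maximal uncertainty) at every timestep. The seed is recorded in the
#' model for provenance.
#'
#' @param spec A [model_spec()].
#' @param seed Optional RNG seed for reproducible initialization.
#' @return A `gc_model` list with fields `spec`, `weights`, `seed`,
#'   `trained`.
#' @export
inception_model <- function(spec = model_spec(), seed = NULL) {
  stopifnot(inherits(spec, "gc_model_spec"))
  if (!identical(spec$kernel_sizes, c(1L, 3L, 5L, 7L)) || spec$branch_filters != 32L) {
    abort("the compiled network is fixed at kernel sizes {1,3,5,7} with 32 branch filters")
  }
  init <- function() {
    blocks <- lapply(seq_len(spec$n_blocks), function(b) {
      new_block_weights(if (b == 1) spec$in_channels else 128L)
    })
    head <- list(W = matrix(0, 1L, 128L), b = 0)
    list(blocks = blocks, head = head)
  }
  weights <- local_seed(seed, init())
  structure(list(spec = spec, weights = weights, seed = seed, trained = FALSE),
    class = "gc_model"
  )
}

#' @export
print.gc_model <- function(x, ...) {
  cat(sprintf(
    "<gc_model> %d inception blocks (%d -> 128 channels), lr %g, %strained\n",
    x$spec$n_blocks, x$spec$in_channels, x$spec$lr,
    if (x$trained) "" else "un"
  ))
  invisible(x)
}

#' Forward pass: per-timestep contact probabilities
#'
#' Evaluation-mode forward pass (batch norm uses running statistics), so the
#' output is deterministic for fixed weights.
#'
#' @param model A `gc_model`.
#' @param X N x 2 x T array of scaled windows (or a single 2 x T matrix).
#' @return N x T matrix of probabilities in (0, 1).
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "gc_model"))
  if (is.matrix(X)) X <- array(X, c(1, nrow(X), ncol(X)))
  if (length(dim(X)) != 3 || dim(X)[2] != model$spec$in_channels) {
    abort(sprintf("X must be N x %d x T", model$spec$in_channels))
  }
  if (dim(X)[3] < max(model$spec$kernel_sizes)) {
    abort("window shorter than the largest kernel")
  }
  .cpp_predict(model$weights, X)
}

#' Run one inception block on a multichannel sequence
#'
#' Exposes a single block (evaluation mode) for architecture checks: the
#' output always has 128 channels and the input's sequence length.
#'
#' @param model A `gc_model`.
#' @param x C_in x L matrix (C_in must match the block's input width).
#' @param block Block index.
#' @return 128 x L matrix (nonnegative: ReLU output).
#' @export
inception_block_forward <- function(model, x, block = 1) {
  stopifnot(inherits(model, "gc_model"))
  w <- model$weights$blocks[[block]]
  if (nrow(x) != ncol(w$W1)) {
    abort(sprintf("block %d expects %d input channels, got %d", block, ncol(w$W1), nrow(x)))
  }
  .cpp_block_forward(w, x)
}

#' Per-stage channel ledger of a model spec
#'
#' Reports, per block, the input channels, branch width, concatenated width
#' and residual width, and checks the architecture invariant that the
#' concatenation equals `length(kernel_sizes) * branch_filters` = 128.
#'
#' @param spec A [model_spec()].
#' @return Tibble with one row per block and columns `block`, `c_in`,
#'   `branch`, `concat`, `residual`, `ok` (invariant satisfied).
#' @export
count_channels <- function(spec) {
  stopifnot(inherits(spec, "gc_model_spec"))
  concat <- length(spec$kernel_sizes) * spec$branch_filters
  ok <- concat == spec$concat_channels && concat == 128L
  tibble(
    block = seq_len(spec$n_blocks),
    c_in = c(spec$in_channels, rep(concat, spec$n_blocks - 1)),
    branch = spec$branch_filters,
    concat = concat,
    residual = concat,
    ok = ok
  )
}
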