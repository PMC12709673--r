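#' Model configuration for the multi-label MLP
#'
#' Defaults are the reference training recipe: two 500-unit ReLU hidden
#' layers, a 7-unit sigmoid output head, Adam with learning rate 1e-4 and
#' L2 weight decay 5e-4, 10 epochs with batch size 1028, summed per-target
#' binary cross-entropy loss, and stratum-weighted sampling with
#' replacement.  Smaller hidden sizes are useful for desk-scale
#' experiments.
#'
#' @param hidden_sizes Integer vector of hidden-layer widths.
#' @param output_dim Number of targets (sigmoid outputs).
#' @param learning_rate,weight_decay Adam step size and L2 penalty.
#' @param epochs,batch_size Training schedule.
#' @param seed Integer seed controlling initialization and sampling.
#' @return List of class `kb_mlpconfig`.
#' @export
mlp_config <- function(hidden_sizes = c(500L, 500L), output_dim = 7L,
                       learning_rate = 1e-4, weight_decay = 5e-4,
                       epochs = 10L, batch_size = 1028L, seed = 1L) {
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 output_dim = as.integer(output_dim),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "kb_mlpconfig")
}

#' k-binding stratum sampling weights
#'
#' The class-imbalance correction weights each k-binding stratum by
#' `w_k = sqrt(n_0 / n_k)`, so rarer (more cross-reactive) strata are
#' oversampled during training; the 0-binding stratum has weight 1 and
#' empty strata get weight 0 (they are never sampled).
#'
#' @param counts Named integer vector of stratum sizes (`n_0` first), e.g.
#'   from [stratum_counts()].
#' @return Numeric vector of weights, same names as `counts`.
#' @export
compute_stratum_weights <- function(counts) {
  if (counts[[1]] == 0) stop("n_0 = 0: stratum weights are undefined")
  w <- ifelse(counts > 0, sqrt(counts[[1]] / counts), 0)
  names(w) <- names(counts)
  w
}

#' Stratum-weighted training indices
#'
#' Draws `n_draws` example indices with replacement, each example sampled
#' with probability proportional to its stratum weight.
#'
#' @param k Integer vector of per-example k-binding values.
#' @param weights Stratum weights from [compute_stratum_weights()]
#'   (position j+1 = weight of stratum k = j).
#' @param n_draws Number of draws (defaults to `length(k)`, one epoch).
#' @param seed Integer seed.
#' @return Integer vector of sampled indices.
#' @export
weighted_sample_idx <- function(k, weights, n_draws = length(k), seed = 1L) {
  w <- weights[k + 1L]
  if (all(w == 0)) stop("all sampling weights are zero")
  with_seed(seed, sample.int(length(k), n_draws, replace = TRUE, prob = w))
}

## PyTorch-style linear-layer init: U(-a, a) with a = 1/sqrt(fan_in),
## for both weights and biases.
init_layer <- function(fan_in, fan_out) {
  a <- 1 / sqrt(fan_in)
  list(W = matrix(stats::runif(fan_in * fan_out, -a, a), fan_in, fan_out),
       b = stats::runif(fan_out, -a, a))
}

mlp_forward <- function(params, x) {
  h <- x
  acts <- list(h)
  nl <- length(params)
  for (i in seq_len(nl)) {
    z <- sweep(h %*% params[[i]]$W, 2L, params[[i]]$b, "+")
    h <- if (i < nl) pmax(z, 0) else z
    acts[[i + 1L]] <- h
  }
  acts
}

#' Train the multi-label binding MLP
#'
#' Minimizes the sum over targets of per-target binary cross-entropy (the
#' multi-label reading of cross-entropy with a sigmoid head) by Adam, on
#' minibatches drawn by stratum-weighted sampling with replacement; each
#' epoch draws as many examples as the dataset holds.  Weight decay is
#' applied as an L2 term added to the gradient.  Training is deterministic
#' given `config$seed`.
#'
#' @param x Numeric embedding matrix (rows = examples).
#' @param y 0/1 label matrix, `output_dim` columns.
#' @param k Integer vector of per-example k-binding values (used by the
#'   sampler); defaults to `rowSums(y)`.
#' @param config An [mlp_config()]; its `output_dim` must match `ncol(y)`.
#' @param stratum_weights Optional precomputed weights; default computed
#'   from the k tally of `x`'s rows.
#' @return Object of class `kb_mlp`: layer parameters, config, input
#'   dimension and the per-epoch training-loss trajectory.
#' @export
mlp_train <- function(x, y, k = NULL, config = mlp_config(),
                      stratum_weights = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y), ncol(y) == config$output_dim)
  if (is.null(k)) k <- as.integer(rowSums(y))
  if (is.null(stratum_weights)) {
    counts <- tabulate(k + 1L, nbins = config$output_dim + 1L)
    names(counts) <- paste0("n_", 0:config$output_dim)
    stratum_weights <- compute_stratum_weights(counts)
  }

  dims <- c(ncol(x), config$hidden_sizes, config$output_dim)
  nl <- length(dims) - 1L
  params <- with_seed(config$seed, {
    lapply(seq_len(nl), function(i) init_layer(dims[i], dims[i + 1L]))
  })
  m <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  v <- m
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  lr <- config$learning_rate
  wd <- config$weight_decay
  epoch_loss <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    idx <- weighted_sample_idx(k, stratum_weights, nrow(x),
                               seed = config$seed * 1009L + epoch)
    losses <- 0
    nb <- 0L
    for (start in seq(1L, length(idx), by = config$batch_size)) {
      bi <- idx[start:min(start + config$batch_size - 1L, length(idx))]
      xb <- x[bi, , drop = FALSE]
      yb <- y[bi, , drop = FALSE]
      nb_rows <- nrow(xb)

      acts <- mlp_forward(params, xb)
      z_out <- acts[[nl + 1L]]
      p <- 1 / (1 + exp(-z_out))
      ## summed-over-targets BCE, averaged over the batch
      pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      losses <- losses + -mean(rowSums(yb * log(pc) + (1 - yb) * log(1 - pc)))
      nb <- nb + 1L

      ## backward
      grads <- vector("list", nl)
      delta <- (p - yb) / nb_rows
      for (i in nl:1) {
        grads[[i]] <- list(W = crossprod(acts[[i]], delta),
                           b = colSums(delta))
        if (i > 1L) {
          delta <- (delta %*% t(params[[i]]$W)) * (acts[[i]] > 0)
        }
      }

      ## Adam with L2 weight decay folded into the gradient
      step <- step + 1L
      bc1 <- 1 - beta1^step
      bc2 <- 1 - beta2^step
      for (i in seq_len(nl)) {
        for (nm in c("W", "b")) {
          g <- grads[[i]][[nm]] + wd * params[[i]][[nm]]
          m[[i]][[nm]] <- beta1 * m[[i]][[nm]] + (1 - beta1) * g
          v[[i]][[nm]] <- beta2 * v[[i]][[nm]] + (1 - beta2) * g * g
          params[[i]][[nm]] <- params[[i]][[nm]] -
            lr * (m[[i]][[nm]] / bc1) / (sqrt(v[[i]][[nm]] / bc2) + eps)
        }
      }
    }
    epoch_loss[epoch] <- losses / nb
    if (!is.finite(epoch_loss[epoch])) {
      stop("training diverged (non-finite loss) at epoch ", epoch)
    }
  }

  structure(list(params = params, config = config, input_dim = ncol(x),
                 loss = epoch_loss),
            class = "kb_mlp")
}

#' Predict binding probabilities
#'
#' @param object A trained `kb_mlp`.
#' @param x Embedding matrix with `input_dim` columns.
#' @param ... Unused.
#' @return Matrix of probabilities in (0, 1), one column per target.
#' @export
predict.kb_mlp <- function(object, x, ...) {
  x <- as.matrix(x)
  if (ncol(x) != object$input_dim) {
    stop("input has ", ncol(x), " columns; model expects ",
         object$input_dim)
  }
  acts <- mlp_forward(object$params, x)
  1 / (1 + exp(-acts[[length(acts)]]))
}

#' @export
print.kb_mlp <- function(x, ...) {
  cat("Multi-label MLP:", x$input_dim, "->",
      paste(x$config$hidden_sizes, collapse = " -> "), "->",
      x$config$output_dim, "(sigmoid)\n")
  cat("Final training loss:", round(utils::tail(x$loss, 1), 4), "\n")
  invisible(x)
}
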