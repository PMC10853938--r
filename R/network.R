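# Dense regression network: two rectified-linear hidden layers with
# biases, a linear output with bias, weighted squared-error loss with L2
# weight penalty, trained with the Nesterov-accelerated adaptive-moment
# (Nadam) optimizer.  Plain matrix algebra with hand-derived backprop.

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Define a dense network
#'
#' Layer sizes follow the two-hidden-layer architecture: `(input, h1, h2,
#' 1)`, e.g. `(49, 16, 8, 1)` for the aqueous model (945 parameters) and
#' `(52, 14, 7, 1)` for the nonaqueous one (855 parameters).  Hidden
#' activations are rectified linear; the output is linear.  Weights are
#' He-initialized from the given seed; biases start at zero.
#'
#' @param layer_sizes integer vector `(input, hidden..., 1)`.
#' @param seed RNG seed for the weight initialization.
#' @param l2 L2 regularization strength applied to all weight matrices
#'   (not biases), default 0.01.
#' @return object of class `gb_network`: `sizes`, `l2`, and `layers`, a
#'   list of `(W, b)` pairs.
#' @export
network_spec <- function(layer_sizes, seed = 1, l2 = 0.01) {
  stopifnot(length(layer_sizes) >= 2, all(layer_sizes >= 1))
  layers <- with_seed(seed, {
    lapply(seq_len(length(layer_sizes) - 1), function(l) {
      fan_in <- layer_sizes[l]
      list(W = matrix(rnorm(fan_in * layer_sizes[l + 1],
                            sd = sqrt(2 / fan_in)),
                      fan_in, layer_sizes[l + 1]),
           b = numeric(layer_sizes[l + 1]))
    })
  })
  structure(list(sizes = as.integer(layer_sizes), l2 = l2, layers = layers),
            class = "gb_network")
}

#' @export
print.gb_network <- function(x, ...) {
  cat(sprintf("<gb_network> %s, %d parameters, l2=%g\n",
              paste(x$sizes, collapse = "-"), count_parameters(x), x$l2))
  invisible(x)
}

#' Count trainable parameters
#'
#' `(in+1)*h1 + (h1+1)*h2 + ... + (h_last+1)*out`, i.e. every weight and
#' bias.
#'
#' @param x a `gb_network` or an integer vector of layer sizes.
#' @return integer parameter count.
#' @examples
#' count_parameters(c(49, 16, 8, 1))  # 945
#' count_parameters(c(52, 14, 7, 1))  # 855
#' @export
count_parameters <- function(x) {
  sizes <- if (inherits(x, "gb_network")) x$sizes else as.integer(x)
  sum((sizes[-length(sizes)] + 1) * sizes[-1])
}

relu <- function(z) pmax(z, 0)

# forward pass; keeps pre-activations for backprop when cache = TRUE
forward_pass <- function(net, X, cache = FALSE) {
  A <- X
  Zs <- list()
  As <- list(A)
  L <- length(net$layers)
  for (l in seq_len(L)) {
    Z <- sweep(A %*% net$layers[[l]]$W, 2, net$layers[[l]]$b, `+`)
    A <- if (l < L) relu(Z) else Z
    if (cache) {
      Zs[[l]] <- Z
      As[[l + 1]] <- A
    }
  }
  if (cache) list(yhat = drop(A), Zs = Zs, As = As) else drop(A)
}

#' Predict with a dense network
#' @param object a `gb_network`.
#' @param newdata numeric vector (one record) or matrix (rows = records)
#'   of reduced features.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.gb_network <- function(object, newdata, ...) {
  m <- if (is.null(dim(newdata))) t(as.matrix(newdata)) else as.matrix(newdata)
  if (ncol(m) != object$sizes[1]) {
    stop("input dimension ", ncol(m), " does not match network input ",
         object$sizes[1], call. = FALSE)
  }
  forward_pass(object, m)
}

#' Training configuration
#'
#' @param learning_rate Nadam step size; 0.001 and 0.0001 are the usual
#'   choices.
#' @param epochs passes over the training split.
#' @param batch_size minibatch size.
#' @param validation_split fraction of records held out for validation,
#'   in (0, 1).
#' @param seed RNG seed controlling the split, shuffling, and (if the
#'   network is not supplied) initialization.
#' @param beta1,beta2,eps Nadam moment decay rates and stabilizer.
#' @return list of class `gb_training_config`.
#' @export
training_config <- function(learning_rate = 0.001, epochs = 200,
                            batch_size = 32, validation_split = 0.2,
                            seed = 1, beta1 = 0.9, beta2 = 0.999,
                            eps = 1e-8) {
  stopifnot(validation_split > 0, validation_split < 1, learning_rate > 0)
  structure(list(learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, validation_split = validation_split,
                 seed = seed, beta1 = beta1, beta2 = beta2, eps = eps),
            class = "gb_training_config")
}

#' Regression quality metrics
#'
#' The reporting set used throughout: mean signed error (`msd`), mean
#' absolute error, root-mean-square error, and the slope, intercept, and
#' coefficient of determination of predicted-versus-reference.
#'
#' @param y reference values.
#' @param yhat predictions.
#' @return named numeric vector `msd, mae, rmse, slope, intercept, r2`.
#' @export
regression_metrics <- function(y, yhat) {
  res <- yhat - y
  fit <- stats::lm.fit(cbind(1, y), yhat)
  c(msd = mean(res), mae = mean(abs(res)), rmse = sqrt(mean(res^2)),
    slope = unname(fit$coefficients[2]), intercept = unname(fit$coefficients[1]),
    r2 = stats::cor(y, yhat)^2)
}

# per-stratum validation split; returns validation indices
split_validation <- function(n, frac, strata, seed) {
  if (is.null(strata)) strata <- rep(1L, n)
  with_seed(seed, {
    unlist(lapply(split(seq_len(n), strata), function(idx) {
      k <- max(1L, round(frac * length(idx)))
      if (length(idx) == 1) return(integer(0))
      sample(idx, k)
    }), use.names = FALSE)
  })
}

#' Train a dense network
#'
#' Minimizes `sum_i w_i (y_i - yhat_i)^2 / sum_i w_i + l2 * sum ||W||^2`
#' with the Nadam optimizer.  The validation split is random per seed,
#' stratified by `strata` (e.g. the solute charge class) so that scarce
#' classes appear in both splits.  Deterministic given the seed.
#'
#' @param x numeric matrix of reduced input features (rows = records).
#' @param y numeric target vector (kcal/mol).
#' @param weights non-negative per-record loss weights, default all 1.
#' @param config a [training_config()].
#' @param net optional starting `gb_network`; when NULL one is initialized
#'   from the config seed.
#' @param hidden hidden layer sizes used when `net` is NULL; `c(16, 8)`
#'   is the aqueous architecture, `c(14, 7)` the nonaqueous one.
#' @param l2 L2 strength used when `net` is NULL.
#' @param strata optional stratification factor for the validation split.
#' @return list with `net` (fitted `gb_network`), `history` (data.frame of
#'   per-epoch train loss and validation RMSE), `metrics_train`,
#'   `metrics_val`, and `val_idx`.
#' @export
train_network <- function(x, y, weights = NULL, config = training_config(),
                          net = NULL, hidden = c(16, 8), l2 = 0.01,
                          strata = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(length(y) == n)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0)) stop("loss weights must be non-negative", call. = FALSE)
  if (is.null(net)) {
    net <- network_spec(c(ncol(x), hidden, 1), seed = config$seed, l2 = l2)
  }
  if (n < count_parameters(net)) {
    warning("fewer records (", n, ") than trainable parameters (",
            count_parameters(net), ")", call. = FALSE)
  }
  val_idx <- split_validation(n, config$validation_split, strata, config$seed)
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- x[tr_idx, , drop = FALSE]
  ytr <- y[tr_idx]
  wtr <- weights[tr_idx]
  L <- length(net$layers)
  m_st <- lapply(net$layers, function(l) list(W = 0 * l$W, b = 0 * l$b))
  v_st <- lapply(net$layers, function(l) list(W = 0 * l$W, b = 0 * l$b))
  step <- 0
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_rmse = numeric(0))
  b1 <- config$beta1
  b2 <- config$beta2
  order_seeds <- with_seed(config$seed + 1,
                           sample.int(.Machine$integer.max / 2, config$epochs))
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(order_seeds[epoch], sample(length(tr_idx)))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    epoch_loss <- 0
    for (batch in batches) {
      Xb <- Xtr[batch, , drop = FALSE]
      yb <- ytr[batch]
      wb <- wtr[batch]
      if (sum(wb) == 0) next
      fwd <- forward_pass(net, Xb, cache = TRUE)
      res <- fwd$yhat - yb
      data_loss <- sum(wb * res^2) / sum(wb)
      if (!is.finite(data_loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch,
             "; reduce the learning rate", call. = FALSE)
      }
      epoch_loss <- epoch_loss + data_loss * length(batch)
      delta <- matrix(2 * wb * res / sum(wb), ncol = 1)
      step <- step + 1
      c1 <- 1 - b1^step
      c2 <- 1 - b2^step
      for (l in rev(seq_len(L))) {
        gW <- crossprod(fwd$As[[l]], delta) + 2 * net$l2 * net$layers[[l]]$W
        gb <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(net$layers[[l]]$W)) * (fwd$Zs[[l - 1]] > 0)
        }
        m_st[[l]]$W <- b1 * m_st[[l]]$W + (1 - b1) * gW
        m_st[[l]]$b <- b1 * m_st[[l]]$b + (1 - b1) * gb
        v_st[[l]]$W <- b2 * v_st[[l]]$W + (1 - b2) * gW^2
        v_st[[l]]$b <- b2 * v_st[[l]]$b + (1 - b2) * gb^2
        nW <- (b1 * m_st[[l]]$W / c1 + (1 - b1) * gW / c1) /
          (sqrt(v_st[[l]]$W / c2) + config$eps)
        nb <- (b1 * m_st[[l]]$b / c1 + (1 - b1) * gb / c1) /
          (sqrt(v_st[[l]]$b / c2) + config$eps)
        net$layers[[l]]$W <- net$layers[[l]]$W - config$learning_rate * nW
        net$layers[[l]]$b <- net$layers[[l]]$b - config$learning_rate * nb
      }
    }
    val_rmse <- if (length(val_idx)) {
      sqrt(mean((forward_pass(net, x[val_idx, , drop = FALSE]) - y[val_idx])^2))
    } else NA_real_
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                train_loss = epoch_loss / length(tr_idx),
                                val_rmse = val_rmse))
  }
  list(net = net,
       history = history,
       metrics_train = regression_metrics(ytr, forward_pass(net, Xtr)),
       metrics_val = if (length(val_idx)) {
         regression_metrics(y[val_idx],
                            forward_pass(net, x[val_idx, , drop = FALSE]))
       } else NULL,
       val_idx = sort(val_idx))
}
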