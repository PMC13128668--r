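# The classifier network: CNN projection of the residue-level embedding,
# concatenation with the processed feature block, fully connected binary
# classifier. Training uses minibatch Adam with early stopping on
# validation loss (best weights restored).

#' Model hyperparameter configuration
#'
#' The eight tunable hyperparameters of the network plus the early-stopping
#' patience and the seed. The published configuration (kernel 7x7, 8
#' filters, 2 dense layers, units equal to the input feature dimension,
#' dropout 0.2, learning rate 1e-3, batch size 32) is the default; see
#' [default_grid()] for the candidate values searched during model
#' selection.
#'
#' @param kernel_size Square convolution kernel size.
#' @param n_filters Filters per convolution block.
#' @param n_layers Number of fully connected hidden layers.
#' @param n_units Units per hidden layer; the string `"input_dim"` resolves
#'   to the concatenated input width.
#' @param dropout Dropout rate applied after each pooling block and each
#'   hidden layer.
#' @param learning_rate Adam learning rate.
#' @param max_epochs Training epoch budget.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param seed Seed governing weight initialisation, batch shuffling, and
#'   dropout.
#' @return A `prohl_model_config`.
#' @export
model_config <- function(kernel_size = 7L, n_filters = 8L, n_layers = 2L,
                         n_units = "input_dim", dropout = 0.2,
                         learning_rate = 1e-3, max_epochs = 30L,
                         batch_size = 32L, patience = 5L, seed = 1L) {
  stopifnot(kernel_size >= 2, n_filters >= 1, n_layers >= 1,
            identical(n_units, "input_dim") || (is.numeric(n_units) && n_units >= 1),
            dropout >= 0, dropout < 1, learning_rate > 0, max_epochs >= 1,
            batch_size >= 1, patience >= 1)
  structure(list(kernel_size = as.integer(kernel_size),
                 n_filters = as.integer(n_filters),
                 n_layers = as.integer(n_layers),
                 n_units = n_units,
                 dropout = dropout,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "prohl_model_config")
}

#' Network shape arithmetic
#'
#' Computes, as a pure function of the input dimensions and configuration,
#' every intermediate shape of the network: two valid `K x K` convolutions
#' each followed by a 2x2 average pool (stride 2, trailing odd row/column
#' dropped), then flattening to a vector of length
#' `n_filters * h4 * w4` that is concatenated with the `n_features`-wide
#' processed feature block. Errors at build time if any spatial dimension
#' collapses below the kernel size.
#'
#' @param d_local Residue-embedding dimension (input height).
#' @param L_padded Padded sequence length (input width).
#' @param n_features Width of the processed feature block.
#' @param config A [model_config()].
#' @return List of shapes used by the training backend, including `q` (the
#'   flattened CNN output length) and `input_dim = q + n_features`.
#' @export
network_dims <- function(d_local, L_padded, n_features, config) {
  k <- config$kernel_size
  h1 <- d_local - k + 1L
  w1 <- L_padded - k + 1L
  if (h1 < 1L || w1 < 1L) {
    stop("input ", d_local, "x", L_padded, " is smaller than the ", k, "x", k,
         " kernel")
  }
  h2 <- h1 %/% 2L
  w2 <- w1 %/% 2L
  h3 <- h2 - k + 1L
  w3 <- w2 - k + 1L
  if (h3 < 1L || w3 < 1L) {
    stop("pooled map ", h2, "x", w2, " is smaller than the ", k, "x", k,
         " kernel of the second block")
  }
  h4 <- h3 %/% 2L
  w4 <- w3 %/% 2L
  if (h4 < 1L || w4 < 1L) stop("spatial dimensions collapse in the second pool")
  q <- config$n_filters * h4 * w4
  input_dim <- q + as.integer(n_features)
  units <- if (identical(config$n_units, "input_dim")) input_dim
           else as.integer(config$n_units)
  list(H = as.integer(d_local), W = as.integer(L_padded), K = k,
       F = config$n_filters,
       h1 = h1, w1 = w1, h2 = h2, w2 = w2, h3 = h3, w3 = w3,
       h4 = h4, w4 = w4, q = as.integer(q), m = as.integer(n_features),
       nlayers = config$n_layers, input_dim = as.integer(input_dim),
       units = rep(as.integer(units), config$n_layers))
}

# He-normal initial weights (Glorot-style for the sigmoid output layer);
# draws from the current R RNG stream
init_params <- function(dims) {
  k2 <- dims$K^2
  he <- function(nr, nc, fan_in) {
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  }
  ins <- c(dims$input_dim, dims$units)[seq_len(dims$nlayers)]
  list(
    W1 = he(dims$F, k2, k2),
    b1 = numeric(dims$F),
    W2 = he(dims$F, dims$F * k2, dims$F * k2),
    b2 = numeric(dims$F),
    Wd = lapply(seq_len(dims$nlayers), function(l) he(dims$units[l], ins[l], ins[l])),
    bd = lapply(seq_len(dims$nlayers), function(l) numeric(dims$units[l])),
    Wout = matrix(stats::rnorm(dims$units[dims$nlayers],
                               sd = sqrt(1 / dims$units[dims$nlayers])),
                  1L, dims$units[dims$nlayers]),
    bout = numeric(1L)
  )
}

zero_like <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

deep_copy_params <- function(params) {
  rapply(params, function(x) x + 0, how = "replace")
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

#' Early-stopping rule
#'
#' Given a full sequence of per-epoch validation losses, the epoch at which
#' training stops: the first epoch lying `patience` epochs after the last
#' strict improvement of the running best loss, or the final epoch if the
#' budget runs out first. A loss sequence improving only at epoch 1 with
#' patience 5 therefore stops at epoch 6.
#'
#' @param val_losses Numeric vector of validation losses per epoch.
#' @param patience Number of epochs without improvement tolerated.
#' @return List with `stop_epoch` and `best_epoch`.
#' @export
early_stop_epoch <- function(val_losses, patience = 5L) {
  best <- Inf
  best_epoch <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]
      best_epoch <- e
    } else if (e - best_epoch >= patience) {
      return(list(stop_epoch = e, best_epoch = best_epoch))
    }
  }
  list(stop_epoch = length(val_losses), best_epoch = best_epoch)
}

#' Train the classifier network
#'
#' Minimises binary cross-entropy with minibatch Adam; after each epoch the
#' validation loss is evaluated and training stops once it has failed to
#' improve for `patience` epochs (or at `max_epochs`), restoring the
#' weights of the best validation epoch. With a fixed seed, data, and
#' configuration, the final weights are reproduced bit for bit.
#'
#' @param ximg Residue-embedding array `d_local x L_padded x n_train`.
#' @param xfeat Processed feature matrix `n_train x m` (m may be 0).
#' @param y Numeric 0/1 vector (1 = long-lived, the positive class).
#' @param val_ximg,val_xfeat,val_y The validation split (disjoint from the
#'   training split).
#' @param config A [model_config()].
#' @return A `prohl_model`: best weights, shapes, config, and a per-epoch
#'   training log.
#' @export
train_model <- function(ximg, xfeat, y, val_ximg, val_xfeat, val_y, config) {
  stopifnot(inherits(config, "prohl_model_config"))
  n <- dim(ximg)[3L]
  if (n == 0L || length(val_y) == 0L) stop("empty training or validation split")
  stopifnot(length(y) == n, nrow(xfeat) == n, all(y %in% c(0, 1)))
  dims <- network_dims(dim(ximg)[1L], dim(ximg)[2L], ncol(xfeat), config)
  set.seed(config$seed)
  params <- init_params(dims)
  mstate <- zero_like(params)
  vstate <- zero_like(params)
  step <- 0
  best_loss <- Inf
  best_epoch <- 0L
  best_params <- NULL
  log_rows <- vector("list", config$max_epochs)
  stop_epoch <- config$max_epochs
  for (e in seq_len(config$max_epochs)) {
    ord <- sample.int(n) - 1L
    res <- nn_epoch_cpp(params, mstate, vstate, step, ximg, xfeat, y, ord,
                        dims, config$learning_rate, config$dropout,
                        config$batch_size)
    step <- res$step
    val_p <- nn_forward_cpp(params, val_ximg, val_xfeat, dims)
    vl <- bce_loss(val_p, val_y)
    log_rows[[e]] <- data.frame(epoch = e, train_loss = res$train_loss,
                                val_loss = vl)
    if (vl < best_loss) {
      best_loss <- vl
      best_epoch <- e
      best_params <- deep_copy_params(params)
    } else if (e - best_epoch >= config$patience) {
      stop_epoch <- e
      break
    }
  }
  structure(list(params = best_params, dims = dims, config = config,
                 log = do.call(rbind, log_rows[!vapply(log_rows, is.null, TRUE)]),
                 best_epoch = best_epoch, stop_epoch = stop_epoch),
            class = "prohl_model")
}

#' Predict with a trained network
#'
#' @param model A `prohl_model`.
#' @param ximg,xfeat Inputs shaped as at training time.
#' @return Data frame with `probability_long_lived` and `predicted_class`
#'   (probability exactly 0.5 goes to the positive class, long-lived).
#' @export
predict_model <- function(model, ximg, xfeat) {
  stopifnot(inherits(model, "prohl_model"))
  p <- nn_forward_cpp(model$params, ximg, xfeat, model$dims)
  data.frame(probability_long_lived = p,
             predicted_class = ifelse(p >= 0.5, LABEL_LONG, LABEL_SHORT),
             stringsAsFactors = FALSE)
}

# stack embedding bundles into the cube/matrix inputs of the network
bundles_to_inputs <- function(bundles) {
  d_local <- nrow(bundles[[1L]]$residue_matrix)
  L_pad <- ncol(bundles[[1L]]$residue_matrix)
  n <- length(bundles)
  ximg <- array(0, dim = c(d_local, L_pad, n))
  for (i in seq_len(n)) ximg[, , i] <- bundles[[i]]$residue_matrix
  xseq <- do.call(rbind, lapply(bundles, `[[`, "sequence_vector"))
  rownames(xseq) <- names(bundles)
  list(ximg = ximg, xseq = xseq)
}
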