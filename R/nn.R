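#' Specify a fully-connected contact-frequency network
#'
#' Architecture of the regression network mapping GReX features to
#' normalized contact frequency: a stack of equally sized hidden layers
#' with a single linear output neuron.
#'
#' @param n_inputs 2 (upstream/downstream GReX) or 3 (plus log1p distance).
#' @param hidden_layers number of hidden layers.
#' @param hidden_neurons neurons per hidden layer.
#' @param activation hidden activation: "relu", "hard_sigmoid" (the
#'   piecewise-linear max(0, min(1, 0.2x + 0.5))), "softsign"
#'   (x / (1 + |x|)), "tanh" or "linear".
#' @param hidden_init,output_init weight initialization scheme for hidden /
#'   output layers: "normal" (sd 0.05), "kaiming_uniform", "kaiming_normal",
#'   "xavier_normal", "uniform" (U(-0.05, 0.05)) or "zeros".
#' @param dropout hidden dropout rate in \[0, 1).
#' @param weight_constraint max-norm bound on incoming weight vectors, or
#'   NULL for none.
#' @param l1,l2 regularization strengths added to the MSE loss.
#' @return an `nn_architecture` object.
#' @export
nn_architecture <- function(n_inputs = 2L, hidden_layers = 2L,
                            hidden_neurons = 90L,
                            activation = c("relu", "hard_sigmoid",
                                           "softsign", "tanh", "linear"),
                            hidden_init = c("kaiming_uniform", "normal",
                                            "kaiming_normal", "xavier_normal",
                                            "uniform", "zeros"),
                            output_init = c("kaiming_normal", "normal",
                                            "kaiming_uniform", "xavier_normal",
                                            "uniform", "zeros"),
                            dropout = 0, weight_constraint = NULL,
                            l1 = 0, l2 = 0) {
  activation <- match.arg(activation)
  hidden_init <- match.arg(hidden_init)
  output_init <- match.arg(output_init)
  stopifnot(n_inputs >= 1, hidden_layers >= 1, hidden_neurons >= 1,
            dropout >= 0, dropout < 1, l1 >= 0, l2 >= 0)
  structure(list(n_inputs = as.integer(n_inputs),
                 hidden_layers = as.integer(hidden_layers),
                 hidden_neurons = as.integer(hidden_neurons),
                 activation = activation, hidden_init = hidden_init,
                 output_init = output_init, dropout = dropout,
                 weight_constraint = weight_constraint,
                 l1 = l1, l2 = l2),
            class = "nn_architecture")
}

#' Specify the training configuration of a contact network
#'
#' @param optimizer "adagrad", "nadam" or "sgd".
#' @param learning_rate positive step size.
#' @param epochs full passes over the training data.
#' @param batch_size mini-batch size.
#' @param cv_folds folds used when the configuration is cross-validated.
#' @param selection_metric "r2" (maximized) or "rmse" (minimized) for model
#'   selection.
#' @param seed integer seed for initialization and batch shuffling.
#' @return a `train_config` object.
#' @export
train_config <- function(optimizer = c("adagrad", "nadam", "sgd"),
                         learning_rate = 0.1, epochs = 50L,
                         batch_size = 80L, cv_folds = 5L,
                         selection_metric = c("r2", "rmse"), seed = 1L) {
  optimizer <- match.arg(optimizer)
  selection_metric <- match.arg(selection_metric)
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 cv_folds = as.integer(cv_folds),
                 selection_metric = selection_metric,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Named network presets
#'
#' The three tuned contact-frequency architectures, reproducible from
#' configuration alone:
#' \describe{
#'   \item{whole_blood}{2 hidden layers x 120 neurons, hard-sigmoid
#'     activation, Kaiming-uniform hidden / Kaiming-normal output
#'     initialization; NAdam, learning rate 0.01, 90 epochs, batch 110.}
#'   \item{cerebellum}{2 x 90, Softsign, Xavier-normal hidden / uniform
#'     output; Adagrad, learning rate 0.3, 50 epochs, batch 80.}
#'   \item{k562_runon}{2 x 150, ReLU, normal hidden / zeros output;
#'     Adagrad, learning rate 0.2, 90 epochs, batch 160.}
#' }
#'
#' @param name preset name.
#' @param n_inputs number of input features (default 2).
#' @param seed training seed stored in the config.
#' @return list with elements `architecture` and `config`.
#' @export
nn_preset <- function(name = c("whole_blood", "cerebellum", "k562_runon"),
                      n_inputs = 2L, seed = 1L) {
  name <- match.arg(name)
  switch(name,
    whole_blood = list(
      architecture = nn_architecture(n_inputs, 2L, 120L, "hard_sigmoid",
                                     hidden_init = "kaiming_uniform",
                                     output_init = "kaiming_normal"),
      config = train_config("nadam", 0.01, 90L, 110L, seed = seed)),
    cerebellum = list(
      architecture = nn_architecture(n_inputs, 2L, 90L, "softsign",
                                     hidden_init = "xavier_normal",
                                     output_init = "uniform"),
      config = train_config("adagrad", 0.3, 50L, 80L, seed = seed)),
    k562_runon = list(
      architecture = nn_architecture(n_inputs, 2L, 150L, "relu",
                                     hidden_init = "normal",
                                     output_init = "zeros"),
      config = train_config("adagrad", 0.2, 90L, 160L, seed = seed)))
}

nn_activation <- function(name) {
  switch(name,
         relu = list(f = function(z) pmax(z, 0),
                     df = function(z, a) (z > 0) * 1),
         hard_sigmoid = list(f = function(z) pmin(pmax(0.2 * z + 0.5, 0), 1),
                             df = function(z, a) (z > -2.5 & z < 2.5) * 0.2),
         softsign = list(f = function(z) z / (1 + abs(z)),
                         df = function(z, a) 1 / (1 + abs(z))^2),
         tanh = list(f = tanh, df = function(z, a) 1 - tanh(z)^2),
         linear = list(f = identity, df = function(z, a) 1))
}

nn_init_matrix <- function(scheme, fan_in, fan_out) {
  w <- switch(scheme,
    normal = stats::rnorm(fan_in * fan_out, 0, 0.05),
    kaiming_uniform = stats::runif(fan_in * fan_out,
                                   -sqrt(6 / fan_in), sqrt(6 / fan_in)),
    kaiming_normal = stats::rnorm(fan_in * fan_out, 0, sqrt(2 / fan_in)),
    xavier_normal = stats::rnorm(fan_in * fan_out, 0,
                                 sqrt(2 / (fan_in + fan_out))),
    uniform = stats::runif(fan_in * fan_out, -0.05, 0.05),
    zeros = rep(0, fan_in * fan_out))
  matrix(w, fan_in, fan_out)
}

nn_init_params <- function(arch) {
  sizes <- c(arch$n_inputs, rep(arch$hidden_neurons, arch$hidden_layers), 1L)
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    scheme <- if (l == L) arch$output_init else arch$hidden_init
    W[[l]] <- nn_init_matrix(scheme, sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b)
}

nn_forward <- function(params, X, act, dropout = 0, training = FALSE) {
  L <- length(params$W)
  a <- X
  zs <- vector("list", L)
  as <- vector("list", L + 1L)
  masks <- vector("list", L)
  as[[1]] <- a
  for (l in seq_len(L)) {
    z <- sweep(a %*% params$W[[l]], 2, params$b[[l]], "+")
    zs[[l]] <- z
    a <- if (l < L) act$f(z) else z
    if (l < L && training && dropout > 0) {
      mask <- matrix(stats::rbinom(length(a), 1L, 1 - dropout) / (1 - dropout),
                     nrow(a), ncol(a))
      a <- a * mask
      masks[[l]] <- mask
    }
    as[[l + 1]] <- a
  }
  list(z = zs, a = as, masks = masks, yhat = as.vector(a))
}

nn_backward <- function(params, fw, y, act, arch) {
  L <- length(params$W)
  n <- length(y)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- matrix(2 * (fw$yhat - y) / n, ncol = 1)
  for (l in rev(seq_len(L))) {
    a_prev <- fw$a[[l]]
    gW[[l]] <- crossprod(a_prev, delta)
    gb[[l]] <- colSums(delta)
    if (arch$l1 > 0) gW[[l]] <- gW[[l]] + arch$l1 * sign(params$W[[l]])
    if (arch$l2 > 0) gW[[l]] <- gW[[l]] + 2 * arch$l2 * params$W[[l]]
    if (l > 1) {
      delta <- delta %*% t(params$W[[l]])
      if (!is.null(fw$masks[[l - 1]])) delta <- delta * fw$masks[[l - 1]]
      delta <- delta * act$df(fw$z[[l - 1]], fw$a[[l]])
    }
  }
  list(W = gW, b = gb)
}

nn_make_optimizer <- function(cfg, params) {
  zeros_like <- function(p) lapply(p, function(x) x * 0)
  state <- switch(cfg$optimizer,
    sgd = list(),
    adagrad = list(GW = zeros_like(params$W), Gb = zeros_like(params$b)),
    nadam = list(mW = zeros_like(params$W), vW = zeros_like(params$W),
                 mb = zeros_like(params$b), vb = zeros_like(params$b),
                 t = 0))
  lr <- cfg$learning_rate
  eps <- 1e-8
  b1 <- 0.9; b2 <- 0.999
  step <- function(params, grads, state) {
    L <- length(params$W)
    if (cfg$optimizer == "sgd") {
      for (l in seq_len(L)) {
        params$W[[l]] <- params$W[[l]] - lr * grads$W[[l]]
        params$b[[l]] <- params$b[[l]] - lr * grads$b[[l]]
      }
    } else if (cfg$optimizer == "adagrad") {
      for (l in seq_len(L)) {
        state$GW[[l]] <- state$GW[[l]] + grads$W[[l]]^2
        state$Gb[[l]] <- state$Gb[[l]] + grads$b[[l]]^2
        params$W[[l]] <- params$W[[l]] -
          lr * grads$W[[l]] / (sqrt(state$GW[[l]]) + eps)
        params$b[[l]] <- params$b[[l]] -
          lr * grads$b[[l]] / (sqrt(state$Gb[[l]]) + eps)
      }
    } else { # nadam
      state$t <- state$t + 1
      bc1 <- 1 - b1^state$t
      bc2 <- 1 - b2^state$t
      for (l in seq_len(L)) {
        state$mW[[l]] <- b1 * state$mW[[l]] + (1 - b1) * grads$W[[l]]
        state$vW[[l]] <- b2 * state$vW[[l]] + (1 - b2) * grads$W[[l]]^2
        state$mb[[l]] <- b1 * state$mb[[l]] + (1 - b1) * grads$b[[l]]
        state$vb[[l]] <- b2 * state$vb[[l]] + (1 - b2) * grads$b[[l]]^2
        mhatW <- b1 * state$mW[[l]] / bc1 + (1 - b1) * grads$W[[l]] / bc1
        mhatb <- b1 * state$mb[[l]] / bc1 + (1 - b1) * grads$b[[l]] / bc1
        params$W[[l]] <- params$W[[l]] -
          lr * mhatW / (sqrt(state$vW[[l]] / bc2) + eps)
        params$b[[l]] <- params$b[[l]] -
          lr * mhatb / (sqrt(state$vb[[l]] / bc2) + eps)
      }
    }
    list(params = params, state = state)
  }
  list(step = step, state = state)
}

nn_apply_constraint <- function(params, bound) {
  if (is.null(bound)) return(params)
  for (l in seq_along(params$W)) {
    norms <- sqrt(colSums(params$W[[l]]^2))
    scale <- pmin(1, bound / pmax(norms, 1e-12))
    params$W[[l]] <- sweep(params$W[[l]], 2, scale, "*")
  }
  params
}

pair_features <- function(pairs, n_inputs) {
  X <- cbind(grex_up = pairs$grex_up, grex_down = pairs$grex_down)
  if (n_inputs == 3L) X <- cbind(X, log1p_distance = pairs$log1p_distance)
  X
}

#' Train a contact-frequency network
#'
#' Minimizes the mean squared error 1/n sum (Y_i - Yhat_i)^2 plus
#' l1 sum|w| + l2 sum w^2 by mini-batch gradient descent with the
#' configured optimizer. Features are z-scored with parameters fitted on
#' the training data only and stored with the model, so any later
#' application (including cross-tissue transfer) reuses the training
#' tissue's scaling. Training is fully determined by the configuration
#' seed. A non-finite training loss aborts with diagnostics.
#'
#' @param train a `pair_dataset`.
#' @param arch an [nn_architecture()].
#' @param cfg a [train_config()].
#' @param verbose print the epoch losses.
#' @return a `contact_nn` model: parameters, architecture, config, feature
#'   scaling, and the per-epoch training loss trace.
#' @export
train_nn <- function(train, arch, cfg, verbose = FALSE) {
  stopifnot(inherits(arch, "nn_architecture"), inherits(cfg, "train_config"))
  X <- pair_features(train, arch$n_inputs)
  y <- train$contact
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  set.seed(cfg$seed)
  params <- nn_init_params(arch)
  act <- nn_activation(arch$activation)
  opt <- nn_make_optimizer(cfg, params)
  state <- opt$state
  n <- nrow(Xs)
  losses <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    epoch_loss <- 0
    n_batches <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      fw <- nn_forward(params, Xs[idx, , drop = FALSE], act,
                       dropout = arch$dropout, training = TRUE)
      loss <- mean((fw$yhat - y[idx])^2)
      if (!is.finite(loss))
        stop(sprintf("non-finite training loss at epoch %d (lr %.3g); %s",
                     epoch, cfg$learning_rate,
                     "consider a smaller learning rate"), call. = FALSE)
      grads <- nn_backward(params, fw, y[idx], act, arch)
      upd <- opt$step(params, grads, state)
      params <- upd$params
      state <- upd$state
      params <- nn_apply_constraint(params, arch$weight_constraint)
      epoch_loss <- epoch_loss + loss
      n_batches <- n_batches + 1L
    }
    losses[epoch] <- epoch_loss / n_batches
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f", epoch, losses[epoch]))
  }
  structure(list(params = params, architecture = arch, config = cfg,
                 center = center, scale = scale, loss_trace = losses),
            class = "contact_nn")
}

#' Predict contact frequency from a trained network
#'
#' @param object a `contact_nn`.
#' @param newdata a `pair_dataset` (or data.frame with the feature columns).
#' @param ... unused.
#' @return numeric vector of predicted contact frequencies.
#' @export
predict.contact_nn <- function(object, newdata, ...) {
  X <- pair_features(newdata, object$architecture$n_inputs)
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  act <- nn_activation(object$architecture$activation)
  nn_forward(object$params, Xs, act)$yhat
}

#' Number of learnable parameters of an architecture
#' @param arch an `nn_architecture`.
#' @return integer parameter count (weights + biases).
#' @export
nn_n_parameters <- function(arch) {
  sizes <- c(arch$n_inputs, rep(arch$hidden_neurons, arch$hidden_layers), 1L)
  sum(sizes[-length(sizes)] * sizes[-1]) + sum(sizes[-1])
}
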