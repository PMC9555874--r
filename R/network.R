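#' Autoencoder hyperparameter specification
#'
#' One segment's full hyperparameter assignment. Defaults correspond to a
#' mid-grid configuration; [hyperparameter_grid()] holds the coarse-search
#' value lists each field is normally drawn from.
#'
#' @param lambda1 L1 (lasso) weight-penalty scale.
#' @param lambda2 L2 (ridge) weight-penalty scale; applied to the sum of
#'   squared weights.
#' @param beta sparsity-penalty scale.
#' @param rho target mean hidden activation in (0, 1].
#' @param activation hidden activation: one of `"sigmoid"`, `"tanh"`,
#'   `"relu"`, `"softplus"`, `"leakyrelu"`.
#' @param learning_rate optimizer step size.
#' @param gamma focal-loss amplification exponent (>= 0).
#' @param optimizer `"adam"`, `"rmsprop"` or `"sgd"`.
#' @param loss_type `"focal"` or `"cross_entropy"` (the latter evaluates the
#'   focal term with gamma = 0 and alpha = 1).
#' @param n_hidden_layers encoder depth; the decoder mirrors it, so the
#'   total hidden stack is a palindrome sharing the bottleneck.
#' @param size_ratio per-layer width multiplier in (0, 1].
#' @param lr_decay learning-rate multiplier applied every 500 epochs; 0
#'   disables decay.
#' @param alpha_mode `"class_freq"` sets the focal balancing weight of each
#'   output node to the batch frequency of its truth class;
#'   `"inverse"` uses one minus that frequency (conventional focal alpha).
#' @return list of class `dae_spec`.
#' @export
dae_spec <- function(lambda1 = 1e-4, lambda2 = 1e-6, beta = 0.001,
                     rho = 0.07, activation = "relu",
                     learning_rate = 1e-3, gamma = 2,
                     optimizer = "adam", loss_type = "focal",
                     n_hidden_layers = 1, size_ratio = 0.5,
                     lr_decay = 0.95, alpha_mode = "class_freq") {
  activation <- match.arg(activation,
                          c("sigmoid", "tanh", "relu", "softplus",
                            "leakyrelu"))
  optimizer <- match.arg(optimizer, c("adam", "rmsprop", "sgd"))
  loss_type <- match.arg(loss_type, c("focal", "cross_entropy"))
  alpha_mode <- match.arg(alpha_mode, c("class_freq", "inverse"))
  stopifnot(lambda1 >= 0, lambda2 >= 0, beta >= 0, rho > 0, rho <= 1,
            learning_rate > 0, gamma >= 0, n_hidden_layers >= 1,
            size_ratio > 0, size_ratio <= 1, lr_decay >= 0, lr_decay <= 1)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, beta = beta,
                 rho = rho, activation = activation,
                 learning_rate = learning_rate, gamma = gamma,
                 optimizer = optimizer, loss_type = loss_type,
                 n_hidden_layers = as.integer(n_hidden_layers),
                 size_ratio = size_ratio, lr_decay = lr_decay,
                 alpha_mode = alpha_mode),
            class = "dae_spec")
}

#' @export
print.dae_spec <- function(x, ...) {
  cat("<dae_spec>", x$loss_type, "loss, gamma", x$gamma, ",", x$activation,
      "x", x$n_hidden_layers, "(ratio", x$size_ratio, "),", x$optimizer,
      "lr", x$learning_rate, "\n")
  invisible(x)
}

activation_fns <- list(
  sigmoid   = list(f = function(z) 1 / (1 + exp(-z)),
                   df = function(z, a) a * (1 - a),
                   to_unit = function(a) a),
  tanh      = list(f = tanh,
                   df = function(z, a) 1 - a^2,
                   to_unit = function(a) (a + 1) / 2),
  relu      = list(f = function(z) pmax(z, 0),
                   df = function(z, a) (z > 0) + 0,
                   to_unit = function(a) a),
  softplus  = list(f = function(z) log1p(exp(-abs(z))) + pmax(z, 0),
                   df = function(z, a) 1 / (1 + exp(-z)),
                   to_unit = function(a) a),
  leakyrelu = list(f = function(z) ifelse(z > 0, z, 0.01 * z),
                   df = function(z, a) ifelse(z > 0, 1, 0.01),
                   to_unit = function(a) a)
)

#' Build a fully connected denoising autoencoder for a segment
#'
#' Input width is `2 * n_variants` (allele-presence pairs). The encoder has
#' `n_hidden_layers` layers, each `round(previous_width * size_ratio)` wide
#' (minimum 2); the decoder mirrors the encoder, sharing the bottleneck
#' width, and the output layer restores `2 * n_variants` nodes under a
#' sigmoid. Weights use seeded uniform Glorot-style fan-based
#' initialization; biases start at zero.
#'
#' @param spec a [dae_spec()].
#' @param n_variants number of variants in the segment (>= 1).
#' @param seed integer seed for weight initialization.
#' @return list of class `dae_net` with weight matrices `W`, bias vectors
#'   `b`, layer `widths`, and the `spec`.
#' @export
build_autoencoder <- function(spec, n_variants, seed = 1L) {
  stopifnot(inherits(spec, "dae_spec"), n_variants >= 1)
  d0 <- 2L * as.integer(n_variants)
  enc <- integer(spec$n_hidden_layers)
  prev <- d0
  for (k in seq_len(spec$n_hidden_layers)) {
    prev <- max(2L, as.integer(round(prev * spec$size_ratio)))
    enc[k] <- prev
  }
  hidden <- c(enc, rev(enc)[-1])
  widths <- c(d0, hidden, d0)
  L <- length(widths) - 1L
  set.seed(seed)
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- widths[l]; fan_out <- widths[l + 1]
    lim <- sqrt(6 / (fan_in + fan_out))
    W[[l]] <- matrix(stats::runif(fan_in * fan_out, -lim, lim),
                     fan_in, fan_out)
    b[[l]] <- numeric(fan_out)
  }
  structure(list(W = W, b = b, widths = widths, spec = spec,
                 n_variants = as.integer(n_variants)),
            class = "dae_net")
}

#' @export
print.dae_net <- function(x, ...) {
  cat("<dae_net> widths:", paste(x$widths, collapse = " -> "), "\n")
  invisible(x)
}

#' Forward pass through an autoencoder
#'
#' @param net a [build_autoencoder()] network.
#' @param x input matrix, samples x `2 * n_variants`.
#' @param keep logical; keep pre-activations and hidden activations for
#'   backpropagation.
#' @return with `keep = FALSE`, the sigmoid output matrix; otherwise a list
#'   with elements `a` (activations per layer, `a[[1]]` the input) and `z`
#'   (pre-activations).
#' @export
forward_pass <- function(net, x, keep = FALSE) {
  act <- activation_fns[[net$spec$activation]]
  sig <- activation_fns$sigmoid
  L <- length(net$W)
  a <- vector("list", L + 1L); z <- vector("list", L)
  a[[1]] <- as.matrix(x)
  for (l in seq_len(L)) {
    z[[l]] <- sweep(a[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    fl <- if (l == L) sig else act
    a[[l + 1]] <- fl$f(z[[l]])
  }
  if (keep) list(a = a, z = z) else a[[L + 1]]
}
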