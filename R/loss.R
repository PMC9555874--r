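#' Focal loss for allele-presence outputs
#'
#' Per output node `t`, let `q_t` be the probability the model assigns to
#' the truth class: `q_t = p_t` when the truth bit `x_t = 1` and
#' `q_t = 1 - p_t` when `x_t = 0`, where the bracketed binary log loss
#' `x_t log(p_t) + (1 - x_t) log(1 - p_t)` equals `log(q_t)`. The loss is
#'
#' `-alpha_t (1 - q_t)^gamma log(q_t)`
#'
#' i.e. cross-entropy of the truth-class probability modulated by
#' `(1 - q_t)^gamma`, which down-weights well-classified nodes (especially
#' the abundant reference alleles at rare-variant sites), and a
#' class-balance weight `alpha_t`. With `gamma = 0` and `alpha_t = 1` this
#' reduces exactly to binary cross-entropy.
#'
#' @param p_t predicted presence probabilities in `[0, 1]` (vector or
#'   matrix); the truth-class probability is clamped to
#'   `[1e-7, 1 - 1e-7]` before the log.
#' @param x_t truth bits, same shape as `p_t`.
#' @param alpha_t balancing weight(s) in `[0, 1]`.
#' @param gamma focusing exponent (>= 0).
#' @param reduce `"sum"` (default, total over all nodes) or `"none"`
#'   (elementwise).
#' @return scalar (or elementwise array) focal loss, >= 0.
#' @export
focal_loss <- function(p_t, x_t, alpha_t = 1, gamma = 0, reduce = "sum") {
  if (gamma < 0) stop("gamma must be >= 0")
  eps <- 1e-7
  p <- pmin(pmax(p_t, eps), 1 - eps)
  q <- x_t * p + (1 - x_t) * (1 - p)
  out <- -alpha_t * (1 - q)^gamma * log(q)
  if (identical(reduce, "sum")) sum(out) else out
}

#' KL sparsity penalty
#'
#' Penalizes deviation of observed mean hidden activations `rho_hat_j`
#' (one per training batch `j`) from the target activation `rho`:
#' `sum_j rho log(rho / rho_hat_j) + (1 - rho) log((1 - rho)/(1 - rho_hat_j))`,
#' the KL divergence between Bernoulli(`rho`) and Bernoulli(`rho_hat_j`)
#' summed over batches. Non-negative, zero iff every `rho_hat_j == rho`.
#'
#' @param rho target mean activation in (0, 1]; `rho = 1` uses the
#'   convention `0 * log(0) = 0` for the second term.
#' @param rho_hat numeric vector of batch-mean activations; clamped into
#'   `(1e-7, 1 - 1e-7)`.
#' @return scalar penalty >= 0.
#' @export
sparsity_penalty <- function(rho, rho_hat) {
  if (rho <= 0 || rho > 1) stop("rho must lie in (0, 1]")
  eps <- 1e-7
  rh <- pmin(pmax(rho_hat, eps), 1 - eps)
  t1 <- rho * log(rho / rh)
  t2 <- if (rho >= 1) 0 else (1 - rho) * log((1 - rho) / (1 - rh))
  sum(t1 + t2)
}

#' Per-node focal balancing weights from a truth batch
#'
#' With `mode = "class_freq"` (the default), each output node's weight is
#' the frequency of that node's truth class within the batch: a node whose
#' truth bit is 1 gets the batch frequency of ones at that node. The
#' `"inverse"` mode uses one minus that frequency, the conventional
#' rare-class-upweighting focal alpha.
#'
#' @param truth 0/1 truth matrix, samples x nodes.
#' @param mode `"class_freq"` or `"inverse"`.
#' @return matrix of alpha weights, same shape as `truth`.
#' @export
focal_alpha <- function(truth, mode = "class_freq") {
  f1 <- matrix(colMeans(truth), nrow(truth), ncol(truth), byrow = TRUE)
  a <- ifelse(truth == 1, f1, 1 - f1)
  if (identical(mode, "inverse")) a <- 1 - a
  a
}

#' Assemble the penalized focal loss (SFL)
#'
#' `total = focal + beta * sparsity + lambda1 * sum|W| + lambda2 * sum(W^2)`.
#' The focal term is the per-sample mean of the node-summed focal loss;
#' `alpha_t` is recomputed from the truth batch per [focal_alpha()]. When
#' `spec$loss_type == "cross_entropy"` the focal term is evaluated with
#' `gamma = 0` and `alpha_t = 1`. Biases are excluded from the weight
#' penalties.
#'
#' @param outputs sigmoid output matrix, samples x nodes.
#' @param truth 0/1 truth matrix of the same shape.
#' @param spec a [dae_spec()].
#' @param W list of weight matrices.
#' @param rho_hat batch-mean hidden activation(s) for the sparsity term;
#'   `NULL` gives a zero sparsity term.
#' @return list of class `loss_terms` with elements `focal`, `sparsity`,
#'   `l1`, `l2`, `total`.
#' @export
total_loss <- function(outputs, truth, spec, W, rho_hat = NULL) {
  if (!identical(dim(outputs), dim(truth))) {
    stop("outputs and truth have mismatched shapes")
  }
  n <- nrow(outputs)
  if (spec$loss_type == "cross_entropy") {
    fl <- focal_loss(outputs, truth, alpha_t = 1, gamma = 0) / n
  } else {
    alpha <- focal_alpha(truth, spec$alpha_mode)
    fl <- focal_loss(outputs, truth, alpha_t = alpha,
                     gamma = spec$gamma) / n
  }
  sp <- if (is.null(rho_hat)) 0 else sparsity_penalty(spec$rho, rho_hat)
  l1 <- sum(vapply(W, function(w) sum(abs(w)), numeric(1)))
  l2 <- sum(vapply(W, function(w) sum(w^2), numeric(1)))
  structure(list(focal = fl, sparsity = sp, l1 = l1, l2 = l2,
                 total = fl + spec$beta * sp + spec$lambda1 * l1 +
                   spec$lambda2 * l2),
            class = "loss_terms")
}

# Mean hidden activation of a forward pass, mapped to [0, 1] (tanh is
# affinely rescaled; relu/softplus means are clamped by the penalty).
batch_rho_hat <- function(net, fw) {
  act <- activation_fns[[net$spec$activation]]
  L <- length(net$W)
  if (L < 2) return(NULL)
  tot <- 0; cnt <- 0
  for (l in 2:L) {
    u <- act$to_unit(fw$a[[l]])
    tot <- tot + sum(u); cnt <- cnt + length(u)
  }
  tot / cnt
}

#' Penalized focal loss and its analytic gradients
#'
#' Runs a forward pass, assembles the full penalized focal loss (focal +
#' sparsity + L1 + L2), and backpropagates analytic gradients with respect
#' to every weight matrix and bias vector, including the gradient of the
#' sparsity term through the batch-mean hidden activation.
#'
#' @param net a `dae_net`.
#' @param x input (possibly masked) allele-presence matrix.
#' @param truth uncorrupted allele-presence truth matrix.
#' @return list with `terms` ([total_loss()] breakdown), `gW`, `gb`
#'   (gradient lists matching `net$W` / `net$b`), and `rho_hat`.
#' @export
sfl_gradients <- function(net, x, truth) {
  spec <- net$spec
  eps <- 1e-7
  n <- nrow(x)
  fw <- forward_pass(net, x, keep = TRUE)
  L <- length(net$W)
  p <- pmin(pmax(fw$a[[L + 1]], eps), 1 - eps)

  rho_hat_raw <- batch_rho_hat(net, fw)
  terms <- total_loss(fw$a[[L + 1]], truth, spec, net$W,
                      rho_hat = rho_hat_raw)

  if (spec$loss_type == "cross_entropy") {
    alpha <- 1; gamma <- 0
  } else {
    alpha <- focal_alpha(truth, spec$alpha_mode); gamma <- spec$gamma
  }
  q <- truth * p + (1 - truth) * (1 - p)      # truth-class probability
  dmod <- if (gamma == 0) 0 else -gamma * (1 - q)^(gamma - 1)
  dL_dq <- -alpha * (dmod * log(q) + (1 - q)^gamma / q)
  dL_dp <- dL_dq * (2 * truth - 1)            # dq/dp = +-1
  dL_dp <- dL_dp / n
  # clamp is flat outside [eps, 1-eps]
  dL_dp[fw$a[[L + 1]] < eps | fw$a[[L + 1]] > 1 - eps] <- 0

  act <- activation_fns[[spec$activation]]
  # sparsity gradient through the pooled mean hidden activation
  sp_grad_per_a <- 0
  if (!is.null(rho_hat_raw) && spec$beta > 0) {
    rh <- pmin(pmax(rho_hat_raw, eps), 1 - eps)
    if (rho_hat_raw > eps && rho_hat_raw < 1 - eps) {
      dS <- -spec$rho / rh +
        (if (spec$rho >= 1) 0 else (1 - spec$rho) / (1 - rh))
      N <- sum(vapply(2:L, function(l) length(fw$a[[l]]), numeric(1)))
      unit_scale <- if (spec$activation == "tanh") 0.5 else 1
      sp_grad_per_a <- spec$beta * dS * unit_scale / N
    }
  }

  gW <- vector("list", L); gb <- vector("list", L)
  delta <- dL_dp * fw$a[[L + 1]] * (1 - fw$a[[L + 1]])   # output sigmoid
  for (l in L:1) {
    gW[[l]] <- crossprod(fw$a[[l]], delta) +
      spec$lambda1 * sign(net$W[[l]]) + 2 * spec$lambda2 * net$W[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      da <- tcrossprod(delta, net$W[[l]])
      if (!identical(sp_grad_per_a, 0)) da <- da + sp_grad_per_a
      delta <- da * act$df(fw$z[[l - 1]], fw$a[[l]])
    }
  }
  list(terms = terms, gW = gW, gb = gb, rho_hat = rho_hat_raw)
}
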