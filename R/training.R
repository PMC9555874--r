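#' Training schedule for the escalating-masking curriculum
#'
#' Training proceeds in masking/training cycles of `epochs_per_cycle`
#' epochs. The per-cycle masking rate starts at `initial_mask_rate` and
#' rises linearly until only `min_unmasked` variants remain unmasked in the
#' final cycle. Training stops early when a cycle's mean total loss fails
#' to improve on the previous cycle's.
#'
#' @param initial_mask_rate masking rate of the first cycle (default 0.80).
#' @param min_unmasked variants left unmasked at the final cycle
#'   (default 5).
#' @param epochs_per_cycle epochs per masking cycle (default 500).
#' @param max_epochs total epoch budget; must be a multiple of
#'   `epochs_per_cycle` (coarse search uses one cycle of 500; tuning up to
#'   35000).
#' @param batch_size samples per minibatch (default 256).
#' @param seed root seed for mask draws and weight initialization.
#' @param escalation `"linear"` (default) or `"geometric"` growth of the
#'   per-cycle rate between its fixed first and last values.
#' @return list of class `training_schedule`.
#' @export
training_schedule <- function(initial_mask_rate = 0.80, min_unmasked = 5,
                              epochs_per_cycle = 500, max_epochs = 500,
                              batch_size = 256, seed = 1L,
                              escalation = "linear") {
  stopifnot(initial_mask_rate > 0, initial_mask_rate < 1, min_unmasked >= 1,
            epochs_per_cycle >= 1, max_epochs >= epochs_per_cycle,
            max_epochs %% epochs_per_cycle == 0, batch_size >= 1)
  escalation <- match.arg(escalation, c("linear", "geometric"))
  structure(list(initial_mask_rate = initial_mask_rate,
                 min_unmasked = as.integer(min_unmasked),
                 epochs_per_cycle = as.integer(epochs_per_cycle),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), escalation = escalation),
            class = "training_schedule")
}

#' Per-cycle masking rates
#'
#' Rates rise from `initial_mask_rate` in cycle 1 to
#' `(n_variants - min_unmasked) / n_variants` in the final cycle; with a
#' single cycle the initial rate is used.
#'
#' @param n_variants variants in the segment (> `min_unmasked`).
#' @param schedule a [training_schedule()].
#' @return numeric vector of length `max_epochs / epochs_per_cycle`,
#'   monotone non-decreasing.
#' @export
masking_schedule <- function(n_variants, schedule = training_schedule()) {
  m <- n_variants
  if (m <= schedule$min_unmasked) {
    stop("n_variants must exceed min_unmasked (", schedule$min_unmasked, ")")
  }
  n_cycles <- schedule$max_epochs %/% schedule$epochs_per_cycle
  final <- (m - schedule$min_unmasked) / m
  if (n_cycles == 1L) return(schedule$initial_mask_rate)
  if (final < schedule$initial_mask_rate) {
    stop("final rate ", signif(final, 4), " below initial rate; segment ",
         "too small for this curriculum")
  }
  if (schedule$escalation == "linear") {
    seq(schedule$initial_mask_rate, final, length.out = n_cycles)
  } else {
    exp(seq(log(schedule$initial_mask_rate), log(final),
            length.out = n_cycles))
  }
}

#' Mask a random subset of variants per sample
#'
#' For each sample independently, `ceiling(rate * n_variants)` variants are
#' drawn uniformly and their allele-presence pair set to (0, 0) — the null
#' encoding. The truth matrix is never touched; masking only corrupts the
#' copy fed to the network.
#'
#' @param x allele-presence matrix (samples x `2 * n_variants`).
#' @param rate masking rate in `[0, 1]`.
#' @return masked copy of `x`.
#' @export
apply_mask <- function(x, rate) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(x)
  m <- ncol(x) %/% 2L
  k <- min(m, ceiling(rate * m))
  for (s in seq_len(nrow(x))) {
    idx <- sample.int(m, k)
    cols <- c(2L * idx - 1L, 2L * idx)
    x[s, cols] <- 0
  }
  x
}

optimizer_init <- function(net) {
  zero <- function(p) lapply(p, function(w) array(0, dim = dim(w) %||%
                                                    length(w)))
  list(mW = zero(net$W), vW = zero(net$W),
       mb = lapply(net$b, function(v) numeric(length(v))),
       vb = lapply(net$b, function(v) numeric(length(v))),
       t = 0L)
}

optimizer_step <- function(net, grads, state, lr) {
  type <- net$spec$optimizer
  state$t <- state$t + 1L
  b1 <- 0.9; b2 <- 0.999; epso <- 1e-8
  for (l in seq_along(net$W)) {
    for (part in c("W", "b")) {
      g <- if (part == "W") grads$gW[[l]] else grads$gb[[l]]
      p <- if (part == "W") net$W[[l]] else net$b[[l]]
      mkey <- paste0("m", part); vkey <- paste0("v", part)
      if (type == "sgd") {
        p <- p - lr * g
      } else if (type == "rmsprop") {
        v <- 0.9 * state[[vkey]][[l]] + 0.1 * g^2
        state[[vkey]][[l]] <- v
        p <- p - lr * g / (sqrt(v) + epso)
      } else { # adam
        mm <- b1 * state[[mkey]][[l]] + (1 - b1) * g
        vv <- b2 * state[[vkey]][[l]] + (1 - b2) * g^2
        state[[mkey]][[l]] <- mm; state[[vkey]][[l]] <- vv
        mhat <- mm / (1 - b1^state$t); vhat <- vv / (1 - b2^state$t)
        p <- p - lr * mhat / (sqrt(vhat) + epso)
      }
      if (part == "W") net$W[[l]] <- p else net$b[[l]] <- p
    }
  }
  list(net = net, state = state)
}

#' Train one segment's denoising autoencoder
#'
#' Runs the escalating-masking curriculum: cycles of `epochs_per_cycle`
#' epochs, masks re-drawn per batch and per sample at the cycle's rate,
#' learning rate multiplied by `lr_decay` every 500 epochs (`lr_decay = 0`
#' disables decay), optimizer state persisting across cycles. Training
#' stops early when a cycle's mean total loss fails to strictly improve on
#' the previous cycle's mean.
#'
#' @param panel training [genotype_panel()].
#' @param segment one-row slice of a `genomic_segments` tibble (or a list
#'   with `start`/`end`), selecting the variant window; `NULL` trains on the
#'   whole panel.
#' @param spec a [dae_spec()].
#' @param schedule a [training_schedule()].
#' @return list of class `dae_fit`: `net` (final weights), `trace`
#'   (per-cycle tibble: cycle, mask_rate, mean focal/sparsity/l1/l2/total),
#'   `stopped_early`, `variants` (the segment's variant table), `spec`,
#'   `schedule`, `segment_id`.
#' @export
train_segment <- function(panel, segment = NULL, spec = dae_spec(),
                          schedule = training_schedule()) {
  if (!is.null(segment)) {
    vi <- seq(segment$start, segment$end)
    panel <- subset_panel(panel, variants = vi)
  }
  m <- n_variants(panel)
  truth_all <- encode_genotypes(panel)
  rates <- masking_schedule(m, schedule)
  n <- nrow(truth_all)
  set.seed(schedule$seed)
  net <- build_autoencoder(spec, m,
                           seed = sample.int(.Machine$integer.max, 1))
  state <- optimizer_init(net)
  lr <- spec$learning_rate
  decay <- if (spec$lr_decay == 0) 1 else spec$lr_decay

  trace <- vector("list", length(rates))
  prev_mean <- Inf
  stopped <- FALSE
  epoch_global <- 0L
  for (cy in seq_along(rates)) {
    cycle_losses <- c()
    terms_acc <- c(focal = 0, sparsity = 0, l1 = 0, l2 = 0)
    nb_acc <- 0L
    for (ep in seq_len(schedule$epochs_per_cycle)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = schedule$batch_size)
      for (st in starts) {
        rows <- perm[st:min(st + schedule$batch_size - 1L, n)]
        truth <- truth_all[rows, , drop = FALSE]
        xin <- apply_mask(truth, rates[cy])
        g <- sfl_gradients(net, xin, truth)
        if (!is.finite(g$terms$total)) {
          stop("non-finite loss at cycle ", cy, ", epoch ", ep,
               " (lr = ", lr, "); try a smaller learning rate")
        }
        upd <- optimizer_step(net, g, state, lr)
        net <- upd$net; state <- upd$state
        cycle_losses <- c(cycle_losses, g$terms$total)
        terms_acc <- terms_acc + c(g$terms$focal, g$terms$sparsity,
                                   g$terms$l1, g$terms$l2)
        nb_acc <- nb_acc + 1L
      }
      epoch_global <- epoch_global + 1L
      if (epoch_global %% 500L == 0L) lr <- lr * decay
    }
    cyc_mean <- mean(cycle_losses)
    trace[[cy]] <- tibble::tibble(
      cycle = cy, mask_rate = rates[cy], mean_total = cyc_mean,
      mean_focal = terms_acc[["focal"]] / nb_acc,
      mean_sparsity = terms_acc[["sparsity"]] / nb_acc,
      mean_l1 = terms_acc[["l1"]] / nb_acc,
      mean_l2 = terms_acc[["l2"]] / nb_acc,
      learning_rate = lr)
    if (cyc_mean >= prev_mean) {
      stopped <- TRUE
      trace <- trace[seq_len(cy)]
      break
    }
    prev_mean <- cyc_mean
  }
  structure(list(net = net, trace = dplyr::bind_rows(trace),
                 stopped_early = stopped,
                 variants = panel$variants, spec = spec,
                 schedule = schedule,
                 segment_id = segment$segment_id %||% 1L),
            class = "dae_fit")
}

#' @export
print.dae_fit <- function(x, ...) {
  cat("<dae_fit> segment ", x$segment_id, ": ", nrow(x$variants),
      " variants, ", nrow(x$trace), " cycle(s)",
      if (x$stopped_early) " (early stop)", "\n", sep = "")
  cat("  final mean total loss: ",
      signif(utils::tail(x$trace$mean_total, 1), 5), "\n", sep = "")
  invisible(x)
}
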