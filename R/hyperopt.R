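#' Coarse-search hyperparameter grid
#'
#' Value lists for the random coarse grid search, one entry per tunable
#' field of [dae_spec()].
#'
#' @return named list of value vectors.
#' @export
hyperparameter_grid <- function() {
  list(
    lambda1 = c(1e-3, 1e-4, 1e-5, 1e-6, 1e-1, 1e-2, 1e-7, 1e-8),
    lambda2 = c(1e-3, 1e-4, 1e-5, 1e-6, 1e-1, 1e-2, 1e-7, 1e-8),
    beta = c(0, 0.001, 0.01, 0.05, 1, 5, 10),
    rho = c(0.001, 0.004, 0.007, 0.01, 0.04, 0.07, 0.1, 0.4, 0.7, 1.0),
    activation = c("sigmoid", "tanh", "relu", "softplus"),
    learning_rate = c(1e-6, 1e-5, 1e-4, 1e-3, 1e-2, 1e-1, 1, 10, 100),
    gamma = c(0, 0.5, 1, 2, 3, 5),
    optimizer = c("adam", "rmsprop", "sgd"),
    loss_type = c("cross_entropy", "focal"),
    n_hidden_layers = c(1, 2, 4, 6, 8),
    size_ratio = c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1),
    lr_decay = c(0.0, 0.25, 0.5, 0.75, 0.95, 0.99, 0.999, 0.9999)
  )
}

spec_key <- function(spec) {
  paste(vapply(names(hyperparameter_grid()),
               function(f) format(spec[[f]], digits = 12), character(1)),
        collapse = "|")
}

#' Randomly sample distinct hyperparameter combinations
#'
#' Each spec draws every field uniformly from its grid value list;
#' duplicates are rejected and redrawn.
#'
#' @param n_combinations number of distinct specs (must not exceed the grid
#'   size).
#' @param seed integer seed.
#' @return list of [dae_spec()] objects.
#' @export
sample_grid <- function(n_combinations, seed = 1L) {
  grid <- hyperparameter_grid()
  total <- prod(vapply(grid, length, numeric(1)))
  if (n_combinations < 1 || n_combinations > total) {
    stop("n_combinations must lie in [1, ", total, "]")
  }
  set.seed(seed)
  out <- list(); seen <- character(0)
  while (length(out) < n_combinations) {
    draw <- lapply(grid, function(v) sample(v, 1))
    # rho = 0 is excluded by construction; beta 0 fine
    sp <- dae_spec(lambda1 = draw$lambda1, lambda2 = draw$lambda2,
                   beta = draw$beta, rho = draw$rho,
                   activation = draw$activation,
                   learning_rate = draw$learning_rate, gamma = draw$gamma,
                   optimizer = draw$optimizer, loss_type = draw$loss_type,
                   n_hidden_layers = draw$n_hidden_layers,
                   size_ratio = draw$size_ratio, lr_decay = draw$lr_decay)
    key <- spec_key(sp)
    if (!key %in% seen) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- sp
    }
  }
  out
}

#' Convert a list of specs to a tibble
#'
#' @param specs list of [dae_spec()] objects.
#' @return tibble with one row per spec and one column per grid field.
#' @export
specs_to_tibble <- function(specs) {
  purrr::map_dfr(specs, function(sp) {
    tibble::as_tibble(sp[names(hyperparameter_grid())])
  })
}

#' Predictive features of a genomic segment
#'
#' LD-complexity features used by the performance meta-model: variant
#' count, mean recombination rate over the segment span (when a genetic map
#' is supplied), mean absolute pairwise dosage correlation, MAF-bin
#' proportions and rare/common split, principal components needed for 90%
#' of dosage variance, variance explained by the first two components,
#' unique haplotype/diplotype counts (haplotypes pseudo-phased when
#' unphased), and mean heterozygosity.
#'
#' @param panel a [genotype_panel()].
#' @param segment one-row segment slice (`start`, `end`); `NULL` uses the
#'   whole panel.
#' @param map optional [genetic_map()] for the recombination-rate feature.
#' @param maf_min rare/common threshold (default 0.005).
#' @param max_corr_pairs cap on sampled pairs for the mean-correlation
#'   feature (default 20000).
#' @param seed seed for pair sampling / pseudo-phasing.
#' @return one-row tibble of features.
#' @export
extract_features <- function(panel, segment = NULL, map = NULL,
                             maf_min = 0.005, max_corr_pairs = 20000,
                             seed = 1L) {
  if (!is.null(segment)) {
    panel <- subset_panel(panel, variants = seq(segment$start, segment$end))
  }
  m <- n_variants(panel)
  if (m < 1 || all(is.na(panel$genotypes))) stop("empty or all-missing segment")
  g <- panel$genotypes
  mafs <- maf(panel)

  mean_rate <- NA_real_
  if (!is.null(map)) {
    span_cm <- diff(range(interp_cM(map, panel$variants$chrom[1],
                                    range(panel$variants$pos))))
    span_mb <- diff(range(panel$variants$pos)) / 1e6
    mean_rate <- if (span_mb > 0) span_cm / span_mb else 0
  }

  ok_var <- which(apply(g, 2, function(col) stats::var(col, na.rm = TRUE)) > 0)
  mean_abs_r <- NA_real_
  if (length(ok_var) >= 2) {
    set.seed(seed)
    pairs <- utils::combn(ok_var, 2)
    if (ncol(pairs) > max_corr_pairs) {
      pairs <- pairs[, sample.int(ncol(pairs), max_corr_pairs)]
    }
    cors <- suppressWarnings(vapply(seq_len(ncol(pairs)), function(t) {
      stats::cor(g[, pairs[1, t]], g[, pairs[2, t]],
                 use = "pairwise.complete.obs")
    }, numeric(1)))
    mean_abs_r <- mean(abs(cors), na.rm = TRUE)
  }

  gp <- g; gp[is.na(gp)] <- 0L
  keep <- which(apply(gp, 2, stats::var) > 0)
  n_pcs_90 <- 1L; var_first2 <- 1
  if (length(keep) >= 2 && nrow(gp) >= 2) {
    pc <- stats::prcomp(gp[, keep, drop = FALSE], center = TRUE)
    ve <- pc$sdev^2 / sum(pc$sdev^2)
    n_pcs_90 <- as.integer(which(cumsum(ve) >= 0.9)[1])
    var_first2 <- sum(ve[seq_len(min(2, length(ve)))])
  }

  hap <- tryCatch(pseudo_phase(panel, seed = seed), error = function(e) NULL)
  n_hap <- if (is.null(hap)) NA_integer_ else {
    length(unique(apply(hap, 1, paste, collapse = "")))
  }
  gdip <- g; gdip[is.na(gdip)] <- -1L
  n_dip <- length(unique(apply(gdip, 1, paste, collapse = "")))
  het <- mean(g == 1L, na.rm = TRUE)

  bins <- maf_bin(pmin(mafs, 0.5))
  bin_prop <- as.list(prop.table(table(bins)))
  names(bin_prop) <- paste0("prop_", gsub("[^0-9a-z._]+", "_",
                                          tolower(names(bin_prop))))
  tibble::as_tibble(c(list(
    n_snps = m,
    mean_recombination_rate = mean_rate,
    mean_pairwise_correlation = mean_abs_r,
    prop_rare = mean(mafs < maf_min, na.rm = TRUE),
    prop_common = mean(mafs >= maf_min, na.rm = TRUE),
    n_pcs_for_90pct_variance = n_pcs_90,
    var_explained_first2_pcs = var_first2,
    n_unique_haplotypes = n_hap,
    n_unique_diplotypes = n_dip,
    mean_heterozygosity = het), bin_prop))
}

meta_design <- function(specs_tbl, features_tbl) {
  cat_cols <- c("activation", "optimizer", "loss_type")
  df <- dplyr::bind_cols(specs_tbl, features_tbl)
  for (cc in cat_cols) {
    df[[cc]] <- factor(df[[cc]], levels = hyperparameter_grid()[[cc]])
  }
  mm <- stats::model.matrix(
    ~ . - 1, data = df,
    contrasts.arg = lapply(df[cat_cols], stats::contrasts,
                           contrasts = FALSE))
  mm[, colSums(is.na(mm)) == 0, drop = FALSE]
}

#' Fit the performance meta-model
#'
#' Gradient-boosted regression trees (XGBoost, default settings, 10-fold
#' cross-validation) mapping hyperparameter combinations plus segment
#' features to the validation dosage r-squared observed in the coarse
#' search. Categorical spec fields are one-hot encoded.
#'
#' @param results tibble of grid results: the [dae_spec()] fields (as from
#'   [specs_to_tibble()]) plus a `validation_r2` column and, optionally, a
#'   `segment_id` used to stratify CV folds; >= 50 rows required.
#' @param features tibble of segment features row-aligned with `results`
#'   (recycled from one row per segment via `segment_id` if it has fewer
#'   rows).
#' @param nrounds boosting rounds (default 100).
#' @param seed seed for fold assignment.
#' @return list of class `performance_model`: `booster`, `cv_r2`,
#'   `feature_names`.
#' @export
fit_performance_model <- function(results, features, nrounds = 100,
                                  seed = 1L) {
  if (nrow(results) < 50) stop("need >= 50 grid results")
  y <- results$validation_r2
  if (stats::var(y) == 0) stop("degenerate constant target")
  if (nrow(features) != nrow(results)) {
    stopifnot(!is.null(results$segment_id),
              nrow(features) == length(unique(results$segment_id)))
    features <- features[match(results$segment_id,
                               sort(unique(results$segment_id))), ]
  }
  spec_cols <- intersect(names(hyperparameter_grid()), names(results))
  X <- meta_design(results[, spec_cols], features)
  set.seed(seed)
  if (!is.null(results$segment_id)) {
    folds <- integer(nrow(X))
    for (sid in unique(results$segment_id)) {
      idx <- which(results$segment_id == sid)
      folds[idx] <- sample(rep(1:10, length.out = length(idx)))
    }
  } else {
    folds <- sample(rep(1:10, length.out = nrow(X)))
  }
  boost <- function(Xm, yv) {
    xgboost::xgb.train(
      params = list(objective = "reg:squarederror", nthread = 1),
      data = xgboost::xgb.DMatrix(Xm, label = yv, nthread = 1),
      nrounds = nrounds, verbose = 0)
  }
  pred_cv <- numeric(nrow(X))
  for (f in 1:10) {
    tr <- folds != f
    bst <- boost(X[tr, , drop = FALSE], y[tr])
    pred_cv[folds == f] <- predict(
      bst, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE], nthread = 1))
  }
  cv_r2 <- stats::cor(pred_cv, y)^2
  booster <- boost(X, y)
  structure(list(booster = booster, cv_r2 = cv_r2,
                 feature_names = colnames(X)),
            class = "performance_model")
}

#' Predict expected r-squared for candidate specs
#'
#' @param object a `performance_model`.
#' @param specs list of [dae_spec()] (or a spec tibble).
#' @param features one-row segment-feature tibble (recycled over specs).
#' @param ... unused.
#' @return numeric vector of predicted r-squared.
#' @export
predict.performance_model <- function(object, specs, features, ...) {
  specs_tbl <- if (is.data.frame(specs)) specs else specs_to_tibble(specs)
  feats <- features[rep(1, nrow(specs_tbl)), , drop = FALSE]
  X <- meta_design(specs_tbl, feats)
  miss <- setdiff(object$feature_names, colnames(X))
  if (length(miss) > 0) {
    X <- cbind(X, matrix(0, nrow(X), length(miss),
                         dimnames = list(NULL, miss)))
  }
  predict(object$booster,
          xgboost::xgb.DMatrix(X[, object$feature_names, drop = FALSE],
                               nthread = 1))
}

#' Select candidate hyperparameter combinations for fine-tuning
#'
#' Ranks candidates by predicted r-squared, keeps the top `n_top`, and adds
#' the best observed combination from the coarse search (deduplicated).
#'
#' @param model a `performance_model`.
#' @param candidate_specs list of candidate [dae_spec()] objects.
#' @param features one-row segment-feature tibble.
#' @param observed_best the single best coarse-search [dae_spec()]
#'   (optional).
#' @param n_top candidates to keep by predicted performance (default 10).
#' @return list of specs (<= `n_top` + 1), attribute `predicted_r2` giving
#'   the prediction for each returned candidate (`NA` for an appended
#'   observed best).
#' @export
select_candidates <- function(model, candidate_specs, features,
                              observed_best = NULL, n_top = 10) {
  stopifnot(length(candidate_specs) >= 1)
  pred <- predict(model, candidate_specs, features)
  ord <- order(pred, decreasing = TRUE)
  keep <- ord[seq_len(min(n_top, length(ord)))]
  out <- candidate_specs[keep]
  pr <- pred[keep]
  if (!is.null(observed_best)) {
    keys <- vapply(out, spec_key, character(1))
    if (!spec_key(observed_best) %in% keys) {
      out <- c(out, list(observed_best))
      pr <- c(pr, NA_real_)
    }
  }
  attr(out, "predicted_r2") <- pr
  out
}
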