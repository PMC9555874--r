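# A fixed single-variant "network" whose output is set by its biases:
# zero weights and output bias (qlogis(p_ref), qlogis(p_alt)).
fixed_fit <- function(p_ref, p_alt, variant, segment_id) {
  spec <- dae_spec(n_hidden_layers = 1, size_ratio = 1)
  net <- build_autoencoder(spec, 1, seed = 1)
  net$W <- lapply(net$W, function(w) w * 0)
  net$b[[1]] <- c(0, 0)
  net$b[[2]] <- stats::qlogis(c(p_ref, p_alt))
  structure(list(net = net, trace = tibble::tibble(), stopped_early = FALSE,
                 variants = variant, spec = spec, schedule = NULL,
                 segment_id = segment_id),
            class = "dae_fit")
}

one_variant <- tibble::tibble(chrom = "1", pos = 100L, ref = "A", alt = "G")

test_that("variant matching is an exact allele-aware join", {
  mv <- tibble::tibble(chrom = "1", pos = c(10L, 20L, 30L),
                       ref = c("A", "C", "G"), alt = c("G", "T", "A"))
  idm <- match_variants(mv, mv)
  expect_equal(idm$map$observed_index, 1:3)
  expect_equal(idm$map$model_index, 1:3)
  swapped <- mv
  swapped$ref[2] <- "T"; swapped$alt[2] <- "C"
  expect_warning(res <- match_variants(swapped, mv), "dropped")
  expect_equal(res$n_matched, 2)
  expect_equal(res$n_dropped, 1)
  expect_equal(res$dropped$pos, 20L)
  expect_error(match_variants(mv[c(2, 1, 3), ], mv), "sorted")
})

test_that("variant matching equals a brute-force dictionary join", {
  set.seed(9)
  pos <- sort(sample(1:5000, 100))
  mv <- tibble::tibble(chrom = "7", pos = pos,
                       ref = sample(c("A", "C"), 100, TRUE), alt = "G")
  obs <- mv[sort(sample(100, 40)), ]
  res <- match_variants(obs, mv)
  dict <- stats::setNames(seq_len(100), paste(mv$chrom, mv$pos, mv$ref, mv$alt))
  oracle <- unname(dict[paste(obs$chrom, obs$pos, obs$ref, obs$alt)])
  expect_equal(res$map$model_index, oracle)
})

test_that("overlapping segment predictions average then renormalize", {
  # networks engineered to output class probabilities (0.6,0.3,0.1) and
  # (0.2,0.5,0.3) for the same variant
  f1 <- fixed_fit(p_ref = 0.75, p_alt = 1 / 3, one_variant, 1L)
  f2 <- fixed_fit(p_ref = 0.625, p_alt = 5 / 7, one_variant, 2L)
  models <- dae_models(list(f1, f2))
  obs <- genotype_panel(matrix(NA_integer_, 1, 1), one_variant, "s1")
  gp <- impute(obs, models)
  expect_equal(as.numeric(gp$p[1, 1, ]), c(0.4, 0.4, 0.2), tolerance = 1e-9)
  # a variant in exactly one segment returns that segment's prediction
  gp1 <- impute(obs, dae_models(list(f1)))
  expect_equal(as.numeric(gp1$p[1, 1, ]), c(0.6, 0.3, 0.1),
               tolerance = 1e-9)
})

test_that("observed genotypes pass through and unobserved sites get imputed", {
  pan <- block_panel(1, n_hap = 160, block_size = 20, gap = 0, r2 = 1,
                     rare_fraction = 0, seed = 21)
  spec <- dae_spec(loss_type = "cross_entropy", activation = "relu",
                   learning_rate = 1e-3, lambda1 = 0, lambda2 = 0, beta = 0,
                   size_ratio = 1)
  sched <- training_schedule(initial_mask_rate = 0.5, min_unmasked = 5,
                             epochs_per_cycle = 30, max_epochs = 60,
                             batch_size = 80, seed = 23)
  fit <- train_segment(pan, NULL, spec, sched)
  models <- dae_models(list(fit))
  # keep 4 variants observed
  obs_full <- array_mask(pan, observed_fraction = 0.2, seed = 25)
  keep <- attr(obs_full, "observed_index")
  obs <- subset_panel(obs_full, variants = keep)
  gp <- impute(obs, models)
  expect_equal(dim(gp$p), c(80, 20, 3))
  sums <- gp$p[, , 1] + gp$p[, , 2] + gp$p[, , 3]
  expect_true(all(abs(sums - 1) <= 1e-6))
  expect_equal(which(gp$genotyped), keep)
  # pass-through: hard calls at observed sites equal the input genotypes
  calls <- hard_calls(gp)
  expect_identical(calls[, keep], unname(obs$genotypes))
  # imputation output covers every model variant exactly once
  expect_identical(gp$variants, models$variants)
})

test_that("imputation is sample-wise independent", {
  f1 <- fixed_fit(0.75, 1 / 3, one_variant, 1L)
  obs3 <- genotype_panel(matrix(c(0L, NA, 2L), 3, 1), one_variant,
                         c("a", "b", "c"))
  gp_all <- impute(obs3, dae_models(list(f1)))
  for (s in 1:3) {
    gp_one <- impute(subset_panel(obs3, samples = s), dae_models(list(f1)))
    expect_equal(gp_one$p[1, , ], gp_all$p[s, , ])
  }
})

test_that("segments with no observed variants are flagged low-confidence", {
  f1 <- fixed_fit(0.75, 1 / 3, one_variant, 1L)
  obs <- genotype_panel(matrix(NA_integer_, 2, 1), one_variant, c("a", "b"))
  gp <- impute(obs, dae_models(list(f1)))
  expect_equal(attr(gp, "low_confidence_segments"), 1L)
})

test_that("model collections survive a save/load round trip", {
  pan <- block_panel(1, n_hap = 30, block_size = 8, gap = 0, seed = 27)
  spec <- dae_spec(loss_type = "cross_entropy")
  sched <- training_schedule(initial_mask_rate = 0.5, min_unmasked = 2,
                             epochs_per_cycle = 2, max_epochs = 2,
                             batch_size = 15, seed = 29)
  fit <- train_segment(pan, NULL, spec, sched)
  models <- dae_models(list(fit))
  dir <- tempfile()
  save_models(models, dir)
  back <- load_models(dir)
  expect_equal(back$fits[[1]]$net$W, models$fits[[1]]$net$W,
               tolerance = 1e-12)
  expect_equal(back$variants, models$variants)
  x <- encode_genotypes(pan)
  expect_equal(forward_pass(back$fits[[1]]$net, x),
               forward_pass(models$fits[[1]]$net, x), tolerance = 1e-10)
})
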