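test_that("random grid draws distinct combinations from the value lists", {
  grid <- hyperparameter_grid()
  specs <- sample_grid(100, seed = 3)
  expect_length(specs, 100)
  keys <- vapply(specs, daeimpute:::spec_key, character(1))
  expect_equal(anyDuplicated(keys), 0)
  for (sp in specs[1:20]) {
    for (f in names(grid)) {
      expect_true(sp[[f]] %in% grid[[f]], info = f)
    }
  }
  expect_identical(vapply(sample_grid(50, seed = 9), daeimpute:::spec_key,
                          character(1)),
                   vapply(sample_grid(50, seed = 9), daeimpute:::spec_key,
                          character(1)))
  expect_error(sample_grid(1e12), "n_combinations")
})

test_that("segment features capture degenerate and simple structures", {
  # identical samples: one diplotype, all variance on no axis
  g <- matrix(rep(c(0L, 1L, 2L, 1L), each = 12), 12, 4)
  pan <- genotype_panel(g, tibble::tibble(chrom = "1", pos = 1:4 * 100L,
                                          ref = "A", alt = "G"))
  f <- extract_features(pan)
  expect_equal(f$n_unique_diplotypes, 1)
  expect_equal(f$n_pcs_for_90pct_variance, 1)
  expect_equal(f$mean_heterozygosity, 0.5)
  # independent equal-frequency variants: near-zero mean correlation
  set.seed(4)
  g2 <- matrix(rbinom(500 * 30, 2, 0.5), 500, 30)
  pan2 <- genotype_panel(g2, tibble::tibble(chrom = "1", pos = 1:30 * 100L,
                                            ref = "A", alt = "G"))
  f2 <- extract_features(pan2)
  expect_lt(f2$mean_pairwise_correlation, 0.1)
  expect_equal(f2$prop_common, 1)
})

test_that("segment features match brute-force recomputation on a toy panel", {
  pan <- block_panel(1, n_hap = 40, block_size = 30, gap = 0,
                     rare_fraction = 0.4, seed = 5)
  map <- generate_genetic_map(pan, background_cM_per_Mb = 10)
  f <- extract_features(pan, map = map)
  g <- pan$genotypes
  expect_equal(f$n_snps, 30)
  expect_equal(f$mean_heterozygosity, mean(g == 1))
  expect_equal(f$n_unique_diplotypes,
               nrow(unique(as.data.frame(g))))
  expect_equal(f$prop_rare, mean(maf(pan) < 0.005))
  # PCA oracle (polymorphic sites)
  keep <- apply(g, 2, var) > 0
  pc <- prcomp(g[, keep])
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  expect_equal(f$n_pcs_for_90pct_variance, which(cumsum(ve) >= 0.9)[1])
  expect_equal(f$var_explained_first2_pcs, sum(ve[1:2]))
  # mean |r| oracle over all polymorphic pairs
  cm <- abs(cor(g[, keep]))
  expect_equal(f$mean_pairwise_correlation, mean(cm[upper.tri(cm)]))
  # recombination rate = span cM / span Mb
  expect_equal(f$mean_recombination_rate, 10)
  # sample-order invariance
  f3 <- extract_features(subset_panel(pan, samples = sample(20)))
  expect_equal(f3$mean_heterozygosity, f$mean_heterozygosity)
  expect_equal(f3$n_unique_diplotypes, f$n_unique_diplotypes)
})

# Smooth synthetic response surface over (gamma, learning rate, size).
surface_r2 <- function(tbl) {
  0.2 + 0.6 * plogis(2 - 0.5 * tbl$gamma -
                       abs(log10(tbl$learning_rate) + 3) / 2 -
                       tbl$n_snps / 8000)
}

test_that("the meta-model learns a smooth response surface and ranks candidates", {
  specs <- sample_grid(300, seed = 6)
  tbl <- specs_to_tibble(specs)
  sizes <- rep(c(500, 1500, 3000, 4500, 6000), each = 60)
  feats <- purrr::map_dfr(sizes, function(s) {
    tibble::tibble(n_snps = s, mean_pairwise_correlation = 0.3,
                   var_explained_first2_pcs = 0.5)
  })
  results <- dplyr::mutate(tbl, segment_id = rep(1:5, each = 60),
                           validation_r2 = surface_r2(
                             dplyr::mutate(tbl, n_snps = sizes)))
  feats_by_seg <- dplyr::distinct(feats)
  model <- fit_performance_model(results, feats_by_seg, seed = 7)
  expect_gte(model$cv_r2, 0.9)

  cands <- sample_grid(200, seed = 8)
  feat1 <- feats_by_seg[1, ]
  sel <- select_candidates(model, cands, feat1, n_top = 10)
  expect_length(sel, 10)
  # ranking equals a brute-force sort of the predictions
  preds <- predict(model, cands, feat1)
  expect_equal(vapply(sel, daeimpute:::spec_key, character(1)),
               vapply(cands[order(preds, decreasing = TRUE)[1:10]],
                      daeimpute:::spec_key, character(1)))
  # selected candidates sit in the true top decile of the surface
  truth <- surface_r2(dplyr::mutate(specs_to_tibble(cands),
                                    n_snps = feat1$n_snps))
  decile <- sort(truth, decreasing = TRUE)[ceiling(0.1 * length(truth))]
  sel_truth <- surface_r2(dplyr::mutate(specs_to_tibble(sel),
                                        n_snps = feat1$n_snps))
  expect_gte(sum(sel_truth >= decile), 8)

  # observed best is appended once and never duplicated
  ob <- cands[[order(preds, decreasing = TRUE)[1]]]
  sel2 <- select_candidates(model, cands, feat1, observed_best = ob)
  expect_length(sel2, 10)
  ob2 <- cands[[order(preds, decreasing = TRUE)[50]]]
  sel3 <- select_candidates(model, cands, feat1, observed_best = ob2)
  expect_length(sel3, 11)
  expect_error(fit_performance_model(results[1:10, ], feats_by_seg), ">= 50")
  expect_error(
    fit_performance_model(dplyr::mutate(results, validation_r2 = 0.5),
                          feats_by_seg), "constant")
})
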