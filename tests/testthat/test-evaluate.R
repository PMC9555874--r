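test_that("per-variant r2 matches the Pearson formula and handles degeneracy", {
  a <- c(0, 1, 2, 1, 0, 2)
  b <- c(0.1, 0.9, 1.8, 1.2, 0.2, 1.7)
  expect_equal(per_variant_r2(b, a), 0.974001268231, tolerance = 1e-10)
  expect_equal(per_variant_r2(a, a), 1)
  expect_true(is.na(per_variant_r2(rep(1, 6), a)))   # constant prediction
  expect_true(is.na(per_variant_r2(b, rep(2, 6))))   # constant truth
  expect_error(per_variant_r2(a, a[-1]), "mismatch")
  # symmetry and affine invariance
  expect_equal(per_variant_r2(b, a), per_variant_r2(a, b))
  expect_equal(per_variant_r2(3 * b - 1, a), per_variant_r2(b, a))
})

test_that("MAF bins partition [0, 0.5] with the standard eight bins", {
  expect_equal(as.character(maf_bin(0.005)), "[0.005,0.01)")
  expect_equal(as.character(maf_bin(0.5)), "[0.4,0.5]")
  expect_equal(as.character(maf_bin(0.0005)), "ultra-rare")
  expect_error(maf_bin(0.6), "minor")
  set.seed(6)
  u <- runif(10000, 0, 0.5)
  bins <- maf_bin(u)
  expect_false(anyNA(bins))                  # every maf lands in one bin
  expect_equal(length(levels(bins)), 9)
  # boundary values land in the right-open bin
  expect_equal(as.character(maf_bin(c(0.001, 0.01, 0.4))),
               c("[0.001,0.005)", "[0.01,0.05)", "[0.4,0.5]"))
})

test_that("concordance and macro F1 match a hand-computed confusion table", {
  truth <- c(0, 0, 0, 1, 1, 2, 2, 2, 2, 1)
  imp <- c(0, 1, 0, 1, 2, 2, 2, 0, 2, 1)
  res <- concordance_and_f1(imp, truth)
  expect_equal(res$concordance, 0.7)
  expect_equal(res$f1, 0.694444444444, tolerance = 1e-10)
  perfect <- concordance_and_f1(truth, truth)
  expect_equal(perfect$concordance, 1)
  expect_equal(perfect$f1, 1)
  # all-hom-ref predictions on balanced truth
  bal <- rep(0:2, each = 5)
  expect_equal(concordance_and_f1(rep(0, 15), bal)$concordance, 1 / 3)
  # missing truth is skipped; all-missing is undefined
  expect_equal(concordance_and_f1(c(0, 1), c(NA, 1))$concordance, 1)
  expect_true(is.na(concordance_and_f1(c(0), c(NA))$f1))
})

test_that("method comparison reports wins, rank-sum and two-proportion tests", {
  x <- c(0.5, 0.61, 0.58, 0.7, 0.66)
  y <- c(0.52, 0.49, 0.6, 0.55, 0.47)
  cmp <- compare_methods(x, y)
  expect_equal(cmp$n_wins_a, 3)
  expect_equal(cmp$n_wins_b, 2)
  # frozen oracle: normal-approximation rank-sum on this 5v5 toy
  expect_equal(cmp$rank_sum_p, 0.09469294, tolerance = 1e-6)
  # two-proportion z equals prop.test without continuity correction
  oracle <- suppressWarnings(
    prop.test(c(3, 2), c(5, 5), correct = FALSE)$p.value)
  expect_equal(cmp$two_proportion_p, oracle, tolerance = 1e-10)
  # identical inputs: no wins, null p-values
  same <- compare_methods(x, x)
  expect_equal(same$n_wins_a + same$n_wins_b, 0)
  expect_gte(same$rank_sum_p, 0.99)
  expect_gte(same$two_proportion_p, 0.99)
  # a uniform +0.1 shift wins every segment
  shift <- compare_methods(x + 0.1, x)
  expect_equal(shift$n_wins_a, 5)
  expect_error(compare_methods(1, 2), "segments")
})

test_that("accuracy report aggregates respect the bin decomposition", {
  pan <- block_panel(2, n_hap = 120, block_size = 20, gap = 8, seed = 7)
  n <- n_samples(pan); m <- n_variants(pan)
  set.seed(8)
  # noisy probabilistic predictions around the truth
  p <- array(0, dim = c(n, m, 3))
  for (k in seq_len(m)) {
    onehot <- matrix(0.05, n, 3)
    onehot[cbind(seq_len(n), pan$genotypes[, k] + 1L)] <- 0.9
    p[, k, ] <- onehot + matrix(runif(n * 3, 0, 0.05), n, 3)
  }
  p <- p / array(rep(p[, , 1] + p[, , 2] + p[, , 3], 3), dim(p))
  gp <- genotype_probabilities(p, pan$variants, pan$sample_ids)
  rep <- accuracy_report(gp, pan)
  pv <- tidy(rep)
  expect_equal(nrow(pv), m)
  # overall mean r2 equals the count-weighted combination of bin means
  bb <- dplyr::filter(rep$by_bin, !is.nan(mean_r2))
  w <- bb$n - bb$n_undefined_r2
  expect_equal(glance(rep)$mean_r2,
               sum(bb$mean_r2 * w) / sum(w), tolerance = 1e-12)
  # determinism
  rep2 <- accuracy_report(gp, pan)
  expect_identical(rep$per_variant, rep2$per_variant)
})
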