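test_that("focal loss evaluates its closed form and reduces to cross-entropy", {
  # frozen hand evaluation: -0.25 * (1-0.9)^2 * log(0.9)
  expect_equal(focal_loss(0.9, 1, alpha_t = 0.25, gamma = 2),
               2.6340129e-4, tolerance = 1e-6)
  expect_equal(focal_loss(1, 1, alpha_t = 1, gamma = 2), 0,
               tolerance = 1e-6)
  expect_error(focal_loss(0.5, 1, gamma = -1), "gamma")
  set.seed(3)
  p <- runif(1000); x <- rbinom(1000, 1, 0.5)
  bce <- -sum(x * log(pmax(p, 1e-7)) + (1 - x) * log(pmax(1 - p, 1e-7)))
  expect_lt(abs(focal_loss(p, x, alpha_t = 1, gamma = 0) - bce), 1e-9)
})

test_that("focal loss is monotone in p and gamma acts as a down-weight", {
  p <- seq(0.01, 0.99, by = 0.01)
  l1 <- focal_loss(p, rep(1, length(p)), 1, 2, reduce = "none")
  expect_true(all(diff(l1) < 0))                     # x = 1: non-increasing
  l0 <- focal_loss(p, rep(0, length(p)), 1, 2, reduce = "none")
  expect_true(all(diff(l0) > 0))                     # x = 0: non-decreasing
  # increasing gamma never increases the loss of a well-classified node
  well <- 0.8                                        # truth class prob > 0.5
  g <- c(0, 0.5, 1, 2, 5)
  ls <- vapply(g, function(gg) focal_loss(well, 1, 1, gg), numeric(1))
  expect_true(all(diff(ls) <= 0))
})

test_that("sparsity penalty is a batch-summed Bernoulli KL", {
  expect_equal(sparsity_penalty(0.1, rep(0.1, 7)), 0)
  expect_equal(sparsity_penalty(0.1, 0.2), 0.03669001, tolerance = 1e-4)
  set.seed(4)
  expect_true(all(replicate(20, sparsity_penalty(runif(1, 0.01, 0.99),
                                                 runif(5, 0.01, 0.99))) >= 0))
  expect_error(sparsity_penalty(0, 0.5), "rho")
  expect_error(sparsity_penalty(1.5, 0.5), "rho")
})

test_that("total loss assembles focal + beta*S + lambda1*L1 + lambda2*L2", {
  set.seed(5)
  out <- matrix(runif(40), 4)
  truth <- matrix(rbinom(40, 1, 0.4), 4)
  W <- list(matrix(rnorm(12), 3), matrix(rnorm(8), 4))
  sp0 <- dae_spec(lambda1 = 0, lambda2 = 0, beta = 0, gamma = 1.5)
  expect_equal(total_loss(out, truth, sp0, W, rho_hat = 0.3)$total,
               total_loss(out, truth, sp0, W, rho_hat = 0.3)$focal)
  sp <- dae_spec(lambda1 = 0.01, lambda2 = 0.1, beta = 0.5, rho = 0.1,
                 gamma = 2)
  lt <- total_loss(out, truth, sp, W, rho_hat = c(0.2, 0.3))
  expect_equal(lt$total,
               lt$focal + 0.5 * lt$sparsity + 0.01 * lt$l1 + 0.1 * lt$l2,
               tolerance = 1e-12)
  expect_equal(lt$sparsity, sparsity_penalty(0.1, c(0.2, 0.3)))
  expect_equal(lt$l1, sum(abs(W[[1]])) + sum(abs(W[[2]])))
  expect_equal(lt$l2, sum(W[[1]]^2) + sum(W[[2]]^2))
  # ridge convention: doubling weights with outputs held fixed scales the
  # L2 contribution by 4 and the L1 contribution by 2
  sp2 <- dae_spec(lambda1 = 0, lambda2 = 0.1, beta = 0, gamma = 2)
  l_a <- total_loss(out, truth, sp2, W)
  l_b <- total_loss(out, truth, sp2, lapply(W, function(w) 2 * w))
  expect_equal(l_b$total - l_b$focal, 4 * (l_a$total - l_a$focal))
  expect_error(total_loss(out[, -1], truth, sp, W), "mismatch")
})

test_that("total loss is permutation-equivariant over variants", {
  pan <- block_panel(1, n_hap = 40, block_size = 10, seed = 6)
  truth <- encode_genotypes(pan)
  set.seed(7)
  out <- matrix(runif(length(truth)), nrow(truth))
  sp <- dae_spec(gamma = 2)
  perm <- sample(10)
  cols <- as.vector(rbind(2 * perm - 1, 2 * perm))
  l1 <- total_loss(out, truth, sp, list(), rho_hat = NULL)
  l2 <- total_loss(out[, cols], truth[, cols], sp, list(), rho_hat = NULL)
  expect_equal(l1$total, l2$total)
})

test_that("class-frequency alpha weights match their definition", {
  truth <- rbind(c(1, 0), c(1, 1), c(0, 1), c(1, 0))
  a <- focal_alpha(truth)                 # col freqs: 0.75, 0.5
  expect_equal(a[, 1], c(0.75, 0.75, 0.25, 0.75))
  expect_equal(a[, 2], c(0.5, 0.5, 0.5, 0.5))
  expect_equal(focal_alpha(truth, "inverse"), 1 - a)
})
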