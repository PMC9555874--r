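# Brute-force window-correlation oracle: all pairs within the window, on
# alt-dosage vectors, |r| thresholded.
brute_pairs <- function(g, B, thr) {
  m <- ncol(g)
  out <- list()
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):min(i + B, m)) {
      r <- suppressWarnings(cor(g[, i], g[, j]))
      if (!is.na(r) && abs(r) >= thr) {
        out[[length(out) + 1]] <- c(i, j, r)
      }
    }
  }
  do.call(rbind, out)
}

brute_box_counts <- function(pairs, n, B) {
  counts <- integer(n)
  for (k in seq_len(n)) {
    lo <- k - B; hi <- k + B
    counts[k] <- sum(pairs[, 1] >= lo & pairs[, 2] <= hi)
  }
  counts
}

test_that("windowed correlations keep perfect LD and drop independence", {
  set.seed(5)
  n <- 1000
  g <- cbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.3))
  g <- cbind(g, g[, 1])        # duplicated column: perfect LD with col 1
  pan <- genotype_panel(g, tibble::tibble(chrom = "1", pos = 1:3 * 10L,
                                          ref = "A", alt = "G"))
  prs <- windowed_thresholded_correlation(pan, tiling_config(box_halfwidth = 5))
  dup <- dplyr::filter(prs, i == 1, j == 3)
  expect_equal(dup$r, 1)
  # two independently simulated variants stay uncorrelated
  expect_false(any(prs$i == 1 & prs$j == 2))
})

test_that("windowed correlations and box counts match brute-force oracles", {
  pan <- block_panel(3, n_hap = 120, block_size = 12, gap = 6,
                     rare_fraction = 0, seed = 21)
  cfg <- tiling_config(box_halfwidth = 8, maf_min = 0)
  prs <- windowed_thresholded_correlation(pan, cfg)
  oracle <- brute_pairs(pan$genotypes, 8, 0.45)
  expect_equal(nrow(prs), nrow(oracle))
  expect_equal(as.matrix(prs), unname(oracle), ignore_attr = TRUE)
  counts <- box_counts(prs, n_variants(pan), cfg)
  expect_equal(counts, brute_box_counts(oracle, n_variants(pan), 8))
})

test_that("box counts are zero without LD and combinatorial inside a block", {
  cfg <- tiling_config(box_halfwidth = 20)
  empty <- tibble::tibble(i = integer(0), j = integer(0), r = numeric(0))
  expect_equal(box_counts(empty, 10, cfg), rep(0L, 10))
  # perfect-LD block of b SNPs well inside the window: b*(b-1)/2 pairs
  b <- 6
  offset <- 30   # block occupies indices 31..36 of 70
  pairs <- tidyr::expand_grid(i = 1:b, j = 1:b) |>
    dplyr::filter(i < j) |>
    dplyr::mutate(i = i + offset, j = j + offset, r = 1)
  counts <- box_counts(pairs, 70, cfg)
  expect_equal(counts[offset + seq_len(b)], rep(b * (b - 1) / 2, b))
})

test_that("segment boundaries split at hotspot gaps and cover all variants", {
  pan <- block_panel(2, n_hap = 200, block_size = 40, gap = 15, seed = 31)
  segs <- tile_genome(pan, toy_tiling_config())
  expect_equal(nrow(segs), 2)
  truth <- attr(pan, "truth")$block_bounds
  # the split lands inside the LD-free gap between the generated blocks
  expect_gt(segs$core_end[1], truth$start[1])
  expect_lt(segs$core_start[2], truth$end[2] + 1)
  expect_true(segs$start[2] > truth$end[1] - 15 &&
                segs$end[1] < truth$start[2] + 15)
  # coverage invariant
  covered <- unlist(purrr::map2(segs$start, segs$end, seq))
  expect_setequal(unique(covered), seq_len(n_variants(pan)))
})

test_that("monotone box counts give a single segment", {
  segs <- segment_boundaries(seq_len(50), tiling_config())
  expect_equal(nrow(segs), 1)
  expect_equal(c(segs$start, segs$end), c(1, 50))
})

test_that("oversize segments split into fixed overlapping windows", {
  cfg <- tiling_config()
  seg6000 <- tibble::tibble(segment_id = 1L, start = 1L, end = 6000L,
                            core_start = 1L, core_end = 6000L,
                            origin = "independent")
  out <- enforce_max_size(seg6000, rep(1L, 6000), cfg)
  expect_equal(nrow(out), 1)
  expect_equal(out$origin, "independent")

  seg9500 <- dplyr::mutate(seg6000, end = 9500L, core_end = 9500L)
  out <- enforce_max_size(seg9500, rep(1L, 9500), cfg)
  expect_equal(out$start, c(1L, 3501L))
  expect_equal(out$end, c(6000L, 9500L))
  expect_equal(unique(out$origin), "size_split")
  # the two windows overlap by exactly split_overlap_snps
  expect_equal(out$end[1] - out$start[2] + 1L, 2500L)
})

test_that("no segment exceeds the maximum size on randomized inputs", {
  set.seed(77)
  for (rep in 1:5) {
    n <- sample(7000:20000, 1)
    counts <- as.integer(round(runif(n, 0, 50)))
    segs <- segment_boundaries(counts, tiling_config())
    segs <- enforce_max_size(segs, counts, tiling_config())
    expect_true(all(segs$end - segs$start + 1 <= 6000))
    covered <- unique(unlist(purrr::map2(segs$start, segs$end, seq)))
    expect_setequal(covered, seq_len(n))
  }
})

test_that("tiling is deterministic and invariant to sample order", {
  pan <- block_panel(3, seed = 41)
  cfg <- toy_tiling_config()
  s1 <- tile_genome(pan, cfg)
  s2 <- tile_genome(pan, cfg)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  perm <- sample(n_samples(pan))
  s3 <- tile_genome(subset_panel(pan, samples = perm), cfg)
  expect_identical(as.data.frame(s1), as.data.frame(s3))
})

test_that("rare variants join the segment of their nearest common variant", {
  pan <- block_panel(2, n_hap = 200, block_size = 30, gap = 12,
                     rare_fraction = 0.5, seed = 51)
  segs <- tile_genome(pan, toy_tiling_config())
  # every variant, rare included, is inside at least one segment
  covered <- unlist(purrr::map2(segs$start, segs$end, seq))
  expect_setequal(unique(covered), seq_len(n_variants(pan)))
  # cores are disjoint
  cores <- unlist(purrr::map2(segs$core_start, segs$core_end, seq))
  expect_equal(anyDuplicated(cores), 0)
})
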