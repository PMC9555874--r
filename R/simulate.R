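#' Generate a synthetic haplotype panel with block-LD structure
#'
#' Builds a diploid panel from haplotypes organized as LD blocks separated
#' by recombination-hotspot gaps, emulating the correlation structure and
#' rare-variant-heavy allele-frequency spectrum of human sequencing panels.
#'
#' Within each block, "tag" variants derive from a two-founder split of the
#' haplotype pool: an exact fraction `q` of haplotypes (drawn per block from
#' `common_maf_range`) carries one founder allele pattern, and independent
#' per-site noise at rate `(1 - sqrt(within_block_r2)) / 2` degrades the
#' pairwise correlation to the requested `within_block_r2` in expectation
#' (`r2 = 1` gives perfect LD). Interspersed rare variants are carried
#' independently at frequencies drawn from a skewed spectrum
#' (`rare_maf_sampler`), so each block mixes strong LD with abundant
#' low-frequency variation. Gap variants between blocks are mutually
#' independent common variants — LD-free hotspot regions.
#'
#' @param n_haplotypes even number of haplotypes; samples = half of it.
#' @param blocks list of block descriptors, each a list with `n_variants`,
#'   `within_block_r2` (in `[0, 1]`), and optionally `rare_fraction`
#'   (default 0.4, fraction of block variants that are independent rare
#'   sites).
#' @param hotspot_gap_variants independent variants inserted between
#'   consecutive blocks (default 20).
#' @param seed integer seed.
#' @param common_maf_range range the per-block tag-variant frequency is
#'   drawn from (default `c(0.15, 0.5)`).
#' @param rare_maf_sampler function(n) returning n rare-variant MAFs;
#'   default draws from Beta(0.4, 8) truncated to `[0.001, 0.05]`, a
#'   rare-skewed spectrum.
#' @param chrom chromosome label (default `"1"`).
#' @param spacing_bp base-pair spacing between adjacent variants
#'   (default 1000).
#' @return a [genotype_panel()] with haplotypes attached; attribute
#'   `truth` is a list with `block_bounds` (tibble: block, start, end
#'   variant indices), `target_maf`, and `variant_role`
#'   (`"tag"`, `"rare"`, `"gap"`).
#' @export
generate_panel <- function(n_haplotypes, blocks,
                           hotspot_gap_variants = 20, seed = 1L,
                           common_maf_range = c(0.15, 0.5),
                           rare_maf_sampler = NULL, chrom = "1",
                           spacing_bp = 1000) {
  stopifnot(n_haplotypes %% 2 == 0, n_haplotypes >= 4, length(blocks) >= 1)
  set.seed(seed)
  if (is.null(rare_maf_sampler)) {
    rare_maf_sampler <- function(n) {
      pmin(pmax(stats::rbeta(n, 0.4, 8) * 0.5, 0.001), 0.05)
    }
  }
  H <- n_haplotypes
  cols <- list(); roles <- character(0); target <- numeric(0)
  bounds <- list()
  pos_at <- 0L
  add_col <- function(col) cols[[length(cols) + 1L]] <<- col

  indep_variant <- function(f) {
    # exact carrier count keeps the realized frequency tight to target
    k <- round(f * H)
    k <- max(min(k, H), 0L)
    col <- integer(H)
    if (k > 0) col[sample.int(H, k)] <- 1L
    col
  }

  for (bidx in seq_along(blocks)) {
    bl <- blocks[[bidx]]
    r2 <- bl$within_block_r2
    if (r2 < 0 || r2 > 1) stop("within_block_r2 must lie in [0, 1]")
    rare_frac <- bl$rare_fraction %||% 0.4
    nv <- bl$n_variants
    eps_noise <- (1 - sqrt(r2)) / 2
    q <- stats::runif(1, common_maf_range[1], common_maf_range[2])
    k <- max(2L, min(H - 2L, round(q * H)))
    z <- integer(H); z[sample.int(H, k)] <- 1L   # founder membership
    n_rare <- round(rare_frac * nv)
    is_rare <- rep(FALSE, nv)
    if (n_rare > 0) is_rare[sample.int(nv, n_rare)] <- TRUE
    start_idx <- length(cols) + 1L
    for (v in seq_len(nv)) {
      if (is_rare[v]) {
        f <- rare_maf_sampler(1)
        add_col(indep_variant(f))
        roles <- c(roles, "rare"); target <- c(target, f)
      } else {
        col <- z
        if (eps_noise > 0) {
          flip <- stats::runif(H) < eps_noise
          col[flip] <- 1L - col[flip]
        }
        add_col(col)
        roles <- c(roles, "tag")
        target <- c(target, min(q * (1 - 2 * eps_noise) + eps_noise,
                                1 - (q * (1 - 2 * eps_noise) + eps_noise)))
      }
    }
    bounds[[bidx]] <- tibble::tibble(block = bidx, start = start_idx,
                                     end = length(cols))
    if (bidx < length(blocks)) {
      for (v in seq_len(hotspot_gap_variants)) {
        f <- stats::runif(1, 0.1, 0.5)
        add_col(indep_variant(f))
        roles <- c(roles, "gap"); target <- c(target, f)
      }
    }
  }
  hap <- do.call(cbind, cols)
  m <- ncol(hap)
  n <- H %/% 2L
  h1 <- hap[seq(1L, H, by = 2L), , drop = FALSE]
  h2 <- hap[seq(2L, H, by = 2L), , drop = FALSE]
  g <- h1 + h2
  hap_paired <- matrix(0L, H, m)
  hap_paired[seq(1L, H, by = 2L), ] <- h1
  hap_paired[seq(2L, H, by = 2L), ] <- h2
  variants <- tibble::tibble(
    chrom = chrom, pos = as.integer(seq_len(m)) * as.integer(spacing_bp),
    ref = "A", alt = "G")
  panel <- genotype_panel(g, variants, haplotypes = hap_paired)
  attr(panel, "truth") <- list(
    block_bounds = dplyr::bind_rows(bounds),
    target_maf = target, variant_role = roles)
  panel
}

#' Mask a panel down to an array-like marker subset
#'
#' Emulates genotyping-array data: only a subset of sites stays observed,
#' all other genotypes become missing. Fraction-based selection is biased
#' toward common variants (selection weight proportional to MAF), as array
#' designs tag common SNPs.
#'
#' @param panel a [genotype_panel()].
#' @param observed_fraction fraction of variants to keep observed, in
#'   `(0, 1]`; ignored when `marker_positions` is given.
#' @param marker_positions integer vector of `pos` values to keep observed.
#' @param seed integer seed for the fraction-based draw.
#' @return a [genotype_panel()] copy with non-selected variants set to
#'   missing; attribute `observed_index` holds the selected variant
#'   indices.
#' @export
array_mask <- function(panel, observed_fraction = NULL,
                       marker_positions = NULL, seed = 1L) {
  m <- n_variants(panel)
  if (!is.null(marker_positions)) {
    sel <- which(panel$variants$pos %in% marker_positions)
  } else {
    stopifnot(observed_fraction > 0, observed_fraction <= 1)
    k <- max(1L, round(observed_fraction * m))
    if (k >= m) {
      sel <- seq_len(m)
    } else {
      set.seed(seed)
      w <- maf(panel)
      w[is.nan(w) | w <= 0] <- 1e-6
      sel <- sample.int(m, k, prob = w)
    }
  }
  if (length(sel) == 0) stop("array_mask: empty marker selection")
  g <- panel$genotypes
  g[, setdiff(seq_len(m), sel)] <- NA_integer_
  out <- genotype_panel(g, panel$variants, panel$sample_ids)
  attr(out, "observed_index") <- sort(sel)
  out
}

#' Generate a piecewise-constant-rate genetic map for a panel
#'
#' Background recombination at `background_cM_per_Mb` with elevated rate
#' around each hotspot position, integrated to a piecewise-linear
#' cumulative-cM map over the panel's variant positions.
#'
#' @param panel a [genotype_panel()] (single chromosome).
#' @param hotspot_positions bp positions of hotspot centers (within the
#'   panel's span; may be empty).
#' @param background_cM_per_Mb background rate (>= 0), default 1.
#' @param hotspot_intensity rate multiplier inside hotspots (>= 0),
#'   default 50.
#' @param hotspot_width_bp width of each hotspot interval (default 2000).
#' @return a [genetic_map()] tibble over the panel's variant positions.
#' @export
generate_genetic_map <- function(panel, hotspot_positions = integer(0),
                                 background_cM_per_Mb = 1,
                                 hotspot_intensity = 50,
                                 hotspot_width_bp = 2000) {
  if (background_cM_per_Mb < 0 || hotspot_intensity < 0) {
    stop("rates must be non-negative")
  }
  pos <- panel$variants$pos
  if (length(hotspot_positions) > 0 &&
      (min(hotspot_positions) < min(pos) ||
       max(hotspot_positions) > max(pos))) {
    stop("hotspot positions outside panel span")
  }
  rate <- rep(background_cM_per_Mb, length(pos))   # cM/Mb on [pos_k, pos_k+1)
  for (h in hotspot_positions) {
    inside <- pos >= h - hotspot_width_bp / 2 & pos <= h + hotspot_width_bp / 2
    rate[inside] <- background_cM_per_Mb * hotspot_intensity
  }
  gaps_mb <- diff(pos) / 1e6
  cm <- c(0, cumsum(rate[-length(rate)] * gaps_mb))
  genetic_map(tibble::tibble(chrom = panel$variants$chrom[1],
                             pos = pos, cM = cm))
}
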