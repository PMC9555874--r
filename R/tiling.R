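#' Tiling configuration
#'
#' Parameters controlling the segmentation of a chromosome into
#' approximately independent genomic segments at recombination hotspots.
#'
#' @param corr_threshold absolute pairwise-correlation threshold for a SNP
#'   pair to count as being in LD (default 0.45).
#' @param box_halfwidth window half-width in common SNPs for pairwise
#'   correlations and box counts (default 500).
#' @param maf_min minimum minor allele frequency for a variant to count as
#'   common (default 0.005); rarer variants are excluded from boundary
#'   detection but still assigned to segments.
#' @param max_segment_snps maximum variants per segment/autoencoder
#'   (default 6000).
#' @param split_overlap_snps overlap between fixed-size windows when an
#'   oversize segment has to be sliced (default 2500).
#' @param smooth_width width (SNPs) of the centered moving average applied
#'   to box counts before local-minimum detection (default 11).
#' @param flank_frac a weak-LD flank extends outward from a hotspot minimum
#'   while smoothed box counts stay below this fraction of the adjacent
#'   core's peak count (default 0.10).
#' @param hotspot_frac prominence rule: a local box-count minimum counts as
#'   a recombination hotspot only when its smoothed count falls below this
#'   fraction of the smaller of the two adjacent region peaks (default
#'   0.25). Shallow within-block wobbles are thereby ignored; minima closer
#'   than `box_halfwidth` SNPs are merged, keeping the deeper one.
#' @return a list of class `tiling_config`.
#' @export
tiling_config <- function(corr_threshold = 0.45, box_halfwidth = 500,
                          maf_min = 0.005, max_segment_snps = 6000,
                          split_overlap_snps = 2500, smooth_width = 11,
                          flank_frac = 0.10, hotspot_frac = 0.25) {
  stopifnot(corr_threshold > 0, corr_threshold < 1,
            box_halfwidth >= 1, maf_min >= 0,
            split_overlap_snps < max_segment_snps,
            smooth_width >= 1, flank_frac > 0, flank_frac < 1,
            hotspot_frac > 0, hotspot_frac < 1)
  structure(list(corr_threshold = corr_threshold,
                 box_halfwidth = as.integer(box_halfwidth),
                 maf_min = maf_min,
                 max_segment_snps = as.integer(max_segment_snps),
                 split_overlap_snps = as.integer(split_overlap_snps),
                 smooth_width = as.integer(smooth_width),
                 flank_frac = flank_frac,
                 hotspot_frac = hotspot_frac),
            class = "tiling_config")
}

#' Windowed, thresholded pairwise SNP correlations
#'
#' Computes Pearson correlations of alternate-allele dosage vectors for all
#' SNP pairs at most `box_halfwidth` apart, on samples non-missing at both
#' sites, and keeps pairs with `|r| >= corr_threshold`. The threshold is
#' applied to `|r|`: LD strength, not direction. The panel should already be
#' restricted to common variants (see [tile_genome()]).
#'
#' @param panel a [genotype_panel()] (common variants only).
#' @param cfg a [tiling_config()].
#' @return tibble with columns `i`, `j` (`i < j`, column indices into the
#'   panel) and `r`; zero-variance variants are excluded and reported in the
#'   `excluded` attribute.
#' @export
windowed_thresholded_correlation <- function(panel, cfg = tiling_config()) {
  g <- panel$genotypes
  m <- ncol(g)
  B <- cfg$box_halfwidth
  v <- apply(g, 2, stats::var, na.rm = TRUE)
  excluded <- which(is.na(v) | v == 0)
  if (length(excluded) > 0) {
    message("windowed correlation: ", length(excluded),
            " zero-variance variant(s) excluded from pairing")
  }
  res_i <- integer(0); res_j <- integer(0); res_r <- numeric(0)
  if (m >= 2) {
    if (!anyNA(g)) {
      z <- scale(g)                       # zero-variance cols become NaN
      n <- nrow(g)
      for (d in seq_len(min(B, m - 1))) {
        i <- seq_len(m - d); j <- i + d
        r <- colSums(z[, i, drop = FALSE] * z[, j, drop = FALSE]) / (n - 1)
        keep <- !is.na(r) & abs(r) >= cfg$corr_threshold
        res_i <- c(res_i, i[keep]); res_j <- c(res_j, j[keep])
        res_r <- c(res_r, r[keep])
      }
    } else {
      for (i in seq_len(m - 1)) {
        for (j in (i + 1):min(i + B, m)) {
          r <- suppressWarnings(
            stats::cor(g[, i], g[, j], use = "pairwise.complete.obs"))
          if (!is.na(r) && abs(r) >= cfg$corr_threshold) {
            res_i <- c(res_i, i); res_j <- c(res_j, j); res_r <- c(res_r, r)
          }
        }
      }
    }
  }
  out <- tibble::tibble(i = res_i, j = res_j, r = res_r)
  out <- dplyr::arrange(out, .data$i, .data$j)
  attr(out, "excluded") <- excluded
  out
}

#' Box counts of local LD strength
#'
#' For each SNP index `k`, counts retained correlation pairs `(i, j)` with
#' both endpoints inside the window `[k - box_halfwidth, k + box_halfwidth]`.
#' The count quantifies local LD strength centered at each SNP; local minima
#' mark recombination hotspots.
#'
#' @param pairs tibble from [windowed_thresholded_correlation()].
#' @param n_variants number of (common) SNPs.
#' @param cfg a [tiling_config()].
#' @return integer vector of length `n_variants`.
#' @export
box_counts <- function(pairs, n_variants, cfg = tiling_config()) {
  B <- cfg$box_halfwidth
  delta <- integer(n_variants + 1L)
  if (nrow(pairs) > 0) {
    lo <- pmax(1L, pairs$j - B)
    hi <- pmin(n_variants, pairs$i + B)
    ok <- lo <= hi
    for (t in which(ok)) {
      delta[lo[t]] <- delta[lo[t]] + 1L
      delta[hi[t] + 1L] <- delta[hi[t] + 1L] - 1L
    }
  }
  cumsum(delta[seq_len(n_variants)])
}

moving_average <- function(x, width) {
  if (width <= 1) return(as.numeric(x))
  h <- width %/% 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Keep only prominent (hotspot-like) minima: the smoothed count at the
# minimum must fall below hotspot_frac of the smaller adjacent region
# peak. Minima within one box half-width of each other merge to the
# deeper one.
filter_hotspot_minima <- function(mins, s, cfg) {
  if (length(mins) == 0) return(mins)
  n <- length(s)
  bounds <- c(1L, mins, n)
  keep <- logical(length(mins))
  for (u in seq_along(mins)) {
    peak_l <- max(s[bounds[u]:mins[u]])
    peak_r <- max(s[mins[u]:bounds[u + 2L]])
    keep[u] <- s[mins[u]] < cfg$hotspot_frac * min(peak_l, peak_r)
  }
  mins <- mins[keep]
  if (length(mins) <= 1) return(mins)
  merged <- mins[1]
  for (m in mins[-1]) {
    last <- merged[length(merged)]
    if (m - last < cfg$box_halfwidth) {
      if (s[m] < s[last]) merged[length(merged)] <- m
    } else {
      merged <- c(merged, m)
    }
  }
  merged
}

# Strict local minima of a numeric vector; plateaus collapse to their
# midpoint. Endpoints are never minima.
local_minima <- function(s) {
  r <- rle(s)
  k <- length(r$values)
  if (k < 3) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mins <- integer(0)
  for (u in 2:(k - 1)) {
    if (r$values[u] < r$values[u - 1] && r$values[u] < r$values[u + 1]) {
      mins <- c(mins, (starts[u] + ends[u]) %/% 2L)
    }
  }
  mins
}

#' Segment boundaries from box counts
#'
#' Smooths the box-count curve with a centered moving average, finds strict
#' local minima (recombination-hotspot centers), and builds one segment per
#' inter-minimum high-LD core plus its adjacent weak-LD flanks. A flank
#' extends outward from a hotspot minimum while smoothed counts stay below
#' `flank_frac` of the adjacent core's peak, so neighboring segments overlap
#' exactly on the shared weak-LD region.
#'
#' @param counts integer vector from [box_counts()].
#' @param cfg a [tiling_config()].
#' @return tibble with columns `segment_id`, `start`, `end` (1-based
#'   inclusive indices into the count vector), `core_start`, `core_end`,
#'   `origin`.
#' @export
segment_boundaries <- function(counts, cfg = tiling_config()) {
  n <- length(counts)
  stopifnot(n >= 1)
  one <- tibble::tibble(segment_id = 1L, start = 1L, end = n,
                        core_start = 1L, core_end = n,
                        origin = "independent")
  if (n < 3) return(one)
  s <- moving_average(counts, cfg$smooth_width)
  mins <- filter_hotspot_minima(local_minima(s), s, cfg)
  if (length(mins) == 0) return(one)
  K <- length(mins)
  # weak-LD run around each hotspot minimum
  core_lo <- c(1L, mins)            # core u spans (mins[u-1]..mins[u])
  core_hi <- c(mins, n)
  peak <- vapply(seq_len(K + 1),
                 function(u) max(s[core_lo[u]:core_hi[u]]), numeric(1))
  weak_lo <- integer(K); weak_hi <- integer(K)
  for (u in seq_len(K)) {
    thr <- cfg$flank_frac * min(peak[u], peak[u + 1])
    lo <- mins[u]
    while (lo > 1 && s[lo - 1] < thr) lo <- lo - 1L
    hi <- mins[u]
    while (hi < n && s[hi + 1] < thr) hi <- hi + 1L
    weak_lo[u] <- lo; weak_hi[u] <- hi
  }
  seg_start <- c(1L, weak_lo)
  seg_end <- c(weak_hi, n)
  core_start <- c(1L, weak_hi + 1L)
  core_end <- c(weak_lo - 1L, n)
  tibble::tibble(
    segment_id = seq_len(K + 1),
    start = seg_start, end = seg_end,
    core_start = pmin(core_start, seg_end),
    core_end = pmax(core_end, seg_start),
    origin = "independent"
  )
}

#' Enforce a maximum segment size
#'
#' Oversize segments are first split recursively at their deepest internal
#' box-count minimum; any piece still exceeding `max_segment_snps` is sliced
#' into fixed windows of `max_segment_snps` SNPs advancing by
#' `max_segment_snps - split_overlap_snps`, the final window anchored at the
#' segment end.
#'
#' @param segments tibble from [segment_boundaries()].
#' @param counts the box-count vector the segments index into.
#' @param cfg a [tiling_config()].
#' @return segment tibble in the same coordinate space with `origin` updated
#'   to `internal_split` / `size_split` for derived pieces.
#' @export
enforce_max_size <- function(segments, counts, cfg = tiling_config()) {
  s <- moving_average(counts, cfg$smooth_width)
  maxn <- cfg$max_segment_snps
  stride <- maxn - cfg$split_overlap_snps

  split_rec <- function(start, end, origin) {
    len <- end - start + 1L
    if (len <= maxn) {
      return(tibble::tibble(start = start, end = end, origin = origin))
    }
    interior <- if (end - start >= 2L) {
      im <- local_minima(s[start:end])
      im[im > 1L & im < (end - start + 1L)] + start - 1L
    } else integer(0)
    if (length(interior) > 0) {
      cut <- interior[which.min(s[interior])]
      return(dplyr::bind_rows(
        split_rec(start, cut, "internal_split"),
        split_rec(cut, end, "internal_split")
      ))
    }
    # no internal minimum: fixed windows with the configured overlap
    starts <- integer(0)
    st <- start
    while (st + maxn - 1L < end) {
      starts <- c(starts, st)
      st <- st + stride
    }
    starts <- c(starts, end - maxn + 1L)
    tibble::tibble(start = starts, end = starts + maxn - 1L,
                   origin = "size_split")
  }

  out <- purrr::pmap_dfr(segments, function(segment_id, start, end,
                                            core_start, core_end, origin) {
    pieces <- split_rec(start, end, origin)
    pieces$core_start <- pmax(pieces$start, core_start)
    pieces$core_end <- pmin(pieces$end, core_end)
    pieces
  })
  out$segment_id <- seq_len(nrow(out))
  out[, c("segment_id", "start", "end", "core_start", "core_end", "origin")]
}

#' Tile a panel into genomic segments
#'
#' End-to-end segmentation: restricts to common variants
#' (`MAF >= maf_min`), computes windowed thresholded correlations and box
#' counts, splits at box-count minima, enforces the maximum segment size,
#' and finally maps segments back to the full variant list, assigning each
#' rare variant to the segment(s) of its nearest common variant.
#'
#' @param panel a [genotype_panel()] (one chromosome).
#' @param cfg a [tiling_config()].
#' @return tibble of class `genomic_segments` with columns `segment_id`,
#'   `start`, `end`, `core_start`, `core_end` (1-based inclusive indices
#'   into the full variant list), `n_snps`, `origin`. Attributes carry the
#'   box counts, the common-variant index, and the config.
#' @export
tile_genome <- function(panel, cfg = tiling_config()) {
  stopifnot(length(unique(panel$variants$chrom)) == 1)
  m <- n_variants(panel)
  common <- which(maf(panel) >= cfg$maf_min & !is.nan(maf(panel)))
  if (length(common) < 3) {
    segs <- tibble::tibble(segment_id = 1L, start = 1L, end = m,
                           core_start = 1L, core_end = m,
                           n_snps = m, origin = "independent")
    counts <- integer(length(common))
  } else {
    cp <- subset_panel(panel, variants = common)
    pairs <- windowed_thresholded_correlation(cp, cfg)
    counts <- box_counts(pairs, length(common), cfg)
    segs_c <- segment_boundaries(counts, cfg)
    segs_c <- enforce_max_size(segs_c, counts, cfg)
    # nearest common variant for every site, then common-space -> full-space
    pos <- panel$variants$pos
    nearest <- vapply(seq_len(m), function(k) {
      which.min(abs(pos[common] - pos[k]))
    }, integer(1))
    segs <- segs_c
    segs$start <- vapply(seq_len(nrow(segs_c)), function(u) {
      min(which(nearest >= segs_c$start[u] & nearest <= segs_c$end[u]))
    }, integer(1))
    segs$end <- vapply(seq_len(nrow(segs_c)), function(u) {
      max(which(nearest >= segs_c$start[u] & nearest <= segs_c$end[u]))
    }, integer(1))
    segs$core_start <- common[segs_c$core_start]
    segs$core_end <- common[segs_c$core_end]
    segs$n_snps <- segs$end - segs$start + 1L
    segs <- segs[, c("segment_id", "start", "end", "core_start", "core_end",
                     "n_snps", "origin")]
  }
  class(segs) <- c("genomic_segments", class(segs))
  attr(segs, "box_counts") <- counts
  attr(segs, "common_index") <- common
  attr(segs, "config") <- cfg
  segs
}

#' Write segments as BED plus a JSON sidecar
#'
#' BED intervals are 0-based half-open over physical positions; the sidecar
#' records variant-index ranges, cores, and origin tags.
#'
#' @param segments a `genomic_segments` tibble from [tile_genome()].
#' @param panel the tiled [genotype_panel()].
#' @param bed_path,json_path output paths.
#' @return `bed_path`, invisibly.
#' @export
write_segments <- function(segments, panel, bed_path,
                           json_path = paste0(bed_path, ".json")) {
  chrom <- panel$variants$chrom[1]
  pos <- panel$variants$pos
  bed <- sprintf("%s\t%d\t%d\tsegment_%d", chrom,
                 pos[segments$start] - 1L, pos[segments$end],
                 segments$segment_id)
  writeLines(bed, bed_path)
  side <- purrr::pmap(segments, function(segment_id, start, end, core_start,
                                         core_end, n_snps, origin) {
    list(segment_id = segment_id, start0 = start - 1L, end0 = end,
         core_start0 = core_start - 1L, core_end0 = core_end,
         origin = origin)
  })
  jsonlite::write_json(side, json_path, auto_unbox = TRUE)
  invisible(bed_path)
}
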