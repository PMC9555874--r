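#' Pseudo-phase an unphased panel
#'
#' Produces a haplotype matrix consistent with the genotypes: homozygous
#' sites are deterministic, heterozygous sites get a random phase drawn once
#' per sample (seeded). If the panel already carries phased haplotypes they
#' are returned unchanged.
#'
#' @param panel a [genotype_panel()]; missing genotypes are not allowed
#'   (impute or drop them first).
#' @param seed integer seed for the random phase assignment.
#' @return integer matrix of 0/1 alleles with `2 * n_samples` rows
#'   (rows `2i-1`, `2i` are sample `i`'s haplotypes).
#' @export
pseudo_phase <- function(panel, seed = 1L) {
  if (!is.null(panel$haplotypes)) return(panel$haplotypes)
  g <- panel$genotypes
  if (anyNA(g)) stop("pseudo_phase: panel contains missing genotypes")
  n <- nrow(g); m <- ncol(g)
  set.seed(seed)
  h <- matrix(0L, 2L * n, m)
  for (i in seq_len(n)) {
    gi <- g[i, ]
    h1 <- as.integer(gi == 2L)
    h2 <- h1
    het <- which(gi == 1L)
    if (length(het) > 0) {
      flip <- stats::runif(length(het)) < 0.5
      h1[het] <- as.integer(flip)
      h2[het] <- as.integer(!flip)
    }
    h[2L * i - 1L, ] <- h1
    h[2L * i, ] <- h2
  }
  h
}

# One recombinant gamete from a parent's two haplotypes. Crossover count is
# Poisson(total cM / 100); crossover points are uniform on the cM scale.
make_gamete <- function(h1, h2, cm) {
  total_cm <- cm[length(cm)] - cm[1]
  start <- sample.int(2L, 1L)
  if (total_cm <= 0) {
    return(if (start == 1L) h1 else h2)
  }
  ncx <- stats::rpois(1L, total_cm / 100)
  if (ncx == 0L) {
    return(if (start == 1L) h1 else h2)
  }
  cuts <- sort(stats::runif(ncx, cm[1], cm[length(cm)]))
  # number of crossovers to the left of a site flips the strand
  k <- findInterval(cm, cuts)
  ifelse((k %% 2L) == 0L, if (start == 1L) h1 else h2,
         if (start == 1L) h2 else h1)
}

#' Simulate offspring genomes by recombination
#'
#' Expands a training panel with simulated offspring: each offspring draws
#' two distinct parents uniformly; each transmitted gamete is a recombinant
#' mosaic of that parent's two (pseudo-phased) haplotypes with a crossover
#' count per chromosome of Poisson(total cM / 100) and crossover positions
#' uniform on the genetic-map (cM) scale — no interference. Offspring
#' genotypes are returned unphased.
#'
#' @param panel parental [genotype_panel()] (>= 2 samples, no missing
#'   genotypes).
#' @param map a [genetic_map()] covering the panel's chromosome(s).
#' @param n_offspring number of offspring genomes to simulate (>= 1).
#' @param seed integer seed; also used for pseudo-phasing when the panel is
#'   unphased.
#' @return a [genotype_panel()] of `n_offspring` samples named
#'   `offspring_1..n`, carrying its phased haplotypes.
#' @export
simulate_offspring <- function(panel, map, n_offspring, seed = 1L) {
  if (n_offspring < 1) stop("n_offspring must be >= 1")
  if (nrow(map) == 0) stop("empty genetic map")
  if (n_samples(panel) < 2) stop("need >= 2 parents")
  hap <- pseudo_phase(panel, seed = seed)
  set.seed(seed + 1L)
  chroms <- unique(panel$variants$chrom)
  cm <- numeric(n_variants(panel))
  for (ch in chroms) {
    sel <- panel$variants$chrom == ch
    cm[sel] <- interp_cM(map, ch, panel$variants$pos[sel])
  }
  n_par <- n_samples(panel)
  m <- n_variants(panel)
  g <- matrix(0L, n_offspring, m)
  hout <- matrix(0L, 2L * n_offspring, m)
  for (o in seq_len(n_offspring)) {
    parents <- sample.int(n_par, 2L)              # without replacement
    gam <- matrix(0L, 2L, m)
    for (k in 1:2) {
      p <- parents[k]
      for (ch in chroms) {
        sel <- panel$variants$chrom == ch
        gam[k, sel] <- make_gamete(hap[2L * p - 1L, sel],
                                   hap[2L * p, sel], cm[sel])
      }
    }
    hout[2L * o - 1L, ] <- gam[1L, ]
    hout[2L * o, ] <- gam[2L, ]
    g[o, ] <- gam[1L, ] + gam[2L, ]
  }
  genotype_panel(g, panel$variants,
                 sample_ids = paste0("offspring_", seq_len(n_offspring)),
                 haplotypes = hout)
}

#' Augment a panel with simulated offspring
#'
#' Convenience wrapper: simulates `n_offspring` genomes and merges them with
#' the original panel.
#'
#' @inheritParams simulate_offspring
#' @return merged [genotype_panel()].
#' @export
augment_panel <- function(panel, map, n_offspring, seed = 1L) {
  off <- simulate_offspring(panel, map, n_offspring, seed = seed)
  if (is.null(panel$haplotypes)) off$haplotypes <- NULL
  merge_panels(panel, off)
}
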