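#' Construct a genotype panel
#'
#' A genotype panel holds unphased diploid genotypes for a set of samples at
#' bi-allelic SNPs. Genotypes are stored as alternate-allele counts: 0
#' (hom-ref), 1 (het), 2 (hom-alt), `NA` (missing). Variant metadata travels
#' as a tibble with one row per site.
#'
#' @param genotypes integer matrix, samples in rows, variants in columns,
#'   values in `{0, 1, 2, NA}`.
#' @param variants data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; one row per genotype column. Positions must be strictly
#'   increasing within a chromosome and alleles single-base (bi-allelic SNPs
#'   only).
#' @param sample_ids character vector, one id per genotype row.
#' @param haplotypes optional phased haplotype matrix (2·samples rows,
#'   variants columns, values 0/1) when phase is known, e.g. from the
#'   synthetic generator. Row `2i-1` and `2i` are the two haplotypes of
#'   sample `i`.
#'
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(genotypes, variants, sample_ids = NULL,
                           haplotypes = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  variants <- tibble::as_tibble(variants)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  if (ncol(genotypes) != nrow(variants)) {
    stop("genotype columns (", ncol(genotypes), ") != variant rows (",
         nrow(variants), ")")
  }
  bad <- !(genotypes %in% c(0L, 1L, 2L) | is.na(genotypes))
  if (any(bad)) stop("genotype values must be 0, 1, 2 or NA")
  ok_snp <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
    variants$ref != variants$alt
  if (!all(ok_snp)) {
    stop("non-bi-allelic-SNP record(s) at row(s): ",
         paste(utils::head(which(!ok_snp), 5), collapse = ", "))
  }
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("positions not strictly increasing on chromosome ", ch)
    }
  }
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(genotypes)))
  stopifnot(length(sample_ids) == nrow(genotypes))
  if (!is.null(haplotypes)) {
    haplotypes <- as.matrix(haplotypes)
    storage.mode(haplotypes) <- "integer"
    stopifnot(nrow(haplotypes) == 2L * nrow(genotypes),
              ncol(haplotypes) == ncol(genotypes))
  }
  structure(
    list(sample_ids = as.character(sample_ids), variants = variants,
         genotypes = genotypes, haplotypes = haplotypes),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", n_samples(x), " samples x ", n_variants(x),
      " variants\n", sep = "")
  miss <- mean(is.na(x$genotypes))
  cat("  chrom(s): ", paste(unique(x$variants$chrom), collapse = ", "),
      "; missing: ", sprintf("%.1f%%", 100 * miss),
      if (!is.null(x$haplotypes)) "; phased haplotypes attached" else "",
      "\n", sep = "")
  invisible(x)
}

#' @export
#' @rdname genotype_panel
n_samples <- function(panel) nrow(panel$genotypes)

#' @export
#' @rdname genotype_panel
n_variants <- function(panel) ncol(panel$genotypes)

#' Minor and alternate allele frequencies of a panel
#'
#' Computed over non-missing calls. `alt_freq()` is the alternate-allele
#' frequency in `[0, 1]`; `maf()` folds it into `[0, 0.5]`.
#'
#' @param panel a [genotype_panel()].
#' @return numeric vector, one value per variant (`NaN` where every call is
#'   missing).
#' @export
alt_freq <- function(panel) {
  colMeans(panel$genotypes, na.rm = TRUE) / 2
}

#' @rdname alt_freq
#' @export
maf <- function(panel) {
  f <- alt_freq(panel)
  pmin(f, 1 - f)
}

#' Subset a panel by variant index and/or sample index
#'
#' @param panel a [genotype_panel()].
#' @param variants integer indices of variants to keep (default all).
#' @param samples integer indices of samples to keep (default all).
#' @return a [genotype_panel()].
#' @export
subset_panel <- function(panel, variants = NULL, samples = NULL) {
  vi <- if (is.null(variants)) seq_len(n_variants(panel)) else variants
  si <- if (is.null(samples)) seq_len(n_samples(panel)) else samples
  hap <- panel$haplotypes
  if (!is.null(hap)) {
    hrows <- as.vector(rbind(2L * si - 1L, 2L * si))
    hap <- hap[hrows, vi, drop = FALSE]
  }
  genotype_panel(panel$genotypes[si, vi, drop = FALSE],
                 panel$variants[vi, , drop = FALSE],
                 panel$sample_ids[si], haplotypes = hap)
}

#' Concatenate two panels sample-wise
#'
#' Both panels must carry identical variant lists. Duplicate sample ids in
#' `b` are disambiguated with a numeric suffix.
#'
#' @param a,b [genotype_panel()] objects over the same variants.
#' @return a [genotype_panel()] with `n_samples(a) + n_samples(b)` samples.
#' @export
merge_panels <- function(a, b) {
  if (n_samples(b) == 0L) return(a)
  if (!identical(dim(a$variants), dim(b$variants)) ||
      !all(a$variants$chrom == b$variants$chrom) ||
      !all(a$variants$pos == b$variants$pos) ||
      !all(a$variants$ref == b$variants$ref) ||
      !all(a$variants$alt == b$variants$alt)) {
    stop("panels have different variant lists; cannot merge")
  }
  ids <- c(a$sample_ids, b$sample_ids)
  dup <- duplicated(ids)
  if (any(dup)) ids[dup] <- paste0(ids[dup], ".", cumsum(dup)[dup])
  hap <- NULL
  if (!is.null(a$haplotypes) && !is.null(b$haplotypes)) {
    hap <- rbind(a$haplotypes, b$haplotypes)
  }
  genotype_panel(rbind(a$genotypes, b$genotypes), a$variants, ids,
                 haplotypes = hap)
}

#' Variant table of a panel as a tibble
#'
#' Adds `maf` and `alt_freq` columns to the variant metadata.
#'
#' @param x a [genotype_panel()].
#' @param ... unused.
#' @return a tibble with one row per variant.
#' @method as_tibble genotype_panel
#' @export
as_tibble.genotype_panel <- function(x, ...) {
  dplyr::mutate(x$variants, alt_freq = alt_freq(x), maf = maf(x))
}
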