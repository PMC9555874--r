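#' Encode genotypes as allele-presence bit pairs
#'
#' Each bi-allelic site becomes two binary input nodes recording the presence
#' (1) or absence (0) of the reference and the alternate allele:
#' hom-ref -> (1,0), het -> (1,1) (either ordering of the heterozygote),
#' hom-alt -> (0,1), missing -> (0,0). The (0,0) "null" pattern doubles as
#' the masked-input state during denoising training.
#'
#' @param panel a [genotype_panel()].
#' @return numeric matrix, samples x (2 * n_variants); variant `i` occupies
#'   columns `2i-1` (ref presence) and `2i` (alt presence). Class
#'   `allele_presence`.
#' @export
encode_genotypes <- function(panel) {
  g <- panel$genotypes
  n <- nrow(g); m <- ncol(g)
  x <- matrix(0, n, 2L * m)
  ref <- !is.na(g) & g <= 1L        # ref allele present: hom-ref or het
  alt <- !is.na(g) & g >= 1L        # alt allele present: het or hom-alt
  x[, seq(1L, 2L * m, by = 2L)] <- ref + 0
  x[, seq(2L, 2L * m, by = 2L)] <- alt + 0
  structure(x, class = c("allele_presence", "matrix", "array"))
}

#' Decode allele-presence bit pairs back to genotype codes
#'
#' Inverse of [encode_genotypes()]: (1,0) -> 0, (1,1) -> 1, (0,1) -> 2,
#' (0,0) -> `NA`.
#'
#' @param x allele-presence matrix (samples x 2m, values 0/1).
#' @return integer matrix samples x m over `{0, 1, 2, NA}`.
#' @export
decode_allele_presence <- function(x) {
  m <- ncol(x) %/% 2L
  ref <- x[, seq(1L, 2L * m, by = 2L), drop = FALSE]
  alt <- x[, seq(2L, 2L * m, by = 2L), drop = FALSE]
  g <- matrix(NA_integer_, nrow(x), m)
  g[ref == 1 & alt == 0] <- 0L
  g[ref == 1 & alt == 1] <- 1L
  g[ref == 0 & alt == 1] <- 2L
  g
}

#' Convert paired allele-presence outputs to genotype class probabilities
#'
#' The autoencoder emits two sigmoid-scaled presence scores per site,
#' `p_ref` and `p_alt`. These are split into three genotype scores —
#' hom-ref: `p_ref (1 - p_alt)`, het: `p_ref p_alt`, hom-alt:
#' `(1 - p_ref) p_alt` — and normalized to sum to one. The fourth product
#' `(1 - p_ref)(1 - p_alt)` corresponds to the null (no-call) state and is
#' dropped: imputation must output a genotype. With `softmax = TRUE` the
#' three scores are passed through exp() before normalization instead of
#' being normalized proportionally.
#'
#' @param p_ref,p_alt numeric vectors (or matrices of equal shape) in
#'   `[0, 1]`.
#' @param softmax logical; apply a true softmax over the three scores
#'   instead of proportional normalization (default `FALSE`).
#' @return matrix with 3 columns (hom-ref, het, hom-alt) whose rows sum
#'   to 1; all-zero score rows fall back to the uniform (1/3, 1/3, 1/3).
#' @export
allele_outputs_to_probabilities <- function(p_ref, p_alt, softmax = FALSE) {
  if (any(p_ref < 0 | p_ref > 1 | p_alt < 0 | p_alt > 1, na.rm = TRUE)) {
    stop("allele-presence outputs must lie in [0, 1]")
  }
  s <- cbind(hom_ref = p_ref * (1 - p_alt),
             het     = p_ref * p_alt,
             hom_alt = (1 - p_ref) * p_alt)
  if (softmax) {
    s <- exp(s)
  }
  tot <- rowSums(s)
  zero <- tot <= 0
  if (any(zero)) {
    s[zero, ] <- 1 / 3
    tot[zero] <- 1
  }
  s / tot
}

#' Alternate-allele dosage from genotype probabilities
#'
#' `dosage = P(het) + 2 P(hom-alt)`, the expected alternate-allele count in
#' `[0, 2]`.
#'
#' @param probs numeric 3-vector or matrix with 3 columns
#'   (hom-ref, het, hom-alt), rows normalized.
#' @return numeric vector of dosages.
#' @export
dosage <- function(probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, ncol = 3, byrow = FALSE)
  stopifnot(ncol(probs) == 3)
  as.numeric(probs[, 2] + 2 * probs[, 3])
}

#' Genotype probability container
#'
#' Wraps a samples x variants x 3 probability array (hom-ref, het, hom-alt)
#' together with the variant table, sample ids, and a per-variant
#' `genotyped` flag marking sites passed through from the observed input
#' rather than imputed.
#'
#' @param p numeric array `n x m x 3`; each `[i, j, ]` slice sums to 1.
#' @param variants variant tibble (`chrom`, `pos`, `ref`, `alt`).
#' @param sample_ids character vector length `n`.
#' @param genotyped logical vector length `m` (default all `FALSE`).
#' @return object of class `genotype_probabilities`.
#' @export
genotype_probabilities <- function(p, variants, sample_ids,
                                   genotyped = NULL) {
  stopifnot(length(dim(p)) == 3, dim(p)[3] == 3,
            dim(p)[2] == nrow(variants), dim(p)[1] == length(sample_ids))
  sums <- p[, , 1] + p[, , 2] + p[, , 3]
  if (any(abs(sums - 1) > 1e-6)) stop("probability rows must sum to 1")
  if (is.null(genotyped)) genotyped <- rep(FALSE, nrow(variants))
  structure(list(p = p, variants = tibble::as_tibble(variants),
                 sample_ids = sample_ids, genotyped = genotyped),
            class = "genotype_probabilities")
}

#' @export
print.genotype_probabilities <- function(x, ...) {
  cat("<genotype_probabilities> ", dim(x$p)[1], " samples x ", dim(x$p)[2],
      " variants (", sum(x$genotyped), " genotyped, ",
      sum(!x$genotyped), " imputed)\n", sep = "")
  invisible(x)
}

#' Hard genotype calls from probabilities
#'
#' Argmax call per sample/variant; ties break toward the genotype with
#' fewer alternate alleles.
#'
#' @param gp a [genotype_probabilities()] object or an `n x 3` matrix.
#' @return integer matrix (or vector) of genotype codes 0/1/2.
#' @export
hard_calls <- function(gp) {
  p <- if (inherits(gp, "genotype_probabilities")) gp$p else gp
  if (length(dim(p)) == 3) {
    n <- dim(p)[1]; m <- dim(p)[2]
    out <- matrix(0L, n, m)
    for (k in seq_len(m)) {
      out[, k] <- max.col(matrix(p[, k, ], n, 3),
                          ties.method = "first") - 1L
    }
    out
  } else {
    max.col(p, ties.method = "first") - 1L
  }
}

#' Dosage matrix from genotype probabilities
#'
#' @param gp a [genotype_probabilities()] object.
#' @return numeric matrix samples x variants of alternate-allele dosages.
#' @export
dosage_matrix <- function(gp) {
  n <- dim(gp$p)[1]; m <- dim(gp$p)[2]
  matrix(gp$p[, , 2], n, m) + 2 * matrix(gp$p[, , 3], n, m)
}
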