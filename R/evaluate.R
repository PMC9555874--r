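#' Per-variant dosage r-squared
#'
#' Squared Pearson correlation of predicted and observed alternate-allele
#' dosages across samples. Undefined (`NA`) when either vector has zero
#' variance; such variants are excluded from aggregate means but counted.
#'
#' @param imputed,truth numeric dosage vectors of equal length.
#' @return scalar in `[0, 1]` or `NA`.
#' @export
per_variant_r2 <- function(imputed, truth) {
  if (length(imputed) != length(truth)) stop("length mismatch")
  ok <- !is.na(imputed) & !is.na(truth)
  if (sum(ok) < 2) return(NA_real_)
  if (stats::var(imputed[ok]) == 0 || stats::var(truth[ok]) == 0) {
    return(NA_real_)
  }
  stats::cor(imputed[ok], truth[ok])^2
}

maf_bin_breaks <- c(0.001, 0.005, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)
maf_bin_labels <- c("[0.001,0.005)", "[0.005,0.01)", "[0.01,0.05)",
                    "[0.05,0.1)", "[0.1,0.2)", "[0.2,0.3)", "[0.3,0.4)",
                    "[0.4,0.5]")

#' Assign minor-allele frequencies to evaluation bins
#'
#' The eight standard evaluation bins partition `[0.001, 0.5]`:
#' `[0.001, 0.005) [0.005, 0.01) [0.01, 0.05) [0.05, 0.1) [0.1, 0.2)
#' [0.2, 0.3) [0.3, 0.4) [0.4, 0.5]`. Bins are half-open with a closed
#' upper end on the last; MAF below 0.001 is labelled `"ultra-rare"` and
#' reported separately. MAF above 0.5 is rejected (not a minor allele).
#'
#' @param maf numeric vector in `[0, 0.5]`.
#' @return factor of bin labels with levels `ultra-rare` then the eight
#'   bins.
#' @export
maf_bin <- function(maf) {
  if (any(maf > 0.5, na.rm = TRUE)) stop("maf > 0.5 is not a minor allele")
  if (any(maf < 0, na.rm = TRUE)) stop("maf must be >= 0")
  idx <- findInterval(maf, maf_bin_breaks, rightmost.closed = TRUE)
  lab <- ifelse(idx == 0, "ultra-rare", maf_bin_labels[pmax(idx, 1)])
  factor(lab, levels = c("ultra-rare", maf_bin_labels))
}

#' Genotype concordance and macro F1
#'
#' Concordance is the fraction of non-missing truth calls matched exactly
#' by the imputed hard calls. F1 is macro-averaged over the three genotype
#' classes (hom-ref, het, hom-alt); classes absent from both truth and
#' prediction are excluded from the macro average.
#'
#' @param imputed,truth integer genotype-code vectors/matrices over
#'   `{0, 1, 2}` (truth may contain `NA`, which is skipped).
#' @return named list `concordance`, `f1`.
#' @export
concordance_and_f1 <- function(imputed, truth) {
  imputed <- as.vector(imputed); truth <- as.vector(truth)
  ok <- !is.na(truth)
  if (!any(ok)) return(list(concordance = NA_real_, f1 = NA_real_))
  imputed <- imputed[ok]; truth <- truth[ok]
  conc <- mean(imputed == truth)
  f1s <- vapply(0:2, function(cl) {
    tp <- sum(imputed == cl & truth == cl)
    fp <- sum(imputed == cl & truth != cl)
    fn <- sum(imputed != cl & truth == cl)
    if (tp + fp + fn == 0) return(NA_real_)
    if (tp == 0) return(0)
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  list(concordance = conc, f1 = mean(f1s, na.rm = TRUE))
}

#' Compare two methods' per-segment accuracies
#'
#' Counts wins by the sign of the paired difference (ties excluded), tests
#' the two metric samples with a two-sided Wilcoxon rank-sum test, and
#' compares the win fractions with a two-proportion z-test (pooled, no
#' continuity correction).
#'
#' @param metric_a,metric_b paired numeric vectors of per-segment
#'   accuracies (>= 2 segments).
#' @return tibble with `n_wins_a`, `n_wins_b`, `n_ties`, `rank_sum_p`,
#'   `two_proportion_p`.
#' @export
compare_methods <- function(metric_a, metric_b) {
  stopifnot(length(metric_a) == length(metric_b))
  if (length(metric_a) < 2) stop("need >= 2 segments to compare")
  d <- metric_a - metric_b
  wa <- sum(d > 0); wb <- sum(d < 0); ties <- sum(d == 0)
  p_rank <- suppressWarnings(
    stats::wilcox.test(metric_a, metric_b, exact = FALSE)$p.value)
  n <- length(d)
  p1 <- wa / n; p2 <- wb / n; pp <- (wa + wb) / (2 * n)
  z_den <- sqrt(2 * pp * (1 - pp) / n)
  p_prop <- if (z_den == 0) 1 else {
    2 * stats::pnorm(-abs((p1 - p2) / z_den))
  }
  tibble::tibble(n_wins_a = wa, n_wins_b = wb, n_ties = ties,
                 rank_sum_p = p_rank, two_proportion_p = p_prop)
}

#' Imputation accuracy report
#'
#' Per-variant dosage r-squared, concordance and macro F1 against a truth
#' panel, stratified by MAF bin (MAF computed on the truth panel) and
#' optionally by segment.
#'
#' @param gp imputed [genotype_probabilities()].
#' @param truth_panel ground-truth [genotype_panel()] over the same
#'   variants and samples.
#' @param segments optional `genomic_segments` tibble; adds per-segment
#'   aggregates.
#' @return list of class `accuracy_report`: `per_variant` tibble (variant,
#'   maf, maf_bin, r2, concordance, f1, genotyped), `by_bin` tibble,
#'   `by_segment` tibble (when segments given), and `summary` (one-row
#'   tibble with mean r2 and counts).
#' @export
accuracy_report <- function(gp, truth_panel, segments = NULL) {
  stopifnot(dim(gp$p)[2] == n_variants(truth_panel),
            dim(gp$p)[1] == n_samples(truth_panel))
  ds <- dosage_matrix(gp)
  calls <- hard_calls(gp)
  gt <- truth_panel$genotypes
  m <- n_variants(truth_panel)
  mafs <- maf(truth_panel)
  r2 <- vapply(seq_len(m), function(k) {
    per_variant_r2(ds[, k], as.numeric(gt[, k]))
  }, numeric(1))
  cf <- lapply(seq_len(m), function(k) {
    concordance_and_f1(calls[, k], gt[, k])
  })
  per_variant <- tibble::tibble(
    chrom = truth_panel$variants$chrom,
    pos = truth_panel$variants$pos,
    maf = mafs,
    maf_bin = maf_bin(mafs),
    r2 = r2,
    concordance = vapply(cf, `[[`, numeric(1), "concordance"),
    f1 = vapply(cf, `[[`, numeric(1), "f1"),
    genotyped = gp$genotyped
  )
  by_bin <- per_variant |>
    dplyr::group_by(.data$maf_bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_undefined_r2 = sum(is.na(.data$r2)),
      mean_r2 = mean(.data$r2, na.rm = TRUE),
      mean_concordance = mean(.data$concordance, na.rm = TRUE),
      mean_f1 = mean(.data$f1, na.rm = TRUE),
      .groups = "drop")
  by_segment <- NULL
  if (!is.null(segments)) {
    by_segment <- purrr::pmap_dfr(
      segments[, c("segment_id", "start", "end")],
      function(segment_id, start, end) {
        sub <- per_variant[start:end, ]
        tibble::tibble(segment_id = segment_id, n = nrow(sub),
                       mean_r2 = mean(sub$r2, na.rm = TRUE),
                       mean_concordance = mean(sub$concordance,
                                               na.rm = TRUE),
                       mean_f1 = mean(sub$f1, na.rm = TRUE))
      })
  }
  summary <- tibble::tibble(
    n_variants = m,
    n_undefined_r2 = sum(is.na(r2)),
    mean_r2 = mean(r2, na.rm = TRUE),
    mean_concordance = mean(per_variant$concordance, na.rm = TRUE),
    mean_f1 = mean(per_variant$f1, na.rm = TRUE))
  structure(list(per_variant = per_variant, by_bin = by_bin,
                 by_segment = by_segment, summary = summary),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report> ", x$summary$n_variants, " variants; mean r2 = ",
      signif(x$summary$mean_r2, 4), " (", x$summary$n_undefined_r2,
      " undefined), concordance = ",
      signif(x$summary$mean_concordance, 4), ", macro F1 = ",
      signif(x$summary$mean_f1, 4), "\n", sep = "")
  invisible(x)
}
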