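#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained segment autoencoder
#'
#' One row per masking/training cycle: mask rate, mean loss terms,
#' learning rate.
#'
#' @param x a `dae_fit` from [train_segment()].
#' @param ... unused.
#' @return a tibble.
#' @method tidy dae_fit
#' @export
tidy.dae_fit <- function(x, ...) x$trace

#' One-row summary of a trained segment autoencoder
#'
#' @param x a `dae_fit`.
#' @param ... unused.
#' @return one-row tibble: segment id, variants, parameters, cycles run,
#'   first/final cycle loss, early-stop flag.
#' @method glance dae_fit
#' @export
glance.dae_fit <- function(x, ...) {
  n_par <- sum(vapply(x$net$W, length, numeric(1))) +
    sum(vapply(x$net$b, length, numeric(1)))
  tibble::tibble(
    segment_id = x$segment_id,
    n_variants = nrow(x$variants),
    n_parameters = n_par,
    n_cycles = nrow(x$trace),
    first_cycle_loss = x$trace$mean_total[1],
    final_cycle_loss = utils::tail(x$trace$mean_total, 1),
    stopped_early = x$stopped_early)
}

#' Tidy an accuracy report
#'
#' @param x an `accuracy_report`.
#' @param ... unused.
#' @return the per-variant tibble.
#' @method tidy accuracy_report
#' @export
tidy.accuracy_report <- function(x, ...) x$per_variant

#' One-row summary of an accuracy report
#'
#' @param x an `accuracy_report`.
#' @param ... unused.
#' @return one-row tibble with mean r2, concordance, macro F1 and counts.
#' @method glance accuracy_report
#' @export
glance.accuracy_report <- function(x, ...) x$summary

#' Loss-trace plot for a trained autoencoder
#'
#' @param object a `dae_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot dae_fit
#' @export
autoplot.dae_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$cycle, y = .data$mean_total)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$mask_rate), alpha = 0.7) +
    ggplot2::scale_size_continuous(range = c(1, 3), name = "mask rate") +
    ggplot2::labs(x = "masking/training cycle", y = "mean total loss",
                  title = sprintf("Segment %s training trace",
                                  object$segment_id)) +
    ggplot2::theme_minimal()
}

#' Accuracy-by-MAF-bin plot
#'
#' @param object an `accuracy_report`.
#' @param metric which aggregate to plot (default `"mean_r2"`).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot accuracy_report
#' @export
autoplot.accuracy_report <- function(object, metric = "mean_r2", ...) {
  d <- dplyr::filter(object$by_bin, .data$n > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$maf_bin,
                                  y = .data[[metric]], group = 1)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "minor allele frequency bin", y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Box-count and segmentation plot
#'
#' Shows the local LD box-count curve over common-variant index with
#' segment core boundaries.
#'
#' @param object a `genomic_segments` tibble from [tile_genome()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot genomic_segments
#' @export
autoplot.genomic_segments <- function(object, ...) {
  counts <- attr(object, "box_counts")
  d <- tibble::tibble(index = seq_along(counts), count = counts)
  common <- attr(object, "common_index")
  cores <- tibble::tibble(
    x = match(object$core_start, common),
    xend = match(object$core_end, common))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$count)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = cores, ggplot2::aes(xintercept = .data$x),
                        linetype = "dashed", colour = "red", na.rm = TRUE) +
    ggplot2::labs(x = "common-variant index", y = "LD box count",
                  title = "Local LD strength and segment cores") +
    ggplot2::theme_minimal()
}
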