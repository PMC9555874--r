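#' Match observed variants against a model variant list
#'
#' Exact join on (chrom, pos, ref, alt); no strand-flip rescue is attempted
#' — mismatched alleles are dropped and counted, since silent strand errors
#' corrupt imputation. Both inputs must be position-sorted.
#'
#' @param observed_variants,model_variants variant tibbles (`chrom`, `pos`,
#'   `ref`, `alt`).
#' @return list: `map` tibble (`observed_index`, `model_index`),
#'   `n_matched`, `n_dropped`, `dropped` tibble of unmatched observed
#'   sites.
#' @export
match_variants <- function(observed_variants, model_variants) {
  for (v in list(observed_variants, model_variants)) {
    for (ch in unique(v$chrom)) {
      if (is.unsorted(v$pos[v$chrom == ch])) {
        stop("variant lists must be position-sorted")
      }
    }
  }
  obs <- dplyr::mutate(observed_variants,
                       observed_index = dplyr::row_number())
  mod <- dplyr::mutate(model_variants, model_index = dplyr::row_number())
  j <- dplyr::inner_join(obs, mod, by = c("chrom", "pos", "ref", "alt"))
  dropped <- dplyr::anti_join(obs, mod, by = c("chrom", "pos", "ref", "alt"))
  if (nrow(dropped) > 0) {
    warning(nrow(dropped), " observed site(s) not matching any model ",
            "variant (allele mismatch or absent); dropped")
  }
  list(map = j[, c("observed_index", "model_index")],
       n_matched = nrow(j), n_dropped = nrow(dropped),
       dropped = dropped[, c("chrom", "pos", "ref", "alt")])
}

#' Impute genotypes with a set of trained segment autoencoders
#'
#' Encodes the observed markers (unobserved model variants become the null
#' (0,0) input), runs every segment's network, converts the paired
#' allele-presence outputs to three-class genotype probabilities, averages
#' and renormalizes the class probabilities of variants covered by several
#' overlapping segments, and finally passes observed input genotypes
#' through to the output unchanged (flagged as genotyped). Segments with
#' zero observed variants are still imputed from the all-null input and
#' reported in the `low_confidence_segments` attribute.
#'
#' @param observed_panel [genotype_panel()] of the assayed markers; its
#'   variants must be a subset of the models' variants (exact allele
#'   match).
#' @param models a `dae_models` collection from [dae_models()] (or a bare
#'   list of [train_segment()] fits spanning one panel).
#' @param softmax passed to [allele_outputs_to_probabilities()].
#' @return a [genotype_probabilities()] over all model variants, with
#'   attributes `match` (the [match_variants()] report) and
#'   `low_confidence_segments`.
#' @export
impute <- function(observed_panel, models, softmax = FALSE) {
  if (!inherits(models, "dae_models")) models <- dae_models(models)
  mv <- models$variants
  m <- nrow(mv)
  n <- n_samples(observed_panel)
  mt <- match_variants(observed_panel$variants, mv)

  g_full <- matrix(NA_integer_, n, m)
  g_full[, mt$map$model_index] <-
    observed_panel$genotypes[, mt$map$observed_index, drop = FALSE]
  x_full <- encode_genotypes(
    genotype_panel(g_full, mv, observed_panel$sample_ids))

  acc <- array(0, dim = c(n, m, 3))
  cover <- integer(m)
  low_conf <- integer(0)
  for (fit in models$fits) {
    vi <- models$segment_index[[as.character(fit$segment_id)]]
    cols <- as.vector(rbind(2L * vi - 1L, 2L * vi))
    xin <- x_full[, cols, drop = FALSE]
    if (all(xin == 0)) low_conf <- c(low_conf, fit$segment_id)
    out <- forward_pass(fit$net, xin)
    p_ref <- out[, seq(1, ncol(out), 2), drop = FALSE]
    p_alt <- out[, seq(2, ncol(out), 2), drop = FALSE]
    probs <- allele_outputs_to_probabilities(as.vector(p_ref),
                                             as.vector(p_alt),
                                             softmax = softmax)
    pr <- array(probs, dim = c(n, length(vi), 3))
    acc[, vi, ] <- acc[, vi, , drop = FALSE] + pr
    cover[vi] <- cover[vi] + 1L
  }
  if (any(cover == 0)) {
    stop("model collection does not cover ", sum(cover == 0), " variant(s)")
  }
  cov_mat <- matrix(cover, n, m, byrow = TRUE)
  for (cl in 1:3) acc[, , cl] <- matrix(acc[, , cl], n, m) / cov_mat
  tot <- matrix(acc[, , 1], n, m) + matrix(acc[, , 2], n, m) +
    matrix(acc[, , 3], n, m)
  for (cl in 1:3) acc[, , cl] <- matrix(acc[, , cl], n, m) / tot

  # pass observed genotypes through unchanged
  genotyped <- logical(m)
  genotyped[mt$map$model_index] <- TRUE
  for (t in seq_len(nrow(mt$map))) {
    k <- mt$map$model_index[t]
    gobs <- g_full[, k]
    known <- which(!is.na(gobs))
    if (length(known) > 0) {
      onehot <- matrix(0, length(known), 3)
      onehot[cbind(seq_along(known), gobs[known] + 1L)] <- 1
      acc[known, k, ] <- onehot
    }
  }
  gp <- genotype_probabilities(acc, mv, observed_panel$sample_ids,
                               genotyped = genotyped)
  attr(gp, "match") <- mt
  attr(gp, "low_confidence_segments") <- low_conf
  gp
}

#' Bundle per-segment fits into a distributable model collection
#'
#' @param fits list of [train_segment()] results covering a panel.
#' @param segments the `genomic_segments` tibble the fits were trained on;
#'   reconstructed from the fits when omitted.
#' @return list of class `dae_models`: `fits`, `variants` (union variant
#'   table), `segment_index` (model-variant indices per segment).
#' @export
dae_models <- function(fits, segments = NULL) {
  stopifnot(length(fits) >= 1)
  all_v <- dplyr::distinct(
    dplyr::bind_rows(lapply(fits, function(f) f$variants)))
  all_v <- dplyr::arrange(all_v, .data$chrom, .data$pos)
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt)
  full_key <- key(all_v)
  seg_index <- list()
  for (f in fits) {
    seg_index[[as.character(f$segment_id)]] <-
      match(key(f$variants), full_key)
  }
  structure(list(fits = fits, variants = all_v,
                 segment_index = seg_index),
            class = "dae_models")
}

#' Save / load a model collection as plain text
#'
#' One JSON file per segment (spec, variant list, flattened weights) plus a
#' manifest JSON indexing the segments — the distributable, reference-free
#' imputation artifact.
#'
#' @param models a `dae_models` collection.
#' @param dir output directory (created if missing).
#' @return the manifest path (`save`), a `dae_models` (`load`).
#' @export
save_models <- function(models, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(models$fits))
  for (i in seq_along(models$fits)) {
    f <- models$fits[[i]]
    files[i] <- file.path(dir, sprintf("segment_%03d.json", f$segment_id))
    obj <- list(
      segment_id = f$segment_id,
      spec = unclass(f$spec),
      variants = f$variants,
      widths = f$net$widths,
      W = lapply(f$net$W, as.vector),
      b = f$net$b,
      trace = f$trace)
    jsonlite::write_json(obj, files[i], auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(package = "daeimpute",
                   n_segments = length(models$fits),
                   files = basename(files))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE)
  mpath
}

#' @rdname save_models
#' @param dir directory holding `manifest.json` and segment files.
#' @export
load_models <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  fits <- lapply(manifest$files, function(fn) {
    obj <- jsonlite::read_json(file.path(dir, fn), simplifyVector = TRUE)
    spec <- do.call(dae_spec, obj$spec)
    widths <- obj$widths
    L <- length(widths) - 1L
    # equal-length layers come back as a matrix (one row per layer)
    as_layer_list <- function(x, L) {
      if (is.matrix(x)) lapply(seq_len(L), function(l) x[l, ]) else x
    }
    Wraw <- as_layer_list(obj$W, L)
    braw <- as_layer_list(obj$b, L)
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      W[[l]] <- matrix(as.numeric(Wraw[[l]]), widths[l], widths[l + 1])
      b[[l]] <- as.numeric(braw[[l]])
    }
    net <- structure(list(W = W, b = b, widths = widths, spec = spec,
                          n_variants = widths[1] %/% 2L),
                     class = "dae_net")
    structure(list(net = net, trace = tibble::as_tibble(obj$trace),
                   stopped_early = NA,
                   variants = tibble::as_tibble(obj$variants),
                   spec = spec, schedule = NULL,
                   segment_id = obj$segment_id),
              class = "dae_fit")
  })
  dae_models(fits)
}
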