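#' Default end-to-end pipeline configuration
#'
#' All tiling and training defaults are the method's canonical values
#' (correlation threshold 0.45, 500-SNP box half-width, 6000-SNP maximum
#' segment with 2500-SNP split overlap, 80% initial masking down to five
#' unmasked variants, 500-epoch cycles, batch size 256); every field can be
#' overridden. A synthetic-panel section drives the built-in generator when
#' no input VCF is given.
#'
#' @param seed root seed; all stage randomness flows from it via fixed
#'   offsets.
#' @param ... overrides for any top-level field.
#' @return nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    vcf = NULL,
    panel = list(n_haplotypes = 1000,
                 blocks = rep(list(list(n_variants = 50,
                                        within_block_r2 = 0.9)), 4),
                 hotspot_gap_variants = 20),
    tiling = list(corr_threshold = 0.45, box_halfwidth = 500,
                  maf_min = 0.005, max_segment_snps = 6000,
                  split_overlap_snps = 2500, smooth_width = 11,
                  flank_frac = 0.10, hotspot_frac = 0.25),
    mask = list(observed_fraction = 0.05),
    spec = list(),
    schedule = list(initial_mask_rate = 0.80, min_unmasked = 5,
                    epochs_per_cycle = 500, max_epochs = 500,
                    batch_size = 256),
    grid_search = list(enabled = FALSE, n_combinations = 0),
    holdout_fraction = 0.2
  )
  ov <- list(...)
  allowed <- list(tiling = names(formals(tiling_config)),
                  spec = names(formals(dae_spec)),
                  schedule = setdiff(names(formals(training_schedule)),
                                     "seed"),
                  mask = c("observed_fraction", "marker_positions"),
                  grid_search = c("enabled", "n_combinations"))
  for (nm in names(ov)) {
    if (!nm %in% names(cfg)) stop("unknown pipeline config field: ", nm)
    if (nm %in% names(allowed)) {
      bad <- setdiff(names(ov[[nm]]), allowed[[nm]])
      if (length(bad)) stop("unknown field in '", nm, "': ", bad[1])
      cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
    } else {
      cfg[[nm]] <- ov[[nm]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

stage_seed <- function(root, stage) {
  offsets <- c(panel = 101, mask = 211, train = 307, grid = 401,
               split = 503)
  as.integer((as.numeric(root) * 1009 + offsets[[stage]]) %% 2147483647)
}

#' Run the end-to-end imputation pipeline
#'
#' Stages: synthesize (or read) a reference panel, tile it into genomic
#' segments, train one autoencoder per segment on the training samples,
#' impute array-masked held-out samples, and score them against their
#' ground truth. Artifacts (segments BED+JSON, models, imputed VCF,
#' per-variant report TSV, manifest JSON) are written under `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return list of class `pipeline_result`: `panel`, `segments`, `models`,
#'   `imputed`, `report`, `manifest_path`, invisibly writing all artifacts.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  panel <- if (!is.null(config$vcf)) {
    read_vcf(config$vcf)
  } else {
    generate_panel(config$panel$n_haplotypes, config$panel$blocks,
                   hotspot_gap_variants = config$panel$hotspot_gap_variants,
                   seed = stage_seed(config$seed, "panel"))
  }

  set.seed(stage_seed(config$seed, "split"))
  n <- n_samples(panel)
  n_hold <- max(1L, round(config$holdout_fraction * n))
  hold <- sort(sample.int(n, n_hold))
  train_idx <- setdiff(seq_len(n), hold)
  train_panel <- subset_panel(panel, samples = train_idx)
  test_panel <- subset_panel(panel, samples = hold)

  tcfg <- do.call(tiling_config, config$tiling)
  segments <- tile_genome(train_panel, tcfg)
  write_segments(segments, train_panel, file.path(out_dir, "segments.bed"))

  spec <- do.call(dae_spec, config$spec)
  sched_args <- config$schedule
  sched_args$seed <- stage_seed(config$seed, "train")
  schedule <- do.call(training_schedule, sched_args)

  grid_results <- NULL
  if (isTRUE(config$grid_search$enabled)) {
    specs <- sample_grid(config$grid_search$n_combinations,
                         seed = stage_seed(config$seed, "grid"))
    grid_results <- grid_search(train_panel, segments[1, ], specs,
                                test_panel, schedule,
                                mask_fraction = config$mask$observed_fraction)
    spec <- attr(grid_results, "best_spec")
  }

  fits <- lapply(seq_len(nrow(segments)), function(u) {
    seg <- segments[u, ]
    train_segment(train_panel, seg, spec, schedule)
  })
  models <- dae_models(fits, segments)
  save_models(models, file.path(out_dir, "models"))

  observed <- array_mask(test_panel,
                         observed_fraction = config$mask$observed_fraction,
                         seed = stage_seed(config$seed, "mask"))
  obs_idx <- attr(observed, "observed_index")
  obs_panel <- subset_panel(observed, variants = obs_idx)
  gp <- impute(obs_panel, models)
  write_vcf(gp, file.path(out_dir, "imputed.vcf"))

  report <- accuracy_report(gp, test_panel, segments)
  utils::write.table(report$per_variant,
                     file.path(out_dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "daeimpute",
    version = as.character(utils::packageVersion("daeimpute")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    n_train_samples = length(train_idx),
    n_test_samples = n_hold,
    n_segments = nrow(segments),
    artifacts = c("segments.bed", "segments.bed.json", "models",
                  "imputed.vcf", "report.tsv"),
    mean_r2 = report$summary$mean_r2)
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)

  structure(list(panel = panel, segments = segments, models = models,
                 imputed = gp, report = report,
                 grid_results = grid_results, manifest_path = mpath),
            class = "pipeline_result")
}

#' Coarse random grid search over one segment
#'
#' Trains each candidate spec on the segment and scores the mean
#' per-variant dosage r-squared on a validation panel under array-style
#' masking.
#'
#' @param panel training [genotype_panel()].
#' @param segment one-row segment slice.
#' @param specs list of [dae_spec()] candidates.
#' @param validation_panel held-out [genotype_panel()].
#' @param schedule a [training_schedule()] (typically one 500-epoch cycle).
#' @param mask_fraction fraction of segment variants observed at
#'   validation (default 0.05).
#' @return tibble: spec fields + `validation_r2`, `concordance`, `f1`;
#'   attribute `best_spec`.
#' @export
grid_search <- function(panel, segment, specs, validation_panel,
                        schedule = training_schedule(),
                        mask_fraction = 0.05) {
  vi <- seq(segment$start, segment$end)
  val_seg <- subset_panel(validation_panel, variants = vi)
  masked <- array_mask(val_seg, observed_fraction = mask_fraction,
                       seed = schedule$seed)
  rows <- vector("list", length(specs))
  best_r2 <- -Inf; best_spec <- NULL
  for (i in seq_along(specs)) {
    fit <- tryCatch(
      train_segment(panel, segment, specs[[i]], schedule),
      error = function(e) NULL)
    if (is.null(fit)) {
      met <- tibble::tibble(validation_r2 = NA_real_,
                            concordance = NA_real_, f1 = NA_real_)
    } else {
      gp <- impute(subset_panel(masked,
                                variants = attr(masked, "observed_index")),
                   dae_models(list(fit)))
      rep <- accuracy_report(gp, val_seg)
      met <- tibble::tibble(validation_r2 = rep$summary$mean_r2,
                            concordance = rep$summary$mean_concordance,
                            f1 = rep$summary$mean_f1)
      if (!is.na(met$validation_r2) && met$validation_r2 > best_r2) {
        best_r2 <- met$validation_r2; best_spec <- specs[[i]]
      }
    }
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(segment_id = segment$segment_id),
      specs_to_tibble(specs[i]), met)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "best_spec") <- best_spec
  out
}
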