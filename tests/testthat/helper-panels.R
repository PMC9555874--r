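# Shared fixture builders. Everything is generated in code; no stored data.

# A tiny deterministic panel: 4 samples x 5 variants with every genotype
# state represented.
toy_panel <- function() {
  g <- rbind(c(0L, 1L, 2L, NA, 0L),
             c(1L, 1L, 0L, 2L, 0L),
             c(2L, 0L, 1L, 1L, 0L),
             c(0L, 2L, 2L, 0L, 1L))
  v <- tibble::tibble(chrom = "22", pos = c(100L, 200L, 350L, 400L, 900L),
                      ref = c("A", "C", "G", "T", "A"),
                      alt = c("G", "T", "A", "C", "C"))
  genotype_panel(g, v, sample_ids = paste0("ind", 1:4))
}

# Block-LD panel via the generator, with uniform blocks.
block_panel <- function(k, n_hap = 200, block_size = 40, gap = 15,
                        r2 = 0.9, rare_fraction = 0.3, seed = 1) {
  generate_panel(
    n_hap,
    rep(list(list(n_variants = block_size, within_block_r2 = r2,
                  rare_fraction = rare_fraction)), k),
    hotspot_gap_variants = gap, seed = seed)
}

# Tiling config scaled to the toy panels above (windows smaller than a
# block, gaps wider than the window).
toy_tiling_config <- function(...) {
  tiling_config(box_halfwidth = 12, smooth_width = 5, ...)
}

# Write a 3-sample toy VCF (with one multi-allelic record to be skipped)
# and return its path plus the expected genotype matrix.
write_toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "NA1", "NA2", "NA3", sep = "\t"),
    paste("22", "100", ".", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0|1", "1/1", sep = "\t"),
    paste("22", "200", ".", "C", "T,A", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/2", sep = "\t"),   # multi-allelic: skipped
    paste("22", "300", ".", "G", "A", ".", "PASS", ".", "GT",
          "1/0", "./.", "0/0", sep = "\t"))
  writeLines(lines, path)
  list(path = path,
       genotypes = rbind(NA1 = c(0L, 1L), NA2 = c(1L, NA), NA3 = c(2L, 0L)))
}

# A constant-rate training schedule whose masking curriculum is flat:
# with 25 variants and 5 left unmasked, first and last rates are both 0.80.
flat_schedule <- function(n_cycles = 4, epochs_per_cycle = 2) {
  training_schedule(initial_mask_rate = 0.80, min_unmasked = 5,
                    epochs_per_cycle = epochs_per_cycle,
                    max_epochs = n_cycles * epochs_per_cycle,
                    batch_size = 64, seed = 11)
}
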