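#' Read unphased genotypes from a VCF file
#'
#' Parses a VCF 4.x file into a [genotype_panel()]. Only bi-allelic SNP
#' records are kept; multi-allelic or non-SNP records are skipped with a
#' message reporting the count. Phase separators ("|") are ignored — all
#' genotypes are treated as unphased.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @return a [genotype_panel()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    message("read_vcf: skipped ", n_skip,
            " multi-allelic/non-SNP record(s)")
  }
  if (!any(keep)) stop("no bi-allelic SNP records in ", path)
  gt_raw <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  # normalize phase and parse allele pair
  g <- matrix(NA_integer_, nrow(gt_raw), ncol(gt_raw))
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  flat <- gsub("|", "/", gt_raw, fixed = TRUE)
  g[] <- unname(known[flat])
  variants <- tibble::tibble(
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]),
    ref = ref[keep], alt = alt[keep]
  )
  genotype_panel(t(g), variants, sample_ids = colnames(gt_raw))
}

vcf_header <- function(sample_ids, with_probs) {
  fmt <- c(
    "##fileformat=VCFv4.2",
    "##source=daeimpute",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  if (with_probs) {
    fmt <- c(
      fmt,
      '##FORMAT=<ID=GP,Number=3,Type=Float,Description="Genotype probabilities (hom-ref, het, hom-alt)">',
      '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Alternate allele dosage">',
      '##INFO=<ID=IMPUTED,Number=0,Type=Flag,Description="Site imputed (not genotyped in input)">'
    )
  }
  c(fmt, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample_ids), collapse = "\t"))
}

gt_string <- c("0/0", "0/1", "1/1")

#' Write a genotype panel or genotype probabilities to VCF
#'
#' Panels are written with a GT field only (missing as "./."). Probability
#' objects are written with `GT:GP:DS`: GT is the argmax genotype (ties
#' toward fewer alternate alleles), GP the three class probabilities to six
#' decimal places, DS the alternate-allele dosage; imputed (non-genotyped)
#' sites carry an `IMPUTED` INFO flag.
#'
#' @param x a [genotype_panel()] or [genotype_probabilities()] object.
#' @param path output path; plain-text VCF 4.2 is written.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  if (inherits(x, "genotype_panel")) {
    lines <- vcf_header(x$sample_ids, with_probs = FALSE)
    g <- t(x$genotypes)                      # variants x samples
    body <- matrix("./.", nrow(g), ncol(g))
    ok <- !is.na(g)
    body[ok] <- gt_string[g[ok] + 1L]
    v <- x$variants
    recs <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".", "GT",
                  sep = "\t")
    lines <- c(lines, paste(recs, apply(body, 1, paste, collapse = "\t"),
                            sep = "\t"))
  } else if (inherits(x, "genotype_probabilities")) {
    lines <- vcf_header(x$sample_ids, with_probs = TRUE)
    v <- x$variants
    m <- dim(x$p)[2]
    calls <- hard_calls(x)
    ds <- dosage_matrix(x)
    recs <- character(m)
    for (k in seq_len(m)) {
      pk <- matrix(x$p[, k, ], ncol = 3)
      # round to 6 decimals, then absorb the rounding residual into the
      # largest class so every printed triple sums to exactly 1
      pr <- round(pk, 6)
      imax <- max.col(pk, ties.method = "first")
      resid <- 1 - rowSums(pr)
      pr[cbind(seq_len(nrow(pr)), imax)] <-
        pr[cbind(seq_len(nrow(pr)), imax)] + resid
      cells <- paste0(gt_string[calls[, k] + 1L], ":",
                      sprintf("%.6f", pr[, 1]), ",",
                      sprintf("%.6f", pr[, 2]), ",",
                      sprintf("%.6f", pr[, 3]), ":",
                      sprintf("%.3f", ds[, k]))
      info <- if (x$genotyped[k]) "." else "IMPUTED"
      recs[k] <- paste(v$chrom[k], v$pos[k], ".", v$ref[k], v$alt[k], ".",
                       "PASS", info, "GT:GP:DS",
                       paste(cells, collapse = "\t"), sep = "\t")
    }
    lines <- c(lines, recs)
  } else {
    stop("write_vcf: unsupported object of class ", class(x)[1])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a genetic map
#'
#' Reads a whitespace-delimited three-column table (chrom, pos in bp,
#' cumulative cM) into a `genetic_map` tibble. Positions must be strictly
#' increasing and cM non-decreasing within each chromosome.
#'
#' @param path path to the map file; a header line is auto-detected.
#' @return tibble with columns `chrom`, `pos`, `cM`, class `genetic_map`.
#' @export
read_genetic_map <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- !grepl("^\\S+\\s+\\d+\\s+[0-9.eE+-]+\\s*$", first)
  d <- utils::read.table(path, header = has_header,
                         col.names = c("chrom", "pos", "cM"))
  genetic_map(tibble::as_tibble(d))
}

#' Construct / validate a genetic map
#'
#' @param df data frame with columns `chrom`, `pos` (1-based bp), `cM`
#'   (cumulative genetic distance).
#' @return the validated tibble with class `genetic_map`.
#' @export
genetic_map <- function(df) {
  df <- tibble::as_tibble(df)[, c("chrom", "pos", "cM")]
  df$pos <- as.integer(df$pos)
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    if (is.unsorted(sub$pos, strictly = TRUE)) {
      stop("map positions not strictly increasing on ", ch)
    }
    if (is.unsorted(sub$cM)) stop("map cM not non-decreasing on ", ch)
  }
  class(df) <- c("genetic_map", class(df))
  df
}

#' Interpolate cumulative genetic distance at physical positions
#'
#' Linear interpolation of the map, constant beyond its ends.
#'
#' @param map a `genetic_map`.
#' @param chrom chromosome name.
#' @param pos integer vector of 1-based bp positions.
#' @return numeric vector of cumulative cM values.
#' @export
interp_cM <- function(map, chrom, pos) {
  sub <- map[map$chrom == chrom, ]
  if (nrow(sub) == 0) stop("chromosome ", chrom, " absent from map")
  if (nrow(sub) == 1) return(rep(sub$cM, length(pos)))
  stats::approx(sub$pos, sub$cM, xout = pos, rule = 2)$y
}
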