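## Variant-selection checklist: the five filters applied before any PCA.
##
## Order used by the pipeline: autosomes -> MAF -> missingness -> LD pruning
## -> artifact-region exclusion. Each filter returns a subset of the input
## variants and never alters the dosages of survivors; removed variants are
## recorded in a `qc_report` attribute (vid, filter).

#' Variant QC thresholds
#'
#' Defaults are the consortium protocol values: minor allele frequency
#' > 0.05 (strict), variant missingness < 0.02 (strict), LD pruning at
#' |r| > 0.5 within a 500 kbp sliding window, autosomes only.
#'
#' @param maf_min minimum minor allele frequency, in `[0, 0.5]`
#' @param missingness_max maximum missing-call fraction, in `[0, 1]`
#' @param ld_r_max maximum absolute genotype correlation within the window,
#'   in `(0, 1]`
#' @param ld_window_bp sliding-window width in basepairs
#' @param autosomes_only restrict to chromosomes 1..22
#' @return list of thresholds, class `qc_thresholds`
#' @export
qc_thresholds <- function(maf_min = 0.05, missingness_max = 0.02,
                          ld_r_max = 0.5, ld_window_bp = 500000L,
                          autosomes_only = TRUE) {
  stopifnot(maf_min >= 0, maf_min <= 0.5,
            missingness_max >= 0, missingness_max <= 1,
            ld_r_max > 0, ld_r_max <= 1, ld_window_bp > 0)
  structure(list(maf_min = maf_min, missingness_max = missingness_max,
                 ld_r_max = ld_r_max, ld_window_bp = as.integer(ld_window_bp),
                 autosomes_only = autosomes_only),
            class = "qc_thresholds")
}

add_qc_report <- function(G, vids, filter) {
  rep0 <- attr(G, "qc_report")
  new <- data.frame(vid = vids, filter = rep(filter, length(vids)),
                    stringsAsFactors = FALSE)
  attr(G, "qc_report") <- rbind(rep0, new)
  G
}

drop_with_report <- function(G, drop, filter) {
  removed <- G$variants$vid[drop]
  rep0 <- attr(G, "qc_report")
  G <- keep_variants(G, !drop)
  attr(G, "qc_report") <- rep0
  add_qc_report(G, removed, filter)
}

#' Keep autosomal variants only
#'
#' Chromosome labels "1".."22" (an optional "chr" prefix is tolerated) are
#' retained; sex chromosomes and anything else are removed.
#'
#' @param G a [genotype_matrix()]
#' @return filtered `genotype_matrix` with updated `qc_report`
#' @export
filter_autosomal <- function(G) {
  chrom <- sub("^chr", "", G$variants$chrom)
  drop_with_report(G, !(chrom %in% as.character(1:22)), "autosomal")
}

#' Minor allele frequency filter
#'
#' A variant is kept iff `min(p, 1 - p) > maf_min` with `p` the
#' alternate-allele frequency over non-missing calls — strictly greater, so
#' a variant with MAF exactly at the threshold is removed. Variants with all
#' calls missing are removed and reported.
#'
#' @param G a [genotype_matrix()]
#' @param maf_min threshold in `[0, 0.5]`
#' @return filtered `genotype_matrix`
#' @export
filter_maf <- function(G, maf_min = 0.05) {
  stopifnot(maf_min >= 0, maf_min <= 0.5)
  p <- alt_freq(G)
  maf <- pmin(p, 1 - p)
  drop <- is.na(maf) | !(maf > maf_min)
  drop_with_report(G, drop, "maf")
}

#' Variant missingness filter
#'
#' A variant is kept iff its missing-call fraction is strictly below
#' `missingness_max`.
#'
#' @param G a [genotype_matrix()]
#' @param missingness_max threshold in `[0, 1]`
#' @return filtered `genotype_matrix`
#' @export
filter_missingness <- function(G, missingness_max = 0.02) {
  stopifnot(missingness_max >= 0, missingness_max <= 1)
  drop_with_report(G, !(variant_missingness(G) < missingness_max), "missingness")
}

#' Sliding-window LD pruning
#'
#' Greedy left-to-right scan within each chromosome: a variant is removed
#' when its genotype correlation magnitude |r| with any already retained
#' variant at most `ld_window_bp` upstream exceeds `ld_r_max`. Correlations
#' are computed on pairwise-complete (non-missing) samples. On a positional
#' tie the higher-MAF variant is scanned (and thus kept) first. The output
#' preserves input order. Zero-variance variants never trigger a removal
#' (their correlation is undefined) and are flagged in the `ld_flags`
#' attribute.
#'
#' @param G a [genotype_matrix()], variants sorted by (chrom, pos)
#' @param ld_r_max correlation magnitude threshold (`|r|`, not r squared)
#' @param ld_window_bp window width in basepairs (distance between variant
#'   positions, not variant count)
#' @return pruned `genotype_matrix`
#' @export
ld_prune <- function(G, ld_r_max = 0.5, ld_window_bp = 500000L) {
  stopifnot(ld_r_max > 0, ld_r_max <= 1, ld_window_bp > 0)
  v <- G$variants
  p <- alt_freq(G)
  maf <- pmin(p, 1 - p)
  zero_var <- apply(G$dosages, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) < 2 || stats::var(x) == 0
  })
  keep <- rep(TRUE, n_variants(G))
  for (chr in unique(v$chrom)) {
    idx <- which(v$chrom == chr)
    # scan order: position, tie broken toward higher MAF
    idx <- idx[order(v$pos[idx], -maf[idx])]
    kept <- integer(0)
    kept_pos <- integer(0)
    for (i in idx) {
      if (zero_var[i]) { kept <- c(kept, i); kept_pos <- c(kept_pos, v$pos[i]); next }
      win <- kept[v$pos[i] - kept_pos <= ld_window_bp & !zero_var[kept]]
      if (length(win)) {
        r <- suppressWarnings(
          stats::cor(G$dosages[, i], G$dosages[, win, drop = FALSE],
                     use = "pairwise.complete.obs"))
        r[is.na(r)] <- 0
        if (any(abs(r) > ld_r_max)) { keep[i] <- FALSE; next }
      }
      kept <- c(kept, i)
      kept_pos <- c(kept_pos, v$pos[i])
    }
  }
  out <- drop_with_report(G, !keep, "ld_prune")
  attr(out, "ld_flags") <- v$vid[zero_var & keep]
  out
}

#' Read exclusion regions from a BED file
#'
#' BED intervals are 0-based half-open; they are converted to the 1-based
#' inclusive convention used for variant positions. An optional fourth
#' column provides the region label.
#'
#' @param path BED file
#' @return data.frame (chrom, start, end, label), 1-based inclusive
#' @export
read_bed_regions <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stop("BED file needs at least 3 columns")
  out <- data.frame(chrom = as.character(bed[[1]]),
                    start = as.integer(bed[[2]]) + 1L,
                    end = as.integer(bed[[3]]),
                    label = if (ncol(bed) >= 4) as.character(bed[[4]])
                            else paste0("region", seq_len(nrow(bed))),
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("malformed BED interval (start >= end)")
  out
}

#' Default artifact-region exclusion list
#'
#' Long-range LD regions known to distort principal components on build-37
#' coordinates: the HLA/MHC region (chr6:25-35 Mb) and the chromosome 8
#' inversion (chr8:6-16 Mb). The list is ordinary data — replace it with a
#' BED file of your own via [read_bed_regions()].
#'
#' @return data.frame (chrom, start, end, label), 1-based inclusive
#' @export
default_exclusion_regions <- function() {
  data.frame(chrom = c("6", "8"),
             start = c(25000000L, 6000000L),
             end = c(35000000L, 16000000L),
             label = c("HLA", "chr8_inversion"),
             stringsAsFactors = FALSE)
}

#' Remove variants inside exclusion regions
#'
#' Variants whose position lies inside any region (1-based inclusive
#' endpoints) on the matching chromosome are removed; a
#' `region_report` attribute lists per-region removal counts.
#'
#' @param G a [genotype_matrix()]
#' @param regions data.frame (chrom, start, end, label), e.g. from
#'   [read_bed_regions()] or [default_exclusion_regions()]
#' @return filtered `genotype_matrix`
#' @export
exclude_regions <- function(G, regions = default_exclusion_regions()) {
  v <- G$variants
  chrom <- sub("^chr", "", v$chrom)
  drop <- rep(FALSE, n_variants(G))
  counts <- integer(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    hit <- chrom == sub("^chr", "", regions$chrom[i]) &
      v$pos >= regions$start[i] & v$pos <= regions$end[i]
    counts[i] <- sum(hit)
    drop <- drop | hit
  }
  out <- drop_with_report(G, drop, "exclude_region")
  attr(out, "region_report") <- data.frame(label = regions$label,
                                           n_removed = counts,
                                           stringsAsFactors = FALSE)
  out
}

#' Apply the full variant-selection checklist
#'
#' Runs, in protocol order: autosomes only, MAF, missingness, LD pruning and
#' artifact-region exclusion. The accumulated `qc_report` maps every removed
#' variant to the filter that removed it.
#'
#' @param G a [genotype_matrix()]
#' @param thresholds a [qc_thresholds()] object
#' @param regions exclusion regions (data.frame) or NULL to skip the region
#'   step
#' @return filtered `genotype_matrix` with `qc_report` attribute
#' @export
apply_variant_qc <- function(G, thresholds = qc_thresholds(),
                             regions = default_exclusion_regions()) {
  if (thresholds$autosomes_only) G <- filter_autosomal(G)
  G <- filter_maf(G, thresholds$maf_min)
  G <- filter_missingness(G, thresholds$missingness_max)
  G <- ld_prune(G, thresholds$ld_r_max, thresholds$ld_window_bp)
  if (!is.null(regions)) G <- exclude_regions(G, regions)
  G
}
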