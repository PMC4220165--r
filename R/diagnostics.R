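## SNP-PC correlation tracks, artifact-region flagging, and median-based
## ancestry assignment.

#' Per-variant absolute genotype-PC correlation track
#'
#' For every variant, the absolute Pearson correlation between its dosages
#' (over non-missing samples) and one principal-component score column.
#' A well-behaved ancestry component correlates weakly but genome-wide;
#' a component driven by a local artifact (an inversion, the HLA region, a
#' platform-specific probe cluster) shows a block of elevated correlation.
#'
#' @param G a [genotype_matrix()]
#' @param scores a `pc_scores` data.frame (from [pca_scores()] or
#'   [project_samples()]) or a matrix with sample rownames
#' @param l component index
#' @return data.frame of class `correlation_track` (chrom, pos, vid,
#'   abs_corr, undefined); zero-variance variants have `NA` correlation and
#'   are flagged `undefined`
#' @export
pc_genotype_correlation <- function(G, scores, l = 1) {
  if (is.data.frame(scores)) scores <- score_matrix(scores)
  hit <- match(G$samples$sid, rownames(scores))
  if (anyNA(hit)) stop("samples of G and scores are not aligned")
  s <- scores[hit, l]
  r <- suppressWarnings(
    as.vector(stats::cor(G$dosages, s, use = "pairwise.complete.obs")))
  out <- data.frame(chrom = G$variants$chrom, pos = G$variants$pos,
                    vid = G$variants$vid, abs_corr = abs(r),
                    undefined = is.na(r), stringsAsFactors = FALSE)
  attr(out, "component") <- l
  class(out) <- c("correlation_track", "data.frame")
  out
}

#' Flag genomic regions with locally elevated genotype-PC correlation
#'
#' Sliding windows (stepped at a quarter window) whose mean absolute
#' correlation exceeds `fold` times the genome-wide mean are merged into
#' maximal intervals, each clipped to the positions of the variants it
#' contains. Chromosomal artifacts driving a component appear as such
#' intervals; the defaults are operational screening values — inspect
#' flagged regions rather than excluding them blindly.
#'
#' @param track a `correlation_track` from [pc_genotype_correlation()]
#' @param window_bp window width in basepairs
#' @param fold threshold multiplier over the genome-wide mean
#' @param min_variants minimum variants in a window for it to be eligible
#' @return data.frame (chrom, start, end, n_variants, mean_abs_corr),
#'   non-overlapping
#' @export
flag_artifact_regions <- function(track, window_bp = 1000000L, fold = 3,
                                  min_variants = 2L) {
  stopifnot(nrow(track) > 0)
  gmean <- mean(track$abs_corr, na.rm = TRUE)
  step <- max(1L, as.integer(window_bp / 4))
  out <- list()
  for (chr in unique(track$chrom)) {
    tt <- track[track$chrom == chr & !is.na(track$abs_corr), ]
    if (nrow(tt) < min_variants) next
    starts <- seq(min(tt$pos), max(tt$pos), by = step)
    flag <- logical(length(starts))
    for (i in seq_along(starts)) {
      inw <- tt$pos >= starts[i] & tt$pos < starts[i] + window_bp
      flag[i] <- sum(inw) >= min_variants &&
        mean(tt$abs_corr[inw]) > fold * gmean
    }
    if (!any(flag)) next
    # merge overlapping/adjacent flagged windows into maximal runs
    runs <- rle(flag)
    ends_idx <- cumsum(runs$lengths)
    starts_idx <- ends_idx - runs$lengths + 1
    for (rid in which(runs$values)) {
      w0 <- starts[starts_idx[rid]]
      w1 <- starts[ends_idx[rid]] + window_bp - 1
      inr <- tt$pos >= w0 & tt$pos <= w1
      out[[length(out) + 1]] <- data.frame(
        chrom = chr, start = min(tt$pos[inr]), end = max(tt$pos[inr]),
        n_variants = sum(inr), mean_abs_corr = mean(tt$abs_corr[inr]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_variants = integer(0),
                      mean_abs_corr = numeric(0)))
  do.call(rbind, out)
}

#' Default per-group boundary multipliers
#'
#' The consortium protocol values: African median ± 2 SD, European ± 4 SD,
#' Hispanic ± 1 SD on each of PC1 and PC2.
#'
#' @return named numeric vector
#' @export
default_ancestry_ksd <- function() {
  c(African = 2, European = 4, Hispanic = 1)
}

#' Fit median-based ancestry boundaries on PC1/PC2
#'
#' Per self-reported group, the median (Q2) and standard deviation of PC1
#' and PC2 over the samples reporting that group; the assignment box is
#' Q2 ± k·SD per axis. Groups with fewer than two samples are skipped with
#' a warning; a group with zero SD is flagged degenerate.
#'
#' @param scores a `pc_scores` data.frame
#' @param labels per-sample group labels, aligned with `scores` rows (NA =
#'   no self-report)
#' @param k_sd single multiplier or named vector per group; defaults to
#'   [default_ancestry_ksd()] with 2 for groups not named there
#' @return data.frame of class `ancestry_boundaries`
#' @export
fit_ancestry_boundaries <- function(scores, labels, k_sd = default_ancestry_ksd()) {
  stopifnot(length(labels) == nrow(scores))
  sm <- score_matrix(scores)
  groups <- setdiff(unique(labels[!is.na(labels)]), "")
  rows <- list()
  for (g in groups) {
    idx <- which(!is.na(labels) & labels == g)
    if (length(idx) < 2) {
      warning("group '", g, "' has < 2 samples; skipped")
      next
    }
    k <- if (length(k_sd) == 1 && is.null(names(k_sd))) k_sd
         else if (g %in% names(k_sd)) k_sd[[g]] else 2
    sd1 <- stats::sd(sm[idx, 1]); sd2 <- stats::sd(sm[idx, 2])
    rows[[g]] <- data.frame(
      group = g, k_sd = k,
      pc1_q2 = stats::median(sm[idx, 1]), pc1_sd = sd1,
      pc2_q2 = stats::median(sm[idx, 2]), pc2_sd = sd2,
      degenerate = (sd1 == 0 || sd2 == 0),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ancestry_boundaries", "data.frame")
  out
}

#' Assign genetic ancestry from fitted boundaries
#'
#' A sample is assigned to a group iff PC1 and PC2 both fall within that
#' group's Q2 ± k·SD interval (axis-aligned box, the default) or, with
#' `mode = "ellipse"`, within the axis-aligned ellipse of the same
#' half-widths. Samples inside multiple groups are labelled `"ambiguous"`,
#' samples inside none `"unassigned"`.
#'
#' @param scores a `pc_scores` data.frame
#' @param boundaries from [fit_ancestry_boundaries()]
#' @param mode `"box"` or `"ellipse"`
#' @return data.frame (sid, label)
#' @export
assign_ancestry <- function(scores, boundaries, mode = c("box", "ellipse")) {
  mode <- match.arg(mode)
  sm <- score_matrix(scores)
  inside <- sapply(seq_len(nrow(boundaries)), function(i) {
    b <- boundaries[i, ]
    dx <- abs(sm[, 1] - b$pc1_q2)
    dy <- abs(sm[, 2] - b$pc2_q2)
    if (mode == "box")
      dx <= b$k_sd * b$pc1_sd & dy <= b$k_sd * b$pc2_sd
    else {
      hx <- b$k_sd * b$pc1_sd; hy <- b$k_sd * b$pc2_sd
      if (hx == 0 || hy == 0) dx == 0 & dy == 0
      else (dx / hx)^2 + (dy / hy)^2 <= 1
    }
  })
  inside <- matrix(inside, nrow = nrow(sm))
  nhit <- rowSums(inside)
  label <- rep("unassigned", nrow(sm))
  one <- nhit == 1
  label[one] <- boundaries$group[apply(inside[one, , drop = FALSE], 1, which)]
  label[nhit > 1] <- "ambiguous"
  data.frame(sid = scores$sid, label = label, stringsAsFactors = FALSE)
}

#' Write a correlation track as TSV
#' @param track a `correlation_track`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_track <- function(track, path) {
  utils::write.table(as.data.frame(track), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
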