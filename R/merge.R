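## Cross-cohort harmonization and cohort summaries.

comp_allele <- function(a) chartr("ACGTacgt", "TGCAtgca", a)

is_strand_ambiguous <- function(ref, alt) {
  toupper(ref) == comp_allele(toupper(alt))
}

# classify how a cohort's alleles relate to the target's at the same site:
# same / swap (ref-alt exchanged) / flip (strand complement) / flipswap /
# ambiguous (A/T or C/G pair, orientation unknowable) / mismatch
allele_action <- function(t_ref, t_alt, o_ref, o_alt, drop_ambiguous = TRUE) {
  t_ref <- toupper(t_ref); t_alt <- toupper(t_alt)
  o_ref <- toupper(o_ref); o_alt <- toupper(o_alt)
  n <- length(t_ref)
  act <- rep("mismatch", n)
  act[o_ref == t_ref & o_alt == t_alt] <- "same"
  act[o_ref == t_alt & o_alt == t_ref] <- "swap"
  fr <- comp_allele(o_ref); fa <- comp_allele(o_alt)
  pending <- act == "mismatch"
  act[pending & fr == t_ref & fa == t_alt] <- "flip"
  pending <- act == "mismatch"
  act[pending & fr == t_alt & fa == t_ref] <- "flipswap"
  if (drop_ambiguous)
    act[is_strand_ambiguous(t_ref, t_alt) | is_strand_ambiguous(o_ref, o_alt)] <- "ambiguous"
  act
}

#' Merge genotype cohorts with allele harmonization
#'
#' Variants are matched across cohorts on (chrom, pos) and restricted to the
#' intersection. Alleles are harmonized to the first cohort: a cohort whose
#' alleles are the strand complement of the target's keeps its dosages, one
#' with ref/alt exchanged has dosages recoded `d -> 2 - d`, and
#' strand-ambiguous A/T or C/G SNPs — whose orientation cannot be determined —
#' are dropped (configurable). Sites with irreconcilable alleles are dropped
#' with a warning rather than raising an error. The merged sample list is the
#' concatenation of the inputs.
#'
#' A `merge_report` attribute counts shared, flipped, swapped, ambiguous and
#' mismatched variants.
#'
#' @param cohorts list of two or more [genotype_matrix()] objects with
#'   disjoint sample identifiers
#' @param policy variant-matching policy; only `"intersect_variants"` is
#'   supported (union would require imputation)
#' @param drop_ambiguous drop strand-ambiguous (A/T, C/G) SNPs; default TRUE
#' @return a [genotype_matrix()] with attribute `merge_report`
#' @export
merge_cohorts <- function(cohorts, policy = "intersect_variants",
                          drop_ambiguous = TRUE) {
  policy <- match.arg(policy)
  if (length(cohorts) < 2) stop("need at least two cohorts to merge")
  sids <- unlist(lapply(cohorts, function(g) g$samples$sid))
  if (anyDuplicated(sids)) stop("cohorts must have disjoint sample identifiers")

  target <- cohorts[[1]]
  key_of <- function(g) paste(g$variants$chrom, g$variants$pos, sep = ":")
  t_keys <- key_of(target)
  shared <- t_keys
  for (g in cohorts[-1]) shared <- intersect(shared, key_of(g))
  keep <- t_keys %in% shared
  report <- list(n_shared = sum(keep), n_flipped = 0L, n_swapped = 0L,
                 n_ambiguous = 0L, n_mismatch = 0L)

  tv <- target$variants[keep, , drop = FALSE]
  t_keys <- t_keys[keep]
  blocks <- list(target$dosages[, keep, drop = FALSE])
  drop_mask <- rep(FALSE, nrow(tv))
  for (g in cohorts[-1]) {
    hit <- match(t_keys, key_of(g))
    ov <- g$variants[hit, , drop = FALSE]
    act <- allele_action(tv$ref, tv$alt, ov$ref, ov$alt, drop_ambiguous)
    d <- g$dosages[, hit, drop = FALSE]
    rec <- act %in% c("swap", "flipswap")
    d[, rec] <- 2 - d[, rec]
    report$n_flipped <- report$n_flipped + sum(act %in% c("flip", "flipswap"))
    report$n_swapped <- report$n_swapped + sum(rec)
    report$n_ambiguous <- report$n_ambiguous + sum(act == "ambiguous")
    report$n_mismatch <- report$n_mismatch + sum(act == "mismatch")
    drop_mask <- drop_mask | act %in% c("ambiguous", "mismatch")
    blocks <- c(blocks, list(d))
  }
  if (any(drop_mask)) {
    if (report$n_mismatch > 0)
      warning(report$n_mismatch, " variant(s) with irreconcilable alleles dropped")
    blocks <- lapply(blocks, function(b) b[, !drop_mask, drop = FALSE])
    tv <- tv[!drop_mask, , drop = FALSE]
  }
  samples <- do.call(rbind, lapply(cohorts, function(g) {
    s <- g$samples[c("sid", "site", "platform", "ancestry", "sex", "phenotype")]
    s
  }))
  G <- genotype_matrix(do.call(rbind, blocks), tv, samples)
  attr(G, "merge_report") <- report
  G
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Stratified cohort summary
#'
#' Counts and integer percentages of samples by recruitment site,
#' self-reported ancestry, sex and genotyping platform, with the combined
#' total. Percentages are computed against the combined N and rounded half
#' away from zero; missing labels are tallied as their own stratum. An empty
#' cohort yields zero counts with blank (`NA`) percentages.
#'
#' @param G a [genotype_matrix()]
#' @return an object of class `cohort_summary`: list with `combined_n` and a
#'   long data.frame `table` (axis, level, count, pct)
#' @export
cohort_summary <- function(G) {
  s <- G$samples
  N <- nrow(s)
  axes <- c("site", "ancestry", "sex", "platform")
  rows <- lapply(axes, function(ax) {
    lab <- as.character(s[[ax]])
    lab[is.na(lab) | lab == ""] <- "missing"
    if (!length(lab))
      return(data.frame(axis = character(0), level = character(0),
                        count = integer(0), pct = numeric(0)))
    tab <- table(lab)
    data.frame(axis = ax, level = names(tab), count = as.integer(tab),
               pct = round_half_away(100 * as.integer(tab) / N),
               stringsAsFactors = FALSE)
  })
  out <- list(combined_n = N, table = do.call(rbind, rows))
  rownames(out$table) <- NULL
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Combined N =", format(x$combined_n, big.mark = ","), "\n")
  for (ax in unique(x$table$axis)) {
    cat("\n", toupper(ax), "\n", sep = "")
    sub <- x$table[x$table$axis == ax, ]
    for (i in seq_len(nrow(sub)))
      cat(sprintf("  %-12s %8s  %3s%%\n", sub$level[i],
                  format(sub$count[i], big.mark = ","), sub$pct[i]))
  }
  invisible(x)
}
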