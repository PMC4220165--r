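# in-code fixtures: random genotype matrices with controllable missingness

random_genotype_matrix <- function(n, M, miss_rate = 0, seed = 1,
                                   maf_range = c(0.1, 0.5), n_chrom = 2,
                                   chrom_length = 1e6) {
  set.seed(seed)
  p <- runif(M, maf_range[1], maf_range[2])
  d <- matrix(rbinom(n * M, 2, rep(p, each = n)), n, M)
  storage.mode(d) <- "double"
  if (miss_rate > 0) d[runif(n * M) < miss_rate] <- NA
  chrom <- sort(rep_len(as.character(seq_len(n_chrom)), M))
  pos <- integer(M)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- sort(sample.int(chrom_length, length(idx)))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, M, replace = TRUE)
  # avoid strand-ambiguous pairs so merge fixtures behave predictably
  alt <- vapply(ref, function(r) sample(setdiff(bases,
    c(r, chartr("ACGT", "TGCA", r))), 1), character(1))
  variants <- data.frame(chrom = chrom, pos = pos,
                         vid = paste(chrom, pos, ref, alt, sep = ":"),
                         ref = ref, alt = alt, stringsAsFactors = FALSE)
  samples <- data.frame(sid = sprintf("S%03d", seq_len(n)),
                        site = "siteA", platform = "chip1",
                        ancestry = NA_character_,
                        sex = sample(c("female", "male"), n, replace = TRUE),
                        phenotype = NA_real_, stringsAsFactors = FALSE)
  genotype_matrix(d, variants, samples)
}

# independent LD-pruning oracle: exhaustive pairwise greedy scan over the
# full correlation matrix (one r per candidate/retained pair, no windowed
# bookkeeping)
prune_oracle <- function(G, r_max, window_bp) {
  v <- G$variants
  p <- alt_freq(G)
  maf <- pmin(p, 1 - p)
  keep <- logical(n_variants(G))
  for (chr in unique(v$chrom)) {
    idx <- which(v$chrom == chr)
    idx <- idx[order(v$pos[idx], -maf[idx])]
    kept <- integer(0)
    for (i in idx) {
      x <- G$dosages[, i]
      drop <- FALSE
      for (j in kept) {
        if (v$pos[i] - v$pos[j] > window_bp) next
        r <- suppressWarnings(cor(x, G$dosages[, j], use = "pairwise.complete.obs"))
        if (!is.na(r) && abs(r) > r_max) { drop <- TRUE; break }
      }
      if (!drop) kept <- c(kept, i)
    }
    keep[kept] <- TRUE
  }
  sort(G$variants$vid[keep])
}

# align component signs of two score/loading matrices column by column
align_signs <- function(a, b) {
  for (l in seq_len(ncol(a))) {
    if (sum(a[, l] * b[, l]) < 0) b[, l] <- -b[, l]
  }
  b
}
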