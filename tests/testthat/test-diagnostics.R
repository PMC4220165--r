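scores_df <- function(sids, pc1, pc2) {
  out <- data.frame(sid = sids, PC1 = pc1, PC2 = pc2,
                    stringsAsFactors = FALSE)
  class(out) <- c("pc_scores", "data.frame")
  out
}

test_that("correlation track: self-correlation 1, orthogonal 0, oracle match", {
  G <- random_genotype_matrix(30, 25, miss_rate = 0.04, seed = 251)
  # component equal to one variant's centered dosages
  x <- G$dosages[, 7]
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  sc <- scores_df(G$samples$sid, x - mean(x), rnorm(30))
  tr <- pc_genotype_correlation(G, sc, 1)
  expect_equal(tr$abs_corr[7], 1, tolerance = 1e-12)
  # direct per-variant recomputation oracle
  oracle <- sapply(seq_len(25), function(j)
    abs(suppressWarnings(cor(G$dosages[, j], sc$PC1,
                             use = "pairwise.complete.obs"))))
  expect_equal(tr$abs_corr, unname(oracle), tolerance = 1e-12)
})

test_that("zero-variance variants are flagged undefined, not numeric", {
  G <- random_genotype_matrix(10, 5, seed = 261)
  G$dosages[, 3] <- 1
  sc <- scores_df(G$samples$sid, rnorm(10), rnorm(10))
  tr <- pc_genotype_correlation(G, sc, 1)
  expect_true(tr$undefined[3])
  expect_true(is.na(tr$abs_corr[3]))
  expect_false(any(tr$undefined[-3]))
})

test_that("track is invariant to affine rescaling of the PC column", {
  G <- random_genotype_matrix(20, 15, seed = 271)
  s <- rnorm(20)
  t1 <- pc_genotype_correlation(G, scores_df(G$samples$sid, s, s), 1)
  t2 <- pc_genotype_correlation(G, scores_df(G$samples$sid, 3 * s - 7, s), 1)
  expect_equal(t1$abs_corr, t2$abs_corr, tolerance = 1e-12)
})

test_that("flat tracks yield no flags; an elevated block yields one interval", {
  set.seed(281)
  flat <- data.frame(chrom = "1", pos = sort(sample.int(3e7, 400)),
                     vid = paste0("v", 1:400),
                     abs_corr = runif(400, 0.04, 0.06), undefined = FALSE)
  class(flat) <- c("correlation_track", "data.frame")
  expect_equal(nrow(flag_artifact_regions(flat)), 0L)
  elev <- flat
  block <- elev$pos >= 1e7 & elev$pos <= 1.2e7
  elev$abs_corr[block] <- 0.9
  fl <- flag_artifact_regions(elev)
  expect_equal(nrow(fl), 1L)
  expect_lte(fl$start, min(elev$pos[block]))
  expect_gte(fl$end, max(elev$pos[block]))
})

test_that("flagged intervals stay within variant bounds and never overlap", {
  set.seed(291)
  tr <- data.frame(chrom = rep(c("1", "2"), each = 300),
                   pos = c(sort(sample.int(2e7, 300)), sort(sample.int(2e7, 300))),
                   vid = paste0("v", 1:600),
                   abs_corr = runif(600, 0, 0.1), undefined = FALSE)
  tr$abs_corr[tr$chrom == "1" & tr$pos < 3e6] <- 0.8
  tr$abs_corr[tr$chrom == "2" & tr$pos > 1.5e7] <- 0.7
  class(tr) <- c("correlation_track", "data.frame")
  fl <- flag_artifact_regions(tr)
  expect_gte(nrow(fl), 2L)
  for (chr in unique(fl$chrom)) {
    sub <- fl[fl$chrom == chr, ]
    rng <- range(tr$pos[tr$chrom == chr])
    expect_true(all(sub$start >= rng[1] & sub$end <= rng[2]))
    if (nrow(sub) > 1) {
      sub <- sub[order(sub$start), ]
      expect_true(all(sub$start[-1] > sub$end[-nrow(sub)]))
    }
  }
})

test_that("ancestry boundaries: medians and SDs match direct computation", {
  set.seed(301)
  n <- 90
  lab <- rep(c("African", "European", "Hispanic"), each = 30)
  pc1 <- rnorm(n, rep(c(-2, 2, 0), each = 30), 0.5)
  pc2 <- rnorm(n, rep(c(0, 0, 2), each = 30), 0.5)
  sc <- scores_df(sprintf("s%02d", 1:n), pc1, pc2)
  b <- fit_ancestry_boundaries(sc, lab)
  for (g in c("African", "European", "Hispanic")) {
    idx <- lab == g
    row <- b[b$group == g, ]
    expect_equal(row$pc1_q2, median(pc1[idx]), label = g)
    expect_equal(row$pc2_sd, sd(pc2[idx]), label = g)
  }
  expect_equal(b$k_sd[b$group == "African"], 2)
  expect_equal(b$k_sd[b$group == "European"], 4)
  expect_equal(b$k_sd[b$group == "Hispanic"], 1)
})

test_that("degenerate groups are flagged; tiny groups are skipped with a warning", {
  sc <- scores_df(paste0("s", 1:5), c(1, 1, 1, 0, 2), c(2, 2, 2, 0, 1))
  lab <- c("A", "A", "A", "B", NA)
  expect_warning(b <- fit_ancestry_boundaries(sc, lab, k_sd = 2), "skipped")
  expect_equal(b$group, "A")
  expect_true(b$degenerate)
})

test_that("assignment equals a brute-force box test; multi-hit is ambiguous", {
  set.seed(311)
  n <- 200
  lab <- sample(c("African", "European", "Hispanic"), n, replace = TRUE)
  pc1 <- rnorm(n, c(African = -3, European = 3, Hispanic = 0)[lab], 0.8)
  pc2 <- rnorm(n, c(African = 0, European = 0, Hispanic = 2.5)[lab], 0.8)
  sc <- scores_df(sprintf("s%03d", 1:n), pc1, pc2)
  b <- fit_ancestry_boundaries(sc, lab)
  got <- assign_ancestry(sc, b)
  # exhaustive per-sample check against the box definition
  for (i in seq_len(n)) {
    hits <- character(0)
    for (j in seq_len(nrow(b))) {
      in1 <- pc1[i] >= b$pc1_q2[j] - b$k_sd[j] * b$pc1_sd[j] &&
             pc1[i] <= b$pc1_q2[j] + b$k_sd[j] * b$pc1_sd[j]
      in2 <- pc2[i] >= b$pc2_q2[j] - b$k_sd[j] * b$pc2_sd[j] &&
             pc2[i] <= b$pc2_q2[j] + b$k_sd[j] * b$pc2_sd[j]
      if (in1 && in2) hits <- c(hits, b$group[j])
    }
    want <- if (length(hits) == 0) "unassigned"
            else if (length(hits) > 1) "ambiguous" else hits
    expect_identical(got$label[i], want)
  }
})

test_that("a sample at the group's medians is assigned; 10 SD out is not", {
  set.seed(321)
  sc <- scores_df(paste0("s", 1:41),
                  c(rnorm(40, 0, 1), 0), c(rnorm(40, 0, 1), 0))
  lab <- c(rep("European", 40), NA)
  b <- fit_ancestry_boundaries(sc, lab)
  far <- scores_df("far", b$pc1_q2 + 10 * b$pc1_sd, b$pc2_q2)
  expect_equal(assign_ancestry(sc, b)$label[41], "European")
  expect_equal(assign_ancestry(far, b)$label, "unassigned")
})

test_that("widening k_sd is monotone: k = 2 assignments are a subset of k = 4", {
  set.seed(331)
  sc <- scores_df(sprintf("s%03d", 1:150), rnorm(150), rnorm(150))
  lab <- rep("G", 150)
  b2 <- fit_ancestry_boundaries(sc, lab, k_sd = 2)
  b4 <- fit_ancestry_boundaries(sc, lab, k_sd = 4)
  in2 <- assign_ancestry(sc, b2)$label == "G"
  in4 <- assign_ancestry(sc, b4)$label == "G"
  expect_true(all(in4[in2]))
  expect_gt(sum(in4), sum(in2))
})

test_that("elliptical mode assigns a strict subset of the box", {
  set.seed(341)
  sc <- scores_df(sprintf("s%03d", 1:300), rnorm(300), rnorm(300))
  lab <- rep("G", 300)
  b <- fit_ancestry_boundaries(sc, lab, k_sd = 1.5)
  box <- assign_ancestry(sc, b, mode = "box")$label == "G"
  ell <- assign_ancestry(sc, b, mode = "ellipse")$label == "G"
  expect_true(all(box[ell]))
  expect_lt(sum(ell), sum(box))
})
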