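test_that("autosome filter keeps 1..22 and matches a brute-force label scan", {
  G <- random_genotype_matrix(5, 100, seed = 21)
  chroms <- sample(c(as.character(1:22), "X", "Y", "chrX", "chr7", "MT"),
                   100, replace = TRUE)
  G$variants$chrom <- chroms
  out <- filter_autosomal(G)
  expected <- sub("^chr", "", chroms) %in% as.character(1:22)
  expect_equal(out$variants$vid, G$variants$vid[expected])
  expect_equal(unname(out$dosages), unname(G$dosages[, expected]))
  # all-autosomal input is the identity
  G2 <- random_genotype_matrix(5, 10, seed = 22)
  expect_equal(filter_autosomal(G2)$variants, G2$variants)
})

test_that("MAF filter is strict and handles monomorphic/all-missing variants", {
  d <- cbind(c(0, 0, 0, 1),      # p = 0.125 -> kept at 0.05
             c(0, 0, 0, 0),      # monomorphic -> removed
             c(NA, NA, NA, NA),  # all missing -> removed
             c(0, 0, 1, 1))      # p = 0.25 -> kept
  G <- genotype_matrix(d,
    data.frame(chrom = "1", pos = 1:4, vid = paste0("v", 1:4),
               ref = "A", alt = "G"),
    data.frame(sid = paste0("s", 1:4), site = "x", platform = "y"))
  out <- filter_maf(G, 0.05)
  expect_equal(out$variants$vid, c("v1", "v4"))
  rep <- attr(out, "qc_report")
  expect_setequal(rep$vid[rep$filter == "maf"], c("v2", "v3"))
  # boundary: p exactly at the threshold is removed (strict >)
  d2 <- matrix(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1), 10, 1)  # p = 0.05
  G2 <- genotype_matrix(d2,
    data.frame(chrom = "1", pos = 1, vid = "b", ref = "A", alt = "G"),
    data.frame(sid = paste0("s", 1:10), site = "x", platform = "y"))
  expect_equal(n_variants(filter_maf(G2, 0.05)), 0L)
})

test_that("missingness filter is strict and matches a per-variant tally", {
  G <- random_genotype_matrix(100, 50, miss_rate = 0.03, seed = 31)
  out <- filter_missingness(G, 0.02)
  expected <- colMeans(is.na(G$dosages)) < 0.02
  expect_equal(out$variants$vid, G$variants$vid[expected])
  # 1/100 kept, 3/100 removed at the default threshold
  d <- matrix(1, 100, 2)
  d[1, 1] <- NA
  d[1:3, 2] <- NA
  G2 <- genotype_matrix(d,
    data.frame(chrom = "1", pos = 1:2, vid = c("one", "three"),
               ref = "A", alt = "G"),
    data.frame(sid = paste0("s", 1:100), site = "x", platform = "y"))
  expect_equal(filter_missingness(G2, 0.02)$variants$vid, "one")
})

test_that("duplicated nearby variants are pruned; orthogonal ones are kept", {
  d <- cbind(c(0, 1, 2, 1), c(0, 1, 2, 1), c(0, 1, 0, 1))
  G <- genotype_matrix(d,
    data.frame(chrom = "1", pos = c(1000, 2000, 3000),
               vid = c("a", "dup_of_a", "other"), ref = "A", alt = "G"),
    data.frame(sid = paste0("s", 1:4), site = "x", platform = "y"))
  out <- ld_prune(G, 0.5, 500000)
  expect_equal(out$variants$vid, c("a", "other"))
  # independent variants survive: orthogonal dosage vectors have r = 0
  d2 <- cbind(c(0, 2, 0, 2), c(0, 0, 2, 2))
  G2 <- genotype_matrix(d2,
    data.frame(chrom = "1", pos = c(1000, 2000), vid = c("p", "q"),
               ref = "A", alt = "G"),
    data.frame(sid = paste0("s", 1:4), site = "x", platform = "y"))
  expect_equal(n_variants(ld_prune(G2, 0.5, 500000)), 2L)
})

test_that("ld_prune matches the exhaustive-pairwise greedy oracle", {
  for (seed in 1:10) {
    G <- random_genotype_matrix(10, 30, miss_rate = 0.05, seed = seed,
                                n_chrom = 2, chrom_length = 5e4)
    out <- ld_prune(G, 0.5, 2e4)
    expect_equal(sort(out$variants$vid), prune_oracle(G, 0.5, 2e4),
                 label = paste("seed", seed))
  }
})

test_that("no retained pair within the window exceeds the r threshold", {
  G <- random_genotype_matrix(30, 60, seed = 77, n_chrom = 2,
                              chrom_length = 5e4)
  # plant some duplicates to give the pruner work
  G$dosages[, 5] <- G$dosages[, 4]
  G$dosages[, 20] <- 2 - G$dosages[, 19]
  out <- ld_prune(G, 0.5, 2e4)
  v <- out$variants
  for (i in seq_len(n_variants(out))) {
    for (j in seq_len(i - 1)) {
      if (v$chrom[i] != v$chrom[j]) next
      if (abs(v$pos[i] - v$pos[j]) > 2e4) next
      r <- suppressWarnings(cor(out$dosages[, i], out$dosages[, j],
                                use = "pairwise.complete.obs"))
      if (!is.na(r)) expect_lte(abs(r), 0.5)
    }
  }
})

test_that("zero-variance variants never trigger removal and are flagged", {
  d <- cbind(c(1, 1, 1, 1), c(0, 1, 2, 1))
  G <- genotype_matrix(d,
    data.frame(chrom = "1", pos = c(1000, 1500), vid = c("flat", "ok"),
               ref = "A", alt = "G"),
    data.frame(sid = paste0("s", 1:4), site = "x", platform = "y"))
  out <- ld_prune(G, 0.5, 500000)
  expect_equal(n_variants(out), 2L)
  expect_equal(attr(out, "ld_flags"), "flat")
})

test_that("exclusion regions: containment, identity, and interval oracle", {
  G <- random_genotype_matrix(4, 200, seed = 41, n_chrom = 3,
                              chrom_length = 4e7)
  regions <- data.frame(chrom = c("1", "2"), start = c(5e6, 1e7),
                        end = c(8e6, 3e7), label = c("r1", "r2"))
  out <- exclude_regions(G, regions)
  inside <- mapply(function(chr, pos) {
    any(regions$chrom == chr & pos >= regions$start & pos <= regions$end)
  }, G$variants$chrom, G$variants$pos)
  expect_equal(out$variants$vid, G$variants$vid[!inside])
  expect_equal(attr(out, "region_report")$n_removed, unname(
    c(sum(inside & G$variants$chrom == "1"), sum(inside & G$variants$chrom == "2"))))
  # HLA-style containment and the empty-list identity
  G6 <- G
  G6$variants$chrom[1] <- "6"; G6$variants$pos[1] <- 30000000L
  G6 <- genotype_matrix(G6$dosages, G6$variants, G6$samples)
  expect_false("6" %in% exclude_regions(G6, default_exclusion_regions())$variants$chrom)
  none <- exclude_regions(G, regions[0, ])
  expect_equal(none$variants$vid, G$variants$vid)
})

test_that("BED input is converted from 0-based half-open coordinates", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("6\t25000000\t35000000\tHLA", f)
  r <- read_bed_regions(f)
  expect_equal(r$start, 25000001L)
  expect_equal(r$end, 35000000L)
  expect_equal(r$label, "HLA")
})

test_that("autosome and MAF filters commute", {
  G <- random_genotype_matrix(20, 80, miss_rate = 0.02, seed = 51)
  G$variants$chrom <- sample(c("1", "2", "X"), 80, replace = TRUE)
  a <- filter_maf(filter_autosomal(G), 0.2)
  b <- filter_autosomal(filter_maf(G, 0.2))
  expect_equal(a$variants$vid, b$variants$vid)
  expect_equal(unname(a$dosages), unname(b$dosages))
})

test_that("filters never alter survivors' dosages", {
  G <- random_genotype_matrix(15, 40, miss_rate = 0.05, seed = 61)
  out <- apply_variant_qc(G, qc_thresholds(ld_window_bp = 1e5), regions = NULL)
  hit <- match(out$variants$vid, G$variants$vid)
  expect_false(anyNA(hit))
  expect_equal(unname(out$dosages), unname(G$dosages[, hit]))
})
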