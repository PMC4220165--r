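test_that("Balding-Nichols frequency draws have the right moments", {
  cfg <- sim_config(n_pops = 2, fst = 0.1, n_variants = 10000, seed = 7,
                    freq_range = c(0.5, 0.5))
  fr <- simulate_frequencies(cfg)
  expect_equal(fr$p_anc, rep(0.5, 10000))
  # var(p_k) = p (1 - p) F = 0.025 at p = 0.5, F = 0.1; moment check at 5%
  v <- apply(fr$p_pop, 2, var)
  expect_lt(max(abs(v - 0.025) / 0.025), 0.05)
  expect_lt(abs(mean(fr$p_pop) - 0.5), 0.01)
})

test_that("small F concentrates population frequencies at the ancestral value", {
  cfg <- sim_config(n_pops = 1, fst = 0.001, n_variants = 2000, seed = 8)
  fr <- simulate_frequencies(cfg)
  expect_lt(max(abs(fr$p_pop[, 1] - fr$p_anc)), 0.15)
  expect_lt(sd(fr$p_pop[, 1] - fr$p_anc), 0.02)
})

test_that("variant map is sorted, unique, and free of strand-ambiguous pairs", {
  cfg <- sim_config(n_variants = 3000, seed = 9)
  v <- simulate_frequencies(cfg)$variants
  expect_false(any(duplicated(v$vid)))
  for (chr in unique(v$chrom))
    expect_true(!is.unsorted(v$pos[v$chrom == chr], strictly = TRUE))
  comp <- chartr("ACGT", "TGCA", v$alt)
  expect_false(any(v$ref == comp))
})

test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- sim_config(n_variants = 400, n_samples = 80, seed = 10,
                    platform_missing = c(chipA = 0, chipB = 0.05))
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$truth, b$truth)
  p1 <- simulate_reference_panel(cfg, 20)
  p2 <- simulate_reference_panel(cfg, 20)
  expect_identical(p1$dosages, p2$dosages)
})

test_that("artifact bookkeeping exactly identifies the perturbed variants", {
  cfg <- sim_config(n_variants = 1000, n_samples = 200, seed = 11,
                    platform_affected_fraction = 0.2)
  fr <- simulate_frequencies(cfg)
  sim <- simulate_cohort(cfg, fr)
  clean_cfg <- sim_config(n_variants = 1000, n_samples = 200, seed = 11,
                          platform_error = c(chipA = 0, chipB = 0))
  clean <- simulate_cohort(clean_cfg, fr)
  expect_equal(length(sim$truth$artifact_variants), 200L)
  differs <- which(colSums(sim$genotypes$dosages != clean$genotypes$dosages) > 0)
  differ_vids <- sim$genotypes$variants$vid[differs]
  expect_true(all(differ_vids %in% sim$truth$miscoded$chipB))
  expect_setequal(sim$truth$miscoded$chipB, differ_vids)
  # only chipB samples are touched
  chipA_rows <- sim$genotypes$samples$platform == "chipA"
  expect_identical(sim$genotypes$dosages[chipA_rows, ],
                   clean$genotypes$dosages[chipA_rows, ])
})

test_that("configured F_ST is recovered by the Hudson estimator", {
  cfg <- sim_config(n_variants = 5000, n_samples = 400, seed = 12,
                    platform_error = c(chipA = 0, chipB = 0))
  sim <- simulate_cohort(cfg)
  fst <- hudson_fst(sim$genotypes, sim$truth$pop)
  expect_lt(abs(fst - 0.1), 0.02)
})

test_that("panel and cohort share variant keys; empty panel request errors", {
  cfg <- sim_config(n_variants = 300, n_samples = 50, seed = 13)
  fr <- simulate_frequencies(cfg)
  sim <- simulate_cohort(cfg, fr)
  panel <- simulate_reference_panel(cfg, n_per_pop = 10, freqs = fr)
  expect_identical(panel$variants$vid, sim$genotypes$variants$vid)
  expect_error(simulate_reference_panel(cfg, n_per_pop = 0), ">= 1")
})

test_that("a single population with no artifacts shows no PC1 structure", {
  cfg <- sim_config(n_pops = 1, fst = 0.1, n_variants = 1200, n_samples = 100,
                    platforms = "chipA", platform_error = c(chipA = 0),
                    seed = 14)
  sim <- simulate_cohort(cfg)
  G <- filter_maf(sim$genotypes, 0.05)
  m <- fit_pca(G, k = 3)
  # variance explained by PC1 stays at the 1/(n-1) noise-floor scale
  expect_lt(m$variance_explained[1], 3 / (100 - 1))
})

test_that("admixed samples land between the parental clusters on PC1", {
  cfg <- sim_config(n_variants = 2000, n_samples = 200, seed = 15,
                    platform_error = c(chipA = 0, chipB = 0),
                    admixed = list(n = 40, parents = c(1, 2), alpha = c(2, 2)))
  sim <- simulate_cohort(cfg)
  G <- filter_maf(sim$genotypes, 0.05)
  m <- fit_pca(G, k = 2)
  pc1 <- m$sample_scores[, 1]
  lab <- sim$truth$pop
  lo <- min(mean(pc1[lab == "POP1"]), mean(pc1[lab == "POP2"]))
  hi <- max(mean(pc1[lab == "POP1"]), mean(pc1[lab == "POP2"]))
  admix_mean <- mean(pc1[lab == "Admixed"])
  expect_gt(admix_mean, lo)
  expect_lt(admix_mean, hi)
  expect_equal(sum(is.na(sim$truth$admix_prop)), 200L)
})

test_that("null phenotype matches its prevalence; confounded model links site", {
  cfg <- sim_config(n_variants = 10, n_samples = 2000, seed = 16)
  sim <- simulate_cohort(cfg)
  ph0 <- simulate_phenotype(sim$genotypes$samples, "null", b0 = -1, seed = 16)
  expect_lt(abs(mean(ph0$phenotype) - plogis(-1)), 0.03)
  ph1 <- simulate_phenotype(sim$genotypes$samples, "confounded", b_site = 2,
                            seed = 16)
  prev <- tapply(ph1$phenotype, ph1$site, mean)
  expect_gt(abs(diff(prev)), 0.2)
})

test_that("per-platform missingness masks only the affected variants of that platform", {
  cfg <- sim_config(n_variants = 600, n_samples = 120, seed = 17,
                    platform_error = c(chipA = 0, chipB = 0),
                    platform_missing = c(chipA = 0, chipB = 0.2))
  sim <- simulate_cohort(cfg)
  G <- sim$genotypes
  aff <- G$variants$vid %in% sim$truth$artifact_variants
  chipB <- G$samples$platform == "chipB"
  expect_equal(sum(is.na(G$dosages[!chipB, ])), 0L)
  expect_equal(sum(is.na(G$dosages[chipB, !aff])), 0L)
  miss_rate <- mean(is.na(G$dosages[chipB, aff]))
  expect_gt(miss_rate, 0.15); expect_lt(miss_rate, 0.25)
})

test_that("injected LD block creates near-duplicate variants dominating PC1", {
  cfg <- sim_config(n_pops = 1, fst = 0.1, n_variants = 800, n_samples = 150,
                    platforms = "chipA", platform_error = c(chipA = 0),
                    n_chrom = 1, chrom_length = 4e7, seed = 18)
  sim <- simulate_cohort(cfg)
  inj <- inject_ld_block(sim$genotypes, "1", 1e7, 1.2e7, seed = 18)
  G <- inj$genotypes
  idx <- match(inj$block$vids, G$variants$vid)
  expect_gt(length(idx), 2)
  cors <- cor(G$dosages[, idx])
  expect_gt(min(abs(cors)), 0.8)
  m <- fit_pca(filter_maf(G, 0.05), k = 2)
  tr <- pc_genotype_correlation(filter_maf(G, 0.05), pca_scores(m), 1)
  block_corr <- mean(tr$abs_corr[tr$vid %in% inj$block$vids], na.rm = TRUE)
  expect_gt(block_corr, 5 * mean(tr$abs_corr, na.rm = TRUE))
})
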