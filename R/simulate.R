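## Synthetic multi-site, multi-platform structured genotype cohorts under the
## Balding-Nichols model. This is the test bed for the whole package: every
## qualitative claim about stratification and platform bias is exercised
## against data whose ground truth is known.

# named substreams of the global seed: each stage draws from its own stream
# so individual stages are reproducible in isolation
sub_seed <- function(seed, name) {
  (as.integer(seed) %% 100000L) + 1000L * (sum(utf8ToInt(name)) %% 20000L)
}

#' Simulation configuration
#'
#' Defaults encode the canonical platform-bias scenario: two populations at
#' F_ST = 0.1, 5,000 variants, 600 samples split over two recruitment sites,
#' each site genotyped exclusively on its own platform (platform fully
#' confounded with site), population membership balanced across sites, and a
#' platform artifact on the second platform affecting 20% of variants at an
#' error rate of 0.05.
#'
#' The artifact model (`error_model`): with `"miscode"` (default), each
#' affected variant is, with probability equal to the platform error rate,
#' systematically allele-miscoded on that platform (`d -> 2 - d` for every
#' sample genotyped on it) — probe-level miscoding, the way real array
#' batch effects act. With `"noise"`, each genotype of the platform at an
#' affected variant is independently perturbed by ±1 (clipped to [0, 2])
#' with that probability — random error, which raises variance but creates
#' almost no mean displacement and is essentially invisible to PCA.
#'
#' @param n_pops number of discrete populations
#' @param fst Balding-Nichols F per population (scalar recycled), in (0, 1)
#' @param n_variants number of bi-allelic variants M
#' @param freq_range range of the ancestral allele frequency (uniform draw)
#' @param n_samples total cohort size (used when `cells` is NULL)
#' @param platforms platform labels; default `chipA`, `chipB`
#' @param sites site labels; default one site per platform
#' @param cells explicit design: data.frame (pop, site, platform, n) samples
#'   per cell; overrides the balanced default
#' @param admixed NULL, or `list(n =, parents = c(i, j), alpha = c(a, b))`
#'   for an admixed group whose proportion from parent i is Beta(a, b)
#' @param platform_error per-platform genotype error rate, named vector;
#'   default 0 on the first platform and 0.05 on the others
#' @param platform_missing per-platform missing-call rate on affected
#'   variants; default 0
#' @param platform_affected_fraction fraction of variants subject to
#'   platform artifacts
#' @param error_model `"miscode"` or `"noise"` (see Details)
#' @param n_chrom,chrom_length genome layout for variant positions
#' @param pheno_model `"null"` or `"confounded"` (see
#'   [simulate_phenotype()])
#' @param seed global seed; fixes every draw via named substreams
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_pops = 2, fst = 0.1, n_variants = 5000,
                       freq_range = c(0.1, 0.9), n_samples = 600,
                       platforms = c("chipA", "chipB"), sites = NULL,
                       cells = NULL, admixed = NULL,
                       platform_error = NULL, platform_missing = NULL,
                       platform_affected_fraction = 0.2,
                       error_model = c("miscode", "noise"),
                       n_chrom = 22, chrom_length = 120000000L,
                       pheno_model = c("null", "confounded"), seed = 1) {
  error_model <- match.arg(error_model)
  pheno_model <- match.arg(pheno_model)
  fst <- rep(fst, length.out = n_pops)
  stopifnot(all(fst > 0 & fst < 1), n_variants > 0, n_pops >= 1,
            platform_affected_fraction >= 0, platform_affected_fraction < 1)
  if (is.null(sites)) sites <- paste0("site", seq_along(platforms))
  if (is.null(cells)) {
    grid <- expand.grid(pop = seq_len(n_pops), si = seq_along(sites))
    per <- floor(n_samples / nrow(grid))
    nvec <- rep(per, nrow(grid))
    extra <- n_samples - sum(nvec)
    if (extra > 0) nvec[seq_len(extra)] <- nvec[seq_len(extra)] + 1L
    cells <- data.frame(pop = grid$pop, site = sites[grid$si],
                        platform = platforms[((grid$si - 1) %% length(platforms)) + 1],
                        n = nvec, stringsAsFactors = FALSE)
  }
  stopifnot(all(cells$n >= 0), all(cells$pop %in% seq_len(n_pops)))
  if (is.null(platform_error)) {
    platform_error <- stats::setNames(c(0, rep(0.05, length(platforms) - 1)),
                                      platforms)
  }
  if (is.null(platform_missing))
    platform_missing <- stats::setNames(rep(0, length(platforms)), platforms)
  stopifnot(all(platform_error >= 0 & platform_error < 1),
            all(platform_missing >= 0 & platform_missing < 1))
  structure(list(
    n_pops = n_pops, fst = fst, n_variants = as.integer(n_variants),
    freq_range = freq_range, platforms = platforms, sites = sites,
    cells = cells, admixed = admixed,
    platform_error = platform_error, platform_missing = platform_missing,
    platform_affected_fraction = platform_affected_fraction,
    error_model = error_model, n_chrom = as.integer(n_chrom),
    chrom_length = as.integer(chrom_length), pheno_model = pheno_model,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Draw the variant map and population allele frequencies
#'
#' Ancestral frequencies are uniform on `freq_range`; each population's
#' frequency is Beta(p(1-F)/F, (1-p)(1-F)/F), the Balding-Nichols draw with
#' mean p and variance p(1-p)F. Variant positions are placed uniformly on
#' `n_chrom` chromosomes (unique within a chromosome, sorted), with
#' non-strand-ambiguous allele pairs, and variant ids follow the
#' `chrom:pos:ref:alt` convention.
#'
#' @param config a [sim_config()]
#' @return list of class `sim_freqs`: `variants` data.frame, `p_anc`
#'   (length M), `p_pop` (M x n_pops)
#' @export
simulate_frequencies <- function(config) {
  set.seed(sub_seed(config$seed, "frequencies"))
  M <- config$n_variants
  p_anc <- stats::runif(M, config$freq_range[1], config$freq_range[2])
  p_pop <- sapply(seq_len(config$n_pops), function(k) {
    f <- config$fst[k]
    stats::rbeta(M, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
  })
  p_pop <- matrix(p_pop, M, config$n_pops)
  chrom <- sort(sample(seq_len(config$n_chrom), M, replace = TRUE))
  pos <- integer(M)
  for (c in unique(chrom)) {
    idx <- which(chrom == c)
    pos[idx] <- sort(sample.int(config$chrom_length, length(idx)))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, M, replace = TRUE)
  alt <- vapply(ref, function(r) {
    sample(setdiff(bases, c(r, comp_allele(r))), 1)
  }, character(1))
  variants <- data.frame(chrom = as.character(chrom), pos = pos,
                         vid = paste(chrom, pos, ref, alt, sep = ":"),
                         ref = ref, alt = alt, stringsAsFactors = FALSE)
  structure(list(variants = variants, p_anc = p_anc, p_pop = p_pop),
            class = "sim_freqs")
}

draw_genotypes <- function(p_eff_rows) {
  # p_eff_rows: n x M matrix of per-sample per-variant alt frequencies
  n <- nrow(p_eff_rows); M <- ncol(p_eff_rows)
  matrix(stats::rbinom(n * M, 2, p_eff_rows), n, M)
}

#' Simulate the study cohort
#'
#' Genotypes are Binomial(2, p) draws from each sample's population
#' frequencies (admixed samples use the mixture frequency of their parental
#' populations at their individual admixture proportion). Site and platform
#' labels follow the design `cells` — deliberately confounded when the
#' design says so. Platform artifacts (per [sim_config()]'s error model)
#' and per-platform missingness are then applied to the affected variant
#' subset.
#'
#' @param config a [sim_config()]
#' @param freqs frequencies from [simulate_frequencies()]; drawn fresh when
#'   NULL
#' @return list with `genotypes` (a [genotype_matrix()]) and `truth`
#'   (per-sample population and admixture proportion; per-variant artifact
#'   flags and, per platform, the miscoded variant ids; the frequency draws)
#' @export
simulate_cohort <- function(config, freqs = NULL) {
  if (is.null(freqs)) freqs <- simulate_frequencies(config)
  set.seed(sub_seed(config$seed, "cohort"))
  cells <- config$cells
  pop <- rep(cells$pop, cells$n)
  site <- rep(cells$site, cells$n)
  platform <- rep(cells$platform, cells$n)
  admix_prop <- rep(NA_real_, length(pop))
  if (!is.null(config$admixed)) {
    ad <- config$admixed
    pop <- c(pop, rep(NA_integer_, ad$n))
    site <- c(site, rep(cells$site[1], ad$n))
    platform <- c(platform, rep(cells$platform[1], ad$n))
    admix_prop <- c(admix_prop, stats::rbeta(ad$n, ad$alpha[1], ad$alpha[2]))
  }
  n <- length(pop)
  M <- config$n_variants
  p_eff <- matrix(0, n, M)
  pure <- !is.na(pop)
  p_eff[pure, ] <- t(freqs$p_pop[, pop[pure], drop = FALSE])
  if (any(!pure)) {
    ad <- config$admixed
    w <- admix_prop[!pure]
    p_eff[!pure, ] <- outer(w, freqs$p_pop[, ad$parents[1]]) +
      outer(1 - w, freqs$p_pop[, ad$parents[2]])
  }
  dos <- draw_genotypes(p_eff)
  storage.mode(dos) <- "double"

  n_aff <- round(config$platform_affected_fraction * M)
  affected <- sort(sample.int(M, n_aff))
  miscoded <- list()
  for (P in config$platforms) {
    eps <- config$platform_error[[P]]
    rows <- which(platform == P)
    if (eps > 0 && length(rows)) {
      if (config$error_model == "miscode") {
        bad <- affected[stats::runif(n_aff) < eps]
        if (length(bad)) dos[rows, bad] <- 2 - dos[rows, bad]
        miscoded[[P]] <- freqs$variants$vid[bad]
      } else {
        for (v in affected) {
          hitr <- rows[stats::runif(length(rows)) < eps]
          if (length(hitr)) {
            shift <- sample(c(-1, 1), length(hitr), replace = TRUE)
            dos[hitr, v] <- pmin(2, pmax(0, dos[hitr, v] + shift))
          }
        }
        miscoded[[P]] <- freqs$variants$vid[affected]
      }
    }
    mrate <- config$platform_missing[[P]]
    if (mrate > 0 && length(rows)) {
      mask <- matrix(stats::runif(length(rows) * n_aff) < mrate,
                     length(rows), n_aff)
      block <- dos[rows, affected, drop = FALSE]
      block[mask] <- NA_real_
      dos[rows, affected] <- block
    }
  }
  ancestry <- ifelse(is.na(pop), "Admixed", paste0("POP", pop))
  samples <- data.frame(
    sid = sprintf("S%05d", seq_len(n)),
    site = site, platform = platform, ancestry = ancestry,
    sex = sample(c("female", "male"), n, replace = TRUE),
    phenotype = NA_real_, stringsAsFactors = FALSE)
  G <- genotype_matrix(dos, freqs$variants, samples)
  truth <- list(pop = ancestry, admix_prop = admix_prop,
                artifact_variants = freqs$variants$vid[affected],
                miscoded = miscoded,
                p_anc = freqs$p_anc, p_pop = freqs$p_pop)
  list(genotypes = G, truth = truth)
}

#' Simulate an artifact-free reference panel
#'
#' Clean genotypes drawn from the same population frequencies as the study
#' cohort (pass the same `freqs`), with no platform error or missingness —
#' the stand-in for an external imputation reference panel. Samples are
#' labelled `site = platform = "reference"`.
#'
#' @param config a [sim_config()]
#' @param n_per_pop panel samples per population (must be >= 1)
#' @param freqs frequencies shared with the cohort
#' @return a [genotype_matrix()]
#' @export
simulate_reference_panel <- function(config, n_per_pop = 100, freqs = NULL) {
  if (n_per_pop < 1) stop("n_per_pop must be >= 1")
  if (is.null(freqs)) freqs <- simulate_frequencies(config)
  set.seed(sub_seed(config$seed, "panel"))
  pop <- rep(seq_len(config$n_pops), each = n_per_pop)
  p_eff <- t(freqs$p_pop[, pop, drop = FALSE])
  dos <- draw_genotypes(p_eff)
  storage.mode(dos) <- "double"
  samples <- data.frame(
    sid = sprintf("R%05d", seq_along(pop)),
    site = "reference", platform = "reference",
    ancestry = paste0("POP", pop), sex = NA_character_,
    phenotype = NA_real_, stringsAsFactors = FALSE)
  genotype_matrix(dos, freqs$variants, samples)
}

#' Simulate a binary phenotype with covariates
#'
#' Under the null model the phenotype is Bernoulli(plogis(b0)) independent
#' of genotype, site and platform. Under the confounded model the linear
#' predictor is `b0 + b_site * (site index - 1)`, making site (and any
#' platform confounded with it) a phenotype confounder. Age and a sex
#' indicator are returned as nuisance covariates.
#'
#' @param samples the `samples` data.frame of a cohort
#' @param model `"null"` or `"confounded"`
#' @param b0 intercept (log-odds); 0 gives 50% prevalence under the null
#' @param b_site site effect on the log-odds scale (confounded model)
#' @param seed substream seed
#' @return data.frame (sid, phenotype, age, sex_num, site)
#' @export
simulate_phenotype <- function(samples, model = c("null", "confounded"),
                               b0 = 0, b_site = 1, seed = 1) {
  model <- match.arg(model)
  set.seed(sub_seed(seed, "phenotype"))
  n <- nrow(samples)
  eta <- rep(b0, n)
  if (model == "confounded")
    eta <- eta + b_site * (as.integer(factor(samples$site)) - 1)
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  sex <- samples$sex
  sex[is.na(sex)] <- sample(c("female", "male"), sum(is.na(sex)), replace = TRUE)
  data.frame(sid = samples$sid, phenotype = y,
             age = round(stats::rnorm(n, 55, 10), 1),
             sex_num = as.numeric(sex == "female"),
             site = samples$site, stringsAsFactors = FALSE)
}

#' Inject a block of near-duplicate variants (local LD artifact)
#'
#' Replaces the dosages of every variant inside the given interval with
#' near-copies of a template variant from that interval (the one with MAF
#' closest to 0.5): each copy equals the template except at a small fraction
#' of genotypes that are redrawn at the template's allele frequency. The
#' block mimics an inversion- or HLA-like region of extreme local LD that
#' captures a principal component.
#'
#' @param G a [genotype_matrix()]
#' @param chrom,start,end interval (1-based inclusive) to convert
#' @param mutation_rate per-genotype probability of deviating from the
#'   template
#' @param seed substream seed
#' @return list with modified `genotypes` and `block` (chrom, start, end,
#'   vids of the block variants)
#' @export
inject_ld_block <- function(G, chrom, start, end, mutation_rate = 0.02,
                            seed = 1) {
  set.seed(sub_seed(seed, "ldblock"))
  idx <- which(G$variants$chrom == as.character(chrom) &
                 G$variants$pos >= start & G$variants$pos <= end)
  if (length(idx) < 2) stop("fewer than 2 variants in the requested block")
  p <- alt_freq(keep_variants(G, idx))
  tmpl_j <- idx[which.min(abs(p - 0.5))]
  tmpl <- G$dosages[, tmpl_j]
  tmpl[is.na(tmpl)] <- stats::rbinom(sum(is.na(tmpl)), 2, mean(tmpl, na.rm = TRUE) / 2)
  p_t <- mean(tmpl) / 2
  n <- n_samples(G)
  for (j in setdiff(idx, tmpl_j)) {
    d <- tmpl
    mut <- stats::runif(n) < mutation_rate
    d[mut] <- stats::rbinom(sum(mut), 2, p_t)
    G$dosages[, j] <- d
  }
  list(genotypes = G,
       block = list(chrom = as.character(chrom), start = start, end = end,
                    vids = G$variants$vid[idx]))
}

#' Hudson's F_ST estimator between two populations
#'
#' Ratio-of-averages form: per variant,
#' `N = (p1 - p2)^2 - p1(1-p1)/(n1 - 1) - p2(1-p2)/(n2 - 1)` and
#' `D = p1(1-p2) + p2(1-p1)` with n the allele counts; F_ST is
#' `sum(N) / sum(D)`. Under the Balding-Nichols model with both populations
#' at divergence F from the shared ancestor, the estimator recovers F.
#'
#' @param G a [genotype_matrix()]
#' @param pop per-sample labels with exactly two distinct values
#' @return estimated F_ST (scalar)
#' @export
hudson_fst <- function(G, pop) {
  lv <- unique(pop)
  if (length(lv) != 2) stop("hudson_fst needs exactly two populations")
  d1 <- G$dosages[pop == lv[1], , drop = FALSE]
  d2 <- G$dosages[pop == lv[2], , drop = FALSE]
  n1 <- 2 * colSums(!is.na(d1)); n2 <- 2 * colSums(!is.na(d2))
  p1 <- colMeans(d1, na.rm = TRUE) / 2
  p2 <- colMeans(d2, na.rm = TRUE) / 2
  ok <- n1 > 1 & n2 > 1 & is.finite(p1) & is.finite(p2)
  N <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  D <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(N[ok]) / sum(D[ok])
}
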