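## Conventional PCA on the sample variance-covariance matrix.

#' Standardize a genotype matrix for PCA
#'
#' Each variant column is centered by its mean over non-missing calls.
#' Under `"patterson"` scaling the centered column is additionally divided
#' by `sqrt(p(1-p))` with `p = mean dosage / 2`, the allele-frequency
#' standardization of the eigenanalysis literature. Missing entries are
#' replaced by 0 after centering (mean imputation), which preserves column
#' means.
#'
#' @param G a [genotype_matrix()]
#' @param scaling `"patterson"` (default) or `"center_only"`
#' @return list with `Z` (samples x variants standardized matrix), `means`,
#'   `scales`
#' @export
standardize_genotypes <- function(G, scaling = c("patterson", "center_only")) {
  scaling <- match.arg(scaling)
  d <- G$dosages
  means <- colMeans(d, na.rm = TRUE)
  if (scaling == "patterson") {
    p_hat <- means / 2
    scales <- sqrt(p_hat * (1 - p_hat))
    if (any(!is.finite(scales)) || any(scales == 0))
      stop("zero-variance (monomorphic) variants present; apply filter_maf() ",
           "before Patterson scaling")
  } else {
    scales <- rep(1, ncol(d))
  }
  Z <- sweep(d, 2, means, "-")
  Z[is.na(Z)] <- 0
  Z <- sweep(Z, 2, scales, "/")
  list(Z = Z, means = means, scales = scales)
}

# deterministic sign convention: the loading entry of largest magnitude is
# made positive (component signs are otherwise arbitrary)
fix_component_signs <- function(loadings, scores) {
  for (l in seq_len(ncol(loadings))) {
    j <- which.max(abs(loadings[, l]))
    if (loadings[j, l] < 0) {
      loadings[, l] <- -loadings[, l]
      scores[, l] <- -scores[, l]
    }
  }
  list(loadings = loadings, scores = scores)
}

#' Principal component analysis of a genotype matrix
#'
#' Eigendecomposition of the samples x samples covariance of the
#' standardized genotype matrix. Sample scores are the projections of the
#' standardized data onto the variant-space eigenvectors (the SNP loadings);
#' the two decompositions are mathematically equivalent and the loadings are
#' recovered from the sample-space factors. Eigenvalues are reported on the
#' sample-covariance scale (divided by n - 1) and variance-explained
#' fractions are eigenvalues over the covariance trace, so they sum to one
#' over all components.
#'
#' @param G a [genotype_matrix()]
#' @param k number of components to retain (default 10; the first ten are
#'   usually the useful ones)
#' @param scaling passed to [standardize_genotypes()]
#' @return object of class `pca_model`: eigenvalues, `sample_scores`
#'   (n x k, rownames sid), `snp_loadings` (M x k orthonormal columns,
#'   rownames vid), `variant_means`, `variant_scales`,
#'   `variance_explained` (length k), `total_variance`, `scaling`
#' @export
fit_pca <- function(G, k = 10, scaling = c("patterson", "center_only")) {
  scaling <- match.arg(scaling)
  n <- n_samples(G); M <- n_variants(G)
  if (k > min(n - 1, M))
    stop("k = ", k, " exceeds min(samples - 1, variants) = ", min(n - 1, M))
  std <- standardize_genotypes(G, scaling)
  Z <- std$Z
  C <- tcrossprod(Z)              # n x n, unnormalized
  eig <- eigen(C, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  total <- sum(ev)
  d <- sqrt(ev[seq_len(k)])
  if (any(d < 1e-10 * max(d, 1)))
    warning("requested components beyond numerical rank; trailing scores are ~0")
  U <- eig$vectors[, seq_len(k), drop = FALSE]
  scores <- U %*% diag(d, k)
  loadings <- crossprod(Z, U)     # M x k, = V * d
  pos <- d > 1e-12 * max(d, 1)
  loadings[, pos] <- sweep(loadings[, pos, drop = FALSE], 2, d[pos], "/")
  loadings[, !pos] <- 0
  fx <- fix_component_signs(loadings, scores)
  rownames(fx$scores) <- G$samples$sid
  rownames(fx$loadings) <- G$variants$vid
  colnames(fx$scores) <- colnames(fx$loadings) <- paste0("PC", seq_len(k))
  structure(list(
    k = k,
    eigenvalues = ev[seq_len(k)] / (n - 1),
    sample_scores = fx$scores,
    snp_loadings = fx$loadings,
    variant_means = stats::setNames(std$means, G$variants$vid),
    variant_scales = stats::setNames(std$scales, G$variants$vid),
    variance_explained = ev[seq_len(k)] / total,
    total_variance = total / (n - 1),
    scaling = scaling
  ), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("pca_model (", x$scaling, "): ", nrow(x$sample_scores), " samples, ",
      nrow(x$snp_loadings), " variants, k = ", x$k, "\n", sep = "")
  cat("variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = " "), "\n")
  invisible(x)
}

#' Scree table: variance explained per component
#'
#' @param model a `pca_model` (or `reference_model`)
#' @param n number of leading components to report (default all fitted)
#' @return data.frame (component, variance_explained)
#' @export
scree <- function(model, n = model$k) {
  stopifnot(n <= model$k)
  data.frame(component = seq_len(n),
             variance_explained = model$variance_explained[seq_len(n)])
}

#' Write PC scores or SNP loadings as TSV
#'
#' @param x matrix with rownames (sid or vid) and PC columns
#' @param path output file
#' @param id_col name of the identifier column
#' @return invisibly, `path`
#' @export
write_scores <- function(x, path, id_col = "sid") {
  df <- data.frame(id = rownames(x), as.data.frame(x), check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
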