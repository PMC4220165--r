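## Reference-panel "loadings" method: derive SNP loadings from an external
## (artifact-free) panel and project every study sample onto them. Study-side
## artifacts that are not present in the panel cannot enter the loadings, so
## the projected components carry ancestry but not platform or site batch
## structure.

REFERENCE_MODEL_VERSION <- "pcstrat_reference_model v1"

#' Fit a reference PCA model (SNP loadings) from a panel
#'
#' The variance-covariance matrix of the panel's centered genotypes is
#' eigendecomposed; the top-k variant-space eigenvectors `e_l` are the SNP
#' loadings. The decomposition is performed in sample space (B x B) and the
#' loadings recovered from it — the two are equivalent, and B is typically
#' much smaller than the number of markers. The default scaling is plain
#' covariance (`center_only`), matching the method's formulation; the
#' eigenvalues are stored normalized by B. Variants with zero variance in
#' the panel carry no loading information and are dropped with a warning.
#'
#' @param G_ref panel [genotype_matrix()] of B unrelated samples
#' @param k number of components, `k <= min(B - 1, M)`
#' @param scaling `"center_only"` (default) or `"patterson"`
#' @return object of class `reference_model`: `variant_keys` (chrom, pos,
#'   ref, alt, vid), `ref_means`, `ref_scales`, `loadings` (M x k,
#'   orthonormal columns), `eigenvalues`, `variance_explained`, `B`, `k`
#' @export
fit_reference <- function(G_ref, k = 10, scaling = c("center_only", "patterson")) {
  scaling <- match.arg(scaling)
  B <- n_samples(G_ref)
  zero_var <- apply(G_ref$dosages, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) < 2 || stats::var(x) == 0
  })
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance variant(s) dropped from reference model")
    G_ref <- keep_variants(G_ref, !zero_var)
  }
  M <- n_variants(G_ref)
  if (k > min(B - 1, M))
    stop("k = ", k, " exceeds min(B - 1, M) = ", min(B - 1, M))
  std <- standardize_genotypes(G_ref, scaling)
  Z <- std$Z
  eig <- eigen(tcrossprod(Z), symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  d <- sqrt(ev[seq_len(k)])
  U <- eig$vectors[, seq_len(k), drop = FALSE]
  loadings <- crossprod(Z, U)
  pos <- d > 1e-12 * max(d, 1)
  loadings[, pos] <- sweep(loadings[, pos, drop = FALSE], 2, d[pos], "/")
  loadings[, !pos] <- 0
  ref_scores <- U %*% diag(d, k)
  fx <- fix_component_signs(loadings, ref_scores)
  rownames(fx$loadings) <- G_ref$variants$vid
  colnames(fx$loadings) <- paste0("PC", seq_len(k))
  structure(list(
    version = REFERENCE_MODEL_VERSION,
    variant_keys = G_ref$variants[, c("chrom", "pos", "ref", "alt", "vid")],
    ref_means = stats::setNames(std$means, G_ref$variants$vid),
    ref_scales = stats::setNames(std$scales, G_ref$variants$vid),
    loadings = fx$loadings,
    eigenvalues = ev[seq_len(k)] / B,
    variance_explained = ev[seq_len(k)] / sum(ev),
    B = B, k = k, scaling = scaling
  ), class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat("reference_model (", x$scaling, "): B = ", x$B, " panel samples, ",
      nrow(x$loadings), " variants, k = ", x$k, "\n", sep = "")
  invisible(x)
}

#' Project study samples onto reference SNP loadings
#'
#' For study sample j and component l the score is the inner product
#' `t_jl = (X_j - Xbar)' e_l` of the centered (and, if the model was scaled,
#' scaled) genotype vector with the l-th loading. Study variants are matched
#' to the model on (chrom, pos) with allele harmonization as in
#' [merge_cohorts()] (swapped alleles recode dosages, strand flips do not,
#' ambiguous SNPs are dropped). The sum is restricted to matched non-missing
#' variants and rescaled by `M_model / M_used` per sample so that scores
#' remain comparable across samples with different missingness.
#'
#' @param G_study study [genotype_matrix()]
#' @param model a [fit_reference()] model
#' @param min_match minimum fraction of model variants that must match
#'   (default 0.5); below this the projection is unreliable and an error is
#'   raised
#' @return object of class `pc_scores`: data.frame `sid`, `PC1..PCk`, with
#'   attribute `source = "projection"`
#' @export
project_samples <- function(G_study, model, min_match = 0.5) {
  stopifnot(inherits(model, "reference_model"))
  mk <- model$variant_keys
  m_key <- paste(mk$chrom, mk$pos, sep = ":")
  s_key <- paste(G_study$variants$chrom, G_study$variants$pos, sep = ":")
  hit <- match(m_key, s_key)
  matched <- !is.na(hit)
  act <- rep("unmatched", nrow(mk))
  if (any(matched)) {
    sv <- G_study$variants[hit[matched], , drop = FALSE]
    act[matched] <- allele_action(mk$ref[matched], mk$alt[matched],
                                  sv$ref, sv$alt)
  }
  usable <- act %in% c("same", "swap", "flip", "flipswap")
  frac <- mean(usable)
  if (frac < min_match)
    stop(sprintf("only %.0f%% of model variants matched the study data (< %.0f%%); projection would be unreliable",
                 100 * frac, 100 * min_match))
  midx <- which(usable)
  d <- G_study$dosages[, hit[midx], drop = FALSE]
  rec <- act[midx] %in% c("swap", "flipswap")
  d[, rec] <- 2 - d[, rec]
  Z <- sweep(d, 2, model$ref_means[midx], "-")
  miss <- is.na(Z)
  Z[miss] <- 0
  Z <- sweep(Z, 2, model$ref_scales[midx], "/")
  t_scores <- Z %*% model$loadings[midx, , drop = FALSE]
  # per-sample rescale for variants that did not contribute
  M_model <- nrow(mk)
  m_used <- M_model - (M_model - length(midx)) - rowSums(miss)
  if (any(m_used == 0)) stop("a study sample has no usable matched genotypes")
  t_scores <- t_scores * (M_model / m_used)
  out <- data.frame(sid = G_study$samples$sid, t_scores,
                    stringsAsFactors = FALSE, check.names = FALSE)
  colnames(out) <- c("sid", paste0("PC", seq_len(model$k)))
  attr(out, "source") <- "projection"
  attr(out, "n_matched") <- length(midx)
  class(out) <- c("pc_scores", "data.frame")
  out
}

#' Extract conventional PCA scores in the same container
#'
#' @param model a `pca_model` from [fit_pca()]
#' @return a `pc_scores` data.frame with `source = "conventional"`
#' @export
pca_scores <- function(model) {
  out <- data.frame(sid = rownames(model$sample_scores), model$sample_scores,
                    stringsAsFactors = FALSE, check.names = FALSE)
  attr(out, "source") <- "conventional"
  class(out) <- c("pc_scores", "data.frame")
  out
}

score_matrix <- function(scores) {
  m <- as.matrix(scores[, grep("^PC", names(scores)), drop = FALSE])
  rownames(m) <- scores$sid
  m
}

## ---- model serialization -------------------------------------------------
## Single plain-text archive; numeric fields use %.17g so doubles round-trip
## exactly.

fmt_g <- function(x) sprintf("%.17g", x)

#' Save / load a reference model
#'
#' The model is written as a single plain-text archive: a version line,
#' scalar fields, the variant table (key, mean, scale), eigenvalues and a
#' dense loadings block. Doubles are written with 17 significant digits and
#' round-trip bit-exactly. Loading a file with a different version line or a
#' truncated loadings block raises an error rather than returning a partial
#' model.
#'
#' @param model a `reference_model`
#' @param path file path
#' @return `save_reference_model` invisibly returns `path`;
#'   `load_reference_model` returns the model
#' @export
save_reference_model <- function(model, path) {
  stopifnot(inherits(model, "reference_model"))
  con <- file(path, "w")
  on.exit(close(con))
  vk <- model$variant_keys
  writeLines(c(
    paste0("#", model$version),
    paste("#scaling", model$scaling),
    paste("#B", model$B),
    paste("#k", model$k),
    paste("#M", nrow(vk)),
    "##variants"), con)
  writeLines(paste(vk$vid, vk$chrom, vk$pos, vk$ref, vk$alt,
                   fmt_g(model$ref_means), fmt_g(model$ref_scales),
                   sep = "\t"), con)
  writeLines("##eigenvalues", con)
  writeLines(paste(fmt_g(model$eigenvalues), collapse = "\t"), con)
  writeLines(paste(fmt_g(model$variance_explained), collapse = "\t"), con)
  writeLines("##loadings", con)
  writeLines(apply(model$loadings, 1, function(r) paste(fmt_g(r), collapse = "\t")), con)
  invisible(path)
}

#' @rdname save_reference_model
#' @export
load_reference_model <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !identical(lines[1], paste0("#", REFERENCE_MODEL_VERSION)))
    stop("not a reference model file or version mismatch: ", path)
  hdr <- function(key) {
    ln <- grep(paste0("^#", key, " "), lines, value = TRUE)[1]
    sub(paste0("^#", key, " "), "", ln)
  }
  scaling <- hdr("scaling")
  B <- as.integer(hdr("B")); k <- as.integer(hdr("k")); M <- as.integer(hdr("M"))
  vstart <- match("##variants", lines)
  estart <- match("##eigenvalues", lines)
  lstart <- match("##loadings", lines)
  if (anyNA(c(vstart, estart, lstart))) stop("corrupt reference model file: ", path)
  vlines <- lines[(vstart + 1):(estart - 1)]
  if (length(vlines) != M) stop("truncated variant table in ", path)
  vt <- do.call(rbind, strsplit(vlines, "\t"))
  variant_keys <- data.frame(chrom = vt[, 2], pos = as.integer(vt[, 3]),
                             ref = vt[, 4], alt = vt[, 5], vid = vt[, 1],
                             stringsAsFactors = FALSE)
  eig <- as.numeric(strsplit(lines[estart + 1], "\t")[[1]])
  vexp <- as.numeric(strsplit(lines[estart + 2], "\t")[[1]])
  llines <- lines[(lstart + 1):length(lines)]
  llines <- llines[nzchar(llines)]
  if (length(llines) != M) stop("truncated loadings block in ", path)
  loadings <- do.call(rbind, lapply(strsplit(llines, "\t"), as.numeric))
  if (ncol(loadings) != k || anyNA(loadings))
    stop("corrupt loadings block in ", path)
  rownames(loadings) <- variant_keys$vid
  colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(
    version = REFERENCE_MODEL_VERSION,
    variant_keys = variant_keys[, c("chrom", "pos", "ref", "alt", "vid")],
    ref_means = stats::setNames(as.numeric(vt[, 6]), variant_keys$vid),
    ref_scales = stats::setNames(as.numeric(vt[, 7]), variant_keys$vid),
    loadings = loadings,
    eigenvalues = eig,
    variance_explained = vexp,
    B = B, k = k, scaling = scaling
  ), class = "reference_model")
}
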