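#' Construct a genotype matrix
#'
#' The central container of the package: an additively coded dosage matrix
#' (samples in rows, variants in columns, entries counting copies of the
#' alternate allele, `NA` for missing calls) together with per-variant and
#' per-sample metadata.
#'
#' @param dosages numeric matrix, samples x variants; every non-missing entry
#'   must be 0, 1 or 2.
#' @param variants data.frame with columns `chrom` (character), `pos`
#'   (1-based integer), `vid` (unique variant identifier), `ref`, `alt`
#'   (allele strings, distinct).
#' @param samples data.frame with columns `sid` (unique sample identifier),
#'   `site`, `platform`; optional `ancestry`, `sex` ("female"/"male"/NA),
#'   `phenotype` (0/1/NA) and any number of numeric covariate columns.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants, samples) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  for (col in c("ancestry", "sex", "phenotype"))
    if (is.null(samples[[col]])) samples[[col]] <- NA
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  G <- structure(
    list(dosages = dosages, variants = variants, samples = samples),
    class = "genotype_matrix"
  )
  validate_genotype_matrix(G)
}

validate_genotype_matrix <- function(G) {
  d <- G$dosages
  if (nrow(d) != nrow(G$samples))
    stop("dosage rows (", nrow(d), ") != number of samples (", nrow(G$samples), ")")
  if (ncol(d) != nrow(G$variants))
    stop("dosage columns (", ncol(d), ") != number of variants (", nrow(G$variants), ")")
  need_v <- c("chrom", "pos", "vid", "ref", "alt")
  miss <- setdiff(need_v, names(G$variants))
  if (length(miss)) stop("variants table lacks column(s): ", paste(miss, collapse = ", "))
  need_s <- c("sid", "site", "platform")
  miss <- setdiff(need_s, names(G$samples))
  if (length(miss)) stop("samples table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(G$samples$sid)) stop("sample identifiers must be unique")
  if (anyDuplicated(G$variants$vid)) stop("variant identifiers must be unique")
  if (nrow(G$variants) && any(G$variants$pos < 1L, na.rm = TRUE))
    stop("variant positions must be >= 1")
  if (nrow(G$variants) && any(G$variants$ref == G$variants$alt))
    stop("ref and alt alleles must differ")
  ok <- is.na(d) | d == 0 | d == 1 | d == 2
  if (!all(ok)) stop("non-missing dosages must be 0, 1 or 2")
  rownames(G$dosages) <- G$samples$sid
  colnames(G$dosages) <- G$variants$vid
  G
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", n_samples(x), " samples x ", n_variants(x),
      " variants\n", sep = "")
  if (n_variants(x)) {
    mr <- mean(is.na(x$dosages))
    cat("  chromosomes: ", paste(unique(x$variants$chrom), collapse = ","),
        "\n  missing calls: ", sprintf("%.2f%%", 100 * mr), "\n", sep = "")
  }
  invisible(x)
}

#' Number of samples / variants in a genotype matrix
#' @param G a `genotype_matrix`
#' @return integer count
#' @export
n_samples <- function(G) nrow(G$dosages)

#' @rdname n_samples
#' @export
n_variants <- function(G) ncol(G$dosages)

#' Subset a genotype matrix by variant or sample index
#'
#' Metadata rows are kept in step with the dosage matrix; dosages of the
#' survivors are never altered.
#'
#' @param G a `genotype_matrix`
#' @param idx logical or integer index over variants (samples for
#'   `keep_samples`)
#' @return a `genotype_matrix`
#' @export
keep_variants <- function(G, idx) {
  G$dosages <- G$dosages[, idx, drop = FALSE]
  G$variants <- G$variants[idx, , drop = FALSE]
  rownames(G$variants) <- NULL
  G
}

#' @rdname keep_variants
#' @export
keep_samples <- function(G, idx) {
  G$dosages <- G$dosages[idx, , drop = FALSE]
  G$samples <- G$samples[idx, , drop = FALSE]
  rownames(G$samples) <- NULL
  G
}

#' Alternate-allele frequency per variant
#'
#' Computed over non-missing calls; a variant with all calls missing yields
#' `NaN`.
#'
#' @param G a `genotype_matrix`
#' @return numeric vector, one frequency per variant
#' @export
alt_freq <- function(G) colMeans(G$dosages, na.rm = TRUE) / 2

#' Missing-call fraction per variant
#' @param G a `genotype_matrix`
#' @return numeric vector in `[0,1]`
#' @export
variant_missingness <- function(G) colMeans(is.na(G$dosages))

#' Attach a sample metadata table to a genotype matrix
#'
#' Joins on `sid`; metadata columns overwrite same-named columns already
#' present. Samples absent from the table keep their existing metadata.
#'
#' @param G a `genotype_matrix`
#' @param meta data.frame with an `sid` column (e.g. from
#'   [read_sample_metadata()])
#' @return a `genotype_matrix`
#' @export
attach_metadata <- function(G, meta) {
  stopifnot(is.data.frame(meta), "sid" %in% names(meta))
  hit <- match(G$samples$sid, meta$sid)
  for (col in setdiff(names(meta), "sid")) {
    cur <- G$samples[[col]]
    if (is.null(cur)) cur <- rep(NA, n_samples(G))
    repl <- meta[[col]][hit]
    cur[!is.na(hit)] <- repl[!is.na(hit)]
    G$samples[[col]] <- cur
  }
  G
}
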