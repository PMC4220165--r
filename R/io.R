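#' Read genotypes from standard text formats
#'
#' Supported dialects: VCF 4.x (GT field only), PLINK text `.ped`/`.map`,
#' PLINK `.raw` (the `--recode A` additive table), and a plain dosage TSV
#' (samples in rows, first column `sid`, remaining header of variant ids).
#' Dosages are additively coded as the number of alternate-allele copies;
#' missing calls become `NA`. Variant order is preserved as on disk.
#'
#' Formats that do not carry full variant annotation (`plink_raw`, `tsv`,
#' and the allele-less `.map`) recover `chrom`, `pos`, `ref`, `alt` from the
#' variant id when it follows the `chrom:pos:ref:alt` convention; otherwise
#' placeholder annotation is used (`chrom = "0"`). For `.ped` input, which
#' does not designate a reference allele, the minor allele observed in the
#' file is coded as alt (tie broken alphabetically, the first allele being
#' ref) — see the package vignette.
#'
#' @param path input file; for `plink_ped` the `.ped` file with its `.map`
#'   alongside.
#' @param format one of `"vcf"`, `"plink_ped"`, `"plink_raw"`, `"tsv"`.
#' @return a [genotype_matrix()]
#' @export
read_genotypes <- function(path, format = c("vcf", "plink_ped", "plink_raw", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    vcf = read_vcf_genotypes(path),
    plink_ped = read_ped_genotypes(path),
    plink_raw = read_raw_genotypes(path),
    tsv = read_tsv_genotypes(path)
  )
}

#' Write genotypes to a standard text format
#'
#' Output is re-readable by [read_genotypes()] with identical dosages and
#' identifiers, and is byte-stable: the same matrix always produces the same
#' bytes (no timestamps).
#'
#' @param G a [genotype_matrix()]
#' @param path output file; for `plink_ped` the `.ped` path (the `.map` is
#'   written alongside).
#' @inheritParams read_genotypes
#' @return invisibly, `path`
#' @export
write_genotypes <- function(G, path, format = c("vcf", "plink_ped", "plink_raw", "tsv")) {
  format <- match.arg(format)
  switch(format,
    vcf = write_vcf_genotypes(G, path),
    plink_ped = write_ped_genotypes(G, path),
    plink_raw = write_raw_genotypes(G, path),
    tsv = write_tsv_genotypes(G, path)
  )
  invisible(path)
}

#' Read a sample metadata table
#'
#' TSV with header `sid, site, platform, ancestry, sex, phenotype`; extra
#' numeric columns are kept as covariates.
#'
#' @param path TSV file path
#' @return data.frame keyed by `sid`
#' @export
read_sample_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sid" %in% names(meta)) stop("metadata table needs an 'sid' column")
  meta$sid <- as.character(meta$sid)
  meta
}

## ---- variant-id key convention ------------------------------------------

variant_key_ids <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

variants_from_vids <- function(vids, counted_allele = NULL) {
  m <- regmatches(vids, regexec("^([^:]+):([0-9]+):([A-Za-z]+):([A-Za-z]+)$", vids))
  parsed <- lengths(m) == 5L
  chrom <- rep("0", length(vids)); pos <- seq_along(vids)
  ref <- rep("N", length(vids))
  alt <- if (is.null(counted_allele)) rep("A", length(vids)) else counted_allele
  if (any(parsed)) {
    part <- do.call(rbind, m[parsed])
    chrom[parsed] <- part[, 2]
    pos[parsed] <- as.integer(part[, 3])
    ref[parsed] <- part[, 4]
    alt[parsed] <- part[, 5]
  }
  bad <- ref == alt
  ref[bad] <- "N"
  data.frame(chrom = chrom, pos = pos, vid = vids, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

default_samples <- function(sids) {
  n <- length(sids)
  data.frame(sid = as.character(sids), site = rep("unknown", n),
             platform = rep("unknown", n), ancestry = rep(NA_character_, n),
             sex = rep(NA_character_, n), phenotype = rep(NA_real_, n),
             stringsAsFactors = FALSE)
}

## ---- VCF -----------------------------------------------------------------

read_vcf_genotypes <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  variants <- data.frame(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    vid = as.character(fix[, "ID"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    stringsAsFactors = FALSE
  )
  no_id <- is.na(variants$vid) | variants$vid == "."
  variants$vid[no_id] <- variant_key_ids(variants[no_id, , drop = FALSE])
  multi <- grepl(",", variants$alt)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic site(s) dropped")
  }
  gt_cols <- if (is.null(vcf@gt) || !ncol(vcf@gt)) 0L else max(0L, ncol(vcf@gt) - 1L)
  if (gt_cols == 0L) {
    dos <- matrix(NA_real_, 0L, nrow(variants))
    samples <- default_samples(character(0))
  } else if (nrow(variants) == 0L) {
    sids <- colnames(vcf@gt)[-1]
    dos <- matrix(NA_real_, gt_cols, 0L)
    samples <- default_samples(sids)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    gt <- matrix(gt, nrow(variants), gt_cols, dimnames = dimnames(gt))
    dos <- matrix(NA_real_, gt_cols, nrow(variants))
    for (s in seq_len(gt_cols)) dos[s, ] <- parse_gt_column(gt[, s])
    samples <- default_samples(colnames(gt))
  }
  G <- genotype_matrix(dos, variants, samples)
  if (any(multi)) G <- keep_variants(G, !multi)
  G
}

parse_gt_column <- function(gt) {
  gt[is.na(gt)] <- "./."
  out <- rep(NA_real_, length(gt))
  toks <- strsplit(gt, "[/|]")
  nall <- lengths(toks)
  if (any(nall != 2L & gt != "."))
    stop("non-diploid GT encountered: '", gt[which(nall != 2L & gt != ".")[1]], "'")
  for (i in seq_along(toks)) {
    a <- toks[[i]]
    if (length(a) == 1L && a == ".") next
    if (any(a == ".")) next
    if (!all(a %in% c("0", "1")))
      stop("unsupported GT allele code in '", gt[i], "' (bi-allelic GT only)")
    out[i] <- sum(a == "1")
  }
  out
}

write_vcf_genotypes <- function(G, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=pcstrat",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  n <- n_samples(G)
  if (n > 0) cols <- c(cols, "FORMAT", G$samples$sid)
  body <- character(0)
  if (n_variants(G) > 0) {
    v <- G$variants
    fixed <- paste(v$chrom, v$pos, v$vid, v$ref, v$alt, ".", ".", ".", sep = "\t")
    if (n > 0) {
      code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
      gt <- matrix("./.", n, n_variants(G))
      ok <- !is.na(G$dosages)
      gt[ok] <- code[as.character(G$dosages[ok])]
      gt_lines <- apply(gt, 2, paste, collapse = "\t")
      body <- paste(fixed, "GT", gt_lines, sep = "\t")
    } else body <- fixed
  }
  writeLines(c(hdr, paste(cols, collapse = "\t"), body), path)
}

## ---- PLINK .ped/.map -----------------------------------------------------

map_path_for <- function(ped_path) sub("\\.ped$", ".map", ped_path)

write_ped_genotypes <- function(G, path) {
  map_path <- map_path_for(path)
  if (identical(map_path, path)) map_path <- paste0(path, ".map")
  v <- G$variants
  writeLines(paste(v$chrom, v$vid, 0, v$pos, sep = "\t"), map_path)
  sex_code <- c(male = "1", female = "2")
  sex <- sex_code[as.character(G$samples$sex)]
  sex[is.na(sex)] <- "0"
  phe <- ifelse(is.na(G$samples$phenotype), "-9",
                ifelse(G$samples$phenotype == 1, "2", "1"))
  lines <- vapply(seq_len(n_samples(G)), function(i) {
    d <- G$dosages[i, ]
    a1 <- ifelse(is.na(d), "0", ifelse(d >= 1, v$alt, v$ref))
    a2 <- ifelse(is.na(d), "0", ifelse(d == 2, v$alt, v$ref))
    paste(c(G$samples$sid[i], G$samples$sid[i], "0", "0", sex[i], phe[i],
            rbind(a1, a2)), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

read_ped_genotypes <- function(path) {
  map_path <- map_path_for(path)
  if (!file.exists(map_path)) stop("companion .map not found: ", map_path)
  map <- utils::read.table(map_path, stringsAsFactors = FALSE,
                           col.names = c("chrom", "vid", "cm", "pos"))
  M <- nrow(map)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  a1 <- matrix("0", n, M); a2 <- matrix("0", n, M)
  sids <- character(n); sex <- character(n); phe <- numeric(n)
  for (i in seq_len(n)) {
    tok <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(tok) != 6 + 2 * M)
      stop("malformed .ped record at line ", i, ": expected ", 6 + 2 * M,
           " fields, got ", length(tok))
    sids[i] <- tok[2]
    sex[i] <- tok[5]
    phe[i] <- suppressWarnings(as.numeric(tok[6]))
    gl <- tok[-(1:6)]
    a1[i, ] <- gl[seq(1, 2 * M, by = 2)]
    a2[i, ] <- gl[seq(2, 2 * M, by = 2)]
  }
  # allele coding: alt = minor allele observed; tie -> alphabetically second
  ref <- character(M); alt <- character(M)
  dos <- matrix(NA_real_, n, M)
  for (j in seq_len(M)) {
    al <- c(a1[, j], a2[, j])
    tab <- sort(table(al[al != "0"]))
    if (length(tab) == 0L) { ref[j] <- "N"; alt[j] <- "A"; next }
    if (length(tab) == 1L) {
      ref[j] <- names(tab)
      alt[j] <- setdiff(c("A", "C", "G", "T", "N"), ref[j])[1]
    } else {
      if (length(tab) > 2L) stop("variant ", map$vid[j], " has >2 alleles")
      if (tab[[1]] == tab[[2]]) {
        ord <- sort(names(tab))
        ref[j] <- ord[1]; alt[j] <- ord[2]
      } else {
        alt[j] <- names(tab)[1]; ref[j] <- names(tab)[2]
      }
    }
    ok <- a1[, j] != "0" & a2[, j] != "0"
    dos[ok, j] <- (a1[ok, j] == alt[j]) + (a2[ok, j] == alt[j])
  }
  variants <- data.frame(chrom = as.character(map$chrom), pos = map$pos,
                         vid = map$vid, ref = ref, alt = alt,
                         stringsAsFactors = FALSE)
  samples <- default_samples(sids)
  samples$sex <- c(`1` = "male", `2` = "female")[sex]
  samples$phenotype <- ifelse(phe == 2, 1, ifelse(phe == 1, 0, NA))
  genotype_matrix(dos, variants, samples)
}

## ---- PLINK .raw ----------------------------------------------------------

write_raw_genotypes <- function(G, path) {
  v <- G$variants
  hdr <- paste(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
                 paste0(v$vid, "_", v$alt)), collapse = " ")
  sex_code <- c(male = "1", female = "2")
  sex <- sex_code[as.character(G$samples$sex)]
  sex[is.na(sex)] <- "0"
  phe <- ifelse(is.na(G$samples$phenotype), "-9",
                ifelse(G$samples$phenotype == 1, "2", "1"))
  lines <- vapply(seq_len(n_samples(G)), function(i) {
    d <- G$dosages[i, ]
    dd <- ifelse(is.na(d), "NA", format(d, trim = TRUE, scientific = FALSE))
    paste(c(G$samples$sid[i], G$samples$sid[i], "0", "0", sex[i], phe[i], dd),
          collapse = " ")
  }, character(1))
  writeLines(c(hdr, lines), path)
}

read_raw_genotypes <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty .raw file: ", path)
  hdr <- strsplit(lines[1], "[ \t]+")[[1]]
  if (length(hdr) < 6 || !identical(hdr[1:2], c("FID", "IID")))
    stop("malformed .raw header at line 1")
  vcols <- hdr[-(1:6)]
  us <- regexpr("_[^_]*$", vcols)
  vids <- ifelse(us > 0, substr(vcols, 1, us - 1), vcols)
  counted <- ifelse(us > 0, substring(vcols, us + 1), "A")
  M <- length(vids)
  body <- lines[-1]; body <- body[nzchar(body)]
  n <- length(body)
  dos <- matrix(NA_real_, n, M)
  sids <- character(n); sex <- character(n); phe <- numeric(n)
  for (i in seq_len(n)) {
    tok <- strsplit(body[i], "[ \t]+")[[1]]
    if (length(tok) != 6 + M)
      stop("malformed .raw record at line ", i + 1)
    sids[i] <- tok[2]; sex[i] <- tok[5]
    phe[i] <- suppressWarnings(as.numeric(tok[6]))
    dos[i, ] <- suppressWarnings(as.numeric(tok[-(1:6)]))
  }
  variants <- variants_from_vids(vids, counted_allele = counted)
  samples <- default_samples(sids)
  samples$sex <- c(`1` = "male", `2` = "female")[sex]
  samples$phenotype <- ifelse(phe == 2, 1, ifelse(phe == 1, 0, NA))
  genotype_matrix(dos, variants, samples)
}

## ---- dosage TSV ----------------------------------------------------------

write_tsv_genotypes <- function(G, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sid", G$variants$vid), collapse = "\t"), con)
  if (n_samples(G)) {
    d <- G$dosages
    txt <- matrix(format(d, trim = TRUE, scientific = FALSE), nrow(d), ncol(d))
    txt[is.na(d)] <- "NA"
    writeLines(paste(G$samples$sid, apply(txt, 1, paste, collapse = "\t"),
                     sep = "\t"), con)
  }
}

read_tsv_genotypes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (!nrow(tab)) {
    vids <- setdiff(names(tab), "sid")
    return(genotype_matrix(matrix(NA_real_, 0, length(vids)),
                           variants_from_vids(vids), default_samples(character(0))))
  }
  if (names(tab)[1] != "sid") stop("dosage TSV must have 'sid' as first column")
  vids <- names(tab)[-1]
  dos <- suppressWarnings(
    matrix(as.numeric(as.matrix(tab[, -1, drop = FALSE])), nrow(tab), length(vids)))
  genotype_matrix(dos, variants_from_vids(vids), default_samples(tab$sid))
}
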