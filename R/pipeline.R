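## End-to-end orchestration: harmonize -> variant QC checklist -> PCA (or
## reference projection) -> diagnostics -> optional association. Stage order
## is fixed; there is deliberately no configuration knob to reorder it.

#' Pipeline configuration
#'
#' @param input a [genotype_matrix()] or a path readable by
#'   [read_genotypes()]
#' @param format input format when `input` is a path
#' @param metadata optional sample metadata TSV path or data.frame
#' @param mode `"conventional"` (PCA on the study covariance) or
#'   `"projection"` (reference-panel loadings)
#' @param reference required in projection mode: a `reference_model`, a
#'   [genotype_matrix()] panel, or a model file path
#' @param thresholds a [qc_thresholds()] object
#' @param exclude regions data.frame, a BED path, or NULL to skip the
#'   region step; default [default_exclusion_regions()]
#' @param k number of components
#' @param scaling PCA scaling; default `"patterson"` for conventional mode
#'   and `"center_only"` for projection
#' @param assoc NULL, or a list with `phenotype` (0/1 vector) and optional
#'   `covariates` (data.frame) to run [logistic_gwas()] with the PC1/PC2
#'   scores appended
#' @param outdir output directory
#' @param seed run seed, recorded in the manifest
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(input, format = "vcf", metadata = NULL,
                            mode = c("conventional", "projection"),
                            reference = NULL, thresholds = qc_thresholds(),
                            exclude = default_exclusion_regions(), k = 10,
                            scaling = NULL, assoc = NULL,
                            outdir = "pcstrat_run", seed = 1) {
  mode <- match.arg(mode)
  if (mode == "projection" && is.null(reference))
    stop("projection mode requires a reference panel or model")
  if (is.null(scaling))
    scaling <- if (mode == "conventional") "patterson" else "center_only"
  structure(list(input = input, format = format, metadata = metadata,
                 mode = mode, reference = reference, thresholds = thresholds,
                 exclude = exclude, k = k, scaling = scaling, assoc = assoc,
                 outdir = outdir, seed = seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in fixed checklist order: input loading and metadata
#' attachment; the five variant-selection steps (autosomes, MAF,
#' missingness, LD pruning, artifact-region exclusion); PCA or reference
#' projection; genotype-PC correlation tracks with artifact flagging;
#' ancestry boundary fitting and assignment (when self-reported labels are
#' present); and optional logistic association. All artifacts are written
#' as TSV into `outdir` together with `run.log` and a `manifest.json`
#' recording every parameter, the seed and per-stage variant/sample counts
#' — the manifest suffices to reproduce the run. Any stage error aborts
#' with the stage name, and files written by the failed run are removed.
#'
#' @param config a [pipeline_config()]
#' @return invisibly, the output directory path
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  logfile <- file.path(outdir, "run.log")
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), paste0(...))
    cat(line, "\n", file = logfile, append = TRUE)
    message(line)
  }
  emit <- function(path) { written <<- c(written, path); path }
  written <- c(written, logfile)
  stage <- "setup"
  counts <- list()
  result <- tryCatch({
    stage <- "load"
    G <- if (inherits(config$input, "genotype_matrix")) config$input
         else read_genotypes(config$input, config$format)
    if (!is.null(config$metadata)) {
      meta <- if (is.data.frame(config$metadata)) config$metadata
              else read_sample_metadata(config$metadata)
      G <- attach_metadata(G, meta)
    }
    counts$input <- list(samples = n_samples(G), variants = n_variants(G))
    logmsg("loaded ", n_samples(G), " samples x ", n_variants(G), " variants")

    stage <- "qc"
    th <- config$thresholds
    regions <- config$exclude
    if (is.character(regions)) regions <- read_bed_regions(regions)
    steps <- list(
      autosomal = function(g) filter_autosomal(g),
      maf = function(g) filter_maf(g, th$maf_min),
      missingness = function(g) filter_missingness(g, th$missingness_max),
      ld_prune = function(g) ld_prune(g, th$ld_r_max, th$ld_window_bp),
      exclude_regions = function(g)
        if (is.null(regions)) g else exclude_regions(g, regions))
    if (!th$autosomes_only) steps$autosomal <- NULL
    for (nm in names(steps)) {
      G <- steps[[nm]](G)
      counts[[nm]] <- list(variants = n_variants(G))
      logmsg("qc/", nm, ": ", n_variants(G), " variants retained")
    }
    qcr <- attr(G, "qc_report")
    if (!is.null(qcr))
      utils::write.table(qcr, emit(file.path(outdir, "qc_report.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- config$mode
    if (config$mode == "conventional") {
      model <- fit_pca(G, k = config$k, scaling = config$scaling)
      scores <- pca_scores(model)
      vexp <- scree(model)
    } else {
      ref <- config$reference
      if (is.character(ref)) ref <- load_reference_model(ref)
      if (inherits(ref, "genotype_matrix"))
        ref <- fit_reference(ref, k = config$k, scaling = config$scaling)
      scores <- project_samples(G, ref)
      vexp <- data.frame(component = seq_len(ref$k),
                         variance_explained = ref$variance_explained)
      save_reference_model(ref, emit(file.path(outdir, "reference_model.txt")))
    }
    write_scores(score_matrix(scores), emit(file.path(outdir, "scores.tsv")))
    utils::write.table(vexp, emit(file.path(outdir, "scree.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logmsg(config$mode, " scores written for ", nrow(scores), " samples")

    stage <- "diagnostics"
    flags <- list()
    for (l in 1:min(2, config$k)) {
      track <- pc_genotype_correlation(G, scores, l)
      write_track(track, emit(file.path(outdir, sprintf("track_pc%d.tsv", l))))
      fl <- flag_artifact_regions(track)
      fl$component <- rep(l, nrow(fl))
      flags[[l]] <- fl
    }
    flags <- do.call(rbind, flags)
    utils::write.table(flags, emit(file.path(outdir, "flagged_regions.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    labels <- G$samples$ancestry
    if (sum(!is.na(labels)) >= 2) {
      bounds <- fit_ancestry_boundaries(scores, labels)
      if (!is.null(bounds) && nrow(bounds)) {
        asg <- assign_ancestry(scores, bounds)
        utils::write.table(asg, emit(file.path(outdir, "assignments.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        logmsg("ancestry assigned: ",
               paste(names(table(asg$label)), table(asg$label),
                     sep = "=", collapse = ", "))
      }
    }

    if (!is.null(config$assoc)) {
      stage <- "association"
      sm <- score_matrix(scores)
      covs <- cbind(as.data.frame(config$assoc$covariates),
                    PC1 = sm[, 1], PC2 = sm[, 2])
      res <- logistic_gwas(G, phenotype = config$assoc$phenotype,
                           covariates = covs)
      write_assoc(res, emit(file.path(outdir, "assoc.tsv")))
      logmsg(sprintf("association done; lambda = %.3f", attr(res, "lambda_gc")))
      counts$lambda_gc <- attr(res, "lambda_gc")
    }

    stage <- "manifest"
    manifest <- list(
      package = "pcstrat",
      mode = config$mode, scaling = config$scaling, k = config$k,
      seed = config$seed,
      thresholds = unclass(config$thresholds),
      stage_order = c("autosomal", "maf", "missingness", "ld_prune",
                      "exclude_regions"),
      counts = counts)
    jsonlite::write_json(manifest, emit(file.path(outdir, "manifest.json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    outdir
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
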