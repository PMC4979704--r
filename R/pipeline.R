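#' Default pipeline configuration
#'
#' Study-scale defaults: QC with Hardy-Weinberg removal at 0.001, overall
#' Weir-Cockerham Fst with a 999-label-permutation structure test (and an
#' optional island-model subsampling null), kinship PCA with a
#' permutation check of PC1 group separation, the six-estimator
#' within-group coancestry permutation test (2500 permutations, Bonferroni
#' family alpha 0.05 over 21 comparisons), and admixture runs for
#' K = 2-4.
#'
#' @param ... named overrides merged over the defaults (nested lists are
#'   merged recursively).
#' @return a named list understood by [runPipeline()].
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    input = list(genotypes = NULL, format = "tsv", locusFile = NULL,
                 metadata = NULL),
    stages = list(qc = TRUE, fst = TRUE, kinship = TRUE,
                  relatedness = TRUE, admixture = TRUE),
    qc = list(hweAlpha = 0.001),
    fst = list(nPermLabels = 999L, islandNull = FALSE, targetFst = 0.0025,
               nReps = 2000L, demeSize = 1500L, nLociSim = 3150L,
               calibrationLoci = 500L),
    kinship = list(scaling = "empirical", nPerm = 999L),
    relatedness = list(estimators = RELATEDNESS_ESTIMATORS, nPerm = 2500L,
                       familyAlpha = 0.05, nTests = 21L),
    admixture = list(K = 2:4, burnIn = 5000L, samples = 2000L,
                     locationPrior = FALSE, symmetryThreshold = 0.1),
    seed = NULL, outDir = NULL)
  .merge_config(cfg, list(...))
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a pipeline configuration file
#'
#' YAML with the same nesting as [pipelineConfig()]; unspecified fields
#' keep their defaults.
#'
#' @param path YAML file path.
#' @return a configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) pmx_stop("missing_file", "file not found: %s", path)
  do.call(pipelineConfig, yaml::read_yaml(path))
}

.pipeline_stage <- function(name, partial, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(
      sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
      class = c("panmix_stage_failure", "panmix_error"),
      partial = partial))
  })
}

#' Run the full panmixia analysis pipeline
#'
#' Executes the enabled stages in order — QC, overall Fst (with a
#' label-permutation structure test and optionally the island-model
#' subsampling null), kinship PCA, within-group coancestry permutation
#' test, admixture for each K — on one input, with all randomness derived
#' from the global seed.  Each stage contributes a section and a verdict
#' ("structured" or "no structure detected") using documented thresholds:
#' label-permutation P < 0.05 for Fst, PC1 group-variance ratio above its
#' permutation 95th percentile for PCA, any Bonferroni-significant
#' group/estimator for relatedness, and a symmetry diagnostic at or above
#' `symmetryThreshold` for admixture.
#'
#' @param config a list from [pipelineConfig()] / [readRunConfig()], or a
#'   path to a YAML configuration.  `input$genotypes` may be a file path
#'   or a [GenotypeTable-class].
#' @return an [AnalysisReport-class].  With `config$outDir` set, the
#'   report is also serialized there (`report.json`, `report.txt`).
#' @examples
#' gt <- generateGenotypes("panmictic", seed = 11)
#' cfg <- pipelineConfig(
#'   input = list(genotypes = gt),
#'   stages = list(admixture = FALSE),
#'   fst = list(nPermLabels = 99), kinship = list(nPerm = 99),
#'   relatedness = list(estimators = "quellergt", nPerm = 99), seed = 11)
#' \donttest{report <- runPipeline(cfg)}
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- .merge_config(pipelineConfig(), config)
  if (!any(unlist(config$stages)))
    pmx_stop("empty_report", "no pipeline stage is enabled")
  gt <- config$input$genotypes
  if (is.character(gt)) {
    gt <- if (identical(config$input$format, "vcf"))
      readGenotypeVcf(gt, config$input$metadata)
    else readGenotypeTsv(gt, config$input$locusFile)
  }
  if (!is(gt, "GenotypeTable"))
    pmx_stop("invalid_spec", "input$genotypes must be a path or GenotypeTable")
  seeds <- derive_seeds(if (is.null(config$seed)) 1L else config$seed, 10L)
  sections <- list()
  verdicts <- character()
  d <- toDosage(gt)
  if (isTRUE(config$stages$qc)) {
    sections$qc <- .pipeline_stage("qc", sections, {
      qc <- qcFilter(d, hweAlpha = config$qc$hweAlpha)
      d <- qc$dosage   # downstream stages use the filtered panel
      qc$report
    })
  }
  if (isTRUE(config$stages$fst)) {
    sections$fst <- .pipeline_stage("fst", sections, {
      est <- wcOverall(d)
      nP <- config$fst$nPermLabels
      labs <- habitat(d)
      null <- with_seed_opt(seeds[[1L]], vapply(seq_len(nP), function(i)
        wc_theta(dosage(d), sample(labs)), numeric(1)))
      permP <- empirical_p_upper(est@theta, null)
      out <- list(estimate = est, labelPermP = permP, nPermLabels = nP)
      if (isTRUE(config$fst$islandNull)) {
        ccal <- islandConfig(nDemes = 3L, demeSize = config$fst$demeSize,
                             nLoci = config$fst$calibrationLoci,
                             migrationRate = 0)
        m <- calibrateMigration(config$fst$targetFst, ccal,
                                seed = seeds[[2L]])
        cfg2 <- islandConfig(nDemes = 3L, demeSize = config$fst$demeSize,
                             nLoci = config$fst$nLociSim, migrationRate = m,
                             seed = seeds[[3L]])
        pop <- simulateIsland(cfg2)
        out$islandNull <- resampleFstNull(
          pop, groupSizes = as.integer(table(factor(habitat(d)))[unique(habitat(d))]),
          nLociSample = min(32L, nrow(d)), nReps = config$fst$nReps,
          observedTheta = est@theta, seed = seeds[[4L]])
      }
      out
    })
    verdicts["fst"] <- if (sections$fst$labelPermP < 0.05) "structured"
                       else "no structure detected"
  }
  if (isTRUE(config$stages$kinship)) {
    sections$kinship <- .pipeline_stage("kinship", sections, {
      K <- kinshipMatrix(d, scaling = config$kinship$scaling)
      pca <- kinshipPca(K)
      sep <- pcSeparation(pca@vectors[, 1L], habitat(d),
                          nPerm = config$kinship$nPerm, seed = seeds[[5L]])
      list(kinship = K, pca = pca, pc1Separation = sep)
    })
    verdicts["kinship"] <- if (sections$kinship$pc1Separation$separated)
      "structured" else "no structure detected"
  }
  if (isTRUE(config$stages$relatedness)) {
    sections$relatedness <- .pipeline_stage("relatedness", sections,
      coancestryPermTest(d, estimators = config$relatedness$estimators,
                         nPerm = config$relatedness$nPerm,
                         familyAlpha = config$relatedness$familyAlpha,
                         nTests = config$relatedness$nTests,
                         seed = seeds[[6L]]))
    pt <- sections$relatedness
    verdicts["relatedness"] <- if (any(pt@empiricalP < pt@threshold))
      "structured" else "no structure detected"
  }
  if (isTRUE(config$stages$admixture)) {
    sections$admixture <- .pipeline_stage("admixture", sections, {
      runs <- lapply(seq_along(config$admixture$K), function(ik)
        gibbsAdmixture(d, K = config$admixture$K[ik],
                       burnIn = config$admixture$burnIn,
                       samples = config$admixture$samples,
                       locationPrior = config$admixture$locationPrior,
                       seed = seeds[[6L + ik]]))
      names(runs) <- paste0("K", config$admixture$K)
      list(runs = runs,
           symmetry = vapply(runs, symmetryDiagnostic, numeric(1)))
    })
    verdicts["admixture"] <-
      if (any(sections$admixture$symmetry >= config$admixture$symmetryThreshold))
        "structured" else "no structure detected"
  }
  report <- new("AnalysisReport", sections = sections, verdicts = verdicts,
                config = config[setdiff(names(config), "input")])
  if (!is.null(config$outDir)) writeAnalysisReport(report, config$outDir)
  report
}

setMethod("show", "AnalysisReport", function(object) {
  cat("AnalysisReport\n")
  for (nm in names(object@verdicts))
    cat(sprintf("  %-12s %s\n", nm, object@verdicts[nm]))
  if ("fst" %in% names(object@sections))
    cat(sprintf("  overall theta = %.5g (label-permutation P = %.3g)\n",
                object@sections$fst$estimate@theta,
                object@sections$fst$labelPermP))
})

#' Serialize an analysis report
#'
#' Writes `report.json` (machine-readable summaries per stage) and
#' `report.txt` (the printed report) into `dir`.  No timestamps are
#' written, so identical runs serialize identically.
#'
#' @param report an [AnalysisReport-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeAnalysisReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sec <- report@sections
  js <- list(verdicts = as.list(report@verdicts))
  if (!is.null(sec$qc))
    js$qc <- list(loci_in = length(sec$qc@lociIn),
                  monomorphic_removed = sec$qc@monomorphicRemoved,
                  hwe_removed = as.list(sec$qc@hweRemoved),
                  max_pairwise_r2 = sec$qc@maxPairwiseR2,
                  loci_out = length(sec$qc@lociOut))
  if (!is.null(sec$fst)) {
    js$fst <- list(theta = sec$fst$estimate@theta,
                   label_perm_p = sec$fst$labelPermP)
    if (!is.null(sec$fst$islandNull))
      js$fst$island_null_empirical_p <- sec$fst$islandNull@empiricalP
  }
  if (!is.null(sec$kinship))
    js$kinship <- list(
      mean_diag = mean(diag(sec$kinship$kinship@K)),
      top_eigenvalues = utils::head(sec$kinship$pca@values, 5),
      pc1_variance_ratio = sec$kinship$pc1Separation$ratio,
      pc1_perm95 = sec$kinship$pc1Separation$perm95)
  if (!is.null(sec$relatedness))
    js$relatedness <- list(
      threshold = sec$relatedness@threshold,
      empirical_p = as.data.frame(as.table(sec$relatedness@empiricalP)))
  if (!is.null(sec$admixture))
    js$admixture <- list(symmetry = as.list(sec$admixture$symmetry))
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- utils::capture.output(show(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
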