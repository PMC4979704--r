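#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

HABITAT_LEVELS <- c("benthic", "littoral", "pelagic")

#' GenotypeTable: SNP genotype calls with sample metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding unphased
#' biallelic SNP genotype calls.  Rows are loci, columns are samples.  The
#' single assay `"calls"` is a character matrix of two-letter genotype
#' strings (e.g. `"AC"`, alphabetically ordered, alleles from A/C/G/T) with
#' `NA` for missing calls.  `colData` carries the per-sample `habitat`
#' (benthic/littoral/pelagic) and genotyping `batch` (1 or 2); `rowData`
#' carries the per-locus `linkage_group`.
#'
#' Validity requires unique sample and locus identifiers, habitat and batch
#' defined for every sample, and at most two distinct allele symbols among
#' the non-missing calls at each locus.
#'
#' @seealso [readGenotypeTsv()], [readGenotypeVcf()], [mergeBatches()],
#'   [toDosage()], [generateGenotypes()]
#' @export
setClass("GenotypeTable", contains = "SummarizedExperiment")

#' DosageMatrix: minor-allele dosage codes
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass with a single
#' integer assay `"dosage"` counting copies of the per-locus minor allele
#' (0/1/2, `NA` missing).  `rowData` records the `major_allele`,
#' `minor_allele`, `linkage_group` and the minor-allele frequency
#' (`minor_freq`) used for the major/minor assignment; `colData` carries the
#' sample metadata of the originating [GenotypeTable].  The minor allele is
#' the less frequent allele over all non-missing calls; a 0.50/0.50 tie is
#' resolved to the alphabetically later symbol.
#'
#' @seealso [toDosage()]
#' @export
setClass("DosageMatrix", contains = "SummarizedExperiment")

.validGenotypeTable <- function(object) {
  msg <- character()
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'calls' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("habitat", "batch") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'habitat' and 'batch'")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample identifiers")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate locus identifiers")
  if ("habitat" %in% colnames(cd)) {
    hab <- as.character(cd$habitat)
    if (anyNA(hab) || !all(hab %in% HABITAT_LEVELS))
      msg <- c(msg, sprintf("habitat must be one of %s for every sample",
                            paste(HABITAT_LEVELS, collapse = "/")))
  }
  if ("batch" %in% colnames(cd)) {
    b <- cd$batch
    if (anyNA(b) || !all(b %in% c(1L, 2L)))
      msg <- c(msg, "batch must be 1 or 2 for every sample")
  }
  if ("calls" %in% SummarizedExperiment::assayNames(object) &&
      nrow(object) > 0L) {
    calls <- SummarizedExperiment::assay(object, "calls")
    ok <- is.na(calls) | grepl("^[ACGT]{2}$", calls)
    if (!all(ok))
      msg <- c(msg, "calls must be two-letter strings over A/C/G/T or NA")
    nall <- apply(calls, 1L, function(x) {
      length(unique(unlist(strsplit(x[!is.na(x)], ""))))
    })
    if (any(nall > 2L))
      msg <- c(msg, sprintf("more than two alleles at locus/loci: %s",
                            paste(rownames(object)[nall > 2L], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
}
setValidity("GenotypeTable", .validGenotypeTable)

.validDosageMatrix <- function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("major_allele", "minor_allele", "minor_freq")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, "rowData must contain major_allele, minor_allele, minor_freq")
  if ("dosage" %in% SummarizedExperiment::assayNames(object)) {
    d <- SummarizedExperiment::assay(object, "dosage")
    if (!all(is.na(d) | d %in% 0:2))
      msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
  }
  if ("minor_freq" %in% colnames(rd) &&
      any(rd$minor_freq > 0.5 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "minor-allele frequency must be <= 0.5 at every locus")
  if (length(msg)) msg else TRUE
}
setValidity("DosageMatrix", .validDosageMatrix)

#' Per-locus quality-control report
#'
#' Returned by [qcFilter()].  Records the input loci, the monomorphic and
#' Hardy-Weinberg removals (with exact-test P-values), the surviving loci and
#' the maximum pairwise composite r-squared among survivors.
#'
#' @slot lociIn character, locus ids before filtering.
#' @slot monomorphicRemoved character, loci removed as monomorphic.
#' @slot hweRemoved named numeric, exact-test P-values of loci removed for
#'   Hardy-Weinberg disequilibrium (names are locus ids).
#' @slot hweAlpha numeric(1), removal threshold used.
#' @slot maxPairwiseR2 numeric(1), maximum off-diagonal r-squared among the
#'   surviving loci (`NA` if fewer than two survive).
#' @slot lociOut character, surviving locus ids.
#' @export
setClass("QCReport", representation(
  lociIn = "character", monomorphicRemoved = "character",
  hweRemoved = "numeric", hweAlpha = "numeric",
  maxPairwiseR2 = "numeric", lociOut = "character"))

#' Weir-Cockerham Fst estimate
#'
#' Returned by [wcOverall()].  `theta` is the multi-locus estimate combined
#' as a ratio of sums of variance components (never the mean of per-locus
#' ratios); `perLocus` holds the per-locus components a (among populations),
#' b (among individuals within populations), c (within individuals) and the
#' per-locus theta.
#'
#' @slot theta numeric(1), overall estimate sum(a)/sum(a+b+c).
#' @slot perLocus DataFrame with columns locus_id, a, b, c, theta, n_pops.
#' @slot lociUsed character, loci contributing to the sums.
#' @slot groups character, group labels in the order used.
#' @export
setClass("FstEstimate", representation(
  theta = "numeric", perLocus = "DataFrame", lociUsed = "character",
  groups = "character"))

#' Island-model simulation configuration
#'
#' Configuration for [simulateIsland()]: `nDemes` demes of `demeSize`
#' diploids exchanging migrants symmetrically at per-generation rate
#' `migrationRate`, at `nLoci` unlinked biallelic loci founded at allele
#' frequencies drawn uniformly on `initFreqRange`.  The burn-in runs at most
#' `burnInGenerations` generations, but stops once the trailing-window trend
#' of realized Fst is indistinguishable from zero (migration-drift
#' equilibrium); `minGenerations` generations are always run.
#'
#' @export
setClass("IslandConfig", representation(
  nDemes = "integer", demeSize = "integer", nLoci = "integer",
  migrationRate = "numeric", initFreqRange = "numeric",
  burnInGenerations = "integer", minGenerations = "integer",
  checkEvery = "integer", seed = "ANY"))

.validIslandConfig <- function(object) {
  msg <- character()
  if (object@nDemes < 2L) msg <- c(msg, "nDemes must be >= 2")
  if (object@demeSize < 2L) msg <- c(msg, "demeSize must be >= 2")
  if (object@nLoci < 1L) msg <- c(msg, "nLoci must be >= 1")
  if (object@migrationRate < 0 || object@migrationRate > 1)
    msg <- c(msg, "migrationRate must be in [0, 1]")
  if (length(object@initFreqRange) != 2L ||
      any(object@initFreqRange <= 0) || any(object@initFreqRange >= 1) ||
      diff(object@initFreqRange) < 0)
    msg <- c(msg, "initFreqRange must be an increasing pair inside (0, 1)")
  if (object@burnInGenerations < 1L)
    msg <- c(msg, "burnInGenerations must be >= 1")
  if (length(msg)) msg else TRUE
}
setValidity("IslandConfig", .validIslandConfig)

#' Simulated island-model population
#'
#' Returned by [simulateIsland()].  `dosage` is a loci x individuals integer
#' matrix of minor-allele counts; `deme` labels each individual; the
#' realized Fst (Weir-Cockerham estimate on the full census with demes as
#' groups) and the number of burn-in generations actually run are recorded.
#'
#' @export
setClass("SimulatedPopulation", representation(
  dosage = "matrix", deme = "factor", demeFreq = "matrix",
  realizedFst = "numeric", generations = "integer",
  config = "IslandConfig", seed = "ANY"))

#' Fst subsampling null distribution
#'
#' Returned by [resampleFstNull()].  Each replicate draws individuals
#' without replacement per deme and loci without replacement from the
#' polymorphic loci of a [SimulatedPopulation], and computes the
#' Weir-Cockerham overall theta with demes as groups.  `empiricalP` is the
#' lower-tail fraction of replicates with theta <= the observed value.
#'
#' @export
setClass("FstNullResult", representation(
  replicateThetas = "numeric", nReps = "integer", observedTheta = "numeric",
  empiricalP = "numeric", groupSizes = "integer", nLociSample = "integer",
  addOne = "logical", seed = "ANY"))

#' Standardized genotype matrix
#'
#' Returned by [standardizeDosage()].  `values` is a samples x loci matrix
#' of standard scores: missing dosages are imputed with the locus mean, each
#' column is centered on its mean and scaled either by its empirical
#' standard deviation or by sqrt(2 p (1-p)) (binomial scaling).
#'
#' @export
setClass("StandardizedMatrix", representation(
  values = "matrix", center = "numeric", scale = "numeric",
  scaling = "character", nImputed = "integer"))

#' Kinship matrix from standardized genotypes
#'
#' Returned by [kinshipMatrix()]: K = M M^T / (2 L) for a samples x loci
#' standardized matrix M with L loci.  Rows and columns are samples; rows
#' sum to zero because the columns of M are centered.
#'
#' @export
setClass("KinshipMatrix", representation(
  K = "matrix", nLoci = "integer", scaling = "character"))

#' Principal components of a kinship matrix
#'
#' Returned by [kinshipPca()].  Full eigendecomposition with eigenvalues in
#' descending order; each eigenvector's sign is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @export
setClass("KinshipPCA", representation(
  values = "numeric", vectors = "matrix", varExplained = "numeric"))

#' Within-group coancestry permutation test
#'
#' Returned by [coancestryPermTest()].  For each group and estimator, the
#' observed mean pairwise relatedness within the group is compared with a
#' null distribution obtained by permuting the sample-to-group assignment
#' (group sizes fixed).  Empirical P-values use the add-one convention
#' (1 + #\{null >= observed\}) / (1 + nPerm); the Bonferroni threshold is
#' familyAlpha / nTests.
#'
#' @export
setClass("CoancestryPermTest", representation(
  observed = "matrix", empiricalP = "matrix", nullMeans = "list",
  nPerm = "integer", familyAlpha = "numeric", nTests = "integer",
  threshold = "numeric", seed = "ANY"))

#' Posterior summary of the admixture Gibbs sampler
#'
#' Returned by [gibbsAdmixture()].  `Q` (samples x K) and `P` (loci x K) are
#' posterior means of the membership proportions and cluster minor-allele
#' frequencies; `alphaTrace` is the post-burn-in trace of the Dirichlet
#' admixture parameter.
#'
#' @export
setClass("AdmixtureResult", representation(
  Q = "matrix", P = "matrix", alphaTrace = "numeric", K = "integer",
  burnIn = "integer", samples = "integer", locationPrior = "logical",
  Qtrace = "ANY", seed = "ANY"))

#' Consolidated pipeline report
#'
#' Returned by [runPipeline()]: one section per enabled stage plus a
#' per-stage verdict ("structured" / "no structure detected") using the
#' documented thresholds.
#'
#' @export
setClass("AnalysisReport", representation(
  sections = "list", verdicts = "character", config = "list"))
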