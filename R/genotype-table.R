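#' Construct a GenotypeTable
#'
#' @param calls character matrix of two-letter genotype strings (loci in
#'   rows, samples in columns; `NA` = missing).  Row and column names are
#'   the locus and sample identifiers.
#' @param habitat character/factor of per-sample habitat labels
#'   (`"benthic"`, `"littoral"`, `"pelagic"`).
#' @param batch integer vector of per-sample genotyping batch (1 or 2).
#' @param linkageGroup integer vector of per-locus linkage groups
#'   (`NA` allowed).
#' @param metadata optional list stored in `metadata()` (e.g. the truth
#'   record of a synthetic dataset).
#' @return a validated [GenotypeTable-class] object.
#' @examples
#' calls <- matrix(c("AC", "AA", "CC", NA), nrow = 2,
#'                 dimnames = list(c("L1", "L2"), c("s1", "s2")))
#' gt <- GenotypeTable(calls, habitat = c("benthic", "pelagic"),
#'                     batch = c(1, 1))
#' habitat(gt)
#' @export
GenotypeTable <- function(calls, habitat, batch,
                          linkageGroup = rep(NA_integer_, nrow(calls)),
                          metadata = list()) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "character"
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    pmx_stop("malformed_header", "calls must have locus row names and sample column names")
  cd <- S4Vectors::DataFrame(
    habitat = factor(as.character(habitat), levels = HABITAT_LEVELS),
    batch = as.integer(batch), row.names = colnames(calls))
  rd <- S4Vectors::DataFrame(linkage_group = as.integer(linkageGroup),
                             row.names = rownames(calls))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(calls = calls),
    colData = cd, rowData = rd, metadata = metadata)
  new("GenotypeTable", se)
}

#' @rdname GenotypeTable-class
#' @export
setMethod("genotypeCalls", "GenotypeTable", function(x)
  SummarizedExperiment::assay(x, "calls"))

#' @rdname GenotypeTable-class
#' @export
setMethod("habitat", "SummarizedExperiment", function(x)
  as.character(SummarizedExperiment::colData(x)$habitat))

#' @rdname GenotypeTable-class
#' @export
setMethod("sampleBatch", "SummarizedExperiment", function(x)
  SummarizedExperiment::colData(x)$batch)

#' @rdname GenotypeTable-class
#' @export
setMethod("linkageGroup", "SummarizedExperiment", function(x)
  SummarizedExperiment::rowData(x)$linkage_group)

setMethod("show", "GenotypeTable", function(object) {
  calls <- genotypeCalls(object)
  cat(sprintf("GenotypeTable: %d loci x %d samples\n",
              nrow(object), ncol(object)))
  cat(sprintf("  habitats: %s\n",
              paste(sprintf("%s=%d", names(table(habitat(object))),
                            table(habitat(object))), collapse = ", ")))
  cat(sprintf("  missing calls: %d (%.1f%%)\n", sum(is.na(calls)),
              100 * mean(is.na(calls))))
})

#' @rdname DosageMatrix-class
#' @export
setMethod("dosage", "DosageMatrix", function(x)
  SummarizedExperiment::assay(x, "dosage"))

#' @rdname DosageMatrix-class
#' @export
setMethod("majorAllele", "DosageMatrix", function(x)
  stats::setNames(SummarizedExperiment::rowData(x)$major_allele, rownames(x)))

#' @rdname DosageMatrix-class
#' @export
setMethod("minorAllele", "DosageMatrix", function(x)
  stats::setNames(SummarizedExperiment::rowData(x)$minor_allele, rownames(x)))

#' @rdname DosageMatrix-class
#' @export
setMethod("minorFreq", "DosageMatrix", function(x)
  stats::setNames(SummarizedExperiment::rowData(x)$minor_freq, rownames(x)))

setMethod("show", "DosageMatrix", function(object) {
  cat(sprintf("DosageMatrix: %d loci x %d samples\n",
              nrow(object), ncol(object)))
  mf <- minorFreq(object)
  cat(sprintf("  minor-allele frequency: %.3f-%.3f (median %.3f)\n",
              min(mf), max(mf), stats::median(mf)))
})

#' Merge two genotyping batches
#'
#' Combines two internally valid tables with disjoint samples, restricting
#' to the loci present in both (partially overlapping SNP panels are
#' reconciled by intersection); locus order follows the first table.
#'
#' @param t1,t2 [GenotypeTable-class] objects with disjoint sample ids.
#' @return a merged `GenotypeTable` covering the shared loci.
#' @export
mergeBatches <- function(t1, t2) {
  stopifnot(is(t1, "GenotypeTable"), is(t2, "GenotypeTable"))
  if (length(intersect(colnames(t1), colnames(t2))))
    pmx_stop("overlapping_samples", "sample ids overlap between batches: %s",
             paste(intersect(colnames(t1), colnames(t2)), collapse = ", "))
  shared <- intersect(rownames(t1), rownames(t2))
  if (!length(shared))
    pmx_stop("empty_locus_intersection", "the two batches share no loci")
  shared <- rownames(t1)[rownames(t1) %in% shared]
  calls <- cbind(genotypeCalls(t1)[shared, , drop = FALSE],
                 genotypeCalls(t2)[shared, , drop = FALSE])
  lg <- linkageGroup(t1)[match(shared, rownames(t1))]
  GenotypeTable(calls,
                habitat = c(habitat(t1), habitat(t2)),
                batch = c(sampleBatch(t1), sampleBatch(t2)),
                linkageGroup = lg)
}

#' Convert genotype calls to minor-allele dosages
#'
#' Assigns per-locus major/minor alleles by frequency over all non-missing
#' calls (a 0.50/0.50 tie resolves to the alphabetically later symbol as
#' minor) and codes each genotype by its count of minor-allele copies.
#' Missingness is preserved.
#'
#' @param t a [GenotypeTable-class].
#' @return a [DosageMatrix-class] carrying the sample metadata of `t`.
#' @examples
#' calls <- matrix(c("CC", "CA", "AA", "CC"), nrow = 1,
#'                 dimnames = list("L1", paste0("s", 1:4)))
#' d <- toDosage(GenotypeTable(calls, habitat = rep("benthic", 4),
#'                             batch = rep(1, 4)))
#' dosage(d)  # C major (0.625), A minor: 0 1 2 0
#' @export
toDosage <- function(t) {
  stopifnot(is(t, "GenotypeTable"))
  calls <- genotypeCalls(t)
  a1 <- substr(calls, 1L, 1L)
  a2 <- substr(calls, 2L, 2L)
  L <- nrow(calls)
  major <- minor <- character(L)
  mfreq <- numeric(L)
  dos <- matrix(NA_integer_, L, ncol(calls), dimnames = dimnames(calls))
  for (l in seq_len(L)) {
    alle <- c(a1[l, ], a2[l, ])
    alle <- alle[!is.na(alle)]
    if (!length(alle))
      pmx_stop("all_missing_locus", "locus %s has no non-missing calls",
               rownames(calls)[l])
    tab <- sort(table(alle))  # ascending count; names sorted within ties
    syms <- names(tab)
    if (length(syms) == 1L) {
      major[l] <- syms; minor[l] <- syms; mfreq[l] <- 0
      dos[l, ] <- ifelse(is.na(calls[l, ]), NA_integer_, 0L)
    } else {
      if (tab[[1L]] == tab[[2L]]) {     # exact tie: later symbol is minor
        minor[l] <- max(syms); major[l] <- min(syms)
      } else {
        minor[l] <- syms[1L]; major[l] <- syms[2L]
      }
      mfreq[l] <- sum(alle == minor[l]) / length(alle)
      dos[l, ] <- (a1[l, ] == minor[l]) + (a2[l, ] == minor[l])
    }
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(dosage = dos),
    colData = SummarizedExperiment::colData(t),
    rowData = S4Vectors::DataFrame(
      linkage_group = linkageGroup(t), major_allele = major,
      minor_allele = minor, minor_freq = mfreq,
      row.names = rownames(calls)),
    metadata = S4Vectors::metadata(t))
  new("DosageMatrix", se)
}

# internal: rebuild a DosageMatrix from an existing one with a locus subset
subset_dosage <- function(d, keep) {
  new("DosageMatrix", methods::as(d, "SummarizedExperiment")[keep, ])
}

# internal: wrap a plain dosage matrix (loci x samples) as a DosageMatrix
dosage_from_matrix <- function(dos, habitat, batch = rep(1L, ncol(dos)),
                               minorFreq = NULL, metadata = list()) {
  if (is.null(minorFreq))
    minorFreq <- rowMeans(dos, na.rm = TRUE) / 2
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(dosage = dos),
    colData = S4Vectors::DataFrame(
      habitat = factor(habitat, levels = HABITAT_LEVELS),
      batch = as.integer(batch), row.names = colnames(dos)),
    rowData = S4Vectors::DataFrame(
      linkage_group = rep(NA_integer_, nrow(dos)),
      major_allele = rep("A", nrow(dos)), minor_allele = rep("G", nrow(dos)),
      minor_freq = pmin(minorFreq, 0.5), row.names = rownames(dos)),
    metadata = metadata)
  new("DosageMatrix", se)
}
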