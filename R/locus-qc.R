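#' Per-locus summary statistics
#'
#' Summaries mirror a classic SNP-panel description: number of non-missing
#' genotypes, major/minor alleles with frequencies (from non-missing calls
#' only), expected heterozygosity He = 2 p (1 - p), and the exact
#' Hardy-Weinberg test P-value.
#'
#' @param d a [DosageMatrix-class].
#' @param loci optional character vector restricting the summary.
#' @return a [S4Vectors::DataFrame] with one row per locus and columns
#'   `locus_id`, `linkage_group`, `n_genotypes`, `major_allele`,
#'   `major_freq`, `minor_allele`, `minor_freq`, `he`, `hwe_p`.
#' @export
summarizeLoci <- function(d, loci = NULL) {
  stopifnot(is(d, "DosageMatrix"))
  if (is.null(loci)) loci <- rownames(d)
  unknown <- setdiff(loci, rownames(d))
  if (length(unknown))
    pmx_stop("unknown_locus", "unknown locus/loci: %s",
             paste(unknown, collapse = ", "))
  dos <- dosage(d)[loci, , drop = FALSE]
  n <- rowSums(!is.na(dos))
  if (any(n == 0L))
    pmx_stop("all_missing_locus", "locus with no non-missing calls")
  pm <- rowSums(dos, na.rm = TRUE) / (2 * n)
  nAA <- rowSums(dos == 0L, na.rm = TRUE)
  nAa <- rowSums(dos == 1L, na.rm = TRUE)
  naa <- rowSums(dos == 2L, na.rm = TRUE)
  hwe <- mapply(hweExactTest, nAA, nAa, naa)
  S4Vectors::DataFrame(
    locus_id = loci,
    linkage_group = linkageGroup(d)[match(loci, rownames(d))],
    n_genotypes = as.integer(n),
    major_allele = majorAllele(d)[loci],
    major_freq = 1 - pm,
    minor_allele = minorAllele(d)[loci],
    minor_freq = pm,
    he = 2 * pm * (1 - pm),
    hwe_p = hwe,
    row.names = loci)
}

#' Mean expected heterozygosity
#'
#' @param x a numeric vector of He values, or the DataFrame returned by
#'   [summarizeLoci()] (its `he` column is used).
#' @return arithmetic mean He.
#' @export
meanHe <- function(x) {
  if (is(x, "DataFrame") || is.data.frame(x)) x <- x$he
  x <- as.numeric(x)
  if (!length(x)) pmx_stop("empty_input", "no He values supplied")
  mean(x)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test for a biallelic locus: given the observed allele
#' counts, heterozygote counts follow the distribution
#' P(nAB) proportional to n! 2^nAB / (nAA! nAB! nBB!).  The two-sided
#' P-value sums the probabilities of all heterozygote counts whose
#' probability does not exceed that of the observed configuration
#' (probability-ordering convention).
#'
#' @param nAA,nAa,naa genotype counts (major homozygote, heterozygote,
#'   minor homozygote).
#' @return the exact P-value in (0, 1].
#' @examples
#' hweExactTest(25, 50, 25)   # modal configuration, P = 1
#' hweExactTest(10, 0, 10)    # strong heterozygote deficit
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  if (any(c(nAA, nAa, naa) < 0) || any(c(nAA, nAa, naa) != round(c(nAA, nAa, naa))))
    pmx_stop("invalid_counts", "genotype counts must be non-negative integers")
  n <- nAA + nAa + naa
  if (n < 1L) pmx_stop("invalid_counts", "all genotype counts are zero")
  nA <- 2 * nAA + nAa
  nB <- 2 * naa + nAa
  if (nA == 0L || nB == 0L) return(1)
  hets <- seq.int(nA %% 2L, min(nA, nB), by = 2L)
  lp <- lfactorial(n) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((nB - hets) / 2) + hets * log(2) +
    lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  pObs <- p[match(nAa, hets)]
  min(1, sum(p[p <= pObs * (1 + 1e-7)]))
}

#' Pairwise composite r-squared between loci
#'
#' Squared Pearson correlation of minor-allele dosage vectors for every
#' locus pair, computed over the samples non-missing at both loci
#' (pairwise-complete).  With unphased data this is the composite
#' (genotypic) measure of linkage disequilibrium.
#'
#' @param d a [DosageMatrix-class] with at least two polymorphic loci.
#' @return a symmetric matrix of r-squared values with unit diagonal.
#' @export
pairwiseR2 <- function(d) {
  stopifnot(is(d, "DosageMatrix"))
  dos <- dosage(d)
  poly <- apply(dos, 1L, function(x) length(unique(x[!is.na(x)])) > 1L)
  if (any(!poly))
    pmx_stop("monomorphic_locus", "monomorphic locus/loci: %s",
             paste(rownames(d)[!poly], collapse = ", "))
  if (nrow(dos) < 2L)
    pmx_stop("too_few_loci", "need at least two loci")
  joint <- crossprod(!is.na(t(dos)))
  off <- joint[upper.tri(joint)]
  if (any(off < 2L))
    pmx_stop("insufficient_overlap",
             "locus pair(s) with fewer than two jointly typed samples")
  r2 <- suppressWarnings(stats::cor(t(dos), use = "pairwise.complete.obs"))^2
  diag(r2) <- 1
  r2
}

#' Locus quality-control filter
#'
#' Applies the standard small-panel filtering chain: drop monomorphic loci,
#' then drop loci failing the exact Hardy-Weinberg test at `hweAlpha`
#' (default 0.001, i.e. only gross departures are removed).  The report
#' records every removal and the maximum pairwise composite r-squared among
#' the survivors as an unlinkedness check.
#'
#' @param d a [DosageMatrix-class].
#' @param hweAlpha Hardy-Weinberg removal threshold; loci with exact-test
#'   P < `hweAlpha` are removed.  `0` disables the HWE removal.
#' @param dropMonomorphic drop loci with no minor-allele copies?
#' @return a list with elements `dosage` (the filtered [DosageMatrix-class])
#'   and `report` (a [QCReport-class]).
#' @export
qcFilter <- function(d, hweAlpha = 0.001, dropMonomorphic = TRUE) {
  stopifnot(is(d, "DosageMatrix"))
  dos <- dosage(d)
  lociIn <- rownames(d)
  # monomorphic = no minor-allele copies among the non-missing calls
  # (an all-heterozygote locus is polymorphic, if far out of HWE)
  poly <- rowSums(dos, na.rm = TRUE) > 0 & rowSums(!is.na(dos)) > 0
  mono <- if (dropMonomorphic) lociIn[!poly] else character()
  keep <- setdiff(lociIn, mono)
  hweRemoved <- stats::setNames(numeric(), character())
  if (hweAlpha > 0 && length(keep)) {
    sub <- dosage(d)[keep, , drop = FALSE]
    pv <- mapply(hweExactTest,
                 rowSums(sub == 0L, na.rm = TRUE),
                 rowSums(sub == 1L, na.rm = TRUE),
                 rowSums(sub == 2L, na.rm = TRUE))
    bad <- pv < hweAlpha
    hweRemoved <- stats::setNames(pv[bad], keep[bad])
    keep <- keep[!bad]
  }
  if (!length(keep))
    pmx_stop("all_loci_removed", "quality control removed every locus")
  out <- subset_dosage(d, keep)
  # r^2 needs dosage variance; skip variance-free survivors (e.g. all-het)
  vkeep <- keep[apply(dosage(out), 1L, function(x)
    length(unique(x[!is.na(x)])) > 1L)]
  maxR2 <- if (length(vkeep) >= 2L) {
    r2 <- pairwiseR2(subset_dosage(d, vkeep))
    max(r2[upper.tri(r2)])
  } else NA_real_
  report <- new("QCReport", lociIn = lociIn, monomorphicRemoved = mono,
                hweRemoved = hweRemoved, hweAlpha = hweAlpha,
                maxPairwiseR2 = maxR2, lociOut = keep)
  list(dosage = out, report = report)
}

setMethod("show", "QCReport", function(object) {
  cat(sprintf("QCReport: %d loci in, %d out\n",
              length(object@lociIn), length(object@lociOut)))
  cat(sprintf("  monomorphic removed: %d\n", length(object@monomorphicRemoved)))
  cat(sprintf("  HWE removed (P < %g): %d\n", object@hweAlpha,
              length(object@hweRemoved)))
  if (length(object@hweRemoved))
    cat(sprintf("    %s (P = %.3g)\n", names(object@hweRemoved),
                object@hweRemoved), sep = "")
  cat(sprintf("  max pairwise r^2 among survivors: %s\n",
              format(object@maxPairwiseR2, digits = 3)))
})

#' @describeIn qcFilter serialize a QCReport to JSON.
#' @param report a [QCReport-class].
#' @param path output file.
#' @export
writeQCReport <- function(report, path) {
  jsonlite::write_json(list(
    loci_in = report@lociIn,
    n_monomorphic_removed = length(report@monomorphicRemoved),
    monomorphic_removed = report@monomorphicRemoved,
    hwe_removed = as.list(report@hweRemoved),
    hwe_alpha = report@hweAlpha,
    max_pairwise_r2 = report@maxPairwiseR2,
    loci_out = report@lociOut), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
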