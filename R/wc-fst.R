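# Vectorized Weir-Cockerham variance components over all loci at once.
# dos: loci x samples matrix of 0/1/2/NA; groups: per-sample labels.
# Returns a matrix with columns a, b, c, r (populations with data), nbar.
# Components use the unequal-sample-size formulation with nbar, nc, pbar,
# s2 (sample variance of allele frequencies over populations) and hbar
# (average observed heterozygote proportion); individuals missing at a
# locus are dropped from that locus only.
wc_components_matrix <- function(dos, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L)
    pmx_stop("too_few_groups", "need at least two groups")
  Z <- stats::model.matrix(~ 0 + groups)
  nm <- !is.na(dos)
  dos0 <- dos
  dos0[!nm] <- 0L
  N <- nm %*% Z                                 # loci x G non-missing counts
  Ssum <- dos0 %*% Z                            # minor-allele copy sums
  H <- ((dos0 == 1L) & nm) %*% Z                # heterozygote counts
  r <- rowSums(N > 0)
  Ntot <- rowSums(N)
  nbar <- Ntot / r
  nc <- (Ntot - rowSums(N^2) / Ntot) / (r - 1)
  pbar <- rowSums(Ssum) / (2 * Ntot)
  p <- Ssum / (2 * N)
  dev <- p - pbar
  dev[N == 0] <- 0
  s2 <- rowSums(N * dev^2) / ((r - 1) * nbar)
  hbar <- rowSums(H) / Ntot
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  bad <- r < 2 | nbar <= 1 | nc <= 0
  a[bad] <- b[bad] <- cc[bad] <- NA_real_
  cbind(a = a, b = b, c = cc, r = r, nbar = nbar)
}

# overall theta = sum(a) / sum(a+b+c), loci with undefined or exactly-zero
# denominator contribution excluded from both sums
wc_theta <- function(dos, groups) {
  comp <- wc_components_matrix(dos, groups)
  denom <- comp[, "a"] + comp[, "b"] + comp[, "c"]
  use <- is.finite(denom) & denom != 0
  if (!any(use))
    pmx_stop("zero_denominator", "no locus contributes variance")
  sum(comp[use, "a"]) / sum(denom[use])
}

#' Weir-Cockerham variance components per locus
#'
#' Estimates the among-population (a), among-individual-within-population
#' (b) and within-individual (c) components of allelic variance for each
#' locus, using observed heterozygote proportions and unequal group sizes.
#' Negative per-locus theta values are retained.
#'
#' @param d a [DosageMatrix-class].
#' @param groups per-sample group labels; defaults to the habitat labels in
#'   `colData(d)`.
#' @param loci optional locus subset.
#' @return a [S4Vectors::DataFrame] with columns `locus_id`, `a`, `b`, `c`,
#'   `theta` (= a/(a+b+c), `NA` for loci without variance) and `n_pops`,
#'   plus one `n_<group>` column of per-group non-missing sample sizes.
#' @export
wcComponents <- function(d, groups = NULL, loci = NULL) {
  stopifnot(is(d, "DosageMatrix"))
  if (is.null(groups)) groups <- habitat(d)
  if (!is.null(loci)) {
    unknown <- setdiff(loci, rownames(d))
    if (length(unknown))
      pmx_stop("unknown_locus", "unknown locus/loci: %s",
               paste(unknown, collapse = ", "))
    d <- subset_dosage(d, loci)
  }
  dos <- dosage(d)
  groups <- factor(groups)
  comp <- wc_components_matrix(dos, groups)
  denom <- comp[, "a"] + comp[, "b"] + comp[, "c"]
  theta <- ifelse(is.finite(denom) & denom != 0, comp[, "a"] / denom, NA_real_)
  sizes <- (!is.na(dos)) %*% stats::model.matrix(~ 0 + groups)
  colnames(sizes) <- paste0("n_", levels(groups))
  out <- S4Vectors::DataFrame(
    locus_id = rownames(d), a = comp[, "a"], b = comp[, "b"], c = comp[, "c"],
    theta = theta, n_pops = as.integer(comp[, "r"]), row.names = rownames(d))
  cbind(out, S4Vectors::DataFrame(sizes))
}

#' Overall Weir-Cockerham Fst
#'
#' Multi-locus theta combined as the ratio of summed variance components,
#' sum(a) / sum(a + b + c) — not the mean of per-locus ratios.  Loci whose
#' components are undefined (fewer than two groups with data) or contribute
#' zero total variance are excluded from both sums.
#'
#' @inheritParams wcComponents
#' @return an [FstEstimate-class].
#' @examples
#' gt <- generateGenotypes("panmictic", seed = 1)
#' wcOverall(toDosage(gt))
#' @export
wcOverall <- function(d, groups = NULL) {
  stopifnot(is(d, "DosageMatrix"))
  if (is.null(groups)) groups <- habitat(d)
  per <- wcComponents(d, groups)
  denom <- per$a + per$b + per$c
  use <- is.finite(denom) & denom != 0
  if (!any(use))
    pmx_stop("zero_denominator", "no locus contributes variance")
  new("FstEstimate",
      theta = sum(per$a[use]) / sum(denom[use]),
      perLocus = per, lociUsed = per$locus_id[use],
      groups = levels(factor(groups)))
}

setMethod("show", "FstEstimate", function(object) {
  cat(sprintf("FstEstimate (Weir-Cockerham): theta = %.5g\n", object@theta))
  cat(sprintf("  %d of %d loci contribute; groups: %s\n",
              length(object@lociUsed), nrow(object@perLocus),
              paste(object@groups, collapse = ", ")))
})
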