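#' Standardize a dosage matrix
#'
#' Converts minor-allele dosages to per-locus standard scores for kinship
#' estimation: missing cells are imputed with the locus mean dosage (they
#' then contribute zero after centering), each locus is centered on its
#' mean and scaled either by its empirical standard deviation (default,
#' the "standard score") or by sqrt(2 p (1 - p)) with p the minor-allele
#' frequency (the binomial scaling of classic kinship estimators).  Under
#' Hardy-Weinberg proportions the two scalings agree in expectation.
#'
#' @param d a [DosageMatrix-class] with every locus polymorphic.
#' @param scaling `"empirical"` or `"binomial"`.
#' @return a [StandardizedMatrix-class] whose `values` slot is a
#'   samples x loci matrix with column means 0.
#' @export
standardizeDosage <- function(d, scaling = c("empirical", "binomial")) {
  stopifnot(is(d, "DosageMatrix"))
  scaling <- match.arg(scaling)
  X <- t(dosage(d))                      # samples x loci
  nImputed <- sum(is.na(X))
  mu <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(is.na(X)) > 0L))
    X[is.na(X[, j]), j] <- mu[j]
  sdv <- if (scaling == "empirical") apply(X, 2L, stats::sd)
         else { p <- mu / 2; sqrt(2 * p * (1 - p)) }
  if (any(!is.finite(sdv)) || any(sdv == 0))
    pmx_stop("monomorphic_locus",
             "monomorphic locus/loci cannot be standardized: %s",
             paste(colnames(X)[!is.finite(sdv) | sdv == 0], collapse = ", "))
  values <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  new("StandardizedMatrix", values = values, center = mu, scale = sdv,
      scaling = scaling, nImputed = as.integer(nImputed))
}

#' Kinship matrix from standardized genotypes
#'
#' K = M M^T / (2 L) for the samples x loci standardized matrix M with L
#' loci (the divisor is twice the number of SNPs in use).  Because the
#' columns of M are centered, every row of K sums to zero; with empirical
#' scaling the mean diagonal is about 0.5.
#'
#' @param M a [StandardizedMatrix-class] (or a [DosageMatrix-class], which
#'   is standardized first with the default scaling).
#' @param scaling passed to [standardizeDosage()] when `M` is a
#'   [DosageMatrix-class].
#' @return a [KinshipMatrix-class].
#' @export
kinshipMatrix <- function(M, scaling = c("empirical", "binomial")) {
  if (is(M, "DosageMatrix")) M <- standardizeDosage(M, match.arg(scaling))
  stopifnot(is(M, "StandardizedMatrix"))
  L <- ncol(M@values)
  new("KinshipMatrix", K = tcrossprod(M@values) / (2 * L),
      nLoci = as.integer(L), scaling = M@scaling)
}

setMethod("show", "KinshipMatrix", function(object) {
  cat(sprintf("KinshipMatrix: %d x %d samples from %d loci (%s scaling)\n",
              nrow(object@K), ncol(object@K), object@nLoci, object@scaling))
  cat(sprintf("  mean diagonal %.3f, mean off-diagonal %.4f\n",
              mean(diag(object@K)),
              mean(object@K[upper.tri(object@K)])))
})

#' Principal components of a kinship matrix
#'
#' Full symmetric eigendecomposition of K.  Eigenvalues are returned in
#' descending order; each eigenvector's sign is fixed so that its
#' largest-magnitude loading is positive (eigenvectors are otherwise
#' sign-ambiguous).  The eigenvectors are the principal components
#' describing population structure.
#'
#' @param K a [KinshipMatrix-class] (or a plain symmetric matrix).
#' @return a [KinshipPCA-class] with `values`, `vectors` (columns are
#'   components, rows keep the sample names) and `varExplained`
#'   (eigenvalue / sum of positive eigenvalues).
#' @export
kinshipPca <- function(K) {
  mat <- if (is(K, "KinshipMatrix")) K@K else as.matrix(K)
  if (any(!is.finite(mat)))
    pmx_stop("nonfinite_kinship", "kinship matrix has non-finite entries")
  e <- eigen(mat, symmetric = TRUE)
  flip <- apply(e$vectors, 2L, function(v) sign(v[which.max(abs(v))]))
  vectors <- sweep(e$vectors, 2L, flip, "*")
  rownames(vectors) <- rownames(mat)
  colnames(vectors) <- paste0("PC", seq_len(ncol(vectors)))
  pos <- sum(pmax(e$values, 0))
  new("KinshipPCA", values = e$values, vectors = vectors,
      varExplained = if (pos > 0) pmax(e$values, 0) / pos else e$values * 0)
}

setMethod("show", "KinshipPCA", function(object) {
  cat(sprintf("KinshipPCA: %d components\n", length(object@values)))
  cat(sprintf("  top eigenvalues: %s\n",
              paste(format(utils::head(object@values, 5), digits = 3),
                    collapse = ", ")))
})

#' Group-separation diagnostic for PCA scores
#'
#' One-way variance ratio (between-group / within-group mean squares) of a
#' principal-component score across group labels, with a label-permutation
#' reference: separation is declared when the observed ratio exceeds the
#' permutation 95th percentile.
#'
#' @param scores numeric vector of PC scores.
#' @param groups group labels.
#' @param nPerm number of label permutations.
#' @param seed integer seed.
#' @return list with `ratio`, `perm95` (the permutation 95th percentile),
#'   `separated` (logical) and `empiricalP`.
#' @export
pcSeparation <- function(scores, groups, nPerm = 999L, seed = NULL) {
  groups <- factor(groups)
  ratio <- function(x, g) {
    fit <- stats::anova(stats::lm(x ~ g))
    fit$`Mean Sq`[1] / fit$`Mean Sq`[2]
  }
  obs <- ratio(scores, groups)
  null <- with_seed_opt(seed, vapply(seq_len(nPerm), function(i)
    ratio(scores, sample(groups)), numeric(1)))
  list(ratio = obs, perm95 = stats::quantile(null, 0.95, names = FALSE),
       separated = obs > stats::quantile(null, 0.95, names = FALSE),
       empiricalP = empirical_p_upper(obs, null))
}
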