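#' @name relatedness-estimators
#' @title Pairwise relatedness estimators
#'
#' @description
#' Six estimators of pairwise relatedness r (twice the kinship
#' coefficient) from unphased biallelic genotypes and reference allele
#' frequencies:
#'
#' * `quellergt` — Queller & Goodnight's regression estimator, numerators
#'   and denominators summed over loci and over the two focal orderings.
#' * `lynchli` — the Li/Lynch similarity-index estimator,
#'   r = sum(S - S0) / sum(1 - S0) with S0 = 2 a2 - a3.
#' * `lynchrd` — Lynch & Ritland's regression estimator with its own
#'   locus weights, averaged over the two reference orderings.
#' * `ritland` — Ritland's method-of-moments kinship estimator (on the r
#'   scale), averaged over loci.
#' * `wang` — Wang's moment estimator in its biallelic specialization:
#'   with two alleles the joint-genotype similarity classes reduce to
#'   identical / one-shared / opposite-homozygote, the moment system in
#'   (k1, k2) is exactly identified, and the multilocus estimate solves
#'   the 1/(2 a2 - a3)-weighted moment equations.
#' * `dyadml` — dyadic maximum likelihood over the three non-inbred IBD
#'   states (k0, k1, k2) on the simplex (no-inbreeding assumption),
#'   maximized by EM (the log-likelihood is concave on the simplex);
#'   r = k2 + k1/2.
#'
#' Moment estimators can be negative; `dyadml` is constrained and
#' therefore upward-biased for unrelated pairs.  Loci missing in either
#' member of a pair, or monomorphic in the reference frequencies, are
#' excluded pair-wise.
NULL

RELATEDNESS_ESTIMATORS <- c("quellergt", "lynchli", "lynchrd", "ritland",
                            "wang", "dyadml")

# dispatch: DX, DY are pairs x loci dosage matrices (NA = missing in either),
# p the minor-allele frequency per locus, strictly inside (0, 1)
estimate_pairs_matrix <- function(DX, DY, p, estimator) {
  switch(estimator,
         quellergt = .rel_quellergt(DX, DY, p),
         lynchli = .rel_lynchli(DX, DY, p),
         lynchrd = .rel_lynchrd(DX, DY, p),
         ritland = .rel_ritland(DX, DY, p),
         wang = .rel_wang(DX, DY, p),
         dyadml = .rel_dyadml(DX, DY, p),
         pmx_stop("unknown_estimator", "unknown estimator '%s'", estimator))
}

.row_ratio <- function(num, den, mask) {
  num[!mask] <- 0; den[!mask] <- 0
  rowSums(num) / rowSums(den)
}

.rel_quellergt <- function(DX, DY, p) {
  mask <- !is.na(DX) & !is.na(DY)
  P <- matrix(p, nrow(DX), length(p), byrow = TRUE)
  half <- function(A, B) {  # focal A
    num <- ifelse(A == 0, 2 * P - B, ifelse(A == 2, B - 2 * P, 0))
    den <- ifelse(A == 0, 2 * P, ifelse(A == 2, 2 - 2 * P, 0))
    list(num = num, den = den)
  }
  hx <- half(DX, DY); hy <- half(DY, DX)
  .row_ratio(hx$num + hy$num, hx$den + hy$den, mask)
}

.rel_lynchli <- function(DX, DY, p) {
  mask <- !is.na(DX) & !is.na(DY)
  a2 <- p^2 + (1 - p)^2
  a3 <- p^3 + (1 - p)^3
  S0 <- matrix(2 * a2 - a3, nrow(DX), length(p), byrow = TRUE)
  diffd <- abs(DX - DY)
  S <- ifelse(diffd == 0, 1, ifelse(diffd == 1, 0.75, 0))
  .row_ratio(S - S0, 1 - S0, mask)
}

.rel_lynchrd <- function(DX, DY, p) {
  mask <- !is.na(DX) & !is.na(DY)
  q <- 1 - p
  Pm <- matrix(p, nrow(DX), length(p), byrow = TRUE)  # minor freq
  Qm <- 1 - Pm
  half <- function(A, B) {  # focal A; returns weighted numerator and weight
    fyA <- (2 - B) / 2; fyB <- B / 2
    num <- ifelse(A == 0, 2 * (fyA - Qm) / Qm,
           ifelse(A == 2, 2 * (fyB - Pm) / Pm,
                  (Qm * B + Pm * (2 - B) - 4 * Pm * Qm) / (2 * Pm * Qm)))
    w <- ifelse(A == 0, 2 * Pm / Qm,
         ifelse(A == 2, 2 * Qm / Pm, (1 - 4 * Pm * Qm) / (2 * Pm * Qm)))
    list(num = num, w = w)
  }
  hx <- half(DX, DY); hy <- half(DY, DX)
  (.row_ratio(hx$num, hx$w, mask) + .row_ratio(hy$num, hy$w, mask)) / 2
}

.rel_ritland <- function(DX, DY, p) {
  mask <- !is.na(DX) & !is.na(DY)
  Pm <- matrix(p, nrow(DX), length(p), byrow = TRUE)
  Qm <- 1 - Pm
  SA <- ((2 - DX) / 2) * ((2 - DY) / 2)
  SB <- (DX / 2) * (DY / 2)
  r <- 2 * (SA / Qm + SB / Pm - 1)
  r[!mask] <- 0
  rowSums(r) / rowSums(mask)
}

.rel_wang <- function(DX, DY, p) {
  mask <- !is.na(DX) & !is.na(DY)
  q <- 1 - p
  a2 <- p^2 + q^2; a3 <- p^3 + q^3; a4 <- p^4 + q^4
  w <- 1 / (2 * a2 - a3)
  W <- matrix(w, nrow(DX), length(p), byrow = TRUE)
  W[!mask] <- 0
  sw <- rowSums(W)
  diffd <- abs(DX - DY)
  P2 <- rowSums(W * (diffd == 1), na.rm = TRUE) / sw
  P4 <- rowSums(W * (diffd == 2), na.rm = TRUE) / sw
  wavg <- function(x) as.vector(W %*% x) / sw
  A <- wavg(2 * (a2 - a3))        # E[one-shared | k1] coefficient
  B <- wavg(4 * (a3 - a4))        # E[one-shared | k0] coefficient
  C <- wavg(2 * p^2 * q^2)        # E[opposite-homozygote | k0] coefficient
  k0 <- P4 / C
  k1 <- (P2 - k0 * B) / A
  k2 <- 1 - k0 - k1
  k2 + k1 / 2
}

# per-pair x per-locus likelihood components for the 3 IBD states
.dyad_lik_components <- function(DX, DY, p) {
  q <- 1 - p
  P <- matrix(p, nrow(DX), length(p), byrow = TRUE)
  Q <- 1 - P
  pg <- function(A) ifelse(A == 0, Q^2, ifelse(A == 1, 2 * P * Q, P^2))
  gx <- pg(DX)
  L0 <- gx * pg(DY)
  L2 <- gx * (DX == DY)
  trans <- ifelse(DX == 0, ifelse(DY == 0, Q, ifelse(DY == 1, P, 0)),
           ifelse(DX == 2, ifelse(DY == 2, P, ifelse(DY == 1, Q, 0)),
                  ifelse(DY == 1, 0.5, ifelse(DY == 0, Q / 2, P / 2))))
  L1 <- gx * trans
  mask <- !is.na(DX) & !is.na(DY)
  L0[!mask] <- 1; L1[!mask] <- 1; L2[!mask] <- 1
  list(L0 = L0, L1 = L1, L2 = L2, mask = mask)
}

.dyad_loglik <- function(comp, k) {
  D <- comp$L0 * k[, 1] + comp$L1 * k[, 2] + comp$L2 * k[, 3]
  D[!comp$mask] <- 1
  rowSums(log(pmax(D, .Machine$double.xmin)))
}

.rel_dyadml <- function(DX, DY, p, tol = 1e-6, maxIter = 5000L) {
  comp <- .dyad_lik_components(DX, DY, p)
  nP <- nrow(DX)
  nl <- rowSums(comp$mask)
  k <- matrix(1 / 3, nP, 3L)
  # EM on the 3-state mixture (concave log-likelihood, monotone updates);
  # converged dyads drop out of the active set to keep large tables fast
  active <- seq_len(nP)
  L0 <- comp$L0; L1 <- comp$L1; L2 <- comp$L2
  msk <- comp$mask; nla <- nl
  ka <- k
  for (it in seq_len(maxIter)) {
    D <- L0 * ka[, 1] + L1 * ka[, 2] + L2 * ka[, 3]
    D[!msk] <- 1
    D <- pmax(D, .Machine$double.xmin)
    knew <- cbind(rowSums(msk * L0 * ka[, 1] / D),
                  rowSums(msk * L1 * ka[, 2] / D),
                  rowSums(msk * L2 * ka[, 3] / D)) / nla
    moved <- matrixStats_rowMaxs(abs(knew - ka))
    ka <- knew
    done <- moved < tol
    if (any(done)) {
      k[active[done], ] <- ka[done, , drop = FALSE]
      stay <- !done
      active <- active[stay]
      if (!length(active)) break
      ka <- ka[stay, , drop = FALSE]
      L0 <- L0[stay, , drop = FALSE]; L1 <- L1[stay, , drop = FALSE]
      L2 <- L2[stay, , drop = FALSE]; msk <- msk[stay, , drop = FALSE]
      nla <- nla[stay]
    }
  }
  if (length(active)) k[active, ] <- ka
  structure(k[, 3] + k[, 2] / 2, k = k)
}

# rowMaxs without a matrixStats dependency
matrixStats_rowMaxs <- function(m) do.call(pmax, asplit(m, 2L))

#' Align external reference frequencies with a dosage orientation
#'
#' A [DosageMatrix-class] orients each locus by the minor allele of the
#' sample at hand; externally supplied reference frequencies (e.g. a
#' generator's truth record) may be expressed for the other allele.  Given
#' the frequencies and the allele symbols they refer to, returns the
#' frequency of each locus's dosage-orientation minor allele.
#'
#' @param d a [DosageMatrix-class].
#' @param freqs named per-locus frequencies.
#' @param alleles named per-locus allele symbols that `freqs` refer to.
#' @return per-locus frequencies aligned with `dosage(d)`.
#' @export
alignFreqs <- function(d, freqs, alleles) {
  loci <- rownames(d)
  f <- unname(freqs[loci])
  a <- unname(alleles[loci])
  # monomorphic loci orient the dosage by the absent allele: the observed
  # symbol is the major one, so the dosage-minor is `a` unless everyone
  # carries `a`
  mono <- minorFreq(d)[loci] == 0
  out <- ifelse(minorAllele(d)[loci] == a, f, 1 - f)
  out[mono] <- ifelse(majorAllele(d)[loci][mono] == a[mono],
                      1 - f[mono], f[mono])
  stats::setNames(out, loci)
}

# reference minor-allele frequencies from the full sample
.ref_freqs <- function(d) {
  dos <- dosage(d)
  rowSums(dos, na.rm = TRUE) / (2 * rowSums(!is.na(dos)))
}

#' Pairwise relatedness for one dyad
#'
#' @param d a [DosageMatrix-class].
#' @param i,j sample identifiers (or indices) of the dyad.
#' @param estimator one of `"quellergt"`, `"lynchli"`, `"lynchrd"`,
#'   `"ritland"`, `"wang"`, `"dyadml"` (see [relatedness-estimators]).
#' @param freqs optional per-locus reference minor-allele frequencies;
#'   defaults to the frequencies of the full sample (including the dyad).
#' @return the relatedness estimate (for `dyadml` with attribute `k`, the
#'   estimated IBD-state probabilities).
#' @export
pairRelatedness <- function(d, i, j, estimator = "quellergt", freqs = NULL) {
  stopifnot(is(d, "DosageMatrix"))
  if (!estimator %in% RELATEDNESS_ESTIMATORS)
    pmx_stop("unknown_estimator", "unknown estimator '%s'", estimator)
  dos <- dosage(d)
  if (is.character(i)) i <- match(i, colnames(dos))
  if (is.character(j)) j <- match(j, colnames(dos))
  if (anyNA(c(i, j)) || i == j)
    pmx_stop("invalid_pair", "need two distinct, known samples")
  if (is.null(freqs)) freqs <- .ref_freqs(d)
  use <- freqs > 0 & freqs < 1
  if (!any(use)) pmx_stop("monomorphic_locus", "no polymorphic locus")
  DX <- matrix(dos[use, i], 1L)
  DY <- matrix(dos[use, j], 1L)
  if (!any(!is.na(DX) & !is.na(DY)))
    pmx_stop("no_shared_loci", "samples share no typed locus")
  estimate_pairs_matrix(DX, DY, freqs[use], estimator)
}

.pair_class <- function(h1, h2) {
  ini <- c(benthic = "B", littoral = "L", pelagic = "P")
  apply(cbind(ini[h1], ini[h2]), 1L, function(x) paste(sort(x), collapse = ""))
}

#' Pairwise coancestry table
#'
#' Relatedness for every unordered sample pair under the requested
#' estimators, with each pair classified by its habitat combination
#' (within-group BB/LL/PP or between-group BL/BP/LP).  Pairs sharing no
#' typed locus are dropped with a warning.
#'
#' @param d a [DosageMatrix-class] with at least two samples.
#' @param estimators subset of the six estimator names (all by default).
#' @param freqs optional reference minor-allele frequencies (defaults to
#'   the full-sample frequencies).
#' @param groups optional per-sample labels used for the pair classes
#'   (defaults to the habitat labels).
#' @param pairs optional two-column data.frame of sample ids restricting
#'   the table to specific dyads (all unordered pairs by default).
#' @return a [S4Vectors::DataFrame] with columns `id1`, `id2`, `class` and
#'   one column per estimator.
#' @export
coancestryTable <- function(d, estimators = RELATEDNESS_ESTIMATORS,
                            freqs = NULL, groups = NULL, pairs = NULL) {
  stopifnot(is(d, "DosageMatrix"))
  bad <- setdiff(estimators, RELATEDNESS_ESTIMATORS)
  if (length(bad))
    pmx_stop("unknown_estimator", "unknown estimator(s): %s",
             paste(bad, collapse = ", "))
  dos <- dosage(d)
  N <- ncol(dos)
  if (N < 2L) pmx_stop("invalid_pair", "need at least two samples")
  if (is.null(freqs)) freqs <- .ref_freqs(d)
  if (is.null(groups)) groups <- habitat(d)
  use <- freqs > 0 & freqs < 1 & !is.na(freqs)
  dos <- dos[use, , drop = FALSE]
  p <- freqs[use]
  if (is.null(pairs)) {
    pr <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
    pr <- pr[order(pr[, 1L], pr[, 2L]), , drop = FALSE]
  } else {
    pr <- cbind(match(pairs[[1L]], colnames(dos)),
                match(pairs[[2L]], colnames(dos)))
    if (anyNA(pr)) pmx_stop("invalid_pair", "unknown sample id in pairs")
  }
  DX <- t(dos)[pr[, 1L], , drop = FALSE]
  DY <- t(dos)[pr[, 2L], , drop = FALSE]
  shared <- rowSums(!is.na(DX) & !is.na(DY))
  if (any(shared == 0L)) {
    pmx_warn("dropping %d pair(s) with no shared typed locus",
             sum(shared == 0L))
    keep <- shared > 0L
    pr <- pr[keep, , drop = FALSE]
    DX <- DX[keep, , drop = FALSE]
    DY <- DY[keep, , drop = FALSE]
  }
  out <- S4Vectors::DataFrame(
    id1 = colnames(dos)[pr[, 1L]], id2 = colnames(dos)[pr[, 2L]],
    class = .pair_class(groups[pr[, 1L]], groups[pr[, 2L]]))
  for (est in estimators)
    out[[est]] <- as.vector(estimate_pairs_matrix(DX, DY, p, est))
  out
}

#' Bonferroni-corrected significance threshold
#'
#' @param familyAlpha family-wise significance level.
#' @param nTests number of comparisons (e.g. 3 groups x 7 estimators = 21,
#'   giving 0.05 / 21 ~ 0.002).
#' @return the per-test threshold familyAlpha / nTests.
#' @export
bonferroniThreshold <- function(familyAlpha, nTests) {
  if (nTests < 1) pmx_stop("invalid_spec", "nTests must be >= 1")
  familyAlpha / nTests
}

#' Permutation test of within-group coancestry
#'
#' Tests, for each group and estimator, whether the mean pairwise
#' relatedness within the group exceeds what is expected when group
#' membership is random: individuals (genotypes) are permuted across
#' groups `nPerm` times with group sizes fixed, the within-group mean is
#' recomputed from the unchanged pairwise values, and the empirical
#' P-value is (1 + #\{null >= observed\}) / (1 + nPerm).  Significance is
#' judged against the Bonferroni threshold familyAlpha / nTests.
#'
#' @inheritParams coancestryTable
#' @param nPerm number of permutations (study default 2500).
#' @param familyAlpha family-wise alpha (default 0.05).
#' @param nTests number of comparisons Bonferroni-corrected for
#'   (default 21).
#' @param seed integer seed.
#' @return a [CoancestryPermTest-class].
#' @export
coancestryPermTest <- function(d, estimators = RELATEDNESS_ESTIMATORS,
                               groups = NULL, freqs = NULL, nPerm = 2500L,
                               familyAlpha = 0.05, nTests = 21L,
                               seed = NULL) {
  stopifnot(is(d, "DosageMatrix"))
  if (is.null(groups)) groups <- habitat(d)
  groups <- factor(groups)
  if (any(table(groups) < 2L))
    pmx_stop("invalid_spec", "every group needs at least two samples")
  if (nPerm < 1L) pmx_stop("invalid_spec", "nPerm must be >= 1")
  N <- ncol(d)
  tab <- coancestryTable(d, estimators, freqs = freqs,
                         groups = as.character(groups))
  i <- match(tab$id1, colnames(d))
  j <- match(tab$id2, colnames(d))
  permLabels <- with_seed_opt(seed, replicate(nPerm, sample(as.integer(groups))))
  G <- nlevels(groups)
  observed <- matrix(NA_real_, G, length(estimators),
                     dimnames = list(levels(groups), estimators))
  empiricalP <- observed
  nullMeans <- list()
  for (est in estimators) {
    r <- tab[[est]]
    ok <- !is.na(r)
    Mv <- Mn <- matrix(0, N, N)
    Mv[cbind(i[ok], j[ok])] <- r[ok]
    Mv <- Mv + t(Mv)
    Mn[cbind(i[ok], j[ok])] <- 1
    Mn <- Mn + t(Mn)
    nullG <- matrix(NA_real_, nPerm, G, dimnames = list(NULL, levels(groups)))
    for (g in seq_len(G)) {
      xobs <- as.numeric(as.integer(groups) == g)
      observed[g, est] <- (xobs %*% Mv %*% xobs) / (xobs %*% Mn %*% xobs)
      X <- matrix(as.numeric(permLabels == g), N, nPerm)
      nullG[, g] <- colSums(X * (Mv %*% X)) / colSums(X * (Mn %*% X))
      empiricalP[g, est] <- empirical_p_upper(observed[g, est], nullG[, g])
    }
    nullMeans[[est]] <- nullG
  }
  new("CoancestryPermTest", observed = observed, empiricalP = empiricalP,
      nullMeans = nullMeans, nPerm = as.integer(nPerm),
      familyAlpha = familyAlpha, nTests = as.integer(nTests),
      threshold = bonferroniThreshold(familyAlpha, nTests), seed = seed)
}

setMethod("show", "CoancestryPermTest", function(object) {
  cat(sprintf(
    "CoancestryPermTest: %d permutations, Bonferroni threshold %.4g (%g / %d)\n",
    object@nPerm, object@threshold, object@familyAlpha, object@nTests))
  cat("  empirical P (within-group mean relatedness, upper tail):\n")
  print(round(object@empiricalP, 4))
  sig <- which(object@empiricalP < object@threshold, arr.ind = TRUE)
  if (nrow(sig)) {
    cat("  significant after Bonferroni:\n")
    for (k in seq_len(nrow(sig)))
      cat(sprintf("    %s / %s\n", rownames(object@empiricalP)[sig[k, 1]],
                  colnames(object@empiricalP)[sig[k, 2]]))
  } else cat("  no group exceeds its permutation null after Bonferroni\n")
})
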