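#' Bayesian admixture model by Gibbs sampling
#'
#' Fits the classic admixture model for unlinked biallelic loci: each
#' individual i has membership proportions Q[i, ] over K clusters
#' (Dirichlet(alpha) prior, alpha shared and inferred), each cluster k has
#' a minor-allele frequency P[l, k] per locus (uniform Beta(1, 1) prior),
#' and every allele copy is drawn by first choosing a cluster from Q[i, ]
#' and then an allele from that cluster's frequency.  One Gibbs cycle
#' samples (i) the latent cluster of every allele copy given (Q, P),
#' (ii) P from its Beta full conditionals, (iii) Q rows from
#' Dirichlet(alpha + cluster counts), and (iv) alpha by a Metropolis step
#' with a uniform prior on (0, 10].  Posterior means are taken over the
#' post-burn-in cycles; no relabeling is applied within a chain (under
#' panmixia the label symmetry of the posterior is itself the signal).
#'
#' Missing genotypes contribute no allele copies.  An optional simplified
#' sampling-location prior replaces the shared Dirichlet mean by
#' group-specific means mu\[g, \] (each with its own Metropolis update),
#' so that Q[i, ] ~ Dirichlet(alpha * K * mu[group(i), ]); it is off by
#' default.
#'
#' @param d a [DosageMatrix-class] with polymorphic loci.
#' @param K number of clusters (>= 1).
#' @param burnIn,samples burn-in and sampling cycles.  Desk-scale defaults
#'   (5000 / 2000) are used throughout the package; study-scale runs
#'   (250000 / 50000) are a matter of passing larger values.
#' @param locationPrior enable the simplified location prior using the
#'   habitat labels of `d`.
#' @param alphaInit initial value of the Dirichlet admixture parameter.
#' @param alphaStep initial Metropolis step standard deviation for alpha.
#' @param alphaAdapt adapt the alpha proposal step during burn-in toward a
#'   0.3-0.5 acceptance rate (frozen once sampling starts, so the sampling
#'   phase is a valid fixed-kernel chain)?  At desk-scale cycle counts a
#'   fixed small step leaves the alpha random walk far from stationarity;
#'   adaptation is the standard remedy.
#' @param storeTrace store every 10th post-burn-in Q draw (for
#'   diagnostics).
#' @param seed integer seed; seeded runs are reproducible.
#' @return an [AdmixtureResult-class].
#' @examples
#' gt <- generateGenotypes("panmictic", seed = 7)
#' res <- gibbsAdmixture(toDosage(gt), K = 2, burnIn = 200, samples = 100,
#'                       seed = 7)
#' symmetryDiagnostic(res)
#' @export
gibbsAdmixture <- function(d, K, burnIn = 5000L, samples = 2000L,
                           locationPrior = FALSE, alphaInit = 1,
                           alphaStep = 0.05, alphaAdapt = TRUE,
                           storeTrace = FALSE, seed = NULL) {
  stopifnot(is(d, "DosageMatrix"))
  K <- as.integer(K)
  if (K < 1L) pmx_stop("invalid_spec", "K must be >= 1")
  if (burnIn < 1L || samples < 1L)
    pmx_stop("invalid_spec", "burnIn and samples must be >= 1")
  dos <- dosage(d)
  L <- nrow(dos); N <- ncol(dos)
  Ymin <- dos; Ymin[is.na(Ymin)] <- 0L          # minor copies per (locus, ind)
  Ymaj <- 2L - dos; Ymaj[is.na(dos)] <- 0L      # major copies
  grp <- if (locationPrior) factor(habitat(d)) else factor(rep(1L, N))
  G <- nlevels(grp)
  if (K == 1L) {
    Q <- matrix(1, N, 1L, dimnames = list(colnames(dos), "cluster1"))
    P <- matrix(rowSums(Ymin) / pmax(rowSums(Ymin + Ymaj), 1L), L, 1L,
                dimnames = list(rownames(dos), "cluster1"))
    return(new("AdmixtureResult", Q = Q, P = P, alphaTrace = numeric(),
               K = 1L, burnIn = as.integer(burnIn),
               samples = as.integer(samples),
               locationPrior = locationPrior, Qtrace = NULL, seed = seed))
  }
  with_seed_opt(seed, {
    pObs <- rowSums(Ymin) / pmax(rowSums(Ymin + Ymaj), 1L)
    P <- matrix(pmin(pmax(pObs + stats::rnorm(L * K, 0, 0.05), 0.01), 0.99),
                L, K)
    Q <- matrix(1 / K, N, K)
    alpha <- alphaInit
    mu <- matrix(1 / K, G, K)
    Qsum <- matrix(0, N, K); Psum <- matrix(0, L, K)
    accWindow <- 0L; accN <- 0L
    alphaTrace <- numeric(samples)
    Qtrace <- if (storeTrace) vector("list", samples %/% 10L) else NULL
    # multinomial split of n copies over K clusters with per-cell weights
    # w_k = q_ik * f(P_lk): sequential binomial thinning, vectorized
    splitCopies <- function(Ycnt, weights) {
      rest <- Ycnt
      wrest <- Reduce(`+`, weights)
      out <- vector("list", K)
      for (k in seq_len(K - 1L)) {
        pr <- weights[[k]] / pmax(wrest, .Machine$double.xmin)
        out[[k]] <- matrix(rbinom(L * N, rest, pmin(pr, 1)), L, N)
        rest <- rest - out[[k]]
        wrest <- wrest - weights[[k]]
      }
      out[[K]] <- rest
      out
    }
    for (cycle in seq_len(burnIn + samples)) {
      wMin <- lapply(seq_len(K), function(k)
        outer(P[, k], Q[, k]))                 # L x N weights, minor copies
      wMaj <- lapply(seq_len(K), function(k)
        outer(1 - P[, k], Q[, k]))
      nMin <- splitCopies(Ymin, wMin)
      nMaj <- splitCopies(Ymaj, wMaj)
      for (k in seq_len(K))
        P[, k] <- rbeta(L, 1 + rowSums(nMin[[k]]), 1 + rowSums(nMaj[[k]]))
      counts <- vapply(seq_len(K), function(k)
        colSums(nMin[[k]]) + colSums(nMaj[[k]]), numeric(N))   # N x K
      prior <- if (locationPrior) alpha * K * mu[as.integer(grp), , drop = FALSE]
               else matrix(alpha, N, K)
      gam <- matrix(rgamma(N * K, shape = counts + prior), N, K)
      Q <- gam / rowSums(gam)
      Q <- pmin(pmax(Q, 1e-12), 1)
      Q <- Q / rowSums(Q)
      slq <- if (locationPrior) rowsum(log(Q), grp) else
        matrix(colSums(log(Q)), 1L)
      logpostAlpha <- function(a) {
        if (a <= 0 || a > 10) return(-Inf)
        pri <- if (locationPrior) a * K * mu else matrix(a, 1L, K)
        tot <- tabulate(as.integer(grp), nbins = G)
        sum(tot * (lgamma(rowSums(pri)) - rowSums(lgamma(pri))) +
              rowSums((pri - 1) * slq))
      }
      aProp <- alpha + stats::rnorm(1, 0, alphaStep)
      accepted <- log(stats::runif(1)) < logpostAlpha(aProp) - logpostAlpha(alpha)
      if (accepted) alpha <- aProp
      if (alphaAdapt && cycle <= burnIn) {
        accWindow <- accWindow + accepted; accN <- accN + 1L
        if (accN == 50L) {
          rate <- accWindow / accN
          if (rate > 0.5) alphaStep <- min(alphaStep * 1.2, 2)
          if (rate < 0.3) alphaStep <- max(alphaStep * 0.8, 0.01)
          accWindow <- 0L; accN <- 0L
        }
      }
      if (locationPrior) {
        for (g in seq_len(G)) {
          prop <- mu[g, ] * exp(stats::rnorm(K, 0, 0.1))
          prop <- prop / sum(prop)
          muNew <- mu; muNew[g, ] <- prop
          lp <- function(mm) {
            pri <- alpha * K * mm[g, ]
            ng <- sum(as.integer(grp) == g)
            ng * (lgamma(sum(pri)) - sum(lgamma(pri))) +
              sum((pri - 1) * slq[g, ])
          }
          if (log(stats::runif(1)) < lp(muNew) - lp(mu)) mu <- muNew
        }
      }
      if (cycle > burnIn) {
        s <- cycle - burnIn
        Qsum <- Qsum + Q; Psum <- Psum + P
        alphaTrace[s] <- alpha
        if (storeTrace && s %% 10L == 0L) Qtrace[[s %/% 10L]] <- Q
      }
    }
    Qm <- Qsum / samples; Pm <- Psum / samples
    dimnames(Qm) <- list(colnames(dos), paste0("cluster", seq_len(K)))
    dimnames(Pm) <- list(rownames(dos), paste0("cluster", seq_len(K)))
    new("AdmixtureResult", Q = Qm, P = Pm, alphaTrace = alphaTrace,
        K = K, burnIn = as.integer(burnIn), samples = as.integer(samples),
        locationPrior = locationPrior, Qtrace = Qtrace, seed = seed)
  })
}

setMethod("show", "AdmixtureResult", function(object) {
  cat(sprintf("AdmixtureResult: K = %d, %d individuals, %d loci\n",
              object@K, nrow(object@Q), nrow(object@P)))
  cat(sprintf("  cycles: %d burn-in + %d sampling; location prior: %s\n",
              object@burnIn, object@samples, object@locationPrior))
  if (length(object@alphaTrace))
    cat(sprintf("  alpha posterior mean %.3f (sd %.3f)\n",
                mean(object@alphaTrace), stats::sd(object@alphaTrace)))
  cat(sprintf("  max deviation from uniform membership: %.3f\n",
              symmetryDiagnostic(object)))
})

#' Deviation of admixture proportions from perfect symmetry
#'
#' The maximum over individuals of the L-infinity distance between the
#' posterior-mean membership row and the uniform vector (1/K, ..., 1/K).
#' Under panmixia every individual is an equal mixture of all clusters and
#' the diagnostic is near zero; a fully assigned individual gives
#' 1 - 1/K.
#'
#' @param result an [AdmixtureResult-class] (or a Q matrix).
#' @return a non-negative scalar.
#' @export
symmetryDiagnostic <- function(result) {
  Q <- if (is(result, "AdmixtureResult")) result@Q else as.matrix(result)
  max(abs(Q - 1 / ncol(Q)))
}

#' Align cluster labels between admixture runs
#'
#' Greedy matching of the columns of `Q` to those of a reference run by
#' correlation, for comparing reported runs (no relabeling is done within
#' a chain).
#'
#' @param Q,Qref membership matrices with equal dimensions.
#' @return `Q` with columns permuted to best match `Qref`.
#' @export
alignClusters <- function(Q, Qref) {
  K <- ncol(Q)
  stopifnot(ncol(Qref) == K)
  cors <- suppressWarnings(stats::cor(Q, Qref))
  cors[!is.finite(cors)] <- 0
  perm <- integer(K)
  for (step in seq_len(K)) {
    idx <- which(cors == max(cors), arr.ind = TRUE)[1L, ]
    perm[idx[2L]] <- idx[1L]
    cors[idx[1L], ] <- -Inf; cors[, idx[2L]] <- -Inf
  }
  Q[, perm, drop = FALSE]
}

# log-likelihood of the dosage data under fixed (Q, P); used by sanity
# checks comparing the posterior mean against random parameters
admixture_loglik <- function(d, Q, P) {
  dos <- dosage(d)
  pInd <- P %*% t(Q)            # L x N per-copy minor probability
  ll <- stats::dbinom(dos, 2L, pInd, log = TRUE)
  sum(ll[!is.na(dos)])
}
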