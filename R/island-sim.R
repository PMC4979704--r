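#' @describeIn IslandConfig-class constructor with study-scale defaults
#'   (three demes of 1500 diploids, 3150 unlinked loci).
#' @param nDemes,demeSize,nLoci,migrationRate,initFreqRange,burnInGenerations,minGenerations,checkEvery,seed
#'   see the class description.
#' @export
islandConfig <- function(nDemes = 3L, demeSize = 1500L, nLoci = 3150L,
                         migrationRate, initFreqRange = c(0.05, 0.95),
                         burnInGenerations = 10L * demeSize,
                         minGenerations = 200L, checkEvery = 50L,
                         seed = NULL) {
  new("IslandConfig", nDemes = as.integer(nDemes),
      demeSize = as.integer(demeSize), nLoci = as.integer(nLoci),
      migrationRate = migrationRate, initFreqRange = initFreqRange,
      burnInGenerations = as.integer(burnInGenerations),
      minGenerations = as.integer(minGenerations),
      checkEvery = as.integer(checkEvery), seed = seed)
}

setMethod("show", "IslandConfig", function(object) {
  cat(sprintf(
    "IslandConfig: %d demes x %d diploids, %d loci, m = %.5g, burn-in <= %d\n",
    object@nDemes, object@demeSize, object@nLoci, object@migrationRate,
    object@burnInGenerations))
})

#' Closed-form island-model migration rate
#'
#' Wright's finite-island approximation Fst = 1 / (1 + 4 N m (d/(d-1))^2)
#' inverted for m; used to initialize [calibrateMigration()].
#'
#' @param targetFst desired equilibrium Fst.
#' @param demeSize diploid deme size N.
#' @param nDemes number of demes d.
#' @return the per-generation migration rate m.
#' @export
islandClosedFormM <- function(targetFst, demeSize, nDemes) {
  cf <- (nDemes / (nDemes - 1))^2
  (1 / targetFst - 1) / (4 * demeSize * cf)
}

# parametric Fst from census deme allele frequencies (ratio of sums;
# across-deme sample variance with divisor d-1, matching the WC estimand)
param_fst <- function(freq) {
  pbar <- rowMeans(freq)
  s2 <- rowSums((freq - pbar)^2) / (ncol(freq) - 1)
  keep <- pbar > 0 & pbar < 1
  sum(s2[keep]) / sum((pbar * (1 - pbar))[keep])
}

#' Forward Wright-Fisher island-model simulation
#'
#' Simulates `nDemes` demes of `demeSize` diploids at unlinked biallelic
#' loci.  Each generation the deme gamete pools receive a fraction
#' `migrationRate` of migrant gametes drawn equally from the other demes
#' (conservative symmetric island migration), then 2N gametes per deme are
#' binomially resampled (Wright-Fisher drift).  Founding allele frequencies
#' are uniform on `initFreqRange` and identical across demes.
#'
#' The burn-in stops at "migration-drift equilibrium": after
#' `minGenerations`, realized Fst is monitored every `checkEvery`
#' generations and the run stops once the trailing-window trend is
#' statistically indistinguishable from zero or practically negligible
#' (<5% relative change across the window), up to the hard cap
#' `burnInGenerations`.  Diploid genotypes are then drawn from the final
#' deme gamete pools, and the realized Fst (Weir-Cockerham estimate on the
#' full census, demes as groups) is recorded.
#'
#' @param cfg an [IslandConfig-class].
#' @return a [SimulatedPopulation-class].
#' @examples
#' cfg <- islandConfig(demeSize = 200, nLoci = 100, migrationRate = 0.05,
#'                     burnInGenerations = 500, seed = 1)
#' pop <- simulateIsland(cfg)
#' pop@realizedFst
#' @export
simulateIsland <- function(cfg) {
  stopifnot(is(cfg, "IslandConfig"))
  methods::validObject(cfg)
  with_seed_opt(cfg@seed, {
    d <- cfg@nDemes; N <- cfg@demeSize; L <- cfg@nLoci
    m <- cfg@migrationRate
    p0 <- runif(L, cfg@initFreqRange[1], cfg@initFreqRange[2])
    freq <- matrix(p0, L, d)
    gen <- 0L
    history <- numeric()
    histGen <- integer()
    repeat {
      steps <- min(cfg@checkEvery, cfg@burnInGenerations - gen)
      if (steps <= 0L) break
      for (s in seq_len(steps)) {
        pool <- (1 - m) * freq + m * (rowSums(freq) - freq) / (d - 1)
        freq <- matrix(rbinom(L * d, 2L * N, as.vector(pool)) / (2 * N), L, d)
      }
      gen <- gen + steps
      history <- c(history, param_fst(freq))
      histGen <- c(histGen, gen)
      if (gen >= cfg@minGenerations && length(history) >= 5L) {
        w <- (length(history) - 4L):length(history)
        fit <- stats::lm(history[w] ~ histGen[w])
        sl <- summary(fit)$coefficients
        flat <- nrow(sl) > 1 &&
          (is.na(sl[2, 4]) || sl[2, 4] > 0.05 ||
             abs(sl[2, 1]) * diff(range(histGen[w])) <
               0.05 * max(mean(history[w]), 1e-6))
        if (flat) break
      }
      if (gen >= cfg@burnInGenerations) break
    }
    # diploid genotypes: individuals of deme j are HWE at freq[, j]
    dos <- do.call(cbind, lapply(seq_len(d), function(j)
      matrix(rbinom(L * N, 2L, rep(freq[, j], N)), L, N)))
    deme <- factor(rep(paste0("deme", seq_len(d)), each = N))
    colnames(dos) <- sprintf("sim_%s_%04d", as.character(deme),
                             sequence(rep(N, d)))
    rownames(dos) <- sprintf("locus%04d", seq_len(L))
    realized <- tryCatch(wc_theta(dos, deme), panmix_error = function(e) 0)
    new("SimulatedPopulation", dosage = dos, deme = deme, demeFreq = freq,
        realizedFst = realized, generations = gen, config = cfg,
        seed = cfg@seed)
  })
}

setMethod("show", "SimulatedPopulation", function(object) {
  cat(sprintf(
    "SimulatedPopulation: %d demes x %d diploids, %d loci\n  realized Fst = %.5g after %d generations (m = %.5g)\n",
    object@config@nDemes, object@config@demeSize, nrow(object@dosage),
    object@realizedFst, object@generations, object@config@migrationRate))
})

#' Calibrate the migration rate to a target Fst
#'
#' Finds a migration rate whose mean realized Fst over `nReplicates`
#' simulations is within `tolerance` (relative) of `targetFst`.  The search
#' starts at the island-model closed form ([islandClosedFormM()]) and
#' refines by bisection on log(m) (realized Fst is monotone decreasing in
#' m), up to `maxRounds` evaluations.
#'
#' @param targetFst target equilibrium Fst, in (0, 0.5).
#' @param cfg an [IslandConfig-class]; its `migrationRate` is ignored.
#'   Calibration can use fewer loci than the final simulation: realized Fst
#'   depends only on the demography.
#' @param tolerance relative tolerance on the mean realized Fst.
#' @param nReplicates simulation replicates per candidate m.
#' @param maxRounds maximum bisection evaluations before the documented
#'   non-convergence error is raised.
#' @param seed integer seed for the calibration simulations.
#' @return the calibrated migration rate (numeric scalar) with attribute
#'   `realizedFst` (the mean realized Fst at acceptance).
#' @export
calibrateMigration <- function(targetFst, cfg, tolerance = 0.15,
                               nReplicates = 3L, maxRounds = 12L,
                               seed = NULL) {
  if (targetFst <= 0 || targetFst >= 0.5)
    pmx_stop("invalid_spec", "targetFst must be in (0, 0.5)")
  seeds <- derive_seeds(seed, maxRounds * nReplicates)
  evalM <- function(m, round) {
    mean(vapply(seq_len(nReplicates), function(i) {
      c2 <- cfg
      c2@migrationRate <- min(m, 1)
      c2@seed <- seeds[[(round - 1L) * nReplicates + i]]
      simulateIsland(c2)@realizedFst
    }, numeric(1)))
  }
  m <- islandClosedFormM(targetFst, cfg@demeSize, cfg@nDemes)
  lo <- hi <- NULL   # lo: m giving Fst above target; hi: m giving Fst below
  for (round in seq_len(maxRounds)) {
    fst <- evalM(m, round)
    if (abs(fst - targetFst) <= tolerance * targetFst) {
      attr(m, "realizedFst") <- fst
      return(m)
    }
    if (fst > targetFst) lo <- m else hi <- m
    m <- if (is.null(lo)) m / 3
         else if (is.null(hi)) m * 3
         else sqrt(lo * hi)
  }
  pmx_stop("calibration_failure",
           "migration calibration did not converge to Fst %.4g in %d rounds",
           targetFst, maxRounds)
}

#' Subsampling null distribution of overall Fst
#'
#' Repeatedly samples individuals without replacement per deme (the study's
#' group sizes by default) and loci without replacement from the loci
#' polymorphic in the full simulated population, computing the overall
#' Weir-Cockerham theta with demes as groups for each replicate.  The
#' empirical P-value of `observedTheta` is the lower-tail fraction of
#' replicates with theta <= observed (plug-in convention by default; set
#' `addOne` for the (count+1)/(reps+1) form).
#'
#' @param pop a [SimulatedPopulation-class].
#' @param groupSizes individuals drawn per deme (default 55/55/49).
#' @param nLociSample loci drawn per replicate (default 32).
#' @param nReps number of replicates.
#' @param observedTheta observed overall theta to locate in the null.
#' @param addOne use (count + 1) / (reps + 1) instead of the plug-in
#'   fraction.
#' @param seed integer seed.
#' @return an [FstNullResult-class].
#' @export
resampleFstNull <- function(pop, groupSizes = c(55L, 55L, 49L),
                            nLociSample = 32L, nReps = 10000L,
                            observedTheta, addOne = FALSE, seed = NULL) {
  stopifnot(is(pop, "SimulatedPopulation"))
  d <- pop@config@nDemes
  if (length(groupSizes) != d)
    pmx_stop("invalid_spec", "need one group size per deme")
  if (any(groupSizes > pop@config@demeSize))
    pmx_stop("invalid_spec", "group sizes exceed deme size")
  poly <- which(apply(pop@dosage, 1L, function(x) length(unique(x)) > 1L))
  if (length(poly) < nLociSample)
    pmx_stop("invalid_spec", "fewer polymorphic loci than requested")
  demeIdx <- split(seq_along(pop@deme), pop@deme)
  groups <- factor(rep(seq_len(d), groupSizes))
  thetas <- with_seed_opt(seed, vapply(seq_len(nReps), function(rep) {
    ind <- unlist(lapply(seq_len(d), function(j)
      sample(demeIdx[[j]], groupSizes[j])))
    loci <- sample(poly, nLociSample)
    wc_theta(pop@dosage[loci, ind, drop = FALSE], groups)
  }, numeric(1)))
  k <- sum(thetas <= observedTheta)
  p <- if (addOne) (k + 1) / (nReps + 1) else k / nReps
  new("FstNullResult", replicateThetas = thetas, nReps = as.integer(nReps),
      observedTheta = observedTheta, empiricalP = p,
      groupSizes = as.integer(groupSizes),
      nLociSample = as.integer(nLociSample), addOne = addOne, seed = seed)
}

setMethod("show", "FstNullResult", function(object) {
  q <- stats::quantile(object@replicateThetas, c(0.025, 0.5, 0.975))
  cat(sprintf("FstNullResult: %d replicates of %d loci x %s individuals\n",
              object@nReps, object@nLociSample,
              paste(object@groupSizes, collapse = "/")))
  cat(sprintf("  null theta quantiles: 2.5%% %.4g, median %.4g, 97.5%% %.4g\n",
              q[1], q[2], q[3]))
  cat(sprintf("  observed theta = %.4g, empirical P (lower tail) = %.4g\n",
              object@observedTheta, object@empiricalP))
})
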