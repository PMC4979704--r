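# Small in-code fixtures and independent oracles shared across tests.

# three samples x two loci, all habitats legal, one missing cell
tiny_calls <- function() {
  matrix(c("AC", "AA", "CC",
           "GG", "GT", NA), nrow = 2, byrow = TRUE,
         dimnames = list(c("L1", "L2"), c("s1", "s2", "s3")))
}

tiny_gt <- function() {
  GenotypeTable(tiny_calls(), habitat = c("benthic", "littoral", "pelagic"),
                batch = c(1, 1, 2), linkageGroup = c(3L, 7L))
}

# random valid GenotypeTable for round-trip properties
random_gt <- function(nSamples = 12, nLoci = 6, seed = 1) {
  withr::with_seed(seed, {
    alleles <- replicate(nLoci, sample(c("A", "C", "G", "T"), 2), simplify = FALSE)
    calls <- vapply(seq_len(nLoci), function(l) {
      dos <- sample(0:2, nSamples, replace = TRUE)
      g <- c(paste0(rep(min(alleles[[l]]), 2), collapse = ""),
             paste0(sort(alleles[[l]]), collapse = ""),
             paste0(rep(max(alleles[[l]]), 2), collapse = ""))
      out <- g[dos + 1]
      out[sample(nSamples, 1)] <- NA
      out
    }, character(nSamples))
    calls <- t(calls)
    dimnames(calls) <- list(sprintf("loc%02d", seq_len(nLoci)),
                            sprintf("s%02d", seq_len(nSamples)))
    GenotypeTable(calls,
                  habitat = sample(c("benthic", "littoral", "pelagic"),
                                   nSamples, replace = TRUE),
                  batch = sample(1:2, nSamples, replace = TRUE),
                  linkageGroup = seq_len(nLoci))
  })
}

# ---- independent HWE oracle -------------------------------------------------
# Conditional distribution of heterozygote counts by recursive enumeration of
# the sequential random pairing of the 2n allele copies (no closed-form pmf):
# draw two copies at random from the remaining pool to form each genotype.
hwe_pairing_pmf <- function(nA, nB) {
  n <- (nA + nB) / 2
  memo <- new.env()
  # returns named vector: P(total hets = h) given remaining na, nb copies
  rec <- function(na, nb) {
    key <- paste(na, nb)
    if (!is.null(memo[[key]])) return(memo[[key]])
    tot <- na + nb
    if (tot == 0) return(c("0" = 1))
    pAA <- if (na >= 2) na * (na - 1) / (tot * (tot - 1)) else 0
    pBB <- if (nb >= 2) nb * (nb - 1) / (tot * (tot - 1)) else 0
    pAB <- 1 - pAA - pBB
    out <- numeric(0)
    add <- function(dist, w, shift) {
      for (h in names(dist)) {
        key2 <- as.character(as.integer(h) + shift)
        out[key2] <<- (if (is.na(out[key2])) 0 else out[key2]) + w * dist[[h]]
      }
    }
    if (pAA > 0) add(rec(na - 2, nb), pAA, 0L)
    if (pBB > 0) add(rec(na, nb - 2), pBB, 0L)
    if (pAB > 0) add(rec(na - 1, nb - 1), pAB, 1L)
    memo[[key]] <- out
    out
  }
  rec(nA, nB)
}

hwe_oracle_p <- function(nAA, nAa, naa) {
  nA <- 2 * nAA + nAa
  nB <- 2 * naa + nAa
  if (nA == 0 || nB == 0) return(1)
  pmf <- hwe_pairing_pmf(nA, nB)
  pObs <- pmf[[as.character(nAa)]]
  sum(pmf[pmf <= pObs * (1 + 1e-7)])
}

# ---- independent Weir-Cockerham oracle --------------------------------------
# ANOVA route: nested mean squares of the allele-copy indicator variable
# (copies within individuals within populations), then the classic
# variance-component recoveries.  Shares no code with the package's
# nbar/nc/pbar/s2/hbar formulation.
wc_anova_oracle <- function(dosVec, groups) {
  ok <- !is.na(dosVec)
  x <- dosVec[ok]
  g <- factor(groups[ok])
  g <- droplevels(g)
  r <- nlevels(g)
  ni <- as.vector(table(g))
  ntot <- sum(ni)
  # allele copy values: individual with dosage x contributes copies
  # (1, 1) if x = 2, (1, 0) if x = 1, (0, 0) if x = 0
  y1 <- as.numeric(x >= 1)
  y2 <- as.numeric(x == 2)
  ybarInd <- (y1 + y2) / 2
  ybarPop <- tapply(y1 + y2, g, sum) / (2 * ni)
  ybar <- sum(y1 + y2) / (2 * ntot)
  SSG <- sum((y1 - ybarInd)^2 + (y2 - ybarInd)^2)
  SSI <- 2 * sum((ybarInd - ybarPop[as.integer(g)])^2)
  SSP <- 2 * sum(ni * (as.vector(ybarPop) - ybar)^2)
  MSG <- SSG / ntot
  MSI <- SSI / (ntot - r)
  MSP <- SSP / (r - 1)
  nc <- (ntot - sum(ni^2) / ntot) / (r - 1)
  a <- (MSP - MSI) / (2 * nc)
  b <- (MSI - MSG) / 2
  cc <- MSG
  c(a = a, b = b, c = cc)
}

# ---- misc -------------------------------------------------------------------
# planted sibship: nSib full sibs from two founders drawn at panel freqs
sibship_calls <- function(nSib, panel = sticklebackPanel(), seed = 1) {
  withr::with_seed(seed, {
    L <- nrow(panel)
    p <- panel$minor_freq
    founder <- function() cbind(rbinom(L, 1, p), rbinom(L, 1, p))
    f1 <- founder(); f2 <- founder()
    dos <- vapply(seq_len(nSib), function(i) {
      a <- f1[cbind(seq_len(L), sample(1:2, L, replace = TRUE))]
      b <- f2[cbind(seq_len(L), sample(1:2, L, replace = TRUE))]
      as.integer(a + b)
    }, integer(L))
    dimnames(dos) <- list(panel$locus_id, sprintf("sib%03d", seq_len(nSib)))
    g0 <- panmix:::genotype_string(panel$major_allele, panel$major_allele)
    g1 <- panmix:::genotype_string(panel$major_allele, panel$minor_allele)
    g2 <- panmix:::genotype_string(panel$minor_allele, panel$minor_allele)
    calls <- matrix(NA_character_, L, nSib, dimnames = dimnames(dos))
    for (l in seq_len(L)) calls[l, ] <- c(g0[l], g1[l], g2[l])[dos[l, ] + 1]
    calls
  })
}

# ad hoc reference panel with arbitrary loci for generator-driven tests
flat_panel <- function(p, prefix = "syn") {
  S4Vectors::DataFrame(
    locus_id = sprintf("%s%04d", prefix, seq_along(p)),
    linkage_group = rep(NA_integer_, length(p)),
    he = 2 * p * (1 - p), n_genotypes = rep(159L, length(p)),
    major_allele = rep("A", length(p)), major_freq = 1 - p,
    minor_allele = rep("G", length(p)), minor_freq = p,
    minor_freq_printed = p, hwe_p = rep(NA_real_, length(p)),
    repaired = rep(FALSE, length(p)),
    row.names = sprintf("%s%04d", prefix, seq_along(p)))
}
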