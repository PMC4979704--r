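ALL_EST <- c("quellergt", "lynchli", "lynchrd", "ritland", "wang", "dyadml")

test_that("an individual compared with its exact duplicate gives r = 1", {
  dos <- rbind(l1 = c(0L, 0L, 2L), l2 = c(2L, 2L, 0L), l3 = c(1L, 1L, 1L),
               l4 = c(0L, 0L, 1L))
  colnames(dos) <- c("a", "a2", "b")
  d <- panmix:::dosage_from_matrix(dos, habitat = rep("benthic", 3))
  p <- c(0.3, 0.4, 0.5, 0.2)
  expect_equal(pairRelatedness(d, "a", "a2", "quellergt", freqs = p), 1)
  expect_equal(pairRelatedness(d, "a", "a2", "lynchli", freqs = p), 1)
  expect_equal(as.numeric(pairRelatedness(d, "a", "a2", "dyadml", freqs = p)),
               1, tolerance = 1e-4)
  expect_error(pairRelatedness(d, "a", "a", "quellergt"),
               class = "panmix_invalid_pair")
  expect_error(pairRelatedness(d, "a", "b", "nadir"),
               class = "panmix_unknown_estimator")
})

test_that("all estimators are symmetric in the dyad", {
  gt <- generateGenotypes("panmictic", seed = 71)
  d <- toDosage(gt)
  for (est in ALL_EST) {
    r1 <- as.numeric(pairRelatedness(d, 3, 17, est))
    r2 <- as.numeric(pairRelatedness(d, 17, 3, est))
    expect_equal(r1, r2, tolerance = 1e-8, label = est)
  }
})

test_that("estimators are invariant to locus order and allele relabeling", {
  withr::with_seed(72, {
    L <- 20; P <- 15
    p <- runif(L, 0.1, 0.5)
    DX <- matrix(rbinom(P * L, 2, rep(p, each = P)), P, L)
    DY <- matrix(rbinom(P * L, 2, rep(p, each = P)), P, L)
    ord <- sample(L)
    for (est in ALL_EST) {
      base <- panmix:::estimate_pairs_matrix(DX, DY, p, est)
      reord <- panmix:::estimate_pairs_matrix(DX[, ord], DY[, ord], p[ord], est)
      flip <- panmix:::estimate_pairs_matrix(2L - DX, 2L - DY, 1 - p, est)
      expect_equal(as.numeric(base), as.numeric(reord), tolerance = 1e-6,
                   label = paste(est, "locus order"))
      expect_equal(as.numeric(base), as.numeric(flip), tolerance = 1e-6,
                   label = paste(est, "allele relabeling"))
    }
  })
})

test_that("pedigree dyads recover their true relatedness on average", {
  # reduced-n version of the recovery study (the acceptance suite runs the
  # full 500-dyad design); reference frequencies are the generator's truth
  means <- function(relationship, seed) {
    gt <- generateGenotypes("pedigree_dyads", relationship = relationship,
                            nDyads = 200, seed = seed)
    d <- toDosage(gt)
    truth <- S4Vectors::metadata(gt)$truth
    tab <- coancestryTable(d, freqs = alignFreqs(d, truth$freqs,
                                                 truth$freqAllele),
                           pairs = truth$dyads)
    vapply(ALL_EST, function(e) mean(tab[[e]]), numeric(1))
  }
  po <- means("parent_offspring", 73)
  expect_true(all(abs(po[c("quellergt", "lynchrd", "ritland", "wang")] - 0.5)
                  < 0.05))
  un <- means("unrelated", 74)
  expect_true(all(abs(un[c("quellergt", "lynchrd", "ritland", "wang")])
                  < 0.05))
  expect_gte(un["dyadml"], 0)   # constrained estimator: upward bias
  fs <- means("full_sib", 75)
  expect_true(all(abs(fs[c("quellergt", "lynchrd", "wang")] - 0.5) < 0.06))
})

test_that("dyadml maximizes the dyad likelihood over the IBD simplex", {
  gt <- generateGenotypes("pedigree_dyads", relationship = "full_sib",
                          nDyads = 40, seed = 76)
  d <- toDosage(gt)
  truth <- S4Vectors::metadata(gt)$truth
  p <- alignFreqs(d, truth$freqs, truth$freqAllele)
  dos <- dosage(d)
  i <- match(truth$dyads$id1, colnames(dos))
  j <- match(truth$dyads$id2, colnames(dos))
  use <- p > 0 & p < 1
  DX <- t(dos)[i, use, drop = FALSE]
  DY <- t(dos)[j, use, drop = FALSE]
  r <- panmix:::.rel_dyadml(DX, DY, p[use])
  k <- attr(r, "k")
  expect_true(all(abs(rowSums(k) - 1) < 1e-8))
  expect_true(all(k >= -1e-12))
  comp <- panmix:::.dyad_lik_components(DX, DY, p[use])
  llOpt <- panmix:::.dyad_loglik(comp, k)
  # EM converges sublinearly when the optimum sits on the simplex
  # boundary; allow a 1e-4 log-likelihood margin there
  for (vertex in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    kv <- matrix(vertex, nrow(k), 3, byrow = TRUE)
    expect_true(all(llOpt >= panmix:::.dyad_loglik(comp, kv) - 1e-4))
  }
})

test_that("coancestry tables cover all pairs with the right classes", {
  gt <- generateGenotypes("panmictic", seed = 81)
  d <- toDosage(gt)
  tab <- coancestryTable(d, estimators = "quellergt")
  expect_equal(nrow(tab), 159 * 158 / 2)
  cls <- table(tab$class)
  expect_equal(unname(cls["BB"]), 55 * 54 / 2)
  expect_equal(unname(cls["LL"]), 55 * 54 / 2)
  expect_equal(unname(cls["PP"]), 49 * 48 / 2)
  expect_equal(unname(cls["BL"]), 55 * 55)
  expect_equal(unname(cls["BP"]), 55 * 49)
  expect_equal(unname(cls["LP"]), 55 * 49)
  # panmixia: within- and between-group values are indistinguishable
  within <- tab$quellergt[tab$class %in% c("BB", "LL", "PP")]
  between <- tab$quellergt[!tab$class %in% c("BB", "LL", "PP")]
  expect_gt(suppressWarnings(stats::ks.test(within, between))$p.value, 0.01)
})

test_that("pairs sharing no typed locus are dropped with a warning", {
  dos <- rbind(l1 = c(0L, NA, 1L), l2 = c(1L, NA, 2L), l3 = c(NA, 1L, 0L))
  colnames(dos) <- c("a", "b", "c")
  d <- panmix:::dosage_from_matrix(dos, habitat = rep("littoral", 3))
  expect_warning(tab <- coancestryTable(d, estimators = "quellergt"),
                 "no shared typed locus")
  expect_identical(nrow(tab), 2L)   # pair (a, b) dropped
  expect_error(pairRelatedness(d, "a", "b", "quellergt"),
               class = "panmix_no_shared_loci")
})

test_that("Bonferroni thresholds follow familyAlpha / nTests", {
  expect_equal(bonferroniThreshold(0.05, 21), 0.05 / 21)
  expect_equal(round(bonferroniThreshold(0.05, 21), 3), 0.002)
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_equal(bonferroniThreshold(0.01, 10), 0.001)
  expect_error(bonferroniThreshold(0.05, 0), class = "panmix_invalid_spec")
})

test_that("permutation test arithmetic: degenerate nPerm = 1", {
  gt <- generateGenotypes("panmictic", seed = 82)
  d <- toDosage(gt)
  pt <- coancestryPermTest(d, estimators = "quellergt", nPerm = 1L, seed = 82)
  expect_true(all(pt@empiricalP %in% c(0.5, 1)))
})

test_that("a planted sibship is detected below the Bonferroni threshold", {
  gt <- generateGenotypes("panmictic", seed = 83)
  calls <- genotypeCalls(gt)
  sib <- sibship_calls(55, seed = 84)
  calls[, habitat(gt) == "benthic"] <- sib
  gt2 <- GenotypeTable(calls, habitat = habitat(gt), batch = sampleBatch(gt),
                       linkageGroup = linkageGroup(gt))
  d <- qcFilter(toDosage(gt2))$dosage
  pt <- coancestryPermTest(d, estimators = "quellergt", nPerm = 2500L,
                           seed = 85)
  expect_lt(pt@empiricalP["benthic", "quellergt"], pt@threshold)
  expect_gt(min(pt@empiricalP[c("littoral", "pelagic"), ]), pt@threshold)
})

test_that("permutation nulls concentrate around the grand mean", {
  gt <- generateGenotypes("panmictic", seed = 86)
  d <- toDosage(gt)
  tab <- coancestryTable(d, estimators = "quellergt")
  grand <- mean(tab$quellergt, na.rm = TRUE)
  pt <- coancestryPermTest(d, estimators = "quellergt", nPerm = 400L,
                           seed = 87)
  for (g in rownames(pt@empiricalP)) {
    null <- pt@nullMeans$quellergt[, g]
    expect_lt(abs(mean(null) - grand), 0.01)
    band <- stats::quantile(null, c(0.025, 0.975))
    expect_gt(pt@observed[g, "quellergt"], band[1] - 0.05)
    expect_lt(pt@observed[g, "quellergt"], band[2] + 0.05)
  }
})
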