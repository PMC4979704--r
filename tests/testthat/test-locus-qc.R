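test_that("summarizeLoci reports counts, frequencies and He from non-missing calls", {
  calls <- matrix(c("CC", "CA", "AA", "CC", NA,
                    "GG", "GG", "GT", "GG", "GG"), nrow = 2, byrow = TRUE,
                  dimnames = list(c("L1", "L2"), paste0("s", 1:5)))
  d <- toDosage(GenotypeTable(calls, habitat = rep("littoral", 5),
                              batch = rep(1, 5)))
  s <- summarizeLoci(d)
  expect_identical(s$n_genotypes, c(4L, 5L))
  expect_equal(unname(s["L1", "minor_freq"]), 3 / 8)  # A copies among 8
  expect_equal(unname(s["L1", "he"]), 2 * (3 / 8) * (5 / 8))
  expect_equal(unname(s["L2", "minor_freq"]), 0.1)
  # He is invariant to swapping major/minor labels
  expect_equal(s$he, 2 * s$major_freq * (1 - s$major_freq))
  expect_error(summarizeLoci(d, "nope"), class = "panmix_unknown_locus")
})

test_that("meanHe averages He and rejects empty input", {
  expect_equal(meanHe(c(0.1, 0.5)), 0.3)
  expect_equal(meanHe(0.42), 0.42)
  expect_equal(meanHe(rep(0.5, 7)), 0.5)   # all loci at p = 0.5
  expect_error(meanHe(numeric()), class = "panmix_empty_input")
})

test_that("exact HWE test matches the sequential-pairing enumeration oracle", {
  # exhaustive over all genotype configurations with n <= 30 individuals
  # (stepped to keep the loop lean; every (nA, nAa) combination is covered)
  for (n in c(2, 3, 5, 9, 17, 30)) {
    for (nA in 0:n) {           # nA = minor allele copies ... up to n (<= 2n)
      for (het in seq(nA %% 2, min(nA, 2 * n - nA), by = 2)) {
        nAA <- (2 * n - nA - het) / 2
        naa <- (nA - het) / 2
        expect_equal(hweExactTest(nAA, het, naa), hwe_oracle_p(nAA, het, naa),
                     tolerance = 1e-9,
                     label = sprintf("n=%d nA=%d het=%d", n, nA, het))
      }
    }
  }
})

test_that("exact HWE test handles the documented edge cases", {
  expect_equal(hweExactTest(25, 50, 25), 1)     # modal configuration
  expect_equal(hweExactTest(1, 0, 0), 1)        # single configuration
  # all-heterozygote with equal allele counts: small P, equals the oracle
  expect_lt(hweExactTest(0, 10, 0), 0.05)
  expect_equal(hweExactTest(0, 10, 0), hwe_oracle_p(0, 10, 0), tolerance = 1e-9)
  expect_error(hweExactTest(0, 0, 0), class = "panmix_invalid_counts")
  expect_error(hweExactTest(-1, 2, 0), class = "panmix_invalid_counts")
})

test_that("exact HWE test is conservative under the null", {
  # 2000 loci simulated in HWE at n = 159: rejection rate at 0.05 is <= 0.06
  pvals <- withr::with_seed(4821, vapply(seq_len(2000), function(i) {
    p <- runif(1, 0.1, 0.5)
    dos <- rbinom(159, 2, p)
    hweExactTest(sum(dos == 0), sum(dos == 1), sum(dos == 2))
  }, numeric(1)))
  expect_lte(mean(pvals < 0.05), 0.06)
})

test_that("pairwise r-squared flags duplicates, complements and unlinked loci", {
  gt <- generateGenotypes("panmictic", seed = 31)
  d <- toDosage(gt)
  dos <- dosage(d)[1:5, ]
  dup <- rbind(dos, dup1 = dos[1, ], comp1 = 2L - dos[1, ])
  d2 <- panmix:::dosage_from_matrix(dup, habitat = habitat(d))
  r2 <- pairwiseR2(d2)
  expect_equal(unname(r2["dup1", rownames(dos)[1]]), 1)
  expect_equal(unname(r2["comp1", rownames(dos)[1]]), 1)  # perfect negative
  expect_equal(unname(diag(r2)), rep(1, nrow(dup)))
  expect_true(isSymmetric(r2))
})

test_that("r-squared of independent HWE loci matches a permutation null", {
  gt <- generateGenotypes("panmictic", seed = 77)
  d <- qcFilter(toDosage(gt))$dosage
  r2 <- pairwiseR2(d)
  obs <- r2[upper.tri(r2)]
  # permutation oracle: shuffling one locus's dosages across samples breaks
  # any dependence; the observed off-diagonal r2 must look like that null
  dos <- dosage(d)
  null <- withr::with_seed(78, {
    unlist(lapply(1:10, function(b) {
      perm <- dos
      for (l in seq_len(nrow(perm))) perm[l, ] <- sample(perm[l, ])
      rp <- suppressWarnings(stats::cor(t(perm), use = "pairwise.complete.obs"))^2
      rp[upper.tri(rp)]
    }))
  })
  expect_gt(suppressWarnings(stats::ks.test(obs, null))$p.value, 0.01)
  expect_lt(max(obs), max(null) * 2 + 0.05)
})

test_that("pairwiseR2 errors on monomorphic loci and insufficient overlap", {
  dos <- rbind(a = c(0L, 0L, 0L, 0L), b = c(0L, 1L, 2L, 1L))
  colnames(dos) <- paste0("s", 1:4)
  d <- panmix:::dosage_from_matrix(dos, habitat = rep("benthic", 4))
  expect_error(pairwiseR2(d), class = "panmix_monomorphic_locus")
  dos2 <- rbind(a = c(0L, 1L, NA, NA), b = c(NA, NA, 1L, 2L))
  colnames(dos2) <- paste0("s", 1:4)
  d2 <- panmix:::dosage_from_matrix(dos2, habitat = rep("benthic", 4))
  expect_error(pairwiseR2(d2), class = "panmix_insufficient_overlap")
})

test_that("qcFilter reproduces the 55 -> 33 -> 32 filtering chain", {
  gt <- generateGenotypes("qc_fixture", seed = 19)
  truth <- S4Vectors::metadata(gt)$truth
  res <- qcFilter(toDosage(gt), hweAlpha = 0.001)
  rep <- res$report
  expect_identical(length(rep@lociIn), 55L)
  expect_setequal(rep@monomorphicRemoved, truth$monomorphic)
  expect_identical(names(rep@hweRemoved), truth$hweViolator)
  expect_lt(rep@hweRemoved[[1]], 1e-10)
  expect_setequal(rep@lociOut, truth$survivors)
  expect_identical(nrow(res$dosage), 32L)
  # survivors satisfy the filter predicates
  dos <- dosage(res$dosage)
  expect_true(all(rowSums(dos, na.rm = TRUE) >= 1))
  s <- summarizeLoci(res$dosage)
  expect_true(all(s$hwe_p >= 0.001))
  expect_true(is.finite(rep@maxPairwiseR2))
})

test_that("qcFilter is the identity on a clean panel and honours hweAlpha = 0", {
  gt <- generateGenotypes("qc_fixture", seed = 23)
  d <- toDosage(gt)
  clean <- qcFilter(d)$dosage
  res <- qcFilter(clean)
  expect_identical(rownames(res$dosage), rownames(clean))
  expect_length(res$report@monomorphicRemoved, 0L)
  expect_length(res$report@hweRemoved, 0L)
  # hweAlpha = 0: only monomorphic loci removed, the violator survives
  res0 <- qcFilter(d, hweAlpha = 0)
  expect_identical(nrow(res0$dosage), 33L)
  expect_true("hwe0001" %in% rownames(res0$dosage))
  # removing everything is an error
  mono <- panmix:::dosage_from_matrix(
    matrix(0L, 2, 4, dimnames = list(c("m1", "m2"), paste0("s", 1:4))),
    habitat = rep("benthic", 4))
  expect_error(qcFilter(mono), class = "panmix_all_loci_removed")
})

test_that("QC reports serialize to JSON with every removal and reason", {
  gt <- generateGenotypes("qc_fixture", seed = 29)
  rep <- qcFilter(toDosage(gt))$report
  path <- withr::local_tempfile(fileext = ".json")
  writeQCReport(rep, path)
  js <- jsonlite::read_json(path)
  expect_identical(length(js$loci_in), 55L)
  expect_identical(js$n_monomorphic_removed, 22L)
  expect_named(js$hwe_removed, "hwe0001")
  expect_identical(length(js$loci_out), 32L)
})
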