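test_that("the built-in SNP panel matches its source description", {
  panel <- sticklebackPanel()
  expect_identical(nrow(panel), 32L)
  r1 <- panel[panel$locus_id == "24644", ]
  expect_identical(r1$major_allele, "C")
  expect_equal(r1$major_freq, 0.95)
  expect_identical(r1$minor_allele, "A")
  expect_equal(r1$minor_freq, 0.05)
  r2 <- panel[panel$locus_id == "24214", ]
  expect_equal(r2$major_freq, 0.5)
  expect_equal(r2$minor_freq, 0.5)
  # frequency pairs sum to one after the documented repair
  expect_equal(panel$major_freq + panel$minor_freq, rep(1, 32),
               tolerance = 1e-9)
  expect_setequal(panel$locus_id[panel$repaired],
                  c("17562", "29288", "20626"))
  expect_true(all(panel$n_genotypes <= 159L))
  expect_true(all(panel$minor_freq >= 0 & panel$minor_freq <= 0.5))
})

test_that("the same seed and spec reproduce a dataset bit-identically", {
  for (mode in c("panmictic", "qc_fixture")) {
    a <- generateGenotypes(mode, seed = 111, missingness = "panel")
    b <- generateGenotypes(mode, seed = 111, missingness = "panel")
    expect_identical(genotypeCalls(a), genotypeCalls(b))
    expect_identical(S4Vectors::metadata(a)$truth, S4Vectors::metadata(b)$truth)
  }
  c1 <- generateGenotypes("pedigree_dyads", relationship = "full_sib",
                          nDyads = 20, seed = 112)
  c2 <- generateGenotypes("pedigree_dyads", relationship = "full_sib",
                          nDyads = 20, seed = 112)
  expect_identical(genotypeCalls(c1), genotypeCalls(c2))
})

test_that("panmictic draws live at the panel frequencies in HWE", {
  gt <- generateGenotypes("panmictic", seed = 113)
  d <- toDosage(gt)
  truth <- S4Vectors::metadata(gt)$truth
  p <- alignFreqs(d, truth$freqs, truth$freqAllele)
  obs <- rowSums(dosage(d)) / (2 * ncol(d))
  se <- sqrt(p * (1 - p) / (2 * ncol(d)))
  expect_true(all(abs(obs - p) <= 3 * se + 1e-9))
  s <- summarizeLoci(d, rownames(d)[rowSums(dosage(d)) > 0])
  expect_lte(sum(s$hwe_p < 0.05), 3L)
})

test_that("requested missingness matches the panel genotype counts exactly", {
  gt <- generateGenotypes("panmictic", seed = 114, missingness = "panel")
  panel <- sticklebackPanel()
  nonMissing <- rowSums(!is.na(genotypeCalls(gt)))
  expect_equal(unname(nonMissing[panel$locus_id]),
               as.numeric(panel$n_genotypes))
})

test_that("Balding-Nichols truth records let the structure be recomputed", {
  gt <- generateGenotypes("balding_nichols", fst = 0.1, seed = 115)
  truth <- S4Vectors::metadata(gt)$truth
  expect_identical(dim(truth$demeFreq), c(32L, 3L))
  expect_equal(truth$fst, 0.1)
  # deme frequencies scatter around the ancestral values with the Beta
  # variance p(1-p)F
  v <- apply(truth$demeFreq, 1, stats::var)
  expect_gt(stats::cor(v, truth$ancestralFreqs *
                         (1 - truth$ancestralFreqs) * 0.1), 0.2)
})

test_that("parent-offspring dyads satisfy the Mendelian sharing constraint", {
  gt <- generateGenotypes("pedigree_dyads", relationship = "parent_offspring",
                          nDyads = 80, seed = 116)
  truth <- S4Vectors::metadata(gt)$truth
  expect_equal(truth$k, c(0, 1, 0))
  expect_equal(truth$r, 0.5)
  d <- dosage(toDosage(gt))
  i <- match(truth$dyads$id1, colnames(d))
  j <- match(truth$dyads$id2, colnames(d))
  # a parent and offspring can never be opposite homozygotes
  expect_true(all(abs(d[, i] - d[, j]) < 2, na.rm = TRUE))
  fs <- S4Vectors::metadata(generateGenotypes(
    "pedigree_dyads", relationship = "full_sib", nDyads = 2,
    seed = 117))$truth
  expect_equal(fs$k, c(0.25, 0.5, 0.25))
})

test_that("the QC fixture plants exactly the advertised violations", {
  gt <- generateGenotypes("qc_fixture", seed = 118)
  truth <- S4Vectors::metadata(gt)$truth
  expect_identical(nrow(gt), 55L)
  expect_length(truth$monomorphic, 22L)
  calls <- genotypeCalls(gt)
  # every planted monomorphic locus carries a single genotype
  expect_true(all(apply(calls[truth$monomorphic, ], 1,
                        function(x) length(unique(x[!is.na(x)]))) == 1L))
  # the violator is all heterozygotes
  expect_true(all(calls[truth$hweViolator, ] == "AC"))
  # the 32 survivors are polymorphic by construction
  d <- toDosage(gt)
  expect_true(all(rowSums(dosage(d)[truth$survivors, ], na.rm = TRUE) >= 1))
})

test_that("island_forward mode samples the study design from a simulation", {
  cfg <- islandConfig(nDemes = 3, demeSize = 120, nLoci = 300,
                      migrationRate = islandClosedFormM(0.05, 120, 3),
                      seed = 119)
  gt <- generateGenotypes("island_forward", islandConfig = cfg, fst = 0.05,
                          seed = 119)
  expect_identical(ncol(gt), 159L)
  expect_identical(nrow(gt), 32L)
  expect_equal(as.integer(table(habitat(gt))[c("benthic", "littoral", "pelagic")]),
               c(55L, 55L, 49L))
  truth <- S4Vectors::metadata(gt)$truth
  expect_true(is.finite(truth$realizedFst))
  expect_identical(length(truth$lociSampled), 32L)
})

test_that("inconsistent generator specs are rejected", {
  expect_error(generateGenotypes("balding_nichols", seed = 1),
               class = "panmix_invalid_spec")
  expect_error(generateGenotypes("balding_nichols", fst = 1.5, seed = 1),
               class = "panmix_invalid_spec")
  expect_error(generateGenotypes("panmictic",
                                 nPerGroup = c(lake = 10), seed = 1),
               class = "panmix_invalid_spec")
})
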