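test_that("TSV round trip is lossless, including missing cells and metadata", {
  for (seed in 1:3) {
    gt <- random_gt(seed = seed)
    path <- withr::local_tempfile(fileext = ".tsv")
    lpath <- withr::local_tempfile(fileext = ".tsv")
    writeGenotypeTsv(gt, path, locusFile = lpath)
    back <- readGenotypeTsv(path, locusFile = lpath)
    expect_identical(genotypeCalls(back), genotypeCalls(gt))
    expect_identical(habitat(back), habitat(gt))
    expect_identical(sampleBatch(back), sampleBatch(gt))
    expect_identical(linkageGroup(back), linkageGroup(gt))
  }
})

test_that("TSV reader raises distinct named errors for malformed input", {
  write_lines <- function(lines) {
    f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame(2))
    writeLines(lines, f)
    f
  }
  expect_error(
    readGenotypeTsv(write_lines(c("id\thabitat\tbatch\tL1", "s1\tbenthic\t1\tAA"))),
    class = "panmix_malformed_header")
  expect_error(
    readGenotypeTsv(write_lines(c("sample_id\thabitat\tbatch\tL1",
                                  "s1\tbenthic\t1\tAA",
                                  "s2\tbenthic\t1\tAC",
                                  "s3\tbenthic\t1\tGG"))),
    class = "panmix_triallelic_locus")
  expect_error(
    readGenotypeTsv(write_lines(c("sample_id\thabitat\tbatch\tL1",
                                  "s1\triverine\t1\tAA"))),
    class = "panmix_unknown_habitat")
  expect_error(
    readGenotypeTsv(write_lines(c("sample_id\thabitat\tbatch\tL1",
                                  "s1\tbenthic\t1\tAA",
                                  "s1\tbenthic\t1\tAA"))),
    class = "panmix_duplicate_ids")
  expect_error(readGenotypeTsv(file.path(tempdir(), "does-not-exist.tsv")),
               class = "panmix_missing_file")
})

test_that("VCF round trip reproduces the table and maps ./. to missing", {
  gt <- random_gt(seed = 4)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  meta <- withr::local_tempfile(fileext = ".tsv")
  writeGenotypeVcf(gt, vcf, metadataFile = meta)
  back <- readGenotypeVcf(vcf, meta)
  expect_identical(genotypeCalls(back), genotypeCalls(gt))
  expect_identical(habitat(back), habitat(gt))
  # a ./. genotype comes back as exactly one missing cell
  gt1 <- tiny_gt()   # exactly one NA call
  vcf1 <- withr::local_tempfile(fileext = ".vcf")
  meta1 <- withr::local_tempfile(fileext = ".tsv")
  writeGenotypeVcf(gt1, vcf1, metadataFile = meta1)
  expect_identical(sum(grepl("\\./\\.", readLines(vcf1))), 1L)
  back1 <- readGenotypeVcf(vcf1, meta1)
  expect_identical(sum(is.na(genotypeCalls(back1))), 1L)
  expect_true(is.na(genotypeCalls(back1)["L2", "s3"]))
})

test_that("multi-allelic VCF records are rejected", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "1\t1\tL1\tA\tC,G\t.\t.\t.\tGT\t0/1"), vcf)
  meta <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\thabitat\tbatch", "s1\tbenthic\t1"), meta)
  expect_error(readGenotypeVcf(vcf, meta), class = "panmix_multiallelic_record")
})

test_that("VCF reader requires metadata for every sample", {
  gt <- tiny_gt()
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeGenotypeVcf(gt, vcf)
  meta <- data.frame(sample_id = c("s1", "s2"),
                     habitat = c("benthic", "littoral"), batch = c(1L, 1L))
  expect_error(readGenotypeVcf(vcf, meta), class = "panmix_missing_metadata")
})

test_that("mergeBatches keeps the shared loci and the union of samples", {
  # two batches with 58 and 57 usable loci sharing 55, as in a two-batch
  # genotyping design
  mk <- function(loci, samples, habitat) {
    calls <- matrix("AC", length(loci), length(samples),
                    dimnames = list(loci, samples))
    calls[1, 1] <- "AA"  # some variation so loci are not all het
    GenotypeTable(calls, habitat = rep(habitat, length(samples)),
                  batch = rep(1L, length(samples)))
  }
  shared <- sprintf("shared%02d", 1:55)
  b1 <- mk(c(shared, "only1a", "only1b", "only1c"),
           sprintf("b1_%02d", 1:4), "benthic")
  b2 <- mk(c(sprintf("only2%s", letters[1:2]), shared),
           sprintf("b2_%02d", 1:3), "littoral")
  merged <- mergeBatches(b1, b2)
  expect_identical(rownames(merged), shared)   # order follows batch 1
  expect_identical(ncol(merged), 7L)
  # symmetric in locus content
  expect_setequal(rownames(mergeBatches(b1, b2)), rownames(mergeBatches(b2, b1)))
  # identical locus sets: all loci retained
  m2 <- mergeBatches(mk(shared, "x1", "benthic"), mk(shared, "x2", "pelagic"))
  expect_identical(nrow(m2), 55L)
  expect_identical(ncol(m2), 2L)
  # failure modes
  expect_error(mergeBatches(mk("A1", "x1", "benthic"), mk("B1", "x2", "benthic")),
               class = "panmix_empty_locus_intersection")
  expect_error(mergeBatches(mk(shared, "x1", "benthic"), mk(shared, "x1", "benthic")),
               class = "panmix_overlapping_samples")
})

test_that("toDosage assigns major/minor by frequency with the documented tie-break", {
  calls <- matrix(c("CC", "CA", "AA", "CC",   # C freq 0.625 -> A minor
                    "GG", "GG", "GG", "GG",   # monomorphic
                    "AC", "AC", "AA", "CC"),  # exactly 0.5/0.5 tie
                  nrow = 3, byrow = TRUE,
                  dimnames = list(c("L1", "L2", "L3"), paste0("s", 1:4)))
  d <- toDosage(GenotypeTable(calls, habitat = rep("benthic", 4),
                              batch = rep(1, 4)))
  expect_identical(unname(dosage(d)["L1", ]), c(0L, 1L, 2L, 0L))
  expect_identical(unname(minorAllele(d)["L1"]), "A")
  expect_equal(unname(minorFreq(d)["L1"]), 0.375)
  expect_identical(unname(dosage(d)["L2", ]), rep(0L, 4))
  expect_equal(unname(minorFreq(d)["L2"]), 0)
  # tie: alphabetically later symbol (C) is minor
  expect_identical(unname(minorAllele(d)["L3"]), "C")
  expect_equal(unname(minorFreq(d)["L3"]), 0.5)
})

test_that("dosage-derived allele frequencies equal call-derived frequencies", {
  gt <- random_gt(seed = 9, nSamples = 30, nLoci = 8)
  d <- toDosage(gt)
  dos <- dosage(d)
  fromDosage <- rowSums(dos, na.rm = TRUE) / (2 * rowSums(!is.na(dos)))
  calls <- genotypeCalls(gt)
  fromCalls <- vapply(seq_len(nrow(calls)), function(l) {
    a <- unlist(strsplit(calls[l, !is.na(calls[l, ])], ""))
    mean(a == minorAllele(d)[l])
  }, numeric(1))
  expect_equal(unname(fromDosage), fromCalls, tolerance = 1e-12)
})

test_that("generated 159 x 32 data reproduce the generator frequencies", {
  gt <- generateGenotypes("panmictic", seed = 202)
  truth <- S4Vectors::metadata(gt)$truth
  d <- toDosage(gt)
  p <- alignFreqs(d, truth$freqs, truth$freqAllele)
  obs <- rowSums(dosage(d)) / (2 * ncol(d))
  se <- sqrt(p * (1 - p) / (2 * ncol(d)))
  expect_true(all(abs(obs - p) <= 3 * se + 1e-9))
})

test_that("toDosage errors on an all-missing locus", {
  calls <- matrix(c("AC", "AA", NA, NA), nrow = 2, byrow = TRUE,
                  dimnames = list(c("L1", "L2"), c("s1", "s2")))
  gt <- GenotypeTable(calls, habitat = c("benthic", "benthic"), batch = c(1, 1))
  expect_error(toDosage(gt), class = "panmix_all_missing_locus")
})
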