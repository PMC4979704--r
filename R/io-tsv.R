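#' Read / write the genotype TSV dialect
#'
#' The dialect has a header row
#' `sample_id habitat batch <locus_1> <locus_2> ...` (tab-separated), one
#' row per sample, and two-letter genotype strings (e.g. `"AC"`) or `NA` in
#' the genotype cells.  A companion locus file with columns
#' `locus_id linkage_group` supplies the per-locus linkage group.
#'
#' @param path path of the genotype TSV.
#' @param locusFile optional path of the companion locus TSV.
#' @return [readGenotypeTsv()] returns a [GenotypeTable-class];
#'   [writeGenotypeTsv()] returns `path` invisibly.
#' @export
readGenotypeTsv <- function(path, locusFile = NULL) {
  if (!file.exists(path)) pmx_stop("missing_file", "file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = "NA")
  if (ncol(df) < 4L ||
      !identical(colnames(df)[1:3], c("sample_id", "habitat", "batch")))
    pmx_stop("malformed_header",
             "header must start with sample_id, habitat, batch, then loci")
  if (anyDuplicated(df$sample_id))
    pmx_stop("duplicate_ids", "duplicate sample ids: %s",
             paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  loci <- colnames(df)[-(1:3)]
  if (anyDuplicated(loci))
    pmx_stop("duplicate_ids", "duplicate locus ids in header")
  if (!all(df$habitat %in% HABITAT_LEVELS))
    pmx_stop("unknown_habitat", "unknown habitat label(s): %s",
             paste(setdiff(unique(df$habitat), HABITAT_LEVELS), collapse = ", "))
  calls <- t(as.matrix(df[, -(1:3), drop = FALSE]))
  dimnames(calls) <- list(loci, df$sample_id)
  bad <- !is.na(calls) & !grepl("^[ACGT]{2}$", calls)
  if (any(bad))
    pmx_stop("malformed_genotype", "malformed genotype cell(s), e.g. '%s'",
             calls[which(bad)[1L]])
  nall <- apply(calls, 1L, function(x)
    length(unique(unlist(strsplit(x[!is.na(x)], "")))))
  if (any(nall > 2L))
    pmx_stop("triallelic_locus", "more than two alleles at locus/loci: %s",
             paste(loci[nall > 2L], collapse = ", "))
  lg <- rep(NA_integer_, length(loci))
  if (!is.null(locusFile)) {
    lf <- utils::read.table(locusFile, sep = "\t", header = TRUE,
                            colClasses = c("character", "integer"))
    lg <- lf$linkage_group[match(loci, lf$locus_id)]
  }
  GenotypeTable(calls, habitat = df$habitat, batch = as.integer(df$batch),
                linkageGroup = lg)
}

#' @rdname readGenotypeTsv
#' @param t a [GenotypeTable-class] to write.
#' @export
writeGenotypeTsv <- function(t, path, locusFile = NULL) {
  stopifnot(is(t, "GenotypeTable"))
  df <- data.frame(sample_id = colnames(t), habitat = habitat(t),
                   batch = sampleBatch(t), check.names = FALSE)
  df <- cbind(df, as.data.frame(t(genotypeCalls(t)), check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  if (!is.null(locusFile)) {
    lf <- data.frame(locus_id = rownames(t), linkage_group = linkageGroup(t))
    utils::write.table(lf, locusFile, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  invisible(path)
}

#' Read / write the sample-metadata sidecar used with VCF
#'
#' Tab-separated columns `sample_id habitat batch`, one row per sample.
#' @param path file path.
#' @return a data.frame with sample_id, habitat and batch.
#' @keywords internal
readSampleMetadata <- function(path) {
  if (!file.exists(path)) pmx_stop("missing_file", "file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "integer"))
  if (!all(c("sample_id", "habitat", "batch") %in% colnames(df)))
    pmx_stop("malformed_header",
             "metadata needs columns sample_id, habitat, batch")
  df
}
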