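#' Read / write genotype tables as VCF
#'
#' VCF v4.2 with biallelic SNP records and a GT field.  Contig and position
#' are synthetic (linkage group as contig, locus index along the file as
#' position); the locus id travels in the ID column.  Habitat and batch are
#' not encoded in the VCF: they travel in a sidecar sample-metadata TSV with
#' columns `sample_id habitat batch` (see [readGenotypeTsv()] for the main
#' TSV dialect).
#'
#' @param path VCF file path.
#' @param metadata sidecar metadata: either a file path or a data.frame with
#'   columns `sample_id`, `habitat`, `batch`.
#' @return [readGenotypeVcf()] returns a [GenotypeTable-class];
#'   [writeGenotypeVcf()] returns `path` invisibly.
#' @export
readGenotypeVcf <- function(path, metadata) {
  if (!file.exists(path)) pmx_stop("missing_file", "file not found: %s", path)
  v <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(v)
  if (any(S4Vectors::elementNROWS(alt) != 1L))
    pmx_stop("multiallelic_record", "multi-allelic record(s) in %s", path)
  refA <- as.character(VariantAnnotation::ref(v))
  altA <- as.character(unlist(alt))
  if (any(nchar(refA) != 1L) || any(nchar(altA) != 1L))
    pmx_stop("multiallelic_record", "non-SNP record(s) in %s", path)
  gtm <- VariantAnnotation::geno(v)$GT
  gtm <- gsub("|", "/", gtm, fixed = TRUE)
  ids <- rownames(gtm)
  calls <- matrix(NA_character_, nrow(gtm), ncol(gtm), dimnames = dimnames(gtm))
  for (code in list(c("0/0", 1L, 1L), c("0/1", 1L, 2L), c("1/0", 1L, 2L),
                    c("1/1", 2L, 2L))) {
    idx <- which(gtm == code[1L], arr.ind = TRUE)
    if (nrow(idx)) {
      al <- cbind(refA, altA)
      calls[idx] <- genotype_string(
        al[cbind(idx[, 1L], as.integer(code[2L]))],
        al[cbind(idx[, 1L], as.integer(code[3L]))])
    }
  }
  if (is.character(metadata) && length(metadata) == 1L)
    metadata <- readSampleMetadata(metadata)
  m <- match(colnames(calls), metadata$sample_id)
  if (anyNA(m))
    pmx_stop("missing_metadata", "no metadata for sample(s): %s",
             paste(colnames(calls)[is.na(m)], collapse = ", "))
  lg <- suppressWarnings(
    as.integer(as.character(GenomicRanges::seqnames(
      SummarizedExperiment::rowRanges(v)))))
  GenotypeTable(calls, habitat = metadata$habitat[m],
                batch = metadata$batch[m], linkageGroup = lg)
}

#' @rdname readGenotypeVcf
#' @param t a [GenotypeTable-class].
#' @param metadataFile optional path; when given, the sample metadata
#'   sidecar is written alongside the VCF.
#' @export
writeGenotypeVcf <- function(t, path, metadataFile = NULL) {
  stopifnot(is(t, "GenotypeTable"))
  calls <- genotypeCalls(t)
  L <- nrow(calls)
  refA <- altA <- character(L)
  gt <- matrix("./.", L, ncol(calls), dimnames = dimnames(calls))
  for (l in seq_len(L)) {
    alle <- sort(unique(unlist(strsplit(calls[l, !is.na(calls[l, ])], ""))))
    refA[l] <- if (length(alle)) alle[1L] else "A"
    altA[l] <- if (length(alle) > 1L) alle[2L] else setdiff(c("A", "C", "G", "T"), refA[l])[1L]
    nref <- (substr(calls[l, ], 1, 1) == refA[l]) +
      (substr(calls[l, ], 2, 2) == refA[l])   # copies of the REF allele
    gt[l, ] <- c("0/0", "0/1", "1/1", "./.")[ifelse(is.na(nref), 4L, 3L - nref)]
  }
  contig <- ifelse(is.na(linkageGroup(t)), 0L, linkageGroup(t))
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(contig),
    ranges = IRanges::IRanges(start = seq_len(L), width = 1L))
  names(gr) <- rownames(calls)
  hdr <- VariantAnnotation::VCFHeader(samples = colnames(calls))
  VariantAnnotation::geno(hdr) <- S4Vectors::DataFrame(
    Number = "1", Type = "String", Description = "Genotype",
    row.names = "GT")
  VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
    fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
                                      row.names = "fileformat"))
  vcf <- VariantAnnotation::VCF(
    rowRanges = gr,
    colData = S4Vectors::DataFrame(Samples = seq_len(ncol(calls)),
                                   row.names = colnames(calls)),
    exptData = list(header = hdr),
    fixed = S4Vectors::DataFrame(
      REF = Biostrings::DNAStringSet(refA),
      ALT = do.call(Biostrings::DNAStringSetList, as.list(altA)),
      QUAL = rep(NA_real_, L), FILTER = rep(".", L)),
    geno = S4Vectors::SimpleList(GT = gt))
  VariantAnnotation::writeVcf(vcf, path)
  if (!is.null(metadataFile)) {
    utils::write.table(
      data.frame(sample_id = colnames(t), habitat = habitat(t),
                 batch = sampleBatch(t)),
      metadataFile, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
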