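#' Built-in stickleback SNP reference panel
#'
#' The 32-locus biallelic SNP panel of a within-lake nine-spined
#' stickleback survey (159 fish from littoral, benthic and pelagic
#' habitats): per locus the linkage group, reported expected
#' heterozygosity, number of successful genotypes, major and minor alleles
#' with frequencies, and the reported Hardy-Weinberg P-value.  Four rows of
#' the source table print allele-frequency pairs that do not sum to one;
#' the `minor_freq` column repairs these as 1 - major frequency (the
#' printed value is kept in `minor_freq_printed`, and `repaired` flags the
#' affected loci).
#'
#' @return a [S4Vectors::DataFrame] with 32 rows.
#' @examples
#' panel <- sticklebackPanel()
#' panel[panel$locus_id == "24644", ]
#' @export
sticklebackPanel <- function() {
  txt <- "
locus_id lg he n major major_freq minor minor_freq_printed hwe_p
24644 1 0.09 159 C 0.95 A 0.05 1.00
29372 1 0.34 157 A 0.78 G 0.22 0.16
28629 2 0.01 159 A 0.99 G 0.01 1.00
29012 2 0.49 158 C 0.57 T 0.43 0.87
2438 3 0.41 158 T 0.71 C 0.29 0.34
16185 4 0.43 159 T 0.69 G 0.31 0.85
4544 5 0.07 159 G 0.96 A 0.04 0.19
17562 5 0.15 159 T 0.92 C 0.02 0.31
31597 6 0.35 159 T 0.76 C 0.24 0.83
24214 8 0.50 158 A 0.50 C 0.50 0.27
25808 8 0.15 159 G 0.92 T 0.08 0.60
29227 8 0.47 158 T 0.62 A 0.38 0.18
20626 9 0.46 159 A 0.63 G 0.27 0.24
18083 10 0.49 159 T 0.57 C 0.43 0.02
29288 10 0.16 159 G 0.91 A 0.01 0.62
19045 11 0.01 159 A 0.997 G 0.003 1.00
9694 13 0.26 159 C 0.85 T 0.15 0.36
7972 14 0.35 159 G 0.77 C 0.23 1.00
31404 14 0.42 159 C 0.70 A 0.30 1.00
12169 15 0.47 159 C 0.62 T 0.38 1.00
27696 15 0.12 159 T 0.94 C 0.06 0.47
31328 15 0.07 159 T 0.93 C 0.07 1.00
13903 16 0.34 150 T 0.78 C 0.22 0.64
13738 17 0.07 158 C 0.96 T 0.04 1.00
18241 17 0.02 159 G 0.99 C 0.01 1.00
34117 17 0.34 158 C 0.78 T 0.22 1.00
4106 18 0.02 159 C 0.99 G 0.01 1.00
24550 19 0.37 159 A 0.75 G 0.25 0.52
25627 19 0.49 159 G 0.55 T 0.45 0.52
27998 19 0.34 159 G 0.79 A 0.21 0.81
13161 20 0.48 159 G 0.59 A 0.41 0.62
16861 21 0.49 159 G 0.56 A 0.44 0.11"
  df <- utils::read.table(text = txt, header = TRUE,
                          colClasses = c("character", "integer", "numeric",
                                         "integer", "character", "numeric",
                                         "character", "numeric", "numeric"))
  minor_freq <- round(1 - df$major_freq, 3)
  S4Vectors::DataFrame(
    locus_id = df$locus_id, linkage_group = df$lg, he = df$he,
    n_genotypes = df$n, major_allele = df$major, major_freq = df$major_freq,
    minor_allele = df$minor, minor_freq = minor_freq,
    minor_freq_printed = df$minor_freq_printed, hwe_p = df$hwe_p,
    repaired = abs(df$major_freq + df$minor_freq_printed - 1) > 1e-9,
    row.names = df$locus_id)
}

# dosage (loci x samples, minor-allele copies) -> two-letter call strings
dosage_to_calls <- function(dos, major, minor) {
  L <- nrow(dos)
  g0 <- genotype_string(major, major)
  g1 <- genotype_string(major, minor)
  g2 <- genotype_string(minor, minor)
  calls <- matrix(NA_character_, L, ncol(dos), dimnames = dimnames(dos))
  for (l in seq_len(L))
    calls[l, ] <- c(g0[l], g1[l], g2[l])[dos[l, ] + 1L]
  calls
}

# per-locus missingness matching the panel's genotype counts: for locus l,
# N - n_genotypes[l] cells are blanked uniformly at random
apply_panel_missingness <- function(calls, targetN) {
  N <- ncol(calls)
  for (l in seq_along(targetN)) {
    k <- N - targetN[l]
    if (k > 0L) calls[l, sample.int(N, k)] <- NA_character_
  }
  calls
}

#' Generate synthetic genotype datasets
#'
#' Emulates the study conditions of a within-lake SNP survey: 159
#' individuals in habitat groups of 55/55/49 typed at the 32 unlinked
#' biallelic loci of [sticklebackPanel()].  Five modes:
#'
#' * `"panmictic"`: Hardy-Weinberg genotypes at the panel frequencies,
#'   identical across groups — the null.  Group labels carry no signal
#'   (first group benthic, then littoral, then pelagic, in sample order).
#' * `"balding_nichols"`: per-group allele frequencies drawn from
#'   Beta(p(1-F)/F, (1-p)(1-F)/F) at target Fst `fst`, Hardy-Weinberg
#'   within groups — a fast surrogate for island-model structure.
#' * `"island_forward"`: delegates to [simulateIsland()] and samples the
#'   requested group sizes and 32 polymorphic loci from the simulated
#'   population.
#' * `"pedigree_dyads"`: `nDyads` labeled pairs with known relatedness
#'   (`relationship` = `"unrelated"`, `"parent_offspring"` or
#'   `"full_sib"`); founders drawn at panel frequencies, alleles
#'   transmitted Mendelianly.
#' * `"qc_fixture"`: a 55-locus panel with 22 monomorphic loci and one
#'   locus forced far out of Hardy-Weinberg equilibrium (every individual
#'   heterozygous), so the standard filtering chain leaves 32 survivors.
#'
#' @param mode generation mode, see above.
#' @param nPerGroup named integer vector of group sizes
#'   (default `c(benthic = 55, littoral = 55, pelagic = 49)`).
#' @param fst target Fst for the structured modes.
#' @param relationship dyad relationship for `"pedigree_dyads"`.
#' @param nDyads number of dyads for `"pedigree_dyads"`.
#' @param missingness `"none"`, or `"panel"` to blank cells uniformly at
#'   random so each panel locus matches its reported genotype count.
#' @param panel reference panel (defaults to [sticklebackPanel()]).
#' @param islandConfig optional [IslandConfig-class] for
#'   `"island_forward"`; by default three demes of 1500 at 3150 loci with
#'   the migration rate set by the island-model closed form for `fst`.
#' @param seed integer seed; the same seed and arguments reproduce the
#'   dataset bit-identically.
#' @return a [GenotypeTable-class]; `metadata(x)$truth` records the mode,
#'   seed and every latent quantity (true frequencies, deme frequencies,
#'   realized Fst, dyad identity coefficients, planted QC violations).
#' @examples
#' gt <- generateGenotypes("panmictic", seed = 42, missingness = "panel")
#' gt
#' @export
generateGenotypes <- function(mode = c("panmictic", "balding_nichols",
                                       "island_forward", "pedigree_dyads",
                                       "qc_fixture"),
                              nPerGroup = c(benthic = 55L, littoral = 55L,
                                            pelagic = 49L),
                              fst = NULL, relationship = c("unrelated",
                                                           "parent_offspring",
                                                           "full_sib"),
                              nDyads = 500L,
                              missingness = c("none", "panel"),
                              panel = sticklebackPanel(),
                              islandConfig = NULL, seed = NULL) {
  mode <- match.arg(mode)
  missingness <- match.arg(missingness)
  if (mode %in% c("balding_nichols", "island_forward")) {
    if (is.null(fst) && is.null(islandConfig))
      pmx_stop("invalid_spec", "mode '%s' requires a target fst", mode)
    if (!is.null(fst) && (fst <= 0 || fst >= 1))
      pmx_stop("invalid_spec", "fst must be in (0, 1)")
  }
  if (is.null(names(nPerGroup)))
    names(nPerGroup) <- HABITAT_LEVELS[seq_along(nPerGroup)]
  if (!all(names(nPerGroup) %in% HABITAT_LEVELS))
    pmx_stop("invalid_spec", "group names must be habitat labels")
  with_seed_opt(seed, {
    switch(mode,
      panmictic = .gen_panmictic(nPerGroup, panel, missingness, seed),
      balding_nichols = .gen_bn(nPerGroup, fst, panel, missingness, seed),
      island_forward = .gen_island(nPerGroup, fst, islandConfig, seed),
      pedigree_dyads = .gen_dyads(match.arg(relationship), nDyads, panel, seed),
      qc_fixture = .gen_qc(nPerGroup, panel, missingness, seed))
  })
}

.group_labels <- function(nPerGroup)
  rep(names(nPerGroup), nPerGroup)

.sample_ids <- function(n) sprintf("ind%03d", seq_len(n))

.gen_panmictic <- function(nPerGroup, panel, missingness, seed) {
  N <- sum(nPerGroup)
  L <- nrow(panel)
  p <- panel$minor_freq
  dos <- matrix(rbinom(L * N, 2L, rep(p, N)), L, N,
                dimnames = list(panel$locus_id, .sample_ids(N)))
  calls <- dosage_to_calls(dos, panel$major_allele, panel$minor_allele)
  if (missingness == "panel")
    calls <- apply_panel_missingness(calls, panel$n_genotypes)
  GenotypeTable(calls, habitat = .group_labels(nPerGroup),
                batch = rep(1L, N), linkageGroup = panel$linkage_group,
                metadata = list(truth = list(
                  mode = "panmictic", freqs = stats::setNames(p, panel$locus_id),
                  freqAllele = stats::setNames(panel$minor_allele,
                                               panel$locus_id),
                  nPerGroup = nPerGroup, seed = seed)))
}

.gen_bn <- function(nPerGroup, fst, panel, missingness, seed) {
  L <- nrow(panel)
  p <- panel$minor_freq
  G <- length(nPerGroup)
  demeFreq <- matrix(rbeta(L * G, rep(p * (1 - fst) / fst, G),
                           rep((1 - p) * (1 - fst) / fst, G)),
                     L, G, dimnames = list(panel$locus_id, names(nPerGroup)))
  dos <- do.call(cbind, lapply(seq_len(G), function(g) {
    n <- nPerGroup[g]
    matrix(rbinom(L * n, 2L, rep(demeFreq[, g], n)), L, n)
  }))
  dimnames(dos) <- list(panel$locus_id, .sample_ids(sum(nPerGroup)))
  calls <- dosage_to_calls(dos, panel$major_allele, panel$minor_allele)
  if (missingness == "panel")
    calls <- apply_panel_missingness(calls, panel$n_genotypes)
  GenotypeTable(calls, habitat = .group_labels(nPerGroup),
                batch = rep(1L, sum(nPerGroup)),
                linkageGroup = panel$linkage_group,
                metadata = list(truth = list(
                  mode = "balding_nichols", fst = fst,
                  ancestralFreqs = stats::setNames(p, panel$locus_id),
                  freqAllele = stats::setNames(panel$minor_allele,
                                               panel$locus_id),
                  demeFreq = demeFreq, nPerGroup = nPerGroup, seed = seed)))
}

.gen_island <- function(nPerGroup, fst, cfg, seed) {
  G <- length(nPerGroup)
  if (is.null(cfg)) {
    m <- islandClosedFormM(fst, demeSize = 1500L, nDemes = G)
    cfg <- islandConfig(nDemes = G, demeSize = 1500L, nLoci = 3150L,
                        migrationRate = m)
  }
  pop <- simulateIsland(cfg)
  demes <- levels(pop@deme)
  idx <- unlist(lapply(seq_len(G), function(g)
    sample(which(as.integer(pop@deme) == g), nPerGroup[g])))
  poly <- which(apply(pop@dosage, 1L, function(x) length(unique(x)) > 1L))
  loci <- sort(sample(poly, min(32L, length(poly))))
  dos <- pop@dosage[loci, idx, drop = FALSE]
  dimnames(dos) <- list(sprintf("sim%04d", loci), .sample_ids(length(idx)))
  calls <- dosage_to_calls(dos, rep("A", nrow(dos)), rep("G", nrow(dos)))
  GenotypeTable(calls, habitat = .group_labels(nPerGroup),
                batch = rep(1L, length(idx)),
                metadata = list(truth = list(
                  mode = "island_forward", targetFst = fst,
                  realizedFst = pop@realizedFst,
                  migrationRate = cfg@migrationRate,
                  generations = pop@generations, lociSampled = loci,
                  nPerGroup = nPerGroup, seed = seed)))
}

.gen_dyads <- function(relationship, nDyads, panel, seed) {
  L <- nrow(panel)
  p <- panel$minor_freq
  draw <- function() matrix(rbinom(nDyads * L, 1L, rep(p, each = nDyads)),
                            nDyads, L)
  pick <- function(a, b) {  # Mendelian pick of one allele per cell
    u <- matrix(runif(nDyads * L) < 0.5, nDyads, L)
    ifelse(u, a, b)
  }
  if (relationship == "unrelated") {
    x <- draw() + draw(); y <- draw() + draw()
    k <- c(1, 0, 0)
  } else if (relationship == "parent_offspring") {
    p1 <- draw(); p2 <- draw()
    x <- p1 + p2
    y <- pick(p1, p2) + draw()
    k <- c(0, 1, 0)
  } else {
    f1a <- draw(); f1b <- draw(); f2a <- draw(); f2b <- draw()
    x <- pick(f1a, f1b) + pick(f2a, f2b)
    y <- pick(f1a, f1b) + pick(f2a, f2b)
    k <- c(0.25, 0.5, 0.25)
  }
  dos <- matrix(NA_integer_, L, 2L * nDyads)
  dos[, seq(1L, 2L * nDyads, by = 2L)] <- t(x)
  dos[, seq(2L, 2L * nDyads, by = 2L)] <- t(y)
  ids <- as.vector(rbind(sprintf("d%04d_1", seq_len(nDyads)),
                         sprintf("d%04d_2", seq_len(nDyads))))
  dimnames(dos) <- list(panel$locus_id, ids)
  calls <- dosage_to_calls(dos, panel$major_allele, panel$minor_allele)
  GenotypeTable(calls, habitat = rep("littoral", 2L * nDyads),
                batch = rep(1L, 2L * nDyads),
                linkageGroup = panel$linkage_group,
                metadata = list(truth = list(
                  mode = "pedigree_dyads", relationship = relationship,
                  k = k, r = k[3] + k[2] / 2,
                  freqs = stats::setNames(p, panel$locus_id),
                  freqAllele = stats::setNames(panel$minor_allele,
                                               panel$locus_id),
                  dyads = data.frame(id1 = ids[seq(1, length(ids), 2)],
                                     id2 = ids[seq(2, length(ids), 2)]),
                  seed = seed)))
}

.gen_qc <- function(nPerGroup, panel, missingness, seed) {
  base <- .gen_panmictic(nPerGroup, panel, missingness, seed)
  N <- ncol(base)
  # the fixture plants exactly 33 polymorphic loci: guarantee each panel
  # locus keeps at least one minor-allele copy (rare alleles can fail to
  # appear by sampling)
  bc <- genotypeCalls(base)
  hom <- genotype_string(panel$major_allele, panel$major_allele)
  het <- genotype_string(panel$major_allele, panel$minor_allele)
  for (l in seq_len(nrow(bc))) {
    nm <- !is.na(bc[l, ])
    if (any(nm) && all(bc[l, nm] == hom[l]))
      bc[l, sample(which(nm), 1L)] <- het[l]
  }
  base <- GenotypeTable(bc, habitat = habitat(base),
                        batch = sampleBatch(base),
                        linkageGroup = linkageGroup(base))
  violator <- matrix("AC", 1L, N, dimnames = list("hwe0001", colnames(base)))
  mono <- matrix("GG", 22L, N,
                 dimnames = list(sprintf("mono%02d", 1:22), colnames(base)))
  calls <- rbind(genotypeCalls(base), violator, mono)
  GenotypeTable(calls, habitat = habitat(base), batch = sampleBatch(base),
                linkageGroup = c(linkageGroup(base), rep(NA_integer_, 23L)),
                metadata = list(truth = list(
                  mode = "qc_fixture",
                  hweViolator = "hwe0001",
                  monomorphic = rownames(mono),
                  survivors = rownames(base), seed = seed)))
}
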