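# Classed conditions: every user-facing failure mode raises a condition of
# class "panmix_<name>" so callers (and tests) can distinguish them.
pmx_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(paste0("panmix_", class), "panmix_error")))
}

pmx_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Run `expr` under a fixed seed without disturbing the caller's RNG stream;
# seed = NULL uses (and advances) the current stream.
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr
  else withr::with_seed(as.integer(seed), expr)
}

# Spawn a stream of child seeds from one user seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  withr::with_seed(as.integer(seed),
                   as.list(sample.int(.Machine$integer.max - 1L, n)))
}

# Empirical P of `observed` in the upper tail of `null`; add-one form gives
# (1 + #{null >= observed}) / (1 + length(null)).
empirical_p_upper <- function(observed, null, addOne = TRUE) {
  k <- sum(null >= observed)
  if (addOne) (1 + k) / (1 + length(null)) else k / length(null)
}

# two-character genotype string from two allele symbols, alphabetical order
genotype_string <- function(a1, a2) {
  swap <- a2 < a1
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  paste0(a1, a2)
}
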