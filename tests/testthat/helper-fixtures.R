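# Small panels and genotype matrices built in code for the tests.

tiny_panel <- function(L = 2L) {
  defs <- c("g.1C>A", "g.2T>C", "g.3G>T", "g.4A>G", "g.5C>G")
  snp_panel(defs[seq_len(L)])
}

# Genotype matrix from per-locus ref-allele dosages (2 = ref hom, 1 = het,
# 0 = alt hom, NA = missing).
gm_from_codes <- function(codes, panel = tiny_panel(ncol(codes))) {
  codes <- as.matrix(codes)
  calls <- matrix(NA_character_, nrow(codes), ncol(codes))
  for (j in seq_len(ncol(codes))) {
    ref <- panel$allele_ref[j]; alt <- panel$allele_alt[j]
    calls[, j] <- c(paste0(alt, alt), paste0(ref, alt), paste0(ref, ref))[codes[, j] + 1L]
  }
  genotype_matrix(calls, panel)
}

# Random genotype matrix with allele frequencies drawn per locus.
random_gm <- function(n, L, seed, missing_rate = 0) {
  set.seed(seed)
  p <- runif(L, 0.2, 0.8)
  codes <- sapply(seq_len(L), function(j) {
    rbinom(n, 1L, p[j]) + rbinom(n, 1L, p[j])
  })
  codes <- matrix(codes, nrow = n)
  if (missing_rate > 0) codes[runif(n * L) < missing_rate] <- NA
  gm_from_codes(codes)
}
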