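#' Published per-locus genotype and allele frequencies for the study panel
#'
#' The printed (2 d.p.) genotype and allele frequencies of the five GDF8
#' SNPs in the Dabieshan cattle study population. Raw genotype counts were
#' never published, so these rounded frequencies are the only per-locus
#' input available for desk recomputation of the diversity indices.
#'
#' @return Data.frame with columns `locus_id`, `freq_ref_hom`, `freq_het`,
#'   `freq_alt_hom`, `p_ref`, `p_alt`.
#' @export
gdf8_published_freqs <- function() {
  data.frame(
    locus_id = c("g.244C>G", "g.400G>A", "g.5070C>A", "g.5076T>C", "g.5148A>C"),
    freq_ref_hom = c(0.12, 0.10, 0.44, 0.50, 0.46),
    freq_het     = c(0.42, 0.43, 0.36, 0.34, 0.38),
    freq_alt_hom = c(0.46, 0.47, 0.20, 0.16, 0.16),
    p_ref = c(0.33, 0.32, 0.62, 0.67, 0.65),
    p_alt = c(0.67, 0.68, 0.38, 0.33, 0.35),
    stringsAsFactors = FALSE
  )
}

#' Published pairwise LD estimates for the study panel
#'
#' The printed D' and r-squared values for all ten pairs of the five GDF8
#' SNPs in the Dabieshan cattle study population, usable as input to
#' [ld_means()] for re-summarization.
#'
#' @return Data.frame with columns `locus_a`, `locus_b`, `D_prime`, `r2`.
#' @export
gdf8_published_ld <- function() {
  loci <- c("g.244C>G", "g.400G>A", "g.5070C>A", "g.5076T>C", "g.5148A>C")
  pairs <- utils::combn(5L, 2L)
  data.frame(
    locus_a = loci[pairs[1L, ]],
    locus_b = loci[pairs[2L, ]],
    D_prime = c(0.943, 0.780, 0.835, 0.815, 0.372, 0.533, 0.572,
                0.966, 0.917, 0.959),
    r2 = c(0.206, 0.191, 0.175, 0.188, 0.038, 0.062, 0.081,
           0.748, 0.758, 0.843),
    stringsAsFactors = FALSE
  )
}
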