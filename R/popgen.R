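#' Allele frequencies from biallelic genotype counts
#'
#' Gene counting for one biallelic locus: each reference homozygote carries
#' two reference alleles, each heterozygote one. Counts may be proportions
#' (any non-negative weights); only their ratios matter.
#'
#' @param genotype_counts Numeric vector of length 3: (ref-homozygote,
#'   heterozygote, alt-homozygote) counts.
#' @return Named numeric vector `c(p_ref, p_alt)` summing to 1.
#' @examples
#' allele_frequencies(c(0.44, 0.36, 0.20))  # p_ref = 0.62
#' @export
allele_frequencies <- function(genotype_counts) {
  if (length(genotype_counts) != 3L || any(genotype_counts < 0) ||
      anyNA(genotype_counts)) {
    stop("genotype_counts must be 3 non-negative numbers (ref-hom, het, alt-hom)")
  }
  n <- sum(genotype_counts)
  if (n <= 0) stop("allele frequencies undefined: no non-missing genotypes")
  p_ref <- (2 * genotype_counts[1L] + genotype_counts[2L]) / (2 * n)
  c(p_ref = unname(p_ref), p_alt = unname(1 - p_ref))
}

#' Gene diversity indices from allele frequencies
#'
#' For allele frequencies \eqn{p_i}:
#' expected homozygosity \eqn{Ho = \sum p_i^2}; gene heterozygosity (Nei
#' gene diversity) \eqn{He = 1 - Ho}; effective allele number
#' \eqn{Ne = 1/\sum p_i^2}; polymorphism information content
#' \eqn{PIC = 1 - \sum p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2} (for a biallelic
#' locus this reduces to \eqn{He - 2p^2q^2}).
#'
#' A monomorphic locus returns `Ho = 1, He = 0, Ne = 1, PIC = 0`.
#'
#' @param allele_freqs Numeric vector of allele frequencies summing to 1.
#' @return Named list with `Ho`, `He`, `Ne`, `PIC`.
#' @examples
#' diversity_indices(c(0.62, 0.38))
#' @export
diversity_indices <- function(allele_freqs) {
  p <- as.numeric(allele_freqs)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
    stop("allele frequencies must be non-negative and sum to 1")
  }
  ho <- sum(p^2)
  sum_cross <- 0
  if (length(p) > 1L) {
    for (i in seq_len(length(p) - 1L)) {
      sum_cross <- sum_cross + sum(2 * p[i]^2 * p[(i + 1L):length(p)]^2)
    }
  }
  list(Ho = ho, He = 1 - ho, Ne = 1 / ho, PIC = 1 - ho - sum_cross)
}

#' Hardy-Weinberg chi-square test for one biallelic locus
#'
#' Compares observed genotype counts with the expectations
#' \eqn{n(p^2, 2pq, q^2)} at the observed allele frequencies, via the plain
#' Pearson statistic \eqn{\chi^2 = \sum (O-E)^2/E} with no continuity
#' correction.
#'
#' `df_mode` controls the reference distribution: `"paper"` uses 2 degrees
#' of freedom (3 genotype classes minus 1, the convention of the POPGENE
#' lineage of software this pipeline reproduces); `"standard"` uses the
#' textbook 1 df (additionally subtracting the estimated allele frequency).
#'
#' @param genotype_counts Integer-like vector of length 3 (ref-hom, het,
#'   alt-hom).
#' @param df_mode `"paper"` (df = 2, default) or `"standard"` (df = 1).
#' @return List with `chi2`, `df`, `p_value`, `expected`.
#' @examples
#' hwe_chi2_test(c(50, 30, 20))
#' @export
hwe_chi2_test <- function(genotype_counts, df_mode = c("paper", "standard")) {
  df_mode <- match.arg(df_mode)
  if (length(genotype_counts) != 3L || any(genotype_counts < 0)) {
    stop("genotype_counts must be 3 non-negative counts")
  }
  n <- sum(genotype_counts)
  if (n < 1) stop("Hardy-Weinberg test undefined: no genotypes")
  p <- allele_frequencies(genotype_counts)[["p_ref"]]
  q <- 1 - p
  if (p <= 0 || q <= 0) stop("Hardy-Weinberg test undefined: locus monomorphic")
  expected <- n * c(p^2, 2 * p * q, q^2)
  if (any(expected == 0)) stop("Hardy-Weinberg test undefined: zero expected count")
  chi2 <- sum((genotype_counts - expected)^2 / expected)
  df <- if (df_mode == "paper") 2L else 1L
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df = df, lower.tail = FALSE),
       expected = expected)
}

#' Per-locus frequency, diversity and Hardy-Weinberg summary
#'
#' One row per panel locus: genotype counts and frequencies (complete cases
#' at that locus), allele frequencies, observed heterozygosity, expected
#' homozygosity Ho, gene heterozygosity He, effective allele number Ne, PIC,
#' and the Hardy-Weinberg chi-square test. Per-locus failures (e.g. a
#' monomorphic or all-missing locus) are returned as flagged rows with `NA`
#' statistics and a note, not errors.
#'
#' @param gm A [genotype_matrix()].
#' @param df_mode Passed to [hwe_chi2_test()].
#' @return A data.frame of class `locus_stats`, one row per locus.
#' @export
summarize_loci <- function(gm, df_mode = c("paper", "standard")) {
  df_mode <- match.arg(df_mode)
  if (n_individuals(gm) == 0L) stop("no individuals: locus statistics undefined")
  codes <- geno_codes(gm)
  panel <- gm$panel
  rows <- lapply(seq_len(n_loci(gm)), function(j) {
    ref <- panel$allele_ref[j]; alt <- panel$allele_alt[j]
    out <- data.frame(
      locus_id = panel$locus_id[j],
      genotype_ref_hom = paste0(ref, ref), genotype_het = paste0(ref, alt),
      genotype_alt_hom = paste0(alt, alt),
      n_ref_hom = NA_integer_, n_het = NA_integer_, n_alt_hom = NA_integer_,
      n_typed = NA_integer_,
      freq_ref_hom = NA_real_, freq_het = NA_real_, freq_alt_hom = NA_real_,
      p_ref = NA_real_, p_alt = NA_real_, het_obs = NA_real_,
      Ho = NA_real_, He = NA_real_, Ne = NA_real_, PIC = NA_real_,
      chi2 = NA_real_, df = NA_integer_, p_value = NA_real_,
      note = "", stringsAsFactors = FALSE
    )
    g <- codes[, j]
    cnt <- c(sum(g == 2L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
             sum(g == 0L, na.rm = TRUE))
    n <- sum(cnt)
    out[, c("n_ref_hom", "n_het", "n_alt_hom", "n_typed")] <- c(cnt, n)
    if (n == 0L) { out$note <- "all calls missing"; return(out) }
    gf <- cnt / n
    out[, c("freq_ref_hom", "freq_het", "freq_alt_hom")] <- gf
    af <- allele_frequencies(cnt)
    out$p_ref <- af[["p_ref"]]; out$p_alt <- af[["p_alt"]]
    out$het_obs <- gf[2L]
    div <- diversity_indices(af)
    out[, c("Ho", "He", "Ne", "PIC")] <- unlist(div)
    if (af[["p_ref"]] %in% c(0, 1)) {
      out$note <- "monomorphic: HWE test undefined"
    } else {
      h <- hwe_chi2_test(cnt, df_mode)
      out$chi2 <- h$chi2; out$df <- h$df; out$p_value <- h$p_value
    }
    out
  })
  res <- do.call(rbind, rows)
  attr(res, "df_mode") <- df_mode
  class(res) <- c("locus_stats", "data.frame")
  res
}
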