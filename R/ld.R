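#' Linkage-disequilibrium statistics from two-locus haplotype frequencies
#'
#' Given the four gamete frequencies at two biallelic loci, computes the
#' disequilibrium coefficient \eqn{D = f_{AB} - p_A p_B}, Lewontin's
#' normalized \eqn{D' = |D| / D_{max}} (with
#' \eqn{D_{max} = \min(p_A p_b, p_a p_B)} when D > 0 and
#' \eqn{\min(p_A p_B, p_a p_b)} when D < 0; D' is defined as 0 when D = 0),
#' and the squared allelic correlation
#' \eqn{r^2 = D^2 / (p_A p_a p_B p_b)}.
#'
#' @param hap_freqs Numeric vector of length 4 in the order
#'   (AB, Ab, aB, ab), where A/B are the reference alleles; must sum to 1.
#' @return An object of class `ld_pair`: list with `D`, `D_prime`, `r2`,
#'   `p_A`, `p_B`.
#' @examples
#' ld_from_haplotypes(c(0.4, 0.1, 0.1, 0.4))  # D = 0.15, D' = 0.6, r2 = 0.36
#' @export
ld_from_haplotypes <- function(hap_freqs) {
  f <- as.numeric(hap_freqs)
  if (length(f) != 4L || any(f < -1e-12) || abs(sum(f) - 1) > 1e-6) {
    stop("hap_freqs must be 4 non-negative gamete frequencies (AB, Ab, aB, ab) summing to 1")
  }
  f <- pmax(f, 0)
  p_A <- f[1L] + f[2L]; p_B <- f[1L] + f[3L]
  p_a <- 1 - p_A; p_b <- 1 - p_B
  if (p_A %in% c(0, 1) || p_B %in% c(0, 1)) {
    stop("linkage disequilibrium undefined: monomorphic locus")
  }
  D <- f[1L] - p_A * p_B
  if (D > 0) {
    d_max <- min(p_A * p_b, p_a * p_B)
  } else if (D < 0) {
    d_max <- min(p_A * p_B, p_a * p_b)
  } else {
    d_max <- NA_real_
  }
  d_prime <- if (D == 0) 0 else abs(D) / d_max
  r2 <- D^2 / (p_A * p_a * p_B * p_b)
  structure(list(D = D, D_prime = d_prime, r2 = r2, p_A = p_A, p_B = p_B),
            class = "ld_pair")
}

#' @export
print.ld_pair <- function(x, ...) {
  cat(sprintf("ld_pair: D = %.4f, D' = %.3f, r2 = %.3f\n", x$D, x$D_prime, x$r2))
  invisible(x)
}

#' Pairwise linkage-disequilibrium matrix for a SNP panel
#'
#' Runs a two-locus EM ([em_haplotype_frequencies()]) on pairwise-complete
#' cases for every pair of panel loci and derives D, D' and r-squared from
#' the estimated gamete frequencies. Pairs where LD is undefined (e.g. a
#' monomorphic locus) are returned as flagged `NA` rows, not errors.
#'
#' @param gm A [genotype_matrix()].
#' @param strong_r2 Threshold above which a pair is flagged as in strong LD
#'   (default 0.33).
#' @param tol,max_iter,n_restarts,seed EM settings, see
#'   [em_haplotype_frequencies()].
#' @return A data.frame of class `ld_table` with one row per locus pair and
#'   columns `locus_a`, `locus_b`, `D`, `D_prime`, `r2`, `strong`, `note`;
#'   summary means are attached via [ld_means()] as attributes `mean_D_prime`
#'   and `mean_r2`.
#' @export
ld_matrix <- function(gm, strong_r2 = 0.33, tol = 1e-8, max_iter = 1000L,
                      n_restarts = 5L, seed = 1L) {
  L <- n_loci(gm)
  if (L < 2L) stop("ld_matrix needs at least 2 loci")
  pairs <- utils::combn(L, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    out <- data.frame(locus_a = gm$panel$locus_id[a],
                      locus_b = gm$panel$locus_id[b],
                      D = NA_real_, D_prime = NA_real_, r2 = NA_real_,
                      strong = NA, note = "", stringsAsFactors = FALSE)
    res <- tryCatch({
      hs <- em_haplotype_frequencies(gm, loci = c(a, b), tol = tol,
                                     max_iter = max_iter,
                                     n_restarts = n_restarts, seed = seed)
      ref_a <- gm$panel$allele_ref[a]; ref_b <- gm$panel$allele_ref[b]
      alt_a <- gm$panel$allele_alt[a]; alt_b <- gm$panel$allele_alt[b]
      key <- c(paste0(ref_a, ref_b), paste0(ref_a, alt_b),
               paste0(alt_a, ref_b), paste0(alt_a, alt_b))
      f4 <- stats::setNames(numeric(4L), key)
      f4[names(hs$freqs)] <- hs$freqs
      ld_from_haplotypes(f4 / sum(f4))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$note <- conditionMessage(res)
    } else {
      out$D <- res$D; out$D_prime <- res$D_prime; out$r2 <- res$r2
      out$strong <- res$r2 > strong_r2
    }
    out
  })
  res <- do.call(rbind, rows)
  class(res) <- c("ld_table", "data.frame")
  ld_means(res, strong_r2 = strong_r2)
}

#' Summarize an LD table: means over all pairs and strong-LD flags
#'
#' Computes the mean D' and mean r-squared over all \eqn{L(L-1)/2} pairs of
#' an LD table (published LD tables can be re-summarized the same way) and
#' (re)derives the strong-LD flag.
#'
#' @param ld_table Data.frame with columns `D_prime` and `r2`.
#' @param strong_r2 Strong-LD threshold on r-squared (default 0.33).
#' @return The table with class `ld_table`, a recomputed `strong` column and
#'   attributes `mean_D_prime` and `mean_r2`.
#' @export
ld_means <- function(ld_table, strong_r2 = 0.33) {
  if (!all(c("D_prime", "r2") %in% names(ld_table))) {
    stop("ld_table must have columns D_prime and r2")
  }
  ld_table$strong <- ld_table$r2 > strong_r2
  attr(ld_table, "mean_D_prime") <- mean(ld_table$D_prime, na.rm = TRUE)
  attr(ld_table, "mean_r2") <- mean(ld_table$r2, na.rm = TRUE)
  attr(ld_table, "strong_r2") <- strong_r2
  if (!inherits(ld_table, "ld_table")) {
    class(ld_table) <- c("ld_table", class(ld_table))
  }
  ld_table
}

#' @export
print.ld_table <- function(x, ...) {
  df <- as.data.frame(x)
  for (col in c("D", "D_prime", "r2")) df[[col]] <- round(df[[col]], 3)
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("mean D' = %.3f, mean r2 = %.3f (strong LD: r2 > %.2f)\n",
              attr(x, "mean_D_prime"), attr(x, "mean_r2"),
              attr(x, "strong_r2")))
  invisible(x)
}
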