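#' EM haplotype-frequency estimation from unphased genotypes
#'
#' Expectation-maximization over phase configurations (gene counting). Each
#' individual's unphased multi-locus genotype is compatible with a set of
#' ordered-locus haplotype pairs; the E-step distributes the individual's
#' weight over those pairs in proportion to the current pair probabilities
#' (\eqn{2 f_h f_k} for h != k, \eqn{f_h^2} otherwise), and the M-step
#' re-estimates frequencies from the expected haplotype counts. Iteration
#' stops when the log-likelihood improves by less than `tol` or after
#' `max_iter` iterations; non-convergence is reported, never silent.
#'
#' Initialization is at linkage-equilibrium product frequencies; because that
#' point can be a stationary saddle (e.g. when every individual is a double
#' heterozygote), additional restarts apply a small deterministic seed-driven
#' jitter and the restart with the best final log-likelihood is returned.
#'
#' Only individuals with complete genotypes at the chosen loci are used
#' (listwise complete cases).
#'
#' @param gm A [genotype_matrix()].
#' @param loci Locus ids or indices to phase (default: all panel loci).
#' @param tol Convergence threshold on the log-likelihood change.
#' @param max_iter Maximum EM iterations per restart.
#' @param n_restarts Number of EM restarts (first restart is unjittered).
#' @param seed Integer seed driving the restart jitter.
#' @return An object of class `haplotype_set`: list with `loci`, `table`
#'   (data.frame of `haplotype`, `freq`, descending), `freqs` (named vector),
#'   `loglik`, `loglik_trace`, `n_iter`, `converged`, `n_used`.
#' @examples
#' gm <- genotype_matrix(
#'   rbind(c("CC", "TT"), c("AA", "CC"), c("CA", "TC")),
#'   snp_panel(c("g.1C>A", "g.2T>C"))
#' )
#' em_haplotype_frequencies(gm)
#' @export
em_haplotype_frequencies <- function(gm, loci = NULL, tol = 1e-8,
                                     max_iter = 1000L, n_restarts = 5L,
                                     seed = 1L) {
  if (!is.null(loci)) gm <- subset_genotypes(gm, loci = loci)
  codes <- geno_codes(gm)
  complete <- stats::complete.cases(codes)
  if (!any(complete)) stop("no individuals with complete genotypes at the chosen loci")
  codes <- codes[complete, , drop = FALSE]
  panel <- gm$panel

  enum <- enumerate_phase_space(codes, panel)
  K <- length(enum$haplotypes)
  n <- nrow(codes)

  # linkage-equilibrium starting point over the observed phase space
  p_ref <- colMeans(codes) / 2
  hap_alleles <- enum$hap_codes  # K x L matrix of ref dosage (0/1) per hap
  f0 <- apply(hap_alleles, 1L, function(h) {
    prod(ifelse(h == 1L, p_ref, 1 - p_ref))
  })
  f0 <- pmax(f0, 1e-12)
  f0 <- f0 / sum(f0)

  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    f <- f0
    if (r > 1L) {
      set.seed(as.integer(seed) + r)
      f <- f * exp(stats::runif(K, -0.5, 0.5))
      f <- f / sum(f)
    }
    fit <- em_iterate(f, enum, n, tol, max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  ord <- order(-best$freqs, enum$haplotypes)
  structure(list(
    loci = panel$locus_id,
    table = data.frame(haplotype = enum$haplotypes[ord],
                       freq = best$freqs[ord], stringsAsFactors = FALSE),
    freqs = stats::setNames(best$freqs, enum$haplotypes),
    loglik = best$loglik, loglik_trace = best$trace,
    n_iter = best$n_iter, converged = best$converged, n_used = n
  ), class = "haplotype_set")
}

# Enumerate, for each distinct multi-locus genotype, all compatible unordered
# haplotype pairs. Returns the haplotype dictionary plus a flat pair table
# indexed by genotype.
enumerate_phase_space <- function(codes, panel) {
  key <- apply(codes, 1L, paste, collapse = "")
  tab <- table(key)
  ugen <- do.call(rbind, strsplit(names(tab), ""))
  storage.mode(ugen) <- "integer"
  counts <- as.integer(tab)

  hap_env <- new.env(parent = emptyenv())
  haps <- character(0)
  hap_index <- function(h_codes) {
    s <- paste(h_codes, collapse = "")
    idx <- hap_env[[s]]
    if (is.null(idx)) {
      haps[[length(haps) + 1L]] <<- s
      idx <- length(haps)
      hap_env[[s]] <- idx
    }
    idx
  }

  g_idx <- integer(0); i_idx <- integer(0); j_idx <- integer(0)
  L <- ncol(ugen)
  for (g in seq_len(nrow(ugen))) {
    gv <- ugen[g, ]
    het <- which(gv == 1L)
    if (length(het) == 0L) {
      h <- hap_index(as.integer(gv == 2L))
      g_idx <- c(g_idx, g); i_idx <- c(i_idx, h); j_idx <- c(j_idx, h)
    } else {
      # fix the first heterozygous locus to carry ref on haplotype 1 so each
      # unordered pair is produced exactly once (2^(h-1) pairs)
      rest <- het[-1L]
      combos <- if (length(rest)) {
        as.matrix(expand.grid(rep(list(0:1), length(rest))))
      } else matrix(integer(0), nrow = 1L, ncol = 0L)
      for (c_i in seq_len(nrow(combos))) {
        h1 <- as.integer(gv == 2L); h2 <- h1
        h1[het[1L]] <- 1L; h2[het[1L]] <- 0L
        if (length(rest)) {
          h1[rest] <- combos[c_i, ]
          h2[rest] <- 1L - combos[c_i, ]
        }
        g_idx <- c(g_idx, g)
        i_idx <- c(i_idx, hap_index(h1)); j_idx <- c(j_idx, hap_index(h2))
      }
    }
  }
  # render haplotype strings in allele letters
  hap_codes <- do.call(rbind, strsplit(haps, ""))
  storage.mode(hap_codes) <- "integer"
  hap_strings <- apply(hap_codes, 1L, function(h) {
    paste(ifelse(h == 1L, panel$allele_ref, panel$allele_alt), collapse = "")
  })
  list(haplotypes = hap_strings, hap_codes = hap_codes,
       g_idx = g_idx, i_idx = i_idx, j_idx = j_idx,
       counts = counts, n_genotypes = nrow(ugen))
}

em_iterate <- function(f, enum, n, tol, max_iter) {
  hom <- enum$i_idx == enum$j_idx
  loglik_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    pp <- ifelse(hom, f[enum$i_idx]^2, 2 * f[enum$i_idx] * f[enum$j_idx])
    s <- as.vector(rowsum(pp, enum$g_idx))          # per-genotype likelihood
    loglik <- sum(enum$counts * log(s))
    trace <- c(trace, loglik)
    w <- enum$counts[enum$g_idx] * pp / s[enum$g_idx]
    cnt <- as.vector(rowsum(c(w, w), c(enum$i_idx, enum$j_idx)))
    idx <- sort(unique(c(enum$i_idx, enum$j_idx)))
    f_new <- numeric(length(f))
    f_new[idx] <- cnt / (2 * n)
    if (abs(loglik - loglik_old) < tol) { converged <- TRUE; f <- f_new; break }
    if (it >= max_iter) { f <- f_new; break }
    f <- f_new
    loglik_old <- loglik
  }
  list(freqs = f, loglik = loglik, trace = trace, n_iter = it,
       converged = converged)
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set over loci:", paste(x$loci, collapse = ", "), "\n")
  cat("n =", x$n_used, "| logLik =", format(x$loglik, digits = 8),
      "| iterations =", x$n_iter,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  tab <- x$table
  tab$freq_pct <- sprintf("%.2f", 100 * tab$freq)
  print.data.frame(utils::head(tab, 12L), row.names = FALSE)
  if (nrow(tab) > 12L) cat("...", nrow(tab) - 12L, "more haplotypes\n")
  invisible(x)
}

#' Drop rare haplotypes from a haplotype set
#'
#' Retains haplotypes with estimated frequency at or above `min_freq`. The
#' retained frequencies are deliberately NOT renormalized — reports quote
#' them on the original scale, so the retained set sums to less than 1 — and
#' the discarded count and mass are recorded as attributes-like fields.
#'
#' @param hs A `haplotype_set`.
#' @param min_freq Frequency floor in `[0, 1)` (default 0.05).
#' @return A `haplotype_set` with fields `n_discarded` and `discarded_mass`
#'   added; `freqs` keeps the full unfiltered vector for posterior use.
#' @export
filter_haplotypes <- function(hs, min_freq = 0.05) {
  stopifnot(inherits(hs, "haplotype_set"))
  if (min_freq < 0 || min_freq >= 1) stop("min_freq must be in [0, 1)")
  keep <- hs$table$freq >= min_freq
  out <- hs
  out$table <- hs$table[keep, , drop = FALSE]
  rownames(out$table) <- NULL
  out$n_discarded <- sum(!keep)
  out$discarded_mass <- sum(hs$table$freq[!keep])
  out$min_freq <- min_freq
  out
}
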