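# Independent oracles: deliberately naive implementations used to validate
# the package's computations. None of them share code with the package paths
# they check.

# Allele frequencies by literal enumeration of every allele copy.
oracle_allele_freq <- function(counts, ref = "R", alt = "A") {
  alleles <- c(rep(ref, 2L * counts[1L]), rep(ref, counts[2L]),
               rep(alt, counts[2L]), rep(alt, 2L * counts[3L]))
  unname(table(factor(alleles, levels = c(ref, alt))) / length(alleles))
}

# Pearson chi-square against Hardy-Weinberg expectations, recomputed from
# first principles.
oracle_hwe_chi2 <- function(counts) {
  n <- sum(counts)
  p <- (counts[1L] + counts[1L] + counts[2L]) / (2 * n)
  e <- c(n * p * p, n * 2 * p * (1 - p), n * (1 - p) * (1 - p))
  sum((counts - e)^2 / e)
}

# --- brute-force haplotype-frequency maximum likelihood ---------------------

# All 2^L haplotype strings over a panel.
all_haplotypes <- function(panel) {
  L <- nrow(panel)
  grid <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), L)))
  apply(grid, 1L, function(b) {
    paste(ifelse(b, panel$allele_ref, panel$allele_alt), collapse = "")
  })
}

# Ordered haplotype pair (h, k) compatible with an unphased call row?
hap_pair_compatible <- function(h, k, calls_row) {
  L <- nchar(h)
  for (j in seq_len(L)) {
    g <- sort(unname(c(substr(calls_row[[j]], 1, 1), substr(calls_row[[j]], 2, 2))))
    hk <- sort(c(substr(h, j, j), substr(k, j, j)))
    if (!identical(g, hk)) return(FALSE)
  }
  TRUE
}

# Log-likelihood of haplotype frequencies for a genotype matrix, summing
# f_h * f_k over all compatible ORDERED pairs (which equals the unordered
# 2 f_h f_k / f_h^2 convention).
oracle_hap_loglik <- function(freqs, gm) {
  haps <- names(freqs)
  ll <- 0
  for (i in seq_len(n_individuals(gm))) {
    row <- gm$calls[i, ]
    if (anyNA(row)) next
    lik <- 0
    for (a in seq_along(haps)) {
      for (b in seq_along(haps)) {
        if (hap_pair_compatible(haps[a], haps[b], row)) {
          lik <- lik + freqs[a] * freqs[b]
        }
      }
    }
    ll <- ll + log(lik)
  }
  ll
}

# Maximize the haplotype likelihood over the simplex by coarse grid search
# (when the support is small) plus local polish of the best points under a
# softmax parameterization. Independent of the EM implementation.
brute_force_hap_freqs <- function(gm, grid_step = 1 / 12, n_polish = 5L,
                                  seed = 42L) {
  panel <- gm$panel
  haps <- all_haplotypes(panel)
  # support: haplotypes appearing in at least one compatible pair
  complete <- !apply(gm$calls, 1L, anyNA)
  rows <- gm$calls[complete, , drop = FALSE]
  in_support <- vapply(haps, function(h) {
    for (i in seq_len(nrow(rows))) {
      for (k in haps) {
        if (hap_pair_compatible(h, k, rows[i, ])) return(TRUE)
      }
    }
    FALSE
  }, TRUE)
  haps <- haps[in_support]
  K <- length(haps)
  # precompute, per individual, which ordered haplotype pairs are compatible
  compat <- lapply(seq_len(nrow(rows)), function(i) {
    m <- matrix(FALSE, K, K)
    for (a in seq_len(K)) for (b in seq_len(K)) {
      m[a, b] <- hap_pair_compatible(haps[a], haps[b], rows[i, ])
    }
    m
  })
  obj <- function(f) {
    pp <- outer(f, f)
    sum(vapply(compat, function(m) log(sum(pp[m])), 0))
  }

  cand <- list()
  if (K <= 4L) {
    m <- round(1 / grid_step)
    grid <- compositions_of(m, K) / m
    vals <- apply(grid, 1L, function(f) if (all(f >= 0)) obj(f) else -Inf)
    ord <- order(-vals)
    for (i in seq_len(min(n_polish, nrow(grid)))) {
      cand[[length(cand) + 1L]] <- grid[ord[i], ]
    }
  } else {
    set.seed(seed)
    for (i in seq_len(25L)) {
      g <- stats::rgamma(K, 1)
      cand[[length(cand) + 1L]] <- g / sum(g)
    }
    cand[[length(cand) + 1L]] <- rep(1 / K, K)
  }
  best <- NULL; best_val <- -Inf
  for (f0 in cand) {
    z0 <- log(pmax(f0, 1e-6))
    fit <- stats::optim(z0, function(z) {
      f <- exp(z - max(z)); f <- f / sum(f)
      -obj(f)
    }, method = "Nelder-Mead",
    control = list(maxit = 3000L, reltol = 1e-12))
    f <- exp(fit$par - max(fit$par)); f <- f / sum(f)
    if (-fit$value > best_val) { best_val <- -fit$value; best <- f }
  }
  list(freqs = stats::setNames(best, haps), loglik = best_val)
}

# All compositions of m into K non-negative parts (rows sum to m).
compositions_of <- function(m, K) {
  if (K == 1L) return(matrix(m, 1L, 1L))
  out <- NULL
  for (first in 0:m) {
    rest <- compositions_of(m - first, K - 1L)
    out <- rbind(out, cbind(first, rest))
  }
  unname(out)
}
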