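#' Maximum-posterior diplotype assignment
#'
#' Assigns each individual with complete genotypes the most probable
#' compatible haplotype pair under the EM frequency estimates: the posterior
#' of a pair (h, k) given the genotype is proportional to \eqn{2 f_h f_k}
#' (or \eqn{f_h^2} for h = k) over the compatible pairs. Assignment is
#' restricted to pairs whose two haplotypes are both in the (possibly
#' filtered) set's retained table; an individual compatible with no such
#' pair is assigned from the full unfiltered frequency vector and flagged.
#' Posterior ties break deterministically to the lexicographically smallest
#' pair label.
#'
#' Diplotype classes are labelled by the concatenated per-locus genotype
#' string (reference allele first, e.g. `"CGGACCTTAA"`), and classes whose
#' population frequency falls below `min_class_freq` are marked as excluded
#' from downstream association.
#'
#' @param gm A [genotype_matrix()] over the same loci as `hs`.
#' @param hs A `haplotype_set` from [em_haplotype_frequencies()], optionally
#'   passed through [filter_haplotypes()].
#' @param min_class_freq Diplotype-class frequency floor (default 0.05).
#' @return A data.frame of class `diplotype_assignment` with columns
#'   `individual_id`, `hap1`, `hap2`, `pair_label`, `class_label`,
#'   `posterior`, `flagged`, `class_freq`, `retained`; the class frequency
#'   table is attached as attribute `class_table`.
#' @export
assign_diplotypes <- function(gm, hs, min_class_freq = 0.05) {
  stopifnot(inherits(hs, "haplotype_set"))
  if (!identical(hs$loci, gm$panel$locus_id)) {
    gm <- subset_genotypes(gm, loci = hs$loci)
  }
  codes <- geno_codes(gm)
  complete <- stats::complete.cases(codes)
  codes_c <- codes[complete, , drop = FALSE]
  if (nrow(codes_c) == 0L) stop("no individuals with complete genotypes")
  enum <- enumerate_phase_space(codes_c, gm$panel)
  freqs <- hs$freqs[enum$haplotypes]
  freqs[is.na(freqs)] <- 0
  retained_haps <- hs$table$haplotype

  key <- apply(codes_c, 1L, paste, collapse = "")
  ukey <- names(table(key))
  # per distinct genotype, choose the best pair once
  pick <- vector("list", length(ukey))
  for (g in seq_len(enum$n_genotypes)) {
    sel <- enum$g_idx == g
    i <- enum$i_idx[sel]; j <- enum$j_idx[sel]
    pp <- ifelse(i == j, freqs[i]^2, 2 * freqs[i] * freqs[j])
    in_retained <- enum$haplotypes[i] %in% retained_haps &
      enum$haplotypes[j] %in% retained_haps
    flagged <- FALSE
    use <- in_retained & pp > 0
    if (!any(use)) { use <- rep(TRUE, length(pp)); flagged <- TRUE }
    pp_use <- pp[use]
    tot <- sum(pp_use)
    post <- if (tot > 0) pp_use / tot else rep(1 / length(pp_use), length(pp_use))
    labs <- mapply(function(a, b) {
      hp <- sort(c(enum$haplotypes[a], enum$haplotypes[b]))
      paste(hp, collapse = "/")
    }, i[use], j[use])
    best <- which(post == max(post))
    if (length(best) > 1L) best <- best[order(labs[best])][1L]
    hp <- strsplit(labs[best], "/", fixed = TRUE)[[1L]]
    pick[[g]] <- list(hap1 = hp[1L], hap2 = hp[2L], label = labs[best],
                      posterior = post[best], flagged = flagged)
  }
  names(pick) <- ukey  # enumerate_phase_space groups genotypes by table(key)

  sel <- lapply(key, function(k) pick[[k]])
  res <- data.frame(
    individual_id = gm$individual_ids[complete],
    hap1 = vapply(sel, `[[`, "", "hap1"),
    hap2 = vapply(sel, `[[`, "", "hap2"),
    pair_label = vapply(sel, `[[`, "", "label"),
    class_label = apply(gm$calls[complete, , drop = FALSE], 1L, paste,
                        collapse = ""),
    posterior = vapply(sel, `[[`, 0, "posterior"),
    flagged = vapply(sel, `[[`, TRUE, "flagged"),
    stringsAsFactors = FALSE
  )
  cls <- table(res$class_label)
  class_tab <- data.frame(class_label = names(cls),
                          n = as.integer(cls),
                          freq = as.integer(cls) / nrow(res),
                          stringsAsFactors = FALSE)
  class_tab <- class_tab[order(-class_tab$freq, class_tab$class_label), ]
  rownames(class_tab) <- NULL
  class_tab$retained <- class_tab$freq >= min_class_freq
  m <- match(res$class_label, class_tab$class_label)
  res$class_freq <- class_tab$freq[m]
  res$retained <- class_tab$retained[m]
  attr(res, "class_table") <- class_tab
  attr(res, "min_class_freq") <- min_class_freq
  class(res) <- c("diplotype_assignment", "data.frame")
  res
}

#' @export
print.diplotype_assignment <- function(x, ...) {
  cat("diplotype_assignment:", nrow(x), "individuals,",
      nrow(attr(x, "class_table")), "classes (",
      sum(attr(x, "class_table")$retained), "retained at freq >=",
      attr(x, "min_class_freq"), ")\n")
  print.data.frame(utils::head(as.data.frame(x), 8L), row.names = FALSE)
  if (nrow(x) > 8L) cat("...", nrow(x) - 8L, "more individuals\n")
  invisible(x)
}
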