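#' Construct a genotype matrix
#'
#' Holds unphased diploid calls for `n` individuals at the loci of a
#' [snp_panel()]. Calls are two-character allele pairs (`"CA"`), unordered:
#' `"CA"` and `"AC"` denote the same genotype and are stored canonically with
#' the reference allele first. Missing calls are `NA` (accepted on input as
#' `""`, `"NN"` or `NA`).
#'
#' @param calls Character matrix (or data.frame) of dimension n x L; column
#'   order must match the panel.
#' @param panel A [snp_panel()].
#' @param individual_ids Unique identifiers; defaults to rownames or `ind_1..n`.
#' @return An object of class `genotype_matrix`: a list with elements `calls`
#'   (canonical character matrix), `panel`, `individual_ids`.
#' @export
genotype_matrix <- function(calls, panel, individual_ids = NULL) {
  if (!inherits(panel, "snp_panel")) stop("panel must be a snp_panel")
  calls <- as.matrix(calls)
  storage.mode(calls) <- "character"
  if (ncol(calls) != nrow(panel)) {
    stop("calls has ", ncol(calls), " columns but panel defines ",
         nrow(panel), " loci")
  }
  if (is.null(individual_ids)) {
    individual_ids <- rownames(calls)
    if (is.null(individual_ids)) {
      individual_ids <- if (nrow(calls)) paste0("ind_", seq_len(nrow(calls))) else character(0)
    }
  }
  individual_ids <- as.character(individual_ids)
  if (length(individual_ids) != nrow(calls)) {
    stop("individual_ids length does not match number of rows")
  }
  if (anyDuplicated(individual_ids)) {
    stop("duplicate individual id(s): ",
         paste(unique(individual_ids[duplicated(individual_ids)]), collapse = ", "))
  }
  calls[calls %in% c("", "NN", "nn", "--", "./.")] <- NA_character_
  calls <- toupper(calls)
  for (j in seq_len(ncol(calls))) {
    calls[, j] <- canonical_call(calls[, j], panel$allele_ref[j],
                                 panel$allele_alt[j], panel$locus_id[j],
                                 individual_ids)
  }
  dimnames(calls) <- list(individual_ids, panel$locus_id)
  structure(list(calls = calls, panel = panel, individual_ids = individual_ids),
            class = "genotype_matrix")
}

# Canonicalize one locus column: ref allele first; reject foreign alleles with
# a message naming the offending cell.
canonical_call <- function(x, ref, alt, locus, ids) {
  present <- !is.na(x)
  if (!any(present)) return(x)
  v <- x[present]
  if (any(nchar(v) != 2L)) {
    bad <- which(present)[nchar(v) != 2L][1L]
    stop("malformed call '", x[bad], "' for individual '", ids[bad],
         "' at locus ", locus)
  }
  a1 <- substr(v, 1, 1); a2 <- substr(v, 2, 2)
  okset <- c(ref, alt)
  bad <- !(a1 %in% okset) | !(a2 %in% okset)
  if (any(bad)) {
    i <- which(present)[bad][1L]
    stop("unknown allele in call '", x[i], "' for individual '", ids[i],
         "' at locus ", locus, " (expected alleles ", ref, "/", alt, ")")
  }
  # ref-first canonical order; het becomes ref+alt, e.g. "AC" at g.5070C>A -> "CA"
  n_ref <- (a1 == ref) + (a2 == ref)
  v <- ifelse(n_ref == 2L, paste0(ref, ref),
              ifelse(n_ref == 1L, paste0(ref, alt), paste0(alt, alt)))
  x[present] <- v
  x
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", n_individuals(x), "individuals x", n_loci(x), "loci\n")
  cat("loci:", paste(x$panel$locus_id, collapse = ", "), "\n")
  miss <- sum(is.na(x$calls))
  if (miss) cat("missing calls:", miss, "\n")
  invisible(x)
}

#' Number of individuals / loci in a genotype matrix
#' @param x A `genotype_matrix`.
#' @return Integer count.
#' @export
n_individuals <- function(x) nrow(x$calls)

#' @rdname n_individuals
#' @export
n_loci <- function(x) ncol(x$calls)

#' Reference-allele dosage codes
#'
#' Converts calls to counts of the reference allele: 2 = ref-homozygote,
#' 1 = heterozygote, 0 = alt-homozygote, `NA` = missing.
#'
#' @param x A `genotype_matrix`.
#' @return Integer matrix n x L.
#' @export
geno_codes <- function(x) {
  codes <- matrix(NA_integer_, n_individuals(x), n_loci(x),
                  dimnames = dimnames(x$calls))
  for (j in seq_len(n_loci(x))) {
    ref <- x$panel$allele_ref[j]
    v <- x$calls[, j]
    codes[, j] <- (substr(v, 1, 1) == ref) + (substr(v, 2, 2) == ref)
  }
  codes
}

#' Subset a genotype matrix by loci and/or individuals
#' @param x A `genotype_matrix`.
#' @param loci Locus ids or indices (default all).
#' @param individuals Individual ids or indices (default all).
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(x, loci = NULL, individuals = NULL) {
  jj <- if (is.null(loci)) seq_len(n_loci(x)) else {
    if (is.character(loci)) match(loci, x$panel$locus_id) else loci
  }
  if (anyNA(jj)) stop("unknown locus id(s)")
  ii <- if (is.null(individuals)) seq_len(n_individuals(x)) else {
    if (is.character(individuals)) match(individuals, x$individual_ids) else individuals
  }
  if (anyNA(ii)) stop("unknown individual id(s)")
  panel <- x$panel[jj, , drop = FALSE]
  class(panel) <- c("snp_panel", "data.frame")
  genotype_matrix(x$calls[ii, jj, drop = FALSE], panel, x$individual_ids[ii])
}

#' Names of the seven body-conformation traits
#'
#' Body length (BL), wither height (WH), hip height (HH), heart girth (HG),
#' abdominal girth (AGR), hip width (HW) and pin bone width (PBW), all in cm.
#'
#' @return Character vector of length 7.
#' @export
trait_names <- function() c("BL", "WH", "HH", "HG", "AGR", "HW", "PBW")

#' Construct a trait table
#'
#' Phenotype records: one row per individual with a categorical age class, a
#' sire id, and body-conformation measurements in cm. Missing measurements
#' are `NA`; trait values must be positive when present.
#'
#' @param df Data.frame with columns `individual_id`, `age`, `sire`, and one
#'   column per trait in [trait_names()] (missing trait columns are allowed
#'   and filled with `NA`).
#' @return An object of class `trait_table` (a data.frame).
#' @export
trait_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("individual_id", "age", "sire")
  if (!all(need %in% names(df))) {
    stop("trait table must have columns: ", paste(need, collapse = ", "))
  }
  df$individual_id <- as.character(df$individual_id)
  if (anyDuplicated(df$individual_id)) {
    stop("duplicate individual id(s) in trait table: ",
         paste(unique(df$individual_id[duplicated(df$individual_id)]), collapse = ", "))
  }
  df$age <- as.character(df$age)
  df$sire <- as.character(df$sire)
  for (tr in trait_names()) {
    if (!tr %in% names(df)) df[[tr]] <- NA_real_
    df[[tr]] <- as.numeric(df[[tr]])
    bad <- !is.na(df[[tr]]) & df[[tr]] <= 0
    if (any(bad)) {
      stop("non-positive ", tr, " value for individual '",
           df$individual_id[which(bad)[1]], "'")
    }
  }
  df <- df[, c(need, trait_names())]
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Bundle genotypes and traits into a herd dataset
#'
#' Individuals present in only one of the two tables are reported (via a
#' message) and excluded from joined views, but the full genotype matrix is
#' retained for genotype-only statistics.
#'
#' @param genotypes A [genotype_matrix()].
#' @param traits A [trait_table()] or `NULL`.
#' @return An object of class `herd_data`: list with `genotypes`, `traits`,
#'   `joined_ids` (ids present in both tables), `unmatched`.
#' @export
herd_data <- function(genotypes, traits = NULL) {
  if (!inherits(genotypes, "genotype_matrix")) stop("genotypes must be a genotype_matrix")
  unmatched <- list(genotype_only = character(0), trait_only = character(0))
  joined <- character(0)
  if (!is.null(traits)) {
    if (!inherits(traits, "trait_table")) traits <- trait_table(traits)
    joined <- intersect(genotypes$individual_ids, traits$individual_id)
    unmatched$genotype_only <- setdiff(genotypes$individual_ids, joined)
    unmatched$trait_only <- setdiff(traits$individual_id, joined)
    n_un <- length(unmatched$genotype_only) + length(unmatched$trait_only)
    if (n_un > 0) {
      message(n_un, " individual(s) present in only one table are dropped ",
              "from joined views (retained for genotype-only statistics)")
    }
  }
  structure(list(genotypes = genotypes, traits = traits,
                 joined_ids = joined, unmatched = unmatched),
            class = "herd_data")
}

#' @export
print.herd_data <- function(x, ...) {
  cat("herd_data:", n_individuals(x$genotypes), "genotyped individuals,",
      if (is.null(x$traits)) 0L else nrow(x$traits), "phenotyped,",
      length(x$joined_ids), "joined\n")
  invisible(x)
}
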