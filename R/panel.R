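#' Parse an HGVS-style locus name
#'
#' Locus names such as `"g.5070C>A"` encode a 1-based coordinate and the two
#' alleles segregating at the site. The coordinate is treated as a label (it
#' is carried into VCF export) and is never used arithmetically.
#'
#' @param x Character vector of locus names of the form `g.<pos><ref>><alt>`.
#' @return A data.frame with columns `locus_id`, `position`, `allele_ref`,
#'   `allele_alt`.
#' @examples
#' parse_locus_name("g.5070C>A")
#' @export
parse_locus_name <- function(x) {
  m <- regmatches(x, regexec("^g\\.([0-9]+)([ACGT])>([ACGT])$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("cannot parse locus name(s): ", paste(x[bad], collapse = ", "),
         " (expected the form 'g.<pos><ref>><alt>', e.g. 'g.5070C>A')")
  }
  data.frame(
    locus_id   = x,
    position   = as.integer(vapply(m, `[`, "", 2L)),
    allele_ref = vapply(m, `[`, "", 3L),
    allele_alt = vapply(m, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
}

#' Construct a SNP panel
#'
#' A panel is an ordered set of biallelic SNP definitions: locus id, reference
#' and alternate allele (the first and second allele in the locus name), and a
#' region label. All downstream statistics treat the panel order as the locus
#' order along the gene.
#'
#' @param locus_id Character vector of unique locus names.
#' @param allele_ref,allele_alt Single-nucleotide alleles (`A`, `C`, `G`, `T`).
#'   If omitted, both are parsed from `locus_id` via [parse_locus_name()].
#' @param region Optional region labels (e.g. `"exon"`, `"UTR3"`, `"other"`).
#' @param position Optional 1-based coordinates; parsed from `locus_id` when
#'   possible.
#' @return An object of class `snp_panel` (a data.frame).
#' @examples
#' snp_panel(c("g.244C>G", "g.400G>A", "g.5070C>A", "g.5076T>C", "g.5148A>C"))
#' @export
snp_panel <- function(locus_id, allele_ref = NULL, allele_alt = NULL,
                      region = NULL, position = NULL) {
  locus_id <- as.character(locus_id)
  if (anyDuplicated(locus_id)) {
    stop("duplicate locus_id in panel: ",
         paste(unique(locus_id[duplicated(locus_id)]), collapse = ", "))
  }
  if (is.null(allele_ref) || is.null(allele_alt)) {
    parsed <- parse_locus_name(locus_id)
    if (is.null(allele_ref)) allele_ref <- parsed$allele_ref
    if (is.null(allele_alt)) allele_alt <- parsed$allele_alt
    if (is.null(position)) position <- parsed$position
  }
  allele_ref <- toupper(as.character(allele_ref))
  allele_alt <- toupper(as.character(allele_alt))
  ok <- c("A", "C", "G", "T")
  if (!all(allele_ref %in% ok) || !all(allele_alt %in% ok)) {
    stop("alleles must be one of A, C, G, T")
  }
  if (any(allele_ref == allele_alt)) {
    stop("allele_ref must differ from allele_alt at: ",
         paste(locus_id[allele_ref == allele_alt], collapse = ", "))
  }
  if (is.null(region)) region <- rep(NA_character_, length(locus_id))
  if (is.null(position)) position <- rep(NA_integer_, length(locus_id))
  panel <- data.frame(
    locus_id = locus_id, allele_ref = allele_ref, allele_alt = allele_alt,
    region = as.character(region), position = as.integer(position),
    stringsAsFactors = FALSE
  )
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("SNP panel with", nrow(x), "loci\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' The five-SNP GDF8 panel of the Dabieshan cattle study population
#'
#' Two synonymous exon-1 sites, two synonymous exon-3 sites and one site in
#' the 3' untranslated region of the bovine myostatin (GDF8) gene.
#'
#' @return A [snp_panel()] of five loci.
#' @export
gdf8_panel <- function() {
  snp_panel(
    c("g.244C>G", "g.400G>A", "g.5070C>A", "g.5076T>C", "g.5148A>C"),
    region = c("exon", "exon", "exon", "exon", "UTR3")
  )
}
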