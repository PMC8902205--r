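#' @importFrom utils read.table write.table
NULL

# Delimiter auto-detection: tab wins if the header contains any tab,
# otherwise comma.
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.table(path, sep = detect_sep(path), header = TRUE,
             stringsAsFactors = FALSE, check.names = FALSE,
             colClasses = "character", na.strings = c("NA", ""))
}

#' Load a genotype/trait/panel dataset from delimited files
#'
#' Reads the three flat tables the pipeline consumes and returns a validated
#' [herd_data()] bundle. Delimiters (comma or tab) are auto-detected per file.
#'
#' The genotype table has one row per individual (first column = id) and one
#' column per locus, cells holding two-character allele pairs (`"CA"`; empty
#' or `"NN"` = missing). The trait table has columns `individual_id`, `age`,
#' `sire` and the traits of [trait_names()]. The optional panel table has
#' columns `locus_id`, `allele_ref`, `allele_alt` and optionally `region`,
#' `position`; without it, alleles are parsed from the genotype header's
#' locus names.
#'
#' @param genotype_path Path to the genotype table.
#' @param trait_path Optional path to the trait table.
#' @param panel_path Optional path to the panel definition table.
#' @return A [herd_data()].
#' @export
load_dataset <- function(genotype_path, trait_path = NULL, panel_path = NULL) {
  gt <- read_table_auto(genotype_path)
  if (ncol(gt) < 2L) stop("genotype table needs an id column plus >=1 locus column")
  ids <- gt[[1L]]
  loci <- names(gt)[-1L]
  if (!is.null(panel_path)) {
    pt <- read_table_auto(panel_path)
    if (!all(c("locus_id", "allele_ref", "allele_alt") %in% names(pt))) {
      stop("panel table must have columns locus_id, allele_ref, allele_alt")
    }
    m <- match(loci, pt$locus_id)
    if (anyNA(m)) {
      stop("genotype column(s) missing from panel: ",
           paste(loci[is.na(m)], collapse = ", "))
    }
    pt <- pt[m, , drop = FALSE]
    panel <- snp_panel(pt$locus_id, pt$allele_ref, pt$allele_alt,
                       region = if ("region" %in% names(pt)) pt$region else NULL,
                       position = if ("position" %in% names(pt)) as.integer(pt$position) else NULL)
  } else {
    panel <- snp_panel(loci)
  }
  gm <- genotype_matrix(as.matrix(gt[, -1L, drop = FALSE]), panel, ids)
  traits <- NULL
  if (!is.null(trait_path)) traits <- trait_table(read_table_auto(trait_path))
  herd_data(gm, traits)
}

#' Write a dataset to delimited files plus a minimal VCF
#'
#' Emits `genotypes.tsv`, `panel.tsv`, `traits.tsv` (when present) in the
#' dialect [load_dataset()] accepts, and `genotypes.vcf`, a minimal VCFv4.2
#' rendering (CHROM/POS/ID/REF/ALT + unphased GT per individual).
#'
#' @param dataset A [herd_data()] (or bare [genotype_matrix()]).
#' @param out_dir Output directory, created if needed.
#' @return Named character vector of the file paths written.
#' @export
write_dataset <- function(dataset, out_dir) {
  if (inherits(dataset, "genotype_matrix")) dataset <- herd_data(dataset)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir)
  }
  gm <- dataset$genotypes
  paths <- c(genotypes = file.path(out_dir, "genotypes.tsv"),
             panel = file.path(out_dir, "panel.tsv"),
             vcf = file.path(out_dir, "genotypes.vcf"))
  gt <- data.frame(individual_id = gm$individual_ids,
                   gm$calls, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(gt, paths[["genotypes"]], sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  write.table(as.data.frame(gm$panel), paths[["panel"]], sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  write_vcf(gm, paths[["vcf"]])
  if (!is.null(dataset$traits)) {
    paths[["traits"]] <- file.path(out_dir, "traits.tsv")
    write.table(as.data.frame(dataset$traits), paths[["traits"]], sep = "\t",
                quote = FALSE, row.names = FALSE, na = "")
  }
  paths
}

#' Export genotypes as a minimal VCF v4.2
#'
#' One record per SNP with GT as the only FORMAT field and one sample column
#' per individual, unphased (`0/1` style). Positions come from the panel
#' (parsed from the `g.` locus names) on a placeholder contig, since the
#' panel carries no genome assembly mapping.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @param contig Contig name used in `#CHROM` (default `"candidate_gene"`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, contig = "candidate_gene") {
  panel <- gm$panel
  pos <- panel$position
  pos[is.na(pos)] <- seq_len(nrow(panel))[is.na(pos)]
  codes <- geno_codes(gm)  # ref-allele dosage
  gt_of <- c(`2` = "0/0", `1` = "0/1", `0` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=haplotrait",
    paste0("##contig=<ID=", contig, ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$individual_ids), collapse = "\t")
  )
  for (j in seq_len(nrow(panel))) {
    gts <- gt_of[as.character(codes[, j])]
    gts[is.na(gts)] <- "./."
    lines <- c(lines, paste(c(contig, pos[j], panel$locus_id[j],
                              panel$allele_ref[j], panel$allele_alt[j],
                              ".", "PASS", ".", "GT", gts), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Import genotypes from a minimal VCF
#'
#' Reads the GT-only VCF dialect written by [write_vcf()] (via the `vcfR`
#' package when installed, otherwise a built-in reader for this dialect) and
#' reconstructs a [genotype_matrix()].
#'
#' @param path VCF file path.
#' @param panel Optional [snp_panel()]; reconstructed from the VCF `ID`,
#'   `REF`, `ALT` columns when omitted.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, panel = NULL) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fixm <- vcfR::getFIX(v)
    if (is.null(dim(fixm))) fixm <- t(fixm)  # single-record VCF
    fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    if (is.null(dim(gt))) gt <- t(gt)
    samples <- colnames(gt)
  } else {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "##")]
    tab <- strsplit(body, "\t", fixed = TRUE)
    header <- tab[[1L]]
    samples <- header[-(1:9)]
    rows <- do.call(rbind, tab[-1L])
    fix <- data.frame(ID = rows[, 3L], REF = rows[, 4L], ALT = rows[, 5L],
                      POS = rows[, 2L], stringsAsFactors = FALSE)
    gt <- rows[, -(1:9), drop = FALSE]          # loci x samples
    gt[] <- sub(":.*", "", gt)
    dimnames(gt) <- list(fix$ID, samples)
  }
  if (is.null(panel)) {
    panel <- snp_panel(fix$ID, fix$REF, fix$ALT,
                       position = suppressWarnings(as.integer(fix$POS)))
  }
  calls <- matrix(NA_character_, length(samples), nrow(panel),
                  dimnames = list(samples, panel$locus_id))
  for (j in seq_len(nrow(panel))) {
    g <- gsub("|", "/", gt[j, ], fixed = TRUE)
    alleles <- c(panel$allele_ref[j], panel$allele_alt[j])
    parts <- strsplit(g, "/", fixed = TRUE)
    calls[, j] <- vapply(parts, function(p) {
      if (length(p) != 2L || any(p == ".")) return(NA_character_)
      paste0(alleles[as.integer(p) + 1L], collapse = "")
    }, "")
  }
  genotype_matrix(calls, panel, samples)
}
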