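#' Build a pipeline configuration
#'
#' Collects every threshold and input the end-to-end pipeline uses. Either
#' `sim` (a [sim_config()], the default: run on a synthetic herd) or the
#' three input paths must be supplied.
#'
#' @param sim A [sim_config()] used when no input paths are given.
#' @param genotype_path,trait_path,panel_path Input files for
#'   [load_dataset()]; override `sim` when `genotype_path` is non-`NULL`.
#' @param hwe_df_mode `"paper"` or `"standard"`, see [hwe_chi2_test()].
#' @param min_hap_freq Haplotype reporting floor (default 0.05).
#' @param min_class_freq Diplotype-class floor for association (default 0.05).
#' @param alpha Significance level (default 0.05).
#' @param strong_r2 Strong-LD threshold (default 0.33).
#' @param seed Seed for the EM restarts (and the simulation when `sim` has
#'   no explicit seed change).
#' @param em_tol,em_max_iter,em_restarts EM settings.
#' @param out_dir Output directory for [run_pipeline()] artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), genotype_path = NULL,
                            trait_path = NULL, panel_path = NULL,
                            hwe_df_mode = c("paper", "standard"),
                            min_hap_freq = 0.05, min_class_freq = 0.05,
                            alpha = 0.05, strong_r2 = 0.33, seed = 1L,
                            em_tol = 1e-8, em_max_iter = 1000L,
                            em_restarts = 5L, out_dir = NULL) {
  hwe_df_mode <- match.arg(hwe_df_mode)
  for (thr in c(min_hap_freq, min_class_freq)) {
    if (thr < 0 || thr >= 1) stop("frequency thresholds must be in [0, 1)")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(sim = sim, genotype_path = genotype_path,
                 trait_path = trait_path, panel_path = panel_path,
                 hwe_df_mode = hwe_df_mode, min_hap_freq = min_hap_freq,
                 min_class_freq = min_class_freq, alpha = alpha,
                 strong_r2 = strong_r2, seed = as.integer(seed),
                 em_tol = em_tol, em_max_iter = em_max_iter,
                 em_restarts = em_restarts, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full association pipeline
#'
#' Executes, in order: data acquisition (simulation or file loading),
#' per-locus diversity and Hardy-Weinberg statistics, the pairwise LD
#' matrix, multi-locus EM haplotype estimation, haplotype filtering,
#' diplotype assignment, and genotype- plus diplotype-level trait
#' association. When `config$out_dir` is set, every artifact is written as a
#' TSV together with a run log recording the seed and every threshold
#' applied; re-running with the same configuration reproduces byte-identical
#' tables. A stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `report_bundle` with elements `herd`,
#'   `locus_stats`, `ld`, `haplotypes`, `haplotypes_filtered`, `diplotypes`,
#'   `assoc`, `config`, `files` (paths written, or `NULL`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  herd <- stage("input", {
    if (!is.null(config$genotype_path)) {
      load_dataset(config$genotype_path, config$trait_path, config$panel_path)
    } else {
      simulate_herd(config$sim)
    }
  })
  locus_stats <- stage("popgen", summarize_loci(herd$genotypes,
                                                df_mode = config$hwe_df_mode))
  ld <- stage("ld", ld_matrix(herd$genotypes, strong_r2 = config$strong_r2,
                              tol = config$em_tol,
                              max_iter = config$em_max_iter,
                              n_restarts = config$em_restarts,
                              seed = config$seed))
  haps <- stage("haplotype_em",
                em_haplotype_frequencies(herd$genotypes, tol = config$em_tol,
                                         max_iter = config$em_max_iter,
                                         n_restarts = config$em_restarts,
                                         seed = config$seed))
  haps_f <- stage("haplotype_filter", filter_haplotypes(haps,
                                                        config$min_hap_freq))
  dips <- stage("diplotype", assign_diplotypes(herd$genotypes, haps_f,
                                               config$min_class_freq))
  assoc <- NULL
  if (!is.null(herd$traits)) {
    assoc <- stage("association",
                   association_report(herd, diplotypes = dips,
                                      alpha = config$alpha))
  }
  bundle <- structure(list(herd = herd, locus_stats = locus_stats, ld = ld,
                           haplotypes = haps, haplotypes_filtered = haps_f,
                           diplotypes = dips, assoc = assoc, config = config,
                           files = NULL),
                      class = "report_bundle")
  if (!is.null(config$out_dir)) {
    bundle$files <- write_report_bundle(bundle, config$out_dir)
  }
  bundle
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

write_report_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir)
  }
  rendered <- render_report(bundle)
  files <- character(0)
  for (nm in names(rendered)) {
    files[nm] <- write_tsv(rendered[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  cfg <- bundle$config
  log_lines <- c(
    "haplotrait run log",
    paste0("package_version=", as.character(utils::packageVersion("haplotrait"))),
    paste0("seed=", cfg$seed),
    paste0("hwe_df_mode=", cfg$hwe_df_mode),
    paste0("min_hap_freq=", cfg$min_hap_freq),
    paste0("min_class_freq=", cfg$min_class_freq),
    paste0("alpha=", cfg$alpha),
    paste0("strong_r2=", cfg$strong_r2),
    paste0("em_tol=", cfg$em_tol),
    paste0("em_max_iter=", cfg$em_max_iter),
    paste0("em_restarts=", cfg$em_restarts),
    paste0("n_individuals=", n_individuals(bundle$herd$genotypes)),
    paste0("n_loci=", n_loci(bundle$herd$genotypes))
  )
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, log_path)
  files["run_log"] <- log_path
  files
}

fmt <- function(x, digits) ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), x))

#' Render a report bundle as paper-shaped formatted tables
#'
#' Applies the reporting rounding rules — frequencies at 2 d.p., diversity
#' and LD statistics at 3 d.p., haplotype frequencies as percentages at
#' 2 d.p., trait means as `mean±SE` at 2 d.p. with grouping letters — to the
#' full-precision bundle. Rounding happens only here; every upstream
#' computation keeps full precision.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @return Named list of character-formatted data.frames: `locus_stats`,
#'   `ld`, `haplotypes`, `diplotype_classes`, and (with traits)
#'   `assoc_genotype`, `assoc_diplotype`, `assoc_overall`.
#' @export
render_report <- function(bundle) {
  ls <- as.data.frame(bundle$locus_stats)
  locus_tab <- data.frame(
    locus = ls$locus_id,
    genotypes = paste(ls$genotype_ref_hom, ls$genotype_het, ls$genotype_alt_hom,
                      sep = "/"),
    geno_freq = paste(fmt(ls$freq_ref_hom, 2), fmt(ls$freq_het, 2),
                      fmt(ls$freq_alt_hom, 2), sep = "/"),
    allele_freq = paste(fmt(ls$p_ref, 2), fmt(ls$p_alt, 2), sep = "/"),
    chi2 = fmt(ls$chi2, 2), p_value = fmt(ls$p_value, 3),
    Ho = fmt(ls$Ho, 3), He = fmt(ls$He, 3), Ne = fmt(ls$Ne, 3),
    PIC = fmt(ls$PIC, 3), note = ls$note, stringsAsFactors = FALSE
  )
  ld <- as.data.frame(bundle$ld)
  ld_tab <- data.frame(
    pair = paste(ld$locus_a, ld$locus_b, sep = " - "),
    D_prime = fmt(ld$D_prime, 3), r2 = fmt(ld$r2, 3),
    strong_LD = ifelse(is.na(ld$strong), "", ifelse(ld$strong, "yes", "no")),
    stringsAsFactors = FALSE
  )
  ld_tab <- rbind(ld_tab, data.frame(
    pair = "mean", D_prime = fmt(attr(bundle$ld, "mean_D_prime"), 3),
    r2 = fmt(attr(bundle$ld, "mean_r2"), 3), strong_LD = "",
    stringsAsFactors = FALSE))
  hf <- bundle$haplotypes_filtered
  hap_tab <- data.frame(
    haplotype = hf$table$haplotype,
    frequency_pct = fmt(100 * hf$table$freq, 2),
    stringsAsFactors = FALSE
  )
  cls <- attr(bundle$diplotypes, "class_table")
  dip_tab <- data.frame(
    diplotype_class = cls$class_label, n = cls$n,
    frequency = fmt(cls$freq, 3),
    retained = ifelse(cls$retained, "yes", "no"), stringsAsFactors = FALSE
  )
  out <- list(locus_stats = locus_tab, ld = ld_tab, haplotypes = hap_tab,
              diplotype_classes = dip_tab)
  if (!is.null(bundle$assoc)) {
    long <- bundle$assoc$table
    # letters are shown only where the trait x marker analysis actually
    # separates classes (more than one distinct letter set)
    key <- paste(long$marker, long$trait)
    informative <- stats::ave(long$letters, key,
                              FUN = function(l) length(unique(l)) > 1L) == "TRUE"
    long$cell <- paste0(fmt(long$lsmean, 2), "±", fmt(long$lsmean_se, 2),
                        ifelse(informative, paste0(" ", long$letters), ""))
    wide <- function(markers) {
      sub <- long[long$marker %in% markers, , drop = FALSE]
      if (!nrow(sub)) return(NULL)
      res <- stats::reshape(
        sub[, c("marker", "class", "trait", "cell")],
        idvar = c("marker", "class"), timevar = "trait", direction = "wide")
      names(res) <- sub("^cell\\.", "", names(res))
      res[order(res$marker, res$class), , drop = FALSE]
    }
    geno_markers <- setdiff(unique(long$marker), "diplotype")
    out$assoc_genotype <- wide(geno_markers)
    out$assoc_diplotype <- wide("diplotype")
    ov <- bundle$assoc$overall
    ov$f_statistic <- fmt(ov$f_statistic, 2)
    ov$p_value <- fmt(as.numeric(ov$p_value), 3)
    out$assoc_overall <- ov
  }
  out[!vapply(out, is.null, TRUE)]
}
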