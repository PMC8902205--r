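#' Published haplotype pool of the Dabieshan cattle study population
#'
#' The five common GDF8 haplotypes with their published population
#' frequencies (summing to 89.8%). The residual 10.2% mass belonged to rare
#' haplotypes that the published table omits (those under the 5% reporting
#' floor); [default_hap_pool()] fills that mass with synthetic rare
#' haplotypes.
#'
#' @return Data.frame with columns `haplotype`, `freq`.
#' @export
gdf8_haplotype_pool <- function() {
  data.frame(
    haplotype = c("CACTA", "GAACC", "GGCTA", "GACTA", "GGACC"),
    freq = c(0.315, 0.238, 0.235, 0.058, 0.052),
    stringsAsFactors = FALSE
  )
}

#' Simulation haplotype pool: published haplotypes plus synthetic rare ones
#'
#' Extends [gdf8_haplotype_pool()] to a full probability distribution by
#' spreading the residual mass uniformly over `n_filler` additional distinct
#' haplotypes (default 7, giving 12 haplotypes in total, the number reported
#' segregating in the study population). The fillers are synthetic: they are
#' the first `n_filler` allele strings, in reference-allele-first binary
#' enumeration order over the panel, that do not collide with the published
#' haplotypes.
#'
#' @param panel A [snp_panel()] (default [gdf8_panel()]).
#' @param main Data.frame of `haplotype`, `freq` for the common haplotypes.
#' @param n_filler Number of synthetic rare haplotypes to carry the residual
#'   mass.
#' @return Data.frame with columns `haplotype`, `freq` summing to 1.
#' @export
default_hap_pool <- function(panel = gdf8_panel(),
                             main = gdf8_haplotype_pool(), n_filler = 7L) {
  resid <- 1 - sum(main$freq)
  if (resid < -1e-9) stop("main haplotype frequencies exceed 1")
  if (n_filler == 0L || resid <= 1e-12) {
    pool <- main
    pool$freq <- pool$freq / sum(pool$freq)
    return(pool)
  }
  L <- nrow(panel)
  all_haps <- apply(as.matrix(expand.grid(rep(list(0:1), L))), 1L, function(b) {
    paste(ifelse(b == 0L, panel$allele_ref, panel$allele_alt), collapse = "")
  })
  # expand.grid varies the first locus fastest; reorder to plain binary order
  ord <- order(apply(as.matrix(expand.grid(rep(list(0:1), L))), 1L,
                     function(b) sum(b * 2^(seq_len(L) - 1L))))
  all_haps <- all_haps[ord]
  fillers <- setdiff(all_haps, main$haplotype)[seq_len(n_filler)]
  if (anyNA(fillers)) stop("panel too small for ", n_filler, " filler haplotypes")
  rbind(main,
        data.frame(haplotype = fillers, freq = rep(resid / n_filler, n_filler),
                   stringsAsFactors = FALSE))
}

#' Default trait baselines and residual standard deviations (cm)
#'
#' Baseline means chosen near the published class means of the study
#' population; residual SDs are synthetic (the study reports only standard
#' errors of class means), chosen so that class-mean SEs at n = 380 come out
#' on the same order as the published tables.
#'
#' @return Data.frame with columns `trait`, `baseline`, `sd`.
#' @export
default_trait_params <- function() {
  data.frame(
    trait = trait_names(),
    baseline = c(126, 110, 110, 149, 169, 31.5, 17.5),
    sd = c(10, 6, 5.5, 10, 15, 4.5, 2.5),
    stringsAsFactors = FALSE
  )
}

#' Build a simulation configuration
#'
#' Defines the synthetic study population: herd size, the haplotype pool
#' gametes are drawn from (random mating: two independent draws per
#' individual), the fixed-effect structure of the traits (age class, sire,
#' Gaussian residual) and optional additive diplotype- or genotype-class
#' trait effects.
#'
#' `trait_effects` is a data.frame with columns `trait`, `locus`, `class`,
#' `shift`: when `locus` is `NA` the effect keys on the diplotype pair label
#' (`"hap1/hap2"`, lexicographically sorted, e.g. `"CACTA/CACTA"`);
#' otherwise on the canonical genotype call at that locus (e.g. `"AA"` at
#' `"g.5070C>A"`). Shifts are additive in cm.
#'
#' @param n_individuals Herd size (default 380, the study size).
#' @param hap_pool Data.frame `haplotype`, `freq` (default
#'   [default_hap_pool()]).
#' @param panel A [snp_panel()] consistent with the pool strings.
#' @param trait_effects Optional effects data.frame as described above.
#' @param trait_params Data.frame `trait`, `baseline`, `sd` (default
#'   [default_trait_params()]).
#' @param n_age_classes,n_sires Numbers of age classes and sires, assigned
#'   uniformly at random (defaults 4 and 10; the study does not publish its
#'   age or sire structure).
#' @param age_effect_sd,sire_effect_sd SDs (cm) of the Gaussian age-class
#'   and sire effects (defaults 3 and 2).
#' @param missing_rate Per-call probability of a missing genotype (default 0).
#' @param seed Integer seed; all draws derive from it deterministically.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 380L, hap_pool = default_hap_pool(),
                       panel = gdf8_panel(), trait_effects = NULL,
                       trait_params = default_trait_params(),
                       n_age_classes = 4L, n_sires = 10L,
                       age_effect_sd = 3, sire_effect_sd = 2,
                       missing_rate = 0, seed = 1L) {
  if (n_individuals < 1L) stop("n_individuals must be >= 1")
  if (abs(sum(hap_pool$freq) - 1) > 1e-9) stop("pool probabilities must sum to 1")
  if (any(hap_pool$freq < 0)) stop("pool probabilities must be non-negative")
  if (anyDuplicated(hap_pool$haplotype)) stop("duplicate haplotype in pool")
  L <- nrow(panel)
  if (any(nchar(hap_pool$haplotype) != L)) {
    stop("haplotype strings must have one allele per panel locus")
  }
  for (j in seq_len(L)) {
    a <- substr(hap_pool$haplotype, j, j)
    ok <- a %in% c(panel$allele_ref[j], panel$allele_alt[j])
    if (!all(ok)) {
      stop("haplotype ", hap_pool$haplotype[!ok][1L],
           " uses an allele not defined at ", panel$locus_id[j])
    }
  }
  if (any(trait_params$sd <= 0)) stop("residual SD must be > 0")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (!is.null(trait_effects)) {
    need <- c("trait", "locus", "class", "shift")
    if (!all(need %in% names(trait_effects))) {
      stop("trait_effects must have columns ", paste(need, collapse = ", "))
    }
    if (!all(trait_effects$trait %in% trait_params$trait)) {
      stop("unknown trait in trait_effects")
    }
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 hap_pool = hap_pool, panel = panel,
                 trait_effects = trait_effects, trait_params = trait_params,
                 n_age_classes = as.integer(n_age_classes),
                 n_sires = as.integer(n_sires),
                 age_effect_sd = age_effect_sd,
                 sire_effect_sd = sire_effect_sd,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw a synthetic genotyped population from the haplotype pool
#'
#' Each individual receives two independent haplotype draws from the pool
#' (random mating, so Hardy-Weinberg proportions hold at pool level by
#' construction); its unphased genotype is the unordered per-locus allele
#' pair. The true phase is retained for oracle tests. Seeded runs are
#' bit-reproducible.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_population`: `genotypes` (a
#'   [genotype_matrix()]), `diplotypes` (data.frame `individual_id`, `hap1`,
#'   `hap2`, `pair_label` with the true phase), `config`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  pool <- config$hap_pool
  draws <- base::sample.int(nrow(pool), 2L * n, replace = TRUE, prob = pool$freq)
  h1 <- pool$haplotype[draws[seq_len(n)]]
  h2 <- pool$haplotype[draws[n + seq_len(n)]]
  L <- nrow(config$panel)
  calls <- matrix(NA_character_, n, L)
  for (j in seq_len(L)) {
    calls[, j] <- paste0(substr(h1, j, j), substr(h2, j, j))
  }
  if (config$missing_rate > 0) {
    calls[stats::runif(n * L) < config$missing_rate] <- NA_character_
  }
  ids <- sprintf("ind_%03d", seq_len(n))
  pair_label <- ifelse(h1 <= h2, paste(h1, h2, sep = "/"),
                       paste(h2, h1, sep = "/"))
  structure(list(
    genotypes = genotype_matrix(calls, config$panel, ids),
    diplotypes = data.frame(individual_id = ids, hap1 = pmin(h1, h2),
                            hap2 = pmax(h1, h2), pair_label = pair_label,
                            stringsAsFactors = FALSE),
    config = config
  ), class = "sim_population")
}

#' Simulate trait records for a synthetic population
#'
#' Generates the seven body-conformation traits under the additive
#' fixed-effects structure the association model assumes:
#' \deqn{y = baseline + class\ effect + age\ effect + sire\ effect + e}
#' with age classes and sires assigned uniformly at random, level effects
#' drawn once from centered Gaussians, and iid Gaussian residuals. Every
#' realized effect is recorded for parameter-recovery tests.
#'
#' @param pop A [generate_population()] result.
#' @param config A [sim_config()]; defaults to the one stored in `pop`.
#' @return A [trait_table()] with attribute `true_effects` (list with
#'   `age_effects`, `sire_effects`, `trait_effects`).
#' @export
simulate_traits <- function(pop, config = pop$config) {
  stopifnot(inherits(pop, "sim_population"))
  set.seed(config$seed + 1L)
  n <- config$n_individuals
  age <- paste0("age", base::sample.int(config$n_age_classes, n, replace = TRUE))
  sire <- paste0("sire", base::sample.int(config$n_sires, n, replace = TRUE))
  age_eff <- stats::setNames(
    stats::rnorm(config$n_age_classes, 0, config$age_effect_sd),
    paste0("age", seq_len(config$n_age_classes)))
  sire_eff <- stats::setNames(
    stats::rnorm(config$n_sires, 0, config$sire_effect_sd),
    paste0("sire", seq_len(config$n_sires)))
  df <- data.frame(individual_id = pop$diplotypes$individual_id,
                   age = age, sire = sire, stringsAsFactors = FALSE)
  # true genotypes from the retained phase (unaffected by missing-call masking)
  calls <- matrix(NA_character_, n, nrow(config$panel))
  for (j in seq_len(nrow(config$panel))) {
    a1 <- substr(pop$diplotypes$hap1, j, j)
    a2 <- substr(pop$diplotypes$hap2, j, j)
    ref <- config$panel$allele_ref[j]; alt <- config$panel$allele_alt[j]
    n_ref <- (a1 == ref) + (a2 == ref)
    calls[, j] <- ifelse(n_ref == 2L, paste0(ref, ref),
                         ifelse(n_ref == 1L, paste0(ref, alt),
                                paste0(alt, alt)))
  }
  for (r in seq_len(nrow(config$trait_params))) {
    tr <- config$trait_params$trait[r]
    y <- config$trait_params$baseline[r] + age_eff[age] + sire_eff[sire] +
      stats::rnorm(n, 0, config$trait_params$sd[r])
    eff <- config$trait_effects
    if (!is.null(eff)) {
      eff_tr <- eff[eff$trait == tr, , drop = FALSE]
      for (e in seq_len(nrow(eff_tr))) {
        if (is.na(eff_tr$locus[e])) {
          parts <- strsplit(eff_tr$class[e], "/", fixed = TRUE)[[1L]]
          if (length(parts) != 2L ||
              !all(parts %in% config$hap_pool$haplotype)) {
            stop("unknown diplotype class in trait_effects: ", eff_tr$class[e])
          }
          hit <- pop$diplotypes$pair_label == eff_tr$class[e]
        } else {
          jj <- match(eff_tr$locus[e], config$panel$locus_id)
          if (is.na(jj)) stop("unknown locus in trait_effects: ", eff_tr$locus[e])
          geno_ok <- c(paste0(config$panel$allele_ref[jj], config$panel$allele_ref[jj]),
                       paste0(config$panel$allele_ref[jj], config$panel$allele_alt[jj]),
                       paste0(config$panel$allele_alt[jj], config$panel$allele_alt[jj]))
          if (!eff_tr$class[e] %in% geno_ok) {
            stop("unknown genotype class in trait_effects: ", eff_tr$class[e],
                 " at ", eff_tr$locus[e])
          }
          hit <- !is.na(calls[, jj]) & calls[, jj] == eff_tr$class[e]
        }
        y[hit] <- y[hit] + eff_tr$shift[e]
      }
    }
    # body measurements are physical lengths: floor at 1 cm (the Gaussian
    # tail below that is ~4 sd out for the smallest trait, so the truncation
    # is essentially never active)
    df[[tr]] <- pmax(y, 1)
  }
  out <- trait_table(df)
  attr(out, "true_effects") <- list(age_effects = age_eff,
                                    sire_effects = sire_eff,
                                    trait_effects = config$trait_effects)
  out
}

#' Simulate a complete herd dataset (genotypes + traits)
#'
#' Convenience wrapper: [generate_population()] then [simulate_traits()],
#' returned as a [herd_data()] with the true diplotypes attached.
#'
#' @param config A [sim_config()].
#' @return A [herd_data()] with extra element `true_diplotypes`.
#' @export
simulate_herd <- function(config = sim_config()) {
  pop <- generate_population(config)
  traits <- simulate_traits(pop)
  herd <- herd_data(pop$genotypes, traits)
  herd$true_diplotypes <- pop$diplotypes
  herd$config <- config
  herd
}
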