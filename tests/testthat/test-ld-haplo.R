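test_that("EM equals direct gene counting when phase is unambiguous", {
  # at most one heterozygous locus per individual: no phase ambiguity
  codes <- rbind(c(2, 2), c(2, 1), c(1, 2), c(0, 0), c(2, 0), c(0, 2))
  gm <- gm_from_codes(codes)
  hs <- em_haplotype_frequencies(gm, n_restarts = 1L)
  expect_true(hs$converged)
  expect_lte(hs$n_iter, 3L)
  # direct gamete counting: each individual's two gametes are known
  # rows: (2,2)->CT+CT, (2,1)->CT+CC, (1,2)->CT+AT, (0,0)->AC+AC,
  #       (2,0)->CC+CC, (0,2)->AT+AT  (alleles: locus1 C/A, locus2 T/C)
  direct <- c(CT = 0, CC = 0, AT = 0, AC = 0)
  pairs <- list(c("CT", "CT"), c("CT", "CC"), c("CT", "AT"),
                c("AC", "AC"), c("CC", "CC"), c("AT", "AT"))
  for (p in pairs) for (g in p) direct[g] <- direct[g] + 1
  direct <- direct / sum(direct)
  expect_equal(hs$freqs[names(direct)[direct > 0]],
               direct[direct > 0], tolerance = 1e-9)
})

test_that("two-locus EM finds the coupling optimum of the classic mixture", {
  # 4 x AABB + 4 x aabb + 2 x AaBb must converge to f(AB) = f(ab) = 0.5
  codes <- rbind(matrix(rep(c(2, 2), 4), ncol = 2, byrow = TRUE),
                 matrix(rep(c(0, 0), 4), ncol = 2, byrow = TRUE),
                 matrix(rep(c(1, 1), 2), ncol = 2, byrow = TRUE))
  gm <- gm_from_codes(codes)
  hs <- em_haplotype_frequencies(gm, seed = 9L)
  f <- sort(hs$freqs, decreasing = TRUE)
  expect_equal(unname(f[c("CT", "AC")]), c(0.5, 0.5), tolerance = 1e-4)
  expect_lt(sum(f) - f["CT"] - f["AC"], 1e-4)
  # brute-force likelihood confirms the maximum
  bf <- brute_force_hap_freqs(gm)
  expect_equal(hs$loglik, bf$loglik, tolerance = 1e-6)
})

test_that("EM log-likelihood is non-decreasing at every iteration", {
  for (seed in c(1L, 5L, 9L)) {
    gm <- random_gm(30L, 3L, seed = seed)
    hs <- em_haplotype_frequencies(gm, seed = seed)
    expect_true(all(diff(hs$loglik_trace) > -1e-9))
    expect_true(hs$converged)
  }
})

test_that("EM matches brute-force simplex maximization on small instances", {
  instances <- list(
    random_gm(10L, 2L, seed = 21L),
    random_gm(12L, 2L, seed = 22L),
    random_gm(10L, 3L, seed = 23L),
    random_gm(12L, 3L, seed = 24L)
  )
  for (gm in instances) {
    hs <- em_haplotype_frequencies(gm, tol = 1e-12, n_restarts = 8L, seed = 2L)
    bf <- brute_force_hap_freqs(gm)
    expect_equal(hs$loglik, bf$loglik, tolerance = 1e-5)
    common <- intersect(names(bf$freqs), names(hs$freqs))
    f_em <- stats::setNames(rep(0, length(bf$freqs)), names(bf$freqs))
    f_em[common] <- hs$freqs[common]
    expect_equal(unname(f_em), unname(bf$freqs), tolerance = 1e-4)
  }
})

test_that("non-convergence is reported, never silent", {
  gm <- random_gm(40L, 3L, seed = 31L)
  hs <- em_haplotype_frequencies(gm, max_iter = 2L, n_restarts = 1L)
  expect_false(hs$converged)
  expect_error(em_haplotype_frequencies(
    genotype_matrix(matrix(NA_character_, 2L, 2L), tiny_panel(2L))),
    "complete")
})

test_that("LD statistics match closed-form hand computations", {
  ld <- ld_from_haplotypes(c(0.4, 0.1, 0.1, 0.4))
  expect_equal(ld$D, 0.15, tolerance = 1e-15)
  expect_equal(ld$D_prime, 0.6, tolerance = 1e-12)
  expect_equal(ld$r2, 0.36, tolerance = 1e-12)

  coupled <- ld_from_haplotypes(c(0.5, 0, 0, 0.5))
  expect_equal(coupled$D, 0.25)
  expect_equal(coupled$D_prime, 1)
  expect_equal(coupled$r2, 1)

  eq <- ld_from_haplotypes(c(0.35 * 0.6, 0.35 * 0.4, 0.65 * 0.6, 0.65 * 0.4))
  expect_equal(eq$D, 0, tolerance = 1e-15)
  expect_equal(eq$D_prime, 0)
  expect_equal(eq$r2, 0, tolerance = 1e-15)

  expect_error(ld_from_haplotypes(c(0.6, 0.4, 0, 0)), "monomorphic")
})

test_that("D' and r2 are invariant to allele relabeling at either locus", {
  set.seed(404)
  for (i in 1:50) {
    f <- rgamma(4, 1); f <- f / sum(f)
    pA <- f[1] + f[2]; pB <- f[1] + f[3]
    if (pA %in% c(0, 1) || pB %in% c(0, 1)) next
    base <- ld_from_haplotypes(f)
    swap_a <- ld_from_haplotypes(f[c(3, 4, 1, 2)])
    swap_b <- ld_from_haplotypes(f[c(2, 1, 4, 3)])
    both <- ld_from_haplotypes(f[c(4, 3, 2, 1)])
    for (alt in list(swap_a, swap_b, both)) {
      expect_equal(alt$D_prime, base$D_prime, tolerance = 1e-12)
      expect_equal(alt$r2, base$r2, tolerance = 1e-12)
    }
  }
})

test_that("ld_matrix covers all pairs, uses pairwise-complete cases, flags strong LD", {
  herd <- simulate_herd(sim_config(seed = 13L, missing_rate = 0.05))
  ld <- ld_matrix(herd$genotypes)
  expect_equal(nrow(ld), 10L)
  expect_true(all(ld$D_prime >= 0 & ld$D_prime <= 1 + 1e-9))
  expect_true(all(ld$r2 >= 0 & ld$r2 <= 1 + 1e-9))
  # single pair: mean equals the pair value
  two <- subset_genotypes(herd$genotypes, loci = 1:2)
  ld2 <- ld_matrix(two)
  expect_equal(nrow(ld2), 1L)
  expect_equal(attr(ld2, "mean_r2"), ld2$r2[1])
})

test_that("published LD table re-summarizes to the published mean and strong pairs", {
  ld <- ld_means(gdf8_published_ld())
  expect_equal(attr(ld, "mean_r2"), 0.329, tolerance = 1e-12)
  strong <- ld[ld$strong, c("locus_a", "locus_b")]
  expect_equal(paste(strong$locus_a, strong$locus_b),
               c("g.5070C>A g.5076T>C", "g.5070C>A g.5148A>C",
                 "g.5076T>C g.5148A>C"))
})

test_that("haplotype filtering preserves mass accounting and is identity at 0", {
  gm <- random_gm(60L, 3L, seed = 15L)
  hs <- em_haplotype_frequencies(gm)
  f0 <- filter_haplotypes(hs, 0)
  expect_equal(f0$table, hs$table)
  expect_equal(f0$n_discarded, 0L)
  f5 <- filter_haplotypes(hs, 0.05)
  expect_true(all(f5$table$freq >= 0.05))
  expect_equal(sum(f5$table$freq) + f5$discarded_mass, sum(hs$table$freq),
               tolerance = 1e-12)
  expect_equal(sum(hs$table$freq), 1, tolerance = 1e-8)
  expect_error(filter_haplotypes(hs, 1), "min_freq")
})

test_that("five-haplotype pool yields five retained haplotypes at the 5% floor", {
  herd <- simulate_herd(sim_config(seed = 2L))
  hs <- em_haplotype_frequencies(herd$genotypes, seed = 2L)
  hf <- filter_haplotypes(hs, 0.05)
  expect_setequal(
    intersect(hf$table$haplotype, gdf8_haplotype_pool()$haplotype),
    hf$table$haplotype
  )
  expect_gte(nrow(hf$table), 3L)
})

test_that("homozygous individuals get a unique diplotype with posterior 1", {
  codes <- rbind(c(2, 2, 2), c(0, 0, 0), c(2, 0, 2))
  gm <- gm_from_codes(codes)
  hs <- em_haplotype_frequencies(gm)
  dip <- assign_diplotypes(gm, hs, min_class_freq = 0)
  expect_equal(dip$posterior, rep(1, 3))
  expect_equal(dip$hap1, dip$hap2)
  expect_equal(dip$hap1[1], "CTG")
})

test_that("diplotype assignment is deterministic under posterior ties", {
  # two double heterozygotes only: both phase pairs equally likely
  codes <- rbind(c(1, 1), c(1, 1))
  gm <- gm_from_codes(codes)
  hs <- em_haplotype_frequencies(gm, seed = 1L)
  d1 <- assign_diplotypes(gm, hs)
  d2 <- assign_diplotypes(gm, hs)
  expect_identical(d1$pair_label, d2$pair_label)
  expect_equal(length(unique(d1$pair_label)), 1L)
})

test_that("individuals incompatible with retained haplotypes are flagged, not lost", {
  # population dominated by CT/AC; one AT-TT-carrying individual forces a
  # rare haplotype below the floor
  codes <- rbind(matrix(rep(c(2, 2), 20), ncol = 2, byrow = TRUE),
                 matrix(rep(c(0, 0), 20), ncol = 2, byrow = TRUE),
                 c(0, 2))
  gm <- gm_from_codes(codes)
  hs <- em_haplotype_frequencies(gm)
  hf <- filter_haplotypes(hs, 0.05)
  dip <- assign_diplotypes(gm, hf, min_class_freq = 0)
  odd <- dip[dip$class_label == "AATT", ]
  expect_true(all(odd$flagged))
  expect_false(any(dip$class_label != "AATT" & dip$flagged))
})

test_that("simulated common diplotype classes surface among the most frequent", {
  herd <- simulate_herd(sim_config(seed = 3L))
  hs <- em_haplotype_frequencies(herd$genotypes, seed = 3L)
  dip <- assign_diplotypes(gm = herd$genotypes, hs = filter_haplotypes(hs))
  tab <- attr(dip, "class_table")
  # the five most common pool pairs map to genotype-string classes that must
  # rank among the top classes by frequency
  panel <- gdf8_panel()
  class_of_pair <- function(h1, h2) {
    paste(vapply(seq_len(nrow(panel)), function(j) {
      a <- c(substr(h1, j, j), substr(h2, j, j))
      nr <- sum(a == panel$allele_ref[j])
      if (nr == 2L) paste0(panel$allele_ref[j], panel$allele_ref[j])
      else if (nr == 1L) paste0(panel$allele_ref[j], panel$allele_alt[j])
      else paste0(panel$allele_alt[j], panel$allele_alt[j])
    }, ""), collapse = "")
  }
  exp_classes <- c(class_of_pair("CACTA", "GAACC"), class_of_pair("CACTA", "GGCTA"),
                   class_of_pair("GAACC", "GAACC"), class_of_pair("GGCTA", "GGCTA"),
                   class_of_pair("CACTA", "CACTA"))
  # under the pool the five classes have expected ranks 1-6 (expected
  # frequencies 0.150/0.148/0.099/0.057/0.055 among ~30 classes); top 8
  # tolerates binomial rank noise at n = 380
  top <- tab$class_label[seq_len(8L)]  # table is sorted by descending frequency
  expect_true(all(exp_classes %in% top))
})
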