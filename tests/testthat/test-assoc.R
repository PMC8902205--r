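make_oneway <- function(k = 3L, n_per = 10L, shifts = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(shifts)) shifts <- seq_len(k)
  data.frame(
    class = rep(paste0("g", seq_len(k)), each = n_per),
    age = "a1", sire = "s1",
    y = rep(shifts, each = n_per) + rnorm(k * n_per),
    stringsAsFactors = FALSE
  )
}

test_that("bonferroni adjustment follows the definition and its bounds", {
  expect_equal(pairwise_bonferroni(c(0.01, 0.02, 0.04), m = 3),
               c(0.03, 0.06, 0.12))
  expect_equal(pairwise_bonferroni(c(0, 1), m = 2), c(0, 1))
  expect_error(pairwise_bonferroni(c(0.1, 0.2), m = 1), "smaller")
  expect_error(pairwise_bonferroni(c(-0.1), m = 1), "\\[0, 1\\]")
  set.seed(7)
  p <- runif(100)
  adj <- pairwise_bonferroni(p, m = 100)
  expect_true(all(adj >= p))
  # order-preserving (ties allowed where the cap at 1 binds)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("with constant covariates the fit reduces to one-way ANOVA", {
  df <- make_oneway(k = 3L, n_per = 12L, seed = 2L)
  res <- fit_trait_model(df, "y")
  # LS-means equal arithmetic class means
  expect_equal(res$classes$lsmean, res$classes$mean, tolerance = 1e-10)
  ref <- anova(lm(y ~ class, data = df))
  expect_equal(res$f_statistic, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(res$p_value, ref$`Pr(>F)`[1], tolerance = 1e-12)
})

test_that("permuting individual order changes no reported statistic", {
  herd <- simulate_herd(sim_config(n_individuals = 120L, seed = 8L))
  df <- as.data.frame(herd$traits)
  df$class <- herd$genotypes$calls[match(df$individual_id,
                                         herd$genotypes$individual_ids), 3]
  a <- fit_trait_model(df, "AGR")
  set.seed(99)
  b <- fit_trait_model(df[sample.int(nrow(df)), ], "AGR")
  expect_equal(a$f_statistic, b$f_statistic, tolerance = 1e-10)
  expect_equal(a$classes, b$classes, tolerance = 1e-9)
  expect_equal(a$pairwise$p_adj, b$pairwise$p_adj, tolerance = 1e-9)
})

test_that("rank-deficient designs error naming the aliased columns", {
  df <- make_oneway(k = 2L, n_per = 6L, seed = 3L)
  df$sire <- ifelse(df$class == "g1", "s1", "s2")  # sire confounded with class
  expect_error(fit_trait_model(df, "y"), "aliased|rank-deficient")
})

test_that("degenerate class structures are refused", {
  df <- make_oneway(k = 1L, n_per = 6L, seed = 4L)
  expect_error(fit_trait_model(df, "y"), ">= 2 classes")
  df2 <- make_oneway(k = 2L, n_per = 6L, seed = 4L)
  df2 <- df2[c(1:6, 7), ]  # second class has a single observation
  expect_error(fit_trait_model(df2, "y"), ">= 2 classes")
})

test_that("grouping letters follow adjusted pairwise significance", {
  df <- make_oneway(k = 3L, n_per = 30L, shifts = c(0, 0.1, 6), seed = 5L)
  res <- fit_trait_model(df, "y")
  cls <- res$classes
  lg3 <- cls$letters[cls$class == "g3"]
  expect_false(lg3 %in% cls$letters[cls$class != "g3"])
  expect_true(any(grepl(substr(cls$letters[cls$class == "g1"], 1, 1),
                        cls$letters[cls$class == "g2"])))
  # letters consistent with adjusted significance at alpha
  for (r in seq_len(nrow(res$pairwise))) {
    l1 <- cls$letters[cls$class == res$pairwise$class_1[r]]
    l2 <- cls$letters[cls$class == res$pairwise$class_2[r]]
    share <- length(intersect(strsplit(l1, "")[[1]], strsplit(l2, "")[[1]])) > 0
    if (res$pairwise$p_adj[r] < res$alpha) {
      expect_false(share)
    } else {
      expect_true(share)
    }
  }
})

test_that("alpha boundaries collapse or split the letter groups", {
  # alpha -> 0: nothing significant, single shared letter
  res0 <- fit_trait_model(make_oneway(k = 3L, n_per = 20L,
                                      shifts = c(0, 0.1, 0.2), seed = 6L),
                          "y", alpha = 1e-12)
  expect_equal(unique(res0$classes$letters), "a")
  # alpha -> 1: every pair "significant", all letters distinct
  res1 <- fit_trait_model(make_oneway(k = 3L, n_per = 20L,
                                      shifts = c(0, 3, 6), seed = 6L),
                          "y", alpha = 1 - 1e-12)
  expect_equal(anyDuplicated(res1$classes$letters), 0L)
})

test_that("a simulated +8 cm AGR genotype effect is recovered within its 95% CI", {
  eff <- data.frame(trait = "AGR", locus = "g.5070C>A", class = "AA",
                    shift = 8, stringsAsFactors = FALSE)
  tp <- default_trait_params()
  tp$sd[tp$trait == "AGR"] <- 6  # recovery scenario: 8 cm shift over SD 6
  cfg <- sim_config(trait_effects = eff, trait_params = tp, seed = 12L)
  herd <- simulate_herd(cfg)
  df <- as.data.frame(herd$traits)
  df$class <- herd$genotypes$calls[match(df$individual_id,
                                         herd$genotypes$individual_ids), 3]
  res <- fit_trait_model(df, "AGR")
  expect_lt(res$p_value, 0.05)
  pw <- res$pairwise
  row <- pw[(pw$class_1 == "AA" & pw$class_2 == "CC") |
              (pw$class_1 == "CC" & pw$class_2 == "AA"), ]
  est <- abs(row$estimate)
  expect_lt(abs(est - 8), 1.96 * row$se)
  expect_lt(row$p_adj, 0.05)
})

test_that("association_report covers markers x traits and flags failed cells", {
  herd <- simulate_herd(sim_config(n_individuals = 150L, seed = 14L))
  hs <- em_haplotype_frequencies(herd$genotypes, seed = 14L)
  dip <- assign_diplotypes(herd$genotypes, filter_haplotypes(hs))
  rep <- association_report(herd, diplotypes = dip)
  expect_equal(nrow(rep$overall), (5L + 1L) * 7L)
  expect_equal(sum(rep$overall$marker != "diplotype"), 35L)
  expect_true(all(rep$overall$p_value >= 0 & rep$overall$p_value <= 1,
                  na.rm = TRUE))
})

test_that("a diplotype class simulated with the largest effects tops the LS-means", {
  pool <- default_hap_pool()
  eff <- do.call(rbind, lapply(c("WH", "HH", "HG", "AGR", "PBW"),
                               function(tr) data.frame(
                                 trait = tr, locus = NA_character_,
                                 class = "CACTA/CACTA", shift = 6,
                                 stringsAsFactors = FALSE)))
  herd <- simulate_herd(sim_config(trait_effects = eff, seed = 16L))
  hs <- em_haplotype_frequencies(herd$genotypes, seed = 16L)
  dip <- assign_diplotypes(herd$genotypes, filter_haplotypes(hs))
  rep <- association_report(herd, diplotypes = dip,
                            traits = c("WH", "HH", "HG", "AGR", "PBW"))
  target <- paste(rep("CACTA", 2L), collapse = "/")
  target_class <- unique(dip$class_label[dip$pair_label == target])
  for (tr in c("WH", "HH", "HG", "AGR", "PBW")) {
    res <- rep$results[["diplotype"]][[tr]]
    expect_s3_class(res, "assoc_result")
    best <- res$classes$class[which.max(res$classes$lsmean)]
    expect_equal(best, target_class)
  }
})
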