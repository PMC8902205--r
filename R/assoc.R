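#' Bonferroni adjustment for a family of pairwise p-values
#'
#' The plain single-step correction: `adjusted = min(1, m * p)`, with `m` the
#' family size (all pairwise class contrasts within one trait-by-marker
#' analysis). Order-preserving by construction.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @param m Family size; defaults to `length(p)` and must be at least that.
#' @return Adjusted p-values, same length as `p`.
#' @examples
#' pairwise_bonferroni(c(0.01, 0.02, 0.04), m = 3)
#' @export
pairwise_bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (m < 1) stop("family size m must be >= 1")
  if (m < length(p)) stop("family size m (", m, ") smaller than number of tests (",
                          length(p), ")")
  pmin(1, m * p)
}

# Compact letter display by insert-and-absorb over the graph whose edges join
# classes NOT significantly different at alpha. Classes are processed in
# descending LS-mean order; each class joins every existing letter group it is
# non-significant with all members of, else founds a new group. Deterministic.
assign_group_letters <- function(class_names, means, sig_pairs, alpha = 0.05) {
  k <- length(class_names)
  if (k == 1L) return(stats::setNames("a", class_names))
  is_sig <- matrix(FALSE, k, k, dimnames = list(class_names, class_names))
  for (r in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs$class_1[r]; b <- sig_pairs$class_2[r]
    s <- isTRUE(sig_pairs$p_adj[r] < alpha)
    is_sig[a, b] <- s; is_sig[b, a] <- s
  }
  ord <- order(-means, class_names)
  groups <- list()
  for (i in ord) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (!any(is_sig[i, groups[[g]]])) {
        groups[[g]] <- c(groups[[g]], i)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- i
  }
  letters_out <- stats::setNames(rep("", k), class_names)
  for (g in seq_along(groups)) {
    lab <- letters[(g - 1L) %% 26L + 1L]
    if (g > 26L) lab <- paste0(lab, (g - 1L) %/% 26L)
    for (i in groups[[g]]) {
      letters_out[i] <- paste0(letters_out[i], lab)
    }
  }
  # letters within a class sorted for stable rendering
  vapply(letters_out, function(s) paste(sort(strsplit(s, "")[[1L]]),
                                        collapse = ""), "")
}

#' Fit the fixed-effects trait model for one marker and one trait
#'
#' Ordinary least squares on the additive fixed-effects design
#' \deqn{y_{ijk} = \mu + g_i + a_j + s_k + e_{ijk}} where \eqn{g_i} is the
#' genotype or diplotype class, \eqn{a_j} the age class and \eqn{s_k} the
#' sire, both fitted as categorical fixed factors. The overall class effect
#' is tested by the partial F-test of the class term against the
#' covariate-only model; least-squares means (predicted class means averaged
#' over the covariate levels) come from the `emmeans` package; all pairwise
#' class contrasts are Bonferroni-adjusted over the
#' \eqn{k(k-1)/2}-contrast family and summarized as grouping letters.
#'
#' @param data Data.frame with the class column, the trait column, and the
#'   covariate columns. Complete cases on those columns are used; classes
#'   with fewer than 2 observations are dropped (with a note).
#' @param trait Name of the trait column.
#' @param class_column Name of the class column (default `"class"`).
#' @param covariates Covariate column names (default `c("age", "sire")`);
#'   use `character(0)` for a one-way analysis.
#' @param alpha Significance level for the grouping letters (default 0.05).
#' @param lsmeans If `FALSE`, skip the LS-mean/pairwise machinery and return
#'   only the overall F-test (used for large calibration sweeps).
#' @return An object of class `assoc_result`: list with `trait`, `classes`
#'   (data.frame: class, n, mean, se, lsmean, lsmean_se, letters),
#'   `f_statistic`, `df`, `p_value`, `pairwise` (class_1, class_2, estimate,
#'   p_raw, p_adj), `dropped_classes`, `model`.
#' @export
fit_trait_model <- function(data, trait, class_column = "class",
                            covariates = c("age", "sire"), alpha = 0.05,
                            lsmeans = TRUE) {
  need <- c(class_column, trait, covariates)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- data[stats::complete.cases(data[, need, drop = FALSE]), need,
             drop = FALSE]
  names(df)[1L] <- "class"
  df$class <- as.character(df$class)
  cnt <- table(df$class)
  dropped <- names(cnt)[cnt < 2L]
  if (length(dropped)) df <- df[!df$class %in% dropped, , drop = FALSE]
  if (length(unique(df$class)) < 2L) {
    stop("association model needs >= 2 classes with >= 2 observations each ",
         "for trait ", trait)
  }
  df$class <- factor(df$class)
  for (cv in covariates) df[[cv]] <- factor(df[[cv]])
  covariates <- covariates[vapply(covariates,
                                  function(cv) nlevels(df[[cv]]) > 1L, TRUE)]

  rhs <- paste(c("class", covariates), collapse = " + ")
  fml <- stats::as.formula(paste0("`", trait, "` ~ ", rhs))
  fit <- stats::lm(fml, data = df)
  if (anyNA(stats::coef(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design for trait ", trait, ": aliased coefficient(s) ",
         paste(aliased, collapse = ", "))
  }
  fml0 <- stats::as.formula(paste0("`", trait, "` ~ ",
                                   if (length(covariates))
                                     paste(covariates, collapse = " + ") else "1"))
  fit0 <- stats::lm(fml0, data = df)
  ftest <- stats::anova(fit0, fit)
  f_stat <- ftest$F[2L]; p_overall <- ftest$`Pr(>F)`[2L]
  fdf <- c(ftest$Df[2L], ftest$Res.Df[2L])

  raw <- stats::aggregate(df[[trait]], list(class = df$class),
                          function(v) c(n = length(v), mean = mean(v),
                                        se = stats::sd(v) / sqrt(length(v))))
  classes <- data.frame(class = as.character(raw$class),
                        n = as.integer(raw$x[, "n"]),
                        mean = raw$x[, "mean"], se = raw$x[, "se"],
                        stringsAsFactors = FALSE)

  pairwise <- NULL
  if (lsmeans) {
    emm <- emmeans::emmeans(fit, "class")
    es <- as.data.frame(emm)
    m <- match(classes$class, as.character(es$class))
    classes$lsmean <- es$emmean[m]
    classes$lsmean_se <- es$SE[m]
    ct <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                          adjust = "none"))
    sides <- strsplit(as.character(ct$contrast), " - ", fixed = TRUE)
    k <- nlevels(df$class)
    pairwise <- data.frame(
      class_1 = vapply(sides, `[`, "", 1L),
      class_2 = vapply(sides, `[`, "", 2L),
      estimate = ct$estimate, se = ct$SE, p_raw = ct$p.value,
      stringsAsFactors = FALSE
    )
    pairwise$p_adj <- pairwise_bonferroni(pairwise$p_raw, m = k * (k - 1L) / 2L)
    classes$letters <- assign_group_letters(classes$class, classes$lsmean,
                                            pairwise, alpha)
  }
  structure(list(trait = trait, classes = classes, f_statistic = f_stat,
                 df = fdf, p_value = p_overall, pairwise = pairwise,
                 dropped_classes = dropped, alpha = alpha, model = fit),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat("assoc_result for trait", x$trait, "\n")
  cls <- x$classes
  for (col in intersect(c("mean", "se", "lsmean", "lsmean_se"), names(cls))) {
    cls[[col]] <- round(cls[[col]], 2)
  }
  print.data.frame(cls, row.names = FALSE)
  cat(sprintf("overall F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1L], x$df[2L], x$f_statistic, x$p_value))
  if (length(x$dropped_classes)) {
    cat("dropped classes (<2 obs):", paste(x$dropped_classes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Full association report across markers, diplotype classes and traits
#'
#' Runs [fit_trait_model()] for every trait against (a) the genotype classes
#' of each panel SNP and (b) the retained diplotype classes, assembling a
#' long results table. Cells whose model cannot be fitted (e.g. a
#' rank-deficient design) are reported as flagged rows, not errors.
#'
#' @param herd A [herd_data()] with traits.
#' @param diplotypes Optional [assign_diplotypes()] result; its retained
#'   classes become the `"diplotype"` marker.
#' @param traits Trait columns to analyze (default all of [trait_names()]
#'   with any data).
#' @param covariates Covariates for the linear model (default age + sire).
#' @param alpha Significance level for grouping letters.
#' @return A list of class `assoc_report`: `results` (named nested list
#'   marker -> trait -> `assoc_result` or condition), `table` (long
#'   data.frame of class rows), `overall` (data.frame of marker x trait
#'   overall p-values).
#' @export
association_report <- function(herd, diplotypes = NULL, traits = NULL,
                               covariates = c("age", "sire"), alpha = 0.05) {
  if (is.null(herd$traits)) stop("association requires a trait table")
  tt <- as.data.frame(herd$traits)
  if (is.null(traits)) {
    traits <- trait_names()[vapply(trait_names(),
                                   function(tr) any(!is.na(tt[[tr]])), TRUE)]
  }
  gm <- herd$genotypes
  joined <- herd$joined_ids
  base <- tt[match(joined, tt$individual_id), , drop = FALSE]

  marker_frames <- list()
  for (j in seq_len(n_loci(gm))) {
    d <- base
    d$class <- gm$calls[match(joined, gm$individual_ids), j]
    marker_frames[[gm$panel$locus_id[j]]] <- d
  }
  if (!is.null(diplotypes)) {
    dip <- diplotypes[diplotypes$retained, , drop = FALSE]
    d <- base
    d$class <- dip$class_label[match(joined, dip$individual_id)]
    marker_frames[["diplotype"]] <- d
  }

  results <- list(); long <- list(); overall <- list()
  for (mk in names(marker_frames)) {
    results[[mk]] <- list()
    for (tr in traits) {
      res <- tryCatch(
        fit_trait_model(marker_frames[[mk]], tr, covariates = covariates,
                        alpha = alpha),
        error = function(e) e
      )
      results[[mk]][[tr]] <- res
      if (inherits(res, "error")) {
        overall[[length(overall) + 1L]] <- data.frame(
          marker = mk, trait = tr, f_statistic = NA_real_,
          p_value = NA_real_, note = conditionMessage(res),
          stringsAsFactors = FALSE)
      } else {
        overall[[length(overall) + 1L]] <- data.frame(
          marker = mk, trait = tr, f_statistic = res$f_statistic,
          p_value = res$p_value, note = "", stringsAsFactors = FALSE)
        cls <- res$classes
        cls$marker <- mk; cls$trait <- tr
        long[[length(long) + 1L]] <- cls
      }
    }
  }
  structure(list(results = results,
                 table = if (length(long)) do.call(rbind, long) else NULL,
                 overall = do.call(rbind, overall), alpha = alpha),
            class = "assoc_report")
}

#' @export
print.assoc_report <- function(x, ...) {
  cat("assoc_report:", nrow(x$overall), "marker x trait analyses\n")
  ov <- x$overall
  ov$p_value <- signif(ov$p_value, 3)
  ov$f_statistic <- round(ov$f_statistic, 2)
  print.data.frame(ov, row.names = FALSE)
  invisible(x)
}
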