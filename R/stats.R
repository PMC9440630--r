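#' Assign ages to developmental stages
#'
#' Left-closed, right-open intervals `[0,3) [3,12) [12,19) [19,35) [35,60)
#' [60,Inf)` (see [age_stages()]); boundary ages such as 35 fall into the
#' older stage.
#'
#' @param age Numeric vector of ages in years (`>= 0`).
#' @return Factor with the six stage labels.
#' @export
assign_age_stage <- function(age) {
  if (any(age < 0)) stop("negative age")
  st <- age_stages()
  idx <- findInterval(age, st$lo)      # left-closed, right-open by construction
  factor(st$label[idx], levels = st$label)
}

# Student-Newman-Keuls pairwise comparisons from group summaries.
# q = |mean_i - mean_j| / sqrt(MSE/2 (1/n_i + 1/n_j)); the studentized-range
# p-value uses the number of ordered means spanned, and the step-down rule
# blocks pairs nested inside a non-significant range.
snk_pairwise <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  means <- tapply(values, group, mean)
  ns <- tapply(values, group, length)
  k <- nlevels(group)
  df_err <- length(values) - k
  mse <- sum(tapply(values, group, function(v) sum((v - mean(v))^2))) / df_err
  ord <- order(means)                  # ranks over ordered means
  rank_of <- match(seq_len(k), ord)
  pairs <- utils::combn(k, 2)
  res <- data.frame(
    group1 = levels(group)[pairs[1, ]],
    group2 = levels(group)[pairs[2, ]],
    stringsAsFactors = FALSE)
  res$span <- abs(rank_of[pairs[1, ]] - rank_of[pairs[2, ]]) + 1L
  se <- sqrt(mse / 2 * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
  res$q <- abs(means[pairs[1, ]] - means[pairs[2, ]]) / se
  res$p <- stats::ptukey(res$q, nmeans = res$span, df = df_err,
                         lower.tail = FALSE)
  # step-down blocking: a pair nested in a non-significant wider range is NS
  res$significant <- res$p < alpha
  lo_rank <- pmin(rank_of[pairs[1, ]], rank_of[pairs[2, ]])
  hi_rank <- pmax(rank_of[pairs[1, ]], rank_of[pairs[2, ]])
  for (i in order(res$span, decreasing = TRUE)) {
    if (!res$significant[i]) {
      nested <- lo_rank >= lo_rank[i] & hi_rank <= hi_rank[i]
      res$significant[nested] <- FALSE
    }
  }
  rownames(res) <- NULL
  res
}

#' Compare an outcome across groups with parametric/nonparametric fallback
#'
#' Runs per-group Shapiro-Wilk normality tests and a Levene
#' (Brown-Forsythe) variance-homogeneity test. If every group is compatible
#' with normality and variances are homogeneous (all diagnostic p >= alpha),
#' a one-way ANOVA is used with Student-Newman-Keuls pairwise comparisons;
#' otherwise the Kruskal-Wallis test with pairwise Mann-Whitney U tests
#' (unadjusted, as conventionally reported). Pairwise results are computed
#' only when the omnibus test is significant. Groups too small for a
#' normality test (n < 3) or with zero variance route to the nonparametric
#' branch.
#'
#' @param values Numeric outcome vector.
#' @param group Grouping vector (factor / character), e.g. structure or age
#'   stage.
#' @param alpha Significance threshold (default 0.05).
#' @return A list of class `"group_test_report"`: `test` ("anova" or
#'   "kruskal"), `statistic`, `p_value`, `pairwise` (data frame or `NULL`),
#'   `pairwise_method`, `diagnostics` (per-group Shapiro p, Levene p).
#' @export
compare_groups <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  sizes <- table(group)
  if (any(sizes < 2)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  shapiro_p <- vapply(levels(group), function(g) {
    v <- values[group == g]
    if (length(v) < 3 || stats::sd(v) == 0) return(0)   # cannot support normality
    tryCatch(stats::shapiro.test(v)$p.value, error = function(e) 0)
  }, numeric(1))
  levene_p <- if (any(tapply(values, group, stats::sd) == 0)) 0 else {
    lt <- car::leveneTest(values ~ group)
    lt[["Pr(>F)"]][1]
  }
  parametric <- all(shapiro_p >= alpha) && levene_p >= alpha

  if (parametric) {
    fit <- stats::aov(values ~ group)
    tab <- summary(fit)[[1]]
    stat <- tab[["F value"]][1]
    p <- tab[["Pr(>F)"]][1]
    if (is.na(p)) { stat <- 0; p <- 1 }        # zero residual + zero effect
    pw <- if (p < alpha) snk_pairwise(values, group, alpha) else NULL
    method <- "SNK"
    test <- "anova"
  } else {
    kt <- stats::kruskal.test(values, group)
    stat <- unname(kt$statistic)
    p <- kt$p.value
    pw <- NULL
    method <- "Mann-Whitney U"
    test <- "kruskal"
    if (p < alpha) {
      cmb <- utils::combn(levels(group), 2)
      pw <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                       stringsAsFactors = FALSE)
      pw$p <- vapply(seq_len(ncol(cmb)), function(i) {
        stats::wilcox.test(values[group == cmb[1, i]],
                           values[group == cmb[2, i]],
                           exact = FALSE)$p.value
      }, numeric(1))
      pw$significant <- pw$p < alpha
    }
  }
  structure(
    list(test = test, statistic = stat, p_value = p,
         pairwise = pw, pairwise_method = method,
         diagnostics = list(shapiro_p = shapiro_p, levene_p = levene_p),
         alpha = alpha, groups = levels(group), sizes = as.integer(sizes)),
    class = "group_test_report")
}

#' @export
print.group_test_report <- function(x, ...) {
  cat(sprintf("<group_test_report> %s: statistic %.4g, p = %.4g (%d groups)\n",
              x$test, x$statistic, x$p_value, length(x$groups)))
  if (!is.null(x$pairwise)) {
    cat(sprintf("pairwise (%s):\n", x$pairwise_method))
    print(x$pairwise, digits = 4)
  }
  invisible(x)
}

#' Correlate paired FTIR and Raman outcomes
#'
#' Pairs the two modalities' outcome tables by (donor, structure) and
#' reports the Pearson correlation and two-sided p-value for each of the
#' four outcomes.
#'
#' @param ftir_outcomes,raman_outcomes [cohort_outcomes()] tables of the two
#'   modalities.
#' @return Data frame `outcome`, `r`, `p`, `n`.
#' @export
pearson_outcomes <- function(ftir_outcomes, raman_outcomes) {
  key <- function(d) paste(d$donor_id, d$structure, sep = "|")
  f <- ftir_outcomes; r <- raman_outcomes
  f$key <- key(f); r$key <- key(r)
  m <- merge(f, r, by = "key", suffixes = c("_ftir", "_raman"))
  if (nrow(m) < 3) stop("need at least 3 paired samples")
  vars <- c("mineral_matrix", "carbonate_phosphate", "crystallinity",
            "collagen_maturity")
  do.call(rbind, lapply(vars, function(v) {
    x <- m[[paste0(v, "_ftir")]]
    y <- m[[paste0(v, "_raman")]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop("zero variance in outcome ", v)
    }
    ct <- stats::cor.test(x, y)
    data.frame(outcome = v, r = unname(ct$estimate), p = ct$p.value,
               n = nrow(m), stringsAsFactors = FALSE)
  }))
}

#' Stage-wise summary of an outcome table
#'
#' Mean and SD of every outcome per age stage with the omnibus p-value and
#' the branch (parametric or not) used, mirroring the usual
#' outcome-by-stage reporting layout.
#'
#' @param outcomes A [cohort_outcomes()] table of one modality.
#' @param exclude Optional data frame `structure`, `age_stage`, `outcome`
#'   of cells to drop before testing (explicit exclusion list; e.g. a cell
#'   shown to carry a structure effect).
#' @return Data frame: one row per outcome, columns `mean_<stage>`,
#'   `sd_<stage>`, `p_value`, `nonparametric`.
#' @export
stage_summary <- function(outcomes, exclude = NULL) {
  vars <- c("mineral_matrix", "carbonate_phosphate", "crystallinity",
            "collagen_maturity")
  stages <- age_stages()$label
  do.call(rbind, lapply(vars, function(v) {
    d <- outcomes
    if (!is.null(exclude)) {
      ex <- exclude[exclude$outcome == v, , drop = FALSE]
      if (nrow(ex) > 0) {
        drop_row <- interaction(d$structure, d$age_stage) %in%
          interaction(ex$structure, ex$age_stage)
        d <- d[!drop_row, , drop = FALSE]
      }
    }
    rep <- compare_groups(d[[v]], d$age_stage)
    row <- data.frame(outcome = v, stringsAsFactors = FALSE)
    for (st in stages) {
      vv <- d[[v]][d$age_stage == st]
      row[[paste0("mean_", st)]] <- mean(vv)
      row[[paste0("sd_", st)]] <- stats::sd(vv)
    }
    row$p_value <- rep$p_value
    row$nonparametric <- rep$test == "kruskal"
    row
  }))
}
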