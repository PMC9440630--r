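test_that("age staging uses left-closed right-open six-stage intervals", {
  expect_equal(as.character(assign_age_stage(0)), "0-3")
  expect_equal(as.character(assign_age_stage(35)), "35-60")
  expect_equal(as.character(assign_age_stage(c(2.9, 3, 11.9, 12, 19, 60, 74))),
               c("0-3", "3-12", "3-12", "12-19", "19-35", ">60", ">60"))
  expect_error(assign_age_stage(-1), "negative")

  d <- make_cohort(40, 0, 74, seed = 5,
                   stage_sizes = c(8, 2, 3, 5, 17, 5))
  expect_equal(as.integer(table(assign_age_stage(d$donors$age))),
               c(8L, 2L, 3L, 5L, 17L, 5L))
})

test_that("compare_groups picks the parametric branch on clean data", {
  rep <- compare_groups(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(rep$test, "anova")
  expect_equal(rep$statistic, 0)
  expect_equal(rep$p_value, 1)
  expect_null(rep$pairwise)          # pairwise only under significance
})

test_that("degenerate variance routes to the nonparametric branch", {
  v <- c(0, 0, 0, 0, 5, 5, 5, 5) + c(rep(0, 4), 1e-9 * (1:4))
  rep <- compare_groups(v, rep(c("a", "b"), each = 4))
  expect_equal(rep$test, "kruskal")
  expect_lt(rep$p_value, 0.05)
  expect_false(is.null(rep$pairwise))
  expect_equal(rep$pairwise_method, "Mann-Whitney U")
})

test_that("a clear mean shift is detected with SNK pairwise comparisons", {
  set.seed(21)
  g <- rep(c("a", "b", "c"), each = 12)
  v <- rnorm(36, mean = rep(c(0, 0, 4), each = 12))
  rep <- compare_groups(v, g)
  expect_lt(rep$p_value, 0.01)
  if (rep$test == "anova") {
    pw <- rep$pairwise
    ac <- pw$significant[(pw$group1 == "a" & pw$group2 == "c") |
                         (pw$group1 == "c" & pw$group2 == "a")]
    ab <- pw$significant[(pw$group1 == "a" & pw$group2 == "b") |
                         (pw$group1 == "b" & pw$group2 == "a")]
    expect_true(ac)
    expect_false(ab)
  }
})

test_that("SNK conclusions do not depend on group ordering", {
  set.seed(8)
  v <- rnorm(30, rep(c(0, 1.5, 3), each = 10))
  g <- rep(c("a", "b", "c"), each = 10)
  r1 <- osteospectra:::snk_pairwise(v, g)
  perm <- c(21:30, 1:10, 11:20)
  r2 <- osteospectra:::snk_pairwise(v[perm], g[perm])
  key <- function(r) {
    k <- paste(pmin(r$group1, r$group2), pmax(r$group1, r$group2))
    r$significant[order(k)]
  }
  expect_equal(key(r1), key(r2))
})

test_that("small or missing groups raise informative errors", {
  expect_error(compare_groups(1:5, c("a", "a", "a", "a", "b")), "b")
  expect_error(compare_groups(1:3, rep("a", 3)), "2 groups")
})

test_that("type-I error stays near nominal under the fallback procedure", {
  set.seed(303)
  rej <- mean(replicate(400, {
    compare_groups(rnorm(30), rep(1:3, each = 10))$p_value < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("pearson_outcomes reports exact correlations on constructed pairs", {
  mk <- function(vals, modality) {
    data.frame(donor_id = sprintf("D%02d", seq_along(vals)), age = 1,
               structure = "diploe", modality = modality,
               mineral_matrix = vals, carbonate_phosphate = vals,
               crystallinity = rev(vals), collagen_maturity = vals + 1,
               stringsAsFactors = FALSE)
  }
  x <- c(1, 2, 3, 5, 8)
  f <- mk(x, "ftir")
  r <- mk(2 * x + 1, "raman")        # affine in x
  res <- pearson_outcomes(f, r)
  expect_equal(res$r[res$outcome == "mineral_matrix"], 1, tolerance = 1e-12)
  # crystallinity pairs rev(x) (ftir) with rev(2x+1) (raman): still r = 1;
  # anti-correlation needs construction across columns
  r2 <- mk(2 * x + 1, "raman")
  r2$collagen_maturity <- -x
  expect_equal(pearson_outcomes(f, r2)$r[4], -1, tolerance = 1e-12)

  r3 <- mk(2 * x + 1, "raman")
  r3$mineral_matrix <- rep(1, 5)
  expect_error(pearson_outcomes(f, r3), "zero variance")
})

test_that("stage summaries honour an explicit exclusion list", {
  d <- make_cohort(24, 0, 74, seed = 13)
  avgs <- cohort_raman_averages(d, seed = 13)
  tab <- cohort_outcomes(avgs)
  full <- stage_summary(tab)
  expect_equal(nrow(full), 4)
  expect_true(all(is.finite(full$p_value)))
  ex <- data.frame(structure = "lamina_interna", age_stage = "19-35",
                   outcome = "carbonate_phosphate", stringsAsFactors = FALSE)
  excl <- stage_summary(tab, exclude = ex)
  expect_equal(nrow(excl), 4)       # schema unchanged, cell dropped
})
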