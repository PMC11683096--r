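# group contrast, partial correlation, FDR, cohort summary

test_that("constant covariates reduce the contrast to a mean difference", {
  set.seed(1)
  d <- tibble::tibble(
    group = rep(c("HC", "sICH"), each = 20),
    alps = rnorm(40, rep(c(1.5, 1.2), each = 20), 0.1),
    age = 50, sex = "male", hypertension = 0L, diabetes = 0L, TIV = 1400)
  suppressMessages(res <- group_contrast(d))
  expect_equal(res$estimate,
               mean(d$alps[d$group == "sICH"]) - mean(d$alps[d$group == "HC"]),
               tolerance = 1e-12)
  # and to the pooled two-sample t-test
  tt <- t.test(alps ~ group, data = d, var.equal = TRUE)
  expect_equal(res$p.value, tt$p.value, tolerance = 1e-12)
  expect_equal(abs(res$statistic), abs(tt$statistic), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("group contrast recovers the generating ALPS difference", {
  co <- make_cohort(cohort_spec(n_per_group = 200L, seed = 31L))
  res <- group_contrast(co)
  expect_equal(res$estimate, -0.25, tolerance = 0.05)
  expect_lt(res$p.value, 1e-6)
})

test_that("rank-deficient designs are reported, not silently fitted", {
  co <- make_cohort(cohort_spec(n_per_group = 30L, seed = 2L))
  co$TIV2 <- co$TIV * 2
  expect_error(
    group_contrast(co, covariates = c("age", "TIV", "TIV2")),
    "collinear")
})

test_that("partial correlation equals its brute-force oracle", {
  set.seed(42)
  n <- 50
  d <- tibble::tibble(
    c1 = rnorm(n), c2 = rnorm(n), c3 = rnorm(n),
    x = rnorm(n) + 0.5 * c1, y = rnorm(n) - 0.3 * c2 + 0.4 * c1)
  d$y2 <- 2 * d$x + 3
  for (m in c("pearson", "spearman")) {
    got <- partial_correlation(d, "x", "y", c("c1", "c2", "c3"), method = m)
    expect_equal(got$r, oracle_partial_cor(d, "x", "y",
                                           c("c1", "c2", "c3"), m),
                 tolerance = 1e-10)
  }
  # empty covariate set reduces to the ordinary correlation
  got0 <- partial_correlation(d, "x", "y", character(), "pearson")
  ref0 <- cor.test(d$x, d$y)
  expect_equal(got0$r, unname(ref0$estimate), tolerance = 1e-12)
  expect_equal(got0$p.value, ref0$p.value, tolerance = 1e-10)
  # exact linear dependence gives r = 1
  expect_equal(partial_correlation(d, "x", "y2", c("c2"), "pearson")$r, 1,
               tolerance = 1e-12)
})

test_that("partial correlation respects its invariances", {
  set.seed(7)
  d <- tibble::tibble(a = rnorm(30), b = rnorm(30), z = rnorm(30))
  r1 <- partial_correlation(d, "a", "b", "z")$r
  expect_equal(partial_correlation(d, "b", "a", "z")$r, r1,
               tolerance = 1e-12)
  d2 <- dplyr::mutate(d, a = 3 * a - 5, z = -2 * z + 1)
  expect_equal(partial_correlation(d2, "a", "b", "z")$r, r1,
               tolerance = 1e-12)
  # Spearman is invariant to monotone transforms of x or y
  rs <- partial_correlation(d, "a", "b", "z", method = "spearman")$r
  d3 <- dplyr::mutate(d, a = exp(a))
  expect_equal(partial_correlation(d3, "a", "b", "z", "spearman")$r, rs,
               tolerance = 1e-12)
})

test_that("BH adjustment matches hand evaluation and is order-preserving", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(rep(0.04, 5)), rep(0.04, 5))
  expect_equal(fdr_adjust(0.2), 0.2)
  p <- c(0.001, 0.5, 0.02, 0.9, 0.04)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))
  expect_identical(order(adj), order(p))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the correlation table reproduces generating signs with FDR", {
  co <- make_cohort(cohort_spec(n_per_group = 300L, seed = 17L))
  tab <- alps_correlations(co)
  expect_true(all(tab$fdr_p >= tab$p.value - 1e-15))
  moca <- tab[tab$subset == "chronic" & tab$variable == "MoCA", ]
  expect_gt(moca$r, 0)
  hem <- tab[tab$subset == "acute_subacute" &
               tab$variable == "hematoma_volume", ]
  expect_lt(hem$r, 0)
})

test_that("cohort summary formats counts and percentages as printed tables do", {
  d <- tibble::tibble(
    group = c(rep("HC", 63), rep("sICH", 58)),
    poor_outcome = c(rep(FALSE, 63), rep(TRUE, 14), rep(FALSE, 44)),
    hypertension = c(rep(0L, 63), rep(1L, 50), rep(0L, 8)),
    age = rnorm(121, 54, 9))
  tab <- summarize_cohort(d, binary = c("poor_outcome", "hypertension"),
                          continuous = "age")
  expect_equal(tab$sICH[tab$variable == "poor_outcome"], "14 (24.1)")
  expect_equal(tab$sICH[tab$variable == "hypertension"], "50 (86.2)")
  expect_equal(tab$HC[tab$variable == "poor_outcome"], "0 (0.0)")
})

test_that("cohort summary picks tests by the normality rule", {
  set.seed(5)
  d <- tibble::tibble(
    group = rep(c("A", "B"), each = 50),
    normalish = rnorm(100, rep(c(0, 1), each = 50)),
    skewed = exp(rnorm(100, rep(c(0, 1), each = 50))))
  tab <- summarize_cohort(d, binary = character(),
                          continuous = c("normalish", "skewed"))
  expect_identical(tab$test[tab$variable == "normalish"], "t")
  expect_identical(tab$test[tab$variable == "skewed"], "wilcoxon")
  expect_match(tab$A[tab$variable == "normalish"], "±")
  expect_match(tab$A[tab$variable == "skewed"], "\\[")
})

test_that("propensity matching returns balanced treated/control pairs", {
  co <- make_cohort(cohort_spec(n_per_group = 100L, seed = 8L))
  m <- propensity_match(co)
  expect_true(nrow(m) %% 2 == 0)
  expect_true(all(table(m$pair_id) == 2))
  expect_true(all(tapply(m$group, m$pair_id,
                         function(g) setequal(g, c("HC", "sICH")))))
})
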