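# backward-elimination logistic model and ROC characterisation

test_that("intercept-only logistic fit matches the closed form", {
  d <- tibble::tibble(y = rep(c(1L, 0L), c(25, 75)), x = 0)
  suppressWarnings(
    fit <- fit_logistic(d, outcome = "y", candidates = "x", p_out = 0))
  b0 <- fit$reduced$estimate[fit$reduced$term == "(Intercept)"]
  expect_equal(b0, log(0.25 / 0.75), tolerance = 1e-6)
  expect_length(fit$retained, 0)
})

test_that("coefficients match a direct maximum-likelihood oracle", {
  set.seed(12)
  n <- 300
  X <- cbind(1, matrix(rnorm(n * 4), n, 4))
  colnames(X) <- c("int", paste0("v", 1:4))
  beta <- c(-0.5, 1, -0.7, 0.3, 0)
  y <- rbinom(n, 1, plogis(drop(X %*% beta)))
  d <- tibble::tibble(y = y, v1 = X[, 2], v2 = X[, 3], v3 = X[, 4],
                      v4 = X[, 5])
  fit <- fit_logistic(d, outcome = "y",
                      candidates = paste0("v", 1:4), p_out = 1.01)
  ref <- oracle_logistic(X, y)
  expect_equal(fit$full$estimate, ref, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(fit$retained, paste0("v", 1:4))   # p_out > 1 keeps all
})

test_that("backward elimination honours its threshold extremes", {
  co <- make_cohort(cohort_spec(n_per_group = 200L, seed = 37L))
  pat <- co[co$group == "sICH", ]
  suppressWarnings({
    keep_all <- fit_logistic(pat, p_out = 1.01)
    drop_all <- fit_logistic(pat, p_out = 0)
  })
  candidates <- c("age", "sex", "GCS", "hypertension", "diabetes", "MoCA",
                  "hematoma_volume", "PHE_volume", "alps")
  expect_identical(keep_all$retained, candidates)
  expect_length(keep_all$trace$removed, 0)
  expect_length(drop_all$retained, 0)
  expect_equal(nrow(drop_all$trace), length(candidates))
})

test_that("an informative ALPS slope is retained while null noise is dropped", {
  hits <- 0L; alps_kept <- 0L
  n_sim <- 40
  for (i in seq_len(n_sim)) {
    set.seed(100 + i)
    n <- 400
    alps <- rnorm(n, 1.4, 0.2)
    z1 <- rnorm(n); z2 <- rnorm(n)
    y <- rbinom(n, 1, plogis(9 - 8 * alps))
    d <- tibble::tibble(y = y, alps = alps, z1 = z1, z2 = z2)
    fit <- suppressWarnings(
      fit_logistic(d, outcome = "y", candidates = c("alps", "z1", "z2")))
    if ("alps" %in% fit$retained) alps_kept <- alps_kept + 1L
    if (identical(fit$retained, "alps")) hits <- hits + 1L
  }
  expect_gte(alps_kept / n_sim, 0.95)
  expect_gte(hits / n_sim, 0.70)
})

test_that("complete separation raises an informative error", {
  set.seed(3)
  d <- tibble::tibble(y = rep(c(0L, 1L), each = 25),
                      x = c(runif(25, 0, 1), runif(25, 1.01, 2)))
  expect_error(suppressWarnings(
    fit_logistic(d, outcome = "y", candidates = "x", p_out = 0.1)),
    "separation|converge")
})

test_that("perfectly separated scores give AUC and Youden of 1", {
  roc <- roc_analysis(c(1, 2, 3, 11, 12, 13),
                      c(0, 0, 0, 1, 1, 1), direction = ">")
  expect_equal(roc$auc, 1.0)
  expect_equal(roc$sensitivity, 1.0)
  expect_equal(roc$specificity, 1.0)
  expect_true(roc$cutoff > 3 && roc$cutoff < 11)
})

test_that("AUC equals the exhaustive pairwise count, with and without ties", {
  set.seed(33)
  for (rep in 1:5) {
    n <- sample(30:120, 1)
    scores <- round(rnorm(n), rep %% 3)   # coarser rounding induces ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    roc <- roc_analysis(scores, labels, direction = ">")
    expect_equal(roc$auc, oracle_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("Youden cutoff equals a brute-force threshold scan", {
  set.seed(44)
  for (direction in c(">", "<")) {
    scores <- round(rnorm(80), 1)
    labels <- rbinom(80, 1, 0.35)
    roc <- roc_analysis(scores, labels, direction = direction)
    ref <- oracle_youden(scores, labels, direction)
    expect_equal(roc$sensitivity + roc$specificity - 1, ref$j,
                 tolerance = 1e-12)
    expect_equal(roc$cutoff, ref$cutoff, tolerance = 1e-12)
    expect_equal(roc$sensitivity, ref$sensitivity, tolerance = 1e-12)
  }
})

test_that("AUC is invariant to monotone transforms; reversal flips it", {
  set.seed(55)
  scores <- rnorm(100); labels <- rbinom(100, 1, 0.3)
  a1 <- roc_analysis(scores, labels, direction = ">")$auc
  a2 <- roc_analysis(exp(scores), labels, direction = ">")$auc
  expect_equal(a1, a2, tolerance = 1e-12)
  a3 <- roc_analysis(scores, labels, direction = "<")$auc
  expect_equal(a3, 1 - a1, tolerance = 1e-12)
})

test_that("AUC and DeLong CI agree with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(66)
  scores <- rnorm(150); labels <- rbinom(150, 1, 0.4)
  mine <- roc_analysis(scores, labels, direction = ">")
  ref <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(mine$ci_low, ci[1], tolerance = 1e-6)
  expect_equal(mine$ci_high, ci[3], tolerance = 1e-6)
})

test_that("identical scores degrade gracefully to AUC 0.5", {
  expect_warning(
    roc <- roc_analysis(rep(1, 20), rep(c(0, 1), 10), direction = ">"),
    "identical")
  expect_equal(roc$auc, 0.5)
  expect_true(is.na(roc$ci_low))
})

test_that("null predictors give AUC near 0.5 at large n", {
  set.seed(77)
  roc <- roc_analysis(rnorm(10000), rbinom(10000, 1, 0.5), direction = ">")
  expect_equal(roc$auc, 0.5, tolerance = 0.02)
})
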