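#' Covariate-adjusted group contrast of an outcome
#'
#' Ordinary least-squares linear model `outcome ~ group + covariates`, the
#' standard way to compare the ALPS index between patients and controls
#' while correcting for confounders (age, sex, hypertension, diabetes, TIV
#' by default). Listwise deletion is applied; sex is coded 0/1
#' (female/male) if character.
#'
#' @param data cohort data frame.
#' @param outcome outcome column name (default "alps").
#' @param group group column name; must have exactly 2 levels. The contrast
#'   is the second level minus the first, levels sorted.
#' @param covariates character vector of covariate column names. Constant
#'   columns are dropped (with a message) before fitting.
#' @return A tibble with one row: `estimate`, `se`, `statistic`, `p.value`,
#'   `n`, `term`.
#' @export
group_contrast <- function(data, outcome = "alps", group = "group",
                           covariates = c("age", "sex", "hypertension",
                                          "diabetes", "TIV")) {
  df <- prepare_model_frame(data, c(outcome, group, covariates))
  assert_that(length(unique(df[[group]])) == 2,
              "group column must have exactly 2 levels")
  assert_that(min(table(df[[group]])) >= 2,
              "need at least 2 subjects per group after listwise deletion")
  df[[group]] <- factor(df[[group]])

  keep <- covariates[vapply(covariates, function(v)
    length(unique(df[[v]])) > 1, logical(1))]
  dropped <- setdiff(covariates, keep)
  if (length(dropped)) {
    message("dropping constant covariate(s): ", paste(dropped, collapse = ", "))
  }
  rhs <- paste(c(group, keep), collapse = " + ")
  fml <- as.formula(paste(outcome, "~", rhs))
  mm <- model.matrix(fml, df)
  if (qr(mm)$rank < ncol(mm)) {
    stop_glue("rank-deficient design; collinear column(s) among: ",
              paste(colnames(mm), collapse = ", "))
  }
  fit <- lm(fml, data = df)
  sm <- summary(fit)$coefficients
  term <- grep(paste0("^", group), rownames(sm), value = TRUE)[1]
  tibble::tibble(
    term = term,
    estimate = sm[term, 1],
    se = sm[term, 2],
    statistic = sm[term, 3],
    p.value = sm[term, 4],
    n = nrow(df)
  )
}

prepare_model_frame <- function(data, cols) {
  missing_cols <- setdiff(cols, names(data))
  assert_that(!length(missing_cols),
              paste("missing column(s):", paste(missing_cols, collapse = ", ")))
  df <- as.data.frame(data)[, cols, drop = FALSE]
  if ("sex" %in% cols && is.character(df$sex)) {
    df$sex <- as.integer(df$sex == "male")
  }
  df[complete.cases(df), , drop = FALSE]
}

#' Partial correlation with covariate adjustment
#'
#' Pearson: `x` and `y` are each residualised on the covariates by least
#' squares and the residuals correlated; the p-value uses a t reference
#' with `n - k - 2` degrees of freedom (`k` covariates). Spearman: `x` and
#' `y` are rank-transformed first, then the same residualisation is applied
#' with the covariates untransformed.
#'
#' @param data data frame.
#' @param x,y column names of the two variables.
#' @param covariates character vector of covariate columns (may be empty).
#' @param method "pearson" or "spearman".
#' @return A tibble: `x`, `y`, `method`, `r`, `p.value`, `n`, `df`,
#'   `covariates`.
#' @export
partial_correlation <- function(data, x, y, covariates = character(),
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  df <- prepare_model_frame(data, c(x, y, covariates))
  n <- nrow(df); k <- length(covariates)
  assert_that(n > k + 2, "need n > #covariates + 2 complete cases")

  xv <- df[[x]]; yv <- df[[y]]
  if (method == "spearman") {
    xv <- rank(xv); yv <- rank(yv)
  }
  if (k > 0) {
    Z <- model.matrix(~ ., df[, covariates, drop = FALSE])
    rx <- resid(lm.fit(Z, xv))
    ry <- resid(lm.fit(Z, yv))
  } else {
    rx <- xv - mean(xv); ry <- yv - mean(yv)
  }
  assert_that(sd(rx) > 0 && sd(ry) > 0,
              "zero-variance residuals: partial correlation undefined")
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  r <- max(-1, min(1, r))          # guard rounding past the boundary
  dfree <- n - k - 2
  p <- if (abs(r) == 1) 0 else {
    tstat <- r * sqrt(dfree / (1 - r^2))
    2 * pt(-abs(tstat), dfree)
  }
  tibble::tibble(x = x, y = y, method = method, r = r, p.value = p,
                 n = n, df = dfree,
                 covariates = paste(covariates, collapse = ","))
}

#' @importFrom stats lm.fit
NULL

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values `p(i) * m / i` with cumulative-minimum
#' enforcement, capped at 1 (the standard BH procedure, delegated to
#' [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as input.
#' @export
fdr_adjust <- function(p) {
  assert_that(all(p >= 0 & p <= 1, na.rm = TRUE),
              "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Run the ALPS partial-correlation table with FDR correction
#'
#' Correlates the ALPS index against MoCA (Spearman) and against haematoma
#' and perihaematomal-oedema volumes (Pearson), with age, sex and TIV as
#' covariates, within each requested patient subset; then applies BH-FDR
#' across each subset's family.
#'
#' @param data cohort data frame.
#' @param subsets named list of row filters (logical vectors or functions
#'   of the data); default: all patients, acute-subacute, chronic.
#' @return Tibble with `subset`, `variable`, `method`, `r`, `p.value`,
#'   `fdr_p`, `n`.
#' @export
alps_correlations <- function(data,
                              subsets = NULL) {
  if (is.null(subsets)) {
    subsets <- list(
      sICH = data$group == "sICH",
      acute_subacute = data$group == "sICH" & data$stage == "acute_subacute",
      chronic = data$group == "sICH" & data$stage == "chronic"
    )
  }
  plan <- list(
    list(var = "MoCA", method = "spearman"),
    list(var = "hematoma_volume", method = "pearson"),
    list(var = "PHE_volume", method = "pearson")
  )
  out <- purrr::map_dfr(names(subsets), function(sn) {
    sub <- data[subsets[[sn]], , drop = FALSE]
    rows <- purrr::map_dfr(plan, function(pl) {
      if (!pl$var %in% names(sub)) return(NULL)
      ok <- sum(complete.cases(sub[, c("alps", pl$var, "age", "sex", "TIV")]))
      if (ok <= 5) return(NULL)
      pc <- partial_correlation(sub, "alps", pl$var,
                                covariates = c("age", "sex", "TIV"),
                                method = pl$method)
      tibble::tibble(subset = sn, variable = pl$var, method = pl$method,
                     r = pc$r, p.value = pc$p.value, n = pc$n)
    })
    if (nrow(rows)) rows$fdr_p <- fdr_adjust(rows$p.value)
    rows
  })
  out
}

#' Table-1-style cohort summary
#'
#' Per-group descriptive statistics with between-group tests: binary
#' variables as "count (percent)" with a chi-squared test; continuous
#' variables as "mean +/- SD" with a t-test when both groups pass
#' Shapiro-Wilk normality (p > 0.05), otherwise "median \[IQR\]" with a
#' Wilcoxon rank-sum test. Percentages are printed to 1 decimal.
#'
#' @param data cohort data frame.
#' @param group grouping column (2 levels).
#' @param binary,continuous character vectors of column names; sensible
#'   defaults for the standard cohort layout.
#' @param welch use Welch's t-test instead of pooled.
#' @return Tibble: `variable`, one formatted column per group, `test`,
#'   `p.value`.
#' @export
summarize_cohort <- function(data, group = "group",
                             binary = intersect(
                               c("sex", "hypertension", "diabetes",
                                 "poor_outcome"), names(data)),
                             continuous = intersect(
                               c("age", "GCS", "TIV", "GM_percent", "MoCA",
                                 "hematoma_volume", "PHE_volume",
                                 "disease_duration", "alps"), names(data)),
                             welch = FALSE) {
  assert_that(nrow(data) > 0, "empty table")
  g <- factor(data[[group]])
  lv <- levels(g)
  assert_that(length(lv) == 2, "group column must have exactly 2 levels")

  fmt_count <- function(x) {
    x <- x[!is.na(x)]
    if (is.character(x)) x <- x == "male"          # sex convention
    k <- sum(x == 1 | x == TRUE)
    sprintf("%d (%s)", k, formatC(100 * k / max(length(x), 1),
                                  format = "f", digits = 1))
  }
  rows <- list()
  for (v in binary) {
    x <- data[[v]]
    vals <- lapply(lv, function(l) fmt_count(x[g == l]))
    xb <- if (is.character(x)) as.integer(x == "male") else as.integer(x)
    p <- tryCatch({
      tab <- table(xb, g)
      if (all(dim(tab) == c(2, 2)))
        suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
      else NA_real_
    }, error = function(e) NA_real_)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      variable = v, !!lv[1] := vals[[1]], !!lv[2] := vals[[2]],
      test = "chi-squared", p.value = p)
  }
  for (v in continuous) {
    x <- data[[v]]
    x1 <- x[g == lv[1] & !is.na(x)]; x2 <- x[g == lv[2] & !is.na(x)]
    normal <- function(z) {
      if (length(z) < 3 || length(z) > 5000 || sd(z) == 0) return(FALSE)
      shapiro.test(z)$p.value > 0.05
    }
    both_norm <- length(x1) >= 3 && length(x2) >= 3 &&
      normal(x1) && normal(x2)
    fmt <- function(z) {
      if (!length(z)) return("-")
      if (both_norm) sprintf("%.1f ± %.1f", mean(z), sd(z))
      else sprintf("%.1f [%.1f;%.1f]", median(z),
                   quantile(z, 0.25), quantile(z, 0.75))
    }
    p <- if (length(x1) >= 2 && length(x2) >= 2) {
      if (both_norm) t.test(x1, x2, var.equal = !welch)$p.value
      else suppressWarnings(wilcox.test(x1, x2)$p.value)
    } else NA_real_
    rows[[length(rows) + 1L]] <- tibble::tibble(
      variable = v, !!lv[1] := fmt(x1), !!lv[2] := fmt(x2),
      test = if (both_norm) if (welch) "welch-t" else "t" else "wilcoxon",
      p.value = p)
  }
  dplyr::bind_rows(rows)
}

#' @importFrom rlang :=
NULL

#' Optional 1:1 propensity-score matching utility
#'
#' Logistic propensity model of group membership on the covariates,
#' greedy 1:1 nearest-neighbour matching on the logit with a caliper of
#' `caliper_sd` standard deviations of the logit (0.2 by default). Provided
#' as a sensitivity utility alongside the covariate-adjusted contrast.
#'
#' @param data cohort data frame.
#' @param group group column (2 levels; second sorted level is "treated").
#' @param covariates covariate columns for the propensity model.
#' @param caliper_sd caliper width in SDs of the propensity logit.
#' @return The matched subset of `data` with a `pair_id` column.
#' @export
propensity_match <- function(data, group = "group",
                             covariates = c("age", "sex", "hypertension",
                                            "diabetes", "TIV"),
                             caliper_sd = 0.2) {
  df <- prepare_model_frame(data, c(group, covariates))
  df$.row <- as.integer(rownames(df))
  gfac <- factor(df[[group]])
  treated <- gfac == levels(gfac)[2]
  fml <- as.formula(paste0("treated ~ ",
                           paste(covariates, collapse = " + ")))
  fit <- glm(fml, data = cbind(df, treated = treated), family = binomial())
  lg <- predict(fit, type = "link")
  cal <- caliper_sd * sd(lg)
  t_idx <- which(treated); c_idx <- which(!treated)
  used <- logical(length(c_idx)); pairs <- list()
  for (i in t_idx[order(lg[t_idx], decreasing = TRUE)]) {
    d <- abs(lg[c_idx] - lg[i]); d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= cal) {
      used[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- c(i, c_idx[j])
    }
  }
  if (!length(pairs)) return(data[0, , drop = FALSE])
  keep <- do.call(rbind, pairs)
  out <- data[df$.row[as.vector(t(keep))], , drop = FALSE]
  out$pair_id <- rep(seq_len(nrow(keep)), each = 2)
  out
}
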