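#' Multivariable logistic model with backward elimination
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()]) of a
#' binary outcome on a candidate predictor set, followed by backward
#' elimination: at each step the predictor with the largest Wald p-value
#' at or above `p_out` is removed and the model refitted, until every
#' remaining predictor has p < `p_out`. A likelihood-ratio criterion is
#' available via `criterion = "lrt"`. Deterministic.
#'
#' @param data data frame.
#' @param outcome binary outcome column (logical or 0/1); default
#'   `poor_outcome` (90-day mRS 3-6).
#' @param candidates candidate predictor columns.
#' @param p_out removal threshold on the elimination p-value (default 0.10).
#' @param criterion "wald" (default) or "lrt".
#' @return A `logistic_fit`: list with `full` and `reduced` coefficient
#'   tibbles (`term`, `estimate`, `se`, `statistic`, `p.value`),
#'   `retained`, `trace` tibble (order removed, p at removal),
#'   `loglik`, `n`, `n_events`, and the reduced `model` object.
#' @export
fit_logistic <- function(data, outcome = "poor_outcome",
                         candidates = c("age", "sex", "GCS", "hypertension",
                                        "diabetes", "MoCA",
                                        "hematoma_volume", "PHE_volume",
                                        "alps"),
                         p_out = 0.10, criterion = c("wald", "lrt")) {
  criterion <- match.arg(criterion)
  df <- prepare_model_frame(data, c(outcome, candidates))
  yv <- df[[outcome]]
  if (is.logical(yv)) yv <- as.integer(yv)
  df[[outcome]] <- yv
  assert_that(length(unique(yv)) == 2, "both outcome classes must be present")
  n <- nrow(df)
  assert_that(n > length(candidates),
              "need more observations than candidate predictors")
  epv <- min(sum(yv == 1), sum(yv == 0)) / length(candidates)
  if (epv < 5) {
    warning(sprintf("events per variable = %.1f (< 5); estimates may be unstable",
                    epv))
  }

  fit_one <- function(preds) {
    fml <- as.formula(paste(outcome, "~",
                            if (length(preds)) paste(preds, collapse = " + ")
                            else "1"))
    fit <- suppressWarnings(glm(fml, data = df, family = binomial(),
                                control = list(epsilon = 1e-8, maxit = 100)))
    if (!fit$converged) stop_glue("logistic fit did not converge")
    if (sqrt(sum(coef(fit)^2, na.rm = TRUE)) > 50) {
      stop_glue("apparent complete separation (diverging coefficients); ",
                "consider a penalized fit")
    }
    fit
  }
  coef_table <- function(fit) {
    sm <- summary(fit)$coefficients
    tibble::tibble(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                   statistic = sm[, 3], p.value = sm[, 4])
  }
  drop_p <- function(fit, preds) {
    # elimination p per predictor (a character covariate contributes its
    # dummy's Wald p; lrt uses the single-term deviance test)
    if (criterion == "wald") {
      tb <- coef_table(fit)
      vapply(preds, function(v) {
        pv <- tb$p.value[grepl(paste0("^", v), tb$term)]
        if (!length(pv) || anyNA(pv)) 1 else max(pv)  # aliased: drop first
      }, numeric(1))
    } else {
      vapply(preds, function(v) {
        red <- fit_one(setdiff(preds, v))
        stat <- red$deviance - fit$deviance
        df_d <- red$df.residual - fit$df.residual
        stats::pchisq(stat, df_d, lower.tail = FALSE)
      }, numeric(1))
    }
  }

  preds <- candidates
  full_fit <- fit_one(preds)
  trace <- list()
  fit <- full_fit
  while (length(preds)) {
    ps <- drop_p(fit, preds)
    worst <- which.max(ps)
    if (ps[worst] < p_out) break
    trace[[length(trace) + 1L]] <- tibble::tibble(
      step = length(trace) + 1L, removed = preds[worst],
      p_at_removal = unname(ps[worst]))
    preds <- preds[-worst]
    fit <- fit_one(preds)
  }

  structure(list(
    full = coef_table(full_fit),
    reduced = coef_table(fit),
    retained = preds,
    trace = if (length(trace)) dplyr::bind_rows(trace) else
      tibble::tibble(step = integer(), removed = character(),
                     p_at_removal = numeric()),
    loglik = as.numeric(stats::logLik(fit)),
    n = n, n_events = sum(yv == 1),
    p_out = p_out, criterion = criterion,
    model = fit
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d (%d events), retained: %s\n",
              x$n, x$n_events,
              if (length(x$retained)) paste(x$retained, collapse = ", ")
              else "(intercept only)"))
  print(x$reduced)
  invisible(x)
}

#' ROC analysis with DeLong CI and Youden cutoff
#'
#' Builds the empirical ROC curve of a continuous score against binary
#' labels and reports: AUC by the trapezoidal rule (identical to the
#' tie-corrected Mann-Whitney probability); a DeLong 95\% confidence
#' interval; and the optimal cutoff maximising Youden's
#' J = sensitivity + specificity - 1 over midpoints between consecutive
#' sorted unique scores, ties broken toward higher sensitivity.
#'
#' `direction = "auto"` (default) orients the score so that AUC >= 0.5;
#' `">"` declares that higher scores indicate the positive class, `"<"`
#' that lower scores do (the ALPS index is lower in poor-outcome patients,
#' so `"<"` is its natural orientation).
#'
#' @param scores numeric vector.
#' @param labels binary vector (logical or 0/1); 1/TRUE = positive class.
#' @param direction "auto", ">" or "<".
#' @param conf confidence level for the DeLong interval.
#' @return A `roc_result`: list with `auc`, `ci_low`, `ci_high`, `cutoff`,
#'   `sensitivity`, `specificity`, `direction`, `n_pos`, `n_neg`, and a
#'   `curve` tibble of (threshold, sensitivity, specificity) plus the
#'   per-threshold table `thresholds`.
#' @export
roc_analysis <- function(scores, labels, direction = c("auto", ">", "<"),
                         conf = 0.95) {
  direction <- match.arg(direction)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- as.integer(labels[ok])
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  assert_that(length(pos) > 0 && length(neg) > 0,
              "both label classes must be present")

  degenerate <- length(unique(scores)) == 1
  if (degenerate) {
    warning("all scores identical: AUC = 0.5, CI undefined")
  }

  orient_auc <- function(s_pos, s_neg) {
    # Mann-Whitney with tie correction, computed via midranks
    r <- rank(c(s_pos, s_neg))
    np <- length(s_pos); nn <- length(s_neg)
    (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  }
  auc_raw <- orient_auc(pos, neg)
  if (direction == "auto") direction <- if (auc_raw >= 0.5) ">" else "<"
  s <- if (direction == ">") scores else -scores
  pos_s <- s[labels == 1]; neg_s <- s[labels == 0]
  auc <- orient_auc(pos_s, neg_s)

  # DeLong variance via placement values
  ci <- c(NA_real_, NA_real_)
  if (!degenerate) {
    v10 <- vapply(pos_s, function(x)
      mean((x > neg_s) + 0.5 * (x == neg_s)), numeric(1))
    v01 <- vapply(neg_s, function(y)
      mean((pos_s > y) + 0.5 * (pos_s == y)), numeric(1))
    var_auc <- stats::var(v10) / length(pos_s) +
      stats::var(v01) / length(neg_s)
    z <- qnorm(1 - (1 - conf) / 2)
    ci <- pmin(pmax(auc + c(-1, 1) * z * sqrt(var_auc), 0), 1)
  }

  # threshold scan over midpoints of sorted unique oriented scores;
  # predicted positive when oriented score > threshold
  u <- sort(unique(s))
  thr <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  thr <- c(min(u) - 1, thr)                    # all-positive end included
  sens <- vapply(thr, function(t) mean(pos_s > t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg_s <= t), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  pick <- best[order(-sens[best])][1]          # tie toward higher sensitivity
  cutoff_oriented <- thr[pick]
  cutoff <- if (direction == ">") cutoff_oriented else -cutoff_oriented

  thresholds <- tibble::tibble(
    threshold = if (direction == ">") thr else -thr,
    sensitivity = sens, specificity = spec, youden_j = j)

  structure(list(
    auc = auc, ci_low = ci[1], ci_high = ci[2],
    cutoff = cutoff, sensitivity = sens[pick], specificity = spec[pick],
    direction = direction, conf = conf,
    n_pos = length(pos), n_neg = length(neg),
    degenerate = degenerate,
    thresholds = thresholds
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (%g%% CI %.3f-%.3f), direction '%s'\n",
              x$auc, 100 * x$conf, x$ci_low, x$ci_high, x$direction))
  cat(sprintf("  cutoff %.4g: sensitivity %.3f, specificity %.3f (n+ = %d, n- = %d)\n",
              x$cutoff, x$sensitivity, x$specificity, x$n_pos, x$n_neg))
  invisible(x)
}
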