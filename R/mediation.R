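#' Single-mediator bootstrap mediation analysis
#'
#' Product-of-coefficients mediation of an exposure effect through one
#' mediator (by default the ALPS -> grey-matter-proportion -> MoCA chain),
#' with percentile bootstrap confidence intervals for the indirect effect.
#' Three least-squares fits on the complete cases give the paths:
#' `M ~ X + covariates` (path a), `Y ~ X + M + covariates` (paths b and
#' c'), `Y ~ X + covariates` (total path c). The indirect effect is `a*b`;
#' in this linear system `c = c' + a*b` to machine precision. The bootstrap
#' resamples subjects with replacement; degenerate resamples (zero variance
#' in X or M) are redrawn and counted.
#'
#' @param data data frame.
#' @param x,m,y exposure, mediator and outcome column names.
#' @param covariates covariate column names (default age, sex, TIV).
#' @param n_boot bootstrap replicates (>= 1000; 5000 is the conventional
#'   reporting standard).
#' @param seed RNG seed; identical seeds give identical intervals.
#' @param conf confidence level (default 0.95).
#' @param ci "percentile" (default) or "bca".
#' @return A `mediation_result`: list with `paths` tibble (a, b, c,
#'   c_prime, indirect with the bootstrap CI on the indirect effect),
#'   `n`, `n_boot`, `seed`, `n_degenerate`, `boot_indirect` (the replicate
#'   estimates), `significant` (CI excludes 0).
#' @export
mediate <- function(data, x = "alps", m = "GM_percent", y = "MoCA",
                    covariates = c("age", "sex", "TIV"),
                    n_boot = 5000, seed = 1L, conf = 0.95,
                    ci = c("percentile", "bca")) {
  ci <- match.arg(ci)
  assert_that(n_boot >= 1000, "n_boot must be at least 1000")
  df <- prepare_model_frame(data, c(x, m, y, covariates))
  n <- nrow(df)
  assert_that(n >= 10, "need at least 10 complete cases")

  Z <- if (length(covariates)) {
    model.matrix(~ ., df[, covariates, drop = FALSE])
  } else {
    matrix(1, n, 1)
  }
  xv <- df[[x]]; mv <- df[[m]]; yv <- df[[y]]
  assert_that(sd(xv) > 0 && sd(mv) > 0,
              "exposure and mediator must vary across subjects")

  fit_paths <- function(idx) {
    Xa <- cbind(Z[idx, , drop = FALSE], x = xv[idx])
    Xb <- cbind(Xa, m = mv[idx])
    ca <- .lm.fit(Xa, mv[idx])$coefficients
    cb <- .lm.fit(Xb, yv[idx])$coefficients
    cc <- .lm.fit(Xa, yv[idx])$coefficients
    k <- ncol(Z)
    c(a = ca[k + 1], b = cb[k + 2], c_prime = cb[k + 1], c = cc[k + 1])
  }
  est <- fit_paths(seq_len(n))
  indirect <- unname(est["a"] * est["b"])

  set.seed(seed)
  boot <- numeric(n_boot)
  n_degen <- 0L
  for (i in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (sd(xv[idx]) > 0 && sd(mv[idx]) > 0) break
      n_degen <- n_degen + 1L
    }
    p <- fit_paths(idx)
    boot[i] <- p["a"] * p["b"]
  }
  alpha <- 1 - conf
  if (ci == "percentile") {
    ci_bounds <- unname(quantile(boot, c(alpha / 2, 1 - alpha / 2),
                                 type = 6))
  } else {
    # bias-corrected and accelerated (jackknife acceleration)
    z0 <- qnorm(mean(boot < indirect))
    jack <- vapply(seq_len(n), function(i) {
      p <- fit_paths(setdiff(seq_len(n), i))
      unname(p["a"] * p["b"])
    }, numeric(1))
    jm <- mean(jack)
    acc <- sum((jm - jack)^3) / (6 * sum((jm - jack)^2)^1.5)
    zq <- qnorm(c(alpha / 2, 1 - alpha / 2))
    adj <- pnorm(z0 + (z0 + zq) / (1 - acc * (z0 + zq)))
    ci_bounds <- unname(quantile(boot, adj, type = 6))
  }

  paths <- tibble::tibble(
    term = c("a", "b", "c", "c_prime", "indirect"),
    estimate = c(unname(est["a"]), unname(est["b"]), unname(est["c"]),
                 unname(est["c_prime"]), indirect),
    ci_low = c(NA, NA, NA, NA, ci_bounds[1]),
    ci_high = c(NA, NA, NA, NA, ci_bounds[2])
  )
  structure(list(
    paths = paths, x = x, m = m, y = y,
    covariates = covariates, n = n, n_boot = n_boot, seed = seed,
    ci_type = ci, conf = conf, n_degenerate = n_degen,
    boot_indirect = boot,
    indirect = indirect,
    ci_low = ci_bounds[1], ci_high = ci_bounds[2],
    significant = ci_bounds[1] > 0 || ci_bounds[2] < 0
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> %s -> %s -> %s (n = %d)\n",
              x$x, x$m, x$y, x$n))
  cat(sprintf("  indirect = %.4f, %g%% bootstrap CI [%.4f, %.4f] (%s, B = %d)%s\n",
              x$indirect, 100 * x$conf, x$ci_low, x$ci_high, x$ci_type,
              x$n_boot, if (x$significant) " *" else ""))
  print(x$paths)
  invisible(x)
}
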