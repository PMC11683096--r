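#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an ALPS result into one row per hemisphere
#' @param x an `alps_result`.
#' @param ... unused.
#' @return A tibble of per-hemisphere directional diffusivities and indices.
#' @exportS3Method generics::tidy
tidy.alps_result <- function(x, ...) x$diffusivities

#' One-row summary of an ALPS result
#' @param x an `alps_result`.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.alps_result <- function(x, ...) {
  tibble::tibble(alps_left = x$alps_left, alps_right = x$alps_right,
                 alps_mean = x$alps_mean, alps_reported = x$alps_reported,
                 lesion_side = x$lesion_side)
}

#' Tidy a mediation result into one row per path
#' @param x a `mediation_result`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.mediation_result <- function(x, ...) x$paths

#' One-row summary of a mediation result
#' @param x a `mediation_result`.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.mediation_result <- function(x, ...) {
  tibble::tibble(indirect = x$indirect, ci_low = x$ci_low,
                 ci_high = x$ci_high, significant = x$significant,
                 n = x$n, n_boot = x$n_boot, ci_type = x$ci_type)
}

#' Tidy a logistic fit (reduced model by default)
#' @param x a `logistic_fit`.
#' @param which "reduced" (post-elimination) or "full".
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.logistic_fit <- function(x, which = c("reduced", "full"), ...) {
  which <- match.arg(which)
  x[[which]]
}

#' One-row summary of a logistic fit
#' @param x a `logistic_fit`.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events,
                 n_retained = length(x$retained),
                 loglik = x$loglik, p_out = x$p_out,
                 criterion = x$criterion)
}

#' Tidy a ROC result into its threshold table
#' @param x a `roc_result`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.roc_result <- function(x, ...) x$thresholds

#' One-row summary of a ROC result
#' @param x a `roc_result`.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
                 cutoff = x$cutoff, sensitivity = x$sensitivity,
                 specificity = x$specificity, direction = x$direction,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}
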