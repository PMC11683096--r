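#' @importFrom stats lm coef resid pnorm pt qnorm sd median quantile rnorm
#'   runif rbinom binomial glm p.adjust shapiro.test t.test wilcox.test
#'   chisq.test cor model.matrix complete.cases setNames predict plogis
#'   as.formula .lm.fit
#' @importFrom rlang .data
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

expit <- function(x) plogis(x)

stop_glue <- function(...) stop(paste0(...), call. = FALSE)

#' @keywords internal
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_glue(msg)
  invisible(TRUE)
}

# deterministic near-uniform points on the unit sphere (Fibonacci lattice),
# optionally jittered by a seeded rotation so repeated tables differ
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  golden <- pi * (1 + sqrt(5))
  theta <- golden * i
  cbind(
    x = sin(phi) * cos(theta),
    y = sin(phi) * sin(theta),
    z = cos(phi)
  )
}
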