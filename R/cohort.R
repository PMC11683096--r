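#' Specification for a synthetic clinical cohort
#'
#' Defines the generating model for a two-arm cohort (healthy controls vs
#' spontaneous intracerebral haemorrhage patients) in which the ALPS index
#' drives grey-matter proportion, cognition, haematoma volume and 90-day
#' outcome with known coefficients, so that every downstream statistical
#' stage can be checked by parameter recovery.
#'
#' Generating model, per subject:
#' \itemize{
#'   \item ALPS ~ Normal(group mean, `alps_sd`);
#'   \item GM\% = intercept + `path_a` * ALPS + e, e ~ N(0, `noise_sd_gm`);
#'   \item MoCA = intercept + `path_b` * GM\% + `path_c_prime` * ALPS + e,
#'     e ~ N(0, `noise_sd_moca`), then clipped to \[0, 30\] and rounded;
#'   \item poor outcome (mRS > 2) ~ Bernoulli(expit(`gamma0` + `gamma1` * ALPS));
#'   \item haematoma volume (acute-subacute patients only) =
#'     intercept + `beta_hematoma` * ALPS + e, floored at 0.
#' }
#' Intercepts are derived from the target means `gm_mean`, `moca_mean`,
#' `hematoma_mean` so the simulated columns sit on a clinically plausible
#' scale. Age, sex, TIV, hypertension, diabetes and GCS are drawn
#' independently of ALPS.
#'
#' @param n_per_group subjects per arm.
#' @param alps_mean_hc,alps_mean_sich,alps_sd ALPS distribution per group.
#' @param path_a ALPS -> GM\% slope (percentage points per ALPS unit).
#' @param path_b GM\% -> MoCA slope (points per percentage point).
#' @param path_c_prime direct ALPS -> MoCA slope.
#' @param gamma0,gamma1 logistic intercept/slope for P(mRS > 2 | ALPS).
#' @param beta_hematoma slope of haematoma volume (mL) on ALPS.
#' @param gm_mean,moca_mean,hematoma_mean target column means used to derive
#'   intercepts.
#' @param noise_sd_gm,noise_sd_moca,noise_sd_hematoma residual SDs.
#' @param prop_acute proportion of patients in the acute-subacute stage
#'   (disease duration <= 21 days).
#' @param seed RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 60L,
                        alps_mean_hc = 1.5,
                        alps_mean_sich = 1.25,
                        alps_sd = 0.2,
                        path_a = 0.4,
                        path_b = 8,
                        path_c_prime = 5,
                        gamma0 = 9,
                        gamma1 = -8,
                        beta_hematoma = -20,
                        gm_mean = 44,
                        moca_mean = 26,
                        hematoma_mean = 13,
                        noise_sd_gm = 1,
                        noise_sd_moca = 2,
                        noise_sd_hematoma = 5,
                        prop_acute = 0.4,
                        seed = 1L) {
  spec <- as.list(environment())
  spec$n_per_group <- as.integer(n_per_group)
  spec$seed <- as.integer(seed)
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    assert_that(n_per_group >= 3, "n_per_group must be at least 3")
    assert_that(alps_sd > 0, "alps_sd must be positive")
    assert_that(noise_sd_gm > 0 && noise_sd_moca > 0 && noise_sd_hematoma > 0,
                "all noise SDs must be positive")
    assert_that(prop_acute >= 0 && prop_acute <= 1,
                "prop_acute must lie in [0, 1]")
  })
  invisible(spec)
}

#' Simulate a cohort table with known effect structure
#'
#' Draws one row per subject under the generating model documented in
#' [cohort_spec()]. Fully reproducible given the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return A tibble with columns `subject_id`, `group` ("HC"/"sICH"),
#'   `stage`, `age`, `sex`, `hypertension`, `diabetes`, `GCS`, `TIV`,
#'   `GM_percent`, `MoCA`, `hematoma_volume`, `PHE_volume`,
#'   `disease_duration`, `mRS`, `poor_outcome`, `lesion_side`, `alps`.
#' @export
make_cohort <- function(spec = cohort_spec()) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_per_group
  ntot <- 2L * n
  group <- rep(c("HC", "sICH"), each = n)
  is_pat <- group == "sICH"

  alps <- rnorm(ntot, ifelse(is_pat, spec$alps_mean_sich, spec$alps_mean_hc),
                spec$alps_sd)
  alps <- pmax(alps, 0.05)

  mean_alps <- (spec$alps_mean_hc + spec$alps_mean_sich) / 2
  gm_int <- spec$gm_mean - spec$path_a * mean_alps
  gm <- gm_int + spec$path_a * alps + rnorm(ntot, 0, spec$noise_sd_gm)
  gm <- pmin(pmax(gm, 1), 99)

  moca_int <- spec$moca_mean - spec$path_b * spec$gm_mean -
    spec$path_c_prime * mean_alps
  moca <- moca_int + spec$path_b * gm + spec$path_c_prime * alps +
    rnorm(ntot, 0, spec$noise_sd_moca)
  moca <- as.integer(round(pmin(pmax(moca, 0), 30)))

  poor <- rbinom(ntot, 1, expit(spec$gamma0 + spec$gamma1 * alps)) == 1
  poor[!is_pat] <- FALSE
  mrs <- integer(ntot)
  mrs[is_pat] <- ifelse(poor[is_pat],
                        sample(3:6, sum(is_pat), replace = TRUE),
                        sample(0:2, sum(is_pat), replace = TRUE))

  stage <- rep("none", ntot)
  stage[is_pat] <- ifelse(runif(sum(is_pat)) < spec$prop_acute,
                          "acute_subacute", "chronic")
  dur <- rep(NA_real_, ntot)
  acute <- stage == "acute_subacute"
  dur[acute] <- sample(1:21, sum(acute), replace = TRUE)
  dur[stage == "chronic"] <- sample(22:900, sum(stage == "chronic"),
                                    replace = TRUE)

  hem_int <- spec$hematoma_mean - spec$beta_hematoma * spec$alps_mean_sich
  hem <- rep(NA_real_, ntot)
  hem[acute] <- pmax(hem_int + spec$beta_hematoma * alps[acute] +
                       rnorm(sum(acute), 0, spec$noise_sd_hematoma), 0)
  phe <- rep(NA_real_, ntot)
  phe[acute] <- pmax(1.5 * hem[acute] +
                       rnorm(sum(acute), 0, spec$noise_sd_hematoma), 0)

  tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(ntot)),
    group = group,
    stage = stage,
    age = round(rnorm(ntot, 54, 10)),
    sex = sample(c("male", "female"), ntot, replace = TRUE,
                 prob = c(0.58, 0.42)),
    hypertension = as.integer(runif(ntot) <
                                ifelse(is_pat, 0.86, 0.27)),
    diabetes = as.integer(runif(ntot) < ifelse(is_pat, 0.17, 0.08)),
    GCS = ifelse(is_pat, pmin(pmax(round(rnorm(ntot, 12, 2)), 7L), 15L),
                 NA_integer_),
    TIV = rnorm(ntot, 1450, 120),
    GM_percent = gm,
    MoCA = ifelse(is_pat, moca, NA_integer_),
    hematoma_volume = hem,
    PHE_volume = phe,
    disease_duration = dur,
    mRS = ifelse(is_pat, mrs, NA_integer_),
    poor_outcome = ifelse(is_pat, poor, NA),
    lesion_side = ifelse(is_pat, sample(c("left", "right"), ntot,
                                        replace = TRUE), "none"),
    alps = alps
  )
}

#' Write / read a cohort table as CSV
#'
#' @param cohort tibble from [make_cohort()] (or the same column layout).
#' @param path CSV path.
#' @return `path` invisibly (write); a tibble (read).
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
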