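#' Configuration for a full reproducible run
#'
#' Collects the parameter blocks for every stage (phantom simulation,
#' cohort simulation, ROI search, mediation bootstrap, elimination
#' threshold) plus seeds and the output directory. Stages are gated by
#' `stages`: any subset of "imaging" (phantom -> tensor -> ALPS) and
#' "cohort" (simulation -> statistics).
#'
#' @param out_dir output directory.
#' @param seed master seed, recorded in every output's provenance block.
#' @param stages character subset of c("imaging", "cohort").
#' @param phantom a [phantom_spec()] (imaging stage).
#' @param n_phantom_per_group phantoms per arm in the imaging demo.
#' @param sich_factor glymphatic factor used for simulated patients.
#' @param cohort a [cohort_spec()] (cohort stage).
#' @param search_radius_mm ROI peak-search radius.
#' @param n_boot mediation bootstrap replicates.
#' @param p_out backward-elimination threshold.
#' @param log_level "INFO" or "QUIET".
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L,
                       stages = c("imaging", "cohort"),
                       phantom = phantom_spec(seed = seed),
                       n_phantom_per_group = 2L,
                       sich_factor = 0.7,
                       cohort = cohort_spec(seed = seed),
                       search_radius_mm = 10,
                       n_boot = 1000,
                       p_out = 0.10,
                       log_level = c("INFO", "QUIET")) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = stages, phantom = phantom,
                 n_phantom_per_group = as.integer(n_phantom_per_group),
                 sich_factor = sich_factor, cohort = cohort,
                 search_radius_mm = search_radius_mm,
                 n_boot = n_boot, p_out = p_out,
                 log_level = match.arg(log_level)),
            class = "run_config")
}

config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  json <- jsonlite::toJSON(lapply(x, unclass), auto_unbox = TRUE, digits = NA,
                           force = TRUE)
  # small stable polynomial hash; avoids a digest dependency
  bytes <- utf8ToInt(as.character(json))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

log_msg <- function(config, ...) {
  if (config$log_level == "INFO") {
    message(format(Sys.time(), "[%H:%M:%S] "), ...)
  }
}

#' Run the full pipeline: simulation -> tensor -> ALPS -> statistics
#'
#' Executes the requested stages in order, writes intermediate artifacts
#' under `config$out_dir`, and returns (and writes as JSON) a single
#' report: ALPS per simulated subject, the group contrast, the
#' correlation table, the mediation result and the prognosis results, plus
#' a provenance block (package version, seeds, config hash). Re-running
#' with the same config reproduces every stochastic output bit-identically.
#'
#' @param config a [run_config()].
#' @return The report, invisibly (a list); written to
#'   `file.path(config$out_dir, "report.json")`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  report <- list(provenance = list(
    package = "glymphr",
    version = as.character(utils::packageVersion("glymphr")),
    seed = config$seed,
    config_hash = hash
  ))

  if ("imaging" %in% config$stages) {
    log_msg(config, "imaging stage: ", 2 * config$n_phantom_per_group,
            " phantoms")
    rows <- list()
    for (grp in c("HC", "sICH")) {
      for (i in seq_len(config$n_phantom_per_group)) {
        sp <- config$phantom
        sp$glymphatic_factor <- if (grp == "HC") sp$glymphatic_factor
          else sp$glymphatic_factor * config$sich_factor
        sp$seed <- config$seed + 1000L * (grp == "sICH") + i
        ph <- make_phantom(sp)
        side <- if (grp == "sICH") c("left", "right")[1 + sp$seed %% 2]
          else "none"
        res <- alps_pipeline(ph$dwi, ph$ground_truth$seeds,
                             lesion_side = side,
                             search_radius_mm = config$search_radius_mm)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject = sprintf("%s%02d", grp, i), group = grp,
          lesion_side = side,
          alps_left = res$alps_left, alps_right = res$alps_right,
          alps_reported = res$alps_reported,
          ground_truth_alps = ph$ground_truth$alps)
      }
    }
    alps_tab <- dplyr::bind_rows(rows)
    readr::write_csv(alps_tab, file.path(config$out_dir, "alps_subjects.csv"))
    report$imaging <- list(alps = alps_tab)
  }

  if ("cohort" %in% config$stages) {
    log_msg(config, "cohort stage: n = ", 2 * config$cohort$n_per_group)
    cohort <- make_cohort(config$cohort)
    write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))

    contrast <- group_contrast(cohort)
    correlations <- alps_correlations(cohort)
    pat <- dplyr::filter(cohort, .data$group == "sICH")
    med <- mediate(pat, n_boot = config$n_boot, seed = config$seed)
    logit <- fit_logistic(pat, p_out = config$p_out)
    roc <- roc_analysis(pat$alps, pat$poor_outcome, direction = "<")
    summary_tab <- summarize_cohort(cohort)

    readr::write_csv(correlations,
                     file.path(config$out_dir, "correlations.csv"))
    readr::write_csv(summary_tab, file.path(config$out_dir, "summary.csv"))
    report$cohort <- list(
      contrast = contrast,
      correlations = correlations,
      mediation = list(paths = med$paths, n = med$n, n_boot = med$n_boot,
                       ci = c(med$ci_low, med$ci_high),
                       significant = med$significant),
      prognosis = list(full = logit$full, reduced = logit$reduced,
                       retained = logit$retained,
                       trace = logit$trace),
      roc = list(auc = roc$auc, ci = c(roc$ci_low, roc$ci_high),
                 cutoff = roc$cutoff, sensitivity = roc$sensitivity,
                 specificity = roc$specificity),
      summary = summary_tab
    )
  }

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns", force = TRUE)
  log_msg(config, "report written to ",
          file.path(config$out_dir, "report.json"))
  invisible(report)
}
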