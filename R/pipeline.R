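#' Pipeline run configuration
#'
#' Defaults equal the published analysis choices: uniform prior on
#' 14--23 years, 18-year threshold, 0.01-year posterior grid, redundancy
#' threshold 0.999, four hypothetical observations, the full structure /
#' weighting grid, and the standard tooth sets of both molar types.
#'
#' @param prior_lower,prior_upper,threshold prior support and threshold
#'   (years).
#' @param grid_step posterior grid step (years).
#' @param redundancy_threshold Pearson overlap bound.
#' @param outcomes outcome codes to rank; `NULL` means those retained by
#'   the redundancy screen.
#' @param tooth_sets named list of FDI vectors; `NULL` means
#'   [standard_tooth_sets()] of both molar types.
#' @param structures,weightings grid restriction.
#' @param n_hypothetical number of hypothetical observations for the
#'   posterior illustration.
#' @param combine `NULL`, or a list with `teethA` and `teethB` (FDI
#'   vectors): fit the two-molar combination for the ranked-best outcome.
#' @param seed integer seed recorded in the report.
#' @return list of class `run_config`.
#' @export
run_config <- function(prior_lower = 14, prior_upper = 23, threshold = 18,
                       grid_step = 0.01, redundancy_threshold = 0.999,
                       outcomes = NULL, tooth_sets = NULL,
                       structures = sex_structures(),
                       weightings = variance_weightings(),
                       n_hypothetical = 4, combine = NULL, seed = 1L) {
  bad <- setdiff(outcomes, outcome_codes())
  if (length(bad))
    stop("unknown outcome code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structures <- match.arg(structures, sex_structures(), several.ok = TRUE)
  weightings <- match.arg(weightings, variance_weightings(), several.ok = TRUE)
  if (!is.null(combine))
    stopifnot(is.list(combine), all(c("teethA", "teethB") %in% names(combine)))
  structure(list(prior_lower = prior_lower, prior_upper = prior_upper,
                 threshold = threshold, grid_step = grid_step,
                 redundancy_threshold = redundancy_threshold,
                 outcomes = outcomes, tooth_sets = tooth_sets,
                 structures = structures, weightings = weightings,
                 n_hypothetical = n_hypothetical, combine = combine,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Redundancy screen, candidate ranking, best-model fit, Bayesian
#' posteriors for hypothetical observations placed in uniform intervals
#' between the observed response extremes, and (optionally) the two-molar
#' combination. Writes a reproducible report bundle (JSON + CSV) to
#' `out_dir`; the same cohort, config and seed give byte-identical output.
#'
#' @param cohort cohort data frame or path to a cohort CSV.
#' @param out_dir output directory (created if needed).
#' @param config a [run_config()].
#' @return invisibly, a list with the screen result, ranking table, best
#'   fit, posterior list and (if configured) the bivariate fit.
#' @export
run_pipeline <- function(cohort, out_dir, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  cohort <- validate_cohort(cohort)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prior <- age_prior(config$prior_lower, config$prior_upper, config$threshold)

  scr <- screen_redundancy(cohort, config$redundancy_threshold)
  jsonlite::write_json(scr, file.path(out_dir, "screen.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  outcomes <- if (is.null(config$outcomes)) scr$retained else config$outcomes
  tooth_sets <- config$tooth_sets
  if (is.null(tooth_sets)) {
    present <- unique(cohort$tooth_fdi)
    tooth_sets <- c(standard_tooth_sets("m1"), standard_tooth_sets("m2"))
    tooth_sets <- Filter(function(s) all(s %in% present), tooth_sets)
  }
  ranked <- rank_candidates(cohort, outcomes, tooth_sets,
                            config$structures, config$weightings)
  utils::write.csv(ranked, file.path(out_dir, "rank.csv"), row.names = FALSE)

  best_teeth <- as.integer(strsplit(ranked$teeth[1], "\\+")[[1]])
  resp <- build_response(cohort, ranked$outcome[1], best_teeth)
  best <- fit_wls(resp, ranked$structure[1], ranked$weighting[1])
  write_model_json(best, file.path(out_dir, "model.json"))

  hyp <- hypothetical_observations(best$y_range, config$n_hypothetical)
  sexes <- intersect(c("F", "M"), unique(cohort$sex))
  posteriors <- list()
  for (s in sexes) for (j in seq_along(hyp)) {
    post <- posterior_age(best, hyp[j], s, prior, config$grid_step)
    posteriors[[paste0(s, "_h", j)]] <- post
  }
  jsonlite::write_json(lapply(posteriors, posterior_to_list),
                       file.path(out_dir, "predictions.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  biv <- NULL
  if (!is.null(config$combine)) {
    mk_spec <- function(teeth) {
      r <- build_response(cohort, ranked$outcome[1], teeth)
      sel <- select_structure(r, setdiff(config$structures, "v"),
                              config$weightings)
      list(outcome = ranked$outcome[1], tooth_set = teeth,
           structure = sel$fit$structure, weighting = sel$fit$weighting)
    }
    biv <- fit_bivariate(cohort, mk_spec(config$combine$teethA),
                         mk_spec(config$combine$teethB))
    write_model_json(biv, file.path(out_dir, "combine.json"))
  }

  report <- list(
    schema_version = SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("molarAge")),
    seed = config$seed,
    config = unclass(config),
    n_rows = nrow(cohort),
    n_participants = length(unique(cohort$participant_id)),
    retained_outcomes = scr$retained,
    best = as.list(ranked[1, ]),
    p_over = vapply(posteriors, `[[`, numeric(1), "p_over"),
    rho = if (!is.null(biv)) biv$rho)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(screen = scr, ranked = ranked, fit = best,
                 posteriors = posteriors, bivariate = biv,
                 report = report))
}
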