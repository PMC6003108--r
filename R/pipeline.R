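#' Run the full agreement-analysis pipeline
#'
#' Ties the stages together: obtain a cohort (from a file or the synthetic
#' generator), predict with every equation, and emit the agreement table, the
#' bias-factor model table with effects profiles, the per-kg class means, the
#' power-law fits (overall and per gender), the cross-tabulations, and a run
#' log (seed, parameters, package version). All outputs are CSV plus a plain
#' text run log; every CSV is re-readable with standard readers.
#'
#' @param input path to a cohort CSV (exclusive with `generate`).
#' @param generate logical; TRUE draws a synthetic cohort from `config`.
#' @param config generator configuration for `generate = TRUE`.
#' @param equations path to an equation config, or `NULL` for the bundled
#'   default library.
#' @param alpha significance threshold for bias-model backward elimination.
#' @param threshold adequacy threshold in percent.
#' @param seed integer seed controlling all randomness.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with all result objects (`cohort`, `predictions`,
#'   `agreement`, `bias_models`, `class_means`, `power_laws`, `crosstabs`,
#'   `paths`).
#' @export
run_pipeline <- function(input = NULL, generate = is.null(input),
                         config = default_cohort_config(),
                         equations = NULL, alpha = 0.05, threshold = 10,
                         seed = 1L, out_dir = tempfile("rmragree-run-")) {
  if (!is.null(input) && generate) {
    stop("supply exactly one of an input file or generate = TRUE", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)

  cohort <- if (!is.null(input)) {
    augment_cohort(read_cohort(input))
  } else {
    generate_cohort(config, seed = seed)
  }
  specs <- if (is.null(equations)) default_equations()
           else load_equation_config(equations)

  pred <- suppressWarnings(predict_all(cohort, specs))
  agree <- agreement_table(pred, cohort)
  agree$adequate <- ifelse(is.na(agree$accuracy_vs_m), NA,
                           adequacy_flag(agree, threshold))
  bm <- suppressWarnings(bias_model_table(pred, cohort, alpha = alpha))
  cm <- class_means(cohort)
  fits <- list(both = fit_power_law(cohort, scope = "both"),
               male = fit_power_law(cohort, scope = "male"),
               female = fit_power_law(cohort, scope = "female"))
  xt <- lapply(stats::setNames(c("gender", "age_group", "education"),
                               c("gender", "age_group", "education")),
               function(f) crosstab_test(cohort, f))

  utils::write.csv(as.data.frame(agree), p("agreement.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(bm$table), p("bias_model.csv"),
                   row.names = FALSE)
  profiles <- dplyr::bind_rows(lapply(names(bm$models), function(nm) {
    tibble::tibble(equation = nm,
                   effects_profile(bm$models[[nm]], retained_only = FALSE))
  }))
  utils::write.csv(as.data.frame(profiles), p("bias_effects.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(cm), p("class_means.csv"), row.names = FALSE)
  fit_tbl <- dplyr::bind_rows(lapply(fits, function(f) {
    tibble::tibble(scope = f$scope, c = f$c, b = f$b, intercept = f$intercept,
                   slope = f$slope, r2 = f$r2, n_points = f$n_points)
  }))
  utils::write.csv(as.data.frame(fit_tbl), p("power_law.csv"),
                   row.names = FALSE)
  flags <- dplyr::bind_rows(lapply(names(xt), function(f) {
    tibble::tibble(factor = f, chi2 = xt[[f]]$chi2, df = xt[[f]]$df,
                   p = xt[[f]]$p)
  }))
  utils::write.csv(as.data.frame(flags), p("crosstab.csv"), row.names = FALSE)
  flag_cells <- dplyr::bind_rows(lapply(names(xt), function(f) {
    if (nrow(xt[[f]]$flags)) tibble::tibble(factor = f, xt[[f]]$flags)
  }))
  utils::write.csv(as.data.frame(flag_cells), p("crosstab_flags.csv"),
                   row.names = FALSE)
  write_cohort(cohort, p("cohort.csv"),
               comment = paste("seed:", seed))

  writeLines(c(
    paste("rmragree", as.character(utils::packageVersion("rmragree"))),
    paste("seed:", seed),
    paste("alpha:", alpha),
    paste("adequacy threshold (%):", threshold),
    paste("cohort:", if (is.null(input)) "synthetic (default generator)"
          else input),
    paste("subjects:", nrow(cohort),
          sprintf("(male %d, female %d; %d excluded underweight)",
                  sum(cohort$gender == "male"),
                  sum(cohort$gender == "female"), sum(cohort$excluded)))
  ), p("run_log.txt"))

  invisible(list(cohort = cohort, predictions = pred, agreement = agree,
                 bias_models = bm, class_means = cm, power_laws = fits,
                 crosstabs = xt, paths = p("")))
}
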