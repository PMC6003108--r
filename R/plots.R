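#' Main-effects plot of a bias model
#'
#' Per-level means of the transformed absolute bias for each factor, the
#' standard way to read which factor drives an equation's disagreement with
#' the calorimeter.
#'
#' @param result a `bias_model` from [fit_bias_model()].
#' @param retained_only plot only retained factors (default FALSE: all three).
#' @return A ggplot object.
#' @export
plot_effects_profile <- function(result, retained_only = FALSE) {
  prof <- effects_profile(result, retained_only = retained_only)
  prof$level <- factor(prof$level, levels = unique(prof$level))
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$level,
                                     y = .data$mean_transformed, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~factor, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "mean transformed |bias|") +
    ggplot2::theme_bw()
}

#' Log-log plot of per-kg RMR against BMI class
#'
#' Class means with the fitted power law, overall or per gender.
#'
#' @param cohort augmented cohort.
#' @param by_gender facet by gender (two fits) instead of a pooled fit.
#' @return A ggplot object.
#' @export
plot_power_law <- function(cohort, by_gender = FALSE) {
  scopes <- if (by_gender) c("male", "female") else "both"
  pts <- dplyr::bind_rows(lapply(scopes, function(s) {
    g <- if (s == "both") NULL else s
    tibble::tibble(scope = s, class_means(cohort, gender = g))
  }))
  lines <- dplyr::bind_rows(lapply(scopes, function(s) {
    f <- fit_power_law(cohort, scope = s)
    k <- seq(1, 5, by = 0.05)
    tibble::tibble(scope = s, bmi_class = k, mean = f$c * k^f$b)
  }))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$bmi_class, y = .data$mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.1) +
    ggplot2::geom_line(data = lines) +
    ggplot2::scale_x_log10(breaks = 1:5) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~scope) +
    ggplot2::labs(x = "BMI class code", y = "RMR (kcal/kg/day)") +
    ggplot2::theme_bw()
}
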