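#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_errorbar
#'   geom_errorbarh geom_abline geom_hline geom_vline geom_line labs
#'   scale_x_log10 theme_minimal
NULL

#' Scatter plot of an MR fit with estimator slopes
#'
#' Instrument-outcome effects against instrument-exposure effects, error
#' bars at one standard error, with one line per fitted estimator through
#' the origin (the Egger line keeps its intercept).
#'
#' @param object an `mr_suite`
#' @param ... unused
#' @return A ggplot object.
#' @export
autoplot.mr_suite <- function(object, ...) {
  if (is.null(object$loo) && object$primary$n_snp == 1) {
    abort("nothing to plot for a single-instrument fit")
  }
  a <- object$aligned
  est <- object$estimates
  p <- ggplot(est, aes(x = 0, y = 0)) # placeholder when data unavailable
  if (!is.null(a)) {
    p <- ggplot(a, aes(x = .data$beta_exp, y = .data$beta_out)) +
      geom_errorbar(aes(ymin = .data$beta_out - .data$se_out,
                        ymax = .data$beta_out + .data$se_out),
                    width = 0, colour = "grey60") +
      geom_errorbarh(aes(xmin = .data$beta_exp - .data$se_exp,
                         xmax = .data$beta_exp + .data$se_exp),
                     height = 0, colour = "grey60") +
      geom_point()
  }
  p +
    geom_abline(data = est, aes(slope = .data$beta, intercept = 0,
                                colour = .data$method)) +
    labs(x = "effect on exposure (SD)", y = "effect on outcome",
         colour = "estimator") +
    theme_minimal()
}

#' Volcano plot of a screening stage
#'
#' Effect size against -log10 p for every tested pair, with the
#' Bonferroni threshold drawn as a horizontal line.
#'
#' @param object a `screen_report`
#' @param ... unused
#' @return A ggplot object.
#' @export
autoplot.screen_report <- function(object, ...) {
  r <- object$results
  thr <- suppressWarnings(min(r$bonferroni_threshold, na.rm = TRUE))
  ggplot(r[!is.na(r$pval), ],
         aes(x = .data$beta, y = -log10(.data$pval),
             colour = isTRUE_v(.data$bonferroni_significant))) +
    geom_point() +
    geom_vline(xintercept = 0, linetype = "dashed") +
    (if (is.finite(thr)) geom_hline(yintercept = -log10(thr), linetype = "dashed")) +
    labs(x = "causal effect estimate", y = expression(-log[10](p)),
         colour = "Bonferroni-significant") +
    theme_minimal()
}

#' Sensitivity curve of the shared-variant posterior in the p12 prior
#'
#' @param curve output of [coloc_sensitivity()]
#' @param pp_min horizontal reference line (default 0.8)
#' @return A ggplot object.
#' @export
plot_coloc_sensitivity <- function(curve, pp_min = 0.8) {
  ggplot(curve, aes(x = .data$p12, y = .data$pp_shared)) +
    geom_line() + geom_point() +
    geom_hline(yintercept = pp_min, linetype = "dashed") +
    scale_x_log10() +
    labs(x = "p12 prior", y = "posterior probability of a shared variant") +
    theme_minimal()
}

#' Forest table plot of odds ratios per SD
#'
#' @param forest the `forest` tibble from [make_report()]
#' @return A ggplot object.
#' @export
plot_forest <- function(forest) {
  forest$label <- paste(forest$exposure, forest$outcome, sep = " → ")
  ggplot(forest, aes(x = .data$or_sd, y = .data$label)) +
    geom_point() +
    geom_errorbarh(aes(xmin = .data$or_low, xmax = .data$or_high), height = 0.2) +
    geom_vline(xintercept = 1, linetype = "dashed") +
    labs(x = "odds ratio per SD (95% CI)", y = NULL) +
    theme_minimal()
}
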