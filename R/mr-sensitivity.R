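#' Leave-one-out sensitivity analysis
#'
#' Refits the primary estimator `n_snp` times, each time omitting one
#' instrument (IVW random-effects, or the Wald ratio when only one
#' instrument remains). If the full-set association is nominally significant
#' (p <= 0.05) but dropping some single SNP makes it non-significant
#' (p > 0.05), that SNP is flagged as driving the association.
#'
#' @param h a `harmonised_set` or aligned tibble with >= 2 instruments
#' @param alpha nominal significance level for the driver rule (default 0.05)
#' @param binary whether the outcome is binary
#' @return List with `loo` (tibble: one `mr_result` row per left-out SNP,
#'   keyed by `snp_left_out`) and `driver_snp` (character, `NA` when none).
#' @export
leave_one_out <- function(h, alpha = 0.05, binary = outcome_is_binary(h)) {
  a <- as_aligned(h)
  if (nrow(a) < 2) abort("leave-one-out needs >= 2 instruments")
  full_p <- ivw(a, "random", binary = binary)$pval
  loo <- purrr::map_dfr(seq_len(nrow(a)), function(i) {
    sub <- a[-i, ]
    res <- if (nrow(sub) == 1) {
      wald_ratio(sub$beta_exp, sub$se_exp, sub$beta_out, sub$se_out, binary = binary)
    } else {
      ivw(sub, "random", binary = binary)
    }
    dplyr::mutate(res, snp_left_out = a$snp_id[i], .before = 1)
  })
  driver <- NA_character_
  if (full_p <= alpha && any(loo$pval > alpha)) {
    worst <- which.max(loo$pval)
    driver <- loo$snp_left_out[worst]
  }
  list(loo = loo, driver_snp = driver)
}

#' Bidirectional-MR reverse-causation flag
#'
#' Given the forward estimate (exposure -> outcome) and the reverse estimate
#' obtained with the roles swapped, flags the pair when both are significant
#' at `alpha` (strict inequality): a significant reverse association means
#' reverse causation cannot be discounted.
#'
#' @param forward,reverse one-row `mr_result` tibbles
#' @param alpha significance level (default 0.05)
#' @return Logical flag.
#' @export
bidirectional <- function(forward, reverse, alpha = 0.05) {
  isTRUE(forward$pval < alpha && reverse$pval < alpha)
}

#' Run the full univariable MR suite on a harmonised pair
#'
#' Routes to the Wald ratio for a single instrument and random-effects IVW
#' for two or more; attaches Cochran's Q, the MR-Egger intercept test (three
#' or more instruments), leave-one-out, the alternative estimators
#' (IVW-fixed, maximum likelihood, simple/weighted median, simple/weighted
#' mode) and their sign concordance with the primary estimate, and an
#' optional reverse-direction fit for the bidirectional check. The verdict
#' fails when any sensitivity rule fires: heterogeneity (`Q_pval < 0.05`),
#' directional pleiotropy (Egger intercept p < 0.05), a driver SNP in
#' leave-one-out, or a significant bidirectional signal.
#'
#' @param h a `harmonised_set`
#' @param reverse optional reverse-direction `harmonised_set`
#'   (outcome as exposure) for the bidirectional test
#' @param alpha sensitivity-test level (default 0.05)
#' @param n_boot bootstrap replicates for median/mode SEs
#' @param seed seed for the bootstrap streams
#' @param binary whether the outcome is binary
#' @return An `mr_suite` list: `primary` (one-row `mr_result`), `estimates`
#'   (tibble of all methods), `sensitivity` (Q, Egger intercept, driver SNP,
#'   concordance, reverse flag), `loo`, `verdict` (`"pass"`, `"fail"`, or
#'   `"not_testable"`), and `fail_reasons`.
#' @export
run_mr_suite <- function(h, reverse = NULL, alpha = 0.05, n_boot = 1000,
                         seed = 1L, binary = outcome_is_binary(h)) {
  a <- as_aligned(h)
  n <- nrow(a)
  if (n == 0) {
    return(structure(list(
      primary = NULL, estimates = NULL,
      sensitivity = tibble::tibble(), loo = NULL,
      verdict = "not_testable", fail_reasons = "no_instruments"
    ), class = "mr_suite"))
  }
  if (n == 1) {
    primary <- wald_ratio(a$beta_exp, a$se_exp, a$beta_out, a$se_out, binary = binary)
    sens <- tibble::tibble(
      Q = NA_real_, Q_pval = NA_real_,
      egger_intercept = NA_real_, egger_intercept_se = NA_real_,
      egger_intercept_pval = NA_real_,
      driver_snp = NA_character_, method_concordance = TRUE,
      reverse_significant = FALSE
    )
    verdict <- "pass"
    reasons <- character()
    if (!is.null(reverse)) {
      rs <- reverse_result(reverse, seed)
      sens$reverse_significant <- bidirectional(primary, rs, alpha)
      if (sens$reverse_significant) { verdict <- "fail"; reasons <- "bidirectional" }
    }
    return(structure(list(primary = primary, estimates = primary,
                          sensitivity = sens, loo = NULL, aligned = a,
                          verdict = verdict, fail_reasons = reasons),
                     class = "mr_suite"))
  }

  primary <- ivw(a, "random", binary = binary)
  estimates <- dplyr::bind_rows(
    primary,
    ivw(a, "fixed", binary = binary),
    max_likelihood(a, binary = binary)
  )
  eg <- NULL
  if (n >= 3) {
    eg <- egger(a, binary = binary)
    estimates <- dplyr::bind_rows(
      estimates, eg$slope,
      median_estimator(a, "simple", n_boot, seed, binary = binary),
      median_estimator(a, "weighted", n_boot, seed, binary = binary),
      mode_estimator(a, "simple", 1, n_boot, seed, binary = binary),
      mode_estimator(a, "weighted", 1, n_boot, seed, binary = binary)
    )
  }
  q <- cochran_q(a, primary$beta)
  lo <- leave_one_out(a, alpha, binary = binary)
  concord <- length(unique(sign(estimates$beta[estimates$beta != 0]))) <= 1

  sens <- tibble::tibble(
    Q = q$Q, Q_pval = q$Q_pval,
    egger_intercept = if (is.null(eg)) NA_real_ else eg$intercept,
    egger_intercept_se = if (is.null(eg)) NA_real_ else eg$intercept_se,
    egger_intercept_pval = if (is.null(eg)) NA_real_ else eg$intercept_pval,
    driver_snp = lo$driver_snp, method_concordance = concord,
    reverse_significant = FALSE
  )
  if (!is.null(reverse)) {
    rs <- reverse_result(reverse, seed)
    sens$reverse_significant <- bidirectional(primary, rs, alpha)
  }

  reasons <- character()
  if (isTRUE(sens$Q_pval < alpha)) reasons <- c(reasons, "heterogeneity")
  if (isTRUE(sens$egger_intercept_pval < alpha)) reasons <- c(reasons, "egger_intercept")
  if (!is.na(sens$driver_snp)) reasons <- c(reasons, "driver_snp")
  if (isTRUE(sens$reverse_significant)) reasons <- c(reasons, "bidirectional")

  structure(list(primary = primary, estimates = estimates, sensitivity = sens,
                 loo = lo$loo, aligned = a,
                 verdict = if (length(reasons)) "fail" else "pass",
                 fail_reasons = reasons),
            class = "mr_suite")
}

reverse_result <- function(reverse, seed) {
  ra <- as_aligned(reverse)
  if (nrow(ra) == 0) return(mr_result("ivw_random", 0L, 0, Inf))
  if (nrow(ra) == 1) {
    wald_ratio(ra$beta_exp, ra$se_exp, ra$beta_out, ra$se_out)
  } else {
    ivw(ra, "random")
  }
}

#' @export
print.mr_suite <- function(x, ...) {
  cat("<mr_suite> verdict:", x$verdict, "\n")
  if (!is.null(x$primary)) {
    cat(sprintf("  primary %s: beta=%.4g (se %.3g, p=%.3g), n_snp=%d\n",
                x$primary$method, x$primary$beta, x$primary$se,
                x$primary$pval, x$primary$n_snp))
  }
  if (length(x$fail_reasons)) cat("  failed:", paste(x$fail_reasons, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.mr_suite <- function(x, ...) {
  if (is.null(x$estimates)) return(tibble::tibble())
  x$estimates
}

#' @export
glance.mr_suite <- function(x, ...) {
  s <- if (nrow(x$sensitivity %||% tibble::tibble()) > 0) x$sensitivity else
    tibble::tibble(Q_pval = NA_real_, egger_intercept_pval = NA_real_,
                   driver_snp = NA_character_, method_concordance = NA,
                   reverse_significant = NA)
  tibble::tibble(
    method = x$primary$method %||% NA_character_,
    beta = x$primary$beta %||% NA_real_,
    pval = x$primary$pval %||% NA_real_,
    n_snp = x$primary$n_snp %||% NA_integer_,
    Q_pval = s$Q_pval[1], egger_intercept_pval = s$egger_intercept_pval[1],
    driver_snp = s$driver_snp[1], method_concordance = s$method_concordance[1],
    reverse_significant = s$reverse_significant[1],
    verdict = x$verdict
  )
}
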