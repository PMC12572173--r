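mr_result <- function(method, n_snp, beta, se, binary = FALSE,
                      converged = TRUE) {
  ci <- ci_from(beta, se)
  out <- tibble::tibble(
    method = method, n_snp = as.integer(n_snp), beta = beta, se = se,
    ci_low = ci[1], ci_high = ci[2], pval = two_sided_p(beta / se),
    or_sd = if (binary) exp(beta) else NA_real_,
    or_low = if (binary) exp(ci[1]) else NA_real_,
    or_high = if (binary) exp(ci[2]) else NA_real_,
    converged = converged
  )
  class(out) <- c("mr_result", class(out))
  out
}

outcome_is_binary <- function(h) {
  isTRUE(attr(h, "outcome_binary")) ||
    (inherits(h, "harmonised_set") && isTRUE(h$outcome_binary))
}

ratio_weights <- function(a) {
  # first-order inverse variance of the per-SNP Wald ratio
  list(ratio = a$beta_out / a$beta_exp, w = a$beta_exp^2 / a$se_out^2)
}

#' Wald ratio causal estimate from a single instrument
#'
#' The single-instrument estimate `beta_out / beta_exp`, with first-order
#' (delta-method) standard error `se_out / |beta_exp|` and a two-sided
#' normal p-value. For binary outcomes the estimate exponentiates to an
#' odds ratio per SD of the exposure.
#'
#' @param beta_exp,se_exp instrument-exposure effect and SE
#' @param beta_out,se_out instrument-outcome effect and SE
#' @param binary whether the outcome is binary (populates `or_sd`)
#' @return A one-row `mr_result` tibble: `method, n_snp, beta, se, ci_low,
#'   ci_high, pval, or_sd, or_low, or_high`.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out, binary = FALSE) {
  if (beta_exp == 0) {
    abort("degenerate instrument: beta_exp = 0", class = "mrtriad_degenerate_instrument")
  }
  mr_result("wald_ratio", 1L, beta_out / beta_exp, se_out / abs(beta_exp),
            binary = binary)
}

#' Inverse-variance weighted causal estimate
#'
#' Precision-weighted regression of outcome effects on exposure effects
#' through the origin, with weights `1/se_out^2` — algebraically the
#' inverse-variance weighted mean of the per-SNP Wald ratios. The
#' fixed-effects SE comes from the weight sum; the random-effects
#' (multiplicative overdispersion) SE inflates it by
#' `sqrt(max(1, Q / (n_snp - 1)))`, so the two coincide under homogeneity.
#'
#' @param h a `harmonised_set` or aligned tibble
#' @param effects `"random"` (default) or `"fixed"`
#' @param binary whether the outcome is binary
#' @return A one-row `mr_result` tibble.
#' @export
ivw <- function(h, effects = c("random", "fixed"), binary = outcome_is_binary(h)) {
  effects <- match.arg(effects)
  a <- as_aligned(h)
  if (nrow(a) < 2) {
    abort("IVW needs >= 2 instruments; use wald_ratio()", class = "mrtriad_routing")
  }
  w <- 1 / a$se_out^2
  beta <- sum(w * a$beta_exp * a$beta_out) / sum(w * a$beta_exp^2)
  se <- sqrt(1 / sum(w * a$beta_exp^2))
  if (effects == "random") {
    rw <- ratio_weights(a)
    q <- sum(rw$w * (rw$ratio - beta)^2)
    se <- se * sqrt(max(1, q / (nrow(a) - 1)))
  }
  mr_result(paste0("ivw_", effects), nrow(a), beta, se, binary = binary)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with a free
#' intercept (weights `1/se_out^2`), after re-orienting every instrument so
#' its exposure effect is non-negative. A non-null intercept indicates
#' directional horizontal pleiotropy; the slope is the pleiotropy-adjusted
#' causal estimate. Standard errors carry the same multiplicative
#' overdispersion (floored at 1) as random-effects IVW.
#'
#' @param h a `harmonised_set` or aligned tibble with >= 3 instruments
#' @param binary whether the outcome is binary
#' @return List with `slope` (a one-row `mr_result`), `intercept`,
#'   `intercept_se`, `intercept_pval`.
#' @export
egger <- function(h, binary = outcome_is_binary(h)) {
  a <- as_aligned(h)
  if (nrow(a) < 3) {
    abort("MR-Egger needs >= 3 instruments", class = "mrtriad_not_applicable")
  }
  flip <- sign(a$beta_exp)
  flip[flip == 0] <- 1
  x <- a$beta_exp * flip
  y <- a$beta_out * flip
  w <- 1 / a$se_out^2
  fit <- lm(y ~ x, weights = w)
  sm <- suppressWarnings(summary(fit))  # exact fits are legitimate here
  disp <- max(1, sm$sigma)  # overdispersion floored at 1, as in IVW-RE
  co <- sm$coefficients
  slope_se <- co["x", "Std. Error"] / sm$sigma * disp
  int_se <- co["(Intercept)", "Std. Error"] / sm$sigma * disp
  list(
    slope = mr_result("egger", nrow(a), co["x", "Estimate"], slope_se, binary = binary),
    intercept = co["(Intercept)", "Estimate"],
    intercept_se = int_se,
    intercept_pval = two_sided_p(co["(Intercept)", "Estimate"] / int_se)
  )
}

weighted_median_of <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  cw <- cumsum(w) - w / 2
  if (cw[1] >= 0.5) return(x[1])
  if (cw[length(cw)] <= 0.5) return(x[length(x)])
  stats::approx(cw, x, xout = 0.5, ties = "ordered")$y
}

boot_se <- function(a, estimator, n_boot, seed) {
  ests <- withr::with_seed(stream_seed(seed, "bootstrap"), {
    vapply(seq_len(n_boot), function(i) {
      b <- a
      b$beta_exp <- rnorm(nrow(a), a$beta_exp, a$se_exp)
      b$beta_out <- rnorm(nrow(a), a$beta_out, a$se_out)
      estimator(b)
    }, numeric(1))
  })
  sd(ests)
}

#' Median-based causal estimators
#'
#' The simple median of the per-SNP Wald ratios, or the weighted median with
#' inverse-variance weights (cumulative-weight interpolation at 0.5). Both
#' are consistent when at least half the (weight in) instruments are valid.
#' The SE comes from a seeded parametric bootstrap resampling each
#' instrument's effects from their reported sampling distributions.
#'
#' @param h a `harmonised_set` or aligned tibble with >= 3 instruments
#' @param kind `"weighted"` (default) or `"simple"`
#' @param n_boot bootstrap replicates (default 1000; < 100 warns)
#' @param seed bootstrap seed
#' @param binary whether the outcome is binary
#' @return A one-row `mr_result` tibble.
#' @export
median_estimator <- function(h, kind = c("weighted", "simple"), n_boot = 1000,
                             seed = 1L, binary = outcome_is_binary(h)) {
  kind <- match.arg(kind)
  a <- as_aligned(h)
  if (nrow(a) < 3) abort("median estimator needs >= 3 instruments")
  if (n_boot < 100) warn("n_boot < 100: bootstrap SE will be unstable")
  est_fun <- function(d) {
    rw <- ratio_weights(d)
    if (kind == "simple") median(rw$ratio) else weighted_median_of(rw$ratio, rw$w)
  }
  mr_result(paste0(kind, "_median"), nrow(a), est_fun(a),
            boot_se(a, est_fun, n_boot, seed), binary = binary)
}

mode_point <- function(ratio, w, bandwidth_factor) {
  if (length(unique(ratio)) == 1) return(ratio[1])
  s <- min(sd(ratio), mad(ratio))
  if (s == 0) s <- sd(ratio)
  h_bw <- bandwidth_factor * 0.9 * s * length(ratio)^(-1 / 5)
  if (h_bw <= 0) abort("zero bandwidth")
  d <- density(ratio, weights = w / sum(w), bw = h_bw, n = 2048)
  d$x[which.max(d$y)]
}

#' Mode-based causal estimators
#'
#' The mode of a kernel-smoothed density of the per-SNP Wald ratios
#' (optionally inverse-variance weighted), consistent when the largest group
#' of instruments sharing a causal estimate is valid — hence robust to a
#' minority of pleiotropic outliers. Bandwidth follows a modified Silverman
#' rule, `0.9 min(sd, mad) n^{-1/5}`, scaled by `bandwidth_factor`. The SE
#' comes from a seeded parametric bootstrap.
#'
#' @inheritParams median_estimator
#' @param bandwidth_factor positive multiplier on the Silverman bandwidth
#' @return A one-row `mr_result` tibble.
#' @export
mode_estimator <- function(h, kind = c("weighted", "simple"),
                           bandwidth_factor = 1, n_boot = 1000, seed = 1L,
                           binary = outcome_is_binary(h)) {
  kind <- match.arg(kind)
  if (bandwidth_factor <= 0) abort("`bandwidth_factor` must be positive")
  a <- as_aligned(h)
  if (nrow(a) < 3) abort("mode estimator needs >= 3 instruments")
  est_fun <- function(d) {
    rw <- ratio_weights(d)
    w <- if (kind == "simple") rep(1, nrow(d)) else rw$w
    mode_point(rw$ratio, w, bandwidth_factor)
  }
  mr_result(paste0(kind, "_mode"), nrow(a), est_fun(a),
            boot_se(a, est_fun, n_boot, seed), binary = binary)
}

#' Maximum-likelihood causal estimate
#'
#' Maximises the likelihood of the observed effect pairs under the model
#' `beta_exp_j ~ N(gamma_j, se_exp_j^2)`, `beta_out_j ~ N(b gamma_j,
#' se_out_j^2)` with a single causal slope `b`. The per-SNP nuisance means
#' profile out in closed form, leaving a one-dimensional optimisation over
#' `b` (tolerance 1e-10); the SE comes from the curvature of the profile
#' log-likelihood at the optimum.
#'
#' @param h a `harmonised_set` or aligned tibble with >= 2 instruments
#' @param binary whether the outcome is binary
#' @return A one-row `mr_result` tibble; `converged` is `FALSE` when the
#'   optimiser hit the search boundary.
#' @export
max_likelihood <- function(h, binary = outcome_is_binary(h)) {
  a <- as_aligned(h)
  if (nrow(a) < 2) abort("maximum likelihood needs >= 2 instruments")
  vx <- a$se_exp^2
  vy <- a$se_out^2
  x <- a$beta_exp
  y <- a$beta_out
  # profile log-likelihood: gamma_j* has closed form given b
  negll <- function(b) {
    g <- (x / vx + b * y / vy) / (1 / vx + b^2 / vy)
    sum((x - g)^2 / vx + (y - b * g)^2 / vy) / 2
  }
  start <- ivw(a, "fixed")$beta
  width <- max(1, abs(start)) * 50
  opt <- optimise(negll, c(start - width, start + width), tol = 1e-10)
  bhat <- opt$minimum
  converged <- abs(bhat - (start - width)) > 1e-6 && abs(bhat - (start + width)) > 1e-6
  eps <- 1e-4 * max(1, abs(bhat))
  curv <- (negll(bhat + eps) - 2 * negll(bhat) + negll(bhat - eps)) / eps^2
  se <- if (curv > 0) 1 / sqrt(curv) else NA_real_
  mr_result("max_likelihood", nrow(a), bhat, se, binary = binary,
            converged = converged)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_j (ratio_j - beta_ref)^2` over the per-SNP Wald ratios with
#' first-order inverse-variance weights, referred to a chi-square with
#' `n_snp - 1` degrees of freedom. A p-value below 0.05 is conventionally
#' read as significant heterogeneity (invalid or pleiotropic instruments).
#'
#' @param h a `harmonised_set` or aligned tibble with >= 2 instruments
#' @param beta_ref the causal estimate to measure dispersion around
#'   (default: the IVW-fixed estimate)
#' @return Tibble with one row: `Q, df, Q_pval`.
#' @export
cochran_q <- function(h, beta_ref = NULL) {
  a <- as_aligned(h)
  if (nrow(a) < 2) abort("Cochran's Q needs >= 2 instruments")
  if (is.null(beta_ref)) beta_ref <- ivw(a, "fixed")$beta
  rw <- ratio_weights(a)
  q <- sum(rw$w * (rw$ratio - beta_ref)^2)
  df <- nrow(a) - 1L
  tibble::tibble(Q = q, df = df, Q_pval = pchisq(q, df, lower.tail = FALSE))
}
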