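# Align several exposure GWAS and one outcome GWAS to the outcome's effect
# alleles over a set of instrument SNPs. Harmonising each exposure *against*
# the outcome (outcome in the reference role) puts every exposure beta on
# the outcome's effect allele in one pass.
align_mvmr <- function(exposures, outcome, snp_ids) {
  out_sub <- tibble::as_tibble(outcome)
  out_sub <- out_sub[out_sub$snp_id %in% snp_ids, ]
  per_exp <- purrr::map(exposures, function(ex) {
    h <- harmonise(out_sub, ex)
    h$aligned
  })
  common <- Reduce(intersect, c(list(out_sub$snp_id), purrr::map(per_exp, "snp_id")))
  if (length(common) == 0) return(NULL)
  y <- out_sub[match(common, out_sub$snp_id), ]
  X <- vapply(per_exp, function(a) a$beta_out[match(common, a$snp_id)],
              numeric(length(common)))
  SE <- vapply(per_exp, function(a) a$se_out[match(common, a$snp_id)],
               numeric(length(common)))
  X <- matrix(X, ncol = length(exposures))
  SE <- matrix(SE, ncol = length(exposures))
  nm <- purrr::map_chr(exposures, ~ .x$trait_id[1])
  colnames(X) <- colnames(SE) <- nm
  list(snp_id = common, beta_exp = X, se_exp = SE,
       beta_out = y$beta, se_out = y$se)
}

#' Multivariable MR by inverse-variance weighted regression
#'
#' Estimates each exposure's *direct* effect on the outcome, conditional on
#' the other exposures, by weighted multivariable regression of the outcome
#' effects on the exposure-effect matrix through the origin (weights
#' `1/se_out^2`). Reports per-exposure conditional F-statistics (the
#' instrument strength of each exposure given the others: the Q-statistic of
#' its effects regressed on the other exposures', scaled by
#' `L - p + 1` for `L` instruments and `p` exposures) and the modified
#' Cochran's Q for residual heterogeneity/pleiotropy with `L - p` degrees of
#' freedom. A phenotypic correlation matrix, when supplied, enters both
#' statistics through per-variant covariance terms
#' `cov_jl,i = rho_jl se_ji se_li`.
#'
#' @param exposures list of `sumstats` tibbles (one per exposure)
#' @param outcome outcome `sumstats` tibble
#' @param instruments an `instrument_set` (e.g. from [reclump_union()]) or a
#'   character vector of instrument `snp_id`s
#' @param covariance optional phenotypic correlation matrix between the
#'   exposures (identity when `NULL`)
#' @return An `mvmr_result`: list with `estimates` (tibble: `exposure, beta,
#'   se, pval, conditional_F`), `modified_Q`, `Q_pval`, `weak_flag` (any
#'   conditional F < 10), `pleiotropy_flag` (`Q_pval < 0.05`), `n_snp`, and
#'   the aligned `data`.
#' @export
mvmr_ivw <- function(exposures, outcome, instruments, covariance = NULL) {
  snp_ids <- if (inherits(instruments, "instrument_set")) {
    instruments$index_snps
  } else {
    as.character(instruments)
  }
  p <- length(exposures)
  al <- align_mvmr(exposures, outcome, snp_ids)
  if (is.null(al) || length(al$snp_id) < p + 1) {
    abort("need at least (number of exposures + 1) aligned instruments")
  }
  L <- length(al$snp_id)
  X <- al$beta_exp
  y <- al$beta_out
  w <- 1 / al$se_out^2
  rho <- covariance %||% diag(p)

  XtWX <- crossprod(X, w * X)
  if (qr(XtWX)$rank < p) {
    abort("exposure effect matrix is rank deficient (collinear exposures)",
          class = "mrtriad_collinearity")
  }
  XtWXi <- solve(XtWX)
  bhat <- unname(drop(XtWXi %*% crossprod(X, w * y)))
  se <- unname(sqrt(diag(XtWXi)))
  pval <- two_sided_p(bhat / se)

  # per-variant covariance of exposure-effect estimates
  cov_i <- function(i) rho * tcrossprod(al$se_exp[i, ])

  cond_F <- vapply(seq_len(p), function(k) {
    xk <- X[, k]
    if (p == 1) {
      resid <- xk
      delta <- numeric(0)
      sig2 <- al$se_exp[, 1]^2
    } else {
      others <- X[, -k, drop = FALSE]
      delta <- drop(solve(crossprod(others), crossprod(others, xk)))
      resid <- xk - drop(others %*% delta)
      sig2 <- vapply(seq_len(L), function(i) {
        ci <- cov_i(i)
        ci[k, k] + drop(t(delta) %*% ci[-k, -k, drop = FALSE] %*% delta) -
          2 * sum(delta * ci[k, -k])
      }, numeric(1))
    }
    sum(resid^2 / sig2) / (L - p + 1)
  }, numeric(1))

  qw <- vapply(seq_len(L), function(i) {
    1 / (al$se_out[i]^2 + drop(t(bhat) %*% cov_i(i) %*% bhat))
  }, numeric(1))
  resid_out <- y - drop(X %*% bhat)
  modq <- sum(qw * resid_out^2)
  q_df <- L - p
  q_pval <- pchisq(modq, q_df, lower.tail = FALSE)

  structure(list(
    estimates = tibble::tibble(
      exposure = colnames(X), beta = bhat, se = se, pval = pval,
      conditional_F = cond_F
    ),
    modified_Q = modq, Q_df = q_df, Q_pval = q_pval,
    weak_flag = any(cond_F < 10), pleiotropy_flag = q_pval < 0.05,
    n_snp = L,
    data = tibble::tibble(snp_id = al$snp_id, beta_out = y, se_out = al$se_out)
  ), class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat("<mvmr_result> ", x$n_snp, " instruments, ", nrow(x$estimates),
      " exposures\n", sep = "")
  print(x$estimates)
  cat(sprintf("  modified Q = %.3g (df %d, p = %.3g); weak=%s pleiotropy=%s\n",
              x$modified_Q, x$Q_df, x$Q_pval, x$weak_flag, x$pleiotropy_flag))
  invisible(x)
}

#' @export
tidy.mvmr_result <- function(x, ...) x$estimates

#' @export
glance.mvmr_result <- function(x, ...) {
  tibble::tibble(n_snp = x$n_snp, modified_Q = x$modified_Q,
                 Q_pval = x$Q_pval, weak_flag = x$weak_flag,
                 pleiotropy_flag = x$pleiotropy_flag)
}

#' Reclump the union of instruments across several traits
#'
#' Pools every variant reaching `p_max` in *any* of the traits and clumps
#' the union exactly as in single-trait selection, but ranking each variant
#' by its smallest p-value across the traits — the instrument-selection rule
#' for multivariable MR. A variant significant in several traits appears
#' once, ranked by its best p-value.
#'
#' @param exposure_stats list of >= 2 `sumstats` tibbles
#' @param panel a `ref_panel`
#' @inheritParams clump
#' @return An `instrument_set` over the union.
#' @export
reclump_union <- function(exposure_stats, panel, p_max = 5e-8, r2_max = 0.01,
                          window = 500000, maf_min = 0.01) {
  if (length(exposure_stats) < 2) abort("need >= 2 traits to reclump a union")
  pooled <- dplyr::bind_rows(purrr::map(exposure_stats, tibble::as_tibble))
  pooled <- pooled[pooled$pval < p_max, ]
  if (nrow(pooled) == 0) {
    abort("no variant reaches p_max in any trait", class = "mrtriad_not_computable")
  }
  best <- pooled |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::slice_min(.data$pval, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  class(best) <- unique(c("sumstats", class(best)))
  clump(best, panel, p_max = p_max, r2_max = r2_max, window = window,
        maf_min = maf_min)
}

#' Phenotypic correlation between traits from overlapping null variants
#'
#' Estimates the phenotypic correlation matrix between traits as the
#' correlation of their z-scores over variants below genome-wide interest in
#' *all* traits (p > `p_null` everywhere), after aligning every trait to the
#' first trait's effect alleles. Under sample overlap this correlation feeds
#' the per-variant genetic covariance used by the modified Q and conditional
#' F statistics (`cov_jl,i = rho_jl se_ji se_li`). With fewer than
#' `min_overlap` usable variants the identity matrix is returned with a
#' warning.
#'
#' @param exposure_stats list of `sumstats` tibbles
#' @param p_null p-value floor defining "null" variants (default 0.01)
#' @param min_overlap minimum usable variant count (default 1000)
#' @return Symmetric correlation matrix, one row/column per trait.
#' @export
build_phenotypic_covariance <- function(exposure_stats, p_null = 0.01,
                                        min_overlap = 1000) {
  k <- length(exposure_stats)
  nm <- purrr::map_chr(exposure_stats, ~ .x$trait_id[1])
  ref <- tibble::as_tibble(exposure_stats[[1]])
  aligned <- purrr::map(exposure_stats[-1], function(tr) {
    harmonise(ref, tr, palindrome_maf_max = 1)$aligned
  })
  common <- Reduce(intersect, c(list(ref$snp_id), purrr::map(aligned, "snp_id")))
  z <- matrix(NA_real_, length(common), k)
  pv <- matrix(NA_real_, length(common), k)
  ref_m <- ref[match(common, ref$snp_id), ]
  z[, 1] <- ref_m$beta / ref_m$se
  pv[, 1] <- ref_m$pval
  for (j in seq_along(aligned)) {
    a <- aligned[[j]][match(common, aligned[[j]]$snp_id), ]
    z[, j + 1] <- a$beta_out / a$se_out
    pv[, j + 1] <- a$pval_out
  }
  keep <- rowSums(pv > p_null) == k
  if (sum(keep) < min_overlap) {
    warn(paste0("only ", sum(keep), " overlapping null variants; ",
                "falling back to the identity matrix"))
    out <- diag(k)
    dimnames(out) <- list(nm, nm)
    return(out)
  }
  out <- cor(z[keep, , drop = FALSE])
  dimnames(out) <- list(nm, nm)
  out
}
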