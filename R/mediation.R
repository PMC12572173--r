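mediation_result <- function(method, beta_total, se_total, beta_direct,
                             se_direct, beta_indirect, se_indirect,
                             proportion, prop_se, usable = TRUE,
                             sign_consistent = NA) {
  ci_i <- ci_from(beta_indirect, se_indirect)
  ci_p <- if (is.na(prop_se)) c(NA_real_, NA_real_) else ci_from(proportion, prop_se)
  out <- tibble::tibble(
    method = method,
    beta_total = beta_total, se_total = se_total,
    beta_direct = beta_direct, se_direct = se_direct,
    beta_indirect = beta_indirect, se_indirect = se_indirect,
    indirect_ci_low = ci_i[1], indirect_ci_high = ci_i[2],
    indirect_pval = two_sided_p(beta_indirect / se_indirect),
    proportion_mediated = proportion, proportion_se = prop_se,
    proportion_ci_low = ci_p[1], proportion_ci_high = ci_p[2],
    usable = usable, sign_consistent = sign_consistent
  )
  class(out) <- c("mediation_result", class(out))
  out
}

#' Mediated effect by the difference method
#'
#' The mediator-transmitted share of an exposure's effect on the outcome:
#' `indirect = total - direct`, where the total effect comes from
#' univariable MR and the direct effect from multivariable MR conditioning
#' on the mediator(s). The proportion mediated is `indirect / total`. The
#' difference SE treats the two estimates as independent (two-sample
#' setting; the shared-data covariance is unavailable from summary
#' statistics, making this conservative), and the proportion's CI uses the
#' delta method. The result is flagged unusable when the MVMR fit showed
#' weak instruments or pleiotropy — the condition under which the product
#' method substitutes.
#'
#' @param total one-row `mr_result`, the univariable total effect
#' @param mvmr an `mvmr_result` containing the exposure's direct effect
#' @param obesity_trait which exposure's direct effect to use (default: the
#'   first row)
#' @return A one-row `mediation_result` tibble.
#' @export
difference_method <- function(total, mvmr, obesity_trait = NULL) {
  if (total$beta == 0) {
    abort("total effect is zero: proportion mediated undefined",
          class = "mrtriad_undefined_proportion")
  }
  est <- mvmr$estimates
  row <- if (is.null(obesity_trait)) est[1, ] else est[est$exposure == obesity_trait, ]
  if (nrow(row) != 1) abort("exposure not found in the MVMR fit")
  indirect <- total$beta - row$beta
  se_ind <- sqrt(total$se^2 + row$se^2)
  prop <- indirect / total$beta
  # proportion = 1 - direct/total; delta method, estimates independent
  prop_se <- sqrt((row$se / total$beta)^2 +
                    (row$beta * total$se / total$beta^2)^2)
  mediation_result("difference", total$beta, total$se, row$beta, row$se,
                   indirect, se_ind, prop, prop_se,
                   usable = !(mvmr$weak_flag || mvmr$pleiotropy_flag))
}

#' Mediated effect by the product method
#'
#' `indirect = beta_EM * beta_MO`: the exposure -> mediator effect times the
#' mediator -> outcome effect, both from univariable MR; the SE follows the
#' product delta method `sqrt(beta_EM^2 se_MO^2 + beta_MO^2 se_EM^2)`. The
#' proportion mediated divides by the univariable total effect, with a
#' delta-method CI. Assumes the exposure/mediator instrument sets have been
#' de-overlapped ([overlap_iv_filter()]) and the sign-consistency rule
#' evaluated ([sign_consistency_filter()]).
#'
#' @param beta_EM one-row `mr_result`, exposure -> mediator
#' @param beta_MO one-row `mr_result`, mediator -> outcome
#' @param total one-row `mr_result`, exposure -> outcome total effect
#' @return A one-row `mediation_result` tibble (with `beta_direct` of `NA`:
#'   the product method does not estimate it).
#' @export
product_method <- function(beta_EM, beta_MO, total) {
  if (total$beta == 0) {
    abort("total effect is zero: proportion mediated undefined",
          class = "mrtriad_undefined_proportion")
  }
  indirect <- beta_EM$beta * beta_MO$beta
  se_ind <- sqrt(beta_EM$beta^2 * beta_MO$se^2 + beta_MO$beta^2 * beta_EM$se^2)
  prop <- indirect / total$beta
  prop_se <- sqrt((se_ind / total$beta)^2 +
                    (indirect * total$se / total$beta^2)^2)
  keep <- sign_consistency_filter(beta_EM$beta, beta_MO$beta, total$beta)
  mediation_result("product", total$beta, total$se, NA_real_, NA_real_,
                   indirect, se_ind, prop, prop_se,
                   sign_consistent = keep$keep)
}

#' Sign-consistency filter for candidate mediators
#'
#' A mediator is kept only when the sign of its implied mediated path,
#' `sgn(beta_EM * beta_MO)`, matches the sign of the total effect
#' `beta_total` — a mediator pulling against the total effect cannot explain
#' a share of it. Any zero input excludes with reason `"zero-effect"`.
#'
#' @param beta_EM,beta_MO,beta_total the three (finite) effect estimates
#' @return List: `keep` (logical) and `reason` (`NA` when kept).
#' @export
sign_consistency_filter <- function(beta_EM, beta_MO, beta_total) {
  if (!all(is.finite(c(beta_EM, beta_MO, beta_total)))) {
    abort("all three effects must be finite")
  }
  if (beta_EM == 0 || beta_MO == 0 || beta_total == 0) {
    return(list(keep = FALSE, reason = "zero-effect"))
  }
  keep <- sign(beta_EM * beta_MO) == sign(beta_total)
  list(keep = keep, reason = if (keep) NA_character_ else "sign_mismatch")
}

#' Remove overlapping instruments between exposure and mediator
#'
#' Any exposure-instrument/mediator-instrument pair on the same chromosome
#' within `window` bp with panel r-squared at or above `r2_overlap`
#' (identical SNPs included) is an overlap: such a variant is pleiotropic
#' when estimating the exposure -> mediator effect. The member from the GWAS
#' with the larger sample size is removed, minimising power loss for the
#' smaller study; a tie removes from the exposure set, whose instrument
#' count is typically larger.
#'
#' @param exposure_ivs,mediator_ivs `instrument_set`s or character vectors
#'   of instrument ids
#' @param panel a `ref_panel` covering both sets
#' @param n_exposure,n_mediator the two GWAS sample sizes
#' @param r2_overlap overlap r² threshold (default 0.01)
#' @param window overlap window in bp (default 500,000)
#' @return List: filtered `exposure_ivs` and `mediator_ivs` (character) and
#'   a `removals` audit tibble (`snp_id, removed_from, partner, r2`).
#' @export
overlap_iv_filter <- function(exposure_ivs, mediator_ivs, panel,
                              n_exposure, n_mediator,
                              r2_overlap = 0.01, window = 500000) {
  ids_e <- if (inherits(exposure_ivs, "instrument_set")) exposure_ivs$index_snps else as.character(exposure_ivs)
  ids_m <- if (inherits(mediator_ivs, "instrument_set")) mediator_ivs$index_snps else as.character(mediator_ivs)
  v <- panel$variants
  if (!all(panel_has(panel, c(ids_e, ids_m)))) {
    abort("all instruments must be present in the panel")
  }
  ve <- v[match(ids_e, v$snp_id), ]
  vm <- v[match(ids_m, v$snp_id), ]
  removals <- tibble::tibble(snp_id = character(), removed_from = character(),
                             partner = character(), r2 = numeric())
  drop_e <- character()
  drop_m <- character()
  from_exposure <- n_exposure >= n_mediator  # tie removes from the exposure set
  for (i in seq_along(ids_e)) {
    near <- which(vm$chrom == ve$chrom[i] & abs(vm$pos - ve$pos[i]) <= window)
    if (length(near) == 0) next
    r2 <- panel_r2(panel, ids_e[i], ids_m[near])
    hit <- near[r2 >= r2_overlap | ids_m[near] == ids_e[i]]
    if (length(hit) == 0) next
    if (from_exposure) {
      drop_e <- c(drop_e, ids_e[i])
      removals <- dplyr::bind_rows(removals, tibble::tibble(
        snp_id = ids_e[i], removed_from = "exposure",
        partner = ids_m[hit[1]], r2 = unname(panel_r2(panel, ids_e[i], ids_m[hit[1]]))))
    } else {
      new_hits <- setdiff(ids_m[hit], drop_m)
      drop_m <- c(drop_m, new_hits)
      if (length(new_hits)) {
        removals <- dplyr::bind_rows(removals, tibble::tibble(
          snp_id = new_hits, removed_from = "mediator", partner = ids_e[i],
          r2 = unname(panel_r2(panel, ids_e[i], new_hits))))
      }
    }
  }
  list(exposure_ivs = setdiff(ids_e, drop_e),
       mediator_ivs = setdiff(ids_m, drop_m),
       removals = removals)
}

#' Choose between the difference and product mediation methods
#'
#' The difference method (multivariable MR) is preferred; the product method
#' substitutes when the MVMR fit shows weak instruments (any conditional
#' F < 10) or pleiotropy (modified Q p < 0.05).
#'
#' @param mvmr an `mvmr_result`
#' @return `"difference"` or `"product"`.
#' @export
select_mediation_method <- function(mvmr) {
  if (mvmr$weak_flag || mvmr$pleiotropy_flag) "product" else "difference"
}
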