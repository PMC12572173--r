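#' Pipeline thresholds and options
#'
#' Collects every analytic threshold used by the three stages, with the
#' conventional defaults: genome-wide instrument significance 5e-8, clump
#' r² 0.01 in 0.5-Mb windows, MAF floor 0.01, palindromic-MAF ceiling 0.42,
#' proxy r² 0.8 in 0.5-Mb windows, MHC exclusion
#' chr6:28,477,897-33,448,354 (GRCh37), and a shared-variant posterior gate
#' of 0.8.
#'
#' @param alpha family-wise significance level (default 0.05)
#' @param p_instr instrument p-value threshold
#' @param r2_clump,clump_window,maf_min clumping parameters
#' @param palindrome_maf palindromic-variant MAF ceiling for harmonisation
#' @param proxy_r2,proxy_window proxy-search parameters
#' @param mhc_chrom,mhc_start,mhc_end region excluded before clumping
#' @param pp_shared_min colocalisation gate on the H4 posterior
#' @param sensitivity_alpha nominal level for the sensitivity battery
#'   (heterogeneity, Egger intercept, leave-one-out, bidirectional); fixed
#'   at 0.05 by convention and deliberately separate from `alpha`
#' @param bonferroni_scope `"global"` (one correction across all tests in a
#'   stage) or `"per_outcome"`
#' @param n_boot bootstrap replicates for median/mode SEs
#' @param master_seed seed expanded into per-component streams
#' @return A `stage_config` list.
#' @export
stage_config <- function(alpha = 0.05, p_instr = 5e-8, r2_clump = 0.01,
                         clump_window = 500000, maf_min = 0.01,
                         palindrome_maf = 0.42, proxy_r2 = 0.8,
                         proxy_window = 500000, mhc_chrom = "6",
                         mhc_start = 28477897, mhc_end = 33448354,
                         pp_shared_min = 0.8, sensitivity_alpha = 0.05,
                         bonferroni_scope = c("global", "per_outcome"),
                         n_boot = 1000, master_seed = 1L) {
  structure(list(
    alpha = alpha, p_instr = p_instr, r2_clump = r2_clump,
    clump_window = clump_window, maf_min = maf_min,
    palindrome_maf = palindrome_maf, proxy_r2 = proxy_r2,
    proxy_window = proxy_window, mhc_chrom = mhc_chrom,
    mhc_start = mhc_start, mhc_end = mhc_end,
    pp_shared_min = pp_shared_min, sensitivity_alpha = sensitivity_alpha,
    bonferroni_scope = match.arg(bonferroni_scope),
    n_boot = n_boot, master_seed = as.integer(master_seed)
  ), class = "stage_config")
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / m` for `m` tests: e.g. 0.05/856 = 5.84e-5 for a screen of 856
#' harmonised metabolites, or 0.05/4 = 1.25e-2 for four mediators.
#'
#' @param alpha family-wise level
#' @param m number of tests (>= 1)
#' @return The per-test threshold.
#' @export
bonferroni_threshold <- function(alpha, m) {
  assert_count(m, "m")
  if (!(alpha > 0 && alpha <= 1)) abort("`alpha` must lie in (0, 1]")
  alpha / m
}

select_instruments <- function(stats, panel, config) {
  stats <- exclude_region(stats, config$mhc_chrom, config$mhc_start, config$mhc_end)
  clump(stats, panel, p_max = config$p_instr, r2_max = config$r2_clump,
        window = config$clump_window, maf_min = config$maf_min)
}

harmonised_for <- function(exposure, outcome, ivs, config) {
  exp_sub <- tibble::as_tibble(exposure)
  exp_sub <- exp_sub[exp_sub$snp_id %in% ivs, ]
  h <- harmonise(exp_sub, outcome, palindrome_maf_max = config$palindrome_maf)
  h$outcome_binary <- identical(outcome$trait_type[1], "binary")
  h
}

#' Stage 1: exposure-driven metabolite screen
#'
#' For each exposure: excludes the MHC region, clumps instruments, then for
#' each metabolite harmonises and runs the full MR suite (with the reverse
#' direction fitted on the metabolite's own instruments for the
#' bidirectional test). Significance is Bonferroni-corrected over the number
#' of metabolites actually harmonised per exposure. Survivors —
#' Bonferroni-significant pairs passing every sensitivity rule — are
#' labelled exposure-driven.
#'
#' @param exposure_stats named list of exposure `sumstats`
#' @param metabolite_stats named list of metabolite `sumstats`
#' @param panel a `ref_panel`
#' @param config a `stage_config`
#' @return A `screen_report`: list with `results` (one row per pair:
#'   primary estimate, sensitivity columns, `bonferroni_significant`,
#'   `survivor`), `threshold`s used, and per-pair suites in `suites`.
#' @export
run_stage1 <- function(exposure_stats, metabolite_stats, panel, config = stage_config()) {
  met_ivs <- purrr::map(metabolite_stats, ~ select_instruments(.x, panel, config))
  rows <- list()
  suites <- list()
  for (en in names(exposure_stats)) {
    ivs <- select_instruments(exposure_stats[[en]], panel, config)
    m_tested <- 0L
    for (mn in names(metabolite_stats)) {
      h <- harmonised_for(exposure_stats[[en]], metabolite_stats[[mn]], ivs$index_snps, config)
      rev_h <- harmonised_for(metabolite_stats[[mn]], exposure_stats[[en]],
                              met_ivs[[mn]]$index_snps, config)
      suite <- run_mr_suite(h, reverse = rev_h, alpha = config$sensitivity_alpha,
                            n_boot = config$n_boot, seed = config$master_seed,
                            binary = FALSE)
      if (suite$verdict != "not_testable") m_tested <- m_tested + 1L
      key <- paste(en, mn, sep = ":")
      suites[[key]] <- suite
      g <- glance(suite)
      rows[[key]] <- dplyr::mutate(g, exposure = en, metabolite = mn, .before = 1)
    }
    # Bonferroni over the harmonised (testable) metabolite count
    for (mn in names(metabolite_stats)) {
      key <- paste(en, mn, sep = ":")
      thr <- if (m_tested > 0) bonferroni_threshold(config$alpha, m_tested) else NA_real_
      rows[[key]]$bonferroni_threshold <- thr
      rows[[key]]$bonferroni_significant <- isTRUE(rows[[key]]$pval < thr)
      rows[[key]]$survivor <- rows[[key]]$bonferroni_significant &&
        identical(rows[[key]]$verdict, "pass")
    }
  }
  results <- dplyr::bind_rows(rows)
  structure(list(stage = "stage1", results = results, suites = suites,
                 config = config),
            class = "screen_report")
}

#' Stage 2: metabolite-to-outcome screen with replication and colocalisation
#'
#' For each surviving metabolite and each outcome: instruments are selected
#' as in Stage 1 (with proxy substitution from the panel when no instrument
#' survives harmonisation), the suite routes to the Wald ratio (single
#' instrument) or random-effects IVW, effects are reported as OR per SD, and
#' significance is Bonferroni-corrected (globally or per outcome, per the
#' config). Optional replication requires, in the replication dataset,
#' p below `alpha / m_replication` with the same effect direction.
#' Each instrument's ±0.5 Mb region is colocalised against the outcome;
#' the pair passes overall only if some region reaches
#' `pp_shared > pp_shared_min`.
#'
#' @param metabolite_stats named list of Stage-1 surviving metabolites
#' @param outcome_stats named list of binary outcome `sumstats`
#' @param panel a `ref_panel`
#' @param config a `stage_config`
#' @param replication_stats optional named list of replication outcome
#'   `sumstats` (names matching `outcome_stats`; missing outcomes skip
#'   replication with a log entry)
#' @return A `screen_report` whose `results` add `or_sd`, replication and
#'   colocalisation columns, and `survivor`.
#' @export
run_stage2 <- function(metabolite_stats, outcome_stats, panel,
                       config = stage_config(), replication_stats = NULL) {
  rows <- list()
  suites <- list()
  coloc_tables <- list()
  for (mn in names(metabolite_stats)) {
    met <- metabolite_stats[[mn]]
    ivs <- select_instruments(met, panel, config)
    for (on in names(outcome_stats)) {
      out <- outcome_stats[[on]]
      h <- harmonised_for(met, out, ivs$index_snps, config)
      proxy_used <- NA_character_
      if (nrow(h$aligned) == 0 && length(ivs$index_snps) > 0) {
        # no instrument survived harmonisation: try proxies in the outcome
        for (target in ivs$index_snps) {
          pr <- tryCatch(
            find_proxies(panel, target, out, r2_min = config$proxy_r2,
                         window = config$proxy_window),
            error = function(e) empty_proxy_table())
          pr <- pr[pr$snp_id %in% met$snp_id, ]
          if (nrow(pr) > 0) {
            h <- harmonised_for(met, out, pr$snp_id[1], config)
            if (nrow(h$aligned) > 0) { proxy_used <- pr$snp_id[1]; break }
          }
        }
      }
      suite <- run_mr_suite(h, alpha = config$sensitivity_alpha,
                            n_boot = config$n_boot,
                            seed = config$master_seed, binary = TRUE)
      key <- paste(mn, on, sep = ":")
      suites[[key]] <- suite
      g <- glance(suite)
      g$or_sd <- if (!is.null(suite$primary)) suite$primary$or_sd else NA_real_
      g$or_low <- if (!is.null(suite$primary)) suite$primary$or_low else NA_real_
      g$or_high <- if (!is.null(suite$primary)) suite$primary$or_high else NA_real_
      g$proxy_used <- proxy_used

      # colocalisation around each instrument region
      best_pp4 <- NA_real_
      if (!is.null(suite$primary) && nrow(h$aligned) > 0) {
        pp4s <- purrr::map_dbl(h$aligned$snp_id, function(snp) {
          tryCatch({
            r1 <- extract_region(met, snp, config$proxy_window)
            r2 <- extract_region(out, snp, config$proxy_window)
            coloc_enumerate(r1, r2)$pp_h4
          }, error = function(e) NA_real_)
        })
        best_pp4 <- if (all(is.na(pp4s))) NA_real_ else max(pp4s, na.rm = TRUE)
        coloc_tables[[key]] <- tibble::tibble(snp_id = h$aligned$snp_id, pp_h4 = pp4s)
      }
      g$coloc_pp4 <- best_pp4
      g$coloc_pass <- isTRUE(best_pp4 > config$pp_shared_min)

      # replication in an independent outcome dataset
      g$replicated <- NA
      if (!is.null(replication_stats)) {
        if (!on %in% names(replication_stats)) {
          inform(paste0("replication dataset lacks outcome '", on, "'; skipped"))
        } else if (!is.null(suite$primary)) {
          hr <- harmonised_for(met, replication_stats[[on]], ivs$index_snps, config)
          rsuite <- run_mr_suite(hr, alpha = config$sensitivity_alpha,
                                 n_boot = config$n_boot,
                                 seed = config$master_seed, binary = TRUE)
          g$replicated <- FALSE
          if (!is.null(rsuite$primary)) {
            g$rep_beta <- rsuite$primary$beta
            g$rep_pval <- rsuite$primary$pval
          }
        }
      }
      rows[[key]] <- dplyr::mutate(g, metabolite = mn, outcome = on, .before = 1)
    }
  }
  results <- dplyr::bind_rows(rows)
  m <- sum(results$verdict != "not_testable")
  if (m > 0) {
    if (config$bonferroni_scope == "global") {
      results$bonferroni_threshold <- bonferroni_threshold(config$alpha, m)
    } else {
      results <- results |>
        dplyr::group_by(.data$outcome) |>
        dplyr::mutate(bonferroni_threshold = bonferroni_threshold(
          config$alpha, max(1L, sum(.data$verdict != "not_testable")))) |>
        dplyr::ungroup()
    }
  } else {
    results$bonferroni_threshold <- NA_real_
  }
  results$bonferroni_significant <- !is.na(results$pval) &
    results$pval < results$bonferroni_threshold
  if ("rep_pval" %in% names(results)) {
    m_rep <- sum(!is.na(results$rep_pval))
    rep_thr <- if (m_rep > 0) bonferroni_threshold(config$alpha, m_rep) else NA_real_
    results$replicated <- ifelse(
      is.na(results$rep_pval), results$replicated,
      results$rep_pval < rep_thr & sign(results$rep_beta) == sign(results$beta))
  }
  results$survivor <- results$bonferroni_significant &
    results$verdict == "pass" &
    results$coloc_pass &
    (is.na(results$replicated) | results$replicated)
  structure(list(stage = "stage2", results = results, suites = suites,
                 coloc = coloc_tables, config = config),
            class = "screen_report")
}

#' Stage 3: mediation of the exposure-outcome effect by metabolites
#'
#' For each exposure-outcome pair: the univariable total effect is estimated
#' and gated by Bonferroni over the number of such pairs; mediators failing
#' the sign-consistency rule are excluded; the exposure and mediator
#' instrument sets are de-overlapped; MVMR over the reclumped union yields
#' the direct effect, and [select_mediation_method()] picks the difference
#' or product method per pair. Instruments on a user-supplied pleiotropy
#' exclusion list are removed up front and every estimate computed without
#' them.
#'
#' @param exposure_stats named list of exposure `sumstats`
#' @param mediator_stats named list of Stage-2 surviving metabolites
#' @param outcome_stats named list of outcome `sumstats`
#' @param panel a `ref_panel`
#' @param config a `stage_config`
#' @param exclusion_list character vector of instrument ids with known
#'   pleiotropic associations, removed before analysis
#' @return List with `mediation` (tibble: one row per
#'   exposure-mediator-outcome triple) and `totals` (per exposure-outcome
#'   total effects and their Bonferroni verdicts).
#' @export
run_stage3 <- function(exposure_stats, mediator_stats, outcome_stats, panel,
                       config = stage_config(), exclusion_list = character()) {
  drop_excluded <- function(stats) {
    out <- tibble::as_tibble(stats)
    out[!out$snp_id %in% exclusion_list, ]
  }
  exposure_stats <- purrr::map(exposure_stats, drop_excluded)
  mediator_stats <- purrr::map(mediator_stats, drop_excluded)

  totals <- list()
  for (en in names(exposure_stats)) {
    ivs <- select_instruments(exposure_stats[[en]], panel, config)
    for (on in names(outcome_stats)) {
      h <- harmonised_for(exposure_stats[[en]], outcome_stats[[on]],
                          ivs$index_snps, config)
      res <- if (nrow(h$aligned) >= 2) ivw(h, "random", binary = TRUE) else
        if (nrow(h$aligned) == 1) wald_ratio(h$aligned$beta_exp, h$aligned$se_exp,
                                             h$aligned$beta_out, h$aligned$se_out,
                                             binary = TRUE) else NULL
      if (is.null(res)) next
      totals[[paste(en, on, sep = ":")]] <- dplyr::mutate(
        res, exposure = en, outcome = on, .before = 1)
    }
  }
  totals <- dplyr::bind_rows(totals)
  if (nrow(totals) > 0) {
    thr <- bonferroni_threshold(config$alpha, nrow(totals))
    totals$bonferroni_threshold <- thr
    totals$taken_forward <- totals$pval < thr
  }

  med_rows <- list()
  for (i in seq_len(nrow(totals))) {
    if (!totals$taken_forward[i]) next
    en <- totals$exposure[i]
    on <- totals$outcome[i]
    total_res <- totals[i, ]
    for (mn in names(mediator_stats)) {
      med <- mediator_stats[[mn]]
      exp_ivs <- select_instruments(exposure_stats[[en]], panel, config)
      med_ivs <- select_instruments(med, panel, config)

      # beta_EM and beta_MO from univariable MR (with de-overlapped IVs)
      flt <- overlap_iv_filter(exp_ivs, med_ivs, panel,
                               n_exposure = exposure_stats[[en]]$n[1],
                               n_mediator = med$n[1],
                               r2_overlap = config$r2_clump,
                               window = config$clump_window)
      h_em <- harmonised_for(exposure_stats[[en]], med, flt$exposure_ivs, config)
      h_mo <- harmonised_for(med, outcome_stats[[on]], flt$mediator_ivs, config)
      if (nrow(h_em$aligned) == 0 || nrow(h_mo$aligned) == 0) next
      b_em <- if (nrow(h_em$aligned) >= 2) ivw(h_em, "random") else
        wald_ratio(h_em$aligned$beta_exp, h_em$aligned$se_exp,
                   h_em$aligned$beta_out, h_em$aligned$se_out)
      b_mo <- if (nrow(h_mo$aligned) >= 2) ivw(h_mo, "random", binary = TRUE) else
        wald_ratio(h_mo$aligned$beta_exp, h_mo$aligned$se_exp,
                   h_mo$aligned$beta_out, h_mo$aligned$se_out, binary = TRUE)

      sgn <- sign_consistency_filter(b_em$beta, b_mo$beta, total_res$beta)
      if (!sgn$keep) {
        med_rows[[paste(en, mn, on, sep = ":")]] <- tibble::tibble(
          exposure = en, mediator = mn, outcome = on, method = "excluded",
          exclusion_reason = sgn$reason)
        next
      }

      mv <- tryCatch({
        union_ivs <- reclump_union(list(exposure_stats[[en]], med), panel,
                                   p_max = config$p_instr,
                                   r2_max = config$r2_clump,
                                   window = config$clump_window,
                                   maf_min = config$maf_min)
        rho <- suppressWarnings(build_phenotypic_covariance(
          list(exposure_stats[[en]], med)))
        mvmr_ivw(list(exposure_stats[[en]], med), outcome_stats[[on]],
                 union_ivs, covariance = rho)
      }, error = function(e) NULL)

      method <- if (is.null(mv)) "product" else select_mediation_method(mv)
      res <- if (method == "difference") {
        difference_method(total_res, mv, obesity_trait = exposure_stats[[en]]$trait_id[1])
      } else {
        product_method(b_em, b_mo, total_res)
      }
      med_rows[[paste(en, mn, on, sep = ":")]] <- dplyr::mutate(
        res, exposure = en, mediator = mn, outcome = on, .before = 1,
        conditional_F_min = if (is.null(mv)) NA_real_ else min(mv$estimates$conditional_F),
        mvmr_Q_pval = if (is.null(mv)) NA_real_ else mv$Q_pval)
    }
  }
  structure(list(stage = "stage3", totals = totals,
                 mediation = dplyr::bind_rows(med_rows), config = config),
            class = "mediation_report")
}

#' Assemble report tables from stage outputs
#'
#' Produces the tabular bundle downstream consumers read: a volcano-style
#' table (one row per tested pair: effect, p-value, significance), a
#' forest-style table for survivors (OR per SD with CI and instrument
#' count), and the mediation table when Stage 3 ran. Ordering is
#' deterministic (by identifiers), and every number is copied from a stage
#' result.
#'
#' @param ... `screen_report` / `mediation_report` objects from the stage
#'   runners
#' @return Named list of tibbles: `volcano`, `forest`, `mediation` (present
#'   when the corresponding stage outputs were supplied; empty tables keep
#'   their headers).
#' @export
make_report <- function(...) {
  reports <- list(...)
  if (length(reports) == 0) abort("at least one stage report is required")
  volcano <- tibble::tibble(exposure = character(), outcome = character(),
                            beta = numeric(), pval = numeric(),
                            significant = logical())
  forest <- tibble::tibble(exposure = character(), outcome = character(),
                           or_sd = numeric(), or_low = numeric(),
                           or_high = numeric(), n_snp = integer())
  mediation <- tibble::tibble()
  for (rp in reports) {
    if (inherits(rp, "screen_report")) {
      r <- rp$results
      exposure_col <- if ("exposure" %in% names(r)) r$exposure else r$metabolite
      outcome_col <- if ("outcome" %in% names(r)) r$outcome else r$metabolite
      volcano <- dplyr::bind_rows(volcano, tibble::tibble(
        exposure = exposure_col, outcome = outcome_col,
        beta = r$beta, pval = r$pval,
        significant = r$bonferroni_significant %||% NA))
      if ("or_sd" %in% names(r)) {
        surv <- r[isTRUE_v(r$survivor), ]
        if (nrow(surv) > 0) {
          forest <- dplyr::bind_rows(forest, tibble::tibble(
            exposure = surv$metabolite, outcome = surv$outcome,
            or_sd = surv$or_sd, or_low = surv$or_low, or_high = surv$or_high,
            n_snp = as.integer(surv$n_snp)))
        }
      }
    } else if (inherits(rp, "mediation_report")) {
      mediation <- dplyr::bind_rows(mediation, rp$mediation)
    }
  }
  volcano <- dplyr::arrange(volcano, .data$exposure, .data$outcome)
  forest <- dplyr::arrange(forest, .data$exposure, .data$outcome)
  list(volcano = volcano, forest = forest, mediation = mediation)
}

isTRUE_v <- function(x) !is.na(x) & x

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report> ", x$stage, ": ", nrow(x$results), " pairs, ",
      sum(isTRUE_v(x$results$survivor)), " survivors\n", sep = "")
  invisible(x)
}

#' @export
tidy.screen_report <- function(x, ...) x$results
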