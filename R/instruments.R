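#' Remove variants inside a genomic region
#'
#' Drops every variant whose position falls inside the closed interval
#' `[start, end]` on `chrom`. The canonical use is excluding the major
#' histocompatibility complex (chr6:28,477,897-33,448,354, GRCh37) before
#' instrument selection, because its extreme LD and pervasive pleiotropy
#' violate the instrumental-variable assumptions.
#'
#' @param stats a `sumstats` tibble
#' @param chrom chromosome label (default `"6"`)
#' @param start,end closed-interval bounds in bp (defaults: the MHC region)
#' @return The filtered `sumstats` tibble.
#' @export
exclude_region <- function(stats, chrom = "6", start = 28477897, end = 33448354) {
  if (start > end) abort("`start` must be <= `end`")
  stats <- tibble::as_tibble(stats)
  drop <- stats$chrom == as.character(chrom) & stats$pos >= start & stats$pos <= end
  out <- stats[!drop, ]
  class(out) <- unique(c("sumstats", class(out)))
  out
}

#' Greedy LD clumping of significant variants
#'
#' Selects an approximately independent set of instruments: variants with
#' `pval < p_max` and minor-allele frequency above `maf_min` are sorted by
#' ascending p-value (ties broken by smaller position, then lexicographic
#' variant id); the best remaining variant becomes an index SNP and every
#' remaining variant within `window` bp on the same chromosome with panel
#' dosage r-squared >= `r2_max` is pruned and recorded against it. Variants
#' absent from the panel are excluded with a logged reason.
#'
#' @param stats a `sumstats` tibble
#' @param panel a `ref_panel` supplying dosage correlations
#' @param p_max association threshold (default genome-wide, 5e-8)
#' @param r2_max LD pruning threshold (default 0.01)
#' @param window pruning window in bp (default 500,000)
#' @param maf_min minor-allele-frequency floor (default 0.01)
#' @return An `instrument_set`: list with `index_snps` (character),
#'   `clump_audit` (tibble `snp_id, index_snp, r2, reason`), and
#'   `thresholds`.
#' @export
clump <- function(stats, panel, p_max = 5e-8, r2_max = 0.01,
                  window = 500000, maf_min = 0.01) {
  stats <- tibble::as_tibble(stats)
  maf <- pmin(stats$eaf, 1 - stats$eaf)
  elig <- stats[stats$pval < p_max & maf > maf_min, ]
  in_panel <- panel_has(panel, elig$snp_id)
  audit <- tibble::tibble(
    snp_id = elig$snp_id[!in_panel], index_snp = NA_character_,
    r2 = NA_real_, reason = rep("absent_from_panel", sum(!in_panel))
  )
  elig <- elig[in_panel, ]
  elig <- elig[order(elig$pval, elig$pos, elig$snp_id), ]

  index_snps <- character()
  while (nrow(elig) > 0) {
    top <- elig[1, ]
    index_snps <- c(index_snps, top$snp_id)
    rest <- elig[-1, ]
    if (nrow(rest) == 0) break
    near <- rest$chrom == top$chrom & abs(rest$pos - top$pos) <= window
    pruned <- rep(FALSE, nrow(rest))
    if (any(near)) {
      r2 <- panel_r2(panel, top$snp_id, rest$snp_id[near])
      pruned[near] <- r2 >= r2_max
    }
    if (any(pruned)) {
      audit <- dplyr::bind_rows(audit, tibble::tibble(
        snp_id = rest$snp_id[pruned], index_snp = top$snp_id,
        r2 = unname(panel_r2(panel, top$snp_id, rest$snp_id[pruned])),
        reason = "pruned"
      ))
    }
    elig <- rest[!pruned, ]
  }
  structure(list(index_snps = index_snps, clump_audit = audit,
                 thresholds = list(p_max = p_max, r2_max = r2_max,
                                   window = window, maf_min = maf_min)),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("<instrument_set> ", length(x$index_snps), " index SNPs (",
      sum(x$clump_audit$reason == "pruned", na.rm = TRUE), " pruned)\n", sep = "")
  invisible(x)
}

#' Instrument-strength F-statistics
#'
#' Per-instrument F is the squared z-score of the instrument-exposure
#' association, `(beta_exp / se_exp)^2`. The conventional weak-instrument
#' flag is raised when the minimum F falls below 10; the mean is reported
#' alongside.
#'
#' @param h a `harmonised_set` (or aligned tibble with `beta_exp`, `se_exp`)
#' @return Tibble with one row: `min_F, mean_F, n_snp, weak_flag`, and the
#'   per-instrument values in the `per_snp` list-column.
#' @export
instrument_strength <- function(h) {
  a <- as_aligned(h)
  if (nrow(a) == 0) abort("no aligned instruments")
  f <- (a$beta_exp / a$se_exp)^2
  tibble::tibble(
    min_F = min(f), mean_F = mean(f), n_snp = nrow(a),
    weak_flag = min(f) < 10,
    per_snp = list(tibble::tibble(snp_id = a$snp_id, F = f))
  )
}

#' Post-hoc power for a two-sample MR test
#'
#' Asymptotic two-sided power of the Wald test of a causal effect, given the
#' variance in the exposure explained by the instruments. For a binary
#' outcome with case fraction `phi = n_cases / N`,
#' `power = Phi(sqrt(N r2 phi (1-phi)) |log OR_SD| - z_{1-alpha/2})`.
#' The quantitative-outcome analogue replaces the binary non-centrality with
#' `sqrt(N r2) |beta|`.
#'
#' @param n_cases,n_controls outcome GWAS counts
#' @param r2_exposure fraction of exposure variance explained by the
#'   instruments, in (0, 1)
#' @param or_sd odds ratio per SD of the exposure (> 0)
#' @param alpha two-sided significance level, in (0, 1)
#' @return Power in \[0, 1\].
#' @export
mr_power <- function(n_cases, n_controls, r2_exposure, or_sd, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must lie in (0, 1)")
  assert_fraction(r2_exposure, "r2_exposure", 0, 1, open_lo = TRUE, open_hi = TRUE)
  if (!is.numeric(or_sd) || any(or_sd <= 0)) abort("`or_sd` must be positive")
  n <- n_cases + n_controls
  phi <- n_cases / n
  ncp <- sqrt(n * r2_exposure * phi * (1 - phi)) * abs(log(or_sd))
  pnorm(ncp - qnorm(1 - alpha / 2))
}

#' @rdname mr_power
#' @param n_total quantitative outcome GWAS sample size
#' @param beta_sd causal effect in SD units
#' @export
mr_power_quantitative <- function(n_total, r2_exposure, beta_sd, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must lie in (0, 1)")
  assert_fraction(r2_exposure, "r2_exposure", 0, 1, open_lo = TRUE, open_hi = TRUE)
  pnorm(sqrt(n_total * r2_exposure) * abs(beta_sd) - qnorm(1 - alpha / 2))
}
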