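#' Locus-scaled colocalisation priors
#'
#' Per-SNP prior probabilities scaled to the locus size:
#' `p1 = p2 = 1 / (10 * n_snps)` for a variant being associated with one
#' trait only, and `p12 = p1 / 10` for association with both. Scaling by the
#' SNP count keeps the prior probability that the locus harbours a causal
#' variant roughly constant across loci of different density.
#'
#' @param n_snps number of shared variants in the locus (>= 1)
#' @return A `coloc_priors` list: `p1, p2, p12`.
#' @export
locus_priors <- function(n_snps) {
  assert_count(n_snps, "n_snps")
  p1 <- 1 / (10 * n_snps)
  new_coloc_priors(p1, p1, p1 / 10)
}

new_coloc_priors <- function(p1, p2, p12) {
  if (!(p12 > 0 && p12 <= min(p1, p2))) abort("need 0 < p12 <= min(p1, p2)")
  if (p1 + p2 + p12 >= 1) abort("p1 + p2 + p12 must be < 1")
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

#' Wakefield approximate Bayes factor (log scale)
#'
#' For an estimate with variance `V = se^2` and a normal prior with
#' standard deviation `prior_sd` on the true effect, the log approximate
#' Bayes factor in favour of association is
#' `0.5 log(1 - r) + 0.5 r z^2` with `r = W / (V + W)`, `W = prior_sd^2`,
#' `z = beta / se`. The default prior SD is 0.20 per SD for quantitative
#' traits and 0.15 on the log-odds scale for binary traits.
#'
#' @param beta,se effect estimate and standard error (`se > 0`)
#' @param trait_type `"quantitative"` or `"binary"` (sets the default prior)
#' @param prior_sd prior effect-size SD (> 0); overrides the default
#' @return Log Bayes factor (vectorised over `beta`, `se`).
#' @export
wakefield_abf <- function(beta, se, trait_type = "quantitative",
                          prior_sd = NULL) {
  prior_sd <- prior_sd %||% if (trait_type == "binary") 0.15 else 0.20
  if (any(prior_sd <= 0)) abort("`prior_sd` must be positive")
  if (any(se <= 0)) abort("`se` must be positive")
  r <- prior_sd^2 / (se^2 + prior_sd^2)
  0.5 * log(1 - r) + 0.5 * r * (beta / se)^2
}

#' Extract a region around a centre variant
#'
#' Same-chromosome variants whose position lies within `half_window` bp of
#' the centre variant (closed interval), the unit on which enumeration
#' colocalisation operates (conventionally +/- 0.5 Mb around an instrument).
#'
#' @param stats a `sumstats` tibble containing `center`
#' @param center `snp_id` of the centre variant
#' @param half_window half-width in bp (default 500,000)
#' @return The regional `sumstats` tibble.
#' @export
extract_region <- function(stats, center, half_window = 500000) {
  stats <- tibble::as_tibble(stats)
  c_row <- stats[stats$snp_id == center, ]
  if (nrow(c_row) == 0) {
    abort(paste0("centre variant '", center, "' not found"),
          class = "mrtriad_lookup_error")
  }
  out <- stats[stats$chrom == c_row$chrom[1] &
                 abs(stats$pos - c_row$pos[1]) <= half_window, ]
  class(out) <- unique(c("sumstats", class(out)))
  out
}

# intersect two regional sumstats on snp_id; alignment to a shared effect
# allele is performed for bookkeeping, but posteriors depend on z^2 only
intersect_regions <- function(region1, region2) {
  h <- harmonise(region1, region2, palindrome_maf_max = 1)
  h$aligned
}

#' Enumeration colocalisation of two traits in a region
#'
#' Single-causal-variant enumeration over the shared variants: per-SNP
#' Wakefield log-ABFs for each trait combine into the likelihoods of the
#' five hypotheses — H0 no association; H1/H2 association with one trait
#' only; H3 both traits, different causal variants; H4 both traits, one
#' shared causal variant — weighted by the per-SNP priors and normalised.
#' All sums run through log-sum-exp, so extreme z-scores do not overflow.
#'
#' @param region1,region2 regional `sumstats` tibbles; intersected on
#'   `snp_id` (variants missing in either trait are dropped)
#' @param priors a `coloc_priors`; default `locus_priors(n shared variants)`
#' @param prior_sd1,prior_sd2 optional effect-size prior SDs per trait
#'   (defaults by trait type: 0.20 quantitative, 0.15 binary)
#' @return A `coloc_result`: tibble with one row — `pp_h0 ... pp_h4`,
#'   `pp_shared` (= `pp_h4`), `n_snps`, `p1, p2, p12`, `top_shared_snp`
#'   (largest per-SNP H4 contribution) — with the per-SNP H4 contributions
#'   in the `h4_contrib` list-column.
#' @export
coloc_enumerate <- function(region1, region2, priors = NULL,
                            prior_sd1 = NULL, prior_sd2 = NULL) {
  region1 <- tibble::as_tibble(region1)
  region2 <- tibble::as_tibble(region2)
  shared <- intersect_regions(region1, region2)
  if (nrow(shared) == 0) {
    abort("no shared variants between the two regions",
          class = "mrtriad_not_computable")
  }
  priors <- priors %||% locus_priors(nrow(shared))
  type1 <- region1$trait_type[1] %||% "quantitative"
  type2 <- region2$trait_type[1] %||% "quantitative"
  l1 <- wakefield_abf(shared$beta_exp, shared$se_exp, type1, prior_sd1)
  l2 <- wakefield_abf(shared$beta_out, shared$se_out, type2, prior_sd2)

  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  # sum over i != j of exp(l1_i + l2_j) = sum_i sum_j - sum_i (i = j)
  both <- s1 + s2
  s3 <- if (both > s12) both + log1p(-exp(s12 - both)) else -Inf

  lh <- c(h0 = 0,
          h1 = log(priors$p1) + s1,
          h2 = log(priors$p2) + s2,
          h3 = log(priors$p1) + log(priors$p2) + s3,
          h4 = log(priors$p12) + s12)
  denom <- logsumexp(lh)
  pp <- exp(lh - denom)

  h4_contrib <- exp(l1 + l2 - s12)
  out <- tibble::tibble(
    pp_h0 = pp[["h0"]], pp_h1 = pp[["h1"]], pp_h2 = pp[["h2"]],
    pp_h3 = pp[["h3"]], pp_h4 = pp[["h4"]], pp_shared = pp[["h4"]],
    n_snps = nrow(shared),
    p1 = priors$p1, p2 = priors$p2, p12 = priors$p12,
    top_shared_snp = shared$snp_id[which.max(h4_contrib)],
    h4_contrib = list(tibble::tibble(snp_id = shared$snp_id,
                                     contribution = h4_contrib))
  )
  class(out) <- c("coloc_result", class(out))
  out
}

#' Sensitivity of the shared-variant posterior to the p12 prior
#'
#' Recomputes the enumeration posteriors over a grid of `p12` values with
#' `p1` and `p2` fixed, tracing how `pp_shared` responds to the prior on a
#' shared causal variant; on fixed data the curve is monotone non-decreasing
#' in `p12`. Grid points violating the prior constraints
#' (`0 < p12 <= min(p1, p2)`) are skipped with a warning.
#'
#' @param region1,region2 regional `sumstats` tibbles
#' @param p12_grid numeric vector of `p12` values; default 8 log-spaced
#'   points from 1e-8 up to `min(p1, p2)`
#' @param priors base `coloc_priors` fixing `p1`, `p2`
#' @return Tibble with one row per retained grid point: `p12`, `pp_shared`,
#'   and all five posteriors.
#' @export
coloc_sensitivity <- function(region1, region2, p12_grid = NULL, priors = NULL) {
  shared_n <- nrow(intersect_regions(region1, region2))
  base <- priors %||% locus_priors(max(shared_n, 1))
  p12_grid <- p12_grid %||% exp(seq(log(1e-8), log(min(base$p1, base$p2)),
                                    length.out = 8))
  purrr::map_dfr(p12_grid, function(p12) {
    ok <- tryCatch({
      pr <- new_coloc_priors(base$p1, base$p2, p12)
      res <- coloc_enumerate(region1, region2, pr)
      dplyr::select(res, "p12", dplyr::starts_with("pp_"), "n_snps")
    }, error = function(e) {
      warn(paste0("skipping p12 = ", signif(p12, 3), ": ", conditionMessage(e)))
      NULL
    })
    ok
  })
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "<coloc_result> n_snps=%d  PP: H0=%.3f H1=%.3f H2=%.3f H3=%.3f H4=%.3f\n",
    x$n_snps, x$pp_h0, x$pp_h1, x$pp_h2, x$pp_h3, x$pp_h4))
  cat("  top shared variant:", x$top_shared_snp, "\n")
  invisible(x)
}
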