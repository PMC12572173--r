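#' Harmonise exposure and outcome summary statistics to a shared effect allele
#'
#' Aligns every exposure variant with its record in the outcome GWAS so both
#' effect sizes refer to the same effect allele. Same-order alleles pass
#' through; swapped alleles flip the outcome beta's sign and replace its EAF
#' by `1 - eaf`; strand-flipped alleles (A<->T, C<->G complements) are
#' re-labelled and then the same rules apply. Palindromic variants (A/T or
#' C/G), whose strand cannot be resolved from the alleles, are excluded as
#' ambiguous when the exposure minor-allele frequency exceeds
#' `palindrome_maf_max`; at or below that threshold their orientation is
#' inferred from EAF concordance (whichever of `eaf_out` and `1 - eaf_out`
#' lies closer to `eaf_exp`; an exact tie excludes the variant).
#'
#' @param exposure,outcome `sumstats` tibbles
#' @param palindrome_maf_max palindromic variants with exposure MAF above
#'   this are dropped as ambiguous (default 0.42)
#' @return A `harmonised_set`: list with `aligned` (tibble of
#'   `snp_id, chrom, pos, effect_allele, other_allele, beta_exp, se_exp,
#'   pval_exp, eaf_exp, beta_out, se_out, pval_out, eaf_out`),
#'   `exclusions` (tibble of `snp_id, reason`), and the two trait labels.
#'   Every exposure variant appears exactly once across
#'   `aligned` and `exclusions`.
#' @export
harmonise <- function(exposure, outcome, palindrome_maf_max = 0.42) {
  exposure <- tibble::as_tibble(exposure)
  outcome <- tibble::as_tibble(outcome)

  dup_exp <- unique(exposure$snp_id[duplicated(exposure$snp_id)])
  dup_out <- unique(outcome$snp_id[duplicated(outcome$snp_id)])
  dup_ids <- union(dup_exp, dup_out)

  exp1 <- exposure[!exposure$snp_id %in% dup_ids, ]
  out1 <- outcome[!outcome$snp_id %in% dup_ids, ]

  merged <- dplyr::inner_join(
    dplyr::select(exp1, "snp_id", "chrom", "pos",
                  ea_exp = "effect_allele", oa_exp = "other_allele",
                  beta_exp = "beta", se_exp = "se", pval_exp = "pval",
                  eaf_exp = "eaf", n_exp = "n"),
    dplyr::select(out1, "snp_id",
                  ea_out = "effect_allele", oa_out = "other_allele",
                  beta_out = "beta", se_out = "se", pval_out = "pval",
                  eaf_out = "eaf", n_out = "n"),
    by = "snp_id"
  )

  absent <- setdiff(exp1$snp_id, out1$snp_id)
  exclusions <- tibble::tibble(
    snp_id = c(intersect(unique(exposure$snp_id), dup_ids), absent),
    reason = c(rep("duplicate", length(intersect(unique(exposure$snp_id), dup_ids))),
               rep("absent_in_outcome", length(absent)))
  )

  if (nrow(merged) == 0) {
    return(new_harmonised_set(empty_aligned(), exclusions,
                              exposure$trait_id[1], outcome$trait_id[1]))
  }

  pal <- is_palindromic(merged$ea_exp, merged$oa_exp)

  same <- merged$ea_out == merged$ea_exp & merged$oa_out == merged$oa_exp
  swap <- merged$ea_out == merged$oa_exp & merged$oa_out == merged$ea_exp
  # after strand complement of the outcome labels (non-palindromic only)
  ea_out_c <- flip_allele(merged$ea_out)
  oa_out_c <- flip_allele(merged$oa_out)
  same_c <- ea_out_c == merged$ea_exp & oa_out_c == merged$oa_exp
  swap_c <- ea_out_c == merged$oa_exp & oa_out_c == merged$ea_exp

  flip <- rep(NA, nrow(merged)) # TRUE: flip outcome beta/eaf; NA: exclude
  reason <- rep(NA_character_, nrow(merged))

  npal <- !pal
  flip[npal & same] <- FALSE
  flip[npal & swap] <- TRUE
  flip[npal & !same & !swap & same_c] <- FALSE
  flip[npal & !same & !swap & swap_c] <- TRUE
  reason[npal & is.na(flip)] <- "allele_mismatch"

  if (any(pal)) {
    # palindromes: allele labels cannot distinguish swap from strand flip
    maf_exp <- pmin(merged$eaf_exp, 1 - merged$eaf_exp)
    mismatch <- pal & !(same | swap) # e.g. A/T in one study, C/G in the other
    reason[mismatch] <- "allele_mismatch"
    ambiguous <- pal & !mismatch & maf_exp > palindrome_maf_max
    reason[ambiguous] <- "ambiguous_palindrome"
    infer <- pal & !mismatch & !ambiguous
    d_keep <- abs(merged$eaf_exp - merged$eaf_out)
    d_flip <- abs(merged$eaf_exp - (1 - merged$eaf_out))
    flip[infer & d_keep < d_flip] <- FALSE
    flip[infer & d_flip < d_keep] <- TRUE
    reason[infer & d_keep == d_flip] <- "ambiguous_palindrome"
  }

  dropped <- !is.na(reason)
  exclusions <- dplyr::bind_rows(
    exclusions,
    tibble::tibble(snp_id = merged$snp_id[dropped], reason = reason[dropped])
  )
  kept <- merged[!dropped, ]
  fl <- flip[!dropped]

  aligned <- tibble::tibble(
    snp_id = kept$snp_id, chrom = kept$chrom, pos = kept$pos,
    effect_allele = kept$ea_exp, other_allele = kept$oa_exp,
    beta_exp = kept$beta_exp, se_exp = kept$se_exp, pval_exp = kept$pval_exp,
    eaf_exp = kept$eaf_exp,
    beta_out = ifelse(fl, -kept$beta_out, kept$beta_out),
    se_out = kept$se_out, pval_out = kept$pval_out,
    eaf_out = ifelse(fl, 1 - kept$eaf_out, kept$eaf_out),
    n_exp = kept$n_exp, n_out = kept$n_out
  )

  new_harmonised_set(aligned, exclusions, exposure$trait_id[1], outcome$trait_id[1])
}

empty_aligned <- function() {
  tibble::tibble(
    snp_id = character(), chrom = character(), pos = integer(),
    effect_allele = character(), other_allele = character(),
    beta_exp = numeric(), se_exp = numeric(), pval_exp = numeric(),
    eaf_exp = numeric(), beta_out = numeric(), se_out = numeric(),
    pval_out = numeric(), eaf_out = numeric(),
    n_exp = numeric(), n_out = numeric()
  )
}

new_harmonised_set <- function(aligned, exclusions, exposure_id, outcome_id) {
  structure(
    list(aligned = aligned, exclusions = exclusions,
         exposure_id = exposure_id %||% NA_character_,
         outcome_id = outcome_id %||% NA_character_),
    class = "harmonised_set"
  )
}

#' @export
print.harmonised_set <- function(x, ...) {
  cat("<harmonised_set> ", x$exposure_id, " -> ", x$outcome_id, "\n", sep = "")
  cat("  aligned variants: ", nrow(x$aligned), "\n", sep = "")
  if (nrow(x$exclusions) > 0) {
    tab <- table(x$exclusions$reason)
    cat("  excluded: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# Accept either a harmonised_set or a plain tibble with the aligned columns
as_aligned <- function(h) {
  if (inherits(h, "harmonised_set")) return(h$aligned)
  tibble::as_tibble(h)
}

#' @importFrom generics tidy
#' @export
tidy.harmonised_set <- function(x, ...) x$aligned

#' @importFrom generics glance
#' @export
glance.harmonised_set <- function(x, ...) {
  tibble::tibble(
    exposure_id = x$exposure_id, outcome_id = x$outcome_id,
    n_aligned = nrow(x$aligned), n_excluded = nrow(x$exclusions)
  )
}
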