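#' GWAS summary statistics as a tibble
#'
#' A `sumstats` table holds one trait's per-variant GWAS summary records:
#' one row per variant with the effect estimate on the standard-deviation
#' scale for quantitative traits or the log-odds scale for binary traits.
#' All genomic coordinates are 1-based GRCh37.
#'
#' @param snp_id variant identifiers (unique within a trait)
#' @param chrom chromosome labels
#' @param pos base-pair positions (1-based, GRCh37)
#' @param effect_allele,other_allele single-base alleles (A/C/G/T)
#' @param eaf effect-allele frequency in (0, 1)
#' @param beta effect size (per SD for quantitative traits, log odds for binary)
#' @param se positive standard error
#' @param pval two-sided p-value in (0, 1]
#' @param n sample size
#' @param trait_id trait label
#' @param trait_type `"quantitative"` or `"binary"`
#' @param ncase,ncontrol optional case/control counts for binary traits
#'
#' @return A tibble with class `sumstats`.
#' @export
sumstats <- function(snp_id, chrom, pos, effect_allele, other_allele, eaf,
                     beta, se, pval, n, trait_id, trait_type = "quantitative",
                     ncase = NA_real_, ncontrol = NA_real_) {
  out <- tibble::tibble(
    snp_id = as.character(snp_id), chrom = as.character(chrom),
    pos = as.integer(pos),
    effect_allele = toupper(as.character(effect_allele)),
    other_allele = toupper(as.character(other_allele)),
    eaf = as.numeric(eaf), beta = as.numeric(beta), se = as.numeric(se),
    pval = as.numeric(pval), n = as.numeric(n),
    trait_id = as.character(trait_id), trait_type = as.character(trait_type),
    ncase = as.numeric(ncase), ncontrol = as.numeric(ncontrol)
  )
  class(out) <- c("sumstats", class(out))
  out
}

SUMSTATS_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n", "trait_id", "trait_type",
                   "ncase", "ncontrol")

# Canonical on-disk column order for the TSV dialect
TSV_DIALECT <- c(
  snp_id = "SNP", chrom = "CHR", pos = "POS", effect_allele = "EA",
  other_allele = "OA", eaf = "EAF", beta = "BETA", se = "SE", pval = "P",
  n = "N", ncase = "NCASE", ncontrol = "NCONTROL"
)

#' Validate summary statistics, rejecting rows that break invariants
#'
#' Enforces the per-record invariants: positive standard errors, distinct
#' alleles, frequencies strictly inside (0, 1), p-values in (0, 1], unique
#' variant identifiers, and (when both are present) consistency of the
#' p-value with the two-sided normal p implied by `beta/se` within 10%
#' relative tolerance. Offending rows are dropped, not fatal.
#'
#' @param stats a `sumstats` tibble (or data frame with the same columns)
#' @return The validated `sumstats` tibble, with an attribute
#'   `"rejections"`: a tibble of `(snp_id, reason)` for every dropped row.
#' @export
validate_sumstats <- function(stats) {
  stats <- tibble::as_tibble(stats)
  missing_cols <- setdiff(setdiff(SUMSTATS_COLS, c("ncase", "ncontrol")), names(stats))
  if (length(missing_cols) > 0) {
    abort(paste0("missing mandatory column(s): ", paste(missing_cols, collapse = ", ")),
          class = "mrtriad_format_error")
  }
  if (!"ncase" %in% names(stats)) stats$ncase <- NA_real_
  if (!"ncontrol" %in% names(stats)) stats$ncontrol <- NA_real_
  stats <- dplyr::select(stats, dplyr::all_of(SUMSTATS_COLS))

  reason <- rep(NA_character_, nrow(stats))
  bad <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  core_na <- !complete.cases(stats[, c("snp_id", "chrom", "pos", "effect_allele",
                                       "other_allele", "eaf", "beta", "se", "pval", "n")])
  reason <- bad(core_na, "missing_value")
  reason <- bad(!(stats$se > 0), "nonpositive_se")
  reason <- bad(stats$effect_allele == stats$other_allele, "identical_alleles")
  reason <- bad(!(stats$effect_allele %in% names(COMPLEMENT)) |
                  !(stats$other_allele %in% names(COMPLEMENT)), "invalid_allele")
  reason <- bad(!(stats$eaf > 0 & stats$eaf < 1), "eaf_out_of_range")
  reason <- bad(!(stats$pval > 0 & stats$pval <= 1), "pval_out_of_range")
  p_implied <- two_sided_p(stats$beta / stats$se)
  inconsistent <- is.finite(p_implied) & p_implied > 1e-300 &
    abs(stats$pval - p_implied) / p_implied > 0.10
  reason <- bad(inconsistent, "pval_beta_se_inconsistent")
  reason <- bad(duplicated(stats$snp_id) | duplicated(stats$snp_id, fromLast = TRUE),
                "duplicate_snp_id")

  rejections <- tibble::tibble(snp_id = stats$snp_id[!is.na(reason)],
                               reason = reason[!is.na(reason)])
  out <- stats[is.na(reason), ]
  class(out) <- c("sumstats", setdiff(class(out), "sumstats"))
  attr(out, "rejections") <- rejections
  out
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab-delimited file in the canonical dialect (columns `SNP, CHR,
#' POS, EA, OA, EAF, BETA, SE, P, N, NCASE, NCONTROL`) or any foreign header
#' via `dialect`, a named character vector mapping canonical internal names
#' (`snp_id`, `chrom`, `pos`, ...) to the file's column names. Rows that
#' violate the record invariants are rejected with a logged reason rather
#' than failing the read.
#'
#' @param path path to a delimited text file with a header
#' @param dialect named character vector mapping internal field names to the
#'   file's column names; default is the canonical TSV dialect
#' @param trait_id,trait_type trait metadata attached to every record
#' @param delim field delimiter (default tab)
#' @return A validated `sumstats` tibble; rejected rows are recorded in the
#'   `"rejections"` attribute.
#' @export
read_sumstats <- function(path, dialect = TSV_DIALECT, trait_id = "trait",
                          trait_type = "quantitative", delim = "\t") {
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  needed <- dialect[setdiff(names(dialect), c("ncase", "ncontrol"))]
  missing_cols <- setdiff(unname(needed), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("file lacks mandatory column(s): ", paste(missing_cols, collapse = ", ")),
          class = "mrtriad_format_error")
  }
  get <- function(field, default = NA_character_) {
    col <- if (field %in% names(dialect)) dialect[[field]] else NA_character_
    if (!is.na(col) && col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  out <- tibble::tibble(
    snp_id = get("snp_id"), chrom = get("chrom"),
    pos = num(get("pos")),
    effect_allele = toupper(get("effect_allele")),
    other_allele = toupper(get("other_allele")),
    eaf = num(get("eaf")), beta = num(get("beta")), se = num(get("se")),
    pval = num(get("pval")), n = num(get("n")),
    trait_id = trait_id, trait_type = trait_type,
    ncase = num(get("ncase")), ncontrol = num(get("ncontrol"))
  )
  out$pos <- as.integer(round(out$pos))
  validate_sumstats(out)
}

#' Write GWAS summary statistics as canonical TSV
#'
#' Writes the canonical tab-delimited dialect (`SNP, CHR, POS, EA, OA, EAF,
#' BETA, SE, P, N, NCASE, NCONTROL`), UTF-8, with missing optional counts as
#' `NA`. Numeric fields keep full precision so a read/write round trip is
#' value-identical.
#'
#' @param stats a `sumstats` tibble
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path) {
  stats <- tibble::as_tibble(stats)
  out <- stats[, names(TSV_DIALECT)]
  names(out) <- unname(TSV_DIALECT)
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}
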