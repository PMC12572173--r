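#' Simulate a genotype reference panel with block LD structure
#'
#' Generates a panel of diploid dosages (individuals x variants, values 0/1/2)
#' with block-diagonal linkage disequilibrium: variants in the same block share
#' a latent Gaussian factor whose correlation is calibrated (via the
#' tetrachoric integral) so that the *dosage* correlation matches
#' `within_block_r`; variants in different blocks are generated independently.
#' Each block draws one minor-allele frequency from `maf_range`, so MAFs vary
#' across blocks while within-block correlations can be hit exactly.
#'
#' Blocks are laid along chromosome 1 at 2-Mb spacing with 10-kb spacing
#' within a block. Setting `mhc_block` places that block on chromosome 6
#' inside the major histocompatibility complex region
#' (chr6:28,477,897-33,448,354, GRCh37), the region conventionally excluded
#' from instrument selection, so region-exclusion logic can be exercised.
#'
#' @param n_individuals number of diploid individuals
#' @param n_blocks number of independent LD blocks
#' @param snps_per_block variants per block
#' @param within_block_r target pairwise dosage correlation within a block,
#'   in `[0, 1)`
#' @param maf_range length-2 numeric: minor-allele frequency range, a subset
#'   of (0, 0.5]
#' @param seed integer seed; identical arguments and seed reproduce the panel
#'   exactly
#' @param mhc_block optional block index to place inside the MHC region on
#'   chromosome 6
#' @return A `ref_panel`: list with `variants` (tibble: `snp_id, chrom, pos,
#'   ref_allele, alt_allele, maf, block`) and `dosages` (matrix, individuals
#'   x variants, columns named by `snp_id`).
#' @export
simulate_reference_panel <- function(n_individuals, n_blocks, snps_per_block,
                                     within_block_r = 0.8,
                                     maf_range = c(0.05, 0.5), seed = 1L,
                                     mhc_block = NULL) {
  assert_count(n_individuals, "n_individuals")
  assert_count(n_blocks, "n_blocks")
  assert_count(snps_per_block, "snps_per_block")
  assert_fraction(within_block_r, "within_block_r", 0, 1, open_hi = TRUE)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an interval inside (0, 0.5]")
  }

  m <- n_blocks * snps_per_block
  withr::with_seed(seed, {
    block_maf <- runif(n_blocks, maf_range[1], maf_range[2])
    dos <- matrix(0L, n_individuals, m)
    for (b in seq_len(n_blocks)) {
      p <- block_maf[b]
      rho <- latent_rho_for(within_block_r, p)
      cols <- (b - 1L) * snps_per_block + seq_len(snps_per_block)
      for (hap in 1:2) {
        u <- rnorm(n_individuals)
        e <- matrix(rnorm(n_individuals * snps_per_block), n_individuals)
        z <- sqrt(rho) * u + sqrt(1 - rho) * e
        dos[, cols] <- dos[, cols] + (z < qnorm(p))
      }
    }
    # non-palindromic ref/alt pairs so palindromes are opt-in downstream
    pairs <- matrix(c("A", "C", "A", "G", "T", "C", "T", "G",
                      "C", "A", "G", "A", "C", "T", "G", "T"),
                    ncol = 2, byrow = TRUE)
    pick <- sample.int(nrow(pairs), m, replace = TRUE)
  })

  block <- rep(seq_len(n_blocks), each = snps_per_block)
  chrom <- rep("1", m)
  pos <- integer(m)
  for (b in seq_len(n_blocks)) {
    idx <- which(block == b)
    if (!is.null(mhc_block) && b == mhc_block) {
      chrom[idx] <- "6"
      pos[idx] <- 28477897L + 10000L * (seq_along(idx) - 1L)
    } else {
      pos[idx] <- 2000000L * b + 10000L * (seq_along(idx) - 1L)
    }
  }
  snp_id <- sprintf("rs%d_%d", block, rep(seq_len(snps_per_block), n_blocks))
  colnames(dos) <- snp_id

  variants <- tibble::tibble(
    snp_id = snp_id, chrom = chrom, pos = pos,
    ref_allele = pairs[pick, 1], alt_allele = pairs[pick, 2],
    maf = block_maf[block], block = block
  )
  structure(list(variants = variants, dosages = dos), class = "ref_panel")
}

# Latent Gaussian correlation giving indicator correlation r_target when two
# standard normals are thresholded at t = qnorm(p):
#   corr = (Phi2(t, t; rho) - p^2) / (p (1 - p)),
#   Phi2(t, t; rho) = p^2 + int_0^rho phi2(t, t; r) dr  (Plackett's identity).
latent_rho_for <- function(r_target, p) {
  if (r_target <= 0) return(0)
  t <- qnorm(p)
  phi2 <- function(r) exp(-t^2 / (1 + r)) / (2 * pi * sqrt(1 - r^2))
  excess <- function(rho) {
    integrate(phi2, 0, rho, rel.tol = 1e-10)$value - r_target * p * (1 - p)
  }
  if (excess(0.999999) < 0) return(0.999999)
  uniroot(excess, c(0, 0.999999), tol = 1e-10)$root
}

#' @export
print.ref_panel <- function(x, ...) {
  cat("<ref_panel> ", nrow(x$dosages), " individuals x ", ncol(x$dosages),
      " variants, ", max(x$variants$block), " LD blocks\n", sep = "")
  invisible(x)
}

panel_has <- function(panel, ids) ids %in% panel$variants$snp_id

# empirical dosage r^2 between one target and a set of candidate variants
panel_r2 <- function(panel, target, candidates) {
  x <- panel$dosages[, target]
  m <- panel$dosages[, candidates, drop = FALSE]
  r <- suppressWarnings(as.vector(cor(x, m)))
  r[is.na(r)] <- 0
  setNames(r^2, candidates)
}

panel_r <- function(panel, target, candidates) {
  x <- panel$dosages[, target]
  m <- panel$dosages[, candidates, drop = FALSE]
  r <- suppressWarnings(as.vector(cor(x, m)))
  r[is.na(r)] <- 0
  setNames(r, candidates)
}

#' Find LD proxies for a variant
#'
#' Searches `candidates` for variants on the target's chromosome within
#' `window` base pairs whose panel dosage r-squared with the target exceeds
#' `r2_min`, the convention used when an instrument is missing from an
#' outcome GWAS (r² > 0.8 within 0.5 Mb). Results are sorted by
#' descending r². The proxy's alleles are mapped onto the target's via the
#' sign of the dosage correlation: a positive correlation aligns the proxy's
#' alt allele with the target's alt allele, a negative one aligns it with the
#' target's ref allele.
#'
#' @param panel a `ref_panel` containing the target
#' @param target `snp_id` of the variant needing a proxy
#' @param candidates `sumstats` tibble of available variants
#' @param r2_min minimum r² (default 0.8)
#' @param window maximum distance in bp (default 500,000)
#' @return Tibble `snp_id, chrom, pos, r2, r_sign, mapped_effect_allele,
#'   mapped_other_allele`, ordered by descending r²; zero rows when no proxy
#'   qualifies.
#' @export
find_proxies <- function(panel, target, candidates, r2_min = 0.8,
                         window = 500000) {
  v <- panel$variants
  if (!target %in% v$snp_id) {
    abort(paste0("target '", target, "' absent from the reference panel"),
          class = "mrtriad_lookup_error")
  }
  trow <- v[v$snp_id == target, ]
  cand <- tibble::as_tibble(candidates)
  cand <- cand[cand$snp_id != target &
                 cand$snp_id %in% v$snp_id &
                 cand$chrom == trow$chrom &
                 abs(cand$pos - trow$pos) <= window, ]
  if (nrow(cand) == 0) return(empty_proxy_table())
  r <- unname(panel_r(panel, target, cand$snp_id))
  keep <- r^2 > r2_min
  cand <- cand[keep, ]
  r <- r[keep]
  if (nrow(cand) == 0) return(empty_proxy_table())
  pv <- v[match(cand$snp_id, v$snp_id), ]
  out <- tibble::tibble(
    snp_id = cand$snp_id, chrom = cand$chrom, pos = cand$pos,
    r2 = unname(r^2), r_sign = sign(unname(r)),
    mapped_effect_allele = ifelse(r > 0, pv$alt_allele, pv$ref_allele),
    mapped_other_allele = ifelse(r > 0, pv$ref_allele, pv$alt_allele)
  )
  dplyr::arrange(out, dplyr::desc(.data$r2))
}

empty_proxy_table <- function() {
  tibble::tibble(snp_id = character(), chrom = character(), pos = integer(),
                 r2 = numeric(), r_sign = numeric(),
                 mapped_effect_allele = character(),
                 mapped_other_allele = character())
}
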