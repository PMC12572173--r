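#' Ground truth for a simulated exposure-metabolite-outcome triad
#'
#' Bundles the causal parameters a simulated study is generated from:
#' the exposure -> metabolite effect (SD units), the metabolite -> outcome
#' effect (log-odds per SD), and the exposure -> outcome *direct* effect
#' (log-odds per SD). The implied proportion of the total exposure -> outcome
#' effect mediated by the metabolite is derived as
#' `beta_EM * beta_MO / (beta_EM * beta_MO + beta_EO_direct)`.
#'
#' @param beta_EM exposure -> metabolite causal effect (SD per SD)
#' @param beta_MO metabolite -> outcome causal effect (log-odds per SD)
#' @param beta_EO_direct exposure -> outcome direct effect (log-odds per SD)
#' @return A `triad_truth` list with the three effects, the derived
#'   `proportion_mediated`, and placeholders (`pleiotropic_snps`,
#'   `coloc_mode`) filled in by the generators.
#' @export
triad_truth <- function(beta_EM = 0.3, beta_MO = 0.2, beta_EO_direct = 0.1) {
  vals <- c(beta_EM, beta_MO, beta_EO_direct)
  if (length(vals) != 3 || !all(is.finite(vals))) {
    abort("truth effects must be finite scalars")
  }
  total <- beta_EM * beta_MO + beta_EO_direct
  structure(list(
    beta_EM = beta_EM, beta_MO = beta_MO, beta_EO_direct = beta_EO_direct,
    beta_EO_total = total,
    proportion_mediated = if (total != 0) beta_EM * beta_MO / total else NA_real_,
    pleiotropic_snps = character(), coloc_mode = NA_character_
  ), class = "triad_truth")
}

#' Simulation configuration for a GWAS summary-statistic triad
#'
#' Defaults describe a desk-scale analogue of a two-sample MR study: a large
#' quantitative exposure GWAS, a metabolite GWAS of the same order, and a
#' balanced case-control outcome GWAS, with the exposure instrumented by many
#' common variants of moderate total heritability.
#'
#' @param n_exposure_gwas,n_metabolite_gwas quantitative GWAS sample sizes
#' @param n_outcome_cases,n_outcome_controls binary outcome GWAS counts
#' @param n_causal_snps number of exposure-causal variants (one per LD block)
#' @param heritability_exposure fraction of exposure variance explained by
#'   the causal variants jointly, in (0, 1)
#' @param pleiotropy_fraction fraction of exposure instruments given a direct
#'   (horizontally pleiotropic) outcome effect, in \[0, 1\]
#' @param pleiotropy_sd standard deviation of those direct effects
#'   (log-odds per SD of genotype)
#' @param pleiotropy_mean mean of the direct effects, expressed relative to
#'   the exposure-raising allele: zero gives balanced pleiotropy, nonzero
#'   gives directional pleiotropy of the kind the Egger intercept test
#'   detects
#' @param palindrome_fraction fraction of panel variants relabelled to
#'   palindromic (A/T or C/G) allele pairs, in \[0, 1\]
#' @param h2_metabolite_specific heritability of the metabolite's own
#'   (non-exposure) genetic component
#' @param n_metabolite_specific number of metabolite-specific causal
#'   variants; default `n_causal_snps`
#' @param seed master seed; expanded into per-component streams
#' @param metabolite_stream integer offset on the metabolite noise stream,
#'   so several metabolites can share one exposure draw while getting
#'   independent measurement noise
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_exposure_gwas = 50000, n_metabolite_gwas = 50000,
                       n_outcome_cases = 25000, n_outcome_controls = 25000,
                       n_causal_snps = 50, heritability_exposure = 0.1,
                       pleiotropy_fraction = 0, pleiotropy_sd = 0.05,
                       pleiotropy_mean = 0,
                       palindrome_fraction = 0.1,
                       h2_metabolite_specific = 0.1,
                       n_metabolite_specific = NULL, seed = 1L,
                       metabolite_stream = 0L) {
  for (nm in c("n_exposure_gwas", "n_metabolite_gwas", "n_outcome_cases",
               "n_outcome_controls", "n_causal_snps")) {
    assert_count(get(nm), nm)
  }
  assert_fraction(heritability_exposure, "heritability_exposure", 0, 1,
                  open_lo = TRUE, open_hi = TRUE)
  assert_fraction(pleiotropy_fraction, "pleiotropy_fraction")
  assert_fraction(palindrome_fraction, "palindrome_fraction")
  structure(list(
    n_exposure_gwas = n_exposure_gwas, n_metabolite_gwas = n_metabolite_gwas,
    n_outcome_cases = n_outcome_cases, n_outcome_controls = n_outcome_controls,
    n_causal_snps = n_causal_snps,
    heritability_exposure = heritability_exposure,
    pleiotropy_fraction = pleiotropy_fraction, pleiotropy_sd = pleiotropy_sd,
    pleiotropy_mean = pleiotropy_mean,
    palindrome_fraction = palindrome_fraction,
    h2_metabolite_specific = h2_metabolite_specific,
    n_metabolite_specific = n_metabolite_specific %||% n_causal_snps,
    seed = as.integer(seed),
    metabolite_stream = as.integer(metabolite_stream)
  ), class = "sim_config")
}

# standardised marginal effects implied by one causal variant per block,
# propagated through the empirical within-block dosage correlations
marginal_from_causal <- function(panel, causal_std) {
  out <- numeric(ncol(panel$dosages))
  nz <- which(causal_std != 0)
  blocks <- panel$variants$block
  for (j in nz) {
    idx <- which(blocks == blocks[j])
    r <- panel_r(panel, panel$variants$snp_id[j], panel$variants$snp_id[idx])
    out[idx] <- out[idx] + r * causal_std[j]
  }
  out
}

# one trait's observed summary statistics from true standardised marginal
# effects; SEs follow 1/sqrt(2 n p (1-p) v) with v = 1 (standardised
# quantitative) or the case/control-balanced analogue for binary traits
draw_sumstats <- function(panel, marg_std, n, trait_id, trait_type,
                          ncase = NA, ncontrol = NA, flip_orient, pal_idx) {
  v <- panel$variants
  p <- v$maf
  het <- 2 * p * (1 - p)
  beta_true <- marg_std / sqrt(het)
  if (trait_type == "binary") {
    phi <- ncase / n
    se <- 1 / sqrt(het * n * phi * (1 - phi))
  } else {
    se <- 1 / sqrt(het * n)
  }
  beta_hat <- beta_true + rnorm(length(beta_true), 0, se)
  eaf_hat <- pmin(pmax(rbinom(length(p), round(2 * n), p) / round(2 * n),
                       1 / (2 * n)), 1 - 1 / (2 * n))
  ea <- v$alt_allele
  oa <- v$ref_allele
  # palindromic relabelling: alleles renamed A/T or C/G, effects untouched
  if (length(pal_idx) > 0) {
    at <- pal_idx[seq_along(pal_idx) %% 2 == 0]
    cg <- setdiff(pal_idx, at)
    ea[at] <- "A"; oa[at] <- "T"
    ea[cg] <- "C"; oa[cg] <- "G"
  }
  # reporting orientation: each study may quote the opposite effect allele
  beta_hat <- ifelse(flip_orient, -beta_hat, beta_hat)
  eaf_hat <- ifelse(flip_orient, 1 - eaf_hat, eaf_hat)
  tmp <- ea
  ea <- ifelse(flip_orient, oa, ea)
  oa <- ifelse(flip_orient, tmp, oa)
  sumstats(
    snp_id = v$snp_id, chrom = v$chrom, pos = v$pos,
    effect_allele = ea, other_allele = oa, eaf = eaf_hat,
    beta = beta_hat, se = se, pval = two_sided_p(beta_hat / se), n = n,
    trait_id = trait_id, trait_type = trait_type,
    ncase = ncase, ncontrol = ncontrol
  )
}

#' Simulate an exposure-metabolite-outcome GWAS summary-statistic triad
#'
#' Draws three independent GWAS (the two-sample assumption) over the panel's
#' variants. Exposure causal variants (one per LD block) jointly explain
#' `heritability_exposure`; the metabolite's per-variant effects are
#' `beta_EM` times the exposure effects plus a metabolite-specific genetic
#' component on disjoint blocks; the binary outcome's log-odds effects
#' combine the direct exposure path, the mediated path through the
#' metabolite, and optional direct (pleiotropic) effects on a random subset
#' of exposure instruments. Standard errors scale as
#' `1/sqrt(2 n maf (1-maf) v)` with `v` the residual variance (quantitative)
#' or its case/control-balanced analogue (binary). A `palindrome_fraction`
#' of variants — chosen preferentially among those with panel MAF >= 0.40 so
#' their effect-allele frequency falls near 0.5 — are relabelled to A/T or
#' C/G pairs, leaving the truth unchanged. Each study independently reports
#' some variants on the opposite effect allele, which harmonisation must
#' undo.
#'
#' @param panel a `ref_panel` with at least
#'   `n_causal_snps + n_metabolite_specific` blocks
#' @param config a `sim_config`
#' @param truth a `triad_truth`
#' @return List with `exposure`, `metabolite`, `outcome` (`sumstats`
#'   tibbles) and `truth`, the input truth augmented with the realised
#'   `causal_snps`, `metabolite_snps` and `pleiotropic_snps`.
#' @export
simulate_triad_study <- function(panel, config, truth) {
  if (!inherits(truth, "triad_truth")) truth <- do.call(triad_truth, truth)
  if (!all(is.finite(c(truth$beta_EM, truth$beta_MO, truth$beta_EO_direct)))) {
    abort("truth effects must be finite")
  }
  n_blocks <- max(panel$variants$block)
  need <- config$n_causal_snps + config$n_metabolite_specific
  if (n_blocks < need) {
    abort(paste0("panel has ", n_blocks, " blocks but ", need,
                 " causal variants are requested (one per block)"))
  }
  m <- ncol(panel$dosages)
  v <- panel$variants

  seed_exp <- stream_seed(config$seed, "exposure")
  seed_met <- (stream_seed(config$seed, "metabolite") +
                 (config$metabolite_stream %||% 0L) * 7919) %% 2147483647L
  seed_out <- stream_seed(config$seed, "outcome")
  seed_pal <- stream_seed(config$seed, "palindrome")

  draws <- withr::with_seed(seed_pal, {
    blocks_perm <- sample.int(n_blocks)
    exp_blocks <- blocks_perm[seq_len(config$n_causal_snps)]
    met_blocks <- blocks_perm[config$n_causal_snps + seq_len(config$n_metabolite_specific)]
    pick_in_block <- function(b) {
      idx <- which(v$block == b)
      idx[sample.int(length(idx), 1)]
    }
    exp_idx <- vapply(exp_blocks, pick_in_block, integer(1))
    met_idx <- vapply(met_blocks, pick_in_block, integer(1))

    b_raw <- rnorm(config$n_causal_snps)
    b_exp <- b_raw * sqrt(config$heritability_exposure / sum(b_raw^2))
    g_raw <- rnorm(config$n_metabolite_specific)
    g_met <- g_raw * sqrt(config$h2_metabolite_specific / sum(g_raw^2))

    n_pleio <- round(config$pleiotropy_fraction * config$n_causal_snps)
    pleio_idx <- if (n_pleio > 0) sample(exp_idx, n_pleio) else integer()
    # direct effects are oriented to the exposure-raising allele, so a
    # nonzero mean is directional in the frame Egger regression uses
    d_pleio <- if (n_pleio > 0) {
      raw <- rnorm(n_pleio, config$pleiotropy_mean %||% 0, config$pleiotropy_sd)
      raw * sign(b_exp[match(pleio_idx, exp_idx)])
    } else numeric()

    n_pal <- round(config$palindrome_fraction * m)
    hi_maf <- which(v$maf >= 0.40)
    pal_idx <- if (n_pal == 0) integer() else if (length(hi_maf) >= n_pal) {
      sample(hi_maf, n_pal)
    } else {
      c(hi_maf, sample(setdiff(seq_len(m), hi_maf), n_pal - length(hi_maf)))
    }
    flips <- matrix(runif(3 * m) < 0.5, nrow = 3)
    list(exp_idx = exp_idx, met_idx = met_idx, b_exp = b_exp, g_met = g_met,
         pleio_idx = pleio_idx, d_pleio = d_pleio, pal_idx = pal_idx,
         flips = flips)
  })

  causal_exp <- numeric(m); causal_exp[draws$exp_idx] <- draws$b_exp
  causal_met_own <- numeric(m); causal_met_own[draws$met_idx] <- draws$g_met
  causal_met <- truth$beta_EM * causal_exp + causal_met_own
  causal_out <- truth$beta_EO_direct * causal_exp + truth$beta_MO * causal_met
  causal_out[draws$pleio_idx] <- causal_out[draws$pleio_idx] + draws$d_pleio

  marg_exp <- marginal_from_causal(panel, causal_exp)
  marg_met <- marginal_from_causal(panel, causal_met)
  marg_out <- marginal_from_causal(panel, causal_out)

  n_out <- config$n_outcome_cases + config$n_outcome_controls
  exposure <- withr::with_seed(seed_exp, draw_sumstats(
    panel, marg_exp, config$n_exposure_gwas, "exposure", "quantitative",
    flip_orient = draws$flips[1, ], pal_idx = draws$pal_idx))
  metabolite <- withr::with_seed(seed_met, draw_sumstats(
    panel, marg_met, config$n_metabolite_gwas, "metabolite", "quantitative",
    flip_orient = draws$flips[2, ], pal_idx = draws$pal_idx))
  outcome <- withr::with_seed(seed_out, draw_sumstats(
    panel, marg_out, n_out, "outcome", "binary",
    ncase = config$n_outcome_cases, ncontrol = config$n_outcome_controls,
    flip_orient = draws$flips[3, ], pal_idx = draws$pal_idx))

  truth$causal_snps <- v$snp_id[draws$exp_idx]
  truth$metabolite_snps <- v$snp_id[draws$met_idx]
  truth$pleiotropic_snps <- v$snp_id[draws$pleio_idx]
  list(exposure = exposure, metabolite = metabolite, outcome = outcome,
       truth = truth)
}

#' Simulate a two-trait locus for colocalisation
#'
#' Builds region summary statistics for two quantitative traits over two
#' adjacent LD blocks of the panel. In `shared` mode one causal variant
#' (in the first block) drives both traits; in `distinct` mode trait 1's
#' causal variant sits in the first block and trait 2's in the second,
#' uncorrelated, block; in `null` mode neither trait has any association.
#' `z_strength` is the causal variant's expected z-score; marginal z-scores
#' decay with panel LD and observed z-scores add unit Gaussian noise.
#'
#' @param panel a `ref_panel` with at least two blocks
#' @param mode one of `"shared"`, `"distinct"`, `"null"`
#' @param z_strength expected causal-variant z-score (> 0 unless `null`)
#' @param seed integer seed
#' @param n1,n2 the two GWAS sample sizes
#' @param blocks length-2 integer: which panel blocks form the region
#' @return List with `trait1` and `trait2` `sumstats` tibbles over the
#'   region's variants, plus `causal1`/`causal2` variant ids (NA under null).
#' @export
simulate_coloc_locus <- function(panel, mode = c("shared", "distinct", "null"),
                                 z_strength = 8, seed = 1L,
                                 n1 = 50000, n2 = 50000, blocks = c(1L, 2L)) {
  mode <- match.arg(mode)
  if (mode != "null" && (!is.numeric(z_strength) || z_strength <= 0)) {
    abort("`z_strength` must be positive for non-null modes")
  }
  v <- panel$variants
  if (max(v$block) < max(blocks)) abort("panel has too few blocks")
  idx <- which(v$block %in% blocks)

  withr::with_seed(stream_seed(seed, "coloc"), {
    in1 <- idx[v$block[idx] == blocks[1]]
    in2 <- idx[v$block[idx] == blocks[2]]
    c1 <- in1[sample.int(length(in1), 1)]
    c2 <- switch(mode, shared = c1,
                 distinct = in2[sample.int(length(in2), 1)], null = NA_integer_)

    z_for <- function(causal) {
      z <- numeric(length(idx))
      if (!is.na(causal) && mode != "null") {
        r <- panel_r(panel, v$snp_id[causal], v$snp_id[idx])
        z <- r * z_strength
      }
      z + rnorm(length(idx))
    }
    z1 <- z_for(c1)
    z2 <- z_for(c2)

    make <- function(z, n, id) {
      p <- v$maf[idx]
      se <- 1 / sqrt(2 * p * (1 - p) * n)
      eaf <- pmin(pmax(rbinom(length(p), round(2 * n), p) / round(2 * n),
                       1 / (2 * n)), 1 - 1 / (2 * n))
      sumstats(
        snp_id = v$snp_id[idx], chrom = v$chrom[idx], pos = v$pos[idx],
        effect_allele = v$alt_allele[idx], other_allele = v$ref_allele[idx],
        eaf = eaf, beta = z * se, se = se, pval = two_sided_p(z), n = n,
        trait_id = id, trait_type = "quantitative"
      )
    }
    list(trait1 = make(z1, n1, "trait1"), trait2 = make(z2, n2, "trait2"),
         causal1 = if (mode == "null") NA_character_ else v$snp_id[c1],
         causal2 = if (mode == "null") NA_character_ else v$snp_id[c2],
         mode = mode)
  })
}
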