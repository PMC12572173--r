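# Shared fixtures, built once per test run. Everything is generated in code;
# sizes are kept small so the whole suite stays fast.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# 30-block panel used by most module tests
small_panel <- function() {
  memo("small_panel", simulate_reference_panel(
    n_individuals = 600, n_blocks = 30, snps_per_block = 5,
    within_block_r = 0.8, maf_range = c(0.1, 0.5), seed = 101
  ))
}

# a clean triad over the small panel (no pleiotropy)
small_triad <- function() {
  memo("small_triad", simulate_triad_study(
    small_panel(),
    sim_config(n_causal_snps = 12, n_metabolite_specific = 12, seed = 202),
    triad_truth(0.3, 0.2, 0.1)
  ))
}

# hand-specifiable aligned instrument table
make_aligned <- function(beta_exp, se_exp, beta_out, se_out,
                         snp_id = paste0("s", seq_along(beta_exp))) {
  tibble::tibble(
    snp_id = snp_id, chrom = "1", pos = seq_along(beta_exp) * 1000L,
    effect_allele = "A", other_allele = "G",
    beta_exp = beta_exp, se_exp = se_exp, pval_exp = 2 * pnorm(-abs(beta_exp / se_exp)),
    eaf_exp = 0.3, beta_out = beta_out, se_out = se_out,
    pval_out = 2 * pnorm(-abs(beta_out / se_out)), eaf_out = 0.3,
    n_exp = 1e5, n_out = 1e5
  )
}

# quick sumstats constructor for harmonisation tests
make_stats <- function(snp_id, ea, oa, beta, eaf, se = 0.02, chrom = "1",
                       pos = NULL, trait_id = "t", trait_type = "quantitative",
                       n = 1e5) {
  sumstats(
    snp_id = snp_id, chrom = chrom,
    pos = pos %||% (seq_along(snp_id) * 1000L),
    effect_allele = ea, other_allele = oa, eaf = eaf, beta = beta, se = se,
    pval = 2 * pnorm(-abs(beta / se)), n = n,
    trait_id = trait_id, trait_type = trait_type
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
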