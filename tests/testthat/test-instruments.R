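test_that("region exclusion uses a closed interval on the stated coordinates", {
  st <- make_stats(c("in_lo", "out_lo", "in_hi", "other_chr"),
                   ea = "A", oa = "G", beta = 0.1, eaf = 0.3,
                   chrom = c("6", "6", "6", "7"),
                   pos = c(28477897L, 28477896L, 33448354L, 30000000L))
  out <- exclude_region(st)
  expect_setequal(out$snp_id, c("out_lo", "other_chr"))
  expect_error(exclude_region(st, "6", 10, 5), "start")
})

test_that("clumping keeps the smallest-p variant per LD neighbourhood", {
  panel <- small_panel()
  tr <- small_triad()
  ivs <- clump(tr$exposure, panel)
  # every index SNP is genome-wide significant with MAF > 0.01
  idx <- tr$exposure[match(ivs$index_snps, tr$exposure$snp_id), ]
  expect_true(all(idx$pval < 5e-8))
  expect_true(all(pmin(idx$eaf, 1 - idx$eaf) > 0.01))
  # pairwise r^2 between index SNPs below the threshold within the window
  v <- panel$variants[match(ivs$index_snps, panel$variants$snp_id), ]
  for (i in seq_along(ivs$index_snps)) {
    near <- which(v$chrom == v$chrom[i] & abs(v$pos - v$pos[i]) <= 5e5 &
                    seq_along(ivs$index_snps) != i)
    if (length(near) > 0) {
      r2 <- panel_r2_test(panel, ivs$index_snps[i], ivs$index_snps[near])
      expect_true(all(r2 < 0.01))
    }
  }
  # every pruned variant really is in LD with its recorded index SNP
  pruned <- ivs$clump_audit[ivs$clump_audit$reason == "pruned", ]
  expect_true(all(pruned$r2 >= 0.01))
})

# brute-force r^2 straight from the dosage matrix, independent of the package
panel_r2_test <- function(panel, a, b) {
  as.vector(cor(panel$dosages[, a], panel$dosages[, b, drop = FALSE]))^2
}

test_that("clumping matches a brute-force greedy oracle and ignores row order", {
  panel <- simulate_reference_panel(400, 5, 4, within_block_r = 0.85,
                                    maf_range = c(0.2, 0.5), seed = 55)
  v <- panel$variants
  set.seed(7)
  z <- rnorm(nrow(v), 0, 1) + sample(c(0, 8), nrow(v), replace = TRUE)
  st <- make_stats(v$snp_id, ea = v$alt_allele, oa = v$ref_allele,
                   beta = z * 0.01, se = 0.01, eaf = v$maf,
                   chrom = v$chrom, pos = v$pos)
  got <- clump(st, panel, p_max = 0.05, r2_max = 0.1, window = 5e5, maf_min = 0.01)

  # oracle: plain greedy over p-sorted eligible variants with direct cor()
  elig <- st[st$pval < 0.05 & pmin(st$eaf, 1 - st$eaf) > 0.01, ]
  elig <- elig[order(elig$pval, elig$pos, elig$snp_id), ]
  expected <- character()
  while (nrow(elig) > 0) {
    top <- elig[1, ]
    expected <- c(expected, top$snp_id)
    keep <- rep(TRUE, nrow(elig))
    for (j in seq_len(nrow(elig))[-1]) {
      if (elig$chrom[j] == top$chrom && abs(elig$pos[j] - top$pos) <= 5e5 &&
          panel_r2_test(panel, top$snp_id, elig$snp_id[j]) >= 0.1) keep[j] <- FALSE
    }
    keep[1] <- FALSE
    elig <- elig[keep, ]
  }
  expect_identical(got$index_snps, expected)

  # row-order invariance
  shuffled <- st[sample(nrow(st)), ]
  got2 <- clump(shuffled, panel, p_max = 0.05, r2_max = 0.1,
                window = 5e5, maf_min = 0.01)
  expect_identical(got2$index_snps, got$index_snps)
})

test_that("two variants in perfect LD keep only the smaller p-value", {
  panel <- small_panel()
  v <- panel$variants
  two <- v[v$block == 1, ][1:2, ]
  # force perfect LD by duplicating a dosage column
  panel2 <- panel
  panel2$dosages[, two$snp_id[2]] <- panel2$dosages[, two$snp_id[1]]
  st <- make_stats(two$snp_id, ea = two$alt_allele, oa = two$ref_allele,
                   beta = c(0.070, 0.065), se = 0.01, eaf = two$maf,
                   chrom = two$chrom, pos = two$pos)
  # pvals ~ 1e-10 and larger; smaller p wins
  got <- clump(st, panel2, p_max = 1e-6, r2_max = 0.01, window = 5e5)
  expect_identical(got$index_snps, two$snp_id[1])
  expect_equal(got$clump_audit$index_snp[got$clump_audit$reason == "pruned"],
               two$snp_id[1])
})

test_that("F-statistics follow the squared-z formula and the <10 rule", {
  a <- make_aligned(beta_exp = c(0.03, 0.2), se_exp = c(0.01, 0.01),
                    beta_out = c(0, 0), se_out = c(0.01, 0.01))
  fr <- instrument_strength(a)
  expect_equal(fr$min_F, 9)       # z = 3
  expect_equal(fr$per_snp[[1]]$F, c(9, 400))
  expect_true(fr$weak_flag)

  a2 <- make_aligned(beta_exp = c(0.1, 0), se_exp = c(0.01, 0.01),
                     beta_out = c(0, 0), se_out = c(0.01, 0.01))
  fr2 <- instrument_strength(a2)
  expect_equal(fr2$min_F, 0)
  expect_true(fr2$weak_flag)

  a3 <- make_aligned(beta_exp = 0.1, se_exp = 0.01, beta_out = 0, se_out = 0.01)
  expect_equal(instrument_strength(a3)$min_F, 100)
  expect_false(instrument_strength(a3)$weak_flag)
})

test_that("power is alpha/2 at the null OR, monotone, and 1 in the limits", {
  expect_equal(mr_power(10000, 10000, 0.05, or_sd = 1, alpha = 0.05), 0.025)
  expect_equal(mr_power(1e9, 1e9, 0.05, or_sd = 1.05), 1, tolerance = 1e-6)
  pw_a <- sapply(c(0.01, 0.05, 0.2, 0.8), function(al)
    mr_power(1000, 1000, 0.05, 1.2, alpha = al))
  expect_true(all(diff(pw_a) > 0))
  ns <- c(1e3, 1e4, 1e5)
  pw_n <- sapply(ns, function(n) mr_power(n, n, 0.05, 1.1))
  expect_true(all(diff(pw_n) > 0))
  pw_r <- sapply(c(0.01, 0.05, 0.2), function(r) mr_power(5000, 5000, r, 1.1))
  expect_true(all(diff(pw_r) > 0))
  pw_o <- sapply(c(1.02, 1.1, 1.3), function(o) mr_power(5000, 5000, 0.05, o))
  expect_true(all(diff(pw_o) > 0))
  expect_error(mr_power(100, 100, 0.05, 1.1, alpha = 1.5), "alpha")
})

test_that("the power formula agrees with Monte-Carlo rejection on simulated studies", {
  # metabolite instrumented by its own variants explaining r2 = 0.1;
  # true OR per SD chosen to land mid-power
  panel <- simulate_reference_panel(400, 16, 3, within_block_r = 0.6,
                                    maf_range = c(0.2, 0.5), seed = 77)
  or_true <- 1.20
  n_case <- 6000
  cfg0 <- sim_config(n_outcome_cases = n_case, n_outcome_controls = n_case,
                     n_causal_snps = 8, n_metabolite_specific = 8,
                     h2_metabolite_specific = 0.1, palindrome_fraction = 0,
                     seed = 1)
  rejections <- vapply(1:600, function(i) {
    cfg <- cfg0
    cfg$seed <- i
    tr <- simulate_triad_study(panel, cfg,
                               triad_truth(beta_EM = 0, beta_MO = log(or_true),
                                           beta_EO_direct = 0))
    h <- harmonise(tr$metabolite[tr$metabolite$snp_id %in% tr$truth$metabolite_snps, ],
                   tr$outcome)
    ivw(h, "fixed")$pval < 0.05
  }, logical(1))
  predicted <- mr_power(n_case, n_case, r2_exposure = 0.1, or_sd = or_true)
  expect_lt(abs(mean(rejections) - predicted), 0.03)
})
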