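make_trait_pair <- function() {
  # one triad provides exposure + metabolite; reuse across MVMR tests
  tr <- small_triad()
  list(tr = tr, panel = small_panel())
}

test_that("MVMR with one exposure reduces to univariable IVW-fixed", {
  tp <- make_trait_pair()
  ivs <- clump(tp$tr$exposure, tp$panel)
  h <- harmonise(tp$tr$exposure[tp$tr$exposure$snp_id %in% ivs$index_snps, ],
                 tp$tr$outcome)
  uv <- ivw(h, "fixed")
  mv <- mvmr_ivw(list(tp$tr$exposure), tp$tr$outcome, ivs)
  expect_equal(mv$estimates$beta, uv$beta, tolerance = 1e-10)
  expect_equal(mv$estimates$se, uv$se, tolerance = 1e-10)
})

test_that("MVMR recovers exactly linear outcome construction to machine precision", {
  tp <- make_trait_pair()
  ivs <- reclump_union(list(tp$tr$exposure, tp$tr$metabolite), tp$panel)
  exp1 <- tibble::as_tibble(tp$tr$exposure)
  exp2 <- tibble::as_tibble(tp$tr$metabolite)
  # outcome betas built exactly as 0.3*exp1 + 0.1*exp2 on matching alleles
  out <- exp1
  m <- match(exp1$snp_id, exp2$snp_id)
  flip <- ifelse(exp2$effect_allele[m] == exp1$effect_allele, 1, -1)
  out$beta <- 0.3 * exp1$beta + 0.1 * flip * exp2$beta[m]
  out$se <- 0.01
  out$pval <- 2 * pnorm(-abs(out$beta / out$se))
  out$trait_id <- "constructed"
  mv <- mvmr_ivw(list(exp1, exp2), out, ivs)
  expect_equal(sort(mv$estimates$beta), sort(c(0.1, 0.3)), tolerance = 1e-10)
})

test_that("a re-measured duplicate exposure is weak; an exact duplicate is singular", {
  tp <- make_trait_pair()
  ivs <- clump(tp$tr$exposure, tp$panel)
  # same underlying exposure trait measured twice (independent noise)
  set.seed(71)
  dup <- tibble::as_tibble(tp$tr$exposure)
  dup$beta <- dup$beta + rnorm(nrow(dup), 0, dup$se)
  dup$pval <- 2 * pnorm(-abs(dup$beta / dup$se))
  dup$trait_id <- "exposure_again"
  mv <- mvmr_ivw(list(tp$tr$exposure, dup), tp$tr$outcome, ivs)
  expect_true(any(mv$estimates$conditional_F < 10))
  expect_true(mv$weak_flag)

  exact <- tibble::as_tibble(tp$tr$exposure)
  exact$trait_id <- "copy"
  expect_error(mvmr_ivw(list(tp$tr$exposure, exact), tp$tr$outcome, ivs),
               class = "mrtriad_collinearity")
})

test_that("reclumping a union ranks variants by their best p-value across traits", {
  tp <- make_trait_pair()
  ivs <- reclump_union(list(tp$tr$exposure, tp$tr$metabolite), tp$panel)
  # the union contains instruments from both causal architectures
  exp_only <- clump(tp$tr$exposure, tp$panel)$index_snps
  met_only <- clump(tp$tr$metabolite, tp$panel)$index_snps
  expect_true(length(intersect(ivs$index_snps, exp_only)) > 0)
  expect_true(length(intersect(ivs$index_snps, met_only)) > 0)

  # a variant significant in both traits appears once with its smaller p
  exp1 <- tibble::as_tibble(tp$tr$exposure)[1:4, ]
  exp1$pval <- c(1e-10, 0.5, 0.5, 0.5)
  exp2 <- exp1
  exp2$trait_id <- "other"
  exp2$pval <- c(1e-20, 0.5, 0.5, 0.5)
  u <- reclump_union(list(exp1, exp2), tp$panel)
  expect_equal(sum(u$index_snps == exp1$snp_id[1]), 1)

  # disjoint, mutually independent instruments are all retained
  a <- tibble::as_tibble(tp$tr$exposure)
  one_per_block_a <- a[match(unique(tp$panel$variants$block), tp$panel$variants$block), ][1:5, ]
  one_per_block_b <- a[match(unique(tp$panel$variants$block), tp$panel$variants$block) + 0L, ][6:10, ]
  one_per_block_a$pval <- 1e-12
  one_per_block_b$pval <- 1e-12
  one_per_block_b$trait_id <- "b"
  u2 <- reclump_union(list(one_per_block_a, one_per_block_b), tp$panel)
  expect_setequal(u2$index_snps, c(one_per_block_a$snp_id, one_per_block_b$snp_id))
})

test_that("phenotypic correlation is 1 with itself, null for independent traits, and recoverable", {
  tp <- make_trait_pair()
  self_rho <- build_phenotypic_covariance(list(tp$tr$exposure, tp$tr$exposure),
                                          min_overlap = 10)
  expect_equal(unname(self_rho[1, 2]), 1, tolerance = 1e-12)

  ind_rho <- build_phenotypic_covariance(list(tp$tr$exposure, tp$tr$metabolite),
                                         min_overlap = 10)
  m <- nrow(tibble::as_tibble(tp$tr$exposure))
  expect_lt(abs(ind_rho[1, 2]), 3 / sqrt(m))

  # z-scores constructed with correlation 0.5 over 5000 variants
  set.seed(61)
  mvar <- 5000
  e1 <- rnorm(mvar); e2 <- 0.5 * e1 + sqrt(0.75) * rnorm(mvar)
  ids <- sprintf("v%05d", 1:mvar)
  se <- 0.01
  t1 <- make_stats(ids, ea = "A", oa = "G", beta = e1 * se, se = se,
                   eaf = 0.3, pos = 1:mvar * 10L, trait_id = "t1")
  t2 <- make_stats(ids, ea = "A", oa = "G", beta = e2 * se, se = se,
                   eaf = 0.3, pos = 1:mvar * 10L, trait_id = "t2")
  rho <- build_phenotypic_covariance(list(t1, t2))
  expect_lt(abs(rho[1, 2] - 0.5), 0.05)

  expect_warning(
    small <- build_phenotypic_covariance(list(t1[1:20, ], t2[1:20, ])),
    "identity")
  expect_equal(unname(small), diag(2))
})

test_that("difference and product methods follow their stated arithmetic", {
  total <- wald_ratio(1, 0.01, 0.4, 0.05)
  mv <- structure(list(
    estimates = tibble::tibble(exposure = "bmi", beta = 0.3, se = 0.04,
                               pval = 0.001, conditional_F = 50),
    weak_flag = FALSE, pleiotropy_flag = FALSE), class = "mvmr_result")
  d <- difference_method(total, mv, "bmi")
  expect_equal(d$beta_indirect, 0.1)
  expect_equal(d$proportion_mediated, 0.25)
  expect_equal(d$se_indirect, sqrt(0.05^2 + 0.04^2))
  expect_true(d$usable)

  # direct = total: nothing mediated
  mv0 <- mv; mv0$estimates$beta <- 0.4
  d0 <- difference_method(total, mv0, "bmi")
  expect_equal(d0$beta_indirect, 0)
  expect_equal(d0$proportion_mediated, 0)

  # weak instruments make the difference result unusable
  mv_w <- mv; mv_w$weak_flag <- TRUE
  expect_false(difference_method(total, mv_w, "bmi")$usable)

  b_em <- wald_ratio(1, 0.01, 0.5, 0.03)
  b_mo <- wald_ratio(1, 0.01, 0.2, 0.02)
  p <- product_method(b_em, b_mo, total)
  expect_equal(p$beta_indirect, 0.10)
  expect_equal(p$proportion_mediated, 0.25)
  expect_equal(p$se_indirect, sqrt(0.5^2 * 0.02^2 + 0.2^2 * 0.03^2))

  b_mo0 <- wald_ratio(1, 0.01, 0, 0.02)
  p0 <- product_method(b_em, b_mo0, total)
  expect_equal(p0$beta_indirect, 0)
  expect_equal(p0$proportion_mediated, 0)

  total0 <- total; total0$beta <- 0
  expect_error(product_method(b_em, b_mo, total0),
               class = "mrtriad_undefined_proportion")

  # bilinearity of the product indirect effect
  b_em2 <- b_em; b_em2$beta <- 2 * b_em$beta
  expect_equal(product_method(b_em2, b_mo, total)$beta_indirect,
               2 * p$beta_indirect)
})

test_that("the sign-consistency filter follows sign algebra with zero exclusion", {
  expect_true(sign_consistency_filter(0.2, 0.3, 0.5)$keep)
  expect_false(sign_consistency_filter(0.2, -0.3, 0.5)$keep)
  expect_true(sign_consistency_filter(-0.2, -0.3, 0.5)$keep)
  z <- sign_consistency_filter(0, 0.3, 0.5)
  expect_false(z$keep)
  expect_equal(z$reason, "zero-effect")
  expect_error(sign_consistency_filter(NA, 1, 1), "finite")
})

test_that("overlapping instruments are removed from the larger study only", {
  panel <- small_panel()
  v <- panel$variants
  b1 <- v$snp_id[v$block == 1]
  b2 <- v$snp_id[v$block == 2]
  b3 <- v$snp_id[v$block == 3]

  # disjoint blocks, far apart: nothing removed
  f0 <- overlap_iv_filter(b1[1], b2[1], panel, 1e5, 5e4)
  expect_equal(nrow(f0$removals), 0)

  # identical shared SNP: removed from the larger-n set (exposure)
  f1 <- overlap_iv_filter(c(b1[1], b3[1]), b1[1], panel, 1e5, 5e4)
  expect_equal(f1$exposure_ivs, b3[1])
  expect_equal(f1$mediator_ivs, b1[1])
  expect_equal(f1$removals$removed_from, "exposure")

  # larger mediator study loses its member instead
  f2 <- overlap_iv_filter(b1[1], c(b1[2], b2[1]), panel, 5e4, 1e5)
  expect_equal(f2$exposure_ivs, b1[1])
  expect_setequal(f2$mediator_ivs, b2[1])
  expect_equal(f2$removals$removed_from, "mediator")
  # never removes from both sets for one overlapping pair
  expect_false(any(f2$removals$snp_id %in% f2$exposure_ivs) &&
                 any(f2$removals$snp_id %in% f2$mediator_ivs))

  # one in-LD cross pair matches a brute-force pair scan
  exp_ivs <- c(b1[1], b2[1])
  med_ivs <- c(b1[3], b3[1])
  f3 <- overlap_iv_filter(exp_ivs, med_ivs, panel, 2e5, 1e5)
  overlap_pairs <- 0
  for (e in exp_ivs) for (mm in med_ivs) {
    same_chr <- v$chrom[v$snp_id == e] == v$chrom[v$snp_id == mm]
    close <- abs(v$pos[v$snp_id == e] - v$pos[v$snp_id == mm]) <= 5e5
    r2 <- cor(panel$dosages[, e], panel$dosages[, mm])^2
    if (same_chr && close && r2 >= 0.01) overlap_pairs <- overlap_pairs + 1
  }
  expect_equal(nrow(f3$removals), overlap_pairs)
  expect_equal(f3$removals$removed_from, rep("exposure", overlap_pairs))
})

test_that("method selection prefers difference and falls back on weakness or pleiotropy", {
  mk <- function(weak, pleio) structure(list(weak_flag = weak, pleiotropy_flag = pleio),
                                        class = "mvmr_result")
  expect_equal(select_mediation_method(mk(FALSE, FALSE)), "difference")
  expect_equal(select_mediation_method(mk(TRUE, FALSE)), "product")
  expect_equal(select_mediation_method(mk(FALSE, TRUE)), "product")
})

test_that("difference and product agree on a clean strong simulation", {
  panel <- small_panel()
  cfg <- sim_config(n_exposure_gwas = 100000, n_metabolite_gwas = 100000,
                    n_outcome_cases = 100000, n_outcome_controls = 100000,
                    n_causal_snps = 12, n_metabolite_specific = 12,
                    palindrome_fraction = 0, seed = 404)
  truth <- triad_truth(0.4, 0.3, 0.12)
  tr <- simulate_triad_study(panel, cfg, truth)
  exp_ivs <- clump(tr$exposure, panel)
  med_ivs <- clump(tr$metabolite, panel)
  h_total <- harmonise(tr$exposure[tr$exposure$snp_id %in% exp_ivs$index_snps, ],
                       tr$outcome)
  total <- ivw(h_total, "fixed", binary = TRUE)
  union_ivs <- reclump_union(list(tr$exposure, tr$metabolite), panel)
  mv <- mvmr_ivw(list(tr$exposure, tr$metabolite), tr$outcome, union_ivs)
  d <- difference_method(total, mv, "exposure")
  flt <- overlap_iv_filter(exp_ivs, med_ivs, panel, 100000, 100000)
  b_em <- ivw(harmonise(tr$exposure[tr$exposure$snp_id %in% flt$exposure_ivs, ],
                        tr$metabolite), "fixed")
  b_mo <- ivw(harmonise(tr$metabolite[tr$metabolite$snp_id %in% flt$mediator_ivs, ],
                        tr$outcome), "fixed", binary = TRUE)
  p <- product_method(b_em, b_mo, total)
  expect_lt(abs(d$proportion_mediated - p$proportion_mediated), 0.05)
  expect_lt(abs(p$proportion_mediated - truth$proportion_mediated), 0.1)
})
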