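test_that("the Wald ratio follows the first-order delta formulas", {
  r <- wald_ratio(0.5, 0.05, 0.1, 0.02)
  expect_equal(r$beta, 0.2)
  expect_equal(r$se, 0.04)
  r0 <- wald_ratio(0.5, 0.05, 0, 0.02)
  expect_equal(r0$beta, 0)
  expect_equal(r0$pval, 1)
  # sign symmetry: negating the exposure effect negates the estimate
  rn <- wald_ratio(-0.5, 0.05, 0.1, 0.02)
  expect_equal(rn$beta, -0.2)
  expect_equal(rn$se, 0.04)
  expect_error(wald_ratio(0, 0.05, 0.1, 0.02),
               class = "mrtriad_degenerate_instrument")
  # binary outcomes carry the OR per SD
  rb <- wald_ratio(0.5, 0.05, 0.1, 0.02, binary = TRUE)
  expect_equal(rb$or_sd, exp(0.2))
})

test_that("IVW equals the inverse-variance-weighted mean of Wald ratios", {
  a <- make_aligned(beta_exp = c(0.2, 0.5, 0.35), se_exp = c(0.01, 0.01, 0.01),
                    beta_out = c(0.05, 0.16, 0.10), se_out = c(0.02, 0.03, 0.025))
  est <- ivw(a, "fixed")
  ratio <- a$beta_out / a$beta_exp
  w <- a$beta_exp^2 / a$se_out^2
  expect_equal(est$beta, sum(w * ratio) / sum(w), tolerance = 1e-12)
  expect_equal(est$se, sqrt(1 / sum(w)), tolerance = 1e-12)

  # duplicated single instrument: estimate equals the common Wald ratio
  a2 <- make_aligned(beta_exp = c(0.4, 0.4), se_exp = c(0.01, 0.01),
                     beta_out = c(0.12, 0.12), se_out = c(0.02, 0.02),
                     snp_id = c("s1", "s2"))
  expect_equal(ivw(a2, "fixed")$beta, 0.3)

  # homogeneity: random-effects SE equals fixed-effects SE (floor at 1)
  expect_equal(ivw(a2, "random")$se, ivw(a2, "fixed")$se)
  expect_error(ivw(a2[1, ]), class = "mrtriad_routing")
})

test_that("MR-Egger recovers an exact line and respects balanced pleiotropy", {
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  a <- make_aligned(beta_exp = x, se_exp = rep(0.01, 5),
                    beta_out = 0.05 + 0.3 * x, se_out = rep(0.02, 5))
  e <- egger(a)
  expect_equal(e$slope$beta, 0.3, tolerance = 1e-12)
  expect_equal(e$intercept, 0.05, tolerance = 1e-12)

  # symmetric +/- offsets with equal weights: intercept 0
  a2 <- make_aligned(beta_exp = c(0.1, 0.1, 0.3, 0.3),
                     se_exp = rep(0.01, 4),
                     beta_out = c(0.3 * 0.1 + 0.02, 0.3 * 0.1 - 0.02,
                                  0.3 * 0.3 + 0.02, 0.3 * 0.3 - 0.02),
                     se_out = rep(0.02, 4))
  expect_equal(egger(a2)$intercept, 0, tolerance = 1e-12)

  # orientation: flipping an instrument's signs changes nothing
  a3 <- a
  a3$beta_exp[2] <- -a3$beta_exp[2]
  a3$beta_out[2] <- -a3$beta_out[2]
  expect_equal(egger(a3)$slope$beta, e$slope$beta)
  expect_error(egger(a[1:2, ]), class = "mrtriad_not_applicable")
})

test_that("Egger intercept test is calibrated under no pleiotropy", {
  set.seed(11)
  rejected <- replicate(400, {
    x <- abs(rnorm(20, 0.2, 0.05))
    se_out <- runif(20, 0.015, 0.03)
    y <- 0.25 * x + rnorm(20, 0, se_out)
    a <- make_aligned(x, rep(1e-4, 20), y, se_out)
    egger(a)$intercept_pval < 0.05
  })
  expect_lt(abs(mean(rejected) - 0.05), 0.035)
})

test_that("median estimators reduce correctly and match the cumulative-weight oracle", {
  a <- make_aligned(beta_exp = rep(1, 3), se_exp = rep(0.01, 3),
                    beta_out = c(0.1, 0.2, 0.9), se_out = rep(0.02, 3))
  expect_equal(median_estimator(a, "simple", n_boot = 200, seed = 1)$beta, 0.2)
  # equal weights: weighted equals simple
  expect_equal(median_estimator(a, "weighted", n_boot = 200, seed = 1)$beta, 0.2)

  # 5-instrument fixture vs the direct cumulative-weight definition
  a5 <- make_aligned(beta_exp = c(0.2, 0.3, 0.25, 0.5, 0.4),
                     se_exp = rep(0.01, 5),
                     beta_out = c(0.05, 0.10, 0.06, 0.18, 0.11),
                     se_out = c(0.02, 0.01, 0.03, 0.015, 0.02))
  ratio <- a5$beta_out / a5$beta_exp
  w <- a5$beta_exp^2 / a5$se_out^2
  ord <- order(ratio)
  rw <- w[ord] / sum(w)
  cum <- cumsum(rw) - rw / 2
  expected <- approx(cum, ratio[ord], xout = 0.5)$y
  got <- median_estimator(a5, "weighted", n_boot = 200, seed = 1)
  expect_equal(got$beta, expected)
  expect_warning(median_estimator(a5, "simple", n_boot = 50, seed = 1), "unstable")
})

test_that("mode estimators find the density peak and resist outliers", {
  a_same <- make_aligned(beta_exp = rep(1, 3), se_exp = rep(0.01, 3),
                         beta_out = rep(0.2, 3), se_out = rep(0.02, 3))
  expect_equal(mode_estimator(a_same, "simple", n_boot = 100, seed = 1)$beta, 0.2)

  a_out <- make_aligned(beta_exp = rep(1, 4), se_exp = rep(0.01, 4),
                        beta_out = c(0.2, 0.2, 0.2, 5.0), se_out = rep(0.02, 4))
  est <- mode_estimator(a_out, "simple", n_boot = 100, seed = 1)
  expect_lt(abs(est$beta - 0.2), 0.05)

  # seeded bootstrap reproduces the SE exactly
  s1 <- mode_estimator(a_out, "weighted", n_boot = 200, seed = 9)$se
  s2 <- mode_estimator(a_out, "weighted", n_boot = 200, seed = 9)$se
  expect_identical(s1, s2)
  expect_error(mode_estimator(a_out, bandwidth_factor = 0), "positive")
})

test_that("maximum likelihood matches IVW when exposure error vanishes and exact data", {
  a <- make_aligned(beta_exp = c(0.2, 0.5, 0.35), se_exp = rep(1e-8, 3),
                    beta_out = c(0.05, 0.16, 0.10), se_out = c(0.02, 0.03, 0.025))
  ml <- max_likelihood(a)
  expect_lt(abs(ml$beta - ivw(a, "fixed")$beta), 1e-6)

  x <- c(0.1, 0.25, 0.4)
  a2 <- make_aligned(x, rep(0.01, 3), 0.3 * x, rep(0.02, 3))
  expect_equal(max_likelihood(a2)$beta, 0.3, tolerance = 1e-6)
  expect_true(max_likelihood(a2)$converged)
})

test_that("Cochran's Q is zero for identical ratios and matches hand arithmetic", {
  a <- make_aligned(beta_exp = c(0.2, 0.4), se_exp = rep(0.01, 2),
                    beta_out = c(0.06, 0.12), se_out = rep(0.02, 2))
  q <- cochran_q(a)
  expect_equal(q$Q, 0, tolerance = 1e-20)
  expect_equal(q$Q_pval, 1)

  a2 <- make_aligned(beta_exp = c(0.2, 0.4), se_exp = rep(0.01, 2),
                     beta_out = c(0.05, 0.14), se_out = c(0.02, 0.03))
  ratio <- a2$beta_out / a2$beta_exp
  w <- a2$beta_exp^2 / a2$se_out^2
  bref <- sum(w * ratio) / sum(w)
  q_hand <- sum(w * (ratio - bref)^2)
  got <- cochran_q(a2)
  expect_equal(got$Q, q_hand, tolerance = 1e-12)
  expect_equal(got$Q_pval, pchisq(q_hand, 1, lower.tail = FALSE))
})

test_that("Q p-values are uniform under homogeneity", {
  set.seed(21)
  pvals <- replicate(500, {
    x <- rnorm(10, 0.3, 0.05)
    se_out <- runif(10, 0.01, 0.03)
    y <- 0.2 * x + rnorm(10, 0, se_out)
    cochran_q(make_aligned(x, rep(1e-6, 10), y, se_out))$Q_pval
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("leave-one-out finds planted drivers and stays silent otherwise", {
  # 4 imprecise null instruments + 1 precise instrument carrying the signal
  a <- make_aligned(beta_exp = rep(0.3, 5), se_exp = rep(0.01, 5),
                    beta_out = c(0.0003, -0.0006, 0.00015, -0.0003, 0.0045),
                    se_out = c(rep(0.0045, 4), 0.0009))
  lo <- leave_one_out(a)
  expect_equal(nrow(lo$loo), 5)
  expect_equal(lo$driver_snp, "s5")

  # homogeneous strong signal: no driver
  x <- seq(0.2, 0.6, length.out = 5)
  a2 <- make_aligned(x, rep(0.01, 5), 0.4 * x, rep(0.005, 5))
  lo2 <- leave_one_out(a2)
  expect_true(is.na(lo2$driver_snp))
})

test_that("the bidirectional rule uses strict inequalities at alpha", {
  f <- wald_ratio(0.5, 0.01, 0.3, 0.02)   # p tiny
  r_ns <- wald_ratio(0.5, 0.01, 0.01, 0.02)  # p large
  expect_false(bidirectional(f, r_ns))
  r_sig <- wald_ratio(0.5, 0.01, 0.3, 0.02)
  expect_true(bidirectional(f, r_sig))
  # p exactly at alpha is not significant
  z <- qnorm(1 - 0.025)
  r_boundary <- wald_ratio(1, 0.01, z * 0.02, 0.02)
  expect_equal(r_boundary$pval, 0.05)
  expect_false(bidirectional(f, r_boundary, alpha = 0.05))
})

test_that("estimates are equivariant under outcome scaling and agree for one instrument", {
  a <- make_aligned(beta_exp = c(0.2, 0.5, 0.35, 0.4),
                    se_exp = rep(0.01, 4),
                    beta_out = c(0.05, 0.16, 0.10, 0.13),
                    se_out = c(0.02, 0.03, 0.025, 0.02))
  for (c_scale in c(2, -0.5)) {
    a_s <- a
    a_s$beta_out <- a$beta_out * c_scale
    a_s$se_out <- a$se_out * abs(c_scale)
    expect_equal(ivw(a_s, "fixed")$beta, c_scale * ivw(a, "fixed")$beta,
                 tolerance = 1e-10)
    expect_equal(egger(a_s)$slope$beta, c_scale * egger(a)$slope$beta,
                 tolerance = 1e-10)
    expect_equal(median_estimator(a_s, "weighted", 100, 1)$beta,
                 c_scale * median_estimator(a, "weighted", 100, 1)$beta,
                 tolerance = 1e-10)
  }
})

test_that("the suite routes by instrument count and reports concordance", {
  a1 <- make_aligned(0.5, 0.01, 0.15, 0.02)
  s1 <- run_mr_suite(a1)
  expect_equal(s1$primary$method, "wald_ratio")
  expect_equal(s1$verdict, "pass")

  tr <- small_triad()
  ivs <- clump(tr$exposure, small_panel())
  h <- harmonise(tr$exposure[tr$exposure$snp_id %in% ivs$index_snps, ],
                 tr$metabolite)
  s <- run_mr_suite(h, n_boot = 200, seed = 3)
  expect_equal(s$primary$method, "ivw_random")
  expect_true(all(c("egger", "weighted_median", "weighted_mode",
                    "max_likelihood") %in% s$estimates$method))
  expect_true(s$sensitivity$method_concordance)
  expect_equal(nrow(s$loo), s$primary$n_snp)

  empty <- run_mr_suite(make_aligned(numeric(), numeric(), numeric(), numeric()))
  expect_equal(empty$verdict, "not_testable")
})
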