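test_that("the full test pipeline reproduces the otitis media analysis", {
  res <- or_homogeneity_test(or_fixture("aom"))
  expect_equal(res$df, 2)
  expect_equal(res$T_LR, 4.732, tolerance = 1e-3)
  expect_equal(res$T_SC, 4.6925, tolerance = 1e-3)
  expect_equal(res$T_W, 4.70, tolerance = 3e-3)
  # none of the tests rejects at 5% (critical value 5.9915)
  crit <- qchisq(0.95, 2)
  expect_lt(res$T_LR, crit); expect_lt(res$T_SC, crit); expect_lt(res$T_W, crit)
  expect_true(all(c(res$p_LR, res$p_SC, res$p_W) > 0.05))
})

test_that("exact copies of one stratum produce zero statistics", {
  set.seed(110)
  cj <- rand_counts_j(n_mean = 10, m_mean = 15)
  n <- array(rep(cj$n, 3), c(2, 2, 3))
  m <- array(rep(cj$m, 3), c(3, 2, 3))
  res <- or_homogeneity_test(stratified_counts(n, m))
  expect_lt(res$T_LR, 1e-6)
  expect_lt(res$T_SC, 1e-6)
  expect_lt(res$T_W, 1e-6)
})

test_that("statistics are invariant to stratum relabeling", {
  aom <- or_fixture("aom")
  res <- or_homogeneity_test(aom)
  perm <- c(3, 1, 2)
  shuffled <- stratified_counts(aom$n[, , perm], aom$m[, , perm],
                                aom$labels[perm])
  res2 <- or_homogeneity_test(shuffled)
  expect_equal(res2$T_LR, res$T_LR, tolerance = 1e-6)
  expect_equal(res2$T_SC, res$T_SC, tolerance = 1e-6)
  expect_equal(res2$T_W, res$T_W, tolerance = 1e-6)
})

test_that("the Wald quadratic form matches a longhand two-stratum computation", {
  set.seed(111)
  x <- rand_stratified(J = 2, n_mean = 15, m_mean = 20)
  fu <- fit_unconstrained(x)
  tw <- wald_statistic(x, fu)
  # longhand: T_W = (log th1 - log th2)^2 / (var log th1 + var log th2),
  # with var log th_j from the delta method on the 3x3 information block
  lth <- vth <- numeric(2)
  for (j in 1:2) {
    B <- bilatOR:::stratum_info_base(stratum_counts(x, j), fu$pi1[j],
                                     fu$pi2[j], fu$rho[j])
    Binv <- solve(B)
    g <- c(1 / (fu$pi1[j] * (1 - fu$pi1[j])),
           -1 / (fu$pi2[j] * (1 - fu$pi2[j])))
    lth[j] <- log(fu$theta[j])
    vth[j] <- t(g) %*% Binv[1:2, 1:2] %*% g
  }
  expect_equal(tw, (lth[1] - lth[2])^2 / sum(vth), tolerance = 1e-8)
})

test_that("Wald statistic is invariant to the contrast basis", {
  aom <- or_fixture("aom")
  fu <- fit_unconstrained(aom)
  tw <- wald_statistic(aom, fu)
  # recompute with an alternative full-rank contrast of the log odds
  # ratios (each stratum versus the last) on the same covariance
  J <- 3
  delta <- V <- NULL
  delta <- numeric(3 * J); V <- matrix(0, 3 * J, 3 * J)
  for (j in 1:J) {
    idx <- 3 * (j - 1) + 1:3
    p1 <- fu$pi1[j]; p2 <- fu$pi2[j]; rh <- fu$rho[j]
    delta[idx] <- c(qlogis(p1), qlogis(p2), log(rh))
    B <- bilatOR:::stratum_info_base(stratum_counts(aom, j), p1, p2, rh)
    g <- diag(c(1 / (p1 * (1 - p1)), 1 / (p2 * (1 - p2)), 1 / rh))
    V[idx, idx] <- g %*% solve(B) %*% g
  }
  C2 <- matrix(0, J - 1, 3 * J)
  for (r in 1:(J - 1)) {
    C2[r, 3 * (r - 1) + 1:2] <- c(1, -1)
    C2[r, 3 * (J - 1) + 1:2] <- c(-1, 1)
  }
  cd <- as.vector(C2 %*% delta)
  tw2 <- drop(t(cd) %*% solve(C2 %*% V %*% t(C2)) %*% cd)
  expect_equal(tw2, tw, tolerance = 1e-8)
})

test_that("nuisance scores vanish at the constrained maximum", {
  for (name in c("aom", "myopia")) {
    x <- or_fixture(name)
    fc <- suppressWarnings(fit_constrained(x))
    for (j in seq_len(x$J)) {
      cj <- stratum_counts(x, j)
      expect_lt(abs(bilatOR:::dl_dpi1_constrained(cj, fc$pi1[j], fc$rho[j],
                                                  fc$theta_common)), 1e-5)
      expect_lt(abs(dl_drho(cj, fc$pi1[j], fc$pi2[j], fc$rho[j])), 1e-5)
    }
    # and so does the pooled odds-ratio score
    sc <- sum(vapply(seq_len(x$J), function(j)
      bilatOR:::dl_dtheta(stratum_counts(x, j), fc$pi1[j], fc$rho[j],
                          fc$theta_common), 0))
    expect_lt(abs(sc), 1e-5)
  }
})

test_that("chi-square p-values are the upper tail at J - 1 df", {
  expect_lt(abs(chi2_pvalue(4.7324, 2) - 0.0938), 1e-4)
  expect_lt(abs(chi2_pvalue(3.8689, 1) - 0.0492), 1e-4)
  expect_identical(chi2_pvalue(0, 2), 1)
  expect_error(chi2_pvalue(1.5, 0), "df")
  expect_error(chi2_pvalue(-1, 2), "non-negative")
})

test_that("single-stratum data admit no homogeneity test", {
  set.seed(112)
  x <- suppressWarnings(rand_stratified(J = 1))
  expect_error(suppressWarnings(or_homogeneity_test(x)), "J = 1")
})

test_that("mismatched fits and data are refused", {
  aom <- or_fixture("aom")
  myo <- or_fixture("myopia")
  fu <- fit_unconstrained(aom)
  fc <- suppressWarnings(fit_constrained(myo))
  expect_error(lr_statistic(fu, fc), "different data")
  expect_error(score_statistic(aom, fc), "correspond")
  expect_error(wald_statistic(myo, fu), "correspond")
})

test_that("null statistics track the chi-square reference in large samples", {
  set.seed(113)
  spec <- sim_spec(J = 2, m = 2000, n = 2000, pi1 = 0.3, rho = 0.5, theta = 1,
                   reps = 1)
  stats <- replicate(200, {
    x <- sample_counts(spec)
    fu <- fit_unconstrained(x)
    fc <- fit_constrained(x, fit_u = fu)
    c(lr_statistic(fu, fc), score_statistic(x, fc), wald_statistic(x, fu))
  })
  for (k in 1:3) {
    ks <- suppressWarnings(ks.test(stats[k, ], "pchisq", df = 1))
    expect_gt(ks$p.value, 0.001)
  }
})
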