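test_that("category probabilities form a simplex and match known cases", {
  # independence reduces to Binomial(2, pi); perfect correlation to one
  # Bernoulli; degenerate event rates put all mass in one cell
  expect_equal(unname(category_probs(0.5, 0)), c(0.25, 0.5, 0.25))
  expect_equal(unname(category_probs(0.3, 1)), c(0.7, 0, 0.3))
  expect_equal(unname(category_probs(0, 0.6)), c(1, 0, 0))
  for (pi in seq(0, 1, by = 0.1)) for (rho in seq(0, 1, by = 0.1)) {
    p <- category_probs(pi, rho)
    expect_true(all(p >= -1e-15))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  expect_error(category_probs(-0.1, 0.5), "pi")
  expect_error(category_probs(0.5, 1.2), "rho")
})

test_that("stratum log-likelihood equals the cell-by-cell oracle", {
  zero <- list(n = matrix(0, 2, 2), m = matrix(0, 3, 2))
  expect_identical(stratum_loglik(zero, 0.3, 0.6, 0.4), 0)
  set.seed(101)
  for (rep in 1:25) {
    cj <- rand_counts_j()
    pars <- c(runif(2, 0.05, 0.95), runif(1, 0.05, 0.9))
    expect_equal(stratum_loglik(cj, pars[1], pars[2], pars[3]),
                 cellwise_loglik(cj, pars[1], pars[2], pars[3]),
                 tolerance = 1e-12)
  }
  # a probability outside its domain with a positive count is a hard error
  cj <- list(n = matrix(c(1, 1, 1, 1), 2, 2), m = matrix(1, 3, 2))
  expect_error(stratum_loglik(cj, -0.2, 0.5, 0.4), "non-positive")
})

test_that("constrained log-likelihood is the exact substitution image", {
  set.seed(102)
  for (rep in 1:20) {
    cj <- rand_counts_j()
    pi1 <- runif(1, 0.05, 0.95); rho <- runif(1, 0, 0.9)
    theta <- exp(runif(1, -1.5, 1.5))
    expect_identical(constrained_stratum_loglik(cj, pi1, rho, theta),
                     stratum_loglik(cj, pi1, pi2_from_theta(pi1, theta), rho))
    # theta implied by an arbitrary (pi1, pi2) pair reproduces the free value
    pi2 <- runif(1, 0.05, 0.95)
    th <- pi1 * (1 - pi2) / (pi2 * (1 - pi1))
    expect_equal(constrained_stratum_loglik(cj, pi1, rho, th),
                 stratum_loglik(cj, pi1, pi2, rho), tolerance = 1e-10)
  }
  # null odds ratio collapses the two groups onto one probability
  cj <- rand_counts_j()
  expect_equal(constrained_stratum_loglik(cj, 0.37, 0.25, 1),
               stratum_loglik(cj, 0.37, 0.37, 0.25), tolerance = 1e-12)
})

test_that("analytic scores match central finite differences", {
  zero <- list(n = matrix(0, 2, 2), m = matrix(0, 3, 2))
  expect_identical(dl_dpi(zero, 1, 0.4, 0.3), 0)
  uni <- list(n = matrix(c(3, 5, 2, 4), 2, 2), m = matrix(0, 3, 2))
  expect_identical(dl_drho(uni, 0.4, 0.5, 0.3), 0)
  set.seed(103)
  for (rep in 1:30) {
    cj <- rand_counts_j()
    pi1 <- runif(1, 0.1, 0.9); pi2 <- runif(1, 0.1, 0.9)
    rho <- runif(1, 0.05, 0.85)
    for (i in 1:2) {
      pii <- c(pi1, pi2)[i]
      num <- fd(function(p) stratum_loglik(cj, if (i == 1) p else pi1,
                                           if (i == 2) p else pi2, rho), pii)
      expect_equal(dl_dpi(cj, i, pii, rho), num,
                   tolerance = 1e-6 * max(1, abs(num)))
    }
    num <- fd(function(r) stratum_loglik(cj, pi1, pi2, r), rho)
    expect_equal(dl_drho(cj, pi1, pi2, rho), num,
                 tolerance = 1e-6 * max(1, abs(num)))
    # the constrained-model scores follow the same contract
    theta <- exp(runif(1, -1, 1))
    numt <- fd(function(t) constrained_stratum_loglik(cj, pi1, rho, t), theta)
    expect_equal(bilatOR:::dl_dtheta(cj, pi1, rho, theta), numt,
                 tolerance = 1e-5 * max(1, abs(numt)))
    nump <- fd(function(p) constrained_stratum_loglik(cj, p, rho, theta), pi1)
    expect_equal(bilatOR:::dl_dpi1_constrained(cj, pi1, rho, theta), nump,
                 tolerance = 1e-5 * max(1, abs(nump)))
  }
})

test_that("closed-form root maximizes the group likelihood", {
  # no bilateral subjects: reduces to the binomial MLE
  uni <- list(n = matrix(c(3, 9, 0, 0), 2, 2), m = matrix(0, 3, 2))
  expect_equal(as.numeric(pi_closed_form(uni, 1, 0.3)), 9 / 12,
               tolerance = 1e-9)
  # symmetric bilateral data at independence
  sym <- list(n = matrix(0, 2, 2), m = matrix(c(5, 10, 5, 1, 1, 1), 3, 2))
  expect_equal(as.numeric(pi_closed_form(sym, 1, 0)), 0.5, tolerance = 1e-9)
  expect_error(pi_closed_form(sym, 1, 1), "rho")
  set.seed(104)
  for (rep in 1:200) {
    cj <- rand_counts_j()
    rho <- runif(1, 0, 0.92)
    for (i in 1:2) {
      root <- as.numeric(pi_closed_form(cj, i, rho))
      oracle <- brute_pi_max(cj, i, rho)
      if (oracle$maximum > 1e-5 && oracle$maximum < 1 - 1e-5) {
        expect_equal(root, oracle$maximum, tolerance = 1e-6)
        expect_lt(abs(dl_dpi(cj, i, root, rho)), 1e-8)
      }
    }
  }
})

test_that("rho information matches the expected negative Hessian", {
  nob <- list(n = matrix(1, 2, 2), m = matrix(0, 3, 2))
  expect_identical(rho_information(nob, 0.3, 0.4, 0.5), 0)
  cj1 <- list(n = matrix(0, 2, 2), m = matrix(c(10, 20, 20, 15, 10, 25), 3, 2))
  cj2 <- list(n = matrix(0, 2, 2), m = matrix(2 * c(10, 20, 20, 15, 10, 25), 3, 2))
  expect_equal(rho_information(cj2, 0.3, 0.4, 0.5),
               2 * rho_information(cj1, 0.3, 0.4, 0.5), tolerance = 1e-12)
  # expectation oracle: -E d^2 l / d rho^2 with counts replaced by
  # m_{+i} p_t and the second derivative taken numerically
  mplus <- c(50, 50)
  cj <- list(n = matrix(0, 2, 2), m = matrix(c(50, 0, 0, 50, 0, 0), 3, 2))
  pis <- c(0.3, 0.4); rho <- 0.5
  h <- 1e-4
  acc <- 0
  for (i in 1:2) {
    p0 <- unname(category_probs(pis[i], rho))
    for (t in 1:3) {
      d2 <- unname((log(category_probs(pis[i], rho + h)[t]) -
                      2 * log(p0[t]) +
                      log(category_probs(pis[i], rho - h)[t])) / h^2)
      acc <- acc - mplus[i] * p0[t] * d2
    }
  }
  expect_equal(rho_information(cj, pis[1], pis[2], rho), acc,
               tolerance = 1e-6 * acc)
})

test_that("expected information blocks match averaged numerical Hessians", {
  # 2x2 group block in (pi, rho), checked entry-wise against the
  # expectation of the outer product of numerical score vectors
  pi <- 0.35; rho <- 0.45; mplus <- 40; nplus <- 25
  I <- bilatOR:::expected_info_group(pi, rho, mplus, nplus)
  h <- 1e-5
  num <- matrix(0, 2, 2)
  p <- unname(category_probs(pi, rho))
  for (t in 1:3) {
    gpi <- unname((log(category_probs(pi + h, rho)[t]) -
                     log(category_probs(pi - h, rho)[t])) / (2 * h))
    grh <- unname((log(category_probs(pi, rho + h)[t]) -
                     log(category_probs(pi, rho - h)[t])) / (2 * h))
    num <- num + mplus * p[t] * outer(c(gpi, grh), c(gpi, grh))
  }
  num[1, 1] <- num[1, 1] + nplus / (pi * (1 - pi))
  expect_equal(I, num, tolerance = 1e-6)
})
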