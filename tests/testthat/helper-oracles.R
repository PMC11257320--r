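# Independent oracles used across the test files.  These deliberately
# avoid the package's analytic derivative / closed-form / scoring code
# paths: finite differences, 1-D golden-section search, and generic
# multi-start box-constrained optimization.

# central finite difference of f at x
fd <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# random single-stratum counts with both groups observed
rand_counts_j <- function(n_mean = 8, m_mean = 12) {
  repeat {
    n <- matrix(rpois(4, n_mean), 2, 2)
    m <- matrix(rpois(6, m_mean), 3, 2)
    if (all(colSums(n) + colSums(m) >= 1)) return(list(n = n, m = m))
  }
}

# random stratified dataset with J strata
rand_stratified <- function(J = 2, n_mean = 8, m_mean = 12) {
  n <- array(0, c(2, 2, J)); m <- array(0, c(3, 2, J))
  for (j in seq_len(J)) {
    cj <- rand_counts_j(n_mean, m_mean)
    n[, , j] <- cj$n; m[, , j] <- cj$m
  }
  stratified_counts(n, m)
}

# brute-force per-cell log-likelihood: sum count * log(prob) term by term
cellwise_loglik <- function(counts_j, pi1, pi2, rho) {
  tot <- 0
  for (i in 1:2) {
    pi <- c(pi1, pi2)[i]
    p <- unname(category_probs(pi, rho))
    nc <- counts_j$n[, i]; mc <- counts_j$m[, i]
    if (nc[1] > 0) tot <- tot + nc[1] * log(1 - pi)
    if (nc[2] > 0) tot <- tot + nc[2] * log(pi)
    for (t in 1:3) if (mc[t] > 0) tot <- tot + mc[t] * log(p[t])
  }
  tot
}

# 1-D maximizer of one group's log-likelihood in pi (rho fixed)
brute_pi_max <- function(counts_j, i, rho) {
  f <- function(p) {
    cj1 <- counts_j
    cellwise_group <- function(pi) {
      pr <- unname(category_probs(pi, rho))
      nc <- cj1$n[, i]; mc <- cj1$m[, i]
      out <- 0
      if (nc[1] > 0) out <- out + nc[1] * log(1 - pi)
      if (nc[2] > 0) out <- out + nc[2] * log(pi)
      for (t in 1:3) if (mc[t] > 0) out <- out + mc[t] * log(pr[t])
      out
    }
    cellwise_group(p)
  }
  stats::optimize(f, c(1e-9, 1 - 1e-9), maximum = TRUE, tol = 1e-10)
}

# multi-start direct maximization of one stratum's (pi1, pi2, rho)
brute_fit_stratum <- function(counts_j) {
  obj <- function(p) -cellwise_loglik(counts_j, p[1], p[2], p[3])
  best <- list(value = Inf)
  for (s in list(c(.5, .5, .5), c(.25, .7, .2), c(.8, .3, .8))) {
    o <- try(optim(s, obj, method = "L-BFGS-B", lower = rep(1e-9, 3),
                   upper = rep(1 - 1e-9, 3), control = list(factr = 1e2)),
             silent = TRUE)
    if (!inherits(o, "try-error") && o$value < best$value) best <- o
  }
  list(par = best$par, loglik = -best$value)
}

# multi-start direct maximization of the constrained model (common theta)
brute_fit_constrained <- function(counts) {
  J <- counts$J
  cjs <- lapply(seq_len(J), function(j) stratum_counts(counts, j))
  obj <- function(p) {
    th <- exp(p[2 * J + 1])
    -sum(vapply(seq_len(J), function(j) {
      pi2 <- pi2_from_theta(p[j], th)
      cellwise_loglik(cjs[[j]], p[j], pi2, p[J + j])
    }, 0))
  }
  best <- list(value = Inf)
  for (th0 in c(0, log(0.5), log(2))) {
    s <- c(rep(.4, J), rep(.5, J), th0)
    o <- try(optim(s, obj, method = "L-BFGS-B",
                   lower = c(rep(1e-9, 2 * J), -12),
                   upper = c(rep(1 - 1e-9, 2 * J), 12),
                   control = list(factr = 1e2)), silent = TRUE)
    if (!inherits(o, "try-error") && o$value < best$value) best <- o
  }
  list(par = best$par, loglik = -best$value,
       theta = exp(best$par[2 * counts$J + 1]))
}
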