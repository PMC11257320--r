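# Donner rho-model likelihood machinery.
#
# Parameterization per stratum j: pi_ij is the event probability shared by
# both organs of a subject in group i, rho_j the within-subject intraclass
# correlation (common to the two groups of a stratum).  A bilateral subject
# contributes a trinomial cell (0/1/2 responding organs); a unilateral
# subject a Bernoulli response.  All combinatorial constants are dropped so
# that differences of log-likelihoods are exact.

.PEPS <- 1e-10  # probability clamp; binding clamps raise boundary flags

clamp01 <- function(x, lo = .PEPS, hi = 1 - .PEPS) {
  if (length(x) == 1L) {
    if (x < lo) lo else if (x > hi) hi else x
  } else pmin(pmax(x, lo), hi)
}

# unchecked, unnamed category probabilities for hot loops
cat_probs_ <- function(pi, rho) {
  c((1 - pi) * (rho * pi - pi + 1),
    2 * pi * (1 - pi) * (1 - rho),
    pi * (rho + pi - rho * pi))
}

#' Trinomial category probabilities under the intraclass-correlation model
#'
#' For a bilateral subject with per-organ event probability \code{pi} and
#' within-subject correlation \code{rho}, the probabilities of 0, 1 or 2
#' responding organs are
#' \deqn{p_0 = (1-\pi)(\rho\pi - \pi + 1),\quad
#'       p_1 = 2\pi(1-\pi)(1-\rho),\quad
#'       p_2 = \pi(\rho + \pi - \rho\pi).}
#'
#' @param pi event probability in \code{[0, 1]}.
#' @param rho intraclass correlation in \code{[0, 1]}.
#' @return numeric vector \code{c(p0, p1, p2)} summing to 1.
#' @export
category_probs <- function(pi, rho) {
  if (!is.finite(pi) || pi < 0 || pi > 1) stop("'pi' must lie in [0, 1]")
  if (!is.finite(rho) || rho < 0 || rho > 1) stop("'rho' must lie in [0, 1]")
  c(p0 = (1 - pi) * (rho * pi - pi + 1),
    p1 = 2 * pi * (1 - pi) * (1 - rho),
    p2 = pi * (rho + pi - rho * pi))
}

# d(p0,p1,p2)/dpi and /drho (no range checks; internal)
dcat_dpi <- function(pi, rho) {
  c((rho - 2) - 2 * (rho - 1) * pi,
    2 * (1 - 2 * pi) * (1 - rho),
    rho + 2 * (1 - rho) * pi)
}
dcat_drho <- function(pi, rho) {
  w <- pi * (1 - pi)
  c(w, -2 * w, w)
}

# log-likelihood contribution of one group: ncnt = (n0, n1), mcnt = (m0, m1, m2)
group_loglik <- function(ncnt, mcnt, pi, rho) {
  p <- c(1 - pi, pi, cat_probs_(clamp01(pi), clamp01(rho, 0)))
  cnt <- c(ncnt, mcnt)
  pos <- cnt > 0
  if (any(p[pos] <= 0)) {
    bad <- which(pos & p <= 0)[1]
    stop(sprintf("log of non-positive probability for cell %d (count %g)",
                 bad, cnt[bad]))
  }
  sum(cnt[pos] * log(p[pos]))
}

#' Stratum log-likelihood
#'
#' Log-likelihood of one stratum's counts at \code{(pi1, pi2, rho)}, with
#' the multinomial/binomial constant omitted.
#'
#' @param counts_j one stratum's counts: a list with matrix \code{n}
#'   (\code{2 x 2}, rows = 0/1 responses, cols = groups) and matrix
#'   \code{m} (\code{3 x 2}), e.g. from \code{\link{stratum_counts}}.
#' @param pi1,pi2 event probabilities of the treatment and control group.
#' @param rho shared intraclass correlation.
#' @return the log-likelihood value (a scalar).
#' @export
stratum_loglik <- function(counts_j, pi1, pi2, rho) {
  group_loglik(counts_j$n[, 1], counts_j$m[, 1], pi1, rho) +
    group_loglik(counts_j$n[, 2], counts_j$m[, 2], pi2, rho)
}

#' Control-group probability implied by the odds-ratio constraint
#'
#' Under a common odds ratio \code{theta}, \code{pi2 =
#' pi1 / (pi1 (1 - theta) + theta)}.
#'
#' @param pi1 treatment-group event probability.
#' @param theta odds ratio (> 0).
#' @return the implied control-group probability.
#' @export
pi2_from_theta <- function(pi1, theta) {
  pi1 / (pi1 * (1 - theta) + theta)
}

#' Constrained stratum log-likelihood
#'
#' Log-likelihood of one stratum profiled on the odds-ratio constraint:
#' the control probability is replaced by its image
#' \code{\link{pi2_from_theta}(pi1, theta)} inside
#' \code{\link{stratum_loglik}}, so the substitution identity holds exactly.
#'
#' @inheritParams stratum_loglik
#' @param theta common odds ratio (> 0).
#' @return the log-likelihood value.
#' @export
constrained_stratum_loglik <- function(counts_j, pi1, rho, theta) {
  if (!is.finite(theta) || theta <= 0) stop("'theta' must be positive")
  stratum_loglik(counts_j, pi1, pi2_from_theta(pi1, theta), rho)
}

#' Score for the event probability of one group
#'
#' Analytic derivative of the stratum log-likelihood with respect to
#' \code{pi_i} (the event probability of group \code{i}), holding the other
#' parameters fixed.
#'
#' @inheritParams stratum_loglik
#' @param i group index (1 = treatment, 2 = control).
#' @param pi event probability of group \code{i}.
#' @return the derivative value.
#' @export
dl_dpi <- function(counts_j, i, pi, rho) {
  ncnt <- counts_j$n[, i]
  mcnt <- counts_j$m[, i]
  p <- cat_probs_(pi, rho)
  dp <- dcat_dpi(pi, rho)
  out <- 0
  if (ncnt[1] > 0) out <- out - ncnt[1] / (1 - pi)
  if (ncnt[2] > 0) out <- out + ncnt[2] / pi
  for (t in 1:3) if (mcnt[t] > 0) out <- out + mcnt[t] * dp[t] / p[t]
  out
}

#' Score for the intraclass correlation of one stratum
#'
#' Analytic derivative of the stratum log-likelihood with respect to
#' \code{rho}; only bilateral subjects contribute.
#'
#' @inheritParams stratum_loglik
#' @return the derivative value.
#' @export
dl_drho <- function(counts_j, pi1, pi2, rho) {
  out <- 0
  for (i in 1:2) {
    pi <- if (i == 1) pi1 else pi2
    mcnt <- counts_j$m[, i]
    if (all(mcnt == 0)) next
    p <- cat_probs_(pi, rho)
    dp <- dcat_drho(pi, rho)
    for (t in 1:3) if (mcnt[t] > 0) out <- out + mcnt[t] * dp[t] / p[t]
  }
  out
}

# Derivative of the constrained stratum log-likelihood in theta, holding
# (pi1, rho) fixed; chain rule through pi2(pi1, theta).
dl_dtheta <- function(counts_j, pi1, rho, theta) {
  den <- pi1 * (1 - theta) + theta
  dl_dpi(counts_j, 2, pi2_from_theta(pi1, theta), rho) *
    (-pi1 * (1 - pi1) / den^2)
}

# Derivative of the constrained stratum log-likelihood in pi1 (theta fixed).
dl_dpi1_constrained <- function(counts_j, pi1, rho, theta) {
  den <- pi1 * (1 - theta) + theta
  dl_dpi(counts_j, 1, pi1, rho) +
    dl_dpi(counts_j, 2, pi2_from_theta(pi1, theta), rho) * theta / den^2
}

# ascending-coefficient polynomial product
polymul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (k in seq_along(a))
    out[k:(k + length(b) - 1L)] <- out[k:(k + length(b) - 1L)] + a[k] * b
  out
}

# Cubic stationarity polynomial of pi for one group: coefficients
# (ascending) of the numerator of dl/dpi after clearing denominators.
pi_cubic_coefs <- function(ncnt, mcnt, rho) {
  P0 <- c(1, rho - 1)          # 1 + (rho-1) pi  (p0 = (1-pi) P0)
  P2 <- c(rho, 1 - rho)        # rho + (1-rho) pi (p2 = pi P2)
  Q0 <- c(rho - 2, -2 * (rho - 1))   # dp0/dpi
  Q2 <- c(rho, 2 * (1 - rho))        # dp2/dpi
  x <- c(0, 1); omx <- c(1, -1); om2x <- c(1, -2)
  f <- numeric(4)
  addp <- function(f, p) { f[seq_along(p)] <- f[seq_along(p)] + p; f }
  f <- addp(f, -ncnt[1] * polymul(polymul(x, P0), P2))
  f <- addp(f, ncnt[2] * polymul(polymul(omx, P0), P2))
  f <- addp(f, mcnt[1] * polymul(polymul(Q0, x), P2))
  f <- addp(f, mcnt[2] * polymul(polymul(om2x, P0), P2))
  f <- addp(f, mcnt[3] * polymul(polymul(Q2, omx), P0))
  f
}

# Real roots of a polynomial with ascending coefficients a0..a3, using the
# trigonometric closed form when the cubic has three real roots.  The
# arccosine argument is clamped within 1e-12 of [-1, 1]; larger excursions
# fall back to polyroot().
cubic_real_roots <- function(cf) {
  scale <- max(abs(cf), 1)
  cf <- cf / scale
  if (abs(cf[4]) < 1e-12) {                 # degenerate: quadratic / linear
    if (abs(cf[3]) < 1e-12) {
      if (abs(cf[2]) < 1e-14) return(numeric(0))
      return(-cf[1] / cf[2])
    }
    disc <- cf[2]^2 - 4 * cf[3] * cf[1]
    if (disc < 0) return(numeric(0))
    return((-cf[2] + c(-1, 1) * sqrt(disc)) / (2 * cf[3]))
  }
  a <- cf[3] / cf[4]; b <- cf[2] / cf[4]; c0 <- cf[1] / cf[4]
  p <- b - a^2 / 3
  q <- 2 * a^3 / 27 - a * b / 3 + c0
  disc <- -(4 * p^3 + 27 * q^2)
  if (disc >= -1e-12 && p < 0) {
    r <- 2 * sqrt(-p / 3)
    arg <- 3 * q / (p * r)                   # = cos(3 d)
    if (abs(arg) > 1 + 1e-12) return(Re(polyroot(cf))[abs(Im(polyroot(cf))) < 1e-8])
    arg <- min(1, max(-1, arg))
    d <- acos(arg) / 3                       # one third of an arccosine
    return(r * cos(d - 2 * pi * (0:2) / 3) - a / 3)
  }
  z <- polyroot(cf)
  Re(z)[abs(Im(z)) < 1e-8 * max(1, abs(z))]
}

#' Closed-form maximizer of one group's event probability
#'
#' Solves the cubic stationarity equation of the stratum log-likelihood in
#' \code{pi_i} (treating \code{rho} as fixed) via the trigonometric closed
#' form, and returns the admissible root.  With no bilateral subjects the
#' root reduces to the binomial MLE \code{n1/(n0+n1)}; when no interior
#' stationary point exists (e.g. a group with all counts in one category)
#' the clamped boundary maximizer is returned with attribute
#' \code{boundary = TRUE}.
#'
#' @inheritParams dl_dpi
#' @return the maximizing probability; attribute \code{"boundary"} is
#'   \code{TRUE} when the clamp bound is active.
#' @export
pi_closed_form <- function(counts_j, i, rho) {
  if (!is.finite(rho) || rho < 0 || rho >= 1)
    stop("'rho' must lie in [0, 1)")
  ncnt <- counts_j$n[, i]
  mcnt <- counts_j$m[, i]
  if (sum(ncnt) + sum(mcnt) == 0) stop("no observations in this group")
  cf <- pi_cubic_coefs(ncnt, mcnt, rho)
  roots <- cubic_real_roots(cf)
  cand <- unique(clamp01(roots[roots > 0 & roots < 1]))
  cand <- c(cand, .PEPS, 1 - .PEPS)
  ll <- vapply(cand, function(p) group_loglik(ncnt, mcnt, p, rho), 0)
  best <- cand[which.max(ll)]
  boundary <- best <= .PEPS || best >= 1 - .PEPS
  if (!boundary) {
    # polish: a couple of Newton steps on the analytic score
    for (it in 1:4) {
      g <- dl_dpi(counts_j, i, best, rho)
      if (abs(g) < 1e-10) break
      h <- (dl_dpi(counts_j, i, best + 1e-6, rho) -
              dl_dpi(counts_j, i, best - 1e-6, rho)) / 2e-6
      if (!is.finite(h) || h >= 0) break
      step <- g / h
      newp <- clamp01(best - step)
      if (group_loglik(ncnt, mcnt, newp, rho) >=
            group_loglik(ncnt, mcnt, best, rho) - 1e-12) best <- newp else break
    }
  }
  structure(best, boundary = boundary)
}

#' Expected information for the intraclass correlation
#'
#' Fisher information for \code{rho} in one stratum given the event
#' probabilities, i.e. \eqn{-E[\partial^2 l_j/\partial\rho^2]} with the
#' expectation taken over the exact category probabilities:
#' \deqn{I(\rho) = \sum_i m_{+i}\,\pi_i(1-\pi_i)\left[
#'   \frac{\pi_i}{\rho\pi_i - \pi_i + 1} + \frac{2}{1-\rho} +
#'   \frac{1-\pi_i}{\rho + \pi_i - \rho\pi_i}\right].}
#' Used as the scaling of the scalar Fisher-scoring update for \code{rho}.
#'
#' @inheritParams stratum_loglik
#' @return the information value; 0 (degenerate) when there are no
#'   bilateral subjects or a probability is at \{0, 1\}.
#' @export
rho_information <- function(counts_j, pi1, pi2, rho) {
  out <- 0
  for (i in 1:2) {
    pi <- if (i == 1) pi1 else pi2
    mp <- sum(counts_j$m[, i])
    if (mp == 0) next
    out <- out + mp * pi * (1 - pi) *
      (pi / (rho * pi - pi + 1) + 2 / (1 - rho) +
         (1 - pi) / (rho + pi - rho * pi))
  }
  out
}

# Expected information of one group's data in (pi, rho): binomial part for
# the unilateral subjects plus the trinomial part sum_t dp_t/dx dp_t/dy / p_t.
expected_info_group <- function(pi, rho, mplus, nplus) {
  I <- matrix(0, 2, 2)
  if (nplus > 0) I[1, 1] <- nplus / (pi * (1 - pi))
  if (mplus > 0) {
    p <- pmax(cat_probs_(pi, rho), 1e-14)
    dpi <- dcat_dpi(pi, rho)
    drh <- dcat_drho(pi, rho)
    I[1, 1] <- I[1, 1] + mplus * sum(dpi^2 / p)
    I[1, 2] <- I[2, 1] <- mplus * sum(dpi * drh / p)
    I[2, 2] <- mplus * sum(drh^2 / p)
  }
  I
}

# Expected information of one stratum's data in (pi1, pi2, rho), the
# block used by the Wald test and (via Jacobian mapping) the score test.
stratum_info_base <- function(counts_j, pi1, pi2, rho) {
  I1 <- expected_info_group(pi1, rho, sum(counts_j$m[, 1]),
                            sum(counts_j$n[, 1]))
  I2 <- expected_info_group(pi2, rho, sum(counts_j$m[, 2]),
                            sum(counts_j$n[, 2]))
  B <- matrix(0, 3, 3)
  B[1, 1] <- I1[1, 1]
  B[2, 2] <- I2[1, 1]
  B[3, 3] <- I1[2, 2] + I2[2, 2]
  B[1, 3] <- B[3, 1] <- I1[1, 2]
  B[2, 3] <- B[3, 2] <- I2[1, 2]
  B
}
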