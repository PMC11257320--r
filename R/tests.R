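# Likelihood-ratio, score and Wald statistics for H0: theta_1 = ... =
# theta_J, each asymptotically chi-square with J - 1 degrees of freedom.

#' Likelihood-ratio homogeneity statistic
#'
#' Twice the difference between the unconstrained and the
#' homogeneity-constrained total log-likelihoods, clamped at zero.
#'
#' @param fit_u unconstrained \code{"or_mle"} fit.
#' @param fit_c constrained \code{"or_mle"} fit on the same data.
#' @return the statistic (non-negative scalar).
#' @export
lr_statistic <- function(fit_u, fit_c) {
  if (!identical(fit_u$fingerprint, fit_c$fingerprint))
    stop("the two fits were computed on different data")
  max(0, 2 * (fit_u$total_loglik - fit_c$total_loglik))
}

# expected information of one stratum in the (theta_j, pi_1j, rho_j)
# parameterization, at the constrained estimates
score_info_stratum <- function(counts_j, pi1, rho, theta) {
  pi2 <- pi2_from_theta(pi1, theta)
  den <- pi1 * (1 - theta) + theta
  B <- stratum_info_base(counts_j, clamp01(pi1), clamp01(pi2),
                         clamp01(rho, 0))
  # d(pi1, pi2, rho) / d(theta, pi1, rho)
  Jmat <- matrix(c(0, 1, 0,
                   -pi1 * (1 - pi1) / den^2, theta / den^2, 0,
                   0, 0, 1), 3, 3, byrow = TRUE)
  t(Jmat) %*% B %*% Jmat
}

#' Score homogeneity statistic
#'
#' Evaluated at the constrained fit: in each stratum only the score in the
#' stratum-specific odds ratio is non-zero (the nuisance scores vanish at
#' the constrained maximum), so the statistic is the sum over strata of
#' \code{U_j^2 [I_j^{-1}]_{theta,theta}} with \code{I_j} the 3x3 expected
#' information in \code{(theta_j, pi_1j, rho_j)}.
#'
#' @param counts a \code{"stratified_counts"} object.
#' @param fit_c constrained \code{"or_mle"} fit of \code{counts}.
#' @return the statistic (non-negative scalar).
#' @export
score_statistic <- function(counts, fit_c) {
  counts <- validate_counts(counts)
  if (!identical(counts_fingerprint(counts), fit_c$fingerprint))
    stop("fit does not correspond to the supplied counts")
  theta <- fit_c$theta_common
  total <- 0
  for (j in seq_len(counts$J)) {
    cj <- stratum_counts(counts, j)
    u <- dl_dtheta(cj, fit_c$pi1[j], fit_c$rho[j], theta)
    I <- score_info_stratum(cj, fit_c$pi1[j], fit_c$rho[j], theta)
    keep <- diag(I) > 1e-12
    keep[1] <- TRUE
    Ik <- I[keep, keep, drop = FALSE]
    inv <- tryCatch(solve(Ik), error = function(e) {
      warning(sprintf("singular information in stratum %d; using a generalized inverse", j))
      MASS::ginv(Ik)
    })
    total <- total + u^2 * inv[1, 1]
  }
  max(0, total)
}

# (J-1) x 3J contrast matrix: consecutive-strata differences of the
# log-odds-ratio, rows (1, -1, 0, -1, 1, 0) spanning strata j, j+1
contrast_matrix <- function(J) {
  C <- matrix(0, J - 1, 3 * J)
  for (r in seq_len(J - 1)) {
    C[r, 3 * (r - 1) + 1:2] <- c(1, -1)
    C[r, 3 * r + 1:2] <- c(-1, 1)
  }
  C
}

#' Wald homogeneity statistic
#'
#' Delta-method quadratic form in consecutive-strata contrasts of the
#' log odds ratio at the unconstrained fit.  The per-stratum covariance of
#' \code{(logit pi_1, logit pi_2, log rho)} is \code{g_j I_j^{-1} g_j^T}
#' with \code{g_j = diag(1/(pi_1(1-pi_1)), 1/(pi_2(1-pi_2)), 1/rho)} and
#' \code{I_j} the expected information of the stratum's observed design,
#' so no separate per-subject normalization is needed.  Boundary-flagged
#' fits produce a warning: the statistic is numerically unstable there.
#'
#' @param counts a \code{"stratified_counts"} object.
#' @param fit_u unconstrained \code{"or_mle"} fit of \code{counts}.
#' @return the statistic (non-negative scalar).
#' @export
wald_statistic <- function(counts, fit_u) {
  counts <- validate_counts(counts)
  if (!identical(counts_fingerprint(counts), fit_u$fingerprint))
    stop("fit does not correspond to the supplied counts")
  if (any(fit_u$boundary_flags))
    warning("boundary solution in the unconstrained fit: the Wald statistic is unstable")
  J <- counts$J
  delta <- numeric(3 * J)
  V <- matrix(0, 3 * J, 3 * J)
  for (j in seq_len(J)) {
    p1 <- clamp01(fit_u$pi1[j]); p2 <- clamp01(fit_u$pi2[j])
    rh <- clamp01(fit_u$rho[j], .PEPS)
    idx <- 3 * (j - 1) + 1:3
    delta[idx] <- c(log(p1 / (1 - p1)), log(p2 / (1 - p2)), log(rh))
    B <- stratum_info_base(stratum_counts(counts, j), p1, p2, rh)
    if (B[3, 3] > 1e-12) {
      Binv <- tryCatch(solve(B), error = function(e)
        stop(sprintf("singular information matrix in stratum %d", j)))
    } else {
      # no bilateral subjects: rho is not estimated; invert the pi block
      Binv <- matrix(0, 3, 3)
      Binv[1:2, 1:2] <- tryCatch(solve(B[1:2, 1:2]), error = function(e)
        stop(sprintf("singular information matrix in stratum %d", j)))
    }
    g <- diag(c(1 / (p1 * (1 - p1)), 1 / (p2 * (1 - p2)), 1 / rh))
    V[idx, idx] <- g %*% Binv %*% g
  }
  C <- contrast_matrix(J)
  cd <- as.vector(C %*% delta)
  mid <- C %*% V %*% t(C)
  q <- tryCatch(solve(mid, cd), error = function(e) {
    bad <- which.min(diag(mid))
    stop(sprintf("singular contrast covariance (check stratum %d)", bad))
  })
  max(0, sum(cd * q))
}

#' Upper-tail chi-square p-value
#'
#' @param T a non-negative statistic.
#' @param df degrees of freedom (>= 1); for the homogeneity tests
#'   \code{df = J - 1}.
#' @return the upper-tail probability.
#' @export
chi2_pvalue <- function(T, df) {
  if (df < 1) stop("df must be >= 1 (J = 1 data admit no homogeneity test)")
  if (!is.finite(T) || T < -1e-9) stop("'T' must be non-negative")
  stats::pchisq(max(0, T), df = df, lower.tail = FALSE)
}

#' Homogeneity test of the odds ratio across strata
#'
#' Fits the unconstrained and the homogeneity-constrained models and
#' computes the likelihood-ratio, score and Wald statistics with their
#' chi-square (\code{J - 1} df) p-values.
#'
#' @param counts a \code{"stratified_counts"} object (or coercible list)
#'   with at least two strata.
#' @param control fitting options, see \code{\link{fit_unconstrained}}.
#' @param alpha nominal level used only for the printed decision
#'   (default 0.05).
#' @return an object of class \code{"or_homtest"}: statistics
#'   \code{T_LR}, \code{T_SC}, \code{T_W}, their p-values, \code{df}, both
#'   fits, and convergence/boundary diagnostics.
#' @examples
#' res <- or_homogeneity_test(or_fixture("aom"))
#' res$T_LR   # 4.7324
#' @export
or_homogeneity_test <- function(counts, control = list(), alpha = 0.05) {
  counts <- validate_counts(counts)
  if (counts$J < 2)
    stop("df must be >= 1 (J = 1 data admit no homogeneity test)")
  fit_u <- fit_unconstrained(counts, control)
  fit_c <- fit_constrained(counts, control, fit_u = fit_u)
  df <- counts$J - 1L
  T_LR <- lr_statistic(fit_u, fit_c)
  T_SC <- score_statistic(counts, fit_c)
  T_W <- wald_statistic(counts, fit_u)
  structure(list(
    T_LR = T_LR, T_SC = T_SC, T_W = T_W, df = df,
    p_LR = chi2_pvalue(T_LR, df), p_SC = chi2_pvalue(T_SC, df),
    p_W = chi2_pvalue(T_W, df),
    alpha = alpha,
    fit_unconstrained = fit_u, fit_constrained = fit_c,
    boundary = any(fit_u$boundary_flags) || any(fit_c$boundary_flags),
    labels = counts$labels), class = "or_homtest")
}

#' @export
print.or_homtest <- function(x, digits = 4, ...) {
  cat("Homogeneity test of the odds ratio across strata\n")
  cat(sprintf("H0: common odds ratio (df = %d)\n\n", x$df))
  print(x$fit_constrained, digits = digits)
  cat("\n")
  print(x$fit_unconstrained, digits = digits)
  cat("\n")
  tab <- data.frame(row.names = c("Statistic", "p-value"),
                    T_LR = round(c(x$T_LR, x$p_LR), digits),
                    T_SC = round(c(x$T_SC, x$p_SC), digits),
                    T_W = round(c(x$T_W, x$p_W), digits))
  print(tab)
  dec <- if (min(x$p_LR, x$p_SC, x$p_W) < x$alpha) "rejected by at least one test"
  else "not rejected"
  cat(sprintf("\nAt level %.2f, H0 is %s.\n", x$alpha, dec))
  if (x$boundary)
    cat("warning: boundary solution present; Wald statistic unstable.\n")
  invisible(x)
}
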