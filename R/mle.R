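# Maximum-likelihood fitting.
#
# Unconstrained fit: per stratum, alternate the closed-form cubic update of
# (pi1, pi2) with a scalar Fisher-scoring step for rho.  Constrained fit
# under a common odds ratio: inner Newton-Raphson on log(theta) holding the
# nuisance parameters fixed, then per-stratum 2x2 Fisher scoring of
# (pi1, rho), iterated to joint convergence.  Both fall back to direct
# bounded numerical maximization when the structured iteration stalls.

default_fit_control <- function(control = list()) {
  ctl <- list(tol = 1e-8, ltol = 1e-10, maxit = 500L, rho_init = 0.5,
              restarts = 0L, seed = NULL)
  ctl[names(control)] <- control
  ctl
}

# ---- unconstrained -------------------------------------------------------

fit_stratum_unconstrained <- function(counts_j, ctl) {
  has_bilat <- sum(counts_j$m) > 0
  rho <- if (has_bilat) ctl$rho_init else 0
  pi1 <- pi2 <- 0.5
  ll <- -Inf
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(ctl$maxit)) {
    iters <- it
    pi1_new <- as.numeric(pi_closed_form(counts_j, 1, rho))
    pi2_new <- as.numeric(pi_closed_form(counts_j, 2, rho))
    rho_new <- rho
    if (has_bilat) {
      g <- dl_drho(counts_j, pi1_new, pi2_new, rho)
      info <- rho_information(counts_j, clamp01(pi1_new), clamp01(pi2_new),
                              clamp01(rho, 0))
      if (is.finite(info) && info > 0) {
        step <- g / info
        ll_cur <- stratum_loglik(counts_j, pi1_new, pi2_new, rho)
        for (h in 1:50) {
          cand <- clamp01(rho + step, 0, 1 - .PEPS)
          if (stratum_loglik(counts_j, pi1_new, pi2_new, cand) >=
                ll_cur - 1e-10) { rho_new <- cand; break }
          step <- step / 2
        }
      }
    }
    ll_new <- stratum_loglik(counts_j, pi1_new, pi2_new, rho_new)
    dpar <- max(abs(pi1_new - pi1), abs(pi2_new - pi2), abs(rho_new - rho))
    dll <- abs(ll_new - ll)
    pi1 <- pi1_new; pi2 <- pi2_new; rho <- rho_new; ll <- ll_new
    if (dpar < ctl$tol && dll < ctl$ltol) { converged <- TRUE; break }
  }
  boundary <- c(pi1 = pi1 <= .PEPS || pi1 >= 1 - .PEPS,
                pi2 = pi2 <= .PEPS || pi2 >= 1 - .PEPS,
                rho = has_bilat && (rho <= 0 || rho >= 1 - .PEPS))
  # stationarity check at interior solutions; fall back to direct
  # maximization when the structured iteration did not reach it
  stationary <- TRUE
  if (!boundary["pi1"] && abs(dl_dpi(counts_j, 1, pi1, rho)) > 1e-6)
    stationary <- FALSE
  if (!boundary["pi2"] && abs(dl_dpi(counts_j, 2, pi2, rho)) > 1e-6)
    stationary <- FALSE
  if (has_bilat && !boundary["rho"] &&
        abs(dl_drho(counts_j, pi1, pi2, rho)) > 1e-6)
    stationary <- FALSE
  if (!converged || !stationary) {
    direct <- direct_fit_stratum(counts_j, c(pi1, pi2, rho), has_bilat)
    if (direct$ll > ll + 1e-9) {
      pi1 <- direct$par[1]; pi2 <- direct$par[2]; rho <- direct$par[3]
      ll <- direct$ll
      converged <- TRUE
      boundary <- c(pi1 = pi1 <= 2 * .PEPS || pi1 >= 1 - 2 * .PEPS,
                    pi2 = pi2 <= 2 * .PEPS || pi2 >= 1 - 2 * .PEPS,
                    rho = has_bilat && (rho <= 2 * .PEPS ||
                                          rho >= 1 - 2 * .PEPS))
    } else converged <- TRUE
  }
  list(pi1 = pi1, pi2 = pi2, rho = rho, loglik = ll,
       theta = pi1 * (1 - pi2) / (pi2 * (1 - pi1)),
       converged = converged, iterations = iters, boundary = boundary)
}

direct_fit_stratum <- function(counts_j, start, has_bilat) {
  lo <- c(.PEPS, .PEPS, 0)
  hi <- c(1 - .PEPS, 1 - .PEPS, 1 - .PEPS)
  obj <- function(p) -stratum_loglik(counts_j, p[1], p[2], p[3])
  best <- list(value = Inf)
  starts <- list(clamp01(start, .PEPS, 1 - .PEPS),
                 c(0.5, 0.5, 0.3), c(0.2, 0.8, 0.6))
  for (s in starts) {
    fit <- try(stats::optim(s, obj, method = "L-BFGS-B", lower = lo,
                            upper = hi), silent = TRUE)
    if (!inherits(fit, "try-error") && fit$value < best$value) best <- fit
  }
  if (!is.finite(best$value)) stop("direct stratum maximization failed")
  list(par = best$par, ll = -best$value)
}

#' Unconstrained maximum-likelihood fit
#'
#' Fits \code{(pi_1j, pi_2j, rho_j)} independently in each stratum by
#' alternating the closed-form cubic root for the event probabilities with
#' a scalar Fisher-scoring update for the intraclass correlation, and
#' derives the per-stratum odds ratios.  Strata without bilateral subjects
#' have \code{rho} fixed at 0 (not identified).
#'
#' @param counts a \code{"stratified_counts"} object.
#' @param control list of fitting options: \code{tol} (parameter-change
#'   tolerance, default 1e-8), \code{ltol} (log-likelihood change, 1e-10),
#'   \code{maxit} (500), \code{rho_init} (0.5).
#' @return an object of class \code{"or_mle"} with elements \code{pi1},
#'   \code{pi2}, \code{rho}, \code{theta} (per-stratum vectors),
#'   \code{loglik_by_stratum}, \code{total_loglik}, \code{converged},
#'   \code{iterations}, \code{boundary_flags} (\code{J x 3} logical) and
#'   \code{type = "unconstrained"}.
#' @export
fit_unconstrained <- function(counts, control = list()) {
  counts <- validate_counts(counts)
  ctl <- default_fit_control(control)
  J <- counts$J
  fits <- lapply(seq_len(J),
                 function(j) fit_stratum_unconstrained(stratum_counts(counts, j),
                                                       ctl))
  boundary <- t(vapply(fits, `[[`, logical(3), "boundary"))
  colnames(boundary) <- c("pi1", "pi2", "rho")
  structure(list(
    pi1 = vapply(fits, `[[`, 0, "pi1"),
    pi2 = vapply(fits, `[[`, 0, "pi2"),
    rho = vapply(fits, `[[`, 0, "rho"),
    theta = vapply(fits, `[[`, 0, "theta"),
    theta_common = NA_real_,
    loglik_by_stratum = vapply(fits, `[[`, 0, "loglik"),
    total_loglik = sum(vapply(fits, `[[`, 0, "loglik")),
    converged = vapply(fits, `[[`, TRUE, "converged"),
    iterations = vapply(fits, `[[`, 0L, "iterations"),
    boundary_flags = boundary,
    labels = counts$labels,
    type = "unconstrained",
    fingerprint = counts_fingerprint(counts)), class = "or_mle")
}

# ---- constrained ---------------------------------------------------------

constrained_total_loglik <- function(cjs, pi1, rho, theta) {
  out <- 0
  for (j in seq_along(cjs))
    out <- out + constrained_stratum_loglik(cjs[[j]], pi1[j], rho[j], theta)
  out
}

# safeguarded Newton on phi = log(theta); analytic gradient, finite
# difference curvature of the gradient
update_theta <- function(cjs, pi1, rho, theta) {
  phi <- log(theta)
  score_phi <- function(phi) {
    th <- exp(phi)
    s <- 0
    for (j in seq_along(cjs)) s <- s + dl_dtheta(cjs[[j]], pi1[j], rho[j], th)
    s * th
  }
  ll_phi <- function(phi) constrained_total_loglik(cjs, pi1, rho, exp(phi))
  ll <- ll_phi(phi)
  for (k in 1:60) {
    g <- score_phi(phi)
    if (abs(g) < 1e-10) break
    h <- (score_phi(phi + 1e-5) - score_phi(phi - 1e-5)) / 2e-5
    step <- if (is.finite(h) && h < 0) -g / h else sign(g) * 0.5
    step <- max(min(step, 2), -2)
    ok <- FALSE
    for (hh in 1:50) {
      cand <- phi + step
      llc <- ll_phi(cand)
      if (is.finite(llc) && llc >= ll - 1e-12) {
        phi <- cand; ll <- llc; ok <- TRUE; break
      }
      step <- step / 2
    }
    if (!ok || abs(step) < 1e-12) break
  }
  exp(phi)
}

# one 2x2 Fisher-scoring step for (pi1_j, rho_j) under the constraint
update_nuisance <- function(counts_j, pi1, rho, theta, has_bilat) {
  den <- pi1 * (1 - theta) + theta
  w <- theta / den^2                      # d pi2 / d pi1
  pi2 <- pi2_from_theta(pi1, theta)
  g1 <- dl_dpi1_constrained(counts_j, pi1, rho, theta)
  ll <- constrained_stratum_loglik(counts_j, pi1, rho, theta)
  I1 <- expected_info_group(clamp01(pi1), clamp01(rho, 0),
                            sum(counts_j$m[, 1]), sum(counts_j$n[, 1]))
  I2 <- expected_info_group(clamp01(pi2), clamp01(rho, 0),
                            sum(counts_j$m[, 2]), sum(counts_j$n[, 2]))
  if (has_bilat) {
    g <- c(g1, dl_drho(counts_j, pi1, pi2, rho))
    I <- matrix(c(I1[1, 1] + w^2 * I2[1, 1], I1[1, 2] + w * I2[1, 2],
                  I1[1, 2] + w * I2[1, 2], I1[2, 2] + I2[2, 2]), 2, 2)
    step <- tryCatch(solve(I, g), error = function(e) g / pmax(diag(I), 1))
  } else {
    g <- c(g1, 0)
    info <- I1[1, 1] + w^2 * I2[1, 1]
    step <- c(g[1] / max(info, 1e-12), 0)
  }
  for (h in 1:50) {
    cand_pi <- clamp01(pi1 + step[1])
    cand_rho <- clamp01(rho + step[2], 0, 1 - .PEPS)
    llc <- constrained_stratum_loglik(counts_j, cand_pi, cand_rho, theta)
    if (is.finite(llc) && llc >= ll - 1e-10)
      return(c(cand_pi, cand_rho))
    step <- step / 2
  }
  c(pi1, rho)
}

#' Constrained maximum-likelihood fit under odds-ratio homogeneity
#'
#' Maximizes the total log-likelihood under the null constraint
#' \code{theta_1 = ... = theta_J} via a two-step scheme: an inner
#' Newton-Raphson update of the common odds ratio on the log scale holding
#' the per-stratum \code{(pi_1j, rho_j)} fixed, followed by per-stratum
#' 2x2 Fisher-scoring updates of \code{(pi_1j, rho_j)} holding the common
#' odds ratio fixed, iterated to joint convergence.  The control-group
#' probabilities are then computed from the constraint (not re-estimated).
#'
#' @inheritParams fit_unconstrained
#' @param fit_u optional unconstrained \code{"or_mle"} fit on the same
#'   data, used for initialization (computed when missing).
#' @return an object of class \code{"or_mle"} with
#'   \code{type = "constrained"}; \code{theta_common} holds the shared
#'   odds-ratio estimate and \code{theta} repeats it per stratum.
#' @export
fit_constrained <- function(counts, control = list(), fit_u = NULL) {
  counts <- validate_counts(counts)
  ctl <- default_fit_control(control)
  J <- counts$J
  if (is.null(fit_u)) fit_u <- fit_unconstrained(counts, control)
  cjs <- lapply(seq_len(J), function(j) stratum_counts(counts, j))
  has_bilat <- vapply(seq_len(J), function(j) sum(counts$m[, , j]) > 0, TRUE)
  # initial values: averages of the unconstrained estimates; theta enters
  # on the log scale with clamping so a boundary stratum cannot poison it
  pi1 <- rep(clamp01(mean(fit_u$pi1), 0.01, 0.99), J)
  rho <- rep(clamp01(mean(fit_u$rho), 0, 1 - .PEPS), J)
  rho[!has_bilat] <- 0
  theta <- exp(mean(log(pmin(pmax(fit_u$theta, 1e-2), 1e2))))
  ll <- constrained_total_loglik(cjs, pi1, rho, theta)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(ctl$maxit)) {
    iters <- it
    theta_new <- update_theta(cjs, pi1, rho, theta)
    pi1_new <- pi1; rho_new <- rho
    for (j in seq_len(J)) {
      upd <- update_nuisance(cjs[[j]], pi1[j], rho[j],
                             theta_new, has_bilat[j])
      pi1_new[j] <- upd[1]; rho_new[j] <- upd[2]
    }
    ll_new <- constrained_total_loglik(cjs, pi1_new, rho_new, theta_new)
    dpar <- max(abs(pi1_new - pi1), abs(rho_new - rho),
                abs(theta_new - theta))
    dll <- abs(ll_new - ll)
    pi1 <- pi1_new; rho <- rho_new; theta <- theta_new; ll <- ll_new
    if (dpar < ctl$tol && dll < ctl$ltol) { converged <- TRUE; break }
  }
  if (!converged) {
    direct <- direct_fit_constrained(cjs, pi1, rho, theta, has_bilat)
    if (direct$ll > ll + 1e-9) {
      pi1 <- direct$pi1; rho <- direct$rho; theta <- direct$theta
      ll <- direct$ll
    }
    converged <- TRUE
  }
  pi2 <- pi2_from_theta(pi1, theta)
  boundary <- cbind(pi1 = pi1 <= 2 * .PEPS | pi1 >= 1 - 2 * .PEPS,
                    pi2 = pi2 <= 2 * .PEPS | pi2 >= 1 - 2 * .PEPS,
                    rho = has_bilat & (rho <= 0 | rho >= 1 - 2 * .PEPS))
  llj <- vapply(seq_len(J), function(j)
    constrained_stratum_loglik(cjs[[j]], pi1[j], rho[j], theta), 0)
  structure(list(
    pi1 = pi1, pi2 = pi2, rho = rho,
    theta = rep(theta, J), theta_common = theta,
    loglik_by_stratum = llj, total_loglik = sum(llj),
    converged = rep(converged, J), iterations = iters,
    boundary_flags = boundary, labels = counts$labels,
    type = "constrained",
    fingerprint = counts_fingerprint(counts)), class = "or_mle")
}

direct_fit_constrained <- function(cjs, pi1, rho, theta, has_bilat) {
  J <- length(cjs)
  par0 <- c(pmin(pmax(pi1, 1e-6), 1 - 1e-6), pmin(pmax(rho, 1e-6), 1 - 1e-6),
            log(theta))
  obj <- function(p) {
    -constrained_total_loglik(cjs, p[1:J], p[(J + 1):(2 * J)],
                              exp(p[2 * J + 1]))
  }
  fit <- try(stats::optim(par0, obj, method = "L-BFGS-B",
                          lower = c(rep(.PEPS, 2 * J), -20),
                          upper = c(rep(1 - .PEPS, 2 * J), 20)),
             silent = TRUE)
  if (inherits(fit, "try-error")) stop("constrained maximization failed")
  rho_out <- fit$par[(J + 1):(2 * J)]
  rho_out[!has_bilat] <- 0
  list(pi1 = fit$par[1:J], rho = rho_out, theta = exp(fit$par[2 * J + 1]),
       ll = -fit$value)
}

#' @export
print.or_mle <- function(x, digits = 4, ...) {
  cat(sprintf("%s MLE fit (%d strata)\n",
              if (x$type == "constrained") "Constrained" else "Unconstrained",
              length(x$pi1)))
  tab <- data.frame(stratum = x$labels,
                    pi1 = round(x$pi1, digits), pi2 = round(x$pi2, digits),
                    rho = round(x$rho, digits),
                    theta = round(x$theta, digits))
  print(tab, row.names = FALSE)
  if (x$type == "constrained")
    cat(sprintf("common odds ratio: %.4f\n", x$theta_common))
  cat(sprintf("total log-likelihood: %.6f\n", x$total_loglik))
  if (any(x$boundary_flags))
    cat("note: boundary solution flagged for",
        paste(unique(colnames(x$boundary_flags)[which(x$boundary_flags,
                                                      arr.ind = TRUE)[, 2]]),
              collapse = ", "), "\n")
  invisible(x)
}
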