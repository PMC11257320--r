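# Monte-Carlo machinery: data generation under the intraclass-correlation
# model and empirical type-I-error / power studies.

#' Specify a simulation scenario
#'
#' @param J number of strata.
#' @param m bilateral subjects per group and stratum (\code{m_{+ij}});
#'   scalar, length-J vector, or \code{2 x J} matrix (rows = groups).
#' @param n unilateral subjects per group and stratum; same shapes as
#'   \code{m} (default equal to \code{m}, matching the equal-allocation
#'   design of the study tables).
#' @param pi1 treatment-group event probabilities (scalar or length J).
#' @param rho intraclass correlations (scalar or length J).
#' @param theta odds ratios per stratum (scalar = common value under the
#'   null; a non-constant vector encodes an alternative).
#' @param reps Monte-Carlo replicates.
#' @param alpha nominal test level.
#' @param seed optional integer seed.
#' @return an object of class \code{"or_sim_spec"}.
#' @export
sim_spec <- function(J, m, n = m, pi1, rho, theta, reps = 10000L,
                     alpha = 0.05, seed = NULL) {
  expand2J <- function(x, what) {
    if (is.matrix(x)) {
      if (!all(dim(x) == c(2, J))) stop(sprintf("'%s' matrix must be 2 x J", what))
      return(x)
    }
    if (length(x) == 1L) x <- rep(x, J)
    if (length(x) != J) stop(sprintf("'%s' must be scalar, length J, or 2 x J", what))
    matrix(rep(x, each = 2), 2, J)
  }
  recyc <- function(x, what) {
    if (length(x) == 1L) x <- rep(x, J)
    if (length(x) != J) stop(sprintf("'%s' must have length 1 or J", what))
    x
  }
  m <- expand2J(m, "m"); n <- expand2J(n, "n")
  pi1 <- recyc(pi1, "pi1"); rho <- recyc(rho, "rho")
  theta <- recyc(theta, "theta")
  if (reps < 1) stop("'reps' must be >= 1")
  if (alpha <= 0 || alpha > 1) stop("'alpha' must lie in (0, 1]")
  if (any(pi1 <= 0 | pi1 >= 1)) stop("'pi1' must lie in (0, 1)")
  if (any(rho < 0 | rho > 1)) stop("'rho' must lie in [0, 1]")
  if (any(theta <= 0)) stop("'theta' must be positive")
  pi2 <- pi2_from_theta(pi1, theta)
  if (any(pi2 <= 0 | pi2 >= 1)) stop("implied 'pi2' outside (0, 1)")
  if (any(colSums(m + n) == 0)) stop("each stratum needs subjects")
  structure(list(J = J, m = m, n = n, pi1 = pi1, pi2 = pi2, rho = rho,
                 theta = theta, reps = as.integer(reps), alpha = alpha,
                 seed = seed), class = "or_sim_spec")
}

#' Draw one replicate dataset
#'
#' Unilateral counts are binomial in the group's event probability;
#' bilateral counts are trinomial with the model's category probabilities.
#' Uses the current RNG state (seed management belongs to the caller).
#'
#' @param spec an \code{"or_sim_spec"} object.
#' @return a \code{"stratified_counts"} object.
#' @export
sample_counts <- function(spec) {
  J <- spec$J
  n <- array(0, c(2, 2, J))
  m <- array(0, c(3, 2, J))
  for (j in seq_len(J)) {
    probs <- c(spec$pi1[j], spec$pi2[j])
    for (i in 1:2) {
      if (spec$n[i, j] > 0) {
        n1 <- stats::rbinom(1, spec$n[i, j], probs[i])
        n[, i, j] <- c(spec$n[i, j] - n1, n1)
      }
      if (spec$m[i, j] > 0)
        m[, i, j] <- stats::rmultinom(1, spec$m[i, j],
                                      category_probs(probs[i], spec$rho[j]))
    }
  }
  stratified_counts(n, m)
}

# run one scenario: per replicate, fit both models, compute the three
# statistics and tally rejections at the chi-square critical value
sim_run <- function(spec, control = list()) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  crit <- stats::qchisq(1 - spec$alpha, df = spec$J - 1)
  rej <- c(T_LR = 0L, T_SC = 0L, T_W = 0L)
  fail <- 0L
  for (r in seq_len(spec$reps)) {
    cnt <- sample_counts(spec)
    res <- try(suppressWarnings({
      fu <- fit_unconstrained(cnt, control)
      fc <- fit_constrained(cnt, control, fit_u = fu)
      c(lr_statistic(fu, fc), score_statistic(cnt, fc),
        wald_statistic(cnt, fu))
    }), silent = TRUE)
    if (inherits(res, "try-error") || any(!is.finite(res)))
      fail <- fail + 1L
    else
      rej <- rej + (res > crit)
  }
  used <- spec$reps - fail
  if (fail > 0.001 * spec$reps)
    warning(sprintf("%d of %d replicates failed to converge", fail, spec$reps))
  p <- rej / used
  structure(list(rejection_rate = 100 * p,
                 mc_standard_error = 100 * sqrt(p * (1 - p) / used),
                 non_convergence_count = fail, reps_used = used,
                 alpha = spec$alpha, spec = spec), class = "or_sim_result")
}

#' Empirical type-I error of the homogeneity tests
#'
#' Runs the scenario's replicates under a common odds ratio and reports
#' the percent rejections of each test at the nominal level.
#'
#' @param spec an \code{"or_sim_spec"} with constant \code{theta}.
#' @param control fitting options passed to the fitters.
#' @return an \code{"or_sim_result"}: percent \code{rejection_rate} and
#'   \code{mc_standard_error} per test, the non-convergence count, and the
#'   replicates actually used.
#' @export
empirical_size <- function(spec, control = list()) {
  if (length(unique(spec$theta)) != 1L)
    stop("'theta' must be constant across strata for a size study")
  sim_run(spec, control)
}

#' Empirical power of the homogeneity tests
#'
#' As \code{\link{empirical_size}} but under a heterogeneous odds-ratio
#' vector; a constant \code{theta} triggers a misuse warning (the run is
#' then a size study).
#'
#' @inheritParams empirical_size
#' @return an \code{"or_sim_result"}.
#' @export
empirical_power <- function(spec, control = list()) {
  if (length(unique(spec$theta)) == 1L)
    warning("'theta' is constant across strata: this is a size run, not power")
  sim_run(spec, control)
}

#' Randomized-settings size study
#'
#' Draws parameter settings uniformly (\code{pi1} per stratum from (0,1),
#' \code{rho} per stratum from (0,1), common \code{theta} from [1,4]) and
#' runs a null-hypothesis size study at each, for box-plot style summaries
#' of the dispersion of the empirical type-I error.
#'
#' @param J number of strata.
#' @param sizes vector of per-group sample sizes (used for both the
#'   bilateral and unilateral counts, \code{m = n}).
#' @param n_settings number of random parameter settings.
#' @param reps_per_setting Monte-Carlo replicates per setting.
#' @param alpha nominal level.
#' @param seed integer seed for both the settings and the replicate
#'   streams (per-setting substreams are derived from it, so results do
#'   not depend on evaluation order).
#' @param control fitting options.
#' @return a data frame with one row per (setting, size): the drawn
#'   parameters, each test's empirical size (percent), its Monte-Carlo
#'   standard error and the non-convergence count.
#' @export
random_settings_study <- function(J = 2, sizes = c(30, 50, 100),
                                  n_settings = 1000, reps_per_setting = 10000,
                                  alpha = 0.05, seed = NULL,
                                  control = list()) {
  if (n_settings < 1) stop("'n_settings' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  pi1s <- matrix(stats::runif(n_settings * J, 0.02, 0.98), n_settings, J)
  rhos <- matrix(stats::runif(n_settings * J), n_settings, J)
  thetas <- stats::runif(n_settings, 1, 4)
  subseeds <- sample.int(.Machine$integer.max - 1L,
                         n_settings * length(sizes))
  out <- vector("list", n_settings * length(sizes))
  k <- 0L
  for (s in seq_len(n_settings)) {
    stopifnot(all(pi2_from_theta(pi1s[s, ], thetas[s]) > 0 &
                    pi2_from_theta(pi1s[s, ], thetas[s]) < 1))
    for (sz in sizes) {
      k <- k + 1L
      spec <- sim_spec(J, m = sz, n = sz, pi1 = pi1s[s, ], rho = rhos[s, ],
                       theta = thetas[s], reps = reps_per_setting,
                       alpha = alpha, seed = subseeds[k])
      r <- suppressWarnings(empirical_size(spec, control))
      out[[k]] <- data.frame(setting = s, size = sz,
                             theta = thetas[s],
                             pi1 = paste(signif(pi1s[s, ], 4), collapse = ";"),
                             rho = paste(signif(rhos[s, ], 4), collapse = ";"),
                             size_LR = r$rejection_rate[["T_LR"]],
                             size_SC = r$rejection_rate[["T_SC"]],
                             size_W = r$rejection_rate[["T_W"]],
                             mcse_SC = r$mc_standard_error[["T_SC"]],
                             failed = r$non_convergence_count)
    }
  }
  do.call(rbind, out)
}

#' @export
print.or_sim_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo study: %d replicates used (%d failed)\n",
              x$reps_used, x$non_convergence_count))
  tab <- rbind(`rejection %` = round(x$rejection_rate, 2),
               `MC SE` = round(x$mc_standard_error, 3))
  print(tab)
  invisible(x)
}
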