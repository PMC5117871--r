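# Least-squares fitting of the gel material parameters, bootstrap
# uncertainty, and identifiability scans.

# Restrict a dataset (embryo_dataset or list with x/v/dvdx/Q[/c_prof]) to
# the fit region and validate.
#' @noRd
fit_data <- function(data, fit_region) {
  if (inherits(data, "embryo_dataset")) data <- unclass(data)
  stopifnot(all(c("x", "v", "dvdx", "Q") %in% names(data)))
  keep <- data$x >= fit_region[1L] & data$x <= fit_region[2L]
  if (sum(keep) < 7L) stop("fewer grid points in the fit region than parameters")
  out <- list(x = data$x[keep], v = data$v[keep], dvdx = data$dvdx[keep],
              Q = data$Q[keep])
  if (!is.null(data$c_prof)) out$c_prof <- data$c_prof[keep]
  out
}

# Exact linear profiling of (beta_tau, C1, C2) at fixed (tau, ell, lambda).
# Returns rss and the linear coefficients.
#' @noRd
profile_linear <- function(M, Q) {
  f <- stats::lm.fit(M, Q)
  rss <- sum(f$residuals^2)
  list(rss = rss, beta_tau = f$coefficients[[1L]],
       C1 = f$coefficients[[2L]], C2 = f$coefficients[[3L]])
}

#' @noRd
nrss_denominator <- function(Q) {
  ss <- sum((Q - mean(Q))^2)
  if (ss <= .Machine$double.eps) stop("degenerate fit: nematic order profile is flat")
  ss
}

# Objective over the nonlinear parameters theta = (log tau, log ell[, lambda]).
#' @noRd
gel_objective <- function(d, include_lambda, refine_dx) {
  c0 <- if (!is.null(d$c_prof)) mean(d$c_prof) else NULL
  lam_max <- if (include_lambda) 0.95 * c0 / max(d$c_prof) else 0
  eval_theta <- function(theta) {
    tau <- exp(theta[1L]); ell <- exp(theta[2L])
    lam <- if (include_lambda) theta[3L] else 0
    M <- steady_basis(d$x, d$v, d$dvdx, tau, ell, lam,
                      c_prof = if (include_lambda) d$c_prof else NULL,
                      c0 = c0, refine_dx = refine_dx)
    c(list(tau = tau, ell = ell, lambda_tau = lam), profile_linear(M, d$Q))
  }
  list(eval = eval_theta,
       rss = function(theta)
         tryCatch(eval_theta(theta)$rss, error = function(e) 1e12),
       lam_max = lam_max, c0 = c0)
}

# Multi-start minimisation over (log tau, log ell[, lambda]).
#' @noRd
optimize_gel <- function(obj, include_lambda, starts) {
  lower <- c(log(1e-3), log(0.05), if (include_lambda) 0)
  upper <- c(log(50), log(50), if (include_lambda) obj$lam_max)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::nlminb(as.numeric(starts[i, ]), obj$rss, lower = lower,
                    upper = upper,
                    control = list(rel.tol = 1e-12, x.tol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    # ties broken toward smaller tau
    if (is.null(best) || fit$objective < best$objective * (1 - 1e-9) ||
        (abs(fit$objective - best$objective) <= best$objective * 1e-9 &&
         fit$par[1L] < best$par[1L]))
      best <- fit
  }
  if (is.null(best)) stop("gel parameter optimisation failed from all starts")
  best
}

#' @noRd
default_starts <- function(include_lambda, n_per_axis = 4L) {
  taus <- log(exp(seq(log(0.05), log(10), length.out = n_per_axis)))
  ells <- log(exp(seq(log(0.5), log(10), length.out = n_per_axis)))
  g <- expand.grid(log_tau = taus, log_ell = ells)
  if (include_lambda) {
    g <- merge(g, data.frame(lambda = c(0, 0.3)))
    g <- g[, c("log_tau", "log_ell", "lambda")]
  }
  as.matrix(g)
}

# Approximate per-parameter 95% confidence intervals from the Jacobian of
# the residuals at the optimum (Gaussian linearisation).
#' @noRd
fit_ci <- function(d, params, include_lambda, refine_dx, rss) {
  c0 <- if (!is.null(d$c_prof)) mean(d$c_prof) else NULL
  phi <- c(tau = params$tau, beta_tau = params$beta_tau, ell = params$ell,
           if (include_lambda) c(lambda_tau = params$lambda_tau),
           C1 = params$C1, C2 = params$C2)
  model <- function(phi) {
    p <- gel_parameters(max(phi[["tau"]], 1e-8), phi[["beta_tau"]],
                        max(phi[["ell"]], 1e-8),
                        if (include_lambda) max(phi[["lambda_tau"]], 0) else 0,
                        phi[["C1"]], phi[["C2"]])
    as.numeric(solve_steady_Q(d$x, d$v, d$dvdx, p,
                              c_prof = if (include_lambda) d$c_prof else NULL,
                              c0 = c0, refine_dx = refine_dx))
  }
  J <- tryCatch(pracma::jacobian(model, phi), error = function(e) NULL)
  p <- length(phi); n <- length(d$Q)
  ci <- matrix(NA_real_, p, 2L, dimnames = list(names(phi), c("lo", "hi")))
  if (is.null(J) || n <= p) return(ci)
  s2 <- rss / (n - p)
  cov <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
  if (is.null(cov)) return(ci)
  se <- sqrt(pmax(diag(cov), 0))
  ci[, 1L] <- phi - 1.96 * se
  ci[, 2L] <- phi + 1.96 * se
  ci
}

#' Fit the gel material parameters to a nematic order profile
#'
#' Nonlinear least squares of the steady-state gel model against a measured
#' nematic order profile, given the flow and compression profiles. The
#' steady solution is affine in `(beta_tau, C1, C2)` at fixed
#' `(tau, ell, lambda_tau)`, so those three are profiled out exactly by
#' linear least squares at every objective evaluation, and a multi-start
#' quasi-Newton search runs over `(tau, ell)` (plus `lambda_tau` when
#' enabled). Ties are broken toward smaller `tau`.
#'
#' When the normalised residual (rss divided by the Q-profile's total sum
#' of squares about its mean) changes by less than 1% when `tau` is pinned
#' anywhere in `(0, tau_bound]` with the remaining parameters re-optimised,
#' `tau` is declared not identifiable from below and reported as the upper
#' bound `tau_bound` with flag `tau_unbounded_below` (displayed
#' `"< 0.5 (n.d.)"`).
#'
#' @param data an [embryo_dataset()] (or list with `x`, `v`, `dvdx`, `Q`
#'   and optionally `c_prof`).
#' @param include_lambda fit the myosin-coupled active-alignment product
#'   `lambda_tau` (requires a myosin profile in `data`).
#' @param fit_region range of x (micrometres) used for the fit; default the
#'   central 30 micrometres.
#' @param tau_bound upper bound (min) used by the identifiability rule,
#'   default 0.5.
#' @param starts matrix of optimisation starts (columns `log(tau)`,
#'   `log(ell)`\[, `lambda_tau`\]); default a 4x4 log-spaced grid over tau
#'   in \[0.05, 10\] min and ell in \[0.5, 10\] micrometres.
#' @param refine_dx solver grid spacing, micrometres (see
#'   [solve_steady_Q()]).
#' @param compute_ci compute linearised 95% confidence intervals (default
#'   TRUE; skipped during bootstrap refits).
#' @return object of class `gel_fit`: `params` ([gel_parameters()]), `rss`,
#'   `nrss` (variance-normalised rss), `n`, `ci` (95% intervals), `flags`
#'   (`tau_unbounded_below`), `tau_label`, `include_lambda`, `fit_region`.
#' @export
fit_gel_parameters <- function(data, include_lambda = FALSE,
                               fit_region = c(-15, 15), tau_bound = 0.5,
                               starts = NULL, refine_dx = 0.25,
                               compute_ci = TRUE) {
  d <- fit_data(data, fit_region)
  if (include_lambda && is.null(d$c_prof))
    stop("include_lambda = TRUE requires a myosin profile in the data")
  ss_tot <- nrss_denominator(d$Q)
  if (max(abs(d$dvdx)) < 1e-10 && max(abs(d$Q)) < 1e-10)
    stop("degenerate fit: flat Q with zero compression")
  obj <- gel_objective(d, include_lambda, refine_dx)
  if (is.null(starts)) starts <- default_starts(include_lambda)
  best <- optimize_gel(obj, include_lambda, starts)
  at <- obj$eval(best$par)
  params <- gel_parameters(at$tau, at$beta_tau, at$ell, at$lambda_tau,
                           at$C1, at$C2)

  # tau lower-identifiability rule: refit with tau pinned over (0, tau_bound]
  nrss_opt <- at$rss / ss_tot
  flat <- FALSE
  if (params$tau > 0) {
    tau_grid <- seq(tau_bound / 10, tau_bound, length.out = 5L)
    worst <- 0
    for (tg in tau_grid) {
      sub_rss <- function(th) obj$rss(c(log(tg), th))
      th0 <- best$par[-1L]
      lo <- c(log(0.05), if (include_lambda) 0)
      hi <- c(log(50), if (include_lambda) obj$lam_max)
      sf <- stats::nlminb(th0, sub_rss, lower = lo, upper = hi,
                          control = list(rel.tol = 1e-12))
      worst <- max(worst, sf$objective / ss_tot - nrss_opt)
    }
    flat <- worst < 0.01
  }
  tau_label <- if (flat) sprintf("< %.1f (n.d.)", tau_bound)
               else sprintf("%.3g", params$tau)
  if (flat) params$tau_reported <- tau_bound

  ci <- if (compute_ci) fit_ci(d, params, include_lambda, refine_dx, at$rss)
        else NULL
  structure(list(params = params, rss = at$rss, nrss = nrss_opt,
                 n = length(d$Q), ci = ci,
                 flags = list(tau_unbounded_below = flat),
                 tau_label = tau_label, include_lambda = include_lambda,
                 fit_region = fit_region, refine_dx = refine_dx),
            class = "gel_fit")
}

#' @export
print.gel_fit <- function(x, ...) {
  cat("Gel model least-squares fit (n =", x$n, "points)\n")
  cat(sprintf("  tau        = %s min%s\n", x$tau_label,
              if (x$flags$tau_unbounded_below) "  [upper bound]" else ""))
  cat(sprintf("  beta*tau   = %.4g min\n", x$params$beta_tau))
  cat(sprintf("  ell        = %.4g um\n", x$params$ell))
  if (x$include_lambda)
    cat(sprintf("  lambda'*tau= %.4g\n", x$params$lambda_tau))
  cat(sprintf("  C1, C2     = %.4g, %.4g\n", x$params$C1, x$params$C2))
  cat(sprintf("  rss = %.4g (normalised %.4g)\n", x$rss, x$nrss))
  invisible(x)
}

#' Bootstrap the gel parameter fit over embryos
#'
#' Resamples embryos with replacement, averages the resampled profiles, and
#' refits the gel model; reports per-parameter medians with the 68%
#' (16th–84th percentile) bootstrap interval.
#'
#' @param datasets list of at least two [embryo_dataset()] objects on a
#'   common grid.
#' @param n_boot number of bootstrap resamples; values below 100 are
#'   allowed but recorded as a warning in the result.
#' @param seed integer seed (resampling is fully determined by it).
#' @inheritParams fit_gel_parameters
#' @param ... passed to [fit_gel_parameters()].
#' @return object of class `gel_bootstrap`: `summary` (data frame with
#'   `median`, `lo68`, `hi68` per parameter), `draws` (matrix of per-resample
#'   estimates), `n_boot`, `seed`, `warnings`.
#' @export
bootstrap_parameters <- function(datasets, n_boot = 200, seed = 1,
                                 include_lambda = FALSE, ...) {
  stopifnot(length(datasets) >= 2L)
  warnings <- character(0)
  if (n_boot < 100)
    warnings <- c(warnings, "n_boot < 100: bootstrap intervals are unreliable")
  full <- fit_gel_parameters(average_embryo_datasets(datasets),
                             include_lambda = include_lambda,
                             compute_ci = FALSE, ...)
  # warm-started refits: full-data optimum plus a coarse grid
  starts <- rbind(c(log(full$params$tau), log(full$params$ell),
                    if (include_lambda) full$params$lambda_tau),
                  default_starts(include_lambda, n_per_axis = 2L))
  pnames <- c("tau", "beta_tau", "ell",
              if (include_lambda) "lambda_tau", "C1", "C2")
  idx <- with_seed(seed, replicate(n_boot,
           sample.int(length(datasets), replace = TRUE), simplify = FALSE))
  draws <- t(vapply(idx, function(ii) {
    f <- fit_gel_parameters(average_embryo_datasets(datasets[ii]),
                            include_lambda = include_lambda, starts = starts,
                            compute_ci = FALSE, ...)
    unlist(f$params[pnames])
  }, numeric(length(pnames))))
  colnames(draws) <- pnames
  qs <- apply(draws, 2L, stats::quantile, probs = c(0.5, 0.16, 0.84),
              names = FALSE)
  summary <- data.frame(parameter = pnames, median = qs[1L, ],
                        lo68 = qs[2L, ], hi68 = qs[3L, ],
                        row.names = NULL)
  structure(list(summary = summary, draws = draws, n_boot = n_boot,
                 seed = seed, full_fit = full, warnings = warnings),
            class = "gel_bootstrap")
}

#' @export
print.gel_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap fit (%d resamples, seed %d): median (16th, 84th)\n",
              x$n_boot, x$seed))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-10s %.4g (%.4g, %.4g)\n", x$summary$parameter[i],
                x$summary$median[i], x$summary$lo68[i], x$summary$hi68[i]))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Identifiability scan of one gel parameter with boundary-only refits
#'
#' For each value of the scanned parameter (with the other material
#' parameters held fixed), refits only the boundary values `C1`, `C2` by
#' exact linear least squares and records the residual. The flat region is
#' the contiguous run of grid values around the minimum whose normalised
#' residual stays within `flat_tol` of the minimum; its upper edge is the
#' reported identifiability bound for `tau`-type scans.
#'
#' @inheritParams fit_gel_parameters
#' @param param which parameter to scan: `"tau"`, `"beta_tau"`, `"ell"` or
#'   `"lambda_tau"`.
#' @param grid vector of parameter values to scan (non-empty).
#' @param params [gel_parameters()] holding the fixed parameter values
#'   (typically a best fit).
#' @param flat_tol flat-region tolerance on the normalised residual
#'   (default 0.05).
#' @return data frame of class `identifiability_scan` with columns `value`,
#'   `rss`, `nrss`; attributes `flat_bound` (upper edge of the flat region,
#'   `NA` if the region is a single point at the minimum), `flat_lo`,
#'   `param`, `flat_tol`.
#' @export
identifiability_scan <- function(data, param = c("tau", "beta_tau", "ell",
                                                 "lambda_tau"),
                                 grid, params, fit_region = c(-15, 15),
                                 flat_tol = 0.05, refine_dx = 0.25) {
  param <- match.arg(param)
  stopifnot(length(grid) >= 1L, inherits(params, "gel_parameters"))
  d <- fit_data(data, fit_region)
  ss_tot <- nrss_denominator(d$Q)
  c0 <- if (!is.null(d$c_prof)) mean(d$c_prof) else NULL
  use_c <- !is.null(d$c_prof) && (params$lambda_tau > 0 || param == "lambda_tau")
  rss <- vapply(grid, function(val) {
    p <- params
    p[[param]] <- val
    M <- steady_basis(d$x, d$v, d$dvdx, p$tau, p$ell, p$lambda_tau,
                      c_prof = if (use_c) d$c_prof else NULL, c0 = c0,
                      refine_dx = refine_dx)
    # C1, C2 only: beta_tau is fixed, its contribution moves to the response
    f <- stats::lm.fit(M[, 2:3, drop = FALSE], d$Q - p$beta_tau * M[, 1L])
    sum(f$residuals^2)
  }, numeric(1L))
  nrss <- rss / ss_tot
  i0 <- which.min(nrss)
  ok <- nrss <= nrss[i0] + flat_tol
  lo <- i0; while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
  hi <- i0; while (hi < length(grid) && ok[hi + 1L]) hi <- hi + 1L
  out <- data.frame(value = grid, rss = rss, nrss = nrss)
  attr(out, "flat_bound") <- if (hi > lo || length(grid) == 1L) grid[hi] else NA_real_
  attr(out, "flat_lo") <- grid[lo]
  attr(out, "param") <- param
  attr(out, "flat_tol") <- flat_tol
  class(out) <- c("identifiability_scan", "data.frame")
  out
}
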