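#' Hill model parameters
#'
#' Three-parameter sigmoidal concentration-response model: maximal response
#' `rmax` (percent of positive control), slope `h` (> 0) and the half-maximal
#' concentration on the log10 micromolar scale.
#'
#' @param rmax Maximal response.
#' @param h Hill slope, strictly positive.
#' @param log10_ac50 log10 AC50 in micromolar.
#' @return An object of class `hill_params`.
#' @export
hill_params <- function(rmax, h, log10_ac50) {
  if (!is.finite(h) || h <= 0) stop("'h' must be positive")
  structure(list(rmax = rmax, h = h, log10_ac50 = log10_ac50),
            class = "hill_params")
}

#' Gain-loss model parameters
#'
#' Four-parameter unimodal ("bell-like") model: a gain phase with
#' half-maximal concentration `log10_ac50_gain` and a loss phase with
#' half-maximal concentration `log10_ac50_loss` (>= gain), sharing one slope
#' `h`; both bottom asymptotes are zero.
#'
#' @param rmax Shared upper asymptote.
#' @param h Slope, strictly positive, shared by the gain and loss factors.
#' @param log10_ac50_gain,log10_ac50_loss Half-maximal concentrations
#'   (log10 micromolar) of the gain and loss phases.
#' @return An object of class `gainloss_params`.
#' @export
gainloss_params <- function(rmax, h, log10_ac50_gain, log10_ac50_loss) {
  if (!is.finite(h) || h <= 0) stop("'h' must be positive")
  if (log10_ac50_loss < log10_ac50_gain) {
    stop("'log10_ac50_loss' must be >= 'log10_ac50_gain'")
  }
  structure(list(rmax = rmax, h = h, log10_ac50_gain = log10_ac50_gain,
                 log10_ac50_loss = log10_ac50_loss),
            class = "gainloss_params")
}

#' Expected response under the Hill model
#'
#' E(R) = rmax / (1 + 10^(-h (log10 c - log10 AC50))). At c = AC50 the
#' response is rmax/2; the curve is strictly monotone in c for h > 0.
#'
#' @param conc Concentration(s) in micromolar, > 0. Vectorized.
#' @param params A [hill_params()].
#' @return Expected response(s).
#' @export
hill_response <- function(conc, params) {
  params$rmax / (1 + 10^(-params$h * (log10(conc) - params$log10_ac50)))
}

#' Expected response under the gain-loss model
#'
#' E(R) = rmax * 1/(1 + 10^(h (gain - log10 c))) * 1/(1 + 10^(h (log10 c - loss))).
#' Reduces to the Hill model as the loss AC50 goes to +infinity; unimodal
#' with its maximum at the midpoint of the two log10 AC50s.
#'
#' @param conc Concentration(s) in micromolar, > 0. Vectorized.
#' @param params A [gainloss_params()].
#' @return Expected response(s).
#' @export
gainloss_response <- function(conc, params) {
  lx <- log10(conc)
  params$rmax *
    (1 / (1 + 10^(params$h * (params$log10_ac50_gain - lx)))) *
    (1 / (1 + 10^(params$h * (lx - params$log10_ac50_loss))))
}

# default parameter box for Hill fitting; needed for identifiability when a
# plateau lies outside the tested range
.hill_bounds <- function(x, y) {
  M <- max(abs(y))
  list(lower = c(rmax = -2 * M, h = 0.01, log10_ac50 = min(x) - 2),
       upper = c(rmax = 2 * M, h = 10, log10_ac50 = max(x) + 2))
}

.hill_curve <- function(p, x) p[1] / (1 + 10^(-p[2] * (x - p[3])))

# Jacobian of the Hill curve wrt (rmax, h, log10_ac50), n x 3
.hill_jac <- function(p, x) {
  u <- 10^(-p[2] * (x - p[3]))
  d1 <- 1 / (1 + u)
  w <- p[1] * log(10) * u * d1^2
  cbind(d1, (x - p[3]) * w, -p[2] * w, deparse.level = 0)
}

.unconverged_fit <- function(n) {
  structure(list(params = NULL, se_log10_ac50 = NA_real_, converged = FALSE,
                 n_points_used = n, residual_ss = NA_real_, fitted = NULL,
                 leverage = NULL),
            class = "curve_fit")
}

#' Fit the Hill model to one profile by nonlinear least squares
#'
#' Least squares in the (rmax, h, log10 AC50) parameterization with box
#' constraints, solved with [stats::nlminb()] using analytic gradients.
#' Five deterministic starts place the initial log10 AC50 at the 10/30/50/
#' 70/90% quantiles of the tested log10 concentrations; the solution with
#' the best final residual sum of squares is kept. The standard error of
#' log10 AC50 comes from the asymptotic covariance s^2 (J'J)^-1 of the
#' converged fit; a fit whose covariance is not computable (e.g. a flat,
#' unidentifiable curve) is flagged as not converged.
#'
#' @param profile A [response_profile()], or any list with elements
#'   `concentrations` and `responses` (pooled-point fits may repeat
#'   concentrations).
#' @param bounds Optional list with `lower`/`upper` vectors over
#'   (rmax, h, log10_ac50); defaults to rmax within +/- 2 max|response|,
#'   h in [0.01, 10] and log10 AC50 within the tested range widened by 2
#'   decades each side.
#' @return An object of class `curve_fit`: `params` ([hill_params()] or
#'   `NULL`), `se_log10_ac50`, `converged`, `n_points_used`, `residual_ss`,
#'   `fitted` values and hat-matrix `leverage` (used for outlier removal).
#' @export
fit_hill <- function(profile, bounds = NULL) {
  x <- log10(profile$concentrations)
  y <- profile$responses
  n <- length(y)
  if (n < 5L) stop("Hill fitting needs at least 5 points")
  M <- max(abs(y))
  if (M == 0 || !all(is.finite(y))) return(.unconverged_fit(n))
  if (is.null(bounds)) bounds <- .hill_bounds(x, y)
  obj <- function(p) {
    r <- y - .hill_curve(p, x)
    sum(r * r)
  }
  gr <- function(p) {
    J <- .hill_jac(p, x)
    r <- y - .hill_curve(p, x)
    -2 * drop(crossprod(J, r))
  }
  r0 <- mean(y[x >= sort(x, decreasing = TRUE)[min(3L, n)]])
  if (abs(r0) < 0.25 * M) r0 <- y[which.max(abs(y))]
  r0 <- min(max(r0, bounds$lower[["rmax"]]), bounds$upper[["rmax"]])
  if (r0 == 0) r0 <- M
  th0 <- stats::quantile(x, c(0.1, 0.3, 0.5, 0.7, 0.9), names = FALSE)
  best <- NULL
  for (th in th0) {
    res <- tryCatch(
      stats::nlminb(c(r0, 1, th), obj, gr, lower = bounds$lower,
                    upper = bounds$upper,
                    control = list(iter.max = 300, eval.max = 400)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) next
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best)) return(.unconverged_fit(n))
  p <- best$par
  J <- .hill_jac(p, x)
  ss <- best$objective
  s2 <- ss / max(1L, n - 3L)
  cov <- tryCatch(solve(crossprod(J)) * s2, error = function(e) NULL)
  se <- if (is.null(cov)) NA_real_ else suppressWarnings(sqrt(cov[3, 3]))
  lev <- if (is.null(cov)) {
    NULL
  } else {
    rowSums((J %*% solve(crossprod(J))) * J)
  }
  converged <- best$convergence == 0 && !is.null(cov) && is.finite(se) &&
    se > 0
  structure(
    list(params = hill_params(p[1], max(p[2], 1e-10), p[3]),
         se_log10_ac50 = se, converged = converged, n_points_used = n,
         residual_ss = ss, fitted = .hill_curve(p, x), leverage = lev),
    class = "curve_fit"
  )
}

#' @export
print.curve_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<curve_fit> log10 AC50 = %.4f (SE %.4f), rmax = %.3g, h = %.3g, SS = %.4g on %d points\n",
                x$params$log10_ac50, x$se_log10_ac50, x$params$rmax,
                x$params$h, x$residual_ss, x$n_points_used))
  } else {
    cat("<curve_fit> not converged\n")
  }
  invisible(x)
}

#' Remove outlying points from a fitted profile
#'
#' Points whose absolute studentized residual from the preliminary fit
#' exceeds `threshold` are removed, largest first, up to `max_frac` of the
#' points. Removal that would leave fewer than 5 points is skipped with a
#' warning; the caller is expected to refit afterwards.
#'
#' @param profile The [response_profile()] the fit was computed on (at least
#'   6 points; shorter profiles are returned unchanged).
#' @param fit The [fit_hill()] result for `profile`.
#' @param threshold Studentized-residual cutoff (default 3).
#' @param max_frac Maximum fraction of points removable (default 0.2).
#' @return The profile with outliers removed (possibly unchanged).
#' @export
remove_outliers <- function(profile, fit, threshold = 3, max_frac = 0.2) {
  n <- length(profile$responses)
  if (n < 6L || !fit$converged || is.null(fit$leverage)) return(profile)
  r <- profile$responses - fit$fitted
  s <- sqrt(fit$residual_ss / max(1L, n - 3L))
  if (s == 0) return(profile)
  denom <- s * sqrt(pmax(1 - fit$leverage, 1e-8))
  rs <- r / denom
  cand <- which(abs(rs) > threshold)
  if (!length(cand)) return(profile)
  kmax <- floor(max_frac * n)
  if (length(cand) > kmax) {
    cand <- cand[order(-abs(rs[cand]))][seq_len(kmax)]
  }
  if (n - length(cand) < 5L) {
    warning("outlier removal skipped: would leave fewer than 5 points")
    return(profile)
  }
  response_profile(profile$compound_id, profile$repeat_id,
                   profile$concentrations[-cand], profile$responses[-cand],
                   profile$metadata)
}

# fit with one round of outlier removal and refit; the standard per-profile
# estimation path
.fit_profile_qc <- function(profile, bounds = NULL) {
  f1 <- fit_hill(profile, bounds)
  if (!f1$converged) return(f1)
  cleaned <- remove_outliers(profile, f1)
  if (length(cleaned$responses) == length(profile$responses)) return(f1)
  fit_hill(cleaned, bounds)
}
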