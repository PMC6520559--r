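#' Assay noise band (detection limits)
#'
#' The detection limit of an assay is taken as +/- `multiplier` standard
#' deviations of the response at the lowest tested concentration, centered at
#' zero because responses are control-normalized percentages.
#'
#' @param sigma Standard deviation of the lowest-concentration responses, in
#'   percent units.
#' @param multiplier Half-width of the band in units of `sigma` (default 3).
#' @return An object of class `noise_band` with fields `sigma`, `multiplier`,
#'   `lower`, `upper`.
#' @export
noise_band <- function(sigma, multiplier = 3) {
  if (!is.finite(sigma) || sigma < 0) stop("'sigma' must be finite and >= 0")
  if (!is.finite(multiplier) || multiplier <= 0) {
    stop("'multiplier' must be positive")
  }
  structure(list(sigma = sigma, multiplier = multiplier,
                 lower = -multiplier * sigma, upper = multiplier * sigma),
            class = "noise_band")
}

#' @export
print.noise_band <- function(x, ...) {
  cat(sprintf("<noise_band> sigma = %.4g, limits = [%.4g, %.4g]\n",
              x$sigma, x$lower, x$upper))
  invisible(x)
}

#' Estimate the noise band from a study
#'
#' `sigma` is the sample standard deviation of the responses observed at each
#' repeat's lowest tested concentration, pooled over every profile in the
#' study (one fixed band per assay). Supply `sigma` directly to use an
#' external estimate, e.g. from DMSO control plates; set
#' `per_compound = TRUE` to instead get one band per compound.
#'
#' @param study An [assay_study()].
#' @param multiplier Band half-width in sigma units (default 3).
#' @param sigma Optional externally supplied sigma overriding estimation.
#' @param per_compound If `TRUE`, return a named list of per-compound bands.
#' @return A [noise_band()], or a named list of them.
#' @export
estimate_noise_band <- function(study, multiplier = 3, sigma = NULL,
                                per_compound = FALSE) {
  if (!is.null(sigma)) return(noise_band(sigma, multiplier))
  first_resp <- function(profiles) {
    vapply(profiles, function(p) p$responses[[1L]], numeric(1))
  }
  if (per_compound) {
    out <- lapply(study$compounds, function(cd) {
      v <- first_resp(cd$profiles)
      if (length(v) < 2L) {
        stop("compound ", cd$compound_id,
             ": need >= 2 lowest-concentration responses to estimate sigma")
      }
      noise_band(stats::sd(v), multiplier)
    })
    return(out)
  }
  v <- unlist(lapply(study$compounds, function(cd) first_resp(cd$profiles)),
              use.names = FALSE)
  if (length(v) < 2L) {
    stop("need >= 2 lowest-concentration responses to estimate sigma")
  }
  noise_band(stats::sd(v), multiplier)
}

#' Is a profile entirely within the noise band?
#'
#' Membership uses closed intervals: a response exactly at a detection limit
#' is within the band ("extending beyond" means strict exceedance).
#'
#' @param profile A [response_profile()].
#' @param band A [noise_band()].
#' @return `TRUE` iff every response r satisfies lower <= r <= upper.
#' @export
is_within_noise <- function(profile, band) {
  all(profile$responses >= band$lower & profile$responses <= band$upper)
}

#' Split a compound's repeats into active and within-noise sets
#'
#' @param compound A [compound_data()].
#' @param band A [noise_band()].
#' @return List with elements `active` (profiles with at least one response
#'   strictly outside the band) and `noise`; together they are all profiles.
#' @export
partition_repeats <- function(compound, band) {
  inside <- vapply(compound$profiles, is_within_noise, logical(1),
                   band = band)
  list(active = compound$profiles[!inside],
       noise = compound$profiles[inside])
}
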