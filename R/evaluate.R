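#' Score clustering output against simulation truth
#'
#' A Type A error is charged to a compound when a true single-cluster
#' compound is classified Conclusive Case 3 (repeats of one true cluster
#' incorrectly separated); a Type B error when a true multiple-cluster
#' compound is classified Conclusive Case 1 (repeats of separate true
#' clusters falsely combined). Rates are computed over all compounds by
#' default; `conditional = TRUE` divides each error count by the number of
#' compounds of the corresponding truth type instead.
#'
#' @param truth Truth list from [simulate_study()].
#' @param assignments Assignments from [casanova_study()] on the same study.
#' @param alpha_threshold Optional threshold annotation carried through.
#' @param conditional Use truth-type-conditional denominators?
#' @return An object of class `error_rates`: `type_a`, `type_b`,
#'   `n_compounds`, raw counts.
#' @export
score_errors <- function(truth, assignments, alpha_threshold = NA_real_,
                         conditional = FALSE) {
  ids_t <- sort(unname(names(truth)))
  ids_a <- sort(unname(vapply(assignments, function(a) a$compound_id,
                              character(1))))
  if (!identical(ids_t, ids_a)) {
    stop("truth and assignments cover different compounds")
  }
  cls <- stats::setNames(
    vapply(assignments, function(a) a$case_class, character(1)),
    vapply(assignments, function(a) a$compound_id, character(1)))
  single <- vapply(truth, function(t) t$n_clusters == 1L, logical(1))
  names(single) <- names(truth)
  cls <- cls[names(single)]
  n <- length(single)
  n_a <- sum(single & cls == "ConclusiveCase3")
  n_b <- sum(!single & cls == "ConclusiveCase1")
  den_a <- if (conditional) max(1L, sum(single)) else n
  den_b <- if (conditional) max(1L, sum(!single)) else n
  structure(list(alpha_threshold = alpha_threshold,
                 type_a = n_a / den_a, type_b = n_b / den_b,
                 n_type_a = n_a, n_type_b = n_b,
                 n_true_single = sum(single), n_compounds = n),
            class = "error_rates")
}

#' @export
print.error_rates <- function(x, ...) {
  cat(sprintf("<error_rates> alpha = %s: Type A = %.4f, Type B = %.4f (n = %d)\n",
              format(x$alpha_threshold), x$type_a, x$type_b, x$n_compounds))
  invisible(x)
}

#' Re-cluster one study across a grid of p-value thresholds
#'
#' Reruns the clustering at each threshold (the conclusive-test level stays
#' fixed at `config$conclusive_alpha`) and scores Type A / Type B errors
#' against truth. Raising the threshold splits more, so Type A is
#' nondecreasing and Type B nonincreasing along the grid.
#'
#' @param study Simulated [assay_study()].
#' @param truth Matching truth from [simulate_study()].
#' @param thresholds Sorted numeric vector of thresholds in \[0, 1\].
#' @param config Base [analysis_config()]; its `alpha` is replaced per
#'   threshold.
#' @param band Optional [noise_band()] (defaults to the study's band).
#' @param conditional Passed to [score_errors()].
#' @return Data frame with columns `threshold`, `type_a`, `type_b`.
#' @export
threshold_sweep <- function(study, truth, thresholds,
                            config = analysis_config(), band = NULL,
                            conditional = FALSE) {
  if (is.unsorted(thresholds)) stop("'thresholds' must be sorted")
  rows <- lapply(thresholds, function(th) {
    cfg <- config
    cfg$alpha <- th
    asg <- casanova_study(study, cfg, band)
    er <- score_errors(truth, asg, th, conditional)
    data.frame(threshold = th, type_a = er$type_a, type_b = er$type_b)
  })
  do.call(rbind, rows)
}

#' Bias and variance of AC50 estimators by simulation cell
#'
#' Summarizes per-compound log10 AC50 estimates against truth within every
#' combination of true AC50, RMAX, number of profiles and aggregation
#' method present in the input: bias = mean(estimate - truth), variance =
#' sample variance of the estimates. Rows with missing estimates
#' (non-converged compounds) are excluded; their count is attached as
#' attribute `n_excluded`.
#'
#' @param estimates Data frame with columns `method`, `log10_ac50`,
#'   `true_log10_ac50` and optionally `rmax`, `n_profiles`.
#' @return Data frame with one row per cell: grouping columns, `bias`,
#'   `variance`, `n_used`.
#' @export
bias_variance_table <- function(estimates) {
  stopifnot(all(c("method", "log10_ac50", "true_log10_ac50") %in%
                  names(estimates)))
  keep <- !is.na(estimates$log10_ac50)
  n_excluded <- sum(!keep)
  estimates <- estimates[keep, , drop = FALSE]
  gcols <- intersect(c("true_log10_ac50", "rmax", "n_profiles", "method"),
                     names(estimates))
  key <- interaction(estimates[gcols], drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(estimates, key), function(d) {
    cbind(d[1, gcols, drop = FALSE],
          data.frame(bias = mean(d$log10_ac50 - d$true_log10_ac50),
                     variance = stats::var(d$log10_ac50),
                     n_used = nrow(d)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Run one cell of the potency-estimation simulation
#'
#' Simulates a [simulate_estimation_study()] cell, fits every profile with
#' the Hill model (outlier removal and refit), aggregates per compound with
#' each requested method and returns the per-compound estimates ready for
#' [bias_variance_table()].
#'
#' @param true_ac50,rmax,n_profiles,sigma,n_compounds Cell parameters, see
#'   [simulate_estimation_study()].
#' @param methods Aggregation methods to evaluate.
#' @param seed Optional integer seed.
#' @return Data frame with one row per compound x method: `compound_id`,
#'   `method`, `log10_ac50` (NA when aggregation failed),
#'   `true_log10_ac50`, `rmax`, `n_profiles`.
#' @export
potency_sim <- function(true_ac50 = 0.1, rmax = 100, n_profiles = 3,
                        sigma = 5, n_compounds = 2000,
                        methods = c("avg", "median", "weighted"),
                        seed = NULL) {
  sim <- simulate_estimation_study(true_ac50, rmax, n_profiles, sigma,
                                   n_compounds, seed)
  rows <- vector("list", length(sim$study$compounds))
  for (i in seq_along(sim$study$compounds)) {
    cd <- sim$study$compounds[[i]]
    fits <- lapply(cd$profiles, .fit_profile_qc)
    est <- vapply(methods, function(m) {
      tryCatch(aggregate_ac50(fits, cd$profiles, m)$log10_ac50,
               error = function(e) NA_real_)
    }, numeric(1))
    rows[[i]] <- data.frame(compound_id = cd$compound_id, method = methods,
                            log10_ac50 = unname(est),
                            true_log10_ac50 = log10(true_ac50),
                            rmax = rmax, n_profiles = as.integer(n_profiles),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
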