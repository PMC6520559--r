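#' Aggregate per-profile AC50 estimates into one cluster-level potency
#'
#' Four strategies over the repeats of one cluster, all on the log10 scale:
#' `avg` (arithmetic mean of the per-profile log10 AC50s), `median`,
#' `weighted` (inverse-variance weighted mean with weights (1/SE)^2) and
#' `one_model` (a single Hill fit to the pooled points of all profiles).
#' Non-converged fits are excluded. Under `weighted`, a fit with SE exactly
#' zero receives the largest finite weight present in the set (equal weights
#' if every SE is zero), so a deterministic fit cannot swamp the average
#' with an infinite weight.
#'
#' @param fits List of [fit_hill()] results, one per profile of the cluster.
#' @param profiles The corresponding profiles; required for `one_model`.
#' @param method One of `"weighted"`, `"avg"`, `"median"`, `"one_model"`.
#' @param compound_id,cluster Identifiers carried into the result.
#' @return An object of class `potency_estimate` with fields `compound_id`,
#'   `cluster`, `method`, `log10_ac50`, `ac50` (micromolar) and
#'   `n_profiles`.
#' @export
aggregate_ac50 <- function(fits, profiles = NULL,
                           method = c("weighted", "avg", "median",
                                      "one_model"),
                           compound_id = NA_character_,
                           cluster = NA_character_) {
  method <- match.arg(method)
  if (method == "one_model") {
    if (is.null(profiles) || !length(profiles)) {
      stop("'one_model' aggregation needs the profiles")
    }
    pooled <- list(
      concentrations = unlist(lapply(profiles,
                                     function(p) p$concentrations)),
      responses = unlist(lapply(profiles, function(p) p$responses)))
    fit <- fit_hill(pooled)
    if (!fit$converged) stop("pooled one-model fit did not converge")
    est <- fit$params$log10_ac50
    n_prof <- length(profiles)
  } else {
    ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
    if (!any(ok)) stop("no converged fits to aggregate")
    vals <- vapply(fits[ok], function(f) f$params$log10_ac50, numeric(1))
    est <- switch(method,
      avg = mean(vals),
      median = stats::median(vals),
      weighted = {
        se <- vapply(fits[ok], function(f) f$se_log10_ac50, numeric(1))
        w <- 1 / se^2
        if (any(se == 0)) {
          finite_w <- w[is.finite(w)]
          w[se == 0] <- if (length(finite_w)) max(finite_w) else 1
        }
        sum(w * vals) / sum(w)
      })
    n_prof <- sum(ok)
  }
  structure(list(compound_id = compound_id, cluster = cluster,
                 method = method, log10_ac50 = est, ac50 = 10^est,
                 n_profiles = n_prof),
            class = "potency_estimate")
}

#' @export
print.potency_estimate <- function(x, ...) {
  cat(sprintf("<potency_estimate> %s / cluster %s [%s]: log10 AC50 = %.4f (%.4g uM, n = %d)\n",
              x$compound_id, x$cluster, x$method, x$log10_ac50, x$ac50,
              x$n_profiles))
  invisible(x)
}

#' Estimate per-cluster potency for a clustered study
#'
#' For every active cluster of every compound, each member profile is fitted
#' with the Hill model (with one round of studentized-residual outlier
#' removal and refit) and the per-profile log10 AC50s are aggregated with
#' the chosen method. Potency is never aggregated across the clusters of a
#' Case 3 compound, and noise clusters get no estimate. Clusters where no
#' profile fit converges are skipped; their count is attached as attribute
#' `n_skipped`.
#'
#' @param study The [assay_study()] that was clustered.
#' @param assignments Output of [casanova_study()].
#' @param method Aggregation method, see [aggregate_ac50()].
#' @return List of `potency_estimate` objects.
#' @export
estimate_potency <- function(study, assignments,
                             method = c("weighted", "avg", "median",
                                        "one_model")) {
  method <- match.arg(method)
  out <- list()
  n_skipped <- 0L
  for (a in assignments) {
    cd <- study$compounds[[a$compound_id]]
    if (is.null(cd)) stop("assignment for unknown compound ", a$compound_id)
    prof_by_id <- stats::setNames(cd$profiles,
                                  vapply(cd$profiles,
                                         function(p) p$repeat_id,
                                         character(1)))
    for (lab in names(a$conclusive)) {
      ids <- names(a$labels)[a$labels == lab]
      profs <- prof_by_id[ids]
      fits <- lapply(profs, .fit_profile_qc)
      est <- tryCatch(
        aggregate_ac50(fits, profs, method, a$compound_id, lab),
        error = function(e) NULL)
      if (is.null(est)) {
        n_skipped <- n_skipped + 1L
      } else {
        out[[length(out) + 1L]] <- est
      }
    }
  }
  attr(out, "n_skipped") <- n_skipped
  out
}
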