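#' Construct a single concentration-response profile
#'
#' A profile ("repeat") is one concentration-response curve for one compound:
#' an ordered vector of tested concentrations and the normalized responses
#' observed at them. Repeats are not conventional replicates -- supplier,
#' library preparation site, purity or experimental day may differ between
#' them, which is precisely why they are clustered downstream.
#'
#' @param compound_id Compound identifier (coerced to character).
#' @param repeat_id Repeat identifier, unique within the compound.
#' @param concentrations Positive concentrations in micromolar. Rows are
#'   re-ordered so that concentrations are strictly increasing; duplicated
#'   concentrations within a repeat are an error.
#' @param responses Responses in percent of the positive control, same length
#'   as `concentrations`.
#' @param metadata Optional named character vector (e.g. supplier, site,
#'   purity, day).
#' @return An object of class `response_profile`.
#' @export
response_profile <- function(compound_id, repeat_id, concentrations, responses,
                             metadata = NULL) {
  compound_id <- as.character(compound_id)
  repeat_id <- as.character(repeat_id)
  concentrations <- as.numeric(concentrations)
  responses <- as.numeric(responses)
  if (length(concentrations) != length(responses)) {
    stop("'concentrations' and 'responses' must have equal length")
  }
  if (length(concentrations) < 2L) {
    stop("a profile needs at least 2 concentration points")
  }
  if (any(!is.finite(concentrations)) || any(concentrations <= 0)) {
    stop("concentrations must be finite and strictly positive")
  }
  o <- order(concentrations)
  concentrations <- concentrations[o]
  responses <- responses[o]
  if (any(diff(concentrations) == 0)) {
    stop("duplicated concentration within repeat '", repeat_id, "'")
  }
  structure(
    list(compound_id = compound_id, repeat_id = repeat_id,
         concentrations = concentrations, responses = responses,
         metadata = metadata),
    class = "response_profile"
  )
}

#' Bundle the repeats of one compound
#'
#' @param profiles List of [response_profile()] objects sharing one
#'   `compound_id`.
#' @return An object of class `compound_data`.
#' @export
compound_data <- function(profiles) {
  if (!length(profiles)) stop("a compound needs at least one profile")
  ids <- vapply(profiles, function(p) p$compound_id, character(1))
  if (length(unique(ids)) != 1L) {
    stop("all profiles must share one compound_id")
  }
  rid <- vapply(profiles, function(p) p$repeat_id, character(1))
  if (anyDuplicated(rid)) stop("duplicated repeat_id within compound ", ids[1])
  structure(list(compound_id = ids[1], profiles = profiles),
            class = "compound_data")
}

#' Assemble compounds into an assay study
#'
#' @param compounds List of [compound_data()] objects with unique ids.
#' @param noise_band Optional [noise_band()] attached to the study.
#' @param provenance Optional named list recording where the data came from.
#' @return An object of class `assay_study`.
#' @export
assay_study <- function(compounds, noise_band = NULL, provenance = list()) {
  ids <- vapply(compounds, function(x) x$compound_id, character(1))
  if (anyDuplicated(ids)) stop("compound ids must be unique")
  names(compounds) <- ids
  structure(list(compounds = compounds, noise_band = noise_band,
                 provenance = provenance),
            class = "assay_study")
}

#' @export
print.response_profile <- function(x, ...) {
  cat(sprintf("<response_profile> %s / %s: %d points, %.3g-%.3g uM\n",
              x$compound_id, x$repeat_id, length(x$concentrations),
              min(x$concentrations), max(x$concentrations)))
  invisible(x)
}

#' @export
print.compound_data <- function(x, ...) {
  cat(sprintf("<compound_data> %s: %d repeats\n", x$compound_id,
              length(x$profiles)))
  invisible(x)
}

#' @export
print.assay_study <- function(x, ...) {
  n_rep <- sum(vapply(x$compounds, function(cd) length(cd$profiles), 1L))
  cat(sprintf("<assay_study> %d compounds, %d repeats%s\n",
              length(x$compounds), n_rep,
              if (is.null(x$noise_band)) "" else ", noise band attached"))
  invisible(x)
}
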