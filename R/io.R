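#' Read a concentration-response study from a long-format table
#'
#' The canonical interchange format is a comma-separated text file with a
#' header row and one row per compound x repeat x concentration. Required
#' columns: `compound_id`, `repeat_id`, `concentration` (micromolar),
#' `response` (percent of positive control). Any further columns are carried
#' along as per-repeat metadata (their first value within each repeat is
#' kept).
#'
#' Rows with missing responses are dropped with a warning giving the count;
#' repeats reduced below 2 points are discarded. Grouping is independent of
#' row order: compounds and repeats are sorted by identifier, points by
#' ascending concentration.
#'
#' @param path Path to a delimited text file.
#' @param format Input dialect; only `"long_table"` is supported.
#' @return An [assay_study()].
#' @export
read_study <- function(path, format = c("long_table")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("compound_id", "repeat_id", "concentration", "response")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  df$compound_id <- as.character(df$compound_id)
  df$repeat_id <- as.character(df$repeat_id)
  n_na <- sum(is.na(df$response))
  if (n_na > 0L) {
    warning(sprintf("dropped %d row(s) with missing response", n_na))
    df <- df[!is.na(df$response), , drop = FALSE]
  }
  bad <- which(!is.finite(df$concentration) | df$concentration <= 0)
  if (length(bad)) {
    stop("non-positive or non-finite concentration at row ", bad[1])
  }
  key <- paste(df$compound_id, df$repeat_id, df$concentration, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (compound, repeat, concentration) at row ",
         which(duplicated(key))[1])
  }
  meta_cols <- setdiff(names(df), required)
  dropped <- 0L
  compounds <- lapply(sort(unique(df$compound_id)), function(cid) {
    dc <- df[df$compound_id == cid, , drop = FALSE]
    profiles <- lapply(sort(unique(dc$repeat_id)), function(rid) {
      dr <- dc[dc$repeat_id == rid, , drop = FALSE]
      if (nrow(dr) < 2L) return(NULL)
      meta <- NULL
      if (length(meta_cols)) {
        meta <- vapply(meta_cols, function(m) as.character(dr[[m]][1]),
                       character(1))
      }
      response_profile(cid, rid, dr$concentration, dr$response, meta)
    })
    null <- vapply(profiles, is.null, logical(1))
    dropped <<- dropped + sum(null)
    profiles <- profiles[!null]
    if (!length(profiles)) return(NULL)
    compound_data(profiles)
  })
  if (dropped > 0L) {
    warning(sprintf("discarded %d repeat(s) with fewer than 2 usable points",
                    dropped))
  }
  compounds <- compounds[!vapply(compounds, is.null, logical(1))]
  assay_study(compounds, provenance = list(source = path, format = format))
}

#' Write clustering and potency results as delimited text tables
#'
#' Produces `repeats.csv` (one row per compound x repeat: cluster label,
#' compound class, conclusive flag of the repeat's cluster) and
#' `clusters.csv` (one row per compound x active cluster with an AC50
#' estimate). The pair round-trips through [read_results()].
#'
#' @param assignments List of cluster assignments from [casanova_study()].
#' @param potencies List of potency estimates from [estimate_potency()];
#'   may be empty (e.g. an all-Case-2 study).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(assignments, potencies, dir) {
  if (!length(assignments)) stop("'assignments' must be non-empty")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep_tab <- do.call(rbind, lapply(assignments, function(a) {
    lab <- a$labels
    concl <- vapply(lab, function(l) {
      if (l == "noise") NA else isTRUE(a$conclusive[[l]])
    }, logical(1))
    data.frame(compound_id = a$compound_id, repeat_id = names(lab),
               cluster = unname(lab), conclusive = unname(concl),
               case_class = a$case_class, row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  if (length(potencies)) {
    clu_tab <- do.call(rbind, lapply(potencies, function(p) {
      data.frame(compound_id = p$compound_id, cluster = p$cluster,
                 method = p$method, log10_ac50 = p$log10_ac50,
                 ac50_uM = 10^p$log10_ac50, n_profiles = p$n_profiles,
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  } else {
    clu_tab <- data.frame(compound_id = character(), cluster = character(),
                          method = character(), log10_ac50 = numeric(),
                          ac50_uM = numeric(), n_profiles = integer())
  }
  paths <- c(repeats = file.path(dir, "repeats.csv"),
             clusters = file.path(dir, "clusters.csv"))
  utils::write.csv(rep_tab, paths[["repeats"]], row.names = FALSE)
  utils::write.csv(clu_tab, paths[["clusters"]], row.names = FALSE)
  invisible(paths)
}

#' Read back results written by [write_results()]
#'
#' Reconstructs the cluster assignments (labels, conclusive flags, class;
#' the ANOVA evidence trail is not serialized) and the potency table.
#'
#' @param dir Directory holding `repeats.csv` and `clusters.csv`.
#' @return List with elements `assignments` and `potencies` (a data frame).
#' @export
read_results <- function(dir) {
  rep_tab <- utils::read.csv(file.path(dir, "repeats.csv"),
                             stringsAsFactors = FALSE,
                             colClasses = c(cluster = "character"))
  clu_tab <- utils::read.csv(file.path(dir, "clusters.csv"),
                             stringsAsFactors = FALSE,
                             colClasses = c(cluster = "character"))
  assignments <- lapply(split(rep_tab, rep_tab$compound_id), function(d) {
    labels <- stats::setNames(d$cluster, d$repeat_id)
    active <- d[d$cluster != "noise", , drop = FALSE]
    concl <- stats::setNames(
      vapply(split(active$conclusive, active$cluster), function(v) v[1],
             logical(1)),
      unique(active$cluster)[order(unique(active$cluster))]
    )
    # split() sorts by cluster label, keep that order explicitly
    concl <- concl[sort(names(concl))]
    structure(list(compound_id = d$compound_id[1], labels = labels,
                   conclusive = as.list(concl),
                   case_class = d$case_class[1], evidence = NULL),
              class = "cluster_assignment")
  })
  names(assignments) <- NULL
  list(assignments = assignments, potencies = clu_tab)
}

#' Write a study in the long-table interchange format
#'
#' Inverse of [read_study()]: one row per compound x repeat x concentration,
#' metadata columns appended when present.
#'
#' @param study An [assay_study()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_study <- function(study, path) {
  rows <- list()
  for (cd in study$compounds) {
    for (p in cd$profiles) {
      d <- data.frame(compound_id = p$compound_id, repeat_id = p$repeat_id,
                      concentration = p$concentrations,
                      response = p$responses, stringsAsFactors = FALSE)
      if (!is.null(p$metadata)) {
        for (m in names(p$metadata)) d[[m]] <- p$metadata[[m]]
      }
      rows[[length(rows) + 1L]] <- d
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
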