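#' Analysis configuration
#'
#' Collects the tunable parameters of the clustering procedure. `alpha` is
#' the significance threshold used for the ANOVA decision tree and the
#' ranked-neighbor pairwise tests; `conclusive_alpha` is the level of the
#' one-sample t-test separating a cluster from the detection limit.
#' "Significant at level alpha" always means p strictly below alpha, so
#' alpha = 0 never splits and alpha = 1 splits every unequal neighbor pair.
#'
#' @param alpha Significance threshold for clustering decisions (default
#'   0.05).
#' @param noise_multiplier Noise band half-width in sigma units (default 3).
#' @param bins Number of concentration bins (default 5).
#' @param points_per_bin Nominal points per bin (default 3).
#' @param conclusive_alpha Level of the conclusive t-test (default 0.05).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(alpha = 0.05, noise_multiplier = 3, bins = 5,
                            points_per_bin = 3, conclusive_alpha = 0.05) {
  stopifnot(alpha >= 0, alpha <= 1,
            conclusive_alpha >= 0, conclusive_alpha <= 1,
            noise_multiplier > 0, bins >= 2)
  structure(list(alpha = alpha, noise_multiplier = noise_multiplier,
                 bins = as.integer(bins),
                 points_per_bin = as.integer(points_per_bin),
                 conclusive_alpha = conclusive_alpha),
            class = "analysis_config")
}

#' Split partition blocks between significantly different ranked neighbors
#'
#' Within each block of `partition`, repeats are sorted by their mean
#' response (ties broken by repeat identifier, so results are deterministic)
#' and each adjacent pair is compared with a two-sample t statistic pooled on
#' the ANOVA mean squared error:
#' t = (m2 - m1) / sqrt(mse * (1/k1 + 1/k2)), on `df` degrees of freedom,
#' where k are the observation counts behind each mean. A cut is placed
#' wherever the two-sided p-value is below `alpha`. Blocks only ever split,
#' never merge, so the result is a refinement of `partition`.
#'
#' When `mse` is exactly zero, any unequal adjacent pair is cut (an
#' infinitely significant difference).
#'
#' @param means Named numeric vector of per-repeat means.
#' @param mse Pooled ANOVA mean squared error.
#' @param df Error degrees of freedom for the t reference distribution.
#' @param counts Named vector of observation counts behind each mean.
#' @param alpha Significance threshold (strict).
#' @param partition List of character vectors of repeat ids.
#' @return The refined partition (list of character vectors).
#' @export
neighbor_split <- function(means, mse, df, counts, alpha, partition) {
  out <- list()
  for (blk in partition) {
    if (length(blk) < 2L) {
      out[[length(out) + 1L]] <- blk
      next
    }
    m <- means[blk]
    k <- counts[blk]
    o <- order(m, blk)
    ids <- blk[o]; m <- unname(m[o]); k <- unname(k[o])
    n1 <- length(ids) - 1L
    cut <- logical(n1)
    for (i in seq_len(n1)) {
      dm <- m[i + 1L] - m[i]
      if (mse == 0 || alpha >= 1) {
        # zero mse: unequal means are infinitely significant; threshold 1
        # means always significant, so any unequal pair is cut even when
        # the two-sided p rounds to 1 in double precision
        cut[i] <- dm != 0
      } else {
        tt <- dm / sqrt(mse * (1 / k[i] + 1 / k[i + 1L]))
        p <- 2 * stats::pt(-abs(tt), df)
        cut[i] <- p < alpha
      }
    }
    grp <- cumsum(c(0L, cut))
    pieces <- split(ids, grp)
    for (p in pieces) out[[length(out) + 1L]] <- unname(p)
  }
  out
}

#' Per-bin subgroup refinement of a partition
#'
#' Runs [neighbor_split()] once per concentration bin, from the highest
#' concentration bin down to the lowest, using the bin-restricted cell means
#' (and cell counts) in place of the overall repeat means. Each pass refines
#' the partition produced by the previous one, so clusters found on the
#' whole concentration range can be further divided where repeats separate
#' only in part of the range.
#'
#' @param anova An `anova_result` from [fit_two_way_anova()].
#' @param partition Starting partition (list of character vectors).
#' @param alpha Significance threshold.
#' @return The refined partition.
#' @export
subgroup_analysis <- function(anova, partition, alpha) {
  n_bins <- nrow(anova$bin_repeat_means)
  for (b in rev(seq_len(n_bins))) {
    partition <- neighbor_split(anova$bin_repeat_means[b, ], anova$mse,
                                anova$df_error, anova$cell_counts[b, ],
                                alpha, partition)
  }
  partition
}

#' Test whether a cluster is conclusively separated from the noise band
#'
#' The per-bin mean responses of the cluster that lie strictly above the
#' upper detection limit (or strictly below the lower limit, whichever side
#' has more exceeding bins -- ties go to the larger total exceedance) are
#' compared with that limit by a one-sided one-sample t-test. The cluster is
#' conclusive iff at least two bin means exceed on the tested side and the
#' p-value is below `alpha`; with fewer than two exceeding means the t-test
#' has no degrees of freedom and the cluster is inconclusive by convention.
#'
#' @param bin_means Numeric vector of per-bin mean responses of the cluster.
#' @param band A [noise_band()].
#' @param alpha Test level (default 0.05).
#' @return Logical: is the cluster conclusively beyond the detection limit?
#' @export
test_conclusive <- function(bin_means, band, alpha = 0.05) {
  above <- bin_means[bin_means > band$upper]
  below <- bin_means[bin_means < band$lower]
  if (length(above) == 0L && length(below) == 0L) return(FALSE)
  use_above <- if (length(above) != length(below)) {
    length(above) > length(below)
  } else {
    sum(above - band$upper) >= sum(band$lower - below)
  }
  d <- if (use_above) above - band$upper else band$lower - below
  if (length(d) < 2L) return(FALSE)
  s <- stats::sd(d)
  tt <- if (s == 0) {
    if (mean(d) > 0) Inf else 0
  } else {
    mean(d) / (s / sqrt(length(d)))
  }
  p <- stats::pt(tt, length(d) - 1L, lower.tail = FALSE)
  p < alpha
}

#' Classify a compound from its cluster structure
#'
#' Five classes: Case 2 (all repeats within the noise band); Conclusive or
#' Inconclusive Case 1 (a single cluster holding every repeat, none within
#' noise); Conclusive or Inconclusive Case 3 (multiple clusters, where the
#' within-noise repeats count as one cluster; conclusive iff at least one
#' active cluster is conclusive).
#'
#' @param labels Named character vector mapping repeat id to cluster label
#'   (`"noise"` for within-noise repeats).
#' @param conclusive Named list/vector of conclusive flags per active
#'   cluster label.
#' @return One of `"Case2"`, `"ConclusiveCase1"`, `"InconclusiveCase1"`,
#'   `"ConclusiveCase3"`, `"InconclusiveCase3"`.
#' @export
classify_compound <- function(labels, conclusive) {
  n <- length(labels)
  n_noise <- sum(labels == "noise")
  active_labels <- setdiff(unique(labels), "noise")
  if (n_noise == n) return("Case2")
  if (n_noise == 0L && length(active_labels) == 1L) {
    return(if (isTRUE(conclusive[[active_labels]])) "ConclusiveCase1"
           else "InconclusiveCase1")
  }
  any_concl <- any(vapply(active_labels, function(l) {
    isTRUE(conclusive[[l]])
  }, logical(1)))
  if (any_concl) "ConclusiveCase3" else "InconclusiveCase3"
}

# per-bin mean response of a set of repeats, pooled over cells
.cluster_bin_means <- function(binned, repeat_ids) {
  sel <- binned$rep %in% match(repeat_ids, binned$repeat_ids)
  vapply(seq_len(binned$n_bins), function(b) {
    mean(binned$y[sel & binned$bin == b])
  }, numeric(1))
}

#' Cluster one compound's repeats
#'
#' The full per-compound procedure: (a) repeats entirely within the noise
#' band are set aside as the "noise" cluster; (b) a compound with no active
#' repeat is Case 2, one with a single active repeat keeps it as a singleton
#' cluster (no ANOVA possible); (c) with two or more active repeats the
#' two-way ANOVA is fitted and the decision tree applied: if the interaction
#' is significant and REPEAT is significant, repeats are first split on their
#' overall means and then refined per bin; if only the interaction is
#' significant, only the per-bin subgroup analysis runs; if only REPEAT is
#' significant, only the overall-mean split runs; otherwise all active
#' repeats form one cluster; (d) every active cluster gets a conclusive flag
#' from [test_conclusive()]; (e) the compound is classified by
#' [classify_compound()].
#'
#' Active clusters are labeled "1", "2", ... in order of decreasing mean
#' response.
#'
#' @param compound A [compound_data()].
#' @param band A [noise_band()].
#' @param config An [analysis_config()].
#' @return An object of class `cluster_assignment` with fields
#'   `compound_id`, `labels`, `conclusive`, `case_class` and `evidence`
#'   (the `anova_result`, or `NULL` when no ANOVA was fitted).
#' @export
casanova <- function(compound, band, config = analysis_config()) {
  if (!length(compound$profiles)) {
    stop("compound ", compound$compound_id, " has no profiles")
  }
  all_ids <- vapply(compound$profiles, function(p) p$repeat_id, character(1))
  parts <- partition_repeats(compound, band)
  labels <- stats::setNames(rep("noise", length(all_ids)), all_ids)
  active <- parts$active
  if (length(active) == 0L) {
    return(structure(list(compound_id = compound$compound_id,
                          labels = labels, conclusive = list(),
                          case_class = "Case2", evidence = NULL),
                     class = "cluster_assignment"))
  }
  binned <- bin_concentrations(active, config$bins, config$points_per_bin)
  active_ids <- binned$repeat_ids
  anova <- NULL
  if (length(active) == 1L) {
    partition <- list(active_ids)
  } else {
    anova <- fit_two_way_anova(binned)
    # threshold 1 means "always significant" (a p-value of exactly 1 still
    # passes), threshold 0 "never significant"
    sig <- function(p) {
      !is.na(p) && (p < config$alpha || config$alpha >= 1)
    }
    g_sig <- sig(anova$p_interaction)
    r_sig <- sig(anova$p_repeat)
    partition <- list(active_ids)
    if (g_sig && r_sig) {
      partition <- neighbor_split(anova$repeat_means, anova$mse,
                                  anova$df_error, anova$repeat_counts,
                                  config$alpha, partition)
      partition <- subgroup_analysis(anova, partition, config$alpha)
    } else if (g_sig) {
      partition <- subgroup_analysis(anova, partition, config$alpha)
    } else if (r_sig) {
      partition <- neighbor_split(anova$repeat_means, anova$mse,
                                  anova$df_error, anova$repeat_counts,
                                  config$alpha, partition)
    }
  }
  # label clusters by decreasing mean response (ties: first repeat id)
  blk_mean <- vapply(partition, function(blk) {
    mean(binned$y[binned$rep %in% match(blk, active_ids)])
  }, numeric(1))
  blk_first <- vapply(partition, function(blk) sort(blk)[1], character(1))
  partition <- partition[order(-blk_mean, blk_first)]
  conclusive <- list()
  for (i in seq_along(partition)) {
    lab <- as.character(i)
    labels[partition[[i]]] <- lab
    conclusive[[lab]] <- test_conclusive(
      .cluster_bin_means(binned, partition[[i]]), band,
      config$conclusive_alpha)
  }
  structure(list(compound_id = compound$compound_id, labels = labels,
                 conclusive = conclusive,
                 case_class = classify_compound(labels, conclusive),
                 evidence = anova),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  k <- length(x$conclusive)
  cat(sprintf("<cluster_assignment> %s: %s, %d active cluster(s), %d noise repeat(s)\n",
              x$compound_id, x$case_class, k, sum(x$labels == "noise")))
  invisible(x)
}

#' Cluster every compound of a study
#'
#' @param study An [assay_study()].
#' @param config An [analysis_config()].
#' @param band Optional [noise_band()]; defaults to the band attached to the
#'   study, or else one estimated with [estimate_noise_band()].
#' @return Named list of `cluster_assignment` objects, one per compound.
#' @export
casanova_study <- function(study, config = analysis_config(), band = NULL) {
  if (is.null(band)) band <- study$noise_band
  if (is.null(band)) {
    band <- estimate_noise_band(study, config$noise_multiplier)
  }
  lapply(study$compounds, casanova, band = band, config = config)
}
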