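#' Bin concentrations into a grouping factor
#'
#' Each profile's points are assigned to `bins` consecutive bins by ascending
#' concentration rank, so that bin 1 holds the lowest concentrations and bin
#' `bins` the highest. With the standard 15-point design and 5 bins this gives
#' the five "3-concentration" bins of the CONC factor. When the point count is
#' not a multiple of `bins`, the remainder points are distributed one per bin
#' starting from bin 1 (e.g. 17 points -> sizes 4,4,3,3,3).
#'
#' Profiles need not share a concentration grid: binning is by each profile's
#' own rank order.
#'
#' @param profiles List of [response_profile()] objects (the active repeats
#'   of one compound).
#' @param bins Number of bins (default 5).
#' @param points_per_bin Nominal points per bin in the reference design
#'   (default 3); actual bin sizes are derived from each profile's length.
#' @return An object of class `binned_responses` holding the long vectors
#'   `bin`, `rep` (indices into `repeat_ids`) and `y`.
#' @export
bin_concentrations <- function(profiles, bins = 5, points_per_bin = 3) {
  if (!length(profiles)) stop("no profiles to bin")
  bins <- as.integer(bins)
  if (bins < 1L) stop("'bins' must be >= 1")
  repeat_ids <- vapply(profiles, function(p) p$repeat_id, character(1))
  bin_idx <- integer(0); rep_idx <- integer(0); y <- numeric(0)
  for (j in seq_along(profiles)) {
    m <- length(profiles[[j]]$responses)
    if (m < bins) {
      stop("repeat '", repeat_ids[j], "' has ", m,
           " points, fewer than ", bins, " bins")
    }
    base <- m %/% bins
    rem <- m %% bins
    sizes <- base + as.integer(seq_len(bins) <= rem)
    bin_idx <- c(bin_idx, rep.int(seq_len(bins), sizes))
    rep_idx <- c(rep_idx, rep.int(j, m))
    y <- c(y, profiles[[j]]$responses)
  }
  structure(list(compound_id = profiles[[1]]$compound_id, n_bins = bins,
                 points_per_bin = as.integer(points_per_bin),
                 repeat_ids = repeat_ids, bin = bin_idx, rep = rep_idx,
                 y = y),
            class = "binned_responses")
}

#' Two-way fixed-effects ANOVA of binned responses
#'
#' Fits the compound-specific model
#' R_ijk = mu + CONC_i + REPEAT_j + gamma_ij + eps_ijk
#' with CONC the binned-concentration factor and REPEAT the profile factor,
#' and returns classical sums-of-squares F tests for both main effects and
#' the interaction. Sums of squares are computed directly from cell means;
#' for the proportional-frequency layouts produced by rank binning (every
#' repeat contributes the same count to a given bin) these equal the
#' classical sequential sums of squares of `anova(lm(...))`.
#'
#' With one observation per cell the interaction is not estimable; the
#' additive model is fitted instead and `p_interaction` is `NA`, with the
#' interaction sum of squares serving as the error term.
#'
#' @param binned A `binned_responses` object from [bin_concentrations()]
#'   with at least 2 repeats and 2 bins.
#' @return An object of class `anova_result`: F statistics and p-values for
#'   CONC, REPEAT and the interaction, the pooled `mse` and its `df_error`,
#'   per-repeat means/counts and the bin x repeat cell means/counts.
#' @export
fit_two_way_anova <- function(binned) {
  I <- binned$n_bins
  J <- length(binned$repeat_ids)
  if (J < 2L) stop("two-way ANOVA needs at least 2 repeats")
  if (I < 2L) stop("two-way ANOVA needs at least 2 bins")
  y <- binned$y
  N <- length(y)
  cell <- (binned$rep - 1L) * I + binned$bin
  cnt <- matrix(tabulate(cell, nbins = I * J), nrow = I, ncol = J)
  if (any(cnt == 0L)) stop("every repeat must contribute to every bin")
  csum <- matrix(0, nrow = I, ncol = J)
  cs <- rowsum(y, cell)
  csum[as.integer(rownames(cs))] <- cs[, 1L]
  gm <- mean(y)
  n_i <- rowSums(cnt); n_j <- colSums(cnt)
  ybar_i <- rowSums(csum) / n_i
  ybar_j <- colSums(csum) / n_j
  cmean <- csum / cnt
  ss_conc <- sum(n_i * (ybar_i - gm)^2)
  ss_rep <- sum(n_j * (ybar_j - gm)^2)
  dev_int <- cmean - outer(ybar_i, rep(1, J)) - outer(rep(1, I), ybar_j) + gm
  ss_int <- sum(cnt * dev_int^2)
  ss_err <- sum((y - cmean[cell])^2)
  df_conc <- I - 1L; df_rep <- J - 1L; df_int <- (I - 1L) * (J - 1L)
  df_err <- N - I * J
  if (df_err == 0L) {
    # saturated cells: fall back to the additive model
    mse <- ss_int / df_int
    df_err_used <- df_int
    f_int <- NA_real_; p_int <- NA_real_
  } else {
    mse <- ss_err / df_err
    df_err_used <- df_err
    if (mse == 0) stop("degenerate data: residual variance is exactly zero")
    f_int <- (ss_int / df_int) / mse
    p_int <- stats::pf(f_int, df_int, df_err_used, lower.tail = FALSE)
  }
  if (mse == 0) stop("degenerate data: residual variance is exactly zero")
  f_conc <- (ss_conc / df_conc) / mse
  f_rep <- (ss_rep / df_rep) / mse
  dimnames(cmean) <- dimnames(cnt) <-
    list(paste0("bin", seq_len(I)), binned$repeat_ids)
  structure(
    list(grand_mean = gm,
         f_conc = f_conc, f_repeat = f_rep, f_interaction = f_int,
         p_conc = stats::pf(f_conc, df_conc, df_err_used, lower.tail = FALSE),
         p_repeat = stats::pf(f_rep, df_rep, df_err_used, lower.tail = FALSE),
         p_interaction = p_int,
         ss = c(conc = ss_conc, repeats = ss_rep, interaction = ss_int,
                error = ss_err),
         mse = mse, df_error = df_err_used,
         repeat_means = stats::setNames(ybar_j, binned$repeat_ids),
         repeat_counts = stats::setNames(n_j, binned$repeat_ids),
         bin_repeat_means = cmean, cell_counts = cnt),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf(
    "<anova_result> F(conc) = %.3g (p = %.3g), F(repeat) = %.3g (p = %.3g), F(int) = %s (p = %s), MSE = %.4g on %d df\n",
    x$f_conc, x$p_conc, x$f_repeat, x$p_repeat,
    format(x$f_interaction, digits = 3), format(x$p_interaction, digits = 3),
    x$mse, x$df_error))
  invisible(x)
}
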