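#' Simulator noise configuration
#'
#' The noise model has three linked quantities taken from the two-way ANOVA
#' of real assays: the pooled mean squared error `MSE` (percent^2), the
#' observed `ResponseRange` (max - min response, percent) and their ratio
#' `CV = MSE / ResponseRange`, which scales the heteroscedastic point noise
#' sd = |E(R)| * CV. Four named presets span the assay noise classes seen in
#' large screening programs (`"low"`, `"moderate-low"`, `"moderate-high"`,
#' `"high"`, with MSE 4/6.25/9/16 on a 100-unit response range);
#' `"moderate"` is an alias for `"moderate-high"`. The noise-band sigma of
#' the simulated assay defaults to sqrt(MSE).
#'
#' @param preset Preset name, ignored when `mse` is given.
#' @param mse Optional explicit ANOVA mean squared error (percent^2).
#' @param response_range Observed response range (default 100).
#' @param sigma_noise_band Noise-band sigma of the simulated assay; defaults
#'   to `sqrt(mse)`.
#' @return An object of class `sim_noise` with fields `mse`,
#'   `response_range`, `cv`, `sigma_noise_band`.
#' @export
sim_noise <- function(preset = c("moderate-high", "low", "moderate-low",
                                 "high", "moderate"),
                      mse = NULL, response_range = 100,
                      sigma_noise_band = NULL) {
  if (is.null(mse)) {
    preset <- match.arg(preset)
    if (preset == "moderate") preset <- "moderate-high"
    mse <- c("low" = 4, "moderate-low" = 6.25, "moderate-high" = 9,
             "high" = 16)[[preset]]
  }
  stopifnot(mse > 0, response_range > 0)
  if (is.null(sigma_noise_band)) sigma_noise_band <- sqrt(mse)
  stopifnot(sigma_noise_band > 0)
  structure(list(mse = mse, response_range = response_range,
                 cv = mse / response_range,
                 sigma_noise_band = sigma_noise_band),
            class = "sim_noise")
}

#' Simulation design for clustering-error studies
#'
#' Defines the sampling scheme of a synthetic qHTS study: per compound, a
#' number of clusters and a number of repeats per cluster are drawn from the
#' given probability vectors; each cluster draws a curve model (Hill or
#' gain-loss), a mean log10 AC50 from a fixed grid without replacement
#' across clusters, and realized curve parameters (see
#' [sample_cluster_params()]). Concentrations are 15 log10-equally spaced
#' values from 1e-4 to 100 micromolar.
#'
#' @param n_compounds Number of compounds passing the detectability screen
#'   (default 2000).
#' @param cluster_count_probs Probabilities of 1..4 clusters per compound.
#' @param repeats_per_cluster_probs Probabilities over repeat counts
#'   (3, 6, 9, 12, 42, 45, 48, 51, 54).
#' @param spacing `"tenfold"` (AC50 grid 1e-4..100, decade steps) or
#'   `"hundredfold"` (grid 1e-4, 1e-2, 1, 100).
#' @param gainloss_prob Probability that a cluster follows the gain-loss
#'   model rather than the Hill model (default 0.5).
#' @param concentrations Tested concentrations in micromolar.
#' @param ac50_sd Sd of the realized cluster log10 AC50 about its grid mean
#'   (default 1/6, placing ~99.7% of realizations within half a grid step).
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(n_compounds = 2000,
                       cluster_count_probs = c(0.60, 0.25, 0.10, 0.05),
                       repeats_per_cluster_probs = c(0.45, 0.25, 0.15, 0.10,
                                                     0.01, 0.01, 0.01, 0.01,
                                                     0.01),
                       spacing = c("tenfold", "hundredfold"),
                       gainloss_prob = 0.5,
                       concentrations = 10^seq(-4, 2, length.out = 15),
                       ac50_sd = 1 / 6) {
  spacing <- match.arg(spacing)
  stopifnot(length(cluster_count_probs) == 4,
            length(repeats_per_cluster_probs) == 9,
            abs(sum(cluster_count_probs) - 1) < 1e-8,
            abs(sum(repeats_per_cluster_probs) - 1) < 1e-8,
            gainloss_prob >= 0, gainloss_prob <= 1,
            all(concentrations > 0), ac50_sd > 0)
  structure(list(n_compounds = as.integer(n_compounds),
                 cluster_count_probs = cluster_count_probs,
                 repeats_per_cluster_probs = repeats_per_cluster_probs,
                 repeat_sizes = c(3L, 6L, 9L, 12L, 42L, 45L, 48L, 51L, 54L),
                 spacing = spacing,
                 ac50_grid = if (spacing == "tenfold") -4:2
                             else c(-4, -2, 0, 2),
                 min_separation = if (spacing == "tenfold") 1 else 2,
                 gainloss_prob = gainloss_prob,
                 concentrations = sort(concentrations),
                 ac50_sd = ac50_sd),
            class = "sim_design")
}

#' Draw the cluster structure of one simulated compound
#'
#' @param design A [sim_design()].
#' @return List with `n_clusters` and integer vector `repeats_per_cluster`.
#' @export
sample_cluster_structure <- function(design) {
  n_clusters <- sample.int(4L, 1L, prob = design$cluster_count_probs)
  reps <- design$repeat_sizes[sample.int(
    length(design$repeat_sizes), n_clusters, replace = TRUE,
    prob = design$repeats_per_cluster_probs)]
  list(n_clusters = n_clusters, repeats_per_cluster = reps)
}

#' Draw curve parameters for each cluster of one compound
#'
#' Grid means (`MEAN`) of log10 AC50 are drawn without replacement across
#' clusters from the spacing grid, so distinct clusters differ by at least
#' one grid step in expectation. Per cluster: the mean maximal response
#' mu_RMAX ~ Uniform(3 sigma, ResponseRange); RMAX ~ Normal(mu_RMAX,
#' sd = sqrt(MSE)); slope h = |Normal(1, sd 3)|; the realized log10 AC50
#' (gain-side AC50 for gain-loss clusters) ~ Normal(MEAN, ac50_sd). A
#' gain-loss cluster additionally picks its loss-side log10 AC50 uniformly
#' from the grid values at least `min_separation` above its gain MEAN; when
#' no grid value qualifies the loss AC50 is set to 3 (i.e. 1000 micromolar,
#' pushing the loss phase beyond the tested range).
#'
#' All repeats of a cluster share the cluster's parameters; repeats differ
#' only through point noise.
#'
#' @param design A [sim_design()].
#' @param noise A [sim_noise()].
#' @param n_clusters Number of clusters (<= grid size).
#' @return List (one element per cluster) of lists with `model`
#'   (`"hill"`/`"gainloss"`), `params`, `mean_log10_ac50`, `mu_rmax`.
#' @export
sample_cluster_params <- function(design, noise, n_clusters) {
  grid <- design$ac50_grid
  if (n_clusters > length(grid)) {
    stop("more clusters than AC50 grid values")
  }
  means <- grid[sample.int(length(grid), n_clusters, replace = FALSE)]
  lapply(seq_len(n_clusters), function(k) {
    mu_rmax <- stats::runif(1, 3 * noise$sigma_noise_band,
                            noise$response_range)
    rmax <- stats::rnorm(1, mu_rmax, sqrt(noise$mse))
    h <- abs(stats::rnorm(1, 1, 3))
    ac50 <- stats::rnorm(1, means[k], design$ac50_sd)
    if (stats::runif(1) < design$gainloss_prob) {
      cand <- grid[grid - means[k] >= design$min_separation]
      loss <- if (length(cand)) cand[sample.int(length(cand), 1L)] else 3
      loss <- max(loss, ac50)  # keep the loss phase after the gain phase
      list(model = "gainloss",
           params = gainloss_params(rmax, max(h, 1e-6), ac50, loss),
           mean_log10_ac50 = means[k], mu_rmax = mu_rmax)
    } else {
      list(model = "hill",
           params = hill_params(rmax, max(h, 1e-6), ac50),
           mean_log10_ac50 = means[k], mu_rmax = mu_rmax)
    }
  })
}

#' Simulate one compound's repeats from drawn cluster parameters
#'
#' Every repeat of every cluster gets the cluster's expected curve evaluated
#' at the design concentrations plus independent heteroscedastic noise
#' Normal(0, sd = |E(R)| * CV) per point, so points with zero expected
#' response carry no noise.
#'
#' @param design A [sim_design()].
#' @param structure Output of [sample_cluster_structure()].
#' @param params Output of [sample_cluster_params()].
#' @param noise A [sim_noise()].
#' @param compound_id Identifier for the simulated compound.
#' @return List with `compound` (a [compound_data()]) and `truth` (cluster
#'   membership per repeat plus the generating parameters).
#' @export
simulate_compound <- function(design, structure, params, noise,
                              compound_id = "c1") {
  conc <- design$concentrations
  profiles <- list()
  membership <- integer(0)
  r <- 0L
  for (k in seq_len(structure$n_clusters)) {
    pk <- params[[k]]
    ey <- if (pk$model == "hill") {
      hill_response(conc, pk$params)
    } else {
      gainloss_response(conc, pk$params)
    }
    for (j in seq_len(structure$repeats_per_cluster[k])) {
      r <- r + 1L
      yy <- ey + stats::rnorm(length(ey), 0, abs(ey) * noise$cv)
      profiles[[r]] <- response_profile(
        compound_id, sprintf("r%02d", r), conc, yy)
      membership[r] <- k
    }
  }
  names(membership) <- vapply(profiles, function(p) p$repeat_id,
                              character(1))
  list(compound = compound_data(profiles),
       truth = list(compound_id = compound_id,
                    n_clusters = structure$n_clusters,
                    membership = membership, clusters = params))
}

#' Simulate a full clustering-error study
#'
#' Compounds are generated until `design$n_compounds` pass the
#' detectability screen (at least one response strictly outside the +/- 3
#' sigma noise band of the simulated assay); ground truth is recorded for
#' every emitted compound. An acceptance rate below 1e-3 aborts with a
#' configuration error.
#'
#' @param design A [sim_design()].
#' @param noise A [sim_noise()].
#' @param seed Optional integer seed.
#' @return List with `study` (an [assay_study()] carrying the known noise
#'   band) and `truth` (named list of per-compound truth records).
#' @export
simulate_study <- function(design, noise, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  band <- noise_band(noise$sigma_noise_band, 3)
  compounds <- vector("list", design$n_compounds)
  truth <- vector("list", design$n_compounds)
  emitted <- 0L
  attempts <- 0L
  while (emitted < design$n_compounds) {
    attempts <- attempts + 1L
    if (attempts > 10000L && emitted / attempts < 1e-3) {
      stop("simulation acceptance rate below 1e-3: ",
           "noise band too wide for the response range")
    }
    cid <- sprintf("c%05d", emitted + 1L)
    st <- sample_cluster_structure(design)
    pars <- sample_cluster_params(design, noise, st$n_clusters)
    sim <- simulate_compound(design, st, pars, noise, cid)
    outside <- any(vapply(sim$compound$profiles, function(p) {
      any(p$responses > band$upper | p$responses < band$lower)
    }, logical(1)))
    if (!outside) next
    emitted <- emitted + 1L
    compounds[[emitted]] <- sim$compound
    truth[[emitted]] <- sim$truth
  }
  names(truth) <- vapply(truth, function(t) t$compound_id, character(1))
  list(study = assay_study(compounds, noise_band = band,
                           provenance = list(generator = "simulate_study")),
       truth = truth)
}

#' Simulate a potency-estimation study
#'
#' The single-cluster setting used to evaluate AC50 estimators: every
#' compound is `n_profiles` Hill curves with identical true parameters
#' (slope 1) on 15 log10-spaced concentrations from 1e-4 to 100 micromolar,
#' plus homoscedastic Normal(0, sd = sigma) noise. True AC50 0.001
#' micromolar shows the upper plateau only, 0.1 both plateaus, 10 the lower
#' plateau only, within the tested range.
#'
#' @param true_ac50 True AC50 in micromolar (typically 0.001, 0.1 or 10).
#' @param rmax True maximal response (typically 25, 50 or 100).
#' @param n_profiles Profiles per compound (typically 3, 6, 9 or 12).
#' @param sigma Residual sd in percent (typically 5 or 10).
#' @param n_compounds Number of simulated compounds (default 2000).
#' @param seed Optional integer seed.
#' @return List with `study` and `truth` (a data frame with one row per
#'   compound: true log10 AC50, rmax, n_profiles, sigma).
#' @export
simulate_estimation_study <- function(true_ac50 = 0.1, rmax = 100,
                                      n_profiles = 3, sigma = 5,
                                      n_compounds = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conc <- 10^seq(-4, 2, length.out = 15)
  ey <- hill_response(conc, hill_params(rmax, 1, log10(true_ac50)))
  compounds <- vector("list", n_compounds)
  for (i in seq_len(n_compounds)) {
    cid <- sprintf("c%05d", i)
    profiles <- lapply(seq_len(n_profiles), function(j) {
      response_profile(cid, sprintf("r%02d", j), conc,
                       ey + stats::rnorm(length(ey), 0, sigma))
    })
    compounds[[i]] <- compound_data(profiles)
  }
  truth <- data.frame(
    compound_id = vapply(compounds, function(cd) cd$compound_id,
                         character(1)),
    true_log10_ac50 = log10(true_ac50), rmax = rmax,
    n_profiles = as.integer(n_profiles), sigma = sigma,
    stringsAsFactors = FALSE)
  list(study = assay_study(compounds,
                           provenance = list(
                             generator = "simulate_estimation_study")),
       truth = truth)
}
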