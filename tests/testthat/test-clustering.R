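test_that("neighbor_split cuts exactly the significant adjacent gaps", {
  means <- c(r1 = 0, r2 = 0.1, r3 = 10)
  counts <- c(r1 = 15, r2 = 15, r3 = 15)
  mse <- 1; df <- 40
  # oracle p-values from the stated pooled two-sample t formula
  p12 <- 2 * pt(-abs(0.1 / sqrt(mse * (2 / 15))), df)
  p23 <- 2 * pt(-abs(9.9 / sqrt(mse * (2 / 15))), df)
  expect_gt(p12, 0.05)
  expect_lt(p23, 0.05)
  part <- neighbor_split(means, mse, df, counts, 0.05,
                         list(c("r1", "r2", "r3")))
  expect_equal(part, list(c("r1", "r2"), "r3"))

  # all means equal: t = 0 everywhere, nothing splits
  part <- neighbor_split(c(r1 = 1, r2 = 1, r3 = 1), mse, df, counts, 0.05,
                         list(c("r1", "r2", "r3")))
  expect_length(part, 1L)

  # alpha = 1 cuts every unequal adjacent pair
  part <- neighbor_split(means, mse, df, counts, 1,
                         list(c("r1", "r2", "r3")))
  expect_length(part, 3L)

  # zero mse: any unequal pair is infinitely significant
  part <- neighbor_split(means, 0, df, counts, 0.05,
                         list(c("r1", "r2", "r3")))
  expect_length(part, 3L)

  # blocks are only refined, never merged across base blocks
  part <- neighbor_split(c(r1 = 0, r2 = 0.001), mse, df, counts, 0.05,
                         list("r1", "r2"))
  expect_length(part, 2L)
})

test_that("subgroup analysis splits repeats that differ only in the top bin", {
  # two repeats identical in bins 1-4, separated in bin 5 by a large gap
  y1 <- c(rep(0, 12), rep(0, 3))
  y2 <- c(rep(0, 12), rep(30, 3))
  noise <- rep(c(-0.5, 0, 0.5), 5)
  profs <- list(make_profile(y1 + noise, rid = "r1"),
                make_profile(y2 + noise, rid = "r2"))
  b <- bin_concentrations(profs, 5)
  a <- fit_two_way_anova(b)
  part <- subgroup_analysis(a, list(c("r1", "r2")), 0.05)
  expect_equal(length(part), 2L)
  # an all-singleton partition cannot be refined further
  part2 <- subgroup_analysis(a, list("r1", "r2"), 0.05)
  expect_equal(length(part2), 2L)
})

test_that("flat curves make subgroup and overall-mean splits agree", {
  set.seed(12)
  profs <- lapply(1:4, function(j) {
    make_profile(rnorm(15, mean = c(0, 0, 8, 8)[j], sd = 0.5),
                 rid = paste0("r", j))
  })
  a <- fit_two_way_anova(bin_concentrations(profs, 5))
  base <- list(paste0("r", 1:4))
  overall <- neighbor_split(a$repeat_means, a$mse, a$df_error,
                            a$repeat_counts, 0.05, base)
  sub <- subgroup_analysis(a, overall, 0.05)
  norm <- function(p) lapply(p, sort)
  expect_equal(norm(sub), norm(overall))
})

test_that("the conclusive t-test separates clusters from the detection limit", {
  band <- noise_band(1, 3)  # limits +/- 3
  # all exceeding means exactly at the limit: t = 0, inconclusive
  expect_false(test_conclusive(rep(3, 5), band))
  # five means far above the limit with tiny spread: conclusive
  expect_true(test_conclusive(c(13, 13.1, 12.9, 13.05, 12.95), band))
  # a single exceeding mean has no degrees of freedom: inconclusive
  expect_false(test_conclusive(c(0, 0, 0, 0, 50), band))
  # all means inside the band: nothing to test
  expect_false(test_conclusive(rep(0, 5), band))
  # below-side exceedance works symmetrically
  expect_true(test_conclusive(-c(13, 13.1, 12.9, 13.05, 12.95), band))
  # oracle check of the one-sided one-sample t on the exceeding means
  bm <- c(4, 5, 6, 3.5, 0)
  d <- bm[bm > 3] - 3
  p <- pt(mean(d) / (sd(d) / sqrt(length(d))), length(d) - 1,
          lower.tail = FALSE)
  expect_equal(test_conclusive(bm, band, alpha = 0.05), p < 0.05)
})

test_that("classification covers exactly the five classes", {
  lab <- function(x) setNames(x, paste0("r", seq_along(x)))
  expect_equal(classify_compound(lab(rep("noise", 3)), list()), "Case2")
  expect_equal(classify_compound(lab(rep("1", 3)), list(`1` = TRUE)),
               "ConclusiveCase1")
  expect_equal(classify_compound(lab(rep("1", 3)), list(`1` = FALSE)),
               "InconclusiveCase1")
  expect_equal(classify_compound(lab(c("1", "2", "2")),
                                 list(`1` = FALSE, `2` = FALSE)),
               "InconclusiveCase3")
  expect_equal(classify_compound(lab(c("1", "2", "2")),
                                 list(`1` = TRUE, `2` = FALSE)),
               "ConclusiveCase3")
  # a single active cluster plus noise repeats is Case 3, not Case 1
  expect_equal(classify_compound(lab(c("1", "1", "noise")),
                                 list(`1` = TRUE)), "ConclusiveCase3")
  expect_equal(classify_compound(lab(c("1", "1", "noise")),
                                 list(`1` = FALSE)), "InconclusiveCase3")
})

test_that("casanova handles the degenerate compound sizes", {
  band <- noise_band(1, 3)
  # all repeats within noise: Case 2
  cd <- compound_data(lapply(1:3, function(j) {
    make_profile(rep(0, 15), rid = paste0("r", j))
  }))
  expect_equal(casanova(cd, band)$case_class, "Case2")
  # a single active repeat becomes its own cluster without an ANOVA
  cd <- compound_data(list(make_profile(seq(0, 60, length.out = 15))))
  a <- casanova(cd, band)
  expect_equal(unname(a$labels), "1")
  expect_null(a$evidence)
  expect_equal(a$case_class, "ConclusiveCase1")
  expect_error(casanova(structure(list(compound_id = "x",
                                       profiles = list()),
                                  class = "compound_data"), band),
               "no profiles")
})

test_that("a clean single cluster stays together and is conclusive", {
  set.seed(21)
  band <- noise_band(2, 3)
  cd <- make_hill_compound("c1", list(hill_params(80, 1, -1)), 12L, sd = 3)
  a <- casanova(cd, band)
  expect_equal(a$case_class, "ConclusiveCase1")
  expect_equal(length(unique(a$labels)), 1L)
})

test_that("disparate clusters separate into a conclusive Case 3", {
  set.seed(22)
  band <- noise_band(2, 3)
  cd <- make_hill_compound(
    "c1", list(hill_params(90, 1, -2), hill_params(40, 1, 0),
               hill_params(1, 1, 0)), c(9L, 3L, 4L), sd = 2)
  a <- casanova(cd, band)
  expect_equal(a$case_class, "ConclusiveCase3")
  expect_gte(length(a$conclusive), 2L)
  expect_true(any(a$labels == "noise"))
  # the high-response cluster is labeled "1" and kept intact
  high <- names(a$labels)[a$labels == "1"]
  expect_setequal(high, paste0("r", sprintf("%02d", 1:9)))
})

test_that("alpha extremes behave like the threshold sweep endpoints", {
  set.seed(23)
  band <- noise_band(2, 3)
  cd <- make_hill_compound(
    "c1", list(hill_params(85, 1, -2), hill_params(45, 1.2, 0)),
    c(4L, 4L), sd = 3)
  a0 <- casanova(cd, band, analysis_config(alpha = 0))
  active0 <- setdiff(unique(a0$labels), "noise")
  expect_length(active0, 1L)
  a1 <- casanova(cd, band, analysis_config(alpha = 1))
  active1 <- setdiff(unique(a1$labels), "noise")
  expect_length(active1, sum(a1$labels != "noise"))
})

test_that("partitions are invariant to repeat relabeling", {
  set.seed(24)
  band <- noise_band(2, 3)
  ys <- lapply(1:6, function(j) {
    hill_response(conc15, hill_params(c(80, 80, 80, 30, 30, 30)[j], 1,
                                      -1)) + rnorm(15, 0, 3)
  })
  cd1 <- compound_data(lapply(1:6, function(j) {
    make_profile(ys[[j]], rid = paste0("r", j))
  }))
  perm <- c(4, 2, 6, 1, 5, 3)
  cd2 <- compound_data(lapply(1:6, function(j) {
    make_profile(ys[[j]], rid = paste0("r", perm[j]))
  }))
  a1 <- casanova(cd1, band)
  a2 <- casanova(cd2, band)
  # same repeats grouped together under both labelings
  part1 <- split(names(a1$labels), a1$labels)
  part2 <- split(paste0("r", match(as.integer(sub("r", "", names(a2$labels))),
                                   perm)), a2$labels)
  norm <- function(p) unname(lapply(p, sort))
  expect_setequal(norm(part1), norm(part2))
  expect_equal(a1$case_class, a2$case_class)
})

test_that("the final partition refines the overall-mean split and alpha is monotone", {
  set.seed(25)
  band <- noise_band(2, 3)
  for (i in 1:8) {
    k <- sample(2:3, 1)
    params <- lapply(seq_len(k), function(j) {
      hill_params(runif(1, 10, 90), abs(rnorm(1, 1, 1)) + 0.2,
                  runif(1, -3, 1))
    })
    cd <- make_hill_compound("c1", params, sample(3:5, k, replace = TRUE),
                             sd = 3)
    parts <- partition_repeats(cd, band)
    if (length(parts$active) < 2) next
    b <- bin_concentrations(parts$active, 5)
    an <- fit_two_way_anova(b)
    base <- list(b$repeat_ids)
    overall <- neighbor_split(an$repeat_means, an$mse, an$df_error,
                              an$repeat_counts, 0.05, base)
    refined <- subgroup_analysis(an, overall, 0.05)
    # every refined block sits inside one overall block
    for (blk in refined) {
      holder <- vapply(overall, function(o) all(blk %in% o), logical(1))
      expect_equal(sum(holder), 1L)
    }
    # lowering alpha never increases the cluster count
    n_hi <- length(subgroup_analysis(an, neighbor_split(
      an$repeat_means, an$mse, an$df_error, an$repeat_counts, 0.05, base),
      0.05))
    n_lo <- length(subgroup_analysis(an, neighbor_split(
      an$repeat_means, an$mse, an$df_error, an$repeat_counts, 0.01, base),
      0.01))
    expect_lte(n_lo, n_hi)
  }
})
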