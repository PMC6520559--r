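# shared fixture builders; all fixtures are generated in code

conc15 <- 10^seq(-4, 2, length.out = 15)

make_profile <- function(responses, cid = "c1", rid = "r1",
                         conc = conc15[seq_along(responses)]) {
  response_profile(cid, rid, conc, responses)
}

# a compound whose repeats follow given Hill params plus iid noise
make_hill_compound <- function(cid, params_list, reps_per_cluster,
                               sd = 0, conc = conc15) {
  profiles <- list()
  r <- 0L
  for (k in seq_along(params_list)) {
    ey <- hill_response(conc, params_list[[k]])
    for (j in seq_len(reps_per_cluster[k])) {
      r <- r + 1L
      profiles[[r]] <- response_profile(
        cid, sprintf("r%02d", r), conc, ey + rnorm(length(conc), 0, sd))
    }
  }
  compound_data(profiles)
}

# long-table data frame for io tests
study_to_df <- function(study) {
  do.call(rbind, lapply(study$compounds, function(cd) {
    do.call(rbind, lapply(cd$profiles, function(p) {
      data.frame(compound_id = p$compound_id, repeat_id = p$repeat_id,
                 concentration = p$concentrations, response = p$responses,
                 stringsAsFactors = FALSE)
    }))
  }))
}

write_df_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# tiny deterministic study: 2 compounds, 3 repeats each
tiny_study <- function(seed = 1, sd = 3) {
  set.seed(seed)
  cds <- list(
    make_hill_compound("cA", list(hill_params(80, 1, -1)), 3L, sd = sd),
    make_hill_compound("cB", list(hill_params(60, 1, 0),
                                  hill_params(20, 1, -2)), c(2L, 1L),
                       sd = sd))
  assay_study(cds)
}
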