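test_that("background correction subtracts control turnover", {
  expect_equal(net_methane(3.52, 0.66), 2.86)
  expect_equal(net_methane(1.93, 0.66), 1.27)
  expect_equal(net_methane(0.66, 0.66), 0)
  expect_equal(net_sulfate(2.756, 0.096), 2.66)
  expect_equal(net_sulfate(0.096, 0.096), 0)
  expect_equal(net_sulfate(0.176, 0.096), 0.08)
  expect_warning(net_methane(0.5, 0.66), "negative net methane")
  expect_warning(net_sulfate(0.05, 0.096), "negative net sulfate")
  expect_error(net_methane(-1, 0.66), "non-negative")
})

test_that("combined ratio and carbon recovery follow the theoretical yield", {
  expect_equal(round(combined_ratio(2.71, 0.19, 0.29), 1), 10)
  expect_equal(combined_ratio(12.25, 0, 1), 12.25)
  expect_equal(combined_ratio(0.5, 0.5, 1), 1)
  expect_error(combined_ratio(1, 1, 0), "positive")

  expect_equal(round(carbon_recovery(11.23), 1), 91.7)
  expect_equal(carbon_recovery(12.25), 100)
  expect_equal(round(carbon_recovery(12.37), 1), 101)
})

test_that("pathway contributions are alkane-normalised and sum to recovery", {
  ct <- pathway_contributions(1.27, 2.66, 0.33)
  expect_equal(round(ct$E_M, 1), 31.4)
  expect_equal(round(ct$E_S, 1), 65.8)
  h <- c(0.1, 0.27, 1)
  pure_m <- pathway_contributions(12.25 * h, 0, h)
  expect_equal(pure_m$E_M, rep(100, 3))
  expect_equal(pure_m$E_S, rep(0, 3))
  pure_s <- pathway_contributions(0, 12.25 * h, h)
  expect_equal(pure_s$E_S, rep(100, 3))
  expect_error(pathway_contributions(1, 1, 0), "positive")
})

test_that("electron-flow split partitions total product into percentages", {
  fl <- electron_flow_split(1.27, 2.66)
  expect_equal(round(fl$flow_M, 1), 32.3)
  expect_equal(round(fl$flow_S, 1), 67.7)
  expect_equal(unlist(electron_flow_split(1, 1)),
               c(flow_M = 50, flow_S = 50))
  expect_equal(unlist(electron_flow_split(5, 0)),
               c(flow_M = 100, flow_S = 0))
  expect_error(electron_flow_split(0, 0), "undefined")
})

test_that("S/M ratio matches hand arithmetic and rejects M = 0", {
  expect_equal(round(sm_ratio(1.27, 2.66), 3), 2.094)
  expect_equal(round(sm_ratio(2.86, 0.08), 4), 0.028)
  expect_equal(sm_ratio(3, 0), 0)
  expect_error(sm_ratio(0, 1), "undefined")
})

test_that("partition identities hold to machine precision on random inputs", {
  set.seed(11)
  for (i in 1:200) {
    M <- runif(1, 0.1, 4)
    S <- runif(1, 0, 3)
    hex <- runif(1, 0.05, 0.4)
    ct <- pathway_contributions(M, S, hex)
    rec <- carbon_recovery(combined_ratio(M, S, hex))
    expect_equal(ct$E_M + ct$E_S, rec, tolerance = 1e-12)

    fl <- electron_flow_split(M, S)
    r1 <- sm_ratio(M, S)
    expect_equal(r1, ct$E_S / ct$E_M, tolerance = 1e-12)
    expect_equal(r1, fl$flow_S / fl$flow_M, tolerance = 1e-12)
    expect_equal(fl$flow_M + fl$flow_S, 100, tolerance = 1e-12)
  }
})

test_that("treatment summaries are replicate-first and linear stats commute", {
  bal <- data.frame(treatment_id = "a", initial_sulfate_mM = 0.5,
                    replicate_id = c("r1", "r2"),
                    combined_ratio = c(10.0, 10.12))
  s <- summarize_treatment(bal, stats = "combined_ratio")
  expect_equal(s$combined_ratio_mean, 10.06)
  expect_equal(s$combined_ratio_se,
               sd(c(10, 10.12)) / sqrt(2))

  one <- summarize_treatment(bal[1, ], stats = "combined_ratio")
  expect_equal(one$combined_ratio_mean, 10)
  expect_true(is.na(one$combined_ratio_se))

  # recovery is a linear transform of the ratio, so means commute ...
  bal$recovery <- carbon_recovery(bal$combined_ratio)
  s2 <- summarize_treatment(bal, stats = c("combined_ratio", "recovery"))
  expect_equal(s2$recovery_mean,
               carbon_recovery(s2$combined_ratio_mean), tolerance = 1e-12)

  # ... but replicate-first S/M means are NOT the ratio of treatment means:
  # the distinction explains why printed treatment means cannot be recombined
  # (e.g. mean ratio 11.23 vs means-arithmetic 10.89 at 0.5 mM sulfate).
  bal2 <- data.frame(treatment_id = "a", initial_sulfate_mM = 0.5,
                     replicate_id = c("r1", "r2"),
                     M = c(2.0, 3.0), S = c(0.2, 0.1))
  bal2$sm_ratio <- sm_ratio(bal2$M, bal2$S)
  s3 <- summarize_treatment(bal2, stats = c("M", "S", "sm_ratio"))
  expect_false(isTRUE(all.equal(s3$sm_ratio_mean,
                                s3$S_mean / s3$M_mean)))
})

test_that("endpoint balances round-trip the generator's recovery target", {
  cfg <- noise_free_config(replicates = 2, recovery_target = 88)
  obs <- quiet_generate(cfg)
  bal <- suppressWarnings(replicate_balances(
    obs, alkane_total = cfg$hexadecane_total,
    background_methane = cfg$background_methane,
    background_sulfate = cfg$background_sulfate,
    liquid_volume = cfg$liquid_volume))
  expect_equal(bal$recovery, rep(88, nrow(bal)), tolerance = 1e-9)
  expect_equal(bal$E_M + bal$E_S, bal$recovery, tolerance = 1e-9)
})

test_that("replicate_balances validates schema and flags bad data", {
  cfg <- noise_free_config(replicates = 1)
  obs <- quiet_generate(cfg)
  expect_error(replicate_balances(obs[, setdiff(names(obs), "sulfate_mmol")]),
               "sulfate_mmol")
  obs2 <- obs[obs$treatment_id == "S25", ]
  obs2$methane_mmol[5] <- obs2$methane_mmol[8]  # break monotonicity
  expect_warning(replicate_balances(obs2), "non-monotone")
})
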