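test_that("seeded generation is bit-reproducible and seed-sensitive", {
  cfg <- simulation_config(replicates = 2, seed = 42)
  a <- quiet_generate(cfg)
  b <- quiet_generate(cfg)
  expect_identical(a, b)
  c <- quiet_generate(simulation_config(replicates = 2, seed = 43))
  expect_false(identical(a, c))
})

test_that("configuration validation rejects invalid parameterisations", {
  expect_error(simulation_config(treatments = numeric(0)), "positive")
  expect_error(simulation_config(replicates = 0), ">= 1")
  expect_error(simulation_config(f_h_start = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(recovery_target = -5), "positive")
  expect_error(simulation_config(noise_sd = list(methane = -1)), "noise_sd")
  expect_error(simulation_config(consumed_fraction = 0), "\\(0, 1\\]")
  expect_error(generate_experiment(list()), "simulation_config")
})

test_that("noise-free mass balance closes at every sampled day", {
  cfg <- uncapped_config(replicates = 1, recovery_target = 95)
  obs <- generate_experiment(cfg)
  Y <- combined_yield("C16H34")
  for (tr in split(obs, obs$treatment_id)) {
    M <- tr$methane_mmol - cfg$background_methane
    S <- tr$initial_sulfate_mM[1] * cfg$liquid_volume - tr$sulfate_mmol -
      cfg$background_sulfate
    # products at the endpoint equal the recovery fraction of the yield on
    # the alkane actually consumed (measured via the residual)
    consumed <- cfg$hexadecane_total - tr$hexadecane_mmol[nrow(tr)]
    expect_equal(M[nrow(tr)] + S[nrow(tr)],
                 cfg$recovery_target / 100 * Y * consumed,
                 tolerance = 1e-9)
    # and the partition ratio is constant over the whole time course
    expect_lt(diff(range(S / M)), 1e-10)
  }
})

test_that("sulfate-limited treatments are capped with a warning", {
  cfg <- noise_free_config(replicates = 1)
  w <- testthat::capture_warnings(obs <- generate_experiment(cfg))
  expect_true(any(grepl("exceeds supply", w)))
  low <- obs[obs$treatment_id == "S0.5", ]
  expect_true(all(low$sulfate_mmol >= 0))
  # sulfate reduced never exceeds what was supplied
  S <- low$initial_sulfate_mM[1] * cfg$liquid_volume - low$sulfate_mmol
  expect_true(all(S <= low$initial_sulfate_mM[1] * cfg$liquid_volume + 1e-12))
  # recovery is preserved despite the cap (remainder routed to methane)
  bal <- suppressWarnings(replicate_balances(
    obs, background_methane = cfg$background_methane,
    background_sulfate = cfg$background_sulfate,
    liquid_volume = cfg$liquid_volume))
  expect_equal(bal$recovery, rep(cfg$recovery_target, nrow(bal)),
               tolerance = 1e-9)
})

test_that("isotope bookkeeping conserves carbon-weighted delta exactly", {
  tf <- seq(0, 400, by = 1)
  M <- 2.5 * stats::plogis(0.4 * (tf - 250) / 30.4375)
  C <- 0.3 * M
  P0 <- 4
  iso <- isotope_trajectory(M, C, f_h = 0.6, epsilon_h = 45,
                            delta_substrate = -30, co2_pool_initial = P0)
  n <- length(tf)
  pool <- P0 + C[n]
  weighted <- (M[n] * iso$d13ch4[n] + pool * iso$d13co2[n]) / (M[n] + pool)
  expect_equal(weighted, -30, tolerance = 1e-6)
})

test_that("isotope trajectory limits behave like single-source systems", {
  tf <- seq(0, 300, by = 1)
  M <- 2 * stats::plogis(0.4 * (tf - 150) / 30.4375)
  C <- 0.3 * M

  # pure aceticlastic: methane at the substrate delta, alpha constant
  iso0 <- isotope_trajectory(M, C, f_h = 0, epsilon_h = 45,
                             delta_substrate = -30, co2_pool_initial = 4)
  expect_equal(iso0$d13ch4, rep(-30, length(tf)), tolerance = 1e-9)
  a0 <- alpha_app(iso0$d13co2, iso0$d13ch4)
  expect_lt(diff(range(a0)), 1e-9)

  # pure hydrogenotrophic with an effectively infinite pool (no feedback):
  # cumulative methane sits at pool delta minus the enrichment factor
  iso1 <- isotope_trajectory(M, C, f_h = 1, epsilon_h = 45,
                             delta_substrate = -30, co2_pool_initial = 1e9)
  expect_equal(iso1$d13ch4[length(tf)], -30 - 45, tolerance = 1e-4)
})

test_that("a rising hydrogenotrophic fraction drives alpha up to a plateau", {
  run_alpha <- function(f_h_end, step = 1) {
    tf <- seq(0, 420, by = step)
    M <- 2.5 * stats::plogis(0.4 * (tf - 250) / 30.4375)
    C <- 0.3 * M
    f_h <- 0.3 + (f_h_end - 0.3) * pmin(pmax((tf - 120) / 300, 0), 1)
    iso <- isotope_trajectory(M, C, f_h, epsilon_h = 45,
                              delta_substrate = -30, co2_pool_initial = 4)
    alpha_app(iso$d13co2, iso$d13ch4)
  }
  a_hi <- run_alpha(0.8)
  expect_true(all(diff(a_hi) > -1e-12))
  # flattening toward a plateau: the rise rate peaks mid-incubation (around
  # the logistic midpoint) and has decayed well below the peak by the end
  n <- length(a_hi)
  rate <- diff(a_hi)
  expect_lt(which.max(rate), 300)
  expect_lt(rate[n - 1], 0.5 * max(rate))
  # plateau ordering follows the final hydrogenotrophic fraction
  a_lo <- run_alpha(0.5)
  expect_lt(a_lo[n], a_hi[n])
  # oracle: the same model at 10x time resolution agrees closely
  a_fine <- run_alpha(0.8, step = 0.1)
  expect_equal(a_hi[n], a_fine[length(a_fine)], tolerance = 1e-3)

  expect_error(isotope_trajectory(c(1, 2), c(1, 2), f_h = 1.5,
                                  epsilon_h = 45, delta_substrate = -30,
                                  co2_pool_initial = 4), "\\[0, 1\\]")
})

test_that("refining the sampling day grid leaves noise-free outputs unchanged", {
  coarse <- uncapped_config(replicates = 1, day_grid = seq(0, 420, by = 30))
  fine <- uncapped_config(replicates = 1, day_grid = seq(0, 420, by = 15))
  a <- generate_experiment(coarse)
  b <- generate_experiment(fine)
  b_common <- b[b$day %in% a$day, ]
  for (col in c("methane_mmol", "sulfate_mmol", "d13ch4_permil",
                "d13co2_permil"))
    expect_equal(b_common[[col]], a[[col]], tolerance = 1e-9)
})

test_that("generated tables carry the full observation schema", {
  cfg <- noise_free_config(replicates = 2)
  obs <- quiet_generate(cfg)
  expect_identical(nrow(obs),
                   length(cfg$treatments) * 2L * length(cfg$day_grid))
  expect_true(all(c("treatment_id", "initial_sulfate_mM", "replicate_id",
                    "day", "methane_mmol", "sulfate_mmol", "d13ch4_permil",
                    "d13co2_permil", "hexadecane_mmol") %in% names(obs)))
  # residual alkane only at the endpoint
  last <- max(obs$day)
  expect_true(all(is.na(obs$hexadecane_mmol[obs$day != last])))
  expect_true(all(!is.na(obs$hexadecane_mmol[obs$day == last])))
  expect_true(all(obs$methane_mmol >= 0) && all(obs$sulfate_mmol >= 0))
  # validates cleanly
  expect_silent(validate_observations(obs))
})
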