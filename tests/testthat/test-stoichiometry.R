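# Independent oracle: solve the element-balance linear system directly.
# Methanogenic unknowns (ch4, co2, h2o_consumed):
#   C: ch4 + co2 = n;  H: 4 ch4 - 2 h2o = 2n + 2;  O: 2 co2 - h2o = 0
oracle_methanogenic <- function(n) {
  A <- rbind(c(1, 1, 0), c(4, 0, -2), c(0, 2, -1))
  stats::setNames(as.numeric(solve(A, c(n, 2 * n + 2, 0))),
                  c("ch4", "co2", "h2o_consumed"))
}
# Sulfidogenic unknowns (so4, h_plus, h2o_produced), with h2s = so4, co2 = n:
#   O: 4 so4 - h2o = 2n... rearranged below;  H; charge.
oracle_sulfidogenic <- function(n) {
  A <- rbind(c(-4, 0, 1),   # O: 2n + h2o - 4 so4 = 0
             c(2, -1, 2),   # H: 2 h2s + 2 h2o - h_plus = 2n + 2
             c(-2, 1, 0))   # charge: h_plus - 2 so4 = 0
  stats::setNames(as.numeric(solve(A, c(-2 * n, 2 * n + 2, 0))),
                  c("so4", "h_plus", "h2o_produced"))
}

test_that("alkane formulas parse and validate the 2n+2 rule", {
  a <- alkane_formula("C16H34")
  expect_identical(c(a$n_carbon, a$n_hydrogen), c(16L, 34L))
  expect_identical(alkane_formula("CH4")$n_carbon, 1L)
  expect_identical(alkane_formula("C1H4")$n_hydrogen, 4L)
  expect_error(alkane_formula("C16H32"), "not a saturated")
  expect_error(alkane_formula("C2H5OH"), "malformed")
  expect_error(alkane_formula("H4"), "malformed")
  expect_error(alkane_formula("C0H2"), "at least one carbon")
})

test_that("hexadecane oxidation coefficients match the balanced equations", {
  m <- methanogenic_yields("C16H34")
  expect_identical(m$ch4_per_alkane, 12.25)
  expect_identical(m$co2_per_alkane, 3.75)
  expect_identical(m$h2o_per_alkane, -7.5)
  expect_identical(m$sulfate_per_alkane, 0)
  expect_identical(m$electron_equivalents, 98)

  s <- sulfidogenic_yields("C16H34")
  expect_identical(s$sulfate_per_alkane, 12.25)
  expect_identical(s$h2s_per_alkane, 12.25)
  expect_identical(s$co2_per_alkane, 16)
  expect_identical(s$h2o_per_alkane, 17)
  expect_identical(s$h_plus_per_alkane, 24.5)
  expect_identical(s$ch4_per_alkane, 0)
  expect_identical(s$electron_equivalents, 98)
})

test_that("small alkanes reproduce hand and oracle solutions", {
  m1 <- methanogenic_yields("CH4")
  expect_identical(c(m1$ch4_per_alkane, m1$co2_per_alkane,
                     m1$h2o_per_alkane), c(1, 0, 0))
  s1 <- sulfidogenic_yields("CH4")
  expect_identical(c(s1$sulfate_per_alkane, s1$co2_per_alkane), c(1, 1))

  m2 <- methanogenic_yields("C2H6")
  expect_identical(c(m2$ch4_per_alkane, m2$co2_per_alkane,
                     m2$h2o_per_alkane), c(1.75, 0.25, -0.5))
  s2 <- sulfidogenic_yields("C2H6")
  expect_identical(s2$sulfate_per_alkane, 1.75)
  expect_identical(s2$electron_equivalents, 14)

  o <- oracle_methanogenic(2)
  expect_equal(m2$ch4_per_alkane, o[["ch4"]])
  expect_equal(m2$co2_per_alkane, o[["co2"]])
  expect_equal(-m2$h2o_per_alkane, o[["h2o_consumed"]])
})

test_that("closed forms agree with the element-balance solver for n = 1..40", {
  for (n in 1:40) {
    f <- alkane_formula(sprintf("C%dH%d", n, 2 * n + 2))
    m <- methanogenic_yields(f)
    s <- sulfidogenic_yields(f)

    om <- oracle_methanogenic(n)
    expect_equal(m$ch4_per_alkane, om[["ch4"]], tolerance = 1e-14)
    expect_equal(m$co2_per_alkane, om[["co2"]], tolerance = 1e-14)
    expect_equal(-m$h2o_per_alkane, om[["h2o_consumed"]], tolerance = 1e-14)

    os <- oracle_sulfidogenic(n)
    expect_equal(s$sulfate_per_alkane, os[["so4"]], tolerance = 1e-14)
    expect_equal(s$h_plus_per_alkane, os[["h_plus"]], tolerance = 1e-14)
    expect_equal(s$h2o_per_alkane, os[["h2o_produced"]], tolerance = 1e-14)

    # the two pathways share the combined yield and electron count
    expect_identical(m$ch4_per_alkane, s$sulfate_per_alkane)
    expect_identical(m$ch4_per_alkane, (3 * n + 1) / 4)
    expect_identical(8 * m$ch4_per_alkane, 6 * n + 2)
    expect_identical(m$electron_equivalents, s$electron_equivalents)

    # element and charge balances close exactly (integer arithmetic)
    expect_identical(unname(element_balance(m)), rep(0, 5))
    expect_identical(unname(element_balance(s)), rep(0, 5))
  }
})

test_that("sulfate demand converts alkane amounts to required concentrations", {
  expect_equal(sulfate_demand(0.34, alkane_formula("C16H34"), 0.2), 20.825)
  expect_equal(round(sulfate_demand(0.34)), 21)
  expect_equal(sulfate_demand(1, alkane_formula("C16H34"), 1), 12.25)
  expect_equal(sulfate_demand(2, alkane_formula("C2H6"), 0.5), 7)
  expect_error(sulfate_demand(0.34, liquid_volume = 0), "positive")
  expect_error(sulfate_demand(-1), "positive")
})

test_that("a 100 ul hexadecane dose is about 0.34 mmol", {
  expect_equal(round(alkane_dose_mmol(100), 2), 0.34)
  expect_equal(round(alkane_molar_mass("C16H34"), 1), 226.4)
})

test_that("stoich_table returns one row per pathway", {
  tab <- stoich_table("C16H34")
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$pathway, c("methanogenic", "sulfidogenic"))
  expect_identical(tab$ch4_per_alkane[1], tab$sulfate_per_alkane[2])
})
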