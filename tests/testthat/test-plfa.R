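test_that("PLFA nomenclature parses and canonicalizes", {
  cases <- list(
    list(raw = "16:0", c = 16, db = 0),
    list(raw = "a15:0", c = 15, db = 0, pref = "a"),
    list(raw = "i15:0", c = 15, db = 0, pref = "i"),
    list(raw = "cy17:0", c = 17, db = 0, pref = "cy"),
    list(raw = "10Me16:0", c = 17, db = 0, pref = "10Me"),
    list(raw = "C18:1ω7", c = 18, db = 1, omega = 7),
    list(raw = "18:1w7c", c = 18, db = 1, omega = 7))
  for (cs in cases) {
    p <- parse_plfa_name(cs$raw)
    expect_equal(p$n_carbons, cs$c, info = cs$raw)
    expect_equal(p$n_double_bonds, cs$db, info = cs$raw)
    if (!is.null(cs$pref)) expect_true(cs$pref %in% p$prefixes, info = cs$raw)
    if (!is.null(cs$omega)) expect_equal(p$omega_position, cs$omega)
  }
  # canonical form is idempotent and unifies spellings
  expect_identical(format(parse_plfa_name("C18:1ω7")),
                   format(parse_plfa_name("18:1w7")))
  expect_identical(format(parse_plfa_name(format(parse_plfa_name("10Me16:0")))),
                   "10Me16:0")
  expect_error(parse_plfa_name("not-a-lipid"), "unparseable")
  expect_error(parse_plfa_name("8:0"), "carbon count")
  expect_error(parse_plfa_name("16:0w7"), "omega")
})

test_that("hydrogen inventory follows CnH2nO2 minus unsaturations", {
  expect_equal(plfa_hydrogen_count("16:0"), 32)  # palmitic C16H32O2
  expect_equal(plfa_hydrogen_count("18:1w7"), 34) # oleic-type C18H34O2
  expect_equal(plfa_hydrogen_count("cy17:0"), 32) # ring costs 2 H
  expect_equal(plfa_hydrogen_count("10Me16:0"), 34) # C17 saturated branched
})

test_that("carbon produced is the concentration change times carbon count", {
  m0 <- plfa_measurement("16:0", "T0", 10, -30, -150)
  m1 <- plfa_measurement("16:0", "Tend", 30, 200, 500)
  expect_equal(carbon_produced(m0, m1), 20 * 16)
  expect_equal(carbon_produced(m0, plfa_measurement("16:0", "Tend", 10, -30, -150)), 0)
  expect_lt(carbon_produced(m0, plfa_measurement("16:0", "Tend", 5, -30, -150)), 0)
  expect_error(carbon_produced(m0, plfa_measurement("18:0", "Tend", 30, 0, 0)),
               "pairing")
})

test_that("incorporation rate = deltaF * C_produced / duration, with clamping", {
  k <- sip_constants()
  m0 <- plfa_measurement("16:0", "T0", 100, -30, -150)
  # deltaF = 0 -> rate 0
  m_same <- plfa_measurement("16:0", "Tend", 150, -30, -150)
  expect_equal(incorporation_rate(m0, m_same, "13C", 84)$rate, 0)
  # engineered deltaF: pick Tend delta giving deltaF = 0.01 exactly
  f0 <- delta_to_atom_fraction(delta_value(-30, "C"), k)
  r1 <- atom_fraction_to_ratio(f0 + 0.01)
  d1 <- (r1 / k$r_vpdb_13c - 1) * 1000
  m1 <- plfa_measurement("16:0", "Tend", 100 + 840 / 16, d1, -150)
  rate <- incorporation_rate(m0, m1, "13C", 84)
  expect_equal(rate$c_produced, 840)
  expect_equal(rate$rate, 0.01 * 840 / 84, tolerance = 1e-9) # 0.1 pmol/L/day
  # clamping of negative production
  m_loss <- plfa_measurement("16:0", "Tend", 90, d1, -150)
  r_cl <- incorporation_rate(m0, m_loss, "13C", 84, clamp = TRUE)
  expect_equal(r_cl$rate, 0)
  expect_true(r_cl$clamped)
  r_raw <- incorporation_rate(m0, m_loss, "13C", 84, clamp = FALSE)
  expect_lt(r_raw$rate, 0)
  expect_error(incorporation_rate(m0, m1, "13C", 0), "invalid duration")
})

test_that("rate is linear in deltaF and C_produced; halving duration doubles it", {
  k <- sip_constants()
  f0 <- delta_to_atom_fraction(delta_value(-30, "C"), k)
  mk <- function(df, conc_gain) {
    d <- (atom_fraction_to_ratio(f0 + df) / k$r_vpdb_13c - 1) * 1000
    list(plfa_measurement("16:0", "T0", 100, -30, -150),
         plfa_measurement("16:0", "Tend", 100 + conc_gain, d, -150))
  }
  base <- do.call(incorporation_rate, c(mk(0.01, 50), list("13C", 84)))
  dbl_f <- do.call(incorporation_rate, c(mk(0.02, 50), list("13C", 84)))
  dbl_c <- do.call(incorporation_rate, c(mk(0.01, 100), list("13C", 84)))
  half_t <- do.call(incorporation_rate, c(mk(0.01, 50), list("13C", 42)))
  expect_equal(dbl_f$rate / base$rate, 2, tolerance = 1e-9)
  expect_equal(dbl_c$rate / base$rate, 2, tolerance = 1e-9)
  expect_equal(half_t$rate / base$rate, 2, tolerance = 1e-9)
})

test_that("deuterium rate supports both atom-inventory conventions", {
  k <- sip_constants()
  f0 <- delta_to_atom_fraction(delta_value(-150, "H"), k)
  d1 <- (atom_fraction_to_ratio(f0 + 0.05) / k$r_vsmow_d - 1) * 1000
  m0 <- plfa_measurement("16:0", "T0", 100, -30, -150)
  m1 <- plfa_measurement("16:0", "Tend", 110, -30, d1)
  r_c <- incorporation_rate(m0, m1, "D", 84, d_inventory = "carbon")
  r_h <- incorporation_rate(m0, m1, "D", 84, d_inventory = "hydrogen")
  expect_equal(r_c$rate, 0.05 * 10 * 16 / 84, tolerance = 1e-6)
  expect_equal(r_h$rate, 0.05 * 10 * 32 / 84, tolerance = 1e-6)
  expect_equal(r_h$rate / r_c$rate, 32 / 16, tolerance = 1e-9)
})

test_that("Ra/Rt discriminant bands and scale invariance", {
  mk_rate <- function(rate, iso) {
    m0 <- plfa_measurement("16:0", "T0", 100, -30, -150)
    structure(list(name = m0$name, isotope = iso, rate = rate, c_produced = 100,
                   delta_f = 0.01, clamped = FALSE, d_inventory = NA, duration = 84),
              class = "production_rate")
  }
  pools <- list(f = 0.5, d = 0.5)
  tc0 <- ra_rt(mk_rate(0, "13C"), mk_rate(10, "D"), 0.5, 0.5)
  expect_equal(tc0$ra_rt, 0)
  expect_equal(tc0$call, "heterotrophic")
  tc1 <- ra_rt(mk_rate(10, "13C"), mk_rate(10, "D"), 0.5, 0.5)
  expect_equal(tc1$ra_rt, 1)
  expect_equal(tc1$call, "autotrophic")
  tc_mix <- ra_rt(mk_rate(3.5, "13C"), mk_rate(10, "D"), 0.5, 0.5)
  expect_equal(tc_mix$ra_rt, 0.35)
  expect_equal(tc_mix$call, "mixed")
  # invariant to common rescaling of both rates
  tc_scaled <- ra_rt(mk_rate(3.5e3, "13C"), mk_rate(1e4, "D"), 0.5, 0.5)
  expect_equal(tc_scaled$ra_rt, tc_mix$ra_rt, tolerance = 1e-12)
  # pool normalization divides each rate by its source strength
  tc_norm <- ra_rt(mk_rate(1, "13C"), mk_rate(10, "D"), 0.2, 0.8)
  expect_equal(tc_norm$ra_rt, (1 / 0.2) / (10 / 0.8))
  expect_error(ra_rt(mk_rate(1, "13C"), mk_rate(0, "D"), 0.5, 0.5),
               "undefined ratio")
})

test_that("acetogen expectation follows the two-carbon acetyl model", {
  expect_equal(acetogen_expectation(0.5), 0.5)
  expect_equal(acetogen_expectation(1), 0)
  expect_equal(acetogen_expectation(c(0.6, 0.7)), c(0.4, 0.3))
  expect_error(acetogen_expectation(1.2), "\\[0, 1\\]")
})

test_that("trophic classification separates producers on simulated data", {
  pools <- sip_pools()
  het_ratios <- vapply(1:100, function(s) {
    g <- generate_plfa(het_producer, pools, 84, 2, s)
    max(plfa_rate_table(g$measurements, 84, pools)$ra_rt)
  }, numeric(1))
  aut_ratios <- vapply(1:100, function(s) {
    g <- generate_plfa(aut_producer, pools, 84, 2, s)
    min(plfa_rate_table(g$measurements, 84, pools)$ra_rt)
  }, numeric(1))
  expect_gte(mean(het_ratios <= 0.3), 0.95)
  expect_gte(mean(aut_ratios >= 0.8), 0.95)
})

test_that("configured rates are recovered by inversion", {
  pools <- sip_pools()
  mix <- list(list(name = "m", profile = c("16:0" = 0.5, "18:1w7" = 0.5),
                   growth = 50, trophic_mode = 0.5))
  # exact round trip at zero noise
  g0 <- generate_plfa(mix, pools, 84, 0, 1)
  r0 <- plfa_rate_table(g0$measurements, 84, pools)
  tr <- g0$truth$lipids[match(r0$plfa_name, g0$truth$lipids$plfa_name), ]
  expect_equal(r0$rate_13c, tr$rate_13c_true, tolerance = 1e-9)
  expect_equal(r0$rate_d, tr$rate_d_true, tolerance = 1e-9)
  # within 10% relative at 2 permil measurement noise
  errs <- vapply(1:50, function(s) {
    g <- generate_plfa(mix, pools, 84, 2, s)
    r <- plfa_rate_table(g$measurements, 84, pools)
    tr <- g$truth$lipids[match(r$plfa_name, g$truth$lipids$plfa_name), ]
    max(abs(r$rate_13c - tr$rate_13c_true) / tr$rate_13c_true,
        abs(r$rate_d - tr$rate_d_true) / tr$rate_d_true)
  }, numeric(1))
  expect_lt(max(errs), 0.10)
})
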