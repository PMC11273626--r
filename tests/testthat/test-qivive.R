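test_that("FBS-to-albumin conversion is linear through the printed points", {
  expect_equal(albumin_from_fbs(5), 1.15)
  expect_equal(albumin_from_fbs(10), 2.3)
  expect_equal(albumin_from_fbs(0), 0)
  expect_error(albumin_from_fbs(-1), "0, 100")
})

test_that("in-vitro unbound fraction reproduces the worked values", {
  expect_equal(round(fu_invitro(1.15, 42.5, fup = 0.092), 2), 0.79)
  expect_equal(round(fu_invitro(2.3, 42.5, fup = 0.092), 2), 0.65)
  # identity: equal albumin concentrations recover fup exactly
  for (f in c(0.05, 0.092, 0.5, 0.91, 1))
    expect_equal(fu_invitro(42.5, 42.5, fup = f), f, tolerance = 1e-12)
  # less albumin in vitro than in plasma => fu in (fup, 1]
  fu <- fu_invitro(seq(0, 40, by = 5), 42.5, fup = 0.092)
  expect_true(all(fu > 0.092 & fu <= 1))
})

test_that("relative potency factors are BMCL ratios", {
  expect_equal(signif(compute_rpf(0.37, 9.9), 2), 0.037)
  expect_equal(signif(compute_rpf(1.1, 2.3), 2), 0.48)
  expect_equal(compute_rpf(3.3, 3.3), 1.0)
  expect_error(compute_rpf(1, 0), "> 0")
  tb <- rpf_table()
  expect_equal(tb$rpf_rhein, tb$bmcl10_ae / tb$bmcl10_rhein)
  expect_setequal(tb$endpoint,
                  c("hepatotoxicity", "nephrotoxicity", "ros", "nrf2"))
})

test_that("aloe-emodin-equivalent unbound concentration is the weighted sum", {
  parent <- list(bpr = 0.55, fup = 0.092)
  met <- list(bpr = 0.96, fup = 0.91)
  # printed constants, equal blood Cmax of 1 uM, ROS RPF 0.63
  eq <- equivalent_unbound_blood(1, 1, 0.63, parent, met)
  expect_equal(eq, 1 / 0.55 * 0.092 + 1 / 0.96 * 0.91 * 0.63,
               tolerance = 1e-12)
  expect_equal(round(eq, 4), 0.7645)
  # zero metabolite concentration reduces to the parent term
  expect_equal(equivalent_unbound_blood(2, 0, 0.63, parent, met),
               2 / 0.55 * 0.092)
  # zero RPF silences the metabolite regardless of concentration
  expect_equal(equivalent_unbound_blood(2, 100, 0, parent, met),
               2 / 0.55 * 0.092)
  expect_error(equivalent_unbound_blood(1, 1, NA, parent, met), "RPF")
})

test_that("reverse dosimetry inverts the forward simulation", {
  cmp <- compound_defaults("rat")
  m <- build_pbk(species_physiology("rat"), cmp$parent, cmp$metabolite)
  expect_equal(reverse_dosimetry(m, 0, 0.63, "liver")$dose, 0)

  # forward-inverse round trip within 0.5%
  for (d in c(5, 80)) {
    s <- pbk_simulate(m, d, "oral", 24)
    target <- aepbk:::sim_equivalent_cmax(s, 0.63, "liver")
    rd <- reverse_dosimetry(m, target, 0.63, "liver")
    expect_true(rd$converged)
    expect_lt(abs(rd$dose - d) / d, 5e-3)
  }

  # monotone: larger target, larger dose
  targets <- c(0.01, 0.05, 0.2)
  doses <- vapply(targets, function(tg)
    reverse_dosimetry(m, tg, 0.63, "liver")$dose, numeric(1))
  expect_true(all(diff(doses) > 0))

  # unreachable target under a tight dose cap is reported, not extrapolated
  rd_oor <- reverse_dosimetry(m, 1e4, 0.63, "liver", dose_cap = 10)
  expect_true(rd_oor$out_of_range)
  expect_true(is.na(rd_oor$dose))
})

test_that("curve conversion preserves responses and concentration order", {
  cmp <- compound_defaults("rat")
  m <- build_pbk(species_physiology("rat"), cmp$parent, cmp$metabolite)
  curve <- make_hill_curve(cv = 0.05, seed = 3,
                           doses = c(0, 2, 6, 20, 60))
  conv <- convert_curve(curve, assay_fbs = 10, m, 0.63, "liver")
  expect_s3_class(conv, "dose_response_curve")
  # responses carried over unchanged, dose 0 maps to dose 0
  expect_equal(conv$response, curve$response)
  expect_equal(conv$dose[curve$dose == 0], rep(0, sum(curve$dose == 0)))
  # rank order preserved
  map <- attr(conv, "dose_map")
  expect_true(all(diff(map$dose) > 0))
  # the albumin correction used is the 10% FBS one
  expect_equal(round(attr(conv, "fu_invitro"), 2), 0.65)
  # unreachable concentrations are censored, not extrapolated
  conv2 <- convert_curve(curve, 10, m, 0.63, "liver", dose_cap = 1)
  expect_true(any(conv2$censored))
  expect_true(all(is.na(conv2$dose[conv2$censored])))
})
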