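rat_model <- function(...) {
  cmp <- compound_defaults("rat", ...)
  build_pbk(species_physiology("rat"), cmp$parent, cmp$metabolite)
}
human_model <- function() {
  cmp <- compound_defaults("human")
  build_pbk(species_physiology("human"), cmp$parent, cmp$metabolite)
}

test_that("model assembly validates its inputs", {
  cmp <- compound_defaults("rat")
  bad <- cmp$parent
  bad$partition_plasma <- bad$partition_plasma[-1]   # drop liver
  expect_error(build_pbk(species_physiology("rat"), bad, cmp$metabolite),
               "partition coefficient")
  bad2 <- cmp$metabolite
  bad2$fup <- 0
  expect_error(build_pbk(species_physiology("rat"), cmp$parent, bad2))
})

test_that("zero dose yields an identically zero state", {
  s <- pbk_simulate(rat_model(), 0, "oral", 12)
  expect_true(all(s$amounts == 0))
  expect_equal(extract_cmax(s, "parent"), 0)
  expect_equal(extract_cmax(s, "metabolite"), 0)
})

test_that("with unit partitioning and no elimination an IV bolus dilutes into total volume", {
  m <- rat_model()
  p <- m$params
  p[c("PL_p", "PK_p", "PF_p", "PR_p", "PS_p")] <- 1
  p[c("vmax_rhein", "vmax_aeg1", "vmax_aeg2", "vmax_aeg3")] <- 0
  p[c("kb", "gfr_total")] <- 0
  m$params <- p
  s <- pbk_simulate(m, 5, "iv", 24)
  v_tot <- sum(p[c("VL", "VK", "VF", "VR", "VS", "VB")])
  expected <- s$dose_umol / v_tot
  mixed <- s$conc$parent_uM[s$time > 4]
  expect_true(all(abs(mixed - expected) / expected < 1e-3))
  # and the dose is conserved in the body
  expect_lt(abs(s$mass_balance[["parent"]]), 1e-6)
})

test_that("parent and metabolite molar balance closes across doses, routes, species", {
  for (m in list(rat_model(), human_model())) {
    for (sc in list(c(1, 1), c(40, 1), c(300, 1), c(5, 2))) {
      route <- if (sc[2] == 1) "oral" else "iv"
      s <- pbk_simulate(m, sc[1], route, 36)
      expect_lt(abs(s$mass_balance[["parent"]]), 1e-3)
      expect_lt(abs(s$mass_balance[["metabolite"]]), 1e-3)
      expect_gt(min(s$amounts), -1e-9)
    }
  }
})

test_that("single-compartment reduction matches the Bateman closed form", {
  m <- one_compartment_model("rat")
  p <- m$params
  v_tot <- sum(p[c("VL", "VK", "VF", "VR", "VS", "VB")])
  ke <- p[["gfr_total"]] * p[["fup_p"]] / (p[["bpr_p"]] * v_tot)
  dose <- 10
  s <- pbk_simulate(m, dose, "oral", 24, n_out = 2401)
  cmax_sim <- extract_cmax(s, "parent", "blood")
  cmax_ana <- bateman_cmax(s$dose_umol, m$parent$fa, m$parent$ka, ke, v_tot)
  expect_lt(abs(cmax_sim - cmax_ana) / cmax_ana, 5e-3)
  # the whole profile, not just the peak
  idx <- seq(101, 2401, by = 100)
  ana <- bateman_conc(s$time[idx], s$dose_umol, m$parent$fa, m$parent$ka,
                      ke, v_tot)
  expect_true(all(abs(s$conc$parent_uM[idx] - ana) / max(ana) < 5e-3))
})

test_that("adaptive solution agrees with an independent fixed-step RK4", {
  m <- rat_model()
  s <- pbk_simulate(m, 40, "oral", 6)
  rk <- oracle_rk4(m, 40, "oral", 6, h = 1e-3)
  expect_lt(abs(extract_cmax(s, "parent") - rk$cmax_parent) /
              rk$cmax_parent, 5e-3)
  expect_lt(abs(extract_cmax(s, "metabolite") - rk$cmax_metabolite) /
              rk$cmax_metabolite, 5e-3)
  # final-state agreement across all compartments
  fin <- s$amounts[nrow(s$amounts), ]
  scale <- max(abs(rk$final))
  expect_true(all(abs(fin - rk$final) / scale < 5e-3))
})

test_that("Cmax behaves like a dose metric", {
  m <- rat_model()
  # linear regime: doubling a small IV dose doubles Cmax within 1%
  c1 <- extract_cmax(pbk_simulate(m, 0.01, "iv", 24), "parent")
  c2 <- extract_cmax(pbk_simulate(m, 0.02, "iv", 24), "parent")
  expect_lt(abs(c2 / c1 - 2), 0.01)
  # never decreasing in dose (saturable clearance allows superlinearity)
  doses <- c(1, 10, 40, 100, 300)
  cm <- vapply(doses, function(d)
    extract_cmax(pbk_simulate(m, d, "oral", 36), "parent"), numeric(1))
  expect_true(all(diff(cm) > 0))
})

test_that("IV parent blood curve is monotone after mixing; metabolite rises then falls", {
  s <- pbk_simulate(rat_model(), 5, "iv", 12)
  cp <- s$conc$parent_uM
  # past the initial distribution phase the parent declines monotonically
  # (down to where the values fade into integrator noise)
  post <- cp[s$time > 1 & cp > 1e-9 * max(cp)]
  expect_true(all(diff(post) < 0))
  cm <- s$conc$metabolite_uM
  ipk <- which.max(cm)
  expect_gt(ipk, 1)
  expect_lt(ipk, length(cm))
  expect_gt(cm[ipk], cm[length(cm)])
})

test_that("Cmax extraction is grid-converged and flags edge peaks", {
  m <- rat_model()
  c_coarse <- extract_cmax(pbk_simulate(m, 40, "oral", 24, n_out = 1201),
                           "parent")
  c_fine <- extract_cmax(pbk_simulate(m, 40, "oral", 24, n_out = 12001),
                         "parent")
  expect_lt(abs(c_coarse - c_fine) / c_fine, 1e-3)
  # IV parent: maximum at the first output time
  s_iv <- pbk_simulate(m, 5, "iv", 12)
  expect_equal(extract_cmax(s_iv, "parent"), s_iv$conc$parent_uM[1])
  # a window too short to cover the metabolite peak is flagged
  expect_warning(extract_cmax(pbk_simulate(m, 40, "oral", 0.5), "metabolite"),
                 "end of the simulation")
  # organ-venous concentrations follow the venous-equilibration convention
  s <- pbk_simulate(m, 40, "oral", 24)
  cl <- extract_cmax(s, "parent", "liver_venous")
  expect_equal(cl, max(s$amounts[, "liver_p"]) /
                 (m$params[["VL"]] * m$params[["PL_p"]]))
})

test_that("local sensitivity coefficients have the expected structure", {
  m <- rat_model()
  # proportionality to dose in the linear regime
  sc_dose <- local_sensitivity(m, 0.1, "oral", 24, "dose")
  expect_lt(abs(sc_dose - 1), 0.05)
  # faster bioactivation lowers parent Cmax and raises metabolite Cmax
  sc_p <- local_sensitivity(m, 40, "oral", 24, "vmax_rhein",
                            compound = "parent")
  sc_m <- local_sensitivity(m, 40, "oral", 24, "vmax_rhein",
                            compound = "metabolite")
  expect_lt(sc_p, 0)
  expect_gt(sc_m, 0)
  expect_error(local_sensitivity(m, 40, "oral", 24, "not_a_param"),
               "unknown parameter")
  # zero-valued parameters cannot be perturbed multiplicatively
  mh <- human_model()   # human metabolite clearance is reported as 0
  expect_error(local_sensitivity(mh, 40, "oral", 24, "clint_m"),
               "zero")
})
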