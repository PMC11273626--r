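test_that("noise-free generators reproduce their functional forms exactly", {
  # Michaelis-Menten at S = Km is half-maximal; at S = 100 direct evaluation
  spec <- synthetic_spec("mm_velocity",
                         list(vmax = 0.472, km = 4.31),
                         design = c(0.5, 1, 2, 4.31, 5, 10, 20, 50, 100),
                         replicates = 1, noise_cv = 0)
  ds <- gen_mm_velocities(spec)
  act <- ds[ds$series == "active", ]
  expect_equal(act$velocity[act$concentration == 4.31], 0.236,
               tolerance = 1e-12)
  expect_equal(act$velocity[act$concentration == 100],
               0.472 * 100 / 104.31, tolerance = 1e-12)
  expect_equal(act$velocity,
               0.472 * act$concentration / (4.31 + act$concentration),
               tolerance = 1e-12)

  # depletion: k = 0 keeps C0; printed-clearance k gives exp(-k t)
  t_design <- c(0, 2, 5, 10, 15, 20, 30, 40, 60, 90, 120)
  d0 <- gen_depletion_course(synthetic_spec(
    "depletion", list(k = 0, c0 = 1, cell_density = 0.5),
    design = t_design, replicates = 1, noise_cv = 0))
  expect_true(all(d0$concentration == 1))
  dk <- gen_depletion_course(synthetic_spec(
    "depletion", list(k = 0.00192, c0 = 1, cell_density = 0.5),
    design = t_design, replicates = 1, noise_cv = 0))
  c120 <- dk$concentration[dk$time == 120 & dk$series == "cells"]
  expect_equal(c120, exp(-0.2304), tolerance = 1e-12)
  expect_equal(round(c120, 3), 0.794)

  # sigmoid: background at dose 0, half-effect at the midpoint
  cv <- gen_dose_response(synthetic_spec(
    "dose_response",
    list(background = 100, max_change = -100, midpoint = 33.70,
         steepness = 1),
    design = c(0, 0.6, 2, 6, 10, 20, 33.70, 60, 100),
    replicates = 1, noise_cv = 0))
  expect_equal(cv$response[cv$dose == 0], 100, tolerance = 1e-12)
  expect_equal(cv$response[cv$dose == 33.70], 50, tolerance = 1e-12)
})

test_that("generators are deterministic under a fixed seed", {
  for (make in list(
    function(s) gen_mm_velocities(synthetic_spec(
      "mm_velocity", list(vmax = 0.5, km = 5),
      design = c(1, 2, 5, 10, 50), noise_cv = 0.1, seed = s)),
    function(s) gen_depletion_course(synthetic_spec(
      "depletion", list(k = 0.002, c0 = 1, cell_density = 0.5),
      design = c(0, 10, 30, 60, 120), noise_cv = 0.1, seed = s)),
    function(s) gen_dose_response(synthetic_spec(
      "dose_response",
      list(background = 100, max_change = -80, midpoint = 20,
           steepness = 1.5),
      design = c(0, 2, 6, 20, 60), noise_cv = 0.1, seed = s)))) {
    expect_identical(make(42L), make(42L))
    expect_false(isTRUE(all.equal(make(42L), make(43L))))
  }
})

test_that("multiplicative noise has the stated mean (law of large numbers)", {
  spec <- synthetic_spec("mm_velocity", list(vmax = 0.472, km = 4.31),
                         design = c(1, 5, 20, 100), replicates = 1000,
                         noise_cv = 0.1, seed = 7L)
  ds <- gen_mm_velocities(spec)
  act <- ds[ds$series == "active", ]
  means <- tapply(act$velocity, act$concentration, mean)
  truth <- 0.472 * as.numeric(names(means)) / (4.31 + as.numeric(names(means)))
  expect_true(all(abs(means - truth) / truth < 0.02))
})

test_that("generator preconditions are enforced", {
  expect_error(gen_mm_velocities(synthetic_spec(
    "mm_velocity", list(vmax = -1, km = 4), design = c(1, 2))),
    "vmax")
  expect_error(gen_mm_velocities(synthetic_spec(
    "mm_velocity", list(vmax = 1, km = 4), design = c(-1, 2))),
    "negative")
  expect_error(gen_depletion_course(synthetic_spec(
    "depletion", list(k = 0.1, c0 = 1, cell_density = 0.5),
    design = c(-5, 0, 10))), "negative time")
  expect_error(gen_dose_response(synthetic_spec(
    "dose_response",
    list(background = 100, max_change = -50, midpoint = -3, steepness = 1),
    design = c(0, 1, 10))), "midpoint")
  expect_error(synthetic_spec("mm_velocity", list(vmax = 1, km = 1),
                              design = 1, noise_cv = -0.1), "noise_cv")
})

test_that("ground-truth BMC10 matches the independent closed form", {
  p <- list(background = 100, max_change = -100, midpoint = 27,
            steepness = 1)
  expect_equal(true_bmc(p, 0.10), 27 / 9, tolerance = 1e-12)
  expect_equal(true_bmc(p, 0.10), oracle_bmc(100, -100, 27, 1),
               tolerance = 1e-12)
  p2 <- list(background = 100, max_change = 250, midpoint = 12,
             steepness = 2.3)
  expect_equal(true_bmc(p2, 0.10), oracle_bmc(100, 250, 12, 2.3),
               tolerance = 1e-12)
  # a shallow curve that never reaches the benchmark response
  expect_true(is.na(true_bmc(list(background = 100, max_change = -5,
                                  midpoint = 10, steepness = 1))))
})
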