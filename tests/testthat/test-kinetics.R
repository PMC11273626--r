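mm_design <- c(0.5, 1, 2, 5, 10, 20, 50, 100)      # microsomal assay
s9_design <- c(0.5, 1, 2, 5, 10, 20, 50, 75, 100)  # S9 assay

test_that("noise-free Michaelis-Menten data are recovered exactly", {
  cases <- list(c(vmax = 0.472, km = 4.31),    # rat rhein formation
                c(vmax = 0.0786, km = 16.9),   # human rhein formation
                c(vmax = 0.799, km = 11.1))    # rat AEG1
  for (cs in cases) {
    ds <- gen_mm_velocities(synthetic_spec(
      "mm_velocity", list(vmax = cs[["vmax"]], km = cs[["km"]]),
      design = mm_design, replicates = 3, noise_cv = 0))
    fit <- fit_michaelis_menten(ds)
    expect_lt(abs(fit$vmax_unscaled - cs[["vmax"]]) / cs[["vmax"]], 1e-3)
    expect_lt(abs(fit$km - cs[["km"]]) / cs[["km"]], 1e-3)
    expect_equal(fit$ce_unscaled, fit$vmax_unscaled / fit$km)
  }
})

test_that("Michaelis-Menten fitting is unbiased at assay-like noise", {
  bias_v <- bias_k <- numeric(100)
  for (s in 1:100) {
    ds <- gen_mm_velocities(synthetic_spec(
      "mm_velocity", list(vmax = 0.472, km = 4.31),
      design = mm_design, replicates = 3, noise_cv = 0.05, seed = s))
    fit <- fit_michaelis_menten(ds)
    bias_v[s] <- (fit$vmax_unscaled - 0.472) / 0.472
    bias_k[s] <- (fit$km - 4.31) / 4.31
  }
  expect_lt(abs(median(bias_v)), 0.02)
  expect_lt(abs(median(bias_k)), 0.02)
})

test_that("Michaelis-Menten fit rejects degenerate inputs", {
  few <- data.frame(concentration = c(1, 1, 2, 5), velocity = c(1, 1, 2, 3))
  expect_error(fit_michaelis_menten(few), "4 distinct")
  flat <- data.frame(concentration = rep(c(1, 2, 5, 10, 50), 2),
                     velocity = rep(0.3, 10))
  expect_error(fit_michaelis_menten(flat), "flat")
  neg <- data.frame(concentration = c(1, 2, 5, 10), velocity = c(1, -2, 3, 4))
  expect_error(fit_michaelis_menten(neg), ">= 0")
  # Km far above the tested range: fit is extrapolated and says so
  ds <- gen_mm_velocities(synthetic_spec(
    "mm_velocity", list(vmax = 5, km = 5000), design = mm_design,
    replicates = 3, noise_cv = 0))
  expect_warning(fit_michaelis_menten(ds), "extrapolated")
})

test_that("catalytic efficiency and scaling are exact and linear", {
  expect_equal(signif(catalytic_efficiency(0.472, 4.31), 3), 0.110)
  expect_equal(signif(catalytic_efficiency(11.1, 4.31), 3), 2.58)
  expect_equal(catalytic_efficiency(3.7, 3.7), 1.0)
  expect_error(catalytic_efficiency(1, 0), "km")

  expect_equal(round(scale_vmax(0.472, 46, 8.5), 1), 11.1)
  expect_equal(round(scale_vmax(0.799, 165, 8.5), 1), 67.2)
  expect_equal(scale_vmax(0, 46, 8.5), 0)
  expect_equal(scale_vmax(2 * 0.3, 46, 8.5), 2 * scale_vmax(0.3, 46, 8.5))
  expect_error(scale_vmax(1, -46, 8.5), "> 0")

  expect_equal(signif(scale_clint(0.00384, 135000, 0.0085), 3), 0.264)
  expect_equal(scale_clint(0, 135000, 0.0085), 0)
  expect_equal(scale_clint(0.00384, 135000, 2 * 0.0085),
               2 * scale_clint(0.00384, 135000, 0.0085))
})

test_that("depletion clearance is recovered from time courses", {
  t_design <- c(0, 2, 5, 10, 15, 20, 30, 40, 60, 90, 120)
  # noise-free: exact recovery of the printed in-vitro clearance
  ds <- gen_depletion_course(synthetic_spec(
    "depletion", list(k = 0.00192, c0 = 1, cell_density = 0.5),
    design = t_design, replicates = 3, noise_cv = 0))
  ce <- clint_from_depletion(ds)
  expect_equal(ce$clint_invitro, 0.00384, tolerance = 1e-10)
  expect_equal(ce$half_life, log(2) / 0.00192, tolerance = 1e-9)

  # constant series: clearance zero, flagged
  d0 <- gen_depletion_course(synthetic_spec(
    "depletion", list(k = 0, c0 = 1, cell_density = 0.5),
    design = t_design, replicates = 1, noise_cv = 0))
  ce0 <- clint_from_depletion(d0)
  expect_equal(ce0$clint_invitro, 0)
  expect_identical(ce0$flag, "no_depletion")

  # noisy: unbiased (median relative bias < 3%) over 100 seeds; the mild
  # depletion over the 120 min window makes individual estimates noisy,
  # but the log-linear estimator is centred on the truth
  err <- vapply(1:100, function(s) {
    d <- gen_depletion_course(synthetic_spec(
      "depletion", list(k = 0.00192, c0 = 1, cell_density = 0.5),
      design = t_design, replicates = 3, noise_cv = 0.05, seed = s))
    (clint_from_depletion(d)$clint_invitro - 0.00384) / 0.00384
  }, numeric(1))
  expect_lt(abs(median(err)), 0.03)
})

test_that("an increasing depletion series warns and clamps to zero", {
  df <- data.frame(time = rep(c(0, 30, 60, 120), each = 2),
                   replicate = rep(1:2, 4),
                   concentration = rep(c(1, 1.1, 1.25, 1.6), each = 2),
                   series = "cells")
  expect_warning(ce <- clint_from_depletion(df, cell_density = 0.5),
                 "increasing")
  expect_equal(ce$clint_invitro, 0)
})

test_that("species scaling factor sets are consistent", {
  r <- scaling_factors("rat"); h <- scaling_factors("human")
  expect_equal(r$microsomal_protein, 46)
  expect_equal(h$microsomal_protein, 40)
  expect_equal(r$s9_protein, 165)
  expect_equal(h$s9_protein, 120.7)
  expect_equal(r$hepatocellularity, 135000)
  # liver masses reconcile scaled/unscaled Vmax ratios of both assays
  expect_equal(round(scale_vmax(0.472, 46, r$liver_mass_g), 1), 11.1)
  expect_equal(signif(scale_vmax(0.0786, 40, h$liver_mass_g), 3), 294)
})
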