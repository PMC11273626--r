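#' Liver scaling factors
#'
#' Protein contents and hepatocellularity used to scale in-vitro kinetic
#' parameters to the whole liver: 46 (rat) and 40 (human) mg microsomal
#' protein per g liver; 165 (rat) and 120.7 (human, 40 microsomal + 80.7
#' cytosolic) mg S9 protein per g liver; 135,000 million hepatocytes per kg
#' liver (rat).  Liver masses are fixed at 8.5 g for a 0.25 kg rat and
#' 1560 g for a 60 kg human; these reconcile the unscaled/scaled maximal
#' rate ratios of the microsomal and S9 incubation data to their printed
#' precision.
#'
#' @param species `"rat"` or `"human"`.
#' @return list with `microsomal_protein` (mg/g liver), `s9_protein`
#'   (mg/g liver), `hepatocellularity` (million cells/kg liver; `NA` for
#'   human, where hepatocyte clearance is not scaled), `liver_mass_g`.
#' @export
scaling_factors <- function(species = c("rat", "human")) {
  species <- match.arg(species)
  if (species == "rat") {
    list(species = "rat", microsomal_protein = 46, s9_protein = 165,
         hepatocellularity = 135000, liver_mass_g = 8.5)
  } else {
    list(species = "human", microsomal_protein = 40, s9_protein = 120.7,
         hepatocellularity = NA_real_, liver_mass_g = 1560)
  }
}

#' Catalytic efficiency
#'
#' `CE = Vmax / Km`.  With unscaled inputs (nmol/min/mg protein over uM)
#' the result is in mL/min/mg protein; with whole-liver inputs (umol/h over
#' uM) it is in L/h.
#'
#' @param vmax maximal rate (> = 0).
#' @param km Michaelis constant (> 0), same concentration units as the
#'   substrate.
#' @return `vmax / km`.
#' @export
catalytic_efficiency <- function(vmax, km) {
  if (any(km <= 0)) stop("km must be > 0")
  vmax / km
}

#' Scale an in-vitro maximal rate to the whole liver
#'
#' `Vmax_scaled [umol/h] = Vmax_unscaled [nmol/min/mg] x protein [mg/g
#' liver] x liver mass [g] x 60 / 1000`.
#'
#' @param vmax_unscaled nmol/min/mg protein (>= 0).
#' @param protein_per_g_liver mg protein per g liver (> 0).
#' @param liver_mass_g liver mass in g (> 0).
#' @return scaled Vmax in umol/h.
#' @export
scale_vmax <- function(vmax_unscaled, protein_per_g_liver, liver_mass_g) {
  if (any(vmax_unscaled < 0)) stop("vmax_unscaled must be >= 0")
  if (any(protein_per_g_liver <= 0) || any(liver_mass_g <= 0))
    stop("protein content and liver mass must be > 0")
  vmax_unscaled * protein_per_g_liver * liver_mass_g * 60 / 1000
}

#' Scale in-vitro intrinsic clearance to the whole liver
#'
#' `CLint_invivo [L/h] = CLint_invitro [mL/min/million cells] x
#' hepatocellularity [million cells/kg liver] x liver mass [kg] x 60 /
#' 1000`.
#'
#' @param clint_invitro mL/min/million cells (>= 0; 0 is a valid reported
#'   value, e.g. hepatic clearance of rhein in humans).
#' @param hepatocellularity million cells per kg liver.
#' @param liver_mass_kg liver mass in kg.
#' @return whole-liver intrinsic clearance in L/h.
#' @export
scale_clint <- function(clint_invitro, hepatocellularity, liver_mass_kg) {
  if (any(clint_invitro < 0)) stop("clint_invitro must be >= 0")
  if (any(hepatocellularity < 0) || any(liver_mass_kg < 0))
    stop("hepatocellularity and liver mass must be >= 0")
  clint_invitro * hepatocellularity * liver_mass_kg * 60 / 1000
}

#' Construct an enzyme-kinetics record
#'
#' Bundles the unscaled and whole-liver Michaelis--Menten parameters of one
#' hepatic pathway.  Catalytic efficiencies are recomputed from `vmax/km`
#' by construction, never stored independently.
#'
#' @param vmax_unscaled nmol/min/mg protein.
#' @param km uM.
#' @param pathway identifier, e.g. `"rhein_formation"`, `"AEG1"`.
#' @param species `"rat"` or `"human"`.
#' @param protein_per_g_liver scaling factor matching the protein source
#'   (microsomal or S9 protein content per g liver).
#' @param liver_mass_g whole-liver mass in g.
#' @param se optional named numeric vector of standard errors
#'   (`vmax`, `km`).
#' @return an object of class `enzyme_kinetics` with fields
#'   `vmax_unscaled`, `km`, `ce_unscaled`, `vmax_scaled` (umol/h),
#'   `ce_scaled` (L/h), `pathway`, `species`.
#' @export
enzyme_kinetics <- function(vmax_unscaled, km, pathway, species,
                            protein_per_g_liver, liver_mass_g, se = NULL) {
  stopifnot(vmax_unscaled > 0, km > 0)
  vmax_scaled <- scale_vmax(vmax_unscaled, protein_per_g_liver, liver_mass_g)
  structure(
    list(vmax_unscaled = vmax_unscaled, km = km,
         ce_unscaled = catalytic_efficiency(vmax_unscaled, km),
         vmax_scaled = vmax_scaled,
         ce_scaled = catalytic_efficiency(vmax_scaled, km),
         pathway = pathway, species = species, se = se),
    class = "enzyme_kinetics")
}

#' @export
print.enzyme_kinetics <- function(x, ...) {
  cat(sprintf("Enzyme kinetics [%s, %s]\n", x$pathway, x$species))
  cat(sprintf("  Vmax (unscaled) %.4g nmol/min/mg   Km %.4g uM\n",
              x$vmax_unscaled, x$km))
  cat(sprintf("  CE   (unscaled) %.4g mL/min/mg\n", x$ce_unscaled))
  cat(sprintf("  Vmax (liver)    %.4g umol/h        CE %.4g L/h\n",
              x$vmax_scaled, x$ce_scaled))
  invisible(x)
}

#' Fit Michaelis--Menten kinetics
#'
#' Untransformed nonlinear least squares of `v = Vmax * S / (Km + S)` on
#' all replicates (no Lineweaver--Burk linearisation, uniform weights).
#' Control series (`series != "active"`, e.g. no-cofactor incubations) are
#' dropped before fitting.
#'
#' @param data a `kinetic_dataset` (from [gen_mm_velocities()] or
#'   [read_kinetic_csv()]), or any data frame with columns `concentration`
#'   and `velocity` (and optionally `series`).
#' @param pathway,species passed through to the [enzyme_kinetics()] record.
#' @param protein_per_g_liver,liver_mass_g scaling inputs; defaults taken
#'   from [scaling_factors()] for the species and a microsomal source when
#'   omitted.
#' @return an `enzyme_kinetics` object with standard errors; the fit is
#'   attached as `attr(x, "fit")`.  A `Km` estimate beyond 10x the highest
#'   tested concentration triggers an "extrapolated" warning.
#' @export
fit_michaelis_menten <- function(data, pathway = "rhein_formation",
                                 species = attr(data, "species") %||% "rat",
                                 protein_per_g_liver = NULL,
                                 liver_mass_g = NULL) {
  df <- as.data.frame(data)
  if (!is.null(df$series)) df <- df[df$series == "active", ]
  df <- df[df$concentration > 0, c("concentration", "velocity")]
  if (any(df$velocity < 0)) stop("velocities must be >= 0")
  if (length(unique(df$concentration)) < 4)
    stop("need at least 4 distinct non-zero substrate concentrations")
  if (all(abs(df$velocity - mean(df$velocity)) < 1e-12 * max(1, mean(df$velocity))))
    stop("flat velocity data: Michaelis-Menten fit cannot converge")

  # starting values: Vmax near the top of the curve, Km near half-max S
  vtop <- max(tapply(df$velocity, df$concentration, mean))
  start <- list(vmax = vtop * 1.2,
                km = stats::median(df$concentration))
  fit <- tryCatch(
    nls(velocity ~ vmax * concentration / (km + concentration),
        data = df, start = start, algorithm = "port",
        lower = c(vmax = 1e-12, km = 1e-12),
        control = list(maxiter = 200)),
    error = function(e) stop("Michaelis-Menten fit failed to converge: ",
                             conditionMessage(e)))
  est <- coef(fit)
  ses <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA, NA))
  if (est[["km"]] > 10 * max(df$concentration))
    warning("Km estimate exceeds 10x the highest tested concentration; ",
            "the fit is extrapolated")

  sf <- scaling_factors(species)
  if (is.null(protein_per_g_liver)) protein_per_g_liver <- sf$microsomal_protein
  if (is.null(liver_mass_g)) liver_mass_g <- sf$liver_mass_g
  out <- enzyme_kinetics(est[["vmax"]], est[["km"]], pathway, species,
                         protein_per_g_liver, liver_mass_g,
                         se = c(vmax = unname(ses[1]), km = unname(ses[2])))
  attr(out, "fit") <- fit
  out
}

#' Intrinsic clearance from a substrate depletion course
#'
#' Log-linear ordinary least squares of `log(C)` on time over the
#' cell-containing series gives the first-order depletion rate `k`
#' (1/min); `CLint_invitro = k / cell_density` (mL/min/million cells) and
#' `half_life = ln(2)/k`.  Non-positive concentrations are dropped with a
#' message; a non-depleting series yields `k <= 0`, which is reported as
#' zero clearance with a flag.
#'
#' @param data a `depletion_dataset` (from [gen_depletion_course()] or
#'   [read_depletion_csv()]) or a data frame with columns `time` and
#'   `concentration` (and optionally `series`).
#' @param cell_density million cells per mL (> 0); defaults to the
#'   dataset attribute when present.
#' @return an object of class `clearance_estimate`: list with
#'   `depletion_rate` (1/min), `clint_invitro` (mL/min/million cells),
#'   `half_life` (min), `n_dropped`, `flag` (`"ok"`, `"no_depletion"`).
#' @export
clint_from_depletion <- function(data, cell_density = attr(data, "cell_density")) {
  if (is.null(cell_density) || cell_density <= 0)
    stop("cell_density (million cells/mL) must be > 0")
  df <- as.data.frame(data)
  if (!is.null(df$series)) df <- df[df$series == "cells", ]
  if (length(unique(df$time)) < 4) stop("need at least 4 time points")
  keep <- df$concentration > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " non-positive concentration(s) dropped before log-linear fit")
  df <- df[keep, ]
  fit <- lm(log(concentration) ~ time, data = df)
  k <- -unname(coef(fit)[["time"]])
  slope_increasing <- k < 0
  if (slope_increasing)
    warning("depletion series is increasing over time; clearance set to 0")
  flag <- if (k <= 0) "no_depletion" else "ok"
  k_eff <- max(k, 0)
  structure(
    list(depletion_rate = k_eff,
         clint_invitro = k_eff / cell_density,
         half_life = if (k_eff > 0) log(2) / k_eff else Inf,
         cell_density = cell_density,
         n_dropped = n_dropped, flag = flag, fit = fit),
    class = "clearance_estimate")
}

#' @export
print.clearance_estimate <- function(x, ...) {
  cat("Intrinsic clearance estimate\n")
  cat(sprintf("  depletion rate  %.5g 1/min (half-life %.4g min)\n",
              x$depletion_rate, x$half_life))
  cat(sprintf("  CLint in vitro  %.5g mL/min/million cells  [%s]\n",
              x$clint_invitro, x$flag))
  invisible(x)
}
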