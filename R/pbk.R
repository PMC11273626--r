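state_names <- c("gut_lumen", "liver_p", "kidney_p", "fat_p", "rich_p",
                 "slow_p", "blood_p", "bile_p", "urine_p", "formed_met",
                 "gluc_p", "liver_m", "kidney_m", "fat_m", "rich_m",
                 "slow_m", "blood_m", "urine_m", "cleared_m")

# Flatten physiology + compound parameters into the vector consumed by the
# C++ right-hand side (layout documented in src/pbk_ode.cpp).
pbk_param_vector <- function(phys, parent, metabolite) {
  vol <- phys$volume_fractions * phys$body_weight   # L (density 1)
  Q <- phys$flow_fractions * phys$cardiac_output    # L/h
  pc_p <- parent$partition_plasma / parent$bpr      # tissue:blood
  pc_m <- metabolite$partition_plasma / metabolite$bpr
  gl <- parent$glucuronidation
  stopifnot(length(gl) == 3)
  v <- c(
    vol[["liver"]], vol[["kidney"]], vol[["fat"]], vol[["rich"]],
    vol[["slow"]], vol[["blood"]],
    Q[["liver"]], Q[["kidney"]], Q[["fat"]], Q[["rich"]], Q[["slow"]],
    parent$ka, parent$kb, phys$gfr_total,
    parent$fup, parent$bpr,
    pc_p[["liver"]], pc_p[["kidney"]], pc_p[["fat"]], pc_p[["rich"]],
    pc_p[["slow"]],
    parent$rhein_formation$vmax_scaled, parent$rhein_formation$km,
    gl[[1]]$vmax_scaled, gl[[1]]$km,
    gl[[2]]$vmax_scaled, gl[[2]]$km,
    gl[[3]]$vmax_scaled, gl[[3]]$km,
    metabolite$fup, metabolite$bpr,
    pc_m[["liver"]], pc_m[["kidney"]], pc_m[["fat"]], pc_m[["rich"]],
    pc_m[["slow"]],
    metabolite$clint_invivo)
  names(v) <- c("VL", "VK", "VF", "VR", "VS", "VB",
                "QL", "QK", "QF", "QR", "QS",
                "ka", "kb", "gfr_total", "fup_p", "bpr_p",
                "PL_p", "PK_p", "PF_p", "PR_p", "PS_p",
                "vmax_rhein", "km_rhein",
                "vmax_aeg1", "km_aeg1", "vmax_aeg2", "km_aeg2",
                "vmax_aeg3", "km_aeg3",
                "fup_m", "bpr_m",
                "PL_m", "PK_m", "PF_m", "PR_m", "PS_m",
                "clint_m")
  v
}

#' Assemble the two-compound PBK model
#'
#' Builds the flow-limited ODE system for the parent compound
#' (aloe-emodin) and its metabolite (rhein): GI tract, liver, kidney, fat,
#' richly and slowly perfused tissues and blood, with oral first-order
#' absorption into the liver, one saturable hepatic conversion of parent
#' to metabolite, three parallel saturable glucuronidation pathways,
#' first-order biliary excretion of the parent from the liver, linear
#' hepatic intrinsic clearance of the metabolite, and renal excretion of
#' both compounds as GFR times the unbound plasma concentration.
#' Metabolism sees the venous-equilibrated liver concentration
#' `C_liver / P_liver`.
#'
#' @param physiology a [species_physiology()].
#' @param parent,metabolite compound parameter lists (see
#'   [compound_defaults()]); `parent` needs `ka`, `fa`, `kb`,
#'   `rhein_formation` and `glucuronidation`, `metabolite` needs
#'   `clint_invivo`.
#' @return an object of class `pbk_model`.
#' @export
build_pbk <- function(physiology, parent, metabolite) {
  stopifnot(inherits(physiology, "species_physiology"))
  validate_compound(parent, "parent")
  validate_compound(metabolite, "metabolite")
  stopifnot(parent$ka >= 0, parent$fa >= 0, parent$fa <= 1, parent$kb >= 0)
  if (any(physiology$flow_fractions <= 0)) stop("non-positive blood flows")
  pv <- pbk_param_vector(physiology, parent, metabolite)
  structure(
    list(physiology = physiology, parent = parent, metabolite = metabolite,
         params = pv),
    class = "pbk_model")
}

#' @export
print.pbk_model <- function(x, ...) {
  cat(sprintf("PBK model: %s -> %s, %s (%g kg BW)\n", x$parent$name,
              x$metabolite$name, x$physiology$species,
              x$physiology$body_weight))
  cat(sprintf("  ka %.3g 1/h, Fa %.3g, kb %.3g 1/h, GFR %.3g L/h\n",
              x$parent$ka, x$parent$fa, x$parent$kb,
              x$physiology$gfr_total))
  invisible(x)
}

#' Simulate the PBK model
#'
#' Integrates the model with an adaptive embedded Runge--Kutta 5(4) method
#' (error-controlled, default rtol 1e-8 / atol 1e-10) and reports amounts
#' per compartment, blood concentrations of parent and metabolite, and the
#' molar mass-balance residuals.
#'
#' @param model a [build_pbk()] model.
#' @param dose dose in mg/kg body weight (>= 0), single administration at
#'   time 0.
#' @param route `"oral"` or `"iv"`.  Oral dosing places `Fa * dose` in the
#'   absorbable gut-lumen pool (transferred to the liver at rate `ka`) and
#'   books `(1 - Fa) * dose` as unabsorbed; IV dosing places the full dose
#'   in blood.
#' @param duration simulation length in h (> 0).
#' @param n_out number of equally spaced output times (the dense grid from
#'   which Cmax is read; the default resolves Cmax to well below 0.1%).
#' @param rtol,atol relative/absolute integration tolerances.
#' @param hmax maximum step size in h.
#' @return an object of class `pbk_sim`: list with `time` (h), `amounts`
#'   (matrix, umol), `conc` (data frame: time, blood parent/metabolite in
#'   uM and ug/mL), `dose_umol`, `unabsorbed_umol`, `mass_balance`
#'   (parent and metabolite relative residuals), `model`, `route`, `dose`.
#' @export
pbk_simulate <- function(model, dose, route = c("oral", "iv"),
                         duration = 24, n_out = 1201,
                         rtol = 1e-8, atol = 1e-10, hmax = 0.1) {
  stopifnot(inherits(model, "pbk_model"), dose >= 0, duration > 0)
  route <- match.arg(route)
  bw <- model$physiology$body_weight
  dose_umol <- dose * bw * 1000 / model$parent$molar_mass
  y0 <- numeric(19)
  unabsorbed <- 0
  if (route == "oral") {
    y0[1] <- model$parent$fa * dose_umol
    unabsorbed <- (1 - model$parent$fa) * dose_umol
  } else {
    y0[7] <- dose_umol
  }
  t_out <- seq(0, duration, length.out = n_out)
  amt <- pbk_integrate_cpp(model$params, y0, t_out, rtol, atol, hmax)
  colnames(amt) <- state_names
  if (min(amt) < -atol * 1e3 - 1e-9)
    stop("negative amounts beyond solver tolerance: min = ", min(amt))

  VB <- model$params[["VB"]]
  cb_p <- amt[, "blood_p"] / VB          # uM
  cb_m <- amt[, "blood_m"] / VB
  conc <- data.frame(
    time = t_out,
    parent_uM = cb_p, metabolite_uM = cb_m,
    parent_ugml = cb_p * model$parent$molar_mass / 1000,
    metabolite_ugml = cb_m * model$metabolite$molar_mass / 1000)

  final <- amt[nrow(amt), ]
  parent_total <- sum(final[c("gut_lumen", "liver_p", "kidney_p", "fat_p",
                              "rich_p", "slow_p", "blood_p", "bile_p",
                              "urine_p", "formed_met", "gluc_p")]) + unabsorbed
  mb_parent <- if (dose_umol > 0) (parent_total - dose_umol) / dose_umol else 0
  met_body <- sum(final[c("liver_m", "kidney_m", "fat_m", "rich_m", "slow_m",
                          "blood_m")])
  met_total <- met_body + final[["urine_m"]] + final[["cleared_m"]]
  mb_met <- if (final[["formed_met"]] > 1e-12)
    (met_total - final[["formed_met"]]) / final[["formed_met"]] else 0

  structure(
    list(time = t_out, amounts = amt, conc = conc,
         dose = dose, route = route, dose_umol = dose_umol,
         unabsorbed_umol = unabsorbed,
         mass_balance = c(parent = mb_parent, metabolite = mb_met),
         model = model),
    class = "pbk_sim")
}

#' @export
print.pbk_sim <- function(x, ...) {
  cat(sprintf("PBK simulation: %s %g mg/kg, %s, %g h\n",
              x$model$physiology$species, x$dose, x$route, max(x$time)))
  cat(sprintf("  Cmax parent     %.4g uM (%.4g ug/mL)\n",
              max(x$conc$parent_uM), max(x$conc$parent_ugml)))
  cat(sprintf("  Cmax metabolite %.4g uM (%.4g ug/mL)\n",
              max(x$conc$metabolite_uM), max(x$conc$metabolite_ugml)))
  cat(sprintf("  mass balance residual: parent %.2e, metabolite %.2e\n",
              x$mass_balance[["parent"]], x$mass_balance[["metabolite"]]))
  invisible(x)
}

#' Maximum concentration from a simulation
#'
#' Reads the maximum concentration off the dense output grid.  Blood
#' concentrations are the central-blood values; organ-venous
#' concentrations use the venous-equilibration convention
#' `C_tissue / P_tissue` (tissue:blood).  A maximum attained at the last
#' output time is flagged with a warning (peak possibly not covered).
#'
#' @param sim a [pbk_simulate()] result.
#' @param compound `"parent"` or `"metabolite"`.
#' @param matrix `"blood"`, `"liver_venous"` or `"kidney_venous"`.
#' @param units `"uM"` or `"ugml"` (blood only).
#' @return the maximum concentration.
#' @export
extract_cmax <- function(sim, compound = c("parent", "metabolite"),
                         matrix = c("blood", "liver_venous", "kidney_venous"),
                         units = c("uM", "ugml")) {
  stopifnot(inherits(sim, "pbk_sim"))
  compound <- match.arg(compound)
  matrix <- match.arg(matrix)
  units <- match.arg(units)
  p <- sim$model$params
  if (matrix == "blood") {
    x <- if (compound == "parent") sim$conc$parent_uM else sim$conc$metabolite_uM
  } else {
    organ <- if (matrix == "liver_venous") "liver" else "kidney"
    amt_col <- paste0(organ, if (compound == "parent") "_p" else "_m")
    V <- p[[if (organ == "liver") "VL" else "VK"]]
    P <- p[[paste0(if (organ == "liver") "PL" else "PK",
                   if (compound == "parent") "_p" else "_m")]]
    x <- sim$amounts[, amt_col] / (V * P)
  }
  imax <- which.max(x)
  if (imax == length(x) && sim$dose > 0 && x[imax] > 0)
    warning("Cmax attained at the end of the simulation window; ",
            "increase 'duration'")
  cmax <- x[imax]
  if (units == "ugml") {
    mw <- if (compound == "parent") sim$model$parent$molar_mass
          else sim$model$metabolite$molar_mass
    cmax <- cmax * mw / 1000
  }
  unname(cmax)
}

#' Local sensitivity of Cmax to a model parameter
#'
#' Normalised sensitivity coefficient
#' `SC = ((Cmax(p * (1 + delta)) - Cmax(p)) / Cmax(p)) / delta` for a
#' single scalar input perturbed multiplicatively.  `"dose"` and `"fa"`
#' are accepted alongside any entry of the flat parameter vector (e.g.
#' `"vmax_rhein"`, `"PL_p"`, `"ka"`).
#'
#' @param model a [build_pbk()] model.
#' @param dose,route,duration dosing scenario (as in [pbk_simulate()]).
#' @param parameter name of the parameter to perturb.
#' @param delta relative perturbation (default 0.05).
#' @param compound,matrix which Cmax to track (see [extract_cmax()]).
#' @return the sensitivity coefficient (dimensionless).
#' @export
local_sensitivity <- function(model, dose, route = "oral", duration = 24,
                              parameter, delta = 0.05,
                              compound = "parent", matrix = "blood") {
  base <- pbk_simulate(model, dose, route, duration)
  c0 <- extract_cmax(base, compound, matrix)
  if (c0 <= 0) stop("baseline Cmax is zero; sensitivity undefined")
  if (parameter == "dose") {
    sim2 <- pbk_simulate(model, dose * (1 + delta), route, duration)
  } else if (parameter == "fa") {
    m2 <- model
    m2$parent$fa <- model$parent$fa * (1 + delta)
    sim2 <- pbk_simulate(m2, dose, route, duration)
  } else {
    if (!parameter %in% names(model$params))
      stop("unknown parameter: ", parameter)
    if (model$params[[parameter]] == 0)
      stop("parameter '", parameter,
           "' is zero and cannot be perturbed multiplicatively")
    m2 <- model
    m2$params[[parameter]] <- model$params[[parameter]] * (1 + delta)
    sim2 <- pbk_simulate(m2, dose, route, duration)
  }
  c1 <- extract_cmax(sim2, compound, matrix)
  ((c1 - c0) / c0) / delta
}
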