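#' Specify a synthetic dataset
#'
#' A `synthetic_spec` describes one of the dataset shapes the pipeline
#' consumes -- Michaelis--Menten velocities, a first-order substrate
#' depletion course, or a sigmoidal concentration--response curve --
#' together with its ground-truth parameters, experimental design, replicate
#' count, noise level and seed.  Generators never touch global random state:
#' the seed is part of the specification, so an identical spec always yields
#' a bit-identical dataset.
#'
#' @param kind one of `"mm_velocity"`, `"depletion"`, `"dose_response"`.
#' @param true_params named list of ground-truth parameters for the chosen
#'   kind (see the individual generators).
#' @param design numeric vector of substrate concentrations (uM), time
#'   points (min) or doses/concentrations depending on `kind`.
#' @param replicates positive integer; incubations in this assay family are
#'   typically run in triplicate, the default.
#' @param noise_cv coefficient of variation of the measurement noise
#'   (>= 0); `0` reproduces the noise-free curve exactly.
#' @param noise_model `"lognormal"` (multiplicative, assay-like
#'   heteroscedastic noise; default) or `"normal"` (additive, sd =
#'   `noise_cv` times the noise-free value).
#' @param seed integer seed owned by this spec.
#'
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(kind = c("mm_velocity", "depletion", "dose_response"),
                           true_params, design, replicates = 3L,
                           noise_cv = 0, noise_model = c("lognormal", "normal"),
                           seed = 1L) {
  kind <- match.arg(kind)
  noise_model <- match.arg(noise_model)
  stopifnot(is.list(true_params), is.numeric(design), length(design) >= 1)
  if (!is.numeric(replicates) || replicates < 1 || replicates != round(replicates))
    stop("'replicates' must be a positive integer")
  if (!is.numeric(noise_cv) || length(noise_cv) != 1 || noise_cv < 0)
    stop("'noise_cv' must be a single non-negative number")
  structure(
    list(kind = kind, true_params = true_params, design = as.numeric(design),
         replicates = as.integer(replicates), noise_cv = noise_cv,
         noise_model = noise_model, seed = as.integer(seed)),
    class = "synthetic_spec")
}

# Apply the spec's noise model to a vector of noise-free values.
# Lognormal noise has unit mean: meanlog = -sigma^2/2 with
# sigma^2 = log(1 + cv^2), so E[obs] = truth for every cv.
apply_noise <- function(x, cv, model) {
  if (cv == 0) return(x)
  if (model == "lognormal") {
    sigma <- sqrt(log(1 + cv^2))
    x * rlnorm(length(x), meanlog = -sigma^2 / 2, sdlog = sigma)
  } else {
    x + rnorm(length(x), 0, cv * abs(x))
  }
}

with_spec_seed <- function(spec, expr) {
  # Localized RNG: restore the caller's random state afterwards.
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)
  force(expr)
}

#' Generate Michaelis--Menten velocity data
#'
#' Emulates microsomal / S9 incubations measuring metabolite formation
#' velocity at a series of substrate concentrations.  The noise-free mean at
#' substrate concentration `S` is `Vmax * S / (Km + S)`.  A no-cofactor
#' control series (velocity 0 plus noise floor, labelled `"control"`) is
#' emitted alongside the active series so that filtering logic downstream
#' can be exercised.
#'
#' @param spec a [synthetic_spec()] with `kind = "mm_velocity"` and
#'   `true_params` containing `vmax` (> 0, nmol/min/mg protein) and `km`
#'   (> 0, uM).
#'
#' @return a `kinetic_dataset`: data frame with columns `concentration`
#'   (uM), `replicate`, `velocity` (nmol/min/mg protein), `series`
#'   (`"active"` or `"control"`), plus attributes `true_params`,
#'   `protein_source`, `species`.
#' @export
gen_mm_velocities <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$kind == "mm_velocity")
  p <- spec$true_params
  if (is.null(p$vmax) || is.null(p$km) || p$vmax <= 0 || p$km <= 0)
    stop("true_params must contain vmax > 0 and km > 0")
  if (any(spec$design < 0)) stop("negative substrate concentrations rejected")
  S <- rep(spec$design, each = spec$replicates)
  truth <- p$vmax * S / (p$km + S)
  v <- with_spec_seed(spec, apply_noise(truth, spec$noise_cv, spec$noise_model))
  out <- data.frame(
    concentration = S,
    replicate = rep(seq_len(spec$replicates), times = length(spec$design)),
    velocity = v,
    series = "active")
  ctrl <- out
  ctrl$velocity <- 0
  ctrl$series <- "control"
  out <- rbind(out, ctrl)
  structure(out, class = c("kinetic_dataset", "data.frame"),
            true_params = p,
            protein_source = p$protein_source %||% "microsomes",
            species = p$species %||% "rat")
}

#' Generate a substrate depletion time course
#'
#' Emulates hepatocyte incubations following the disappearance of a
#' substrate: `C(t) = C0 * exp(-k * t)` plus noise for the cell-containing
#' series, and a no-cells control that stays at `C0` plus noise.
#'
#' @param spec a [synthetic_spec()] with `kind = "depletion"` and
#'   `true_params` containing `k` (first-order depletion rate, 1/min,
#'   >= 0), `c0` (initial concentration, uM, > 0) and `cell_density`
#'   (million cells/mL, > 0).  `design` holds the sampling times in
#'   minutes.
#'
#' @return a `depletion_dataset`: data frame with columns `time` (min),
#'   `replicate`, `concentration` (uM), `series` (`"cells"` or
#'   `"control"`), with attributes `true_params` and `cell_density`.
#' @export
gen_depletion_course <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$kind == "depletion")
  p <- spec$true_params
  if (is.null(p$k) || p$k < 0) stop("true_params must contain k >= 0")
  if (is.null(p$c0) || p$c0 <= 0) stop("true_params must contain c0 > 0")
  if (is.null(p$cell_density) || p$cell_density <= 0)
    stop("true_params must contain cell_density > 0")
  if (any(spec$design < 0)) stop("negative time points rejected")
  t <- rep(spec$design, each = spec$replicates)
  truth <- p$c0 * exp(-p$k * t)
  obs <- with_spec_seed(spec, {
    cells <- apply_noise(truth, spec$noise_cv, spec$noise_model)
    ctrl <- apply_noise(rep(p$c0, length(t)), spec$noise_cv, spec$noise_model)
    list(cells = cells, ctrl = ctrl)
  })
  base <- data.frame(
    time = t,
    replicate = rep(seq_len(spec$replicates), times = length(spec$design)))
  out <- rbind(
    cbind(base, concentration = obs$cells, series = "cells"),
    cbind(base, concentration = obs$ctrl, series = "control"))
  structure(out, class = c("depletion_dataset", "data.frame"),
            true_params = p, cell_density = p$cell_density)
}

# Four-parameter sigmoid used by the generator and as the ground-truth
# reference curve: background at dose 0, approaching background + max_change
# as dose -> Inf (max_change < 0 for decreasing endpoints like viability).
sigmoid_response <- function(dose, background, max_change, midpoint, steepness) {
  frac <- ifelse(dose > 0,
                 dose^steepness / (midpoint^steepness + dose^steepness), 0)
  background + max_change * frac
}

#' Generate a sigmoidal concentration--response curve
#'
#' Emulates a continuous in-vitro endpoint (cell viability, ROS induction,
#' Nrf2 reporter activity) measured at a series of exposure concentrations
#' including a solvent control at 0.  The noise-free curve is a Hill-type
#' four-parameter sigmoid.
#'
#' @param spec a [synthetic_spec()] with `kind = "dose_response"` and
#'   `true_params` containing `background` (response at dose 0),
#'   `max_change` (asymptotic change; negative for decreasing endpoints),
#'   `midpoint` (> 0; dose of half-maximal change) and `steepness` (> 0,
#'   Hill coefficient).  `design` holds the doses (must include 0 for a
#'   usable curve).
#'
#' @return a `dose_response_curve` (see [dose_response_curve()]) carrying
#'   the ground-truth parameters and the analytic benchmark concentration
#'   `attr(x, "true_bmc10")` at which the noise-free response differs from
#'   background by 10 percent (see [true_bmc()]).
#' @export
gen_dose_response <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$kind == "dose_response")
  p <- spec$true_params
  need <- c("background", "max_change", "midpoint", "steepness")
  if (!all(need %in% names(p))) stop("true_params must contain: ",
                                     paste(need, collapse = ", "))
  if (p$midpoint <= 0) stop("midpoint must be > 0")
  if (p$steepness <= 0) stop("steepness must be > 0")
  if (any(spec$design < 0)) stop("negative doses rejected")
  d <- rep(spec$design, each = spec$replicates)
  truth <- sigmoid_response(d, p$background, p$max_change, p$midpoint, p$steepness)
  resp <- with_spec_seed(spec, apply_noise(truth, spec$noise_cv, spec$noise_model))
  direction <- if (p$max_change < 0) "decreasing" else "increasing"
  curve <- dose_response_curve(
    dose = d,
    response = resp,
    replicate = rep(seq_len(spec$replicates), times = length(spec$design)),
    direction = direction)
  attr(curve, "true_params") <- p
  attr(curve, "true_bmc10") <- true_bmc(p, bmr = 0.10)
  curve
}

#' Analytic benchmark concentration of the generating sigmoid
#'
#' Closed-form inverse of the four-parameter sigmoid: the dose at which the
#' noise-free response differs from background by a fraction `bmr` of
#' background.  Used as ground truth when testing benchmark-dose recovery.
#'
#' @param true_params list with `background`, `max_change`, `midpoint`,
#'   `steepness` as in [gen_dose_response()].
#' @param bmr benchmark response as a fraction of background (default 0.10).
#' @return the benchmark dose, or `NA` if the curve never reaches it.
#' @export
true_bmc <- function(true_params, bmr = 0.10) {
  p <- true_params
  target_frac <- bmr * p$background / abs(p$max_change)
  if (target_frac >= 1) return(NA_real_)
  # frac/(1-frac) inversion of the Hill term
  p$midpoint * (target_frac / (1 - target_frac))^(1 / p$steepness)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
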