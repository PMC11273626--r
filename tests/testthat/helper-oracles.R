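# Independent numerical oracles, deliberately re-derived rather than
# calling package internals.

# --- fixed-step RK4 integration of an R-side transcription of the PBK
#     mass balances (independent of the compiled right-hand side) --------

oracle_pbk_rhs <- function(y, p) {
  cbp <- y["blood_p"] / p$VB
  cvl <- y["liver_p"] / (p$VL * p$PL_p)
  cvk <- y["kidney_p"] / (p$VK * p$PK_p)
  cvf <- y["fat_p"] / (p$VF * p$PF_p)
  cvr <- y["rich_p"] / (p$VR * p$PR_p)
  cvs <- y["slow_p"] / (p$VS * p$PS_p)
  qc <- p$QL + p$QK + p$QF + p$QR + p$QS
  mm <- function(v, k, c) v * c / (k + c)
  v_rh <- mm(p$vmax_rhein, p$km_rhein, cvl)
  v_g <- mm(p$vmax_aeg1, p$km_aeg1, cvl) + mm(p$vmax_aeg2, p$km_aeg2, cvl) +
    mm(p$vmax_aeg3, p$km_aeg3, cvl)
  renal_p <- p$gfr_total * p$fup_p * cbp / p$bpr_p

  cbm <- y["blood_m"] / p$VB
  cvlm <- y["liver_m"] / (p$VL * p$PL_m)
  cvkm <- y["kidney_m"] / (p$VK * p$PK_m)
  cvfm <- y["fat_m"] / (p$VF * p$PF_m)
  cvrm <- y["rich_m"] / (p$VR * p$PR_m)
  cvsm <- y["slow_m"] / (p$VS * p$PS_m)
  renal_m <- p$gfr_total * p$fup_m * cbm / p$bpr_m

  c(gut_lumen = -p$ka * y[["gut_lumen"]],
    liver_p = p$ka * y[["gut_lumen"]] + p$QL * (cbp - cvl) -
      p$kb * y[["liver_p"]] - v_rh - v_g,
    kidney_p = p$QK * (cbp - cvk) - renal_p,
    fat_p = p$QF * (cbp - cvf),
    rich_p = p$QR * (cbp - cvr),
    slow_p = p$QS * (cbp - cvs),
    blood_p = p$QL * cvl + p$QK * cvk + p$QF * cvf + p$QR * cvr +
      p$QS * cvs - qc * cbp,
    bile_p = p$kb * y[["liver_p"]],
    urine_p = renal_p,
    formed_met = v_rh,
    gluc_p = v_g,
    liver_m = v_rh + p$QL * (cbm - cvlm) - p$clint_m * cvlm,
    kidney_m = p$QK * (cbm - cvkm) - renal_m,
    fat_m = p$QF * (cbm - cvfm),
    rich_m = p$QR * (cbm - cvrm),
    slow_m = p$QS * (cbm - cvsm),
    blood_m = p$QL * cvlm + p$QK * cvkm + p$QF * cvfm + p$QR * cvrm +
      p$QS * cvsm - qc * cbm,
    urine_m = renal_m,
    cleared_m = p$clint_m * cvlm)
}

oracle_rk4 <- function(model, dose, route, duration, h = 5e-4) {
  p <- as.list(model$params)
  bw <- model$physiology$body_weight
  dose_umol <- dose * bw * 1000 / model$parent$molar_mass
  nm <- c("gut_lumen", "liver_p", "kidney_p", "fat_p", "rich_p", "slow_p",
          "blood_p", "bile_p", "urine_p", "formed_met", "gluc_p",
          "liver_m", "kidney_m", "fat_m", "rich_m", "slow_m", "blood_m",
          "urine_m", "cleared_m")
  y <- setNames(numeric(19), nm)
  if (route == "oral") y["gut_lumen"] <- model$parent$fa * dose_umol
  else y["blood_p"] <- dose_umol
  n <- ceiling(duration / h)
  cmax_p <- y[["blood_p"]] / p$VB
  cmax_m <- 0
  for (i in seq_len(n)) {
    k1 <- oracle_pbk_rhs(y, p)
    k2 <- oracle_pbk_rhs(y + h / 2 * k1, p)
    k3 <- oracle_pbk_rhs(y + h / 2 * k2, p)
    k4 <- oracle_pbk_rhs(y + h * k3, p)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    cmax_p <- max(cmax_p, y[["blood_p"]] / p$VB)
    cmax_m <- max(cmax_m, y[["blood_m"]] / p$VB)
  }
  list(cmax_parent = cmax_p, cmax_metabolite = cmax_m, final = y)
}

# --- closed forms ------------------------------------------------------

# one-compartment first-order absorption/elimination blood concentration
bateman_conc <- function(t, dose_umol, fa, ka, ke, V) {
  fa * dose_umol * ka / (V * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
}

bateman_cmax <- function(dose_umol, fa, ka, ke, V) {
  tmax <- log(ka / ke) / (ka - ke)
  bateman_conc(tmax, dose_umol, fa, ka, ke, V)
}

# analytic benchmark dose of the generating four-parameter sigmoid,
# re-derived here: response(d) = bg + mc * d^s/(m^s + d^s) equals
# bg * (1 -+ bmr) at d = m * (u/(1-u))^(1/s), u = bmr*bg/|mc|
oracle_bmc <- function(bg, mc, m, s, bmr = 0.10) {
  u <- bmr * bg / abs(mc)
  m * (u / (1 - u))^(1 / s)
}

# reduce a PBK model to an effectively one-compartment system: unit
# partitioning and blood flows scaled up 20-fold so every tissue
# equilibrates much faster than absorption/elimination (perfusion rates
# >> ka, ke); metabolism and biliary loss off, renal excretion the only
# sink.  The lumped system then follows the Bateman equation with
# V = total volume and ke = GFR * fup / (BPR * V).
one_compartment_model <- function(species = "rat") {
  cmp <- compound_defaults(species)
  phys <- species_physiology(species)
  model <- build_pbk(phys, cmp$parent, cmp$metabolite)
  p <- model$params
  p[c("QL", "QK", "QF", "QR", "QS")] <-
    20 * p[c("QL", "QK", "QF", "QR", "QS")]
  p[c("PL_p", "PK_p", "PF_p", "PR_p", "PS_p",
      "PL_m", "PK_m", "PF_m", "PR_m", "PS_m")] <- 1
  p[c("vmax_rhein", "vmax_aeg1", "vmax_aeg2", "vmax_aeg3",
      "kb", "clint_m")] <- 0
  p["bpr_p"] <- 1
  p["fup_p"] <- 0.2
  model$params <- p
  model
}

make_hill_curve <- function(bg = 100, mc = -100, m = 30, s = 1.5, cv = 0,
                            seed = 1,
                            doses = c(0, 0.6, 2, 6, 10, 20, 60, 100),
                            replicates = 3) {
  gen_dose_response(synthetic_spec(
    "dose_response",
    true_params = list(background = bg, max_change = mc, midpoint = m,
                       steepness = s),
    design = doses, replicates = replicates, noise_cv = cv, seed = seed))
}
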