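#' Estimated daily intake of a scenario
#'
#' `EDI [mg/kg bw/day] = content [mg/g] x daily amount [g/day] / body
#' weight [kg]`.  The same arithmetic serves scenarios expressed per
#' daily unit (content in mg/unit, daily amount in units/day).
#'
#' @param content aloe-emodin content, mg per g product (>= 0).
#' @param daily_amount recommended daily amount, g/day (>= 0).
#' @param body_weight consumer body weight in kg (> 0; default 60).
#' @return EDI in mg/kg bw/day.
#' @export
compute_edi <- function(content, daily_amount, body_weight = 60) {
  if (any(body_weight <= 0)) stop("body weight must be > 0")
  if (any(content < 0) || any(daily_amount < 0))
    stop("content and daily amount must be >= 0")
  content * daily_amount / body_weight
}

#' Summarise exposure across scenarios
#'
#' Per-scenario EDIs plus the geometric mean (zero EDIs excluded with a
#' message), the empirical 95th percentile (linear interpolation,
#' `quantile type 7`) and the range.
#'
#' @param scenarios data frame with columns `product`, `category`,
#'   `content` (mg/g), `daily_amount` (g/day) and optionally `bw` (kg,
#'   default 60).
#' @return an object of class `exposure_summary`: list with `scenarios`
#'   (with an `edi` column), `gm`, `p95`, `range`, `n_zero`.
#' @export
summarize_exposure <- function(scenarios) {
  need <- c("product", "category", "content", "daily_amount")
  if (!all(need %in% names(scenarios)))
    stop("scenario table must have columns: ", paste(need, collapse = ", "))
  bw <- scenarios$bw %||% rep(60, nrow(scenarios))
  edi <- compute_edi(scenarios$content, scenarios$daily_amount, bw)
  scenarios$edi <- edi
  pos <- edi[edi > 0]
  if (length(pos) == 0) stop("need at least one scenario with EDI > 0")
  n_zero <- sum(edi == 0)
  if (n_zero > 0)
    message(n_zero, " zero-EDI scenario(s) excluded from the geometric mean")
  structure(
    list(scenarios = scenarios,
         gm = exp(mean(log(pos))),
         p95 = unname(quantile(edi, 0.95, type = 7)),
         range = range(edi),
         n_zero = n_zero),
    class = "exposure_summary")
}

#' @export
print.exposure_summary <- function(x, ...) {
  cat(sprintf("Exposure summary over %d scenarios (mg/kg bw/day)\n",
              nrow(x$scenarios)))
  cat(sprintf("  range [%.3g, %.3g]  GM %.3g  P95 %.3g\n",
              x$range[1], x$range[2], x$gm, x$p95))
  invisible(x)
}

#' Margin of exposure
#'
#' The fold difference between a point of departure and an estimated
#' daily intake: `MOE = BMDL10 / EDI`.
#'
#' @param bmdl point of departure, mg/kg bw/day (>= 0).
#' @param edi estimated daily intake, mg/kg bw/day (> 0).
#' @return the margin (dimensionless fold).
#' @export
margin_of_exposure <- function(bmdl, edi) {
  if (any(edi <= 0)) stop("EDI must be > 0 for a margin of exposure")
  bmdl / edi
}
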