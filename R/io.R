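# Delimited-text I/O (one header line, dot decimal separator) and the
# five-stage pipeline driver.

fmt_num <- function(x) sprintf("%.17g", x)   # lossless double round-trip

write_delim_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a Michaelis--Menten velocity dataset
#'
#' Columns: `concentration` (uM), `replicate`, `velocity`
#' (nmol/min/mg protein), `series`.
#'
#' @param data a `kinetic_dataset`.
#' @param path CSV file path.
#' @return the path (writer) / a `kinetic_dataset` (reader).
#' @export
write_kinetic_csv <- function(data, path) write_delim_exact(data, path)

#' @rdname write_kinetic_csv
#' @param species,protein_source metadata attached on read.
#' @export
read_kinetic_csv <- function(path, species = "rat",
                             protein_source = "microsomes") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("concentration", "replicate", "velocity", "series")
  if (!all(need %in% names(df)))
    stop("kinetic CSV must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(df$concentration)) || any(!is.finite(df$velocity)))
    stop("malformed numbers in kinetic CSV")
  structure(df, class = c("kinetic_dataset", "data.frame"),
            species = species, protein_source = protein_source)
}

#' Write / read a depletion time course
#'
#' Columns: `time` (min), `replicate`, `concentration` (uM), `series`.
#'
#' @param data a `depletion_dataset`.
#' @param path CSV file path.
#' @return the path (writer) / a `depletion_dataset` (reader).
#' @export
write_depletion_csv <- function(data, path) write_delim_exact(data, path)

#' @rdname write_depletion_csv
#' @param cell_density million cells/mL, attached on read.
#' @export
read_depletion_csv <- function(path, cell_density = 0.5) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "replicate", "concentration", "series")
  if (!all(need %in% names(df)))
    stop("depletion CSV must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(df$time)) || any(!is.finite(df$concentration)))
    stop("malformed numbers in depletion CSV")
  if (any(df$time < 0)) stop("negative time points rejected")
  structure(df, class = c("depletion_dataset", "data.frame"),
            cell_density = cell_density)
}

#' Write a dose--response curve to CSV
#'
#' Columns: `dose` (units in the header comment column `units`),
#' `replicate`, `response`.
#'
#' @param curve a `dose_response_curve`.
#' @param path CSV file path.
#' @return the path, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  df <- data.frame(dose = curve$dose, replicate = curve$replicate,
                   response = curve$response,
                   direction = attr(curve, "direction"),
                   units = attr(curve, "units") %||% "uM")
  write_delim_exact(df, path)
}

#' Load a dose--response curve from CSV
#'
#' Validates the documented schema: columns `dose`, `replicate`,
#' `response` (plus optional `direction`, `units`), finite numbers,
#' non-negative doses, and a required dose-0 control row.
#'
#' @param path CSV file path.
#' @return a [dose_response_curve()].
#' @export
load_curve <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("dose", "replicate", "response")
  if (!all(need %in% names(df)))
    stop("curve CSV must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(df$dose)) || any(!is.finite(df$response)))
    stop("malformed numbers in curve CSV")
  if (any(df$dose < 0)) stop("negative doses rejected")
  if (!0 %in% df$dose)
    stop("curve is missing the required dose-0 control row")
  direction <- if (!is.null(df$direction)) df$direction[1] else "decreasing"
  units <- if (!is.null(df$units)) df$units[1] else "uM"
  dose_response_curve(df$dose, df$response, df$replicate,
                      direction = direction, units = units)
}

#' Load a pipeline configuration
#'
#' JSON configuration with fields `species`, `bmd` (`family`, `bmr`,
#' `n_boot`, `seed`), `endpoints` (name -> `curve` path, `fbs` percent,
#' optional `organ`), optional `scenarios` (CSV path) and `out_dir`.
#' Referenced files must exist.
#'
#' @param path JSON file path.
#' @return the validated configuration list.
#' @export
load_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  stopifnot(!is.null(cfg$species), !is.null(cfg$endpoints))
  if (is.null(cfg$bmd)) cfg$bmd <- list()
  cfg$bmd <- modifyList(list(family = "hill", bmr = 0.10,
                             n_boot = 1000, seed = 1L), cfg$bmd)
  for (ep in names(cfg$endpoints)) {
    cfg$endpoints[[ep]]$curve <- resolve(cfg$endpoints[[ep]]$curve)
    if (!file.exists(cfg$endpoints[[ep]]$curve))
      stop("curve file for endpoint '", ep, "' not found: ",
           cfg$endpoints[[ep]]$curve)
  }
  if (!is.null(cfg$scenarios)) {
    cfg$scenarios <- resolve(cfg$scenarios)
    if (!file.exists(cfg$scenarios))
      stop("scenario file not found: ", cfg$scenarios)
  }
  cfg
}

#' Run the five-stage QIVIVE pipeline
#'
#' Executes: (1) model parameterisation for the configured species
#' (shipped kinetic parameter defaults, or parameters refitted from
#' kinetic CSVs when the config supplies them); (2) PBK model assembly;
#' (3) QIVIVE conversion of every configured endpoint curve to an in-vivo
#' dose--response curve in its target organ; (4) BMD analysis of each
#' converted curve; (5) comparison against the exposure scenarios, when
#' configured.  Every numeric artifact is written as CSV/JSON under
#' `out_dir` together with a provenance log (config hash, seeds, package
#' version).
#'
#' @param config a configuration list (see [load_config()]) or a path to
#'   a JSON config.
#' @return an object of class `pipeline_report`: list with `bmd` (one
#'   [bmd_analysis()] result per endpoint/organ), `curves` (converted
#'   curves), `exposure` (an [summarize_exposure()] or `NULL`),
#'   `margins` (data frame or `NULL`), `log` (character).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_config(config)
  t0 <- Sys.time()
  log <- character()
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    log <<- c(log, msg)
    message(msg)
  }
  cfg_hash <- substr(digest_config(config), 1, 12)
  say("pipeline start (species %s, config %s)", config$species, cfg_hash)

  say("stage 1/5: kinetic parameters")
  cmp <- tryCatch({
    cmp <- compound_defaults(config$species)
    if (!is.null(config$kinetics)) {
      sf <- scaling_factors(config$species)
      if (!is.null(config$kinetics$microsomes)) {
        ds <- read_kinetic_csv(config$kinetics$microsomes, config$species)
        cmp$parent$rhein_formation <-
          fit_michaelis_menten(ds, "rhein_formation", config$species)
        say("  refitted rhein-formation kinetics from %s",
            config$kinetics$microsomes)
      }
      if (!is.null(config$kinetics$depletion)) {
        dep <- read_depletion_csv(config$kinetics$depletion,
                                  config$kinetics$cell_density %||% 0.5)
        ce <- clint_from_depletion(dep)
        cmp$metabolite$clint_invivo <-
          scale_clint(ce$clint_invitro, sf$hepatocellularity,
                      sf$liver_mass_g / 1000)
        say("  refitted metabolite clearance from %s",
            config$kinetics$depletion)
      }
    }
    cmp
  }, error = function(e) stop("pipeline stage 1 (kinetics) failed: ",
                              conditionMessage(e)))

  say("stage 2/5: PBK model assembly")
  model <- tryCatch(
    build_pbk(species_physiology(config$species), cmp$parent, cmp$metabolite),
    error = function(e) stop("pipeline stage 2 (PBK) failed: ",
                             conditionMessage(e)))

  say("stage 3/5: QIVIVE conversion")
  rpfs <- rpf_table()
  curves <- list(); results <- list()
  for (ep in names(config$endpoints)) {
    epc <- config$endpoints[[ep]]
    row <- rpfs[rpfs$endpoint == ep, ]
    if (nrow(row) == 0)
      stop("pipeline stage 3 (QIVIVE) failed: no RPF available for ",
           "endpoint '", ep, "'")
    organ <- epc$organ %||% row$organ
    curve <- load_curve(epc$curve)
    conv <- convert_curve(curve, epc$fbs %||% 10, model, row$rpf_rhein, organ)
    curves[[paste(ep, organ, sep = "_")]] <- conv
    say("  %s (%s): %d concentration levels converted", ep, organ,
        nrow(attr(conv, "dose_map")))
  }

  say("stage 4/5: BMD analysis")
  for (nm in names(curves)) {
    results[[nm]] <- tryCatch(
      bmd_analysis(curves[[nm]], family = config$bmd$family,
                   bmr = config$bmd$bmr, n_boot = config$bmd$n_boot,
                   seed = config$bmd$seed),
      error = function(e) stop("pipeline stage 4 (BMD) failed for ", nm,
                               ": ", conditionMessage(e)))
    say("  %s: BMD %.4g [%.4g, %.4g] mg/kg bw", nm, results[[nm]]$bmd,
        results[[nm]]$bmdl, results[[nm]]$bmdu)
  }

  exposure <- NULL; margins <- NULL
  if (!is.null(config$scenarios)) {
    say("stage 5/5: exposure comparison")
    scen <- read.csv(config$scenarios, stringsAsFactors = FALSE)
    exposure <- summarize_exposure(scen)
    margins <- do.call(rbind, lapply(names(results), function(nm) {
      data.frame(endpoint = nm, bmdl = results[[nm]]$bmdl,
                 edi_p95 = exposure$p95,
                 margin_p95 = margin_of_exposure(results[[nm]]$bmdl,
                                                 exposure$p95))
    }))
  } else say("stage 5/5: exposure comparison skipped (no scenarios)")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(curves))
      write_curve_csv(curves[[nm]],
                      file.path(config$out_dir, paste0("invivo_", nm, ".csv")))
    bmd_df <- do.call(rbind, lapply(names(results), function(nm)
      data.frame(endpoint_organ = nm, model = results[[nm]]$model_name,
                 bmd = results[[nm]]$bmd, bmdl = results[[nm]]$bmdl,
                 bmdu = results[[nm]]$bmdu, units = "mg/kg bw/day")))
    write.csv(bmd_df, file.path(config$out_dir, "bmd_results.csv"),
              row.names = FALSE)
    if (!is.null(margins))
      write.csv(margins, file.path(config$out_dir, "margins.csv"),
                row.names = FALSE)
    writeLines(c(sprintf("config_hash: %s", cfg_hash),
                 sprintf("seed: %s", config$bmd$seed),
                 sprintf("aepbk_version: %s",
                         as.character(utils::packageVersion("aepbk"))),
                 log),
               file.path(config$out_dir, "pipeline_log.txt"))
  }
  say("pipeline done in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
  structure(list(bmd = results, curves = curves, exposure = exposure,
                 margins = margins, model = model, log = log),
            class = "pipeline_report")
}

# Stable hash of the configuration (provenance only): serialize to
# canonical JSON and fold into a hex digest without external digest deps.
digest_config <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  bytes <- as.numeric(charToRaw(s))
  h <- c(17, 31, 73, 127)
  for (i in seq_along(bytes)) {
    j <- (i - 1) %% 4 + 1
    h[j] <- (h[j] * 131 + bytes[i]) %% 2147483647
  }
  paste(sprintf("%08x", as.integer(h)), collapse = "")
}
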