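# Pipeline orchestration: run a chain of analyses from a single config and
# collect a versioned report with units, seeds, and a reproducibility hash.

#' Validate an analysis configuration
#'
#' A configuration is a named list (or a YAML file with the same structure)
#' with a `stages` list; each stage is a list with a `stage` name plus
#' stage-specific parameters. Supported stages: `synthetic_membrane`,
#' `observables`, `mechanics_rsf`, `compressibility`, `defects`,
#' `isotherm_mixing`, `flicker`.
#'
#' @param config A named list or a path to a YAML file.
#' @return The validated config (invisibly usable downstream).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  if (is.null(config$stages) || length(config$stages) == 0L)
    stop("config declares no stages")
  known <- c("synthetic_membrane", "observables", "mechanics_rsf",
             "compressibility", "defects", "isotherm_mixing", "flicker")
  for (s in config$stages) {
    if (is.null(s$stage)) stop("every stage needs a `stage` name")
    if (!(s$stage %in% known))
      stop("unknown stage '", s$stage, "'; known: ",
           paste(known, collapse = ", "))
  }
  boltz <- c("mechanics_rsf", "compressibility", "flicker")
  needs_T <- any(vapply(config$stages, function(s) s$stage %in% boltz,
                        logical(1L)))
  if (needs_T && is.null(config$temperature))
    stop("config must declare `temperature` when a Boltzmann-relation stage",
         " is requested")
  for (p in config$input_paths)
    if (!file.exists(p)) stop("input path does not exist: ", p)
  if (is.null(config$seed)) config$seed <- 1L
  config
}

default_or <- function(x, default) if (is.null(x)) default else x

#' Run an analysis pipeline from a configuration
#'
#' Stages execute in the order given, sharing state (a generated or loaded
#' frame series, its leaflet assignment, sample pools). Every numeric
#' result carries a unit; the report records the seed, the package version
#' and an md5 hash of the canonical JSON serialization, so identical
#' configs yield identical report hashes. A failing stage aborts with the
#' stage name; completed stages are attached to the error condition as
#' `partial_report`.
#'
#' @param config A named list or YAML path accepted by [validate_config()].
#' @return A list of class `pipeline_report`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  state <- new.env(parent = emptyenv())
  report <- list(package_version = as.character(utils::packageVersion("membramech")),
                 seed = config$seed, stages = list())
  for (k in seq_along(config$stages)) {
    s <- config$stages[[k]]
    res <- tryCatch(run_stage(s, config, state), error = function(e) {
      err <- simpleError(paste0("stage '", s$stage, "' failed: ",
                                conditionMessage(e)))
      err$partial_report <- report
      stop(err)
    })
    report$stages[[s$stage]] <- res
  }
  report$config_hash <- report_hash(config)
  report$report_hash <- report_hash(report$stages)
  class(report) <- "pipeline_report"
  report
}

run_stage <- function(s, config, state) {
  temperature <- default_or(config$temperature, 303.15)
  switch(s$stage,
    synthetic_membrane = {
      gen <- make_lattice_membrane(
        n_lipids_per_leaflet = default_or(s$n_lipids_per_leaflet, 324L),
        apl = default_or(s$apl, 60.7),
        thickness = default_or(s$thickness, 37.8),
        z_sigma = default_or(s$z_sigma, 1),
        d_coeff = default_or(s$d_coeff, 7.7),
        tilt_sigma = default_or(s$tilt_sigma, 0.15),
        n_frames = default_or(s$n_frames, 50L),
        dt = default_or(s$dt, 0.1),
        temperature = temperature,
        seed = config$seed)
      state$frames <- gen$frames
      state$topology <- gen$topology
      state$leaflets <- assign_leaflets(gen$frames, gen$topology)
      list(n_lipids = 2L * gen$params$n_per_leaflet,
           box_A = gen$params$box, n_frames = n_frames(gen$frames))
    },
    observables = {
      need_frames(state)
      refs <- reference_points(state$frames, state$topology)
      apl <- area_per_lipid(state$frames, state$leaflets, state$topology,
                            refs = refs)
      mt <- membrane_thickness(state$frames, state$leaflets, state$topology,
                               atom_tag = default_or(s$atom_tag, "P"))
      inter <- interdigitation(state$frames, state$leaflets, state$topology)
      out <- list(
        APL = list(value = as.numeric(apl$system_apl), unit = "A^2",
                   se = apl$system_apl_se),
        MT = list(value = as.numeric(mt$thickness), unit = "nm", sd = mt$sd),
        interdigitation = list(value = as.numeric(inter$width), unit = "A",
                               sd = inter$sd))
      if (n_frames(state$frames) >= 20L) {
        D <- lateral_diffusion(state$frames, state$leaflets, state$topology,
                               refs = refs)
        out$D <- list(value = as.numeric(D$D), unit = "um^2/s", se = D$D_se)
      }
      state$refs <- refs
      out
    },
    mechanics_rsf = {
      need_frames(state)
      samples <- tilt_splay_samples(state$frames, state$leaflets,
                                    state$topology, refs = state$refs)
      apl <- default_or(s$apl, 60.7)
      out <- list(pair_filter = as.list(samples$pair_filter_log))
      out$kappa_tilt <- tryCatch({
        m <- fit_tilt_modulus(samples, temperature)
        list(value = as.numeric(m$value), unit = "J", se = m$uncertainty)
      }, error = function(e) list(error = conditionMessage(e)))
      out$kappa <- tryCatch({
        m <- fit_bending_rigidity_rsf(samples, temperature, apl = apl)
        list(value = as.numeric(m$value), unit = "J", se = m$uncertainty)
      }, error = function(e) list(error = conditionMessage(e)))
      out
    },
    compressibility = {
      series <- if (!is.null(s$ka)) {
        sample_thickness_series(ka = s$ka, a0 = default_or(s$a0, 60.7),
                                t0 = default_or(s$t0, 3.78),
                                temperature = temperature,
                                n = default_or(s$n, 1e4),
                                seed = config$seed)
      } else stop("compressibility stage needs a `ka` target or input data")
      r <- area_compressibility(series)
      list(KA = list(value = as.numeric(r$KA), unit = "mN/m", se = r$KA_se,
                     convention = r$convention))
    },
    defects = {
      need_frames(state)
      grid <- occupancy_grid(state$frames, state$leaflets, state$topology,
                             frame = default_or(s$frame, 1L),
                             leaflet = default_or(s$leaflet, "upper"),
                             spacing = default_or(s$spacing, 0.5))
      radii <- default_or(s$radii, seq(0.1, 0.5, by = 0.1))
      curve <- probe_defect_fraction(grid, radii)
      list(F_exp = exposed_fraction(grid),
           defect_curve = as.list(stats::setNames(curve$fraction,
                                                  paste0("r_", curve$radius_nm))))
    },
    isotherm_mixing = {
      comps <- lapply(seq_along(default_or(s$component_moduli, c(59, 648))),
                      function(i) {
        make_isotherm("exponential", A0 = default_or(s$A0, 80),
                      k = s$component_moduli[[i]],
                      composition = stats::setNames(1, paste0("C", i)),
                      seed = config$seed + i)
      })
      fr <- default_or(s$fractions, c(0.8, 0.2))
      mixed <- make_mixed_isotherm(comps, fr, delta = default_or(s$delta, 0),
                                   seed = config$seed)
      mix <- excess_free_energy(mixed, comps, fr,
                                pi_max = default_or(s$pi_max, 33))
      list(apl_at_33 = list(value = as.numeric(apl_at_pressure(mixed, 33)),
                            unit = "A^2"),
           modulus = list(value = as.numeric(
             compressibility_modulus(mixed, 33)$modulus), unit = "mN/m"),
           dG_excess_at_max = list(value = mix$dG_excess[nrow(mix)],
                                   unit = "J/mol"))
    },
    flicker = {
      contours <- make_fluctuating_vesicle(
        kappa = default_or(s$kappa, 1.9e-19),
        sigma_bar = default_or(s$sigma_bar, 10),
        R = default_or(s$R, 5),
        temperature = temperature,
        n_frames = default_or(s$n_frames, 1200L),
        seed = config$seed)
      spec <- spectrum_statistical(contours,
                                   n_modes = default_or(s$n_modes, 20L))
      fit <- fit_bending_rigidity(spec,
                                  mode_range = default_or(s$mode_range,
                                                          c(3L, 20L)))
      list(kappa = list(value = as.numeric(fit$kappa), unit = "J",
                        se = fit$kappa_se),
           sigma_bar = fit$sigma_bar)
    })
}

need_frames <- function(state) {
  if (is.null(state$frames))
    stop("no frame series in pipeline state; run a `synthetic_membrane` ",
         "stage or load frames first")
}

# md5 of the canonical JSON serialization (fixed precision).
report_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = 12, force = TRUE)
  unname(tools::md5sum(tf))
}

#' Write a pipeline report as JSON
#'
#' @param report A `pipeline_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = 12, force = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> stages:", paste(names(x$stages), collapse = ", "),
      "\n  seed:", x$seed, " report hash:", x$report_hash, "\n")
  invisible(x)
}
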