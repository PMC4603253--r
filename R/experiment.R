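#' Build an isolated rhythm-generating population
#'
#' A single flexor rhythm-generating population with sparse recurrent
#' excitation and no other circuitry; the standard preparation for mapping
#' the silence / bursting / tonic regime structure along a leak-reversal
#' ramp.
#'
#' @inheritParams build_model1
#' @return A \code{\link{network_spec}} with one population
#'   (\code{"l-RG-F"}).
#' @export
build_isolated_rg <- function(size_overrides = list(),
                              config = cpg_defaults()) {
  row <- config$populations[config$populations$role == "RG-F", ]
  pop <- pop_from_defaults(config, "left", "RG-F",
                           size = resolve_size(size_overrides, "RG-F",
                                               row$size))
  network_spec(list(pop),
               list(projection_spec("l-RG-F", "l-RG-F", "excitatory",
                                    config$p_connect,
                                    config$weights$rg_recurrent)))
}

#' Preset experiment catalog
#'
#' Declarative configurations reproducing the package's standard in-silico
#' experiments: the isolated-RG ramp, the intact Model 1 / Model 2 ramps,
#' the commissural-ablation series, the axon-guidance knockouts, the
#' unified-architecture V1/V2b experiments, and the burst-deletion probes.
#'
#' @param model core architecture for the ablation, knockout and unified
#'   presets (\code{"model1"} or \code{"model2"}).
#' @param config parameter configuration.
#' @return Named list of experiment configurations consumable by
#'   \code{\link{run_experiment}}.
#' @export
preset_catalog <- function(model = "model1", config = cpg_defaults()) {
  d <- config$drive
  ramp <- list(alpha_start = d$ramp[1], alpha_end = d$ramp[2],
               duration = d$ramp_duration)
  const <- list(alpha_start = d$mid, alpha_end = d$mid,
                duration = d$constant_duration)
  probe_alpha <- list(alpha_start = d$probe, alpha_end = d$probe,
                      duration = 90000)
  list(
    fig5_isolated_rg = list(
      architecture = "isolated_rg",
      protocol = list(alpha_start = d$fig5_ramp[1],
                      alpha_end = d$fig5_ramp[2],
                      duration = d$ramp_duration)),
    model1_ramp = list(architecture = "model1", protocol = ramp),
    model2_ramp = list(architecture = "model2", protocol = ramp),
    ablate_v0_both = list(architecture = model, protocol = ramp,
                          lesion = list(removed_roles = c("V0D", "V0V"))),
    ablate_v0v = list(architecture = model, protocol = ramp,
                      lesion = list(removed_roles = "V0V")),
    ablate_v2a = list(architecture = model, protocol = ramp,
                      lesion = list(removed_roles = "V2a")),
    ablate_v0d = list(architecture = model, protocol = ramp,
                      lesion = list(removed_roles = "V0D")),
    ko_netrin1 = list(architecture = model, protocol = ramp,
                      knockout = list(type = "Netrin1", f_reroute = 0.8)),
    ko_dcc = list(architecture = model, protocol = ramp,
                  knockout = list(type = "DCC", f_reroute = 0.8)),
    ko_epha4 = list(architecture = "model1", protocol = ramp,
                    knockout = list(type = "EphA4", f_reroute = 0.8)),
    unified_intact = list(architecture = "unified", core = model,
                          protocol = const),
    unified_v1_silence = list(architecture = "unified", core = model,
                              protocol = const,
                              lesion = list(removed_roles = "V1")),
    unified_v1v2b_silence = list(architecture = "unified", core = model,
                                 protocol = const,
                                 lesion = list(removed_roles = c("V1", "V2b"))),
    hemicord = list(architecture = "unified", core = model,
                    protocol = const,
                    lesion = list(hemisection_side = "left")),
    hemicord_v2b_silence = list(architecture = "unified", core = model,
                                protocol = const,
                                lesion = list(removed_roles = "V2b",
                                              hemisection_side = "left")),
    deletion_probe_flexor = list(
      architecture = model, protocol = probe_alpha,
      deletion_type = "flexor",
      perturbations = list(list(target = "l-RG-F", relative_onset = 0.55,
                                cycles = 1.6, sign = "inhibitory",
                                amplitude = 3))),
    deletion_probe_extensor = list(
      architecture = model, protocol = probe_alpha,
      deletion_type = "extensor",
      perturbations = list(list(target = "l-RG-E", relative_onset = 0.55,
                                cycles = 1.6, sign = "inhibitory",
                                amplitude = 3)))
  )
}

#' Digest of a configuration
#'
#' MD5 digest of the canonical JSON serialization; used to tag every output
#' file of a run.
#'
#' @param x any jsonlite-serializable object.
#' @return Hex digest string.
#' @export
config_digest <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = 12, null = "null")
  unname(tools::md5sum(f))
}

# Materialize every default into an experiment configuration so that the
# stored config is self-describing.
resolve_experiment_config <- function(preset = NULL, config_list = NULL,
                                      overrides = list(), seed = 1,
                                      scale = 1, model = "model1",
                                      defaults = cpg_defaults()) {
  cfg <- if (!is.null(preset)) {
    cat_ <- preset_catalog(model = model, config = defaults)
    if (!preset %in% names(cat_))
      stop("unknown preset: ", preset, "; available: ",
           paste(names(cat_), collapse = ", "))
    cat_[[preset]]
  } else if (!is.null(config_list)) config_list
  else stop("either a preset name or a config must be given")
  cfg <- utils::modifyList(cfg, overrides)
  cfg$preset <- preset
  cfg$seed <- as.integer(seed)
  cfg$scale <- scale
  if (is.null(cfg$sim)) cfg$sim <- list()
  if (is.null(cfg$sim$dt)) cfg$sim$dt <- 0.1
  if (is.null(cfg$sim$noise_sigma)) cfg$sim$noise_sigma <- 0
  if (is.null(cfg$analysis)) cfg$analysis <- list()
  if (is.null(cfg$analysis$window)) cfg$analysis$window <- 20000
  if (is.null(cfg$analysis$bin)) cfg$analysis$bin <- 100
  if (is.null(cfg$analysis$skip)) cfg$analysis$skip <- 10000
  if (is.null(cfg$size_overrides)) cfg$size_overrides <- list()
  cfg
}

#' Run a preset or configured experiment
#'
#' Builds the network, applies any knockout and lesion (in that order),
#' scales it, realizes the connectome, simulates the drive protocol and
#' analyses the spike record.  The whole pipeline is deterministic for a
#' fixed seed.
#'
#' @param preset preset name (see \code{\link{preset_catalog}}), or NULL
#'   when \code{config} is given.
#' @param config explicit experiment configuration list (as in the catalog).
#' @param overrides named list merged over the preset configuration.
#' @param seed integer seed controlling connectome realization, initial
#'   conditions and any noise.
#' @param scale population-size scale factor (connection probabilities are
#'   rescaled to preserve expected in-degrees; see
#'   \code{\link{scale_network}}).
#' @param model core architecture used by presets that are model-agnostic.
#' @return An object of class \code{experiment_result}: the materialized
#'   config and its digest, the network spec, spike record, activity trace,
#'   and the analyses that apply (windowed coordination report, regime
#'   profile and frequency/amplitude series for single-population runs,
#'   deletion report for probe runs).
#' @export
run_experiment <- function(preset = NULL, config = NULL, overrides = list(),
                           seed = 1, scale = 1, model = "model1") {
  defaults <- cpg_defaults()
  cfg <- resolve_experiment_config(preset, config, overrides, seed, scale,
                                   model, defaults)

  spec <- switch(cfg$architecture,
    isolated_rg = build_isolated_rg(cfg$size_overrides, defaults),
    model1 = build_model1(cfg$size_overrides, defaults),
    model2 = build_model2(cfg$size_overrides, defaults),
    unified = build_unified(if (is.null(cfg$core)) "model1" else cfg$core,
                            cfg$size_overrides, defaults),
    stop("unknown architecture: ", cfg$architecture))
  if (!is.null(cfg$knockout))
    spec <- apply_knockout(spec, knockout_spec(cfg$knockout$type,
                                               cfg$knockout$f_reroute))
  if (!is.null(cfg$lesion)) {
    les <- cfg$lesion
    spec <- apply_lesion(spec, lesion_spec(
      removed_roles = if (is.null(les$removed_roles)) character(0)
                      else les$removed_roles,
      sides = les$sides,
      hemisection_side = if (is.null(les$hemisection_side)) "none"
                         else les$hemisection_side))
  }
  if (scale != 1) spec <- scale_network(spec, scale)

  conn <- instantiate(spec, seed = seed, config = defaults)

  prot <- alpha_ramp(cfg$protocol$alpha_start, cfg$protocol$alpha_end,
                     cfg$protocol$duration)
  # deletion probes: pulse length is stated in expected cycles; convert
  # using a calibration window of the unperturbed rhythm
  if (!is.null(cfg$perturbations)) {
    for (pp in cfg$perturbations) {
      onset <- pp$relative_onset * cfg$protocol$duration
      dur <- if (!is.null(pp$duration)) pp$duration else {
        period <- estimate_period(conn, prot, cfg, onset)
        pp$cycles * period
      }
      prot <- add_perturbation(prot, perturbation_spec(
        pp$target, onset, dur, pp$sign, pp$amplitude))
    }
  }

  scfg <- simulation_config(dt = cfg$sim$dt, duration = cfg$protocol$duration,
                            seed = seed, noise_sigma = cfg$sim$noise_sigma)
  record <- simulate(conn, prot, scfg)
  cfg$digest <- NULL
  digest <- config_digest(cfg)

  trace <- rate_histogram(record, bin = cfg$analysis$bin)
  result <- list(config = cfg, digest = digest, spec = spec,
                 connectome = conn, record = record, trace = trace)

  have <- colnames(trace$rate)
  if (any(grepl("RG-E", have))) {
    result$coordination <- coordination_report(
      record, window = cfg$analysis$window, bin = cfg$analysis$bin,
      skip = cfg$analysis$skip)
  } else {
    bursts <- detect_bursts(trace, have[1])
    result$bursts <- bursts
    result$regimes <- regime_profile(trace, bursts, have[1])
    result$freq_amp <- frequency_amplitude_series(
      bursts, window = 10000, duration = record$duration)
  }

  if (!is.null(cfg$perturbations) && !is.null(cfg$deletion_type)) {
    pp <- cfg$perturbations[[1]]
    onset <- pp$relative_onset * cfg$protocol$duration
    side <- substr(pp$target, 1, 2)
    target_pop <- pp$target
    antagonist <- if (cfg$deletion_type == "flexor")
      paste0(side, "RG-E") else paste0(side, "RG-F")
    contra <- mirror_name(target_pop)
    bt <- detect_bursts(trace, target_pop)
    bc <- detect_bursts(trace, contra)
    result$deletions <- tryCatch(
      classify_deletions(bt, trace, antagonist, bc, fit_end = onset,
                         type = cfg$deletion_type),
      error = function(e) e)
  }
  class(result) <- "experiment_result"
  result
}

# Short unperturbed pilot run to estimate the cycle period at the probe's
# working drive (used to size deletion pulses in cycle units).
estimate_period <- function(conn, prot, cfg, until) {
  scfg <- simulation_config(dt = cfg$sim$dt, duration = until,
                            seed = cfg$seed)
  rec <- simulate(conn, drive_protocol(prot$times, prot$alpha,
                                       prot$duration), scfg)
  tr <- rate_histogram(rec, bin = cfg$analysis$bin)
  pop <- if ("l-RG-F" %in% colnames(tr$rate)) "l-RG-F"
         else colnames(tr$rate)[1]
  b <- detect_bursts(tr, pop)
  if (nrow(b) < 4) stop("cannot estimate cycle period: too few bursts")
  mean(diff(b$onset))
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Experiment %s (digest %s)\n",
              if (is.null(x$config$preset)) "<custom>" else x$config$preset,
              substr(x$digest, 1, 8)))
  print(x$record)
  if (!is.null(x$coordination)) {
    cat("Coordination labels (left-right / flexor-extensor) per window:\n")
    print(x$coordination[, c("t_mid", "frequency", "lr_label", "fe_label")])
  }
  if (!is.null(x$regimes)) {
    cat("Regime profile:", paste(rle(x$regimes$regime)$values,
                                 collapse = " -> "), "\n")
  }
  invisible(x)
}
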