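#' Simulation configuration
#'
#' @param dt integration step (ms).
#' @param duration simulated time (ms).
#' @param seed integer seed for initial conditions and membrane noise.
#' @param noise_sigma standard deviation (nS) of the optional
#'   Ornstein-Uhlenbeck excitatory conductance noise; 0 disables it.
#' @param noise_tau OU correlation time (ms).
#' @param record_V character vector of population names whose first
#'   neuron's voltage trace is recorded (or \code{"pop#k"} for neuron k).
#' @param record_dt trace sampling interval (ms).
#' @return An object of class \code{simulation_config}.
#' @export
simulation_config <- function(dt = 0.1, duration = 10000, seed = 1,
                              noise_sigma = 0, noise_tau = 50,
                              record_V = character(0), record_dt = 1) {
  stopifnot(dt > 0, duration >= dt, noise_tau > 0, noise_sigma >= 0)
  structure(list(dt = dt, duration = duration, seed = as.integer(seed),
                 noise_sigma = noise_sigma, noise_tau = noise_tau,
                 record_V = record_V, record_dt = record_dt),
            class = "simulation_config")
}

resolve_record_neurons <- function(conn, record_V) {
  if (length(record_V) == 0) return(integer(0))
  pt <- conn$populations
  vapply(record_V, function(spec) {
    parts <- strsplit(spec, "#", fixed = TRUE)[[1]]
    name <- parts[1]
    k <- if (length(parts) > 1) as.integer(parts[2]) else 1L
    row <- pt[pt$name == name, ]
    if (nrow(row) == 0) stop("record_V names a missing population: ", name)
    if (k > row$size) stop("record_V neuron index exceeds population size")
    as.integer(row$offset + k - 1L)       # 0-based for the engine
  }, integer(1), USE.NAMES = FALSE)
}

expand_perturbations <- function(conn, protocol) {
  perts <- protocol$perturbations
  if (length(perts) == 0)
    return(list(neuron = integer(0), on = numeric(0), off = numeric(0),
                gE = numeric(0), gI = numeric(0)))
  pt <- conn$populations
  neuron <- integer(0); on <- numeric(0); off <- numeric(0)
  gE <- numeric(0); gI <- numeric(0)
  for (p in perts) {
    row <- pt[pt$name == p$target, ]
    if (nrow(row) == 0) next                 # target lesioned away: no-op
    idx <- row$offset + seq_len(row$size) - 1L
    neuron <- c(neuron, idx)
    on <- c(on, rep(p$onset, row$size))
    off <- c(off, rep(p$onset + p$duration, row$size))
    if (p$sign == "excitatory") {
      gE <- c(gE, rep(p$amplitude, row$size)); gI <- c(gI, rep(0, row$size))
    } else {
      gE <- c(gE, rep(0, row$size)); gI <- c(gI, rep(p$amplitude, row$size))
    }
  }
  list(neuron = as.integer(neuron), on = on, off = off, gE = gE, gI = gI)
}

#' Simulate a connectome under a drive protocol
#'
#' Advances the full network with the compiled fixed-step
#' exponential-Euler engine.  The run is deterministic given the
#' connectome, protocol, seed and step size; synaptic events are delivered
#' with a fixed one-step delay; per-step effective leak reversals are
#' computed from the drive schedule via \code{\link{drive_to_leak}}.
#' Initial voltages are drawn uniformly within +/- 5 mV of each neuron's
#' initial effective leak reversal, with gates at steady state.
#'
#' @param connectome a \code{\link{instantiate}}d connectome.
#' @param protocol a \code{\link{drive_protocol}}; its duration must cover
#'   the configured simulation duration.
#' @param config a \code{\link{simulation_config}}.
#' @return An object of class \code{spike_record}: per-spike neuron indices
#'   and times (ms), the population table, run metadata, and any recorded
#'   voltage traces.
#' @export
simulate <- function(connectome, protocol, config = simulation_config()) {
  stopifnot(inherits(connectome, "connectome"),
            inherits(protocol, "drive_protocol"),
            inherits(config, "simulation_config"))
  if (protocol$duration < config$duration)
    stop("protocol duration is shorter than the simulation duration")

  rec_idx <- resolve_record_neurons(connectome, config$record_V)
  pe <- expand_perturbations(connectome, protocol)

  res <- .cpg_simulate_cpp(
    connectome$param_matrix,
    as.integer(connectome$neuron_pop),
    connectome$neuron_EL0,
    connectome$neuron_gain,
    connectome$neuron_gnap,
    connectome$syn_ptr, connectome$syn_target,
    connectome$syn_weight, connectome$syn_inhib,
    connectome$tonic_gE,
    pe$neuron, pe$on, pe$off, pe$gE, pe$gI,
    protocol$times, protocol$alpha,
    config$dt, config$duration, config$seed,
    config$noise_sigma, config$noise_tau,
    rec_idx, config$record_dt,
    numeric(0))

  structure(list(neuron = res$spike_neuron,
                 time = res$spike_time,
                 populations = connectome$populations,
                 duration = config$duration,
                 V = res$V, V_time = res$V_time,
                 V_names = config$record_V,
                 meta = list(dt = config$dt, seed = config$seed,
                             connectome_seed = connectome$seed,
                             noise_sigma = config$noise_sigma)),
            class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("Spike record: %d spikes, %d neurons, %.1f s (dt = %g ms, seed %d)\n",
              length(x$time), sum(x$populations$size), x$duration / 1000,
              x$meta$dt, x$meta$seed))
  invisible(x)
}

#' Extract one population's spikes
#'
#' @param record a \code{spike_record}.
#' @param population population name.
#' @return List with \code{neuron} (1-based, within population),
#'   \code{time} (ms) and \code{size}.
#' @export
population_spikes <- function(record, population) {
  pt <- record$populations
  row <- pt[pt$name == population, ]
  if (nrow(row) == 0) stop("unknown population: ", population)
  sel <- record$neuron > row$offset & record$neuron <= row$offset + row$size
  list(neuron = record$neuron[sel] - row$offset, time = record$time[sel],
       size = row$size)
}

#' Write spikes and population map as TSV
#'
#' @param record a \code{spike_record}.
#' @param spikes_path,popmap_path output files.
#' @param digest config digest echoed in the header.
#' @return Invisibly, the two paths.
#' @export
write_spikes <- function(record, spikes_path, popmap_path,
                         digest = NA_character_) {
  con <- file(spikes_path, "w")
  writeLines(sprintf("# spinalcpg spikes; dt=%g ms; seed=%d; digest=%s",
                     record$meta$dt, record$meta$seed, digest), con)
  utils::write.table(data.frame(neuron_id = record$neuron,
                                t_ms = record$time),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  utils::write.table(record$populations, popmap_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(spikes_path, popmap_path))
}
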