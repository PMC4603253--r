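#' Write an experiment result to disk
#'
#' Writes, per recorded population, a spike TSV and a rate-trace TSV, plus
#' the structured reports as JSON (coordination, regimes,
#' frequency/amplitude, deletions, as available), a run log, and a manifest
#' (JSON) carrying the config digest and tool version.  All files embed the
#' digest so outputs are self-describing.
#'
#' @param result an \code{\link{run_experiment}} result.
#' @param dir output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
write_outputs <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  digest <- result$digest
  files <- character(0)
  header <- sprintf("# spinalcpg %s; digest=%s",
                    as.character(utils::packageVersion("spinalcpg")), digest)

  pops <- if (is.null(result$record)) character(0)
          else result$record$populations$name
  for (p in pops) {
    safe <- gsub("[^A-Za-z0-9]+", "_", p)
    sp <- population_spikes(result$record, p)
    f1 <- file.path(dir, paste0(safe, "_spikes.tsv"))
    con <- file(f1, "w")
    writeLines(header, con)
    utils::write.table(data.frame(neuron_id = sp$neuron, t_ms = sp$time),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    f2 <- file.path(dir, paste0(safe, "_trace.tsv"))
    con <- file(f2, "w")
    writeLines(header, con)
    utils::write.table(data.frame(t_ms = result$trace$time,
                                  rate = result$trace$rate[, p]),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    files <- c(files, f1, f2)
  }

  write_report <- function(obj, name) {
    f <- file.path(dir, name)
    payload <- list(digest = digest, data = obj)
    jsonlite::write_json(payload, f, auto_unbox = TRUE, digits = 8,
                         null = "null", na = "null", force = TRUE)
    files <<- c(files, f)
  }
  if (!is.null(result$coordination))
    write_report(as.data.frame(result$coordination), "coordination.json")
  if (!is.null(result$regimes))
    write_report(result$regimes, "regimes.json")
  if (!is.null(result$freq_amp))
    write_report(result$freq_amp, "frequency_amplitude.json")
  if (!is.null(result$deletions) && !inherits(result$deletions, "error"))
    write_report(as.data.frame(result$deletions), "deletions.json")

  log_path <- file.path(dir, "run.log")
  writeLines(c(header,
               sprintf("seed=%s", result$config$seed),
               sprintf("scale=%s", result$config$scale),
               sprintf("dt_ms=%s", result$config$sim$dt),
               sprintf("duration_ms=%s", result$config$protocol$duration),
               sprintf("analysis_window_ms=%s", result$config$analysis$window),
               sprintf("n_spikes=%d", length(result$record$time))),
             log_path)

  manifest <- list(tool = "spinalcpg",
                   version = as.character(utils::packageVersion("spinalcpg")),
                   digest = digest,
                   config = result$config,
                   files = basename(files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 12, null = "null",
                       na = "null")
  invisible(manifest)
}

#' Read spikes written by \code{\link{write_outputs}} back into a record
#'
#' @param spikes_paths named character vector of per-population spike TSVs
#'   (names are population names).
#' @param sizes named integer vector of population sizes.
#' @param duration record duration (ms).
#' @return A \code{spike_record} suitable for re-analysis with new
#'   thresholds.
#' @export
read_spike_record <- function(spikes_paths, sizes, duration) {
  stopifnot(length(spikes_paths) == length(sizes))
  pops <- names(spikes_paths)
  offsets <- c(0L, cumsum(unname(sizes)))[seq_along(sizes)]
  neuron <- integer(0); time <- numeric(0)
  for (i in seq_along(pops)) {
    d <- utils::read.table(spikes_paths[i], header = TRUE, sep = "\t",
                           comment.char = "#")
    neuron <- c(neuron, d$neuron_id + offsets[i])
    time <- c(time, d$t_ms)
  }
  structure(list(neuron = as.integer(neuron), time = time,
                 populations = data.frame(name = pops, role = NA, side = NA,
                                          size = unname(sizes),
                                          offset = offsets,
                                          stringsAsFactors = FALSE),
                 duration = duration,
                 meta = list(dt = NA_real_, seed = NA_integer_)),
            class = "spike_record")
}
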