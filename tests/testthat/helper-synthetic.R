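# Synthetic records and burst series used across tests.

# spike record with given per-neuron spike times (list indexed by neuron)
synth_record <- function(times_by_neuron, n_neurons, duration,
                         population = "pop") {
  neuron <- rep(seq_along(times_by_neuron),
                vapply(times_by_neuron, length, 0L))
  spinalcpg:::spike_record_from_times(unlist(times_by_neuron),
                                      n_neurons = n_neurons,
                                      duration = duration,
                                      population = population,
                                      neuron = neuron)
}

# activity trace straight from a rate vector (bin in ms)
synth_trace <- function(rate, bin = 100, population = "pop") {
  structure(list(time = (seq_along(rate) - 0.5) * bin,
                 rate = matrix(rate, ncol = 1,
                               dimnames = list(NULL, population)),
                 bin = bin, sizes = 50L,
                 duration = length(rate) * bin),
            class = "activity_trace")
}

# burst series from onset/offset vectors (ms)
synth_bursts <- function(onset, offset, peak = NULL, duration = NULL) {
  if (is.null(peak)) peak <- rep(10, length(onset))
  if (is.null(duration)) duration <- max(offset) + 1000
  structure(data.frame(onset = onset, offset = offset, peak = peak),
            class = c("burst_series", "data.frame"),
            bin = 100, population = "pop", duration = duration)
}

# square-wave rate trace: period and duty in ms fractions
synth_square <- function(n_bins, period_bins, duty_bins, amp = 20,
                         bin = 100) {
  phase <- (seq_len(n_bins) - 1) %% period_bins
  synth_trace(ifelse(phase < duty_bins, amp, 0), bin = bin)
}
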