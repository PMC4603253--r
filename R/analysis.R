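#' Population rate histogram
#'
#' Converts a spike record into per-population mean firing-rate time series
#' in spikes/(neuron x s): the count of population spikes in each bin
#' divided by population size and bin length.
#'
#' @param record a \code{spike_record}.
#' @param bin bin width (ms), default 100.
#' @param populations population names to include (default all).
#' @return An object of class \code{activity_trace}: \code{time} (bin
#'   centers, ms), \code{rate} (matrix, bins x populations), \code{bin}
#'   (ms), \code{sizes}.
#' @export
rate_histogram <- function(record, bin = 100, populations = NULL) {
  stopifnot(bin > 0)
  pt <- record$populations
  if (is.null(populations)) populations <- pt$name
  if (any(pt$size[match(populations, pt$name)] == 0))
    stop("empty population in rate histogram")
  nb <- ceiling(record$duration / bin)
  rate <- matrix(0, nrow = nb, ncol = length(populations),
                 dimnames = list(NULL, populations))
  for (p in populations) {
    row <- pt[pt$name == p, ]
    if (nrow(row) == 0) stop("unknown population: ", p)
    sel <- record$neuron > row$offset & record$neuron <= row$offset + row$size
    tt <- record$time[sel]
    tt <- tt[tt >= 0 & tt < record$duration]
    if (length(tt) > 0) {
      idx <- pmin(nb, floor(tt / bin) + 1L)
      cnt <- tabulate(idx, nbins = nb)
      rate[, p] <- cnt / (row$size * bin / 1000)
    }
  }
  structure(list(time = (seq_len(nb) - 0.5) * bin, rate = rate, bin = bin,
                 sizes = pt$size[match(populations, pt$name)],
                 duration = record$duration),
            class = "activity_trace")
}

# Rolling reference level (90th percentile over a sliding window) and the
# derived hysteresis thresholds, floored so silent stretches do not yield
# zero thresholds.
burst_thresholds <- function(x, bin, on_frac = 0.30, off_frac = 0.15,
                             ref_window = 20000, ref_quantile = 0.9,
                             floor_rate = 0.5) {
  w <- max(3L, round(ref_window / bin))
  ref <- zoo::rollapply(zoo::zoo(x), width = w,
                        FUN = stats::quantile, probs = ref_quantile,
                        names = FALSE, partial = TRUE, align = "center")
  ref <- as.numeric(ref)
  list(on = pmax(on_frac * ref, floor_rate),
       off = pmax(off_frac * ref, floor_rate * off_frac / on_frac),
       ref = ref)
}

#' Detect population bursts by hysteresis thresholding
#'
#' Thresholds a rate trace against a running reference level (the 90th
#' percentile over a sliding window): a burst opens at an upward crossing of
#' \code{on_frac x reference} and closes at a downward crossing of
#' \code{off_frac x reference}.  Bursts shorter than \code{min_dur} are
#' discarded, as are stretches active at the trace boundaries without a
#' threshold crossing (so a constant, tonic trace yields zero bursts).
#'
#' @param trace an \code{\link{rate_histogram}} activity trace.
#' @param population column to analyse (default the first).
#' @param on_frac,off_frac hysteresis fractions, \code{0 < off_frac <
#'   on_frac <= 1}.
#' @param min_dur minimum burst duration (ms).
#' @param ref_window sliding reference window (ms).
#' @param floor_rate absolute floor (spikes/(neuron x s)) of the on
#'   threshold.
#' @return An object of class \code{burst_series}: data frame with columns
#'   \code{onset}, \code{offset} (ms) and \code{peak} (spikes/(neuron x s)),
#'   with the thresholds used attached as attributes.
#' @export
detect_bursts <- function(trace, population = NULL, on_frac = 0.30,
                          off_frac = 0.15, min_dur = 200,
                          ref_window = 20000, floor_rate = 0.5) {
  stopifnot(inherits(trace, "activity_trace"),
            off_frac > 0, off_frac < on_frac, on_frac <= 1)
  if (is.null(population)) population <- colnames(trace$rate)[1]
  x <- trace$rate[, population]
  th <- burst_thresholds(x, trace$bin, on_frac, off_frac, ref_window,
                         floor_rate = floor_rate)
  onset <- numeric(0); offset <- numeric(0); peak <- numeric(0)
  active <- FALSE
  open_from_start <- x[1] >= th$on[1]
  cur_on <- NA_real_; cur_peak <- -Inf
  tgrid <- trace$time - trace$bin / 2          # bin left edges
  for (i in seq_along(x)) {
    if (open_from_start) {                     # skip until first release
      if (x[i] < th$off[i]) open_from_start <- FALSE
      next
    }
    if (!active && x[i] >= th$on[i]) {
      active <- TRUE; cur_on <- tgrid[i]; cur_peak <- x[i]
    } else if (active) {
      cur_peak <- max(cur_peak, x[i])
      if (x[i] < th$off[i]) {
        active <- FALSE
        if (tgrid[i] - cur_on >= min_dur) {
          onset <- c(onset, cur_on); offset <- c(offset, tgrid[i])
          peak <- c(peak, cur_peak)
        }
      }
    }
  }
  # a stretch still active at the end has no closing crossing: discard
  res <- data.frame(onset = onset, offset = offset, peak = peak)
  structure(res, class = c("burst_series", "data.frame"),
            thresholds = th, bin = trace$bin, population = population,
            duration = trace$duration)
}

#' Classify a population trace as silence, bursting or tonic
#'
#' @param trace an \code{\link{rate_histogram}} activity trace.
#' @param bursts the matching \code{\link{detect_bursts}} series.
#' @param population column of the trace (default the burst series' own).
#' @param eps silence threshold on the mean rate (spikes/(neuron x s)).
#' @param min_window minimum observation window (ms).
#' @return One of \code{"silence"}, \code{"bursting"}, \code{"tonic"}.
#' @export
classify_regime <- function(trace, bursts, population = NULL, eps = 0.1,
                            min_window = 10000) {
  if (trace$duration < min_window)
    stop("window too short for regime classification")
  if (is.null(population)) population <- attr(bursts, "population")
  x <- trace$rate[, population]
  if (mean(x) < eps) return("silence")
  if (nrow(bursts) >= 3) {
    th <- attr(bursts, "thresholds")
    tgrid <- trace$time - trace$bin / 2
    troughs_ok <- TRUE
    for (i in seq_len(nrow(bursts) - 1)) {
      sel <- tgrid >= bursts$offset[i] & tgrid < bursts$onset[i + 1]
      if (any(sel) && !any(x[sel] < th$off[sel])) troughs_ok <- FALSE
    }
    if (troughs_ok) return("bursting")
  }
  "tonic"
}

#' Windowed regime profile along a drive ramp
#'
#' Labels consecutive windows of a trace as silence, bursting or tonic:
#' silence when the window mean rate is below \code{eps}; bursting when at
#' least one detected burst onset falls in the window; tonic otherwise
#' (sustained activity without burst structure).
#'
#' @inheritParams classify_regime
#' @param window window length (ms).
#' @return Data frame with columns \code{t_start}, \code{t_mid},
#'   \code{regime}.
#' @export
regime_profile <- function(trace, bursts, population = NULL, window = 10000,
                           eps = 0.1) {
  if (is.null(population)) population <- attr(bursts, "population")
  x <- trace$rate[, population]
  tgrid <- trace$time
  starts <- seq(0, trace$duration - window, by = window)
  regime <- vapply(starts, function(t0) {
    sel <- tgrid >= t0 & tgrid < t0 + window
    if (mean(x[sel]) < eps) return("silence")
    nb <- sum(bursts$onset >= t0 & bursts$onset < t0 + window)
    if (nb >= 1) "bursting" else "tonic"
  }, character(1))
  data.frame(t_start = starts, t_mid = starts + window / 2, regime = regime,
             stringsAsFactors = FALSE)
}

#' Windowed burst frequency and amplitude
#'
#' @param bursts a \code{\link{detect_bursts}} series.
#' @param window window length (ms).
#' @param duration total span (ms); defaults to the trace duration the
#'   bursts were detected on.
#' @return Data frame with \code{t_mid}, \code{frequency} (Hz, reciprocal of
#'   the mean inter-onset interval; NA where fewer than two onsets fall in
#'   the window) and \code{amplitude} (mean burst peak; NA where no burst).
#' @export
frequency_amplitude_series <- function(bursts, window = 10000,
                                       duration = attr(bursts, "duration")) {
  starts <- seq(0, duration - window, by = window)
  out <- lapply(starts, function(t0) {
    sel <- bursts$onset >= t0 & bursts$onset < t0 + window
    on <- bursts$onset[sel]
    freq <- if (length(on) >= 2) 1000 / mean(diff(on)) else NA_real_
    amp <- if (length(on) >= 1) mean(bursts$peak[sel]) else NA_real_
    c(freq, amp)
  })
  m <- do.call(rbind, out)
  data.frame(t_mid = starts + window / 2, frequency = m[, 1],
             amplitude = m[, 2])
}

circular_stats <- function(phases) {
  z <- mean(exp(2i * pi * phases))
  mu <- (Arg(z) / (2 * pi)) %% 1
  list(mean = mu, R = Mod(z))
}

#' Phase relation between two burst series
#'
#' For each reference cycle (onset to next onset), the phase of the other
#' series' onsets within the cycle is collected; the circular mean and
#' concentration R classify the relation: \code{"synchrony"} when the mean
#' phase lies within \code{tol} of 0 with R at least \code{R_min},
#' \code{"alternation"} when within \code{tol} of 0.5 with sufficient R,
#' \code{"uncoordinated"} otherwise (including phase locking at an
#' intermediate lag).
#'
#' @param ref,other \code{\link{detect_bursts}} series (data frames with an
#'   \code{onset} column).
#' @param min_cycles minimum number of reference cycles containing an event
#'   of the other series.
#' @param tol phase tolerance around 0 (synchrony) and 0.5 (alternation).
#' @param R_min concentration threshold.
#' @param window optional \code{c(t0, t1)} (ms) restricting both series.
#' @param event event used on both series: burst \code{"onset"}
#'   (homologous left-right pairs) or burst \code{"midpoint"} (midpoint to
#'   midpoint; robust for pairs with very different duty cycles, e.g.
#'   flexor vs extensor, where anti-phase operation yields 0.5 regardless
#'   of burst lengths).
#' @return List with \code{phase} (circular mean in [0,1)), \code{R},
#'   \code{n_cycles} and \code{label}.
#' @export
phase_relation <- function(ref, other, min_cycles = 5, tol = 0.2,
                           R_min = 0.7, window = NULL,
                           event = c("onset", "midpoint")) {
  event <- match.arg(event)
  ro <- if (event == "midpoint") (ref$onset + ref$offset) / 2 else ref$onset
  oo <- if (event == "midpoint") (other$onset + other$offset) / 2
        else other$onset
  if (!is.null(window)) {
    ro <- ro[ro >= window[1] & ro < window[2]]
    oo <- oo[oo >= window[1] & oo < window[2]]
  }
  phases <- numeric(0)
  if (length(ro) >= 2) {
    for (i in seq_len(length(ro) - 1)) {
      inside <- oo[oo >= ro[i] & oo < ro[i + 1]]
      if (length(inside) > 0)
        phases <- c(phases, (inside - ro[i]) / (ro[i + 1] - ro[i]))
    }
  }
  n <- length(phases)
  if (n < min_cycles)
    stop(sprintf("insufficient cycles for phase relation (%d < %d)",
                 n, min_cycles))
  cs <- circular_stats(phases)
  d0 <- pmin(cs$mean, 1 - cs$mean)             # circular distance to 0
  label <- if (cs$R < R_min) "uncoordinated"
           else if (d0 <= tol) "synchrony"
           else if (abs(cs$mean - 0.5) <= tol) "alternation"
           else "uncoordinated"
  list(phase = cs$mean, R = cs$R, n_cycles = n, label = label)
}

#' Windowed coordination report
#'
#' Splits a run into analysis windows and reports, per window, the
#' oscillation frequency (from the reference flexor series), burst
#' amplitudes, and the left-right and flexor-extensor phase labels.
#'
#' @param record a \code{spike_record} of a bilateral network.
#' @param window window length (ms).
#' @param bin histogram bin (ms).
#' @param skip initial transient excluded from the first window (ms).
#' @param min_cycles per-window minimum cycles for a phase label.
#' @param ... further arguments to \code{\link{detect_bursts}}.
#' @return An object of class \code{coordination_report}: a data frame with
#'   one row per window (frequency, amplitudes, phases, concentrations,
#'   labels); the burst series are attached as attributes.
#' @export
coordination_report <- function(record, window = 20000, bin = 100,
                                skip = 5000, min_cycles = 3,
                                on_frac = 0.45, off_frac = 0.2, ...) {
  tr <- rate_histogram(record, bin = bin)
  have <- colnames(tr$rate)
  ref_name <- if ("l-RG-F" %in% have) "l-RG-F"
              else if ("r-RG-F" %in% have) "r-RG-F"
              else stop("coordination report needs an RG-F population")
  contra_name <- mirror_name(ref_name)
  ext_name <- sub("RG-F", "RG-E", ref_name)
  if (record$duration < skip + 2 * window)
    window <- max(5000, record$duration - skip)
  bl <- detect_bursts(tr, ref_name, on_frac = on_frac, off_frac = off_frac, ...)
  br <- if (contra_name %in% have)
    detect_bursts(tr, contra_name, on_frac = on_frac, off_frac = off_frac, ...)
    else NULL
  be <- if (ext_name %in% have)
    detect_bursts(tr, ext_name, on_frac = on_frac, off_frac = off_frac, ...)
    else NULL
  starts <- seq(skip, record$duration - window, by = window)
  rel <- function(a, b, win, event = "onset") {
    if (is.null(b)) return(list(phase = NA_real_, R = NA_real_,
                                label = "undefined"))
    tryCatch(phase_relation(a, b, min_cycles = min_cycles, window = win,
                            event = event),
             error = function(e) list(phase = NA_real_, R = NA_real_,
                                      label = "undefined"))
  }
  rows <- lapply(starts, function(t0) {
    win <- c(t0, t0 + window)
    sel <- bl$onset >= t0 & bl$onset < t0 + window
    freq <- if (sum(sel) >= 2) 1000 / mean(diff(bl$onset[sel])) else NA_real_
    amp_f <- if (any(sel)) mean(bl$peak[sel]) else NA_real_
    lr <- rel(bl, br, win)
    fe <- rel(bl, be, win, event = "midpoint")
    data.frame(t_start = t0, t_mid = t0 + window / 2,
               frequency = freq, amplitude_flexor = amp_f,
               lr_phase = lr$phase, lr_R = lr$R, lr_label = lr$label,
               fe_phase = fe$phase, fe_R = fe$R, fe_label = fe$label,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  bursts <- list(bl, br, be)
  names(bursts) <- c(ref_name, contra_name, ext_name)
  structure(rep, class = c("coordination_report", "data.frame"),
            bursts = bursts, reference = ref_name)
}

#' Classify burst deletions against an expected-cycle model
#'
#' Fits a mean period and phase grid to the pre-perturbation cycles of the
#' target series, extrapolates the expected burst onsets, and flags every
#' expected onset with no detected burst within a quarter cycle as a
#' deletion.  For each deletion the ipsilateral antagonist is labelled
#' \code{"sustained"} when it is continuously active throughout the
#' deletion window -- its rate never returns toward baseline (fixed floor
#' of 2 spikes/(neuron x s)) -- and \code{"rhythmic"} otherwise, the
#' contralateral timing deviation is the largest departure of contralateral
#' onsets from their own pre-perturbation grid during the deletion (as a
#' fraction of the contralateral cycle), and the rhythm is flagged as
#' resetting when the post-deletion onsets deviate more than a quarter
#' cycle from the extrapolated pre-deletion grid.
#'
#' @param target \code{\link{detect_bursts}} series of the perturbed
#'   population.
#' @param antagonist_trace activity trace containing the ipsilateral
#'   antagonist.
#' @param antagonist_population column name of the antagonist.
#' @param contralateral \code{\link{detect_bursts}} series of the homologous
#'   contralateral population.
#' @param fit_end end (ms) of the clean pre-perturbation stretch used to fit
#'   the expected-cycle model (normally the perturbation onset).
#' @param search_end end (ms) of the deletion search (default: end of run,
#'   less one cycle).
#' @param cv_max refuse to classify when the pre-perturbation period
#'   coefficient of variation exceeds this value.
#' @param type deletion type recorded in the report (\code{"flexor"} or
#'   \code{"extensor"}).
#' @return An object of class \code{deletion_report}: data frame of deletion
#'   events (expected onset, type, antagonist behaviour, contralateral
#'   deviation, resetting flag) with the fitted period attached.
#' @export
classify_deletions <- function(target, antagonist_trace,
                               antagonist_population, contralateral,
                               fit_end, search_end = NULL, cv_max = 0.2,
                               type = c("flexor", "extensor")) {
  type <- match.arg(type)
  pre <- target$onset[target$onset < fit_end]
  if (length(pre) < 6)
    stop("need at least 5 clean pre-perturbation cycles")
  per <- diff(pre)
  if (stats::sd(per) / mean(per) > cv_max)
    stop("unstable pre-perturbation rhythm (period CV > cv_max)")
  period <- mean(per)
  if (is.null(search_end))
    search_end <- attr(target, "duration") - period

  # deletions are missed expected onsets *before the rhythm resumes*: once
  # a burst is detected again, later grid mismatches reflect resetting (or
  # period change), not further deletions
  post <- target$onset[target$onset >= fit_end]
  resume_t <- if (length(post) > 0) post[1] else search_end
  grid <- seq(pre[length(pre)] + period, search_end, by = period)
  candidates <- grid[grid < resume_t - 0.25 * period | grid <= fit_end + period]
  missed <- vapply(candidates, function(g) {
    g < resume_t - 0.25 * period &&
      !any(abs(target$onset - g) <= 0.25 * period)
  }, logical(1))

  # contralateral grid anchored locally (re-anchoring avoids accumulating
  # period-estimate error over long extrapolations)
  cpre_all <- contralateral$onset[contralateral$onset < fit_end]
  cperiod <- if (length(cpre_all) >= 3) mean(diff(cpre_all)) else period

  tgrid <- antagonist_trace$time
  ab <- detect_bursts(antagonist_trace, antagonist_population)
  apre <- ab$onset[ab$onset < fit_end]
  aperiod <- if (length(apre) >= 3) mean(diff(apre)) else period

  local_dev <- function(onsets, anchor_pool, g, p) {
    anchor <- anchor_pool[anchor_pool < g]
    if (length(anchor) == 0) return(NA_real_)
    a0 <- anchor[length(anchor)]
    sel <- onsets[onsets >= g & onsets < g + 1.5 * p]
    if (length(sel) == 0) return(NA_real_)
    max(vapply(sel, function(o) {
      frac <- (o - a0) / p
      min(abs(frac - round(frac)))
    }, numeric(1)))
  }

  events <- lapply(candidates[missed], function(g) {
    # antagonist sampled over the window the missing burst would occupy;
    # "sustained" means continuously active (never silent) throughout,
    # as opposed to returning to baseline between bursts
    sel <- tgrid >= g & tgrid < g + 0.6 * period
    x <- antagonist_trace$rate[sel, antagonist_population]
    sustained <- length(x) > 0 && all(x >= 2)
    cdev <- local_dev(contralateral$onset, contralateral$onset, g, cperiod)
    adev <- if (sustained) NA_real_
            else local_dev(ab$onset, ab$onset, g, aperiod)
    data.frame(expected_onset = g, type = type,
               antagonist = if (sustained) "sustained" else "rhythmic",
               antagonist_deviation = adev,
               contralateral_deviation = cdev,
               stringsAsFactors = FALSE)
  })
  rep <- if (length(events) > 0) do.call(rbind, events)
         else data.frame(expected_onset = numeric(0), type = character(0),
                         antagonist = character(0),
                         antagonist_deviation = numeric(0),
                         contralateral_deviation = numeric(0))

  resetting <- NA
  if (any(missed)) {
    post3 <- utils::head(post, 3)
    if (length(post3) > 0) {
      dev <- vapply(post3, function(o) {
        frac <- (o - pre[length(pre)]) / period
        min(abs(frac - round(frac)))
      }, numeric(1))
      resetting <- mean(dev) > 0.25
    }
  }
  rep$resetting <- if (nrow(rep) > 0) resetting else logical(0)
  structure(rep, class = c("deletion_report", "data.frame"),
            period = period, grid = grid)
}

#' Phase-duration regression slopes
#'
#' Regresses the flexor- and extensor-phase durations on the cycle period
#' across cycles.  Phases are flexor-referenced: the flexor phase is the
#' flexor burst duration and the extensor phase is the inter-flexor-burst
#' gap, so the two slopes sum to one.  A flexor-dominated rhythm shows a
#' small flexor slope and an extensor slope near one.
#'
#' @param flexor \code{\link{detect_bursts}} series of the flexor center.
#' @param extensor optional extensor burst series (unused by the
#'   flexor-referenced phase definitions; accepted for interface symmetry).
#' @param min_cycles minimum number of cycles.
#' @param min_period_ratio minimum max/min cycle-period ratio; the slopes
#'   are ill-conditioned without period spread (e.g. use a ramp run).
#' @return An object of class \code{phase_duration_fit}: list with
#'   \code{flexor_slope}, \code{extensor_slope}, \code{n_cycles} and the
#'   per-cycle data frame.
#' @export
phase_duration_slopes <- function(flexor, extensor = NULL, min_cycles = 10,
                                  min_period_ratio = 1.2) {
  on <- flexor$onset
  off <- flexor$offset
  n <- length(on) - 1
  if (n < min_cycles)
    stop("need at least ", min_cycles, " cycles for phase-duration slopes")
  period <- diff(on)
  flex_dur <- (off - on)[seq_len(n)]
  ext_dur <- period - flex_dur
  if (max(period) / min(period) < min_period_ratio)
    stop("insufficient period range for phase-duration regression")
  fit_f <- stats::lm(flex_dur ~ period)
  fit_e <- stats::lm(ext_dur ~ period)
  structure(list(flexor_slope = unname(stats::coef(fit_f)[2]),
                 extensor_slope = unname(stats::coef(fit_e)[2]),
                 n_cycles = n,
                 cycles = data.frame(period = period, flexor = flex_dur,
                                     extensor = ext_dur)),
            class = "phase_duration_fit")
}

#' @export
print.phase_duration_fit <- function(x, ...) {
  cat(sprintf("Phase-duration fit over %d cycles: flexor slope %.3f, extensor slope %.3f\n",
              x$n_cycles, x$flexor_slope, x$extensor_slope))
  invisible(x)
}

#' Does a series have a single interior maximum?
#'
#' Smooths with a centered running mean and counts interior local maxima;
#' used to check that a burst-amplitude profile rises and then falls along a
#' drive ramp.
#'
#' @param x numeric series (NAs dropped).
#' @param k running-mean width (odd).
#' @return TRUE when exactly one interior local maximum remains after
#'   smoothing and it is not at either end.
#' @export
single_interior_peak <- function(x, k = 3) {
  x <- x[!is.na(x)]
  if (length(x) < 5) return(FALSE)
  sm <- stats::filter(x, rep(1 / k, k), sides = 2)
  sm <- as.numeric(sm[!is.na(sm)])
  d <- diff(sm)
  d <- d[d != 0]
  runs <- rle(sign(d))$values
  peaks <- sum(utils::head(runs, -1) > 0 & utils::tail(runs, -1) < 0)
  peaks == 1 && runs[1] > 0 && runs[length(runs)] < 0
}
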