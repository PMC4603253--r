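#' Map the drive parameter alpha to an effective leak reversal
#'
#' The network-wide excitability drive \code{alpha} (emulating neuroactive
#' drug concentration) scales every drive-sensitive neuron's leak reversal
#' as \code{E_L = E_L0 * (1 - drive_gain * alpha)}.  Because baseline leak
#' reversals are negative, increasing \code{alpha} depolarizes.
#'
#' @param E_L0 baseline leak reversal potential (mV), normally negative.
#' @param alpha drive level in [0, 1).
#' @param drive_gain dimensionless per-population scaling of alpha.
#' @return Effective leak reversal (mV).
#' @examples
#' drive_to_leak(-70, 0)        # -70
#' drive_to_leak(-70, 12/70)    # -58: the top of the standard ramp
#' @export
drive_to_leak <- function(E_L0, alpha, drive_gain = 1) {
  if (any(alpha < 0 | alpha >= 1))
    stop("alpha must lie in [0, 1)")
  E_L0 * (1 - drive_gain * alpha)
}

#' Piecewise-linear drive protocol
#'
#' @param times knot times (ms), increasing, starting at 0.
#' @param alpha alpha values at the knots, each in [0, 1).
#' @param duration protocol duration (ms); defaults to the last knot.
#' @return An object of class \code{drive_protocol} with an empty
#'   perturbation list.
#' @seealso \code{\link{alpha_ramp}}, \code{\link{add_perturbation}}
#' @export
drive_protocol <- function(times, alpha, duration = max(times)) {
  stopifnot(length(times) == length(alpha), length(times) >= 2)
  if (is.unsorted(times, strictly = FALSE)) stop("knot times must be sorted")
  if (times[1] != 0) stop("schedule must start at t = 0")
  if (any(alpha < 0 | alpha >= 1)) stop("alpha must lie in [0, 1)")
  if (duration > max(times))
    stop("schedule must be defined on [0, duration]")
  structure(list(times = as.numeric(times), alpha = as.numeric(alpha),
                 duration = as.numeric(duration), perturbations = list()),
            class = "drive_protocol")
}

#' Linear alpha ramp
#'
#' @param alpha_start,alpha_end drive values, \code{0 <= alpha_start <=
#'   alpha_end < 1}.  Equal values yield a constant-drive protocol.
#' @param duration ramp duration (ms).
#' @return A \code{\link{drive_protocol}}.
#' @examples
#' alpha_ramp(0, 0.5, 100000)   # alpha = 0.25 at t = 50 s
#' @export
alpha_ramp <- function(alpha_start, alpha_end, duration) {
  if (!(alpha_start >= 0 && alpha_start <= alpha_end && alpha_end < 1))
    stop("need 0 <= alpha_start <= alpha_end < 1")
  drive_protocol(c(0, duration), c(alpha_start, alpha_end), duration)
}

#' Evaluate a drive protocol
#'
#' @param protocol a \code{\link{drive_protocol}}.
#' @param t time (ms); vectorized.
#' @return alpha(t), linearly interpolated between knots.
#' @export
alpha_at <- function(protocol, t) {
  stats::approx(protocol$times, protocol$alpha, xout = t, rule = 2)$y
}

#' Transient perturbation of one population
#'
#' @param target population name (e.g. \code{"l-RG-F"}).
#' @param onset pulse onset (ms).
#' @param duration pulse duration (ms).
#' @param sign \code{"excitatory"} or \code{"inhibitory"}.
#' @param amplitude added constant synaptic conductance (nS), >= 0.
#' @return An object of class \code{perturbation_spec}.
#' @export
perturbation_spec <- function(target, onset, duration, sign, amplitude) {
  sign <- match.arg(sign, c("excitatory", "inhibitory"))
  stopifnot(onset >= 0, duration > 0, amplitude >= 0)
  structure(list(target = target, onset = onset, duration = duration,
                 sign = sign, amplitude = amplitude),
            class = "perturbation_spec")
}

#' Attach a perturbation to a drive protocol
#'
#' During \code{[onset, onset + duration]} the target population receives an
#' added constant synaptic conductance of the given sign; this is the
#' controlled stimulus used to elicit flexor or extensor burst deletions.
#' Two perturbations on the same target may not overlap in time.
#'
#' @param protocol a \code{\link{drive_protocol}}.
#' @param pert a \code{\link{perturbation_spec}}.
#' @return The protocol with the perturbation appended.
#' @export
add_perturbation <- function(protocol, pert) {
  stopifnot(inherits(protocol, "drive_protocol"),
            inherits(pert, "perturbation_spec"))
  if (pert$onset + pert$duration > protocol$duration)
    stop("perturbation window exceeds the protocol duration")
  for (q in protocol$perturbations) {
    if (q$target == pert$target &&
        pert$onset < q$onset + q$duration &&
        q$onset < pert$onset + pert$duration)
      stop("overlapping perturbations on the same target are rejected")
  }
  protocol$perturbations <- c(protocol$perturbations, list(pert))
  protocol
}

#' @export
print.drive_protocol <- function(x, ...) {
  cat(sprintf("Drive protocol: %.1f s, alpha %g -> %g, %d perturbation(s)\n",
              x$duration / 1000, x$alpha[1], x$alpha[length(x$alpha)],
              length(x$perturbations)))
  invisible(x)
}
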