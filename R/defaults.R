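#' Frozen default configuration
#'
#' Returns the versioned default parameter set used by all network builders,
#' drive protocols and presets.  The values are the package's own frozen
#' choices: membrane kinetics follow the canonical persistent-sodium
#' half-center formulation (fast Na with instantaneous activation,
#' delayed-rectifier K, slowly inactivating persistent Na, leak,
#' single-exponential conductance synapses); population sizes follow the
#' published circuit diagrams (200 neurons per rhythm-generating population,
#' 50 for every other class); connection probabilities, synaptic weights and
#' per-population drive gains were tuned once against the qualitative regime
#' structure the architectures must express and are not revisited.
#'
#' Elements:
#' \describe{
#'   \item{membrane}{named list of \code{\link{membrane_parameters}} templates
#'     (\code{rg} for rhythmogenic populations, \code{relay} for all others).}
#'   \item{populations}{data frame of per-role defaults: size, baseline leak
#'     reversal \code{E_L0} (mV), uniform jitter half-width \code{E_L_spread}
#'     (mV), \code{drive_gain} (dimensionless scaling of the drive parameter
#'     alpha), and flags \code{drive_sensitive} and \code{rhythmogenic}.}
#'   \item{p_connect}{default per-pair Bernoulli connection probability.}
#'   \item{weights}{named list of synaptic conductance increments (nS) per
#'     projection class, at full population scale.}
#'   \item{v2b_fraction}{fraction of the reciprocal flexor-extensor inhibitory
#'     weight carried by V2b (rather than Inrg) populations in the unified
#'     architecture.}
#' }
#'
#' @return A nested list (see Details).
#' @export
cpg_defaults <- function() {
  rg <- membrane_parameters()
  relay <- membrane_parameters(g_NaP = 0, g_L = 1.0)

  populations <- data.frame(
    role = c("RG-F", "RG-E", "Inrg-F", "Inrg-E",
             "V0D", "V0V", "V3", "V2a", "InV0V",
             "V2b", "V1", "InV1"),
    size = c(200L, 200L, 50L, 50L, 50L, 50L, 50L, 50L, 50L, 50L, 50L, 50L),
    E_L0 = c(-70, -59, -66, -66, -67, -66, -66.5, -70, -66, -66, -66, -66),
    E_L_spread = c(2.25, 1.5, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    drive_gain = c(1.0, 0.15, 0, 0, 0.15, 0.15, 0.8, 1.5, 0, 0, 0, 0),
    drive_sensitive = c(TRUE, TRUE, FALSE, FALSE,
                        TRUE, TRUE, TRUE, TRUE, FALSE,
                        FALSE, FALSE, FALSE),
    rhythmogenic = c(TRUE, TRUE, rep(FALSE, 10)),
    stringsAsFactors = FALSE
  )

  weights <- list(
    rg_recurrent = 0.015,    # sparse excitation within each RG population
    rg_fe_exc    = 0.06,    # weak flexor->extensor excitation (masked by inhibition)
    rgf_inrgf    = 0.50,    # RG-F -> Inrg-F
    inrgf_rge    = 1.50,    # Inrg-F -| RG-E
    rge_inrge    = 0.50,    # RG-E -> Inrg-E
    inrge_rgf    = 0.015,    # Inrg-E -| RG-F (weak: flexor dominance)
    rgf_v0d      = 0.30,    # RG-F -> V0D
    v0d_rgf      = 0.60,    # V0D -| contralateral RG-F
    rgf_v3       = 0.35,    # RG-F -> V3
    v3_rgf       = 0.06,    # V3 -> contralateral RG-F
    rg_v2a       = 0.30,    # RG-F (Model 1) or RG-E (Model 2) -> V2a
    v2a_v0v      = 0.60,    # V2a -> V0V
    v0v_inv0v    = 0.60,    # V0V -> contralateral InV0V (Model 1)
    inv0v_rgf    = 0.06,    # InV0V -| RG-F (Model 1)
    v0v_rgf      = 0.006,    # V0V -> contralateral RG-F (Model 2)
    rgf_v2bf     = 0.50,    # RG-F -> V2b-F
    v2bf_rge     = 1.50,    # V2b-F -| RG-E (full weight; split by v2b_fraction)
    rge_v2be     = 0.50,    # RG-E -> V2b-E
    v2be_rgf     = 0.08,    # V2b-E -| RG-F (full weight; split by v2b_fraction)
    v0d_v1       = 1.00,    # contralateral V0D -| V1
    v1_rge       = 1.00,    # V1 -| RG-E
    v1_inv1      = 1.50,    # V1 -| InV1
    inv1_rgf     = 0.07,    # InV1 -| RG-F
    v1_drive     = 0.80,    # tonic excitatory conductance onto V1 (nS, contralateral source)
    inv1_drive   = 0.80     # tonic excitatory conductance onto InV1 (nS, ipsilateral source)
  )

  # Drive-protocol constants: the isolated-RG ramp spans the standard
  # -70 -> -58 mV leak-reversal window (alpha = 0 .. 12/70); the network
  # ramp range and the constant mid-range drive were fixed empirically from
  # the frozen defaults (usable oscillatory range of the intact models).
  drive <- list(
    fig5_ramp = c(0, 12 / 70),
    ramp = c(0.05, 0.14),
    mid = 0.09,
    probe = 0.075,
    ramp_duration = 150000,
    constant_duration = 60000
  )

  list(
    membrane = list(rg = rg, relay = relay),
    populations = populations,
    p_connect = 0.1,
    gnap_jitter = 0.02,
    weights = weights,
    v2b_fraction = 1.0,
    drive = drive
  )
}
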