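#' Population specification
#'
#' Declares one neural population of the bilateral CPG network.
#'
#' @param name unique identifier, conventionally \code{"l-<role>"} or
#'   \code{"r-<role>"} (the V2b class is split into the flexor- and
#'   extensor-coactive halves \code{V2b-F}/\code{V2b-E}, both of role
#'   \code{V2b}).
#' @param side \code{"left"} or \code{"right"}.
#' @param role one of RG-F, RG-E, Inrg-F, Inrg-E, V0D, V0V, V3, V2a, V1,
#'   V2b, InV0V, InV1.
#' @param size neuron count (>= 1).
#' @param E_L0 baseline leak reversal potential (mV).
#' @param E_L_spread half-width of the per-neuron uniform jitter of
#'   \code{E_L0} (mV).
#' @param drive_sensitive whether the leak reversal scales with the drive
#'   parameter alpha.
#' @param drive_gain dimensionless scaling of alpha for this population.
#' @param rhythmogenic whether neurons carry a positive persistent sodium
#'   conductance (only rhythm-generating centers do).
#' @return An object of class \code{population_spec}.
#' @export
population_spec <- function(name, side, role, size, E_L0, E_L_spread = 1,
                            drive_sensitive = FALSE, drive_gain = 0,
                            rhythmogenic = FALSE) {
  side <- match.arg(side, c("left", "right"))
  role <- match.arg(role, cpg_roles())
  stopifnot(size >= 1, E_L_spread >= 0)
  structure(list(name = name, side = side, role = role,
                 size = as.integer(size), E_L0 = E_L0,
                 E_L_spread = E_L_spread,
                 drive_sensitive = isTRUE(drive_sensitive),
                 drive_gain = if (isTRUE(drive_sensitive)) drive_gain else 0,
                 rhythmogenic = isTRUE(rhythmogenic)),
            class = "population_spec")
}

#' Recognized population roles
#' @return Character vector of role labels.
#' @export
cpg_roles <- function() {
  c("RG-F", "RG-E", "Inrg-F", "Inrg-E", "V0D", "V0V", "V3", "V2a",
    "V1", "V2b", "InV0V", "InV1")
}

# roles whose projections are inhibitory / excitatory
inhibitory_roles <- function() c("V0D", "V1", "V2b", "Inrg-F", "Inrg-E",
                                 "InV0V", "InV1")

#' Projection specification
#'
#' Declares a projection between two populations.  Commissural projections
#' carry a \code{crossing_fraction}: the fraction of source axons reaching
#' the nominal contralateral target; the remainder is rerouted to
#' \code{reroute_target} (by default the homologous population on the
#' opposite side of the nominal target).  Axon-guidance knockouts
#' manipulate these fields.
#'
#' @param source,target population names.
#' @param sign \code{"excitatory"} or \code{"inhibitory"}; must be
#'   consistent with the source role's transmitter phenotype.
#' @param p_connect per source-target pair Bernoulli probability in (0, 1].
#' @param weight synaptic conductance increment (nS) per spike.
#' @param weight_jitter multiplicative uniform jitter half-width (fraction).
#' @param commissural whether the projection crosses the midline.
#' @param crossing_fraction fraction of source axons reaching the nominal
#'   target (1 in the intact network).
#' @param reroute_target population receiving the misrouted axons, or NA for
#'   the homolog of the nominal target on the opposite side.
#' @return An object of class \code{projection_spec}.
#' @export
projection_spec <- function(source, target, sign, p_connect, weight,
                            weight_jitter = 0, commissural = FALSE,
                            crossing_fraction = 1, reroute_target = NA) {
  sign <- match.arg(sign, c("excitatory", "inhibitory"))
  if (!(p_connect > 0 && p_connect <= 1))
    stop("p_connect must lie in (0, 1]")
  stopifnot(weight >= 0, weight_jitter >= 0,
            crossing_fraction >= 0, crossing_fraction <= 1)
  structure(list(source = source, target = target, sign = sign,
                 p_connect = p_connect, weight = weight,
                 weight_jitter = weight_jitter,
                 commissural = isTRUE(commissural),
                 crossing_fraction = crossing_fraction,
                 reroute_target = reroute_target),
            class = "projection_spec")
}

#' Network specification
#'
#' @param populations list of \code{\link{population_spec}}.
#' @param projections list of \code{\link{projection_spec}}.
#' @param tonic_drives list of constant architecture-level drives, each a
#'   list with \code{target} (population name), \code{conductance} (nS) and
#'   \code{source_side} (\code{"left"}, \code{"right"} or \code{"local"});
#'   a hemisection removes drives sourced from the removed side.
#' @return An object of class \code{network_spec}.
#' @export
network_spec <- function(populations, projections, tonic_drives = list()) {
  names(populations) <- vapply(populations, `[[`, "", "name")
  if (anyDuplicated(names(populations)))
    stop("population names must be unique")
  spec <- structure(list(populations = populations,
                         projections = projections,
                         tonic_drives = tonic_drives),
                    class = "network_spec")
  validate_network_spec(spec)
  spec
}

validate_network_spec <- function(spec) {
  pops <- names(spec$populations)
  for (pr in spec$projections) {
    if (!(pr$source %in% pops) || !(pr$target %in% pops))
      stop("projection endpoint names a missing population: ",
           pr$source, " -> ", pr$target)
    role <- spec$populations[[pr$source]]$role
    expected <- if (role %in% inhibitory_roles()) "inhibitory" else "excitatory"
    if (pr$sign != expected)
      stop(sprintf("projection sign %s inconsistent with source role %s",
                   pr$sign, role))
  }
  for (d in spec$tonic_drives) {
    if (!(d$target %in% pops))
      stop("tonic drive targets a missing population: ", d$target)
  }
  invisible(spec)
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("CPG network: %d populations (%d neurons), %d projections, %d tonic drive(s)\n",
              length(x$populations),
              sum(vapply(x$populations, `[[`, 0L, "size")),
              length(x$projections), length(x$tonic_drives)))
  invisible(x)
}

other_side <- function(side) if (side == "left") "right" else "left"
side_prefix <- function(side) if (side == "left") "l-" else "r-"

#' Homologous population name on the opposite side
#' @param name population name with an \code{l-}/\code{r-} prefix.
#' @return The mirrored name.
#' @export
mirror_name <- function(name) {
  ifelse(startsWith(name, "l-"), sub("^l-", "r-", name),
         sub("^r-", "l-", name))
}

pop_from_defaults <- function(config, side, role, name_suffix = role,
                              size = NULL, E_L0 = NULL) {
  row <- config$populations[config$populations$role == role, ]
  population_spec(
    name = paste0(side_prefix(side), name_suffix), side = side, role = role,
    size = if (is.null(size)) row$size else size,
    E_L0 = if (is.null(E_L0)) row$E_L0 else E_L0,
    E_L_spread = row$E_L_spread,
    drive_sensitive = row$drive_sensitive,
    drive_gain = row$drive_gain,
    rhythmogenic = row$rhythmogenic)
}

resolve_size <- function(size_overrides, role, default) {
  if (!is.null(size_overrides[[role]])) size_overrides[[role]] else default
}

# Core half-center circuitry shared by both commissural models: per side,
# RG-F and RG-E with sparse recurrent excitation, reciprocal inhibition via
# Inrg-F / Inrg-E, and weak mutual flexor-extensor excitation.
build_core <- function(size_overrides, config, inrg_weight_scale = 1) {
  w <- config$weights
  p <- config$p_connect
  pops <- list()
  projs <- list()
  for (side in c("left", "right")) {
    sp <- side_prefix(side)
    for (role in c("RG-F", "RG-E", "Inrg-F", "Inrg-E")) {
      row <- config$populations[config$populations$role == role, ]
      pops[[paste0(sp, role)]] <-
        pop_from_defaults(config, side, role,
                          size = resolve_size(size_overrides, role, row$size))
    }
    new_projs <- list(
      projection_spec(paste0(sp, "RG-F"), paste0(sp, "RG-F"), "excitatory",
                      p, w$rg_recurrent),
      projection_spec(paste0(sp, "RG-E"), paste0(sp, "RG-E"), "excitatory",
                      p, w$rg_recurrent),
      projection_spec(paste0(sp, "RG-F"), paste0(sp, "RG-E"), "excitatory",
                      p, w$rg_fe_exc),
      projection_spec(paste0(sp, "RG-F"), paste0(sp, "Inrg-F"), "excitatory",
                      p, w$rgf_inrgf),
      projection_spec(paste0(sp, "Inrg-F"), paste0(sp, "RG-E"), "inhibitory",
                      p, w$inrgf_rge * inrg_weight_scale),
      projection_spec(paste0(sp, "RG-E"), paste0(sp, "Inrg-E"), "excitatory",
                      p, w$rge_inrge),
      projection_spec(paste0(sp, "Inrg-E"), paste0(sp, "RG-F"), "inhibitory",
                      p, w$inrge_rgf * inrg_weight_scale)
    )
    projs <- c(projs, Filter(function(pr) pr$weight > 0, new_projs))
  }
  list(pops = pops, projs = projs)
}

# V0D and V3 commissural pathways, identical in both models.
build_v0d_v3 <- function(size_overrides, config) {
  w <- config$weights
  p <- config$p_connect
  pops <- list()
  projs <- list()
  for (side in c("left", "right")) {
    sp <- side_prefix(side)
    co <- side_prefix(other_side(side))
    for (role in c("V0D", "V3")) {
      row <- config$populations[config$populations$role == role, ]
      pops[[paste0(sp, role)]] <-
        pop_from_defaults(config, side, role,
                          size = resolve_size(size_overrides, role, row$size))
    }
    projs <- c(projs, list(
      projection_spec(paste0(sp, "RG-F"), paste0(sp, "V0D"), "excitatory",
                      p, w$rgf_v0d),
      projection_spec(paste0(sp, "V0D"), paste0(co, "RG-F"), "inhibitory",
                      p, w$v0d_rgf, commissural = TRUE),
      projection_spec(paste0(sp, "RG-F"), paste0(sp, "V3"), "excitatory",
                      p, w$rgf_v3),
      projection_spec(paste0(sp, "V3"), paste0(co, "RG-F"), "excitatory",
                      p, w$v3_rgf, commissural = TRUE)
    ))
  }
  list(pops = pops, projs = projs)
}

#' Build the Model 1 bilateral network
#'
#' Architecture with flexor-driven V2a-V0V commissural pathways: per side,
#' RG-F and RG-E rhythm-generating centers reciprocally inhibit each other
#' via Inrg populations; V0D (excited by the ipsilateral RG-F) inhibits the
#' contralateral RG-F; V3 (excited by the ipsilateral RG-F) excites the
#' contralateral RG-F; V2a (excited by the ipsilateral RG-F) excites the
#' ipsilateral V0V, which excites a contralateral inhibitory relay (InV0V)
#' that inhibits the contralateral RG-F.
#'
#' @param size_overrides named list of per-role neuron counts overriding the
#'   defaults (RG populations 200, all others 50).
#' @param config parameter configuration, by default
#'   \code{\link{cpg_defaults}()}.
#' @return A \code{\link{network_spec}}.
#' @export
build_model1 <- function(size_overrides = list(), config = cpg_defaults()) {
  w <- config$weights
  p <- config$p_connect
  core <- build_core(size_overrides, config)
  cin <- build_v0d_v3(size_overrides, config)
  pops <- c(core$pops, cin$pops)
  projs <- c(core$projs, cin$projs)
  for (side in c("left", "right")) {
    sp <- side_prefix(side)
    co <- side_prefix(other_side(side))
    for (role in c("V2a", "V0V", "InV0V")) {
      row <- config$populations[config$populations$role == role, ]
      pops[[paste0(sp, role)]] <-
        pop_from_defaults(config, side, role,
                          size = resolve_size(size_overrides, role, row$size))
    }
    projs <- c(projs, list(
      projection_spec(paste0(sp, "RG-F"), paste0(sp, "V2a"), "excitatory",
                      p, w$rg_v2a),
      projection_spec(paste0(sp, "V2a"), paste0(sp, "V0V"), "excitatory",
                      p, w$v2a_v0v),
      projection_spec(paste0(sp, "V0V"), paste0(co, "InV0V"), "excitatory",
                      p, w$v0v_inv0v, commissural = TRUE),
      projection_spec(paste0(sp, "InV0V"), paste0(sp, "RG-F"), "inhibitory",
                      p, w$inv0v_rgf)
    ))
  }
  network_spec(pops, projs)
}

#' Build the Model 2 bilateral network
#'
#' As \code{\link{build_model1}} except that the V2a populations are excited
#' by the ipsilateral extensor centers (RG-E) and the V0V populations excite
#' the contralateral RG-F directly, with no InV0V relay.
#'
#' @inheritParams build_model1
#' @return A \code{\link{network_spec}}.
#' @export
build_model2 <- function(size_overrides = list(), config = cpg_defaults()) {
  w <- config$weights
  p <- config$p_connect
  core <- build_core(size_overrides, config)
  cin <- build_v0d_v3(size_overrides, config)
  pops <- c(core$pops, cin$pops)
  projs <- c(core$projs, cin$projs)
  for (side in c("left", "right")) {
    sp <- side_prefix(side)
    co <- side_prefix(other_side(side))
    for (role in c("V2a", "V0V")) {
      row <- config$populations[config$populations$role == role, ]
      pops[[paste0(sp, role)]] <-
        pop_from_defaults(config, side, role,
                          size = resolve_size(size_overrides, role, row$size))
    }
    projs <- c(projs, list(
      projection_spec(paste0(sp, "RG-E"), paste0(sp, "V2a"), "excitatory",
                      p, w$rg_v2a),
      projection_spec(paste0(sp, "V2a"), paste0(sp, "V0V"), "excitatory",
                      p, w$v2a_v0v),
      projection_spec(paste0(sp, "V0V"), paste0(co, "RG-F"), "excitatory",
                      p, w$v0v_rgf, commissural = TRUE)
    ))
  }
  network_spec(pops, projs)
}

#' Build the unified V1/V2b architecture
#'
#' Extends a core commissural model with, per side: V2b populations carrying
#' a configurable fraction (default half) of the reciprocal flexor-extensor
#' inhibition in parallel with the Inrg populations (split into the
#' flexor-coactive \code{V2b-F} and extensor-coactive \code{V2b-E} halves);
#' and V1 populations that receive a constant tonic excitatory drive sourced
#' from the contralateral side plus inhibition from the contralateral V0D,
#' and in turn inhibit the ipsilateral RG-E and an interposed tonically
#' active inhibitory population (InV1) that inhibits the ipsilateral RG-F.
#' A hemisection removes the contralaterally sourced V1 drive, silencing V1
#' on the surviving side.
#'
#' @param core \code{"model1"} or \code{"model2"}.
#' @inheritParams build_model1
#' @return A \code{\link{network_spec}}.
#' @export
build_unified <- function(core = c("model1", "model2"),
                          size_overrides = list(), config = cpg_defaults()) {
  core <- match.arg(core)
  w <- config$weights
  p <- config$p_connect
  fv <- config$v2b_fraction

  # rebuild the chosen core with Inrg inhibition scaled down by the V2b share
  base_builder <- function(so, cf) {
    if (core == "model1") build_model1(so, cf) else build_model2(so, cf)
  }
  cf <- config
  cf$weights$inrgf_rge <- w$inrgf_rge * (1 - fv)
  cf$weights$inrge_rgf <- w$inrge_rgf * (1 - fv)
  base <- base_builder(size_overrides, cf)

  pops <- base$populations
  projs <- base$projections
  drives <- base$tonic_drives
  v2b_row <- config$populations[config$populations$role == "V2b", ]
  v2b_size <- resolve_size(size_overrides, "V2b", v2b_row$size)

  for (side in c("left", "right")) {
    sp <- side_prefix(side)
    half <- max(1L, as.integer(round(v2b_size / 2)))
    for (suffix in c("V2b-F", "V2b-E")) {
      pops[[paste0(sp, suffix)]] <-
        pop_from_defaults(config, side, "V2b", name_suffix = suffix,
                          size = half)
    }
    for (role in c("V1", "InV1")) {
      row <- config$populations[config$populations$role == role, ]
      pops[[paste0(sp, role)]] <-
        pop_from_defaults(config, side, role,
                          size = resolve_size(size_overrides, role, row$size))
    }
    co <- side_prefix(other_side(side))
    projs <- c(projs, list(
      projection_spec(paste0(sp, "RG-F"), paste0(sp, "V2b-F"), "excitatory",
                      p, w$rgf_v2bf),
      projection_spec(paste0(sp, "V2b-F"), paste0(sp, "RG-E"), "inhibitory",
                      p, w$v2bf_rge * fv),
      projection_spec(paste0(sp, "RG-E"), paste0(sp, "V2b-E"), "excitatory",
                      p, w$rge_v2be),
      projection_spec(paste0(sp, "V2b-E"), paste0(sp, "RG-F"), "inhibitory",
                      p, w$v2be_rgf * fv),
      projection_spec(paste0(sp, "V0D"), paste0(co, "V1"), "inhibitory",
                      p, w$v0d_v1, commissural = TRUE),
      projection_spec(paste0(sp, "V1"), paste0(sp, "RG-E"), "inhibitory",
                      p, w$v1_rge),
      projection_spec(paste0(sp, "V1"), paste0(sp, "InV1"), "inhibitory",
                      p, w$v1_inv1),
      projection_spec(paste0(sp, "InV1"), paste0(sp, "RG-F"), "inhibitory",
                      p, w$inv1_rgf)
    ))
    drives <- c(drives, list(
      list(target = paste0(sp, "V1"), conductance = w$v1_drive,
           source_side = other_side(side)),
      list(target = paste0(sp, "InV1"), conductance = w$inv1_drive,
           source_side = side)
    ))
  }
  network_spec(pops, projs, drives)
}

#' Mirror a network left-right
#'
#' Swaps the left/right labels of every population, projection and tonic
#' drive.  The intact builders are bilaterally symmetric: the mirror of a
#' built network equals itself.
#'
#' @param spec a \code{\link{network_spec}}.
#' @return The mirrored \code{network_spec}.
#' @export
mirror_network <- function(spec) {
  pops <- lapply(spec$populations, function(p) {
    p$name <- mirror_name(p$name)
    p$side <- other_side(p$side)
    p
  })
  projs <- lapply(spec$projections, function(pr) {
    pr$source <- mirror_name(pr$source)
    pr$target <- mirror_name(pr$target)
    if (!is.na(pr$reroute_target))
      pr$reroute_target <- mirror_name(pr$reroute_target)
    pr
  })
  drives <- lapply(spec$tonic_drives, function(d) {
    d$target <- mirror_name(d$target)
    if (d$source_side %in% c("left", "right"))
      d$source_side <- other_side(d$source_side)
    d
  })
  network_spec(pops, projs, drives)
}

#' Edge-list view of a network
#'
#' One row per projection, suitable for auditing a build against a frozen
#' transcription of the circuit diagram.
#'
#' @param spec a \code{\link{network_spec}}.
#' @param by_role collapse population names to their roles.
#' @return A data frame with columns source, target, sign, p_connect,
#'   weight, commissural, crossing_fraction.
#' @export
edge_table <- function(spec, by_role = FALSE) {
  nm <- function(x) if (by_role) spec$populations[[x]]$role else x
  do.call(rbind, lapply(spec$projections, function(pr) {
    data.frame(source = nm(pr$source), target = nm(pr$target),
               sign = pr$sign, p_connect = pr$p_connect,
               weight = pr$weight, commissural = pr$commissural,
               crossing_fraction = pr$crossing_fraction,
               stringsAsFactors = FALSE)
  }))
}

#' Export the edge list as TSV
#'
#' @param spec a \code{\link{network_spec}}.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(spec, path) {
  utils::write.table(edge_table(spec), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Scale a network for desk-size runs
#'
#' Multiplies every population size by \code{scale} (rounded, floored at one
#' neuron) and compensates so each neuron's expected synaptic input is
#' preserved.  The default \code{"degree"} mode raises connection
#' probabilities by \code{1/scale} (capped at 1, with any remainder folded
#' into the weight), keeping expected in-degrees -- and therefore the
#' per-neuron input statistics -- close to the full-size network; the
#' \code{"weight"} mode keeps probabilities and multiplies weights by
#' \code{1/scale} instead, preserving only the mean input but with sparser,
#' larger unitary events.
#'
#' @param spec a \code{\link{network_spec}}.
#' @param scale population-size scale factor in (0, 1].
#' @param mode \code{"degree"} (default) or \code{"weight"}.
#' @return The scaled \code{network_spec}.
#' @export
scale_network <- function(spec, scale, mode = c("degree", "weight")) {
  mode <- match.arg(mode)
  stopifnot(scale > 0, scale <= 1)
  if (scale == 1) return(spec)
  pops <- lapply(spec$populations, function(p) {
    p$size <- max(1L, as.integer(round(p$size * scale)))
    p
  })
  projs <- lapply(spec$projections, function(pr) {
    if (mode == "weight") {
      pr$weight <- pr$weight / scale
    } else {
      p_new <- pr$p_connect / scale
      if (p_new > 1) {                 # fold the excess into the weight
        pr$weight <- pr$weight * p_new
        p_new <- 1
      }
      pr$p_connect <- p_new
    }
    pr
  })
  network_spec(pops, projs, spec$tonic_drives)
}
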