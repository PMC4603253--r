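#' Lesion specification
#'
#' @param removed_roles character vector of population roles to remove.
#' @param sides optional side restriction (\code{"left"}, \code{"right"});
#'   NULL removes the role on both sides.
#' @param hemisection_side \code{"none"}, \code{"left"} or \code{"right"}:
#'   remove one entire side of the cord.
#' @return An object of class \code{lesion_spec}.
#' @export
lesion_spec <- function(removed_roles = character(0), sides = NULL,
                        hemisection_side = c("none", "left", "right")) {
  hemisection_side <- match.arg(hemisection_side)
  structure(list(removed_roles = removed_roles, sides = sides,
                 hemisection_side = hemisection_side),
            class = "lesion_spec")
}

#' Apply a lesion (population removal or hemisection)
#'
#' Removes the named populations and every incident projection and tonic
#' drive.  A hemisection removes all populations of one side, which also
#' eliminates every commissural projection, and drops tonic drives sourced
#' from the removed side (so the contralaterally driven V1 populations on
#' the surviving side fall silent).  The input spec is left unchanged.
#'
#' @param spec a \code{\link{network_spec}}.
#' @param lesion a \code{\link{lesion_spec}}.
#' @return The lesioned \code{network_spec}.
#' @export
apply_lesion <- function(spec, lesion) {
  stopifnot(inherits(spec, "network_spec"), inherits(lesion, "lesion_spec"))
  drop <- vapply(spec$populations, function(p) {
    hit <- p$role %in% lesion$removed_roles &&
      (is.null(lesion$sides) || p$side %in% lesion$sides)
    hit || (lesion$hemisection_side != "none" &&
              p$side == lesion$hemisection_side)
  }, logical(1))
  missing_roles <- setdiff(lesion$removed_roles,
                           vapply(spec$populations, `[[`, "", "role"))
  if (length(missing_roles) > 0)
    warning("lesion names absent role(s), ignored: ",
            paste(missing_roles, collapse = ", "))
  kept <- names(spec$populations)[!drop]
  pops <- spec$populations[kept]
  projs <- Filter(function(pr) pr$source %in% kept && pr$target %in% kept,
                  spec$projections)
  drives <- Filter(function(d) {
    d$target %in% kept &&
      !(d$source_side %in% lesion$hemisection_side)
  }, spec$tonic_drives)
  network_spec(pops, projs, drives)
}

#' Knockout specification (axon-guidance mutant)
#'
#' @param type \code{"Netrin1"}, \code{"DCC"} or \code{"EphA4"}.
#' @param f_reroute fraction in [0, 1] of affected axons failing their
#'   normal guidance.
#' @return An object of class \code{knockout_spec}.
#' @export
knockout_spec <- function(type = c("Netrin1", "DCC", "EphA4"),
                          f_reroute = 0.8) {
  type <- match.arg(type)
  stopifnot(f_reroute >= 0, f_reroute <= 1)
  structure(list(type = type, f_reroute = f_reroute),
            class = "knockout_spec")
}

#' Apply an axon-guidance knockout
#'
#' Rewires commissural (or, for EphA4, ipsilateral premotor) projections:
#' \describe{
#'   \item{Netrin1}{V0D and V0V commissural projections keep only a
#'     \code{1 - f_reroute} crossing fraction; the misrouted axons target
#'     the homologous population on the source's own side.  V3 untouched.}
#'   \item{DCC}{the same reduction applied to V0D, V0V and V3.}
#'   \item{EphA4}{a fraction \code{f_reroute} of V2a->V0V axons crosses the
#'     midline where it should not, targeting the contralateral V0V;
#'     V0-family crossing untouched.}
#' }
#' The input spec is left unchanged.
#'
#' @param spec a \code{\link{network_spec}}.
#' @param ko a \code{\link{knockout_spec}}.
#' @return The rewired \code{network_spec}.
#' @export
apply_knockout <- function(spec, ko) {
  stopifnot(inherits(spec, "network_spec"), inherits(ko, "knockout_spec"))
  affected_sources <- switch(ko$type,
    Netrin1 = c("V0D", "V0V"),
    DCC = c("V0D", "V0V", "V3"),
    EphA4 = "V2a")
  projs <- lapply(spec$projections, function(pr) {
    src_role <- spec$populations[[pr$source]]$role
    tgt_role <- spec$populations[[pr$target]]$role
    if (ko$type %in% c("Netrin1", "DCC")) {
      if (pr$commissural && src_role %in% affected_sources) {
        pr$crossing_fraction <- pr$crossing_fraction * (1 - ko$f_reroute)
        if (is.na(pr$reroute_target))
          pr$reroute_target <- mirror_name(pr$target)
      }
    } else {                                    # EphA4
      if (!pr$commissural && src_role == "V2a" && tgt_role == "V0V") {
        pr$crossing_fraction <- pr$crossing_fraction * (1 - ko$f_reroute)
        pr$reroute_target <- mirror_name(pr$target)
      }
    }
    pr
  })
  network_spec(spec$populations, projs, spec$tonic_drives)
}
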