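#' Realize a network specification as an explicit connectome
#'
#' Draws per-pair Bernoulli synapses for every projection (self-connections
#' excluded within recurrent projections), applies multiplicative weight
#' jitter, assigns per-neuron leak-reversal jitter, and resolves
#' crossing-fraction rerouting: each source axon reaches the nominal target
#' with probability \code{crossing_fraction} and the reroute target
#' otherwise.  The draw is fully determined by the seed.
#'
#' @param spec a \code{\link{network_spec}}.
#' @param seed integer seed; identical seeds yield bit-identical connectomes.
#' @param config parameter configuration supplying the membrane templates.
#' @return An object of class \code{connectome}: population table
#'   (\code{populations}: name, role, side, size, offset), per-neuron
#'   vectors (\code{neuron_pop}, \code{neuron_EL0}, \code{neuron_gain},
#'   \code{tonic_gE}), the synapse table in CSR-by-source layout
#'   (\code{syn_ptr}, \code{syn_target}, \code{syn_weight},
#'   \code{syn_inhib}), the packed membrane parameter matrix
#'   (\code{param_matrix}) and the seed used.
#' @export
instantiate <- function(spec, seed = 1, config = cpg_defaults()) {
  stopifnot(inherits(spec, "network_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(as.integer(seed))

  pops <- spec$populations
  sizes <- vapply(pops, `[[`, 0L, "size")
  offsets <- c(0L, cumsum(sizes))[seq_along(sizes)]
  names(offsets) <- names(pops)
  N <- sum(sizes)

  pop_table <- data.frame(
    name = names(pops),
    role = vapply(pops, `[[`, "", "role"),
    side = vapply(pops, `[[`, "", "side"),
    size = sizes, offset = offsets,
    rhythmogenic = vapply(pops, `[[`, FALSE, "rhythmogenic"),
    row.names = NULL, stringsAsFactors = FALSE)

  # two membrane classes: rhythmogenic (persistent Na present) and relay
  param_matrix <- membrane_param_matrix(
    list(rg = config$membrane$rg, relay = config$membrane$relay))
  neuron_pop <- integer(N)     # 0-based row of param_matrix per neuron? no:
  # engine's pop index selects a parameter row; use 2 classes
  neuron_class <- integer(N)
  neuron_EL0 <- numeric(N)
  neuron_gain <- numeric(N)
  neuron_gnap <- rep(1, N)
  gj <- if (is.null(config$gnap_jitter)) 0 else config$gnap_jitter
  for (i in seq_along(pops)) {
    p <- pops[[i]]
    idx <- offsets[i] + seq_len(p$size)
    neuron_class[idx] <- if (p$rhythmogenic) 0L else 1L
    neuron_EL0[idx] <- p$E_L0 +
      stats::runif(p$size, -p$E_L_spread, p$E_L_spread)
    neuron_gain[idx] <- if (p$drive_sensitive) p$drive_gain else 0
    if (p$rhythmogenic && gj > 0)
      neuron_gnap[idx] <- stats::runif(p$size, 1 - gj, 1 + gj)
  }

  tonic_gE <- numeric(N)
  for (d in spec$tonic_drives) {
    idx <- offsets[[d$target]] + seq_len(sizes[[d$target]])
    tonic_gE[idx] <- tonic_gE[idx] + d$conductance
  }

  src_list <- list()
  tgt_list <- list()
  w_list <- list()
  inh_list <- list()
  k <- 0
  for (pr in spec$projections) {
    ns <- sizes[[pr$source]]
    nt <- sizes[[pr$target]]
    src_off <- offsets[[pr$source]]
    tgt_off <- offsets[[pr$target]]
    recurrent <- pr$source == pr$target
    reroute <- pr$crossing_fraction < 1
    if (reroute) {
      rt <- if (is.na(pr$reroute_target)) mirror_name(pr$target)
            else pr$reroute_target
      if (!(rt %in% names(pops)))
        stop("reroute target names a missing population: ", rt)
      rt_off <- offsets[[rt]]
      nrt <- sizes[[rt]]
      crossed <- stats::runif(ns) < pr$crossing_fraction
    }
    for (s in seq_len(ns)) {
      if (reroute && !crossed[s]) {
        off <- rt_off; n_this <- nrt; self_ok <- TRUE
      } else {
        off <- tgt_off; n_this <- nt; self_ok <- !recurrent
      }
      hit <- which(stats::runif(n_this) < pr$p_connect)
      if (!self_ok) hit <- hit[hit != s]   # no autapses in recurrent projections
      if (length(hit) == 0) next
      w <- rep(pr$weight, length(hit))
      if (pr$weight_jitter > 0)
        w <- w * stats::runif(length(hit), 1 - pr$weight_jitter,
                              1 + pr$weight_jitter)
      k <- k + 1
      src_list[[k]] <- rep(src_off + s, length(hit))
      tgt_list[[k]] <- off + hit
      w_list[[k]] <- w
      inh_list[[k]] <- rep(pr$sign == "inhibitory", length(hit))
    }
  }
  src <- if (k > 0) unlist(src_list) else integer(0)
  tgt <- if (k > 0) unlist(tgt_list) else integer(0)
  wgt <- if (k > 0) unlist(w_list) else numeric(0)
  inh <- if (k > 0) unlist(inh_list) else logical(0)

  ord <- order(src, tgt)
  src <- src[ord]; tgt <- tgt[ord]; wgt <- wgt[ord]; inh <- inh[ord]
  syn_ptr <- c(0L, cumsum(tabulate(src, nbins = N)))

  structure(list(populations = pop_table,
                 neuron_pop = neuron_class,
                 neuron_EL0 = neuron_EL0,
                 neuron_gain = neuron_gain,
                 neuron_gnap = neuron_gnap,
                 tonic_gE = tonic_gE,
                 syn_ptr = as.integer(syn_ptr),
                 syn_target = as.integer(tgt - 1L),
                 syn_weight = wgt,
                 syn_inhib = inh,
                 param_matrix = param_matrix,
                 n_neurons = N,
                 seed = as.integer(seed)),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("Connectome: %d neurons in %d populations, %d synapses (seed %d)\n",
              x$n_neurons, nrow(x$populations), length(x$syn_target),
              x$seed))
  invisible(x)
}

#' Number of synapses between two populations of a connectome
#'
#' @param conn a \code{\link{instantiate}}d connectome.
#' @param source,target population names.
#' @return Integer synapse count.
#' @export
synapse_count <- function(conn, source, target) {
  pt <- conn$populations
  s <- pt[pt$name == source, ]
  t <- pt[pt$name == target, ]
  src_of <- rep.int(seq_len(conn$n_neurons),
                    diff(conn$syn_ptr))
  in_src <- src_of > s$offset & src_of <= s$offset + s$size
  tgt1 <- conn$syn_target + 1L
  in_tgt <- tgt1 > t$offset & tgt1 <= t$offset + t$size
  sum(in_src & in_tgt)
}
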