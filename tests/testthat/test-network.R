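role_sizes <- function(spec, side) {
  pops <- Filter(function(p) p$side == side, spec$populations)
  out <- vapply(pops, `[[`, 0L, "size")
  names(out) <- vapply(pops, `[[`, "", "role")
  tapply(out, names(out), sum)
}

# canonical role-level edge multiset for audits
role_edges <- function(spec) {
  et <- edge_table(spec, by_role = TRUE)
  sort(sprintf("%s->%s:%s%s", et$source, et$target,
               substr(et$sign, 1, 1), ifelse(et$commissural, "+x", "")))
}

test_that("Model 1 roster matches the published population counts", {
  spec <- build_model1()
  for (side in c("left", "right")) {
    rs <- role_sizes(spec, side)
    expect_equal(rs[["RG-F"]], 200L)
    expect_equal(rs[["RG-E"]], 200L)
    for (r in c("Inrg-F", "Inrg-E", "V0D", "V3", "V2a", "V0V", "InV0V"))
      expect_equal(rs[[r]], 50L)
  }
})

test_that("builders are bilaterally mirror-symmetric", {
  for (spec in list(build_model1(), build_model2(),
                    build_unified("model1"))) {
    m <- mirror_network(spec)
    expect_setequal(names(spec$populations), names(m$populations))
    expect_identical(role_edges(spec), role_edges(m))
    a <- edge_table(spec)
    b <- edge_table(m)
    key <- function(d) sort(paste(d$source, d$target, d$sign, d$weight))
    expect_identical(key(a), key(b))
  }
})

test_that("only commissural interneurons cross the midline", {
  for (spec in list(build_model1(), build_model2())) {
    et <- edge_table(spec, by_role = TRUE)
    expect_true(all(et$source[et$commissural] %in% c("V0D", "V0V", "V3")))
    # and every commissural projection is intact (full crossing)
    expect_true(all(et$crossing_fraction[et$commissural] == 1))
  }
})

test_that("Model 2 drops the InV0V relay and drives V2a from RG-E", {
  spec <- build_model2()
  roles <- vapply(spec$populations, `[[`, "", "role")
  expect_false("InV0V" %in% roles)
  et <- edge_table(spec, by_role = TRUE)
  v2a_in <- et[et$target == "V2a", ]
  expect_true(all(v2a_in$source == "RG-E"))
  expect_true(all(!v2a_in$commissural))
  # V0V excites the contralateral flexor center directly
  v0v_out <- et[et$source == "V0V", ]
  expect_true(all(v0v_out$target == "RG-F" & v0v_out$commissural &
                    v0v_out$sign == "excitatory"))
})

test_that("role-level edge tables match the frozen transcriptions", {
  model1_expected <- c(
    # half-center core, per side
    "RG-F->RG-F:e", "RG-E->RG-E:e", "RG-F->RG-E:e",
    "RG-F->Inrg-F:e", "Inrg-F->RG-E:i",
    "RG-E->Inrg-E:e", "Inrg-E->RG-F:i",
    # commissural pathways
    "RG-F->V0D:e", "V0D->RG-F:i+x",
    "RG-F->V3:e", "V3->RG-F:e+x",
    "RG-F->V2a:e", "V2a->V0V:e", "V0V->InV0V:e+x", "InV0V->RG-F:i")
  expect_identical(role_edges(build_model1()),
                   sort(rep(model1_expected, 2)))

  model2_expected <- c(
    "RG-F->RG-F:e", "RG-E->RG-E:e", "RG-F->RG-E:e",
    "RG-F->Inrg-F:e", "Inrg-F->RG-E:i",
    "RG-E->Inrg-E:e", "Inrg-E->RG-F:i",
    "RG-F->V0D:e", "V0D->RG-F:i+x",
    "RG-F->V3:e", "V3->RG-F:e+x",
    "RG-E->V2a:e", "V2a->V0V:e", "V0V->RG-F:e+x")
  expect_identical(role_edges(build_model2()),
                   sort(rep(model2_expected, 2)))

  # unified: V2b fully replaces the Inrg-mediated reciprocal inhibition and
  # the V1 circuit is added (V0D also projects to the contralateral V1)
  unified_expected <- c(
    "RG-F->RG-F:e", "RG-E->RG-E:e", "RG-F->RG-E:e",
    "RG-F->Inrg-F:e", "RG-E->Inrg-E:e",
    "RG-F->V0D:e", "V0D->RG-F:i+x",
    "RG-F->V3:e", "V3->RG-F:e+x",
    "RG-F->V2a:e", "V2a->V0V:e", "V0V->InV0V:e+x", "InV0V->RG-F:i",
    "RG-F->V2b:e", "V2b->RG-E:i",
    "RG-E->V2b:e", "V2b->RG-F:i",
    "V0D->V1:i+x", "V1->RG-E:i", "V1->InV1:i", "InV1->RG-F:i")
  expect_identical(role_edges(build_unified("model1")),
                   sort(rep(unified_expected, 2)))
})

test_that("the unified build adds the V1/V2b circuit with its drives", {
  spec <- build_unified("model1")
  for (side in c("left", "right")) {
    rs <- role_sizes(spec, side)
    expect_equal(rs[["V2b"]], 50L)    # two 25-neuron halves
    expect_equal(rs[["V1"]], 50L)
    expect_equal(rs[["InV1"]], 50L)
  }
  # V1 tonic drive is sourced contralaterally, InV1 locally
  drv <- spec$tonic_drives
  v1 <- Filter(function(d) grepl("V1$", d$target) & !grepl("InV1", d$target), drv)
  expect_length(v1, 2)
  for (d in v1) {
    side <- if (startsWith(d$target, "l-")) "left" else "right"
    expect_identical(d$source_side, spinalcpg:::other_side(side))
  }
  expect_error(build_unified("model3"))
})

test_that("instantiate realizes exact and statistical synapse counts", {
  cfg <- cpg_defaults()
  mk <- function(p_connect, n1, n2) {
    a <- population_spec("l-RG-F", "left", "RG-F", n1, -70, 0)
    b <- population_spec("l-RG-E", "left", "RG-E", n2, -60, 0)
    network_spec(list(a, b),
                 list(projection_spec("l-RG-F", "l-RG-E", "excitatory",
                                      p_connect, 0.1)))
  }
  conn <- instantiate(mk(1, 3, 3), seed = 7, config = cfg)
  expect_equal(length(conn$syn_target), 9L)

  conn <- instantiate(mk(0.1, 200, 200), seed = 7, config = cfg)
  n <- length(conn$syn_target)
  expect_lt(abs(n - 4000), 4 * sqrt(4000 * 0.9))

  expect_error(projection_spec("a", "b", "excitatory", 0, 0.1), "p_connect")
})

test_that("identical seeds yield bit-identical connectomes", {
  spec <- scale_network(build_model1(), 0.25)
  a <- instantiate(spec, seed = 42)
  b <- instantiate(spec, seed = 42)
  expect_identical(a, b)
  c <- instantiate(spec, seed = 43)
  expect_false(identical(a$syn_target, c$syn_target))
})

test_that("recurrent projections exclude self-connections", {
  a <- population_spec("l-RG-F", "left", "RG-F", 10, -70, 0)
  spec <- network_spec(list(a),
                       list(projection_spec("l-RG-F", "l-RG-F",
                                            "excitatory", 1, 0.1)))
  conn <- instantiate(spec, seed = 1)
  expect_equal(length(conn$syn_target), 90L)
  src <- rep.int(seq_len(10), diff(conn$syn_ptr))
  expect_true(all(src != conn$syn_target + 1L))
})

test_that("lesions remove populations and incident projections only", {
  spec <- build_model1()
  les <- apply_lesion(spec, lesion_spec(c("V0D", "V0V")))
  roles <- vapply(les$populations, `[[`, "", "role")
  expect_false(any(roles %in% c("V0D", "V0V")))
  # non-incident projections untouched
  gone <- c("l-V0D", "r-V0D", "l-V0V", "r-V0V")
  untouched <- Filter(function(pr) !(pr$source %in% gone) &&
                        !(pr$target %in% gone), spec$projections)
  expect_equal(length(les$projections), length(untouched))
  # input spec is unchanged (transforms are pure)
  expect_length(Filter(function(p) p$role == "V0D",
                       spec$populations), 2)
  expect_warning(apply_lesion(build_model2(), lesion_spec("InV0V")),
                 "absent")
})

test_that("hemisection removes one side, all crossings and the V1 drive", {
  spec <- build_unified("model1")
  hemi <- apply_lesion(spec, lesion_spec(hemisection_side = "left"))
  sides <- vapply(hemi$populations, `[[`, "", "side")
  expect_true(all(sides == "right"))
  expect_false(any(vapply(hemi$projections, `[[`, FALSE, "commissural")))
  v1_drives <- Filter(function(d) grepl("V1$", d$target) &
                        !grepl("InV1", d$target), hemi$tonic_drives)
  expect_length(v1_drives, 0)
  # the locally sourced InV1 drive survives
  expect_true(any(grepl("InV1", vapply(hemi$tonic_drives, `[[`, "",
                                       "target"))))
})

test_that("axon-guidance knockouts rewire the prescribed pathways", {
  spec <- build_model1()
  # f = 0: identity
  expect_identical(edge_table(apply_knockout(spec, knockout_spec("Netrin1", 0))),
                   edge_table(spec))
  net <- apply_knockout(spec, knockout_spec("Netrin1", 0.8))
  et <- edge_table(net, by_role = TRUE)
  expect_true(all(abs(et$crossing_fraction[et$commissural &
                                             et$source %in% c("V0D", "V0V")] -
                        0.2) < 1e-12))
  expect_true(all(et$crossing_fraction[et$source == "V3"] == 1))

  dcc <- apply_knockout(spec, knockout_spec("DCC", 0.8))
  et <- edge_table(dcc, by_role = TRUE)
  expect_true(all(abs(et$crossing_fraction[et$commissural] - 0.2) < 1e-12))

  eph <- apply_knockout(spec, knockout_spec("EphA4", 0.8))
  pr <- Filter(function(p) p$source == "l-V2a", eph$projections)[[1]]
  expect_equal(pr$crossing_fraction, 0.2)
  expect_identical(pr$reroute_target, "r-V0V")
  et <- edge_table(eph, by_role = TRUE)
  expect_true(all(et$crossing_fraction[et$commissural] == 1))
})

test_that("knockout then lesion composes regardless of order", {
  spec <- build_model1()
  ko <- knockout_spec("EphA4", 0.5)          # touches V2a->V0V
  les <- lesion_spec("V0D")                  # disjoint projections
  a <- apply_lesion(apply_knockout(spec, ko), les)
  b <- apply_knockout(apply_lesion(spec, les), ko)
  expect_identical(edge_table(a), edge_table(b))
})

test_that("rerouted axons reach the homologous population", {
  cfg <- cpg_defaults()
  spec <- apply_knockout(build_model1(), knockout_spec("Netrin1", 1))
  spec <- scale_network(spec, 0.25)
  conn <- instantiate(spec, seed = 3, config = cfg)
  # all V0D output now lands ipsilaterally: l-V0D -> l-RG-F only
  expect_gt(synapse_count(conn, "l-V0D", "l-RG-F"), 0)
  expect_equal(synapse_count(conn, "l-V0D", "r-RG-F"), 0)
})

test_that("network scaling preserves expected input statistics", {
  spec <- build_model1()
  sc <- scale_network(spec, 0.25)
  expect_equal(sc$populations[["l-RG-F"]]$size, 50L)
  pr0 <- spec$projections[[1]]
  pr <- sc$projections[[1]]
  # degree mode: expected in-degree p*N preserved (p raised, w kept or folded)
  n0 <- spec$populations[[pr0$source]]$size
  n1 <- sc$populations[[pr$source]]$size
  expect_equal(pr0$p_connect * n0 * pr0$weight,
               pr$p_connect * n1 * pr$weight, tolerance = 1e-12)
  # weight mode: the halved-sizes/doubled-weights rule
  sw <- scale_network(spec, 0.5, mode = "weight")
  expect_equal(sw$projections[[1]]$weight, 2 * pr0$weight)
  expect_equal(sw$projections[[1]]$p_connect, pr0$p_connect)
})
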