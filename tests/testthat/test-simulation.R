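membrane_param_matrix_stub <- function() {
  spinalcpg:::membrane_param_matrix(list(rg = membrane_parameters()))
}

test_that("an empty network yields an empty spike record", {
  res <- spinalcpg:::.cpg_simulate_cpp(
    membrane_param_matrix_stub(), integer(0), numeric(0), numeric(0),
    numeric(0), 0L, integer(0), numeric(0), logical(0), numeric(0),
    integer(0), numeric(0), numeric(0), numeric(0), numeric(0),
    c(0, 1000), c(0, 0), 0.1, 1000, 1L, 0, 50, integer(0), 1, numeric(0))
  expect_length(res$spike_time, 0)
})

test_that("identical seed and config reproduce bit-identical records", {
  cfg <- cpg_defaults()
  spec <- scale_network(build_isolated_rg(config = cfg), 0.25)
  conn <- instantiate(spec, seed = 9, config = cfg)
  prot <- alpha_ramp(0.08, 0.08, 15000)
  sc <- simulation_config(duration = 15000, seed = 9)
  a <- simulate(conn, prot, sc)
  b <- simulate(conn, prot, sc)
  expect_identical(a$time, b$time)
  expect_identical(a$neuron, b$neuron)
  expect_gt(length(a$time), 0)
  # and the optional membrane noise is seeded too
  scn <- simulation_config(duration = 5000, seed = 4, noise_sigma = 0.2)
  expect_identical(simulate(conn, prot, scn)$time,
                   simulate(conn, prot, scn)$time)
})

test_that("a population below the bursting range stays silent", {
  cfg <- cpg_defaults()
  spec <- scale_network(build_isolated_rg(config = cfg), 0.25)
  conn <- instantiate(spec, seed = 2, config = cfg)
  rec <- simulate(conn, alpha_ramp(0, 0, 12000),
                  simulation_config(duration = 12000, seed = 2))
  expect_length(rec$time[rec$time > 2000], 0)
})

test_that("protocol must cover the simulation duration", {
  cfg <- cpg_defaults()
  spec <- scale_network(build_isolated_rg(config = cfg), 0.1)
  conn <- instantiate(spec, seed = 1, config = cfg)
  expect_error(simulate(conn, alpha_ramp(0, 0.1, 5000),
                        simulation_config(duration = 10000)),
               "duration")
})

test_that("regime labels survive dt refinement on the isolated ramp", {
  cfg <- cpg_defaults()
  spec <- scale_network(build_isolated_rg(config = cfg), 0.25)
  conn <- instantiate(spec, seed = 1, config = cfg)
  prot <- alpha_ramp(0.09, 0.09, 30000)
  freqs <- vapply(c(0.1, 0.05), function(dt) {
    rec <- simulate(conn, prot, simulation_config(dt = dt, duration = 30000,
                                                  seed = 1))
    tr <- rate_histogram(rec, bin = 100)
    b <- detect_bursts(tr, "l-RG-F")
    expect_identical(classify_regime(tr, b, "l-RG-F"), "bursting")
    on <- b$onset[b$onset > 5000]
    1000 / mean(diff(on))
  }, numeric(1))
  expect_lt(abs(freqs[1] - freqs[2]) / freqs[2], 0.05)
})

test_that("voltage traces are recorded for named neurons", {
  cfg <- cpg_defaults()
  spec <- scale_network(build_isolated_rg(config = cfg), 0.1)
  conn <- instantiate(spec, seed = 1, config = cfg)
  rec <- simulate(conn, alpha_ramp(0, 0, 2000),
                  simulation_config(duration = 2000, seed = 1,
                                    record_V = c("l-RG-F", "l-RG-F#3")))
  expect_equal(ncol(rec$V), 2)
  expect_true(all(rec$V > -100 & rec$V < 60))
  expect_equal(nrow(rec$V), length(rec$V_time))
})

test_that("spike times are strictly increasing per neuron and in range", {
  cfg <- cpg_defaults()
  spec <- scale_network(build_isolated_rg(config = cfg), 0.25)
  conn <- instantiate(spec, seed = 3, config = cfg)
  rec <- simulate(conn, alpha_ramp(0.1, 0.1, 10000),
                  simulation_config(duration = 10000, seed = 3))
  expect_true(all(rec$time >= 0 & rec$time <= 10000))
  for (n in unique(rec$neuron)) {
    st <- rec$time[rec$neuron == n]
    expect_true(all(diff(st) > 0))
    # refractory gate on detection
    expect_true(all(diff(st) > membrane_parameters()$refractory))
  }
})
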