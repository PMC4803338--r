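test_that("double-exponential waveform is peak-normalized with the closed-form peak time", {
  s <- exp2_synapse(site("trunk_prox", 0.9), 0.5, 5, 10, -73, onsets = 0)
  tr <- 0.5; td <- 5
  tp <- tr * td / (td - tr) * log(td / tr)
  expect_equal(tp, 1.2783, tolerance = 1e-3)
  expect_equal(exp2_waveform(0, s), 0)
  expect_equal(exp2_waveform(tp, s), 10e-3, tolerance = 1e-9)   # peak = gmax
  expect_lt(exp2_waveform(200, s), 1e-12)
  t <- seq(0, 40, by = 0.001)
  g <- exp2_waveform(t, s)
  expect_true(all(g >= 0))
  expect_equal(max(g), 10e-3, tolerance = 1e-6)
  # superposition: k synchronous events equal k times one event
  s3 <- exp2_synapse(site("trunk_prox", 0.9), 0.5, 5, 10, -73,
                     onsets = c(0, 0, 0))
  expect_equal(exp2_waveform(t, s3), 3 * g)
  expect_error(exp2_synapse(site("soma", 0.5), 5, 0.5, 1, 0, 0), "tau_r")
})

test_that("the integrator reproduces the analytic conductance waveform", {
  site90 <- site_um(90, "apical")
  spec <- simulation_spec(duration = 30, probes = list(
    g = list(site = site90, qty = "gsyn")))
  syn <- inhibitory_synapse(site90, 20, onsets = c(5, 12))
  rec <- simulate_protocol(shared_passive, protocol(syn), spec)
  expect_equal(rec$series$g, exp2_waveform(rec$time, syn), tolerance = 1e-6)
})

test_that("distributed excitation spans 140-420 um in equal shares", {
  ex <- make_distributed_excitation()
  expect_length(ex, 8)
  expect_true(all(vapply(ex, function(e) e$gmax_nS, numeric(1)) == 2.5))
  pos <- vapply(ex, function(e) e$site$dist_um, numeric(1))
  expect_equal(range(pos), c(140, 420))
  expect_equal(diff(pos), rep(40, 7))
  one <- make_distributed_excitation(n = 1)
  expect_equal(one[[1]]$site$dist_um, 280)
  expect_equal(one[[1]]$gmax_nS, 20)
  expect_error(make_distributed_excitation(n = 0), "n must be")
})

test_that("inhibitory trains and frequency drives lay out their events", {
  tr <- make_inhibitory_train(4, 75, 70, site_um(100, "basal"), onset = 0)
  expect_equal(diff(tr$onsets), rep(1000 / 75, 3), tolerance = 1e-9)
  expect_length(make_inhibitory_train(1, 75, 10, site("soma", 0.5))$onsets, 1)
  fd <- make_frequency_drive(90, 600)
  expect_length(fd$events, 54)                      # 90 Hz x 0.6 s
  expect_error(make_frequency_drive(0), "freq")
  f80 <- make_frequency_drive(80, 600); f70 <- make_frequency_drive(70, 600)
  expect_equal(f80$events[[2]]$onset - f80$events[[1]]$onset, 1000 / 80)
  expect_equal(f70$events[[2]]$onset - f70$events[[1]]$onset, 1000 / 70)
})

test_that("jittered inhibition is truncated, seeded and conductance-additive", {
  j1 <- make_jittered_inhibition(25, 40, 1, seed = 11)
  j2 <- make_jittered_inhibition(25, 40, 1, seed = 11)
  expect_identical(j1, j2)                                 # determinism
  pos <- vapply(j1, function(e) e$site$dist_um, numeric(1))
  expect_true(all(pos >= 0 & pos <= 500))                  # trunk truncation
  # sigma = 0: co-located synapses act like one summed synapse
  j0 <- make_jittered_inhibition(25, 0, 0, seed = 1, stim_onset = t0_std)
  spec <- simulation_spec(duration = 30)
  r_many <- simulate_protocol(shared_passive,
                              do.call(protocol, j0), spec)
  r_one <- simulate_protocol(shared_passive,
                             protocol(inhibitory_synapse(
                               site_um(90, "apical"), 25,
                               onsets = t0_std + 2)), spec)
  expect_equal(r_many$series$oblique370, r_one$series$oblique370,
               tolerance = 1e-9)
})

test_that("BAC pairing degenerates to the bare step at zero conductance", {
  spec <- simulation_spec(duration = 40)
  r0 <- simulate_protocol(shared_model, make_bac_pairing(5, 0, t0 = t0_std),
                          spec)
  rs <- simulate_protocol(shared_model, std_step(), spec)
  expect_equal(r0$series$soma, rs$series$soma, tolerance = 1e-12)
  # and the distal-only variant carries no step event
  d <- make_bac_pairing(5, 14, somatic = FALSE)
  expect_true(all(vapply(d$events, inherits, logical(1), "syn_event")))
})
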