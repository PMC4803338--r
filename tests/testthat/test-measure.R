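test_that("amplitude is the maximum deviation from rest", {
  tr <- c(-73, -40, 10, -60)
  expect_equal(amplitude(tr, -73), 83)
  expect_equal(amplitude(rep(-70, 10), -70), 0)
  expect_equal(amplitude(tr + 5, -73 + 5), amplitude(tr, -73))
  expect_error(amplitude(numeric(0), -70), "empty")
})

test_that("spike detection counts threshold crossings with a refractory gap", {
  t <- seq(0, 100, by = 0.1)
  bump <- function(mu) 85 * exp(-(t - mu)^2 / (2 * 0.5^2))
  for (k in 1:3) {
    v <- -73 + Reduce(`+`, lapply(seq_len(k) * 20, bump))
    expect_length(detect_somatic_spikes(v, t, -73), k)
  }
  expect_length(detect_somatic_spikes(rep(-60, length(t)), t, -73), 0)
  # two crossings 1 ms apart collapse into one detection
  v2 <- -73 + bump(50) * (1 + 0.2 * sin(2 * pi * t))
  expect_lte(length(detect_somatic_spikes(-73 + bump(50) + bump(51), t, -73)), 1)
})

test_that("normalization and classification behave at the edges", {
  ctrl <- simulate_protocol(shared_model, std_step(),
                            simulation_spec(duration = 40))
  expect_equal(normalized_bap(ctrl, ctrl, "oblique370"), 1)
  flat <- ctrl
  flat$series$oblique370 <- rep(flat$rest[["oblique370"]],
                                length(flat$time))
  expect_equal(normalized_bap(flat, ctrl, "oblique370"), 0)
  expect_identical(classify_outcome(ctrl, ctrl, "oblique370"), "BAP_INTACT")
  # a passive model has no calcium current to normalize by
  pctrl <- simulate_protocol(shared_passive, std_step(),
                             simulation_spec(duration = 40))
  expect_error(calcium_spike_magnitude(pctrl, pctrl), "zero control")
  expect_equal(calcium_spike_magnitude(ctrl, ctrl), 1)
})

test_that("very strong early proximal inhibition silences the soma", {
  ctrl <- simulate_protocol(shared_model, std_step(),
                            simulation_spec(duration = 40))
  r <- run_step_with_inh(shared_model, 120, loc_um = 90, onset = -1)
  expect_identical(classify_outcome(r, ctrl, "oblique370"),
                   "NO_SOMATIC_SPIKE")
})

test_that("split_bimodal cuts at the widest gap", {
  b <- split_bimodal(c(0.1, 0.15, 0.2, 0.9, 0.95, 1.02))
  expect_equal(b$low, c(0.1, 0.15, 0.2))
  expect_equal(b$gap, 0.7)
  expect_error(split_bimodal(1), "at least two")
})
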