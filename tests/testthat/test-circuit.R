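test_that("silencing the interneuron reduces to the single-cell trial", {
  circ <- ffi_circuit(shared_model)
  off <- run_ffi_trial(circ, in_active = FALSE, t0 = t0_std)
  plain <- simulate_protocol(shared_model,
                             do.call(protocol,
                                     make_distributed_excitation(onset = t0_std)),
                             simulation_spec(duration = 50))
  for (p in c("soma", "oblique370", "tuft650"))
    expect_lt(max(abs(off$recording$series[[p]] - plain$series[[p]])), 1e-9)
})

test_that("slowing sodium gating strictly delays the interneuron spike", {
  lat <- vapply(c("fast", "slow"), function(v) {
    circ <- ffi_circuit(shared_model, interneuron_model(v))
    tr <- run_ffi_trial(circ, in_active = TRUE, t0 = t0_std)
    tr$recording$in_spike_time - t0_std
  }, numeric(1))
  expect_true(all(is.finite(lat)))
  expect_gt(lat[["slow"]], lat[["fast"]])
})

test_that("the feedforward delay is a couple of milliseconds and t0-invariant", {
  circ <- ffi_circuit(shared_model)
  d1 <- effective_delay(run_ffi_trial(circ, TRUE, t0 = 10))
  d2 <- effective_delay(run_ffi_trial(circ, TRUE, t0 = 17))
  expect_equal(d1, d2)
  expect_gte(d1, 2); expect_lte(d1, 3)
  expect_error(effective_delay(run_ffi_trial(circ, FALSE, t0 = 10)),
               "silenced")
})

test_that("without the excitatory source nothing fires", {
  circ <- ffi_circuit(shared_model, ex_in_gmax_nS = 0, ex_pc_total_nS = 0)
  tr <- run_ffi_trial(circ, in_active = TRUE, t0 = t0_std)
  expect_false(any(tr$events$cell == "PC"))
  expect_false(any(tr$events$cell == "IN" & tr$events$event == "spike"))
})
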