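test_that("the additive STDP rule matches its closed form", {
  rule <- stdp_rule()
  # depression branch applies at exactly zero interval
  expect_equal(stdp_delta(0) / rule$w_max, -0.00106)
  expect_equal(stdp_delta(20) / rule$w_max, 0.001 * exp(-1), tolerance = 1e-12)
  expect_lt(abs(stdp_delta(500)), 1e-14)
  expect_lt(abs(stdp_delta(-500)), 1e-14)
  # independent re-evaluation at random intervals
  set.seed(3)
  dt <- stats::runif(1000, -100, 100)
  ref <- ifelse(dt <= 0, -rule$a_minus * exp(dt / rule$tau_minus),
                rule$a_plus * exp(-dt / rule$tau_plus)) * rule$w_max
  expect_equal(stdp_delta(dt, rule), ref, tolerance = 1e-12)
})

test_that("weights never leave the hard bounds under random schedules", {
  rule <- stdp_rule()
  set.seed(9)
  for (rep in 1:20) {
    w <- stats::runif(1, rule$w_min, rule$w_max)
    steps <- stdp_delta(stats::runif(200, -40, 40), rule) *
      sample(c(1, 50), 200, replace = TRUE)
    for (s in steps) {
      w <- min(max(w + s, rule$w_min), rule$w_max)
      expect_gte(w, rule$w_min); expect_lte(w, rule$w_max)
    }
  }
})

test_that("accumulated change is linear in pairing count when unclipped", {
  r1 <- run_pairing_protocol(shared_model, "oblique", 5, n_pairings = 1,
                             w_init = 5e-5)
  r3 <- run_pairing_protocol(shared_model, "oblique", 5, n_pairings = 3,
                             w_init = 5e-5)
  expect_gt(r1$dw, 0)
  expect_equal(r3$dw, 3 * r1$dw, tolerance = 1e-12)
})

test_that("pairing sign follows the pre/post order at basal and oblique synapses", {
  for (syn in c("basal", "oblique")) {
    pos <- run_pairing_protocol(shared_model, syn, 5)
    neg <- run_pairing_protocol(shared_model, syn, -5)
    expect_gt(pos$dw, 0)
    expect_lt(neg$dw, 0)
  }
})

test_that("the distal calcium signal is bimodal in the pairing interval", {
  s <- distal_calcium_scan(shared_model, seq(-20, 20, by = 5))
  b <- split_bimodal(s$ca_integral)
  expect_gt(b$gap, 5 * max(diff(sort(b$low)), 1e-9))
  expect_gt(length(b$low), 0); expect_gt(length(b$high), 0)
  # coincident pairings sit on the high branch
  expect_true(s$ca_integral[s$dt_ms == 0] %in% b$high)
  expect_true(s$ca_integral[s$dt_ms == -20] %in% b$low)
  # without the distal synapse only the low mode remains
  s0 <- distal_calcium_scan(shared_model, c(-10, 0, 10), distal_g_nS = 0)
  expect_lt(max(s0$ca_integral), min(b$high))
  # with distal inhibition every pairing falls low
  si <- distal_calcium_scan(shared_model, c(-10, 0, 10),
                            inhibition = inhibitory_synapse(
                              site_um(460, "apical"), 50, onsets = 20 + 1.5))
  expect_lt(max(si$ca_integral), min(b$high))
})
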