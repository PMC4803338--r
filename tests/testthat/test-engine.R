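test_that("the passive cable rests exactly at the leak reversal", {
  rec <- simulate_protocol(shared_passive, protocol(),
                           simulation_spec(duration = 100))
  for (p in c("soma", "axon", "basal75", "oblique370", "tuft650"))
    expect_true(all(abs(rec$series[[p]] + 70) < 0.01), info = p)
})

test_that("passive steady state matches a direct linear-system solve", {
  skip_if_not_installed("Matrix")
  model <- shared_passive
  # long subthreshold somatic step; engine steady state at the end
  rec <- simulate_protocol(model,
                           protocol(step_current(onset = 0, amp_nA = 0.05,
                                                 dur_ms = 400)),
                           simulation_spec(duration = 400))
  cpp <- model$cpp
  n <- length(cpp$parent)
  # conductance matrix: leak on the diagonal, axial couplings off-diagonal
  G <- Matrix::sparseMatrix(i = seq_len(n), j = seq_len(n),
                            x = cpp$gleak_uS, dims = c(n, n))
  for (i in which(cpp$parent >= 0)) {
    p <- cpp$parent[i] + 1L
    g <- cpp$g_ax[i]
    G[i, i] <- G[i, i] + g; G[p, p] <- G[p, p] + g
    G[i, p] <- G[i, p] - g; G[p, i] <- G[p, i] - g
  }
  rhs <- cpp$gleak_uS * (-70)
  soma_seg <- resolve_site(model$morph, site("soma", 0.5))$seg_id
  rhs[soma_seg] <- rhs[soma_seg] + 0.05
  v <- as.numeric(Matrix::solve(G, rhs))
  for (p in c("soma", "basal75", "oblique370", "tuft650")) {
    seg <- resolve_site(model$morph, probe_set()[[p]]$site)$seg_id
    eng <- tail(rec$series[[p]], 1)
    expect_equal(eng, v[seg], tolerance = 1e-3, info = p) # within 0.1%
  }
})

test_that("a single compartment follows the analytic RC charging curve", {
  # minimal hand-built model: one passive segment, step current
  cpp <- list(parent = -1L, cm_nf = 0.1, g_ax = 0, area_cm2 = 1e-4,
              gna_uS = 0, gna2_uS = 0, na_shift = 0, na2_shift = 0,
              gkdr_uS = 0, gka_uS = 0, gcah_uS = 0, gcal_uS = 0, gkca_uS = 0,
              gleak_uS = 0.01, el = -70, kin = kinetics_defaults())
  dt <- 0.01
  res <- dendrogate:::.engine_run(
    cpp,
    list(steps = matrix(c(0, 0, 50, 0.1), 1, 4), synapses = list(),
         interneuron = NULL),
    list(dt = dt, duration = 50, v_init = -70,
         probe_seg = 0L, probe_qty = 0L), NULL)
  tau <- 0.1 / 0.01                     # C/g = 10 ms
  vinf <- -70 + 0.1 / 0.01              # +10 mV deflection
  t <- res$time
  analytic <- vinf + (-70 - vinf) * exp(-t / tau)
  expect_lt(max(abs(res$series[-1, 1] - analytic[-1])), 0.05)
})

test_that("the full model fires one spike on the threshold step", {
  rec <- simulate_protocol(shared_model, std_step(),
                           simulation_spec(duration = 40))
  spk <- detect_somatic_spikes(rec$series$soma, rec$time, rec$rest[["soma"]])
  expect_length(spk, 1)
  # resting potential is near the shunting reversal (-73 mV)
  expect_lt(abs(rec$rest[["soma"]] + 73.8), 1)
  # the somatic peak follows stimulus onset with a short latency
  peak <- rec$time[which.max(rec$series$soma)] - t0_std
  expect_gt(peak, 2); expect_lt(peak, 3)
  # the bAP attenuates along the apical tree
  amps <- vapply(c("soma", "oblique370", "tuft650"), function(p)
    amplitude(rec$series[[p]], rec$rest[[p]]), numeric(1))
  expect_true(all(diff(amps) < 0))
  expect_lt(amps[["tuft650"]] / amps[["soma"]], 0.4)
})

test_that("halving the time step leaves bAP amplitudes and classes stable", {
  # the tuft sits on the steep flank of the attenuation profile, so its
  # residual amplitude is the most step-sensitive quantity; the propagating
  # bAP amplitudes move by a few percent and no classification ever flips
  for (dt in c(0.1, 0.05)) {
    rec <- simulate_protocol(shared_model, std_step(),
                             simulation_spec(duration = 40, dt = dt))
    a <- vapply(c("basal75", "oblique370"), function(p)
      amplitude(rec$series[[p]], rec$rest[[p]]), numeric(1))
    if (dt == 0.1) ref <- a else
      expect_true(all(abs(a - ref) / ref < 0.05))
  }
  # and never flips the gating classification
  ctrl1 <- simulate_protocol(shared_model, std_step(),
                             simulation_spec(duration = 40))
  ctrl2 <- simulate_protocol(shared_model, std_step(),
                             simulation_spec(duration = 40, dt = 0.05))
  for (g in c(10, 50)) {
    r1 <- run_step_with_inh(shared_model, g)
    p <- protocol(step_current(onset = t0_std),
                  inhibitory_synapse(site_um(90, "apical"), g,
                                     onsets = t0_std + 2))
    r2 <- simulate_protocol(shared_model, p,
                            simulation_spec(duration = 40, dt = 0.05))
    expect_identical(classify_outcome(r1, ctrl1, "oblique370"),
                     classify_outcome(r2, ctrl2, "oblique370"))
  }
})

test_that("doubling the spatial discretization barely moves the spike", {
  fine <- build_neuron_model(build_simplified_pyramidal(list(
    trunk_prox_nseg = 38, trunk_dist_nseg = 146, apical_branch_nseg = 182,
    basal_branch_nseg = 182)))
  r1 <- simulate_protocol(shared_model, std_step(),
                          simulation_spec(duration = 30))
  r2 <- simulate_protocol(fine, std_step(), simulation_spec(duration = 30))
  t1 <- r1$time[which.max(r1$series$soma)]
  t2 <- r2$time[which.max(r2$series$soma)]
  expect_lte(abs(t1 - t2), 0.1)
})

test_that("simulation is deterministic and validates its inputs", {
  r1 <- simulate_protocol(shared_model, std_step(),
                          simulation_spec(duration = 25))
  r2 <- simulate_protocol(shared_model, std_step(),
                          simulation_spec(duration = 25))
  expect_identical(r1$series, r2$series)
  expect_error(simulate_protocol(shared_model,
                                 protocol(step_current(onset = 50)),
                                 simulation_spec(duration = 25)),
               "outside")
})
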