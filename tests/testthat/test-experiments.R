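test_that("bisection agrees with a dense grid sweep of the transition", {
  cc <- critical_conductance(shared_model, 90, resolution_nS = 0.5,
                             bracket_nS = c(0, 60))
  sweep <- dendrogate:::.strength_sweep(shared_model, 90,
                                        seq(20, 32, by = 1))
  grid_crit <- min(sweep$strength_nS[sweep$norm_bap < 0.5])
  expect_lt(abs(cc$critical_nS - grid_crit), 1)
  # zero strength leaves the bAP intact (valid lower bracket)
  expect_gt(sweep$norm_bap[1], 0.9)
})

test_that("window widths converge under onset-grid refinement", {
  w <- vapply(c(0.5, 0.25), function(step) {
    m <- timing_strength_map(shared_model, 90, "somatic_step", "bap",
                             strengths_nS = 50,
                             onsets_ms = seq(0, 4, by = step))
    window_width(m, 50)
  }, numeric(1))
  expect_lte(abs(w[1] - w[2]), 0.5)
})

test_that("the frequency scan reports no transition for a calcium-free cell", {
  nocalc <- build_neuron_model(channels = list(gcal_zone = 0, gcah = 0,
                                               gkca = 0))
  expect_error(critical_frequency_scan(nocalc, freqs = seq(60, 90, by = 10)),
               "no abrupt transition")
  expect_error(critical_frequency_scan(shared_model, freqs = c(80, 90)),
               "length")
})

test_that("experiments are deterministic and write tidy outputs", {
  r1 <- run_experiment("s1", shared_model, seed = 5, quick = TRUE)
  r2 <- run_experiment("s1", shared_model, seed = 5, quick = TRUE)
  expect_identical(r1$table, r2$table)
  expect_true(r1$summary$all_or_none)
  out <- file.path(tempdir(), "dg-test-out")
  run_experiment("fig7", shared_model, out_dir = out)
  expect_true(file.exists(file.path(out, "fig7.csv")))
  expect_true(file.exists(file.path(out, "fig7_meta.json")))
  meta <- jsonlite::read_json(file.path(out, "fig7_meta.json"))
  expect_equal(meta$id, "fig7")
  expect_error(run_experiment("fig99"), "arg")
})

test_that("repetitive basal inhibition gates the burst where one pulse fails", {
  tab <- run_experiment("s2", shared_model, quick = TRUE)$table
  one <- tab$norm_bap_basal[tab$n_pulses == 1 & tab$freq_hz == 75]
  four <- tab$norm_bap_basal[tab$n_pulses == 4 & tab$freq_hz == 75]
  expect_gt(one, 0.5)
  expect_lt(four, 0.5)
})

test_that("the compartment matrix reproduces the site-specific gating pattern", {
  cm <- compartment_matrix(shared_model, "bac")
  canceled <- function(cond, pr) cm$canceled[cm$condition == cond & cm$probe == pr]
  # distal inhibition kills the calcium spike but spares the bAPs below
  expect_true(canceled("distal", "tuft650"))
  expect_false(canceled("distal", "oblique370"))
  expect_false(canceled("distal", "basal75"))
  # proximal inhibition silences the apical dendrite but not the basal tree
  expect_true(canceled("proximal", "oblique370"))
  expect_true(canceled("proximal", "tuft650"))
  expect_false(canceled("proximal", "basal75"))
  # one basal pulse cannot stop the whole burst; the 75 Hz train can
  expect_false(canceled("basal", "basal75"))
  expect_true(canceled("basal_train", "basal75"))
  expect_false(canceled("basal_train", "oblique370"))
})
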