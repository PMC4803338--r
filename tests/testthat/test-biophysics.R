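test_that("A-type density law is linear with a distal clamp", {
  expect_equal(ka_density(0), 0.029)
  expect_equal(ka_density(250), 0.029 * (1 + 4 * 250 / 500)) # 0.087
  expect_equal(ka_density(500), 5 * 0.029)
  expect_equal(ka_density(600), ka_density(500))
  expect_error(ka_density(-1), "negative")
})

test_that("channel distribution follows the spatial rules", {
  m <- build_simplified_pyramidal()
  d <- assemble_channel_distribution(m)
  seg600 <- d[d$kind == "tuft" & abs(d$dist_um - 600) < 3, ][1, ]
  expect_equal(seg600$gcah, 3 * 0.00015)   # calcium zone, 3-fold Ca_H
  expect_equal(seg600$gcal, 0.005)
  soma <- d[d$kind == "soma", ][1, ]
  expect_equal(soma$gkca, 2 * 0.00025)     # 2-fold at the soma
  expect_equal(soma$gcah, 2 * 0.00015)
  expect_equal(soma$na_shift, 0)
  axon <- d[d$kind == "axon", ][1, ]
  expect_equal(axon$gna + axon$gna2, 0.6)
  expect_equal(axon$gna, axon$gna2)        # 50/50 split
  expect_equal(axon$na2_shift, -10)
  dend <- d[d$kind == "trunk", ]
  expect_true(all(dend$na_shift == 5))
  expect_true(all(dend$gna == 0.009 & dend$gkdr == 0.01))
  # basal sections use the somatic A-type value
  expect_true(all(d$gka[d$kind == "basal"] == 0.029))
  expect_error(assemble_channel_distribution(m, list(ca_zone = c(2000, 2500))),
               "outside")
})

test_that("gating steady states are probabilities over the working range", {
  v <- seq(-120, 60, by = 2)
  for (ch in c("Na", "K_DR", "K_A", "Ca_H", "Ca_L")) {
    g <- channel_gates(ch, v)
    expect_true(all(g$inf >= 0 & g$inf <= 1), info = ch)
    expect_true(all(g$tau_ms > 0), info = ch)
  }
  g <- channel_gates("K_Ca", v = rep(-60, 5), ca = c(0, 1e-4, 0.01, 0.5, 10))
  expect_true(all(g$inf >= 0 & g$inf <= 1))
})

test_that("a voltage shift translates the activation curve exactly", {
  v <- seq(-80, 20, by = 5)
  shifted <- channel_gates("Na", v, shift_act = 5)
  unshifted <- channel_gates("Na", v - 5)
  expect_equal(shifted$inf[shifted$gate == "m"],
               unshifted$inf[unshifted$gate == "m"])
})

test_that("membrane current matches an independent term-by-term sum", {
  m <- build_simplified_pyramidal()
  d <- assemble_channel_distribution(m)
  kin <- kinetics_defaults()
  pas <- list(rm = 40000, el = -70)
  set.seed(7)
  for (k in 1:20) {
    v <- stats::runif(1, -90, 30)
    row <- d[sample(nrow(d), 1), ]
    g <- list(na_m = stats::runif(1), na_h = stats::runif(1),
              kdr_n = stats::runif(1), ka_n = stats::runif(1),
              ka_l = stats::runif(1), cah_m = stats::runif(1),
              cah_h = stats::runif(1), cal_m = stats::runif(1),
              cal_h = stats::runif(1), kca_m = stats::runif(1))
    out <- membrane_current(v, g, 1e-4, row, pas, kin)
    # independent hand summation of every term
    hand <- (row$gna + row$gna2) * g$na_m^3 * g$na_h * (v - 60) +
      row$gkdr * g$kdr_n * (v + 80) +
      row$gka * g$ka_n * g$ka_l * (v + 80) +
      row$gcah * g$cah_m^2 * g$cah_h * (v - 140) +
      row$gcal * g$cal_m * g$cal_h * (v - 140) +
      row$gkca * g$kca_m * (v + 80) +
      (v + 70) / 40000
    expect_equal(unname(out["total"]), hand, tolerance = 1e-12)
  }
  # reversal potential zeroes the current
  z <- membrane_current(-80, list(na_m = 0, na_h = 0, kdr_n = 0.5, ka_n = 0,
                                  ka_l = 0, cah_m = 0, cah_h = 0, cal_m = 0,
                                  cal_h = 0, kca_m = 0),
                        1e-4, d[d$kind == "soma", ][1, ], pas, kin)
  expect_equal(unname(z["K_DR"]), 0)
  # all gates closed: only leak
  gates0 <- list(na_m = 0, na_h = 0, kdr_n = 0, ka_n = 0, ka_l = 0,
                 cah_m = 0, cah_h = 0, cal_m = 0, cal_h = 0, kca_m = 0)
  o <- membrane_current(-60, gates0, 1e-4, d[1, ], pas, kin)
  expect_equal(unname(o["total"]), unname(o["leak"]))
})
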