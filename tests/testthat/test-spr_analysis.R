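# Wild-type two-process rate constants used as generating truth throughout
wt_spr <- list(kon1 = 3200, koff1 = 0.007, kon2 = 130, koff2 = 2.0e-5,
               rmax1 = 10, rmax2 = 90)

test_that("reference subtraction is pointwise with interpolation", {
  tm <- seq(0, 100, by = 1)
  smp <- data.frame(time = tm, response = rep(100, length(tm)))
  blk <- data.frame(time = tm, response = rep(10, length(tm)))
  out <- subtract_reference(smp, blk)
  expect_equal(out$response, rep(90, length(tm)))
  # identical sample and blank -> zero
  expect_equal(subtract_reference(smp, smp)$response, rep(0, length(tm)))
  # blank of zeros -> unchanged
  blk0 <- data.frame(time = tm, response = 0)
  expect_equal(subtract_reference(smp, blk0)$response, smp$response)
  # blank on a coarser grid is interpolated
  blk2 <- data.frame(time = seq(0, 100, by = 5), response = 10)
  expect_equal(subtract_reference(smp, blk2)$response, rep(90, length(tm)))
  blk3 <- data.frame(time = seq(200, 300, by = 1), response = 0)
  expect_error(subtract_reference(smp, blk3), "cover")
})

test_that("noise-free dissociation round trip recovers both off-rates within 0.5%", {
  st <- simulate_sensorgram_set(wt_spr$kon1, wt_spr$koff1, wt_spr$kon2,
                                wt_spr$koff2, wt_spr$rmax1, wt_spr$rmax2,
                                noise_sd = 0)
  d <- fit_dissociation(st)
  expect_false(d$single_process)
  expect_equal(d$koff1, wt_spr$koff1, tolerance = 0.005)
  expect_equal(d$koff2, wt_spr$koff2, tolerance = 0.005)
  expect_gt(d$koff1, d$koff2)
  expect_true(all(d$amplitudes$A1 >= 0) && all(d$amplitudes$A2 >= 0))
})

test_that("single-exponential dissociation falls back with a flag", {
  st <- simulate_sensorgram_set(wt_spr$kon1, wt_spr$koff1, wt_spr$kon2,
                                wt_spr$koff2, wt_spr$rmax1, rmax2 = 0,
                                noise_sd = 0)
  d <- fit_dissociation(st)
  expect_true(d$single_process)
  expect_equal(d$koff1, wt_spr$koff1, tolerance = 0.005)
  expect_true(is.na(d$koff2))
})

test_that("constant response is rejected as unidentifiable", {
  tm <- seq(0, 7800, by = 10)
  df <- data.frame(time = tm, response = 50, conc = 1e-6)
  st <- sensorgram_set(df, t_inj = 600)
  expect_error(fit_dissociation(st), "constant")
  expect_error(fit_association(st, 0.007, 2e-5), "constant")
})

test_that("noise-free association round trip recovers both on-rates within 1%", {
  st <- simulate_sensorgram_set(wt_spr$kon1, wt_spr$koff1, wt_spr$kon2,
                                wt_spr$koff2, wt_spr$rmax1, wt_spr$rmax2,
                                noise_sd = 0)
  a <- fit_association(st, wt_spr$koff1, wt_spr$koff2)
  expect_equal(a$kon1, wt_spr$kon1, tolerance = 0.01)
  expect_equal(a$kon2, wt_spr$kon2, tolerance = 0.01)
  # observed rates increase strictly with concentration
  expect_true(all(diff(a$kobs$kobs1[order(a$kobs$conc)]) > 0))
  expect_true(all(diff(a$kobs$kobs2[order(a$kobs$conc)]) > 0))
  # kobs for the fast process at 1 uM: c*kon1 + koff1
  expect_equal(1e-6 * a$kon1 + wt_spr$koff1, 0.0102, tolerance = 0.01)
})

test_that("association plateau of each fitted curve equals C1 + C2", {
  st <- simulate_sensorgram_set(wt_spr$kon1, wt_spr$koff1, wt_spr$kon2,
                                wt_spr$koff2, wt_spr$rmax1, wt_spr$rmax2,
                                t_inj = 3000, noise_sd = 0)
  a <- fit_association(st, wt_spr$koff1, wt_spr$koff2)
  # analytic plateau of the fitted model vs the generating equilibrium level
  for (i in seq_len(nrow(a$amplitudes))) {
    cc <- a$amplitudes$conc[i]
    gen_plateau <-
      wt_spr$rmax1 * cc * wt_spr$kon1 / (cc * wt_spr$kon1 + wt_spr$koff1) +
      wt_spr$rmax2 * cc * wt_spr$kon2 / (cc * wt_spr$kon2 + wt_spr$koff2)
    expect_equal(a$amplitudes$C1[i] + a$amplitudes$C2[i], gen_plateau,
                 tolerance = 0.02)
  }
})

test_that("kinetic summary reproduces KD arithmetic and stays self-consistent", {
  st <- simulate_sensorgram_set(wt_spr$kon1, wt_spr$koff1, wt_spr$kon2,
                                wt_spr$koff2, wt_spr$rmax1, wt_spr$rmax2,
                                noise_sd = 0)
  d <- fit_dissociation(st)
  a <- fit_association(st, d$koff1, d$koff2)
  s <- summarize_kinetics(d, a)
  # KD_i * kon_i = koff_i to machine precision
  expect_equal(s$kd1 * s$kon1, s$koff1, tolerance = 1e-12)
  expect_equal(s$kd2 * s$kon2, s$koff2, tolerance = 1e-12)
  expect_equal(s$geo_mean_kd, sqrt(s$kd1 * s$kd2), tolerance = 1e-12)
  # fast process carries the minor share of the amplitude in this system
  expect_lt(s$amplitude_fraction_1, 0.15)
  expect_equal(s$cooperativity, "positive")
})

test_that("printed-table arithmetic: koff/kon reproduces the tabulated KDs at 2 s.f.", {
  round_sf <- function(x, sf) signif(x, sf)
  # fast and slow process of each construct with measurable binding
  expect_equal(round_sf(0.007 / 3200 * 1e6, 2), 2.2)       # WT fast
  expect_equal(round_sf(2.0e-5 / 130 * 1e6, 2), 0.15)      # WT slow
  expect_equal(round_sf(0.004 / 8000 * 1e6, 2), 0.5)       # S231D fast
  expect_equal(round_sf(4.5e-5 / 64 * 1e6, 2), 0.7)        # S231D slow
  expect_equal(round_sf(3.0e-5 / 3.0 * 1e6, 2), 10)        # S235D slow
  # S235D fast sits at 3.08 uM: consistent with the tabulated 3.0 +/- 1.0
  expect_equal(0.004 / 1300 * 1e6, 3.0, tolerance = 0.05)
  # geometric means
  expect_equal(round_sf(sqrt(0.5 * 0.7), 2), 0.59)         # S231D
  expect_equal(sqrt((0.007 / 3200) * (2e-5 / 130)) * 1e6, 0.55,
               tolerance = 0.06)
})

test_that("stochastic round trip: off-rates tight, on-rates within their information limit", {
  # the long dissociation phase pins both off-rates to a few percent; the
  # on-rates are limited by the amplitude-rate degeneracy of the association
  # equation when each curve's amplitude is free (verified by comparing the
  # residual sum of squares at the fitted and generating rates: the fitted
  # ones sit at the global minimum), so their spread is bounded much wider
  errs <- t(vapply(1:50, function(i) {
    st <- simulate_sensorgram_set(wt_spr$kon1, wt_spr$koff1, wt_spr$kon2,
                                  wt_spr$koff2, wt_spr$rmax1, wt_spr$rmax2,
                                  dt = 20, noise_sd = 0.5, seed = 7000 + i)
    d <- fit_dissociation(st)
    a <- fit_association(st, d$koff1, d$koff2)
    c(abs(d$koff1 - wt_spr$koff1) / wt_spr$koff1,
      abs(d$koff2 - wt_spr$koff2) / wt_spr$koff2,
      abs(a$kon1 - wt_spr$kon1) / wt_spr$kon1,
      abs(a$kon2 - wt_spr$kon2) / wt_spr$kon2)
  }, numeric(4)))
  med <- apply(errs, 2, median)
  expect_lt(med[1], 0.05)   # koff1
  expect_lt(med[2], 0.05)   # koff2
  expect_lt(med[3], 0.35)   # kon1
  expect_lt(med[4], 0.75)   # kon2
})

test_that("flow-cell aggregation reports mean and SD per quantity", {
  sums <- lapply(1:3, function(fc) {
    st <- simulate_sensorgram_set(wt_spr$kon1, wt_spr$koff1, wt_spr$kon2,
                                  wt_spr$koff2, wt_spr$rmax1, wt_spr$rmax2,
                                  dt = 20, noise_sd = 0.5, seed = 300 + fc)
    d <- fit_dissociation(st)
    summarize_kinetics(d, fit_association(st, d$koff1, d$koff2))
  })
  agg <- aggregate_kinetics(sums)
  expect_equal(agg$n, rep(3L, nrow(agg)))
  kd1 <- agg[agg$param == "kd1", ]
  expect_equal(kd1$mean, 2.2e-6, tolerance = 0.1)
  expect_true(all(is.finite(agg$sd)))
})
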