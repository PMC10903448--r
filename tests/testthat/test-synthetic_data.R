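test_that("all generators are deterministic for a fixed seed", {
  p_emp <- list(y0 = 0.05, a1 = 0.75, k1 = 50, a2 = 0.2, k2 = 1.5)
  t1 <- simulate_shrinkage_trace("empirical", p_emp, noise_sd = 0.01,
                                 seed = 5, rate = 200)
  t2 <- simulate_shrinkage_trace("empirical", p_emp, noise_sd = 0.01,
                                 seed = 5, rate = 200)
  expect_identical(t1, t2)

  s <- build_dilution_series(17e-6, 12, 1.5, 32e-9)
  m1 <- simulate_mst_curve("1to1", list(s1 = 900, s2 = 845, kd = 1.49e-6),
                           s, noise_rel = 0.01, seed = 5)
  m2 <- simulate_mst_curve("1to1", list(s1 = 900, s2 = 845, kd = 1.49e-6),
                           s, noise_rel = 0.01, seed = 5)
  expect_identical(m1, m2)

  g1 <- simulate_sensorgram_set(3200, 0.007, 130, 2e-5, 10, 90, dt = 60,
                                noise_sd = 0.5, seed = 5)
  g2 <- simulate_sensorgram_set(3200, 0.007, 130, 2e-5, 10, 90, dt = 60,
                                noise_sd = 0.5, seed = 5)
  expect_identical(g1, g2)
  # and the global RNG state is left untouched
  set.seed(99); before <- .Random.seed
  invisible(simulate_mst_curve("1to1",
                               list(s1 = 900, s2 = 845, kd = 1.49e-6),
                               s, noise_rel = 0.01, seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("physical shrinkage simulator obeys its osmotic limits", {
  # zero permeability: flat signal
  tr0 <- simulate_shrinkage_trace(
    "physical", list(pf = 0, c_in = 2e-4, c_out = 4e-4),
    duration = 5, rate = 100, noise_sd = 0)
  expect_equal(tr0$signal, rep(0, nrow(tr0)))
  # signal monotone non-decreasing (volume non-increasing) under hyperosmotic
  # challenge, approaching 1 as V -> n_in / c_out
  tr <- simulate_shrinkage_trace(
    "physical", list(pf = 0.04, c_in = 2e-4, c_out = 4e-4),
    duration = 5, rate = 200, noise_sd = 0)
  expect_true(all(diff(tr$signal) >= -1e-9))
  expect_gt(max(tr$signal), 0.99)
  expect_lte(max(tr$signal), 1 + 1e-6)
})

test_that("physical and empirical modes agree in the small-perturbation limit", {
  # for c_out / c_in = 1.1 the volume ODE linearised about equilibrium
  # relaxes at Pf * (S/V0) * VW * c_out^2 / c_in, i.e. essentially the rate
  # the Pf formula inverts (Pf * (S/V0) * VW * C_out) for a small gradient
  pf <- 0.02
  c_in <- 4e-4; c_out <- 4.4e-4
  g <- vesicle_geometry(100)
  k_lin <- pf * g$sv0 * 18 * c_out^2 / c_in
  tr <- simulate_shrinkage_trace(
    "physical", list(pf = pf, c_in = c_in, c_out = c_out),
    duration = 8 / k_lin, rate = 250 * k_lin, noise_sd = 0)
  fit <- fit_double_exponential(tr$time, tr$signal)
  # dominant fitted rate within 10% of the linearised prediction
  dom <- if (abs(fit$a1) >= abs(fit$a2)) fit$k1 else fit$k2
  expect_equal(dom, k_lin, tolerance = 0.10)
})

test_that("sensorgram generator is continuous at the end of injection", {
  kon1 <- 3200; koff1 <- 0.007; kon2 <- 130; koff2 <- 2e-5
  t_inj <- 600
  st <- simulate_sensorgram_set(kon1, koff1, kon2, koff2, 10, 90,
                                t_inj = t_inj, dt = 1, noise_sd = 0)
  for (cc in unique(st$conc)) {
    cv <- st[st$conc == cc, ]
    i <- which.min(abs(cv$time - t_inj))
    # association formula evaluated at t_inj equals the dissociation start
    kobs1 <- cc * kon1 + koff1; kobs2 <- cc * kon2 + koff2
    c1 <- 10 * cc * kon1 / kobs1; c2 <- 90 * cc * kon2 / kobs2
    assoc_end <- c1 * (1 - exp(-kobs1 * t_inj)) + c2 * (1 - exp(-kobs2 * t_inj))
    expect_equal(cv$response[i], assoc_end, tolerance = 1e-10)
    # no jump across the boundary
    expect_lt(abs(cv$response[i] - cv$response[i - 1]),
              5 * abs(cv$response[i - 1] - cv$response[i - 2]) + 1e-6)
  }
  # zero concentration is rejected by the container contract
  expect_error(
    simulate_sensorgram_set(3200, 0.007, 130, 2e-5, 10, 90, concs = 0),
    "positive")
})

test_that("study fixture writes all assay files plus a truth manifest, reproducibly", {
  d1 <- file.path(tempdir(), "fix1"); d2 <- file.path(tempdir(), "fix2")
  man <- make_study_fixture(d1, seed = 1, trace_rate = 100, spr_dt = 120,
                            n_flow_cells = 1)
  make_study_fixture(d2, seed = 1, trace_rate = 100, spr_dt = 120,
                     n_flow_cells = 1)
  files <- c("shrinkage_traces.csv", "mst_curves.csv", "spr_sensorgrams.csv",
             "truth_manifest.json")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_equal(man$seed, 1)
  tr <- read_table(file.path(d1, "shrinkage_traces.csv"), "trace")
  # 5 constructs x 4 conditions x 3 replicates
  expect_equal(nrow(unique(tr[c("construct", "condition", "replicate")])),
               5 * 4 * 3)
  ms <- read_table(file.path(d1, "mst_curves.csv"), "mst")
  expect_setequal(unique(ms$construct), c("WT", "S229D", "S231D", "S235D"))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("noise-free fixture parameters are recovered by the analysis chain", {
  d <- file.path(tempdir(), "fix_clean")
  man <- make_study_fixture(d, seed = 3, trace_noise_sd = 0,
                            fnorm_noise_rel = 0, spr_noise_sd = 0,
                            pf_rep_cv = 0, trace_rate = 500, spr_dt = 60,
                            n_flow_cells = 1, n_replicates = 1)
  g <- vesicle_geometry(man$radius_nm)
  tr <- read_table(file.path(d, "shrinkage_traces.csv"), "trace")
  wt <- tr[tr$construct == "WT" & tr$condition == "CaCl2", ]
  fit <- fit_double_exponential(wt$time, wt$signal)
  pf <- pf_um_per_s(compute_pf(fit$k1, g$sv0, 18, man$c_out))
  expect_equal(pf, 365, tolerance = 1e-3)
  # S231D binding curve gives back its one-to-one affinity
  ms <- read_table(file.path(d, "mst_curves.csv"), "mst")
  s231 <- ms[ms$construct == "S231D", ]
  f <- fit_mst_curve(s231$conc, s231$fnorm, man$partner_conc, model = "1to1")
  expect_equal(f$params[["kd"]], 1.49e-6, tolerance = 1e-3)
  unlink(d, recursive = TRUE)
})

test_that("default-seed study fixture reproduces the qualitative gating pattern", {
  # only wild type under Ca2+ + calmodulin drops; every construct stays
  # above the empty-liposome background
  d <- file.path(tempdir(), "fix_full")
  man <- make_study_fixture(d, seed = 1, trace_rate = 200, spr_dt = 120,
                            n_flow_cells = 1)
  g <- vesicle_geometry(man$radius_nm)
  tr <- read_table(file.path(d, "shrinkage_traces.csv"), "trace")
  pf_stats <- list()
  for (cons in unique(tr$construct)) for (cond in unique(tr$condition)) {
    sub <- tr[tr$construct == cons & tr$condition == cond, ]
    pfs <- vapply(split(sub, sub$replicate), function(r) {
      fit <- fit_double_exponential(r$time, r$signal)
      pf_um_per_s(compute_pf(fit$k1, g$sv0, 18, man$c_out))
    }, numeric(1))
    pf_stats[[paste(cons, cond, sep = "|")]] <-
      c(mean = mean(pfs), sd = sd(pfs))
  }
  verdict <- function(cons) {
    base <- pf_stats[[paste(cons, "CaCl2", sep = "|")]]
    cam <- pf_stats[[paste(cons, "CaCl2+CaM", sep = "|")]]
    z_test(base["mean"], base["sd"], cam["mean"], cam["sd"])
  }
  expect_true(verdict("WT")$significant)
  expect_gt(verdict("WT")$z, 0)
  for (cons in c("S229D", "S231D", "S235D"))
    expect_false(verdict(cons)$significant)
  unlink(d, recursive = TRUE)
})
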