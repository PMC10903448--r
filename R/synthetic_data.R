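#' Seeded simulators for stopped-flow, MST and SPR experiments
#'
#' Every generator is a pure function of its parameters and `seed`: the
#' global random-number state is saved and restored, so simulations are
#' reproducible and side-effect free.
#'
#' @name synthetic_data
NULL

# Run expr with a locally seeded RNG, restoring the global state afterwards.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a stopped-flow vesicle shrinkage trace
#'
#' Two generating modes. `"empirical"` draws the trace directly from the
#' bi-exponential observation model,
#' `y = y0 + A1*exp(-k1*(t - x0)) + A2*exp(-k2*(t - x0))`, plus i.i.d.
#' Gaussian noise. `"physical"` integrates the osmotic volume equation for a
#' spherical vesicle of fixed surface area,
#' `dV/dt = -Pf * S * VW * (c_out - n_in / V)`, with the internal osmolyte
#' amount `n_in = c_in(0) * V0` conserved, and maps volume to a normalised
#' scattering signal `(V0 - V(t)) / (V0 - Vinf)` with `Vinf = n_in / c_out`;
#' an optional small slow exponential component emulates the background
#' liposome population seen in reconstitution data.
#'
#' @param mode `"empirical"` or `"physical"`.
#' @param params named list. Empirical: `y0, a1, k1, a2, k2` and optional
#'   `x0` (default 0). Physical: `pf` (cm/s), `radius_nm` (default 100),
#'   `c_in`, `c_out` (osmol/cm^3), optional `vw` (18), `bg_amp` (background
#'   slow-component amplitude, default 0), `bg_k` (its rate, 1/s, default 1).
#' @param duration trace length, s (default 5).
#' @param rate sampling rate, Hz (default 1000).
#' @param noise_sd additive Gaussian noise SD, a.u. (default 0).
#' @param seed integer seed or `NULL`.
#' @return data.frame with `time` and `signal`.
#' @export
simulate_shrinkage_trace <- function(mode = c("empirical", "physical"),
                                     params, duration = 5, rate = 1000,
                                     noise_sd = 0, seed = NULL) {
  mode <- match.arg(mode)
  if (duration <= 0 || rate <= 0)
    stop("`duration` and `rate` must be positive", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  time <- seq(0, duration, by = 1 / rate)
  clean <- if (mode == "empirical") {
    x0 <- if (is.null(params$x0)) 0 else params$x0
    params$y0 + params$a1 * exp(-params$k1 * (time - x0)) +
      params$a2 * exp(-params$k2 * (time - x0))
  } else {
    .physical_shrinkage(time, params)
  }
  noisy <- .with_seed(seed, clean + stats::rnorm(length(time), 0, noise_sd))
  data.frame(time = time, signal = noisy)
}

.physical_shrinkage <- function(time, params) {
  pf <- params$pf
  stopifnot(is.finite(pf), pf >= 0)
  radius_nm <- if (is.null(params$radius_nm)) 100 else params$radius_nm
  vw <- if (is.null(params$vw)) 18 else params$vw
  c_in <- params$c_in
  c_out <- params$c_out
  stopifnot(c_in > 0, c_out > 0)
  r_cm <- radius_nm * 1e-7
  v0 <- 4 / 3 * pi * r_cm^3
  s_area <- 4 * pi * r_cm^2
  n_in <- c_in * v0
  if (pf == 0 || c_out <= c_in)
    vol <- rep(v0, length(time))
  else {
    rhs <- function(t, y, parms) {
      list(-pf * s_area * vw * (c_out - n_in / y[1]))
    }
    sol <- deSolve::ode(y = c(V = v0), times = time, func = rhs,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-10 * v0)
    vol <- sol[, "V"]
  }
  v_inf <- n_in / c_out
  main <- if (c_out > c_in) (v0 - vol) / (v0 - v_inf) else rep(0, length(time))
  bg_amp <- if (is.null(params$bg_amp)) 0 else params$bg_amp
  bg_k <- if (is.null(params$bg_k)) 1 else params$bg_k
  (1 - bg_amp) * main + bg_amp * (1 - exp(-bg_k * time))
}

#' Simulate an MST binding curve
#'
#' Evaluates the chosen equilibrium model along a dilution series and applies
#' multiplicative Gaussian noise, `fnorm_i = y_i * (1 + e_i)`,
#' `e_i ~ N(0, noise_rel^2)`.
#'
#' @param model `"1to1"` (params `s1, s2, kd`) or `"2to1"`
#'   (params `s0, sa, sb, kd1, kd2`); or `"flat"` (params `s`) for a
#'   non-binding control curve.
#' @param params named list of model parameters (concentrations molar).
#' @param series a [build_dilution_series()] object.
#' @param noise_rel relative noise SD (default 0).
#' @param seed integer seed or `NULL`.
#' @return data.frame with `conc` (molar) and `fnorm`.
#' @export
simulate_mst_curve <- function(model = c("1to1", "2to1", "flat"), params,
                               series, noise_rel = 0, seed = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(series, "dilution_series"))
  if (noise_rel < 0) stop("`noise_rel` must be non-negative", call. = FALSE)
  conc <- series$concentrations
  p_tot <- series$partner_conc
  y <- switch(model,
    "1to1" = signal_1to1(conc, p_tot, params$s1, params$s2, params$kd),
    "2to1" = signal_2to1(conc, p_tot, params$s0, params$sa, params$sb,
                         params$kd1, params$kd2),
    "flat" = rep(params$s, length(conc)))
  noisy <- .with_seed(seed, y * (1 + stats::rnorm(length(y), 0, noise_rel)))
  data.frame(conc = conc, fnorm = noisy)
}

#' Simulate a multi-concentration SPR sensorgram set
#'
#' Forward model of the two-process kinetics used by the analysis: during
#' association, `R(t) = sum_i Ci * (1 - exp(-(c*kon_i + koff_i) * t))` with
#' equilibrium amplitudes `Ci = Rmax_i * c * kon_i / (c * kon_i + koff_i)`;
#' after the end of injection at `t_inj` each process decays from its
#' association endpoint, `R(t) = sum_i Ai * exp(-koff_i * (t - t_inj))` with
#' `Ai = Ci * (1 - exp(-(c*kon_i + koff_i) * t_inj))`, so the trace is
#' continuous at `t_inj` by construction.
#'
#' @param kon1,kon2 association rate constants, 1/M/s.
#' @param koff1,koff2 dissociation rate constants, 1/s.
#' @param rmax1,rmax2 saturation responses of the two processes, RU.
#' @param concs analyte concentrations, molar (default the 8-point series
#'   110 nM to 3.6 uM used for a 200 ul injection at 20 ul/min).
#' @param t_inj injection end, s (default 600: 200 ul at 20 ul/min).
#' @param t_end end of the dissociation phase, s (default 7800:
#'   600 s association + 120 min dissociation).
#' @param dt sampling interval, s (default 10).
#' @param noise_sd additive Gaussian noise SD, RU (default 0).
#' @param seed integer seed or `NULL`.
#' @param flow_cell optional label.
#' @return a [sensorgram_set()].
#' @export
simulate_sensorgram_set <- function(kon1, koff1, kon2, koff2,
                                    rmax1, rmax2,
                                    concs = spr_concentration_series(),
                                    t_inj = 600, t_end = 7800, dt = 10,
                                    noise_sd = 0, seed = NULL,
                                    flow_cell = NA_character_) {
  stopifnot(t_inj > 0, t_end > t_inj, dt > 0)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  time <- seq(0, t_end, by = dt)
  one_conc <- function(cc) {
    kobs1 <- cc * kon1 + koff1
    kobs2 <- cc * kon2 + koff2
    c1 <- rmax1 * cc * kon1 / kobs1
    c2 <- rmax2 * cc * kon2 / kobs2
    a1 <- c1 * (1 - exp(-kobs1 * t_inj))
    a2 <- c2 * (1 - exp(-kobs2 * t_inj))
    resp <- ifelse(time < t_inj,
                   c1 * (1 - exp(-kobs1 * time)) +
                     c2 * (1 - exp(-kobs2 * time)),
                   a1 * exp(-koff1 * (time - t_inj)) +
                     a2 * exp(-koff2 * (time - t_inj)))
    data.frame(time = time, response = resp, conc = cc,
               phase = ifelse(time < t_inj, "assoc", "dissoc"))
  }
  df <- do.call(rbind, lapply(concs, one_conc))
  df$response <- .with_seed(
    seed, df$response + stats::rnorm(nrow(df), 0, noise_sd))
  sensorgram_set(df, t_inj = t_inj, flow_cell = flow_cell)
}

#' Default SPR analyte concentration series
#'
#' Eight concentrations log-spaced from 110 nM to 3.6 uM, the design used
#' for injections over immobilised calmodulin.
#'
#' @return numeric vector, molar.
#' @export
spr_concentration_series <- function() {
  10^seq(log10(110e-9), log10(3.6e-6), length.out = 8)
}

#' Default per-construct ground truth for the study simulator
#'
#' Encodes the effect structure of the calmodulin-gating study design:
#' wild-type permeability is reduced roughly 2.4-fold only under
#' Ca2+ + calmodulin; the three phospho-mimicking mutants (S229D, S231D,
#' S235D) conduct water like wild type in every condition; empty control
#' liposomes sit at the background level. Wild-type binding follows the
#' two-to-one cooperative model with an increasing curve, S231D the
#' one-to-one model with a decreasing curve, and S229D/S235D show no
#' binding. SPR truths are the two-process rate constants per construct.
#'
#' @return nested list keyed by construct.
#' @export
study_truth_defaults <- function() {
  pf_flat <- function(pf) list("CaCl2" = pf, "EGTA" = pf,
                               "CaCl2+CaM" = pf, "EGTA+CaM" = pf)
  list(
    WT = list(
      pf_um_s = list("CaCl2" = 365, "EGTA" = 365,
                     "CaCl2+CaM" = 126, "EGTA+CaM" = 365),
      mst = list(model = "2to1",
                 params = list(s0 = 850, sa = 880, sb = 920,
                               kd1 = 40e-6, kd2 = 2.5e-6),
                 top_conc = 156e-6, bottom_conc = 0.18e-6),
      spr = list(kon1 = 3200, koff1 = 0.007, kon2 = 130, koff2 = 2.0e-5,
                 rmax1 = 10, rmax2 = 90)),
    S229D = list(
      pf_um_s = pf_flat(350),
      mst = list(model = "flat", params = list(s = 870),
                 top_conc = 16e-6, bottom_conc = 0.18e-6),
      spr = NULL),
    S231D = list(
      pf_um_s = pf_flat(380),
      mst = list(model = "1to1",
                 params = list(s1 = 900, s2 = 845, kd = 1.49e-6),
                 top_conc = 17e-6, bottom_conc = 0.2e-6),
      spr = list(kon1 = 8000, koff1 = 0.004, kon2 = 64, koff2 = 4.5e-5,
                 rmax1 = 10, rmax2 = 90)),
    S235D = list(
      pf_um_s = pf_flat(340),
      mst = list(model = "flat", params = list(s = 860),
                 top_conc = 156e-6, bottom_conc = 1.8e-6),
      spr = list(kon1 = 1300, koff1 = 0.004, kon2 = 3.0, koff2 = 3.0e-5,
                 rmax1 = 10, rmax2 = 90)),
    control = list(
      pf_um_s = pf_flat(142.2),
      mst = NULL, spr = NULL)
  )
}

#' Write a complete synthetic study fixture to disk
#'
#' Generates input files for all three assay types with the study's design:
#' shrinkage traces for every construct x buffer condition in triplicate,
#' 12-point MST dilution series in triplicate for each binding construct,
#' and SPR sensorgram sets for the constructs with measurable binding, plus
#' a `truth_manifest.json` recording every generating parameter and the
#' seed, for recovery testing.
#'
#' Per-replicate permeability truths are jittered multiplicatively
#' (`pf_rep_cv`, default 8%) to emulate reconstitution-to-reconstitution
#' variability; each trace also receives additive Gaussian noise.
#'
#' @param dir output directory (created if missing).
#' @param seed integer master seed; every file records it.
#' @param truth per-construct truth list, see [study_truth_defaults()].
#' @param c_out external osmolality after mixing, osmol/cm^3 (default 4e-4,
#'   i.e. 400 mOsm/L from 1:1 mixing with an 800 mOsm osmolyte solution).
#' @param radius_nm vesicle radius, nm.
#' @param trace_noise_sd additive trace noise, a.u.
#' @param fnorm_noise_rel relative MST noise.
#' @param spr_noise_sd additive sensorgram noise, RU.
#' @param pf_rep_cv replicate-level coefficient of variation of Pf.
#' @param n_replicates replicate count (default 3).
#' @param n_flow_cells SPR flow cells (default 3).
#' @param trace_rate trace sampling rate, Hz.
#' @param spr_dt sensorgram sampling interval, s.
#' @return invisibly, the manifest list.
#' @export
make_study_fixture <- function(dir, seed = 1,
                               truth = study_truth_defaults(),
                               c_out = 4e-4, radius_nm = 100,
                               trace_noise_sd = 0.01,
                               fnorm_noise_rel = 0.01,
                               spr_noise_sd = 0.5,
                               pf_rep_cv = 0.08,
                               n_replicates = 3, n_flow_cells = 3,
                               trace_rate = 500, spr_dt = 10) {
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop("cannot create output directory: ", dir, call. = FALSE)
  geom <- vesicle_geometry(radius_nm)
  partner_conc <- 32e-9
  manifest <- list(seed = seed, c_out = c_out, radius_nm = radius_nm,
                   partner_conc = partner_conc,
                   trace_noise_sd = trace_noise_sd,
                   fnorm_noise_rel = fnorm_noise_rel,
                   spr_noise_sd = spr_noise_sd, pf_rep_cv = pf_rep_cv,
                   constructs = truth)

  traces <- list(); mst <- list(); spr <- list()
  i_sub <- 0L
  next_seed <- function() {
    i_sub <<- i_sub + 1L
    (seed * 10007L + i_sub) %% 2147483647L
  }

  for (cons in names(truth)) {
    tr <- truth[[cons]]
    # --- shrinkage traces ---
    for (cond in names(tr$pf_um_s)) {
      pf_true <- tr$pf_um_s[[cond]]
      for (rep_i in seq_len(n_replicates)) {
        s1 <- next_seed()
        jit <- .with_seed(s1, stats::rnorm(1, 0, pf_rep_cv))
        pf_rep <- pf_true * exp(jit)
        k1 <- pf_to_k1(pf_rep / 1e4, geom$sv0, 18, c_out)
        trc <- simulate_shrinkage_trace(
          "empirical",
          params = list(y0 = 0.05, a1 = 0.75, k1 = k1, a2 = 0.2, k2 = 1.5),
          duration = 5, rate = trace_rate,
          noise_sd = trace_noise_sd, seed = next_seed())
        traces[[length(traces) + 1L]] <- data.frame(
          time_s = trc$time, signal = trc$signal, construct = cons,
          condition = cond, replicate = rep_i)
      }
    }
    # --- MST curves ---
    if (!is.null(tr$mst)) {
      fct <- implied_dilution_factor(tr$mst$top_conc, tr$mst$bottom_conc, 12)
      series <- build_dilution_series(tr$mst$top_conc, 12, fct, partner_conc)
      for (rep_i in seq_len(n_replicates)) {
        cur <- simulate_mst_curve(tr$mst$model, tr$mst$params, series,
                                  noise_rel = fnorm_noise_rel,
                                  seed = next_seed())
        mst[[length(mst) + 1L]] <- data.frame(
          conc_molar = cur$conc, fnorm = cur$fnorm, construct = cons,
          replicate = rep_i)
      }
    }
    # --- SPR sensorgram sets ---
    if (!is.null(tr$spr)) {
      for (fc in seq_len(n_flow_cells)) {
        st <- simulate_sensorgram_set(
          tr$spr$kon1, tr$spr$koff1, tr$spr$kon2, tr$spr$koff2,
          tr$spr$rmax1, tr$spr$rmax2, dt = spr_dt,
          noise_sd = spr_noise_sd, seed = next_seed(),
          flow_cell = paste0("fc", fc))
        spr[[length(spr) + 1L]] <- data.frame(
          time_s = st$time, response_ru = st$response,
          conc_molar = st$conc, phase = st$phase, construct = cons,
          flow_cell = paste0("fc", fc))
      }
    }
  }

  utils::write.csv(do.call(rbind, traces),
                   file.path(dir, "shrinkage_traces.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, mst),
                   file.path(dir, "mst_curves.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, spr),
                   file.path(dir, "spr_sensorgrams.csv"), row.names = FALSE)
  manifest$t_inj <- 600
  jsonlite::write_json(manifest, file.path(dir, "truth_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
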