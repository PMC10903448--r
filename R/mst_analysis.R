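#' Build an MST dilution series
#'
#' Final (post-mixing) total-titrant concentrations for a serial dilution:
#' `conc[i] = top_final_conc / dilution_factor^(i-1)`. The partner (labelled
#' species) concentration is constant across the series.
#'
#' @param top_final_conc highest final titrant concentration, molar.
#' @param n_points number of points in the series (>= 1).
#' @param dilution_factor serial dilution ratio (> 1 unless `n_points == 1`).
#'   Defaults to 1.5, which reproduces typical 12-point series spanning
#'   roughly two orders of magnitude; 2 gives the classical 2:1 series.
#' @param partner_conc final labelled-partner concentration, molar.
#' @return object of class `dilution_series`: list with `concentrations`
#'   (strictly decreasing, molar), `partner_conc`, `n_points`.
#' @examples
#' s <- build_dilution_series(16e-6, 12, 1.5, 32e-9)
#' range(s$concentrations) # ~0.185 to 16 uM
#' @export
build_dilution_series <- function(top_final_conc, n_points,
                                  dilution_factor = 1.5,
                                  partner_conc = 0) {
  if (!is.finite(top_final_conc) || top_final_conc <= 0)
    stop("`top_final_conc` must be positive", call. = FALSE)
  if (n_points < 1 || n_points != round(n_points))
    stop("`n_points` must be a positive integer", call. = FALSE)
  if (n_points > 1 && (!is.finite(dilution_factor) || dilution_factor <= 1))
    stop("`dilution_factor` must be > 1", call. = FALSE)
  if (partner_conc < 0)
    stop("`partner_conc` must be non-negative", call. = FALSE)
  conc <- top_final_conc / dilution_factor^(seq_len(n_points) - 1)
  structure(list(concentrations = conc, partner_conc = partner_conc,
                 n_points = as.integer(n_points)),
            class = "dilution_series")
}

#' Dilution factor implied by a printed concentration range
#'
#' Convenience inverse of [build_dilution_series()]: the constant ratio that
#' takes `top` down to `bottom` in `n_points` steps.
#'
#' @param top,bottom highest and lowest concentration (same units).
#' @param n_points number of points in the series.
#' @return dilution factor (ratio per step).
#' @export
implied_dilution_factor <- function(top, bottom, n_points) {
  stopifnot(top > bottom, bottom > 0, n_points >= 2)
  (top / bottom)^(1 / (n_points - 1))
}

#' Extract Fnorm from a raw MST fluorescence trace
#'
#' The thermophoresis signal is the change in fluorescence on local heating:
#' the mean over a "hot" window minus the mean over a "cold" (pre-heating)
#' window. In `"ratio"` mode the conventional per-mille normalisation
#' `1000 * mean(hot) / mean(cold)` is returned instead.
#'
#' @param time,fluorescence numeric vectors of equal length (s, a.u.).
#' @param cold_window,hot_window length-2 numeric `c(start, end)` in seconds;
#'   cold must precede hot and both must lie inside the trace.
#' @param mode `"diff"` (default) or `"ratio"`.
#' @return scalar Fnorm (a.u. or per-mille).
#' @export
compute_fnorm <- function(time, fluorescence, cold_window, hot_window,
                          mode = c("diff", "ratio")) {
  mode <- match.arg(mode)
  stopifnot(length(time) == length(fluorescence),
            length(cold_window) == 2, length(hot_window) == 2)
  if (cold_window[2] > hot_window[1])
    stop("cold window must end before the hot window starts", call. = FALSE)
  if (cold_window[1] < min(time) || hot_window[2] > max(time))
    stop("windows must lie within the trace", call. = FALSE)
  in_cold <- time >= cold_window[1] & time <= cold_window[2]
  in_hot <- time >= hot_window[1] & time <= hot_window[2]
  if (!any(in_cold) || !any(in_hot))
    stop("empty averaging window", call. = FALSE)
  m_cold <- mean(fluorescence[in_cold])
  m_hot <- mean(fluorescence[in_hot])
  if (mode == "diff") m_hot - m_cold else 1000 * m_hot / m_cold
}

# Multi-start Levenberg-Marquardt minimisation of a residual function.
# Returns the best converged fit (lowest deviance) or NULL if all starts fail.
.ms_nlslm <- function(starts, resid_fn, control = NULL) {
  if (is.null(control))
    control <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                          ptol = 1e-14)
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, control = control),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  best
}

# Parameter standard errors from an nls.lm fit; NA where the normal matrix
# is singular (e.g. unidentified amplitude in a degenerate fit).
.nlslm_se <- function(fit) {
  npar <- length(fit$par)
  ndat <- length(fit$fvec)
  dof <- max(ndat - npar, 1L)
  s2 <- fit$deviance / dof
  cv <- tryCatch(s2 * solve(fit$hessian), error = function(e) NULL)
  if (is.null(cv)) return(rep(NA_real_, npar))
  d <- diag(cv)
  ifelse(d >= 0, sqrt(d), NA_real_)
}

# Small-sample corrected information criterion for least-squares fits
# (k counts the fitted parameters plus the noise variance).
.aicc <- function(rss, n, n_par) {
  k <- n_par + 1
  if (n - k - 1 <= 0) return(Inf)
  n * log(rss / n + .Machine$double.xmin) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit an MST binding curve
#'
#' Nonlinear least-squares fit of Fnorm against total titrant concentration
#' using the exact one-to-one ligand-depletion model ([signal_1to1()]), the
#' two-to-one cooperative model ([signal_2to1()]), or both with selection by
#' small-sample-corrected information criterion (`model = "auto"`; ties go to
#' the simpler model). Dissociation constants are log-parameterised and
#' multi-started on a log-spaced grid spanning the concentration range
#' (a tenth of the lowest to ten times the highest concentration).
#'
#' A curve is flagged `no_binding` when the fitted amplitude is smaller than
#' three times a median-absolute-deviation estimate of the residual noise,
#' when the fitted dissociation constant exceeds the top concentration by
#' more than `kd_range_factor` (the curve never approaches saturation in the
#' measured range), or when the standard error of every fitted dissociation
#' constant exceeds its estimate (the affinity is not determined by the
#' data).
#'
#' @param conc total titrant concentrations, molar.
#' @param fnorm thermophoresis signal per concentration (a.u.).
#' @param partner_conc labelled-partner concentration, molar.
#' @param model `"1to1"`, `"2to1"` or `"auto"`.
#' @param n_starts number of log-spaced dissociation-constant starts.
#' @param kd_range_factor `no_binding` threshold on fitted KD relative to the
#'   top concentration (default 10).
#' @param amplitude_sigma `no_binding` threshold on amplitude in robust
#'   residual SDs (default 3).
#' @return object of class `mst_fit`: list with `model_kind` (`"one_to_one"`,
#'   `"two_to_one"` or `"no_binding"`), `params` and `se` (named; KDs in
#'   molar), `rss`, `aicc`, `fitted`, `residuals`, `data`, and for
#'   `model = "auto"` the per-model criterion values in `selection`.
#' @examples
#' s <- build_dilution_series(17e-6, 12, 1.4976, 32e-9)
#' y <- signal_1to1(s$concentrations, s$partner_conc, 900, 850, 1.49e-6)
#' fit <- fit_mst_curve(s$concentrations, y, s$partner_conc, model = "1to1")
#' fit$params[["kd"]] # 1.49e-6
#' @export
fit_mst_curve <- function(conc, fnorm, partner_conc,
                          model = c("auto", "1to1", "2to1"),
                          n_starts = 8, kd_range_factor = 10,
                          amplitude_sigma = 3) {
  model <- match.arg(model)
  stopifnot(length(conc) == length(fnorm))
  keep <- is.finite(conc) & is.finite(fnorm)
  conc <- conc[keep]; fnorm <- fnorm[keep]
  n <- length(conc)
  if (n < 4) stop("need at least 4 finite curve points", call. = FALSE)

  fits <- list()
  if (model %in% c("auto", "1to1"))
    fits$one_to_one <- .fit_mst_1to1(conc, fnorm, partner_conc, n_starts)
  if (model %in% c("auto", "2to1"))
    fits$two_to_one <- .fit_mst_2to1(conc, fnorm, partner_conc, n_starts)
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits))
    stop("MST fit failed to converge from all starts (n = ", n, " points)",
         call. = FALSE)

  crit <- vapply(fits, function(f) f$aicc, numeric(1))
  # ties (and near-ties within numerical slack) favour the simpler model
  pick <- names(fits)[1]
  if (length(fits) == 2 && crit[["two_to_one"]] < crit[["one_to_one"]] - 1e-9)
    pick <- "two_to_one"
  else if (length(fits) == 1) pick <- names(fits)[1]
  out <- fits[[pick]]
  out$selection <- crit

  # no-binding decision on the selected fit
  amp <- if (out$model_kind == "one_to_one")
    abs(out$params[["s2"]] - out$params[["s1"]])
  else abs(out$params[["sb"]] - out$params[["s0"]])
  noise <- stats::mad(out$residuals, constant = 1.4826)
  floor_scale <- 1e-9 * max(1, abs(stats::median(fnorm)))
  top_kd <- if (out$model_kind == "one_to_one") out$params[["kd"]]
  else max(out$params[["kd1"]], out$params[["kd2"]])
  # an affinity whose standard error exceeds the estimate itself is not
  # determined by the data: treat it like no detectable binding
  kd_idx <- grepl("^kd", names(out$params))
  kd_undetermined <- all(is.finite(out$se[kd_idx]) &
                           out$se[kd_idx] > out$params[kd_idx])
  if (amp <= amplitude_sigma * noise + floor_scale ||
      top_kd > kd_range_factor * max(conc) || kd_undetermined) {
    out$model_kind <- "no_binding"
    out$params <- out$params[!grepl("^kd", names(out$params))]
    out$se <- out$se[!grepl("^kd", names(out$se))]
  }
  structure(out, class = "mst_fit")
}

.fit_mst_1to1 <- function(conc, fnorm, p_tot, n_starts) {
  kd_grid <- 10^seq(log10(min(conc) / 10), log10(max(conc) * 10),
                    length.out = n_starts)
  s1_0 <- fnorm[which.min(conc)]
  s2_0 <- fnorm[which.max(conc)]
  starts <- lapply(kd_grid, function(kd)
    c(s1 = s1_0, s2 = s2_0, lkd = log10(kd)))
  resid_fn <- function(p)
    fnorm - signal_1to1(conc, p_tot, p[["s1"]], p[["s2"]], 10^p[["lkd"]])
  fit <- .ms_nlslm(starts, resid_fn)
  if (is.null(fit)) return(NULL)
  p <- fit$par
  se_raw <- .nlslm_se(fit)
  names(se_raw) <- names(p)
  kd <- 10^p[["lkd"]]
  params <- c(s1 = p[["s1"]], s2 = p[["s2"]], kd = kd)
  se <- c(s1 = se_raw[["s1"]], s2 = se_raw[["s2"]],
          kd = kd * log(10) * se_raw[["lkd"]])
  list(model_kind = "one_to_one", params = params, se = se,
       rss = fit$deviance, aicc = .aicc(fit$deviance, length(conc), 3),
       fitted = fnorm - fit$fvec, residuals = fit$fvec,
       data = data.frame(conc = conc, fnorm = fnorm),
       partner_conc = p_tot)
}

.fit_mst_2to1 <- function(conc, fnorm, p_tot, n_starts) {
  ngrid <- max(4, ceiling(n_starts / 2))
  kd_grid <- 10^seq(log10(min(conc) / 10), log10(max(conc) * 10),
                    length.out = ngrid)
  s0_0 <- fnorm[which.min(conc)]
  sb_0 <- fnorm[which.max(conc)]
  sa_0 <- (s0_0 + sb_0) / 2
  starts <- list()
  for (k1 in kd_grid) for (k2 in kd_grid)
    starts[[length(starts) + 1]] <-
      c(s0 = s0_0, sa = sa_0, sb = sb_0, lkd1 = log10(k1), lkd2 = log10(k2))
  resid_fn <- function(p)
    fnorm - signal_2to1(conc, p_tot, p[["s0"]], p[["sa"]], p[["sb"]],
                        10^p[["lkd1"]], 10^p[["lkd2"]])
  # coarse screen on the start grid, then polish the most promising starts
  rss0 <- vapply(starts, function(p) sum(resid_fn(p)^2), numeric(1))
  keep <- order(rss0)[seq_len(min(6, length(starts)))]
  fit <- .ms_nlslm(starts[keep], resid_fn)
  if (is.null(fit)) return(NULL)
  p <- fit$par
  se_raw <- .nlslm_se(fit)
  names(se_raw) <- names(p)
  kd1 <- 10^p[["lkd1"]]; kd2 <- 10^p[["lkd2"]]
  params <- c(s0 = p[["s0"]], sa = p[["sa"]], sb = p[["sb"]],
              kd1 = kd1, kd2 = kd2)
  se <- c(s0 = se_raw[["s0"]], sa = se_raw[["sa"]], sb = se_raw[["sb"]],
          kd1 = kd1 * log(10) * se_raw[["lkd1"]],
          kd2 = kd2 * log(10) * se_raw[["lkd2"]])
  list(model_kind = "two_to_one", params = params, se = se,
       rss = fit$deviance, aicc = .aicc(fit$deviance, length(conc), 5),
       fitted = fnorm - fit$fvec, residuals = fit$fvec,
       data = data.frame(conc = conc, fnorm = fnorm),
       partner_conc = p_tot)
}

#' @export
print.mst_fit <- function(x, ...) {
  cat("MST binding-curve fit:", x$model_kind, "\n")
  if (x$model_kind != "no_binding") {
    kd <- x$params[grepl("^kd", names(x$params))]
    for (nm in names(kd))
      cat(sprintf("  %s = %.3g uM (se %.2g uM)\n", toupper(nm),
                  kd[[nm]] * 1e6, x$se[[nm]] * 1e6))
  }
  cat(sprintf("  RSS = %.4g over %d points\n", x$rss, nrow(x$data)))
  invisible(x)
}

#' Summarise replicate MST fits
#'
#' Mean and standard deviation of each dissociation constant across replicate
#' curve fits, reported alongside the per-fit standard errors so the spread
#' over dilution series and the fit uncertainty can be compared.
#'
#' @param fits list of `mst_fit` objects of the same model kind.
#' @return data.frame with one row per dissociation constant: `param`,
#'   `mean`, `sd` (across replicates), `mean_fit_se`, `n`.
#' @export
summarize_mst_replicates <- function(fits) {
  fits <- Filter(function(f) f$model_kind != "no_binding", fits)
  if (!length(fits)) stop("no binding fits to summarise", call. = FALSE)
  kinds <- unique(vapply(fits, function(f) f$model_kind, character(1)))
  if (length(kinds) > 1)
    stop("replicate fits have mixed model kinds: ",
         paste(kinds, collapse = ", "), call. = FALSE)
  kd_names <- grep("^kd", names(fits[[1]]$params), value = TRUE)
  do.call(rbind, lapply(kd_names, function(nm) {
    vals <- vapply(fits, function(f) f$params[[nm]], numeric(1))
    ses <- vapply(fits, function(f) f$se[[nm]], numeric(1))
    data.frame(param = nm, mean = mean(vals),
               sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
               mean_fit_se = mean(ses, na.rm = TRUE), n = length(vals))
  }))
}
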