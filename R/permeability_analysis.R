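#' Average and normalise replicate shrinkage traces
#'
#' Replicate stopped-flow light-scattering traces of the same sample are
#' interpolated onto a common time grid (the grid of the first trace,
#' restricted to the overlap of all traces), averaged pointwise, and min-max
#' normalised to `[0, 1]`. Constant offsets between replicates are removed by
#' the normalisation.
#'
#' @param traces list of data.frames with `time` (s) and `signal` (a.u.).
#' @param n_expected expected replicate count (default 3); fewer triggers a
#'   warning, not an error.
#' @return data.frame with `time` and `signal` (normalised average).
#' @export
preprocess_traces <- function(traces, n_expected = 3) {
  stopifnot(is.list(traces), length(traces) >= 1)
  if (length(traces) < n_expected)
    warning("only ", length(traces), " of ", n_expected,
            " expected replicate traces supplied", call. = FALSE)
  lo <- max(vapply(traces, function(d) min(d$time), numeric(1)))
  hi <- min(vapply(traces, function(d) max(d$time), numeric(1)))
  if (lo >= hi)
    stop("replicate traces have disjoint time ranges", call. = FALSE)
  grid <- traces[[1]]$time[traces[[1]]$time >= lo & traces[[1]]$time <= hi]
  ys <- vapply(traces, function(d)
    stats::approx(d$time, d$signal, xout = grid)$y, numeric(length(grid)))
  avg <- rowMeans(ys)
  rng <- range(avg)
  if (diff(rng) <= 0)
    stop("averaged trace is constant: nothing to normalise", call. = FALSE)
  data.frame(time = grid, signal = (avg - rng[1]) / diff(rng))
}

#' Bi-exponential fit of a vesicle shrinkage trace
#'
#' Fits `y = y0 + A1*exp(-k1*(x - x0)) + A2*exp(-k2*(x - x0))` by nonlinear
#' least squares. For a fixed pair of rate constants the baseline and the
#' amplitudes are linear, so the fit profiles them out and optimises only the
#' two log-parameterised rates, multi-started on a log-spaced grid scaled to
#' the trace's time span. After fitting, the processes are sorted so `k1` is
#' the larger rate; in a reconstitution assay the fast component reflects
#' protein-mediated water efflux, the slow one the background liposome
#' population.
#'
#' @param time,signal numeric vectors (s, a.u.).
#' @param x0 time offset, fixed (default `min(time)`); a free offset is
#'   unidentifiable jointly with the amplitudes.
#' @param degenerate_tol relative rate separation under which the two
#'   processes are flagged as near-degenerate.
#' @return object of class `double_exp_fit`: `y0`, `a1`, `k1`, `a2`, `k2`,
#'   `x0`, `se` (named), `rss`, `fitted`, `residuals`, `near_degenerate`.
#' @export
fit_double_exponential <- function(time, signal, x0 = min(time),
                                   degenerate_tol = 1e-3) {
  stopifnot(length(time) == length(signal))
  keep <- is.finite(time) & is.finite(signal)
  time <- time[keep]; signal <- signal[keep]
  n <- length(time)
  if (n < 11) stop("need at least 11 trace points", call. = FALSE)
  if (stats::sd(signal) < 1e-12 * max(1, abs(mean(signal))))
    stop("constant trace: rate constants are unidentifiable", call. = FALSE)
  tt <- time - x0
  span <- max(tt) - min(tt)
  dt <- stats::median(diff(sort(time)))
  curves <- list(data.frame(t = tt, response = signal))
  basis <- function(cv, lk)
    cbind(1, exp(-10^lk[1] * cv$t), exp(-10^lk[2] * cv$t))
  grid <- seq(log10(0.1 / span), log10(2 / dt), length.out = 14)
  pairs <- expand.grid(lk1 = grid, lk2 = grid)
  pairs <- pairs[pairs$lk1 > pairs$lk2, , drop = FALSE]
  rss0 <- apply(pairs, 1, function(p)
    sum(.varpro_eval(curves, basis, c(p[["lk1"]], p[["lk2"]]))$resid^2))
  keep_i <- order(rss0)[seq_len(min(4, nrow(pairs)))]
  starts <- lapply(keep_i, function(i)
    c(lk1 = pairs$lk1[i], lk2 = pairs$lk2[i]))
  fit <- .ms_nlslm(starts, function(p) .varpro_eval(curves, basis, p)$resid)
  if (is.null(fit))
    stop("bi-exponential fit failed to converge from all starts",
         call. = FALSE)
  ev <- .varpro_eval(curves, basis, fit$par)
  k <- 10^unname(fit$par)
  coefs <- ev$amps[1, ]            # y0, A for rate 1, A for rate 2
  ord <- order(k, decreasing = TRUE)
  k_s <- k[ord]
  a_s <- coefs[-1][ord]
  se_raw <- .nlslm_se(fit)[ord]
  se <- c(k1 = k_s[1] * log(10) * se_raw[1],
          k2 = k_s[2] * log(10) * se_raw[2])
  near_deg <- abs(log(k_s[1] / k_s[2])) < degenerate_tol
  if (near_deg)
    warning("rate constants nearly degenerate (k1 ~ k2); ",
            "amplitudes are poorly determined", call. = FALSE)
  structure(list(y0 = unname(coefs[1]), a1 = unname(a_s[1]), k1 = k_s[1],
                 a2 = unname(a_s[2]), k2 = k_s[2], x0 = x0,
                 se = se, rss = fit$deviance,
                 fitted = signal - ev$resid, residuals = ev$resid,
                 near_degenerate = near_deg, n = n),
            class = "double_exp_fit")
}

#' @export
print.double_exp_fit <- function(x, ...) {
  cat(sprintf("Bi-exponential fit: k1 = %.4g 1/s, k2 = %.4g 1/s\n",
              x$k1, x$k2))
  cat(sprintf("  y0 = %.4g, A1 = %.4g, A2 = %.4g; RSS = %.4g (n = %d)\n",
              x$y0, x$a1, x$a2, x$rss, x$n))
  invisible(x)
}

#' Spherical vesicle geometry
#'
#' Surface-to-volume ratio of a spherical vesicle, `S/V0 = 3/r`. Extrusion
#' through a 200 nm polycarbonate filter yields vesicles of roughly 100 nm
#' radius, the default.
#'
#' @param radius_nm vesicle radius in nanometres.
#' @return list with `radius_cm` and `sv0` (1/cm).
#' @export
vesicle_geometry <- function(radius_nm = 100) {
  if (!is.finite(radius_nm) || radius_nm <= 0)
    stop("`radius_nm` must be positive", call. = FALSE)
  r_cm <- radius_nm * 1e-7
  list(radius_cm = r_cm, sv0 = 3 / r_cm)
}

#' Adjust the fast rate constant for reconstitution efficiency
#'
#' Corrects the fitted fast shrinkage rate for the empty-liposome background
#' and for differences in the amount of protein incorporated, quantified by
#' densitometry factors `n1` (between constructs, normalised to the reference
#' construct) and `n2` (between replicate reconstitutions of one construct,
#' normalised to the first).
#'
#' The default `"ratio"` reading subtracts the control rate and divides by
#' the relative protein amount,
#' `k1_adj = (k1_measured - k1_control) / (n1 * n2)`, rescaling every
#' measurement to reference-construct loading. The `"literal"` reading
#' `k1_measured - k1_control * n1 * n2` is also available. Negative adjusted
#' rates are floored at zero and flagged via attribute `"floored"`.
#'
#' @param k1_measured fitted fast rate constant, 1/s.
#' @param k1_control fast rate of matched empty liposomes, 1/s.
#' @param n1,n2 reconstitution-efficiency factors (> 0, dimensionless).
#' @param mode `"ratio"` (default) or `"literal"`.
#' @return adjusted rate constant, 1/s.
#' @export
adjust_k1 <- function(k1_measured, k1_control, n1 = 1, n2 = 1,
                      mode = c("ratio", "literal")) {
  mode <- match.arg(mode)
  if (any(!is.finite(c(n1, n2))) || any(c(n1, n2) <= 0))
    stop("`n1` and `n2` must be positive", call. = FALSE)
  adj <- if (mode == "ratio") (k1_measured - k1_control) / (n1 * n2)
  else k1_measured - k1_control * n1 * n2
  floored <- adj < 0
  adj[floored] <- 0
  if (any(floored))
    warning("adjusted k1 below zero floored at 0", call. = FALSE)
  structure(adj, floored = any(floored))
}

#' Osmotic water permeability from the fast shrinkage rate
#'
#' `Pf = k1 / ((S/V0) * VW * C_out)` with `S/V0` the initial
#' surface-to-volume ratio (1/cm), `VW` the partial molar volume of water
#' (18 cm^3/mol) and `C_out` the external osmolality (osmol/cm^3). The
#' result is in cm/s; multiply by 1e4 for um/s.
#'
#' @param k1 fast rate constant, 1/s.
#' @param sv0 surface-to-volume ratio, 1/cm (see [vesicle_geometry()]).
#' @param vw partial molar volume of water, cm^3/mol (default 18).
#' @param c_out external osmolality after mixing, osmol/cm^3
#'   (1 osmol/L = 1e-3 osmol/cm^3).
#' @return Pf in cm/s.
#' @seealso [pf_to_k1()] for the inverse, [pf_um_per_s()] for unit helpers.
#' @export
compute_pf <- function(k1, sv0, vw = 18, c_out) {
  if (any(!is.finite(c(sv0, vw, c_out))) || any(c(sv0, vw, c_out) <= 0))
    stop("`sv0`, `vw` and `c_out` must be positive", call. = FALSE)
  if (any(k1 < 0)) stop("`k1` must be non-negative", call. = FALSE)
  k1 / (sv0 * vw * c_out)
}

#' Fast rate constant implied by a permeability
#'
#' Inverse of [compute_pf()]: `k1 = Pf * (S/V0) * VW * C_out`.
#'
#' @param pf osmotic permeability, cm/s.
#' @inheritParams compute_pf
#' @return k1 in 1/s.
#' @export
pf_to_k1 <- function(pf, sv0, vw = 18, c_out) {
  if (any(!is.finite(c(sv0, vw, c_out))) || any(c(sv0, vw, c_out) <= 0))
    stop("`sv0`, `vw` and `c_out` must be positive", call. = FALSE)
  pf * sv0 * vw * c_out
}

#' Convert Pf between cm/s and um/s
#' @param pf_cm_s permeability in cm/s.
#' @return permeability in um/s.
#' @export
pf_um_per_s <- function(pf_cm_s) pf_cm_s * 1e4

#' Z-test for the difference of two population means
#'
#' `Z = (mean1 - mean2) / sqrt(sigma1^2 + sigma2^2)` with a two-sided p-value
#' from the standard normal. Used to compare permeability values or binding
#' constants reported as mean +/- uncertainty.
#'
#' @param mean1,mean2 group means.
#' @param sigma1,sigma2 group uncertainties (>= 0, not both zero).
#' @param alpha significance level (default 0.05).
#' @return object of class `group_comparison`: `z`, `p`, `significant`,
#'   `alpha`.
#' @examples
#' z_test(365, 35.0, 126, 27.7) # p < 0.001
#' @export
z_test <- function(mean1, sigma1, mean2, sigma2, alpha = 0.05) {
  if (any(c(sigma1, sigma2) < 0) || any(!is.finite(c(sigma1, sigma2))))
    stop("sigmas must be finite and non-negative", call. = FALSE)
  if (sigma1 == 0 && sigma2 == 0)
    stop("at least one sigma must be positive", call. = FALSE)
  z <- (mean1 - mean2) / sqrt(sigma1^2 + sigma2^2)
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(z = z, p = p, significant = p < alpha, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Z = %.3f, two-sided p = %.3g (%ssignificant at alpha = %g)\n",
              x$z, x$p, if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Full permeability pipeline for one construct and condition
#'
#' Averages and normalises the replicate traces, fits the bi-exponential,
#' adjusts the fast rate for the empty-liposome control and reconstitution
#' efficiency, and converts to Pf.
#'
#' @param traces list of replicate trace data.frames (`time`, `signal`).
#' @param k1_control fast rate of matched empty liposomes, 1/s (0 for the
#'   control itself).
#' @param n1,n2 reconstitution factors, see [adjust_k1()].
#' @param geometry from [vesicle_geometry()].
#' @param vw partial molar water volume, cm^3/mol.
#' @param c_out external osmolality, osmol/cm^3.
#' @param adjust_mode passed to [adjust_k1()].
#' @return object of class `permeability_result`: `k1_measured`,
#'   `k1_adjusted`, `pf_cm_s`, `pf_um_s`, plus the underlying
#'   `double_exp_fit` in `$fit`.
#' @export
estimate_permeability <- function(traces, k1_control = 0, n1 = 1, n2 = 1,
                                  geometry = vesicle_geometry(),
                                  vw = 18, c_out,
                                  adjust_mode = "ratio") {
  avg <- preprocess_traces(traces)
  fit <- fit_double_exponential(avg$time, avg$signal)
  k1_adj <- adjust_k1(fit$k1, k1_control, n1, n2, mode = adjust_mode)
  pf <- compute_pf(as.numeric(k1_adj), geometry$sv0, vw, c_out)
  structure(list(k1_measured = fit$k1, k1_adjusted = as.numeric(k1_adj),
                 pf_cm_s = pf, pf_um_s = pf_um_per_s(pf), fit = fit),
            class = "permeability_result")
}
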