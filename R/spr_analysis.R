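#' Sensorgram containers
#'
#' A sensorgram set is a long data.frame with columns `time` (s from
#' injection start), `response` (RU), `conc` (molar analyte concentration)
#' and `phase` (`"assoc"` or `"dissoc"`), carrying the injection end time as
#' attribute `t_inj` and optionally a `flow_cell` label. The constructor
#' validates phase consistency against `t_inj`.
#'
#' @param data data.frame with the columns above (`phase` optional: it is
#'   derived from `t_inj` when absent).
#' @param t_inj injection end time, s; association is `[0, t_inj)`,
#'   dissociation `[t_inj, end]`.
#' @param flow_cell optional flow-cell label.
#' @return data.frame of class `sensorgram_set`.
#' @export
sensorgram_set <- function(data, t_inj, flow_cell = NA_character_) {
  req <- c("time", "response", "conc")
  if (!all(req %in% names(data)))
    stop("sensorgram data needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (!is.finite(t_inj) || t_inj <= 0)
    stop("`t_inj` must be positive", call. = FALSE)
  if (any(data$conc <= 0))
    stop("analyte concentrations must be positive", call. = FALSE)
  if (is.null(data$phase))
    data$phase <- ifelse(data$time < t_inj, "assoc", "dissoc")
  if (!all(data$phase %in% c("assoc", "dissoc")))
    stop("`phase` must be 'assoc' or 'dissoc'", call. = FALSE)
  for (cc in split(data, data$conc))
    if (is.unsorted(cc$time, strictly = FALSE))
      stop("time must be non-decreasing within each concentration",
           call. = FALSE)
  structure(data, t_inj = t_inj, flow_cell = flow_cell,
            class = c("sensorgram_set", "data.frame"))
}

#' Subtract the blank-channel contribution from a sensorgram
#'
#' Pointwise subtraction of a reference (blank flow-cell) curve. When the
#' time grids differ the blank is linearly interpolated onto the sample grid;
#' sample points outside the blank's time range are an error.
#'
#' @param sample,blank data.frames with `time` and `response` columns.
#' @return the sample with `response` replaced by the difference; other
#'   columns and attributes preserved.
#' @export
subtract_reference <- function(sample, blank) {
  stopifnot(all(c("time", "response") %in% names(sample)),
            all(c("time", "response") %in% names(blank)))
  if (min(sample$time) < min(blank$time) - 1e-9 ||
      max(sample$time) > max(blank$time) + 1e-9)
    stop("blank does not cover the sample time range", call. = FALSE)
  b <- stats::approx(blank$time, blank$response, xout = sample$time,
                     rule = 2)$y
  sample$response <- sample$response - b
  sample
}

# Variable-projection residuals for a global multi-curve exponential model:
# for fixed rate parameters the per-curve amplitudes enter linearly and are
# solved by ordinary least squares; returns residuals, amplitudes and RSS.
.varpro_eval <- function(curves, basis_fn, rates) {
  resid <- list(); amps <- list()
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    X <- basis_fn(cv, rates)
    # near-identical basis columns (e.g. both processes saturated on the
    # start grid) are harmless here: any least-squares solution gives the
    # same residual, which is all the rate screen needs
    cf <- tryCatch(
      suppressWarnings(
        stats::lsfit(X, cv$response, intercept = FALSE)$coefficients),
      error = function(e) NULL)
    if (is.null(cf) || any(!is.finite(cf))) {
      cf <- rep(0, ncol(X))
      fit <- rep(0, nrow(X))
    } else fit <- drop(X %*% cf)
    resid[[i]] <- cv$response - fit
    amps[[i]] <- cf
  }
  list(resid = unlist(resid), amps = do.call(rbind, amps))
}

#' Global bi-exponential fit of SPR dissociation phases
#'
#' Fits `R(t) = A1*exp(-koff1*t) + A2*exp(-koff2*t)` to every dissociation
#' phase in the set simultaneously, with the two dissociation rate constants
#' shared across analyte concentrations and the amplitudes free per curve.
#' Time is re-zeroed at the end of injection. Rates are log-parameterised
#' (positivity) and multi-started on a log-spaced grid over
#' `koff_range` (default 1e-6 to 1 1/s, 4 starts per decade); rate pairs are
#' screened by their variable-projection RSS and the best polished by
#' Levenberg-Marquardt. After fitting, processes are sorted so
#' `koff1 >= koff2` (process 1 is the fast one).
#'
#' If one process carries less than `min_amp_frac` of the total amplitude the
#' fit is refit as a single exponential and flagged `single_process`; `koff2`
#' and `A2` are then `NA`.
#'
#' @param set a [sensorgram_set()].
#' @param koff_range numeric length-2, bracketing rate grid (1/s).
#' @param starts_per_decade start-grid density for the rate screen.
#' @param min_amp_frac single-process fallback threshold (default 0.005).
#' @return object of class `dissociation_fit`: `koff1`, `koff2` (1/s), `se`,
#'   `amplitudes` (data.frame: conc, A1, A2), `rss`, `single_process`,
#'   `n_points`.
#' @export
fit_dissociation <- function(set, koff_range = c(1e-6, 1),
                             starts_per_decade = 4, min_amp_frac = 0.005) {
  t_inj <- attr(set, "t_inj")
  dis <- set[set$phase == "dissoc", , drop = FALSE]
  if (!nrow(dis)) stop("no dissociation-phase data", call. = FALSE)
  curves <- lapply(split(dis, dis$conc), function(d) {
    d$t <- d$time - t_inj
    d
  })
  npts <- sum(vapply(curves, nrow, integer(1)))
  if (max(vapply(curves, nrow, integer(1))) < 20)
    stop("need >= 20 dissociation points in at least one curve",
         call. = FALSE)
  if (stats::sd(dis$response) < 1e-12 * max(1, abs(mean(dis$response))))
    stop("constant response: dissociation kinetics are unidentifiable",
         call. = FALSE)

  basis2 <- function(cv, lk) cbind(exp(-10^lk[1] * cv$t),
                                   exp(-10^lk[2] * cv$t))
  grid <- seq(log10(koff_range[1]), log10(koff_range[2]),
              by = 1 / starts_per_decade)
  pairs <- expand.grid(lk1 = grid, lk2 = grid)
  pairs <- pairs[pairs$lk1 > pairs$lk2, , drop = FALSE]
  rss0 <- apply(pairs, 1, function(p)
    sum(.varpro_eval(curves, basis2, c(p[["lk1"]], p[["lk2"]]))$resid^2))
  keep <- order(rss0)[seq_len(min(4, nrow(pairs)))]
  starts <- lapply(keep, function(i)
    c(lk1 = pairs$lk1[i], lk2 = pairs$lk2[i]))
  resid_fn <- function(p) .varpro_eval(curves, basis2, p)$resid
  fit <- .ms_nlslm(starts, resid_fn)
  if (is.null(fit))
    stop("dissociation fit failed to converge from all starts", call. = FALSE)

  ev <- .varpro_eval(curves, basis2, fit$par)
  k <- 10^unname(fit$par)
  amps <- ev$amps
  # sort so process 1 is the faster dissociation
  ord <- order(k, decreasing = TRUE)
  k <- k[ord]; amps <- amps[, ord, drop = FALSE]
  se_raw <- .nlslm_se(fit)[ord]
  se <- c(koff1 = k[1] * log(10) * se_raw[1],
          koff2 = k[2] * log(10) * se_raw[2])

  tot <- sum(abs(amps))
  frac <- colSums(abs(amps)) / max(tot, .Machine$double.eps)
  single <- any(frac < min_amp_frac) || abs(log(k[1] / k[2])) < 1e-3
  if (single) {
    basis1 <- function(cv, lk) cbind(exp(-10^lk[1] * cv$t))
    starts1 <- lapply(grid, function(g) c(lk1 = g))
    fit1 <- .ms_nlslm(starts1, function(p)
      .varpro_eval(curves, basis1, p)$resid)
    ev1 <- .varpro_eval(curves, basis1, fit1$par)
    k1 <- 10^unname(fit1$par)
    se1 <- k1 * log(10) * .nlslm_se(fit1)[1]
    out <- list(koff1 = k1, koff2 = NA_real_,
                se = c(koff1 = se1, koff2 = NA_real_),
                amplitudes = data.frame(
                  conc = as.numeric(names(curves)),
                  A1 = ev1$amps[, 1], A2 = NA_real_),
                rss = fit1$deviance, single_process = TRUE,
                n_points = npts, t_inj = t_inj)
    return(structure(out, class = "dissociation_fit"))
  }
  structure(list(koff1 = k[1], koff2 = k[2], se = se,
                 amplitudes = data.frame(conc = as.numeric(names(curves)),
                                         A1 = amps[, 1], A2 = amps[, 2]),
                 rss = fit$deviance, single_process = FALSE,
                 n_points = npts, t_inj = t_inj),
            class = "dissociation_fit")
}

#' Global two-process fit of SPR association phases
#'
#' With the dissociation rate constants fixed from [fit_dissociation()], fits
#' `R(t) = C1*(1 - exp(-(c*kon1 + koff1)*t)) + C2*(1 - exp(-(c*kon2 + koff2)*t))`
#' to every association phase simultaneously: association rate constants
#' `kon1`, `kon2` shared across concentrations, amplitudes free per curve.
#' The fast dissociation process is paired with the fast association process
#' (the fixed `koff1` sits in the first exponent). Rates are
#' log-parameterised and multi-started.
#'
#' @param set a [sensorgram_set()].
#' @param koff1,koff2 dissociation rate constants (1/s), fixed.
#' @param kon_range numeric length-2 bracket for the start grid (1/M/s).
#' @param starts_per_decade start-grid density.
#' @return object of class `association_fit`: `kon1`, `kon2` (1/M/s), `se`,
#'   `amplitudes` (conc, C1, C2), `kobs` (conc, kobs1, kobs2), `rss`.
#' @export
fit_association <- function(set, koff1, koff2, kon_range = c(1e1, 1e7),
                            starts_per_decade = 2) {
  stopifnot(is.finite(koff1), koff1 > 0, is.finite(koff2), koff2 > 0)
  t_inj <- attr(set, "t_inj")
  asc <- set[set$phase == "assoc", , drop = FALSE]
  if (!nrow(asc)) stop("no association-phase data", call. = FALSE)
  curves <- split(asc, asc$conc)
  if (stats::sd(asc$response) < 1e-12 * max(1, abs(mean(asc$response))))
    stop("constant response: association kinetics are unidentifiable",
         call. = FALSE)
  basis <- function(cv, lkon) {
    c1 <- cv$conc[1]
    cbind(1 - exp(-(c1 * 10^lkon[1] + koff1) * cv$time),
          1 - exp(-(c1 * 10^lkon[2] + koff2) * cv$time))
  }
  grid <- seq(log10(kon_range[1]), log10(kon_range[2]),
              by = 1 / starts_per_decade)
  pairs <- expand.grid(lk1 = grid, lk2 = grid)
  rss0 <- apply(pairs, 1, function(p)
    sum(.varpro_eval(curves, basis, c(p[["lk1"]], p[["lk2"]]))$resid^2))
  keep <- order(rss0)[seq_len(min(4, nrow(pairs)))]
  starts <- lapply(keep, function(i)
    c(lk1 = pairs$lk1[i], lk2 = pairs$lk2[i]))
  fit <- .ms_nlslm(starts, function(p) .varpro_eval(curves, basis, p)$resid)
  if (is.null(fit))
    stop("association fit failed to converge from all starts", call. = FALSE)
  ev <- .varpro_eval(curves, basis, fit$par)
  kon <- 10^unname(fit$par)
  se_raw <- .nlslm_se(fit)
  se <- c(kon1 = kon[1] * log(10) * se_raw[1],
          kon2 = kon[2] * log(10) * se_raw[2])
  concs <- as.numeric(names(curves))
  structure(list(kon1 = kon[1], kon2 = kon[2], se = se,
                 amplitudes = data.frame(conc = concs,
                                         C1 = ev$amps[, 1], C2 = ev$amps[, 2]),
                 kobs = data.frame(conc = concs,
                                   kobs1 = concs * kon[1] + koff1,
                                   kobs2 = concs * kon[2] + koff2),
                 koff1 = koff1, koff2 = koff2,
                 rss = fit$deviance),
            class = "association_fit")
}

#' Combine dissociation and association fits into equilibrium constants
#'
#' `KD_i = koff_i / kon_i` for each process, the geometric-mean overall
#' affinity `sqrt(KD1 * KD2)` used to compare constructs when the two
#' processes cannot be mechanistically separated (cooperativity vs avidity),
#' the amplitude share of process 1, and the cooperativity classification
#' from [classify_cooperativity()].
#'
#' @param d a `dissociation_fit`.
#' @param a an `association_fit` fitted with `d`'s rate constants.
#' @return object of class `kinetic_summary`: `kd1`, `kd2`, `geo_mean_kd`
#'   (molar), `amplitude_fraction_1`, `cooperativity`, plus the input rate
#'   constants.
#' @examples
#' # Fast process koff 0.007 1/s, kon 3200 1/M/s gives KD1 = 2.2 uM
#' @export
summarize_kinetics <- function(d, a) {
  stopifnot(inherits(d, "dissociation_fit"), inherits(a, "association_fit"))
  if (a$kon1 <= 0 || a$kon2 <= 0)
    stop("association rate constants must be positive", call. = FALSE)
  kd1 <- d$koff1 / a$kon1
  kd2 <- d$koff2 / a$kon2
  amp1 <- sum(a$amplitudes$C1)
  amp_frac <- amp1 / (amp1 + sum(a$amplitudes$C2))
  structure(list(kd1 = kd1, kd2 = kd2,
                 geo_mean_kd = sqrt(kd1 * kd2),
                 amplitude_fraction_1 = amp_frac,
                 cooperativity = classify_cooperativity(kd1, kd2),
                 koff1 = d$koff1, koff2 = d$koff2,
                 kon1 = a$kon1, kon2 = a$kon2),
            class = "kinetic_summary")
}

#' @export
print.kinetic_summary <- function(x, ...) {
  cat(sprintf("Two-process kinetics: KD1 = %.3g uM, KD2 = %.3g uM\n",
              x$kd1 * 1e6, x$kd2 * 1e6))
  cat(sprintf("  geometric-mean KD = %.3g uM; amplitude fraction (fast) = %.2f\n",
              x$geo_mean_kd * 1e6, x$amplitude_fraction_1))
  cat("  cooperativity (or avidity):", x$cooperativity, "\n")
  invisible(x)
}

#' Aggregate kinetic summaries across flow cells
#'
#' Mean and standard deviation of each rate and equilibrium constant over
#' independently analysed flow cells.
#'
#' @param summaries list of `kinetic_summary` objects.
#' @return data.frame with one row per quantity: `param`, `mean`, `sd`, `n`.
#' @export
aggregate_kinetics <- function(summaries) {
  stopifnot(length(summaries) >= 1)
  qs <- c("koff1", "koff2", "kon1", "kon2", "kd1", "kd2", "geo_mean_kd",
          "amplitude_fraction_1")
  do.call(rbind, lapply(qs, function(q) {
    vals <- vapply(summaries, function(s) s[[q]], numeric(1))
    data.frame(param = q, mean = mean(vals),
               sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
               n = length(vals))
  }))
}
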