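#' Equilibrium binding models with ligand depletion
#'
#' Closed-form and numerical solvers for the free-ligand concentration when a
#' labelled partner at concentration `p_tot` is titrated with a ligand at
#' total concentration `l_tot`, plus the signal models built on top of them.
#' All concentrations are molar; convert at the I/O boundary only.
#'
#' @name binding_models
NULL

.check_conc <- function(l_tot, p_tot) {
  if (any(!is.finite(l_tot)) || any(l_tot < 0))
    stop("`l_tot` must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(p_tot)) || any(p_tot < 0))
    stop("`p_tot` must be finite and non-negative", call. = FALSE)
  invisible(TRUE)
}

.check_kd <- function(kd, name = "kd") {
  if (any(!is.finite(kd)) || any(kd <= 0))
    stop(sprintf("`%s` must be finite and positive", name), call. = FALSE)
  invisible(TRUE)
}

#' Free ligand for one-to-one binding with depletion
#'
#' Solves the mass-balance quadratic for a 1:1 complex exactly. With total
#' ligand `l_tot`, total partner `p_tot` and dissociation constant `kd`, the
#' free ligand is the physical root
#' \deqn{L_{free} = \tfrac{1}{2}(L_{tot}-P_{tot}-K_D) +
#'   \sqrt{\tfrac{1}{4}(K_D+P_{tot}-L_{tot})^2 + L_{tot} K_D}.}
#'
#' @param l_tot total ligand (titrant) concentration, molar; vectorised.
#' @param p_tot total labelled-partner concentration, molar.
#' @param kd equilibrium dissociation constant, molar.
#' @return free ligand concentration, molar, in `[0, l_tot]`.
#' @examples
#' solve_free_ligand_1to1(10e-6, 4e-6, 2e-6) # 6.899 uM
#' @export
solve_free_ligand_1to1 <- function(l_tot, p_tot, kd) {
  .check_conc(l_tot, p_tot)
  .check_kd(kd)
  b <- kd + p_tot - l_tot
  disc <- sqrt(b^2 + 4 * l_tot * kd)
  # same root written two ways; the rational form avoids the catastrophic
  # cancellation of (-b + disc) when the partner is in large excess
  lf <- ifelse(b > 0,
               2 * l_tot * kd / (b + disc),
               0.5 * (-b + disc))
  pmin(pmax(lf, 0), l_tot)
}

#' One-to-one binding signal with ligand depletion
#'
#' Signal of the labelled partner as its bound fraction changes:
#' `y = s1 + (s2 - s1) * Lfree / (Lfree + kd)`, with `Lfree` from
#' [solve_free_ligand_1to1()]. `s1` is the signal of the unbound partner,
#' `s2` of the saturated complex.
#'
#' @inheritParams solve_free_ligand_1to1
#' @param s1,s2 signals of the free and saturated labelled partner (a.u.).
#' @return signal, same length as `l_tot`.
#' @export
signal_1to1 <- function(l_tot, p_tot, s1, s2, kd) {
  stopifnot(is.finite(s1), is.finite(s2))
  lf <- solve_free_ligand_1to1(l_tot, p_tot, kd)
  s1 + (s2 - s1) * lf / (lf + kd)
}

#' Species fractions of a two-site labelled partner
#'
#' Partition function over \{free, singly bound, doubly bound\} partner with
#' stepwise macroscopic dissociation constants `kd1` (first site) and `kd2`
#' (second site): `Q = 1 + L/kd1 + L^2/(kd1*kd2)`.
#'
#' @param l_free free ligand concentration, molar.
#' @param kd1,kd2 stepwise macroscopic dissociation constants, molar.
#' @return list with components `f0`, `f1`, `f2` (fractions summing to 1).
#' @keywords internal
two_site_fractions <- function(l_free, kd1, kd2) {
  q1 <- l_free / kd1
  q2 <- l_free^2 / (kd1 * kd2)
  q <- 1 + q1 + q2
  list(f0 = 1 / q, f1 = q1 / q, f2 = q2 / q)
}

#' Free ligand for two-to-one cooperative binding
#'
#' A labelled partner with two ligand sites (stepwise constants `kd1`, `kd2`)
#' depletes ligand according to
#' `l_tot = Lfree + p_tot * (f1 + 2*f2)` with fractions from the two-site
#' partition function. The mass balance is strictly increasing in `Lfree`, so
#' the unique root in `[0, l_tot]` is found by bracketed root-finding
#' (tolerance `1e-12 * l_tot` absolute).
#'
#' @inheritParams solve_free_ligand_1to1
#' @param kd1,kd2 stepwise macroscopic dissociation constants, molar.
#' @return free ligand concentration, molar.
#' @examples
#' solve_free_ligand_2to1(5e-6, 0.4e-6, 40e-6, 2.5e-6) # ~4.83 uM
#' @export
solve_free_ligand_2to1 <- function(l_tot, p_tot, kd1, kd2) {
  .check_conc(l_tot, p_tot)
  .check_kd(kd1, "kd1")
  .check_kd(kd2, "kd2")
  solve1 <- function(lt, pt) {
    if (lt == 0) return(0)
    if (pt == 0) return(lt)
    bal <- function(lf) {
      fr <- two_site_fractions(lf, kd1, kd2)
      lf + pt * (fr$f1 + 2 * fr$f2) - lt
    }
    # bal(0) = -lt < 0, bal(lt) >= 0: root bracketed by construction
    r <- stats::uniroot(bal, c(0, lt), tol = 1e-12 * lt, maxiter = 1000L)
    if (abs(r$f.root) > 1e-6 * lt)
      stop("free-ligand solver did not converge: residual ", r$f.root,
           " at l_tot=", lt, call. = FALSE)
    r$root
  }
  mapply(solve1, l_tot, p_tot)
}

#' Two-to-one cooperative binding signal
#'
#' Population-weighted signal of the labelled partner,
#' `y = s0*f0 + sa*f1 + sb*f2`, with species fractions evaluated at the free
#' ligand concentration from [solve_free_ligand_2to1()]. `s0`, `sa`, `sb` are
#' the signals of the free, singly bound and doubly bound partner.
#'
#' @inheritParams solve_free_ligand_2to1
#' @param s0,sa,sb signals of free, singly and doubly bound partner (a.u.).
#' @return signal, same length as `l_tot`.
#' @export
signal_2to1 <- function(l_tot, p_tot, s0, sa, sb, kd1, kd2) {
  stopifnot(is.finite(s0), is.finite(sa), is.finite(sb))
  lf <- solve_free_ligand_2to1(l_tot, p_tot, kd1, kd2)
  fr <- two_site_fractions(lf, kd1, kd2)
  s0 * fr$f0 + sa * fr$f1 + sb * fr$f2
}

#' Classify cooperativity from stepwise dissociation constants
#'
#' For two identical independent sites the statistical factor alone gives
#' `kd2 = 4 * kd1`; `kd2 < 4 * kd1` therefore indicates positive
#' cooperativity (site occupation increases the affinity of the second site).
#'
#' @param kd1,kd2 stepwise macroscopic dissociation constants, molar.
#' @return `"positive"` or `"none-or-negative"`.
#' @examples
#' classify_cooperativity(40e-6, 2.5e-6) # positive
#' @export
classify_cooperativity <- function(kd1, kd2) {
  .check_kd(kd1, "kd1")
  .check_kd(kd2, "kd2")
  ifelse(kd2 < 4 * kd1, "positive", "none-or-negative")
}
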