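# Independent brute-force oracles used across test files. These solve the
# same physical problems as the package but by plain bisection on the mass
# balance, written without reference to the package internals.

# 1:1 depletion: find Lfree with Lfree + Ptot*Lfree/(Lfree+Kd) = Ltot
oracle_lfree_1to1 <- function(l_tot, p_tot, kd) {
  if (l_tot == 0) return(0)
  f <- function(lf) lf + p_tot * lf / (lf + kd) - l_tot
  lo <- 0; hi <- l_tot
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# two-site depletion: Ltot = Lfree + Ptot*(f1 + 2*f2) with partition function
# Q = 1 + L/K1 + L^2/(K1*K2)
oracle_lfree_2to1 <- function(l_tot, p_tot, kd1, kd2) {
  if (l_tot == 0) return(0)
  f <- function(lf) {
    q <- 1 + lf / kd1 + lf^2 / (kd1 * kd2)
    bound_per_p <- (lf / kd1 + 2 * lf^2 / (kd1 * kd2)) / q
    lf + p_tot * bound_per_p - l_tot
  }
  lo <- 0; hi <- l_tot
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

oracle_fractions <- function(lf, kd1, kd2) {
  q <- 1 + lf / kd1 + lf^2 / (kd1 * kd2)
  c(f0 = 1 / q, f1 = (lf / kd1) / q, f2 = (lf^2 / (kd1 * kd2)) / q)
}

# mass-balance residual (relative) of a claimed free-ligand value
mass_balance_resid_1to1 <- function(lf, l_tot, p_tot, kd) {
  if (l_tot == 0) return(abs(lf))
  abs(lf + p_tot * lf / (lf + kd) - l_tot) / l_tot
}

mass_balance_resid_2to1 <- function(lf, l_tot, p_tot, kd1, kd2) {
  if (l_tot == 0) return(abs(lf))
  q <- 1 + lf / kd1 + lf^2 / (kd1 * kd2)
  bound <- (lf / kd1 + 2 * lf^2 / (kd1 * kd2)) / q
  abs(lf + p_tot * bound - l_tot) / l_tot
}
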