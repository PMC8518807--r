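# Shared fixtures and independent oracles.

R_GAS <- 8.314

ab_text <- c(
  "species A init=1",
  "species B init=0",
  "reaction R1: A <-> B ; kf=2, kr=1",
  "system T=300 flow=0")

# Central finite-difference Jacobian (oracle for the analytic one).
fd_jacobian <- function(net, conc, h_rel = 1e-6) {
  n <- length(conc)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- h_rel * max(abs(conc[j]), 1)
    cp <- conc; cm <- conc
    cp[j] <- cp[j] + h
    cm[j] <- max(cm[j] - h, 0)
    J[, j] <- (time_derivatives(net, cp) - time_derivatives(net, cm)) /
      (cp[j] - cm[j])
  }
  J
}

# Eigenvalue oracle for stability (independent of the Routh-Hurwitz path).
eig_verdict <- function(A, tol = 1e-9) {
  ev <- eigen(A, only.values = TRUE)$values
  s <- max(abs(ev), 1)
  if (any(Re(ev) > tol * s)) "unstable"
  else if (any(abs(Re(ev)) <= tol * s)) "marginal"
  else "stable"
}

# Positive real roots of a polynomial (coefficients in increasing powers),
# via base R polyroot: oracle for steady-state counts of 1-species models.
positive_real_roots <- function(coeffs, tol = 1e-8) {
  r <- polyroot(coeffs)
  re <- Re(r[abs(Im(r)) < tol * (1 + abs(r))])
  sort(re[re > tol])
}

# Random strictly positive composition.
rand_conc <- function(n, lo = 0.1, hi = 2) exp(runif(n, log(lo), log(hi)))
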