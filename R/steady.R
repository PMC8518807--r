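#' Locate steady states by multistart root search
#'
#' Finds the non-negative roots of `dc/dt = 0`.  For closed (or partially
#' closed) systems the root problem is augmented with the conserved-moiety
#' constraints `m . c = m . c_init`, so the states returned live on the
#' stoichiometric compatibility class of the network's initial composition.
#' Starts are drawn log-uniformly over a concentration window (default
#' `[1e-6, 1e2]` mol/L) plus any user guesses; a damped Newton iteration in
#' log-concentration space polishes each start; converged roots are
#' deduplicated and classified by [classify_stability()].
#'
#' @param net a [reaction_network].
#' @param n_starts number of random starts (default 64).
#' @param seed RNG seed for the starts (default 20210805).
#' @param guesses optional list/matrix of starting compositions.
#' @param window log-uniform sampling window, c(lo, hi) in mol/L.
#' @param residual_tol acceptance threshold on `max |dc/dt|`
#'   (mol/(L s), default 1e-9).
#' @param dedup_tol relative distance below which two roots are the same.
#' @param verify_integration if TRUE (default), each root is additionally
#'   checked by a short integration started from a nearby composition.
#' @return list of `steady_state` objects, each with fields `conc`,
#'   `residual_norm`, `jacobian_eigenvalues`, `verdict`
#'   (stable/unstable/marginal) and `n_unstable`.
#' @export
find_steady_states <- function(net, n_starts = 64, seed = DEFAULT_SEED,
                               guesses = NULL, window = c(1e-6, 1e2),
                               residual_tol = 1e-9, dedup_tol = 1e-6,
                               verify_integration = TRUE) {
  stopifnot(n_starts >= 1)
  n_sp <- n_species(net)
  free <- which(!net$species$clamped)
  L <- conservation_laws(net)
  target <- if (ncol(L)) drop(crossprod(L, initial_state(net))) else numeric(0)
  starts <- with_seed(seed, {
    m <- matrix(exp(stats::runif(n_starts * length(free),
                                 log(window[1]), log(window[2]))),
                nrow = n_starts)
    m
  })
  if (!is.null(guesses)) {
    gm <- if (is.matrix(guesses)) guesses else do.call(rbind, guesses)
    starts <- rbind(gm[, free, drop = FALSE], starts)
  }
  ## integration-seeded starts: a few multistart points are relaxed toward
  ## their attractors first, which catches stable roots that plain Newton
  ## walks away from (e.g. beyond a fold of the rate function)
  n_relax <- min(8, nrow(starts))
  relaxed <- list()
  for (i in seq_len(n_relax)) {
    cc <- initial_state(net)
    cc[free] <- starts[i, ]
    r <- integrate_to_steady(net, cc, tol = residual_tol, max_chunks = 6)
    if (!is.null(r)) relaxed[[length(relaxed) + 1]] <- pmax(r[free], 1e-300)
  }
  if (length(relaxed))
    starts <- rbind(do.call(rbind, relaxed), starts)
  roots <- list()
  for (i in seq_len(nrow(starts))) {
    sol <- newton_log(net, starts[i, ], free, L, target, residual_tol)
    if (is.null(sol)) next
    if (any(sol < -1e-12)) next        # negative-component root: discard
    sol[sol < 0] <- 0
    dup <- FALSE
    for (r in roots) {
      if (max(abs(sol - r)) / (1 + max(abs(r))) < dedup_tol) { dup <- TRUE; break }
    }
    if (!dup) roots[[length(roots) + 1]] <- sol
  }
  if (!length(roots)) {
    warning("no steady state found in ", nrow(starts), " starts")
    return(list())
  }
  out <- lapply(roots, function(cc) steady_state_at(net, cc, residual_tol,
                                                    verify_integration))
  out[!vapply(out, is.null, logical(1))]
}

## Damped Newton in log-concentration space on the clamped-free species,
## with conservation constraints appended.  Returns the full concentration
## vector or NULL on failure.
newton_log <- function(net, start_free, free, L, target, residual_tol,
                       max_iter = 300) {
  conc <- initial_state(net)
  u <- log(pmax(start_free, 1e-300))
  Lf <- if (ncol(L)) L[free, , drop = FALSE] else NULL
  Ffun <- function(u) {
    conc[free] <- exp(u)
    d <- time_derivatives(net, conc)[free]
    if (ncol(L)) c(d, drop(crossprod(Lf, exp(u))) - target) else d
  }
  Jfun <- function(u) {
    conc[free] <- exp(u)
    J <- jacobian_at(net, conc)[free, free, drop = FALSE]
    Ju <- J * rep(exp(u), each = length(free))
    if (ncol(L)) rbind(Ju, t(Lf * exp(u))) else Ju
  }
  Fv <- Ffun(u)
  fn <- max(abs(Fv))
  for (it in seq_len(max_iter)) {
    if (fn < residual_tol * 1e-3) break
    step <- tryCatch(qr.solve(Jfun(u), -Fv, tol = 1e-13),
                     error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    smax <- max(abs(step))
    if (smax > 3) step <- step * (3 / smax)   # trust region in log space
    lambda <- 1
    stalled <- FALSE
    repeat {
      u2 <- u + lambda * step
      F2 <- tryCatch(Ffun(u2), error = function(e) NULL)
      if (!is.null(F2) && all(is.finite(F2)) && max(abs(F2)) < fn) break
      lambda <- lambda / 2
      if (lambda < 1e-8) { stalled <- TRUE; break }
    }
    if (stalled) break                 # accept if already converged below
    u <- u2; Fv <- F2; fn <- max(abs(F2))
  }
  if (fn >= residual_tol) return(NULL)
  conc[free] <- exp(u)
  conc
}

steady_state_at <- function(net, conc, residual_tol = 1e-9,
                            verify_integration = TRUE) {
  d <- time_derivatives(net, conc)
  res <- max(abs(d))
  if (res > residual_tol) return(NULL)
  J <- jacobian_at(net, conc)
  cls <- classify_stability(J, conserved = conservation_laws(net),
                            clamped = net$species$clamped)
  verified <- NA
  if (verify_integration) {
    tau <- relaxation_time(net, conc)
    near <- conc * (1 + 1e-8) + 1e-14
    tr <- tryCatch(integrate_network(net, near, t_end = 0.01 * tau, n_out = 3),
                   error = function(e) NULL)
    verified <- !is.null(tr) && all(is.finite(final_state(tr)))
  }
  structure(list(conc = conc, residual_norm = res,
                 jacobian_eigenvalues = cls$eigenvalues,
                 verdict = cls$verdict, n_unstable = cls$n_unstable,
                 routh_hurwitz = cls$routh_hurwitz,
                 verified = verified,
                 clamped_caveat = any(net$species$clamped)),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat("steady state (", x$verdict, "): ",
      paste(names(x$conc), "=", signif(x$conc, 10), collapse = ", "), "\n",
      sep = "")
  cat("  max|dc/dt| = ", x$residual_norm,
      "; unstable modes: ", x$n_unstable, "\n", sep = "")
  if (isTRUE(x$clamped_caveat))
    cat("  [clamped scenario: boundary species held fixed]\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Stability
## ---------------------------------------------------------------------------

## Characteristic polynomial coefficients of A via Faddeev-LeVerrier:
## p(s) = s^n + c1 s^(n-1) + ... + cn.  Returns c(1, c1, ..., cn).
char_poly <- function(A) {
  n <- nrow(A)
  cs <- numeric(n + 1)
  cs[1] <- 1
  M <- diag(n)
  for (k in seq_len(n)) {
    M <- A %*% M
    cs[k + 1] <- -sum(diag(M)) / k
    M <- M + cs[k + 1] * diag(n)
  }
  cs
}

## Number of right-half-plane roots of a real polynomial by the Routh array.
## coeffs: c(a0, a1, ..., an), a0 != 0 (descending powers).  Returns a list
## with n_rhp and degenerate (TRUE when a zero pivot / zero row was hit and
## an epsilon substitution was needed).
routh_rhp_count <- function(coeffs) {
  coeffs <- coeffs / coeffs[1]
  n <- length(coeffs) - 1
  if (n == 0) return(list(n_rhp = 0L, degenerate = FALSE))
  ncol_r <- ceiling((n + 1) / 2)
  rows <- matrix(0, n + 1, ncol_r)
  r1 <- coeffs[seq(1, n + 1, by = 2)]
  r2 <- coeffs[seq(2, n + 1, by = 2)]
  rows[1, seq_along(r1)] <- r1
  rows[2, seq_along(r2)] <- r2
  degenerate <- FALSE
  scale <- max(abs(coeffs))
  eps0 <- 1e-30 * scale
  for (i in 3:(n + 1)) {
    piv <- rows[i - 1, 1]
    if (abs(piv) < eps0) {
      if (all(abs(rows[i - 1, ]) < eps0)) {
        ## zero row: differentiate the auxiliary polynomial of the row above
        degenerate <- TRUE
        ord <- n - i + 3                   # degree of auxiliary polynomial
        aux <- rows[i - 2, ]
        pw <- seq(ord, by = -2, length.out = ncol_r)
        rows[i - 1, ] <- aux * pmax(pw, 0)
        piv <- rows[i - 1, 1]
        if (abs(piv) < eps0) piv <- eps0
      } else {
        degenerate <- TRUE
        piv <- eps0
        rows[i - 1, 1] <- piv
      }
    }
    for (j in seq_len(ncol_r - 1)) {
      rows[i, j] <- (piv * rows[i - 2, j + 1] -
                     rows[i - 2, 1] * rows[i - 1, j + 1]) / piv
    }
  }
  first <- rows[, 1]
  first <- first[abs(first) > 0]
  n_rhp <- sum(diff(sign(first)) != 0)
  list(n_rhp = as.integer(n_rhp), degenerate = degenerate)
}

#' Classify local stability of a Jacobian
#'
#' Applies the Routh-Hurwitz criterion to the characteristic polynomial
#' (computed by Faddeev-LeVerrier) *and* computes the eigenvalues directly;
#' the two verdicts must agree, otherwise the state is reported `marginal`
#' with a warning.  Structural zero modes — conserved moieties of a closed
#' system and clamped species — are deflated first by projecting the
#' Jacobian onto the stoichiometric subspace, so they never masquerade as
#' marginal dynamics.
#'
#' @param jacobian square matrix (species x species).
#' @param conserved optional conserved-moiety matrix ([conservation_laws()]);
#'   its span is removed before analysis.
#' @param clamped optional logical vector marking clamped species, whose
#'   rows/columns are removed.
#' @param tol eigenvalue real-part tolerance for calling a mode neutral.
#' @return list with `verdict` ("stable", "unstable" or "marginal"),
#'   `n_unstable`, `eigenvalues` (of the deflated Jacobian),
#'   `routh_hurwitz` (RHP root count and degeneracy flag) and `agreement`.
#' @export
classify_stability <- function(jacobian, conserved = NULL, clamped = NULL,
                               tol = 1e-9) {
  A <- as.matrix(jacobian)
  if (!is.null(clamped) && any(clamped)) {
    keep <- !clamped
    A <- A[keep, keep, drop = FALSE]
    if (!is.null(conserved)) conserved <- conserved[keep, , drop = FALSE]
  }
  if (!is.null(conserved) && ncol(conserved) > 0) {
    n <- nrow(A)
    Q <- qr.Q(qr(cbind(conserved, diag(n))))[, -seq_len(ncol(conserved)),
                                             drop = FALSE]
    A <- t(Q) %*% A %*% Q
  }
  if (nrow(A) == 0)
    return(list(verdict = "stable", n_unstable = 0L,
                eigenvalues = complex(0), routh_hurwitz = NULL,
                agreement = TRUE))
  ev <- eigen(A, only.values = TRUE)$values
  scale <- max(abs(ev), 1)
  n_pos <- sum(Re(ev) > tol * scale)
  n_neu <- sum(abs(Re(ev)) <= tol * scale)
  eig_verdict <- if (n_pos > 0) "unstable" else if (n_neu > 0) "marginal"
                 else "stable"
  cp <- char_poly(A)
  rh <- tryCatch(routh_rhp_count(cp), error = function(e) NULL)
  overflow <- is.null(rh) || any(!is.finite(cp))
  if (overflow) {
    warning("characteristic polynomial unusable; eigenvalue verdict only")
    verdict <- eig_verdict
    rh <- list(n_rhp = NA_integer_, degenerate = TRUE)
  } else {
    rh_verdict <- if (rh$n_rhp > 0) "unstable"
                  else if (rh$degenerate) "marginal" else "stable"
    if (eig_verdict == "marginal" || rh_verdict == "marginal") {
      verdict <- "marginal"
    } else if (rh_verdict == eig_verdict) {
      verdict <- eig_verdict
    } else {
      warning("Routh-Hurwitz and eigenvalue verdicts disagree (",
              rh_verdict, " vs ", eig_verdict, "); reporting marginal")
      verdict <- "marginal"
    }
  }
  list(verdict = verdict, n_unstable = n_pos, eigenvalues = ev,
       routh_hurwitz = rh,
       agreement = !overflow && (rh$n_rhp > 0) == (n_pos > 0))
}
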