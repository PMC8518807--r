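#' Integrate a reaction network in time
#'
#' Stiff-capable adaptive integration of the kinetic equations
#' (deSolve's `lsoda`/`lsodar` with the analytic Jacobian).  Tolerances
#' default tight (`rtol = 1e-10`, `atol = 1e-12`) because entropy balances
#' are differences of nearly equal numbers.  With `stop_at_steady = TRUE`
#' integration halts as soon as `max |dc/dt| < steady_tol` (root finding on
#' the residual), which is how steady states are reached "by numerical
#' integration of the composition".
#'
#' @param net a [reaction_network].
#' @param c0 initial concentrations (mol/L); defaults to the network's
#'   declared initial state.
#' @param t_end final time (s).
#' @param n_out number of equally spaced output times (>= 2).
#' @param rtol,atol solver tolerances.
#' @param stop_at_steady stop early once the residual drops below
#'   `steady_tol`.
#' @param steady_tol residual threshold (mol/(L s)) for the early stop.
#' @param times explicit output times, overriding `t_end`/`n_out`.
#' @return a `trajectory`: list with `times`, `states` (time x species
#'   matrix), `derivatives` (same shape) and the originating `network`.
#' @export
integrate_network <- function(net, c0 = initial_state(net), t_end = NULL,
                              n_out = 201, rtol = 1e-10, atol = 1e-12,
                              stop_at_steady = FALSE, steady_tol = 1e-12,
                              times = NULL) {
  c0 <- check_conc(net, c0)
  if (is.null(times)) {
    if (is.null(t_end) || t_end <= 0) stop("t_end must be positive")
    times <- seq(0, t_end, length.out = max(2, n_out))
  }
  rhs <- function(t, y, parms) {
    y[y < 0 & y > -atol] <- 0
    list(time_derivatives(net, y))
  }
  jac <- function(t, y, parms) {
    y[y < 0 & y > -atol] <- 0
    jacobian_at(net, y)
  }
  if (stop_at_steady) {
    rootfun <- function(t, y, parms) {
      y[y < 0 & y > -atol] <- 0
      max(abs(time_derivatives(net, y))) - steady_tol
    }
    sol <- deSolve::lsodar(y = c0, times = times, func = rhs,
                           jacfunc = jac, jactype = "fullusr",
                           rootfunc = rootfun, rtol = rtol, atol = atol,
                           maxsteps = 50000)
  } else {
    sol <- deSolve::lsoda(y = c0, times = times, func = rhs,
                          jacfunc = jac, jactype = "fullusr",
                          rtol = rtol, atol = atol, maxsteps = 50000)
  }
  st <- unname(sol[, -1, drop = FALSE])
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0)
    stop("solver failure at t = ", sol[nrow(sol), 1],
         "; last state: ", paste(signif(st[nrow(st), ], 6), collapse = ", "))
  ## clip integration noise below atol to zero
  st[st < 0 & st > -atol] <- 0
  if (any(st < 0))
    stop("negative concentration beyond tolerance at t = ",
         sol[which(st < 0, arr.ind = TRUE)[1, 1], 1])
  colnames(st) <- net$species$name
  deriv <- t(apply(st, 1, function(cc) time_derivatives(net, cc)))
  if (n_species(net) == 1) deriv <- matrix(deriv, ncol = 1)
  colnames(deriv) <- net$species$name
  structure(list(times = unname(sol[, 1]), states = st,
                 derivatives = deriv, network = net),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  n <- length(x$times)
  cat("trajectory:", n, "points, t in [", x$times[1], ",", x$times[n], "] s\n")
  cat("final state:",
      paste(colnames(x$states), "=", signif(x$states[n, ], 8),
            collapse = ", "), "\n")
  cat("final max|dc/dt| =", max(abs(x$derivatives[n, ])), "\n")
  invisible(x)
}

#' @export
plot.trajectory <- function(x, log = "", ...) {
  graphics::matplot(x$times, x$states, type = "l", lty = 1, log = log,
                    xlab = "time (s)", ylab = "concentration (mol/L)", ...)
  graphics::legend("topright", colnames(x$states), col = seq_len(ncol(x$states)),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Final state of a trajectory
#' @param traj a `trajectory`.
#' @return named concentration vector at the last time point.
#' @export
final_state <- function(traj) {
  stats::setNames(traj$states[nrow(traj$states), ], colnames(traj$states))
}

## Characteristic relaxation time from the Jacobian at a state: 1/|Re| of
## the slowest non-structural mode.  Fallback when the spectrum is all-zero.
relaxation_time <- function(net, conc) {
  Q <- stoich_subspace(net)
  J <- jacobian_at(net, conc)
  ev <- eigen(t(Q) %*% J %*% Q, only.values = TRUE)$values
  re <- abs(Re(ev))
  re <- re[re > 1e-12]
  if (!length(re)) return(1)
  1 / min(re)
}
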