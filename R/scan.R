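#' Parameter-branch scan with hysteresis detection
#'
#' Continuation along a parameter grid: at each grid point the network is
#' integrated to its steady state seeded from the state found at the
#' previous point (the experimentalist's quasi-static sweep), then polished
#' by Newton iteration and classified.  With `bidirectional = TRUE` the
#' sweep is repeated in the reverse direction; a mismatch between the two
#' sweeps on an overlapping window is the hysteresis signature of
#' bistability.  The internal entropy production is recorded per point and
#' scanned for slope discontinuities (second-difference outliers), the
#' bifurcation signature on the thermodynamic branch.
#'
#' @param net a [reaction_network].
#' @param parameter parameter path: `"flow"`, `"kf:<pair>"`, `"kr:<pair>"`,
#'   `"k:<reaction>"`, `"inflow:<species>"`, `"clamp:<species>"`.
#' @param grid monotone parameter values.
#' @param bidirectional sweep both ways (default TRUE).
#' @param c0 starting composition for the first grid point.
#' @param steady_tol residual defining arrival at the steady state.
#' @param seed_perturbation tiny deterministic relative perturbation applied
#'   to each seeding state (alternating signs across species).  It lets the
#'   sweep fall off a branch that loses stability — e.g. onto a
#'   symmetry-broken branch — instead of riding an unstable exactly
#'   symmetric solution.
#' @param mismatch_tol relative distance above which up- and down-sweep
#'   states count as different branches.
#' @param max_chunks integration is run in growing chunks until the residual
#'   drops below `steady_tol`, at most this many times (then the point is
#'   marked missing).
#' @return a `branch_scan`: grids, per-point states/entropy production for
#'   each sweep, `hysteresis` flag, mismatch window, and slope-discontinuity
#'   locations.
#' @export
scan_branch <- function(net, parameter, grid, bidirectional = TRUE,
                        c0 = initial_state(net), steady_tol = 1e-10,
                        seed_perturbation = 1e-7, mismatch_tol = 1e-4,
                        max_chunks = 12) {
  if (is.unsorted(grid) && is.unsorted(rev(grid)))
    stop("grid must be monotone")
  up <- sweep_once(net, parameter, grid, c0, steady_tol,
                   seed_perturbation, max_chunks)
  down <- NULL
  hysteresis <- FALSE
  mismatch <- logical(length(grid))
  if (bidirectional) {
    start_down <- if (!is.null(up$states[[length(grid)]]))
      up$states[[length(grid)]] else c0
    down_rev <- sweep_once(net, parameter, rev(grid), start_down,
                           steady_tol, seed_perturbation, max_chunks)
    down <- list(states = rev(down_rev$states),
                 sigma_int = rev(down_rev$sigma_int),
                 verdict = rev(down_rev$verdict),
                 converged = rev(down_rev$converged))
    for (i in seq_along(grid)) {
      su <- up$states[[i]]; sd <- down$states[[i]]
      if (is.null(su) || is.null(sd)) next
      mismatch[i] <- max(abs(su - sd)) / max(max(abs(su)), 1e-12) >
        mismatch_tol
    }
    hysteresis <- any(mismatch)
  }
  structure(list(parameter = parameter, grid = grid,
                 up = up[c("states", "sigma_int", "verdict", "converged")],
                 down = down, hysteresis = hysteresis, mismatch = mismatch,
                 discontinuities_up = slope_discontinuities(grid, up$sigma_int),
                 discontinuities_down = if (!is.null(down))
                   slope_discontinuities(grid, down$sigma_int) else numeric(0),
                 clamped_caveat = any(net$species$clamped)),
            class = "branch_scan")
}

sweep_once <- function(net, parameter, grid, c0, steady_tol,
                       seed_perturbation, max_chunks) {
  n <- length(grid)
  states <- vector("list", n)
  sigma <- rep(NA_real_, n)
  verdict <- rep(NA_character_, n)
  converged <- rep(FALSE, n)
  state <- check_conc(net, c0)
  pattern <- rep(c(1, -1), length.out = n_species(net))
  for (i in seq_len(n)) {
    neti <- set_parameter(net, parameter, grid[i])
    seed <- pmax(state * (1 + seed_perturbation * pattern), 0)
    res <- integrate_to_steady(neti, seed, steady_tol, max_chunks)
    if (is.null(res)) next                     # point marked missing
    ## Newton polish on the integrated state
    free <- which(!neti$species$clamped)
    L <- conservation_laws(neti)
    target <- if (ncol(L)) drop(crossprod(L, seed)) else numeric(0)
    pol <- newton_log(neti, pmax(res[free], 1e-30), free, L, target,
                      residual_tol = 1e-9)
    if (!is.null(pol)) res <- pol
    ss <- steady_state_at(neti, res, residual_tol = 1e-6,
                          verify_integration = FALSE)
    if (is.null(ss)) next
    states[[i]] <- ss$conc
    verdict[i] <- ss$verdict
    converged[i] <- TRUE
    sigma[i] <- tryCatch(entropy_production_internal(neti, ss$conc),
                         error = function(e) NA_real_)
    state <- ss$conc
  }
  list(states = states, sigma_int = sigma, verdict = verdict,
       converged = converged)
}

## Integrate in growing chunks until max|dc/dt| < tol; NULL on failure.
integrate_to_steady <- function(net, c0, tol, max_chunks = 12) {
  state <- c0
  t_chunk <- max(10 * relaxation_time(net, pmax(state, 1e-12)), 1)
  for (ch in seq_len(max_chunks)) {
    traj <- tryCatch(
      integrate_network(net, state, t_end = t_chunk, n_out = 11,
                        stop_at_steady = TRUE, steady_tol = tol),
      error = function(e) NULL)
    if (is.null(traj)) return(NULL)
    state <- final_state(traj)
    if (max(abs(time_derivatives(net, state))) < tol) return(state)
    t_chunk <- t_chunk * 4
  }
  NULL
}

## Locations (grid values) where the slope of y(grid) breaks: the change in
## local slope is both an outlier (> 5x the median slope change, the
## second-difference criterion) and large relative to the slope itself
## (> 25%), so smooth curvature on a continuous branch is not flagged.
slope_discontinuities <- function(grid, y) {
  ok <- is.finite(y)
  if (sum(ok) < 5) return(numeric(0))
  g <- grid[ok]; yy <- y[ok]
  s <- diff(yy) / diff(g)
  ds <- abs(diff(s))
  med <- stats::median(ds)
  if (med == 0) med <- max(ds) * 1e-12 + 1e-300
  rel <- ds / pmax(abs(s[-1]), abs(s[-length(s)]), 1e-300)
  idx <- which(ds > 5 * med & rel > 0.25)
  g[idx + 1]
}

#' @export
print.branch_scan <- function(x, ...) {
  cat("branch scan over '", x$parameter, "' (", length(x$grid),
      " points)\n", sep = "")
  cat("  hysteresis:", x$hysteresis, "\n")
  if (length(x$discontinuities_up))
    cat("  slope discontinuities (up sweep) near:",
        paste(signif(x$discontinuities_up, 6), collapse = ", "), "\n")
  if (isTRUE(x$clamped_caveat))
    cat("  [clamped scenario: entropy balance is a necessary condition only]\n")
  invisible(x)
}

#' @export
plot.branch_scan <- function(x, what = c("sigma", "state"), species = 1, ...) {
  what <- match.arg(what)
  yu <- if (what == "sigma") x$up$sigma_int else
    vapply(x$up$states, function(s) if (is.null(s)) NA_real_ else s[species],
           numeric(1))
  graphics::plot(x$grid, yu, type = "b", pch = 16,
                 xlab = x$parameter,
                 ylab = if (what == "sigma") "sigma_int (J/(K s L))"
                        else "concentration (mol/L)", ...)
  if (!is.null(x$down)) {
    yd <- if (what == "sigma") x$down$sigma_int else
      vapply(x$down$states, function(s) if (is.null(s)) NA_real_ else
        s[species], numeric(1))
    graphics::lines(x$grid, yd, type = "b", col = 2, pch = 1)
    graphics::legend("topleft", c("up sweep", "down sweep"), col = 1:2,
                     pch = c(16, 1), bty = "n")
  }
  invisible(x)
}
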