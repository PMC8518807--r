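#' Zero contour of the entropy balance
#'
#' Evaluates `sigma_total = sigma_int + sigma_exch` over a 2-D grid of two
#' species' concentrations (the remaining species fixed, by default at the
#' supplied base composition, normally a NESS) and extracts the zero-level
#' contour.  The balance vanishes along whole *curves* of compositions;
#' only the points on those curves that also satisfy `dc/dt = 0` are actual
#' stationary states, and they are flagged.
#'
#' @param net an open, thermodynamically complete [reaction_network].
#' @param species_pair character(2): names of the scanned species.
#' @param grid_x,grid_y strictly positive concentration grids (mol/L).
#' @param others base composition fixing the remaining species (default the
#'   network's initial state).
#' @param ref reference equilibrium for the exchange potentials.
#' @param stationary_tol kinetic residual below which a contour point is
#'   marked as a NESS.
#' @return a `balance_contour`: the grid, the `sigma_total` matrix, and a
#'   data.frame `points` (columns x, y, sigma_total, max_dcdt, is_ness) of
#'   contour points.
#' @export
balance_zero_contour <- function(net, species_pair, grid_x, grid_y,
                                 others = initial_state(net), ref = NULL,
                                 stationary_tol = 1e-6) {
  if (net$flow_rate <= 0 && !any(net$species$clamped))
    message("closed network: the zero-balance set is the equilibrium manifold")
  ix <- match(species_pair, net$species$name)
  if (any(is.na(ix))) stop("unknown species in species_pair")
  if (any(grid_x <= 0) || any(grid_y <= 0))
    stop("grids must be strictly positive (zero-concentration cells skipped)")
  if (is.null(ref) && net$flow_rate > 0) ref <- equilibrium_point(net)
  base <- check_conc(net, others)
  z <- matrix(NA_real_, length(grid_x), length(grid_y))
  for (i in seq_along(grid_x)) {
    for (j in seq_along(grid_y)) {
      cc <- base
      cc[ix[1]] <- grid_x[i]
      cc[ix[2]] <- grid_y[j]
      z[i, j] <- tryCatch(
        entropy_production_internal(net, cc) + entropy_exchange(net, cc, ref),
        error = function(e) NA_real_)
    }
  }
  cl <- grDevices::contourLines(grid_x, grid_y, z, levels = 0)
  pts <- do.call(rbind, lapply(cl, function(seg)
    data.frame(x = seg$x, y = seg$y)))
  if (is.null(pts) && min(z, na.rm = TRUE) >= -1e-12 * max(abs(z), na.rm = TRUE)) {
    ## sigma_total >= 0 everywhere (e.g. a closed network, where
    ## sigma_exch = 0 and sigma_int >= 0): the zero set touches zero
    ## instead of crossing it.  Trace it as the per-column minimum of the
    ## surface, refined by 1-D minimization.
    zmax <- max(z, na.rm = TRUE)
    rows <- list()
    for (i in seq_along(grid_x)) {
      j <- which.min(z[i, ])
      if (!is.finite(z[i, j])) next
      lo <- grid_y[max(j - 1, 1)]
      hi <- grid_y[min(j + 1, length(grid_y))]
      fy <- function(y) {
        cc <- base
        cc[ix[1]] <- grid_x[i]
        cc[ix[2]] <- y
        entropy_production_internal(net, cc) + entropy_exchange(net, cc, ref)
      }
      opt <- stats::optimize(fy, c(lo, hi), tol = 1e-12)
      if (opt$objective < 1e-8 * zmax)
        rows[[length(rows) + 1]] <- data.frame(x = grid_x[i],
                                               y = opt$minimum)
    }
    if (length(rows)) pts <- do.call(rbind, rows)
  }
  if (is.null(pts)) pts <- data.frame(x = numeric(0), y = numeric(0))
  if (nrow(pts)) {
    eval_pt <- function(x, y) {
      cc <- base
      cc[ix[1]] <- x
      cc[ix[2]] <- y
      c(entropy_production_internal(net, cc) + entropy_exchange(net, cc, ref),
        max(abs(time_derivatives(net, cc))))
    }
    vals <- t(mapply(eval_pt, pts$x, pts$y))
    pts$sigma_total <- vals[, 1]
    pts$max_dcdt <- vals[, 2]
    pts$is_ness <- pts$max_dcdt < stationary_tol
    ## polish the most nearly stationary contour points by Newton steps in
    ## the scanned plane: actual NESSs lie *on* the zero contour, and only
    ## there does the kinetic residual vanish too
    cand <- utils::head(order(pts$max_dcdt), 8)
    for (ci in cand) {
      xy <- c(pts$x[ci], pts$y[ci])
      for (it in 1:50) {
        cc <- base
        cc[ix] <- xy
        Fv <- time_derivatives(net, cc)[ix]
        if (max(abs(Fv)) < stationary_tol * 1e-3) break
        Jv <- jacobian_at(net, cc)[ix, ix]
        step <- tryCatch(solve(Jv, -Fv), error = function(e) NULL)
        if (is.null(step) || !all(is.finite(step))) break
        xy2 <- xy + step
        if (any(xy2 <= 0)) break
        xy <- xy2
      }
      cc <- base
      cc[ix] <- xy
      full_res <- max(abs(time_derivatives(net, cc)))
      if (full_res < stationary_tol &&
          xy[1] >= min(grid_x) && xy[1] <= max(grid_x) &&
          xy[2] >= min(grid_y) && xy[2] <= max(grid_y)) {
        near <- abs(pts$x - xy[1]) + abs(pts$y - xy[2]) <
          1e-8 * (max(grid_x) + max(grid_y))
        if (!any(pts$is_ness & near)) {
          st <- tryCatch(entropy_production_internal(net, cc) +
                           entropy_exchange(net, cc, ref),
                         error = function(e) NA_real_)
          pts <- rbind(pts, data.frame(x = xy[1], y = xy[2],
                                       sigma_total = st,
                                       max_dcdt = full_res, is_ness = TRUE))
        }
      }
    }
  } else {
    pts$sigma_total <- pts$max_dcdt <- numeric(0)
    pts$is_ness <- logical(0)
  }
  structure(list(species_pair = species_pair, grid_x = grid_x,
                 grid_y = grid_y, sigma_total = z, points = pts,
                 clamped_caveat = any(net$species$clamped)),
            class = "balance_contour")
}

#' @export
print.balance_contour <- function(x, ...) {
  cat("zero-balance contour over (", x$species_pair[1], ",",
      x$species_pair[2], "):", nrow(x$points), "contour points,",
      sum(x$points$is_ness), "of them stationary (actual NESS)\n")
  invisible(x)
}

#' @export
plot.balance_contour <- function(x, ...) {
  graphics::contour(x$grid_x, x$grid_y, x$sigma_total,
                    xlab = x$species_pair[1], ylab = x$species_pair[2], ...)
  graphics::contour(x$grid_x, x$grid_y, x$sigma_total, levels = 0,
                    add = TRUE, col = "red", lwd = 2)
  if (any(x$points$is_ness))
    graphics::points(x$points$x[x$points$is_ness],
                     x$points$y[x$points$is_ness], pch = 19)
  invisible(x)
}
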