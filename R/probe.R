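#' Probe the local potential around a stationary state
#'
#' Numerical simulation of the evolution criterion at a NESS: the state is
#' displaced by `radius` along unit directions (uniform on the sphere of the
#' free-species subspace, seeded, plus any user-supplied directions such as
#' the enantiomer-symmetric/antisymmetric modes), each displaced composition
#' is integrated, and the fate is recorded — returned to the probed state,
#' escaped to another known attractor, or escaped out of the concentration
#' window.  A stable NESS is a *well* (every direction returns); an unstable
#' NESS is a *saddle* (the fates are mixed: the directions spanning its
#' stable manifold return, the rest leave).  `d_F P/dt <= 0` is verified
#' along every probe trajectory.
#'
#' @param net a [reaction_network].
#' @param ness a `steady_state` (from [find_steady_states()]) or a
#'   concentration vector at a stationary point.
#' @param radius probe amplitude (mol/L); default `1e-3` times the smallest
#'   positive component of the state.
#' @param n_directions number of random directions (>= 8).
#' @param seed RNG seed for the directions.
#' @param extra_directions optional matrix/list of additional displacement
#'   directions (full species dimension); they are normalized but *not*
#'   re-projected, so exact symmetry modes stay exact.
#' @param known_attractors optional named list of other stationary
#'   compositions used to label escapes.
#' @param t_return integration horizon; default 50 times the slowest
#'   relaxation time at the probed state.
#' @param return_tol relative distance under which a probe counts as
#'   returned (default 1e-6).
#' @param escape_tol relative distance under which an escape is attributed
#'   to a known attractor (default 1e-4).
#' @param window concentration window; leaving it counts as
#'   `escaped(unbounded)`.
#' @param check_gec verify the evolution criterion along each probe path.
#' @return a `probe_report`: fields `ness`, `radius`, `directions`,
#'   `fates`, `classification` (`well`/`saddle`/`source`),
#'   `returning` (logical per direction), `max_dFP`.
#' @export
local_potential_probe <- function(net, ness, radius = NULL,
                                  n_directions = 16, seed = DEFAULT_SEED,
                                  extra_directions = NULL,
                                  known_attractors = NULL,
                                  t_return = NULL,
                                  return_tol = 1e-6, escape_tol = 1e-4,
                                  window = c(0, 1e6), check_gec = TRUE) {
  stopifnot(n_directions >= 8)
  cstar <- if (inherits(ness, "steady_state")) ness$conc else
    check_conc(net, ness)
  if (is.null(radius)) radius <- 1e-3 * min(cstar[cstar > 0])
  n_sp <- n_species(net)
  free <- !net$species$clamped
  ## random directions: uniform on the sphere, projected on the
  ## stoichiometric subspace so closed-system probes stay on the
  ## compatibility class
  Q <- stoich_subspace(net)
  dirs <- with_seed(seed, {
    m <- matrix(stats::rnorm(n_directions * n_sp), n_directions, n_sp)
    m[, !free] <- 0
    m <- m %*% Q %*% t(Q)
    m / sqrt(rowSums(m^2))
  })
  rownames(dirs) <- paste0("random", seq_len(n_directions))
  if (!is.null(extra_directions)) {
    em <- if (is.matrix(extra_directions)) extra_directions
          else do.call(rbind, extra_directions)
    em <- em / sqrt(rowSums(em^2))
    if (is.null(rownames(em)))
      rownames(em) <- paste0("user", seq_len(nrow(em)))
    dirs <- rbind(em, dirs)
  }
  colnames(dirs) <- net$species$name
  if (is.null(t_return)) t_return <- 50 * relaxation_time(net, cstar)
  scale <- max(abs(cstar))
  fates <- character(nrow(dirs))
  max_dFP <- rep(NA_real_, nrow(dirs))
  ref <- NULL
  if (check_gec && is_thermo_complete(net))
    ref <- tryCatch(equilibrium_point(net), error = function(e) NULL)
  for (i in seq_len(nrow(dirs))) {
    start <- cstar + radius * dirs[i, ]
    if (any(start < 0)) start <- pmax(start, 0)
    traj <- tryCatch(
      integrate_network(net, start, t_end = t_return, n_out = 101),
      error = function(e) NULL)
    if (is.null(traj)) { fates[i] <- "escaped(integration-failure)"; next }
    fin <- final_state(traj)
    if (check_gec && is_thermo_complete(net) && all(traj$states > 0)) {
      g <- tryCatch(gec_decomposition(net, traj, ref),
                    error = function(e) NULL)
      if (!is.null(g)) max_dFP[i] <- max(g$dFP)
    }
    if (any(fin > window[2]) || any(fin < window[1])) {
      fates[i] <- "escaped(unbounded)"
    } else if (max(abs(fin - cstar)) / scale < return_tol) {
      fates[i] <- "returned"
    } else {
      fates[i] <- "escaped(other)"
      for (nm in names(known_attractors)) {
        att <- known_attractors[[nm]]
        if (max(abs(fin - att)) / max(abs(att)) < escape_tol) {
          fates[i] <- paste0("escaped(", nm, ")")
          break
        }
      }
    }
  }
  returning <- fates == "returned"
  classification <- if (all(returning)) "well"
                    else if (any(returning)) "saddle" else "source"
  structure(list(ness = cstar, radius = radius, directions = dirs,
                 fates = stats::setNames(fates, rownames(dirs)),
                 returning = stats::setNames(returning, rownames(dirs)),
                 classification = classification,
                 max_dFP = stats::setNames(max_dFP, rownames(dirs)),
                 t_return = t_return),
            class = "probe_report")
}

#' @export
print.probe_report <- function(x, ...) {
  cat("local-potential probe:", x$classification, "\n")
  cat("  state:", paste(names(x$ness), "=", signif(x$ness, 8),
                        collapse = ", "), "\n")
  cat("  radius:", x$radius, "mol/L; horizon:", signif(x$t_return, 4), "s\n")
  tab <- table(x$fates)
  for (nm in names(tab)) cat("  ", nm, ": ", tab[[nm]], "\n", sep = "")
  if (!all(is.na(x$max_dFP)))
    cat("  max dFP along probes:", max(x$max_dFP, na.rm = TRUE),
        "(criterion: <= 0)\n")
  invisible(x)
}
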