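#' Reaction affinities
#'
#' The thermodynamic force of a reversible pair at composition `conc`,
#' `Af = R T log(v_f / v_r)` (J/mol, ideal activities): positive when the
#' forward direction is spontaneous, zero when the pair is at equilibrium.
#'
#' @param net a thermodynamically complete [reaction_network].
#' @param conc concentration vector (mol/L).
#' @return named vector of affinities, one per reversible pair.
#' @export
affinities <- function(net, conc) {
  stop_if_thermo_incomplete(net)
  v <- reaction_rates(net, conc)
  vf <- v[net$pairs$fwd]; vr <- v[net$pairs$rev]
  bad <- vf <= 0 | vr <= 0
  if (any(bad))
    stop("affinity undefined for pair '", net$pairs$id[which(bad)[1]],
         "': zero forward or reverse rate at this composition")
  stats::setNames(R_GAS * net$temperature * log(vf / vr), net$pairs$id)
}

## forward/reverse rates per pair, as a list(vf, vr)
pair_rates <- function(net, conc) {
  v <- reaction_rates(net, conc)
  list(vf = stats::setNames(v[net$pairs$fwd], net$pairs$id),
       vr = stats::setNames(v[net$pairs$rev], net$pairs$id))
}

#' Internal entropy production
#'
#' Specific internal entropy production
#' `sigma_int = R * sum_pairs (v_f - v_r) log(v_f / v_r)`
#' `          = (1/T) * sum_pairs Af * (v_f - v_r)`,
#' in J/(K s L).  Each summand is a force times the current it drives, so
#' `sigma_int >= 0` always, with equality exactly at detailed balance.
#'
#' @inheritParams affinities
#' @return non-negative scalar (J K^-1 s^-1 L^-1).
#' @export
entropy_production_internal <- function(net, conc) {
  stop_if_thermo_incomplete(net)
  pr <- pair_rates(net, conc)
  bad <- pr$vf <= 0 | pr$vr <= 0
  if (any(bad))
    stop("entropy production undefined for pair '",
         names(pr$vf)[which(bad)[1]], "': zero unidirectional rate")
  R_GAS * sum((pr$vf - pr$vr) * log(pr$vf / pr$vr))
}

#' Check Wegscheider (detailed-balance) consistency and species potentials
#'
#' A closed mass-action network relaxes to detailed balance iff the vector
#' `log(kf/kr)` over pairs lies in the row space of the transposed
#' stoichiometric matrix, i.e. `log Keq_rho = sum_k nu_krho * g_k` for some
#' species potentials `g` (dimensionless, in units of RT).  Returns the
#' least-squares `g` and the residual; `consistent` is TRUE when the
#' residual is at rounding level.
#'
#' @param net a thermodynamically complete [reaction_network].
#' @param tol residual tolerance on `log Keq`.
#' @return list with `consistent`, `g` (named, RT units), `residual`.
#' @export
wegscheider_check <- function(net, tol = 1e-8) {
  stop_if_thermo_incomplete(net)
  Nf <- net$N[, net$pairs$fwd, drop = FALSE]   # net stoichiometry per pair
  lnK <- log(net$k[net$pairs$fwd] / net$k[net$pairs$rev])
  ## minimum-norm least-squares species potentials (pseudoinverse handles
  ## both under- and overdetermined pair sets)
  g <- stats::setNames(drop(MASS::ginv(t(Nf)) %*% lnK), net$species$name)
  residual <- max(abs(drop(t(Nf) %*% g) - lnK))
  list(consistent = residual < tol, g = g, residual = residual)
}

#' Detailed-balance reference equilibrium
#'
#' A strictly positive composition at which every pair of the chemical
#' subnetwork is individually equilibrated (`v_f = v_r`).  By default the
#' canonical point `c_ref = exp(g)` built from the species potentials of
#' [wegscheider_check()]; with `class_of` given, the equilibrium on the
#' stoichiometric compatibility class of that composition is located
#' instead (by root search on the closed subnetwork).
#'
#' @param net a thermodynamically complete [reaction_network] with
#'   Wegscheider-consistent rate constants.
#' @param class_of optional composition whose conserved moieties pin the
#'   equilibrium.
#' @return named concentration vector (mol/L) with `v_f = v_r` for every
#'   pair.
#' @export
equilibrium_point <- function(net, class_of = NULL) {
  wc <- wegscheider_check(net)
  if (!wc$consistent)
    stop("rate constants violate the Wegscheider conditions (residual ",
         signif(wc$residual, 3), "); no detailed-balance reference exists ",
         "- supply explicit reference potentials (mu0)")
  ceq <- exp(wc$g)
  if (is.null(class_of)) return(ceq)
  closed <- close_network(net)
  closed$species$init <- as.numeric(class_of)
  closed <- compile_network(closed)
  L <- conservation_laws(closed)
  free <- which(!closed$species$clamped)
  target <- if (ncol(L)) drop(crossprod(L, check_conc(closed, class_of)))
            else numeric(0)
  sol <- newton_log(closed, pmax(as.numeric(class_of)[free], 1e-8),
                    free, L, target, residual_tol = 1e-11)
  if (is.null(sol)) stop("failed to locate the class equilibrium")
  sol
}

## Closed chemical subnetwork: flow switched off, clamping kept (clamped
## species are boundary conditions, not dynamic species).
close_network <- function(net) {
  net$flow_rate <- 0
  net$species$exchanged <- FALSE
  compile_network(net)
}

#' Relative chemical potentials
#'
#' `mu_k = R T log(c_k / c_ref,k)` (J/mol) with `c_ref` a detailed-balance
#' equilibrium of the closed chemical subnetwork; with these potentials
#' every pair affinity is exactly `Af = -sum_k nu_k mu_k`.
#'
#' @inheritParams affinities
#' @param ref reference equilibrium; default [equilibrium_point()].
#' @return named vector of chemical potentials (J/mol).
#' @export
chem_potentials <- function(net, conc, ref = equilibrium_point(net)) {
  conc <- check_conc(net, conc)
  if (any(conc <= 0))
    stop("chemical potential undefined at zero concentration (",
         net$species$name[which(conc <= 0)[1]], ")")
  stats::setNames(R_GAS * net$temperature * log(conc / ref),
                  net$species$name)
}

#' Internal entropy production from relative chemical potentials
#'
#' The unidirectional (SNA) form: every one-way reaction contributes
#' `R * v_rho * log prod_k (c_k/c_eq,k)^(-nu_krho)`, i.e. rate times its own
#' force written in relative chemical potentials.  For Wegscheider-
#' consistent constants this equals [entropy_production_internal()]
#' identically — the two expressions are the same function written per
#' unidirectional reaction versus per reversible pair.
#'
#' @inheritParams affinities
#' @param ref_equilibrium a detailed-balance equilibrium of the closed
#'   subnetwork (checked; residual must be below `ref_tol`).
#' @param ref_tol acceptance tolerance on the reference (per-pair
#'   `|log(vf/vr)|` at the reference).
#' @return scalar sigma_int (J K^-1 s^-1 L^-1).
#' @export
entropy_production_relative <- function(net, conc,
                                        ref_equilibrium = equilibrium_point(net),
                                        ref_tol = 1e-9) {
  stop_if_thermo_incomplete(net)
  conc <- check_conc(net, conc)
  ref <- check_conc(net, ref_equilibrium)
  ## verify the reference really is detailed-balanced
  pr <- pair_rates(net, ref)
  if (max(abs(log(pr$vf / pr$vr))) > ref_tol)
    stop("ref_equilibrium is not a detailed-balance equilibrium ",
         "(max |log(vf/vr)| = ", signif(max(abs(log(pr$vf / pr$vr))), 3), ")")
  v <- reaction_rates(net, conc)
  lr <- log(conc / ref)
  ## force of unidirectional reaction rho in RT units: -sum_k nu_k log(c/ceq)
  forces <- -drop(crossprod(net$N, lr))
  R_GAS * sum(v * forces)
}

#' Entropy exchange with the surroundings
#'
#' For an open CSTR, `sigma_exch = -(1/T) sum_k mu_k J_k` over exchanged
#' species, with matter currents `J_k = flow * (c_in,k - c_k)` and relative
#' chemical potentials `mu_k` ([chem_potentials()]).  Closed networks return
#' 0.  At any NESS `sigma_int + sigma_exch = 0` exactly; away from
#' stationarity the sum equals `-(1/T) dG/dt` for the ideal free energy
#' built from the same potentials.
#'
#' @inheritParams affinities
#' @param ref reference equilibrium for the potentials (default the
#'   canonical detailed-balance point; Wegscheider-inconsistent constants
#'   require an explicit reference).
#' @return scalar sigma_exch (J K^-1 s^-1 L^-1).
#' @export
entropy_exchange <- function(net, conc, ref = NULL) {
  conc <- check_conc(net, conc)
  if (net$flow_rate == 0) return(0)
  if (is.null(ref)) ref <- equilibrium_point(net)
  mu <- chem_potentials(net, conc, ref)
  ex <- net$species$exchanged
  Jk <- net$flow_rate * (net$species$inflow[ex] - conc[ex])
  -sum(mu[ex] * Jk) / net$temperature
}

#' Entropy balance residual
#'
#' `sigma_total = sigma_int + sigma_exch`: zero at every NESS, but zero
#' balance alone is *not* a NESS certificate — whole curves of compositions
#' satisfy it — so the kinetic residual `max |dc/dt|` is reported alongside
#' and compositions with zero balance but nonzero kinetics are labeled
#' "balance-only".
#'
#' @inheritParams entropy_exchange
#' @param stationary_tol kinetic residual below which the point counts as
#'   stationary.
#' @return list with `sigma_total`, `sigma_int`, `sigma_exch`,
#'   `max_dcdt`, `stationary`, `label` and `clamped_caveat`.
#' @export
balance_residual <- function(net, conc, ref = NULL, stationary_tol = 1e-9) {
  si <- entropy_production_internal(net, conc)
  se <- entropy_exchange(net, conc, ref)
  md <- max(abs(time_derivatives(net, conc)))
  tot <- si + se
  label <- if (md < stationary_tol) "NESS"
           else if (abs(tot) < 1e-10 * max(si, R_GAS)) "balance-only"
           else "off-balance"
  list(sigma_total = tot, sigma_int = si, sigma_exch = se,
       max_dcdt = md, stationary = md < stationary_tol, label = label,
       clamped_caveat = any(net$species$clamped))
}

#' Full thermodynamic state at a composition
#'
#' Per-pair forward/backward rates and affinities, the entropy-production
#' components and the relative chemical potentials, bundled as a
#' `thermo_state`.
#'
#' @inheritParams entropy_exchange
#' @return a `thermo_state` object.
#' @export
thermo_state <- function(net, conc, ref = NULL) {
  conc <- check_conc(net, conc)
  if (is.null(ref) && net$flow_rate > 0) ref <- equilibrium_point(net)
  pr <- pair_rates(net, conc)
  af <- affinities(net, conc)
  si <- entropy_production_internal(net, conc)
  se <- entropy_exchange(net, conc, ref)
  mu <- if (!is.null(ref)) chem_potentials(net, conc, ref)
        else tryCatch(chem_potentials(net, conc), error = function(e) NULL)
  structure(list(conc = conc, v_f = pr$vf, v_r = pr$vr, affinity = af,
                 sigma_int = si, sigma_exch = se, sigma_total = si + se,
                 chem_potentials = mu,
                 clamped_caveat = any(net$species$clamped)),
            class = "thermo_state")
}

#' @export
print.thermo_state <- function(x, ...) {
  cat("thermo state at",
      paste(names(x$conc), "=", signif(x$conc, 8), collapse = ", "), "\n")
  df <- data.frame(pair = names(x$affinity), v_f = x$v_f, v_r = x$v_r,
                   Af_J_mol = x$affinity, row.names = NULL)
  print(df, digits = 8)
  cat("sigma_int  =", x$sigma_int, "J/(K s L)\n")
  cat("sigma_exch =", x$sigma_exch, "J/(K s L)\n")
  cat("sigma_total =", x$sigma_total, "J/(K s L)\n")
  if (isTRUE(x$clamped_caveat))
    cat("[clamped scenario: exchange with the implicit chemostats is not",
        "accounted; balance is a necessary condition only]\n")
  invisible(x)
}

#' Selectivity identity at a NESS of a competitive network
#'
#' For two channels `A <-> C` and `A <-> D` fed from the same reactant, the
#' NESS selectivity satisfies
#' `[C]/[D] = (KeqC/KeqD) * exp((AfD - AfC)/(R T))` — an identity under the
#' mass-action affinity definition.  Returns the residual and both factors.
#'
#' @param net a [reaction_network] containing the two pairs.
#' @param conc composition (normally a NESS).
#' @param pairC,pairD pair ids of the channels producing C and D.
#' @return list with `residual`, `ratio` (`[C]/[D]`), `keq_ratio`,
#'   `affinity_factor`.
#' @export
selectivity_identity_residual <- function(net, conc, pairC, pairD) {
  conc <- check_conc(net, conc)
  af <- affinities(net, conc)
  rowC <- net$pairs[net$pairs$id == pairC, ]
  rowD <- net$pairs[net$pairs$id == pairD, ]
  if (!nrow(rowC) || !nrow(rowD)) stop("unknown pair id")
  spC <- names(which(net$Mp[, rowC$fwd] > 0))
  spD <- names(which(net$Mp[, rowD$fwd] > 0))
  if (length(spC) != 1 || length(spD) != 1)
    stop("pairs must each produce a single species")
  if (conc[spD] == 0) stop("zero concentration of ", spD)
  keqC <- net$k[rowC$fwd] / net$k[rowC$rev]
  keqD <- net$k[rowD$fwd] / net$k[rowD$rev]
  RT <- R_GAS * net$temperature
  pred <- (keqC / keqD) * exp((af[[pairD]] - af[[pairC]]) / RT)
  ratio <- conc[[spC]] / conc[[spD]]
  list(residual = abs(ratio - pred), ratio = ratio,
       keq_ratio = keqC / keqD,
       affinity_factor = exp((af[[pairD]] - af[[pairC]]) / RT))
}
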