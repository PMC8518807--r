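#' Unidirectional (SNA) reaction list
#'
#' Returns the ordered list of unidirectional mass-action reactions — the
#' stoichiometric-network-analysis view in which a reversible step is two
#' distinct reactions.  Every reversible pair contributes exactly two
#' entries linked by `pair_id`.
#'
#' @param net a [reaction_network].
#' @return list of reaction records (`name`, `reactants`, `products`, `k`,
#'   `pair_id`, `direction`).
#' @export
sna_decompose <- function(net) net$reactions

check_conc <- function(net, conc) {
  if (length(conc) != n_species(net))
    stop("concentration vector has length ", length(conc),
         ", expected ", n_species(net))
  if (any(conc < 0))
    stop("negative concentration for species ",
         net$species$name[which(conc < 0)[1]])
  stats::setNames(as.numeric(conc), net$species$name)
}

#' Mass-action reaction rates
#'
#' `v_rho = k_rho * prod_k c_k^m_krho` with `m` the reactant stoichiometry;
#' all rates are non-negative.
#'
#' @param net a [reaction_network].
#' @param conc concentration vector (mol/L), species order.
#' @return named rate vector (mol/(L s)), one entry per unidirectional
#'   reaction.
#' @export
reaction_rates <- function(net, conc) {
  conc <- check_conc(net, conc)
  pw <- matrix(conc, n_species(net), n_reactions(net)) ^ net$Mr  # 0^0 == 1
  stats::setNames(net$k * apply(pw, 2, prod), colnames(net$Mr))
}

#' Time derivatives of the concentrations
#'
#' `dc/dt = N v(c)` plus, for each exchanged species,
#' `flow_rate * (inflow - c)`; clamped species are held fixed (`dc/dt = 0`).
#'
#' @inheritParams reaction_rates
#' @return named vector dc/dt (mol/(L s)).
#' @export
time_derivatives <- function(net, conc) {
  conc <- check_conc(net, conc)
  v <- reaction_rates(net, conc)
  dc <- drop(net$N %*% v)
  ex <- net$species$exchanged
  if (net$flow_rate > 0)
    dc[ex] <- dc[ex] + net$flow_rate * (net$species$inflow[ex] - conc[ex])
  dc[net$species$clamped] <- 0
  stats::setNames(dc, net$species$name)
}

#' Analytic Jacobian of the kinetic equations
#'
#' Exact mass-action derivatives `d(dc_i/dt)/dc_j`, with `-flow_rate` added
#' on the diagonal of exchanged species and clamped rows zeroed.  At a zero
#' concentration the one-sided derivative is used (the mass-action power
#' rule, with `c^0 = 1`).
#'
#' @inheritParams reaction_rates
#' @return a species-by-species matrix.
#' @export
jacobian_at <- function(net, conc) {
  conc <- check_conc(net, conc)
  n_sp <- n_species(net)
  n_rx <- n_reactions(net)
  ## dv[rho, j] = dv_rho / dc_j
  dv <- matrix(0, n_rx, n_sp)
  for (rho in seq_len(n_rx)) {
    m <- net$Mr[, rho]
    act <- which(m > 0)
    for (j in act) {
      others <- act[act != j]
      term <- net$k[rho] * m[j] * conc[j]^(m[j] - 1)
      if (length(others))
        term <- term * prod(conc[others]^m[others])
      dv[rho, j] <- term
    }
  }
  J <- net$N %*% dv
  ex <- net$species$exchanged
  if (net$flow_rate > 0)
    diag(J)[ex] <- diag(J)[ex] - net$flow_rate
  J[net$species$clamped, ] <- 0
  dimnames(J) <- list(net$species$name, net$species$name)
  J
}

#' Conserved-moiety basis
#'
#' Basis of the left null space of the stoichiometric matrix restricted to
#' free species (neither exchanged nor clamped): vectors `m` with
#' `m . dc/dt = 0` along every trajectory.  Empty when flow or clamping
#' couples every species to the surroundings.
#'
#' @param net a [reaction_network].
#' @return numeric matrix, one column per conserved moiety (rows = species;
#'   exchanged/clamped species have zero weight).  Zero columns when there
#'   is no conservation.
#' @export
conservation_laws <- function(net) {
  free <- !(net$species$exchanged & net$flow_rate > 0) & !net$species$clamped
  n_sp <- n_species(net)
  out <- matrix(0, n_sp, 0, dimnames = list(net$species$name, NULL))
  if (!any(free)) return(out)
  sub <- net$N[free, , drop = FALSE]
  ## columns of MASS::Null(sub) span {m : t(m) %*% sub == 0}
  B <- MASS::Null(sub)
  if (!length(B)) return(out)
  full <- matrix(0, n_sp, ncol(B), dimnames = list(net$species$name, NULL))
  full[free, ] <- B
  ## scale so the largest-magnitude entry is +1 (cosmetic, deterministic)
  for (j in seq_len(ncol(full))) {
    i <- which.max(abs(full[, j]))
    full[, j] <- full[, j] / full[i, j]
  }
  full
}

## Orthonormal basis of the stoichiometric subspace (the orthogonal
## complement of the conserved moieties); used to deflate structural zero
## eigenvalues before stability analysis.
stoich_subspace <- function(net) {
  L <- conservation_laws(net)
  n <- n_species(net)
  if (ncol(L) == 0) return(diag(n))
  qr.Q(qr(cbind(L, diag(n))))[, -seq_len(ncol(L)), drop = FALSE] -> Q
  ## qr of [L | I] gives first ncol(L) columns spanning L; the rest span
  ## the complement
  Q
}
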