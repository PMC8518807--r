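#' Built-in model presets
#'
#' Constructors for the package's reference systems.  Every preset is built
#' by emitting the plain-text network dialect and parsing it back, so a
#' preset is exactly what a user could write in a network file.
#'
#' @name presets
NULL

preset_from_text <- function(lines) parse_network(lines)

#' Closed two-state interconversion A <-> B
#'
#' The minimal reversible transformation: closed, mass-conserving, relaxing
#' to the unique equilibrium `[B]/[A] = k1/km1` on its compatibility class.
#'
#' @param k1,km1 forward/backward rate constants (1/s).
#' @param total total concentration `[A]+[B]` (mol/L), all in A initially.
#' @param temperature K.
#' @return a [reaction_network].
#' @export
make_ab <- function(k1 = 2, km1 = 1, total = 1, temperature = 300) {
  stopifnot(k1 > 0, km1 > 0, total >= 0)
  preset_from_text(c(
    paste0("species A init=", fmt_num(total)),
    "species B init=0",
    paste0("reaction R1: A <-> B ; kf=", fmt_num(k1), ", kr=", fmt_num(km1)),
    paste0("system T=", fmt_num(temperature), " flow=0")))
}

#' Competitive two-channel CSTR: A <-> C and A <-> D
#'
#' An ideal open-flow reactor fed with A, producing C and D through two
#' reversible channels.  With the default constants both channels share the
#' equilibrium constant `Keq = 10` but channel C is kinetically ten times
#' faster, so the NESS selectivity `[C]/[D]` rises from 1 (at vanishing
#' flow, the thermodynamically controlled limit) toward `k1C/k1D = 10` as
#' the flow rate increases.  The linear kinetics give the closed-form NESS
#' `[C] = k1C a/(km1C + f)`, `[D] = k1D a/(km1D + f)`.
#'
#' With mirror-identical constants (`k1C = k1D`, `km1C = km1D`) the two
#' products are enantiomers and the NESS selectivity is exactly 1.
#'
#' @param k1C,km1C,k1D,km1D channel rate constants (1/s).
#' @param inflow_A inflow concentration of A (mol/L).
#' @param flow CSTR dilution rate (1/s).
#' @param temperature K.
#' @return a [reaction_network] with A, C, D exchanged.
#' @export
make_competitive <- function(k1C = 10, km1C = 1, k1D = 1, km1D = 0.1,
                             inflow_A = 1, flow = 1, temperature = 300) {
  stopifnot(k1C > 0, km1C > 0, k1D > 0, km1D > 0, inflow_A >= 0, flow >= 0)
  preset_from_text(c(
    paste0("species A init=", fmt_num(inflow_A),
           " exchanged inflow=", fmt_num(inflow_A)),
    "species C init=0 exchanged inflow=0",
    "species D init=0 exchanged inflow=0",
    paste0("reaction RC: A <-> C ; kf=", fmt_num(k1C), ", kr=", fmt_num(km1C)),
    paste0("reaction RD: A <-> D ; kf=", fmt_num(k1D), ", kr=", fmt_num(km1D)),
    paste0("system T=", fmt_num(temperature), " flow=", fmt_num(flow))))
}

## Closed-form NESS of the competitive preset (linear kinetics):
## a from total balance, then c = k1C a/(km1C+f), d = k1D a/(km1D+f).
competitive_closed_form <- function(k1C = 10, km1C = 1, k1D = 1, km1D = 0.1,
                                    inflow_A = 1, flow = 1) {
  f <- flow
  ## f(a_in - a) = (k1C + k1D) a - km1C c - km1D d, with c, d linear in a
  gC <- k1C / (km1C + f)
  gD <- k1D / (km1D + f)
  a <- f * inflow_A / (f + k1C + k1D - km1C * gC - km1D * gD)
  c(A = a, C = gC * a, D = gD * a)
}

#' Schloegl bistable model (clamped boundary species)
#'
#' `A <-> X` and `3X <-> 2X + B` with A and B clamped: a single free species
#' whose steady states are the positive roots of the cubic
#' `k1 a - km1 x - k2 x^3 + km2 b x^2 = 0`.  The textbook bistable system:
#' inside the bistable parameter window two stable states coexist with an
#' intervening unstable one, the reachable state is path dependent, and
#' parameter sweeps show hysteresis.  Because the boundary species are
#' clamped rather than exchanged through modeled flows, every thermodynamic
#' report on this preset carries the clamped-scenario caveat.
#'
#' The default constants make the steady-state condition
#' `(x-1)(x-2)(x-3) = 0`: states 1 and 3 stable, 2 unstable.
#'
#' @param k1,km1,k2,km2 rate constants.
#' @param a_clamped,b_clamped clamped concentrations of A and B (mol/L).
#' @param x0 initial `[X]` (mol/L).
#' @param temperature K.
#' @return a [reaction_network].
#' @export
make_schlogl <- function(k1 = 1, km1 = 11, k2 = 1, km2 = 6,
                         a_clamped = 6, b_clamped = 1, x0 = 0.5,
                         temperature = 300) {
  stopifnot(k1 > 0, km1 > 0, k2 > 0, km2 > 0,
            a_clamped > 0, b_clamped > 0)
  preset_from_text(c(
    paste0("species A init=", fmt_num(a_clamped), " clamped"),
    paste0("species X init=", fmt_num(x0)),
    paste0("species B init=", fmt_num(b_clamped), " clamped"),
    paste0("reaction R1: A <-> X ; kf=", fmt_num(k1), ", kr=", fmt_num(km1)),
    paste0("reaction R2: 3 X <-> 2 X + B ; kf=", fmt_num(k2),
           ", kr=", fmt_num(km2)),
    paste0("system T=", fmt_num(temperature), " flow=0")))
}

## Steady-state cubic of the Schloegl preset, coefficients of
## x^0..x^3 in dX/dt = k1 a - km1 x + km2 b x^2 - k2 x^3.
schlogl_cubic <- function(net) {
  k <- stats::setNames(net$k, colnames(net$Mr))
  a <- net$species$init[net$species$name == "A"]
  b <- net$species$init[net$species$name == "B"]
  c(k[["R1.f"]] * a, -k[["R1.r"]], k[["R2.r"]] * b, -k[["R2.f"]])
}

#' Frank model of spontaneous mirror symmetry breaking
#'
#' Open-flow Frank network: direct production `A <-> L`, `A <-> D`
#' (mirror-symmetric constants), enantioselective autocatalysis
#' `A + L <-> 2L`, `A + D <-> 2D`, and mutual inhibition `L + D <-> P`.
#' All species are carried by the reactor flow by default (A fed at
#' `inflow_A`); all steps are reversible (reverse constants default to
#' `0.05` times the forward ones, keeping every affinity finite and the
#' near-equilibrium regime reachable at practical flow rates).  The
#' constant set must be exactly mirror symmetric; a chiral bias in the
#' inputs is a deliberate, separate modification, not a default.
#'
#' With the default constants the racemic branch is stable below a critical
#' flow rate (located at run time by [find_smsb_threshold()], about
#' 0.013/s) and breaks mirror symmetry above it: the racemic NESS becomes a
#' saddle whose stable manifold is the racemic subspace, and two
#' mirror-image scalemic NESSs are the attractors.  The default `flow`
#' sits inside the symmetry-broken regime.
#'
#' @param k_prod,k_auto,k_inhib forward constants of production,
#'   autocatalysis and mutual inhibition.
#' @param km_prod,km_auto,km_inhib reverse constants (defaults
#'   `0.05 * forward`).  `km_prod/k_prod` must equal `km_auto/k_auto` for
#'   detailed-balance consistency of the A-to-L cycle.
#' @param inflow_A inflow concentration of A (mol/L).
#' @param flow CSTR dilution rate (1/s).
#' @param exchange_LD wash out L and D with the flow (default TRUE; with
#'   FALSE only A and P are exchanged, and the autocatalytic growth of the
#'   enantiomeric excess is never balanced by dilution, so the racemic
#'   state is unstable at every flow).
#' @param l0,d0 initial enantiomer concentrations (mol/L); defaults racemic.
#' @param temperature K.
#' @return a [reaction_network].
#' @export
make_frank <- function(k_prod = 0.1, km_prod = 0.05 * k_prod,
                       k_auto = 1, km_auto = 0.05 * k_auto,
                       k_inhib = 1, km_inhib = 0.05 * k_inhib,
                       inflow_A = 1, flow = 0.1, exchange_LD = TRUE,
                       l0 = 0.1, d0 = 0.1, temperature = 300) {
  stopifnot(k_prod > 0, km_prod > 0, k_auto > 0, km_auto > 0,
            k_inhib > 0, km_inhib > 0, inflow_A >= 0, flow >= 0)
  ld <- if (exchange_LD) " exchanged inflow=0" else ""
  preset_from_text(c(
    paste0("species A init=", fmt_num(inflow_A),
           " exchanged inflow=", fmt_num(inflow_A)),
    paste0("species L init=", fmt_num(l0), ld),
    paste0("species D init=", fmt_num(d0), ld),
    "species P init=0 exchanged inflow=0",
    paste0("reaction PL: A <-> L ; kf=", fmt_num(k_prod),
           ", kr=", fmt_num(km_prod)),
    paste0("reaction PD: A <-> D ; kf=", fmt_num(k_prod),
           ", kr=", fmt_num(km_prod)),
    paste0("reaction AL: A + L <-> 2 L ; kf=", fmt_num(k_auto),
           ", kr=", fmt_num(km_auto)),
    paste0("reaction AD: A + D <-> 2 D ; kf=", fmt_num(k_auto),
           ", kr=", fmt_num(km_auto)),
    paste0("reaction IN: L + D <-> P ; kf=", fmt_num(k_inhib),
           ", kr=", fmt_num(km_inhib)),
    paste0("system T=", fmt_num(temperature), " flow=", fmt_num(flow))))
}

#' Enantiomeric excess of a composition
#' @param conc named concentration vector containing `L` and `D`.
#' @return `([L]-[D])/([L]+[D])`, or 0 when both vanish.
#' @export
enantiomeric_excess <- function(conc) {
  l <- conc[["L"]]; d <- conc[["D"]]
  if (l + d == 0) return(0)
  (l - d) / (l + d)
}

#' Validate the mirror symmetry of a Frank-type network
#'
#' Checks structurally that swapping the labels L and D maps the reaction
#' set (including rate constants, initial/inflow concentrations of the
#' achiral species) onto itself.
#'
#' @param net a [reaction_network] with species L and D.
#' @return TRUE, invisibly; error if the parameter set carries a chiral
#'   bias.
#' @export
check_mirror_symmetry <- function(net) {
  swap <- function(x) {
    names(x) <- sub("^__tmp$", "D",
                    sub("^D$", "L", sub("^L$", "__tmp", names(x))))
    x
  }
  key <- function(r) {
    s <- function(side) paste(sort(paste(names(side), side)), collapse = "+")
    paste(s(r$reactants), "->", s(r$products), "@", fmt_num(r$k))
  }
  orig <- sort(vapply(net$reactions, key, character(1)))
  swapped <- sort(vapply(net$reactions, function(r) {
    r$reactants <- swap(r$reactants); r$products <- swap(r$products); key(r)
  }, character(1)))
  if (!identical(orig, swapped))
    stop("parameter set breaks the L <-> D mirror symmetry")
  sp <- net$species
  iL <- match("L", sp$name); iD <- match("D", sp$name)
  if (is.na(iL) || is.na(iD)) stop("network has no species L and D")
  if (sp$exchanged[iL] != sp$exchanged[iD] ||
      sp$inflow[iL] != sp$inflow[iD] || sp$clamped[iL] != sp$clamped[iD])
    stop("exchange configuration breaks the L <-> D mirror symmetry")
  invisible(TRUE)
}

#' Racemic stationary state of a mirror-symmetric network
#'
#' Solves `dc/dt = 0` on the racemic subspace (`[L] = [D]` imposed
#' exactly), so the racemic NESS is found even where it is unstable in the
#' full space.  Returns a `steady_state` whose stability verdict is from
#' the *full* Jacobian.
#'
#' @param net a mirror-symmetric [reaction_network] (see
#'   [check_mirror_symmetry()]).
#' @param start optional starting composition.
#' @return a `steady_state`, or NULL if no racemic root is found.
#' @export
racemic_ness <- function(net, start = NULL) {
  check_mirror_symmetry(net)
  iL <- match("L", net$species$name)
  iD <- match("D", net$species$name)
  if (is.null(start)) {
    start <- pmax(initial_state(net), 1e-4)
    m <- (start[iL] + start[iD]) / 2
    start[iL] <- start[iD] <- m
    ## approach the racemic NESS by integration first: the dynamics are
    ## L<->D equivariant, so a symmetric start stays on the racemic
    ## subspace, where the NESS is typically attracting even when it is a
    ## saddle of the full space
    appr <- integrate_to_steady(net, start, tol = 1e-10, max_chunks = 8)
    if (!is.null(appr)) {
      appr[c(iL, iD)] <- mean(appr[c(iL, iD)])  # re-symmetrize rounding
      start <- pmax(appr, 1e-300)
    }
  }
  keep <- setdiff(seq_len(n_species(net)), iD)   # D tied to L
  expand <- function(x) {
    cc <- numeric(n_species(net))
    cc[keep] <- x
    cc[iD] <- cc[iL]
    stats::setNames(cc, net$species$name)
  }
  Ffun <- function(u) {
    cc <- expand(exp(u))
    time_derivatives(net, cc)[keep]
  }
  Jfun <- function(u) {
    cc <- expand(exp(u))
    J <- jacobian_at(net, cc)
    Jr <- J[keep, keep, drop = FALSE]
    Jr[, keep == iL] <- Jr[, keep == iL, drop = FALSE] +
      J[keep, iD, drop = FALSE]
    Jr * rep(exp(u), each = length(keep))
  }
  u <- log(pmax(start[keep], 1e-8))
  Fv <- Ffun(u); fn <- max(abs(Fv))
  for (it in 1:200) {
    if (fn < 1e-13) break
    step <- tryCatch(qr.solve(Jfun(u), -Fv, tol = 1e-13),
                     error = function(e) NULL)
    if (is.null(step)) return(NULL)
    smax <- max(abs(step)); if (smax > 3) step <- step * 3 / smax
    lambda <- 1
    repeat {
      u2 <- u + lambda * step
      F2 <- Ffun(u2)
      if (all(is.finite(F2)) && max(abs(F2)) < fn) break
      lambda <- lambda / 2
      if (lambda < 1e-10) return(NULL)
    }
    u <- u2; Fv <- F2; fn <- max(abs(F2))
  }
  if (fn > 1e-9) return(NULL)
  steady_state_at(net, expand(exp(u)), verify_integration = FALSE)
}

#' Locate the mirror-symmetry-breaking threshold flow
#'
#' Bisects the reactor flow rate on the sign of the leading real part of
#' the racemic NESS Jacobian spectrum: below the threshold the racemic
#' state is stable, above it the antisymmetric mode grows and the system
#' breaks chiral symmetry.  (For the default Frank parameters the racemic
#' state destabilizes as the flow *decreases* through the threshold; the
#' bisection only assumes the sign changes once across the bracket.)
#'
#' @param net a mirror-symmetric Frank-type network (any flow value).
#' @param flow_range bracket of flow rates to search.
#' @param tol absolute tolerance on the threshold flow.
#' @return list with `threshold`, `stable_side` (which end of the bracket
#'   is stable), and the bracket actually used.
#' @export
find_smsb_threshold <- function(net, flow_range = c(1e-4, 2), tol = 1e-6) {
  lead <- function(f) {
    ss <- racemic_ness(set_parameter(net, "flow", f))
    if (is.null(ss)) stop("racemic NESS not found at flow = ", f)
    max(Re(ss$jacobian_eigenvalues))
  }
  lo <- flow_range[1]; hi <- flow_range[2]
  flo <- lead(lo); fhi <- lead(hi)
  if (sign(flo) == sign(fhi))
    stop("racemic stability does not change across flow_range: leading ",
         "eigenvalues ", signif(flo, 4), " and ", signif(fhi, 4))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- lead(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  list(threshold = (lo + hi) / 2,
       stable_side = if (flo < 0) "low" else "high",
       bracket = flow_range)
}

#' Seeded random thermodynamically consistent fixture network
#'
#' Generates `n_pairs` reversible uni/bimolecular mass-action pairs over
#' `n_species` species.  Rate constants are built from random standard
#' potentials `g_k` (in RT units) as
#' `k_f = s * exp(-(1/2) sum nu g)`, `k_r = s * exp(+(1/2) sum nu g)` with
#' a random symmetric prefactor `s`, so `log Keq = -sum_k nu_k g_k` and the
#' closed network satisfies the Wegscheider conditions exactly, relaxing to
#' the detailed-balance equilibrium `c_eq = exp(-g)`.  With `driven = TRUE`
#' an open-flow drive (CSTR exchange of a random subset of species) is
#' added on top of the same consistent chemistry.
#'
#' @param n_species >= 2.
#' @param n_pairs >= 1.
#' @param driven add a CSTR drive.
#' @param seed RNG seed; the same seed yields a byte-identical serialized
#'   network.
#' @param temperature K.
#' @return a [reaction_network].
#' @export
random_network <- function(n_species = 4, n_pairs = 4, driven = FALSE,
                           seed = DEFAULT_SEED, temperature = 300) {
  stopifnot(n_species >= 2, n_pairs >= 1)
  with_seed(seed, {
    spn <- paste0("S", seq_len(n_species))
    g <- stats::rnorm(n_species, 0, 1)
    for (attempt in 1:100) {
      rx <- lapply(seq_len(n_pairs), function(p) {
        repeat {
          nl <- sample(1:2, 1)
          nr <- sample(1:2, 1)
          lhs <- table(sample(spn, nl, replace = TRUE))
          rhs <- table(sample(spn, nr, replace = TRUE))
          net_change <- any(!names(lhs) %in% names(rhs)) ||
            any(!names(rhs) %in% names(lhs)) ||
            any(lhs[names(rhs)[names(rhs) %in% names(lhs)]] !=
                rhs[names(rhs)[names(rhs) %in% names(lhs)]])
          if (net_change) break
        }
        list(lhs = lhs, rhs = rhs, s = exp(stats::runif(1, -1, 1)))
      })
      used <- unique(unlist(lapply(rx, function(r)
        c(names(r$lhs), names(r$rhs)))))
      if (all(spn %in% used)) break
      if (attempt == 100)
        stop("could not connect all species in 100 attempts")
    }
    exch <- if (driven) sort(sample(seq_len(n_species),
                                    max(1, ceiling(n_species / 2)))) else
      integer(0)
    lines <- character(0)
    for (i in seq_len(n_species)) {
      init <- exp(stats::runif(1, log(0.1), log(2)))
      l <- paste0("species ", spn[i], " init=", fmt_num(init))
      if (i %in% exch)
        l <- paste0(l, " exchanged inflow=",
                    fmt_num(exp(stats::runif(1, log(0.1), log(2)))))
      lines <- c(lines, l)
    }
    side_txt <- function(tb) paste(ifelse(tb == 1, names(tb),
                                          paste(tb, names(tb))),
                                   collapse = " + ")
    for (p in seq_len(n_pairs)) {
      r <- rx[[p]]
      nu <- stats::setNames(numeric(n_species), spn)
      nu[names(r$rhs)] <- nu[names(r$rhs)] + as.numeric(r$rhs)
      nu[names(r$lhs)] <- nu[names(r$lhs)] - as.numeric(r$lhs)
      dg <- sum(nu * g)
      kf <- r$s * exp(-dg / 2)
      kr <- r$s * exp(+dg / 2)
      lines <- c(lines, paste0("reaction P", p, ": ", side_txt(r$lhs),
                               " <-> ", side_txt(r$rhs),
                               " ; kf=", fmt_num(kf), ", kr=", fmt_num(kr)))
    }
    flow <- if (driven) exp(stats::runif(1, log(0.05), log(1))) else 0
    lines <- c(lines, paste0("system T=", fmt_num(temperature),
                             " flow=", fmt_num(flow)))
    preset_from_text(lines)
  })
}

#' Look up a preset network by name
#'
#' Known names: `"ab"`, `"competitive"`, `"competitive-enantiomer"`
#' (mirror-identical constants), `"schlogl"` (factored-cubic parameters,
#' states 1/2/3), `"frank"`.  Extra `params` are passed to the constructor.
#'
#' @param name preset name.
#' @param params named list of constructor arguments.
#' @return a [reaction_network].
#' @export
preset <- function(name, params = list()) {
  ctor <- switch(name,
    "ab" = make_ab,
    "competitive" = make_competitive,
    "competitive-enantiomer" = function(...)
      make_competitive(k1C = 1, km1C = 0.1, k1D = 1, km1D = 0.1,
                       flow = 0.5, ...),
    "schlogl" = make_schlogl,
    "frank" = make_frank,
    stop("unknown preset '", name, "'"))
  do.call(ctor, params)
}
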