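test_that("affinities follow RT log(vf/vr) with the spontaneous-forward sign", {
  net <- make_ab(2, 1, 1)
  # equilibrated pair: zero affinity
  expect_equal(unname(affinities(net, c(1, 2))), 0)
  # [A]=[B]=1: Af = RT log 2, forward spontaneous
  expect_equal(unname(affinities(net, c(1, 1))), R_GAS * 300 * log(2),
               tolerance = 1e-12)
  expect_gt(affinities(net, c(1, 1)), 0)
  # enantiomer pairs at a mirror-symmetric composition have equal affinities
  fr <- make_frank()
  cc <- c(A = 0.5, L = 0.2, D = 0.2, P = 0.1)
  af <- affinities(fr, cc)
  expect_equal(af[["PL"]], af[["PD"]])
  expect_equal(af[["AL"]], af[["AD"]])
  # zero rate: affinity undefined
  expect_error(affinities(net, c(1, 0)), "zero forward or reverse")
})

test_that("internal entropy production is R sum (vf-vr) log(vf/vr), >= 0", {
  net <- make_ab(2, 1, 1)
  expect_equal(entropy_production_internal(net, c(2 / 3, 4 / 3)), 0)
  expect_equal(entropy_production_internal(net, c(1, 1)), R_GAS * log(2),
               tolerance = 1e-12)
  # catalysis: scaling both constants x10 (same Keq) multiplies sigma by 10
  cat10 <- make_ab(20, 10, 1)
  expect_equal(entropy_production_internal(cat10, c(1, 1)),
               10 * entropy_production_internal(net, c(1, 1)))
  # non-negativity at random compositions of random fixture networks
  set.seed(7)
  worst <- 0
  for (rep in 1:40) {
    rn <- random_network(4, 4, driven = rep %% 2 == 0, seed = 100 + rep)
    for (j in 1:25) {
      s <- entropy_production_internal(rn, rand_conc(4, 0.01, 10))
      worst <- min(worst, s)
    }
  }
  expect_gte(worst, -1e-12 * R_GAS)
})

test_that("relative-potential form (per unidirectional reaction) equals the pair form", {
  # hand-checkable case: A<->B, k1=2, km1=1, [A]=[B]=1, ref (2/3, 4/3):
  # R*(2 log((1)/(2/3) * (4/3)/(1)) + 1 * log((1)/(4/3) * (2/3)/(1)))
  # = R*(2 log 2 - log 2) = R log 2, equal to (2-1) R log 2 from the pairs
  net <- make_ab(2, 1, 1)
  v14 <- entropy_production_relative(net, c(1, 1), c(2 / 3, 4 / 3))
  expect_equal(v14, R_GAS * (2 * log(2) + log(1 / 2)), tolerance = 1e-12)
  expect_equal(v14, entropy_production_internal(net, c(1, 1)),
               tolerance = 1e-12)
  # at the reference itself the production vanishes
  expect_equal(entropy_production_relative(net, c(2 / 3, 4 / 3),
                                           c(2 / 3, 4 / 3)), 0)
  # a non-equilibrium reference is rejected
  expect_error(entropy_production_relative(net, c(1, 1), c(1, 1)),
               "not a detailed-balance equilibrium")
  # identity sweep on Wegscheider-consistent random networks
  set.seed(13)
  for (rep in 1:50) {
    rn <- random_network(4, sample(3:5, 1), seed = 200 + rep)
    wc <- wegscheider_check(rn)
    expect_true(wc$consistent)
    ref <- equilibrium_point(rn)
    for (j in 1:50) {
      cc <- rand_conc(4, 0.05, 5)
      e11 <- entropy_production_internal(rn, cc)
      e14 <- entropy_production_relative(rn, cc, ref)
      expect_lt(abs(e14 - e11) / max(e11, R_GAS), 1e-10)
    }
  }
})

test_that("entropy exchange balances internal production exactly at a NESS", {
  # closed network: no exchange
  expect_equal(entropy_exchange(make_ab(2, 1, 1), c(1, 1)), 0)
  nets <- list(make_competitive(), make_competitive(flow = 0.2),
               make_frank(), random_network(4, 4, driven = TRUE, seed = 31))
  for (net in nets) {
    ss <- find_steady_states(net, n_starts = 16)
    expect_gt(length(ss), 0)
    for (s in ss) {
      si <- entropy_production_internal(net, s$conc)
      se <- entropy_exchange(net, s$conc)
      expect_lt(abs(si + se), 1e-10 * max(si, R_GAS))
      expect_gt(si, 0)    # NESS of a driven system dissipates
    }
  }
})

test_that("off-NESS, sigma_int + sigma_exch equals -(1/T) dG/dt", {
  net <- make_competitive()
  ref <- equilibrium_point(net)
  G <- function(cc) sum(cc * (chem_potentials(net, cc, ref) - R_GAS * 300))
  tr <- integrate_network(net, c(A = 1, C = 0.3, D = 0.05), t_end = 2,
                          n_out = 21)
  for (i in c(3, 10, 18)) {
    cc <- tr$states[i, ]
    tot <- entropy_production_internal(net, cc) + entropy_exchange(net, cc, ref)
    h <- 1e-7
    cp <- nessflow:::rk4_step(net, cc, h)
    cm <- nessflow:::rk4_step(net, cc, -h)
    dGdt <- (G(cp) - G(cm)) / (2 * h)
    expect_lt(abs(tot + dGdt / 300) / max(abs(tot), R_GAS), 1e-8)
  }
})

test_that("balance residual distinguishes NESS from balance-only points", {
  net <- make_competitive()
  ness <- find_steady_states(net, n_starts = 8)[[1]]$conc
  br <- balance_residual(net, ness)
  expect_equal(br$label, "NESS")
  expect_lt(abs(br$sigma_total), 1e-10 * max(br$sigma_int, R_GAS))
  # equilibrium of a closed network: 0 = 0 + 0
  ab <- make_ab(2, 1, 1)
  bre <- balance_residual(ab, c(1 / 3, 2 / 3))
  expect_equal(bre$sigma_total, 0, tolerance = 1e-14)
  expect_equal(bre$sigma_int, 0, tolerance = 1e-14)
  # a balance-zero composition off the contour of stationarity:
  # found by bisection along a line through the NESS
  dir <- c(A = 0, C = -0.1, D = 0.1)
  f <- function(t) {
    cc <- ness + t * dir
    entropy_production_internal(net, cc) + entropy_exchange(net, cc)
  }
  root <- uniroot(f, c(0.5, 3), tol = 1e-14)$root
  expect_gt(root, 0.01)  # genuinely away from the NESS
  cc <- ness + root * dir
  brc <- balance_residual(net, cc)
  expect_equal(brc$label, "balance-only")
  expect_gt(brc$max_dcdt, 1e-6)
})

test_that("Wegscheider-inconsistent constants are detected and rejected", {
  # triangle A->B->C->A with a thermodynamically inconsistent cycle
  bad <- parse_network(c(
    "species A init=1", "species B init=1", "species C init=1",
    "reaction R1: A <-> B ; kf=2, kr=1",
    "reaction R2: B <-> C ; kf=2, kr=1",
    "reaction R3: C <-> A ; kf=2, kr=1",
    "system T=300 flow=0"))
  wc <- wegscheider_check(bad)
  expect_false(wc$consistent)
  expect_error(equilibrium_point(bad), "Wegscheider")
  # the consistent triangle passes
  good <- parse_network(c(
    "species A init=1", "species B init=1", "species C init=1",
    "reaction R1: A <-> B ; kf=2, kr=1",
    "reaction R2: B <-> C ; kf=2, kr=1",
    "reaction R3: C <-> A ; kf=1, kr=4",
    "system T=300 flow=0"))
  expect_true(wegscheider_check(good)$consistent)
  eq <- equilibrium_point(good)
  expect_equal(max(abs(affinities(good, eq))), 0, tolerance = 1e-9)
})

test_that("driven random networks reach a NESS with positive dissipation", {
  net <- random_network(4, 4, driven = TRUE, seed = 77)
  st <- find_steady_states(net, n_starts = 16)
  expect_gt(length(st), 0)
  expect_gt(entropy_production_internal(net, st[[1]]$conc), 0)
  # undriven twin relaxes to detailed balance: all affinities vanish
  closed <- random_network(4, 4, driven = FALSE, seed = 77)
  tr <- integrate_network(closed, t_end = 2000, stop_at_steady = TRUE,
                          steady_tol = 1e-13)
  fin <- final_state(tr)
  expect_lt(max(abs(affinities(closed, fin))), 1e-6)
  expect_lt(entropy_production_internal(closed, fin), 1e-12)
})

test_that("selectivity identity holds along the whole flow grid", {
  for (f in c(0.01, 0.1, 1, 5, 20)) {
    net <- make_competitive(flow = f)
    ness <- find_steady_states(net, n_starts = 8)[[1]]$conc
    sel <- selectivity_identity_residual(net, ness, "RC", "RD")
    expect_lt(sel$residual, 1e-10)
    expect_equal(sel$ratio, 10 * (0.1 + f) / (1 + f), tolerance = 1e-8)
  }
})
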