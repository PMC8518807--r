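test_that("presets parse through the standard network format", {
  nets <- list(ab = make_ab(), competitive = make_competitive(),
               schlogl = make_schlogl(), frank = make_frank(),
               random = random_network(5, 4, driven = TRUE, seed = 2))
  for (nm in names(nets)) {
    txt <- format_network(nets[[nm]])
    expect_identical(format_network(parse_network(txt)), txt, label = nm)
  }
})

test_that("make_ab equilibrium and affinity behave as advertised", {
  net <- make_ab(2, 1, total = 1)
  eq <- equilibrium_point(net, class_of = initial_state(net))
  expect_equal(eq[["B"]] / eq[["A"]], 2, tolerance = 1e-10)
  sym <- make_ab(1.3, 1.3, total = 2)
  eqs <- equilibrium_point(sym, class_of = initial_state(sym))
  expect_equal(eqs[["B"]] / eqs[["A"]], 1, tolerance = 1e-10)
  expect_equal(unname(affinities(net, c(1, 1))), R_GAS * 300 * log(2),
               tolerance = 1e-12)
})

test_that("competitive selectivity follows the flow-rate limits", {
  # f = 1: closed form 10 (0.1 + 1)/(1 + 1) = 5.5
  net <- make_competitive(flow = 1)
  ness <- find_steady_states(net, n_starts = 8)[[1]]$conc
  expect_equal(ness[["C"]] / ness[["D"]], 5.5, tolerance = 1e-8)
  # f -> 0: selectivity -> KeqC/KeqD = 1; f -> inf: -> k1C/k1D = 10
  lo <- make_competitive(flow = 1e-5)
  nl <- find_steady_states(lo, n_starts = 8)[[1]]$conc
  expect_equal(nl[["C"]] / nl[["D"]], 1, tolerance = 1e-3)
  hi <- make_competitive(flow = 1e4)
  nh <- find_steady_states(hi, n_starts = 8)[[1]]$conc
  expect_equal(nh[["C"]] / nh[["D"]], 10, tolerance = 1e-3)
  # enantiomer mode: selectivity 1 from any start
  en <- make_competitive(k1C = 1, km1C = 0.1, k1D = 1, km1D = 0.1,
                         flow = 0.5)
  tr <- integrate_network(en, c(A = 0.2, C = 0.9, D = 0.1), t_end = 200,
                          stop_at_steady = TRUE, steady_tol = 1e-13)
  fin <- final_state(tr)
  expect_equal(fin[["C"]] / fin[["D"]], 1, tolerance = 1e-8)
})

test_that("Schloegl preset is path dependent inside the bistable window", {
  sg <- make_schlogl()   # states {1, 2, 3}
  lo <- integrate_network(sg, c(A = 6, X = 0.5, B = 1), t_end = 50,
                          stop_at_steady = TRUE, steady_tol = 1e-12)
  hi <- integrate_network(sg, c(A = 6, X = 3.5, B = 1), t_end = 50,
                          stop_at_steady = TRUE, steady_tol = 1e-12)
  expect_equal(final_state(lo)[["X"]], 1, tolerance = 1e-6)
  expect_equal(final_state(hi)[["X"]], 3, tolerance = 1e-6)
  # detailed-balance parameter choice: unique equilibrium, no bistability
  db <- make_schlogl(k1 = 1, km1 = 1, k2 = 1, km2 = 1,
                     a_clamped = 1, b_clamped = 1)
  expect_true(wegscheider_check(db)$consistent)
  ss <- find_steady_states(db, n_starts = 24)
  expect_equal(length(ss), 1L)
  expect_equal(max(abs(affinities(db, ss[[1]]$conc))), 0, tolerance = 1e-8)
})

test_that("Schloegl sweep shows hysteresis across the bistable window", {
  sg <- make_schlogl(x0 = 0.5)
  sc <- scan_branch(sg, "kf:R1", seq(0.8, 1.2, length.out = 21))
  expect_true(sc$hysteresis)
  expect_gt(sum(sc$mismatch), 2)       # a whole window, not one point
  # jump locations sit inside the fold interval of the cubic
  expect_true(all(sc$discontinuities_up > 0.9 & sc$discontinuities_up < 1.15))
  # no hysteresis for the linear competitive network
  sc2 <- scan_branch(make_competitive(), "flow",
                     seq(0.2, 2, length.out = 10))
  expect_false(sc2$hysteresis)
  expect_equal(length(sc2$discontinuities_up), 0L)
})

test_that("Frank trajectories are exactly equivariant under L <-> D", {
  fn <- make_frank()
  c0 <- c(A = 1, L = 0.17, D = 0.06, P = 0.01)
  c0m <- c(A = 1, L = 0.06, D = 0.17, P = 0.01)
  t_out <- seq(0, 30, length.out = 31)
  tr <- integrate_network(fn, c0, times = t_out)
  trm <- integrate_network(fn, c0m, times = t_out)
  swapped <- trm$states[, c("A", "D", "L", "P")]
  expect_lt(max(abs(tr$states - swapped)), 1e-9)
  ee <- apply(tr$states, 1, enantiomeric_excess)
  eem <- apply(trm$states, 1, enantiomeric_excess)
  expect_equal(ee, -eem, tolerance = 1e-12)
  # exact racemic start stays racemic indefinitely
  trr <- integrate_network(fn, c(A = 1, L = 0.1, D = 0.1, P = 0),
                           t_end = 200, n_out = 51)
  expect_equal(max(abs(trr$states[, "L"] - trr$states[, "D"])), 0)
})

test_that("chirally biased Frank parameter sets are rejected", {
  fn <- make_frank()
  bad <- set_parameter(fn, "kf:AL", 1.01)
  expect_error(check_mirror_symmetry(bad), "mirror symmetry")
  expect_silent(check_mirror_symmetry(fn))
})

test_that("SMSB threshold separates racemic well from racemic saddle", {
  fn <- make_frank()
  th <- find_smsb_threshold(fn, c(1e-3, 0.3))
  expect_gt(th$threshold, 1e-3)
  expect_lt(th$threshold, 0.3)
  expect_equal(th$stable_side, "low")
  below <- racemic_ness(set_parameter(fn, "flow", th$threshold / 2))
  above <- racemic_ness(set_parameter(fn, "flow", th$threshold * 2))
  expect_equal(below$verdict, "stable")
  expect_equal(above$verdict, "unstable")
  # above threshold: two mirror scalemic attractors from seeded biases
  net <- set_parameter(fn, "flow", th$threshold * 2)
  sp <- integrate_network(net, c(A = 1, L = 0.1 * (1 + 1e-8), D = 0.1, P = 0),
                          t_end = 1e4, stop_at_steady = TRUE,
                          steady_tol = 1e-13)
  sm <- integrate_network(net, c(A = 1, L = 0.1, D = 0.1 * (1 + 1e-8), P = 0),
                          t_end = 1e4, stop_at_steady = TRUE,
                          steady_tol = 1e-13)
  eplus <- enantiomeric_excess(final_state(sp))
  eminus <- enantiomeric_excess(final_state(sm))
  expect_gt(eplus, 0.1)
  expect_equal(eplus, -eminus, tolerance = 1e-6)
})

test_that("random fixture networks are reproducible and consistent", {
  a <- random_network(5, 5, driven = TRUE, seed = 123)
  b <- random_network(5, 5, driven = TRUE, seed = 123)
  expect_identical(format_network(a), format_network(b))
  expect_false(identical(format_network(a),
                         format_network(random_network(5, 5, driven = TRUE,
                                                       seed = 124))))
  for (seed in 1:10)
    expect_true(wegscheider_check(random_network(4, 4, seed = seed))$consistent)
})

test_that("preset lookup matches the constructors", {
  expect_identical(format_network(preset("ab")), format_network(make_ab()))
  expect_identical(format_network(preset("competitive",
                                         list(flow = 0.3))),
                   format_network(make_competitive(flow = 0.3)))
  expect_error(preset("nope"), "unknown preset")
})
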