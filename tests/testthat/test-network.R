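test_that("parser expands reversible statements and validates input", {
  net <- parse_network(ab_text)
  expect_s3_class(net, "reaction_network")
  expect_equal(nrow(net$species), 2L)
  expect_equal(length(net$reactions), 2L)
  expect_equal(nrow(net$pairs), 1L)
  expect_true(is_thermo_complete(net))

  uni <- parse_network(c("species A init=1", "species B init=0",
                         "reaction R1: A -> B ; kf=1",
                         "system T=300 flow=0"))
  expect_equal(length(uni$reactions), 1L)
  expect_false(is_thermo_complete(uni))
  expect_error(affinities(uni, c(1, 1)), "incomplete")

  expect_error(parse_network("species A init=1\nreaction R: A <-> Z ; kf=1, kr=1"),
               "unknown species")
  expect_error(parse_network(c("species A init=1", "species B init=0",
                               "reaction R: A <-> B ; kf=-1, kr=1")),
               "rate constant")
  expect_error(parse_network(c("species A init=1",
                               "species A init=2")), "duplicate")
  expect_error(parse_network(c("species A init=1 clamped exchanged inflow=1",
                               "system T=300 flow=0")),
               "clamped and exchanged")
  expect_error(parse_network(c("species A init=1 exchanged inflow=1",
                               "species B init=0",
                               "reaction R: A <-> B ; kf=1, kr=1",
                               "reaction R: B <-> A ; kf=1, kr=1")),
               "pair")
})

test_that("serialization round-trips bit-exactly", {
  nets <- list(parse_network(ab_text), make_competitive(), make_schlogl(),
               make_frank(), random_network(5, 5, driven = TRUE, seed = 11))
  for (net in nets) {
    txt <- format_network(net)
    rt <- parse_network(txt)
    expect_identical(format_network(rt), txt)
    expect_equal(rt$species, net$species)
    expect_equal(rt$k, net$k)
    expect_equal(rt$N, net$N)
    expect_equal(rt$temperature, net$temperature)
    expect_equal(rt$flow_rate, net$flow_rate)
  }
  # awkward constants survive the 17-digit serializer
  net <- make_ab(k1 = 1 / 3, km1 = 2e-7, total = 0.123456789012345678)
  expect_identical(format_network(parse_network(format_network(net))),
                   format_network(net))
})

test_that("SNA decomposition pairs forward and reverse steps", {
  net <- parse_network(ab_text)
  rx <- sna_decompose(net)
  expect_equal(vapply(rx, `[[`, character(1), "direction"),
               c("forward", "reverse"))
  expect_equal(vapply(rx, `[[`, numeric(1), "k"), c(2, 1))
  # 3 reversible pairs -> 6 unidirectional reactions
  net3 <- random_network(4, 3, seed = 5)
  expect_equal(length(sna_decompose(net3)), 6L)
  # net stoichiometry of a pair: forward column = -(reverse column)
  for (seed in 1:5) {
    net <- random_network(4, 4, seed = seed)
    expect_equal(net$N[, net$pairs$fwd], -net$N[, net$pairs$rev],
                 ignore_attr = TRUE)
  }
})

test_that("mass-action rates follow the power law", {
  net <- parse_network(c("species A init=1", "species B init=0",
                         "reaction R1: A -> B ; kf=2",
                         "system T=300 flow=0"))
  expect_equal(unname(reaction_rates(net, c(1, 0))), 2)
  # third-order autocatalytic step: 3X -> 2X + B at [X] = 2 gives 8k
  sg <- make_schlogl(k2 = 0.7)
  v <- reaction_rates(sg, c(A = 6, X = 2, B = 1))
  expect_equal(unname(v["R2.f"]), 0.7 * 2^3)
  expect_equal(unname(reaction_rates(net, c(0, 0))), 0)
  expect_error(reaction_rates(net, c(-0.1, 0)), "negative")
  # homogeneity: scaling one reactant by lambda scales v by lambda^order
  cc <- c(A = 6, X = 1.3, B = 1)
  lam <- 1.7
  cc2 <- cc; cc2["X"] <- cc["X"] * lam
  v1 <- reaction_rates(sg, cc); v2 <- reaction_rates(sg, cc2)
  ord <- sg$Mr["X", ]
  expect_equal(unname(v2), unname(v1 * lam^ord))
})

test_that("time derivatives include stoichiometry, flow, and clamping", {
  net <- parse_network(ab_text)
  expect_equal(unname(time_derivatives(net, c(1, 1))), c(-1, 1))
  # equilibrium ratio [B]/[A] = k1/km1 annihilates the derivatives
  expect_equal(unname(time_derivatives(net, c(1, 2))), c(0, 0))
  # balanced exchange: inflow = outflow
  ex <- parse_network(c("species A init=1 exchanged inflow=1",
                        "system T=300 flow=0.5"))
  expect_equal(unname(time_derivatives(ex, 1)), 0)
  # clamped species are held fixed
  sg <- make_schlogl()
  d <- time_derivatives(sg, c(A = 6, X = 0.5, B = 1))
  expect_equal(unname(d[c("A", "B")]), c(0, 0))
})

test_that("conservation laws span the closed-system left null space", {
  net <- parse_network(ab_text)
  L <- conservation_laws(net)
  expect_equal(ncol(L), 1L)
  expect_equal(unname(L[, 1] / max(L[, 1])), c(1, 1))
  # open competitive network: flow couples every species, no conservation
  expect_equal(ncol(conservation_laws(make_competitive())), 0L)
  # closed Frank network conserves the total moiety A + L + D + 2P
  fr <- make_frank(flow = 0, exchange_LD = FALSE)
  fr$species$exchanged <- FALSE
  fr <- nessflow:::compile_network(fr)
  Lf <- conservation_laws(fr)
  expect_equal(ncol(Lf), 1L)
  m <- Lf[, 1] / Lf["A", 1]
  expect_equal(unname(m[c("A", "L", "D", "P")]), c(1, 1, 1, 2))
  # m . dc/dt = 0 at random compositions
  for (i in 1:10) {
    cc <- rand_conc(4)
    expect_lt(abs(sum(m * time_derivatives(fr, cc))), 1e-12)
  }
})

test_that("parameter paths address rate constants, flow and boundaries", {
  net <- make_competitive()
  n2 <- set_parameter(net, "kf:RC", 3.5)
  expect_equal(n2$k[n2$pairs$fwd[n2$pairs$id == "RC"]], 3.5)
  n3 <- set_parameter(net, "flow", 0.25)
  expect_equal(n3$flow_rate, 0.25)
  n4 <- set_parameter(net, "inflow:A", 2)
  expect_equal(n4$species$inflow[n4$species$name == "A"], 2)
  expect_error(set_parameter(net, "kf:NOPE", 1), "no reaction")
})
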