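test_that("both topologies give 9 states with 8 reversible transition pairs", {
  for (topo in c("glycine-desensitization", "sequential")) {
    sch <- build_scheme("optimized", topology = topo)
    expect_length(sch$states, 9L)
    expect_equal(nrow(sch$transitions), 16L)
    # every directed transition has its reverse
    key <- with(sch$transitions, paste(from, to))
    rev_key <- with(sch$transitions, paste(to, from))
    expect_setequal(key, rev_key)
    expect_equal(sch$open_states, c("O1", "O2"))
  }
})

test_that("transition graph is connected: every state reachable from S1", {
  for (topo in c("glycine-desensitization", "sequential")) {
    sch <- build_scheme("original", topology = topo)
    Q <- generator_matrix(sch, glutamate = 1000, glycine = 100)
    adj <- Q > 0
    reach <- c(TRUE, rep(FALSE, 8))
    for (i in 1:9) reach <- reach | as.logical(adj %*% reach)
    expect_true(all(reach))
  }
})

test_that("paired-sites convention doubles the first glutamate binding step", {
  sch <- build_scheme("original", statistical_factors = "paired-sites")
  tr <- sch$transitions
  first <- tr[tr$from == "S1" & tr$to == "S2", ]
  # 2 * kon = 2 * 17 uM^-1 s^-1 = 0.034 uM^-1 ms^-1
  expect_equal(first$rate, 2 * 17 / 1000)
  expect_equal(first$ligand, "glu")
  none <- build_scheme("original", statistical_factors = "none")
  expect_equal(none$transitions[none$transitions$from == "S1", "rate"],
               17 / 1000)
})

test_that("ode_rhs conserves probability and matches an independent generator", {
  sch <- build_scheme("optimized")
  # apo state with no ligand is stationary
  p_apo <- c(1, rep(0, 8))
  expect_equal(ode_rhs(p_apo, 0, glutamate = 0, glycine = 0, scheme = sch),
               rep(0, 9))
  # derivatives sum to zero for arbitrary occupancies
  set.seed(42)
  for (i in 1:5) {
    p <- stats::runif(9); p <- p / sum(p)
    d <- ode_rhs(p, 0, glutamate = 500, glycine = 30, scheme = sch)
    expect_lt(abs(sum(d)), 1e-12)
  }
  # independent generator oracle, assembled transition by transition from
  # the printed rates (glycine-desensitization topology, no factors)
  r <- unclass(rate_constants("optimized")) / 1000
  glu <- 250; gly <- 20
  Q <- matrix(0, 9, 9)
  put <- function(i, j, k) {
    Q[j, i] <<- Q[j, i] + k
    Q[i, i] <<- Q[i, i] - k
  }
  put(1, 2, r["kon"] * glu);      put(2, 1, r["koff"])
  put(2, 3, r["kon"] * glu);      put(3, 2, r["koff"])
  put(3, 4, r["k32"]);            put(4, 3, r["k23"])
  put(4, 5, r["k21"]);            put(5, 4, r["k12"])
  put(5, 6, r["k1_O1"]);          put(6, 5, r["kO1_1"])
  put(6, 7, r["kO1_O2"]);         put(7, 6, r["kO2_O1"])
  put(3, 8, r["kgly_off"]);       put(8, 3, r["kgly_on"] * gly)
  put(8, 9, r["kgly_off"]);       put(9, 8, r["kgly_on"] * gly)
  p <- stats::runif(9); p <- p / sum(p)
  expect_equal(ode_rhs(p, 0, glu, gly, sch), as.numeric(Q %*% p),
               tolerance = 1e-12)
  expect_error(ode_rhs(p, 0, -1, gly, sch), "non-negative")
})

test_that("resting occupancy is the glutamate-free stationary distribution", {
  sch <- build_scheme("optimized")
  p0 <- equilibrium_occupancy(sch, 20)
  expect_equal(sum(p0), 1)
  expect_equal(unname(p0["S1"]), 1)  # apo state absorbs without glutamate
  # sequential topology: glycine front equilibrates with ratio r = on/off
  seq_sch <- build_scheme("optimized", statistical_factors = "none",
                          topology = "sequential")
  p0s <- equilibrium_occupancy(seq_sch, 20)
  r <- (1 / 1000 * 20) / (24 / 1000)
  expected <- c(1, r, r^2) / sum(c(1, r, r^2))
  expect_equal(unname(p0s[1:3]), expected, tolerance = 1e-9)
  expect_equal(unname(sum(p0s[4:9])), 0)
})
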