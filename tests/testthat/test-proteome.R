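test_that("uptake follows the saturating product form", {
  p <- proteome_params(mu = 1000, k = 50)
  expect_identical(uptake(0, 5, p), 0)
  expect_identical(uptake(7, 0, p), 0)
  expect_equal(uptake(10, 5, p), 500)            # S*A = k: half-saturation
  expect_equal(uptake(10, 10, p), 1000 * 100 / 150)
  # bounded below mu, monotone in each argument
  S <- seq(0, 20, by = 2.5)
  expect_true(all(uptake(S, 5, p) < p$mu))
  expect_true(all(diff(uptake(S, 5, p)) >= 0))
  expect_true(all(diff(uptake(5, S, p)) >= 0))
  expect_error(uptake(-1, 5, p), "nonnegative")
  expect_error(uptake(5, -1, p), "nonnegative")
})

test_that("ppGpp balance matches its closed-form steady state", {
  p <- proteome_params()
  expect_equal(ppgpp_rhs(0, 0, p), p$theta_b)
  gamma_star <- function(R) (p$theta_b + p$theta_i * R / (1 + R)) / p$delta_G
  expect_equal(gamma_star(1), 9.5625)
  expect_equal(ppgpp_rhs(gamma_star(1), 1, p), 0)
  # long-time integration of the one-dimensional balance at fixed R
  relax_gamma <- function(R, t_end) {
    out <- deSolve::lsoda(c(G = 0), c(0, t_end),
                          function(t, s, parms) list(ppgpp_rhs(s, R, p)),
                          parms = NULL, rtol = 1e-10, atol = 1e-12)
    unname(out[nrow(out), 2])
  }
  expect_equal(relax_gamma(1, 50), 9.5625, tolerance = 1e-6)
  expect_equal(relax_gamma(1e6, 50), 19.0625, tolerance = 1e-4)
  # saturation limit of the induction term
  expect_equal((p$theta_b + p$theta_i) / p$delta_G, 19.0625)
  # converges within 1% by t = 20 / delta_G at any fixed R
  for (R in c(0, 0.3, 2, 40)) {
    expect_equal(relax_gamma(R, 20 / p$delta_G), gamma_star(R),
                 tolerance = 0.01)
  }
  expect_error(ppgpp_rhs(-1, 1, p), "nonnegative")
})

test_that("sector equations match an independent literal transcription", {
  p <- proteome_params()
  set.seed(41)
  for (i in 1:100) {
    state <- stats::runif(6, 0, 50)
    names(state) <- c("Gamma", "m_E", "m_R", "E", "y", "R")
    S <- stats::runif(1, 0, 10)
    A <- stats::runif(1, 0, 10)
    expect_equal(proteome_rhs(state, S, A, p),
                 oracle_proteome_rhs(state, S, A, p), tolerance = 1e-14)
  }
})

test_that("the vector field points inward at the nonnegativity boundary", {
  p <- proteome_params()
  # boundary evaluation at the origin
  d0 <- proteome_rhs(rep(0, 6), 0, 0, p)
  expect_equal(unname(d0["Gamma"]), p$theta_b)
  expect_equal(unname(d0["m_E"]), 0)             # Hill term vanishes at Gamma = 0
  expect_equal(unname(d0["m_R"]), p$theta_R)     # repression fully released
  expect_true(all(d0[c("E", "y", "R")] == 0))
  # any state with a zero component has a nonnegative derivative there
  set.seed(42)
  for (i in 1:50) {
    state <- stats::runif(6, 0, 20)
    names(state) <- c("Gamma", "m_E", "m_R", "E", "y", "R")
    zero_at <- sample(6, sample(1:3, 1))
    state[zero_at] <- 0
    d <- proteome_rhs(state, stats::runif(1, 0, 5), stats::runif(1, 0, 5), p)
    expect_true(all(d[zero_at] >= 0))
  }
})

test_that("trajectories started nonnegative stay nonnegative", {
  p <- proteome_params()
  set.seed(43)
  for (i in 1:5) {
    init <- stats::runif(6, 0, 10)
    init[sample(6, 2)] <- 0
    names(init) <- c("Gamma", "m_E", "m_R", "E", "y", "R")
    # starts with R = 0 sit on the ribosome-capacity guard's discontinuity;
    # lsoda grumbles at the first step but integrates through it
    traj <- suppressWarnings(
      proteome_trajectory(stats::runif(1, 0, 10), stats::runif(1, 0, 10),
                          p, times = seq(0, 20, by = 0.1), init = init))
    expect_false(anyNA(traj))
    expect_true(all(as.matrix(traj[-1]) >= 0))
  }
})

test_that("steady states satisfy the residual criterion and fixed-point identities", {
  p <- proteome_params()
  rich <- proteome_steady_state(10, 10, p)
  expect_lt(rich$residual, 1e-8)
  expect_lt(max(abs(proteome_rhs(rich$state, 10, 10, p))), 1e-8)
  # internal ppGpp consistency at zero nutrients
  starve <- proteome_steady_state(0, 0, p)
  R_star <- starve$state[["R"]]
  expect_equal(starve$state[["Gamma"]],
               (p$theta_b + p$theta_i * R_star / (1 + R_star)) / p$delta_G,
               tolerance = 1e-8)
  # rich environments allocate more ribosomes than poor ones
  poor <- proteome_steady_state(0.5, 0.5, p)
  expect_gt(rich$state[["R"]], poor$state[["R"]])
  # amino-acid scarcity swells the metabolic-sector fraction
  scarce <- proteome_steady_state(10, 0.5, p)
  expect_gt(sector_fractions(scarce$state)[["E"]],
            sector_fractions(rich$state)[["E"]])
  # mRNA pools respect their transcription-capped bounds
  for (ss in list(rich, poor, scarce, starve)) {
    expect_lte(ss$state[["m_E"]], (p$theta_E + p$theta_hat_E * p$mu) / p$eta_E)
    expect_lte(ss$state[["m_R"]], (p$theta_R + p$theta_hat_R * p$mu) / p$eta_R)
  }
})

test_that("the steady state is reached from scattered starting points", {
  p <- proteome_params()
  ref <- proteome_steady_state(1, 1, p)
  set.seed(44)
  for (i in 1:5) {
    init <- stats::runif(6, 0.01, 30)
    names(init) <- c("Gamma", "m_E", "m_R", "E", "y", "R")
    alt <- proteome_steady_state(1, 1, p, init = init)
    expect_equal(alt$state, ref$state, tolerance = 1e-6)
  }
})

test_that("parameter objects validate, serialise and fingerprint", {
  expect_error(proteome_params(mu = -1), "nonnegative")
  expect_error(proteome_params(phi = 1.5), "phi")
  expect_error(proteome_params(n = 0.5), "Hill")
  expect_error(proteome_params(J_R = 2), "J_E and J_R")
  p <- proteome_params(theta_i = 1.5)
  for (ext in c(".yml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_proteome_params(p, path)
    expect_equal(read_proteome_params(path), p)
  }
  bad <- withr::local_tempfile(fileext = ".yml")
  writeLines("not_a_param: 3", bad)
  expect_error(read_proteome_params(bad), "not_a_param")
  expect_false(params_fingerprint(p) == params_fingerprint(proteome_params()))
})
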