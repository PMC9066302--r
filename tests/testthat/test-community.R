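test_that("Monod uptake has the textbook shape", {
  expect_identical(monod_uptake(0, 2e-10, 40), 0)
  expect_equal(monod_uptake(40, 2e-10, 40), 1e-10)   # S = K: half-saturation
  expect_error(monod_uptake(1, 1, 0), "positive")
  expect_error(monod_uptake(-1, 1, 1), "nonnegative")
  # effective rate at a surface node equals k1 times the direct steady state
  surf <- default_surface()
  pair <- strain_pair()
  S_node <- surf$S_grid[20]
  A_node <- surf$A_grid[18]
  node <- interpolate_rates(surf, S_node, A_node)
  direct <- proteome_steady_state(S_node, A_node)
  expect_equal(node$lambda, direct$lambda, tolerance = 1e-6)
  expect_equal(pair$x$k1 * node$lambda, 1e-11 * direct$lambda,
               tolerance = 1e-6)
})

test_that("community vector field has the stated structure", {
  pair <- strain_pair()
  rates <- list(lambda_hat_x = 2e-10, lambda_hat_y = 3e-10,
                beta_hat_x = 1e-9, beta_hat_y = 2e-9)
  # empty culture is a fixed point
  d <- community_rhs(c(S = 1, X = 1, Y = 1, Bx = 0, By = 0), rates, pair)
  expect_true(all(d == 0))
  # without substrate nothing is taken up or produced
  d0 <- community_rhs(c(S = 0, X = 1, Y = 2, Bx = 1e4, By = 1e4), rates, pair)
  expect_true(all(d0 == 0))
  # exchange symmetry: symmetric rates and state give equal strain growth
  sym_rates <- list(lambda_hat_x = 2e-10, lambda_hat_y = 2e-10,
                    beta_hat_x = 1e-9, beta_hat_y = 1e-9)
  ds <- community_rhs(c(S = 1, X = 0.5, Y = 0.5, Bx = 1e4, By = 1e4),
                      sym_rates, pair)
  expect_equal(ds[["Bx"]], ds[["By"]])
  expect_equal(ds[["X"]], ds[["Y"]])
  expect_error(community_rhs(c(S = -1, X = 1, Y = 1, Bx = 1, By = 1),
                             rates, pair), "nonnegative")
})

test_that("multiscale trajectories respect the model's monotonicities", {
  surf <- default_surface()
  traj <- simulate_multiscale(community_init(), surf, T = 60, dt = 1)
  m <- as.data.frame(traj)
  expect_true(all(m[c("S", "X", "Y", "Bx", "By")] >= 0))
  expect_true(all(diff(m$S) <= 1e-12))          # substrate never replenished
  expect_true(all(diff(m$Bx) >= -1e-6))         # no death terms
  expect_true(all(diff(m$By) >= -1e-6))
  expect_true(all(diff(m$time) > 0))
  expect_error(simulate_multiscale(community_init(), surf, T = 10, dt = 20),
               "dt")
  expect_error(simulate_multiscale(community_init(S0 = -1), surf, T = 5),
               "nonnegative")
})

test_that("a monoculture is the co-culture with the partner absent", {
  surf <- default_surface()
  init <- community_init(Bx0 = 2e4, By0 = 0)
  direct <- simulate_multiscale(init, surf, T = 40, dt = 1)
  mono <- simulate_monoculture("x", community_init(Bx0 = 2e4, By0 = 5e9),
                               surf, T = 40, dt = 1)
  expect_identical(as.data.frame(mono), as.data.frame(direct))
  # amino-acid starvation cripples the monoculture relative to supplementation
  starved <- final_state(simulate_monoculture(
    "x", community_init(X0 = 0, Bx0 = 2e4, By0 = 0), surf, T = 180))
  fed <- final_state(simulate_monoculture(
    "x", community_init(X0 = 2, Bx0 = 2e4, By0 = 0), surf, T = 180))
  expect_lt(starved[["Bx"]], 0.25 * fed[["Bx"]])
})

test_that("final densities are Cauchy in the coupling interval", {
  surf <- default_surface()
  finals <- vapply(c(2, 1, 0.5, 0.25), function(dt) {
    final_state(simulate_multiscale(community_init(), surf,
                                    T = 180, dt = dt))[["Bx"]]
  }, numeric(1))
  gaps <- abs(diff(finals)) / finals[-1]
  expect_true(all(diff(gaps) < 0))      # successive refinements shrink
  expect_lt(gaps[2], 0.01)              # halving dt = 1 moves finals < 1%
})

test_that("relabelling the strains mirrors the trajectory exactly", {
  surf <- default_surface()
  pair <- strain_pair()
  swapped <- list(x = pair$y, y = pair$x)
  fwd <- simulate_multiscale(community_init(X0 = 0.4, Y0 = 1.2,
                                            Bx0 = 1e4, By0 = 3e4),
                             surf, pair, T = 60, dt = 1)
  rev <- simulate_multiscale(community_init(X0 = 1.2, Y0 = 0.4,
                                            Bx0 = 3e4, By0 = 1e4),
                             surf, swapped, T = 60, dt = 1)
  expect_equal(rev$Bx, fwd$By, tolerance = 1e-10)
  expect_equal(rev$By, fwd$Bx, tolerance = 1e-10)
  expect_equal(rev$X, fwd$Y, tolerance = 1e-10)
  expect_equal(rev$S, fwd$S, tolerance = 1e-10)
})
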