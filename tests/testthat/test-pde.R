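test_that("the printed flow profile evaluates correctly", {
  expect_equal(flow_velocity(30), 0.04057, tolerance = 1e-3)
  expect_lt(abs(flow_velocity(60)), 1e-15)
  opt <- optimize(flow_velocity, c(0, 60), maximum = TRUE)
  expect_equal(opt$objective, 0.115, tolerance = 0.01)
  expect_equal(opt$maximum, 46.0, tolerance = 0.02)
})

test_that("without flow the uniform equilibrium is stationary", {
  p <- pde_params(D = 0.1, k_off = 0.005, t_flow = 5000, t_post = 5000,
                  dt_out = 500, velocity = function(x) 0 * x)
  sol <- solve_pde(p)
  Astar <- 1.56 / (1 + 0.174)
  expect_equal(Astar, 1.3288, tolerance = 1e-4)
  expect_lt(max(abs(sol$A - Astar)), 1e-6 * Astar)
})

test_that("mass is closed to solver tolerance at all times", {
  sol <- solve_pde(pde_params(t_post = 500, dt_out = 10))
  closure <- 0.174 * rowMeans(sol$A) + sol$A_cyt
  expect_lt(max(abs(closure - 1.56)) / 1.56, 1e-6)
  ## and for the two-state solver
  ts <- solve_two_state(pde_params(t_flow = 200, t_post = 0, dt_out = 20),
                        k_off_fast = 1, k_off_slow = 0.001,
                        fraction_fast = 0.5)
  closure2 <- 0.174 * (rowMeans(ts$A_fast) + rowMeans(ts$A_slow)) + ts$A_cyt
  expect_lt(max(abs(closure2 - 1.56)) / 1.56, 1e-6)
})

test_that("concentrations stay non-negative and ASI decays monotonically after flow", {
  sol <- solve_pde(pde_params(D = 0.1, k_off = 0.005, t_post = 1000,
                              dt_out = 10))
  expect_true(all(sol$A >= 0))
  m <- compute_metrics(sol)
  post <- m$times > 500
  expect_true(all(diff(m$ASI[post]) < 1e-9))
  ## and relaxes towards uniformity
  expect_lt(m$ASI[length(m$ASI)], 0.2 * m$peak_ASI)
})

test_that("metric conventions behave as documented", {
  sol <- solve_pde(pde_params(t_post = 0, dt_out = 25))
  m_res <- compute_metrics(sol)
  m_met <- compute_metrics(sol, convention = "methods")
  expect_equal(m_met$peak_ASI, 2 * m_res$peak_ASI, tolerance = 1e-12)
  expect_equal(m_met$peak_depletion, 1 - m_res$peak_depletion,
               tolerance = 1e-12)
  ## uniform profile: ASI = 0, depletion = 0 under the default convention
  p0 <- pde_params(t_flow = 10, t_post = 0, dt_out = 5,
                   velocity = function(x) 0 * x)
  m0 <- compute_metrics(solve_pde(p0))
  expect_equal(m0$peak_ASI, 0, tolerance = 1e-9)
  expect_equal(m0$peak_depletion, 0, tolerance = 1e-9)
})

test_that("a cleared posterior gives the printed metric maxima", {
  ## synthetic solution with P_pole = 0: ASI = 0.5 and depletion = 1.0
  sol <- solve_pde(pde_params(t_flow = 10, t_post = 0, dt_out = 5))
  sol$A <- matrix(rep(c(rep(2, 200), rep(0, 200)), each = nrow(sol$A)),
                  nrow = nrow(sol$A))
  m <- compute_metrics(sol)
  expect_equal(m$peak_ASI, 0.5)
  expect_equal(m$peak_depletion, 1.0)
})

test_that("halving the grid changes peak ASI by less than 1%", {
  m400 <- compute_metrics(solve_pde(pde_params(t_post = 0, dt_out = 25)))
  m200 <- compute_metrics(solve_pde(pde_params(n_grid = 200L, t_post = 0,
                                               dt_out = 25)))
  expect_lt(abs(m200$peak_ASI - m400$peak_ASI) / m400$peak_ASI, 0.01)
})

test_that("adaptive RK and lsoda integrators agree at the reference set", {
  m_l <- compute_metrics(solve_pde(pde_params(t_post = 0, dt_out = 50)))
  m_rk <- compute_metrics(solve_pde(pde_params(t_post = 0, dt_out = 50,
                                               method = "ode45")))
  expect_equal(m_rk$peak_ASI, m_l$peak_ASI, tolerance = 1e-5)
})

test_that("segregation weakens with k_off and vanishes for fast exchange", {
  ko <- c(1e-4, 1e-3, 1e-2, 1e-1, 1)
  sw <- sweep_pde(0.1, ko, pde_params(t_post = 0, dt_out = 50))
  expect_true(all(is.na(sw$error)))
  expect_true(all(diff(sw$peak_ASI) < 0))  # monotone decrease in k_off
  expect_lt(sw$peak_ASI[sw$k_off == 0.1], 0.05)
  expect_lt(sw$peak_ASI[sw$k_off == 1], 0.01)
})

test_that("decay half-times exceed the window when decay is too slow", {
  m <- compute_metrics(solve_pde(pde_params(D = 0.01, k_off = 1e-4,
                                            t_post = 100, dt_out = 10)))
  expect_equal(m$t_half_ASI, Inf)
})

test_that("two-state steady state weights membrane shares by residence time", {
  ## occupancy weights f/k_off: slow share 0.910 at fraction_fast 0.99
  ts <- solve_two_state(pde_params(k_off = 0.01, t_flow = 50, t_post = 0,
                                   dt_out = 25),
                        k_off_fast = 1, k_off_slow = 1e-3,
                        fraction_fast = 0.99)
  slow_share <- mean(ts$A_slow[1, ]) / mean(ts$A[1, ])
  expect_equal(slow_share, 0.910, tolerance = 1e-3)
  ## the share is stationary without flow
  ts0 <- solve_two_state(pde_params(k_off = 0.01, t_flow = 500, t_post = 0,
                                    dt_out = 100,
                                    velocity = function(x) 0 * x),
                         k_off_fast = 1, k_off_slow = 1e-3,
                         fraction_fast = 0.99)
  expect_lt(max(abs(ts0$fast_fraction - ts0$fast_fraction[1])), 1e-6)
})

test_that("equal off-rates collapse the two-state model to one species", {
  p <- pde_params(k_off = 0.005, t_flow = 200, t_post = 0, dt_out = 50)
  one <- solve_pde(p)
  two <- solve_two_state(p, k_off_fast = 0.005, k_off_slow = 0.005,
                         fraction_fast = 0.3)
  expect_equal(two$A, one$A, tolerance = 1e-6)
})

test_that("slow-dominated mixtures segregate like the slow species alone", {
  base <- pde_params(D = 0.1, k_off = 0.005, t_post = 0, dt_out = 100)
  m_slow <- compute_metrics(solve_pde(pde_params(D = 0.1, k_off = 0.005,
                                                 t_post = 0, dt_out = 100)))
  two <- solve_two_state(base, k_off_fast = 1, k_off_slow = 0.005,
                         fraction_fast = 0.05)
  m_two <- compute_metrics(two)
  expect_equal(m_two$peak_ASI, m_slow$peak_ASI, tolerance = 0.05)
})

test_that("parameter validation rejects impossible configurations", {
  expect_error(pde_params(rho_A = 0), "rho_A")
  expect_error(pde_params(n_grid = 4), "n_grid")
  expect_error(solve_two_state(pde_params(), k_off_fast = 0.001,
                               k_off_slow = 0.1), "k_off_fast")
  expect_error(solve_two_state(pde_params(), fraction_fast = 1.5),
               "fraction_fast")
})
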