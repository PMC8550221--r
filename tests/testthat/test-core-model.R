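test_that("rate matrix has series structure and eigenvalues -k_i", {
  A <- build_system_matrix(pool_params(0.1, 0.01, 0.1))
  expect_equal(A, matrix(c(-0.1, 0.01, 0, -0.01), 2, 2))
  expect_true(all(colSums(A) <= 1e-15))           # mass never created

  A0 <- build_system_matrix(pool_params(0.1, 0.01, 0))
  expect_equal(A0, diag(c(-0.1, -0.01)))

  p3 <- pool_params(0.2, 0.01, 0.3, 0.5, k3 = 1e-4, a32 = 0.2)
  A3 <- build_system_matrix(p3)
  expect_equal(sort(Re(eigen(A3)$values)), sort(-c(0.2, 0.01, 1e-4)))
  expect_true(all(colSums(A3) <= 1e-15))
})

test_that("parameter invariants are enforced", {
  expect_error(pool_params(0.01, 0.1, 0.1), "k1 > k2")
  expect_error(pool_params(0.1, 0.01, 1.5), "a21")
  expect_error(pool_params(0.1, 0.01, 0.1, -0.1), "slowProp")
  expect_error(pool_params(0.1, 0.01, 0.1, 0.5, k3 = 0.02, a32 = 0.1),
               "k3")
  expect_silent(pool_params(0.01, 0.1, 2, check = FALSE))
})

test_that("initial state splits stock by slowProp and converts deltas", {
  s <- initial_state(30, pool_params(0.1, 0.01, 0.1, 0.5), 0, 0, 1958)
  expect_equal(s$C, c(15, 15))

  s2 <- initial_state(30, pool_params(0.1, 0.01, 0.1, 1), 0, 0, 1958)
  expect_equal(s2$C[1], 0)

  s3 <- initial_state(30, pool_params(0.1, 0.01, 0.1, 0.52), 150, -42, 1958)
  expect_equal(s3$C, c(14.4, 15.6))
  expect_equal(s3$F, c(1.150, 0.958))

  expect_error(initial_state(-1, demo_params(), 0, 0, 1958), "non-negative")
})

test_that("closed system conserves mass", {
  # a21 = 1, k2 ~ 0, lambda = 0, no inputs: total stock is invariant
  p <- pool_params(0.1, 1e-12, 1, 0.5, check = FALSE)
  st <- model_state(2000, c(10, 5), c(1, 1))
  tr <- simulate_pools(p, 0, const_atm(), st, 2050, lambda = 0)
  expect_lt(max(abs(tr$total_stock - 15)), 1e-6)
})

test_that("uncoupled fast pool matches the one-pool closed form", {
  p <- pool_params(0.1, 0.01, 0, 0, check = FALSE)
  st <- model_state(2000, c(3, 0), c(1, 1))
  tr <- simulate_pools(p, 2, const_atm(), st, 2040)
  exact <- 2 / 0.1 + (3 - 2 / 0.1) * exp(-0.1 * (tr$time - 2000))
  expect_lt(max(abs(tr$C1 - exact) / exact), 1e-6)
})

test_that("long simulation converges to the steady-state stocks", {
  p <- pool_params(0.11, 0.005, 0.09, 0.5)
  ss <- steady_state_stocks(p, 1.9)
  st <- model_state(0, c(10, 20), c(1, 1))
  tr <- simulate_pools(p, 1.9, const_atm(), st, 3000)
  expect_lt(abs(tail(tr$C1, 1) - ss[["C1"]]) / ss[["C1"]], 1e-6)
  expect_lt(abs(tail(tr$C2, 1) - ss[["C2"]]) / ss[["C2"]], 1e-6)
})

test_that("mass balance holds step-by-step and dt refinement is converged", {
  p <- demo_params()
  atm <- synth_atmosphere()
  st <- initial_state(40, p, 100, -42, 1985)
  inputs <- input_series(1985:2010, 3)
  tr <- simulate_pools(p, inputs, atm, st, 2010)
  # d(C1+C2)/dt = I - (1-a21) k1 C1 - k2 C2, checked by finite differences
  dt <- diff(tr$time[1:2])
  mid <- function(x) (x[-1] + x[-length(x)]) / 2
  lhs <- diff(tr$total_stock) / dt
  rhs <- 3 - (1 - p$a21) * p$k1 * mid(tr$C1) - p$k2 * mid(tr$C2)
  expect_lt(max(abs(lhs - rhs)), 1e-3)

  tr2 <- simulate_pools(p, inputs, atm, st, 2010, dt = 1 / 24)
  expect_lt(abs(tail(tr2$total_stock, 1) - tail(tr$total_stock, 1)) /
              tail(tr$total_stock, 1), 1e-3)
})

test_that("pool ratios relax to the atmosphere when decay is off", {
  p <- pool_params(0.3, 0.05, 0.5, 0.5)
  st <- model_state(0, c(5, 5), c(0.5, 2))
  tr <- simulate_pools(p, 1, const_atm(0), st, 400, lambda = 0)
  expect_equal(tail(tr$F1, 1), 1, tolerance = 1e-8)
  expect_equal(tail(tr$F2, 1), 1, tolerance = 1e-3)
})

test_that("bulk delta stays inside the envelope of pools and atmosphere", {
  p <- demo_params()
  atm <- synth_atmosphere()
  st <- initial_state(40, p, -10, -42, 1958)
  tr <- simulate_pools(p, 2.5, atm, st, 2010)
  lo <- min(-42, -10, atm$delta14c)
  hi <- max(-42, -10, atm$delta14c)
  expect_true(all(tr$delta14c_bulk >= lo - 1e-9))
  expect_true(all(tr$delta14c_bulk <= hi + 1e-9))
})

test_that("bulk delta is the stock-weighted pool mean", {
  st <- model_state(0, c(10, 30), ratio_from_delta(c(100, -40)))
  expect_equal(bulk_delta14c(st), -5)
  st2 <- model_state(0, c(7, 0), ratio_from_delta(c(33, -40)))
  expect_equal(bulk_delta14c(st2), 33)
  st3 <- model_state(0, c(4, 4), ratio_from_delta(c(12, 12)))
  expect_equal(bulk_delta14c(st3), 12)
  expect_error(bulk_delta14c(model_state(0, c(0, 0), c(1, 1))), "zero total")
})

test_that("one-pool spin-up equilibrium matches k/(k+lambda)", {
  atm <- const_atm(0)
  for (k in c(0.005, 0.05, 0.2)) {
    expect_equal(one_pool_equilibrium_ratio(k, atm, 1990),
                 k / (k + LAMBDA_14C), tolerance = 1e-6)
  }
  expect_equal(delta_from_ratio(one_pool_equilibrium_ratio(0.005, atm, 1990)),
               -23.6, tolerance = 0.01)
  # k = lambda halves the ratio (needs a longer spin-up to converge)
  expect_equal(one_pool_equilibrium_ratio(LAMBDA_14C, atm, 1990,
                                          spinup_years = 2e5), 0.5,
               tolerance = 1e-6)
  expect_warning(one_pool_equilibrium_ratio(LAMBDA_14C, atm, 1990),
                 "spin-up")
})

test_that("a very fast pool tracks the atmosphere", {
  atm <- synth_atmosphere()
  for (yr in c(1963, 1975, 1995)) {
    expect_equal(one_pool_equilibrium_ratio(10, atm, yr),
                 atm_ratio_at(atm, yr), tolerance = 0.02)
  }
})

test_that("window conventions for initial pool deltas", {
  atm <- synth_atmosphere()
  p <- demo_params()
  d1 <- initial_pool_deltas(p, atm, 1958, "window1")
  expect_identical(d1[["slow"]], -42)
  d2 <- initial_pool_deltas(p, const_atm(0), 1985, "window2")
  expect_equal(ratio_from_delta(d2[["fast"]]),
               p$k1 / (p$k1 + LAMBDA_14C), tolerance = 1e-6)
  expect_equal(ratio_from_delta(d2[["slow"]]),
               p$k2 / (p$k2 + LAMBDA_14C), tolerance = 1e-6)
  # near-equal rates give near-equal pool deltas
  pe <- pool_params(0.0500001, 0.05, 0.1, 0.5, check = FALSE)
  de <- initial_pool_deltas(pe, atm, 1985, "window2")
  expect_equal(de[["fast"]], de[["slow"]], tolerance = 1e-3)
})

test_that("trajectories export to CSV at full precision", {
  p <- demo_params()
  st <- initial_state(40, p, 100, -42, 1985)
  tr <- simulate_pools(p, 3, const_atm(100), st, 1990)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- read.csv(path)
  expect_equal(back$total_stock, tr$total_stock, tolerance = 1e-10)
  expect_equal(back$delta14C_bulk, tr$delta14c_bulk, tolerance = 1e-9)
})
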